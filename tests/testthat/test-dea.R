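test_that("single-input single-output CCR matches the closed-form ratio", {
  p <- dmu_panel(c(1, 2), c(1, 1), ids = c("A", "B"))
  expect_equal(solve_envelopment(p, "A", "ccr")$theta, 1.0, tolerance = 1e-9)
  expect_equal(solve_envelopment(p, "B", "ccr")$theta, 0.5, tolerance = 1e-9)

  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    x <- runif(n, 1, 10); y <- runif(n, 1, 10)
    p <- dmu_panel(x, y)
    for (j in seq_len(n)) {
      expect_equal(solve_envelopment(p, j, "ccr")$theta,
                   oracle_theta_1x1(x, y, j), tolerance = 1e-9)
    }
  }
})

test_that("identical DMUs are all efficient with zero slacks", {
  p <- dmu_panel(matrix(3, 4, 2), matrix(5, 4, 2))
  d <- dea(p)
  expect_equal(d$scores$oe, rep(1, 4))
  expect_equal(d$scores$te, rep(1, 4))
  expect_true(all(abs(d$ccr$slack_input) < 1e-9))
  expect_true(all(abs(d$ccr$slack_output) < 1e-9))
  expect_equal(d$scores$classification, rep("efficient", 4))
})

test_that("a 2-input instance reproduces the vertex-enumeration value", {
  X <- rbind(c(2, 4), c(4, 2), c(4, 4)); Y <- cbind(c(1, 1, 1))
  p <- dmu_panel(X, Y, ids = c("A", "B", "C"))
  th <- solve_envelopment(p, "C", "ccr")$theta
  expect_lt(th, 1)
  expect_equal(th, oracle_theta(X, Y, 3), tolerance = 1e-9)
  expect_equal(th, 0.75)   # 0.5A + 0.5B uses (3,3) against C's (4,4)
})

test_that("solver agrees with the multiplier-form oracle on random panels", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:5, 1); m <- sample(1:2, 1); s <- sample(1:2, 1)
    p <- random_small_panel(n, m, s)
    j <- sample(n, 1)
    expect_equal(solve_envelopment(p, j, "ccr")$theta,
                 oracle_theta(p$X, p$Y, j, vrs = FALSE), tolerance = 1e-7)
    expect_equal(solve_envelopment(p, j, "bcc")$theta,
                 oracle_theta(p$X, p$Y, j, vrs = TRUE), tolerance = 1e-7)
  }
})

test_that("CCR efficiency never exceeds BCC efficiency", {
  set.seed(29)
  for (i in 1:10) {
    p <- random_small_panel(sample(4:8, 1), 2, 2)
    d <- dea(p)
    expect_true(all(d$scores$oe <= d$scores$te + 1e-7))
  }
})

test_that("theta is units-invariant and slacks scale with the rescaled input", {
  set.seed(37)
  p <- random_small_panel(6, 2, 1)
  d1 <- dea(p, model = "ccr")
  X2 <- p$X; X2[, 1] <- X2[, 1] * 100
  d2 <- dea(dmu_panel(X2, p$Y), model = "ccr")
  expect_equal(d2$scores$oe, d1$scores$oe, tolerance = 1e-7)
  expect_equal(d2$ccr$slack_input[, 1], 100 * d1$ccr$slack_input[, 1],
               tolerance = 1e-6)
  expect_equal(d2$ccr$slack_input[, 2], d1$ccr$slack_input[, 2],
               tolerance = 1e-7)
})

test_that("adding a radially dominated DMU leaves existing scores unchanged", {
  set.seed(41)
  p <- random_small_panel(5, 2, 2)
  d1 <- dea(p, model = "ccr")
  Xb <- rbind(p$X, 1.5 * p$X[2, ])   # strictly worse copy of DMU 2
  Yb <- rbind(p$Y, p$Y[2, ])
  d2 <- dea(dmu_panel(Xb, Yb), model = "ccr")
  expect_equal(d2$scores$oe[1:5], d1$scores$oe, tolerance = 1e-7)
  expect_equal(d2$scores$oe[6], d1$scores$oe[2] / 1.5, tolerance = 1e-7)
})

test_that("phase 2 finds the maximal slack of a weakly efficient DMU", {
  # B matches A's output with the same first input but double the second:
  # theta = 1 yet one unit of input-2 slack remains
  p <- dmu_panel(rbind(c(1, 1), c(1, 2)), cbind(c(1, 1)), ids = c("A", "B"))
  sol <- solve_envelopment(p, "B", "ccr")
  expect_equal(sol$theta, 1, tolerance = 1e-9)
  expect_equal(unname(sol$slack_input), c(0, 1), tolerance = 1e-9)
  d <- dea(p)
  expect_equal(d$scores$classification[2], "weakly_efficient")
})

test_that("the literal epsilon objective reproduces the two-phase solution", {
  set.seed(43)
  p <- random_small_panel(5, 2, 1)
  for (j in 1:5) {
    a <- solve_envelopment(p, j, "ccr")
    b <- solve_envelopment(p, j, "ccr", epsilon = 1e-8)
    expect_equal(b$theta, a$theta, tolerance = 1e-6)
  }
})

test_that("efficiency decomposition reproduces printed SE values", {
  expect_equal(efficiency_decomposition(0.883, 0.911), 0.969)
  expect_equal(efficiency_decomposition(0.835, 0.857), 0.974)
  expect_equal(efficiency_decomposition(1.0, 1.0), 1.0)
  expect_error(efficiency_decomposition(0.5, 0), class = "nhrdea_invalid_input")
  expect_error(efficiency_decomposition(0.9, 0.8), class = "nhrdea_invalid_input")
})

test_that("returns-to-scale labels follow the CCR lambda sum", {
  expect_equal(classify_rts(1.0), "crs")
  expect_equal(classify_rts(0.80), "irs")
  expect_equal(classify_rts(1.30), "drs")
  expect_equal(classify_rts(0.7, theta_ccr = 1, theta_bcc = 1), "crs")
  expect_equal(classify_rts(0.8, lambda_sum_range = c(0.8, 1.1)), "crs")
  expect_error(classify_rts(-0.1), class = "nhrdea_invalid_input")
})

test_that("efficiency classification covers the decomposition patterns", {
  expect_equal(classify_efficiency(1, 1, 1, slacks = 0), "efficient")
  expect_equal(classify_efficiency(0.858, 1, 0.858), "scale_inefficient")
  expect_equal(classify_efficiency(0.835, 0.857, 0.974),
               "tech_and_scale_inefficient")
  expect_equal(classify_efficiency(0.9, 0.9, 1), "tech_inefficient")
  expect_equal(classify_efficiency(1, 1, 1, slacks = 2), "weakly_efficient")
  expect_error(classify_efficiency(0.9, 0.5, 0.5),
               class = "nhrdea_consistency_error")
})

test_that("projection targets apply radial and slack-only modes", {
  pt <- projection_targets(100, 50, theta = 1, s_minus = 0, s_plus = 0)
  expect_equal(pt$inputs, 100); expect_equal(pt$outputs, 50)

  pt <- projection_targets(100, 50, theta = 0.835, s_minus = 19.396,
                           s_plus = 2.194, mode = "slack_only")
  expect_equal(pt$inputs, 80.604)
  expect_equal(pt$outputs, 52.194)

  pt <- projection_targets(100, 50, theta = 0.835, s_minus = 19.396,
                           s_plus = 2.194, mode = "standard")
  expect_equal(pt$inputs, 64.104)
  expect_false(pt$negative_flag)

  expect_warning(
    pt <- projection_targets(10, 5, theta = 0.5, s_minus = 9, s_plus = 0),
    "negative")
  expect_true(pt$negative_flag)
})

test_that("summaries report means and counts", {
  one <- data.frame(oe = 1, te = 1, se = 1, rts = "crs",
                    classification = "efficient")
  s <- summarize_dea(one)
  expect_equal(unname(s$means), c(1, 1, 1))
  expect_equal(s$n_efficient, 1); expect_equal(s$n_inefficient, 0)
  expect_error(summarize_dea(one[0, ]), class = "nhrdea_invalid_input")
})

test_that("panels reject nonpositive data unless substitution is requested", {
  expect_error(dmu_panel(c(1, 0), c(1, 1)), class = "nhrdea_invalid_input")
  p <- dmu_panel(c(1, 0), c(1, 1), zero_substitute = 1e-6)
  expect_equal(p$X[2, 1], 1e-6)
})
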