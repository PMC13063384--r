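test_that("response rate handles full, partial and empty returns", {
  expect_equal(response_rate(17, 17), 100.0)
  expect_equal(response_rate(17, 16), 94.1)
  expect_equal(response_rate(10, 0), 0.0)
  expect_error(response_rate(0, 0), class = "nhrdea_invalid_input")
  expect_error(response_rate(10, 11), class = "nhrdea_invalid_input")
})

test_that("judgment-basis coefficient sums the printed source weights", {
  all_high <- c(practical_experience = "high", theoretical_analysis = "high",
                literature = "high", intuition = "high")
  expect_equal(judgment_basis(all_high), 1.0)
  lows <- c(practical_experience = "low", theoretical_analysis = "low",
            literature = "low", intuition = "low")
  expect_equal(judgment_basis(lows), 0.6)
  mixed <- c(practical_experience = "medium", theoretical_analysis = "high",
             literature = "low", intuition = "high")
  expect_equal(judgment_basis(mixed), 0.9)
  # literature/intuition weight is fixed at 0.1 regardless of level
  for (lev in c("high", "medium", "low")) {
    v <- lows; v["literature"] <- lev
    expect_equal(judgment_basis(v), 0.6)
  }
  expect_error(judgment_basis(lows[-1]), class = "nhrdea_invalid_input")
  bad <- all_high; bad["practical_experience"] <- "extreme"
  expect_error(judgment_basis(bad), class = "nhrdea_invalid_input")
})

test_that("authority coefficient is the half-up rounded mean of Ca and Cs", {
  expect_equal(authority_coefficient(0.98, 0.86), 0.92)
  expect_equal(authority_coefficient(0.94, 0.85), 0.90)
  expect_equal(authority_coefficient(1.0, 1.0), 1.0)
  expect_error(authority_coefficient(1.2, 0.5), class = "nhrdea_invalid_input")
  expect_error(authority_coefficient(0.5, -0.1), class = "nhrdea_invalid_input")
})

test_that("familiarity levels map to the five-point score scale", {
  expect_equal(familiarity_score(c("very_familiar", "moderate", "very_unfamiliar")),
               c(1.0, 0.6, 0.2))
  expect_error(familiarity_score("expert"), class = "nhrdea_invalid_input")
})

test_that("item statistics use the sample SD and count full scores", {
  s <- item_statistics(c(5, 5, 5, 5))
  expect_equal(s$mean, 5); expect_equal(s$cv, 0)
  expect_equal(s$full_score_rate, 1)

  s <- item_statistics(c(5, 5, 4, 4))
  expect_equal(s$mean, 4.5)
  expect_equal(s$sd, sd(c(5, 5, 4, 4)))  # n-1 denominator
  expect_equal(round(s$sd, 3), 0.577)
  expect_equal(round(s$cv, 3), 0.128)
  expect_equal(s$full_score_rate, 0.5)

  s <- item_statistics(c(1, 5))
  expect_equal(s$mean, 3); expect_equal(s$full_score_rate, 0.5)

  expect_error(item_statistics(5), class = "nhrdea_insufficient_data")
  expect_error(item_statistics(c(0, 3)), class = "nhrdea_invalid_input")
})

test_that("CV is invariant under a common positive scaling of the scores", {
  # c(1,2) and c(2,4) both live on the Likert scale and differ by x2
  expect_equal(item_statistics(c(1, 2, 1, 2))$cv,
               item_statistics(c(2, 4, 2, 4))$cv)
  expect_equal(item_statistics(c(1, 1, 2))$cv, item_statistics(c(2, 2, 4))$cv)
})

test_that("full-score rate is invariant under permutation of the column", {
  set.seed(42)
  for (i in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    expect_equal(item_statistics(sample(x))$full_score_rate,
                 item_statistics(x)$full_score_rate)
  }
})

test_that("Kendall's W is 1 for identical rankings and 0 for reversed pairs", {
  ident <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(kendalls_w(ident, tie_correction = TRUE)$w, 1)
  expect_equal(kendalls_w(ident, tie_correction = FALSE)$w, 1)
  # two exactly reversed rankings: every rank sum equals (n+1), so the
  # rank-variance numerator S is 0 and W = 0
  rev2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(kendalls_w(rev2, tie_correction = FALSE)$w, 0)
  expect_equal(kendalls_w(rev2)$chi2, 0)
})

test_that("tie-corrected W agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:5) {
    sc <- matrix(sample(1:5, 6 * 9, replace = TRUE), 6, 9)
    mine <- kendalls_w(sc, tie_correction = TRUE)
    ref <- vegan::kendall.global(t(sc))$Concordance_analysis
    expect_equal(mine$w, unname(ref["W", 1]), tolerance = 1e-10)
    expect_equal(mine$chi2, unname(ref["Chi2", 1]), tolerance = 1e-10)
  }
})

test_that("W is invariant to expert relabeling and rank-preserving transforms", {
  set.seed(5)
  sc <- matrix(sample(1:5, 5 * 8, replace = TRUE), 5, 8)
  w0 <- kendalls_w(sc)$w
  expect_equal(kendalls_w(sc[sample(5), ])$w, w0)
  # a strictly increasing transform of one expert's scores keeps ranks
  sc2 <- sc; sc2[3, ] <- exp(sc2[3, ])
  expect_equal(kendalls_w(sc2)$w, w0)
})

test_that("uncorrected chi-squared identity holds exactly", {
  set.seed(9)
  for (i in 1:10) {
    m <- sample(3:10, 1); n <- sample(4:15, 1)
    sc <- matrix(sample(1:5, m * n, replace = TRUE), m, n)
    w <- kendalls_w(sc, tie_correction = FALSE)
    expect_equal(w$chi2, m * (n - 1) * w$w, tolerance = 1e-12)
    expect_equal(w$df, n - 1)
    expect_gte(w$w, 0); expect_lte(w$w, 1)
  }
})

test_that("an all-tied matrix is degenerate under tie correction", {
  flat <- matrix(3, 4, 5)
  expect_error(kendalls_w(flat, tie_correction = TRUE),
               class = "nhrdea_degenerate")
})

test_that("rating matrix validation rejects bad input", {
  expect_error(rating_matrix(matrix(c(1, 2, NA, 4), 2)),
               class = "nhrdea_invalid_input")
  expect_error(rating_matrix(matrix(c(1, 2, 6, 4), 2)),
               class = "nhrdea_invalid_input")
  expect_error(rating_matrix(matrix(1:4, 1)), class = "nhrdea_insufficient_data")
})

test_that("item metadata derives and checks hierarchy levels", {
  meta <- item_meta(c("1", "1.1", "1.1.1"), c("a", "b", "c"), c("S", "S", "P"))
  expect_equal(meta$level, c(1L, 2L, 3L))
  expect_error(item_meta("1.1", "a", "S", level = 3),
               class = "nhrdea_invalid_input")
  expect_error(item_meta("1", "a", "X"), class = "nhrdea_invalid_input")
})

test_that("screening applies every enabled criterion with reasons", {
  st <- data.frame(id = c("a", "b"),
                   mean = c(3.4, 4.9), cv = c(0.1, 0.05),
                   full_score_rate = c(0.9, 0.9))
  out <- screen_delphi_items(st)
  expect_false(out$retained[1]); expect_equal(out$reason[1], "mean")
  expect_true(out$retained[2]); expect_equal(out$reason[2], "")

  # planted violations: 3 of 10 items each break exactly one criterion
  st10 <- data.frame(
    mean = c(rep(4.5, 7), 3.0, 4.5, 4.5),
    cv = c(rep(0.10, 7), 0.10, 0.30, 0.10),
    full_score_rate = c(rep(0.80, 7), 0.80, 0.80, 0.50))
  out10 <- screen_delphi_items(st10)
  expect_equal(sum(out10$retained), 7)
  expect_equal(out10$reason[8:10], c("mean", "cv", "fsr"))

  # empty input -> empty output
  expect_equal(nrow(screen_delphi_items(st10[0, ])), 0)
})

test_that("relaxing any screening threshold never removes a retained item", {
  set.seed(21)
  st <- data.frame(mean = runif(40, 2.5, 5), cv = runif(40, 0, 0.5),
                   full_score_rate = runif(40))
  base <- screen_delphi_items(st, screening_thresholds(3.5, 0.25, 0.7))
  relaxed <- list(screening_thresholds(3.0, 0.25, 0.7),
                  screening_thresholds(3.5, 0.40, 0.7),
                  screening_thresholds(3.5, 0.25, 0.5),
                  screening_thresholds(NA, NA, NA))
  for (th in relaxed) {
    out <- screen_delphi_items(st, th)
    expect_true(all(out$retained[base$retained]))
  }
})

test_that("the strict threshold preset raises the mean cutoff to 4", {
  th <- screening_thresholds(preset = "strict")
  expect_equal(th$mean_min, 4.0)
  st <- data.frame(mean = 3.8, cv = 0.1, full_score_rate = 0.9)
  expect_true(screen_delphi_items(st)$retained)
  expect_false(screen_delphi_items(st, th)$retained)
})
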