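# Independent oracles for the envelopment solver.
#
# The multiplier (ratio) form of the input-oriented DEA program is
#   max u'y0  s.t.  v'x0 = 1,  u'y_j - v'x_j <= 0 (all j),  u, v >= 0
# (BCC adds a free intercept u0 inside the ratio constraints and the
# objective).  The program is bounded (u'y0 <= v'x0 = 1 via DMU0's own
# constraint) and its feasible set is pointed, so the optimum sits at a
# vertex: enumerate every candidate vertex as the solution of a square
# system of active constraints and take the best feasible one.  This
# path shares no code with the package's simplex.

oracle_theta <- function(X, Y, j, vrs = FALSE, tol = 1e-7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  nv <- m + s + as.integer(vrs)          # v, u [, u0]
  # rows of the constraint list: first the equality, then inequalities
  # ratio constraints  u'y_k - v'x_k (+u0) <= 0, then v >= 0, u >= 0
  eq <- c(X[j, ], rep(0, s + as.integer(vrs)))
  ineq <- matrix(0, n + m + s, nv)
  for (k in seq_len(n)) {
    ineq[k, ] <- c(-X[k, ], Y[k, ], if (vrs) 1)
  }
  for (i in seq_len(m)) ineq[n + i, i] <- -1          # -v_i <= 0
  for (r in seq_len(s)) ineq[n + m + r, m + r] <- -1  # -u_r <= 0
  obj <- c(rep(0, m), Y[j, ], if (vrs) 1)

  best <- -Inf
  combs <- utils::combn(nrow(ineq), nv - 1)
  for (ci in seq_len(ncol(combs))) {
    A <- rbind(eq, ineq[combs[, ci], , drop = FALSE])
    b <- c(1, rep(0, nv - 1))
    z <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(z)) next
    if (any(ineq %*% z > tol)) next
    val <- sum(obj * z)
    if (val > best) best <- val
  }
  best
}

# closed form for single-input single-output CCR
oracle_theta_1x1 <- function(x, y, j) (y[j] / x[j]) / max(y / x)

random_small_panel <- function(n_dmu, m, s) {
  dmu_panel(matrix(runif(n_dmu * m, 1, 10), n_dmu),
            matrix(runif(n_dmu * s, 1, 10), n_dmu))
}
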