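# Dense two-phase primal simplex for the envelopment programs.
#
# DEA programs are small but systematically degenerate: right-hand
# sides contain structural zeros, optimal bases are non-unique, and
# planted-frontier test panels make constraint blocks rank-deficient.
# General-purpose simplex routines available to this package fail on
# exactly those cases (artificial variables stuck in a degenerate
# stage-1 basis; singular basis factorizations), so the package carries
# its own solver: Bland's pivoting rule guarantees termination under
# degeneracy, and redundant rows left over from phase 1 are detected
# and dropped.
#
# Solves  min/max  c'x  s.t.  A x = b, x >= 0.

.simplex_pivot <- function(T, basis, r, j) {
  T[r, ] <- T[r, ] / T[r, j]
  for (i in seq_len(nrow(T))) {
    if (i != r && abs(T[i, j]) > 0) T[i, ] <- T[i, ] - T[i, j] * T[r, ]
  }
  basis[r] <- j
  list(T = T, basis = basis)
}

# run Bland-rule iterations on tableau T with cost vector cost over
# columns `allowed`; returns the final tableau and basis
.simplex_iterate <- function(T, basis, cost, allowed, tol = 1e-9,
                             max_iter = 10000L) {
  m <- nrow(T); ncols <- ncol(T) - 1L
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    rc <- cost[seq_len(ncols)] - as.vector(cb %*% T[, seq_len(ncols), drop = FALSE])
    enter <- 0L
    for (j in allowed) {            # Bland: smallest eligible index enters
      if (rc[j] < -tol && !(j %in% basis)) { enter <- j; break }
    }
    if (enter == 0L) return(list(T = T, basis = basis, status = "optimal"))
    col <- T[, enter]
    rows <- which(col > tol)
    if (!length(rows)) return(list(T = T, basis = basis, status = "unbounded"))
    ratio <- T[rows, ncols + 1L] / col[rows]
    best <- rows[ratio <= min(ratio) + tol]
    leave <- best[which.min(basis[best])]  # Bland: smallest basis index leaves
    p <- .simplex_pivot(T, basis, leave, enter)
    T <- p$T; basis <- p$basis
  }
  list(T = T, basis = basis, status = "iteration_limit")
}

# obj, Aeq (m x n), beq: solve min (or max) obj'x s.t. Aeq x = beq, x >= 0
.simplex_solve <- function(obj, Aeq, beq, maximize = FALSE, tol = 1e-9) {
  Aeq <- as.matrix(Aeq)
  m <- nrow(Aeq); n <- ncol(Aeq)
  stopifnot(length(obj) == n, length(beq) == m)
  flip <- beq < 0
  Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
  beq[flip] <- -beq[flip]
  cost <- if (maximize) -obj else obj

  # phase 1: artificial basis, minimize sum of artificials
  T <- cbind(Aeq, diag(m), beq)
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(1, m))
  r1 <- .simplex_iterate(T, basis, c1, allowed = seq_len(n + m), tol = tol)
  if (r1$status != "optimal") {
    stop_solver(paste("phase-1 simplex failed:", r1$status))
  }
  T <- r1$T; basis <- r1$basis
  if (sum(c1[basis] * T[, ncol(T)]) > 1e-7) {
    stop_solver("linear program is infeasible")
  }
  # drive artificials out of the basis; rows that cannot pivot are redundant
  drop_rows <- integer()
  for (i in seq_along(basis)) {
    if (basis[i] > n) {
      j <- which(abs(T[i, seq_len(n)]) > tol & !(seq_len(n) %in% basis))
      if (length(j)) {
        p <- .simplex_pivot(T, basis, i, j[1])
        T <- p$T; basis <- p$basis
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
  }
  if (length(drop_rows)) {
    T <- T[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  # phase 2 on the original columns only
  c2 <- c(cost, rep(0, m))
  r2 <- .simplex_iterate(T, basis, c2, allowed = seq_len(n), tol = tol)
  if (r2$status == "unbounded") stop_solver("linear program is unbounded")
  if (r2$status != "optimal") {
    stop_solver(paste("phase-2 simplex failed:", r2$status))
  }
  T <- r2$T; basis <- r2$basis
  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- T[inb, ncol(T)]
  x[x < 0 & x > -1e-9] <- 0
  val <- sum(obj * x)
  list(value = val, x = x)
}
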