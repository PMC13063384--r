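# Input-oriented CCR/BCC envelopment DEA with two-phase slack
# maximization, efficiency decomposition, returns-to-scale labels and
# projection targets.
#
# Phase 1 solves  min theta  s.t.  X'lambda + S- = theta x0,
# Y'lambda - S+ = y0, lambda,S>=0 (BCC adds sum(lambda)=1); phase 2
# fixes theta* and maximizes the slack sum.  The non-Archimedean epsilon
# of the classical single-LP formulation is available via `epsilon`.

#' DMU input-output panel
#'
#' Validates and wraps the data of a DEA evaluation: one row per
#' decision-making unit, strictly positive input and output columns.
#' Nonpositive entries are rejected (DEA envelopment models require
#' positive data) unless a small-constant substitution is explicitly
#' requested.
#'
#' @param inputs numeric matrix or data.frame, rows DMUs, columns input
#'   indicators; strictly positive.
#' @param outputs numeric matrix or data.frame of output indicators.
#' @param ids optional DMU identifiers (default row numbers).
#' @param zero_substitute optional positive constant replacing
#'   nonpositive cells; off by default.
#' @return an object of class `dmu_panel` with elements `X` (n x m),
#'   `Y` (n x s), `ids`, and the recorded [dea_rule_of_thumb()] verdict.
#' @export
dmu_panel <- function(inputs, outputs, ids = NULL, zero_substitute = NULL) {
  X <- as.matrix(inputs); Y <- as.matrix(outputs)
  if (!is.numeric(X) || !is.numeric(Y) || anyNA(X) || anyNA(Y)) {
    stop_invalid("inputs and outputs must be numeric with no missing cells")
  }
  if (nrow(X) != nrow(Y)) stop_invalid("inputs and outputs must cover the same DMUs")
  if (nrow(X) < 2L) stop_insufficient("need at least 2 DMUs")
  if (!is.null(zero_substitute)) {
    if (!is.numeric(zero_substitute) || zero_substitute <= 0) {
      stop_invalid("zero_substitute must be a positive constant")
    }
    X[X <= 0] <- zero_substitute
    Y[Y <= 0] <- zero_substitute
  }
  if (any(X <= 0) || any(Y <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)
    if (!nrow(bad)) bad <- which(Y <= 0, arr.ind = TRUE)
    stop_invalid(sprintf(
      "all DEA data must be strictly positive (first offending cell: row %d, column %d)",
      bad[1, 1], bad[1, 2]))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  if (anyDuplicated(ids)) stop_invalid("DMU ids must be unique")
  if (is.null(colnames(X))) colnames(X) <- paste0("input", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("output", seq_len(ncol(Y)))
  rownames(X) <- rownames(Y) <- ids
  structure(list(X = X, Y = Y, ids = as.character(ids),
                 rule_of_thumb = dea_rule_of_thumb(nrow(X), ncol(X), ncol(Y))),
            class = "dmu_panel")
}

#' @export
print.dmu_panel <- function(x, ...) {
  cat(sprintf("DMU panel: %d units, %d inputs, %d outputs (rule of thumb %s)\n",
              nrow(x$X), ncol(x$X), ncol(x$Y),
              if (x$rule_of_thumb$feasible) "satisfied" else "violated"))
  invisible(x)
}

# thin wrapper over the package simplex; objective `obj` over x >= 0
# with equality constraints Aeq x = beq
.lp_solve <- function(obj, Aeq, beq, maximize = FALSE) {
  .simplex_solve(obj, Aeq, beq, maximize = maximize)
}

# constraint matrix for the envelopment program at DMU j.
# columns: [theta?] lambda(n) S-(m) S+(s); theta column present iff
# `with_theta`; otherwise theta enters the rhs as theta_fix.
.envelopment_constraints <- function(X, Y, j, vrs, with_theta, theta_fix = 1) {
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  nv <- n + m + s + as.integer(with_theta)
  rows <- m + s + as.integer(vrs)
  A <- matrix(0, rows, nv); b <- numeric(rows)
  off <- as.integer(with_theta)
  for (i in seq_len(m)) {
    if (with_theta) A[i, 1] <- -X[j, i]
    A[i, off + seq_len(n)] <- X[, i]
    A[i, off + n + i] <- 1
    b[i] <- if (with_theta) 0 else theta_fix * X[j, i]
  }
  for (r in seq_len(s)) {
    A[m + r, off + seq_len(n)] <- Y[, r]
    A[m + r, off + n + m + r] <- -1
    b[m + r] <- Y[j, r]
  }
  if (vrs) {
    A[m + s + 1, off + seq_len(n)] <- 1
    b[m + s + 1] <- 1
  }
  list(A = A, b = b, n = n, m = m, s = s, off = off)
}

#' Solve the envelopment program for one DMU
#'
#' Input-oriented radial efficiency of a single DMU under constant (CCR)
#' or variable (BCC) returns to scale.  By default the two-phase
#' procedure is used: phase 1 minimizes the radial score theta, phase 2
#' fixes theta at its optimum and maximizes the total slack, yielding
#' the max-slack solution the classical non-Archimedean formulation
#' targets.  Passing a small `epsilon` instead solves the literal
#' single-LP objective `theta - epsilon * (sum(S-) + sum(S+))`.
#'
#' @param panel a [dmu_panel()].
#' @param dmu DMU id or index to evaluate.
#' @param model `"ccr"` (constant returns) or `"bcc"` (variable returns).
#' @param tol numeric tolerance used when reporting exact efficiency.
#' @param epsilon optional non-Archimedean constant; `NULL` (default)
#'   selects the two-phase procedure.
#' @param lambda_range logical; also solve for the min/max of
#'   `sum(lambda)` over the optimal set (used for robust returns-to-scale
#'   labels under alternative optima).  CCR only.
#' @return a list with `theta`, `lambda` (length n), `slack_input`
#'   (length m), `slack_output` (length s), `lambda_sum`, and, when
#'   requested, `lambda_sum_range` (length-2 numeric).
#' @examples
#' p <- dmu_panel(inputs = c(1, 2), outputs = c(1, 1), ids = c("A", "B"))
#' solve_envelopment(p, "B", model = "ccr")$theta  # 0.5
#' @export
solve_envelopment <- function(panel, dmu, model = c("ccr", "bcc"),
                              tol = 1e-6, epsilon = NULL,
                              lambda_range = FALSE) {
  stopifnot(inherits(panel, "dmu_panel"))
  model <- match.arg(model)
  j <- if (is.character(dmu)) match(dmu, panel$ids) else as.integer(dmu)
  if (is.na(j) || j < 1 || j > nrow(panel$X)) stop_invalid("unknown DMU")
  vrs <- model == "bcc"
  X <- panel$X; Y <- panel$Y

  con <- .envelopment_constraints(X, Y, j, vrs, with_theta = TRUE)
  n <- con$n; m <- con$m; s <- con$s
  obj <- numeric(1 + n + m + s)
  obj[1] <- 1
  if (!is.null(epsilon)) {
    if (!is.numeric(epsilon) || epsilon <= 0) {
      stop_invalid("epsilon must be a small positive constant")
    }
    obj[1 + n + seq_len(m + s)] <- -epsilon
  }
  p1 <- .lp_solve(obj, con$A, con$b, maximize = FALSE)
  theta <- p1$x[1]
  lam <- p1$x[1 + seq_len(n)]
  sm <- p1$x[1 + n + seq_len(m)]
  sp <- p1$x[1 + n + m + seq_len(s)]

  if (is.null(epsilon)) {
    # phase 2: maximize total slack at fixed theta*
    con2 <- .envelopment_constraints(X, Y, j, vrs, with_theta = FALSE,
                                     theta_fix = theta)
    obj2 <- c(rep(0, n), rep(1, m + s))
    p2 <- .lp_solve(obj2, con2$A, con2$b, maximize = TRUE)
    lam <- p2$x[seq_len(n)]
    sm <- p2$x[n + seq_len(m)]
    sp <- p2$x[n + m + seq_len(s)]
  }

  out <- list(theta = theta,
              lambda = stats::setNames(lam, panel$ids),
              slack_input = stats::setNames(pmax(sm, 0), colnames(X)),
              slack_output = stats::setNames(pmax(sp, 0), colnames(Y)),
              lambda_sum = sum(lam), model = model, dmu = panel$ids[j])
  if (lambda_range && !vrs) {
    con2 <- .envelopment_constraints(X, Y, j, vrs, with_theta = FALSE,
                                     theta_fix = theta)
    obj3 <- c(rep(1, n), rep(0, m + s))
    lo <- .lp_solve(obj3, con2$A, con2$b, maximize = FALSE)$value
    hi <- .lp_solve(obj3, con2$A, con2$b, maximize = TRUE)$value
    out$lambda_sum_range <- c(lo, hi)
  }
  out
}

#' Scale efficiency from overall and technical efficiency
#'
#' SE = OE/TE: overall (CCR) efficiency divided by pure technical (BCC)
#' efficiency, the component of inefficiency attributable to operating
#' away from the most productive scale size.
#'
#' @param oe overall efficiency score(s), in (0, 1].
#' @param te technical efficiency score(s), in (0, 1], with `oe <= te`
#'   up to `tol`.
#' @param digits decimals for the reported value (half-up, default 3);
#'   `NULL` returns full precision.
#' @param tol tolerance on the ordering and range checks.
#' @return scale efficiency score(s).
#' @examples
#' efficiency_decomposition(0.883, 0.911)  # 0.969
#' @export
efficiency_decomposition <- function(oe, te, digits = 3, tol = 1e-6) {
  if (!is.numeric(oe) || !is.numeric(te) || anyNA(oe) || anyNA(te)) {
    stop_invalid("oe and te must be numeric")
  }
  if (any(te <= 0)) stop_invalid("technical efficiency must be positive")
  if (any(oe <= 0) || any(oe > te + tol) || any(te > 1 + tol)) {
    stop_invalid("need 0 < OE <= TE <= 1 (within tolerance)")
  }
  se <- oe / te
  if (is.null(digits)) se else round_half_up(se, digits)
}

#' Returns-to-scale label from the CCR intensity weights
#'
#' Classifies a DMU's returns to scale from the sum of the optimal CCR
#' intensity weights: constant (`"crs"`) when the sum is 1 within
#' tolerance (or the DMU is efficient under both models, or 1 lies in
#' the supplied min/max range over alternative optima), increasing
#' (`"irs"`) when below 1, decreasing (`"drs"`) when above 1.
#'
#' @param lambda_sum sum of the optimal CCR lambda weights.
#' @param theta_ccr,theta_bcc optional efficiency scores; both equal to
#'   1 forces `"crs"`.
#' @param tol tolerance (default 1e-6).
#' @param lambda_sum_range optional length-2 min/max of the lambda sum
#'   over the CCR optimal set.
#' @return one of `"crs"`, `"irs"`, `"drs"`.
#' @export
classify_rts <- function(lambda_sum, theta_ccr = NULL, theta_bcc = NULL,
                         tol = 1e-6, lambda_sum_range = NULL) {
  if (!is.numeric(lambda_sum) || lambda_sum < 0) {
    stop_invalid("lambda_sum must be nonnegative")
  }
  if (!is.null(theta_ccr) && !is.null(theta_bcc) &&
      abs(theta_ccr - 1) <= tol && abs(theta_bcc - 1) <= tol) {
    return("crs")
  }
  if (!is.null(lambda_sum_range) &&
      lambda_sum_range[1] <= 1 + tol && lambda_sum_range[2] >= 1 - tol) {
    return("crs")
  }
  if (abs(lambda_sum - 1) <= tol) "crs"
  else if (lambda_sum < 1) "irs"
  else "drs"
}

#' Efficiency classification of a DMU
#'
#' Labels each DMU from its efficiency decomposition: `"efficient"` when
#' OE = TE = SE = 1 with zero slacks; `"weakly_efficient"` when the
#' radial scores are 1 but slacks remain; `"scale_inefficient"` when
#' TE = 1 but SE < 1; `"tech_inefficient"` when TE < 1 with SE = 1; and
#' `"tech_and_scale_inefficient"` when both TE and SE fall below 1.
#' The triple is checked for consistency (OE = TE x SE) up to
#' `consistency_tol`, which defaults to 1e-3 so that scores rounded to
#' 3 decimals still validate.
#'
#' @param oe,te,se efficiency scores (vectors of equal length).
#' @param slacks total slack per DMU (scalar or vector; default 0).
#' @param tol tolerance for equality with 1 (default 1e-6).
#' @param consistency_tol tolerance on |OE - TE x SE|.
#' @return character vector of classification labels.
#' @examples
#' classify_efficiency(0.858, 1, 0.858)  # "scale_inefficient"
#' @export
classify_efficiency <- function(oe, te, se, slacks = 0, tol = 1e-6,
                                consistency_tol = 1e-3) {
  k <- max(length(oe), length(te), length(se))
  oe <- rep_len(oe, k); te <- rep_len(te, k); se <- rep_len(se, k)
  slacks <- rep_len(slacks, k)
  if (any(abs(oe - te * se) > consistency_tol)) {
    nhr_stop("inconsistent efficiency triple: OE must equal TE x SE",
             "nhrdea_consistency_error")
  }
  vapply(seq_len(k), function(i) {
    te1 <- abs(te[i] - 1) <= tol
    se1 <- abs(se[i] - 1) <= tol
    oe1 <- abs(oe[i] - 1) <= tol
    if (oe1 && te1 && se1) {
      if (slacks[i] <= tol) "efficient" else "weakly_efficient"
    } else if (te1 && !se1) {
      "scale_inefficient"
    } else if (!te1 && se1) {
      "tech_inefficient"
    } else {
      "tech_and_scale_inefficient"
    }
  }, character(1))
}

#' Slack-based projection targets
#'
#' Input/output levels an inefficient DMU should move to.  The
#' `"standard"` mode applies the radial contraction before removing the
#' input slack, `x* = theta x0 - S-`; the `"slack_only"` mode subtracts
#' the slack from the observed input directly, `x* = x0 - S-`, the
#' reading sometimes used when quoting DEA software slack tables.  Both
#' modes add the output slack, `y* = y0 + S+`.  Efficient DMUs project
#' to themselves.
#'
#' @param x0,y0 observed input and output vectors.
#' @param theta radial efficiency score.
#' @param s_minus,s_plus input and output slack vectors.
#' @param mode `"standard"` or `"slack_only"`.
#' @return a list of class `projection_target` with `inputs`, `outputs`,
#'   `mode`, and a logical `negative_flag` raised when a target input
#'   goes below zero (a mode/data mismatch).
#' @export
projection_targets <- function(x0, y0, theta, s_minus, s_plus,
                               mode = c("standard", "slack_only")) {
  mode <- match.arg(mode)
  if (length(s_minus) != length(x0) || length(s_plus) != length(y0)) {
    stop_invalid("slack vectors must match the input/output dimensions")
  }
  xt <- if (mode == "standard") theta * x0 - s_minus else x0 - s_minus
  yt <- y0 + s_plus
  neg <- any(xt < 0)
  if (neg) {
    warning("negative projection target: slack exceeds the (contracted) input",
            call. = FALSE)
  }
  structure(list(inputs = xt, outputs = yt, mode = mode,
                 negative_flag = neg),
            class = "projection_target")
}

#' Run a full DEA evaluation over a panel
#'
#' Solves the input-oriented CCR and/or BCC envelopment programs for
#' every DMU with two-phase slack maximization, then decomposes
#' efficiency (SE = OE/TE), labels returns to scale from the CCR
#' intensity-weight sums (with an alternative-optima min/max check) and
#' classifies each DMU.
#'
#' @param panel a [dmu_panel()].
#' @param model `"both"` (default), `"ccr"` or `"bcc"`.
#' @param tol equality tolerance for efficiency = 1 (default 1e-6).
#' @param epsilon optional non-Archimedean constant passed to
#'   [solve_envelopment()]; `NULL` uses the two-phase procedure.
#' @return an object of class `dea`: a list with `scores` (a
#'   `data.frame` of per-DMU `oe`, `te`, `se`, `rts`, `classification`),
#'   per-model detail lists (`ccr`, `bcc`: theta, lambda matrix, slack
#'   matrices, lambda sums), the panel and tolerances.
#' @examples
#' p <- dmu_panel(inputs = cbind(x = c(2, 4, 4), y2 = c(4, 2, 4)),
#'                outputs = cbind(y = c(1, 1, 1)), ids = c("A", "B", "C"))
#' dea(p)$scores
#' @export
dea <- function(panel, model = c("both", "ccr", "bcc"), tol = 1e-6,
                epsilon = NULL) {
  stopifnot(inherits(panel, "dmu_panel"))
  model <- match.arg(model)
  n <- nrow(panel$X)
  run <- function(mod, lambda_range) {
    sols <- lapply(seq_len(n), function(j) {
      solve_envelopment(panel, j, model = mod, tol = tol, epsilon = epsilon,
                        lambda_range = lambda_range)
    })
    # bind per-DMU vectors as rows; matrix() keeps an n x 1 shape when a
    # block has a single column, where t(vapply(...)) would transpose it
    rows <- function(field, k, names) {
      matrix(vapply(sols, `[[`, numeric(k), field), nrow = n, byrow = TRUE,
             dimnames = list(NULL, names))
    }
    list(theta = vapply(sols, `[[`, numeric(1), "theta"),
         lambda = rows("lambda", n, panel$ids),
         slack_input = rows("slack_input", ncol(panel$X), colnames(panel$X)),
         slack_output = rows("slack_output", ncol(panel$Y), colnames(panel$Y)),
         lambda_sum = vapply(sols, `[[`, numeric(1), "lambda_sum"),
         lambda_sum_range = if (lambda_range)
           t(vapply(sols, `[[`, numeric(2), "lambda_sum_range")) else NULL)
  }
  ccr <- if (model %in% c("both", "ccr")) run("ccr", lambda_range = TRUE)
  bcc <- if (model %in% c("both", "bcc")) run("bcc", lambda_range = FALSE)

  scores <- data.frame(dmu = panel$ids, stringsAsFactors = FALSE)
  scores$oe <- if (!is.null(ccr)) pmin(ccr$theta, 1) else NA_real_
  scores$te <- if (!is.null(bcc)) pmin(bcc$theta, 1) else NA_real_
  if (!is.null(ccr) && !is.null(bcc)) {
    scores$se <- efficiency_decomposition(scores$oe, pmax(scores$te, scores$oe),
                                          digits = NULL, tol = tol)
    scores$rts <- vapply(seq_len(n), function(j) {
      classify_rts(ccr$lambda_sum[j], scores$oe[j], scores$te[j], tol = tol,
                   lambda_sum_range = ccr$lambda_sum_range[j, ])
    }, character(1))
    tot_slack <- rowSums(ccr$slack_input) + rowSums(ccr$slack_output)
    scores$classification <- classify_efficiency(
      scores$oe, scores$te, scores$se, slacks = tot_slack, tol = tol,
      consistency_tol = 1e-6)
  } else {
    scores$se <- NA_real_; scores$rts <- NA_character_
    scores$classification <- NA_character_
  }
  structure(list(scores = scores, ccr = ccr, bcc = bcc, panel = panel,
                 model = model, tol = tol, epsilon = epsilon),
            class = "dea")
}

#' @export
print.dea <- function(x, digits = 3, ...) {
  cat(sprintf("Input-oriented DEA (%s), %d DMUs\n", x$model,
              nrow(x$scores)))
  df <- x$scores
  for (cn in c("oe", "te", "se")) {
    if (!all(is.na(df[[cn]]))) df[[cn]] <- round_half_up(df[[cn]], digits)
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summary table of a DEA evaluation
#'
#' Column means of the efficiency scores (3 decimals, half-up) and
#' counts by classification and returns-to-scale label.
#'
#' @param results a `dea` object or a `data.frame` with columns `oe`,
#'   `te`, `se` and optionally `rts`, `classification`.
#' @param digits decimals for reported means.
#' @return a list of class `dea_summary` with `means`, `n_dmu`,
#'   `classification_counts`, `rts_counts`, `n_efficient`,
#'   `n_inefficient`.
#' @export
summarize_dea <- function(results, digits = 3) {
  df <- if (inherits(results, "dea")) results$scores else as.data.frame(results)
  if (nrow(df) == 0L) stop_invalid("no DEA results to summarize")
  means <- vapply(c("oe", "te", "se"), function(cn) {
    if (cn %in% names(df)) round_half_up(mean(df[[cn]]), digits) else NA_real_
  }, numeric(1))
  cls <- if ("classification" %in% names(df)) table(df$classification) else table(character())
  rts <- if ("rts" %in% names(df)) table(df$rts) else table(character())
  n_eff <- sum(df$classification == "efficient")
  structure(list(means = means, n_dmu = nrow(df),
                 classification_counts = cls, rts_counts = rts,
                 n_efficient = n_eff, n_inefficient = nrow(df) - n_eff),
            class = "dea_summary")
}

#' @export
print.dea_summary <- function(x, ...) {
  cat(sprintf("%d DMUs: %d efficient, %d inefficient\n", x$n_dmu,
              x$n_efficient, x$n_inefficient))
  cat(sprintf("Mean OE = %.3f, TE = %.3f, SE = %.3f\n",
              x$means["oe"], x$means["te"], x$means["se"]))
  if (length(x$rts_counts)) {
    cat("Returns to scale:",
        paste(sprintf("%s = %d", names(x$rts_counts), x$rts_counts),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-DMU efficiency table in reporting layout
#'
#' Flattens a `dea` result into the conventional reporting layout: one
#' row per DMU with OE, TE, SE (3 decimals, half-up), the
#' returns-to-scale label (`"—"` for constant returns), total CCR input
#' and output slack, and an Efficient/Inefficient label.
#'
#' @param d a `dea` object fitted with `model = "both"`.
#' @param digits decimals (default 3).
#' @return a `data.frame` with columns `dmu`, `oe`, `te`, `se`, `rts`,
#'   `s_minus`, `s_plus`, `efficiency`.
#' @export
dea_efficiency_table <- function(d, digits = 3) {
  stopifnot(inherits(d, "dea"))
  if (is.null(d$ccr) || is.null(d$bcc)) {
    stop_invalid("the reporting table needs both CCR and BCC results")
  }
  sc <- d$scores
  data.frame(
    dmu = sc$dmu,
    oe = round_half_up(sc$oe, digits),
    te = round_half_up(sc$te, digits),
    se = round_half_up(sc$se, digits),
    rts = ifelse(sc$rts == "crs", "—", sc$rts),
    s_minus = round_half_up(rowSums(d$ccr$slack_input), digits),
    s_plus = round_half_up(rowSums(d$ccr$slack_output), digits),
    efficiency = ifelse(sc$classification == "efficient", "Efficient",
                        "Inefficient"),
    stringsAsFactors = FALSE)
}
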