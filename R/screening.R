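# DEA dimensionality rules of thumb and correlation-based third-stage
# indicator selection.

#' DEA dimensionality rules of thumb
#'
#' Checks the conventional discriminatory-power constraints tying the
#' number of candidate indicators to the number of decision-making units:
#' the combined indicator count should not exceed half the number of
#' DMUs, the DMU count should be no less than the product of input and
#' output counts, and (reported separately) the DMU count should be at
#' least twice the combined indicator count.  The overall `feasible`
#' verdict requires the first two.
#'
#' @param n_dmu number of DMUs.
#' @param n_inputs number of input indicators.
#' @param n_outputs number of output indicators.
#' @return a list of class `dea_rule_of_thumb` with logical elements
#'   `half_rule`, `product_rule`, `twice_rule`, `feasible` plus the
#'   counts.
#' @examples
#' dea_rule_of_thumb(12, 3, 2)$feasible  # TRUE
#' dea_rule_of_thumb(12, 4, 4)$feasible  # FALSE: product rule
#' @export
dea_rule_of_thumb <- function(n_dmu, n_inputs, n_outputs) {
  for (v in list(n_dmu, n_inputs, n_outputs)) {
    if (!is_count(v) || v < 1) stop_invalid("all counts must be >= 1")
  }
  k <- n_inputs + n_outputs
  half <- k <= n_dmu / 2
  prod_rule <- n_inputs * n_outputs <= n_dmu
  twice <- n_dmu >= 2 * k
  structure(list(n_dmu = n_dmu, n_inputs = n_inputs, n_outputs = n_outputs,
                 half_rule = half, product_rule = prod_rule,
                 twice_rule = twice, feasible = half && prod_rule),
            class = "dea_rule_of_thumb")
}

#' @export
print.dea_rule_of_thumb <- function(x, ...) {
  cat(sprintf(
    "DEA rule of thumb for %d DMUs, %d inputs + %d outputs:\n", x$n_dmu,
    x$n_inputs, x$n_outputs))
  cat(sprintf("  indicators <= n_dmu/2 : %s\n", x$half_rule))
  cat(sprintf("  inputs x outputs <= n : %s\n", x$product_rule))
  cat(sprintf("  n >= 2 x indicators   : %s\n", x$twice_rule))
  cat(sprintf("  feasible              : %s\n", x$feasible))
  invisible(x)
}

#' Candidate indicator table for selection
#'
#' Wraps per-DMU values of candidate indicators together with their
#' input/output role tags.
#'
#' @param values numeric matrix or data.frame, rows DMUs, columns
#'   indicators; no missing values, at least 3 DMUs.
#' @param roles named character vector mapping every indicator to
#'   `"input"` or `"output"`.
#' @return an object of class `indicator_table`.
#' @export
indicator_table <- function(values, roles) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop_invalid("indicator values must be numeric with no missing cells")
  }
  if (nrow(values) < 3L) stop_insufficient("need at least 3 DMUs")
  if (is.null(colnames(values))) {
    stop_invalid("indicator columns must be named")
  }
  roles <- unlist(roles)
  if (!all(colnames(values) %in% names(roles))) {
    stop_invalid("every indicator needs an input/output role tag")
  }
  roles <- roles[colnames(values)]
  if (!all(roles %in% c("input", "output"))) {
    stop_invalid("roles must be 'input' or 'output'")
  }
  structure(list(values = values, roles = roles), class = "indicator_table")
}

#' Pairwise Pearson correlations with two-tailed p values
#'
#' Pearson r for every indicator pair, with two-tailed p values from the
#' t distribution on n - 2 degrees of freedom (via [stats::cor.test()]).
#' Zero-variance columns are flagged and excluded from the pair set.
#'
#' @param table an [indicator_table()] (or numeric matrix with named
#'   columns).
#' @return a list of class `indicator_correlations`: symmetric matrices
#'   `r` and `p` (unit diagonal / zero diagonal), `dropped`
#'   (zero-variance indicator ids), `n_dmu`, `roles` (if known), and
#'   `pairs`, a long-format `data.frame` (`a`, `b`, `r`, `p`).
#' @export
indicator_correlations <- function(table) {
  if (inherits(table, "indicator_table")) {
    vals <- table$values
    roles <- table$roles
  } else {
    vals <- as.matrix(table)
    roles <- NULL
  }
  if (nrow(vals) < 3L) stop_insufficient("need at least 3 DMUs")
  v <- apply(vals, 2, stats::var)
  dropped <- colnames(vals)[v <= .Machine$double.eps]
  keep <- setdiff(colnames(vals), dropped)
  vals <- vals[, keep, drop = FALSE]
  k <- ncol(vals)
  r <- diag(1, k); p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(keep, keep)
  pairs <- NULL
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ct <- stats::cor.test(vals[, i], vals[, j], method = "pearson",
                            alternative = "two.sided")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      pairs <- rbind(pairs, data.frame(a = keep[i], b = keep[j],
                                       r = unname(ct$estimate),
                                       p = ct$p.value,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(r = r, p = p, dropped = dropped, n_dmu = nrow(vals),
                 roles = if (!is.null(roles)) roles[keep] else NULL,
                 pairs = pairs),
            class = "indicator_correlations")
}

#' Select indicators by cross-role correlation strength
#'
#' Third-stage indicator selection: an indicator survives only if it has
#' at least one qualifying cross-role pair (an input-output pair with
#' |r| > `r_min` and p below a permitted significance level); survivors
#' are ranked by their maximum cross-role |r| and the `k` strongest are
#' kept, subject to the [dea_rule_of_thumb()] constraints for the panel's
#' DMU count (the lowest-ranked indicators are dropped until the
#' selection is feasible, never emptying a role).  Ties are broken by
#' indicator id order.
#'
#' @param corr an [indicator_correlations()] result carrying roles, or an
#'   [indicator_table()] (correlations are then computed).
#' @param k maximum number of indicators to keep; defaults to
#'   `floor(n_dmu / 2)`.
#' @param r_min minimum absolute correlation for a qualifying pair
#'   (default 0.7, exclusive).
#' @param alpha significance level(s); a pair qualifies when its p value
#'   is below `max(alpha)` (default `c(0.01, 0.05)`).
#' @return a list of class `indicator_selection`: `selected` ids,
#'   `inputs`, `outputs`, `ranking` (per-indicator max cross-role |r|),
#'   `eliminated`, `trace` (a `data.frame` of decisions), and the pair
#'   table.
#' @export
select_indicators <- function(corr, k = NULL, r_min = 0.7,
                              alpha = c(0.01, 0.05)) {
  if (inherits(corr, "indicator_table")) corr <- indicator_correlations(corr)
  stopifnot(inherits(corr, "indicator_correlations"))
  roles <- corr$roles
  if (is.null(roles)) stop_invalid("selection needs input/output roles")
  if (is.null(k)) k <- floor(corr$n_dmu / 2)
  if (!is_count(k) || k < 2) stop_invalid("k must be a count >= 2")
  ids <- colnames(corr$r)
  amax <- max(alpha)

  cross <- corr$pairs[roles[corr$pairs$a] != roles[corr$pairs$b], , drop = FALSE]
  qual <- cross[abs(cross$r) > r_min & cross$p < amax, , drop = FALSE]
  if (nrow(qual) == 0L) {
    nhr_stop(paste0("no cross-role pair exceeds |r| > ", r_min,
                    " at alpha = ", amax, ": selection is empty"),
             "nhrdea_empty_selection")
  }
  maxr <- vapply(ids, function(id) {
    rows <- qual[qual$a == id | qual$b == id, , drop = FALSE]
    if (nrow(rows) == 0L) NA_real_ else max(abs(rows$r))
  }, numeric(1))
  eliminated <- ids[is.na(maxr)]
  surv <- ids[!is.na(maxr)]
  if (!any(roles[surv] == "input") || !any(roles[surv] == "output")) {
    nhr_stop("selection must keep at least one input and one output",
             "nhrdea_empty_selection")
  }
  # rank survivors by max cross-role |r|, ties by id order
  ord <- surv[order(-maxr[surv], surv)]
  trace <- data.frame(id = eliminated,
                      action = rep("eliminated", length(eliminated)),
                      detail = rep(sprintf("no cross-role pair with |r| > %g and p < %g",
                                           r_min, amax), length(eliminated)),
                      stringsAsFactors = FALSE)
  sel <- utils::head(ord, k)
  if (length(ord) > k) {
    trace <- rbind(trace, data.frame(
      id = ord[-seq_len(k)], action = "dropped",
      detail = sprintf("outside top %d by max cross-role |r|", k),
      stringsAsFactors = FALSE))
  }
  # never empty a role while trimming for the dimensionality rules
  repeat {
    ni <- sum(roles[sel] == "input"); no <- sum(roles[sel] == "output")
    if (ni == 0L || no == 0L) {
      missing_role <- if (ni == 0L) "input" else "output"
      cand <- ord[roles[ord] == missing_role][1]
      sel <- c(utils::head(sel, length(sel) - 1L), cand)
      next
    }
    rot <- dea_rule_of_thumb(corr$n_dmu, ni, no)
    if (rot$feasible || length(sel) <= 2L) break
    drop_id <- sel[length(sel)]
    trace <- rbind(trace, data.frame(
      id = drop_id, action = "dropped",
      detail = "dimensionality rule of thumb", stringsAsFactors = FALSE))
    sel <- sel[-length(sel)]
  }
  sel <- sel[order(match(sel, ids))]
  structure(list(selected = sel,
                 inputs = sel[roles[sel] == "input"],
                 outputs = sel[roles[sel] == "output"],
                 ranking = sort(maxr[surv], decreasing = TRUE),
                 eliminated = eliminated,
                 trace = trace, pairs = cross,
                 rule_of_thumb = dea_rule_of_thumb(
                   corr$n_dmu, sum(roles[sel] == "input"),
                   sum(roles[sel] == "output"))),
            class = "indicator_selection")
}

#' @export
print.indicator_selection <- function(x, ...) {
  cat(sprintf("Selected %d indicators (%d input, %d output): %s\n",
              length(x$selected), length(x$inputs), length(x$outputs),
              paste(x$selected, collapse = ", ")))
  if (length(x$eliminated)) {
    cat("Eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}
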