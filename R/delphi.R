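# Delphi expert-consultation statistics: enthusiasm (response rate),
# authority (Ca, Cs, Cr), consensus (CV, Kendall's W) and item screening.

#' Item metadata for a hierarchical indicator system
#'
#' Builds the metadata table for candidate indicators.  Each indicator
#' carries a hierarchical code (for example `"1.1.1"`), a label, its
#' hierarchy level (the number of code components) and a
#' structure-process-outcome tag following Donabedian's framework.
#'
#' @param id character vector of hierarchical codes (`"1"`, `"1.1"`, ...).
#' @param label character vector of indicator names.
#' @param spo character vector of tags, each one of `"S"`, `"P"`, `"O"`.
#' @param level optional integer vector of hierarchy levels; defaults to
#'   the code depth and must equal it when supplied.
#' @return a `data.frame` with columns `id`, `label`, `level`, `spo`.
#' @export
item_meta <- function(id, label, spo, level = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop_invalid("duplicated indicator codes")
  depth <- code_depth(id)
  if (is.null(level)) level <- depth
  if (any(level != depth)) {
    stop_invalid("hierarchical code depth must equal the stated level")
  }
  spo <- as.character(spo)
  if (!all(spo %in% c("S", "P", "O"))) {
    stop_invalid("every item needs an S, P or O tag")
  }
  if (length(label) != length(id) || length(spo) != length(id)) {
    stop_invalid("id, label and spo must have equal length")
  }
  data.frame(id = id, label = as.character(label),
             level = as.integer(level), spo = spo,
             stringsAsFactors = FALSE)
}

#' Expert rating matrix for one consultation round
#'
#' Validates and wraps a matrix of Likert importance scores, one row per
#' responding expert and one column per candidate indicator.  Experts who
#' did not return the round are excluded as whole rows before
#' construction; partially answered rows are rejected.
#'
#' @param scores numeric matrix or data.frame of integer scores in 1..5;
#'   rows are experts, columns items.
#' @param items optional [item_meta()] table; its `id` order must match
#'   the score columns.
#' @param round_id integer consultation round.
#' @return an object of class `rating_matrix`.
#' @export
rating_matrix <- function(scores, items = NULL, round_id = 1L) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop_invalid("scores must be numeric")
  if (anyNA(scores)) {
    stop_invalid("missing cells are not allowed: drop non-responding experts as whole rows")
  }
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop_insufficient("need at least 2 experts and 2 items")
  }
  if (!all(scores %in% 1:5)) {
    stop_invalid("all scores must be integers in 1..5")
  }
  if (!is.null(items)) {
    if (nrow(items) != ncol(scores)) {
      stop_invalid("items table must have one row per score column")
    }
    colnames(scores) <- items$id
  } else if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("item", seq_len(ncol(scores)))
  }
  structure(list(scores = scores, items = items,
                 round_id = as.integer(round_id)),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("Delphi rating matrix, round %d: %d experts x %d items\n",
              x$round_id, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Questionnaire response rate (enthusiasm coefficient)
#'
#' The share of distributed questionnaires returned, in percent.  A rate
#' above 70% is conventionally read as good engagement.
#'
#' @param n_sent number of questionnaires distributed (>= 1).
#' @param n_returned number returned, between 0 and `n_sent`.
#' @return the rate in percent, rounded half-up to 1 decimal.
#' @examples
#' response_rate(17, 17)  # 100.0
#' response_rate(17, 16)  # 94.1
#' @export
response_rate <- function(n_sent, n_returned) {
  if (!is_count(n_sent) || n_sent < 1) stop_invalid("n_sent must be a count >= 1")
  if (!is_count(n_returned) || n_returned > n_sent) {
    stop_invalid("n_returned must be a count between 0 and n_sent")
  }
  round_half_up(100 * n_returned / n_sent, 1)
}

.judgment_weights <- list(
  practical_experience = c(high = 0.5, medium = 0.4, low = 0.3),
  theoretical_analysis = c(high = 0.3, medium = 0.2, low = 0.1),
  literature           = c(high = 0.1, medium = 0.1, low = 0.1),
  intuition            = c(high = 0.1, medium = 0.1, low = 0.1)
)

.familiarity_scores <- c(very_familiar = 1.0, familiar = 0.8, moderate = 0.6,
                         unfamiliar = 0.4, very_unfamiliar = 0.2)

#' Judgment-basis coefficient Ca
#'
#' Scores an expert's self-assessed judgment basis.  Practical experience
#' weighs 0.5/0.4/0.3 for high/medium/low influence, theoretical analysis
#' 0.3/0.2/0.1, and literature reference and intuition each carry a fixed
#' weight of 0.1 regardless of the stated level.  Ca is the sum, ranging
#' from 0.6 to the theoretical maximum of 1.0.
#'
#' @param levels named character vector or list with entries
#'   `practical_experience`, `theoretical_analysis`, `literature`,
#'   `intuition`, each one of `"high"`, `"medium"`, `"low"`.
#' @return the Ca score.
#' @examples
#' judgment_basis(c(practical_experience = "high",
#'                  theoretical_analysis = "high",
#'                  literature = "high", intuition = "high"))  # 1.0
#' @export
judgment_basis <- function(levels) {
  levels <- unlist(levels)
  need <- names(.judgment_weights)
  if (!all(need %in% names(levels))) {
    stop_invalid(paste("levels must name all four sources:",
                       paste(need, collapse = ", ")))
  }
  extra <- setdiff(names(levels), need)
  if (length(extra)) stop_invalid(paste("unknown judgment source:", extra[1]))
  w <- vapply(need, function(s) {
    lev <- as.character(levels[[s]])
    if (!lev %in% c("high", "medium", "low")) {
      stop_invalid(paste0("unknown level '", lev, "' for source ", s))
    }
    .judgment_weights[[s]][[lev]]
  }, numeric(1))
  sum(w)
}

#' Familiarity coefficient Cs
#'
#' Maps an expert's self-rated topic familiarity to its score:
#' very_familiar = 1.0, familiar = 0.8, moderate = 0.6, unfamiliar = 0.4,
#' very_unfamiliar = 0.2.
#'
#' @param level character vector of familiarity levels.
#' @return numeric vector of Cs scores.
#' @export
familiarity_score <- function(level) {
  level <- as.character(level)
  bad <- setdiff(level, names(.familiarity_scores))
  if (length(bad)) stop_invalid(paste("unknown familiarity level:", bad[1]))
  unname(.familiarity_scores[level])
}

#' Expert authority coefficient Cr
#'
#' Cr = (Ca + Cs)/2, the mean of the judgment-basis and familiarity
#' coefficients.  Cr above 0.7 is conventionally read as reliable expert
#' judgment.
#'
#' @param ca judgment-basis coefficient(s) in \[0, 1\].
#' @param cs familiarity coefficient(s) in \[0, 1\].
#' @param digits decimals for the reported value (half-up); default 2.
#' @return the rounded authority coefficient(s).
#' @examples
#' authority_coefficient(0.98, 0.86)  # 0.92
#' authority_coefficient(0.94, 0.85)  # 0.90
#' @export
authority_coefficient <- function(ca, cs, digits = 2) {
  if (!is.numeric(ca) || !is.numeric(cs) || anyNA(ca) || anyNA(cs) ||
      any(ca < 0 | ca > 1) || any(cs < 0 | cs > 1)) {
    stop_invalid("ca and cs must lie in [0, 1]")
  }
  round_half_up((ca + cs) / 2, digits)
}

#' Per-item rating statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation (sd/mean) and full-score rate (share of experts awarding the
#' maximum score of 5) for one item's column of Likert scores.
#'
#' @param x numeric vector of at least two scores in 1..5.
#' @return a one-row `data.frame` with columns `mean`, `sd`, `cv`,
#'   `full_score_rate` (a proportion in \[0, 1\]).
#' @examples
#' item_statistics(c(5, 5, 4, 4))
#' @export
item_statistics <- function(x) {
  if (length(x) < 2L) stop_insufficient("need at least 2 scores per item")
  if (anyNA(x) || !all(x %in% 1:5)) stop_invalid("scores must be integers in 1..5")
  m <- mean(x)
  s <- stats::sd(x)
  data.frame(mean = m, sd = s, cv = s / m, full_score_rate = mean(x == 5))
}

#' Rating statistics for every item of a round
#'
#' @param ratings a [rating_matrix()].
#' @return a `data.frame` with one row per item: `id`, `mean`, `sd`,
#'   `cv`, `full_score_rate`.
#' @export
delphi_item_stats <- function(ratings) {
  stopifnot(inherits(ratings, "rating_matrix"))
  sc <- ratings$scores
  out <- do.call(rbind, lapply(seq_len(ncol(sc)),
                               function(j) item_statistics(sc[, j])))
  cbind(data.frame(id = colnames(sc), stringsAsFactors = FALSE), out)
}

#' Kendall's coefficient of concordance W
#'
#' Agreement among m experts ranking n items, from the variance of item
#' rank sums.  Within-expert ranks use average ranks for ties; with
#' `tie_correction = TRUE` (the default, appropriate for heavily tied
#' Likert data) the usual tie term \eqn{\sum (t^3 - t)} is subtracted
#' from the denominator.  The associated chi-squared statistic is
#' \eqn{\chi^2 = m (n - 1) W} on n - 1 degrees of freedom; with
#' `tie_correction = FALSE` this identity is exact against the
#' uncorrected rank-variance formula.
#'
#' @param ratings a [rating_matrix()] or a numeric matrix (rows experts,
#'   columns items) with at least 2 experts and 3 items.
#' @param tie_correction logical; subtract the tie term from the
#'   denominator.
#' @return an object of class `kendall_w`: a list with `w`, `chi2`, `df`,
#'   `p_value`, `tie_corrected`, `n_experts`, `n_items`.
#' @examples
#' m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
#' kendalls_w(m)$w  # 1: perfect concordance
#' @export
kendalls_w <- function(ratings, tie_correction = TRUE) {
  sc <- if (inherits(ratings, "rating_matrix")) ratings$scores else as.matrix(ratings)
  if (!is.numeric(sc) || anyNA(sc)) stop_invalid("ratings must be a complete numeric matrix")
  m <- nrow(sc); n <- ncol(sc)
  if (m < 2L || n < 3L) stop_insufficient("need at least 2 experts and 3 items")
  rk <- t(apply(sc, 1, rank, ties.method = "average"))
  rsum <- colSums(rk)
  s <- sum((rsum - mean(rsum))^2)
  denom <- m^2 * (n^3 - n) / 12
  if (tie_correction) {
    tie_term <- sum(apply(sc, 1, function(row) {
      t <- table(row)
      sum(t^3 - t)
    }))
    denom <- denom - m * tie_term / 12
  }
  if (denom <= .Machine$double.eps) {
    stop_degenerate("all items tied for every expert: concordance undefined")
  }
  w <- s / denom
  chi2 <- m * (n - 1) * w
  structure(list(w = w, chi2 = chi2, df = n - 1L,
                 p_value = stats::pchisq(chi2, n - 1, lower.tail = FALSE),
                 tie_corrected = tie_correction,
                 n_experts = m, n_items = n),
            class = "kendall_w")
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf("Kendall's W = %.3f (%s), chi2 = %.2f, df = %d, p %s\n",
              x$w, if (x$tie_corrected) "tie-corrected" else "uncorrected",
              x$chi2, x$df,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  invisible(x)
}

#' Screening thresholds for Delphi item retention
#'
#' Retention requires mean >= `mean_min`, coefficient of variation
#' < `cv_max` and full-score rate > `fsr_min`; set any threshold to `NA`
#' to disable that criterion.  The `"strict"` preset raises the mean
#' cutoff to 4.0, the stricter reading sometimes used for first-stage
#' screening; the default keeps 3.5.
#'
#' @param mean_min minimum mean importance score (default 3.5).
#' @param cv_max maximum coefficient of variation, exclusive (default 0.25).
#' @param fsr_min full-score-rate threshold, exclusive, as a proportion
#'   (default 0.70).
#' @param preset `"default"` or `"strict"`.
#' @return a list of class `screening_thresholds`.
#' @export
screening_thresholds <- function(mean_min = 3.5, cv_max = 0.25, fsr_min = 0.70,
                                 preset = c("default", "strict")) {
  preset <- match.arg(preset)
  if (preset == "strict") mean_min <- 4.0
  chk <- function(v, lo, hi) is.na(v) || (is.numeric(v) && v >= lo && v <= hi)
  if (!chk(mean_min, 1, 5) || !chk(cv_max, 0, Inf) || !chk(fsr_min, 0, 1)) {
    stop_invalid("thresholds out of range")
  }
  structure(list(mean_min = mean_min, cv_max = cv_max, fsr_min = fsr_min),
            class = "screening_thresholds")
}

#' Screen Delphi items on consensus statistics
#'
#' Applies the retention rules to per-item statistics: an item is kept
#' iff every enabled criterion passes (mean >= mean_min, CV < cv_max,
#' full-score rate > fsr_min).  Each removed item records which criteria
#' failed.
#'
#' @param stats a `data.frame` with columns `mean`, `cv`,
#'   `full_score_rate` (proportion), and optionally `id`; typically from
#'   [delphi_item_stats()].
#' @param thresholds a [screening_thresholds()] object.
#' @return `stats` with added logical `retained` and character `reason`
#'   columns (`""` for retained items, otherwise a comma-separated list
#'   among `"mean"`, `"cv"`, `"fsr"`).
#' @export
screen_delphi_items <- function(stats, thresholds = screening_thresholds()) {
  stopifnot(inherits(thresholds, "screening_thresholds"))
  if (nrow(stats) == 0L) {
    stats$retained <- logical(0)
    stats$reason <- character(0)
    return(stats)
  }
  need <- c("mean", "cv", "full_score_rate")
  if (!all(need %in% names(stats))) {
    stop_invalid("stats needs columns mean, cv, full_score_rate")
  }
  fail_mean <- if (is.na(thresholds$mean_min)) rep(FALSE, nrow(stats)) else
    stats$mean < thresholds$mean_min
  fail_cv <- if (is.na(thresholds$cv_max)) rep(FALSE, nrow(stats)) else
    stats$cv >= thresholds$cv_max
  fail_fsr <- if (is.na(thresholds$fsr_min)) rep(FALSE, nrow(stats)) else
    stats$full_score_rate <= thresholds$fsr_min
  reason <- vapply(seq_len(nrow(stats)), function(i) {
    paste(c("mean", "cv", "fsr")[c(fail_mean[i], fail_cv[i], fail_fsr[i])],
          collapse = ",")
  }, character(1))
  stats$retained <- reason == ""
  stats$reason <- reason
  stats
}
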