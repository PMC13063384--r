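# Seeded synthetic generators: Likert rating matrices with a tunable
# common ranking, input-output panels built on a known efficient
# frontier with planted radial inefficiency, and positive indicator
# tables with a target correlation structure.  All generators take a
# mandatory seed and restore the caller's RNG state.

#' Simulate a Delphi rating matrix
#'
#' Draws a latent item-importance ranking (equally spaced latent means
#' over the 1..5 scale, in a random item order) and gives each expert a
#' noisy, discretized copy: score = clip(round(latent + noise), 1, 5)
#' with noise standard deviation `2 * (1 - consensus_strength)`.  At
#' `consensus_strength = 1` all experts agree exactly (Kendall's W = 1);
#' at 0 the scores are essentially unrelated across experts.  With
#' probability `full_score_bias` a score is bumped to the maximum of 5,
#' emulating the ceiling effects of importance ratings.
#'
#' @param n_experts number of experts (>= 2).
#' @param n_items number of items (>= 3).
#' @param consensus_strength agreement level in \[0, 1\].
#' @param full_score_bias probability of bumping a score to 5.
#' @param seed mandatory integer seed; identical arguments give an
#'   identical matrix.
#' @param round_id consultation round recorded on the result.
#' @return a [rating_matrix()].
#' @export
generate_rating_matrix <- function(n_experts, n_items,
                                   consensus_strength = 0.7,
                                   full_score_bias = 0, seed,
                                   round_id = 1L) {
  if (!is_count(n_experts) || n_experts < 2) stop_invalid("n_experts must be >= 2")
  if (!is_count(n_items) || n_items < 3) stop_invalid("n_items must be >= 3")
  if (!is.numeric(consensus_strength) || consensus_strength < 0 ||
      consensus_strength > 1) {
    stop_invalid("consensus_strength must lie in [0, 1]")
  }
  if (!is.numeric(full_score_bias) || full_score_bias < 0 ||
      full_score_bias > 1) {
    stop_invalid("full_score_bias must be a probability")
  }
  with_seed(seed, {
    latent <- sample(seq(1, 5, length.out = n_items))
    sd_noise <- 2 * (1 - consensus_strength)
    sc <- t(vapply(seq_len(n_experts), function(e) {
      raw <- latent + stats::rnorm(n_items, sd = sd_noise)
      pmin(pmax(round(raw), 1), 5)
    }, numeric(n_items)))
    if (full_score_bias > 0) {
      bump <- matrix(stats::runif(length(sc)) < full_score_bias, nrow(sc))
      sc[bump] <- 5
    }
    colnames(sc) <- paste0("item", seq_len(n_items))
    rating_matrix(sc, round_id = round_id)
  })
}

#' Simulate a DMU panel with planted inefficiency
#'
#' Builds an input-output panel on a known efficient frontier and
#' returns the true input-oriented efficiency of every DMU.  All units
#' share a common input mix `x_base` and output mix `y_base`; unit j
#' operates at scale `t_j` and its inputs are divided by its
#' inefficiency factor `c_j` in (0, 1], so that with `noise_sd = 0` the
#' true radial score is exactly `c_j`.  Under `frontier_kind = "crs"`
#' the frontier is the ray through `(x_base, y_base)`; under `"vrs"` the
#' input requirement grows convexly with scale (`t^1.7`), and every
#' inefficient unit is placed at the scale of one of the efficient
#' units so that its variable-returns score is also exactly `c_j`.
#' Optional multiplicative lognormal noise on the inputs (`noise_sd`)
#' makes the planted scores approximate.
#'
#' @param n_dmu number of DMUs.
#' @param n_inputs,n_outputs dimensions of the input and output vectors.
#' @param frontier_kind `"crs"` or `"vrs"`.
#' @param inefficiency_factors per-DMU factors in (0, 1]; at least one
#'   must equal 1 so the frontier is attained.  Default all 1.
#' @param noise_sd standard deviation of lognormal input noise
#'   (default 0).
#' @param seed mandatory integer seed.
#' @return a list with `panel` (a [dmu_panel()]) and `true_theta`.
#' @export
generate_dmu_panel <- function(n_dmu, n_inputs = 1, n_outputs = 1,
                               frontier_kind = c("crs", "vrs"),
                               inefficiency_factors = rep(1, n_dmu),
                               noise_sd = 0, seed) {
  frontier_kind <- match.arg(frontier_kind)
  if (!is_count(n_dmu) || n_dmu < 2) stop_invalid("n_dmu must be >= 2")
  cf <- inefficiency_factors
  if (length(cf) != n_dmu || any(cf <= 0) || any(cf > 1)) {
    stop_invalid("inefficiency_factors must be n_dmu values in (0, 1]")
  }
  if (max(cf) < 1) {
    stop_invalid("at least one inefficiency factor must equal 1 so the frontier is attained")
  }
  with_seed(seed, {
    x_base <- stats::runif(n_inputs, 1, 10)
    y_base <- stats::runif(n_outputs, 1, 10)
    t <- stats::runif(n_dmu, 0.5, 2)
    if (frontier_kind == "vrs") {
      # inefficient units sit at the scale of an efficient unit so the
      # convex-hull frontier passes through their projection point
      eff <- which(cf == 1)
      ineff <- which(cf < 1)
      if (length(ineff)) t[ineff] <- t[sample(rep(eff, 2), length(ineff),
                                              replace = TRUE)]
      xlev <- t^1.7
    } else {
      xlev <- t
    }
    X <- outer(xlev / cf, x_base)
    Y <- outer(t, y_base)
    if (noise_sd > 0) {
      X <- X * matrix(exp(stats::rnorm(length(X), sd = noise_sd)), nrow(X))
    }
    colnames(X) <- paste0("input", seq_len(n_inputs))
    colnames(Y) <- paste0("output", seq_len(n_outputs))
    list(panel = dmu_panel(X, Y), true_theta = cf)
  })
}

#' Simulate positive indicators with a target correlation structure
#'
#' Gaussian-copula draw: standard normal deviates are mixed through the
#' eigendecomposition of the target correlation matrix and mapped to
#' positive values by a mild lognormal transform (`100 * exp(0.25 z)`),
#' which keeps the empirical Pearson correlations close to the target
#' (within about 0.15 for 50 or more DMUs).
#'
#' @param n_dmu number of rows (DMUs).
#' @param target_corr symmetric positive semi-definite correlation
#'   matrix; its column names (or `ind1..k`) name the indicators.
#' @param seed mandatory integer seed.
#' @param roles optional named role vector to attach, producing an
#'   [indicator_table()]; otherwise a plain matrix is returned.
#' @return an `indicator_table` (when roles are given) or a numeric
#'   matrix.
#' @export
generate_correlated_indicators <- function(n_dmu, target_corr, seed,
                                           roles = NULL) {
  target_corr <- as.matrix(target_corr)
  k <- ncol(target_corr)
  if (nrow(target_corr) != k || any(abs(target_corr - t(target_corr)) > 1e-8)) {
    stop_invalid("target_corr must be symmetric")
  }
  ev <- eigen(target_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop_invalid("target_corr must be positive semi-definite")
  }
  if (!is_count(n_dmu) || n_dmu < 3) stop_invalid("n_dmu must be >= 3")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  nm <- colnames(target_corr)
  if (is.null(nm)) nm <- paste0("ind", seq_len(k))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_dmu * k), n_dmu, k) %*% t(L)
    M <- 100 * exp(0.25 * Z)
    colnames(M) <- nm
    if (is.null(roles)) M else indicator_table(M, roles)
  })
}
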