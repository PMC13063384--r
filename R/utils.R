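# internal helpers: classed errors, half-up rounding, seeded RNG scope

nhr_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "nhrdea_error")))
}

stop_invalid <- function(msg) nhr_stop(msg, "nhrdea_invalid_input")
stop_insufficient <- function(msg) nhr_stop(msg, "nhrdea_insufficient_data")
stop_degenerate <- function(msg) nhr_stop(msg, "nhrdea_degenerate")
stop_schema <- function(msg) nhr_stop(msg, "nhrdea_schema_error")
stop_solver <- function(msg) nhr_stop(msg, "nhrdea_solver_error")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, as used
#' for reported coefficients and efficiency scores.  Base [round()] uses
#' round-half-to-even, which disagrees on exact .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.895, 2)  # 0.90
#' round(0.895, 2)          # may give 0.89
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("'seed' must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# number of dot-separated components of a hierarchical code like "1.2.3"
code_depth <- function(id) {
  lengths(strsplit(as.character(id), ".", fixed = TRUE))
}
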