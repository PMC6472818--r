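#' Round half away from zero
#'
#' Decimal rounding with ties broken away from zero ("half-up" for positive
#' values), matching how the study's tables are printed. Base [round()] uses
#' banker's rounding, which disagrees on exact .5 ties (e.g. 1.25 at 1 dp).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` decimal places.
#' @examples
#' round_half_up(1.25, 1)  # 1.3, where round() gives 1.2
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against e.g. 0.285 being stored just below the tie
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Competition ranking of scores (best = 1)
#'
#' Ranks in descending order of score; tied values share the minimum rank and
#' the following rank is skipped ("1224"-style), as used for the per-target
#' technology rankings.
#'
#' @param scores Numeric vector of scores (higher is better).
#' @return Integer vector of ranks, same length and names as `scores`.
#' @examples
#' competition_rank(c(A = 0.9, B = 0.5, C = 0.9))  # A=1, B=3, C=1
#' @export
competition_rank <- function(scores) {
  if (!is.numeric(scores)) abort("`scores` must be numeric.")
  if (anyNA(scores)) abort("`scores` must not contain missing values.")
  as.integer(rank(-scores, ties.method = "min"))
}
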