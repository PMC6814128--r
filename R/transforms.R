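## Normal-score transformation of ordinal class traits.

#' Normal scores for an ordinal trait
#'
#' Replaces each non-missing observation by
#' \eqn{\Phi^{-1}((r_i - 3/8)/(n + 1/4))}, where \eqn{r_i} is its mid-rank
#' among the non-missing values and n the non-missing count (Blom offsets;
#' ties share their mid-rank and hence an identical score).  Missing values
#' stay missing.  Scores are computed over the whole vector handed in, i.e.
#' per site when sites are analysed separately.
#'
#' @param x Numeric vector of ordinal codes (missing allowed).
#' @return Numeric vector of normal scores, same length and missingness as
#'   \code{x}.
#' @export
normal_score <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2L) stop("normal_score needs at least two non-missing values")
  if (length(unique(x[obs])) < 2L)
    stop("normal_score is undefined for a constant vector")
  r <- rank(x[obs], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[obs] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}
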