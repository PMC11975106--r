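# Posterior-summary utilities: one-sided evidence ratios and equal-tailed
# credibility intervals over draws. (Fitting the multilevel models that
# produce such draws is deliberately outside this package.)

#' One-sided evidence ratio from posterior draws
#'
#' The ratio of the number of draws on the hypothesised side of zero to the
#' number on the other side. 95% of draws in favour gives 19 (the
#' conventional "strong" threshold, a 95:5 ratio); all draws in favour
#' gives `Inf`. Draws exactly at zero contribute half a count to each side.
#'
#' @param draws numeric vector of at least 100 finite posterior draws.
#' @param direction `"positive"` (default) or `"negative"`: the hypothesised
#'   sign.
#' @return Non-negative ratio, possibly `Inf`.
#' @examples
#' evidence_ratio(c(rep(1, 95), rep(-1, 5)) + 0)   # 19
#' @export
evidence_ratio <- function(draws, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(draws) < 100) stop_insufficient("posterior draws", ">= 100")
  if (any(!is.finite(draws))) stop("draws must be finite")
  pos <- sum(draws > 0) + 0.5 * sum(draws == 0)
  neg <- length(draws) - pos
  ratio <- if (direction == "positive") pos / neg else neg / pos
  if (is.nan(ratio)) Inf else ratio
}

#' Equal-tailed credibility interval and median
#'
#' @param draws numeric vector of at least 100 finite posterior draws.
#' @param level interval mass in (0, 1); 0.95 gives the 2.5% and 97.5%
#'   quantiles.
#' @return Named numeric vector `low`, `median`, `high`.
#' @export
credibility_interval <- function(draws, level = 0.95) {
  if (length(draws) < 100) stop_insufficient("posterior draws", ">= 100")
  if (any(!is.finite(draws))) stop("draws must be finite")
  if (level <= 0 || level >= 1) stop("level must lie strictly in (0, 1)")
  q <- stats::quantile(draws, c((1 - level) / 2, 0.5, (1 + level) / 2),
                       names = FALSE)
  c(low = q[1], median = q[2], high = q[3])
}
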