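# Rescaling, standardisation, and variance-sharing combination of
# heterogeneous score columns into composite scores.

#' Rescale a score column to the unit interval
#'
#' `(x - min) / (max - min)` over non-missing values; missing values are
#' preserved. Used so heterogeneous replication measures can be fairly
#' weighted against each other.
#'
#' @param x numeric vector with at least 2 distinct non-missing values.
#' @return Vector in `[0, 1]` with `NA`s preserved.
#' @export
scale_unit_interval <- function(x) {
  v <- x[!is.na(x)]
  if (length(unique(v)) < 2)
    stop("degenerate column: fewer than 2 distinct values")
  (x - min(v)) / (max(v) - min(v))
}

#' Standardise a score column (z-scores)
#'
#' Centres to mean 0 and scales to SD 1 using the population SD convention
#' (divisor n). Missing values are preserved.
#'
#' @param x numeric vector with at least 2 distinct non-missing values.
#' @return Standardised vector.
#' @export
standardize <- function(x) {
  v <- x[!is.na(x)]
  if (length(unique(v)) < 2)
    stop("degenerate column: fewer than 2 distinct values")
  (x - mean(v)) / sqrt(mean((v - mean(v))^2))
}

# First-principal-axis squared-loading weights of a column block, from the
# pairwise-complete correlation matrix; non-negative, sum to 1.
vs_weights <- function(mat) {
  r <- stats::cor(mat, use = "pairwise.complete.obs")
  if (any(!is.finite(r))) stop("degenerate correlation matrix")
  e <- eigen(r, symmetric = TRUE)
  if (e$values[1] <= 1e-12) stop("singular correlation matrix")
  v <- e$vectors[, 1]
  w <- v^2 / sum(v^2)
  names(w) <- colnames(mat)
  w
}

#' Combine standardised scores by variance sharing
#'
#' Weights each selected column by the squared loading of the first
#' principal axis of the columns' correlation matrix (normalised to sum 1)
#' and returns the weighted sum. Columns that share more variance with the
#' common axis therefore contribute more; a pure-noise column is
#' down-weighted. The sign is fixed so the combined score correlates
#' positively with the across-column mean. Rows missing any selected column
#' yield a missing combined value.
#'
#' @param matrix data.frame or matrix of scores.
#' @param columns names (or indices) of at least 2 standardised columns.
#' @return List with `combined` (numeric vector) and `weights` (named,
#'   non-negative, summing to 1).
#' @export
variance_sharing_combine <- function(matrix, columns) {
  m <- as.matrix(as.data.frame(matrix)[, columns, drop = FALSE])
  if (ncol(m) < 2) stop("need at least 2 columns to combine")
  w <- vs_weights(m)
  combined <- as.numeric(m %*% w)
  combined[rowSums(is.na(m)) > 0] <- NA_real_
  cm <- rowMeans(m)
  ok <- stats::complete.cases(combined, cm)
  if (sum(ok) >= 2 && stats::sd(combined[ok]) > 0 &&
      stats::cor(combined[ok], cm[ok]) < 0)
    combined <- -combined
  list(combined = combined, weights = w)
}

#' Combined replication score
#'
#' The composite of the length-adjusted pitch DTW similarity and the
#' distributional pitch similarity: both columns are rescaled to `[0, 1]`,
#' then combined with variance-sharing weights applied on that scale, so
#' the composite stays in `[0, 1]` and typically sits above `pitchdtwladj`
#' when the distributional similarity runs higher.
#'
#' @param matrix data.frame containing columns `pitchdtwladj` and
#'   `klpitchsim`.
#' @return List with `combined` and `weights` as in
#'   [variance_sharing_combine()].
#' @export
combine_replication <- function(matrix) {
  matrix <- as.data.frame(matrix)
  need <- c("pitchdtwladj", "klpitchsim")
  if (!all(need %in% names(matrix)))
    stop("matrix must contain columns pitchdtwladj and klpitchsim")
  m <- cbind(pitchdtwladj = scale_unit_interval(matrix$pitchdtwladj),
             klpitchsim = scale_unit_interval(matrix$klpitchsim))
  w <- vs_weights(m)
  combined <- as.numeric(m %*% w)
  combined[rowSums(is.na(m)) > 0] <- NA_real_
  list(combined = combined, weights = w)
}
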