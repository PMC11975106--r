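# Subsequence dynamic time warping.
#
# The performance must be consumed in full while the reference is open at
# both ends, so a correctly played fragment aligns against its best-matching
# reference segment at zero cost. Steps are diagonal, vertical and
# horizontal with unit weights; each visited cell contributes its local cost
# once. The optimal path minimises cumulative cost, with ties broken by
# shorter path length; the reported distance is then normalised by path
# length times the local-cost cap so it lies in [0, 1].

DTW_COST_CAP <- 12        # semitone cost cap (one octave)
DTW_MATCH_TOL <- 0        # exact pitch for the aligned proportion
PIOI_W_IOI <- 1           # weight of the timing component in the joint cost
PIOI_MATCH_TOL <- 0.1     # combined-cost tolerance for the joint proportion

# DP over an n x m local-cost matrix; returns the optimal path and its raw
# cumulative cost. Open begin/end on columns (the reference axis).
dtw_core <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  C <- matrix(Inf, n, m); L <- matrix(0L, n, m); P <- matrix(0L, n, m)
  C[1, ] <- cost[1, ]; L[1, ] <- 1L                 # free start anywhere
  if (n >= 2) for (i in 2:n) for (j in 1:m) {
    # candidate predecessors: 1 = diagonal, 2 = vertical, 3 = horizontal
    bc <- C[i - 1L, j]; bl <- L[i - 1L, j]; bp <- 2L
    if (j >= 2L) {
      cc <- C[i - 1L, j - 1L]; cl <- L[i - 1L, j - 1L]
      if (cc < bc || (cc == bc && cl < bl)) { bc <- cc; bl <- cl; bp <- 1L }
      else if (cc == bc && cl == bl) bp <- 1L       # prefer diagonal on ties
      hc <- C[i, j - 1L]; hl <- L[i, j - 1L]
      if (hc < bc || (hc == bc && hl < bl)) { bc <- hc; bl <- hl; bp <- 3L }
    }
    C[i, j] <- bc + cost[i, j]; L[i, j] <- bl + 1L; P[i, j] <- bp
  }
  # end tie-break: minimal cost, then minimal length, then rightmost column
  # (maximal reference coverage of the rendered segment)
  ends <- which(C[n, ] == min(C[n, ]))
  ends <- ends[L[n, ends] == min(L[n, ends])]
  jend <- max(ends)
  # backtrack
  path <- matrix(0L, L[n, jend], 2L)
  i <- n; j <- jend; k <- nrow(path)
  repeat {
    path[k, ] <- c(i, j); k <- k - 1L
    p <- P[i, j]
    if (p == 0L) break
    if (p == 1L) { i <- i - 1L; j <- j - 1L }
    else if (p == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(cost = C[n, jend], path = path, length = nrow(path))
}

#' Align a performed pitch sequence against a reference
#'
#' Subsequence DTW (open-begin/open-end on the reference) with local cost
#' `min(|pitch difference|, 12)` semitones. The normalised distance is the
#' cumulative cost along the optimal path divided by path length times the
#' 12-semitone cap, so identical sequences score 0 and nothing exceeds 1.
#'
#' @param perf_pitches,ref_pitches non-empty integer vectors of MIDI pitches.
#' @param match_tol local cost at or below which a reference position counts
#'   as matched (default 0, exact pitch).
#' @return An object of class `AlignmentResult`: list with `path` (two-column
#'   matrix of performance/reference indices), `normalized_distance`,
#'   `matched_ref_indices`, `ref_length`.
#' @examples
#' a <- dtw_align(c(60, 62, 64), c(60, 62, 64, 65, 67))
#' a$normalized_distance    # 0: exact fragment
#' @export
dtw_align <- function(perf_pitches, ref_pitches, match_tol = DTW_MATCH_TOL) {
  if (!length(perf_pitches) || !length(ref_pitches))
    stop_insufficient("empty pitch sequence", ">= 1 pitch each")
  cost <- pmin(abs(outer(as.numeric(perf_pitches), as.numeric(ref_pitches),
                         "-")), DTW_COST_CAP)
  res <- dtw_core(cost)
  local <- cost[res$path]
  matched <- sort(unique(res$path[local <= match_tol, 2L]))
  structure(list(path = res$path,
                 normalized_distance = res$cost / (res$length * DTW_COST_CAP),
                 matched_ref_indices = matched,
                 ref_length = length(ref_pitches)),
            class = "AlignmentResult")
}

#' DTW similarity from an alignment
#'
#' One minus the normalised DTW distance, clipped to `[0, 1]`; the
#' `pitchdtwsim` measure.
#'
#' @param alignment an [dtw_align()] result.
#' @return Similarity in `[0, 1]`.
#' @export
pitch_similarity <- function(alignment) {
  stopifnot(inherits(alignment, "AlignmentResult"))
  min(max(1 - alignment$normalized_distance, 0), 1)
}

#' Proportion of the reference matched by the performance
#'
#' The `palignedprop` measure: the fraction of reference positions that find
#' a counterpart (within the match tolerance) on the optimal warping path. A
#' perfect 5-note fragment of a 15-note reference scores 5/15.
#'
#' @param alignment an [dtw_align()] result.
#' @param ref_length reference length; defaults to the one recorded in the
#'   alignment.
#' @return Proportion in `[0, 1]`.
#' @export
aligned_proportion <- function(alignment, ref_length = alignment$ref_length) {
  stopifnot(inherits(alignment, "AlignmentResult"), ref_length >= 1)
  length(alignment$matched_ref_indices) / ref_length
}

#' Length-adjusted similarity
#'
#' The exact product of a DTW similarity and the corresponding aligned
#' proportion (`pitchdtwladj`, `pioidtwladj`), so fair replications of short
#' sections attract lower scores than equally fair replications of longer
#' ones.
#'
#' @param sim,prop values in `[0, 1]`.
#' @return `sim * prop`.
#' @export
length_adjusted <- function(sim, prop) {
  if (any(c(sim, prop) < 0) || any(c(sim, prop) > 1))
    stop("arguments must lie in [0, 1]")
  sim * prop
}
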