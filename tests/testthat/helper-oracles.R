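# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# Enumerate every monotone warping path (open begin/end on the reference),
# minimise cumulative cost with ties broken by shorter path, and return the
# normalised distance cost / (length * cap). Feasible for sequences <= ~7.
bf_dtw_distance <- function(perf, ref, cap = 12, cost_fun = NULL) {
  if (is.null(cost_fun))
    cost_fun <- function(a, b) min(abs(a - b), cap)
  n <- length(perf); m <- length(ref)
  best <- c(Inf, Inf)  # cost, length
  walk <- function(i, j, cost, len) {
    cost <- cost + cost_fun(perf[i], ref[j])
    len <- len + 1
    if (i == n) {
      if (cost < best[1] || (cost == best[1] && len < best[2]))
        best <<- c(cost, len)
      # horizontal continuation from row n can only lengthen the path
    }
    if (i < n) {
      walk(i + 1, j, cost, len)
      if (j < m) walk(i + 1, j + 1, cost, len)
    }
    if (j < m) walk(i, j + 1, cost, len)
  }
  for (j0 in seq_len(m)) walk(1, j0, 0, 0)
  best[1] / (best[2] * cap)
}

# Greedy retrograde note count by direct segment-pair search: at each
# position take the longest segment (>= min_len) whose pitches reverse an
# earlier, fully preceding segment; counted occurrences never overlap.
bf_retrograde_notes <- function(p, min_len = 3) {
  n <- length(p)
  count <- 0; s <- 1
  while (s <= n) {
    hit <- 0
    maxL <- min(n - s + 1, s - 1)
    if (maxL >= min_len) for (L in seq(maxL, min_len, by = -1)) {
      ok <- FALSE
      for (a in seq_len(s - L))
        if (identical(p[s:(s + L - 1)], rev(p[a:(a + L - 1)]))) { ok <- TRUE; break }
      if (ok) { hit <- L; break }
    }
    if (hit > 0) { count <- count + hit; s <- s + hit } else s <- s + 1
  }
  count
}

bf_sequence_notes <- function(p, min_len = 3) {
  n <- length(p)
  count <- 0; s <- 1
  while (s <= n) {
    hit <- 0
    maxL <- min(n - s + 1, s - 1)
    if (maxL >= min_len) for (L in seq(maxL, min_len, by = -1)) {
      ok <- FALSE
      for (a in seq_len(s - L)) {
        d <- p[s:(s + L - 1)] - p[a:(a + L - 1)]
        if (d[1] != 0 && all(d == d[1])) { ok <- TRUE; break }
      }
      if (ok) { hit <- L; break }
    }
    if (hit > 0) { count <- count + hit; s <- s + hit } else s <- s + 1
  }
  count
}

# Build a simple isochronous performance from pitches (0.5 s grid).
mk_perf <- function(pitch, ioi = 0.5, ratio = 0.8, velocity = 64) {
  n <- length(pitch)
  iois <- rep_len(ioi, n)
  onset <- cumsum(c(0, iois[-n]))
  performance(pitch, onset, onset + ratio * iois, velocity = velocity)
}

# All pitch sequences of the given lengths over an alphabet.
all_sequences <- function(alphabet, lengths) {
  out <- list()
  for (l in lengths) {
    g <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, lapply(seq_len(nrow(g)), function(k) as.numeric(g[k, ])))
  }
  out
}
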