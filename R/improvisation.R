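# The eighteen improvisation measures ("scoretypes"): note extent,
# diversity/range of intervals, IOIs and pitches, repeated and passing
# notes, dynamics (crescendo/diminuendo runs, accents), rests, windowed
# tempo statistics, articulation variation, and detectors for retrogrades
# and transposed sequences. Infeasible measures are returned as NA, never
# silently 0, so downstream standardisation is not biased.

CRESC_RUN_MIN <- 3L       # minimum notes in a crescendo/diminuendo run
CRESC_VEL_MIN <- 10L      # minimum total velocity change across a run
ACCENT_DELTA <- 15L       # velocity excess over the local window mean
ACCENT_WINDOW <- 5L       # centred window (self excluded, edge-truncated)
IMPROV_WINDOW <- 4L       # IOIs per sliding window for the M9 measures
PATTERN_MIN_LEN <- 3L     # minimum notes in a retrograde/sequence segment

IMPROV_MEASURES <- c(
  "NumNotes", "M1pintervaldivers", "M1pintervalrange", "M2ioidivers",
  "M2ioirange", "M3pitchdivers", "M3prange", "M4repeatnotes",
  "M5Passnotesprop", "M6crescdim", "M7AccentProp", "M8silenceprop",
  "M9windioirange", "M12VaryStaccLeg", "M13retronotes", "M14sequences",
  "M12aStaccLegabsdiff", "M9aWindioiabsdiff")

#' Map improvisation tasks to their most pertinent measure
#'
#' Each of the 14 taught variation methods has one designated scoretype used
#' when assessing whether that method was learned:
#' `1:8, 2:9, 3:3, 4:4, 5:10, 6:11, 7:12, 8:18, 9:17, 10:17, 11:17, 12:15,
#' 13:16, 14:3` (tasks 9-11 share the articulation measure; 3 and 14 share
#' the interval range).
#'
#' @return data.frame with columns `task` (1-14), `scoretype` (index into
#'   the 18-measure list) and `measure` (its name).
#' @export
task_score_map <- function() {
  scoretype <- c(8L, 9L, 3L, 4L, 10L, 11L, 12L, 18L, 17L, 17L, 17L, 15L,
                 16L, 3L)
  data.frame(task = 1:14, scoretype = scoretype,
             measure = IMPROV_MEASURES[scoretype])
}

#' Number of notes
#' @param perf a [performance()].
#' @return Note count (the taught ceiling for improvisations was 30).
#' @export
num_notes <- function(perf) n_notes(perf)

#' Shannon diversity of a discrete value sequence
#'
#' Base-2 entropy of the relative-frequency distribution, used for interval,
#' pitch and IOI diversity. IOIs are first discretised into the same
#' log2-ratio-to-median bins as [ioi_distribution()]; intervals and pitches
#' are used as exact integers. A distinct-value count is available as an
#' alternative convention.
#'
#' @param values non-empty vector (discrete after any binning).
#' @param type `"entropy"` (bits, default) or `"distinct"` (count).
#' @return Non-negative diversity; 0 for a constant sequence and at most
#'   `log2(number of distinct values)`.
#' @export
diversity <- function(values, type = c("entropy", "distinct")) {
  type <- match.arg(type)
  if (!length(values)) stop_insufficient("empty value sequence", ">= 1 value")
  if (type == "distinct") return(length(unique(values)))
  p <- as.numeric(table(values)) / length(values)
  -sum(p * log2(p))
}

#' Range of an ordered-scale value sequence
#' @param values non-empty numeric vector.
#' @return `max - min`, in the input's units.
#' @export
value_range <- function(values) {
  if (!length(values)) stop_insufficient("empty value sequence", ">= 1 value")
  diff(range(values))
}

#' Count of immediately repeated notes
#' @param perf a non-empty [performance()].
#' @return Number of notes whose pitch equals the preceding note's pitch.
#' @export
repeat_notes <- function(perf) {
  p <- perf$notes$pitch
  if (!length(p)) stop_insufficient("empty performance", ">= 1 note")
  sum(diff(p) == 0L)
}

#' Proportion of passing/neighbour notes
#'
#' A passing note lies close to its antecedent: within `tol` semitones
#' (default 1-2, i.e. a step) but not a repetition.
#'
#' @param perf a [performance()] with at least 2 notes.
#' @param tol inclusive semitone range `c(min, max)` counted as "close".
#' @return Proportion of notes 2..n that are passing notes (denominator
#'   n - 1).
#' @export
passing_notes_prop <- function(perf, tol = c(1L, 2L)) {
  p <- perf$notes$pitch
  if (length(p) < 2) stop_insufficient("passing notes", ">= 2 notes")
  d <- abs(diff(p))
  mean(d >= tol[1] & d <= tol[2])
}

#' Count of crescendos and diminuendos
#'
#' Maximal strictly monotone velocity runs of at least `run_min` notes whose
#' total change is at least `vel_min` count as one crescendo or diminuendo
#' (gradual loudness change, as taught).
#'
#' @param perf a [performance()].
#' @param run_min minimum run length in notes (default 3).
#' @param vel_min minimum total velocity change (default 10).
#' @return Non-negative count (0 for short or flat inputs).
#' @export
cresc_dim_count <- function(perf, run_min = CRESC_RUN_MIN,
                            vel_min = CRESC_VEL_MIN) {
  v <- perf$notes$velocity
  if (length(v) < run_min) return(0L)
  s <- sign(diff(v))
  count <- 0L
  start <- 1L
  for (k in seq_along(s)) {
    if (k == length(s) || s[k + 1L] != s[k] || s[k] == 0) {
      # run of equal-signed steps from `start` to k covers notes start..k+1
      if (s[k] != 0 && (k + 1L - start + 1L) >= run_min &&
          abs(v[k + 1L] - v[start]) >= vel_min)
        count <- count + 1L
      start <- k + 1L
    }
  }
  count
}

#' Proportion of accented notes
#'
#' A note is accented when its velocity exceeds the mean of its surrounding
#' window (up to 2 notes each side, self excluded, truncated at the edges)
#' by at least `delta` (abrupt loudness change, as taught).
#'
#' @param perf a [performance()] with at least 3 notes.
#' @param delta velocity excess threshold (default 15).
#' @param window full window size including self (default 5).
#' @return Proportion in `[0, 1]` over all notes.
#' @export
accent_prop <- function(perf, delta = ACCENT_DELTA, window = ACCENT_WINDOW) {
  v <- perf$notes$velocity
  n <- length(v)
  if (n < 3) stop_insufficient("accents", ">= 3 notes")
  half <- (window - 1L) %/% 2L
  acc <- vapply(seq_len(n), function(i) {
    idx <- setdiff(max(1L, i - half):min(n, i + half), i)
    v[i] - mean(v[idx]) >= delta
  }, logical(1))
  mean(acc)
}

#' Proportion of performed time that is silent
#'
#' Sum of positive gaps between a note's offset and the next onset, divided
#' by the total span (last offset minus first onset).
#'
#' @param perf a monophonic [performance()] with at least 2 notes.
#' @return Proportion in `[0, 1]`; 0 for perfectly legato playing.
#' @export
silence_prop <- function(perf) {
  notes <- perf$notes
  n <- nrow(notes)
  if (n < 2) stop_insufficient("silences", ">= 2 notes")
  gaps <- pmax(notes$onset[-1] - notes$offset[-n], 0)
  sum(gaps) / (notes$offset[n] - notes$onset[1])
}

#' Windowed IOI statistics
#'
#' Average IOIs over sliding windows of `window` consecutive IOIs (step 1):
#' `M9windioirange` is the range (max - min) of the window means, and
#' `M9aWindioiabsdiff` the mean absolute difference between successive
#' window means. Both are 0 for isochronous playing and grow with deliberate
#' speed changes.
#'
#' @param perf a [performance()] with at least `window + 1` notes.
#' @param window IOIs per window (default 4).
#' @return Named list `M9windioirange`, `M9aWindioiabsdiff` (seconds).
#' @export
windowed_ioi_stats <- function(perf, window = IMPROV_WINDOW) {
  iois <- compute_iois(perf)
  if (length(iois) < window)
    stop_insufficient("windowed IOI stats", sprintf(">= %d notes", window + 1))
  k <- length(iois) - window + 1L
  means <- vapply(seq_len(k), function(i) mean(iois[i:(i + window - 1L)]),
                  numeric(1))
  list(M9windioirange = diff(range(means)),
       M9aWindioiabsdiff = if (k >= 2) mean(abs(diff(means))) else 0)
}

#' Articulation (staccato/legato) statistics
#'
#' For each note but the last, the articulation ratio is its duration over
#' its IOI, capped at 1 (1 = legato, small = staccato). `M12VaryStaccLeg` is
#' the population standard deviation of these ratios; `M12aStaccLegabsdiff`
#' the mean of `|duration[i+1] - duration[i]| / ioi[i]` over adjacent pairs
#' (absolute values keep every contribution positive).
#'
#' @param perf a [performance()] with at least 3 notes.
#' @return Named list `M12VaryStaccLeg`, `M12aStaccLegabsdiff`.
#' @export
articulation_stats <- function(perf) {
  notes <- perf$notes
  n <- nrow(notes)
  if (n < 3) stop_insufficient("articulation stats", ">= 3 notes")
  iois <- diff(notes$onset)
  dur <- notes$offset - notes$onset
  a <- pmin(dur[-n] / iois, 1)
  list(M12VaryStaccLeg = sqrt(mean((a - mean(a))^2)),
       M12aStaccLegabsdiff = mean(abs(diff(dur)) / iois))
}

# Greedy left-to-right detector shared by the retrograde and sequence
# measures. `match_fun(a, s, L)` says whether the earlier segment starting
# at `a` matches the later one starting at `s`, both of length L. Later
# occurrences are non-overlapping; an earlier segment must end before the
# later one starts. Leftmost position first, longest match at each position.
scan_pattern_notes <- function(n, min_len, match_fun) {
  count <- 0L
  s <- min_len + 1L          # need at least min_len earlier notes
  while (s <= n - min_len + 1L) {
    best <- 0L
    max_len <- min(n - s + 1L, s - 1L)  # earlier copy must fit before s
    if (max_len >= min_len) for (L in max_len:min_len) {
      found <- FALSE
      for (a in 1:(s - L)) if (match_fun(a, s, L)) { found <- TRUE; break }
      if (found) { best <- L; break }
    }
    if (best > 0L) { count <- count + best; s <- s + best }
    else s <- s + 1L
  }
  count
}

#' Notes involved in melodic retrogrades
#'
#' Scans left to right for non-overlapping contiguous segments of at least
#' `min_len` notes whose pitch sequence is the exact reverse of an earlier,
#' non-overlapping contiguous segment. Counts the notes of the later
#' (retrograde) occurrences only; at each position the longest match wins.
#'
#' @param perf a [performance()].
#' @param min_len minimum segment length (default 3).
#' @return Non-negative note count (0 when shorter than `2 * min_len`).
#' @export
retrograde_notes <- function(perf, min_len = PATTERN_MIN_LEN) {
  p <- perf$notes$pitch
  n <- length(p)
  if (n < 2L * min_len) return(0L)
  scan_pattern_notes(n, min_len, function(a, s, L) {
    if (a + L - 1L >= s) return(FALSE)
    all(p[s:(s + L - 1L)] == rev(p[a:(a + L - 1L)]))
  })
}

#' Notes involved in transposed sequences
#'
#' Scans left to right for non-overlapping contiguous segments of at least
#' `min_len` notes whose interval pattern equals that of an earlier segment
#' at a non-zero uniform transposition (a musical "sequence": repeat higher
#' or lower). Literal zero-transposition repeats are excluded. Counts the
#' notes of the later occurrences only.
#'
#' @inheritParams retrograde_notes
#' @return Non-negative note count.
#' @export
sequence_notes <- function(perf, min_len = PATTERN_MIN_LEN) {
  p <- perf$notes$pitch
  n <- length(p)
  if (n < 2L * min_len) return(0L)
  scan_pattern_notes(n, min_len, function(a, s, L) {
    if (a + L - 1L >= s) return(FALSE)
    shift <- p[s] - p[a]
    shift != 0L && all(p[s:(s + L - 1L)] - p[a:(a + L - 1L)] == shift)
  })
}

#' Score an improvisation with all 18 measures
#'
#' Computes every scoretype from a monophonic performance. Measures whose
#' preconditions fail for a short input are returned as `NA` (flagged
#' missing), never coerced to 0. The optional prompt is carried through for
#' bookkeeping; the measures themselves are functions of the improvisation
#' alone.
#'
#' @param perf a monophonic [performance()] with at least 2 notes.
#' @param prompt optional 3-5-note prompt [performance()].
#' @return Named list of class `improv_scores` with the 18 measures in the
#'   canonical order of `IMPROV_MEASURES`.
#' @export
score_improvisation <- function(perf, prompt = NULL) {
  stopifnot(inherits(perf, "Performance"))
  n <- n_notes(perf)
  if (n < 2) stop_insufficient("improvisation scoring", ">= 2 notes")
  p <- perf$notes$pitch
  intervals <- diff(p)
  iois <- compute_iois(perf)
  ioi_bins <- ioi_bin_index(log2(iois / stats::median(iois)))

  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  wioi <- try_na(windowed_ioi_stats(perf))
  artic <- try_na(articulation_stats(perf))

  out <- list(
    NumNotes = n,
    M1pintervaldivers = diversity(intervals),
    M1pintervalrange = value_range(intervals),
    M2ioidivers = diversity(ioi_bins),
    M2ioirange = value_range(iois),
    M3pitchdivers = diversity(p),
    M3prange = value_range(p),
    M4repeatnotes = repeat_notes(perf),
    M5Passnotesprop = passing_notes_prop(perf),
    M6crescdim = cresc_dim_count(perf),
    M7AccentProp = try_na(accent_prop(perf)),
    M8silenceprop = silence_prop(perf),
    M9windioirange = if (all(is.na(wioi))) NA_real_ else wioi$M9windioirange,
    M12VaryStaccLeg = if (all(is.na(artic))) NA_real_ else artic$M12VaryStaccLeg,
    M13retronotes = retrograde_notes(perf),
    M14sequences = sequence_notes(perf),
    M12aStaccLegabsdiff = if (all(is.na(artic))) NA_real_ else artic$M12aStaccLegabsdiff,
    M9aWindioiabsdiff = if (all(is.na(wioi))) NA_real_ else wioi$M9aWindioiabsdiff)
  structure(out, prompt_notes = if (is.null(prompt)) NA_integer_ else
    n_notes(prompt), class = "improv_scores")
}

#' @export
print.improv_scores <- function(x, ...) {
  cat("Improvisation scores (raw units):\n")
  print(round(unlist(x), 4))
  invisible(x)
}
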