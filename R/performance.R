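#' Construct a monophonic performance
#'
#' A `Performance` is the package's internal representation of one recorded
#' rendition: an ordered sequence of sounded notes plus session metadata.
#' Notes are kept sorted by onset (ties broken by pitch) and all times are in
#' seconds; tick arithmetic lives only at the MIDI I/O boundary.
#'
#' @param pitch integer vector of MIDI note numbers (0-127).
#' @param onset numeric vector of note-on times in seconds (>= 0).
#' @param offset numeric vector of note-off times in seconds; each must
#'   exceed the corresponding onset.
#' @param velocity integer vector of MIDI velocities (1-127); recycled if
#'   length 1.
#' @param meta optional metadata list, see [performance_metadata()].
#' @return An object of class `Performance`: a list with elements `notes`
#'   (a data.frame with columns `pitch`, `onset`, `offset`, `velocity`) and
#'   `meta`.
#' @examples
#' p <- performance(c(60, 62, 64), c(0, 0.5, 1), c(0.4, 0.9, 1.4))
#' n_notes(p)
#' @export
performance <- function(pitch, onset, offset, velocity = 64L, meta = list()) {
  n <- length(pitch)
  if (length(onset) != n || length(offset) != n)
    stop("pitch, onset and offset must have equal length")
  velocity <- rep_len(as.integer(velocity), n)
  pitch <- as.integer(pitch)
  if (n > 0) {
    if (any(pitch < 0L | pitch > 127L)) stop("pitch outside MIDI range 0-127")
    if (any(velocity < 1L | velocity > 127L)) stop("velocity outside 1-127")
    if (any(onset < 0)) stop("onsets must be >= 0")
    if (any(offset <= onset)) stop("every offset must exceed its onset")
  }
  notes <- data.frame(pitch = pitch, onset = as.numeric(onset),
                      offset = as.numeric(offset), velocity = velocity)
  ord <- order(notes$onset, notes$pitch)
  notes <- notes[ord, , drop = FALSE]
  rownames(notes) <- NULL
  structure(list(notes = notes, meta = meta), class = "Performance")
}

#' Session metadata for a performance
#'
#' Describes where a performance sits in the longitudinal cross-over design:
#' who played, which 3-month session, which of the five performance items,
#' which instrument, and how many improvisation (`imprct`) and replication
#' (`repct`) training blocks the participant had completed at that point.
#'
#' @param participant_id,group opaque labels.
#' @param session one of `"m0","m3","m6","m9","m12","m15","m18"`.
#' @param item performance item 1-5 (1-3 replication, 4-5 improvisation).
#' @param instrument `"kbipK"` (keyboard) or `"kbipI"` (iPad).
#' @param imprct,repct completed improvisation / replication training blocks,
#'   each 0-2 with `imprct + repct <= 4`.
#' @param nimptasks number of improvisation tasks claimed (item 5).
#' @param claimed_tasks integer subset of 1:14.
#' @return A named list of class `PerformanceMetadata`.
#' @export
performance_metadata <- function(participant_id = NA_character_,
                                 group = NA_character_,
                                 session = NA_character_,
                                 item = NA_integer_,
                                 instrument = NA_character_,
                                 imprct = NA_integer_, repct = NA_integer_,
                                 nimptasks = NA_integer_,
                                 claimed_tasks = integer()) {
  sessions <- c("m0", "m3", "m6", "m9", "m12", "m15", "m18")
  if (!is.na(session) && !session %in% sessions)
    stop("session must be one of ", paste(sessions, collapse = ", "))
  if (!is.na(item) && !(item %in% 1:5)) stop("item must be in 1..5")
  if (!is.na(instrument) && !instrument %in% c("kbipK", "kbipI"))
    stop("instrument must be 'kbipK' or 'kbipI'")
  if (!is.na(imprct) && !is.na(repct) && imprct + repct > 4)
    stop("imprct + repct must be <= 4")
  if (length(claimed_tasks) && !all(claimed_tasks %in% 1:14))
    stop("claimed_tasks must be a subset of 1:14")
  structure(list(participant_id = participant_id, group = group,
                 session = session, item = as.integer(item),
                 instrument = instrument, imprct = as.integer(imprct),
                 repct = as.integer(repct), nimptasks = as.integer(nimptasks),
                 claimed_tasks = as.integer(claimed_tasks)),
            class = "PerformanceMetadata")
}

#' @export
print.Performance <- function(x, ...) {
  n <- nrow(x$notes)
  cat(sprintf("<Performance: %d note%s", n, if (n == 1) "" else "s"))
  if (n > 0)
    cat(sprintf(", %.2f-%.2f s, pitch %d-%d", min(x$notes$onset),
                max(x$notes$offset), min(x$notes$pitch), max(x$notes$pitch)))
  cat(">\n")
  if (!is.null(x$meta$participant_id) && !is.na(x$meta$participant_id))
    cat(sprintf("  participant %s, session %s, item %s\n",
                x$meta$participant_id, x$meta$session, x$meta$item))
  invisible(x)
}

#' @export
as.data.frame.Performance <- function(x, ...) x$notes

#' Number of notes in a performance
#' @param perf a [performance()].
#' @return Integer note count.
#' @export
n_notes <- function(perf) {
  stopifnot(inherits(perf, "Performance"))
  nrow(perf$notes)
}

#' Resolve overlaps to a strictly monophonic note stream
#'
#' An earlier note that is still sounding when the next begins is truncated
#' to the next onset (truncation, not deletion, so the pitch sequence is
#' preserved); notes left with non-positive duration are dropped. The result
#' satisfies the no-overlap invariant and the operation is idempotent.
#'
#' @param perf a [performance()].
#' @return A `Performance` with no overlapping notes.
#' @export
extract_monophonic <- function(perf) {
  stopifnot(inherits(perf, "Performance"))
  notes <- perf$notes
  n <- nrow(notes)
  if (n < 2) return(perf)
  off <- notes$offset
  # notes already sorted by onset; clip each offset at the next onset
  off[-n] <- pmin(off[-n], notes$onset[-1])
  keep <- off > notes$onset
  notes$offset <- off
  notes <- notes[keep, , drop = FALSE]
  rownames(notes) <- NULL
  structure(list(notes = notes, meta = perf$meta), class = "Performance")
}

#' Inter-onset intervals of a performance
#'
#' The IOI is the time between successive note onsets, the basic timing unit
#' of all the timing-sensitive measures.
#'
#' @param perf a [performance()] with at least 2 notes.
#' @return Numeric vector of `n_notes(perf) - 1` positive intervals, seconds.
#' @export
compute_iois <- function(perf) {
  stopifnot(inherits(perf, "Performance"))
  n <- n_notes(perf)
  if (n < 2) stop_insufficient("IOIs require >= 2 notes", ">= 2 notes")
  diff(perf$notes$onset)
}
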