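# Standard MIDI File I/O.
#
# Reading supports SMF type 0 and 1 (metrical division only), merges all
# tracks/channels except percussion (channel 10), honours the tempo map when
# converting ticks to seconds, and treats velocity-0 note-ons as note-offs.
# Writing emits a type 0 file at PPQ 480 and a fixed 120 BPM tempo.

MIDI_PPQ <- 480L
MIDI_TEMPO_US <- 500000L  # microseconds per quarter note = 120 BPM

# --- byte helpers -----------------------------------------------------------

u32be <- function(x) as.raw(c(bitwAnd(bitwShiftR(x, 24), 255L),
                              bitwAnd(bitwShiftR(x, 16), 255L),
                              bitwAnd(bitwShiftR(x, 8), 255L),
                              bitwAnd(x, 255L)))
u16be <- function(x) as.raw(c(bitwAnd(bitwShiftR(x, 8), 255L),
                              bitwAnd(x, 255L)))

read_u32be <- function(b, i) sum(as.integer(b[i:(i + 3)]) * c(16777216, 65536, 256, 1))
read_u16be <- function(b, i) sum(as.integer(b[i:(i + 1)]) * c(256, 1))

# MIDI variable-length quantity encoding of a non-negative integer
encode_varint <- function(x) {
  stopifnot(x >= 0)
  bytes <- bitwAnd(x, 127L)
  x <- bitwShiftR(x, 7L)
  while (x > 0) {
    bytes <- c(bitwOr(bitwAnd(x, 127L), 128L), bytes)
    x <- bitwShiftR(x, 7L)
  }
  as.raw(bytes)
}

# decode varint starting at position i; returns list(value, next_pos)
decode_varint <- function(b, i) {
  val <- 0L
  repeat {
    byte <- as.integer(b[i]); i <- i + 1L
    val <- bitwOr(bitwShiftL(val, 7L), bitwAnd(byte, 127L))
    if (byte < 128L) break
  }
  list(value = val, pos = i)
}

# --- writing ----------------------------------------------------------------

#' Write a performance as a Standard MIDI File
#'
#' Emits SMF type 0, single track, PPQ 480, fixed tempo 120 BPM. Onsets and
#' offsets are quantised to the nearest tick; a note quantised to zero
#' duration is stretched to one tick so it survives a round trip.
#'
#' @param perf a non-empty [performance()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [read_midi()]
#' @export
write_midi <- function(perf, path) {
  stopifnot(inherits(perf, "Performance"))
  notes <- perf$notes
  if (nrow(notes) == 0) stop("cannot write an empty performance")
  ticks_per_sec <- MIDI_PPQ * 1e6 / MIDI_TEMPO_US
  on_tick <- as.integer(round(notes$onset * ticks_per_sec))
  off_tick <- as.integer(round(notes$offset * ticks_per_sec))
  off_tick <- pmax(off_tick, on_tick + 1L)  # >= 1 tick after quantisation

  ev <- data.frame(
    tick = c(on_tick, off_tick),
    kind = rep(c(1L, 0L), each = nrow(notes)),  # offs sort before ons
    pitch = rep(notes$pitch, 2L),
    vel = c(notes$velocity, rep(0L, nrow(notes))))
  ev <- ev[order(ev$tick, ev$kind, ev$pitch), , drop = FALSE]

  body <- list(as.raw(c(0x00, 0xFF, 0x51, 0x03)),
               as.raw(c(0x07, 0xA1, 0x20)))  # 500000 us/qn
  prev <- 0L
  for (k in seq_len(nrow(ev))) {
    delta <- ev$tick[k] - prev
    prev <- ev$tick[k]
    status <- if (ev$kind[k] == 1L) 0x90 else 0x80
    body[[length(body) + 1L]] <-
      c(encode_varint(delta), as.raw(c(status, ev$pitch[k], ev$vel[k])))
  }
  body[[length(body) + 1L]] <- as.raw(c(0x00, 0xFF, 0x2F, 0x00))
  track <- do.call(c, body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), u32be(6L), u16be(0L), u16be(1L),
             u16be(MIDI_PPQ),
             charToRaw("MTrk"), u32be(length(track)), track), con)
  invisible(path)
}

# --- reading ----------------------------------------------------------------

#' Read a Standard MIDI File as a performance
#'
#' Parses SMF type 0 or 1, merges all tracks and channels (percussion
#' channel 10 is ignored), applies the file's tempo map to convert ticks to
#' seconds, and pairs note-ons with note-offs (velocity-0 note-ons count as
#' note-offs). Metadata fields are left unset; attach them with
#' [performance_metadata()] or a sidecar CSV.
#'
#' @param path path to a `.mid` file.
#' @param unmatched what to do with a note-on that never receives a
#'   note-off: `"close"` (default) closes it at the track end, `"error"`
#'   raises a format error.
#' @return A [performance()] (not yet overlap-resolved; see
#'   [extract_monophonic()]).
#' @export
read_midi <- function(path, unmatched = c("close", "error")) {
  unmatched <- match.arg(unmatched)
  b <- readBin(path, "raw", file.info(path)$size)
  if (length(b) < 14 || rawToChar(b[1:4]) != "MThd")
    stop("not a Standard MIDI File: ", path)
  fmt <- read_u16be(b, 9L)
  ntrk <- read_u16be(b, 11L)
  division <- read_u16be(b, 13L)
  if (fmt > 1L) stop("unsupported SMF type ", fmt, " (only 0/1)")
  if (bitwAnd(division, 32768L) != 0L)
    stop("SMPTE time division not supported")

  pos <- 15L
  notes <- list()
  tempos <- list()  # (tick, us_per_qn)
  for (trk in seq_len(ntrk)) {
    if (pos + 7L > length(b) + 1L) stop("truncated MIDI file")
    if (rawToChar(b[pos:(pos + 3L)]) != "MTrk") stop("missing MTrk chunk")
    tlen <- read_u32be(b, pos + 4L)
    i <- pos + 8L
    end <- i + tlen
    pos <- end
    tick <- 0L
    status <- NA_integer_
    open <- list()  # per channel+pitch: list of (tick, velocity)
    track_notes <- list()
    while (i < end) {
      d <- decode_varint(b, i); i <- d$pos
      tick <- tick + d$value
      byte <- as.integer(b[i])
      if (byte >= 128L) { status <- byte; i <- i + 1L }
      else if (is.na(status)) stop("malformed MIDI: data byte with no status")
      hi <- bitwShiftR(status, 4L)
      ch <- bitwAnd(status, 15L)
      if (status == 255L) {                       # meta event
        type <- as.integer(b[i]); i <- i + 1L
        d <- decode_varint(b, i); i <- d$pos
        if (type == 81L && d$value == 3L)
          tempos[[length(tempos) + 1L]] <-
            c(tick, sum(as.integer(b[i:(i + 2L)]) * c(65536, 256, 1)))
        i <- i + d$value
      } else if (status %in% c(240L, 247L)) {     # sysex
        d <- decode_varint(b, i); i <- d$pos
        i <- i + d$value
      } else if (hi %in% c(8L, 9L)) {             # note off / note on
        pitch <- as.integer(b[i]); vel <- as.integer(b[i + 1L]); i <- i + 2L
        if (ch == 9L) next                        # percussion channel 10
        key <- paste0(ch, ":", pitch)
        if (hi == 9L && vel > 0L) {
          open[[key]] <- c(open[[key]], list(c(tick, vel)))
        } else {
          stack <- open[[key]]
          if (length(stack)) {
            started <- stack[[1L]]
            open[[key]] <- stack[-1L]
            if (tick > started[1L])
              track_notes[[length(track_notes) + 1L]] <-
                c(pitch, started[1L], tick, started[2L])
          }
        }
      } else if (hi %in% c(10L, 11L, 14L)) {      # aftertouch/CC/pitch bend
        i <- i + 2L
      } else if (hi %in% c(12L, 13L)) {           # program change/pressure
        i <- i + 1L
      } else stop("unhandled MIDI status byte ", status)
    }
    if (length(open) && any(lengths(open) > 0)) {
      if (unmatched == "error")
        stop("note-on without matching note-off in ", path)
      for (key in names(open)) for (st in open[[key]]) {
        pitch <- as.integer(sub(".*:", "", key))
        if (tick > st[1L])
          track_notes[[length(track_notes) + 1L]] <- c(pitch, st[1L], tick, st[2L])
      }
    }
    notes <- c(notes, track_notes)
  }
  if (!length(notes)) stop("empty performance: no notes in ", path)

  m <- do.call(rbind, notes)
  tempo_map <- if (length(tempos)) do.call(rbind, tempos) else
    matrix(c(0, MIDI_TEMPO_US), nrow = 1)
  tempo_map <- tempo_map[order(tempo_map[, 1]), , drop = FALSE]
  if (tempo_map[1, 1] > 0)
    tempo_map <- rbind(c(0, MIDI_TEMPO_US), tempo_map)

  tick_to_sec <- function(tk) {
    starts <- tempo_map[, 1]
    # cumulative seconds at each tempo-change tick
    seg <- diff(starts) * tempo_map[-nrow(tempo_map), 2] / (division * 1e6)
    cum <- c(0, cumsum(seg))
    idx <- findInterval(tk, starts)
    cum[idx] + (tk - starts[idx]) * tempo_map[idx, 2] / (division * 1e6)
  }
  performance(pitch = m[, 1], onset = tick_to_sec(m[, 2]),
              offset = tick_to_sec(m[, 3]), velocity = m[, 4])
}
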