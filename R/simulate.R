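# Synthetic performance generation: reference melodies, error-perturbed
# learner replications, task-driven improvisations, and full longitudinal
# cohorts mirroring the counterbalanced cross-over study design. Every
# generator is deterministic given its seed and returns a ground-truth edit
# log so planted structure can be checked against the scoring measures.

PITCH_LO <- 60L           # C4: bottom of the taught 20-key span
PITCH_HI <- 79L           # G5: top of the span
REF_IOIS <- c(0.25, 0.5, 1.0)
IMPROV_MAX_NOTES <- 30L   # taught ceiling for improvisations
IMPROV_BASE_IOI <- 0.5
IMPROV_BASE_RATIO <- 0.8  # duration / IOI of the neutral elaboration
IMPROV_BASE_VEL <- 64L

#' Generate a reference melody
#'
#' Builds a monophonic melody the way the taught references were built:
#' 3-5-note fragments joined together (maximum 30 notes), pitches confined
#' to the 20-key C4-G5 span, steps biased towards 2 semitones or less
#' within fragments, IOIs drawn from 0.25/0.5/1.0 s, legato-ish
#' articulation, constant velocity.
#'
#' @param length total notes, 3-30.
#' @param seed integer seed; the same seed yields the identical melody.
#' @return A [performance()].
#' @export
generate_reference <- function(length, seed = NULL) {
  if (!is_count(length) || length < 3 || length > 30)
    stop("reference length must be an integer in 3..30")
  with_seed(seed, {
    # fragment lengths of 3-5 summing to `length`
    lens <- integer()
    left <- length
    while (left > 0) {
      l <- if (left <= 5) left else sample(3:5, 1)
      if (left - l == 1 || left - l == 2) l <- max(3L, l - (3L - (left - l)))
      lens <- c(lens, l)
      left <- left - l
    }
    pitch <- integer(length)
    pos <- 1L
    cur <- sample(63:76, 1)
    for (l in lens) {
      for (k in seq_len(l)) {
        if (pos > 1L || k > 1L) {
          step <- if (k == 1L) sample(c(-5:-3, 3:5), 1)  # fragment boundary
          else sample(c(-2L, -1L, 1L, 2L), 1)
          cur <- cur + step
          if (cur > PITCH_HI) cur <- cur - 2L * (cur - PITCH_HI)
          if (cur < PITCH_LO) cur <- cur + 2L * (PITCH_LO - cur)
        }
        pitch[pos] <- cur
        pos <- pos + 1L
      }
    }
    iois <- sample(REF_IOIS, length, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    onset <- cumsum(c(0, iois[-length]))
    performance(pitch, onset, onset + 0.8 * iois, velocity = 64L)
  })
}

#' Learner error model for replication attempts
#'
#' Single-parameter-per-phenomenon model of novice replication error:
#' per-note pitch substitution, deletion and insertion probabilities,
#' geometric decay of substitution magnitude over 1-4 semitones, partial
#' completion (only the first part of the melody attempted), lognormal IOI
#' jitter, and Gaussian velocity noise.
#'
#' @param p_sub,p_del,p_ins per-note error probabilities
#'   (`p_sub + p_del <= 1`).
#' @param sub_decay geometric decay of substitution magnitudes 1-4.
#' @param completion proportion of the reference attempted, in (0, 1].
#' @param timing_jitter_sd lognormal sigma of multiplicative IOI jitter.
#' @param velocity_sd SD of additive velocity noise (MIDI units).
#' @return List of class `ReplicationErrorModel`.
#' @export
replication_error_model <- function(p_sub = 0.1, p_del = 0.05, p_ins = 0.05,
                                    sub_decay = 0.5, completion = 1,
                                    timing_jitter_sd = 0.05,
                                    velocity_sd = 5) {
  probs <- c(p_sub = p_sub, p_del = p_del, p_ins = p_ins)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_sub + p_del > 1) stop("p_sub + p_del must be <= 1")
  if (completion <= 0 || completion > 1) stop("completion must be in (0, 1]")
  structure(list(p_sub = p_sub, p_del = p_del, p_ins = p_ins,
                 sub_decay = sub_decay, completion = completion,
                 timing_jitter_sd = timing_jitter_sd,
                 velocity_sd = velocity_sd),
            class = "ReplicationErrorModel")
}

#' Simulate a learner's replication attempt
#'
#' Keeps the first `ceiling(completion * n)` reference notes, then applies
#' per-note pitch substitutions (magnitude geometric over 1-4 semitones,
#' random sign), deletions and insertions, multiplies each IOI by lognormal
#' jitter, and perturbs velocities. The returned performance carries an
#' `edit_log` attribute with the ground-truth counts.
#'
#' @param ref the reference [performance()].
#' @param model a [replication_error_model()].
#' @param seed integer seed.
#' @return A [performance()] with attribute `edit_log`.
#' @export
simulate_replication <- function(ref, model, seed = NULL) {
  stopifnot(inherits(ref, "Performance"),
            inherits(model, "ReplicationErrorModel"))
  notes <- ref$notes
  n <- nrow(notes)
  with_seed(seed, {
    keep <- seq_len(ceiling(model$completion * n))
    pitch <- notes$pitch[keep]
    iois <- diff(notes$onset)[seq_len(length(keep) - 1L)]
    ratio <- pmin((notes$offset - notes$onset)[keep] /
                    c(iois, IMPROV_BASE_IOI), 1)
    vel <- notes$velocity[keep]
    m <- length(keep)

    u <- stats::runif(m)
    sub_idx <- which(u < model$p_sub)
    del_idx <- which(u >= model$p_sub & u < model$p_sub + model$p_del)
    if (length(sub_idx)) {
      mag <- sample(1:4, length(sub_idx), replace = TRUE,
                    prob = model$sub_decay^(0:3))
      pitch[sub_idx] <- pmin(pmax(
        pitch[sub_idx] + sample(c(-1L, 1L), length(sub_idx), TRUE) * mag,
        0L), 127L)
    }
    ins_after <- which(stats::runif(m) < model$p_ins)

    keep_mask <- !seq_len(m) %in% del_idx
    iois_full <- c(iois, IMPROV_BASE_IOI)   # nominal ioi for the last note
    rows <- lapply(seq_len(m), function(i) {
      out <- list()
      if (keep_mask[i])
        out[[1L]] <- c(pitch[i], iois_full[i], ratio[i], vel[i])
      if (i %in% ins_after) {
        ip <- pmin(pmax(pitch[i] + sample(c(-4:-1, 1:4), 1), 0L), 127L)
        out[[length(out) + 1L]] <- c(ip, iois_full[i], ratio[i], vel[i])
      }
      out
    })
    rows <- do.call(rbind, unlist(rows, recursive = FALSE))
    if (is.null(rows) || nrow(rows) == 0)
      rows <- matrix(c(notes$pitch[1], IMPROV_BASE_IOI, 0.8,
                       notes$velocity[1]), nrow = 1)
    k <- nrow(rows)
    jit <- exp(stats::rnorm(k, 0, model$timing_jitter_sd))
    iois_out <- rows[, 2] * jit
    onset <- cumsum(c(0, iois_out[-k])) + notes$onset[1]
    vel_out <- pmin(pmax(round(rows[, 4] +
                                 stats::rnorm(k, 0, model$velocity_sd)), 1L), 127L)
    out <- performance(rows[, 1], onset, onset + rows[, 3] * iois_out, vel_out)
    attr(out, "edit_log") <- list(
      n_ref = n, n_kept = m, n_sub = length(sub_idx),
      n_del = length(del_idx), n_ins = length(ins_after),
      sub_positions = sub_idx, del_positions = del_idx)
    out
  })
}

#' Specify one improvisation task with an intensity
#'
#' @param task integer 1-14, one of the taught variation methods (repeats,
#'   passing notes, interval spread, rhythm, crescendo/diminuendo, accents,
#'   rests, speeds, legato, staccato, slurring, retrograde, sequence,
#'   modulation).
#' @param intensity how strongly the task is applied, in `[0, 1]`.
#' @return List of class `ImprovTaskSpec`.
#' @export
improv_task_spec <- function(task, intensity = 1) {
  if (!is_count(task) || task < 1 || task > 14)
    stop("task must be an integer in 1..14")
  if (intensity < 0 || intensity > 1) stop("intensity must lie in [0, 1]")
  structure(list(task = as.integer(task), intensity = intensity),
            class = "ImprovTaskSpec")
}

# number of planted events for a task at a given intensity
task_plant_count <- function(task, intensity) {
  k <- switch(task,
              round(intensity * 5),      # 1 repeats
              round(intensity * 6),      # 2 passing notes
              if (intensity > 0) 2L else 0L,  # 3 wide intervals
              round(intensity * 6),      # 4 rhythm diversity
              round(intensity * 3),      # 5 crescendo/diminuendo ramps
              round(intensity * 5),      # 6 accents
              round(intensity * 8),      # 7 rests
              0L,                        # 8 speeds (global, no insertions)
              round(intensity * 6),      # 9 legato
              round(intensity * 6),      # 10 staccato
              round(intensity * 3),      # 11 slurring pairs
              if (intensity > 0) 3L + round(2 * intensity) else 0L,  # 12 retro
              if (intensity > 0) 3L + round(2 * intensity) else 0L,  # 13 seq
              if (intensity > 0) 2L else 0L)  # 14 modulation
  as.integer(k)
}

#' Simulate an improvisation on a prompt
#'
#' Elaborates a 3-5-note aural prompt into a melody of at most `max_notes`
#' notes (the taught ceiling of 30) and applies each requested task's
#' transformation with strength proportional to its intensity: task 1
#' inserts immediate repeats, 2 passing notes, 3/14 widen intervals, 4
#' diversifies IOIs, 5 plants crescendo/diminuendo ramps, 6 accents, 7
#' rests, 8 changes speed halfway, 9-11 vary articulation, 12 appends a
#' retrograde of an opening segment, 13 a transposed (sequence) copy. With
#' no tasks (or all intensities 0) the result is a neutral elaboration. The
#' `edit_log` attribute records what was planted.
#'
#' @param prompt a 3-5-note [performance()].
#' @param tasks list of [improv_task_spec()]s (at most 14).
#' @param max_notes output ceiling (default 30).
#' @param seed integer seed.
#' @return A [performance()] with attribute `edit_log`.
#' @export
simulate_improvisation <- function(prompt, tasks = list(),
                                   max_notes = IMPROV_MAX_NOTES, seed = NULL) {
  stopifnot(inherits(prompt, "Performance"))
  np <- n_notes(prompt)
  if (np < 3 || np > 5) stop("prompt must have 3-5 notes")
  if (inherits(tasks, "ImprovTaskSpec")) tasks <- list(tasks)
  if (length(tasks) > 14) stop("at most 14 tasks")
  task_ids <- vapply(tasks, `[[`, integer(1), "task")
  intens <- vapply(tasks, `[[`, numeric(1), "intensity")

  with_seed(seed, {
    planted <- mapply(task_plant_count, task_ids, intens)
    grows <- task_ids %in% c(1L, 2L, 12L, 13L)  # tasks that add notes
    budget <- sum(if (length(planted)) planted[grows] else 0L)
    base_len <- max(np + 3L, min(16L, max_notes - budget))

    # neutral elaboration: continue the prompt with leaps of 3-5 semitones
    pitch <- prompt$notes$pitch
    cur <- pitch[np]
    while (length(pitch) < base_len) {
      step <- sample(c(-5:-3, 3:5), 1)
      cur <- cur + step
      if (cur > PITCH_HI) cur <- cur - 2L * (cur - PITCH_HI)
      if (cur < PITCH_LO) cur <- cur + 2L * (PITCH_LO - cur)
      pitch <- c(pitch, cur)
    }
    st <- data.frame(pitch = pitch,
                     ioi = IMPROV_BASE_IOI,
                     ratio = IMPROV_BASE_RATIO,
                     vel = IMPROV_BASE_VEL)
    log <- list()

    insert_row <- function(st, after, row) {
      if (after >= nrow(st)) rbind(st, row)
      else rbind(st[1:after, ], row, st[(after + 1):nrow(st), ])
    }
    for (t in seq_along(task_ids)) {
      id <- task_ids[t]; k <- planted[t]
      if (k == 0L && id != 8L) next
      n <- nrow(st)
      if (id == 1L) {                    # immediate repeats
        for (q in seq_len(k)) {
          i <- sample(nrow(st), 1)
          st <- insert_row(st, i, st[i, ])
        }
      } else if (id == 2L) {             # passing/neighbour notes
        for (q in seq_len(k)) {
          i <- sample(nrow(st) - 1L, 1)
          row <- st[i, ]
          row$pitch <- row$pitch + sample(c(-2L, -1L, 1L, 2L), 1)
          st <- insert_row(st, i, row)
        }
      } else if (id %in% c(3L, 14L)) {   # widen intervals / modulation
        jump <- if (id == 3L) 7L + round(5 * max(intens[t], 0)) else
          4L + round(4 * max(intens[t], 0))
        idx <- sample(2:nrow(st), 2)
        st$pitch[idx[1]] <- min(st$pitch[idx[1] - 1L] + jump, 127L)
        st$pitch[idx[2]] <- max(st$pitch[idx[2] - 1L] - jump, 0L)
      } else if (id == 4L) {             # rhythm diversity
        idx <- sample(n, min(k, n))
        st$ioi[idx] <- sample(c(0.125, 0.25, 1.0, 1.5), length(idx), TRUE)
      } else if (id == 5L) {             # crescendo / diminuendo ramps
        starts <- seq(1L, by = 5L, length.out = k)
        starts <- starts[starts + 3L <= n]
        for (s in starts) {
          dir <- sample(c(-1, 1), 1)
          st$vel[s:(s + 3L)] <- IMPROV_BASE_VEL - dir * 12L + dir * 8L * (0:3)
        }
      } else if (id == 6L) {             # accents
        idx <- seq(2L, by = 3L, length.out = k)
        idx <- idx[idx <= n]
        st$vel[idx] <- pmin(IMPROV_BASE_VEL + 30L, 127L)
      } else if (id == 7L) {             # rests
        idx <- sample(n - 1L, min(k, n - 1L))
        st$ratio[idx] <- 0.15
      } else if (id == 8L) {             # different speeds
        half <- seq(floor(n / 2) + 1L, n)
        st$ioi[half] <- st$ioi[half] * (1 + intens[t])
      } else if (id == 9L) {             # legato
        idx <- sample(n - 1L, min(k, n - 1L))
        st$ratio[idx] <- 1.0
      } else if (id == 10L) {            # staccato
        idx <- sample(n - 1L, min(k, n - 1L))
        st$ratio[idx] <- 0.15
      } else if (id == 11L) {            # slurring: legato/staccato pairs
        starts <- sample(n - 2L, min(k, n - 2L))
        st$ratio[starts] <- 1.0
        st$ratio[starts + 1L] <- 0.15
      } else if (id == 12L) {            # retrograde of an opening segment
        seg <- rev(st$pitch[seq_len(min(k, nrow(st)))])
        for (p in seg) {
          row <- st[nrow(st), ]; row$pitch <- p
          row$ioi <- IMPROV_BASE_IOI; row$ratio <- IMPROV_BASE_RATIO
          st <- rbind(st, row)
        }
      } else if (id == 13L) {            # transposed sequence
        L <- min(k, nrow(st))
        shift <- sample(c(-5L, -4L, 4L, 5L), 1)
        seg <- st$pitch[seq_len(L)] + shift
        for (p in seg) {
          row <- st[nrow(st), ]; row$pitch <- p
          row$ioi <- IMPROV_BASE_IOI; row$ratio <- IMPROV_BASE_RATIO
          st <- rbind(st, row)
        }
      }
      log[[length(log) + 1L]] <- list(task = id, planted = k)
    }

    if (nrow(st) > max_notes) st <- st[seq_len(max_notes), ]
    n <- nrow(st)
    onset <- cumsum(c(0, st$ioi[-n]))
    out <- performance(pmin(pmax(st$pitch, 0L), 127L), onset,
                       onset + st$ratio * st$ioi,
                       pmin(pmax(round(st$vel), 1L), 127L))
    attr(out, "edit_log") <- log
    out
  })
}

#' Cohort and cross-over layout for the synthetic study
#'
#' Describes the longitudinal design the generator emulates: participants in
#' counterbalanced groups, five performance sessions (four 3-month training
#' blocks then a retention session), five items per session (1-3
#' replication, 4-5 improvisation), and learning rates expressing how error
#' parameters decline (log-linearly) per completed training block. Timing
#' learning defaults to zero: rhythm is deliberately not planted.
#'
#' @param n_participants cohort size (default 68).
#' @param n_groups number of counterbalanced groups (default 10, minimum 4).
#' @param sessions performance sessions.
#' @param learning_rates list with `pitch` (replication-error decline per
#'   repct block), `timing` (IOI-jitter decline), and `improv` (added task
#'   intensity per imprct block).
#' @param seed master seed for the whole cohort.
#' @return List of class `SimulationDesign`.
#' @export
simulation_design <- function(n_participants = 68L, n_groups = 10L,
                              sessions = c("m3", "m6", "m9", "m12", "m15"),
                              learning_rates = list(pitch = 0.6, timing = 0,
                                                    improv = 0.3),
                              seed = 1L) {
  if (n_groups < 4) stop("counterbalancing requires at least 4 groups")
  stopifnot(all(c("pitch", "timing", "improv") %in% names(learning_rates)))
  structure(list(n_participants = as.integer(n_participants),
                 n_groups = as.integer(n_groups), sessions = sessions,
                 learning_rates = learning_rates, seed = as.integer(seed)),
            class = "SimulationDesign")
}

# training schedule of one group: instrument per block and task per block.
# Instrument order alternates between group halves (zero correlation between
# instrument and block count); task order alternates within halves.
group_schedule <- function(group, n_groups) {
  k_first <- group <= ceiling(n_groups / 2)
  r_first <- group %% 2 == 1
  list(instrument = if (k_first) c("kbipK", "kbipK", "kbipI", "kbipI")
       else c("kbipI", "kbipI", "kbipK", "kbipK"),
       task = if (r_first) c("rep", "imp", "rep", "imp")
       else c("imp", "rep", "imp", "rep"))
}

#' Generate a synthetic longitudinal cohort
#'
#' For every participant, session and item, generates the appropriate
#' performance: items 1-3 are replication attempts of a reference melody
#' with error parameters that decline log-linearly with the number of
#' completed replication blocks (`repct`), item 1 the most accurate
#' (pre-rehearsed) and item 2 the least; items 4-5 are improvisations whose
#' planted-task intensity grows with completed improvisation blocks
#' (`imprct`). Instrument and task orders are counterbalanced across
#' groups.
#'
#' @param design a [simulation_design()].
#' @param dir optional directory; when given, every performance and
#'   reference is written as a MIDI file and a `metadata.csv` sidecar is
#'   produced.
#' @return List of class `SyntheticCohort` with `metadata` (one row per
#'   performance) and `recordings` (parallel list of
#'   `list(perf, ref, prompt)`).
#' @export
generate_cohort <- function(design, dir = NULL) {
  stopifnot(inherits(design, "SimulationDesign"))
  lr <- design$learning_rates
  sessions <- design$sessions
  items <- 1:5
  total <- design$n_participants * length(sessions) * length(items)
  seeds <- derive_seeds(design$seed, total + design$n_participants)

  base_sub <- c(0.08, 0.30, 0.18)       # items 1-3: rehearsed, new, practised
  base_completion <- c(0.95, 0.60, 0.78)

  meta_rows <- vector("list", total)
  recordings <- vector("list", total)
  idx <- 0L
  for (p in seq_len(design$n_participants)) {
    group <- ((p - 1L) %% design$n_groups) + 1L
    sched <- group_schedule(group, design$n_groups)
    for (s in seq_along(sessions)) {
      blocks_done <- min(s, 4L)
      repct <- sum(sched$task[seq_len(blocks_done)] == "rep")
      imprct <- blocks_done - repct
      instrument <- sched$instrument[min(s, 4L)]
      kb_factor <- if (instrument == "kbipK") 0.85 else 1
      for (item in items) {
        idx <- idx + 1L
        sd_i <- seeds[idx]
        meta <- performance_metadata(
          participant_id = sprintf("P%02d", p),
          group = sprintf("G%02d", group),
          session = sessions[s], item = item, instrument = instrument,
          imprct = imprct, repct = repct)
        if (item <= 3L) {
          child <- derive_seeds(sd_i, 3L)
          ref <- generate_reference(with_seed(child[1], sample(10:16, 1)),
                                    seed = child[2])
          decay <- exp(-lr$pitch * repct) * kb_factor
          model <- replication_error_model(
            p_sub = base_sub[item] * decay,
            p_del = 0.5 * base_sub[item] * decay,
            p_ins = 0.4 * base_sub[item] * decay,
            completion = 1 - (1 - base_completion[item]) * decay,
            timing_jitter_sd = 0.08 * exp(-lr$timing * repct),
            velocity_sd = 6)
          perf <- simulate_replication(ref, model, seed = child[3])
          perf$meta <- meta
          recordings[[idx]] <- list(perf = perf, ref = ref, prompt = NULL)
          meta_rows[[idx]] <- data.frame(
            participant_id = meta$participant_id, group = meta$group,
            session = meta$session, item = item, instrument = instrument,
            imprct = imprct, repct = repct, nimptasks = NA_integer_,
            claimed_tasks = "")
        } else {
          child <- derive_seeds(sd_i, 4L)
          prompt <- generate_reference(with_seed(child[1], sample(3:5, 1)),
                                       seed = child[2])
          nimp <- if (item == 4L) 1L else with_seed(child[3], sample(1:3, 1))
          claimed <- with_seed(child[3], sample(1:14, nimp))
          intensity <- min(1, 0.15 + lr$improv * imprct)
          tasks <- lapply(claimed, improv_task_spec, intensity = intensity)
          perf <- simulate_improvisation(prompt, tasks, seed = child[4])
          perf$meta <- meta
          recordings[[idx]] <- list(perf = perf, ref = NULL, prompt = prompt)
          meta_rows[[idx]] <- data.frame(
            participant_id = meta$participant_id, group = meta$group,
            session = meta$session, item = item, instrument = instrument,
            imprct = imprct, repct = repct, nimptasks = nimp,
            claimed_tasks = paste(sort(claimed), collapse = ";"))
        }
      }
    }
  }
  metadata <- do.call(rbind, meta_rows)
  metadata$midi_path <- NA_character_
  metadata$ref_path <- NA_character_

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(nrow(metadata))) {
      pf <- file.path(dir, sprintf("perf_%04d.mid", k))
      write_midi(recordings[[k]]$perf, pf)
      metadata$midi_path[k] <- pf
      side <- if (!is.null(recordings[[k]]$ref)) recordings[[k]]$ref
      else recordings[[k]]$prompt
      rf <- file.path(dir, sprintf("side_%04d.mid", k))
      write_midi(side, rf)
      metadata$ref_path[k] <- rf
    }
    utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  structure(list(metadata = metadata, recordings = recordings,
                 design = design), class = "SyntheticCohort")
}

#' Score every performance of a synthetic cohort
#'
#' Applies [score_replication()] to items 1-3 (against their references)
#' and [score_improvisation()] to items 4-5, returning one row per
#' performance: the metadata plus the 8 replication and 18 improvisation
#' measure columns (`NA` where not applicable).
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame.
#' @export
score_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  rep_cols <- c("pitchdtwsim", "palignedprop", "pitchdtwladj", "pioidtwsim",
                "pioialignedprop", "pioidtwladj", "klpitchsim", "klioisim")
  rows <- lapply(seq_along(cohort$recordings), function(k) {
    rec <- cohort$recordings[[k]]
    repv <- stats::setNames(rep(NA_real_, length(rep_cols)), rep_cols)
    impv <- stats::setNames(rep(NA_real_, length(IMPROV_MEASURES)),
                            IMPROV_MEASURES)
    if (!is.null(rec$ref)) {
      repv[] <- unlist(score_replication(extract_monophonic(rec$perf),
                                         rec$ref))
    } else {
      impv[] <- unlist(score_improvisation(extract_monophonic(rec$perf),
                                           rec$prompt))
    }
    c(repv, impv)
  })
  cbind(cohort$metadata, do.call(rbind, rows))
}
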