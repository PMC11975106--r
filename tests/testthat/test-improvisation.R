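test_that("diversity is Shannon entropy with a distinct-count alternative", {
  expect_equal(diversity(rep(5, 10)), 0)
  expect_equal(diversity(c(1, 2, 3, 4)), 2)
  expect_equal(diversity(c(1, 1, 1, 2)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(diversity(c(1, 1, 2, 3), type = "distinct"), 3)
  expect_error(diversity(numeric()), "insufficient")
})

test_that("value range is max minus min", {
  expect_equal(value_range(c(-2, 3, 1)), 5)
  expect_equal(value_range(rep(7, 4)), 0)
  expect_equal(value_range(60:79), 19)  # the full 20-key span
})

test_that("repeated notes are counted pairwise", {
  expect_equal(repeat_notes(mk_perf(c(60, 60, 62, 62, 62, 64))), 3)
  expect_equal(repeat_notes(mk_perf(c(60, 62, 64))), 0)
  n <- 7
  expect_equal(repeat_notes(mk_perf(rep(71, n))), n - 1)
})

test_that("passing notes are steps of one or two semitones", {
  expect_equal(passing_notes_prop(mk_perf(60:67)), 1)      # chromatic run
  expect_equal(passing_notes_prop(mk_perf(c(60, 64, 67, 72))), 0)  # arpeggio
  expect_equal(passing_notes_prop(mk_perf(c(60, 62, 66, 67))), 2 / 3)
})

test_that("crescendo/diminuendo runs need length 3 and velocity change 10", {
  expect_equal(cresc_dim_count(mk_perf(rep(60, 4),
                                       velocity = c(40, 55, 70, 85))), 1)
  expect_equal(cresc_dim_count(mk_perf(rep(60, 5), velocity = 64)), 0)
  expect_equal(cresc_dim_count(mk_perf(rep(60, 6),
                                       velocity = c(40, 60, 80, 60, 40, 60))), 2)
  # monotone but too small a change
  expect_equal(cresc_dim_count(mk_perf(rep(60, 3), velocity = c(60, 62, 64))), 0)
})

test_that("accents are velocity spikes over the local window mean", {
  expect_equal(accent_prop(mk_perf(rep(60, 6), velocity = 64)), 0)
  v <- rep(64, 10); v[5] <- 94
  expect_equal(accent_prop(mk_perf(rep(60, 10), velocity = v)), 1 / 10)
  alt <- rep(c(59, 69), 5)
  expect_equal(accent_prop(mk_perf(rep(60, 10), velocity = alt)), 0)
})

test_that("silence proportion is the gap share of the performed span", {
  legato <- performance(c(60, 62, 64), c(0, 1, 2), c(1, 2, 3))
  expect_equal(silence_prop(legato), 0)
  p <- performance(c(60, 62), c(0, 2), c(1, 3))
  expect_equal(silence_prop(p), 1 / 3)
  # staccato with equal sound and gap over each IOI
  st <- mk_perf(rep(60, 6), ioi = 1, ratio = 0.5)
  expect_equal(silence_prop(st), sum(rep(0.5, 5)) / 5.5)
})

test_that("windowed IOI statistics capture a mid-piece tempo change", {
  iso <- mk_perf(rep(60, 9), ioi = 0.5)
  w <- windowed_ioi_stats(iso)
  expect_equal(w$M9windioirange, 0)
  expect_equal(w$M9aWindioiabsdiff, 0)
  # IOIs (1,1,1,1,.5,.5,.5,.5): window-4 means 1, .875, .75, .625, .5
  on <- cumsum(c(0, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5))
  p <- performance(rep(60, 9), on, on + 0.2)
  w2 <- windowed_ioi_stats(p, window = 4)
  expect_equal(w2$M9windioirange, 0.5)
  expect_equal(w2$M9aWindioiabsdiff, mean(rep(0.125, 4)))
  # invariant to uniform transposition
  q <- performance(rep(72, 9), on, on + 0.2)
  expect_equal(windowed_ioi_stats(q), w2)
  expect_error(windowed_ioi_stats(mk_perf(rep(60, 4))), "insufficient")
})

test_that("articulation statistics match hand-computed alternation", {
  flat <- mk_perf(rep(60, 6), ioi = 0.5, ratio = 0.8)
  a <- articulation_stats(flat)
  expect_equal(a$M12VaryStaccLeg, 0)
  expect_equal(a$M12aStaccLegabsdiff, 0)
  # durations alternate 0.1/0.5 over constant IOI 0.5: ratios (.2, 1, .2, 1)
  dur <- rep(c(0.1, 0.5), length.out = 5)
  on <- (0:4) * 0.5
  p <- performance(rep(60, 5), on, on + dur)
  a2 <- articulation_stats(p)
  expect_equal(a2$M12VaryStaccLeg, 0.4)       # population SD of (.2, 1) runs
  expect_equal(a2$M12aStaccLegabsdiff, 0.8)   # |0.4| / 0.5 every pair
  expect_gte(a2$M12VaryStaccLeg, 0)
})

test_that("retrograde and sequence detectors match spec examples", {
  expect_equal(retrograde_notes(mk_perf(c(60, 62, 64, 64, 62, 60))), 3)
  expect_equal(retrograde_notes(mk_perf(60:67)), 0)
  expect_equal(sequence_notes(mk_perf(c(60, 62, 64, 65, 67, 69))), 3)
  # literal repeat is a zero transposition: not a sequence
  expect_equal(sequence_notes(mk_perf(c(60, 62, 64, 60, 62, 64))), 0)
  expect_equal(retrograde_notes(mk_perf(c(60, 62, 64, 60, 62))), 0)
})

test_that("pattern detectors agree with exhaustive enumeration on short melodies", {
  for (p in all_sequences(c(60, 62, 64), 6:7)) {
    perf <- mk_perf(p)
    expect_equal(retrograde_notes(perf), bf_retrograde_notes(p),
                 info = paste(p, collapse = ","))
    expect_equal(sequence_notes(perf), bf_sequence_notes(p),
                 info = paste(p, collapse = ","))
  }
})

test_that("degenerate input zeroes diversity, range and variation measures", {
  n <- 10
  s <- score_improvisation(mk_perf(rep(64, n)))
  expect_equal(s$NumNotes, n)
  expect_equal(s$M4repeatnotes, n - 1)
  zero <- c("M1pintervaldivers", "M1pintervalrange", "M2ioidivers",
            "M2ioirange", "M3pitchdivers", "M3prange", "M6crescdim",
            "M7AccentProp", "M9windioirange", "M12VaryStaccLeg",
            "M14sequences", "M9aWindioiabsdiff", "M12aStaccLegabsdiff")
  for (m in zero) expect_equal(s[[m]], 0, info = m)
})

test_that("composed scoring agrees with the individual measures", {
  set.seed(77)
  for (k in 1:12) {
    prompt <- generate_reference(4, seed = 300 + k)
    imp <- simulate_improvisation(prompt,
                                  list(improv_task_spec(sample(14, 1),
                                                        runif(1))),
                                  seed = 400 + k)
    s <- score_improvisation(imp)
    expect_equal(s$NumNotes, n_notes(imp))
    expect_equal(s$M4repeatnotes, repeat_notes(imp))
    expect_equal(s$M5Passnotesprop, passing_notes_prop(imp))
    expect_equal(s$M8silenceprop, silence_prop(imp))
    expect_equal(s$M13retronotes, retrograde_notes(imp))
    expect_equal(s$M14sequences, sequence_notes(imp))
    expect_equal(s$M12aStaccLegabsdiff,
                 articulation_stats(imp)$M12aStaccLegabsdiff)
    v <- unlist(s)
    props <- v[c("M5Passnotesprop", "M7AccentProp", "M8silenceprop")]
    expect_true(all(props >= 0 & props <= 1, na.rm = TRUE))
    expect_lte(s$M3pitchdivers, log2(length(unique(imp$notes$pitch))) + 1e-12)
  }
})

test_that("short inputs flag infeasible measures as missing, not zero", {
  s <- score_improvisation(mk_perf(c(60, 62)))
  expect_true(is.na(s$M7AccentProp))
  expect_true(is.na(s$M9windioirange))
  expect_true(is.na(s$M12VaryStaccLeg))
  expect_equal(s$NumNotes, 2)
  expect_error(score_improvisation(mk_perf(60)), "insufficient")
})

test_that("the task-to-scoretype map is the published assignment", {
  tm <- task_score_map()
  expect_equal(tm$scoretype,
               c(8, 9, 3, 4, 10, 11, 12, 18, 17, 17, 17, 15, 16, 3))
  expect_equal(tm$measure[1], "M4repeatnotes")
  expect_equal(tm$measure[12], "M13retronotes")
  expect_equal(length(unique(tm$scoretype)), 11)  # the 11 pertinent scoretypes
})
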