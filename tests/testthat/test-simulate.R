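test_that("reference melodies respect the taught pitch span and length", {
  set.seed(1)
  for (seed in 1:10) {
    len <- sample(3:30, 1)
    ref <- generate_reference(len, seed = seed)
    expect_equal(n_notes(ref), len)
    expect_true(all(ref$notes$pitch >= 60 & ref$notes$pitch <= 79))
    expect_true(all(diff(ref$notes$onset) %in% c(0.25, 0.5, 1.0)))
  }
  # determinism and full-length honouring
  expect_equal(generate_reference(30, seed = 3)$notes,
               generate_reference(30, seed = 3)$notes)
  expect_equal(n_notes(generate_reference(30, seed = 1)), 30)
  expect_error(generate_reference(2), "3..30")
  expect_error(generate_reference(31), "3..30")
})

test_that("an error-free replication reproduces the reference scores exactly", {
  ref <- generate_reference(14, seed = 6)
  clean <- replication_error_model(p_sub = 0, p_del = 0, p_ins = 0,
                                   completion = 1, timing_jitter_sd = 0,
                                   velocity_sd = 0)
  perf <- simulate_replication(ref, clean, seed = 1)
  s <- score_replication(perf, ref)
  expect_equal(s$pitchdtwladj, 1)
  expect_equal(s$pioidtwsim, 1)
  log <- attr(perf, "edit_log")
  expect_equal(log$n_sub + log$n_del + log$n_ins, 0)
})

test_that("partial completion maps directly onto the aligned proportion", {
  ref <- generate_reference(20, seed = 7)
  half <- replication_error_model(p_sub = 0, p_del = 0, p_ins = 0,
                                  completion = 0.5, timing_jitter_sd = 0,
                                  velocity_sd = 0)
  perf <- simulate_replication(ref, half, seed = 2)
  expect_equal(n_notes(perf), 10)
  s <- score_replication(perf, ref)
  expect_equal(s$palignedprop, 0.5)
  expect_equal(s$pitchdtwsim, 1)
})

test_that("the edit log bounds the observable damage", {
  ref <- generate_reference(20, seed = 8)
  model <- replication_error_model(p_sub = 0.3, p_del = 0.1, p_ins = 0.1)
  for (seed in 1:10) {
    perf <- simulate_replication(ref, model, seed = seed)
    log <- attr(perf, "edit_log")
    expect_equal(n_notes(perf), log$n_kept - log$n_del + log$n_ins)
    expect_identical(simulate_replication(ref, model, seed = seed)$notes,
                     perf$notes)
  }
})

test_that("higher substitution rates lower the pitch similarity on average", {
  ref <- generate_reference(16, seed = 9)
  mean_sim <- function(p_sub) {
    m <- replication_error_model(p_sub = p_sub, p_del = 0, p_ins = 0,
                                 timing_jitter_sd = 0, velocity_sd = 0)
    mean(vapply(1:40, function(s)
      score_replication(simulate_replication(ref, m, seed = s),
                        ref)$pitchdtwsim, numeric(1)))
  }
  expect_gt(mean_sim(0.1), mean_sim(0.3))
})

test_that("improvisations respect the prompt contract and the 30-note ceiling", {
  prompt <- generate_reference(4, seed = 10)
  set.seed(2)
  for (seed in 1:8) {
    tasks <- lapply(sample(14, 3), improv_task_spec, intensity = 1)
    imp <- simulate_improvisation(prompt, tasks, seed = seed)
    expect_lte(n_notes(imp), 30)
    expect_gte(n_notes(imp), 7)
  }
  # the neutral elaboration opens with the prompt itself
  neutral <- simulate_improvisation(prompt, list(), seed = 1)
  expect_identical(neutral$notes$pitch[1:4], prompt$notes$pitch)
  expect_error(simulate_improvisation(generate_reference(6, seed = 1)),
               "3-5 notes")
  expect_error(improv_task_spec(15), "1..14")
  expect_error(improv_task_spec(3, 2), "intensity")
})

test_that("a full-intensity retrograde task plants a detectable retrograde", {
  prompt <- generate_reference(4, seed = 11)
  for (seed in 1:10) {
    imp <- simulate_improvisation(prompt, list(improv_task_spec(12, 1)),
                                  seed = seed)
    expect_gte(retrograde_notes(imp), 3)
  }
})

test_that("a neutral elaboration plants no task structure", {
  prompt <- generate_reference(4, seed = 12)
  zero <- lapply(1:14, improv_task_spec, intensity = 0)
  imp <- simulate_improvisation(prompt, zero, seed = 3)
  none <- simulate_improvisation(prompt, list(), seed = 3)
  expect_identical(imp$notes, none$notes)
  s <- score_improvisation(imp)
  expect_equal(s$M4repeatnotes, 0)
  expect_equal(s$M6crescdim, 0)
  expect_equal(s$M2ioidivers, 0)
  expect_equal(s$M9aWindioiabsdiff, 0)
})

test_that("the cohort has the designed shape and counterbalancing", {
  design <- simulation_design(n_participants = 8, n_groups = 4,
                              seed = 42)
  cohort <- generate_cohort(design)
  md <- cohort$metadata
  expect_equal(nrow(md), 8 * 5 * 5)
  expect_equal(length(cohort$recordings), nrow(md))
  expect_true(all(md$imprct + md$repct <= 4))
  expect_true(all(md$imprct <= 2 & md$repct <= 2))
  # instrument indicator uncorrelated with training-block count
  expect_equal(cor(md$instrument == "kbipK", md$imprct + md$repct), 0)
  expect_error(simulation_design(n_groups = 3), "at least 4")
})

test_that("cohort MIDI export writes one file pair per metadata row", {
  design <- simulation_design(n_participants = 2, n_groups = 4, seed = 5,
                              sessions = c("m3", "m6"))
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(design, dir = dir)
  md <- utils::read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(md), 2 * 2 * 5)
  expect_true(all(file.exists(cohort$metadata$midi_path)))
  back <- read_midi(cohort$metadata$midi_path[1])
  expect_identical(back$notes$pitch,
                   cohort$recordings[[1]]$perf$notes$pitch)
})

test_that("replication training raises replication scores in the cohort", {
  design <- simulation_design(n_participants = 12, n_groups = 4, seed = 7)
  scores <- score_cohort(generate_cohort(design))
  rep <- scores[scores$item <= 3, ]
  expect_gt(coef(lm(pitchdtwladj ~ repct, rep))["repct"], 0)
  means <- tapply(rep$pitchdtwladj, rep$repct, mean)
  expect_true(all(diff(means) > 0))
})
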