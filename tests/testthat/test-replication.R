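test_that("joint features are tempo-invariant with median-normalised log IOIs", {
  p <- performance(c(60, 62, 64, 65), c(0, 0.5, 1.5, 2.0),
                   c(0.4, 1.3, 1.9, 2.4))
  f <- joint_features(p)
  # IOIs (0.5, 1.0, 0.5), median 0.5 -> log2 ratios (0, 1, 0)
  expect_equal(unname(f[, "log_ioi"]), c(0, 1, 0))
  expect_equal(unname(f[, "pitch"]), c(60, 62, 64))
  # doubling global tempo leaves the features unchanged
  q <- performance(p$notes$pitch, p$notes$onset * 2, p$notes$offset * 2)
  expect_equal(joint_features(q), f)
  iso <- mk_perf(c(60, 64, 67, 72))
  expect_true(all(joint_features(iso)[, "log_ioi"] == 0))
})

test_that("joint pitch+IOI scores are 1 for identity and tempo-rescaled copies", {
  ref <- generate_reference(12, seed = 5)
  expect_equal(unlist(pioi_scores(ref, ref)),
               c(pioidtwsim = 1, pioialignedprop = 1, pioidtwladj = 1))
  fast <- performance(ref$notes$pitch, ref$notes$onset / 2,
                      ref$notes$offset / 2, ref$notes$velocity)
  expect_equal(unlist(pioi_scores(fast, ref)),
               c(pioidtwsim = 1, pioialignedprop = 1, pioidtwladj = 1))
})

test_that("a timing distortion lowers the joint score below the pitch-only score", {
  ref <- mk_perf(c(60, 62, 64, 65, 67))
  on <- ref$notes$onset
  on[4:5] <- on[4:5] + 0.5   # one IOI doubled
  perf <- performance(ref$notes$pitch, on, on + 0.4)
  pitch_sim <- pitch_similarity(dtw_align(perf$notes$pitch, ref$notes$pitch))
  joint <- pioi_scores(perf, ref)
  expect_lt(joint$pioidtwsim, pitch_sim)
  # joint distance agrees with brute-force enumeration under the joint cost
  fp <- joint_features(perf); fr <- joint_features(ref)
  bf <- bf_dtw_distance(seq_len(nrow(fp)), seq_len(nrow(fr)), cap = 2,
                        cost_fun = function(i, j)
                          min(abs(fp[i, 1] - fr[j, 1]), 12) / 12 +
                          min(abs(fp[i, 2] - fr[j, 2]), 2) / 2)
  expect_equal(1 - joint$pioidtwsim, bf)
})

test_that("pitch distributions are order-invariant relative frequencies", {
  p <- mk_perf(c(60, 60, 62))
  d <- pitch_distribution(p)
  expect_equal(unname(d), c(2 / 3, 1 / 3))
  perm <- mk_perf(c(62, 60, 60))
  expect_equal(pitch_distribution(perm), d)
  # additive smoothing over a union support, by hand: counts (2, 0), alpha .5
  sm <- pitch_distribution(mk_perf(c(60, 60)), support = c(60, 62),
                           alpha = 0.5)
  expect_equal(unname(sm), c(2.5 / 3, 0.5 / 3))
  expect_equal(sum(sm), 1)
})

test_that("IOI distributions bin log tempo ratios with catch-all edges", {
  iso <- mk_perf(rep(60, 10))
  d <- ioi_distribution(iso, alpha = 0)
  expect_equal(sum(d), 1)
  expect_equal(d[7], 1)  # all mass in the central bin containing 0
  # uniform tempo change leaves the distribution unchanged
  slow <- performance(rep(60, 10), (0:9) * 2, (0:9) * 2 + 0.4)
  expect_equal(ioi_distribution(slow), ioi_distribution(iso))
  # IOIs (0.5, 1, 0.5): ratios to median log2 = (0, 1, 0); width 6/13
  p <- performance(c(60, 62, 64, 65), c(0, 0.5, 1.5, 2.0), c(0.4, 1.4, 1.9, 2.4))
  d2 <- ioi_distribution(p, alpha = 0)
  expect_equal(d2[7], 2 / 3)                       # bin of ratio 0
  expect_equal(d2[floor((1 + 3) / (6 / 13)) + 1], 1 / 3)  # bin of ratio 1
})

test_that("KL similarity matches the closed form and is symmetric", {
  p <- c(0.9, 0.1); q <- c(0.1, 0.9)
  j <- 0.5 * (0.9 * log(9) + 0.1 * log(1 / 9)) * 2
  expect_equal(kl_similarity(p, q), exp(-j))
  expect_equal(kl_similarity(p, q), kl_similarity(q, p))
  expect_equal(kl_similarity(p, p), 1)
  expect_error(kl_similarity(p, c(0.5, 0.25, 0.25)), "length")
  expect_error(kl_similarity(c(0.9, 0.2), q), "sum to 1")
  expect_error(kl_similarity(c(1, 0), c(0.5, 0.5)), "strictly positive")
})

test_that("scoring a performance against itself is maximal", {
  for (seed in c(2, 3, 4)) {
    x <- generate_reference(sample(8:20, 1), seed = seed)
    s <- score_replication(x, x)
    expect_equal(s$pitchdtwsim, 1)
    expect_equal(s$palignedprop, 1)
    expect_equal(s$pitchdtwladj, 1)
    expect_equal(s$pioidtwsim, 1)
    expect_gte(s$klpitchsim, 0.98)
    expect_gte(s$klioisim, 0.98)
  }
})

test_that("a perfect half rendition halves the aligned proportion exactly", {
  ref <- generate_reference(30, seed = 21)
  half <- performance(ref$notes$pitch[1:15], ref$notes$onset[1:15],
                      ref$notes$offset[1:15])
  s <- score_replication(half, ref)
  expect_equal(s$pitchdtwsim, 1)
  expect_equal(s$palignedprop, 0.5)
  expect_equal(s$pitchdtwladj, 0.5)
})

test_that("all eight measures stay in range with exact product invariants", {
  set.seed(31)
  for (k in 1:20) {
    ref <- generate_reference(sample(6:20, 1), seed = 1000 + k)
    perf <- simulate_replication(ref, replication_error_model(
      p_sub = runif(1, 0, 0.4), p_del = runif(1, 0, 0.2),
      p_ins = runif(1, 0, 0.2), completion = runif(1, 0.4, 1),
      timing_jitter_sd = runif(1, 0, 0.2)), seed = 2000 + k)
    s <- score_replication(perf, ref)
    v <- unlist(s)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(s$pitchdtwladj, s$pitchdtwsim * s$palignedprop)
    expect_equal(s$pioidtwladj, s$pioidtwsim * s$pioialignedprop)
    expect_lte(s$pitchdtwladj, min(s$pitchdtwsim, s$palignedprop))
  }
})

test_that("every measure is invariant to uniform time rescaling", {
  ref <- generate_reference(15, seed = 8)
  perf <- simulate_replication(ref, replication_error_model(p_sub = 0.2),
                               seed = 9)
  s1 <- unlist(score_replication(perf, ref))
  slow <- performance(perf$notes$pitch, perf$notes$onset * 3,
                      perf$notes$offset * 3, perf$notes$velocity)
  expect_equal(unlist(score_replication(slow, ref)), s1)
})

test_that("KL fields ignore note order but DTW fields do not", {
  ref <- generate_reference(12, seed = 14)
  rev_perf <- performance(rev(ref$notes$pitch), ref$notes$onset,
                          ref$notes$offset, ref$notes$velocity)
  s <- score_replication(rev_perf, ref)
  expect_equal(s$klpitchsim, 1)
  expect_lt(s$pitchdtwsim, 1)   # non-palindromic melody reversed
})

test_that("a single-note performance yields pitch measures with timing fields missing", {
  ref <- generate_reference(10, seed = 4)
  one <- performance(ref$notes$pitch[1], 0, 0.4)
  s <- score_replication(one, ref)
  expect_false(is.na(s$pitchdtwsim))
  expect_false(is.na(s$klpitchsim))
  expect_true(is.na(s$pioidtwsim))
  expect_true(is.na(s$klioisim))
  expect_true(attr(s, "low_information"))
})
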