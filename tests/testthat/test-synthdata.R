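test_that("subject geometry is deterministic in the seed and similar under scaling", {
  cfg <- sim_config()
  g1 <- simulate_subject_geometry(cfg, seed = 81)
  g2 <- simulate_subject_geometry(cfg, seed = 81)
  expect_identical(g1, g2)

  gs <- simulate_subject_geometry(cfg, scale = 1.2)
  g0 <- simulate_subject_geometry(cfg, scale = 1.0)
  for (i in seq_len(nrow(default_segments()))) {
    spec <- default_segments()[i, ]
    len <- function(g) {
      a <- unlist(g$markers[g$markers$marker == spec$marker_a, c("x", "y", "z")])
      b <- unlist(g$markers[g$markers$marker == spec$marker_b, c("x", "y", "z")])
      segment_length_sample(a, b)
    }
    expect_equal(len(gs), 1.2 * len(g0), tolerance = 1e-12)
  }

  flat_cfg <- sim_config(face_scale_sd = 0)
  ga <- simulate_subject_geometry(flat_cfg, seed = 1)
  gb <- simulate_subject_geometry(flat_cfg, seed = 2)
  expect_equal(ga$markers, gb$markers)
})

test_that("designed offsets are exact by construction", {
  cfg <- fast_config(jitter_sd_mm = 0, dropout = 0)
  g <- simulate_subject_geometry(cfg, scale = 1)

  # neutral with no noise: percent change identically zero
  zero <- c(brow = 0, eyebrow = 0, lips = 0, jaw = 0)
  neu <- simulate_trial(g, "neutral", cfg, offsets_pct = zero, seed = 82)
  fneu <- extract_trial_features(neu, subject_id = "s", condition = "neutral")
  same <- simulate_trial(g, "control_self", cfg, offsets_pct = zero, seed = 82)
  fsame <- extract_trial_features(same, subject_id = "s", condition = "control_self")
  expect_equal(percent_change(fsame, fneu)$pct_change, rep(0, 4),
               tolerance = 1e-9)

  # injected +10% brow offset recovered to numerical precision
  brow10 <- c(brow = 10, eyebrow = 0, lips = 0, jaw = 0)
  perf <- simulate_trial(g, "happy", cfg, offsets_pct = brow10, seed = 83)
  fperf <- extract_trial_features(perf, subject_id = "s", condition = "happy")
  pc <- percent_change(fperf, fneu)
  expect_equal(pc$pct_change[pc$segment == "brow"], 10, tolerance = 1e-6)
  expect_equal(pc$pct_change[pc$segment == "lips"], 0, tolerance = 1e-6)
})

test_that("dropout produces segment coverage near the squared retention rate", {
  cfg <- sim_config(duration_s = 20, dropout = 0.3, jitter_sd_mm = 0)
  g <- simulate_subject_geometry(cfg, scale = 1)
  tr <- simulate_trial(g, "neutral", cfg, seed = 84)
  f <- extract_trial_features(tr, min_coverage = 0)
  # both markers must survive: coverage ~ (1 - 0.3)^2 = 0.49
  expect_equal(mean(f$coverage), 0.49, tolerance = 0.05)
})

test_that("a simulated cohort is complete, readable, and reproducible", {
  cfg <- fast_config(n_subjects = 2, seed = 85)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim1 <- simulate_cohort(cfg, d1)
  sim2 <- simulate_cohort(cfg, d2)

  # 2 subjects x (9 characters + 9 emotions + control-self)
  expect_equal(nrow(sim1$manifest), 2 * 19)
  expect_true(all(file.exists(sim1$manifest$path)))
  expect_setequal(unique(sim1$vocal$parameter), names(default_vocal_spec()))

  # generator emits the exact trajectory dialect
  tr <- read_trial(sim1$manifest$path[1], sample_rate = cfg$sample_rate)
  expect_equal(n_frames(tr), cfg$duration_s * cfg$sample_rate)
  expect_setequal(marker_labels(tr), base_face_layout()$marker)

  # bit-reproducible under the same config + seed
  f1 <- readLines(sim1$manifest$path[5])
  f5 <- sim2$manifest$path[5]
  expect_identical(f1, readLines(f5))
  expect_identical(sim1$vocal$value, sim2$vocal$value)
})

test_that("the pipeline recovers designed effect sizes from trajectories", {
  cfg <- fast_config(n_subjects = 3, seed = 86)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, dir)
  feats <- extract_cohort_features(sim$manifest, sample_rate = cfg$sample_rate)
  norm <- normalize_cohort(feats)

  # realised truth: total offsets relative to the subject's neutral trial
  neutral <- sim$truth[sim$truth$condition == "neutral",
                       c("subject_id", "segment", "total")]
  names(neutral)[3] <- "neutral_total"
  truth <- dplyr::inner_join(sim$truth[sim$truth$condition != "neutral", ],
                             neutral, by = c("subject_id", "segment"))
  truth$expected <- 100 * ((1 + truth$total / 100) /
                             (1 + truth$neutral_total / 100) - 1)
  j <- dplyr::inner_join(norm, truth,
                         by = c("subject_id", "condition", "segment"))
  expect_equal(nrow(j), nrow(norm))
  # frame-level jitter and dropout leave only trial-mean sampling noise
  # (about 0.1 percentage points SD at 2-s trials) and no systematic bias
  expect_lt(max(abs(j$pct_change - j$expected)), 0.5)
  expect_lt(abs(mean(j$pct_change - j$expected)), 0.05)
})

test_that("feature-level and trajectory-level generators share one offset model", {
  cfg <- fast_config(n_subjects = 2, seed = 87)
  sf <- simulate_features(cfg)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, dir)
  # same seed -> identical drawn offsets and vocal tables
  expect_identical(sf$truth$total, sim$truth$total)
  expect_identical(sf$vocal$value, sim$vocal$value)
})

test_that("zero vocal coupling removes the jaw-voice correlation", {
  cfg <- fast_config(seed = 88)
  for (p in names(cfg$vocal)) cfg$vocal[[p]]$coef <- 0
  sf <- simulate_features(cfg)
  res <- correlate_face_voice(sf$face, sf$vocal,
                              conditions = emotion_names(FALSE), n_tests = 4)
  jaw_r <- res$r[res$segment == "jaw"]
  expect_true(all(abs(jaw_r) < 0.2))
})
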