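test_that("Euclidean segment length: identity, 3-4-5, symmetry, rigid invariance", {
  expect_equal(segment_length_sample(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(segment_length_sample(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(segment_length_sample(c(3, 4, 0), c(0, 0, 0)), 5)
  t <- c(10, -7, 2)
  expect_equal(segment_length_sample(c(0, 0, 0) + t, c(3, 4, 0) + t), 5)
  expect_true(is.na(segment_length_sample(c(NA, 0, 0), c(1, 1, 1))))
  expect_true(is.na(segment_length_sample(c(Inf, 0, 0), c(1, 1, 1))))
})

test_that("segment series applies the AND validity rule and never fills gaps", {
  coords <- list(a = matrix(0, 4, 3),
                 b = matrix(rep(c(3, 4, 0), each = 4), 4, 3))
  coords$b[3, ] <- NA
  tr <- make_traj(coords)
  ser <- compute_segment_series(tr, segment_spec("s", "a", "b"))
  expect_identical(ser$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(attr(ser, "n_valid"), 3)
  expect_equal(ser$length_mm[ser$valid], rep(5, 3))
  expect_true(is.na(ser$length_mm[3]))

  expect_error(compute_segment_series(tr, segment_spec("s", "a", "zz")),
               "unknown marker")

  both_out <- make_traj(list(a = matrix(NA_real_, 3, 3),
                             b = matrix(NA_real_, 3, 3)))
  ser0 <- compute_segment_series(both_out, segment_spec("s", "a", "b"))
  expect_equal(attr(ser0, "n_valid"), 0)
  expect_error(mean_segment_length(ser0), "0 valid frames")
})

test_that("trial-mean segment length uses the valid-frame denominator", {
  # arithmetic mean over valid frames
  mk <- function(lengths) {
    n <- length(lengths)
    b <- cbind(lengths, 0, 0)
    b[is.na(lengths), ] <- NA
    make_traj(list(a = matrix(0, n, 3), b = b))
  }
  spec <- segment_spec("s", "a", "b")
  expect_equal(mean_segment_length(compute_segment_series(mk(c(1, 2, 3)), spec)), 2)
  expect_equal(mean_segment_length(compute_segment_series(mk(c(5, NA, 7, NA)), spec)), 6)
  # constant length over any gap-free duration
  expect_equal(mean_segment_length(compute_segment_series(mk(rep(10, 37)), spec)), 10)
})

test_that("gap-free trial mean equals the sum / (sample rate x duration) form", {
  set.seed(7)
  n <- 240
  b <- cbind(50 + rnorm(n), rnorm(n), rnorm(n))
  tr <- make_traj(list(a = matrix(0, n, 3), b = b), sample_rate = 120)
  ser <- compute_segment_series(tr, segment_spec("s", "a", "b"))
  sr <- 120; t_trial <- n / sr
  oracle <- sum(ser$length_mm) / (sr * t_trial)
  expect_equal(mean_segment_length(ser), oracle, tolerance = 1e-12)
})

test_that("trial features: four default segments, eight with supplementary set", {
  cfg <- sim_config(jitter_sd_mm = 0, dropout = 0)
  g <- simulate_subject_geometry(cfg, seed = 5)
  tr <- simulate_trial(g, "happy", fast_config(jitter_sd_mm = 0, dropout = 0),
                       seed = 6)
  f4 <- extract_trial_features(tr, default_segments())
  expect_equal(nrow(f4), 4)
  expect_setequal(f4$segment, c("brow", "eyebrow", "lips", "jaw"))
  expect_true(all(f4$md_mm > 0))
  expect_true(all(f4$coverage == 1))

  f8 <- extract_trial_features(tr, all_segments())
  expect_equal(nrow(f8), 8)

  expect_error(extract_trial_features(tr, tibble::tibble()), "nonempty")
})

test_that("every trial mean is invariant under a common rigid motion", {
  cfg <- fast_config(jitter_sd_mm = 0, dropout = 0)
  g <- simulate_subject_geometry(cfg, seed = 11)
  tr <- simulate_trial(g, "angry", cfg, seed = 12)
  f0 <- extract_trial_features(tr, all_segments())

  # random rotation (QR of a Gaussian matrix) + translation
  set.seed(13)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_); R <- R * sign(diag(qr.R(qr_)))[col(R)]
  shift <- c(100, -250, 40)
  xyz <- as.matrix(tr[, c("x", "y", "z")]) %*% t(R)
  moved <- tr
  moved$x <- xyz[, 1] + shift[1]
  moved$y <- xyz[, 2] + shift[2]
  moved$z <- xyz[, 3] + shift[3]
  moved <- marker_traj(moved, sample_rate = sample_rate(tr))
  f1 <- extract_trial_features(moved, all_segments())
  expect_equal(f1$md_mm, f0$md_mm, tolerance = 1e-9)
})

test_that("masking frames at the mean leaves the mean; masking above lowers it", {
  lengths <- c(4, 6, 5, 5, 7, 3)  # mean 5
  n <- length(lengths)
  mk <- function(l) make_traj(list(a = matrix(0, n, 3),
                                   b = {
                                     b <- cbind(l, 0, 0)
                                     b[is.na(l), ] <- NA
                                     b
                                   }))
  spec <- segment_spec("s", "a", "b")
  m0 <- mean_segment_length(compute_segment_series(mk(lengths), spec))
  at_mean <- lengths; at_mean[c(3, 4)] <- NA
  expect_equal(mean_segment_length(compute_segment_series(mk(at_mean), spec)), m0)
  above <- lengths; above[c(2, 5)] <- NA
  expect_lt(mean_segment_length(compute_segment_series(mk(above), spec)), m0)
})
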