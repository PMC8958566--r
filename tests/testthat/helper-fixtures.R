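# shared builders and independent oracles for the test suite

# small trajectory from explicit per-marker coordinate lists
make_traj <- function(coords, sample_rate = 120) {
  # coords: named list marker -> n x 3 matrix (NA rows = gaps)
  n <- nrow(coords[[1]])
  df <- purrr::map_dfr(names(coords), function(m) {
    tibble::tibble(frame = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1) / sample_rate,
                   marker = m,
                   x = coords[[m]][, 1], y = coords[[m]][, 2],
                   z = coords[[m]][, 3])
  })
  marker_traj(df, sample_rate = sample_rate)
}

# a simple balanced two-factor repeated-measures table
make_balanced_table <- function(n_subjects = 8, levels_a = 3, levels_b = 3,
                                effect_a = 0, subj_sd = 1, noise_sd = 1,
                                seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                   A = factor(seq_len(levels_a)),
                   B = factor(seq_len(levels_b)),
                   stringsAsFactors = FALSE)
  subj <- stats::rnorm(n_subjects, 0, subj_sd)
  d$y <- subj[match(d$subject_id, unique(d$subject_id))] +
    effect_a * as.numeric(d$A) + stats::rnorm(nrow(d), 0, noise_sd)
  tibble::as_tibble(d)
}

# closed-form compound-symmetry RM-ANOVA oracle for balanced gap-free data:
# classical sums of squares with subject as a block, error variance scaled
# as SSE / (N - S) to match maximum-likelihood estimation
rm_anova_oracle <- function(data, response, factors, subject = "subject_id") {
  d <- as.data.frame(data)
  d[[subject]] <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  fml <- stats::as.formula(paste0(
    "`", response, "` ~ `", subject, "` + `", factors[1], "` * `",
    factors[2], "`"))
  at <- stats::anova(stats::lm(fml, data = d))
  rn <- gsub("`", "", rownames(at), fixed = TRUE)
  sse <- at["Residuals", "Sum Sq"]
  n <- nrow(d)
  s <- nlevels(d[[subject]])
  sigma2 <- sse / (n - s)
  effects <- c(factors, paste0(factors[1], ":", factors[2]))
  tibble::tibble(
    effect = effects,
    statistic = at[match(effects, rn), "Mean Sq"] / sigma2,
    den_df = n - s
  )
}

# raw varimax criterion: sum over components of the variance of squared
# loadings (without Kaiser row normalisation)
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(col) mean(col^2) - mean(col)^2))
}

# brute-force k = 2 rotation oracle: scan the rotation angle on a grid and
# return the angle maximising the raw varimax criterion
varimax_angle_oracle <- function(L2, step = 0.001) {
  angles <- seq(0, pi / 2, by = step)
  crit <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    varimax_criterion(L2 %*% R)
  }, numeric(1))
  angles[which.max(crit)]
}

# principal angle of a 2x2 orthogonal matrix, folded into [0, pi/2)
# (varimax is indeterminate to column sign and order)
fold_angle <- function(R) {
  a <- atan2(R[2, 1], R[1, 1])
  a <- a %% (pi / 2)
  a
}

zero_effects <- function() {
  list(coop = c(brow = 0, eyebrow = 0, lips = 0),
       assert = c(jaw = 0),
       valence = c(brow = 0, eyebrow = 0, lips = 0),
       arousal = c(jaw = 0),
       self_boost = c(eyebrow = 0, lips = 0, jaw = 0))
}

# small, fast configuration for feature-level simulations
fast_config <- function(...) {
  sim_config(duration_s = 2, ...)
}
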