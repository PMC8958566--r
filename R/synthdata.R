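#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. The defaults encode
#' the study conditions the analysis assumes: 24 subjects, a 120 Hz capture
#' of 7 facial markers, 9 characters on the 3x3 cooperativeness x
#' assertiveness grid, 9 emotions (8 on the valence x arousal grid plus the
#' neutral baseline), and one control-self trial; condition effects enter as
#' multiplicative rest-length offsets so the designed percent change is
#' analytic ground truth. Trials default to 10 s (set `duration_s = 120` for
#' full performance-length runs).
#'
#' Noise structure: per-subject face scale (removed by normalisation),
#' per-subject expressive-style offsets shared across that subject's
#' performance trials (they survive normalisation and act as the random
#' intercept), per-trial behavioural noise, frame-level Gaussian marker
#' jitter, and marker dropout gaps. A speech-articulation oscillation is
#' applied identically in every condition, including neutral, so the
#' baseline correction can cancel it; `articulation_in_all = FALSE` disables
#' it in the performance conditions to probe violations of that assumption.
#'
#' @param n_subjects number of subjects (default 24).
#' @param duration_s trial duration in seconds (default 10).
#' @param sample_rate capture rate in Hz (default 120).
#' @param face_scale_sd SD of the per-subject global face-size factor.
#' @param articulation_amp_mm,articulation_rate_hz amplitude (mm) and rate
#'   (Hz) of the shared articulation oscillation on the lower face.
#' @param articulation_in_all apply articulation in all conditions (default
#'   TRUE).
#' @param jitter_sd_mm frame-level marker jitter SD (mm).
#' @param dropout per marker-frame probability of a reconstruction gap.
#' @param trial_noise_pct SD (percent units) of per-trial behavioural noise
#'   on each segment's rest length.
#' @param subject_noise_pct SD (percent units) of the per-subject expressive
#'   offset applied to performance trials.
#' @param effects named list of effect slopes in percent units per factor
#'   step: `coop` (named vector over segments), `assert`, `valence`,
#'   `arousal`, and `self_boost` (extra expansion of the performed self).
#' @param vocal vocal-parameter generator spec: a list with `coupling`
#'   (named list parameter -> list(source, coef, base, sd)); sources are
#'   `"intensity"` (the trial's realised jaw offset, percent),
#'   `"quality"` (mean realised brow/eyebrow/lips offset) or `"none"`.
#' @param n_whisper_missing number of librarian trials whose vocal rows are
#'   dropped (whispered; default 2).
#' @param scheme character scheme table.
#' @param seed integer seed for [simulate_cohort()]/[simulate_features()].
#' @return A `facekin_sim_config` list.
#' @export
sim_config <- function(n_subjects = 24,
                       duration_s = 10,
                       sample_rate = 120,
                       face_scale_sd = 0.1,
                       articulation_amp_mm = 2,
                       articulation_rate_hz = 4,
                       articulation_in_all = TRUE,
                       jitter_sd_mm = 0.3,
                       dropout = 0.02,
                       trial_noise_pct = 2,
                       subject_noise_pct = 1.5,
                       effects = list(
                         coop = c(brow = 3, eyebrow = 2, lips = 4),
                         assert = c(jaw = 3),
                         valence = c(brow = 2.5, eyebrow = 2.5, lips = 2.5),
                         arousal = c(jaw = 3),
                         self_boost = c(eyebrow = 2, lips = 2, jaw = 2)
                       ),
                       vocal = default_vocal_spec(),
                       n_whisper_missing = 2,
                       scheme = default_character_scheme(),
                       seed = 1) {
  stopifnot(n_subjects >= 1, duration_s > 0, sample_rate > 0,
            face_scale_sd >= 0, jitter_sd_mm >= 0,
            dropout >= 0, dropout < 1,
            trial_noise_pct >= 0, subject_noise_pct >= 0)
  check_character_scheme(scheme)
  known_segments <- c("brow", "eyebrow", "lips", "jaw")
  for (nm in setdiff(names(effects), "self_boost")) {
    bad <- setdiff(names(effects[[nm]]), known_segments)
    if (length(bad) > 0) {
      abort(paste0("sim_config: effect map names unknown segment(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(list(
    n_subjects = n_subjects, duration_s = duration_s,
    sample_rate = sample_rate, face_scale_sd = face_scale_sd,
    articulation_amp_mm = articulation_amp_mm,
    articulation_rate_hz = articulation_rate_hz,
    articulation_in_all = articulation_in_all,
    jitter_sd_mm = jitter_sd_mm, dropout = dropout,
    trial_noise_pct = trial_noise_pct,
    subject_noise_pct = subject_noise_pct,
    effects = effects, vocal = vocal,
    n_whisper_missing = n_whisper_missing,
    scheme = scheme, seed = seed
  ), class = "facekin_sim_config")
}

#' @rdname sim_config
#' @export
default_vocal_spec <- function() {
  list(
    pitch = list(source = "intensity", coef = 25, base = 150, sd = 35),
    loudness = list(source = "intensity", coef = 0.6, base = 65, sd = 1.2),
    duration = list(source = "quality", coef = -0.8, base = 95, sd = 4),
    pause_duration = list(source = "intensity", coef = -0.5, base = 12, sd = 2.5),
    shimmer = list(source = "intensity", coef = -0.25, base = 5, sd = 1.2),
    timbre_brightness = list(source = "quality", coef = -1.0, base = 50, sd = 5),
    timbre_roughness = list(source = "quality", coef = -0.6, base = 30, sd = 4),
    voice_jitter = list(source = "none", coef = 0, base = 1.5, sd = 0.4),
    hnr = list(source = "none", coef = 0, base = 18, sd = 2.5),
    spectral_tilt = list(source = "none", coef = 0, base = -12, sd = 2),
    attack_time = list(source = "none", coef = 0, base = 40, sd = 6),
    speech_rate = list(source = "none", coef = 0, base = 4, sd = 0.5)
  )
}

# unit-scale neutral marker layout (mm): x depth, y lateral, z vertical
base_face_layout <- function() {
  tibble(
    marker = c("mid_brow", "eyebrow_l", "eyebrow_r", "nose_bridge",
               "lip_l", "lip_r", "jaw"),
    x = c(0, 5, 5, 0, 15, 15, 18),
    y = c(0, -22, 22, 0, -28, 28, 0),
    z = c(35, 25, 25, 0, -35, -35, -75)
  )
}

#' Neutral face geometry for one synthetic subject
#'
#' The 7-marker neutral layout (mid-brow, left/right inner eyebrow, nose
#' bridge, left/right lip corner, jaw) scaled by a per-subject face-size
#' factor drawn from `N(1, face_scale_sd)`.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (deterministic layout per seed).
#' @param scale optional explicit scale factor overriding the random draw.
#' @return List with `markers` (tibble `marker`, `x`, `y`, `z`) and `scale`.
#' @export
simulate_subject_geometry <- function(config = sim_config(), seed = NULL,
                                      scale = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scale)) {
    scale <- max(0.5, 1 + rnorm(1, 0, config$face_scale_sd))
  }
  layout <- base_face_layout()
  layout$x <- layout$x * scale
  layout$y <- layout$y * scale
  layout$z <- layout$z * scale
  list(markers = layout, scale = scale)
}

#' Designed percent offsets of a condition
#'
#' The ground-truth percent change each condition applies to the four
#' default segments, from the effect map: cooperativeness slopes on brow /
#' eyebrow / lips and an assertiveness slope on jaw for characters (levels
#' low/medium/high coded -1/0/+1), valence slopes on the upper segments and
#' an arousal slope on jaw for emotions (coded -1/+1), the self-boost for
#' the performed self, and zero for neutral and control-self.
#'
#' @param condition condition name.
#' @param config a [sim_config()].
#' @return Named numeric vector over `brow`, `eyebrow`, `lips`, `jaw`.
#' @export
designed_offsets <- function(condition, config = sim_config()) {
  segs <- c(brow = 0, eyebrow = 0, lips = 0, jaw = 0)
  add <- function(v, w) { v[names(w)] <- v[names(w)] + w; v }
  lev3 <- c(low = -1, medium = 0, high = 1)
  if (condition %in% config$scheme$name) {
    row <- config$scheme[config$scheme$name == condition, ]
    segs <- add(segs, config$effects$coop * lev3[[row$cooperativeness]])
    segs <- add(segs, config$effects$assert * lev3[[row$assertiveness]])
    if (condition == "self" && !is.null(config$effects$self_boost)) {
      segs <- add(segs, config$effects$self_boost)
    }
  } else if (condition %in% emotion_names(FALSE)) {
    eg <- emotion_grid(condition)
    vnum <- if (eg$valence == "positive") 1 else -1
    anum <- if (eg$arousal == "high") 1 else -1
    segs <- add(segs, config$effects$valence * vnum)
    segs <- add(segs, config$effects$arousal * anum)
  } else if (!condition %in% c("neutral", "control_self")) {
    abort(paste0("designed_offsets: unknown condition '", condition, "'"))
  }
  segs
}

# displace distal markers so each default segment's rest length is scaled by
# (1 + pct/100); nose_bridge is the fixed reference, distal sets are disjoint
apply_segment_offsets <- function(markers, offsets_pct) {
  m <- markers
  pos <- function(lab) unlist(m[m$marker == lab, c("x", "y", "z")])
  set_pos <- function(lab, p) {
    m[m$marker == lab, c("x", "y", "z")] <<- as.list(p)
  }
  nb <- pos("nose_bridge")
  # brow: move mid_brow along its axis from the nose bridge
  mb <- pos("mid_brow")
  set_pos("mid_brow", nb + (mb - nb) * (1 + offsets_pct[["brow"]] / 100))
  # jaw: move the jaw marker along its axis from the nose bridge
  jw <- pos("jaw")
  set_pos("jaw", nb + (jw - nb) * (1 + offsets_pct[["jaw"]] / 100))
  # eyebrow / lips: scale the pair about its midpoint
  for (seg in list(c("eyebrow_l", "eyebrow_r", "eyebrow"),
                   c("lip_l", "lip_r", "lips"))) {
    a <- pos(seg[1]); b <- pos(seg[2])
    ctr <- (a + b) / 2
    mult <- 1 + offsets_pct[[seg[3]]] / 100
    set_pos(seg[1], ctr + (a - ctr) * mult)
    set_pos(seg[2], ctr + (b - ctr) * mult)
  }
  m
}

#' Simulate one trial's marker trajectories
#'
#' Builds a trajectory as neutral geometry, plus the condition's rest-length
#' offsets, plus the shared articulation oscillation (jaw lowering and lip
#' widening at the syllable rate), plus frame-level Gaussian jitter, with
#' dropout gaps in the validity mask.
#'
#' @param geometry output of [simulate_subject_geometry()].
#' @param condition condition name (decides the designed offsets when
#'   `offsets_pct` is not given).
#' @param config a [sim_config()].
#' @param offsets_pct optional named total percent offsets for
#'   `brow`/`eyebrow`/`lips`/`jaw`, overriding the designed values (used by
#'   the cohort generator to add behavioural noise).
#' @param seed optional integer seed.
#' @return A [marker_traj] trial.
#' @export
simulate_trial <- function(geometry, condition, config = sim_config(),
                           offsets_pct = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offsets_pct)) offsets_pct <- designed_offsets(condition, config)
  static <- apply_segment_offsets(geometry$markers, offsets_pct)
  n <- round(config$duration_s * config$sample_rate)
  tt <- (seq_len(n) - 1) / config$sample_rate
  labs <- static$marker
  coords <- array(0, dim = c(n, 3, length(labs)),
                  dimnames = list(NULL, c("x", "y", "z"), labs))
  for (j in seq_along(labs)) {
    coords[, , j] <- matrix(unlist(static[j, c("x", "y", "z")]),
                            nrow = n, ncol = 3, byrow = TRUE)
  }
  articulate <- config$articulation_in_all ||
    condition %in% c("neutral", "control_self")
  if (articulate && config$articulation_amp_mm > 0) {
    phase <- runif(1, 0, 2 * pi)
    osc <- sin(2 * pi * config$articulation_rate_hz * tt + phase)
    nb <- unlist(static[static$marker == "nose_bridge", c("x", "y", "z")])
    jw <- unlist(static[static$marker == "jaw", c("x", "y", "z")])
    ax <- (jw - nb) / sqrt(sum((jw - nb)^2))
    for (a in 1:3) {
      coords[, a, "jaw"] <- coords[, a, "jaw"] +
        config$articulation_amp_mm * osc * ax[a]
    }
    lip_axis <- c(0, 1, 0)  # lateral widening
    for (a in 1:3) {
      coords[, a, "lip_r"] <- coords[, a, "lip_r"] +
        0.5 * config$articulation_amp_mm * osc * lip_axis[a]
      coords[, a, "lip_l"] <- coords[, a, "lip_l"] -
        0.5 * config$articulation_amp_mm * osc * lip_axis[a]
    }
  }
  if (config$jitter_sd_mm > 0) {
    coords <- coords + rnorm(length(coords), 0, config$jitter_sd_mm)
  }
  df <- purrr::map_dfr(seq_along(labs), function(j) {
    tibble(frame = seq_len(n) - 1L, time_s = tt, marker = labs[j],
           x = coords[, 1, j], y = coords[, 2, j], z = coords[, 3, j])
  })
  if (config$dropout > 0) {
    gap <- runif(nrow(df)) < config$dropout
    df$x[gap] <- NA_real_
    df$y[gap] <- NA_real_
    df$z[gap] <- NA_real_
  }
  marker_traj(df, sample_rate = config$sample_rate)
}

cohort_conditions <- function(config) {
  c(config$scheme$name, emotion_names(TRUE), "control_self")
}

subject_ids <- function(n) sprintf("s%02d", seq_len(n))

# realised per-trial offsets for every (subject, condition, segment):
# designed + subject expressive style (performance trials only) + trial noise;
# the neutral trial keeps only its own trial noise, which all of the
# subject's percent-change scores share through the baseline division
draw_cohort_offsets <- function(config) {
  segs <- c("brow", "eyebrow", "lips", "jaw")
  subjects <- subject_ids(config$n_subjects)
  conditions <- cohort_conditions(config)
  purrr::map_dfr(subjects, function(s) {
    style <- setNames(rnorm(4, 0, config$subject_noise_pct), segs)
    purrr::map_dfr(conditions, function(cond) {
      designed <- designed_offsets(cond, config)
      eps <- rnorm(4, 0, config$trial_noise_pct)
      performance <- !cond %in% c("neutral", "control_self")
      total <- designed + eps + if (performance) style else 0
      tibble(subject_id = s, condition = cond, segment = segs,
             designed = unname(designed), total = unname(total))
    })
  })
}

draw_vocal_table <- function(offsets, config) {
  spec <- config$vocal
  wide <- tidyr::pivot_wider(offsets[c("subject_id", "condition", "segment", "total")],
                             names_from = "segment", values_from = "total")
  wide$intensity <- wide$jaw
  wide$quality <- (wide$brow + wide$eyebrow + wide$lips) / 3
  wide <- wide[wide$condition != "control_self", ]
  vocal <- purrr::map_dfr(names(spec), function(pn) {
    p <- spec[[pn]]
    latent <- switch(p$source,
                     intensity = wide$intensity,
                     quality = wide$quality,
                     none = 0)
    tibble(subject_id = wide$subject_id, condition = wide$condition,
           parameter = pn,
           value = p$base + p$coef * latent + rnorm(nrow(wide), 0, p$sd))
  })
  if (config$n_whisper_missing > 0) {
    libs <- unique(vocal$subject_id)
    # always keep at least one donor subject for the librarian condition
    whisper <- head(libs, min(config$n_whisper_missing, length(libs) - 1))
    drop <- vocal$condition == "librarian" & vocal$subject_id %in% whisper
    vocal <- vocal[!drop, ]
  }
  vocal
}

#' Simulate a full synthetic cohort with trajectory files
#'
#' Draws subject geometries and per-trial offsets, writes one trajectory TSV
#' per (subject, condition) trial plus `manifest.csv` and `vocal.csv` under
#' `dir`, and returns the manifest, the vocal table and the ground truth.
#' All randomness flows from `config$seed`, so identical configurations
#' reproduce identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return List `manifest`, `vocal`, `truth` (realised and designed percent
#'   offsets per trial and segment), `subjects` (id, face scale).
#' @export
simulate_cohort <- function(config = sim_config(), dir) {
  set.seed(config$seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subjects <- subject_ids(config$n_subjects)
  # offsets and vocal are drawn first so the feature-level generator
  # (simulate_features) sees the identical stream under the same seed
  offsets <- draw_cohort_offsets(config)
  vocal <- draw_vocal_table(offsets, config)
  geoms <- purrr::map(subjects, function(s) {
    simulate_subject_geometry(config)
  })
  names(geoms) <- subjects
  manifest <- purrr::map_dfr(subjects, function(s) {
    purrr::map_dfr(cohort_conditions(config), function(cond) {
      off <- offsets[offsets$subject_id == s & offsets$condition == cond, ]
      ov <- setNames(off$total, off$segment)
      traj <- simulate_trial(geoms[[s]], cond, config, offsets_pct = ov)
      path <- file.path(dir, paste0(s, "_", cond, ".tsv"))
      write_trial(traj, path)
      tibble(subject_id = s, condition = cond, path = path,
             duration_s = config$duration_s)
    })
  })
  write_feature_table(manifest, file.path(dir, "manifest.csv"))
  write_feature_table(vocal, file.path(dir, "vocal.csv"))
  list(manifest = manifest, vocal = vocal, truth = offsets,
       subjects = tibble(subject_id = subjects,
                         scale = vapply(geoms, `[[`, numeric(1), "scale")))
}

#' Simulate cohort features without trajectories
#'
#' Fast path for simulation studies: draws the same per-trial offset
#' structure as [simulate_cohort()] and converts it analytically to the
#' percent-change scores the trajectory pipeline would recover (performance
#' multiplier over the subject's neutral-trial multiplier), skipping frame
#' synthesis, file I/O and feature extraction. Marker jitter and dropout
#' contribute negligibly to trial means at capture scale and are not
#' emulated here.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return List `face` (normalised long table: all non-neutral conditions),
#'   `vocal`, `truth`.
#' @export
simulate_features <- function(config = sim_config(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  offsets <- draw_cohort_offsets(config)
  vocal <- draw_vocal_table(offsets, config)
  neutral <- offsets[offsets$condition == "neutral",
                     c("subject_id", "segment", "total")]
  names(neutral)[3] <- "neutral_total"
  perf <- offsets[offsets$condition != "neutral", ]
  face <- dplyr::left_join(perf, neutral, by = c("subject_id", "segment"))
  face$pct_change <- 100 * ((1 + face$total / 100) /
                              (1 + face$neutral_total / 100) - 1)
  list(face = face[c("subject_id", "condition", "segment", "pct_change")],
       vocal = vocal, truth = offsets)
}
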