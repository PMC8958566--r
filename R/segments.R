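#' Facial segment specifications
#'
#' A segment is a pair of facial markers whose Euclidean length indexes
#' expansion/contraction of a facial region (e.g., lip corner to lip corner).
#' `segment_spec()` builds a one-row spec; `default_segments()` returns the
#' four standard segments (brow, eyebrow, lips, jaw) and
#' `supplementary_segments()` the four exploratory vertical segments from the
#' nose bridge to each inner eyebrow and lip corner.
#'
#' The default marker wiring is a documented convention (the exact pairs are
#' configurable): brow = mid-brow to nose bridge (vertical, upper face);
#' eyebrow = left to right inner eyebrow (horizontal, upper); lips = left to
#' right lip corner (horizontal, lower); jaw = nose bridge to jaw (vertical,
#' lower).
#'
#' @param name segment identifier, unique within a spec set.
#' @param marker_a,marker_b the two marker labels (must differ).
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param region `"upper"` or `"lower"` face.
#' @return A tibble with columns `segment`, `marker_a`, `marker_b`,
#'   `orientation`, `region`.
#' @export
segment_spec <- function(name, marker_a, marker_b,
                         orientation = c("vertical", "horizontal"),
                         region = c("upper", "lower")) {
  orientation <- match.arg(orientation)
  region <- match.arg(region)
  if (identical(marker_a, marker_b)) {
    abort("segment_spec: marker_a and marker_b must differ")
  }
  tibble(segment = name, marker_a = marker_a, marker_b = marker_b,
         orientation = orientation, region = region)
}

#' @rdname segment_spec
#' @export
default_segments <- function() {
  dplyr::bind_rows(
    segment_spec("brow", "mid_brow", "nose_bridge", "vertical", "upper"),
    segment_spec("eyebrow", "eyebrow_l", "eyebrow_r", "horizontal", "upper"),
    segment_spec("lips", "lip_l", "lip_r", "horizontal", "lower"),
    segment_spec("jaw", "nose_bridge", "jaw", "vertical", "lower")
  )
}

#' @rdname segment_spec
#' @export
supplementary_segments <- function() {
  dplyr::bind_rows(
    segment_spec("eyebrow_vert_l", "nose_bridge", "eyebrow_l", "vertical", "upper"),
    segment_spec("eyebrow_vert_r", "nose_bridge", "eyebrow_r", "vertical", "upper"),
    segment_spec("lips_vert_l", "nose_bridge", "lip_l", "vertical", "lower"),
    segment_spec("lips_vert_r", "nose_bridge", "lip_r", "vertical", "lower")
  )
}

#' @rdname segment_spec
#' @export
all_segments <- function() {
  dplyr::bind_rows(default_segments(), supplementary_segments())
}

check_segment_specs <- function(specs) {
  if (!is.data.frame(specs) || nrow(specs) == 0) {
    abort("segment specs must be a nonempty data frame (see segment_spec())")
  }
  if (anyDuplicated(specs$segment)) {
    abort("segment names must be unique within a spec set")
  }
  invisible(specs)
}

#' Euclidean length of a marker pair
#'
#' The distance between two 3D points,
#' `d = sqrt((x2-x1)^2 + (y2-y1)^2 + (z2-z1)^2)`, in millimetres.
#' `segment_length_sample()` takes two length-3 coordinate vectors;
#' `segment_length()` is the vectorised form over matching coordinate columns.
#'
#' @param p_a,p_b numeric length-3 points (mm). Non-finite input yields `NA`
#'   (an invalid sample), mirroring the gap handling upstream.
#' @return Length in mm.
#' @export
segment_length_sample <- function(p_a, p_b) {
  stopifnot(length(p_a) == 3, length(p_b) == 3)
  if (!all(is.finite(p_a)) || !all(is.finite(p_b))) return(NA_real_)
  sqrt(sum((p_b - p_a)^2))
}

segment_length <- function(xa, ya, za, xb, yb, zb) {
  sqrt((xb - xa)^2 + (yb - ya)^2 + (zb - za)^2)
}

#' Per-frame segment length series
#'
#' Joins the two markers of a segment spec frame by frame and computes the
#' Euclidean length wherever both markers are valid. A frame is valid for the
#' segment only when both contributing markers are valid (gaps propagate by
#' AND); invalid frames are excluded from downstream means, never filled.
#'
#' @param set a [marker_traj] trial.
#' @param spec a one-row segment spec (see [segment_spec()]).
#' @return A tibble with `segment`, `frame`, `time_s`, `length_mm`, `valid`,
#'   plus attributes `n_valid` and `sample_rate`.
#' @export
compute_segment_series <- function(set, spec) {
  stopifnot(inherits(set, "marker_traj"), nrow(spec) == 1)
  labs <- marker_labels(set)
  missing_marks <- setdiff(c(spec$marker_a, spec$marker_b), labs)
  if (length(missing_marks) > 0) {
    abort(paste0("compute_segment_series: unknown marker label(s): ",
                 paste(missing_marks, collapse = ", ")))
  }
  a <- as_tibble(set)[set$marker == spec$marker_a,
                      c("frame", "time_s", "x", "y", "z", "valid")]
  b <- as_tibble(set)[set$marker == spec$marker_b, c("frame", "x", "y", "z", "valid")]
  ab <- dplyr::inner_join(a, b, by = "frame", suffix = c("_a", "_b"))
  out <- tibble(
    segment = spec$segment,
    frame = ab$frame,
    time_s = ab$time_s,
    valid = ab$valid_a & ab$valid_b,
    length_mm = segment_length(ab$x_a, ab$y_a, ab$z_a, ab$x_b, ab$y_b, ab$z_b)
  )
  out$length_mm[!out$valid] <- NA_real_
  structure(out, n_valid = sum(out$valid), sample_rate = sample_rate(set))
}

#' Trial-mean segment length
#'
#' The mean Euclidean length of a segment over the trial, in mm. For a
#' gap-free trial this equals the textbook sum-over-frames divided by
#' `sample_rate * duration`; when gaps are present the denominator is the
#' number of valid frames, so omitted gaps do not bias the mean downward.
#'
#' @param series output of [compute_segment_series()].
#' @param min_valid minimum number of valid frames required (default 1).
#' @return Mean length in mm, or an error when fewer than `min_valid` frames
#'   are valid.
#' @export
mean_segment_length <- function(series, min_valid = 1) {
  n_valid <- sum(series$valid)
  if (n_valid < min_valid) {
    abort(paste0("mean_segment_length: segment '", series$segment[1],
                 "' has ", n_valid, " valid frames (< ", min_valid, ")"),
          class = "facekin_undefined_feature")
  }
  mean(series$length_mm[series$valid])
}

#' Per-trial segment features
#'
#' Computes the trial-mean length of every requested segment, together with
#' the valid-frame count and coverage fraction. Segments whose coverage falls
#' below `min_coverage` get `md_mm = NA` (an undefined feature) and are
#' reported in a warning.
#'
#' @param set a [marker_traj] trial.
#' @param specs segment spec table (default [default_segments()]).
#' @param min_coverage minimum fraction of frames that must be valid for a
#'   segment mean to be defined (default 0.5).
#' @param subject_id,condition optional identifiers carried into the output.
#' @return A tibble with one row per segment: `subject_id`, `condition`,
#'   `segment`, `md_mm`, `n_valid`, `coverage`.
#' @export
extract_trial_features <- function(set, specs = default_segments(),
                                   min_coverage = 0.5,
                                   subject_id = NA_character_,
                                   condition = NA_character_) {
  check_segment_specs(specs)
  nf <- n_frames(set)
  rows <- purrr::map(seq_len(nrow(specs)), function(i) {
    ser <- compute_segment_series(set, specs[i, ])
    n_valid <- sum(ser$valid)
    coverage <- if (nf > 0) n_valid / nf else 0
    md <- if (nf > 0 && coverage >= min_coverage && n_valid >= 1) {
      mean(ser$length_mm[ser$valid])
    } else {
      NA_real_
    }
    tibble(subject_id = subject_id, condition = condition,
           segment = specs$segment[i], md_mm = md,
           n_valid = n_valid, coverage = coverage)
  })
  out <- dplyr::bind_rows(rows)
  undef <- out$segment[is.na(out$md_mm)]
  if (length(undef) > 0) {
    warn(paste0("extract_trial_features: undefined feature(s) for ",
                subject_id, "/", condition, ": ",
                paste(undef, collapse = ", ")))
  }
  out
}

#' Extract features for a whole cohort
#'
#' Reads every trial in a manifest and stacks the per-trial segment features.
#'
#' @param manifest tibble with `subject_id`, `condition`, `path`.
#' @param specs segment spec table.
#' @param sample_rate nominal sampling rate of the trial files (Hz).
#' @param min_coverage see [extract_trial_features()].
#' @return Long tibble: `subject_id`, `condition`, `segment`, `md_mm`,
#'   `n_valid`, `coverage`.
#' @export
extract_cohort_features <- function(manifest, specs = default_segments(),
                                    sample_rate = 120, min_coverage = 0.5) {
  check_segment_specs(specs)
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    set <- read_trial(manifest$path[i], sample_rate = sample_rate)
    extract_trial_features(set, specs, min_coverage = min_coverage,
                           subject_id = manifest$subject_id[i],
                           condition = manifest$condition[i])
  })
}
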