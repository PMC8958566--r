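#' Percent change relative to the neutral baseline
#'
#' Converts a subject's trial-mean segment lengths into percent change
#' relative to that subject's neutral-speech baseline:
#' `100 * (Md[performance] - Md[neutral]) / Md[neutral]`.
#' Positive values mean segment expansion relative to neutral speech. Because
#' both terms come from the same face speaking the same script, the ratio
#' removes face-size differences across subjects and speech-articulation
#' movement common to all conditions.
#'
#' @param perf per-trial features for one performance trial (output of
#'   [extract_trial_features()]).
#' @param neutral features of the same subject's neutral trial.
#' @return Tibble `subject_id`, `condition`, `segment`, `pct_change`.
#' @export
percent_change <- function(perf, neutral) {
  if (!identical(sort(perf$segment), sort(neutral$segment))) {
    abort("percent_change: performance and neutral trials cover different segments")
  }
  subj <- unique(c(perf$subject_id, neutral$subject_id))
  subj <- subj[!is.na(subj)]
  if (length(subj) > 1) {
    abort("percent_change: performance and neutral trials are from different subjects")
  }
  j <- dplyr::inner_join(perf[c("subject_id", "condition", "segment", "md_mm")],
                         neutral[c("segment", "md_mm")],
                         by = "segment", suffix = c("", "_neutral"))
  bad <- j$segment[is.na(j$md_mm_neutral) | j$md_mm_neutral <= 0]
  if (length(bad) > 0) {
    abort(paste0("percent_change: neutral baseline undefined or non-positive for ",
                 paste(paste0("(", j$subject_id[1], ", ", bad, ")"), collapse = ", ")),
          class = "facekin_normalization_error")
  }
  tibble(subject_id = j$subject_id, condition = j$condition, segment = j$segment,
         pct_change = 100 * (j$md_mm - j$md_mm_neutral) / j$md_mm_neutral)
}

#' Normalise a cohort of trial features to each subject's baseline
#'
#' Applies [percent_change()] per subject using that subject's
#' `baseline_condition` trial, returning one normalised row per non-baseline
#' trial and segment. Baseline rows are excluded from the output (they are 0
#' by construction). Subjects lacking a baseline trial are reported together
#' in a single error.
#'
#' @param features long cohort feature table from [extract_cohort_features()].
#' @param baseline_condition condition name of the baseline (default
#'   `"neutral"`).
#' @return Tibble `subject_id`, `condition`, `segment`, `pct_change`.
#' @export
normalize_cohort <- function(features, baseline_condition = "neutral") {
  subjects <- unique(features$subject_id)
  base <- features[features$condition == baseline_condition, ]
  missing_base <- setdiff(subjects, unique(base$subject_id))
  if (length(missing_base) > 0) {
    abort(paste0("normalize_cohort: no '", baseline_condition,
                 "' trial for subject(s): ",
                 paste(sort(missing_base), collapse = ", ")))
  }
  perf <- features[features$condition != baseline_condition, ]
  purrr::map_dfr(subjects, function(s) {
    ps <- perf[perf$subject_id == s, ]
    ns <- base[base$subject_id == s, ]
    purrr::map_dfr(unique(ps$condition), function(cond) {
      percent_change(ps[ps$condition == cond, ], ns)
    })
  })
}

#' Screen normalised features for extreme outliers
#'
#' Report-only screen: flags rows whose robust z-score (median/MAD per
#' parameter) exceeds `z_threshold` in magnitude. Data are never modified or
#' removed; the report mirrors a visual screen for extreme values. Parameters
#' with zero spread produce no flags.
#'
#' @param table tidy table with a numeric `value_col` and a `parameter_col`
#'   identifying which parameter each row belongs to.
#' @param z_threshold flag threshold on |robust z| (default 4).
#' @param value_col,parameter_col column names (defaults `pct_change`,
#'   `segment`).
#' @return Tibble of flagged rows with their robust z, empty when clean.
#' @export
screen_outliers <- function(table, z_threshold = 4,
                            value_col = "pct_change", parameter_col = "segment") {
  if (nrow(table) == 0) abort("screen_outliers: empty table")
  out <- table
  out$.value <- out[[value_col]]
  out$.param <- out[[parameter_col]]
  flagged <- out |>
    dplyr::group_by(.data$.param) |>
    dplyr::mutate(.z = {
      med <- median(.data$.value, na.rm = TRUE)
      s <- mad(.data$.value, na.rm = TRUE)
      if (!is.finite(s) || s == 0) rep(0, length(.data$.value))
      else (.data$.value - med) / s
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(abs(.data$.z) > z_threshold)
  flagged <- flagged[setdiff(names(flagged), c(".value", ".param"))]
  names(flagged)[names(flagged) == ".z"] <- "robust_z"
  flagged
}
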