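#' Correlate facial segment scores with vocal parameters
#'
#' Pearson product-moment correlations between each facial segment's percent
#' change and each vocal parameter, over trials joined on
#' (subject, condition). Two-tailed t test, Fisher-z confidence interval,
#' and a Bonferroni significance flag at `alpha / n_tests` (defaulting to
#' the four-segment family, i.e. .0125 at alpha = .05). Trials with a
#' missing vocal value (e.g. whispered trials) are dropped from the pairs,
#' not imputed.
#'
#' @param face normalised facial table (`subject_id`, `condition`,
#'   `segment`, `pct_change`).
#' @param vocal tidy vocal table (`subject_id`, `condition`, `parameter`,
#'   `value`).
#' @param conditions optional character vector restricting which conditions
#'   enter (e.g. the nine characters, or the eight non-neutral emotions).
#' @param parameters vocal parameters to correlate (default pitch and
#'   loudness).
#' @param alpha family-wise alpha (default 0.05).
#' @param n_tests size of the Bonferroni family (default: number of
#'   segments).
#' @param conf_level confidence level of the Fisher-z interval (default
#'   0.95).
#' @return Tibble: `segment`, `parameter`, `n`, `r`, `r_squared`,
#'   `statistic` (t), `df`, `p.value`, `conf_low`, `conf_high`,
#'   `significant`.
#' @export
correlate_face_voice <- function(face, vocal, conditions = NULL,
                                 parameters = c("pitch", "loudness"),
                                 alpha = 0.05, n_tests = NULL,
                                 conf_level = 0.95) {
  if (!is.null(conditions)) {
    face <- face[face$condition %in% conditions, ]
    vocal <- vocal[vocal$condition %in% conditions, ]
  }
  vocal <- vocal[vocal$parameter %in% parameters, ]
  segs <- unique(face$segment)
  if (is.null(n_tests)) n_tests <- length(segs)
  alpha_c <- bonferroni_threshold(alpha, n_tests)
  grid <- expand.grid(segment = segs, parameter = parameters,
                      stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    f <- face[face$segment == grid$segment[i],
              c("subject_id", "condition", "pct_change")]
    v <- vocal[vocal$parameter == grid$parameter[i],
               c("subject_id", "condition", "value")]
    pairs <- dplyr::inner_join(f, v, by = c("subject_id", "condition"))
    pairs <- pairs[complete.cases(pairs[c("pct_change", "value")]), ]
    n <- nrow(pairs)
    if (n < 3) {
      abort(paste0("correlate_face_voice: fewer than 3 complete pairs for ",
                   grid$segment[i], " x ", grid$parameter[i]))
    }
    if (sd(pairs$pct_change) == 0 || sd(pairs$value) == 0) {
      return(tibble(segment = grid$segment[i], parameter = grid$parameter[i],
                    n = n, r = NA_real_, r_squared = NA_real_,
                    statistic = NA_real_, df = n - 2L, p.value = NA_real_,
                    conf_low = NA_real_, conf_high = NA_real_,
                    significant = NA))
    }
    ct <- cor.test(pairs$pct_change, pairs$value, method = "pearson",
                   alternative = "two.sided", conf.level = conf_level)
    tibble(segment = grid$segment[i], parameter = grid$parameter[i],
           n = n, r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
           statistic = unname(ct$statistic), df = unname(ct$parameter),
           p.value = ct$p.value,
           conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
           significant = ct$p.value < alpha_c)
  })
}

#' Performed-self versus control-self contrast
#'
#' Paired per-segment contrast between the acted "self" trial and the
#' unannounced conversational recitation (control-self), both expressed as
#' percent change from the neutral baseline. Reports the paired mean
#' difference (performed minus control), a paired t test and Cohen's dz.
#'
#' @param normalized normalised table containing both conditions.
#' @param performed,control condition labels (defaults `"self"`,
#'   `"control_self"`).
#' @return Tibble `segment`, `n`, `mean_diff`, `cohens_dz`, `statistic`,
#'   `df`, `p.value`.
#' @export
compare_self <- function(normalized, performed = "self",
                         control = "control_self") {
  p <- normalized[normalized$condition == performed, ]
  c_ <- normalized[normalized$condition == control, ]
  unpaired <- sort(c(setdiff(p$subject_id, c_$subject_id),
                     setdiff(c_$subject_id, p$subject_id)))
  if (length(unpaired) > 0) {
    abort(paste0("compare_self: subject(s) missing one of the two trials: ",
                 paste(unique(unpaired), collapse = ", ")))
  }
  j <- dplyr::inner_join(p[c("subject_id", "segment", "pct_change")],
                         c_[c("subject_id", "segment", "pct_change")],
                         by = c("subject_id", "segment"),
                         suffix = c("_perf", "_ctrl"))
  j |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise({
      d <- .data$pct_change_perf - .data$pct_change_ctrl
      if (sd(d) == 0) {
        tibble(n = length(d), mean_diff = mean(d), cohens_dz = NA_real_,
               statistic = NA_real_, df = length(d) - 1L, p.value = NA_real_)
      } else {
        tt <- t.test(d)
        tibble(n = length(d), mean_diff = mean(d),
               cohens_dz = mean(d) / sd(d),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p.value = tt$p.value)
      }
    }, .groups = "drop")
}
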