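#' Dimensional grouping of the basic emotions
#'
#' Maps each of the nine scripted emotions onto the valence x arousal
#' circumplex cells used by the analysis: happy, proud and surprised are
#' positive valence + high arousal; angry, fearful and disgusted negative +
#' high; calm positive + low; sad negative + low. Neutral is the baseline
#' condition: it carries no valence/arousal coordinates and is excluded from
#' the univariate analyses (it enters only as the normalisation baseline and
#' in the multivariate analysis).
#'
#' @param name character vector of emotion names.
#' @return Tibble `name`, `valence` (`positive`/`negative`), `arousal`
#'   (`high`/`low`), `is_baseline`.
#' @export
emotion_grid <- function(name) {
  grid <- tibble(
    name = c("happy", "proud", "surprised", "angry", "fearful", "disgusted",
             "calm", "sad", "neutral"),
    valence = c("positive", "positive", "positive", "negative", "negative",
                "negative", "positive", "negative", NA),
    arousal = c("high", "high", "high", "high", "high", "high",
                "low", "low", NA),
    is_baseline = c(rep(FALSE, 8), TRUE)
  )
  unknown <- setdiff(name, grid$name)
  if (length(unknown) > 0) {
    abort(paste0("emotion_grid: unknown emotion(s): ",
                 paste(unknown, collapse = ", ")))
  }
  grid[match(name, grid$name), ]
}

#' @rdname emotion_grid
#' @param include_baseline include `"neutral"` in the returned names.
#' @export
emotion_names <- function(include_baseline = TRUE) {
  nm <- c("happy", "proud", "surprised", "angry", "fearful", "disgusted",
          "calm", "sad")
  if (include_baseline) c(nm, "neutral") else nm
}

#' The 3x3 character scheme
#'
#' Stock characters are organised by crossing three levels of cooperativeness
#' (tendency to satisfy another's concerns) with three levels of
#' assertiveness (tendency to satisfy one's own concerns). The exact
#' name-to-cell placement is a configuration input; the default shipped here
#' is a documented convention, not ground truth, and can be replaced by any
#' complete 3x3 bijection.
#'
#' @return Tibble `name`, `cooperativeness`, `assertiveness` with levels
#'   `low`/`medium`/`high`.
#' @export
default_character_scheme <- function() {
  tibble(
    name = c("bully", "king", "hero",
             "jester", "self", "lover",
             "recluse", "loner", "librarian"),
    cooperativeness = rep(c("low", "medium", "high"), 3),
    assertiveness = rep(c("high", "medium", "low"), each = 3)
  )
}

check_character_scheme <- function(scheme) {
  lv <- c("low", "medium", "high")
  if (!is.data.frame(scheme) ||
      !all(c("name", "cooperativeness", "assertiveness") %in% names(scheme))) {
    abort("character scheme needs columns name, cooperativeness, assertiveness")
  }
  if (nrow(scheme) != 9 || anyDuplicated(scheme$name)) {
    abort("character scheme must assign exactly nine distinct names")
  }
  if (!all(scheme$cooperativeness %in% lv) || !all(scheme$assertiveness %in% lv)) {
    abort("character scheme levels must be low/medium/high")
  }
  cells <- paste(scheme$cooperativeness, scheme$assertiveness)
  if (anyDuplicated(cells)) {
    abort("character scheme must be a bijection: each 3x3 cell used exactly once")
  }
  invisible(scheme)
}

#' @rdname default_character_scheme
#' @param name character vector of character names.
#' @param scheme a complete 3x3 scheme table (default
#'   [default_character_scheme()]).
#' @export
character_grid <- function(name, scheme = default_character_scheme()) {
  check_character_scheme(scheme)
  unknown <- setdiff(name, scheme$name)
  if (length(unknown) > 0) {
    abort(paste0("character_grid: name(s) not in scheme: ",
                 paste(unknown, collapse = ", ")))
  }
  scheme[match(name, scheme$name), ]
}

factor_sum <- function(x, levels) {
  f <- factor(x, levels = levels)
  stats::contrasts(f) <- contr.sum(length(levels))
  f
}

#' Attach design coordinates to a trial table
#'
#' Labels every row of a manifest-like table with its condition kind
#' (`character`, `emotion`, `baseline`, `control_self`) and the corresponding
#' design factors, coded as sum-to-zero (deviation) contrasts so that type
#' III tests are well-defined even in the unbalanced emotion design.
#'
#' @param manifest tibble with at least `subject_id` and `condition`.
#' @param scheme character scheme table (see [default_character_scheme()]).
#' @return Input tibble plus `kind`, `cooperativeness`, `assertiveness`,
#'   `valence`, `arousal` factor columns (NA outside their kind) and
#'   `subject_id` coerced to factor.
#' @export
build_design_table <- function(manifest, scheme = default_character_scheme()) {
  check_character_scheme(scheme)
  cond <- manifest$condition
  kind <- dplyr::case_when(
    cond %in% scheme$name ~ "character",
    cond == "neutral" ~ "baseline",
    cond == "control_self" ~ "control_self",
    cond %in% emotion_names(FALSE) ~ "emotion",
    TRUE ~ NA_character_
  )
  if (anyNA(kind)) {
    abort(paste0("build_design_table: unlabelled condition(s): ",
                 paste(unique(cond[is.na(kind)]), collapse = ", ")))
  }
  out <- as_tibble(manifest)
  out$kind <- kind
  cg <- character_grid(scheme$name, scheme)
  out$cooperativeness <- factor_sum(
    ifelse(kind == "character", cg$cooperativeness[match(cond, cg$name)], NA),
    c("low", "medium", "high"))
  out$assertiveness <- factor_sum(
    ifelse(kind == "character", cg$assertiveness[match(cond, cg$name)], NA),
    c("low", "medium", "high"))
  eg <- emotion_grid(emotion_names(FALSE))
  out$valence <- factor_sum(
    ifelse(kind == "emotion", eg$valence[match(cond, eg$name)], NA),
    c("negative", "positive"))
  out$arousal <- factor_sum(
    ifelse(kind == "emotion", eg$arousal[match(cond, eg$name)], NA),
    c("low", "high"))
  out$subject_id <- factor(out$subject_id)
  out
}

#' Cell counts of the emotion design
#'
#' The 2x2 valence x arousal grouping is unbalanced by construction (three
#' emotions in each high-arousal cell, one in each low-arousal cell); this
#' reports the realised cell counts of a design table.
#'
#' @param design output of [build_design_table()].
#' @return Tibble `valence`, `arousal`, `n`.
#' @export
emotion_cell_counts <- function(design) {
  design |>
    dplyr::filter(.data$kind == "emotion") |>
    dplyr::count(.data$valence, .data$arousal)
}
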