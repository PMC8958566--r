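#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> extract -> normalize -> analyze -> correlate ->
#' pca and writes every stage's output under `out_dir`. The input is either
#' a [sim_config()] (or list / YAML file of overrides for one), in which
#' case a synthetic cohort is generated, or a configuration naming an
#' existing `manifest` CSV and `vocal` CSV to analyse recorded data.
#'
#' Stage outputs: `features.csv` (trial segment means), `normalized.csv`
#' (percent change), `outlier_flags.csv`, `anova_character.csv`,
#' `anova_emotion.csv`, `marginal_means.csv`, `correlations.csv`,
#' `self_contrast.csv`, `pca_loadings.csv`, `pca_condition_scores.csv`,
#' `scree.csv`, and a `report.json` run report listing the seed, a
#' configuration hash, per-stage row counts, output paths and warnings
#' (imputed cells, dropped vocal trials, outlier flags).
#'
#' @param config a `facekin_sim_config`, a list of overrides for
#'   [sim_config()], or the path to a YAML file of such overrides (a
#'   `scheme` block may be given as nine `name: [coop, assert]` entries).
#'   May also carry `manifest` and `vocal` paths to skip simulation.
#' @param out_dir output directory.
#' @param seed optional integer overriding the config seed.
#' @param segments segment set to analyse (default [default_segments()]).
#' @param alpha family-wise alpha (default 0.05).
#' @param k number of rotated components (default 2).
#' @return The run report, invisibly a list; also written as JSON.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         segments = default_segments(), alpha = 0.05, k = 2) {
  config <- parse_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  warnings <- character()

  # -- simulate (or load) ----------------------------------------------------
  if (!is.null(config$manifest_path)) {
    manifest <- read_manifest(config$manifest_path)
    vocal <- read_feature_table(config$vocal_path,
                                required = c("subject_id", "condition",
                                             "parameter", "value"))
  } else {
    sim <- simulate_cohort(config, dir = file.path(out_dir, "trials"))
    manifest <- sim$manifest
    vocal <- sim$vocal
  }

  # -- extract ---------------------------------------------------------------
  features <- extract_cohort_features(manifest, specs = segments,
                                      sample_rate = config$sample_rate)
  paths$features <- file.path(out_dir, "features.csv")
  write_feature_table(features, paths$features)

  # -- normalize -------------------------------------------------------------
  normalized <- normalize_cohort(features)
  flags <- screen_outliers(normalized)
  paths$normalized <- file.path(out_dir, "normalized.csv")
  write_feature_table(
    tidyr::pivot_wider(normalized, names_from = "segment",
                       values_from = "pct_change"),
    paths$normalized)
  paths$outlier_flags <- file.path(out_dir, "outlier_flags.csv")
  write_feature_table(flags, paths$outlier_flags)
  if (nrow(flags) > 0) {
    warnings <- c(warnings, paste0(nrow(flags), " outlier flag(s) raised"))
  }

  # -- analyze ---------------------------------------------------------------
  design <- build_design_table(manifest, scheme = config$scheme)
  suite_char <- run_univariate_suite(normalized, design, set = "character",
                                     alpha = alpha)
  suite_emo <- run_univariate_suite(normalized, design, set = "emotion",
                                    alpha = alpha)
  paths$anova_character <- file.path(out_dir, "anova_character.csv")
  paths$anova_emotion <- file.path(out_dir, "anova_emotion.csv")
  write_feature_table(tidy(suite_char), paths$anova_character)
  write_feature_table(tidy(suite_emo), paths$anova_emotion)
  emm <- dplyr::bind_rows(
    purrr::imap_dfr(as.list(suite_char), function(f, seg)
      dplyr::mutate(marginal_means(f), segment = seg, set = "character")),
    purrr::imap_dfr(as.list(suite_emo), function(f, seg)
      dplyr::mutate(marginal_means(f), segment = seg, set = "emotion"))
  )
  paths$marginal_means <- file.path(out_dir, "marginal_means.csv")
  write_feature_table(emm, paths$marginal_means)

  # -- correlate -------------------------------------------------------------
  corr <- dplyr::bind_rows(
    dplyr::mutate(
      correlate_face_voice(normalized, vocal,
                           conditions = config$scheme$name, alpha = alpha),
      condition_set = "character", .before = 1),
    dplyr::mutate(
      correlate_face_voice(normalized, vocal,
                           conditions = emotion_names(FALSE), alpha = alpha),
      condition_set = "emotion", .before = 1)
  )
  paths$correlations <- file.path(out_dir, "correlations.csv")
  write_feature_table(corr, paths$correlations)
  self_contrast <- compare_self(normalized)
  paths$self_contrast <- file.path(out_dir, "self_contrast.csv")
  write_feature_table(self_contrast, paths$self_contrast)

  # -- pca -------------------------------------------------------------------
  multi <- build_multivariate_table(normalized, vocal, scheme = config$scheme)
  multi_z <- zscore_within_subject(multi)
  multi_full <- impute_similar_case(multi_z)
  n_imputed <- sum(multi_full$imputed)
  if (n_imputed > 0) {
    warnings <- c(warnings, paste0(n_imputed, " cell(s) imputed"))
  }
  pca <- pca_varimax(multi_full, k = k)
  paths$pca_loadings <- file.path(out_dir, "pca_loadings.csv")
  write_feature_table(tidy(pca), paths$pca_loadings)
  paths$pca_condition_scores <- file.path(out_dir, "pca_condition_scores.csv")
  write_feature_table(pca$condition_scores, paths$pca_condition_scores)
  paths$scree <- file.path(out_dir, "scree.csv")
  write_feature_table(pca$scree, paths$scree)

  report <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "seed")]),
    alpha = alpha,
    bonferroni_alpha = attr(suite_char, "alpha_corrected"),
    counts = list(
      trials = nrow(manifest),
      feature_rows = nrow(features),
      normalized_rows = nrow(normalized),
      character_anova_rows = attr(suite_char, "n_obs"),
      emotion_anova_rows = attr(suite_emo, "n_obs"),
      multivariate_rows = nrow(dplyr::distinct(
        multi_full[c("subject_id", "condition")])),
      imputed_cells = n_imputed,
      outlier_flags = nrow(flags)
    ),
    outputs = paths,
    warnings = warnings
  )
  paths$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report$outputs <- paths
  invisible(report)
}

parse_pipeline_config <- function(config) {
  if (inherits(config, "facekin_sim_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("run_pipeline: config must be a sim_config, a list, or a YAML path")
  }
  manifest_path <- config$manifest
  vocal_path <- config$vocal_table
  config$manifest <- NULL
  config$vocal_table <- NULL
  if (!is.null(config$scheme) && !is.data.frame(config$scheme)) {
    sc <- config$scheme
    config$scheme <- tibble(
      name = names(sc),
      cooperativeness = vapply(sc, `[[`, "", 1),
      assertiveness = vapply(sc, `[[`, "", 2)
    )
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("run_pipeline: unknown config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  out <- do.call(sim_config, config)
  out$manifest_path <- manifest_path
  out$vocal_path <- vocal_path
  out
}
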