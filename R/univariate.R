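#' Bonferroni-corrected significance threshold
#'
#' Divides the family-wise alpha by the number of tests in the family; with
#' the four facial segments and alpha = .05 this gives the working threshold
#' of .0125.
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param n_tests number of tests in the family (>= 1).
#' @return Corrected per-test alpha.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("bonferroni_threshold: alpha must be in (0, 1)")
  }
  if (!is.numeric(n_tests) || n_tests < 1) {
    abort("bonferroni_threshold: n_tests must be >= 1")
  }
  alpha / n_tests
}

#' Mixed-effects repeated-measures ANOVA for one segment
#'
#' Fits the linear mixed-effects model
#' `response ~ factor_a * factor_b + (1 | subject)` by maximum likelihood
#' (lme4), with sum-to-zero contrasts, and derives type III F tests with
#' Satterthwaite denominator degrees of freedom (lmerTest). Effects are
#' ordered A, B, A:B. Marginal and conditional R-squared are computed from
#' the variance decomposition: fixed-effect variance over total, and fixed
#' plus random-intercept variance over total.
#'
#' @param data tibble containing the response, both factors and the subject
#'   column; factor columns should already carry sum-to-zero contrasts (as
#'   produced by [build_design_table()]).
#' @param response name of the response column (a segment's percent change).
#' @param factors length-2 character vector of within-subject factor names.
#' @param subject name of the subject grouping column.
#' @param alpha per-test significance threshold used for the `significant`
#'   flag (pass a Bonferroni-corrected value for families of segments).
#' @return A `facekin_anova` object: list with `table` (one row per effect:
#'   `effect`, `sumsq`, `meansq`, `num_df`, `den_df`, `statistic`, `p.value`,
#'   `significant`), `r2_marg`, `r2_cond`, `model`, plus metadata.
#' @export
fit_segment_model <- function(data, response, factors, subject = "subject_id",
                              alpha = 0.05) {
  stopifnot(length(factors) == 2)
  cols <- c(response, factors, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("fit_segment_model: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- as_tibble(data)[cols]
  d <- d[complete.cases(d), ]
  if (anyNA(d[[response]]) || nrow(d) == 0) {
    abort("fit_segment_model: no complete rows")
  }
  if (length(unique(d[[subject]])) < 2) {
    abort("fit_segment_model: need at least 2 subjects")
  }
  for (f in factors) {
    d[[f]] <- droplevels(factor(d[[f]]))
    if (nlevels(d[[f]]) < 2) {
      abort(paste0("fit_segment_model: factor '", f, "' has fewer than 2 levels"))
    }
    stats::contrasts(d[[f]]) <- contr.sum(nlevels(d[[f]]))
  }
  if (var(d[[response]]) == 0) {
    abort("fit_segment_model: response has zero variance (degenerate model)")
  }
  fml <- as.formula(paste0("`", response, "` ~ `", factors[1], "` * `",
                           factors[2], "` + (1 | `", subject, "`)"))
  fit <- lmerTest::lmer(fml, data = d, REML = FALSE)
  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X)) {
    abort("fit_segment_model: rank-deficient fixed-effect design (aliased terms)")
  }
  at <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  eff <- rownames(at)
  # normalise lmerTest's backtick-quoted effect labels
  eff <- gsub("`", "", eff, fixed = TRUE)
  tab <- tibble(
    effect = eff,
    sumsq = at$`Sum Sq`,
    meansq = at$`Mean Sq`,
    num_df = at$NumDF,
    den_df = at$DenDF,
    statistic = at$`F value`,
    p.value = at$`Pr(>F)`
  )
  order_wanted <- c(factors[1], factors[2], paste0(factors[1], ":", factors[2]))
  tab <- tab[match(order_wanted, tab$effect), ]
  tab$significant <- tab$p.value < alpha
  r2 <- r_squared(fit)
  structure(list(table = tab, r2_marg = r2[["r2_marg"]],
                 r2_cond = r2[["r2_cond"]], model = fit,
                 response = response, factors = factors, alpha = alpha,
                 n_obs = nrow(d)),
            class = "facekin_anova")
}

#' Marginal and conditional R-squared of a random-intercept model
#'
#' Variance-decomposition R-squared for mixed models: the marginal value is
#' the variance of the fixed-effect predictions over the total (fixed +
#' random-intercept + residual) variance; the conditional value adds the
#' random-intercept variance to the numerator.
#'
#' @param model a fitted `merMod` (random intercept).
#' @return Named vector `r2_marg`, `r2_cond`.
#' @export
r_squared <- function(model) {
  if (!inherits(model, "merMod")) {
    abort("r_squared: model must be a fitted merMod")
  }
  var_fix <- var(as.vector(lme4::getME(model, "X") %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  var_ran <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_res <- attr(vc, "sc")^2
  tot <- var_fix + var_ran + var_res
  c(r2_marg = var_fix / tot, r2_cond = (var_fix + var_ran) / tot)
}

#' Estimated marginal means of the fixed effects
#'
#' Means of the fixed-effect predictions over the full factor grid, averaged
#' over the other factor — the values behind segment-by-level profile plots.
#'
#' @param object a `facekin_anova` fit.
#' @return Tibble `factor`, `level`, `emmean`.
#' @export
marginal_means <- function(object) {
  stopifnot(inherits(object, "facekin_anova"))
  fit <- object$model
  fr <- lme4::getME(fit, "X")
  mf <- stats::model.frame(fit)
  fA <- object$factors[1]; fB <- object$factors[2]
  grid <- expand.grid(levels(mf[[fA]]), levels(mf[[fB]]),
                      stringsAsFactors = FALSE)
  names(grid) <- c(fA, fB)
  for (f in c(fA, fB)) {
    grid[[f]] <- factor(grid[[f]], levels = levels(mf[[f]]))
    stats::contrasts(grid[[f]]) <- contr.sum(nlevels(grid[[f]]))
  }
  tt <- stats::delete.response(stats::terms(fit, fixed.only = TRUE))
  Xg <- stats::model.matrix(tt, grid)
  grid$pred <- as.vector(Xg %*% lme4::fixef(fit))
  dplyr::bind_rows(
    grid |> dplyr::group_by(level = .data[[fA]]) |>
      dplyr::summarise(emmean = mean(.data$pred), .groups = "drop") |>
      dplyr::mutate(factor = fA, .before = 1),
    grid |> dplyr::group_by(level = .data[[fB]]) |>
      dplyr::summarise(emmean = mean(.data$pred), .groups = "drop") |>
      dplyr::mutate(factor = fB, .before = 1)
  )
}

#' Run the univariate ANOVA suite over segments
#'
#' Joins a normalised feature table with design coordinates and fits the
#' mixed-model repeated-measures ANOVA for every segment, for either the
#' character factors (cooperativeness, assertiveness) or the emotion factors
#' (valence, arousal). Baseline and control-self rows never enter; the
#' emotion suite uses only the eight non-neutral emotions. Significance flags
#' use the Bonferroni-corrected threshold `alpha / n_segments`.
#'
#' @param normalized long normalised table (`subject_id`, `condition`,
#'   `segment`, `pct_change`) from [normalize_cohort()].
#' @param design design table from [build_design_table()] (only
#'   `subject_id`/`condition`/factor columns are used).
#' @param set `"character"` or `"emotion"`.
#' @param segments segments to analyse (default: all in the table).
#' @param alpha family-wise alpha before correction (default 0.05).
#' @return A `facekin_anova_suite`: named list of `facekin_anova` objects
#'   with attributes `set`, `alpha_corrected`, `n_obs`.
#' @export
run_univariate_suite <- function(normalized, design,
                                 set = c("character", "emotion"),
                                 segments = NULL, alpha = 0.05) {
  set <- match.arg(set)
  factors <- if (set == "character") c("cooperativeness", "assertiveness")
             else c("valence", "arousal")
  dd <- dplyr::distinct(design[c("subject_id", "condition", "kind", factors)])
  dd$subject_id <- as.character(dd$subject_id)
  joined <- dplyr::inner_join(normalized, dd,
                              by = c("subject_id", "condition"))
  joined <- joined[joined$kind == set, ]
  if (is.null(segments)) segments <- unique(joined$segment)
  alpha_c <- bonferroni_threshold(alpha, length(segments))
  fits <- list()
  for (seg in segments) {
    d <- joined[joined$segment == seg, ]
    wide <- tidyr::pivot_wider(d, names_from = "segment",
                               values_from = "pct_change")
    fits[[seg]] <- tryCatch(
      fit_segment_model(wide, response = seg, factors = factors,
                        subject = "subject_id", alpha = alpha_c),
      error = function(e) e
    )
  }
  failed <- names(fits)[vapply(fits, inherits, TRUE, what = "error")]
  if (length(failed) > 0) {
    warn(paste0("run_univariate_suite: fit failed for segment(s): ",
                paste(failed, collapse = ", ")))
  }
  structure(fits, class = "facekin_anova_suite", set = set,
            alpha = alpha, alpha_corrected = alpha_c,
            n_obs = nrow(dplyr::distinct(joined[c("subject_id", "condition")])))
}
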