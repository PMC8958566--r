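#' Within-subject z-scoring
#'
#' Standardises every parameter within each subject across that subject's
#' conditions (mean 0, SD 1), putting facial percent-change scores and
#' heterogeneous vocal parameters on one scale before the multivariate
#' analysis. Missing values are ignored in the mean/SD and left missing.
#'
#' @param table tidy table `subject_id`, `condition`, `parameter`, `value`.
#' @return Same shape, with `value` replaced by its within-subject z-score.
#' @export
zscore_within_subject <- function(table) {
  counts <- table |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$condition), .groups = "drop")
  few <- counts$subject_id[counts$n < 2]
  if (length(few) > 0) {
    abort(paste0("zscore_within_subject: subject(s) with < 2 conditions: ",
                 paste(few, collapse = ", ")))
  }
  out <- table |>
    dplyr::group_by(.data$subject_id, .data$parameter) |>
    dplyr::mutate(.sd = sd(.data$value, na.rm = TRUE),
                  .mu = mean(.data$value, na.rm = TRUE)) |>
    dplyr::ungroup()
  bad <- out[!is.na(out$.sd) & out$.sd == 0, ]
  if (nrow(bad) > 0) {
    bad <- dplyr::distinct(bad[c("subject_id", "parameter")])
    abort(paste0("zscore_within_subject: zero within-subject variance for: ",
                 paste(paste0("(", bad$subject_id, ", ", bad$parameter, ")"),
                       collapse = ", ")))
  }
  out$value <- (out$value - out$.mu) / out$.sd
  out[setdiff(names(out), c(".sd", ".mu"))]
}

#' Similar-case imputation of missing cells
#'
#' Fills each missing (subject, condition, parameter) value with the mean of
#' that parameter in the same condition across the other subjects — the
#' "similar cases". Intended to run after within-subject z-scoring, so donor
#' values are on a common scale. Imputed cells are flagged.
#'
#' @param table tidy table `subject_id`, `condition`, `parameter`, `value`,
#'   possibly with `NA` values or absent rows for some cells of the full
#'   subject x condition x parameter grid.
#' @return Completed table with an `imputed` logical column.
#' @export
impute_similar_case <- function(table) {
  full <- tidyr::expand_grid(
    subject_id = unique(table$subject_id),
    condition = unique(table$condition),
    parameter = unique(table$parameter)
  )
  out <- dplyr::left_join(full, table,
                          by = c("subject_id", "condition", "parameter"))
  out$imputed <- is.na(out$value)
  donors <- out |>
    dplyr::filter(!.data$imputed) |>
    dplyr::group_by(.data$condition, .data$parameter) |>
    dplyr::summarise(.donor = mean(.data$value), .groups = "drop")
  out <- dplyr::left_join(out, donors, by = c("condition", "parameter"))
  no_donor <- out[out$imputed & is.na(out$.donor), ]
  if (nrow(no_donor) > 0) {
    abort(paste0("impute_similar_case: no donor for cell(s): ",
                 paste(paste0("(", no_donor$subject_id, ", ",
                              no_donor$condition, ", ", no_donor$parameter, ")"),
                       collapse = ", ")))
  }
  out$value[out$imputed] <- out$.donor[out$imputed]
  out[setdiff(names(out), ".donor")]
}

#' Component-retention diagnostics
#'
#' Given the eigenvalues of the correlation-scale decomposition, reports the
#' Kaiser count (eigenvalues strictly greater than 1) and the scree data
#' (component index, eigenvalue, variance fraction) for elbow inspection.
#' The pipeline's retained k is a configuration choice (default 2).
#'
#' @param eigenvalues numeric vector, non-increasing.
#' @return List with `kaiser_k` and `scree` (a tibble).
#' @export
select_n_components <- function(eigenvalues) {
  if (length(eigenvalues) == 0) abort("select_n_components: empty input")
  if (any(diff(eigenvalues) > 1e-8)) {
    abort("select_n_components: eigenvalues must be in descending order")
  }
  list(
    kaiser_k = sum(eigenvalues > 1),
    scree = tibble(component = seq_along(eigenvalues),
                   eigenvalue = eigenvalues,
                   var_fraction = eigenvalues / sum(eigenvalues))
  )
}

#' Varimax-rotated principal component analysis
#'
#' Principal components of the parameter correlation matrix, with the first
#' `k` loading columns (eigenvectors scaled by the square roots of their
#' eigenvalues) rotated by the varimax criterion (orthogonal, raw criterion
#' without Kaiser row normalisation, so the rotation maximises the plain
#' variance of squared loadings). Rotation preserves communalities and the
#' total variance explained by the retained block. Each rotated component is
#' sign-fixed so its largest-magnitude loading is positive. Component scores
#' are standardised scores rotated by the same orthogonal matrix; condition
#' scores are the per-condition means over subjects.
#'
#' @param table complete tidy table `subject_id`, `condition`, `parameter`,
#'   `value` (typically z-scored and imputed).
#' @param k number of components to retain and rotate (default 2).
#' @return A `facekin_pca` object: list with `eigenvalues`, `kaiser_k`,
#'   `scree`, `loadings` (rotated, parameters x k), `unrotated` loadings,
#'   `rotmat`, `var_explained` (fraction per rotated component),
#'   `communality`, `scores` (per subject x condition), `condition_scores`
#'   (per-condition means), `n`, `parameters`.
#' @export
pca_varimax <- function(table, k = 2) {
  wide <- tidyr::pivot_wider(table[c("subject_id", "condition", "parameter", "value")],
                             names_from = "parameter", values_from = "value")
  params <- setdiff(names(wide), c("subject_id", "condition"))
  X <- as.matrix(wide[params])
  if (anyNA(X)) {
    abort("pca_varimax: table has missing values; impute first")
  }
  p <- ncol(X)
  if (k < 1 || k > p) {
    abort(paste0("pca_varimax: k must be between 1 and ", p))
  }
  Xs <- scale(X)  # correlation-scale decomposition
  R <- stats::cor(X)
  ei <- eigen(R, symmetric = TRUE)
  ev <- ei$values
  V <- ei$vectors
  load_full <- V %*% diag(sqrt(pmax(ev, 0)), p, p)
  rownames(load_full) <- params
  Lk <- load_full[, seq_len(k), drop = FALSE]
  if (k > 1) {
    vm <- varimax(Lk, normalize = FALSE, eps = 1e-10)
    Lrot <- unclass(vm$loadings)
    rot <- vm$rotmat
  } else {
    Lrot <- Lk
    rot <- diag(1)
  }
  # sign convention: largest |loading| of each component is positive
  flips <- vapply(seq_len(k), function(j) {
    sign(Lrot[which.max(abs(Lrot[, j])), j])
  }, numeric(1))
  flips[flips == 0] <- 1
  Lrot <- sweep(Lrot, 2, flips, `*`)
  rot <- sweep(rot, 2, flips, `*`)
  colnames(Lrot) <- paste0("RC", seq_len(k))
  # standardised unrotated scores, then the same orthogonal rotation
  scores_un <- Xs %*% V[, seq_len(k), drop = FALSE] %*%
    diag(1 / sqrt(ev[seq_len(k)]), k, k)
  scores <- scores_un %*% rot
  colnames(scores) <- colnames(Lrot)
  scores_tbl <- dplyr::bind_cols(wide[c("subject_id", "condition")],
                                 as_tibble(scores))
  cond_scores <- scores_tbl |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("RC"), mean),
                     .groups = "drop")
  sel <- select_n_components(ev)
  structure(list(
    eigenvalues = ev,
    kaiser_k = sel$kaiser_k,
    scree = sel$scree,
    loadings = Lrot,
    unrotated = Lk,
    rotmat = rot,
    var_explained = colSums(Lrot^2) / p,
    communality = rowSums(Lrot^2),
    scores = scores_tbl,
    condition_scores = cond_scores,
    n = nrow(X),
    parameters = params,
    k = k
  ), class = "facekin_pca")
}

#' Loading-magnitude band labels
#'
#' Classifies loading magnitudes into the descriptive bands used when
#' interpreting rotated components: below 0.35 "below threshold", 0.35-0.49
#' "moderately low", 0.50-0.59 "moderate", 0.60-0.79 "strong", 0.80 and
#' above "very strong". Sign is ignored; |value| must not exceed 1.
#'
#' @param value numeric vector of loadings.
#' @return Character vector of band labels.
#' @export
classify_loading <- function(value) {
  if (any(abs(value) > 1 + 1e-12, na.rm = TRUE)) {
    abort("classify_loading: |value| must be <= 1")
  }
  a <- abs(value)
  dplyr::case_when(
    a >= 0.80 ~ "very strong",
    a >= 0.60 ~ "strong",
    a >= 0.50 ~ "moderate",
    a >= 0.35 ~ "moderately low",
    TRUE ~ "below threshold"
  )
}

#' Assemble the combined face-voice multivariate table
#'
#' Binds the facial percent-change scores and the vocal parameter table into
#' one tidy (subject, condition, parameter, value) table over the conditions
#' entering the multivariate analysis (by default the nine characters plus
#' all nine emotions including neutral; control-self is excluded). Neutral
#' facial rows, absent from the normalised table because they are 0 by
#' construction, are filled in as exact zeros.
#'
#' @param normalized normalised facial table.
#' @param vocal tidy vocal table (`subject_id`, `condition`, `parameter`,
#'   `value`).
#' @param conditions conditions to include (default: characters in `scheme`
#'   plus the nine emotions).
#' @param scheme character scheme used for the default condition set.
#' @return Tidy combined table.
#' @export
build_multivariate_table <- function(normalized, vocal, conditions = NULL,
                                     scheme = default_character_scheme()) {
  if (is.null(conditions)) {
    conditions <- c(scheme$name, emotion_names(TRUE))
  }
  face <- normalized[normalized$condition %in% conditions,
                     c("subject_id", "condition", "segment", "pct_change")]
  names(face)[3:4] <- c("parameter", "value")
  if ("neutral" %in% conditions && !"neutral" %in% face$condition) {
    zero <- tidyr::expand_grid(subject_id = unique(face$subject_id),
                               condition = "neutral",
                               parameter = unique(face$parameter),
                               value = 0)
    face <- dplyr::bind_rows(face, zero)
  }
  voc <- vocal[vocal$condition %in% conditions,
               c("subject_id", "condition", "parameter", "value")]
  dplyr::bind_rows(face, voc)
}
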