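#' Tidy and glance methods
#'
#' `tidy()` on a `facekin_anova` returns the effect table (one row per
#' effect); on a `facekin_anova_suite` it stacks the per-segment tables with
#' a `segment` column; on a `facekin_pca` it returns the rotated loadings in
#' long form with magnitude band labels. `glance()` returns one-row model
#' summaries (R-squared for fits, variance shares for the PCA).
#'
#' @param x object to tidy.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.facekin_anova <- function(x, ...) {
  x$table
}

#' @rdname tidy.facekin_anova
#' @export
glance.facekin_anova <- function(x, ...) {
  tibble(r2_marg = x$r2_marg, r2_cond = x$r2_cond,
         n_obs = x$n_obs, alpha = x$alpha)
}

#' @rdname tidy.facekin_anova
#' @export
tidy.facekin_anova_suite <- function(x, ...) {
  purrr::imap_dfr(as.list(x), function(fit, seg) {
    if (inherits(fit, "error")) {
      return(tibble(segment = seg, effect = NA_character_,
                    error = conditionMessage(fit)))
    }
    dplyr::mutate(dplyr::bind_cols(tidy(fit), glance(fit)[c("r2_marg", "r2_cond")]),
                  segment = seg, .before = 1)
  })
}

#' @rdname tidy.facekin_anova
#' @export
glance.facekin_anova_suite <- function(x, ...) {
  tibble(set = attr(x, "set"), n_segments = length(x),
         alpha = attr(x, "alpha"),
         alpha_corrected = attr(x, "alpha_corrected"),
         n_obs = attr(x, "n_obs"))
}

#' @rdname tidy.facekin_anova
#' @export
tidy.facekin_pca <- function(x, ...) {
  ld <- as_tibble(x$loadings)
  ld$parameter <- rownames(x$loadings)
  long <- tidyr::pivot_longer(ld, cols = -"parameter",
                              names_to = "component", values_to = "loading")
  long$band <- classify_loading(pmin(1, pmax(-1, long$loading)))
  long
}

#' @rdname tidy.facekin_anova
#' @export
glance.facekin_pca <- function(x, ...) {
  out <- tibble(n = x$n, n_parameters = length(x$parameters),
                k = x$k, kaiser_k = x$kaiser_k,
                total_var_explained = sum(x$var_explained))
  for (j in seq_len(x$k)) {
    out[[paste0("var_RC", j)]] <- x$var_explained[j]
  }
  out
}

#' @export
print.facekin_anova <- function(x, ...) {
  cat("Mixed-effects RM-ANOVA:", x$response, "~",
      paste(x$factors, collapse = " * "), "+ (1 | subject)\n")
  print(x$table)
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f; n = %d; alpha = %g\n",
              x$r2_marg, x$r2_cond, x$n_obs, x$alpha))
  invisible(x)
}

#' @export
print.facekin_pca <- function(x, ...) {
  cat(sprintf("Varimax-rotated PCA: %d parameters, %d rows, k = %d (Kaiser k = %d)\n",
              length(x$parameters), x$n, x$k, x$kaiser_k))
  cat(sprintf("Variance explained: %s (total %.1f%%)\n",
              paste(sprintf("%s %.1f%%", colnames(x$loadings),
                            100 * x$var_explained), collapse = ", "),
              100 * sum(x$var_explained)))
  print(round(x$loadings, 2))
  invisible(x)
}
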