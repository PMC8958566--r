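#' Plot estimated marginal means by factor level
#'
#' Profile plot of each segment's estimated marginal mean percent change
#' across the levels of the design factors (the data behind
#' cooperativeness/valence and assertiveness/arousal segment figures).
#'
#' @param suite a `facekin_anova_suite`.
#' @return A ggplot object.
#' @export
plot_segment_means <- function(suite) {
  emm <- purrr::imap_dfr(as.list(suite), function(f, seg) {
    dplyr::mutate(marginal_means(f), segment = seg)
  })
  ggplot2::ggplot(emm, ggplot2::aes(x = .data$level, y = .data$emmean,
                                    group = .data$segment,
                                    colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = "factor level", y = "% change vs neutral",
                  colour = "segment") +
    ggplot2::theme_minimal()
}

#' Scree plot of a rotated PCA
#'
#' Eigenvalues by component with the Kaiser line at 1.
#'
#' @param pca a `facekin_pca`.
#' @return A ggplot object.
#' @export
plot_scree <- function(pca) {
  ggplot2::ggplot(pca$scree, ggplot2::aes(x = .data$component,
                                          y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "component", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' Condition map in rotated component space
#'
#' Per-condition mean scores on the first two rotated components, coloured
#' by condition kind (characters vs emotions), the view in which characters
#' sit inside the emotion space near their intuitive emotion partners.
#'
#' @param object a `facekin_pca`.
#' @param scheme character scheme used to label kinds.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.facekin_pca <- function(object, scheme = default_character_scheme(),
                                 ...) {
  cs <- object$condition_scores
  cs$kind <- ifelse(cs$condition %in% scheme$name, "character", "emotion")
  rc <- colnames(object$loadings)[seq_len(min(2, object$k))]
  if (length(rc) < 2) {
    abort("autoplot.facekin_pca: need at least 2 rotated components")
  }
  ggplot2::ggplot(cs, ggplot2::aes(x = .data[[rc[2]]], y = .data[[rc[1]]],
                                   colour = .data$kind,
                                   label = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = paste0(rc[2], " (quality)"),
                  y = paste0(rc[1], " (intensity)")) +
    ggplot2::theme_minimal()
}
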