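#' Plot a permutation-importance report
#'
#' Box plots of the per-trial importance scores of the top-ranked properties,
#' ordered by decreasing mean score.
#'
#' @param object A `vim_report`.
#' @param top_n How many top-ranked properties to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vim_report <- function(object, top_n = 50, ...) {
  keep <- dplyr::arrange(object$summary, .data$rank)$accession
  keep <- keep[seq_len(min(top_n, length(keep)))]
  df <- tidy(object, trials = TRUE) |>
    dplyr::filter(.data$accession %in% keep) |>
    dplyr::mutate(accession = factor(.data$accession, levels = keep))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accession, y = .data$vim)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "permutation importance (OOB count units)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot a nested-selection error curve
#'
#' Per-step distribution of out-of-bag error percentages with the acceptance
#' threshold drawn as a horizontal line; the selected prefix is shaded.
#'
#' @param object A `nested_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nested_selection <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(object$step_errors,
                  selected = .data$k <= length(object$selected)),
    "errors"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k), y = .data$errors,
                                   fill = .data$selected)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$threshold_pct, colour = "red") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey55", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "properties in nested model",
                  y = "OOB error (%) over 20 residues") +
    ggplot2::theme_minimal()
}

#' Plot PCA scores coloured by family
#'
#' @param object A `bpp_pca`.
#' @param components Which two components to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bpp_pca <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  if (!all(pcs %in% names(object$scores))) {
    rlang::abort("requested components not present in scores")
  }
  vf <- 100 * object$variance_fraction[components]
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                               colour = .data$family)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = sprintf("%s (%.2f%%)", pcs[1], vf[1]),
      y = sprintf("%s (%.2f%%)", pcs[2], vf[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot an encoding comparison side by side
#'
#' Score scatter of both encodings' first two components, faceted by scheme,
#' with the PC1+PC2 variance percentage in the facet label.
#'
#' @param object An `encoding_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.encoding_comparison <- function(object, ...) {
  df <- purrr::imap_dfr(object$pca, function(fit, scheme) {
    pct <- object$summary$pc12_pct[object$summary$scheme == scheme]
    dplyr::mutate(fit$scores[, c("id", "family", "PC1", "PC2")],
                  scheme = sprintf("%s (PC1+PC2 = %.2f%%)", scheme, pct))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$family)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~scheme, scales = "free") +
    ggplot2::theme_minimal()
}
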