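#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a permutation-importance report
#'
#' @param x A `vim_report` from [permutation_vim()].
#' @param trials If `TRUE`, return one row per (trial, property) score
#'   instead of the per-property summary.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vim_report <- function(x, trials = FALSE, ...) {
  if (!trials) {
    return(dplyr::arrange(x$summary, .data$rank))
  }
  tibble::as_tibble(x$trials) |>
    dplyr::mutate(trial = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"trial", names_to = "accession", values_to = "vim")
}

#' @rdname tidy.vim_report
#' @export
glance.vim_report <- function(x, ...) {
  tibble::tibble(
    n_properties = ncol(x$trials),
    n_trials = nrow(x$trials),
    ntree = x$config$ntree,
    scheme = x$scheme_name,
    n_positive_mean = sum(x$summary$mean_vim > 0)
  )
}

#' Tidy a nested-selection result
#'
#' @param x A `nested_selection` from [nested_selection()].
#' @param ... Unused.
#' @return One row per nested step: `k`, `accession_added`, `mean_error`,
#'   `sd_error`, `selected` flag.
#' @export
tidy.nested_selection <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$step_errors, -"errors"),
    selected = .data$k <= length(x$selected)
  )
}

#' @rdname tidy.nested_selection
#' @export
glance.nested_selection <- function(x, ...) {
  tibble::tibble(
    n_ranked = length(x$ranked_properties),
    n_selected = length(x$selected),
    threshold_pct = x$threshold_pct,
    min_mean_error = min(x$step_errors$mean_error),
    scheme = x$scheme_name
  )
}

#' Tidy a reduction-pipeline result
#'
#' @param x A `bpp_reduction` from [reduce_pipeline()].
#' @param ... Unused.
#' @return The per-stage count table.
#' @export
tidy.bpp_reduction <- function(x, ...) x$stages

#' @rdname tidy.bpp_reduction
#' @export
glance.bpp_reduction <- function(x, ...) {
  tibble::tibble(
    n_input = x$stages$n_in[1],
    n_selected = length(x$selected),
    threshold_pct = x$selection$threshold_pct,
    scheme = x$scheme_name
  )
}

#' Tidy a PCA result
#'
#' @param x A `bpp_pca` from [run_pca()].
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in the requested shape.
#' @export
tidy.bpp_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                         ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble::tibble(
      component = seq_along(x$variance_fraction),
      variance_fraction = x$variance_fraction,
      cumulative = cumsum(x$variance_fraction)
    )
  )
}

#' @rdname tidy.bpp_pca
#' @export
glance.bpp_pca <- function(x, ...) {
  vf <- x$variance_fraction
  tibble::tibble(
    n = x$n, p = x$p,
    n_dropped_columns = length(x$dropped_columns),
    pc1_fraction = vf[1],
    pc12_fraction = sum(vf[seq_len(min(2, length(vf)))])
  )
}

#' Tidy an encoding-comparison report
#'
#' @param x An `encoding_comparison` from [compare_encodings()].
#' @param ... Unused.
#' @return The per-scheme variance summary.
#' @export
tidy.encoding_comparison <- function(x, ...) x$summary

#' @rdname tidy.encoding_comparison
#' @export
glance.encoding_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary[, c("scheme", "pc12_pct")],
                             names_from = "scheme", values_from = "pc12_pct")
  dplyr::mutate(wide, n_sequences = x$n_sequences,
                block_length = x$block_length,
                bpp_minus_binary8 = .data$bpp - .data$binary8)
}
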