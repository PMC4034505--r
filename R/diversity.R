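#' Principal component analysis of an encoded feature matrix
#'
#' Covariance (center-only) PCA: columns are mean-centered but not scaled to
#' unit variance, because binary feature matrices contain constant columns
#' (high-order bits) for which unit-variance scaling is undefined.
#' Zero-variance columns are dropped and listed.  Eigenvector signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is made positive, so results are reproducible across platforms.
#'
#' @param data A data frame with numeric feature columns; `id` and `family`
#'   columns, if present, are carried into the scores as metadata.
#' @param n_components Number of components to retain in scores/loadings
#'   (default: all).
#'
#' @return An object of class `bpp_pca`: list with `scores` (tibble: `id`,
#'   `family`, `PC1..PCK`), `loadings` (tibble: `column`, `PC1..PCK`),
#'   `variance_fraction` (over all components, summing to 1),
#'   `dropped_columns`, `n`, `p`, and the centering/scaling flags.
#' @export
run_pca <- function(data, n_components = NULL) {
  stopifnot(is.data.frame(data))
  meta_cols <- intersect(c("id", "family"), names(data))
  feat <- dplyr::select(tibble::as_tibble(data), -dplyr::any_of(meta_cols))
  if (!all(vapply(feat, is.numeric, logical(1)))) {
    rlang::abort("all feature columns must be numeric")
  }
  x <- as.matrix(feat)
  if (nrow(x) < 2) rlang::abort("PCA needs at least 2 rows")
  vars <- apply(x, 2, stats::var)
  dropped <- colnames(x)[vars == 0]
  x <- x[, vars > 0, drop = FALSE]
  if (ncol(x) == 0) {
    rlang::abort("all columns have zero variance; nothing to decompose")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  vfrac <- ev / sum(ev)
  k_all <- length(ev)
  k <- if (is.null(n_components)) k_all else min(as.integer(n_components), k_all)

  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  sco <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  scores <- dplyr::bind_cols(
    tibble::tibble(
      id = if ("id" %in% meta_cols) data$id else paste0("row", seq_len(nrow(x))),
      family = if ("family" %in% meta_cols) data$family else NA_character_
    ),
    tibble::as_tibble(sco)
  )
  loadings <- dplyr::bind_cols(tibble::tibble(column = rownames(rot)),
                               tibble::as_tibble(rot))
  structure(
    list(scores = scores, loadings = loadings, variance_fraction = vfrac,
         dropped_columns = dropped, n = nrow(x), p = ncol(x),
         center = TRUE, scale = FALSE),
    class = "bpp_pca"
  )
}

#' @export
print.bpp_pca <- function(x, ...) {
  cat("Covariance PCA:", x$n, "rows x", x$p, "columns (",
      length(x$dropped_columns), "zero-variance dropped )\n")
  k <- min(5, length(x$variance_fraction))
  cat("Variance fractions:",
      paste(formatC(x$variance_fraction[seq_len(k)], digits = 4,
                    format = "f"), collapse = " "),
      if (length(x$variance_fraction) > k) "..." else "", "\n")
  invisible(x)
}

#' Compare property and binary encodings of one sequence family set
#'
#' The head-to-head diversity analysis: extract the gap-free homologous
#' block, encode it once with the property table and once in 8-bit binary,
#' run covariance PCA on both, and report how much variance the first two
#' components of each capture, together with per-family score centroids.
#'
#' @param aln An alignment tibble (may contain gap columns).
#' @param table Index table for the property encoding; default [raaindex()].
#' @param max_gap_fraction Passed to [extract_block()].
#'
#' @return An object of class `encoding_comparison`: list with `summary`
#'   (tibble: `scheme`, `pc1_pct`, `pc2_pct`, `pc12_pct`), `centroids`
#'   (tibble: `scheme`, `family`, `PC1`, `PC2`), `pca` (list of the two
#'   `bpp_pca` fits), `n_sequences` and `block_length`.
#' @export
compare_encodings <- function(aln, table = raaindex(), max_gap_fraction = 0) {
  check_alignment(aln)
  aln <- dplyr::arrange(aln, .data$id)  # order-invariant reporting
  block <- extract_block(aln, max_gap_fraction)
  fits <- list(
    bpp = run_pca(encode_set(block, "bpp", table = table)),
    binary8 = run_pca(encode_set(block, "binary8"))
  )
  summary <- purrr::imap_dfr(fits, function(fit, scheme) {
    vf <- fit$variance_fraction
    tibble::tibble(
      scheme = scheme,
      pc1_pct = 100 * vf[1],
      pc2_pct = 100 * ifelse(length(vf) > 1, vf[2], 0),
      pc12_pct = 100 * sum(vf[seq_len(min(2, length(vf)))])
    )
  })
  centroids <- purrr::imap_dfr(fits, function(fit, scheme) {
    sc <- fit$scores
    if (all(is.na(sc$family))) return(tibble::tibble())
    sc |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(PC1 = mean(.data$PC1),
                       PC2 = if ("PC2" %in% names(sc)) mean(.data$PC2) else NA_real_,
                       .groups = "drop") |>
      dplyr::mutate(scheme = scheme, .before = 1)
  })
  structure(
    list(summary = summary, centroids = centroids, pca = fits,
         n_sequences = nrow(block),
         block_length = nchar(block$sequence[1])),
    class = "encoding_comparison"
  )
}

#' @export
print.encoding_comparison <- function(x, ...) {
  cat("Encoding comparison:", x$n_sequences, "sequences,",
      x$block_length, "residue block\n")
  print(x$summary)
  invisible(x)
}

#' Export PCA scores as TSV
#'
#' Writes one row per sequence: `id`, `family`, then the retained component
#' scores.
#'
#' @param result A `bpp_pca` from [run_pca()].
#' @param file Output TSV path.
#' @return The scores tibble, invisibly.
#' @export
export_scores <- function(result, file) {
  stopifnot(inherits(result, "bpp_pca"))
  readr::write_tsv(result$scores, file)
  invisible(result$scores)
}
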