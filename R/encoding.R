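#' Read an aligned FASTA file into an alignment tibble
#'
#' Sequences must all have the same (gapped) length; `.` gap characters are
#' normalized to `-`.  Family tags are metadata only: they are taken from a
#' `family=<tag>` token in the FASTA header, or from a sidecar
#' two-column TSV (`id`, `family`) given as `family_file`.
#'
#' @param file Path to an aligned FASTA file.
#' @param family_file Optional path to a TSV with columns `id` and `family`.
#'
#' @return An alignment tibble with columns `id`, `family` (possibly `NA`)
#'   and `sequence` (uppercase, gap `-`).
#' @export
read_alignment <- function(file, family_file = NULL) {
  seqs <- Biostrings::readAAStringSet(file)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1)
  fam <- stringr::str_match(headers, "family=(\\S+)")[, 2]
  aln <- tibble::tibble(
    id = ids,
    family = fam,
    sequence = toupper(chartr(".", "-", as.character(seqs)))
  )
  if (!is.null(family_file)) {
    tags <- readr::read_tsv(family_file, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    if (!all(c("id", "family") %in% names(tags))) {
      rlang::abort("`family_file` must have columns id and family")
    }
    aln$family <- tags$family[match(aln$id, tags$id)]
  }
  check_alignment(aln)
  aln
}

#' Write an alignment tibble as FASTA
#'
#' @param aln An alignment tibble (`id`, optional `family`, `sequence`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(aln, file) {
  check_alignment(aln)
  headers <- aln$id
  if ("family" %in% names(aln)) {
    has_fam <- !is.na(aln$family)
    headers[has_fam] <- paste0(aln$id[has_fam], " family=", aln$family[has_fam])
  }
  set <- Biostrings::AAStringSet(aln$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

check_alignment <- function(aln, arg = "aln") {
  if (!is.data.frame(aln) || !all(c("id", "sequence") %in% names(aln))) {
    rlang::abort(paste0("`", arg, "` must have columns id and sequence"))
  }
  if (nrow(aln) < 1) rlang::abort(paste0("`", arg, "` has no sequences"))
  if (anyDuplicated(aln$id)) rlang::abort(paste0("duplicate ids in `", arg, "`"))
  if (length(unique(nchar(aln$sequence))) != 1) {
    rlang::abort(paste0("sequences in `", arg, "` must all have equal length"))
  }
  invisible(aln)
}

aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
}

#' Extract the homologous (gap-free) block of an alignment
#'
#' Removes every column whose gap fraction exceeds `max_gap_fraction`.  With
#' the strict default of 0 the result contains no gaps at all; with a larger
#' tolerance, residual gaps in retained columns are imputed by the column's
#' majority residue (ties broken by canonical residue order) and the number
#' of imputations is recorded.
#'
#' @param aln An alignment tibble (see [read_alignment()]).
#' @param max_gap_fraction Maximum tolerated fraction of gaps per column,
#'   in `[0, 1)`; default 0.
#'
#' @return The gap-free alignment tibble.  Attributes: `"kept_columns"`
#'   (indices into the original columns) and `"n_imputed"`.
#' @export
extract_block <- function(aln, max_gap_fraction = 0) {
  check_alignment(aln)
  stopifnot(is.numeric(max_gap_fraction), max_gap_fraction >= 0,
            max_gap_fraction < 1)
  chars <- aln_char_matrix(aln)
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0) {
    rlang::abort("no alignment column survives the gap filter")
  }
  chars <- chars[, keep, drop = FALSE]
  n_imputed <- 0L
  if (any(chars == "-")) {
    for (j in seq_len(ncol(chars))) {
      gaps <- chars[, j] == "-"
      if (!any(gaps)) next
      resid <- chars[!gaps, j]
      counts <- table(factor(resid, levels = residue_order()))
      fill <- names(counts)[which.max(counts)]  # ties: first in canonical order
      chars[gaps, j] <- fill
      n_imputed <- n_imputed + sum(gaps)
    }
    message(n_imputed, " residual gap(s) imputed by column majority residue")
  }
  out <- aln
  out$sequence <- apply(chars, 1, paste, collapse = "")
  attr(out, "kept_columns") <- keep
  attr(out, "n_imputed") <- n_imputed
  out
}

split_residues <- function(seq, context = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    rlang::abort(paste0(context, " must be a non-empty string"))
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% residue_order())
  if (length(bad) > 0) {
    rlang::abort(paste0("cannot encode ", context, ": unknown residue '",
                        res[bad[1]], "' at position ", bad[1]))
  }
  res
}

#' Encode a sequence as a numeric property lattice
#'
#' Concatenates, from N- to C-terminus, each residue's row of property values
#' from an index table (columns in table order), yielding a vector of length
#' `L * m` for a sequence of length L and a table of m properties.
#'
#' @param seq A gap-free sequence string over the 20 standard residues.
#' @param table An index table; defaults to the packaged [raaindex()].
#'
#' @return A named numeric vector (`pos<i>_<accession>`).
#' @export
#' @examples
#' encode_bpp("A")[1]  # 0.18, the JACR890101 value of alanine
encode_bpp <- function(seq, table = raaindex()) {
  check_index_table(table)
  res <- split_residues(seq)
  mat <- index_matrix(table)
  out <- as.vector(t(mat[res, , drop = FALSE]))
  names(out) <- paste0(
    "pos", rep(seq_along(res), each = ncol(mat)), "_",
    rep(colnames(mat), length(res))
  )
  out
}

#' The 8-bit binary residue code
#'
#' Each residue maps to the big-endian 8-bit binary expansion of its ordinal
#' (0-19) in the canonical residue order, an injective code of the same
#' dimensionality per residue as the packaged reduced property table.
#'
#' @return A tibble with columns `residue`, `ordinal` and `b1`..`b8`
#'   (most significant bit first).
#' @export
binary8_codes <- function() {
  ords <- seq_along(residue_order()) - 1L
  bits <- t(vapply(ords, function(o) as.integer(intToBits(o))[8:1],
                   integer(8)))
  colnames(bits) <- paste0("b", 1:8)
  dplyr::bind_cols(
    tibble::tibble(residue = residue_order(), ordinal = ords),
    tibble::as_tibble(bits)
  )
}

#' Encode a sequence in 8-bit binary notation
#'
#' @param seq A gap-free sequence string over the 20 standard residues.
#' @return A named 0/1 numeric vector of length `8 * nchar(seq)`.
#' @seealso [binary8_codes()] for the bit table, [decode_binary8()] for the
#'   inverse.
#' @export
encode_binary8 <- function(seq) {
  res <- split_residues(seq)
  codes <- binary8_codes()
  bits <- as.matrix(codes[, paste0("b", 1:8)])
  rownames(bits) <- codes$residue
  out <- as.numeric(t(bits[res, , drop = FALSE]))
  names(out) <- paste0("pos", rep(seq_along(res), each = 8), "_b",
                       rep(1:8, length(res)))
  out
}

#' @rdname encode_binary8
#' @param bits A 0/1 vector of length divisible by 8, as produced by
#'   [encode_binary8()].
#' @return `decode_binary8()` returns the sequence string.
#' @export
decode_binary8 <- function(bits) {
  stopifnot(length(bits) %% 8 == 0, all(bits %in% c(0, 1)))
  mat <- matrix(as.integer(bits), ncol = 8, byrow = TRUE)
  ords <- as.vector(mat %*% 2^(7:0))
  if (any(ords > 19)) rlang::abort("bit pattern does not code a residue")
  paste(residue_order()[ords + 1], collapse = "")
}

#' Encode a gap-free alignment as a feature matrix
#'
#' One row per sequence, `id` and `family` carried through as metadata
#' columns, followed by the numeric feature lattice under the chosen scheme.
#'
#' @param aln A gap-free alignment tibble (run [extract_block()] first if
#'   needed).
#' @param scheme `"bpp"` (property encoding via `table`) or `"binary8"`.
#' @param table Index table for the `"bpp"` scheme; defaults to [raaindex()].
#' @param window,step Optional sliding-window fragmentation: when `window`
#'   is given, every sequence is cut into fragments of that length at starts
#'   `1, 1+step, ...` and each fragment becomes one encoded row (ids
#'   suffixed `_frag<k>`).  Off by default: rows are whole blocks.
#'
#' @return A tibble of class `encoded_tbl` with attributes `scheme`,
#'   `block_length` and `d` (features per residue).
#' @export
encode_set <- function(aln, scheme = c("bpp", "binary8"), table = NULL,
                       window = NULL, step = 1) {
  scheme <- match.arg(scheme)
  check_alignment(aln)
  if (any(grepl("-", aln$sequence, fixed = TRUE))) {
    rlang::abort("alignment contains gaps; run extract_block() first")
  }
  if (!is.null(window)) {
    len <- nchar(aln$sequence[1])
    window <- as.integer(window)
    step <- as.integer(step)
    if (window < 1 || window > len) {
      rlang::abort("`window` must be between 1 and the block length")
    }
    if (step < 1) rlang::abort("`step` must be a positive integer")
    starts <- seq(1L, len - window + 1L, by = step)
    aln <- tidyr::expand_grid(aln, start = starts) |>
      dplyr::mutate(
        id = paste0(.data$id, "_frag",
                    match(.data$start, starts)),
        sequence = substr(.data$sequence, .data$start,
                          .data$start + window - 1L)
      ) |>
      dplyr::select(-"start")
  }
  if (scheme == "bpp") {
    if (is.null(table)) table <- raaindex()
    check_index_table(table)
    rows <- lapply(aln$sequence, encode_bpp, table = table)
    d <- length(index_accessions(table))
  } else {
    rows <- lapply(aln$sequence, encode_binary8)
    d <- 8L
  }
  feat <- do.call(rbind, rows)
  out <- dplyr::bind_cols(
    tibble::tibble(
      id = aln$id,
      family = if ("family" %in% names(aln)) aln$family else NA_character_
    ),
    tibble::as_tibble(feat)
  )
  structure(out, scheme = scheme, block_length = nchar(aln$sequence[1]),
            d = d, class = c("encoded_tbl", class(out)))
}

#' Write / read an encoded feature matrix as TSV
#'
#' The TSV holds one row per sequence (`id`, `family`, features); a JSON
#' sidecar (`<file>.json`) records the scheme, block length and per-residue
#' dimensionality so the matrix can be re-read with its metadata.
#'
#' @param encoded An `encoded_tbl` from [encode_set()].
#' @param file Output TSV path.
#' @return `write_encoded()` returns `file` invisibly; `read_encoded()`
#'   returns the `encoded_tbl`.
#' @export
write_encoded <- function(encoded, file) {
  readr::write_tsv(tibble::as_tibble(encoded), file)
  meta <- list(scheme = attr(encoded, "scheme"),
               block_length = attr(encoded, "block_length"),
               d = attr(encoded, "d"))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(file) {
  out <- readr::read_tsv(file, col_types = readr::cols(
    id = "c", family = "c", .default = "d"
  ), progress = FALSE)
  meta_path <- paste0(file, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    structure(out, scheme = meta$scheme, block_length = meta$block_length,
              d = meta$d, class = c("encoded_tbl", class(out)))
  } else {
    out
  }
}
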