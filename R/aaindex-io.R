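#' Parse an AAindex1 flat file
#'
#' Reads amino-acid property records in the AAindex1 flat-file dialect:
#' records separated by `//`, with `H` (accession), `D` (description),
#' `R`/`A`/`T`/`J` (literature provenance), `C` (correlated accessions) and
#' `I` (index values) lines.  The two rows of ten values under the `I` line
#' follow the AAindex residue header (`A/L R/K N/M D/F C/P Q/S E/T G/W H/Y
#' I/V`), i.e. the canonical residue order split in two.  Literal `NA` tokens
#' become missing values.  Pair-substitution matrices (AAindex2/3 records
#' carrying an `M` line) are rejected.
#'
#' @param file Path to a flat file, or a length-one string containing
#'   flat-file text (distinguished by the presence of a newline), or a
#'   character vector of lines.
#'
#' @return A tibble with one row per record: `accession`, `description`,
#'   `provenance`, and one numeric column per residue (canonical order),
#'   possibly containing `NA`.
#' @seealso [as_index_table()] to assemble complete records into a property
#'   table, [raaindex()] for the packaged reduced table.
#' @export
read_aaindex <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (length(file) == 1) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(file)
  }
  lines <- sub("\r$", "", lines)

  # split into records on '//' terminator lines
  term <- grepl("^//", lines)
  rec_id <- cumsum(dplyr::lag(term, default = FALSE))
  keep <- !term & nzchar(trimws(lines))
  recs <- split(lines[keep], rec_id[keep])
  recs <- recs[vapply(recs, length, 1L) > 0]
  if (length(recs) == 0) {
    rlang::abort("no AAindex records found in input")
  }
  rows <- purrr::map(recs, parse_aaindex_record)
  dplyr::bind_rows(rows)
}

parse_aaindex_record <- function(rec) {
  tag <- substr(rec, 1, 1)
  # continuation lines start with whitespace and belong to the previous tag
  cont <- grepl("^\\s", rec)
  eff_tag <- tag
  for (i in seq_along(rec)) {
    if (cont[i] && i > 1) eff_tag[i] <- eff_tag[i - 1]
  }
  body <- trimws(substring(rec, 2))
  body[cont] <- trimws(rec[cont])

  get_field <- function(t) paste(body[eff_tag == t], collapse = " ")

  if (!any(eff_tag == "H")) {
    rlang::abort(paste0("malformed AAindex record (missing H line): '",
                        substr(rec[1], 1, 40), "'"))
  }
  accession <- strsplit(get_field("H"), "\\s+")[[1]][1]
  if (is.na(accession) || !nzchar(accession)) {
    rlang::abort("malformed AAindex record: empty accession on H line")
  }
  if (any(eff_tag == "M" & !cont)) {
    rlang::abort(paste0(
      "record ", accession,
      " is a pair-substitution matrix (AAindex2/3); only single-residue",
      " AAindex1 indices are supported"
    ))
  }
  i_pos <- which(eff_tag == "I" & !cont)
  if (length(i_pos) != 1) {
    rlang::abort(paste0("malformed AAindex record ", accession,
                        ": expected exactly one I line"))
  }
  value_lines <- which(eff_tag == "I" & cont)
  tokens <- unlist(strsplit(trimws(body[value_lines]), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) != 20) {
    rlang::abort(paste0("malformed AAindex record ", accession, ": expected 20",
                        " index values, found ", length(tokens)))
  }
  vals <- suppressWarnings(as.numeric(ifelse(tokens == "NA", NA, tokens)))
  bad <- which(!is.na(tokens) & tokens != "NA" & is.na(vals))
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed AAindex record ", accession,
                        ": non-numeric value '", tokens[bad[1]], "'"))
  }
  row <- tibble::tibble(
    accession = accession,
    description = get_field("D"),
    provenance = trimws(paste(get_field("A"), get_field("T"), get_field("J")))
  )
  values <- as.list(vals)
  names(values) <- aaindex_value_order()
  dplyr::bind_cols(row, tibble::as_tibble(values))
}

#' Assemble parsed property records into a complete index table
#'
#' Drops every property that has a missing value for any residue (the
#' preprocessing step applied to raw AAindex data before selection) and
#' pivots the survivors into a 20-residue by m-property table.
#'
#' @param properties A tibble as returned by [read_aaindex()]: one row per
#'   property with `accession` plus 20 residue columns.
#'
#' @return An index table: a tibble with a `residue` column (20 canonical
#'   rows) and one numeric, NA-free column per retained accession.  The
#'   accessions dropped for missing values are recorded in the
#'   `"dropped"` attribute, and a message reports their number.
#' @export
as_index_table <- function(properties) {
  stopifnot(is.data.frame(properties), "accession" %in% names(properties))
  res <- residue_order()
  if (!all(res %in% names(properties))) {
    rlang::abort("`properties` must have one column per residue (A..V)")
  }
  if (anyDuplicated(properties$accession)) {
    rlang::abort("duplicate accessions in property collection")
  }
  vals <- as.matrix(properties[, res, drop = FALSE])
  has_na <- apply(vals, 1, anyNA)
  dropped <- properties$accession[has_na]
  message(length(dropped), " propert", if (length(dropped) == 1) "y" else "ies",
          " dropped for missing values")
  if (all(has_na)) {
    rlang::abort("no complete properties remain after dropping missing values")
  }
  kept <- properties[!has_na, , drop = FALSE]
  mat <- t(as.matrix(kept[, res, drop = FALSE]))
  colnames(mat) <- kept$accession
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble::tibble(residue = res), out)
  attr(out, "dropped") <- dropped
  out
}

# validate the index-table contract used across the package
check_index_table <- function(table, arg = "table") {
  if (!is.data.frame(table) || !"residue" %in% names(table)) {
    rlang::abort(paste0("`", arg, "` must be an index table with a residue column"))
  }
  if (nrow(table) != 20 || !identical(as.character(table$residue), residue_order())) {
    rlang::abort(paste0("`", arg, "` must have exactly the 20 canonical residue rows"))
  }
  acc <- index_accessions(table)
  if (length(acc) < 1) {
    rlang::abort(paste0("`", arg, "` has no property columns"))
  }
  mat <- index_matrix(table)
  if (anyNA(mat)) {
    rlang::abort(paste0("`", arg, "` contains missing values; drop incomplete",
                        " properties with as_index_table() first"))
  }
  invisible(table)
}

index_accessions <- function(table) setdiff(names(table), "residue")

# 20 x m numeric matrix, rows in canonical residue order
index_matrix <- function(table) {
  acc <- index_accessions(table)
  mat <- as.matrix(as.data.frame(table[, acc, drop = FALSE]))
  rownames(mat) <- as.character(table$residue)
  storage.mode(mat) <- "double"
  mat
}

#' The packaged reduced amino-acid index (rAAindex)
#'
#' Returns the packaged eight-property reduced index table: for each of the
#' 20 residues, the values of the eight AAindex accessions JACR890101,
#' COWR900101, ZIMJ680103, MEEJ810102, FAUJ880110, WARP780101, PONP800108
#' and LIFS790102 retained by random-forest selection.  The table is read
#' from the package's data file and is identical across calls.
#'
#' @return An index table tibble (20 rows, `residue` plus 8 numeric columns).
#' @seealso [raaindex_annotations()] for the accession descriptions,
#'   [encode_bpp()] to encode sequences with it.
#' @export
#' @examples
#' raaindex()
raaindex <- function() {
  path <- system.file("extdata", "raaindex.tsv", package = "raaindex",
                      mustWork = TRUE)
  read_index_table(path)
}

#' Annotations of the packaged rAAindex accessions
#'
#' Published annotation listings disagree on the description strings of these
#' eight accessions, so two variants are carried verbatim (`description` and
#' `description_alt`); the accession itself is the authoritative identifier.
#'
#' @return A tibble with columns `accession`, `description`,
#'   `description_alt`.
#' @export
raaindex_annotations <- function() {
  tibble::tribble(
    ~accession, ~description, ~description_alt,
    "JACR890101", "Number of full nonbonding orbitals (Fauchere et al., 1988)",
    "Normalized hydrophobicity scales for alpha/beta-proteins (Cid et al., 1992)",
    "COWR900101", "Conformational preference for parallel beta-strands (Lifson-Sander, 1979)",
    "Consensus normalized hydrophobicity scale (Eisenberg, 1984)",
    "ZIMJ680103", "Retention coefficient in NaH2PO4 (Meek-Rossetti, 1981)",
    "Polarity (Grantham, 1974)",
    "MEEJ810102", "Average number of surrounding residues (Ponnuswamy et al., 1980)",
    "Hydration number (Hopfinger, 1971), Cited by Charton-Charton (1982)",
    "FAUJ880110", "Polarity (Zimmerman et al., 1968)",
    "Conformational preference for parallel beta-strands (Lifson-Sander, 1979)",
    "WARP780101", "Average interactions per side chain atom (Warme-Morgan, 1978)",
    "Retention coefficient in NaClO4 (Meek-Rossetti, 1981)",
    "PONP800108", "Weights from the IFH scale (Jacobs-White, 1989)",
    "Average number of surrounding residues (Ponnuswamy et al., 1980)",
    "LIFS790102", "Hydrophobicity index, 3.0 pH (Cowan-Whittaker, 1990)",
    "Transfer-free energy from chx to oct (Radzicka-Wolfenden, 1988)"
  )
}

#' Write / read an index table as TSV
#'
#' Tab-separated text with a `residue` column and one column per accession.
#' `read_index_table(write_index_table(x, f))` reproduces `x` exactly to the
#' printed precision.
#'
#' @param table An index table (see [as_index_table()]).
#' @param file Path to write to / read from.
#' @return `write_index_table()` returns `file` invisibly;
#'   `read_index_table()` returns the index table tibble.
#' @export
write_index_table <- function(table, file) {
  if (!is.data.frame(table) || !"residue" %in% names(table)) {
    rlang::abort("`table` must be an index table with a residue column")
  }
  readr::write_tsv(table, file)
  invisible(file)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(file) {
  out <- readr::read_tsv(file, col_types = readr::cols(
    residue = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (length(index_accessions(out)) > 0) check_index_table(out, "file")
  out
}

#' Render an index table in the AAindex1 flat-file dialect
#'
#' The inverse convenience of [read_aaindex()]: one record per property with
#' `H`, `D` and `I` lines and the two standard rows of ten values.
#'
#' @param table An index table.
#' @param descriptions Optional named character vector of descriptions,
#'   indexed by accession.
#' @return A single string of flat-file text.
#' @export
format_aaindex <- function(table, descriptions = NULL) {
  check_index_table(table)
  mat <- index_matrix(table)
  recs <- vapply(index_accessions(table), function(acc) {
    v <- formatC(mat[, acc], format = "g", digits = 7)
    desc <- if (!is.null(descriptions) && acc %in% names(descriptions)) {
      descriptions[[acc]]
    } else ""
    paste(
      paste0("H ", acc),
      paste0("D ", desc),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("    ", paste(v[1:10], collapse = "  ")),
      paste0("    ", paste(v[11:20], collapse = "  ")),
      "//",
      sep = "\n"
    )
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}
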