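#' Canonical residue order
#'
#' The 20 standard amino acids in the canonical row order used throughout the
#' package (Ala, Arg, Asn, Asp, Cys, Gln, Glu, Gly, His, Ile, Leu, Lys, Met,
#' Phe, Pro, Ser, Thr, Trp, Tyr, Val).  All property tables, encodings and
#' binary codes index residues in this order.
#'
#' @return A character vector of 20 one-letter residue codes.
#' @export
#' @examples
#' residue_order()
residue_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# AAindex flat files print values in two rows of ten under the I line, with
# the header A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V: first row = first ten
# residues of the canonical order, second row = last ten.
aaindex_value_order <- function() residue_order()

#' Hydropathy class labels for the 20 residues
#'
#' Binary hydrophobic/hydrophilic labels used as the response variable in
#' random-forest property selection.  The default `"kyte_doolittle"` scheme
#' labels as hydrophobic the seven residues with positive Kyte-Doolittle
#' hydropathy (A, C, F, I, L, M, V) and the remaining thirteen as
#' hydrophilic.  A custom scheme may be supplied as a data frame with columns
#' `residue` and `class`; it must cover all 20 residues and use both classes.
#'
#' @param scheme Either the string `"kyte_doolittle"` or a data frame with
#'   columns `residue` and `class` (values `"hydrophobic"`/`"hydrophilic"`).
#' @param scheme_name Name recorded in reports when `scheme` is a data frame.
#'
#' @return A tibble with columns `residue` and `class` (factor with levels
#'   `hydrophilic`, `hydrophobic`), ordered canonically, with attribute
#'   `scheme_name`.
#' @export
#' @examples
#' hydropathy_labels()
hydropathy_labels <- function(scheme = "kyte_doolittle",
                              scheme_name = "custom") {
  if (is.character(scheme) && length(scheme) == 1) {
    if (!identical(scheme, "kyte_doolittle")) {
      rlang::abort(paste0("unknown labelling scheme: '", scheme, "'"))
    }
    hydrophobic <- c("A", "C", "F", "I", "L", "M", "V")
    out <- tibble::tibble(
      residue = residue_order(),
      class = factor(
        ifelse(residue_order() %in% hydrophobic, "hydrophobic", "hydrophilic"),
        levels = c("hydrophilic", "hydrophobic")
      )
    )
    attr(out, "scheme_name") <- "kyte_doolittle"
    return(out)
  }
  if (!is.data.frame(scheme) || !all(c("residue", "class") %in% names(scheme))) {
    rlang::abort("`scheme` must be \"kyte_doolittle\" or a data frame with columns residue, class")
  }
  tbl <- tibble::as_tibble(scheme[c("residue", "class")])
  if (!setequal(tbl$residue, residue_order()) || nrow(tbl) != 20) {
    rlang::abort("label scheme must cover exactly the 20 standard residues")
  }
  cls <- as.character(tbl$class)
  if (!all(cls %in% c("hydrophilic", "hydrophobic"))) {
    rlang::abort("label classes must be 'hydrophobic' or 'hydrophilic'")
  }
  if (length(unique(cls)) < 2) {
    rlang::abort("degenerate labels: both classes must be represented")
  }
  ord <- match(residue_order(), tbl$residue)
  out <- tibble::tibble(
    residue = residue_order(),
    class = factor(cls[ord], levels = c("hydrophilic", "hydrophobic"))
  )
  attr(out, "scheme_name") <- scheme_name
  out
}

# labels tibble -> 0/1 integer vector aligned with canonical residue order
labels_as_int <- function(labels) {
  labels <- hydropathy_labels(labels, scheme_name = label_scheme_name(labels))
  as.integer(labels$class == "hydrophobic")
}

label_scheme_name <- function(labels) {
  nm <- attr(labels, "scheme_name")
  if (is.null(nm)) "custom" else nm
}
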