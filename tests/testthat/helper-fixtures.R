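# shared fixture builders; everything is generated in code at test time

# property-collection tibble (one row per accession) from a named list of
# length-20 value vectors
make_props <- function(values) {
  rows <- lapply(names(values), function(acc) {
    v <- as.list(values[[acc]])
    names(v) <- residue_order()
    dplyr::bind_cols(
      tibble::tibble(accession = acc, description = paste("synthetic", acc),
                     provenance = "generated in test"),
      tibble::as_tibble(v)
    )
  })
  dplyr::bind_rows(rows)
}

# index table with m standard-normal property columns
rand_index_table <- function(m, seed, prefix = "RND") {
  set.seed(seed)
  cols <- stats::setNames(
    lapply(seq_len(m), function(i) rnorm(20)),
    sprintf("%s%03d", prefix, seq_len(m))
  )
  dplyr::bind_cols(tibble::tibble(residue = residue_order()),
                   tibble::as_tibble(cols))
}

# AAindex1 flat-file text for a named list of value vectors (NA allowed)
make_aaindex_text <- function(values) {
  recs <- vapply(names(values), function(acc) {
    v <- values[[acc]]
    fmt <- ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 7))
    paste(
      paste0("H ", acc),
      paste0("D synthetic record ", acc),
      "R PMID:0000000",
      "A Nobody, A.",
      "T Synthetic fixture",
      "J In-memory (2026)",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("    ", paste(fmt[1:10], collapse = "  ")),
      paste0("    ", paste(fmt[11:20], collapse = "  ")),
      "//",
      sep = "\n"
    )
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}

# the hand-built single-variable toy used for the importance-count oracle:
# x orders the six samples as 0,0,0 | 1,1,1 with a wide margin; the fixed
# bootstrap holds rows 3 and 6 out of bag
toy_forest <- function() {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
              dimnames = list(NULL, "v1"))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  inbag <- matrix(c(2L, 1L, 0L, 1L, 2L, 0L), ncol = 1)
  list(x = x, y = y, inbag = inbag,
       fit = rf_forest(x, y, ntree = 1, mtry = 1, seed = 7, inbag = inbag))
}

# small synthetic family alignment for encoding/diversity tests
small_families <- function(seed = 1, ...) {
  gen_family_alignment(family_spec(n_families = 2, n_per_family = 6,
                                   block_length = 12, seed = seed, ...))
}
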