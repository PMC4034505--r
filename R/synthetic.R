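#' Specification of a synthetic property table
#'
#' Describes a 20-residue property table with planted structure emulating a
#' real property database: informative columns aligned with the hydropathy
#' dichotomy, redundant near-copies of them, and label-independent noise.
#'
#' Informative columns are drawn with unit within-class standard deviation
#' and class means `label_gap` apart, i.e. `label_gap` is a Cohen's-d style
#' standardized effect size.  Redundant columns are an informative column
#' plus noise tuned so the realized correlation is close to `redundancy_r`;
#' noise columns are standard normal, independent of the labels.  Under this
#' construction distinct informative columns share only the label component,
#' so their mutual correlation stays well below `redundancy_r` and the
#' planted redundancy structure is identifiable.
#'
#' @param n_informative,n_redundant_per_informative,n_noise Column counts.
#' @param redundancy_r Target |r| between a redundant copy and its parent.
#' @param label_gap Separation of class means in column-sd units.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#'
#' @return A list of class `table_spec`.
#' @export
table_spec <- function(n_informative = 5, n_redundant_per_informative = 2,
                       n_noise = 50, redundancy_r = 0.9, label_gap = 2,
                       seed = 1) {
  stopifnot(n_informative >= 0, n_redundant_per_informative >= 0,
            n_noise >= 0, label_gap >= 0)
  if (redundancy_r <= 0 || redundancy_r > 1) {
    rlang::abort("`redundancy_r` must be in (0, 1]")
  }
  if (n_informative + n_noise == 0) {
    rlang::abort("the spec must yield at least one property")
  }
  if (n_redundant_per_informative > 0 && n_informative == 0) {
    rlang::abort("redundant copies require at least one informative column")
  }
  structure(
    list(n_informative = as.integer(n_informative),
         n_redundant_per_informative = as.integer(n_redundant_per_informative),
         n_noise = as.integer(n_noise), redundancy_r = redundancy_r,
         label_gap = label_gap, seed = as.integer(seed)),
    class = "table_spec"
  )
}

#' Generate a property table with planted signal
#'
#' @param spec A [table_spec()].
#' @param labels Hydropathy labels defining the two classes.
#'
#' @return A list with `table` (an index table) and `manifest` (tibble:
#'   `accession`, `role` in informative/redundant/noise, `signal_group`
#'   linking each informative column and its copies, `parent`, `target_r`).
#' @export
gen_index_table <- function(spec, labels = hydropathy_labels()) {
  stopifnot(inherits(spec, "table_spec"))
  labels <- hydropathy_labels(labels, scheme_name = label_scheme_name(labels))
  y <- labels_as_int(labels)
  rng <- local_rng(spec$seed)

  cols <- list()
  manifest <- list()
  for (i in seq_len(spec$n_informative)) {
    acc <- sprintf("INF%03d", i)
    # unit within-class sd, class means label_gap apart (Cohen's-d scaling)
    col <- spec$label_gap * y + rng$norm(20)
    cols[[acc]] <- col
    manifest[[acc]] <- tibble::tibble(
      accession = acc, role = "informative", signal_group = i,
      parent = NA_character_, target_r = NA_real_
    )
    for (j in seq_len(spec$n_redundant_per_informative)) {
      racc <- sprintf("RED%03d%s", i, LETTERS[j])
      s <- stats::sd(col) * sqrt(1 / spec$redundancy_r^2 - 1)
      cols[[racc]] <- col + rng$norm(20, sd = s)
      manifest[[racc]] <- tibble::tibble(
        accession = racc, role = "redundant", signal_group = i,
        parent = acc, target_r = spec$redundancy_r
      )
    }
  }
  for (i in seq_len(spec$n_noise)) {
    acc <- sprintf("NSE%03d", i)
    cols[[acc]] <- rng$norm(20)
    manifest[[acc]] <- tibble::tibble(
      accession = acc, role = "noise", signal_group = NA_integer_,
      parent = NA_character_, target_r = NA_real_
    )
  }
  table <- dplyr::bind_cols(tibble::tibble(residue = residue_order()),
                            tibble::as_tibble(cols))
  list(table = table, manifest = dplyr::bind_rows(manifest))
}

#' Specification of a synthetic sequence family set
#'
#' Families of equal size evolve from per-family consensus sequences by
#' i.i.d. per-site substitution.  In `property_structured` mode the family
#' consensi are offset in the (standardized) property space of a reference
#' index table and substitutions prefer residues close to the original
#' residue in that space (softmax over negative Euclidean distance); in
#' `uniform_random` mode consensi and substitutions are uniform over
#' residues.  Optional all-gap-bearing columns can be injected to exercise
#' gap removal.
#'
#' @param n_families,n_per_family,block_length Positive integers; defaults
#'   mirror a 4-family, 280-sequence, 28-residue study set.
#' @param divergence Per-site substitution probability within a family.
#' @param between_family_shift Scale of the per-family offset in standardized
#'   property space (`property_structured` mode only).
#' @param mode `"property_structured"` or `"uniform_random"`.
#' @param temperature Softmax temperature for property-structured choices.
#' @param n_gap_columns Extra columns containing gaps to inject.
#' @param seed Integer seed.
#'
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_families = 4, n_per_family = 70, block_length = 28,
                        divergence = 0.15, between_family_shift = 1,
                        mode = c("property_structured", "uniform_random"),
                        temperature = 1, n_gap_columns = 0, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_families >= 1, n_per_family >= 1,
            divergence >= 0, divergence <= 1, temperature > 0,
            n_gap_columns >= 0)
  if (block_length < 1) rlang::abort("`block_length` must be positive")
  structure(
    list(n_families = as.integer(n_families),
         n_per_family = as.integer(n_per_family),
         block_length = as.integer(block_length),
         divergence = divergence,
         between_family_shift = between_family_shift,
         mode = mode, temperature = temperature,
         n_gap_columns = as.integer(n_gap_columns),
         seed = as.integer(seed)),
    class = "family_spec"
  )
}

#' Generate an aligned synthetic sequence family set
#'
#' @param spec A [family_spec()].
#' @param table Reference index table defining the property space; default
#'   [raaindex()].
#'
#' @return An alignment tibble (`id`, `family`, `sequence`) with attribute
#'   `"gap_columns"` giving the indices of injected gap-bearing columns.
#' @export
gen_family_alignment <- function(spec, table = raaindex()) {
  stopifnot(inherits(spec, "family_spec"))
  check_index_table(table)
  rng <- local_rng(spec$seed)
  z <- scale(index_matrix(table))  # residues in standardized property space
  res <- residue_order()
  nres <- length(res)

  softmax_pick <- function(dist2) {
    w <- exp(-sqrt(dist2) / spec$temperature)
    rng$pick(nres, prob = w)
  }

  seqs <- character(0)
  fams <- character(0)
  ids <- character(0)
  for (f in seq_len(spec$n_families)) {
    if (spec$mode == "property_structured") {
      center <- rng$norm(ncol(z), sd = spec$between_family_shift)
      d2c <- rowSums((z - matrix(center, nres, ncol(z), byrow = TRUE))^2)
      consensus <- vapply(seq_len(spec$block_length),
                          function(i) res[softmax_pick(d2c)], character(1))
    } else {
      consensus <- res[rng$pick_n(spec$block_length, nres)]
    }
    for (s in seq_len(spec$n_per_family)) {
      sq <- consensus
      mut <- rng$unif(spec$block_length) < spec$divergence
      for (i in which(mut)) {
        orig <- match(sq[i], res)
        if (spec$mode == "property_structured") {
          d2 <- rowSums((z - matrix(z[orig, ], nres, ncol(z), byrow = TRUE))^2)
          d2[orig] <- Inf  # a substitution always changes the residue
          sq[i] <- res[softmax_pick(d2)]
        } else {
          sq[i] <- res[-orig][rng$pick_n(1, nres - 1)]
        }
      }
      seqs <- c(seqs, paste(sq, collapse = ""))
      fams <- c(fams, sprintf("family%d", f))
      ids <- c(ids, sprintf("family%d_seq%03d", f, s))
    }
  }
  aln <- tibble::tibble(id = ids, family = fams, sequence = seqs)

  gap_cols <- integer(0)
  if (spec$n_gap_columns > 0) {
    n <- nrow(aln)
    chars <- aln_char_matrix(aln)
    insert_at <- sort(rng$pick_n(spec$n_gap_columns, spec$block_length + 1))
    # build new matrix with injected columns; each injected column is gap in
    # roughly half the sequences and a uniform residue elsewhere
    pieces <- list()
    prev <- 0
    for (k in seq_along(insert_at)) {
      at <- insert_at[k] - 1
      if (at > prev) pieces[[length(pieces) + 1]] <- chars[, (prev + 1):at, drop = FALSE]
      gapcol <- ifelse(rng$unif(n) < 0.5, "-", res[rng$pick_n(n, nres)])
      if (!any(gapcol == "-")) gapcol[1] <- "-"  # guarantee at least one gap
      pieces[[length(pieces) + 1]] <- matrix(gapcol, ncol = 1)
      prev <- at
    }
    if (prev < ncol(chars)) {
      pieces[[length(pieces) + 1]] <- chars[, (prev + 1):ncol(chars), drop = FALSE]
    }
    chars <- do.call(cbind, pieces)
    gap_cols <- which(apply(chars == "-", 2, any))
    aln$sequence <- apply(chars, 1, paste, collapse = "")
  }
  attr(aln, "gap_columns") <- gap_cols
  aln
}

# Small deterministic RNG wrapper: isolates generation from the global R RNG
# while remaining seed-reproducible.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    function(...) {
      outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(outer)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", outer, envir = globalenv())
        }
      })
      f(...)
    }
  }
  list(
    norm = with_state(function(n, sd = 1) stats::rnorm(n, sd = sd)),
    unif = with_state(function(n) stats::runif(n)),
    pick = with_state(function(n, prob) sample.int(n, 1, prob = prob)),
    pick_n = with_state(function(k, n) sample.int(n, k, replace = TRUE))
  )
}
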