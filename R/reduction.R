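#' Remove highly correlated properties
#'
#' Backward elimination of redundant property columns: while any pair of
#' retained columns has Pearson |r| above `threshold` (computed over the 20
#' residue values), the pair with the highest |r| is located and the member
#' with the larger mean |r| against all other retained columns is dropped
#' (ties by lexicographic accession, the later one dropped).  The procedure
#' is deterministic and idempotent.
#'
#' @param table An index table (see [as_index_table()]).
#' @param threshold Correlation threshold in `(0, 1]`; default 0.85.
#'
#' @return The pruned index table.  Attribute `"removal_log"` holds a tibble
#'   with one row per dropped accession: `dropped`, `kept_partner`, `r`.
#' @export
prune_correlated <- function(table, threshold = 0.85) {
  check_index_table(table)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    rlang::abort("`threshold` must be a single number in (0, 1]")
  }
  acc <- index_accessions(table)
  mat <- index_matrix(table)
  cm <- abs(stats::cor(mat))
  cm[is.na(cm)] <- 0  # constant columns carry no correlation signal
  diag(cm) <- 0

  keep <- acc
  log <- list()
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= threshold) break
    hits <- which(sub == mx, arr.ind = TRUE)
    # deterministic pair choice: lexicographically first (row, col) pair
    pair <- sort(c(keep[hits[1, "row"]], keep[hits[1, "col"]]))
    others <- setdiff(keep, pair)
    mean_r <- vapply(pair, function(a) {
      if (length(others) == 0) return(sub[pair[1], pair[2]])
      mean(cm[a, c(others, setdiff(pair, a))])
    }, numeric(1))
    drop <- if (mean_r[1] > mean_r[2]) pair[1]
            else if (mean_r[2] > mean_r[1]) pair[2]
            else pair[2]  # lexicographic tie-break: later accession dropped
    log[[length(log) + 1]] <- tibble::tibble(
      dropped = drop, kept_partner = setdiff(pair, drop), r = mx
    )
    keep <- setdiff(keep, drop)
  }
  out <- table[, c("residue", keep), drop = FALSE]
  attr(out, "removal_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(dropped = character(), kept_partner = character(),
                   r = numeric())
  out
}

#' Repeated-forest permutation importance of every property
#'
#' Runs `config$n_trials` independent random-forest trials on the 20 residues
#' (properties as predictors, the binary hydropathy class as response).  In
#' each trial one forest is grown on stratified bootstrap samples and each
#' property's importance is the mean over trees of the increase in out-of-bag
#' misclassification counts when that property's OOB values are permuted.
#' Trials use seed streams derived from `config$seed` by a counter, so the
#' report is reproducible bit-for-bit.
#'
#' @param table An index table.
#' @param labels Hydropathy labels (see [hydropathy_labels()]).
#' @param config An [rf_config()].
#'
#' @return An object of class `vim_report`: list with `trials` (n_trials x m
#'   score matrix), `summary` (tibble: `accession`, `mean_vim`, `sd_vim`,
#'   `median_vim`, `rank`), `config` and `scheme_name`.  Ranks order by
#'   decreasing mean importance, ties broken lexicographically.
#' @export
permutation_vim <- function(table, labels = hydropathy_labels(),
                            config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  d <- prepare_xy(table, labels)
  m <- ncol(d$x)
  trials <- cpp_vim_trials(d$x, d$y, config$ntree,
                           resolve_mtry(config$mtry, m),
                           config$n_trials, config$seed, STREAM_VIM,
                           d$tie_class)
  colnames(trials) <- colnames(d$x)
  summ <- tibble::tibble(
    accession = colnames(d$x),
    mean_vim = colMeans(trials),
    sd_vim = apply(trials, 2, stats::sd),
    median_vim = apply(trials, 2, stats::median)
  )
  ord <- order(-summ$mean_vim, summ$accession)
  summ$rank <- integer(nrow(summ))
  summ$rank[ord] <- seq_len(nrow(summ))
  structure(
    list(trials = trials, summary = summ, config = config,
         scheme_name = d$scheme_name),
    class = "vim_report"
  )
}

#' @export
print.vim_report <- function(x, ...) {
  cat("Permutation importance over", nrow(x$trials), "forest trials (",
      x$config$ntree, "trees each), labels:", x$scheme_name, "\n")
  print(dplyr::arrange(x$summary, .data$rank), ...)
  invisible(x)
}

#' Keep properties with positive mean importance
#'
#' Drops every property whose mean permutation importance is zero or less and
#' returns the survivors ordered by decreasing mean importance (ties broken
#' by lexicographic accession order).  An empty result is allowed and is
#' flagged with a message.
#'
#' @param report A `vim_report` from [permutation_vim()].
#' @return Character vector of ranked accessions.
#' @export
filter_by_mean_vim <- function(report) {
  stopifnot(inherits(report, "vim_report"))
  kept <- dplyr::filter(report$summary, .data$mean_vim > 0)
  kept <- dplyr::arrange(kept, dplyr::desc(.data$mean_vim), .data$accession)
  if (nrow(kept) == 0) message("no property has positive mean importance")
  kept$accession
}

#' Nested forward selection along an importance ranking
#'
#' For each prefix size k of the ranked property list, fits `trials_per_step`
#' forests on the first k properties and records each trial's ensemble
#' out-of-bag error percentage over the 20 residues.  The selected subset is
#' the longest prefix before the first step whose mean error exceeds
#' `threshold_pct`; if no step exceeds it, the full ranking is selected.
#' Note per-trial errors are multiples of 5% (one residue = 1/20), so the
#' threshold operates on the across-trial mean, which is fractional.
#'
#' @param ranked Character vector of accessions, most important first.
#' @param table An index table containing at least those accessions.
#' @param labels Hydropathy labels.
#' @param threshold_pct Acceptable mean error in percent (default 2.0).
#' @param trials_per_step Forests fitted per prefix size (default 100).
#' @param config An [rf_config()] providing `ntree` and `seed` (its
#'   `n_trials` is ignored here).
#'
#' @return An object of class `nested_selection`: list with
#'   `ranked_properties`, `step_errors` (tibble: `k`, `accession_added`,
#'   `mean_error`, `sd_error`, `errors` list-column of per-trial
#'   percentages), `threshold_pct` and `selected`.
#'   If already the first step exceeds the threshold an error of class
#'   `raaindex_empty_selection` is thrown carrying the diagnostic curve in
#'   its `step_errors` field.
#' @export
nested_selection <- function(ranked, table, labels = hydropathy_labels(),
                             threshold_pct = 2.0, trials_per_step = 100,
                             config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  check_index_table(table)
  if (length(ranked) == 0) rlang::abort("`ranked` must name at least one property")
  if (!all(ranked %in% index_accessions(table))) {
    rlang::abort("`ranked` contains accessions absent from `table`")
  }
  d <- prepare_xy(table[, c("residue", ranked), drop = FALSE], labels)

  steps <- purrr::map(seq_along(ranked), function(k) {
    xk <- d$x[, ranked[seq_len(k)], drop = FALSE]
    errs <- cpp_oob_error_trials(
      xk, d$y, config$ntree, resolve_mtry(config$mtry, k),
      as.integer(trials_per_step), config$seed,
      STREAM_NESTED + (k - 1) * 1e4, d$tie_class
    )
    tibble::tibble(
      k = k, accession_added = ranked[k],
      mean_error = mean(errs), sd_error = stats::sd(errs),
      errors = list(errs)
    )
  })
  step_errors <- dplyr::bind_rows(steps)

  over <- which(step_errors$mean_error > threshold_pct)
  n_sel <- if (length(over) == 0) length(ranked) else over[1] - 1L
  if (n_sel == 0) {
    rlang::abort(
      paste0("empty selection: mean error at the first step (",
             formatC(step_errors$mean_error[1], digits = 3, format = "g"),
             "%) already exceeds the ", threshold_pct, "% threshold"),
      class = "raaindex_empty_selection",
      step_errors = step_errors
    )
  }
  structure(
    list(ranked_properties = ranked, step_errors = step_errors,
         threshold_pct = threshold_pct, selected = ranked[seq_len(n_sel)],
         config = config, scheme_name = d$scheme_name),
    class = "nested_selection"
  )
}

#' @export
print.nested_selection <- function(x, ...) {
  cat("Nested forward selection over", length(x$ranked_properties),
      "ranked properties; threshold", x$threshold_pct, "%\n")
  cat("Selected", length(x$selected), "properties:",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Full property-reduction pipeline
#'
#' Composes the reduction stages: assemble complete properties
#' ([as_index_table()]), prune correlated columns ([prune_correlated()]),
#' estimate permutation importance over repeated forest trials
#' ([permutation_vim()]), keep positive-mean properties ranked by importance
#' ([filter_by_mean_vim()]) and run nested forward selection against the
#' error threshold ([nested_selection()]).
#'
#' @param properties Either a parsed property collection (one row per
#'   accession, as from [read_aaindex()]) or an already assembled index
#'   table.
#' @param labels Hydropathy labels.
#' @param config An [rf_config()].
#' @param corr_threshold Correlation threshold for pruning.
#' @param threshold_pct Mean-error threshold (percent) for nested selection.
#' @param trials_per_step Forests per nested step.
#'
#' @return An object of class `bpp_reduction`: list with `table` (the
#'   selected index table), `selected`, `stages` (tibble of per-stage
#'   in/dropped/out counts), `vim` (the `vim_report`), `selection` (the
#'   `nested_selection`), `prune_log` and `scheme_name`.
#' @export
reduce_pipeline <- function(properties, labels = hydropathy_labels(),
                            config = rf_config(), corr_threshold = 0.85,
                            threshold_pct = 2.0, trials_per_step = 100) {
  if ("residue" %in% names(properties)) {
    table0 <- properties
    check_index_table(table0, "properties")
    n_raw <- length(index_accessions(table0))
    n_dropped_na <- 0L
  } else {
    n_raw <- nrow(properties)
    table0 <- suppressMessages(as_index_table(properties))
    n_dropped_na <- length(attr(table0, "dropped"))
  }
  n_complete <- length(index_accessions(table0))

  pruned <- prune_correlated(table0, corr_threshold)
  n_pruned <- length(index_accessions(pruned))

  vim <- permutation_vim(pruned, labels, config)
  ranked <- filter_by_mean_vim(vim)
  if (length(ranked) == 0) {
    rlang::abort("no property has positive mean importance; nothing to select")
  }
  selection <- nested_selection(ranked, pruned, labels,
                                threshold_pct = threshold_pct,
                                trials_per_step = trials_per_step,
                                config = config)
  stages <- tibble::tibble(
    stage = c("complete_values", "correlation_pruning", "positive_mean_vim",
              "nested_selection"),
    n_in = c(n_raw, n_complete, n_pruned, length(ranked)),
    n_dropped = c(n_dropped_na, n_complete - n_pruned,
                  n_pruned - length(ranked),
                  length(ranked) - length(selection$selected)),
    n_out = c(n_complete, n_pruned, length(ranked),
              length(selection$selected))
  )
  structure(
    list(table = pruned[, c("residue", selection$selected), drop = FALSE],
         selected = selection$selected, stages = stages, vim = vim,
         selection = selection, prune_log = attr(pruned, "removal_log"),
         scheme_name = vim$scheme_name, config = config),
    class = "bpp_reduction"
  )
}

#' @export
print.bpp_reduction <- function(x, ...) {
  cat("Property-reduction pipeline (labels:", x$scheme_name, ")\n")
  print(x$stages)
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
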