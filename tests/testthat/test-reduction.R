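test_that("correlation pruning removes duplicates and respects the threshold", {
  set.seed(41)
  base <- rnorm(20)
  tbl <- dplyr::bind_cols(
    tibble::tibble(residue = residue_order()),
    tibble::tibble(AAA = base, BBB = base, CCC = rnorm(20))
  )
  out <- prune_correlated(tbl)
  expect_equal(length(index_accessions <- setdiff(names(out), "residue")), 2)
  expect_true("CCC" %in% names(out))
  log <- attr(out, "removal_log")
  expect_equal(nrow(log), 1)
  expect_equal(log$r, 1)

  # identity when nothing exceeds the threshold, and idempotence in general
  indep <- rand_index_table(6, seed = 42)
  expect_equal(prune_correlated(indep), indep, ignore_attr = TRUE)
  for (s in 1:5) {
    t1 <- rand_index_table(15, seed = s)
    t1$DUP1 <- t1$RND001 + rnorm(20, sd = 0.1)
    t1$DUP2 <- t1$RND002 + rnorm(20, sd = 0.15)
    p1 <- prune_correlated(t1)
    expect_equal(prune_correlated(p1), p1, ignore_attr = TRUE)
    cm <- abs(stats::cor(as.matrix(p1[-1])))
    diag(cm) <- 0
    expect_lte(max(cm), 0.85)
  }

  expect_error(prune_correlated(tbl, threshold = 0), "in \\(0, 1\\]")
  expect_error(prune_correlated(tbl, threshold = 1.2), "in \\(0, 1\\]")
})

test_that("a constant property scores exactly zero importance in every trial", {
  set.seed(43)
  y <- labels_as_int(hydropathy_labels())
  tbl <- dplyr::bind_cols(
    tibble::tibble(residue = residue_order()),
    tibble::tibble(FLAT = rep(1.5, 20), SEP = 2.5 * y + rnorm(20, sd = 0.4),
                   NSE = rnorm(20))
  )
  v <- permutation_vim(tbl, config = rf_config(ntree = 50, n_trials = 25,
                                               seed = 2))
  expect_true(all(v$trials[, "FLAT"] == 0))
})

test_that("importance reports are seed-deterministic and well-formed", {
  gen <- gen_index_table(table_spec(n_informative = 2, n_noise = 8, seed = 3))
  cfg <- rf_config(ntree = 60, n_trials = 15, seed = 10)
  v1 <- permutation_vim(gen$table, config = cfg)
  v2 <- permutation_vim(gen$table, config = cfg)
  expect_identical(v1$trials, v2$trials)
  expect_identical(v1$summary, v2$summary)
  expect_setequal(v1$summary$rank, seq_len(ncol(v1$trials)))
  expect_true(all(v1$summary$sd_vim >= 0))
})

test_that("a planted perfect separator ranks first across seeds", {
  y <- labels_as_int(hydropathy_labels())
  wins <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    tbl <- dplyr::bind_cols(
      tibble::tibble(residue = residue_order()),
      tibble::tibble(SEP = 10 * y + rnorm(20, sd = 0.3)),
      tibble::as_tibble(stats::setNames(
        lapply(1:8, function(i) rnorm(20)), sprintf("NSE%02d", 1:8)
      ))
    )
    v <- permutation_vim(tbl, config = rf_config(ntree = 80, n_trials = 5,
                                                 seed = s))
    wins <- wins + (v$summary$accession[v$summary$rank == 1] == "SEP")
  }
  expect_gte(wins / n_seeds, 0.95)
})

test_that("noise importance is centered at zero over fresh random tables", {
  # unconditional unbiasedness: a new noise draw per replicate
  vals <- vapply(1:150, function(s) {
    gen <- gen_index_table(table_spec(n_informative = 2,
                                      n_redundant_per_informative = 0,
                                      n_noise = 6, seed = 5000 + s))
    v <- permutation_vim(gen$table,
                         config = rf_config(ntree = 40, n_trials = 2, seed = s))
    v$summary$mean_vim[v$summary$accession == "NSE001"]
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("mean-importance filtering matches a brute-force filter-and-sort", {
  for (s in 1:5) {
    set.seed(s)
    m <- 12
    trials <- matrix(rnorm(30 * m, mean = rep(runif(m, -0.2, 0.4), each = 30)),
                     30, m, dimnames = list(NULL, sprintf("P%02d", 1:m)))
    rep <- structure(
      list(trials = trials,
           summary = tibble::tibble(
             accession = colnames(trials),
             mean_vim = colMeans(trials),
             sd_vim = apply(trials, 2, sd),
             median_vim = apply(trials, 2, median),
             rank = rank(-colMeans(trials), ties.method = "first")
           ),
           config = rf_config(), scheme_name = "test"),
      class = "vim_report"
    )
    got <- filter_by_mean_vim(rep)
    mu <- colMeans(trials)
    want <- names(sort(mu[mu > 0], decreasing = TRUE))
    expect_equal(got, want)
  }
  # all-negative means give an empty, flagged result
  neg <- structure(
    list(trials = matrix(-1, 5, 2, dimnames = list(NULL, c("A", "B"))),
         summary = tibble::tibble(accession = c("A", "B"), mean_vim = c(-1, -1),
                                  sd_vim = 0, median_vim = -1, rank = 1:2),
         config = rf_config(), scheme_name = "test"),
    class = "vim_report"
  )
  expect_message(out <- filter_by_mean_vim(neg), "no property")
  expect_length(out, 0)
})

test_that("nested selection follows the threshold rule", {
  y <- labels_as_int(hydropathy_labels())
  set.seed(61)
  tbl <- dplyr::bind_cols(
    tibble::tibble(residue = residue_order()),
    tibble::tibble(SEP = 8 * y + rnorm(20, sd = 0.2)),
    tibble::as_tibble(stats::setNames(lapply(1:4, function(i) rnorm(20)),
                                      sprintf("NSE%02d", 1:4)))
  )
  cfg <- rf_config(ntree = 60, seed = 3)

  # a single perfectly separating property is selected with ~zero error
  one <- nested_selection("SEP", tbl, trials_per_step = 20, config = cfg)
  expect_equal(one$selected, "SEP")
  expect_lt(one$step_errors$mean_error[1], 1)

  # nothing can exceed a 100% threshold, so everything is selected
  ranked <- c("SEP", sprintf("NSE%02d", 1:4))
  all_in <- nested_selection(ranked, tbl, threshold_pct = 100,
                             trials_per_step = 10, config = cfg)
  expect_equal(all_in$selected, ranked)

  # the selection is always a prefix and every selected step obeys the bar
  sel <- nested_selection(ranked, tbl, threshold_pct = 25,
                          trials_per_step = 20, config = cfg)
  expect_equal(sel$selected,
               sel$ranked_properties[seq_along(sel$selected)])
  expect_true(all(sel$step_errors$mean_error[seq_along(sel$selected)] <= 25))

  # raising the threshold never shrinks the selected prefix
  lens <- vapply(c(5, 15, 40, 100), function(th) {
    length(nested_selection(ranked, tbl, threshold_pct = th,
                            trials_per_step = 20, config = cfg)$selected)
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))

  # pure-noise ranking fails at the first step with a diagnostic curve
  err <- tryCatch(
    nested_selection(sprintf("NSE%02d", 1:4), tbl, threshold_pct = 2,
                     trials_per_step = 10, config = cfg),
    error = function(e) e
  )
  expect_s3_class(err, "raaindex_empty_selection")
  expect_s3_class(err$step_errors, "tbl_df")
})

test_that("a planted separator survives nested selection over repeated seeds", {
  y <- labels_as_int(hydropathy_labels())
  hits <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    set.seed(2000 + s)
    tbl <- dplyr::bind_cols(
      tibble::tibble(residue = residue_order()),
      tibble::tibble(SEP = 9 * y + rnorm(20, sd = 0.3)),
      tibble::as_tibble(stats::setNames(lapply(1:3, function(i) rnorm(20)),
                                        sprintf("NSE%02d", 1:3)))
    )
    sel <- tryCatch(
      nested_selection(c("SEP", sprintf("NSE%02d", 1:3)), tbl,
                       threshold_pct = 2, trials_per_step = 15,
                       config = rf_config(ntree = 60, seed = s)),
      error = function(e) NULL
    )
    hits <- hits + (!is.null(sel) && "SEP" %in% sel$selected)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("the pipeline composes its stages and keeps counts consistent", {
  gen <- gen_index_table(table_spec(n_informative = 1,
                                    n_redundant_per_informative = 0,
                                    n_noise = 6, label_gap = 9, seed = 8))
  red <- suppressMessages(reduce_pipeline(
    gen$table, config = rf_config(ntree = 60, n_trials = 10, seed = 8),
    trials_per_step = 15
  ))
  expect_true("INF001" %in% red$selected)
  expect_equal(red$stages$n_in - red$stages$n_dropped, red$stages$n_out)
  # stage chaining: each stage's output feeds the next
  expect_equal(red$stages$n_out[-nrow(red$stages)], red$stages$n_in[-1])
  expect_equal(setdiff(names(red$table), "residue"), red$selected)

  expect_identical(
    red$selected,
    suppressMessages(reduce_pipeline(
      gen$table, config = rf_config(ntree = 60, n_trials = 10, seed = 8),
      trials_per_step = 15
    ))$selected
  )
})
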