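test_that("generators are seed-deterministic and validate their specs", {
  s1 <- gen_index_table(table_spec(seed = 4))
  s2 <- gen_index_table(table_spec(seed = 4))
  s3 <- gen_index_table(table_spec(seed = 5))
  expect_identical(s1, s2)
  expect_false(identical(s1$table, s3$table))

  a1 <- gen_family_alignment(family_spec(seed = 6, n_per_family = 4))
  a2 <- gen_family_alignment(family_spec(seed = 6, n_per_family = 4))
  expect_identical(a1, a2)

  expect_error(table_spec(n_informative = 0, n_noise = 0), "at least one")
  expect_error(table_spec(n_informative = 0, n_redundant_per_informative = 2,
                          n_noise = 5), "redundant copies require")
  expect_error(table_spec(redundancy_r = 0), "\\(0, 1\\]")
  expect_error(family_spec(block_length = 0), "positive")
})

test_that("generated tables carry the planted structure", {
  spec <- table_spec(n_informative = 2, n_redundant_per_informative = 1,
                     n_noise = 3, seed = 9)
  gen <- gen_index_table(spec)
  expect_equal(length(setdiff(names(gen$table), "residue")), 2 + 2 + 3)
  expect_equal(sort(unique(gen$manifest$role)),
               c("informative", "noise", "redundant"))
  expect_equal(gen$manifest$parent[gen$manifest$accession == "RED001A"],
               "INF001")

  # a single informative column and nothing else
  solo <- gen_index_table(table_spec(n_informative = 1,
                                     n_redundant_per_informative = 0,
                                     n_noise = 0, seed = 1))
  expect_equal(setdiff(names(solo$table), "residue"), "INF001")

  # informative columns separate the classes by about label_gap within-sd
  y <- labels_as_int(hydropathy_labels())
  gaps <- vapply(1:30, function(s) {
    g <- gen_index_table(table_spec(n_informative = 1,
                                    n_redundant_per_informative = 0,
                                    n_noise = 0, label_gap = 2, seed = s))
    col <- g$table$INF001
    (mean(col[y == 1]) - mean(col[y == 0])) /
      sqrt((12 * var(col[y == 0]) + 6 * var(col[y == 1])) / 18)
  }, numeric(1))
  expect_equal(mean(gaps), 2, tolerance = 0.2)
})

test_that("redundant copies hit their target correlation on average", {
  rs <- vapply(1:40, function(s) {
    gen <- gen_index_table(table_spec(n_informative = 1,
                                      n_redundant_per_informative = 1,
                                      n_noise = 0, redundancy_r = 0.9,
                                      seed = s))
    abs(cor(gen$table$INF001, gen$table$RED001A))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.05)
})

test_that("family alignments respect divergence and tagging", {
  frozen <- gen_family_alignment(family_spec(divergence = 0, n_per_family = 5,
                                             n_families = 3, block_length = 9,
                                             seed = 2))
  expect_equal(nrow(frozen), 15)
  expect_equal(length(unique(frozen$family)), 3)
  per_family <- tapply(frozen$sequence, frozen$family,
                       function(x) length(unique(x)))
  expect_true(all(per_family == 1))

  div <- gen_family_alignment(family_spec(divergence = 0.5, n_per_family = 5,
                                          n_families = 2, block_length = 30,
                                          seed = 2))
  expect_gt(length(unique(div$sequence)), 1)
  expect_true(all(nchar(div$sequence) == 30))
  expect_false(anyDuplicated(div$id) > 0)
})

test_that("property-structured substitutions stay closer in property space", {
  z <- scale(as.matrix(raaindex()[, -1]))
  rownames(z) <- residue_order()
  mean_dist <- function(aln) {
    chars <- do.call(rbind, strsplit(aln$sequence, ""))
    d <- 0; nd <- 0
    for (fam in unique(aln$family)) {
      sub <- chars[aln$family == fam, , drop = FALSE]
      cons <- apply(sub, 2, function(col) names(sort(-table(col)))[1])
      for (i in seq_len(nrow(sub))) {
        mut <- which(sub[i, ] != cons)
        for (j in mut) {
          d <- d + sqrt(sum((z[sub[i, j], ] - z[cons[j], ])^2))
          nd <- nd + 1
        }
      }
    }
    if (nd == 0) NA_real_ else d / nd
  }
  res <- vapply(1:10, function(s) {
    ps <- gen_family_alignment(family_spec(seed = s, n_families = 2,
                                           n_per_family = 10,
                                           block_length = 20,
                                           mode = "property_structured"))
    ur <- gen_family_alignment(family_spec(seed = s, n_families = 2,
                                           n_per_family = 10,
                                           block_length = 20,
                                           mode = "uniform_random"))
    c(ps = mean_dist(ps), ur = mean_dist(ur))
  }, numeric(2))
  expect_lt(mean(res["ps", ]), mean(res["ur", ]))
})

test_that("a zero label gap removes the planted ranking advantage", {
  # with no class separation, informative columns are indistinguishable from
  # noise: the top-ranked property is 'informative' at roughly chance rate
  top_inf <- vapply(1:20, function(s) {
    gen <- gen_index_table(table_spec(n_informative = 2,
                                      n_redundant_per_informative = 0,
                                      n_noise = 8, label_gap = 0, seed = s))
    v <- permutation_vim(gen$table,
                         config = rf_config(ntree = 40, n_trials = 5, seed = s))
    grepl("INF", v$summary$accession[v$summary$rank == 1])
  }, logical(1))
  expect_lt(mean(top_inf), 0.6)  # chance is 0.2
})
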