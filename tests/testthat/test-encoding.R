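test_that("gap-column removal matches a brute-force column scan", {
  # gapless alignment passes through unchanged
  aln <- small_families(seed = 2)
  expect_equal(extract_block(aln), aln, ignore_attr = TRUE)

  # an all-gap column among three is removed
  tiny <- tibble::tibble(id = c("a", "b"), sequence = c("A-C", "G-W"))
  out <- extract_block(tiny)
  expect_equal(out$sequence, c("AC", "GW"))
  expect_equal(attr(out, "kept_columns"), c(1L, 3L))

  # injected gap columns are found exactly
  for (s in 1:5) {
    gapped <- small_families(seed = s, n_gap_columns = 3)
    chars <- do.call(rbind, strsplit(gapped$sequence, ""))
    want <- which(colSums(chars == "-") == 0)
    got <- extract_block(gapped)
    expect_equal(attr(got, "kept_columns"), want)
    expect_false(any(grepl("-", got$sequence, fixed = TRUE)))
  }

  # partial tolerance imputes the majority residue
  part <- tibble::tibble(id = c("a", "b", "c", "d"),
                         sequence = c("AC", "A-", "AC", "AW"))
  expect_message(imp <- extract_block(part, max_gap_fraction = 0.5), "imputed")
  expect_equal(imp$sequence[2], "AC")

  all_gap <- tibble::tibble(id = c("a", "b"), sequence = c("-", "-"))
  expect_error(extract_block(all_gap), "no alignment column")
})

test_that("property encoding reproduces each residue's packaged row", {
  rt <- raaindex()
  mat <- as.matrix(rt[, -1])
  for (i in seq_len(20)) {
    expect_equal(unname(encode_bpp(residue_order()[i])), unname(mat[i, ]))
  }
  # concatenation law and positional locality
  expect_equal(unname(encode_bpp("AW")),
               c(unname(encode_bpp("A")), unname(encode_bpp("W"))))
  a <- encode_bpp("ARNDC")
  b <- encode_bpp("ARWDC")  # mutate position 3
  diff_pos <- which(a != b)
  expect_true(all(diff_pos > 2 * 8 & diff_pos <= 3 * 8))

  expect_error(encode_bpp("ARX"), "unknown residue 'X' at position 3")
  expect_error(encode_bpp(""), "non-empty")
})

test_that("binary code is the big-endian ordinal expansion and round-trips", {
  expect_equal(unname(encode_binary8("A")), rep(0, 8))
  expect_equal(unname(encode_binary8("V")), c(0, 0, 0, 1, 0, 0, 1, 1))  # 19

  codes <- binary8_codes()
  expect_equal(nrow(dplyr::distinct(codes[paste0("b", 1:8)])), 20)

  set.seed(51)
  for (i in 1:10) {
    s <- paste(sample(residue_order(), 15, replace = TRUE), collapse = "")
    expect_equal(decode_binary8(encode_binary8(s)), s)
  }
})

test_that("set encoding has the expected lattice shape and metadata", {
  spec <- family_spec(n_families = 4, n_per_family = 7, block_length = 28,
                      seed = 3)
  aln <- gen_family_alignment(spec)
  bpp <- encode_set(aln, "bpp")
  bin <- encode_set(aln, "binary8")

  expect_equal(dim(bpp), c(28, 2 + 28 * 8))  # 28 sequences x 224 features
  expect_equal(dim(bin), dim(bpp))           # dimension-fair comparison
  expect_equal(attr(bpp, "scheme"), "bpp")
  expect_equal(attr(bin, "d"), 8L)
  expect_equal(bpp$family, aln$family)

  one <- encode_set(tibble::tibble(id = "x", sequence = "AW"), "bpp")
  expect_equal(nrow(one), 1)
  expect_equal(unname(unlist(one[1, -(1:2)])), unname(encode_bpp("AW")))

  mixed <- tibble::tibble(id = c("a", "b"), sequence = c("AC", "ACD"))
  expect_error(encode_set(mixed, "bpp"), "equal length")
  gapped <- tibble::tibble(id = c("a", "b"), sequence = c("A-", "AC"))
  expect_error(encode_set(gapped, "bpp"), "gaps")
})

test_that("sliding-window fragmentation encodes overlapping fragments", {
  aln <- tibble::tibble(id = "x", family = "f1", sequence = "ARNDC")
  frag <- encode_set(aln, "bpp", window = 3, step = 1)
  expect_equal(nrow(frag), 3)
  expect_equal(frag$id, paste0("x_frag", 1:3))
  expect_equal(attr(frag, "block_length"), 3)
  expect_equal(unname(unlist(frag[2, -(1:2)])), unname(encode_bpp("RND")))
  expect_equal(nrow(encode_set(aln, "bpp", window = 3, step = 2)), 2)
  expect_error(encode_set(aln, "bpp", window = 9), "block length")
})

test_that("encoded matrices survive a TSV round trip with their metadata", {
  aln <- small_families(seed = 7)
  enc <- encode_set(aln, "bpp")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_encoded(enc, tf)
  back <- read_encoded(tf)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(enc),
               ignore_attr = TRUE)
  expect_equal(attr(back, "scheme"), "bpp")
  expect_equal(attr(back, "block_length"), 12)
})

test_that("aligned FASTA files round-trip with family tags", {
  aln <- small_families(seed = 9)
  ff <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, ff)
  back <- read_alignment(ff)
  expect_equal(back, aln, ignore_attr = TRUE)

  # sidecar TSV tags override header tags
  tags <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = aln$id, family = "relabelled"), tags)
  relab <- read_alignment(ff, family_file = tags)
  expect_true(all(relab$family == "relabelled"))
})
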