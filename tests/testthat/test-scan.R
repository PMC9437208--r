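test_that("motif_spec validates its fields", {
  expect_error(motif_spec("CT"), "3-letter")
  expect_error(motif_spec("CUX"), "3-letter")
  expect_error(motif_spec("CTG", min_units = 1), ">= 2")
  expect_error(motif_spec("CTG", min_units = 4, max_mismatches = 12),
               "3\\*min_units")
  sp <- motif_spec("ctg", min_units = 6, max_mismatches = 2)
  expect_equal(sp$unit, "CTG")
  expect_setequal(tritarget:::spec_units(sp), c("CAG", "CTG"))
})

test_that("scan_sequence finds exact, complement and mismatched runs", {
  sp6 <- motif_spec("CTG", TRUE, 6, 0)
  h <- scan_sequence(paste0("AAA", strrep("CTG", 6), "AAA"), sp6)
  expect_equal(h$start, 3L)
  expect_equal(h$end, 21L)
  expect_equal(h$n_units, 6L)
  expect_equal(h$matched_unit, "CTG")
  expect_equal(h$n_mismatches, 0L)

  h <- scan_sequence("CAGCAGCAGCAG", motif_spec("CTG", TRUE, 4, 0))
  expect_equal(nrow(h), 1L)
  expect_equal(h$matched_unit, "CAG")

  h <- scan_sequence("CTGCTGCTACTGCTGCTG", motif_spec("CTG", TRUE, 6, 2))
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_mismatches, 1L)

  expect_equal(nrow(scan_sequence(strrep("CTG", 5),
                                  motif_spec("CTG", TRUE, 6, 0))), 0L)
})

test_that("runs are found in any reading phase", {
  # a CTG run entered mid-unit: TGCTGCTG... contains (TGC)-phase copies
  seq <- paste0("AA", substring(strrep("CTG", 8), 2))
  h <- scan_sequence(seq, motif_spec("CTG", TRUE, 6, 0))
  expect_equal(nrow(h), 1L)
  expect_gte(h$n_units, 6L)
})

test_that("non-DNA characters are rejected with their position", {
  expect_error(scan_sequence("ACGTQACGT", motif_spec("CTG")), "position 5")
  expect_no_error(scan_sequence("ACGTNNNACGT", motif_spec("CTG")))
})

test_that("N never matches and only degrades hits", {
  sp <- motif_spec("CTG", TRUE, 6, 2)
  base <- paste0("AT", strrep("CTG", 6), "AT")
  h0 <- scan_sequence(base, sp)
  expect_equal(h0$n_mismatches, 0L)
  for (pos in c(3L, 10L, 19L)) {   # inside the run
    s <- base
    substr(s, pos, pos) <- "N"
    h <- scan_sequence(s, sp)
    expect_lte(nrow(h), nrow(h0))
    if (nrow(h)) expect_gte(h$n_mismatches, 1L)
  }
  # N outside the run changes nothing
  s <- base; substr(s, 1, 1) <- "N"
  expect_equal(scan_sequence(s, sp), h0)
})

test_that("scanner equals the exhaustive oracle on random sequences", {
  set.seed(11)
  specs <- c(lapply(4:7, function(k) motif_spec("CTG", TRUE, k, 0)),
             lapply(6:7, function(k) motif_spec("CTG", TRUE, k, 2)))
  for (i in 1:60) {
    s <- random_dna(sample(30:150, 1), planted = i %% 2 == 0)
    for (sp in specs)
      expect_equal(scan_sequence(s, sp), oracle_scan(s, sp),
                   info = paste("seq", i, tritarget:::spec_key(sp)))
  }
})

test_that("reverse-complement symmetry holds under coordinate reflection", {
  set.seed(12)
  sp <- motif_spec("CTG", TRUE, 4, 0)
  for (i in 1:25) {
    s <- random_dna(120, planted = TRUE)
    h_fwd <- scan_sequence(s, sp)
    h_rev <- scan_sequence(reverse_complement(s), sp)
    expect_equal(nrow(h_fwd), nrow(h_rev))
    if (nrow(h_fwd)) {
      # reflect reverse-strand coordinates back onto the forward strand
      n <- nchar(s)
      refl <- data.frame(start = n - rev(h_rev$end),
                         end = n - rev(h_rev$start))
      expect_equal(h_fwd$start, refl$start)
      expect_equal(h_fwd$end, refl$end)
      expect_equal(h_fwd$matched_unit,
                   reverse_complement(rev(h_rev$matched_unit)))
    }
  }
})

test_that("build_catalog nests across k and rejects duplicates", {
  tx <- c(g1 = paste0("AT", strrep("CAG", 7), "AT"),
          g2 = random_dna(60), g3 = random_dna(60))
  specs <- lapply(5:8, function(k) motif_spec("CTG", TRUE, k, 0))
  cat_ <- build_catalog(tx, specs)
  expect_equal(catalog_genes(cat_, "CTG/CAG:k6:m0"), "g1")
  expect_equal(catalog_genes(cat_, "CTG/CAG:k7:m0"), "g1")
  expect_equal(catalog_genes(cat_, "CTG/CAG:k8:m0"), character(0))
  expect_setequal(cat_$background, c("g1", "g2", "g3"))
  expect_error(build_catalog(c(g1 = "ACGT", g1 = "ACGT"), specs[[1]]),
               "duplicate")
  empty <- build_catalog(stats::setNames(character(), character()),
                         specs[[1]])
  expect_length(empty$background, 0L)
  expect_length(empty$sets[[1]], 0L)
})

test_that("catalog order-independence and summary prevalences", {
  set.seed(13)
  tx <- stats::setNames(replicate(12, random_dna(90, planted = TRUE)),
                        sprintf("g%02d", 1:12))
  specs <- list(motif_spec("CTG", TRUE, 4, 0), motif_spec("CTG", TRUE, 5, 0))
  a <- build_catalog(tx, specs)
  b <- build_catalog(rev(tx), specs)
  expect_equal(a$sets, b$sets)

  sm <- catalog_summary(a)
  expect_equal(sm$prevalence, sm$n_genes / length(a$background))
  expect_true(all(diff(sm$n_genes[order(sm$k)]) <= 0))
  expect_error(catalog_summary(repeat_catalog(list(x = character()),
                                              character(),
                                              list(motif_spec("CTG")))),
               "empty")
})
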