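test_that("the generator is deterministic under seed and varies across seeds", {
  tr <- sim_truth(seed = 71, n_genes = 300)
  lab1 <- simulate_labels(tr); lab2 <- simulate_labels(tr)
  expect_identical(lab1, lab2)
  a <- simulate_counts(tr, lab1, 4, 4)
  b <- simulate_counts(tr, lab1, 4, 4)
  expect_identical(a$counts, b$counts)
  c_ <- simulate_counts(tr, lab1, 4, 4, seed = 999)
  expect_false(identical(a$counts, c_$counts))
})

test_that("scanning simulated transcripts recovers planted labels exactly", {
  tr <- sim_truth(seed = 72, n_genes = 120, seq_length = 400,
                  motifs = data.frame(unit = "CTG", k = 6, m = 0,
                                      prevalence = 0.1))
  lab <- simulate_labels(tr)
  tx <- simulate_transcripts(tr, lab)
  sp <- motif_spec("CTG", TRUE, 6, 0)
  cat_scan <- build_catalog(tx, sp)
  expect_equal(catalog_genes(cat_scan, "CTG/CAG:k6:m0"),
               sort(lab$plant$gene_id))
  # zero prevalence -> scanner finds nothing
  tr0 <- sim_truth(seed = 73, n_genes = 40, seq_length = 300,
                   motifs = data.frame(unit = "CTG", k = 6, m = 0,
                                       prevalence = 0))
  tx0 <- simulate_transcripts(tr0)
  expect_length(catalog_genes(build_catalog(tx0, sp), "CTG/CAG:k6:m0"), 0L)
})

test_that("longer planted runs are members of shorter-run sets", {
  tr <- sim_truth(seed = 74, n_genes = 60, seq_length = 300,
                  motifs = data.frame(unit = "CTG", k = 7, m = 0,
                                      prevalence = 0.1))
  lab <- simulate_labels(tr)
  tx <- simulate_transcripts(tr, lab)
  cat_ <- build_catalog(tx, list(motif_spec("CTG", TRUE, 6, 0),
                                 motif_spec("CTG", TRUE, 7, 0)))
  expect_equal(catalog_genes(cat_, "CTG/CAG:k6:m0"),
               catalog_genes(cat_, "CTG/CAG:k7:m0"))
  expect_setequal(catalog_genes(cat_, "CTG/CAG:k7:m0"),
                  lab$plant$gene_id)
  # planted catalog agrees with the scanner without any sequences
  pc <- planted_catalog(lab, list(motif_spec("CTG", TRUE, 6, 0),
                                  motif_spec("CTG", TRUE, 7, 0)))
  expect_equal(pc$sets, cat_$sets)
})

test_that("planted mismatch runs carry their mismatch budget", {
  tr <- sim_truth(seed = 75, n_genes = 50, seq_length = 300,
                  motifs = data.frame(unit = "CTG", k = 6, m = 2,
                                      prevalence = 0.1))
  lab <- simulate_labels(tr)
  tx <- simulate_transcripts(tr, lab)
  cat_ <- build_catalog(tx, motif_spec("CTG", TRUE, 6, 2))
  expect_setequal(catalog_genes(cat_, "CTG/CAG:k6:m2"), lab$plant$gene_id)
})

test_that("simulated files round-trip through the package readers", {
  tmp <- withr::local_tempdir()
  tr <- sim_truth(seed = 76, n_genes = 80, seq_length = 200)
  lab <- simulate_labels(tr)
  tx <- simulate_transcripts(tr, lab)
  write_transcripts(tx, file.path(tmp, "t.fasta"))
  rt <- read_transcripts(file.path(tmp, "t.fasta"))
  expect_equal(names(rt), names(tx))
  expect_equal(as.vector(rt), as.vector(unclass(tx)))

  cm <- simulate_counts(tr, lab, 3, 3)
  counts_df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE)
  tritarget:::write_tsv(counts_df, file.path(tmp, "c.tsv"))
  expect_equal(read_counts_tsv(file.path(tmp, "c.tsv")), cm$counts)

  gs <- simulate_gene_sets(lab, lab$genes[1:20], n_sets = 5)
  write_gmt(gs$collection, file.path(tmp, "s.gmt"))
  expect_equal(read_gmt(file.path(tmp, "s.gmt")), gs$collection)

  cat_ <- planted_catalog(lab, motif_spec("CTG", TRUE, 6, 0))
  write_catalog_tsv(cat_, file.path(tmp, "cat.tsv"))
  back <- read_catalog_tsv(file.path(tmp, "cat.tsv"),
                           background = lab$genes)
  expect_equal(back$sets, cat_$sets)
})

test_that("closed-form expected ratio and null construction", {
  expect_equal(expected_enrichment_ratio(1, 0.1), 1)
  expect_equal(expected_enrichment_ratio(3, 0.1), 3 / 1.2)
  expect_equal(expected_enrichment_ratio(5, 0.5), 5 / 3)
  tr <- sim_truth(seed = 77, rho = 3)
  expect_equal(expected_enrichment_ratio(tr), 3 / 1.2)
  cm <- simulate_counts(tr, simulate_labels(tr), 4, 4)
  expect_equal(attr(cm, "sim")$expected_ratio, 3 / 1.2)
})

test_that("planted gene sets are recovered by ORA", {
  tr <- sim_truth(seed = 78, n_genes = 1000)
  lab <- simulate_labels(tr)
  up <- sample(lab$genes, 120)
  gs <- simulate_gene_sets(lab, up, n_sets = 50, enriched_fraction = 0.2,
                           odds = 8, seed = 79)
  res <- ora_gene_sets(up, lab$genes, gs$collection)
  called <- res$set[res$q < 0.05]
  truth_sets <- names(gs$collection)[gs$enriched]
  sens <- mean(truth_sets %in% called)
  expect_gte(sens, 0.8)
})

test_that("the tibialis-like preset carries its documented structure", {
  co <- simulate_cohort("tibialis-like", seed = 80, n_case = 10,
                        n_control = 5, with_sequences = FALSE)
  sm <- catalog_summary(co$catalog)
  ctg <- sm[sm$motif == "CTG/CAG", ]
  expect_equal(ctg$prevalence[order(ctg$k)], c(0.12, 0.06, 0.05, 0.034),
               tolerance = 1e-9)
  # rotation-equivalent control families share one gene set
  expect_equal(catalog_genes(co$catalog, "CGG/CCG:k6:m0"),
               catalog_genes(co$catalog, "GCG/CGC:k6:m0"))
  expect_equal(ncol(co$counts$counts), 15L)
  expect_false(is.null(co$counts$phenotype))
})
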