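test_that("enrichment cells report exact expectation and ratio", {
  bg <- sprintf("g%04d", 1:1000)
  rep_genes <- bg[1:100]
  de <- c(bg[1:5], bg[101:145])          # overlap 5 of 50
  cell <- enrichment_cell(de, rep_genes, bg)
  expect_equal(cell$expected, 5)
  expect_equal(cell$ratio, 1)
  expect_true(cell$displayable)

  de4 <- c(bg[1:20], bg[101:130])        # overlap 20 of 50 -> ratio 4
  cell4 <- enrichment_cell(de4, rep_genes, bg)
  expect_equal(cell4$ratio, 4)
  expect_equal(cell4$fisher_p, hyper2_oracle(20, 100, 50, 1000),
               tolerance = 1e-12)

  cell0 <- enrichment_cell(bg[101:150], rep_genes, bg)
  expect_equal(cell0$ratio, 0)
  expect_false(cell0$displayable)
  expect_error(enrichment_cell("a", "a", character()), "empty background")
  expect_message(enrichment_cell(c(bg[1], "NOT_THERE"), rep_genes, bg),
                 "dropped")
})

test_that("fisher_exact_p agrees with stats::fisher.test", {
  set.seed(41)
  for (i in 1:40) {
    N <- sample(10:80, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    xs <- max(0, K + n - N):min(K, n)
    x <- xs[sample.int(length(xs), 1)]
    tab <- matrix(c(x, K - x, n - x, N - K - n + x), 2)
    expect_equal(fisher_exact_p(x, K, n, N),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact_p(x, K, n, N, "greater"),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_p(10, 5, 5, 20), "impossible")
})

test_that("enrichment grid partitions, nests and adjusts by family", {
  tr <- sim_truth(seed = 42, n_genes = 1000, rho = 4, pi0 = 0.08)
  lab <- simulate_labels(tr)
  cm <- simulate_counts(tr, lab, 12, 8)
  det <- de_analysis(cm, fc_threshold = 1)
  specs <- list(motif_spec("CTG", TRUE, 6, 0), motif_spec("CGG", TRUE, 6, 0))
  sets <- list(`CTG/CAG:k6:m0` = catalog_genes(planted_catalog(lab, specs[[1]]),
                                               "CTG/CAG:k6:m0"),
               `CGG/CCG:k6:m0` = sample(lab$genes, 100))
  cat_ <- repeat_catalog(sets, lab$genes, specs)
  grid <- enrichment_grid(det, cat_, fc_thresholds = c(1, 1.5, 2))
  expect_equal(nrow(grid), 2 * 3 * 3)
  # partition: up + down = both
  for (fc in c(1, 1.5, 2)) {
    g <- grid[grid$fc_threshold == fc & grid$spec == "CTG/CAG:k6:m0", ]
    expect_equal(g$n_de[g$direction == "both"],
                 g$n_de[g$direction == "up"] + g$n_de[g$direction == "down"])
    expect_equal(g$n_de_repeat[g$direction == "both"],
                 g$n_de_repeat[g$direction == "up"] +
                   g$n_de_repeat[g$direction == "down"])
  }
  # nesting: n_de non-increasing in threshold within a direction
  for (dir in c("up", "down", "both")) {
    g <- grid[grid$direction == dir & grid$spec == "CTG/CAG:k6:m0", ]
    expect_true(all(diff(g$n_de[order(g$fc_threshold)]) <= 0))
  }
  # families adjusted separately
  for (fam in c("ctg_cag", "control")) {
    i <- grid$family == fam
    expect_equal(grid$q[i], bh_oracle(grid$fisher_p[i]), tolerance = 1e-12)
  }
})

test_that("ORA finds a planted set and calibrates on permuted queries", {
  tr <- sim_truth(seed = 43, n_genes = 500)
  lab <- simulate_labels(tr)
  bg <- lab$genes
  query <- sample(bg, 60)
  coll <- list(exact = query, other = sample(bg, 40),
               tiny = sample(bg, 2))
  res <- ora_gene_sets(query, bg, coll)
  expect_false("tiny" %in% res$set)        # below min_size
  expect_equal(res$set[1], "exact")        # minimal p in the collection
  expect_lt(res$p[1], 1e-10)

  # null calibration: random sets against a random query
  set.seed(44)
  ps <- c()
  for (i in 1:10) {
    coll_null <- lapply(1:40, function(j) sample(bg, 25))
    names(coll_null) <- paste0("s", 1:40)
    res0 <- ora_gene_sets(sample(bg, 50), bg, coll_null)
    ps <- c(ps, res0$p)
  }
  expect_lt(mean(ps < 0.05), 0.09)
  expect_warning(ora_gene_sets(query, bg, list()), "empty")
})
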