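test_that("repeat-bearing TF flags come from the catalog", {
  tr <- sim_truth(seed = 51, n_genes = 400)
  lab <- simulate_labels(tr)
  cat_ <- planted_catalog(lab, motif_spec("CTG", TRUE, 6, 0))
  carriers <- catalog_genes(cat_, "CTG/CAG:k6:m0")
  tfs <- c(carriers[1:20], setdiff(lab$genes, carriers)[1:80])
  flags <- flag_repeat_tfs(tfs, cat_)
  expect_equal(sum(flags$repeat_bearing), 20L)
  expect_true(all(flags$in_background))
  expect_message(flag_repeat_tfs(c(tfs, "MISSING"), cat_), "absent")
})

test_that("KS rank test matches exhaustive enumeration for small groups", {
  set.seed(52)
  for (i in 1:12) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    ranks <- sample(100, m + n)
    tab <- data.frame(tf_id = paste0("t", seq_len(m + n)), rank = ranks,
                      repeat_bearing = c(rep(TRUE, m), rep(FALSE, n)))
    res <- ks_rank_test(tab)
    oracle <- ks_enum_oracle(ranks[1:m], ranks[-(1:m)], "greater")
    expect_equal(res$D, oracle$D, tolerance = 1e-12)
    expect_equal(res$p, oracle$p, tolerance = 1e-9)
  }
})

test_that("top-ranked carriers give an extreme KS p", {
  tab <- data.frame(tf_id = paste0("t", 1:100), rank = 1:100,
                    repeat_bearing = c(rep(TRUE, 5), rep(FALSE, 95)))
  res <- ks_rank_test(tab)
  expect_lt(res$p, 1e-3)
  # D+ = F_repeat(5) - F_other(5) = 1 - 0
  expect_equal(res$D, 1)
  # degenerate group sizes are refused
  tab$repeat_bearing <- TRUE
  expect_error(ks_rank_test(tab), "at least 3")
  # excluded TFs (not significant / outside background) don't enter
  tab2 <- data.frame(tf_id = paste0("t", 1:20), rank = 1:20,
                     repeat_bearing = rep(c(TRUE, FALSE), 10),
                     significant = rep(c(TRUE, FALSE), each = 10))
  res2 <- ks_rank_test(tab2)
  expect_equal(res2$n_repeat + res2$n_other, 10L)
})

test_that("the exact null rejection rate of the rank test is near nominal", {
  # P(p < 0.05) for a 20 v 80 split equals the largest attainable p below
  # 0.05; verify it lies in a sane band around the nominal level
  ps <- sort(unique(replicate(500, {
    x <- sample(100, 20)
    suppressWarnings(stats::ks.test(x, setdiff(1:100, x),
                                    alternative = "greater")$p.value)
  })))
  exact_rate <- max(ps[ps < 0.05])
  expect_gt(exact_rate, 0.03)
  expect_lt(exact_rate, 0.05)
})

test_that("network coverage counts repeat-TF targets correctly", {
  flags <- data.frame(tf_id = c("R1", "R2", "N1"),
                      repeat_bearing = c(TRUE, TRUE, FALSE))
  de <- sprintf("g%02d", 1:10)
  full <- data.frame(tf_id = rep("R1", 10), gene_id = de)
  expect_equal(unname(network_coverage(full, flags, de)$coverage["total"]), 1)
  none <- data.frame(tf_id = rep("N1", 10), gene_id = de)
  expect_equal(unname(network_coverage(none, flags, de)$coverage["total"]), 0)
  half <- rbind(data.frame(tf_id = "R1", gene_id = de[1:5]),
                data.frame(tf_id = "N1", gene_id = de[6:10]))
  cov <- network_coverage(half, flags, de)
  expect_equal(unname(cov$coverage["total"]), 0.5)
  # monotone non-decreasing under edge addition
  more <- rbind(half, data.frame(tf_id = "R2", gene_id = de[6]))
  expect_gte(unname(network_coverage(more, flags, de)$coverage["total"]),
             unname(cov$coverage["total"]))
  expect_error(network_coverage(half[0, ], flags, de), "empty")
})

test_that("simulated TF tables honour flags, bias and wiring", {
  tr <- sim_truth(seed = 53, n_genes = 800,
                  motifs = data.frame(unit = "CTG", k = 6, m = 0,
                                      prevalence = 0.15))
  lab <- simulate_labels(tr)
  de <- sample(lab$genes, 40)
  tf <- simulate_tf_table(tr, lab, de, n_tf = 100, repeat_fraction = 0.2,
                          rank_bias = 1, coverage = 0.5, seed = 99)
  expect_equal(sum(tf$table$repeat_bearing), 20L)
  # bias 1: carriers occupy the top ranks
  expect_setequal(tf$table$rank[tf$table$repeat_bearing], 1:20)
  expect_lt(ks_rank_test(tf$table)$p, 1e-3)
  # wired coverage is exact
  flags <- tf$table[, c("tf_id", "repeat_bearing")]
  cov <- network_coverage(tf$edges, flags, de)
  expect_equal(unname(cov$coverage["total"]), 0.5)
})
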