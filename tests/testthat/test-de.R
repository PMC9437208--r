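make_cm <- function(counts, n_case, n_control, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(counts)))
  rownames(counts) <- genes
  count_matrix(counts, c(rep("case", n_case), rep("control", n_control)))
}

test_that("expression filter keeps genes expressed in at least one condition", {
  set.seed(21)
  counts <- matrix(rpois(6 * 100, 50), ncol = 6)
  counts[1, ] <- 0                              # silent everywhere
  counts[2, ] <- c(500, 600, 550, 0, 0, 0)      # case-only expression
  counts[3, ] <- c(0, 3, 500, 500, 400, 450)    # patchy in cases, on in ctrl
  cm <- make_cm(counts, 3, 3)
  kept <- filter_low_expression(cm)
  expect_false("g001" %in% rownames(kept$counts))
  expect_true("g002" %in% rownames(kept$counts))
  expect_true("g003" %in% rownames(kept$counts))
  expect_equal(ncol(kept$counts), 6L)
  # order preserved
  expect_equal(rownames(kept$counts),
               intersect(rownames(cm$counts), rownames(kept$counts)))
  expect_error(filter_low_expression(make_cm(matrix(0L, 2, 4), 2, 2)),
               "positive library size|below the expression")
})

test_that("expression filter agrees with a per-gene CPM recomputation", {
  tr <- sim_truth(seed = 22, n_genes = 500)
  cm <- simulate_counts(tr, simulate_labels(tr), 5, 5)
  # plant 10% all-low genes
  low <- sample(rownames(cm$counts), 50)
  cm$counts[low, ] <- rbinom(50 * 10, 1, 0.2)
  kept <- filter_low_expression(cm)
  # independent oracle: literal CPM computation per gene and condition
  lib <- colSums(cm$counts)
  cpm <- t(t(cm$counts) / lib) * 1e6
  is_case <- cm$condition == "case"
  keep_oracle <- sapply(seq_len(nrow(cpm)), function(g)
    all(cpm[g, is_case] > 1) || all(cpm[g, !is_case] > 1))
  expect_equal(rownames(kept$counts), rownames(cm$counts)[keep_oracle])
})

test_that("TMM factors: identity, scale-invariance, composition shift", {
  set.seed(23)
  base <- matrix(rpois(1000 * 4, 100), ncol = 4)
  cm_same <- make_cm(cbind(base[, 1], base[, 1], base[, 1]), 2, 1)
  expect_equal(unname(tmm_factors(cm_same)), rep(1, 3), tolerance = 1e-12)

  # scalar rescaling of a column changes its library size, not its factor
  doubled <- cbind(base, base[, 1] * 2L)
  rownames(doubled) <- sprintf("g%04d", seq_len(nrow(doubled)))
  cm <- make_cm(doubled, 3, 2)
  f <- tmm_factors(cm)
  expect_equal(prod(f), 1, tolerance = 1e-9)
  expect_equal(unname(f[5] / f[1]), 1, tolerance = 1e-2)

  # a genuine composition shift: one sample inflates a few genes 50x;
  # the trimmed majority then carries M = log2(lib1/lib2) exactly
  shifted <- base[, 1]
  shifted[1:10] <- shifted[1:10] * 50L
  cm_c <- make_cm(cbind(base[, 1], shifted), 1, 1)
  f_c <- tmm_factors(cm_c)
  expect_equal(unname(f_c[2] / f_c[1]),
               sum(base[, 1]) / sum(shifted), tolerance = 0.01)

  perm <- c(3, 1, 2, 5, 4)
  cm_p <- count_matrix(doubled[, perm], cm$condition[perm])
  expect_equal(unname(tmm_factors(cm_p)), unname(f[perm]),
               tolerance = 1e-12)
})

test_that("log_cpm matches its formula and is scale-invariant", {
  counts <- matrix(c(0L, 10L, 1000L, 0L, 10L, 1000L), ncol = 2)
  cm <- make_cm(counts, 1, 1)
  cm$condition <- c("case", "control")
  nm <- log_cpm(cm, factors = c(1, 1))
  lib <- sum(counts[, 1])
  expect_equal(nm$logcpm[1, 1], log2(0.5 / (lib + 1) * 1e6))
  expect_equal(nm$logcpm[2, 1], log2(10.5 / (lib + 1) * 1e6))
  expect_true(all(diff(nm$logcpm[, 1]) > 0))   # monotone in count

  # scale invariance holds up to the prior count, so test at high counts
  big <- matrix(c(5000L, 8000L, 120000L, 5000L, 8000L, 120000L), ncol = 2)
  cmb <- make_cm(big, 1, 1)
  cmb$condition <- c("case", "control")
  nb <- log_cpm(cmb, factors = c(1, 1))
  nb2 <- log_cpm(make_cm(big * 2L, 1, 1), factors = c(1, 1))
  expect_equal(nb$logcpm, nb2$logcpm, tolerance = 1e-3)
})

test_that("moderated t: label swap negates logFC exactly", {
  tr <- sim_truth(seed = 24, n_genes = 300)
  cm <- simulate_counts(tr, simulate_labels(tr), 5, 5)
  nm <- log_cpm(cm, tmm_factors(cm))
  det <- de_test(nm)
  nm_swap <- nm
  nm_swap$condition <- ifelse(nm$condition == "case", "control", "case")
  det_swap <- de_test(nm_swap)
  expect_equal(det$logFC, -det_swap$logFC)
  expect_equal(det$p, det_swap$p)
})

test_that("moderated t detects a strong planted shift", {
  # logFC 2.0 at sigma 0.5, 10 v 10: q < 0.05 in nearly every replicate
  hits <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    x <- matrix(rnorm(200 * 20, 5, 0.5), ncol = 20)
    x[1, 1:10] <- x[1, 1:10] + 2
    rownames(x) <- sprintf("g%03d", 1:200)
    nm <- structure(list(logcpm = x,
                         condition = rep(c("case", "control"), each = 10),
                         phenotype = NULL),
                    class = "normalized_matrix")
    det <- de_test(nm)
    if (det$q[det$gene_id == "g001"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("bh_adjust performs the step-up and matches the literal oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  set.seed(25)
  for (i in 1:25) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("classification respects both the FDR and fold-change gates", {
  det <- data.frame(gene_id = c("a", "b", "c", "d"),
                    logFC = c(0.4, 1.0, 0.7, -0.9),
                    t = 0, p = c(0.001, 0.1, 0.001, 0.001),
                    q = c(0.001, 0.2, 0.001, 0.001), status = "ns")
  class(det) <- c("de_table", "data.frame")
  cl <- classify_de(det, fc_threshold = 1.5, alpha = 0.05)
  expect_equal(cl$status, c("ns", "ns", "up", "down"))
  cl1 <- classify_de(det, fc_threshold = 1)
  expect_equal(cl1$status, c("up", "ns", "up", "down"))
  expect_error(classify_de(det, fc_threshold = 0.5), ">= 1")
  expect_setequal(de_genes(det, "both", 1.5), c("c", "d"))
})

test_that("the DE workflow is deterministic", {
  tr <- sim_truth(seed = 26, n_genes = 400)
  cm <- simulate_counts(tr, simulate_labels(tr), 4, 4)
  a <- de_analysis(cm)
  b <- de_analysis(cm)
  attr(a, "normalized") <- attr(b, "normalized") <- NULL
  expect_identical(a, b)
})
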