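#' Fisher exact p-value for a 2x2 overlap table
#'
#' Hypergeometric exact test for the overlap `x` between a set of size `n`
#' drawn from a universe of size `N` containing `K` marked items.
#' Two-sided p-values sum the point probabilities of all overlaps no more
#' likely than the observed one (with the same `1 + 1e-7` relative
#' tolerance as `stats::fisher.test`, which this reproduces); one-sided
#' alternatives are upper-/lower-tail hypergeometric sums.
#'
#' @param x observed overlap count.
#' @param K number of marked items in the universe.
#' @param n size of the drawn set.
#' @param N universe size.
#' @param alternative `"two.sided"` (default), `"greater"` (enrichment) or
#'   `"less"` (depletion).
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(x, K, n, N,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(N >= 1, K >= 0, n >= 0, K <= N, n <= N)
  lo <- max(0L, K + n - N); hi <- min(K, n)
  if (x < lo || x > hi) stop("overlap x = ", x, " impossible for margins")
  if (alternative == "greater")
    return(stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE))
  if (alternative == "less")
    return(stats::phyper(x, K, N - K, n))
  support <- lo:hi
  pmf <- stats::dhyper(support, K, N - K, n)
  obs <- pmf[x - lo + 1]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

#' Observed/expected enrichment of repeat-bearing genes among DE genes
#'
#' The core over-representation statistic: the observed number of
#' repeat-bearing differentially expressed genes divided by the number
#' expected from the prevalence of repeat-bearing genes in the background
#' (`expected = n_de * n_repeat_bg / n_bg`), with a Fisher exact p-value on
#' the corresponding 2x2 table.  Genes outside the background are dropped
#' with a message.
#'
#' @param de_genes character vector of DE gene ids.
#' @param repeat_genes character vector of repeat-bearing gene ids.
#' @param background character vector: the gene universe (typically the
#'   genes expressed in the tissue).
#' @param alternative sidedness for [fisher_exact_p()]; default two-sided.
#' @return One-row data.frame of class `enrichment_cell`: `n_de_repeat`,
#'   `n_de`, `n_repeat_bg`, `n_bg`, `expected`, `ratio`, `fisher_p`,
#'   `displayable` (`TRUE` iff at least two overlapping genes; a display
#'   flag only, never a filter on the statistics).
#' @export
enrichment_cell <- function(de_genes, repeat_genes, background,
                            alternative = "two.sided") {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  de_genes <- unique(as.character(de_genes))
  repeat_genes <- unique(as.character(repeat_genes))
  n_out <- sum(!de_genes %in% background) +
    sum(!repeat_genes %in% background)
  if (n_out > 0)
    message(n_out, " gene(s) outside the background were dropped")
  de_genes <- intersect(de_genes, background)
  repeat_genes <- intersect(repeat_genes, background)
  x <- length(intersect(de_genes, repeat_genes))
  n_de <- length(de_genes); K <- length(repeat_genes)
  N <- length(background)
  expected <- n_de * K / N
  out <- data.frame(
    n_de_repeat = x, n_de = n_de, n_repeat_bg = K, n_bg = N,
    expected = expected,
    ratio = if (expected > 0) x / expected else NA_real_,
    fisher_p = fisher_exact_p(x, K, n_de, N, alternative = alternative),
    displayable = x >= 2L)
  class(out) <- c("enrichment_cell", "data.frame")
  out
}

#' Enrichment grid over motifs, repeat lengths and fold-change thresholds
#'
#' One [enrichment_cell()] per (catalog spec x fold-change threshold x
#' direction), against the background of genes present in both the DE
#' table and the catalog.  P-values are BH-adjusted in two separate
#' families: the CTG/CAG cells (the disease motif across lengths and
#' mismatch budgets) and the control-motif cells (e.g. CGG, CGT, GAA,
#' GCG), so a genuine CTG/CAG signal is never penalised for the size of
#' the control panel, and vice versa.
#'
#' @param det a `de_table` (see [de_test()]).
#' @param catalog a `repeat_catalog`.
#' @param fc_thresholds numeric fold-change thresholds (>= 1).
#' @param directions subset of `c("up", "down", "both")`.
#' @param alpha FDR level for DE classification.
#' @param alternative sidedness of the Fisher test.
#' @param adjust_families split BH adjustment into CTG/CAG vs control
#'   families (default) or adjust all cells together.
#' @return data.frame of class `enrichment_grid`, one row per cell, with
#'   columns `spec`, `motif`, `k`, `m`, `family`, `direction`,
#'   `fc_threshold`, the [enrichment_cell()] columns, and `q`.
#' @export
enrichment_grid <- function(det, catalog, fc_thresholds = c(1, 1.5, 2),
                            directions = c("up", "down", "both"),
                            alpha = 0.05, alternative = "two.sided",
                            adjust_families = TRUE) {
  stopifnot(inherits(det, "de_table"), inherits(catalog, "repeat_catalog"))
  if (any(fc_thresholds < 1)) stop("fold-change thresholds must be >= 1")
  directions <- match.arg(directions, c("up", "down", "both"),
                          several.ok = TRUE)
  background <- intersect(det$gene_id, catalog$background)
  if (!length(background)) stop("DE table and catalog share no genes")
  det_bg <- det[det$gene_id %in% background, , drop = FALSE]
  class(det_bg) <- class(det)

  rows <- list()
  for (key in names(catalog$sets)) {
    sp <- if (!is.null(catalog$specs)) catalog$specs[[key]] else NULL
    rep_genes <- intersect(catalog$sets[[key]], background)
    for (fc in fc_thresholds) {
      for (dir in directions) {
        dg <- de_genes(det_bg, direction = dir, fc_threshold = fc,
                       alpha = alpha)
        cell <- enrichment_cell(dg, rep_genes, background,
                                alternative = alternative)
        meta <- data.frame(
          spec = key,
          motif = if (!is.null(sp)) spec_label(sp) else NA_character_,
          k = if (!is.null(sp)) sp$min_units else NA_integer_,
          m = if (!is.null(sp)) sp$max_mismatches else NA_integer_,
          family = if (!is.null(sp) && spec_is_ctg_cag(sp)) "ctg_cag"
                   else "control",
          direction = dir, fc_threshold = fc,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- cbind(meta, as.data.frame(cell))
      }
    }
  }
  grid <- do.call(rbind, rows)
  if (adjust_families && !all(is.na(grid$motif))) {
    grid$q <- NA_real_
    for (fam in unique(grid$family)) {
      i <- grid$family == fam
      grid$q[i] <- bh_adjust(grid$fisher_p[i])
    }
  } else {
    grid$q <- bh_adjust(grid$fisher_p)
  }
  rownames(grid) <- NULL
  class(grid) <- c("enrichment_grid", "data.frame")
  grid
}

#' @export
print.enrichment_grid <- function(x, ...) {
  cat("<enrichment_grid> ", nrow(x), " cells (",
      sum(x$family == "ctg_cag"), " CTG/CAG, ",
      sum(x$family == "control"), " control); min q = ",
      sprintf("%.3g", min(x$q)), "\n", sep = "")
  invisible(x)
}

#' Bar-chart of an enrichment grid
#'
#' Observed/expected ratio bars per cell at one fold-change threshold and
#' direction, disease-motif cells coloured, control motifs grey, observed
#' DE counts annotated above each bar.  Cells with fewer than two
#' overlapping genes (not `displayable`) are drawn hollow.
#'
#' @param x an `enrichment_grid`.
#' @param fc_threshold,direction which slice of the grid to draw.
#' @param ... passed to `graphics::barplot`.
#' @export
plot.enrichment_grid <- function(x, fc_threshold = x$fc_threshold[1],
                                 direction = x$direction[1], ...) {
  g <- x[x$fc_threshold == fc_threshold & x$direction == direction, ]
  if (!nrow(g)) stop("no cells at that threshold/direction")
  col <- ifelse(g$family == "ctg_cag", "darkorange3", "grey60")
  col[!g$displayable] <- NA
  bp <- graphics::barplot(g$ratio, names.arg = g$spec, las = 2, col = col,
                          border = ifelse(g$family == "ctg_cag",
                                          "darkorange3", "grey60"),
                          ylab = "observed / expected", ...)
  graphics::text(bp, pmax(g$ratio, 0), labels = g$n_de_repeat, pos = 3,
                 cex = 0.8)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Over-representation analysis against a gene-set collection
#'
#' One-sided hypergeometric upper-tail test of a query gene list against
#' each set in a collection (e.g. pathway or predicted miRNA-target sets
#' read from GMT), BH-adjusted across the collection.  Sets with fewer
#' than `min_size` members after intersection with the background are
#' skipped.
#'
#' @param genes query gene ids (intersected with the background).
#' @param background gene universe.
#' @param collection named list of gene-id vectors (see [read_gmt()]).
#' @param min_size minimum post-intersection set size (default 3).
#' @return data.frame with one row per tested set: `set`, `set_size`,
#'   `overlap`, `expected`, `ratio`, `p`, `q`, sorted by `p`.
#' @export
ora_gene_sets <- function(genes, background, collection, min_size = 3L) {
  background <- unique(as.character(background))
  genes <- intersect(unique(as.character(genes)), background)
  if (!length(collection)) {
    warning("empty gene-set collection")
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), expected = numeric(),
                      ratio = numeric(), p = numeric(), q = numeric()))
  }
  sets <- lapply(collection, intersect, y = background)
  keep <- lengths(sets) >= min_size
  sets <- sets[keep]
  N <- length(background); n <- length(genes)
  res <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    x <- length(intersect(genes, sets[[nm]]))
    expected <- n * K / N
    data.frame(set = nm, set_size = K, overlap = x, expected = expected,
               ratio = if (expected > 0) x / expected else NA_real_,
               p = fisher_exact_p(x, K, n, N, alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    warning("no gene set large enough after background intersection")
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), expected = numeric(),
                      ratio = numeric(), p = numeric(), q = numeric()))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
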