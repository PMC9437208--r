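#' Per-gene Pearson correlation with a continuous phenotype
#'
#' Correlates each gene's normalized expression with a per-sample
#' phenotype score (e.g. normalized dorsiflexion strength).  Samples with
#' missing phenotype are dropped pairwise; p-values use the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with `n - 2` degrees of freedom, and
#' q-values are BH-adjusted within the tested gene subset.  Genes (or a
#' phenotype) with zero variance get `r = NA`, are flagged, and are
#' excluded from the BH adjustment.
#'
#' @param nm a `normalized_matrix` (see [log_cpm()]); its `phenotype`
#'   field is used unless `phenotype` is supplied.
#' @param phenotype optional numeric per-sample score overriding
#'   `nm$phenotype`.
#' @param gene_subset optional character vector restricting the genes
#'   tested (e.g. the repeat-bearing set).
#' @param include_controls correlate across all samples (default) or cases
#'   only.
#' @return data.frame of class `phenotype_correlation`: `gene_id`, `r`,
#'   `p`, `q`, `n`, `zero_variance`, sorted by `|r|` descending
#'   (zero-variance rows last).
#' @export
gene_phenotype_correlation <- function(nm, phenotype = NULL,
                                       gene_subset = NULL,
                                       include_controls = TRUE) {
  stopifnot(inherits(nm, "normalized_matrix"))
  y <- if (!is.null(phenotype)) as.numeric(phenotype) else nm$phenotype
  if (is.null(y)) stop("no phenotype scores available")
  if (length(y) != ncol(nm$logcpm))
    stop("'phenotype' must have one score per sample")
  keep <- !is.na(y)
  if (!include_controls) keep <- keep & nm$condition == "case"
  if (sum(keep) < 3L)
    stop("need at least 3 samples with a phenotype score")
  x <- nm$logcpm[, keep, drop = FALSE]
  y <- y[keep]
  if (!is.null(gene_subset)) {
    x <- x[rownames(x) %in% gene_subset, , drop = FALSE]
    if (!nrow(x)) stop("no genes left after subsetting")
  }
  n <- length(y)
  sy <- stats::sd(y)
  xc <- x - rowMeans(x)
  sx <- sqrt(rowSums(xc^2) / (n - 1))
  zero_var <- sx == 0 | sy == 0
  r <- rep(NA_real_, nrow(x))
  if (sy > 0)
    r[!zero_var] <- (xc[!zero_var, , drop = FALSE] %*% (y - mean(y)) /
                       (n - 1)) / (sx[!zero_var] * sy)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  q <- rep(NA_real_, length(p))
  q[!zero_var] <- bh_adjust(p[!zero_var])
  out <- data.frame(gene_id = rownames(x), r = as.numeric(r), p = p, q = q,
                    n = n, zero_variance = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(!is.finite(out$r), -abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phenotype_correlation", "data.frame")
  out
}

#' @export
print.phenotype_correlation <- function(x, ...) {
  cat("<phenotype_correlation> ", nrow(x), " genes over ", x$n[1],
      " samples; top |r| = ", sprintf("%.3f", abs(x$r[1])), "\n", sep = "")
  invisible(x)
}
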