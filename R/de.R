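#' Assemble a gene-by-sample count matrix with condition labels
#'
#' @param counts integer matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (colnames = sample ids); no negative values.
#' @param condition character/factor of length `ncol(counts)` with values
#'   `"case"` or `"control"`.
#' @param phenotype optional numeric per-sample score (NA allowed).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, phenotype = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("'counts' must have unique rownames (gene ids)")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("negative counts are not allowed")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("'condition' must have one label per sample")
  if (!all(condition %in% c("case", "control")))
    stop("condition labels must be 'case' or 'control'")
  if (!is.null(phenotype)) {
    phenotype <- as.numeric(phenotype)
    if (length(phenotype) != ncol(counts))
      stop("'phenotype' must have one score per sample")
  }
  structure(list(counts = counts, condition = condition,
                 phenotype = phenotype),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", sum(x$condition == "case"), " case / ",
      sum(x$condition == "control"), " control",
      if (!is.null(x$phenotype)) ", with phenotype" else "", ")\n", sep = "")
  invisible(x)
}

cpm_raw <- function(counts) {
  lib <- colSums(counts)
  sweep(counts, 2, lib, "/") * 1e6
}

#' Remove genes below the expression floor
#'
#' A gene is kept iff in at least one condition its CPM (raw library-size
#' CPM) exceeds 1 in *every* sample of that condition — i.e. the gene is
#' consistently expressed in cases, or in controls, or both.  This keeps
#' condition-specific genes such as strongly silenced ones.
#'
#' @param cm a [count_matrix()].
#' @param cpm_min CPM floor (default 1).
#' @return A `count_matrix` restricted to kept genes, order preserved.
#' @export
filter_low_expression <- function(cm, cpm_min = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- colSums(cm$counts)
  if (any(lib <= 0)) stop("every sample must have a positive library size")
  cpm <- cpm_raw(cm$counts)
  keep <- rep(FALSE, nrow(cpm))
  for (cond in unique(cm$condition)) {
    cols <- cm$condition == cond
    keep <- keep | apply(cpm[, cols, drop = FALSE] > cpm_min, 1, all)
  }
  if (!any(keep))
    stop("all genes fall below the expression filter; nothing to analyse")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition, cm$phenotype)
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalization (30% M-trim, 5% A-trim,
#' inverse-asymptotic-variance weights, reference column chosen by 75th
#' percentile), rescaled to geometric mean 1.  Computed by
#' `edgeR::calcNormFactors`.
#'
#' @param cm a [count_matrix()] with at least 2 samples.
#' @return Named numeric vector of per-sample factors (product = 1).
#' @export
tmm_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(colSums(cm$counts) <= 0))
    stop("every sample must have a positive library size")
  f <- edgeR::calcNormFactors(cm$counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(cm$counts))
}

#' Normalized log2 counts-per-million
#'
#' `logcpm[g,s] = log2((count + prior) / (lib_size * factor + 1) * 1e6)`,
#' with prior count 0.5: the expression scale used by every downstream
#' stage (testing, PCA, clustering, phenotype correlation).
#'
#' @param cm a [count_matrix()].
#' @param factors per-sample positive scaling factors; defaults to
#'   [tmm_factors()].
#' @param prior_count pseudo-count added to each count (default 0.5).
#' @return An object of class `normalized_matrix`: list with `logcpm`,
#'   `tmm_factor`, `lib_size`, `condition`, `phenotype`.
#' @export
log_cpm <- function(cm, factors = tmm_factors(cm), prior_count = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(factors <= 0)) stop("scaling factors must be positive")
  lib <- colSums(cm$counts)
  eff <- lib * factors
  logcpm <- log2(sweep(cm$counts + prior_count, 2, eff + 1, "/") * 1e6)
  structure(list(logcpm = logcpm, tmm_factor = factors, lib_size = lib,
                 condition = cm$condition, phenotype = cm$phenotype),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("<normalized_matrix> ", nrow(x$logcpm), " genes x ", ncol(x$logcpm),
      " samples (log2 CPM, TMM-scaled)\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), returned in
#' the original order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Moderated two-sample differential expression test
#'
#' For each gene a two-sample t-test on normalized log2 CPM with a
#' moderated variance
#' \deqn{\tilde{s}^2_g = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' where \eqn{s_g^2} is the pooled within-group variance,
#' \eqn{d_g = n_1 + n_2 - 2}, \eqn{s_0^2} is the median pooled variance
#' across genes, and \eqn{d_0} (default 4) sets the strength of shrinkage.
#' P-values come from the t distribution with \eqn{d_0 + d_g} degrees of
#' freedom; q-values from [bh_adjust()].  `logFC` is the difference of
#' group-mean log-CPMs, case minus control.
#'
#' @param nm a `normalized_matrix` (see [log_cpm()]) with at least two
#'   samples per condition.
#' @param d0 prior degrees of freedom for variance moderation.
#' @return A data.frame of class `de_table`: `gene_id`, `logFC`, `t`, `p`,
#'   `q` (and `status = "ns"` until [classify_de()] is applied).
#' @export
de_test <- function(nm, d0 = 4) {
  stopifnot(inherits(nm, "normalized_matrix"))
  case <- nm$condition == "case"
  ctrl <- nm$condition == "control"
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per condition")
  x <- nm$logcpm
  m1 <- rowMeans(x[, case, drop = FALSE])
  m2 <- rowMeans(x[, ctrl, drop = FALSE])
  v1 <- apply(x[, case, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, ctrl, drop = FALSE], 1, stats::var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  s0_2 <- stats::median(s2)
  s2_mod <- (d0 * s0_2 + dg * s2) / (d0 + dg)
  logfc <- m1 - m2
  tstat <- logfc / sqrt(s2_mod * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = d0 + dg)
  p <- pmax(p, .Machine$double.xmin)     # keep p in (0, 1] for BH
  out <- data.frame(gene_id = rownames(x), logFC = logfc, t = tstat,
                    p = p, q = bh_adjust(p), status = "ns",
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Classify genes as up / down / not significant
#'
#' `up` iff `q < alpha` and `logFC >= log2(fc_threshold)`; `down` iff
#' `q < alpha` and `logFC <= -log2(fc_threshold)`; otherwise `ns`.
#' `fc_threshold = 1` recovers significance-only classification.
#'
#' @param det a `de_table` from [de_test()].
#' @param fc_threshold fold-change threshold on the natural scale (>= 1).
#' @param alpha FDR level (default 0.05).
#' @return The `de_table` with `status` filled in; the thresholds are
#'   recorded in attributes `fc_threshold` and `alpha`.
#' @export
classify_de <- function(det, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(det, "de_table"))
  if (fc_threshold < 1) stop("'fc_threshold' must be >= 1")
  lfc <- log2(fc_threshold)
  det$status <- "ns"
  det$status[det$q < alpha & det$logFC >= lfc] <- "up"
  det$status[det$q < alpha & det$logFC <= -lfc] <- "down"
  attr(det, "fc_threshold") <- fc_threshold
  attr(det, "alpha") <- alpha
  det
}

#' DE gene ids for a direction at a fold-change threshold
#'
#' @param det a `de_table`.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param fc_threshold,alpha passed to [classify_de()].
#' @return Character vector of gene ids.
#' @export
de_genes <- function(det, direction = c("both", "up", "down"),
                     fc_threshold = 1.5, alpha = 0.05) {
  direction <- match.arg(direction)
  det <- classify_de(det, fc_threshold, alpha)
  keep <- if (direction == "both") det$status != "ns"
          else det$status == direction
  det$gene_id[keep]
}

#' @export
print.de_table <- function(x, ...) {
  cat("<de_table> ", nrow(x), " genes; up ", sum(x$status == "up"),
      ", down ", sum(x$status == "down"), ", ns ", sum(x$status == "ns"),
      "\n", sep = "")
  invisible(x)
}

#' Full differential expression workflow
#'
#' Convenience wrapper: expression filter, TMM factors, log-CPM,
#' moderated test, classification.
#'
#' @inheritParams filter_low_expression
#' @inheritParams de_test
#' @inheritParams classify_de
#' @param prior_count pseudo-count for [log_cpm()].
#' @return A classified `de_table`; the `normalized_matrix` is attached as
#'   attribute `"normalized"`.
#' @export
de_analysis <- function(cm, fc_threshold = 1.5, alpha = 0.05, d0 = 4,
                        prior_count = 0.5, cpm_min = 1) {
  cm <- filter_low_expression(cm, cpm_min = cpm_min)
  nm <- log_cpm(cm, tmm_factors(cm), prior_count = prior_count)
  det <- classify_de(de_test(nm, d0 = d0), fc_threshold, alpha)
  attr(det, "normalized") <- nm
  det
}
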