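#' Flag repeat-bearing transcription factors
#'
#' Marks each TF as repeat-bearing according to one catalog entry (by
#' default the 6-unit CTG/CAG set, motivated by the ~18-nt length of
#' repeat-derived siRNAs).  TFs absent from the catalog background are
#' flagged unknown (`in_background = FALSE`) and excluded from the rank
#' test, with a message.
#'
#' @param tf_ids character vector of TF gene ids.
#' @param catalog a `repeat_catalog`.
#' @param spec catalog entry to use: a [motif_spec()] or spec key string.
#'   Defaults to the CTG/CAG `k = 6` entry if present (any mismatch
#'   budget), otherwise must be given.
#' @return data.frame: `tf_id`, `repeat_bearing`, `in_background`.
#' @export
flag_repeat_tfs <- function(tf_ids, catalog, spec = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  if (is.null(spec)) {
    keys <- grep("^(CTG|CAG)(/(CAG|CTG))?:k6:", names(catalog$sets),
                 value = TRUE)
    if (!length(keys))
      stop("catalog has no CTG/CAG k=6 entry; pass 'spec' explicitly")
    spec <- keys[1]
  }
  set <- catalog_genes(catalog, spec)
  tf_ids <- as.character(tf_ids)
  in_bg <- tf_ids %in% catalog$background
  if (any(!in_bg))
    message(sum(!in_bg), " TF(s) absent from the catalog background; ",
            "excluded from rank tests")
  data.frame(tf_id = tf_ids,
             repeat_bearing = tf_ids %in% set,
             in_background = in_bg,
             stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov test on the ranks of repeat-bearing TFs
#'
#' Tests whether repeat-bearing transcription factors sit at better
#' (smaller) ranks than the remaining TFs in an upstream target-enrichment
#' ranking.  Only TFs flagged significant by the upstream analysis and
#' present in the catalog background enter the test.  The default
#' alternative is one-sided ("repeat-bearing TFs rank higher"); exact
#' p-values are used for small samples (no ties are possible since ranks
#' are unique).
#'
#' @param table data.frame with columns `tf_id`, `rank` (1 = strongest),
#'   `repeat_bearing` (logical), optionally `significant` (logical,
#'   default all `TRUE`) and `in_background` (logical, default all
#'   `TRUE`).
#' @param alternative `"better"` (one-sided, default) or `"two.sided"`.
#' @return List of class `ks_rank_test`: `D`, `p`, `n_repeat`, `n_other`,
#'   `alternative`.
#' @export
ks_rank_test <- function(table, alternative = c("better", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("tf_id", "rank", "repeat_bearing") %in% names(table)))
  if (anyDuplicated(table$rank)) stop("ranks must be unique")
  keep <- rep(TRUE, nrow(table))
  if ("significant" %in% names(table)) keep <- keep & table$significant
  if ("in_background" %in% names(table)) keep <- keep & table$in_background
  tab <- table[keep, , drop = FALSE]
  r_rep <- tab$rank[tab$repeat_bearing]
  r_oth <- tab$rank[!tab$repeat_bearing]
  if (length(r_rep) < 3L || length(r_oth) < 3L)
    stop("need at least 3 repeat-bearing and 3 other significant TFs ",
         "(have ", length(r_rep), " and ", length(r_oth), ")")
  ## alternative = "greater": CDF of x lies above that of y, i.e. the
  ## repeat-bearing ranks are stochastically smaller (better)
  alt <- if (alternative == "better") "greater" else "two.sided"
  kt <- suppressWarnings(stats::ks.test(r_rep, r_oth, alternative = alt))
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 n_repeat = length(r_rep), n_other = length(r_oth),
                 alternative = alternative),
            class = "ks_rank_test")
}

#' @export
print.ks_rank_test <- function(x, ...) {
  cat("<ks_rank_test> D = ", sprintf("%.3f", x$D), ", p = ",
      sprintf("%.3g", x$p), " (", x$n_repeat, " repeat-bearing vs ",
      x$n_other, " other TFs, ", x$alternative, ")\n", sep = "")
  invisible(x)
}

#' Coverage of DE genes by repeat-bearing TFs in a regulatory network
#'
#' Given a TF-to-gene edge table and repeat-bearing flags, reports the
#' fraction of DE genes (overall and per direction) with at least one
#' incoming edge from a repeat-bearing TF, plus each TF's out-degree into
#' the DE set.
#'
#' @param edges data.frame with columns `tf_id`, `gene_id` (duplicate
#'   edges are collapsed).
#' @param tf_flags data.frame from [flag_repeat_tfs()] (columns `tf_id`,
#'   `repeat_bearing`).
#' @param det a `de_table` with classified `status`, or a character vector
#'   of DE gene ids (then per-direction fractions are `NA`).
#' @return List of class `network_coverage`: `coverage` (named fractions
#'   `total`, `up`, `down`), `n_de`, `covered_genes`, `tf_degree`
#'   (data.frame `tf_id`, `repeat_bearing`, `de_out_degree`), `edges_de`
#'   (bipartite edge list restricted to DE genes, for export/plotting).
#' @export
network_coverage <- function(edges, tf_flags, det) {
  stopifnot(all(c("tf_id", "gene_id") %in% names(edges)))
  if (!nrow(edges)) stop("empty network")
  edges <- unique(edges[, c("tf_id", "gene_id")])
  if (inherits(det, "de_table")) {
    up <- det$gene_id[det$status == "up"]
    down <- det$gene_id[det$status == "down"]
    all_de <- c(up, down)
  } else {
    up <- down <- NULL
    all_de <- as.character(det)
  }
  rep_tfs <- tf_flags$tf_id[tf_flags$repeat_bearing]
  covered <- unique(edges$gene_id[edges$tf_id %in% rep_tfs])
  frac <- function(set) {
    if (is.null(set)) return(NA_real_)
    if (!length(set)) return(NA_real_)
    mean(set %in% covered)
  }
  deg <- stats::aggregate(
    gene_id ~ tf_id, data = edges[edges$gene_id %in% all_de, , drop = FALSE],
    FUN = length)
  names(deg) <- c("tf_id", "de_out_degree")
  deg$repeat_bearing <- deg$tf_id %in% rep_tfs
  structure(list(
    coverage = c(total = frac(all_de), up = frac(up), down = frac(down)),
    n_de = length(all_de),
    covered_genes = intersect(all_de, covered),
    tf_degree = deg[order(-deg$de_out_degree), ],
    edges_de = edges[edges$gene_id %in% all_de, , drop = FALSE]),
    class = "network_coverage")
}

#' @export
print.network_coverage <- function(x, ...) {
  cat("<network_coverage> ", sprintf("%.1f%%", 100 * x$coverage["total"]),
      " of ", x$n_de, " DE genes targeted by repeat-bearing TFs\n",
      sep = "")
  invisible(x)
}
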