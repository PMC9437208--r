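#' Summarise one cohort's DE results for cross-cohort comparison
#'
#' @param name cohort label.
#' @param det a classified `de_table`, or a list with elements `up` and
#'   `down` (character vectors of gene ids).
#' @param catalog optional `repeat_catalog` + `spec` to record the
#'   repeat-bearing subset of the DE genes (defaults to the CTG/CAG k=6
#'   entry, as in [flag_repeat_tfs()]).
#' @param fc_threshold,alpha classification thresholds when `det` is a
#'   `de_table`.
#' @param spec catalog entry (key or [motif_spec()]).
#' @return Object of class `cohort_de_summary`: list with `name`, `up`,
#'   `down`, `de` (union), `repeat_de` (repeat-bearing subset, possibly
#'   empty when no catalog given).
#' @export
cohort_de_summary <- function(name, det, catalog = NULL,
                              fc_threshold = 1.5, alpha = 0.05,
                              spec = NULL) {
  if (inherits(det, "de_table")) {
    up <- de_genes(det, "up", fc_threshold, alpha)
    down <- de_genes(det, "down", fc_threshold, alpha)
  } else {
    up <- unique(as.character(det$up)); down <- unique(as.character(det$down))
  }
  de <- union(up, down)
  repeat_de <- character()
  if (!is.null(catalog)) {
    if (is.null(spec)) {
      keys <- grep("^(CTG|CAG)(/(CAG|CTG))?:k6:", names(catalog$sets),
                   value = TRUE)
      spec <- if (length(keys)) keys[1] else names(catalog$sets)[1]
    }
    repeat_de <- intersect(de, catalog_genes(catalog, spec))
  }
  structure(list(name = name, up = up, down = down, de = de,
                 repeat_de = repeat_de),
            class = "cohort_de_summary")
}

#' Venn-style counts of DE genes shared across cohorts
#'
#' For each multiplicity 1..n, the number of genes differentially
#' expressed in exactly that many cohorts (any direction), for all DE
#' genes and for the repeat-bearing subset (a gene counts as
#' repeat-bearing if any cohort lists it so).
#'
#' @param cohorts list of `cohort_de_summary` objects (>= 2).
#' @return data.frame: `n_cohorts`, `n_genes`, `n_repeat_genes`; counts
#'   sum to the union sizes.
#' @export
venn_counts <- function(cohorts) {
  stopifnot(length(cohorts) >= 2L,
            all(vapply(cohorts, inherits, TRUE, "cohort_de_summary")))
  all_de <- unlist(lapply(cohorts, `[[`, "de"))
  mult <- table(all_de)
  rep_genes <- unique(unlist(lapply(cohorts, `[[`, "repeat_de")))
  out <- data.frame(n_cohorts = seq_along(cohorts))
  out$n_genes <- vapply(out$n_cohorts,
                        function(k) sum(mult == k), 0L)
  out$n_repeat_genes <- vapply(out$n_cohorts, function(k)
    sum(names(mult)[mult == k] %in% rep_genes), 0L)
  out
}

#' Do repeat-bearing DE genes replicate across cohorts more often?
#'
#' Partitions the reference cohort's DE genes into repeat-bearing and
#' remaining, and tests (one-sided Fisher exact, by default) whether the
#' repeat-bearing genes are found differentially expressed in at least one
#' other cohort more often than the remaining genes.  Overlap is
#' direction-agnostic by default (a gene DE in any direction elsewhere
#' counts); set `direction_matched = TRUE` to require the same direction.
#'
#' @param reference a `cohort_de_summary` whose `repeat_de` is populated.
#' @param others list of `cohort_de_summary` objects for other cohorts.
#' @param direction_matched require the same direction in the other cohort.
#' @param alternative `"greater"` (repeat genes replicate more, default) or
#'   `"two.sided"`.
#' @return List of class `repeat_overlap_test`: `frac_repeat`,
#'   `frac_other`, `fisher_p`, `table` (the 2x2 counts).
#' @export
repeat_overlap_test <- function(reference, others,
                                direction_matched = FALSE,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(reference, "cohort_de_summary"))
  if (inherits(others, "cohort_de_summary")) others <- list(others)
  rep_set <- reference$repeat_de
  other_set <- setdiff(reference$de, rep_set)
  if (!length(rep_set) || !length(other_set))
    stop("reference DE partition has an empty row (",
         length(rep_set), " repeat-bearing, ", length(other_set),
         " remaining); test undefined")
  overlaps <- function(g, dir) {
    any(vapply(others, function(o) {
      pool <- if (direction_matched) o[[dir]] else o$de
      g %in% pool
    }, TRUE))
  }
  dir_of <- function(g) if (g %in% reference$up) "up" else "down"
  ov_rep <- vapply(rep_set, function(g) overlaps(g, dir_of(g)), TRUE)
  ov_oth <- vapply(other_set, function(g) overlaps(g, dir_of(g)), TRUE)
  a <- sum(ov_rep); b <- length(rep_set) - a
  c_ <- sum(ov_oth); d <- length(other_set) - c_
  N <- a + b + c_ + d
  p <- fisher_exact_p(a, K = a + b, n = a + c_, N = N,
                      alternative = if (alternative == "greater")
                        "greater" else "two.sided")
  structure(list(frac_repeat = a / (a + b), frac_other = c_ / (c_ + d),
                 fisher_p = p,
                 table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                                dimnames = list(c("repeat", "other"),
                                                c("overlaps", "unique")))),
            class = "repeat_overlap_test")
}

#' @export
print.repeat_overlap_test <- function(x, ...) {
  cat("<repeat_overlap_test> ", sprintf("%.1f%%", 100 * x$frac_repeat),
      " of repeat-bearing vs ", sprintf("%.1f%%", 100 * x$frac_other),
      " of remaining DE genes replicate; p = ",
      sprintf("%.3g", x$fisher_p), "\n", sep = "")
  invisible(x)
}
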