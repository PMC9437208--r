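#' Parameters of a synthetic repeat-silencing cohort
#'
#' Bundles every knob of the generator, which emulates the statistical
#' structure assumed by the analysis: a case/control negative-binomial
#' count matrix in which genes carrying planted CTG/CAG repeat runs are
#' preferentially dysregulated (down-biased), with a per-patient severity
#' that scales the planted effects and drives a clinical phenotype score.
#'
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param n_genes number of genes.
#' @param motifs data.frame with columns `unit`, `k`, `m`, `prevalence`:
#'   each row plants runs of exactly `k` units of `unit` (with `m`
#'   mismatches) in a disjoint `prevalence` fraction of genes.  Catalog
#'   membership then follows at-least-k semantics via nesting.
#' @param mu_log2 mean/sd of the baseline log2 relative-abundance
#'   distribution (CPM-like scale).
#' @param dispersion_meanlog,dispersion_sdlog lognormal parameters of the
#'   per-gene NB dispersion.
#' @param pi0 probability that a non-repeat gene is differentially
#'   expressed.
#' @param rho relative risk of DE for CTG/CAG repeat genes (DE probability
#'   `min(1, rho * pi0)`).
#' @param delta probability that a DE repeat gene is downregulated
#'   (silencing bias); non-repeat DE genes are down with probability 1/2.
#' @param lfc_range range of planted `|log2FC|`, drawn uniformly.
#' @param severity_range per-case severity, drawn uniformly; controls have
#'   severity 0.  A case's realised effect is `severity * |log2FC|`.
#' @param sigma_y phenotype noise: `y = 1 - severity + N(0, sigma_y)`.
#' @param lib_size_range library sizes, drawn uniformly.
#' @param seq_length transcript length in nt for [simulate_transcripts()].
#' @param tf_rank_bias default rank bias for [simulate_tf_table()]
#'   (0 = null, 1 = carriers occupy the top ranks).
#' @return List of class `sim_truth`.
#' @export
sim_truth <- function(seed = 1L, n_genes = 2000L,
                      motifs = data.frame(unit = "CTG", k = 6L, m = 0L,
                                          prevalence = 0.1),
                      mu_log2 = c(mean = 4, sd = 1.8),
                      dispersion_meanlog = log(0.1),
                      dispersion_sdlog = 0.4,
                      pi0 = 0.05, rho = 3, delta = 0.7,
                      lfc_range = c(1, 2.5),
                      severity_range = c(0.3, 1),
                      sigma_y = 0.1,
                      lib_size_range = c(1e6, 2e6),
                      seq_length = 1500L,
                      tf_rank_bias = 0.8) {
  stopifnot(all(c("unit", "k", "m", "prevalence") %in% names(motifs)),
            sum(motifs$prevalence) <= 1, all(motifs$prevalence >= 0),
            pi0 >= 0, pi0 <= 1, rho >= 0, delta >= 0, delta <= 1,
            min(1, rho * pi0) <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 motifs = motifs, mu_log2 = mu_log2,
                 dispersion_meanlog = dispersion_meanlog,
                 dispersion_sdlog = dispersion_sdlog,
                 pi0 = pi0, rho = rho, delta = delta,
                 lfc_range = lfc_range, severity_range = severity_range,
                 sigma_y = sigma_y, lib_size_range = lib_size_range,
                 seq_length = as.integer(seq_length),
                 tf_rank_bias = tf_rank_bias),
            class = "sim_truth")
}

#' Closed-form expected enrichment ratio implied by the generator
#'
#' With DE probability `pi0` for non-repeat genes and `min(1, rho * pi0)`
#' for repeat genes at repeat prevalence `prev`, the expected
#' observed/expected enrichment ratio among truly DE genes is
#' \deqn{\rho \,/\, (1 - prev + \rho \cdot prev).}
#'
#' @param rho relative risk (or a `sim_truth`, from which `rho` and the
#'   total CTG/CAG prevalence are taken).
#' @param prevalence repeat-gene prevalence.
#' @return Expected enrichment ratio (1 when `rho = 1`).
#' @export
expected_enrichment_ratio <- function(rho, prevalence = NULL) {
  if (inherits(rho, "sim_truth")) {
    truth <- rho
    prevalence <- sum(truth$motifs$prevalence[
      truth$motifs$unit %in% c("CTG", "CAG")])
    rho <- truth$rho
  }
  rho / (1 - prevalence + rho * prevalence)
}

#' Assign planted repeat labels to a gene universe
#'
#' Draws, per motif row of the truth object, a disjoint random subset of
#' genes of size `round(prevalence * n_genes)` and records its planted
#' `(unit, k, m)`.  CTG rows are planted as CTG or CAG at random (the
#' transcribed strand carries either member of the pair).
#'
#' @param truth a [sim_truth()].
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return List of class `sim_labels`: `genes` (all ids), `plant`
#'   (data.frame `gene_id`, `unit`, `k`, `m`).
#' @export
simulate_labels <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(truth$n_genes))
  pool <- genes
  plant <- list()
  for (i in seq_len(nrow(truth$motifs))) {
    row <- truth$motifs[i, ]
    n <- round(row$prevalence * truth$n_genes)
    if (n > length(pool)) stop("motif prevalences exceed the gene universe")
    if (n == 0) next
    chosen <- sample(pool, n)
    pool <- setdiff(pool, chosen)
    unit <- as.character(row$unit)
    ## plant either strand of the pair at random
    units <- sample(c(unit, reverse_complement(unit)), n, replace = TRUE)
    plant[[length(plant) + 1L]] <- data.frame(
      gene_id = chosen, unit = units, k = row$k, m = row$m,
      stringsAsFactors = FALSE)
  }
  plant <- if (length(plant)) do.call(rbind, plant)
           else data.frame(gene_id = character(), unit = character(),
                           k = integer(), m = integer())
  structure(list(genes = genes, plant = plant), class = "sim_labels")
}

## Does a planted (unit, k, m) run guarantee membership in `spec`'s set?
## Matching is rotation-closed, exactly like the scanner: a planted run of
## k copies of `unit` is k copies of a rotation of any rotation-equivalent
## spec unit.
planted_matches <- function(unit, k, m, spec) {
  unit %in% spec_rotation_set(spec) & spec$min_units <= k &
    spec$max_mismatches >= m
}

#' Repeat catalog implied by planted labels (no sequences needed)
#'
#' Derives catalog membership directly from the planted truth: a gene
#' belongs to a spec's set iff its planted unit is in the spec's pair, its
#' planted run length is at least the spec's `min_units`, and its planted
#' mismatch count is within the spec's budget.  Agrees with scanning the
#' simulated transcripts (which are rejection-sampled to contain no
#' accidental runs).
#'
#' @param labels a `sim_labels`.
#' @param specs a [motif_spec()] or list of them.
#' @return A `repeat_catalog`.
#' @export
planted_catalog <- function(labels, specs) {
  stopifnot(inherits(labels, "sim_labels"))
  if (inherits(specs, "motif_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, spec_key, "")
  pl <- labels$plant
  sets <- lapply(specs, function(sp) {
    if (!nrow(pl)) return(character())
    sort(pl$gene_id[planted_matches(pl$unit, pl$k, pl$m, sp)])
  })
  repeat_catalog(sets, background = labels$genes, specs = specs)
}

#' Simulate transcript sequences with planted repeat runs
#'
#' Background sequences are i.i.d. uniform DNA, rejection-resampled
#' against the scanner so that they contain no unplanted qualifying run
#' for any verification spec.  Planted genes receive one run of `k` copies
#' of their unit (with `m` random mismatches) at a uniform position; the
#' final sequence is re-scanned and resampled until its catalog membership
#' equals the planted expectation, so label/catalog agreement is exact by
#' construction.
#'
#' @param truth a [sim_truth()].
#' @param labels a `sim_labels` (defaults to [simulate_labels()]).
#' @param seed RNG seed.
#' @param verify_specs specs against which sequences are checked; defaults
#'   to the truth's motif grid plus, per row, the same spec at `k + 1`
#'   (guards against accidental run extension by flanking bases).
#' @param max_tries resampling bound per gene before the configuration is
#'   declared infeasible.
#' @return Named character vector of sequences (class `sim_transcripts`),
#'   with the `sim_labels` attached as attribute `"labels"`.
#' @export
simulate_transcripts <- function(truth, labels = simulate_labels(truth),
                                 seed = truth$seed + 1L,
                                 verify_specs = NULL, max_tries = 50L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(labels, "sim_labels"))
  set.seed(seed)
  if (is.null(verify_specs)) {
    verify_specs <- list()
    for (i in seq_len(nrow(truth$motifs))) {
      row <- truth$motifs[i, ]
      verify_specs <- c(verify_specs, list(
        motif_spec(row$unit, TRUE, row$k, row$m),
        motif_spec(row$unit, TRUE, row$k + 1L, row$m)))
    }
  }
  len <- truth$seq_length
  pl <- labels$plant
  alphabet <- c("A", "C", "G", "T")
  out <- character(length(labels$genes))
  names(out) <- labels$genes
  for (g in labels$genes) {
    row <- pl[pl$gene_id == g, , drop = FALSE]
    planted <- nrow(row) == 1L
    expect <- vapply(verify_specs, function(sp) {
      planted && planted_matches(row$unit, row$k, row$m, sp)
    }, TRUE)
    ## specs with a smaller mismatch budget than the planted run are
    ## indeterminate for that gene's own family (sub-windows may or may
    ## not clear the tighter budget) and are not checked
    check <- vapply(verify_specs, function(sp) {
      !(planted && row$unit %in% spec_rotation_set(sp) &&
          sp$max_mismatches < row$m)
    }, TRUE)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample(alphabet, len, replace = TRUE)
      if (planted) {
        k <- row$k; m <- row$m
        run <- rep(strsplit(row$unit, "")[[1]], k)
        if (m > 0) {
          pos <- sample(length(run), m)
          for (p in pos) run[p] <- sample(setdiff(alphabet, run[p]), 1)
        }
        at <- sample(len - length(run) + 1L, 1)
        s[at:(at + length(run) - 1L)] <- run
      }
      sq <- paste(s, collapse = "")
      got <- vapply(verify_specs, function(sp)
        nrow(scan_sequence(sq, sp)) > 0L, TRUE)
      if (all(got[check] == expect[check])) { out[g] <- sq; ok <- TRUE; break }
    }
    if (!ok)
      stop("could not realise planted configuration for ", g, " within ",
           max_tries, " tries; configuration infeasible")
  }
  structure(out, labels = labels, class = c("sim_transcripts", class(out)))
}

#' Simulate a case/control count matrix with planted repeat silencing
#'
#' Negative-binomial counts on top of a log2 baseline abundance, with DE
#' indicators drawn at probability `pi0` (non-repeat genes) or
#' `min(1, rho * pi0)` (CTG/CAG repeat genes), downregulation probability
#' `delta` for DE repeat genes and 1/2 otherwise, and case effects scaled
#' by per-patient severity.  The phenotype column decreases in severity.
#'
#' Multi-cohort structure is modelled through `de_plan`: passing the plan
#' of a previously simulated cohort (see [sim_de_plan()]) pins the DE
#' status, direction and effect size of the covered genes, so e.g. the
#' repeat-gene silencing can be shared across tissues (the common siRNA
#' mechanism) while the remaining dysregulation stays cohort-specific.
#'
#' @param truth a [sim_truth()].
#' @param labels a `sim_labels`.
#' @param n_case,n_control cohort sizes (>= 2 each).
#' @param seed RNG seed.
#' @param de_plan optional list with gene-named vectors `is_de`,
#'   `direction`, `lfc` covering a subset of genes whose planted DE is
#'   reused instead of redrawn.
#' @return A [count_matrix()] with attribute `"sim"`: list with `is_de`,
#'   `direction`, `lfc` (signed planted log2FC), `severity`,
#'   `target_genes` (the CTG/CAG-planted set), `expected_ratio` (the
#'   closed form of [expected_enrichment_ratio()]), and `truth`.
#' @export
simulate_counts <- function(truth, labels = simulate_labels(truth),
                            n_case = 20L, n_control = 10L,
                            seed = truth$seed + 2L, de_plan = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(labels, "sim_labels"),
            n_case >= 2L, n_control >= 2L)
  set.seed(seed)
  G <- truth$n_genes
  genes <- labels$genes
  pl <- labels$plant
  target <- if (nrow(pl)) pl$gene_id[pl$unit %in% c("CTG", "CAG")]
            else character()
  is_target <- genes %in% target

  mu <- stats::rnorm(G, truth$mu_log2["mean"], truth$mu_log2["sd"])
  disp <- stats::rlnorm(G, truth$dispersion_meanlog, truth$dispersion_sdlog)
  p_de <- ifelse(is_target, min(1, truth$rho * truth$pi0), truth$pi0)
  is_de <- stats::rbinom(G, 1L, p_de) == 1L
  p_down <- ifelse(is_target, truth$delta, 0.5)
  direction <- ifelse(stats::runif(G) < p_down, -1, 1)
  lfc <- stats::runif(G, truth$lfc_range[1], truth$lfc_range[2]) *
    direction * is_de
  if (!is.null(de_plan)) {
    g <- intersect(names(de_plan$is_de), genes)
    idx <- match(g, genes)
    is_de[idx] <- de_plan$is_de[g]
    direction[idx] <- ifelse(de_plan$direction[g] != 0,
                             de_plan$direction[g], direction[idx])
    lfc[idx] <- de_plan$lfc[g]
  }

  n <- n_case + n_control
  severity <- c(stats::runif(n_case, truth$severity_range[1],
                             truth$severity_range[2]),
                rep(0, n_control))
  condition <- c(rep("case", n_case), rep("control", n_control))
  lib <- round(stats::runif(n, truth$lib_size_range[1],
                            truth$lib_size_range[2]))
  counts <- matrix(0L, G, n,
                   dimnames = list(genes,
                                   c(sprintf("case%02d", seq_len(n_case)),
                                     sprintf("ctrl%02d", seq_len(n_control)))))
  for (s in seq_len(n)) {
    mu_s <- mu + lfc * severity[s]
    p_s <- 2^mu_s
    p_s <- p_s / sum(p_s)
    counts[, s] <- stats::rnbinom(G, mu = lib[s] * p_s, size = 1 / disp)
  }
  phenotype <- 1 - severity + stats::rnorm(n, 0, truth$sigma_y)
  cm <- count_matrix(counts, condition, phenotype)
  prev <- mean(is_target)
  attr(cm, "sim") <- list(
    is_de = stats::setNames(is_de, genes),
    direction = stats::setNames(direction * is_de, genes),
    lfc = stats::setNames(lfc, genes),
    severity = stats::setNames(severity, colnames(counts)),
    target_genes = sort(target),
    expected_ratio = expected_enrichment_ratio(truth$rho, prev),
    truth = truth)
  cm
}

#' Extract a cohort's planted DE plan
#'
#' Returns the planted DE status, direction and signed log2 fold change of
#' a simulated cohort, optionally restricted to a gene subset, in the form
#' [simulate_counts()] accepts as `de_plan`.  Restricting to the
#' CTG/CAG-planted genes and passing the plan to further cohorts models
#' silencing shared across tissues.
#'
#' @param cm a [count_matrix()] produced by [simulate_counts()].
#' @param genes optional character vector restricting the plan (e.g.
#'   `attr(cm, "sim")$target_genes`).
#' @return List with gene-named `is_de`, `direction`, `lfc`.
#' @export
sim_de_plan <- function(cm, genes = NULL) {
  sim <- attr(cm, "sim")
  if (is.null(sim)) stop("'cm' was not produced by simulate_counts()")
  if (is.null(genes)) genes <- names(sim$is_de)
  list(is_de = sim$is_de[genes], direction = sim$direction[genes],
       lfc = sim$lfc[genes])
}

#' Simulate a ranked TF table and regulatory network
#'
#' Draws `n_tf` transcription factors from the gene universe, a fraction
#' of them from the planted CTG/CAG repeat genes.  Latent rank scores are
#' uniform for non-carriers and shrunk towards 0 by `rank_bias` for
#' carriers (`bias = 0` is the null; `bias = 1` puts every carrier above
#' every non-carrier).  The TF-to-gene network is wired so that a stated
#' fraction of the DE genes receives at least one edge from a
#' repeat-bearing TF.
#'
#' @param truth a [sim_truth()].
#' @param labels a `sim_labels`.
#' @param de_gene_ids character vector of DE genes to wire the network to.
#' @param n_tf number of TFs (>= 10).
#' @param repeat_fraction fraction of TFs drawn from planted repeat genes.
#' @param rank_bias rank-shift parameter in `[0, 1]`; defaults to
#'   `truth$tf_rank_bias`.
#' @param sig_fraction fraction of TFs flagged significant by the
#'   (simulated) upstream enrichment, best ranks first.
#' @param coverage target fraction of DE genes covered by repeat TFs.
#' @param extra_edges additional random TF-gene edges added on top of the
#'   wiring (background network density).
#' @param seed RNG seed.
#' @return List with `table` (data.frame `tf_id`, `rank`, `fdr`,
#'   `significant`, `repeat_bearing`) and `edges` (data.frame `tf_id`,
#'   `gene_id`).
#' @export
simulate_tf_table <- function(truth, labels, de_gene_ids, n_tf = 100L,
                              repeat_fraction = 0.2,
                              rank_bias = truth$tf_rank_bias,
                              sig_fraction = 1, coverage = 0.5,
                              extra_edges = 200L,
                              seed = truth$seed + 3L) {
  stopifnot(inherits(labels, "sim_labels"), n_tf >= 10L,
            rank_bias >= 0, rank_bias <= 1)
  set.seed(seed)
  pl <- labels$plant
  ## repeat-bearing TFs are 6-unit carriers (the siRNA-length criterion)
  carriers_pool <- if (nrow(pl))
    pl$gene_id[pl$unit %in% c("CTG", "CAG") & pl$k >= 6L]
    else character()
  n_rep <- round(repeat_fraction * n_tf)
  if (n_rep > length(carriers_pool))
    stop("not enough planted repeat genes to draw ", n_rep, " repeat TFs")
  rep_tfs <- sample(carriers_pool, n_rep)
  oth_tfs <- sample(setdiff(labels$genes, carriers_pool), n_tf - n_rep)
  tf_id <- c(rep_tfs, oth_tfs)
  repeat_bearing <- c(rep(TRUE, n_rep), rep(FALSE, n_tf - n_rep))
  latent <- c(stats::runif(n_rep) * (1 - rank_bias),
              stats::runif(n_tf - n_rep))
  rk <- rank(latent, ties.method = "first")
  tab <- data.frame(tf_id = tf_id, rank = as.integer(rk),
                    fdr = rk / n_tf * 0.05,
                    significant = rk <= round(sig_fraction * n_tf),
                    repeat_bearing = repeat_bearing,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL

  de_gene_ids <- unique(as.character(de_gene_ids))
  edges <- data.frame(tf_id = character(), gene_id = character())
  if (length(de_gene_ids)) {
    n_cov <- round(coverage * length(de_gene_ids))
    covered <- if (n_cov) sample(de_gene_ids, n_cov) else character()
    uncovered <- setdiff(de_gene_ids, covered)
    e1 <- if (length(covered) && n_rep)
      data.frame(tf_id = sample(rep_tfs, length(covered), replace = TRUE),
                 gene_id = covered)
    e2 <- if (length(uncovered))
      data.frame(tf_id = sample(oth_tfs, length(uncovered), replace = TRUE),
                 gene_id = uncovered)
    edges <- rbind(edges, e1, e2)
  }
  if (extra_edges > 0) {
    ## background edges from non-repeat TFs to non-DE genes only, so the
    ## wired coverage fraction is preserved exactly
    pool <- setdiff(labels$genes, de_gene_ids)
    edges <- rbind(edges, data.frame(
      tf_id = sample(oth_tfs, extra_edges, replace = TRUE),
      gene_id = sample(pool, extra_edges, replace = TRUE)))
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  list(table = tab, edges = edges)
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Random gene sets from the universe; a stated fraction is enriched for a
#' target gene list (e.g. planted upregulated genes) by an odds
#' multiplier on the sampling weights.  Stands in for predicted
#' miRNA-target or pathway collections.
#'
#' @param labels a `sim_labels` (supplies the universe).
#' @param target_genes gene list the enriched sets favour.
#' @param n_sets number of sets (>= 1).
#' @param size_range set sizes, drawn uniformly.
#' @param enriched_fraction fraction of sets enriched.
#' @param odds weight multiplier for target genes in enriched sets
#'   (1 = null).
#' @param seed RNG seed.
#' @return List with `collection` (named list of gene vectors) and
#'   `enriched` (logical vector, the truth).
#' @export
simulate_gene_sets <- function(labels, target_genes, n_sets = 100L,
                               size_range = c(10L, 50L),
                               enriched_fraction = 0.2, odds = 5,
                               seed = 4L) {
  stopifnot(inherits(labels, "sim_labels"), n_sets >= 1L, odds >= 1)
  set.seed(seed)
  universe <- labels$genes
  target_genes <- intersect(unique(as.character(target_genes)), universe)
  n_enr <- round(enriched_fraction * n_sets)
  enriched <- c(rep(TRUE, n_enr), rep(FALSE, n_sets - n_enr))
  collection <- lapply(seq_len(n_sets), function(i) {
    size <- sample(seq(size_range[1], size_range[2]), 1)
    w <- rep(1, length(universe))
    if (enriched[i]) w[universe %in% target_genes] <- odds
    sample(universe, size, prob = w)
  })
  names(collection) <- sprintf("SET_%03d", seq_len(n_sets))
  list(collection = collection, enriched = enriched)
}

#' Simulate a complete named cohort
#'
#' The `"tibialis-like"` preset emulates a distal-muscle cohort: 40 cases
#' with graded severity vs 10 controls, 2000 genes, CTG/CAG runs planted
#' at nested prevalences for 4-7 units (exact-k fractions 0.060 / 0.010 /
#' 0.016 / 0.034, echoing the decreasing at-least-k catalog sizes of a
#' transcriptome-wide scan), control motifs CGG / CGT / GAA / GCG planted
#' at k = 6, repeat genes at relative DE risk 3 with downregulation bias
#' 0.7, a phenotype score decreasing in severity, a biased TF ranking and
#' a network wired to 50% repeat-TF coverage.  `"null"` keeps the same
#' shape with no planted association (`rho = 1`, `delta = 0.5`, unbiased
#' TF ranks).
#'
#' @param preset `"tibialis-like"` or `"null"`.
#' @param seed master seed.
#' @param n_case,n_control cohort sizes (preset defaults 40 / 10).
#' @param with_sequences also generate transcript FASTA (slower).
#' @param dir if non-NULL, write all inputs as plain-text files
#'   (`transcripts.fasta`, `counts.tsv`, `samples.tsv`, `tf_ranks.tsv`,
#'   `tf_edges.tsv`, `sets.gmt`, `truth.json`) into this directory.
#' @return List of class `sim_cohort`: `truth`, `labels`, `counts`
#'   (a [count_matrix()]), `sequences` (or NULL), `tf` (table + edges),
#'   `gene_sets`, `catalog` (the planted catalog over the full grid), and
#'   `files` (paths, when `dir` was given).
#' @export
simulate_cohort <- function(preset = c("tibialis-like", "null"),
                            seed = 1L, n_case = 40L, n_control = 10L,
                            with_sequences = TRUE, dir = NULL) {
  preset <- match.arg(preset)
  motifs <- data.frame(
    unit = c("CTG", "CTG", "CTG", "CTG", "CGG", "CGT", "GAA", "GCG"),
    k = c(4L, 5L, 6L, 7L, 6L, 6L, 6L, 6L),
    m = 0L,
    prevalence = c(0.060, 0.010, 0.016, 0.034, 0.024, 0.004, 0.017, 0.036))
  truth <- sim_truth(seed = seed, n_genes = 2000L, motifs = motifs,
                     rho = if (preset == "null") 1 else 3,
                     delta = if (preset == "null") 0.5 else 0.7,
                     tf_rank_bias = if (preset == "null") 0 else 0.8)
  labels <- simulate_labels(truth)
  counts <- simulate_counts(truth, labels, n_case, n_control)
  grid_specs <- c(
    lapply(4:7, function(k) motif_spec("CTG", TRUE, k,
                                       if (k >= 6) 2L else 0L)),
    lapply(c("CGG", "CGT", "GAA", "GCG"),
           function(u) motif_spec(u, TRUE, 6L, 0L)))
  catalog <- planted_catalog(labels, grid_specs)
  ## sequences are verified against the analysis grid itself (plus k+1
  ## guards), so scanning the FASTA reproduces the planted catalog exactly
  verify <- c(grid_specs, lapply(grid_specs, function(sp)
    motif_spec(sp$unit, sp$include_complement, sp$min_units + 1L,
               sp$max_mismatches)))
  sim <- attr(counts, "sim")
  true_de <- names(sim$is_de)[sim$is_de]
  tf <- simulate_tf_table(truth, labels, de_gene_ids = true_de)
  up_true <- names(sim$direction)[sim$direction > 0]
  gs <- simulate_gene_sets(labels, up_true, seed = truth$seed + 4L)
  sequences <- if (with_sequences)
    simulate_transcripts(truth, labels, verify_specs = verify)
    else NULL
  out <- structure(list(truth = truth, labels = labels, counts = counts,
                        sequences = sequences, tf = tf,
                        gene_sets = gs$collection,
                        gene_sets_enriched = gs$enriched,
                        catalog = catalog, files = NULL),
                   class = "sim_cohort")
  if (!is.null(dir)) out$files <- write_sim_cohort(out, dir)
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", x$truth$n_genes, " genes, ",
      sum(x$counts$condition == "case"), " case / ",
      sum(x$counts$condition == "control"), " control; rho = ",
      x$truth$rho, ", seed = ", x$truth$seed, "\n", sep = "")
  invisible(x)
}
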