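## Known configuration keys and the stages that consume them.
pipeline_config_keys <- function() {
  c("fasta", "counts", "samples", "de_table", "catalog",
    "tf_ranks", "tf_edges", "gmt", "cohorts",
    "units", "pair", "k", "mismatches",
    "fc_thresholds", "alpha", "d0", "prior_count", "cpm_min",
    "directions", "heatmap_genes", "out_dir", "seed")
}

#' Build and validate a pipeline configuration
#'
#' A flat named list of paths and options.  Unknown keys are rejected;
#' required combinations are checked before any stage runs.  Either
#' `fasta` (scan stage) or `catalog` (a precomputed catalog TSV), and
#' either `counts` + `samples` or an injected `de_table`, must be given.
#'
#' @param ... configuration entries; see Details.
#' @details Recognised keys: `fasta`, `counts`, `samples`, `de_table`,
#'   `catalog`, `tf_ranks`, `tf_edges`, `gmt`, `cohorts` (named character
#'   vector of other cohorts' DE table TSVs), `units` (motif units,
#'   default CTG + controls CGG/CGT/GAA/GCG), `pair` (default TRUE), `k`
#'   (default 4:7 for the first unit, 6 for controls), `mismatches`
#'   (default 0,0,2,2 over k = 4:7), `fc_thresholds` (default 1, 1.5, 2),
#'   `alpha` (0.05), `d0` (4), `prior_count` (0.5), `cpm_min` (1),
#'   `directions` (up/down/both), `heatmap_genes` (100), `out_dir`,
#'   `seed` (0).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), pipeline_config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(pair = TRUE, fc_thresholds = c(1, 1.5, 2),
                   alpha = 0.05, d0 = 4, prior_count = 0.5, cpm_min = 1,
                   directions = c("up", "down", "both"),
                   heatmap_genes = 100L, seed = 0L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'")
  if (is.null(cfg$fasta) && is.null(cfg$catalog))
    stop("config needs 'fasta' (to scan) or 'catalog' (precomputed)")
  if (is.null(cfg$de_table) && (is.null(cfg$counts) || is.null(cfg$samples)))
    stop("config needs 'counts' + 'samples', or an injected 'de_table'")
  for (k in c("fasta", "counts", "samples", "de_table", "catalog",
              "tf_ranks", "tf_edges", "gmt")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("config file missing: ", k, " = ", cfg[[k]])
  }
  if (!is.null(cfg$cohorts)) {
    miss <- cfg$cohorts[!file.exists(cfg$cohorts)]
    if (length(miss))
      stop("cohort DE table(s) missing: ", paste(miss, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

## Stable hash of the configuration (md5 of its deparsed canonical form).
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

## Default motif grid for the scan stage.
config_specs <- function(cfg) {
  if (is.null(cfg$units)) {
    specs <- c(
      lapply(4:7, function(k) motif_spec("CTG", TRUE, k,
                                         if (k >= 6) 2L else 0L)),
      lapply(c("CGG", "CGT", "GAA", "GCG"),
             function(u) motif_spec(u, TRUE, 6L, 0L)))
  } else {
    ks <- if (is.null(cfg$k)) rep(6L, length(cfg$units)) else cfg$k
    ms <- if (is.null(cfg$mismatches)) rep(0L, length(cfg$units))
          else cfg$mismatches
    stopifnot(length(ks) == length(cfg$units),
              length(ms) == length(cfg$units))
    specs <- lapply(seq_along(cfg$units), function(i)
      motif_spec(cfg$units[i], cfg$pair, ks[i], ms[i]))
  }
  specs
}

#' Run the full analysis pipeline
#'
#' Executes scan, differential expression, sample structure, repeat-gene
#' enrichment, gene-set ORA, TF rank/network, cross-cohort overlap and
#' phenotype correlation — each stage only when its inputs are configured
#' — writing one plain-text table per stage into `out_dir`.  Every table
#' carries a `#` header with the package version, configuration hash and
#' seed, and identical configurations produce byte-identical tables.  A
#' failure after some stages have completed leaves their outputs in place
#' plus a machine-readable `error.json`.
#'
#' @param config a [pipeline_config()] (or arguments for one).
#' @return Invisibly, a list of in-memory stage results; file outputs in
#'   `config$out_dir` (see [validate_pipeline_outputs()] for the roster).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  hdr <- sprintf("tritarget %s config=%s seed=%d",
                 as.character(utils::packageVersion("tritarget")),
                 hash, as.integer(config$seed))
  log_con <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(stage, ...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage,
                   "] ", ...)
    writeLines(line, log_con)
    message(line)
  }
  res <- list(config = config, hash = hash)
  set.seed(as.integer(config$seed))
  out <- function(name) file.path(config$out_dir, name)

  run_stage <- function(stage, expr) {
    logmsg(stage, "start")
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(list(stage = stage,
                                message = conditionMessage(e)),
                           out("error.json"), auto_unbox = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- scan ---------------------------------------------------------
  catalog <- run_stage("scan", {
    if (!is.null(config$fasta)) {
      tx <- read_transcripts(config$fasta)
      specs <- config_specs(config)
      names(specs) <- vapply(specs, spec_key, "")
      ## one scanning pass yields both the hit table and the catalog
      per_spec <- lapply(specs, function(sp) {
        hs <- lapply(names(tx), function(g) {
          h <- scan_sequence(tx[[g]], sp)
          if (nrow(h)) cbind(gene_id = g, h) else NULL
        })
        do.call(rbind, hs)
      })
      sets <- lapply(per_spec, function(h)
        if (is.null(h)) character() else sort(unique(h$gene_id)))
      hits <- unique(do.call(rbind, unname(per_spec)))
      if (is.null(hits))
        hits <- data.frame(gene_id = character(), start = integer(),
                           end = integer(), matched_unit = character(),
                           n_units = integer(), n_mismatches = integer())
      hits <- hits[order(hits$gene_id, hits$start), , drop = FALSE]
      write_tsv(hits, out("hits.tsv"), header = hdr)
      repeat_catalog(sets, background = names(tx), specs = specs)
    } else {
      read_catalog_tsv(config$catalog)
    }
  })
  write_catalog_tsv(catalog, out("catalog.tsv"), header = hdr)
  write_tsv(catalog_summary(catalog), out("catalog_summary.tsv"),
            header = hdr)
  res$catalog <- catalog

  ## --- differential expression -------------------------------------
  nm <- NULL
  det <- run_stage("de", {
    if (!is.null(config$de_table)) {
      read_de_table(config$de_table)
    } else {
      cm <- read_count_matrix(config$counts, config$samples)
      d <- de_analysis(cm, fc_threshold = config$fc_thresholds[1],
                       alpha = config$alpha, d0 = config$d0,
                       prior_count = config$prior_count,
                       cpm_min = config$cpm_min)
      nm <- attr(d, "normalized")
      d
    }
  })
  write_tsv(as.data.frame(det), out("de_table.tsv"), header = hdr)
  res$de <- det

  ## --- sample structure ---------------------------------------------
  if (!is.null(nm)) {
    run_stage("structure", {
      emb <- pca_samples(nm)
      emb_df <- data.frame(sample_id = rownames(emb$coords),
                           PC1 = emb$coords[, 1], PC2 = emb$coords[, 2],
                           explained1 = emb$explained[1],
                           explained2 = emb$explained[2])
      write_tsv(emb_df, out("embedding.tsv"), header = hdr)
      top <- top_loading_genes(emb, config$heatmap_genes)
      dg <- upgma_linkage(nm$logcpm[top, , drop = FALSE], "rows",
                          zscore = TRUE)
      ds <- upgma_linkage(nm$logcpm[top, , drop = FALSE], "cols")
      link_df <- data.frame(axis = c(rep("gene", nrow(dg$merge)),
                                     rep("sample", nrow(ds$merge))),
                            left = c(dg$merge[, 1], ds$merge[, 1]),
                            right = c(dg$merge[, 2], ds$merge[, 2]),
                            height = c(dg$height, ds$height))
      write_tsv(link_df, out("linkage.tsv"), header = hdr)
      ordered <- nm$logcpm[top[dg$order], ds$order, drop = FALSE]
      write_tsv(data.frame(gene_id = rownames(ordered),
                           round(ordered, 4), check.names = FALSE),
                out("heatmap_matrix.tsv"), header = hdr)
      res$embedding <- emb
    })
  }

  ## --- enrichment grid ----------------------------------------------
  run_stage("enrich", {
    grid <- enrichment_grid(det, catalog,
                            fc_thresholds = config$fc_thresholds,
                            directions = config$directions,
                            alpha = config$alpha)
    write_tsv(as.data.frame(grid), out("enrichment.tsv"), header = hdr)
    res$enrichment <- grid
  })

  if (!is.null(config$gmt)) {
    run_stage("ora", {
      collection <- read_gmt(config$gmt)
      bg <- intersect(det$gene_id, catalog$background)
      ora_up <- ora_gene_sets(de_genes(det, "up", 1.5, config$alpha),
                              bg, collection)
      ora_dn <- ora_gene_sets(de_genes(det, "down", 1.5, config$alpha),
                              bg, collection)
      ora <- rbind(cbind(direction = "up", ora_up),
                   cbind(direction = "down", ora_dn))
      write_tsv(ora, out("ora.tsv"), header = hdr)
      res$ora <- ora
    })
  }

  ## --- TF ranks and network -----------------------------------------
  if (!is.null(config$tf_ranks)) {
    run_stage("tfrank", {
      tf <- utils::read.delim(config$tf_ranks, comment.char = "#",
                              stringsAsFactors = FALSE)
      tf$repeat_bearing <- NULL      # always derived from the catalog
      tf$in_background <- NULL
      flags <- flag_repeat_tfs(tf$tf_id, catalog)
      tf <- merge(tf, flags, by = "tf_id", sort = FALSE)
      write_tsv(tf, out("tf_flags.tsv"), header = hdr)
      ks <- ks_rank_test(tf)
      jsonlite::write_json(list(D = ks$D, p = ks$p,
                                n_repeat = ks$n_repeat,
                                n_other = ks$n_other,
                                alternative = ks$alternative),
                           out("ks.json"), auto_unbox = TRUE, digits = NA)
      res$ks <- ks
      if (!is.null(config$tf_edges)) {
        edges <- utils::read.delim(config$tf_edges, comment.char = "#",
                                   stringsAsFactors = FALSE)
        det_cls <- classify_de(det, 1.5, config$alpha)
        cov <- network_coverage(edges, tf, det_cls)
        cov_df <- data.frame(subset = names(cov$coverage),
                             coverage = as.numeric(cov$coverage),
                             n_de = cov$n_de)
        write_tsv(cov_df, out("coverage.tsv"), header = hdr)
        write_tsv(cov$edges_de, out("network_edges.tsv"), header = hdr)
        res$coverage <- cov
      }
    })
  }

  ## --- cross-cohort overlap -----------------------------------------
  if (!is.null(config$cohorts) && length(config$cohorts) >= 1) {
    run_stage("overlap", {
      ref <- cohort_de_summary("reference", det, catalog,
                               fc_threshold = 1.5, alpha = config$alpha)
      others <- lapply(names(config$cohorts), function(nm_)
        cohort_de_summary(nm_, read_de_table(config$cohorts[[nm_]]),
                          catalog, fc_threshold = 1.5,
                          alpha = config$alpha))
      vc <- venn_counts(c(list(ref), others))
      write_tsv(vc, out("venn.tsv"), header = hdr)
      ov <- tryCatch(repeat_overlap_test(ref, others), error = function(e) {
        logmsg("overlap", "replication test skipped: ", conditionMessage(e))
        NULL
      })
      if (!is.null(ov)) {
        jsonlite::write_json(list(frac_repeat = ov$frac_repeat,
                                  frac_other = ov$frac_other,
                                  fisher_p = ov$fisher_p),
                             out("overlap_test.json"), auto_unbox = TRUE,
                             digits = NA)
        res$overlap <- ov
      }
    })
  }

  ## --- phenotype correlation ----------------------------------------
  if (!is.null(nm) && !is.null(nm$phenotype) &&
      any(!is.na(nm$phenotype))) {
    run_stage("phenocorr", {
      pc <- gene_phenotype_correlation(nm)
      write_tsv(as.data.frame(pc), out("phenotype_correlation.tsv"),
                header = hdr)
      res$phenotype <- pc
    })
  }

  jsonlite::write_json(list(version = as.character(
                              utils::packageVersion("tritarget")),
                            config_hash = hash,
                            seed = as.integer(config$seed),
                            stages = names(res)),
                       out("run_info.json"), auto_unbox = TRUE)
  logmsg("pipeline", "done")
  invisible(res)
}

## Column schemas of the pipeline's tabular outputs.
pipeline_schemas <- function() {
  list(
    catalog.tsv = c("motif", "k", "m", "gene_id"),
    catalog_summary.tsv = c("motif", "k", "m", "n_genes", "prevalence"),
    de_table.tsv = c("gene_id", "logFC", "t", "p", "q", "status"),
    embedding.tsv = c("sample_id", "PC1", "PC2", "explained1",
                      "explained2"),
    linkage.tsv = c("axis", "left", "right", "height"),
    enrichment.tsv = c("spec", "motif", "k", "m", "family", "direction",
                       "fc_threshold", "n_de_repeat", "n_de",
                       "n_repeat_bg", "n_bg", "expected", "ratio",
                       "fisher_p", "displayable", "q"),
    ora.tsv = c("direction", "set", "set_size", "overlap", "expected",
                "ratio", "p", "q"),
    tf_flags.tsv = c("tf_id", "rank", "repeat_bearing", "in_background"),
    coverage.tsv = c("subset", "coverage", "n_de"),
    venn.tsv = c("n_cohorts", "n_genes", "n_repeat_genes"),
    phenotype_correlation.tsv = c("gene_id", "r", "p", "q", "n",
                                  "zero_variance"))
}

#' Validate pipeline output files against their schemas
#'
#' Checks that each table present in a pipeline output directory starts
#' with the versioned `#` header and carries the expected columns, and
#' that the JSON reports parse.  Only files that exist are checked
#' (stages are optional), but `catalog.tsv`, `de_table.tsv` and
#' `enrichment.tsv` must exist.
#'
#' @param dir a [run_pipeline()] output directory.
#' @return `TRUE` (invisibly); otherwise an error describing the first
#'   violation.
#' @export
validate_pipeline_outputs <- function(dir) {
  schemas <- pipeline_schemas()
  required <- c("catalog.tsv", "de_table.tsv", "enrichment.tsv")
  for (f in required)
    if (!file.exists(file.path(dir, f)))
      stop("required pipeline output missing: ", f)
  for (f in names(schemas)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) next
    first <- readLines(path, n = 1L)
    if (!grepl("^# tritarget .* config=[0-9a-f]{32} seed=", first))
      stop(f, ": missing or malformed '#' version header")
    df <- utils::read.delim(path, comment.char = "#", nrows = 5L,
                            check.names = FALSE)
    need <- schemas[[f]]
    if (!all(need %in% names(df)))
      stop(f, ": missing column(s) ",
           paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (f in c("ks.json", "overlap_test.json", "run_info.json")) {
    path <- file.path(dir, f)
    if (file.exists(path)) jsonlite::read_json(path)
  }
  invisible(TRUE)
}
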