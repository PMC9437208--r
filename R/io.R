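#' Read transcript sequences from FASTA
#'
#' Gzip-transparent FASTA reader (via `Biostrings`); headers are parsed up
#' to the first whitespace as gene ids.  Duplicate ids are rejected, since
#' downstream cataloging requires one representative transcript per gene.
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_transcripts <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write transcript sequences to FASTA
#'
#' @param sequences named character vector of DNA sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_transcripts <- function(sequences, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(sequences))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a gene-by-sample counts table
#'
#' TSV with gene ids in the first column and sample ids in the header;
#' lines starting with `#` are ignored.
#'
#' @param path counts TSV.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `condition` and optionally `phenotype`.
#'
#' @param path sample sheet TSV.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df
}

#' Assemble a count matrix from a counts TSV and sample sheet
#'
#' @param counts_path,samples_path file paths.
#' @return A [count_matrix()] with samples ordered as in the sheet.
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  m <- read_counts_tsv(counts_path)
  sh <- read_sample_sheet(samples_path)
  missing <- setdiff(sh$sample_id, colnames(m))
  if (length(missing))
    stop("sample(s) in sheet but not in counts: ",
         paste(missing, collapse = ", "))
  m <- m[, sh$sample_id, drop = FALSE]
  count_matrix(m, sh$condition,
               if ("phenotype" %in% names(sh)) sh$phenotype else NULL)
}

#' Read / write GMT gene-set collections
#'
#' GMT is tab-delimited: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return `read_gmt`: named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param collection named list of gene-id vectors.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(collection, path, description = "synthetic") {
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], description,
            collection[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an externally produced DE table
#'
#' Accepts a TSV with columns `gene_id`, `logFC`, `p`, `q` (e.g. exact
#' limma-voom output produced elsewhere) and returns it as a `de_table`
#' ready for classification and enrichment, so the moderated-t surrogate
#' can be bypassed.
#'
#' @param path DE table TSV.
#' @return A `de_table`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "logFC", "p", "q")
  if (!all(need %in% names(df)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (!"t" %in% names(df)) df$t <- NA_real_
  if (!"status" %in% names(df)) df$status <- "ns"
  df <- df[, c("gene_id", "logFC", "t", "p", "q", "status")]
  class(df) <- c("de_table", "data.frame")
  df
}

#' Write a repeat catalog / hits as TSV
#'
#' The catalog is written long-format (`motif`, `k`, `m`, `gene_id`); hits
#' are BED-like (`gene_id`, `start`, `end`, `matched_unit`, `n_units`,
#' `n_mismatches`) with 0-based half-open coordinates.
#'
#' @param catalog a `repeat_catalog`.
#' @param path output TSV.
#' @param header optional comment line (without the leading `#`).
#' @export
write_catalog_tsv <- function(catalog, path, header = NULL) {
  rows <- lapply(names(catalog$sets), function(key) {
    sp <- catalog$specs[[key]]
    g <- catalog$sets[[key]]
    if (!length(g)) return(NULL)
    data.frame(motif = spec_label(sp), k = sp$min_units,
               m = sp$max_mismatches, gene_id = g,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(motif = character(), k = integer(), m = integer(),
                     gene_id = character())
  write_tsv(df, path, header = header)
  invisible(path)
}

#' Read a long-format catalog TSV
#'
#' @param path catalog TSV from [write_catalog_tsv()].
#' @param background gene universe; defaults to the gene ids present in
#'   the file (which loses never-matching genes, so supply it when known).
#' @return A `repeat_catalog`.
#' @export
read_catalog_tsv <- function(path, background = NULL) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  key <- sprintf("%s:k%d:m%d", df$motif, df$k, df$m)
  sets <- split(df$gene_id, key)
  meta <- unique(data.frame(key = key, motif = df$motif, k = df$k,
                            m = df$m, stringsAsFactors = FALSE))
  specs <- lapply(seq_len(nrow(meta)), function(i) {
    unit <- strsplit(meta$motif[i], "/", fixed = TRUE)[[1]][1]
    motif_spec(unit, grepl("/", meta$motif[i]), meta$k[i], meta$m[i])
  })
  names(specs) <- meta$key
  if (is.null(background)) background <- sort(unique(df$gene_id))
  repeat_catalog(sets[meta$key], background, specs)
}

## TSV writer used by every stage: optional '# ...' header comment, tabs,
## no quoting, no rownames — deterministic byte output.
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write every input of a simulated cohort as plain-text files
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_sim_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c()
  cm <- cohort$counts
  counts_df <- data.frame(gene_id = rownames(cm$counts),
                          cm$counts, check.names = FALSE)
  f["counts"] <- write_tsv(counts_df, file.path(dir, "counts.tsv"))
  samples <- data.frame(sample_id = colnames(cm$counts),
                        condition = cm$condition,
                        phenotype = cm$phenotype)
  f["samples"] <- write_tsv(samples, file.path(dir, "samples.tsv"))
  if (!is.null(cohort$sequences))
    f["fasta"] <- write_transcripts(cohort$sequences,
                                    file.path(dir, "transcripts.fasta"))
  f["tf_ranks"] <- write_tsv(cohort$tf$table,
                             file.path(dir, "tf_ranks.tsv"))
  f["tf_edges"] <- write_tsv(cohort$tf$edges,
                             file.path(dir, "tf_edges.tsv"))
  f["gmt"] <- write_gmt(cohort$gene_sets, file.path(dir, "sets.gmt"))
  f["catalog"] <- write_catalog_tsv(cohort$catalog,
                                    file.path(dir, "catalog.tsv"))
  truth <- cohort$truth
  truth_json <- unclass(truth)
  truth_json$expected_ratio <- expected_enrichment_ratio(truth)
  f["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_json, f["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  f
}
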