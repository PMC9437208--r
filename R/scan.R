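#' Scan one transcript sequence for tandem trinucleotide repeat runs
#'
#' Finds every maximal run of at least `spec$min_units` consecutive copies of
#' the motif unit (or, when paired, its reverse complement), tolerating up to
#' `spec$max_mismatches` mismatched nucleotides per `3 * min_units` window.
#' Matching is phase-free: each window is compared against all three cyclic
#' rotations of each searched unit, so runs are found in any reading frame,
#' mirroring what an alignment-based search would report.  `N` bases never
#' match any motif base.
#'
#' A window of length `3k` (`k = min_units`) qualifies when its Hamming
#' distance to `k` tandem copies of any rotation of a searched unit is at
#' most `max_mismatches`.  Each qualifying window is assigned to the unit
#' with the fewer mismatches (ties break to the lexicographically smaller
#' unit).  Overlapping qualifying windows of the same assigned unit are
#' merged into one maximal run that reports the total units covered and the
#' minimum mismatch count of any window inside it.  When overlapping windows
#' start out of phase the merged interval need not be a multiple of 3; the
#' run then reports `floor(length/3)` units.
#'
#' @param seq a single DNA string over A/C/G/T/N (case-insensitive).
#' @param spec a [motif_spec()].
#' @return A data.frame with columns `start` (0-based), `end` (half-open),
#'   `matched_unit`, `n_units`, `n_mismatches`, sorted by `start`.
#' @examples
#' scan_sequence(paste0("AAA", strrep("CTG", 6), "AAA"),
#'               motif_spec("CTG", min_units = 6))
#' @export
scan_sequence <- function(seq, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  if (length(seq) != 1L || !is.character(seq))
    stop("'seq' must be a single character string")
  si <- utf8ToInt(toupper(seq))
  bad <- which(!si %in% c(65L, 67L, 71L, 84L, 78L))  # A C G T N
  if (length(bad))
    stop("non-DNA character '", intToUtf8(si[bad[1]]), "' at position ",
         bad[1], " (1-based); only A/C/G/T/N are allowed")
  n <- length(si)
  L <- 3L * spec$min_units
  empty <- data.frame(start = integer(), end = integer(),
                      matched_unit = character(), n_units = integer(),
                      n_mismatches = integer(), stringsAsFactors = FALSE)
  if (n < L) return(empty)

  units <- spec_units(spec)
  n_win <- n - L + 1L
  ## per unit: minimum window mismatches over the 3 rotations, all starts;
  ## comparing window i against k copies of rotation r is comparing the
  ## sequence against one of the 3 phase-shifted periodic templates
  mism <- matrix(NA_integer_, nrow = n_win, ncol = length(units))
  for (ui in seq_along(units)) {
    u <- utf8ToInt(units[ui])
    best <- rep.int(.Machine$integer.max, n_win)
    for (a in 0:2) {
      tpl <- rep_len(u[((0:2 + a) %% 3L) + 1L], n)
      cs <- c(0L, cumsum(si != tpl))
      ws <- cs[(L + 1L):(n + 1L)] - cs[seq_len(n_win)]
      best <- pmin.int(best, ws)
    }
    mism[, ui] <- best
  }

  qual <- mism <= spec$max_mismatches
  any_q <- which(rowSums(qual) > 0L)
  if (!length(any_q)) return(empty)
  ## assign each qualifying window to the best unit (lexicographic tie-break:
  ## 'units' is sorted, max.col(ties.method = "first") picks the smaller one)
  pick <- max.col(-mism[any_q, , drop = FALSE], ties.method = "first")

  hits <- empty
  for (ui in seq_along(units)) {
    st <- any_q[pick == ui]
    st <- st[mism[st, ui] <= spec$max_mismatches]
    if (!length(st)) next
    runs <- merge_windows(st, mism[st, ui], L)
    runs$matched_unit <- units[ui]
    hits <- rbind(hits, runs)
  }
  hits <- hits[order(hits$start, hits$matched_unit), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("start", "end", "matched_unit", "n_units", "n_mismatches")]
}

## Merge overlapping qualifying windows (1-based starts, fixed length L)
## into maximal runs; 0-based half-open coordinates on output.
merge_windows <- function(starts, mismatches, L) {
  o <- order(starts)
  starts <- starts[o]; mismatches <- mismatches[o]
  out_start <- integer(); out_end <- integer(); out_mm <- integer()
  cur_start <- starts[1]; cur_end <- starts[1] + L
  cur_mm <- mismatches[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] < cur_end) {          # overlap: extend the run
      cur_end <- max(cur_end, starts[i] + L)
      cur_mm <- min(cur_mm, mismatches[i])
    } else {
      out_start <- c(out_start, cur_start); out_end <- c(out_end, cur_end)
      out_mm <- c(out_mm, cur_mm)
      cur_start <- starts[i]; cur_end <- starts[i] + L
      cur_mm <- mismatches[i]
    }
  }
  out_start <- c(out_start, cur_start); out_end <- c(out_end, cur_end)
  out_mm <- c(out_mm, cur_mm)
  data.frame(start = out_start - 1L, end = out_end - 1L,
             n_units = (out_end - out_start) %/% 3L,
             n_mismatches = out_mm, stringsAsFactors = FALSE)
}

#' Build a repeat catalog over a transcriptome
#'
#' Scans one representative transcript per gene against a grid of motif
#' specifications and records, for each specification, the set of genes with
#' at least one qualifying run, together with the full background universe
#' scanned.  Gene identifiers must already be unique (one transcript per
#' gene); duplicates are rejected rather than silently collapsed.
#'
#' @param transcripts a named character vector of DNA sequences (names are
#'   gene ids), or a `Biostrings::DNAStringSet`.
#' @param specs a single [motif_spec()] or a list of them.
#' @return An object of class `repeat_catalog`: a list with `sets` (named
#'   list of gene-id character vectors, one per spec), `specs`, and
#'   `background` (all scanned gene ids).
#' @export
build_catalog <- function(transcripts, specs) {
  if (inherits(transcripts, "DNAStringSet"))
    transcripts <- stats::setNames(as.character(transcripts),
                                   names(transcripts))
  if (length(transcripts) &&
      (is.null(names(transcripts)) || any(!nzchar(names(transcripts)))))
    stop("'transcripts' must be named by gene id")
  dup <- names(transcripts)[duplicated(names(transcripts))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         "; supply one representative transcript per gene")
  if (inherits(specs, "motif_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "motif_spec")))
  names(specs) <- vapply(specs, spec_key, "")

  sets <- lapply(specs, function(sp) {
    has <- vapply(transcripts, function(sq) nrow(scan_sequence(sq, sp)) > 0L,
                  TRUE)
    sort(names(transcripts)[has])
  })
  repeat_catalog(sets, background = names(transcripts), specs = specs)
}

#' Construct a repeat catalog from explicit gene sets
#'
#' Low-level constructor used by [build_catalog()] and by simulations that
#' plant repeat membership directly without generating sequences.
#'
#' @param sets named list of gene-id character vectors; names are spec keys
#'   of the form `"CTG/CAG:k6:m2"` (or any unique label when `specs` carries
#'   the metadata).
#' @param background character vector: every gene id scanned.
#' @param specs optional named list of [motif_spec()] objects parallel to
#'   `sets`.
#' @return A `repeat_catalog`.
#' @export
repeat_catalog <- function(sets, background, specs = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  background <- as.character(background)
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  out <- lapply(sets, setdiff, y = background)
  if (any(lengths(out) > 0L))
    stop("catalog set contains gene id(s) absent from the background")
  if (!is.null(specs)) {
    stopifnot(length(specs) == length(sets))
    names(specs) <- names(sets)
  }
  structure(list(sets = sets, specs = specs, background = background),
            class = "repeat_catalog")
}

#' @export
print.repeat_catalog <- function(x, ...) {
  cat("<repeat_catalog> ", length(x$sets), " spec(s), background ",
      length(x$background), " genes\n", sep = "")
  for (k in names(x$sets))
    cat("  ", k, ": ", length(x$sets[[k]]), " genes\n", sep = "")
  invisible(x)
}

#' Genes matching one catalog entry
#'
#' @param catalog a `repeat_catalog`.
#' @param spec a [motif_spec()] or a spec key string naming the entry.
#' @return Character vector of gene ids.
#' @export
catalog_genes <- function(catalog, spec) {
  key <- if (inherits(spec, "motif_spec")) spec_key(spec) else spec
  if (!key %in% names(catalog$sets))
    stop("catalog has no entry '", key, "'; available: ",
         paste(names(catalog$sets), collapse = ", "))
  catalog$sets[[key]]
}

#' Summarise a repeat catalog
#'
#' One row per specification: the number of matching genes and their
#' prevalence in the scanned background.  Rows are ordered by
#' (motif, min_units, max_mismatches).
#'
#' @param catalog a `repeat_catalog` with a non-empty background.
#' @return data.frame with columns `motif`, `k`, `m`, `n_genes`,
#'   `prevalence`.
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  if (!length(catalog$background))
    stop("catalog background is empty; nothing to summarise")
  if (is.null(catalog$specs))
    stop("catalog carries no motif_spec metadata")
  df <- data.frame(
    motif = vapply(catalog$specs, spec_label, ""),
    k = vapply(catalog$specs, function(s) s$min_units, 0L),
    m = vapply(catalog$specs, function(s) s$max_mismatches, 0L),
    n_genes = lengths(catalog$sets),
    stringsAsFactors = FALSE)
  df$prevalence <- df$n_genes / length(catalog$background)
  df <- df[order(df$motif, df$k, df$m), , drop = FALSE]
  rownames(df) <- NULL
  df
}
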