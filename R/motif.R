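#' Define a trinucleotide repeat query
#'
#' A motif specification describes one repeat search: a 3-letter DNA unit,
#' whether its reverse complement is searched alongside it (CTG pairs with
#' CAG), the minimum number of consecutive units, and a per-window mismatch
#' budget.  "k repeats" always means *at least* k consecutive units, so a
#' 7-unit run satisfies a 6-unit query.
#'
#' @param unit 3-letter DNA string over A/C/G/T, e.g. `"CTG"`.
#' @param include_complement if `TRUE` (default) the reverse complement of
#'   `unit` is searched as well and hits report which member matched.
#' @param min_units minimum number of consecutive units, integer >= 2.
#' @param max_mismatches mismatched nucleotides tolerated within one
#'   `3 * min_units` window; must be `<= 3 * min_units - 1`.
#' @return An object of class `motif_spec`.
#' @examples
#' motif_spec("CTG", min_units = 6, max_mismatches = 2)
#' @export
motif_spec <- function(unit, include_complement = TRUE, min_units = 6L,
                       max_mismatches = 0L) {
  unit <- toupper(as.character(unit))
  if (nchar(unit) != 3L || grepl("[^ACGT]", unit))
    stop("'unit' must be a 3-letter string over A/C/G/T, got '", unit, "'")
  min_units <- as.integer(min_units)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(min_units) || min_units < 2L)
    stop("'min_units' must be an integer >= 2")
  if (is.na(max_mismatches) || max_mismatches < 0L ||
      max_mismatches > 3L * min_units - 1L)
    stop("'max_mismatches' must lie in [0, 3*min_units - 1]")
  structure(
    list(unit = unit,
         include_complement = isTRUE(include_complement),
         min_units = min_units,
         max_mismatches = max_mismatches),
    class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("<motif_spec> ", spec_label(x), ": >=", x$min_units,
      " units, <=", x$max_mismatches, " mismatches per window\n", sep = "")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", toupper(seq))
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

## Units actually searched: the unit itself plus (optionally) its reverse
## complement, deduplicated (palindromic pairs collapse).
spec_units <- function(spec) {
  u <- spec$unit
  if (spec$include_complement) u <- unique(c(u, reverse_complement(u)))
  sort(u)
}

## Canonical pair label, e.g. "CTG/CAG" (unit first, complement second) or
## just "CTG" when unpaired.
spec_label <- function(spec) {
  if (spec$include_complement) {
    rc <- reverse_complement(spec$unit)
    if (rc != spec$unit) return(paste0(spec$unit, "/", rc))
  }
  spec$unit
}

## Unique key identifying a spec inside a catalog.
spec_key <- function(spec) {
  sprintf("%s:k%d:m%d", spec_label(spec), spec$min_units, spec$max_mismatches)
}

## TRUE when the spec's unit pair is the CTG/CAG family (the disease motif);
## used to separate multiple-testing families in enrichment grids.
spec_is_ctg_cag <- function(spec) {
  any(spec_units(spec) %in% c("CTG", "CAG"))
}

## The 3 cyclic rotations of a 3-mer.
rotations3 <- function(unit) {
  u <- strsplit(unit, "", fixed = TRUE)[[1]]
  vapply(0:2, function(a)
    paste(u[((seq_len(3) - 1L + a) %% 3L) + 1L], collapse = ""), "")
}

## Every 3-mer the scanner accepts for this spec: all rotations of both
## pair members.  Motif families that are rotations of each other (e.g.
## GCG/CGC vs CGG/CCG) therefore match identical windows.
spec_rotation_set <- function(spec) {
  sort(unique(unlist(lapply(spec_units(spec), rotations3))))
}
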