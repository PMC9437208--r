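---
title: "Detecting dysregulation of endogenous CTG/CAG-repeat genes"
author: "tritarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dysregulation of endogenous CTG/CAG-repeat genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritarget)
```

## The scientific question

Myotonic dystrophy type 1 (DM1) is caused by an expanded CTG repeat in the
3'UTR of *DMPK*.  The expanded repeat is transcribed (bidirectionally, so
both CUG and CAG repeat RNAs exist), folds into long hairpins, and can be
processed by Dicer into ~18-nt repeat-derived small interfering RNAs.  If
those siRNAs act through the RNA-interference machinery, genes whose own
transcripts carry complementary endogenous repeat runs — roughly six
consecutive CTG or CAG units, since 6 × 3 nt ≈ 18 nt — become candidate
silencing targets, and should be over-represented among the genes that
change expression in patient tissues.

`tritarget` implements that analysis end to end on gene-level RNA-seq
counts: it catalogs repeat-bearing genes from transcript sequences, runs a
differential-expression (DE) workflow, quantifies the over-representation
of repeat-bearing genes among DE genes across motifs, repeat lengths and
fold-change thresholds, tests whether repeat-bearing transcription factors
rank highly in an upstream target-enrichment analysis, measures how much
of the DE set a repeat-TF regulatory network covers, compares DE sets
across cohorts, and correlates expression with a clinical severity
phenotype.  A fully parameterised synthetic cohort generator encodes the
assumed data-generating process so that every statistic can be validated
against planted ground truth.

## The repeat scanner

The scanner replaces an alignment-based repeat search with an explicit,
testable algorithm.  A query is a `motif_spec`: a 3-mer unit, whether its
reverse complement is searched alongside (CTG pairs with CAG), a minimum
unit count `k`, and a mismatch budget `m`.  A window of `3k` nucleotides
qualifies when its Hamming distance to `k` tandem copies of *any of the
three cyclic rotations* of either paired unit is at most `m`; overlapping
qualifying windows of the same matched unit merge into one maximal run.
Design choices worth knowing:

* **Phase-free matching.** An alignment search finds a repeat run in any
  reading phase, so the scanner tests all three rotations.  A consequence
  is that rotation-equivalent families collapse: a (GCG)~n~ run *is* a
  (CGG)~n~ run read one base later, so the GCG/CGC and CGG/CCG queries
  accept identical windows.  Both labels are kept in the default grid for
  interface parity, but their gene sets coincide by construction.
* **At-least-k semantics.** "k repeats" means at least `k` consecutive
  units, so gene sets shrink weakly as `k` grows and grow weakly as `m`
  grows; these nesting properties are enforced by tests.
* **Mismatch defaults.** The default grid searches k = 4..7 with `m = 0`
  for k ∈ {4, 5} and `m = 2` for k ∈ {6, 7}, attaching the mismatch
  tolerance to the lengths where near-perfect siRNA complementarity is
  biologically plausible.
* **`N` handling.** `N` never matches a motif base, so masking can only
  remove or degrade hits.
* **Determinism.** When a window qualifies for both members of a pair with
  equal mismatches, the lexicographically smaller unit wins.  Coordinates
  are 0-based half-open.  Merged runs whose interval union is not a
  multiple of 3 (possible only when mismatched windows overlap out of
  phase) report `floor(length / 3)` units.

## Differential expression

The DE module follows standard count-based practice: genes are kept when
their CPM exceeds 1 in *every* sample of at least one condition (so
condition-specific genes, e.g. strongly silenced ones, survive);
between-sample scaling uses TMM (30% M-trim, 5% A-trim, precision
weights, factors rescaled to geometric mean 1, via `edgeR`); expression is
log2 CPM with a 0.5 prior count.  Testing uses a moderated two-sample t:

$$ \tilde s^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
   \qquad t_g = \frac{\Delta \bar x_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}}, $$

with pooled within-group variance $s^2_g$, residual degrees of freedom
$d_g = n_1 + n_2 - 2$, prior variance $s_0^2$ set to the median pooled
variance, prior degrees of freedom $d_0 = 4$, and p-values from the t
distribution with $d_0 + d_g$ df.  This is a deliberately simple
moderated-t scheme — not a reimplementation of limma-voom's
precision-weight model — and it is documented as such; `read_de_table()`
lets users inject an externally produced DE table (gene, logFC, p, q)
whenever exact limma output is preferred.  The log-fold change is the
difference of group-mean log-CPMs, which is what the fold-change gates
act on; q-values are Benjamini–Hochberg.  Calibration is verified on
fully null simulated cohorts (uniform raw p-values, essentially no
q < 0.05 discoveries).

Two small facts that the test suite encodes because they are easy to get
wrong: TMM factors live on the CPM scale, so multiplying a whole column
by a constant changes that sample's library size but *not* its factor;
and log-CPM "scale invariance" under doubling of counts and library sizes
holds only up to the prior count, i.e. asymptotically in the counts.

## Enrichment of repeat-bearing genes

The central statistic is the observed/expected ratio: among `n_de` DE
genes, the number also in a repeat set of prevalence `K/N` has expectation
`n_de * K / N`; the ratio divides the observed overlap by that
expectation, and a two-sided Fisher exact test (hypergeometric
point-probability summation) supplies the p-value.  The grid crosses every
catalog entry with fold-change thresholds (default 1, 1.5, 2) and
directions (up, down, both).  Choices:

* **Background** is the set of genes surviving the expression filter in
  the tissue and present in the catalog — prevalence is a property of the
  expressed transcriptome, not of the whole annotation.
* **Two multiple-testing families.** The CTG/CAG cells are BH-adjusted
  separately from the control-motif cells (CGG, CGT, GAA, GCG), so a true
  disease-motif signal is not penalised by the size of the control panel
  and the controls provide an honest negative panel.
* **The "at least two genes" rule** from bar-chart displays is a
  `displayable` flag only; statistics are never filtered by it.
* Generic over-representation against user-supplied GMT collections
  (pathways, predicted miRNA-target sets) uses the one-sided
  hypergeometric upper tail with BH across the collection; sets smaller
  than 3 after background intersection are skipped.

## Transcription factors, networks, cohorts, phenotype

TF analysis consumes an externally produced ranking (the upstream
target-enrichment engine is a database product, not reimplemented).  TFs
are flagged repeat-bearing by membership in the 6-unit CTG/CAG catalog
set, and a one-sided two-sample Kolmogorov–Smirnov test asks whether
carrier ranks are stochastically smaller (better) than the rest of the
significant TFs; exact p-values are used at small sample sizes (ranks are
unique, so there are no ties).  Network coverage is the fraction of DE
genes with at least one incoming edge from a repeat-bearing TF in a
TF→gene edge table.

Cross-cohort comparison counts genes DE in exactly 1..n cohorts and tests
whether the reference cohort's repeat-bearing DE genes are re-detected in
at least one other cohort more often than the remaining DE genes
(one-sided Fisher; the hypothesis is directional).  Overlap is
direction-agnostic by default, matching how up- and downregulated genes
are pooled in practice; a direction-matched mode exists.

Phenotype analysis computes the per-gene Pearson correlation between
normalized expression and a continuous severity score (e.g. normalized
dorsiflexion strength) across samples with a non-missing score, with
p-values from the t transform $t = r\sqrt{(n-2)/(1-r^2)}$ and BH within
the tested subset.  Controls are included by default (the score exists
for them too and anchors the healthy end of the scale); zero-variance
genes are flagged and excluded from the adjustment.

## The synthetic cohort generator

`sim_truth()` collects every parameter of the assumed data-generating
process; the defaults are the package's reference study conditions and
are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | desk-scale transcriptome |
| `motifs` | CTG, k = 6, m = 0, prevalence 0.1 | planted repeat runs |
| `mu_log2` | N(4, 1.8) | baseline log2 relative abundance (CPM-like) |
| dispersion | lognormal(log 0.1, 0.4) | per-gene NB dispersion |
| `pi0` | 0.05 | DE probability, non-repeat genes |
| `rho` | 3 | relative DE risk of CTG/CAG carriers |
| `delta` | 0.7 | P(down) for DE carriers (silencing bias) |
| `lfc_range` | U(1, 2.5) | planted |log2FC| |
| `severity_range` | U(0.3, 1) | per-case severity; controls 0 |
| `sigma_y` | 0.1 | phenotype noise; y = 1 − severity + ε |
| `lib_size_range` | U(1e6, 2e6) | library sizes |
| `seq_length` | 1500 nt | transcript length |

Counts are negative-binomial around per-sample expected counts obtained
by softmax-normalising per-gene log2 abundances, so planted effects are
compositional exactly as in real libraries.  A case's realised effect is
`severity * |log2FC|`, which ties expression change, sample ordination
and the phenotype score together: the phenotype decreases in severity,
mimicking a strength measurement.  The closed-form expected enrichment
ratio implied by the truth, $\rho / (1 - prev + \rho \cdot prev)$, is
attached to every simulated cohort and is what ratio-recovery tests
compare against.  Multi-cohort structure is modelled by sharing the
repeat genes' DE plan across cohorts (`sim_de_plan()`), while non-repeat
dysregulation stays cohort-specific — the replication asymmetry the
cross-cohort test is designed to detect.

Transcript sequences are uniform random DNA rejection-resampled against
the scanner itself so that no *unplanted* qualifying run exists for any
analysis spec, and planted runs are re-verified after insertion; planted
labels and scanned catalogs therefore agree exactly, trading generation
speed for exactness.  The `tibialis-like` preset (40 cases / 10 controls,
nested CTG/CAG prevalences 0.12/0.06/0.05/0.034 for k = 4..7, four
control motifs, biased TF ranks, 50% wired network coverage) mirrors the
scale and structure of a distal-muscle biopsy cohort; the `null` preset
keeps the shape with no planted association.

What the generator does *not* emulate: splicing (and hence
splicing-factor sequestration effects), UTR/CDS positional structure,
gene length and GC biases, batch effects, and correlated gene modules.
Passing tests therefore demonstrate that the statistics are correct and
calibrated under the assumed model, not that the biological mechanism
holds in any particular real cohort.

## Numerical and testing choices

Fisher p-values are computed by direct hypergeometric summation with the
same `1 + 1e-7` relative tolerance as `stats::fisher.test`, and the test
suite checks them against an independent `lchoose`-based enumeration over
every 2×2 table with universe size up to 60.  BH adjustment, UPGMA
(average linkage, verified against a textbook agglomerator via cophenetic
matrices on all instances with ≤ 8 items), and the exact small-sample KS
distribution are cross-checked the same way.  PCA uses SVD on gene-wise
mean-centred data with a deterministic sign convention (largest-magnitude
loading positive).  Property and calibration tests run at 2000 genes with
20 case / 10 control (or smaller) cohorts and 20 replicate seeds — sizes
chosen so the whole suite exercises every guarantee at desk scale; the
discrete exact KS null means its rejection rate at 0.05 sits slightly
below nominal (the largest attainable p under 0.05), which the
calibration band accounts for.

## Limitations

* The moderated-t surrogate does not model the mean–variance trend within
  a dataset (no per-observation precision weights); very low-count genes
  are handled by the CPM filter rather than by weighting.
* The scanner is transcript-level: it records run positions but performs
  no UTR/CDS annotation, no genome/intron scanning, and no repeat-length
  genotyping of the expansion itself.
* Upstream database products (TF target libraries, pathway and
  miRNA-target collections) are consumed as input files; their content is
  outside the package's scope.
* Rotation-equivalent motif families are indistinguishable by design (see
  above); treat the control panel as four labels over three independent
  families.
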