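# tritarget

Transcriptome-wide detection of dysregulated genes that carry endogenous
trinucleotide repeat runs — the putative targets of repeat-derived small
interfering RNAs in CTG-repeat expansion disease (myotonic dystrophy
type 1).

In DM1 the expanded CTG repeat in the *DMPK* 3'UTR is transcribed into
long hairpin RNA that Dicer can process into ~18-nt siRNAs.  Genes whose
own transcripts contain roughly six consecutive CTG or CAG units
(6 × 3 nt ≈ 18 nt) are candidate silencing targets.  `tritarget` is for
computational biologists who want to test that hypothesis on gene-level
RNA-seq count data: it catalogs repeat-bearing genes from transcript
FASTA, runs differential expression, and quantifies whether
repeat-bearing genes are over-represented among the dysregulated ones.

## The core statistic

For a repeat catalog entry with `K` carrier genes in an expressed
background of `N` genes, and `n_de` differentially expressed genes of
which `x` are carriers, the package reports the enrichment ratio

    ratio = x / E[x],   E[x] = n_de * K / N

with a Fisher exact p-value (two-sided, hypergeometric point-probability
summation) on the corresponding 2×2 table, over a grid of motifs
(CTG/CAG plus control motifs CGG/CGT/GAA/GCG), repeat lengths
(k = 4..7, with 2 mismatches tolerated at k ≥ 6), directions (up / down
/ both) and fold-change thresholds (1, 1.5, 2), BH-adjusted with the
disease-motif and control-motif families kept separate.  Around it sit:
a phase-free mismatch-tolerant repeat scanner; a TMM / log-CPM /
moderated-t DE workflow (BH FDR); PCA and UPGMA sample structure; a
one-sided Kolmogorov–Smirnov test on the ranks of repeat-bearing
transcription factors; TF→gene network coverage of the DE set;
cross-cohort replication tests; per-gene phenotype correlation; and a
negative-binomial cohort simulator with planted, severity-scaled
repeat-gene silencing that provides ground truth for every statistic.

## Worked example

Simulate a cohort with the documented study conditions (2000 genes, 10%
CTG/CAG carrier prevalence, carriers at 3× relative risk of
dysregulation, 20 cases vs 10 controls), run the DE workflow, and test
carrier enrichment:

```r
library(tritarget)

tr  <- sim_truth(seed = 42)                 # rho = 3, prevalence 0.1
lab <- simulate_labels(tr)
cm  <- simulate_counts(tr, lab, n_case = 20, n_control = 10)
det <- de_analysis(cm, fc_threshold = 1.5)
det
#> <de_table> 1999 genes; up 55, down 63, ns 1881

cat6 <- planted_catalog(lab, motif_spec("CTG", TRUE, 6, 0))
grid <- enrichment_grid(det, cat6, fc_thresholds = c(1, 1.5),
                        directions = "both")
grid[, c("spec", "fc_threshold", "n_de_repeat", "n_de", "expected",
         "ratio", "fisher_p", "q")]
#>            spec fc_threshold n_de_repeat n_de expected    ratio     fisher_p            q
#> 1 CTG/CAG:k6:m0          1.0          30  123 12.30615 2.437805 1.305368e-06 1.695814e-06
#> 2 CTG/CAG:k6:m0          1.5          29  118 11.80590 2.456398 1.695814e-06 1.695814e-06

expected_enrichment_ratio(tr)
#> [1] 2.5
```

Of 123 significant genes (q < 0.05), 30 carry a planted 6-unit CTG/CAG
run where 12.3 were expected from the 10% carrier prevalence — an
enrichment ratio of 2.44, against the generator's closed-form expectation
of 2.5 (`rho / (1 - prev + rho * prev)`), with a Fisher q of about 2e-6.
The per-sample phenotype (a strength-like score decreasing in disease
severity) correlates strongly with individual silenced genes:

```r
head(gene_phenotype_correlation(attr(det, "normalized")), 3)
#>   gene_id          r            p            q  n zero_variance
#> 1  G01099 -0.9459026 3.229366e-15 6.455502e-12 30         FALSE
#> 2  G01123  0.9283690 1.474177e-13 1.268763e-10 30         FALSE
#> 3  G00130 -0.9270030 1.904096e-13 1.268763e-10 30         FALSE
```

For real data, replace the simulated pieces with files:
`read_transcripts()` + `build_catalog()` for the repeat catalog,
`read_count_matrix()` for counts and sample sheet, and either the
built-in DE workflow or an injected external DE table
(`read_de_table()`).  `run_pipeline(pipeline_config(...))` orchestrates
every stage from a single validated configuration and writes one
versioned, deterministic table per stage; `simulate_cohort("tibialis-like",
seed, dir = ...)` emits a complete synthetic input set (FASTA, counts,
sample sheet, TF ranking and edges, GMT, truth JSON).

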