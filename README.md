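# apdtsig

Analysis of androgen-pathway-directed-therapy (APDT) response in
patient-derived prostate cancer organoids.

Organoid cultures grown from a bone-metastasis patient-derived xenograft are
heterogeneous: every organoid potentially represents a different tumour
clone, so classical replicate-based differential-expression statistics fit
the design poorly. `apdtsig` implements a query-based alternative built for a
design of two independent experiments, each with four arms — androgen
withdrawal (`NODHT`), androgen agonist (`DHT`, 1 nM), agonist + vehicle
(`VEH`), and agonist + enzalutamide (`ENZA`, 10 µM) — with a single bulk
RNA-seq sample per arm. The package also quantifies the downstream phenotypes
of APDT resistance: gene-set enrichment of the signature, splice-variant
screening by exon read depth, enzalutamide-induced reversible dormancy read
out by the Fucci2BL live cell-cycle reporter, and cyst/spheroid morphometry.

## The method

Expression is normalised to RPKM,
`RPKM = count x 10^9 / (transcript_length_bases x total_mapped_reads)`,
and genes with no mapped reads in any sample are set aside. For each
expressed gene the four APDT-vs-control log2 fold changes are

    FC_e,m = log2((APDT_e,m + c) / (control_e,m + c)),
    e in {Experiment 1, Experiment 2},  m in {NODHT vs DHT, ENZA vs VEH},

with pseudocount `c` (default 0.5 RPKM). The signature is built by:

1. **Concordance filter** — keep genes whose four fold changes share one
   sign and all reach `min_abs_log2fc` (default 0.5) in magnitude.
2. **Inverse-variability ranking** — score each gene by the mean coefficient
   of variation within the biologically equivalent same-treatment arms
   ({DHT, VEH} and {NODHT, ENZA}, pooled over experiments); combine the rank
   by descending mean |log2FC| with the rank by ascending variability into a
   rank product (ties broken by gene id).
3. **Four-class signature** — cross the response direction with the
   control-arm expression stratum (HIGH/LOW mean RPKM over {DHT, VEH}),
   giving DOWN_HIGH / DOWN_LOW / UP_HIGH / UP_LOW.

Signature genes are tested for over-representation in merged functional
categories by the fold-enrichment score `E = (k/K) / (n/N)` (`N` universe
genes, `n` signature genes, `K` category genes, `k` their overlap) with a
Fisher 2x2 exact test p-value.

Every input has a synthetic generator with planted ground truth
(`simulate_expression()`, `simulate_gene_sets()`, `simulate_fucci()`,
`simulate_masks()`), so the whole pipeline is testable without sequencing
data.

## Worked example

```r
library(apdtsig)

# study-design fixture: 17,004 genes, 787 planted responders, CV 0.2
sim <- simulate_expression(sim_config(seed = 1))
fit <- apdt_signature(sim$expr)
print(fit)
#> APDT response signature: 787 of 17004 genes
#>
#> DOWN_HIGH  DOWN_LOW   UP_HIGH    UP_LOW
#>       313       203       172        99
#> min |log2FC|: 0.5  pseudocount: 0.5  high/low RPKM threshold: 15.26
```

The fit recovers a 787-gene signature whose class counts match the planted
composition (312/206/171/98) to within a few genes; the high/low RPKM
threshold is derived from the control-arm expression of the retained genes.
Enrichment of the signature in simulated categories planted at 5-fold
over-representation:

```r
sets <- simulate_gene_sets(sim$truth, n_sets = 5, enrichment_factor = 5,
                           seed = 2)
res <- enrich_all(sets, fit, rownames(sim$expr$rpkm))
res[, c("category", "N", "K", "n", "k", "E", "p")]
#>   category     N    K   n   k        E             p
#> 1  SET0001 17004 1976 787 399 4.362770 4.660554e-172
#> 2  SET0002 17004 1074 787 263 5.290879 9.324176e-126
#> 3  SET0004 17004  873 787 193 4.776606  5.457045e-81
#> 4  SET0003 17004  809 787 178 4.753876  7.040569e-74
#> 5  SET0005 17004  515 787 114 4.782709  1.108763e-46
```

Dormancy under four weeks of enzalutamide followed by washout:

```r
traces <- classify_traces(simulate_fucci(seed = 3))
frac <- dormancy_fraction(traces)
frac$g0_fraction
#> [1] 0.450 0.540 0.755 0.895 0.275
reversibility_test(frac, c("ENZA","ENZA","ENZA","ENZA","VEH"))$verdict
#> [1] "REVERSED"
```

The G0 (red-only) fraction climbs to 0.895 by week 4 and collapses to 0.275
one week after enzalutamide removal — the reversible-dormancy phenotype.

An end-to-end run writing all stage outputs plus a checksummed manifest:

```r
run_pipeline(default_pipeline_config("run1", seed = 1))
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --out run1 --seed 1`.

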