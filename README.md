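# xenores

Analysis toolkit for dual-species xenograft sequencing studies of
acquired drug resistance — human tumor cells growing in mouse brain (or
flank), profiled by bulk RNA-seq against a combined human+mouse
annotation, tracked by bioluminescence imaging, and compared by
whole-exome sequencing before and after resistance emerges.

It is written for the computational side of such a study: the bespoke
statistics that sit *between* the standard upstream tools (alignment,
counting, DE model fitting, variant calling — all out of scope and
consumed as tables) and the figures.

## What it computes

**Cross-species contamination filter.** Reads from one species
occasionally align to genes of the other. From species-pure control
libraries, the per-gene cross-mapping rate for human gene *g* is the
pooled ratio

    ĉ_g = Σ_s counts(g, s) / Σ_s mouse_gene_total(s)     (s over mouse-only controls)

and symmetrically for mouse genes. In a xenograft sample *x* the
predicted contamination is ĉ_g · M_x; a gene is excluded when the mean
predicted fraction ĉ_g M_x / k_gx over xenograft samples strictly
exceeds 10%.

**Normalization.** Median-of-ratios size factors, a log
variance-stabilizing transform `log2(k/s + 1)`, and RPKM.

**Signature scoring.** Per-sample mean of median-centered transformed
expression over a signature gene set; median split into high/low strata
(ties go low); per-cell uncentered means for single-cell data; Welch *t*
group comparisons.

**Enrichment.** Gene ranking by `sign(log2FC) / adjP`; the classic
(unweighted) Kolmogorov–Smirnov-style running-sum enrichment score with
a gene-set-permutation p-value; hypergeometric over-representation
reported as −log10(p).

**Variant persistence filter.** Two stages: damaging-variant quality
criteria (VQSR pass, MAF ≤ 2×10⁻⁵, DP ≥ 8, GQ ≥ 20, MQ ≥ 40,
PLdiff/DP ≥ 8, non-LCR), then the paired control-vs-resistant
persistence rule (DP > 11 in both samples, alt reads > 2 in the
resistant, ref reads > 2 in the control, NRAF > 0.15 in the resistant,
ΔNRAF > 0.25, called in all four resistant-on-drug in vivo samples),
then an expression gate (mean RPKM > 10).

**Pre-clinical endpoints.** On longitudinal tumor-burden series:
progression-free survival (first post-treatment burden ≥ 2× the last
pre-treatment burden), resistance onset (first burden ≥ 10× the running
post-treatment nadir), metastasis incidence (detection persisting
through two further timepoints), waterfall percent change, trapezoidal
AUC, caliper volume (major × minor² × 0.52) — with exact Mann–Whitney,
Kaplan–Meier, and log-rank tests.

**Synthetic data.** Seeded generators (`sim_config()`, `gen_*()`)
produce every input with planted ground truth: NB dual-species counts
with planted cross-mapping, survival cohorts whose hazard follows a
planted signature, piecewise-exponential burden trajectories, and
variant tables whose decoys each violate one named criterion. The test
suite uses them to verify parameter recovery end to end.

## Worked example

```r
library(xenores)

cfg <- sim_config(seed = 42)            # the stated synthetic world
sim <- gen_dual_species_counts(cfg)     # counts + planted truth
sim$data
#> DualSpeciesCounts: 1000 genes (500 human, 500 mouse) x 10 samples
#>   samples: human_only=2, mouse_only=2, xenograft=6

model <- estimate_crossmap_rates(sim$data)
res <- filter_genes(model, sim$data, threshold = 0.10)
length(res$excluded)
#> [1] 25
head(subset(res$report, decision == "excluded"), 3)
#>    gene_id species    rate mean_pred_fraction decision            reason
#> 4  HG00004   human 0.00242              0.452 excluded crossmap_fraction
#> 66 HG00066   human 0.00474              0.506 excluded crossmap_fraction
#> 90 HG00090   human 0.00298              0.542 excluded crossmap_fraction
setequal(res$excluded, sim$contaminated_genes)
#> [1] TRUE                               # exactly the 25 planted genes
```

The excluded genes are precisely those planted with ~50% cross-mapped
reads; their `mean_pred_fraction` is the model's estimate of that
contamination. Signature scoring and survival stratification on a
simulated cohort:

```r
surv <- gen_survival_cohort(cfg, n_samples = 100)
tab <- stratify_median(score_bulk(surv$expr, surv$signature))
head(tab, 3)
#>   unit_id  score stratum group
#> 1    S001 -0.515     low  <NA>
#> 2    S002  0.414    high  <NA>
#> 3    S003 -0.366     low  <NA>
lr <- logrank_test(surv$survival$time, surv$survival$event, tab$stratum)
sprintf("log-rank chisq = %.1f, p = %.2g", lr$chisq, lr$p)
#> [1] "log-rank chisq = 29.3, p = 6.3e-08"
```

The cohort was generated with hazard ratio 4 for signature-high samples;
the estimated strata separate survival accordingly. Resistance calls on
burden trajectories recover the planted labels:

```r
tra <- gen_burden_trajectories(sim_config(seed = 42, n_animals = 20))
calls <- vapply(tra$series, function(s) resistance_time(s)$resistant, logical(1))
sum(calls); all(calls == tra$truth$resistant)
#> [1] 10
#> [1] TRUE
```

## Command line

An installed `exec/xenores` script exposes the pipeline stages:

```sh
xenores simulate   --seed 1 --out-dir sim --what counts
xenores xenofilter --counts sim/counts.tsv --genes sim/genes.tsv \
                   --samples sim/samples.tsv --out-dir filtered
xenores score      --matrix expr.tsv --signature sig.txt --out scores.tsv
xenores enrich     --de-table de.tsv --gmt sets.gmt --out enrich.tsv
xenores variants   --table variants.tsv --rpkm rpkm.tsv --out-dir vout
xenores endpoints  --burden burden.tsv --treatment-start 21 \
                   --mode resistance --out calls.tsv
```

## Documentation

The methods vignette (`vignettes/xenores-methods.Rmd`) describes the
models, every tunable threshold with its default and strictness
convention, what the synthetic world does and does not emulate, and the
package's design decisions on points the underlying methods leave open.
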