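---
title: "Methods: cross-species filtering, signature scoring and resistance endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species filtering, signature scoring and resistance endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenores)
```

# The analysis problem

Brain-metastasis xenograft studies sequence intact metastatic tissue in
which human tumor cells grow inside mouse stroma. Reads are aligned to a
combined human+mouse annotation, so each library yields counts for genes
of both species — plus an artifact: some reads of one species align to
genes of the other (cross-mapping). `xenores` implements the gene-level
remedies and downstream endpoint statistics such a study needs:

1. estimate per-gene cross-mapping propensity from species-pure control
   libraries and exclude unsalvageable genes (`estimate_crossmap_rates()`,
   `filter_genes()`);
2. normalize and transform counts (`size_factors_median_of_ratios()`,
   `vst_log()`, `rpkm()`);
3. score samples or cells against a resistance/metastasis gene signature
   and stratify cohorts at the median (`score_bulk()`, `score_cells()`,
   `stratify_median()`);
4. rank genes for enrichment analysis and compute the classic running-sum
   enrichment score and a hypergeometric over-representation score
   (`build_rank_statistic()`, `enrichment_score_classic()`,
   `ora_hypergeometric()`);
5. filter somatic variants that persist from a drug-sensitive control
   population into a resistant one (`variant_filter()`);
6. call pre-clinical endpoints on longitudinal tumor-burden series and
   test them (`pfs_time()`, `resistance_time()`, `incidence_call()`,
   `mann_whitney()`, `km_estimate()`, `logrank_test()`).

A seeded synthetic-data module (`sim_config()` and the `gen_*()`
generators) produces every input with planted ground truth, which is how
the package validates itself end to end.

# Cross-mapping model

For human gene $g$, species-pure mouse libraries (sham-injected animals)
expose cross-mapping directly: every read assigned to $g$ there is an
artifact. The pooled estimator is

$$\hat c_g \;=\; \frac{\sum_{s \in \text{mouse-only}} k_{gs}}
                     {\sum_{s \in \text{mouse-only}} M_s},$$

where $k_{gs}$ is the count of gene $g$ in control $s$ and $M_s$ the
total reads mapped to mouse-annotated genes in $s$; symmetrically for
mouse genes over human-only controls. In a xenograft sample $x$ the
predicted contamination of $g$ is $\hat c_g M_x$, and $g$ is **excluded**
when the mean over xenograft samples of
$\hat c_g M_x / k_{gx}$ strictly exceeds 0.10 — contamination exceeding
10% of the reads mapped to that gene. A fraction of exactly 0.10 is
retained.

Choices the source description leaves open, and what this package does:

* **Denominator.** The normalizing total is reads mapped to
  opposite-species *genes* (not raw sequenced reads, not per-kb): it is
  the only observable in a count matrix, and it cancels exactly in the
  predicted fraction, making decisions invariant to global rescaling.
  `pooling = "mean_of_ratios"` averages per-control ratios instead of
  pooling sums; with balanced control depths the two coincide.
* **Aggregation.** The predicted fraction is averaged over xenograft
  samples (`aggregate = "mean"`); `"max"` (exclude if any sample exceeds)
  is exposed and is strictly more aggressive.
* **Zero-count guards.** Observed 0 with predicted > 0 contributes
  fraction 1 (the gene's signal there is plausibly all artifact);
  observed 0 with predicted 0 contributes 0. Genes silent in every
  xenograft sample are excluded as `no_signal` — nothing to analyze.
* **No pseudocounts** in the estimator: a gene with zero control reads
  has $\hat c_g = 0$ and is trivially retained; unbiasedness is worth
  more than shrinkage at the depths this filter targets ($\geq 10^6$
  reads).

# Normalization

`size_factors_median_of_ratios()` is the standard median-of-ratios
estimator over genes expressed in every sample, rescaled so the factors'
geometric mean is 1. The variance-stabilizing transform used downstream
is the log stand-in $\log_2(k/s_j + 1)$, not the parametric
dispersion-based VST: signature scoring median-centers each gene across
the cohort, which absorbs gene-wise offsets, so score *differences* are
insensitive to the exact stabilizer. The transform is tagged in the
returned object so an alternative can be slotted in.

RPKM uses reads mapped to annotated genes as the per-sample total; the
downstream expression gate on variant-bearing genes is strict
(mean RPKM $> 10$; exactly 10 fails).

# Signature scoring and stratification

The bulk score of sample $j$ is
$\frac{1}{|S|}\sum_{g \in S}\,(v_{gj} - \mathrm{med}_{j'}\,v_{gj'})$ over
signature genes $S$ present in the matrix; missing genes are dropped with
a warning, never imputed. Cohorts are split at the median score with a
deterministic tie rule — a score exactly at the median goes **low**,
which is conservative for the "high stratum fares worse" hypothesis.
Per-cell scores are plain uncentered means ("average expression"), with
`center = TRUE` available; no per-gene scaling is applied before
averaging, since none is prescribed. Group comparisons use the Welch
unequal-variance $t$ with Satterthwaite degrees of freedom, with an exact
fast path ($t = 0,\ p = 1$) for degenerate constant groups.

# Enrichment statistics

The ranking statistic is $\mathrm{sign}(\log_2 \mathrm{FC}) / p_{adj}$,
with $p_{adj} = 0$ floored at $10^{-300}$ and ties broken
lexicographically by gene id so ranked lists are reproducible. The
enrichment score is the **classic** (unweighted, exponent-0)
Kolmogorov–Smirnov-style running sum: $+1/n_{hit}$ at set members,
$-1/(N - n_{hit})$ elsewhere, ES = the signed value of maximal absolute
deviation. Internally the running sum is kept on the integer common
denominator $n_{hit}(N-n_{hit})$, so exact ties in $|ES|$ break at the
first index identically everywhere — float accumulation order cannot
flip the sign of a $\pm$-tied extreme.

The permutation $p$-value uses **gene-set permutation** (random same-size
sets from the ranked list), $(1 + \#\{|ES_{perm}| \ge |ES_{obs}|\})/(1 +
n_{perm})$: it needs no sample-level expression, which is the right null
at desk scale, but it is *not* the phenotype-permutation null of the
interactive GSEA application — set-to-set correlation structure is not
preserved. Over-representation uses the upper-tail hypergeometric
probability reported as $-\log_{10}(p)$, a transparent stand-in for
proprietary pathway-tool scores on the same scale.

# Variant persistence filter

Stage one keeps potentially damaging calls (loss-of-function, or
missense predicted deleterious) that pass VQSR, population frequency
(MAF $\le 2\times10^{-5}$ dominant preset; $\le 10^{-3}$ recessive),
DP $\ge 8$, GQ $\ge 20$, MQ $\ge 40$, PLdiff/DP $\ge 8$, and fall outside
low-complexity regions — all inclusive thresholds. Stage two keeps
variants that *persist* from the control (C2D) to the resistant (R2D)
population, all strict: DP $> 11$ in both; alt reads $> 2$ in R2D; ref
reads $> 2$ in C2D; NRAF $> 0.15$ in R2D; NRAF$_R$ − NRAF$_C$ $> 0.25$;
called in all four resistant-on-drug late in vivo (RoL) samples. A final
gate keeps genes with mean RPKM $> 10$.

Conventions: NRAF $=$ alt/DP (depth, not alt+ref, in the denominator —
the conventional VCF reading; configurable); RoL "presence" is a boolean
input column (caller emitted a non-reference genotype), no re-genotyping;
PLdiff is carried as an annotation-time input column and divided by the
min-sample DP. Rejections report the *first* failing criterion in filter
order. Note an implication structure among criteria: DP $> 11$ plus
$\Delta$NRAF $> 0.25$ forces alt$_R \ge 4$ and NRAF$_R > 0.25$, so those
two persistence criteria (and quality DP) can never fail alone; the
synthetic decoy pool covers the thirteen independently violable criteria
and boundary tests cover the rest.

# Burden endpoints

Trajectories are analyzed at observed timepoints only — no interpolation,
matching discrete imaging schedules; dorsal+ventral signal summation is
assumed done upstream, one value per timepoint.

* **PFS**: event at the first post-treatment observation reaching 2.0×
  the last pre-treatment burden, inclusive ("~200%" is read as exactly
  2.0×; the threshold is an argument); otherwise censored at the last
  observation.
* **Resistance**: running nadir of post-treatment burdens is the maximal
  drug response; resistant at the first observation at or above 10× that
  nadir, inclusive.
* **Incidence**: burden above the detection threshold at a timepoint and
  the two following observations (persistence through two subsequent
  imaging sessions).
* **AUC** is trapezoidal on raw (untransformed) burden, windows
  configurable; **percent change** and **Day-0 normalization** are the
  waterfall/relative-burden transforms.
* **Volume** $=$ major × minor² × 0.52 (mm³).

Statistics: Mann–Whitney U with half-credit ties — exact p from the null
U distribution for tie-free data up to $n_A n_B \le 400$, complete
enumeration for tied data while $\binom{n}{n_A} \le 2\times10^5$, then a
tie- and continuity-corrected normal approximation (the returned
`method` says which path ran); Kaplan–Meier product-limit; the standard
O−E log-rank with hypergeometric variance (1 df), returning $p = 1$ with
a warning when there are no events.

# The synthetic world

The generators state one fixed world rather than tunable difficulty:

* **Counts**: negative binomial with variance $\mu + \mu^2\phi$,
  dispersion $\phi = 0.05$ (typical for cell-line-derived bulk RNA-seq;
  $\phi = 0$ degenerates to Poisson), lognormal gene means scaled to
  $10^6$ gene-mapped reads per species library, xenograft libraries an
  even tumor/stroma split. Cross-mapped reads for human gene $g$ in any
  library with mouse material are Poisson(rate$_g$ × realized mouse-gene
  total) — exactly the estimator's model, so recovery is well-posed.
  Default rates put 25/500 planted human genes near 50% contamination
  and everything else near 0.5%, i.e. far on either side of the 10%
  exclusion boundary, emulating the homolog-driven bimodality of real
  cross-mapping.
* **Survival cohorts**: a latent per-sample score; the above-median half
  is planted signature-high with a +1 log2 shift on 50 signature genes
  (Gaussian unit noise); event times exponential with hazard
  0.01/day × hazard ratio 4 for planted-high; administrative censoring
  at day 365 plus exponential dropout at 0.001/day.
* **Burden trajectories**: growth 0.2/day, regression −0.15/day from
  treatment day 21, weekly imaging for 16 timepoints; exactly
  round($n$ × resistant fraction 0.5) animals resume growth 21 days
  after treatment start; lognormal noise σ = 0.1. Planted call days come
  from the closed-form piecewise exponential evaluated on the imaging
  grid.
* **Variants**: positives pass everything with wide margins (e.g.
  NRAF$_R$ = 0.5 vs NRAF$_C$ = 0); each decoy sits at or just past one
  criterion's boundary (DP = 11, ΔNRAF = 0.20 via NRAF$_C$ = 0.3,
  RoL 3/4, mean RPKM = 10, ...).

What the generators do **not** emulate — and therefore what a green test
does not establish: GC/length biases and batch effects in counts; shared
co-expression structure among signature genes; non-proportional hazards
or informative censoring; inter-animal growth-rate heterogeneity and
irregular imaging schedules; sequencing-error structure in allele
counts. The suite demonstrates that the implementations compute their
stated definitions and recover parameters under their own model
assumptions, not that those assumptions hold in any particular dataset.

# Numerical and degenerate-input conventions

Strictness follows the stated wording everywhere: "exceeded 10%" —
exclusion strictly above threshold; "greater than" / "more than" —
strict persistence and RPKM gates; "DP ≥ 8", "MAF ≤ 2e-5" — inclusive
quality gates; "reaches ~200%", "at least 10x" — inclusive endpoint
crossings. Median ties stratify low. Ranked-list ties break by gene id.
The permutation p never returns 0 (the +1/+1 estimator). All generators
`set.seed()` from their config, so identical config and seed give
byte-identical outputs, and seeded helpers restore the caller's RNG
state.

# Limitations

Gene-level exclusion is coarser than read-level disambiguation
(Xenome/XenofilteR-class tools) and discards genuinely expressed genes
with high homology. The log VST stand-in compresses low counts more than
the parametric transform. The gene-set permutation null is liberal
relative to phenotype permutation when set genes are co-regulated.
Variant-filter semantics for PLdiff depend on the upstream annotation's
definition of the PL pair. Endpoint calls are grid-resolution limited:
an event between imaging sessions is dated at the first session that
observes it.
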