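---
title: "Covariate-modulated polygenic enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-modulated polygenic enrichment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question and the approach

Genome-wide association signal for a polygenic trait is not spread uniformly
across the genome: genic categories (introns, UTRs, exons), gene sets, and
linkage disequilibrium (LD) structure all modulate a SNP's propensity to carry
association. `ldenrich` asks whether a set of annotation intervals — in the
motivating application, evolutionary markers such as human accelerated regions
(HAR), segmental duplications (SD) and ohnologs — is enriched in GWAS
association *after* those known modulators are accounted for.

The framework has five stages, each exposed as package functions and driven
end-to-end by `run_full()` or the numbered scripts under `analysis/`:

1. **LD-weighted annotation scores.** A SNP can tag a region it does not
   physically sit in. For SNP $i$ the affiliation score for category $c$ is
   $\mathrm{LDscore}_i = \sum_j \delta_j r^2_{ij}$, summing floored pairwise
   $r^2$ (window $\pm 1$ Mb, values $< 0.2$ set to 0, self pair $= 1$) over
   reference-panel SNPs $j$ inside the category ($\delta_j = 1$). The total-LD
   burden TotLD is the same sum with $\delta \equiv 1$. An isolated SNP inside
   a region scores exactly 1, which motivates the stratification threshold.
2. **Genomic control from intergenic SNPs.** SNPs with all genic LD scores
   exactly zero and no LD partner within 100 kb of a protein-coding gene or
   inside ncRNA/TFBS/miRNA-binding-site intervals form an empirical null set.
   $\lambda_{GC}$ is the median squared z-score of LD-pruned ($r^2 < 0.2$)
   intergenic sets across 100 seeded pruning iterations, divided by the
   $\chi^2_1$ median (computed at run time from `qchisq(0.5, 1)`, not
   hard-coded).
3. **Conditional fold enrichment.** SNPs at or beyond genome-wide significance
   ($-\log_{10} p \ge 7.3$) are removed; the curve is the ratio of the
   stratum's $-\log_{10}p$ exceedance fraction to that of all SNPs across a
   threshold grid. The stratum is `score >= 1`.
4. **PLSR with jackknife inference.** Squared z-scores are regressed on the
   standardized covariate block (intron, exon, 3'UTR, 5'UTR, evolutionary
   score, brain, TotLD) by single-response partial least squares; the model
   order $A$ is the smallest latent-variable count explaining more than 99 %
   of descriptor variance. Significance comes from approximate t-tests with
   delete-group jackknife variances over 50 LD-aware cross-validation folds.
5. **Matched controls.** Random SNP sets matched to an annotation's physical
   SNPs on minor allele frequency and TotLD isolate how much of the observed
   enrichment LD and allele frequency alone produce.

# Models and estimators

## LD and scores

$r^2$ is the squared Pearson correlation of genotype dosages — the composite
(unphased) LD estimator — computed within a $\pm$ 1 Mb window on the same
chromosome. The "1 Mb window" is read as a $\pm 1$ Mb flank; a total-width
reading ($\pm$ 500 kb) is available through `window_bp`. The 0.2 floor applies
to TotLD as well, since it is defined by the same procedure. Flooring keeps the
pair structure sparse, which also makes the neighbourhood an exact object the
pruning, fold-construction and brute-force test oracles can share.

Interval membership uses BED half-open `[start, end)` intervals against
1-based SNP positions: a SNP at position $q$ is inside iff $s < q \le e$.
Overlapping intervals count once (union semantics). The brain category scores
whole gene bodies of a designated gene set. The 100 kb intergenic proximity
rule measures distance from interval boundaries (distance 0 inside).

## Genomic control

Greedy pruning visits candidates in a seeded random order and keeps a SNP iff
it has no kept neighbour at $r^2 \ge 0.2$ — the only LD threshold the
framework uses anywhere. Each of the 100 iterations reshuffles the visiting
order with a derived sub-seed; the estimate is the median of per-iteration
medians (robust and symmetric; a pooled variant would weight iterations by
retained-set size). Whether downstream analyses use raw or corrected
statistics is configurable (`apply_gc_correction`) and off by default: the
estimation step is always reported, the division $z^2 / \lambda_{GC}$ is
opt-in, since a well-behaved study should not need it and silent rescaling
would hide inflation from the reader.

## Fold enrichment

"Cumulative distribution" is implemented as the exceedance (survival)
fraction of $-\log_{10} p$: enrichment must appear as a positive deflection
above 1 at stringent thresholds, which a lower-tail CDF cannot produce.
Ties at a grid point are included via $\ge$. The default grid is 200 equally
spaced points on $[0, 7.3)$. The complement identity
$w\,\mathrm{fold}_{in}(x) + (1-w)\,\mathrm{fold}_{out}(x) = 1$ with
$w = |in|/|all|$ holds by construction and is asserted exactly in the tests.
Where no SNP exceeds a threshold the fold is recorded as missing rather than
0/0.

## PLSR and the jackknife

PLSR handles the strong collinearity between LD-weighted covariates (scores
share LD neighbourhoods with TotLD by construction) that destabilizes
ordinary least squares. The implementation is single-response NIPALS with
deflation; for one response the standard algorithms coincide. With $A$ equal
to the covariate count and a full-rank design it reproduces OLS to 1e-8,
which the tests assert against a normal-equations solve, and the fit agrees
with an independent PLS implementation (mixOmics) used purely as a
cross-check. A response orthogonal to every covariate yields the zero model
(coefficients 0, one degenerate LV) rather than a numerical error.

Coefficients are reported on the centered-and-scaled scale without re-adding
intercepts ("non-centered standardized"); the raw-scale back-transform and
intercept are also emitted for transparency.

Cross-validation folds must respect LD: a block split across folds leaks
information between training and held-out SNPs. Blocks are connected
components of the floored $r^2$ graph (the weakest faithful construction that
prevents leakage), additionally split if a component's span exceeds the LD
window, and whole blocks are assigned round-robin over a seeded shuffle.
Jackknife refits keep the full fit's $A$ and the global centering/scaling so
that leave-fold-out coefficients are on the full fit's scale; the variance is
the delete-group form $\frac{k-1}{k} \sum_f (b_{(-f)} - \bar b)^2$, and the
t-test uses $k - 1 = 49$ degrees of freedom ("approximate" is inherited from
the jackknife, which ignores refit dependence). A zero jackknife sd (e.g.
exactly duplicated folds) reports a signed-infinity t sentinel with p = 0
rather than crashing.

The residual diagnostics refit the model without TotLD (optionally also
without the evolutionary score), bin TotLD into equal-count bins and report
mean residualized $z^2$ per bin with the response mean re-added, so a
zero-coefficient reduced model reproduces raw per-bin means. Bins empty
within a stratum are merged leftward and logged.

MHC reruns drop (or keep only) chromosome 6 positions 25,652,429–33,421,466
(hg19), bounds inclusive; the synthetic genome carries its own MHC-like
region whose coordinates come from the generator configuration.

## Matched controls

Matching is cell-exact on a 2-D grid: MAF in 25 equal-width bins on
(0, 0.5], TotLD in deciles of the pooled distribution (deciles adapt to
TotLD's heavy right tail, where equal-width bins would leave most cells
empty). Matching sources are the SNPs physically inside the annotation (raw
indicator 1), with their TotLD as the matching covariate. Per-cell counts are
conserved exactly; sets are disjoint from the source; with `allow_reuse`
undersupplied cells sample with replacement, otherwise they error listing the
deficient cells. One hundred matched sets are drawn by default, each from an
independent derived sub-seed, and summarized by the pointwise median and
2.5/97.5 percentile envelope.

# The synthetic study

The generator exists so every stage is exercisable without external
downloads, and its defaults define the package's reference study:

* **Panel:** 20,000 SNPs on two 40 Mb chromosomes ("1" and "6"),
  200 diploid samples. LD is block-diagonal with exponential block spacings
  (mean 20 kb). Within a block, haplotypes share a Bernoulli clade indicator
  flipped per site with a mutation probability solved (by `uniroot` on the
  closed-form correlation) to hit a target mean within-block $r^2$ of 0.5 —
  strong but realistic local LD. Block allele frequencies follow a truncated
  Beta(0.8, 0.8) on (0.01, 0.5), mimicking a common-variant panel.
  Block-diagonal LD makes the brute-force oracle, the pruning adjacency and
  fold construction exact and fast; it deliberately omits long-range and
  inter-chromosomal LD.
* **Tracks:** genes cover ~8 % of the genome in clusters of 7 (cluster gaps
  leave the gene deserts the intergenic definition needs), each 30 kb with
  five 1 kb exons, 300 bp 5'UTR and 1 kb 3'UTR; introns are gene minus
  exon/UTR by interval subtraction, so intron/exon disjointness holds by
  construction. Brain genes are a 15 % gene subset, ohnolog-like intervals a
  25 % subset; 400 HAR-like intervals of 800 bp and 40 SD-like intervals of
  60 kb are placed uniformly; ncRNA/TFBS/miRNA-binding-site tracks provide
  the intergenic context; one 4 Mb MHC-like region on chromosome "6"
  receives 15 extra genes (elevated gene density).
* **Summary statistics:** causal effects
  $\beta_j \sim N(0,\; h^2_{snp} + \sum_c \tau_c a_{jc})$ with
  $h^2_{snp} = 2\times10^{-6}$ and planted $\tau$ (z² scale):
  HAR $2\times10^{-5}$, exon $10^{-5}$, 3'/5'UTR $10^{-5}$, intron
  $4\times10^{-6}$, brain $5\times10^{-6}$, SD and Ohno 0. Marginal z-scores
  follow the summary-statistic model
  $z = \sqrt{n}\,R\beta + \varepsilon,\ \varepsilon \sim N(0, \lambda R)$
  with $n = 50{,}000$, $R$ the realized blockwise dosage correlation and
  $\lambda$ the inflation knob (1 by default). With these values an
  annotation-tagging SNP gains roughly 1–3 units of expected $z^2$ —
  comparable to strong functional-category enrichment in real GWAS — and the
  per-SNP baseline contributes mean $z^2 \approx 1.5$. Sampling z directly
  from the summary-statistic model (not individual-level phenotypes) keeps
  replicate draws cheap; `precompute_block_factors()` caches the per-block
  Cholesky factors for replicated draws over a fixed genome.

What passing tests on this generator do **not** show: behaviour under
long-range LD, population stratification, allele-frequency-dependent
architectures, imputation error, or INDELs. The generator is a statistical
emulator of the analysis assumptions, not a demographic simulation.

## Calibration and power settings

Two auxiliary configurations are documented conditions, fixed a priori:

* `lambda_null_config()`: 55,000 SNPs on two 110 Mb chromosomes,
  gene-sparse (genic fraction 0.5 %), all $\tau = 0$, $h^2_{snp} = 0$ — over
  50,000 SNPs are intergenic, and $\hat\lambda_{GC}$ should land in
  [0.95, 1.05] at inflation 1 and [1.40, 1.60] at inflation 1.5.
* The jackknife power analysis uses the reference study with
  $\tau_{HAR} = 10^{-4}$ (a strong planted signal, chosen by an a-priori
  power calculation targeting an expected $z^2$ uplift of ~5 for
  HAR-tagging SNPs); the null calibration sets $\tau_{HAR} = 0$ while
  keeping the other planted effects, i.e. the evolutionary covariate is null
  in a study that still has genic enrichment.

Replicate "studies" in calibration tests fix one genome (panel, tracks, LD)
and redraw the GWAS: for a summary-statistic method the GWAS draw is the
stochastic object of interest, and this keeps the suite fast.

# Numerical choices and degenerate inputs

* p- and z-columns are linked by the two-sided normal relation; rows with
  $p \le 0$ or $p > 1$ are dropped with a logged count (a floor at 1e-300 is
  deliberately not the default: silent flooring hides corrupt inputs).
  Missing z takes magnitude from p with the sign flagged unknown — every
  downstream statistic uses $z^2$ or p only.
* Allele alignment matches the pair up to swap (swap flips the z sign);
  strand-ambiguous A/T and C/G sites are kept by default because the
  synthetic pipeline controls its own alleles; real-data users can drop them.
* Monomorphic panel variants are removed at construction so zero-variance
  dosage vectors never reach the correlation kernel.
* $r^2$ is clamped at 1 to absorb floating-point overshoot for identical
  dosage columns.
* PLSR extraction stops on a weight or score norm below 1e-12 (the zero
  model); the LV-count rule then reports what was extractable.
* `fold_curve` errors on a stratum emptied by the significance cap rather
  than returning an all-missing curve.

# Repository shape

The package is organised as an analysis workflow: the computation lives in
`R/` (so tests and the acceptance script exercise it as an installed
package), and the numbered drivers under `analysis/` narrate the study —
simulate, annotate, genomic control, enrichment curves, PLSR, matched
controls — writing compact tables under `results/`. `run_full()` is the
programmatic pipeline entry point; there is deliberately no shell CLI beyond
`Rscript` on the drivers, since the intended user runs R.

# Known limitations

* Dense per-window $r^2$ extraction is O(pairs × samples); biobank-scale
  panels would need banded/streamed LD, which is out of scope.
* The jackknife treats leave-fold-out refits as exchangeable; with 50 folds
  the t reference with 49 df is approximate by design.
* Matched controls use binned cell-exact matching, not nearest-neighbour or
  propensity matching; envelope coverage is the binomial-free summary across
  sets, with no multiplicity adjustment across grid points.
* The multiple-testing annotation in coefficient tables (Bonferroni across
  the covariate-by-phenotype grid) is a default, exposed in the table
  companion columns, not a claim about the only defensible correction.
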