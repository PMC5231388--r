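# ldenrich

Covariate-modulated polygenic enrichment analysis of GWAS summary statistics
in LD-weighted annotation categories.

## The problem

Are trait associations enriched in a set of genomic regions — say,
evolutionary markers such as human accelerated regions (HAR), segmental
duplications (SD) or ohnologs — or does the apparent enrichment just reflect
linkage disequilibrium (LD) with introns, UTRs, brain genes and the sheer LD
burden of those regions? `ldenrich` is for statistical geneticists who have
per-SNP GWAS summary statistics, a reference genotype panel, and BED interval
tracks, and want that question answered with LD taken seriously rather than
ignored.

The framework:

* **LD-weighted affiliation scores.** For SNP *i* and region category *c*,
  `LDscore_i = Σ_j δ_j r²_ij` over reference-panel SNPs *j* within ±1 Mb,
  with r² < 0.2 floored to 0 and a self term of 1; `TotLD` is the same sum
  over all panel SNPs. An isolated SNP inside a region scores exactly 1.
* **Genomic control from intergenic SNPs.** λ_GC = median squared z-score of
  LD-pruned intergenic SNP sets across 100 pruning iterations, divided by
  the χ²₁ median (≈ 0.455). Intergenic means: all genic LD scores zero and no
  LD partner within 100 kb of a protein-coding gene or inside
  ncRNA/TFBS/miRNA-binding-site tracks.
* **Conditional fold enrichment.** SNPs stratified at affiliation score ≥ 1;
  fold(x) is the stratum's −log₁₀(p) exceedance fraction over that of all
  SNPs, for x below genome-wide significance (−log₁₀ p < 7.3).
* **PLSR with jackknife t-tests.** Squared z-scores regressed on the
  standardized covariate block (intron, exon, 3'UTR, 5'UTR, evolutionary
  score, brain, TotLD) by partial least squares — stable under the strong
  collinearity of LD-weighted covariates — with the latent-variable count
  chosen to explain > 99 % of descriptor variance. Coefficients get
  approximate t-tests from delete-group jackknife variances over 50 LD-aware
  cross-validation folds (blocks of linked SNPs never split across folds),
  with MHC-excluded and MHC-only reruns.
* **Matched controls.** Random SNP sets matched to an annotation's SNPs on
  minor allele frequency and TotLD quantify how much enrichment LD and
  allele frequency alone produce.
* **A synthetic-data generator** (block-LD panel, annotation tracks, summary
  statistics with planted per-annotation effects) makes every stage testable
  without downloads and defines the package's reference study.

## Worked example

The numbered scripts under `analysis/` run the whole study on the reference
synthetic genome (20,000 SNPs, 200 panel samples, planted HAR enrichment
τ = 2×10⁻⁵ plus genic/brain effects; seed 42) and write their tables under
`results/`. Running them in order prints, among other things:

```
$ Rscript analysis/01_simulate.R
  panel: 20000 variants x 200 samples
  Mean z^2 inside HAR: 3.07; outside: 1.77

$ Rscript analysis/03_lambda.R
  lambda_GC = 1.3176 (15090 intergenic SNPs, 100 pruning iterations)

$ Rscript analysis/04_enrichment.R
   category  n_in   fold_x2 fold_x2_noMHC
1:      HAR   136 2.0877916     2.0723699
2:       SD   866 0.9221482     0.9731282
3:     Ohno   610 4.3929190     3.7648052

$ Rscript analysis/05_plsr.R
  HAR   coefficient 0.0875 (jackknife sd 0.0278, t 3.15, p 0.0028)
  SD    coefficient -0.0295 (jackknife sd 0.0334, t -0.88, p 0.381)
  Ohno  coefficient 0.0841 (jackknife sd 0.0552, t 1.52, p 0.134)

$ Rscript analysis/06_matched_controls.R
   category n_source source_fold_x2 matched_median_x2 matched_hi_x2
1:      HAR       88      2.3310229         1.0459745      1.613294
2:       SD      593      0.9875642         0.7780809      1.064624
3:     Ohno      402      3.7964569         1.0594764      1.456780
```

Reading these numbers: HAR-affiliated SNPs carry about twice the
sub-significant association signal of the background (fold 2.09 at
−log₁₀ p = 2), and that survives covariate control — the PLSR coefficient is
positive and significant (p = 0.003), as it should be, since the generator
planted a HAR effect. Ohno shows a *larger* raw fold enrichment (4.39), but
it evaporates in the regression (p = 0.134): ohnolog intervals are gene
bodies, and their enrichment is carried entirely by the genic covariates —
exactly the confounding the framework exists to strip away. The matched
controls agree: HAR's own curve (2.33) exceeds the 97.5th percentile of its
MAF/TotLD-matched envelope (1.61), so the excess is annotation content, while
SD stays inside its envelope. λ_GC = 1.32 with no planted inflation reflects
genuine polygenic signal reaching intergenic SNPs, not bias.

The same machinery is available programmatically:

```r
library(ldenrich)
cfg <- run_config(generator = generator_config(), seed = 1,
                  out_dir = "ldenrich_run")
res <- run_full(cfg)   # scores, lambda, curves, PLSR tables, matched sets
res$plsr[["synthetic:HAR"]]$all$coefficients
```

For real data, point `run_config(paths = list(stats = ..., panel = ...,
panel_format = "vcf", tracks = list(HAR = "har.bed", ...)))` at your own
summary statistics (TSV with SNP/CHR/BP/A1/A2/P/Z/N columns), reference
panel (VCF or dosage matrix) and BED tracks.

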