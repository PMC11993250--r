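---
title: "Methods: scoring and inference for dorsal-vessel cell-division defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and inference for dorsal-vessel cell-division defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorsalvessel)
```

## The anatomical blueprint

The *Drosophila* embryonic dorsal vessel is a linear tube of exactly 104
contractile cardial cells (CCs). `reference_blueprint()` encodes the
wild-type composition: 12 CCs per row in the anterior aorta, then seven
repeated cardiac hemisegments A2–A8 per row (left and right), each with 2
Svp-lineage CCs followed by 4 Tin-lineage CCs — except A8, abbreviated to
2 Svp + 2 Tin. Both rows together:
2 × (12 + 7×2 + 6×4 + 2) = 104.

```{r}
bp <- reference_blueprint()
total_cc_count(bp)
```

Scoring is pure bookkeeping against this blueprint. A hemisegment whose Tin
count deviates from expectation (in either direction) carries a *symmetric*
cell-division defect; a deviating Svp count marks an
*asymmetric-or-earlier* defect. The two classes are evaluated
independently — one hemisegment can carry both — and signed deltas are kept
for diagnostics. Deviations of any magnitude count equally: the scoring
contract is "an increase or decrease", not an effect-size measure.

Two segment-range presets exist because a fully penetrant A2-specific
phenotype (every A2 hemisegment reduced to a single Svp CC in trx-like
genotypes) would otherwise dominate cohort statistics: `A2_A8` scores all
hemisegments, `A3_A8` excludes A2. Whether A2 records enter a given
comparison is therefore an explicit argument, never a hidden rule.

## Data model and file dialect

Tables are UTF-8 delimited text (comma or tab, auto-detected from the
header) with fixed column names: `genotype`, `embryo_id`, `row`, `segment`,
`svp_count`, `tin_count`, and optional `anterior_cc_count`. Row labels
normalize case-insensitively to left/right, segments to upper-case A2–A8.
The record key (genotype, embryo, row, segment) must be unique; missing
(unscoreable) hemisegments are simply absent rows, and every denominator
downstream counts present records only. This matches real cohorts, where
hemisegment totals fall short of embryos × 14.

Anterior-aorta CC counts attach to A2 records (one value per row per
embryo) because they are counted as the CCs immediately preceding the A2
Svp CCs; keeping them in the same table avoids a second keyed file.

Supplementary-style tabulations often record *changes* per hemisegment
rather than absolute counts. `deltas_to_counts()` converts signed deltas
(0 = no change) to absolute counts as `expected + delta`. We read such
tables as deltas relative to the blueprint because that is the only
convention under which a "no change" row is well defined without an
external count.

## The permutation test

Hemisegments of one embryo share genetic background, staging and scoring
context, so their defect indicators are correlated; pooling them into a
2×2 contingency test overstates the effective sample size. Inference is
therefore at the embryo level. For embryos j = 1..n with defect
proportions Y_j and genotype indicator I_j, the model

Y_j = β0 + β1 I_j + e_j

has the closed-form least-squares solution β0 = mean(Y | I=0),
β1 = mean(Y | I=1) − mean(Y | I=0). Because the proportions are
non-normal and heteroscedastic, the null distribution of β̂1 is obtained
by permuting the genotype labels among the embryos. With n the number of
permuted estimates meeting the exceedance rule and N the number of random
permutations, p = (n+1)/(N+1), bounded below by 1/(N+1).

Numerical choices:

* **Exceedance rule.** Default two-sided: a permuted estimate counts if
  |β̂1_perm| ≥ |β̂1_obs|; one-sided alternatives use the signed
  inequality. Ties count as exceedances — conservative, and the reason
  constant data give p = 1 rather than an artifactual rejection. A
  tolerance of 1e-12 absorbs float noise from reordered sums. The source
  convention does not state sidedness; two-sided is the conservative
  reading, and both one-sided forms are available via `alternative`.
* **Shuffling.** Permutations are independent uniform draws of the
  group-1 subset (duplicates allowed, identity not excluded), matching the
  add-one p formula. The default N = 1e6 reproduces published practice;
  tests and the pipeline default use smaller N since the Monte-Carlo error
  sqrt(p(1−p)/N) is already negligible for screening purposes.
* **Oracle.** `exact_permutation_pvalue()` enumerates all choose(n, n1)
  label assignments (guarded at 1e6) and reports the exact exceedance
  fraction n/N alongside the add-one convention, serving as the
  independent reference the sampled test is validated against.
* **Seeds.** Every comparison runs on one named seed recorded in its
  result; `run_pipeline()` derives per-comparison substreams from the
  master seed so any single p-value can be regenerated in isolation.

No multiple-comparison correction is applied by default: pairwise
comparisons are reported as such, and correcting is left to the caller
(a deliberate choice, since inventing an unstated correction would change
reported values silently).

## Classical statistics

Welch's unequal-variance t-test (Satterthwaite fractional df, two-tailed),
the classical equal-variance one-way ANOVA (the SPSS default the field's
reports correspond to, not Welch ANOVA), and BCa bootstrap intervals are
implemented from their standard formulas, with `stats::t.test`,
`stats::oneway.test` and `boot::boot.ci` used as independent oracles in the
test suite rather than as the implementation.

The BCa construction follows Efron: bias correction z0 from the bootstrap
distribution's position relative to the observed statistic with a midpoint
convention for ties, acceleration from jackknife skewness, and adjusted
percentile endpoints (quantile type 7). A degenerate bootstrap distribution
(all resample statistics equal) collapses to the point value with a warning
flag instead of producing NaN endpoints. B = 5000 resamples is the default,
matching the convention for between-group CC comparisons. The bootstrap is
applied by default to the pairwise mean difference (`bca_mean_diff_ci()`,
resampling groups independently, combined delete-one jackknife); a
one-sample interface takes any statistic.

ANOVA with zero within-group sum of squares raises an error rather than
returning an infinite F: on integer count data this arises from constant
groups, and silently returning Inf would propagate into p = 0.

## Lumen widths

Internal lumen diameters (µm) are measured at five positions: A2, A3, A4
(posterior aorta) and A6, A7 (heart proper). Per embryo, the region width
is the mean over its positions; if several diameters are recorded at one
position (e.g. multiple Z planes) they are averaged per position first —
the least surprising reduction, and one that covers both one-measurement
and per-plane acquisition. Embryos missing any position are an error, not
silently dropped. `compare_region_widths()` is a Welch test of per-embryo
heart-proper versus posterior-aorta widths within one genotype: wild-type
anatomy gives a strongly significant dilation (about 2.18 vs 0.66 µm);
a homeotically transformed heart proper gives none.

## The synthetic-cohort generator

No public per-hemisegment dataset accompanies the study design this package
supports, so every pipeline stage is exercised on synthetic cohorts from
`generate_embryo_table()`. The generator emulates the *statistical
structure* the inference assumes, phenomenologically:

* **Clustered defects.** Each embryo draws a per-class defect probability
  from a Beta distribution with mean m and intra-embryo correlation ρ
  (shapes a = m(1−ρ)/ρ, b = (1−m)(1−ρ)/ρ; ρ = 0 degenerates to a shared
  fixed rate); hemisegment indicators are Bernoulli at that rate. The
  beta-binomial is the minimal model with the one property the inference
  depends on — within-embryo correlation — and ρ equals the intra-class
  correlation of indicators (1/(a+b+1)).
* **Defect magnitudes.** A defective hemisegment perturbs the blueprint
  count by a signed magnitude drawn from `magnitude_probs` (default
  ±1 at 0.35 each, ±2 at 0.15 each), clamped at 0; Svp counts are capped
  at 4 unless `svp_supernumerary_allowed` (trr/Set1-like genotypes show
  supernumerary Svp CCs; trx-like do not).
* **Deterministic phenotype flags**, applied after stochastic defects and
  overriding them so penetrance-1 phenotypes are exact:
  `a2_single_svp_penetrance` forces `svp_count = 1` in A2, and a
  non-trivial `a8_tin_surplus_probs` sets A8 Tin to expectation plus a
  drawn surplus.
* **Reproducibility.** Each embryo runs on an independent substream
  derived from the master seed, so regeneration is bit-identical and
  enlarging a cohort leaves earlier embryos unchanged.

Preset parameter choices (`preset_configs()`), made once as plausible
field values where no source states them: trx_like uses symmetric rate
0.25 with ρ = 0.3, asymmetric rate 0 (its Svp phenotype is the
deterministic A2 flag, not a stochastic rate), A8 surplus distribution
(0,1,2,3) = (0.1, 0.5, 0.3, 0.1) giving a per-segment A8 Tin mean near
6.8, and a heart-proper lumen collapsed to the aorta mean (0.66 µm) to
mimic the homeotic transformation. trr_like and set1_like elevate both
classes (0.20 symmetric; 0.13 and 0.15 asymmetric). All ρ values are
framework parameters — no empirical estimate of the within-embryo
correlation exists — and are set to 0.3 throughout, including in the
validity simulations. Lumen standard deviations default to 0.1 µm;
anterior-aorta counts are integer-rounded normal draws (mean 12.2, sd 0.8;
12.6 for trx_like, reflecting that mutant counts run slightly high without
differing significantly).

What passing tests on these cohorts shows — and does not. The generator
reproduces clustering, penetrant phenotypes, missingness and blueprint
conformance, so green tests demonstrate that the pipeline's bookkeeping is
exact and its inference holds its error rates *under the assumed
beta-binomial clustering*. Real embryos may violate that model (e.g.
segment-specific defect rates, left–right asymmetries, scorer effects),
and no synthetic result certifies behaviour under those departures.

## Simulation sizes in the test suite

The suite's stochastic checks use sizes chosen to keep Monte-Carlo error
well inside the asserted bands: type-I error of the permutation pipeline
under a clustered null (m = 0.15, ρ = 0.3, 15 vs 15 embryos) over 2000
replicates at 999 permutations each, with the pooled Fisher exact test run
on the same replicates as the anticonservative contrast; power monotonicity
over effect rates (0.15, 0.30, 0.50) at 150 replicates each; BCa coverage
on the normal mean (n = 30) over 1000 replicates at 999 resamples; and the
end-to-end class-separation check over 40 replicates at 10^4 permutations.
The sampled-vs-exact oracle comparisons run at 10^5 permutations on 8-embryo
datasets, within 3 Monte-Carlo standard errors of the enumerated value.

## Known limitations

* Scoring is binary per class; partial penetrance within a hemisegment
  (mosaic counts) is representable only through the magnitude distribution.
* The permutation test assumes embryos are exchangeable under the null
  within the pooled sample; batch effects between cohorts would violate
  this and are not modelled.
* The A2 anterior-CC convention ties anterior counts to A2 records; rows
  missing their A2 record lose their anterior count.
* BCa intervals degrade on very small samples (n < 8) where the jackknife
  acceleration is noisy; the implementation warns only for fully
  degenerate bootstrap distributions.
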