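---
title: "Methods: dual linkage and association mapping of field flowering time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual linkage and association mapping of field flowering time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmap)
```

## Scope and rationale

`dualmap` implements the analysis chain used to dissect natural variation
of flowering time measured in a field common garden on inbred plant
material (natural accessions of a selfing species plus biparental
recombinant inbred line, RIL, families): phenology scaling of calendar
dates to photothermal units, analysis of the field design, genome-wide
association (GWA) scans corrected for population structure, QTL mapping in
the RIL families, and the integration layer that uses QTL support and
candidate-gene proximity to separate plausible associations from artefacts
of structure correction. A seeded synthetic-data generator reproduces the
statistical structure of each input so that every stage is testable without
external downloads.

## Phenology model

Flowering dates are scaled to photothermal units (PTU). For a plant
germinating on day $g$ and flowering on day $ft$,

$$\mathrm{PTT} = \sum_{i=g}^{ft} \max(0,\ \mu_i - \mu_b)\,\lambda_i
\qquad \text{for days with daily mean} > 3\,^\circ\mathrm{C},$$

where $\mu_i$ is the mean temperature during daylight, $\mu_b = 3\,^\circ$C
the base temperature, and $\lambda_i$ the photoperiod as a fraction of 24 h.
Chilling exposure is accumulated as $\sum (\mu_v - \mu_c)$ over days whose
daily mean $\mu_c$ falls below the vernalization threshold
$\mu_v = 6\,^\circ$C.

Three corners of this model are under-determined and resolved as follows:

* the 3 °C gate is **strict** (`tmean > 3`); a day at exactly 3 °C
  contributes nothing;
* the daily increment is **floored at zero** when the daylight mean falls
  below the base temperature, so cold spells never subtract units;
* accumulation **never resets** during sub-gate spells; both boundary days
  ($g$ and $ft$) are included.

When a weather file lacks a photoperiod column, `daylength()` supplies the
astronomical daylength from latitude via the standard solar-declination
(CBM) formula; tests hold it to within 0.25 h of a minute-resolution solar
elevation integration at mid latitudes.

## Field-design model

Measured PTU are analysed with the fixed-effects model
`trait ~ block + genotype (+ block:genotype) + cov(control 1) + cov(control 2)`,
where the covariates are the per-array trait values of two control
accessions replicated in every array; they absorb array-level heterogeneity
within blocks. All factors are fixed. Least-square means are model
predictions averaged over blocks with covariates at their global means
(raw covariate values, not array-centred — configurable through the input
table). Broad-sense heritability uses
$\sigma^2_G = \max(0, (MS_G - MS_E)/r)$ and
$H^2 = \sigma^2_G/(\sigma^2_G + MS_E)$ with $r$ the (median) replicate
count. Transgressive segregation is flagged when an extreme RIL mean passes
the more extreme parent by two parental standard deviations (SD taken
across that parent's replicate plants); transgression intensity is the RIL
range over the absolute parental difference, a scale-free ratio.

## GWA scans

Two scans over MAF-filtered SNPs (strictly > 10 % by default):

* **Rank-sum scan** — a two-sided Wilcoxon test per SNP; exact p-values by
  full enumeration (midranks under ties) when both genotype classes hold at
  most 10 accessions, otherwise the normal approximation with tie and
  continuity corrections.
* **Mixed-model scan** — $y = X\beta + u + \varepsilon$ with
  $u \sim N(0, \sigma^2_g K)$ on the identity-by-state kinship $K$ (the
  fraction of shared calls per pair, diagonal 1). The variance ratio
  $\delta = \sigma^2_e/\sigma^2_g$ is profiled by REML on the spectrum of
  the projected kinship, maximised on a 100-point grid over
  $\log_{10}\delta \in [-5, 5]$ with local polish — the grid is
  configurable; per-SNP REML refitting is available (`per_snp_reml`) but
  the default reuses the null-model ratio, which is orders of magnitude
  faster and nearly indistinguishable in calibration at these panel sizes.

With $K = I$ the generalised least squares test collapses to the ordinary
regression F-test exactly (a tested identity rather than a failure mode).
Missing calls are handled by casewise deletion per SNP. Additional fixed
covariates (e.g. a candidate-gene functional class) can be supplied, which
also covers single-marker candidate tests via a one-column genotype matrix.
Scan diagnostics report the genomic-control inflation factor
$\lambda = \mathrm{median}(\chi^2_1)/0.455$, QQ coordinates, and p-value
distributions stratified by MAF bin, because rare alleles distort the two
scans in opposite directions.

## QTL mapping

Mapping is single-family Haley–Knott regression on expected genotype
dosages. Map algebra uses Haldane distances,
$r = \tfrac12(1 - e^{-2d/100})$, expanded to the fraction observed between
fixed RIL genotypes, $R = 2r/(1+2r)$; input maps are interpreted as
RIL-map distances and inverted directly. Conditional $P(A)$ at a query
position comes from the nearest informative flanking markers (heterozygous
calls, expected to be rare after 5–6 selfing generations, are treated as
missing). The scan statistic is $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$ on a
0.5 cM grid by default (0.1 cM supported, proportionally slower).

Genome-wide thresholds come from permutations of the phenotype against
whole genotype rows (preserving marker correlation); at least 1000
permutations are recommended for final analyses, and the operating
characteristics quoted below use 200 to keep run times at desk scale.
Multi-QTL models are built by forward cofactor search: accept the highest
exceedance, mask ±10 cM around accepted peaks, rescan conditionally,
repeat. This plays the role of composite-interval-mapping peak filtration;
it is not numerically equivalent to that machinery, and support intervals
are 1.5-LOD drops on the conditional scan (extended one grid point) rather
than Bayesian credible intervals — a deliberate simplification that keeps
the downstream contract to `{peak, interval, effect}`. Additive effects are
half the fitted difference between homozygote classes, signed as the effect
of the recurrent-parent allele; per-QTL variance shares are drop-one
$\Delta R^2$ and the model $R^2$ estimates $V(G)/V(P)$. A two-locus scan
tests the interaction term of `y ~ g1 + g2 + g1:g2` over a coarse grid
(5 cM, pairs ≥ 10 cM apart) with a permutation null of the maximum
interaction F.

## Integration of the two maps

Candidate genes receive symmetric windows (default 20 kb, inclusive ends,
strand ignored, distance to the gene interval). Top-SNP sets of sizes
3000…50 are ranked by p with deterministic `(chrom, pos)` tie-breaks.
Enrichment of a flag (near-candidate, in-QTL, or both) is the flagged
fraction among top SNPs over the background fraction; its null distribution
is resampled by drawing top-set-sized SNP subsets uniformly without
replacement from the (already MAF-filtered) background — a MAF-stratified
draw is available but not the default. QTL intervals are pooled across
families for flags, with per-family ids retained for reporting.
Classification of candidate genes follows the dual-mapping logic: detected
by both scans and overlapped by a QTL (`confirmed`), by one scan with QTL
support (`emma_only_qtl`, or `wilcoxon_only_qtl` — the signature of
mixed-model false negatives), or without QTL support (`no_qtl`, potential
false positives). Orphan peaks are top-ranked SNPs inside QTL intervals
with no candidate gene within 20 kb, greedily merged below 100 kb spacing —
a formalisation of visual "neat peak" screening, and only a proxy for it.

## Synthetic data

`simulate_panel()` uses the Balding–Nichols model (ancestral frequencies
uniform on (0.05, 0.95); subpopulation frequencies Beta-distributed at the
target $F_{ST}$; inbred Bernoulli calls). It induces exactly the
kinship–phenotype confounding the mixed model must remove, at desk scale; a
coalescent backend is out of scope. Default dimensions follow the study
system: 184 accessions, 5 subpopulations, $F_{ST}$ 0.3, five chromosomes
with A. thaliana-like lengths; SNP counts default to 5000 (the real panel's
216 509 SNPs are neither necessary nor practical for testing the
statistical properties). Traits add causal SNP effects, a
kinship-structured polygenic term, subpopulation mean shifts and unit
noise; realized variance fractions are recorded in a truth record, as is
every other generated ground truth.

`simulate_ril_family()` breeds families in silico: F1 of two fully
homozygous parents, the configured intercross generations (default 2, by
random mating), then single-seed descent (default 6 selfings), with
crossovers Poisson in map length and uniform in position (Haldane, no
interference — matching the scan's map functions). The genetic map handed
to mapping is re-estimated from the simulated recombinant fractions, so
simulator and scan are internally consistent; true QTL positions are
projected into those estimated coordinates in the truth record, because
intercrossing expands the realized map. Residual heterozygosity matches the
Mendelian expectation ($2^{-k}$ after $k$ selfings from the F1; half that
after intercrossing).

`simulate_weather_and_layout()` builds an autumn-sown season at latitude
50.6°N: an annual temperature sinusoid (coldest mid-January) with AR(1)
noise, daylight means offset above daily means, photoperiod from
`daylength()`; each genotype flowers on the first day its cumulative PTU
reaches its threshold (thresholds spanning 270–580 PTU, the magnitude of
the panel's variation). The layout replicates genotypes over 3 blocks and
arrays with two control accessions per array. What this generator does
*not* emulate: vernalization-dependent development, genotype-specific
photoperiod sensitivity, spatial field gradients beyond block/array
effects, or measurement censoring from 3-day scoring intervals — so
passing tests certify the statistical machinery, not the biology of any
particular field season.

## Numerical choices and degenerate inputs

* REML: eigenvalues of the projected kinship are clipped at zero; a
  non-PSD kinship after that margin is an error. A flat profile (identity
  kinship) returns the OLS limit.
* Scan grids always include the terminal marker; positions beyond the map
  clamp to it (with a warning). Conflicting zero-distance flanking markers
  fall back to the prior 0.5.
* Monomorphic SNPs carry `p = 1` and a flag; monomorphic chromosomes scan
  to zero LOD with a warning.
* Permutation thresholds use quantile type 7; `alpha = 1` degenerates to
  the minimum of the max-LOD distribution.
* Top-set ties at the cut break by `(chrom, pos)`; enrichment draws are
  seeded per ladder cell, so a full ladder is reproducible bit for bit.
* Enrichment of a flag absent from the background is undefined (error in
  the single-ratio function; skipped with a warning in the ladder).

## Operating characteristics

The test suite measures, among others: genomic inflation on
structure-only panels (200 accessions × 5000 SNPs, 20 seeds) — naive scans
inflate beyond $\lambda = 1.2$ while mixed scans stay within
$[0.9, 1.1]$ and pass KS uniformity; single-QTL recovery (25 % PVE, 300
lines, 80 markers, 100 seeds) — peaks within ±5 cM and 1.5-LOD intervals
covering the truth in well over 80 % of seeds, with null families clearing
the permutation threshold in ≥ 94 %; heritability recovery within ±0.07 at
targets 0.3 and 0.8; and null-enrichment cell coverage near the nominal
95 %. Problem sizes were chosen as the smallest at which these
distributional properties are stable; `scripts/acceptance.R` re-derives the
same quantities from scratch at slightly reduced replicate counts.

## Known limitations

* The forward-search QTL model and LOD-drop intervals approximate, but do
  not reproduce, composite interval mapping with Bayesian credible
  intervals; effect estimates near linked QTLs inherit the usual
  forward-selection biases.
* The uniform resampling null for enrichment ignores MAF composition of
  top sets (an optional stratified draw exists) and any LD clustering of
  top SNPs.
* `daylength()` degrades near polar latitudes in winter, where declination
  formulas diverge; the field designs this package targets sit at mid
  latitudes.
* Accessions are assumed fully inbred: no dominance terms anywhere, and
  heterozygous calls are discarded, not modelled.
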