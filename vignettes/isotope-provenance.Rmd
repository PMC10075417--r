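---
title: "Isotope-based provenance and diet analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-based provenance and diet analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoprov)
```

## The problem

Skeletal tissue archives geochemistry. Tooth enamel mineralises in childhood
and is essentially closed thereafter, so its ⁸⁷Sr/⁸⁶Sr ratio reflects the
bedrock-driven strontium signature of wherever the individual grew up; bone
remodels continuously and converges on the residence-at-death signal. Bone
collagen δ¹³C and δ¹⁵N record diet over the last decades of life (C3 vs C4
plant input and trophic level respectively), while incremental dentine lays
down a childhood-to-adolescence dietary time series, section by section.

`paleoprov` turns these observations into a reproducible statistical
pipeline for early-medieval (and comparable) cemetery series: estimate what
"local" looks like per burial region, call each individual local, mobile or
migrant, quantify migrant frequencies over time, characterise the common
dietary envelope of each population, flag dietary outliers, and compare
childhood (dentine) against adulthood (bone) diet, down to per-section
life-history profiles.

## Local ranges: KDE + highest-density intervals

The local range of bioavailable ⁸⁷Sr/⁸⁶Sr for a region is estimated from
the pooled biomineral reference sample of that region — human and animal,
enamel and bone. Bone alone would understate variability (diagenesis pulls
bone values toward local groundwater); enamel of adults may contain
immigrants. Pooling all strata and taking a wide interval is a deliberate
compromise that minimises over-calling of non-locals.

The estimator is a Gaussian kernel density estimate with the Sheather–Jones
"solve-the-equation" bandwidth (`sj_bandwidth()`, delegating to
`stats::bw.SJ(method = "ste")`), evaluated on a regular grid of 2¹² points
spanning the data range extended by three bandwidths on each side and
renormalised to unit mass by the trapezoid rule (`fit_kde()`). The grid
resolution keeps discretisation error well below the 5-decimal precision at
which Sr ratios are reported.

`hdr()` implements the density-quantile construction of highest-density
regions: sort grid cells by density, accumulate mass until the requested
coverage is reached, take the density of the last included cell as the
threshold, and return maximal runs of above-threshold cells as intervals.
`local_range()` then anchors the reported interval at the most prominent
mode (`anchor = "mode_interval"`): the HDR interval containing the global
density maximum. For the unimodal reference distributions this coincides
with the full hull over all HDR intervals, which remains available as
`anchor = "full_hull"` for multimodal reference sets.

Numerical conventions:

* coverage defaults to 0.99 everywhere — the conservative cutoff that keeps
  methodological uncertainty from inflating the non-local count;
* interval bounds stay unrounded through all computations and are rounded
  (5 decimals for Sr, 1 decimal for δ) only at reporting time;
* samples with fewer than 8 values fall back from Sheather–Jones to
  Silverman's rule with a warning, as does a failed fixed-point search;
  zero-spread samples are an error;
* reference sets below n = 20 carry a "may underestimate variability"
  warning but still return a range.

The package ships the published regional ranges (STB 0.70805–0.71096, REG
0.70813–0.71195, AED 0.70857–0.71104, MUC 0.70802–0.71021) and the macro
pre-Alpine range 0.7081–0.7110 via `published_sr_ranges()`, so
classification can run without access to the reference database.

## Classification: local, mobile, migrant

`classify_individual()` applies three nested exclusions, at 5-decimal
precision:

1. **local** — the value lies in the closed burial-region interval. A value
   exactly on a printed bound is local: boundary inclusion is the
   conservative direction for non-local calling.
2. **mobile** — outside the burial region, but strictly inside another
   region's range: movement within the macro area cannot be excluded.
3. **migrant** — outside the burial region, matching no other region's
   interior, and outside the macro range: an origin beyond the Northern
   pre-Alpine foreland.

Alternative-region matching uses the *open* interval deliberately: a ratio
exactly on the edge of another region's printed range is the most extreme
value that range can produce and is no positive evidence of an origin
there, so it does not rescue an individual from the migrant call. With
closed matching the published cohort would contain one extra mobile whose
value coincides with a neighbouring region's upper bound; the open
convention reproduces the published partition. A non-local inside the macro
range that matches no named region is counted mobile (the weaker claim) and
flagged `mobile_indeterminate`. Missing values are `indeterminate` and are
excluded from all denominators.

Cohort proportions (`summarize_cohort()`) carry Wald normal-approximation
intervals, k/n ± z·√(p(1−p)/n) truncated to [0, 1]. The Wald form was
chosen because it back-computes the intervals printed alongside published
cohort proportions, which Wilson or Clopper–Pearson intervals do not; it is
isolated in `wald_ci()` and trivially swappable. Note that printed
percentages depend on the exact assessed denominator, which published
reports do not always state; the package therefore always reports k and n
explicitly.

`mfm_by_period()` computes the minimum frequency of migrants — the share of
adults per period with enamel values outside the macro range. It is a lower
bound by construction: origins with similar geology are invisible. Regions
whose own local variability exceeds the macro range (Regensburg in the
shipped defaults) should be excluded via `exclude_regions`, otherwise their
locals register as false migrants. Group comparisons use Pearson chi-square
without continuity correction, with Bonferroni-adjusted pairwise post-hocs
(`compare_groups()`), matching the conventions of the statistical software
commonly used in this field.

## Diet: common variability, outliers, bone vs dentine

`diet_variability()` defines the "common intra-populational diet
variability" per pooled-site population as the 99% HDI (same machinery as
the Sr baselines, mode-anchored, univariate per isotope) of the adult bone
collagen values, alongside mean and SD. Sites under 5 km apart share ground
conditions and catchments and are pooled (`default_diet_grouping()`).
Infans I children are excluded by default — nursing elevates δ¹⁵N — but are
retained in outlier screening. `detect_outliers()` flags an individual when
either isotope leaves its population HDI (boundary inclusive), with the
direction of departure.

`bone_dentine_deltas()` compares adulthood and later-childhood diet via the
absolute bone-minus-bulk-dentine differences for individuals with both
tissues. Bulk dentine is defined as the unweighted mean of the root
sections (`bulk_from_root_sections()`), excluding crown sections to avoid
the weaning signal. Group means are reported for individuals with and
without *notable attributes* — the disjunction {ACD, non-local enamel Sr,
bone diet outlier}, exposed as a plain logical map so the predicate is
configurable — and compared with a Mann–Whitney U test (exact for small
untied samples, normal approximation with tie correction otherwise, as
implemented by `stats::wilcox.test`). Deltas above 1.5 ‰ are additionally
flagged for reporting; this threshold is descriptive, never a
classification rule — classification stays HDI-based. Report tables round
half-up at one decimal, the convention of printed isotope tables (base R's
`round()` is half-even and would turn a mean of 1.45 into 1.4).

## Dentine profiles and life-history shifts

Serial sections are cut in 1-mm slices from the crown downward.
`assign_section_ages()` interpolates ages linearly along the section index,
separately within the crown and root formation windows, so the sections
tile each window contiguously. The M1 windows (crown 0–3.5 y, root
3.5–9.5 y) anchor the scheme; M2 (2.5–7, 7–15) and M3 (7.5–11, 11–20) are
package defaults in the same spirit and are configurable per call — a
deliberately minimal scheme given that published per-section age tables
are rarely reproducible from main texts.

`detect_shifts()` screens a profile for two event kinds: crossings of the
population HDI between adjacent sections (`exit_local_range` /
`enter_local_range`) and adjacent-section jumps of at least `min_step`
(default 1.5 ‰, the conventional cutoff for a "greater difference";
`step_change`). Event ages are midpoints between the two section mid-ages,
so localisation error is bounded by half the inter-section spacing. A
simple threshold detector is intentional: the substantive claims it
supports are qualitative (a residence change around a given age), and a
Bayesian change-point model would add machinery without changing any call.

## The synthetic generator

`generate_cohort()` draws cohorts under the generative model the analysis
assumes, so every stage can be tested against known truth with no external
data:

* one unimodal normal local Sr distribution per region, with mode and SD
  back-derived from the published 99% ranges (mode = midpoint,
  SD = half-width/2.576);
* migrants at the regional mode plus an offset that must land outside the
  macro range (offsets that do not are an error, not a silent fix);
* mobiles drawn uniformly from the feasible set: another region's interior
  minus the burial region's range;
* bone diet values bivariate normal around (−19.7, 9.2) ‰ with 0.7 ‰
  spread; bulk dentine follows bone with 0.3 ‰ noise;
* ACD women receive a +3 ‰ childhood δ¹³C (millet) shift and +0.8 ‰ δ¹⁵N
  in dentine only — bone stays with the local group, modelling long
  residence after immigration;
* serial M1 profiles with a linear weaning decline across the crown window
  and, for migrants, a δ¹³C step at a random age, with 0.3 ‰ section noise.

One master seed drives everything; two runs with the same configuration are
identical. What the generator does *not* emulate: diagenesis of enamel,
spatially structured isoscapes, multimodal local distributions (a
two-component REG-like option is the obvious extension), measurement-lab
offsets, and demographic age structure. Passing recovery tests therefore
demonstrates the statistical machinery, not robustness to those real-data
complications.

`generate_reference_set()` additionally emulates the diagenetic shrinkage
of bone strata toward the local mode (SD multiplied by a configurable
factor), mirroring why bone alone cannot define the baseline.

## Test problem sizes

The package's own verification uses sizes chosen to make Monte-Carlo error
small relative to the tolerances tested: 100-seed replications for
baseline recovery (n = 500 draws), migrant-fraction recovery (cohorts of
156 at an injected fraction of 0.23) and change-point localisation; 60
replications of n = 200 for the null outlier rate; and grids of 4096 cells
for the exhaustive HDR cross-checks. The brute-force oracles (grid search
over the Sheather–Jones objective, exhaustive HDR threshold search) live in
the test suite and are independent of the package's code paths.

## Known limitations

* Geographical redundancy of ⁸⁷Sr/⁸⁶Sr means every non-local count is a
  minimum; the package cannot assign specific origins, only exclude them.
* The published regional ranges are reproduced as shipped constants at
  their printed 5-decimal precision; re-estimating them requires the
  underlying reference database.
* Printed cohort CIs can differ by up to one percentage point from
  recomputed Wald intervals when the assessed denominator is ambiguous;
  the package reports k and n rather than guessing.
* The M2/M3 formation windows are package defaults, not a validated
  odontological age table; per-study customisation is expected.
* Laboratory-specific analytical precisions (0.1–0.2 ‰) are recorded
  upstream but not propagated as weights into any test.
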