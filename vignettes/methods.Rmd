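---
title: "Methods: isotope calibration, pathway assignment and cover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope calibration, pathway assignment and cover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photopath)
```

`photopath` builds photosynthetic-pathway trait tables the way national
plot-survey programs build them: voucher records are filtered to a clean
species list, pathways are assigned by literature, lineage inference or
calibrated tissue δ¹³C, and point-intercept surveys are aggregated to
pathway cover per plot. This vignette documents the models behind each
stage, the defaults and why they were chosen, the numerical decisions, and
what the synthetic data generator does and does not emulate.

## 1. Isotope calibration

### δ notation

An IRMS reports the ¹³C/¹²C abundance ratio of combusted tissue relative to
a reference gas. `delta_from_ratios()` expresses this per mil:

$$\delta^{13}C = \left(\frac{R_{sa}}{R_{ref}} - 1\right) \times 1000.$$

The function is linear in $R_{sa}$ and zero when sample and reference
ratios coincide; non-positive ratios are a domain error.

### Drift correction

Instrument response drifts over a long autorun. `drift_correct()` models
the drift as linear in sequence position and estimates the slope by OLS of
the repeated standards' raw readings on position, with a separate intercept
per standard so that standards of different isotopic composition pool into
a single slope. The fitted trend is subtracted from every reading. On a
noise-free run with injected linear drift the slope is recovered exactly
(the test suite asserts 1e-9); a run in which no standard appears at two
distinct positions cannot constrain drift and is returned unchanged with a
warning. Drift correction is applied *before* normalization: the
normalization then absorbs any constant offset the subtraction introduces,
so the order only matters if drift were estimated from already-normalized
values, which would be circular.

### Normalization to VPDB

Two normalizations are implemented, matching the two ways facilities
anchor a run:

* **Multipoint** (`fit_multipoint()`): OLS of verified standard values
  (y) on measured values (x) over all standard readings in the run;
  unknowns are corrected as $\delta^T = a\,\delta^M + b$. With two
  standards the fit is exact; with more, residuals are the usual OLS
  residuals and the regression σ is reported.
* **Two-point** (`fit_two_point()`): the affine map through two anchor
  standards,
  $$\delta_{sa,c} = \delta_{std1} + (\delta_{sa,m} - \delta_{std1,m})
  \frac{\delta_{std2} - \delta_{std1}}{\delta_{std2,m} - \delta_{std1,m}}.$$
  A commonly printed shorthand of this formula omits the
  $(\delta_{std2} - \delta_{std1})$ scale factor, which is dimensionally
  inconsistent (it reduces to the full form only when the anchors are
  exactly 1‰ apart); the package deliberately implements the full,
  dimensionally consistent normalization. The two forms of calibration
  agree exactly when the multipoint fit uses the same two anchors.

Both corrections are affine with positive slope for any well-posed
standard set, so they preserve the ordering of measurements. When
`calibrate_run()` fits a two-point correction to a whole run it averages
each standard's repeats and, unless anchors are named, picks the pair of
facility standards spanning the widest verified range (alphabetical
tie-break) — the widest span minimises extrapolation for unknowns.

### Run QC

`run_qc()` reports the maximum and SD of the absolute deviation of
corrected standard readings from their verified values, together with the
number of standard readings; facilities quote exactly this kind of
"uncertainty ≤ x ‰ based on repeat analysis of standards" statistic. The
max-deviation form was chosen (rather than, say, RMSE) because it matches
the "≤" phrasing such statements use. Replicate agreement is the mean ± SD
of the absolute difference between replicate pairs; when a run carries no
replicates these fields are `NA`, never zero.

## 2. Taxonomy filtering

Herbaria determine specimens to the lowest possible rank, which leaves the
record stream mixed. `filter_species_records()` applies four rules, in
order: family- or genus-level determinations (`sp.`, `spp.`, family names)
are excluded; hybrids (`×`) are excluded; infraspecific taxa (`var.`,
`subsp.`, `f.`) are collapsed to their binomial, on the assumption that
varieties and subspecies share the species' pathway; and duplicate
binomials are deduplicated after case/whitespace normalization. Authority
strings are stripped before parsing. The report counts reconcile exactly:

```
n_input = n_unique + n_excluded_genus_or_family + n_excluded_hybrid
          + n_duplicates_removed
```

where a collapsed infraspecific record that merges into an existing
binomial is counted among the removed duplicates (and separately as
collapsed). Filtering is idempotent, and output order is alphabetical so
downstream artifacts are deterministic. Synonyms are deliberately *not*
merged: the herbarium name is the point of truth, and any synonym
annotations are carried along rather than resolved, because automatic
synonym merging across jurisdictions is a known source of silent errors.

## 3. Pathway assignment

### The cascade

`assign_pathways()` applies three routes in strict precedence:

1. **Literature.** All entries for a species are gathered; concordant
   entries yield one assignment carrying every supporting source.
   Discordant entries are resolved by evidence rank — by default
   `direct` (physiological or isotopic measurement) >
   `database` (trait compilation/flora) > `inference` — with losing
   sources recorded in a discrepancy note. Ties at the top rank are broken
   deterministically by `source_id` order and flagged tentative. The
   ranking is configurable because "best direct evidence" is ultimately a
   judgement call.
2. **Lineage.** A species in a genus whose known members all share one
   pathway inherits it (`lineage_inferred`). Genera documented to contain
   several pathways are never inferable.
3. **Isotopes.** Only species in families known to contain C₄ lineages
   (the target families) or in genera with CAM potential are classified
   from tissue δ¹³C; all other families are presumed C₃-only and a missing
   assignment is reported as such rather than guessed.

Species failing all three routes are returned with an explicit
`unassigned_reason` — never dropped.

### Thresholds and edge decisions

* C₃/C₄: δ < −19‰ ⇒ C₃, δ > −19‰ ⇒ C₄. The two tissue distributions leave
  a wide gap around −19‰, so the rule is insensitive to calibration error
  of a few tenths of a per mil. A value of exactly −19‰ is undefined under
  strict inequalities; it is labelled `ambiguous` and routed to manual
  review rather than forced to a side.
* CAM rule (CAM-potential genera only): δ > −20‰ ⇒ CAM; −24‰ ≤ δ ≤ −20‰ ⇒
  C₃+CAM; δ < −24‰ ⇒ C₃. Stated interval endpoints leave the band
  (−21, −20) unallocated; the package closes the gap by assigning it to
  C₃+CAM, i.e. the partition is (−∞, −24), [−24, −20], (−20, ∞). This
  preserves every stated exemplar interval, and all CAM/C₃+CAM isotope
  calls are tentative anyway, because δ¹³C cannot separate CAM from C₄ nor
  weakly expressed CAM from C₃.
* Documented-C₄ genera with CAM potential (e.g. *Portulaca*) keep their C₄
  assignment but receive a standing note that C₄-CAM cannot be excluded,
  rather than a distinct label.
* When several specimens of one species carry δ values, the first row
  (specimen-priority order) is used and the rest are noted as replicates.

### Summaries

`summarize_pathways()` reports counts per pathway, the family composition
of the C₄ flora with percentage shares *truncated* (not rounded) to one
decimal — so a printed share never exceeds the exact ratio — and the list
of genera containing ≥ 2 pathways, always computed from the assignments
rather than hard-coded.

## 4. Cover analysis

Species cover is the percentage of point-intercept positions at which the
species was hit. A point intercepting one species several times (layered
canopy) counts once, so a single species saturates at 100% but plot totals
can exceed 100% through overlap. Complete plots have 1010 points (ten
100 m transects read at 1 m spacing with inclusive endpoints, 10 × 101);
partial surveys are normalized by observed points with a warning.
`pathway_cover()` sums member-species covers per pathway and reports
unassigned species as their own category, so pathway covers plus
unassigned cover equal total species cover exactly. Relative C₄ cover is
100 × C₄/(C₃ + C₄); facultative classes contribute to neither pole by
default (configurable via `pole_map`), and a plot with no C₃ and no C₄
cover returns `NA` rather than an error.

## 5. The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth. It emulates:

* **Pathway-conditional δ¹³C**: C₃ ~ Normal(−27, 2.5) truncated to
  [−37, −20]; C₄ ~ Normal(−13, 1.0) truncated to [−16, −12]; C₃-CAM ~
  Uniform(−27, −13), reflecting how variable facultative-CAM tissue is.
  These match the field ranges and means for the three well-characterised
  classes. The rarer classes are set once at field-plausible values
  consistent with the thresholds: CAM ~ N(−15, 1.5) on [−19, −11] (full
  CAM sits above −20‰), C₃-C₄ intermediates ~ N(−25, 2) on [−30, −20]
  (intermediates express C₄ anatomy weakly and isotopically resemble C₃),
  C₄-CAM ~ N(−13.5, 1) on [−16, −11]. Truncation uses the inverse-CDF
  method so the number of RNG draws is deterministic. Under these defaults
  C₃ truth never exceeds −20‰ and C₄ truth never falls below −16‰, so the
  −19‰ rule has ≥ 1‰ of margin on both sides — that is what makes the
  ≥ 99% label-recovery check at 0.3‰ noise a property of the design rather
  than luck.
* **Voucher records**: each species yields a barcoded record at a plot;
  configurable fractions of extra records are exact duplicates (default
  0.15), infraspecific variants (0.08), genus-only determinations (0.05)
  and hybrids (0.02), chosen so a raw registry shrinks by roughly a third
  on filtering, as multi-state herbarium streams do.
* **Surveys**: 1010 points per plot; multiple species may be hit at one
  point (an occupancy-per-species Bernoulli model), since field protocols
  differ on single- vs multi-hit recording and the multi-hit model is the
  more general choice. Per-species occupancies are Beta(1.2, ·) with mean
  0.06 — sparse arid-zone cover with a few local dominants.
* **IRMS runs**: a full standard block at run start and end, one
  interleaved standard per ten unknowns (cycling through the facility
  set), ~10% of unknowns re-measured as replicates, and raw readings =
  truth + drift × position + N(0, noise_sd). Defaults: noise 0.1‰, drift
  0.005‰/position — typical of a well-behaved continuous-flow instrument.
* **Reproducibility**: every artifact derives its own child seed from the
  master seed, so adding one output never perturbs another, and the same
  configuration reproduces byte-identical CSVs.

What it does **not** emulate: geographic realism (bioregion polygons,
climate gradients), phenological or within-species δ variation, sample
contamination, or identification error. Passing tests therefore
demonstrate that the *pipeline* is correct under the stated statistical
assumptions, not that those assumptions hold for any particular field
dataset.

The simulated literature covers 72% of species by default (with a 0.003
discrepancy rate, i.e. a rare second source disagreeing at weaker
evidence), reflecting how much of a continental flora is typically
assignable from published sources before any isotope work.

## 6. Problem sizes and determinism

The test suite and examples run at deliberately desk-scale sizes — pools of
tens to a few hundred species, 1–4 plots, runs of 50–200 unknowns, and
1000-species draws for the label-recovery property — which keep the full
suite under a minute while leaving every statistical check well-powered
(binomial SEs are computed at the stated n, and stochastic checks use
3-SE or wider margins at fixed seeds). All randomness flows from explicit
seeds; no test depends on ambient RNG state.

## 7. Known limitations

* Name parsing is rule-based (markers, placeholders, authorities); it does
  not resolve nomenclature against a taxonomic backbone, by design.
* Drift is modelled as linear; runs with step changes (e.g. after a
  re-tune) would need a piecewise model.
* The two-point anchor-selection heuristic (widest verified span) is a
  convention; facilities sometimes anchor on matrix-matched standards
  instead, which `calibrate_run(anchors = …)` supports.
* Isotope classification is only attempted inside the C₄-target families
  and CAM-potential genera; a C₄ species outside those families would be
  missed, mirroring the screening design the pipeline reproduces.
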