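# photopath

Plant photosynthetic pathway (C₃ / C₄ / CAM) assignment from plot-based
vegetation surveys and bulk-tissue stable carbon isotope analysis, as a
tested, reproducible R pipeline.

## The problem

Continental-scale questions about vegetation change — how warming and rising
CO₂ shift the balance between C₃, C₄ and CAM plants — need two things that
rarely exist together: a trait table giving the photosynthetic pathway of
every recorded species, and systematic plot surveys from which pathway
*cover* can be computed. Building such a trait table is a pipeline problem:
herbarium voucher records must be filtered to a clean species list,
literature and trait databases cross-referenced, and the species that remain
unassigned sent for isotope-ratio mass spectrometry (IRMS), whose raw δ¹³C
readings must be drift-corrected and normalized to the VPDB scale before a
threshold rule can classify them.

`photopath` implements every stage of that pipeline, plus a synthetic-data
generator that emulates the statistical structure of the field data (plot
geometry, pathway-conditional δ¹³C distributions, instrument drift and
noise, interleaved standards, replicates), so the whole analysis is testable
end to end without any external data service.

## The core methods

**δ notation.** Isotope ratios are expressed per mil relative to VPDB:
δ¹³C = (R_sa/R_ref − 1) × 1000, with R the ¹³C/¹²C abundance ratio.

**Normalization.** Raw readings are corrected for linear instrument drift
estimated from repeated standards, then mapped to the VPDB scale either by
multipoint OLS of verified standard values on measured values
(δᵀ = a·δᴹ + b) or by a two-point correction anchored at two standards:

δ_sa,c = δ_std1 + (δ_sa,m − δ_std1,m) · (δ_std2 − δ_std1)/(δ_std2,m − δ_std1,m)

Run-level QC reports the maximum absolute deviation of corrected standards
from their verified values and the mean ± SD absolute difference between
replicate samples.

**Classification.** For species in families where both C₃ and C₄ occur,
tissue δ¹³C < −19‰ ⇒ C₃ and δ¹³C > −19‰ ⇒ C₄ (the two tissue distributions,
roughly −37…−20‰ and −16…−12‰, do not overlap at −19‰). For genera with
confirmed CAM potential a three-way rule applies: > −20‰ ⇒ CAM (tentative),
−24…−20‰ ⇒ potentially C₃+CAM (tentative), < −24‰ ⇒ C₃. Literature
assignments always take precedence over isotopes, and exclusive-genus
lineage inference sits between them.

**Cover.** Point-intercept surveys (ten 100 m transects per 1-ha plot, read
every metre: 1010 points) give species cover = 100 × hits/points, pathway
cover by summation, and relative C₄ cover = 100 × C₄/(C₃ + C₄).

## Worked example

```r
library(photopath)

cfg <- pipeline_config(sim = sim_config(n_species = 120, n_plots = 4,
                                        seed = 2024))
res <- run_pipeline(cfg, out_dir = "demo_out")

res$filter
#> <species_filter> 156 records -> 120 unique species
#>   excluded: 6 genus/family-only, 2 hybrid; 10 collapsed to binomial; 28 duplicates

res$summary
#> <pathway_summary> 120 assigned, 0 unassigned
#>   pathway     n
#> 1 C3         94
#> 2 C3-C4       1
#> 3 C4         24
#> 4 CAM         1
#> C4 flora by family (share %, truncated to 1 dp):
#>   family             n share_pct
#> 1 Poaceae           13      54.1
#> 2 Cyperaceae         5      20.8
#> 3 Chenopodiaceae     4      16.6
```

The voucher registry (156 raw records) is filtered to 120 unique species;
every species is then assigned through literature, lineage or calibrated
isotopes, and the C₄ flora is dominated by grasses — shares are truncated,
not rounded, to one decimal. Per-plot cover comes out as:

```r
dplyr::select(res$plot_cover, plot_id, c3_cover, c4_cover, relative_c4)
#>   plot_id    c3_cover c4_cover relative_c4
#> 1 NSWFIN0001     94.7    47.6        33.5
#> 2 NSWGAS0001    119.      6.34        5.06
#> 3 VICFIN0001    245.     58.7        19.3
#> 4 WASTP0001     194.     77.9        28.6
```

`relative_c4` is the percentage of the C₃+C₄ cover contributed by C₄
species (cover sums exceed 100% because canopies overlap). The CSIRO-style
IRMS run in the same pipeline calibrates with

```r
res$calibrated$CSIRO$model
#> <calibration: multipoint > delta_vpdb = 0.99283 * measured + -0.248636
#>   run uncertainty (max |corrected std - verified|): 0.0647 permil, n = 9
```

All artifacts (`species_registry.csv`, `survey_points.csv`,
`pathway_table.csv`, `sources_table.csv`, `plot_cover.csv`, a provenance
YAML, …) are written to `out_dir`, and the same configuration reproduces
byte-identical files.

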