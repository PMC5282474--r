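# dualpet

Analysis toolkit for **preclinical dual-tracer PET studies of
neuroinflammation and amyloidosis**, for imaging scientists who quantify
TSPO (activated-microglia) and amyloid tracer uptake in transgenic mouse
models and relate it to terminal fluid biomarkers such as sTREM2.

Cross-sectional studies of amyloid mouse models ask *when* and *where*
microglial activation and fibrillar amyloid deposition arise, and whether
they converge spatially with age. The standard analysis chain is:

1. **SUVR quantification.** Each reference-scaled image yields
   `SUVR = mean(target VOI) / mean(reference VOI)`, with tracer-specific
   white-matter reference regions and a composite forebrain target.
2. **Voxel-wise mapping.** Per age group, a pooled-variance two-sample
   Student t statistic (TG − WT, equal groups of N = 8,
   df = n₁ + n₂ − 2) at every brain voxel; Benjamini–Hochberg FDR at
   q = 0.05 converts the one-sided elevation contrast into a t threshold
   and a binarized map.
3. **Overlap analysis.** The two tracers' binary maps combine into a
   four-category code per voxel (0 neither, 1 TSPO only, 2 amyloid only,
   3 both), summarized as percent occupancy of the whole brain, Dice
   coefficients — binary `2|A∩B|/(|A|+|B|)` and a fuzzy variant
   `2Σmin(a⁺,b⁺)/(Σa⁺+Σb⁺)` on the non-binarized t-maps — and per-tracer
   transition flows between ages.
4. **Association statistics.** ANOVA with Tukey HSD across ages, Pearson
   correlations of sTREM2 with the imaging endpoints, standardized
   (z-scored) age-adjusted regressions, standardized-difference timelines
   `d(a) = (mean_TG − wt_interp(a)) / SD_TG` against linearly aging
   controls, and noncentral-t group-size planning.

Because raw images from such studies are rarely deposited, `dualpet` also
provides a **synthetic 3D phantom cohort generator** (parametric mouse-brain
atlas, hinged-logistic amyloid growth, early diffuse + plaque-associated
inflammation, correlated voxel noise, coupled terminal biomarkers) so the
entire pipeline runs end to end without external data. See the methods
vignette (`vignettes/dualpet-methods.Rmd`) for the model.

## Worked example

```r
library(dualpet)

atlas <- build_atlas()
atlas
#> <region_atlas> 36x51x31 voxels, 10 regions, brain 1076 mm^3
#>   ref_wm_tspo          29.0 mm^3
#>   ref_wm_amyloid       67.0 mm^3
#>   target_forebrain    156.0 mm^3

cohort <- simulate_cohort(cohort_design(seed = 1))   # 2 genotypes x 4 ages x 8
cohort
#> <phantom_cohort> 128 images (64 subjects x 2 tracer(s)), 64 biomarker rows

head(cohort_suvr_table(cohort)[, c("subject_id", "tracer", "suvr")], 3)
#>   subject_id tracer     suvr
#> 1 tg_05mo_01   tspo 1.056962
#> 3 tg_05mo_02   tspo 1.038649
#> 5 tg_05mo_03   tspo 1.045913

run_pipeline(default_config(seed = 1), "run1")
rep <- jsonlite::read_json("run1/report.json", simplifyVector = TRUE)
round(rep$occupancy[, c("age_months", "pct_tspo_only",
                        "pct_amyloid_only", "pct_both")], 2)
#>   age_months pct_tspo_only pct_amyloid_only pct_both
#> 1          5          5.98             0.00     0.00
#> 2          8         68.94             0.17    10.44
#> 3         13         46.34             0.37    43.86
#> 4         16          1.92             0.35    89.05
round(rep$dice, 3)
#>  age_months dice_binary dice_continuous
#>           5       0.000           0.334
#>           8       0.232           0.364
#>          13       0.652           0.646
#>          16       0.987           0.727
subset(rep$correlations, genotype == "TG")
#>   genotype            x      y         R            p  n
#> 1       TG    tspo_suvr sTREM2 0.9831965 1.018944e-23 32
#> 2       TG amyloid_suvr sTREM2 0.9461213 3.097712e-16 32
#> 3       TG  total_Abeta sTREM2 0.8596290 2.960264e-10 32
```

Reading the output: at 5 months the transgenic brain already shows
significantly elevated TSPO binding in ~6% of brain voxels while no voxel
survives FDR for the amyloid tracer; by 16 months ~89% of the brain is
elevated for *both* tracers and the maps nearly coincide (binary
Dice 0.99). Forebrain SUVR endpoints correlate strongly with terminal
sTREM2 across the transgenic cohort. The run directory also contains per-map
NIfTI volumes, `suvr_table.csv`, `occupancy.csv`, `dice.csv`,
`transitions.csv`, the association tables, and the resolved YAML
configuration; re-running the same configuration reproduces every number
bit-identically.

A thin command-line wrapper over the same stages is installed at
`inst/cli/dualpet.R`
(`Rscript dualpet.R run-all --config cfg.yaml --out DIR`, plus per-stage
subcommands `simulate`, `quantify`, `voxelwise`, `overlap`, `associate`,
`report`).

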