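# mpfkit

Fast single-point **macromolecular proton fraction (MPF) mapping** with
synthetic-reference normalization, plus the histological-validation analysis
that goes with it — in one R package, testable end to end on a digital
mouse-brain phantom.

MPF is the bound-pool fraction of the two-pool magnetization-transfer (MT)
model and a well-established quantitative myelin surrogate: demyelination
lowers it in both white and gray matter. The fast single-point method maps
MPF from just three spoiled gradient-echo volumes (MT-, T1- and PD-weighted)
plus B0/B1 field maps: a two-point variable-flip-angle fit gives R1 and PD, a
**synthetic reference** (the Ernst signal the MT sequence would give with the
saturation pulse off) normalizes the MT-weighted image, and a voxelwise
root-solve of the two-pool pulsed-MT matrix equation — with all parameters
except MPF fixed by standard constraints (R = 19 s⁻¹, T2B = 10 µs,
T2F·R1F = 0.022, R1B = 1 s⁻¹, all configurable) — yields MPF per voxel.
Histology-side, the package quantifies Luxol-Fast-Blue myelin staining as the
red-channel optical density `OD = 100·(1 − I_R/I_B)` with off-tissue
background correction, and runs the comparison statistics: MANOVA + t-tests
with Cohen's d, Pearson/OLS regression of MPF on LFB OD, Fisher r-to-z and
ANCOVA group-equality tests, factorial ANOVA for regional effects, and
Bland–Altman / within-subject-CoV repeatability.

The package is aimed at quantitative-MRI methods researchers who need a
reference implementation of the single-point pipeline, a ground-truth phantom
to validate reconstruction code against, or the statistical battery for an
MRI–histology validation study.

## Worked example

Simulate one cuprizone-treated "animal" (a labeled phantom carrying the
published per-structure MPF means), acquire the five-sequence protocol with
Rician noise at 1% of the white-matter signal, reconstruct, and compare
per-structure means against truth:

```r
library(mpfkit)
ph  <- make_phantom(phantom_spec(group = "cuprizone"))
sig <- 0.01 * reference_wm_signal(ph)
acq <- simulate_acquisition(ph, sigma = sig, seed = 42)
qm  <- reconstruct_session(acq, noise_floor = sig)
structure_map_means(qm$mpf, ph)
#>             structure   mean     sd n_voxels truth
#> 1     corpus_callosum  9.638 0.3163     4560  9.65
#> 2 anterior_commissure 10.758 0.3482     1396 10.78
#> 3    internal_capsule 11.727 0.3801     1152 11.75
#> 4            thalamus  9.405 0.3072     2544  9.41
#> 5        caudoputamen  8.113 0.2724     1248  8.10
#> 6              cortex  7.666 0.2561    43744  7.67
```

`mean` is the reconstructed structure-mean MPF in percent, `truth` the value
the phantom was built with: every structure is recovered to within a few
hundredths of a percentage point despite the noise, and the white–gray
contrast (corpus callosum ≫ cortex) that makes MPF a myelin marker is
preserved. `qm` also carries the fitted `r1`, `pd`, the upsampled `b0`/`b1`
maps and a validity mask.

On the statistics side, the bundled group summaries
(`cohort_reference_summaries()`) reproduce the published structure-averaged
regression of MPF on LFB optical density:

```r
ref <- cohort_reference_summaries()  # 6 structures x 2 groups x 2 measures
cohens_d_from_summary(13.15, 0.73, 7, 9.65, 0.95, 7)$d
#> [1] 4.131394
```

A command-line wrapper (`inst/scripts/mpfkit`) exposes the stages
(`simulate`, `reconstruct`, `quantify-histology`, `analyze`, `repeatability`,
`end-to-end`) over the same functions; see `?cli_dispatch`.

## Package layout

- `R/mt_physics.R` — lineshapes, saturation rates, Ernst signal, two-pool
  steady state
- `R/field_relaxometry.R` — AFI B1, dual-TE B0, VFA R1/PD, field-map
  filling/upsampling
- `R/mpf_reconstruction.R` — constraints, synthetic reference, single-point
  solver, map reconstruction
- `R/phantom.R` — digital phantom, acquisition simulator, LFB renderer,
  cohort/rescan generators
- `R/histology.R` — optical-density quantification and aggregation
- `R/stats.R` — validation statistics
- `R/interface.R` — NIfTI/PNG/YAML/JSON I/O, CLI dispatcher, end-to-end run

The methods vignette (`vignettes/mpf-mapping.Rmd`) documents the model, the
phantom's assumptions, numerical choices and known limitations.
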