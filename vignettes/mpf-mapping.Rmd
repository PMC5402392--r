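---
title: "Single-point MPF mapping: model, phantom and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-point MPF mapping: model, phantom and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfkit)
```

# The two-pool pulsed-MT signal model

`mpfkit` models brain tissue as the binary spin bath of magnetization
transfer: a free water pool (F) and a semi-solid macromolecular pool (B),
coupled by the cross-relaxation rate constant $R$. The bound-pool fraction of
the total equilibrium magnetization is the **macromolecular proton fraction**
(MPF, $f$), the myelin surrogate the whole package exists to map. Each pool
has its own longitudinal rate ($R_{1F}$, $R_{1B}$) and transverse time
($T_{2F}$, $T_{2B}$); forward and reverse exchange rates are $Rf$ and
$R(1-f)$, so detailed balance holds by construction.

The MT-weighted spoiled gradient-echo (SPGR) sequence applies, every TR, an
off-resonance saturation pulse followed by a small-angle excitation. Over the
pulse of duration $t_m$ the pools are saturated at mean rates
$W = \pi\,\omega_{1,\mathrm{rms}}^2\, g(\Delta)$, where
$\omega_{1,\mathrm{rms}}$ is the RMS pulse amplitude and $g$ the pool's
absorption lineshape: super-Lorentzian for the semi-solid pool (the powder
average over orientations, singular on resonance and therefore only evaluated
at offsets of 1 kHz and beyond), Lorentzian for the liquid pool (direct
saturation). The longitudinal magnetization $(M_{zF}, M_{zB})$ then evolves
per TR as

1. relaxation–exchange *with* saturation for $t_m$,
2. instantaneous excitation by $\alpha$ acting on the free pool only,
3. free relaxation–exchange for $TR - t_m$,

each stage an affine map built from $2\times 2$ matrix exponentials of the
relaxation–exchange generator. The steady state is the fixed point of the
composed affine map, obtained in closed form; the signal is
$PD\,\sin\alpha\,M_{zF}$ at excitation. Ideal spoiling is assumed throughout
(the acquisition-side RF-spoiling phase schedules are not modeled). With zero
saturation power and $f = 0$ the model collapses to the Ernst equation, which
the tests assert to $10^{-10}$, and the closed-form fixed point matches a
2000-TR brute-force iteration to better than $10^{-6}$ over the tested grid.

## Single-point inversion with a synthetic reference

A full multi-parameter qMT fit needs many offsets/powers; the single-point
method instead fixes all two-pool parameters except $f$ through standard
constraints and inverts a *single* MT-weighted image. The package uses, and
exposes as configuration (`single_point_constraints()`):

| parameter | default | meaning |
|---|---|---|
| $R$ | 19 s⁻¹ | cross-relaxation rate constant |
| $T_{2B}$ | 10 µs | bound-pool transverse time |
| $T_{2F} R_{1F}$ | 0.022 | free-pool constraint product |
| $R_{1B}$ | 1 s⁻¹ | bound-pool longitudinal rate |

These are the conventional constraint values of the single-point literature;
rodent-brain values at a particular field strength are a calibration input,
which is exactly why they are configuration keys rather than constants.

The measured (VFA) $R_1$ is interpreted as the slow eigenvalue of the coupled
relaxation–exchange matrix; `r1f_from_observed()` solves that constraint for
$R_{1F}$ at each candidate $f$. Normalization uses a **synthetic reference**:
the Ernst signal the MT sequence would give with the saturation pulse off,
computed from the fitted $R_1$/$PD$ maps at the MT sequence's TR and
B1-corrected flip angle — no separately acquired reference image is needed.
The measured ratio (MT-weighted / synthetic reference) is matched against the
model ratio, which is strictly decreasing in $f$ at the protocol settings (a
tested invariant), so the root is unique. The solver runs a vectorized
bracketed bisection on $f \in [0, 0.45]$ for a fixed 26 iterations
($|\Delta f| < 10^{-7}$, beyond the $10^{-6}$ working tolerance); bisection
was preferred over secant refinement because it vectorizes across all voxels
of a volume and is unconditionally safe on a monotone model. Ratios outside
the attainable band $[\,\mathrm{ratio}(0.45), \mathrm{ratio}(0)\,]$ are
flagged invalid (`NA`), never clamped. Local fields enter as the effective
offset $\Delta + B_0$ and as the $B_1$ scale applied to both
$\omega_{1,\mathrm{rms}}$ and the excitation angle.

## Field mapping and relaxometry

* **B1** — dual-TR actual flip-angle imaging (AFI): with $n = TR_2/TR_1$ and
  $r = S_2/S_1$, $\cos\alpha = (rn-1)/(n-r)$. This closed form is a short-TR
  approximation; on noiseless, ideally spoiled signals it recovers the actual
  angle to about $10^{-3}$ relative at $T_1 \ge 1$ s, a documented systematic
  error the package accepts (see *Accuracy budget* below).
* **B0** — dual-TE phase difference: principal value of $\Delta\phi$ over
  $2\pi\,\Delta TE$, exact (to $10^{-9}$) within $\pm 1/(2\Delta TE)$ =
  ±294 Hz at the protocol's echo times; larger offsets alias and no spatial
  unwrapping is attempted, adequate at the simulated shim quality.
* **R1/PD** — two-point variable-flip-angle (DESPOT1) fit of the T1- and
  PD-weighted SPGR pair, linearized as $S/\sin\alpha$ vs $S/\tan\alpha$ with
  B1-corrected angles; exact on noiseless Ernst signals.

Field maps are acquired (and simulated) on a 2× coarser in-plane grid, as in
practice. Before use they are masked to tissue, out-of-tissue voxels are
filled from the nearest tissue values (iterative neighbor averaging), and the
maps are brought to the imaging grid by voxel-center-aligned bilinear
interpolation. The filling step matters: without it, background values (B0 of
zero, undefined B1) bleed into edge voxels of the cortex during
interpolation.

# The digital phantom

The synthetic cohort stands in for the animals of a demyelination study. The
phantom is a schematic, *labeled* geometry — an ellipsoidal brain whose outer
shell is cortex, a callosal slab, a thin anterior-commissure bar, paired
internal-capsule limbs, a central thalamus and paired caudoputamen — on a
96×96×24 grid at 0.1×0.1×0.5 mm. Validation needs structure labels, not
anatomy, so no atlas is used. Per-structure MPF values are the published
group means bundled in `cohort_reference_summaries()` (e.g. corpus callosum
13.15% control, 9.65% cuprizone); choosing the control or cuprizone column
yields the two cohorts. Structure-resolved $T_1$ and $PD$ are not reported in
those summaries, so the phantom assumes high-field rodent-brain values
($T_1$ 1.6 s in white matter, 1.9 s in gray matter; relative $PD$ 0.85/0.95)
— these are flagged as assumptions and are configurable.

Two modeling decisions were forced by round-trip consistency and are worth
stating explicitly:

* **Constraint-consistent tissue parameters.** Per-voxel two-pool parameters
  are assembled from $(f, R_{1,\mathrm{obs}} = 1/T_1)$ with the *same*
  constraint family the solver assumes ($R_{1B}$ from the constraint set,
  $R_{1F}$ from the observed-R1 inversion). An alternative assembly
  ($R_{1F} = R_{1B} = 1/T_1$) yields the same observed $R_1$ but, inverted
  under the standard constraints, biases recovered MPF by about −1.1
  percentage points at $f = 0.13$. That experiment measures sensitivity to
  constraint mis-specification — a real and separately explorable effect (the
  constraints are config keys) — not the correctness of the inversion, which
  is what the phantom is for.
* **MT-transparent low-power readouts.** Only the MT-weighted sequence is
  simulated with the two-pool propagator. The T1-/PD-weighted, B0-GRE and
  AFI readouts are simulated as single-pool steady states at the observed
  $R_1$: simulating them two-pool (excitation on the free pool only) makes
  the two-point VFA overestimate $R_1$ (0.711 vs 0.625 s⁻¹ at $f=0.13$) and
  drags recovered MPF down by ~0.5 pp. Real low-power readouts do carry
  second-order MT effects; the phantom deliberately excludes them so that
  passing tests certify the reconstruction chain, not a particular
  readout-MT model.

Magnitude noise is Rician (two independent Gaussian quadrature channels of
standard deviation $\sigma$; the background magnitude mean
$\sigma\sqrt{\pi/2}$ is a tested invariant); phases are arguments of the
noisy complex signals. The noise anchor is `reference_wm_signal()`, the
noiseless T1-weighted corpus-callosum mean, with $\sigma$ = 1% of it in the
standard noisy condition. All stochastic stages take explicit seeds and are
bit-reproducible.

## Synthetic histology

Luxol-Fast-Blue sections are rendered by inverting the optical-density
definition $OD = 100(1 - I_R/I_B)$: per-pixel OD comes from the MPF truth
through the linear calibration $MPF = 0.135\,OD + 5.941$ (the pooled
structure-averaged regression of the reference study, so the MRI and
histology arms of the phantom are mutually consistent), the red channel is
$I_B(1 - OD/100)$ quantized to 8 bits, and green/blue are cosmetic. Three
adjacent sections per location are emitted, quantified by ROI red-channel
means with four off-tissue background ROIs, and averaged per structure and
location. With noise off, quantification inverts rendering up to 8-bit
rounding (≤ 0.5/245 of full scale, ≈ 0.2 OD points); this round trip is
asserted in the tests.

# Statistics

The analysis stage reproduces the validation statistics of an MRI–histology
comparison: Shapiro–Wilk normality; one-way MANOVA (Wilks' Λ, Rao's F)
followed by per-structure equal-variance t-tests and Cohen's d (df-weighted
pooled SD — at equal n the average-variance form, as asserted in tests);
Pearson/OLS regression of MPF on LFB OD with t-based CIs; Fisher r-to-z
comparison of group correlations; ANCOVA equality of slopes (interaction
test) and intercepts (group effect under homogeneous slopes); three-factor
fixed-effects ANOVA with sum-to-zero coding and Type III tests (main effects
plus pairwise interactions, no three-way term) via `car::Anova`; and
Bland–Altman repeatability with bias, 1.96-SD limits of agreement, one-sample
t on the bias, mean-centered Levene test, and within-subject CoV (per-pair
SD over pair mean; aggregated across subjects as the arithmetic mean by
default, RMS optionally — the convention is ambiguous in common usage, so
both are offered). Two-tailed tests at α = 0.05 throughout, with no
multiple-testing correction, matching standard practice in this validation
literature. Whether animal should be a random factor in the regional ANOVA
is left as stated: the model is fixed-effects as written.

Worked example on the bundled structure-averaged group summaries:

```{r worked-example, eval = FALSE}
ref <- cohort_reference_summaries()
w <- reshape(ref[, c("structure", "measure", "group", "mean")],
             idvar = c("structure", "group"), timevar = "measure",
             direction = "wide")
names(w) <- sub("^mean\\.", "", names(w))
ctl <- w[w$group == "control", ]
pearson_regression(ctl$lfb_od_percent, ctl$mpf_percent)[c("r", "slope", "intercept")]
#> $r        0.933
#> $slope    0.1387
#> $intercept 5.650
cohens_d_from_summary(13.15, 0.73, 7, 9.65, 0.95, 7)$d
#> [1] 4.131
```

# Accuracy budget and known limitations

On the noiseless 96×96×24 phantom the full chain (five-sequence simulation →
field maps → VFA → synthetic reference → single-point inversion) recovers
per-structure MPF within 0.017 percentage points. The dominant residual is
the AFI short-TR approximation (~10⁻³ in $B_1$, which propagates at roughly
15 pp of MPF per unit $B_1$ error at this protocol); interpolation of the
coarse field maps contributes a few 10⁻⁴. Under the standard noisy condition
(σ = 1% of WM signal) the per-voxel MPF SD is ≈ 0.3–0.5 pp and structure
means are reproducible to ~0.02 pp across seeds. Because noise averages over
10³–10⁴ voxels per structure while the AFI floor does not shrink, the
deterministic floor — not noise — limits agreement with truth at replicate
level; the repository's test suite states this where it applies.

Problem sizes used by the default test and acceptance runs, chosen as
representative working sizes: the full-resolution phantom for noiseless and
20-replicate noisy recovery; 48×48×12 phantoms for unit tests of the
reconstruction chain; 1000 simulated null datasets for ANOVA type-I
calibration; 100 simulated rescan sessions (7 subjects, 2% single-scan CoV)
for Bland–Altman calibration.

What passing tests do *not* show about real data: the phantom has no
partial-volume mixing beyond nearest-label assignment, no anatomy, no
motion/registration error, ideal spoiling, exactly known protocol timing, a
noiseless linear MPF–OD relation underlying the synthetic histology, and
tissue parameters drawn from the same constraint family the solver assumes.
Real-world deviations from any of these (notably constraint mis-calibration
at a given field strength, which the configuration exposes for sensitivity
analysis) will add biases the synthetic validation cannot reveal.
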