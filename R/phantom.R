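# Digital mouse-brain-like phantom: labeled geometry carrying per-structure
# two-pool parameters, five-sequence acquisition simulation with smooth
# B0/B1 fields and Rician noise, and synthetic LFB-stained sections.

#' Reference group summaries for the six analyzed brain structures
#'
#' Published group-level means and standard deviations of MPF (percent) and
#' LFB optical density (percent) in control and cuprizone-treated mice
#' (n = 7 per group) for the six structures quantified by the pipeline:
#' corpus callosum, anterior commissure, internal capsule, thalamus,
#' caudoputamen and cortex.  These summaries parameterize the phantom
#' cohorts and serve as worked-example inputs for the statistics module.
#'
#' @return Data frame with columns `structure`, `measure` (`mpf_percent` or
#'   `lfb_od_percent`), `group` (`control`/`cuprizone`), `mean`, `sd`, `n`.
#' @export
cohort_reference_summaries <- function() {
  st <- c("corpus_callosum", "anterior_commissure", "internal_capsule",
          "thalamus", "caudoputamen", "cortex")
  mpf_c <- c(13.15, 11.93, 12.74, 10.01, 8.54, 8.13)
  mpf_s <- c(0.73, 0.74, 0.67, 0.44, 0.25, 0.22)
  mpf_z <- c(9.65, 10.78, 11.75, 9.41, 8.10, 7.67)
  mpf_zs <- c(0.95, 0.77, 0.69, 0.51, 0.33, 0.27)
  od_c <- c(49.14, 46.09, 52.54, 25.76, 30.68, 16.46)
  od_cs <- c(3.23, 7.61, 8.43, 3.69, 6.21, 3.40)
  od_z <- c(29.35, 37.48, 39.92, 20.59, 18.64, 12.21)
  od_zs <- c(4.27, 4.01, 5.87, 4.90, 5.09, 3.30)
  data.frame(
    structure = rep(st, 4),
    measure = rep(c("mpf_percent", "lfb_od_percent"), each = 2 * length(st)),
    group = rep(rep(c("control", "cuprizone"), each = length(st)), 2),
    mean = c(mpf_c, mpf_z, od_c, od_z),
    sd = c(mpf_s, mpf_zs, od_cs, od_zs),
    n = 7L,
    stringsAsFactors = FALSE)
}

#' Five-sequence acquisition protocol of the MPF mapping pipeline
#'
#' Sequence parameter bundles of the whole-brain protocol: MT-weighted SPGR
#' (TR 22 ms, flip 9 deg, Gaussian saturation pulse at 4.5 kHz offset,
#' effective flip 900 deg, duration 10 ms), T1-weighted SPGR (TR 16 ms,
#' flip 16 deg), PD-weighted SPGR (TR 16 ms, flip 3 deg), dual-TE GRE for B0
#' (TR 20 ms, flip 8 deg, TE 2.4/4.1 ms), and dual-TR AFI for B1
#' (TR 13/65 ms, flip 60 deg).
#'
#' @return Named list with [spgr_protocol()] elements `mt`, `t1w`, `pdw`,
#'   `b0` and an `afi` list (`tr1`, `tr2`, `flip`, `TE`).
#' @export
default_protocols <- function() {
  list(
    mt = spgr_protocol(0.022, 9, 0.0025,
                       mt_pulse("gaussian", 0.010, 900, 4500), "mt_w"),
    t1w = spgr_protocol(0.016, 16, 0.0025, label = "t1_w"),
    pdw = spgr_protocol(0.016, 3, 0.0025, label = "pd_w"),
    b0 = spgr_protocol(0.020, 8, c(0.0024, 0.0041), label = "b0_gre"),
    afi = list(tr1 = 0.013, tr2 = 0.065, flip = 60, TE = 0.0037))
}

#' Per-structure tissue table of the digital phantom
#'
#' @param group `"control"` or `"cuprizone"`; selects the per-structure MPF
#'   means of [cohort_reference_summaries()].  T1 and relative PD are not
#'   structure-resolved in the reference summaries; white matter defaults to
#'   T1 = 1.6 s, gray matter to 1.9 s (high-field rodent brain assumptions),
#'   with relative PD 0.85 (WM) and 0.95 (GM).
#' @return Data frame with columns `label`, `name`, `mpf_percent`, `t1_s`,
#'   `pd_rel`, `in_analysis`.
#' @export
default_structures <- function(group = c("control", "cuprizone")) {
  group <- match.arg(group)
  ref <- cohort_reference_summaries()
  ref <- ref[ref$measure == "mpf_percent" & ref$group == group, ]
  st <- c("corpus_callosum", "anterior_commissure", "internal_capsule",
          "thalamus", "caudoputamen", "cortex")
  wm <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  d <- data.frame(
    label = seq_along(st),
    name = st,
    mpf_percent = ref$mean[match(st, ref$structure)],
    t1_s = ifelse(wm, 1.6, 1.9),
    pd_rel = ifelse(wm, 0.85, 0.95),
    in_analysis = TRUE,
    stringsAsFactors = FALSE)
  # non-analyzed surround tissue filling the rest of the brain
  rbind(d, data.frame(label = 7L, name = "brain_other", mpf_percent = 8.0,
                      t1_s = 1.9, pd_rel = 0.95, in_analysis = FALSE))
}

#' Phantom specification
#'
#' @param group Cohort whose per-structure MPF means the phantom carries.
#' @param structures Structure table as from [default_structures()].
#' @param dim Grid dimensions (voxels).
#' @param voxel Voxel size (mm).
#' @param b1_coef,b0_coef Coefficients `(1, x, y, z, x^2, y^2, z^2)` of the
#'   smooth second-order B1 (dimensionless scale) and B0 (Hz) fields over
#'   normalized coordinates in `[-1, 1]`.
#' @param jitter_sd Within-structure Gaussian jitter of MPF (percentage
#'   points), seeded; 0 disables.
#' @param seed Seed for the jitter realization.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(group = "control",
                         structures = default_structures(group),
                         dim = c(96, 96, 24), voxel = c(0.1, 0.1, 0.5),
                         b1_coef = c(1.04, 0.02, 0, 0, -0.10, -0.10, -0.04),
                         b0_coef = c(0, 40, 30, 0, -50, -50, 25),
                         jitter_sd = 0, seed = NULL) {
  stopifnot(length(dim) == 3, length(voxel) == 3, jitter_sd >= 0,
            !anyDuplicated(structures$label),
            all(structures$mpf_percent >= 0, structures$mpf_percent <= 50))
  structure(list(group = group, structures = structures, dim = dim,
                 voxel = voxel, b1_coef = b1_coef, b0_coef = b0_coef,
                 jitter_sd = jitter_sd, seed = seed),
            class = "phantom_spec")
}

.poly_field <- function(coef, x, y, z) {
  coef[1] + coef[2] * x + coef[3] * y + coef[4] * z +
    coef[5] * x^2 + coef[6] * y^2 + coef[7] * z^2
}

#' Build the labeled digital phantom
#'
#' Constructs a schematic mouse-brain-like geometry on the requested grid:
#' an ellipsoidal brain whose outer shell is cortex, a callosal slab, a thin
#' commissural bar, paired internal-capsule limbs, a central thalamus and
#' paired caudoputamen ellipsoids, surrounded by non-analyzed brain tissue.
#' Each voxel carries the structure's macromolecular proton fraction
#' (optionally with seeded within-structure jitter), proton density and an
#' observed R1 of `1/t1_s`; smooth B0/B1 fields are evaluated on the grid.
#' The deep structures are checked to be pairwise disjoint.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `mpf_phantom`: list with integer array
#'   `labels` (0 = background), the structure table, and per-voxel truth
#'   arrays `f` (fraction), `r1_obs` (1/s), `pd`, `b0` (Hz), `b1`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  x <- array(rep(seq(-1, 1, length.out = d[1]), times = d[2] * d[3]), d)
  y <- array(rep(rep(seq(-1, 1, length.out = d[2]), each = d[1]),
                 times = d[3]), d)
  z <- array(rep(seq(-1, 1, length.out = d[3]), each = d[1] * d[2]), d)
  rho <- (x / 0.88)^2 + (y / 0.92)^2 + (z / 0.97)^2
  st <- spec$structures
  lab_of <- function(nm) st$label[match(nm, st$name)]
  labels <- array(0L, d)
  labels[rho <= 1] <- lab_of("brain_other")
  labels[rho <= 1 & rho >= 0.62] <- lab_of("cortex")
  deep <- list(
    corpus_callosum = rho < 0.62 & y >= 0.30 & y <= 0.44 & abs(x) <= 0.55,
    anterior_commissure = rho < 0.62 & y >= -0.56 & y <= -0.46 &
      abs(x) <= 0.30 & abs(z) <= 0.45,
    internal_capsule = rho < 0.62 & abs(x) >= 0.30 & abs(x) <= 0.36 &
      y >= -0.30 & y <= 0.05 & abs(z) <= 0.5,
    thalamus = (x / 0.26)^2 + ((y + 0.12) / 0.18)^2 + (z / 0.5)^2 <= 1,
    caudoputamen = ((abs(x) - 0.46) / 0.09)^2 + ((y - 0.05) / 0.16)^2 +
      (z / 0.4)^2 <= 1)
  for (i in seq_along(deep)) for (j in seq_len(i - 1))
    if (any(deep[[i]] & deep[[j]]))
      stop("phantom structures overlap: ", names(deep)[i], " / ",
           names(deep)[j])
  for (nm in names(deep)) labels[deep[[nm]]] <- lab_of(nm)

  f <- array(NA_real_, d); pd <- array(0, d); r1 <- array(NA_real_, d)
  for (i in seq_len(nrow(st))) {
    m <- labels == st$label[i]
    f[m] <- st$mpf_percent[i] / 100
    pd[m] <- st$pd_rel[i]
    r1[m] <- 1 / st$t1_s[i]
  }
  if (spec$jitter_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    inb <- labels > 0
    f[inb] <- clip(f[inb] + stats::rnorm(sum(inb), 0, spec$jitter_sd / 100),
                   0, 0.45)
  }
  structure(list(spec = spec, structures = st, labels = labels, f = f,
                 r1_obs = r1, pd = pd,
                 b0 = .poly_field(spec$b0_coef, x, y, z),
                 b1 = .poly_field(spec$b1_coef, x, y, z)),
            class = "mpf_phantom")
}

# in-plane resampling to the coarse field-mapping grid: nearest-label point
# sampling for tissue properties (no partial-volume mixing, the phantom's
# nearest-label convention) and block averaging for smooth fields (value at
# the coarse voxel center up to second order)
.decimate_xy <- function(vol, fac = 2) {
  d <- dim(vol)
  stopifnot(d[1] %% fac == 0, d[2] %% fac == 0)
  vol[seq(1, d[1], fac), seq(1, d[2], fac), , drop = FALSE]
}

.block_mean_xy <- function(vol, fac = 2) {
  d <- dim(vol)
  stopifnot(d[1] %% fac == 0, d[2] %% fac == 0)
  out <- array(0, c(d[1] / fac, d[2] / fac, d[3]))
  for (i in seq_len(fac)) for (j in seq_len(fac))
    out <- out + vol[seq(i, d[1], fac), seq(j, d[2], fac), , drop = FALSE]
  out / fac^2
}

#' Reference white-matter signal level of a phantom
#'
#' Mean noiseless T1-weighted signal over the corpus callosum; the anchor
#' for expressing noise standard deviations as a fraction of the
#' white-matter signal.
#'
#' @param phantom An [make_phantom()] result.
#' @param protocols Protocol list (see [default_protocols()]).
#' @return Scalar signal amplitude (a.u.).
#' @export
reference_wm_signal <- function(phantom, protocols = default_protocols()) {
  m <- phantom$labels ==
    phantom$structures$label[phantom$structures$name == "corpus_callosum"]
  mean(spgr_signal(phantom$pd[m], phantom$r1_obs[m],
                   protocols$t1w$flip * phantom$b1[m], protocols$t1w$TR))
}

#' Simulate the five-sequence acquisition over a phantom
#'
#' Generates the source data of one imaging session: the MT-weighted volume
#' from the two-pool pulsed-MT steady state (per-voxel parameters assembled
#' from the phantom's f and observed R1 under the constraint set, with the
#' local B0/B1 fields), T1-/PD-weighted volumes from the Ernst equation, a
#' dual-TE phase pair encoding the B0 field, and a dual-TR AFI magnitude
#' pair encoding the B1 field.  The low-power non-MT readouts are treated as
#' MT-transparent (single-pool).  Field-mapping sequences are simulated on a
#' 2x coarser in-plane grid, as acquired in practice.  Magnitudes receive
#' Rician noise (two Gaussian quadrature channels of standard deviation
#' `sigma`); phases are the arguments of the noisy complex signals.
#'
#' @param phantom An [make_phantom()] result.
#' @param protocols Protocol list (see [default_protocols()]).
#' @param sigma Gaussian channel noise standard deviation (a.u.).
#' @param seed Seed for the noise realization.
#' @param constraints [single_point_constraints()] used to assemble the
#'   two-pool parameters from the phantom truth.
#' @param lowres_fields Simulate B0/AFI on the coarse grid (default) or on
#'   the full grid.
#' @return List with arrays `mt_w`, `t1_w`, `pd_w` (full grid), `b0_phase1`,
#'   `b0_phase2`, `afi1`, `afi2` (coarse grid when `lowres_fields`), plus
#'   `sigma` and the protocol list.
#' @export
simulate_acquisition <- function(phantom, protocols = default_protocols(),
                                 sigma = 0, seed = NULL,
                                 constraints = single_point_constraints(),
                                 lowres_fields = TRUE) {
  stopifnot(inherits(phantom, "mpf_phantom"), sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(phantom$labels)
  inb <- which(phantom$labels > 0)
  f <- phantom$f[inb]; r1 <- phantom$r1_obs[inb]; pdv <- phantom$pd[inb]
  b0 <- phantom$b0[inb]; b1 <- phantom$b1[inb]

  p <- .two_pool_from_observed(r1, f, constraints)
  pl <- protocols$mt$mt_pulse
  w1rms <- omega1_rms_from_pulse(pl)
  mt <- array(0, d)
  mt[inb] <- .mt_ss_core(p$f, p$R1F, p$R1B, p$T2F, p$T2B, p$R, pdv,
                         protocols$mt$TR, protocols$mt$flip, pl$duration,
                         pl$offset, w1rms, b0, b1)
  t1w <- array(0, d)
  t1w[inb] <- spgr_signal(pdv, r1, protocols$t1w$flip * b1, protocols$t1w$TR)
  pdw <- array(0, d)
  pdw[inb] <- spgr_signal(pdv, r1, protocols$pdw$flip * b1, protocols$pdw$TR)

  if (lowres_fields) {
    pd_lo <- .decimate_xy(phantom$pd)
    r1_lo <- .decimate_xy(ifelse(phantom$labels > 0, phantom$r1_obs, 0))
    b0_lo <- .block_mean_xy(phantom$b0)
    b1_lo <- .block_mean_xy(phantom$b1)
  } else {
    pd_lo <- phantom$pd
    r1_lo <- ifelse(phantom$labels > 0, phantom$r1_obs, 0)
    b0_lo <- phantom$b0; b1_lo <- phantom$b1
  }
  tiss <- pd_lo > 0 & r1_lo > 0
  gre_mag <- array(0, dim(pd_lo))
  gre_mag[tiss] <- spgr_signal(pd_lo[tiss], r1_lo[tiss],
                               protocols$b0$flip * b1_lo[tiss],
                               protocols$b0$TR)
  noisy_phase <- function(mag, te) {
    ph <- 2 * pi * b0_lo * te
    re <- mag * cos(ph); im <- mag * sin(ph)
    if (sigma > 0) {
      re <- re + stats::rnorm(length(re), 0, sigma)
      im <- im + stats::rnorm(length(im), 0, sigma)
    }
    array(atan2(im, re), dim(mag))
  }
  afi <- list(s1 = array(0, dim(pd_lo)), s2 = array(0, dim(pd_lo)))
  sa <- afi_signal(r1_lo[tiss], pd_lo[tiss],
                   protocols$afi$flip * b1_lo[tiss],
                   protocols$afi$tr1, protocols$afi$tr2)
  afi$s1[tiss] <- sa$s1; afi$s2[tiss] <- sa$s2

  add_rice <- function(v) array(rician(v, sigma), dim(v))
  list(mt_w = add_rice(mt), t1_w = add_rice(t1w), pd_w = add_rice(pdw),
       b0_phase1 = noisy_phase(gre_mag, protocols$b0$TEs[1]),
       b0_phase2 = noisy_phase(gre_mag, protocols$b0$TEs[2]),
       afi1 = add_rice(afi$s1), afi2 = add_rice(afi$s2),
       sigma = sigma, protocols = protocols)
}

#' Reconstruct field maps and the MPF map from a simulated session
#'
#' Convenience wrapper chaining [dual_te_b0()], [afi_b1()] (with in-plane
#' upsampling of the coarse field maps to the imaging grid) and
#' [reconstruct_mpf_map()].
#'
#' @param acq Output of [simulate_acquisition()].
#' @param constraints A [single_point_constraints()].
#' @param noise_floor Background noise level for the signal mask (a.u.).
#' @return A `quant_maps` object (see [reconstruct_mpf_map()]) with the
#'   upsampled `b0` and `b1` maps attached.
#' @export
reconstruct_session <- function(acq, constraints = single_point_constraints(),
                                noise_floor = acq$sigma) {
  pr <- acq$protocols
  b0_lo <- array(dual_te_b0(acq$b0_phase1, acq$b0_phase2,
                            pr$b0$TEs[1], pr$b0$TEs[2]),
                 dim(acq$b0_phase1))
  b1_lo <- array(afi_b1(acq$afi1, acq$afi2, pr$afi$tr1, pr$afi$tr2,
                        pr$afi$flip),
                 dim(acq$afi1))
  # trust only in-tissue coarse voxels; fill the rest from nearest tissue
  tissue_lo <- acq$afi1 > pmax(5 * noise_floor, .Machine$double.eps)
  b0_lo <- fill_field_map(b0_lo, tissue_lo)
  b1_lo <- fill_field_map(b1_lo, tissue_lo & is.finite(b1_lo))
  dxy <- dim(acq$mt_w)[1:2]
  b0 <- upsample_xy(b0_lo, dxy)
  b1 <- upsample_xy(b1_lo, dxy)
  qm <- reconstruct_mpf_map(acq$mt_w, acq$t1_w, acq$pd_w, b0, b1,
                            protocols = pr, constraints = constraints,
                            noise_floor = noise_floor)
  qm$b0 <- b0; qm$b1 <- b1
  qm
}

#' Per-structure means of a reconstructed map
#'
#' @param map 3D array (e.g. the `mpf` element of a `quant_maps`).
#' @param phantom The phantom that generated the data.
#' @param analysis_only Restrict to the six analyzed structures.
#' @return Data frame with `structure`, `mean`, `sd`, `n_voxels`, and the
#'   phantom's true structure value `truth` (same units as `map` for MPF).
#' @export
structure_map_means <- function(map, phantom, analysis_only = TRUE) {
  st <- phantom$structures
  if (analysis_only) st <- st[st$in_analysis, ]
  out <- lapply(seq_len(nrow(st)), function(i) {
    m <- phantom$labels == st$label[i]
    v <- map[m]
    data.frame(structure = st$name[i], mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE), n_voxels = sum(m),
               truth = st$mpf_percent[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Calibration linking MPF to LFB optical density
#'
#' Linear mapping `MPF = slope * OD + intercept` used to render synthetic
#' histology consistent with the MRI phantom; defaults are the pooled
#' structure-averaged regression coefficients of the reference study, so
#' rendered sections and MPF maps are mutually consistent.
#'
#' @param slope,intercept Regression coefficients (MPF percent per OD
#'   percent; MPF percent).
#' @return List with `slope` and `intercept`.
#' @export
lfb_calibration <- function(slope = 0.135, intercept = 5.941) {
  stopifnot(slope > 0)
  list(slope = slope, intercept = intercept)
}

#' Render synthetic LFB-stained RGB sections from an MPF truth slice
#'
#' Inverts the optical-density definition: per-pixel OD (percent) is
#' `(MPF - intercept)/slope` clipped to `[0, 100]`, and the red channel is
#' `I_B * (1 - OD/100)` (stronger myelin staining absorbs more red light).
#' Green and blue channels are set for a plausible blue-stain appearance and
#' are not used by quantification.  Pixels outside tissue (`NA` MPF) render
#' at the background intensity.  Three adjacent sections per anatomical
#' location are emitted by default, each with an independent seeded noise
#' realization.
#'
#' @param mpf_slice 2D matrix of MPF truth (percent), `NA` outside tissue.
#' @param calibration An [lfb_calibration()].
#' @param I_B Background red-channel intensity (8-bit units, in (0, 255]).
#' @param noise_sd Gaussian pixel noise (8-bit units) added per channel.
#' @param n_sections Number of adjacent sections to render.
#' @param seed Seed for the noise realizations.
#' @return List of `n_sections` numeric arrays `nrow x ncol x 3` with values
#'   in 0..255 (8-bit quantized).
#' @export
render_lfb_sections <- function(mpf_slice, calibration = lfb_calibration(),
                                I_B = 245, noise_sd = 0, n_sections = 3,
                                seed = NULL) {
  stopifnot(is.matrix(mpf_slice), I_B > 0, I_B <= 255, n_sections >= 1)
  if (!is.null(seed)) set.seed(seed)
  od <- clip((mpf_slice - calibration$intercept) / calibration$slope, 0, 100)
  od[is.na(mpf_slice)] <- 0
  chan <- function(absorb) I_B * (1 - absorb * od / 100)
  base <- c(chan(1), chan(0.80), chan(0.25))     # R, G, B
  lapply(seq_len(n_sections), function(s) {
    img <- base
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    array(clip(round(img), 0, 255), c(dim(mpf_slice), 3))
  })
}

#' Simulate a two-group cohort of per-animal ROI measurements
#'
#' Light-weight cohort generator for the statistics pipeline: per-animal,
#' per-structure MPF means are drawn from the reference group summaries
#' (Gaussian, seeded); matching LFB optical densities follow the linear
#' calibration with an animal-level histological residual, and are expanded
#' to per-location, per-section raw measurements with measurement noise.
#'
#' @param n_per_group Animals per group.
#' @param seed Seed for all draws.
#' @param ref Reference summaries (see [cohort_reference_summaries()]).
#' @param calibration An [lfb_calibration()].
#' @param n_locations Anatomical locations (sections sites) per animal.
#' @param n_sections Adjacent sections per location (histology).
#' @param mpf_location_sd SD of the per-location MPF measurement around the
#'   animal mean (percentage points).
#' @param od_residual_sd SD of the animal-level OD residual around the
#'   calibration line (OD percent).
#' @param od_section_sd SD of the per-section OD measurement (OD percent).
#' @return Raw measurement data frame with columns `animal_id`, `group`,
#'   `structure`, `location`, `section_index`, `measure`, `value`.
#' @export
simulate_cohort <- function(n_per_group = 7, seed = NULL,
                            ref = cohort_reference_summaries(),
                            calibration = lfb_calibration(),
                            n_locations = 2, n_sections = 3,
                            mpf_location_sd = 0.15, od_residual_sd = 3,
                            od_section_sd = 1.5) {
  if (!is.null(seed)) set.seed(seed)
  refm <- ref[ref$measure == "mpf_percent", ]
  rows <- list()
  for (g in c("control", "cuprizone")) {
    rg <- refm[refm$group == g, ]
    for (a in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", substr(g, 1, 3), a)
      for (i in seq_len(nrow(rg))) {
        m_true <- stats::rnorm(1, rg$mean[i], rg$sd[i])
        od_true <- (m_true - calibration$intercept) / calibration$slope +
          stats::rnorm(1, 0, od_residual_sd)
        od_true <- clip(od_true, 0, 100)
        for (loc in seq_len(n_locations)) {
          rows[[length(rows) + 1]] <- data.frame(
            animal_id = id, group = g, structure = rg$structure[i],
            location = loc, section_index = NA_integer_,
            measure = "mpf_percent",
            value = stats::rnorm(1, m_true, mpf_location_sd),
            stringsAsFactors = FALSE)
          for (s in seq_len(n_sections)) {
            rows[[length(rows) + 1]] <- data.frame(
              animal_id = id, group = g, structure = rg$structure[i],
              location = loc, section_index = s,
              measure = "lfb_od_percent",
              value = clip(stats::rnorm(1, od_true, od_section_sd), 0, 100),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate paired scan-rescan structure means
#'
#' Draws per-subject true structure values from the control reference
#' summaries and two repeated measurements with multiplicative Gaussian
#' measurement error, emulating a scan-rescan repeatability session.
#'
#' @param n_subjects Number of subjects.
#' @param cv Within-subject coefficient of variation of a single measurement
#'   (fraction, e.g. 0.02).
#' @param seed Seed.
#' @param ref Reference summaries.
#' @return Data frame with `subject`, `structure`, `scan1`, `scan2`.
#' @export
simulate_rescan <- function(n_subjects = 7, cv = 0.02, seed = NULL,
                            ref = cohort_reference_summaries()) {
  if (!is.null(seed)) set.seed(seed)
  refm <- ref[ref$measure == "mpf_percent" & ref$group == "control", ]
  out <- list()
  for (i in seq_len(nrow(refm))) {
    truth <- stats::rnorm(n_subjects, refm$mean[i], refm$sd[i])
    out[[i]] <- data.frame(
      subject = seq_len(n_subjects), structure = refm$structure[i],
      scan1 = truth * (1 + stats::rnorm(n_subjects, 0, cv)),
      scan2 = truth * (1 + stats::rnorm(n_subjects, 0, cv)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
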