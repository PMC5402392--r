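# Single-point MPF reconstruction: synthetic-reference normalization and
# voxelwise inversion of the two-pool pulsed-MT steady state.

#' Constraint set of the single-point method
#'
#' The single-point inversion fixes all two-pool parameters except the
#' macromolecular proton fraction through standard constraints: the
#' cross-relaxation rate constant `R`, the bound-pool transverse time `T2B`,
#' the product `T2F * R1F` of the free pool, and the bound-pool longitudinal
#' rate `R1B`.  Defaults are the conventional values of the single-point
#' literature; all four are configurable because constraint values for a
#' given field strength and species are calibration inputs.
#'
#' @param R Cross-relaxation rate constant (1/s).
#' @param T2B Bound-pool transverse relaxation time (s).
#' @param T2F_R1F Dimensionless product `T2F * R1F` of the free pool.
#' @param R1B Bound-pool longitudinal rate (1/s).
#' @return An object of class `single_point_constraints`.
#' @export
single_point_constraints <- function(R = 19, T2B = 1e-5, T2F_R1F = 0.022,
                                     R1B = 1) {
  stopifnot(R > 0, T2B > 0, T2F_R1F > 0, R1B > 0)
  structure(list(R = R, T2B = T2B, T2F_R1F = T2F_R1F, R1B = R1B),
            class = "single_point_constraints")
}

# Assemble full two-pool parameters for candidate f at observed R1 under the
# constraint set (vectorized).  Shared by the solver and the phantom, so a
# forward simulation and its inversion use one parameter family.
.two_pool_from_observed <- function(r1_obs, f, constraints) {
  R1F <- r1f_from_observed(r1_obs, f, constraints$R, constraints$R1B)
  list(f = f, R1F = R1F, R1B = constraints$R1B,
       T2F = constraints$T2F_R1F / R1F, T2B = constraints$T2B,
       R = constraints$R)
}

#' Synthetic reference signal for MT-image normalization
#'
#' The Ernst-equation signal the MT-weighted sequence would give with the
#' saturation pulse switched off, computed from fitted `R1` and `PD` at the
#' MT sequence's TR and B1-corrected flip angle.  Replaces an acquired
#' no-saturation reference image.
#'
#' @param r1 Observed longitudinal rate (1/s); vectorized.
#' @param pd Proton density (a.u.); vectorized.
#' @param mt_protocol The MT-weighted [spgr_protocol()].
#' @param b1_scale B1 scale factor; vectorized.
#' @return Reference amplitude (a.u.); `NA` where `r1` or `pd` is `NA`.
#' @export
synthetic_reference <- function(r1, pd, mt_protocol, b1_scale = 1) {
  stopifnot(inherits(mt_protocol, "spgr_protocol"))
  spgr_signal(pd, r1, mt_protocol$flip * b1_scale, mt_protocol$TR)
}

# normalized model ratio MT / reference for candidate f (vectorized over
# voxels; f, r1_obs, b0, b1, sl_g of common length).  Unlike the exported
# r1f_from_observed(), degenerate noise voxels are clamped to a tiny
# positive R1F instead of erroring; they end up without a root (NA).
.model_ratio <- function(f, r1_obs, b0, b1, constraints, mt_protocol,
                         w1rms, sl_g) {
  kF <- constraints$R * f
  kB <- constraints$R * (1 - f)
  den <- constraints$R1B + kB - r1_obs
  R1F <- ifelse(den > 0, r1_obs - kF + kF * kB / den, NA_real_)
  R1F <- pmax(R1F, 1e-3)
  R1F[is.na(R1F)] <- 1e-3
  p <- list(f = f, R1F = R1F, R1B = constraints$R1B,
            T2F = constraints$T2F_R1F / R1F, T2B = constraints$T2B,
            R = constraints$R)
  pl <- mt_protocol$mt_pulse
  num <- .mt_ss_core(p$f, p$R1F, p$R1B, p$T2F, p$T2B, p$R, 1,
                     mt_protocol$TR, mt_protocol$flip, pl$duration,
                     pl$offset, w1rms, b0, b1, sl_g = sl_g)
  num / spgr_signal(1, r1_obs, mt_protocol$flip * b1, mt_protocol$TR)
}

#' Single-point MPF inversion of normalized MT signals
#'
#' Solves, per voxel, for the macromolecular proton fraction `f` such that
#' the two-pool pulsed-MT steady-state signal, normalized by the synthetic
#' reference, equals the measured ratio.  All other two-pool parameters are
#' fixed by the constraint set and the observed R1
#' (see [r1f_from_observed()]); the saturation offset is corrected by the
#' local B0 offset and pulse amplitude and flip angle by the local B1 scale.
#' The model ratio is strictly decreasing in `f`, so a bracketed bisection on
#' `f` in `[0, 0.45]` (run to `|df| < 1e-7`) finds the unique root.
#'
#' @param ratio Measured MT/reference signal ratio in (0, 1]; vectorized.
#' @param r1_obs Observed longitudinal rate (1/s); vectorized.
#' @param b0_offset Local B0 offset (Hz); vectorized.
#' @param b1_scale Local B1 scale; vectorized.
#' @param constraints A [single_point_constraints()].
#' @param mt_protocol The MT-weighted [spgr_protocol()] (must carry an
#'   `mt_pulse`).
#' @return Macromolecular proton fraction (dimensionless); `NA` where the
#'   ratio falls outside the model's attainable range or inputs are invalid.
#' @export
solve_mpf_voxel <- function(ratio, r1_obs, b0_offset = 0, b1_scale = 1,
                            constraints = single_point_constraints(),
                            mt_protocol) {
  stopifnot(inherits(constraints, "single_point_constraints"),
            inherits(mt_protocol, "spgr_protocol"))
  pl <- mt_protocol$mt_pulse
  if (is.null(pl)) stop("mt_protocol must include an mt_pulse")
  n <- max(length(ratio), length(r1_obs), length(b0_offset), length(b1_scale))
  ratio <- rep_len(ratio, n); r1_obs <- rep_len(r1_obs, n)
  b0 <- rep_len(b0_offset, n); b1 <- rep_len(b1_scale, n)
  w1rms <- omega1_rms_from_pulse(pl)
  ok <- is.finite(ratio) & is.finite(r1_obs) & is.finite(b0) &
    is.finite(b1) & ratio > 0 & ratio <= 1 & r1_obs > 0 & b1 > 0
  f_out <- rep(NA_real_, n)
  if (!any(ok)) return(f_out)
  rr <- ratio[ok]; r1 <- r1_obs[ok]; b0k <- b0[ok]; b1k <- b1[ok]
  # bound-pool lineshape depends only on the effective offset: one quadrature
  sl_g <- lineshape(pl$offset + b0k, constraints$T2B, "super_lorentzian")
  lo <- rep(0, length(rr)); hi <- rep(0.45, length(rr))
  r_hi <- .model_ratio(lo, r1, b0k, b1k, constraints, mt_protocol, w1rms, sl_g)
  r_lo <- .model_ratio(hi, r1, b0k, b1k, constraints, mt_protocol, w1rms, sl_g)
  inb <- rr <= r_hi & rr >= r_lo
  for (i in seq_len(26)) {      # 0.45 / 2^26 < 1e-7
    mid <- (lo + hi) / 2
    rm <- .model_ratio(mid, r1, b0k, b1k, constraints, mt_protocol, w1rms, sl_g)
    take_upper <- rm > rr       # model decreasing in f: root above mid
    lo <- ifelse(take_upper, mid, lo)
    hi <- ifelse(take_upper, hi, mid)
  }
  f_vals <- (lo + hi) / 2
  f_vals[!inb] <- NA_real_
  f_out[ok] <- f_vals
  f_out
}

#' Reconstruct an MPF map from the three source volumes
#'
#' Full single-point synthetic-reference reconstruction: two-point VFA fit of
#' R1 and PD from the T1- and PD-weighted volumes (with B1 correction),
#' synthetic-reference normalization of the MT-weighted volume, and voxelwise
#' single-point MPF inversion with B0/B1 correction, inside a signal mask.
#'
#' @param mt_w,t1_w,pd_w 3D source volumes on a common grid (a.u.).
#' @param b0_map B0 offset map (Hz) on the same grid, or `NULL` for 0.
#' @param b1_map B1 scale map on the same grid, or `NULL` for 1.
#' @param protocols Named list of [spgr_protocol()]s with elements `mt`,
#'   `t1w`, `pdw` (see [default_protocols()]).
#' @param constraints A [single_point_constraints()].
#' @param mask Optional logical array restricting the fit; by default voxels
#'   with PD-weighted signal below `5 * noise_floor` are excluded.
#' @param noise_floor Background noise level of the PD-weighted volume (a.u.)
#'   used for the default mask.
#' @return An object of class `quant_maps`: list with arrays `mpf` (percent),
#'   `r1` (1/s), `pd` (a.u.), logical `valid`, and the fraction
#'   `invalid_fraction` of in-mask voxels where the inversion failed.
#'   Out-of-mask voxels are `NA`.
#' @export
reconstruct_mpf_map <- function(mt_w, t1_w, pd_w, b0_map = NULL,
                                b1_map = NULL,
                                protocols = default_protocols(),
                                constraints = single_point_constraints(),
                                mask = NULL, noise_floor = 0) {
  dm <- dim(mt_w)
  if (!identical(dm, dim(t1_w)) || !identical(dm, dim(pd_w)))
    stop("source volumes must share one grid")
  if (is.null(b0_map)) b0_map <- array(0, dm)
  if (is.null(b1_map)) b1_map <- array(1, dm)
  if (!identical(dm, dim(b0_map)) || !identical(dm, dim(b1_map)))
    stop("field maps must share the source grid")
  if (is.null(mask)) mask <- pd_w > 5 * noise_floor & pd_w > 0
  stopifnot(identical(dim(mask), dm))
  idx <- which(mask)
  fit <- vfa_r1_pd(t1_w[idx], pd_w[idx], protocols$t1w$flip,
                   protocols$pdw$flip, protocols$t1w$TR, b1_map[idx])
  sref <- synthetic_reference(fit$r1, fit$pd, protocols$mt, b1_map[idx])
  f <- solve_mpf_voxel(mt_w[idx] / sref, fit$r1, b0_map[idx], b1_map[idx],
                       constraints, protocols$mt)
  mpf <- array(NA_real_, dm); r1 <- array(NA_real_, dm)
  pd <- array(NA_real_, dm); valid <- array(FALSE, dm)
  mpf[idx] <- 100 * f
  r1[idx] <- fit$r1
  pd[idx] <- fit$pd
  valid[idx] <- is.finite(f)
  invalid_fraction <- 1 - sum(valid) / length(idx)
  if (invalid_fraction > 0.5)
    warning(sprintf("MPF inversion failed in %.0f%% of in-mask voxels",
                    100 * invalid_fraction))
  structure(list(mpf = mpf, r1 = r1, pd = pd, valid = valid,
                 invalid_fraction = invalid_fraction),
            class = "quant_maps")
}
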