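# Field mapping (AFI B1, dual-TE B0) and two-point variable-flip-angle
# R1/PD estimation.

#' AFI B1 map from a dual-TR signal pair
#'
#' Closed-form inversion of the actual flip-angle imaging (AFI) method:
#' with `n = TR2/TR1` and `r = S2/S1`, the actual excitation angle satisfies
#' `cos(alpha) = (r n - 1)/(n - r)` (short-TR approximation), and the B1
#' scale is `alpha / nominal_flip`.
#'
#' @param s1,s2 Steady-state magnitudes of the TR1 and TR2 interleaves
#'   (a.u.); vectorized.
#' @param tr1,tr2 The two repetition times (s), `tr2 > tr1`.
#' @param nominal_flip Nominal excitation angle (degrees).
#' @return B1 scale factor (actual/nominal); `NA` where the signal ratio
#'   falls outside the invertible domain.
#' @export
afi_b1 <- function(s1, s2, tr1, tr2, nominal_flip) {
  n <- tr2 / tr1
  stopifnot(n > 1, nominal_flip > 0)
  r <- s2 / s1
  ca <- (r * n - 1) / (n - r)
  bad <- !is.finite(ca) | ca < -1 | ca > 1 | r >= n | s1 <= 0
  ca[bad] <- NA_real_
  (acos(ca) * 180 / pi) / nominal_flip
}

#' Forward AFI steady-state signal pair
#'
#' Ideally spoiled steady state of the two-TR AFI sequence for a
#' mono-exponential tissue; the simulation counterpart of [afi_b1()].
#'
#' @param r1 Longitudinal rate (1/s).
#' @param pd Proton density (a.u.).
#' @param flip_actual Actual excitation angle (degrees).
#' @param tr1,tr2 Repetition times (s).
#' @return List with signal vectors `s1` and `s2`.
#' @export
afi_signal <- function(r1, pd, flip_actual, tr1, tr2) {
  a <- flip_actual * pi / 180
  E1 <- exp(-tr1 * r1)
  E2 <- exp(-tr2 * r1)
  den <- 1 - E1 * E2 * cos(a)^2
  list(s1 = pd * sin(a) * (1 - E2 + (1 - E1) * E2 * cos(a)) / den,
       s2 = pd * sin(a) * (1 - E1 + (1 - E2) * E1 * cos(a)) / den)
}

#' B0 offset from a dual-TE phase pair
#'
#' Phase-difference field mapping: the B0 offset in Hz is the principal value
#' of `phase2 - phase1` divided by `2 pi (te2 - te1)`.  Offsets beyond
#' `+/- 1/(2 dTE)` alias into the principal range (no spatial unwrapping).
#'
#' @param phase1,phase2 Phases at the two echoes (radians); vectorized.
#' @param te1,te2 Echo times (s), `te2 > te1`.
#' @return B0 offset (Hz).
#' @export
dual_te_b0 <- function(phase1, phase2, te1, te2) {
  stopifnot(te2 > te1)
  dphi <- wrap_phase(phase2 - phase1)
  dphi / (2 * pi * (te2 - te1))
}

#' Two-point variable-flip-angle R1 and PD estimation
#'
#' Linearized DESPOT1 fit on a T1-weighted / PD-weighted SPGR pair: the line
#' through the points `(S_i/tan a_i, S_i/sin a_i)` has slope `E1 = exp(-TR R1)`
#' and intercept `PD (1 - E1)`, with `a_i` the B1-corrected flip angles.
#' Exact on noiseless Ernst signals.
#'
#' @param s_t1w,s_pdw Signal magnitudes at the larger and smaller flip angle
#'   (a.u.); vectorized.
#' @param flip1,flip2 Nominal flip angles of the two acquisitions (degrees);
#'   must differ after B1 correction.
#' @param tr Common repetition time (s).
#' @param b1_scale B1 scale factor (dimensionless); vectorized.
#' @return List with components `r1` (1/s), `pd` (a.u.) and logical `valid`;
#'   voxels with `E1` outside (0, 1) or non-positive signals are invalid
#'   (`NA` estimates).
#' @export
vfa_r1_pd <- function(s_t1w, s_pdw, flip1, flip2, tr, b1_scale = 1) {
  stopifnot(flip1 != flip2, tr > 0)
  a1 <- flip1 * pi / 180 * b1_scale
  a2 <- flip2 * pi / 180 * b1_scale
  y1 <- s_t1w / sin(a1); x1 <- s_t1w / tan(a1)
  y2 <- s_pdw / sin(a2); x2 <- s_pdw / tan(a2)
  E1 <- (y1 - y2) / (x1 - x2)
  pd <- (y1 - E1 * x1) / (1 - E1)
  valid <- is.finite(E1) & E1 > 0 & E1 < 1 & s_t1w > 0 & s_pdw > 0
  r1 <- ifelse(valid, -log(pmax(E1, .Machine$double.xmin)) / tr, NA_real_)
  pd[!valid] <- NA_real_
  if (!any(valid)) stop("vfa_r1_pd: no valid voxel (degenerate signal pair)")
  list(r1 = r1, pd = pd, valid = valid)
}

#' Fill invalid field-map voxels from nearest valid neighbors
#'
#' Replaces invalid voxels (background or failed inversions) by iterative
#' in-plane nearest-valid-neighbor averaging, so that interpolation of a
#' low-resolution field map onto the imaging grid is not contaminated by
#' out-of-tissue values at the brain edge.
#'
#' @param vol 3D numeric array (a field map).
#' @param valid Logical array of the same dimension marking trusted voxels.
#' @param max_iter Safety bound on dilation sweeps.
#' @return Array with all voxels filled.
#' @export
fill_field_map <- function(vol, valid, max_iter = 200) {
  stopifnot(identical(dim(vol), dim(valid)))
  out <- vol
  out[!valid] <- NA_real_
  for (k in seq_len(dim(vol)[3])) {
    sl <- out[, , k]
    if (!anyNA(sl)) next
    if (all(is.na(sl))) { out[, , k] <- 0; next }
    nr <- nrow(sl); nc <- ncol(sl)
    for (it in seq_len(max_iter)) {
      if (!anyNA(sl)) break
      # mean of available 4-neighbors
      up <- rbind(sl[-1, , drop = FALSE], NA)
      dn <- rbind(NA, sl[-nr, , drop = FALSE])
      lf <- cbind(sl[, -1, drop = FALSE], NA)
      rt <- cbind(NA, sl[, -nc, drop = FALSE])
      stack <- cbind(as.vector(up), as.vector(dn), as.vector(lf),
                     as.vector(rt))
      nb <- rowMeans(stack, na.rm = TRUE)
      fillable <- is.na(sl) & is.finite(nb)
      sl[fillable] <- nb[fillable]
    }
    out[, , k] <- sl
  }
  out
}

#' In-plane bilinear upsampling of a volume
#'
#' Resamples each axial slice of a 3D array to a new in-plane matrix size by
#' bilinear interpolation (voxel-center aligned).  Used to bring
#' low-resolution B0/B1 maps onto the imaging grid.
#'
#' @param vol 3D numeric array.
#' @param dim_xy Target in-plane dimensions, length 2.
#' @return 3D array of dimension `c(dim_xy, dim(vol)[3])`.
#' @export
upsample_xy <- function(vol, dim_xy) {
  vol <- array(as.numeric(vol), dim(vol))
  d <- dim(vol)
  stopifnot(length(d) == 3, length(dim_xy) == 2)
  if (all(d[1:2] == dim_xy)) return(vol)
  # voxel-center mapping from target index to source index
  map_idx <- function(nt, ns) ((seq_len(nt) - 0.5) * ns / nt) + 0.5
  xi <- pmin(pmax(map_idx(dim_xy[1], d[1]), 1), d[1])
  yi <- pmin(pmax(map_idx(dim_xy[2], d[2]), 1), d[2])
  x0 <- pmin(floor(xi), d[1] - 1); fx <- xi - x0
  y0 <- pmin(floor(yi), d[2] - 1); fy <- yi - y0
  out <- array(NA_real_, c(dim_xy, d[3]))
  for (k in seq_len(d[3])) {
    sl <- vol[, , k]
    a <- sl[cbind(rep(x0, length(y0)), rep(y0, each = length(x0)))]
    b <- sl[cbind(rep(x0 + 1, length(y0)), rep(y0, each = length(x0)))]
    cc <- sl[cbind(rep(x0, length(y0)), rep(y0 + 1, each = length(x0)))]
    dd <- sl[cbind(rep(x0 + 1, length(y0)), rep(y0 + 1, each = length(x0)))]
    wx <- rep(fx, length(y0)); wy <- rep(fy, each = length(x0))
    out[, , k] <- matrix((1 - wx) * (1 - wy) * a + wx * (1 - wy) * b +
                         (1 - wx) * wy * cc + wx * wy * dd,
                         dim_xy[1], dim_xy[2])
  }
  out
}
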