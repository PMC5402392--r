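# Two-pool pulsed magnetization-transfer signal model for spoiled gradient
# echo.  All public functions take offsets in Hz and flip angles in degrees;
# internally angles are radians and offsets rad/s.

#' Two-pool tissue parameters
#'
#' Container for the biophysical parameters of the binary spin-bath model of
#' magnetization transfer: a free (water) pool and a bound (macromolecular)
#' pool coupled by cross-relaxation.
#'
#' @param f Macromolecular proton fraction, i.e. the bound-pool fraction of
#'   total equilibrium magnetization (dimensionless, `0 <= f < 0.5`).
#' @param R1F,R1B Longitudinal relaxation rates of the free and bound pools
#'   (1/s).
#' @param T2F,T2B Transverse relaxation times of the free and bound pools (s).
#'   `T2B` is of the order of 1e-5 s for the semi-solid pool.
#' @param R Cross-relaxation rate constant (1/s); the forward exchange rate
#'   is `R * f` and the reverse rate `R * (1 - f)`, so detailed balance holds
#'   by construction.
#' @param PD Proton density (arbitrary units, `>= 0`).
#' @return An object of class `two_pool_params` (a named list).
#' @examples
#' two_pool_params(f = 0.13, R1F = 0.48, R1B = 1, T2F = 0.045, T2B = 1e-5, R = 19)
#' @export
two_pool_params <- function(f, R1F, R1B, T2F, T2B, R, PD = 1) {
  stopifnot(f >= 0, f < 0.5, R1F > 0, R1B > 0, T2F > 0, T2B > 0, R >= 0, PD >= 0)
  structure(list(f = f, R1F = R1F, R1B = R1B, T2F = T2F, T2B = T2B,
                 R = R, PD = PD),
            class = "two_pool_params")
}

#' Off-resonance saturation pulse
#'
#' @param shape `"gaussian"` or `"rectangular"`.
#' @param duration Pulse duration t_m (s).
#' @param effective_flip Effective flip angle (degrees), the time integral of
#'   omega_1 expressed as an angle.
#' @param offset Offset frequency from water resonance (Hz). The pulsed-MT
#'   model is only valid far off-resonance; `|offset|` must be >= 1000 Hz.
#' @return An object of class `mt_pulse`.
#' @examples
#' mt_pulse("gaussian", duration = 0.010, effective_flip = 900, offset = 4500)
#' @export
mt_pulse <- function(shape = c("gaussian", "rectangular"), duration,
                     effective_flip, offset) {
  shape <- match.arg(shape)
  stopifnot(duration > 0, effective_flip >= 0)
  if (abs(offset) < 1000)
    stop("mt_pulse offset must be at least 1000 Hz off resonance")
  structure(list(shape = shape, duration = duration,
                 effective_flip = effective_flip, offset = offset),
            class = "mt_pulse")
}

#' Spoiled gradient-echo protocol
#'
#' @param TR Repetition time (s).
#' @param flip Readout excitation flip angle (degrees), in (0, 90).
#' @param TEs Echo time(s) (s); two entries for the dual-TE B0 sequence.
#' @param mt_pulse Optional [mt_pulse()] applied before each excitation.
#' @param label Sequence name.
#' @return An object of class `spgr_protocol`.
#' @export
spgr_protocol <- function(TR, flip, TEs = numeric(), mt_pulse = NULL,
                          label = "") {
  stopifnot(TR > 0, flip > 0, flip < 90)
  if (!is.null(mt_pulse)) {
    stopifnot(inherits(mt_pulse, "mt_pulse"))
    if (TR <= mt_pulse$duration)
      stop("TR must exceed the saturation pulse duration")
  }
  structure(list(TR = TR, flip = flip, TEs = TEs, mt_pulse = mt_pulse,
                 label = label),
            class = "spgr_protocol")
}

# Gauss-Legendre nodes cached per length
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_cache[[key]]
}

#' Absorption lineshape of a proton pool
#'
#' Value of the normalized absorption lineshape g at offset `delta`.  The
#' super-Lorentzian, the conventional lineshape of the semi-solid
#' macromolecular pool, is the powder average
#' \deqn{g(\Delta) = \sqrt{2/\pi}\int_0^1 \frac{T_2}{|3u^2-1|}
#'   \exp\left[-2\left(\frac{2\pi\Delta T_2}{3u^2-1}\right)^2\right] du,}
#' evaluated by fixed-order Gauss-Legendre quadrature; it is singular on
#' resonance, so offsets below 1 kHz are rejected.  The Lorentzian, used for
#' the liquid free pool, is \eqn{g(\Delta) = (T_2/\pi)/(1+(2\pi\Delta T_2)^2)}.
#'
#' @param delta Offset frequency (Hz); vectorized.
#' @param t2 Transverse relaxation time of the pool (s).
#' @param kind `"super_lorentzian"` or `"lorentzian"`.
#' @param nodes Number of quadrature nodes for the super-Lorentzian.
#' @return Lineshape value(s) in seconds.
#' @examples
#' lineshape(4500, 1e-5, "super_lorentzian")
#' lineshape(0, 0.022, "lorentzian")  # = 0.022 / pi
#' @export
lineshape <- function(delta, t2, kind = c("super_lorentzian", "lorentzian"),
                      nodes = 512) {
  kind <- match.arg(kind)
  stopifnot(t2 > 0)
  if (kind == "lorentzian")
    return((t2 / pi) / (1 + (2 * pi * delta * t2)^2))
  if (any(abs(delta) < 1000))
    stop("super-Lorentzian lineshape requires |delta| >= 1000 Hz")
  gl <- .gl_nodes(nodes)
  den <- 3 * gl$x^2 - 1
  # integrand columns: quadrature nodes; rows: offsets
  ex <- exp(-2 * outer(delta, den, function(d, s) (2 * pi * d * t2 / s)^2))
  drop(sqrt(2 / pi) * (ex %*% (gl$w * t2 / abs(den))))
}

#' RMS amplitude of a saturation pulse
#'
#' Root-mean-square omega_1 over the pulse duration, the power metric entering
#' the pulsed-MT saturation rates.  The peak amplitude is scaled so that the
#' time integral of omega_1 equals the effective flip angle.  Gaussian pulses
#' are truncated at +/-3 sigma (sigma = t_m/6) and sampled on a uniform grid.
#'
#' @param pulse An [mt_pulse()].
#' @param nsamp Number of waveform samples for the Gaussian shape.
#' @return omega_1,rms in rad/s.
#' @examples
#' omega1_rms_from_pulse(mt_pulse("rectangular", 0.01, 900, 4500))  # 5*pi/0.01
#' @export
omega1_rms_from_pulse <- function(pulse, nsamp = 512) {
  stopifnot(inherits(pulse, "mt_pulse"), pulse$duration > 0)
  theta <- pulse$effective_flip * pi / 180
  if (theta == 0) return(0)
  if (pulse$shape == "rectangular")
    return(theta / pulse$duration)
  tm <- pulse$duration
  t <- seq(0, tm, length.out = nsamp)
  w <- exp(-(t - tm / 2)^2 / (2 * (tm / 6)^2))
  w <- w * theta / pracma::trapz(t, w)
  sqrt(pracma::trapz(t, w^2) / tm)
}

#' Saturation rates of the two pools under off-resonance irradiation
#'
#' Mean saturation rates during the pulse: `W_B` uses the super-Lorentzian
#' lineshape of the bound pool, `W_F` (direct saturation of the free pool)
#' the Lorentzian lineshape, both as `pi * omega1rms^2 * g(delta_eff)`.
#'
#' @param omega1_rms RMS pulse amplitude (rad/s).
#' @param delta_eff Effective offset, nominal offset plus local B0 offset (Hz).
#' @param T2F,T2B Transverse relaxation times of free and bound pool (s).
#' @return List with components `W_F` and `W_B` (1/s), vectorized over inputs.
#' @export
saturation_rates <- function(omega1_rms, delta_eff, T2F, T2B) {
  if (all(omega1_rms == 0))
    return(list(W_F = 0 * delta_eff, W_B = 0 * delta_eff))
  list(W_F = pi * omega1_rms^2 * lineshape(delta_eff, T2F, "lorentzian"),
       W_B = pi * omega1_rms^2 * lineshape(delta_eff, T2B, "super_lorentzian"))
}

#' Ernst steady-state SPGR signal
#'
#' @param pd Proton density (a.u.).
#' @param r1 Longitudinal rate (1/s).
#' @param flip Flip angle (degrees), in `[0, 90]`.
#' @param tr Repetition time (s).
#' @return Signal amplitude; all arguments vectorized.
#' @export
spgr_signal <- function(pd, r1, flip, tr) {
  stopifnot(all(tr > 0), all(flip >= 0), all(flip <= 90))
  a <- flip * pi / 180
  E1 <- exp(-tr * r1)
  pd * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Free-pool R1 consistent with an observed longitudinal rate
#'
#' Inverts the bi-exponential relaxation of the coupled two-pool system: the
#' returned `R1F` is the free-pool rate for which the slow (smaller-magnitude)
#' eigenvalue of the relaxation-exchange matrix equals the observed rate
#' `r1_obs`, given the bound-pool rate and exchange constraints.  This is the
#' constraint step of the single-point method: the measured (VFA) R1 is
#' interpreted as the slow eigenvalue.
#'
#' @param r1_obs Observed longitudinal rate (1/s); vectorized.
#' @param f Macromolecular proton fraction; vectorized.
#' @param R Cross-relaxation rate constant (1/s).
#' @param r1b Bound-pool R1 (1/s).
#' @return `R1F` (1/s).
#' @export
r1f_from_observed <- function(r1_obs, f, R, r1b) {
  kF <- R * f
  kB <- R * (1 - f)
  den <- r1b + kB - r1_obs
  if (any(den <= 0))
    stop("r1f_from_observed: r1_obs exceeds r1b + R*(1-f); constraints inconsistent")
  r1_obs - kF + kF * kB / den
}

# ---- vectorized 2x2 linear-algebra kernels --------------------------------
# A 2x2 matrix batch is a list with numeric components a,b,c,d = [[a,b],[c,d]].

.expm2 <- function(M) {
  tr <- M$a + M$d
  de <- M$a * M$d - M$b * M$c
  disc <- sqrt(pmax((M$a - M$d)^2 / 4 + M$b * M$c, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  # spectral form exp(M) = e^{l2} I + (e^{l1}-e^{l2})/(l1-l2) (M - l2 I);
  # confluent limit when eigenvalues coincide
  w <- ifelse(disc > 1e-9, (exp(l1) - exp(l2)) / (l1 - l2 + (disc <= 1e-9)),
              exp(l1))
  list(a = exp(l2) + w * (M$a - l2), b = w * M$b,
       c = w * M$c, d = exp(l2) + w * (M$d - l2))
}

.solve2 <- function(M, x1, x2) {
  de <- M$a * M$d - M$b * M$c
  list(x1 = (M$d * x1 - M$b * x2) / de,
       x2 = (M$a * x2 - M$c * x1) / de)
}

.mul2v <- function(M, x1, x2) {
  list(x1 = M$a * x1 + M$b * x2, x2 = M$c * x1 + M$d * x2)
}

.mul22 <- function(L, R) {
  list(a = L$a * R$a + L$b * R$c, b = L$a * R$b + L$b * R$d,
       c = L$c * R$a + L$d * R$c, d = L$c * R$b + L$d * R$d)
}

# Vectorized steady state of the MT-weighted SPGR cycle.  All arguments are
# numeric vectors of common length (or scalars).  Per TR the magnetization
# (MzF, MzB), normalized to (1-f, f), undergoes: saturation pulse of duration
# tm with rates (W_F, W_B); instantaneous excitation by alpha acting on the
# free pool only; free relaxation-exchange for TR - tm.  Ideal spoiling.
.mt_ss_core <- function(f, R1F, R1B, T2F, T2B, R, pd, tr, flip_deg, tm,
                        delta, w1rms, b0 = 0, b1 = 1, sl_g = NULL,
                        nodes = 512) {
  kF <- R * f
  kB <- R * (1 - f)
  alpha <- flip_deg * pi / 180 * b1
  w1 <- w1rms * b1
  powered <- any(w1 > 0) && tm > 0
  if (powered) {
    deff <- delta + b0
    if (is.null(sl_g)) sl_g <- lineshape(deff, T2B, "super_lorentzian", nodes)
    W_F <- pi * w1^2 * lineshape(deff, T2F, "lorentzian")
    W_B <- pi * w1^2 * sl_g
  } else {
    W_F <- 0; W_B <- 0; tm <- 0
  }
  m0F <- 1 - f
  m0B <- f
  b1v <- R1F * m0F
  b2v <- R1B * m0B
  A0 <- list(a = -(R1F + kF), b = kB + 0 * f, c = kF, d = -(R1B + kB))
  if (powered) {
    As <- list(a = A0$a - W_F, b = A0$b, c = A0$c, d = A0$d - W_B)
    P1 <- .expm2(list(a = As$a * tm, b = As$b * tm, c = As$c * tm, d = As$d * tm))
    u <- .solve2(As, b1v, b2v)
    c1 <- list(x1 = (P1$a - 1) * u$x1 + P1$b * u$x2,
               x2 = P1$c * u$x1 + (P1$d - 1) * u$x2)
  } else {
    P1 <- list(a = 1 + 0 * f, b = 0 * f, c = 0 * f, d = 1 + 0 * f)
    c1 <- list(x1 = 0 * f, x2 = 0 * f)
  }
  tf <- tr - tm
  P2 <- .expm2(list(a = A0$a * tf, b = A0$b * tf, c = A0$c * tf, d = A0$d * tf))
  u0 <- .solve2(A0, b1v, b2v)
  c2 <- list(x1 = (P2$a - 1) * u0$x1 + P2$b * u0$x2,
             x2 = P2$c * u0$x1 + (P2$d - 1) * u0$x2)
  ca <- cos(alpha)
  # cycle propagator Pc = P2 D P1, D = diag(cos alpha, 1)
  P2D <- list(a = P2$a * ca, b = P2$b, c = P2$c * ca, d = P2$d)
  Pc <- .mul22(P2D, P1)
  cc1 <- .mul2v(P2D, c1$x1, c1$x2)
  cc <- list(x1 = cc1$x1 + c2$x1, x2 = cc1$x2 + c2$x2)
  IM <- list(a = 1 - Pc$a, b = -Pc$b, c = -Pc$c, d = 1 - Pc$d)
  Mss <- .solve2(IM, cc$x1, cc$x2)
  Mex <- .mul2v(P1, Mss$x1, Mss$x2)
  pd * sin(alpha) * (Mex$x1 + c1$x1)
}

#' Steady-state signal of the MT-weighted spoiled gradient-echo sequence
#'
#' Closed-form fixed point of the per-TR propagator of the two-pool pulsed-MT
#' matrix model.  Each TR consists of the off-resonance saturation pulse
#' (duration t_m, mean rates W_F/W_B from the pulse RMS amplitude and the
#' pool lineshapes at the effective offset), an instantaneous excitation of
#' the free pool by the B1-scaled readout flip angle, and free
#' relaxation-exchange for the remainder of the TR.  Ideal spoiling is
#' assumed.  With no saturation pulse and `f = 0` the signal reduces to the
#' Ernst equation.
#'
#' @param params A [two_pool_params()].
#' @param protocol An [spgr_protocol()]; its `mt_pulse` may be `NULL` (zero
#'   saturation power).
#' @param b0_offset Local static-field offset added to the pulse offset (Hz).
#' @param b1_scale Local transmit-field scale applied to both the saturation
#'   amplitude and the excitation flip angle (dimensionless, > 0).
#' @return Steady-state signal amplitude (a.u.).
#' @export
mt_spgr_steady_state <- function(params, protocol, b0_offset = 0,
                                 b1_scale = 1) {
  stopifnot(inherits(params, "two_pool_params"),
            inherits(protocol, "spgr_protocol"), all(b1_scale > 0))
  pl <- protocol$mt_pulse
  if (is.null(pl)) {
    w1rms <- 0; tm <- 0; delta <- Inf
  } else {
    w1rms <- omega1_rms_from_pulse(pl); tm <- pl$duration; delta <- pl$offset
  }
  .mt_ss_core(params$f, params$R1F, params$R1B, params$T2F, params$T2B,
              params$R, params$PD, protocol$TR, protocol$flip, tm, delta,
              w1rms, b0_offset, b1_scale)
}
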