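# Independent reference implementations used as oracles: deliberately
# scalar, matrix-based and brute-force, sharing no code with the package
# internals they check.

# dense 2x2 matrix exponential via eigendecomposition
oracle_expm2 <- function(M) {
  e <- eigen(M)
  Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
}

# long-run time stepping of the per-TR MT-SPGR cycle from thermal
# equilibrium (brute-force steady state)
oracle_mt_ss_iter <- function(f, R1F, R1B, T2F, T2B, R, pd, tr, flip_deg,
                              tm, delta, w1rms, b0 = 0, b1 = 1, n = 2000) {
  kF <- R * f; kB <- R * (1 - f)
  w1 <- w1rms * b1
  WF <- if (w1 > 0) pi * w1^2 * (T2F / pi) /
    (1 + (2 * pi * (delta + b0) * T2F)^2) else 0
  WB <- if (w1 > 0) pi * w1^2 * oracle_superlorentzian(delta + b0, T2B) else 0
  alpha <- flip_deg * pi / 180 * b1
  Meq <- c(1 - f, f)
  beq <- c(R1F * Meq[1], R1B * Meq[2])
  As <- matrix(c(-(R1F + kF + WF), kB, kF, -(R1B + kB + WB)), 2, byrow = TRUE)
  A0 <- matrix(c(-(R1F + kF), kB, kF, -(R1B + kB)), 2, byrow = TRUE)
  P1 <- oracle_expm2(As * tm)
  c1 <- (P1 - diag(2)) %*% solve(As, beq)
  P2 <- oracle_expm2(A0 * (tr - tm))
  c2 <- (P2 - diag(2)) %*% solve(A0, beq)
  D <- diag(c(cos(alpha), 1))
  M <- Meq
  for (i in seq_len(n)) M <- as.vector(P2 %*% (D %*% (P1 %*% M + c1)) + c2)
  Mex <- P1 %*% M + c1
  pd * sin(alpha) * Mex[1]
}

# adaptive-quadrature super-Lorentzian (split at the u = 1/sqrt(3) dip)
oracle_superlorentzian <- function(delta, t2) {
  fn <- function(u) t2 / abs(3 * u^2 - 1) *
    exp(-2 * (2 * pi * delta * t2 / (3 * u^2 - 1))^2)
  sqrt(2 / pi) * (stats::integrate(fn, 0, 1 / sqrt(3), rel.tol = 1e-10)$value +
                  stats::integrate(fn, 1 / sqrt(3), 1, rel.tol = 1e-10)$value)
}

oracle_ernst <- function(pd, r1, flip_deg, tr) {
  a <- flip_deg * pi / 180
  E1 <- exp(-tr * r1)
  pd * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

# protocol constants shared by tests
mt_proto <- function() spgr_protocol(0.022, 9, 0.0025,
                                     mt_pulse("gaussian", 0.010, 900, 4500))

small_phantom <- function(...) {
  make_phantom(phantom_spec(dim = c(48, 48, 12), ...))
}
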