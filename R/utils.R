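# small shared helpers

# wrap angles to the principal interval (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rician-distributed magnitude: true signal plus two independent Gaussian
# quadrature channels of standard deviation sigma
rician <- function(signal, sigma) {
  if (sigma <= 0) return(signal)
  sqrt((signal + stats::rnorm(length(signal), 0, sigma))^2 +
       stats::rnorm(length(signal), 0, sigma)^2)
}
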