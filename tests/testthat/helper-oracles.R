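# Independent oracles used across the suite.  None of these share code with
# the series engine: Taylor coefficients come from trigonometric quadrature
# on a circle, convolutions from a brute-force double loop, and the
# Mittag-Leffler function from direct log-Gamma summation.

# Taylor coefficients 0..M of lambda -> f(sum_k a_k lambda^k) at lambda = 0,
# by the Cauchy-integral / trapezoid rule on a circle of radius r (spectrally
# accurate for analytic f; a high-order finite-difference formula in disguise).
oracle_compose_coefs <- function(f, a, M, r = 0.4, N = 128L) {
  j <- 0:(N - 1)
  lam <- r * exp(2i * pi * j / N)
  u <- vapply(lam, function(l) sum(a * l^(seq_along(a) - 1L)), complex(1))
  fu <- f(u)
  vapply(0:M, function(i)
    Re(mean(fu * exp(-2i * pi * i * j / N)) / r^i), numeric(1))
}

# brute-force truncated convolution
oracle_convolve <- function(a, b, M) {
  out <- numeric(M + 1)
  for (i in 0:M)
    for (k in 0:i)
      if (k + 1 <= length(a) && i - k + 1 <= length(b))
        out[i + 1] <- out[i + 1] + a[k + 1] * b[i - k + 1]
  out
}

# one-parameter Mittag-Leffler function E_q(z) for z >= 0 by direct summation
oracle_mittag_leffler <- function(z, q, n_terms = 200L) {
  k <- 0:(n_terms - 1)
  sum(exp(k * log(z) - lgamma(q * k + 1)))
}

# tau_series with given plain coefficients a_i (c_i = a_i * Gamma(i q + 1))
tau_from_plain_coefs <- function(a, q) {
  tau_series(a * gamma((seq_along(a) - 1L) * q + 1), q)
}

plain_coefs <- function(ts) ts$coeffs / gamma((0:ts$M) * ts$order + 1)

# random HNN-scale state
rand_state <- function() stats::runif(5, -2, 2)
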