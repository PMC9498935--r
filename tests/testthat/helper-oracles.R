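# Independent brute-force oracles used by the tests.

# Inverse standard normal by root-finding on pnorm (independent of qnorm).
z_oracle <- function(p) {
  stats::uniroot(function(z) stats::pnorm(z) - p, c(-12, 12),
                 tol = .Machine$double.eps^0.75)$root
}

# d' with the log-linear correction, built only on pnorm + uniroot.
dprime_oracle <- function(n_hits, n_deviants, n_fa, n_opportunities) {
  hr <- (n_hits + 0.5) / (n_deviants + 1)
  far <- (n_fa + 0.5) / (n_opportunities + 1)
  z_oracle(hr) - z_oracle(far)
}

# A flat (difficulty-independent) true-d' map shared by several tests.
flat_dprime <- function(value = 0) {
  stats::setNames(rep(list(rep(value, 20)), 3), FEATURES)
}

# Random rotation matrix in 3-D (det +1 unless reflect).
random_rotation <- function(reflect = FALSE) {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (xor(det(Q) < 0, reflect)) Q[, 1] <- -Q[, 1]
  Q
}
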