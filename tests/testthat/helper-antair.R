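# Shared fixtures: the harvester-ant parameter set and random draws used by
# the property-style tests.

# Calibrated rates with a configurable social-contagion ratio beta0/gamma0.
ant_params <- function(N = 500, ratio = 10) {
  air_params(beta0 = ratio * 1.21, gamma0 = 1.21, delta = 0.63,
             E0 = 0.0944, alpha = 1.47, N = N)
}

# Random valid parameter draws: rates log-uniform on [1e-2, 1e2], alpha
# uniform on [1, 2], N log-uniform on [10, 1000].
random_params <- function(n, seed = 2024) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    air_params(beta0 = 10^stats::runif(1, -2, 2),
               gamma0 = 10^stats::runif(1, -2, 2),
               delta = 10^stats::runif(1, -2, 2),
               E0 = 10^stats::runif(1, -2, 1),
               alpha = stats::runif(1, 1, 2),
               N = round(10^stats::runif(1, 1, 3)))
  })
}

# A random non-negative state summing to N.
random_state <- function(params) {
  w <- stats::runif(3)
  w <- w / sum(w) * params$N
  c(A = w[1], I = w[2], R = w[3])
}

# Central-difference Jacobian of air_rhs, the numerical-differentiation
# oracle used against the closed form.
fd_jacobian <- function(state, params, h = NULL) {
  if (is.null(h)) h <- 1e-6 * params$N
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (air_rhs(up, params) - air_rhs(dn, params)) / (2 * h)
  }
  J
}

# Distance between two complex pairs under the best pairing, immune to the
# unstable ordering of near-conjugate values.
pair_dist <- function(a, b) {
  min(max(Mod(a - b)), max(Mod(a - rev(b))))
}
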