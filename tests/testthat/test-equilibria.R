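test_that("phi root function matches direct evaluation and is monotone", {
  expect_equal(air_phi(0, 0), 0)
  expect_equal(air_phi(0, 3), 1)
  # sqrt((1+10)^2 + 26.92) - 11
  expect_equal(air_phi(10, 26.92), 1.1622366, tolerance = 1e-6)
  # guarded arithmetic stays accurate for tiny y where the naive form cancels
  expect_equal(air_phi(0, 1e-12), 5e-13, tolerance = 1e-6)
  y <- c(0.1, 1, 10, 100)
  expect_true(all(diff(air_phi(2, y)) > 0))
  x <- c(0, 1, 5, 20)
  expect_true(all(diff(air_phi(x, 3)) < 0))
  expect_error(air_phi(-1, 1), "non-negative")
})

test_that("trivial equilibrium is the all-inactive colony", {
  p <- ant_params()
  eq <- trivial_equilibrium(p)
  expect_equal(as.numeric(eq), c(A = 0, I = 500, R = 0))
  expect_equal(unname(air_rhs(as.numeric(eq), p)), c(0, 0, 0))
})

test_that("nontrivial equilibrium solves the steady-state quadratic", {
  for (ps in random_params(100, seed = 5)) {
    eq <- nontrivial_equilibrium(ps)
    k <- mean_degree(ps$E0, ps$alpha, ps$N)
    resid <- ps$gamma0 * k / (ps$delta * ps$N) * eq$A^2 +
      (1 + ps$gamma0 / ps$beta0) * eq$A - ps$N
    expect_lt(abs(resid), 1e-10 * ps$N)
    expect_true(eq$A > 0 && eq$I > 0 && eq$R > 0)
    expect_lt(abs(eq$A + eq$I + eq$R - ps$N), 1e-10 * ps$N)
    # the quadratic's other root is negative: exactly one admissible root
    roots <- Re(polyroot(c(-ps$N, 1 + ps$gamma0 / ps$beta0,
                           ps$gamma0 * k / (ps$delta * ps$N))))
    expect_equal(sum(roots > 0), 1)
    expect_equal(eq$A, max(roots), tolerance = 1e-9)
  }
})

test_that("equilibrium activity matches the harvester-ant benchmark", {
  p <- ant_params(N = 500, ratio = 10)
  eq <- nontrivial_equilibrium(p)
  # independent quadratic-root oracle
  k <- mean_degree(p$E0, p$alpha, p$N)
  oracle <- max(Re(polyroot(c(-p$N, 1 + p$gamma0 / p$beta0,
                              p$gamma0 * k / (p$delta * p$N)))))
  expect_equal(eq$A, oracle, tolerance = 1e-12)
  expect_equal(eq$A / p$N, 0.3123, tolerance = 1e-3)
})

test_that("weak social contagion collapses onto the trivial equilibrium", {
  p <- air_params(1e-8, 1.21, 0.63, 0.0944, 1.47, 500)
  eq <- nontrivial_equilibrium(p)
  expect_lt(eq$A, 1e-4 * p$N)
  expect_gt(eq$I, (1 - 1e-4) * p$N)
})

test_that("equilibrium activity responds monotonically to the rates", {
  base <- ant_params(N = 200)
  A_of <- function(p) nontrivial_equilibrium(p)$A
  I_of <- function(p) nontrivial_equilibrium(p)$I
  deltas <- seq(0.2, 2, length.out = 8)
  As <- vapply(deltas, function(d)
    A_of(air_params(base$beta0, base$gamma0, d, base$E0, base$alpha, base$N)),
    1.0)
  expect_true(all(diff(As) > 0)) # faster rest recovery sustains more activity
  gammas <- seq(0.2, 2, length.out = 8)
  Ag <- vapply(gammas, function(g)
    A_of(air_params(base$beta0, g, base$delta, base$E0, base$alpha, base$N)),
    1.0)
  expect_true(all(diff(Ag) < 0))
  betas <- seq(1, 20, length.out = 8)
  Ib <- vapply(betas, function(b)
    I_of(air_params(b, base$gamma0, base$delta, base$E0, base$alpha, base$N)),
    1.0)
  expect_true(all(diff(Ib) < 0))
})

test_that("asymptotic equilibrium approximates the exact one at large N", {
  p <- ant_params(N = 1e6)
  exact <- nontrivial_equilibrium(p)
  asym <- asymptotic_equilibrium(p)
  expect_equal(asym$A / exact$A, 1, tolerance = 0.05)
  # algebraic ratio of the limiting forms
  expect_equal(asym$I / asym$A, p$gamma0 / p$beta0, tolerance = 1e-12)
  expect_equal(asym$R, p$N)
  # the limiting activity is an exact power law in N
  Ns <- round(10^seq(2, 5, length.out = 6))
  As <- vapply(Ns, function(N) asymptotic_equilibrium(ant_params(N))$A, 1.0)
  fit <- fit_scaling_exponent(Ns, As)
  expect_equal(fit$exponent, scaling_exponent(1.47), tolerance = 1e-8)
  p1 <- air_params(1, 1, 1, 0.1, 1, 100)
  expect_error(asymptotic_equilibrium(p1), "alpha > 1")
})

test_that("validity ratio quantifies when the asymptote applies", {
  p <- ant_params(N = 500)
  expect_equal(asymptotic_validity_ratio(p), 22.245, tolerance = 1e-3)
  ratios <- vapply(c(100, 500, 2000), function(N)
    asymptotic_validity_ratio(ant_params(N)), 1.0)
  expect_true(all(diff(ratios) > 0))
  # weakening social contagion degrades the approximation
  weaker <- vapply(c(10, 1, 0.1), function(r)
    asymptotic_validity_ratio(ant_params(N = 500, ratio = r)), 1.0)
  expect_true(all(diff(weaker) < 0))
})

test_that("closed-form Jacobian matches numerical differentiation", {
  set.seed(7)
  for (ps in random_params(50, seed = 7)) {
    st <- random_state(ps)
    st <- pmax(st, 0.05 * ps$N)
    st <- st / sum(st) * ps$N
    J <- air_jacobian(st, ps)
    Jfd <- fd_jacobian(st, ps)
    scale <- max(1, max(abs(J)))
    expect_lt(max(abs(J - Jfd)) / scale, 1e-6)
  }
})

test_that("trivial equilibrium spectrum is {0, -delta, beta0 <k>}", {
  for (ps in random_params(20, seed = 13)) {
    J <- air_jacobian(c(A = 0, I = ps$N, R = 0), ps)
    ev <- sort(Re(eigen(J, only.values = TRUE)$values))
    k <- mean_degree(ps$E0, ps$alpha, ps$N)
    expected <- sort(c(0, -ps$delta, ps$beta0 * k))
    expect_equal(ev, expected, tolerance = 1e-12)
    expect_equal(stability_report(ps, "trivial")$verdict, "unstable")
  }
})

test_that("nontrivial equilibrium is marginally stable", {
  for (ps in random_params(30, seed = 17)) {
    rep <- stability_report(ps, "nontrivial")
    ev <- rep$eigenvalues
    zero_tol <- 1e-9 * max(ps$delta, ps$gamma0, ps$beta0)
    expect_equal(sum(abs(ev) < zero_tol), 1) # structural zero of conservation
    nz <- ev[abs(ev) >= zero_tol]
    expect_true(all(Re(nz) < 0))
    expect_equal(rep$verdict, "marginally_stable")
  }
})

test_that("Routh-Hurwitz coefficients are positive and factor the spectrum", {
  for (ps in random_params(200, seed = 23)) {
    rh <- routh_hurwitz(ps)
    expect_identical(rh[["a0"]], 1)
    expect_gt(rh[["a1"]], 0)
    expect_gt(rh[["a2"]], 0)
    roots <- polyroot(c(rh[["a2"]], rh[["a1"]], rh[["a0"]]))
    nz <- stability_report(ps)$nonzero_eigenvalues
    expect_lt(pair_dist(roots, nz) / max(Mod(nz)), 1e-8)
  }
})

test_that("Lyapunov energy certifies global stability", {
  p <- ant_params(N = 300)
  eq <- nontrivial_equilibrium(p)
  expect_equal(lyapunov_value(eq$A, eq$R, p), 0)
  expect_equal(lyapunov_rate(eq$A, eq$R, p), 0)
  # positive definite away from the equilibrium, non-positive decay rate
  As <- seq(1, p$N, length.out = 40)
  Rs <- seq(0, p$N, length.out = 40)
  grid <- expand.grid(A = As, R = Rs)
  V <- lyapunov_value(grid$A, grid$R, p)
  dV <- lyapunov_rate(grid$A, grid$R, p)
  off <- abs(grid$A - eq$A) > 1e-6 | abs(grid$R - eq$R) > 1e-6
  expect_true(all(V[off] > 0))
  expect_true(all(dV <= 1e-12))
  expect_error(lyapunov_value(0, 10, p), "positive")
})

test_that("analytic decay rate matches the chain rule along the flow", {
  p <- ant_params(N = 500)
  traj <- simulate_air(p, t_end = 5, n_points = 40)
  h <- 1e-6
  for (i in c(3, 10, 25)) {
    A <- traj$A[i]; R <- traj$R[i]
    d <- air_rhs(unlist(traj[i, c("A", "I", "R")]), p)
    # gradient of V dotted with the vector field, by central differences
    dVdA <- (lyapunov_value(A + h, R, p) - lyapunov_value(A - h, R, p)) / (2 * h)
    dVdR <- (lyapunov_value(A, R + h, p) - lyapunov_value(A, R - h, p)) / (2 * h)
    chain <- dVdA * d[["A"]] + dVdR * d[["R"]]
    expect_equal(lyapunov_rate(A, R, p), chain, tolerance = 1e-6)
  }
  # V is non-increasing along integrated trajectories
  V <- lyapunov_value(traj$A, traj$R, p)
  expect_true(all(diff(V) <= 1e-9))
})

test_that("log-log fitting recovers exact power laws", {
  Ns <- c(10, 30, 100, 300, 1000)
  fit <- fit_scaling_exponent(Ns, 7.3 * Ns^0.75)
  expect_equal(fit$exponent, 0.75, tolerance = 1e-10)
  expect_equal(fit$prefactor, 7.3, tolerance = 1e-8)
  # isometric networks (alpha = 1) give exactly proportional activity
  As <- vapply(Ns, function(N)
    nontrivial_equilibrium(air_params(5, 1, 0.5, 0.2, 1, N))$A, 1.0)
  expect_equal(fit_scaling_exponent(Ns, As)$exponent, 1, tolerance = 0.001)
  expect_error(fit_scaling_exponent(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fit_scaling_exponent(Ns, c(-1, 1, 1, 1, 1)), "positive")
})
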