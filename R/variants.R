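#' Ablation variant: no refractory state
#'
#' Two-compartment control model in which active ants inactivate directly
#' (still by contact with active ants) instead of passing through a refractory
#' state:
#' \deqn{\dot A = c(\beta_0 A I - \gamma_0 A^2), \qquad \dot I = -\dot A,}
#' with \eqn{c = \langle k\rangle/N}. Its positive equilibrium
#' \eqn{(A^\star, I^\star) = (\beta_0, \gamma_0) N / (\beta_0+\gamma_0)} is a
#' fixed fraction of the colony, so activity scales isometrically with size
#' regardless of `alpha`: the refractory reservoir is necessary for hypometric
#' scaling.
#'
#' @param beta0,gamma0,E0,alpha,N as in [air_params()].
#' @return An object of class `no_refractory_params`.
#' @export
no_refractory_params <- function(beta0, gamma0, E0, alpha, N) {
  p <- air_params(beta0, gamma0, delta = 1, E0 = E0, alpha = alpha, N = N)
  p$delta <- NULL
  class(p) <- "no_refractory_params"
  p
}

#' @describeIn no_refractory_params rates of change `(dA, dI)`; the two
#'   components sum to zero.
#' @param A,I non-negative counts with `A + I = N`.
#' @param params a `no_refractory_params` object.
#' @export
no_refractory_rhs <- function(A, I, params) {
  if (A < 0 || I < 0) stop("counts must be non-negative", call. = FALSE)
  c0 <- kbar(params) / params$N
  dA <- c0 * (params$beta0 * A * I - params$gamma0 * A^2)
  c(A = dA, I = -dA)
}

#' @describeIn no_refractory_params the positive equilibrium
#'   `(A*, I*) = N (beta0, gamma0) / (beta0 + gamma0)`.
#' @export
no_refractory_equilibrium <- function(params) {
  s <- params$beta0 + params$gamma0
  c(A = params$beta0 / s * params$N, I = params$gamma0 / s * params$N)
}

#' Ablation variant: no reverse social contagion
#'
#' Control model in which the socially driven inactivation is replaced by a
#' spontaneous active-to-refractory transition at constant rate `mu`:
#' \deqn{\dot A = c\beta_0 A I - \mu A,\quad
#'       \dot I = \delta R - c\beta_0 A I,\quad
#'       \dot R = -\delta R + \mu A.}
#' A positive equilibrium exists only when \eqn{\mu < \beta_0\langle k\rangle}:
#' \eqn{A^\star = N\frac{\delta}{\delta+\mu}
#'      \frac{\beta_0\langle k\rangle-\mu}{\beta_0\langle k\rangle}},
#' \eqn{I^\star = \mu N/(\beta_0\langle k\rangle)},
#' \eqn{R^\star = (\mu/\delta) A^\star}. Since the correction factor
#' \eqn{1 - \mu/(\beta_0\langle k\rangle)} tends to 1 as the colony grows,
#' activity again scales isometrically: hypometric scaling requires the
#' inactivation itself to be socially driven. The default
#' `mu = 0.1` 1/s keeps spontaneous inactivation an order of magnitude below
#' the social rates, so the equilibrium stays well inside feasibility over
#' colony sizes 10-1000.
#'
#' @param beta0,delta,E0,alpha,N as in [air_params()].
#' @param mu spontaneous active-to-refractory rate (1/s, > 0).
#' @return An object of class `no_reverse_params`.
#' @export
no_reverse_params <- function(beta0, delta, mu = 0.1, E0, alpha, N) {
  check_positive_scalar(mu, "mu")
  p <- air_params(beta0, gamma0 = 1, delta = delta, E0 = E0,
                  alpha = alpha, N = N)
  p$gamma0 <- NULL
  p$mu <- mu
  class(p) <- "no_reverse_params"
  p
}

#' @describeIn no_reverse_params rates of change `(dA, dI, dR)`; conservative.
#' @param state named numeric `c(A, I, R)`.
#' @param params a `no_reverse_params` object.
#' @export
no_reverse_rhs <- function(state, params) {
  state <- check_state(state)
  c0 <- kbar(params) / params$N
  A <- state[["A"]]; I <- state[["I"]]; R <- state[["R"]]
  dA <- c0 * params$beta0 * A * I - params$mu * A
  dR <- -params$delta * R + params$mu * A
  c(A = dA, I = -dA - dR, R = dR)
}

#' @describeIn no_reverse_params the positive equilibrium, or an infeasibility
#'   marker. Returns a list with `feasible`; when `mu >= beta0 * <k>` only the
#'   trivial equilibrium exists and `feasible` is `FALSE` (a value, not an
#'   error, so parameter sweeps can traverse the boundary).
#' @export
no_reverse_equilibrium <- function(params) {
  bk <- params$beta0 * kbar(params)
  if (params$mu >= bk) {
    return(list(feasible = FALSE, A = 0, I = params$N, R = 0,
                reason = sprintf("mu = %g >= beta0*<k> = %g: only the trivial equilibrium exists",
                                 params$mu, bk)))
  }
  A <- params$N * params$delta / (params$delta + params$mu) * (bk - params$mu) / bk
  I <- params$mu / bk * params$N
  R <- params$mu / params$delta * A
  list(feasible = TRUE, A = A, I = I, R = R)
}

#' Integrate an ablation variant
#'
#' Runs either control model through the same adaptive integrator as
#' [simulate_air()] and returns the same trajectory container; the
#' no-refractory variant carries a zero-filled `R` column so downstream
#' plotting and IO are uniform.
#'
#' @param params a `no_refractory_params` or `no_reverse_params` object.
#' @param init initial state: `c(A, I)` for the no-refractory variant,
#'   `c(A, I, R)` for the no-reverse variant; defaults to the single-inactive
#'   start used for the full model.
#' @param t_end,n_points,rel_tol,abs_tol as in [simulate_air()].
#' @return An `air_trajectory` data frame with columns `t, A, I, R`.
#' @export
simulate_variant <- function(params, init = NULL, t_end, n_points = 400,
                             rel_tol = 1e-9, abs_tol = 1e-12) {
  times <- seq(0, t_end, length.out = n_points)
  if (inherits(params, "no_refractory_params")) {
    if (is.null(init)) init <- c(A = params$N - 1, I = 1)
    rhs <- function(t, y, p) list(no_refractory_rhs(y[["A"]], y[["I"]], p))
    sol <- deSolve::ode(init, times, rhs, params, method = "lsoda",
                        rtol = rel_tol, atol = abs_tol)
    traj <- as.data.frame(sol)
    names(traj)[1] <- "t"
    traj$R <- 0
  } else if (inherits(params, "no_reverse_params")) {
    if (is.null(init)) init <- c(A = params$N - 1, I = 1, R = 0)
    rhs <- function(t, y, p) list(no_reverse_rhs(y, p))
    sol <- deSolve::ode(init, times, rhs, params, method = "lsoda",
                        rtol = rel_tol, atol = abs_tol)
    traj <- as.data.frame(sol)
    names(traj)[1] <- "t"
  } else {
    stop("`params` must be a variant parameter object", call. = FALSE)
  }
  structure(traj, params = params, class = c("air_trajectory", "data.frame"))
}
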