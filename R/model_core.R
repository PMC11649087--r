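#' Right-hand side of the A/I/R compartmental model
#'
#' Instantaneous rates of change of the active, inactive, and refractory
#' counts. With \eqn{c = \langle k\rangle / N},
#' \deqn{\dot A = c(\beta_0 A I - \gamma_0 A^2),\quad
#'       \dot I = \delta R - c\beta_0 A I,\quad
#'       \dot R = -\delta R + c\gamma_0 A^2,}
#' so the three components sum to zero and the colony size is conserved.
#'
#' @param state named numeric vector `c(A =, I =, R =)` of non-negative counts.
#' @param params an [air_params()] object.
#' @return Named numeric vector of derivatives `(A, I, R)` in 1/s.
#' @examples
#' p <- air_params(12.1, 1.21, 0.63, 0.0944, 1.47, 500)
#' air_rhs(c(A = 499, I = 1, R = 0), p)
#' @export
air_rhs <- function(state, params) {
  state <- check_state(state)
  c0 <- kbar(params) / params$N
  A <- state[["A"]]; I <- state[["I"]]; R <- state[["R"]]
  dA <- c0 * (params$beta0 * A * I - params$gamma0 * A^2)
  dR <- -params$delta * R + c0 * params$gamma0 * A^2
  dI <- -dA - dR
  c(A = dA, I = dI, R = dR)
}

#' Integrate the A/I/R model
#'
#' Adaptive integration of the compartmental dynamics with [deSolve::ode()]
#' (lsoda). The default initial condition is the fully-aroused colony with a
#' single inactive individual, `c(A = N - 1, I = 1, R = 0)`.
#'
#' @param params an [air_params()] object.
#' @param init initial state `c(A, I, R)`, non-negative, summing to `N`.
#' @param t_end final time (s, > 0).
#' @param n_points number of output points (the grid includes `t = 0`).
#' @param rel_tol,abs_tol integrator tolerances.
#' @param grid `"linear"` or `"log"` output time spacing; the log grid spans
#'   `[t_end / 10^4, t_end]` after the initial point, convenient when the
#'   transient covers several decades.
#' @return An `air_trajectory`: a data frame with columns `t`, `A`, `I`, `R`
#'   and the parameters attached as attribute `"params"`.
#' @examples
#' p <- air_params(12.1, 1.21, 0.63, 0.0944, 1.47, 500)
#' traj <- simulate_air(p, t_end = 50)
#' tail(traj, 1)
#' @export
simulate_air <- function(params, init = NULL, t_end, n_points = 400,
                         rel_tol = 1e-9, abs_tol = 1e-12,
                         grid = c("linear", "log")) {
  grid <- match.arg(grid)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    stop("`t_end` must be a positive time in seconds", call. = FALSE)
  }
  if (is.null(init)) init <- c(A = params$N - 1, I = 1, R = 0)
  init <- check_state(init)
  if (abs(sum(init) - params$N) > 1e-8 * params$N) {
    stop("initial state must sum to the colony size N", call. = FALSE)
  }
  if (init[["A"]] == 0) {
    warning("A0 = 0: activity cannot start; only the refractory pool drains",
            call. = FALSE)
  }
  times <- switch(grid,
    linear = seq(0, t_end, length.out = n_points),
    log = c(0, exp(seq(log(t_end / 1e4), log(t_end), length.out = n_points - 1)))
  )
  rhs <- function(t, y, parms) list(air_rhs(y, parms))
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = params,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol)
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    stop(sprintf("integration failed (lsoda istate = %d) at rel_tol = %g, abs_tol = %g",
                 istate, rel_tol, abs_tol), call. = FALSE)
  }
  traj <- as.data.frame(sol)
  names(traj)[1] <- "t"
  structure(traj, params = params, class = c("air_trajectory", "data.frame"))
}

#' Maximum conservation error of a trajectory
#'
#' The model conserves the colony size exactly; an integrated trajectory should
#' satisfy `A + I + R = N` to within the integrator tolerance. Returns
#' `max |A + I + R - N|` over the time grid.
#'
#' @param traj an `air_trajectory` from [simulate_air()].
#' @return Non-negative scalar (counts).
#' @export
conservation_residual <- function(traj) {
  if (!inherits(traj, "air_trajectory") || nrow(traj) == 0L) {
    stop("`traj` must be a non-empty air_trajectory", call. = FALSE)
  }
  params <- attr(traj, "params")
  max(abs(traj$A + traj$I + traj$R - params$N))
}

#' Write / read a trajectory as CSV with a JSON parameter sidecar
#'
#' The CSV has header `t,A,I,R` (seconds and counts); the parameters used are
#' stored next to it in `<path>.json` so a trajectory file is self-describing.
#'
#' @param traj an `air_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the reconstructed `air_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "A", "I", "R")], path,
                   row.names = FALSE)
  p <- attr(traj, "params")
  jsonlite::write_json(unclass(p), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  p <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- air_params(p$beta0, p$gamma0, p$delta, p$E0, p$alpha, p$N)
  structure(df, params = params, class = c("air_trajectory", "data.frame"))
}
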