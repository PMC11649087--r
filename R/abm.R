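# Agent state codes used throughout the Monte Carlo engine.
STATE_A <- 1L
STATE_I <- 2L
STATE_R <- 3L

#' Configuration for the agent-based Monte Carlo model
#'
#' Discrete-time stochastic counterpart of the compartmental model: `N` agents
#' carry states A/I/R and interact over an Erdos-Renyi contact network that is
#' redrawn independently at every step (a memoryless switching network,
#' the full-mixing limit). Per-step transition probabilities are the linear
#' forms `beta0*dt`, `gamma0*dt`, `delta*dt`, validated to lie in `[0, 1]`.
#'
#' @param params an [air_params()] object.
#' @param dt time step (s); the default matches 15 frames-per-second video.
#' @param n_steps number of steps per realization.
#' @param combine how multiple active neighbours combine into one transition
#'   probability: `"binomial"` (default) treats each active neighbour as an
#'   independent Bernoulli contact, `1 - (1 - r dt)^m`, which matches the
#'   mean-field bilinear/quadratic terms to first order in `dt`; `"linear"`
#'   uses `min(m r dt, 1)` for sensitivity analysis.
#' @return An `abm_config` list.
#' @export
abm_config <- function(params, dt = 0.0667, n_steps = 150,
                       combine = c("binomial", "linear")) {
  combine <- match.arg(combine)
  check_positive_scalar(dt, "dt")
  probs <- c(beta = params$beta0 * dt, gamma = params$gamma0 * dt,
             delta = params$delta * dt)
  if (any(probs > 1)) {
    stop(sprintf("per-step probabilities must be <= 1; got beta0*dt = %.3g, gamma0*dt = %.3g, delta*dt = %.3g",
                 probs[1], probs[2], probs[3]), call. = FALSE)
  }
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  structure(list(params = params, dt = dt, n_steps = as.integer(n_steps),
                 probs = probs, combine = combine),
            class = "abm_config")
}

#' Draw one switching Erdos-Renyi contact network
#'
#' Each of the `N(N-1)/2` pairs is linked independently with probability
#' `p = k_mean / N` (clipped at 1 with a warning), so the expected mean degree
#' is `k_mean * (N - 1) / N`.
#'
#' @param N number of agents (>= 2).
#' @param k_mean target average degree (>= 0).
#' @return Integer matrix with two columns (`u`, `v`), 1-based agent ids,
#'   one row per undirected edge.
#' @export
draw_network <- function(N, k_mean) {
  if (N < 2) stop("`N` must be >= 2", call. = FALSE)
  if (k_mean < 0) stop("`k_mean` must be >= 0", call. = FALSE)
  p <- k_mean / N
  if (p > 1) {
    warning(sprintf("link probability k_mean/N = %.3g clipped at 1", p),
            call. = FALSE)
    p <- 1
  }
  if (p == 0) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("u", "v"))))
  g <- igraph::sample_gnp(N, p)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  colnames(el) <- c("u", "v")
  el
}

# per-agent count of active neighbours given an edge list
active_neighbour_counts <- function(states, edges) {
  N <- length(states)
  if (nrow(edges) == 0L) return(integer(N))
  act <- states == STATE_A
  u <- edges[, 1]; v <- edges[, 2]
  tabulate(c(u[act[v]], v[act[u]]), nbins = N)
}

#' One synchronous update of the agent-based model
#'
#' All transitions are evaluated from the time-`t` snapshot: an inactive agent
#' with `m` active neighbours activates with probability
#' `1 - (1 - beta0 dt)^m`; an active agent with `m` active neighbours becomes
#' refractory with probability `1 - (1 - gamma0 dt)^m` (only the focal agent
#' transitions -- both endpoints of an active-active edge roll independently);
#' a refractory agent becomes inactive with probability `delta dt`. Agent
#' count is conserved exactly.
#'
#' @param states integer vector of agent states (1 = A, 2 = I, 3 = R).
#' @param edges edge matrix from [draw_network()].
#' @param probs named numeric `c(beta, gamma, delta)` of per-step
#'   probabilities, each in `[0, 1]`.
#' @param combine `"binomial"` or `"linear"`, see [abm_config()].
#' @return Updated integer state vector.
#' @export
abm_step <- function(states, edges, probs, combine = "binomial") {
  if (any(probs < 0) || any(probs > 1)) {
    stop("per-step probabilities must lie in [0, 1]", call. = FALSE)
  }
  m <- active_neighbour_counts(states, edges)
  p_act <- switch(combine,
    binomial = 1 - (1 - probs[["beta"]])^m,
    linear = pmin(m * probs[["beta"]], 1),
    stop("unknown `combine` dialect", call. = FALSE))
  p_ref <- switch(combine,
    binomial = 1 - (1 - probs[["gamma"]])^m,
    linear = pmin(m * probs[["gamma"]], 1))
  r <- stats::runif(length(states))
  out <- states
  out[states == STATE_I & r < p_act] <- STATE_A
  out[states == STATE_A & r < p_ref] <- STATE_R
  out[states == STATE_R & r < probs[["delta"]]] <- STATE_I
  out
}

#' Run one realization of the agent-based model
#'
#' Starts (by default) from the all-active colony with a single inactive
#' agent, mirroring the compartmental simulations, and redraws the contact
#' network at every step.
#'
#' @param config an [abm_config()].
#' @param seed optional integer seed for reproducibility.
#' @param init optional integer state vector of length `N` (1 = A, 2 = I,
#'   3 = R).
#' @return Data frame with columns `step`, `t`, `A`, `I`, `R`
#'   (`n_steps + 1` rows of integer counts, each summing to `N`).
#' @export
abm_run <- function(config, seed = NULL, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- config$params$N
  k <- kbar(config$params)
  if (is.null(init)) {
    init <- rep(STATE_A, N)
    init[1] <- STATE_I
  }
  if (length(init) != N) stop("`init` must have length N", call. = FALSE)
  states <- init
  counts <- matrix(0L, nrow = config$n_steps + 1L, ncol = 3)
  counts[1, ] <- tabulate(states, nbins = 3)
  for (s in seq_len(config$n_steps)) {
    edges <- draw_network(N, k)
    states <- abm_step(states, edges, config$probs, config$combine)
    counts[s + 1L, ] <- tabulate(states, nbins = 3)
  }
  data.frame(step = 0:config$n_steps,
             t = (0:config$n_steps) * config$dt,
             A = counts[, 1], I = counts[, 2], R = counts[, 3])
}

#' Ensemble of agent-based realizations
#'
#' Runs independent seeded realizations and summarizes the per-step mean and
#' standard deviation of each compartment count.
#'
#' @param config an [abm_config()].
#' @param n_realizations number of independent realizations (>= 1).
#' @param seed root seed; per-realization seeds are spawned from it, so the
#'   whole ensemble is reproducible bit-for-bit.
#' @param init optional common initial state vector.
#' @return An `abm_ensemble` list with `times`, `mean` and `sd` (matrices with
#'   columns `A`, `I`, `R`), `n_realizations`, and `config`.
#' @export
abm_ensemble <- function(config, n_realizations = 10, seed = 1, init = NULL) {
  if (n_realizations < 1) stop("`n_realizations` must be >= 1", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_realizations)
  runs <- lapply(seeds, function(s) {
    r <- abm_run(config, seed = s, init = init)
    as.matrix(r[, c("A", "I", "R")])
  })
  arr <- simplify2array(runs) # steps x 3 x realizations
  mn <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  if (n_realizations == 1) sdv[] <- 0
  colnames(mn) <- colnames(sdv) <- c("A", "I", "R")
  structure(list(times = (0:config$n_steps) * config$dt, mean = mn, sd = sdv,
                 n_realizations = n_realizations, config = config),
            class = "abm_ensemble")
}

#' @export
print.abm_ensemble <- function(x, ...) {
  cat(sprintf("ABM ensemble: N = %d, %d realizations, %d steps of %.4g s\n",
              as.integer(x$config$params$N), x$n_realizations,
              x$config$n_steps, x$config$dt))
  invisible(x)
}

#' Maximum normalized deviation between an ensemble mean and the ODE
#'
#' Samples the compartmental trajectory on the ensemble's step grid and
#' returns `max |mean - ode| / N` over steps and compartments, a scale-free
#' summary of mean-field agreement.
#'
#' @param ensemble an [abm_ensemble()] summary.
#' @param traj an `air_trajectory` whose time grid contains the ensemble's
#'   times (same `N`).
#' @return Non-negative scalar.
#' @export
compare_to_ode <- function(ensemble, traj) {
  idx <- vapply(ensemble$times, function(tt) which.min(abs(traj$t - tt)), 1L)
  if (max(abs(traj$t[idx] - ensemble$times)) > 1e-6 * ensemble$config$dt) {
    stop("trajectory grid does not contain the ensemble time points; integrate with times = k*dt",
         call. = FALSE)
  }
  N <- ensemble$config$params$N
  ode <- as.matrix(traj[idx, c("A", "I", "R")])
  max(abs(ensemble$mean - ode)) / N
}

#' Write ensemble summary as CSV
#' @param ensemble an [abm_ensemble()].
#' @param path CSV path; columns `t, mean_A, sd_A, mean_I, sd_I, mean_R, sd_R`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  df <- data.frame(t = ensemble$times,
                   mean_A = ensemble$mean[, "A"], sd_A = ensemble$sd[, "A"],
                   mean_I = ensemble$mean[, "I"], sd_I = ensemble$sd[, "I"],
                   mean_R = ensemble$mean[, "R"], sd_R = ensemble$sd[, "R"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
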