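#' Specification of a synthetic calibration dataset
#'
#' Describes a multi-colony dataset with the statistical structure the
#' calibration pipeline assumes: a set of colony sizes, 30 s of video at
#' 15 frames per second in a square nest arena, a one-body-length contact
#' radius, and a one-pixel movement threshold separating active from
#' non-active individuals. Defaults mirror the harvester-ant recordings the
#' model was calibrated on: 16 colonies spanning 40-360 workers, 450 frames
#' at `dt = 0.0667` s, a 248 mm arena, and a 6 mm contact radius. The planted
#' dynamics use the calibrated rates with strong social contagion
#' (`beta0 = 10 * gamma0`), the regime in which steady-state activity is
#' best identified. Pixel size is set to 0.5 mm (a ~500-pixel video across
#' the arena); active ants step at least one pixel per frame while inactive
#' and refractory ants jitter with sub-pixel Gaussian noise, so the
#' displacement threshold cleanly separates the planted states.
#'
#' @param gamma0,delta,E0,alpha planted model rates and network scaling.
#' @param beta0_ratio planted `beta0 / gamma0`.
#' @param sizes colony sizes.
#' @param n_frames frames per colony.
#' @param dt frame interval (s).
#' @param arena_mm arena side (mm).
#' @param radius_mm contact radius (mm).
#' @param pixel_mm pixel size (mm).
#' @param step_mm range of per-frame step lengths for active ants (mm); the
#'   lower end must be at least one pixel.
#' @param jitter_mm per-axis Gaussian jitter s.d. for non-active ants (mm);
#'   must be well below one pixel.
#' @param burn_in Monte Carlo steps discarded before recording, so recorded
#'   frames sample the quasi-stationary state as a real video would.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(gamma0 = 1.21, delta = 0.63, E0 = 0.0944,
                         alpha = 1.47, beta0_ratio = 10,
                         sizes = round(seq(40, 360, length.out = 16)),
                         n_frames = 450, dt = 0.0667,
                         arena_mm = 248, radius_mm = 6, pixel_mm = 0.5,
                         step_mm = c(1.05, 3) * pixel_mm,
                         jitter_mm = pixel_mm / 6, burn_in = 150) {
  if (jitter_mm >= pixel_mm) {
    stop("`jitter_mm` must be below the pixel size", call. = FALSE)
  }
  if (step_mm[1] < pixel_mm) {
    stop("active steps must be at least one pixel", call. = FALSE)
  }
  structure(list(gamma0 = gamma0, delta = delta, E0 = E0, alpha = alpha,
                 beta0 = beta0_ratio * gamma0, sizes = sizes,
                 n_frames = as.integer(n_frames), dt = dt,
                 arena_mm = arena_mm, radius_mm = radius_mm,
                 pixel_mm = pixel_mm, step_mm = step_mm,
                 jitter_mm = jitter_mm, burn_in = as.integer(burn_in)),
            class = "fixture_spec")
}

planted_params <- function(spec, N) {
  air_params(spec$beta0, spec$gamma0, spec$delta, spec$E0, spec$alpha, N)
}

# integer initial state near the deterministic equilibrium
equilibrium_init <- function(params) {
  eq <- nontrivial_equilibrium(params)
  nA <- max(1L, round(eq$A))
  nI <- max(1L, round(eq$I))
  nR <- params$N - nA - nI
  if (nR < 0) { nI <- nI + nR; nR <- 0L }
  rep(c(STATE_A, STATE_I, STATE_R), times = c(nA, nI, nR))
}

#' Generate a network fixture: switching contact networks + planted states
#'
#' For each colony size, runs the agent-based model on freshly drawn
#' Erdos-Renyi networks with mean degree `2 E0 N^(alpha-1)`, starting near
#' the deterministic equilibrium and discarding a burn-in, and records the
#' per-frame edge lists together with activity labels equal to the planted
#' active states. This is the fixture on which the network-scaling and
#' rate-recovery stages of [calibrate()] are validated: the contact structure
#' follows the posited degree scaling by construction.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer seed; the same seed reproduces the fixture exactly.
#' @return A list with `colonies` (a list of [frame_networks()]) and
#'   `planted` (the planted parameter values).
#' @export
generate_network_fixture <- function(spec, seed = 1) {
  set.seed(seed)
  colonies <- lapply(spec$sizes, function(N) {
    params <- planted_params(spec, N)
    cfg <- abm_config(params, dt = spec$dt, n_steps = 1L)
    k <- kbar(params)
    states <- equilibrium_init(params)
    for (b in seq_len(spec$burn_in)) {
      states <- abm_step(states, draw_network(N, k), cfg$probs)
    }
    edges <- vector("list", spec$n_frames)
    active <- matrix(FALSE, spec$n_frames, N)
    for (f in seq_len(spec$n_frames)) {
      el <- draw_network(N, k)
      edges[[f]] <- el
      active[f, ] <- states == STATE_A
      states <- abm_step(states, el, cfg$probs)
    }
    frame_networks(N = N, edges = edges, active = active, dt = spec$dt)
  })
  list(colonies = colonies,
       planted = list(beta0 = spec$beta0, gamma0 = spec$gamma0,
                      delta = spec$delta, E0 = spec$E0, alpha = spec$alpha))
}

#' Generate a track fixture: positions whose movement encodes the states
#'
#' Places ants uniformly in the arena and evolves their states with the
#' agent-based transition rules on the spatial proximity graph (contacts =
#' pairs within the contact radius). Active ants take a uniformly oriented
#' step of at least one pixel; inactive and refractory ants receive sub-pixel
#' Gaussian jitter; positions reflect at the arena walls. Displacement-based
#' activity scoring therefore recovers the planted states (up to the rare
#' jitter excursion or wall-shortened step), which is what this fixture is
#' for. Its contact structure arises from geometry, not from the
#' degree-scaling law, so network-scaling recovery is tested on
#' [generate_network_fixture()] instead.
#'
#' @param spec a [fixture_spec()]; for spatial dynamics, colony sizes well
#'   below the arena capacity keep contact counts moderate.
#' @param seed integer seed.
#' @return A list with `tracks` (data frame `colony, frame, ant, x, y`),
#'   `planted_active` (per-colony logical matrices aligned with
#'   [score_activity()]: row `f` flags movement between frames `f - 1` and
#'   `f`, row 1 is `NA`), and `planted` parameters.
#' @export
generate_track_fixture <- function(spec, seed = 1) {
  set.seed(seed)
  out_tracks <- list()
  planted_active <- list()
  for (ci in seq_along(spec$sizes)) {
    N <- spec$sizes[ci]
    params <- planted_params(spec, N)
    cfg <- abm_config(params, dt = spec$dt, n_steps = 1L)
    pos <- matrix(stats::runif(2 * N, 0, spec$arena_mm), ncol = 2)
    states <- equilibrium_init(params)[sample.int(N)]
    X <- matrix(NA_real_, spec$n_frames, N)
    Y <- matrix(NA_real_, spec$n_frames, N)
    act <- matrix(NA, spec$n_frames, N)
    X[1, ] <- pos[, 1]; Y[1, ] <- pos[, 2]
    for (f in seq_len(spec$n_frames - 1L)) {
      d <- as.matrix(stats::dist(pos))
      hit <- which(d <= spec$radius_mm & upper.tri(d), arr.ind = TRUE)
      el <- cbind(hit[, 1], hit[, 2])
      storage.mode(el) <- "integer"
      moving <- states == STATE_A
      states <- abm_step(states, el, cfg$probs)
      # ants move according to their state during the (f, f+1) interval
      step_len <- ifelse(moving,
                         stats::runif(N, spec$step_mm[1], spec$step_mm[2]),
                         abs(stats::rnorm(N, 0, spec$jitter_mm)))
      theta <- stats::runif(N, 0, 2 * pi)
      pos <- pos + step_len * cbind(cos(theta), sin(theta))
      pos <- reflect_into(pos, spec$arena_mm)
      X[f + 1L, ] <- pos[, 1]; Y[f + 1L, ] <- pos[, 2]
      act[f + 1L, ] <- moving
    }
    out_tracks[[ci]] <- data.frame(
      colony = ci,
      frame = rep(seq_len(spec$n_frames), times = N),
      ant = rep(seq_len(N), each = spec$n_frames),
      x = as.vector(X), y = as.vector(Y))
    planted_active[[ci]] <- act
  }
  list(tracks = do.call(rbind, out_tracks),
       planted_active = planted_active,
       planted = list(beta0 = spec$beta0, gamma0 = spec$gamma0,
                      delta = spec$delta, E0 = spec$E0, alpha = spec$alpha))
}

reflect_into <- function(pos, side) {
  # reflective walls; a fold handles the (rare) step longer than the arena
  p <- pos %% (2 * side)
  ifelse(p > side, 2 * side - p, p)
}

#' Worked-example event counts
#'
#' The pooled counts from the manually tracked harvester-ant videos behind
#' the calibrated rates: 9861 frames with an interacting active-active pair,
#' 800 of them followed by an inactivation at the next tracked frame, at a
#' frame interval of 0.0667 s. Feeding these to [estimate_gamma0()]
#' reproduces the calibrated reverse social contagion rate.
#'
#' @return A list with `n_interaction_frames`, `n_inactivation_events`, `dt`.
#' @examples
#' with(printed_counts_fixture(),
#'      estimate_gamma0(n_interaction_frames, n_inactivation_events, dt))
#' @export
printed_counts_fixture <- function() {
  list(n_interaction_frames = 9861L, n_inactivation_events = 800L,
       dt = 0.0667)
}
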