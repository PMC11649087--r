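#' Per-colony container of per-frame contact networks and activity flags
#'
#' The calibration pipeline consumes, for each colony, the sequence of
#' per-frame proximity networks together with a per-frame activity flag for
#' every individual (active = moved at least one pixel since the previous
#' frame; inactive and refractory individuals are indistinguishable in data
#' and both score as not active).
#'
#' @param N number of tracked individuals.
#' @param edges list of integer edge matrices (two columns, 1-based ids),
#'   one per frame; no self-edges.
#' @param active logical matrix, frames x N; `NA` where undefined (first
#'   frame of a displacement-scored track).
#' @param dt frame interval (s).
#' @return A `frame_networks` object.
#' @export
frame_networks <- function(N, edges, active, dt = 0.0667) {
  if (nrow(active) != length(edges)) {
    stop("`active` must have one row per frame in `edges`", call. = FALSE)
  }
  if (ncol(active) != N) stop("`active` must have N columns", call. = FALSE)
  for (e in edges) {
    if (nrow(e) && any(e[, 1] == e[, 2])) {
      stop("self-edges are not allowed", call. = FALSE)
    }
  }
  structure(list(N = N, edges = edges, active = active, dt = dt),
            class = "frame_networks")
}

#' Build per-frame proximity networks from tracked positions
#'
#' Two individuals are connected in a frame when their Euclidean distance is
#' at most `radius` (inclusive: a pair at exactly the threshold counts as a
#' contact). The default 6 mm corresponds to one ant body length. Rows with
#' missing coordinates are skipped (counted in the `dropped` attribute).
#'
#' @param tracks data frame with columns `frame`, `ant`, `x`, `y`
#'   (millimetres) for a single colony.
#' @param radius contact radius (mm).
#' @return A list of integer edge matrices, one per frame (named by frame),
#'   with ant ids mapped to `1..N` in sorted order; the mapping is attached as
#'   attribute `"ants"`.
#' @export
build_proximity_networks <- function(tracks, radius = 6) {
  stopifnot(all(c("frame", "ant", "x", "y") %in% names(tracks)))
  ok <- stats::complete.cases(tracks[, c("frame", "ant", "x", "y")])
  dropped <- sum(!ok)
  tracks <- tracks[ok, ]
  ants <- sort(unique(tracks$ant))
  frames <- sort(unique(tracks$frame))
  nets <- lapply(frames, function(f) {
    sub <- tracks[tracks$frame == f, ]
    id <- match(sub$ant, ants)
    d <- as.matrix(stats::dist(cbind(sub$x, sub$y)))
    hit <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
    el <- cbind(u = id[hit[, 1]], v = id[hit[, 2]])
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    storage.mode(el) <- "integer"
    el
  })
  names(nets) <- frames
  attr(nets, "ants") <- ants
  attr(nets, "dropped") <- dropped
  nets
}

#' Score per-frame activity from displacements
#'
#' An individual is flagged (instantaneously) active at frame `f` when it
#' moved at least one pixel between frames `f - 1` and `f`. Flags at the first
#' frame are `NA` (no previous frame) and are excluded from all counts.
#'
#' @param tracks data frame with columns `frame`, `ant`, `x`, `y` for one
#'   colony; each individual needs at least two frames.
#' @param pixel_size pixel size in mm; a displacement of exactly one pixel
#'   scores as active.
#' @return Logical matrix frames x ants (dimnames from the data), `NA` in the
#'   first row.
#' @export
score_activity <- function(tracks, pixel_size = 0.5) {
  stopifnot(all(c("frame", "ant", "x", "y") %in% names(tracks)))
  ants <- sort(unique(tracks$ant))
  frames <- sort(unique(tracks$frame))
  if (length(frames) < 2) {
    stop("need at least 2 frames per individual to score displacement",
         call. = FALSE)
  }
  X <- matrix(NA_real_, length(frames), length(ants))
  Y <- X
  fi <- match(tracks$frame, frames)
  ai <- match(tracks$ant, ants)
  X[cbind(fi, ai)] <- tracks$x
  Y[cbind(fi, ai)] <- tracks$y
  disp <- sqrt(diff(X)^2 + diff(Y)^2)
  act <- rbind(NA, disp >= pixel_size)
  dimnames(act) <- list(frames, ants)
  act
}

#' Fit the network-size scaling of contact counts
#'
#' The model posits `E = E0 * N^alpha` for the average number of simultaneous
#' contacts (edges) in a colony of size `N`; this fits `log E` against
#' `log N` by ordinary least squares across colonies. Colonies with zero mean
#' edge count are excluded with a warning.
#'
#' @param N vector of colony sizes (>= 3 after exclusions).
#' @param E vector of per-colony mean edge counts.
#' @return A list with `E0`, `alpha`, `r_squared`, and `n_colonies`; `alpha`
#'   outside `[1, 2]` is flagged via the `in_range` field.
#' @export
fit_network_scaling <- function(N, E) {
  keep <- E > 0
  if (any(!keep)) {
    warning(sprintf("%d zero-edge colonies excluded from the scaling fit",
                    sum(!keep)), call. = FALSE)
  }
  N <- N[keep]; E <- E[keep]
  if (length(unique(N)) < 3) {
    stop("need at least 3 colonies with positive edge counts", call. = FALSE)
  }
  fit <- fit_scaling_exponent(N, E)
  list(E0 = fit$prefactor, alpha = fit$exponent,
       r_squared = fit$r_squared, n_colonies = length(N),
       in_range = fit$exponent >= 1 && fit$exponent <= 2)
}

#' Fit the reverse-contagion slope q
#'
#' The per-colony extent of reverse social contagion, `y = 2 A^2 E / N^2`
#' (with `A` the steady-state active count and `E` the mean edge count),
#' is proportional to `(delta/gamma0) * N` in the large-colony limit, where
#' the refractory pool absorbs almost the whole colony. The fitted slope `q`
#' of `y` against `N` therefore estimates `delta / gamma0`. The default fit is
#' least squares through the origin (the model predicts exact
#' proportionality); `method = "ols"` adds an intercept for sensitivity
#' analysis. At moderate colony sizes the estimate is biased low by the
#' factor `R*/N < 1`; see the methods vignette.
#'
#' @param N colony sizes (>= 3 colonies).
#' @param E per-colony mean edge counts.
#' @param A per-colony mean active counts.
#' @param method `"origin"` (through-origin, default) or `"ols"`.
#' @return A list with `q`, `method`, `y` (the fitted responses), and
#'   `degenerate` (`TRUE` when all `A` are zero).
#' @export
reverse_contagion_slope <- function(N, E, A, method = c("origin", "ols")) {
  method <- match.arg(method)
  if (length(N) < 3) stop("need at least 3 colonies", call. = FALSE)
  y <- 2 * A^2 * E / N^2
  if (all(y == 0)) {
    return(list(q = 0, method = method, y = y, degenerate = TRUE))
  }
  q <- if (method == "origin") {
    sum(N * y) / sum(N^2)
  } else {
    unname(stats::coef(stats::lm(y ~ N))[2])
  }
  list(q = q, method = method, y = y, degenerate = FALSE)
}

#' Estimate the reverse social contagion rate from event counts
#'
#' Divides the number of inactivation events (an active-active contact
#' followed by a loss of activity at the next tracked frame) by the number of
#' active-active contact observations to obtain the per-frame probability of
#' reverse social contagion, then divides by the frame interval to convert it
#' to a rate.
#'
#' @param n_interaction_frames count of active-active contact observations
#'   (> 0).
#' @param n_inactivation_events count of those followed by an inactivation
#'   (<= `n_interaction_frames`).
#' @param dt frame interval (s).
#' @return A list with `probability` and `gamma0` (1/s).
#' @examples
#' estimate_gamma0(9861, 800, 0.0667)
#' @export
estimate_gamma0 <- function(n_interaction_frames, n_inactivation_events,
                            dt = 0.0667) {
  if (n_interaction_frames < 0 || n_inactivation_events < 0 ||
      n_inactivation_events > n_interaction_frames) {
    stop("need 0 <= events <= interaction frames", call. = FALSE)
  }
  check_positive_scalar(dt, "dt")
  if (n_interaction_frames == 0) {
    stop("no active-active interactions observed: gamma0 is undefined",
         call. = FALSE)
  }
  p <- n_inactivation_events / n_interaction_frames
  list(probability = p, gamma0 = p / dt)
}

#' Estimate the refractory-to-inactive rate
#'
#' Combines the reverse-contagion slope `q` (an estimate of `delta / gamma0`)
#' with the event-count estimate of `gamma0`: `delta = q * gamma0`.
#'
#' @param q fitted slope (> 0).
#' @param gamma0 reverse social contagion rate (1/s, > 0).
#' @return `delta` in 1/s.
#' @examples
#' estimate_delta(0.519, 1.21)
#' @export
estimate_delta <- function(q, gamma0) {
  check_positive_scalar(q, "q")
  check_positive_scalar(gamma0, "gamma0")
  q * gamma0
}

#' Count reverse social contagion events in one colony
#'
#' With `unit = "edge"` (the convention of the source data), each
#' (edge, frame) with both endpoints active counts one interaction
#' observation, and it counts as an event when at least one endpoint is no
#' longer active at the next frame. With `unit = "ant"`, each (focal active
#' ant, active neighbour, frame) incidence counts one observation and a focal
#' ant that loses activity at the next frame counts one event; this focal-ant
#' convention is the estimator consistent with a per-individual transition
#' probability per active contact (an active-active edge gives either
#' endpoint a chance to transition, so edge-level counting roughly doubles
#' the apparent probability).
#'
#' @param colony a [frame_networks()] object.
#' @param unit `"edge"` or `"ant"`.
#' @return Named integer vector `c(interactions, events)`.
#' @export
count_reverse_events <- function(colony, unit = c("edge", "ant")) {
  unit <- match.arg(unit)
  n_frames <- length(colony$edges)
  interactions <- 0L
  events <- 0L
  for (f in seq_len(n_frames - 1L)) {
    act_now <- colony$active[f, ]
    act_next <- colony$active[f + 1L, ]
    if (any(is.na(act_now)) || any(is.na(act_next))) next
    el <- colony$edges[[f]]
    if (nrow(el) == 0L) next
    aa <- act_now[el[, 1]] & act_now[el[, 2]]
    if (!any(aa)) next
    el <- el[aa, , drop = FALSE]
    if (unit == "edge") {
      interactions <- interactions + nrow(el)
      events <- events + sum(!act_next[el[, 1]] | !act_next[el[, 2]])
    } else {
      # focal-ant incidences: each active-active edge contributes both ends
      m <- tabulate(c(el[, 1], el[, 2]), nbins = colony$N)
      interactions <- interactions + sum(m)
      events <- events + sum(!act_next[m > 0 & act_now])
    }
  }
  c(interactions = interactions, events = events)
}

#' End-to-end calibration of model parameters
#'
#' Runs the full estimation chain on a multi-colony dataset of per-frame
#' contact networks with activity flags: (i) per-colony mean edge and active
#' counts; (ii) log-log fit of edges versus size for `E0` and `alpha`;
#' (iii) through-origin fit of `2 A^2 E / N^2` versus `N` for
#' `q = delta/gamma0`; (iv) pooled event counts for `gamma0`; and (v)
#' `delta = q * gamma0`. The activation rate `beta0` is not estimated: the
#' probability of an activation-like event observable in data is independent
#' of `beta0` because inactive and refractory individuals cannot be told
#' apart, so the result deliberately carries no `beta0` field.
#'
#' @param colonies list of [frame_networks()] objects (>= 3 colonies).
#' @param dt frame interval (s) used for the rate conversion; defaults to the
#'   colonies' own `dt` when they agree.
#' @param q_fit `"origin"` or `"ols"`, see [reverse_contagion_slope()].
#' @param event_unit `"edge"` or `"ant"`, see [count_reverse_events()].
#' @return An `air_calibration` list with `E0`, `alpha`, `q`, `gamma0`,
#'   `delta`, `probability`, the pooled event counts, a per-colony summary
#'   data frame, and fit diagnostics.
#' @export
calibrate <- function(colonies, dt = NULL, q_fit = c("origin", "ols"),
                      event_unit = c("edge", "ant")) {
  q_fit <- match.arg(q_fit)
  event_unit <- match.arg(event_unit)
  if (length(colonies) < 3) {
    stop("calibration needs at least 3 colonies to fit the network scaling",
         call. = FALSE)
  }
  if (is.null(dt)) {
    dts <- unique(vapply(colonies, function(cl) cl$dt, 1.0))
    if (length(dts) != 1) stop("colonies disagree on dt; pass `dt` explicitly",
                               call. = FALSE)
    dt <- dts
  }
  per <- lapply(colonies, function(cl) {
    rows <- which(rowSums(is.na(cl$active)) == 0)
    A_bar <- if (length(rows)) mean(rowSums(cl$active[rows, , drop = FALSE]))
             else 0
    data.frame(N = cl$N,
               E = mean(vapply(cl$edges, nrow, 1L)),
               A = A_bar)
  })
  per <- do.call(rbind, per)
  net <- fit_network_scaling(per$N, per$E)
  qres <- reverse_contagion_slope(per$N, per$E, per$A, method = q_fit)
  counts <- rowSums(vapply(colonies,
                           function(cl) count_reverse_events(cl, event_unit),
                           c(interactions = 0L, events = 0L)) * 1)
  degenerate_gamma <- counts[["interactions"]] == 0
  gam <- if (degenerate_gamma) {
    list(probability = NA_real_, gamma0 = NA_real_)
  } else {
    estimate_gamma0(counts[["interactions"]], counts[["events"]], dt)
  }
  delta <- if (qres$degenerate || degenerate_gamma || qres$q <= 0 ||
               is.na(gam$gamma0) || gam$gamma0 <= 0) {
    NA_real_
  } else {
    estimate_delta(qres$q, gam$gamma0)
  }
  structure(list(
    E0 = net$E0, alpha = net$alpha, q = qres$q,
    gamma0 = gam$gamma0, delta = delta,
    probability = gam$probability,
    n_interaction_frames = counts[["interactions"]],
    n_inactivation_events = counts[["events"]],
    per_colony = per, dt = dt,
    q_fit = q_fit, event_unit = event_unit,
    degenerate = qres$degenerate || degenerate_gamma,
    network_fit = net
  ), class = "air_calibration")
}

#' @export
print.air_calibration <- function(x, ...) {
  cat("Calibrated activity-regulation parameters\n")
  cat(sprintf("  E0 = %.4g, alpha = %.3f (R^2 = %.3f, %d colonies)\n",
              x$E0, x$alpha, x$network_fit$r_squared,
              x$network_fit$n_colonies))
  cat(sprintf("  q = delta/gamma0 = %.4g (%s fit)\n", x$q, x$q_fit))
  cat(sprintf("  gamma0 = %.4g 1/s (probability %.4g from %d/%d %s-unit events)\n",
              x$gamma0, x$probability, x$n_inactivation_events,
              x$n_interaction_frames, x$event_unit))
  cat(sprintf("  delta = %.4g 1/s\n", x$delta))
  if (x$degenerate) cat("  [degenerate: no usable activity or interactions]\n")
  invisible(x)
}

#' Assemble calibration input from tracked positions
#'
#' Convenience wrapper chaining [build_proximity_networks()] and
#' [score_activity()] for a multi-colony track table.
#'
#' @param tracks data frame with columns `colony`, `frame`, `ant`, `x`, `y`.
#' @param radius contact radius (mm).
#' @param pixel_size pixel size (mm) for the displacement threshold.
#' @param dt frame interval (s).
#' @return A list of [frame_networks()] objects, one per colony.
#' @export
tracks_to_networks <- function(tracks, radius = 6, pixel_size = 0.5,
                               dt = 0.0667) {
  stopifnot("colony" %in% names(tracks))
  lapply(split(tracks, tracks$colony), function(sub) {
    nets <- build_proximity_networks(sub, radius = radius)
    act <- score_activity(sub, pixel_size = pixel_size)
    frame_networks(N = length(attr(nets, "ants")), edges = nets,
                   active = act, dt = dt)
  })
}
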