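test_that("proximity networks use an inclusive one-body-length threshold", {
  tr <- data.frame(frame = 1, ant = 1:2, x = c(0, 5.9), y = 0)
  expect_equal(nrow(build_proximity_networks(tr)[[1]]), 1)
  tr$x <- c(0, 6.1)
  expect_equal(nrow(build_proximity_networks(tr)[[1]]), 0)
  tr$x <- c(0, 6)
  expect_equal(nrow(build_proximity_networks(tr)[[1]]), 1)
  # three collinear ants 4 mm apart form a path: ends are 8 mm apart
  tr3 <- data.frame(frame = 1, ant = 1:3, x = c(0, 4, 8), y = 2)
  el <- build_proximity_networks(tr3)[[1]]
  expect_equal(nrow(el), 2)
  expect_false(any(el[, 1] == 1 & el[, 2] == 3))
})

test_that("a planted geometric contact graph is recovered exactly", {
  set.seed(21)
  n <- 25
  pts <- data.frame(frame = 1, ant = seq_len(n),
                    x = runif(n, 0, 60), y = runif(n, 0, 60))
  el <- build_proximity_networks(pts, radius = 10)[[1]]
  # brute-force oracle over all pairs
  want <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
    if (d <= 10) want <- rbind(want, c(i, j))
  }
  got <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
  # rows with missing coordinates are skipped, not fatal
  pts$x[3] <- NA
  expect_silent(build_proximity_networks(pts, radius = 10))
})

test_that("activity scoring applies the one-pixel displacement rule", {
  tr <- data.frame(frame = rep(1:4, 2), ant = rep(1:2, each = 4),
                   x = c(0, 0, 0, 0,      0, 0.5, 0.5, 0.74),
                   y = c(5, 5, 5, 5,      5, 5,   5,   5))
  act <- score_activity(tr, pixel_size = 0.5)
  expect_true(all(is.na(act[1, ])))
  expect_equal(unname(act[-1, "1"]), c(FALSE, FALSE, FALSE)) # stationary
  # exactly one pixel counts; below threshold does not
  expect_equal(unname(act[-1, "2"]), c(TRUE, FALSE, FALSE))
  expect_error(score_activity(tr[tr$frame == 1, ]), "2 frames")
})

test_that("network-size scaling fit inverts a planted power law", {
  Ns <- round(seq(40, 360, length.out = 16))
  fit <- fit_network_scaling(Ns, 0.0944 * Ns^1.47)
  expect_equal(fit$E0, 0.0944, tolerance = 1e-8)
  expect_equal(fit$alpha, 1.47, tolerance = 1e-8)
  expect_true(fit$in_range)
  # a size-independent edge count is flagged out of the model's range
  flat <- fit_network_scaling(Ns, rep(12, 16))
  expect_equal(flat$alpha, 0, tolerance = 1e-8)
  expect_false(flat$in_range)
  expect_warning(fit_network_scaling(c(Ns, 400), c(0.0944 * Ns^1.47, 0)),
                 "zero-edge")
  expect_error(fit_network_scaling(c(10, 20), c(1, 2)), "3 colonies")
})

test_that("reverse-contagion slope fits proportionality through the origin", {
  Ns <- c(40, 120, 200, 280, 360)
  E <- 0.0944 * Ns^1.47
  # construct active counts so that 2 A^2 E / N^2 = 0.519 N exactly
  A <- sqrt(0.519 * Ns^3 / (2 * E))
  res <- reverse_contagion_slope(Ns, E, A)
  expect_equal(res$q, 0.519, tolerance = 1e-10)
  expect_false(res$degenerate)
  # with an intercept allowed the slope is unchanged on exact data
  expect_equal(reverse_contagion_slope(Ns, E, A, method = "ols")$q, 0.519,
               tolerance = 1e-8)
  dead <- reverse_contagion_slope(Ns, E, rep(0, 5))
  expect_true(dead$degenerate)
  expect_equal(dead$q, 0)
  expect_error(reverse_contagion_slope(1:2, 1:2, 1:2), "3 colonies")
})

test_that("event counts give the reverse social contagion rate", {
  est <- estimate_gamma0(9861, 800, 0.0667)
  expect_equal(round(est$probability, 4), 0.0811)
  expect_equal(est$gamma0, 1.2163, tolerance = 1e-4)
  zero <- estimate_gamma0(1000, 0, 0.0667)
  expect_equal(zero$probability, 0)
  expect_equal(zero$gamma0, 0)
  expect_error(estimate_gamma0(0, 0, 0.0667), "undefined")
  expect_error(estimate_gamma0(10, 11, 0.0667), "events")
})

test_that("delta combines the slope with the contagion rate", {
  expect_equal(estimate_delta(0.519, 1.2163), 0.6313, tolerance = 1e-4)
  expect_equal(estimate_delta(1, 0.77), 0.77)
  expect_error(estimate_delta(0, 1), "q")
  expect_error(estimate_delta(0.5, -1), "gamma0")
})

test_that("event counting matches a hand-built two-frame colony", {
  # frame 1: ants 1-2-3 active in a path 1-2, 2-3; ant 4 inactive
  # frame 2: ant 2 loses activity
  edges <- list(matrix(c(1L, 2L, 2L, 3L), ncol = 2, byrow = TRUE),
                matrix(integer(0), ncol = 2))
  active <- rbind(c(TRUE, TRUE, TRUE, FALSE),
                  c(TRUE, FALSE, TRUE, FALSE))
  colony <- frame_networks(N = 4, edges = edges, active = active, dt = 0.1)
  # edge unit: both edges are active-active; both touch ant 2's flip
  expect_equal(count_reverse_events(colony, "edge"),
               c(interactions = 2L, events = 2L))
  # ant unit: incidences 1,2,2,3 -> 4; only focal ant 2 flips
  expect_equal(count_reverse_events(colony, "ant"),
               c(interactions = 4L, events = 1L))
  expect_error(frame_networks(4, list(matrix(c(1L, 1L), ncol = 2)),
                              active[1, , drop = FALSE]), "self-edges")
})

test_that("calibration needs enough colonies and flags degenerate data", {
  edges <- replicate(3, matrix(c(1L, 2L), ncol = 2), simplify = FALSE)
  quiet <- frame_networks(N = 3, edges = edges,
                          active = matrix(FALSE, 3, 3), dt = 0.1)
  expect_error(calibrate(list(quiet)), "3 colonies")
  dataset <- list(quiet,
                  frame_networks(4, replicate(3, matrix(c(1L, 3L), ncol = 2),
                                              simplify = FALSE),
                                 matrix(FALSE, 3, 4), dt = 0.1),
                  frame_networks(5, replicate(3, matrix(c(2L, 5L), ncol = 2),
                                              simplify = FALSE),
                                 matrix(FALSE, 3, 5), dt = 0.1))
  cal <- calibrate(dataset)
  expect_true(cal$degenerate)
  expect_equal(cal$q, 0)
  expect_true(is.na(cal$delta))
})

test_that("estimates are invariant to a common spatial rescaling", {
  spec <- fixture_spec(sizes = c(40, 60, 80), n_frames = 60, burn_in = 40)
  fx <- generate_track_fixture(spec, seed = 31)
  scale <- 2.2
  scaled <- fx$tracks
  scaled$x <- scaled$x * scale
  scaled$y <- scaled$y * scale
  base <- calibrate(tracks_to_networks(fx$tracks, radius = 6,
                                       pixel_size = 0.5, dt = spec$dt))
  resc <- calibrate(tracks_to_networks(scaled, radius = 6 * scale,
                                       pixel_size = 0.5 * scale, dt = spec$dt))
  expect_equal(resc$E0, base$E0, tolerance = 1e-10)
  expect_equal(resc$alpha, base$alpha, tolerance = 1e-10)
  expect_equal(resc$gamma0, base$gamma0, tolerance = 1e-10)
  expect_equal(resc$q, base$q, tolerance = 1e-10)
})

test_that("no activation rate is reported: it is not identifiable from video", {
  spec <- fixture_spec(sizes = c(20, 30, 40), n_frames = 40, burn_in = 30)
  fx <- generate_network_fixture(spec, seed = 33)
  cal <- calibrate(fx$colonies)
  expect_false("beta0" %in% names(cal))
})
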