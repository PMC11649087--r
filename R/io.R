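#' Write / read a per-colony frame-network dataset
#'
#' On-disk layout per colony directory: one whitespace-separated edge-list
#' file per frame (`frame_0000.txt`, 0-based node ids, one `u v` pair per
#' line), an `activity.csv` table (`frame,ant,active`), and a `meta.yaml`
#' with `N` and `dt`. The writers and readers round-trip losslessly.
#'
#' @param colony a [frame_networks()] object.
#' @param dir output directory (created if needed).
#' @return `write_frame_networks()` returns `dir` invisibly;
#'   `read_frame_networks()` returns the reconstructed [frame_networks()].
#' @export
write_frame_networks <- function(colony, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(colony$edges)) {
    el <- colony$edges[[f]]
    path <- file.path(dir, sprintf("frame_%04d.txt", f - 1L))
    if (nrow(el)) {
      utils::write.table(el - 1L, path, row.names = FALSE,
                         col.names = FALSE)
    } else {
      file.create(path)
    }
  }
  n_frames <- length(colony$edges)
  act <- data.frame(frame = rep(seq_len(n_frames) - 1L, each = colony$N),
                    ant = rep(seq_len(colony$N) - 1L, times = n_frames),
                    active = as.vector(t(colony$active)))
  utils::write.csv(act, file.path(dir, "activity.csv"), row.names = FALSE)
  yaml::write_yaml(list(N = colony$N, dt = colony$dt, n_frames = n_frames),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_frame_networks
#' @export
read_frame_networks <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  files <- sprintf("frame_%04d.txt", seq_len(meta$n_frames) - 1L)
  edges <- lapply(files, function(f) {
    path <- file.path(dir, f)
    if (file.size(path) == 0) {
      return(matrix(integer(0), ncol = 2))
    }
    el <- as.matrix(utils::read.table(path))
    el <- unname(el) + 1L
    storage.mode(el) <- "integer"
    el
  })
  act <- utils::read.csv(file.path(dir, "activity.csv"))
  active <- matrix(NA, meta$n_frames, meta$N)
  active[cbind(act$frame + 1L, act$ant + 1L)] <- as.logical(act$active)
  frame_networks(N = meta$N, edges = edges, active = active, dt = meta$dt)
}

#' Write / read a multi-colony track table
#'
#' CSV with header `colony,frame,ant,x_mm,y_mm`; in memory the columns are
#' `colony, frame, ant, x, y` (millimetres).
#'
#' @param tracks track data frame.
#' @param path CSV path.
#' @return `write_track_table()` returns `path` invisibly;
#'   `read_track_table()` returns the data frame.
#' @export
write_track_table <- function(tracks, path) {
  out <- data.frame(colony = tracks$colony, frame = tracks$frame,
                    ant = tracks$ant, x_mm = tracks$x, y_mm = tracks$y)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @export
read_track_table <- function(path) {
  df <- utils::read.csv(path)
  data.frame(colony = df$colony, frame = df$frame, ant = df$ant,
             x = df$x_mm, y = df$y_mm)
}

#' Read a model-parameter configuration file
#'
#' YAML (or JSON) file with keys `beta0, gamma0, delta, E0, alpha, N` and
#' optionally `t_end, n_points, rel_tol, abs_tol`.
#'
#' @param path config file path.
#' @return A list with `params` (an [air_params()]) and `control` (the
#'   remaining settings).
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("beta0", "gamma0", "delta", "E0", "alpha", "N")
  if (!all(need %in% names(cfg))) {
    stop("config must define ", paste(need, collapse = ", "), call. = FALSE)
  }
  params <- air_params(cfg$beta0, cfg$gamma0, cfg$delta, cfg$E0, cfg$alpha,
                       cfg$N)
  list(params = params, control = cfg[setdiff(names(cfg), need)])
}
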