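# Trajectory containers and the preprocessing chain:
# read -> rescale -> trim -> resample -> velocity (-> mirror).

#' Construct a trajectory
#'
#' One trial's time-stamped cursor path.  Raw (device-coordinate) and
#' normalized trajectories share this container; `choice` is only meaningful
#' once coordinates are normalized (targets at x = -1 and x = +1).
#'
#' @param times Numeric vector of timestamps in seconds, strictly increasing.
#' @param xs,ys Numeric coordinate vectors, same length as `times`.
#' @param participant_id,trial_id Identifiers.
#' @param choice -1 (left) or +1 (right), or `NULL` if not yet determined.
#' @param outcome_label Optional free-text outcome annotation.
#' @return An object of class `dl_trajectory`.
#' @export
trajectory <- function(times, xs, ys, participant_id = "p1", trial_id = 1L,
                       choice = NULL, outcome_label = NULL) {
  n <- length(times)
  if (n < 2 || length(xs) != n || length(ys) != n) {
    dl_stop("`times`, `xs`, `ys` must have equal length >= 2",
            "dl_format_error")
  }
  if (!all(is.finite(times)) || !all(is.finite(xs)) || !all(is.finite(ys))) {
    dl_stop("trajectory samples must be finite", "dl_format_error")
  }
  if (any(diff(times) <= 0)) {
    dl_stop("`times` must be strictly increasing", "dl_format_error")
  }
  structure(list(participant_id = participant_id, trial_id = trial_id,
                 times = as.numeric(times), xs = as.numeric(xs),
                 ys = as.numeric(ys), choice = choice,
                 outcome_label = outcome_label),
            class = "dl_trajectory")
}

#' @export
print.dl_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dl_trajectory> participant %s, trial %s: %d samples over %.3f s%s\n",
    x$participant_id, x$trial_id, n_samples(x),
    x$times[n_samples(x)] - x$times[1],
    if (is.null(x$choice)) "" else sprintf(", choice %+d", x$choice)))
  invisible(x)
}

#' Number of samples in a trajectory
#' @param traj A `dl_trajectory`.
#' @return Integer sample count.
#' @export
n_samples <- function(traj) length(traj$times)

#' Construct a velocity profile
#'
#' Per-sample cursor velocities aligned with a trajectory.
#'
#' @param vxs,vys Numeric vectors, normalized units/second.
#' @param method_tag Text describing the derivative estimator used.
#' @return An object of class `dl_velocity`.
#' @export
velocity_profile <- function(vxs, vys, method_tag = "unknown") {
  if (length(vxs) != length(vys)) {
    dl_stop("`vxs` and `vys` must have equal length", "dl_format_error")
  }
  structure(list(vxs = as.numeric(vxs), vys = as.numeric(vys),
                 method_tag = method_tag),
            class = "dl_velocity")
}

#' Screen geometry of the experimental layout
#'
#' @param start Length-2 numeric, device coordinates of the trial start
#'   location.
#' @param left_target,right_target Length-2 numeric, device coordinates of the
#'   two response locations.
#' @param y_up `TRUE` when the device y-axis increases upward; typical screen
#'   pixel coordinates have `y_up = FALSE`.
#' @return An object of class `dl_geometry`.
#' @export
screen_geometry <- function(start, left_target, right_target, y_up = FALSE) {
  for (v in list(start, left_target, right_target)) {
    if (!is.numeric(v) || length(v) != 2 || !all(is.finite(v))) {
      dl_stop("geometry points must be finite length-2 numerics",
              "dl_geometry_error")
    }
  }
  if (left_target[1] == right_target[1]) {
    dl_stop("left and right targets must differ in the horizontal coordinate",
            "dl_geometry_error")
  }
  if (left_target[2] == start[2] || right_target[2] == start[2]) {
    dl_stop("targets must differ vertically from the start position",
            "dl_geometry_error")
  }
  structure(list(start = as.numeric(start),
                 left_target = as.numeric(left_target),
                 right_target = as.numeric(right_target),
                 y_up = isTRUE(y_up)),
            class = "dl_geometry")
}

#' Read cursor logs from delimited text
#'
#' Expects long format, one row per sample, with header columns
#' `participant`, `trial`, `t`, `x`, `y` and optionally `outcome`.  Rows with
#' non-finite coordinates are dropped; samples are ordered by time within each
#' (participant, trial) group and duplicate timestamps are collapsed to their
#' first occurrence.
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect `"auto"` (by extension: `.tsv`/`.tab` means tab-separated,
#'   otherwise comma), `"csv"` or `"tsv"`.
#' @return List of `dl_trajectory` objects, one per (participant, trial).
#' @export
read_trajectories <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    dl_stop(sprintf("file not found: %s", path), "dl_io_error")
  }
  sep <- if (dialect == "tsv" ||
             (dialect == "auto" && grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)))
    "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) dl_stop(sprintf("empty or unreadable file: %s", path),
                                "dl_empty_input_error"))
  required <- c("participant", "trial", "t", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    dl_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "dl_format_error")
  }
  if (nrow(df) == 0) {
    dl_stop(sprintf("no samples in file: %s", path), "dl_empty_input_error")
  }
  ok <- is.finite(df$t) & is.finite(df$x) & is.finite(df$y)
  if (!all(ok)) df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) {
    dl_stop("all rows have non-finite coordinates", "dl_empty_input_error")
  }
  df <- df[order(df$participant, df$trial, df$t), , drop = FALSE]
  key <- paste(df$participant, df$trial, sep = "\r")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    g <- g[!duplicated(g$t), , drop = FALSE]
    trajectory(times = g$t, xs = g$x, ys = g$y,
               participant_id = as.character(g$participant[1]),
               trial_id = g$trial[1],
               outcome_label = if ("outcome" %in% names(g))
                 as.character(g$outcome[1]) else NULL)
  })
  unname(out)
}

#' Write trajectories (and optionally velocities) to delimited text
#'
#' Emits the same long-format schema [read_trajectories()] reads
#' (`participant`, `trial`, `t`, `x`, `y`[, `outcome`]), plus `vx`, `vy`
#' columns when velocity profiles are supplied — so simulated and
#' preprocessed data are interchangeable with raw logs everywhere downstream.
#'
#' @param trajs List of `dl_trajectory` objects.
#' @param path Output path; `.tsv`/`.tab` extension writes tab-separated,
#'   anything else comma-separated.
#' @param vels Optional list of `dl_velocity` objects aligned with `trajs`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, vels = NULL) {
  if (length(trajs) == 0) dl_stop("no trajectories to write",
                                  "dl_empty_input_error")
  rows <- lapply(seq_along(trajs), function(k) {
    tr <- trajs[[k]]
    d <- data.frame(participant = tr$participant_id, trial = tr$trial_id,
                    t = tr$times, x = tr$xs, y = tr$ys)
    if (!is.null(vels)) {
      d$vx <- vels[[k]]$vxs
      d$vy <- vels[[k]]$vys
    }
    if (!is.null(tr$outcome_label)) d$outcome <- tr$outcome_label
    d
  })
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spatially normalize a trajectory
#'
#' Applies the affine map taking the start position to (0, 0) and the target
#' row to y = 1, with the left/right targets at x = -1 and x = +1.  The
#' horizontal scale is the mean of the two start-to-target x spans, so for
#' layouts symmetric about the start (the typical paradigm) both targets map
#' exactly to (+/-1, 1).  The vertical map divides by the signed start-to-
#' target-row span, which flips screen-down-positive pixel coordinates
#' automatically.
#'
#' @param raw A `dl_trajectory` in device coordinates.
#' @param geom A `dl_geometry`.
#' @return A `dl_trajectory` with normalized coordinates (time untouched) and
#'   `choice` set to the sign of the final x (or `NULL` if the final x is 0).
#' @export
rescale <- function(raw, geom) {
  if (!inherits(geom, "dl_geometry")) {
    dl_stop("`geom` must be a dl_geometry", "dl_geometry_error")
  }
  sx <- (abs(geom$right_target[1] - geom$start[1]) +
         abs(geom$left_target[1] - geom$start[1])) / 2
  target_row_y <- (geom$left_target[2] + geom$right_target[2]) / 2
  sy <- target_row_y - geom$start[2]
  if (sx == 0 || sy == 0) {
    dl_stop("degenerate geometry: zero horizontal or vertical span",
            "dl_geometry_error")
  }
  xs <- (raw$xs - geom$start[1]) / sx
  # ensure left target lands on the negative side regardless of axis direction
  if ((geom$left_target[1] - geom$start[1]) / sx > 0) xs <- -xs
  ys <- (raw$ys - geom$start[2]) / sy
  fx <- xs[length(xs)]
  trajectory(times = raw$times, xs = xs, ys = ys,
             participant_id = raw$participant_id, trial_id = raw$trial_id,
             choice = if (fx == 0) NULL else as.integer(sign(fx)),
             outcome_label = raw$outcome_label)
}

#' Trim the static head and tail of a trajectory
#'
#' Movement-initiation samples (while the cursor has not yet moved `epsilon`
#' from its first position) are dropped except the last of them, and the
#' static tail (samples after the cursor has settled within `epsilon` of its
#' final position) is dropped except the first of them.  Times are shifted so
#' the first retained sample is at t = 0.
#'
#' @param traj A spatially normalized `dl_trajectory`.
#' @param epsilon Displacement threshold in normalized units (> 0).
#' @return A trimmed `dl_trajectory` with `choice` set from the final x.
#' @export
trim <- function(traj, epsilon = 0.01) {
  if (!is.numeric(epsilon) || epsilon <= 0) {
    dl_stop("`epsilon` must be positive", "dl_parameter_error")
  }
  n <- n_samples(traj)
  d_head <- sqrt((traj$xs - traj$xs[1])^2 + (traj$ys - traj$ys[1])^2)
  if (all(d_head < epsilon)) {
    dl_stop("trajectory never moves beyond `epsilon`: degenerate trial",
            "dl_degenerate_error")
  }
  first_moving <- which(d_head >= epsilon)[1]
  i0 <- first_moving - 1L  # last sample of the static head
  d_tail <- sqrt((traj$xs - traj$xs[n])^2 + (traj$ys - traj$ys[n])^2)
  moving_tail <- which(d_tail > epsilon)
  i1 <- if (length(moving_tail) == 0) n else
    min(max(moving_tail) + 1L, n)  # first sample of the static tail
  idx <- i0:i1
  if (length(idx) < 2) {
    dl_stop("trimming left fewer than 2 samples: degenerate trial",
            "dl_degenerate_error")
  }
  fx <- traj$xs[i1]
  if (fx == 0) {
    dl_stop("final x is exactly 0: choice undetermined", "dl_degenerate_error")
  }
  trajectory(times = traj$times[idx] - traj$times[i0],
             xs = traj$xs[idx], ys = traj$ys[idx],
             participant_id = traj$participant_id, trial_id = traj$trial_id,
             choice = as.integer(sign(fx)),
             outcome_label = traj$outcome_label)
}

#' Resample a trajectory to a uniform time grid
#'
#' Linear interpolation onto `n_points` equally spaced times spanning the
#' input's duration; endpoints and total duration are preserved exactly.
#'
#' @param traj A `dl_trajectory`.
#' @param n_points Number of output samples (>= 2); 101 by convention.
#' @return A `dl_trajectory` with exactly `n_points` uniformly spaced samples.
#' @export
resample <- function(traj, n_points = 101) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 2) {
    dl_stop("`n_points` must be an integer >= 2", "dl_parameter_error")
  }
  n <- n_samples(traj)
  if (traj$times[n] <= traj$times[1]) {
    dl_stop("trajectory duration must be positive", "dl_degenerate_error")
  }
  grid <- seq(traj$times[1], traj$times[n], length.out = n_points)
  xs <- stats::approx(traj$times, traj$xs, xout = grid)$y
  ys <- stats::approx(traj$times, traj$ys, xout = grid)$y
  trajectory(times = grid, xs = xs, ys = ys,
             participant_id = traj$participant_id, trial_id = traj$trial_id,
             choice = traj$choice, outcome_label = traj$outcome_label)
}

#' Estimate cursor velocities
#'
#' Time derivatives of the x and y coordinate series on the uniform
#' (post-resampling) grid.  `method = "savgol"` fits a local least-squares
#' polynomial (Savitzky-Golay differentiation filter, via
#' [signal::sgolayfilt()]), which smooths measurement jitter; the filter's own
#' least-squares boundary treatment handles the endpoints.  `method = "fd"`
#' uses central finite differences with one-sided differences at the
#' endpoints.
#'
#' @param traj A uniformly sampled `dl_trajectory` (resample first).
#' @param method `"savgol"` (default) or `"fd"`.
#' @param window Filter window length (odd, > `polyorder`); savgol only.
#' @param polyorder Local polynomial degree; savgol only.
#' @return A `dl_velocity` aligned with `traj`.
#' @export
estimate_velocity <- function(traj, method = c("savgol", "fd"),
                              window = 7, polyorder = 2) {
  method <- match.arg(method)
  if (!is_uniform_grid(traj$times)) {
    dl_stop("trajectory is not on a uniform time grid; resample() it first",
            "dl_precondition_error")
  }
  dt <- (traj$times[n_samples(traj)] - traj$times[1]) / (n_samples(traj) - 1)
  if (method == "savgol") {
    if (window %% 2 != 1 || window <= polyorder) {
      dl_stop("`window` must be odd and greater than `polyorder`",
              "dl_parameter_error")
    }
    if (n_samples(traj) < window) {
      dl_stop("trajectory shorter than the filter window",
              "dl_precondition_error")
    }
    vx <- signal::sgolayfilt(traj$xs, p = polyorder, n = window, m = 1, ts = dt)
    vy <- signal::sgolayfilt(traj$ys, p = polyorder, n = window, m = 1, ts = dt)
    tag <- sprintf("savgol(window=%d,polyorder=%d)", window, polyorder)
  } else {
    vx <- fd_derivative(traj$xs, dt)
    vy <- fd_derivative(traj$ys, dt)
    tag <- "central-fd"
  }
  velocity_profile(vx, vy, method_tag = tag)
}

# Central differences in the interior, one-sided at the two endpoints.
fd_derivative <- function(z, dt) {
  n <- length(z)
  v <- numeric(n)
  if (n > 2) v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dt)
  v[1] <- (z[2] - z[1]) / dt
  v[n] <- (z[n] - z[n - 1]) / dt
  v
}

#' Mirror a trajectory so the reference option sits at x = +1
#'
#' When comparing trials in which the option of interest (e.g. the
#' higher-reward option) appeared on different sides, trajectories are
#' canonicalized so that option is always at the right-hand corner.
#'
#' @param traj A spatially normalized `dl_trajectory`.
#' @param reference_side -1 if the reference option is at the left target in
#'   this trial, +1 if already at the right.
#' @return The trajectory, x-negated (and `choice` flipped) when
#'   `reference_side` is -1; unchanged otherwise.
#' @export
mirror_to_canonical <- function(traj, reference_side) {
  if (!reference_side %in% c(-1, 1)) {
    dl_stop("`reference_side` must be -1 or +1", "dl_parameter_error")
  }
  if (reference_side == 1) return(traj)
  trajectory(times = traj$times, xs = -traj$xs, ys = traj$ys,
             participant_id = traj$participant_id, trial_id = traj$trial_id,
             choice = if (is.null(traj$choice)) NULL else -traj$choice,
             outcome_label = traj$outcome_label)
}

#' Full preprocessing chain for one raw trajectory
#'
#' Convenience wrapper: [rescale()] (if geometry is given), [trim()],
#' [resample()], [estimate_velocity()].
#'
#' @param raw A `dl_trajectory` (device coordinates if `geom` given,
#'   otherwise assumed already normalized).
#' @param geom Optional `dl_geometry`.
#' @param epsilon Trim threshold, normalized units.
#' @param n_points Resampling grid size.
#' @param velocity_method,window,polyorder Passed to [estimate_velocity()].
#' @return List with elements `trajectory` (a trimmed, resampled
#'   `dl_trajectory`) and `velocity` (a `dl_velocity`).
#' @export
preprocess_trajectory <- function(raw, geom = NULL, epsilon = 0.01,
                                  n_points = 101,
                                  velocity_method = "savgol",
                                  window = 7, polyorder = 2) {
  tr <- if (is.null(geom)) raw else rescale(raw, geom)
  tr <- trim(tr, epsilon = epsilon)
  tr <- resample(tr, n_points = n_points)
  vel <- estimate_velocity(tr, method = velocity_method,
                           window = window, polyorder = polyorder)
  list(trajectory = tr, velocity = vel)
}
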