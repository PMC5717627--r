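# Conventional mouse-tracking trajectory measures: motion time and signed
# maximum deviation, plus per-option summary tables.

#' Motion time of a trimmed trajectory
#'
#' Time from the cursor leaving the start location to settling in the
#' response area, operationalized as the duration of the trimmed trajectory.
#'
#' @param traj A trimmed `dl_trajectory`.
#' @return Duration in seconds (> 0).
#' @export
motion_time <- function(traj) {
  if (!inherits(traj, "dl_trajectory") || n_samples(traj) < 2) {
    dl_stop("motion_time needs a trimmed trajectory with >= 2 samples",
            "dl_precondition_error")
  }
  traj$times[n_samples(traj)] - traj$times[1]
}

#' Signed maximum deviation (max-d)
#'
#' Largest perpendicular distance of the path from the ideal straight-line
#' trajectory, signed positive when the deviating point lies on the side of
#' the non-chosen option (i.e. the path bows toward the alternative) and
#' negative on the outer side.
#'
#' @param traj A trimmed, normalized `dl_trajectory` with `choice` set.
#' @param reference `"chord"` (default) measures from the line through the
#'   trajectory's own first and last points; `"diagonal"` from the idealized
#'   (0,0) to (choice, 1) line.
#' @return Signed deviation in normalized units.
#' @export
max_deviation <- function(traj, reference = c("chord", "diagonal")) {
  reference <- match.arg(reference)
  n <- n_samples(traj)
  ch <- traj$choice
  if (is.null(ch)) {
    dl_stop("trajectory has no choice assigned; trim() it first",
            "dl_precondition_error")
  }
  if (reference == "chord") {
    s <- c(traj$xs[1], traj$ys[1])
    e <- c(traj$xs[n], traj$ys[n])
  } else {
    s <- c(0, 0)
    e <- c(ch, 1)
  }
  dx <- e[1] - s[1]
  dy <- e[2] - s[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) {
    dl_stop("coincident endpoints: deviation undefined", "dl_degenerate_error")
  }
  # z-component of (e - s) x (p - s): positive on the left of the travel
  # direction.  For a right choice the non-chosen option lies to the left,
  # for a left choice to the right, so the sign flips with the choice.
  cross <- (dx * (traj$ys - s[2]) - dy * (traj$xs - s[1])) / len
  signed <- ch * cross
  signed[which.max(abs(signed))]
}

#' Per-trial measures table
#'
#' @param trajs List of trimmed `dl_trajectory` objects (or a single one).
#' @param reference Passed to [max_deviation()].
#' @return data.frame with one row per trial: `participant`, `trial`,
#'   `choice`, `motion_time`, `max_d`.
#' @export
trajectory_measures <- function(trajs, reference = "chord") {
  if (inherits(trajs, "dl_trajectory")) trajs <- list(trajs)
  if (length(trajs) == 0) {
    dl_stop("no trajectories supplied", "dl_empty_input_error")
  }
  do.call(rbind, lapply(trajs, function(tr) {
    data.frame(participant = tr$participant_id, trial = tr$trial_id,
               choice = tr$choice,
               motion_time = motion_time(tr),
               max_d = max_deviation(tr, reference = reference))
  }))
}

#' Per-option summary of trajectory measures
#'
#' Counts and mean measures per response option, in the layout of the
#' conventional per-block / per-participant summary tables (option, N,
#' motion time, max-d), plus the percentage of trials choosing each option.
#' Options never chosen get `N = 0` and `NA` means.
#'
#' @param measures data.frame from [trajectory_measures()] (needs columns
#'   `choice`, `motion_time`, `max_d`).
#' @param group_label Text label attached to every row.
#' @return data.frame with one row per option (+1 first, then -1): columns
#'   `group`, `option`, `n`, `motion_time`, `max_d`, `pct`.
#' @export
summarize_measures <- function(measures, group_label = "") {
  if (is.null(measures) || nrow(measures) == 0) {
    dl_stop("no measures supplied", "dl_empty_input_error")
  }
  total <- nrow(measures)
  rows <- lapply(c(1, -1), function(opt) {
    sel <- measures[measures$choice == opt, , drop = FALSE]
    n <- nrow(sel)
    data.frame(group = group_label, option = opt, n = n,
               motion_time = if (n) mean(sel$motion_time) else NA_real_,
               max_d = if (n) mean(sel$max_d) else NA_real_,
               pct = 100 * n / total)
  })
  do.call(rbind, rows)
}
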