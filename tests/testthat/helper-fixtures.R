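# Shared fixtures and independent oracles.

# Typical screen layout: pixel coordinates, y increasing downward,
# start bottom-centre, targets in the top corners, symmetric about the start.
default_geom <- function() {
  screen_geometry(start = c(400, 600),
                  left_target = c(100, 100),
                  right_target = c(700, 100),
                  y_up = FALSE)
}

# Write a long-format log to a temp file and return its path.
write_log <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  sep <- if (ext %in% c(".tsv", ".tab")) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# A clean normalized trajectory from (0,0) to (choice, 1) along a smooth
# curve, uniform times.
make_smooth_traj <- function(n = 60, duration = 0.6, choice = 1L,
                             bow = 0.15, trial_id = 1L,
                             participant_id = "p1") {
  u <- seq(0, 1, length.out = n)
  xs <- choice * u + bow * sin(pi * u) * (-choice)
  ys <- u
  trajectory(times = u * duration, xs = xs, ys = ys,
             participant_id = participant_id, trial_id = trial_id,
             choice = choice)
}

# Random landscape parameters with coefficients of moderate size.
random_params <- function(alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- param_vector_names(alpha)[-1]
  landscape_params(alpha = alpha,
                   tau = exp(stats::runif(1, log(0.02), log(0.5))),
                   coeffs = stats::setNames(stats::runif(length(nms), -0.5, 0.5),
                                            nms))
}

# Oracle: central finite differences of the potential.
numeric_gradient <- function(params, x, y, h = 1e-6) {
  list(dVdx = (potential(params, x + h, y) - potential(params, x - h, y)) / (2 * h),
       dVdy = (potential(params, x, y + h) - potential(params, x, y - h)) / (2 * h))
}

# Oracle: central finite differences of the multi-trajectory error in
# (tau, c_ij), same ordering as error_jacobian().
numeric_error_jacobian <- function(params, trajs, vels, h = 1e-7) {
  v0 <- params_to_vector(params)
  vapply(seq_along(v0), function(q) {
    vp <- v0; vp[q] <- vp[q] + h
    vm <- v0; vm[q] <- vm[q] - h
    (multi_error(vector_to_params(vp, params$alpha), trajs, vels) -
     multi_error(vector_to_params(vm, params$alpha), trajs, vels)) / (2 * h)
  }, numeric(1))
}

# Oracle: the velocity-matching objective is linear in (1/tau, c/tau), so its
# global minimum has a closed form via linear least squares on the stacked
# residuals (valid when all trajectories have equal length, as after
# resampling).  Independent of the iterative optimizer.
linear_ls_oracle <- function(trajs, vels, alpha) {
  rows_A <- list(); rows_v <- list()
  for (k in seq_along(trajs)) {
    b <- decisionlandscape:::velocity_basis(alpha, trajs[[k]]$xs, trajs[[k]]$ys)
    rows_A[[k]] <- rbind(cbind(-b$bx, -b$Gx), cbind(-b$by, -b$Gy))
    rows_v[[k]] <- c(vels[[k]]$vxs, vels[[k]]$vys)
  }
  A <- do.call(rbind, rows_A)
  v <- do.call(c, rows_v)
  w <- qr.solve(A, v)          # w = (1/tau, c/tau)
  tau <- 1 / w[1]
  nms <- param_vector_names(alpha)[-1]
  landscape_params(alpha = alpha, tau = tau,
                   coeffs = stats::setNames(w[-1] * tau, nms))
}

# Circular arc from (0,0) to (1,1) with the given sagitta, bowed toward the
# left option (side = +1 bows left, the non-chosen side for a right choice;
# side = -1 mirrors it about the chord).  Analytic maximum perpendicular
# deviation from the chord equals the sagitta.
arc_trajectory <- function(sagitta, side = 1, n = 101) {
  s <- c(0, 0); e <- c(1, 1)
  m <- (s + e) / 2
  nrm <- side * c(-1, 1) / sqrt(2)      # unit normal, left of travel if side=1
  R <- (sum((e - s)^2) / 4 + sagitta^2) / (2 * sagitta)
  centre <- m + (sagitta - R) * nrm
  th_s <- atan2(s[2] - centre[2], s[1] - centre[1])
  th_e <- atan2(e[2] - centre[2], e[1] - centre[1])
  th_m <- atan2(m[2] + sagitta * nrm[2] - centre[2],
                m[1] + sagitta * nrm[1] - centre[1])
  # sweep from th_s to th_e passing through th_m
  sweep <- (th_e - th_s) %% (2 * pi)
  mid <- (th_m - th_s) %% (2 * pi)
  if (mid > sweep) sweep <- sweep - 2 * pi
  th <- th_s + seq(0, 1, length.out = n) * sweep
  trajectory(times = seq(0, 1, length.out = n),
             xs = centre[1] + R * cos(th),
             ys = centre[2] + R * sin(th),
             choice = 1L)
}

# Simulate + preprocess a small dataset; returns lists ready for fitting.
simulated_dataset <- function(params, n_trials, seed, ...,
                              symmetric_starts = TRUE) {
  cfg <- simulation_config(seed = seed, ...)
  trajs <- generate_dataset(params, n_trials, cfg,
                            symmetric_starts = symmetric_starts)
  pp <- lapply(trajs, preprocess_trajectory)
  list(trajs = lapply(pp, `[[`, "trajectory"),
       vels = lapply(pp, `[[`, "velocity"))
}
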