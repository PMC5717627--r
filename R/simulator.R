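# Forward simulation of the landscape dynamics
#   tau dx/dt = -dV/dx,  tau dy/dt = -dV/dy
# by fixed-step classical 4th-order Runge-Kutta, with optional additive
# velocity noise (an Euler-Maruyama-style sqrt(dt) perturbation on top of the
# deterministic step).  Used both as the synthetic-data generator and as the
# parameter-recovery harness for the fitting module.

#' Simulation settings
#'
#' @param dt Integration step, seconds.
#' @param t_max Time cap, seconds.
#' @param stop_radius Normalized distance to a target at which the trial
#'   terminates.
#' @param start_offset_scale Scale (normalized units) of the random initial
#'   displacement from (0, 0) used by [generate_dataset()].
#' @param velocity_noise_scale Scale of the additive velocity noise,
#'   normalized units/second; 0 gives deterministic paths.
#' @param seed Integer seed for the noise and start-offset generator, or
#'   `NULL` to use the current RNG state.
#' @param x_bounds,y_bounds Arena limits; integration also terminates when
#'   the state exits this box.  The cubic vertical baseline makes the model
#'   unbounded below for y well under the start row, and strong couplings can
#'   tilt the field outward, so an escaping state would otherwise diverge;
#'   the path up to the arena edge is still a valid trial.
#' @return An object of class `dl_simconfig`.
#' @export
simulation_config <- function(dt = 0.001, t_max = 5, stop_radius = 0.05,
                              start_offset_scale = 0.02,
                              velocity_noise_scale = 0, seed = NULL,
                              x_bounds = c(-1.5, 1.5),
                              y_bounds = c(-0.25, 1.5)) {
  if (dt <= 0 || t_max <= dt || stop_radius <= 0) {
    dl_stop("need dt > 0, t_max > dt, stop_radius > 0", "dl_parameter_error")
  }
  structure(list(dt = dt, t_max = t_max, stop_radius = stop_radius,
                 start_offset_scale = start_offset_scale,
                 velocity_noise_scale = velocity_noise_scale, seed = seed,
                 x_bounds = x_bounds, y_bounds = y_bounds),
            class = "dl_simconfig")
}

#' Simulate one trajectory from a known landscape
#'
#' Integrates the gradient system forward from `(x0, y0)` until the state
#' first comes within `stop_radius` of either attractor (-1, 1) or (1, 1),
#' or until `t_max`.  With zero noise the output is fully deterministic.
#'
#' @param params A `dl_params` object.
#' @param x0,y0 Normalized start position (not exactly a critical point when
#'   noise is 0, or the cursor never moves).
#' @param config A `dl_simconfig`.
#' @param participant_id,trial_id Identifiers stamped on the output.
#' @return A `dl_trajectory` on a uniform `dt` grid, `choice` set to the
#'   target reached (or the sign of the final x at `t_max`).
#' @export
simulate_trajectory <- function(params, x0 = 0.01, y0 = 0.01,
                                config = simulation_config(),
                                participant_id = "sim", trial_id = 1L) {
  dt <- config$dt
  n_max <- floor(config$t_max / dt)
  xs <- numeric(n_max + 1)
  ys <- numeric(n_max + 1)
  xs[1] <- x0
  ys[1] <- y0
  noise <- config$velocity_noise_scale
  # precomputed scalar field (avoids rebuilding the index table per RK4 stage)
  tb <- coeff_table(params$alpha)
  ci <- tb$i; cj <- tb$j; ckm1 <- tb$k - 1
  cv <- unname(params$coeffs)
  inv_tau <- 1 / params$tau
  field <- function(x, y) {
    gx <- x^3 - x + sum(cv * ci * x^(ci - 1) * y^cj / ckm1)
    gy <- y^2 - y + sum(cv * cj * x^ci * y^(cj - 1) / ckm1)
    list(vx = -gx * inv_tau, vy = -gy * inv_tau)
  }

  reached <- 0L
  n_used <- n_max
  for (s in seq_len(n_max)) {
    x <- xs[s]; y <- ys[s]
    k1 <- field(x, y)
    k2 <- field(x + dt / 2 * k1$vx, y + dt / 2 * k1$vy)
    k3 <- field(x + dt / 2 * k2$vx, y + dt / 2 * k2$vy)
    k4 <- field(x + dt * k3$vx, y + dt * k3$vy)
    xn <- x + dt / 6 * (k1$vx + 2 * k2$vx + 2 * k3$vx + k4$vx)
    yn <- y + dt / 6 * (k1$vy + 2 * k2$vy + 2 * k3$vy + k4$vy)
    if (noise > 0) {
      xn <- xn + noise * sqrt(dt) * stats::rnorm(1)
      yn <- yn + noise * sqrt(dt) * stats::rnorm(1)
    }
    if (!is.finite(xn) || !is.finite(yn)) {
      dl_stop(sprintf("non-finite state at integration step %d (t = %.4f s)",
                      s, s * dt), "dl_numeric_error")
    }
    xs[s + 1] <- xn
    ys[s + 1] <- yn
    if (sqrt((xn - 1)^2 + (yn - 1)^2) <= config$stop_radius) {
      reached <- 1L; n_used <- s; break
    }
    if (sqrt((xn + 1)^2 + (yn - 1)^2) <= config$stop_radius) {
      reached <- -1L; n_used <- s; break
    }
    if (xn < config$x_bounds[1] || xn > config$x_bounds[2] ||
        yn < config$y_bounds[1] || yn > config$y_bounds[2]) {
      n_used <- s; break  # escaped the arena; keep the path so far
    }
  }
  idx <- seq_len(n_used + 1)
  if (reached == 0L) {
    disp <- sqrt((xs[idx] - x0)^2 + (ys[idx] - y0)^2)
    if (max(disp) < 1e-9) {
      dl_stop("cursor never moved: start is a critical point (stall)",
              "dl_degenerate_error")
    }
  }
  fx <- xs[n_used + 1]
  trajectory(times = (idx - 1) * dt, xs = xs[idx], ys = ys[idx],
             participant_id = participant_id, trial_id = trial_id,
             choice = if (reached != 0L) reached
                      else if (fx == 0) NULL else as.integer(sign(fx)))
}

#' Generate a synthetic dataset of trajectories
#'
#' Independent simulations with start positions displaced from (0, 0):
#' horizontal offsets drawn from N(0, scale), vertical offsets |N(0, scale)|
#' (kept nonnegative so starts sit inside the basin leading to the target
#' row).  With `symmetric_starts = TRUE` trials come in mirrored pairs
#' (+x0, y0) / (-x0, y0), guaranteeing a left/right balanced design.
#'
#' @param params A `dl_params` object.
#' @param n_trials Number of trajectories (>= 1).
#' @param config A `dl_simconfig`; its `seed` (if non-`NULL`) makes the
#'   dataset reproducible.
#' @param symmetric_starts Generate mirrored start pairs.
#' @param participant_id Identifier stamped on all trials.
#' @return List of `dl_trajectory` objects, trial ids 1..n.  Trials that
#'   stall (never move) are dropped with a warning; if all stall, an error.
#' @export
generate_dataset <- function(params, n_trials, config = simulation_config(),
                             symmetric_starts = FALSE,
                             participant_id = "sim") {
  if (n_trials < 1) dl_stop("`n_trials` must be >= 1", "dl_empty_input_error")
  if (!is.null(config$seed)) set.seed(config$seed)
  sc <- config$start_offset_scale
  if (symmetric_starts) {
    npair <- ceiling(n_trials / 2)
    xo <- abs(stats::rnorm(npair, 0, sc))
    yo <- abs(stats::rnorm(npair, 0, sc))
    x0 <- as.vector(rbind(xo, -xo))[seq_len(n_trials)]
    y0 <- as.vector(rbind(yo, yo))[seq_len(n_trials)]
  } else {
    x0 <- stats::rnorm(n_trials, 0, sc)
    y0 <- abs(stats::rnorm(n_trials, 0, sc))
  }
  out <- vector("list", n_trials)
  stalled <- logical(n_trials)
  for (k in seq_len(n_trials)) {
    out[[k]] <- tryCatch(
      simulate_trajectory(params, x0[k], y0[k], config,
                          participant_id = participant_id, trial_id = k),
      dl_degenerate_error = function(e) NULL)
    stalled[k] <- is.null(out[[k]])
  }
  if (all(stalled)) {
    dl_stop("all simulated trials stalled; check params and start offsets",
            "dl_degenerate_error")
  }
  if (any(stalled)) {
    warning(sprintf("%d of %d simulated trials stalled and were dropped",
                    sum(stalled), n_trials))
  }
  out[!stalled]
}
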