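# Velocity-matching estimation of landscape parameters.
#
# For a trajectory sampled at positions (x_i, y_i) with numerically estimated
# velocities (vx_i, vy_i), the per-trajectory error is the mean squared
# mismatch between those data velocities and the model velocity field
# evaluated at the same positions:
#
#   H(tau, c) = mean_i [ (vx_model(x_i, y_i) - vx_i)^2
#                       + (vy_model(x_i, y_i) - vy_i)^2 ].
#
# For N trajectories the objective is the plain average of the per-trajectory
# H values.  Because the model velocity is -grad V / tau with V polynomial in
# (x, y) and linear in the coefficients, both the objective and its gradient
# in (tau, c_ij) are available in closed form; the optimizer works on
# (log tau, c_ij) so tau stays positive without an explicit constraint.

# Per-point basis of the model velocity field:
#   vx_model = -(bx + Gx %*% c) / tau,   vy_model = -(by + Gy %*% c) / tau
# with bx = x^3 - x, by = y^2 - y and one basis column per coefficient.
velocity_basis <- function(alpha, x, y) {
  tb <- coeff_table(alpha)
  n <- length(x)
  p <- nrow(tb)
  Gx <- matrix(0, n, p)
  Gy <- matrix(0, n, p)
  for (q in seq_len(p)) {
    i <- tb$i[q]; j <- tb$j[q]; km1 <- tb$k[q] - 1
    Gx[, q] <- i * x^(i - 1) * y^j / km1
    Gy[, q] <- j * x^i * y^(j - 1) / km1
  }
  list(bx = x^3 - x, by = y^2 - y, Gx = Gx, Gy = Gy)
}

check_aligned <- function(traj, vel) {
  if (n_samples(traj) != length(vel$vxs)) {
    dl_stop("trajectory and velocity profile have different lengths",
            "dl_alignment_error")
  }
}

#' Velocity-matching error for one trajectory
#'
#' Mean over sample points of the squared difference between the model
#' velocity field (evaluated at the observed positions) and the data
#' velocities, summed over the x and y components.
#'
#' @param params A `dl_params` object.
#' @param traj A preprocessed `dl_trajectory`.
#' @param vel The matching `dl_velocity`.
#' @return Nonnegative scalar, (normalized units/second)^2.
#' @export
velocity_error <- function(params, traj, vel) {
  check_aligned(traj, vel)
  mv <- model_velocity(params, traj$xs, traj$ys)
  mean((mv$vx - vel$vxs)^2 + (mv$vy - vel$vys)^2)
}

#' Average velocity-matching error over a trajectory set
#'
#' @param params A `dl_params` object.
#' @param trajs List of `dl_trajectory` objects (N >= 1).
#' @param vels List of matching `dl_velocity` objects.
#' @return Arithmetic mean of [velocity_error()] over the set.
#' @export
multi_error <- function(params, trajs, vels) {
  if (length(trajs) == 0) {
    dl_stop("no trajectories supplied", "dl_empty_input_error")
  }
  if (length(trajs) != length(vels)) {
    dl_stop("`trajs` and `vels` have different lengths", "dl_alignment_error")
  }
  mean(vapply(seq_along(trajs),
              function(k) velocity_error(params, trajs[[k]], vels[[k]]),
              numeric(1)))
}

# Analytic gradient of one trajectory's H in (tau, c_ij).
# d vx_model / d tau = -vx_model / tau; d vx_model / d c_q = -Gx[, q] / tau.
traj_error_jacobian <- function(params, traj, vel) {
  check_aligned(traj, vel)
  basis <- velocity_basis(params$alpha, traj$xs, traj$ys)
  tau <- params$tau
  cvec <- params$coeffs
  vxm <- -(basis$bx + drop(basis$Gx %*% cvec)) / tau
  vym <- -(basis$by + drop(basis$Gy %*% cvec)) / tau
  rx <- vxm - vel$vxs
  ry <- vym - vel$vys
  m <- n_samples(traj)
  d_tau <- (2 / m) * (sum(rx * (-vxm / tau)) + sum(ry * (-vym / tau)))
  d_c <- (2 / m) * (-1 / tau) *
    (drop(crossprod(basis$Gx, rx)) + drop(crossprod(basis$Gy, ry)))
  c(d_tau, d_c)
}

#' Analytic Jacobian of the multi-trajectory error
#'
#' Partial derivatives of [multi_error()] with respect to tau and each
#' coupling coefficient, in the order of [param_vector_names()].  The tau
#' partial follows from the chain rule through the `-1/tau` factor of the
#' velocity field.
#'
#' @inheritParams multi_error
#' @return Named numeric vector of partials, one per free parameter.
#' @export
error_jacobian <- function(params, trajs, vels) {
  if (length(trajs) == 0) {
    dl_stop("no trajectories supplied", "dl_empty_input_error")
  }
  if (length(trajs) != length(vels)) {
    dl_stop("`trajs` and `vels` have different lengths", "dl_alignment_error")
  }
  per <- vapply(seq_along(trajs),
                function(k) traj_error_jacobian(params, trajs[[k]], vels[[k]]),
                numeric(1 + length(params$coeffs)))
  g <- if (is.matrix(per)) rowMeans(per) else mean(per)
  stats::setNames(g, param_vector_names(params$alpha))
}

#' Fit a decision landscape to a set of trajectories
#'
#' Quasi-Newton (L-BFGS-B) minimization of the velocity-matching error with
#' its analytic gradient, started from the baseline landscape (all
#' coefficients zero, `tau = tau0`).  tau is optimized on the log scale,
#' boxed to `log_tau_bounds` so degenerate fits (tau diverging when data
#' velocities are near zero) are capped and flagged rather than erroring.
#' Numerical non-convergence never raises: the result carries
#' `converged = FALSE` instead.
#'
#' @param trajs List of preprocessed `dl_trajectory` objects, or a single one.
#' @param vels List of matching `dl_velocity` objects, or a single one.
#' @param alpha Integer model order (>= 2).
#' @param tau0 Starting time-scale in seconds.
#' @param log_tau_bounds Length-2 numeric, box for log(tau).
#' @param maxit Iteration cap.
#' @param pgtol Projected-gradient tolerance of the optimizer.
#' @return An object of class `dl_fit`: `params` (fitted `dl_params`),
#'   `error` (final objective, equal to the mean of `per_trajectory_errors`),
#'   `per_trajectory_errors`, `initial_error` (objective at the baseline
#'   start), `converged`, `n_evaluations` and the optimizer `message`.
#' @examples
#' p <- landscape_params(alpha = 2, tau = 0.05)
#' tr <- simulate_trajectory(p, x0 = 0.02, y0 = 0.02)
#' pp <- preprocess_trajectory(tr)
#' fit_landscape(pp$trajectory, pp$velocity, alpha = 2)
#' @export
fit_landscape <- function(trajs, vels, alpha = 3, tau0 = 0.05,
                          log_tau_bounds = c(-8, 4),
                          maxit = 500, pgtol = 1e-8) {
  if (inherits(trajs, "dl_trajectory")) trajs <- list(trajs)
  if (inherits(vels, "dl_velocity")) vels <- list(vels)
  if (length(trajs) == 0) {
    dl_stop("no trajectories supplied", "dl_empty_input_error")
  }
  alpha <- check_alpha(alpha)
  p <- nrow(coeff_table(alpha))

  unpack <- function(theta) {
    vector_to_params(c(exp(theta[1]), theta[-1]), alpha)
  }
  fn <- function(theta) multi_error(unpack(theta), trajs, vels)
  gr <- function(theta) {
    pars <- unpack(theta)
    j <- error_jacobian(pars, trajs, vels)
    c(j[1] * pars$tau, j[-1])  # d/d log(tau) = tau * d/d tau
  }

  theta0 <- c(log(tau0), numeric(p))
  initial_error <- fn(theta0)
  res <- tryCatch(
    stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                 lower = c(log_tau_bounds[1], rep(-Inf, p)),
                 upper = c(log_tau_bounds[2], rep(Inf, p)),
                 control = list(maxit = maxit, pgtol = pgtol, factr = 1e3)),
    error = function(e) NULL)

  if (is.null(res) || !is.finite(res$value) || res$value > initial_error) {
    # fall back to the baseline start rather than report a worse point
    theta <- theta0
    value <- initial_error
    converged <- FALSE
    n_eval <- if (is.null(res)) 0L else unname(res$counts[1])
    message <- "optimizer failed to improve on the baseline start"
  } else {
    theta <- res$par
    value <- res$value
    converged <- res$convergence == 0
    n_eval <- unname(res$counts[1])
    message <- res$message
  }
  at_bound <- theta[1] <= log_tau_bounds[1] + 1e-9 ||
              theta[1] >= log_tau_bounds[2] - 1e-9
  params <- unpack(theta)
  per <- vapply(seq_along(trajs),
                function(k) velocity_error(params, trajs[[k]], vels[[k]]),
                numeric(1))
  structure(list(params = params,
                 error = mean(per),
                 per_trajectory_errors = per,
                 initial_error = initial_error,
                 converged = converged && !at_bound,
                 tau_at_bound = at_bound,
                 n_evaluations = n_eval,
                 message = message),
            class = "dl_fit")
}

#' @export
print.dl_fit <- function(x, ...) {
  cat(sprintf("<dl_fit> alpha = %d, objective %.6g (from %.6g), %s\n",
              x$params$alpha, x$error, x$initial_error,
              if (x$converged) "converged" else "NOT converged"))
  print(round(params_to_vector(x$params), 6))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Flat parameter mapping plus objective values and convergence metadata.
#'
#' @param fit A `dl_fit` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  out <- c(list(alpha = fit$params$alpha, tau = fit$params$tau),
           as.list(fit$params$coeffs),
           list(error = fit$error,
                initial_error = fit$initial_error,
                per_trajectory_errors = fit$per_trajectory_errors,
                converged = fit$converged,
                n_evaluations = fit$n_evaluations))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
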