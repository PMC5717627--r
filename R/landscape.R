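# Decision-landscape potential model.
#
# The cursor is modelled as an overdamped particle in a potential V(x, y):
#
#   tau * dx/dt = -dV/dx,   tau * dy/dt = -dV/dy,   tau > 0,
#
# where V = Vx(x) + Vy(y) + Vxy(x, y).  The fixed baseline
# Vx(x) = x^4/4 - x^2/2 and Vy(y) = y^3/3 - y^2/2 places attractors at the
# two response locations (-1, 1) and (1, 1) and a repellor at the start
# (0, 0).  The fitted coupling part is a polynomial
#
#   Vxy(x, y) = sum_{k=2..alpha} sum_{i+j=k, i,j>=1} c_ij x^i y^j / (k - 1)
#
# whose coefficients c_ij encode asymmetry and finer structure; c11 is the
# primary left/right asymmetry parameter.

#' Coupling-term index table for a model order
#'
#' Enumerates the exponent pairs (i, j) of the coupling polynomial for a given
#' maximum total degree `alpha`: all pairs with i, j >= 1 and i + j <= alpha,
#' ordered by total degree k = i + j ascending, then by i descending.  This
#' fixed order defines the layout of parameter vectors throughout the package.
#'
#' @param alpha Integer model order, >= 2.
#' @return A data.frame with columns `i`, `j`, `k` (k = i + j).
#' @export
coeff_table <- function(alpha) {
  check_alpha(alpha)
  do.call(rbind, lapply(2:alpha, function(k) {
    i <- (k - 1):1
    data.frame(i = i, j = k - i, k = k)
  }))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha != round(alpha) || alpha < 2) {
    dl_stop("`alpha` must be a single integer >= 2", "dl_parameter_error")
  }
  invisible(as.integer(alpha))
}

#' Names of the free parameters, in canonical order
#'
#' @param alpha Integer model order, >= 2.
#' @return Character vector: `"tau"` followed by `"c<i><j>"` in the order of
#'   [coeff_table()].  Length is 2 for `alpha = 2`, 4 for `alpha = 3`, 7 for
#'   `alpha = 4`.
#' @export
param_vector_names <- function(alpha) {
  tb <- coeff_table(alpha)
  c("tau", sprintf("c%d%d", tb$i, tb$j))
}

#' Construct a landscape parameter set
#'
#' @param alpha Integer model order (maximum total degree of the coupling
#'   polynomial), >= 2.
#' @param tau Time-scale in seconds, > 0.  Larger `tau` slows the modelled
#'   motion uniformly.
#' @param coeffs Named numeric vector of coupling coefficients (names like
#'   `"c11"`, `"c21"`); coefficients not named default to 0.  `NULL` means the
#'   baseline landscape (all zero).
#' @return An object of class `dl_params`.
#' @examples
#' landscape_params(alpha = 3, tau = 0.08, coeffs = c(c11 = 0.3, c21 = -0.1))
#' @export
landscape_params <- function(alpha = 2, tau = 0.05, coeffs = NULL) {
  alpha <- check_alpha(alpha)
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    dl_stop("`tau` must be a single positive number", "dl_parameter_error")
  }
  nms <- param_vector_names(alpha)[-1]
  cv <- stats::setNames(numeric(length(nms)), nms)
  if (!is.null(coeffs)) {
    if (is.null(names(coeffs)) || any(names(coeffs) == "")) {
      dl_stop("`coeffs` must be a fully named numeric vector", "dl_parameter_error")
    }
    unknown <- setdiff(names(coeffs), nms)
    if (length(unknown)) {
      dl_stop(sprintf("coefficient(s) %s not defined for alpha = %d",
                      paste(unknown, collapse = ", "), alpha),
              "dl_parameter_error")
    }
    cv[names(coeffs)] <- as.numeric(coeffs)
  }
  structure(list(alpha = alpha, tau = tau, coeffs = cv),
            class = "dl_params")
}

#' @export
print.dl_params <- function(x, ...) {
  cat(sprintf("<dl_params> alpha = %d, tau = %g\n", x$alpha, x$tau))
  print(round(x$coeffs, 6))
  invisible(x)
}

#' Flatten parameters to a numeric vector (tau first)
#'
#' @param params A `dl_params` object.
#' @return Named numeric vector ordered as [param_vector_names()].
#' @export
params_to_vector <- function(params) {
  c(tau = params$tau, params$coeffs)
}

#' Rebuild parameters from a flat vector
#'
#' @param v Numeric vector ordered as [param_vector_names()] (tau first).
#' @param alpha Integer model order.
#' @return A `dl_params` object.
#' @export
vector_to_params <- function(v, alpha) {
  nms <- param_vector_names(alpha)
  if (length(v) != length(nms)) {
    dl_stop(sprintf("parameter vector has length %d, expected %d for alpha = %d",
                    length(v), length(nms), alpha), "dl_parameter_error")
  }
  landscape_params(alpha = alpha, tau = v[[1]],
                   coeffs = stats::setNames(v[-1], nms[-1]))
}

#' Fixed baseline potential
#'
#' `Vx(x) + Vy(y) = x^4/4 - x^2/2 + y^3/3 - y^2/2`, with integration
#' constants set to zero.  Attractors at (-1, 1) and (1, 1), repellor at
#' (0, 0).
#'
#' @param x,y Numeric vectors of normalized coordinates (recycled together).
#' @return Numeric vector of potential values.
#' @export
baseline_potential <- function(x, y) {
  x^4 / 4 - x^2 / 2 + y^3 / 3 - y^2 / 2
}

#' Fitted coupling potential Vxy
#'
#' @param params A `dl_params` object.
#' @param x,y Numeric vectors of normalized coordinates.
#' @return Numeric vector of coupling-potential values
#'   `sum c_ij x^i y^j / (k - 1)`.
#' @export
coupling_potential <- function(params, x, y) {
  tb <- coeff_table(params$alpha)
  out <- numeric(length(x + y))  # recycled length
  for (p in seq_len(nrow(tb))) {
    cp <- params$coeffs[[p]]
    if (cp != 0) {
      out <- out + cp * x^tb$i[p] * y^tb$j[p] / (tb$k[p] - 1)
    }
  }
  out
}

#' Full decision-landscape potential
#'
#' @inheritParams coupling_potential
#' @return `baseline_potential(x, y) + coupling_potential(params, x, y)`.
#' @export
potential <- function(params, x, y) {
  baseline_potential(x, y) + coupling_potential(params, x, y)
}

#' Analytic gradient of the potential
#'
#' @inheritParams coupling_potential
#' @return List with numeric components `dVdx` and `dVdy`:
#'   `dVdx = x^3 - x + sum c_ij i x^(i-1) y^j / (k-1)` and
#'   `dVdy = y^2 - y + sum c_ij j x^i y^(j-1) / (k-1)`.
#' @export
landscape_gradient <- function(params, x, y) {
  tb <- coeff_table(params$alpha)
  dx <- x^3 - x + 0 * y
  dy <- y^2 - y + 0 * x
  for (p in seq_len(nrow(tb))) {
    cp <- params$coeffs[[p]]
    if (cp != 0) {
      i <- tb$i[p]; j <- tb$j[p]; km1 <- tb$k[p] - 1
      dx <- dx + cp * i * x^(i - 1) * y^j / km1
      dy <- dy + cp * j * x^i * y^(j - 1) / km1
    }
  }
  list(dVdx = dx, dVdy = dy)
}

#' Model velocity field
#'
#' The velocity the fitted dynamical system predicts at a position:
#' `(-dV/dx / tau, -dV/dy / tau)`.
#'
#' @inheritParams coupling_potential
#' @return List with numeric components `vx` and `vy` in normalized
#'   units/second.
#' @export
model_velocity <- function(params, x, y) {
  g <- landscape_gradient(params, x, y)
  list(vx = -g$dVdx / params$tau, vy = -g$dVdy / params$tau)
}

#' Write parameters to a flat YAML or JSON mapping
#'
#' The serialized form is a flat mapping `{alpha, tau, c11, c21, ...}`.
#'
#' @param params A `dl_params` object.
#' @param path Output file; format chosen by extension (`.json` for JSON,
#'   anything else YAML).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  flat <- c(list(alpha = params$alpha, tau = params$tau),
            as.list(params$coeffs))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

#' Read parameters from a flat YAML or JSON mapping
#'
#' @param path File written by [write_params()] (or hand-authored in the same
#'   flat `{alpha, tau, c11, ...}` layout).
#' @return A `dl_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    dl_stop(sprintf("parameter file not found: %s", path), "dl_io_error")
  }
  flat <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(flat$alpha) || is.null(flat$tau)) {
    dl_stop("parameter file must contain `alpha` and `tau`", "dl_format_error")
  }
  cf <- flat[setdiff(names(flat), c("alpha", "tau"))]
  landscape_params(alpha = flat$alpha, tau = flat$tau,
                   coeffs = if (length(cf)) unlist(cf) else NULL)
}
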