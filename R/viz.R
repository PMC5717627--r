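# 3D rendering of decision landscapes: tabulate V on a grid, draw it with
# base persp(), optionally lifting trajectories onto the surface or
# overlaying a second landscape for comparison.

#' Tabulate the potential on a regular grid
#'
#' @param params A `dl_params` object.
#' @param x_range,y_range Length-2 numeric bounds of the plotting window.
#' @param resolution Points per axis (>= 2).
#' @return An object of class `dl_surface`: `x`, `y` (axis grids) and
#'   `values` (resolution x resolution matrix, `values[i, j] = V(x[i], y[j])`),
#'   plus the generating `params`.
#' @export
evaluate_surface <- function(params, x_range = c(-1.2, 1.2),
                             y_range = c(-0.2, 1.2), resolution = 101) {
  if (length(x_range) != 2 || length(y_range) != 2 ||
      diff(x_range) <= 0 || diff(y_range) <= 0) {
    dl_stop("ranges must be increasing length-2 numerics", "dl_parameter_error")
  }
  if (resolution < 2) {
    dl_stop("`resolution` must be >= 2", "dl_parameter_error")
  }
  x <- seq(x_range[1], x_range[2], length.out = resolution)
  y <- seq(y_range[1], y_range[2], length.out = resolution)
  values <- outer(x, y, function(xx, yy) potential(params, xx, yy))
  if (!all(is.finite(values))) {
    dl_stop("non-finite potential values on the grid", "dl_numeric_error")
  }
  structure(list(x = x, y = y, values = values, params = params),
            class = "dl_surface")
}

#' Heights of a trajectory lifted onto its landscape
#'
#' @param params A `dl_params` object.
#' @param traj A `dl_trajectory`.
#' @return Numeric vector `V(x_i, y_i)` along the path.
#' @export
lift_trajectory <- function(params, traj) {
  potential(params, traj$xs, traj$ys)
}

#' Export a surface grid as delimited text
#'
#' Long format, one row per node: columns `x`, `y`, `V`.
#'
#' @param surface A `dl_surface`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  df <- expand.grid(x = surface$x, y = surface$y)
  df$V <- as.vector(surface$values)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a decision landscape as a 3D surface
#'
#' Writes a static PNG.  Trajectories are drawn lifted onto the surface
#' (z = V(x, y) along the path); a second surface can be overlaid as a
#' wireframe for side-by-side landscape comparison.
#'
#' @param surface A `dl_surface`.
#' @param out_path Output PNG path.
#' @param trajectories Optional list of `dl_trajectory` objects to overlay.
#' @param comparison Optional second `dl_surface` on the same ranges.
#' @param theta,phi Viewing angles passed to [graphics::persp()].
#' @param col,comparison_col Surface colours.
#' @param width,height Device size in pixels.
#' @return `out_path`, invisibly.
#' @export
plot_landscape <- function(surface, out_path, trajectories = NULL,
                           comparison = NULL, theta = 40, phi = 25,
                           col = "lightsteelblue", comparison_col = "grey70",
                           width = 900, height = 700) {
  ok <- tryCatch({
    grDevices::png(out_path, width = width, height = height)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) dl_stop(sprintf("cannot write figure to %s", out_path),
                   "dl_io_error")
  on.exit(grDevices::dev.off(), add = TRUE)

  zlim <- range(surface$values,
                if (!is.null(comparison)) comparison$values else NULL)
  pmat <- graphics::persp(surface$x, surface$y, surface$values,
                          theta = theta, phi = phi, zlim = zlim,
                          col = col, border = NA, shade = 0.55,
                          ticktype = "detailed",
                          xlab = "x", ylab = "y", zlab = "V(x, y)")
  if (!is.null(comparison)) {
    # overlay as a coarse wireframe so both landscapes stay visible
    step <- max(1L, floor(length(comparison$x) / 25))
    ix <- seq(1, length(comparison$x), by = step)
    iy <- seq(1, length(comparison$y), by = step)
    for (i in ix) {
      pts <- grDevices::trans3d(comparison$x[i], comparison$y[iy],
                                comparison$values[i, iy], pmat)
      graphics::lines(pts, col = comparison_col)
    }
    for (j in iy) {
      pts <- grDevices::trans3d(comparison$x[ix], comparison$y[j],
                                comparison$values[ix, j], pmat)
      graphics::lines(pts, col = comparison_col)
    }
  }
  if (!is.null(trajectories)) {
    if (inherits(trajectories, "dl_trajectory")) {
      trajectories <- list(trajectories)
    }
    for (tr in trajectories) {
      z <- lift_trajectory(surface$params, tr)
      graphics::lines(grDevices::trans3d(tr$xs, tr$ys, z, pmat),
                      col = "firebrick", lwd = 2)
    }
  }
  invisible(out_path)
}
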