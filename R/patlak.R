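#' Patlak plot coordinates
#'
#' Transforms a tissue TAC into Patlak coordinates at the frame mid-times:
#' x(t) = integral(Cp, 0, t) / Cp(t) ("normalized time") and
#' y(t) = C(t) / Cp(t), with the plasma integral exact under the
#' piecewise-linear input representation. For irreversible uptake the points
#' become collinear after an equilibration time t*, with slope Ki and
#' intercept V. Mid-times where Cp <= 0 are excluded with a warning.
#'
#' @param tac_obj A [tac()].
#' @param inp An [input_function()] (metabolite-corrected).
#' @return A data frame with columns `x`, `y`, `mid_time`.
#' @export
patlak_points <- function(tac_obj, inp) {
  mid <- tac_obj$time
  cp <- if_cp(inp, mid)
  keep <- cp > 0
  if (!all(keep))
    warning(sum(!keep), " point(s) excluded: Cp <= 0 at mid-time(s) ",
            paste(signif(mid[!keep], 4), collapse = ", "))
  data.frame(x = if_cp_int(inp, mid[keep]) / cp[keep],
             y = tac_obj$activity[keep] / cp[keep],
             mid_time = mid[keep])
}

# shared OLS core; both patlak_fit and patlak_image go through this exact
# arithmetic so voxelwise maps and per-curve fits agree bitwise
patlak_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx^2)
  slope <- sum(dx * y) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sst <- sum((y - my)^2)
  c(slope = slope, intercept = intercept,
    r2 = if (sst > 0) 1 - sum(res^2) / sst else NaN)
}

#' Patlak graphical fit
#'
#' Ordinary least-squares line through the Patlak points with mid-times in
#' `[t_star, t_max]`; the slope is the net influx rate Ki, the intercept the
#' distribution volume V of free tracer in blood and reversible compartments.
#'
#' @param points Patlak points from [patlak_points()].
#' @param t_star Start of the linear window, min (default 40).
#' @param t_max End of the window, min (default 70).
#' @return An object of class `patlak_fit` with `ki`, `v`, `r_squared`,
#'   `t_star`, `t_max`, `n_points`.
#' @export
patlak_fit <- function(points, t_star = 40, t_max = 70) {
  use <- points$mid_time >= t_star - 1e-9 & points$mid_time <= t_max + 1e-9
  if (sum(use) < 2) stop("need >= 2 Patlak points with mid-time in [",
                         t_star, ", ", t_max, "]")
  o <- patlak_ols(points$x[use], points$y[use])
  structure(list(ki = unname(o["slope"]), v = unname(o["intercept"]),
                 r_squared = unname(o["r2"]), t_star = t_star, t_max = t_max,
                 n_points = sum(use)),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> Ki = %.4g mL/cm3/min, V = %.4g (r2 = %.4f, %d pts, %g-%g min)\n",
              x$ki, x$v, x$r_squared, x$n_points, x$t_star, x$t_max))
  invisible(x)
}

#' Voxelwise Patlak parametric images
#'
#' Runs the Patlak fit in every voxel of a dynamic image (indirect voxelwise
#' Patlak on reconstructed frames), producing Ki, V and r-squared volumes.
#' The Patlak abscissa is shared across voxels, so the per-voxel work reduces
#' to an ordinary least-squares line through that voxel's normalized TAC;
#' the arithmetic is identical to looping [patlak_fit()] over voxels.
#' Voxels whose fit is degenerate get `NaN` so downstream statistics can
#' exclude them explicitly.
#'
#' @param img A [dynamic_image()].
#' @param inp An [input_function()].
#' @param t_star,t_max Patlak window, min (defaults 40 and 70).
#' @return An object of class `parametric_image` with 3D arrays `ki`, `v`,
#'   `r2`, plus `voxel_mm`, `t_star`, `t_max`.
#' @export
patlak_image <- function(img, inp, t_star = 40, t_max = 70) {
  sched <- img$schedule
  mid <- sched$mid
  cp <- if_cp(inp, mid)
  use <- cp > 0 & mid >= t_star - 1e-9 & mid <= t_max + 1e-9
  if (any(cp <= 0 & mid >= t_star - 1e-9 & mid <= t_max + 1e-9))
    warning("frames with Cp <= 0 excluded from the Patlak window")
  if (sum(use) < 2) stop("Patlak window [", t_star, ", ", t_max,
                         "] contains fewer than 2 usable frames")
  x <- (if_cp_int(inp, mid) / cp)[use]
  d <- dim(img$data)
  nvox <- prod(d[1:3])
  Y <- matrix(img$data[, , , use, drop = FALSE], nvox, sum(use))
  Y <- sweep(Y, 2, cp[use], "/")
  ki <- v <- r2 <- numeric(nvox)
  for (i in seq_len(nvox)) {
    o <- patlak_ols(x, Y[i, ])
    ki[i] <- o[1]; v[i] <- o[2]; r2[i] <- o[3]
  }
  bad <- !is.finite(ki)
  ki[bad] <- NaN; v[bad] <- NaN
  structure(list(ki = array(ki, d[1:3]), v = array(v, d[1:3]),
                 r2 = array(r2, d[1:3]), voxel_mm = img$voxel_mm,
                 t_star = t_star, t_max = t_max),
            class = "parametric_image")
}

#' @export
print.parametric_image <- function(x, ...) {
  d <- dim(x$ki)
  cat(sprintf("<parametric_image> Ki/V/r2 %dx%dx%d (%.1f mm), window %g-%g min\n",
              d[1], d[2], d[3], x$voxel_mm, x$t_star, x$t_max))
  invisible(x)
}
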