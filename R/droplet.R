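#' Solvent density field of a sessile cylindrical droplet
#'
#' Container for a time-averaged 2-D solvent density map of a cylindrical
#' (quasi-2-D) droplet resting on a substrate. The grid holds one value per
#' bin of the droplet's cross-section: rows run along the surface normal `z`
#' (ascending, starting at the substrate plane `z0`), columns along the
#' in-plane coordinate `y`. Bin centers are at `z0 + (i - 1/2) * dz` and
#' `y0 + (j - 1) * dy`.
#'
#' @param grid Numeric matrix of densities (any consistent unit, e.g.
#'   amu/nm^3); non-negative.
#' @param dy,dz Bin widths, nm.
#' @param z0 Height of the substrate plane, nm.
#' @param rho_bulk Bulk liquid density, same unit as `grid`.
#' @param y0 `y` coordinate of the first column's bin center, nm.
#' @return An object of class `density_field`.
#' @export
density_field <- function(grid, dy, dz, z0 = 0, rho_bulk, y0 = dy / 2) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop_domain("`grid` must be a numeric matrix.")
  }
  if (anyNA(grid) || any(grid < 0)) {
    stop_domain("`grid` must be non-negative and non-missing.")
  }
  if (!is.numeric(dy) || !is.numeric(dz) || dy <= 0 || dz <= 0) {
    stop_domain("`dy` and `dz` must be positive bin widths in nm.")
  }
  if (!is.numeric(rho_bulk) || rho_bulk <= 0) {
    stop_domain("`rho_bulk` must be positive.")
  }
  structure(
    list(grid = grid, dy = dy, dz = dz, z0 = z0, rho_bulk = rho_bulk,
         y0 = y0),
    class = "density_field"
  )
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field: %d x %d bins (z x y), dy=%g dz=%g nm, z0=%g nm, rho_bulk=%g>\n",
              nrow(x$grid), ncol(x$grid), x$dy, x$dz, x$z0, x$rho_bulk))
  invisible(x)
}

field_y <- function(field) field$y0 + (seq_len(ncol(field$grid)) - 1) * field$dy
field_z <- function(field) field$z0 + (seq_len(nrow(field$grid)) - 0.5) * field$dz

#' @exportS3Method ggplot2::autoplot
autoplot.density_field <- function(object, ...) {
  df <- tibble(
    y = rep(field_y(object), times = nrow(object$grid)),
    z = rep(field_z(object), each = ncol(object$grid)),
    density = as.vector(t(object$grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$z, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y (nm)", y = "z (nm)", fill = "density")
}

#' Locate the liquid–vapor interface of a droplet density field
#'
#' Finds sub-bin points where the density crosses the iso-level
#' `iso_fraction * rho_bulk`, by linear interpolation along every grid edge
#' (horizontal and vertical neighbor pairs) that brackets the level. With the
#' conventional `iso_fraction = 0.5` this is the Gibbs dividing surface of a
#' diffuse interface.
#'
#' @param field A [density_field()].
#' @param iso_fraction Iso-level as a fraction of the bulk density, in (0, 1).
#' @return A tibble with columns `y`, `z` (nm) of interface points.
#' @export
extract_interface <- function(field, iso_fraction = 0.5) {
  stopifnot(inherits(field, "density_field"))
  if (iso_fraction <= 0 || iso_fraction >= 1) {
    stop_domain("`iso_fraction` must lie strictly between 0 and 1.")
  }
  g <- field$grid
  level <- iso_fraction * field$rho_bulk
  y <- field_y(field)
  z <- field_z(field)

  # horizontal edges: neighbors along y within each row
  a <- g[, -ncol(g), drop = FALSE] - level
  b <- g[, -1, drop = FALSE] - level
  hit <- which(a * b < 0, arr.ind = TRUE)
  t_h <- a[hit] / (a[hit] - b[hit])
  pts_h <- tibble(y = y[hit[, 2]] + t_h * field$dy, z = z[hit[, 1]])

  # vertical edges: neighbors along z within each column
  a <- g[-nrow(g), , drop = FALSE] - level
  b <- g[-1, , drop = FALSE] - level
  hit <- which(a * b < 0, arr.ind = TRUE)
  t_v <- a[hit] / (a[hit] - b[hit])
  pts_v <- tibble(y = y[hit[, 2]], z = z[hit[, 1]] + t_v * field$dz)

  pts <- dplyr::bind_rows(pts_h, pts_v)
  if (nrow(pts) == 0) {
    stop_domain("No interface found: no grid edge crosses the iso-level.")
  }
  dplyr::arrange(pts, .data$y, .data$z)
}

#' Least-squares circle through interface points
#'
#' Fits a circle to liquid–vapor interface points by minimizing the mean
#' squared algebraic distance (Kasa fit), optionally followed by a geometric
#' refinement that minimizes the true radial residuals. Points closer to the
#' substrate than `z_excl` are excluded first: solvent layering next to the
#' wall distorts the interface there.
#'
#' @param points Data frame with columns `y` and `z` (nm).
#' @param z0 Substrate-plane height, nm.
#' @param z_excl Exclusion distance above `z0`, nm.
#' @param geometric Run the geometric refinement after the algebraic fit?
#' @return An object of class `circle_fit` with fields `yc`, `zc`, `R`,
#'   `rms_residual` and `n_points`.
#' @export
fit_circle <- function(points, z0 = 0, z_excl = 0.8, geometric = TRUE) {
  if (!is.data.frame(points) || !all(c("y", "z") %in% names(points))) {
    stop_domain("`points` must be a data frame with columns `y` and `z`.")
  }
  pts <- dplyr::filter(points, .data$z > z0 + z_excl)
  if (nrow(pts) < 5) {
    stop_domain(sprintf(
      "Need at least 5 interface points above z0 + z_excl; got %d.", nrow(pts)
    ))
  }
  yv <- pts$y
  zv <- pts$z
  A <- cbind(2 * yv, 2 * zv, 1)
  b <- yv^2 + zv^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol) || qr(A)$rank < 3) {
    stop_domain("Degenerate circle fit: interface points are collinear.")
  }
  yc <- sol[1]
  zc <- sol[2]
  R <- sqrt(sol[3] + yc^2 + zc^2)

  if (geometric) {
    obj <- function(p) {
      r <- sqrt((yv - p[1])^2 + (zv - p[2])^2)
      sum((r - p[3])^2)
    }
    opt <- stats::optim(c(yc, zc, R), obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    yc <- opt$par[1]
    zc <- opt$par[2]
    R <- opt$par[3]
  }
  radial <- sqrt((yv - yc)^2 + (zv - zc)^2)
  structure(
    list(yc = unname(yc), zc = unname(zc), R = unname(R),
         rms_residual = sqrt(mean((radial - R)^2)), n_points = nrow(pts)),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit: center (%.3f, %.3f) nm, R = %.3f nm, rms = %.4f nm, n = %d>\n",
              x$yc, x$zc, x$R, x$rms_residual, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.circle_fit <- function(x, ...) {
  tibble(yc = x$yc, zc = x$zc, R = x$R,
         rms_residual = x$rms_residual, n_points = x$n_points)
}

#' Contact angle of a fitted droplet cross-section
#'
#' Intersects the fitted interface circle with the substrate plane:
#' `cos(theta) = (z0 - zc) / R`, with the angle measured through the liquid.
#' A center on the plane gives 90 degrees; a center below it, a wetting angle
#' under 90 degrees.
#'
#' @param fit A [fit_circle()] result.
#' @param z0 Substrate-plane height, nm.
#' @return A one-row tibble of class `angle_estimate` with columns `theta`
#'   (degrees), `cos_theta`, `R` (nm), `n_points` and `rms_residual`.
#' @export
contact_angle_from_fit <- function(fit, z0 = 0) {
  stopifnot(inherits(fit, "circle_fit"))
  ct <- (z0 - fit$zc) / fit$R
  if (abs(ct) > 1) {
    stop_domain("Detached droplet: the fitted circle does not intersect the substrate plane.")
  }
  out <- tibble(
    theta = acosd(ct),
    cos_theta = ct,
    R = fit$R,
    n_points = fit$n_points,
    rms_residual = fit$rms_residual
  )
  class(out) <- c("angle_estimate", class(out))
  out
}

#' Full droplet analysis pipeline
#'
#' Runs interface extraction, near-wall exclusion, circle fitting and the
#' plane intersection in one call.
#'
#' @inheritParams extract_interface
#' @inheritParams fit_circle
#' @param verbose Log point counts and residuals to stderr?
#' @return A one-row `angle_estimate` tibble (see
#'   [contact_angle_from_fit()]).
#' @examples
#' drop <- make_droplet_field(theta_true = 120, R = 8, seed = 1)
#' analyze_droplet(drop$field)
#' @export
analyze_droplet <- function(field, iso_fraction = 0.5, z_excl = 0.8,
                            geometric = TRUE, verbose = FALSE) {
  pts <- extract_interface(field, iso_fraction)
  fit <- fit_circle(pts, z0 = field$z0, z_excl = z_excl,
                    geometric = geometric)
  est <- contact_angle_from_fit(fit, z0 = field$z0)
  if (verbose) {
    message(sprintf(
      "analyze_droplet: %d interface points (%d used), R = %.3f nm, rms = %.4f nm, theta = %.2f deg",
      nrow(pts), fit$n_points, fit$R, fit$rms_residual, est$theta
    ))
  }
  est
}

#' Extrapolate droplet contact angles to the macroscopic limit
#'
#' Simulated droplets are finite; their measured angle carries a
#' size-dependent bias. For cylindrical droplets the cosine of the contact
#' angle is regressed linearly on the inverse base radius `1/R` and the
#' intercept — the infinite-droplet limit — is converted back to an angle.
#'
#' @param estimates Data frame with columns `theta` (degrees) and `R` (nm),
#'   one row per droplet, e.g. stacked [analyze_droplet()] results.
#' @return An object of class `macro_angle` with the extrapolated angle
#'   (`theta_inf`, degrees), the fitted slope (nm) and the underlying
#'   [stats::lm()] fit; see [tidy()]/[glance()].
#' @examples
#' ests <- tibble::tibble(R = c(5, 8, 12, 16, 20),
#'                        theta = acos(cos(113 * pi / 180) + 0.3 / c(5, 8, 12, 16, 20)) * 180 / pi)
#' extrapolate_macroscopic(ests)
#' @export
extrapolate_macroscopic <- function(estimates) {
  if (!is.data.frame(estimates) || !all(c("theta", "R") %in% names(estimates))) {
    stop_domain("`estimates` must be a data frame with columns `theta` and `R`.")
  }
  if (nrow(estimates) < 2 || length(unique(estimates$R)) < 2) {
    stop_domain("Need at least 2 estimates with distinct radii to extrapolate.")
  }
  df <- tibble(inv_R = 1 / estimates$R, cos_theta = cosd(estimates$theta))
  fit <- lm(cos_theta ~ inv_R, data = df)
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (abs(intercept) > 1) {
    stop_domain(sprintf(
      "Extrapolated cos(theta) = %.4f lies outside [-1, 1]; the 1/R trend does not reach a physical macroscopic angle.",
      intercept
    ))
  }
  structure(
    list(theta_inf = acosd(intercept), cos_theta_inf = intercept,
         slope = slope, n = nrow(estimates), fit = fit,
         data = tibble(R = estimates$R, theta = estimates$theta,
                       inv_R = df$inv_R, cos_theta = df$cos_theta)),
    class = "macro_angle"
  )
}

#' @export
print.macro_angle <- function(x, ...) {
  cat(sprintf("<macro_angle: theta_inf = %.2f degrees (%d droplets, slope %.3f nm)>\n",
              x$theta_inf, x$n, x$slope))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.macro_angle <- function(x, ...) {
  tibble(theta_inf = x$theta_inf, cos_theta_inf = x$cos_theta_inf,
         slope = x$slope, n = x$n)
}

#' @exportS3Method generics::glance
glance.macro_angle <- function(x, ...) {
  s <- summary(x$fit)
  tibble(theta_inf = x$theta_inf, slope = x$slope, n = x$n,
         r_squared = s$r.squared, sigma = s$sigma)
}

#' @exportS3Method ggplot2::autoplot
autoplot.macro_angle <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$inv_R, .data$cos_theta)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$cos_theta_inf,
                         slope = object$slope, linetype = 2) +
    ggplot2::labs(x = expression(1 / R ~ (nm^-1)),
                  y = expression(cos ~ theta))
}
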