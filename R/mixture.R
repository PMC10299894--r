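#' Fit the surface-tension curve of a binary solvent mixture
#'
#' Builds a monotone representation of `gamma(x)`, the liquid–vapor surface
#' tension of a water/organic mixture as a function of organic mole fraction
#' `x`, from tabulated measurements.
#'
#' The default is a shape-preserving monotone piecewise-cubic interpolant
#' (Fritsch–Carlson, via [stats::splinefun()] with `method = "monoH.FC"`),
#' which reproduces every data point exactly and never overshoots between
#' points. A parametric exponential-decay alternative
#' `gamma(x) = g1 + (g0 - g1) * (exp(-k*x) - exp(-k)) / (1 - exp(-k))`
#' is fitted by Levenberg–Marquardt least squares and is the right choice for
#' noisy tables. A plain linear interpolation is also available.
#'
#' Non-monotone tension data are warned about and pre-smoothed by isotonic
#' regression (decreasing) before interpolation.
#'
#' @param data Data frame with numeric columns `x` (mole fraction, strictly
#'   increasing in `[0, 1]`) and `gamma` (surface tension, mN/m).
#' @param method `"monotone"` (default), `"exponential"` or `"linear"`.
#' @param solubility_limit Mole fraction beyond which lipids dissolve and the
#'   two-state adsorption model breaks down; downstream profiles flag (but
#'   still compute) points beyond it.
#' @return A `mixture_curve` object; evaluate it with [predict()].
#' @examples
#' tbl <- tibble::tibble(x = c(0, 0.05, 0.1, 0.2, 0.5, 1),
#'                       gamma = c(72, 55, 46, 36, 27, 22))
#' curve <- fit_mixture_tension(tbl)
#' predict(curve, c(0, 0.1, 1))
#' @export
fit_mixture_tension <- function(data, method = c("monotone", "exponential",
                                                 "linear"),
                                solubility_limit = 0.20) {
  method <- match.arg(method)
  if (!is.data.frame(data) || !all(c("x", "gamma") %in% names(data))) {
    stop_domain("`data` must be a data frame with columns `x` and `gamma`.")
  }
  x <- as.numeric(data$x)
  gamma <- as.numeric(data$gamma)
  if (anyNA(x) || anyNA(gamma)) stop_domain("`x` and `gamma` must be non-missing.")
  if (any(x < 0 | x > 1)) stop_domain("Mole fractions `x` must lie in [0, 1].")
  if (any(diff(x) <= 0)) stop_domain("`x` must be strictly increasing.")
  check_tension(gamma)
  n_min <- if (method == "linear") 2L else 3L
  if (length(x) < n_min) {
    stop_domain(sprintf("At least %d points are required for method \"%s\".",
                        n_min, method))
  }

  if (any(diff(gamma) > 0) && method != "exponential") {
    warn("`gamma` is not non-increasing in `x`; applying isotonic (decreasing) pre-smoothing.")
    iso <- isoreg(x, -gamma)
    gamma <- -iso$yf
  }

  coefs <- NULL
  fun <- switch(method,
    monotone = stats::splinefun(x, gamma, method = "monoH.FC"),
    linear = stats::approxfun(x, gamma, rule = 2),
    exponential = {
      start <- list(g0 = max(gamma), g1 = min(gamma), k = 3)
      fit <- minpack.lm::nlsLM(
        gamma ~ g1 + (g0 - g1) * (exp(-k * x) - exp(-k)) / (1 - exp(-k)),
        data = data.frame(x = x, gamma = gamma),
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      coefs <- coef(fit)
      function(xx) {
        unname(coefs[["g1"]] + (coefs[["g0"]] - coefs[["g1"]]) *
                 (exp(-coefs[["k"]] * xx) - exp(-coefs[["k"]])) /
                 (1 - exp(-coefs[["k"]])))
      }
    }
  )

  structure(
    list(x = x, gamma = gamma, fun = fun, method = method,
         coefs = coefs, solubility_limit = solubility_limit),
    class = "mixture_curve"
  )
}

#' @export
predict.mixture_curve <- function(object, x, ...) {
  if (missing(x)) return(object$fun(object$x))
  object$fun(x)
}

#' @export
print.mixture_curve <- function(x, ...) {
  cat(sprintf("<mixture_curve: %s, %d points, gamma %.1f -> %.1f mN/m, solubility limit %.2f>\n",
              x$method, length(x$x), x$fun(0), x$fun(1), x$solubility_limit))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mixture_curve <- function(x, ...) {
  tibble(
    method = x$method,
    n_points = length(x$x),
    gamma_w = x$fun(0),
    gamma_alc = x$fun(1),
    solubility_limit = x$solubility_limit
  )
}

#' Adsorption contact angle along a solvent-exchange path
#'
#' Re-solves the adsorption-angle condition at each mixture composition,
#' holding the adhesion numerator `2*wsl - wll` solvent-independent (alcohol
#' changes the lipid packing only marginally) while the solvent surface
#' tension follows the fitted `gamma(x)`. As the solvent becomes less polar
#' the threshold angle drops; compositions where the monolayer is favorable
#' at every angle are marked `"always_adsorbs"` with `theta_ads = 0`.
#'
#' @param curve A [fit_mixture_tension()] result.
#' @param model An [adhesion_model()].
#' @param x_grid Mole fractions at which to evaluate; values beyond the
#'   curve's solubility limit are flagged but still computed.
#' @return A tibble of class `theta_ads_profile` with columns `x`, `gamma`,
#'   `theta_ads`, `status` and `beyond_solubility`.
#' @export
theta_ads_profile <- function(curve, model = adhesion_model(),
                              x_grid = seq(0, 0.2, by = 0.01)) {
  stopifnot(inherits(curve, "mixture_curve"))
  if (any(x_grid < 0 | x_grid > 1)) {
    stop_domain("`x_grid` mole fractions must lie in [0, 1].")
  }
  rows <- purrr::map(x_grid, function(xi) {
    g <- curve$fun(xi)
    sol <- solve_adsorption_angle(model, g)
    theta <- switch(sol$status,
      root = sol$theta,
      always_adsorbs = 0,
      NA_real_
    )
    tibble(x = xi, gamma = g, theta_ads = theta, status = sol$status)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(beyond_solubility = .data$x > curve$solubility_limit)
  class(out) <- c("theta_ads_profile", class(out))
  out
}

#' Adsorption free energy along a solvent-exchange path
#'
#' Evaluates the two-state adsorption free energy for one or more real
#' substrates as water is exchanged for the organic solvent. The solvent
#' enters only through the adhesion tension, modeled by the two-endpoint
#' Zisman line of each substrate ([zisman_from_endpoints()]) evaluated at
#' `gamma(x)`; the works of adhesion `wll` and `wsl` are held at their
#' in-water values, with `wsl` evaluated (by default) at the in-water
#' adsorption contact angle. Compositions beyond the solubility limit are
#' flagged `beyond_solubility`: there the two-state model breaks down as
#' lipids dissolve into micelles.
#'
#' @inheritParams theta_ads_profile
#' @param theta_w Water contact angle(s) of the substrate(s), degrees; an
#'   optionally named vector gives one profile per substrate.
#' @param gamma_alc Neat-organic surface tension for the Zisman endpoint,
#'   mN/m.
#' @param theta_eval Angle at which `wsl` is evaluated, degrees; default the
#'   in-water adsorption contact angle.
#' @return A tibble of class `free_energy_profile` with columns `substrate`,
#'   `theta_w`, `x`, `gamma`, `adhesion_tension`, `free_energy` (mN/m) and
#'   `beyond_solubility`.
#' @examples
#' tbl <- tibble::tibble(x = c(0, 0.05, 0.1, 0.2, 0.5, 1),
#'                       gamma = c(72, 55, 46, 36, 27, 22))
#' curve <- fit_mixture_tension(tbl)
#' free_energy_profile(curve, theta_w = c(oxidized_Si = 45, Si = 66, glass = 104))
#' @export
free_energy_profile <- function(curve, theta_w, model = adhesion_model(),
                                gamma_alc = 22,
                                x_grid = seq(0, 0.2, by = 0.01),
                                theta_eval = NULL) {
  stopifnot(inherits(curve, "mixture_curve"))
  check_angle(theta_w, "theta_w")
  check_tension(gamma_alc, "gamma_alc")
  if (any(x_grid < 0 | x_grid > 1)) {
    stop_domain("`x_grid` mole fractions must lie in [0, 1].")
  }
  gamma_w <- curve$fun(0)
  if (is.null(theta_eval)) {
    sol <- solve_adsorption_angle(model, gamma_w)
    theta_eval <- if (sol$status == "root") sol$theta else 90
  }
  wsl <- wsl_at(model, theta_eval)
  labels <- names(theta_w) %||% paste0("theta_w=", format(theta_w))

  out <- purrr::map2(theta_w, labels, function(tw, lab) {
    line <- zisman_from_endpoints(gamma_w, tw, gamma_alc)
    g <- curve$fun(x_grid)
    tibble(
      substrate = lab,
      theta_w = tw,
      x = x_grid,
      gamma = g,
      adhesion_tension = zisman_adhesion_tension(g, line),
      free_energy = model$wll / 2 - wsl +
        zisman_adhesion_tension(g, line)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(beyond_solubility = .data$x > curve$solubility_limit)
  attr(out, "theta_eval") <- theta_eval
  attr(out, "wsl") <- wsl
  class(out) <- c("free_energy_profile", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.theta_ads_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$theta_ads)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$beyond_solubility)) +
    ggplot2::labs(x = "organic mole fraction x",
                  y = "adsorption contact angle (degrees)",
                  shape = "beyond solubility")
}

#' @exportS3Method ggplot2::autoplot
autoplot.free_energy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$free_energy,
                                       colour = .data$substrate)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "organic mole fraction x",
                  y = "adsorption free energy (mN/m)",
                  colour = "substrate")
}
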