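#' Substrate–lipid adhesion model
#'
#' Bundles the two works of adhesion that drive the two-state monolayer
#' adsorption model: the lipid–lipid monolayer work of adhesion in vacuum,
#' `wll`, and a linear law for the substrate–lipid work of adhesion as a
#' function of the substrate's water contact angle,
#' `wsl(theta) = wsl_intercept + wsl_slope * theta`.
#'
#' The default parameters are the simulation-derived anchors for a
#' dilauroyl-phosphatidylcholine (DLPC) monolayer on an alkanol self-assembled
#' monolayer substrate of tunable polarity: `wll = 49` mN/m, and `wsl` running
#' linearly from 57 mN/m on the fully polar substrate (theta = 0 deg) to
#' 52 mN/m on the nonpolar one (theta = 113 deg).
#'
#' @param wll Lipid–lipid monolayer work of adhesion in vacuum, mN/m. Must be
#'   positive.
#' @param wsl_intercept Substrate–lipid work of adhesion at theta = 0 deg, mN/m.
#' @param wsl_slope Change of `wsl` per degree of water contact angle,
#'   mN/m/deg; typically small and negative.
#' @return An object of class `adhesion_model`.
#' @examples
#' m <- adhesion_model()
#' wsl_at(m, c(0, 113))
#' @export
adhesion_model <- function(wll = 49,
                           wsl_intercept = 57,
                           wsl_slope = -5 / 113) {
  check_tension(wll, "wll")
  if (!is.numeric(wsl_intercept) || !is.numeric(wsl_slope) ||
      anyNA(c(wsl_intercept, wsl_slope))) {
    stop_domain("`wsl_intercept` and `wsl_slope` must be numeric.")
  }
  # wsl must stay positive over the whole physical angle range
  ends <- wsl_intercept + wsl_slope * c(0, 180)
  if (any(ends <= 0)) {
    stop_domain("wsl(theta) must be positive for all theta in [0, 180] degrees.")
  }
  structure(
    list(wll = wll, wsl_intercept = wsl_intercept, wsl_slope = wsl_slope),
    class = "adhesion_model"
  )
}

#' @describeIn adhesion_model Construct the model anchored at two printed
#'   `(theta, wsl)` points instead of intercept/slope.
#' @param theta1,w1,theta2,w2 Two `(theta in degrees, wsl in mN/m)` anchor
#'   points; `theta1 != theta2`.
#' @export
adhesion_model_from_points <- function(wll = 49, theta1 = 0, w1 = 57,
                                       theta2 = 113, w2 = 52) {
  if (theta1 == theta2) stop_domain("Anchor angles must differ.")
  slope <- (w2 - w1) / (theta2 - theta1)
  adhesion_model(wll = wll, wsl_intercept = w1 - slope * theta1,
                 wsl_slope = slope)
}

#' @export
print.adhesion_model <- function(x, ...) {
  cat("<adhesion_model>\n")
  cat(sprintf("  wll        : %.3f mN/m\n", x$wll))
  cat(sprintf("  wsl(theta) : %.3f %+.5f * theta  [mN/m, theta in degrees]\n",
              x$wsl_intercept, x$wsl_slope))
  invisible(x)
}

#' Substrate–lipid work of adhesion at a given contact angle
#'
#' Evaluates the linear law `wsl(theta)` of an [adhesion_model()].
#'
#' @param model An [adhesion_model()].
#' @param theta Water contact angle(s), degrees, in `[0, 180]`.
#' @return Work of adhesion in mN/m, vectorized over `theta`.
#' @examples
#' wsl_at(adhesion_model(), 113)
#' @export
wsl_at <- function(model, theta) {
  stopifnot(inherits(model, "adhesion_model"))
  check_angle(theta)
  model$wsl_intercept + model$wsl_slope * theta
}
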