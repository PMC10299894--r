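#' Zisman-type adhesion-tension line
#'
#' Empirical linear ansatz for the adhesion tension of a probe liquid on a
#' fixed substrate, `gamma * cos(theta) = c0 + c1 * gamma`. For a binary
#' water/organic mixture the two coefficients follow from two boundary
#' conditions: neat water (`gamma_w`, contact angle `theta_w`) and the neat
#' organic solvent, which wets well enough that its adhesion tension is its
#' own surface tension `gamma_alc`.
#'
#' @param c0 Intercept, mN/m.
#' @param c1 Dimensionless slope.
#' @return An object of class `zisman_line`.
#' @seealso [zisman_from_endpoints()], [zisman_adhesion_tension()]
#' @export
zisman_line <- function(c0, c1) {
  if (!is.numeric(c0) || !is.numeric(c1) || anyNA(c(c0, c1)) ||
      !all(is.finite(c(c0, c1)))) {
    stop_domain("`c0` and `c1` must be finite numbers.")
  }
  structure(list(c0 = c0, c1 = c1), class = "zisman_line")
}

#' @export
print.zisman_line <- function(x, ...) {
  cat(sprintf("<zisman_line>  gamma*cos(theta) = %.4f %+.5f * gamma  [mN/m]\n",
              x$c0, x$c1))
  invisible(x)
}

#' Build the adhesion-tension line from its two solvent endpoints
#'
#' Pins the line at neat water, where the adhesion tension is
#' `gamma_w * cos(theta_w)`, and at the neat organic solvent, where it equals
#' `gamma_alc`:
#' `c1 = (gamma_w * cos(theta_w) - gamma_alc) / (gamma_w - gamma_alc)` and
#' `c0 = gamma_alc * (1 - c1)`.
#'
#' @param gamma_w Water surface tension, mN/m.
#' @param theta_w Water contact angle on the substrate, degrees.
#' @param gamma_alc Surface tension of the neat organic solvent, mN/m.
#' @return A [zisman_line()].
#' @examples
#' zisman_from_endpoints(72, 104, 22)
#' @export
zisman_from_endpoints <- function(gamma_w = 72, theta_w, gamma_alc = 22) {
  check_tension(gamma_w, "gamma_w")
  check_tension(gamma_alc, "gamma_alc")
  check_angle(theta_w, "theta_w")
  if (gamma_w == gamma_alc) {
    stop_domain("Endpoint tensions are equal: the adhesion-tension line is degenerate.")
  }
  c1 <- (gamma_w * cosd(theta_w) - gamma_alc) / (gamma_w - gamma_alc)
  zisman_line(c0 = gamma_alc * (1 - c1), c1 = c1)
}

#' Adhesion tension of a mixture at a given surface tension
#'
#' Evaluates a [zisman_line()]: `gamma * cos(theta) = c0 + c1 * gamma`. The
#' mixture's surface tension is the only solvent descriptor needed.
#'
#' @param gamma Mixture surface tension(s), mN/m.
#' @param line A [zisman_line()].
#' @return Adhesion tension in mN/m, vectorized over `gamma`.
#' @examples
#' zisman_adhesion_tension(47, zisman_from_endpoints(72, 45, 22))
#' @export
zisman_adhesion_tension <- function(gamma, line) {
  stopifnot(inherits(line, "zisman_line"))
  check_tension(gamma)
  line$c0 + line$c1 * gamma
}

#' Critical water contact angle of a solvent pair
#'
#' The water contact angle at which the adhesion-tension line becomes flat,
#' `cos(theta_wc) = gamma_alc / gamma_w`: on such a substrate the adhesion
#' tension of the mixture is independent of composition. Substrates below
#' `theta_wc` see their adhesion tension decrease on adding the organic
#' solvent; substrates above it see it increase. For water/ethanol
#' (72 and 22 mN/m) the critical angle is about 72 degrees.
#'
#' @inheritParams zisman_from_endpoints
#' @return Angle in degrees.
#' @examples
#' critical_water_angle(72, 22)
#' @export
critical_water_angle <- function(gamma_w = 72, gamma_alc = 22) {
  check_tension(gamma_w, "gamma_w")
  check_tension(gamma_alc, "gamma_alc")
  if (gamma_alc > gamma_w) {
    stop_domain("`gamma_alc` must not exceed `gamma_w` (cosine would exceed 1).")
  }
  acosd(gamma_alc / gamma_w)
}
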