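#' Monolayer adsorption free energy, term by term
#'
#' Free-energy difference per unit monolayer area between a surface-adsorbed
#' lipid monolayer and the bulk bilayer it would otherwise form, for a solid
#' substrate characterized by its water contact angle `theta`:
#'
#' `dF/A = wll/2 - wsl(theta) + gamma * cos(theta)`
#'
#' The three terms are the work of splitting the bilayer into two leaflets
#' across vacuum (`wll/2`), the gain from attaching the monolayer to the dry
#' substrate (`-wsl(theta)`), and the cost of removing the solvent from the
#' substrate, expressed through the Young equation as the solvent adhesion
#' tension (`gamma * cos(theta)`). Negative totals favor the adsorbed
#' monolayer.
#'
#' @param theta Substrate contact angle(s) of the solvent, degrees in
#'   `[0, 180]`.
#' @param model An [adhesion_model()].
#' @param gamma Solvent liquid–vapor surface tension, mN/m.
#' @return A tibble with one row per `theta` and columns `theta`, `term_ll`,
#'   `term_sl`, `term_adhesion`, `total` (all tensions in mN/m).
#' @examples
#' adsorption_free_energy(c(0, 66, 113))
#' @export
adsorption_free_energy <- function(theta, model = adhesion_model(),
                                   gamma = 72) {
  check_angle(theta)
  check_tension(gamma)
  term_ll <- rep(model$wll / 2, length(theta))
  term_sl <- -wsl_at(model, theta)
  term_adhesion <- gamma * cosd(theta)
  tibble(
    theta = theta,
    term_ll = term_ll,
    term_sl = term_sl,
    term_adhesion = term_adhesion,
    total = term_ll + term_sl + term_adhesion
  )
}

# scalar dF/A, used by the root solvers
free_energy_total <- function(theta, model, gamma) {
  model$wll / 2 - wsl_at(model, theta) + gamma * cosd(theta)
}

#' Adsorption contact angle
#'
#' Solves for the threshold contact angle above which the adsorbed monolayer
#' is thermodynamically stable against the bulk bilayer: the root of the
#' adsorption free energy on `[0, 180]` degrees, equivalently the fixed point
#' `cos(theta_ads) = (2 * wsl(theta_ads) - wll) / (2 * gamma)`.
#'
#' Roots are bracketed by a sign-change scan on a 0.1-degree grid and then
#' bisected to a `1e-9` mN/m residual. If the free energy does not change
#' sign, a typed outcome is returned instead of an angle: `"never_adsorbs"`
#' when the monolayer is unfavorable at every angle, `"always_adsorbs"` when
#' it is favorable everywhere. If several sign changes exist the smallest
#' root is returned and `n_roots` flags the multiplicity.
#'
#' @inheritParams adsorption_free_energy
#' @param f_tol Residual tolerance on the free energy at the root, mN/m.
#' @return An `angle_solution` with fields `theta` (degrees, `NA` when there
#'   is no root), `status` (`"root"`, `"never_adsorbs"` or
#'   `"always_adsorbs"`), `n_roots` and `f_root`; see [tidy()] for a tibble
#'   view.
#' @examples
#' solve_adsorption_angle()                # about 66 degrees in neat water
#' solve_adsorption_angle(gamma = 25)      # weaker solvent: smaller angle
#' @export
solve_adsorption_angle <- function(model = adhesion_model(), gamma = 72,
                                   f_tol = 1e-9) {
  check_tension(gamma)
  res <- bisect_angle_root(function(th) free_energy_total(th, model, gamma),
                           f_tol = f_tol)
  status <- switch(res$status,
    all_positive = "never_adsorbs",
    all_negative = "always_adsorbs",
    "root"
  )
  new_angle_solution(res$root, status, res$n_roots, res$f_root,
                     quantity = "adsorption_contact_angle",
                     model = model, gamma = gamma)
}

#' Hydrocarbon-liquid approximation of the adsorption contact angle
#'
#' Treating the lipid tails as a hydrocarbon liquid gives `wll ~ 2*gamma_hc`
#' and `wsl ~ gamma_hc * (1 + cos(theta_hc))`, which collapses the implicit
#' adsorption-angle condition to the closed form
#' `cos(theta_ads) = gamma_hc * cos(theta_hc) / gamma`; with a fully wetting
#' hydrocarbon (`theta_hc = 0`) this is simply the ratio of the two surface
#' tensions. For C10–C18 alkanes (`gamma_hc` = 23–28 mN/m) in water this
#' predicts a threshold of roughly 67–71 degrees.
#'
#' @param gamma_hc Hydrocarbon–vapor surface tension, mN/m.
#' @param gamma Solvent surface tension, mN/m.
#' @param theta_hc Contact angle of the hydrocarbon liquid on the substrate,
#'   degrees; alkanes wet most solids, so the default is 0.
#' @return Adsorption contact angle in degrees.
#' @examples
#' theta_ads_hydrocarbon(28, 72)
#' theta_ads_hydrocarbon(23, 72)
#' @export
theta_ads_hydrocarbon <- function(gamma_hc, gamma = 72, theta_hc = 0) {
  check_tension(gamma_hc, "gamma_hc")
  check_tension(gamma)
  check_angle(theta_hc, "theta_hc")
  ratio <- gamma_hc * cosd(theta_hc) / gamma
  if (ratio <= 0) {
    stop_domain("gamma_hc * cos(theta_hc) must be positive.")
  }
  if (ratio > 1) {
    stop_domain(paste0(
      "gamma_hc * cos(theta_hc) exceeds gamma: no adsorption threshold; ",
      "the surface always lies below hydrocarbon wetting."
    ))
  }
  acosd(ratio)
}

#' Linearized adsorption free energy
#'
#' Around the adsorption angle the substrate–lipid adhesion varies so weakly
#' that `wsl(theta)` can be frozen at `wsl(theta_ads)`, giving the one-line
#' approximation `dF/A ~ gamma * (cos(theta) - cos(theta_ads))`: the
#' adsorption strength then depends on the substrate only through its contact
#' angle.
#'
#' @param theta Substrate contact angle(s), degrees.
#' @param theta_ads Adsorption contact angle, degrees.
#' @param gamma Solvent surface tension, mN/m.
#' @return Approximate free energy per area, mN/m, vectorized over `theta`.
#' @examples
#' linearized_free_energy(0, 65.73, 72)
#' @export
linearized_free_energy <- function(theta, theta_ads, gamma = 72) {
  check_angle(theta)
  check_angle(theta_ads, "theta_ads")
  check_tension(gamma)
  gamma * (cosd(theta) - cosd(theta_ads))
}

#' Monolayer adsorption free energy at the air–water interface
#'
#' The air–water interface is the limiting substrate with `wsl = 0` (air
#' interacts negligibly) and `theta = 180` degrees (a perfect hydrophobic
#' interface), which reduces the adsorption free energy to
#' `dF_air/A = wll/2 - gamma`. A negative value means a full Langmuir
#' monolayer at the interface is preferred over bilayers in the bulk.
#'
#' @param model An [adhesion_model()]; only `wll` is used.
#' @param gamma Liquid–vapor surface tension, mN/m.
#' @return Free energy per area, mN/m.
#' @examples
#' air_water_free_energy()            # -47.5, i.e. -48 mN/m at integer precision
#' air_water_free_energy(gamma = 22)  # positive in neat ethanol
#' @export
air_water_free_energy <- function(model = adhesion_model(), gamma = 72) {
  check_tension(gamma)
  model$wll / 2 - gamma
}

#' Equivalent contact angle of the air–water interface
#'
#' The contact angle `theta*` of a hypothetical solid substrate whose
#' monolayer adsorption free energy equals that of the air–water interface,
#' obtained by equating the two free-energy expressions:
#' `cos(theta*) = wsl(theta*) / gamma - 1`. Solids with contact angles above
#' `theta*` adsorb monolayers more strongly than the free water surface.
#'
#' @inheritParams solve_adsorption_angle
#' @return An `angle_solution`; `status = "no_equivalent_angle"` when the
#'   implicit equation has no root in `[0, 180]` degrees.
#' @examples
#' equivalent_contact_angle()   # about 106-107 degrees
#' @export
equivalent_contact_angle <- function(model = adhesion_model(), gamma = 72,
                                     f_tol = 1e-9) {
  check_tension(gamma)
  # dF(theta) - dF_air, in mN/m: gamma*cos(theta) - wsl(theta) + gamma
  f <- function(th) gamma * cosd(th) - wsl_at(model, th) + gamma
  res <- bisect_angle_root(f, f_tol = f_tol)
  status <- if (res$status == "root") "root" else "no_equivalent_angle"
  new_angle_solution(res$root, status, res$n_roots, res$f_root,
                     quantity = "equivalent_contact_angle",
                     model = model, gamma = gamma)
}

#' Monolayer adsorption free energy in a neat organic solvent
#'
#' Hypothetical limit of solvent exchange in which the adhesion tension has
#' relaxed to the organic solvent's own surface tension
#' (`gamma * cos(theta) -> gamma_alc`):
#' `dF_alc/A = wll/2 - wsl(theta_eval) + gamma_alc`, independent of the
#' substrate contact angle. `wsl` is evaluated by default at the in-water
#' adsorption angle, consistent with its weak (about 10%) variation across
#' the polarity range.
#'
#' @param model An [adhesion_model()].
#' @param gamma_alc Surface tension of the neat organic solvent, mN/m.
#' @param theta_eval Angle (degrees) at which `wsl` is evaluated; defaults to
#'   the in-water adsorption contact angle of `model`.
#' @param gamma_w Water surface tension used to find the default
#'   `theta_eval`, mN/m.
#' @return Free energy per area, mN/m.
#' @examples
#' neat_organic_free_energy()   # about -8 mN/m in neat ethanol
#' @export
neat_organic_free_energy <- function(model = adhesion_model(), gamma_alc = 22,
                                     theta_eval = NULL, gamma_w = 72) {
  check_tension(gamma_alc, "gamma_alc")
  if (is.null(theta_eval)) {
    sol <- solve_adsorption_angle(model, gamma_w)
    if (sol$status != "root") {
      stop_domain(paste0(
        "No in-water adsorption angle to evaluate wsl at (status: ",
        sol$status, "); supply `theta_eval` explicitly."
      ))
    }
    theta_eval <- sol$theta
  }
  check_angle(theta_eval, "theta_eval")
  model$wll / 2 - wsl_at(model, theta_eval) + gamma_alc
}

#' Free-energy decomposition curve versus contact angle
#'
#' Convenience wrapper evaluating [adsorption_free_energy()] on an angle grid
#' and returning it in long format, ready for plotting.
#'
#' @inheritParams adsorption_free_energy
#' @param theta Angle grid, degrees; defaults to 0–180 in 1-degree steps.
#' @return A long tibble with columns `theta`, `component` and `tension`,
#'   of class `free_energy_curve`.
#' @export
free_energy_curve <- function(model = adhesion_model(), gamma = 72,
                              theta = seq(0, 180, by = 1)) {
  out <- adsorption_free_energy(theta, model, gamma) |>
    tidyr::pivot_longer(-"theta", names_to = "component",
                        values_to = "tension")
  class(out) <- c("free_energy_curve", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.free_energy_curve <- function(object, ...) {
  labels <- c(term_ll = "bilayer splitting  w[ll]/2",
              term_sl = "substrate adhesion  -w[sl]",
              term_adhesion = "solvent adhesion  gamma*cos(theta)",
              total = "total  dF/A")
  ggplot2::ggplot(object, ggplot2::aes(.data$theta, .data$tension,
                                       colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = labels[unique(object$component)]) +
    ggplot2::labs(x = "contact angle (degrees)", y = "tension (mN/m)",
                  colour = NULL)
}
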