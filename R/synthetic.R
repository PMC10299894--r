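#' Synthetic sessile-droplet density field
#'
#' Generates the 2-D solvent density map of a cylindrical droplet whose
#' cross-section is a circular cap with a known contact angle, emulating a
#' time-averaged simulation density grid. The cap's circle (radius `R`) is
#' placed so the substrate plane cuts it at the prescribed angle
#' (`zc = z0 - R * cos(theta_true)`), and the liquid–vapor interface is
#' diffuse:
#' `rho(d) = rho_bulk * (1 - tanh(2 * (d - R) / width)) / 2`,
#' with `d` the distance from the circle center. Optional additive Gaussian
#' noise (clamped at zero density) emulates finite sampling.
#'
#' @param theta_true True contact angle, degrees, in (0, 180).
#' @param R Cap circle radius, nm; must be at least `3 * width`.
#' @param width Diffuse-interface width parameter, nm.
#' @param dy,dz Bin widths, nm.
#' @param rho_bulk Bulk liquid density (default: water's molecular number
#'   density, 33.4 nm^-3).
#' @param noise_sd Standard deviation of additive Gaussian density noise.
#' @param seed Integer seed; identical seeds give bit-identical grids.
#' @param pad Vacuum padding around the droplet, nm.
#' @return A list of class `synthetic_droplet`: `field` (a
#'   [density_field()]) and `truth` (theta_true, R, yc, zc, width).
#' @examples
#' drop <- make_droplet_field(theta_true = 90, R = 10)
#' drop$truth$zc   # 0: the center sits on the substrate plane
#' @export
make_droplet_field <- function(theta_true, R, width = 0.4, dy = 0.1,
                               dz = 0.1, rho_bulk = 33.4, noise_sd = 0,
                               seed = NULL, pad = 2) {
  check_angle(theta_true, "theta_true", lower = 1e-6, upper = 180 - 1e-6)
  if (R < 3 * width) stop_domain("`R` must be at least 3 * width.")
  z0 <- 0
  zc <- z0 - R * cosd(theta_true)
  if (zc + R <= z0) stop_domain("Cap lies entirely below the substrate plane.")

  half_y <- (if (theta_true >= 90) R else R * sind(theta_true)) + pad
  z_top <- zc + R + pad
  ny <- ceiling(2 * half_y / dy)
  nz <- ceiling((z_top - z0) / dz)
  y0 <- -half_y + dy / 2
  y <- y0 + (seq_len(ny) - 1) * dy
  z <- z0 + (seq_len(nz) - 0.5) * dz

  d <- sqrt(outer(z - zc, y, function(zz, yy) zz^2 + yy^2))
  grid <- rho_bulk * 0.5 * (1 - tanh(2 * (d - R) / width))
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(grid), sd = noise_sd)
    } else {
      withr::with_seed(seed, stats::rnorm(length(grid), sd = noise_sd))
    }
    grid <- grid + noise
  }
  grid <- pmax(grid, 0)

  structure(
    list(
      field = density_field(grid, dy = dy, dz = dz, z0 = z0,
                            rho_bulk = rho_bulk, y0 = y0),
      truth = list(theta_true = theta_true, R = R, yc = 0, zc = zc,
                   width = width, rho_bulk = rho_bulk, noise_sd = noise_sd,
                   seed = seed)
    ),
    class = "synthetic_droplet"
  )
}

# closed-form w = -0.1 * integral_a^b P dD for the generator forms; the
# antiderivatives vanish at infinity, so b = Inf gives the full tail
analytic_work_window <- function(form, params, a, b) {
  antider <- switch(form,
    nine_three = function(D) {
      params$A * (-params$sigma^9 / (8 * D^8) + params$sigma^3 / (2 * D^2))
    },
    power = function(D) params$C / ((params$n - 1) * D^(params$n - 1))
  )
  -convert_pressure_length(antider(b) - antider(a))
}

#' Synthetic pressure–distance curve with a closed-form work of adhesion
#'
#' Samples an attractive pressure–distance curve whose integral is known
#' analytically, providing an independent oracle for the trapezoid
#' integration in [work_of_adhesion()]. Two forms are available:
#'
#' * `"nine_three"`: `P(D) = A * ((sigma/D)^9 - (sigma/D)^3)`, the wall
#'   analogue of a Lennard-Jones interaction — repulsive core, attractive
#'   van-der-Waals tail, zero crossing at `D = sigma`. The default amplitude
#'   is scaled so the total work of adhesion from contact is 49 mN/m, the
#'   magnitude of a lipid–lipid monolayer adhesion.
#' * `"power"`: a pure attractive tail `P(D) = -C / D^n` (`n > 1`).
#'
#' @param form `"nine_three"` or `"power"`.
#' @param A Amplitude of the nine-three form, bar.
#' @param sigma Zero-crossing distance of the nine-three form, nm.
#' @param C,n Prefactor (bar nm^n) and exponent of the power form.
#' @param D_range Sampled separation range, nm.
#' @param n_points Number of (equally spaced) samples.
#' @param noise_sd Standard deviation of additive Gaussian pressure noise,
#'   bar.
#' @param seed Integer seed for the noise.
#' @param D_contact Contact separation stored on the curve; defaults to
#'   `sigma` for the nine-three form and `D_range[1]` for the power form.
#' @return A list of class `synthetic_pd`: `curve` (a [pd_curve()]) and
#'   `truth` with `analytic_work` (contact to infinity, mN/m),
#'   `analytic_work_window` (contact to the last sample, mN/m) and the
#'   generator parameters.
#' @examples
#' pd <- make_pd_curve(form = "power", C = 1, n = 3, D_range = c(1, 50))
#' pd$truth$analytic_work  # 0.05 mN/m
#' @export
make_pd_curve <- function(form = c("nine_three", "power"),
                          A = 49 / (0.1 * 3 / 8), sigma = 1,
                          C = 1, n = 3,
                          D_range = NULL, n_points = 200,
                          noise_sd = 0, seed = NULL, D_contact = NULL) {
  form <- match.arg(form)
  if (form == "power" && n <= 1 && C != 0) {
    stop_domain("Power-law pressure with exponent n <= 1 is not integrable.")
  }
  if (is.null(D_range)) {
    D_range <- if (form == "nine_three") c(0.9 * sigma, 12 * sigma) else c(1, 20)
  }
  D <- seq(D_range[1], D_range[2], length.out = n_points)
  P <- switch(form,
    nine_three = A * ((sigma / D)^9 - (sigma / D)^3),
    power = -C / D^n
  )
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(P), sd = noise_sd)
    } else {
      withr::with_seed(seed, stats::rnorm(length(P), sd = noise_sd))
    }
    P <- P + noise
  }

  params <- list(A = A, sigma = sigma, C = C, n = n)
  if (is.null(D_contact)) {
    D_contact <- if (form == "nine_three") sigma else D_range[1]
  }
  zero_amp <- (form == "nine_three" && A == 0) || (form == "power" && C == 0)
  truth <- list(
    form = form, params = params, D_contact = D_contact,
    analytic_work = if (zero_amp) 0 else
      analytic_work_window(form, params, D_contact, Inf),
    analytic_work_window = if (zero_amp) 0 else
      analytic_work_window(form, params, max(D_contact, D[1]), D[length(D)]),
    noise_sd = noise_sd, seed = seed
  )
  structure(
    list(curve = pd_curve(D, P, D_contact = D_contact), truth = truth),
    class = "synthetic_pd"
  )
}

mixture_gamma_fun <- function(gamma_w, gamma_alc, shape, k, beta) {
  switch(shape,
    linear = function(x) gamma_w + x * (gamma_alc - gamma_w),
    exponential = function(x) {
      gamma_alc + (gamma_w - gamma_alc) *
        (exp(-k * x) - exp(-k)) / (1 - exp(-k))
    },
    stretched = function(x) {
      gamma_alc + (gamma_w - gamma_alc) *
        (exp(-k * x^beta) - exp(-k)) / (1 - exp(-k))
    }
  )
}

#' Synthetic binary-mixture tension and wetting tables
#'
#' Emulates the tabulated data a solvent-exchange analysis starts from: the
#' surface tension of a water/organic mixture versus organic mole fraction,
#' `gamma(x)`, monotonically decreasing from `gamma_w` to `gamma_alc`, and —
#' for each requested substrate — the cosine of the mixture contact angle
#' derived from the two-endpoint adhesion-tension line
#' ([zisman_from_endpoints()]). Optional Gaussian noise is added to both
#' tables; the exact generating curves are returned as the truth record.
#'
#' @param gamma_w,gamma_alc Endpoint surface tensions, mN/m
#'   (`gamma_alc < gamma_w`).
#' @param shape `"exponential"` (default; fast initial drop, as in
#'   water/ethanol), `"stretched"` or `"linear"`.
#' @param k Decay rate of the exponential shapes.
#' @param beta Stretching exponent of the `"stretched"` shape.
#' @param n_points Number of compositions, equally spaced on `[0, 1]`.
#' @param theta_w Water contact angles of the substrates, degrees (named
#'   vector for labels).
#' @param noise_sd Gaussian noise standard deviations: on `gamma` (mN/m) and,
#'   scaled by `1/gamma`, on `cos_theta`.
#' @param seed Integer seed.
#' @return A list of class `synthetic_mixture`: `tension` (tibble `x`,
#'   `gamma`), `wetting` (tibble `x`, `substrate`, `theta_w`, `gamma`,
#'   `cos_theta`) and `truth` (generator parameters, the exact `gamma_fun`,
#'   and the per-substrate Zisman coefficients).
#' @export
make_mixture_table <- function(gamma_w = 72, gamma_alc = 22,
                               shape = c("exponential", "stretched", "linear"),
                               k = 4, beta = 0.6, n_points = 21,
                               theta_w = c(45, 66, 104), noise_sd = 0,
                               seed = NULL) {
  shape <- match.arg(shape)
  check_tension(gamma_w, "gamma_w")
  check_tension(gamma_alc, "gamma_alc")
  if (gamma_alc >= gamma_w) stop_domain("`gamma_alc` must be below `gamma_w`.")
  check_angle(theta_w, "theta_w")

  gfun <- mixture_gamma_fun(gamma_w, gamma_alc, shape, k, beta)
  x <- seq(0, 1, length.out = n_points)
  g_true <- gfun(x)

  labels <- names(theta_w) %||% paste0("theta_w=", format(theta_w))
  lines <- purrr::map(theta_w, ~zisman_from_endpoints(gamma_w, .x, gamma_alc))
  names(lines) <- labels

  build <- function() {
    g_obs <- g_true + if (noise_sd > 0) stats::rnorm(n_points, sd = noise_sd) else 0
    wet <- purrr::map2(theta_w, labels, function(tw, lab) {
      line <- lines[[lab]]
      ct <- zisman_adhesion_tension(g_true, line) / g_true
      if (noise_sd > 0) ct <- ct + stats::rnorm(n_points, sd = noise_sd / g_true)
      tibble(x = x, substrate = lab, theta_w = tw, gamma = g_true,
             cos_theta = pmin(1, pmax(-1, ct)))
    })
    list(tension = tibble(x = x, gamma = g_obs),
         wetting = dplyr::bind_rows(wet))
  }
  tabs <- if (is.null(seed)) build() else withr::with_seed(seed, build())

  structure(
    list(
      tension = tabs$tension,
      wetting = tabs$wetting,
      truth = list(gamma_w = gamma_w, gamma_alc = gamma_alc, shape = shape,
                   k = k, beta = beta, gamma_fun = gfun,
                   zisman = purrr::map(lines, ~tibble(c0 = .x$c0, c1 = .x$c1)),
                   theta_w = theta_w, noise_sd = noise_sd, seed = seed)
    ),
    class = "synthetic_mixture"
  )
}
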