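# shared fixtures

# exact points on a circle arc (angles in radians, measured from +y axis)
circle_points <- function(yc, zc, R, t = seq(0.1, pi - 0.1, length.out = 60)) {
  tibble::tibble(y = yc + R * cos(t), z = zc + R * sin(t))
}

# independent fixed-point iteration for the implicit adsorption-angle
# condition cos(theta) = (2 * wsl(theta) - wll) / (2 * gamma); converges
# because wsl varies far more slowly than the cosine
fixed_point_theta_ads <- function(model, gamma, theta0 = 90, tol = 1e-10,
                                  max_iter = 10000) {
  th <- theta0
  for (i in seq_len(max_iter)) {
    arg <- (2 * wsl_at(model, th) - model$wll) / (2 * gamma)
    if (abs(arg) > 1) return(NA_real_)
    th_new <- acos(arg) * 180 / pi
    if (abs(th_new - th) < tol) return(th_new)
    th <- th_new
  }
  th
}

# six-point monotone mixture tension table used across solvent tests
mixture_table_6pt <- tibble::tibble(
  x = c(0, 0.05, 0.1, 0.2, 0.5, 1),
  gamma = c(72, 55, 46, 36, 27, 22)
)
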