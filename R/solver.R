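# Deterministic, derivative-free root finding on an angular interval.
#
# Sign changes are located on a fixed 0.1-degree scan grid, then each bracket
# is collapsed by bisection until the function value is below `f_tol`.  The
# scan grid doubles as the uniqueness diagnostic: the number of sign changes
# is reported alongside the smallest root.
bisect_angle_root <- function(f, lower = 0, upper = 180,
                              f_tol = 1e-9, grid_step = 0.1,
                              max_iter = 200L) {
  grid <- seq(lower, upper, by = grid_step)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  fg <- vapply(grid, f, numeric(1))

  exact <- which(fg == 0)
  sgn <- sign(fg)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  n_roots <- length(cross) + length(exact)

  if (n_roots == 0L) {
    status <- if (all(fg > 0)) "all_positive" else "all_negative"
    return(list(root = NA_real_, status = status, n_roots = 0L,
                f_root = NA_real_))
  }

  if (length(exact) && (!length(cross) || grid[exact[1]] < grid[cross[1]])) {
    return(list(root = grid[exact[1]], status = "root", n_roots = n_roots,
                f_root = 0))
  }

  a <- grid[cross[1]]
  b <- grid[cross[1] + 1L]
  fa <- fg[cross[1]]
  for (i in seq_len(max_iter)) {
    m <- (a + b) / 2
    fm <- f(m)
    if (abs(fm) < f_tol) {
      return(list(root = m, status = "root", n_roots = n_roots, f_root = fm))
    }
    if (sign(fm) == sign(fa)) {
      a <- m
      fa <- fm
    } else {
      b <- m
    }
  }
  m <- (a + b) / 2
  list(root = m, status = "root", n_roots = n_roots, f_root = f(m))
}

new_angle_solution <- function(theta, status, n_roots, f_root, quantity,
                               model, gamma) {
  structure(
    list(theta = theta, status = status, n_roots = n_roots,
         f_root = f_root, quantity = quantity, model = model, gamma = gamma),
    class = "angle_solution"
  )
}

#' @export
print.angle_solution <- function(x, ...) {
  cat(sprintf("<angle_solution: %s>\n", x$quantity))
  if (x$status == "root") {
    cat(sprintf("  theta      : %.4f degrees (%d deg at integer precision)\n",
                x$theta, round_half_away(x$theta)))
    cat(sprintf("  |residual| : %.3g mN/m\n", abs(x$f_root)))
    if (x$n_roots > 1L) {
      cat(sprintf("  note       : %d sign changes on [0,180]; smallest root reported\n",
                  x$n_roots))
    }
  } else {
    cat(sprintf("  status     : %s\n", x$status))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.angle_solution <- function(x, ...) {
  tibble(
    quantity = x$quantity,
    theta = x$theta,
    theta_int = if (is.na(x$theta)) NA_real_ else round_half_away(x$theta),
    status = x$status,
    n_roots = x$n_roots,
    residual = x$f_root
  )
}
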