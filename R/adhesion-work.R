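#' Pressure–distance curve between two separating surfaces
#'
#' Container for the interaction pressure `P(D)` recorded while two condensed
#' surfaces (two bilayer leaflets, or a monolayer and a substrate) are
#' reversibly separated. Negative pressure means attraction; `D` is the
#' surface separation.
#'
#' @param D Separations, nm, strictly increasing, length >= 3.
#' @param P Interaction pressures, bar; same length as `D`.
#' @param D_contact Lower integration bound (equilibrium contact
#'   separation), nm; `NULL` to auto-detect at integration time (zero
#'   crossing of `P` nearest the minimum of the running integral).
#' @return A tibble of class `pd_curve` with columns `D` and `P` and a
#'   `D_contact` attribute.
#' @export
pd_curve <- function(D, P, D_contact = NULL) {
  if (length(D) != length(P) || length(D) < 3) {
    stop_domain("`D` and `P` must have equal length >= 3.")
  }
  if (anyNA(D) || anyNA(P)) stop_domain("`D` and `P` must be non-missing.")
  if (any(diff(D) <= 0)) stop_domain("`D` must be strictly increasing.")
  if (!is.null(D_contact) && (D_contact < D[1] || D_contact > D[length(D)])) {
    stop_domain("`D_contact` must lie within the sampled range of `D`.")
  }
  out <- tibble(D = as.numeric(D), P = as.numeric(P))
  attr(out, "D_contact") <- D_contact
  class(out) <- c("pd_curve", class(out))
  out
}

#' Convert a pressure–length product to a surface tension
#'
#' Unit bookkeeping for pressure–distance integrals:
#' 1 bar nm = 1e5 Pa * 1e-9 m = 1e-4 J/m^2 = 0.1 mN/m.
#'
#' @param value Value(s) in bar nm.
#' @return Value(s) in mN/m.
#' @examples
#' convert_pressure_length(-490)  # -49 mN/m
#' @export
convert_pressure_length <- function(value) {
  value * 0.1
}

# D_contact heuristic: the running integral of P is most negative where
# adhesion is complete; the physically meaningful lower bound is the zero
# crossing of P nearest that point (equilibrium contact).
auto_d_contact <- function(D, P) {
  run <- pracma::cumtrapz(D, P)
  d_min <- D[which.min(run)]
  s <- sign(P)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) == 0) return(D[1])
  crossings <- vapply(idx, function(i) {
    D[i] + (0 - P[i]) * (D[i + 1] - D[i]) / (P[i + 1] - P[i])
  }, numeric(1))
  crossings <- c(crossings, D[P == 0])
  crossings[which.min(abs(crossings - d_min))]
}

# fit P ~ -C / D^n on the outermost points (log-log least squares)
fit_power_tail <- function(D, P, n_fit) {
  idx <- utils::tail(seq_along(D), n_fit)
  Dt <- D[idx]
  Pt <- P[idx]
  if (any(Pt >= 0)) {
    stop_domain("Power-law tail fit requires the outermost pressures to be attractive (P < 0).")
  }
  fit <- lm(log(-Pt) ~ log(Dt))
  n <- -unname(coef(fit)[2])
  C <- exp(unname(coef(fit)[1]))
  if (n <= 1) {
    stop_domain(sprintf(
      "Fitted tail exponent n = %.3f is not integrable (need n > 1).", n
    ))
  }
  list(C = C, n = n)
}

#' Work of adhesion from a pressure–distance curve
#'
#' Integrates the interaction pressure from the contact separation outward,
#' `w = -integral(P dD)`, so that a purely attractive curve (negative
#' pressures) yields a positive work of adhesion. The sampled part is
#' integrated by the trapezoid rule; beyond the last sample an optional
#' power-law tail `P ~ -C / D^n` (fitted to the outermost quartile of
#' points, at least 4) is integrated analytically to infinity, which matters
#' for slowly decaying van-der-Waals tails. Input pressures are in bar and
#' distances in nm; the result is converted to mN/m (1 bar nm = 0.1 mN/m).
#'
#' @param curve A [pd_curve()] (or any data frame with columns `D` in nm and
#'   `P` in bar).
#' @param tail `"none"` or `"power"`.
#' @param d_contact Lower integration bound, nm; `"auto"` (default) uses the
#'   curve's `D_contact` attribute if set, otherwise the zero crossing of
#'   `P` nearest the minimum of the running integral.
#' @param n_tail_points Number of outermost points used for the tail fit.
#' @return A one-row tibble of class `adhesion_work` with columns `work`,
#'   `work_core`, `work_tail` (mN/m), `d_contact` (nm), `tail_exponent`,
#'   `tail_prefactor` and `n_points`.
#' @examples
#' pd <- make_pd_curve(form = "power", C = 1, n = 3, D_range = c(1, 50),
#'                     n_points = 400)
#' work_of_adhesion(pd$curve, tail = "power")
#' @export
work_of_adhesion <- function(curve, tail = c("none", "power"),
                             d_contact = "auto", n_tail_points = NULL) {
  tail <- match.arg(tail)
  if (!is.data.frame(curve) || !all(c("D", "P") %in% names(curve))) {
    stop_domain("`curve` must have columns `D` and `P`.")
  }
  D <- curve$D
  P <- curve$P
  if (any(diff(D) <= 0)) stop_domain("`D` must be strictly increasing.")

  if (identical(d_contact, "auto")) {
    d_contact <- attr(curve, "D_contact") %||% auto_d_contact(D, P)
  }
  if (d_contact < D[1] || d_contact >= D[length(D)]) {
    stop_domain("`d_contact` must lie within the sampled range of `D`.")
  }

  # clip the curve at d_contact, interpolating the pressure there
  keep <- D > d_contact
  Dc <- c(d_contact, D[keep])
  Pc <- c(stats::approx(D, P, xout = d_contact)$y, P[keep])

  work_core <- -convert_pressure_length(pracma::trapz(Dc, Pc))

  work_tail <- 0
  tail_C <- NA_real_
  tail_n <- NA_real_
  if (tail == "power") {
    n_fit <- n_tail_points %||% max(4L, ceiling(length(D) / 4))
    if (sum(keep) < n_fit) {
      stop_domain("Not enough points beyond `d_contact` for the tail fit.")
    }
    tf <- fit_power_tail(D, P, n_fit)
    tail_C <- tf$C
    tail_n <- tf$n
    D_max <- D[length(D)]
    # -integral_{Dmax}^{inf} (-C/D^n) dD = C / ((n-1) Dmax^(n-1))
    work_tail <- convert_pressure_length(tail_C / ((tail_n - 1) * D_max^(tail_n - 1)))
  }

  out <- tibble(
    work = work_core + work_tail,
    work_core = work_core,
    work_tail = work_tail,
    d_contact = d_contact,
    tail_exponent = tail_n,
    tail_prefactor = tail_C,
    n_points = length(Dc)
  )
  class(out) <- c("adhesion_work", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.pd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$D, .data$P)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "separation D (nm)", y = "pressure P (bar)")
}
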