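#' Hill-type odorant activation
#'
#' Fraction of odorant receptors activated at a log10 dilution `x`. With the
#' half-activating dilution written as \eqn{10^{k_{od}}}, the Hill function
#' in dilution units reduces to
#' \deqn{f(x) = \frac{1}{1 + 10^{\,n (k_{od} - x)}},}
#' so the undiluted stock concentration cancels and only the log10 offset
#' \eqn{k_{od} - x} matters.
#'
#' @param x log10 odorant dilution (vectorized; `-Inf` means no odorant).
#' @param k_od log10 half-activation dilution of the ORN.
#' @param n Hill coefficient (> 0).
#' @return Activation fraction in \[0, 1\], same length as `x`.
#' @examples
#' activation_fraction(-5.9, k_od = -5.9, n = 0.7) # exactly 1/2
#' @export
activation_fraction <- function(x, k_od, n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    abort("`n` must be a single positive number.", class = "sensillum_domain_error")
  }
  if (!is.numeric(k_od) || any(is.na(k_od)) || any(k_od == Inf) || any(k_od == -Inf)) {
    abort("`k_od` must be finite.", class = "sensillum_domain_error")
  }
  if (!is.numeric(x) || any(is.na(x))) {
    abort("`x` must be numeric and non-missing.", class = "sensillum_domain_error")
  }
  # x = +/-Inf are meaningful limits (saturation / no odorant)
  1 / (1 + 10^(n * (k_od - x)))
}

#' Activation-induced dendritic conductance gain
#'
#' Scales the receptor-activation fraction to the conductance gain `g` that
#' divides the dendritic membrane resistivity: \eqn{g = g_{max} f}.
#'
#' @param fraction Activation fraction in \[0, 1\] (vectorized).
#' @param g_max Maximal conductance gain (\eqn{\ge 0}).
#' @return Conductance gain in \[0, `g_max`\].
#' @export
conductance_gain <- function(fraction, g_max) {
  if (!is.numeric(g_max) || length(g_max) != 1L || !is.finite(g_max) || g_max < 0) {
    abort("`g_max` must be a single non-negative number.",
          class = "sensillum_domain_error")
  }
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    abort("`fraction` must lie in [0, 1].", class = "sensillum_domain_error")
  }
  g_max * fraction
}

#' Somatic input resistance from soma surface area
#'
#' The somatic input resistance is inversely proportional to soma surface:
#' \eqn{R_{in} = \rho_s / A_s}. All resistances are rescaled by the
#' auxiliary-cell resistance \eqn{R_A} (set to 1), so the result is
#' dimensionless.
#'
#' @param A_s Soma surface area, \eqn{\mu m^2} (> 0, vectorized).
#' @param rho_s Soma membrane resistivity, \eqn{\mu m^2}.
#' @return Dimensionless input resistance.
#' @export
input_resistance <- function(A_s, rho_s) {
  if (any(!is.finite(A_s)) || any(A_s <= 0)) {
    abort("`A_s` must be positive.", class = "sensillum_domain_error")
  }
  if (!is.numeric(rho_s) || length(rho_s) != 1L || !is.finite(rho_s) || rho_s <= 0) {
    abort("`rho_s` must be a single positive number.",
          class = "sensillum_domain_error")
  }
  rho_s / A_s
}

#' Dendritic resistance under odorant activation
#'
#' Receptor activation adds membrane conductance, dividing the basal
#' dendritic resistivity: \eqn{R_d = \rho_{d,0} / (A_d (1 + g))}. At `g = 0`
#' this is the basal dendritic resistance; as `g` grows the dendrite shunts.
#'
#' @param A_d Outer-dendrite surface area, \eqn{\mu m^2} (> 0).
#' @param rho_d0 Basal dendritic membrane resistivity, \eqn{\mu m^2}.
#' @param g Conductance gain (\eqn{\ge 0}, vectorized).
#' @return Dimensionless dendritic resistance.
#' @export
dendritic_resistance <- function(A_d, rho_d0, g = 0) {
  if (any(!is.finite(A_d)) || any(A_d <= 0)) {
    abort("`A_d` must be positive.", class = "sensillum_domain_error")
  }
  if (!is.numeric(rho_d0) || length(rho_d0) != 1L || !is.finite(rho_d0) || rho_d0 <= 0) {
    abort("`rho_d0` must be a single positive number.",
          class = "sensillum_domain_error")
  }
  if (any(is.na(g)) || any(g < 0)) {
    abort("`g` must be non-negative.", class = "sensillum_domain_error")
  }
  rho_d0 / (A_d * (1 + g))
}

#' Input resistance of a finite leaky cable
#'
#' Exact input resistance of a uniform leaky cylinder with one open and one
#' sealed end, from linear cable theory:
#' \deqn{R_d = \sqrt{r_m r_a}\,\coth\!\left(L \sqrt{r_a / r_m}\right),}
#' where \eqn{l = L\sqrt{r_a/r_m}} is the electrotonic length and
#' \eqn{R_\infty = \sqrt{r_m r_a}} the semi-infinite input resistance. For
#' electrotonically short dendrites (\eqn{l \ll 1}) this reduces to
#' \eqn{r_m / L}, i.e. resistivity over membrane area — the approximation
#' used by [dendritic_resistance()]. Provided to validate that
#' approximation.
#'
#' @param r_m Membrane resistance (per unit length form), > 0.
#' @param r_a Axial (cytoplasmic) resistivity, > 0.
#' @param L Cable length, > 0.
#' @return List with `R_d` (exact input resistance), `l` (electrotonic
#'   length), `R_inf`, and `R_short` (the short-cable approximation
#'   \eqn{r_m/L}).
#' @examples
#' cable_input_resistance(r_m = 1, r_a = 1, L = 1)$R_d # coth(1)
#' @export
cable_input_resistance <- function(r_m, r_a, L) {
  for (v in list(r_m = r_m, r_a = r_a, L = L)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort("`r_m`, `r_a` and `L` must be single positive numbers.",
            class = "sensillum_domain_error")
    }
  }
  l <- L * sqrt(r_a / r_m)
  R_inf <- sqrt(r_m * r_a)
  list(R_d = R_inf / tanh(l), l = l, R_inf = R_inf, R_short = r_m / L)
}

#' Lateral surface area of a cylinder from volume and length
#'
#' Outer dendrites reconstructed from volume-EM are treated as cylinders;
#' their membrane surface is recovered from measured volume and length:
#' \eqn{r = \sqrt{V / (\pi L)}}, \eqn{A = 2 \pi r L = 2\sqrt{\pi V L}}.
#'
#' @param volume Segment volume, \eqn{\mu m^3} (> 0, vectorized).
#' @param length Segment length, \eqn{\mu m} (> 0).
#' @return Lateral surface area, \eqn{\mu m^2}.
#' @examples
#' cylinder_lateral_area(pi, 1) # unit-radius cylinder: 2*pi
#' @export
cylinder_lateral_area <- function(volume, length) {
  if (any(!is.finite(volume)) || any(volume <= 0) ||
      any(!is.finite(length)) || any(length <= 0)) {
    abort("`volume` and `length` must be positive.",
          class = "sensillum_domain_error")
  }
  2 * sqrt(pi * volume * length)
}
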