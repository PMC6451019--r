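#' Build and calibrate a two-ORN sensillum circuit
#'
#' The sensillum is modeled as three Thevenin branches meeting at the shared
#' lymph node: the auxiliary cell (battery \eqn{E_A}, resistance
#' \eqn{R_A \equiv 1} after rescaling) and two ORNs, each a somatic battery
#' \eqn{E_i} behind the somatic input resistance \eqn{R_{in,i}} and the
#' stimulus-dependent dendritic resistance \eqn{R_{d,i}}. The somatic
#' batteries are not free: they are calibrated so that, with no odorant
#' (`g1 = g2 = 0`), both membrane potentials equal the common resting
#' potential \eqn{V_0}.
#'
#' `calibrate_resting()` performs that calibration by solving the resting
#' Kirchhoff system jointly with the two constraints
#' \eqn{V_{m1} = V_{m2} = V_0} (a 6-by-6 linear system), and cross-checks
#' the result against the closed-form expressions for the resting currents
#' and batteries (the \eqn{\xi_0, \Theta_0, \alpha_i, \beta_i}
#' intermediates, stored in `$resting`). Disagreement beyond 1e-6 mV is an
#' internal error, guarding against sign-convention drift.
#'
#' `sensillum_model()` is a convenience wrapper that looks a sensillum up in
#' a reference table (default: [default_orn_params()]) and calibrates it.
#'
#' @param common A [common_params()] object.
#' @param orn1,orn2 [orn_spec()] objects with `A_d` set; by convention
#'   `orn1` is the larger "A" (large-spike) neuron.
#' @return An object of class `sensillum_model`: the inputs plus the derived
#'   batteries `E_1`, `E_2` (mV), basal resistances, and the closed-form
#'   resting intermediates in `$resting`.
#' @examples
#' m <- sensillum_model("ab4")
#' c(m$E_1, m$E_2)
#' @export
calibrate_resting <- function(common, orn1, orn2) {
  stopifnot(inherits(common, "common_params"),
            inherits(orn1, "orn_spec"), inherits(orn2, "orn_spec"))
  if (is.na(orn1$A_d) || is.na(orn2$A_d)) {
    abort("Both ORNs need `A_d` set before calibration.",
          class = "sensillum_calibration_error")
  }
  R_in1 <- input_resistance(orn1$A_s, common$rho_s)
  R_in2 <- input_resistance(orn2$A_s, common$rho_s)
  R_d1 <- dendritic_resistance(orn1$A_d, common$rho_d0, 0)
  R_d2 <- dendritic_resistance(orn2$A_d, common$rho_d0, 0)
  R_1 <- R_in1 + R_d1
  R_2 <- R_in2 + R_d2

  # canonical: resting Kirchhoff system + the two membrane-potential
  # constraints, unknowns (V_A, I_A, I_1, I_2, E_1, E_2)
  A <- rbind(
    c(1, -1, 0, 0, 0, 0),        # V_A - I_A R_A        = E_A
    c(1, 0, -R_1, 0, -1, 0),     # V_A - I_1 R_1 - E_1  = 0
    c(1, 0, 0, -R_2, 0, -1),     # V_A - I_2 R_2 - E_2  = 0
    c(0, 1, 1, 1, 0, 0),         # I_A + I_1 + I_2      = 0
    c(0, 0, R_in1, 0, 1, 0),     # E_1 + R_in1 I_1      = V_0
    c(0, 0, 0, R_in2, 0, 1)      # E_2 + R_in2 I_2      = V_0
  )
  b <- c(common$E_A, 0, 0, 0, common$V_0, common$V_0)
  s <- tryCatch(solve(A, b), error = function(e) {
    abort("Resting calibration system is singular for these parameters.",
          class = "sensillum_calibration_error", parent = e)
  })
  names(s) <- c("V_A", "I_A", "I_1", "I_2", "E_1", "E_2")

  # closed-form cross-check
  cf <- .resting_closed_form(common, R_in1, R_in2, R_1, R_2)
  dev <- max(abs(cf$E_1 - s[["E_1"]]), abs(cf$E_2 - s[["E_2"]]))
  if (!is.finite(dev) || dev > 1e-6) {
    abort(sprintf(
      "Internal error: closed-form resting batteries deviate from the constrained solve by %.3g mV.",
      dev), class = "sensillum_internal_error")
  }
  if (cf$Theta_0 <= 0) {
    abort("Calibration infeasible: non-positive resting scale factor.",
          class = "sensillum_calibration_error")
  }

  structure(list(
    common = common, orn1 = orn1, orn2 = orn2,
    E_1 = s[["E_1"]], E_2 = s[["E_2"]], R_A = 1,
    R_in1 = R_in1, R_in2 = R_in2, R_d1_0 = R_d1, R_d2_0 = R_d2,
    R_1_0 = R_1, R_2_0 = R_2,
    resting = c(cf, list(V_A = s[["V_A"]], I_A = s[["I_A"]],
                         I_1 = s[["I_1"]], I_2 = s[["I_2"]]))
  ), class = "sensillum_model")
}

# Closed-form resting currents and batteries from the two-constraint
# reduction of the Kirchhoff system (R_A = 1 throughout).
.resting_closed_form <- function(common, R_in1, R_in2, R_1, R_2) {
  D <- R_1 * R_2 + R_1 + R_2
  alpha_1 <- (1 + R_2 / 2) / D
  beta_1 <- R_2 / D
  alpha_2 <- (1 + R_1 / 2) / D
  beta_2 <- R_1 / D
  xi_0 <- (R_in1 * beta_1 - R_in2 * beta_2) /
    (1 - R_in1 * alpha_1 - R_in2 * alpha_2)
  Theta_0 <- 1 / (1 - 0.5 * (R_in1 * (xi_0 * alpha_1 + beta_1) +
                             R_in2 * (-xi_0 * alpha_2 + beta_2)))
  dv <- common$E_A - common$V_0
  list(
    xi_0 = xi_0, Theta_0 = Theta_0,
    alpha_1 = alpha_1, alpha_2 = alpha_2, beta_1 = beta_1, beta_2 = beta_2,
    E_1 = common$E_A - dv * Theta_0 * (1 + xi_0 / 2),
    E_2 = common$E_A - dv * Theta_0 * (1 - xi_0 / 2),
    I_A_cf = -dv * Theta_0 * (xi_0 * (alpha_1 - alpha_2) + beta_1 + beta_2),
    I_1_cf = dv * Theta_0 * (xi_0 * alpha_1 + beta_1),
    I_2_cf = dv * Theta_0 * (-xi_0 * alpha_2 + beta_2)
  )
}

#' @param sensillum Sensillum name present in `orn_table` (e.g. `"ab4"`).
#' @param orn_table Reference table in the format of [default_orn_params()].
#' @rdname calibrate_resting
#' @export
sensillum_model <- function(sensillum = "ab4", common = common_params(),
                            orn_table = default_orn_params()) {
  rows <- orn_table[orn_table$sensillum == sensillum, , drop = FALSE]
  if (nrow(rows) != 2L) {
    abort(sprintf("Sensillum '%s' not found (or not exactly 2 ORNs) in `orn_table`.",
                  sensillum), class = "sensillum_param_error")
  }
  rows <- rows[order(rows$orn), ]
  mk <- function(i) orn_spec(rows$label[i], rows$A_s[i], rows$A_d[i],
                             rows$k_od[i], rows$A_d_is_measured[i])
  m <- calibrate_resting(common, mk(1L), mk(2L))
  m$sensillum <- sensillum
  m
}

#' @export
print.sensillum_model <- function(x, ...) {
  cat(sprintf("<sensillum_model> %s / %s\n", x$orn1$label, x$orn2$label))
  cat(sprintf("  calibrated batteries: E_1 = %.3f mV, E_2 = %.3f mV\n",
              x$E_1, x$E_2))
  cat(sprintf("  basal resistances (R_A = 1): R_1 = %.4f, R_2 = %.4f\n",
              x$R_1_0, x$R_2_0))
  cat(sprintf("  resting V_A = %.3f mV, V_m = %g mV (both ORNs)\n",
              x$resting$V_A, x$common$V_0))
  invisible(x)
}

#' Solve the sensillum circuit at given activation levels
#'
#' Computes the steady-state transepithelial potential \eqn{V_A}, membrane
#' potentials \eqn{V_{m1}, V_{m2}} and branch currents for conductance
#' gains `g1`, `g2` (or log10 dilutions `x1`, `x2`, mapped through the
#' Hill activation of each ORN). Two routes are implemented: the
#' closed-form Thevenin solution for the currents and, as an independent
#' check, a direct solve of the four Kirchhoff equations; they agree to
#' machine precision.
#'
#' Currents are in mV per unit \eqn{R_A} (arbitrary units) and satisfy
#' \eqn{I_A + I_1 + I_2 = 0}; with the calibrated model and the reference
#' parameters, the resting \eqn{V_A} comes out negative — a consequence of
#' the published battery/resistivity values, reproduced as given.
#'
#' @param model A calibrated [sensillum_model()].
#' @param g1,g2 Conductance gains of ORN1/ORN2, each in \[0, `g_max`\]
#'   (vectorized, recycled to common length).
#' @param x1,x2 Alternatively, log10 odorant dilutions, converted with each
#'   ORN's `k_od`; use `-Inf` for "no stimulus". Overrides `g1`/`g2`.
#' @param method `"closed_form"` (default) or `"direct"`.
#' @return A tibble, one row per stimulus, with columns `g1`, `g2`, `V_A`,
#'   `V_m1`, `V_m2` (mV), `I_A`, `I_1`, `I_2` (arbitrary units), and the
#'   resistances in effect (`R_1`, `R_2`, `R_in1`, `R_in2`, `R_d1`, `R_d2`).
#' @examples
#' m <- sensillum_model("ab4")
#' solve_circuit(m)                     # resting state
#' solve_circuit(m, g1 = 10)            # ORN1 (ab4A) saturated
#' @export
solve_circuit <- function(model, g1 = 0, g2 = 0, x1 = NULL, x2 = NULL,
                          method = c("closed_form", "direct")) {
  stopifnot(inherits(model, "sensillum_model"))
  method <- match.arg(method)
  cm <- model$common
  if (!is.null(x1)) {
    if (is.na(model$orn1$k_od)) abort("`x1` given but orn1 has no k_od.",
                                      class = "sensillum_param_error")
    g1 <- conductance_gain(activation_fraction(x1, model$orn1$k_od, cm$n),
                           cm$g_max)
  }
  if (!is.null(x2)) {
    if (is.na(model$orn2$k_od)) abort("`x2` given but orn2 has no k_od.",
                                      class = "sensillum_param_error")
    g2 <- conductance_gain(activation_fraction(x2, model$orn2$k_od, cm$n),
                           cm$g_max)
  }
  nn <- max(length(g1), length(g2))
  g1 <- rep_len(g1, nn); g2 <- rep_len(g2, nn)
  if (any(g1 < 0) || any(g2 < 0)) {
    abort("Conductance gains must be non-negative.",
          class = "sensillum_domain_error")
  }
  R_d1 <- dendritic_resistance(model$orn1$A_d, cm$rho_d0, g1)
  R_d2 <- dendritic_resistance(model$orn2$A_d, cm$rho_d0, g2)
  R_1 <- model$R_in1 + R_d1
  R_2 <- model$R_in2 + R_d2

  if (method == "closed_form") {
    w1 <- R_2 / (R_1 + R_2)
    w2 <- R_1 / (R_1 + R_2)
    E_T <- model$E_1 * w1 + model$E_2 * w2
    R_T <- R_1 * R_2 / (R_1 + R_2)
    I_A <- (E_T - cm$E_A) / (R_T + model$R_A)
    I_1 <- (model$E_2 - model$E_1) / (R_1 + R_2) - I_A * w1
    I_2 <- (model$E_1 - model$E_2) / (R_1 + R_2) - I_A * w2
    V_A <- cm$E_A + I_A * model$R_A
  } else {
    sol <- vapply(seq_len(nn), function(i) {
      M <- rbind(c(1, -model$R_A, 0, 0),
                 c(1, 0, -R_1[i], 0),
                 c(1, 0, 0, -R_2[i]),
                 c(0, 1, 1, 1))
      tryCatch(solve(M, c(cm$E_A, model$E_1, model$E_2, 0)),
               error = function(e) {
                 abort("Singular circuit system.",
                       class = "sensillum_numeric_error", parent = e)
               })
    }, numeric(4L))
    V_A <- sol[1L, ]; I_A <- sol[2L, ]; I_1 <- sol[3L, ]; I_2 <- sol[4L, ]
  }

  tibble::tibble(
    g1 = g1, g2 = g2,
    V_A = V_A,
    V_m1 = model$E_1 + model$R_in1 * I_1,
    V_m2 = model$E_2 + model$R_in2 * I_2,
    I_A = I_A, I_1 = I_1, I_2 = I_2,
    R_1 = R_1, R_2 = R_2,
    R_in1 = model$R_in1, R_in2 = model$R_in2,
    R_d1 = R_d1, R_d2 = R_d2
  )
}

#' Linearized membrane-potential changes for a given LFP deflection
#'
#' When one ORN is stimulated, its neighbor's total resistance stays fixed,
#' so both membrane-potential changes are exactly linear in the
#' transepithelial deflection \eqn{\Delta V_A}. With ORN1 stimulated:
#' \deqn{\Delta V_{m1} = -\Delta V_A\, R_{in1} (1 + 1/R_2), \qquad
#'       \Delta V_{m2} = \Delta V_A\, R_{in2} / R_2,}
#' and symmetrically when ORN2 is stimulated. The stimulated neuron
#' depolarizes while \eqn{V_A} drops; the neighbor's change follows the
#' sign of \eqn{\Delta V_A} — the ephaptic hyperpolarization.
#'
#' @param delta_VA Change in transepithelial potential, mV (vectorized;
#'   negative on activation under this model's sign convention).
#' @param model A calibrated [sensillum_model()].
#' @param stimulated Which ORN is stimulated, `1` or `2`.
#' @param g_neighbor Conductance gain at which the neighbor is held
#'   (default 0: basal).
#' @return A tibble with columns `delta_VA`, `dVm_stimulated`,
#'   `dVm_neighbor` (mV).
#' @export
ephaptic_delta_vm <- function(delta_VA, model, stimulated = 1,
                              g_neighbor = 0) {
  stopifnot(inherits(model, "sensillum_model"), stimulated %in% c(1, 2))
  cm <- model$common
  if (stimulated == 1) {
    R_nb <- model$R_in2 + dendritic_resistance(model$orn2$A_d, cm$rho_d0,
                                               g_neighbor)
    dVm_s <- -delta_VA * model$R_in1 * (1 + 1 / R_nb)
    dVm_n <- delta_VA * model$R_in2 / R_nb
  } else {
    R_nb <- model$R_in1 + dendritic_resistance(model$orn1$A_d, cm$rho_d0,
                                               g_neighbor)
    dVm_s <- -delta_VA * model$R_in2 * (1 + 1 / R_nb)
    dVm_n <- delta_VA * model$R_in1 / R_nb
  }
  tibble::tibble(delta_VA = delta_VA, dVm_stimulated = dVm_s,
                 dVm_neighbor = dVm_n)
}

#' Predicted spike/LFP slope ratio of a sensillum pair
#'
#' The passive model predicts that each ORN's depolarization is linear in
#' the LFP with slope \eqn{R_{in,i}(1 + 1/R_{j,0})}. Taking firing rate as
#' a proxy for depolarization, the ratio of the B neuron's slope to the A
#' neuron's is
#' \deqn{r = \frac{R_{in2}(1 + 1/R_{1,0})}{R_{in1}(1 + 1/R_{2,0})},}
#' evaluated at basal resistances. For the typical geometry (A larger than
#' B) this exceeds 1: the larger neuron has the shallower spike-per-LFP
#' slope.
#'
#' @param model A calibrated [sensillum_model()].
#' @return The dimensionless slope ratio `r`.
#' @examples
#' spike_lfp_ratio(sensillum_model("ab4"))
#' @export
spike_lfp_ratio <- function(model) {
  stopifnot(inherits(model, "sensillum_model"))
  if (model$R_1_0 <= 0 || model$R_2_0 <= 0) {
    abort("Basal resistances must be positive.",
          class = "sensillum_domain_error")
  }
  (model$R_in2 * (1 + 1 / model$R_1_0)) /
    (model$R_in1 * (1 + 1 / model$R_2_0))
}

#' Dendritic surface of ORN1 implied by a spike/LFP slope ratio
#'
#' Inverts the spike/LFP ratio relation to express ORN1's basal total
#' resistance, and hence its dendritic surface, in terms of the measured
#' ratio `r` and ORN2's geometry:
#' \deqn{R_{1,0} = \frac{R_{2,0}}{r\kappa + R_{2,0}(r\kappa - 1)},\quad
#'       \kappa = R_{in1}/R_{in2},\qquad
#'       A_{d1} = \rho_{d,0}\,(R_{1,0} - R_{in1})^{-1}.}
#' Used when dendritic surfaces are unavailable from morphometry: `A_d2`
#' and `r` are fitted and `A_d1` follows. Feeding the result back into
#' [spike_lfp_ratio()] reproduces `r` exactly.
#'
#' @param r Spike/LFP slope ratio (B over A), > 0.
#' @param orn1 [orn_spec()] for ORN1 (only `A_s` is used).
#' @param orn2 [orn_spec()] for ORN2 with `A_d` set.
#' @param common A [common_params()] object.
#' @return ORN1's dendritic surface area `A_d1`, \eqn{\mu m^2}.
#' @examples
#' p <- default_params()$sensilla$ab4
#' r <- spike_lfp_ratio(sensillum_model("ab4"))
#' dendrite_area_from_ratio(r, p$orn1, p$orn2, common_params()) # = 38
#' @export
dendrite_area_from_ratio <- function(r, orn1, orn2, common) {
  stopifnot(inherits(orn1, "orn_spec"), inherits(orn2, "orn_spec"),
            inherits(common, "common_params"))
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    abort("`r` must be a single positive number.",
          class = "sensillum_domain_error")
  }
  if (is.na(orn2$A_d)) {
    abort("ORN2 needs `A_d` set.", class = "sensillum_param_error")
  }
  R_in1 <- input_resistance(orn1$A_s, common$rho_s)
  R_in2 <- input_resistance(orn2$A_s, common$rho_s)
  R_2_0 <- R_in2 + dendritic_resistance(orn2$A_d, common$rho_d0, 0)
  kappa <- R_in1 / R_in2
  den <- r * kappa + R_2_0 * (r * kappa - 1)
  if (den <= 0) {
    abort("Non-physical parameters: ratio relation has no positive solution.",
          class = "sensillum_nonphysical_error")
  }
  R_1_0 <- R_2_0 / den
  if (R_1_0 <= R_in1) {
    abort("Non-physical parameters: implied total resistance does not exceed the somatic input resistance.",
          class = "sensillum_nonphysical_error")
  }
  common$rho_d0 / (R_1_0 - R_in1)
}
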