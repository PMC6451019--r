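#' Dose-response curve of one ORN, with optional neighbor background
#'
#' Sweeps the stimulated ORN's odorant concentration over a log10-dilution
#' grid while the neighbor is held at a constant background activation
#' fraction, and reports the LFP response and both membrane potentials.
#' Responses are changes from the background-only steady state (the
#' baseline is re-zeroed at the background condition), and the LFP is
#' reported as \eqn{|\Delta V_A|}, matching how peak LFP deflections are
#' read off extracellular recordings.
#'
#' @param model A calibrated [sensillum_model()].
#' @param stimulated Which ORN is swept, `1` (the "A" neuron) or `2`.
#' @param x_grid log10 dilutions to evaluate (default −10 to 0 by 0.25;
#'   append `Inf` for the saturation limit).
#' @param background_fraction Activation fraction of the neighbor,
#'   in \[0, 1\].
#' @return A tibble of class `sensillum_dose_response` with columns
#'   `orn_label`, `background`, `x`, `lfp_mV` (\eqn{|\Delta V_A|}),
#'   `vm_active_mV`, `vm_neighbor_mV`, `dVm_active_mV`, `dVm_neighbor_mV`.
#' @examples
#' m <- sensillum_model("ab4")
#' dose_response(m, 1, x_grid = c(-8, -6, -4, Inf))
#' @export
dose_response <- function(model, stimulated = 1,
                          x_grid = seq(-10, 0, by = 0.25),
                          background_fraction = 0) {
  stopifnot(inherits(model, "sensillum_model"), stimulated %in% c(1, 2))
  if (length(x_grid) == 0L) {
    abort("`x_grid` must be non-empty.", class = "sensillum_domain_error")
  }
  if (background_fraction < 0 || background_fraction > 1) {
    abort("`background_fraction` must lie in [0, 1].",
          class = "sensillum_domain_error")
  }
  cm <- model$common
  g_bg <- conductance_gain(background_fraction, cm$g_max)
  orn_s <- if (stimulated == 1) model$orn1 else model$orn2
  if (is.na(orn_s$k_od)) {
    abort(sprintf("%s has no odorant sensitivity k_od.", orn_s$label),
          class = "sensillum_param_error")
  }
  g_s <- conductance_gain(activation_fraction(x_grid, orn_s$k_od, cm$n),
                          cm$g_max)
  if (stimulated == 1) {
    base <- solve_circuit(model, g1 = 0, g2 = g_bg)
    sol <- solve_circuit(model, g1 = g_s, g2 = g_bg)
    vm_a <- sol$V_m1; vm_n <- sol$V_m2
    vm_a0 <- base$V_m1; vm_n0 <- base$V_m2
  } else {
    base <- solve_circuit(model, g1 = g_bg, g2 = 0)
    sol <- solve_circuit(model, g1 = g_bg, g2 = g_s)
    vm_a <- sol$V_m2; vm_n <- sol$V_m1
    vm_a0 <- base$V_m2; vm_n0 <- base$V_m1
  }
  out <- tibble::tibble(
    orn_label = orn_s$label,
    background = background_fraction,
    x = x_grid,
    lfp_mV = abs(sol$V_A - base$V_A),
    vm_active_mV = vm_a,
    vm_neighbor_mV = vm_n,
    dVm_active_mV = vm_a - vm_a0,
    dVm_neighbor_mV = vm_n - vm_n0
  )
  class(out) <- c("sensillum_dose_response", class(out))
  out
}

#' Saturating LFP response of one ORN
#'
#' The plateau of the dose-response curve: the LFP deflection when the
#' stimulated ORN's activation fraction reaches 1 (the infinite-dose
#' limit), relative to the background-only baseline.
#'
#' @inheritParams dose_response
#' @return The saturating \eqn{|\Delta V_A|}, mV.
#' @examples
#' saturating_lfp(sensillum_model("ab4"), 1) # ab4A plateau
#' @export
saturating_lfp <- function(model, stimulated = 1, background_fraction = 0) {
  dr <- dose_response(model, stimulated, x_grid = Inf, background_fraction)
  dr$lfp_mV[1L]
}

#' Membrane depolarization versus LFP response
#'
#' Pairs each LFP response along a concentration sweep with the stimulated
#' ORN's membrane-potential change. Because the neighbor's resistance is
#' fixed during single-ORN stimulation, the relation is exactly linear with
#' slope \eqn{R_{in}(1 + 1/R_{neighbor,0})} — the quantity the measured
#' spike/LFP slope is taken to reflect.
#'
#' @inheritParams dose_response
#' @return A tibble with columns `orn_label`, `x`, `lfp_mV`,
#'   `dVm_active_mV`, plus attribute `slope` (the analytic
#'   \eqn{|\Delta V_m| / |\Delta V_A|} coefficient).
#' @export
depolarization_vs_lfp <- function(model, stimulated = 1,
                                  x_grid = seq(-10, 0, by = 0.25)) {
  dr <- dose_response(model, stimulated, x_grid, background_fraction = 0)
  R_nb <- if (stimulated == 1) model$R_2_0 else model$R_1_0
  R_in <- if (stimulated == 1) model$R_in1 else model$R_in2
  out <- tibble::tibble(orn_label = dr$orn_label, x = dr$x,
                        lfp_mV = dr$lfp_mV, dVm_active_mV = dr$dVm_active_mV)
  attr(out, "slope") <- R_in * (1 + 1 / R_nb)
  out
}

#' Ephaptic-inhibition asymmetry between the two ORNs
#'
#' Quantifies how strongly each ORN's activation hyperpolarizes its
#' neighbor: for each direction (ORN1 active, ORN2 active) and each
#' neighbor background level, the maximal (saturating) membrane-potential
#' changes are computed and summarized as the ratio
#' \eqn{|\Delta V_{m,neighbor}| / |\Delta V_{m,active}|}. A larger ratio
#' means stronger ephaptic inhibition exerted by the active neuron. For
#' size-asymmetric pairs the larger ORN inhibits its neighbor more
#' effectively than the reverse.
#'
#' @param model A calibrated [sensillum_model()].
#' @param background_levels Neighbor activation fractions to evaluate.
#' @return A tibble with one row per (stimulated ORN, background):
#'   `stimulated`, `orn_label`, `background`, `dVm_active_max_mV`,
#'   `dVm_neighbor_max_mV`, `ratio_neighbor_over_active`.
#' @examples
#' asymmetry_report(sensillum_model("ab4"))
#' @export
asymmetry_report <- function(model, background_levels = c(0, 0.5)) {
  stopifnot(inherits(model, "sensillum_model"))
  grid <- tidyr::expand_grid(stimulated = c(1L, 2L),
                             background = background_levels)
  purrr::pmap_dfr(grid, function(stimulated, background) {
    dr <- dose_response(model, stimulated, x_grid = Inf,
                        background_fraction = background)
    tibble::tibble(
      stimulated = stimulated,
      orn_label = dr$orn_label,
      background = background,
      dVm_active_max_mV = dr$dVm_active_mV,
      dVm_neighbor_max_mV = dr$dVm_neighbor_mV,
      ratio_neighbor_over_active = abs(dr$dVm_neighbor_mV) /
        abs(dr$dVm_active_mV)
    )
  })
}

#' Sublinearity of the LFP response to a binary odorant mixture
#'
#' In the shared-lymph circuit, two simultaneously active ORNs partially
#' shunt each other, so the mixture LFP falls short of the sum of the
#' single-odorant LFPs. The deficit
#' \deqn{(|\Delta V_A(x_1)| + |\Delta V_A(x_2)|) - |\Delta V_A(x_1, x_2)|}
#' measures the magnitude of ephaptic inhibition; it is non-negative for
#' this passive model and zero when either stimulus is absent.
#'
#' @param model A calibrated [sensillum_model()].
#' @param x1,x2 log10 dilutions of the two private odorants (use `Inf` for
#'   saturation, `-Inf` for none).
#' @return A one-row tibble with `lfp_orn1_mV`, `lfp_orn2_mV`,
#'   `lfp_joint_mV`, `linear_sum_mV`, `deficit_mV`.
#' @examples
#' mixture_linearity_deficit(sensillum_model("ab4"), Inf, Inf)
#' @export
mixture_linearity_deficit <- function(model, x1, x2) {
  stopifnot(inherits(model, "sensillum_model"))
  base <- solve_circuit(model, 0, 0)
  s1 <- solve_circuit(model, x1 = x1, x2 = -Inf)
  s2 <- solve_circuit(model, x1 = -Inf, x2 = x2)
  s12 <- solve_circuit(model, x1 = x1, x2 = x2)
  l1 <- abs(s1$V_A - base$V_A)
  l2 <- abs(s2$V_A - base$V_A)
  l12 <- abs(s12$V_A - base$V_A)
  tibble::tibble(lfp_orn1_mV = l1, lfp_orn2_mV = l2, lfp_joint_mV = l12,
                 linear_sum_mV = l1 + l2, deficit_mV = l1 + l2 - l12)
}

#' Shared-receptor scenario: size effect isolated from sensitivity
#'
#' Simulates both ORNs of a pair under the assumption that they express the
#' same odorant receptor (identical `k_od`), so any difference between
#' their dose-response curves reflects morphometry alone. For a
#' size-asymmetric pair the larger neuron still produces the larger
#' saturating LFP and the shallower \eqn{\Delta V_m}-per-LFP slope: the
#' plateau depends only on geometry and `g_max`, not on `k_od`, which
#' merely translates the curves along the dilution axis.
#'
#' @param model A calibrated [sensillum_model()].
#' @param shared_k_od The common log10 sensitivity given to both ORNs.
#' @param x_grid log10 dilutions to evaluate.
#' @return A tibble: both ORNs' dose-response curves (stacked, as in
#'   [dose_response()]) computed with the shared sensitivity.
#' @export
same_receptor_scenario <- function(model, shared_k_od,
                                   x_grid = seq(-10, 0, by = 0.25)) {
  stopifnot(inherits(model, "sensillum_model"))
  o1 <- model$orn1; o1$k_od <- shared_k_od
  o2 <- model$orn2; o2$k_od <- shared_k_od
  m2 <- calibrate_resting(model$common, o1, o2)
  dplyr::bind_rows(
    dose_response(m2, 1, x_grid),
    dose_response(m2, 2, x_grid)
  )
}
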