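test_that("dose-response curves are nonnegative, monotone, and saturate at oracle plateaus", {
  sat <- list(ab3 = c(16.92254, 13.02839),
              ab4 = c(17.6432, 12.28186),
              ab5 = c(19.00983, 19.29264)) # frozen direct-solve oracle values
  for (sn in names(sat)) {
    m <- ref_model(sn)
    for (side in 1:2) {
      dr <- dose_response(m, side, x_grid = c(seq(-10, 0, by = 0.5), Inf))
      expect_true(all(dr$lfp_mV >= 0))
      expect_true(all(diff(dr$lfp_mV) >= -1e-12))
      expect_equal(dr$lfp_mV[nrow(dr)], sat[[sn]][side], tolerance = 1e-5)
    }
  }
  # plateau ordering: A > B for ab3/ab4; near-equal (< 2%) for ab5
  expect_gt(sat$ab3[1], sat$ab3[2])
  expect_gt(sat$ab4[1], sat$ab4[2])
  expect_lt(abs(sat$ab5[1] - sat$ab5[2]) / max(unlist(sat["ab5"])), 0.02)
  expect_equal(saturating_lfp(ref_model("ab4"), 1), 17.6432,
               tolerance = 1e-5)
  expect_error(dose_response(ref_model("ab4"), 1, x_grid = numeric(0)),
               class = "sensillum_domain_error")
})

test_that("background activation of the neighbor shrinks the stimulated ORN's plateau", {
  m <- ref_model("ab4")
  # frozen oracle: ab4A plateau drops from 17.64 to 11.32 under 50% background
  expect_equal(saturating_lfp(m, 1, background_fraction = 0.5), 11.31837,
               tolerance = 1e-5)
  plateaus <- vapply(seq(0, 1, by = 0.25), function(b)
    saturating_lfp(m, 1, background_fraction = b), numeric(1))
  expect_true(all(diff(plateaus) < 0))
})

test_that("neighbor hyperpolarizes whenever one ORN is activated", {
  for (sn in c("ab3", "ab4", "ab5")) {
    m <- ref_model(sn)
    for (side in 1:2) {
      dr <- dose_response(m, side, x_grid = seq(-9, 0, by = 0.5))
      active <- dr$lfp_mV > 1e-6
      expect_true(all(dr$dVm_neighbor_mV[active] < 0))
      expect_true(all(dr$dVm_active_mV[active] > 0))
    }
  }
})

test_that("depolarization is linear in the LFP with the analytic slope", {
  m <- ref_model("ab4")
  dvA <- depolarization_vs_lfp(m, 1, x_grid = seq(-9, -3, by = 0.5))
  slopesA <- dvA$dVm_active_mV[-1] / dvA$lfp_mV[-1]
  expect_lt(diff(range(slopesA)), 1e-9)
  expect_equal(attr(dvA, "slope"), 0.4217356, tolerance = 1e-6)
  expect_equal(slopesA[1], attr(dvA, "slope"), tolerance = 1e-9)
  dvB <- depolarization_vs_lfp(m, 2, x_grid = seq(-6, 0, by = 0.5))
  expect_equal(attr(dvB, "slope"), 0.4 * (1 + 137 / 30 / (1 + 137 * 17 / (30 * 38))),
               tolerance = 1e-9) # R_in2 (1 + 1/R_{1,0}) = 1.0003
  # slope ratio B/A equals the spike/LFP ratio
  expect_equal(attr(dvB, "slope") / attr(dvA, "slope"), spike_lfp_ratio(m),
               tolerance = 1e-9)
})

test_that("ephaptic inhibition is asymmetric toward the smaller neuron", {
  rep4 <- asymmetry_report(ref_model("ab4"))
  r_A0 <- rep4$ratio_neighbor_over_active[rep4$stimulated == 1 &
                                          rep4$background == 0]
  r_B0 <- rep4$ratio_neighbor_over_active[rep4$stimulated == 2 &
                                          rep4$background == 0]
  expect_equal(r_A0, 0.87821, tolerance = 1e-4)
  expect_equal(r_B0, 0.32853, tolerance = 1e-4)
  # A's inhibition of B is stronger in both background conditions
  for (b in c(0, 0.5)) {
    rA <- rep4$ratio_neighbor_over_active[rep4$stimulated == 1 &
                                          rep4$background == b]
    rB <- rep4$ratio_neighbor_over_active[rep4$stimulated == 2 &
                                          rep4$background == b]
    expect_gt(rA, rB)
  }
  # symmetric pair: equal ratios in both directions
  o <- orn_spec("twin", 80, 22, -4)
  reps <- asymmetry_report(calibrate_resting(common_params(), o, o))
  sym <- tidyr::pivot_wider(reps[, c("stimulated", "background",
                                     "ratio_neighbor_over_active")],
                            names_from = "stimulated",
                            values_from = "ratio_neighbor_over_active")
  expect_equal(sym$`1`, sym$`2`, tolerance = 1e-9)
})

test_that("mixture responses are sublinear by the shared-lymph deficit", {
  m <- ref_model("ab4")
  d <- mixture_linearity_deficit(m, Inf, Inf)
  expect_equal(d$linear_sum_mV, 17.6432 + 12.28186, tolerance = 1e-5)
  expect_equal(d$lfp_joint_mV, 22.69408, tolerance = 1e-5)
  expect_equal(d$deficit_mV, 7.23098, tolerance = 1e-4)
  # absent second stimulus: no deficit
  expect_equal(mixture_linearity_deficit(m, Inf, -Inf)$deficit_mV, 0,
               tolerance = 1e-12)
  # deficit grows with the second odorant's concentration
  defs <- vapply(c(-6, -4, -2, 0, Inf), function(x2)
    mixture_linearity_deficit(m, Inf, x2)$deficit_mV, numeric(1))
  expect_true(all(diff(defs) > 0))
  expect_true(all(defs >= 0))
})

test_that("with a shared receptor, size alone sets plateaus and slopes", {
  m <- ref_model("ab4")
  sc <- same_receptor_scenario(m, shared_k_od = -4.5,
                               x_grid = c(seq(-8, 0, by = 0.5), Inf))
  pA <- max(sc$lfp_mV[sc$orn_label == "ab4A"])
  pB <- max(sc$lfp_mV[sc$orn_label == "ab4B"])
  # plateaus are sensitivity-independent: same as the private-odorant values
  expect_equal(pA, 17.6432, tolerance = 1e-5)
  expect_equal(pB, 12.28186, tolerance = 1e-5)
  expect_gt(pA, pB)
  # shifting the shared sensitivity translates curves without moving plateaus
  sc2 <- same_receptor_scenario(m, shared_k_od = -6.5,
                                x_grid = c(seq(-10, -2, by = 0.5), Inf))
  iA <- sc$orn_label == "ab4A" & is.finite(sc$x)
  iA2 <- sc2$orn_label == "ab4A" & is.finite(sc2$x)
  expect_equal(sc$lfp_mV[iA], sc2$lfp_mV[iA2], tolerance = 1e-9)
  # identical geometry + shared sensitivity: identical curves
  o <- orn_spec("twin", 80, 22, -4)
  mt <- calibrate_resting(common_params(), o, o)
  st <- same_receptor_scenario(mt, -4, x_grid = seq(-8, 0))
  half <- nrow(st) / 2
  expect_equal(st$lfp_mV[seq_len(half)], st$lfp_mV[half + seq_len(half)],
               tolerance = 1e-12)
})

test_that("size asymmetry orders plateaus and depolarization slopes", {
  cm <- common_params()
  big <- orn_spec("big", A_s = 120, A_d = 40, k_od = -4)
  small <- orn_spec("small", A_s = 60, A_d = 15, k_od = -4)
  m <- calibrate_resting(cm, big, small)
  expect_gt(saturating_lfp(m, 1), saturating_lfp(m, 2))
  sA <- attr(depolarization_vs_lfp(m, 1, x_grid = c(-5, -4)), "slope")
  sB <- attr(depolarization_vs_lfp(m, 2, x_grid = c(-5, -4)), "slope")
  expect_lt(sA, sB)
})
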