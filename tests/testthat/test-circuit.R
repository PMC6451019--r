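test_that("resting calibration pins both membrane potentials at V_0", {
  for (sn in c("ab3", "ab4", "ab5")) {
    m <- ref_model(sn)
    rest <- solve_circuit(m, 0, 0)
    expect_lt(abs(rest$V_m1 - (-60)), 1e-9)
    expect_lt(abs(rest$V_m2 - (-60)), 1e-9)
    # batteries match the independent constrained-solve oracle
    g <- ref_geom[[sn]]
    cal <- oracle_calibrate(77, -60, 30 / g$A_s1, 30 / g$A_s2,
                            30 / g$A_s1 + 17 / g$A_d1,
                            30 / g$A_s2 + 17 / g$A_d2)
    expect_equal(m$E_1, cal$E_1, tolerance = 1e-9)
    expect_equal(m$E_2, cal$E_2, tolerance = 1e-9)
  }
  # frozen oracle values
  m4 <- ref_model("ab4")
  expect_equal(m4$E_1, -74.25, tolerance = 1e-6)
  expect_equal(m4$E_2, -77.125, tolerance = 1e-6)
  m5 <- ref_model("ab5")
  expect_equal(m5$E_1, -82.18623, tolerance = 1e-5)
  expect_equal(m5$E_2, -81.52396, tolerance = 1e-5)
})

test_that("identical ORNs calibrate symmetrically", {
  o <- orn_spec("twin", A_s = 80, A_d = 22, k_od = -4)
  m <- calibrate_resting(common_params(), o, o)
  expect_equal(m$E_1, m$E_2, tolerance = 1e-12)
  expect_equal(m$resting$xi_0, 0, tolerance = 1e-12)
  expect_equal(spike_lfp_ratio(m), 1, tolerance = 1e-12)
})

test_that("closed-form and direct circuit solutions agree over random models", {
  set.seed(101)
  for (i in 1:50) {
    cm <- common_params(E_A = runif(1, 40, 120), V_0 = runif(1, -80, -40),
                        rho_s = runif(1, 5, 80), rho_d0 = runif(1, 2, 60),
                        n = runif(1, 0.3, 2), g_max = runif(1, 1, 30))
    o1 <- orn_spec("o1", runif(1, 20, 200), runif(1, 5, 100), -4)
    o2 <- orn_spec("o2", runif(1, 20, 200), runif(1, 5, 100), -4)
    m <- calibrate_resting(cm, o1, o2)
    g1 <- runif(1, 0, cm$g_max); g2 <- runif(1, 0, cm$g_max)
    a <- solve_circuit(m, g1, g2, method = "closed_form")
    b <- solve_circuit(m, g1, g2, method = "direct")
    for (col in c("V_A", "V_m1", "V_m2", "I_A", "I_1", "I_2")) {
      expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
    }
    # current conservation to machine precision
    expect_lt(abs(a$I_A + a$I_1 + a$I_2),
              1e-12 * max(abs(c(a$I_A, a$I_1, a$I_2))))
  }
})

test_that("solved states match the independent linear-solve oracle", {
  m <- ref_model("ab4")
  rest <- solve_circuit(m)
  expect_equal(rest$V_A, -30.8875, tolerance = 1e-6)
  sat <- solve_circuit(m, g1 = 10)
  expect_equal(sat$V_A, -48.5307, tolerance = 1e-4)
  expect_equal(sat$V_m1, -52.55923, tolerance = 1e-4)
  expect_equal(sat$V_m2, -66.53452, tolerance = 1e-4)
  # no driving-force differences: a dead circuit
  cm <- common_params(E_A = 10, V_0 = -60)
  o <- orn_spec("o", 50, 20)
  m0 <- calibrate_resting(cm, o, o)
  m0$E_1 <- m0$E_2 <- 10 # force all batteries equal
  s <- solve_circuit(m0)
  expect_equal(s$V_A, 10)
  expect_equal(max(abs(c(s$I_A, s$I_1, s$I_2))), 0, tolerance = 1e-12)
})

test_that("stimulus can be given as log10 dilution through each ORN's Hill curve", {
  m <- ref_model("ab4")
  # x at k_od gives half-maximal conductance
  s <- solve_circuit(m, x1 = -5.9, x2 = -Inf)
  expect_equal(s$g1, 5)
  expect_equal(s$g2, 0)
  # saturating dilution equals the g = g_max state
  expect_equal(solve_circuit(m, x1 = Inf)$V_A, solve_circuit(m, g1 = 10)$V_A)
})

test_that("linearized membrane-potential changes match full circuit differences", {
  for (sn in c("ab3", "ab4", "ab5")) {
    m <- ref_model(sn)
    base <- solve_circuit(m, 0, 0)
    for (g in c(0.5, 2, 10)) {
      st <- solve_circuit(m, g1 = g, g2 = 0)
      dVA <- st$V_A - base$V_A
      lin <- ephaptic_delta_vm(dVA, m, stimulated = 1)
      expect_equal(lin$dVm_stimulated, st$V_m1 - base$V_m1, tolerance = 1e-9)
      expect_equal(lin$dVm_neighbor, st$V_m2 - base$V_m2, tolerance = 1e-9)
      st2 <- solve_circuit(m, g1 = 0, g2 = g)
      lin2 <- ephaptic_delta_vm(st2$V_A - base$V_A, m, stimulated = 2)
      expect_equal(lin2$dVm_stimulated, st2$V_m2 - base$V_m2, tolerance = 1e-9)
      expect_equal(lin2$dVm_neighbor, st2$V_m1 - base$V_m1, tolerance = 1e-9)
    }
  }
  m <- ref_model("ab4")
  z <- ephaptic_delta_vm(0, m, 1)
  expect_equal(unlist(z[, 2:3]), c(dVm_stimulated = 0, dVm_neighbor = 0))
  # linearity: doubling the LFP deflection doubles both outputs
  a <- ephaptic_delta_vm(-5, m, 1)
  b <- ephaptic_delta_vm(-10, m, 1)
  expect_equal(2 * a$dVm_stimulated, b$dVm_stimulated)
  expect_equal(2 * a$dVm_neighbor, b$dVm_neighbor)
  # frozen check: saturating ab4A deflection
  lin <- ephaptic_delta_vm(-17.6432, m, 1)
  expect_equal(lin$dVm_stimulated, 7.44077, tolerance = 1e-4)
  expect_equal(lin$dVm_neighbor, -6.53452, tolerance = 1e-4)
})

test_that("spike/LFP slope ratio and its inversion are exact inverses", {
  expect_equal(spike_lfp_ratio(ref_model("ab4")), 2.371837, tolerance = 1e-6)
  expect_equal(spike_lfp_ratio(ref_model("ab3")), 1.554290, tolerance = 1e-6)
  p <- default_params()
  for (sn in c("ab3", "ab4", "ab5")) {
    m <- ref_model(sn)
    r <- spike_lfp_ratio(m)
    o1 <- p$sensilla[[sn]]$orn1
    A_d1 <- dendrite_area_from_ratio(r, o1, p$sensilla[[sn]]$orn2, p$common)
    expect_equal(A_d1, m$orn1$A_d, tolerance = 1e-9)
    # and feeding the area back reproduces r
    o1$A_d <- A_d1
    m2 <- calibrate_resting(p$common, o1, p$sensilla[[sn]]$orn2)
    expect_equal(spike_lfp_ratio(m2), r, tolerance = 1e-9)
  }
  # non-physical branch: ratio so large the implied resistance collapses
  expect_error(
    dendrite_area_from_ratio(50, p$sensilla$ab4$orn1, p$sensilla$ab4$orn2,
                             p$common),
    class = "sensillum_nonphysical_error")
})

test_that("degenerate parameters are rejected eagerly with typed errors", {
  expect_error(common_params(rho_s = -1), class = "sensillum_param_error")
  expect_error(common_params(E_A = -70, V_0 = -60),
               class = "sensillum_param_error")
  expect_error(orn_spec("x", A_s = 0), class = "sensillum_param_error")
  expect_error(orn_spec("x", A_s = 50, A_d = -3),
               class = "sensillum_param_error")
  m <- ref_model("ab4")
  expect_error(solve_circuit(m, g1 = -1), class = "sensillum_domain_error")
  o <- orn_spec("free", A_s = 50) # no A_d
  expect_error(calibrate_resting(common_params(), o, o),
               class = "sensillum_calibration_error")
})
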