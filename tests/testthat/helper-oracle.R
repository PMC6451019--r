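# Independent oracles: plain linear-algebra solves of the Kirchhoff system,
# written without reference to the package's circuit code paths.

# Steady state of the three-branch circuit for given batteries/resistances.
oracle_solve <- function(E_A, E_1, E_2, R_1, R_2, R_A = 1) {
  A <- rbind(c(1, -R_A, 0, 0),
             c(1, 0, -R_1, 0),
             c(1, 0, 0, -R_2),
             c(0, 1, 1, 1))
  s <- solve(A, c(E_A, E_1, E_2, 0))
  list(V_A = s[1], I_A = s[2], I_1 = s[3], I_2 = s[4])
}

# Batteries E_1, E_2 that put both membrane potentials at V_0 at rest:
# resting Kirchhoff system solved jointly with the two constraints.
oracle_calibrate <- function(E_A, V_0, R_in1, R_in2, R_1, R_2, R_A = 1) {
  A <- rbind(c(1, -R_A, 0, 0, 0, 0),
             c(1, 0, -R_1, 0, -1, 0),
             c(1, 0, 0, -R_2, 0, -1),
             c(0, 1, 1, 1, 0, 0),
             c(0, 0, R_in1, 0, 1, 0),
             c(0, 0, 0, R_in2, 0, 1))
  s <- solve(A, c(E_A, 0, 0, 0, V_0, V_0))
  list(V_A = s[1], I_A = s[2], I_1 = s[3], I_2 = s[4],
       E_1 = s[5], E_2 = s[6])
}

# Reference geometries (soma / dendrite areas, sensitivities) used across
# the tests; identical to default_orn_params() but spelled out so the
# oracles do not depend on package accessors.
ref_geom <- list(
  ab3 = list(A_s1 = 98, A_s2 = 91, A_d1 = 46, A_d2 = 16,
             k1 = -4.8, k2 = -5.1),
  ab4 = list(A_s1 = 137, A_s2 = 75, A_d1 = 38, A_d2 = 25,
             k1 = -5.9, k2 = -2.5),
  ab5 = list(A_s1 = 65, A_s2 = 67, A_d1 = 20, A_d2 = 20,
             k1 = -1, k2 = -2)
)
ref_common <- list(E_A = 77, V_0 = -60, rho_s = 30, rho_d0 = 17,
                   n = 0.7, g_max = 10)

# Oracle LFP at a given pair of conductance gains, for a reference geometry.
oracle_lfp <- function(geom, g1 = 0, g2 = 0, cm = ref_common) {
  R_in1 <- cm$rho_s / geom$A_s1
  R_in2 <- cm$rho_s / geom$A_s2
  R_1_0 <- R_in1 + cm$rho_d0 / geom$A_d1
  R_2_0 <- R_in2 + cm$rho_d0 / geom$A_d2
  cal <- oracle_calibrate(cm$E_A, cm$V_0, R_in1, R_in2, R_1_0, R_2_0)
  R_1 <- R_in1 + cm$rho_d0 / (geom$A_d1 * (1 + g1))
  R_2 <- R_in2 + cm$rho_d0 / (geom$A_d2 * (1 + g2))
  s <- oracle_solve(cm$E_A, cal$E_1, cal$E_2, R_1, R_2)
  list(dVA = s$V_A - cal$V_A, V_A = s$V_A, V_A_rest = cal$V_A,
       V_m1 = cal$E_1 + R_in1 * s$I_1, V_m2 = cal$E_2 + R_in2 * s$I_2,
       cal = cal)
}

ref_model <- function(sensillum) sensillum_model(sensillum)
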