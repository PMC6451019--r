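# Reference circuit parameters for the Drosophila ab3/ab4/ab5 sensilla.
# Units: batteries/potentials in mV; resistivities and surface areas in um^2
# (resistances are rescaled by the auxiliary-cell resistance R_A = 1);
# k_od is a log10 dilution; n and g_max are dimensionless.
# A_d_is_measured marks dendritic surfaces obtained from morphometry (ab5);
# the ab3/ab4 dendritic surfaces are model-fitted values.
common:
  E_A: 77.0
  V_0: -60.0
  rho_s: 30.0
  rho_d0: 17.0
  n: 0.7
  g_max: 10.0
sensilla:
  ab3:
    A:
      A_s: 98.0
      A_d: 46.0
      k_od: -4.8
      A_d_is_measured: no
    B:
      A_s: 91.0
      A_d: 16.0
      k_od: -5.1
      A_d_is_measured: no
  ab4:
    A:
      A_s: 137.0
      A_d: 38.0
      k_od: -5.9
      A_d_is_measured: no
    B:
      A_s: 75.0
      A_d: 25.0
      k_od: -2.5
      A_d_is_measured: no
  ab5:
    A:
      A_s: 65.0
      A_d: 20.0
      k_od: -1.0
      A_d_is_measured: yes
    B:
      A_s: 67.0
      A_d: 20.0
      k_od: -2.0
      A_d_is_measured: yes
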