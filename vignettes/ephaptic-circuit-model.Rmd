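---
title: "The passive circuit model behind sensillum: assumptions, calibration, and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The passive circuit model behind sensillum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensillum)
```

## The model

An insect olfactory sensillum houses (typically) two olfactory receptor
neurons, ORN~1~ and ORN~2~, whose outer dendrites share a small lymph
compartment charged by an auxiliary cell. `sensillum` models this as three
Thevenin branches meeting at the lymph node:

* the auxiliary cell: battery $E_A$ in series with resistance $R_A$;
* each ORN: somatic battery $E_i$ in series with the somatic input
  resistance $R_{\mathrm{in},i}$ and the dendritic resistance $R_{d,i}$,
  with total $R_i = R_{\mathrm{in},i} + R_{d,i}$.

Kirchhoff's laws give four linear equations in
$(V_A, I_A, I_1, I_2)$:
$$V_A = E_A + I_A R_A,\quad V_A = E_1 + I_1 R_1,\quad
  V_A = E_2 + I_2 R_2,\quad I_A + I_1 + I_2 = 0,$$
and the membrane potentials follow as $V_{m,i} = E_i + R_{\mathrm{in},i} I_i$.
The model is purely resistive: it describes the plateau of a sustained
response, so capacitive currents are zero and nothing here is
time-resolved. The recorded local field potential (LFP) is the deflection
of $V_A$ from rest; on activation $\Delta V_A$ is negative under this
parameterization, and all reported LFP responses are $|\Delta V_A|$,
matching how peak LFP deflections are read from recordings.

All resistances are rescaled by $R_A$ (formally $R_A = 1$), which leaves
every voltage unchanged and makes currents "mV per unit $R_A$" (arbitrary
units). With the packaged reference parameters the resting $V_A$ comes out
negative (about $-31$ mV for ab4), whereas transepithelial potentials are
conventionally reported positive; the parameter set is reproduced as
published and the sign convention is internally consistent — only
*changes* in $V_A$ carry scientific weight here.

### Morphometry sets the resistances

Two assumptions tie the electrical parameters to anatomy:

* $R_{\mathrm{in},i} = \rho_s / A_{s,i}$ — somatic input resistance is
  inversely proportional to soma surface area;
* $R_{d,i} = \rho_{d,0} / (A_{d,i}(1 + g_i))$ — the dendrite is an
  electrotonically short cylinder whose membrane conductance rises with
  receptor activation.

The short-cable form is an approximation to the exact input resistance of
a leaky cylinder, $R_d = \sqrt{r_m r_a}\coth(L\sqrt{r_a/r_m})$, valid when
the electrotonic length $l = L\sqrt{r_a/r_m} \ll 1$ (relative error
$\approx l^2/3$). `cable_input_resistance()` implements the exact formula
so the approximation can be checked rather than trusted.

Receptor activation follows a Hill function of odorant concentration.
Writing concentrations as dilutions of the undiluted stock,
$\mathrm{od} = 10^x$ with $x \le 0$, and the half-activation point as
$K_\mathrm{od} = 10^{k_\mathrm{od}}$, the stock concentration cancels:
$$g = \frac{g_{\max}}{1 + 10^{\,n(k_\mathrm{od} - x)}}.$$
Only the product $g_{\max} = \rho_{d,0}\,\sigma_{d,\max}$ is a model
parameter; receptor density, unitary conductance and maximal conductivity
are never needed individually.

### Parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| $E_A$ | auxiliary-cell battery | mV | 77 |
| $V_0$ | common ORN resting potential | mV | −60 |
| $\rho_s$ | soma membrane resistivity ($R_A$-rescaled) | µm² | 30 |
| $\rho_{d,0}$ | basal dendritic resistivity ($R_A$-rescaled) | µm² | 17 |
| $n$ | Hill coefficient of activation | — | 0.7 |
| $g_{\max}$ | maximal conductance gain | — | 10 |
| $A_{s,i}$, $A_{d,i}$ | soma / outer-dendrite surface | µm² | per ORN |
| $k_{\mathrm{od},i}$ | log10 half-activating dilution | — | per ORN |

The packaged defaults (`default_params()`) are the reference values for
the *Drosophila* ab3, ab4 and ab5 sensilla; the ab5 dendritic surfaces are
morphometric measurements while the ab3/ab4 ones are fitted values, which
the `A_d_is_measured` flag records because the fitting stage treats the
two cases differently.

## Calibration of the somatic batteries

$E_1$ and $E_2$ are not free constants. Since the resting potential is set
by the spike-initiation machinery, both neurons are required to rest at
$V_0 = -60$ mV with no odorant; the auxiliary battery $E_A$ is shared by
all sensilla, while $E_1, E_2$ differ per sensillum because the basal
resistances differ. `calibrate_resting()` solves the resting Kirchhoff
system *jointly* with the two constraints $V_{m1} = V_{m2} = V_0$ — a
6×6 linear system — and, at every call, cross-checks the result against
the closed-form expressions for the resting currents and batteries (the
$\xi_0, \Theta_0, \alpha_i, \beta_i$ reduction, exposed in `$resting`).
The direct solve is canonical; a disagreement beyond $10^{-6}$ mV raises
an internal error. This guards against sign-convention drift between the
two derivations, which is the easiest mistake to make in this algebra.
Every calibrated model satisfies $V_{m1} = V_{m2} = V_0$ to well below
$10^{-9}$ mV.

`solve_circuit()` likewise has two routes — the closed-form Thevenin
solution used everywhere, and a direct linear solve of the four branch
equations kept as an independent check. The test suite sweeps randomized
circuits and requires agreement to $10^{-9}$ relative.

## Simulation conventions

```{r}
m <- sensillum_model("ab4")
m
dose_response(m, stimulated = 1, x_grid = c(-7, -6, -5, Inf))
```

Decisions that were genuinely open, and how they were fixed:

* **"50% background activation"** means activation *fraction* 0.5 of the
  neighbor, i.e. $g = 0.5\,g_{\max}$, held constant while the other ORN's
  concentration is swept. The alternative reading (50% of the saturating
  LFP) differs because the LFP is a nonlinear function of $g$; the
  g-fraction reading was chosen because background activation acts on the
  conductance, not on the recorded field.
* **Baselines under background are re-zeroed**: responses are changes from
  the background-only steady state, matching how sustained-background
  experiments are analyzed.
* **"Saturating" responses** use the infinite-dose limit (activation
  fraction exactly 1), not the largest tested concentration, unless a
  finite dilution is given.
* **Default dilution grid**: $-10$ to $0$ in steps of $0.25$ log10 units,
  covering all reference sensitivities with margin on both flanks.

Two closed-form relations are exposed because they carry the scientific
claims. With only ORN~1~ stimulated, its neighbor's resistance is fixed,
so both membrane-potential changes are exactly linear in the LFP:
$\Delta V_{m1} = -\Delta V_A R_{\mathrm{in}1}(1 + 1/R_2)$ and
$\Delta V_{m2} = \Delta V_A R_{\mathrm{in}2}/R_2$. The ratio of the two
slopes (B over A) at basal resistances,
$$r = \frac{R_{\mathrm{in}2}(1 + 1/R_{1,0})}{R_{\mathrm{in}1}(1 + 1/R_{2,0})},$$
is the model's counterpart of the measured spike/LFP slope ratio, and its
inversion (`dendrite_area_from_ratio()`) turns a measured $r$ plus one
dendritic surface into the other — exactly, as the round-trip tests
require.

```{r}
spike_lfp_ratio(m)
asymmetry_report(m)
```

## The fitting stage

`global_fit()` fits LFP dose–response tables from several sensilla
simultaneously: common circuit constants shared by all sensilla, one
$k_\mathrm{od}$ per ORN, and — for sensilla without measured dendritic
surfaces — $A_{d2}$ and $r$ free with $A_{d1}$ derived, so the fitted
geometry always satisfies the slope-ratio relation exactly. Residuals are
model LFP minus replicate-mean LFP, optionally weighted by 1/s.e.m. (the
default is unweighted, since nothing in the measurement model privileges
either choice; both are exposed). The optimizer is bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) restarted from 32 jittered
initial points by default, with sensitivity starts taken from the
half-maximum of each measured curve. Infeasible parameter combinations —
calibration failures, non-physical ratio inversions — yield a large
finite penalty residual rather than an error, so multistarts can escape
them. `r` is bounded to $(1, 5]$, the range spanned by measured slope
ratios; bounds are configurable.

Numerical conventions: the resting-potential constraint pins $V_0$ (it is
never fitted); the first start is always the undithered initial point, so
a fit rerun from its own optimum cannot move by more than the optimizer
tolerance (the suite checks the best objective is no worse than any
recorded start); degenerate inputs (curves with fewer than four
concentrations, flat Hill-fit data, constant abscissa in the linear fit)
raise typed errors up front instead of propagating NaNs.

**Identifiability.** With a single sensillum and all five common constants
free, the problem is under-determined — the shared constants are only
pinned down jointly across geometries — and `global_fit()` flags such
configurations. Even with three sensilla, one synthetic study at
realistic noise leaves the fully-free fit weakly identified: $\rho_s$
drifts to its bound and sensitivity estimates absorb shifts of order one
log unit. For that reason the *recovery harness*
(`recovery_experiment()`) defaults to the constrained configuration —
common constants fixed at their reference values, sensitivities and free
dendritic surfaces estimated — which is the question the harness is meant
to answer: how well can the ORN-specific parameters be recovered from one
study's worth of data. Users can pass any `fit_config()` to study the
joint problem.

## The synthetic-data generator

`generate_lfp_data()` emulates the structure of single-sensillum LFP
dose–response measurements: per sensillum, each ORN stimulated alone by
its private odorant across a dilution grid, `replicates = 9` independent
sensilla (the typical sample size of such datasets), reported per
replicate so means and s.e.m. can be formed downstream. Noise is
additive, homoscedastic Gaussian on |LFP| with `noise_sd = 0.5` mV,
chosen to match the error-bar scale of published curves; it is untruncated
(rare negative values are left to the fit). One master seed spawns
per-run child seeds in `recovery_experiment()`, all reported.

What the generator does **not** emulate — and therefore what passing
recovery tests do and do not show: real LFP noise is likely
heteroscedastic (larger near the plateau) and correlated within a
sensillum across concentrations; real dose–response curves include
adaptation and temporal dynamics that a steady-state model cannot
produce; and real data include sensillum types (e.g. coeloconics) whose
dendritic branching violates the short-cable geometry, which is
plausibly why a single shared parameter set cannot fit them together
with basiconics. Recovery results certify the estimation machinery under
the stated noise model, not the adequacy of that noise model for any
particular recording rig.

Problem sizes used by the packaged experiments: dilution grid $-8 \dots
-2$ (7 concentrations), 9 replicates, noise 0.5 mV, 20 generate-and-fit
cycles, 4 multistarts per recovery fit (the constrained problem is
smooth enough that more starts only reconfirm the optimum). Under these
conditions the median absolute recovery error is about 0.03 log units
for $k_\mathrm{od}$ and about 3% for the free dendritic surfaces — an
order of magnitude inside the 0.2 / 20% acceptance bands the tests
enforce.

## Known limitations

* Two ORNs per sensillum; the four-neuron case is out of scope.
* Steady-state only: no spikes, no capacitive transients, no
  time-resolved inhibition.
* The spike/LFP ratio enters through the *assumption* that firing-rate
  slope reflects $\Delta V_m / \Delta V_A$; the model does not generate
  spikes.
* The homoscedastic noise model is a stated simplification; a
  heteroscedastic option is a natural extension.
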