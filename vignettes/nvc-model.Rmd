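---
title: "A mechanistic neurovascular coupling model: equations, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic neurovascular coupling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcsim)
```

## The model

`nvcsim` simulates the chain from neural activity to hemodynamic and
electrophysiological observables in a cortical region, and estimates its
parameters from stimulus-response time series. The chain has four coupled
layers.

### Neuronal activity and vasoactive signaling

Three lumped populations carry phenomenological activity states: pyramidal
neurons (`N_Pyr`), NO-releasing interneurons (`N_NO`) and NPY-releasing
interneurons (`N_NPY`). Each is driven by a square-pulse stimulus channel
(gain `ku_i`, sign flag ±1), pyramidal activity excites both interneuron
classes, the interneurons cross-inhibit each other, and both feed back
negatively on the pyramidal population. Wherever an activity excites a
target it enters through the hard rectifier `E = max(N, 0)`; the inhibitory
feedback onto pyramidal cells uses the raw state. Activity decays
first-order (`sinkN_i`). Intracellular calcium integrates activity,
`dCa/dt = k_Ca (1 + N) - sinkCa Ca` with `k_Ca = 10` fixed for all three
populations.

Calcium drives three vasoactive cascades with deliberately different
kinetics:

* **NO (fast dilator):** calcium-dependent NO synthesis, transfer to the
  vascular smooth muscle pool, elimination `sinkNO > 1/s` (an experimental
  constraint on NO lifetime).
* **PGE2 (slow dilator):** calcium activates phospholipases producing
  arachidonic acid, which is converted by a saturable COX-2 step
  (Michaelis-Menten in AA) to PGE2 and passed to the smooth muscle pool.
* **NPY (slowest, constrictor):** calcium-dependent NPY release with a
  Michaelis-Menten transfer `Vmax NPY / (Km + NPY)` to the smooth muscle
  pool and a slow sink.

Deviations of the three smooth-muscle pools from their resting values are
weighted (`ky_NO`, `ky_PGE2` positive; `ky_NPY` entering negatively) and
summed into the scalar vascular drive `G`. All signaling species are in
arbitrary units; no unit-conversion layer exists on purpose.

### Three-compartment viscoelastic Windkessel

Arterial/arteriolar (a), capillary (c) and venous (v) compartments form an
electrical-analog circuit: volumes are charges, pressures voltages, flows
currents. Everything is normalized: baseline volumes `V0 = (0.29, 0.44,
0.27)` sum to 1, baseline resistances `R0 = (0.74, 0.08, 0.18)` sum to 1,
all baseline flows are 1, and the arterio-venous boundary pressure is 1.
Each compartment balances its mid-compartment pressure against a nonlinear
elastic pressure through a viscoelastic element:

$$k_{vis,i}\,\dot V_i \;=\; \bar p_i(f) \;-\;
\frac{V_{i,0}}{C_{i,0}}\Big(\frac{V_i}{V_{i,0}}\Big)^{K_i} \;+\; G\,\delta_{i,a},$$

where the mid-compartment pressures are half the flow brackets
`((r1+r2) f1 + (r2+r3) f2 + r3 f3)/2` (arterial), `((r2+r3) f2 + r3 f3)/2`
(capillary) and `r3 f3 / 2` (venous); `C_{i,0} = V_{i,0}/\bar p_{i,0}` is
the baseline secant compliance and `K_i > 1` a stiffening exponent (the
instantaneous secant compliance falls as `(V/V_0)^{-(K_i-1)}`). The source
publications print this equation with typography too damaged to transcribe
literally; the form above is the unique viscoelastic balance that
reproduces every recoverable printed structure — the flow brackets, the
inflow solution `f0 = (2\Delta p_r - \text{bracket})/r_1`, the baseline
relations for pressures, compliances and segment lengths, and the baseline
as an *exact* fixed point — which is the property the equations are
defined by. The drive `G` acts only on the arterial equation; capillary
and venous compartments respond passively.

An optional nonlinear-vessel variant (`vascular_switch` in
`simulate_nvc()`) lets the capillary/venous stiffness and viscoelasticity
take different values from a configured time onward — useful for
exploring whether long stimulations need stiffer downstream vessels — and
is off by default.

Resistances follow Poiseuille scaling at fixed segment length,
`r_i = l_i^3 / V_i^2` with `l_i = (r_{i,0} V_{i,0}^2)^{1/3}`. Together
with flow conservation `f_i = f_{i-1} - \dot V_i` and the pressure
boundary condition the system is an index-1 DAE. Rather than calling a DAE
integrator, `vascular_rhs()` exploits that the seven unknowns
`(\dot V_a, \dot V_c, \dot V_v, f_0..f_3)` enter *linearly* once the
volumes are known, and solves the exact 7×7 linear system at every
right-hand-side evaluation. The algebraic constraints therefore hold to
linear-solver precision at all times; a residual-form check
(`wk_residual()`) verifies this independently in the tests.

### Oxygen transport

Oxygen amounts in the three vascular compartments and a tissue compartment
(volume fraction 34.8) follow advection with the outlet-boundary
concentrations `C_i = n_i / V_i`, diffusion into tissue driven by the mean
compartment pO2 minus tissue pO2, an arterio-venous diffusion shunt, and
consumption `CMRO2 = CMRO2_0 (1 + k_met (N_NO + N_NPY + N_Pyr))`. Blood
pO2 and concentration are linked by a Hill saturation curve (`p50 = 36`
mmHg, `h = 2.6`, `cO2_max = 9.26` mM); tissue oxygen is dissolved
(Henry's law, 1.46 µM/mmHg). The inlet concentration is the arterial blood
content minus a documented leak of 0.116 mM.

The diffusion conductances, basal metabolism and inlet concentration are
not free parameters: `calibrate_o2_baseline()` solves the resting balance
exactly for a supplied interface-pO2 profile. The shipped default profile
(arterial 90, arterio-capillary 48, capillary-venous 35, outlet 32, tissue
25 mmHg; shunt fraction 0.2 of the arterial wall loss) is a **synthetic
stand-in** — the microvascular measurements the original analysis was
calibrated to are not reprinted anywhere accessible — chosen so that (i)
the inlet leak reproduces the documented 0.116 mM, (ii) the volume-weighted
baseline saturation is ≈0.60, matching the conventional 60/40 µM oxy/deoxy
hemoglobin baseline, and (iii) tissue pO2 lies below all mean vascular
pressures so every wall flux is directed into tissue. Compartment
saturation is the average of inlet and outlet boundary concentrations over
`cO2_max`; the alternative transcription as a concentration *difference*
over `cO2_max` is an extraction fraction, not a saturation, and is
inconsistent with the hemoglobin and BOLD equations that consume `S_iO2`,
so the average reading is used.

### Observables

All observables are baseline-referenced, so a null stimulus maps to
exactly zero. Diameter change is `100(\sqrt{V/V_0}-1)` %. Hemoglobin
changes scale the summed compartment amounts by a single factor fixing
baseline total hemoglobin at 100 µM, which preserves
`ΔHbO + ΔHbR = ΔHbT` to machine precision (a profile whose baseline HbO
falls outside 60 ± 3 µM triggers a calibration warning rather than a
second, closure-breaking scale). The gradient-echo BOLD signal sums
intravascular and extravascular contributions with intrinsic signal ratios
`ε_i = λ e^{-TE\,R2^*_{i,0}} / e^{-TE\,R2e_0}`, quadratic
hematocrit-dependent baseline rates `R2^*_{i,0} = A^* + C^*(1-S_{i,0})^2`,
quadratic intravascular relaxation changes, and extravascular changes that
are linear in the `|S_{off} - S|`-weighted volume deviations for arterial
and venous blood and quadratic for capillaries. LFP is proportional to
pyramidal activity (`ky4`). CBF is the fractional inflow change, CBV the
percent volume change.

The `susceptibility_off()` configuration makes blood magnetically
indistinguishable from tissue (`Δχ = 0`, `C^* = 0`, `λ = 1`,
`A^* = R2e_0`); under it the BOLD output is identically zero for *any*
trajectory, a structural null used in the tests.

## Numerical choices

* **Initialization.** With zero stimulus the activity fixed point is
  `N = 0`, which makes the resting network triangular; the steady state is
  computed in closed form and its residual checked against 1e-9. This is
  exact where root-finding or a long pre-simulation would only
  approximate.
* **Discontinuities.** Stimulus on/off switches partition the horizon into
  constant-input segments integrated piecewise (`lsoda`, rtol 1e-8 / atol
  1e-10 by default; 1e-6 / 1e-8 during fitting), so square-pulse edges are
  handled exactly. The activity rectifier is kept as an exact piecewise
  function — smoothing would introduce an unreported shape parameter — and
  its kinks are resolved by the adaptive step control.
* **Validity guards.** Vessel collapse (`V ≤ 0`), oxygen depletion or
  super-saturation, and negative CMRO2 abort a simulation rather than
  being clamped; during optimization such failures return a large finite
  sentinel (1e12 plus a term decreasing with the fraction of experiments
  completed) so optimizers stay directional. Negative intracellular
  calcium (activity suppressed below `N = -1` for long) is reported as a
  warning marking the edge of the model's validity.

## Estimation machinery

The cost is the SEM-weighted least-squares sum over all records; with
known noise it is the negative log-likelihood up to a constant. A
parameter vector is *acceptable* when the cost passes a chi-square test at
the data-point count (`chi2_cutoff(n, 0.05)`), and confidence regions use
the likelihood-ratio rule `J ≤ J_best + χ²(df = number of estimated
parameters)` — the two degree-of-freedom conventions are implemented
separately and never conflated. SEM flooring (values below a series' mean
raw SEM raised to that mean) is applied to the series for which the source
analyses prescribe it; storing the raw SEMs makes the rule idempotent.

Qualitative mechanistic knowledge enters the objective as hinge penalties
that are zero when satisfied: the NO contribution peaks before PGE2 before
NPY and has decayed by stimulus end, with post-stimulus net constriction;
oxy- and deoxyhemoglobin peak together with a bounded amplitude ratio; LFP
peaks early, plateaus below its peak, undershoots after stimulus end and
recovers (inverted for negative responses, for which the arm-ordering
family is skipped — nothing is known about the arm ordering there). The
exact penalty weights of the original study are not published; each
violated clause here contributes `weight × violation` with weight 1e4,
which dominates any chi-square cutoff while remaining finite, and all
tolerances are explicit arguments of `nvc_demands()`.

Optimization is a global-then-local contract: Latin-hypercube multistart
over the log10 box (bounds ±4.5 by default) with Nelder-Mead (Brent in one
dimension) refinement, deterministic for a fixed seed. Posterior
uncertainty uses a random-walk Metropolis sampler on `exp(-J_opt/2)`
(penalties included, so qualitative demands constrain the posterior too),
collecting the chi-square-acceptable set and building pointwise min/max
simulation envelopes. Vectors whose post-stimulus series show slopes more
than 10× the largest in-stimulus slope — spikes hiding between data points
— can be filtered out (`filter_unrealistic()`, threshold configurable;
removal above 5 % warns that the threshold is probably mis-set).

## The synthetic-data generator

`study_template()` reproduces the *shapes* of five published stimulus-
response data sets: whisker-stimulation diameter series at three durations
(288 points in total, matching the printed count), optogenetic/sensory
arteriolar responses, hemoglobin series for six stimulation conditions
plus a 23-point BOLD validation series, macaque BOLD+LFP blocks at 1 s
resolution for positive and negative responses, and human CBV/BOLD/CBF
block designs. `generate_fixture()` simulates a template at a true
parameter vector, samples the template grids and adds independent Gaussian
noise whose SD equals the declared SEM column — exactly the likelihood's
noise model, so the cost at the true vector is chi-square distributed
(the coverage checks exploit this). Fixtures are byte-reproducible for a
given seed and restore the caller's RNG state.

Per-setup parameter blocks mirror the sharing structure of the source
studies (`study_sharing_map()`): e.g. the sensory conditions carry their
own stimulus gains, the negative-response setups their own strongly
attenuated gains (suppressive drive reaching a neighbouring area is far
weaker than direct sensory drive; full-strength inverted drive would push
the oxygen model outside its envelope).

### Default parameters

The source publications never print fitted values for the kinetic
constants (only posterior profiles), so the defaults in `default_theta()`
are this package's documented reference set, chosen once to realize the
mechanistic behavior the biology dictates: electrophysiology settling
within ~1-2 s; a fast NO arm (seconds), a slow PGE2 arm (tens of seconds)
and a slowest NPY arm (constriction outlasting the dilators); a two-peak
arteriolar response to a 30 s stimulus with a post-stimulus undershoot;
dilation of ~10-15 % in arterioles and a few percent in venules with CBF
increases below +60 %; and hemoglobin excursions of order 10 µM. They are
reference dynamics for testing and synthetic data, not estimates of any
real tissue.

What passing tests on these synthetic data do show: the pipeline
(simulate → observe → corrupt → refit → accept) is self-consistent, the
estimator recovers identifiable parameters, and the coverage of the
chi-square acceptance matches its nominal level. What they cannot show:
that the model or these defaults describe any particular measured animal
or human data set — real data have correlated noise, baseline drifts,
digitization error and inter-subject variability that the generator
deliberately omits.

### Problem sizes

The shipped tests and the acceptance script use reduced problem sizes
chosen as sensible desk-scale defaults: recovery fixtures free three drive
weights (`ky_NO`, `ky_PGE2`, `ky_NPY`) on the 30 s diameter paradigm —
the setting where all three arms are expressed and hence identifiable —
within a ±0.35 log10 box; coverage uses 50-60 noisy replicates of the
macaque template. Larger studies (more free parameters, full multi-study
sharing, 1e5-sample chains) use the same code paths unchanged.

## Known limitations

* The activity layer is phenomenological; it has no membrane potentials,
  ion channels or distinct interneuron morphologies, and astrocytic and
  capillary-endothelial signaling pathways are deliberately absent.
* Negative-response dynamics compress cross-area inhibition into sign
  flags and attenuated gains on the same three populations.
* One simulation variable serves both single-vessel and lumped
  measurements; diameter data from individual arterioles and voxel-scale
  CBV share `V_a`.
* The oxygen calibration profile is a documented stand-in (see above);
  absolute saturations and the oxygen extraction fraction inherit its
  uncertainty even though all baseline-referenced observables are
  insensitive to modest profile changes.
* Instantaneous square-pulse offsets produce a brief post-stimulus
  transient in the NO arm (the cross-inhibiting NPY activity outlives the
  stimulus by a second or two); it is a genuine feature of the rectified
  cross-inhibition architecture, not an integration artifact.
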