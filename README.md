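# nvcsim

Mechanistic simulation and estimation of neurovascular coupling (NVC) —
the signaling chain by which neural activity controls local cerebral
blood flow, volume and oxygenation, and thereby the signals neuroscience
actually measures: vessel diameter, oxy-/deoxyhemoglobin, BOLD fMRI, LFP,
CBF and CBV.

The package is for modelers of hemodynamic imaging data who want a single
forward model that spans rodent two-photon diameter measurements,
optical-imaging hemoglobin data, and primate/human BOLD — plus the
statistical machinery to fit it: SEM-weighted least squares, a χ²
acceptance test, mechanistic (qualitative-feature) penalty terms,
multistart optimization and Metropolis posterior sampling with
uncertainty envelopes.

## The model in brief

Three lumped neural populations — pyramidal cells and NO- and
NPY-releasing interneurons — carry activity states N_i driven by square
pulse stimuli, with rectified excitation E = max(N, 0), cross-inhibition
and negative feedback. Calcium (dCa/dt = k_Ca(1 + N) − sink·Ca) drives
three vasoactive cascades with distinct kinetics: fast NO (dilating),
slow PGE₂ (dilating), slowest NPY (constricting). Their smooth-muscle
pools combine into a scalar drive

  G = ky_NO·ΔNO_vsm + ky_PGE2·ΔPGE2_vsm − ky_NPY·ΔNPY_vsm,

which actuates the arterial compartment of a normalized three-compartment
viscoelastic Windkessel (volumes V_a, V_c, V_v; baselines 0.29/0.44/0.27;
resistances r_i = l_i³/V_i²; baselines 0.74/0.08/0.18; unit boundary
pressure and unit baseline flows):

  k_vis,i · dV_i/dt = p̄_i(f) − (V_i,0/C_i,0)(V_i/V_i,0)^K_i + G·δ_i,a,

closed as an index-1 DAE solved exactly (linearly) at each step. Oxygen is
advected through the compartments, diffuses to tissue down pO₂ gradients
(Hill saturation: p50 = 36 mmHg, h = 2.6, c_max = 9.26 mM) and is consumed
at CMRO₂ = CMRO₂,₀(1 + k_met·ΣN). Volumes and saturations map to diameter
change 100(√(V/V₀) − 1), hemoglobin changes (baseline HbT = 100 μM),
gradient-echo BOLD (intra- + extravascular compartments), LFP = ky₄·N_Pyr,
CBF and CBV.

Fitting minimizes J_lsq = Σ((y − ŷ)/SEM)² plus hinge penalties encoding
mechanistic demands (NO peaks before PGE₂ before NPY; ΔHbO/ΔHbR co-timed;
LFP early peak → plateau → post-stimulus undershoot). A fit is acceptable
when J_lsq ≤ χ²₀.₉₅(n data points); confidence regions use
J ≤ J_best + χ²₀.₉₅(n estimated parameters). See the methods vignette
(`vignettes/nvc-model.Rmd`) for the full equations and design choices.

## Worked example

Simulate a 30 s whisker-stimulation block and look at the arteriolar
diameter response:

```r
library(nvcsim)
p <- nvc_params()                       # documented reference parameters
sim <- simulate_nvc(p, build_paradigm("drew", "long"), seq(0, 75, 0.25))
da <- sim_observable(sim, "diameter_a")
```

This prints the hallmark two-phase dilation with a post-stimulus
undershoot:

```
first peak:  +9.3% at 3.5 s     (fast NO arm)
second peak: +14.7% at 28.5 s   (slow PGE2 arm)
undershoot:  -1.5% at 61.2 s    (lingering NPY constriction)
```

Generate a synthetic macaque-style dataset (BOLD + LFP, positive and
negative responses, 1 s resolution, Gaussian noise with SD equal to the
declared SEM) and score a parameter vector:

```r
fx <- generate_fixture(fixture_spec("shmuel", noise_sd = 0.05, seed = 1))
prob <- make_fit_problem(fx$configs, fx$data, free = "ky4", base_params = p)
cost_report(prob, log10(p$theta[["ky4"]]))
```

```
J_lsq = 133.2 on 160 points; chi2 cutoff(alpha=0.05) = 190.52 -> PASS
      experiment observable        J  n
 shmuel:negative       BOLD 28.90517 40
 shmuel:positive       BOLD 30.99967 40
 shmuel:negative        LFP 39.30504 40
 shmuel:positive        LFP 34.00783 40
```

The cost at the generating vector passes the χ² acceptance test, as it
should: with SEM-scaled Gaussian noise J_lsq at the truth is χ²(160)
distributed. `fit_nvc()` refits free parameters from scratch
(Latin-hypercube multistart + local refinement), `sample_posterior()`
draws the χ²-acceptable set and `posterior_envelope()` turns it into
pointwise simulation uncertainty bands.

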