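Package: nvcsim
Title: Mechanistic Neurovascular Coupling Simulation and Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and parameter estimation for a mechanistic
    model of neurovascular coupling. Phenomenological pyramidal and
    interneuron activity drives three vasoactive signaling arms (nitric
    oxide, prostaglandin E2, neuropeptide Y) acting on a three-compartment
    viscoelastic Windkessel model of the cerebral vasculature, coupled to
    oxygen transport with Hill-type hemoglobin saturation. Model states map
    to measured observables: vessel diameter change, hemoglobin
    concentration changes, BOLD, LFP, CBF and CBV. Includes
    SEM-weighted least-squares fitting with a chi-square acceptance test,
    qualitative-feature penalties, Metropolis posterior sampling with
    uncertainty envelopes, and a synthetic-data generator emulating the
    sampling designs of published stimulus-response studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
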