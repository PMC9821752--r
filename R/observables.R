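#' Vessel diameter change from volume
#'
#' Diameter change is the square root of the fractional volume change,
#' reported in percent: 100 (sqrt(V/V0) - 1).
#'
#' @param V volume series (> 0)
#' @param V0 baseline volume
#' @export
diameter_change <- function(V, V0) {
  stop_if(any(V <= 0) || V0 <= 0, "volumes must be positive")
  100 * (sqrt(V / V0) - 1)
}

#' Hemoglobin concentration changes in micromolar
#'
#' Sums the per-compartment hemoglobin amounts (volume times saturation) and
#' scales the normalized totals so that baseline total hemoglobin is 100 uM.
#' With that single scale the closure dHbO + dHbR = dHbT holds exactly at
#' every time point. The published analyses assume a 60/40 uM oxy/deoxy
#' baseline split; if the calibrated baseline saturation implies a baseline
#' HbO outside 60 +- 3 uM a calibration warning is emitted.
#'
#' @param volumes n x 3 matrix of compartment volumes over time
#' @param saturations n x 3 matrix of compartment saturations
#' @param params `nvc_params`
#' @param hbt0 baseline total hemoglobin concentration (uM)
#' @return data.frame with columns dHbO, dHbR, dHbT (uM)
#' @export
hemoglobin_concentration_change <- function(volumes, saturations, params,
                                            hbt0 = 100) {
  volumes <- as.matrix(volumes); saturations <- as.matrix(saturations)
  V0 <- params$wk$V0
  S0 <- params$oxy$S0
  scale <- hbt0 / sum(V0)
  hbo0 <- scale * sum(V0 * S0)
  if (abs(hbo0 - 0.6 * hbt0) > 0.03 * hbt0) {
    warning(sprintf(
      "baseline saturation profile implies HbO0 = %.1f uM, incompatible ",
      hbo0), "with the 60/40 split")
  }
  hbt <- scale * rowSums(volumes)
  hbo <- scale * rowSums(volumes * saturations)
  data.frame(dHbO = hbo - hbo0,
             dHbR = (hbt - hbo) - (hbt0 - hbo0),
             dHbT = hbt - hbt0)
}

# intravascular relaxation coefficients; linear in hematocrit
bold_Astar <- function(Hct) 14.87 * Hct + 14.686
bold_Cstar <- function(Hct) 302.06 * Hct + 41.83

#' BOLD signal from volumes and saturations
#'
#' Gradient-echo BOLD as a volume- and relaxation-weighted sum over the
#' three vascular compartments and the extravascular space. Baseline
#' intravascular relaxation rates follow the quadratic hematocrit
#' expression R2*_i0 = A* + C*(1 - S_i0)^2; intrinsic compartment signal
#' ratios are eps_i = lambda exp(-TE R2*_i0) / exp(-TE R2e_0). Relaxation
#' changes are quadratic in (1 - S) intravascularly; extravascularly the
#' arterial and venous contributions are linear in the |S_off - S|-weighted
#' volume deviation with prefactor (4 pi / 3) dchi Hct gamma B0, and the
#' capillary contribution quadratic with prefactor 0.04 (dchi Hct gamma
#' B0)^2. The signal is normalized to its own baseline and reported as
#' percent change, so the null stimulus maps to exactly zero.
#'
#' @param volumes n x 3 matrix of compartment volumes (normalized units)
#' @param saturations n x 3 matrix of saturations in \[0, 1\]
#' @param params `nvc_params` (baseline volumes and saturations)
#' @param acq acquisition settings; defaults to the set stored in `params`
#' @return percent-change series of length n
#' @export
bold_signal <- function(volumes, saturations, params, acq = params$acq) {
  volumes <- as.matrix(volumes); saturations <- as.matrix(saturations)
  stop_if(is.null(acq$TE) || is.null(acq$B0), "TE and B0 must be set")
  stop_if(any(saturations < 0 | saturations > 1),
          "saturations must lie in [0, 1]")
  V0 <- params$wk$V0
  S0 <- params$oxy$S0
  Hct <- acq$Hct
  Astar <- if (is.null(acq$force_Astar)) bold_Astar(Hct) else
    rep(acq$force_Astar, 3)
  Cstar <- if (isTRUE(acq$force_Cstar0)) c(0, 0, 0) else bold_Cstar(Hct)

  R2i0 <- Astar + Cstar * (1 - S0)^2
  eps <- acq$lambda * exp(-acq$TE * R2i0) / exp(-acq$TE * acq$R2e0)

  # compartment-to-voxel mapping: baseline intravascular fraction Viv0
  vhat <- volumes * acq$Viv0 / sum(V0)
  vhat0 <- V0 * acq$Viv0 / sum(V0)
  Ve <- 1 - rowSums(vhat)
  Ve0 <- 1 - sum(vhat0)

  dR2i <- sweep((1 - saturations)^2, 2, (1 - S0)^2, `-`)
  dR2i <- sweep(dR2i, 2, Cstar, `*`)

  sus <- acq$dchi * Hct * acq$gam * acq$B0     # per-compartment scale
  dev <- abs(acq$SoffO2 - saturations)
  dev0 <- abs(acq$SoffO2 - S0)
  lin <- (4 * pi / 3) *
    (sus[1] * (vhat[, 1] * dev[, 1] - vhat0[1] * dev0[1]) +
       sus[3] * (vhat[, 3] * dev[, 3] - vhat0[3] * dev0[3]))
  quad <- 0.04 * sus[2]^2 *
    (vhat[, 2] * dev[, 2]^2 - vhat0[2] * dev0[2]^2)
  dR2e <- lin + quad

  Si <- sweep(vhat * exp(-acq$TE * dR2i), 2, eps, `*`)
  Se <- Ve * exp(-acq$TE * dR2e)
  H <- 1 / (Ve0 + sum(eps * vhat0))
  signal <- H * (rowSums(Si) + Se)
  100 * (unname(signal) - 1)
}

#' Local field potential observable
#'
#' Proportional to the phenomenological pyramidal activity state,
#' baseline-referenced (resting pyramidal activity is zero).
#'
#' @param N_Pyr pyramidal activity series
#' @param ky4 positive scaling constant
#' @export
lfp_signal <- function(N_Pyr, ky4) {
  stop_if(ky4 <= 0, "ky4 must be positive")
  ky4 * N_Pyr
}

#' Cerebral blood flow change
#'
#' Fractional change of the arterial inflow relative to its baseline of 1.
#'
#' @param f0 inflow series
#' @export
cbf_signal <- function(f0) f0 - 1

#' Cerebral blood volume change
#'
#' Percent change of a volume series (total or per compartment).
#'
#' @param V volume series
#' @param V0 baseline volume
#' @export
cbv_signal <- function(V, V0) 100 * (V / V0 - 1)

observable_kinds <- c("diameter_a", "diameter_v", "dHbO", "dHbR", "dHbT",
                      "BOLD", "LFP", "CBF", "CBV", "CBV_a", "CBV_v")

observable_units <- c(diameter_a = "pct", diameter_v = "pct",
                      dHbO = "uM", dHbR = "uM", dHbT = "uM",
                      BOLD = "pct", LFP = "au", CBF = "fraction",
                      CBV = "pct", CBV_a = "pct", CBV_v = "pct")

#' Extract observable series from a simulation
#'
#' Maps a simulated trajectory to one of the measured quantities. All
#' observables are baseline-referenced, so the null stimulus yields exactly
#' zero.
#'
#' @param sim `nvc_sim` from [simulate_nvc()]
#' @param kind one of diameter_a, diameter_v, dHbO, dHbR, dHbT, BOLD, LFP,
#'   CBF, CBV, CBV_a, CBV_v
#' @param params parameter object (defaults to the one stored in `sim`)
#' @param acq acquisition settings for BOLD
#' @return numeric series along `sim$time`
#' @export
sim_observable <- function(sim, kind, params = attr(sim, "params"),
                           acq = params$acq) {
  kind <- match.arg(kind, observable_kinds)
  V0 <- params$wk$V0
  vol <- as.matrix(sim[, c("V_a", "V_c", "V_v")])
  sat <- as.matrix(sim[, c("S_a", "S_c", "S_v")])
  switch(kind,
    diameter_a = diameter_change(sim$V_a, V0[["a"]]),
    diameter_v = diameter_change(sim$V_v, V0[["v"]]),
    dHbO = hemoglobin_concentration_change(vol, sat, params)$dHbO,
    dHbR = hemoglobin_concentration_change(vol, sat, params)$dHbR,
    dHbT = hemoglobin_concentration_change(vol, sat, params)$dHbT,
    BOLD = bold_signal(vol, sat, params, acq),
    LFP = lfp_signal(sim$N_Pyr, params$theta[["ky4"]]),
    CBF = cbf_signal(sim$f0),
    CBV = cbv_signal(rowSums(vol), sum(V0)),
    CBV_a = cbv_signal(sim$V_a, V0[["a"]]),
    CBV_v = cbv_signal(sim$V_v, V0[["v"]])
  )
}

#' Experiment configuration
#'
#' Couples a stimulus paradigm with the observables measured, their sampling
#' grids and the acquisition settings.
#'
#' @param study,variant forwarded to [build_paradigm()]
#' @param observables named list: observable kind -> numeric time grid (s)
#' @param acq acquisition settings ([nvc_acq()]); the macaque BOLD setup
#'   (TE 20 ms, 4.7 T) is the package default
#' @param perturbation optional character vector for [apply_perturbation()]
#' @param overrides named numeric vector of setup-specific parameter values
#'   applied on top of the shared vector before simulating (the per-setup
#'   "unique" blocks of the studies' sharing structure)
#' @export
experiment_config <- function(study, variant, observables, acq = nvc_acq(),
                              perturbation = NULL, overrides = NULL) {
  stop_if(!all(names(observables) %in% observable_kinds),
          "unknown observable kind(s): ",
          paste(setdiff(names(observables), observable_kinds),
                collapse = ", "))
  structure(list(study = study, variant = variant,
                 paradigm = build_paradigm(study, variant),
                 observables = observables, acq = acq,
                 perturbation = perturbation, overrides = overrides,
                 id = paste(study, variant, sep = ":")),
            class = "experiment_config")
}

#' Simulate the observables of an experiment
#'
#' Runs the model under the experiment's paradigm and samples every
#' configured observable on its grid.
#'
#' @param params `nvc_params`
#' @param config [experiment_config()]
#' @param rtol,atol integrator tolerances
#' @return data.frame with columns experiment, observable, time, value,
#'   units; the full trajectory is attached as attribute `"sim"`
#' @export
simulate_observables <- function(params, config, rtol = 1e-8, atol = 1e-10) {
  if (!is.null(config$overrides)) {
    params <- set_theta(params, config$overrides)
  }
  if (!is.null(config$perturbation)) {
    params <- apply_perturbation(params, config$perturbation)
  }
  grids <- config$observables
  times <- sort(unique(c(0, unlist(grids))))
  sim <- simulate_nvc(params, config$paradigm, times,
                      rtol = rtol, atol = atol)
  out <- do.call(rbind, lapply(names(grids), function(kind) {
    series <- sim_observable(sim, kind, params, config$acq)
    data.frame(experiment = config$id, observable = kind,
               time = grids[[kind]],
               value = interp_series(sim$time, series, grids[[kind]]),
               units = observable_units[[kind]])
  }))
  attr(out, "sim") <- sim
  out
}

#' Write observable series to delimited text
#'
#' @param obs data.frame from [simulate_observables()]
#' @param path output path
#' @export
write_observables <- function(obs, path) {
  utils::write.csv(obs[, c("time", "observable", "value", "units")],
                   path, row.names = FALSE)
  invisible(path)
}
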