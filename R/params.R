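#' Default kinetic parameter values
#'
#' Named vector of the free (fittable) kinetic and vascular parameters with
#' the package's default values. The published model never reports fitted
#' values for these constants (only posterior profiles), so the defaults are
#' a documented reference set chosen to reproduce the mechanistic ordering of
#' the three vasoactive arms: fast NO, slower PGE2, slowest NPY (see the
#' methods vignette). All values are rates (1/s) or dimensionless gains in
#' the model's arbitrary concentration units.
#'
#' @return named numeric vector
#' @export
default_theta <- function() {
  c(
    # stimulus gains (per neuron channel)
    ku_NO = 0.4, ku_NPY = 0.3, ku_Pyr = 1,
    # pyramidal -> interneuron feed-forward, interneuron cross-inhibition,
    # interneuron -> pyramidal feedback
    kPF1 = 0.3, kPF2 = 0.2, kIN1 = 0.82, kIN2 = 0.3,
    kINF1 = 0.1, kINF2 = 0.48,
    # activity decay (NPY interneurons slowest: their build-up shapes the
    # NO decline and the LFP sag)
    sinkN_NO = 2, sinkN_NPY = 0.6, sinkN_Pyr = 1.5,
    # calcium elimination (inflow gain k_Ca is fixed, see nvc_params)
    sinkCa_NO = 4, sinkCa_NPY = 4, sinkCa_Pyr = 4,
    # pyramidal PGE2 cascade: the slow dilator
    kPL = 0.15, kCOX = 3, KmCOX = 2, kPGE2 = 0.18, sinkPGE2 = 0.18,
    # NO-interneuron cascade: the fast dilator (sinkNO must exceed 1/s)
    kNOS = 1, kNO = 2, sinkNO = 1.3,
    # NPY-interneuron cascade, Michaelis-Menten transfer: the slowest arm
    kNPY = 0.08, Vmax = 1, Km = 4, sinkNPY = 0.05,
    # vasoactive drive weights and metabolic gain
    ky_NO = 0.9, ky_PGE2 = 0.55, ky_NPY = 0.06,
    kmet = 0.15,
    # LFP scaling
    ky4 = 1,
    # Windkessel stiffness and viscoelasticity (capillary/venous compartments
    # slow and passive)
    Ka = 2, Kc = 4, Kv = 4,
    kvis_a = 1, kvis_c = 40, kvis_v = 40
  )
}

#' Construct a full model parameter object
#'
#' Bundles the free kinetic vector with the fixed model constants: the
#' calcium inflow gain (k_Ca = 10 for all three neurons), the per-channel
#' stimulus sign flags, the normalized Windkessel baselines
#' (V_i0 = 0.29/0.44/0.27, R_i0 = 0.74/0.08/0.18, boundary pressure 1), the
#' oxygen-transport constants, the baseline oxygen calibration, and the MR
#' acquisition settings. The resting steady state of the signaling network is
#' solved in closed form and stored.
#'
#' @param theta named numeric vector of free parameters; defaults from
#'   [default_theta()]. A partial vector overrides only the named entries.
#' @param sign length-3 vector of +-1 stimulus sign flags for the
#'   (NO, NPY, Pyr) channels; negative-response experiments flip them.
#' @param acq acquisition settings from [nvc_acq()]
#' @param o2_profile baseline oxygen partial-pressure profile passed to
#'   [calibrate_o2_baseline()]
#' @param check validate invariants (all rates positive, sinkNO > 1,
#'   stiffness > 1, positive signaling steady state)
#' @return an object of class `nvc_params`
#' @export
nvc_params <- function(theta = NULL, sign = c(1, 1, 1), acq = nvc_acq(),
                       o2_profile = default_o2_profile(), check = TRUE) {
  th <- default_theta()
  if (!is.null(theta)) {
    stop_if(is.null(names(theta)) || !all(names(theta) %in% names(th)),
            "unknown parameter name(s): ",
            paste(setdiff(names(theta), names(th)), collapse = ", "))
    th[names(theta)] <- theta
  }
  stop_if(length(sign) != 3L || !all(sign %in% c(-1, 1)),
          "sign must be three values in {-1, +1}")

  p <- list(
    theta = th,
    kCa = 10,
    sign = as.numeric(sign),
    wk = wk_baseline(),
    oxy = calibrate_o2_baseline(o2_profile),
    acq = acq
  )
  class(p) <- "nvc_params"
  if (check) validate_params(p)
  p$rest <- neuro_steady_state(p)
  p
}

validate_params <- function(p) {
  th <- p$theta
  stop_if(any(!is.finite(th)) || any(th <= 0),
          "all kinetic parameters must be finite and > 0")
  stop_if(th[["sinkNO"]] <= 1, "sinkNO must exceed 1 s^-1")
  stop_if(any(th[c("Ka", "Kc", "Kv")] <= 1), "stiffness K must exceed 1")
  # positive signaling steady state requires the saturable steps to outrun
  # their resting input
  ca_pyr0 <- p$kCa / th[["sinkCa_Pyr"]]
  stop_if(th[["kCOX"]] <= th[["kPL"]] * ca_pyr0,
          "kCOX must exceed kPL * resting pyramidal calcium ",
          "(no finite AA steady state otherwise)")
  ca_npy0 <- p$kCa / th[["sinkCa_NPY"]]
  stop_if(th[["Vmax"]] <= th[["kNPY"]] * ca_npy0,
          "Vmax must exceed kNPY * resting NPY-interneuron calcium ",
          "(no finite NPY steady state otherwise)")
  invisible(p)
}

#' Update free parameters of an existing parameter object
#'
#' @param p `nvc_params` object
#' @param theta named numeric vector (subset of free parameter names)
#' @param sign optional new sign flags
#' @return updated, re-validated `nvc_params`
#' @export
set_theta <- function(p, theta, sign = NULL) {
  stopifnot(inherits(p, "nvc_params"))
  th <- p$theta
  stop_if(!all(names(theta) %in% names(th)),
          "unknown parameter name(s): ",
          paste(setdiff(names(theta), names(th)), collapse = ", "))
  th[names(theta)] <- theta
  p$theta <- th
  if (!is.null(sign)) p$sign <- as.numeric(sign)
  validate_params(p)
  p$rest <- neuro_steady_state(p)
  p
}

#' Apply a pharmacological perturbation switch
#'
#' Boolean channel-cutting switches: `"bibp"` zeroes the NPY drive weight
#' (NPY receptor Y1 blockade), `"cnqx_ap5"` zeroes the pyramidal-to-
#' interneuron couplings (glutamatergic blockade). Weights are set to a tiny
#' positive floor rather than zero so the positivity invariants still hold;
#' the floor is far below any dynamic effect.
#'
#' @param p `nvc_params`
#' @param which character vector among `"bibp"`, `"cnqx_ap5"`
#' @export
apply_perturbation <- function(p, which) {
  eps <- 1e-12
  for (w in which) {
    p <- switch(w,
      bibp = set_theta(p, c(ky_NPY = eps)),
      cnqx_ap5 = set_theta(p, c(kPF1 = eps, kPF2 = eps)),
      stop("unknown perturbation: ", w, call. = FALSE)
    )
  }
  p
}

#' MR acquisition settings
#'
#' @param TE echo time (s)
#' @param B0 field strength (T)
#' @param lambda intravascular/extravascular spin-density ratio
#' @param R2e0 baseline extravascular transverse relaxation rate (1/s)
#' @param Hct_a,Hct_c,Hct_v compartment hematocrit
#' @param dchi susceptibility of fully deoxygenated blood
#' @param gam proton gyromagnetic ratio (rad/s/T)
#' @param SoffO2 saturation at which blood and tissue susceptibility match
#' @param Viv0 baseline intravascular volume fraction of the voxel
#' @export
nvc_acq <- function(TE = 0.020, B0 = 4.7, lambda = 1.15, R2e0 = 25.1,
                    Hct_a = 0.44, Hct_c = 0.33, Hct_v = 0.44,
                    dchi = 2.64e-7, gam = 2.68e8, SoffO2 = 0.95,
                    Viv0 = 0.05) {
  stop_if(TE <= 0 || B0 <= 0, "TE and B0 must be positive")
  stop_if(any(c(Hct_a, Hct_c, Hct_v) <= 0) || any(c(Hct_a, Hct_c, Hct_v) >= 1),
          "hematocrit must lie in (0, 1)")
  list(TE = TE, B0 = B0, lambda = lambda, R2e0 = R2e0,
       Hct = c(a = Hct_a, c = Hct_c, v = Hct_v),
       dchi = dchi, gam = gam, SoffO2 = SoffO2, Viv0 = Viv0)
}

#' Susceptibility-off acquisition configuration
#'
#' Returns a modified acquisition list in which blood is magnetically
#' indistinguishable from tissue: the deoxyhemoglobin susceptibility and the
#' intravascular quadratic relaxation coefficient are zero, the spin-density
#' ratio is 1 and the intravascular baseline relaxation equals the
#' extravascular rate. Under this configuration the BOLD signal is
#' identically zero for any trajectory, which serves as a structural null
#' check of the signal model.
#'
#' @param acq acquisition list from [nvc_acq()]
#' @export
susceptibility_off <- function(acq = nvc_acq()) {
  acq$dchi <- 0
  acq$lambda <- 1
  acq$force_Cstar0 <- TRUE   # zero the quadratic intravascular coefficient
  acq$force_Astar <- acq$R2e0
  acq
}

#' Default log10 parameter bounds
#'
#' The estimation works in log10 space with bounds \[-4.5, 4.5\] for every
#' free parameter unless overridden.
#'
#' @param pars parameter names (default: all free parameters)
#' @param lower,upper bounds in log10 units
#' @return data.frame with columns name, lower, upper
#' @export
default_bounds <- function(pars = names(default_theta()),
                           lower = -4.5, upper = 4.5) {
  data.frame(name = pars, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' @export
print.nvc_params <- function(x, ...) {
  cat("<nvc_params>\n")
  cat(" free parameters:", length(x$theta), "\n")
  cat(" sign flags (NO, NPY, Pyr):", x$sign, "\n")
  cat(" CMRO2_0:", signif(x$oxy$CMRO2_0, 4),
      " baseline OEF:", signif(x$oxy$OEF, 3), "\n")
  cat(" baseline saturations:",
      paste(sprintf("%s=%.3f", c("a", "c", "v"), x$oxy$S0), collapse = " "),
      "\n")
  invisible(x)
}

#' Read / write parameter files
#'
#' Flat key/value YAML files naming free parameters; unspecified values keep
#' the documented defaults. `sign` may be given as a length-3 list.
#'
#' @param path file path
#' @rdname param_io
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  sign <- vals$sign %||% c(1, 1, 1)
  vals$sign <- NULL
  nvc_params(theta = unlist(vals), sign = unlist(sign))
}

#' @param p `nvc_params`
#' @rdname param_io
#' @export
write_params <- function(p, path) {
  vals <- as.list(p$theta)
  vals$sign <- as.list(p$sign)
  yaml::write_yaml(vals, path)
  invisible(path)
}
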