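#' Oxygen-transport constants
#'
#' Fixed physicochemical constants of the oxygen module: the hemoglobin
#' half-saturation pressure p50 = 36 mmHg, Hill exponent h = 2.6, maximum
#' blood oxygen concentration 9.26 mM, tissue solubility 1.46 uM/mmHg,
#' tissue volume fraction 34.8 (same normalized volume units as the vascular
#' compartments) and the arterial inlet leak 0.116 mM.
#'
#' @export
o2_constants <- function() {
  list(p50 = 36, h = 2.6, cO2_max = 9.26,
       sigma = 1.46e-3,    # mM per mmHg
       Vt = 34.8, cO2_leak = 0.116)
}

#' Hemoglobin saturation curve: pressure and concentration
#'
#' `o2_pressure` inverts the Hill saturation curve,
#' pO2 = p50 (cO2_max / c - 1)^(-1/h), valid for 0 < c < cO2_max;
#' concentrations at or above cO2_max signal super-saturation and are
#' rejected. `o2_concentration` is the forward curve
#' c = cO2_max / (1 + (p50/p)^h). `o2_pressure_tissue` applies Henry's law
#' pO2 = c / sigma for dissolved tissue oxygen.
#'
#' @param c blood oxygen concentration (mM)
#' @param const constants from [o2_constants()]
#' @return partial pressure in mmHg (or mM for the inverse)
#' @rdname o2_curve
#' @export
o2_pressure <- function(c, const = o2_constants()) {
  stop_if(any(c <= 0), "oxygen concentration must be positive")
  stop_if(any(c >= const$cO2_max),
          "concentration at or above cO2_max: super-saturation")
  const$p50 * (const$cO2_max / c - 1)^(-1 / const$h)
}

#' @param p partial pressure (mmHg)
#' @rdname o2_curve
#' @export
o2_concentration <- function(p, const = o2_constants()) {
  stop_if(any(p <= 0), "partial pressure must be positive")
  const$cO2_max / (1 + (const$p50 / p)^const$h)
}

#' @rdname o2_curve
#' @export
o2_pressure_tissue <- function(c, const = o2_constants()) {
  c / const$sigma
}

#' Oxygen metabolism driven by neural activity
#'
#' CMRO2 = CMRO2_0 (1 + k_met (N_NO + N_NPY + N_Pyr)). A negative result is
#' rejected rather than clamped: it flags a k_met too large for the
#' trajectory's activity undershoot.
#'
#' @param N_sum summed neural activity N_NO + N_NPY + N_Pyr
#' @param params `nvc_params`
#' @export
cmro2 <- function(N_sum, params) {
  out <- params$oxy$CMRO2_0 * (1 + params$theta[["kmet"]] * N_sum)
  stop_if(any(out < 0),
          "negative CMRO2: kmet too large for this trajectory")
  out
}

#' Compartment oxygen saturation
#'
#' The saturation of a compartment is the average of its inlet and outlet
#' boundary concentrations divided by the maximum blood concentration, giving
#' a value in \[0, 1\].
#'
#' @param c_in,c_out boundary concentrations (mM)
#' @param const constants from [o2_constants()]
#' @export
o2_saturation <- function(c_in, c_out, const = o2_constants()) {
  s <- (c_in + c_out) / 2 / const$cO2_max
  if (any(s < 0 | s > 1)) {
    stop("saturation outside [0, 1]: boundary concentrations out of range",
         call. = FALSE)
  }
  s
}

#' Hemoglobin amounts per compartment
#'
#' In normalized volume units total hemoglobin tracks volume: HbT_i = V_i,
#' HbO_i = V_i S_i, HbR_i = V_i (1 - S_i); HbO + HbR = HbT identically.
#'
#' @param volumes length-3 volumes
#' @param saturations length-3 saturations in \[0, 1\]
#' @return list with HbT, HbO, HbR vectors
#' @export
hemoglobin_amounts <- function(volumes, saturations) {
  stop_if(any(saturations < 0 | saturations > 1),
          "saturations must lie in [0, 1]")
  list(HbT = volumes, HbO = volumes * saturations,
       HbR = volumes * (1 - saturations))
}

#' Default baseline oxygen partial-pressure profile
#'
#' Interface pressures (mmHg) used to calibrate the diffusion conductances
#' and basal metabolism. The published model derives these from measured
#' microvascular pO2 profiles that are not reprinted; the values shipped
#' here are synthetic stand-ins chosen so that (i) the arterial inlet leak
#' equals the documented 0.116 mM, (ii) the volume-weighted baseline
#' saturation is close to 0.60, matching the 60/40 uM oxy/deoxy hemoglobin
#' baseline split, and (iii) tissue pO2 lies below all mean vascular
#' pressures so every diffusion flux is directed into tissue.
#'
#' @return list with arterial pO2 and the a/c, c/v, outlet and tissue values
#' @export
default_o2_profile <- function() {
  list(pO2_art = 90, pO2_ac = 48, pO2_cv = 35, pO2_out = 32, pO2_t = 25,
       shunt_frac = 0.2)
}

#' Calibrate the baseline oxygen transport
#'
#' Solves the steady-state oxygen balance at rest (all flows 1, baseline
#' volumes) for the diffusion conductances g_a, g_c, g_v, g_s, the basal
#' metabolic rate CMRO2_0 and the arterial inlet concentration, such that the
#' supplied pO2 profile is an exact fixed point of the oxygen equations.
#' At rest the advective balance fixes each compartment's total wall loss;
#' `shunt_frac` apportions the arterial loss between tissue diffusion and the
#' arterio-venous shunt. Calibration is idempotent: recalibrating at the
#' returned fixed point reproduces the same constants.
#'
#' @param profile list from [default_o2_profile()]
#' @param const physicochemical constants
#' @param V0 baseline compartment volumes
#' @return list with conductances, CMRO2_0, inlet/boundary concentrations,
#'   baseline saturations S0, baseline amounts n0 and the implied oxygen
#'   extraction fraction OEF
#' @export
calibrate_o2_baseline <- function(profile = default_o2_profile(),
                                  const = o2_constants(),
                                  V0 = c(0.29, 0.44, 0.27)) {
  p_art <- profile$pO2_art
  cin_blood <- o2_concentration(p_art, const)       # cO2_in before the leak
  C_in <- cin_blood - const$cO2_leak                # effective inlet boundary
  stop_if(C_in <= 0, "leak exceeds arterial oxygen content")
  C_ac <- o2_concentration(profile$pO2_ac, const)
  C_cv <- o2_concentration(profile$pO2_cv, const)
  C_out <- o2_concentration(profile$pO2_out, const)
  stop_if(!(C_in > C_ac && C_ac > C_cv && C_cv > C_out),
          "profile must be strictly decreasing along the vascular tree")

  p_in <- o2_pressure(C_in, const)
  pbar <- c(a = (p_in + profile$pO2_ac) / 2,
            c = (profile$pO2_ac + profile$pO2_cv) / 2,
            v = (profile$pO2_cv + profile$pO2_out) / 2)
  p_t <- profile$pO2_t
  stop_if(any(pbar <= p_t),
          "infeasible profile: tissue pO2 above a mean vascular pO2")

  loss_a <- C_in - C_ac                  # arterial wall loss (flow = 1)
  j_s <- profile$shunt_frac * loss_a
  j_a <- loss_a - j_s
  j_c <- C_ac - C_cv
  j_v <- (C_cv - C_out) + j_s
  g <- c(a = j_a / (pbar[["a"]] - p_t),
         c = j_c / (pbar[["c"]] - p_t),
         v = j_v / (pbar[["v"]] - p_t),
         s = j_s / (pbar[["a"]] - pbar[["v"]]))

  CMRO2_0 <- j_a + j_c + j_v             # equals C_in - C_out
  S0 <- c(a = o2_saturation(C_in, C_ac, const),
          c = o2_saturation(C_ac, C_cv, const),
          v = o2_saturation(C_cv, C_out, const))
  n0 <- c(a = V0[1] * C_ac, c = V0[2] * C_cv, v = V0[3] * C_out,
          t = const$Vt * const$sigma * p_t)
  names(n0) <- c("a", "c", "v", "t")

  c(const, list(
    profile = profile, g = g, CMRO2_0 = CMRO2_0,
    cO2_in = cin_blood, C_in = C_in, p_in = p_in,
    C_bound = c(inlet = C_in, ac = C_ac, cv = C_cv, out = C_out),
    S0 = S0, n0 = n0, p_t0 = p_t,
    OEF = CMRO2_0 / cin_blood,
    S0_weighted = sum(V0 * S0) / sum(V0)
  ))
}

#' Read / write a calibration profile file
#'
#' Delimited text with columns `quantity, value` listing the baseline
#' interface pressures (mmHg) and the shunt fraction, overriding the
#' documented defaults.
#'
#' @param path file path
#' @rdname o2_profile_io
#' @export
read_o2_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("quantity", "value") %in% names(df)),
          "profile file needs columns quantity, value")
  prof <- default_o2_profile()
  unknown <- setdiff(df$quantity, names(prof))
  stop_if(length(unknown) > 0, "unknown profile quantities: ",
          paste(unknown, collapse = ", "))
  prof[df$quantity] <- as.list(df$value)
  prof
}

#' @param profile profile list as from [default_o2_profile()]
#' @rdname o2_profile_io
#' @export
write_o2_profile <- function(profile, path) {
  utils::write.csv(data.frame(quantity = names(profile),
                              value = unlist(profile)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Oxygen right-hand side
#'
#' Advection with outlet-boundary concentrations C_i = n_i / V_i (the inlet
#' boundary is the constant leak-corrected arterial concentration), diffusion
#' to tissue driven by mean compartment pO2 minus tissue pO2, an
#' arterio-venous shunt, and metabolic consumption in tissue.
#'
#' @param n named length-4 oxygen amounts (a, c, v, t)
#' @param f flows f0..f3 from the vascular closure
#' @param V length-3 compartment volumes
#' @param N_sum summed neural activity (for CMRO2)
#' @param params `nvc_params`
#' @return list with dn (length 4), boundary concentrations, fluxes j,
#'   CMRO2 and saturations S
#' @export
oxygen_rhs <- function(n, f, V, N_sum, params) {
  oxy <- params$oxy
  n <- as.numeric(n); f <- as.numeric(f); V <- as.numeric(V)
  C_ac <- n[1] / V[1]
  C_cv <- n[2] / V[2]
  C_out <- n[3] / V[3]
  C_t <- n[4] / oxy$Vt
  p_t <- C_t / oxy$sigma
  p_ac <- o2_pressure(C_ac, oxy)
  p_cv <- o2_pressure(C_cv, oxy)
  p_out <- o2_pressure(C_out, oxy)
  pbar <- c((oxy$p_in + p_ac) / 2, (p_ac + p_cv) / 2, (p_cv + p_out) / 2)
  j <- oxy$g[1:3] * (pbar - p_t)
  j_s <- oxy$g[["s"]] * (pbar[1] - pbar[3])
  met <- cmro2(N_sum, params)
  dn <- c(
    a = f[1] * oxy$C_in - f[2] * C_ac - j[[1]] - j_s,
    c = f[2] * C_ac - f[3] * C_cv - j[[2]],
    v = f[3] * C_cv - f[4] * C_out - j[[3]] + j_s,
    t = sum(j) - met
  )
  S <- c(a = o2_saturation(oxy$C_in, C_ac, oxy),
         c = o2_saturation(C_ac, C_cv, oxy),
         v = o2_saturation(C_cv, C_out, oxy))
  list(dn = dn, C = c(ac = C_ac, cv = C_cv, out = C_out, t = C_t),
       j = c(a = j[[1]], c = j[[2]], v = j[[3]], s = j_s),
       CMRO2 = met, S = S, p_t = p_t)
}
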