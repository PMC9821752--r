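#' Rectified neuronal activity
#'
#' The phenomenological activity states may be negative (suppression below
#' baseline); wherever an activity feeds a coupling term it is first passed
#' through a hard rectifier E = max(N, 0). The rectifier is applied exactly,
#' not smoothed, so no extra shape parameter is introduced.
#'
#' @param N activity value(s)
#' @return rectified value(s)
#' @export
rectify_activity <- function(N) {
  stop_if(any(!is.finite(N)), "non-finite activity: upstream numerical failure")
  pmax(N, 0)
}

neuro_state_names <- c("N_NO", "N_NPY", "N_Pyr", "Ca_NO", "Ca_NPY", "Ca_Pyr",
                       "AA", "PGE2", "PGE2_vsm", "NO", "NO_vsm",
                       "NPY", "NPY_vsm")

#' Time derivatives of the neuronal and signaling states
#'
#' Implements the coupled activity/calcium equations and the three
#' intracellular vasoactive cascades. Pyramidal activity excites both
#' interneuron classes (rectified), the interneurons cross-inhibit each other
#' (rectified), and both interneuron activities feed back negatively on the
#' pyramidal population (unrectified, as only the rectified couplings are
#' written with E). Calcium follows dCa/dt = k_Ca (1 + N) - sink_Ca Ca.
#' The pyramidal arm converts calcium to arachidonic acid and on to PGE2
#' acting on vascular smooth muscle; the NO arm is a linear two-step chain;
#' the NPY arm transfers via Michaelis-Menten kinetics.
#'
#' @param state named numeric vector containing the 13 neuro/signaling fields
#' @param params `nvc_params`
#' @param u length-3 stimulus values in \{0, 1\} for the (NO, NPY, Pyr)
#'   channels; scaled internally by k_u,i and the sign flags
#' @return named vector of derivatives (same order as `state`)
#' @export
neuro_rhs <- function(state, params, u = c(0, 0, 0)) {
  th <- params$theta
  s <- as.list(state[neuro_state_names])
  E_Pyr <- rectify_activity(s$N_Pyr)
  E_NO <- rectify_activity(s$N_NO)
  E_NPY <- rectify_activity(s$N_NPY)
  uin <- th[c("ku_NO", "ku_NPY", "ku_Pyr")] * params$sign * u

  mm_npy <- th[["Vmax"]] * s$NPY / (th[["Km"]] + s$NPY)
  mm_aa <- th[["kCOX"]] * s$AA / (th[["KmCOX"]] + s$AA)

  d <- c(
    N_NO  = uin[[1]] + th[["kPF1"]] * E_Pyr - th[["kIN1"]] * E_NPY -
      th[["sinkN_NO"]] * s$N_NO,
    N_NPY = uin[[2]] + th[["kPF2"]] * E_Pyr - th[["kIN2"]] * E_NO -
      th[["sinkN_NPY"]] * s$N_NPY,
    N_Pyr = uin[[3]] - th[["kINF1"]] * s$N_NO - th[["kINF2"]] * s$N_NPY -
      th[["sinkN_Pyr"]] * s$N_Pyr,
    Ca_NO  = params$kCa * (1 + s$N_NO) - th[["sinkCa_NO"]] * s$Ca_NO,
    Ca_NPY = params$kCa * (1 + s$N_NPY) - th[["sinkCa_NPY"]] * s$Ca_NPY,
    Ca_Pyr = params$kCa * (1 + s$N_Pyr) - th[["sinkCa_Pyr"]] * s$Ca_Pyr,
    AA = th[["kPL"]] * s$Ca_Pyr - mm_aa,
    PGE2 = mm_aa - th[["kPGE2"]] * s$PGE2,
    PGE2_vsm = th[["kPGE2"]] * s$PGE2 - th[["sinkPGE2"]] * s$PGE2_vsm,
    NO = th[["kNOS"]] * s$Ca_NO - th[["kNO"]] * s$NO,
    NO_vsm = th[["kNO"]] * s$NO - th[["sinkNO"]] * s$NO_vsm,
    NPY = th[["kNPY"]] * s$Ca_NPY - mm_npy,
    NPY_vsm = mm_npy - th[["sinkNPY"]] * s$NPY_vsm
  )
  if (any(!is.finite(d))) {
    bad <- neuro_state_names[!is.finite(d)]
    stop("NaN derivative for state component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d
}

#' Resting steady state of the signaling network
#'
#' With zero stimulus the activity equations vanish at N = 0, which makes the
#' resting network triangular: calcium, then each cascade, can be solved in
#' closed form. The residual of the full right-hand side at the returned
#' state is checked against 1e-9.
#'
#' @param params `nvc_params`
#' @return named vector of the 13 resting neuro/signaling values
#' @export
neuro_steady_state <- function(params) {
  th <- params$theta
  ca0 <- params$kCa / th[c("sinkCa_NO", "sinkCa_NPY", "sinkCa_Pyr")]
  s_pl <- th[["kPL"]] * ca0[[3]]          # resting AA production
  AA0 <- th[["KmCOX"]] * s_pl / (th[["kCOX"]] - s_pl)
  w <- th[["kNPY"]] * ca0[[2]]            # resting NPY production
  NPY0 <- th[["Km"]] * w / (th[["Vmax"]] - w)
  rest <- c(
    N_NO = 0, N_NPY = 0, N_Pyr = 0,
    Ca_NO = ca0[[1]], Ca_NPY = ca0[[2]], Ca_Pyr = ca0[[3]],
    AA = AA0,
    PGE2 = s_pl / th[["kPGE2"]],
    PGE2_vsm = s_pl / th[["sinkPGE2"]],
    NO = th[["kNOS"]] * ca0[[1]] / th[["kNO"]],
    NO_vsm = th[["kNOS"]] * ca0[[1]] / th[["sinkNO"]],
    NPY = NPY0,
    NPY_vsm = w / th[["sinkNPY"]]
  )
  res <- neuro_rhs(rest, params, u = c(0, 0, 0))
  stop_if(max(abs(res)) >= 1e-9,
          "resting steady state residual above tolerance: ",
          format(max(abs(res))))
  rest
}

#' Total vasoactive drive G
#'
#' Deviations of the three vascular-smooth-muscle species from their resting
#' values, weighted and summed: NO and PGE2 dilate (positive weights), NPY
#' constricts (negative weight). G may be negative (net constriction).
#'
#' @param signaling named vector containing NO_vsm, PGE2_vsm, NPY_vsm
#' @param baseline resting state of the same parameter vector (defaults to
#'   the stored resting state); a baseline solved under different parameters
#'   is rejected
#' @param params `nvc_params`
#' @export
vasoactive_drive <- function(signaling, params, baseline = params$rest) {
  res <- neuro_rhs(baseline, params, u = c(0, 0, 0))
  stop_if(max(abs(res)) >= 1e-8,
          "baseline is not a resting state of these parameters")
  th <- params$theta
  th[["ky_NO"]] * (signaling[["NO_vsm"]] - baseline[["NO_vsm"]]) +
    th[["ky_PGE2"]] * (signaling[["PGE2_vsm"]] - baseline[["PGE2_vsm"]]) -
    th[["ky_NPY"]] * (signaling[["NPY_vsm"]] - baseline[["NPY_vsm"]])
}
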