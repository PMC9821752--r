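state_names <- c(neuro_state_names, "V_a", "V_c", "V_v",
                 "nO2_a", "nO2_c", "nO2_v", "nO2_t")
budget_names <- c("Q_in", "Q_out", "Q_met", "Q_flow")

#' Initial (resting) model state
#'
#' Closed-form resting signaling state, baseline volumes and calibrated
#' baseline oxygen amounts. Optionally appends the four cumulative budget
#' states (advective influx, efflux, metabolized oxygen and net blood
#' inflow) used by the conservation checks.
#'
#' @param params `nvc_params`
#' @param budget include cumulative budget states
#' @export
nvc_initial_state <- function(params, budget = FALSE) {
  y <- c(params$rest,
         V_a = params$wk$V0[["a"]], V_c = params$wk$V0[["c"]],
         V_v = params$wk$V0[["v"]],
         nO2_a = params$oxy$n0[["a"]], nO2_c = params$oxy$n0[["c"]],
         nO2_v = params$oxy$n0[["v"]], nO2_t = params$oxy$n0[["t"]])
  if (budget) y <- c(y, Q_in = 0, Q_out = 0, Q_met = 0, Q_flow = 0)
  y
}

# flat evaluation context: every scalar the combined right-hand side needs
build_ctx <- function(params) {
  th <- as.list(params$theta)
  wk <- params$wk
  oxy <- params$oxy
  rest <- params$rest
  c(th, list(
    kCa = params$kCa, sign = params$sign,
    l = wk$l, pel0 = wk$pel0, V0 = wk$V0, dp_r = wk$dp_r,
    K = c(th$Ka, th$Kc, th$Kv), kvis = c(th$kvis_a, th$kvis_c, th$kvis_v),
    g = oxy$g, CMRO2_0 = oxy$CMRO2_0, C_in = oxy$C_in, p_in = oxy$p_in,
    Vt = oxy$Vt, sigma = oxy$sigma, p50 = oxy$p50, h = oxy$h,
    cO2_max = oxy$cO2_max,
    NOv0 = rest[["NO_vsm"]], PGE2v0 = rest[["PGE2_vsm"]],
    NPYv0 = rest[["NPY_vsm"]]
  ))
}

# combined right-hand side; u is the per-channel stimulus value for the
# current constant segment, passed via parms = list(ctx, u, budget)
nvc_ode <- function(t, y, parms) {
  cx <- parms$ctx
  u <- parms$u
  y <- unname(y)
  E1 <- max(y[1], 0); E2 <- max(y[2], 0); E3 <- max(y[3], 0)
  uin <- c(cx$ku_NO, cx$ku_NPY, cx$ku_Pyr) * cx$sign * u
  mm_aa <- cx$kCOX * y[7] / (cx$KmCOX + y[7])
  mm_npy <- cx$Vmax * y[12] / (cx$Km + y[12])
  dy <- numeric(length(y))
  dy[1] <- uin[1] + cx$kPF1 * E3 - cx$kIN1 * E2 - cx$sinkN_NO * y[1]
  dy[2] <- uin[2] + cx$kPF2 * E3 - cx$kIN2 * E1 - cx$sinkN_NPY * y[2]
  dy[3] <- uin[3] - cx$kINF1 * y[1] - cx$kINF2 * y[2] - cx$sinkN_Pyr * y[3]
  dy[4] <- cx$kCa * (1 + y[1]) - cx$sinkCa_NO * y[4]
  dy[5] <- cx$kCa * (1 + y[2]) - cx$sinkCa_NPY * y[5]
  dy[6] <- cx$kCa * (1 + y[3]) - cx$sinkCa_Pyr * y[6]
  dy[7] <- cx$kPL * y[6] - mm_aa
  dy[8] <- mm_aa - cx$kPGE2 * y[8]
  dy[9] <- cx$kPGE2 * y[8] - cx$sinkPGE2 * y[9]
  dy[10] <- cx$kNOS * y[4] - cx$kNO * y[10]
  dy[11] <- cx$kNO * y[10] - cx$sinkNO * y[11]
  dy[12] <- cx$kNPY * y[5] - mm_npy
  dy[13] <- mm_npy - cx$sinkNPY * y[13]

  g_NO <- cx$ky_NO * (y[11] - cx$NOv0)
  g_PGE2 <- cx$ky_PGE2 * (y[9] - cx$PGE2v0)
  g_NPY <- -cx$ky_NPY * (y[13] - cx$NPYv0)
  G <- g_NO + g_PGE2 + g_NPY

  V <- y[14:16]
  if (any(V <= 0)) stop("vessel collapse: V <= 0", call. = FALSE)
  r <- cx$l^3 / V^2
  pel <- cx$pel0 * (V / cx$V0)^cx$K
  a1 <- (r[1] + r[2]) / 2; a2 <- (r[2] + r[3]) / 2; a3 <- r[3] / 2
  A <- matrix(0, 7, 7)
  A[1, 1] <- cx$kvis[1]; A[1, 5] <- -a1; A[1, 6] <- -a2; A[1, 7] <- -a3
  A[2, 2] <- cx$kvis[2]; A[2, 6] <- -a2; A[2, 7] <- -a3
  A[3, 3] <- cx$kvis[3]; A[3, 7] <- -a3
  A[4, 1] <- 1; A[4, 4] <- -1; A[4, 5] <- 1
  A[5, 2] <- 1; A[5, 5] <- -1; A[5, 6] <- 1
  A[6, 3] <- 1; A[6, 6] <- -1; A[6, 7] <- 1
  A[7, 4] <- r[1]; A[7, 5] <- 2 * a1; A[7, 6] <- 2 * a2; A[7, 7] <- 2 * a3
  b <- c(G - pel[1], -pel[2], -pel[3], 0, 0, 0, 2 * cx$dp_r)
  x <- solve(A, b)
  dy[14:16] <- x[1:3]
  f <- x[4:7]
  dp <- r * (f[1:3] + f[2:4]) / 2

  # oxygen
  C_ac <- y[17] / V[1]; C_cv <- y[18] / V[2]; C_out <- y[19] / V[3]
  if (C_ac <= 0 || C_cv <= 0 || C_out <= 0)
    stop("oxygen amount depleted", call. = FALSE)
  if (C_ac >= cx$cO2_max || C_cv >= cx$cO2_max || C_out >= cx$cO2_max)
    stop("oxygen super-saturation", call. = FALSE)
  p_ac <- cx$p50 * (cx$cO2_max / C_ac - 1)^(-1 / cx$h)
  p_cv <- cx$p50 * (cx$cO2_max / C_cv - 1)^(-1 / cx$h)
  p_out <- cx$p50 * (cx$cO2_max / C_out - 1)^(-1 / cx$h)
  p_t <- (y[20] / cx$Vt) / cx$sigma
  pbar_a <- (cx$p_in + p_ac) / 2
  pbar_c <- (p_ac + p_cv) / 2
  pbar_v <- (p_cv + p_out) / 2
  j_a <- cx$g[[1]] * (pbar_a - p_t)
  j_c <- cx$g[[2]] * (pbar_c - p_t)
  j_v <- cx$g[[3]] * (pbar_v - p_t)
  j_s <- cx$g[[4]] * (pbar_a - pbar_v)
  met <- cx$CMRO2_0 * (1 + cx$kmet * (y[1] + y[2] + y[3]))
  dy[17] <- f[1] * cx$C_in - f[2] * C_ac - j_a - j_s
  dy[18] <- f[2] * C_ac - f[3] * C_cv - j_c
  dy[19] <- f[3] * C_cv - f[4] * C_out - j_v + j_s
  dy[20] <- j_a + j_c + j_v - met

  if (parms$budget) {
    dy[21] <- f[1] * cx$C_in
    dy[22] <- f[4] * C_out
    dy[23] <- met
    dy[24] <- f[1] - f[4]
  }

  aux <- c(G = G, f0 = f[1], f1 = f[2], f2 = f[3], f3 = f[4],
           dp_sum = sum(dp),
           S_a = (cx$C_in + C_ac) / 2 / cx$cO2_max,
           S_c = (C_ac + C_cv) / 2 / cx$cO2_max,
           S_v = (C_cv + C_out) / 2 / cx$cO2_max,
           CMRO2 = met, p_t = p_t,
           g_NO = g_NO, g_PGE2 = g_PGE2, g_NPY = g_NPY)
  list(dy, aux)
}

#' Simulate the full neurovascular model
#'
#' Integrates the coupled neuronal, signaling, vascular and oxygen equations
#' over the requested output times under a stimulus paradigm. The stimulus
#' on/off switches partition the horizon into constant-input segments that
#' are integrated piecewise, so the square-pulse discontinuities are handled
#' exactly; the activity rectifier's kinks are exact in the right-hand side
#' and resolved by the adaptive step control.
#'
#' @param params `nvc_params`
#' @param paradigm a [stimulus_paradigm()]; its sign flags override the ones
#'   stored in `params` unless `use_param_sign = TRUE`
#' @param times strictly increasing output times (s); times before the first
#'   stimulus hold the resting state
#' @param budget append cumulative oxygen/blood budget states
#' @param rtol,atol integrator tolerances (lsoda)
#' @param use_param_sign keep the sign flags stored in `params`
#' @param vascular_switch optional nonlinear-vessel variant: a list with a
#'   switch time `time` (s) and replacement values among `Kc`, `Kv`,
#'   `kvis_c`, `kvis_v`; from the switch time onwards the capillary/venous
#'   stiffness and viscoelasticity take the replacement values (off by
#'   default)
#' @return data.frame of class `nvc_sim` with the state trajectories plus
#'   the drive G, its three signed arm contributions, flows f0..f3, the
#'   pressure-boundary sum, compartment saturations, CMRO2 and tissue pO2
#' @export
simulate_nvc <- function(params, paradigm, times, budget = FALSE,
                         rtol = 1e-8, atol = 1e-10, use_param_sign = FALSE,
                         vascular_switch = NULL) {
  stopifnot(inherits(params, "nvc_params"),
            inherits(paradigm, "stimulus_paradigm"))
  stop_if(is.unsorted(times, strictly = TRUE),
          "times must be strictly increasing")
  if (!use_param_sign) params$sign <- paradigm$sign
  ctx <- build_ctx(params)
  ctx_late <- NULL
  if (!is.null(vascular_switch)) {
    stop_if(is.null(vascular_switch$time), "vascular_switch needs a time")
    allowed <- intersect(names(vascular_switch),
                         c("Kc", "Kv", "kvis_c", "kvis_v"))
    p2 <- set_theta(params, unlist(vascular_switch[allowed]))
    ctx_late <- build_ctx(p2)
  }
  y0 <- nvc_initial_state(params, budget = budget)

  t0 <- min(times[1], 0)
  tend <- times[length(times)]
  bp <- stimulus_breakpoints(paradigm)
  if (!is.null(vascular_switch)) bp <- c(bp, vascular_switch$time)
  bp <- sort(unique(bp[bp > t0 & bp < tend]))
  seg_edges <- unique(c(t0, bp, tend))

  out <- NULL
  collected <- numeric(0)
  y <- y0
  for (k in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[k]; b <- seg_edges[k + 1]
    u <- stimulus_value(paradigm, (a + b) / 2)
    cx <- if (!is.null(ctx_late) && a >= vascular_switch$time) ctx_late
          else ctx
    tt <- unique(c(a, times[times >= a & times <= b], b))
    sol <- deSolve::lsoda(y, tt, nvc_ode,
                          parms = list(ctx = cx, u = u, budget = budget),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    stop_if(attr(sol, "istate")[1] < 0, "integration failed in segment ",
            k, " [", a, ", ", b, "]")
    y <- sol[nrow(sol), 1 + seq_along(y)]
    keep <- sol[, 1] %in% times & !(sol[, 1] %in% collected)
    out <- rbind(out, sol[keep, , drop = FALSE])
    collected <- c(collected, sol[keep, 1])
  }
  df <- as.data.frame(out)
  nm <- c(state_names, if (budget) budget_names)
  names(df) <- c("time", nm, names(df)[-seq_len(1 + length(nm))])
  if (any(df[paste0("Ca_", c("NO", "NPY", "Pyr"))] < -1e-9)) {
    warning("negative intracellular calcium encountered: ",
            "activity undershoot beyond the model's validity range")
  }
  attr(df, "params") <- params
  attr(df, "paradigm") <- paradigm
  class(df) <- c("nvc_sim", "data.frame")
  df
}

#' @export
print.nvc_sim <- function(x, ...) {
  cat("<nvc_sim> ", nrow(x), " time points over [",
      min(x$time), ", ", max(x$time), "] s, paradigm ",
      attr(x, "paradigm")$label, "\n", sep = "")
  invisible(x)
}

#' Write a simulated trajectory to delimited text
#'
#' Columns: time, the three volumes, the four flows and the drive G.
#'
#' @param sim `nvc_sim`
#' @param path output path
#' @export
write_trajectory <- function(sim, path) {
  utils::write.csv(sim[, c("time", "V_a", "V_c", "V_v",
                           paste0("f", 0:3), "G")],
                   path, row.names = FALSE)
  invisible(path)
}
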