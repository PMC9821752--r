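#' Baseline quantities of the three-compartment Windkessel
#'
#' All vascular variables are normalized: baseline volumes sum to 1, baseline
#' flows are 1, baseline resistances sum to 1, and the arterio-venous
#' boundary pressure difference is 1. From the normalized baselines the entry
#' pressures, secant compliances and segment lengths follow:
#' p_a0 = dp_r, p_i0 = dp_r - sum of upstream resistances;
#' C_i0 = V_i0 / (p_i0 - r_i0 f_i0 / 2)  (volume over mid-compartment
#' pressure); l_i = (r_i0 V_i0^2)^(1/3) so that r_i = l_i^3 / V_i^2 recovers
#' r_i0 at rest.
#'
#' @param V0 baseline volumes (arterial, capillary, venous)
#' @param R0 baseline resistances
#' @param dp_r boundary pressure difference (normalized)
#' @return list with V0, r0, dp_r, entry pressures p0, mid-compartment
#'   pressures pmid0, compliances C0, lengths l, and the elastic pressure
#'   scale pel0 = V0 / C0
#' @export
wk_baseline <- function(V0 = c(0.29, 0.44, 0.27),
                        R0 = c(0.74, 0.08, 0.18), dp_r = 1) {
  stop_if(abs(sum(V0) - 1) > 1e-9 || abs(sum(R0) - 1) > 1e-9,
          "normalized baselines must satisfy sum(V0) = sum(R0) = 1")
  p0 <- dp_r - c(0, cumsum(R0)[1:2])           # entry pressures a, c, v
  pmid0 <- p0 - R0 / 2                         # baseline flows are 1
  stop_if(any(pmid0 <= 0),
          "nonpositive compliance denominator: inconsistent baseline constants")
  C0 <- V0 / pmid0
  l <- (R0 * V0^2)^(1 / 3)
  names(V0) <- names(R0) <- names(p0) <- names(pmid0) <- names(C0) <-
    names(l) <- c("a", "c", "v")
  list(V0 = V0, r0 = R0, dp_r = dp_r, p0 = p0, pmid0 = pmid0,
       C0 = C0, l = l, pel0 = V0 / C0)
}

#' Instantaneous resistance from volume
#'
#' Poiseuille scaling at fixed segment length: r = l^3 / V^2.
#'
#' @param l segment length (normalized)
#' @param V compartment volume (> 0)
#' @export
resistance_from_volume <- function(l, V) {
  stop_if(any(V <= 0), "vessel collapse (V <= 0) is outside the model domain")
  l^3 / V^2
}

#' Inflow solved from the pressure boundary condition
#'
#' The total pressure drop over the three compartments equals the boundary
#' pressure dp_r; solving the half-resistance drops for the arterial inflow
#' gives f0 = (2 dp_r - ((r1+r2) f1 + (r2+r3) f2 + r3 f3)) / r1.
#'
#' @param r length-3 instantaneous resistances
#' @param f length-3 downstream flows (f1, f2, f3)
#' @param dp_r boundary pressure
#' @export
solve_inflow <- function(r, f, dp_r = 1) {
  stop_if(r[[1]] <= 0, "arterial resistance must be positive")
  (2 * dp_r - ((r[[1]] + r[[2]]) * f[[1]] + (r[[2]] + r[[3]]) * f[[2]] +
                 r[[3]] * f[[3]])) / r[[1]]
}

# mid-compartment pressures expressed through downstream flows; these are the
# flow brackets of the volume equations (each equals half the printed bracket)
wk_pmid <- function(r, f123) {
  c(a = ((r[[1]] + r[[2]]) * f123[[1]] + (r[[2]] + r[[3]]) * f123[[2]] +
           r[[3]] * f123[[3]]) / 2,
    c = ((r[[2]] + r[[3]]) * f123[[2]] + r[[3]] * f123[[3]]) / 2,
    v = r[[3]] * f123[[3]] / 2)
}

#' Vascular right-hand side: the DAE closed as a linear solve
#'
#' The three viscoelastic volume balances
#' k_vis,i dV_i/dt = pmid_i - pel_i(V_i) + G (arterial only), with elastic
#' pressure pel_i(V) = (V_i0/C_i0) (V/V_i0)^K_i, together with flow
#' conservation f_i = f_(i-1) - dV_i/dt and the pressure boundary condition,
#' form an index-1 DAE that is linear in the seven unknowns
#' (dVa, dVc, dVv, f0..f3) once the volumes are given. The closure solves
#' that 7x7 system exactly at every evaluation, so the algebraic constraints
#' hold to linear-solver precision along the trajectory.
#'
#' @param V named/unnamed length-3 volumes (a, c, v)
#' @param G vasoactive drive (finite scalar)
#' @param params `nvc_params`
#' @return list with dV (length 3), f (f0..f3), r, pmid, pel, dp (per-segment
#'   pressure drops)
#' @export
vascular_rhs <- function(V, G, params) {
  stopifnot(inherits(params, "nvc_params"))
  wk <- params$wk
  th <- params$theta
  stop_if(!is.finite(G), "drive G must be finite")
  V <- as.numeric(V)
  r <- resistance_from_volume(wk$l, V)
  K <- th[c("Ka", "Kc", "Kv")]
  kvis <- th[c("kvis_a", "kvis_c", "kvis_v")]
  pel <- wk$pel0 * (V / wk$V0)^K

  # unknowns x = (dVa, dVc, dVv, f0, f1, f2, f3)
  A <- matrix(0, 7, 7)
  b <- numeric(7)
  half <- c(r[[1]] + r[[2]], r[[2]] + r[[3]], r[[3]]) / 2
  A[1, 1] <- kvis[[1]]; A[1, 5:7] <- -half;          b[1] <- G - pel[[1]]
  A[2, 2] <- kvis[[2]]; A[2, 6:7] <- -half[2:3];     b[2] <- -pel[[2]]
  A[3, 3] <- kvis[[3]]; A[3, 7] <- -half[[3]];       b[3] <- -pel[[3]]
  A[4, c(1, 4, 5)] <- c(1, -1, 1)
  A[5, c(2, 5, 6)] <- c(1, -1, 1)
  A[6, c(3, 6, 7)] <- c(1, -1, 1)
  A[7, 4:7] <- c(r[[1]], 2 * half)
  b[7] <- 2 * wk$dp_r
  x <- solve(A, b)

  f <- x[4:7]
  pmid <- wk_pmid(r, f[2:4])
  dp <- r * (f[1:3] + f[2:4]) / 2
  list(dV = stats::setNames(x[1:3], c("a", "c", "v")),
       f = stats::setNames(f, paste0("f", 0:3)),
       r = stats::setNames(r, c("a", "c", "v")),
       pmid = pmid, pel = stats::setNames(pel, c("a", "c", "v")), dp = dp)
}

#' Residual form of the vascular DAE
#'
#' Independent check of the linear-solve closure: given candidate derivatives
#' and flows, returns the seven residuals of the volume balances, the flow
#' conservation relations and the pressure boundary condition.
#'
#' @param dV candidate volume derivatives (length 3)
#' @param V volumes (length 3)
#' @param f candidate flows f0..f3 (length 4)
#' @param G drive
#' @param params `nvc_params`
#' @return numeric length-7 residual vector
#' @export
wk_residual <- function(dV, V, f, G, params) {
  wk <- params$wk
  th <- params$theta
  r <- resistance_from_volume(wk$l, as.numeric(V))
  K <- th[c("Ka", "Kc", "Kv")]
  kvis <- th[c("kvis_a", "kvis_c", "kvis_v")]
  pel <- wk$pel0 * (as.numeric(V) / wk$V0)^K
  pmid <- wk_pmid(r, f[2:4])
  c(kvis * dV - (pmid - pel + c(G, 0, 0)),
    dV - (f[1:3] - f[2:4]),
    sum(r * (f[1:3] + f[2:4]) / 2) - wk$dp_r)
}
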