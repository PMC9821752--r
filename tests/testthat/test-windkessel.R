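test_that("baseline derivation reproduces the hand-computed constants", {
  wk <- wk_baseline()
  expect_equal(unname(wk$p0[["a"]]), 1)
  expect_equal(unname(wk$p0[["c"]]), 0.26)
  expect_equal(unname(wk$p0[["v"]]), 0.18)
  expect_equal(unname(wk$l[["a"]]), (0.74 * 0.29^2)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(round(unname(wk$l[["a"]]), 4), 0.3963)
  # compliances: volume over mid-compartment pressure
  expect_equal(unname(wk$C0), unname(wk$V0 / (wk$p0 - wk$r0 / 2)),
               tolerance = 1e-12)
  expect_error(wk_baseline(V0 = c(0.5, 0.3, 0.3)), "normalized")
})

test_that("resistance-volume power law inverts the baseline lengths", {
  wk <- wk_baseline()
  expect_equal(unname(resistance_from_volume(wk$l, wk$V0)), unname(wk$r0),
               tolerance = 1e-12)
  expect_equal(resistance_from_volume(1, 1), 1)
  expect_equal(resistance_from_volume(1, 2), 1 / 4)
  expect_error(resistance_from_volume(1, -1), "collapse")
})

test_that("inflow solution satisfies the pressure boundary condition", {
  wk <- wk_baseline()
  expect_equal(solve_inflow(wk$r0, c(1, 1, 1)), 1, tolerance = 1e-12)
  expect_equal(solve_inflow(wk$r0, c(0, 0, 0)), 2 / wk$r0[[1]])
  # random flows: the pressure drops computed with the returned f0 sum to 1
  set.seed(42)
  for (i in 1:20) {
    f123 <- runif(3, 0.5, 1.5)
    r <- runif(3, 0.05, 0.8)
    f0 <- solve_inflow(r, f123)
    f <- c(f0, f123)
    dp <- r * (f[1:3] + f[2:4]) / 2
    expect_equal(sum(dp), 1, tolerance = 1e-12)
  }
})

test_that("the vascular closure has the baseline as fixed point and the right signs", {
  wk <- ref_params$wk
  at_rest <- vascular_rhs(wk$V0, G = 0, ref_params)
  expect_lt(max(abs(at_rest$dV)), 1e-12)
  expect_equal(unname(at_rest$f), rep(1, 4), tolerance = 1e-12)
  expect_equal(sum(at_rest$dp), 1, tolerance = 1e-12)

  # a sudden positive drive dilates the arterial compartment; the flows
  # adjust instantaneously, so the downstream derivatives are only
  # second-order small rather than exactly zero
  dil <- vascular_rhs(wk$V0, G = 0.2, ref_params)
  expect_gt(dil$dV[["a"]], 0)
  expect_lt(abs(dil$dV[["c"]]), 0.01 * dil$dV[["a"]])
  expect_lt(abs(dil$dV[["v"]]), 0.01 * dil$dV[["a"]])
})

test_that("reduced-ODE closure satisfies the residual form of the DAE", {
  set.seed(7)
  for (i in 1:25) {
    V <- ref_params$wk$V0 * runif(3, 0.8, 1.25)
    G <- runif(1, -0.2, 0.6)
    out <- vascular_rhs(V, G, ref_params)
    res <- wk_residual(out$dV, V, out$f, G, ref_params)
    expect_lt(max(abs(res)), 1e-10)
    # blood conservation is built into the closure
    expect_equal(sum(out$dV), out$f[["f0"]] - out$f[["f3"]],
                 tolerance = 1e-10)
  }
})

test_that("mass conservation and pressure boundary hold along a trajectory", {
  sim <- ref_sim_long
  # budget state Q_flow integrates f0 - f3; it must match the volume change
  dV <- with(sim, V_a + V_c + V_v) - 1
  expect_lt(max(abs(dV - sim$Q_flow)), 1e-6)
  expect_lt(max(abs(sim$dp_sum - 1)), 1e-8)
})

test_that("a sustained drive dilates to a plateau and releases without drift", {
  # constant G applied directly to the vascular subsystem
  p <- ref_params
  f <- function(t, y, parms) list(vascular_rhs(y, parms, p)$dV)
  wk <- p$wk
  on <- deSolve::lsoda(unname(wk$V0), seq(0, 60, 0.5), f, parms = 0.3,
                       rtol = 1e-10, atol = 1e-12)
  Va <- on[, 2]
  expect_gt(Va[nrow(on)], Va[1])
  # plateau: last 10 s change below 0.1% of the excursion
  expect_lt(abs(Va[121] - Va[101]), 0.001 * (max(Va) - Va[1]))
  # release from the dilated state: return to baseline within 0.1%, no drift
  off <- deSolve::lsoda(on[nrow(on), -1], seq(0, 300, 1), f, parms = 0,
                        rtol = 1e-10, atol = 1e-12)
  Vend <- off[nrow(off), -1]
  expect_lt(max(abs(Vend - wk$V0) / wk$V0), 0.001)
})

test_that("venous volume peaks no earlier than arterial volume", {
  sim <- simulate_nvc(ref_params, build_paradigm("drew", "mid"),
                      seq(0, 40, 0.25))
  t_a <- sim$time[which.max(sim$V_a)]
  t_v <- sim$time[which.max(sim$V_v)]
  expect_gte(t_v, t_a)
})

test_that("the stiffness-switch variant changes only post-switch dynamics", {
  par10 <- build_paradigm("drew", "mid")
  tt <- seq(0, 40, 0.5)
  base <- simulate_nvc(ref_params, par10, tt)
  sw <- simulate_nvc(ref_params, par10, tt,
                     vascular_switch = list(time = 2, Kc = 8, Kv = 8,
                                            kvis_c = 10, kvis_v = 10))
  pre <- tt <= 2
  expect_equal(sw$V_v[pre], base$V_v[pre], tolerance = 1e-8)
  expect_gt(max(abs(sw$V_v[!pre] - base$V_v[!pre])), 1e-4)
  # stiffer, faster venous compartment follows the arterial change more
  expect_false(identical(sw$V_c, base$V_c))
})
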