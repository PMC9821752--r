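test_that("metabolic rate scales linearly with summed activity", {
  base <- ref_params$oxy$CMRO2_0
  expect_equal(cmro2(0, ref_params), base)
  p0 <- set_theta(ref_params, c(kmet = 1e-12))
  expect_equal(cmro2(3, p0), p0$oxy$CMRO2_0, tolerance = 1e-9)
  p5 <- set_theta(ref_params, c(kmet = 0.5))
  expect_equal(cmro2(1, p5), 1.5 * base)
  expect_error(cmro2(-1 / ref_params$theta[["kmet"]] - 1, ref_params),
               "negative CMRO2")
})

test_that("saturation curve honours p50, Henry's law and monotonicity", {
  const <- o2_constants()
  expect_equal(o2_pressure(const$cO2_max / 2), 36)
  expect_equal(o2_pressure_tissue(1.46e-3), 1)
  cc <- seq(0.5, 9, length.out = 40)
  expect_true(all(diff(o2_pressure(cc)) > 0))
  # round trip with the forward curve
  expect_equal(o2_concentration(o2_pressure(cc)), cc, tolerance = 1e-10)
  expect_error(o2_pressure(9.3), "super-saturation")
})

test_that("compartment saturation is the scaled boundary average", {
  const <- o2_constants()
  expect_equal(o2_saturation(const$cO2_max, const$cO2_max), 1)
  expect_equal(o2_saturation(1e-12, 1e-12), 0, tolerance = 1e-10)
  expect_equal(o2_saturation(4, 2), o2_saturation(8, 4) / 2)
})

test_that("hemoglobin closure holds exactly", {
  expect_equal(hemoglobin_amounts(0.29, 1)$HbR, 0)
  expect_equal(hemoglobin_amounts(0.29, 0.95)$HbO, 0.2755)
  set.seed(3)
  V <- runif(50, 0.1, 0.6)
  S <- runif(50)
  hb <- hemoglobin_amounts(V, S)
  expect_equal(hb$HbO + hb$HbR, hb$HbT, tolerance = 1e-15)
  expect_identical(hb$HbT, V)
})

test_that("baseline calibration yields an exact oxygen fixed point", {
  oxy <- ref_params$oxy
  rhs <- oxygen_rhs(oxy$n0, f = rep(1, 4), V = ref_params$wk$V0,
                    N_sum = 0, ref_params)
  expect_lt(max(abs(rhs$dn)), 1e-10)
  # the arterial inlet leak is reproduced from the documented profile
  expect_equal(oxy$cO2_in - o2_concentration(oxy$p_in), oxy$cO2_leak,
               tolerance = 1e-10)
  # idempotent: recalibrating from the same profile returns the same values
  again <- calibrate_o2_baseline(oxy$profile)
  expect_equal(again$g, oxy$g)
  expect_equal(again$CMRO2_0, oxy$CMRO2_0)
  # infeasible profile: tissue above vascular pressures
  bad <- oxy$profile
  bad$pO2_t <- 80
  expect_error(calibrate_o2_baseline(bad), "infeasible")
})

test_that("oxygen budget identity holds algebraically and along trajectories", {
  # algebraic: summed derivatives equal advection in - out - metabolism
  set.seed(11)
  for (i in 1:20) {
    V <- ref_params$wk$V0 * runif(3, 0.85, 1.2)
    n <- ref_params$oxy$n0 * runif(4, 0.8, 1.1)
    f <- runif(4, 0.7, 1.5)
    N_sum <- runif(1, -0.5, 1.5)
    r <- oxygen_rhs(n, f, V, N_sum, ref_params)
    expect_equal(sum(r$dn),
                 f[1] * ref_params$oxy$C_in - f[4] * r$C[["out"]] - r$CMRO2,
                 tolerance = 1e-12)
  }
  # integrated: cumulative budget states close the balance on a stimulated run
  sim <- ref_sim_long
  total <- with(sim, nO2_a + nO2_c + nO2_v + nO2_t)
  lhs <- total - total[1]
  rhs <- with(sim, Q_in - Q_out - Q_met)
  expect_lt(max(abs(lhs - rhs)), 1e-5)
})

test_that("shunt removal and washout behave as expected", {
  # no shunt: g_s = 0 leaves the shunt flux identically zero
  prof <- default_o2_profile()
  prof$shunt_frac <- 0
  p0 <- nvc_params(o2_profile = prof)
  r <- oxygen_rhs(p0$oxy$n0, rep(1, 4), p0$wk$V0, 0, p0)
  expect_equal(unname(r$j[["s"]]), 0)

  # doubling flow at fixed metabolism raises venous saturation
  relax <- function(flow) {
    f <- function(t, y, parms) {
      list(oxygen_rhs(y, rep(flow, 4), ref_params$wk$V0, 0, ref_params)$dn)
    }
    out <- deSolve::lsoda(unname(ref_params$oxy$n0), c(0, 200), f, NULL,
                          rtol = 1e-10, atol = 1e-12)
    n <- out[nrow(out), -1]
    oxygen_rhs(n, rep(flow, 4), ref_params$wk$V0, 0, ref_params)$S[["v"]]
  }
  expect_gt(relax(2), relax(1))
})

test_that("calibration profile files override the documented defaults", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(quantity = c("pO2_t", "shunt_frac"),
                       value = c(22, 0.1)), path, row.names = FALSE)
  prof <- read_o2_profile(path)
  expect_equal(prof$pO2_t, 22)
  expect_equal(prof$shunt_frac, 0.1)
  expect_equal(prof$pO2_art, default_o2_profile()$pO2_art)
  # round trip of a full profile
  write_o2_profile(prof, path)
  expect_equal(read_o2_profile(path), prof)
  # the calibrated model still has an exact fixed point
  p <- nvc_params(o2_profile = prof)
  r <- oxygen_rhs(p$oxy$n0, rep(1, 4), p$wk$V0, 0, p)
  expect_lt(max(abs(r$dn)), 1e-10)
})
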