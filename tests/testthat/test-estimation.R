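mk_data <- function(sim) {
  data.frame(experiment = sim$experiment, observable = sim$observable,
             time = sim$time, mean = sim$value, sem = 1)
}

test_that("least-squares cost matches its definition and is additive", {
  sim <- data.frame(experiment = "e1", observable = "LFP",
                    time = 1:4, value = c(0, 1, 2, 3))
  data <- mk_data(sim)
  expect_equal(as.numeric(lsq_cost(sim, data)), 0)
  # one point off by 2 SEM contributes 4
  d2 <- data
  d2$mean[2] <- d2$mean[2] + 2
  expect_equal(as.numeric(lsq_cost(sim, d2)), 4)
  d2$sem <- 0.5
  expect_equal(as.numeric(lsq_cost(sim, d2)), 16)
  # additivity over disjoint datasets
  simB <- data.frame(experiment = "e2", observable = "BOLD",
                     time = 1:3, value = c(1, 1, 1))
  dB <- mk_data(simB)
  dB$mean <- dB$mean + c(1, -1, 3)
  both <- lsq_cost(rbind(sim, simB), rbind(d2, dB))
  expect_equal(as.numeric(both),
               as.numeric(lsq_cost(sim, d2)) + as.numeric(lsq_cost(simB, dB)))
  # ordering invariance
  shuffled <- rbind(d2, dB)[sample(7), ]
  expect_equal(as.numeric(lsq_cost(rbind(simB, sim), shuffled)),
               as.numeric(both))
  # a record with no simulated counterpart is an error
  dBad <- rbind(d2, data.frame(experiment = "e1", observable = "LFP",
                               time = 99, mean = 0, sem = 1))
  expect_error(lsq_cost(sim, dBad), "missing simulated point")
})

test_that("chi-square cutoff matches independent density integration", {
  expect_equal(chi2_cutoff(1, 0.05), 3.8415, tolerance = 1e-4)
  for (df in c(1, 23, 122, 160, 288, 354)) {
    oracle <- uniroot(function(q)
      integrate(dchisq, 0, q, df = df, rel.tol = 1e-10)$value - 0.95,
      c(max(df / 3, 1e-3), 3 * df + 30), tol = 1e-8)$root
    expect_equal(chi2_cutoff(df, 0.05), oracle, tolerance = 1e-4)
  }
  expect_error(chi2_cutoff(0, 0.05), ">= 1")
  expect_error(chi2_cutoff(10, 1.5), "alpha")
})

test_that("chi-square acceptance is a boundary test on J_lsq", {
  expect_true(chi2_test(292.59, 288, 0.05))
  expect_true(chi2_test(0, 10, 0.05))
  cut <- chi2_cutoff(50, 0.05)
  expect_true(chi2_test(cut, 50, 0.05))
  expect_false(chi2_test(cut + 1e-9, 50, 0.05))
})

test_that("SEM flooring raises small SEMs to the series mean, idempotently", {
  d <- data.frame(experiment = "uhlirova:sensory_awake",
                  observable = "diameter_a",
                  time = 1:3, mean = 0, sem = c(1, 1, 4))
  f1 <- sem_floor(d)
  expect_equal(f1$sem, c(2, 2, 4))
  expect_equal(sem_floor(f1)$sem, c(2, 2, 4))
  # constant-SEM series unchanged
  dc <- d
  dc$sem <- rep(2, 3)
  expect_equal(sem_floor(dc)$sem, rep(2, 3))
  # unflagged series untouched by the default rule
  dn <- d
  dn$experiment <- "drew:long"
  expect_equal(sem_floor(dn)$sem, c(1, 1, 4))
  # shmuel LFP is flagged, shmuel BOLD is not
  ds <- d
  ds$experiment <- "shmuel:positive"
  ds$observable <- "LFP"
  expect_equal(sem_floor(ds)$sem, c(2, 2, 4))
  ds$observable <- "BOLD"
  expect_equal(sem_floor(ds)$sem, c(1, 1, 4))
})

test_that("qualitative penalty is zero for compliant dynamics and positive otherwise", {
  expect_equal(as.numeric(qualitative_penalty(ref_sim_long)), 0)
  simS <- simulate_nvc(ref_params, build_paradigm("shmuel", "positive"),
                       seq(0, 45, 0.25))
  expect_equal(as.numeric(qualitative_penalty(simS)), 0)
  # slowing the NO cascade while accelerating NPY violates the arm ordering
  pv <- set_theta(ref_params, c(kNO = 0.05, sinkNO = 1.05,
                                sinkNPY = 1.5, Vmax = 3, Km = 0.5))
  simV <- simulate_nvc(pv, build_paradigm("drew", "long"), seq(0, 75, 0.25))
  pen <- qualitative_penalty(simV)
  expect_gt(as.numeric(pen), 0)
  expect_gt(attr(pen, "clauses")[["arm_order_PGE2_NPY"]], 0)
  # an unsatisfiable amplitude-ratio band flags the hemoglobin clause
  pen2 <- qualitative_penalty(ref_sim_long,
                              nvc_demands(hb_ratio = c(0.98, 0.99)))
  expect_gt(attr(pen2, "clauses")[["hb_ratio_high"]], 0)
  # penalties only ever add
  expect_gte(as.numeric(pen2), 0)
})

test_that("total objective reduces to J_lsq in the zero-penalty region", {
  cfgs <- study_template("drew")[3]      # 30 s stimulation
  fx <- generate_fixture(fixture_spec("drew", noise_sd = 0), ref_params)
  dat <- fx$data[fx$data$experiment == "drew:long", ]
  prob <- make_fit_problem(cfgs, dat, free = "ky_PGE2",
                           base_params = ref_params,
                           demands = list("drew:long" = list()))
  th0 <- log10(ref_params$theta[["ky_PGE2"]])
  v <- total_objective(th0, prob)
  expect_equal(attr(v, "penalty"), 0)
  expect_equal(as.numeric(v), attr(v, "J_lsq"))
  expect_lt(as.numeric(v), 1e-4)
  # record ordering does not change the objective
  prob2 <- make_fit_problem(cfgs, dat[rev(seq_len(nrow(dat))), ],
                            free = "ky_PGE2", base_params = ref_params)
  expect_equal(as.numeric(total_objective(th0, prob2)), as.numeric(v))
  # bound violations are rejected before simulation
  expect_error(total_objective(9, prob), "bounds")
  # a parameter vector outside the model's validity returns the sentinel
  prob3 <- make_fit_problem(cfgs, dat, free = "kCOX",
                            base_params = ref_params)
  v3 <- total_objective(-4.4, prob3)   # kCOX ~ 4e-5: no finite steady state
  expect_gte(as.numeric(v3), 1e12)
  expect_true(is.finite(as.numeric(v3)))
})

test_that("posterior envelope brackets the best-fit trajectory", {
  cfgs <- study_template("drew")[2]      # 10 s stimulation only
  fx <- generate_fixture(fixture_spec("drew", noise_sd = 0.08, seed = 4),
                         ref_params)
  dat <- fx$data[fx$data$experiment == "drew:mid", ]
  prob <- make_fit_problem(cfgs, dat, free = "ky_PGE2",
                           base_params = ref_params)
  th0 <- log10(ref_params$theta[["ky_PGE2"]])
  samp <- sample_posterior(prob, th0, n_samples = 40, seed = 3, step = 0.02)
  expect_true(samp$acceptable[1])
  env <- posterior_envelope(prob, samp, max_draws = 10)
  best_idx <- which.min(samp$J_lsq)
  best_obs <- do.call(rbind, lapply(names(prob$configs), function(id)
    simulate_observables(nvcsim:::expand_free(prob, samp$chain[best_idx, ])[[id]],
                         prob$configs[[id]], rtol = prob$rtol,
                         atol = prob$atol)))
  m <- merge(env, best_obs, by = c("experiment", "observable", "time"))
  expect_true(all(m$value >= m$lo - 1e-9 & m$value <= m$hi + 1e-9))
})

quad_problem <- function() {
  list(objective = function(x) {
    J <- sum((x - 0.3)^2) * 50
    structure(J, J_lsq = J)
  },
  free = "a", n_points = 10, alpha = 0.05,
  bounds = data.frame(name = "a", lower = -2, upper = 2))
}

test_that("multistart optimizer solves a convex problem deterministically", {
  prob <- quad_problem()
  fit1 <- fit_nvc(prob, n_starts = 8, n_refine = 2, maxit = 300, seed = 5)
  expect_lt(abs(unname(fit1$par) - 0.3), 1e-6)
  fit2 <- fit_nvc(prob, n_starts = 8, n_refine = 2, maxit = 300, seed = 5)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$par, fit2$par)
})

test_that("posterior sampling reproduces the analytic confidence region", {
  # linear-Gaussian toy: y = a + b x + N(0,1), J_lsq is exactly quadratic
  set.seed(2)
  x <- seq(-1, 1, length.out = 40)
  a_true <- 0.4; b_true <- -0.7
  y <- a_true + b_true * x + rnorm(length(x))
  X <- cbind(1, x)
  obj <- function(th) {
    J <- sum((y - X %*% th)^2)
    structure(J, J_lsq = J)
  }
  prob <- list(objective = obj, free = c("a", "b"),
               n_points = length(x), alpha = 0.05,
               bounds = data.frame(name = c("a", "b"),
                                   lower = -3, upper = 3))
  start <- as.numeric(solve(crossprod(X), crossprod(X, y)))
  samp <- sample_posterior(prob, start, n_samples = 4000, seed = 11,
                           step = 0.12)
  expect_true(samp$acceptable[1])
  acc <- samp$chain[samp$acceptable, , drop = FALSE]
  # profile interval for the intercept: hat(a) +- sqrt(Delta * Var(a))
  Delta <- qchisq(0.95, df = 2)
  v_aa <- solve(crossprod(X))[1, 1]
  analytic_width <- 2 * sqrt(Delta * v_aa)
  sampled_width <- diff(range(acc[, "a"]))
  expect_equal(sampled_width, analytic_width, tolerance = 0.1)
  # the acceptable set always contains the start (best-fit) vector
  expect_true(any(apply(samp$chain, 1, function(r) all(r == start)) &
                    samp$acceptable))
})

test_that("spike filtering removes injected post-stimulus spikes", {
  tt <- seq(0, 30, 1)
  smooth <- data.frame(experiment = "e", observable = "LFP", time = tt,
                       value = sin(tt / 5))
  spiky <- smooth
  spiky$value[25] <- spiky$value[25] + 50
  # removal fraction 1/3 exceeds the 5% sanity bound, hence the warning
  expect_warning(
    res <- filter_unrealistic(list(smooth, smooth, spiky),
                              stim_off = c(e = 15)),
    "mis-set")
  expect_equal(res$keep, c(TRUE, TRUE, FALSE))
  expect_equal(res$removed_fraction, 1 / 3)
  res2 <- suppressWarnings(filter_unrealistic(list(smooth), c(e = 15)))
  expect_true(res2$keep)
})
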