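#' SEM-weighted least-squares cost
#'
#' Sum over all data records of squared residuals normalized by the
#' per-point standard error: J_lsq = sum ((y - yhat) / sem)^2. The
#' simulation must provide a value at exactly every (experiment, observable,
#' time) record.
#'
#' @param sim data.frame with columns experiment, observable, time, value
#'   (as from [simulate_observables()], possibly row-bound over experiments)
#' @param data data.frame with columns experiment, observable, time, mean,
#'   sem
#' @return J_lsq, with attribute `"by_observable"` giving the per-series
#'   contributions and counts
#' @export
lsq_cost <- function(sim, data) {
  stop_if(any(data$sem <= 0), "nonpositive SEM in data")
  m <- merge(data, sim[, c("experiment", "observable", "time", "value")],
             by = c("experiment", "observable", "time"), all.x = TRUE)
  if (any(is.na(m$value))) {
    miss <- m[is.na(m$value), c("experiment", "observable", "time")]
    stop("missing simulated point for ", nrow(miss), " data record(s), e.g. ",
         paste(unlist(miss[1, ]), collapse = " / "), call. = FALSE)
  }
  res2 <- ((m$mean - m$value) / m$sem)^2
  by <- stats::aggregate(res2,
                         by = list(experiment = m$experiment,
                                   observable = m$observable),
                         FUN = sum)
  names(by)[3] <- "J"
  by$n <- stats::aggregate(res2, by = list(m$experiment, m$observable),
                           FUN = length)$x
  structure(sum(res2), by_observable = by)
}

#' Chi-square acceptance threshold
#'
#' Upper alpha-tail quantile of the chi-square distribution with as many
#' degrees of freedom as there are data points.
#'
#' @param n_points number of data points (>= 1)
#' @param alpha significance level in (0, 1)
#' @export
chi2_cutoff <- function(n_points, alpha = 0.05) {
  stop_if(n_points < 1, "n_points must be >= 1")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  stats::qchisq(1 - alpha, df = n_points)
}

#' Chi-square acceptance test
#'
#' A parameter vector is acceptable when its weighted least-squares cost
#' does not exceed the chi-square cutoff at the data-point count.
#'
#' @param J_lsq cost from [lsq_cost()]
#' @param n_points number of data points
#' @param alpha significance level
#' @return logical pass flag
#' @export
chi2_test <- function(J_lsq, n_points, alpha = 0.05) {
  J_lsq <= chi2_cutoff(n_points, alpha)
}

#' SEM flooring rule
#'
#' Within each flagged (experiment, observable) series, SEM values smaller
#' than the series' mean raw SEM are raised to that mean, preventing a few
#' extreme points from dominating the fit. The raw SEMs are kept in a
#' `sem_raw` column so the rule is idempotent. By default the rule is
#' applied to all series whose experiment id starts with "uhlirova" and to
#' LFP series of "shmuel" experiments, mirroring the source analyses.
#'
#' @param data dataset data.frame
#' @param flag logical vector (length nrow) or function(experiment,
#'   observable) returning one; NULL applies the default rule above
#' @export
sem_floor <- function(data, flag = NULL) {
  if (is.null(data$sem_raw)) data$sem_raw <- data$sem
  if (is.null(flag)) {
    flag <- function(experiment, observable) {
      startsWith(experiment, "uhlirova") |
        (startsWith(experiment, "shmuel") & observable == "LFP")
    }
  }
  fl <- if (is.function(flag)) flag(data$experiment, data$observable) else flag
  key <- interaction(data$experiment, data$observable, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g & fl)
    if (!length(idx)) next
    m <- mean(data$sem_raw[idx])
    data$sem[idx] <- ifelse(data$sem_raw[idx] < m, m, data$sem_raw[idx])
  }
  stop_if(any(data$sem <= 0), "nonpositive SEM after flooring")
  data
}

#' Qualitative demand set
#'
#' Tunable tolerances and weights for the three demand families enforced as
#' hinge penalties during fitting: the timing and role of the three
#' vasoactive arms, the co-timing and amplitude balance of the oxy/deoxy
#' hemoglobin responses, and the shape of the LFP response.
#'
#' @param arm_order,hb_timing,lfp_shape enable each family
#' @param weight penalty weight per unit violation (dimensionless violations
#'   are of order 1, so the default 1e4 dominates any chi-square cutoff)
#' @param no_decay_frac the NO arm contribution at stimulus end must have
#'   decayed below this fraction of its peak
#' @param hb_peak_tol allowed peak-time difference (s) between dHbO and
#'   -dHbR
#' @param hb_ratio allowed range of peak-amplitude ratio |dHbO|/|dHbR|
#' @param lfp_peak_window LFP must peak within this many seconds of onset
#' @param lfp_plateau_frac late-stimulation LFP mean must lie below this
#'   fraction of the early peak
#' @param lfp_recovery_frac terminal |LFP| must lie below this fraction of
#'   the peak
#' @export
nvc_demands <- function(arm_order = TRUE, hb_timing = TRUE, lfp_shape = TRUE,
                        weight = 1e4, no_decay_frac = 0.9, hb_peak_tol = 3,
                        hb_ratio = c(1, 5), lfp_peak_window = 5,
                        lfp_plateau_frac = 0.9, lfp_recovery_frac = 0.2) {
  list(arm_order = arm_order, hb_timing = hb_timing, lfp_shape = lfp_shape,
       weight = weight, no_decay_frac = no_decay_frac,
       hb_peak_tol = hb_peak_tol, hb_ratio = hb_ratio,
       lfp_peak_window = lfp_peak_window,
       lfp_plateau_frac = lfp_plateau_frac,
       lfp_recovery_frac = lfp_recovery_frac)
}

peak_time <- function(t, x) t[which.max(x)]

#' Qualitative-feature penalty
#'
#' Evaluates the enabled demand families on a simulated trajectory and
#' returns a nonnegative penalty that is zero exactly when every clause is
#' satisfied; each violated clause contributes weight times its violation
#' magnitude. Demands (inverted for negative-response variants):
#' (i) the NO arm contribution peaks before the PGE2 arm, which peaks before
#' the NPY arm; the NO contribution has decayed at stimulus end; the total
#' drive turns net-constrictive after the dilators subside;
#' (ii) the oxy- and deoxyhemoglobin responses peak at the same time (within
#' tolerance) with a bounded amplitude ratio;
#' (iii) LFP peaks early, sits on a plateau below the peak for the rest of
#' the stimulation, undershoots below baseline after stimulus end and then
#' recovers.
#'
#' @param sim `nvc_sim` holding the per-arm drive contributions
#' @param demands from [nvc_demands()]
#' @param negative TRUE for negative-response variants (series inverted)
#' @return penalty, with per-clause breakdown attribute `"clauses"`
#' @export
qualitative_penalty <- function(sim, demands = nvc_demands(),
                                negative = FALSE) {
  par <- attr(sim, "paradigm")
  bp <- stimulus_breakpoints(par)
  stop_if(is.null(bp) || !length(bp), "simulation has no stimulus window")
  t_on <- min(bp); t_off <- max(bp)
  t <- sim$time
  stim <- t >= t_on & t <= t_off
  post <- t > t_off
  sgn <- if (negative) -1 else 1
  cl <- c()

  # nothing is known about the ordering of the three arms for
  # negative-response variants; the arm family applies to positive ones only
  if (isTRUE(demands$arm_order) && !negative) {
    need <- c("g_NO", "g_PGE2", "g_NPY")
    stop_if(!all(need %in% names(sim)), "missing drive contributions")
    gNO <- sgn * sim$g_NO; gPG <- sgn * sim$g_PGE2; gNP <- -sgn * sim$g_NPY
    # gNP is the (positive) magnitude of the constrictive arm
    tNO <- peak_time(t, abs(gNO)); tPG <- peak_time(t, abs(gPG))
    tNP <- peak_time(t, abs(gNP))
    span <- max(t) - min(t)
    cl["arm_order_NO_PGE2"] <- max(0, (tNO - tPG) / span)
    cl["arm_order_PGE2_NPY"] <- max(0, (tPG - tNP) / span)
    pk <- max(abs(gNO))
    if (pk > 0) {
      at_off <- abs(gNO[which.min(abs(t - t_off))])
      cl["arm_NO_decay"] <- max(0, at_off / pk - demands$no_decay_frac)
    }
    G <- sgn * sim$G
    if (any(post)) {
      scale <- max(abs(G))
      if (scale > 0) {
        cl["arm_post_constriction"] <- max(0, min(G[post]) / scale)
      }
    }
  }

  if (isTRUE(demands$hb_timing)) {
    p <- attr(sim, "params")
    hb <- hemoglobin_concentration_change(
      sim[, c("V_a", "V_c", "V_v")], sim[, c("S_a", "S_c", "S_v")], p)
    dO <- sgn * hb$dHbO; dR <- sgn * hb$dHbR
    tO <- peak_time(t, dO); tR <- peak_time(t, -dR)
    cl["hb_peak_timing"] <- max(0, abs(tO - tR) - demands$hb_peak_tol) /
      max(1, demands$hb_peak_tol)
    aO <- max(abs(dO)); aR <- max(abs(dR))
    if (aR > 0) {
      ratio <- aO / aR
      cl["hb_ratio_low"] <- max(0, demands$hb_ratio[1] - ratio)
      cl["hb_ratio_high"] <- max(0, ratio - demands$hb_ratio[2])
    }
  }

  if (isTRUE(demands$lfp_shape)) {
    p <- attr(sim, "params")
    lfp <- sgn * lfp_signal(sim$N_Pyr, p$theta[["ky4"]])
    pk <- max(lfp[stim])
    if (pk > 0) {
      tpk <- peak_time(t[stim], lfp[stim])
      cl["lfp_early_peak"] <- max(0, tpk - (t_on + demands$lfp_peak_window)) /
        demands$lfp_peak_window
      late <- stim & t >= (t_on + t_off) / 2
      plateau <- mean(lfp[late])
      cl["lfp_plateau_below_peak"] <- max(0, plateau / pk -
                                            demands$lfp_plateau_frac)
      cl["lfp_plateau_positive"] <- max(0, -plateau / pk)
      if (any(post)) {
        cl["lfp_undershoot"] <- max(0, min(lfp[post]) / pk)
        cl["lfp_recovery"] <- max(0, abs(lfp[length(lfp)]) / pk -
                                    demands$lfp_recovery_frac)
      }
    } else {
      cl["lfp_no_response"] <- 1
    }
  }

  structure(demands$weight * sum(cl), clauses = cl)
}

#' Assemble a fit problem
#'
#' Bundles experiment configurations, a dataset, the free parameters and the
#' demand set into the single object consumed by [total_objective()],
#' [fit_nvc()] and [sample_posterior()]. Free parameters are estimated in
#' log10 space. A free name of the form `"<param>@<variant>"` is unique to
#' the experiment with that variant (parameter sharing across setups);
#' plain names are shared by all experiments.
#'
#' @param configs list of [experiment_config()] objects
#' @param data dataset data.frame (experiment, observable, time, mean, sem)
#' @param free character vector of free parameter names
#' @param base_params `nvc_params` providing every non-estimated value
#' @param demands NULL, or a named list experiment id -> list(demands =
#'   [nvc_demands()], negative = flag)
#' @param bounds data.frame(name, lower, upper) in log10 units
#' @param alpha chi-square significance level
#' @param rtol,atol integrator tolerances used during fitting
#' @export
make_fit_problem <- function(configs, data, free, base_params = nvc_params(),
                             demands = NULL,
                             bounds = default_bounds(free), alpha = 0.05,
                             rtol = 1e-6, atol = 1e-8) {
  names(configs) <- vapply(configs, `[[`, "", "id")
  stop_if(!all(data$experiment %in% names(configs)),
          "data reference experiments without a configuration")
  plain <- sub("@.*$", "", free)
  stop_if(!all(plain %in% names(default_theta())),
          "unknown free parameter(s): ",
          paste(free[!plain %in% names(default_theta())], collapse = ", "))
  structure(list(configs = configs, data = data, free = free,
                 base_params = base_params, demands = demands,
                 bounds = bounds, alpha = alpha, rtol = rtol, atol = atol,
                 n_points = nrow(data)),
            class = "fit_problem")
}

# per-config full parameter objects given the free log10 vector
expand_free <- function(problem, theta_log) {
  stop_if(length(theta_log) != length(problem$free),
          "theta has wrong length")
  names(theta_log) <- problem$free
  th <- 10^theta_log
  lapply(problem$configs, function(cfg) {
    shared <- !grepl("@", names(th))
    mine <- endsWith(names(th), paste0("@", cfg$variant))
    vals <- th[shared | mine]
    names(vals) <- sub("@.*$", "", names(vals))
    vals <- vals[!duplicated(names(vals), fromLast = TRUE)]
    set_theta(problem$base_params, vals)
  })
}

#' Total objective: least squares plus qualitative penalties
#'
#' Simulates every experiment of the problem at the candidate parameters,
#' evaluates the SEM-weighted least-squares cost against the dataset and
#' adds the qualitative-feature penalties. Bound violations are rejected
#' before simulation. A failed simulation returns a large finite sentinel
#' (1e12 plus a term decreasing with the fraction of experiments completed)
#' so optimizers remain directional.
#'
#' @param theta_log free parameter vector in log10 space
#' @param problem [make_fit_problem()]
#' @return J_opt with attributes `"J_lsq"`, `"penalty"`
#' @export
total_objective <- function(theta_log, problem) {
  b <- problem$bounds
  stop_if(any(theta_log < b$lower - 1e-12 | theta_log > b$upper + 1e-12),
          "parameter bounds violated")
  done <- 0
  res <- tryCatch({
    plist <- expand_free(problem, theta_log)
    sims <- list()
    obs <- NULL
    for (id in names(problem$configs)) {
      o <- simulate_observables(plist[[id]], problem$configs[[id]],
                                rtol = problem$rtol, atol = problem$atol)
      sims[[id]] <- attr(o, "sim")
      obs <- rbind(obs, o)
      done <- done + 1
    }
    J <- lsq_cost(obs, problem$data)
    pen <- 0
    for (id in names(problem$demands %||% list())) {
      d <- problem$demands[[id]]
      pen <- pen + qualitative_penalty(sims[[id]],
                                       d$demands %||% nvc_demands(),
                                       negative = isTRUE(d$negative))
    }
    structure(as.numeric(J) + as.numeric(pen),
              J_lsq = as.numeric(J), penalty = as.numeric(pen),
              by_observable = attr(J, "by_observable"))
  }, error = function(e) {
    n <- length(problem$configs)
    structure(1e12 + 1e10 * (1 - done / n), J_lsq = NA_real_,
              penalty = NA_real_, failure = conditionMessage(e))
  })
  res
}

#' Cost report for a candidate parameter vector
#'
#' @param problem [make_fit_problem()]
#' @param theta_log free parameter vector (log10)
#' @return list of class `cost_report`: J_lsq, per-observable breakdown,
#'   n_points, chi-square cutoff, pass flag, penalty and J_opt
#' @export
cost_report <- function(problem, theta_log) {
  J <- total_objective(theta_log, problem)
  cut <- chi2_cutoff(problem$n_points, problem$alpha)
  structure(list(J_lsq = attr(J, "J_lsq"), J_opt = as.numeric(J),
                 penalty = attr(J, "penalty"),
                 by_observable = attr(J, "by_observable"),
                 n_points = problem$n_points, alpha = problem$alpha,
                 cutoff = cut,
                 pass = isTRUE(attr(J, "J_lsq") <= cut)),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("J_lsq = %.4g on %d points; chi2 cutoff(alpha=%g) = %.2f -> %s\n",
              x$J_lsq, x$n_points, x$alpha, x$cutoff,
              if (x$pass) "PASS" else "FAIL"))
  if (!is.null(x$penalty) && is.finite(x$penalty) && x$penalty > 0) {
    cat(sprintf("qualitative penalty = %.4g (J_opt = %.4g)\n",
                x$penalty, x$J_opt))
  }
  if (!is.null(x$by_observable)) {
    print(x$by_observable, row.names = FALSE)
  }
  invisible(x)
}

# resolve the objective: fit problems simulate the model; custom problems
# (list with $objective, $bounds, $free, $n_points, $alpha) supply their own
# function returning J_opt with a "J_lsq" attribute
objective_of <- function(problem) {
  if (inherits(problem, "fit_problem")) {
    function(x) total_objective(x, problem)
  } else {
    stop_if(is.null(problem$objective), "problem has no objective")
    problem$objective
  }
}

#' Fit the model by multistart optimization
#'
#' Global-then-local strategy: a Latin-hypercube sample of the bounded
#' log10 box is scored, the best starts are refined with Nelder-Mead, and
#' the overall best vector is returned together with the evaluation history.
#' Deterministic for a fixed seed.
#'
#' @param problem [make_fit_problem()]
#' @param n_starts Latin-hypercube sample size
#' @param n_refine number of best starts refined locally
#' @param maxit local iterations per refinement
#' @param seed RNG seed
#' @param start optional matrix (rows = extra start vectors, log10)
#' @return list with par (log10), value (J_opt), report ([cost_report()]),
#'   history (data.frame of all evaluations) and counts
#' @export
fit_nvc <- function(problem, n_starts = 30, n_refine = 3, maxit = 150,
                    seed = 1, start = NULL) {
  set.seed(seed)
  d <- length(problem$free)
  b <- problem$bounds
  fobj <- objective_of(problem)
  history <- new.env()
  history$n <- 0L
  history$rows <- list()
  obj <- function(x) {
    x <- pmin(pmax(x, b$lower), b$upper)
    v <- fobj(x)
    history$n <- history$n + 1L
    history$rows[[history$n]] <- c(x, J_opt = as.numeric(v),
                                   J_lsq = attr(v, "J_lsq") %||% NA_real_)
    as.numeric(v)
  }
  X <- lhs::randomLHS(n_starts, d)
  X <- sweep(sweep(X, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
  if (!is.null(start)) X <- rbind(X, start)
  vals <- apply(X, 1, obj)
  ord <- order(vals)
  best_par <- X[ord[1], ]
  best_val <- vals[ord[1]]
  for (i in seq_len(min(n_refine, nrow(X)))) {
    o <- if (d == 1) {
      stats::optim(X[ord[i], ], obj, method = "Brent",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = maxit))
    } else {
      stats::optim(X[ord[i], ], obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    }
    if (o$value < best_val) {
      best_val <- o$value
      best_par <- pmin(pmax(o$par, b$lower), b$upper)
    }
  }
  hist_df <- as.data.frame(do.call(rbind, history$rows))
  names(hist_df)[seq_len(d)] <- problem$free
  list(par = stats::setNames(best_par, problem$free), value = best_val,
       report = if (inherits(problem, "fit_problem"))
         cost_report(problem, best_par),
       history = hist_df, n_evaluations = history$n)
}

#' Posterior sampling of acceptable parameters
#'
#' Random-walk Metropolis sampler on the penalized objective (target
#' proportional to exp(-J_opt / 2)) within the log10 bounds. The
#' "acceptable set" collects every visited vector that passes the
#' chi-square test at the data-point count and lies within the
#' likelihood-ratio confidence region J_lsq <= J_lsq(best) + chi-square
#' quantile at df = number of estimated parameters.
#'
#' @param problem [make_fit_problem()]
#' @param start log10 start vector; must itself pass the chi-square test
#' @param n_samples chain length
#' @param seed RNG seed
#' @param step proposal standard deviation (log10 units)
#' @return list with chain, J (J_lsq and J_opt per sample), acceptable flag
#'   vector, acceptance rate, best-seen vector/cost, and thresholds
#' @export
sample_posterior <- function(problem, start, n_samples = 1000, seed = 1,
                             step = 0.05) {
  set.seed(seed)
  d <- length(problem$free)
  b <- problem$bounds
  fobj <- objective_of(problem)
  v0 <- fobj(start)
  J0 <- attr(v0, "J_lsq")
  cut_n <- chi2_cutoff(problem$n_points, problem$alpha)
  stop_if(!isTRUE(J0 <= cut_n), "start vector does not pass the chi2 test")
  chain <- matrix(NA_real_, n_samples + 1, d,
                  dimnames = list(NULL, problem$free))
  Jl <- Jo <- numeric(n_samples + 1)
  chain[1, ] <- start; Jl[1] <- J0; Jo[1] <- as.numeric(v0)
  cur <- start; cur_o <- as.numeric(v0); cur_l <- J0
  n_acc <- 0
  for (i in seq_len(n_samples)) {
    prop <- cur + stats::rnorm(d, 0, step)
    if (all(prop >= b$lower & prop <= b$upper)) {
      v <- fobj(prop)
      if (stats::runif(1) < exp((cur_o - as.numeric(v)) / 2)) {
        cur <- prop; cur_o <- as.numeric(v)
        cur_l <- attr(v, "J_lsq") %||% NA_real_
        n_acc <- n_acc + 1
      }
    }
    chain[i + 1, ] <- cur; Jl[i + 1] <- cur_l; Jo[i + 1] <- cur_o
  }
  best <- min(Jl, na.rm = TRUE)
  ci_cut <- best + chi2_cutoff(d, problem$alpha)
  acceptable <- !is.na(Jl) & Jl <= cut_n & Jl <= ci_cut
  if (!any(acceptable)) {
    warning("no acceptable samples: chain never entered the chi2 region")
  }
  list(chain = chain, J_lsq = Jl, J_opt = Jo, acceptable = acceptable,
       acceptance_rate = n_acc / n_samples,
       best_J_lsq = best, chi2_cutoff = cut_n, ci_cutoff = ci_cut)
}

#' Pointwise simulation envelope over the acceptable set
#'
#' @param problem [make_fit_problem()]
#' @param samples output of [sample_posterior()]
#' @param max_draws cap on the number of acceptable vectors simulated
#'   (unique vectors, thinned evenly)
#' @return data.frame experiment, observable, time, lo, hi
#' @export
posterior_envelope <- function(problem, samples, max_draws = 50) {
  idx <- which(samples$acceptable)
  stop_if(!length(idx), "no acceptable samples to envelope")
  vecs <- unique(samples$chain[idx, , drop = FALSE])
  if (nrow(vecs) > max_draws) {
    vecs <- vecs[round(seq(1, nrow(vecs), length.out = max_draws)), ,
                 drop = FALSE]
  }
  all_obs <- lapply(seq_len(nrow(vecs)), function(i) {
    plist <- expand_free(problem, vecs[i, ])
    do.call(rbind, lapply(names(problem$configs), function(id) {
      simulate_observables(plist[[id]], problem$configs[[id]],
                           rtol = problem$rtol, atol = problem$atol)
    }))
  })
  ref <- all_obs[[1]][, c("experiment", "observable", "time")]
  vals <- vapply(all_obs, `[[`, numeric(nrow(ref)), "value")
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  ref$lo <- apply(vals, 1, min)
  ref$hi <- apply(vals, 1, max)
  ref
}

#' Remove unrealistically spiking acceptable vectors
#'
#' A vector is unrealistic when, for any observable series, the maximum
#' absolute slope between post-stimulus sample points exceeds `factor`
#' times the maximum slope that series shows during the stimulus window.
#' Such spikes fall between data points and are invisible to the cost, but
#' are judged implausible. Removal fractions above 5 percent trigger a
#' warning (the threshold is probably mis-set).
#'
#' @param obs_list list of observable data.frames, one per acceptable
#'   vector (each with columns experiment, observable, time, value)
#' @param stim_off named numeric: experiment id -> stimulus end time (s)
#' @param factor slope-ratio threshold
#' @return list with keep (logical), removed_fraction
#' @export
filter_unrealistic <- function(obs_list, stim_off, factor = 10) {
  spiky_series <- function(time, value, t_off) {
    sl <- abs(diff(value) / diff(time))
    tm <- (time[-1] + time[-length(time)]) / 2
    in_stim <- tm <= t_off
    if (!any(in_stim) || !any(!in_stim)) return(FALSE)
    ref <- max(sl[in_stim])
    if (ref == 0) ref <- .Machine$double.eps
    max(sl[!in_stim]) > factor * ref
  }
  keep <- vapply(obs_list, function(obs) {
    bad <- FALSE
    for (key in unique(paste(obs$experiment, obs$observable))) {
      sel <- paste(obs$experiment, obs$observable) == key
      ex <- obs$experiment[sel][1]
      if (spiky_series(obs$time[sel], obs$value[sel], stim_off[[ex]])) {
        bad <- TRUE
        break
      }
    }
    !bad
  }, logical(1))
  frac <- mean(!keep)
  if (frac > 0.05) {
    warning(sprintf("removed %.1f%% of vectors: spike threshold may be mis-set",
                    100 * frac))
  }
  list(keep = keep, removed_fraction = frac)
}
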