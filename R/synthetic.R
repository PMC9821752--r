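#' Study-shaped synthetic templates
#'
#' Each template reproduces the data shape of one source study: which
#' observables were measured under which stimulus variants, on which time
#' grids, and with which acquisition settings. Grids mirror the published
#' sampling (1 s resolution for BOLD/LFP, denser two-photon grids for
#' diameters); the Drew template has 288 points in total and the Desjardins
#' BOLD validation series 23 points, matching the printed counts.
#'
#' @param template one of drew, uhlirova, desjardins, shmuel, huber
#' @return list of [experiment_config()] objects
#' @export
study_template <- function(template) {
  template <- match.arg(template, c("drew", "uhlirova", "desjardins",
                                    "shmuel", "huber"))
  g <- function(from, to, by) seq(from, to, by = by)
  switch(template,
    drew = list(
      experiment_config("drew", "short",
                        list(diameter_a = g(0.3, 14.4, 0.3),
                             diameter_v = g(0.3, 14.4, 0.3))),
      experiment_config("drew", "mid",
                        list(diameter_a = g(0.8, 38.4, 0.8),
                             diameter_v = g(0.8, 38.4, 0.8))),
      experiment_config("drew", "long",
                        list(diameter_a = g(1.25, 60, 1.25),
                             diameter_v = g(1.25, 60, 1.25)))
    ),
    uhlirova = lapply(c("og_pyr_anesth", "og_in_anesth", "sensory_anesth",
                        "sensory_awake"), function(v)
      experiment_config("uhlirova", v,
                        list(diameter_a = g(0.5, 15, 0.5)))),
    desjardins = c(
      lapply(c("og_in_short", "og_exc_short", "sensory_short"), function(v)
        experiment_config("desjardins", v,
                          list(dHbO = g(0.5, 10, 0.5),
                               dHbR = g(0.5, 10, 0.5),
                               dHbT = g(0.5, 10, 0.5)),
                          overrides = if (v == "sensory_short")
                            sensory_gain_overrides(1.1))),
      lapply(c("og_in_long", "sensory_long"), function(v)
        experiment_config("desjardins", v,
                          list(dHbO = g(1, 30, 1), dHbR = g(1, 30, 1),
                               dHbT = g(1, 30, 1)),
                          overrides = if (v == "sensory_long")
                            sensory_gain_overrides(1))),
      list(experiment_config("desjardins", "og_exc_long",
                             list(dHbO = g(1, 30, 1), dHbR = g(1, 30, 1),
                                  dHbT = g(1, 30, 1),
                                  BOLD = g(1, 23, 1)),
                             acq = nvc_acq(TE = 0.015, B0 = 9.4)))
    ),
    shmuel = lapply(c("positive", "negative"), function(v)
      experiment_config("shmuel", v,
                        list(BOLD = g(1, 40, 1), LFP = g(1, 40, 1)),
                        acq = nvc_acq(TE = 0.020, B0 = 4.7),
                        overrides = if (v == "negative")
                          negative_gain_overrides())),
    huber = c(
      lapply(c("positive", "negative"), function(v)
        experiment_config("huber", v,
                          list(BOLD = g(2, 60, 2), CBV = g(2, 60, 2),
                               CBF = g(4, 60, 4)),
                          acq = nvc_acq(TE = 0.032, B0 = 7),
                          overrides = if (v == "negative")
                            negative_gain_overrides())),
      lapply(c("excitatory", "inhibitory"), function(v)
        experiment_config("huber", v,
                          list(CBV = g(4, 60, 4), CBV_a = g(4, 60, 4),
                               CBV_v = g(4, 60, 4)),
                          acq = nvc_acq(TE = 0.032, B0 = 7),
                          overrides = if (v == "inhibitory")
                            negative_gain_overrides()))
    )
  )
}

#' Default stimulus-gain block for negative-response setups
#'
#' Negative responses arise from suppression of ongoing activity in areas
#' neighbouring the stimulated one; the suppressive drive that arrives there
#' is much weaker than the direct sensory drive. The study templates
#' therefore give negative-response setups their own attenuated stimulus
#' gains (the setups' "unique" parameter block), keeping the inverted
#' response within the physiological envelope of the vascular and oxygen
#' models.
#'
#' @export
negative_gain_overrides <- function() {
  c(ku_NO = 0.12, ku_NPY = 0.06, ku_Pyr = 0.15)
}

#' Stimulus-gain block for pulsed whisker stimulation
#'
#' The pulsed air-puff paradigms drive the neurons only ~30 percent of the
#' time; the per-pulse gains of the sensory setups are correspondingly
#' larger than the constant-block gains, and differ slightly between the
#' short and long sensory conditions (their own "unique" blocks).
#'
#' @param scale relative strength of the condition
#' @export
sensory_gain_overrides <- function(scale = 1) {
  scale * c(ku_NO = 1.3, ku_NPY = 1.0, ku_Pyr = 3.3)
}

#' Fixture specification
#'
#' A reproducible recipe for a synthetic dataset: the study template, the
#' true parameter values (overrides of the defaults, natural units), the
#' per-point noise level and the seed. Identical specs with identical seeds
#' yield identical datasets.
#'
#' @param template study template id
#' @param theta_true named numeric overrides of [default_theta()]
#' @param noise_sd noise standard deviation; either a single number applied
#'   everywhere or a fraction of each series' dynamic range when
#'   `relative = TRUE`. The declared SEM column always equals the noise SD
#'   actually used, so the cost at the true vector is chi-square
#'   distributed.
#' @param relative interpret `noise_sd` as a fraction of series range
#' @param seed RNG seed
#' @export
fixture_spec <- function(template, theta_true = NULL, noise_sd = 0.05,
                         relative = TRUE, seed = 1) {
  structure(list(template = template, theta_true = theta_true,
                 noise_sd = noise_sd, relative = relative, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic dataset from a fixture specification
#'
#' Simulates every observable of the template at the true parameter vector,
#' samples the template grids, adds independent Gaussian noise with the
#' declared SEM as standard deviation, and returns the dataset together
#' with the ground truth. Noise generation uses its own RNG stream and
#' restores the caller's RNG state, so fixture generation does not disturb
#' surrounding code.
#'
#' @param spec [fixture_spec()]
#' @param base_params baseline parameter object the truth overrides
#' @return list with `data` (dataset data.frame), `truth` (named vector of
#'   the true overrides), `clean` (noise-free values) and `configs`
#' @export
generate_fixture <- function(spec, base_params = nvc_params()) {
  configs <- study_template(spec$template)
  params <- if (is.null(spec$theta_true)) base_params else
    set_theta(base_params, spec$theta_true)
  obs <- do.call(rbind, lapply(configs, function(cfg) {
    o <- tryCatch(simulate_observables(params, cfg),
                  error = function(e) stop(
                    "simulation failed at the true vector for ", cfg$id,
                    ": ", conditionMessage(e), call. = FALSE))
    attr(o, "sim") <- NULL
    o
  }))
  rng_state <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                          globalenv()))
  set.seed(spec$seed)
  key <- paste(obs$experiment, obs$observable)
  sd_pt <- numeric(nrow(obs))
  for (k in unique(key)) {
    sel <- key == k
    sd_pt[sel] <- if (spec$relative) {
      rng <- diff(range(obs$value[sel]))
      spec$noise_sd * max(rng, 1e-6)
    } else spec$noise_sd
  }
  noisy <- obs$value + if (all(sd_pt == 0)) 0 else
    stats::rnorm(nrow(obs), 0, sd_pt)
  data <- data.frame(experiment = obs$experiment,
                     observable = obs$observable,
                     time = obs$time, mean = noisy,
                     sem = ifelse(sd_pt == 0, 1, sd_pt))
  list(data = data, truth = spec$theta_true, clean = obs$value,
       configs = configs, params = params)
}

#' Read and write datasets
#'
#' Delimited-text datasets with header experiment, observable, time, mean,
#' sem. Reading validates the schema, rejects nonpositive SEMs and
#' nonmonotone times within a series (reporting offending line numbers) and
#' preserves unknown columns; write/read round-trips are lossless.
#'
#' @param path file path
#' @rdname dataset_io
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("experiment", "observable", "time", "mean", "sem")
  missing_cols <- setdiff(req, names(df))
  stop_if(length(missing_cols) > 0, "missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(df)
  bad_sem <- which(df$sem <= 0)
  stop_if(length(bad_sem) > 0, "nonpositive sem at line(s): ",
          paste(bad_sem + 1, collapse = ", "))
  key <- paste(df$experiment, df$observable)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (is.unsorted(df$time[idx], strictly = TRUE)) {
      off <- idx[which(diff(df$time[idx]) <= 0) + 1]
      stop("nonmonotone time within series '", k, "' at line(s): ",
           paste(off + 1, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' @param data dataset data.frame
#' @rdname dataset_io
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Write a fixture with its manifest
#'
#' Writes the dataset as delimited text plus a YAML manifest recording the
#' generating specification and a content hash of the data file, so a
#' fixture's provenance can be verified later.
#'
#' @param fx output of [generate_fixture()]
#' @param spec the [fixture_spec()] that generated it
#' @param dir output directory (created if needed)
#' @return paths of the written files
#' @export
write_fixture <- function(fx, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "data.csv")
  write_dataset(fx$data, data_path)
  hash <- unname(tools::md5sum(data_path))
  manifest <- list(template = spec$template,
                   theta_true = as.list(spec$theta_true),
                   noise_sd = spec$noise_sd, relative = spec$relative,
                   seed = spec$seed, n_records = nrow(fx$data),
                   data_hash = hash)
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  c(data = data_path, manifest = manifest_path)
}

#' Parameter-recovery harness
#'
#' For each seed: draw a true vector uniformly (in log10) inside the given
#' recovery box, generate a synthetic fixture, refit the free parameters
#' from scratch and report per-parameter relative errors and the
#' chi-square verdicts at both the refitted and the true vector.
#'
#' @param template study template id (a reduced set of its experiments can
#'   be selected with `use_configs`)
#' @param free names of the free parameters to perturb and recover
#' @param seeds integer vector of seeds (one fixture + fit per seed)
#' @param half_width half-width of the recovery box around the default
#'   values, log10 units
#' @param noise_sd,relative forwarded to [fixture_spec()]
#' @param use_configs optional indices selecting a subset of the template's
#'   experiments
#' @param n_starts,maxit optimizer budget per fit
#' @param base_params baseline parameter object
#' @return data.frame with one row per (seed, parameter): true and fitted
#'   values, relative error, J at fit, chi-square pass flags
#' @export
recovery_harness <- function(template, free, seeds, half_width = 0.35,
                             noise_sd = 0, relative = TRUE,
                             use_configs = NULL, n_starts = 12, maxit = 120,
                             base_params = nvc_params()) {
  if (!length(seeds)) {
    return(data.frame(seed = integer(), parameter = character(),
                      true = numeric(), fitted = numeric(),
                      rel_error = numeric(), J_lsq = numeric(),
                      pass_fit = logical(), pass_true = logical()))
  }
  center <- log10(default_theta()[free])
  rows <- list()
  for (s in seeds) {
    set.seed(s)
    true_log <- center + stats::runif(length(free), -half_width, half_width)
    spec <- fixture_spec(template, theta_true = 10^true_log,
                         noise_sd = noise_sd, relative = relative, seed = s)
    fx <- generate_fixture(spec, base_params)
    configs <- fx$configs
    if (!is.null(use_configs)) {
      keep_ids <- vapply(configs[use_configs], `[[`, "", "id")
      configs <- configs[use_configs]
      fx$data <- fx$data[fx$data$experiment %in% keep_ids, ]
    }
    problem <- make_fit_problem(configs, fx$data, free, base_params,
                                bounds = data.frame(
                                  name = free,
                                  lower = center - half_width,
                                  upper = center + half_width))
    fit <- tryCatch(fit_nvc(problem, n_starts = n_starts, maxit = maxit,
                            seed = s),
                    error = function(e) NULL)
    J_true <- attr(total_objective(true_log, problem), "J_lsq")
    pass_true <- chi2_test(J_true, problem$n_points, problem$alpha)
    if (is.null(fit)) {
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, parameter = free, true = 10^true_log, fitted = NA_real_,
        rel_error = NA_real_, J_lsq = NA_real_, pass_fit = FALSE,
        pass_true = pass_true)
      next
    }
    fitted <- 10^fit$par
    rows[[length(rows) + 1]] <- data.frame(
      seed = s, parameter = free, true = 10^true_log, fitted = fitted,
      rel_error = abs(fitted - 10^true_log) / 10^true_log,
      J_lsq = fit$report$J_lsq, pass_fit = fit$report$pass,
      pass_true = pass_true)
  }
  do.call(rbind, rows)
}
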