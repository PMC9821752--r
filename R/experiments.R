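#' Square-pulse stimulus
#'
#' Returns 1 when t lies inside any of the (closed) on-intervals, else 0.
#'
#' @param t time(s), finite
#' @param intervals two-column matrix of (t_on, t_off) rows; may be NULL or
#'   zero-row for an always-off channel
#' @export
square_stimulus <- function(t, intervals) {
  stop_if(any(!is.finite(t)), "t must be finite")
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(0, length(t)))
  out <- numeric(length(t))
  for (k in seq_len(nrow(intervals))) {
    out[t >= intervals[k, 1] & t <= intervals[k, 2]] <- 1
  }
  out
}

# intervals constructor with overlap/ordering validation
stim_intervals <- function(on, off) {
  m <- cbind(on, off)
  stop_if(any(m[, 2] <= m[, 1]), "t_off must exceed t_on")
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L) {
    stop_if(any(m[-1, 1] < m[-nrow(m), 2]), "intervals must not overlap")
  }
  m
}

pulse_train <- function(t0, n, width, period) {
  on <- t0 + (seq_len(n) - 1) * period
  stim_intervals(on, on + width)
}

#' Stimulus paradigm constructor
#'
#' A paradigm holds one interval set per neuron channel (u1 drives the
#' NO interneurons, u2 the NPY interneurons, u3 the pyramidal neurons) and
#' the per-channel sign flags.
#'
#' @param u1,u2,u3 two-column (t_on, t_off) matrices or NULL
#' @param sign length-3 vector of +-1 flags
#' @param label free-text label
#' @export
stimulus_paradigm <- function(u1 = NULL, u2 = NULL, u3 = NULL,
                              sign = c(1, 1, 1), label = "") {
  structure(list(u = list(u1 = u1, u2 = u2, u3 = u3),
                 sign = sign, label = label),
            class = "stimulus_paradigm")
}

#' @export
print.stimulus_paradigm <- function(x, ...) {
  cat("<stimulus_paradigm>", x$label, "\n")
  for (i in 1:3) {
    iv <- x$u[[i]]
    cat(sprintf("  u%d (sign %+d): %s\n", i, x$sign[i],
                if (is.null(iv) || nrow(iv) == 0) "off" else
                  paste(apply(iv, 1, function(r)
                    sprintf("[%g, %g]", r[1], r[2])), collapse = " ")))
  }
  invisible(x)
}

# all stimulus switch times, for exact piecewise integration
stimulus_breakpoints <- function(paradigm) {
  sort(unique(unlist(lapply(paradigm$u, function(m) if (!is.null(m)) c(m)))))
}

# per-channel stimulus value at time t (scalar)
stimulus_value <- function(paradigm, t) {
  vapply(paradigm$u, function(m) square_stimulus(t, m), numeric(1))
}

#' Build a published stimulus paradigm
#'
#' Reconstructs the stimulation protocols of the five source studies.
#' Sensory stimuli drive all three neuron channels; optogenetic stimulation
#' of pyramidal neurons drives only u3; optogenetic stimulation of
#' (all) inhibitory interneurons drives u1 and u2.
#'
#' Studies and variants:
#' \describe{
#'   \item{drew}{`short` (one 125 ms block), `mid` (10 s), `long` (30 s);
#'     whisker air-puff trains collapsed to constant blocks.}
#'   \item{uhlirova}{`og_pyr_anesth` (single 80 ms light pulse, u3),
#'     `og_in_anesth` (pair of 160 ms pulses separated by 130 ms, u1+u2),
#'     `sensory_anesth` (2 s train), `sensory_awake` (1 s of 100 ms puffs at
#'     3 Hz), `og_awake` (single 250 ms pulse, u1+u2).}
#'   \item{desjardins}{`og_in_short`/`og_exc_short` (single 100 ms pulse),
#'     `og_in_long`/`og_exc_long` (20 s of 100 ms pulses at 1 Hz),
#'     `sensory_short` (2 s of 100 ms puffs at 3 Hz), `sensory_long`
#'     (20 s at 3 Hz).}
#'   \item{shmuel}{`positive` (20 s visual block), `negative` (21 s block
#'     with negative sign flags).}
#'   \item{huber}{`positive`/`excitatory` (30 s block), `negative`/
#'     `inhibitory` (30 s block with negative sign flags).}
#' }
#'
#' @param study one of drew, uhlirova, desjardins, shmuel, huber
#' @param variant a printed condition of that study (see Details)
#' @return a [stimulus_paradigm()]
#' @export
build_paradigm <- function(study, variant) {
  study <- match.arg(study, c("drew", "uhlirova", "desjardins",
                              "shmuel", "huber"))
  all3 <- function(iv, sign = c(1, 1, 1), label)
    stimulus_paradigm(iv, iv, iv, sign = sign, label = label)
  bad <- function(valid) stop("unknown variant for ", study,
                              "; valid: ", paste(valid, collapse = ", "),
                              call. = FALSE)
  lab <- paste(study, variant, sep = ":")
  switch(study,
    drew = {
      dur <- switch(variant, short = 0.125, mid = 10, long = 30,
                    bad(c("short", "mid", "long")))
      all3(stim_intervals(0, dur), label = lab)
    },
    uhlirova = switch(variant,
      og_pyr_anesth = stimulus_paradigm(
        u3 = stim_intervals(0, 0.08), label = lab),
      og_in_anesth = {
        iv <- stim_intervals(c(0, 0.29), c(0.16, 0.45))
        stimulus_paradigm(u1 = iv, u2 = iv, label = lab)
      },
      sensory_anesth = all3(stim_intervals(0, 2), label = lab),
      sensory_awake = all3(pulse_train(0, 3, 0.1, 1 / 3), label = lab),
      og_awake = {
        iv <- stim_intervals(0, 0.25)
        stimulus_paradigm(u1 = iv, u2 = iv, label = lab)
      },
      bad(c("og_pyr_anesth", "og_in_anesth", "sensory_anesth",
            "sensory_awake", "og_awake"))
    ),
    desjardins = switch(variant,
      og_in_short = {
        iv <- stim_intervals(0, 0.1)
        stimulus_paradigm(u1 = iv, u2 = iv, label = lab)
      },
      og_in_long = {
        iv <- pulse_train(0, 20, 0.1, 1)
        stimulus_paradigm(u1 = iv, u2 = iv, label = lab)
      },
      og_exc_short = stimulus_paradigm(u3 = stim_intervals(0, 0.1),
                                       label = lab),
      og_exc_long = stimulus_paradigm(u3 = pulse_train(0, 20, 0.1, 1),
                                      label = lab),
      sensory_short = all3(pulse_train(0, 6, 0.1, 1 / 3), label = lab),
      sensory_long = all3(pulse_train(0, 60, 0.1, 1 / 3), label = lab),
      bad(c("og_in_short", "og_in_long", "og_exc_short", "og_exc_long",
            "sensory_short", "sensory_long"))
    ),
    shmuel = switch(variant,
      positive = all3(stim_intervals(0, 20), label = lab),
      # the negative-response block is prolonged by 1 s and the stimulus
      # acts suppressively via the sign flags
      negative = all3(stim_intervals(0, 21), sign = c(-1, -1, -1),
                      label = lab),
      bad(c("positive", "negative"))
    ),
    huber = switch(variant,
      positive = ,
      excitatory = all3(stim_intervals(0, 30), label = lab),
      negative = ,
      inhibitory = all3(stim_intervals(0, 30), sign = c(-1, -1, -1),
                        label = lab),
      bad(c("positive", "excitatory", "negative", "inhibitory"))
    )
  )
}

#' Read / write a stimulus paradigm as YAML
#'
#' Interval lists per channel plus sign flags and label, mirroring the
#' printed protocols.
#'
#' @param path file path
#' @rdname paradigm_io
#' @export
read_paradigm <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(ch) {
    if (is.null(y[[ch]]) || !length(y[[ch]])) return(NULL)
    m <- do.call(rbind, lapply(y[[ch]], unlist))
    stim_intervals(m[, 1], m[, 2])
  }
  stimulus_paradigm(mk("u1"), mk("u2"), mk("u3"),
                    sign = unlist(y$sign) %||% c(1, 1, 1),
                    label = y$label %||% "")
}

#' @param paradigm a [stimulus_paradigm()]
#' @rdname paradigm_io
#' @export
write_paradigm <- function(paradigm, path) {
  enc <- function(m) {
    if (is.null(m)) list() else
      lapply(seq_len(nrow(m)), function(i) as.list(unname(m[i, ])))
  }
  yaml::write_yaml(list(label = paradigm$label,
                        sign = as.list(paradigm$sign),
                        u1 = enc(paradigm$u$u1), u2 = enc(paradigm$u$u2),
                        u3 = enc(paradigm$u$u3)), path)
  invisible(path)
}

#' Total stimulus on-time of a paradigm channel
#'
#' @param paradigm a [stimulus_paradigm()]
#' @param channel 1, 2 or 3
#' @export
stimulus_on_time <- function(paradigm, channel = 3) {
  iv <- paradigm$u[[channel]]
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  sum(iv[, 2] - iv[, 1])
}

#' Parameter sharing across experimental setups
#'
#' A sharing map lists the experimental setups of a study and, per setup,
#' which free parameters take setup-specific ("unique") values; everything
#' else is shared. The reduced global vector names shared parameters plainly
#' and unique ones as `"<param>@<setup>"`. `apply_sharing_map` expands the
#' reduced vector into one full named vector per setup;
#' `flatten_sharing_map` inverts it (round-trip bijection).
#'
#' @param setups character vector of setup names
#' @param unique named list: setup -> character vector of parameter names
#'   unique to that setup
#' @param shared character vector of the shared parameter names
#' @export
sharing_map <- function(setups, unique = list(),
                        shared = names(default_theta())) {
  stop_if(!all(names(unique) %in% setups),
          "unique entries must name declared setups")
  # the reference setup (first) anchors the shared block, so it may not
  # carry unique overrides of its own
  stop_if(setups[1] %in% names(unique),
          "the first setup anchors the shared block and cannot have ",
          "unique parameters")
  structure(list(setups = setups, unique = unique, shared = shared),
            class = "sharing_map")
}

#' @param map a [sharing_map()]
#' @param global reduced named vector covering every shared name and every
#'   `param@setup` combination
#' @return named list of full parameter vectors, one per setup
#' @rdname sharing_map
#' @export
apply_sharing_map <- function(map, global) {
  out <- list()
  for (s in map$setups) {
    v <- global[map$shared]
    names(v) <- map$shared
    for (pn in map$unique[[s]] %||% character()) {
      key <- paste0(pn, "@", s)
      stop_if(!key %in% names(global),
              "sharing map references missing block: ", key)
      v[pn] <- global[[key]]
    }
    stop_if(any(is.na(v)), "global vector does not cover the sharing map")
    out[[s]] <- v
  }
  out
}

#' @param per_setup named list of full per-setup vectors
#' @rdname sharing_map
#' @export
flatten_sharing_map <- function(map, per_setup) {
  global <- per_setup[[map$setups[1]]][map$shared]
  names(global) <- map$shared
  for (s in map$setups) {
    for (pn in map$unique[[s]] %||% character()) {
      global[paste0(pn, "@", s)] <- per_setup[[s]][[pn]]
    }
  }
  global
}

#' Per-study sharing maps following the published overview table
#'
#' Drew: all parameters shared across the three stimulus lengths.
#' Desjardins: interneuron stimulus gains shared across optogenetic setups
#' (on the inhibitory channels), the pyramidal gain on the excitatory setup,
#' and per-variant unique gains for the two sensory durations.
#' Shmuel: stimulus gains, inter-neuronal couplings and activity sinks
#' unique between the positive and negative response; the LFP scaling is
#' present (shared).
#' Huber: stimulus gains unique per setup, everything else shared.
#'
#' @param study study id
#' @export
study_sharing_map <- function(study) {
  study <- match.arg(study, c("drew", "uhlirova", "desjardins",
                              "shmuel", "huber"))
  ku <- c("ku_NO", "ku_NPY", "ku_Pyr")
  neuro <- c("kPF1", "kPF2", "kIN1", "kIN2", "kINF1", "kINF2")
  sinks <- c("sinkN_NO", "sinkN_NPY", "sinkN_Pyr")
  switch(study,
    drew = sharing_map(c("short", "mid", "long")),
    uhlirova = sharing_map(c("og_pyr_anesth", "og_in_anesth",
                             "sensory_anesth", "sensory_awake", "og_awake")),
    desjardins = sharing_map(
      c("og_in_short", "og_in_long", "og_exc_short", "og_exc_long",
        "sensory_short", "sensory_long"),
      unique = list(sensory_short = ku, sensory_long = ku)),
    shmuel = sharing_map(c("positive", "negative"),
                         unique = list(negative = c(ku, neuro, sinks))),
    huber = sharing_map(c("positive", "excitatory", "negative", "inhibitory"),
                        unique = list(excitatory = ku, negative = ku,
                                      inhibitory = ku))
  )
}
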