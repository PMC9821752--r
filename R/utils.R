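`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# linear interpolation of a simulated column onto requested times; errors if
# the requested times fall outside the simulated horizon
interp_series <- function(sim_time, sim_value, at) {
  stop_if(min(at) < min(sim_time) - 1e-9 || max(at) > max(sim_time) + 1e-9,
          "requested times lie outside the simulated horizon")
  stats::approx(sim_time, sim_value, xout = at, rule = 2)$y
}
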