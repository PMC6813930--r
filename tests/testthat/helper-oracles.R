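# Independent fixed-step integration oracle: classical 4th-order
# Runge-Kutta at a small constant step, with the TLR switch re-evaluated on
# the same macro grid as the adaptive integrator. Shares only the compiled
# right-hand side (whose agreement with the reference R implementation is
# tested separately).

air_integrate_rk4 <- function(initial, params, t_end, dt = 1e-3,
                              macro_step = 0.05) {
  y <- as.numeric(initial)[1:18]
  R <- tlr_update(y[1], 0, params)
  boundaries <- seq(0, t_end, by = macro_step)
  for (i in seq_len(length(boundaries) - 1L)) {
    pv <- sepsim:::.air_parms_vec(params)
    times <- seq(boundaries[i], boundaries[i + 1L], by = dt)
    out <- deSolve::rk4(y = c(y, Rsw = R), times = times,
                        func = "air_derivs", parms = pv,
                        dllname = "sepsim", initfunc = "air_initmod",
                        nout = 1L)
    y <- pmax(as.numeric(out[nrow(out), 2:19]), 0)
    if (y[4] > 1) y[4] <- 1
    if (y[18] > 1) y[18] <- 1
    R <- tlr_update(y[1], R, params)
  }
  list(state = stats::setNames(y, sepsim:::.air_state_names), R = R)
}

# quick coupled severe run, reused by several tests (computed once)
severe_run_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_scenario(scenario(severity = "Severe", t_end = 48))
    cache
  }
})

first_crossing <- function(time, values, threshold, upward = FALSE) {
  idx <- if (upward) which(values > threshold) else which(values < threshold)
  if (length(idx)) time[min(idx)] else NA_real_
}
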