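# Build a ca_trajectory by hand from synthetic series, so the metrics can be
# exercised independently of the ODE models.
synthetic_trajectory <- function(time, ..., units = NULL) {
  cols <- list(...)
  states <- do.call(cbind, cols)
  colnames(states) <- names(cols)
  if (is.null(units)) units <- setNames(rep("uM", ncol(states)),
                                        colnames(states))
  structure(list(time = time, states = states, units = units,
                 meta = list(model = "synthetic", stimulus = "none",
                             solver = list(dt_out = diff(time[1:2])))),
            class = "ca_trajectory")
}

# quick solver settings for structural tests where full accuracy is wasted
fast_settings <- function(dt_out = 0.1)
  solver_settings(rtol = 1e-6, atol = 1e-8, dt_out = dt_out)
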