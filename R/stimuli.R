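#' Stimulus protocols
#'
#' Time-dependent scalar inputs used by the glutamate-evoked models (synaptic
#' glutamate concentration, in uM) and by the Riera model (the IP3 production
#' rate X_IP3, in uM/s). All protocols are piecewise constant, defined for
#' every t >= 0, with a finite, enumerable set of discontinuities so the
#' integrator can restart at each edge.
#'
#' `stimulus_constant()` holds a single level for all time.
#'
#' `stimulus_pulse_train()` is `high` on the half-open intervals
#' \[onset + k*period, onset + k*period + duration) for k = 0..n_pulses-1 and
#' `baseline` elsewhere. The first phase after `onset` is the high phase; use
#' `onset` to delay or re-phase the train. With `n_pulses = 0` the train
#' degenerates to a constant protocol at `baseline`.
#'
#' `stimulus_piecewise()` takes breakpoint times (first must be 0) and one
#' value per breakpoint; value `i` applies on \[times\[i\], times\[i+1\]) and the
#' last value extends to infinity.
#'
#' @param level,baseline,high scalar levels (uM for glutamate, uM/s for an
#'   IP3-production rate); must be finite and >= 0.
#' @param onset time of the first pulse edge, s.
#' @param duration high-phase duration per pulse, s; must satisfy
#'   `duration <= period`.
#' @param period pulse repetition period, s.
#' @param n_pulses number of pulses (>= 0).
#' @param times,values breakpoint times (strictly increasing, starting at 0)
#'   and the level applying from each breakpoint.
#' @param unit unit string carried as metadata ("uM" or "uM/s"); the engine
#'   itself is unit-agnostic.
#' @return An object of class `ca_stimulus`.
#' @examples
#' am <- stimulus_pulse_train(baseline = 0.002, high = 5,
#'                            duration = 62.5, period = 125, n_pulses = 2)
#' eval_stimulus(am, c(0, 62.5, 70))
#' @seealso [eval_stimulus()], [stimulus_breakpoints()]
#' @export
stimulus_constant <- function(level, unit = "uM") {
  stopifnot(is.numeric(level), length(level) == 1L)
  if (!is.finite(level) || level < 0)
    stop("stimulus level must be finite and >= 0", call. = FALSE)
  structure(list(kind = "constant", baseline = level, unit = unit),
            class = "ca_stimulus")
}

#' @rdname stimulus_constant
#' @export
stimulus_pulse_train <- function(baseline, high, onset = 0, duration, period,
                                 n_pulses, unit = "uM") {
  vals <- c(baseline = baseline, high = high, onset = onset,
            duration = duration, period = period, n_pulses = n_pulses)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("pulse-train arguments must be finite and >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (duration > period)
    stop("duration must not exceed period", call. = FALSE)
  if (n_pulses != round(n_pulses) || n_pulses < 0)
    stop("n_pulses must be a non-negative integer", call. = FALSE)
  if (n_pulses == 0) return(stimulus_constant(baseline, unit))
  structure(list(kind = "pulse_train", baseline = baseline, high = high,
                 onset = onset, duration = duration, period = period,
                 n_pulses = as.integer(n_pulses), unit = unit),
            class = "ca_stimulus")
}

#' @rdname stimulus_constant
#' @export
stimulus_piecewise <- function(times, values, unit = "uM") {
  if (length(times) != length(values) || length(times) < 1L)
    stop("times and values must have equal, positive length", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)) || any(values < 0))
    stop("breakpoints must be finite; values must be >= 0", call. = FALSE)
  if (times[1L] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  structure(list(kind = "piecewise_constant", times = as.numeric(times),
                 values = as.numeric(values), unit = unit),
            class = "ca_stimulus")
}

#' Evaluate a stimulus protocol
#'
#' Returns the protocol value at each time in `t`, using the half-open
#' convention: a pulse starting at `s` with duration `d` is high on
#' \[s, s + d). Evaluation is pure and vectorized over `t`.
#'
#' @param stimulus a [stimulus_constant()], [stimulus_pulse_train()] or
#'   [stimulus_piecewise()] object.
#' @param t times, s; all must be >= 0.
#' @return numeric vector of protocol values, same length as `t`.
#' @export
eval_stimulus <- function(stimulus, t) {
  stopifnot(inherits(stimulus, "ca_stimulus"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("evaluation times must be finite and >= 0", call. = FALSE)
  switch(stimulus$kind,
    constant = rep(stimulus$baseline, length(t)),
    pulse_train = {
      rel <- t - stimulus$onset
      k <- floor(rel / stimulus$period)
      phase <- rel - k * stimulus$period
      hi <- rel >= 0 & k < stimulus$n_pulses & phase < stimulus$duration
      ifelse(hi, stimulus$high, stimulus$baseline)
    },
    piecewise_constant = {
      idx <- findInterval(t, stimulus$times)
      stimulus$values[pmax(idx, 1L)]
    },
    stop("unknown stimulus kind", call. = FALSE))
}

#' Discontinuity times of a stimulus protocol
#'
#' Enumerates every time at which the protocol value can jump, up to `t_end`.
#' The integrator restarts at each of these edges so no pulse is stepped over.
#'
#' @inheritParams eval_stimulus
#' @param t_end upper bound, s.
#' @return sorted numeric vector of edge times in (0, t_end).
#' @export
stimulus_breakpoints <- function(stimulus, t_end = Inf) {
  stopifnot(inherits(stimulus, "ca_stimulus"))
  bp <- switch(stimulus$kind,
    constant = numeric(0),
    pulse_train = {
      k <- seq_len(stimulus$n_pulses) - 1L
      starts <- stimulus$onset + k * stimulus$period
      sort(c(starts, starts + stimulus$duration))
    },
    piecewise_constant = stimulus$times[-1L])
  bp[bp > 0 & bp < t_end]
}

#' @export
print.ca_stimulus <- function(x, ...) {
  cat("<ca_stimulus:", x$kind, ">\n")
  switch(x$kind,
    constant = cat("  level:", x$baseline, x$unit, "\n"),
    pulse_train = cat(sprintf(
      "  %g -> %g %s, onset %g s, duration %g s, period %g s, %d pulse(s)\n",
      x$baseline, x$high, x$unit, x$onset, x$duration, x$period, x$n_pulses)),
    piecewise_constant = cat("  breakpoints:",
      paste(sprintf("(%g s, %g %s)", x$times, x$values, x$unit),
            collapse = " "), "\n"))
  invisible(x)
}

# compact one-line description for trajectory metadata / run logs
format_stimulus <- function(stimulus) {
  if (is.null(stimulus)) return("none")
  switch(stimulus$kind,
    constant = sprintf("constant %g %s", stimulus$baseline, stimulus$unit),
    pulse_train = sprintf(
      "pulse_train %g/%g %s onset %g dur %g per %g n %d",
      stimulus$baseline, stimulus$high, stimulus$unit, stimulus$onset,
      stimulus$duration, stimulus$period, stimulus$n_pulses),
    piecewise_constant = sprintf("piecewise_constant %d segment(s)",
                                 length(stimulus$values)))
}
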