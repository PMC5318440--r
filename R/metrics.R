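# Oscillation analysis: peak detection with topographic prominence, the
# sustained-oscillation / cessation classification used throughout the
# comparability experiments, the percent-change statistic, pairwise run
# comparison, and glutamate regime scans.

# local maxima (interior points; left-strict so plateau onsets count once)
# with topographic prominence: extend from each peak in both directions
# until a strictly higher sample (or the boundary), take the minimum on each
# side, prominence = height - max(left min, right min).
.peak_prominences <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), value = numeric(0),
                                prominence = numeric(0)))
  mid <- 2:(n - 1L)
  idx <- mid[x[mid] > x[mid - 1L] & x[mid] >= x[mid + 1L]]
  prom <- vapply(idx, function(i) {
    higher <- which(x[1:i] > x[i])
    lmin <- min(x[(if (length(higher)) max(higher) else 1L):i])
    higher <- which(x[i:n] > x[i])
    rmin <- min(x[i:(if (length(higher)) i + min(higher) - 1L else n)])
    x[i] - max(lmin, rmin)
  }, numeric(1L))
  data.frame(index = idx, value = x[idx], prominence = prom)
}

#' Detect peaks by topographic prominence
#'
#' Interior local maxima of a uniformly sampled series whose topographic
#' prominence (height above the highest saddle connecting the peak to higher
#' terrain, or to the series boundary) reaches `prominence`.
#'
#' @param x numeric series sampled on a uniform grid.
#' @param prominence minimum prominence, in the units of `x`.
#' @param times optional time stamps; must be a uniform grid (checked to
#'   within 1e-6 of the median spacing).
#' @return data.frame with columns `index`, `time` (if `times` given),
#'   `value`, `prominence`.
#' @examples
#' t <- seq(0, 100, by = 0.05)
#' nrow(detect_peaks(sin(2 * pi * t / 10), 0.5, t))  # 10
#' @export
detect_peaks <- function(x, prominence, times = NULL) {
  stopifnot(is.numeric(x), length(x) >= 3L, prominence >= 0)
  if (!is.null(times)) {
    if (length(times) != length(x))
      stop("times must match x in length", call. = FALSE)
    d <- diff(times)
    if (any(abs(d - stats::median(d)) > 1e-6 * stats::median(d) + 1e-12))
      stop("times must form a uniform grid", call. = FALSE)
  }
  pk <- .peak_prominences(x)
  pk <- pk[pk$prominence >= prominence, , drop = FALSE]
  if (!is.null(times))
    pk <- data.frame(index = pk$index, time = times[pk$index],
                     value = pk$value, prominence = pk$prominence)
  rownames(pk) <- NULL
  pk
}

#' Oscillation classification criteria
#'
#' The single operational definition of "oscillating" used everywhere in the
#' package, including the regime scans. A peak qualifies when its topographic
#' prominence reaches `max(prominence_floor, rel_prominence * range)` for
#' concentration variables, or `rel_prominence * range` for dimensionless
#' fraction variables (no absolute floor: fractions live on \[0, 1\]), where
#' the range is taken over the analysis window. A variable is oscillating
#' when at least `min_peaks` qualifying peaks fall inside the analysis
#' window (the final `window_fraction` of the run, excluding the initial
#' transient). Oscillation has ceased when the gap between the last
#' qualifying peak and the end of the run exceeds `cessation_gap` mean
#' inter-peak intervals; the cessation time is the time of that last peak.
#'
#' @param prominence_floor absolute prominence floor for concentration
#'   variables, uM.
#' @param rel_prominence relative prominence, as a fraction of the variable's
#'   range over the analysis window.
#' @param window_fraction final fraction of the run analyzed for the
#'   sustained-oscillation classification.
#' @param min_peaks minimum number of qualifying window peaks for
#'   `oscillating = TRUE`.
#' @param cessation_gap trailing peak-free gap, in units of the mean
#'   inter-peak interval, after which the oscillation counts as ceased.
#' @param noise_floor absolute lower bound on any prominence threshold, so
#'   that a variable resting at a steady state is never classified as
#'   oscillating on double-precision ripples (the default sits orders of
#'   magnitude below genuine fraction-variable oscillations and orders of
#'   magnitude above solver round-off).
#' @return list of class `oscillation_criteria`.
#' @export
oscillation_criteria <- function(prominence_floor = 0.005,
                                 rel_prominence = 0.01,
                                 window_fraction = 2 / 3, min_peaks = 3L,
                                 cessation_gap = 2, noise_floor = 1e-9) {
  stopifnot(prominence_floor >= 0, rel_prominence >= 0,
            window_fraction > 0, window_fraction <= 1, min_peaks >= 1,
            cessation_gap > 0, noise_floor >= 0)
  structure(list(prominence_floor = prominence_floor,
                 rel_prominence = rel_prominence,
                 window_fraction = window_fraction,
                 min_peaks = as.integer(min_peaks),
                 cessation_gap = cessation_gap, noise_floor = noise_floor),
            class = "oscillation_criteria")
}

# classification of a single series; dimensionless = no absolute floor
.classify_series <- function(time, x, dimensionless, criteria) {
  t_end <- time[length(time)]
  w0 <- t_end * (1 - criteria$window_fraction)
  win <- time >= w0
  rng <- diff(range(x[win]))
  thr <- criteria$rel_prominence * rng
  if (!dimensionless) thr <- max(criteria$prominence_floor, thr)
  thr <- max(thr, criteria$noise_floor)
  pk <- .peak_prominences(x)
  pk <- pk[pk$prominence >= thr, , drop = FALSE]
  pt <- time[pk$index]
  n_win <- sum(pt >= w0)
  oscillating <- n_win >= criteria$min_peaks
  cessation <- NA_real_
  if (nrow(pk) >= 2L) {
    ipi <- mean(diff(pt))
    if (t_end - pt[length(pt)] > criteria$cessation_gap * ipi)
      cessation <- pt[length(pt)]
  }
  list(peak_times = pt, peak_values = pk$value,
       mean_interval = if (nrow(pk) >= 2L) mean(diff(pt)) else NA_real_,
       amplitude = rng, n_peaks_window = n_win, threshold = thr,
       oscillating = oscillating, cessation_time = cessation)
}

#' Oscillation summary of a trajectory
#'
#' Classifies every state variable of a trajectory by the criteria of
#' [oscillation_criteria()]: qualifying peaks (over the whole run), mean
#' inter-peak interval, amplitude over the analysis window, the
#' sustained-oscillation flag, and the cessation time (time of the last
#' qualifying peak, reported only when oscillation has actually ceased
#' before the end of the run).
#'
#' @param traj a `ca_trajectory` (from [integrate_model()]).
#' @param criteria an [oscillation_criteria()] object.
#' @return object of class `oscillation_summary`: a named list, one entry
#'   per variable, plus attributes `t_end` and `window_start`.
#' @export
oscillation_summary <- function(traj, criteria = oscillation_criteria()) {
  stopifnot(inherits(traj, "ca_trajectory"),
            inherits(criteria, "oscillation_criteria"))
  if (length(traj$time) < 3L)
    stop("trajectory too short to analyze", call. = FALSE)
  out <- lapply(colnames(traj$states), function(v)
    .classify_series(traj$time, traj$states[, v],
                     dimensionless = identical(traj$units[[v]], ""),
                     criteria))
  names(out) <- colnames(traj$states)
  structure(out, class = "oscillation_summary",
            t_end = traj$time[length(traj$time)],
            window_start = traj$time[length(traj$time)] *
              (1 - criteria$window_fraction))
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat(sprintf("<oscillation_summary> window [%g, %g] s\n",
              attr(x, "window_start"), attr(x, "t_end")))
  for (v in names(x)) {
    s <- x[[v]]
    cat(sprintf(
      "  %-8s %-3s peaks(win) %3d, amplitude %.4g, period %s s, %s\n", v,
      if (s$oscillating) "osc" else "---", s$n_peaks_window, s$amplitude,
      if (is.na(s$mean_interval)) "-" else sprintf("%.3g", s$mean_interval),
      if (is.na(s$cessation_time)) "sustained/none"
      else sprintf("ceased at %.1f s", s$cessation_time)))
  }
  invisible(x)
}

#' Percent change between an original and a reproduced value
#'
#' (y - x) / x * 100, with x the original (reference) value and y the
#' reproduced (candidate) value.
#'
#' @param x reference value(s), nonzero.
#' @param y candidate value(s).
#' @return percent change.
#' @examples
#' percent_change(2, 1)     # -50
#' percent_change(1, 1.54)  # +54
#' @export
percent_change <- function(x, y) {
  if (any(x == 0))
    stop("percent change is undefined for a zero reference", call. = FALSE)
  (y - x) / x * 100
}

#' Compare two runs variable by variable
#'
#' For every variable the two runs share: the minimum and maximum of each
#' run, the percent change of the candidate's extrema against the
#' reference's, and the sustained-oscillation flags of both runs. The
#' reference may be a full trajectory or a plain data.frame with a `time`
#' column and one column per variable (e.g. a digitized reference curve).
#'
#' @param reference a `ca_trajectory` or data.frame (reference, the `x` of
#'   the percent-change statistic).
#' @param candidate a `ca_trajectory` (the `y`).
#' @param criteria an [oscillation_criteria()] object.
#' @return object of class `comparison_report`: data.frame with one row per
#'   shared variable and columns `variable`, `ref_min`, `ref_max`,
#'   `cand_min`, `cand_max`, `min_pct`, `max_pct`, `ref_oscillating`,
#'   `cand_oscillating`.
#' @export
compare_runs <- function(reference, candidate,
                         criteria = oscillation_criteria()) {
  as_tab <- function(x) {
    if (inherits(x, "ca_trajectory")) return(x)
    stopifnot(is.data.frame(x), "time" %in% names(x))
    states <- as.matrix(x[setdiff(names(x), "time")])
    structure(list(time = x$time, states = states,
                   units = stats::setNames(rep("uM", ncol(states)),
                                           colnames(states)),
                   meta = list(model = "reference")),
              class = "ca_trajectory")
  }
  ref <- as_tab(reference); cand <- as_tab(candidate)
  common <- intersect(colnames(ref$states), colnames(cand$states))
  if (!length(common))
    stop("runs share no variables", call. = FALSE)
  lo <- max(min(ref$time), min(cand$time))
  hi <- min(max(ref$time), max(cand$time))
  if (hi <= lo) stop("runs share no time window", call. = FALSE)
  sr <- oscillation_summary(ref, criteria)
  sc <- oscillation_summary(cand, criteria)
  rw <- ref$time >= lo & ref$time <= hi
  cw <- cand$time >= lo & cand$time <= hi
  rows <- lapply(common, function(v) {
    rmin <- min(ref$states[rw, v]); rmax <- max(ref$states[rw, v])
    cmin <- min(cand$states[cw, v]); cmax <- max(cand$states[cw, v])
    data.frame(variable = v, ref_min = rmin, ref_max = rmax,
               cand_min = cmin, cand_max = cmax,
               min_pct = if (rmin == 0 && cmin == 0) 0
                         else percent_change(rmin, cmin),
               max_pct = if (rmax == 0 && cmax == 0) 0
                         else percent_change(rmax, cmax),
               ref_oscillating = sr[[v]]$oscillating,
               cand_oscillating = sc[[v]]$oscillating,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("comparison_report",
                                            "data.frame"))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  y <- x
  class(y) <- "data.frame"
  y$min_pct <- sprintf("%+.2f", y$min_pct)
  y$max_pct <- sprintf("%+.2f", y$max_pct)
  print(y, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Scan constant glutamate levels
#'
#' Integrates a glutamate-evoked model once per level and classifies each
#' run: do all state variables sustain oscillation, and when does the
#' cytosolic Ca2+ oscillation cease (if it does)?
#'
#' @param model a [ca_model()] with the `glutamate` stimulus slot.
#' @param levels constant glutamate levels, uM, sorted increasing; the
#'   Dupont model requires strictly positive levels.
#' @param t_end run length per level, s.
#' @param settings a [solver_settings()].
#' @param criteria an [oscillation_criteria()].
#' @return data.frame of class `glu_scan`: columns `glu`, `all_oscillating`,
#'   `ca_oscillating`, `ca_cessation_time`, `ca_peaks_window`.
#' @export
glu_scan <- function(model, levels, t_end = 600,
                     settings = solver_settings(),
                     criteria = oscillation_criteria()) {
  stopifnot(inherits(model, "ca_model"))
  if (model$stimulus_slot != "glutamate")
    stop("glu_scan applies to glutamate-evoked models", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE) || any(levels < 0))
    stop("levels must be >= 0 and strictly increasing", call. = FALSE)
  rows <- lapply(levels, function(g) {
    traj <- tryCatch(
      integrate_model(model, stimulus_constant(g), t_end, settings),
      error = function(e) stop("integration failed at Glu = ", g, " uM: ",
                               conditionMessage(e), call. = FALSE))
    s <- oscillation_summary(traj, criteria)
    data.frame(glu = g,
               all_oscillating = all(vapply(s, `[[`, TRUE, "oscillating")),
               ca_oscillating = s$Ca$oscillating,
               ca_cessation_time = s$Ca$cessation_time,
               ca_peaks_window = s$Ca$n_peaks_window)
  })
  structure(do.call(rbind, rows), class = c("glu_scan", "data.frame"))
}

#' Non-oscillatory band and cessation threshold of a scan
#'
#' `oscillation_band()` returns the lowest and highest level of the longest
#' contiguous run of levels at which not all variables oscillate (ties
#' broken toward lower glutamate); `cessation_threshold()` the smallest
#' level whose Ca2+ oscillation ceases before the end of the run.
#'
#' @param scan a [glu_scan()] result.
#' @return `oscillation_band()`: named numeric `c(lower, upper)`, or `NULL`
#'   when every level is all-oscillating. `cessation_threshold()`: a level,
#'   or `NA` if none ceases.
#' @export
oscillation_band <- function(scan) {
  stopifnot(inherits(scan, "glu_scan") || is.data.frame(scan))
  flag <- !scan$all_oscillating
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]  # which.max takes the first tie
  c(lower = scan$glu[starts[best]], upper = scan$glu[ends[best]])
}

#' @rdname oscillation_band
#' @export
cessation_threshold <- function(scan) {
  stopifnot(inherits(scan, "glu_scan") || is.data.frame(scan))
  idx <- which(is.finite(scan$ca_cessation_time))
  if (!length(idx)) return(NA_real_)
  scan$glu[min(idx)]
}

#' Synthetic oscillatory traces
#'
#' Deterministic fixture traces for exercising the metrics independently of
#' the models: a sinusoid `amplitude * sin(2 pi t / period)`, a damped
#' sinusoid with envelope `amplitude * exp(-t / tau)`, or a constant. The
#' seed only affects the optional additive Gaussian noise; with
#' `noise_sd = 0` the trace is identical for every seed.
#'
#' @param kind `"sine"`, `"damped_sine"` or `"constant"`.
#' @param t_end,dt trace length and sampling interval, s.
#' @param amplitude,period,tau,level shape parameters (units of the trace
#'   and s).
#' @param noise_sd standard deviation of additive noise (0 = none).
#' @param seed RNG seed for the noise.
#' @return data.frame with columns `time`, `value`.
#' @export
make_synthetic_trace <- function(kind = c("sine", "damped_sine", "constant"),
                                 t_end = 100, dt = 0.05, amplitude = 1,
                                 period = 10, tau = 20, level = 0,
                                 noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(t_end > 0, dt > 0, period > 0, tau > 0, noise_sd >= 0)
  t <- seq(0, t_end, by = dt)
  x <- switch(kind,
    sine = amplitude * sin(2 * pi * t / period),
    damped_sine = amplitude * exp(-t / tau) * sin(2 * pi * t / period),
    constant = rep(level, length(t)))
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    x <- x + stats::rnorm(length(x), sd = noise_sd)
  }
  data.frame(time = t, value = x)
}
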