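#' Solver settings
#'
#' Numerical controls for [integrate_model()]. The default is a stiff-capable
#' adaptive method (lsoda) at tight tolerances with a 0.05-s output grid;
#' with these defaults a tenfold tolerance refinement changes reported Ca2+
#' extrema in the registry scenarios by well under 0.1%. The fixed-step
#' explicit mode (classical forward Euler) is retained for pedagogy only and
#' is not used by any scenario.
#'
#' @param rtol relative tolerance (> 0).
#' @param atol absolute tolerance, uM (> 0); also the clipping band for
#'   slightly negative solver output.
#' @param dt_out output sampling interval, s (> 0).
#' @param max_step optional cap on the internal step, s. When a pulse train
#'   is active and `max_step` is `NULL`, the integrator caps the step at one
#'   tenth of the shorter pulse phase so no edge region is skated over.
#' @param method `"stiff"` (lsoda, adaptive) or `"explicit"` (fixed-step
#'   forward Euler on a grid of `euler_step`).
#' @param euler_step step size for the explicit method, s.
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-10, dt_out = 0.05,
                            max_step = NULL, method = c("stiff", "explicit"),
                            euler_step = 0.001) {
  method <- match.arg(method)
  stopifnot(rtol > 0, atol > 0, dt_out > 0, euler_step > 0,
            is.null(max_step) || max_step > 0)
  structure(list(rtol = rtol, atol = atol, dt_out = dt_out,
                 max_step = max_step, method = method,
                 euler_step = euler_step),
            class = "solver_settings")
}

# Integrate dydt = flux(state, stim_value) segment-wise between stimulus
# discontinuities. `flux` takes the clipped state and the (constant within a
# segment) stimulus value. Shared by integrate_model() and the tests' toy
# systems.
.integrate_segments <- function(flux, y0, t_end, stimulus, settings) {
  bp <- if (is.null(stimulus)) numeric(0) else
    stimulus_breakpoints(stimulus, t_end)
  edges <- sort(unique(c(0, bp, t_end)))
  hmax <- settings$max_step
  if (is.null(hmax) && !is.null(stimulus) &&
      stimulus$kind == "pulse_train") {
    phases <- c(stimulus$duration, stimulus$period - stimulus$duration)
    hmax <- max(min(phases[phases > 0]) / 10, settings$dt_out)
  }
  deriv <- function(t, y, parms)
    list(flux(pmax(y, 0), parms))
  ts_all <- NULL
  ys_all <- NULL
  y <- y0
  for (i in seq_len(length(edges) - 1L)) {
    a <- edges[i]; b <- edges[i + 1L]
    times <- seq(a, b, by = settings$dt_out)
    if (times[length(times)] < b) times <- c(times, b)
    sval <- if (is.null(stimulus)) NULL else
      eval_stimulus(stimulus, (a + b) / 2)  # constant within the segment;
      # the midpoint avoids float ambiguity at the edges themselves

    sol <- if (settings$method == "stiff") {
      deSolve::ode(y, times, deriv, parms = sval, method = "lsoda",
                   rtol = settings$rtol, atol = settings$atol,
                   hmax = if (is.null(hmax)) Inf else hmax)
    } else {
      grid <- seq(a, b, by = settings$euler_step)
      if (grid[length(grid)] < b) grid <- c(grid, b)
      full <- deSolve::ode(y, grid, deriv, parms = sval, method = "euler")
      idx <- findInterval(times, grid)
      full[idx, , drop = FALSE]
    }
    last <- as.numeric(sol[nrow(sol), 1L])
    if (abs(last - b) > 1e-8 * max(1, b) || anyNA(as.vector(sol)))
      stop("integration failed at t = ", signif(last, 6), " s",
           call. = FALSE)
    y <- sol[nrow(sol), -1L]
    keep <- if (i == 1L) seq_len(nrow(sol)) else seq(2L, nrow(sol))
    ts_all <- c(ts_all, sol[keep, 1L])
    ys_all <- rbind(ys_all, sol[keep, -1L, drop = FALSE])
  }
  if (any(!is.finite(ys_all)))
    stop("non-finite state encountered during integration", call. = FALSE)
  if (any(ys_all < -settings$atol))
    stop("state fell below -atol (", -settings$atol, "); model left the ",
         "admissible region", call. = FALSE)
  ys_all[ys_all < 0] <- 0
  list(time = ts_all, states = ys_all)
}

#' Integrate a model into a trajectory
#'
#' Solves the model ODEs over \[0, t_end\] under the given stimulus,
#' restarting the solver at every stimulus discontinuity so pulse edges are
#' honored exactly, and samples the solution on a uniform grid. States that
#' the solver reports in \[-atol, 0) are clipped to 0; anything below -atol
#' aborts.
#'
#' @param model a [ca_model()] object.
#' @param stimulus a `ca_stimulus`, required iff the model has a stimulus
#'   slot (`riera`, `depitta`, `dupont`); must be `NULL` for `lavrentovich`.
#' @param t_end simulation end time, s (> 0).
#' @param settings a [solver_settings()] object.
#' @return object of class `ca_trajectory`: list with `time` (s), `states`
#'   (matrix, one column per state variable), `units`, and `meta` (model
#'   name, variants, stimulus description, solver settings).
#' @examples
#' \donttest{
#' traj <- integrate_model(ca_model("lavrentovich"), t_end = 600)
#' summary(traj)
#' }
#' @export
integrate_model <- function(model, stimulus = NULL, t_end,
                            settings = solver_settings()) {
  stopifnot(inherits(model, "ca_model"), t_end > 0)
  needs_stim <- model$stimulus_slot != "none"
  if (needs_stim && is.null(stimulus))
    stop("model '", model$name, "' requires a ", model$stimulus_slot,
         " stimulus", call. = FALSE)
  if (!needs_stim && !is.null(stimulus))
    stop("model '", model$name, "' takes no stimulus", call. = FALSE)
  if (!is.null(stimulus) && !inherits(stimulus, "ca_stimulus"))
    stop("stimulus must be a ca_stimulus object", call. = FALSE)
  flux <- .model_flux(model)
  sol <- .integrate_segments(function(y, s) flux(y, s), model$initial_state,
                             t_end, stimulus, settings)
  colnames(sol$states) <- model$state_names
  structure(list(time = sol$time, states = sol$states,
                 units = model$state_units,
                 meta = list(model = model$name, variants = model$variants,
                             params = model$params,
                             stimulus = format_stimulus(stimulus),
                             t_end = t_end,
                             solver = unclass(settings))),
            class = "ca_trajectory")
}

#' Simulate a model (classic generic)
#'
#' Thin wrapper around [integrate_model()] so model objects follow the usual
#' `simulate()` idiom. The models are deterministic; `seed` and `nsim` are
#' accepted for signature compatibility and ignored beyond a warning when
#' `nsim > 1`.
#'
#' @param object a [ca_model()] object.
#' @param nsim,seed ignored (deterministic dynamics).
#' @param stimulus,t_end,settings passed to [integrate_model()].
#' @param ... unused.
#' @return a `ca_trajectory`.
#' @export
simulate.ca_model <- function(object, nsim = 1, seed = NULL, stimulus = NULL,
                              t_end = 600, settings = solver_settings(),
                              ...) {
  if (nsim > 1)
    warning("the dynamics are deterministic; returning a single trajectory")
  integrate_model(object, stimulus = stimulus, t_end = t_end,
                  settings = settings)
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat("<ca_trajectory:", x$meta$model, ">\n")
  cat(sprintf("  %d samples over [0, %g] s (dt = %g s)\n", length(x$time),
              max(x$time), x$meta$solver$dt_out))
  cat("  stimulus:", x$meta$stimulus, "\n")
  rng <- apply(x$states, 2L, range)
  cat("  ranges  :", paste(sprintf("%s [%.4g, %.4g]", colnames(x$states),
                                   rng[1L, ], rng[2L, ]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.ca_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$states, check.names = FALSE)
}

#' @export
plot.ca_trajectory <- function(x, vars = colnames(x$states), ...) {
  vars <- match.arg(vars, colnames(x$states), several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(vars), 1L),
                       mar = c(2.5, 4, 0.8, 0.8))
  on.exit(graphics::par(old))
  for (v in vars) {
    u <- x$units[[v]]
    graphics::plot(x$time, x$states[, v], type = "l",
                   xlab = "time (s)",
                   ylab = if (u == "") v else paste0(v, " (", u, ")"), ...)
  }
  invisible(x)
}

#' Trajectory serialization
#'
#' `write_trajectory()` writes the time grid and states as CSV (column names
#' carry units as `name_uM`; fixed `%.10g` formatting so identical runs give
#' byte-identical files) plus an optional JSON metadata sidecar.
#' `read_trajectory()` reads the pair back.
#'
#' @param traj a `ca_trajectory`.
#' @param csv_path output CSV path.
#' @param meta_path optional JSON sidecar path.
#' @return `write_trajectory()`: `csv_path`, invisibly. `read_trajectory()`:
#'   a `ca_trajectory` (metadata only if a sidecar is given).
#' @export
write_trajectory <- function(traj, csv_path, meta_path = NULL) {
  stopifnot(inherits(traj, "ca_trajectory"))
  cols <- c("time_s", paste0(colnames(traj$states), ifelse(
    traj$units == "", "", paste0("_", gsub("/", "", traj$units)))))
  m <- cbind(traj$time, traj$states)
  lines <- c(paste(cols, collapse = ","),
             apply(m, 1L, function(r) paste(sprintf("%.10g", r),
                                            collapse = ",")))
  writeLines(lines, csv_path)
  if (!is.null(meta_path))
    jsonlite::write_json(traj$meta, meta_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  invisible(csv_path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(csv_path, meta_path = NULL) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  nm <- sub("_(uM|uMs|1s)$", "", colnames(df)[-1L])
  units <- ifelse(grepl("_uM$", colnames(df)[-1L]), "uM",
                  ifelse(grepl("_uMs$", colnames(df)[-1L]), "uM/s", ""))
  states <- as.matrix(df[, -1L, drop = FALSE])
  colnames(states) <- nm
  meta <- if (!is.null(meta_path)) jsonlite::read_json(meta_path,
                                                       simplifyVector = TRUE)
          else list(model = "unknown", stimulus = "unknown",
                    solver = list(dt_out = diff(df[[1L]][1:2])))
  structure(list(time = df[[1L]], states = states,
                 units = stats::setNames(units, nm), meta = meta),
            class = "ca_trajectory")
}

#' @export
summary.ca_trajectory <- function(object, criteria = oscillation_criteria(),
                                  ...) {
  oscillation_summary(object, criteria)
}
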