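# Named registry of every simulation condition used in the reproduction and
# comparability experiments. Durations are package decisions (the original
# figure time axes are not printed): 600 s for Lavrentovich / De Pitta /
# Dupont conditions, 1200 s for the Riera pulse conditions so the
# [100, 900) s X_IP3 pulse ends well inside the run.

.scenario <- function(id, model, note, variants = list(), params = list(),
                      stimulus = NULL, t_end = 600) {
  list(id = id, model = model, variants = variants, params = params,
       stimulus = stimulus, t_end = t_end, note = note)
}

.xip3_pulse <- function(baseline)
  stimulus_piecewise(c(0, 100, 900), c(baseline, 0.43, baseline),
                     unit = "uM/s")

.am_two_pulse <- function() stimulus_pulse_train(0.002, 5, 0, 62.5, 125, 2)

# the six Lavrentovich <-> Riera parameter pairs that sit in equations of
# identical form in the two models (Lavrentovich name = Riera name)
.swap_pairs <- c(v_in = "j_in", v_M2 = "V_SERCA", k_f = "v2",
                 v_p = "v_delta", k_p = "K_dCa", k_deg = "K_IP3")

#' Parameter pairs shared by the Lavrentovich and Riera models
#'
#' The six parameters that appear in equations of identical algebraic form
#' in the two spontaneous models, used for the cross-substitution
#' experiments: membrane influx (v_in / j_in), maximal SERCA rate
#' (v_M2 / V_SERCA), ER leak rate (k_f / v2), maximal PLC-delta rate
#' (v_p / v_delta), PLC-delta half-activation (k_p / K_dCa) and IP3
#' degradation (k_deg / K_IP3).
#'
#' @return named character vector: names are Lavrentovich parameters, values
#'   the corresponding Riera parameters.
#' @export
parameter_swaps <- function() .swap_pairs

.build_registry <- function() {
  riera_all_in_lav <- as.list(coef(ca_model("riera"))[.swap_pairs])
  names(riera_all_in_lav) <- names(.swap_pairs)
  lav_all_in_riera <- as.list(coef(ca_model("lavrentovich"))[
    names(.swap_pairs)])
  names(lav_all_in_riera) <- .swap_pairs
  sc <- list(
    .scenario("lavrentovich_fig3", "lavrentovich",
      "Spontaneous oscillations with the published setup; all three variables plotted over 600 s."),
    .scenario("riera_fig4b_baseline0", "riera",
      "Clamped total free Ca2+ (2 uM); X_IP3 pulse 0.43 uM/s on [100, 900) s, zero outside. IP3 drops to near zero before the pulse.",
      stimulus = .xip3_pulse(0), t_end = 1200),
    .scenario("riera_fig4b_baseline02", "riera",
      "As baseline0 but with the inferred nonzero pre/post-pulse X_IP3 of 0.2 uM/s, which keeps h and IP3 high before the pulse.",
      stimulus = .xip3_pulse(0.2), t_end = 1200),
    .scenario("depitta_fig12am", "depitta",
      "Amplitude-modulation stimulus: two-pulse glutamate train alternating 0.002 and 5 uM, 62.5 s pulses, 125 s period.",
      stimulus = .am_two_pulse()),
    .scenario("dupont_fig2", "dupont",
      "Constant 8 uM glutamate with the corrected Ca2+ equation; Ca2+ and receptor dimer oscillations.",
      stimulus = stimulus_constant(8)),
    .scenario("lavrentovich_zeroflux", "lavrentovich",
      "Membrane flux balance v_in - k_out Ca forced to zero: oscillations disappear and Ca + CaER is conserved.",
      variants = list(zero_membrane_flux = TRUE)),
    .scenario("riera_xip3_zero", "riera",
      "Clamped total free Ca2+ with X_IP3 = 0 throughout: no oscillation, IP3 nearly vanishes.",
      stimulus = stimulus_constant(0, unit = "uM/s")),
    .scenario("lavrentovich_vm2_5p8", "lavrentovich",
      "SERCA maximum lowered to 5.8 uM/s to maximize oscillation frequency: more Ca2+ peaks than the published 15 uM/s.",
      params = list(v_M2 = 5.8)),
    .scenario("riera_free_catotal_xip3_const", "riera",
      "Total free Ca2+ left dynamic (membrane fluxes active) with constant X_IP3 = 0.43 uM/s.",
      variants = list(clamp_ca_free = FALSE),
      stimulus = stimulus_constant(0.43, unit = "uM/s")),
    .scenario("depitta_const_0p1", "depitta",
      "Constant 0.1 uM glutamate (low end of the constant-stimulus comparison).",
      stimulus = stimulus_constant(0.1)),
    .scenario("depitta_const_2p5", "depitta",
      "Constant 2.5 uM glutamate: all three variables oscillate, Ca2+ maxima higher than at 0.1 uM.",
      stimulus = stimulus_constant(2.5)),
    .scenario("dupont_const_0p1", "dupont",
      "Constant 0.1 uM glutamate; all six variables oscillate.",
      stimulus = stimulus_constant(0.1)),
    .scenario("dupont_const_2p5", "dupont",
      "Constant 2.5 uM glutamate: only Ca2+ and the inactive-receptor fraction oscillate, and Ca2+ maxima are LOWER than at 0.1 uM (opposite to De Pitta).",
      stimulus = stimulus_constant(2.5)),
    .scenario("depitta_sevenpulse_5s15s", "depitta",
      "Seven-pulse train 0.002/5 uM, 5 s pulses, 15 s period.",
      stimulus = stimulus_pulse_train(0.002, 5, 0, 5, 15, 7)),
    .scenario("depitta_sevenpulse_1s6s", "depitta",
      "Seven-pulse train 0.002/5 uM, 1 s pulses, 6 s period.",
      stimulus = stimulus_pulse_train(0.002, 5, 0, 1, 6, 7)),
    .scenario("dupont_sevenpulse_5s15s", "dupont",
      "Seven-pulse train 0.002/5 uM, 5 s pulses, 15 s period; Ca2+ keeps oscillating even at the 2 nM baseline.",
      stimulus = stimulus_pulse_train(0.002, 5, 0, 5, 15, 7)),
    .scenario("dupont_sevenpulse_1s6s", "dupont",
      "Seven-pulse train 0.002/5 uM, 1 s pulses, 6 s period.",
      stimulus = stimulus_pulse_train(0.002, 5, 0, 1, 6, 7)),
    .scenario("depitta_at_dupont_stim", "depitta",
      "De Pitta under Dupont's native stimulus (constant 8 uM): oscillation ceases around 100 s.",
      stimulus = stimulus_constant(8)),
    .scenario("dupont_at_depitta_stim", "dupont",
      "Dupont under De Pitta's native AM two-pulse stimulus.",
      stimulus = .am_two_pulse()),
    .scenario("lavrentovich_beta35", "lavrentovich",
      "ER balance scaled by an effective volume ratio beta = 35: concentrations drop and the published setup stops oscillating (expected outcome, not an error).",
      variants = list(beta_er = 35)),
    .scenario("lavrentovich_with_riera_params", "lavrentovich",
      "All six shared parameters replaced by their Riera values simultaneously. NOTE: this reconstruction sustains slow large-amplitude oscillations here, unlike the one-or-zero-peak behavior reported for the original comparison; the one-by-one substitutions do reproduce it (see parameter_swaps()).",
      params = riera_all_in_lav),
    .scenario("riera_with_lavrentovich_params", "riera",
      "All six shared parameters replaced by their Lavrentovich values simultaneously (clamped total free Ca2+, constant X_IP3 0.43 uM/s).",
      params = lav_all_in_riera,
      stimulus = stimulus_constant(0.43, unit = "uM/s"))
  )
  names(sc) <- vapply(sc, `[[`, "", "id")
  sc
}

#' The scenario registry
#'
#' `scenario_registry()` returns every named scenario; `list_scenarios()` a
#' compact table; `get_scenario(id)` one scenario (unknown ids raise an
#' error that lists the registry). The glutamate regime scans
#' (`depitta_gluscan`, `dupont_gluscan`) are exposed through [glu_scan()]
#' rather than as single-trajectory scenarios.
#'
#' @return `scenario_registry()`: named list of scenario specs (`id`,
#'   `model`, `variants`, `params`, `stimulus`, `t_end`, `note`).
#' @export
scenario_registry <- function() {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- .build_registry()
  .registry_cache$reg
}
.registry_cache <- new.env(parent = emptyenv())

#' @rdname scenario_registry
#' @export
list_scenarios <- function() {
  reg <- scenario_registry()
  data.frame(id = names(reg),
             model = vapply(reg, `[[`, "", "model"),
             t_end = vapply(reg, `[[`, 0, "t_end"),
             stimulus = vapply(reg, function(s)
               format_stimulus(s$stimulus), ""),
             note = vapply(reg, `[[`, "", "note"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname scenario_registry
#' @param id scenario identifier.
#' @export
get_scenario <- function(id) {
  reg <- scenario_registry()
  if (!id %in% names(reg))
    stop("unknown scenario '", id, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[id]]
}

.scenario_model <- function(sc) {
  ca_model(sc$model, variants = sc$variants, params = sc$params)
}

#' Run a registry scenario
#'
#' Builds the scenario's model and stimulus, integrates it, and summarizes
#' the oscillations. Re-running with identical inputs reproduces the result
#' exactly (the dynamics are deterministic and CSV output uses fixed
#' formatting). Overrides may replace `t_end` or any model parameter.
#'
#' @param id scenario identifier (see [list_scenarios()]).
#' @param overrides named list: `t_end` and/or model parameter values.
#' @param out_dir optional directory; when given, writes
#'   `<id>_trajectory.csv`, `<id>_meta.json` (solver/run log sidecar) and
#'   `<id>_summary.json`.
#' @param plot when TRUE and `out_dir` is given, also writes a PNG of the
#'   trajectory.
#' @param settings a [solver_settings()].
#' @param criteria an [oscillation_criteria()].
#' @return invisible list with `scenario`, `trajectory`, `summary`, `files`.
#' @export
run_scenario <- function(id, overrides = list(), out_dir = NULL,
                         plot = FALSE, settings = solver_settings(),
                         criteria = oscillation_criteria()) {
  sc <- get_scenario(id)
  t_end <- sc$t_end
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be named", call. = FALSE)
    if ("t_end" %in% names(overrides)) {
      t_end <- overrides$t_end
      overrides$t_end <- NULL
    }
    if (length(overrides))
      sc$params <- utils::modifyList(as.list(sc$params), overrides)
  }
  model <- .scenario_model(sc)
  traj <- integrate_model(model, sc$stimulus, t_end, settings)
  summ <- oscillation_summary(traj, criteria)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(id, "_trajectory.csv"))
    meta <- file.path(out_dir, paste0(id, "_meta.json"))
    sj <- file.path(out_dir, paste0(id, "_summary.json"))
    write_trajectory(traj, csv, meta)
    jsonlite::write_json(
      lapply(summ, function(s) s[c("peak_times", "peak_values",
                                   "mean_interval", "amplitude",
                                   "oscillating", "cessation_time")]),
      sj, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    files <- c(trajectory = csv, meta = meta, summary = sj)
    if (plot) {
      png_path <- file.path(out_dir, paste0(id, ".png"))
      grDevices::png(png_path, width = 900, height = 200 *
                       ncol(traj$states))
      plot(traj)
      grDevices::dev.off()
      files <- c(files, plot = png_path)
    }
  }
  invisible(list(scenario = sc, trajectory = traj, summary = summ,
                 files = files))
}

## ---- run-configuration files (YAML) ---------------------------------------

.config_keys <- c("id", "model", "variants", "params", "stimulus", "t_end",
                  "note")
.stim_keys <- c("kind", "baseline", "high", "onset", "duration", "period",
                "n_pulses", "times", "values", "unit")

.stimulus_to_config <- function(stim) {
  if (is.null(stim)) return(NULL)
  unclass(stim)
}

.stimulus_from_config <- function(blk) {
  if (is.null(blk)) return(NULL)
  unknown <- setdiff(names(blk), .stim_keys)
  if (length(unknown))
    stop("unknown stimulus key(s): ",
         paste("stimulus:", unknown, collapse = ", "), call. = FALSE)
  if (is.null(blk$kind)) stop("stimulus: kind is required", call. = FALSE)
  unit <- if (is.null(blk$unit)) "uM" else blk$unit
  switch(blk$kind,
    constant = stimulus_constant(blk$baseline, unit),
    pulse_train = stimulus_pulse_train(blk$baseline, blk$high,
      if (is.null(blk$onset)) 0 else blk$onset, blk$duration, blk$period,
      blk$n_pulses, unit),
    piecewise_constant = stimulus_piecewise(unlist(blk$times),
                                            unlist(blk$values), unit),
    stop("unknown stimulus kind '", blk$kind, "'", call. = FALSE))
}

#' Scenario configuration files
#'
#' Scenarios round-trip through YAML configuration files with keys `id`,
#' `model`, `variants`, `params`, `t_end`, `note` and a `stimulus` block
#' (`kind`, `baseline`, `high`, `onset`, `duration`, `period`, `n_pulses`
#' or `times`/`values`, `unit`). Unknown keys are rejected with the
#' offending key path.
#'
#' @param path YAML file path.
#' @param scenario a scenario spec (as from [get_scenario()]).
#' @return `load_scenario_config()`: a validated scenario spec.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in c("id", "model"))
    if (is.null(cfg[[k]])) stop("configuration key '", k, "' is required",
                                call. = FALSE)
  t_end <- if (is.null(cfg$t_end)) 600 else cfg$t_end
  if (!is.numeric(t_end) || t_end <= 0)
    stop("t_end: must be a positive duration in seconds", call. = FALSE)
  sc <- .scenario(cfg$id, cfg$model,
                  note = if (is.null(cfg$note)) "" else cfg$note,
                  variants = if (is.null(cfg$variants)) list()
                             else cfg$variants,
                  params = if (is.null(cfg$params)) list() else cfg$params,
                  stimulus = .stimulus_from_config(cfg$stimulus),
                  t_end = t_end)
  .scenario_model(sc)  # validates model name, variant flags, param names
  sc
}

#' @rdname load_scenario_config
#' @export
write_scenario_config <- function(scenario, path) {
  cfg <- list(id = scenario$id, model = scenario$model,
              variants = scenario$variants, params = scenario$params,
              stimulus = .stimulus_to_config(scenario$stimulus),
              t_end = scenario$t_end, note = scenario$note)
  cfg <- cfg[!vapply(cfg, function(x) is.null(x) || (is.list(x) &&
                                                       !length(x)),
                     logical(1L))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}
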