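# Printed parameter sets, initial conditions and state layouts of the four
# astrocyte Ca2+ excitability models. Every parameter carries its unit;
# values are exactly the published ones (units reconstructed on the
# 1/s | uM/s | 1/(uM s) | 1/(uM^4 s) grammar where the source typography
# dropped the solidus).

.model_tables <- list(
  lavrentovich = list(
    states = c(Ca = "uM", CaER = "uM", IP3 = "uM"),
    initial = c(Ca = 0.1, CaER = 1.5, IP3 = 0.1),
    params = c(k2 = 0.1, k_CaA = 0.15, k_CaI = 0.15, k_deg = 0.08, k_f = 0.5,
               k_IP3 = 0.1, k_out = 0.5, k_p = 0.3, m = 2.2, n = 2.02,
               v_in = 0.05, v_M2 = 15, v_M3 = 40, v_p = 0.05),
    units = c(k2 = "uM", k_CaA = "uM", k_CaI = "uM", k_deg = "1/s",
              k_f = "1/s", k_IP3 = "uM", k_out = "1/s", k_p = "uM", m = "",
              n = "", v_in = "uM/s", v_M2 = "uM/s", v_M3 = "1/s",
              v_p = "uM/s"),
    stimulus_slot = "none",
    variants = list(zero_membrane_flux = FALSE, beta_er = NULL)),
  riera = list(
    states = c(Ca = "uM", Ca_free = "uM", h = "", IP3 = "uM"),
    initial = c(Ca = 0.09, Ca_free = 2, h = 0.79, IP3 = 0.14),
    params = c(a = 0.2, c1 = 0.185, d1 = 0.13, d2 = 1.049, d3 = 0.9434,
               d5 = 0.082, epsilon = 0.01, H_CCE = 10, j_in = 0.065,
               K_IP3 = 1.25, K_dCa = 0.55, k_out = 0.5, K_p = 0.1, v1 = 6,
               v2 = 0.11, v_delta = 0.15, V_SERCA = 0.9, x_CCE = 0.01),
    units = c(a = "1/(uM s)", c1 = "", d1 = "uM", d2 = "uM", d3 = "uM",
              d5 = "uM", epsilon = "", H_CCE = "uM", j_in = "uM/s",
              K_IP3 = "1/s", K_dCa = "uM", k_out = "1/s", K_p = "uM",
              v1 = "1/s", v2 = "1/s", v_delta = "uM/s", V_SERCA = "uM/s",
              x_CCE = "uM/s"),
    stimulus_slot = "xip3",
    variants = list(modified_h = TRUE, clamp_ca_free = TRUE)),
  depitta = list(
    states = c(Ca = "uM", h = "", IP3 = "uM"),
    initial = c(Ca = 0.09, h = 0.78, IP3 = 0.22),
    params = c(a2 = 0.2, c1 = 0.185, Ca_free = 2, d1 = 0.13, d2 = 1.049,
               d3 = 0.9434, d5 = 0.08234, kappa_d = 1.5, K3 = 1, K_pi = 0.6,
               K_D = 0.7, K_ER = 0.1, K_p = 10, K_PLCd = 0.1, K_R = 1.3,
               r5P = 0.04, r_C = 6, r_L = 0.11, v3K = 2, v_beta = 0.2,
               v_delta = 0.02, v_ER = 0.9),
    units = c(a2 = "1/(uM s)", c1 = "", Ca_free = "uM", d1 = "uM", d2 = "uM",
              d3 = "uM", d5 = "uM", kappa_d = "uM", K3 = "uM", K_pi = "uM",
              K_D = "uM", K_ER = "uM", K_p = "uM", K_PLCd = "uM", K_R = "uM",
              r5P = "1/s", r_C = "1/s", r_L = "1/s", v3K = "uM/s",
              v_beta = "uM/s", v_delta = "uM/s", v_ER = "uM/s"),
    stimulus_slot = "glutamate",
    variants = list()),
  dupont = list(
    states = c(Ca = "uM", DAG = "uM", DIM = "uM", IP3 = "uM", PKC = "",
               Ri = ""),
    initial = c(Ca = 0.1, DAG = 0.025, DIM = 0.014, IP3 = 0.2, PKC = 0.2,
                Ri = 0.9898),
    params = c(alpha = 0.1, b1 = 1e-4, Ca_tot = 80, k1 = 0.12, K_A = 5e-4,
               K_A1 = 5e-4, k_act = 0.2, K_act = 0.34, K_AD = 0.06,
               K_aff = 2, k_des = 0.2, k_di = 0.1, k_i = 7.5, K_I = 0.4,
               k_i_plus = 25, k_i_minus = 0.0025, k_l = 0.0025,
               K_MD = 0.012, K_P = 0.4, k_PLC = 1.25, R_tot = 0.075,
               v0 = 0.025, V_M1 = 0.05, V_MD = 0.0325, V_MP = 2,
               V_PKC = 0.2),
    units = c(alpha = "", b1 = "", Ca_tot = "uM", k1 = "1/s", K_A = "uM",
              K_A1 = "uM", k_act = "1/s", K_act = "uM", K_AD = "uM",
              K_aff = "uM^2", k_des = "1/s", k_di = "uM", k_i = "1/s",
              K_I = "uM", k_i_plus = "1/(uM^4 s)", k_i_minus = "1/s",
              k_l = "1/s", K_MD = "uM", K_P = "uM", k_PLC = "1/s",
              R_tot = "uM", v0 = "uM/s", V_M1 = "uM/s", V_MD = "uM/s",
              V_MP = "uM/s", V_PKC = "uM/s"),
    stimulus_slot = "glutamate",
    variants = list(modified_ca = TRUE))
)

#' Construct a single-astrocyte Ca2+ model
#'
#' Builds one of the four implemented models with its published parameter set
#' and initial conditions. Variants default to the corrected equation forms
#' (`modified_h` for Riera, `modified_ca` for Dupont) that reproduce the
#' published figures; the original (erroneous) equations remain selectable
#' for demonstration.
#'
#' Models and state variables:
#' \describe{
#'   \item{`lavrentovich`}{spontaneous oscillator; Ca, CaER, IP3 (all uM).
#'     Variants: `zero_membrane_flux` (replace v_in - k_out Ca by 0, making
#'     Ca + CaER a conserved quantity), `beta_er` (multiply the whole ER
#'     balance by an effective volume ratio, e.g. 35).}
#'   \item{`riera`}{spontaneous oscillator driven by an IP3-production rate
#'     X_IP3 (stimulus slot `xip3`, uM/s); Ca, Ca_free (total free Ca2+), h,
#'     IP3. Variants: `modified_h` (corrected sign of the inactivation term;
#'     the original printed equation lets h escape \[0, 1\]),
#'     `clamp_ca_free` (hold total free Ca2+ at its initial value, i.e. zero
#'     net membrane flux).}
#'   \item{`depitta`}{glutamate-evoked (slot `glutamate`, uM); Ca, h, IP3 on
#'     the Li-Rinzel kernel with glutamate-driven and Ca2+-driven IP3
#'     production and degradation.}
#'   \item{`dupont`}{glutamate-evoked mGlu5R cascade; Ca, DAG, DIM, IP3, PKC,
#'     Ri. Variant: `modified_ca` (Ca2+ balance carries the store-driving
#'     factor (Ca_tot - (alpha + 1) Ca), following the earlier model line the
#'     published equation appears to have dropped). Requires strictly
#'     positive glutamate (receptor dimerization divides by Glu^2); use a
#'     small baseline such as 0.002 uM rather than zero.}
#' }
#'
#' @param name one of `"lavrentovich"`, `"riera"`, `"depitta"`, `"dupont"`.
#' @param variants named list of variant flags (see Details); unknown flags
#'   are an error.
#' @param params named list/vector of parameter overrides; unknown names are
#'   an error.
#' @param initial_state optional replacement initial state (named or in state
#'   order).
#' @return An object of class `ca_model` with elements `name`, `state_names`,
#'   `state_units`, `params`, `param_units`, `initial_state`, `variants`,
#'   `stimulus_slot`.
#' @examples
#' m <- ca_model("lavrentovich")
#' coef(m)[["v_M2"]]
#' m58 <- ca_model("lavrentovich", params = list(v_M2 = 5.8))
#' @export
ca_model <- function(name = c("lavrentovich", "riera", "depitta", "dupont"),
                     variants = list(), params = list(),
                     initial_state = NULL) {
  name <- match.arg(name)
  tab <- .model_tables[[name]]
  if (length(variants)) {
    unknown <- setdiff(names(variants), names(tab$variants))
    if (length(unknown) || is.null(names(variants)))
      stop("unknown variant flag(s) for model '", name, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  var <- utils::modifyList(tab$variants, as.list(variants))
  p <- tab$params
  if (length(params)) {
    params <- unlist(params)
    unknown <- setdiff(names(params), names(p))
    if (length(unknown) || is.null(names(params)))
      stop("unknown parameter(s) for model '", name, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    p[names(params)] <- params
  }
  y0 <- tab$initial
  if (!is.null(initial_state)) {
    if (length(initial_state) != length(y0))
      stop("initial_state must have length ", length(y0), call. = FALSE)
    if (!is.null(names(initial_state))) {
      if (!setequal(names(initial_state), names(y0)))
        stop("initial_state names must match: ",
             paste(names(y0), collapse = ", "), call. = FALSE)
      y0[names(initial_state)] <- initial_state
    } else y0[] <- initial_state
  }
  frac <- names(tab$states)[tab$states == ""]
  if (any(y0[frac] < 0 | y0[frac] > 1))
    stop("fraction variables must start in [0, 1]", call. = FALSE)
  structure(list(name = name, state_names = names(tab$states),
                 state_units = tab$states, params = p,
                 param_units = tab$units, initial_state = y0,
                 variants = var, stimulus_slot = tab$stimulus_slot),
            class = "ca_model")
}

#' @export
print.ca_model <- function(x, ...) {
  cat("<ca_model:", x$name, ">\n")
  cat("  states  :", paste(sprintf("%s%s", x$state_names,
    ifelse(x$state_units == "", "", paste0(" [", x$state_units, "]"))),
    collapse = ", "), "\n")
  cat("  initial :", paste(sprintf("%s = %g", x$state_names,
                                   x$initial_state), collapse = ", "), "\n")
  cat("  stimulus:", x$stimulus_slot, "\n")
  if (length(x$variants)) {
    v <- vapply(x$variants, function(f)
      if (is.null(f)) "unset" else format(f), "")
    cat("  variants:", paste(names(v), v, sep = " = ", collapse = ", "),
        "\n")
  }
  cat("  ", length(x$params), " parameters (see coef() or ",
      "model_parameter_table())\n", sep = "")
  invisible(x)
}

#' @export
coef.ca_model <- function(object, ...) object$params

#' @export
summary.ca_model <- function(object, ...) {
  print(object)
  print(model_parameter_table(object), row.names = FALSE)
  invisible(object)
}

#' Parameter table of a model
#'
#' @param model a [ca_model()] object or model name.
#' @return data.frame with columns `parameter`, `value`, `unit`, suitable for
#'   CSV export with [utils::write.csv()].
#' @export
model_parameter_table <- function(model) {
  if (is.character(model)) model <- ca_model(model)
  stopifnot(inherits(model, "ca_model"))
  data.frame(parameter = names(model$params),
             value = unname(model$params),
             unit = unname(model$param_units[names(model$params)]),
             stringsAsFactors = FALSE)
}

## ---- right-hand sides -----------------------------------------------------
## Exported rhs_* functions validate their inputs; the .flux_* internals are
## the unvalidated cores the integrator calls (with states clipped at zero).

.flux_lavrentovich <- function(state, p, zero_membrane_flux, beta_er) {
  ca <- state[[1L]]; ca_er <- state[[2L]]; ip3 <- state[[3L]]
  v_cicr <- 4 * p[["v_M3"]] *
    (p[["k_CaA"]]^p[["n"]] * ca^p[["n"]]) /
    ((ca^p[["n"]] + p[["k_CaA"]]^p[["n"]]) *
       (ca^p[["n"]] + p[["k_CaI"]]^p[["n"]])) *
    ip3^p[["m"]] / (ip3^p[["m"]] + p[["k_IP3"]]^p[["m"]]) * (ca_er - ca)
  v_plc <- p[["v_p"]] * ca^2 / (ca^2 + p[["k_p"]]^2)
  v_serca <- p[["v_M2"]] * ca^2 / (ca^2 + p[["k2"]]^2)
  leak <- p[["k_f"]] * (ca_er - ca)
  membrane <- if (zero_membrane_flux) 0 else p[["v_in"]] - p[["k_out"]] * ca
  d_er <- v_serca - v_cicr - leak
  if (!is.null(beta_er)) d_er <- beta_er * d_er
  c(membrane + v_cicr - v_serca + leak, d_er,
    v_plc - p[["k_deg"]] * ip3)
}

.flux_riera <- function(state, p, xip3_value, modified_h, clamp_ca_free) {
  ca <- state[[1L]]; ca_free <- state[[2L]]
  h <- state[[3L]]; ip3 <- state[[4L]]
  ca_er <- (ca_free - ca) / p[["c1"]]
  m_inf <- ip3 * ca / ((ip3 + p[["d1"]]) * (ca + p[["d5"]]))
  v_rel <- p[["c1"]] * (p[["v1"]] * m_inf^3 * h^3 + p[["v2"]]) * (ca_er - ca)
  v_serca <- p[["V_SERCA"]] * ca^2 / (ca^2 + p[["K_p"]]^2)
  membrane <- if (clamp_ca_free) 0 else {
    v_cce <- p[["x_CCE"]] * p[["H_CCE"]]^2 / (p[["H_CCE"]]^2 + ca_er^2)
    p[["epsilon"]] * (p[["j_in"]] + v_cce - p[["k_out"]] * ca)
  }
  alpha_h <- p[["a"]] * p[["d2"]] * (ip3 + p[["d1"]]) / (ip3 + p[["d3"]])
  beta_h <- p[["a"]] * ca
  dh <- if (modified_h) alpha_h * (1 - h) - beta_h * h
        else            alpha_h * (1 - h) + beta_h * h
  plc_delta <- p[["v_delta"]] * ca^2 / (ca^2 + p[["K_dCa"]]^2)
  c(v_rel - v_serca + membrane, membrane, dh,
    xip3_value + plc_delta - p[["K_IP3"]] * ip3)
}

.flux_depitta <- function(state, p, glu) {
  ca <- state[[1L]]; h <- state[[2L]]; ip3 <- state[[3L]]
  m_inf <- ip3 / (ip3 + p[["d1"]])
  n_inf <- ca / (ca + p[["d5"]])
  q2 <- p[["d2"]] * (ip3 + p[["d1"]]) / (ip3 + p[["d3"]])
  drive <- p[["Ca_free"]] - (1 + p[["c1"]]) * ca
  j_chan <- p[["r_C"]] * m_inf^3 * n_inf^3 * h^3 * drive
  j_leak <- p[["r_L"]] * drive
  j_pump <- p[["v_ER"]] * ca^2 / (ca^2 + p[["K_ER"]]^2)
  k_gamma <- p[["K_R"]] *
    (1 + (p[["K_p"]] / p[["K_R"]]) * ca / (ca + p[["K_pi"]]))
  v_glu <- p[["v_beta"]] * glu^0.7 / (glu^0.7 + k_gamma^0.7)
  v_delta <- p[["v_delta"]] / (1 + ip3 / p[["kappa_d"]]) *
    ca^2 / (ca^2 + p[["K_PLCd"]]^2)
  v_3k <- p[["v3K"]] * ca^4 / (ca^4 + p[["K_D"]]^4) *
    ip3 / (ip3 + p[["K3"]])
  c(j_chan + j_leak - j_pump,
    (q2 / (q2 + ca) - h) * p[["a2"]] * (q2 + ca),
    v_glu + v_delta - v_3k - p[["r5P"]] * ip3)
}

.flux_dupont <- function(state, p, glu, modified_ca) {
  ca <- state[[1L]]; dag <- state[[2L]]; dim <- state[[3L]]
  ip3 <- state[[4L]]; pkc <- state[[5L]]; ri <- state[[6L]]
  r2 <- p[["K_aff"]] * dim / glu^2
  dimp <- (p[["R_tot"]] - sqrt(p[["k_di"]] * r2) - 2 * r2 - 2 * dim) / 2
  ira <- (1 - ri) * ip3^2 / (ip3^2 + p[["K_I"]]^2) *
    ca^3 / (ca^3 + p[["K_act"]]^3)
  drive <- p[["k_i"]] * (p[["b1"]] + ira)
  if (modified_ca) drive <- drive * (p[["Ca_tot"]] - (p[["alpha"]] + 1) * ca)
  c(p[["v0"]] + drive - p[["V_MP"]] * ca^2 / (ca^2 + p[["K_P"]]^2) -
      p[["k_l"]] * ca,
    p[["k_PLC"]] * dim - p[["V_MD"]] * dag / (dag + p[["K_MD"]]),
    p[["V_M1"]] * dimp / (dimp + p[["K_A1"]]) -
      p[["V_PKC"]] * pkc * dim / (dim + p[["K_A"]]),
    p[["k_PLC"]] * dim - p[["k1"]] * ip3,
    p[["k_act"]] * dag / (dag + p[["K_AD"]]) * (1 - pkc) -
      p[["k_des"]] * pkc,
    p[["k_i_plus"]] * ca^4 * (1 - ri) *
      p[["K_act"]]^3 / (p[["K_act"]]^3 + ca^3) - p[["k_i_minus"]] * ri)
}

.check_state <- function(state, n, what) {
  if (length(state) != n)
    stop(what, " expects a state vector of length ", n, call. = FALSE)
  if (any(state < 0))
    stop("state components must be >= 0", call. = FALSE)
}

.stim_value <- function(stim, t) {
  if (inherits(stim, "ca_stimulus")) eval_stimulus(stim, t) else stim
}

#' Model right-hand sides
#'
#' Time derivatives of the four models, exposed as pure functions for direct
#' inspection and testing. Each takes the full published parameter vector (as
#' from `coef(ca_model(name))`) so that single-parameter substitutions are
#' explicit. Concentration derivatives are in uM/s, fraction derivatives in
#' 1/s.
#'
#' @param t time, s (the dynamics are time-invariant; `t` only positions the
#'   stimulus).
#' @param state named or ordered state vector (see [ca_model()] for layouts);
#'   all components must be >= 0.
#' @param params named parameter vector, default the published values.
#' @param zero_membrane_flux replace the Lavrentovich membrane net flux
#'   v_in - k_out Ca by 0 (Ca + CaER then is conserved).
#' @param beta_er optional dimensionless factor multiplying the whole ER
#'   balance (effective volume ratio; `NULL` to disable).
#' @return named numeric vector of time derivatives.
#' @export
rhs_lavrentovich <- function(t, state, params = coef(ca_model("lavrentovich")),
                             zero_membrane_flux = FALSE, beta_er = NULL) {
  .check_state(state, 3L, "rhs_lavrentovich")
  d <- .flux_lavrentovich(state, params, zero_membrane_flux, beta_er)
  names(d) <- c("Ca", "CaER", "IP3")
  d
}

#' @rdname rhs_lavrentovich
#' @param x_ip3 IP3 production stimulus: a `ca_stimulus` (evaluated at `t`)
#'   or a plain rate in uM/s.
#' @param modified_h use the corrected h equation
#'   dh/dt = alpha_h (1 - h) - beta_h h; `FALSE` restores the printed
#'   original with the + sign, under which h grows without bound.
#' @param clamp_ca_free hold total free Ca2+ constant (zero net membrane
#'   flux).
#' @export
rhs_riera <- function(t, state, params = coef(ca_model("riera")), x_ip3 = 0,
                      modified_h = TRUE, clamp_ca_free = TRUE) {
  .check_state(state, 4L, "rhs_riera")
  if (params[["c1"]] == 0) stop("c1 must be nonzero", call. = FALSE)
  if (modified_h && (state[[3L]] < 0 || state[[3L]] > 1))
    stop("h must lie in [0, 1]", call. = FALSE)
  d <- .flux_riera(state, params, .stim_value(x_ip3, t), modified_h,
                   clamp_ca_free)
  names(d) <- c("Ca", "Ca_free", "h", "IP3")
  d
}

#' @rdname rhs_lavrentovich
#' @param glu glutamate stimulus: a `ca_stimulus` (evaluated at `t`) or a
#'   plain concentration in uM.
#' @export
rhs_depitta <- function(t, state, params = coef(ca_model("depitta")),
                        glu = 0) {
  .check_state(state, 3L, "rhs_depitta")
  g <- .stim_value(glu, t)
  if (g < 0) stop("glutamate concentration must be >= 0", call. = FALSE)
  d <- .flux_depitta(state, params, g)
  names(d) <- c("Ca", "h", "IP3")
  d
}

#' @rdname rhs_lavrentovich
#' @param modified_ca use the corrected Ca2+ balance carrying the factor
#'   (Ca_tot - (alpha + 1) Ca) on the release term; `FALSE` restores the
#'   printed original without it.
#' @export
rhs_dupont <- function(t, state, params = coef(ca_model("dupont")), glu,
                       modified_ca = TRUE) {
  .check_state(state, 6L, "rhs_dupont")
  g <- .stim_value(glu, t)
  if (g <= 0 && state[[3L]] > 0)
    stop("the Dupont receptor stage divides by Glu^2; use a small positive ",
         "baseline (e.g. 0.002 uM for the published 2 nM) instead of zero",
         call. = FALSE)
  d <- .flux_dupont(state, params, g, modified_ca)
  names(d) <- c("Ca", "DAG", "DIM", "IP3", "PKC", "Ri")
  d
}

# internal dispatch: closure of (t, clipped_state, stim_value) for a model
.model_flux <- function(model) {
  p <- model$params
  v <- model$variants
  switch(model$name,
    lavrentovich = function(state, s)
      .flux_lavrentovich(state, p, v$zero_membrane_flux, v$beta_er),
    riera = function(state, s)
      .flux_riera(state, p, s, v$modified_h, v$clamp_ca_free),
    depitta = function(state, s) .flux_depitta(state, p, s),
    dupont = function(state, s) .flux_dupont(state, p, s, v$modified_ca))
}
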