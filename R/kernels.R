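#' Li-Rinzel IP3-receptor gating kernel
#'
#' Parameters and steady-state gating functions of the two-variable reduction
#' of the De Young-Keizer IP3 receptor model. Cytosolic Ca2+ activates the
#' receptor through `n_inf`, IP3 opens it through `m_inf`, and slow Ca2+
#' inactivation is tracked by the gating variable h with steady state `h_inf`
#' and time constant `tau_h`.
#'
#' `li_rinzel_params()` defaults are the values the De Pitta model uses for
#' this kernel (its rC, rL, vER, KER play the roles of the CICR, leak, SERCA
#' maximum-rate and SERCA affinity constants here; the kernel's own source
#' prints no numbers):
#' \tabular{lll}{
#'   field \tab meaning \tab default \cr
#'   d1 \tab IP3 dissociation constant (uM) \tab 0.13 \cr
#'   d2 \tab Ca2+ inactivation dissociation constant (uM) \tab 1.049 \cr
#'   d3 \tab IP3 dissociation constant, inactivated state (uM) \tab 0.9434 \cr
#'   d5 \tab Ca2+ activation dissociation constant (uM) \tab 0.08234 \cr
#'   a2 \tab Ca2+ inactivation binding rate (1/(uM s)) \tab 0.2 \cr
#'   r_cicr \tab maximal CICR rate (1/s) \tab 6 \cr
#'   r_leak \tab ER leak rate (1/s) \tab 0.11 \cr
#'   v_serca \tab maximal SERCA rate (uM/s) \tab 0.9 \cr
#'   k_serca \tab SERCA affinity (uM) \tab 0.1 \cr
#'   c1 \tab ER/cytosol effective volume ratio \tab 0.185 \cr
#'   ca_free \tab total free Ca2+ (uM) \tab 2 \cr
#' }
#'
#' @param d1,d2,d3,d5 dissociation constants, uM.
#' @param a2 inactivation binding rate, 1/(uM s).
#' @param r_cicr,r_leak CICR and ER-leak rate constants, 1/s.
#' @param v_serca maximal SERCA pump rate, uM/s.
#' @param k_serca SERCA half-activation Ca2+, uM.
#' @param c1 ER-to-cytosol effective volume ratio (dimensionless).
#' @param ca_free total free Ca2+ concentration, uM.
#' @return `li_rinzel_params()`: a named list of class `li_rinzel_params`.
#' @export
li_rinzel_params <- function(d1 = 0.13, d2 = 1.049, d3 = 0.9434, d5 = 0.08234,
                             a2 = 0.2, r_cicr = 6, r_leak = 0.11,
                             v_serca = 0.9, k_serca = 0.1, c1 = 0.185,
                             ca_free = 2) {
  p <- list(d1 = d1, d2 = d2, d3 = d3, d5 = d5, a2 = a2, r_cicr = r_cicr,
            r_leak = r_leak, v_serca = v_serca, k_serca = k_serca, c1 = c1,
            ca_free = ca_free)
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                   is.finite(v) && v > 0, logical(1L))
  if (any(bad))
    stop("Li-Rinzel parameters must be strictly positive scalars: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "li_rinzel_params")
}

#' @rdname li_rinzel_params
#' @param ca cytosolic Ca2+ concentration, uM (>= 0).
#' @param ip3 cytosolic IP3 concentration, uM (>= 0).
#' @param params a [li_rinzel_params()] object.
#' @return `li_rinzel_gates()`: a list with `m_inf`, `n_inf`, `h_inf`
#'   (dimensionless, in \[0, 1\]), `tau_h` (s) and `Q2` (uM), where
#'   m_inf = IP3/(IP3 + d1), n_inf = Ca/(Ca + d5),
#'   Q2 = d2 (IP3 + d1)/(IP3 + d3), h_inf = Q2/(Q2 + Ca) and
#'   tau_h = 1/(a2 (Q2 + Ca)).
#' @examples
#' p <- li_rinzel_params()
#' li_rinzel_gates(ca = p$d5, ip3 = p$d1, p)  # both half-saturated
#' @export
li_rinzel_gates <- function(ca, ip3, params = li_rinzel_params()) {
  stopifnot(inherits(params, "li_rinzel_params"))
  if (any(ca < 0) || any(ip3 < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  q2 <- params$d2 * (ip3 + params$d1) / (ip3 + params$d3)
  list(m_inf = ip3 / (ip3 + params$d1),
       n_inf = ca / (ca + params$d5),
       h_inf = q2 / (q2 + ca),
       tau_h = 1 / (params$a2 * (q2 + ca)),
       Q2 = q2)
}

#' Hofer single-cell flux kernel
#'
#' Flux terms of the single-astrocyte core of the Hofer network model:
#' IP3R release (CICR plus ER leak), linear SERCA pump, plasma-membrane
#' influx and efflux, Ca2+-activated PLC-delta IP3 production, IP3
#' degradation, and the recovery/inactivation balance of the fraction of
#' active IP3 receptors R. The spatial terms of the original network model
#' (Ca2+/IP3 diffusion, gap-junction transfer) are outside the scope of this
#' kernel.
#'
#' `hofer_params()` ships no default values: the source at hand prints the
#' equations but not the numbers, so every field must be supplied explicitly.
#'
#' @param k1,k2 IP3R release rate constants (1/s and the CICR saturable
#'   rate, 1/s).
#' @param Ka,KIP3,Kr,KCa,Ki half-saturation constants, uM.
#' @param k3,k5,k6,k9 first-order rate constants, 1/s.
#' @param v40,v41,v7,v8 maximal flux rates, uM/s.
#' @return `hofer_params()`: a named list of class `hofer_params`.
#' @export
hofer_params <- function(k1, k2, Ka, KIP3, k3, v40, v41, Kr, k5, v7, KCa,
                         v8, k9, k6, Ki) {
  args <- as.list(environment())
  missing_ <- names(args)[!vapply(args, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1L))]
  if (length(missing_))
    stop("Hofer kernel parameters must all be given as finite scalars; ",
         "missing or invalid: ", paste(missing_, collapse = ", "),
         call. = FALSE)
  if (any(unlist(args) <= 0))
    stop("Hofer kernel parameters must be strictly positive", call. = FALSE)
  structure(args, class = "hofer_params")
}

#' PLC-beta IP3 production, both printed algebraic forms
#'
#' The receptor/G-protein-driven IP3 production term of the Hofer model is
#' printed as v8 * ((1 + kG) (kG/(1 + kG) + a0))^-1 * a0. Expanding the
#' denominator shows it equals the much simpler v8 * a0 / (kG + (1 + kG) a0),
#' which raises the question whether the published form carries a typo. Both
#' forms are computed exactly as written so their algebraic identity can be
#' verified numerically.
#'
#' @param alpha0 degree of receptor saturation (dimensionless, >= 0).
#' @param kappa_g G-protein kinetics ratio (dimensionless, >= 0).
#' @param v8 maximal PLC-beta rate, uM/s.
#' @param form `"original"` (as printed) or `"simplified"` (expanded).
#' @return PLC-beta IP3 production rate, uM/s.
#' @export
hofer_plc_beta <- function(alpha0, kappa_g, v8,
                           form = c("original", "simplified")) {
  form <- match.arg(form)
  if (any(alpha0 < 0) || any(kappa_g < 0))
    stop("alpha0 and kappa_g must be >= 0", call. = FALSE)
  if (any(kappa_g == 0 & alpha0 == 0))
    stop("alpha0 and kappa_g cannot both be zero (denominator vanishes)",
         call. = FALSE)
  if (form == "original")
    v8 * alpha0 / ((1 + kappa_g) * (kappa_g / (1 + kappa_g) + alpha0))
  else
    v8 * alpha0 / (kappa_g + (1 + kappa_g) * alpha0)
}

#' @rdname hofer_params
#' @param ca,ca_er cytosolic and ER Ca2+ concentrations, uM (>= 0).
#' @param ip3 cytosolic IP3 concentration, uM (>= 0).
#' @param r fraction of active IP3 receptors, in \[0, 1\].
#' @param params a [hofer_params()] object.
#' @return `hofer_single_cell_fluxes()`: a list with fluxes `v_rel`,
#'   `v_serca`, `v_in`, `v_out`, `v_plc_delta`, `v_deg` (uM/s) and `dr_dt`
#'   (1/s). Setting `dr_dt` to zero and solving gives the receptor fixed
#'   point R = Ki^2/(Ki^2 + Ca^2).
#' @export
hofer_single_cell_fluxes <- function(ca, ca_er, ip3, r, params) {
  if (!inherits(params, "hofer_params"))
    stop("params must be a hofer_params object (no defaults are shipped)",
         call. = FALSE)
  if (any(c(ca, ca_er, ip3) < 0) || any(r < 0) || any(r > 1))
    stop("states must be >= 0 with r in [0, 1]", call. = FALSE)
  p <- params
  list(
    v_rel = (p$k1 + p$k2 * r * ca^2 * ip3^2 /
               ((ca^2 + p$Ka^2) * (ip3^2 + p$KIP3^2))) * (ca_er - ca),
    v_serca = p$k3 * ca,
    v_in = p$v40 + p$v41 * ip3^2 / (ip3^2 + p$Kr^2),
    v_out = p$k5 * ca,
    v_plc_delta = p$v7 * ca^2 / (ca^2 + p$KCa^2),
    v_deg = p$k9 * ip3,
    dr_dt = p$k6 * (p$Ki^2 / (p$Ki^2 + ca^2) - r))
}
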