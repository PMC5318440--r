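# Hand-evaluated derivative values below were computed independently from
# the published tables (plain arithmetic on the printed formulas) and frozen.

test_that("model construction carries the published tables and defaults", {
  lav <- ca_model("lavrentovich")
  expect_equal(coef(lav)[["v_M2"]], 15)
  expect_equal(unname(lav$initial_state), c(0.1, 1.5, 0.1))
  dep <- ca_model("depitta")
  expect_equal(dep$initial_state,
               c(Ca = 0.09, h = 0.78, IP3 = 0.22))
  expect_equal(coef(dep)[["d5"]], 0.08234)   # per-model d5, not harmonized
  expect_equal(coef(ca_model("riera"))[["d5"]], 0.082)
  # corrected variants are the defaults
  expect_true(ca_model("riera")$variants$modified_h)
  expect_true(ca_model("dupont")$variants$modified_ca)
  expect_equal(ca_model("dupont")$initial_state[["Ri"]], 0.9898)
})

test_that("bad names, flags, parameters and initial fractions are rejected", {
  expect_error(ca_model("hodgkin"), "arg")
  expect_error(ca_model("lavrentovich", variants = list(modified_h = TRUE)),
               "variant")
  expect_error(ca_model("lavrentovich", params = list(vmax = 2)),
               "unknown parameter")
  expect_error(ca_model("depitta", initial_state = c(0.09, 1.5, 0.22)),
               "\\[0, 1\\]")
  expect_error(ca_model("depitta", initial_state = c(0.09, 0.78)),
               "length")
})

test_that("parameter tables export every printed value with its unit", {
  tab <- model_parameter_table("dupont")
  expect_equal(nrow(tab), 26)
  expect_equal(tab$value[tab$parameter == "k_i_plus"], 25)
  expect_equal(tab$unit[tab$parameter == "k_i_plus"], "1/(uM^4 s)")
  expect_equal(model_parameter_table("lavrentovich")$value[
    model_parameter_table("lavrentovich")$parameter == "k_deg"], 0.08)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  expect_equal(utils::read.csv(csv)$value, tab$value)
})

test_that("Lavrentovich derivatives match hand evaluation of the table", {
  y <- c(Ca = 0.1, CaER = 1.5, IP3 = 0.1)
  d <- rhs_lavrentovich(0, y)
  # at Ca = 0.1 the membrane fluxes cancel (v_in - k_out Ca = 0), so the
  # Ca/ER pair is antisymmetric; v_SERCA = 15*0.01/0.02 = 7.5 uM/s
  expect_equal(d[["Ca"]], -d[["CaER"]])
  expect_equal(d[["Ca"]], 16.9833591043604, tolerance = 1e-12)
  expect_equal(d[["IP3"]], 0.005 - 0.008)
  # membrane balance shows up in the total-Ca derivative
  y2 <- c(Ca = 0.3, CaER = 1.5, IP3 = 0.1)
  d2 <- rhs_lavrentovich(0, y2)
  expect_equal(d2[["Ca"]] + d2[["CaER"]], 0.05 - 0.5 * 0.3)
  # zero membrane flux: exact cancellation for any state
  d3 <- rhs_lavrentovich(0, y2, zero_membrane_flux = TRUE)
  expect_equal(d3[["Ca"]] + d3[["CaER"]], 0)
  # the ER volume-ratio option scales only the ER balance
  d4 <- rhs_lavrentovich(0, y2, beta_er = 35)
  expect_equal(d4[["CaER"]], 35 * d2[["CaER"]])
  expect_equal(d4[["Ca"]], d2[["Ca"]])
  expect_error(rhs_lavrentovich(0, c(-0.1, 1.5, 0.1)), ">= 0")
})

test_that("Riera derivatives, h-equation variants and clamp behave as printed", {
  y <- c(Ca = 0.09, Ca_free = 2, h = 0.79, IP3 = 0.14)
  d <- rhs_riera(0, y, x_ip3 = 0.43)
  # clamped total free Ca2+: membrane term zero in both equations
  expect_equal(d[["Ca_free"]], 0)
  # ER concentration (2 - 0.09)/0.185 = 10.3243 uM enters v_Rel
  expect_equal(d[["Ca"]], -0.082627848220811, tolerance = 1e-12)
  expect_equal(d[["IP3"]], 0.258911783644559, tolerance = 1e-12)
  expect_equal(d[["h"]], -0.00324006645744878, tolerance = 1e-12)
  # original (uncorrected) h-equation flips the sign of the beta_h term:
  # the difference is exactly 2 beta_h h with beta_h = a Ca = 0.018 1/s
  d_orig <- rhs_riera(0, y, x_ip3 = 0.43, modified_h = FALSE)
  expect_equal(d_orig[["h"]] - d[["h"]], 2 * 0.018 * 0.79)
  # at h = 1 the original equation still grows: it escapes the unit interval
  y1 <- c(Ca = 0.09, Ca_free = 2, h = 1, IP3 = 0.14)
  expect_gt(rhs_riera(0, y1, x_ip3 = 0, modified_h = FALSE)[["h"]], 0)
  expect_lte(rhs_riera(0, y1, x_ip3 = 0, modified_h = TRUE)[["h"]], 0)
  # unclamped: both Ca and Ca_free move by the same membrane term
  d_free <- rhs_riera(0, y, x_ip3 = 0.43, clamp_ca_free = FALSE)
  expect_gt(abs(d_free[["Ca_free"]]), 0)
  expect_equal(d_free[["Ca"]] - d[["Ca"]], d_free[["Ca_free"]])
  expect_error(rhs_riera(0, y, params = replace(coef(ca_model("riera")),
                                                "c1", 0), x_ip3 = 0),
               "c1")
})

test_that("De Pitta derivatives match hand evaluation of the table", {
  y <- c(Ca = 0.09, h = 0.78, IP3 = 0.22)
  d <- rhs_depitta(0, y, glu = 0.1)
  # J_leak = 0.11*(2 - 1.185*0.09) = 0.20827 uM/s is part of the frozen sum
  expect_equal(d[["Ca"]], -0.00381656917254125, tolerance = 1e-12)
  expect_equal(d[["h"]], -0.000154320096269555, tolerance = 1e-12)
  expect_equal(d[["IP3"]], 0.0174346295055332, tolerance = 1e-12)
  # no glutamate: the receptor-driven production term vanishes
  d0 <- rhs_depitta(0, y, glu = 0)
  expect_equal(d0[["IP3"]], -0.00109305280724556, tolerance = 1e-12)
  expect_equal(d0[["Ca"]], d[["Ca"]])
  expect_error(rhs_depitta(0, y, glu = -1), ">= 0")
})

test_that("Dupont derivatives, reconstructions and Ca-equation variants", {
  y <- c(Ca = 0.1, DAG = 0.025, DIM = 0.014, IP3 = 0.2, PKC = 0.2,
         Ri = 0.9898)
  d <- rhs_dupont(0, y, glu = 8)
  # IP3 balance straight off the printed row: 1.25*0.014 - 0.12*0.2
  expect_equal(d[["IP3"]], -0.0065)
  expect_equal(d[["Ca"]], -0.0026521223407982, tolerance = 1e-12)
  expect_equal(d[["DAG"]], -0.00445945945945946, tolerance = 1e-12)
  expect_equal(d[["DIM"]], 0.0101450661423391, tolerance = 1e-12)
  expect_equal(d[["PKC"]], 0.00705882352941178, tolerance = 1e-12)
  expect_equal(d[["Ri"]], -0.00244963269154426, tolerance = 1e-12)
  # original Ca equation drops the store factor (Ca_tot - (alpha+1) Ca)
  d_orig <- rhs_dupont(0, y, glu = 8, modified_ca = FALSE)
  expect_equal(d_orig[["Ca"]], -0.0917674438969713, tolerance = 1e-12)
  shared <- 0.025 - 2 * 0.01 / (0.01 + 0.16) - 0.0025 * 0.1
  expect_equal((d[["Ca"]] - shared) / (d_orig[["Ca"]] - shared),
               80 - 1.1 * 0.1)
  expect_equal(d[-1], d_orig[-1])
  # dimer-free limit: R2 = 0 and phosphorylated dimer pool = R_tot / 2
  y0 <- replace(y, "DIM", 0)
  expect_equal(rhs_dupont(0, y0, glu = 8)[["DIM"]],
               0.0493421052631579, tolerance = 1e-12)
  # zero glutamate with bound dimer present is a domain error
  expect_error(rhs_dupont(0, y, glu = 0), "baseline")
})

test_that("all four right-hand sides are finite on the physiological box", {
  set.seed(42)
  lav <- coef(ca_model("lavrentovich"))
  rie <- coef(ca_model("riera"))
  dep <- coef(ca_model("depitta"))
  dup <- coef(ca_model("dupont"))
  for (i in 1:50) {
    conc <- function(n) runif(n, 0, 100)
    frac <- function(n) runif(n, 0, 1)
    expect_true(all(is.finite(rhs_lavrentovich(0, conc(3), lav))))
    expect_true(all(is.finite(rhs_riera(0, c(conc(2), frac(1), conc(1)),
                                        rie, x_ip3 = runif(1, 0, 1)))))
    expect_true(all(is.finite(rhs_depitta(0, c(conc(1), frac(1), conc(1)),
                                          dep, glu = runif(1, 0, 10)))))
    expect_true(all(is.finite(rhs_dupont(0, c(conc(4), frac(2)), dup,
                                         glu = runif(1, 0.01, 10)))))
  }
})

test_that("right-hand sides are time-invariant given the stimulus value", {
  y <- c(Ca = 0.09, h = 0.78, IP3 = 0.22)
  expect_identical(rhs_depitta(0, y, glu = 2.5),
                   rhs_depitta(1e4, y, glu = 2.5))
  st <- stimulus_pulse_train(0.002, 5, 0, 62.5, 125, 2)
  # a stimulus object is evaluated at t; same value, same derivative
  expect_identical(rhs_depitta(70, y, glu = st),
                   rhs_depitta(0, y, glu = 0.002))
})
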