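test_that("peak detection counts sinusoid peaks and ignores flat traces", {
  tr <- make_synthetic_trace("sine", t_end = 100, dt = 0.05, amplitude = 1,
                             period = 10)
  pk <- detect_peaks(tr$value, prominence = 0.5, times = tr$time)
  expect_equal(nrow(pk), 10)
  expect_equal(pk$time, 2.5 + 10 * (0:9), tolerance = 0.05)
  flat <- make_synthetic_trace("constant", t_end = 50, level = 3)
  expect_equal(nrow(detect_peaks(flat$value, 0.01)), 0)
  expect_error(detect_peaks(c(1, 2, 1), 0.1, times = c(0, 1, 3)),
               "uniform")
})

test_that("damped-sine peaks stop where the analytic envelope crosses", {
  # a peak of A exp(-t/tau) sin(2 pi t / T) at time t has topographic
  # prominence ~ A exp(-t/tau) (1 + exp(-T/(2 tau))): its base is the
  # shallower adjacent trough, half a period later. Solving prominence = p
  # gives the analytic time of the last qualifying peak,
  # t* = tau log(A (1 + exp(-T/(2 tau))) / p); detection must agree with
  # this closed form to within one period.
  for (case in list(c(tau = 20, p = 0.1), c(tau = 35, p = 0.05))) {
    tau <- case[["tau"]]; p <- case[["p"]]
    tr <- make_synthetic_trace("damped_sine", t_end = 250, dt = 0.02,
                               amplitude = 1, period = 10, tau = tau)
    pk <- detect_peaks(tr$value, prominence = p, times = tr$time)
    t_star <- tau * log((1 + exp(-10 / (2 * tau))) / p)
    expect_gt(nrow(pk), 3)
    expect_lt(abs(pk$time[nrow(pk)] - t_star), 10)
  }
})

test_that("the percent-change statistic has its identity and scaling laws", {
  expect_equal(percent_change(2, 1), -50)
  expect_equal(percent_change(1, 1.54), 54)
  set.seed(3)
  x <- runif(100, -5, 5)
  x <- x[x != 0]
  expect_equal(percent_change(x, x), rep(0, length(x)))
  expect_equal(percent_change(x, 2 * x), rep(100, length(x)))
  expect_error(percent_change(0, 1), "zero")
})

test_that("synthetic traces are deterministic given the seed", {
  a <- make_synthetic_trace("damped_sine", seed = 1)
  b <- make_synthetic_trace("damped_sine", seed = 999)
  expect_identical(a, b)  # no noise: seed is irrelevant
  n1 <- make_synthetic_trace("sine", noise_sd = 0.1, seed = 7)
  n2 <- make_synthetic_trace("sine", noise_sd = 0.1, seed = 7)
  n3 <- make_synthetic_trace("sine", noise_sd = 0.1, seed = 8)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_error(make_synthetic_trace("square"), "arg")
})

test_that("a window-spanning sinusoid is sustained; a damped one ceases", {
  t <- seq(0, 300, by = 0.05)
  traj <- synthetic_trajectory(
    t,
    Ca = 0.3 + 0.2 * sin(2 * pi * t / 25),
    # h rings down and is exactly flat from t = 80 s on
    h = 0.5 + 0.1 * pmax(1 - t / 80, 0) * sin(2 * pi * t / 25),
    units = c(Ca = "uM", h = ""))
  s <- oscillation_summary(traj)
  expect_true(s$Ca$oscillating)
  expect_true(is.na(s$Ca$cessation_time))
  expect_equal(s$Ca$mean_interval, 25, tolerance = 0.01)
  expect_equal(s$Ca$amplitude, 0.4, tolerance = 1e-3)
  # the damped fraction variable stops early; its last qualifying peak is
  # long before the end of the trace
  expect_false(s$h$oscillating)
  expect_false(is.na(s$h$cessation_time))
  expect_lt(s$h$cessation_time, 200)
})

test_that("classification is invariant to time shift and positive rescale", {
  base <- function(t) 0.1 + 0.05 * sin(2 * pi * t / 12)
  t <- seq(0, 240, by = 0.05)
  classify <- function(x, unit = "uM")
    oscillation_summary(synthetic_trajectory(t, v = x,
                                             units = c(v = unit)))$v
  f0 <- classify(base(t))
  expect_true(f0$oscillating)
  expect_equal(classify(base(t - 31))$oscillating, f0$oscillating)  # shift
  f5 <- classify(5 * base(t), unit = "")  # rescale under the relative rule
  expect_equal(f5$oscillating, f0$oscillating)
  expect_equal(f5$n_peaks_window, f0$n_peaks_window)
})

test_that("run comparison reports extrema, percent changes and flags", {
  t <- seq(0, 200, by = 0.05)
  ref <- synthetic_trajectory(t, Ca = 2 + sin(2 * pi * t / 10),
                              IP3 = 1 + 0.5 * cos(2 * pi * t / 10))
  same <- compare_runs(ref, ref)
  expect_equal(same$min_pct, c(0, 0))
  expect_equal(same$max_pct, c(0, 0))
  scaled <- synthetic_trajectory(t, Ca = 1.1 * (2 + sin(2 * pi * t / 10)),
                                 IP3 = 1.1 * (1 + 0.5 * cos(2 * pi * t / 10)))
  rep_ <- compare_runs(ref, scaled)
  expect_equal(rep_$min_pct, c(10, 10), tolerance = 1e-8)
  expect_equal(rep_$max_pct, c(10, 10), tolerance = 1e-8)
  expect_true(all(rep_$ref_oscillating))
  # a plain data.frame works as the reference side
  df <- data.frame(time = t, Ca = 2 + sin(2 * pi * t / 10))
  expect_equal(compare_runs(df, scaled)$variable, "Ca")
  other <- synthetic_trajectory(t, DAG = t * 0 + 1)
  expect_error(compare_runs(ref, other), "no variables")
})

test_that("band extraction picks the longest run, ties toward lower Glu", {
  fake <- function(flags, glu = seq_along(flags) / 10)
    structure(data.frame(glu = glu, all_oscillating = flags,
                         ca_oscillating = TRUE,
                         ca_cessation_time = NA_real_,
                         ca_peaks_window = 10L),
              class = c("glu_scan", "data.frame"))
  sc <- fake(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(oscillation_band(sc), c(lower = 0.5, upper = 0.7))
  tie <- fake(c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(oscillation_band(tie), c(lower = 0.1, upper = 0.2))
  expect_null(oscillation_band(fake(rep(TRUE, 4))))
  sc$ca_cessation_time <- c(NA, NA, NA, NA, 410, 300, 200, 100)
  expect_equal(cessation_threshold(sc), 0.5)
  expect_true(is.na(cessation_threshold(fake(rep(TRUE, 3)))))
})

test_that("a degenerate single-level scan returns a single record", {
  sc <- glu_scan(ca_model("depitta"), levels = 0.1, t_end = 60,
                 settings = fast_settings())
  expect_s3_class(sc, "glu_scan")
  expect_equal(nrow(sc), 1)
  expect_equal(sc$glu, 0.1)
  expect_error(glu_scan(ca_model("lavrentovich"), 1), "glutamate-evoked")
  expect_error(glu_scan(ca_model("depitta"), c(2, 1)), "increasing")
})
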