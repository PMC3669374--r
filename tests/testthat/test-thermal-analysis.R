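make_table <- function(tt, y) {
  structure(data.frame(temperature = tt, rg_mean = y, rg_sem = 0,
                       n_samples = 1L),
            label = "synthetic", class = c("sweep_table", "data.frame"))
}

test_that("locate_Tc finds interior maxima and refuses monotone tables", {
  tab <- make_table(1:5, c(1, 2, 3, 2, 1))
  expect_equal(locate_Tc(tab), 3)
  expect_error(locate_Tc(make_table(1:5, 1:5)), "no interior peak")
  expect_error(locate_Tc(make_table(1:5, 5:1)), "no interior peak")
  # discrete ties break toward lower temperature
  expect_lt(abs(locate_Tc(make_table(1:5, c(1, 3, 2.5, 3, 1))) - 2), 0.5)
})

test_that("quadratic refinement recovers analytic maxima within half a step", {
  set.seed(7)
  for (k in 1:100) {
    tpeak <- runif(1, 0.015, 0.035)
    width <- runif(1, 0.004, 0.02)
    amp <- runif(1, 0.5, 5)
    tt <- seq(0.01, 0.04, by = 0.0025)
    y <- 1 + amp * exp(-(tt - tpeak)^2 / (2 * width^2))
    k0 <- which.max(y)
    if (k0 == 1L || k0 == length(y)) next
    tc <- locate_Tc(make_table(tt, y))
    # refinement agrees with the brute-force argmax oracle
    expect_lt(abs(tc - tt[k0]), 0.0025)
    # and recovers the analytic peak better than the grid itself
    expect_lt(abs(tc - tpeak), 0.0025 / 2)
  }
})

test_that("response windows sit at the 25%-rise crossings", {
  # symmetric peak with flat shoulders: baseline 1, peak 2 at T = 0.02,
  # ramps of slope 200 between offsets 0.005 and 0
  tt <- seq(0.01, 0.03, by = 0.0025)
  y <- pmax(1, 2 - abs(tt - 0.02) * 200)
  rs <- response_window(make_table(tt, y))
  expect_equal(rs$T_c, 0.02, tolerance = 1e-6)
  expect_equal(rs$window_high - rs$T_c, rs$T_c - rs$window_low,
               tolerance = 1e-9)
  # threshold 1.25 crosses the ramps 0.00375 from the centre
  expect_equal(rs$window_low, 0.01625, tolerance = 1e-9)
  expect_equal(rs$window_high, 0.02375, tolerance = 1e-9)

  # trapezoid with a flat top: edges at the ramp crossings
  y2 <- pmin(2, pmax(1, 2 - (abs(tt - 0.02) - 0.0025) * 200))
  rs2 <- response_window(make_table(tt, y2))
  # ramps run from 1 (at offset 0.0075) to 2 (at offset 0.0025):
  # the 1.25 level crosses 0.00625 from the centre
  expect_equal(rs2$window_low, 0.02 - 0.00625, tolerance = 1e-9)
  expect_equal(rs2$window_high, 0.02 + 0.00625, tolerance = 1e-9)

  # locality: flat far-away points do not move the edges
  tt3 <- c(0.001, 0.005, tt, 0.035, 0.039)
  y3 <- c(1, 1, y, 1, 1)
  rs3 <- response_window(make_table(tt3, y3))
  expect_equal(rs3$window_low, rs$window_low, tolerance = 1e-6)
  expect_equal(rs3$window_high, rs$window_high, tolerance = 1e-6)
})

test_that("effective dimension fits invert exact and noisy power laws", {
  rg <- 10
  qstar <- 2 * pi / rg
  q <- exp(seq(log(qstar) - 1, log(qstar) + 1, length.out = 30))
  mk <- function(s) structure(data.frame(q = q, s = s),
                              class = c("sq_table", "data.frame"))
  fit2 <- fit_effective_dimension(mk(q^-2), rg)
  expect_equal(fit2$D_e, 2, tolerance = 1e-9)
  expect_equal(fit_effective_dimension(mk(q^-3), rg)$D_e, 3, tolerance = 1e-9)

  set.seed(11)
  noisy <- 5 * q^-2 * exp(rnorm(length(q), sd = 0.01))
  fitn <- fit_effective_dimension(mk(noisy), rg)
  expect_equal(fitn$D_e, 2, tolerance = 0.05)
  expect_true(fitn$se > 0)

  sparse <- mk(q^-2)[c(1, 2, 29, 30), ]
  expect_error(fit_effective_dimension(sparse, rg), "insufficient")
})

test_that("potential comparison ranks by T_c and flags ties", {
  mk <- function(tc, label) structure(
    list(T_c = tc, window_low = tc - 0.003, window_high = tc + 0.003,
         rg_peak = 2, rg_low_T_baseline = 1, rg_high_T_plateau = 1,
         grid_spacing = 0.001, label = label), class = "response_summary")
  out <- compare_potentials(list(mk(0.020, "MJ"), mk(0.024, "BT"),
                                 mk(0.017, "BFKV")))
  expect_identical(out$ranking$label, c("BFKV", "MJ", "BT"))
  expect_true(all(out$pairs$delta_Tc >= 0))
  expect_false(any(out$pairs$tied))

  # shuffled input order yields the identical report
  out2 <- compare_potentials(list(mk(0.024, "BT"), mk(0.017, "BFKV"),
                                  mk(0.020, "MJ")))
  expect_identical(out, out2)

  tied <- compare_potentials(list(mk(0.0200, "MJ"), mk(0.0201, "BT")))
  expect_true(all(tied$pairs$tied))
  expect_error(compare_potentials(list(mk(0.02, "MJ"))), "at least 2")
})

test_that("temperature sweeps are reproducible and flat for athermal chains", {
  s <- random_sequence(14, seed = 21)
  m0 <- synthetic_matrix("null")
  cfg <- mc_config(temperature = 1, n_mcs = 3000, record_every = 150)
  tt <- c(0.5, 1, 2, 4)
  sw <- temperature_sweep(s, m0, tt, cfg, n_samples = 6, master_seed = 31,
                          box_size = 16)
  sw2 <- temperature_sweep(s, m0, tt, cfg, n_samples = 6, master_seed = 31,
                           box_size = 16)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  expect_true(is.unsorted(c(0, diff(sw$temperature))) == FALSE)

  # with eps = 0 temperature cancels: all means agree within 3 SEM bands
  grand <- mean(sw$rg_mean)
  expect_true(all(abs(sw$rg_mean - grand) <= 3 * sw$rg_sem + 1e-12))

  expect_error(temperature_sweep(s, m0, c(1, 2), cfg, 2, 1), "at least 3")
  expect_error(temperature_sweep(s, m0, c(2, 1, 3), cfg, 2, 1), "increasing")
})
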