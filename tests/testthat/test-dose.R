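test_that("charge accumulation follows the Faradaic bookkeeping", {
  led <- dose_ledger()
  led0 <- accumulate_charge(led, rep(0, 8), dt = 10)
  expect_equal(unname(led0$q), rep(0, 9))

  # 5 uA for 3600 s on channel 2: Q+ = 0.018 C, D = 1.2696e-6 g
  led <- accumulate_charge(dose_ledger(), 5, 3600, channels = 2)
  expect_equal(unname(led$qp["2"]), 0.018)
  expect_equal(unname(channel_doses(led)["2"]),
               0.022 * 0.018 * 309.33 / 96485.3321)
  expect_equal(unname(channel_doses(led)["2"]), 1.2696e-6, tolerance = 1e-4)

  # rectification: +5 uA then -5 uA leaves Q = 0 but Q+ = 5e-4 C
  led <- accumulate_charge(dose_ledger(), 5, 100, channels = 2)
  led <- accumulate_charge(led, -5, 100, channels = 2)
  expect_equal(unname(led$q["2"]), 0)
  expect_equal(unname(led$qp["2"]), 5e-4)
  expect_error(accumulate_charge(dose_ledger(), 5, dt = 0), "positive")
})

test_that("totals sum even channels only", {
  led <- dose_ledger()
  expect_equal(unname(ledger_totals(led)), c(0, 0))
  # four even channels at the charge giving D_i = 6.25e-6 g each
  qp_each <- 6.25e-6 / dose_per_coulomb()
  led <- accumulate_charge(led, rep(qp_each * 1e6, 4), 1,
                           channels = c(2, 4, 6, 8))
  expect_equal(unname(ledger_totals(led)["D"]), 2.5e-5)   # the 0.025 mg target
  # odd-channel charge contributes nothing
  led2 <- accumulate_charge(dose_ledger(), rep(20, 4), 1000,
                            channels = c(1, 3, 5, 7))
  expect_equal(unname(ledger_totals(led2)["D"]), 0)
  expect_equal(unname(ledger_totals(led2)["Q"]), 0)
})

test_that("rectified-charge identity and dose monotonicity hold", {
  set.seed(13)
  led <- dose_ledger()
  neg_mag <- numeric(9)
  last_d <- 0
  for (i in 1:200) {
    i_uA <- runif(8, -10, 30)
    led <- accumulate_charge(led, i_uA, 0.1)
    all_i <- c(i_uA, -sum(i_uA))
    neg_mag <- neg_mag + pmax(-all_i, 0) * 1e-6 * 0.1
    expect_true(all(led$q <= led$qp + 1e-18))
    d <- unname(ledger_totals(led)["D"])
    expect_gte(d, last_d)
    last_d <- d
  }
  expect_equal(unname(led$qp - led$q), unname(neg_mag))
})

test_that("dose is linear in efficiency, current and time", {
  base <- accumulate_charge(dose_ledger(), 5, 1000, channels = 2)
  d_base <- ledger_totals(base)["D"]
  twice_i <- accumulate_charge(dose_ledger(), 10, 1000, channels = 2)
  twice_t <- accumulate_charge(dose_ledger(), 5, 2000, channels = 2)
  expect_equal(unname(ledger_totals(twice_i)["D"]), unname(2 * d_base))
  expect_equal(unname(ledger_totals(twice_t)["D"]), unname(2 * d_base))
  k2 <- dose_constants(eta = 0.044)
  led2 <- accumulate_charge(dose_ledger(k = k2), 5, 1000, channels = 2)
  expect_equal(unname(ledger_totals(led2)["D"]), unname(2 * d_base))
})

test_that("sampled accumulation equals the brute-force integral", {
  # piecewise-constant pulsed trace aligned to the grid: exact
  dt <- 0.1
  t <- seq(0, 130 - dt, by = dt)
  i_t <- ifelse(pulse_gate(t), 5, 0)
  led <- dose_ledger()
  for (v in i_t) led <- accumulate_charge(led, v, dt, channels = 2)
  expect_equal(unname(led$qp["2"]), 5e-6 * 120)   # 2 periods x 60 s on
  # smooth trace: halving dt shrinks the error (left-rectangle rule, O(dt))
  f <- function(t) 5 + 3 * sin(t / 7)
  riemann <- function(dt) {
    tt <- seq(0, 100 - dt, by = dt)
    sum(f(tt) * dt) * 1e-6
  }
  exact <- integrate(f, 0, 100)$value * 1e-6
  e1 <- abs(riemann(0.2) - exact)
  e2 <- abs(riemann(0.1) - exact)
  expect_lt(e2, 0.6 * e1)
})

test_that("required charge and analytic time-to-dose match hand arithmetic", {
  expect_equal(charge_for_dose(2.5e-5), 2.5e-5 * 96485.3321 / (0.022 * 309.33))
  expect_equal(charge_for_dose(2.5e-5), 0.35445, tolerance = 1e-4)
  expect_equal(charge_for_dose(0), 0)
  expect_equal(charge_for_dose(2.5e-5, dose_constants(eta = 0.044)),
               charge_for_dose(2.5e-5) / 2)
  expect_error(charge_for_dose(-1), "non-negative")

  t_min <- time_to_dose(2.5e-5, 4, 2.45, 60 / 65)
  expect_equal(t_min, 39182, tolerance = 1e-4)        # ~10.9 h
  t_max <- time_to_dose(2.5e-5, 4, 5, 60 / 65)
  expect_equal(t_max, 19199, tolerance = 1e-4)        # ~5.3 h
  expect_equal(time_to_dose(2.5e-5, 4, 5, 0.5) /
               time_to_dose(2.5e-5, 4, 5, 1), 2)
  expect_identical(time_to_dose(2.5e-5, 4, 0), Inf)
})

test_that("dose maps place eight edge entries and a zero center", {
  led <- accumulate_charge(dose_ledger(), rep(5, 4), 1000,
                           channels = c(2, 4, 6, 8))
  dm <- dose_map(led)
  expect_equal(nrow(dm), 9)
  expect_equal(dm$dose_g[dm$channel == 0], 0)
  expect_equal(dm$radius_mm[dm$channel == 0], 0)
  even <- dm$dose_g[dm$channel %in% c(2, 4, 6, 8)]
  expect_true(all(even > 0) && diff(range(even)) == 0)  # uniform
  expect_equal(dm$dose_g[dm$channel %in% c(1, 3, 5, 7)], rep(0, 4))
})
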