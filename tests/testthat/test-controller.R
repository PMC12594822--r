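test_that("treatment modes assign roles and validate target ranges", {
  sp <- mode_setpoints("FLX", flx_levels)
  expect_equal(sp$role[c(2, 4, 6, 8)], rep("current_source", 4))
  expect_equal(sp$role[c(1, 3, 5, 7)], rep("grounded", 4))
  sp_stop <- mode_setpoints("STOP", rep(0, 8))
  expect_true(all(sp_stop$role == "grounded"))
  expect_true(all(sp_stop$target_uA == 0))
  sp_ef <- mode_setpoints("EF", c(4.4, 0, 50, 0, 10, 0, 10, 0))
  expect_equal(sp_ef$role[c(1, 3, 5, 7)], rep("current_source", 4))
  expect_equal(sp_ef$role[c(2, 4, 6, 8)], rep("high_impedance", 4))
  # an even-channel EF target violates the mode
  expect_error(mode_setpoints("EF", c(10, 3, 10, 0, 10, 0, 10, 0)),
               "channel 2")
  expect_error(mode_setpoints("FLX", c(0, 2, 0, 5, 0, 5, 0, 5)),
               "channel 2.*range \\[2.45, 5\\]")
  expect_error(mode_setpoints("FLX", c(0, 5, 0, 60, 0, 5, 0, 5)),
               "channel 4")
})

test_that("pulse gate and duty cycle follow the 60 s / 5 s scheme", {
  expect_true(pulse_gate(30))
  expect_false(pulse_gate(62))
  expect_true(pulse_gate(65))     # next period starts
  expect_equal(round(100 * duty_cycle(), 1), 92.3)
  expect_equal(duty_cycle(pulse_schedule(30, 30)), 0.5)
  expect_error(pulse_gate(-1))
})

test_that("feedback converges within ticks and rails out of compliance", {
  cfg <- default_cfg
  expect_equal(feedback_step(5, 5, 26L, cfg), 26L)   # no error, no move
  # static 100 kOhm load from code 0: within 0.2 uA of target by tick 5
  ld <- static_load(1e5)
  pol <- table_policy(flx_table())
  s <- simulate_window(pol, 1, load = ld, noise_sd_v = 0, record = TRUE)
  i2 <- s$records$current_uA[s$records$channel == 2]
  expect_true(all(abs(i2[5:10] - 5) <= 0.2))
  # out-of-compliance load: code rails, delivered = compliance limit
  ld2 <- static_load(2e6)
  s2 <- simulate_window(pol, 5, load = ld2, noise_sd_v = 0, record = TRUE)
  i2 <- s2$records$current_uA[s2$records$channel == 2]
  lim <- 4.7 / 2.01e6 * 1e6
  expect_equal(tail(i2, 20), rep(lim, 20), tolerance = 0.05)
})

test_that("delivered current respects target and compliance up to one DAC LSB", {
  set.seed(17)
  ld <- make_load(load_params())
  s <- simulate_window(table_policy(flx_table()), 120, load = ld,
                       record = TRUE)
  tgt <- matrix(s$records$target_uA, ncol = 8, byrow = TRUE)
  expect_true(all(s$true_currents <= tgt + dac_lsb(default_cfg) + 1e-9))
})

test_that("dose stop grounds all channels with bounded overshoot", {
  tiny_target <- 2e-9  # grams, reached in under a minute at 4 x 5 uA
  # overshoot at the stop tick itself is bounded by one tick's charge
  set.seed(19)
  s_stop <- simulate_window(table_policy(flx_table()), 120,
                            load = make_load(load_params()),
                            dose_target = tiny_target, run_to = "stop")
  d_stop <- unname(ledger_totals(s_stop$ledger)["D"])
  tick_dose <- 4 * 5.5e-6 * 0.1 * dose_per_coulomb()
  expect_true(s_stop$stopped)
  expect_gte(d_stop, tiny_target)
  expect_lte(d_stop - tiny_target, tick_dose)
  set.seed(19)
  s <- simulate_window(table_policy(flx_table()), 120,
                       load = make_load(load_params()),
                       dose_target = tiny_target, record = TRUE)
  expect_true(s$stopped)
  # every record after the stop tick is grounded STOP with zero target
  after <- s$records[s$records$t_s >= s$stop_elapsed, ]
  expect_true(nrow(after) > 0)
  expect_true(all(after$mode == "STOP"))
  expect_true(all(after$target_uA == 0))
  expect_true(all(abs(after$current_uA) < 0.2))  # measurement noise only
})

test_that("planned EF-to-FLX switch flips channel roles at its hour", {
  plan <- experiment_plan(days = 1, window_h = 0.1, day_modes = "EF",
                          events = data.frame(day = 0, hour = 0.05,
                                              mode = "FLX"))
  pol <- plan_policy(plan, 0)
  early <- pol(60); late <- pol(200)
  expect_equal(early$mode, "EF")
  expect_equal(late$mode, "FLX")
  set.seed(23)
  s <- simulate_window(pol, 360, load = make_load(load_params()),
                       record = TRUE)
  pre <- s$records[s$records$t_s < 180 & s$records$phase == "on", ]
  post <- s$records[s$records$t_s > 260 & s$records$phase == "on", ]
  # before the switch odd channels source, even are Hi-Z at 0
  expect_true(all(pre$target_uA[pre$channel %% 2 == 1] > 0))
  expect_true(all(pre$target_uA[pre$channel %% 2 == 0] == 0))
  # after the switch (applied at a pulse boundary) even channels source
  expect_true(all(post$target_uA[post$channel %% 2 == 0] > 0))
  expect_true(all(post$target_uA[post$channel %% 2 == 1] == 0))
})

test_that("duty-cycle accounting is exact over whole pulse periods", {
  ld <- static_load(1e5)
  s <- simulate_window(table_policy(flx_table()), 650, load = ld,
                       noise_sd_v = 0, record = TRUE)   # 10 whole periods
  # true delivered charge per even channel = duty * target * elapsed,
  # within DAC quantization of the held current level
  q_true <- colSums(s$true_currents) * 1e-6 * 0.1
  held <- 26 * dac_lsb(default_cfg)   # code nearest 5 uA
  expect_equal(unname(q_true[c(2, 4, 6, 8)]),
               rep(duty_cycle() * held * 1e-6 * 650, 4), tolerance = 1e-6)
})

test_that("policy interface clamps out-of-range requests with a warning", {
  expect_warning(lv <- clamp_targets("FLX", c(0, 6, 0, 5, 0, 5, 0, 5)),
                 "clamped")
  expect_equal(lv[2], 5)
  expect_warning(lv2 <- clamp_targets("FLX", c(0, 1, 0, 5, 0, 5, 0, 5)),
                 "clamped")
  expect_equal(lv2[2], 2.45)
  # non-source channels are forced to zero
  expect_warning(lv3 <- clamp_targets("EF", c(10, 3, 10, 0, 10, 0, 10, 0)))
  expect_equal(lv3[2], 0)
  # empty actuation table means STOP
  pol <- table_policy(flx_table()[0, ])
  expect_equal(pol(0)$mode, "STOP")
  # a finished table also returns STOP
  pol2 <- table_policy(flx_table(duration_s = 100))
  expect_equal(pol2(50)$mode, "FLX")
  expect_equal(pol2(150)$mode, "STOP")
})

test_that("resume restores state; completed or corrupt snapshots handled", {
  plan <- experiment_plan()
  q <- numeric(9); qp <- numeric(9)
  saved <- resume_state(130, "FLX", flx_levels, q, qp)
  st <- resume_session(saved, plan)
  expect_equal(st$elapsed, 130)
  expect_equal(st$mode, "FLX")
  expect_false(st$stopped)
  # a snapshot already past the dose target resumes straight into STOP
  qp_done <- qp; qp_done[c(2, 4, 6, 8)] <- charge_for_dose(2.5e-5) / 4 * 1.01
  done <- resume_state(5000, "FLX", flx_levels, q, qp_done)
  st2 <- resume_session(done, plan)
  expect_true(st2$stopped)
  expect_equal(st2$mode, "STOP")
  # missing fields are unrecoverable
  broken <- saved; broken$targets <- NULL
  expect_error(resume_session(broken, plan), "unrecoverable")
})

test_that("stitched interrupted runs match uninterrupted runs in dose", {
  run_once <- function(interrupt_at = NULL) {
    set.seed(31)
    ld <- make_load(load_params(drift_sd = 0, movement_rate = 0))
    pol <- table_policy(flx_table())
    if (is.null(interrupt_at)) {
      s <- simulate_window(pol, 400, load = ld, record = FALSE)
      return(ledger_totals(s$ledger)["D"])
    }
    s1 <- simulate_window(pol, interrupt_at, load = ld, record = FALSE)
    cp <- s1$final
    st <- resume_session(cp, experiment_plan())
    s2 <- simulate_window(pol, 400 - interrupt_at, load = ld,
                          init = st, record = FALSE)
    ledger_totals(s2$ledger)["D"]
  }
  d_full <- run_once()
  d_stitched <- run_once(interrupt_at = 170)
  tick_dose <- 4 * 5e-6 * 0.1 * dose_per_coulomb()
  expect_lt(abs(d_full - d_stitched), tick_dose)
  # pulse phase carries across the gap: 170 s into the period sequence
  # resumes mid-period rather than restarting at pulse-on
  expect_equal(pulse_gate(170 %% 65), 170 %% 65 < 60)
})
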