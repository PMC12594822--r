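#' Treatment-mode channel roles and target ranges
#'
#' The device runs one of three treatment modes. In EF mode the odd
#' channels source current (4.4--50 uA targets) to impose a radially
#' inward electric field while the even channels are high-impedance
#' (0 uA) so no drug moves. In FLX mode the even channels source the
#' fluoxetine-delivery current (2.45--5 uA targets) while the odd channels
#' are grounded at 0 V to lower the return resistance. STOP grounds
#' everything. The center return is always grounded.
#'
#' @format NULL
#' @keywords internal
.mode_table <- list(
  EF = list(source_parity = 1L, range = c(4.4, 50)),
  FLX = list(source_parity = 0L, range = c(2.45, 5)),
  STOP = list(source_parity = NA_integer_, range = c(0, 0))
)

#' Channel roles for a treatment mode
#'
#' @param mode `"EF"`, `"FLX"` or `"STOP"`.
#' @param n_channels Number of outer channels.
#' @return Character vector of roles (`"current_source"`, `"grounded"`,
#'   `"high_impedance"`), one per outer channel.
#' @export
mode_roles <- function(mode, n_channels = 8L) {
  mode <- match.arg(mode, names(.mode_table))
  ch <- seq_len(n_channels)
  if (mode == "EF") ifelse(ch %% 2 == 1, "current_source", "high_impedance")
  else if (mode == "FLX") ifelse(ch %% 2 == 0, "current_source", "grounded")
  else rep("grounded", n_channels)
}

#' Per-channel setpoints for a treatment mode
#'
#' Assigns roles and validates the requested target currents against the
#' mode's allowed range. Source-side targets must be zero (channel
#' disabled) or within range; non-source channels must request 0.
#'
#' @param mode `"EF"`, `"FLX"` or `"STOP"`.
#' @param levels Target currents, microamps, one per outer channel.
#' @param n_channels Number of outer channels.
#' @return `data.frame` with `channel`, `role`, `target_uA`.
#' @examples
#' mode_setpoints("FLX", c(0, 5, 0, 5, 0, 5, 0, 5))
#' @export
mode_setpoints <- function(mode, levels = numeric(n_channels),
                           n_channels = 8L) {
  mode <- match.arg(mode, names(.mode_table))
  stopifnot(length(levels) == n_channels)
  roles <- mode_roles(mode, n_channels)
  rng <- .mode_table[[mode]]$range
  for (ch in seq_len(n_channels)) {
    if (roles[ch] == "current_source") {
      if (levels[ch] != 0 && (levels[ch] < rng[1] || levels[ch] > rng[2]))
        stop(sprintf("channel %d target %g uA outside %s range [%g, %g] uA",
                     ch, levels[ch], mode, rng[1], rng[2]))
    } else if (levels[ch] != 0) {
      stop(sprintf("channel %d must be 0 in %s mode (role %s), got %g uA",
                   ch, mode, roles[ch], levels[ch]))
    }
  }
  data.frame(channel = seq_len(n_channels), role = roles, target_uA = levels)
}

#' Clamp requested targets into a mode's range
#'
#' The policy interface clamps out-of-range requests to the range boundary
#' with a warning instead of erroring, so an over-eager healing policy
#' cannot drive the hardware outside its specification.
#'
#' @inheritParams mode_setpoints
#' @return Clamped `levels`.
#' @export
clamp_targets <- function(mode, levels, n_channels = 8L) {
  mode <- match.arg(mode, names(.mode_table))
  roles <- mode_roles(mode, n_channels)
  rng <- .mode_table[[mode]]$range
  src <- roles == "current_source"
  out <- ifelse(src, ifelse(levels == 0, 0, pmin(pmax(levels, rng[1]), rng[2])),
                0)
  changed <- which(out != levels)
  if (length(changed))
    warning(sprintf("clamped %s targets on channel(s) %s into [%g, %g] uA",
                    mode, paste(changed, collapse = ", "), rng[1], rng[2]))
  out
}

#' Pulse schedule
#'
#' The delivery current is pulsed — held at target for `on_s` seconds then
#' at 0 uA for `off_s` seconds — so the electrodes can charge and
#' discharge. The default 60 s / 5 s scheme gives a 92.3% duty cycle.
#'
#' @param on_s Seconds at target per period.
#' @param off_s Seconds at zero per period.
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(on_s = 60, off_s = 5) {
  stopifnot(on_s > 0, off_s >= 0)
  structure(list(on_s = on_s, off_s = off_s), class = "pulse_schedule")
}

#' Pulse gate and duty cycle
#'
#' `pulse_gate()` is TRUE while `t mod (on_s + off_s) < on_s`;
#' `duty_cycle()` is `on_s / (on_s + off_s)`.
#'
#' @param t Seconds since actuation start (vectorized).
#' @param sched A [pulse_schedule()].
#' @return Logical gate / duty fraction.
#' @export
pulse_gate <- function(t, sched = pulse_schedule()) {
  stopifnot(all(t >= 0))
  (t %% (sched$on_s + sched$off_s)) < sched$on_s
}

#' @rdname pulse_gate
#' @export
duty_cycle <- function(sched = pulse_schedule()) {
  sched$on_s / (sched$on_s + sched$off_s)
}

#' One feedback step of the DAC code
#'
#' Deadbeat correction on a resistive load: the code moves by the measured
#' current error expressed in DAC LSBs, clamping at 0 and full scale. On a
#' static in-compliance load this converges to within one LSB of the
#' target within a couple of ticks.
#'
#' @param target Target current, microamps.
#' @param measured Last measured current, microamps.
#' @param code Current DAC code.
#' @param cfg A [device_config()].
#' @return The new DAC code (integer).
#' @export
feedback_step <- function(target, measured, code, cfg = device_config()) {
  new_code <- code + round((target - measured) / dac_lsb(cfg))
  as.integer(pmin(pmax(new_code, 0), 2^cfg$n_dac - 1))
}

#' Experiment plan
#'
#' A multi-day treatment plan: each day has an actuation window (default
#' 23 h, leaving 1 h for power-bank swaps and animal care), a starting
#' mode with target levels, optional timed mode-switch events (e.g. EF to
#' FLX at hour 6 of Day 1), and a dose target at which delivery stops.
#'
#' @param days Number of days.
#' @param window_h Actuation window per day, hours (<= 24).
#' @param dose_target_mg Total fluoxetine dose target, milligrams.
#' @param day_modes Character vector of starting modes per day (recycled).
#' @param events `data.frame` with columns `day` (0-based), `hour` (within
#'   the window) and `mode`; applied at their times, ordered.
#' @param ef_levels,flx_levels Default per-channel target levels (uA) used
#'   when a day runs EF / FLX mode.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(days = 1L, window_h = 23, dose_target_mg = 0.025,
                            day_modes = "FLX",
                            events = NULL,
                            ef_levels = c(10, 0, 10, 0, 10, 0, 10, 0),
                            flx_levels = c(0, 5, 0, 5, 0, 5, 0, 5)) {
  stopifnot(days >= 1, window_h > 0, window_h <= 24, dose_target_mg > 0)
  if (!is.null(events)) {
    stopifnot(all(c("day", "hour", "mode") %in% names(events)))
    events <- events[order(events$day, events$hour), , drop = FALSE]
    stopifnot(all(events$mode %in% names(.mode_table)),
              all(events$hour >= 0 & events$hour <= window_h))
  }
  structure(list(days = as.integer(days), window_h = window_h,
                 dose_target = dose_target_mg * 1e-3,
                 day_modes = rep_len(day_modes, days), events = events,
                 ef_levels = ef_levels, flx_levels = flx_levels),
            class = "experiment_plan")
}

#' Read an experiment plan from YAML
#'
#' Keys: `days`, `window_h`, `dose_target_mg`, `day_modes`, `events`
#' (list of maps with `day`, `hour`, `mode`), `ef_levels`, `flx_levels`.
#'
#' @param path YAML file path.
#' @return An [experiment_plan()].
#' @export
read_plan <- function(path) {
  y <- yaml::read_yaml(path)
  ev <- NULL
  if (!is.null(y$events))
    ev <- do.call(rbind, lapply(y$events, function(e)
      data.frame(day = e$day, hour = e$hour, mode = e$mode)))
  args <- y[intersect(names(y), c("days", "window_h", "dose_target_mg",
                                  "day_modes", "ef_levels", "flx_levels"))]
  args$ef_levels <- if (!is.null(args$ef_levels)) unlist(args$ef_levels)
  args$flx_levels <- if (!is.null(args$flx_levels)) unlist(args$flx_levels)
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(experiment_plan, c(args, list(events = ev)))
}

#' Policies: mapping elapsed time to treatment mode and targets
#'
#' A policy is a function of elapsed window time (seconds) returning
#' `list(mode =, levels =)`. `table_policy()` wraps an actuation table
#' (ordered fixed-duration rows of per-channel targets, the device's
#' `.csv` "Load" artifact); past the end of the table — or for an empty
#' table — it returns STOP. `step_policy()` cycles through a list of
#' levels on a fixed timer, standing in for an external wound-healing
#' policy during tests. `plan_policy()` realises an [experiment_plan()]
#' day: the day's starting mode, with the plan's events applied at their
#' hours. Out-of-range requests are clamped with a warning via
#' [clamp_targets()].
#'
#' @param table `data.frame` as returned by [load_actuation_table()].
#' @return A policy function.
#' @export
table_policy <- function(table) {
  if (nrow(table) == 0) {
    return(function(t) list(mode = "STOP", levels = numeric(8)))
  }
  ends <- cumsum(table$duration_s)
  lev <- as.matrix(table[, grep("^ch\\d+_uA$", names(table)), drop = FALSE])
  function(t) {
    k <- findInterval(t, c(0, ends), rightmost.closed = FALSE)
    if (k > nrow(table)) return(list(mode = "STOP", levels = numeric(ncol(lev))))
    list(mode = table$mode[k],
         levels = clamp_targets(table$mode[k], lev[k, ], ncol(lev)))
  }
}

#' @rdname table_policy
#' @param period_s Seconds each entry of `levels_list` is held.
#' @param levels_list List of per-channel target vectors (uA).
#' @param mode Treatment mode the stepped targets apply to.
#' @export
step_policy <- function(period_s, levels_list, mode = "FLX") {
  force(period_s); force(levels_list); force(mode)
  function(t) {
    k <- (floor(t / period_s) %% length(levels_list)) + 1
    list(mode = mode, levels = clamp_targets(mode, levels_list[[k]]))
  }
}

#' @rdname table_policy
#' @param plan An [experiment_plan()].
#' @param day Day index, 0-based.
#' @export
plan_policy <- function(plan, day) {
  levels_for <- function(mode) switch(mode, EF = plan$ef_levels,
                                      FLX = plan$flx_levels,
                                      numeric(length(plan$flx_levels)))
  ev <- plan$events
  ev <- if (is.null(ev)) ev else ev[ev$day == day, , drop = FALSE]
  start_mode <- plan$day_modes[day + 1]
  function(t) {
    mode <- start_mode
    if (!is.null(ev) && nrow(ev) > 0) {
      past <- which(ev$hour * 3600 <= t)
      if (length(past)) mode <- ev$mode[max(past)]
    }
    list(mode = mode, levels = levels_for(mode))
  }
}

#' Resume checkpoint
#'
#' The last recorded controller state — timestamp, elapsed actuation
#' duration, mode and target currents, and a dose-ledger snapshot — from
#' which an interrupted actuation can continue after power loss. The gap
#' interval contributes zero charge.
#'
#' @param elapsed Elapsed actuation seconds at the checkpoint.
#' @param mode Treatment mode at the checkpoint.
#' @param targets Per-channel target currents, microamps.
#' @param q,qp Ledger charge vectors (coulombs, outer channels + center).
#' @param stopped Whether the dose stop had engaged.
#' @param timestamp Session-relative timestamp, seconds.
#' @return An object of class `resume_state`.
#' @export
resume_state <- function(elapsed, mode, targets, q, qp, stopped = FALSE,
                         timestamp = elapsed) {
  structure(list(timestamp = timestamp, elapsed = elapsed, mode = mode,
                 targets = targets, q = q, qp = qp, stopped = stopped),
            class = "resume_state")
}

#' Restore a controller state from a checkpoint
#'
#' Validates the snapshot and prepares the state [simulate_window()]
#' continues from: elapsed actuation time (so the pulse phase carries on),
#' targets, and the dose ledger. If the snapshot already satisfies the
#' plan's dose target the restored state is an immediate STOP.
#'
#' @param saved A [resume_state()] (e.g. from a read-back session log).
#' @param plan An [experiment_plan()] (for the dose target).
#' @param k A [dose_constants()].
#' @return A list with `elapsed`, `mode`, `targets`, `q`, `qp`, `stopped`.
#' @export
resume_session <- function(saved, plan, k = dose_constants()) {
  need <- c("timestamp", "elapsed", "mode", "targets", "q", "qp")
  missing <- need[vapply(need, function(f) is.null(saved[[f]]), logical(1))]
  if (length(missing))
    stop("unrecoverable session: checkpoint missing field(s) ",
         paste(missing, collapse = ", "))
  if (!saved$mode %in% names(.mode_table))
    stop("unrecoverable session: unknown mode ", saved$mode)
  nc <- length(saved$targets)
  even <- seq(2, nc, by = 2)
  dose <- sum(saved$qp[even]) * k$eta * k$molar_mass / k$faraday
  stopped <- isTRUE(saved$stopped) || dose >= plan$dose_target
  list(elapsed = saved$elapsed,
       mode = if (stopped) "STOP" else saved$mode,
       targets = saved$targets, q = saved$q, qp = saved$qp,
       stopped = stopped)
}

# Vectorized network solve shared by solve_network() and the tick engine.
# Returns currents (uA) and node voltages (V) for the outer channels.
.solve_vec <- function(src, i_prog, r, v_pol, r_sense, v_cc) {
  total_r <- r_sense + r
  i <- numeric(length(src))
  head_v <- pmax(v_cc - v_pol, 0)
  i_lim <- head_v / total_r * 1e6
  i[src] <- pmin(pmax(i_prog[src], 0), i_lim[src])
  v_app <- numeric(length(src))
  v_app[src] <- i[src] * 1e-6 * total_r[src] + v_pol[src]
  v_el <- v_app - i * 1e-6 * r_sense
  list(i = i, v_app = v_app, v_el = v_el)
}

#' Simulate one actuation window under closed-loop control
#'
#' The tick engine of the digital twin. Every sample period (100 ms) it:
#' applies the pulse gate; syncs mode/targets to the policy at each
#' pulse-period boundary (mid-period policy changes wait for the next
#' pulse-on edge); deadbeat-adjusts each source channel's DAC code toward
#' its target using the previous tick's measured current; solves the star
#' network for the delivered currents under voltage compliance; measures
#' both sense-resistor nodes with noisy, quantized 16-sample ADC bursts;
#' accumulates measured charge into the dose ledger (left-rectangle rule);
#' engages STOP once the even-channel dose total reaches the target
#' (channels ground from the next tick, so overshoot is bounded by one
#' tick's charge); and advances the synthetic load. A resume checkpoint is
#' taken at every pulse-period boundary.
#'
#' @param policy A policy function, e.g. [table_policy()] or
#'   [plan_policy()].
#' @param duration_s Window length to simulate, seconds.
#' @param cfg A [device_config()].
#' @param load A [make_load()] object (advanced in place).
#' @param sched A [pulse_schedule()].
#' @param k A [dose_constants()].
#' @param dose_target Total dose target, grams.
#' @param noise_sd_v Gaussian measurement noise s.d. per ADC sample, volts.
#' @param init Optional restored state from [resume_session()].
#' @param run_to `"window"` simulates the whole window; `"stop"` ends the
#'   loop once the dose stop engages (everything after is grounded).
#' @param record If FALSE, skip telemetry recording (dose-only run).
#' @param session_start ISO-8601 string stored in the session metadata.
#' @return An object of class `twin_session`: list with `records` (long
#'   `data.frame`, 8 rows per tick), `ledger` ([dose_ledger()]),
#'   `checkpoints` (list of [resume_state()]), `stopped`, `stop_elapsed`
#'   (elapsed seconds when STOP engaged, or `NA`), `final` (a
#'   [resume_state()] at the end), `meta`, and when recording the
#'   `true_currents` matrix (ticks x channels, uA).
#' @export
simulate_window <- function(policy, duration_s, cfg = device_config(),
                            load = make_load(load_params()),
                            sched = pulse_schedule(), k = dose_constants(),
                            dose_target = 2.5e-5, noise_sd_v = 0.001,
                            init = NULL, run_to = c("window", "stop"),
                            record = TRUE,
                            session_start = "1970-01-01T00:00:00Z") {
  run_to <- match.arg(run_to)
  dt <- cfg$sample_period
  nc <- cfg$n_channels
  n_ticks <- floor(duration_s / dt)
  period <- sched$on_s + sched$off_s
  lsb <- dac_lsb(cfg)
  code_max <- 2^cfg$n_dac - 1
  adc_max <- 2^cfg$n_adc - 1
  adc_scale <- 2^cfg$n_adc / cfg$v_cc
  even <- seq(2, nc, by = 2)
  dose_scale <- k$eta * k$molar_mass / k$faraday

  start_elapsed <- 0
  mode <- "STOP"; targets <- numeric(nc)
  q <- numeric(nc + 1); qp <- numeric(nc + 1)
  stopped <- FALSE
  if (!is.null(init)) {
    start_elapsed <- init$elapsed
    mode <- init$mode; targets <- init$targets
    q <- init$q; qp <- init$qp; stopped <- init$stopped
  }
  codes <- integer(nc)
  measured <- numeric(nc)
  stop_elapsed <- if (stopped) start_elapsed else NA_real_

  if (record) {
    m_aa <- matrix(0, n_ticks, nc); m_ae <- matrix(0, n_ticks, nc)
    m_im <- matrix(0, n_ticks, nc); m_it <- matrix(0, n_ticks, nc)
    m_tg <- matrix(0, n_ticks, nc)
    v_mode <- character(n_ticks); v_phase <- logical(n_ticks)
    v_t <- numeric(n_ticks)
  }
  checkpoints <- list()
  burst <- cfg$burst_n
  n_draw <- burst * 2 * nc
  last_tick <- n_ticks

  for (tick in seq_len(n_ticks)) {
    elapsed <- start_elapsed + (tick - 1) * dt
    phase_t <- elapsed %% period
    boundary <- phase_t < dt
    if (boundary || tick == 1L) {
      checkpoints[[length(checkpoints) + 1L]] <-
        resume_state(elapsed, mode, targets, q, qp, stopped)
      if (!stopped) {
        pol <- policy(elapsed)
        mode <- pol$mode
        targets <- rep_len(pol$levels, nc)
      }
    }
    if (stopped) mode <- "STOP"
    gate <- phase_t < sched$on_s
    src <- if (mode == "EF") seq(1, nc, 2) else if (mode == "FLX") even
           else integer(0)
    src_mask <- logical(nc); src_mask[src] <- TRUE
    eff <- numeric(nc)
    if (gate && length(src)) eff[src] <- targets[src]

    # deadbeat DAC update; channels at 0 uA are simply set to code 0
    on <- eff > 0
    codes[!on] <- 0L
    if (any(on))
      codes[on] <- pmin(pmax(codes[on] +
        round((eff[on] - measured[on]) / lsb), 0), code_max)

    i_prog <- codes * lsb
    net <- .solve_vec(src_mask, i_prog, load$r, load$v_pol,
                      cfg$r_sense, cfg$v_cc)
    i_true <- net$i
    v_el_true <- net$v_el
    v_el_true[!src_mask & mode == "EF"] <- load$v_pol[!src_mask]

    # burst-sampled, quantized, averaged ADC measurement of both nodes
    nodes <- c(net$v_app, v_el_true)
    samp <- rep(nodes, each = burst) + stats::rnorm(n_draw, 0, noise_sd_v)
    codes_adc <- pmin(pmax(floor(samp * adc_scale), 0), adc_max)
    avg <- .colMeans(codes_adc, burst, 2L * nc)
    a_app <- avg[seq_len(nc)]; a_el <- avg[nc + seq_len(nc)]
    measured <- (a_app - a_el) / adc_scale / cfg$r_sense * 1e6

    # Faradaic bookkeeping on the measured currents (left-rectangle rule)
    dq <- measured * 1e-6 * dt
    q[seq_len(nc)] <- q[seq_len(nc)] + dq
    q[nc + 1] <- q[nc + 1] - sum(dq)
    qp[seq_len(nc)] <- qp[seq_len(nc)] + pmax(dq, 0)
    dose <- sum(qp[even]) * dose_scale
    if (!stopped && dose >= dose_target) {
      stopped <- TRUE
      stop_elapsed <- elapsed + dt
    }

    step_load(load, i_true, dt)

    if (record) {
      m_aa[tick, ] <- a_app; m_ae[tick, ] <- a_el
      m_im[tick, ] <- measured; m_it[tick, ] <- i_true; m_tg[tick, ] <- eff
      v_mode[tick] <- mode; v_phase[tick] <- gate; v_t[tick] <- elapsed
    }
    if (stopped && run_to == "stop") { last_tick <- tick; break }
  }

  ledger <- dose_ledger(nc, k)
  ledger$q[] <- q; ledger$qp[] <- qp
  ledger$t_last <- start_elapsed + last_tick * dt
  final <- resume_state(start_elapsed + last_tick * dt,
                        if (stopped) "STOP" else mode, targets,
                        q, qp, stopped)
  out <- list(
    records = NULL, ledger = ledger, checkpoints = checkpoints,
    stopped = stopped, stop_elapsed = stop_elapsed, final = final,
    meta = list(cfg = cfg, sched = sched, k = k, dose_target = dose_target,
                noise_sd_v = noise_sd_v, session_start = session_start,
                start_elapsed = start_elapsed, n_ticks = last_tick,
                format = "iontotwin-session v1")
  )
  if (record) {
    idx <- seq_len(last_tick)
    ord <- function(m) as.vector(t(m[idx, , drop = FALSE]))
    out$records <- data.frame(
      t_s = rep(v_t[idx], each = nc),
      channel = rep(seq_len(nc), last_tick),
      code_applied = ord(m_aa), code_electrode = ord(m_ae),
      v_applied = ord(m_aa) / adc_scale, v_electrode = ord(m_ae) / adc_scale,
      current_uA = ord(m_im), target_uA = ord(m_tg),
      mode = rep(v_mode[idx], each = nc),
      phase = rep(ifelse(v_phase[idx], "on", "off"), each = nc)
    )
    out$true_currents <- m_it[idx, , drop = FALSE]
  }
  class(out) <- "twin_session"
  out
}

#' @export
print.twin_session <- function(x, ...) {
  tot <- ledger_totals(x$ledger)
  cat(sprintf("<twin_session> %d ticks (%.1f s), mode end: %s\n",
              x$meta$n_ticks, x$meta$n_ticks * x$meta$cfg$sample_period,
              x$final$mode))
  cat(sprintf("  dose: %.4g mg (target %.4g mg)%s\n", tot["D"] * 1e3,
              x$meta$dose_target * 1e3,
              if (x$stopped) sprintf(" — STOP at %.1f s", x$stop_elapsed)
              else ""))
  invisible(x)
}
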