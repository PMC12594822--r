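#' Operating-mode current draws
#'
#' The device's power modes and typical current consumption. Ranges are
#' represented by their upper bounds by default (conservative budgets):
#' sleep < 10 mA (modeled as 10), standby ~50 mA, actuation without
#' transmission 70--150 mA (150), actuation with real-time WiFi
#' transmission 70--170 mA (170).
#'
#' @param sleep,standby,actuation_no_tx,actuation_tx Current draws, mA.
#' @return `data.frame` with `mode`, `draw_mA`.
#' @export
power_modes <- function(sleep = 10, standby = 50, actuation_no_tx = 150,
                        actuation_tx = 170) {
  stopifnot(sleep > 0, standby > 0, actuation_no_tx > 0, actuation_tx > 0)
  data.frame(mode = c("sleep", "standby", "actuation_no_tx", "actuation_tx"),
             draw_mA = c(sleep, standby, actuation_no_tx, actuation_tx))
}

#' Energy budget for a mode schedule
#'
#' Charge consumed (mAh) by a sequence of (mode, hours) entries:
#' `sum(draw * hours)`. A 23 h actuation-with-transmission day plus 1 h of
#' standby costs 3960 mAh at the default draws — why sleep mode matters
#' once the dose target is reached within 6--12 h.
#'
#' @param schedule `data.frame` with columns `mode` and `hours`.
#' @param modes A [power_modes()] table.
#' @return Total charge, mAh.
#' @export
power_budget <- function(schedule, modes = power_modes()) {
  if (nrow(schedule) == 0) return(0)
  stopifnot(all(c("mode", "hours") %in% names(schedule)),
            all(schedule$hours >= 0))
  unknown <- setdiff(schedule$mode, modes$mode)
  if (length(unknown))
    stop("unknown power mode(s): ", paste(unknown, collapse = ", "))
  draw <- modes$draw_mA[match(schedule$mode, modes$mode)]
  sum(draw * schedule$hours)
}

#' Run a multi-day simulated experiment
#'
#' Simulates each day's actuation window under the plan's policy on a
#' seeded synthetic load, writing one session log, one dose report and one
#' spatial dose map per day plus a run summary. The dose ledger resets at
#' each day's window start (the dose target is per day, as in the 7-day
#' in vivo protocol); the wound load persists across days. Deterministic:
#' the same seed yields byte-identical outputs.
#'
#' @param plan An [experiment_plan()].
#' @param scenario Scenario preset name or YAML path (see
#'   [load_scenario()]).
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [device_config()].
#' @param sched A [pulse_schedule()].
#' @param k A [dose_constants()].
#' @param noise_sd_v ADC measurement noise s.d. per sample, volts.
#' @param record Write full telemetry (set FALSE for dose-only speed).
#' @return Invisibly, a list with `summary` (per-day `data.frame`),
#'   `session_paths` and `out_dir`.
#' @export
run_experiment <- function(plan, scenario = "nominal_wound", seed = 1,
                           out_dir = tempfile("iontotwin_"),
                           cfg = device_config(), sched = pulse_schedule(),
                           k = dose_constants(), noise_sd_v = 0.001,
                           record = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  params <- load_scenario(scenario)  # validated before simulation starts
  set.seed(seed)
  load <- make_load(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  window_s <- plan$window_h * 3600
  summary <- data.frame(day = integer(0), mode_start = character(0),
                        dose_mg = numeric(0), stopped = logical(0),
                        stop_elapsed_s = numeric(0))
  paths <- character(0)
  for (day in seq_len(plan$days) - 1L) {
    policy <- plan_policy(plan, day)
    session <- simulate_window(
      policy, window_s, cfg = cfg, load = load, sched = sched, k = k,
      dose_target = plan$dose_target, noise_sd_v = noise_sd_v,
      record = record,
      session_start = sprintf("day %d, t0 = %d s", day, day * 86400L))
    tot <- ledger_totals(session$ledger)
    summary <- rbind(summary, data.frame(
      day = day, mode_start = plan$day_modes[day + 1],
      dose_mg = unname(tot["D"]) * 1e3, stopped = session$stopped,
      stop_elapsed_s = ifelse(session$stopped, session$stop_elapsed, NA)))
    sp <- file.path(out_dir, sprintf("day_%d_session.csv", day))
    if (record) { write_session(session, sp); paths <- c(paths, sp) }
    dm <- dose_map(session$ledger)
    data.table::fwrite(dm, file.path(out_dir, sprintf("day_%d_dose_map.csv", day)))
    rep_df <- data.frame(channel = names(session$ledger$q),
                         q_C = unname(session$ledger$q),
                         qp_C = unname(session$ledger$qp),
                         dose_g = unname(channel_doses(session$ledger)))
    data.table::fwrite(rep_df, file.path(out_dir, sprintf("day_%d_dose_report.csv", day)))
  }
  data.table::fwrite(summary, file.path(out_dir, "summary.csv"))
  invisible(list(summary = summary, session_paths = paths, out_dir = out_dir))
}

#' Render tables and figures from recorded sessions
#'
#' For each readable session log: per-channel current/voltage traces, the
#' cumulative dose curve, and the spatial dose map, written as PDF figures
#' plus a CSV summary. Unreadable files are reported per file and the rest
#' are still processed; inputs are never modified.
#'
#' @param session_paths Character vector of session CSV paths.
#' @param out_dir Output directory for figures and summaries.
#' @param cfg A [device_config()].
#' @param k A [dose_constants()].
#' @return Invisibly, a `data.frame` summary (one row per session) with
#'   attribute `failed` listing unreadable files. Errors if no session
#'   could be read.
#' @export
report_sessions <- function(session_paths, out_dir = tempfile("report_"),
                            cfg = device_config(), k = dose_constants()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); failed <- character(0)
  for (p in session_paths) {
    s <- tryCatch(read_session(p), error = function(e) {
      message("skipping unreadable session ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(s)) { failed <- c(failed, p); next }
    rec <- s$records
    base <- tools::file_path_sans_ext(basename(p))
    ledger <- reconstruct_ledger(rec, cfg, k)
    tot <- ledger_totals(ledger)

    if (nrow(rec)) {
      g1 <- ggplot2::ggplot(rec, ggplot2::aes(x = t_s)) +
        ggplot2::geom_line(ggplot2::aes(y = current_uA), colour = "steelblue") +
        ggplot2::geom_line(ggplot2::aes(y = target_uA), colour = "black",
                           linetype = 2) +
        ggplot2::facet_wrap(~channel, nrow = 2) +
        ggplot2::labs(x = "time (s)", y = "current (uA)",
                      title = "Measured vs target channel currents")
      ggplot2::ggsave(file.path(out_dir, paste0(base, "_traces.pdf")), g1,
                      width = 10, height = 5)

      dt <- cfg$sample_period
      even <- rec[rec$channel %% 2 == 0, ]
      even <- even[order(even$t_s, even$channel), ]
      dq <- pmax(even$current_uA, 0) * 1e-6 * dt * k$eta * k$molar_mass / k$faraday
      curve <- data.frame(t_s = even$t_s, channel = even$channel, dose_g = dq)
      curve <- curve[order(curve$channel, curve$t_s), ]
      curve$dose_g <- stats::ave(curve$dose_g, curve$channel, FUN = cumsum)
      g2 <- ggplot2::ggplot(curve,
              ggplot2::aes(t_s, dose_g * 1e3, colour = factor(channel))) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (s)", y = "cumulative dose (mg)",
                      colour = "channel", title = "Per-channel dose")
      ggplot2::ggsave(file.path(out_dir, paste0(base, "_dose.pdf")), g2,
                      width = 7, height = 4)
    }

    dm <- dose_map(ledger)
    dm$x <- dm$radius_mm * cospi(dm$angle_deg / 180)
    dm$y <- dm$radius_mm * sinpi(dm$angle_deg / 180)
    g3 <- ggplot2::ggplot(dm, ggplot2::aes(x, y, size = dose_g * 1e3,
                                           colour = dose_g * 1e3)) +
      ggplot2::geom_point() +
      ggplot2::coord_equal() +
      ggplot2::labs(title = "Spatial dose map", size = "dose (mg)",
                    colour = "dose (mg)")
    ggplot2::ggsave(file.path(out_dir, paste0(base, "_map.pdf")), g3,
                    width = 5, height = 4)
    data.table::fwrite(dm[, c("channel", "angle_deg", "radius_mm", "dose_g")],
                       file.path(out_dir, paste0(base, "_map.csv")))
    rows[[length(rows) + 1]] <- data.frame(
      session = p, n_records = nrow(rec),
      total_Q_C = unname(tot["Q"]), total_dose_mg = unname(tot["D"]) * 1e3)
  }
  if (!length(rows))
    stop("no readable sessions among ", length(session_paths), " input(s)")
  out <- do.call(rbind, rows)
  data.table::fwrite(out, file.path(out_dir, "sessions_summary.csv"))
  attr(out, "failed") <- failed
  invisible(out)
}
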