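#' Synthetic wound-load parameters
#'
#' Parameters of the seeded electrical environment the actuator drives:
#' per-channel wound plus contact resistance following a clipped
#' log-random-walk, multiplicative movement-artifact spikes at Poisson
#' times with exponential decay, a single-pole RC electrode-polarization
#' state per channel, and optional per-channel fault multipliers (e.g. a
#' dried-out capillary). The device's own literature motivates dynamic
#' wound and contact resistances but gives no magnitudes; every default
#' here is a documented stand-in, chosen so fluoxetine-range targets
#' (2.45--5 uA) are comfortably in compliance at baseline while
#' electric-field targets above roughly 22 uA compliance-limit.
#'
#' @param baseline_r Baseline series resistance, ohms; scalar or one per
#'   channel.
#' @param drift_sd Random-walk scale, ohms per sqrt(second), applied on the
#'   log scale relative to baseline.
#' @param movement_rate Movement-artifact events per hour per channel.
#' @param movement_magnitude Multiplicative resistance spike factor.
#' @param movement_decay Spike decay time constant, seconds.
#' @param polarization_c Electrode double-layer capacitance, farads (0
#'   disables polarization).
#' @param polarization_r Polarization resistance, ohms.
#' @param fault_channels Named numeric vector of resistance multipliers,
#'   names are channel numbers (e.g. `c("6" = 50)`).
#' @param r_clip Length-2 multiplicative clip range for the random walk.
#' @param n_channels Number of outer channels.
#' @param seed Optional integer; if non-NULL the global RNG is seeded when
#'   the load is created, making the trajectory reproducible on its own.
#' @return An object of class `load_params`.
#' @export
load_params <- function(baseline_r = 2e5, drift_sd = 200,
                        movement_rate = 6, movement_magnitude = 2,
                        movement_decay = 30, polarization_c = 1e-4,
                        polarization_r = 5e4, fault_channels = NULL,
                        r_clip = c(0.2, 5), n_channels = 8L, seed = NULL) {
  if (any(baseline_r <= 0)) stop("baseline resistance must be positive")
  stopifnot(drift_sd >= 0, movement_rate >= 0, movement_magnitude > 0,
            movement_decay > 0, polarization_c >= 0, polarization_r >= 0,
            r_clip[1] > 0, r_clip[2] >= r_clip[1])
  structure(list(baseline_r = rep_len(baseline_r, n_channels),
                 drift_sd = drift_sd, movement_rate = movement_rate,
                 movement_magnitude = movement_magnitude,
                 movement_decay = movement_decay,
                 polarization_c = polarization_c,
                 polarization_r = polarization_r,
                 fault_channels = fault_channels, r_clip = r_clip,
                 n_channels = as.integer(n_channels), seed = seed),
            class = "load_params")
}

#' Instantiate a synthetic load
#'
#' Returns a stateful load object (an environment) whose per-channel
#' resistance and polarization evolve as [step_load()] is called.
#' Deterministic for a given seed: the same seed yields identical
#' trajectories when the stepping sequence is identical.
#'
#' @param params A [load_params()].
#' @return An object of class `load_state`: environment with fields `r`
#'   (effective per-channel resistance, ohms), `v_pol` (polarization
#'   voltage, volts) and `t` (elapsed seconds).
#' @export
make_load <- function(params) {
  stopifnot(inherits(params, "load_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  nc <- params$n_channels
  fault <- rep(1, nc)
  if (!is.null(params$fault_channels)) {
    idx <- as.integer(names(params$fault_channels))
    if (any(is.na(idx) | idx < 1 | idx > nc))
      stop("fault_channels names must be channel numbers")
    fault[idx] <- as.numeric(params$fault_channels)
  }
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$log_r <- log(params$baseline_r)      # random-walk component
  e$spike <- rep(0, nc)                  # log-scale movement boost
  e$fault <- fault
  e$v_pol <- rep(0, nc)
  e$t <- 0
  e$sig_log <- params$drift_sd / mean(params$baseline_r)  # per sqrt(s), log scale
  e$r <- exp(e$log_r) * fault
  class(e) <- "load_state"
  e
}

#' @export
print.load_state <- function(x, ...) {
  cat(sprintf("<load_state> t = %.1f s\n", x$t))
  cat("  R (kOhm):", paste(sprintf("%.1f", x$r / 1e3), collapse = " "), "\n")
  cat("  V_pol (mV):", paste(sprintf("%.1f", x$v_pol * 1e3), collapse = " "), "\n")
  invisible(x)
}

#' Advance the synthetic load by one time step
#'
#' Resistance advances by a clipped log-random-walk plus exponentially
#' decaying movement spikes arriving at Poisson times; the polarization
#' voltage relaxes toward `I * polarization_r` with time constant
#' `polarization_r * polarization_c` (toward 0 when the channel is off,
#' which is what the 5 s pulse-off phase is for).
#'
#' @param load A [make_load()] object; modified in place.
#' @param i_uA Per-channel delivered currents this step, microamps.
#' @param dt Step length, seconds.
#' @return The load, invisibly.
#' @export
step_load <- function(load, i_uA, dt) {
  p <- load$params
  nc <- p$n_channels
  if (p$drift_sd > 0) {
    load$log_r <- load$log_r + stats::rnorm(nc, 0, load$sig_log * sqrt(dt))
    lo <- log(p$baseline_r * p$r_clip[1]); hi <- log(p$baseline_r * p$r_clip[2])
    load$log_r <- pmin(pmax(load$log_r, lo), hi)
  }
  if (p$movement_rate > 0) {
    hit <- stats::runif(nc) < p$movement_rate * dt / 3600
    if (any(hit)) load$spike[hit] <- load$spike[hit] + log(p$movement_magnitude)
    load$spike <- load$spike * exp(-dt / p$movement_decay)
  }
  load$r <- exp(load$log_r + load$spike) * load$fault
  if (p$polarization_c > 0 && p$polarization_r > 0) {
    tau <- p$polarization_r * p$polarization_c
    v_inf <- i_uA * 1e-6 * p$polarization_r
    a <- exp(-dt / tau)
    load$v_pol <- v_inf + (load$v_pol - v_inf) * a
  }
  load$t <- load$t + dt
  invisible(load)
}

#' Solve the star network for channel currents and voltages
#'
#' Each outer channel is a current source, grounded, or high-impedance; the
#' center electrode is the grounded return. A source channel delivers its
#' programmed current if the required drive voltage
#' `I * (r_sense + R_load) + V_pol` fits under the supply, otherwise it
#' compliance-limits at `(v_cc - V_pol) / (r_sense + R_load)`. Grounded and
#' Hi-Z outer channels carry no current (all return current flows through
#' the center), so the center current is minus the sum of the outer
#' currents.
#'
#' @param roles Character vector, one of `"current_source"`, `"grounded"`,
#'   `"high_impedance"` per outer channel.
#' @param i_prog_uA Programmed source current per channel, microamps
#'   (ignored except for `current_source` channels).
#' @param load A [make_load()] object (only read).
#' @param cfg A [device_config()].
#' @param center_grounded Must be `TRUE`; the device always grounds the
#'   center return.
#' @return A `data.frame` with one row per outer channel plus a final
#'   center row (channel 0): `channel`, `current_uA`, `v_applied`,
#'   `v_electrode`.
#' @export
solve_network <- function(roles, i_prog_uA, load, cfg = device_config(),
                          center_grounded = TRUE) {
  if (!isTRUE(center_grounded))
    stop("configuration error: the center return must be grounded (0 V)")
  nc <- length(roles)
  stopifnot(length(i_prog_uA) == nc, all(roles %in%
    c("current_source", "grounded", "high_impedance")))
  total_r <- cfg$r_sense + load$r
  i <- numeric(nc); v_app <- numeric(nc); v_el <- numeric(nc)
  src <- roles == "current_source"
  if (any(src)) {
    head_v <- pmax(cfg$v_cc - load$v_pol[src], 0)
    i_lim <- head_v / total_r[src] * 1e6
    i[src] <- pmin(pmax(i_prog_uA[src], 0), i_lim)
    v_app[src] <- i[src] * 1e-6 * total_r[src] + load$v_pol[src]
    v_el[src] <- v_app[src] - i[src] * 1e-6 * cfg$r_sense
  }
  hiz <- roles == "high_impedance"
  v_el[hiz] <- load$v_pol[hiz]  # floating electrode shows its polarization
  data.frame(channel = c(seq_len(nc), 0L),
             current_uA = c(i, -sum(i)),
             v_applied = c(v_app, 0),
             v_electrode = c(v_el, 0))
}

#' Named load scenarios
#'
#' Built-in presets: `"bench_resistor"` (fixed 46.13 kOhm calibration
#' resistors, no dynamics or polarization), `"nominal_wound"` (defaults),
#' `"faulty_capillary"` (nominal plus a 50x resistance fault on channel 6),
#' `"restless_animal"` (frequent large movement artifacts). A path to a
#' YAML file with [load_params()] fields is also accepted.
#'
#' @param name Preset name or YAML path.
#' @param seed Optional seed stored in the returned params.
#' @return A [load_params()].
#' @export
load_scenario <- function(name = "nominal_wound", seed = NULL) {
  presets <- list(
    bench_resistor = function() load_params(baseline_r = 46130, drift_sd = 0,
      movement_rate = 0, polarization_c = 0, seed = seed),
    nominal_wound = function() load_params(seed = seed),
    faulty_capillary = function() load_params(fault_channels = c("6" = 50),
      seed = seed),
    restless_animal = function() load_params(movement_rate = 60,
      movement_magnitude = 3, seed = seed)
  )
  if (name %in% names(presets)) return(presets[[name]]())
  if (!file.exists(name)) stop("unknown scenario preset and no such file: ", name)
  y <- yaml::read_yaml(name)
  if (!is.null(y$fault_channels)) y$fault_channels <- unlist(y$fault_channels)
  if (!is.null(seed)) y$seed <- seed
  do.call(load_params, y)
}
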