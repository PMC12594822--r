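#' Two-point linear calibration record
#'
#' A gain/offset correction mapping a raw device reading to a true value,
#' `true = gain * raw + offset`, fitted per channel and per quantity
#' (ADC voltage, I-DAC current or ADC current).
#'
#' @param gain Dimensionless multiplier; must be non-zero.
#' @param offset Offset in the units of the calibrated quantity.
#' @param channel_id Integer channel identifier.
#' @param quantity One of `"adc_voltage"`, `"idac_current"`, `"adc_current"`.
#' @return An object of class `linear_cal`.
#' @export
linear_cal <- function(gain = 1, offset = 0, channel_id = 1L,
                       quantity = c("adc_current", "adc_voltage", "idac_current")) {
  quantity <- match.arg(quantity)
  if (!is.finite(gain) || gain == 0) stop("calibration gain must be non-zero")
  structure(list(gain = gain, offset = offset,
                 channel_id = as.integer(channel_id), quantity = quantity),
            class = "linear_cal")
}

#' @export
print.linear_cal <- function(x, ...) {
  cat(sprintf("<linear_cal> ch %d %s: true = %.6g * raw + %.6g\n",
              x$channel_id, x$quantity, x$gain, x$offset))
  invisible(x)
}

#' Fit a two-point calibration
#'
#' Solves for the gain and offset that make `true = gain * raw + offset`
#' hold exactly at two reference points, the classic two-point calibration
#' used on each channel of the device (low point at the bottom of the
#' 2--50 uA sweep range, high point at the largest in-compliance set point).
#'
#' @param ref_lo,ref_hi Numeric length-2 vectors `c(raw, true)`; the raw
#'   coordinates must differ.
#' @inheritParams linear_cal
#' @return A [linear_cal()].
#' @examples
#' fit_two_point(c(2, 2.4), c(48, 50.7))  # recovers gain/offset exactly
#' @export
fit_two_point <- function(ref_lo, ref_hi, channel_id = 1L,
                          quantity = "adc_current") {
  stopifnot(length(ref_lo) == 2, length(ref_hi) == 2)
  if (ref_lo[1] == ref_hi[1])
    stop("degenerate two-point fit: identical raw reference values")
  gain <- (ref_hi[2] - ref_lo[2]) / (ref_hi[1] - ref_lo[1])
  offset <- ref_lo[2] - gain * ref_lo[1]
  linear_cal(gain, offset, channel_id, quantity)
}

#' Apply a calibration to raw readings
#'
#' @param raw Raw device reading(s).
#' @param cal A [linear_cal()].
#' @return Corrected value(s), `gain * raw + offset`.
#' @export
apply_cal <- function(raw, cal) {
  stopifnot(inherits(cal, "linear_cal"))
  cal$gain * raw + cal$offset
}

#' Device imperfection model for bench simulation
#'
#' Linear distortions and saturation injected into the simulated actuation
#' and sensing paths, standing in for the part-to-part errors the real
#' calibration removes. All default to the ideal device.
#'
#' @param dac_gain,dac_offset Multiplicative and additive (uA) error on the
#'   programmed DAC current.
#' @param adc_gain,adc_offset Multiplicative and additive (V) error on the
#'   analog node voltage seen by the ADC.
#' @param v_sat Output saturation ceiling, volts (the real DAC leaves its
#'   linear range near 4.2 V; `Inf` disables saturation).
#' @param noise_sd_v Gaussian noise s.d. (V) added per ADC sample.
#' @return An object of class `device_errors`.
#' @export
device_errors <- function(dac_gain = 1, dac_offset = 0,
                          adc_gain = 1, adc_offset = 0,
                          v_sat = Inf, noise_sd_v = 0) {
  structure(list(dac_gain = dac_gain, dac_offset = dac_offset,
                 adc_gain = adc_gain, adc_offset = adc_offset,
                 v_sat = v_sat, noise_sd_v = noise_sd_v),
            class = "device_errors")
}

#' Bench transfer-function sweep against a known load resistor
#'
#' Simulates the bench calibration procedure: the channel drives a known
#' resistor, target currents step over the calibration range (default
#' 2--50 uA in 2 uA steps, 25 points), the device reports its own
#' burst-averaged reading at each point (default 200 samples per step) and
#' a noiseless network solve plays the multimeter's role as truth. The
#' absolute error column is device minus true. Set points whose required
#' drive voltage exceeds the supply are flagged, not dropped.
#'
#' @param load_r Load resistance, ohms. Keep below
#'   [max_calibration_load()] so the full range stays linear.
#' @param cfg A [device_config()].
#' @param errors A [device_errors()] describing the simulated hardware.
#' @param step Target-current increment, uA.
#' @param range Length-2 sweep range, uA.
#' @param avg_n Device samples averaged per step.
#' @param cal Optional [linear_cal()] applied to the device reading.
#' @return A `data.frame` with columns `set_uA`, `dac_code`, `device_uA`,
#'   `true_uA`, `abs_error_uA`, `in_compliance`; attributes `step` and
#'   `avg_n`.
#' @export
sweep_transfer <- function(load_r, cfg = device_config(),
                           errors = device_errors(), step = 2,
                           range = c(2, 50), avg_n = 200, cal = NULL) {
  targets <- seq(range[1], range[2], by = step)
  lsb <- dac_lsb(cfg)
  total_r <- load_r + cfg$r_sense
  n <- length(targets)
  out <- data.frame(set_uA = targets, dac_code = NA_integer_,
                    device_uA = NA_real_, true_uA = NA_real_,
                    abs_error_uA = NA_real_, in_compliance = NA)
  for (k in seq_len(n)) {
    code <- min(round(targets[k] / lsb), 2^cfg$n_dac - 1)
    i_prog <- idac_output(code, cfg) * errors$dac_gain + errors$dac_offset
    v_req <- i_prog * 1e-6 * total_r
    v_ceiling <- min(errors$v_sat, cfg$v_cc)
    ok <- v_req <= v_ceiling
    i_true <- if (ok) i_prog else v_ceiling / total_r * 1e6
    v_applied <- i_true * 1e-6 * total_r
    v_electrode <- v_applied - i_true * 1e-6 * cfg$r_sense

    read_node <- function(v) {
      va <- v * errors$adc_gain + errors$adc_offset
      samples <- va + stats::rnorm(avg_n, 0, errors$noise_sd_v)
      burst_average(quantize_to_code(pmin(pmax(samples, 0), cfg$v_cc), cfg))
    }
    dev_uA <- current_from_codes(read_node(v_applied), read_node(v_electrode), cfg)
    if (!is.null(cal)) dev_uA <- apply_cal(dev_uA, cal)

    out$dac_code[k] <- code
    out$device_uA[k] <- dev_uA
    out$true_uA[k] <- i_true
    out$abs_error_uA[k] <- dev_uA - i_true
    out$in_compliance[k] <- ok
  }
  attr(out, "step") <- step
  attr(out, "avg_n") <- avg_n
  out
}

#' Calibrate a channel from a sweep table
#'
#' Two-point fit using the low end of the sweep and the largest
#' in-compliance set point, mapping the device's raw reading onto the true
#' (multimeter) value.
#'
#' @param sweep A table from [sweep_transfer()].
#' @inheritParams linear_cal
#' @return A [linear_cal()].
#' @export
calibrate_from_sweep <- function(sweep, channel_id = 1L,
                                 quantity = "adc_current") {
  ok <- which(sweep$in_compliance)
  if (length(ok) < 2) stop("fewer than two in-compliance sweep points")
  lo <- ok[1]; hi <- ok[length(ok)]
  fit_two_point(c(sweep$device_uA[lo], sweep$true_uA[lo]),
                c(sweep$device_uA[hi], sweep$true_uA[hi]),
                channel_id, quantity)
}

#' Largest load resistor keeping the sweep in the linear range
#'
#' The DAC output stays linear up to about 4.2 V; driving the full-scale
#' current through a larger resistance saturates the sweep near full scale.
#' The bound is `v_linear / i_max`: 4.2 V / 50 uA = 84 kOhm at the default
#' configuration, so any calibration resistor below 84 kOhm keeps the whole
#' 2--50 uA range linear.
#'
#' @param cfg A [device_config()].
#' @param v_linear Linear output ceiling, volts.
#' @return Maximum load resistance, ohms.
#' @export
max_calibration_load <- function(cfg = device_config(), v_linear = 4.2) {
  v_linear / (cfg$i_max * 1e-6)
}

#' Persist and load calibration tables
#'
#' CSV with columns `channel`, `quantity`, `gain`, `offset`, `timestamp`.
#'
#' @param cals A list of [linear_cal()] records.
#' @param path Output / input CSV path.
#' @param timestamp Character timestamp stored with each record.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns a list of [linear_cal()] records.
#' @export
write_calibration <- function(cals, path, timestamp = "1970-01-01T00:00:00Z") {
  if (inherits(cals, "linear_cal")) cals <- list(cals)
  df <- data.frame(
    channel = vapply(cals, `[[`, integer(1), "channel_id"),
    quantity = vapply(cals, `[[`, character(1), "quantity"),
    gain = vapply(cals, `[[`, numeric(1), "gain"),
    offset = vapply(cals, `[[`, numeric(1), "offset"),
    timestamp = timestamp
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  lapply(seq_len(nrow(df)), function(k)
    linear_cal(df$gain[k], df$offset[k], df$channel[k], df$quantity[k]))
}
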