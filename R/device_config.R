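#' Device configuration
#'
#' Immutable electrical constants of the actuator: supply voltage, converter
#' bit depths, full-scale channel current, sense resistance and the sampling
#' scheme. The defaults reproduce the published device specification: a
#' 4.7 V supply feeding 8-bit current DACs (0--50 uA full scale) and 12-bit
#' ADCs, 10 kOhm current-sense resistors, eight outer channels plus one
#' grounded center return, and 16-sample measurement bursts spaced 0.5 ms
#' apart taken every 100 ms.
#'
#' @param v_cc Supply voltage, volts.
#' @param n_adc ADC bit depth.
#' @param n_dac Current-DAC bit depth.
#' @param i_max Full-scale channel current, microamps.
#' @param r_sense Per-channel current-sense resistance, ohms.
#' @param r_sense_tol Sense-resistor tolerance (fraction), carried as
#'   metadata; the nominal value is always used for code-to-current
#'   conversion, as the device firmware does.
#' @param n_channels Number of outer channels (the center return is extra).
#' @param burst_n Samples per measurement burst.
#' @param burst_spacing Seconds between samples within a burst.
#' @param sample_period Seconds between burst averages (the control tick).
#' @param dac_denominator Either `"2^N"` (default, matching the ADC
#'   code-to-voltage convention) or `"2^N-1"` for the DAC transfer function
#'   denominator. With 8 bits both round to the printed 0.2 uA step.
#' @return An object of class `device_config` (a named list).
#' @examples
#' cfg <- device_config()
#' dac_lsb(cfg)  # 0.195 uA, rounds to the printed 0.2 uA
#' adc_lsb(cfg)  # 1.147 mV, rounds to the printed 1.1 mV
#' @export
device_config <- function(v_cc = 4.7, n_adc = 12L, n_dac = 8L, i_max = 50,
                          r_sense = 10000, r_sense_tol = 0.001,
                          n_channels = 8L, burst_n = 16L,
                          burst_spacing = 5e-4, sample_period = 0.1,
                          dac_denominator = c("2^N", "2^N-1")) {
  dac_denominator <- match.arg(dac_denominator)
  stopifnot(v_cc > 0, i_max > 0, n_adc >= 1, n_dac >= 1, r_sense > 0,
            n_channels >= 1, burst_n >= 1, burst_spacing > 0)
  if (sample_period <= burst_n * burst_spacing)
    stop("sample_period must exceed burst_n * burst_spacing")
  structure(list(
    v_cc = v_cc, n_adc = as.integer(n_adc), n_dac = as.integer(n_dac),
    i_max = i_max, r_sense = r_sense, r_sense_tol = r_sense_tol,
    n_channels = as.integer(n_channels), burst_n = as.integer(burst_n),
    burst_spacing = burst_spacing, sample_period = sample_period,
    dac_denominator = dac_denominator
  ), class = "device_config")
}

#' @export
print.device_config <- function(x, ...) {
  cat("<device_config>\n")
  cat(sprintf("  supply        : %.2f V\n", x$v_cc))
  cat(sprintf("  actuation     : %d-bit I-DAC, 0-%g uA (LSB %.3f uA)\n",
              x$n_dac, x$i_max, dac_lsb(x)))
  cat(sprintf("  sensing       : %d-bit ADC (LSB %.3f mV), R_sense %g Ohm (+/-%g%%)\n",
              x$n_adc, 1e3 * adc_lsb(x), x$r_sense, 100 * x$r_sense_tol))
  cat(sprintf("  channels      : %d outer + 1 center return\n", x$n_channels))
  cat(sprintf("  sampling      : %d-sample bursts %.1f ms apart, every %.0f ms\n",
              x$burst_n, 1e3 * x$burst_spacing, 1e3 * x$sample_period))
  invisible(x)
}

#' Converter step sizes
#'
#' `dac_lsb()` is the current-DAC step (microamps per code); `adc_lsb()` the
#' ADC voltage step (volts per code). At the default configuration these are
#' 50/2^8 = 0.195 uA and 4.7/2^12 = 1.147 mV, which round to the published
#' 0.2 uA actuation and 1.1 mV sensing resolutions.
#'
#' @param cfg A [device_config()].
#' @return Step size (uA for `dac_lsb`, V for `adc_lsb`).
#' @export
dac_lsb <- function(cfg) {
  denom <- if (cfg$dac_denominator == "2^N") 2^cfg$n_dac else 2^cfg$n_dac - 1
  cfg$i_max / denom
}

#' @rdname dac_lsb
#' @export
adc_lsb <- function(cfg) cfg$v_cc / 2^cfg$n_adc

#' Read a device configuration file
#'
#' Flat YAML with keys `v_cc`, `n_adc`, `n_dac`, `i_max_uA`, `r_sense_ohm`,
#' `n_channels`, `burst_n`, `burst_spacing_s`, `sample_period_s`. Missing
#' keys fall back to the defaults of [device_config()].
#'
#' @param path Path to a YAML file.
#' @return A [device_config()].
#' @export
read_device_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  d <- device_config()
  device_config(
    v_cc = pick("v_cc", d$v_cc),
    n_adc = pick("n_adc", d$n_adc),
    n_dac = pick("n_dac", d$n_dac),
    i_max = pick("i_max_uA", d$i_max),
    r_sense = pick("r_sense_ohm", d$r_sense),
    n_channels = pick("n_channels", d$n_channels),
    burst_n = pick("burst_n", d$burst_n),
    burst_spacing = pick("burst_spacing_s", d$burst_spacing),
    sample_period = pick("sample_period_s", d$sample_period)
  )
}
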