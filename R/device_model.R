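#' ADC code to voltage
#'
#' The ideal voltage transfer function of the sensing path: an integer (or
#' burst-averaged fractional) ADC code maps to `code / 2^n_adc * v_cc`
#' volts. Strictly monotone in the code.
#'
#' @param code ADC code(s), 0 to 2^n_adc - 1. Fractional values are allowed
#'   because burst averages of integer codes are fractional.
#' @param cfg A [device_config()].
#' @return Voltage(s), volts.
#' @examples
#' cfg <- device_config()
#' code_to_voltage(2048, cfg)  # 2.35 V
#' @export
code_to_voltage <- function(code, cfg) {
  if (any(code < 0 | code > 2^cfg$n_adc - 1))
    stop("ADC code out of range [0, 2^n_adc - 1]")
  code / 2^cfg$n_adc * cfg$v_cc
}

#' Channel current from a pair of ADC codes
#'
#' The ideal current transfer function of the sensing path: the voltage drop
#' across the sense resistor, `(V_applied - V_electrode) / r_sense`, with
#' both node voltages obtained from [code_to_voltage()]. The sign is
#' preserved: the current is negative when the electrode node sits above the
#' applied node.
#'
#' @param a_applied ADC code(s) at the applied-voltage node.
#' @param a_electrode ADC code(s) at the electrode node.
#' @param cfg A [device_config()].
#' @return Current(s), microamps.
#' @export
current_from_codes <- function(a_applied, a_electrode, cfg) {
  dv <- code_to_voltage(a_applied, cfg) - code_to_voltage(a_electrode, cfg)
  dv / cfg$r_sense * 1e6
}

#' Ideal current-DAC output
#'
#' Programmed source current for a DAC code: `code / 2^n_dac * i_max`
#' microamps (denominator configurable via
#' `device_config(dac_denominator=)`). Monotone in the code; the single-step
#' increment at the default configuration is 0.195 uA, the printed 0.2 uA
#' actuation resolution.
#'
#' @param dac_code DAC code(s), 0 to 2^n_dac - 1.
#' @param cfg A [device_config()].
#' @return Current(s), microamps.
#' @export
idac_output <- function(dac_code, cfg) {
  if (any(dac_code < 0 | dac_code > 2^cfg$n_dac - 1))
    stop("DAC code out of range [0, 2^n_dac - 1]")
  dac_code * dac_lsb(cfg)
}

#' Quantize a voltage to an ADC code
#'
#' Inverse of [code_to_voltage()] for simulation: floor then clamp to
#' [0, 2^n_adc - 1]. Clamping is the contract (saturation, not an error);
#' the round-trip error for in-range voltages is at most one ADC LSB.
#'
#' @param voltage Voltage(s), volts. Must be finite.
#' @param cfg A [device_config()].
#' @return Integer ADC code(s).
#' @export
quantize_to_code <- function(voltage, cfg) {
  if (any(!is.finite(voltage))) stop("voltage must be finite")
  code <- floor(voltage / cfg$v_cc * 2^cfg$n_adc)
  pmin(pmax(code, 0), 2^cfg$n_adc - 1)
}

#' Burst average of ADC samples
#'
#' The firmware takes a burst of sixteen samples at each input, 0.5 ms
#' apart, and stores their arithmetic mean to suppress noise: for i.i.d.
#' zero-mean noise of s.d. sigma on the codes, the averaged code has s.d.
#' sigma/sqrt(n). The average is kept real-valued, not re-quantized.
#'
#' @param samples Non-empty numeric vector of ADC codes.
#' @return The mean code (real-valued).
#' @export
burst_average <- function(samples) {
  if (length(samples) == 0) stop("empty sample burst")
  mean(samples)
}

#' Fraction of incident RF power accepted by the antenna
#'
#' Scalar relation between the reflection-coefficient magnitude |S11| (in
#' dB, non-positive) at the matching-network input and the fraction of
#' power accepted: `1 - 10^(s11_db / 10)`. At the device's tuned
#' -15.3 dB this is 0.9705, i.e. 97% of the power from the LNA.
#'
#' @param s11_db |S11| in dB; must be <= 0.
#' @return Fraction of incident power accepted, in [0, 1].
#' @export
rf_accepted_fraction <- function(s11_db) {
  if (any(s11_db > 0)) stop("|S11| in dB must be <= 0")
  1 - 10^(s11_db / 10)
}
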