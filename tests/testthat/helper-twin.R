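# Shared fixtures: built in code, no files checked in.

default_cfg <- device_config()

# A static, noiseless load: pure resistor bank, no drift/movement/polarization
static_load <- function(r = 1e5, n_channels = 8L) {
  make_load(load_params(baseline_r = r, drift_sd = 0, movement_rate = 0,
                        polarization_c = 0, n_channels = n_channels))
}

flx_levels <- c(0, 5, 0, 5, 0, 5, 0, 5)
ef_levels <- c(10, 0, 10, 0, 10, 0, 10, 0)

# One-row FLX actuation table as a data.frame
flx_table <- function(duration_s = 1e9, levels = flx_levels, mode = "FLX") {
  df <- data.frame(duration_s = duration_s)
  for (ch in 1:8) df[[paste0("ch", ch, "_uA")]] <- levels[ch]
  df$mode <- mode
  df
}

write_table_csv <- function(df, path = tempfile(fileext = ".csv")) {
  data.table::fwrite(df, path)
  path
}

# Dose per coulomb of rectified charge at the default constants
dose_per_coulomb <- function(k = dose_constants()) k$eta * k$molar_mass / k$faraday
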