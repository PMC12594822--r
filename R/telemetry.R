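.session_format <- "iontotwin-session v1"
.record_cols <- c("t_s", "code_applied", "code_electrode", "v_applied",
                  "v_electrode", "current_uA", "target_uA")

#' Write / read a session log
#'
#' The SD-card-style CSV: metadata and resume checkpoints as `#`-prefixed
#' header lines (format version first, then JSON-encoded configuration,
#' schedule, dose constants and checkpoints), followed by a declared
#' column header and one row per channel per sample period (8 consecutive
#' rows share each timestamp). Floating-point fields are written with 17
#' significant digits so the round trip is bit-exact.
#'
#' `read_session()` tolerates a truncated final row (power loss
#' mid-write): the recoverable prefix is returned and the result carries
#' `truncated = TRUE`.
#'
#' @param session A `twin_session` from [simulate_window()].
#' @param path CSV path.
#' @return `write_session()` returns `path` invisibly. `read_session()`
#'   returns a list with `records`, `meta`, `checkpoints` and `truncated`.
#' @export
write_session <- function(session, path) {
  m <- session$meta
  hdr <- c(
    paste0("# ", m$format),
    paste0("# session_start: ", m$session_start),
    paste0("# meta: ", jsonlite::toJSON(list(
      start_elapsed = m$start_elapsed, dose_target = m$dose_target,
      noise_sd_v = m$noise_sd_v, n_ticks = m$n_ticks,
      cfg = unclass(m$cfg), sched = unclass(m$sched), k = unclass(m$k)),
      auto_unbox = TRUE, digits = NA)),
    vapply(session$checkpoints, function(cp)
      paste0("# checkpoint: ",
             jsonlite::toJSON(unclass(cp), auto_unbox = TRUE, digits = NA)),
      character(1))
  )
  rec <- session$records
  if (is.null(rec)) {
    rec <- data.frame(t_s = numeric(0), channel = integer(0),
                      code_applied = numeric(0), code_electrode = numeric(0),
                      v_applied = numeric(0), v_electrode = numeric(0),
                      current_uA = numeric(0), target_uA = numeric(0),
                      mode = character(0), phase = character(0))
  }
  out <- rec
  for (col in .record_cols) out[[col]] <- sprintf("%.17g", rec[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != paste0("# ", .session_format))
    stop("session format version mismatch or not a session file: ", path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  if (length(body) == 0) stop("malformed session: missing column header")
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  rows <- body[-1]
  truncated <- FALSE
  if (length(rows)) {
    nfield <- lengths(gregexpr(",", rows, fixed = TRUE)) + 1L
    bad <- which(nfield != length(header))
    if (length(bad)) {
      if (!identical(bad, length(rows)))
        stop("malformed session row at data line ", bad[1])
      rows <- rows[-length(rows)]
      truncated <- TRUE
    }
  }
  rec <- if (length(rows)) {
    data.table::fread(text = c(body[1], rows), data.table = FALSE,
                      colClasses = list(character = c("mode", "phase")))
  } else {
    df <- data.frame(t_s = numeric(0), channel = integer(0),
                     code_applied = numeric(0), code_electrode = numeric(0),
                     v_applied = numeric(0), v_electrode = numeric(0),
                     current_uA = numeric(0), target_uA = numeric(0),
                     mode = character(0), phase = character(0))
    df[header[seq_len(min(length(header), ncol(df)))]]
  }
  for (col in intersect(.record_cols, names(rec)))
    rec[[col]] <- as.numeric(rec[[col]])
  rec$channel <- as.integer(rec$channel)

  grab <- function(key) {
    pre <- paste0("# ", key, ": ")
    sub(pre, "", meta_lines[startsWith(meta_lines, pre)], fixed = TRUE)
  }
  meta_json <- grab("meta")
  meta <- if (length(meta_json)) jsonlite::fromJSON(meta_json[1]) else list()
  meta$session_start <- grab("session_start")
  meta$format <- .session_format
  cps <- lapply(grab("checkpoint"), function(j) {
    x <- jsonlite::fromJSON(j)
    resume_state(x$elapsed, x$mode, x$targets, x$q, x$qp,
                 isTRUE(x$stopped), x$timestamp)
  })
  list(records = rec, meta = meta, checkpoints = cps, truncated = truncated)
}

#' Load an actuation table
#'
#' The device's "Load" artifact: an ordered CSV of fixed-duration
#' per-channel target currents with header
#' `duration_s,ch1_uA,...,ch8_uA,mode`. Rows are validated against the
#' treatment-mode ranges; errors name the offending row. An empty table is
#' returned as a zero-row schedule (the controller treats it as STOP).
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
load_actuation_table <- function(path) {
  expected <- c("duration_s", paste0("ch", 1:8, "_uA"), "mode")
  info <- file.info(path)
  if (is.na(info$size)) stop("no such actuation table: ", path)
  if (info$size == 0)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 10)), expected)[
        , expected, drop = FALSE])
  df <- data.table::fread(path, data.table = FALSE)
  if (!identical(names(df), expected))
    stop("bad actuation-table header; expected ",
         paste(expected, collapse = ","))
  if (nrow(df) == 0) return(df)
  num_cols <- expected[1:9]
  for (col in num_cols)
    if (!is.numeric(df[[col]]))
      stop("non-numeric cell in column ", col, " of actuation table")
  for (r in seq_len(nrow(df))) {
    if (!is.finite(df$duration_s[r]) || df$duration_s[r] <= 0)
      stop(sprintf("actuation table row %d: duration must be > 0", r))
    levels <- as.numeric(df[r, paste0("ch", 1:8, "_uA")])
    tryCatch(mode_setpoints(df$mode[r], levels),
             error = function(e)
               stop(sprintf("actuation table row %d: %s", r,
                            conditionMessage(e)), call. = FALSE))
  }
  df
}

#' Minimum FIFO buffer capacity
#'
#' The firmware buffers telemetry records between the sampling core and
#' the WiFi/SD core; the buffer must ride out the worst-case transmission
#' latency (a few seconds) without loss. Capacity is
#' `ceil(rate * worst_latency)` times a safety factor, at least 1 slot.
#'
#' @param rate Records per second.
#' @param worst_latency Worst-case consumer stall, seconds.
#' @param safety_factor Multiplier on the minimum (default 2).
#' @return Integer number of slots.
#' @export
fifo_capacity <- function(rate, worst_latency, safety_factor = 2) {
  stopifnot(rate > 0, worst_latency >= 0, safety_factor >= 1)
  max(1L, as.integer(ceiling(rate * worst_latency) * safety_factor))
}

#' Seeded producer/consumer FIFO simulation
#'
#' Records are produced at a fixed rate; the consumer drains the queue
#' instantly except during randomly arriving stalls of up to
#' `worst_latency` seconds. Records arriving at a full queue are dropped.
#' At the capacity computed by [fifo_capacity()] no record is ever lost.
#'
#' @param rate Records per second.
#' @param worst_latency Maximum stall duration, seconds.
#' @param capacity Queue capacity, slots.
#' @param duration_s Simulated time.
#' @param stall_rate Stalls per second (Poisson arrivals).
#' @return List with `produced`, `dropped`, `max_occupancy`.
#' @export
simulate_fifo <- function(rate, worst_latency, capacity, duration_s = 60,
                          stall_rate = 0.2) {
  dt <- 1 / rate
  n <- floor(duration_s * rate)
  occupancy <- 0L; dropped <- 0L; max_occ <- 0L
  stall_until <- -1
  t <- 0
  for (k in seq_len(n)) {
    t <- t + dt
    if (t >= stall_until) {
      occupancy <- 0L  # the consumer catches up the moment a stall ends
      if (stats::runif(1) < stall_rate * dt)
        stall_until <- t + stats::runif(1, 0.5, 1) * worst_latency
    }
    if (occupancy < capacity) occupancy <- occupancy + 1L
    else dropped <- dropped + 1L
    if (occupancy > max_occ) max_occ <- occupancy
    if (t >= stall_until) occupancy <- 0L
  }
  list(produced = n, dropped = dropped, max_occupancy = max_occ)
}

#' Reconstruct a dose ledger from recorded telemetry
#'
#' Replays [accumulate_charge()]'s left-rectangle rule over the logged
#' per-channel currents, in record order with the same scalar
#' accumulation the controller uses online, so the reconstruction matches
#' the online ledger exactly. The center-channel charge is the negative
#' sum of the outer channels at each sample.
#'
#' @param records A session `records` data.frame (or several stitched).
#' @param cfg A [device_config()] (for the sample period).
#' @param k A [dose_constants()].
#' @param n_channels Number of outer channels.
#' @return A [dose_ledger()].
#' @export
reconstruct_ledger <- function(records, cfg = device_config(),
                               k = dose_constants(), n_channels = 8L) {
  ledger <- dose_ledger(n_channels, k)
  dt <- cfg$sample_period
  for (ch in seq_len(n_channels)) {
    x <- records$current_uA[records$channel == ch] * 1e-6 * dt
    acc <- 0; accp <- 0
    for (v in x) { acc <- acc + v; if (v > 0) accp <- accp + v }
    ledger$q[ch] <- acc; ledger$qp[ch] <- accp
  }
  # center return: minus the per-sample sum of outer currents, accumulated
  # tick by tick in the controller's order (records come 8 rows per tick)
  if (nrow(records)) {
    ord <- order(records$t_s, records$channel)
    m <- matrix(records$current_uA[ord] * 1e-6 * dt, nrow = n_channels)
    tick_sums <- -colSums(m)
    accc <- 0
    for (v in tick_sums) accc <- accc + v
    ledger$q["center"] <- accc
  }
  ledger$t_last <- if (nrow(records)) max(records$t_s) + dt else 0
  ledger
}

#' Stitch session logs into one continuous series
#'
#' Sessions must cover non-overlapping, ordered time ranges (power-loss
#' gaps between them are allowed and contribute zero charge). Returns the
#' concatenated records and the dose ledger reconstructed by replaying the
#' accumulation over every record.
#'
#' @param sessions List of session objects (from [simulate_window()] or
#'   [read_session()]); each must carry `records`.
#' @param cfg A [device_config()].
#' @param k A [dose_constants()].
#' @return List with `records`, `ledger` and `gaps` (seconds between
#'   consecutive sessions).
#' @export
stitch_sessions <- function(sessions, cfg = device_config(),
                            k = dose_constants()) {
  stopifnot(length(sessions) >= 1)
  recs <- lapply(sessions, `[[`, "records")
  rng <- lapply(recs, function(r)
    if (nrow(r)) range(r$t_s) else c(NA_real_, NA_real_))
  gaps <- numeric(0)
  for (j in seq_len(length(recs) - 1)) {
    a <- rng[[j]]; b <- rng[[j + 1]]
    if (anyNA(a) || anyNA(b)) next
    if (b[1] <= a[2])
      stop(sprintf("overlapping sessions: %d ends at %.3f s, %d starts at %.3f s",
                   j, a[2], j + 1, b[1]))
    gaps <- c(gaps, b[1] - a[2])
  }
  all_rec <- do.call(rbind, recs)
  list(records = all_rec,
       ledger = reconstruct_ledger(all_rec, cfg, k),
       gaps = gaps)
}
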