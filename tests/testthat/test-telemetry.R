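make_session <- function(duration = 30, seed = 41, record = TRUE,
                         dose_target = 2.5e-5) {
  set.seed(seed)
  simulate_window(table_policy(flx_table()), duration,
                  load = make_load(load_params()),
                  dose_target = dose_target, record = record)
}

test_that("session logs round-trip bit-exactly", {
  s <- make_session(30)
  p <- tempfile(fileext = ".csv")
  write_session(s, p)
  back <- read_session(p)
  expect_false(back$truncated)
  expect_equal(back$records, s$records)            # all fields, exact
  expect_identical(back$records$current_uA, s$records$current_uA)
  expect_identical(back$records$t_s, s$records$t_s)
  # checkpoints survive the round trip
  expect_equal(length(back$checkpoints), length(s$checkpoints))
  expect_equal(back$checkpoints[[1]]$targets, s$checkpoints[[1]]$targets)
  expect_equal(back$meta$dose_target, s$meta$dose_target)

  # empty session round-trips to an empty session
  s0 <- make_session(0.05)   # shorter than one tick: no records
  p0 <- tempfile(fileext = ".csv")
  write_session(s0, p0)
  b0 <- read_session(p0)
  expect_equal(nrow(b0$records), 0)
})

test_that("a truncated log returns the recoverable prefix", {
  s <- make_session(10)
  p <- tempfile(fileext = ".csv")
  write_session(s, p)
  lines <- readLines(p)
  cut <- substr(lines[length(lines)], 1, 25)       # power loss mid-write
  writeLines(c(lines[-length(lines)], cut), p)
  back <- read_session(p)
  expect_true(back$truncated)
  expect_equal(nrow(back$records), nrow(s$records) - 1)
  expect_equal(back$records, s$records[-nrow(s$records), ],
               ignore_attr = "row.names")
  # a corrupt interior row is an error, not silent loss
  writeLines(c(lines[1:20], "garbage,row", lines[21:30]), p)
  expect_error(read_session(p), "malformed")
  # wrong format marker is a version mismatch
  writeLines(c("# other-format v9", lines[-1]), p)
  expect_error(read_session(p), "version mismatch")
})

test_that("actuation tables validate rows and ranges", {
  p <- write_table_csv(flx_table(duration_s = 3600))
  tab <- load_actuation_table(p)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$ch2_uA, 5)
  # out-of-range cell names its row
  bad <- flx_table(); bad$ch2_uA <- 60
  expect_error(load_actuation_table(write_table_csv(bad)),
               "row 1.*channel 2")
  bad2 <- rbind(flx_table(), flx_table()); bad2$duration_s[2] <- -5
  expect_error(load_actuation_table(write_table_csv(bad2)), "row 2")
  # bad header
  hdrless <- flx_table(); names(hdrless)[1] <- "secs"
  expect_error(load_actuation_table(write_table_csv(hdrless)), "header")
  # empty file gives an empty schedule (controller STOPs)
  p0 <- tempfile(fileext = ".csv"); file.create(p0)
  tab0 <- load_actuation_table(p0)
  expect_equal(nrow(tab0), 0)
  expect_equal(table_policy(tab0)(0)$mode, "STOP")
})

test_that("FIFO capacity arithmetic and no-loss contract", {
  expect_equal(fifo_capacity(10, 5), 100L)      # ceil(50) x safety 2
  expect_equal(fifo_capacity(10, 0), 1L)        # minimum one slot
  expect_equal(fifo_capacity(10, 5, safety_factor = 1), 50L)
  set.seed(47)
  res <- simulate_fifo(10, 5, capacity = fifo_capacity(10, 5),
                       duration_s = 600, stall_rate = 0.5)
  expect_equal(res$dropped, 0L)
  expect_gt(res$max_occupancy, 10)              # stalls actually backed up
  # an undersized buffer does lose records under the same stalls
  set.seed(47)
  res2 <- simulate_fifo(10, 5, capacity = 10, duration_s = 600,
                        stall_rate = 0.5)
  expect_gt(res2$dropped, 0L)
})

test_that("offline reconstruction equals the online ledger exactly", {
  s <- make_session(65)
  off <- reconstruct_ledger(s$records)
  expect_equal(unname(off$q), unname(s$ledger$q), tolerance = 0)
  expect_equal(unname(off$qp[1:8]), unname(s$ledger$qp[1:8]), tolerance = 0)
  expect_equal(unname(ledger_totals(off)), unname(ledger_totals(s$ledger)),
               tolerance = 0)
  # and survives the CSV round trip
  p <- tempfile(fileext = ".csv")
  write_session(s, p)
  off2 <- reconstruct_ledger(read_session(p)$records)
  expect_equal(unname(ledger_totals(off2)), unname(ledger_totals(s$ledger)),
               tolerance = 0)
})

test_that("stitching sums sessions and rejects overlap", {
  set.seed(51)
  ld <- make_load(load_params(drift_sd = 0, movement_rate = 0))
  pol <- table_policy(flx_table())
  s1 <- simulate_window(pol, 50, load = ld)
  st <- s1$final; st$elapsed <- st$elapsed + 30    # 30 s power-loss gap
  s2 <- simulate_window(pol, 50, load = ld,
                        init = resume_session(st, experiment_plan()))
  out <- stitch_sessions(list(s1, s2))
  expect_equal(out$gaps, 30 + 0.1, tolerance = 0.01)
  d1 <- ledger_totals(reconstruct_ledger(s1$records))["D"]
  d_stitched <- ledger_totals(out$ledger)["D"]
  # additivity: the stitched dose is the sum of per-session contributions
  d2_only <- ledger_totals(reconstruct_ledger(s2$records))["D"]
  expect_equal(unname(d_stitched), unname(d1 + d2_only), tolerance = 1e-9)
  # single session is the identity
  alone <- stitch_sessions(list(s1))
  expect_equal(unname(ledger_totals(alone$ledger)),
               unname(ledger_totals(s1$ledger)), tolerance = 0)
  expect_error(stitch_sessions(list(s1, s1)), "overlapping")
})
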