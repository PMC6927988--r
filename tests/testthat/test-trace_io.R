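# Sweep archive: round-trip identity, unit normalization, error paths.

make_tiny_recording <- function() {
  set.seed(42)
  sweeps <- lapply(c(-100, 150), function(a) {
    v <- -65 + cumsum(rnorm(500, 0, 0.3))
    new_sweep(v, 10000, a, step_onset = 10, step_offset = 40)
  })
  new_recording(sweeps, cell_id = "c01", group = "control")
}

test_that("archives round-trip bit-identically and writes are deterministic", {
  rec <- make_tiny_recording()
  d1 <- file.path(tempdir(), "arch1"); d2 <- file.path(tempdir(), "arch2")
  write_archive(rec, d1)
  write_archive(rec, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  back <- read_archive(d1)
  expect_identical(back$sweeps[[1]]$voltage, rec$sweeps[[1]]$voltage)
  expect_identical(back$sweeps[[2]]$command_current,
                   rec$sweeps[[2]]$command_current)
  expect_equal(back$cell_id, rec$cell_id)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$junction_potential_mv, 15.2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("units declared in the manifest are normalized on load", {
  d <- file.path(tempdir(), "arch_units")
  dir.create(d, showWarnings = FALSE)
  v_volts <- c(-0.07, -0.069, -0.068, -0.0685)
  writeLines(c("time_ms,voltage_V,current_nA",
               paste(c(0, 0.1, 0.2, 0.3), v_volts, c(0, 0.1, 0.1, 0), sep = ",")),
             file.path(d, "sweep_001.csv"))
  writeLines(jsonlite::toJSON(list(
    format = "icephys-sweep-archive", version = 1, cell_id = "u",
    sampling_rate_hz = 10000, voltage_unit = "V", current_unit = "nA",
    sweeps = list(list(file = "sweep_001.csv", step_amplitude_pa = 0.1,
                       step_onset_ms = 0.1, step_offset_ms = 0.3,
                       n_samples = 4))), auto_unbox = TRUE),
    file.path(d, "manifest.json"))
  rec <- read_archive(d)
  expect_equal(rec$sweeps[[1]]$voltage, v_volts * 1000)
  expect_equal(rec$sweeps[[1]]$step_amplitude, 100)   # 0.1 nA -> 100 pA
  expect_equal(rec$sweeps[[1]]$command_current[2], 100)
  unlink(d, recursive = TRUE)
})

test_that("malformed archives are rejected with field-level messages", {
  rec <- make_tiny_recording()
  d <- file.path(tempdir(), "arch_bad")
  write_archive(rec, d)
  # truncated sweep file: drop the last 100 lines
  f <- file.path(d, "sweep_001.csv")
  lines <- readLines(f)
  writeLines(lines[1:400], f)
  expect_error(read_archive(d), "truncated|declares")
  writeLines(lines, f)
  # unknown voltage unit
  man <- jsonlite::fromJSON(file.path(d, "manifest.json"), simplifyVector = FALSE)
  man$voltage_unit <- "furlong"
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, null = "null"),
             file.path(d, "manifest.json"))
  expect_error(read_archive(d), "unknown voltage unit")
  # missing sampling rate
  man$voltage_unit <- "mV"; man$sampling_rate_hz <- NULL
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, null = "null"),
             file.path(d, "manifest.json"))
  expect_error(read_archive(d), "sampling_rate_hz")
  unlink(d, recursive = TRUE)
  expect_error(read_archive(file.path(tempdir(), "no_such_dir")), "manifest")
})

test_that("sweep and recording invariants are enforced", {
  expect_error(new_sweep(c(-65, -65), 10000, 100, step_onset = 0,
                         step_offset = 10), "inside the sweep")
  expect_error(new_sweep(rnorm(100) - 65, 10000, 100, 1, 5,
                         command_current = numeric(3)), "length")
  expect_error(new_recording(list()), "at least one sweep")
  s1 <- sweep_of(rep(-65, 100), rate = 10000)
  s2 <- sweep_of(rep(-65, 100), rate = 20000)
  expect_error(new_recording(list(s1, s2)), "share one sampling rate")
})

test_that("validate_protocol flags computable analyses", {
  full <- new_recording(lapply(c(-100, 50, 100, 150),
                               function(a) sweep_of(rep(-65, 100), rate = 10000, amp = a,
                                                    onset = 2, offset = 8)))
  caps <- validate_protocol(full)
  expect_true(caps$sag_capable)
  expect_true(caps$rheobase_capable)
  expect_true(caps$fi_capable)
  expect_true(caps$ladder_monotone)
  expect_equal(caps$ladder_increment, 50)

  sag_only <- new_recording(list(sweep_of(rep(-65, 100), rate = 10000, amp = -100,
                                          onset = 2, offset = 8)))
  caps <- validate_protocol(sag_only)
  expect_true(caps$sag_capable)
  expect_false(caps$rheobase_capable)

  flat <- new_recording(list(sweep_of(rep(-65, 100))))
  caps <- validate_protocol(flat)
  expect_false(caps$sag_capable)
  expect_false(caps$rheobase_capable)
  expect_false(caps$fi_capable)
})
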