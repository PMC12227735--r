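test_that("spike_train validates ordering, epoch bounds and emptiness", {
  st <- spike_train("A", c(0.5, 1.0, 1.5))
  expect_s3_class(st, "spike_train")
  expect_equal(n_spikes(st), 3L)
  expect_true(attr(st, "epoch_inferred"))
  expect_equal(st$epoch_start, -0.5)

  expect_error(spike_train("A", c(1, 1, 2)), "strictly increasing")
  expect_error(spike_train("A", c(2, 1)), "strictly increasing")
  expect_error(spike_train("A", c(1, 2), epoch_start = 1.5, epoch_end = 3),
               "outside the epoch")
  expect_error(spike_train("A", 1:3, epoch_start = 5, epoch_end = 4),
               "greater than")
  expect_error(spike_train("A", numeric(0)), "epoch bounds are required")
  empty <- spike_train("A", numeric(0), 0, 10)
  expect_equal(n_spikes(empty), 0L)
})

test_that("injection_event resolves substances, doses and units", {
  inj <- injection_event(300, "nicotine", 30, "ug/kg")
  expect_equal(inj$dose, 30)
  # micro sign normalised
  expect_equal(injection_event(1, "nicotine", 30, "µg/kg")$dose_units,
               "ug/kg")
  # saline needs no dose
  expect_true(is.na(injection_event(10, "saline")$dose))
  # wrong unit table entry
  expect_error(injection_event(1, "ethanol", 30, "ug/kg"), "mg/kg")
  expect_error(injection_event(1, "nicotine", -5, "ug/kg"), "> 0")
  expect_error(injection_event(1, "cocaine", 5, "mg/kg"))
})

test_that("neuron_record enforces injection ordering and epoch containment", {
  st <- spike_train("A", c(1, 2, 3), 0, 500)
  inj <- list(injection_event(100, "saline"),
              injection_event(300, "nicotine", 30, "ug/kg"))
  rec <- neuron_record("A", st, inj, projection = "NAc")
  expect_equal(rec$projection, "NAc")
  expect_error(neuron_record("A", st, rev(inj)), "sorted")
  expect_error(neuron_record("B", st), "does not match")
  expect_error(
    neuron_record("A", st, list(injection_event(600, "saline"))),
    "within the epoch")
})

test_that("spike tables parse, sort per neuron, and round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("neuron_id,spike_time_s", "A,0.5", "A,1.0", "A,1.5"), path)
  trains <- read_spike_table(path)
  expect_length(trains, 1L)
  expect_equal(trains$A$spike_times, c(0.5, 1.0, 1.5))

  # header-only file -> empty list
  writeLines("neuron_id,spike_time_s", path)
  expect_length(read_spike_table(path), 0L)

  # interleaved neurons: grouped and sorted, matching a naive per-id oracle
  set.seed(4)
  a <- sort(runif(20, 0, 100)); b <- sort(runif(15, 0, 100))
  rows <- data.frame(id = c(rep("a", 20), rep("b", 15)), t = c(a, b))
  rows <- rows[sample(nrow(rows)), ]
  writeLines(c("neuron_id,spike_time_s",
               sprintf("%s,%.17g", rows$id, rows$t)), path)
  trains <- read_spike_table(path)
  expect_equal(trains$a$spike_times, a)
  expect_equal(trains$b$spike_times, b)

  # malformed row names its line
  writeLines(c("neuron_id,spike_time_s", "A,1.0", "A,oops"), path)
  expect_error(read_spike_table(path), "line 3")

  # duplicate timestamps rejected
  writeLines(c("neuron_id,spike_time_s", "A,1.0", "A,1.0"), path)
  expect_error(read_spike_table(path), "duplicate")

  # write/read round trip preserves full precision
  st <- spike_train("x", sort(runif(50, 0, 100)) + pi * 1e-8, 0, 100)
  out <- withr::local_tempfile(fileext = ".csv")
  write_spike_table(st, out)
  back <- read_spike_table(out, epoch = c(0, 100))
  expect_identical(back$x$spike_times, st$spike_times)
})

test_that("session metadata parses events and rejects unknown fields", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"injections":[{"time":300,"substance":"nicotine","dose":30,"units":"ug/kg"}],
               "projection":"NAc"}', path)
  meta <- read_session_metadata(path)
  expect_length(meta$injections, 1L)
  expect_equal(meta$injections[[1]]$time, 300)
  expect_equal(meta$projection, "NAc")

  writeLines('{"injections":[{"time":10,"substance":"saline"}]}', path)
  expect_true(is.na(read_session_metadata(path)$injections[[1]]$dose))

  writeLines('{"injections":[{"time":10,"substance":"ethanol","dose":250,"units":"ug/kg"}]}',
             path)
  expect_error(read_session_metadata(path), "mg/kg")

  writeLines('{"injections":[{"substance":"saline"}]}', path)
  expect_error(read_session_metadata(path), "time")

  writeLines('{"injections":[{"time":1,"substance":"mescaline","dose":1,"units":"mg/kg"}]}',
             path)
  expect_error(read_session_metadata(path), "unknown substance")
})

test_that("reports are deterministic and carry a manifest with the seed", {
  df <- data.frame(neuron_id = c("a", "b", "c"),
                   label = c("activated", "inhibited", "nonresponsive"),
                   delta_f_pct = c(35.2, -41.7, 3.3),
                   percentile = c(0.99, 0.01, 0.5))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_report(df, p1, config = list(n_shuffles = 1000), seed = 42)
  write_report(df, p2, config = list(n_shuffles = 1000), seed = 42)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(length(readLines(p1)), 4L)
  manifest <- jsonlite::fromJSON(sub("\\.csv$", "_manifest.json", p1))
  expect_equal(manifest$seed, 42)
  expect_equal(manifest$config$n_shuffles, 1000)
  expect_error(
    suppressWarnings(write_report(df, file.path(tempdir(),
                                                "no/such/dir/x.csv"))),
    "cannot write")
})

test_that("current traces read from CSV with inferred sampling rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 0.1, by = 1e-4)
  writeLines(c("time_s,current_pA", sprintf("%.6f,%.6f", t, sin(t * 100))),
             path)
  tr <- read_current_trace(path)
  expect_equal(tr$sampling_rate, 10000, tolerance = 1e-6)
  expect_length(tr$samples, length(t))
})
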