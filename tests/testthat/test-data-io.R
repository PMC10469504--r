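make_test_signal <- function(C = 2, T = 400, fs = 100, seed = 1) {
  set.seed(seed)
  matrix(rnorm(C * T, sd = 20), C, T)
}

test_that("EDF files round-trip within 16-bit quantisation", {
  sig <- make_test_signal()
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(path, sig, c("C3", "C4"), 100)
  rec <- read_recording(path)
  expect_equal(rec$meta$channel_names, c("C3", "C4"))
  expect_equal(rec$meta$sampling_rate, 100)
  expect_equal(dim(rec$signals), dim(sig))
  qstep <- (apply(sig, 1, max) - apply(sig, 1, min)) / 65535
  expect_true(all(abs(rec$signals - sig) <= qstep + 1e-9))
})

test_that("annotated events survive the EDF round trip", {
  sig <- make_test_signal()
  ev <- data.frame(onset_sample = c(11L, 101L, 301L),
                   code = c("769", "770", "771"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(path, sig, c("C3", "C4"), 100, events = ev)
  rec <- read_recording(path)
  expect_equal(nrow(rec$meta$event_table), 3)
  expect_equal(rec$meta$event_table$onset_sample, ev$onset_sample)
  expect_equal(rec$meta$event_table$code, ev$code)
})

test_that("truncated files raise a format error, never silent truncation", {
  sig <- make_test_signal()
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(path, sig, c("C3", "C4"), 100)
  full <- readBin(path, "raw", file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".edf")
  writeBin(full[1:(length(full) - 101)], trunc_path)
  expect_error(read_recording(trunc_path), "format error")
  writeBin(full[1:100], trunc_path)
  expect_error(read_recording(trunc_path), "format error")
})

test_that("GDF fixtures written by the package read back with events", {
  sig <- make_test_signal(C = 3)
  ev <- data.frame(onset_sample = c(51L, 201L), code = c(769L, 772L))
  path <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(path, sig, c("C3", "Cz", "C4"), 100, events = ev)
  rec <- read_recording(path)
  expect_equal(rec$meta$channel_names, c("C3", "Cz", "C4"))
  expect_equal(rec$meta$sampling_rate, 100)
  qstep <- (apply(sig, 1, max) - apply(sig, 1, min)) / 65535
  expect_true(all(abs(rec$signals - sig) <= qstep + 1e-9))
  expect_equal(rec$meta$event_table$onset_sample, ev$onset_sample)
  expect_equal(rec$meta$event_table$code, c("769", "772"))
})

test_that("channel selection reorders and reports missing names", {
  sig <- make_test_signal(C = 4)
  meta <- list(channel_names = c("C3", "Cz", "C4", "Pz"), sampling_rate = 100,
               event_table = NULL, subject_id = "S1")
  sel <- select_channels(sig, meta, c("C4", "C3"))
  expect_equal(sel$meta$channel_names, c("C4", "C3"))
  expect_equal(sel$signals, sig[c(3, 1), ])
  expect_error(select_channels(sig, meta, c("C3", "F7")), "F7")
})

test_that("the default motor-cortex selection is the 18 standard names", {
  expect_length(physionet_motor_channels, 18)
  expect_equal(physionet_motor_channels,
               c("C1", "C2", "C3", "C4", "C5", "C6",
                 "CP1", "CP2", "CP3", "CP4", "CP5", "CP6",
                 "P1", "P2", "P3", "P4", "P5", "P6"))
  set.seed(2)
  names64 <- c(physionet_motor_channels, paste0("X", 1:46))
  sig <- matrix(rnorm(64 * 50), 64, 50)
  meta <- list(channel_names = names64, sampling_rate = 160,
               event_table = NULL, subject_id = "S1")
  sel <- select_channels(sig, meta, physionet_motor_channels)
  expect_equal(nrow(sel$signals), 18)
})

test_that("epoching is pure slicing with an explicit label map", {
  sig <- make_test_signal(C = 2, T = 1000)
  ev <- data.frame(onset_sample = c(1L, 201L, 401L, 601L),
                   code = c("769", "770", "771", "772"))
  meta <- list(channel_names = c("C3", "C4"), sampling_rate = 100,
               event_table = tibble::as_tibble(ev), subject_id = "S7")
  es <- extract_epochs(sig, meta, epoch_length = 150)
  expect_equal(dim(es$data), c(4, 2, 150))
  expect_equal(es$labels, 0:3)
  expect_equal(es$subject, rep("S7", 4))
  for (i in 1:4) {
    expect_identical(es$data[i, , ],
                     sig[, ev$onset_sample[i]:(ev$onset_sample[i] + 149)])
  }
})

test_that("an epoch running past the recording end names the event", {
  sig <- make_test_signal(C = 2, T = 300)
  meta <- list(channel_names = c("C3", "C4"), sampling_rate = 100,
               event_table = tibble::tibble(onset_sample = c(1L, 251L),
                                            code = c("769", "770")),
               subject_id = "S1")
  expect_error(extract_epochs(sig, meta, epoch_length = 100), "event 2")
})

test_that("channel selection and epoching commute", {
  sig <- make_test_signal(C = 4, T = 500)
  meta <- list(channel_names = c("C3", "Cz", "C4", "Pz"), sampling_rate = 100,
               event_table = tibble::tibble(onset_sample = c(11L, 211L),
                                            code = c("769", "770")),
               subject_id = "S1")
  sel_first <- select_channels(sig, meta, c("C4", "C3"))
  a <- extract_epochs(sel_first$signals, sel_first$meta, epoch_length = 100)
  b <- extract_epochs(sig, meta, epoch_length = 100)
  b_sel <- b$data[, c(3, 1), , drop = FALSE]
  expect_identical(a$data, b_sel)
})

test_that("a 4.5-second window at 250 Hz yields 1125-sample trials", {
  fs <- 250
  sig <- matrix(rnorm(2 * 3000), 2, 3000)
  meta <- list(channel_names = c("C3", "C4"), sampling_rate = fs,
               event_table = tibble::tibble(onset_sample = c(101L, 1501L),
                                            code = c("769", "772")),
               subject_id = "A01")
  es <- extract_epochs(sig, meta, epoch_length = as.integer(4.5 * fs))
  expect_equal(dim(es$data)[3], 1125L)
  expect_equal(es$labels, c(0L, 3L))
})

test_that("label maps load from the packaged tables", {
  lm <- load_label_map("bci2a")
  expect_equal(lm$code, c("769", "770", "771", "772"))
  expect_equal(lm$label, 0:3)
  lp <- load_label_map("physionet")
  expect_equal(nrow(lp), 4)
})
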