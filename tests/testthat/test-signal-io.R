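test_that("EDF write/read round-trips a recording", {
  set.seed(1)
  layout <- default_layout()
  fs <- 100
  x <- matrix(rnorm(10 * fs * 3, sd = 50), nrow = 10)
  rec <- swd_recording(x, fs, layout)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording_edf(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs, fs)
  expect_equal(nrow(back$samples), 10)
  expect_equal(back$channels$label, layout$label)
  expect_equal(back$channels$hemisphere, layout$hemisphere)
  expect_equal(back$channels$ap_mm, layout$ap_mm)
  # 16-bit quantization: error bounded by one digital step per channel
  step <- apply(abs(x), 1, max) / 32767
  for (ch in 1:10)
    expect_lt(max(abs(back$samples[ch, ] - x[ch, ])), step[ch] * 1.01)
})

test_that("EDF reader rejects duplicate channel labels", {
  set.seed(2)
  rec <- swd_recording(matrix(rnorm(200), nrow = 2), 50,
                       data.frame(label = c("A", "B"), hemisphere = "left",
                                  ap_mm = 0, ml_mm = 0))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording_edf(rec, path)
  # overwrite the second 16-byte label field with a copy of the first
  con <- file(path, "r+b")
  seek(con, 256, rw = "write")
  writeChar(formatC("A", width = 16, flag = "-"), con, nchars = 16,
            eos = NULL)
  seek(con, 256 + 16, rw = "write")
  writeChar(formatC("A", width = 16, flag = "-"), con, nchars = 16,
            eos = NULL)
  close(con)
  expect_error(read_recording_edf(path), "duplicate")
})

test_that("recording container validates its inputs", {
  lay <- data.frame(label = c("A", "A"), hemisphere = "left",
                    ap_mm = 0, ml_mm = 0)
  expect_error(swd_recording(matrix(0, 2, 10), 100, lay), "duplicate")
  expect_error(swd_recording(matrix(0, 2, 10), 0,
                             data.frame(label = c("A", "B"))), "fs")
  rec <- swd_recording(matrix(1:20, 2, 10), 10,
                       data.frame(label = c("A", "B"), hemisphere = "left",
                                  ap_mm = 0, ml_mm = 0))
  expect_equal(channel_trace(rec, "B", from = 0.5, to = 1), rec$samples[2, 6:10])
  expect_error(channel_trace(rec, "C"), "unknown channel")
  expect_error(channel_trace(rec, "A", from = 0, to = 2), "outside")
})

test_that("event CSV round-trips exactly and validates rows", {
  ev <- data.frame(onset_s = c(100.123456789, 200 + pi),
                   offset_s = c(125.987654321, 230.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_identical(back$onset_s, ev$onset_s)
  expect_identical(back$offset_s, ev$offset_s)

  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  write_events(empty, path)
  expect_equal(nrow(read_events(path)), 0)

  writeLines(c("onset_s,offset_s", "10,5"), path)
  expect_error(read_events(path), "row 1")
  expect_error(write_events(data.frame(onset_s = c(0, 5),
                                       offset_s = c(10, 20)), path),
               "overlap")
})

test_that("config files load from JSON and YAML", {
  cfg <- list(alpha = 0.05, band = c(6, 8), fs = 200)
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, pj, auto_unbox = TRUE)
  got <- read_config(pj)
  expect_equal(got$alpha, 0.05)
  expect_equal(got$band, c(6, 8))

  py <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, py)
  expect_equal(read_config(py)$fs, 200)
  expect_error(read_config(withr::local_tempfile(fileext = ".txt")),
               "not found")
})
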