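test_that("eeg_record validates its invariants", {
  expect_error(eeg_record(matrix(1:4, 2), fs = 0), "positive")
  expect_error(eeg_record(matrix(c(1, NA, 3, 4), 2), fs = 250), "non-finite")
  expect_error(eeg_record(matrix(1:4, 2), fs = 250, lead_labels = c("a", "a")), "unique")
  expect_error(eeg_record(matrix(1:2, 2), fs = 250), "at least 2 timepoints")
  r <- eeg_record(matrix(rnorm(20), 2), fs = 100)
  expect_identical(r$lead_labels, c("1", "2"))
  expect_equal(eeg_duration(r), 0.1)
})

test_that("EDF round-trips a synthetic multi-lead recording", {
  path <- withr::local_tempfile(fileext = ".edf")
  set.seed(42)
  rec <- eeg_record(matrix(rnorm(4 * 500, sd = 20), nrow = 4), fs = 250,
                    lead_labels = c("3", "56", "9", "19"), subject_id = "S01")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(n_leads(back), 4)
  expect_equal(back$fs, 250)
  expect_identical(back$lead_labels, rec$lead_labels)
  expect_identical(back$subject_id, "S01")
  # 16-bit quantisation over each lead's range bounds the round-trip error
  for (l in 1:4) {
    qstep <- diff(range(rec$samples[l, ])) / 65535
    expect_lt(max(abs(back$samples[l, ] - rec$samples[l, ])), qstep)
  }
})

test_that("EDF ramp fixture matches the writer input within quantisation", {
  path <- withr::local_tempfile(fileext = ".edf")
  ramp <- matrix(rep(seq(0, 249), each = 2), nrow = 2, byrow = TRUE)
  write_edf(eeg_record(ramp, fs = 250), path)
  back <- read_edf(path)
  expect_equal(n_timepoints(back), 250)
  expect_lt(max(abs(back$samples - ramp)), 249 / 65535)
})

test_that("EDF with mixed sampling rates is rejected", {
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(eeg_record(matrix(rnorm(2 * 250), 2), fs = 250), path)
  # corrupt signal 2's samples-per-record field (blockwise signal header:
  # 16+80+8+8+8+8+8+80 = 216 bytes per signal precede the spr block)
  con <- file(path, "r+b")
  seek(con, 256 + 2 * 216 + 8, rw = "write")
  writeChar(formatC("125", width = 8, flag = "-"), con, eos = NULL)
  close(con)
  expect_error(read_edf(path), "mixed sampling rates")
})

test_that("read_matrix honours headers, defaults and preconditions", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B,C", "1,2,3", "4,5,6", "7,8,9"), p)
  r <- read_matrix(p, fs = 250)
  expect_identical(r$lead_labels, c("A", "B", "C"))
  expect_equal(r$samples["B", ], c(2, 5, 8))

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4", "5,6"), p2)
  r2 <- read_matrix(p2, fs = 100)
  expect_identical(r2$lead_labels, c("1", "2"))

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,5"), p3)
  expect_error(read_matrix(p3, fs = 250), "ragged")
  expect_error(read_matrix(p2, fs = 0), "fs")
})

test_that("a 7500-row matrix at 250 Hz reads as a 30 s record", {
  p <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(rnorm(7500 * 2), ncol = 2)
  utils::write.table(m, p, sep = ",", row.names = FALSE, col.names = FALSE)
  r <- read_matrix(p, fs = 250)
  expect_equal(eeg_duration(r), 30)
})

test_that("write_matrix / read_matrix round-trip preserves samples", {
  p <- withr::local_tempfile(fileext = ".csv")
  rec <- eeg_record(matrix(rnorm(3 * 100), 3), fs = 200,
                    lead_labels = c("x", "y", "z"))
  write_matrix(rec, p)
  back <- read_matrix(p, fs = 200)
  expect_identical(back$lead_labels, rec$lead_labels)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
})

test_that("epochs are half-open windows with exact sample counts", {
  rec <- eeg_record(matrix(rnorm(300 * 250), 1), fs = 250)
  ep <- extract_epoch(rec, 90, 120)
  expect_equal(n_timepoints(ep), 7500)
  expect_equal(ep$samples[1, 1], rec$samples[1, 90 * 250 + 1])
  expect_equal(ep$samples[1, 7500], rec$samples[1, 120 * 250])  # end excluded
  whole <- extract_epoch(rec, 0, eeg_duration(rec))
  expect_equal(whole$samples, rec$samples)
  expect_error(extract_epoch(rec, 290, 320), "exceeds")
  expect_error(extract_epoch(rec, 120, 90), "start_s < end_s")
  expect_equal(study_windows()$train, c(90, 120))
  expect_equal(study_windows()$test, c(210, 240))
})

test_that("select_leads subsets and reorders; epoching commutes with it", {
  set.seed(7)
  rec <- eeg_record(matrix(rnorm(64 * 500), 64), fs = 250,
                    lead_labels = as.character(1:64))
  same <- select_leads(rec, rec$lead_labels)
  expect_equal(same$samples, rec$samples)
  sub <- select_leads(rec, study_leads())
  expect_equal(n_leads(sub), 10)
  expect_identical(sub$lead_labels, c("3", "56", "9", "19", "6", "36", "40", "46", "26", "31"))
  expect_equal(sub$samples["56", ], rec$samples["56", ])
  expect_error(select_leads(rec, "99"), "unknown lead")

  a <- select_leads(extract_epoch(rec, 0.5, 1.5), study_leads())
  b <- extract_epoch(select_leads(rec, study_leads()), 0.5, 1.5)
  expect_equal(a$samples, b$samples)
  expect_identical(a$lead_labels, b$lead_labels)
})

test_that("score tables validate subjects and subscore names", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,TPM,ACH", "S1,1.2,10", "S2,0.8,12"), p)
  sc <- read_scores(p)
  expect_equal(nrow(sc), 2)
  expect_identical(names(sc), c("subject_id", "TPM", "ACH"))

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,BOGUS", "S1,1"), p2)
  expect_error(read_scores(p2), "unknown subscore")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,TPM", "S1,1", "S1,2"), p3)
  expect_error(read_scores(p3), "duplicate")
})
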