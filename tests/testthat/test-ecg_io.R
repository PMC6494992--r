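test_that("WFDB records round-trip through write and read in both formats", {
  set.seed(7)
  for (fmt in c(212L, 16L)) {
    n <- 101L                            # odd sample count exercises 212 padding
    sig <- matrix(as.integer(sample(-2048:2047, 2L * n, replace = TRUE)), ncol = 2L)
    ann <- tibble::tibble(sample = c(10L, 50L, 2000L), code = c(1L, 5L, 1L),
                          symbol = c("N", "V", "N"))
    rec <- ecggan:::new_ecg_record(paste0("rt", fmt), 360, sig,
                                   lead_names = c("MLII", "V5"),
                                   annotations = ann)
    dir <- withr::local_tempdir()
    hea <- write_wfdb_record(rec, dir, fmt = fmt)
    back <- read_wfdb_record(hea)
    expect_identical(back$signals, sig)
    expect_equal(back$sampling_rate, 360)
    expect_equal(back$n_samples, n)
    expect_equal(back$n_leads, 2L)
    # annotation at sample 2000 needs the long-interval (SKIP) encoding
    expect_equal(back$annotations$sample, ann$sample)
    expect_equal(back$annotations$code, ann$code)
    expect_equal(back$annotations$symbol, ann$symbol)
  }
})

test_that("missing files raise I/O errors naming the file", {
  expect_error(read_wfdb_record("no/such/record.hea"), "record.hea",
               class = "ecggan_error_io")
  dir <- withr::local_tempdir()
  writeLines(c("ghost 1 360 100", "ghost.dat 212 200 11 0 0 0 0 MLII"),
             file.path(dir, "ghost.hea"))
  expect_error(read_wfdb_record(file.path(dir, "ghost.hea")), "ghost.dat",
               class = "ecggan_error_io")
})

test_that("truncated data files raise format errors", {
  dir <- withr::local_tempdir()
  writeLines(c("short 1 360 1000", "short.dat 16 200 11 0 0 0 0 MLII"),
             file.path(dir, "short.hea"))
  writeBin(1:10, file.path(dir, "short.dat"), size = 2L, endian = "little")
  expect_error(read_wfdb_record(file.path(dir, "short.hea")),
               class = "ecggan_error_format")
})

test_that("extract_lead divides raw samples by the configured constant", {
  rec <- ecggan:::new_ecg_record("x", 360,
                                 cbind(c(400L, 0L, 200L, -200L, 100L),
                                       c(0L, 0L, 0L, 0L, 0L)))
  expect_equal(extract_lead(rec, 0L), c(2, 0, 1, -1, 0.5))
  expect_equal(extract_lead(rec, 1L), rep(0, 5))
  # linearity: dividing 200 * x recovers x exactly
  set.seed(3)
  x <- sample(-10:10, 5)
  rec2 <- ecggan:::new_ecg_record("y", 360, matrix(200L * x, ncol = 1L))
  expect_identical(extract_lead(rec2, 0L), as.numeric(x))
  expect_equal(extract_lead(rec2, 0L, scale = 100), 2 * x)
  expect_error(extract_lead(rec, 2L), class = "ecggan_error_index")
  expect_error(extract_lead(rec, -1), class = "ecggan_error_index")
})

test_that("segment_windows discards the trailing partial window", {
  # 650,000-sample record at the published window length: floor = 208
  w <- segment_windows(numeric(650000), window_length = 3120L)
  expect_equal(nrow(w), 208L)
  expect_equal(w$start_index, seq(0L, by = 3120L, length.out = 208L))
  expect_equal(nrow(segment_windows(numeric(3120), 3120L)), 1L)
  expect_equal(segment_windows(numeric(3120), 3120L)$start_index, 0L)
  expect_equal(nrow(segment_windows(numeric(3119), 3120L)), 0L)
})

test_that("non-overlapping windows partition a prefix of the input", {
  set.seed(11)
  x <- rnorm(1000)
  w <- segment_windows(x, window_length = 300L)
  expect_equal(nrow(w), 3L)
  expect_identical(unlist(w$values), x[1:900])
  # overlapping hop: starts advance by hop and stay in range
  w2 <- segment_windows(x, window_length = 300L, hop = 100L)
  expect_equal(w2$start_index, seq(0L, 700L, by = 100L))
  for (i in seq_len(nrow(w2))) {
    expect_identical(w2$values[[i]], x[(w2$start_index[i] + 1):(w2$start_index[i] + 300)])
  }
})

test_that("min-max normalization honours both conventions", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 5, 10), mode = "as-printed"), c(-1, -0.5, 0))
  set.seed(4)
  x <- rnorm(50)
  u <- minmax_normalize(x)
  expect_true(all(u >= 0 & u <= 1))
  expect_equal(range(u), c(0, 1))
  expect_equal(minmax_normalize(u), u)           # idempotent on [0,1]
  a <- minmax_normalize(x, mode = "as-printed")
  expect_equal(range(a), c(-1, 0))
  expect_error(minmax_normalize(c(3, 3, 3)), class = "ecggan_error_domain")
})

test_that("sequence and window text containers round-trip with sidecars", {
  dir <- withr::local_tempdir()
  set.seed(5)
  x <- rnorm(100)
  p <- file.path(dir, "seq.txt")
  write_sequence(x, p, record_id = "r1", sampling_rate = 360, lead_index = 0L,
                 scaling = 200)
  back <- read_sequence(p)
  expect_equal(back$values, x)
  expect_equal(back$meta$record_id, "r1")
  expect_equal(back$meta$scaling, 200)
  w <- segment_windows(rnorm(500), window_length = 100L, record_id = "rec")
  wp <- file.path(dir, "win.csv")
  write_windows(w, wp)
  wb <- read_windows(wp)
  expect_equal(ecggan:::as_window_matrix(wb), ecggan:::as_window_matrix(w))
  expect_equal(wb$source_record, w$source_record)
  expect_equal(wb$start_index, w$start_index)
  expect_error(read_sequence(file.path(dir, "nope.txt")), class = "ecggan_error_io")
})
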