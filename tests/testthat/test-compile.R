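test_that("column_mapping validates its invariants", {
  expect_error(column_mapping("Tx", "Tx", "DT", "ymd HMS"), "different source")
  expect_error(column_mapping("Tx", "Rx", c("a", "b", "c"), "ymd HMS"),
               "one combined column or two")
  expect_error(column_mapping("Tx", "Rx", "DT", "ymd HMS", delimiter = ",,"),
               "single character")
  expect_error(column_mapping("Tx", "Rx", "DT", "ymd HMS",
                              header_row = 2, skip_rows = 2),
               "after the skipped preamble")
  m <- column_mapping("Tx", "Rx", c("D", "T"), "dmy HMS")
  expect_s3_class(m, "column_mapping")
  expect_identical(m$datetime_mode, "split")
})

test_that("file scanning matches extensions case-insensitively and errors when empty", {
  d <- withr::local_tempdir()
  file.create(file.path(d, c("b.csv", "a.CSV", "notes.txt")))
  found <- scan_detection_files(d, ".csv")
  expect_identical(basename(found), c("a.CSV", "b.csv"))  # sorted, both cases
  expect_error(scan_detection_files(d, ".tsv"), "no detection files found")
  expect_error(scan_detection_files(file.path(d, "nope"), ".csv"),
               "does not exist")
})

test_that("combined and split date/time columns parse to identical instants", {
  d <- withr::local_tempdir()
  f1 <- write_raw_lines(file.path(d, "combined.csv"),
                        "DateTime,Tx,Rx",
                        c("2021-06-01 12:00:00,T1,R1",
                          "2021-06-01 12:00:30,T2,R1"))
  f2 <- write_raw_lines(file.path(d, "split.csv"),
                        "Date,Time,Tx,Rx",
                        c("01/06/2021,12:00:00,T1,R1",
                          "01/06/2021,12:00:30,T2,R1"))
  m1 <- column_mapping("Tx", "Rx", "DateTime", "ymd HMS")
  m2 <- column_mapping("Tx", "Rx", c("Date", "Time"), "dmy HMS")
  p1 <- parse_detection_file(f1, m1)
  p2 <- parse_detection_file(f2, m2)
  expect_identical(p1$timestamp, p2$timestamp)
  expect_identical(p1$timestamp[1],
                   as.POSIXct("2021-06-01 12:00:00", tz = "UTC"))
})

test_that("preamble rows are skipped and row counts follow the file arithmetic", {
  d <- withr::local_tempdir()
  f <- write_raw_lines(file.path(d, "pre.csv"), "DateTime,Tx,Rx",
                       c("2021-06-01 12:00:00,T1,R1",
                         "2021-06-01 12:01:00,T1,R1",
                         "2021-06-01 12:02:00,T1,R1"),
                       preamble = c("# vendor banner", "# unit 123"))
  m <- column_mapping("Tx", "Rx", "DateTime", "ymd HMS",
                      header_row = 3, skip_rows = 2)
  p <- parse_detection_file(f, m)
  expect_identical(nrow(p), 6L - 2L - 1L)  # lines - preamble - header
})

test_that("an unparseable timestamp is an error naming file, row and string", {
  d <- withr::local_tempdir()
  f <- write_raw_lines(file.path(d, "bad.csv"), "DateTime,Tx,Rx",
                       c("2021-06-01 12:00:00,T1,R1",
                         "junk-stamp,T1,R1"))
  m <- column_mapping("Tx", "Rx", "DateTime", "ymd HMS")
  err <- expect_error(parse_detection_file(f, m), "bad.csv")
  expect_match(conditionMessage(err), "junk-stamp")
  expect_match(conditionMessage(err), "rows 2")
})

test_that("timestamps are normalised to UTC and round-trip losslessly", {
  d <- withr::local_tempdir()
  f <- write_raw_lines(file.path(d, "tz.csv"), "DateTime,Tx,Rx",
                       c("2021-06-01 12:00:00,T1,R1",
                         "2021-06-01 12:00:00.250,T2,R1"))
  m <- column_mapping("Tx", "Rx", "DateTime", c("ymd HMS", "ymd HMOS"),
                      tz = "Europe/Berlin")
  p <- parse_detection_file(f, m)
  expect_identical(attr(p$timestamp, "tzone"), "UTC")
  expect_identical(as.numeric(p$timestamp[1]),
                   as.numeric(utc("2021-06-01 10:00:00")))  # CEST = UTC+2
  expect_equal(as.numeric(p$timestamp[2]) - as.numeric(p$timestamp[1]), 0.25)
  # format -> re-parse reproduces the same instants, fractions included
  rt <- parse_timestamps(telclean:::format_timestamp(p$timestamp),
                         c("ymd HMS", "ymd HMOS"))
  expect_equal(as.numeric(rt), as.numeric(p$timestamp))
})

test_that("retained source columns land in extras and dropped ones vanish", {
  d <- withr::local_tempdir()
  f <- write_raw_lines(file.path(d, "x.csv"), "DateTime,Tx,Rx,Sensor,Junk",
                       c("2021-06-01 12:00:00,T1,R1,42,zzz"))
  m <- column_mapping("Tx", "Rx", "DateTime", "ymd HMS",
                      drop_columns = "Junk")
  p <- parse_detection_file(f, m)
  expect_true("Sensor" %in% names(p))
  expect_identical(p$Sensor, "42")
  expect_false("Junk" %in% names(p))
  expect_false(any(c("Tx", "Rx", "DateTime") %in% names(p)))
})

test_that("duplicate partition keys on (transmitter, receiver, timestamp) and keeps the first copy", {
  t1 <- utc("2021-06-01 12:00:00")
  base <- det_table(rep(t1, 3), transmitter = "T1", receiver = "R1",
                    src = c("a", "b", "c"))
  p <- partition_duplicates(base)
  expect_identical(nrow(p$unique), 1L)
  expect_identical(nrow(p$duplicates), 2L)
  expect_identical(p$unique$src, "a")

  two_rx <- det_table(rep(t1, 2), transmitter = "T1", receiver = c("R1", "R2"))
  p2 <- partition_duplicates(two_rx)
  expect_identical(nrow(p2$unique), 2L)
  expect_identical(nrow(p2$duplicates), 0L)

  # millisecond fractions participate in the key
  ms <- det_table(t1 + c(0, 0.001), transmitter = "T1", receiver = "R1")
  expect_identical(nrow(partition_duplicates(ms)$unique), 2L)
})

test_that("compilation is invariant to batch size and counts duplicates across files", {
  d <- withr::local_tempdir()
  m <- column_mapping("Tx", "Rx", "DateTime", "ymd HMS")
  mk_rows <- function(n, off, tx) sprintf("2021-06-01 %02d:00:00,%s,R1",
                                          off + seq_len(n), tx)
  write_raw_lines(file.path(d, "a.csv"), "DateTime,Tx,Rx", mk_rows(5, 0, "T1"))
  write_raw_lines(file.path(d, "b.csv"), "DateTime,Tx,Rx", mk_rows(5, 5, "T1"))
  write_raw_lines(file.path(d, "c.csv"), "DateTime,Tx,Rx",
                  c(mk_rows(5, 0, "T1"), mk_rows(3, 10, "T2")))  # 5 repeats of a.csv

  res_all <- compile_detections(d, m)
  res_b1 <- compile_detections(d, m, batch_size = 1)
  res_b3 <- compile_detections(d, m, batch_size = 3)
  expect_identical(res_all$detections, res_b1$detections)
  expect_identical(res_all$detections, res_b3$detections)
  expect_identical(res_all$duplicates, res_b1$duplicates)

  expect_identical(unname(res_all$report["input"]), 18L)
  expect_identical(unname(res_all$report["duplicates"]), 5L)
  expect_identical(unname(res_all$report["kept"]), 13L)
  # survivors come from the lexicographically first file
  expect_true(all(res_all$duplicates$source_file == "c.csv"))
  # output sorted by timestamp, then transmitter, then receiver
  expect_false(is.unsorted(res_all$detections$timestamp))

  res_nodedupe <- compile_detections(d, m, dedupe = FALSE)
  expect_identical(nrow(res_nodedupe$detections), 18L)
  expect_identical(nrow(res_nodedupe$duplicates), 0L)
})
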