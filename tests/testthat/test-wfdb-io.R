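test_that("format-212 byte packing matches the hand-decoded examples", {
  expect_identical(ecgfusion:::decode_212(as.raw(c(0xE8, 0x03, 0x00))),
                   c(1000L, 0L))
  expect_identical(ecgfusion:::decode_212(as.raw(c(0xFF, 0xFF, 0xFF))),
                   c(-1L, -1L))
  expect_identical(ecgfusion:::encode_212(c(1000L, 0L)),
                   as.raw(c(0xE8, 0x03, 0x00)))
  # odd sample count: final pair zero-padded
  expect_identical(ecgfusion:::encode_212(c(7L)),
                   ecgfusion:::encode_212(c(7L, 0L)))
  expect_error(ecgfusion:::encode_212(c(5000L)), "overflow")
})

test_that("write_record / read_record round-trips samples and annotations", {
  dir <- withr::local_tempdir()
  adc <- cbind(c(1000L, 0L, -1L, 512L, -2048L, 2047L, 3L, -7L),
               c(0L, 1L, -1L, 2L, 3L, -4L, 5L, -6L))
  rec <- ecg_record(adc * 1.0, fs = 360,
                    annotations = data.frame(sample = c(1L, 5L),
                                             symbol = c("N", "V")))
  write_record(rec, dir, name = "rt", digital = TRUE)
  back <- read_record(file.path(dir, "rt.hea"), physical = FALSE)
  expect_equal(unname(back$signal), unname(rec$signal))
  expect_equal(back$fs, 360)
  expect_equal(back$annotations$sample, c(1L, 5L))
  expect_equal(back$annotations$symbol, c("N", "V"))

  # physical units: gain applied on the way back
  phys <- read_record(file.path(dir, "rt.hea"))
  expect_equal(unname(phys$signal), unname(rec$signal) / 200)
})

test_that("binary annotations survive long gaps and the text dialect matches", {
  dir <- withr::local_tempdir()
  ann <- data.frame(sample = c(10L, 900L, 5000L, 5400L),
                    symbol = c("N", "L", "V", "/"))
  rec <- ecg_record(matrix(0, 6000, 1), fs = 360, annotations = ann)
  write_record(rec, dir, name = "bin", annotation_dialect = "binary")
  write_record(rec, dir, name = "txt", annotation_dialect = "text")
  expect_equal(read_record(file.path(dir, "bin.hea"))$annotations, ann)
  expect_equal(read_record(file.path(dir, "txt.hea"))$annotations, ann)
})

test_that("synthetic records round-trip through the WFDB writer", {
  dir <- withr::local_tempdir()
  rec <- fixture_record(duration_s = 10)
  write_record(rec, dir, name = "synth")
  back <- read_record(file.path(dir, "synth.hea"))
  expect_equal(nrow(back$signal), nrow(rec$signal))
  # quantization error bounded by half an ADC step (gain 200)
  expect_lt(max(abs(back$signal[, 1] - rec$signal[, 1])), 0.5 / 200 + 1e-12)
  expect_equal(back$annotations$symbol, rec$annotations$symbol)
})

test_that("malformed inputs fail the way the reader contract says", {
  dir <- withr::local_tempdir()
  rec <- ecg_record(matrix(c(1, 2, 3, 4), 4, 1), fs = 100)
  expect_error(write_record(ecg_record(matrix(numeric(0), 0, 1), 100), dir),
               "empty")
  write_record(rec, dir, name = "bad", digital = TRUE)
  # unsupported format code
  hea <- readLines(file.path(dir, "bad.hea"))
  writeLines(sub(" 212 ", " 16 ", hea, fixed = TRUE),
             file.path(dir, "bad.hea"))
  expect_error(read_record(file.path(dir, "bad.hea")), "unsupported format")
  # checksum mismatch warns but still returns the record
  writeLines(sub(" 16 ", " 212 ", hea, fixed = TRUE),
             file.path(dir, "bad.hea"))
  hea <- readLines(file.path(dir, "bad.hea"))
  parts <- strsplit(hea[2], " ")[[1]]
  parts[7] <- "9999"
  writeLines(c(hea[1], paste(parts, collapse = " ")),
             file.path(dir, "bad.hea"))
  expect_warning(read_record(file.path(dir, "bad.hea"), physical = FALSE),
                 "checksum")
  # missing .dat
  file.remove(file.path(dir, "bad.dat"))
  expect_error(read_record(file.path(dir, "bad.hea")), "not found")
})

test_that("beat symbols map to AAMI classes per the EC57 convention", {
  expect_equal(map_symbol_to_aami(c("N", "L", "R", "e", "j")),
               rep("N", 5))
  expect_equal(map_symbol_to_aami(c("A", "a", "J", "S")), rep("S", 4))
  expect_equal(map_symbol_to_aami(c("V", "E")), rep("V", 2))
  expect_equal(map_symbol_to_aami("F"), "F")
  expect_equal(map_symbol_to_aami(c("/", "f", "Q")), rep("Q", 3))
  expect_error(map_symbol_to_aami("+"), "not a beat")
  expect_error(map_symbol_to_aami("~"), "not a beat")
  # the mapping is configurable
  expect_equal(map_symbol_to_aami("Z", map = c(Z = "Q")), "Q")
})
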