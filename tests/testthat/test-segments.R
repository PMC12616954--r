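# Segment table parsing and coordinate arithmetic.

test_that("segment tables parse with thousands separators and preserve order", {
  txt <- paste(
    "id\tchrom\tstart\tend\tgain",
    "13.1\tchr13\t22,222,612\t22,545,849\t1",
    "13.3\tchr13\t23609688\t23854091\t1",
    sep = "\n"
  )
  seg <- parse_segments(txt)
  expect_equal(seg$id, c("13.1", "13.3"))
  expect_equal(seg$start[1], 22222612)
  expect_equal(seg$size, c(323238, 244404))
})

test_that("degenerate and malformed segment tables are handled", {
  expect_equal(nrow(parse_segments("id\tchrom\tstart\tend\tgain\n")), 0)
  expect_error(
    parse_segments("id\tchrom\tstart\tend\tgain\nX\tchr1\t200\t100\t1\n"),
    "row 1"
  )
  expect_error(parse_segments("id\tchrom\tstart\tgain\nX\tchr1\t1\t1\n"), "missing")
  expect_error(
    parse_segments("id\tchrom\tstart\tend\tgain\nX\tchr1\tfoo\t100\t1\n"),
    "non-numeric"
  )
  expect_error(parse_segments(paste(
    "id\tchrom\tstart\tend\tgain",
    "A\tchr1\t100\t500\t1", "B\tchr1\t400\t900\t1",
    sep = "\n"
  )), "overlap")
})

test_that("segment size follows the 1-based inclusive convention", {
  seg <- parse_segments(paste(
    "id\tchrom\tstart\tend\tgain",
    "one\tchr1\t5\t5\t1",
    "sliver\tchr13\t23312551\t23312698\t1",
    sep = "\n"
  ))
  expect_equal(segment_size(seg)$size, c(1, 148))
})

test_that("segments round-trip through serialization and export to BED", {
  seg <- case_config("case1")$segments
  again <- parse_segments(write_segments(seg))
  expect_equal(again$start, seg$start)
  expect_equal(again$end, seg$end)
  expect_equal(again$gain, seg$gain)
  bed <- strsplit(export_bed(seg), "\n")[[1]]
  f <- strsplit(bed[1], "\t")[[1]]
  expect_equal(as.numeric(f[2]), seg$start[1] - 1) # 0-based half-open start
  expect_equal(as.numeric(f[3]), seg$end[1])
})
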