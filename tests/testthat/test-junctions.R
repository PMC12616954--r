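# Junction notation, normalization, VCF breakend import, validation.

test_that("oriented junction notation maps to breakend pairs", {
  seg <- parse_segments(paste(
    "id\tchrom\tstart\tend\tgain",
    "X\tchr1\t1000\t2000\t1", "Y\tchr1\t5000\t6000\t1",
    sep = "\n"
  ))
  jt <- function(tok) {
    j <- parse_junctions(sprintf("id\tjunction\thomology_bp\nJ\t%s\t0", tok), seg)
    j$key
  }
  expect_equal(jt("+X:+Y"), "X:end|Y:start")
  expect_equal(jt("-X:-Y"), "X:start|Y:end")
  expect_equal(jt("+X:-Y"), "X:end|Y:end")
  expect_equal(jt("-X:+Y"), "X:start|Y:start")
})

test_that("junction normalization is strand-symmetric (an involution)", {
  seg <- case_config("case1")$segments
  a <- parse_junctions("id\tjunction\thomology_bp\nJ\t+13.3:+13.1\t23", seg)
  b <- parse_junctions("id\tjunction\thomology_bp\nJ\t-13.1:-13.3\t23", seg)
  expect_equal(a$key, b$key)
})

test_that("bad junction tokens are rejected", {
  seg <- parse_segments("id\tchrom\tstart\tend\tgain\nX\tchr1\t10\t20\t1")
  expect_error(
    parse_junctions("id\tjunction\thomology_bp\nJ\t+X:+Z\t0", seg),
    "unknown segment"
  )
  expect_error(
    parse_junctions("id\tjunction\thomology_bp\nJ\tXY\t0", seg),
    "malformed"
  )
})

test_that("VCF breakend pairs import to the equivalent junction", {
  cfg <- case_config("case1")
  seg <- cfg$segments
  vcf <- paste(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr13\t23854091\tbnd_a\tN\tN[chr13:22222612[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_b",
    "chr13\t22222612\tbnd_b\tN\t]chr13:23854091]N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_a",
    sep = "\n"
  )
  jn <- import_vcf_bnd(vcf, seg)
  expect_equal(nrow(jn), 1)
  direct <- parse_junctions("id\tjunction\thomology_bp\nJ\t+13.3:+13.1\t23", seg)
  expect_equal(jn$key, direct$key)
})

test_that("unpaired and off-boundary breakends are skipped with a warning", {
  seg <- case_config("case1")$segments
  unpaired <- paste(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr13\t23854091\tbnd_a\tN\tN[chr13:22222612[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_zz",
    sep = "\n"
  )
  expect_warning(out <- import_vcf_bnd(unpaired, seg), "unpaired")
  expect_equal(nrow(out), 0)
  shifted <- paste(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr13\t23854092\tbnd_a\tN\tN[chr13:22222613[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_b",
    "chr13\t22222613\tbnd_b\tN\t]chr13:23854092]N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_a",
    sep = "\n"
  )
  expect_warning(out0 <- import_vcf_bnd(shifted, seg, tolerance = 0), "boundary")
  expect_equal(nrow(out0), 0)
  out1 <- import_vcf_bnd(shifted, seg, tolerance = 10)
  expect_equal(nrow(out1), 1)
})

test_that("configuration validation flags the specified violations", {
  cfg <- case_config("case1")
  expect_equal(nrow(validate_configuration(cfg$segments, cfg$junctions)), 0)
  seg2 <- cfg$segments
  seg2$gain[2] <- 0L
  rep2 <- validate_configuration(seg2, cfg$junctions)
  expect_true(any(rep2$kind == "zero_gain"))
  jn3 <- cfg$junctions
  jn3$seg_a[1] <- "nope"
  rep3 <- validate_configuration(cfg$segments, jn3)
  expect_true(any(rep3$kind == "unknown_segment"))
})
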