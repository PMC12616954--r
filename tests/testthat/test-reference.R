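# Reference tiling: copy-neutral gap derivation and telomere anchors.

test_that("case 3 tiling reproduces the copy-neutral gap arithmetic", {
  cfg <- case_config("case3")
  ref <- cfg$reference
  # gap between 20.1 and 20.2: the central ~2.3 Mb copy-neutral region
  mid <- ref[ref$id == "NML_chr20_2", ]
  expect_equal(mid$size, 12115100 - 9780418 - 1) # 2,334,681
  # gap between 20.2 and 20.3 is 30,996 bp
  g23 <- ref[ref$id == "NML_chr20_3", ]
  expect_equal(g23$size, 12350710 - 12319713 - 1)
  expect_equal(g23$size, 30996)
  # 20.3|20.4|20.5 are adjacent: no copy-neutral tiles between them
  ids <- ref$id
  expect_equal(
    ids[seq(match("20.3", ids), match("20.5", ids))],
    c("20.3", "20.4", "20.5")
  )
})

test_that("tiling covers each chromosome exactly with anchored telomeres", {
  for (case in c("case1", "case2", "case3")) {
    ref <- case_config(case)$reference
    for (ch in unique(ref$chrom)) {
      t <- ref[ref$chrom == ch, ]
      expect_equal(sum(t$size), default_genome()$lengths[[ch]])
      expect_true(all(t$start[-1] == t$end[-nrow(t)] + 1)) # no overlap, no gap
      expect_equal(t$role[1], "telomere_anchor")
      expect_equal(t$role[nrow(t)], "telomere_anchor")
    }
  }
})

test_that("a single duplication gets exactly two flanking gap tiles", {
  seg <- parse_segments("id\tchrom\tstart\tend\tgain\nD\tchrA\t400001\t600000\t1")
  ref <- build_reference(seg, c(chrA = 1000000))
  expect_equal(nrow(ref), 3)
  expect_equal(ref$id, c("NML_chrA_1", "D", "NML_chrA_2"))
})

test_that("overlapping duplications are rejected", {
  seg <- tibble::tibble(
    id = c("A", "B"), chrom = "chr1", start = c(100, 400), end = c(500, 900),
    gain = 1L, role = "duplicated", note = "", size = c(401, 501)
  )
  expect_error(build_reference(seg, c(chr1 = 10000)), "overlap")
})
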