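# Topology enumeration: cassette chaining, archetype cuts, general DFS,
# canonical forms, and equivalence with the brute-force oracle.

test_that("junctions chain into the expected cassette cycles", {
  ch <- chain_cassette(generic_config())
  expect_length(ch, 1)
  expect_true(ch[[1]]$cyclic)
  expect_setequal(ch[[1]]$copies$seg, c("D1", "D2"))

  c1 <- chain_cassette(case_config("case1"))
  expect_length(c1, 1)
  expect_true(c1[[1]]$cyclic)
  cyc <- cycle_from_start(c1[[1]], "13.1")
  expect_equal(cyc$copies$seg, c("13.1", "13.2", "13.3"))
  expect_equal(cyc$copies$orient, c(1L, -1L, 1L))

  tc <- chain_cassette(tandem_config())
  expect_true(tc[[1]]$cyclic)
  expect_equal(nrow(tc[[1]]$copies), 1) # self-cycle of length 1
})

test_that("archetype enumeration counts match the cassette-cut model", {
  expect_length(enumerate_archetype(generic_config()), 3)
  expect_length(enumerate_archetype(tandem_config()), 1)
  c1 <- case_config("case1")
  expect_length(enumerate_archetype(c1, resolution_bp = 500), 3)
  # at resolution 0 the 148 bp sliver becomes a cut site; its inverted
  # orientation admits no extra trans split, so 3 + 1 structures
  expect_length(enumerate_archetype(c1, resolution_bp = 0), 4)
  c2 <- case_config("case2")
  a2 <- enumerate_archetype(c2)
  expect_length(a2, 3)
  trans <- a2[[which(vapply(a2, function(s) s$meta$type == "trans", TRUE))]]
  chroms_touched <- vapply(trans$haplotypes, function(h) {
    paste(unique(c(h$seg[1], h$seg[nrow(h)])), collapse = "+")
  }, "")
  expect_setequal(chroms_touched, c(
    "NML_chr16_1+NML_chr17_2", "NML_chr17_1+NML_chr16_2"
  )) # reciprocal translocation: 16pter->17qter and 17pter->16qter
})

test_that("archetype enumeration rejects non-archetype configurations", {
  c3 <- case_config("case3")
  expect_error(enumerate_archetype(c3), "enumerate_general")
})

test_that("general enumeration equals the brute-force oracle on small fixtures", {
  for (cfg in list(generic_config(), tandem_config(), case_config("case2"))) {
    expect_same_structure_sets(
      enumerate_general(cfg),
      brute_force_oracle(cfg)
    )
  }
  c1 <- case_config("case1")
  expect_same_structure_sets(
    enumerate_general(c1),
    brute_force_oracle(c1, max_copies = 13)
  )
})

test_that("archetype structures are contained in the general enumeration", {
  for (cfg in list(generic_config(), tandem_config(), case_config("case1"), case_config("case2"))) {
    gen <- enumerate_general(cfg)
    arch <- enumerate_archetype(cfg, resolution_bp = 0)
    expect_true(all(keys_of(arch) %in% keys_of(gen)))
  }
})

test_that("every emitted structure satisfies copy and junction accounting", {
  for (cfg in list(generic_config(), case_config("case1"), case_config("case2"))) {
    for (st in enumerate_general(cfg)) {
      expect_length(validate_structure(st, cfg), 0)
      cc <- structure_copy_counts(st, cfg)
      ref <- cfg$reference
      expect_equal(cc$realized_total, 2 + ref$gain)
    }
  }
})

test_that("enumeration is deterministic and monotone in the homologue cap", {
  cfg <- generic_config()
  a <- enumerate_general(cfg)
  b <- enumerate_general(cfg)
  expect_identical(keys_of(a), keys_of(b))
  one <- enumerate_general(cfg, max_modified_homologues = 1)
  expect_true(all(keys_of(one) %in% keys_of(a)))
  expect_lte(length(one), length(a))
})

test_that("canonical form is invariant under haplotype relabeling only", {
  cfg <- case_config("case2")
  sts <- enumerate_general(cfg)
  trans <- sts[[which(vapply(sts, function(s) length(s$haplotypes) == 2, TRUE))]]
  swapped <- trans
  swapped$haplotypes <- rev(swapped$haplotypes)
  expect_equal(structure_key(swapped), trans$key)
  deep <- unserialize(serialize(trans, NULL))
  expect_equal(structure_key(deep), trans$key)
  expect_length(unique(keys_of(sts)), length(sts))
})

test_that("the chromoanasynthesis case enumerates 12 inherited structures", {
  c3 <- case_config("case3")
  g3 <- enumerate_general(c3, forbid_same_chromosome_pair = TRUE)
  expect_length(g3, 12)
  mid_orients <- vapply(g3, function(st) {
    h <- st$haplotypes[[1]]
    paste(sort(unique(h$orient[h$seg == "NML_chr20_2"])), collapse = ",")
  }, "")
  # the central 2.3 Mb copy-neutral region appears inverted in 4 structures
  expect_equal(sum(mid_orients == "-1"), 4)
  expect_equal(sum(mid_orients == "1"), 8)
  for (st in g3) expect_length(validate_structure(st, c3), 0)
})
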