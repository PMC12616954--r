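# Structure resolution from signature counts, and the spanning-yield power
# model (expected counts, size limit, length-distribution summaries).

test_that("published count patterns resolve the case structures", {
  c1 <- case_config("case1")
  s1 <- case_structures("case1", config = c1)
  r1 <- resolve_structures(
    c("13.1-13.3-13.1" = 5, "NML-13.1-13.3" = 3, "13.3-13.1-NML" = 1),
    s1, c1
  )
  expect_equal(r1$supported, "Alt2")

  c2 <- case_config("case2")
  s2 <- case_structures("case2", config = c2)
  r2 <- resolve_structures(c("16-17-NML" = 3), s2, c2)
  expect_setequal(r2$supported, c("Alt2", "Alt3"))
  req <- r2$unresolved_pairs$required[[1]]
  expect_equal(req$seg, "16")
  expect_match(r2$unresolved_pairs$note, "FISH") # 2.01 Mb span is infeasible
})

test_that("degenerate observations behave as documented", {
  cfg <- generic_config()
  sts <- enumerate_archetype(cfg)
  all_supported <- resolve_structures(
    tibble::tibble(signature = character(), n_molecules = numeric()), sts, cfg
  )
  expect_setequal(all_supported$supported, names(sts))
  impossible <- resolve_structures(c("D1-D2-D1" = 2, "D2-D1-D2" = 2), sts, cfg)
  expect_true(impossible$contradictory)
  expect_length(impossible$supported, 0)
})

test_that("dropping an observed class never shrinks the supported set", {
  cfg <- generic_config()
  sts <- enumerate_archetype(cfg)
  counts <- c("D1-D2-D1" = 3, "NML-D1-D2" = 2, "D2-D1-NML" = 1)
  full <- resolve_structures(counts, sts, cfg)$supported
  for (drop in names(counts)) {
    sub <- resolve_structures(counts[setdiff(names(counts), drop)], sts, cfg)$supported
    expect_true(all(full %in% sub))
  }
})

test_that("min_support gates which classes drive exclusion", {
  cfg <- generic_config()
  sts <- enumerate_archetype(cfg)
  counts <- c("D1-D2-D1" = 5, "D2-D1-D2" = 1) # contradictory at support 1
  expect_true(resolve_structures(counts, sts, cfg, min_support = 1)$contradictory)
  r2 <- resolve_structures(counts, sts, cfg, min_support = 2)
  expect_false(r2$contradictory)
})

test_that("expected spanning counts follow the interval-excess formula", {
  expect_equal(expected_spanning(2e5, 2e4, molecules = c(1e5, 2e5), genome_length = 1e6)$expected_count, 0)
  one <- expected_spanning(1e5, 2e4, molecules = 5e5, genome_length = 1e6)
  expect_equal(one$expected_count, (5e5 - 1.4e5) / 1e6)
  # strictly decreasing in duplication size and flank margin
  lm <- length_model_geometric()
  ec <- vapply(seq(1e5, 6e5, 1e5), function(D) {
    expected_spanning(D, 2e4, lm, 1e7, n_molecules = 1000)$expected_count
  }, 0)
  expect_true(all(diff(ec) < 0))
  ef <- vapply(c(0, 2e4, 4e4), function(FF) {
    expected_spanning(2e5, FF, lm, 1e7, n_molecules = 1000)$expected_count
  }, 0)
  expect_true(all(diff(ef) < 0))
})

test_that("the closed form agrees with Monte-Carlo placement within 3 SE", {
  lm <- length_model_geometric()
  cf <- expected_spanning(2e5, 2e4, lm, 5e6, n_molecules = 800)
  mc <- expected_spanning(2e5, 2e4, lm, 5e6,
    n_molecules = 800,
    method = "monte_carlo", seed = 11, nrep = 300
  )
  expect_lt(abs(cf$expected_count - mc$expected_count), 3 * mc$se)
  lens <- draw_lengths(lm, 500)
  cf2 <- expected_spanning(3e5, 2e4, lens, 5e6)
  mc2 <- expected_spanning(3e5, 2e4, lens, 5e6, method = "monte_carlo", seed = 3, nrep = 300)
  expect_lt(abs(cf2$expected_count - mc2$expected_count), 3 * mc2$se)
})

test_that("the resolvable-size limit is monotone in coverage and support", {
  lm <- length_model_geometric()
  l_lo <- estimate_size_limit(lm, coverage = 100, min_count = 1)
  l_hi <- estimate_size_limit(lm, coverage = 200, min_count = 1)
  expect_gte(l_hi$size_limit_bp, l_lo$size_limit_bp)
  l1 <- estimate_size_limit(lm, coverage = 400, min_count = 1)
  l5 <- estimate_size_limit(lm, coverage = 400, min_count = 5)
  expect_gte(l1$size_limit_bp, l5$size_limit_bp)
  # with study-like coverage the limit sits in the hundreds of kilobases
  l <- estimate_size_limit(lm, coverage = 400, F_bp = 20000, min_count = 3)
  expect_gt(l$size_limit_bp, 1e5)
  expect_lt(l$size_limit_bp, 1.5e6)
})

test_that("bin decline recovers the configured survival ratio", {
  set.seed(17)
  lens <- draw_lengths(length_model_geometric(survival = 0.5), 20000)
  bd <- bin_decline(lens, 100000, 200000)
  early <- bd$decline_pct[2:5]
  expect_lt(max(abs(early - 50)), 10)
  expect_equal(nrow(bin_decline(rep(250000, 5))), 1)
  expect_equal(nrow(bin_decline(numeric())), 0)
})

test_that("N50 follows the half-the-bases definition", {
  expect_equal(n50(c(300, 200, 100)), 300)
  expect_equal(n50(42), 42)
  expect_equal(n50(rep(7, 10)), 7)
  expect_error(n50(numeric()), "empty")
})
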