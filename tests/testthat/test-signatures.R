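# Spanning-signature derivation, canonicalization, diagnostic uniqueness,
# and the segments whose spanning decides structure pairs.

test_that("case 1 resolved-structure signatures match the published classes", {
  cfg <- case_config("case1")
  sts <- case_structures("case1", config = cfg)
  s_alt2 <- derive_signatures(sts$Alt2, cfg, 500)
  expect_setequal(
    s_alt2$signature,
    c("NML-13.1-13.3", "13.1-13.3-13.1", "13.3-13.1-NML")
  )
  # at resolution 0 the inverted 148 bp sliver becomes a spanning target
  s0 <- derive_signatures(sts$Alt2, cfg, 0)
  expect_true("13.1-13.2-13.3" %in% s0$signature)
  expect_equal(s0$target[s0$signature == "13.1-13.2-13.3"], "13.2")
})

test_that("case 2 signature sets match the published classes", {
  cfg <- case_config("case2")
  sts <- case_structures("case2", config = cfg)
  expect_setequal(
    derive_signatures(sts$Alt3, cfg, 500)$signature,
    c("NML-16-17", "16-17-NML", "NML-17-16", "17-16-NML")
  )
  expect_setequal(
    derive_signatures(sts$Alt2, cfg, 500)$signature,
    c("NML-17-16", "17-16-17", "16-17-NML")
  )
})

test_that("a reference haplotype yields no abnormal signatures", {
  cfg <- generic_config()
  ref_walk <- ogmtopo:::ref_walk(cfg$reference, "chrA")
  ref_model <- ogmtopo:::new_structure("Ref", list(ref_walk), cfg)
  expect_equal(nrow(derive_signatures(ref_model, cfg, 500)), 0)
})

test_that("diagnostic uniqueness singles out the cassette-insertion pattern", {
  cfg <- case_config("case1")
  sts <- case_structures("case1", config = cfg)
  dm <- diagnostic_matrix(sts, cfg, 500)
  row <- dm$matrix[dm$matrix$signature == "13.1-13.3-13.1", ]
  expect_equal(row$structures[[1]], "Alt2")
  expect_equal(row$unique_to, "Alt2")
})

test_that("the trans structure of the generic case has no unique signature", {
  cfg <- generic_config()
  sts <- enumerate_archetype(cfg)
  dm <- diagnostic_matrix(sts, cfg, 500)
  trans_label <- sts[[which(vapply(sts, function(s) s$meta$type == "trans", TRUE))]]$label
  uni <- dm$unique$signatures[dm$unique$label == trans_label][[1]]
  expect_length(uni, 0)
  cis_labels <- setdiff(dm$unique$label, trans_label)
  for (l in cis_labels) {
    expect_gt(length(dm$unique$signatures[dm$unique$label == l][[1]]), 0)
  }
})

test_that("required spans name exactly the deciding segments", {
  c1 <- case_config("case1")
  s1 <- case_structures("case1", config = c1)
  req <- required_spans(s1$Alt2, s1$Alt3, c1, 500)
  expect_true("13.3" %in% req$seg)
  expect_false("13.1" %in% req$seg)
  expect_equal(req$size[req$seg == "13.3"], 244404)

  c2 <- case_config("case2")
  s2 <- case_structures("case2", config = c2)
  req2 <- required_spans(s2$Alt2, s2$Alt3, c2, 500)
  expect_equal(req2$seg, "16")
  expect_equal(req2$size, 2008808)

  expect_equal(nrow(required_spans(s1$Alt2, s1$Alt2, c1, 500)), 0)
})

test_that("distinguishable pairs and nonempty required spans coincide", {
  cfg <- generic_config()
  sts <- enumerate_archetype(cfg)
  sigsets <- lapply(sts, function(st) sort(derive_signatures(st, cfg, 500)$key))
  for (p in utils::combn(seq_along(sts), 2, simplify = FALSE)) {
    differ <- !identical(sigsets[[p[1]]], sigsets[[p[2]]])
    req <- required_spans(sts[[p[1]]], sts[[p[2]]], cfg, 500)
    expect_equal(nrow(req) > 0, differ)
  }
})

test_that("signature canonicalization is an idempotent reversal quotient", {
  segs <- c("A", "B", "NML")
  set.seed(42)
  for (i in 1:50) {
    l <- sample(segs, 1)
    r <- sample(segs, 1)
    lo <- sample(c(1L, -1L), 1)
    ro <- sample(c(1L, -1L), 1)
    to <- sample(c(1L, -1L), 1)
    a <- ogmtopo:::canonical_signature(l, lo, "T", to, r, ro)
    # the reversed-with-flips triple canonicalizes identically
    b <- ogmtopo:::canonical_signature(r, -ro, "T", -to, l, -lo)
    expect_equal(a$key, b$key)
    expect_equal(a$signature, b$signature)
  }
})

test_that("raising the resolution does not add classes for large targets", {
  cfg <- case_config("case1")
  sts <- case_structures("case1", config = cfg)
  for (st in sts) {
    s0 <- derive_signatures(st, cfg, 0)
    s500 <- derive_signatures(st, cfg, 500)
    expect_lte(nrow(s500), sum(s0$size >= 500))
    expect_true(all(s500$size >= 500))
  }
})
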