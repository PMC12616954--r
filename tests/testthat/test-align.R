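# Label alignment: DP behaviour on clean and degraded windows, equivalence
# with the exhaustive placement oracle, orientation handling.

map_fixture <- function(n = 60, spacing = 5000, seed = 8) {
  pos <- spacing_model_labels(n * spacing, spacing, 500, seed = seed)
  ogmtopo:::new_label_map("m", n * spacing, pos)
}

test_that("a noise-free window aligns uniquely at its true offset", {
  m <- map_fixture()
  w <- m$positions[m$positions > 50000 & m$positions <= 200000] - 50000
  pl <- align_molecule(w, 150000, m)
  expect_gte(nrow(pl), 1)
  best <- pl[1, ]
  expect_equal(best$n_matched, length(w))
  expect_equal(best$map_start, m$positions[m$positions > 50000][1])
  expect_equal(best$orientation, 1L)
})

test_that("a deleted label costs one miss but keeps the placement", {
  m <- map_fixture()
  w <- m$positions[m$positions > 50000 & m$positions <= 200000] - 50000
  w2 <- w[-10]
  pl <- align_molecule(w2, 150000, m)
  best <- pl[1, ]
  expect_equal(best$n_matched, length(w2))
  expect_equal(best$map_start, m$positions[m$positions > 50000][1])
  full <- align_molecule(w, 150000, m)[1, ]
  expect_lt(best$score, full$score)
})

test_that("an unrelated map attracts no placement above threshold", {
  m <- map_fixture(seed = 8)
  other <- map_fixture(seed = 99)
  w <- m$positions[m$positions > 50000 & m$positions <= 200000] - 50000
  pl_true <- align_molecule(w, 150000, m)
  pl_other <- align_molecule(w, 150000, other)
  expect_gt(pl_true$score[1], 0.7 * length(w))
  if (nrow(pl_other) > 0) {
    expect_lt(pl_other$score[1], 0.5 * pl_true$score[1])
  }
})

test_that("a reversed molecule aligns equally well in the other orientation", {
  m <- map_fixture()
  w <- m$positions[m$positions > 50000 & m$positions <= 200000] - 50000
  wr <- sort(150000 - w)
  pf <- align_molecule(w, 150000, m)[1, ]
  pr <- align_molecule(wr, 150000, m)[1, ]
  expect_equal(pr$score, pf$score, tolerance = 1e-9)
  expect_equal(pr$orientation, -1L)
})

test_that("the banded DP equals the exhaustive placement oracle", {
  params <- alignment_params(band = 25, min_aligned_labels = 1, score_frac = -Inf)
  set.seed(31)
  for (rep in 1:12) {
    ref <- sort(runif(sample(8:18, 1), 0, 1e5))
    k <- sample(3:6, 1)
    mol <- sort(runif(k, 0, 3e4))
    dp <- ogmtopo:::align_dp_cpp(
      mol, ref, params$match_bonus, params$interval_weight,
      params$miss_penalty, params$extra_penalty, as.integer(params$band)
    )
    ex <- ogmtopo:::align_exhaustive(mol, ref, params)
    expect_equal(dp$score, ex, tolerance = 1e-9)
  }
})
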