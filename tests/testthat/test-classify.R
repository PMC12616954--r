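# Molecule classification under the informative-molecule criterion.

quiet_noise <- function() {
  noise_model(
    label_dropout_prob = 0, false_per_100kb = 0, sizing_cv = 0,
    chimera_prob = 0
  )
}

test_that("noise-free molecules recover only truth signatures", {
  fx <- make_fixture("generic_alt2", seed = 6, coverage = 12, noise = quiet_noise())
  cs <- classify_set(fx$molecules, fx$candidates, fx$catalog, fx$config,
    min_length = 190000
  )
  truth_sigs <- derive_signatures(fx$candidates$Alt2, fx$config, 500)$signature
  inf <- cs$records[cs$records$verdict == "informative", ]
  expect_gt(nrow(inf), 0)
  got <- unique(unlist(strsplit(inf$signature, ",")))
  expect_true(all(got %in% truth_sigs))
  expect_equal(sum(cs$tallies$n[cs$tallies$verdict == "chimera_suspect"], na.rm = TRUE), 0)
})

test_that("noise-free spanning molecules with ample flanks are informative", {
  fx <- make_fixture("generic_alt2", seed = 6, coverage = 12, noise = quiet_noise())
  truth_map <- fx$genome_maps[[1]] # Alt2 haplotype
  tg <- truth_map$copies[truth_map$copies$target & truth_map$copies$abnormal, ]
  meta <- ogmtopo:::catalog_meta(fx$catalog)
  mols <- fx$molecules
  margin <- 30000 # comfortably more than 4 labels at 5 kb spacing
  for (i in seq_len(nrow(mols))) {
    if (mols$map_id[i] != truth_map$map_id) next
    spans <- tg[mols$src_start[i] < tg$start - margin & mols$src_end[i] > tg$end + margin, ]
    if (nrow(spans) == 0) next
    r <- ogmtopo:::classify_one(mols$labels[[i]], mols$length[i], meta, alignment_params())
    expect_equal(r$verdict, "informative", info = mols$molecule_id[i])
    expect_true(all(spans$signature %in% strsplit(r$signature, ",")[[1]]),
      info = mols$molecule_id[i]
    )
  }
})

test_that("a molecule with too few flank labels is not informative", {
  fx <- make_fixture("generic_alt2", seed = 6, coverage = 1, noise = quiet_noise())
  truth_map <- fx$genome_maps[[1]]
  tg <- truth_map$copies[truth_map$copies$target & truth_map$copies$abnormal, ][1, ]
  after <- truth_map$positions[truth_map$positions > tg$end]
  start <- tg$start - 60000
  end <- after[3] + 100 # exactly 3 labels beyond the copy
  lab <- truth_map$positions[truth_map$positions > start & truth_map$positions <= end] - start
  r <- classify_molecule(lab, end - start, fx$catalog)
  expect_false(r$verdict == "informative" &&
    tg$signature %in% strsplit(r$signature, ",")[[1]])
})

test_that("reference-context spans are reference-like, not informative", {
  fx <- make_fixture("generic_alt2", seed = 6, coverage = 1, noise = quiet_noise())
  ref_map <- fx$genome_maps[[which(vapply(fx$genome_maps, function(m) m$provenance == "reference", TRUE))]]
  d1 <- ref_map$copies[ref_map$copies$seg == "D1", ]
  start <- d1$start - 80000
  end <- d1$end + 80000
  lab <- ref_map$positions[ref_map$positions > start & ref_map$positions <= end] - start
  r <- classify_molecule(lab, end - start, fx$catalog)
  expect_equal(r$verdict, "reference_like")
})

test_that("classification is orientation-invariant", {
  fx <- make_fixture("generic_alt2", seed = 6, coverage = 8, noise = quiet_noise())
  meta <- ogmtopo:::catalog_meta(fx$catalog)
  mols <- fx$molecules[fx$molecules$length > 250000, ]
  for (i in seq_len(min(10, nrow(mols)))) {
    lab <- mols$labels[[i]]
    len <- mols$length[i]
    a <- ogmtopo:::classify_one(lab, len, meta, alignment_params())
    b <- ogmtopo:::classify_one(sort(len - lab), len, meta, alignment_params())
    expect_equal(a$verdict, b$verdict)
    expect_equal(a$signature, b$signature)
  }
})

test_that("raising the flank requirement never increases informative counts", {
  fx <- make_fixture("generic_alt2", seed = 12, coverage = 15)
  n_inf <- vapply(c(2, 4, 6, 8), function(k) {
    cs <- classify_set(fx$molecules, fx$candidates, fx$catalog, fx$config,
      params = alignment_params(min_flank_labels = k), min_length = 190000
    )
    sum(cs$records$verdict == "informative")
  }, 0)
  expect_true(all(diff(n_inf) <= 0))
})

test_that("the length pre-filter and empty input behave as documented", {
  fx <- make_fixture("generic_alt2", seed = 12, coverage = 4)
  cs <- classify_set(fx$molecules, fx$candidates, fx$catalog, fx$config,
    min_length = 300000
  )
  expect_equal(cs$n_classified, sum(fx$molecules$length >= 300000))
  cs0 <- classify_set(fx$molecules[0, ], fx$candidates, fx$catalog, fx$config)
  expect_true(all(cs0$counts$n_molecules == 0))
  expect_equal(nrow(cs0$records), 0)
})
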