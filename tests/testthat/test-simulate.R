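# Synthetic OGM data: label synthesis, map assembly, molecule sampling,
# and the CMAP/BNX text dialects.

test_that("motif scanning finds forward-strand occurrences", {
  expect_equal(scan_labels("AACTTAAGT", "CTTAAG"), 3L)
  expect_equal(scan_labels("ACGTACGT", "CTTAAG"), integer())
  expect_equal(scan_labels("AAAA", "AA"), c(1L, 2L, 3L)) # overlaps counted
  expect_error(scan_labels("ACGTX", "CTTAAG"), "non-ACGTN")
})

test_that("the spacing model is Poisson-consistent and seed-deterministic", {
  n <- vapply(1:30, function(s) {
    length(spacing_model_labels(1e6, 5000, 500, seed = s))
  }, 0)
  expected <- 1e6 / 5000
  # merging trims a few percent; stay within 3 sigma of the Poisson mean
  expect_lt(abs(mean(n) - expected * (1 - 0.09)), 3 * sqrt(expected / 30) + 5)
  expect_identical(
    spacing_model_labels(1e6, 5000, 500, seed = 7),
    spacing_model_labels(1e6, 5000, 500, seed = 7)
  )
  expect_equal(spacing_model_labels(0, 5000, 500, seed = 1), numeric())
  gaps <- diff(spacing_model_labels(1e6, 2000, 500, seed = 3))
  expect_true(all(gaps >= 500))
})

test_that("derivative map assembly reflects, shifts and merges labels", {
  seg <- parse_segments(paste(
    "id\tchrom\tstart\tend\tgain",
    "D\tchrA\t101\t200\t1",
    sep = "\n"
  ))
  cfg <- suppressWarnings(dup_config(
    seg,
    parse_junctions("id\tjunction\thomology_bp\nJ\t+D:+D\t0", seg),
    c(chrA = 300)
  ))
  labels <- list(NML_chrA_1 = c(10, 60), D = c(10, 50), NML_chrA_2 = numeric())
  rev_walk <- tibble::tibble(seg = "D", orient = -1L, adj_in = NA)
  st <- ogmtopo:::new_structure("revD", list(rev_walk), cfg)
  m <- assemble_derivative_map(st, cfg, labels, merge_distance = 0)[[1]]
  expect_equal(m$positions, c(51, 91)) # pos -> size - pos + 1
  expect_equal(m$length, 100)

  # full reference walk: lengths add, offsets shift
  ref_walk <- ogmtopo:::ref_walk(cfg$reference, "chrA")
  rst <- ogmtopo:::new_structure("ref", list(ref_walk), cfg)
  mr <- assemble_derivative_map(rst, cfg, labels, merge_distance = 0)[[1]]
  expect_equal(mr$length, 300)
  expect_equal(mr$positions, c(10, 60, 110, 150))

  # labels within the merge distance collapse to one
  labels2 <- list(NML_chrA_1 = c(95), D = c(5, 80), NML_chrA_2 = numeric())
  m2 <- assemble_derivative_map(rst, cfg, labels2, merge_distance = 50)[[1]]
  expect_equal(length(m2$positions), 2) # 95 and 105 merge
})

test_that("double reflection restores a label map", {
  pos <- c(10, 50, 70)
  len <- 100
  once <- sort(len - pos + 1)
  twice <- sort(len - once + 1)
  expect_equal(twice, pos)
})

test_that("molecule sampling hits the requested depth and truth metadata", {
  cfg <- generic_config()
  labels <- segment_label_registry(cfg, seed = 5)
  maps <- reference_maps(cfg, labels)
  lm <- length_model_geometric()
  mols <- sample_molecules(maps, coverage = 50, lm, noise_model(), seed = 9)
  depth <- sum(mols$length) / sum(vapply(maps, `[[`, 1, "length"))
  expect_lt(abs(depth - 50) / 50, 0.05)
  expect_true(all(mols$map_id %in% names(maps) | mols$map_id %in% vapply(maps, `[[`, "", "map_id")))
  again <- sample_molecules(maps, coverage = 50, lm, noise_model(), seed = 9)
  expect_identical(mols$labels, again$labels)
})

test_that("zero-noise molecules are exact windows of their source map", {
  cfg <- generic_config()
  labels <- segment_label_registry(cfg, seed = 5)
  maps <- reference_maps(cfg, labels)
  quiet <- noise_model(
    label_dropout_prob = 0, false_per_100kb = 0, sizing_cv = 0,
    chimera_prob = 0
  )
  mols <- sample_molecules(maps, coverage = 5, length_model_geometric(), quiet, seed = 3)
  m <- maps[[1]]
  for (i in seq_len(min(nrow(mols), 25))) {
    src <- m$positions[m$positions > mols$src_start[i] & m$positions <= mols$src_end[i]] -
      mols$src_start[i]
    got <- mols$labels[[i]]
    if (mols$reversed[i]) got <- sort(mols$length[i] - got)
    expect_equal(sort(got), sort(src), tolerance = 1e-8)
  }
})

test_that("chimera fraction and length-bin survival match their settings", {
  cfg <- generic_config()
  labels <- segment_label_registry(cfg, seed = 5)
  maps <- reference_maps(cfg, labels)
  nm <- noise_model(chimera_prob = 0.05)
  mols <- sample_molecules(maps, coverage = 120, length_model_geometric(survival = 0.5), nm, seed = 21)
  n <- nrow(mols)
  p_hat <- mean(mols$chimera)
  expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # per-bin survival of non-chimeric, non-truncated lengths
  plain <- mols$length[!mols$chimera]
  bd <- bin_decline(plain, 100000, 200000)
  declines <- bd$decline_pct[!is.na(bd$decline_pct)][1:3]
  expect_lt(abs(mean(declines) - 50), 15)
})

test_that("CMAP and BNX files round-trip through the minimal dialects", {
  cfg <- generic_config()
  labels <- segment_label_registry(cfg, seed = 5)
  maps <- reference_maps(cfg, labels)
  tmp <- tempfile(fileext = ".cmap")
  write_cmap(maps, tmp)
  back <- read_cmap(tmp)
  expect_length(back, length(maps))
  expect_equal(back[[1]]$positions, round(maps[[1]]$positions, 1))
  expect_equal(back[[1]]$length, round(maps[[1]]$length, 1))
  expect_equal(back[[1]]$map_id, maps[[1]]$map_id)
  # NumSites equals emitted site rows
  lines <- readLines(tmp)
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), sum(vapply(maps, function(m) length(m$positions), 0)))

  mols <- sample_molecules(maps, coverage = 2, length_model_geometric(), noise_model(), seed = 2)
  tmpb <- tempfile(fileext = ".bnx")
  write_bnx(mols[1:3, ], tmpb)
  mb <- read_bnx(tmpb)
  expect_equal(nrow(mb), 3)
  expect_equal(mb$labels[[2]], round(mols$labels[[2]], 1))

  # empty molecule set: header-only file, re-read as empty
  tmpe <- tempfile(fileext = ".bnx")
  write_bnx(mols[0, ], tmpe)
  expect_equal(nrow(read_bnx(tmpe)), 0)
})

test_that("fixtures are seed-deterministic and carry the declared truth", {
  d1 <- tempfile()
  d2 <- tempfile()
  fx1 <- make_fixture("tandem", seed = 4, coverage = 3, dir = d1)
  fx2 <- make_fixture("tandem", seed = 4, coverage = 3, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), info = f)
  }
  fx_c2 <- make_fixture("case2_like", seed = 1, coverage = 0.5)
  truth <- fx_c2$candidates[[fx_c2$truth]]
  expect_length(truth$haplotypes, 2) # the translocation structure
  expect_error(make_fixture("no_such_scenario"), "unknown scenario")
})
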