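# Self-contained synthetic scenarios: reduced-scale geometries that emulate
# the bundled case studies (maps kept under ~5 Mb so simulation and
# classification stay fast), with ground-truth structures for end-to-end
# testing. Scale reductions keep the qualitative size ordering of the
# originals (a small spannable duplication, a large hard-to-span one, a
# sub-resolution inverted sliver, an adjacent triplication block).

fixture_registry <- function() {
  list(
    generic_alt1 = list(mode = "archetype", truth = "Alt1", coverage = 40),
    generic_alt2 = list(mode = "archetype", truth = "Alt2", coverage = 40),
    generic_alt3 = list(mode = "archetype", truth = "Alt3", coverage = 40),
    tandem = list(mode = "archetype", truth = "Alt1", coverage = 30),
    case1_like = list(mode = "archetype", truth = "Alt1", coverage = 60),
    case2_like = list(mode = "archetype", truth = "Alt3", coverage = 50),
    case3_like = list(mode = "general_inherited", truth = NULL, coverage = 50)
  )
}

fixture_tables <- function(scenario) {
  switch(scenario,
    generic_alt1 = ,
    generic_alt2 = ,
    generic_alt3 = list(
      segments = paste(
        "id\tchrom\tstart\tend\tgain",
        "D1\tchrA\t600001\t800000\t1",
        "D2\tchrA\t1100001\t1250000\t1",
        sep = "\n"
      ),
      junctions = "id\tjunction\thomology_bp\nJ1\t+D1:+D2\t0\nJ2\t+D2:+D1\t0",
      lengths = c(chrA = 2000000)
    ),
    tandem = list(
      segments = "id\tchrom\tstart\tend\tgain\nD\tchrA\t900001\t1100000\t1",
      junctions = "id\tjunction\thomology_bp\nJ\t+D:+D\t0",
      lengths = c(chrA = 2000000)
    ),
    case1_like = list(
      segments = paste(
        "id\tchrom\tstart\tend\tgain",
        "E1\tchrB\t1000001\t1320000\t1",
        "E2\tchrB\t2000001\t2000148\t1",
        "E3\tchrB\t2400001\t2640000\t1",
        sep = "\n"
      ),
      junctions = paste(
        "id\tjunction\thomology_bp",
        "JE1\t+E1:-E2\t5", "JE2\t-E2:+E3\t0", "JE3\t+E3:+E1\t23",
        sep = "\n"
      ),
      lengths = c(chrB = 4000000)
    ),
    case2_like = list(
      segments = paste(
        "id\tchrom\tstart\tend\tgain",
        "FB\tchrC\t1500001\t3500000\t1",
        "FS\tchrD\t800001\t1100000\t1",
        sep = "\n"
      ),
      junctions = "id\tjunction\thomology_bp\nJF1\t+FB:+FS\t2\nJF2\t+FS:+FB\t0",
      lengths = c(chrC = 5000000, chrD = 2500000)
    ),
    case3_like = list(
      segments = paste(
        "id\tchrom\tstart\tend\tgain",
        "G1\tchrE\t500001\t800000\t1",
        "G2\tchrE\t2300001\t2500000\t1",
        "G3\tchrE\t2520001\t2720000\t1",
        "G4\tchrE\t2720001\t2780000\t2",
        "G5\tchrE\t2780001\t2810000\t1",
        sep = "\n"
      ),
      junctions = paste(
        "id\tjunction\thomology_bp",
        "JG1\t-G1:-G5\t38", "JG2\t+G2:-G1\t4", "JG3\t-G3:-G4\t0", "JG4\t-G4:+G2\t2",
        sep = "\n"
      ),
      lengths = c(chrE = 5000000)
    ),
    abort(sprintf("unknown scenario '%s'", scenario))
  )
}

#' Build a self-contained synthetic scenario
#'
#' Generates the full package of artefacts for one named scenario: the
#' configuration, the candidate structures, the ground-truth structure, per
#' -tile label sets, genome label maps (truth haplotypes plus unmodified
#' homologues), the candidate map catalog, and a noisy molecule set with
#' truth metadata. Deterministic given the seed (same seed, byte-identical
#' files when `dir` is written).
#'
#' @param scenario One of `generic_alt1`, `generic_alt2`, `generic_alt3`,
#'   `tandem`, `case1_like`, `case2_like`, `case3_like`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param coverage Fold-coverage (default: scenario registry value).
#' @param length_model A `length_model` (default geometric, survival 0.5,
#'   minimum 150 kb).
#' @param noise A `noise_model`.
#' @param mean_spacing Mean label spacing (bp, default 5000).
#' @param resolution_bp Signature resolution (default 500).
#' @param dir Optional directory: writes `segments.tsv`, `junctions.tsv`,
#'   `ref_<chrom>.cmap`, `alt_<label>.cmap`, `molecules.bnx`, `truth.json`.
#' @return A list of class `ogm_fixture` with elements `scenario`, `config`,
#'   `candidates`, `truth`, `labels`, `genome_maps`, `catalog`,
#'   `molecules`, `params`.
#' @export
make_fixture <- function(scenario, seed = 1, coverage = NULL,
                         length_model = length_model_geometric(),
                         noise = noise_model(), mean_spacing = 5000,
                         resolution_bp = 500, dir = NULL) {
  reg <- fixture_registry()
  if (!scenario %in% names(reg)) {
    abort(sprintf("unknown scenario '%s'", scenario))
  }
  info <- reg[[scenario]]
  tabs <- fixture_tables(scenario)
  segments <- parse_segments(tabs$segments)
  junctions <- parse_junctions(tabs$junctions, segments)
  config <- dup_config(segments, junctions, tabs$lengths)
  candidates <- if (info$mode == "archetype") {
    enumerate_archetype(config, resolution_bp = resolution_bp)
  } else {
    enumerate_general(config, forbid_same_chromosome_pair = TRUE)
  }
  truth_label <- info$truth %||% case3_like_truth(candidates)
  truth <- candidates[[truth_label]]
  labels <- segment_label_registry(
    config, mean_spacing, noise$merge_distance,
    seed = derive_seed(seed, paste0(scenario, "_labels"))
  )
  genome_maps <- genome_maps_for(truth, config, labels, noise$merge_distance, resolution_bp)
  catalog <- candidate_maps(candidates, config, labels, noise$merge_distance, resolution_bp)
  coverage <- coverage %||% info$coverage
  molecules <- sample_molecules(
    genome_maps, coverage, length_model, noise,
    seed = derive_seed(seed, paste0(scenario, "_molecules"))
  )
  fx <- structure(
    list(
      scenario = scenario, config = config, candidates = candidates,
      truth = truth_label, labels = labels, genome_maps = genome_maps,
      catalog = catalog, molecules = molecules,
      params = list(
        seed = seed, coverage = coverage, mean_spacing = mean_spacing,
        resolution_bp = resolution_bp, noise = unclass(noise),
        length_model = unclass(length_model)
      )
    ),
    class = "ogm_fixture"
  )
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

# Truth pick for the chromoanasynthesis-like scenario: the structure with
# the large distal duplication copy inverted but the middle copy-neutral
# region in reference orientation, mirroring the resolved real-data analogue.
case3_like_truth <- function(candidates) {
  for (st in candidates) {
    h <- st$haplotypes[[1]]
    g1_inv <- any(h$seg == "G1" & h$orient < 0)
    mid_fwd <- all(h$orient[h$seg == "NML_chrE_2"] > 0)
    if (g1_inv && mid_fwd) {
      return(st$label)
    }
  }
  candidates[[1]]$label
}

# Maps of the true genome: the truth structure's haplotypes (weight 1) plus
# reference maps weighted by the unmodified homologue count.
genome_maps_for <- function(truth, config, labels, merge_distance, resolution_bp) {
  ref <- config$reference
  mod <- assemble_derivative_map(truth, config, labels, merge_distance, resolution_bp)
  h_by_chrom <- table(vapply(
    truth$haplotypes,
    function(h) ref$chrom[match(h$seg[1], ref$id)], ""
  ))
  refs <- reference_maps(config, labels, merge_distance, resolution_bp)
  refs <- purrr::imap(refs, function(m, nm) {
    ch <- sub("^ref_", "", nm)
    m$weight <- 2 - (if (ch %in% names(h_by_chrom)) h_by_chrom[[ch]] else 0)
    m
  })
  refs <- refs[vapply(refs, function(m) m$weight > 0, TRUE)]
  c(mod, unname(refs))
}

#' @export
print.ogm_fixture <- function(x, ...) {
  cat(
    "<ogm_fixture> ", x$scenario, ": truth ", x$truth, ", ",
    length(x$candidates), " candidate(s), ", nrow(x$molecules),
    " molecule(s)\n",
    sep = ""
  )
  invisible(x)
}

write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(fx$config$segments, file.path(dir, "segments.tsv"))
  jn <- fx$config$junctions
  writeLines(
    c(
      "id\tjunction\thomology_bp\tnote",
      sprintf("%s\t%s\t%d\t%s", jn$id, jn$junction, as.integer(jn$homology_bp), jn$note)
    ),
    file.path(dir, "junctions.tsv")
  )
  refs <- fx$genome_maps[vapply(fx$genome_maps, function(m) m$provenance == "reference", TRUE)]
  if (length(refs) > 0) write_cmap(refs, file.path(dir, "ref.cmap"))
  for (st in fx$candidates) {
    mm <- fx$catalog[vapply(fx$catalog, function(m) st$label %in% attr(m, "structures"), TRUE)]
    if (length(mm) > 0) {
      write_cmap(mm, file.path(dir, sprintf("alt_%s.cmap", st$label)))
    }
  }
  write_bnx(fx$molecules, file.path(dir, "molecules.bnx"))
  truth <- list(
    scenario = fx$scenario, truth = fx$truth, params = fx$params,
    candidates = lapply(unclass(fx$candidates), function(st) {
      list(label = st$label, key = st$key)
    }),
    molecules = fx$molecules[, c(
      "molecule_id", "length", "map_id", "src_start", "src_end",
      "reversed", "chimera", "chimera_map_id"
    )]
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
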