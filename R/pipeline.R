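# End-to-end pipeline (enumerate -> signatures -> classify -> resolve ->
# power), flat-file run configuration, and ASCII structure rendering.

#' Run the full resolution pipeline on a fixture
#'
#' Composes the stages end to end: candidate enumeration (already carried by
#' the fixture), signature derivation, molecule classification, structure
#' resolution, and a spanning-power table across duplication sizes. When
#' `out_dir` is given, writes `structures.json`, `signatures.tsv`,
#' `matrix.json`, `counts.tsv`, `report.json`, `power.tsv` and
#' `pipeline.log`.
#'
#' @param fixture An `ogm_fixture` from [make_fixture()], or a scenario name
#'   (built with `seed`).
#' @param out_dir Optional output directory.
#' @param params An `alignment_params`.
#' @param min_length Length pre-filter for classification (bp).
#' @param min_support Exclusion threshold for [resolve_structures()].
#' @param seed Seed used when `fixture` is a scenario name.
#' @return A list of class `dup_report`: `fixture`, `signatures`,
#'   `diagnostic`, `counts`, `resolution`, `power`, `recovered` (logical:
#'   supported set equals the truth uniquely).
#' @export
run_pipeline <- function(fixture, out_dir = NULL, params = alignment_params(),
                         min_length = 0, min_support = 1, seed = 1) {
  if (is.character(fixture)) fixture <- make_fixture(fixture, seed = seed)
  config <- fixture$config
  candidates <- fixture$candidates
  res_bp <- fixture$params$resolution_bp
  sigs <- purrr::map_dfr(candidates, derive_signatures,
    config = config, resolution_bp = res_bp
  )
  diag <- diagnostic_matrix(candidates, config, res_bp)
  counts <- classify_set(
    fixture$molecules, candidates, fixture$catalog, config,
    params = params, min_length = min_length, resolution_bp = res_bp
  )
  resolution <- resolve_structures(
    counts$counts, candidates, config,
    resolution_bp = res_bp, min_support = min_support
  )
  lens <- fixture$molecules$length
  lm <- length_model_geometric(
    survival = fixture$params$length_model$survival,
    min_bp = fixture$params$length_model$min_bp,
    bin_bp = fixture$params$length_model$bin_bp
  )
  dgrid <- seq(50000, 1000000, by = 50000)
  power <- purrr::map_dfr(dgrid, function(D) {
    expected_spanning(
      D,
      F_bp = params$min_flank_labels * fixture$params$mean_spacing,
      molecules = lm, genome_length = sum(vapply(fixture$genome_maps, `[[`, 1, "length")),
      n_molecules = nrow(fixture$molecules)
    )
  })
  recovered <- identical(resolution$supported, fixture$truth)
  report <- structure(
    list(
      fixture = fixture, signatures = sigs, diagnostic = diag,
      counts = counts, resolution = resolution, power = power,
      recovered = recovered
    ),
    class = "dup_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.dup_report <- function(x, ...) {
  cat("<dup_report> scenario ", x$fixture$scenario, "\n", sep = "")
  print(x$resolution)
  cat("  truth: ", x$fixture$truth, " (recovered: ", x$recovered, ")\n", sep = "")
  invisible(x)
}

#' @method glance dup_report
#' @export
glance.dup_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(scenario = x$fixture$scenario, truth = x$fixture$truth, recovered = x$recovered),
    glance(x$resolution)
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- report$fixture
  jsonlite::write_json(
    lapply(unclass(fx$candidates), function(st) {
      list(
        label = st$label, key = st$key,
        haplotypes = lapply(st$haplotypes, function(h) as.list(as.data.frame(h)))
      )
    }),
    file.path(out_dir, "structures.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  sig <- report$signatures
  writeLines(
    c(
      "label\tsignature\ttarget\tsize",
      sprintf("%s\t%s\t%s\t%d", sig$label, sig$signature, sig$target, as.integer(sig$size))
    ),
    file.path(out_dir, "signatures.tsv")
  )
  jsonlite::write_json(
    report$diagnostic$matrix, file.path(out_dir, "matrix.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  ct <- report$counts$counts
  writeLines(
    c(
      "signature\ttarget\tsize\tn_molecules",
      sprintf("%s\t%s\t%s\t%d", ct$signature, ct$target, ct$size, ct$n_molecules)
    ),
    file.path(out_dir, "counts.tsv")
  )
  res <- report$resolution
  jsonlite::write_json(
    list(
      supported = res$supported, contradictory = res$contradictory,
      status = res$status %>% mutate(missing_signatures = purrr::map_chr(
        .data$missing_signatures, paste,
        collapse = ","
      )),
      truth = fx$truth, recovered = report$recovered
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  pw <- report$power
  writeLines(
    c(
      "D\tF_bp\tS\texpected_count",
      sprintf("%d\t%d\t%d\t%.4f", as.integer(pw$D), as.integer(pw$F_bp), as.integer(pw$S), pw$expected_count)
    ),
    file.path(out_dir, "power.tsv")
  )
  writeLines(
    c(
      sprintf("ogmtopo %s", as.character(utils::packageVersion("ogmtopo"))),
      sprintf("scenario: %s", fx$scenario),
      sprintf("seed: %d", fx$params$seed),
      sprintf("coverage: %s", fx$params$coverage),
      sprintf("molecules: %d", nrow(fx$molecules)),
      sprintf("supported: %s", paste(res$supported, collapse = ","))
    ),
    file.path(out_dir, "pipeline.log")
  )
  invisible(out_dir)
}

#' Read a flat key=value run configuration
#'
#' Lines of `key = value` (or `key: value`); `#` comments and blank lines
#' ignored. Values that parse as numbers become numeric.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^\\s*([^=:]+?)\\s*[=:]\\s*(.*?)\\s*$", l))[[1]]
    if (length(m) != 3) {
      abort(sprintf("malformed config line: '%s'", l))
    }
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Render a structure as an ASCII cartoon
#'
#' One line per haplotype: copies as labelled blocks in walk order, reverse
#' copies marked with `<`, junction adjacencies marked with `*`.
#'
#' @param structure A `dup_structure`.
#' @param collapse_nml Shorten copy-neutral tile names to `NML` (default
#'   TRUE).
#' @return Character vector of lines (also printed invisibly via `cat` when
#'   interactive printing is desired).
#' @export
render_structure <- function(structure, collapse_nml = TRUE) {
  lines <- vapply(seq_along(structure$haplotypes), function(i) {
    h <- structure$haplotypes[[i]]
    nm <- h$seg
    if (collapse_nml) nm <- sub("^NML_[^_]+_[0-9]+$", "NML", nm)
    blocks <- sprintf(
      "%s[%s%s]",
      ifelse(!is.na(h$adj_in) & h$adj_in != "ref", "*", ""),
      nm, ifelse(h$orient < 0, "<", ">")
    )
    paste0(structure$label, " hap", i, ": ", paste(blocks, collapse = "-"))
  }, "")
  lines
}
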