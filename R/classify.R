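# Classification of molecules against candidate structure maps under the
# informative-molecule criterion: a molecule is informative for a spanning
# signature only if its best placement completely spans a duplicated-segment
# copy with at least `min_flank_labels` matched labels on each flank, and
# the reference (NML) pattern appears on at most one flank (copies with
# reference context on both sides are reference-like, not informative).

#' Build the candidate map catalog for classification
#'
#' Assembles one label map per candidate-structure haplotype plus the
#' reference chromosome maps, deduplicating identical maps, and carries each
#' map's annotated copy intervals (abnormal copies with their signatures,
#' native copies for reference-like detection).
#'
#' @param structures A `dup_structure_set` of candidates.
#' @param config A `dup_config`.
#' @param labels Per-tile label registry ([segment_label_registry()]).
#' @param merge_distance Label merge distance (bp).
#' @param resolution_bp Resolution for signature annotation.
#' @return A list of `label_map`s, each with a `structures` attribute listing
#'   the candidate labels it belongs to (`character(0)` for reference maps).
#' @export
candidate_maps <- function(structures, config = set_config(structures),
                           labels, merge_distance = 500, resolution_bp = 500) {
  maps <- list()
  digests <- character()
  add <- function(m, label) {
    dg <- paste(round(m$positions), collapse = ",")
    hit <- match(dg, digests)
    if (!is.na(hit)) {
      st <- attr(maps[[hit]], "structures")
      attr(maps[[hit]], "structures") <<- unique(c(st, label))
      return(invisible())
    }
    attr(m, "structures") <- label
    digests <<- c(digests, dg)
    maps[[length(maps) + 1]] <<- m
    invisible()
  }
  for (m in reference_maps(config, labels, merge_distance, resolution_bp)) {
    add(m, character(0))
  }
  for (st in structures) {
    for (m in assemble_derivative_map(st, config, labels, merge_distance, resolution_bp)) {
      add(m, st$label)
    }
  }
  maps
}

#' Classify one molecule against the candidate maps
#'
#' Aligns the molecule to every catalog map in both orientations, keeps
#' placements within the ambiguity margin of the best, and applies the
#' informative-molecule criterion. Verdicts: `informative` (exactly one
#' abnormal signature spanned with enough flank labels on both sides),
#' `reference_like` (a native copy spanned, reference context both sides),
#' `uninformative` (no confident or an ambiguous placement), or
#' `chimera_suspect` (anomalous label density).
#'
#' @param labels,length Molecule label positions and length.
#' @param maps Catalog from [candidate_maps()].
#' @param params An `alignment_params`.
#' @return A one-row tibble: `verdict`, `signature`, `map_id`, `score`,
#'   `n_matched`, `left_flank`, `right_flank`, `note`.
#' @export
classify_molecule <- function(labels, length, maps, params = alignment_params()) {
  r <- classify_one(labels, length, catalog_meta(maps), params)
  tibble(
    verdict = r$verdict, signature = r$signature, map_id = r$map_id,
    score = r$score, n_matched = r$n_matched,
    left_flank = r$left_flank, right_flank = r$right_flank, note = r$note
  )
}

# Precomputed per-catalog lookups shared across molecules.
catalog_meta <- function(maps) {
  list(
    maps = maps,
    map_ids = vapply(maps, `[[`, "", "map_id"),
    density = max(vapply(maps, function(m) length(m$positions) / m$length, 1)),
    targets = lapply(maps, function(m) {
      if (is.null(m$copies)) {
        return(NULL)
      }
      tg <- m$copies[m$copies$target, , drop = FALSE]
      if (nrow(tg) == 0) NULL else tg
    })
  )
}

# Lean classification core (base R, no tibble churn).
classify_one <- function(labels, length, meta, params) {
  rec <- function(verdict, signature = NA_character_, map_id = NA_character_,
                  score = NA_real_, n_matched = NA_integer_,
                  left_flank = NA_integer_, right_flank = NA_integer_,
                  note = "") {
    list(
      verdict = verdict, signature = signature, map_id = map_id,
      score = score, n_matched = n_matched,
      left_flank = left_flank, right_flank = right_flank, note = note
    )
  }
  nlab <- base::length(labels)
  if (nlab < params$min_aligned_labels) {
    return(rec("uninformative", note = "too few labels"))
  }
  # chimera heuristic: global or windowed label density far above map density
  if (nlab / length > params$chimera_density_factor * meta$density ||
    max_window_density(labels, params$chimera_window) >
      params$chimera_density_factor * meta$density) {
    return(rec("chimera_suspect", note = "label density anomaly"))
  }
  rev_lab <- sort(length - labels)
  min_score <- params$score_frac * nlab
  hits <- list()
  for (mi in seq_along(meta$maps)) {
    m <- meta$maps[[mi]]
    for (o in c(1L, -1L)) {
      h <- align_dp_cpp(
        if (o > 0) labels else rev_lab, m$positions,
        params$match_bonus, params$interval_weight,
        params$miss_penalty, params$extra_penalty, as.integer(params$band)
      )
      n <- base::length(h$mol_idx)
      if (n >= params$min_aligned_labels && is.finite(h$score) &&
        h$score >= min_score) {
        hits[[base::length(hits) + 1]] <- list(
          mi = mi, score = h$score, n = n, ref_idx = h$ref_idx,
          mol_pos = (if (o > 0) labels else rev_lab)[h$mol_idx],
          first_i = h$mol_idx[1], last_i = h$mol_idx[n]
        )
      }
    }
  }
  if (base::length(hits) == 0) {
    return(rec("uninformative", note = "no placement above threshold"))
  }
  # split-alignment chimera check: the best placement leaves a long run of
  # molecule labels unexplained at one end (two molecules read as one align
  # as one fragment plus a dangling label block)
  gb <- hits[[which.max(vapply(hits, `[[`, 1, "score"))]]
  end_gap <- max(gb$first_i - 1L, nlab - gb$last_i)
  if (end_gap >= max(8, ceiling(0.2 * nlab))) {
    return(rec("chimera_suspect",
      map_id = meta$map_ids[gb$mi], score = gb$score, n_matched = gb$n,
      note = "split alignment: unexplained label block at molecule end"
    ))
  }
  if (has_interval_break(gb, meta$maps[[gb$mi]]$positions)) {
    return(rec("chimera_suspect",
      map_id = meta$map_ids[gb$mi], score = gb$score, n_matched = gb$n,
      note = "gross interval disagreement inside the alignment (join artefact)"
    ))
  }
  scores <- vapply(hits, `[[`, 1, "score")
  best <- max(scores)
  near <- hits[scores >= best * (1 - params$ambiguity_margin)]
  # one reading per near-best placement: the abnormal signatures of the
  # copies it fully spans with enough matched flank labels (a long molecule
  # may legitimately span several), "REF" when only native copies are
  # spanned, "NONE" when the placement explains the molecule without
  # spanning any copy. All near-best readings must agree: a molecule whose
  # labels are explained almost as well without the abnormal copy is not
  # distinctively matched.
  readings <- list()
  for (h in near) {
    if (h$n < params$min_matched_frac * nlab) next
    if (h$score < params$min_score_per_match * h$n) next
    if (has_interval_break(h, meta$maps[[h$mi]]$positions)) next
    tg <- meta$targets[[h$mi]]
    sigs <- character()
    n_spanned <- 0L
    minlf <- NA_integer_
    minrf <- NA_integer_
    if (!is.null(tg)) {
      ref_pos <- meta$maps[[h$mi]]$positions[h$ref_idx]
      for (k in seq_len(nrow(tg))) {
        lf <- sum(ref_pos < tg$start[k])
        rf <- sum(ref_pos > tg$end[k])
        if (lf >= params$min_flank_labels && rf >= params$min_flank_labels) {
          n_spanned <- n_spanned + 1L
          minlf <- min(minlf, lf, na.rm = TRUE)
          minrf <- min(minrf, rf, na.rm = TRUE)
          if (tg$abnormal[k]) sigs <- c(sigs, tg$signature[k])
        }
      }
    }
    sigs <- sort(unique(sigs))
    key <- if (base::length(sigs) > 0) {
      paste(sigs, collapse = ",")
    } else if (n_spanned > 0) "REF" else "NONE"
    readings[[base::length(readings) + 1]] <- list(
      map_id = meta$map_ids[h$mi], score = h$score, n = h$n,
      sigs = sigs, key = key, lf = minlf, rf = minrf
    )
  }
  bi <- which.max(scores)
  if (base::length(readings) == 0) {
    return(rec("uninformative",
      map_id = meta$map_ids[hits[[bi]]$mi], score = best,
      n_matched = hits[[bi]]$n, note = "no reliable placement"
    ))
  }
  keys <- unique(vapply(readings, `[[`, "", "key"))
  if (base::length(keys) > 1) {
    return(rec("uninformative",
      map_id = readings[[1]]$map_id, score = best,
      note = "ambiguous: near-best placements imply discordant readings"
    ))
  }
  r1 <- readings[[which.max(vapply(readings, `[[`, 1, "score"))]]
  if (keys == "NONE") {
    return(rec("uninformative",
      map_id = r1$map_id, score = r1$score, n_matched = r1$n,
      note = "no copy fully spanned with flanks"
    ))
  }
  if (keys == "REF") {
    return(rec("reference_like",
      map_id = r1$map_id, score = r1$score, n_matched = r1$n,
      left_flank = r1$lf, right_flank = r1$rf
    ))
  }
  rec("informative",
    signature = r1$key, map_id = r1$map_id,
    score = r1$score, n_matched = r1$n, left_flank = r1$lf, right_flank = r1$rf
  )
}

# A chimeric join shows up either as one matched transition whose molecule
# and map intervals disagree grossly (large both in absolute bp and relative
# terms), or as a cluster of moderate absolute disagreements where the
# aligner smeared the join over several transitions. Both are far beyond
# sizing noise (a few percent per interval) or label-merge displacement
# (half the merge distance).
has_interval_break <- function(hit, map_positions, abs_bp = 2000, rel = 0.5,
                               cluster_bp = 1500, cluster_n = 3,
                               cluster_window = 10) {
  if (hit$n < 2) {
    return(FALSE)
  }
  dm <- diff(hit$mol_pos)
  dr <- diff(map_positions[hit$ref_idx])
  dev <- abs(dm - dr)
  if (any(dev > abs_bp & dev / pmax(dr, 500) > rel)) {
    return(TRUE)
  }
  bad <- as.integer(dev > cluster_bp)
  if (sum(bad) < cluster_n) {
    return(FALSE)
  }
  w <- min(cluster_window, length(bad))
  cs <- cumsum(bad)
  sums <- cs[w:length(bad)] - c(0, cs)[seq_len(length(bad) - w + 1)]
  any(sums >= cluster_n)
}

max_window_density <- function(labels, window) {
  if (length(labels) == 0) {
    return(0)
  }
  labels <- sort(labels)
  n <- length(labels)
  j <- 1
  bestn <- 0
  for (i in seq_len(n)) {
    while (labels[i] - labels[j] > window) j <- j + 1
    bestn <- max(bestn, i - j + 1)
  }
  bestn / window
}

#' Classify a molecule set and tally signature support
#'
#' Applies [classify_molecule()] to each molecule (optionally after a
#' molecule-length pre-filter, the analogue of down-sampling to long
#' molecules) and tallies informative molecules per signature class.
#'
#' @param molecules An `ogm_molecules` tibble.
#' @param structures Candidate `dup_structure_set`.
#' @param maps Catalog from [candidate_maps()].
#' @param config A `dup_config`.
#' @param params An `alignment_params`.
#' @param min_length Molecules shorter than this (bp) are dropped before
#'   classification (default 0 = keep all).
#' @param resolution_bp Resolution for the signature class table.
#' @return A list of class `dup_counts`: `counts` (tibble `signature`,
#'   `target`, `size`, `n_molecules`, covering every abnormal class of every
#'   candidate, zeros included), `records` (per-molecule verdicts),
#'   `tallies` (verdict totals).
#' @export
classify_set <- function(molecules, structures, maps,
                         config = set_config(structures),
                         params = alignment_params(), min_length = 0,
                         resolution_bp = 500) {
  keep <- molecules$length >= min_length
  mol <- molecules[keep, , drop = FALSE]
  meta <- catalog_meta(maps)
  recs <- lapply(seq_len(nrow(mol)), function(i) {
    classify_one(mol$labels[[i]], mol$length[i], meta, params)
  })
  records <- tibble(
    molecule_id = mol$molecule_id, length = mol$length,
    verdict = vapply(recs, `[[`, "", "verdict"),
    signature = vapply(recs, `[[`, "", "signature"),
    map_id = vapply(recs, `[[`, "", "map_id"),
    score = vapply(recs, `[[`, 1, "score"),
    n_matched = vapply(recs, function(r) as.integer(r$n_matched), 1L),
    left_flank = vapply(recs, function(r) as.integer(r$left_flank), 1L),
    right_flank = vapply(recs, function(r) as.integer(r$right_flank), 1L),
    note = vapply(recs, `[[`, "", "note")
  )
  classes <- purrr::map_dfr(structures, derive_signatures,
    config = config, resolution_bp = resolution_bp
  ) %>%
    distinct(.data$signature, .data$target, .data$size)
  if (nrow(records) > 0) {
    # a molecule spanning several abnormal copies supports several classes
    obs <- records %>%
      filter(.data$verdict == "informative") %>%
      tidyr::separate_longer_delim("signature", delim = ",") %>%
      dplyr::count(.data$signature, name = "n_molecules")
  } else {
    obs <- tibble(signature = character(), n_molecules = integer())
  }
  counts <- classes %>%
    left_join(obs, by = "signature") %>%
    mutate(n_molecules = ifelse(is.na(.data$n_molecules), 0L, .data$n_molecules)) %>%
    arrange(.data$size, .data$signature)
  # observed classes absent from every candidate still count as observations
  extra <- setdiff(obs$signature, counts$signature)
  if (length(extra) > 0) {
    counts <- bind_rows(counts, obs %>%
      filter(.data$signature %in% extra) %>%
      mutate(target = NA_character_, size = NA_real_))
  }
  tallies <- if (nrow(records) > 0) {
    records %>% dplyr::count(.data$verdict, name = "n")
  } else {
    tibble(verdict = character(), n = integer())
  }
  structure(
    list(
      counts = counts, records = records, tallies = tallies,
      min_length = min_length, n_input = nrow(molecules), n_classified = nrow(mol)
    ),
    class = "dup_counts"
  )
}

#' @export
print.dup_counts <- function(x, ...) {
  cat(
    "<dup_counts> ", x$n_classified, " molecule(s) classified",
    if (x$min_length > 0) sprintf(" (length >= %s bp)", format(x$min_length, big.mark = ",")),
    "\n",
    sep = ""
  )
  print(x$counts)
  if (nrow(x$tallies) > 0) {
    cat("verdicts: ", paste(x$tallies$verdict, x$tallies$n, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy dup_counts
#' @export
tidy.dup_counts <- function(x, ...) x$counts

#' @method glance dup_counts
#' @export
glance.dup_counts <- function(x, ...) {
  inf <- sum(x$counts$n_molecules)
  tibble(
    n_molecules = x$n_classified, n_informative = inf,
    n_signature_classes = nrow(x$counts),
    n_observed_classes = sum(x$counts$n_molecules > 0)
  )
}
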