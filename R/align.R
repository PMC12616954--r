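# Molecule-to-map alignment wrapper around the banded DP, plus the
# exhaustive placement oracle used in tests.

#' Alignment and classification parameters
#'
#' @param match_bonus Score for a matched label pair.
#' @param interval_weight Penalty weight on the relative difference of the
#'   matched inter-label intervals.
#' @param miss_penalty Penalty per skipped map label inside the alignment.
#' @param extra_penalty Penalty per unmatched molecule label.
#' @param band Maximum number of consecutive skipped labels considered on
#'   either sequence.
#' @param min_aligned_labels Minimum matched labels for a usable placement.
#' @param score_frac Minimum score as a fraction of the molecule label count.
#' @param ambiguity_margin Placements within this fractional score margin of
#'   the best are treated as equally plausible.
#' @param min_flank_labels Minimum matched labels on each flank of a spanned
#'   copy for the molecule to be informative (default 4).
#' @param min_matched_frac Minimum fraction of the molecule's labels matched
#'   for a placement to support an informative reading (default 0.75).
#' @param min_score_per_match Minimum score per matched label for a
#'   placement to support a reading (default 0.65); clean placements score
#'   near the match bonus per label, composite (chimeric) ones well below.
#' @param chimera_density_factor Flag molecules whose label density exceeds
#'   this multiple of the densest map's density.
#' @param chimera_window Window (bp) for the local density check.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(match_bonus = 1, interval_weight = 3,
                             miss_penalty = 0.5, extra_penalty = 0.5,
                             band = 5, min_aligned_labels = 6,
                             score_frac = 0.25, ambiguity_margin = 0.05,
                             min_flank_labels = 4,
                             min_matched_frac = 0.75,
                             min_score_per_match = 0.65,
                             chimera_density_factor = 3,
                             chimera_window = 50000) {
  stopifnot(
    match_bonus > 0, interval_weight >= 0, miss_penalty >= 0,
    extra_penalty >= 0, band >= 1, min_flank_labels >= 0
  )
  structure(
    list(
      match_bonus = match_bonus, interval_weight = interval_weight,
      miss_penalty = miss_penalty, extra_penalty = extra_penalty,
      band = band, min_aligned_labels = min_aligned_labels,
      score_frac = score_frac, ambiguity_margin = ambiguity_margin,
      min_flank_labels = min_flank_labels,
      min_matched_frac = min_matched_frac,
      min_score_per_match = min_score_per_match,
      chimera_density_factor = chimera_density_factor,
      chimera_window = chimera_window
    ),
    class = "alignment_params"
  )
}

#' Align a molecule to a label map
#'
#' Runs the banded dynamic program in both molecule orientations and
#' returns placements ordered best-first. Scores reward matched label pairs
#' by inter-label interval agreement and penalize skipped map labels and
#' unmatched molecule labels; the molecule aligns near-globally, the map
#' end-free.
#'
#' @param labels Numeric molecule label positions (bp from molecule start).
#' @param length Molecule length (bp).
#' @param map A `label_map`.
#' @param params An `alignment_params`.
#' @param both_orientations Evaluate the reversed molecule too (default).
#' @return A tibble: `map_id`, `orientation` (+1/-1), `score`, `n_matched`,
#'   `map_start`, `map_end`, `mol_idx` and `ref_idx` (list-columns of
#'   matched indices, molecule indices in the orientation used), ordered by
#'   decreasing score; zero rows when nothing aligns above the thresholds.
#' @export
align_molecule <- function(labels, length, map, params = alignment_params(),
                           both_orientations = TRUE) {
  orientations <- if (both_orientations) c(1L, -1L) else 1L
  rows <- lapply(orientations, function(o) {
    lab <- if (o > 0) labels else sort(length - labels)
    hit <- align_dp_cpp(
      lab, map$positions, params$match_bonus, params$interval_weight,
      params$miss_penalty, params$extra_penalty, as.integer(params$band)
    )
    n <- length(hit$mol_idx)
    if (n == 0 || !is.finite(hit$score)) {
      return(NULL)
    }
    tibble(
      map_id = map$map_id, orientation = o, score = hit$score, n_matched = n,
      map_start = map$positions[hit$ref_idx[1]],
      map_end = map$positions[hit$ref_idx[n]],
      mol_idx = list(hit$mol_idx), ref_idx = list(hit$ref_idx)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(out)
  }
  out <- out[out$n_matched >= params$min_aligned_labels &
    out$score >= params$score_frac * max(length(labels), 1), , drop = FALSE]
  out[order(-out$score, out$map_start), , drop = FALSE]
}

# Exhaustive placement oracle: best score over every monotone matching of
# molecule labels to map labels under the same scoring. Exponential; for
# tests on small instances only.
align_exhaustive <- function(labels, map_positions, params = alignment_params()) {
  M <- length(labels)
  N <- length(map_positions)
  best <- -Inf
  rec <- function(i, j, score, last_i, last_j) {
    # i: next molecule label to consider (1-based); all labels < i decided
    if (i > M) {
      best <<- max(best, score)
      return()
    }
    # skip molecule label i
    rec(i + 1, j, score - params$extra_penalty, last_i, last_j)
    # or match it to any map label > last_j
    for (jj in seq_len(N)) {
      if (jj <= last_j) next
      gain <- if (last_i == 0) {
        params$match_bonus
      } else {
        dm <- labels[i] - labels[last_i]
        dr <- map_positions[jj] - map_positions[last_j]
        rel <- abs(dm - dr) / max(dr, 500)
        params$match_bonus - params$interval_weight * rel -
          params$miss_penalty * (jj - last_j - 1)
      }
      rec(i + 1, jj, score + gain, i, jj)
    }
  }
  rec(1, 0, 0, 0, 0)
  best
}
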