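# Synthetic OGM molecules: windows of source label maps with label dropout,
# false labels, per-interval sizing noise, random read direction and
# occasional chimeric joins, with full truth metadata.

#' Molecule noise model
#'
#' Defaults emulate routine optical-map single-molecule behaviour: 10
#' percent label dropout, 0.8 false labels per 100 kb, 2 percent sizing
#' error per inter-label interval, 1 percent chimeric molecules, 500 bp
#' label merge distance. These are declared assumptions of the generator
#' (tunable), not measured instrument constants.
#'
#' @param label_dropout_prob Per-label dropout probability.
#' @param false_per_100kb False (spurious) labels per 100 kb of molecule.
#' @param sizing_cv Fractional sizing error per inter-label interval.
#' @param chimera_prob Probability a molecule is a chimera of two fragments.
#' @param merge_distance Minimum resolvable label separation (bp).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(label_dropout_prob = 0.10, false_per_100kb = 0.8,
                        sizing_cv = 0.02, chimera_prob = 0.01,
                        merge_distance = 500) {
  stopifnot(
    label_dropout_prob >= 0, label_dropout_prob <= 1,
    false_per_100kb >= 0, sizing_cv >= 0,
    chimera_prob >= 0, chimera_prob <= 1, merge_distance >= 0
  )
  structure(
    list(
      label_dropout_prob = label_dropout_prob, false_per_100kb = false_per_100kb,
      sizing_cv = sizing_cv, chimera_prob = chimera_prob,
      merge_distance = merge_distance
    ),
    class = "noise_model"
  )
}

# One raw fragment: a window of a source map with noise applied.
# Returns list(length, labels, truth fields).
draw_fragment <- function(maps, weights, lengths, length_model, noise) {
  i <- sample.int(length(maps), 1, prob = weights * lengths)
  map <- maps[[i]]
  L0 <- draw_lengths(length_model, 1)
  start <- runif(1, 0, max(map$length - 1, 1))
  end <- min(start + L0, map$length)
  len <- end - start
  lab <- map$positions[map$positions > start & map$positions <= end] - start
  # dropout
  if (length(lab) > 0 && noise$label_dropout_prob > 0) {
    keep <- runif(length(lab)) >= noise$label_dropout_prob
    lab <- lab[keep]
  }
  # false labels
  nf <- rpois(1, noise$false_per_100kb * len / 1e5)
  if (nf > 0) lab <- sort(c(lab, runif(nf, 0, len)))
  # per-interval sizing noise (stretches the whole coordinate system)
  if (noise$sizing_cv > 0 && length(lab) > 0) {
    pts <- c(0, lab, len)
    d <- diff(pts)
    d <- pmax(d * (1 + rnorm(length(d), 0, noise$sizing_cv)), 1)
    pts <- cumsum(c(0, d))
    lab <- pts[seq(2, length(pts) - 1)]
    len <- pts[length(pts)]
  }
  list(
    length = len, labels = merge_labels(lab, noise$merge_distance),
    map_id = map$map_id, src_start = start, src_end = end
  )
}

#' Sample noisy molecules from label maps
#'
#' Draws molecules until the total sampled bases reach `coverage` times the
#' total (weighted) map length. Each molecule picks a source map with
#' probability proportional to weighted map length, a uniform start, a
#' length from the length model (truncated at the map end), then label
#' dropout, false labels, per-interval sizing noise, a random unrecorded
#' read direction, and (at `chimera_prob`) a second independent fragment
#' stuck onto the first. Truth metadata is recorded per molecule.
#'
#' @param maps List of `label_map` (the true genome maps); a map's `weight`
#'   field counts how many homologues it represents.
#' @param coverage Target fold-coverage (> 0).
#' @param length_model A `length_model` ([length_model_geometric()]).
#' @param noise A `noise_model`.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return A tibble of class `ogm_molecules`: `molecule_id`, `length`,
#'   `labels` (list-column, bp from molecule start), `map_id`, `src_start`,
#'   `src_end`, `reversed`, `chimera`, `chimera_map_id`.
#' @export
sample_molecules <- function(maps, coverage, length_model, noise = noise_model(),
                             seed = 1) {
  stopifnot(coverage > 0)
  weights <- vapply(maps, function(m) m$weight %||% 1, 1)
  lengths <- vapply(maps, `[[`, 1, "length")
  if (mean_length(length_model) > max(lengths)) {
    abort("degenerate length model: minimum molecule length exceeds map length")
  }
  target <- coverage * sum(weights * lengths)
  rows <- list()
  with_seed(seed, {
    total <- 0
    i <- 0
    while (total < target) {
      i <- i + 1
      fr <- draw_fragment(maps, weights, lengths, length_model, noise)
      chim <- runif(1) < noise$chimera_prob
      if (chim) {
        fr2 <- draw_fragment(maps, weights, lengths, length_model, noise)
        fr$labels <- c(fr$labels, fr2$labels + fr$length)
        fr$length <- fr$length + fr2$length
        chimera_map <- fr2$map_id
      } else {
        chimera_map <- NA_character_
      }
      reversed <- runif(1) < 0.5
      lab <- fr$labels
      if (reversed) lab <- sort(fr$length - lab)
      rows[[i]] <- list(
        molecule_id = sprintf("M%06d", i), length = fr$length,
        labels = lab, map_id = fr$map_id,
        src_start = fr$src_start, src_end = fr$src_end,
        reversed = reversed, chimera = chim, chimera_map_id = chimera_map
      )
      total <- total + fr$length
    }
  })
  out <- tibble(
    molecule_id = vapply(rows, `[[`, "", "molecule_id"),
    length = vapply(rows, `[[`, 1, "length"),
    labels = lapply(rows, `[[`, "labels"),
    map_id = vapply(rows, `[[`, "", "map_id"),
    src_start = vapply(rows, `[[`, 1, "src_start"),
    src_end = vapply(rows, `[[`, 1, "src_end"),
    reversed = vapply(rows, `[[`, TRUE, "reversed"),
    chimera = vapply(rows, `[[`, TRUE, "chimera"),
    chimera_map_id = vapply(rows, `[[`, "", "chimera_map_id")
  )
  class(out) <- c("ogm_molecules", class(out))
  out
}
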