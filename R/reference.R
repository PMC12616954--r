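# Reference haplotype tiling: copy-neutral gaps and telomere anchors derived
# around the duplicated segments.

#' Default chromosome lengths and centromere positions
#'
#' Bundled GRCh38 chromosome lengths and approximate centromere midpoints for
#' the chromosomes used by the bundled case configurations. These are
#' configuration inputs, replaceable by the caller.
#'
#' @return A named list with `lengths` and `centromeres` (named numeric, bp).
#' @export
default_genome <- function() {
  list(
    lengths = c(
      chr13 = 114364328, chr16 = 90338345, chr17 = 83257441, chr20 = 64444167
    ),
    centromeres = c(
      chr13 = 17700000, chr16 = 36800000, chr17 = 25100000, chr20 = 28100000
    )
  )
}

#' Build reference haplotype tilings
#'
#' Tiles each chromosome into copy-neutral gap segments and the duplicated
#' segments, adding telomeric flanks. The reference of a chromosome carrying
#' two interspersed duplications therefore reads NML-DUP1-NML-DUP2-NML. Gap
#' ids are deterministic (`NML_<chrom>_<k>`, numbered pter to qter); the first
#' and last tile of each chromosome are telomere anchors. Zero-length gaps
#' between adjacent duplications produce no gap segment.
#'
#' @param segments Segments tibble (duplicated segments).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp). For
#'   chromosomes absent from the vector, bundled defaults are used when known,
#'   otherwise `max(end) + 1e6`.
#' @param centromeres Optional named numeric vector of centromere positions.
#' @param min_gap Gaps smaller than this many bp are dropped (default 1).
#' @return A tibble tiling each chromosome: columns `chrom`, `id`, `start`,
#'   `end`, `size`, `role` (`telomere_anchor`, `copy_neutral`, `duplicated`),
#'   `gain`, `centromere` (logical: tile contains the centromere).
#' @export
build_reference <- function(segments, chrom_lengths = NULL, centromeres = NULL,
                            min_gap = 1) {
  check_no_overlap(segments)
  defaults <- default_genome()
  if (is.null(centromeres)) centromeres <- defaults$centromeres
  tiles <- list()
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    len <- unname(chrom_lengths[ch])
    if (is.null(chrom_lengths) || length(len) == 0 || is.na(len)) {
      len <- unname(defaults$lengths[ch])
    }
    if (is.na(len)) len <- max(s$end) + 1e6
    if (max(s$end) > len) {
      abort(sprintf("segment end beyond chromosome length on %s", ch))
    }
    bounds <- c(1, rbind(s$start, s$end + 1), len + 1)
    k <- 0L
    rows <- list()
    # leading flank
    gaps_before <- c(s$start, len + 1) # gap i precedes segment i; last is qter
    prev_end <- 0
    for (i in seq_len(nrow(s) + 1)) {
      gap_start <- prev_end + 1
      gap_end <- if (i <= nrow(s)) s$start[i] - 1 else len
      if (gap_end - gap_start + 1 >= min_gap &&
        (gap_end >= gap_start)) {
        k <- k + 1L
        rows[[length(rows) + 1]] <- tibble(
          chrom = ch, id = sprintf("NML_%s_%d", ch, k),
          start = gap_start, end = gap_end,
          role = "copy_neutral", gain = 0L
        )
      } else if (i == 1 || i == nrow(s) + 1) {
        abort(sprintf("no telomeric flank left of/right of duplications on %s", ch))
      }
      if (i <= nrow(s)) {
        rows[[length(rows) + 1]] <- tibble(
          chrom = ch, id = s$id[i], start = s$start[i], end = s$end[i],
          role = "duplicated", gain = s$gain[i]
        )
        prev_end <- s$end[i]
      }
    }
    tile <- bind_rows(rows)
    tile$role[1] <- "telomere_anchor"
    tile$role[nrow(tile)] <- "telomere_anchor"
    tiles[[ch]] <- tile
  }
  out <- bind_rows(tiles)
  out$size <- out$end - out$start + 1
  cen <- centromeres[out$chrom]
  out$centromere <- !is.na(cen) & out$start <= cen & cen <= out$end
  out
}

#' Assemble a validated rearrangement configuration
#'
#' Bundles segments, junctions and the derived reference tiling into the
#' configuration object consumed by the enumeration and signature modules.
#'
#' @param segments Segments tibble ([parse_segments()]).
#' @param junctions Junctions tibble ([parse_junctions()]).
#' @param chrom_lengths,centromeres Optional genome geometry; see
#'   [build_reference()].
#' @param min_gap Minimum retained copy-neutral gap (bp).
#' @return An object of class `dup_config`: a list with `segments`,
#'   `junctions`, `reference` (tiling tibble), and lookup tables used by the
#'   enumerators.
#' @export
dup_config <- function(segments, junctions, chrom_lengths = NULL,
                       centromeres = NULL, min_gap = 1) {
  reference <- build_reference(segments, chrom_lengths, centromeres, min_gap)
  cfg <- structure(
    list(
      segments = segments, junctions = junctions, reference = reference,
      chroms = unique(reference$chrom)
    ),
    class = "dup_config"
  )
  rep <- validate_configuration(segments, junctions)
  if (nrow(rep) > 0) {
    warn(paste0(
      "configuration has ", nrow(rep), " validation issue(s); see validate_configuration()"
    ))
  }
  cfg
}

#' @export
print.dup_config <- function(x, ...) {
  cat(
    "<dup_config> ", nrow(x$segments), " duplicated segment(s), ",
    nrow(x$junctions), " junction(s) on ", length(x$chroms),
    " chromosome(s)\n",
    sep = ""
  )
  invisible(x)
}

# Tiling helpers -------------------------------------------------------------

ref_neighbour <- function(reference, seg_id, side) {
  i <- match(seg_id, reference$id)
  ch <- reference$chrom[i]
  idx <- which(reference$chrom == ch)
  pos <- match(i, idx)
  if (side == "end") {
    if (pos == length(idx)) {
      return(NA_character_)
    }
    reference$id[idx[pos + 1]]
  } else {
    if (pos == 1) {
      return(NA_character_)
    }
    reference$id[idx[pos - 1]]
  }
}

chrom_tiles <- function(reference, ch) reference[reference$chrom == ch, ]

anchor_ids <- function(reference, ch, which = c("pter", "qter")) {
  which <- match.arg(which)
  t <- chrom_tiles(reference, ch)
  if (which == "pter") t$id[1] else t$id[nrow(t)]
}
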