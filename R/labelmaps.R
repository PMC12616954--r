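# Label maps: ordered label positions along reference and derivative
# haplotypes, assembled from per-segment label sets so that every copy of a
# segment carries the same labels wherever it appears.

new_label_map <- function(map_id, length, positions, provenance = "reference",
                          copies = NULL, weight = 1) {
  stopifnot(!is.unsorted(positions), all(positions >= 1), all(positions <= length))
  structure(
    list(
      map_id = map_id, length = length, positions = as.numeric(positions),
      provenance = provenance, copies = copies, weight = weight
    ),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(
    "<label_map> ", x$map_id, ": ", length(x$positions), " labels over ",
    format(x$length, big.mark = ","), " bp (", x$provenance, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy label_map
#' @export
tidy.label_map <- function(x, ...) {
  tibble(map_id = x$map_id, site = seq_along(x$positions), position = x$positions)
}

#' Scan a nucleotide sequence for label motif sites
#'
#' Returns the 1-based start positions of the labelling motif on the forward
#' strand. The default motif (CTTAAG, the DLE-1 recognition site used by
#' Direct Label and Stain chemistry) is its own reverse complement's partner
#' on the opposite strand, so forward-strand scanning suffices.
#'
#' @param sequence Uppercase nucleotide text (A/C/G/T/N).
#' @param motif Non-empty motif (default `"CTTAAG"`).
#' @return Integer vector of 1-based match start positions (overlapping
#'   occurrences each counted).
#' @export
scan_labels <- function(sequence, motif = "CTTAAG") {
  stopifnot(nzchar(motif))
  if (grepl("[^ACGTN]", sequence)) {
    abort("sequence contains non-ACGTN characters")
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence))
    return(as.integer(Biostrings::start(hits)))
  }
  m <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) {
    return(integer())
  }
  as.integer(m)
}

# Merge labels closer than merge_distance into their cluster mean; iterate to
# a fixed point so the invariant (consecutive gaps >= merge_distance) holds.
merge_labels <- function(positions, merge_distance) {
  positions <- sort(positions)
  repeat {
    if (length(positions) < 2) {
      return(positions)
    }
    gaps <- diff(positions)
    if (all(gaps >= merge_distance)) {
      return(positions)
    }
    grp <- cumsum(c(1, gaps >= merge_distance))
    positions <- as.numeric(tapply(positions, grp, mean))
  }
}

#' Draw label positions from a homogeneous spacing model
#'
#' Sequence-free label synthesis: label positions are a homogeneous Poisson
#' process with the given mean spacing, then merged under the instrument
#' resolution (labels closer than `merge_distance` collapse to one).
#'
#' @param length Span to label (bp).
#' @param mean_spacing Mean inter-label spacing (bp; default 5000).
#' @param merge_distance Minimum resolvable label separation (bp; default 500).
#' @param seed RNG seed.
#' @return Sorted numeric label positions in `[1, length]`.
#' @export
spacing_model_labels <- function(length, mean_spacing = 5000,
                                 merge_distance = 500, seed = 1) {
  stopifnot(mean_spacing > merge_distance)
  if (length <= 0) {
    return(numeric())
  }
  with_seed(seed, {
    n <- rpois(1, length / mean_spacing)
    pos <- sort(runif(n, 1, length))
  })
  merge_labels(pos, merge_distance)
}

# One label set per reference tile, deterministic in (seed, tile id).
segment_label_registry <- function(config, mean_spacing = 5000,
                                   merge_distance = 500, seed = 1) {
  ref <- config$reference
  out <- lapply(seq_len(nrow(ref)), function(i) {
    spacing_model_labels(
      ref$size[i], mean_spacing, merge_distance,
      seed = derive_seed(seed, paste0("labels_", ref$id[i]))
    )
  })
  setNames(out, ref$id)
}

#' Assemble label maps for a derivative structure
#'
#' Concatenates per-segment label sets along each haplotype walk, reflecting
#' positions (`pos -> size - pos + 1`) for reverse-oriented copies, shifting
#' by cumulative copy lengths and merging labels that fall closer than
#' `merge_distance` across junctions. Each copy's interval in map
#' coordinates is recorded, together with its abnormal spanning signature
#' where it has one.
#'
#' @param structure A `dup_structure`.
#' @param config A `dup_config`.
#' @param labels Named list of per-tile label positions
#'   ([segment_label_registry()]).
#' @param merge_distance Minimum resolvable label separation (bp).
#' @param resolution_bp Resolution used to annotate copy signatures.
#' @return A list of `label_map`, one per haplotype, map ids
#'   `<label>_hap<i>`.
#' @export
assemble_derivative_map <- function(structure, config, labels,
                                    merge_distance = 500, resolution_bp = 500) {
  missing <- setdiff(unique(unlist(lapply(structure$haplotypes, `[[`, "seg"))), names(labels))
  if (length(missing) > 0) {
    abort(paste0("no label set for segment(s): ", paste(missing, collapse = ", ")))
  }
  ref <- config$reference
  sizes <- setNames(ref$size, ref$id)
  purrr::imap(structure$haplotypes, function(hap, i) {
    offset <- 0
    pos <- numeric()
    starts <- numeric(nrow(hap))
    ends <- numeric(nrow(hap))
    for (k in seq_len(nrow(hap))) {
      sg <- hap$seg[k]
      sl <- sizes[[sg]]
      p <- labels[[sg]]
      if (hap$orient[k] < 0) p <- sort(sl - p + 1)
      pos <- c(pos, p + offset)
      starts[k] <- offset + 1
      ends[k] <- offset + sl
      offset <- offset + sl
    }
    copies <- tibble(
      copy = seq_len(nrow(hap)), seg = hap$seg, orient = hap$orient,
      start = starts, end = ends
    )
    copies <- annotate_copy_signatures(copies, structure, i, config, resolution_bp)
    new_label_map(
      map_id = paste0(structure$label, "_hap", i),
      length = offset,
      positions = merge_labels(pos, merge_distance),
      provenance = paste0(structure$label, "/haplotype ", i),
      copies = copies
    )
  })
}

# Per-copy signature annotation: visible duplicated copies get their
# canonical signature (abnormal) or are flagged native (reference context).
annotate_copy_signatures <- function(copies, structure, hap_index, config,
                                     resolution_bp) {
  ref <- config$reference
  visible <- setNames(ref$size >= resolution_bp, ref$id)
  role <- setNames(ref$role, ref$id)
  hap <- structure$haplotypes[[hap_index]]
  copies$target <- FALSE
  copies$abnormal <- FALSE
  copies$signature <- NA_character_
  for (k in seq_len(nrow(hap))) {
    sg <- hap$seg[k]
    if (role[[sg]] != "duplicated" || !visible[[sg]]) next
    lc <- walk_context(hap, k, -1L, visible)
    rc <- walk_context(hap, k, +1L, visible)
    copies$target[k] <- TRUE
    if (lc$abnormal || rc$abnormal) {
      cs <- canonical_signature(lc$id, lc$orient, sg, hap$orient[k], rc$id, rc$orient)
      copies$abnormal[k] <- TRUE
      copies$signature[k] <- cs$signature
    }
  }
  copies
}

#' Reference label maps, one per chromosome
#'
#' @param config A `dup_config`.
#' @param labels Per-tile label registry.
#' @param merge_distance Minimum label separation (bp).
#' @param resolution_bp Resolution used to annotate native copies.
#' @return A list of `label_map` named `ref_<chrom>`.
#' @export
reference_maps <- function(config, labels, merge_distance = 500,
                           resolution_bp = 500) {
  ref <- config$reference
  out <- lapply(config$chroms, function(ch) {
    walk <- ref_walk(ref, ch)
    st <- new_structure(paste0("ref_", ch), list(walk), config)
    m <- assemble_derivative_map(st, config, labels, merge_distance, resolution_bp)[[1]]
    m$map_id <- paste0("ref_", ch)
    m$provenance <- "reference"
    m
  })
  setNames(out, paste0("ref_", config$chroms))
}
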