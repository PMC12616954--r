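# Bundled case-study configurations: three published interspersed
# duplication / triplication rearrangements used as worked examples and
# regression fixtures. Coordinates are GRCh38; sizes follow the 1-based
# inclusive convention.

case_registry <- function() {
  list(
    case1 = list(
      desc = "chr13: 323 kb + 148 bp (inverted) + 244 kb linked duplications",
      mode = "archetype",
      # published figure labels keyed on cut-site metadata
      relabel = c(cis_13.3 = "Alt1", cis_13.1 = "Alt2", trans_13.1_13.3 = "Alt3")
    ),
    case2 = list(
      desc = "chr16 (2.01 Mb) + chr17 (564 kb) linked duplications",
      mode = "archetype",
      relabel = c(cis_16 = "Alt1", cis_17 = "Alt2", trans_16_17 = "Alt3")
    ),
    case3 = list(
      desc = "chr20 chromoanasynthesis: 4 duplications + 1 triplication",
      mode = "general_inherited",
      relabel = NULL
    )
  )
}

#' Bundled case-study configurations
#'
#' Loads one of the three bundled rearrangement configurations (segment and
#' junction tables shipped with the package).
#'
#' @param name One of `"case1"`, `"case2"`, `"case3"`.
#' @return A `dup_config`.
#' @examples
#' case_config("case1")$segments
#' @export
case_config <- function(name = c("case1", "case2", "case3")) {
  name <- match.arg(name)
  extd <- system.file("extdata", package = "ogmtopo")
  seg <- read_segments(file.path(extd, paste0(name, "_segments.tsv")))
  jn <- read_junctions(file.path(extd, paste0(name, "_junctions.tsv")), seg)
  dup_config(seg, jn)
}

#' Candidate structures of a bundled case
#'
#' Enumerates the candidate structures of a bundled case with the mode the
#' case calls for (archetype cassette cuts for the two-junction/three-junction
#' cyclic cases; general enumeration in inherited mode for the
#' chromoanasynthesis case) and, where the corresponding figure labels are
#' published, relabels the structures to match them (figure label order is
#' presentation metadata, not derivable from cut-site position).
#'
#' @param name `"case1"`, `"case2"` or `"case3"`.
#' @param resolution_bp Minimum resolvable segment size for archetype cuts.
#' @param config Optional pre-built `dup_config` for the case.
#' @return A `dup_structure_set` with published labels where available.
#' @export
case_structures <- function(name = c("case1", "case2", "case3"),
                            resolution_bp = 500, config = NULL) {
  name <- match.arg(name)
  reg <- case_registry()[[name]]
  if (is.null(config)) config <- case_config(name)
  if (reg$mode == "archetype") {
    sts <- enumerate_archetype(config, resolution_bp = resolution_bp)
  } else {
    sts <- enumerate_general(config, forbid_same_chromosome_pair = TRUE)
  }
  if (!is.null(reg$relabel)) {
    sts <- unclass(sts)
    for (i in seq_along(sts)) {
      meta_key <- paste(
        c(sts[[i]]$meta$type, sts[[i]]$meta$cuts),
        collapse = "_"
      )
      if (meta_key %in% names(reg$relabel)) {
        sts[[i]]$label <- reg$relabel[[meta_key]]
      }
    }
    sts <- sts[order(vapply(sts, `[[`, "", "label"))]
    sts <- new_structure_set(sts, config)
  }
  sts
}
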