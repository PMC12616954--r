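# StructureModel: one or two derivative haplotypes as ordered oriented copies
# of reference tiles, with an adjacency trace ("ref" or a junction id) between
# consecutive copies.

new_structure <- function(label, haplotypes, config, meta = list()) {
  st <- structure(
    list(label = label, haplotypes = haplotypes, meta = meta),
    class = "dup_structure"
  )
  st$key <- structure_key(st)
  st
}

# A haplotype is a tibble: seg, orient (+1/-1), adj_in ("ref"/junction id/NA).
hap_string <- function(h) {
  paste(
    sprintf(
      "%s%s%s",
      ifelse(is.na(h$adj_in), "", paste0("(", h$adj_in, ")")),
      h$seg, ifelse(h$orient < 0, "'", "")
    ),
    collapse = "|"
  )
}

#' Canonical key of a structure model
#'
#' The key is invariant under relabeling (listing order) of the haplotypes;
#' haplotypes themselves are anchored pter to qter, so whole-haplotype
#' reversal is not a symmetry.
#'
#' @param structure A `dup_structure`.
#' @return A character scalar key.
#' @export
structure_key <- function(structure) {
  paste(sort(vapply(structure$haplotypes, hap_string, "")), collapse = " // ")
}

#' @export
print.dup_structure <- function(x, ...) {
  cat("<dup_structure> ", x$label, "\n", sep = "")
  for (h in x$haplotypes) {
    cat("  ", hap_string(h), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.dup_structure <- function(x, ...) hap_string_set(x)

hap_string_set <- function(x) {
  paste(vapply(x$haplotypes, hap_string, ""), collapse = " // ")
}

#' Tidy a set of structure models
#'
#' @param x A `dup_structure_set` (as returned by the enumerators).
#' @param ... Unused.
#' @return A tibble with one row per haplotype copy: `label`, `haplotype`,
#'   `position`, `seg`, `orient`, `adj_in`.
#' @method tidy dup_structure_set
#' @export
tidy.dup_structure_set <- function(x, ...) {
  purrr::map_dfr(x, function(st) {
    purrr::imap_dfr(st$haplotypes, function(h, i) {
      tibble(
        label = st$label, haplotype = i, position = seq_len(nrow(h)),
        seg = h$seg, orient = h$orient, adj_in = h$adj_in
      )
    })
  })
}

#' @method tidy dup_structure
#' @export
tidy.dup_structure <- function(x, ...) {
  tidy.dup_structure_set(structure(list(x), class = "dup_structure_set"), ...)
}

#' Summarise a set of structure models
#' @param x A `dup_structure_set`.
#' @param ... Unused.
#' @return One row per structure: `label`, `n_haplotypes`, `n_copies`,
#'   `n_junction_adjacencies`, `key`.
#' @method glance dup_structure_set
#' @export
glance.dup_structure_set <- function(x, ...) {
  purrr::map_dfr(x, function(st) {
    copies <- do.call(rbind, lapply(st$haplotypes, as.data.frame))
    tibble(
      label = st$label,
      n_haplotypes = length(st$haplotypes),
      n_copies = nrow(copies),
      n_junction_adjacencies = sum(!is.na(copies$adj_in) & copies$adj_in != "ref"),
      key = st$key
    )
  })
}

new_structure_set <- function(structures, config) {
  names(structures) <- vapply(structures, `[[`, "", "label")
  structure(structures, class = "dup_structure_set", config = config)
}

#' @export
print.dup_structure_set <- function(x, ...) {
  cat("<dup_structure_set> ", length(x), " structure(s)\n", sep = "")
  for (st in x) {
    cat("  ", st$label, ": ", hap_string_set(st), "\n", sep = "")
  }
  invisible(x)
}

set_config <- function(x) attr(x, "config")

# Validation ------------------------------------------------------------------

#' Check a structure model against diploid copy and junction accounting
#'
#' Verifies that realized copies across modified plus unmodified homologues
#' equal `2 + gain` for every segment of the involved chromosomes, that each
#' junction's breakend pair appears exactly once across adjacency traces,
#' that cited reference adjacencies exist in the reference, and that each
#' haplotype is anchored pter to qter in forward orientation (and carries
#' exactly one centromere when centromere positions are available).
#'
#' @param structure A `dup_structure`.
#' @param config A `dup_config`.
#' @return A character vector of violation messages (empty when valid).
#' @export
validate_structure <- function(structure, config) {
  ref <- config$reference
  junctions <- config$junctions
  msgs <- character()
  h_by_chrom <- table(vapply(
    structure$haplotypes,
    function(h) ref$chrom[match(h$seg[1], ref$id)], ""
  ))
  copies <- do.call(rbind, lapply(structure$haplotypes, as.data.frame))
  for (i in seq_len(nrow(ref))) {
    id <- ref$id[i]
    ch <- ref$chrom[i]
    h_c <- if (ch %in% names(h_by_chrom)) h_by_chrom[[ch]] else 0
    realized <- sum(copies$seg == id) + (2 - h_c)
    if (realized != 2 + ref$gain[i]) {
      msgs <- c(msgs, sprintf(
        "segment %s: realized copies %d != %d", id, realized, 2 + ref$gain[i]
      ))
    }
  }
  used <- copies$adj_in[!is.na(copies$adj_in) & copies$adj_in != "ref"]
  for (j in junctions$id) {
    if (sum(used == j) != 1) {
      msgs <- c(msgs, sprintf("junction %s used %d times", j, sum(used == j)))
    }
  }
  for (h in structure$haplotypes) {
    first <- h$seg[1]
    last <- h$seg[nrow(h)]
    ch1 <- ref$chrom[match(first, ref$id)]
    ch2 <- ref$chrom[match(last, ref$id)]
    if (first != anchor_ids(ref, ch1, "pter") || h$orient[1] != 1) {
      msgs <- c(msgs, "haplotype does not start at a forward pter anchor")
    }
    if (last != anchor_ids(ref, ch2, "qter") || h$orient[nrow(h)] != 1) {
      msgs <- c(msgs, "haplotype does not end at a forward qter anchor")
    }
    msgs <- c(msgs, check_adjacencies(h, config))
    if ("centromere" %in% names(ref) && any(ref$centromere)) {
      ncen <- sum(ref$centromere[match(h$seg, ref$id)])
      if (ncen != 1) {
        msgs <- c(msgs, sprintf("haplotype carries %d centromeres", ncen))
      }
    }
  }
  msgs
}

# Verify each consecutive pair is joined by the cited adjacency.
check_adjacencies <- function(h, config) {
  ref <- config$reference
  junctions <- config$junctions
  msgs <- character()
  if (nrow(h) < 2) {
    return(msgs)
  }
  for (i in 2:nrow(h)) {
    s <- h$seg[i - 1]
    t <- h$seg[i]
    os <- h$orient[i - 1]
    ot <- h$orient[i]
    exit_side <- if (os > 0) "end" else "start"
    entry_side <- if (ot > 0) "start" else "end"
    adj <- h$adj_in[i]
    if (is.na(adj)) {
      msgs <- c(msgs, "missing adjacency trace")
    } else if (adj == "ref") {
      nb <- ref_neighbour(ref, s, exit_side)
      ok <- !is.na(nb) && nb == t && os == ot
      if (!ok) msgs <- c(msgs, sprintf("invalid reference adjacency %s->%s", s, t))
    } else {
      j <- junctions[junctions$id == adj, ]
      if (nrow(j) != 1) {
        msgs <- c(msgs, sprintf("unknown junction %s", adj))
      } else {
        want <- normalize_breakends(s, exit_side, t, entry_side)
        if (junction_key(want) != j$key) {
          msgs <- c(msgs, sprintf("junction %s does not join %s(%s)->%s(%s)",
            adj, s, exit_side, t, entry_side))
        }
      }
    }
  }
  msgs
}

#' Per-segment realized copy counts of a structure
#' @param structure A `dup_structure`.
#' @param config A `dup_config`.
#' @return A tibble `seg`, `modified_copies`, `realized_total`.
#' @export
structure_copy_counts <- function(structure, config) {
  ref <- config$reference
  copies <- do.call(rbind, lapply(structure$haplotypes, as.data.frame))
  h_by_chrom <- table(vapply(
    structure$haplotypes,
    function(h) ref$chrom[match(h$seg[1], ref$id)], ""
  ))
  tibble(
    seg = ref$id,
    modified_copies = vapply(ref$id, function(id) sum(copies$seg == id), 0),
    realized_total = vapply(seq_len(nrow(ref)), function(i) {
      ch <- ref$chrom[i]
      h_c <- if (ch %in% names(h_by_chrom)) h_by_chrom[[ch]] else 0
      sum(copies$seg == ref$id[i]) + (2 - h_c)
    }, 0)
  )
}
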