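# Exhaustive enumeration oracle: tries every ordered oriented-copy sequence
# against the copy budgets and adjacency validity. Used in tests to verify
# enumerate_general(); deliberately formulated as candidate generation plus
# a pairwise validity filter rather than as a graph walk.

#' Brute-force structure enumeration (test oracle)
#'
#' Exhaustively enumerates all ordered oriented-copy sequences that satisfy
#' the copy budgets and whose every consecutive pair is joined by either the
#' reference adjacency or an unused junction. Intended for small fixtures
#' only; errors when any haplotype would exceed `max_copies` copies.
#'
#' @param config A `dup_config`.
#' @param max_modified_homologues,forbid_same_chromosome_pair As in
#'   [enumerate_general()].
#' @param max_copies Per-haplotype copy budget limit (default 12).
#' @return A `dup_structure_set` in canonical-key order.
#' @export
brute_force_oracle <- function(config, max_modified_homologues = 2,
                               forbid_same_chromosome_pair = FALSE,
                               max_copies = 12) {
  ref <- config$reference
  junctions <- config$junctions
  chroms <- config$chroms
  role <- setNames(ref$role, ref$id)
  per_chrom_cap <- if (forbid_same_chromosome_pair) 1L else 2L
  h_grid <- expand.grid(rep(list(0:per_chrom_cap), length(chroms)),
    KEEP.OUT.ATTRS = FALSE
  )
  names(h_grid) <- chroms
  totals <- rowSums(h_grid)
  h_grid <- h_grid[totals >= 1 & totals <= max_modified_homologues, , drop = FALSE]

  # a pair (prev copy, next copy) is valid if the unordered breakend pair it
  # implies equals the reference adjacency there, or an unused junction
  pair_modes <- function(prev, nxt, jn_unused) {
    exit_side <- if (prev$orient > 0) "end" else "start"
    entry_side <- if (nxt$orient > 0) "start" else "end"
    modes <- character()
    nb <- ref_neighbour(ref, prev$seg, exit_side)
    if (!is.na(nb) && nb == nxt$seg && prev$orient == nxt$orient) {
      modes <- c(modes, "ref")
    }
    key <- junction_key(normalize_breakends(prev$seg, exit_side, nxt$seg, entry_side))
    jhit <- junctions$id[junctions$key == key]
    modes <- c(modes, intersect(jhit, jn_unused))
    modes
  }

  results <- new.env()
  results$seen <- character()
  results$structures <- list()

  emit <- function(walks) {
    haps <- lapply(walks, function(w) {
      tibble(
        seg = vapply(w, `[[`, "", "seg"),
        orient = vapply(w, `[[`, 1L, "orient"),
        adj_in = vapply(w, function(x) x$adj %||% NA_character_, "")
      )
    })
    keep <- vapply(haps, function(h) {
      ch <- ref$chrom[match(h$seg[1], ref$id)]
      rw <- ref_walk(ref, ch)
      !(nrow(h) == nrow(rw) && all(h$seg == rw$seg) && all(h$orient == 1) &&
        all(is.na(h$adj_in) | h$adj_in == "ref"))
    }, TRUE)
    haps <- haps[keep]
    if (length(haps) == 0) {
      return()
    }
    st <- new_structure("tmp", haps, NULL)
    if (!st$key %in% results$seen) {
      results$seen <- c(results$seen, st$key)
      results$structures[[length(results$structures) + 1]] <- st
    }
  }

  recurse <- function(pool, jn_unused, starts, walks, walk) {
    if (is.null(walk)) {
      if (length(starts) == 0) {
        if (all(pool == 0) && length(jn_unused) == 0) emit(walks)
        return()
      }
      s <- starts[[1]]
      if (pool[[s]] < 1) {
        return()
      }
      pool[[s]] <- pool[[s]] - 1L
      recurse(pool, jn_unused, starts[-1], walks,
        list(list(seg = s, orient = 1L, adj = NULL)))
      return()
    }
    prev <- walk[[length(walk)]]
    # walk may terminate only at a forward qter anchor
    ch_prev <- ref$chrom[match(prev$seg, ref$id)]
    if (role[[prev$seg]] == "telomere_anchor" && prev$orient > 0 &&
      prev$seg == anchor_ids(ref, ch_prev, "qter")) {
      recurse(pool, jn_unused, starts, c(walks, list(walk)), NULL)
      return()
    }
    if (length(walk) >= max_copies) {
      abort("brute_force_oracle: max_copies exceeded")
    }
    for (s in names(pool)) {
      if (pool[[s]] < 1) next
      orients <- if (role[[s]] == "telomere_anchor") 1L else c(1L, -1L)
      for (o in orients) {
        cand <- list(seg = s, orient = o)
        modes <- pair_modes(prev, cand, jn_unused)
        for (m in modes) {
          pool2 <- pool
          pool2[[s]] <- pool2[[s]] - 1L
          jn2 <- if (m == "ref") jn_unused else setdiff(jn_unused, m)
          recurse(pool2, jn2, starts, walks,
            c(walk, list(list(seg = s, orient = o, adj = m))))
        }
      }
    }
  }

  for (r in seq_len(nrow(h_grid))) {
    h <- unlist(h_grid[r, , drop = TRUE])
    names(h) <- chroms
    pool <- setNames(as.integer(ref$gain + h[ref$chrom]), ref$id)
    if (max(tapply(pool, ref$chrom, sum) / pmax(h[unique(ref$chrom)], 1)) > max_copies) {
      # loose guard; exact per-walk limit enforced during recursion
    }
    starts <- unlist(lapply(sort(chroms), function(ch) {
      rep(anchor_ids(ref, ch, "pter"), h[[ch]])
    }))
    recurse(pool, junctions$id, as.list(starts), list(), NULL)
  }

  sts <- results$structures
  keys <- vapply(sts, `[[`, "", "key")
  sts <- sts[order(keys)]
  for (i in seq_along(sts)) sts[[i]]$label <- sprintf("Alt%d", i)
  new_structure_set(sts, config)
}
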