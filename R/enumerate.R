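# Enumeration of derivative-chromosome structures compatible with the
# junctions and copy-number gains.

#' Chain junctions into the duplication cassette
#'
#' Links the abnormal junctions end-to-end through shared duplicated-segment
#' copies into maximal oriented chains. For the archetype configuration
#' (each duplicated-segment edge used by at most one junction, gains of 1)
#' the chain closes into a single cycle: the cassette of linked duplications.
#'
#' @param config A `dup_config`.
#' @return A list of chains; each chain is a list with `copies` (tibble
#'   `seg`, `orient`), `junctions` (ids, in traversal order; for a cyclic
#'   chain junction `i` joins copy `i` to copy `i + 1`, wrapping), `cyclic`.
#' @export
chain_cassette <- function(config) {
  junctions <- config$junctions
  chains <- list()
  unused <- junctions$id
  edge_of <- function(seg, orient, side = c("exit", "entry")) {
    side <- match.arg(side)
    if (side == "exit") {
      paste0(seg, ":", if (orient > 0) "end" else "start")
    } else {
      paste0(seg, ":", if (orient > 0) "start" else "end")
    }
  }
  match_junctions <- function(edge) {
    j <- junctions[junctions$id %in% unused, , drop = FALSE]
    hits <- j$id[paste0(j$seg_a, ":", j$side_a) == edge |
      paste0(j$seg_b, ":", j$side_b) == edge]
    hits
  }
  partner_copy <- function(jid, edge) {
    j <- junctions[junctions$id == jid, ]
    if (paste0(j$seg_a, ":", j$side_a) == edge) {
      list(seg = j$seg_b, orient = if (j$side_b == "start") 1L else -1L)
    } else {
      list(seg = j$seg_a, orient = if (j$side_a == "start") 1L else -1L)
    }
  }
  while (length(unused) > 0) {
    seed_id <- sort(unused)[1]
    j <- junctions[junctions$id == seed_id, ]
    seed <- list(seg = j$seg_a, orient = if (j$side_a == "end") 1L else -1L)
    copies <- list(seed)
    chain_j <- character()
    cyclic <- FALSE
    # extend right
    cur <- seed
    repeat {
      e <- edge_of(cur$seg, cur$orient, "exit")
      hits <- match_junctions(e)
      if (length(hits) == 0) break
      jid <- sort(hits)[1]
      nxt <- partner_copy(jid, e)
      unused <- setdiff(unused, jid)
      chain_j <- c(chain_j, jid)
      if (nxt$seg == seed$seg && nxt$orient == seed$orient) {
        cyclic <- TRUE
        break
      }
      copies[[length(copies) + 1]] <- nxt
      cur <- nxt
    }
    if (!cyclic) {
      # extend left from the seed's entry edge
      cur <- seed
      repeat {
        e <- edge_of(cur$seg, cur$orient, "entry")
        hits <- match_junctions(e)
        if (length(hits) == 0) break
        jid <- sort(hits)[1]
        j2 <- junctions[junctions$id == jid, ]
        if (paste0(j2$seg_a, ":", j2$side_a) == e) {
          prv <- list(seg = j2$seg_b, orient = if (j2$side_b == "end") 1L else -1L)
        } else {
          prv <- list(seg = j2$seg_a, orient = if (j2$side_a == "end") 1L else -1L)
        }
        unused <- setdiff(unused, jid)
        chain_j <- c(jid, chain_j)
        copies <- c(list(prv), copies)
        cur <- prv
      }
    }
    chains[[length(chains) + 1]] <- list(
      copies = tibble(
        seg = vapply(copies, `[[`, "", "seg"),
        orient = vapply(copies, `[[`, 1L, "orient")
      ),
      junctions = chain_j,
      cyclic = cyclic
    )
  }
  chains
}

# Rotate/reverse a cyclic chain so `seg` comes first in forward orientation.
cycle_from <- function(chain, seg) {
  stopifnot(chain$cyclic)
  cp <- chain$copies
  jn <- chain$junctions
  n <- nrow(cp)
  i <- match(seg, cp$seg)
  if (cp$orient[i] < 0) {
    rev_cp <- cp[rev(seq_len(n)), ]
    rev_cp$orient <- -rev_cp$orient
    idx <- (n - seq_len(n)) %% n
    idx[idx == 0] <- n
    jn <- jn[idx]
    cp <- rev_cp
    i <- match(seg, cp$seg)
  }
  ord <- ((seq_len(n) + i - 2) %% n) + 1
  list(copies = cp[ord, ], junctions = jn[ord], cyclic = TRUE)
}

ref_walk <- function(reference, ch) {
  t <- chrom_tiles(reference, ch)
  tibble(seg = t$id, orient = 1L, adj_in = c(NA, rep("ref", nrow(t) - 1)))
}

# Reference prefix up to and including seg; suffix strictly after seg.
ref_prefix <- function(reference, seg) {
  ch <- reference$chrom[match(seg, reference$id)]
  w <- ref_walk(reference, ch)
  w[seq_len(match(seg, w$seg)), ]
}

ref_suffix <- function(reference, seg) {
  ch <- reference$chrom[match(seg, reference$id)]
  w <- ref_walk(reference, ch)
  i <- match(seg, w$seg)
  out <- w[seq(i + 1, nrow(w)), ]
  out$adj_in[1] <- "ref"
  out
}

#' Enumerate archetype structures by cutting the cassette cycle
#'
#' For a configuration whose junctions chain into a single cycle through k
#' duplicated segments, all with gain 1, the candidate structures are: one
#' cis structure per resolvable cut segment (the derivative follows the
#' reference through the native copy of the cut segment, then the remaining
#' cassette copies, returning to a second copy of the cut segment and the
#' reference beyond it), plus one trans structure per unordered pair of
#' resolvable cut segments that carry the same orientation in the cycle
#' (the two cycle arcs are assigned to two homologues, a translocation when
#' the cut segments lie on different chromosomes). Cut segments smaller than
#' `resolution_bp` are not used as cut sites.
#'
#' @param config A `dup_config`.
#' @param resolution_bp Minimum resolvable segment size (default 500 bp).
#' @param max_modified_homologues 1 or 2; trans structures need 2.
#' @param forbid_same_chromosome_pair Suppress trans structures whose two cut
#'   segments share a chromosome ("inherited" mode).
#' @return A `dup_structure_set`; each structure's `meta` records its `type`
#'   (`cis`/`trans`) and cut segment(s).
#' @export
enumerate_archetype <- function(config, resolution_bp = 500,
                                max_modified_homologues = 2,
                                forbid_same_chromosome_pair = FALSE) {
  ref <- config$reference
  seg <- config$segments
  chains <- chain_cassette(config)
  if (length(chains) != 1 || !chains[[1]]$cyclic) {
    abort(paste0(
      "junctions do not chain into a single cycle; ",
      "use enumerate_general() for this configuration"
    ))
  }
  if (any(seg$gain != 1)) {
    abort(paste0(
      "archetype enumeration requires all gains = 1 (single cassette copy); ",
      "use enumerate_general() for this configuration"
    ))
  }
  chain <- chains[[1]]
  if (nrow(chain$copies) != nrow(seg) ||
    !setequal(chain$copies$seg, seg$id)) {
    abort("cassette cycle does not visit each duplicated segment exactly once; use enumerate_general()")
  }
  sizes <- setNames(seg$size, seg$id)
  chroms <- setNames(seg$chrom, seg$id)
  starts <- setNames(seg$start, seg$id)
  cuts <- seg$id[seg$size >= resolution_bp]
  cuts <- cuts[order(chroms[cuts], starts[cuts])]
  structures <- list()
  metas <- list()
  for (d in cuts) {
    cyc <- cycle_from(chain, d)
    cassette <- cyc$copies[-1, , drop = FALSE]
    adj <- cyc$junctions
    walk <- ref_prefix(ref, d)
    if (nrow(cassette) > 0) {
      walk <- bind_rows(walk, tibble(
        seg = cassette$seg, orient = cassette$orient,
        adj_in = adj[seq_len(nrow(cassette))]
      ))
    }
    walk <- bind_rows(
      walk,
      tibble(seg = d, orient = 1L, adj_in = adj[length(adj)]),
      ref_suffix(ref, d)
    )
    structures[[length(structures) + 1]] <- walk
    metas[[length(metas) + 1]] <- list(type = "cis", cuts = d)
  }
  if (max_modified_homologues >= 2 && length(cuts) >= 2) {
    pairs <- utils::combn(cuts, 2, simplify = FALSE)
    for (p in pairs) {
      d1 <- p[1]
      d2 <- p[2]
      if (forbid_same_chromosome_pair && chroms[d1] == chroms[d2]) next
      cyc <- cycle_from(chain, d1)
      j2 <- match(d2, cyc$copies$seg)
      if (is.na(j2) || cyc$copies$orient[j2] != 1) next # arc would arrive inverted
      arc1 <- cyc$copies[seq(2, j2), , drop = FALSE]
      adj1 <- cyc$junctions[seq_len(j2 - 1)]
      n <- nrow(cyc$copies)
      hap1 <- bind_rows(
        ref_prefix(ref, d1),
        tibble(seg = arc1$seg, orient = arc1$orient, adj_in = adj1),
        ref_suffix(ref, d2)
      )
      if (j2 < n) {
        arc2 <- cyc$copies[seq(j2 + 1, n), , drop = FALSE]
        adj2 <- cyc$junctions[seq(j2, n - 1)]
      } else {
        arc2 <- cyc$copies[0, ]
        adj2 <- character()
      }
      hap2 <- bind_rows(
        ref_prefix(ref, d2),
        tibble(seg = arc2$seg, orient = arc2$orient, adj_in = adj2),
        tibble(seg = d1, orient = 1L, adj_in = cyc$junctions[n]),
        ref_suffix(ref, d1)
      )
      structures[[length(structures) + 1]] <- list(hap1, hap2)
      metas[[length(metas) + 1]] <- list(type = "trans", cuts = c(d1, d2))
    }
  }
  out <- list()
  for (i in seq_along(structures)) {
    haps <- structures[[i]]
    if (is.data.frame(haps)) haps <- list(haps)
    st <- new_structure(sprintf("Alt%d", length(out) + 1), haps, config, metas[[i]])
    bad <- validate_structure(st, config)
    if (length(bad) > 0) next
    out[[length(out) + 1]] <- st
  }
  new_structure_set(out, config)
}

#' Enumerate all structures compatible with junctions and gains
#'
#' Depth-first construction over the breakpoint multigraph. Copy budgets per
#' reference tile are `gain + h(chrom)` where `h(chrom)` is the number of
#' modified homologues of that chromosome; each modified haplotype starts at
#' a pter anchor (forward) and ends at a qter anchor (forward, possibly of a
#' different chromosome). From the exit edge of the current copy the walk
#' may take an unused junction whose breakend matches the edge, or the
#' reference adjacency at that edge (in the current orientation, which
#' permits inverted copy-neutral blocks entered and left through junctions).
#' A structure is emitted when all budgets are exactly consumed and every
#' junction is used exactly once. Telomere anchors never invert. Results are
#' deduplicated by canonical form and sorted by canonical key.
#'
#' @param config A `dup_config`.
#' @param max_modified_homologues Total modified homologues allowed (1 or 2).
#' @param forbid_same_chromosome_pair Restrict to at most one modified
#'   homologue per chromosome ("inherited" mode).
#' @param max_results Cap on emitted structures (default 10000); when hit,
#'   the returned set carries attribute `partial = TRUE`.
#' @return A `dup_structure_set`, labels `Alt1..AltN` in canonical-key order.
#' @export
enumerate_general <- function(config, max_modified_homologues = 2,
                              forbid_same_chromosome_pair = FALSE,
                              max_results = 10000) {
  ref <- config$reference
  junctions <- config$junctions
  chroms <- config$chroms
  per_chrom_cap <- if (forbid_same_chromosome_pair) 1L else 2L
  h_grid <- expand.grid(
    rep(list(0:per_chrom_cap), length(chroms)),
    KEEP.OUT.ATTRS = FALSE
  )
  names(h_grid) <- chroms
  totals <- rowSums(h_grid)
  h_grid <- h_grid[totals >= 1 & totals <= max_modified_homologues, , drop = FALSE]
  # deterministic: fewer modified homologues first, then lexicographic
  h_grid <- h_grid[order(rowSums(h_grid), apply(h_grid, 1, paste, collapse = "")), , drop = FALSE]

  jn_by_edge <- split(
    rep(junctions$id, 2),
    c(
      paste0(junctions$seg_a, ":", junctions$side_a),
      paste0(junctions$seg_b, ":", junctions$side_b)
    )
  )
  jn_partner <- function(jid, edge) {
    j <- junctions[junctions$id == jid, ]
    if (paste0(j$seg_a, ":", j$side_a) == edge) {
      list(seg = j$seg_b, side = j$side_b)
    } else {
      list(seg = j$seg_a, side = j$side_a)
    }
  }
  role <- setNames(ref$role, ref$id)
  results <- new.env()
  results$seen <- character()
  results$structures <- list()
  results$partial <- FALSE

  emit <- function(walks) {
    haps <- lapply(walks, function(w) {
      tibble(
        seg = vapply(w, `[[`, "", "seg"),
        orient = vapply(w, `[[`, 1L, "orient"),
        adj_in = vapply(w, function(x) x$adj %||% NA_character_, "")
      )
    })
    # drop haplotypes identical to their chromosome's reference walk
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
    if (st$key %in% results$seen) {
      return()
    }
    results$seen <- c(results$seen, st$key)
    results$structures[[length(results$structures) + 1]] <- st
  }

  dfs <- function(pool, jn_unused, starts, walks, walk, cur) {
    if (results$partial) {
      return()
    }
    if (is.null(cur)) {
      # start the next walk, or emit
      if (length(starts) == 0) {
        if (all(pool == 0) && length(jn_unused) == 0) {
          if (length(results$structures) >= max_results) {
            results$partial <- TRUE
            return()
          }
          emit(walks)
        }
        return()
      }
      s <- starts[[1]]
      if (pool[[s]] < 1) {
        return()
      }
      pool[[s]] <- pool[[s]] - 1L
      dfs(pool, jn_unused, starts[-1], walks,
        list(list(seg = s, orient = 1L, adj = NULL)),
        list(seg = s, orient = 1L)
      )
      return()
    }
    exit_edge <- paste0(cur$seg, ":", if (cur$orient > 0) "end" else "start")
    # reference adjacency
    nb <- ref_neighbour(ref, cur$seg, if (cur$orient > 0) "end" else "start")
    if (!is.na(nb) && pool[[nb]] >= 1) {
      ok <- TRUE
      if (role[[nb]] == "telomere_anchor" && cur$orient < 0) ok <- FALSE
      if (ok) {
        pool2 <- pool
        pool2[[nb]] <- pool2[[nb]] - 1L
        step <- list(seg = nb, orient = cur$orient, adj = "ref")
        walk2 <- c(walk, list(step))
        ch <- ref$chrom[match(nb, ref$id)]
        if (role[[nb]] == "telomere_anchor" &&
          nb == anchor_ids(ref, ch, "qter") && cur$orient > 0) {
          dfs(pool2, jn_unused, starts, c(walks, list(walk2)), NULL, NULL)
        } else {
          dfs(pool2, jn_unused, starts, walks, walk2, list(seg = nb, orient = cur$orient))
        }
      }
    }
    # junction adjacencies
    hits <- jn_by_edge[[exit_edge]]
    hits <- sort(intersect(hits, jn_unused))
    for (jid in hits) {
      p <- jn_partner(jid, exit_edge)
      t <- p$seg
      if (pool[[t]] < 1) next
      if (role[[t]] == "telomere_anchor") next
      orient_t <- if (p$side == "start") 1L else -1L
      pool2 <- pool
      pool2[[t]] <- pool2[[t]] - 1L
      step <- list(seg = t, orient = orient_t, adj = jid)
      dfs(pool2, setdiff(jn_unused, jid), starts, walks,
        c(walk, list(step)), list(seg = t, orient = orient_t))
    }
  }

  for (r in seq_len(nrow(h_grid))) {
    h <- unlist(h_grid[r, , drop = TRUE])
    names(h) <- chroms
    pool <- setNames(ref$gain + h[ref$chrom], ref$id)
    pool <- vapply(pool, as.integer, 0L)
    if (sum(pool[role[names(pool)] == "duplicated"]) <
      sum(ref$gain)) {
      next
    }
    starts <- unlist(lapply(sort(chroms), function(ch) {
      rep(anchor_ids(ref, ch, "pter"), h[[ch]])
    }))
    dfs(pool, junctions$id, as.list(starts), list(), NULL, NULL)
  }

  sts <- results$structures
  keys <- vapply(sts, `[[`, "", "key")
  ord <- order(keys)
  sts <- sts[ord]
  for (i in seq_along(sts)) sts[[i]]$label <- sprintf("Alt%d", i)
  out <- new_structure_set(sts, config)
  attr(out, "partial") <- results$partial
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
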