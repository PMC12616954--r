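# Spanning-molecule signatures: the left-context / spanned-copy /
# right-context triples a long molecule reveals when it completely spans one
# duplicated-segment copy, and their diagnostic power across candidate
# structures.

# Canonical form of a (left, target, right) oriented triple. Molecules are
# unoriented, so a signature equals its reversal with orientations flipped.
# Between the two forms we keep the one with more forward-oriented elements
# (tie: target forward); the display label omits orientation marks, which at
# this granularity keeps distinct classes distinct for all-direct contexts
# while printing inverted sub-resolution targets in reference order.
canonical_signature <- function(left, left_or, target, target_or, right, right_or) {
  a <- list(l = left, lo = left_or, t = target, to = target_or, r = right, ro = right_or)
  b <- list(
    l = right, lo = -right_or, t = target, to = -target_or,
    r = left, ro = -left_or
  )
  fwd <- function(x) {
    sum(c(
      if (x$l != "NML") x$lo > 0 else NA,
      x$to > 0,
      if (x$r != "NML") x$ro > 0 else NA
    ), na.rm = TRUE)
  }
  pick <- if (fwd(a) > fwd(b)) a else if (fwd(b) > fwd(a)) b else if (a$to > 0) a else b
  disp <- function(x) paste(x$l, x$t, x$r, sep = "-")
  om <- function(o) if (o > 0) "+" else "-"
  key <- paste0(
    pick$l, if (pick$l != "NML") om(pick$lo), "|",
    pick$t, om(pick$to), "|",
    pick$r, if (pick$r != "NML") om(pick$ro)
  )
  list(signature = disp(pick), key = key)
}

# Context on one side of copy i in a haplotype walk: NML if every adjacency
# out to the first visible copy is the reference adjacency traversed in the
# walk's local orientation, else the first visible segment (oriented).
walk_context <- function(hap, i, dir, visible) {
  n <- nrow(hap)
  abnormal <- FALSE
  j <- i
  repeat {
    jn <- j + dir
    if (jn < 1 || jn > n) {
      return(list(id = "NML", orient = 1L, abnormal = abnormal))
    }
    adj <- if (dir > 0) hap$adj_in[jn] else hap$adj_in[j]
    if (!is.na(adj) && adj != "ref") abnormal <- TRUE
    j <- jn
    if (visible[[hap$seg[j]]]) break
  }
  if (!abnormal) {
    return(list(id = "NML", orient = 1L, abnormal = FALSE))
  }
  list(id = hap$seg[j], orient = hap$orient[j], abnormal = TRUE)
}

#' Derive abnormal spanning signatures of a structure
#'
#' For each copy of each duplicated segment of size at least `resolution_bp`,
#' computes the left and right flanking context after collapsing segments
#' below the resolution. A context is `NML` when the flank continues along
#' the reference in the copy's own orientation; otherwise it names the first
#' resolvable segment encountered. Only abnormal signatures (at least one
#' non-NML context) are returned; fully reference-like copies are dropped.
#'
#' @param structure A `dup_structure`.
#' @param config A `dup_config`.
#' @param resolution_bp Minimum resolvable segment size (default 500 bp,
#'   the approximate resolving power of optical mapping).
#' @return A tibble: `label`, `target`, `target_orient`, `left`, `right`,
#'   `size`, `signature` (canonical display label), `key` (oriented key).
#' @export
derive_signatures <- function(structure, config, resolution_bp = 500) {
  ref <- config$reference
  visible <- setNames(ref$size >= resolution_bp, ref$id)
  role <- setNames(ref$role, ref$id)
  size <- setNames(ref$size, ref$id)
  rows <- list()
  for (hap in structure$haplotypes) {
    for (i in seq_len(nrow(hap))) {
      sg <- hap$seg[i]
      if (role[[sg]] != "duplicated" || !visible[[sg]]) next
      lc <- walk_context(hap, i, -1L, visible)
      rc <- walk_context(hap, i, +1L, visible)
      if (!lc$abnormal && !rc$abnormal) next
      cs <- canonical_signature(
        lc$id, lc$orient, sg, hap$orient[i], rc$id, rc$orient
      )
      rows[[length(rows) + 1]] <- tibble(
        label = structure$label, target = sg, target_orient = hap$orient[i],
        left = lc$id, right = rc$id, size = size[[sg]],
        signature = cs$signature, key = cs$key
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      label = character(), target = character(), target_orient = integer(),
      left = character(), right = character(), size = numeric(),
      signature = character(), key = character()
    ))
  }
  distinct(bind_rows(rows), .data$key, .keep_all = TRUE)
}

#' Signature-by-structure diagnostic matrix
#'
#' Maps each abnormal spanning signature to the set of candidate structures
#' whose derived signature set contains it, and lists each structure's
#' uniquely diagnostic signatures.
#'
#' @param structures A `dup_structure_set` (2 or more structures over one
#'   configuration).
#' @param config A `dup_config` (defaults to the set's attached config).
#' @param resolution_bp Minimum resolvable segment size.
#' @return A list of class `dup_diagnostic`: `matrix` (tibble `signature`,
#'   `target`, `size`, `structures` list-column, `n_structures`,
#'   `unique_to`), and `unique` (tibble `label`, `signatures` list-column).
#' @export
diagnostic_matrix <- function(structures, config = set_config(structures),
                              resolution_bp = 500) {
  sigs <- purrr::map_dfr(structures, derive_signatures,
    config = config, resolution_bp = resolution_bp
  )
  mat <- sigs %>%
    group_by(.data$signature, .data$target, .data$size) %>%
    summarise(structures = list(sort(unique(.data$label))), .groups = "drop") %>%
    mutate(
      n_structures = purrr::map_int(.data$structures, length),
      unique_to = purrr::map_chr(
        .data$structures,
        ~ if (length(.x) == 1) .x[[1]] else NA_character_
      )
    ) %>%
    arrange(.data$size, .data$signature)
  uni <- tibble(label = vapply(structures, `[[`, "", "label")) %>%
    mutate(signatures = purrr::map(.data$label, function(l) {
      sort(mat$signature[!is.na(mat$unique_to) & mat$unique_to == l])
    }))
  structure(list(matrix = mat, unique = uni), class = "dup_diagnostic")
}

#' @export
print.dup_diagnostic <- function(x, ...) {
  cat("<dup_diagnostic> ", nrow(x$matrix), " abnormal signature class(es)\n", sep = "")
  print(x$matrix %>% mutate(structures = purrr::map_chr(.data$structures, paste, collapse = ",")))
  invisible(x)
}

#' @method tidy dup_diagnostic
#' @export
tidy.dup_diagnostic <- function(x, ...) {
  x$matrix %>%
    tidyr::unnest_longer(col = "structures", values_to = "label") %>%
    select("signature", "target", "size", "label", "unique_to")
}

#' Segments whose spanning signatures distinguish two structures
#'
#' Lists the duplicated segments whose signature sets differ between two
#' candidate structures: a molecule completely spanning a copy of such a
#' segment (plus flanking labels) can discriminate the pair. An empty result
#' means the two structures are indistinguishable by spanning molecules at
#' this resolution.
#'
#' @param structure_a,structure_b Two `dup_structure` objects over one
#'   configuration.
#' @param config A `dup_config`.
#' @param resolution_bp Minimum resolvable segment size.
#' @return A tibble `seg`, `size`, sorted by size.
#' @export
required_spans <- function(structure_a, structure_b, config, resolution_bp = 500) {
  sa <- derive_signatures(structure_a, config, resolution_bp)
  sb <- derive_signatures(structure_b, config, resolution_bp)
  segtab <- config$segments
  out <- lapply(segtab$id, function(s) {
    ka <- sort(sa$key[sa$target == s])
    kb <- sort(sb$key[sb$target == s])
    if (identical(ka, kb)) {
      return(NULL)
    }
    tibble(seg = s, size = segtab$size[segtab$id == s])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(seg = character(), size = numeric()))
  }
  arrange(out, .data$size)
}
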