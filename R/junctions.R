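# Abnormal break junctions: the oriented `±seg:±seg` notation, normalization
# to unordered breakend pairs, VCF breakend import, configuration validation.

# Parse one "<sign><seg>:<sign><seg>" token into an unordered breakend pair.
# The notation means: a copy of the first segment traversed with the given
# orientation is immediately followed by a copy of the second in its
# orientation. Exiting a forward copy uses its end edge, a reverse copy its
# start edge; entering forward uses the start edge, reverse the end edge.
parse_junction_token <- function(token, segment_ids) {
  token <- gsub("[−‒–]", "-", gsub("\\s", "", token))
  m <- regmatches(token, regexec("^([+-])([^:]+):([+-])(.+)$", token))[[1]]
  if (length(m) != 5) {
    abort(sprintf("malformed junction token: '%s'", token))
  }
  sa <- m[3]
  sb <- m[5]
  for (s in c(sa, sb)) {
    if (!s %in% segment_ids) {
      abort(sprintf("junction token '%s' names unknown segment '%s'", token, s))
    }
  }
  side_a <- if (m[2] == "+") "end" else "start"
  side_b <- if (m[4] == "+") "start" else "end"
  normalize_breakends(sa, side_a, sb, side_b)
}

normalize_breakends <- function(seg_a, side_a, seg_b, side_b) {
  a <- paste0(seg_a, ":", side_a)
  b <- paste0(seg_b, ":", side_b)
  if (a <= b) {
    list(seg_a = seg_a, side_a = side_a, seg_b = seg_b, side_b = side_b)
  } else {
    list(seg_a = seg_b, side_a = side_b, seg_b = seg_a, side_b = side_a)
  }
}

junction_key <- function(j) {
  paste0(j$seg_a, ":", j$side_a, "|", j$seg_b, ":", j$side_b)
}

#' Parse a break-junction table
#'
#' Reads a tab-separated junction table with columns `id`, `junction`,
#' `homology_bp` (and optionally `note`), where `junction` uses the oriented
#' `±seg:±seg` notation. Junctions are normalized to unordered breakend
#' pairs, so `+X:+Y` and `-Y:-X` parse to the same junction.
#'
#' @param text TSV text or a path to a file.
#' @param segments Segments tibble the junction endpoints must refer to.
#' @return A tibble with columns `id`, `junction` (the input token), `seg_a`,
#'   `side_a`, `seg_b`, `side_b` (normalized breakends), `homology_bp`,
#'   `note`, `key` (canonical breakend-pair key).
#' @export
parse_junctions <- function(text, segments) {
  lines <- read_table_lines(text)
  if (length(lines) == 0) {
    return(empty_junctions())
  }
  header <- strsplit(lines[[1]], "\t")[[1]]
  required <- c("id", "junction", "homology_bp")
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(paste0("junction table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t")[[1]]
    f <- c(f, rep("", max(0, length(header) - length(f))))
    rec <- setNames(as.list(f[seq_along(header)]), header)
    be <- parse_junction_token(rec$junction, segments$id)
    hom <- clean_int(rec$homology_bp)
    if (is.na(hom) || hom < 0) {
      abort(sprintf("junction table row %d (%s): bad homology_bp", i, rec$id))
    }
    tibble(
      id = rec$id, junction = rec$junction,
      seg_a = be$seg_a, side_a = be$side_a,
      seg_b = be$seg_b, side_b = be$side_b,
      homology_bp = hom,
      note = if (!is.null(rec$note)) rec$note else ""
    )
  })
  out <- bind_rows(rows)
  out$key <- paste0(out$seg_a, ":", out$side_a, "|", out$seg_b, ":", out$side_b)
  out
}

empty_junctions <- function() {
  tibble(
    id = character(), junction = character(),
    seg_a = character(), side_a = character(),
    seg_b = character(), side_b = character(),
    homology_bp = numeric(), note = character(), key = character()
  )
}

#' Read a junction table from a file
#' @param path Path to a TSV junction table.
#' @param segments Segments tibble.
#' @return A junctions tibble; see [parse_junctions()].
#' @export
read_junctions <- function(path, segments) parse_junctions(path, segments)

#' Import junctions from VCF breakend (BND) records
#'
#' Reads Manta-style paired BND records (bracket ALT notation, mates resolved
#' by INFO `MATEID` or by reciprocal coordinates) and maps each mate pair to
#' one junction whose breakends are matched to the nearest duplicated-segment
#' boundary within `tolerance` bp. Unpaired records and breakends farther
#' than the tolerance from any boundary are skipped with a warning.
#'
#' @param vcf Path to a VCF file, or a character scalar of VCF text.
#' @param segments Segments tibble.
#' @param tolerance Maximum distance (bp) between a breakend and a segment
#'   boundary (default 10).
#' @return A junctions tibble; see [parse_junctions()].
#' @export
import_vcf_bnd <- function(vcf, segments, tolerance = 10) {
  if (length(vcf) == 1 && grepl("\n", vcf)) {
    path <- tempfile(fileext = ".vcf")
    writeLines(vcf, path)
    vcf <- path
  }
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressMessages(vcfR::read.vcfR(vcf, verbose = FALSE))
    fm <- vcfR::getFIX(v)
    if (is.null(dim(fm))) fm <- t(as.matrix(fm)) # single-record VCF
    fix <- as.data.frame(fm, stringsAsFactors = FALSE)
    mateid <- vcfR::extract.info(v, element = "MATEID")
    fix$INFO <- mateid[seq_len(nrow(fix))]
  } else {
    lines <- readLines(vcf, warn = FALSE)
    lines <- lines[!grepl("^#", lines)]
    parts <- strsplit(lines, "\t")
    fix <- data.frame(
      CHROM = vapply(parts, `[`, "", 1), POS = vapply(parts, `[`, "", 2),
      ID = vapply(parts, `[`, "", 3), REF = vapply(parts, `[`, "", 4),
      ALT = vapply(parts, `[`, "", 5), stringsAsFactors = FALSE
    )
    info <- vapply(parts, `[`, "", 8)
    m <- regmatches(info, regexec("MATEID=([^;]+)", info))
    fix$INFO <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  bnd <- fix[grepl("[][]", fix$ALT), , drop = FALSE]
  if (nrow(bnd) == 0) {
    return(empty_junctions())
  }
  recs <- lapply(seq_len(nrow(bnd)), function(i) {
    alt <- bnd$ALT[i]
    m <- regmatches(alt, regexec("([][])([^:]+):([0-9]+)([][])", alt))[[1]]
    if (length(m) != 5) {
      return(NULL)
    }
    # REF base before the bracket (t[p[ / t]p]) => local sequence extends
    # left of POS, i.e. this breakend sits at a segment END edge.
    list(
      id = bnd$ID[i], chrom = bnd$CHROM[i], pos = as.numeric(bnd$POS[i]),
      mate_chrom = m[3], mate_pos = as.numeric(m[4]),
      ends_here = !grepl("^[][]", alt),
      mateid = bnd$INFO[i]
    )
  })
  recs <- Filter(Negate(is.null), recs)
  byid <- setNames(recs, vapply(recs, `[[`, "", "id"))
  used <- character()
  out <- list()
  for (r in recs) {
    if (r$id %in% used) next
    mate <- NULL
    if (!is.na(r$mateid) && r$mateid %in% names(byid)) {
      mate <- byid[[r$mateid]]
    } else {
      for (q in recs) {
        if (q$id != r$id && q$chrom == r$mate_chrom &&
          abs(q$pos - r$mate_pos) <= 1 && r$chrom == q$mate_chrom) {
          mate <- q
          break
        }
      }
    }
    if (is.null(mate)) {
      warn(sprintf("unpaired BND record %s skipped", r$id))
      used <- c(used, r$id)
      next
    }
    used <- c(used, r$id, mate$id)
    ea <- match_boundary(r$chrom, r$pos, r$ends_here, segments, tolerance)
    eb <- match_boundary(mate$chrom, mate$pos, mate$ends_here, segments, tolerance)
    if (is.null(ea) || is.null(eb)) {
      warn(sprintf("BND pair %s/%s: breakend not within %d bp of a segment boundary; skipped",
        r$id, mate$id, tolerance))
      next
    }
    be <- normalize_breakends(ea$seg, ea$side, eb$seg, eb$side)
    out[[length(out) + 1]] <- tibble(
      id = paste0(r$id, "_", mate$id), junction = "",
      seg_a = be$seg_a, side_a = be$side_a,
      seg_b = be$seg_b, side_b = be$side_b,
      homology_bp = 0, note = "imported from VCF BND"
    )
  }
  if (length(out) == 0) {
    return(empty_junctions())
  }
  res <- bind_rows(out)
  res$key <- paste0(res$seg_a, ":", res$side_a, "|", res$seg_b, ":", res$side_b)
  res
}

# A breakend that "ends here" (sequence extends to the left of pos) sits at a
# segment end edge; one that "starts here" sits at a start edge.
match_boundary <- function(chrom, pos, ends_here, segments, tolerance) {
  s <- segments[segments$chrom == chrom, ]
  if (nrow(s) == 0) {
    return(NULL)
  }
  coord <- if (ends_here) s$end else s$start
  d <- abs(coord - pos)
  i <- which.min(d)
  if (d[i] > tolerance) {
    return(NULL)
  }
  list(seg = s$id[i], side = if (ends_here) "end" else "start")
}

#' Validate a segment/junction configuration
#'
#' Checks that every junction endpoint is a duplicated-segment edge, that
#' every duplicated segment has gain >= 1, and flags duplicated segments
#' touched by no junction.
#'
#' @param segments Segments tibble.
#' @param junctions Junctions tibble.
#' @return A tibble of violations (`kind`, `subject`, `message`); zero rows
#'   when the configuration is clean.
#' @export
validate_configuration <- function(segments, junctions) {
  issues <- list()
  dup_ids <- segments$id[segments$role == "duplicated" | segments$gain > 0]
  for (i in seq_len(nrow(junctions))) {
    for (s in c(junctions$seg_a[i], junctions$seg_b[i])) {
      if (!s %in% segments$id) {
        issues[[length(issues) + 1]] <- tibble(
          kind = "unknown_segment", subject = junctions$id[i],
          message = sprintf("junction %s names unknown segment %s", junctions$id[i], s)
        )
      } else if (!s %in% dup_ids) {
        issues[[length(issues) + 1]] <- tibble(
          kind = "non_duplicated_endpoint", subject = junctions$id[i],
          message = sprintf("junction %s endpoint %s is not a duplicated segment", junctions$id[i], s)
        )
      }
    }
  }
  zero_gain <- segments$id[segments$role == "duplicated" & segments$gain < 1]
  for (s in zero_gain) {
    issues[[length(issues) + 1]] <- tibble(
      kind = "zero_gain", subject = s,
      message = sprintf("duplicated segment %s has gain 0", s)
    )
  }
  touched <- unique(c(junctions$seg_a, junctions$seg_b))
  lonely <- setdiff(segments$id[segments$gain > 0], touched)
  for (s in lonely) {
    issues[[length(issues) + 1]] <- tibble(
      kind = "untouched_segment", subject = s,
      message = sprintf("duplicated segment %s is touched by no junction", s)
    )
  }
  if (length(issues) == 0) {
    return(tibble(kind = character(), subject = character(), message = character()))
  }
  bind_rows(issues)
}
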