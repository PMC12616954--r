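# Duplication segments: parsing, validation, coordinate arithmetic.

# Strip thousands separators and unicode minus signs from a numeric field.
clean_int <- function(x) {
  x <- gsub("[,  ]", "", x)
  x <- gsub("[−‒–]", "-", x)
  suppressWarnings(as.numeric(x))
}

#' Parse a duplication-segment table
#'
#' Reads a tab-separated table of duplicated segments with columns
#' `id`, `chrom`, `start`, `end`, `gain` (and optionally `role`, `note`).
#' Coordinates are 1-based inclusive. Numeric fields may contain thousands
#' separators; they are accepted on input and never emitted.
#'
#' @param text Character scalar holding the TSV text, or a path to a file.
#' @return A tibble with one row per segment, in input order: columns
#'   `id`, `chrom`, `start`, `end`, `gain`, `role`, `note`, plus `size`
#'   (`end - start + 1`).
#' @examples
#' parse_segments("id\tchrom\tstart\tend\tgain\nD1\tchrA\t1001\t2000\t1\n")
#' @export
parse_segments <- function(text) {
  lines <- read_table_lines(text)
  if (length(lines) == 0) {
    return(empty_segments())
  }
  header <- strsplit(lines[[1]], "\t")[[1]]
  required <- c("id", "chrom", "start", "end", "gain")
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(paste0("segment table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  body <- lines[-1]
  if (length(body) == 0) {
    return(empty_segments())
  }
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t")[[1]]
    f <- c(f, rep("", max(0, length(header) - length(f))))
    rec <- setNames(as.list(f[seq_along(header)]), header)
    start <- clean_int(rec$start)
    end <- clean_int(rec$end)
    gain <- clean_int(rec$gain)
    if (is.na(start) || is.na(end) || is.na(gain)) {
      abort(sprintf("segment table row %d (%s): non-numeric coordinate or gain", i, rec$id))
    }
    if (start > end) {
      abort(sprintf("segment table row %d (%s): start > end", i, rec$id))
    }
    tibble(
      id = rec$id, chrom = rec$chrom, start = start, end = end,
      gain = as.integer(gain),
      role = if (!is.null(rec$role) && nzchar(rec$role)) rec$role else "duplicated",
      note = if (!is.null(rec$note)) rec$note else ""
    )
  })
  out <- bind_rows(rows)
  if (anyDuplicated(out$id)) {
    abort("segment ids must be unique")
  }
  check_no_overlap(out)
  out$size <- out$end - out$start + 1
  out
}

empty_segments <- function() {
  tibble(
    id = character(), chrom = character(), start = numeric(), end = numeric(),
    gain = integer(), role = character(), note = character(), size = numeric()
  )
}

check_no_overlap <- function(segments) {
  dup <- segments[segments$gain > 0 | segments$role == "duplicated", ]
  for (ch in unique(dup$chrom)) {
    s <- dup[dup$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      abort(sprintf("duplicated segments overlap on %s", ch))
    }
  }
  invisible(segments)
}

read_table_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  }
  lines <- trimws(lines, which = "right")
  lines[!grepl("^\\s*#", lines) & nzchar(lines)]
}

#' Read a segment table from a file
#' @param path Path to a tab-separated segment table.
#' @return A segments tibble; see [parse_segments()].
#' @export
read_segments <- function(path) parse_segments(path)

#' Segment sizes under the 1-based inclusive convention
#'
#' @param segments A segments tibble (see [parse_segments()]).
#' @return The input with a `size` column equal to `end - start + 1`.
#' @examples
#' seg <- parse_segments("id\tchrom\tstart\tend\tgain\nD1\tchrA\t5\t5\t1\n")
#' segment_size(seg)$size # 1
#' @export
segment_size <- function(segments) {
  stopifnot(all(c("start", "end") %in% names(segments)))
  if (any(segments$start > segments$end)) {
    abort("segment with start > end")
  }
  segments$size <- segments$end - segments$start + 1
  segments
}

#' Write segments as a TSV table
#' @param segments Segments tibble.
#' @param path Output path; if `NULL`, the TSV text is returned.
#' @return The path (invisibly) or the TSV text.
#' @export
write_segments <- function(segments, path = NULL) {
  header <- "id\tchrom\tstart\tend\tgain\trole\tnote"
  rows <- sprintf(
    "%s\t%s\t%d\t%d\t%d\t%s\t%s",
    segments$id, segments$chrom, as.integer(segments$start),
    as.integer(segments$end), segments$gain, segments$role, segments$note
  )
  txt <- paste(c(header, rows), collapse = "\n")
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Export segments to BED
#'
#' Converts the 1-based inclusive segment coordinates to BED's 0-based
#' half-open convention at this boundary (start - 1, end unchanged).
#'
#' @param segments Segments tibble.
#' @param path Output path; if `NULL` the BED text is returned.
#' @return The path (invisibly) or the BED text.
#' @export
export_bed <- function(segments, path = NULL) {
  rows <- sprintf(
    "%s\t%d\t%d\t%s\t%d",
    segments$chrom, as.integer(segments$start) - 1L, as.integer(segments$end),
    segments$id, segments$gain
  )
  txt <- paste(rows, collapse = "\n")
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(path)
}
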