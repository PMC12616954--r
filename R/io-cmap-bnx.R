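# Minimal CMAP / BNX text dialects for label maps and molecules.
#
# CMAP: comment header, then tab-separated
#   CMapId ContigLength NumSites SiteID LabelChannel Position
# one row per site (single channel), positions as one-decimal floats.
#
# BNX: "# BNX File Version 1.2"-style header; per molecule a `0` line
# (id, length) and a `1` line (label positions terminated by the length).

#' Write label maps to a CMAP file
#' @param maps A `label_map` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(maps, path) {
  if (inherits(maps, "label_map")) maps <- list(maps)
  lines <- c(
    "# CMAP File Version:\t0.2",
    "# Label Channels:\t1",
    "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition",
    "#f int\tfloat\tint\tint\tint\tfloat"
  )
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    n <- length(m$positions)
    lines <- c(lines, sprintf("# map %d\t%s", i, m$map_id))
    if (n > 0) {
      lines <- c(lines, sprintf(
        "%d\t%.1f\t%d\t%d\t1\t%.1f", i, m$length, n, seq_len(n), m$positions
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read label maps from a CMAP file
#' @param path Path to a CMAP file written in the package's dialect.
#' @return A list of `label_map` (map ids recovered from the `# map` comment
#'   lines when present, else `cmap_<id>`).
#' @export
read_cmap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idmap <- list()
  for (l in grep("^# map ", lines, value = TRUE)) {
    f <- strsplit(sub("^# map ", "", l), "\t")[[1]]
    if (length(f) == 2) idmap[[f[1]]] <- f[2]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    return(list())
  }
  parts <- strsplit(body, "\t")
  bad <- which(vapply(parts, length, 0L) != 6)
  if (length(bad) > 0) {
    abort(sprintf("malformed CMAP record at data line %d", bad[1]))
  }
  df <- data.frame(
    id = vapply(parts, `[`, "", 1), len = as.numeric(vapply(parts, `[`, "", 2)),
    nsites = as.integer(vapply(parts, `[`, "", 3)),
    pos = as.numeric(vapply(parts, `[`, "", 6)), stringsAsFactors = FALSE
  )
  out <- lapply(split(df, df$id), function(d) {
    if (nrow(d) != d$nsites[1]) {
      abort(sprintf("CMAP map %s: NumSites %d but %d site rows", d$id[1], d$nsites[1], nrow(d)))
    }
    mid <- idmap[[d$id[1]]] %||% paste0("cmap_", d$id[1])
    new_label_map(mid, d$len[1], sort(d$pos), provenance = "cmap")
  })
  out[order(as.integer(names(out)))]
}

#' Write molecules to a BNX file
#' @param molecules An `ogm_molecules` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bnx <- function(molecules, path) {
  lines <- c(
    "# BNX File Version:\t1.2",
    "# Label Channels:\t1",
    "#0h LabelChannel\tMoleculeId\tLength",
    "#1h LabelChannel\tLabelPositions[N]"
  )
  for (i in seq_len(nrow(molecules))) {
    lines <- c(
      lines,
      sprintf("0\t%d\t%.1f", i, molecules$length[i]),
      paste(c("1", sprintf("%.1f", c(molecules$labels[[i]], molecules$length[i]))),
        collapse = "\t"
      )
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read molecules from a BNX file
#' @param path Path to a BNX file in the package's dialect.
#' @return An `ogm_molecules` tibble (truth columns NA).
#' @export
read_bnx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- list()
  i <- 1
  while (i <= length(body)) {
    f0 <- strsplit(body[i], "\t")[[1]]
    if (f0[1] != "0" || length(f0) < 3) {
      abort(sprintf("malformed BNX 0-line at data line %d", i))
    }
    if (i + 1 > length(body)) {
      abort(sprintf("BNX molecule at data line %d has no 1-line", i))
    }
    f1 <- strsplit(body[i + 1], "\t")[[1]]
    if (f1[1] != "1") {
      abort(sprintf("malformed BNX 1-line at data line %d", i + 1))
    }
    len <- as.numeric(f0[3])
    pos <- as.numeric(f1[-1])
    labels <- pos[-length(pos)] # last entry is the molecule length terminator
    rows[[length(rows) + 1]] <- list(
      molecule_id = sprintf("M%06d", as.integer(f0[2])), length = len,
      labels = labels
    )
    i <- i + 2
  }
  out <- tibble(
    molecule_id = vapply(rows, `[[`, "", "molecule_id"),
    length = vapply(rows, `[[`, 1, "length"),
    labels = lapply(rows, `[[`, "labels"),
    map_id = NA_character_, src_start = NA_real_, src_end = NA_real_,
    reversed = NA, chimera = NA, chimera_map_id = NA_character_
  )
  class(out) <- c("ogm_molecules", class(out))
  out
}
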