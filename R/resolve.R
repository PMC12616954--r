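# Structure resolution from classified molecule counts, and spanning-yield
# power analysis: how many informative molecules to expect for a duplication
# of a given size under a molecule-length distribution.

#' Resolve candidate structures from observed signature counts
#'
#' Set-logical exclusion: a candidate structure is excluded as soon as an
#' observed abnormal signature class (with at least `min_support` molecules)
#' is absent from its derived signature set; candidates never excluded are
#' supported. For every still-tied pair of supported structures the report
#' lists the segments whose spanning would decide the pair
#' ([required_spans()]); when the smallest such segment exceeds
#' `feasibility_bp` the report notes that an orthogonal method (e.g. FISH)
#' is advisable.
#'
#' @param counts A tibble with columns `signature` and `n_molecules` (as
#'   produced by [classify_set()]), or a named numeric vector.
#' @param structures A `dup_structure_set` of candidates.
#' @param config A `dup_config` (defaults to the set's attached config).
#' @param resolution_bp Minimum resolvable segment size.
#' @param min_support Minimum molecule count for a class to drive exclusion
#'   (default 1; the source analyses acted on 3-5 molecules, and counts
#'   below 3 deserve reporting rather than auto-deciding).
#' @param feasibility_bp Span size above which the tie note recommends an
#'   orthogonal method (default 550000, a practical single-molecule limit).
#' @return A `dup_resolution` list: `candidates`, `observed`, `status`
#'   (tibble `label`, `status`, `missing_signatures`), `supported`,
#'   `unresolved_pairs` (tibble `label_a`, `label_b`, `required` list-col,
#'   `note`), `contradictory`.
#' @export
resolve_structures <- function(counts, structures, config = set_config(structures),
                               resolution_bp = 500, min_support = 1,
                               feasibility_bp = 550000) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble(signature = names(counts), n_molecules = as.numeric(counts))
  }
  stopifnot(all(c("signature", "n_molecules") %in% names(counts)))
  observed <- counts$signature[counts$n_molecules >= min_support]
  sig_sets <- lapply(structures, function(st) {
    derive_signatures(st, config, resolution_bp)$signature
  })
  status <- purrr::imap_dfr(sig_sets, function(sigs, label) {
    missing <- setdiff(observed, sigs)
    tibble(
      label = label,
      status = if (length(missing) > 0) "excluded" else "supported",
      missing_signatures = list(missing)
    )
  })
  supported <- status$label[status$status == "supported"]
  contradictory <- length(supported) == 0 && length(observed) > 0
  pairs <- list()
  if (length(supported) >= 2) {
    for (p in utils::combn(supported, 2, simplify = FALSE)) {
      req <- required_spans(
        structures[[p[1]]], structures[[p[2]]], config, resolution_bp
      )
      note <- if (nrow(req) == 0) {
        "indistinguishable by spanning molecules"
      } else if (min(req$size) > feasibility_bp) {
        sprintf(
          "smallest deciding span (%s, %s bp) exceeds %s bp; an orthogonal method (e.g. FISH) is advisable",
          req$seg[which.min(req$size)], format(min(req$size), big.mark = ","),
          format(feasibility_bp, big.mark = ",")
        )
      } else {
        sprintf(
          "decidable by molecules spanning %s (%s bp)",
          req$seg[which.min(req$size)], format(min(req$size), big.mark = ",")
        )
      }
      pairs[[length(pairs) + 1]] <- tibble(
        label_a = p[1], label_b = p[2], required = list(req), note = note
      )
    }
  }
  if (length(supported) >= 2) {
    status$status[status$label %in% supported &
      vapply(status$label, function(l) {
        any(vapply(pairs, function(pp) {
          (pp$label_a == l || pp$label_b == l) && nrow(pp$required[[1]]) == 0
        }, TRUE))
      }, TRUE)] <- "indistinguishable"
  }
  structure(
    list(
      candidates = vapply(structures, `[[`, "", "label"),
      observed = counts[counts$n_molecules >= min_support, , drop = FALSE],
      status = status,
      supported = supported,
      unresolved_pairs = if (length(pairs)) bind_rows(pairs) else
        tibble(label_a = character(), label_b = character(), required = list(), note = character()),
      contradictory = contradictory,
      min_support = min_support,
      resolution_bp = resolution_bp
    ),
    class = "dup_resolution"
  )
}

#' @export
print.dup_resolution <- function(x, ...) {
  cat("<dup_resolution>\n")
  if (x$contradictory) {
    cat("  no consistent candidate: observed signatures fit no single structure\n")
  } else {
    cat("  supported: ", paste(x$supported, collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$unresolved_pairs) > 0) {
    for (i in seq_len(nrow(x$unresolved_pairs))) {
      cat(
        "  tie ", x$unresolved_pairs$label_a[i], "/", x$unresolved_pairs$label_b[i],
        ": ", x$unresolved_pairs$note[i], "\n",
        sep = ""
      )
    }
  }
  invisible(x)
}

#' @method tidy dup_resolution
#' @export
tidy.dup_resolution <- function(x, ...) x$status

#' @method glance dup_resolution
#' @export
glance.dup_resolution <- function(x, ...) {
  tibble(
    n_candidates = length(x$candidates),
    n_supported = length(x$supported),
    n_observed_classes = nrow(x$observed),
    contradictory = x$contradictory,
    resolved = length(x$supported) == 1
  )
}

# Length models ---------------------------------------------------------------

#' Geometric-bin molecule length model
#'
#' Molecule lengths follow the empirical shape of optical-map molecule sets:
#' above a minimum length, the number of molecules falls by a constant
#' factor per 100 kb bin. A length is `min_bp + bin_bp * K + U` with
#' `K ~ Geometric(1 - survival)` and `U ~ Uniform(0, bin_bp)`.
#'
#' @param survival Per-bin survival ratio in (0, 1) (default 0.5, inside the
#'   35-55 percent per-bin decline band observed on real molecule sets).
#' @param min_bp Minimum molecule length (default 150000).
#' @param bin_bp Bin width (default 100000).
#' @return An object of class `length_model`.
#' @export
length_model_geometric <- function(survival = 0.5, min_bp = 150000, bin_bp = 100000) {
  stopifnot(survival > 0, survival < 1, min_bp >= 0, bin_bp > 0)
  structure(
    list(kind = "geometric", survival = survival, min_bp = min_bp, bin_bp = bin_bp),
    class = "length_model"
  )
}

#' Empirical molecule length model
#' @param lengths Numeric vector of molecule lengths (bp).
#' @return An object of class `length_model`.
#' @export
length_model_empirical <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  structure(list(kind = "empirical", lengths = as.numeric(lengths)), class = "length_model")
}

#' Draw molecule lengths from a length model
#' @param model A `length_model`.
#' @param n Number of lengths.
#' @return Numeric vector of lengths (bp).
#' @export
draw_lengths <- function(model, n) {
  if (model$kind == "empirical") {
    return(sample(model$lengths, n, replace = TRUE))
  }
  k <- rgeom(n, prob = 1 - model$survival)
  model$min_bp + model$bin_bp * k + runif(n, 0, model$bin_bp)
}

mean_length <- function(model) {
  if (model$kind == "empirical") {
    return(mean(model$lengths))
  }
  model$min_bp + model$bin_bp * (model$survival / (1 - model$survival)) + model$bin_bp / 2
}

# E[max(0, L - s)] under the model, exactly (geometric: closed form per bin).
expected_excess <- function(model, s) {
  if (model$kind == "empirical") {
    return(mean(pmax(0, model$lengths - s)))
  }
  p <- 1 - model$survival
  b <- model$bin_bp
  total <- 0
  k <- 0
  repeat {
    pk <- p * model$survival^k
    lo <- model$min_bp + b * k
    hi <- lo + b
    contrib <- if (s <= lo) {
      (lo + hi) / 2 - s
    } else if (s >= hi) {
      0
    } else {
      (hi - s)^2 / (2 * b)
    }
    total <- total + pk * contrib
    k <- k + 1
    if (pk < 1e-12 && lo > s) break
    if (k > 10000) break
  }
  total
}

#' Expected number of molecules spanning a duplication
#'
#' A molecule is informative for a duplicated segment of size `D` only if it
#' spans the whole segment plus a flanking margin `F` on each side, i.e. an
#' interval of `S = D + 2F`. For molecules dropped uniformly on a genome of
#' length `G`, a molecule of length `L` spans the interval with probability
#' `max(0, L - S) / G`, so the expected count is the sum of that quantity
#' over molecules (closed form), or a Monte-Carlo placement simulation.
#'
#' @param D Duplication size (bp).
#' @param F_bp Flanking margin (bp); the bp-equivalent of the minimum flank
#'   label requirement (defaults to 4 labels x 5000 bp mean spacing).
#' @param molecules Numeric vector of molecule lengths, or a `length_model`.
#' @param genome_length Genome (or map) length the molecules are spread over.
#' @param n_molecules Number of molecules when `molecules` is a model.
#' @param method `"closed_form"` or `"monte_carlo"`.
#' @param seed RNG seed for Monte-Carlo mode.
#' @param nrep Monte-Carlo replicates of the placement experiment (default
#'   200); the estimate is the mean spanning count with its standard error.
#' @return A tibble (class `dup_power`): `D`, `F_bp`, `S`, `expected_count`,
#'   `se` (NA for the closed form), `method`.
#' @export
expected_spanning <- function(D, F_bp = 4 * 5000, molecules, genome_length,
                              n_molecules = NULL,
                              method = c("closed_form", "monte_carlo"),
                              seed = 1, nrep = 200) {
  method <- match.arg(method)
  stopifnot(genome_length > 0)
  S <- D + 2 * F_bp
  parametric <- inherits(molecules, "length_model")
  if (parametric && is.null(n_molecules)) {
    abort("n_molecules is required with a length_model")
  }
  if (method == "closed_form") {
    ev <- if (parametric) {
      n_molecules * expected_excess(molecules, S) / genome_length
    } else {
      sum(pmax(0, as.numeric(molecules) - S)) / genome_length
    }
    se <- NA_real_
  } else {
    # place every molecule uniformly on [0, G] and count those spanning a
    # fixed interval of length S; repeat nrep times
    x0 <- (genome_length - S) / 2
    if (x0 < 0) abort("spanning interval exceeds genome_length")
    counts <- with_seed(seed, {
      vapply(seq_len(nrep), function(r) {
        L <- if (parametric) {
          draw_lengths(molecules, n_molecules)
        } else {
          as.numeric(molecules)
        }
        starts <- runif(length(L), 0, genome_length)
        sum(starts <= x0 & starts + L >= x0 + S)
      }, 0)
    })
    ev <- mean(counts)
    se <- stats::sd(counts) / sqrt(nrep)
  }
  out <- tibble(
    D = D, F_bp = F_bp, S = S, expected_count = ev, se = se, method = method
  )
  class(out) <- c("dup_power", class(out))
  out
}

#' Largest duplication size resolvable at a given coverage
#'
#' Bisects (to 1 kb) for the largest duplication size `D` whose expected
#' informative spanning-molecule count is at least `min_count`, given a
#' molecule length model and total coverage. The expected count is strictly
#' decreasing in `D`, so the bisection is exact to the granularity. The
#' returned object records its inputs: the estimate is a property of the
#' configured molecule-length distribution and coverage, not of any
#' instrument in general.
#'
#' @param length_model A `length_model`.
#' @param coverage Total molecule coverage (fold) of the locus.
#' @param F_bp Flanking margin (bp) as in [expected_spanning()].
#' @param min_count Minimum expected informative molecule count (default 1).
#' @param max_bp Upper bracket for the search (default 5e6).
#' @return A tibble: `size_limit_bp`, `min_count`, `coverage`, `F_bp`,
#'   `survival`, `min_length_bp`.
#' @export
estimate_size_limit <- function(length_model, coverage, F_bp = 4 * 5000,
                                min_count = 1, max_bp = 5e6) {
  mu <- mean_length(length_model)
  expected_at <- function(D) {
    # coverage-normalised: n molecules per bp of genome = coverage / mu
    coverage * expected_excess(length_model, D + 2 * F_bp) / mu
  }
  lo <- 0
  hi <- max_bp
  if (expected_at(lo) < min_count) {
    lo <- -1
    hi <- 0
  } else {
    while (expected_at(hi) >= min_count && hi < 1e9) hi <- hi * 2
  }
  while (hi - lo > 1000) {
    mid <- (lo + hi) / 2
    if (expected_at(mid) >= min_count) lo <- mid else hi <- mid
  }
  tibble(
    size_limit_bp = max(0, round(lo / 1000) * 1000),
    min_count = min_count, coverage = coverage, F_bp = F_bp,
    survival = if (length_model$kind == "geometric") length_model$survival else NA_real_,
    min_length_bp = if (length_model$kind == "geometric") length_model$min_bp else NA_real_
  )
}

#' Molecule-count decline across length bins
#'
#' Histograms molecule lengths into fixed-width bins above a floor and
#' reports the percent decline between consecutive occupied bins.
#'
#' @param molecule_lengths Numeric vector (bp).
#' @param bin_bp Bin width (default 100 kb).
#' @param floor_bp Only lengths above this floor are binned (default 200 kb).
#' @return A tibble: `bin_start`, `bin_end`, `count`, `decline_pct`
#'   (NA for the first bin).
#' @export
bin_decline <- function(molecule_lengths, bin_bp = 100000, floor_bp = 200000) {
  x <- molecule_lengths[molecule_lengths > floor_bp]
  if (length(x) == 0) {
    return(tibble(
      bin_start = numeric(), bin_end = numeric(),
      count = integer(), decline_pct = numeric()
    ))
  }
  bin <- floor((x - floor_bp) / bin_bp)
  tab <- table(factor(bin, levels = 0:max(bin)))
  counts <- as.integer(tab)
  n <- length(counts)
  decline <- c(NA_real_, 100 * (1 - counts[-1] / counts[-n]))
  tibble(
    bin_start = floor_bp + bin_bp * (seq_len(n) - 1),
    bin_end = floor_bp + bin_bp * seq_len(n),
    count = counts,
    decline_pct = decline
  )
}

#' Molecule length N50
#'
#' The largest length `L` such that molecules of length at least `L`
#' together contain at least half of all molecule bases.
#'
#' @param molecule_lengths Numeric vector (bp), non-empty.
#' @return N50 in bp.
#' @examples
#' n50(c(300, 200, 100)) # 300: the 300-bp molecule alone holds half the bases
#' @export
n50 <- function(molecule_lengths) {
  if (length(molecule_lengths) == 0) {
    abort("n50 of an empty molecule set is undefined")
  }
  l <- sort(as.numeric(molecule_lengths), decreasing = TRUE)
  half <- sum(l) / 2
  l[which(cumsum(l) >= half)[1]]
}
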