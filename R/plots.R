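# ggplot2 displays for counts tables, power curves and molecule length
# distributions.

#' @method autoplot dup_counts
#' @export
autoplot.dup_counts <- function(object, ...) {
  d <- object$counts
  d$signature <- factor(d$signature, levels = d$signature[order(d$size)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signature, y = .data$n_molecules)) +
    ggplot2::geom_col(fill = "#2b6cb0") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "abnormal spanning signature (ordered by target size)",
      y = "informative molecules"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot dup_power
#' @export
autoplot.dup_power <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$D / 1000, y = .data$expected_count)) +
    ggplot2::geom_line(color = "#2b6cb0") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "duplication size (kb)",
      y = "expected informative spanning molecules"
    ) +
    ggplot2::theme_minimal()
}

#' Molecule length distribution with bin-decline overlay
#'
#' @param molecules An `ogm_molecules` tibble (or numeric lengths).
#' @param bin_bp Bin width (default 100 kb).
#' @param floor_bp Floor above which decline is computed (default 200 kb).
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(molecules, bin_bp = 100000, floor_bp = 200000) {
  lens <- if (is.numeric(molecules)) molecules else molecules$length
  bd <- bin_decline(lens, bin_bp, floor_bp)
  ggplot2::ggplot(bd, ggplot2::aes(x = .data$bin_start / 1000, y = .data$count)) +
    ggplot2::geom_col(fill = "#718096") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$decline_pct), "",
        sprintf("-%.0f%%", .data$decline_pct)
      )),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      x = "molecule length bin (kb)", y = "molecules",
      title = sprintf("N50 = %s bp", format(n50(lens), big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}
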