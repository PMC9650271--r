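#' Plot a chromosome build as stacked scaffold ideograms
#'
#' One horizontal bar per linkage group, segments colored by how each
#' scaffold was placed (marker order vs overlap insertion), with `-`
#' oriented scaffolds hatched darker.
#'
#' @param object An `anchor_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anchor_result
#' @export
autoplot.anchor_result <- function(object, ...) {
  e <- object$builds$entries |>
    dplyr::mutate(length = unname(object$scaffold_lens[.data$scaffold])) |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::mutate(xend = cumsum(.data$length),
                  xstart = .data$xend - .data$length) |>
    dplyr::ungroup()
  ggplot2::ggplot(e) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xstart / 1e3, xmax = .data$xend / 1e3,
      ymin = -0.4, ymax = 0.4,
      fill = .data$placed_by, alpha = .data$orientation
    ), color = "grey30", linewidth = 0.2) +
    ggplot2::scale_alpha_manual(values = c(`+` = 1, `-` = 0.6)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$linkage_group),
                        switch = "y") +
    ggplot2::labs(x = "position (kb)", y = NULL, fill = "placed by",
                  alpha = "orientation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
}

#' Plot the NG curve of an assembly
#'
#' Cumulative sequence length against the fraction of the assumed genome
#' size covered, with the NG50 marked by a dashed bar — the standard way
#' to compare contiguity across assemblies of one genome.
#'
#' @param object An `assembly_stats`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assembly_stats
#' @export
autoplot.assembly_stats <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(ng_frac = 100 * .data$cumulative / object$genome_size_bp)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ng_frac,
                                       y = .data$length / 1e6)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "NG(x): percent of genome size covered",
                  y = "sequence length (Mbp)") +
    ggplot2::coord_cartesian(xlim = c(0, 100)) +
    ggplot2::theme_minimal()
  if (object$ng50_defined) {
    p <- p + ggplot2::geom_vline(xintercept = 50, linetype = "dashed")
  }
  p
}

#' Plot a k-mer multiplicity histogram
#'
#' Count-versus-multiplicity spectrum of a k-mer tally; the singleton bar
#' at multiplicity 1 is the usual indicator of consensus errors.
#'
#' @param tally Tibble with columns `kmer`, `count`.
#' @param max_multiplicity Right edge of the plotted spectrum.
#' @return A ggplot object.
#' @export
plot_kmer_spectrum <- function(tally, max_multiplicity = 60) {
  d <- tally |>
    dplyr::count(multiplicity = pmin(.data$count, max_multiplicity),
                 name = "n_kmers")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$multiplicity,
                                  y = .data$n_kmers)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers") +
    ggplot2::theme_minimal()
}
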