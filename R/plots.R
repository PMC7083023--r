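#' Histogram of recovered molecule sizes
#'
#' The molecule size distribution in linked-read data is long-tailed (many
#' short molecules, a heavy right tail), which is why depth filtering, not
#' size alone, separates split molecules from ordinary short ones.
#'
#' @param submolecules tibble from [recover_submolecules()].
#' @param bins histogram bin count.
#' @return A ggplot object.
#' @export
plot_molecule_sizes <- function(submolecules, bins = 60) {
  ggplot2::ggplot(submolecules,
                  ggplot2::aes(x = (.data$end - .data$start) / 1e3)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "recovered molecule size (kbp)", y = "count") +
    ggplot2::theme_minimal()
}

#' Molecule-depth profile along the genome
#'
#' @param profile a `depth_profile`.
#' @param chrom optional chromosome to restrict to.
#' @return A ggplot object with the genome-wide mean and the duplication /
#'   deletion depth thresholds drawn as reference lines.
#' @export
plot_depth_profile <- function(profile, chrom = NULL) {
  b <- profile$bins
  if (!is.null(chrom)) b <- b[b$chrom == chrom, , drop = FALSE]
  mu <- profile$mu_depth
  sg <- profile$sigma_depth
  ggplot2::ggplot(b, ggplot2::aes(x = .data$start / 1e6, y = .data$count)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = mu, linetype = 1, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = mu + sg, linetype = 2, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5 * mu + 0.5 * sg, linetype = 3,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "molecule depth") +
    ggplot2::theme_minimal()
}

#' Plot calls along the genome
#'
#' @param object an `sv_callset`.
#' @param pass_only plot PASS calls only.
#' @param ... unused.
#' @return A ggplot object: one horizontal segment per call (source
#'   interval), coloured by SV type, with insertion loci as points.
#' @method autoplot sv_callset
#' @export
autoplot.sv_callset <- function(object, pass_only = TRUE, ...) {
  calls <- if (pass_only) pass_calls(object) else object$calls
  if (nrow(calls) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no calls"))
  }
  calls$y <- seq_len(nrow(calls))
  p <- ggplot2::ggplot(calls) +
    ggplot2::geom_segment(ggplot2::aes(
      x = (.data$bp1_lo + .data$bp1_hi) / 2e6,
      xend = (.data$bp2_lo + .data$bp2_hi) / 2e6,
      y = .data$y, yend = .data$y, colour = .data$sv_type),
      linewidth = 2) +
    ggplot2::facet_wrap(~chrom1, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = NULL, colour = "type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  ins <- calls[!is.na(calls$bp3_lo) & calls$chrom3 == calls$chrom1, ,
               drop = FALSE]
  if (nrow(ins) > 0) {
    p <- p + ggplot2::geom_point(
      data = ins,
      ggplot2::aes(x = (.data$bp3_lo + .data$bp3_hi) / 2e6, y = .data$y),
      shape = 25, fill = "black")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
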