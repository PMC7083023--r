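#' Caller configuration
#'
#' Collects every tunable of the calling pipeline with defaults matching the
#' published method where the method states a value, and documented
#' conventions where it does not.
#'
#' Key defaults and their provenance:
#' * `T` (fragment merge gap) and `Q` (leftmost-anchor distance) are derived
#'   from the expected molecule size as `T = mu/4`, `Q = 2*mu`.
#' * `min_submolecule_length = 3000` bp: very short recovered submolecules are
#'   noise, not molecules.
#' * candidate-split span bound `mu + 3*sigma` over the two submolecule spans.
#' * `min_rp_support = 3` discordant read pairs per event.
#' * `gamma = 0.6` quasi-clique density.
#' * 7 Mbp cap on inversion and duplication sizes (largest inversion reported
#'   in the literature); size floors DEL/TRA > 100 kbp, INV > 80 kbp,
#'   DUP > 40 kbp with > 80 kbp source-to-insertion displacement.
#' * depth filter: keep DUP iff source depth >= mu_depth + sigma_depth, keep
#'   DEL iff depth <= 0.5*mu_depth + 0.5*sigma_depth, keep TRA iff source
#'   depth within mu_depth +/- 1.5*sigma_depth.
#'
#' Conventions chosen by this package (the method leaves them open): a MAPQ
#' floor of 20, barcode tag `BX`, concordance bounds estimated as insert
#' mean +/- 4 sd from the data, depth bin size 10 kbp, quasi-clique
#' `min_support` of 4 split-molecule-pair vertices spanning >= 4 barcodes
#' (halved in haploid mode).
#'
#' @param barcode_tag BAM tag carrying the pool barcode.
#' @param mapq_min minimum mapping quality for a read pair to be used.
#' @param read_len read length in bp (used to compute fragment right ends).
#' @param concordance numeric length-2 `c(min, max)` insert-span bounds for a
#'   concordant pair, or `NULL` to estimate mean +/- 4 sd from the input.
#' @param mu_init initial expected molecule size in bp used to bootstrap the
#'   two-pass recovery.
#' @param merge_gap,anchor_dist overrides for `T` and `Q`; `NULL` derives them
#'   from the current molecule-size estimate.
#' @param min_submolecule_length minimum recovered submolecule length in bp;
#'   if `min_length_relative = TRUE` the floor is 10% of the molecule-size
#'   mean instead.
#' @param min_length_relative use the relative (10% of mu) short-molecule
#'   floor rather than the absolute one.
#' @param depth_bin_size molecule-depth profile bin size in bp.
#' @param span_bound_sd multiplier k in the candidate-split span bound
#'   `mu + k*sigma`.
#' @param min_rp_support minimum discordant read pairs supporting one event.
#' @param rp_pad padding in bp around breakpoint intervals when counting
#'   supporting read pairs; `NULL` uses the concordance upper bound.
#' @param breakpoint_window per-split breakpoint uncertainty in bp; `NULL`
#'   uses `T` (mu/4).
#' @param min_del_size,min_inv_size,min_dup_size,min_tra_size per-type event
#'   size floors in bp.
#' @param max_inv_size,max_dup_size size caps in bp for inversions and
#'   duplications.
#' @param dup_min_distance minimum source-to-insertion displacement in bp for
#'   an interspersed duplication.
#' @param tra_anchor_window window in bp around a discordant-anchor end when
#'   attaching same-barcode submolecules; `NULL` uses the molecule-size mean.
#' @param gamma quasi-clique density parameter in (0, 1].
#' @param min_support minimum split-molecule-pair vertices (and distinct
#'   barcodes) per reported event; `NULL` gives 4 (diploid) or 2 (haploid).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param max_splits_per_barcode cap on candidate splits retained per barcode
#'   (largest total span first).
#' @param merge_calls merge same-type calls overlapping > 50% reciprocally at
#'   reporting.
#'
#' @return A list of class `caller_config`.
#' @export
#' @examples
#' cfg <- caller_config(mapq_min = 30)
#' cfg$gamma
caller_config <- function(barcode_tag = "BX",
                          mapq_min = 20,
                          read_len = 150L,
                          concordance = NULL,
                          mu_init = 45000,
                          merge_gap = NULL,
                          anchor_dist = NULL,
                          min_submolecule_length = 3000,
                          min_length_relative = FALSE,
                          depth_bin_size = 10000,
                          span_bound_sd = 3,
                          min_rp_support = 3,
                          rp_pad = NULL,
                          breakpoint_window = NULL,
                          min_del_size = 100e3,
                          min_inv_size = 80e3,
                          min_dup_size = 40e3,
                          min_tra_size = 100e3,
                          max_inv_size = 7e6,
                          max_dup_size = 7e6,
                          dup_min_distance = 80e3,
                          tra_anchor_window = NULL,
                          gamma = 0.6,
                          min_support = NULL,
                          ploidy = c("diploid", "haploid"),
                          max_splits_per_barcode = 128L,
                          merge_calls = TRUE) {
  ploidy <- match.arg(ploidy)
  if (is.null(min_support)) {
    min_support <- if (ploidy == "haploid") 2L else 4L
  }
  stopifnot(gamma > 0, gamma <= 1, min_rp_support >= 0, mu_init > 0)
  if (!is.null(concordance)) {
    stopifnot(length(concordance) == 2, concordance[1] < concordance[2])
  }
  structure(
    list(
      barcode_tag = barcode_tag,
      mapq_min = mapq_min,
      read_len = as.integer(read_len),
      concordance = concordance,
      mu_init = mu_init,
      merge_gap = merge_gap,
      anchor_dist = anchor_dist,
      min_submolecule_length = min_submolecule_length,
      min_length_relative = min_length_relative,
      depth_bin_size = depth_bin_size,
      span_bound_sd = span_bound_sd,
      min_rp_support = min_rp_support,
      rp_pad = rp_pad,
      breakpoint_window = breakpoint_window,
      min_del_size = min_del_size,
      min_inv_size = min_inv_size,
      min_dup_size = min_dup_size,
      min_tra_size = min_tra_size,
      max_inv_size = max_inv_size,
      max_dup_size = max_dup_size,
      dup_min_distance = dup_min_distance,
      tra_anchor_window = tra_anchor_window,
      gamma = gamma,
      min_support = as.integer(min_support),
      ploidy = ploidy,
      max_splits_per_barcode = as.integer(max_splits_per_barcode),
      merge_calls = isTRUE(merge_calls)
    ),
    class = "caller_config"
  )
}

#' @export
print.caller_config <- function(x, ...) {
  cat("<caller_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(val)) "<auto>" else paste(format(val), collapse = ", ")))
  }
  invisible(x)
}

# Breakpoint window actually used for split-pair matching.
bp_window <- function(config, stats) {
  if (!is.null(config$breakpoint_window)) config$breakpoint_window else stats$merge_gap
}

sv_types <- c("DEL", "INV", "DUP_DIRECT", "DUP_INVERTED", "TRA")
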