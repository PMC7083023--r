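#' Filter SV calls by molecule depth
#'
#' Molecule depth — the number of recovered submolecules covering a locus —
#' is the physical-coverage analogue of read depth, and copy-number-changing
#' events must perturb it. With genome-wide mean `mu_depth` and standard
#' deviation `sigma_depth`:
#' * duplications are kept iff mean depth over the source interval is at
#'   least `mu_depth + sigma_depth` (the source accrues the copy's reads);
#' * deletions are kept iff depth over the deleted interval is at most
#'   `0.5*mu_depth + 0.5*sigma_depth`;
#' * translocations are kept iff source depth lies within
#'   `mu_depth +/- 1.5*sigma_depth` (a moved segment keeps copy number, so
#'   depth must look normal — a gain there signals a duplication, a loss a
#'   plain deletion);
#' * inversions are copy-neutral and pass unconditionally.
#'
#' The discard conditions are strict inequalities, so a call exactly at a
#' boundary is kept. Failing calls are retained with
#' `filter_status = "depth_fail"`; calls whose source interval has no depth
#' information get `"no_depth"`. Both are excluded from PASS output.
#'
#' The "source" interval is the segment between breakpoints 1 and 2 (the
#' copied, deleted, or moved segment), measured midpoint-to-midpoint of the
#' breakpoint intervals; depth over it is the length-weighted bin mean.
#'
#' @param calls call tibble from [cliques_to_calls()].
#' @param profile a `depth_profile`.
#' @return The call tibble with `depth_source` and `filter_status` updated.
#' @export
#' @examples
#' # mu_depth = 10, sigma_depth = 2: a DUP with source depth 11 is discarded
#' # (11 < 12); a DEL with depth 5.9 is kept (5.9 <= 6).
filter_by_molecule_depth <- function(calls, profile) {
  if (nrow(calls) == 0) return(calls)
  mu <- profile$mu_depth
  sg <- profile$sigma_depth
  src_lo <- (calls$bp1_lo + calls$bp1_hi) / 2
  src_hi <- (calls$bp2_lo + calls$bp2_hi) / 2
  depth <- interval_mean_depth(profile, calls$chrom1, src_lo, src_hi)
  calls$depth_source <- depth
  verdict <- dplyr::case_when(
    calls$filter_status != "PASS" ~ calls$filter_status,
    is.na(depth) ~ "no_depth",
    calls$sv_type %in% c("DUP_DIRECT", "DUP_INVERTED") &
      depth < mu + sg ~ "depth_fail",
    calls$sv_type == "DEL" & depth > 0.5 * mu + 0.5 * sg ~ "depth_fail",
    calls$sv_type == "TRA" &
      (depth < mu - 1.5 * sg | depth > mu + 1.5 * sg) ~ "depth_fail",
    TRUE ~ "PASS"
  )
  calls$filter_status <- verdict
  calls
}
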