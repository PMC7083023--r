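#' Molecule-size statistics and derived recovery parameters
#'
#' Packages the molecule-size mean and standard deviation together with the
#' derived recovery parameters: the fragment merge gap `T = mu/4`, the
#' leftmost-anchor distance `Q = 2*mu`, and the short-submolecule floor
#' (3 kbp absolute by default, or 10% of `mu` in relative mode).
#'
#' @param mu mean molecule size in bp.
#' @param sigma standard deviation of molecule sizes in bp.
#' @param config a [caller_config()]; supplies overrides for `T`, `Q` and the
#'   minimum-length mode.
#' @return A list of class `molecule_stats` with fields `mu`, `sigma`,
#'   `merge_gap` (T), `anchor_dist` (Q), `min_length`.
#' @export
#' @examples
#' s <- molecule_stats(50000)
#' s$merge_gap   # 12500
#' s$anchor_dist # 100000
molecule_stats <- function(mu, sigma = NA_real_, config = caller_config()) {
  stopifnot(mu > 0)
  merge_gap <- config$merge_gap %||% (mu / 4)
  anchor_dist <- config$anchor_dist %||% (2 * mu)
  min_length <- if (isTRUE(config$min_length_relative)) {
    0.1 * mu
  } else {
    config$min_submolecule_length
  }
  structure(list(mu = mu, sigma = sigma, merge_gap = merge_gap,
                 anchor_dist = anchor_dist, min_length = min_length),
            class = "molecule_stats")
}

#' @export
print.molecule_stats <- function(x, ...) {
  cat(sprintf(
    "<molecule_stats> mu=%.0f sigma=%s T=%.0f Q=%.0f min_length=%.0f\n",
    x$mu, ifelse(is.na(x$sigma), "NA", sprintf("%.0f", x$sigma)),
    x$merge_gap, x$anchor_dist, x$min_length))
  invisible(x)
}

#' Recover submolecules from concordant fragments
#'
#' Greedy sliding-window reconstruction of the large input molecules: within
#' each (barcode, chromosome) group, fragments sorted by start are scanned
#' left to right; a fragment joins the open submolecule iff its gap to the
#' submolecule's current right end is at most `T`, or its start is within `Q`
#' of the submolecule's leftmost fragment start; otherwise the submolecule is
#' closed and a new one opened. Submolecules shorter than the minimum length
#' are then discarded.
#'
#' @param fragments tibble `chrom`, `start`, `end`, `barcode` (any order;
#'   sorted internally).
#' @param stats a [molecule_stats()].
#' @return Tibble `chrom`, `start`, `end`, `barcode`, `n_fragments`, one row
#'   per surviving submolecule, with a unique `submol_id`.
#' @export
#' @examples
#' fr <- tibble::tibble(chrom = "chr1", start = c(0, 10e3), end = c(1e3, 11e3),
#'                      barcode = "BX1")
#' recover_submolecules(fr, molecule_stats(50000))  # one submolecule [0, 11k)
recover_submolecules <- function(fragments, stats) {
  stopifnot(inherits(stats, "molecule_stats"))
  if (nrow(fragments) == 0) {
    return(tibble(submol_id = integer(), chrom = character(),
                  start = numeric(), end = numeric(), barcode = character(),
                  n_fragments = integer()))
  }
  dt <- data.table::as.data.table(fragments)
  data.table::setorder(dt, barcode, chrom, start, end)
  grp <- data.table::rleid(dt$barcode, dt$chrom)
  sid <- greedy_submolecules(grp, dt$start, dt$end,
                             stats$merge_gap, stats$anchor_dist)
  dt[, `:=`(sid = sid)]
  sub <- dt[, list(chrom = chrom[1], start = min(start), end = max(end),
                   barcode = barcode[1], n_fragments = .N), by = "sid"]
  sub <- sub[(end - start) >= stats$min_length]
  tibble(submol_id = seq_len(nrow(sub)), chrom = sub$chrom,
         start = sub$start, end = sub$end, barcode = sub$barcode,
         n_fragments = sub$n_fragments)
}

#' Estimate molecule-size statistics from recovered submolecules
#'
#' The mean and (population) standard deviation of the recovered submolecule
#' lengths; the derived `T`/`Q` parameters are recomputed from the new mean
#' unless overridden in the configuration.
#'
#' @param submolecules tibble from [recover_submolecules()].
#' @param config a [caller_config()].
#' @return A [molecule_stats()].
#' @export
estimate_molecule_stats <- function(submolecules, config = caller_config()) {
  if (nrow(submolecules) < 2) {
    abort("need at least 2 submolecules to estimate molecule statistics")
  }
  len <- submolecules$end - submolecules$start
  mu <- mean(len)
  sigma <- sqrt(mean((len - mu)^2))
  molecule_stats(mu, sigma, config)
}

#' Two-pass molecule recovery with size bootstrap
#'
#' Runs [recover_submolecules()] with `T`/`Q` derived from an initial
#' expected molecule size, re-estimates the size distribution from the
#' recovered submolecules, and runs one second pass with the updated
#' parameters. One refinement iteration keeps the procedure deterministic and
#' cheap; the estimate moves to within a few percent of the truth in one step
#' on data of the assumed structure.
#'
#' @param fragments fragment tibble.
#' @param config a [caller_config()] (`mu_init` seeds the first pass).
#' @return List with `submolecules` (second-pass tibble) and `stats` (the
#'   final [molecule_stats()]).
#' @export
recover_molecules <- function(fragments, config = caller_config()) {
  if (nrow(fragments) == 0) abort("no fragments: cannot recover molecules")
  stats0 <- molecule_stats(config$mu_init, config = config)
  pass1 <- recover_submolecules(fragments, stats0)
  stats1 <- estimate_molecule_stats(pass1, config)
  pass2 <- recover_submolecules(fragments, stats1)
  stats2 <- estimate_molecule_stats(pass2, config)
  # keep the T/Q actually used for pass 2, but report the refreshed mu/sigma
  stats2$merge_gap <- stats1$merge_gap
  stats2$anchor_dist <- stats1$anchor_dist
  list(submolecules = pass2, stats = stats2)
}

#' Genome-wide molecule-depth profile
#'
#' Bins the genome and counts, per bin, the number of submolecules
#' overlapping it — the physical-coverage analogue of read depth. The depth
#' mean and (population) standard deviation are computed over unmasked bins
#' only.
#'
#' @param submolecules tibble from [recover_submolecules()].
#' @param genome named chromosome length vector.
#' @param mask optional `region_mask`; bins overlapping a masked region are
#'   excluded from the mean/sd.
#' @param bin_size bin width in bp.
#' @return A list of class `depth_profile`: `bin_size`, `bins` (tibble
#'   `chrom`, `start`, `count`, `masked`), `mu_depth`, `sigma_depth`,
#'   `genome`.
#' @export
compute_depth_profile <- function(submolecules, genome, mask = NULL,
                                  bin_size = 10000) {
  stopifnot(bin_size > 0, !is.null(names(genome)))
  bins <- lapply(names(genome), function(cn) {
    nb <- max(1L, ceiling(genome[[cn]] / bin_size))
    cnt <- numeric(nb + 1L)
    s <- submolecules[submolecules$chrom == cn, , drop = FALSE]
    if (nrow(s) > 0) {
      b0 <- pmin(pmax(floor(s$start / bin_size), 0), nb - 1L) + 1L
      b1 <- pmin(pmax(floor((s$end - 1) / bin_size), 0), nb - 1L) + 1L
      add <- tabulate(b0, nbins = nb + 1L)
      rem <- tabulate(b1 + 1L, nbins = nb + 1L)
      cnt <- cumsum(add - rem)
    }
    starts <- (seq_len(nb) - 1L) * bin_size
    msk <- mask_excludes_interval(mask, rep(cn, nb), starts,
                                  pmin(starts + bin_size, genome[[cn]]))
    tibble(chrom = cn, start = starts, count = as.numeric(cnt[seq_len(nb)]),
           masked = msk)
  })
  bins <- bind_rows(bins)
  use <- bins$count[!bins$masked]
  mu <- if (length(use) > 0) mean(use) else 0
  sigma <- if (length(use) > 0) sqrt(mean((use - mu)^2)) else 0
  structure(list(bin_size = bin_size, bins = bins, mu_depth = mu,
                 sigma_depth = sigma, genome = genome),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> bin=%g bp, %d bins, mu_depth=%.2f sigma_depth=%.2f\n",
              x$bin_size, nrow(x$bins), x$mu_depth, x$sigma_depth))
  invisible(x)
}

#' Mean molecule depth over an interval
#'
#' Length-weighted mean of the depth-profile bins overlapped by the interval,
#' so the value does not depend on the bin grid phase.
#'
#' @param profile a `depth_profile`.
#' @param chrom,start,end interval (vectors allowed, 0-based half-open).
#' @return Numeric vector of mean depths; `NA` where the interval lies
#'   outside the profile.
#' @export
interval_mean_depth <- function(profile, chrom, start, end) {
  bs <- profile$bin_size
  vapply(seq_along(chrom), function(i) {
    b <- profile$bins[profile$bins$chrom == chrom[i], , drop = FALSE]
    if (nrow(b) == 0 || end[i] <= start[i]) return(NA_real_)
    lo <- floor(start[i] / bs)
    hi <- floor((end[i] - 1) / bs)
    idx <- which(b$start >= lo * bs & b$start <= hi * bs)
    if (length(idx) == 0) return(NA_real_)
    bstart <- b$start[idx]
    w <- pmin(bstart + bs, end[i]) - pmax(bstart, start[i])
    sum(b$count[idx] * w) / sum(w)
  }, numeric(1))
}
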