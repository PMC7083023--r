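# shared fixtures and small constructors used across test files

# one read-pair row; positions 0-based, canonical order is up to the caller
rp <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
               barcode = "BX1", mapq = 60) {
  tibble::tibble(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
                 chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
                 barcode = barcode, mapq = mapq)
}

frag <- function(chrom, start, end, barcode = "BX1") {
  tibble::tibble(chrom = chrom, start = start, end = end, barcode = barcode)
}

# a candidate split row in the package's layout
mk_split <- function(id, barcode, chrom, ls, le, rs, re, chrom2 = chrom,
                     inter = chrom != chrom2) {
  tibble::tibble(split_id = id, barcode = barcode, inter = inter,
                 chrom1 = chrom, l_start = ls, l_end = le,
                 chrom2 = chrom2, r_start = rs, r_end = re)
}

# a split-molecule-pair row
mk_pair <- function(id, sv_type, chrom, b1lo, b1hi, b2lo, b2hi,
                    chrom3 = NA_character_, b3lo = NA_real_, b3hi = NA_real_,
                    split_a = id * 2L, split_b = id * 2L + 1L,
                    barcode_a = paste0("A", id), barcode_b = paste0("B", id)) {
  tibble::tibble(pair_id = id, sv_type = sv_type, chrom1 = chrom,
                 bp1_lo = b1lo, bp1_hi = b1hi, bp2_lo = b2lo, bp2_hi = b2hi,
                 chrom3 = chrom3, bp3_lo = b3lo, bp3_hi = b3hi,
                 split_a = split_a, split_b = split_b,
                 barcode_a = barcode_a, barcode_b = barcode_b,
                 rp_support = 5L)
}

mk_call <- function(id, sv_type, chrom, b1lo, b1hi, b2lo, b2hi,
                    chrom3 = NA_character_, b3lo = NA_real_, b3hi = NA_real_,
                    status = "PASS", n_split = 10L) {
  tibble::tibble(call_id = id, sv_type = sv_type, chrom1 = chrom,
                 bp1_lo = b1lo, bp1_hi = b1hi, bp2_lo = b2lo, bp2_hi = b2hi,
                 chrom3 = chrom3, bp3_lo = b3lo, bp3_hi = b3hi,
                 n_split_molecules = n_split, n_barcodes = n_split,
                 rp_support = 6L, depth_source = NA_real_,
                 filter_status = status)
}

# independent reimplementation of the greedy submolecule scan, written as a
# direct simulation of the sliding-window rule (oracle for the Rcpp kernel)
oracle_submolecules <- function(fragments, gapT, anchorQ, min_length) {
  fr <- fragments[order(fragments$barcode, fragments$chrom,
                        fragments$start, fragments$end), ]
  out <- list()
  for (key in unique(paste(fr$barcode, fr$chrom))) {
    g <- fr[paste(fr$barcode, fr$chrom) == key, ]
    open_anchor <- g$start[1]
    open_right <- g$end[1]
    open_n <- 1L
    close_submol <- function(anchor, right, n, row) {
      out[[length(out) + 1L]] <<- tibble::tibble(
        chrom = row$chrom, start = anchor, end = right,
        barcode = row$barcode, n_fragments = n)
    }
    if (nrow(g) > 1) {
      for (i in 2:nrow(g)) {
        joins <- (g$start[i] - open_right <= gapT) ||
          (g$start[i] - open_anchor <= anchorQ)
        if (joins) {
          open_right <- max(open_right, g$end[i])
          open_n <- open_n + 1L
        } else {
          close_submol(open_anchor, open_right, open_n, g[1, ])
          open_anchor <- g$start[i]
          open_right <- g$end[i]
          open_n <- 1L
        }
      }
    }
    close_submol(open_anchor, open_right, open_n, g[1, ])
  }
  res <- dplyr::bind_rows(out)
  res[res$end - res$start >= min_length, , drop = FALSE]
}

# small cached simulation with one planted inversion, reused by several files
shared_inv_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- tibble::tibble(
        sv_type = "INV", chrom = "chr1", start = 2e6, end = 2.5e6,
        chrom_ins = NA_character_, pos_ins = NA_real_,
        orientation = "inverted", zygosity = "hom")
      cache <<- simulate_linked_reads(
        sim_config(genome = c(chr1 = 6e6), svs = truth, phys_cov = 50,
                   seed = 42))
    }
    cache
  }
})

# the corresponding fitted callset, computed once
shared_inv_callset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- call_svs(shared_inv_sim())
    cache
  }
})
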