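#' Simulation configuration for synthetic linked-read data
#'
#' Describes the statistical structure of a linked-read experiment: a small
#' reference genome, large input molecules with a long-tailed size
#' distribution, barcode pools of 2-30 molecules, high physical coverage but
#' low per-molecule sequence coverage, and a set of planted structural
#' variants.
#'
#' Defaults mirror the conditions of the scaled simulation study: 50 kbp mean
#' molecules (lognormal), pools uniform on 2-30 molecules, 50x physical
#' coverage, ~0.1x per-molecule sequence coverage, 150 bp reads with a 500 bp
#' mean insert, 1% of read pairs relocated at random to emulate mismapping.
#'
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param svs truth tibble as returned by [random_svs()], or `NULL` for none.
#' @param zygosity `"hom"`, `"het"`, or `"mixed"` (each variant hom or het
#'   with equal probability). Ignored when `ploidy = 1`.
#' @param mol_mean mean molecule length in bp.
#' @param mol_dist `"lognormal"` (default, sdlog `mol_sdlog`) or
#'   `"exponential"` molecule size law.
#' @param mol_sdlog sdlog of the lognormal molecule size law.
#' @param pool_range integer range of molecules per barcode pool.
#' @param phys_cov target physical coverage (summed molecule length per
#'   reference bp).
#' @param per_mol_cov per-molecule sequence coverage (read bases per molecule
#'   bp).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd outer insert-span distribution of a read pair.
#' @param noise_rate fraction of read pairs whose second mate is relocated
#'   uniformly at random (mismapping noise).
#' @param jitter_sd sd in bp of Gaussian jitter added to mapped positions.
#' @param seed integer seed; fully determines the output.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome = c(chr1 = 5e6), phys_cov = 20, seed = 1)
sim_config <- function(genome = c(chr1 = 30e6),
                       ploidy = 2,
                       svs = NULL,
                       zygosity = c("hom", "het", "mixed"),
                       mol_mean = 50000,
                       mol_dist = c("lognormal", "exponential"),
                       mol_sdlog = 0.7,
                       pool_range = c(2L, 30L),
                       phys_cov = 50,
                       per_mol_cov = 0.1,
                       read_len = 150L,
                       insert_mean = 500,
                       insert_sd = 60,
                       noise_rate = 0.01,
                       jitter_sd = 5,
                       seed = 1L) {
  zygosity <- match.arg(zygosity)
  mol_dist <- match.arg(mol_dist)
  stopifnot(length(genome) >= 1, all(genome > 0), !is.null(names(genome)),
            ploidy %in% c(1, 2), mol_mean > 0, phys_cov > 0,
            per_mol_cov > 0, pool_range[1] >= 1, pool_range[2] >= pool_range[1],
            noise_rate >= 0, noise_rate <= 1)
  structure(
    list(genome = genome, ploidy = as.integer(ploidy), svs = svs,
         zygosity = zygosity, mol_mean = mol_mean, mol_dist = mol_dist,
         mol_sdlog = mol_sdlog, pool_range = as.integer(pool_range),
         phys_cov = phys_cov, per_mol_cov = per_mol_cov,
         read_len = as.integer(read_len), insert_mean = insert_mean,
         insert_sd = insert_sd, noise_rate = noise_rate,
         jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Construct a planted-variant truth tibble
#'
#' @param sv_type,chrom,start,end,chrom_ins,pos_ins,orientation,zygosity
#'   per-variant fields; `chrom_ins`/`pos_ins` are `NA` for DEL/INV.
#' @return A truth tibble (see [random_svs()]).
#' @export
sv_truth_tbl <- function(sv_type = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         chrom_ins = character(), pos_ins = numeric(),
                         orientation = character(), zygosity = character()) {
  tibble(sv_type = as.character(sv_type), chrom = as.character(chrom),
         start = as.numeric(start), end = as.numeric(end),
         chrom_ins = as.character(chrom_ins), pos_ins = as.numeric(pos_ins),
         orientation = as.character(orientation),
         zygosity = as.character(zygosity))
}

#' Draw a random non-overlapping set of structural variants
#'
#' Samples per-type event counts with sizes log-uniform inside the caller's
#' detection windows, placed uniformly with a separation margin so that no two
#' events (or insertion points) interact. Duplication insertion loci are
#' placed more than `dup_min_distance` from the source; translocation sources
#' and insertion loci are placed on different chromosomes.
#'
#' @param genome named chromosome length vector.
#' @param n_del,n_inv,n_dup,n_tra event counts per type.
#' @param del_size,inv_size,dup_size,tra_size length-2 size ranges in bp.
#' @param dup_min_distance minimum source-to-insertion displacement in bp.
#' @param margin minimum separation between events and from chromosome ends.
#' @param zygosity `"hom"`, `"het"`, or `"mixed"`.
#' @param max_tries rejection-sampling budget.
#' @return A truth tibble with columns `sv_type`, `chrom`, `start`, `end`,
#'   `chrom_ins`, `pos_ins`, `orientation`, `zygosity`.
#' @export
#' @examples
#' withr::with_seed(1, random_svs(c(chr1 = 30e6), n_del = 3))
random_svs <- function(genome,
                       n_del = 0, n_inv = 0, n_dup = 0, n_tra = 0,
                       del_size = c(120e3, 400e3),
                       inv_size = c(100e3, 600e3),
                       dup_size = c(50e3, 300e3),
                       tra_size = c(120e3, 400e3),
                       dup_min_distance = 80e3,
                       margin = 100e3,
                       zygosity = "hom",
                       max_tries = 10000L) {
  chroms <- names(genome)
  if (n_tra > 0 && length(genome) < 2) {
    abort("translocation simulation needs at least two chromosomes")
  }
  taken <- list()  # list of c(chrom, start, end) occupied (with margin)
  overlaps_taken <- function(chrom, s, e) {
    for (iv in taken) {
      if (iv[[1]] == chrom && s < iv[[3]] + margin && e + margin > iv[[2]]) {
        return(TRUE)
      }
    }
    FALSE
  }
  claim <- function(chrom, s, e) taken[[length(taken) + 1L]] <<- list(chrom, s, e)
  rsize <- function(rng) round(exp(runif(1, log(rng[1]), log(rng[2]))))
  place_interval <- function(size, on = chroms) {
    for (i in seq_len(max_tries)) {
      chrom <- sample(on, 1, prob = genome[on])
      if (genome[chrom] < size + 2 * margin) next
      s <- floor(runif(1, margin, genome[chrom] - size - margin))
      if (!overlaps_taken(chrom, s, s + size)) {
        return(list(chrom = chrom, start = s, end = s + size))
      }
    }
    abort("could not place a variant; genome too small for the requested set")
  }
  place_point <- function(on, avoid_chrom = NULL, avoid_iv = NULL) {
    for (i in seq_len(max_tries)) {
      chrom <- sample(on, 1, prob = genome[on])
      p <- floor(runif(1, margin, genome[chrom] - margin))
      if (overlaps_taken(chrom, p, p + 1)) next
      if (!is.null(avoid_iv) && chrom == avoid_chrom &&
          p > avoid_iv[1] - dup_min_distance && p < avoid_iv[2] + dup_min_distance) next
      return(list(chrom = chrom, pos = p))
    }
    abort("could not place an insertion point")
  }
  zyg <- function() switch(zygosity,
                           hom = "hom", het = "het",
                           mixed = sample(c("hom", "het"), 1))
  out <- list()
  add <- function(rec) out[[length(out) + 1L]] <<- rec
  for (i in seq_len(n_del)) {
    iv <- place_interval(rsize(del_size))
    claim(iv$chrom, iv$start, iv$end)
    add(sv_truth_tbl("DEL", iv$chrom, iv$start, iv$end, NA_character_,
                     NA_real_, "direct", zyg()))
  }
  for (i in seq_len(n_inv)) {
    iv <- place_interval(rsize(inv_size))
    claim(iv$chrom, iv$start, iv$end)
    add(sv_truth_tbl("INV", iv$chrom, iv$start, iv$end, NA_character_,
                     NA_real_, "inverted", zyg()))
  }
  for (i in seq_len(n_dup)) {
    iv <- place_interval(rsize(dup_size))
    claim(iv$chrom, iv$start, iv$end)
    pt <- place_point(chroms, iv$chrom, c(iv$start, iv$end))
    claim(pt$chrom, pt$pos, pt$pos + 1)
    ori <- sample(c("direct", "inverted"), 1)
    type <- if (ori == "direct") "DUP_DIRECT" else "DUP_INVERTED"
    add(sv_truth_tbl(type, iv$chrom, iv$start, iv$end, pt$chrom, pt$pos,
                     ori, zyg()))
  }
  for (i in seq_len(n_tra)) {
    iv <- place_interval(rsize(tra_size))
    claim(iv$chrom, iv$start, iv$end)
    other <- setdiff(chroms, iv$chrom)
    pt <- place_point(other)
    claim(pt$chrom, pt$pos, pt$pos + 1)
    add(sv_truth_tbl("TRA", iv$chrom, iv$start, iv$end, pt$chrom, pt$pos,
                     "direct", zyg()))
  }
  bind_rows(out)
}

#' Build donor haplotype coordinate maps with planted variants
#'
#' Applies a truth set to the reference coordinate space, producing for each
#' haplotype a piecewise-linear donor-to-reference map: deletions remove a
#' segment, inversions reverse one, interspersed duplications insert a distant
#' copy (direct or inverted), and non-reciprocal translocations insert a copy
#' and delete the source. Heterozygous variants are applied to haplotype 1
#' only.
#'
#' @param genome named chromosome length vector.
#' @param truth truth tibble (see [random_svs()]); `NULL` or empty gives
#'   identity maps.
#' @param ploidy number of haplotypes.
#' @return A list of class `donor_map` with elements `haplotypes` (per
#'   haplotype, per donor chromosome, a tibble of pieces with donor and
#'   reference coordinates and strand), `genome`, and `truth`.
#' @export
#' @examples
#' truth <- sv_truth_tbl("DEL", "chr1", 1e6, 1.2e6, NA, NA, "direct", "hom")
#' dm <- plant_svs(c(chr1 = 5e6), truth)
#' map_donor_interval(dm, 1, "chr1", 0.9e6, 1.1e6)
plant_svs <- function(genome, truth = NULL, ploidy = 2) {
  if (is.null(truth)) truth <- sv_truth_tbl()
  stopifnot(all(truth$sv_type %in% sv_types))
  if (nrow(truth) > 0) {
    body <- truth %>%
      mutate(kind = "body", c = .data$chrom, s = .data$start, e = .data$end)
    ins <- truth %>%
      filter(.data$sv_type %in% c("DUP_DIRECT", "DUP_INVERTED", "TRA")) %>%
      mutate(kind = "ins", c = .data$chrom_ins, s = .data$pos_ins,
             e = .data$pos_ins + 1)
    occ <- bind_rows(body, ins) %>% arrange(.data$c, .data$s)
    bad <- occ %>%
      group_by(.data$c) %>%
      mutate(prev_e = lag(.data$e)) %>%
      filter(!is.na(.data$prev_e) & .data$s < .data$prev_e)
    if (nrow(bad) > 0) abort("planted variants overlap; refusing to build donor map")
    if (any(truth$start < 0) || any(truth$end > genome[truth$chrom])) {
      abort("variant outside chromosome bounds")
    }
  }
  haps <- lapply(seq_len(ploidy), function(h) {
    tr <- if (h == 1) truth else filter(truth, .data$zygosity == "hom")
    build_hap_map(genome, tr)
  })
  structure(list(haplotypes = haps, genome = genome, truth = truth),
            class = "donor_map")
}

# One haplotype: per donor chromosome, ordered pieces
# (chrom, r_start, r_end, strand, d_start, d_end).
build_hap_map <- function(genome, truth) {
  chroms <- names(genome)
  dropped <- filter(truth, .data$sv_type %in% c("DEL", "TRA"))
  flipped <- filter(truth, .data$sv_type == "INV")
  inserts <- filter(truth, .data$sv_type %in% c("DUP_DIRECT", "DUP_INVERTED", "TRA"))
  out <- lapply(chroms, function(cn) {
    L <- genome[[cn]]
    ev_here <- filter(truth, .data$chrom == cn)
    ins_here <- filter(inserts, .data$chrom_ins == cn)
    cuts <- sort(unique(c(0, L, ev_here$start, ev_here$end, ins_here$pos_ins)))
    seg <- tibble(chrom = cn, r_start = head(cuts, -1), r_end = tail(cuts, -1),
                  strand = "+")
    drop_here <- filter(dropped, .data$chrom == cn)
    flip_here <- filter(flipped, .data$chrom == cn)
    keep <- rep(TRUE, nrow(seg))
    for (i in seq_len(nrow(drop_here))) {
      keep <- keep & !(seg$r_start >= drop_here$start[i] &
                         seg$r_end <= drop_here$end[i])
    }
    for (i in seq_len(nrow(flip_here))) {
      hit <- seg$r_start >= flip_here$start[i] & seg$r_end <= flip_here$end[i]
      seg$strand[hit] <- "-"
    }
    seg <- seg[keep, , drop = FALSE]
    # splice insertion pieces in front of the base segment starting at pos_ins
    if (nrow(ins_here) > 0) {
      pieces <- vector("list", nrow(seg) + nrow(ins_here))
      k <- 1L
      for (i in seq_len(nrow(seg))) {
        at <- which(ins_here$pos_ins == seg$r_start[i])
        for (j in at) {
          ori <- if (ins_here$orientation[j] == "inverted") "-" else "+"
          pieces[[k]] <- tibble(chrom = ins_here$chrom[j],
                                r_start = ins_here$start[j],
                                r_end = ins_here$end[j], strand = ori)
          k <- k + 1L
        }
        pieces[[k]] <- seg[i, ]
        k <- k + 1L
      }
      # insertion at the very end of the chromosome (r_start == L) -- not
      # generated by random_svs but handled for completeness
      at_end <- which(ins_here$pos_ins == L)
      for (j in at_end) {
        ori <- if (ins_here$orientation[j] == "inverted") "-" else "+"
        pieces[[k]] <- tibble(chrom = ins_here$chrom[j],
                              r_start = ins_here$start[j],
                              r_end = ins_here$end[j], strand = ori)
        k <- k + 1L
      }
      seg <- bind_rows(pieces[seq_len(k - 1L)])
    }
    len <- seg$r_end - seg$r_start
    seg$d_start <- cumsum(c(0, head(len, -1)))
    seg$d_end <- seg$d_start + len
    seg
  })
  names(out) <- chroms
  out
}

#' Map a donor-coordinate interval to reference intervals
#'
#' @param dm a `donor_map`.
#' @param hap haplotype index.
#' @param dchrom donor chromosome name.
#' @param start,end donor interval (0-based half-open).
#' @return Tibble of reference pieces (`chrom`, `start`, `end`, `strand`)
#'   covered by the donor interval.
#' @export
map_donor_interval <- function(dm, hap, dchrom, start, end) {
  pieces <- dm$haplotypes[[hap]][[dchrom]]
  hit <- pieces$d_start < end & pieces$d_end > start
  p <- pieces[hit, , drop = FALSE]
  lo <- pmax(p$d_start, start) - p$d_start
  hi <- pmin(p$d_end, end) - p$d_start
  ref_lo <- ifelse(p$strand == "+", p$r_start + lo, p$r_end - hi)
  ref_hi <- ifelse(p$strand == "+", p$r_start + hi, p$r_end - lo)
  tibble(chrom = p$chrom, start = ref_lo, end = ref_hi, strand = p$strand)
}

# Vectorized: map donor read left-ends to reference left-ends.
# x: donor read start; rl: read length. Returns chrom, pos, flip.
map_reads_to_ref <- function(pieces, x, rl) {
  mid <- x + rl / 2
  idx <- findInterval(mid, pieces$d_start)
  idx[idx < 1L] <- 1L
  off <- x - pieces$d_start[idx]
  plus <- pieces$strand[idx] == "+"
  pos <- ifelse(plus,
                pieces$r_start[idx] + off,
                pieces$r_end[idx] - off - rl)
  list(chrom = pieces$chrom[idx], pos = pos, flip = !plus)
}

#' Simulate barcoded linked-read alignments
#'
#' Samples large molecules on the donor haplotypes, partitions them into
#' barcode pools, samples read pairs along each molecule at low per-molecule
#' coverage, and maps every read through the donor map back to reference
#' coordinates. Reads from molecules spanning a planted variant thereby
#' produce split mappings and discordant orientations exactly as a mapper
#' would report them, without simulating bases.
#'
#' @param config a [sim_config()].
#' @return A list of class `linked_sim` with elements:
#'   * `reads`: tibble of read pairs (`chrom1`, `pos1`, `strand1`, `chrom2`,
#'     `pos2`, `strand2`, `barcode`, `mapq`), coordinate-sorted, 0-based.
#'   * `truth`: the planted-variant truth tibble.
#'   * `molecules`: per-molecule reference footprints (`mol_id`, `barcode`,
#'     `chrom`, `start`, `end`), for parameter-recovery checks.
#'   * `config`: the input configuration.
#' @export
#' @examples
#' sim <- simulate_linked_reads(sim_config(genome = c(chr1 = 2e6),
#'   phys_cov = 10, seed = 7))
#' nrow(sim$reads)
simulate_linked_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_linked_reads_impl(config))
}

simulate_linked_reads_impl <- function(cfg) {
  genome <- cfg$genome
  truth <- cfg$svs
  if (!is.null(truth) && nrow(truth) > 0 && cfg$zygosity != "hom" &&
      cfg$ploidy == 2) {
    if (cfg$zygosity == "het") {
      truth$zygosity <- "het"
    } else if (cfg$zygosity == "mixed") {
      truth$zygosity <- sample(c("hom", "het"), nrow(truth), replace = TRUE)
    }
  } else if (!is.null(truth) && nrow(truth) > 0) {
    truth$zygosity <- "hom"
  }
  dm <- plant_svs(genome, truth, ploidy = cfg$ploidy)
  rl <- cfg$read_len
  G <- sum(genome)
  n_mol <- round(cfg$phys_cov * G / cfg$mol_mean)
  n_hap <- cfg$ploidy

  # molecule sizes (long-tailed)
  sizes <- switch(cfg$mol_dist,
    lognormal = rlnorm(n_mol, meanlog = log(cfg$mol_mean) - cfg$mol_sdlog^2 / 2,
                       sdlog = cfg$mol_sdlog),
    exponential = rexp(n_mol, rate = 1 / cfg$mol_mean))
  sizes <- pmax(round(sizes), 1000)

  hap <- sample.int(n_hap, n_mol, replace = TRUE)
  # donor chromosome lengths per haplotype
  dlen <- lapply(seq_len(n_hap), function(h)
    vapply(dm$haplotypes[[h]], function(p) max(p$d_end), numeric(1)))
  chrom_idx <- sample.int(length(genome), n_mol, replace = TRUE, prob = genome)
  dchrom <- names(genome)[chrom_idx]
  Lc <- vapply(seq_len(n_mol), function(i) dlen[[hap[i]]][[dchrom[i]]],
               numeric(1))
  sizes <- pmin(sizes, Lc)
  mstart <- floor(runif(n_mol) * (Lc - sizes + 1))

  # barcode pools of 2-30 molecules
  max_pools <- ceiling(n_mol / cfg$pool_range[1]) + 1L
  psize <- sample(seq(cfg$pool_range[1], cfg$pool_range[2]), max_pools,
                  replace = TRUE)
  pool_of <- rep.int(seq_along(psize), psize)[seq_len(n_mol)]
  # molecules are assigned to pools in random order already (iid draws above)
  barcode <- sprintf("BX%07d", pool_of)

  mol <- tibble(mol_id = seq_len(n_mol), hap = hap, dchrom = dchrom,
                d_start = mstart, d_end = mstart + sizes, barcode = barcode)

  # read pairs per molecule
  n_pairs <- rpois(n_mol, sizes * cfg$per_mol_cov / (2 * rl))
  pair_mol <- rep.int(mol$mol_id, n_pairs)
  np <- length(pair_mol)
  insert <- pmax(round(rnorm(np, cfg$insert_mean, cfg$insert_sd)), 2 * rl)
  msz <- sizes[pair_mol]
  insert <- pmin(insert, msz)
  fwd <- mol$d_start[pair_mol] + floor(runif(np) * (msz - insert + 1))
  rev_start <- fwd + insert - rl

  reads <- tibble(
    pair_id = rep(seq_len(np), 2L),
    mate = rep(c(1L, 2L), each = np),
    hap = rep(mol$hap[pair_mol], 2L),
    dchrom = rep(mol$dchrom[pair_mol], 2L),
    dpos = c(fwd, rev_start),
    fwd = rep(c(TRUE, FALSE), each = np)
  )

  # map through donor pieces, grouped by (hap, donor chromosome)
  reads$chrom <- NA_character_
  reads$pos <- NA_real_
  for (h in seq_len(n_hap)) {
    for (cn in names(genome)) {
      sel <- which(reads$hap == h & reads$dchrom == cn)
      if (length(sel) == 0) next
      m <- map_reads_to_ref(dm$haplotypes[[h]][[cn]], reads$dpos[sel], rl)
      reads$chrom[sel] <- m$chrom
      reads$pos[sel] <- m$pos
      reads$fwd[sel] <- xor(reads$fwd[sel], m$flip)
    }
  }
  if (cfg$jitter_sd > 0) {
    reads$pos <- reads$pos + round(rnorm(nrow(reads), 0, cfg$jitter_sd))
  }
  reads$pos <- pmin(pmax(reads$pos, 0), genome[reads$chrom] - rl)

  m1 <- reads[reads$mate == 1L, ]
  m2 <- reads[reads$mate == 2L, ]
  pairs <- tibble(
    chrom1 = m1$chrom, pos1 = m1$pos, strand1 = ifelse(m1$fwd, "+", "-"),
    chrom2 = m2$chrom, pos2 = m2$pos, strand2 = ifelse(m2$fwd, "+", "-"),
    barcode = mol$barcode[pair_mol], mapq = 60L
  )

  # mismapping noise: relocate mate 2 uniformly
  if (cfg$noise_rate > 0 && np > 0) {
    hitn <- which(runif(np) < cfg$noise_rate)
    if (length(hitn) > 0) {
      nc <- sample.int(length(genome), length(hitn), replace = TRUE,
                       prob = genome)
      pairs$chrom2[hitn] <- names(genome)[nc]
      pairs$pos2[hitn] <- floor(runif(length(hitn)) * (genome[nc] - rl))
      pairs$strand2[hitn] <- sample(c("+", "-"), length(hitn), replace = TRUE)
    }
  }
  pairs <- canonicalize_pairs(pairs, names(genome))
  pairs <- arrange(pairs, match(.data$chrom1, names(genome)), .data$pos1)

  # reference footprints of the simulated molecules
  foot <- molecule_footprints(dm, mol)

  structure(list(reads = pairs, truth = truth %||% sv_truth_tbl(),
                 molecules = foot, config = cfg, donor_map = dm),
            class = "linked_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Put each pair in canonical (chrom1,pos1) <= (chrom2,pos2) order.
canonicalize_pairs <- function(pairs, chrom_order) {
  c1 <- match(pairs$chrom1, chrom_order)
  c2 <- match(pairs$chrom2, chrom_order)
  swap <- c1 > c2 | (c1 == c2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, ]
    pairs$chrom1[swap] <- tmp$chrom2
    pairs$pos1[swap] <- tmp$pos2
    pairs$strand1[swap] <- tmp$strand2
    pairs$chrom2[swap] <- tmp$chrom1
    pairs$pos2[swap] <- tmp$pos1
    pairs$strand2[swap] <- tmp$strand1
  }
  pairs
}

# Reference footprint pieces of each simulated molecule.
molecule_footprints <- function(dm, mol) {
  out <- vector("list", nrow(mol))
  grp <- split(seq_len(nrow(mol)), list(mol$hap, mol$dchrom), drop = TRUE)
  for (g in grp) {
    h <- mol$hap[g[1]]
    cn <- mol$dchrom[g[1]]
    pieces <- dm$haplotypes[[h]][[cn]]
    pd <- data.table::data.table(ps = pieces$d_start, pe = pieces$d_end,
                                 chrom = pieces$chrom, rs = pieces$r_start,
                                 re = pieces$r_end, strand = pieces$strand)
    md <- data.table::data.table(idx = g, ms = mol$d_start[g], me = mol$d_end[g])
    data.table::setkey(pd, ps, pe)
    ov <- data.table::foverlaps(
      data.table::setnames(data.table::copy(md), c("ms", "me"), c("ps", "pe")),
      pd, type = "any", nomatch = NULL)
    lo <- pmax(ov$ps, ov$i.ps) - ov$ps
    hi <- pmin(ov$pe, ov$i.pe) - ov$ps
    keep <- hi > lo
    ov <- ov[keep]; lo <- lo[keep]; hi <- hi[keep]
    out[[length(out) + 1L]] <- tibble(
      mol_id = mol$mol_id[ov$idx],
      barcode = mol$barcode[ov$idx],
      chrom = ov$chrom,
      start = ifelse(ov$strand == "+", ov$rs + lo, ov$re - hi),
      end = ifelse(ov$strand == "+", ov$rs + hi, ov$re - lo))
  }
  bind_rows(out) %>% arrange(.data$mol_id, .data$chrom, .data$start)
}

#' Write and read a truth set as TSV
#'
#' @param truth truth tibble.
#' @param path file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the truth tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sv_type = "c", chrom = "c", start = "d", end = "d",
                    chrom_ins = "c", pos_ins = "d", orientation = "c",
                    zygosity = "c"))
}
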