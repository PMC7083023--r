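#' Enumerate intra-chromosomal candidate splits
#'
#' A *candidate split* is a pair of submolecules sharing one barcode that
#' could be the two mapped halves of a single molecule spanning an SV
#' breakpoint. All same-barcode, same-chromosome submolecule pairs whose
#' span sum is at most `mu + k*sigma` (k = `span_bound_sd`, default 3) are
#' recorded; a longer pair cannot come from one molecule. Inter-chromosomal
#' splits are produced only by [anchor_translocation_splits()].
#'
#' @param submolecules tibble from [recover_submolecules()].
#' @param stats a [molecule_stats()] with `mu` and `sigma` estimated.
#' @param config a [caller_config()].
#' @return Candidate-split tibble: `split_id`, `barcode`, `inter`, `chrom1`,
#'   `l_start`, `l_end`, `chrom2`, `r_start`, `r_end` with
#'   `l_start <= r_start` (left/right submolecule of the split).
#' @export
enumerate_candidate_splits <- function(submolecules, stats,
                                       config = caller_config()) {
  empty <- tibble(split_id = integer(), barcode = character(),
                  inter = logical(), chrom1 = character(),
                  l_start = numeric(), l_end = numeric(),
                  chrom2 = character(), r_start = numeric(), r_end = numeric())
  if (nrow(submolecules) < 2) return(empty)
  bound <- stats$mu + config$span_bound_sd * ifelse(is.na(stats$sigma), 0,
                                                   stats$sigma)
  dt <- data.table::data.table(
    barcode = submolecules$barcode, chrom = submolecules$chrom,
    id = submolecules$submol_id, start = submolecules$start,
    end = submolecules$end, span = submolecules$end - submolecules$start)
  j <- merge(dt, dt, by = c("barcode", "chrom"), allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  j <- j[j$id_a < j$id_b & (j$span_a + j$span_b) <= bound]
  if (nrow(j) == 0) return(empty)
  # order halves left/right by start (tie: end)
  a_left <- j$start_a < j$start_b | (j$start_a == j$start_b & j$end_a <= j$end_b)
  out <- tibble(
    barcode = j$barcode, inter = FALSE, chrom1 = j$chrom,
    l_start = ifelse(a_left, j$start_a, j$start_b),
    l_end = ifelse(a_left, j$end_a, j$end_b),
    chrom2 = j$chrom,
    r_start = ifelse(a_left, j$start_b, j$start_a),
    r_end = ifelse(a_left, j$end_b, j$end_a),
    spansum = j$span_a + j$span_b)
  # per-barcode cap, largest spans first (explosion control)
  cap <- config$max_splits_per_barcode
  out <- out %>%
    group_by(.data$barcode) %>%
    arrange(dplyr::desc(.data$spansum), .by_group = TRUE) %>%
    slice(seq_len(min(n(), cap))) %>%
    ungroup() %>%
    select(-"spansum") %>%
    arrange(.data$chrom1, .data$l_start, .data$r_start, .data$barcode)
  out$split_id <- seq_len(nrow(out))
  select(out, "split_id", dplyr::everything())
}

#' Attach submolecules to inter-chromosomal discordant anchors
#'
#' Exhaustive cross-chromosome pairing of candidate splits is infeasible, so
#' translocation candidates are built the other way around: each
#' inter-chromosomal discordant read pair acts as an anchor, and same-barcode
#' submolecules lying within `anchor_window` of each anchor end are attached
#' as the two halves of an inter-chromosomal candidate split.
#'
#' @param discordant discordant-pair tibble (class `interchromosomal` rows
#'   are used).
#' @param submolecules tibble from [recover_submolecules()].
#' @param stats a [molecule_stats()] (`mu` is the default anchor window).
#' @param config a [caller_config()].
#' @return Candidate-split tibble (see [enumerate_candidate_splits()]) with
#'   `inter = TRUE` and `chrom1 < chrom2` in input chromosome order.
#' @export
anchor_translocation_splits <- function(discordant, submolecules, stats,
                                        config = caller_config()) {
  empty <- tibble(split_id = integer(), barcode = character(),
                  inter = logical(), chrom1 = character(),
                  l_start = numeric(), l_end = numeric(),
                  chrom2 = character(), r_start = numeric(), r_end = numeric())
  anc <- discordant[discordant$pair_class == "interchromosomal", , drop = FALSE]
  if (nrow(anc) == 0 || nrow(submolecules) == 0) return(empty)
  win <- config$tra_anchor_window %||% stats$mu
  bound <- stats$mu + config$span_bound_sd * ifelse(is.na(stats$sigma), 0,
                                                   stats$sigma)
  sub <- data.table::data.table(
    barcode = submolecules$barcode, chrom = submolecules$chrom,
    id = submolecules$submol_id, start = submolecules$start,
    end = submolecules$end, ws = submolecules$start - win,
    we = submolecules$end + win)
  data.table::setkey(sub, barcode, chrom, ws, we)
  # two lookup tables: anchor end 1 and end 2
  a1 <- data.table::data.table(aid = seq_len(nrow(anc)), barcode = anc$barcode,
                               chrom = anc$chrom1, ws = anc$pos1, we = anc$pos1)
  a2 <- data.table::data.table(aid = seq_len(nrow(anc)), barcode = anc$barcode,
                               chrom = anc$chrom2, ws = anc$pos2, we = anc$pos2)
  h1 <- data.table::foverlaps(a1, sub, type = "within", nomatch = NULL)
  h2 <- data.table::foverlaps(a2, sub, type = "within", nomatch = NULL)
  if (nrow(h1) == 0 || nrow(h2) == 0) return(empty)
  m <- merge(h1[, list(aid, id1 = id, s1 = start, e1 = end, c1 = chrom)],
             h2[, list(aid, id2 = id, s2 = start, e2 = end, c2 = chrom)],
             by = "aid", allow.cartesian = TRUE)
  m <- m[m$c1 != m$c2 & (m$e1 - m$s1) + (m$e2 - m$s2) <= bound]
  if (nrow(m) == 0) return(empty)
  bc <- anc$barcode[m$aid]
  out <- tibble(barcode = bc, inter = TRUE,
                chrom1 = m$c1, l_start = m$s1, l_end = m$e1,
                chrom2 = m$c2, r_start = m$s2, r_end = m$e2) %>%
    distinct(.data$barcode, .data$chrom1, .data$l_start, .data$l_end,
             .data$chrom2, .data$r_start, .data$r_end, .keep_all = TRUE) %>%
    arrange(.data$chrom1, .data$chrom2, .data$l_start, .data$r_start)
  out$split_id <- seq_len(nrow(out)) + 10000000L
  select(out, "split_id", dplyr::everything())
}

#' Remove candidate splits with no discordant read-pair support
#'
#' A real SV-spanning molecule is accompanied by discordant read pairs
#' bridging the same junction; candidate splits with no discordant pair
#' landing near both halves are coincidences of molecule placement and are
#' dropped before the (quadratic) cross-barcode pairing step.
#'
#' @param splits candidate-split tibble.
#' @param discordant discordant-pair tibble.
#' @param stats a [molecule_stats()]; the breakpoint window (`T`) widens the
#'   padding, since a submolecule's recovered edge lies up to a fragment gap
#'   away from the true junction.
#' @param config a [caller_config()]; `rp_pad` (default: concordance upper
#'   bound) adds insert-scale padding.
#' @param pad total padding in bp; overrides the derived value.
#' @return The supported subset of `splits`.
#' @export
filter_splits_by_support <- function(splits, discordant, stats,
                                     config = caller_config(), pad = NULL) {
  if (nrow(splits) == 0 || nrow(discordant) == 0) {
    return(splits[integer(0), , drop = FALSE])
  }
  pad <- pad %||% ((config$rp_pad %||% 1000) + bp_window(config, stats))
  sdt <- data.table::data.table(
    sid = splits$split_id, chrom = splits$chrom1,
    ws = splits$l_start - pad, we = splits$l_end + pad,
    chrom2 = splits$chrom2, rs = splits$r_start - pad,
    re = splits$r_end + pad)
  data.table::setkey(sdt, chrom, ws, we)
  ddt <- data.table::data.table(chrom = discordant$chrom1,
                                ws = discordant$pos1, we = discordant$pos1,
                                c2 = discordant$chrom2, p2 = discordant$pos2)
  ov <- data.table::foverlaps(ddt, sdt, type = "within", nomatch = NULL)
  ok <- ov[ov$c2 == ov$chrom2 & ov$p2 >= ov$rs & ov$p2 <= ov$re]
  keep <- unique(ok$sid)
  splits[splits$split_id %in% keep, , drop = FALSE]
}

# ---- split-molecule-pair matching -----------------------------------------

# bucketed band join: rows of a and b where |a[[ka]] - b[[kb]]| <= w and
# a$chrom_key == b$chrom_key. Returns data.table with a-cols suffixed _a,
# b-cols suffixed _b.
band_join <- function(a, b, ka, kb, w, key_a = "chrom1", key_b = "chrom1") {
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
  adt <- data.table::as.data.table(a)
  bdt <- data.table::as.data.table(b)
  data.table::setnames(adt, names(adt), paste0(names(adt), "_a"))
  data.table::setnames(bdt, names(bdt), paste0(names(bdt), "_b"))
  adt[, `:=`(bucket = floor(adt[[paste0(ka, "_a")]] / w),
             ck = adt[[paste0(key_a, "_a")]])]
  res <- vector("list", 3)
  for (k in -1:1) {
    bdt2 <- data.table::copy(bdt)
    bdt2[, `:=`(bucket = floor(bdt2[[paste0(kb, "_b")]] / w) + k,
                ck = bdt2[[paste0(key_b, "_b")]])]
    res[[k + 2]] <- merge(adt, bdt2, by = c("ck", "bucket"),
                          allow.cartesian = TRUE)
  }
  out <- data.table::rbindlist(res)
  out <- out[abs(out[[paste0(ka, "_a")]] - out[[paste0(kb, "_b")]]) <= w]
  unique(out, by = c(paste0("split_id", "_a"), paste0("split_id", "_b")))
}

# interval [lo, hi) from a lower-bound estimate
bp_from_lower <- function(est, w) list(lo = est, hi = est + w)
# interval from an upper-bound estimate
bp_from_upper <- function(est, w) list(lo = est - w, hi = est)
# intersection of [lo1,hi1) and [lo2,hi2), clamped to be non-empty
bp_intersect <- function(lo1, hi1, lo2, hi2) {
  lo <- pmax(lo1, lo2)
  hi <- pmin(hi1, hi2)
  hi <- pmax(hi, lo + 1)
  list(lo = lo, hi = hi)
}

mk_pairs <- function(sv_type, j, chrom1, bp1, bp2, chrom3 = NA_character_,
                     bp3 = NULL) {
  if (is.null(j) || nrow(j) == 0) return(NULL)
  tibble(
    sv_type = sv_type,
    chrom1 = chrom1,
    bp1_lo = bp1$lo, bp1_hi = bp1$hi,
    bp2_lo = bp2$lo, bp2_hi = bp2$hi,
    chrom3 = chrom3,
    bp3_lo = if (is.null(bp3)) NA_real_ else bp3$lo,
    bp3_hi = if (is.null(bp3)) NA_real_ else bp3$hi,
    split_a = j$split_id_a, split_b = j$split_id_b,
    barcode_a = j$barcode_a, barcode_b = j$barcode_b)
}

#' Match candidate splits into split-molecule pairs
#'
#' Pairs candidate splits across *different* barcodes whose submolecule
#' geometry is arrangeable as the two split molecules of one SV type
#' (deletion, inversion, direct/inverted interspersed duplication,
#' non-reciprocal translocation), derives the breakpoint intervals implied by
#' the arrangement, applies the per-type size windows, and counts discordant
#' read-pair support, dropping pairs below `min_rp_support`.
#'
#' @param splits candidate-split tibble (intra and/or inter rows).
#' @param discordant discordant-pair tibble (for support counting).
#' @param stats a [molecule_stats()].
#' @param config a [caller_config()].
#' @return Split-molecule-pair tibble: `pair_id`, `sv_type`, `chrom1`
#'   (breakpoints 1/2), `bp1_lo/hi`, `bp2_lo/hi`, `chrom3`, `bp3_lo/hi`
#'   (insertion locus, DUP/TRA only), `split_a`, `split_b`, `barcode_a`,
#'   `barcode_b`, `rp_support`.
#' @export
match_split_molecule_pairs <- function(splits, discordant, stats,
                                       config = caller_config()) {
  w <- bp_window(config, stats)
  intra <- splits[!splits$inter, , drop = FALSE]
  inter <- splits[splits$inter, , drop = FALSE]
  out <- list()

  # --- deletions: both splits gap over the deleted interval ---------------
  j <- band_join(intra, intra, "l_end", "l_end", w)
  if (!is.null(j)) {
    j <- j[j$split_id_a < j$split_id_b & j$barcode_a != j$barcode_b &
             abs(j$r_start_a - j$r_start_b) <= w]
    bp1 <- bp_from_lower(pmax(j$l_end_a, j$l_end_b), w)
    bp2 <- bp_from_upper(pmin(j$r_start_a, j$r_start_b), w)
    size <- (j$r_start_a + j$r_start_b) / 2 - (j$l_end_a + j$l_end_b) / 2
    keep <- size >= config$min_del_size & bp1$hi <= bp2$lo
    out$DEL <- mk_pairs("DEL", j[keep], j$chrom1_a[keep],
                        lapply(bp1, `[`, keep), lapply(bp2, `[`, keep))
  }

  # --- inversions: a crosses the left breakpoint, b the right -------------
  j <- band_join(intra, intra, "l_end", "l_start", w)
  if (!is.null(j)) {
    j <- j[j$split_id_a != j$split_id_b & j$barcode_a != j$barcode_b &
             abs(j$r_end_a - j$r_start_b) <= w]
    bp1 <- bp_intersect(j$l_end_a, j$l_end_a + w,
                        j$l_start_b - w, j$l_start_b + 1)
    bp2 <- bp_intersect(j$r_end_a, j$r_end_a + w,
                        j$r_start_b - w, j$r_start_b + 1)
    size <- (bp2$lo + bp2$hi) / 2 - (bp1$lo + bp1$hi) / 2
    keep <- size >= config$min_inv_size & size <= config$max_inv_size
    out$INV <- mk_pairs("INV", j[keep], j$chrom1_a[keep],
                        lapply(bp1, `[`, keep), lapply(bp2, `[`, keep))
  }

  # --- interspersed duplications ------------------------------------------
  out$DUP_R <- match_dup_right(intra, w, config)
  out$DUP_L <- match_dup_left(intra, w, config)

  # --- translocations -----------------------------------------------------
  # the signature has three candidate splits: one at each insertion junction
  # (inter-chromosomal, from anchoring) and one over the deleted source
  # (intra-chromosomal); any cross-barcode combination signalling the same
  # breakpoints pairs up
  out$TRA1 <- match_tra(inter, w, config, source_side = 1L)
  out$TRA2 <- match_tra(inter, w, config, source_side = 2L)
  out$TRA3 <- match_tra_source(intra, inter, w, config, source_side = 1L)
  out$TRA4 <- match_tra_source(intra, inter, w, config, source_side = 2L)

  pairs <- bind_rows(out)
  if (nrow(pairs) == 0) {
    return(tibble(pair_id = integer(), sv_type = character(),
                  chrom1 = character(), bp1_lo = numeric(), bp1_hi = numeric(),
                  bp2_lo = numeric(), bp2_hi = numeric(),
                  chrom3 = character(), bp3_lo = numeric(), bp3_hi = numeric(),
                  split_a = integer(), split_b = integer(),
                  barcode_a = character(), barcode_b = character(),
                  rp_support = integer()))
  }
  # canonical dedup of unordered split pairs per type
  pairs <- pairs %>%
    mutate(lo_id = pmin(.data$split_a, .data$split_b),
           hi_id = pmax(.data$split_a, .data$split_b)) %>%
    arrange(.data$sv_type, .data$lo_id, .data$hi_id, .data$bp1_lo) %>%
    distinct(.data$sv_type, .data$lo_id, .data$hi_id, .keep_all = TRUE) %>%
    select(-"lo_id", -"hi_id")
  pairs$pair_id <- seq_len(nrow(pairs))
  sup <- count_rp_support(pairs, discordant, config, per_junction = TRUE)
  pairs$rp_support <- sup$total
  # an event must reach the global support floor; every junction of a
  # 3-breakpoint event must be bridged by at least one discordant pair, and a
  # translocation's deleted source must additionally show the deletion-type
  # far-pair junction
  pairs <- pairs[sup$total >= config$min_rp_support &
                   sup$j1 >= 1L & sup$j2 >= 1L & sup$j3 >= 1L, , drop = FALSE]
  pairs$pair_id <- seq_len(nrow(pairs))
  select(pairs, "pair_id", dplyr::everything())
}

# duplication with insertion locus to the right of the source (p > e):
#   x: L maps into source start (l_start ~ s, direct) or source end
#      (l_end ~ e, inverted); R ends at insertion (r_end ~ p)
#   y: L at source edge; R starts at insertion (r_start ~ p)
match_dup_right <- function(intra, w, config) {
  j <- band_join(intra, intra, "r_end", "r_start", w)
  if (is.null(j) || nrow(j) == 0) return(NULL)
  j <- j[j$split_id_a != j$split_id_b & j$barcode_a != j$barcode_b]
  if (nrow(j) == 0) return(NULL)
  res <- list()
  # direct: x.l_start ~ s, y.l_end ~ e
  bp1 <- bp_from_upper(j$l_start_a + 1, w + 1)
  bp2 <- bp_from_lower(j$l_end_b, w)
  bp3 <- bp_intersect(j$r_end_a, j$r_end_a + w,
                      j$r_start_b - w, j$r_start_b + 1)
  size <- mid(bp2) - mid(bp1)
  disp <- mid(bp3) - mid(bp2)
  keep <- size >= config$min_dup_size & size <= config$max_dup_size &
    disp > config$dup_min_distance &
    j$l_end_a <= j$l_end_b + w & j$l_start_b >= j$l_start_a - w
  res$dir <- mk_pairs("DUP_DIRECT", j[keep], j$chrom1_a[keep],
                      lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                      j$chrom1_a[keep], lapply(bp3, `[`, keep))
  # inverted: x.l_end ~ e, y.l_start ~ s
  bp1 <- bp_from_upper(j$l_start_b + 1, w + 1)
  bp2 <- bp_from_lower(j$l_end_a, w)
  size <- mid(bp2) - mid(bp1)
  disp <- mid(bp3) - mid(bp2)
  keep <- size >= config$min_dup_size & size <= config$max_dup_size &
    disp > config$dup_min_distance &
    j$l_end_b <= j$l_end_a + w & j$l_start_a >= j$l_start_b - w
  res$inv <- mk_pairs("DUP_INVERTED", j[keep], j$chrom1_a[keep],
                      lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                      j$chrom1_a[keep], lapply(bp3, `[`, keep))
  bind_rows(res)
}

# duplication with insertion locus to the left of the source (p < s):
#   x (left junction): l_end ~ p; y (right junction): l_start ~ p
match_dup_left <- function(intra, w, config) {
  j <- band_join(intra, intra, "l_end", "l_start", w)
  if (is.null(j) || nrow(j) == 0) return(NULL)
  j <- j[j$split_id_a != j$split_id_b & j$barcode_a != j$barcode_b]
  if (nrow(j) == 0) return(NULL)
  res <- list()
  bp3 <- bp_intersect(j$l_end_a, j$l_end_a + w,
                      j$l_start_b - w, j$l_start_b + 1)
  # direct: x.r_start ~ s, y.r_end ~ e
  bp1 <- bp_from_upper(j$r_start_a + 1, w + 1)
  bp2 <- bp_from_lower(j$r_end_b, w)
  size <- mid(bp2) - mid(bp1)
  disp <- mid(bp1) - mid(bp3)
  keep <- size >= config$min_dup_size & size <= config$max_dup_size &
    disp > config$dup_min_distance &
    j$r_end_a <= j$r_end_b + w & j$r_start_b >= j$r_start_a - w
  res$dir <- mk_pairs("DUP_DIRECT", j[keep], j$chrom1_a[keep],
                      lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                      j$chrom1_a[keep], lapply(bp3, `[`, keep))
  # inverted: y.r_start ~ s, x.r_end ~ e
  bp1 <- bp_from_upper(j$r_start_b + 1, w + 1)
  bp2 <- bp_from_lower(j$r_end_a, w)
  size <- mid(bp2) - mid(bp1)
  disp <- mid(bp1) - mid(bp3)
  keep <- size >= config$min_dup_size & size <= config$max_dup_size &
    disp > config$dup_min_distance &
    j$r_end_b <= j$r_end_a + w & j$r_start_a >= j$r_start_b - w
  res$inv <- mk_pairs("DUP_INVERTED", j[keep], j$chrom1_a[keep],
                      lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                      j$chrom1_a[keep], lapply(bp3, `[`, keep))
  bind_rows(res)
}

mid <- function(bp) (bp$lo + bp$hi) / 2

# translocation from inter-chromosomal candidate splits; source_side selects
# whether the moved segment lies on the split's chrom1 or chrom2 half.
match_tra <- function(inter, w, config, source_side = 1L) {
  if (nrow(inter) == 0) return(NULL)
  if (source_side == 1L) {
    # source on chrom1: x: l_start ~ s, r_end ~ p; y: l_end ~ e, r_start ~ p
    j <- band_join(inter, inter, "r_end", "r_start", w)
    if (is.null(j) || nrow(j) == 0) return(NULL)
    j <- j[j$split_id_a != j$split_id_b & j$barcode_a != j$barcode_b &
             j$chrom2_a == j$chrom2_b]
    if (nrow(j) == 0) return(NULL)
    bp1 <- bp_from_upper(j$l_start_a + 1, w + 1)
    bp2 <- bp_from_lower(j$l_end_b, w)
    bp3 <- bp_intersect(j$r_end_a, j$r_end_a + w,
                        j$r_start_b - w, j$r_start_b + 1)
    size <- mid(bp2) - mid(bp1)
    keep <- size >= config$min_tra_size &
      j$l_end_a <= j$l_end_b + w & j$l_start_b >= j$l_start_a - w
    mk_pairs("TRA", j[keep], j$chrom1_a[keep],
             lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
             j$chrom2_a[keep], lapply(bp3, `[`, keep))
  } else {
    # source on chrom2: x: r_start ~ s, l_end ~ p; y: r_end ~ e, l_start ~ p
    j <- band_join(inter, inter, "l_end", "l_start", w)
    if (is.null(j) || nrow(j) == 0) return(NULL)
    j <- j[j$split_id_a != j$split_id_b & j$barcode_a != j$barcode_b &
             j$chrom2_a == j$chrom2_b]
    if (nrow(j) == 0) return(NULL)
    bp1 <- bp_from_upper(j$r_start_a + 1, w + 1)
    bp2 <- bp_from_lower(j$r_end_b, w)
    bp3 <- bp_intersect(j$l_end_a, j$l_end_a + w,
                        j$l_start_b - w, j$l_start_b + 1)
    size <- mid(bp2) - mid(bp1)
    keep <- size >= config$min_tra_size &
      j$r_end_a <= j$r_end_b + w & j$r_start_b >= j$r_start_a - w
    mk_pairs("TRA", j[keep], j$chrom2_a[keep],
             lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
             j$chrom1_a[keep], lapply(bp3, `[`, keep))
  }
}

# translocation pairs built from one source-side (intra-chromosomal,
# deletion-like) split and one insertion-junction (inter-chromosomal) split
match_tra_source <- function(intra, inter, w, config, source_side = 1L) {
  if (nrow(intra) == 0 || nrow(inter) == 0) return(NULL)
  res <- list()
  if (source_side == 1L) {
    # source on the inter split's chrom1
    # S x left-junction split: both constrain the source start s
    j <- band_join(intra, inter, "l_end", "l_start", w)
    if (!is.null(j) && nrow(j) > 0) {
      j <- j[j$barcode_a != j$barcode_b]
      bp1 <- bp_intersect(j$l_end_a, j$l_end_a + w,
                          j$l_start_b - w, j$l_start_b + 1)
      bp2 <- bp_from_upper(j$r_start_a + 1, w + 1)
      bp3 <- bp_from_lower(j$r_end_b, w)
      size <- mid(bp2) - mid(bp1)
      keep <- size >= config$min_tra_size
      res$sx <- mk_pairs("TRA", j[keep], j$chrom1_a[keep],
                         lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                         j$chrom2_b[keep], lapply(bp3, `[`, keep))
    }
    # S x right-junction split: both constrain the source end e
    j <- band_join(intra, inter, "r_start", "l_end", w)
    if (!is.null(j) && nrow(j) > 0) {
      j <- j[j$barcode_a != j$barcode_b]
      bp1 <- bp_from_lower(j$l_end_a, w)
      bp2 <- bp_intersect(j$l_end_b, j$l_end_b + w,
                          j$r_start_a - w, j$r_start_a + 1)
      bp3 <- bp_from_upper(j$r_start_b + 1, w + 1)
      size <- mid(bp2) - mid(bp1)
      keep <- size >= config$min_tra_size
      res$sy <- mk_pairs("TRA", j[keep], j$chrom1_a[keep],
                         lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                         j$chrom2_b[keep], lapply(bp3, `[`, keep))
    }
  } else {
    # source on the inter split's chrom2 (insertion chromosome sorts first)
    inter2 <- inter
    j <- band_join(intra, inter2, "l_end", "r_start", w,
                   key_a = "chrom1", key_b = "chrom2")
    if (!is.null(j) && nrow(j) > 0) {
      j <- j[j$barcode_a != j$barcode_b]
      bp1 <- bp_intersect(j$l_end_a, j$l_end_a + w,
                          j$r_start_b - w, j$r_start_b + 1)
      bp2 <- bp_from_upper(j$r_start_a + 1, w + 1)
      bp3 <- bp_from_lower(j$l_end_b, w)
      size <- mid(bp2) - mid(bp1)
      keep <- size >= config$min_tra_size
      res$sx <- mk_pairs("TRA", j[keep], j$chrom1_a[keep],
                         lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                         j$chrom1_b[keep], lapply(bp3, `[`, keep))
    }
    j <- band_join(intra, inter2, "r_start", "r_end", w,
                   key_a = "chrom1", key_b = "chrom2")
    if (!is.null(j) && nrow(j) > 0) {
      j <- j[j$barcode_a != j$barcode_b]
      bp1 <- bp_from_lower(j$l_end_a, w)
      bp2 <- bp_intersect(j$r_end_b, j$r_end_b + w,
                          j$r_start_a - w, j$r_start_a + 1)
      bp3 <- bp_from_upper(j$l_start_b + 1, w + 1)
      size <- mid(bp2) - mid(bp1)
      keep <- size >= config$min_tra_size
      res$sy <- mk_pairs("TRA", j[keep], j$chrom1_a[keep],
                         lapply(bp1, `[`, keep), lapply(bp2, `[`, keep),
                         j$chrom1_b[keep], lapply(bp3, `[`, keep))
    }
  }
  out <- bind_rows(res)
  if (is.null(out) || nrow(out) == 0) NULL else out
}

# expected discordant classes per SV type (TRA_SRC: the deleted source of a
# non-reciprocal translocation is itself a junction bridged by FR-far pairs)
rp_classes <- list(
  DEL = "intra_far",
  INV = c("intra_inverted_FF", "intra_inverted_RR"),
  DUP_DIRECT = c("intra_everted_RF", "intra_far"),
  DUP_INVERTED = c("intra_inverted_FF", "intra_inverted_RR"),
  TRA = "interchromosomal",
  TRA_SRC = "intra_far")

#' Count discordant read pairs supporting split-molecule pairs
#'
#' For each split-molecule pair, counts discordant read pairs of the SV
#' type's expected orientation class whose two ends fall inside the pair's
#' breakpoint intervals padded by `rp_pad` (DEL/INV: one end per breakpoint;
#' DUP/TRA: one end at a source edge, the other at the insertion locus).
#'
#' @param pairs split-molecule-pair tibble.
#' @param discordant discordant-pair tibble.
#' @param config a [caller_config()].
#' @param pad padding in bp; default `config$rp_pad` or 1000.
#' @param per_junction also return per-junction counts (for 3-breakpoint
#'   events, junction 1 = bp1-bp3, junction 2 = bp2-bp3; for 2-breakpoint
#'   events both equal the total).
#' @return Integer vector of support counts aligned with `pairs`, or, with
#'   `per_junction = TRUE`, a tibble with columns `total`, `j1`, `j2`.
#' @export
count_rp_support <- function(pairs, discordant, config = caller_config(),
                             pad = NULL, per_junction = FALSE) {
  n <- nrow(pairs)
  wrap <- function(total, j1 = total, j2 = total, j3 = total) {
    if (per_junction) tibble(total = total, j1 = j1, j2 = j2, j3 = j3)
    else total
  }
  if (n == 0) return(wrap(integer(0)))
  pad <- pad %||% config$rp_pad %||% 1000
  # window-pair table: one row per (pair, window combination)
  base <- tibble(pid = seq_len(n), junction = 1L, sv_type = pairs$sv_type,
                 cA = pairs$chrom1, loA = pairs$bp1_lo - pad,
                 hiA = pairs$bp1_hi + pad,
                 cB = pairs$chrom1, loB = pairs$bp2_lo - pad,
                 hiB = pairs$bp2_hi + pad)
  two_bp <- pairs$sv_type %in% c("DEL", "INV")
  wp <- base[two_bp, , drop = FALSE]
  if (any(!two_bp)) {
    p3 <- pairs[!two_bp, , drop = FALSE]
    pid3 <- which(!two_bp)
    wp <- bind_rows(
      wp,
      tibble(pid = pid3, junction = 1L, sv_type = p3$sv_type, cA = p3$chrom1,
             loA = p3$bp1_lo - pad, hiA = p3$bp1_hi + pad,
             cB = p3$chrom3, loB = p3$bp3_lo - pad, hiB = p3$bp3_hi + pad),
      tibble(pid = pid3, junction = 2L, sv_type = p3$sv_type, cA = p3$chrom1,
             loA = p3$bp2_lo - pad, hiA = p3$bp2_hi + pad,
             cB = p3$chrom3, loB = p3$bp3_lo - pad, hiB = p3$bp3_hi + pad))
    is_tra <- p3$sv_type == "TRA"
    if (any(is_tra)) {
      pt <- p3[is_tra, , drop = FALSE]
      wp <- bind_rows(
        wp,
        tibble(pid = pid3[is_tra], junction = 3L, sv_type = "TRA_SRC",
               cA = pt$chrom1, loA = pt$bp1_lo - pad, hiA = pt$bp1_hi + pad,
               cB = pt$chrom1, loB = pt$bp2_lo - pad, hiB = pt$bp2_hi + pad))
    }
  }
  if (nrow(discordant) == 0 || nrow(wp) == 0) return(wrap(integer(n)))
  # canonicalize each window pair like discordant pairs are canonicalized:
  # (chromA, loA) first in chromosome order of appearance
  chrom_order <- unique(c(discordant$chrom1, discordant$chrom2, wp$cA, wp$cB))
  swap <- match(wp$cA, chrom_order) > match(wp$cB, chrom_order) |
    (wp$cA == wp$cB & wp$loA > wp$loB)
  wp2 <- wp
  wp2$cA[swap] <- wp$cB[swap]; wp2$loA[swap] <- wp$loB[swap]
  wp2$hiA[swap] <- wp$hiB[swap]
  wp2$cB[swap] <- wp$cA[swap]; wp2$loB[swap] <- wp$loA[swap]
  wp2$hiB[swap] <- wp$hiA[swap]
  wdt <- data.table::as.data.table(wp2)
  data.table::setkey(wdt, cA, loA, hiA)
  ddt <- data.table::data.table(chrom = discordant$chrom1,
                                s = discordant$pos1, e = discordant$pos1,
                                c2 = discordant$chrom2, p2 = discordant$pos2,
                                cls = discordant$pair_class)
  ov <- data.table::foverlaps(ddt, wdt, by.x = c("chrom", "s", "e"),
                              type = "within", nomatch = NULL)
  ok <- ov[ov$c2 == ov$cB & ov$p2 >= ov$loB & ov$p2 <= ov$hiB]
  if (nrow(ok) == 0) return(wrap(integer(n), integer(n), integer(n),
                                 if_else(pairs$sv_type == "TRA", 0L, 0L)))
  ok <- ok[mapply(function(cl, tp) cl %in% rp_classes[[tp]],
                  ok$cls, ok$sv_type)]
  cnt <- integer(n)
  cj1 <- integer(n)
  cj2 <- integer(n)
  cj3 <- integer(n)
  if (nrow(ok) > 0) {
    tb <- table(ok$pid[ok$junction != 3L])
    cnt[as.integer(names(tb))] <- as.integer(tb)
    t1 <- table(ok$pid[ok$junction == 1L])
    cj1[as.integer(names(t1))] <- as.integer(t1)
    t2 <- table(ok$pid[ok$junction == 2L])
    cj2[as.integer(names(t2))] <- as.integer(t2)
    t3 <- table(ok$pid[ok$junction == 3L])
    cj3[as.integer(names(t3))] <- as.integer(t3)
  }
  cj1[two_bp] <- cnt[two_bp]
  cj2[two_bp] <- cnt[two_bp]
  cj3[pairs$sv_type != "TRA"] <- cnt[pairs$sv_type != "TRA"]
  wrap(cnt, cj1, cj2, cj3)
}

#' Test one split pair against one SV type's signature
#'
#' Scalar wrapper around the same geometry used by
#' [match_split_molecule_pairs()]: returns whether the two candidate splits
#' are arrangeable as the given SV type, and if so the implied breakpoint
#' intervals (insertion locus as breakpoint 3 for duplications and
#' translocations).
#'
#' @param sv_type one of `DEL`, `INV`, `DUP_DIRECT`, `DUP_INVERTED`, `TRA`.
#' @param split_a,split_b single-row candidate-split tibbles (different
#'   barcodes).
#' @param stats a [molecule_stats()].
#' @param config a [caller_config()].
#' @return A list with `ok` (logical) and, when `ok`, `bp1`, `bp2` (and
#'   `bp3`) as `c(lo, hi)` plus `chrom1`/`chrom3`.
#' @export
signature_predicate <- function(sv_type, split_a, split_b, stats,
                                config = caller_config()) {
  if (!sv_type %in% sv_types) abort(paste("unknown sv_type:", sv_type))
  splits <- bind_rows(split_a, split_b)
  splits$split_id <- c(1L, 2L)
  if (!"inter" %in% names(splits)) splits$inter <- splits$chrom1 != splits$chrom2
  w <- bp_window(config, stats)
  intra <- splits[!splits$inter, , drop = FALSE]
  inter <- splits[splits$inter, , drop = FALSE]
  res <- switch(sv_type,
    DEL = {
      j <- band_join(intra, intra, "l_end", "l_end", w)
      if (!is.null(j)) {
        j <- j[j$split_id_a < j$split_id_b & j$barcode_a != j$barcode_b &
                 abs(j$r_start_a - j$r_start_b) <= w]
        bp1 <- bp_from_lower(pmax(j$l_end_a, j$l_end_b), w)
        bp2 <- bp_from_upper(pmin(j$r_start_a, j$r_start_b), w)
        size <- (j$r_start_a + j$r_start_b) / 2 - (j$l_end_a + j$l_end_b) / 2
        keep <- size >= config$min_del_size & bp1$hi <= bp2$lo
        mk_pairs("DEL", j[keep], j$chrom1_a[keep],
                 lapply(bp1, `[`, keep), lapply(bp2, `[`, keep))
      }
    },
    INV = {
      j <- band_join(intra, intra, "l_end", "l_start", w)
      if (!is.null(j)) {
        j <- j[j$split_id_a != j$split_id_b & j$barcode_a != j$barcode_b &
                 abs(j$r_end_a - j$r_start_b) <= w]
        bp1 <- bp_intersect(j$l_end_a, j$l_end_a + w,
                            j$l_start_b - w, j$l_start_b + 1)
        bp2 <- bp_intersect(j$r_end_a, j$r_end_a + w,
                            j$r_start_b - w, j$r_start_b + 1)
        size <- (bp2$lo + bp2$hi) / 2 - (bp1$lo + bp1$hi) / 2
        keep <- size >= config$min_inv_size & size <= config$max_inv_size
        mk_pairs("INV", j[keep], j$chrom1_a[keep],
                 lapply(bp1, `[`, keep), lapply(bp2, `[`, keep))
      }
    },
    DUP_DIRECT = ,
    DUP_INVERTED = {
      r <- bind_rows(match_dup_right(intra, w, config),
                     match_dup_left(intra, w, config))
      if (!is.null(r) && nrow(r) > 0) r[r$sv_type == sv_type, ] else NULL
    },
    TRA = bind_rows(match_tra(inter, w, config, 1L),
                    match_tra(inter, w, config, 2L)))
  if (is.null(res) || nrow(res) == 0) return(list(ok = FALSE))
  res <- res[1, ]
  list(ok = TRUE, chrom1 = res$chrom1,
       bp1 = c(res$bp1_lo, res$bp1_hi), bp2 = c(res$bp2_lo, res$bp2_hi),
       chrom3 = res$chrom3,
       bp3 = if (is.na(res$bp3_lo)) NULL else c(res$bp3_lo, res$bp3_hi))
}
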