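#' Load a satellite/low-complexity exclusion mask from BED
#'
#' Reads a BED3+ file of regions to exclude (satellite and other
#' low-complexity regions where mapping is unreliable) and normalizes it:
#' intervals are sorted and overlapping or bookended intervals are merged, so
#' membership queries are deterministic.
#'
#' @param path BED3+ file (0-based half-open, as BED is defined).
#' @return A tibble (`chrom`, `start`, `end`) of class `region_mask`, sorted
#'   and non-overlapping. An empty file yields an empty mask.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t10", "chr1\t5\t20"), bed)
#' load_region_mask(bed)  # one merged interval [0, 20)
load_region_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_mask())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) {
      abort(sprintf("malformed BED line %d in %s", i, path))
    }
  }
  tbl <- tibble(chrom = vapply(fields, `[`, "", 1),
                start = as.numeric(vapply(fields, `[`, "", 2)),
                end = as.numeric(vapply(fields, `[`, "", 3)))
  normalize_mask(tbl)
}

empty_mask <- function() {
  structure(tibble(chrom = character(), start = numeric(), end = numeric()),
            class = c("region_mask", class(tibble())))
}

#' Normalize a mask: sort and merge overlapping intervals
#'
#' @param tbl tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return A `region_mask` tibble.
#' @export
normalize_mask <- function(tbl) {
  if (nrow(tbl) == 0) return(empty_mask())
  gr <- GenomicRanges::GRanges(tbl$chrom,
                               IRanges::IRanges(tbl$start + 1, tbl$end))
  gr <- GenomicRanges::reduce(gr)
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1,
                end = GenomicRanges::end(gr)) %>%
    arrange(.data$chrom, .data$start)
  structure(out, class = c("region_mask", class(tibble())))
}

#' Query mask membership
#'
#' `mask_excludes_pos()` tests single positions; `mask_excludes_interval()`
#' tests whether an interval overlaps any masked region.
#'
#' @param mask a `region_mask` (or `NULL`, excluding nothing).
#' @param chrom,pos,start,end vectors of positions/intervals (0-based).
#' @return Logical vector.
#' @export
mask_excludes_pos <- function(mask, chrom, pos) {
  mask_excludes_interval(mask, chrom, pos, pos + 1)
}

#' @rdname mask_excludes_pos
#' @export
mask_excludes_interval <- function(mask, chrom, start, end) {
  n <- length(start)
  if (is.null(mask) || nrow(mask) == 0 || n == 0) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, pmax(end, start + 1)))
  m <- GenomicRanges::GRanges(mask$chrom, IRanges::IRanges(mask$start + 1, mask$end))
  # chromosomes absent from the mask are simply unmasked, not a warning
  suppressWarnings(IRanges::overlapsAny(q, m))
}

#' Estimate concordant insert-span bounds from the data
#'
#' Samples properly oriented (FR) same-chromosome pairs with spans below an
#' initial cap and returns `mean +/- 4 sd` of the outer span as the
#' concordance window, the standard read-pair convention.
#'
#' @param pairs read-pair tibble (see [classify_read_pairs()]).
#' @param config a [caller_config()].
#' @param init_cap initial span cap in bp for the estimation sample.
#' @param n_sample maximum number of pairs used.
#' @return Numeric `c(min, max)`.
#' @export
estimate_concordance <- function(pairs, config = caller_config(),
                                 init_cap = 50000, n_sample = 1e6) {
  span <- pairs$pos2 + config$read_len - pairs$pos1
  ok <- pairs$chrom1 == pairs$chrom2 & pairs$strand1 == "+" &
    pairs$strand2 == "-" & span > 0 & span <= init_cap
  s <- span[ok]
  if (length(s) > n_sample) s <- s[seq_len(n_sample)]
  if (length(s) < 2) abort("too few proper pairs to estimate concordance bounds")
  mu <- mean(s)
  sdev <- sd(s)
  c(max(0, mu - 4 * sdev), mu + 4 * sdev)
}

#' Classify barcoded read pairs into fragments and discordant pairs
#'
#' Partitions read pairs: a properly oriented FR pair on one chromosome with
#' insert span inside the concordance window, both mates unmasked and above
#' the MAPQ floor, becomes one *fragment* (the full outer span of the pair);
#' every other retained pair becomes a *discordant pair* labelled with its
#' orientation class. Records without a barcode are skipped and counted.
#'
#' Discordant classes: `interchromosomal`; `intra_inverted_FF` / `_RR`
#' (inversion signature); `intra_far` (FR with span above the window,
#' deletion-type signature); `intra_everted_RF` (RF, direct-duplication
#' signature); `intra_short` (FR below the window).
#'
#' @param pairs tibble with columns `chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`, `barcode`, `mapq` (0-based positions, canonical
#'   (chrom1,pos1) <= (chrom2,pos2) order; rows are re-canonicalized if not).
#' @param mask optional `region_mask`.
#' @param config a [caller_config()].
#' @param chrom_order chromosome ordering used for canonicalization; default
#'   the order of appearance.
#' @return A list of class `classified_pairs`:
#'   * `fragments`: tibble `chrom`, `start`, `end`, `barcode`;
#'   * `discordant`: tibble `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'     `strand2`, `barcode`, `pair_class`;
#'   * `concordance`: the `c(min, max)` window used;
#'   * `counts`: named vector of input/skipped/emitted record counts.
#' @export
classify_read_pairs <- function(pairs, mask = NULL, config = caller_config(),
                                chrom_order = NULL) {
  req <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
           "barcode", "mapq")
  if (!all(req %in% names(pairs))) {
    abort(paste("pairs tibble must have columns:", paste(req, collapse = ", ")))
  }
  n_in <- nrow(pairs)
  no_bc <- is.na(pairs$barcode) | pairs$barcode == ""
  if (n_in > 0 && all(no_bc)) {
    abort("no record carries a barcode; check the barcode tag")
  }
  pairs <- pairs[!no_bc, , drop = FALSE]
  low_q <- pairs$mapq < config$mapq_min
  pairs <- pairs[!low_q, , drop = FALSE]
  rl <- config$read_len
  masked <- mask_excludes_interval(mask, pairs$chrom1, pairs$pos1, pairs$pos1 + rl) |
    mask_excludes_interval(mask, pairs$chrom2, pairs$pos2, pairs$pos2 + rl)
  pairs <- pairs[!masked, , drop = FALSE]

  if (is.null(chrom_order)) chrom_order <- unique(c(pairs$chrom1, pairs$chrom2))
  pairs <- canonicalize_pairs(pairs, chrom_order)

  conc <- config$concordance
  if (is.null(conc)) conc <- estimate_concordance(pairs, config)

  span <- pairs$pos2 + rl - pairs$pos1
  same <- pairs$chrom1 == pairs$chrom2
  fr <- pairs$strand1 == "+" & pairs$strand2 == "-"
  ff <- pairs$strand1 == "+" & pairs$strand2 == "+"
  rr <- pairs$strand1 == "-" & pairs$strand2 == "-"
  rf <- pairs$strand1 == "-" & pairs$strand2 == "+"
  concordant <- same & fr & span >= conc[1] & span <= conc[2]

  frag <- tibble(chrom = pairs$chrom1[concordant],
                 start = pairs$pos1[concordant],
                 end = pairs$pos2[concordant] + rl,
                 barcode = pairs$barcode[concordant])

  d <- pairs[!concordant, , drop = FALSE]
  dsame <- same[!concordant]
  cls <- dplyr::case_when(
    !dsame ~ "interchromosomal",
    ff[!concordant] ~ "intra_inverted_FF",
    rr[!concordant] ~ "intra_inverted_RR",
    rf[!concordant] ~ "intra_everted_RF",
    fr[!concordant] & span[!concordant] > conc[2] ~ "intra_far",
    TRUE ~ "intra_short"
  )
  disc <- tibble(chrom1 = d$chrom1, pos1 = d$pos1, strand1 = d$strand1,
                 chrom2 = d$chrom2, pos2 = d$pos2, strand2 = d$strand2,
                 barcode = d$barcode, pair_class = cls)

  structure(list(
    fragments = arrange(frag, match(.data$chrom, chrom_order), .data$start),
    discordant = arrange(disc, match(.data$chrom1, chrom_order), .data$pos1),
    concordance = conc,
    counts = c(input = n_in, no_barcode = sum(no_bc), low_mapq = sum(low_q),
               masked = sum(masked), fragments = nrow(frag),
               discordant = nrow(disc))
  ), class = "classified_pairs")
}

#' Read barcoded read pairs from a BAM file
#'
#' Loads primary, non-duplicate, mapped-pair records carrying the barcode tag
#' from a coordinate-sorted BAM and returns one row per read pair in the
#' package's pair-tibble layout (0-based positions).
#'
#' @param path BAM file path (indexed or not; read sequentially).
#' @param barcode_tag barcode tag name (linked-read convention `BX`).
#' @return Pair tibble suitable for [classify_read_pairs()].
#' @export
read_linked_alignments <- function(path, barcode_tag = "BX") {
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  so <- hdr$text[["@HD"]]
  if (!is.null(so) && !any(grepl("SO:coordinate", so))) {
    abort("BAM file is not coordinate-sorted")
  }
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isFirstMateRead = TRUE)
  p <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("flag", "rname", "strand", "pos", "mapq", "mrnm", "mpos"),
    tag = barcode_tag)
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  bc <- b$tag[[barcode_tag]]
  if (is.null(bc)) bc <- rep(NA_character_, length(b$pos))
  mate_rev <- bitwAnd(b$flag, 32L) != 0L
  pairs <- tibble(
    chrom1 = as.character(b$rname), pos1 = b$pos - 1,
    strand1 = as.character(b$strand),
    chrom2 = as.character(b$mrnm), pos2 = b$mpos - 1,
    strand2 = ifelse(mate_rev, "-", "+"),
    barcode = as.character(bc), mapq = b$mapq)
  chrom_order <- names(hdr$targets)
  canonicalize_pairs(pairs, chrom_order)
}

#' Write simulated read pairs as SAM/BAM
#'
#' Emits two 150M records per pair with the barcode in the `BX` tag,
#' coordinate-sorted; `write_linked_bam()` additionally converts to an
#' indexed BAM via Rsamtools.
#'
#' @param pairs pair tibble (as produced by [simulate_linked_reads()]).
#' @param genome named chromosome length vector for the header.
#' @param path output path (`.sam` for `write_linked_sam`).
#' @param read_len read length used for flags/CIGAR.
#' @return The output path, invisibly (for `write_linked_bam`, the BAM path).
#' @export
write_linked_sam <- function(pairs, genome, path, read_len = 150L) {
  n <- nrow(pairs)
  qname <- sprintf("p%07d", seq_len(n))
  # mate1 and mate2 records
  f1 <- 1L + 64L + ifelse(pairs$strand1 == "-", 16L, 0L) +
    ifelse(pairs$strand2 == "-", 32L, 0L)
  f2 <- 1L + 128L + ifelse(pairs$strand2 == "-", 16L, 0L) +
    ifelse(pairs$strand1 == "-", 32L, 0L)
  rec <- tibble(
    qname = c(qname, qname),
    flag = c(f1, f2),
    rname = c(pairs$chrom1, pairs$chrom2),
    pos = c(pairs$pos1, pairs$pos2) + 1,
    mapq = c(pairs$mapq, pairs$mapq),
    rnext = c(pairs$chrom2, pairs$chrom1),
    pnext = c(pairs$pos2, pairs$pos1) + 1,
    bx = c(pairs$barcode, pairs$barcode))
  rec <- arrange(rec, match(.data$rname, names(genome)), .data$pos)
  hd <- c("@HD\tVN:1.6\tSO:coordinate",
          sprintf("@SQ\tSN:%s\tLN:%d", names(genome), as.integer(genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*\tBX:Z:%s",
                  rec$qname, rec$flag, rec$rname, as.integer(rec$pos),
                  as.integer(rec$mapq), as.integer(read_len),
                  ifelse(rec$rnext == rec$rname, "=", rec$rnext),
                  as.integer(rec$pnext), rec$bx)
  writeLines(c(hd, body), path)
  invisible(path)
}

#' @rdname write_linked_sam
#' @export
write_linked_bam <- function(pairs, genome, path, read_len = 150L) {
  sam <- sub("\\.bam$", ".sam", path)
  if (identical(sam, path)) sam <- paste0(path, ".sam")
  write_linked_sam(pairs, genome, sam, read_len = read_len)
  bam <- Rsamtools::asBam(sam, sub("\\.bam$", "", path),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(bam)
}
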