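#' Call large structural variants from linked-read alignments
#'
#' Runs the full discovery pipeline: classify barcoded read pairs into
#' concordant fragments and discordant pairs; recover submolecules per
#' barcode (two-pass, bootstrapping the molecule-size estimate); compute the
#' genome-wide molecule-depth profile; enumerate candidate splits (plus
#' anchored inter-chromosomal splits for translocations) and prune those
#' without read-pair support; match splits across barcodes into
#' split-molecule pairs per SV signature; cluster pairs into quasi-cliques on
#' the SV graph; convert cliques to calls and apply the molecule-depth
#' filter. Same-type calls overlapping reciprocally are merged at reporting.
#'
#' @param input read pairs as a tibble (see [classify_read_pairs()]), a
#'   `linked_sim` object from [simulate_linked_reads()], or a path to a
#'   coordinate-sorted BAM with barcode tags.
#' @param mask optional `region_mask` of excluded (satellite) regions.
#' @param config a [caller_config()].
#' @param genome named chromosome length vector; taken from the simulation or
#'   BAM header when `input` carries one, otherwise inferred from the data.
#' @return An `sv_callset`: list with `calls` (all calls with
#'   `filter_status`), `stats` (final [molecule_stats()]), `profile`
#'   (`depth_profile`), `counts` (records surviving each stage), `config`.
#'   PASS calls via [pass_calls()] or `tidy()`.
#' @export
#' @examples
#' sim <- simulate_linked_reads(sim_config(genome = c(chr1 = 3e6),
#'   phys_cov = 15, seed = 2))
#' cs <- call_svs(sim)
#' glance(cs)
call_svs <- function(input, mask = NULL, config = caller_config(),
                     genome = NULL) {
  if (inherits(input, "linked_sim")) {
    genome <- genome %||% input$config$genome
    pairs <- input$reads
  } else if (is.character(input)) {
    hdr <- Rsamtools::scanBamHeader(input)[[1]]
    genome <- genome %||% hdr$targets
    pairs <- read_linked_alignments(input, barcode_tag = config$barcode_tag)
  } else {
    pairs <- input
  }
  if (is.null(genome)) {
    genome <- tapply(pmax(pairs$pos1, pairs$pos2) + 2 * config$read_len,
                     pairs$chrom1, max)
    genome <- setNames(as.numeric(genome), names(genome))
    if (length(genome) == 0) genome <- c(chr1 = 1e6)
  }
  if (nrow(pairs) == 0) {
    empty_calls <- cliques_to_calls(
      tibble(clique_id = integer(), sv_type = character(), members = list(),
             n_vertices = integer(), n_edges = integer(),
             gamma_achieved = numeric()),
      tibble(), tibble(), config)
    counts <- c(input = 0L, no_barcode = 0L, low_mapq = 0L, masked = 0L,
                fragments = 0L, discordant = 0L, submolecules = 0L,
                candidate_splits = 0L, supported_splits = 0L,
                split_molecule_pairs = 0L, quasi_cliques = 0L,
                calls = 0L, pass = 0L)
    return(structure(
      list(calls = empty_calls,
           stats = molecule_stats(config$mu_init, config = config),
           profile = compute_depth_profile(
             tibble(chrom = character(), start = numeric(), end = numeric()),
             genome, mask = mask, bin_size = config$depth_bin_size),
           graph = build_sv_graph(tibble(pair_id = integer())),
           counts = counts, config = config, genome = genome),
      class = "sv_callset"))
  }
  cls <- classify_read_pairs(pairs, mask = mask, config = config,
                             chrom_order = names(genome))
  rec <- recover_molecules(cls$fragments, config)
  sub <- rec$submolecules
  stats <- rec$stats
  profile <- compute_depth_profile(sub, genome, mask = mask,
                                   bin_size = config$depth_bin_size)
  cfg <- config
  if (is.null(cfg$rp_pad)) cfg$rp_pad <- ceiling(cls$concordance[2])
  splits <- enumerate_candidate_splits(sub, stats, cfg)
  tra_splits <- anchor_translocation_splits(cls$discordant, sub, stats, cfg)
  all_splits <- bind_rows(splits, tra_splits)
  supported <- filter_splits_by_support(all_splits, cls$discordant, stats, cfg)
  pairs_sm <- match_split_molecule_pairs(supported, cls$discordant, stats, cfg)
  graph <- build_sv_graph(pairs_sm)
  cliques <- find_quasi_cliques(graph, gamma = cfg$gamma,
                                min_support = cfg$min_support)
  calls <- cliques_to_calls(cliques, pairs_sm, cls$discordant, cfg)
  calls <- filter_by_molecule_depth(calls, profile)
  if (cfg$merge_calls && nrow(calls) > 1) {
    pass <- calls[calls$filter_status == "PASS", , drop = FALSE]
    rest <- calls[calls$filter_status != "PASS", , drop = FALSE]
    pass <- dedupe_calls(pass, ins_tol = stats$mu / 2)
    calls <- bind_rows(pass, rest) %>%
      arrange(.data$sv_type, .data$chrom1, .data$bp1_lo)
    calls$call_id <- seq_len(nrow(calls))
  }
  counts <- c(cls$counts,
              submolecules = nrow(sub),
              candidate_splits = nrow(all_splits),
              supported_splits = nrow(supported),
              split_molecule_pairs = nrow(pairs_sm),
              quasi_cliques = nrow(cliques),
              calls = nrow(calls),
              pass = sum(calls$filter_status == "PASS"))
  structure(list(calls = calls, stats = stats, profile = profile,
                 graph = graph, counts = counts, config = cfg,
                 genome = genome),
            class = "sv_callset")
}

#' PASS calls of a callset
#'
#' @param x an `sv_callset`.
#' @return Tibble of calls with `filter_status == "PASS"`.
#' @export
pass_calls <- function(x) {
  x$calls[x$calls$filter_status == "PASS", , drop = FALSE]
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset> %d calls (%d PASS) | mu_molecule=%.0f bp, mu_depth=%.1f\n",
              nrow(x$calls), sum(x$calls$filter_status == "PASS"),
              x$stats$mu, x$profile$mu_depth))
  tab <- table(pass_calls(x)$sv_type)
  if (length(tab) > 0) {
    cat("  PASS by type:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy methods for callsets
#'
#' `tidy()` returns the PASS calls as a tibble (`all = TRUE` for every call);
#' `glance()` returns a one-row summary of stage counts and depth/molecule
#' statistics.
#'
#' @param x an `sv_callset`.
#' @param all include non-PASS calls.
#' @param ... unused.
#' @return A tibble.
#' @method tidy sv_callset
#' @export
tidy.sv_callset <- function(x, all = FALSE, ...) {
  if (all) x$calls else pass_calls(x)
}

#' @rdname tidy.sv_callset
#' @method glance sv_callset
#' @export
glance.sv_callset <- function(x, ...) {
  bind_cols(tibble(mu_molecule = x$stats$mu, sigma_molecule = x$stats$sigma,
                   mu_depth = x$profile$mu_depth,
                   sigma_depth = x$profile$sigma_depth),
            as_tibble(as.list(x$counts)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- output formats --------------------------------------------------------

#' Write calls as BEDPE
#'
#' Standard ten BEDPE columns (breakpoint-1 interval, breakpoint-2 interval,
#' name = SV type, score = number of supporting split molecules) followed by
#' the insertion-locus interval, read-pair support, source molecule depth,
#' and filter status. Coordinates are 0-based half-open.
#'
#' @param x an `sv_callset` or call tibble.
#' @param path output file.
#' @param pass_only write only PASS calls.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path, pass_only = TRUE) {
  calls <- if (inherits(x, "sv_callset")) x$calls else x
  if (pass_only && nrow(calls) > 0) {
    calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  }
  out <- tibble(
    chrom1 = calls$chrom1, start1 = calls$bp1_lo, end1 = calls$bp1_hi,
    chrom2 = calls$chrom1, start2 = calls$bp2_lo, end2 = calls$bp2_hi,
    name = calls$sv_type, score = calls$n_split_molecules,
    strand1 = ".", strand2 = ".",
    ins_chrom = if_else(is.na(calls$chrom3), ".", calls$chrom3),
    ins_start = calls$bp3_lo, ins_end = calls$bp3_hi,
    rp_support = calls$rp_support, depth_source = calls$depth_source,
    filter = calls$filter_status)
  readr::write_tsv(out, path, col_names = TRUE)
  invisible(path)
}

#' Read a BEDPE call file written by [write_bedpe()]
#'
#' @param path BEDPE file.
#' @return A call tibble.
#' @export
read_bedpe <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble(call_id = seq_len(nrow(x)), sv_type = x$name,
         chrom1 = x$chrom1, bp1_lo = x$start1, bp1_hi = x$end1,
         bp2_lo = x$start2, bp2_hi = x$end2,
         chrom3 = if_else(x$ins_chrom == ".", NA_character_, x$ins_chrom),
         bp3_lo = x$ins_start, bp3_hi = x$ins_end,
         n_split_molecules = x$score, n_barcodes = NA_integer_,
         rp_support = x$rp_support, depth_source = x$depth_source,
         filter_status = x$filter)
}

#' Write calls as VCF 4.2 with symbolic alleles
#'
#' One record per call with symbolic ALT (`<DEL>`, `<INV>`, `<DUP>`,
#' `<TRA>`), 1-based positions at the breakpoint-interval midpoints,
#' confidence intervals in `CIPOS`/`CIEND`, the second breakpoint in
#' `END`/`CHR2`/`POS2`, and the insertion locus in `INSCHROM`/`INSPOS`.
#'
#' @param x an `sv_callset` or call tibble.
#' @param path output file.
#' @param genome named chromosome length vector for contig headers (taken
#'   from the callset if present).
#' @param pass_only write only PASS calls.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path, genome = NULL, pass_only = TRUE) {
  calls <- if (inherits(x, "sv_callset")) x$calls else x
  if (is.null(genome) && inherits(x, "sv_callset")) genome <- x$genome
  if (pass_only && nrow(calls) > 0) {
    calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=splitmol",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", names(genome), as.integer(genome))
    },
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=DUP,Description=\"Interspersed segmental duplication\">",
    "##ALT=<ID=TRA,Description=\"Non-reciprocal translocation\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Chromosome of breakpoint 2\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Position of breakpoint 2\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"CI around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"CI around END\">",
    "##INFO=<ID=INSCHROM,Number=1,Type=String,Description=\"Insertion locus chromosome\">",
    "##INFO=<ID=INSPOS,Number=1,Type=Integer,Description=\"Insertion locus position\">",
    "##INFO=<ID=ORIENT,Number=1,Type=String,Description=\"Duplication orientation\">",
    "##INFO=<ID=SPLITMOL,Number=1,Type=Integer,Description=\"Supporting split molecules\">",
    "##INFO=<ID=RPSUP,Number=1,Type=Integer,Description=\"Supporting discordant read pairs\">",
    "##FILTER=<ID=depth_fail,Description=\"Molecule depth outside expected range\">",
    "##FILTER=<ID=no_depth,Description=\"No depth information at source\">",
    "##FILTER=<ID=min_support_fail,Description=\"Too few split molecules\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  p1 <- floor((calls$bp1_lo + calls$bp1_hi) / 2) + 1
  p2 <- floor((calls$bp2_lo + calls$bp2_hi) / 2) + 1
  alt_type <- dplyr::case_when(
    calls$sv_type %in% c("DUP_DIRECT", "DUP_INVERTED") ~ "DUP",
    TRUE ~ calls$sv_type)
  info <- sprintf(
    "SVTYPE=%s;END=%d;CHR2=%s;POS2=%d;CIPOS=%d,%d;CIEND=%d,%d;SPLITMOL=%d;RPSUP=%d",
    alt_type, as.integer(p2), calls$chrom1, as.integer(p2),
    as.integer(calls$bp1_lo - (p1 - 1)), as.integer(calls$bp1_hi - (p1 - 1)),
    as.integer(calls$bp2_lo - (p2 - 1)), as.integer(calls$bp2_hi - (p2 - 1)),
    calls$n_split_molecules, calls$rp_support)
  has3 <- !is.na(calls$bp3_lo)
  ins <- ifelse(has3,
                sprintf(";INSCHROM=%s;INSPOS=%d", calls$chrom3,
                        as.integer(floor((calls$bp3_lo + calls$bp3_hi) / 2) + 1)),
                "")
  ori <- ifelse(calls$sv_type == "DUP_INVERTED", ";ORIENT=inverted",
                ifelse(calls$sv_type == "DUP_DIRECT", ";ORIENT=direct", ""))
  rec <- sprintf("%s\t%d\t%s\t%s\t<%s>\t.\t%s\t%s",
                 calls$chrom1, as.integer(p1),
                 sprintf("SM%04d", calls$call_id), "N", alt_type,
                 calls$filter_status, paste0(info, ins, ori))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
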