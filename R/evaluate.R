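#' Score SV calls against a truth set
#'
#' Matches predictions to truth records with the standard benchmarking
#' protocol: types must be compatible (the two duplication orientations are
#' one DUP class unless `split_dup_classes = TRUE`), the source/body
#' intervals must overlap reciprocally by strictly more than
#' `min_reciprocal` (default 50%; exactly 50% is not a match), and for
#' duplications and translocations the predicted insertion locus must lie
#' within `mu_molecule/2` of the simulated one. Matching is one-to-one,
#' greedy by descending reciprocal overlap, so one broad call cannot absorb
#' several truth records. Both sets are size-filtered per class first
#' (DEL/TRA > 100 kbp, INV > 80 kbp, DUP > 40 kbp by default).
#'
#' @param truth truth tibble (see [random_svs()]) or a call tibble.
#' @param calls call tibble (PASS rows are scored; pass a pre-filtered tibble
#'   to score everything).
#' @param mu_molecule mean molecule size in bp; the insertion-locus tolerance
#'   is `mu_molecule/2`.
#' @param min_reciprocal reciprocal-overlap threshold (strict).
#' @param split_dup_classes score direct and inverted duplications as
#'   separate classes.
#' @param size_filter named per-class minimum sizes applied to both sets.
#' @return A list of class `sv_eval`: `report` (per-class tibble `sv_class`,
#'   `n_sim`, `n_pred`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1` —
#'   undefined ratios are `NA`, not 0) and `matches` (tibble of matched
#'   truth/call index pairs with overlaps).
#' @export
evaluate_calls <- function(truth, calls, mu_molecule = 50000,
                           min_reciprocal = 0.5,
                           split_dup_classes = FALSE,
                           size_filter = c(DEL = 100e3, INV = 80e3,
                                           DUP = 40e3, TRA = 100e3)) {
  cls <- function(x) {
    if (split_dup_classes) x
    else if_else(x %in% c("DUP_DIRECT", "DUP_INVERTED"), "DUP", x)
  }
  tr <- tibble(
    sv_class = cls(truth$sv_type), chrom = truth$chrom,
    start = truth$start, end = truth$end,
    ins_chrom = truth$chrom_ins %||% rep(NA_character_, nrow(truth)),
    ins_pos = truth$pos_ins %||% rep(NA_real_, nrow(truth)))
  ca <- tibble(
    sv_class = cls(calls$sv_type), chrom = calls$chrom1,
    start = (calls$bp1_lo + calls$bp1_hi) / 2,
    end = (calls$bp2_lo + calls$bp2_hi) / 2,
    ins_chrom = calls$chrom3,
    ins_pos = (calls$bp3_lo + calls$bp3_hi) / 2)
  base_class <- function(x) sub("^DUP.*", "DUP", x)
  classes <- sort(unique(c(tr$sv_class, ca$sv_class)))
  tr <- tr[tr$end - tr$start > size_filter[base_class(tr$sv_class)], , drop = FALSE]
  ca <- ca[ca$end - ca$start > size_filter[base_class(ca$sv_class)], , drop = FALSE]

  cand <- list()
  for (i in seq_len(nrow(tr))) {
    same <- which(ca$sv_class == tr$sv_class[i] & ca$chrom == tr$chrom[i])
    if (length(same) == 0) next
    ov <- pmin(ca$end[same], tr$end[i]) - pmax(ca$start[same], tr$start[i])
    ro <- pmin(ov / (tr$end[i] - tr$start[i]),
               ov / (ca$end[same] - ca$start[same]))
    ok <- ro > min_reciprocal
    if (tr$sv_class[i] %in% c("DUP", "DUP_DIRECT", "DUP_INVERTED", "TRA")) {
      ok <- ok & !is.na(ca$ins_pos[same]) &
        ca$ins_chrom[same] == tr$ins_chrom[i] &
        abs(ca$ins_pos[same] - tr$ins_pos[i]) <= mu_molecule / 2
    }
    if (any(ok, na.rm = TRUE)) {
      sel <- same[which(ok)]
      cand[[length(cand) + 1L]] <- tibble(truth_idx = i, call_idx = sel,
                                          overlap = ro[which(ok)])
    }
  }
  cand <- bind_rows(cand)
  matches <- tibble(truth_idx = integer(), call_idx = integer(),
                    overlap = numeric())
  if (nrow(cand) > 0) {
    cand <- arrange(cand, dplyr::desc(.data$overlap), .data$truth_idx,
                    .data$call_idx)
    used_t <- logical(nrow(tr))
    used_c <- logical(nrow(ca))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      ti <- cand$truth_idx[k]
      ci <- cand$call_idx[k]
      if (!used_t[ti] && !used_c[ci]) {
        used_t[ti] <- TRUE
        used_c[ci] <- TRUE
        keep[k] <- TRUE
      }
    }
    matches <- cand[keep, , drop = FALSE]
  }
  report <- purrr::map_dfr(classes, function(cl) {
    n_sim <- sum(tr$sv_class == cl)
    n_pred <- sum(ca$sv_class == cl)
    tp <- sum(tr$sv_class[matches$truth_idx] == cl)
    fp <- n_pred - tp
    fn <- n_sim - tp
    tibble(sv_class = cl, n_sim = n_sim, n_pred = n_pred,
           tp = tp, fp = fp, fn = fn,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           f1 = {
             p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
             r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
             if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
             else NA_real_
           })
  })
  structure(list(report = report, matches = matches,
                 n_truth = nrow(tr), n_calls = nrow(ca)),
            class = "sv_eval")
}

#' @export
print.sv_eval <- function(x, ...) {
  cat("<sv_eval>\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' Merge two call sets by reciprocal overlap
#'
#' Union mode collapses calls of the same type overlapping reciprocally by
#' more than `min_reciprocal` into one call spanning the interval union and
#' passes everything else through; intersection mode keeps only matching
#' pairs, as the interval intersection.
#'
#' @param set_a,set_b call tibbles.
#' @param mode `"union"` or `"intersection"`.
#' @param min_reciprocal reciprocal-overlap threshold (strict).
#' @return A merged call tibble.
#' @export
merge_call_sets <- function(set_a, set_b, mode = c("union", "intersection"),
                            min_reciprocal = 0.5) {
  mode <- match.arg(mode)
  a_body <- body_intervals(set_a)
  b_body <- body_intervals(set_b)
  pairs <- list()
  for (i in seq_len(nrow(set_a))) {
    same <- which(set_b$sv_type == set_a$sv_type[i] &
                    set_b$chrom1 == set_a$chrom1[i])
    if (length(same) == 0) next
    ov <- pmin(b_body$end[same], a_body$end[i]) -
      pmax(b_body$start[same], a_body$start[i])
    ro <- pmin(ov / (a_body$end[i] - a_body$start[i]),
               ov / (b_body$end[same] - b_body$start[same]))
    hit <- same[which(ro > min_reciprocal)]
    if (length(hit) > 0) {
      pairs[[length(pairs) + 1L]] <- tibble(ai = i, bi = hit[1])
    }
  }
  pairs <- bind_rows(pairs)
  if (mode == "intersection") {
    if (nrow(pairs) == 0) return(set_a[integer(0), , drop = FALSE])
    out <- set_a[pairs$ai, , drop = FALSE]
    out$bp1_lo <- pmax(set_a$bp1_lo[pairs$ai], set_b$bp1_lo[pairs$bi])
    out$bp1_hi <- pmax(out$bp1_lo + 1, pmin(set_a$bp1_hi[pairs$ai],
                                            set_b$bp1_hi[pairs$bi]))
    out$bp2_lo <- pmax(set_a$bp2_lo[pairs$ai], set_b$bp2_lo[pairs$bi])
    out$bp2_hi <- pmax(out$bp2_lo + 1, pmin(set_a$bp2_hi[pairs$ai],
                                            set_b$bp2_hi[pairs$bi]))
    return(out)
  }
  merged <- set_a
  if (nrow(pairs) > 0) {
    merged$bp1_lo[pairs$ai] <- pmin(set_a$bp1_lo[pairs$ai],
                                    set_b$bp1_lo[pairs$bi])
    merged$bp1_hi[pairs$ai] <- pmax(set_a$bp1_hi[pairs$ai],
                                    set_b$bp1_hi[pairs$bi])
    merged$bp2_lo[pairs$ai] <- pmin(set_a$bp2_lo[pairs$ai],
                                    set_b$bp2_lo[pairs$bi])
    merged$bp2_hi[pairs$ai] <- pmax(set_a$bp2_hi[pairs$ai],
                                    set_b$bp2_hi[pairs$bi])
  }
  matched_b <- if (nrow(pairs) > 0) pairs$bi else integer(0)
  rest_b <- setdiff(seq_len(nrow(set_b)), matched_b)
  bind_rows(merged, set_b[rest_b, , drop = FALSE])
}

body_intervals <- function(calls) {
  tibble(start = (calls$bp1_lo + calls$bp1_hi) / 2,
         end = (calls$bp2_lo + calls$bp2_hi) / 2)
}

# collapse duplicate calls within one call set (same-type calls overlapping
# > 50% reciprocally with agreeing insertion loci become one call)
dedupe_calls <- function(calls, min_reciprocal = 0.5, ins_tol = 25000) {
  if (nrow(calls) < 2) return(calls)
  body <- body_intervals(calls)
  keep <- rep(TRUE, nrow(calls))
  ord <- order(-calls$n_split_molecules, calls$chrom1, calls$bp1_lo)
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (!keep[i]) next
    for (k2 in seq_along(ord)) {
      j <- ord[k2]
      if (j == i || !keep[j]) next
      if (calls$sv_type[j] != calls$sv_type[i] ||
          calls$chrom1[j] != calls$chrom1[i]) next
      ov <- min(body$end[i], body$end[j]) - max(body$start[i], body$start[j])
      ro <- min(ov / (body$end[i] - body$start[i]),
                ov / (body$end[j] - body$start[j]))
      if (is.na(ro) || ro <= min_reciprocal) next
      if (!is.na(calls$bp3_lo[i]) && !is.na(calls$bp3_lo[j])) {
        if (is.na(calls$chrom3[i]) || is.na(calls$chrom3[j]) ||
            calls$chrom3[i] != calls$chrom3[j]) next
        d <- abs((calls$bp3_lo[i] + calls$bp3_hi[i]) / 2 -
                   (calls$bp3_lo[j] + calls$bp3_hi[j]) / 2)
        if (d > ins_tol) next
      }
      keep[j] <- FALSE
    }
  }
  calls[keep, , drop = FALSE]
}
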