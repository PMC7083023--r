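#' Build the SV graph over split-molecule pairs
#'
#' Vertices are split-molecule pairs; an edge joins two vertices iff they
#' signal the same event: same SV type, same chromosomes, and every
#' corresponding breakpoint interval overlaps (bp1 with bp1, bp2 with bp2,
#' and bp3 with bp3 when present). Any overlap (>= 1 bp) counts; the
#' intervals are already molecule-gap-sized, so a reciprocal requirement
#' would only fragment true clusters.
#'
#' @param pairs split-molecule-pair tibble from
#'   [match_split_molecule_pairs()].
#' @return A list of class `sv_graph` with `vertices` (the input tibble) and
#'   `edges` (tibble `from`, `to` of `pair_id`s, `from < to`).
#' @export
build_sv_graph <- function(pairs) {
  edges <- tibble(from = integer(), to = integer())
  if (nrow(pairs) >= 2) {
    dt <- data.table::data.table(
      id = pairs$pair_id, sv_type = pairs$sv_type, c1 = pairs$chrom1,
      c3 = ifelse(is.na(pairs$chrom3), "", pairs$chrom3),
      b1lo = pairs$bp1_lo, b1hi = pairs$bp1_hi - 1,
      b2lo = pairs$bp2_lo, b2hi = pairs$bp2_hi,
      b3lo = pairs$bp3_lo, b3hi = pairs$bp3_hi)
    data.table::setkey(dt, sv_type, c1, c3, b1lo, b1hi)
    ov <- data.table::foverlaps(dt, dt, type = "any", nomatch = NULL)
    ov <- ov[ov$id < ov$i.id &
               ov$b2lo < ov$i.b2hi & ov$i.b2lo < ov$b2hi]
    has3 <- !is.na(ov$b3lo)
    ov <- ov[!has3 | (ov$b3lo < ov$i.b3hi & ov$i.b3lo < ov$b3hi)]
    edges <- tibble(from = ov$id, to = ov$i.id) %>%
      arrange(.data$from, .data$to)
  }
  structure(list(vertices = pairs, edges = edges), class = "sv_graph")
}

#' @export
print.sv_graph <- function(x, ...) {
  cat(sprintf("<sv_graph> %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Extract gamma-quasi-cliques from the SV graph
#'
#' Within each connected component, repeatedly finds a large vertex set whose
#' induced edge count is at least `gamma * choose(|V|, 2)`: greedy peeling
#' removes the minimum-degree vertex until the density bound holds, then a
#' local add-back pass restores removed vertices that keep the bound.
#' Extracted members are removed and the search repeats until no set with at
#' least `min_support` vertices (spanning `min_support` distinct barcodes)
#' remains, so reported cliques are vertex-disjoint. Processing order is
#' fixed by (chromosome, bp1 start, id) for deterministic output.
#'
#' @param graph an `sv_graph`.
#' @param gamma density parameter in (0, 1].
#' @param min_support minimum vertices and distinct barcodes per clique.
#' @return Tibble with `clique_id`, `sv_type`, `members` (list column of
#'   `pair_id`s), `n_vertices`, `n_edges`, `gamma_achieved`.
#' @export
find_quasi_cliques <- function(graph, gamma = 0.6, min_support = 4L) {
  stopifnot(gamma > 0, gamma <= 1)
  v <- graph$vertices
  if (nrow(v) == 0) {
    return(tibble(clique_id = integer(), sv_type = character(),
                  members = list(), n_vertices = integer(),
                  n_edges = integer(), gamma_achieved = numeric()))
  }
  # deterministic vertex order
  ord <- order(v$chrom1, v$bp1_lo, v$pair_id)
  v <- v[ord, , drop = FALSE]
  idx_of <- setNames(seq_len(nrow(v)), v$pair_id)
  adj <- vector("list", nrow(v))
  if (nrow(graph$edges) > 0) {
    ef <- idx_of[as.character(graph$edges$from)]
    et <- idx_of[as.character(graph$edges$to)]
    adj_dt <- data.table::data.table(a = c(ef, et), b = c(et, ef))
    data.table::setorder(adj_dt, a, b)
    adj_split <- split(adj_dt$b, adj_dt$a)
    adj[as.integer(names(adj_split))] <- adj_split
  }
  comp_id <- graph_components(nrow(v), adj)
  out <- list()
  for (comp in split(seq_len(nrow(v)), comp_id)) {
    remaining <- comp
    repeat {
      if (length(remaining) < min_support) break
      qc <- peel_quasi_clique(remaining, adj, gamma, v$bp1_lo, v$pair_id)
      if (length(qc$members) < min_support) break
      remaining <- setdiff(remaining, qc$members)
      bcs <- unique(c(v$barcode_a[qc$members], v$barcode_b[qc$members]))
      if (length(bcs) < min_support) next
      out[[length(out) + 1L]] <- tibble(
        sv_type = v$sv_type[qc$members[1]],
        members = list(sort(v$pair_id[qc$members])),
        n_vertices = length(qc$members),
        n_edges = qc$n_edges,
        gamma_achieved = if (length(qc$members) > 1) {
          qc$n_edges / choose(length(qc$members), 2)
        } else 1)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(clique_id = integer(), sv_type = character(),
                  members = list(), n_vertices = integer(),
                  n_edges = integer(), gamma_achieved = numeric()))
  }
  res$clique_id <- seq_len(nrow(res))
  select(res, "clique_id", dplyr::everything())
}

# connected components over adjacency lists (iterative DFS)
graph_components <- function(n, adj) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack) > 0) {
      x <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (nb in adj[[x]]) {
        if (comp[nb] == 0L) {
          comp[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  comp
}

# greedy peel to density >= gamma, then add-back; operates on vertex indices
peel_quasi_clique <- function(vs, adj, gamma, leftmost, ids) {
  in_set <- rep(FALSE, length(leftmost))
  in_set[vs] <- TRUE
  deg <- vapply(vs, function(x) sum(in_set[adj[[x]]]), integer(1))
  names(deg) <- vs
  m <- sum(deg) / 2
  set <- vs
  removed <- integer(0)
  while (length(set) > 1 && m < gamma * choose(length(set), 2)) {
    # remove min-degree vertex; ties: larger leftmost coordinate, larger id
    d <- deg[as.character(set)]
    cand <- set[d == min(d)]
    if (length(cand) > 1) {
      o <- order(leftmost[cand], ids[cand], decreasing = TRUE)
      drop_v <- cand[o[1]]
    } else {
      drop_v <- cand
    }
    m <- m - deg[as.character(drop_v)]
    in_set[drop_v] <- FALSE
    for (nb in adj[[drop_v]]) {
      if (in_set[nb]) deg[as.character(nb)] <- deg[as.character(nb)] - 1L
    }
    set <- setdiff(set, drop_v)
    removed <- c(removed, drop_v)
  }
  # add back removed vertices that keep the density bound (deterministic
  # order: smaller leftmost coordinate first)
  removed <- removed[order(leftmost[removed], ids[removed])]
  for (x in removed) {
    dx <- sum(in_set[adj[[x]]])
    if ((m + dx) >= gamma * choose(length(set) + 1, 2)) {
      in_set[x] <- TRUE
      set <- c(set, x)
      m <- m + dx
    }
  }
  list(members = set, n_edges = m)
}

#' Convert quasi-cliques to SV calls
#'
#' Each quasi-clique defines one putative SV. Every breakpoint interval of
#' the call is the intersection of the members' corresponding intervals when
#' non-empty, otherwise the interval bounded by the members' median
#' endpoints. Support is annotated as the number of distinct candidate
#' splits and barcodes among members, plus a recount of discordant read
#' pairs against the call's own intervals. Calls with fewer distinct
#' candidate splits than `min_support` are retained with
#' `filter_status = "min_support_fail"` and excluded from PASS output.
#'
#' @param cliques tibble from [find_quasi_cliques()].
#' @param pairs the split-molecule-pair tibble the graph was built from.
#' @param discordant discordant-pair tibble (for the support recount).
#' @param config a [caller_config()].
#' @return Call tibble: `call_id`, `sv_type`, `chrom1`, `bp1_lo/hi`,
#'   `bp2_lo/hi`, `chrom3`, `bp3_lo/hi`, `n_split_molecules`, `n_barcodes`,
#'   `rp_support`, `depth_source` (filled by the depth filter),
#'   `filter_status`.
#' @export
cliques_to_calls <- function(cliques, pairs, discordant,
                             config = caller_config()) {
  empty <- tibble(call_id = integer(), sv_type = character(),
                  chrom1 = character(), bp1_lo = numeric(), bp1_hi = numeric(),
                  bp2_lo = numeric(), bp2_hi = numeric(),
                  chrom3 = character(), bp3_lo = numeric(), bp3_hi = numeric(),
                  n_split_molecules = integer(), n_barcodes = integer(),
                  rp_support = integer(), depth_source = numeric(),
                  filter_status = character())
  if (nrow(cliques) == 0) return(empty)
  pidx <- setNames(seq_len(nrow(pairs)), pairs$pair_id)
  rows <- purrr::map(seq_len(nrow(cliques)), function(i) {
    mem <- pairs[pidx[as.character(cliques$members[[i]])], , drop = FALSE]
    b1 <- consensus_interval(mem$bp1_lo, mem$bp1_hi)
    b2 <- consensus_interval(mem$bp2_lo, mem$bp2_hi)
    has3 <- !all(is.na(mem$bp3_lo))
    b3 <- if (has3) consensus_interval(mem$bp3_lo, mem$bp3_hi) else c(NA, NA)
    splits <- unique(c(mem$split_a, mem$split_b))
    bcs <- unique(c(mem$barcode_a, mem$barcode_b))
    tibble(sv_type = mem$sv_type[1], chrom1 = mem$chrom1[1],
           bp1_lo = b1[1], bp1_hi = b1[2], bp2_lo = b2[1], bp2_hi = b2[2],
           chrom3 = mem$chrom3[1], bp3_lo = b3[1], bp3_hi = b3[2],
           n_split_molecules = length(splits), n_barcodes = length(bcs))
  })
  calls <- bind_rows(rows) %>%
    arrange(.data$sv_type, .data$chrom1, .data$bp1_lo)
  calls$call_id <- seq_len(nrow(calls))
  calls$rp_support <- count_rp_support(calls, discordant, config)
  calls$depth_source <- NA_real_
  calls$filter_status <- if_else(calls$n_split_molecules >= config$min_support,
                                 "PASS", "min_support_fail")
  select(calls, "call_id", dplyr::everything())
}

# intersection of intervals if non-empty, else median endpoints
consensus_interval <- function(lo, hi) {
  ilo <- max(lo)
  ihi <- min(hi)
  if (ihi > ilo) return(c(ilo, ihi))
  mlo <- median(lo)
  mhi <- median(hi)
  if (mhi <= mlo) mhi <- mlo + 1
  c(mlo, mhi)
}
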