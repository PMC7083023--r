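test_that("edges require same type and overlap of every breakpoint interval", {
  pairs <- dplyr::bind_rows(
    mk_pair(1L, "INV", "chr1", 1e6, 1.01e6, 2e6, 2.01e6),
    mk_pair(2L, "INV", "chr1", 1e6, 1.01e6, 2e6, 2.01e6),
    mk_pair(3L, "DEL", "chr1", 1e6, 1.01e6, 2e6, 2.01e6),
    mk_pair(4L, "INV", "chr1", 1.02e6, 1.03e6, 2e6, 2.01e6))
  g <- build_sv_graph(pairs)
  expect_equal(nrow(g$edges), 1)           # only 1-2: 3 is DEL, 4 misses bp1
  expect_equal(c(g$edges$from, g$edges$to), c(1L, 2L))
})

test_that("adjacency equals an all-pairs oracle on random pair sets", {
  pairs <- withr::with_seed(55, {
    n <- 25
    lo1 <- round(runif(n, 0, 3e6))
    lo2 <- lo1 + round(runif(n, 2e5, 6e5))
    has3 <- runif(n) < 0.4
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      mk_pair(i, sample(c("DEL", "INV", "DUP_DIRECT"), 1), "chr1",
              lo1[i], lo1[i] + 3e4, lo2[i], lo2[i] + 3e4,
              chrom3 = if (has3[i]) "chr1" else NA_character_,
              b3lo = if (has3[i]) lo2[i] + 5e5 else NA_real_,
              b3hi = if (has3[i]) lo2[i] + 5.3e5 else NA_real_)
    }))
  })
  g <- build_sv_graph(pairs)
  ov <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2
  want <- list()
  for (i in 1:(nrow(pairs) - 1)) for (j in (i + 1):nrow(pairs)) {
    a <- pairs[i, ]; b <- pairs[j, ]
    if (a$sv_type != b$sv_type) next
    if (!ov(a$bp1_lo, a$bp1_hi, b$bp1_lo, b$bp1_hi)) next
    if (!ov(a$bp2_lo, a$bp2_hi, b$bp2_lo, b$bp2_hi)) next
    if (!is.na(a$bp3_lo) != !is.na(b$bp3_lo)) next
    if (!is.na(a$bp3_lo) && !ov(a$bp3_lo, a$bp3_hi, b$bp3_lo, b$bp3_hi)) next
    want[[length(want) + 1L]] <- c(a$pair_id, b$pair_id)
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(g$edges), if (is.null(want)) 0 else nrow(want))
  if (!is.null(want)) {
    expect_setequal(paste(g$edges$from, g$edges$to),
                    paste(pmin(want[, 1], want[, 2]),
                          pmax(want[, 1], want[, 2])))
  }
})

# helper: graph from an explicit edge list over k identical-geometry vertices
graph_from_edges <- function(k, edges, sv_type = "INV") {
  pairs <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
    mk_pair(i, sv_type, "chr1", 1e6, 1.1e6, 2e6, 2.1e6)
  }))
  g <- build_sv_graph(pairs)   # complete graph
  g$edges <- tibble::tibble(from = as.integer(edges[, 1]),
                            to = as.integer(edges[, 2]))
  g
}

# exhaustive best gamma-quasi-clique by bitmask enumeration
best_quasi_clique_size <- function(k, edges, gamma) {
  adj <- matrix(FALSE, k, k)
  for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1], edges[r, 2]] <- TRUE
    adj[edges[r, 2], edges[r, 1]] <- TRUE
  }
  best <- 0
  for (m in 1:(2^k - 1)) {
    v <- which(bitwAnd(m, 2^(0:(k - 1))) > 0)
    if (length(v) <= best) next
    e <- sum(adj[v, v]) / 2
    if (e >= gamma * choose(length(v), 2)) best <- length(v)
  }
  best
}

test_that("gamma density bound is exactly gamma * choose(V, 2)", {
  # 5 vertices need ceiling(0.6 * 10) = 6 edges; give exactly 6 (connected)
  e6 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5), c(1, 3))
  g <- graph_from_edges(5, e6)
  qc <- find_quasi_cliques(g, gamma = 0.6, min_support = 4)
  expect_equal(qc$n_vertices[1], 5)
  expect_gte(qc$gamma_achieved[1], 0.6)
  # one edge fewer (a 5-cycle) leaves no dense subset of size >= 4 at all
  g5 <- graph_from_edges(5, e6[1:5, ])
  qc5 <- find_quasi_cliques(g5, gamma = 0.6, min_support = 4)
  expect_equal(nrow(qc5), 0)
  # ... but the triangle-and-better subsets qualify at support 3
  qc3 <- find_quasi_cliques(graph_from_edges(5, e6), gamma = 1,
                            min_support = 3)
  expect_true(all(qc3$gamma_achieved >= 1 | nrow(qc3) == 0))
})

test_that("gamma = 1 on a triangle-free graph reports nothing at support 3", {
  # 5-cycle: no triangle, so no clique of size >= 3
  cyc <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5))
  g <- graph_from_edges(5, cyc)
  qc <- find_quasi_cliques(g, gamma = 1, min_support = 3)
  expect_equal(nrow(qc), 0)
})

test_that("greedy result is within one vertex of the exhaustive optimum", {
  withr::with_seed(66, {
    for (rep in 1:12) {
      k <- sample(6:12, 1)
      dens <- runif(1, 0.3, 0.9)
      all_e <- t(combn(k, 2))
      edges <- all_e[runif(nrow(all_e)) < dens, , drop = FALSE]
      if (nrow(edges) == 0) next
      g <- graph_from_edges(k, edges)
      qc <- find_quasi_cliques(g, gamma = 0.6, min_support = 2)
      got <- if (nrow(qc) > 0) max(qc$n_vertices) else 0
      best <- best_quasi_clique_size(k, edges, 0.6)
      expect_gte(got, best - 1)
      # every reported set satisfies the density bound
      if (nrow(qc) > 0) {
        expect_true(all(qc$n_edges >= 0.6 * choose(qc$n_vertices, 2)))
      }
    }
  })
})

test_that("a true clique plus pendant vertex is recovered and cliques are disjoint", {
  # 6-clique (1..6) plus pendant 7 attached to 1
  e <- rbind(t(combn(6, 2)), c(1, 7))
  g <- graph_from_edges(7, e)
  qc <- find_quasi_cliques(g, gamma = 0.6, min_support = 4)
  expect_gte(qc$n_vertices[1], 6)
  expect_true(all(qc$n_edges >= 0.6 * choose(qc$n_vertices, 2)))
  # vertex-disjoint: no id in two cliques
  all_members <- unlist(qc$members)
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("cliques below the barcode floor are not reported", {
  pairs <- dplyr::bind_rows(lapply(1:4, function(i) {
    mk_pair(i, "DEL", "chr1", 1e6, 1.1e6, 2e6, 2.1e6,
            barcode_a = "only_a", barcode_b = "only_b")
  }))
  g <- build_sv_graph(pairs)
  expect_equal(nrow(find_quasi_cliques(g, 0.6, min_support = 4)), 0)
})

test_that("clique calls use interval intersection, else median endpoints", {
  pairs <- dplyr::bind_rows(
    mk_pair(1L, "DEL", "chr1", 0, 100, 5e5, 5.2e5),
    mk_pair(2L, "DEL", "chr1", 50, 150, 5e5, 5.2e5),
    mk_pair(3L, "DEL", "chr1", 80, 180, 5e5, 5.2e5))
  cl <- tibble::tibble(clique_id = 1L, sv_type = "DEL",
                       members = list(c(1L, 2L, 3L)), n_vertices = 3L,
                       n_edges = 3L, gamma_achieved = 1)
  disc <- rp("chr1", 1, "+", "chr1", 2, "-")[0, ] %>%
    dplyr::mutate(pair_class = character(0))
  call <- cliques_to_calls(cl, pairs, disc, caller_config(min_support = 2))
  expect_equal(c(call$bp1_lo, call$bp1_hi), c(80, 100))    # intersection
  expect_equal(c(call$bp2_lo, call$bp2_hi), c(5e5, 5.2e5)) # identity

  # disjoint bp1 intervals fall back to median endpoints
  pairs$bp1_lo <- c(0, 200, 400)
  pairs$bp1_hi <- c(100, 300, 500)
  call2 <- cliques_to_calls(cl, pairs, disc, caller_config(min_support = 2))
  expect_equal(c(call2$bp1_lo, call2$bp1_hi), c(200, 300))

  # support below min_support is retained but flagged
  call3 <- cliques_to_calls(cl, pairs, disc, caller_config(min_support = 10))
  expect_equal(call3$filter_status, "min_support_fail")
})

test_that("identical inputs give identical cliques and calls", {
  pairs <- withr::with_seed(77, {
    dplyr::bind_rows(lapply(1:15, function(i) {
      lo <- round(runif(1, 0, 1e5))
      mk_pair(i, "DEL", "chr1", lo, lo + 5e4, 1e6 + lo, 1e6 + lo + 5e4)
    }))
  })
  g <- build_sv_graph(pairs)
  q1 <- find_quasi_cliques(g, 0.6, 2)
  q2 <- find_quasi_cliques(g, 0.6, 2)
  expect_identical(q1, q2)
})
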