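stats50 <- molecule_stats(50000, sigma = 10000)

test_that("candidate split enumeration honours the span-sum bound", {
  # spans 50k + 40k = 90k > mu + 3 sigma = 80k -> rejected
  sub <- tibble::tibble(submol_id = 1:2, chrom = "chr1",
                        start = c(0, 200000), end = c(50000, 240000),
                        barcode = "b1", n_fragments = 3L)
  expect_equal(nrow(enumerate_candidate_splits(sub, stats50)), 0)

  # one submolecule alone can never form a split
  expect_equal(nrow(enumerate_candidate_splits(sub[1, ], stats50)), 0)

  # four short submolecules on one chromosome: C(4,2) = 6 splits
  sub4 <- tibble::tibble(submol_id = 1:4, chrom = "chr1",
                         start = c(0, 1e5, 2e5, 3e5),
                         end = c(0, 1e5, 2e5, 3e5) + 10000,
                         barcode = "b1", n_fragments = 3L)
  sp <- enumerate_candidate_splits(sub4, stats50)
  expect_equal(nrow(sp), 6)
  expect_true(all(sp$l_start <= sp$r_start))

  # different chromosomes never pair here
  sub4$chrom <- c("chr1", "chr2", "chr1", "chr2")
  expect_equal(nrow(enumerate_candidate_splits(sub4, stats50)), 2)
})

# analytic split constructors from a planted event's geometry: flank/overhang
# lengths pick the submolecule edges exactly as molecules crossing each
# junction would map
del_splits <- function(s, e, bc1 = "x", bc2 = "y") {
  dplyr::bind_rows(
    mk_split(1L, bc1, "chr1", s - 30000, s - 500, e + 300, e + 25000),
    mk_split(2L, bc2, "chr1", s - 20000, s - 800, e + 600, e + 30000))
}
inv_splits <- function(s, e, bc1 = "x", bc2 = "y") {
  dplyr::bind_rows(
    mk_split(1L, bc1, "chr1", s - 30000, s - 400, e - 20000, e - 300),
    mk_split(2L, bc2, "chr1", s + 350, s + 15000, e + 250, e + 28000))
}
dup_dir_splits <- function(s, e, p, bc1 = "x", bc2 = "y") {
  # p > e: left junction split (source start + insertion flank),
  # right junction split (source end + insertion continuation)
  dplyr::bind_rows(
    mk_split(1L, bc1, "chr1", s + 200, s + 18000, p - 25000, p - 350),
    mk_split(2L, bc2, "chr1", e - 22000, e - 250, p + 280, p + 26000))
}
dup_inv_splits <- function(s, e, p, bc1 = "x", bc2 = "y") {
  dplyr::bind_rows(
    mk_split(1L, bc1, "chr1", e - 19000, e - 300, p - 24000, p - 400),
    mk_split(2L, bc2, "chr1", s + 260, s + 17000, p + 300, p + 23000))
}
tra_splits <- function(s, e, p, bc1 = "x", bc2 = "y") {
  dplyr::bind_rows(
    mk_split(1L, bc1, "chr1", s + 150, s + 16000, p - 21000, p - 300,
             chrom2 = "chr2"),
    mk_split(2L, bc2, "chr1", e - 18000, e - 200, p + 250, p + 24000,
             chrom2 = "chr2"))
}

test_that("signature predicates accept each type's geometry and emit sane breakpoints", {
  cfg <- caller_config()
  check <- function(splits, type, s, e, p = NULL, chrom3 = NULL) {
    r <- signature_predicate(type, splits[1, ], splits[2, ], stats50, cfg)
    expect_true(r$ok)
    w <- stats50$merge_gap
    expect_true(r$bp1[1] <= s + w && r$bp1[2] >= s - w)
    expect_true(r$bp2[1] <= e + w && r$bp2[2] >= e - w)
    if (!is.null(p)) {
      expect_true(r$bp3[1] <= p + w && r$bp3[2] >= p - w)
    }
    invisible(r)
  }
  check(del_splits(2e6, 2.3e6), "DEL", 2e6, 2.3e6)
  check(inv_splits(2e6, 2.5e6), "INV", 2e6, 2.5e6)
  check(dup_dir_splits(2e6, 2.1e6, 3e6), "DUP_DIRECT", 2e6, 2.1e6, 3e6)
  check(dup_inv_splits(2e6, 2.1e6, 3e6), "DUP_INVERTED", 2e6, 2.1e6, 3e6)
  check(tra_splits(2e6, 2.2e6, 5e6), "TRA", 2e6, 2.2e6, 5e6)

  # wrong-type geometry is rejected
  expect_false(signature_predicate("DEL", inv_splits(2e6, 2.5e6)[1, ],
                                   inv_splits(2e6, 2.5e6)[2, ],
                                   stats50, cfg)$ok)
  expect_error(signature_predicate("BOGUS", del_splits(2e6, 2.3e6)[1, ],
                                   del_splits(2e6, 2.3e6)[2, ],
                                   stats50, cfg), "unknown sv_type")
})

test_that("size windows and caps are enforced on the predicate", {
  cfg <- caller_config()
  # inversion implied by gaps 10 Mbp apart exceeds the 7 Mbp cap
  expect_false(signature_predicate("INV", inv_splits(2e6, 12e6)[1, ],
                                   inv_splits(2e6, 12e6)[2, ],
                                   stats50, cfg)$ok)
  # inversion just under the cap is fine
  expect_true(signature_predicate("INV", inv_splits(2e6, 8.9e6)[1, ],
                                  inv_splits(2e6, 8.9e6)[2, ],
                                  stats50, cfg)$ok)
  # deletion below the 100 kbp floor
  expect_false(signature_predicate("DEL", del_splits(2e6, 2.05e6)[1, ],
                                   del_splits(2e6, 2.05e6)[2, ],
                                   stats50, cfg)$ok)
  # duplication copied only 60 kbp away: below the 80 kbp displacement floor
  sp <- dup_dir_splits(2e6, 2.06e6, 2.12e6)
  expect_false(signature_predicate("DUP_DIRECT", sp[1, ], sp[2, ],
                                   stats50, cfg)$ok)
})

test_that("DEL/INV predicate decisions match a hand-coded geometric oracle", {
  cfg <- caller_config()
  w <- stats50$merge_gap
  oracle_del <- function(a, b) {
    # both splits gap over one deleted interval: gap starts and ends agree
    # within w and the implied deletion is large enough
    agree <- abs(a$l_end - b$l_end) <= w && abs(a$r_start - b$r_start) <= w
    size <- (a$r_start + b$r_start) / 2 - (a$l_end + b$l_end) / 2
    agree && size >= cfg$min_del_size &&
      max(a$l_end, b$l_end) + w <= min(a$r_start, b$r_start) - w
  }
  oracle_inv <- function(a, b) {
    # one split ends at both inversion edges, the other starts at them
    f <- function(x, y) {
      abs(x$l_end - y$l_start) <= w && abs(x$r_end - y$r_start) <= w &&
        {
          size <- (y$r_start + x$r_end) / 2 - (y$l_start + x$l_end) / 2
          size >= cfg$min_inv_size && size <= cfg$max_inv_size
        }
    }
    f(a, b) || f(b, a)
  }
  withr::with_seed(202, {
    for (k in 1:30) {
      coords <- sort(round(runif(4, 0, 5e6)))
      a <- mk_split(1L, "x", "chr1", coords[1], coords[2], coords[3], coords[4])
      jitter <- round(runif(4, -2 * w, 2 * w))
      b <- mk_split(2L, "y", "chr1",
                    coords[1] + jitter[1], coords[2] + jitter[2],
                    coords[3] + jitter[3], coords[4] + jitter[4])
      if (b$l_start >= b$l_end || b$r_start >= b$r_end ||
          b$l_end > b$r_start) next
      expect_equal(signature_predicate("DEL", a, b, stats50, cfg)$ok,
                   oracle_del(a, b), info = paste("DEL case", k))
      expect_equal(signature_predicate("INV", a, b, stats50, cfg)$ok,
                   oracle_inv(a, b), info = paste("INV case", k))
    }
  })
})

test_that("read-pair support counts equal a linear-scan oracle", {
  cfg <- caller_config(rp_pad = 1000)
  pair <- mk_pair(1L, "DEL", "chr1", 1.0e6, 1.01e6, 1.2e6, 1.21e6)
  expect_equal(count_rp_support(pair, rp("chr1", 1, "+", "chr1", 2, "-")[0, ] %>%
                                  dplyr::mutate(pair_class = character(0)),
                                cfg), 0L)

  # 3 FF pairs bridging both INV breakpoints count as 3
  inv_pair <- mk_pair(1L, "INV", "chr1", 1.0e6, 1.01e6, 1.5e6, 1.51e6)
  disc <- dplyr::bind_rows(
    rp("chr1", 1.0e6 + 100, "+", "chr1", 1.5e6 + 200, "+"),
    rp("chr1", 1.0e6 - 300, "+", "chr1", 1.5e6 + 900, "+"),
    rp("chr1", 1.0e6 + 500, "+", "chr1", 1.5e6 - 100, "+")) %>%
    dplyr::mutate(pair_class = "intra_inverted_FF")
  expect_equal(count_rp_support(inv_pair, disc, cfg), 3L)

  # planted DEL support equals a brute-force scan over random discordants
  del_pair <- mk_pair(2L, "DEL", "chr1", 2.0e6, 2.02e6, 2.4e6, 2.42e6)
  disc2 <- withr::with_seed(33, {
    n <- 60
    tibble::tibble(
      chrom1 = "chr1", pos1 = round(runif(n, 1.9e6, 2.1e6)), strand1 = "+",
      chrom2 = "chr1", pos2 = round(runif(n, 2.3e6, 2.5e6)), strand2 = "-",
      barcode = "b", mapq = 60,
      pair_class = sample(c("intra_far", "intra_inverted_FF"), n, TRUE))
  })
  got <- count_rp_support(del_pair, disc2, cfg)
  want <- sum(disc2$pair_class == "intra_far" &
                disc2$pos1 >= 2.0e6 - 1000 & disc2$pos1 <= 2.02e6 + 1000 &
                disc2$pos2 >= 2.4e6 - 1000 & disc2$pos2 <= 2.42e6 + 1000)
  expect_equal(got, as.integer(want))
})

test_that("translocation anchoring attaches only nearby same-barcode submolecules", {
  cfg <- caller_config(tra_anchor_window = 50000)
  st <- stats50
  anchor <- rp("chr1", 5.0e6, "+", "chr2", 8.0e6, "-", barcode = "bx9") %>%
    dplyr::mutate(pair_class = "interchromosomal")
  sub <- tibble::tibble(
    submol_id = 1:3,
    chrom = c("chr1", "chr2", "chr2"),
    start = c(4.95e6, 8.01e6, 9.5e6),
    end = c(4.99e6, 8.05e6, 9.54e6),
    barcode = c("bx9", "bx9", "bx9"), n_fragments = 3L)
  got <- anchor_translocation_splits(anchor, sub, st, cfg)
  expect_equal(nrow(got), 1)  # the 9.5 Mbp submolecule is out of window
  expect_equal(got$l_end, 4.99e6)
  expect_equal(got$r_start, 8.01e6)

  # wrong barcode: nothing attaches
  sub$barcode <- "other"
  expect_equal(nrow(anchor_translocation_splits(anchor, sub, st, cfg)), 0)
})

test_that("anchored candidates equal a brute-force window search at toy scale", {
  cfg <- caller_config(tra_anchor_window = 5e5)
  st <- stats50
  win <- 5e5
  set <- withr::with_seed(44, {
    n_sub <- 40
    sub <- tibble::tibble(
      submol_id = seq_len(n_sub),
      chrom = sample(c("chr1", "chr2"), n_sub, TRUE),
      start = round(runif(n_sub, 0, 5e6)),
      barcode = sample(c("a", "b", "c", "d"), n_sub, TRUE),
      n_fragments = 3L)
    sub$end <- sub$start + round(runif(n_sub, 5e3, 4e4))
    anc <- tibble::tibble(
      chrom1 = "chr1", pos1 = round(runif(10, 0, 5e6)), strand1 = "+",
      chrom2 = "chr2", pos2 = round(runif(10, 0, 5e6)), strand2 = "-",
      barcode = sample(c("a", "b", "c", "d"), 10, TRUE),
      pair_class = "interchromosomal")
    list(sub = sub, anc = anc)
  })
  got <- anchor_translocation_splits(set$anc, set$sub, st, cfg)
  # brute force: every anchor x submol-pair combination within windows
  bound <- st$mu + 3 * st$sigma
  want <- list()
  for (i in seq_len(nrow(set$anc))) {
    a <- set$anc[i, ]
    s1 <- set$sub[set$sub$barcode == a$barcode & set$sub$chrom == a$chrom1 &
                    set$sub$start - win <= a$pos1 &
                    set$sub$end + win >= a$pos1, ]
    s2 <- set$sub[set$sub$barcode == a$barcode & set$sub$chrom == a$chrom2 &
                    set$sub$start - win <= a$pos2 &
                    set$sub$end + win >= a$pos2, ]
    for (x in seq_len(nrow(s1))) for (y in seq_len(nrow(s2))) {
      if ((s1$end[x] - s1$start[x]) + (s2$end[y] - s2$start[y]) <= bound) {
        want[[length(want) + 1L]] <- tibble::tibble(
          barcode = a$barcode, l_start = s1$start[x], r_start = s2$start[y])
      }
    }
  }
  want <- dplyr::distinct(dplyr::bind_rows(want))
  expect_gt(nrow(want), 0)  # the fixture must actually exercise attachment
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$barcode, got$l_start, got$r_start),
                  paste(want$barcode, want$l_start, want$r_start))
})

test_that("matching is canonical: same-barcode never pairs, each pair once", {
  cfg <- caller_config(min_rp_support = 0)
  splits <- del_splits(2e6, 2.3e6, bc1 = "same", bc2 = "same")
  got <- match_split_molecule_pairs(splits, tibble::tibble(
    chrom1 = character(), pos1 = numeric(), strand1 = character(),
    chrom2 = character(), pos2 = numeric(), strand2 = character(),
    barcode = character(), pair_class = character()), stats50, cfg)
  expect_equal(nrow(got), 0)

  splits2 <- del_splits(2e6, 2.3e6)
  disc <- rp("chr1", 2e6 - 200, "+", "chr1", 2.3e6 + 250, "-") %>%
    dplyr::mutate(pair_class = "intra_far")
  disc <- dplyr::bind_rows(disc, disc, disc)
  got2 <- match_split_molecule_pairs(splits2, disc, stats50,
                                     caller_config(rp_pad = 1000))
  expect_equal(nrow(got2), 1)  # symmetric pair reported exactly once
  expect_equal(got2$sv_type, "DEL")
  expect_equal(got2$rp_support, 3L)
  # below the >= 3 floor the pair is dropped
  got3 <- match_split_molecule_pairs(splits2, disc[1:2, ], stats50,
                                     caller_config(rp_pad = 1000))
  expect_equal(nrow(got3), 0)
})

test_that("breakpoint intervals sit inside the splits' envelopes", {
  sim <- shared_inv_sim()
  cfg <- caller_config()
  cls <- classify_read_pairs(sim$reads, config = cfg)
  rec <- recover_molecules(cls$fragments, cfg)
  cfg$rp_pad <- ceiling(cls$concordance[2])
  sp <- enumerate_candidate_splits(rec$submolecules, rec$stats, cfg)
  sp <- filter_splits_by_support(sp, cls$discordant, rec$stats, cfg)
  prs <- match_split_molecule_pairs(sp, cls$discordant, rec$stats, cfg)
  expect_gt(nrow(prs), 0)
  w <- splitmol:::bp_window(cfg, rec$stats)
  idx <- match(prs$split_a, sp$split_id)
  idx_b <- match(prs$split_b, sp$split_id)
  env_lo <- pmin(sp$l_start[idx], sp$l_start[idx_b]) - w
  env_hi <- pmax(sp$r_end[idx], sp$r_end[idx_b]) + w
  expect_true(all(prs$bp1_lo >= env_lo & prs$bp1_hi <= env_hi))
  expect_true(all(prs$bp2_lo >= env_lo & prs$bp2_hi <= env_hi))
  expect_true(all(prs$bp1_hi > prs$bp1_lo & prs$bp2_hi > prs$bp2_lo))
})
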