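test_that("site He follows the allele-frequency formula, including missing calls", {
  gm <- toy_matrix(cbind(c(0L, 0L, 2L, 2L),
                         c(0L, 0L, 0L, 0L),
                         c(0L, 1L, 2L, NA)))
  st <- site_stats(gm)
  expect_equal(st$p_alt, c(0.5, 0, 0.5))
  expect_equal(st$he, c(0.5, 0, 0.5))      # hand count: (1 + 2) / 6 = 0.5
  expect_equal(st$n_chrom, c(8L, 8L, 6L))
  expect_error(site_stats(gm, samples = character()), "empty")
})

test_that("window He, het rate and pi match their definitions", {
  # sites with He 0.5 and 0.375 -> mean 0.4375
  gm <- toy_matrix(cbind(c(0L, 2L, 0L, 2L), c(0L, 0L, 1L, 1L)),
                   pos = c(150, 250))
  w <- list(chrom = "chr1", start0 = 0, end0 = 1000)
  expect_equal(window_mean_he(gm, w), (0.5 + 0.375) / 2)
  expect_true(is.na(window_mean_he(gm, list(chrom = "chr1", start0 = 500,
                                            end0 = 1000))))
  # het rate: counts code-1 calls only, normalised by actual span
  expect_equal(het_rate(gm, w, "s03"), 100 * 1 / 1000)
  expect_equal(het_rate(gm, w, "s01"), 0)
  w5k <- list(chrom = "chr1", start0 = 0, end0 = 5000)
  gm10 <- toy_matrix(matrix(1L, 1, 10), pos = seq(100, 1000, by = 100))
  expect_equal(het_rate(gm10, w5k, "s01"), 100 * 10 / 5000)
  # one site, n = 4, j = 2, window 100 bp
  gm1 <- toy_matrix(rbind(1L, 1L), pos = 50)
  expect_equal(nucleotide_diversity(gm1, list(chrom = "chr1", start0 = 0, end0 = 100)),
               (2 * 2 * 2 / (4 * 3)) / 100)
  # monomorphic window
  gm0 <- toy_matrix(rbind(0L, 0L), pos = 50)
  expect_equal(nucleotide_diversity(gm0, list(chrom = "chr1", start0 = 0, end0 = 100)), 0)
})

test_that("window pi equals the pairwise allele-copy enumeration oracle", {
  withr::local_seed(5)
  for (rep in 1:25) {
    gm <- random_matrix(2, 12, missing_rate = 0.2, max_pos = 900)
    w <- list(chrom = "chr1", start0 = 0, end0 = 1000)
    expect_equal(nucleotide_diversity(gm, w),
                 oracle_window_pi(gm$geno, 1000), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches an independent transliteration and sign expectations", {
  withr::local_seed(6)
  for (rep in 1:50) {
    gm <- random_matrix(6, 30, missing_rate = 0.15, max_pos = 5000)
    w <- list(chrom = "chr1", start0 = 0, end0 = 5000)
    got <- tajimas_d(gm, w)
    exp <- oracle_tajimas_d(gm$geno)
    if (is.na(exp)) expect_true(is.na(got)) else expect_equal(got, exp, tolerance = 1e-9)
  }
  # all sites at intermediate frequency (j = 5 of n = 10) -> positive D
  gm <- toy_matrix(matrix(rep(c(2L, 2L, 1L, 0L, 0L), 8), nrow = 5),
                   pos = seq(100, by = 100, length.out = 8))
  d <- tajimas_d(gm, list(chrom = "chr1", start0 = 0, end0 = 1000))
  expect_gt(d, 0)
  # S = 0 -> undefined
  gm0 <- toy_matrix(matrix(0L, 5, 4))
  expect_true(is.na(tajimas_d(gm0, list(chrom = "chr1", start0 = 0, end0 = 1000))))
})

test_that("Hudson FST matches the per-site oracle and its anchors", {
  ga_ids <- sprintf("s%02d", 1:10)
  gb_ids <- sprintf("s%02d", 11:20)
  # fixed difference -> 1
  gm <- toy_matrix(rbind(matrix(0L, 10, 6), matrix(2L, 10, 6)))
  expect_equal(fst(gm, ga_ids, gb_ids), 1)
  # identical frequency profiles -> ~0 (unbiased estimator, small negative ok)
  gm2 <- toy_matrix(rbind(matrix(rep(c(0L, 1L, 2L, 1L, 0L), 8), 10, 4),
                          matrix(rep(c(0L, 1L, 2L, 1L, 0L), 8), 10, 4)))
  expect_lt(abs(fst(gm2, ga_ids, gb_ids)), 0.1)
  expect_error(fst(gm, ga_ids, ga_ids), "differ")
  withr::local_seed(8)
  for (rep in 1:30) {
    gm3 <- random_matrix(20, 20, missing_rate = 0.1)
    got <- fst(gm3, ga_ids, gb_ids)
    expect_equal(got, oracle_hudson_fst(gm3$geno[1:10, ], gm3$geno[11:20, ]),
                 tolerance = 1e-12)
  }
})

test_that("p-distance matches the pair enumeration oracle", {
  gm <- toy_matrix(rbind(matrix(0L, 3, 8), matrix(2L, 3, 8)))
  a <- sprintf("s%02d", 1:3); b <- sprintf("s%02d", 4:6)
  expect_equal(p_distance(gm, a, b), 1)          # opposite homozygotes
  gm_id <- toy_matrix(rbind(matrix(1L, 3, 8), matrix(1L, 3, 8)))
  expect_equal(p_distance(gm_id, a, b), 0)
  expect_error(p_distance(gm, a, a), "disjoint")
  withr::local_seed(9)
  for (rep in 1:20) {
    gm3 <- random_matrix(6, 15, missing_rate = 0.2)
    expect_equal(p_distance(gm3, a, b),
                 oracle_p_distance(gm3$geno[1:3, ], gm3$geno[4:6, ]),
                 tolerance = 1e-12)
  }
})

test_that("statistics are invariant to ref/alt relabelling and sample order", {
  withr::local_seed(10)
  gm <- random_matrix(12, 40, missing_rate = 0.1, max_pos = 8000)
  w <- list(chrom = "chr1", start0 = 0, end0 = 8000)
  flip <- gm
  flip$geno <- 2L - gm$geno
  expect_equal(window_mean_he(gm, w), window_mean_he(flip, w))
  expect_equal(nucleotide_diversity(gm, w), nucleotide_diversity(flip, w))
  expect_equal(tajimas_d(gm, w), tajimas_d(flip, w))
  a <- sprintf("s%02d", 1:6); b <- sprintf("s%02d", 7:12)
  expect_equal(fst(gm, a, b), fst(flip, a, b), tolerance = 1e-12)
  expect_equal(fst(gm, a, b), fst(gm, b, a), tolerance = 1e-12)
  # permuting sample order leaves group statistics unchanged
  shuf <- subset_geno(gm, sample_ids = sample(gm$samples$sample_id))
  expect_equal(window_mean_he(shuf, w, samples = a), window_mean_he(gm, w, samples = a))
  expect_equal(fst(shuf, a, b), fst(gm, a, b), tolerance = 1e-12)
})

test_that("vectorised window_stats agrees with the single-window functions", {
  withr::local_seed(12)
  gm <- random_matrix(10, 120, missing_rate = 0.1, max_pos = 3e4)
  wins <- make_windows(c(chr1 = 3e4), size = 5e3, step = 2500)
  ws <- window_stats(gm, wins, tajima = TRUE)
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    expect_equal(ws$mean_he[i], window_mean_he(gm, w))
    expect_equal(ws$pi[i], nucleotide_diversity(gm, w))
    d1 <- ws$tajimas_d[i]; d2 <- tajimas_d(gm, w)
    if (is.na(d2)) expect_true(is.na(d1)) else expect_equal(d1, d2)
  }
  wf <- window_fst(gm, wins, sprintf("s%02d", 1:5), sprintf("s%02d", 6:10))
  for (i in seq_len(nrow(wins))) {
    got <- wf$fst[i]
    exp <- fst(gm, sprintf("s%02d", 1:5), sprintf("s%02d", 6:10), window = wins[i, ])
    if (is.na(exp)) expect_true(is.na(got)) else expect_equal(got, exp)
  }
})

test_that("group_distances reports symmetric pairs", {
  withr::local_seed(13)
  gm <- random_matrix(9, 30)
  groups <- list(A = sprintf("s%02d", 1:3), B = sprintf("s%02d", 4:6),
                 C = sprintf("s%02d", 7:9))
  gd <- group_distances(gm, groups)
  expect_equal(nrow(gd), 3)
  expect_equal(gd$fst[gd$group_a == "A" & gd$group_b == "B"],
               fst(gm, groups$B, groups$A), tolerance = 1e-12)
})
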