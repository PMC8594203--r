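test_that("genotype groups partition non-missing samples exhaustively and disjointly", {
  gm <- toy_matrix(cbind(c(0L, 1L, 1L, 2L, NA)))
  gg <- genotype_groups(gm, 1)
  expect_equal(unname(gg$sizes), c(1L, 2L, 1L))
  expect_true(all(gg$flagged))
  all_ids <- unname(unlist(gg$groups))
  expect_equal(sort(all_ids), sort(gm$samples$sample_id[!is.na(gm$geno[, 1])]))
  expect_equal(anyDuplicated(all_ids), 0L)
  # all-het SNP: single non-empty group
  gm2 <- toy_matrix(cbind(rep(1L, 6)))
  gg2 <- genotype_groups(gm2, 1)
  expect_equal(unname(gg2$sizes), c(0L, 6L, 0L))
  expect_error(genotype_groups(gm, list(chrom = "chr9", pos = 1)), "not found")
  # sizes match a counting oracle on a random matrix
  withr::local_seed(61)
  gm3 <- random_matrix(40, 10)
  for (s in 1:10) {
    gg3 <- genotype_groups(gm3, s)
    expect_equal(unname(gg3$sizes),
                 unname(vapply(0:2, function(k) sum(gm3$geno[, s] == k, na.rm = TRUE),
                               integer(1))))
  }
})

test_that("quantitative association reproduces the Welch oracle", {
  gm <- toy_matrix(cbind(c(rep(1L, 5), rep(0L, 5))))
  traits <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                           yld = c(10, 12, 11, 13, 12, 5, 6, 5, 7, 6))
  gg <- genotype_groups(gm, 1)
  res <- quantitative_assoc(gg, traits, "yld", pair = c("het", "hom_ref"))
  exp <- oracle_welch_t(traits$yld[1:5], traits$yld[6:10])
  expect_equal(res$statistic, exp$t, tolerance = 1e-9)
  expect_equal(res$p_value, exp$p, tolerance = 1e-9)
  expect_lt(res$p_value, 0.01)
  # identical values -> t = 0, p = 1
  traits2 <- tibble::tibble(sample_id = sprintf("s%02d", 1:10), yld = rep(4, 10))
  res2 <- quantitative_assoc(gg, traits2, "yld")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  # flagged class refused
  gg5 <- genotype_groups(gm, 1, min_group_size = 6)
  expect_error(quantitative_assoc(gg5, traits, "yld"), "min_group_size")
})

test_that("categorical association is the Pearson chi-square without correction", {
  gm <- toy_matrix(cbind(c(rep(1L, 20), rep(0L, 20))))
  # balanced table -> chi-square 0, p 1
  traits <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                           col = rep(c("red", "white"), 20))
  gg <- genotype_groups(gm, 1)
  res <- categorical_assoc(gg, traits, "col", classes = c("hom_ref", "het"))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # perfectly separated 2x2 -> chi-square = n = 40
  traits2 <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                            col = rep(c("red", "white"), each = 20))
  res2 <- categorical_assoc(gg, traits2, "col", classes = c("hom_ref", "het"))
  expect_equal(res2$statistic, 40)
  expect_lt(res2$p_value, 1e-9)
  # random tables match the formula oracle
  withr::local_seed(62)
  for (rep in 1:20) {
    traits3 <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                              col = sample(c("a", "b", "c"), 40, replace = TRUE))
    res3 <- categorical_assoc(gg, traits3, "col", classes = c("hom_ref", "het"))
    tab <- rbind(table(factor(traits3$col[1:20], levels = c("a", "b", "c"))),
                 table(factor(traits3$col[21:40], levels = c("a", "b", "c"))))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    exp <- oracle_chisq(tab)
    expect_equal(res3$statistic, exp$x2, tolerance = 1e-9)
    expect_equal(res3$p_value, exp$p, tolerance = 1e-9)
  }
})

test_that("two-locus median-test comparison assigns consistent letters", {
  # two well-separated combination classes get distinct letters
  gm <- toy_matrix(cbind(c(rep(1L, 6), rep(0L, 6)), rep(0L, 12)),
                   pos = c(100, 200))
  traits <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                           starch = c(rep(9, 6), rep(1, 6)))
  res <- allele_combination_assoc(gm, 1, 2, traits, "starch")
  expect_equal(nrow(res$classes), 2)
  expect_true(res$overall$p_value < 0.05)
  expect_equal(length(unique(res$classes$letter)), 2)
  expect_true(all(res$pairwise$adjusted_p <= 1))
  # identical values share a letter
  traits2 <- tibble::tibble(sample_id = sprintf("s%02d", 1:12), starch = rep(3, 12))
  res2 <- allele_combination_assoc(gm, 1, 2, traits2, "starch")
  expect_equal(length(unique(res2$classes$letter)), 1)
  # pairwise p matrix matches the per-pair oracle; Bonferroni is exact
  withr::local_seed(63)
  gm4 <- toy_matrix(cbind(sample(0:2, 60, replace = TRUE),
                          sample(0:1, 60, replace = TRUE)),
                    pos = c(100, 200))
  traits4 <- tibble::tibble(sample_id = sprintf("s%02d", 1:60),
                            starch = rnorm(60))
  res4 <- allele_combination_assoc(gm4, 1, 2, traits4, "starch",
                                   min_group_size = 4)
  combos <- combination_for_test(gm4, traits4)
  for (i in seq_len(nrow(res4$pairwise))) {
    pr <- c(res4$pairwise$class_a[i], res4$pairwise$class_b[i])
    exp <- oracle_median_test(combos[pr])
    expect_equal(res4$pairwise$p_value[i], exp$p, tolerance = 1e-9)
  }
  expect_equal(res4$pairwise$adjusted_p,
               pmin(1, res4$pairwise$p_value * nrow(res4$pairwise)))
  # letters consistent with adjusted pairwise significance
  for (i in seq_len(nrow(res4$pairwise))) {
    la <- res4$classes$letter[res4$classes$combo == res4$pairwise$class_a[i]]
    lb <- res4$classes$letter[res4$classes$combo == res4$pairwise$class_b[i]]
    shares <- any(strsplit(la, "")[[1]] %in% strsplit(lb, "")[[1]])
    if (res4$pairwise$adjusted_p[i] < 0.05) {
      expect_false(shares)
    } else {
      expect_true(shares)
    }
  }
})

test_that("combination frequencies separate populations as constructed", {
  # wild all het/het, cultivars all hom/hom
  gm <- toy_matrix(cbind(c(rep(1L, 6), rep(0L, 6)), c(rep(1L, 6), rep(0L, 6))),
                   pos = c(100, 200),
                   pop_class = c(rep("wild", 6), rep("breeding", 6)))
  cf <- combination_frequency(gm, 1, 2, wild_ids(gm), cultivar_ids(gm))
  wide <- tidyr::pivot_wider(cf$table, names_from = "population",
                             values_from = c("n", "frequency"))
  expect_equal(sort(unique(cf$table$combo)), c("het/het", "hom_ref/hom_ref"))
  expect_equal(max(abs(wide$frequency_wild - wide$frequency_cultivar)), 1)
  expect_lt(cf$test$p_value, 0.01)
  # identical populations -> identical frequencies, p = 1
  gm2 <- toy_matrix(cbind(rep(c(0L, 0L, 1L, 1L, 2L, 2L), 2),
                          rep(c(1L, 1L, 2L, 2L, 0L, 0L), 2)),
                    pos = c(100, 200),
                    pop_class = rep(c("wild", "breeding"), each = 6))
  cf2 <- combination_frequency(gm2, 1, 2, wild_ids(gm2), cultivar_ids(gm2))
  expect_equal(cf2$test$p_value, 1)
})
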