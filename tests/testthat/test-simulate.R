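test_that("the simulator is deterministic under its seed", {
  small <- function(seed) {
    sim_config(n_chrom = 1, chrom_length_bp = 4e5, n_cultivar = 30,
               sweep_regions = tibble::tibble(chrom = "chr1", start0 = 1e5,
                                              end0 = 1.6e5,
                                              cultivar_target_freq = 0.98),
               balancing_blocks = NULL, seed = seed)
  }
  a <- simulate_genotypes(small(5))
  b <- simulate_genotypes(small(5))
  expect_identical(a$matrix$geno, b$matrix$geno)
  expect_identical(a$matrix$sites, b$matrix$sites)
  expect_identical(simulate_traits(a), simulate_traits(b))
  pa <- withr::local_tempfile(fileext = ".vcf")
  pb <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(a$matrix, pa); write_vcf(b$matrix, pb)
  expect_identical(unname(tools::md5sum(pa)), unname(tools::md5sum(pb)))
  # a different seed changes the draw
  c <- simulate_genotypes(small(6))
  expect_false(identical(a$matrix$geno, c$matrix$geno))
})

test_that("with F = 0 and no planted regions cultivars sit at Hardy-Weinberg", {
  cfg <- sim_config(n_chrom = 1, chrom_length_bp = 5e6, n_cultivar = 500,
                    f_background = 1e-9, drift = 0.001,
                    sweep_regions = NULL, balancing_blocks = NULL,
                    causal = list(), missing_rate = 0, seed = 77)
  sim <- simulate_genotypes(cfg)
  cv <- cultivar_ids(sim$matrix)
  st <- site_stats(sim$matrix, cv)
  obs_het <- colMeans(sim$matrix$geno[match(cv, sim$matrix$samples$sample_id), ] == 1L)
  keep <- st$he > 0.05           # avoid ratio blow-up at near-fixed sites
  expect_equal(mean(obs_het[keep] / st$he[keep]), 1, tolerance = 0.02)
})

test_that("heterozygote excess and planted structure appear as configured", {
  sim <- default_sim()
  gm <- sim$matrix
  cv <- cultivar_ids(gm)
  # cultivar observed het exceeds expected het genome-wide (F = -0.1)
  cvrows <- match(cv, gm$samples$sample_id)
  st <- site_stats(gm, cv)
  bg <- region_free_sites(gm$sites, sim$truth)
  obs <- colMeans(gm$geno[cvrows, bg] == 1L, na.rm = TRUE)
  keep <- st$he[bg] > 0.05
  expect_gt(mean(obs[keep] / st$he[bg][keep]), 1.05)
  # sweep windows: cultivar He collapses towards 2 * 0.98 * 0.02
  sw <- sim$truth$sweeps[1, ]
  he_sw <- window_mean_he(gm, sw, samples = cv)
  expect_lt(he_sw, 0.06)
  he_wild <- window_mean_he(gm, sw, samples = wild_ids(gm))
  expect_gt(he_wild, he_sw)
  # balancing blocks: most cultivars heterozygous
  bl <- sim$truth$blocks[1, ]
  bidx <- sites_in_block(gm$sites, bl)
  expect_gt(mean(gm$geno[cvrows, bidx] == 1L, na.rm = TRUE), 0.85)
})

test_that("infeasible heterozygote laws are refused", {
  expect_error(sim_config(balancing_blocks = tibble::tibble(
    chrom = "chr1", start0 = 0, end0 = 2e4, het_prob = 1.2
  )), "het_prob")
  expect_error(sim_config(sweep_regions = tibble::tibble(
    chrom = "chr1", start0 = c(0, 1e4), end0 = c(2e4, 3e4),
    cultivar_target_freq = 0.98
  )), "overlap")
  expect_error(sim_config(sweep_regions = tibble::tibble(
    chrom = "chr9", start0 = 0, end0 = 2e4, cultivar_target_freq = 0.98
  )), "bounds")
})

test_that("simulated traits carry the configured genotype effects", {
  sim <- default_sim()
  traits <- simulate_traits(sim)
  causal <- sim$truth$causal
  gm <- sim$matrix
  # quantitative: het effect +10 at noise sd 4 -> strong separation
  cs <- causal[causal$trait_name == "root_weight", ]
  g <- gm$geno[, which(gm$sites$chrom == cs$chrom & gm$sites$pos == cs$pos)]
  het <- traits$root_weight[!is.na(g) & g == 1L]
  hom <- traits$root_weight[!is.na(g) & g == 0L]
  expect_gt(length(het), 10)
  expect_gt(length(hom), 10)
  expect_lt(t.test(het, hom)$p.value, 1e-10)
  expect_equal(mean(het) - mean(hom), 10, tolerance = 2)
  # zero effects, zero noise -> constant trait
  cfg0 <- sim_config(n_chrom = 1, chrom_length_bp = 2e5, n_cultivar = 20,
                     sweep_regions = NULL, balancing_blocks = NULL,
                     causal = list(list(trait_name = "flat", type = "quantitative",
                                        chrom = "chr1", pos = NULL,
                                        effect_het = 0, effect_hom_alt = 0,
                                        noise_sd = 0, baseline = 7)),
                     seed = 9)
  t0 <- simulate_traits(simulate_genotypes(cfg0))
  expect_true(all(t0$flat == 7))
})

test_that("truth files round-trip through the recovery scorer", {
  sim <- default_sim()
  dir <- withr::local_tempdir()
  paths <- write_truth(sim$truth, dir)
  expect_true(all(file.exists(paths)))
  bed <- readr::read_tsv(paths[["sweeps"]], col_names = c("chrom", "start0", "end0",
                                                          "label", "score"),
                         show_col_types = FALSE)
  expect_equal(nrow(bed), nrow(sim$truth$sweeps))
  expect_equal(bed$start0, sim$truth$sweeps$start0)
  # identity: called = truth scores perfectly
  sc <- score_recovery(bed, sim$truth$sweeps)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$precision, 1)
  # no calls: sensitivity 0, precision flagged NA
  sc0 <- score_recovery(bed[0, ], sim$truth$sweeps)
  expect_equal(sc0$sensitivity, 0)
  expect_true(is.na(sc0$precision))
})

test_that("score_recovery matches a brute-force overlap check on perturbed truth", {
  withr::local_seed(71)
  truth <- tibble::tibble(chrom = "chr1",
                          start0 = c(1e5, 3e5, 6e5),
                          end0 = c(2e5, 4e5, 7e5))
  for (rep in 1:20) {
    shift <- sample(-8e4:8e4, 3)
    called <- dplyr::mutate(truth, start0 = start0 + shift, end0 = end0 + shift)
    got <- score_recovery(called, truth, 0.5)
    # brute force: interval i recovered iff its shifted copy overlaps >= 50% both ways
    rec <- vapply(1:3, function(i) {
      any(vapply(1:3, function(k) {
        ov <- min(called$end0[k], truth$end0[i]) - max(called$start0[k], truth$start0[i])
        ov >= 0.5 * (truth$end0[i] - truth$start0[i]) &&
          ov >= 0.5 * (called$end0[k] - called$start0[k])
      }, logical(1)))
    }, logical(1))
    expect_equal(got$sensitivity, mean(rec))
  }
})
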