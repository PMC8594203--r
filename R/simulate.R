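#' Configuration for the domestication-scenario cohort simulator
#'
#' Assembles and validates the parameters of [simulate_genotypes()]. The
#' defaults describe a desk-scale domestication scenario: a small
#' high-diversity wild progenitor panel and a large cultivar panel derived
#' from it by allele-frequency drift, with a genome-wide heterozygote excess
#' in cultivars (negative inbreeding-like coefficient `f_background`),
#' planted selective sweeps where the cultivar alternate-allele frequency is
#' pushed near fixation, and planted balancing-selection blocks where the
#' cultivar heterozygote probability is overridden to a high value.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param snp_density SNPs per bp (default 1/500, comparable to a dense
#'   crop resequencing map).
#' @param n_wild,n_cultivar Panel sizes (defaults 14 wild, 200 cultivars).
#' @param wild_beta Length-2 numeric, Beta(a, b) law of the wild
#'   alternate-allele frequency (default `c(0.8, 0.8)`, a U-shaped site
#'   frequency spectrum with mean 0.5).
#' @param drift Bottleneck drift parameter in `(0, 1)`: the cultivar
#'   frequency is drawn from Beta with mean p and variance `drift * p(1-p)`.
#' @param f_background Inbreeding-like coefficient in `(-1, 1)` controlling
#'   the cultivar heterozygote excess (negative = excess; default -0.1).
#' @param sweep_regions Tibble (or data frame) of planted sweeps: `chrom`,
#'   `start0`, `end0`, `cultivar_target_freq`. Use `NULL` for none.
#' @param balancing_blocks Tibble of planted balancing-selection blocks:
#'   `chrom`, `start0`, `end0`, `het_prob`. Use `NULL` for none.
#' @param causal `NULL` for the default trait set (placed on the available
#'   chromosomes), an empty `list()` for no traits, or a list of causal
#'   trait specifications, each a list with
#'   `trait_name`, `type` (`"quantitative"`/`"categorical"`), `chrom`,
#'   `pos` (filled in by the simulator when `NULL`: a SNP is picked),
#'   `effect_het`, `effect_hom_alt`, `noise_sd` (quantitative) or
#'   `log_odds_het`, `log_odds_hom_alt`, `levels` (categorical).
#' @param missing_rate Fraction of genotype calls dropped to missing.
#' @param seed Integer seed; all randomness flows from it, and the same
#'   configuration always yields identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2,
                       chrom_length_bp = 5e6,
                       snp_density = 1 / 500,
                       n_wild = 14,
                       n_cultivar = 200,
                       wild_beta = c(0.8, 0.8),
                       drift = 0.05,
                       f_background = -0.1,
                       sweep_regions = default_sweeps(),
                       balancing_blocks = default_balancing_blocks(),
                       causal = NULL,
                       missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_chrom = as.integer(n_chrom),
    chrom_length_bp = as.numeric(chrom_length_bp),
    snp_density = snp_density,
    n_wild = as.integer(n_wild),
    n_cultivar = as.integer(n_cultivar),
    wild_beta = wild_beta,
    drift = drift,
    f_background = f_background,
    sweep_regions = if (is.null(sweep_regions)) empty_regions("cultivar_target_freq")
                    else as_tibble(sweep_regions),
    balancing_blocks = if (is.null(balancing_blocks)) empty_regions("het_prob")
                       else as_tibble(balancing_blocks),
    causal = causal %||% default_causal(as.integer(n_chrom)),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_length_bp > 0,
            cfg$snp_density > 0, cfg$n_wild >= 1, cfg$n_cultivar >= 1,
            length(cfg$wild_beta) == 2, all(cfg$wild_beta > 0),
            cfg$drift > 0, cfg$drift < 1,
            cfg$f_background > -1, cfg$f_background < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  planted <- dplyr::bind_rows(
    cfg$sweep_regions[c("chrom", "start0", "end0")],
    cfg$balancing_blocks[c("chrom", "start0", "end0")]
  )
  if (nrow(planted)) {
    if (any(!planted$chrom %in% paste0("chr", seq_len(cfg$n_chrom))) ||
        any(planted$start0 < 0) || any(planted$end0 > cfg$chrom_length_bp)) {
      abort("planted regions must lie within chromosome bounds.")
    }
    ov <- merge_intervals(planted)
    if (sum(ov$end0 - ov$start0) < sum(planted$end0 - planted$start0)) {
      abort("planted regions must not overlap.")
    }
    if (any(cfg$balancing_blocks$het_prob < 0 | cfg$balancing_blocks$het_prob > 1)) {
      abort("balancing-block het_prob must be in [0, 1].")
    }
  }
  structure(cfg, class = "sim_config")
}

empty_regions <- function(extra) {
  out <- tibble(chrom = character(), start0 = numeric(), end0 = numeric())
  out[[extra]] <- numeric()
  out
}

# Five 100-kb sweeps (comparable to empirical merged sweep sizes) where the
# cultivar alternate allele is pushed to near fixation.
default_sweeps <- function() {
  tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start0 = c(5e5, 15e5, 25e5, 1e6, 3e6),
    end0 = c(5e5, 15e5, 25e5, 1e6, 3e6) + 1e5,
    cultivar_target_freq = 0.98
  )
}

# Three 60-kb balancing-selection blocks heterozygous in most cultivars.
default_balancing_blocks <- function() {
  tibble(
    chrom = c("chr1", "chr2", "chr2"),
    start0 = c(3.5e6, 2e6, 4e6),
    end0 = c(3.5e6, 2e6, 4e6) + 6e4,
    het_prob = 0.9
  )
}

default_causal <- function(n_chrom = 2) {
  chr2 <- paste0("chr", min(2L, n_chrom))
  list(
    list(trait_name = "root_weight", type = "quantitative", chrom = "chr1",
         pos = NULL, effect_het = 10, effect_hom_alt = 0, noise_sd = 4,
         baseline = 50),
    list(trait_name = "starch_content", type = "quantitative", chrom = chr2,
         pos = NULL, effect_het = 0, effect_hom_alt = 8, noise_sd = 4,
         baseline = 25),
    list(trait_name = "cbb_resistance", type = "categorical", chrom = chr2,
         pos = NULL, log_odds_het = 2, log_odds_hom_alt = 0,
         levels = c("susceptible", "resistant"), baseline_log_odds = -1)
  )
}

#' Simulate a wild + cultivar diploid genotype cohort
#'
#' Forward allele-frequency simulation of a domestication scenario. Site
#' positions are uniform at the configured density and sorted. The wild
#' alternate-allele frequency p is Beta-distributed and wild genotypes are
#' Hardy-Weinberg draws at p. The cultivar frequency p' is a Beta drift of p
#' (bottleneck), overridden to `cultivar_target_freq` inside planted sweeps;
#' cultivar genotypes are drawn with heterozygote probability
#' `2 p'(1-p')(1-F)` (F = `f_background`; overridden to `het_prob` inside
#' balancing blocks), with the homozygous classes splitting the remaining
#' mass proportionally to their Hardy-Weinberg weights. Calls are then set
#' missing uniformly at `missing_rate`. All draws consume a single RNG
#' stream seeded from `config$seed`, so identical configurations give
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (a [geno_matrix()]; wild samples `wild_*`
#'   with `pop_class = "wild"`, cultivars `cv_*` split between landraces and
#'   breeding lines), `truth` (a `TruthSet`: list with `sweeps`, `blocks`,
#'   `causal` tibbles) and `chrom_lengths`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chrom))
    n_per_chrom <- round(cfg$chrom_length_bp * cfg$snp_density)
    sites <- purrr::map_dfr(chroms, function(ch) {
      pos <- sort(sample.int(cfg$chrom_length_bp, n_per_chrom))
      tibble(chrom = ch, pos = pos)
    })
    n_sites_total <- nrow(sites)
    ra <- sample(c("A", "C", "G", "T"), n_sites_total, replace = TRUE)
    alt_of <- c(A = "G", C = "T", G = "A", T = "C")  # transitions, fixed map
    sites$ref <- ra
    sites$alt <- unname(alt_of[ra])
    # wild allele frequency law
    p_wild <- rbeta(n_sites_total, cfg$wild_beta[1], cfg$wild_beta[2])
    # cultivar frequency: Beta drift around p, overridden inside sweeps
    nu <- 1 / cfg$drift - 1  # so that var = drift * p (1 - p)
    p_cult <- rbeta(n_sites_total, p_wild * nu, (1 - p_wild) * nu)
    in_sweep <- region_member(sites, cfg$sweep_regions)
    if (any(in_sweep > 0)) {
      p_cult[in_sweep > 0] <-
        cfg$sweep_regions$cultivar_target_freq[in_sweep[in_sweep > 0]]
    }
    # genotype class probabilities
    wild_geno <- draw_genotypes(p_wild, het_prob = 2 * p_wild * (1 - p_wild),
                                n_ind = cfg$n_wild)
    het_c <- 2 * p_cult * (1 - p_cult) * (1 - cfg$f_background)
    in_block <- region_member(sites, cfg$balancing_blocks)
    if (any(in_block > 0)) {
      het_c[in_block > 0] <- cfg$balancing_blocks$het_prob[in_block[in_block > 0]]
    }
    if (any(het_c > 1)) {
      abort(sprintf("infeasible heterozygote probability > 1 at %d site(s).",
                    sum(het_c > 1)))
    }
    cult_geno <- draw_genotypes(p_cult, het_prob = het_c, n_ind = cfg$n_cultivar)
    geno <- rbind(wild_geno, cult_geno)
    if (cfg$missing_rate > 0) {
      geno[runif(length(geno)) < cfg$missing_rate] <- NA_integer_
    }
    n_land <- max(1L, round(cfg$n_cultivar * 0.15))
    samples <- tibble(
      sample_id = c(sprintf("wild_%02d", seq_len(cfg$n_wild)),
                    sprintf("cv_%03d", seq_len(cfg$n_cultivar))),
      pop_class = c(rep("wild", cfg$n_wild),
                    rep("landrace", n_land),
                    rep("breeding", cfg$n_cultivar - n_land))
    )
    gm <- geno_matrix(geno, sites = sites, samples = samples)
    causal <- resolve_causal(cfg, gm)
    truth <- list(
      sweeps = dplyr::mutate(cfg$sweep_regions, label = "sweep"),
      blocks = dplyr::mutate(cfg$balancing_blocks, label = "balancing_block"),
      causal = causal
    )
    list(matrix = gm, truth = truth,
         chrom_lengths = tibble(chrom = chroms,
                                length_bp = cfg$chrom_length_bp),
         config = cfg)
  })
}

# region index (0 = none) of each site; regions assumed non-overlapping
region_member <- function(sites, regions) {
  out <- integer(nrow(sites))
  if (!nrow(regions)) return(out)
  for (i in seq_len(nrow(regions))) {
    hit <- sites$chrom == regions$chrom[i] &
      sites$pos - 1L >= regions$start0[i] & sites$pos - 1L < regions$end0[i]
    out[hit] <- i
  }
  out
}

# draw n_ind diploid genotypes per site given per-site het probability and
# allele frequency p (hom classes split the residual mass by HWE weights)
draw_genotypes <- function(p, het_prob, n_ind) {
  n_sites <- length(p)
  hw_ref <- (1 - p)^2
  hw_alt <- p^2
  denom <- hw_ref + hw_alt
  denom[denom == 0] <- 1
  p2 <- (1 - het_prob) * hw_alt / denom        # P(hom alt)
  p1 <- het_prob
  u <- matrix(runif(n_ind * n_sites), nrow = n_ind, ncol = n_sites)
  g <- matrix(0L, nrow = n_ind, ncol = n_sites)
  g[u < rep(p2, each = n_ind)] <- 2L
  het_zone <- u >= rep(p2, each = n_ind) & u < rep(p2 + p1, each = n_ind)
  g[het_zone] <- 1L
  g
}

# attach causal SNP positions: nearest matrix SNP to the requested position,
# or a mid-chromosome SNP when pos is NULL
resolve_causal <- function(cfg, gm) {
  specs <- cfg$causal
  if (!length(specs)) {
    return(tibble(trait_name = character(), type = character(),
                  chrom = character(), pos = integer()))
  }
  purrr::map_dfr(seq_along(specs), function(i) {
    sp <- specs[[i]]
    on_chr <- which(gm$sites$chrom == sp$chrom)
    if (!length(on_chr)) abort(paste0("no SNPs on ", sp$chrom, " for causal trait."))
    target <- sp$pos %||% (cfg$chrom_length_bp * (0.3 + 0.1 * i))
    # prefer a common SNP near the target so genotype classes are populated
    g <- gm$geno[, on_chr, drop = FALSE]
    n_called <- colSums(!is.na(g))
    p <- ifelse(n_called > 0, colSums(g, na.rm = TRUE) / (2 * n_called), 0)
    common <- on_chr[pmin(p, 1 - p) >= 0.1]
    pool <- if (length(common)) common else on_chr
    sidx <- pool[which.min(abs(gm$sites$pos[pool] - target))]
    tibble(
      trait_name = sp$trait_name,
      type = sp$type,
      chrom = sp$chrom,
      pos = gm$sites$pos[sidx],
      effect_het = sp$effect_het %||% NA_real_,
      effect_hom_alt = sp$effect_hom_alt %||% NA_real_,
      noise_sd = sp$noise_sd %||% NA_real_,
      baseline = sp$baseline %||% 0,
      log_odds_het = sp$log_odds_het %||% NA_real_,
      log_odds_hom_alt = sp$log_odds_hom_alt %||% NA_real_,
      baseline_log_odds = sp$baseline_log_odds %||% 0,
      levels = paste(sp$levels %||% character(), collapse = ",")
    )
  })
}

#' Simulate genotype-linked traits
#'
#' Quantitative traits are `baseline + sum of genotype-class effects at the
#' causal SNPs + Gaussian noise`; categorical traits follow a logistic
#' probability from class log-odds. A missing genotype at a causal SNP
#' contributes zero effect. Draws consume the RNG stream seeded from
#' `seed` (default: the configuration seed plus 1, so genotype and trait
#' noise are independent but jointly reproducible).
#'
#' @param sim Output of [simulate_genotypes()].
#' @param seed Integer seed for the trait noise stream.
#' @return A trait tibble: `sample_id` plus one column per causal trait.
#' @export
simulate_traits <- function(sim, seed = NULL) {
  gm <- sim$matrix
  causal <- sim$truth$causal
  seed <- seed %||% (sim$config$seed + 1L)
  withr::with_seed(seed, {
    out <- tibble(sample_id = gm$samples$sample_id)
    for (i in seq_len(nrow(causal))) {
      cs <- causal[i, ]
      sidx <- which(gm$sites$chrom == cs$chrom & gm$sites$pos == cs$pos)
      g <- gm$geno[, sidx]
      if (cs$type == "quantitative") {
        eff <- ifelse(is.na(g), 0,
                      ifelse(g == 1L, cs$effect_het,
                             ifelse(g == 2L, cs$effect_hom_alt, 0)))
        out[[cs$trait_name]] <- cs$baseline + eff +
          rnorm(n_samples(gm), sd = cs$noise_sd)
      } else {
        lo <- cs$baseline_log_odds +
          ifelse(is.na(g), 0,
                 ifelse(g == 1L, cs$log_odds_het,
                        ifelse(g == 2L, cs$log_odds_hom_alt, 0)))
        pr <- 1 / (1 + exp(-lo))
        lev <- strsplit(cs$levels, ",", fixed = TRUE)[[1]]
        out[[cs$trait_name]] <- lev[1 + rbinom(n_samples(gm), 1, pr)]
      }
    }
    out
  })
}

#' Write simulator truth files
#'
#' Emits the planted sweep and balancing-block intervals as BED and the
#' causal SNP specifications as TSV, readable by [score_recovery()] and the
#' pipeline report.
#'
#' @param truth The `truth` element of [simulate_genotypes()] output.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sweeps = file.path(dir, "truth_sweeps.bed"),
    blocks = file.path(dir, "truth_blocks.bed"),
    causal = file.path(dir, "truth_causal.tsv")
  )
  write_regions_bed(
    dplyr::mutate(truth$sweeps, score = .data$cultivar_target_freq),
    paths[["sweeps"]]
  )
  write_regions_bed(
    dplyr::mutate(truth$blocks, score = .data$het_prob),
    paths[["blocks"]]
  )
  readr::write_tsv(truth$causal, paths[["causal"]])
  invisible(paths)
}

#' Score recovery of planted regions
#'
#' A truth interval is recovered when some called region achieves reciprocal
#' overlap of at least `min_reciprocal_overlap` (the overlap spans that
#' fraction of BOTH intervals). Sensitivity is the fraction of truth
#' intervals recovered; precision is the fraction of called regions that
#' match some truth interval (NA, flagged, when nothing was called).
#'
#' @param called Tibble of called regions (`chrom`, `start0`, `end0`).
#' @param truth Tibble of truth intervals (`chrom`, `start0`, `end0`).
#' @param min_reciprocal_overlap Fraction in `(0, 1]` (default 0.5).
#' @return A tibble with `sensitivity`, `precision`, `n_truth`, `n_called`,
#'   `n_recovered`, `n_matched_calls`.
#' @export
score_recovery <- function(called, truth, min_reciprocal_overlap = 0.5) {
  called <- as_tibble(called)
  truth <- as_tibble(truth)
  if (!nrow(truth)) abort("truth set is empty.")
  recovered <- logical(nrow(truth))
  matched <- logical(nrow(called))
  for (i in seq_len(nrow(truth))) {
    for (k in seq_len(nrow(called))) {
      if (called$chrom[k] != truth$chrom[i]) next
      ov <- min(called$end0[k], truth$end0[i]) - max(called$start0[k], truth$start0[i])
      if (ov <= 0) next
      if (ov / (called$end0[k] - called$start0[k]) >= min_reciprocal_overlap &&
          ov / (truth$end0[i] - truth$start0[i]) >= min_reciprocal_overlap) {
        recovered[i] <- TRUE
        matched[k] <- TRUE
      }
    }
  }
  tibble(
    sensitivity = mean(recovered),
    precision = if (nrow(called)) mean(matched) else NA_real_,
    n_truth = nrow(truth),
    n_called = nrow(called),
    n_recovered = sum(recovered),
    n_matched_calls = sum(matched)
  )
}
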