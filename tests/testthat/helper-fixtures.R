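# Small in-code fixtures shared across test files.

# matrix from a samples x sites integer matrix, positions defaulting to a
# regular grid on one chromosome
toy_matrix <- function(geno, pos = NULL, chrom = "chr1", pop_class = NULL) {
  geno <- as.matrix(geno)
  n_sites <- ncol(geno)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n_sites)
  ids <- sprintf("s%02d", seq_len(nrow(geno)))
  geno_matrix(
    geno,
    sites = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
    samples = data.frame(
      sample_id = ids,
      pop_class = pop_class %||% rep("breeding", nrow(geno))
    )
  )
}

# random dosage matrix with missingness, uniform genotype draw
random_matrix <- function(n_samples, n_sites, missing_rate = 0.1,
                          chrom = "chr1", max_pos = n_sites * 200) {
  geno <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
                 nrow = n_samples)
  geno[runif(length(geno)) < missing_rate] <- NA_integer_
  toy_matrix(geno, pos = sort(sample.int(max_pos, n_sites)), chrom = chrom)
}

# one shared default-scenario simulation per test run (lazily built)
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_genotypes(sim_config(seed = seed))
  }
  .sim_cache[[key]]
}

# plain-R union-merge of possibly overlapping intervals (test construction
# helper so oracle inputs are disjoint, as call_sweeps output would be)
merge_regions_for_test <- function(df) {
  df <- df[order(df$start0), ]
  out <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$start0[i] <= out$end0[last]) {
      out$end0[last] <- max(out$end0[last], df$end0[i])
      out$score[last] <- max(out$score[last], df$score[i])
    } else {
      out <- rbind(out, df[i, ])
    }
  }
  out
}

# explicit two-locus class construction for the median-test oracle
combination_for_test <- function(gm, traits, min_n = 4) {
  lab <- c("hom_ref", "het", "hom_alt")
  ga <- gm$geno[, 1]; gb <- gm$geno[, 2]
  ok <- !is.na(ga) & !is.na(gb)
  combo <- paste(lab[ga[ok] + 1], lab[gb[ok] + 1], sep = "/")
  vals <- split(traits[[2]][match(gm$samples$sample_id[ok], traits$sample_id)],
                combo)
  vals[vapply(vals, length, integer(1)) >= min_n]
}

# site indices outside any planted region
region_free_sites <- function(sites, truth) {
  planted <- rbind(truth$sweeps[c("chrom", "start0", "end0")],
                   truth$blocks[c("chrom", "start0", "end0")])
  inside <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(planted))) {
    inside <- inside | (sites$chrom == planted$chrom[i] &
                        sites$pos - 1 >= planted$start0[i] &
                        sites$pos - 1 < planted$end0[i])
  }
  which(!inside)
}

# site indices inside one block interval
sites_in_block <- function(sites, block) {
  which(sites$chrom == block$chrom &
        sites$pos - 1 >= block$start0 & sites$pos - 1 < block$end0)
}
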