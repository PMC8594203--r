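#' Filter SNP sites on minor allele frequency and integrity
#'
#' Retains exactly the sites with MAF strictly greater than `maf_min` and
#' integrity (per-site call rate, the fraction of samples with a non-missing
#' genotype) strictly greater than `integrity_min`. MAF is computed from
#' non-missing allele counts only. The sample set is unchanged, and the
#' filter is idempotent.
#'
#' @param x A [geno_matrix()] with at least one sample.
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5)`. Default 0.05.
#' @param integrity_min Minimum call rate, in `(0, 1]`. Default 0.8.
#' @return A filtered [geno_matrix()] with attribute `n_removed`.
#' @examples
#' gm <- geno_matrix(
#'   rbind(a = c(0L, 0L), b = c(1L, 0L), c = c(2L, 0L)),
#'   sites = data.frame(chrom = "chr1", pos = c(1, 2), ref = "A", alt = "T"),
#'   samples = data.frame(sample_id = c("a", "b", "c"))
#' )
#' n_sites(filter_sites(gm))  # monomorphic site 2 removed
#' @export
filter_sites <- function(x, maf_min = 0.05, integrity_min = 0.8) {
  validate_geno_matrix(x)
  if (n_samples(x) == 0L) abort("cannot filter a matrix with zero samples.")
  if (maf_min < 0 || maf_min >= 0.5) abort("`maf_min` must be in [0, 0.5).")
  if (integrity_min <= 0 || integrity_min > 1) abort("`integrity_min` must be in (0, 1].")
  g <- x$geno
  n_called <- colSums(!is.na(g))
  integrity <- n_called / n_samples(x)
  alt <- colSums(g, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- which(!is.na(maf) & maf > maf_min & integrity > integrity_min)
  out <- subset_geno(x, site_idx = keep)
  attr(out, "n_removed") <- n_sites(x) - length(keep)
  out
}
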