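#' Build a diploid genotype matrix object
#'
#' The central container of the package: biallelic SNP genotypes for a panel
#' of diploid accessions, dosage-coded per sample and site as 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous alternate) or `NA` (missing
#' call). Sites are kept sorted by chromosome and position; all coordinates
#' are stored 1-based (VCF convention) in `sites$pos` while windows and
#' regions elsewhere in the package use 0-based half-open intervals.
#'
#' @param geno Integer matrix, samples x sites, values in `c(0, 1, 2, NA)`.
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `id`; one row per matrix column, sorted by
#'   (`chrom`, `pos`).
#' @param samples Data frame with columns `sample_id` and optionally
#'   `pop_class` (one of `"wild"`, `"landrace"`, `"breeding"`) and `country`;
#'   one row per matrix row.
#'
#' @return An object of class `geno_matrix`: a list with elements `geno`,
#'   `sites` (tibble) and `samples` (tibble).
#' @examples
#' gm <- geno_matrix(
#'   rbind(a = c(0L, 1L), b = c(2L, NA)),
#'   sites = data.frame(chrom = "chr1", pos = c(100, 200), ref = "A", alt = "T"),
#'   samples = data.frame(sample_id = c("a", "b"))
#' )
#' gm
#' @export
geno_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  if (!"id" %in% names(sites)) sites$id <- NA_character_
  if (!"pop_class" %in% names(samples)) samples$pop_class <- NA_character_
  if (!"country" %in% names(samples)) samples$country <- NA_character_
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  obj <- structure(
    list(geno = geno, sites = sites, samples = samples),
    class = "geno_matrix"
  )
  validate_geno_matrix(obj)
  dimnames(obj$geno) <- list(samples$sample_id, NULL)
  obj
}

validate_geno_matrix <- function(x) {
  geno <- x$geno
  sites <- x$sites
  samples <- x$samples
  if (nrow(geno) != nrow(samples)) {
    abort("`geno` must have one row per sample.")
  }
  if (ncol(geno) != nrow(sites)) {
    abort("`geno` must have one column per site.")
  }
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites))) {
    abort(paste0("`sites` must have columns: ", paste(req, collapse = ", "), "."))
  }
  if (!"sample_id" %in% names(samples)) {
    abort("`samples` must have a `sample_id` column.")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample ids must be unique.")
  }
  bad <- setdiff(unique(as.vector(geno)), c(0L, 1L, 2L, NA))
  if (length(bad)) {
    abort(paste0("genotype codes must be 0, 1, 2 or NA; found: ",
                 paste(bad, collapse = ", "), "."))
  }
  if (nrow(sites)) {
    if (any(sites$pos < 1L)) abort("site positions must be >= 1.")
    if (any(sites$ref == sites$alt)) abort("ref and alt alleles must differ.")
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) {
      abort("sites must be sorted by (chrom, pos).")
    }
  }
  invisible(x)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d biallelic SNP sites\n",
              n_samples(x), n_sites(x)))
  if (n_sites(x)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(x$sites$chrom), collapse = ", ")))
    miss <- mean(is.na(x$geno))
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  }
  cls <- table(x$samples$pop_class, useNA = "no")
  if (length(cls)) {
    cat("  pop_class: ",
        paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Dimensions of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @return Integer count of samples or sites.
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_sites <- function(x) ncol(x$geno)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param sample_ids Character vector of sample ids to keep (in this order).
#' @param site_idx Integer vector of site indices to keep (must stay sorted).
#' @return A new [geno_matrix()].
#' @export
subset_geno <- function(x, sample_ids = NULL, site_idx = NULL) {
  if (is.null(sample_ids)) sample_ids <- x$samples$sample_id
  missing_ids <- setdiff(sample_ids, x$samples$sample_id)
  if (length(missing_ids)) {
    abort(paste0("unknown sample ids: ", paste(missing_ids, collapse = ", "), "."))
  }
  ridx <- match(sample_ids, x$samples$sample_id)
  if (is.null(site_idx)) site_idx <- seq_len(n_sites(x))
  geno_matrix(
    x$geno[ridx, site_idx, drop = FALSE],
    sites = x$sites[site_idx, , drop = FALSE],
    samples = x$samples[ridx, , drop = FALSE]
  )
}

#' Sample ids by population class
#'
#' Cultivars are the union of landraces and breeding lines; wild accessions
#' form the progenitor panel.
#'
#' @param x A [geno_matrix()].
#' @return Character vector of sample ids.
#' @export
cultivar_ids <- function(x) {
  x$samples$sample_id[x$samples$pop_class %in% c("landrace", "breeding")]
}

#' @rdname cultivar_ids
#' @export
wild_ids <- function(x) {
  x$samples$sample_id[x$samples$pop_class %in% "wild"]
}

# Resolve a sample subset argument (NULL = all) to row indices, erroring on
# unknown ids or an empty subset where one is required.
sample_rows <- function(x, samples, allow_empty = FALSE) {
  if (is.null(samples)) return(seq_len(n_samples(x)))
  missing_ids <- setdiff(samples, x$samples$sample_id)
  if (length(missing_ids)) {
    abort(paste0("unknown sample ids: ", paste(missing_ids, collapse = ", "), "."))
  }
  idx <- match(samples, x$samples$sample_id)
  if (!allow_empty && !length(idx)) abort("sample subset is empty.")
  idx
}
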