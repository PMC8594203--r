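#' Read diploid SNP genotypes from a VCF file
#'
#' Reads a VCF v4.x file with a GT FORMAT field into a [geno_matrix()].
#' Multiallelic records and non-SNP records (indels, symbolic alleles) are
#' dropped and counted; phased and unphased separators are treated
#' identically, and only the unphased heterozygous/homozygous state is kept.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param metadata Data frame of sample metadata with at least `sample_id`
#'   and usually `pop_class` (`wild`/`landrace`/`breeding`). Every sample in
#'   the VCF must appear in `metadata`; offenders are listed in the error.
#' @param verbose Report the number of excluded records?
#'
#' @return A [geno_matrix()] whose `samples` tibble carries the metadata
#'   columns, with attribute `n_excluded` giving the count of dropped
#'   multiallelic/non-SNP records.
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path, metadata, verbose = FALSE) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  metadata <- as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) {
    abort("`metadata` must have a `sample_id` column.")
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE,
                                          checkFile = FALSE, convertNA = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || !nrow(fix)) {
    gm <- geno_matrix(
      matrix(integer(), nrow = nrow(metadata), ncol = 0),
      sites = tibble(chrom = character(), pos = integer(),
                     ref = character(), alt = character()),
      samples = metadata
    )
    attr(gm, "n_excluded") <- 0L
    return(gm)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!keep)
  if (verbose && n_excluded) {
    inform(sprintf("read_vcf: excluded %d multiallelic/non-SNP record(s).",
                   n_excluded))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE,
                         IDtoRowNames = FALSE)
  if (is.null(gt)) abort("VCF has no GT field.")
  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, metadata$sample_id)
  if (length(unknown)) {
    abort(paste0("VCF samples absent from metadata: ",
                 paste(unknown, collapse = ", "), "."))
  }
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # normalise phased separators, then map to dosage
  core <- gsub("|", "/", substr(gt, 1, 3), fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[core == "0/0"] <- 0L
  code[core %in% c("0/1", "1/0")] <- 1L
  code[core == "1/1"] <- 2L
  unparsed <- !is.na(gt) & is.na(code) & !core %in% c("./.", ".|.", ".")
  if (any(unparsed)) {
    i <- which(unparsed, arr.ind = TRUE)[1, ]
    abort(sprintf("unparseable GT '%s' at record %d, sample '%s'.",
                  gt[i[1], i[2]], i[1], vcf_samples[i[2]]))
  }
  meta_sub <- metadata[match(vcf_samples, metadata$sample_id), , drop = FALSE]
  sites <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    id = dplyr::na_if(as.character(fix[, "ID"]), ".")
  )
  o <- order(sites$chrom, sites$pos)
  gm <- geno_matrix(t(code)[, o, drop = FALSE],
                    sites = sites[o, , drop = FALSE],
                    samples = meta_sub)
  attr(gm, "n_excluded") <- n_excluded
  gm
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits one record per site with a GT-only FORMAT; missing calls are written
#' as `./.`. Output is deterministic: the same matrix always yields
#' byte-identical files.
#'
#' @param x A [geno_matrix()] (sites must be sorted; enforced by the class).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  validate_geno_matrix(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hetscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t")
  ), con = con, sep = "\n")
  if (n_sites(x)) {
    gt <- matrix("./.", nrow = n_sites(x), ncol = n_samples(x))
    g <- t(x$geno)
    gt[which(g == 0L)] <- "0/0"
    gt[which(g == 1L)] <- "0/1"
    gt[which(g == 2L)] <- "1/1"
    body <- paste(
      x$sites$chrom, x$sites$pos,
      ifelse(is.na(x$sites$id), ".", x$sites$id),
      x$sites$ref, x$sites$alt, ".", "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con = con, sep = "\n")
  }
  invisible(path)
}
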