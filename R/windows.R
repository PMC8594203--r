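#' Generate genomic windows
#'
#' Produces sliding or non-overlapping windows over each chromosome,
#' 0-based half-open. Windows start at 0, advance by `step` and are
#' truncated at the chromosome end; a terminal partial window is kept when it
#' spans at least 1 bp. Statistics that normalise by window length use the
#' actual span (`end0 - start0`), so truncated windows are not biased.
#'
#' @param chrom_lengths Data frame with columns `chrom` and `length_bp`, or a
#'   named numeric vector of chromosome lengths.
#' @param size Window size in bp.
#' @param step Step in bp; `NULL` means non-overlapping (`step = size`).
#'   `step > size` is an error because it would silently drop sites.
#'
#' @return A tibble with columns `chrom`, `start0`, `end0`.
#' @examples
#' make_windows(c(chr1 = 100e3), size = 50e3, step = 10e3)
#' @export
make_windows <- function(chrom_lengths, size, step = NULL) {
  cl <- as_chrom_lengths(chrom_lengths)
  size <- as.integer(size)
  if (is.null(step)) step <- size
  step <- as.integer(step)
  if (size <= 0L || step <= 0L) abort("`size` and `step` must be positive.")
  if (step > size) abort("`step` must not exceed `size` (sites would be dropped).")
  out <- purrr::map2(cl$chrom, cl$length_bp, function(chrom, len) {
    len <- as.integer(len)
    if (len < 1L) return(NULL)
    starts <- seq.int(0L, len - 1L, by = step)
    tibble(chrom = chrom, start0 = starts, end0 = pmin(starts + size, len))
  })
  dplyr::bind_rows(out)
}

as_chrom_lengths <- function(chrom_lengths) {
  if (is.numeric(chrom_lengths) && !is.null(names(chrom_lengths))) {
    return(tibble(chrom = names(chrom_lengths),
                  length_bp = as.numeric(chrom_lengths)))
  }
  cl <- as_tibble(chrom_lengths)
  if (!all(c("chrom", "length_bp") %in% names(cl))) {
    abort("`chrom_lengths` needs columns `chrom` and `length_bp`.")
  }
  cl
}

# Indices of sites (1-based positions) falling in a 0-based half-open window.
# pos - 1 in [start0, end0)  <=>  pos in [start0 + 1, end0].
sites_in_window <- function(sites, chrom, start0, end0) {
  which(sites$chrom == chrom & sites$pos >= start0 + 1L & sites$pos <= end0)
}

# For many windows on one chromosome with sorted positions, return a matrix of
# [lo, hi] site-index bounds per window (hi < lo when empty). O(W log S).
window_site_bounds <- function(pos, windows) {
  lo <- findInterval(windows$start0 - 0.5, pos) + 1L  # first pos >= start0
  hi <- findInterval(windows$end0 - 0.5, pos)         # last pos <= end0 - 1
  cbind(lo = lo, hi = hi)
}

# sum of a cumulative vector over index ranges [lo, hi], 0 when empty
prefix_range_sum <- function(cv, lo, hi) {
  cvp <- c(0, cv)
  out <- cvp[pmax(hi, 0L) + 1L] - cvp[pmax(lo - 1L, 0L) + 1L]
  out[hi < lo] <- 0
  out
}

iranges_from <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)  # 1-based closed
}

tibble_from_iranges <- function(ir, chrom) {
  tibble(chrom = chrom,
         start0 = IRanges::start(ir) - 1L,
         end0 = IRanges::end(ir))
}

# Union-merge 0-based half-open intervals per chromosome (book-ended
# intervals coalesce). `df` needs chrom/start0/end0; extra columns dropped.
merge_intervals <- function(df) {
  if (!nrow(df)) return(tibble(chrom = character(), start0 = integer(), end0 = integer()))
  df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::reduce(iranges_from(d$start0, d$end0))
      tibble(start0 = IRanges::start(ir) - 1L, end0 = IRanges::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start0)
}

#' Overlap regions with gene annotation
#'
#' Assigns genes to regions by half-open interval overlap of at least 1 bp;
#' a gene may map to several regions and vice versa.
#'
#' @param regions Data frame of regions with `chrom`, `start0`, `end0` (plus
#'   any other columns, preserved).
#' @param genes Data frame of genes with `gene_id`, `chrom`, `start0`, `end0`
#'   (see [read_gene_annotation()]).
#' @return A tibble with one row per overlapping (region, gene) pair:
#'   the region columns plus `gene_id`. Regions without genes are absent.
#' @export
intersect_regions <- function(regions, genes) {
  regions <- as_tibble(regions)
  genes <- as_tibble(genes)
  if (!nrow(regions) || !nrow(genes)) {
    return(dplyr::bind_cols(regions[0, , drop = FALSE],
                            tibble(gene_id = character())))
  }
  empty <- dplyr::bind_cols(regions[0, , drop = FALSE],
                            tibble(gene_id = character()))
  out <- purrr::map(unique(regions$chrom), function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    hits <- IRanges::findOverlaps(iranges_from(r$start0, r$end0),
                                  iranges_from(g$start0, g$end0))
    if (!length(hits)) return(NULL)
    dplyr::bind_cols(
      r[S4Vectors::queryHits(hits), , drop = FALSE],
      tibble(gene_id = g$gene_id[S4Vectors::subjectHits(hits)])
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) empty else out
}
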