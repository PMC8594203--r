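#' Wild-to-cultivar diversity ratio scan
#'
#' Computes a per-window diversity statistic (mean expected heterozygosity
#' `"he"` or nucleotide diversity `"pi"`) separately in a wild and a
#' cultivar panel and forms the wild/cultivar ratio, so that large values
#' flag diversity lost in cultivars. Windows are excluded (ratio undefined)
#' when the cultivar value is 0 or the window holds fewer than `min_sites`
#' SNPs; zero-denominator windows can optionally be force-marked instead.
#' The sweep threshold is the empirical `1 - top_q` quantile of the defined
#' ratios (linear interpolation); a window is above when its ratio is `>=`
#' the threshold.
#'
#' @param x A [geno_matrix()].
#' @param wild,cultivar Character vectors of sample ids for the two panels.
#' @param chrom_lengths Chromosome lengths (see [make_windows()]).
#' @param statistic `"he"` or `"pi"`.
#' @param size,step Window size and step in bp (defaults 50 kb / 10 kb).
#' @param top_q Upper tail fraction defining the threshold (default 0.01,
#'   the top 1 percent).
#' @param min_sites Minimum SNPs per window for a defined ratio (default 5).
#' @param include_zero_denominator Mark zero-cultivar-diversity windows as
#'   above threshold instead of excluding them? Default `FALSE`.
#' @return An object of class `ratio_scan`: list with `windows` (tibble:
#'   window columns, `n_sites`, `value_wild`, `value_cultivar`, `ratio`,
#'   `above`), `threshold`, `statistic`, `top_q`.
#' @export
ratio_scan <- function(x, wild, cultivar, chrom_lengths,
                       statistic = c("he", "pi"),
                       size = 50e3, step = 10e3, top_q = 0.01, min_sites = 5,
                       include_zero_denominator = FALSE) {
  statistic <- match.arg(statistic)
  if (!length(wild) || !length(cultivar)) {
    abort("both `wild` and `cultivar` must be non-empty.")
  }
  wins <- make_windows(chrom_lengths, size = size, step = step)
  col <- if (statistic == "he") "mean_he" else "pi"
  ws_w <- window_stats(x, wins, samples = wild)
  ws_c <- window_stats(x, wins, samples = cultivar)
  w <- wins
  w$n_sites <- ws_w$n_sites
  w$value_wild <- ws_w[[col]]
  w$value_cultivar <- ws_c[[col]]
  defined <- !is.na(w$value_wild) & !is.na(w$value_cultivar) &
    w$value_cultivar > 0 & w$n_sites >= min_sites
  w$ratio <- ifelse(defined, w$value_wild / w$value_cultivar, NA_real_)
  if (!any(defined)) abort("all window ratios are undefined.")
  threshold <- unname(stats::quantile(w$ratio[defined], 1 - top_q, type = 7))
  w$above <- !is.na(w$ratio) & w$ratio >= threshold
  if (include_zero_denominator) {
    zero_den <- !is.na(w$value_wild) & !is.na(w$value_cultivar) &
      w$value_cultivar == 0 & w$value_wild > 0 & w$n_sites >= min_sites
    w$above <- w$above | zero_den
  }
  structure(list(windows = w, threshold = threshold,
                 statistic = statistic, top_q = top_q),
            class = "ratio_scan")
}

#' @export
print.ratio_scan <- function(x, ...) {
  cat(sprintf("<ratio_scan> statistic %s, wild/cultivar, top %.3g%%\n",
              x$statistic, 100 * x$top_q))
  cat(sprintf("  threshold %.4g; %d of %d defined windows above\n",
              x$threshold, sum(x$windows$above), sum(!is.na(x$windows$ratio))))
  invisible(x)
}

#' @rdname ratio_scan
#' @param object A `ratio_scan` object.
#' @param ... Unused.
#' @method tidy ratio_scan
#' @export
tidy.ratio_scan <- function(x, ...) x$windows

#' @rdname ratio_scan
#' @method glance ratio_scan
#' @export
glance.ratio_scan <- function(x, ...) {
  tibble(statistic = x$statistic, top_q = x$top_q, threshold = x$threshold,
         n_windows = nrow(x$windows),
         n_defined = sum(!is.na(x$windows$ratio)),
         n_above = sum(x$windows$above))
}

#' @rdname ratio_scan
#' @method autoplot ratio_scan
#' @export
autoplot.ratio_scan <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes((.data$start0 + .data$end0) / 2e6,
                                  .data$ratio, colour = .data$above)) +
    ggplot2::geom_point(size = 0.5, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)",
                  y = sprintf("%s (wild / cultivar)", object$statistic),
                  title = "Selective sweep ratio scan") +
    ggplot2::theme_minimal()
}

#' Merge above-threshold windows into sweep regions
#'
#' Windows flagged above the scan threshold that overlap or are book-ended
#' are merged into maximal regions; each region's score is the maximum
#' constituent ratio.
#'
#' @param scan A [ratio_scan()] object.
#' @return Tibble of regions: `chrom`, `start0`, `end0`, `label`
#'   (`"sweep_he"` or `"sweep_pi"`), `score`, `n_windows`.
#' @export
call_sweeps <- function(scan) {
  stopifnot(inherits(scan, "ratio_scan"))
  w <- scan$windows[scan$windows$above, , drop = FALSE]
  label <- paste0("sweep_", scan$statistic)
  regions <- merge_intervals(w)
  if (!nrow(regions)) {
    return(tibble(chrom = character(), start0 = integer(), end0 = integer(),
                  label = character(), score = numeric(), n_windows = integer()))
  }
  regions |>
    dplyr::mutate(purrr::map_dfr(seq_len(dplyr::n()), function(i) {
      inw <- w$chrom == regions$chrom[i] &
        w$start0 >= regions$start0[i] & w$end0 <= regions$end0[i]
      tibble(label = label, score = max(w$ratio[inw]), n_windows = sum(inw))
    })) |>
    dplyr::arrange(.data$chrom, .data$start0)
}

#' Intersect He-based and pi-based sweep regions
#'
#' Pairwise interval intersections (span of at least 1 bp) between the two
#' sweep sets; each output region carries its parent region coordinates.
#'
#' @param he_sweeps,pi_sweeps Region tibbles from [call_sweeps()].
#' @return Tibble of `sweep_both` regions with `score` (the smaller of the
#'   two parent scores) and parent interval columns.
#' @export
intersect_sweeps <- function(he_sweeps, pi_sweeps) {
  he_sweeps <- as_tibble(he_sweeps)
  pi_sweeps <- as_tibble(pi_sweeps)
  if (!nrow(he_sweeps) || !nrow(pi_sweeps)) {
    return(tibble(chrom = character(), start0 = integer(), end0 = integer(),
                  label = character(), score = numeric(),
                  he_start0 = integer(), he_end0 = integer(),
                  pi_start0 = integer(), pi_end0 = integer()))
  }
  out <- purrr::map_dfr(intersect(unique(he_sweeps$chrom), unique(pi_sweeps$chrom)),
                 function(ch) {
    a <- he_sweeps[he_sweeps$chrom == ch, , drop = FALSE]
    b <- pi_sweeps[pi_sweeps$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(iranges_from(a$start0, a$end0),
                                  iranges_from(b$start0, b$end0))
    if (!length(hits)) return(NULL)
    qa <- a[S4Vectors::queryHits(hits), , drop = FALSE]
    qb <- b[S4Vectors::subjectHits(hits), , drop = FALSE]
    tibble(
      chrom = ch,
      start0 = pmax(qa$start0, qb$start0),
      end0 = pmin(qa$end0, qb$end0),
      label = "sweep_both",
      score = pmin(qa$score, qb$score),
      he_start0 = qa$start0, he_end0 = qa$end0,
      pi_start0 = qb$start0, pi_end0 = qb$end0
    )
  })
  if (!nrow(out)) {
    return(tibble(chrom = character(), start0 = integer(), end0 = integer(),
                  label = character(), score = numeric(),
                  he_start0 = integer(), he_end0 = integer(),
                  pi_start0 = integer(), pi_end0 = integer()))
  }
  dplyr::arrange(out, .data$chrom, .data$start0)
}

#' Summarise a sweep region set
#'
#' Total span, genome fraction and gene content of a set of sweep regions;
#' optionally intersects the sweep genes with an externally supplied gene
#' list (e.g. differentially expressed genes).
#'
#' @param sweeps Region tibble (from [call_sweeps()] or [intersect_sweeps()]).
#' @param chrom_lengths Chromosome lengths (see [make_windows()]).
#' @param annotation Optional gene annotation tibble
#'   (see [read_gene_annotation()]).
#' @param gene_list Optional character vector of gene ids to cross-reference.
#' @return List with `n_regions`, `total_span_bp`, `genome_fraction`,
#'   `genes` (region-gene tibble or `NULL`), `n_genes`,
#'   `genes_in_list` (when `gene_list` is given).
#' @export
sweep_summary <- function(sweeps, chrom_lengths, annotation = NULL,
                          gene_list = NULL) {
  sweeps <- as_tibble(sweeps)
  cl <- as_chrom_lengths(chrom_lengths)
  span <- sum(sweeps$end0 - sweeps$start0)
  out <- list(
    n_regions = nrow(sweeps),
    total_span_bp = span,
    genome_fraction = span / sum(cl$length_bp),
    genes = NULL, n_genes = 0L
  )
  if (!is.null(annotation) && nrow(sweeps)) {
    g <- intersect_regions(sweeps, annotation)
    out$genes <- g
    out$n_genes <- length(unique(g$gene_id))
    if (!is.null(gene_list)) {
      out$genes_in_list <- intersect(unique(g$gene_id), gene_list)
    }
  }
  out
}
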