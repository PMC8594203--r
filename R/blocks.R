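#' Per-accession heterozygous block calls in fixed windows
#'
#' Counts heterozygous SNP calls per accession in non-overlapping windows
#' (default 20 kb) and calls a window a heterozygous block for an accession
#' when its count strictly exceeds the population cutoff: the mean het-SNP
#' count per window over all (accession, window) pairs, computed from the
#' data (never hardcoded).
#'
#' @param x A [geno_matrix()].
#' @param samples Character vector of accession ids to evaluate (typically
#'   the cultivars).
#' @param chrom_lengths Chromosome lengths (see [make_windows()]).
#' @param window Window size in bp; windows are non-overlapping.
#' @return An object of class `het_block_calls`: a tibble with one row per
#'   (accession, window): `sample_id`, `chrom`, `start0`, `end0`, `n_het`,
#'   `is_block`; attribute `cutoff` carries the population mean count.
#' @export
per_accession_het_blocks <- function(x, samples = NULL, chrom_lengths,
                                     window = 20e3) {
  idx <- sample_rows(x, samples)
  ids <- x$samples$sample_id[idx]
  wins <- make_windows(chrom_lengths, size = window, step = NULL)
  het01 <- (x$geno[idx, , drop = FALSE] == 1L)
  het01[is.na(het01)] <- FALSE
  counts <- purrr::map(split(seq_len(nrow(wins)), wins$chrom), function(wi) {
    w <- wins[wi, , drop = FALSE]
    on_chr <- which(x$sites$chrom == w$chrom[1])
    b <- window_site_bounds(x$sites$pos[on_chr] - 1L, w)
    ch <- apply(het01[, on_chr, drop = FALSE], 1, cumsum)  # sites x accessions
    if (is.null(dim(ch))) ch <- matrix(ch, nrow = 1)
    cnt <- matrix(0L, nrow = nrow(w), ncol = length(ids))
    for (k in seq_len(nrow(w))) {
      if (b[k, "hi"] >= b[k, "lo"]) {
        top <- ch[b[k, "hi"], ]
        bot <- if (b[k, "lo"] > 1) ch[b[k, "lo"] - 1, ] else 0
        cnt[k, ] <- as.integer(top - bot)
      }
    }
    dplyr::bind_cols(
      w[rep(seq_len(nrow(w)), times = length(ids)), , drop = FALSE],
      tibble(sample_id = rep(ids, each = nrow(w)),
             n_het = as.vector(cnt))
    )
  })
  calls <- dplyr::bind_rows(counts)
  cutoff <- mean(calls$n_het)
  calls$is_block <- calls$n_het > cutoff
  calls <- calls |>
    dplyr::select("sample_id", "chrom", "start0", "end0", "n_het", "is_block") |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start0)
  structure(calls, cutoff = cutoff,
            class = c("het_block_calls", class(calls)))
}

#' Highly heterozygous blocks from population block frequency
#'
#' Computes the population frequency of the heterozygous-block call per
#' window (het accessions / evaluated accessions), marks the windows whose
#' frequency reaches the empirical `quantile` cutoff (linear-interpolation
#' quantile; frequency `>=` cutoff, so ties can saturate the marked set),
#' and merges adjacent qualifying windows into highly heterozygous block
#' regions.
#'
#' @param block_calls Output of [per_accession_het_blocks()].
#' @param quantile Quantile in `(0, 1)` defining the empirical cutoff
#'   (default 0.95, i.e. the top 5 percent of window frequencies).
#' @return An object of class `het_block_freq`: list with `table` (tibble
#'   per window: `chrom`, `start0`, `end0`, `het_count`, `n_called`,
#'   `frequency`, `is_highly_het`), `regions` (tibble of merged
#'   `highly_het_block` regions with `score` = max constituent frequency and
#'   `n_windows`), and `cutoff`.
#' @export
highly_het_blocks <- function(block_calls, quantile = 0.95) {
  if (quantile <= 0 || quantile >= 1) abort("`quantile` must be in (0, 1).")
  freq <- as_tibble(block_calls) |>
    dplyr::group_by(.data$chrom, .data$start0, .data$end0) |>
    dplyr::summarise(het_count = sum(.data$is_block),
                     n_called = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(frequency = .data$het_count / .data$n_called) |>
    dplyr::arrange(.data$chrom, .data$start0)
  cutoff <- unname(stats::quantile(freq$frequency, quantile, type = 7))
  freq$is_highly_het <- freq$frequency >= cutoff
  marked <- freq[freq$is_highly_het, , drop = FALSE]
  regions <- merge_intervals(marked)
  if (nrow(regions)) {
    regions <- regions |>
      dplyr::mutate(purrr::map_dfr(seq_len(dplyr::n()), function(i) {
        inw <- marked$chrom == regions$chrom[i] &
          marked$start0 >= regions$start0[i] & marked$end0 <= regions$end0[i]
        tibble(label = "highly_het_block",
               score = max(marked$frequency[inw]),
               n_windows = sum(inw))
      }))
  } else {
    regions$label <- character()
    regions$score <- numeric()
    regions$n_windows <- integer()
  }
  structure(list(table = freq, regions = regions, cutoff = cutoff,
                 quantile = quantile),
            class = "het_block_freq")
}

#' @export
print.het_block_freq <- function(x, ...) {
  cat(sprintf("<het_block_freq> %d windows, cutoff %.4f (quantile %.2f)\n",
              nrow(x$table), x$cutoff, x$quantile))
  cat(sprintf("  %d window(s) marked, %d merged highly heterozygous block(s)\n",
              sum(x$table$is_highly_het), nrow(x$regions)))
  invisible(x)
}

#' @rdname highly_het_blocks
#' @param x,object A `het_block_freq` object.
#' @param ... Unused.
#' @method tidy het_block_freq
#' @export
tidy.het_block_freq <- function(x, ...) x$table

#' @rdname highly_het_blocks
#' @method glance het_block_freq
#' @export
glance.het_block_freq <- function(x, ...) {
  tibble(n_windows = nrow(x$table),
         cutoff = x$cutoff,
         quantile = x$quantile,
         n_marked = sum(x$table$is_highly_het),
         n_blocks = nrow(x$regions),
         blocks_span_bp = sum(x$regions$end0 - x$regions$start0))
}

#' @rdname highly_het_blocks
#' @method autoplot het_block_freq
#' @export
autoplot.het_block_freq <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes((.data$start0 + .data$end0) / 2e6,
                               .data$frequency,
                               colour = .data$is_highly_het)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = "heterozygous-block frequency",
                  title = "Population frequency of heterozygous blocks") +
    ggplot2::theme_minimal()
}

#' Trait segregation between heterozygous and homozygous accession groups
#'
#' For one highly heterozygous block, splits the evaluated accessions into a
#' heterozygous group (block call in at least one constituent window) and a
#' homozygous group, and compares a quantitative trait between the groups
#' with a two-sided Wilcoxon rank-sum test: exact enumeration when both
#' groups have at most 10 accessions and the values are untied, otherwise
#' the tie-corrected normal approximation without continuity correction.
#'
#' @param block One-row tibble with `chrom`, `start0`, `end0` (a region from
#'   [highly_het_blocks()]).
#' @param block_calls Output of [per_accession_het_blocks()].
#' @param traits Trait table with `sample_id` and trait columns.
#' @param trait_name Name of a quantitative trait column.
#' @return One-row tibble: block coordinates, `trait_name`, `n_het`,
#'   `n_hom`, `statistic` (rank-sum W), `p_value` (`NA` with a flag when a
#'   group is empty), `undefined`.
#' @export
trait_segregation <- function(block, block_calls, traits, trait_name) {
  block <- check_window(block)
  traits <- as_tibble(traits)
  if (!trait_name %in% names(traits)) {
    abort(paste0("trait `", trait_name, "` not found."))
  }
  calls <- as_tibble(block_calls) |>
    dplyr::filter(.data$chrom == block$chrom,
                  .data$start0 < block$end0, .data$end0 > block$start0) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(het = any(.data$is_block), .groups = "drop")
  dat <- dplyr::inner_join(calls, traits, by = "sample_id")
  vals <- dat[[trait_name]]
  a <- vals[dat$het & !is.na(vals)]
  b <- vals[!dat$het & !is.na(vals)]
  out <- tibble(chrom = block$chrom, start0 = block$start0, end0 = block$end0,
                trait_name = trait_name, n_het = length(a), n_hom = length(b),
                statistic = NA_real_, p_value = NA_real_,
                undefined = length(a) == 0 || length(b) == 0)
  if (out$undefined) return(out)
  exact <- length(a) <= 10 && length(b) <= 10 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  out$statistic <- unname(wt$statistic)
  out$p_value <- wt$p.value
  out
}

#' Trait segregation across all highly heterozygous blocks
#'
#' Runs [trait_segregation()] for every block region and adds a
#' Benjamini-Hochberg q-value across blocks per trait.
#'
#' @param blocks Region tibble from [highly_het_blocks()] (`$regions`).
#' @param block_calls Output of [per_accession_het_blocks()].
#' @param traits Trait table.
#' @param trait_names Character vector of quantitative trait columns.
#' @return Tibble of per-(block, trait) results with `q_value`.
#' @export
trait_segregation_scan <- function(blocks, block_calls, traits, trait_names) {
  blocks <- as_tibble(blocks)
  res <- purrr::map_dfr(trait_names, function(tn) {
    purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
      trait_segregation(blocks[i, , drop = FALSE], block_calls, traits, tn)
    })
  })
  res |>
    dplyr::group_by(.data$trait_name) |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup()
}
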