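#' Partition a genome into heterozygous and homozygous regions
#'
#' Slides windows along each chromosome, computes the heterozygous-SNP rate
#' (het calls / window span, as a fraction) for one reference accession, and
#' labels each window homozygous when the rate is below `rate_threshold`,
#' heterozygous otherwise. Because sliding windows overlap, labels can
#' conflict at overlaps; a base is assigned to the heterozygous class when
#' ANY overlapping window is heterozygous (union of the rarer label), and
#' the homozygous class is the union of homozygous windows minus the
#' heterozygous union. Merged regions with span not exceeding `min_len` are
#' discarded.
#'
#' @param x A [geno_matrix()].
#' @param reference_sample Sample id whose heterozygous calls define the
#'   partition.
#' @param chrom_lengths Chromosome lengths (data frame or named vector, see
#'   [make_windows()]).
#' @param window,step Window size and step in bp (defaults 25 kb / 5 kb).
#' @param rate_threshold Het-SNP rate (fraction of window bases) below which
#'   a window is homozygous. Default 0.002, i.e. 50 het SNPs per 25 kb.
#' @param min_len Minimum region span in bp (regions with span `<= min_len`
#'   are dropped). Default 50 kb.
#' @return Tibble of disjoint-within-label regions: `chrom`, `start0`,
#'   `end0`, `label` (`"heterozygous"`/`"homozygous"`), `score` (mean window
#'   het rate over constituent windows), `n_windows`.
#' @export
classify_het_hom_regions <- function(x, reference_sample, chrom_lengths,
                                     window = 25e3, step = 5e3,
                                     rate_threshold = 0.002, min_len = 50e3) {
  if (step > window) abort("`step` must not exceed `window`.")
  ridx <- sample_rows(x, reference_sample)
  if (length(ridx) != 1L) abort("`reference_sample` must be a single sample id.")
  wins <- make_windows(chrom_lengths, size = window, step = step)
  is_het_site <- x$geno[ridx, ] == 1L & !is.na(x$geno[ridx, ])
  rates <- purrr::map(split(seq_len(nrow(wins)), wins$chrom), function(wi) {
    w <- wins[wi, , drop = FALSE]
    on_chr <- which(x$sites$chrom == w$chrom[1])
    b <- window_site_bounds(x$sites$pos[on_chr] - 1L, w)
    chet <- cumsum(is_het_site[on_chr])
    cnt <- prefix_range_sum(chet, b[, "lo"], b[, "hi"])
    w$het_rate <- cnt / (w$end0 - w$start0)
    w
  })
  wins <- dplyr::bind_rows(rates)
  wins$is_het <- wins$het_rate >= rate_threshold
  out <- purrr::map(c(heterozygous = TRUE, homozygous = FALSE), function(het) {
    sub <- wins[wins$is_het == het, , drop = FALSE]
    reg <- merge_intervals(sub)
    if (!het && nrow(reg)) {
      # homozygous = hom-window union minus het-window union
      het_union <- merge_intervals(wins[wins$is_het, , drop = FALSE])
      reg <- purrr::map_dfr(unique(reg$chrom), function(ch) {
        r <- reg[reg$chrom == ch, , drop = FALSE]
        h <- het_union[het_union$chrom == ch, , drop = FALSE]
        ir <- IRanges::setdiff(iranges_from(r$start0, r$end0),
                               iranges_from(h$start0, h$end0))
        tibble_from_iranges(ir, ch)
      })
    }
    reg
  })
  regions <- dplyr::bind_rows(out, .id = "label") |>
    dplyr::filter(.data$end0 - .data$start0 > min_len)
  if (!nrow(regions)) {
    return(tibble(chrom = character(), start0 = integer(), end0 = integer(),
                  label = character(), score = numeric(), n_windows = integer()))
  }
  # score: mean het rate of windows whose midpoint falls in the region
  wins$mid <- (wins$start0 + wins$end0) / 2
  regions <- regions |>
    dplyr::mutate(purrr::map_dfr(seq_len(dplyr::n()), function(i) {
      inw <- wins$chrom == regions$chrom[i] &
        wins$mid >= regions$start0[i] & wins$mid < regions$end0[i]
      tibble(score = mean(wins$het_rate[inw]), n_windows = sum(inw))
    })) |>
    dplyr::select("chrom", "start0", "end0", "label", "score", "n_windows") |>
    dplyr::arrange(.data$chrom, .data$start0)
  regions
}

#' Compare window diversity between heterozygous and homozygous regions
#'
#' Assigns each statistics window (typically 50 kb / 10 kb from
#' [window_stats()] and [window_fst()]) to the region class containing its
#' midpoint, then contrasts the two classes with a Welch two-sample
#' two-tailed t-test, per chromosome and genome-wide, using window-level
#' values as replicates. A class with fewer than 2 windows on a chromosome
#' yields `NA` test results for that chromosome.
#'
#' @param regions Output of [classify_het_hom_regions()].
#' @param win_stats Tibble of windows with `chrom`, `start0`, `end0` and the
#'   statistic columns named in `stats`.
#' @param stats Character vector of statistic column names to compare
#'   (e.g. `c("pi", "tajimas_d", "fst")`).
#' @param per_chrom Also report per-chromosome tests?
#' @return Tibble with `chrom` (`"genome"` for the pooled row), `statistic`,
#'   `n_het`, `n_hom`, `mean_het`, `mean_hom`, `t`, `p_value`.
#' @export
compare_region_diversity <- function(regions, win_stats,
                                     stats = c("pi", "tajimas_d", "fst"),
                                     per_chrom = TRUE) {
  win_stats <- as_tibble(win_stats)
  missing_cols <- setdiff(stats, names(win_stats))
  if (length(missing_cols)) {
    abort(paste0("`win_stats` lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  win_stats$class <- assign_region_class(win_stats, regions)
  dat <- win_stats[!is.na(win_stats$class), , drop = FALSE]
  scopes <- list(genome = dat)
  if (per_chrom) {
    scopes <- c(scopes, split(dat, dat$chrom))
  }
  purrr::map_dfr(names(scopes), function(sc) {
    d <- scopes[[sc]]
    purrr::map_dfr(stats, function(st) {
      a <- d[[st]][d$class == "heterozygous"]
      b <- d[[st]][d$class == "homozygous"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      res <- tibble(chrom = sc, statistic = st,
                    n_het = length(a), n_hom = length(b),
                    mean_het = if (length(a)) mean(a) else NA_real_,
                    mean_hom = if (length(b)) mean(b) else NA_real_,
                    t = NA_real_, p_value = NA_real_)
      if (length(a) >= 2 && length(b) >= 2) {
        if (sd(a) == 0 && sd(b) == 0) {
          # degenerate: both classes constant
          res$t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
          res$p_value <- if (mean(a) == mean(b)) 1 else 0
        } else {
          ht <- t.test(a, b)  # Welch, two-sided
          res$t <- unname(ht$statistic)
          res$p_value <- ht$p.value
        }
      }
      res
    })
  })
}

# midpoint-rule class assignment of windows to regions
assign_region_class <- function(windows, regions) {
  cls <- rep(NA_character_, nrow(windows))
  mid <- (windows$start0 + windows$end0) / 2
  for (lab in unique(regions$label)) {
    r <- regions[regions$label == lab, , drop = FALSE]
    for (ch in unique(r$chrom)) {
      rc <- r[r$chrom == ch, , drop = FALSE]
      wi <- which(windows$chrom == ch)
      if (!length(wi)) next
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(start = as.integer(floor(mid[wi])) + 1L, width = 1L),
        iranges_from(rc$start0, rc$end0)
      )
      cls[wi[S4Vectors::queryHits(hit)]] <- lab
    }
  }
  cls
}
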