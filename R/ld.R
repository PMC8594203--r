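#' Linkage disequilibrium r-squared between two sites
#'
#' Squared Pearson correlation of dosage codes across samples with both
#' genotypes called. `NA` when either site has zero dosage variance in the
#' pairwise-complete subset.
#'
#' @param x A [geno_matrix()].
#' @param site_a,site_b Site indices (columns of the matrix).
#' @param samples Optional character vector of sample ids.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(x, site_a, site_b, samples = NULL) {
  idx <- sample_rows(x, samples)
  a <- x$geno[idx, site_a]
  b <- x$geno[idx, site_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Linkage disequilibrium decay curve
#'
#' Scores all intra-chromosome site pairs up to `max_dist` apart (or a
#' seeded uniform subsample when the pair count exceeds `max_pairs`),
#' averages r-squared in distance bins, and reports the decay point: the
#' midpoint of the first bin whose mean r-squared drops to `r2_threshold`
#' or below.
#'
#' @inheritParams ld_r2
#' @param max_dist Maximum pair distance in bp (default 1 Mb).
#' @param bin Distance bin width in bp (default 1 kb).
#' @param r2_threshold Decay threshold on mean r-squared (default 0.2).
#' @param max_pairs Cap on scored pairs; beyond it a uniform subsample is
#'   drawn with `sample_seed`.
#' @param sample_seed Seed for the pair subsample (only used above the cap).
#' @return An object of class `ld_decay`: list with `curve` (tibble
#'   `bin_start`, `bin_end`, `n_pairs`, `mean_r2`), `decay_point_bp`
#'   (`NA` if the curve never reaches the threshold) and `n_pairs_scored`.
#' @export
ld_decay <- function(x, samples = NULL, max_dist = 1e6, bin = 1e3,
                     r2_threshold = 0.2, max_pairs = 1e6, sample_seed = 1L) {
  idx <- sample_rows(x, samples)
  pairs <- purrr::map(unique(x$sites$chrom), function(ch) {
    on_chr <- which(x$sites$chrom == ch)
    if (length(on_chr) < 2) return(NULL)
    pos <- x$sites$pos[on_chr]
    # all ordered pairs within max_dist, via a sliding right bound
    hi <- findInterval(pos + max_dist, pos)
    a <- rep.int(seq_along(pos), pmax(hi - seq_along(pos), 0L))
    b <- unlist(lapply(seq_along(pos), function(i) {
      if (hi[i] > i) seq.int(i + 1L, hi[i]) else integer()
    }), use.names = FALSE)
    if (!length(a)) return(NULL)
    tibble(site_a = on_chr[a], site_b = on_chr[b],
           distance_bp = pos[b] - pos[a])
  })
  pairs <- dplyr::bind_rows(pairs)
  if (!nrow(pairs)) {
    return(structure(
      list(curve = tibble(bin_start = numeric(), bin_end = numeric(),
                          n_pairs = integer(), mean_r2 = numeric()),
           decay_point_bp = NA_real_, n_pairs_scored = 0L),
      class = "ld_decay"))
  }
  if (nrow(pairs) > max_pairs) {
    pairs <- withr::with_seed(sample_seed,
      pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE])
  }
  g <- x$geno[idx, , drop = FALSE]
  pairs$r2 <- purrr::map2_dbl(pairs$site_a, pairs$site_b, function(a, b) {
    va <- g[, a]; vb <- g[, b]
    ok <- !is.na(va) & !is.na(vb)
    if (sum(ok) < 2) return(NA_real_)
    va <- va[ok]; vb <- vb[ok]
    if (var(va) == 0 || var(vb) == 0) return(NA_real_)
    cor(va, vb)^2
  })
  pairs$bin_start <- floor(pairs$distance_bp / bin) * bin
  curve <- pairs |>
    dplyr::filter(!is.na(.data$r2)) |>
    dplyr::group_by(bin_start = .data$bin_start) |>
    dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2)) |>
    dplyr::mutate(bin_end = .data$bin_start + bin, .after = "bin_start") |>
    dplyr::arrange(.data$bin_start)
  below <- which(curve$mean_r2 <= r2_threshold)
  decay <- if (length(below)) (curve$bin_start[below[1]] + curve$bin_end[below[1]]) / 2 else NA_real_
  structure(
    list(curve = curve, decay_point_bp = decay,
         n_pairs_scored = sum(!is.na(pairs$r2))),
    class = "ld_decay"
  )
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("<ld_decay> %d pairs scored in %d bins\n",
              x$n_pairs_scored, nrow(x$curve)))
  if (!is.na(x$decay_point_bp)) {
    cat(sprintf("  decay point (mean r2 <= threshold): %.0f bp\n", x$decay_point_bp))
  } else {
    cat("  mean r2 never reaches the threshold within max_dist\n")
  }
  invisible(x)
}

#' @rdname ld_decay
#' @param object An `ld_decay` object.
#' @param ... Unused.
#' @method tidy ld_decay
#' @export
tidy.ld_decay <- function(x, ...) x$curve

#' @rdname ld_decay
#' @method glance ld_decay
#' @export
glance.ld_decay <- function(x, ...) {
  tibble(n_pairs_scored = x$n_pairs_scored,
         n_bins = nrow(x$curve),
         decay_point_bp = x$decay_point_bp)
}

#' @rdname ld_decay
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes((.data$bin_start + .data$bin_end) / 2e3,
                               .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.2, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}
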