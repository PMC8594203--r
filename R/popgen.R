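#' Per-site allele frequencies and expected heterozygosity
#'
#' For each site, computes the alternate-allele frequency among non-missing
#' allele copies, the minor allele frequency, the call rate, and the expected
#' heterozygosity He = 1 - p^2 - (1-p)^2 = 2p(1-p), the probability that two
#' randomly drawn allele copies differ. He lies in `[0, 0.5]` for a biallelic
#' site and is maximal at p = 0.5. Sites with no called genotypes get `NA`.
#'
#' @param x A [geno_matrix()].
#' @param samples Optional character vector of sample ids restricting the
#'   panel (default: all samples). Must be non-empty.
#' @return A tibble with one row per site: the site columns plus `n_chrom`
#'   (non-missing allele copies), `call_rate`, `p_alt`, `maf`, `he`.
#' @export
site_stats <- function(x, samples = NULL) {
  idx <- sample_rows(x, samples)
  g <- x$geno[idx, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  n_chrom <- 2L * n_called
  j <- colSums(g, na.rm = TRUE)
  p_alt <- ifelse(n_chrom > 0, j / n_chrom, NA_real_)
  dplyr::bind_cols(
    x$sites,
    tibble(
      n_chrom = n_chrom,
      call_rate = n_called / length(idx),
      p_alt = p_alt,
      maf = pmin(p_alt, 1 - p_alt),
      he = 2 * p_alt * (1 - p_alt)
    )
  )
}

# alt copies (j) and allele-copy totals (n) per site for a sample index set
site_counts <- function(x, idx) {
  g <- x$geno[idx, , drop = FALSE]
  n <- 2L * colSums(!is.na(g))
  list(j = colSums(g, na.rm = TRUE), n = n)
}

check_window <- function(window) {
  window <- as_tibble(window)
  if (nrow(window) != 1L || !all(c("chrom", "start0", "end0") %in% names(window))) {
    abort("`window` must be a single row with chrom, start0, end0.")
  }
  if (window$start0 < 0 || window$end0 <= window$start0) {
    abort("window must satisfy 0 <= start0 < end0.")
  }
  window
}

#' Mean expected heterozygosity of a window
#'
#' Unweighted mean of per-site He over the SNPs whose 0-based position falls
#' in `[start0, end0)`. Windows with no SNPs return `NA`.
#'
#' @inheritParams site_stats
#' @param window One-row data frame (or list) with `chrom`, `start0`, `end0`.
#' @return A single numeric value.
#' @export
window_mean_he <- function(x, window, samples = NULL) {
  window <- check_window(window)
  idx <- sites_in_window(x$sites, window$chrom, window$start0, window$end0)
  if (!length(idx)) return(NA_real_)
  sc <- site_counts(x, sample_rows(x, samples))
  p <- ifelse(sc$n[idx] > 0, sc$j[idx] / sc$n[idx], NA_real_)
  mean(2 * p * (1 - p), na.rm = TRUE)
}

#' Heterozygosity rate of one accession in a window
#'
#' Count of heterozygous calls divided by the window span, times 100
#' (percent per bp). Missing calls are never counted. Truncated terminal
#' windows are normalised by their actual span.
#'
#' @inheritParams window_mean_he
#' @param sample A single sample id.
#' @return Percentage of window bases that carry a heterozygous SNP call.
#' @export
het_rate <- function(x, window, sample) {
  window <- check_window(window)
  if (length(sample) != 1L) abort("`sample` must be a single sample id.")
  ridx <- sample_rows(x, sample)
  idx <- sites_in_window(x$sites, window$chrom, window$start0, window$end0)
  n_het <- sum(x$geno[ridx, idx] == 1L, na.rm = TRUE)
  100 * n_het / (window$end0 - window$start0)
}

#' Nucleotide diversity of a window
#'
#' Per-bp nucleotide diversity: at each site the unbiased estimator of the
#' average pairwise difference among the n non-missing allele copies,
#' pi_s = 2 j (n - j) / (n (n - 1)) with j alternate copies, summed over
#' sites and divided by the window span. Sites with fewer than 2 allele
#' copies are skipped.
#'
#' @inheritParams window_mean_he
#' @return Nucleotide diversity per bp (0 for windows with no polymorphism).
#' @export
nucleotide_diversity <- function(x, window, samples = NULL) {
  window <- check_window(window)
  idx <- sites_in_window(x$sites, window$chrom, window$start0, window$end0)
  sc <- site_counts(x, sample_rows(x, samples))
  sum(pi_site(sc$j[idx], sc$n[idx])) / (window$end0 - window$start0)
}

pi_site <- function(j, n) {
  out <- rep(0, length(j))
  ok <- n >= 2
  out[ok] <- 2 * j[ok] * (n[ok] - j[ok]) / (n[ok] * (n[ok] - 1))
  out
}

tajima_constants <- function(n) {
  # Standard normalising constants for Tajima's D at n sampled chromosomes.
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D of a window
#'
#' Normalised difference between the pairwise-diversity and
#' segregating-sites estimators of the population mutation rate. Positive
#' values indicate an excess of intermediate-frequency variants (balancing
#' selection); negative values follow sweeps or expansions. With per-site
#' missingness the sample size n is taken as the modal non-missing
#' chromosome count over the window's sites, and the diversity term is the
#' window sum of per-site pi (not per bp). `NA` when the window has fewer
#' than `min_segsites` segregating sites or fewer than 4 chromosomes.
#'
#' @inheritParams window_mean_he
#' @param min_segsites Minimum segregating sites for a defined value.
#' @return Tajima's D, or `NA` when undefined.
#' @export
tajimas_d <- function(x, window, samples = NULL, min_segsites = 3) {
  window <- check_window(window)
  idx <- sites_in_window(x$sites, window$chrom, window$start0, window$end0)
  sc <- site_counts(x, sample_rows(x, samples))
  tajd_from_counts(sc$j[idx], sc$n[idx], min_segsites)
}

tajd_from_counts <- function(j, n, min_segsites = 3) {
  called <- n > 0
  j <- j[called]; n <- n[called]
  if (!length(j)) return(NA_real_)
  seg <- j > 0 & j < n
  S <- sum(seg)
  if (S < min_segsites) return(NA_real_)
  n_modal <- modal_value(n)
  if (n_modal < 4) return(NA_real_)
  k <- tajima_constants(n_modal)
  pi_total <- sum(pi_site(j, n))
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_total - S / k$a1) / denom
}

modal_value <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])  # ties: smallest value wins
}

#' Window-level population-genetic statistics for many windows
#'
#' Vectorised computation of per-window SNP counts, mean He, nucleotide
#' diversity and (optionally) Tajima's D over a window set from
#' [make_windows()], for one sample group.
#'
#' @inheritParams site_stats
#' @param windows Tibble from [make_windows()].
#' @param tajima Also compute Tajima's D per window?
#' @param min_segsites Passed to the Tajima's D computation.
#' @return `windows` with added columns `n_sites`, `mean_he`, `pi` and
#'   optionally `tajimas_d`.
#' @export
window_stats <- function(x, windows, samples = NULL, tajima = FALSE,
                         min_segsites = 3) {
  windows <- as_tibble(windows)
  sc <- site_counts(x, sample_rows(x, samples))
  p <- ifelse(sc$n > 0, sc$j / sc$n, NA_real_)
  he <- 2 * p * (1 - p)
  pis <- pi_site(sc$j, sc$n)
  out <- purrr::map(split(seq_len(nrow(windows)), windows$chrom), function(wi) {
    w <- windows[wi, , drop = FALSE]
    on_chr <- which(x$sites$chrom == w$chrom[1])
    pos <- x$sites$pos[on_chr] - 1L  # 0-based
    b <- window_site_bounds(pos, w)
    che <- cumsum(ifelse(is.na(he[on_chr]), 0, he[on_chr]))
    cn <- cumsum(!is.na(he[on_chr]))
    cpi <- cumsum(pis[on_chr])
    n_sites <- as.integer(pmax(b[, "hi"] - b[, "lo"] + 1L, 0L))
    n_he <- prefix_range_sum(cn, b[, "lo"], b[, "hi"])
    w$n_sites <- n_sites
    w$mean_he <- ifelse(n_he > 0,
                        prefix_range_sum(che, b[, "lo"], b[, "hi"]) / n_he,
                        NA_real_)
    w$pi <- prefix_range_sum(cpi, b[, "lo"], b[, "hi"]) / (w$end0 - w$start0)
    if (tajima) {
      w$tajimas_d <- purrr::map_dbl(seq_len(nrow(w)), function(k) {
        if (b[k, "hi"] < b[k, "lo"]) return(NA_real_)
        rng <- on_chr[b[k, "lo"]:b[k, "hi"]]
        tajd_from_counts(sc$j[rng], sc$n[rng], min_segsites)
      })
    }
    w
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$chrom, .data$start0)
}

#' Fixation index between two sample groups
#'
#' Default is Hudson's estimator as a ratio of averages over sites:
#' `FST = sum(N_s) / sum(D_s)` with
#' `N_s = (p1 - p2)^2 - p1(1 - p1)/(n1 - 1) - p2(1 - p2)/(n2 - 1)` and
#' `D_s = p1(1 - p2) + p2(1 - p1)`, where `p` are alternate-allele
#' frequencies and `n` allele-copy counts per group. The `"nei"` option is
#' Nei's GST, `(Ht - Hs)/Ht` as a ratio of sums with `Ht` at the mean of the
#' two group frequencies. Sites lacking 2 called allele copies in either
#' group are skipped; the value is `NA` when the denominator sum is 0.
#' Slightly negative values can occur and are reported unclamped.
#'
#' @param x A [geno_matrix()].
#' @param group_a,group_b Character vectors of sample ids (distinct groups).
#' @param window Optional one-row window restricting the site set.
#' @param site_idx Optional integer site indices restricting the site set.
#' @param estimator `"hudson"` (default) or `"nei"`.
#' @return A single numeric FST value.
#' @export
fst <- function(x, group_a, group_b, window = NULL, site_idx = NULL,
                estimator = c("hudson", "nei")) {
  estimator <- match.arg(estimator)
  if (setequal(group_a, group_b)) abort("`group_a` and `group_b` must differ.")
  ia <- sample_rows(x, group_a)
  ib <- sample_rows(x, group_b)
  if (!is.null(window)) {
    window <- check_window(window)
    site_idx <- sites_in_window(x$sites, window$chrom, window$start0, window$end0)
  }
  if (is.null(site_idx)) site_idx <- seq_len(n_sites(x))
  sa <- site_counts(x, ia)
  sb <- site_counts(x, ib)
  fst_from_counts(sa$j[site_idx], sa$n[site_idx],
                  sb$j[site_idx], sb$n[site_idx], estimator)
}

fst_from_counts <- function(j1, n1, j2, n2, estimator = "hudson") {
  ok <- n1 >= 2 & n2 >= 2
  j1 <- j1[ok]; n1 <- n1[ok]; j2 <- j2[ok]; n2 <- n2[ok]
  if (!length(j1)) return(NA_real_)
  p1 <- j1 / n1
  p2 <- j2 / n2
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    num <- ht - hs
    den <- ht
  }
  if (sum(den) == 0) return(NA_real_)
  sum(num) / sum(den)
}

#' Mean pairwise genotype distance between two groups
#'
#' For diploid unphased genotypes the p-distance between two samples is the
#' mean over shared non-missing sites of `|code_i - code_j| / 2` (normalised
#' dosage distance, 0 for identical genotypes, 1 for opposite homozygotes).
#' The group distance averages this over all cross-group sample pairs; pairs
#' with no shared called site are skipped with a warning.
#'
#' @inheritParams fst
#' @return Mean cross-group p-distance.
#' @export
p_distance <- function(x, group_a, group_b) {
  if (length(intersect(group_a, group_b))) abort("groups must be disjoint.")
  ia <- sample_rows(x, group_a)
  ib <- sample_rows(x, group_b)
  g <- x$geno
  d <- matrix(NA_real_, length(ia), length(ib))
  for (a in seq_along(ia)) {
    va <- g[ia[a], ]
    for (b in seq_along(ib)) {
      vb <- g[ib[b], ]
      shared <- !is.na(va) & !is.na(vb)
      if (!any(shared)) next
      d[a, b] <- mean(abs(va[shared] - vb[shared]) / 2)
    }
  }
  if (anyNA(d)) {
    warn(sprintf("%d sample pair(s) share no called site and were skipped.",
                 sum(is.na(d))))
  }
  mean(d, na.rm = TRUE)
}

#' Pairwise FST and p-distance between population groups
#'
#' Convenience wrapper computing [fst()] and [p_distance()] for every pair
#' of groups in a named list of sample-id vectors.
#'
#' @param x A [geno_matrix()].
#' @param groups Named list of character vectors of sample ids.
#' @param estimator Passed to [fst()].
#' @return Tibble with `group_a`, `group_b`, `fst`, `p_distance`.
#' @export
group_distances <- function(x, groups, estimator = "hudson") {
  stopifnot(is.list(groups), !is.null(names(groups)))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    tibble(
      group_a = pr[1], group_b = pr[2],
      fst = fst(x, groups[[pr[1]]], groups[[pr[2]]], estimator = estimator),
      p_distance = p_distance(x, groups[[pr[1]]], groups[[pr[2]]])
    )
  })
}

#' Per-window FST between two groups
#'
#' Hudson (or Nei) FST computed independently in each window, vectorised
#' over a window set from [make_windows()].
#'
#' @inheritParams fst
#' @param windows Tibble from [make_windows()].
#' @return `windows` with added columns `n_sites` and `fst`.
#' @export
window_fst <- function(x, windows, group_a, group_b,
                       estimator = c("hudson", "nei")) {
  estimator <- match.arg(estimator)
  if (setequal(group_a, group_b)) abort("`group_a` and `group_b` must differ.")
  windows <- as_tibble(windows)
  sa <- site_counts(x, sample_rows(x, group_a))
  sb <- site_counts(x, sample_rows(x, group_b))
  out <- purrr::map(split(seq_len(nrow(windows)), windows$chrom), function(wi) {
    w <- windows[wi, , drop = FALSE]
    on_chr <- which(x$sites$chrom == w$chrom[1])
    b <- window_site_bounds(x$sites$pos[on_chr] - 1L, w)
    w$n_sites <- as.integer(pmax(b[, "hi"] - b[, "lo"] + 1L, 0L))
    w$fst <- purrr::map_dbl(seq_len(nrow(w)), function(k) {
      if (b[k, "hi"] < b[k, "lo"]) return(NA_real_)
      rng <- on_chr[b[k, "lo"]:b[k, "hi"]]
      fst_from_counts(sa$j[rng], sa$n[rng], sb$j[rng], sb$n[rng], estimator)
    })
    w
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$chrom, .data$start0)
}
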