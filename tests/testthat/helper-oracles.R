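# Independent brute-force / enumeration oracles used to check the package's
# statistics. These deliberately take the slow, literal route (explicit pair
# enumeration, per-site loops) and share no code with the implementation.

# expand dosage genotypes into allele copies (0/1), dropping NA
alleles_of <- function(genos) {
  genos <- genos[!is.na(genos)]
  unlist(lapply(genos, function(g) switch(as.character(g),
                                          "0" = c(0L, 0L),
                                          "1" = c(0L, 1L),
                                          "2" = c(1L, 1L))))
}

oracle_he <- function(genos) {
  al <- alleles_of(genos)
  if (!length(al)) return(NA_real_)
  p <- sum(al) / length(al)
  1 - p^2 - (1 - p)^2
}

# mean pairwise difference among allele copies at one site (all C(n,2) pairs)
oracle_pi_site <- function(genos) {
  al <- alleles_of(genos)
  n <- length(al)
  if (n < 2) return(0)
  prs <- utils::combn(n, 2)
  mean(al[prs[1, ]] != al[prs[2, ]])
}

oracle_window_pi <- function(geno_mat, span) {
  sum(apply(geno_mat, 2, oracle_pi_site)) / span
}

# Tajima's D: straight transliteration of the published constants
oracle_tajimas_d <- function(geno_mat, min_segsites = 3) {
  j <- colSums(geno_mat, na.rm = TRUE)
  n <- 2 * colSums(!is.na(geno_mat))
  j <- j[n > 0]; n <- n[n > 0]
  S <- sum(j > 0 & j < n)
  if (S < min_segsites) return(NA_real_)
  nn <- as.numeric(names(sort(table(n), decreasing = TRUE))[1])
  if (nn < 4) return(NA_real_)
  pi_tot <- 0
  for (s in seq_along(j)) {
    if (n[s] >= 2) pi_tot <- pi_tot + 2 * j[s] * (n[s] - j[s]) / (n[s] * (n[s] - 1))
  }
  a1 <- sum(1 / seq_len(nn - 1)); a2 <- sum(1 / seq_len(nn - 1)^2)
  b1 <- (nn + 1) / (3 * (nn - 1)); b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson FST, ratio of averages, spreadsheet-style per-site loop
oracle_hudson_fst <- function(ga, gb) {
  num <- 0; den <- 0
  for (s in seq_len(ncol(ga))) {
    aa <- alleles_of(ga[, s]); ab <- alleles_of(gb[, s])
    n1 <- length(aa); n2 <- length(ab)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(aa) / n1; p2 <- sum(ab) / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_p_distance <- function(ga, gb) {
  vals <- c()
  for (i in seq_len(nrow(ga))) {
    for (k in seq_len(nrow(gb))) {
      shared <- which(!is.na(ga[i, ]) & !is.na(gb[k, ]))
      if (!length(shared)) next
      vals <- c(vals, mean(abs(ga[i, shared] - gb[k, shared]) / 2))
    }
  }
  mean(vals)
}

# textbook squared Pearson correlation from raw sums
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  sxy <- sum(a * b) - sum(a) * sum(b) / n
  sxx <- sum(a^2) - sum(a)^2 / n
  syy <- sum(b^2) - sum(b)^2 / n
  if (sxx == 0 || syy == 0) return(NA_real_)
  (sxy / sqrt(sxx * syy))^2
}

oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  all_w <- apply(utils::combn(n, na), 2, function(ix) {
    sum(rank(pooled)[ix]) - na * (na + 1) / 2
  })
  mu <- na * (n - na) / 2
  p <- mean(abs(all_w - mu) >= abs(w_obs - mu))
  list(w = w_obs, p = p)
}

# tie-corrected normal approximation without continuity correction
oracle_wilcoxon_normal <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - na * nb / 2) / sqrt(sigma2)
  list(w = w, p = 2 * stats::pnorm(-abs(z)))
}

# Mood's median test: explicit counting, manual chi-square
oracle_median_test <- function(value_list) {
  grand <- stats::median(unlist(value_list))
  above <- vapply(value_list, function(v) sum(v > grand), numeric(1))
  below <- vapply(value_list, function(v) sum(v <= grand), numeric(1))
  oracle_chisq(cbind(above, below))
}

# brute-force window enumeration
oracle_windows <- function(len, size, step) {
  out <- NULL
  start <- 0
  while (start < len) {
    out <- rbind(out, c(start, min(start + size, len)))
    start <- start + step
  }
  out
}

# quadratic interval-overlap oracle on half-open intervals
oracle_overlaps <- function(a, b) {
  hits <- NULL
  for (i in seq_len(nrow(a))) {
    for (k in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[k] &&
          a$start0[i] < b$end0[k] && b$start0[k] < a$end0[i]) {
        hits <- rbind(hits, c(i, k))
      }
    }
  }
  hits
}
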