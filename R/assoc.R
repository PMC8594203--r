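#' Partition samples by genotype class at a SNP
#'
#' Splits the (non-missing) samples at one SNP into homozygous-reference,
#' heterozygous and homozygous-alternate groups; groups below
#' `min_group_size` are flagged rather than dropped so downstream tests can
#' refuse them explicitly.
#'
#' @param x A [geno_matrix()].
#' @param snp Site index, or a one-row data frame / list with `chrom` and
#'   `pos` identifying the SNP.
#' @param samples Optional character vector of sample ids.
#' @param min_group_size Minimum class size considered testable (default 5).
#' @return An object of class `genotype_groups`: list with `site` (one-row
#'   tibble), `groups` (named list `hom_ref`/`het`/`hom_alt` of sample ids),
#'   `sizes`, `flagged` (logical per class), `min_group_size`.
#' @export
genotype_groups <- function(x, snp, samples = NULL, min_group_size = 5) {
  sidx <- resolve_snp(x, snp)
  ridx <- sample_rows(x, samples)
  g <- x$geno[ridx, sidx]
  ids <- x$samples$sample_id[ridx]
  groups <- list(hom_ref = ids[!is.na(g) & g == 0L],
                 het = ids[!is.na(g) & g == 1L],
                 hom_alt = ids[!is.na(g) & g == 2L])
  sizes <- vapply(groups, length, integer(1))
  structure(list(site = x$sites[sidx, , drop = FALSE], groups = groups,
                 sizes = sizes, flagged = sizes < min_group_size,
                 min_group_size = min_group_size),
            class = "genotype_groups")
}

resolve_snp <- function(x, snp) {
  if (is.numeric(snp) && length(snp) == 1L) {
    sidx <- as.integer(snp)
    if (sidx < 1L || sidx > n_sites(x)) abort("SNP index out of range.")
    return(sidx)
  }
  snp <- as.list(snp)
  sidx <- which(x$sites$chrom == snp$chrom & x$sites$pos == snp$pos)
  if (length(sidx) != 1L) {
    abort(sprintf("SNP %s:%s not found in the matrix.", snp$chrom, snp$pos))
  }
  sidx
}

#' @export
print.genotype_groups <- function(x, ...) {
  cat(sprintf("<genotype_groups> %s:%d %s>%s\n", x$site$chrom, x$site$pos,
              x$site$ref, x$site$alt))
  for (cl in names(x$groups)) {
    cat(sprintf("  %-7s n=%d%s\n", cl, x$sizes[[cl]],
                if (x$flagged[[cl]]) " (below min_group_size)" else ""))
  }
  invisible(x)
}

#' Quantitative trait comparison between two genotype classes
#'
#' Welch two-tailed t-test of a quantitative trait between two genotype
#' classes (e.g. heterozygous vs homozygous-reference accessions). Both
#' classes must pass the group-size floor. When both groups are constant
#' with equal means the test is degenerate and p = 1 is returned.
#'
#' @param groups A [genotype_groups()] object.
#' @param traits Trait table with `sample_id` and trait columns.
#' @param trait_name Quantitative trait column name.
#' @param pair Length-2 character vector naming the classes to compare,
#'   from `c("hom_ref", "het", "hom_alt")`.
#' @return One-row tibble: SNP coordinates, trait, test label, per-class n
#'   and means, `statistic` (t), `p_value`.
#' @export
quantitative_assoc <- function(groups, traits, trait_name,
                               pair = c("het", "hom_ref")) {
  stopifnot(inherits(groups, "genotype_groups"))
  if (length(pair) != 2L || !all(pair %in% c("hom_ref", "het", "hom_alt")) ||
      pair[1] == pair[2]) {
    abort("`pair` must name two distinct genotype classes.")
  }
  if (any(groups$flagged[pair])) {
    abort(paste0("class(es) below min_group_size: ",
                 paste(pair[groups$flagged[pair]], collapse = ", "), "."))
  }
  vals <- trait_values(traits, trait_name, groups$groups[pair])
  a <- vals[[1]]; b <- vals[[2]]
  if (sd(a) == 0 && sd(b) == 0) {
    tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else
      sign(mean(a) - mean(b)) * Inf),
      p.value = if (mean(a) == mean(b)) 1 else 0)
  } else {
    tt <- t.test(a, b)  # Welch, two-sided
  }
  tibble(chrom = groups$site$chrom, pos = groups$site$pos,
         trait_name = trait_name, test = "t_test",
         class_a = pair[1], class_b = pair[2],
         n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b),
         statistic = unname(tt$statistic), p_value = tt$p.value)
}

trait_values <- function(traits, trait_name, group_list) {
  traits <- as_tibble(traits)
  if (!trait_name %in% names(traits)) {
    abort(paste0("trait `", trait_name, "` not found."))
  }
  lapply(group_list, function(ids) {
    v <- traits[[trait_name]][match(ids, traits$sample_id)]
    v[!is.na(v)]
  })
}

#' Categorical trait association with genotype class
#'
#' Pearson chi-square test (no continuity correction) of the genotype-class
#' by trait-category contingency table. Rows or columns with zero margins
#' are dropped with a warning; cells with expected counts below 5 set a
#' warning flag in the result.
#'
#' @inheritParams quantitative_assoc
#' @param trait_name Categorical trait column name.
#' @param classes Genotype classes to include (default all non-empty).
#' @return One-row tibble with `statistic` (X-squared), `df`, `p_value`,
#'   `low_expected` flag, and the collapsed table dimensions.
#' @export
categorical_assoc <- function(groups, traits, trait_name,
                              classes = c("hom_ref", "het", "hom_alt")) {
  stopifnot(inherits(groups, "genotype_groups"))
  traits <- as_tibble(traits)
  vals <- trait_values(traits, trait_name, groups$groups[classes])
  tab <- t(vapply(vals, function(v) table(factor(v, levels = sort(unique(unlist(vals))))),
                  numeric(length(unique(unlist(vals))))))
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn("dropping zero-margin row(s)/column(s) from the contingency table.")
  }
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(tibble(chrom = groups$site$chrom, pos = groups$site$pos,
                  trait_name = trait_name, test = "chi_square",
                  n_classes = nrow(tab), n_categories = ncol(tab),
                  statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                  low_expected = NA))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(chrom = groups$site$chrom, pos = groups$site$pos,
         trait_name = trait_name, test = "chi_square",
         n_classes = nrow(tab), n_categories = ncol(tab),
         statistic = unname(ct$statistic), df = as.integer(ct$parameter),
         p_value = ct$p.value,
         low_expected = any(ct$expected < 5))
}

# Mood's median test across k groups: counts above / at-or-below the grand
# median (ties go to the "<= median" cell), Pearson chi-square without
# continuity correction.
median_test <- function(value_list) {
  grand <- median(unlist(value_list))
  tab <- t(vapply(value_list, function(v) {
    c(above = sum(v > grand), not_above = sum(v <= grand))
  }, numeric(2)))
  if (any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                grand_median = grand))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = as.integer(ct$parameter),
       p_value = ct$p.value, grand_median = grand)
}

#' Two-locus genotype-class combinations and trait comparison
#'
#' Builds combination classes as the cross of genotype classes at two SNPs
#' (unphased; e.g. `het/hom_alt`), keeps combinations with at least
#' `min_group_size` samples, runs an overall Mood's median test across the
#' classes, all pairwise median tests with Bonferroni adjustment, and
#' assigns compact display letters: classes that share no significant
#' adjusted pairwise difference share a letter (greedy assignment in
#' descending-median order).
#'
#' @param x A [geno_matrix()].
#' @param snp_a,snp_b SNP identifiers (see [genotype_groups()]).
#' @param traits Trait table.
#' @param trait_name Quantitative trait column name.
#' @param samples Optional sample subset.
#' @param min_group_size Minimum combination class size (default 5).
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return List of class `combo_assoc` with `overall` (one-row tibble),
#'   `pairwise` (tibble of pairs with `p_value`, `adjusted_p`), `classes`
#'   (tibble with `combo`, `n`, `median`, `letter`).
#' @export
allele_combination_assoc <- function(x, snp_a, snp_b, traits, trait_name,
                                     samples = NULL, min_group_size = 5,
                                     alpha = 0.05,
                                     adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  combos <- combination_classes(x, snp_a, snp_b, samples)
  vals <- trait_values(traits, trait_name, combos)
  vals <- vals[vapply(vals, length, integer(1)) >= min_group_size]
  if (length(vals) < 2) abort("fewer than 2 combination classes pass min_group_size.")
  ov <- median_test(vals)
  overall <- tibble(trait_name = trait_name, test = "median_test",
                    n_classes = length(vals),
                    grand_median = ov$grand_median,
                    statistic = ov$statistic, df = ov$df, p_value = ov$p_value)
  prs <- utils::combn(names(vals), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(prs, function(pr) {
    mt <- median_test(vals[pr])
    tibble(class_a = pr[1], class_b = pr[2],
           statistic = mt$statistic, p_value = mt$p_value)
  })
  pairwise$adjusted_p <- if (adjust == "bonferroni") {
    pmin(1, pairwise$p_value * nrow(pairwise))
  } else {
    stats::p.adjust(pairwise$p_value, method = "BH")
  }
  classes <- tibble(combo = names(vals),
                    n = vapply(vals, length, integer(1)),
                    median = vapply(vals, median, numeric(1)))
  classes$letter <- assign_letters(classes, pairwise, alpha)
  structure(list(overall = overall, pairwise = pairwise, classes = classes,
                 alpha = alpha, adjust = adjust),
            class = "combo_assoc")
}

combination_classes <- function(x, snp_a, snp_b, samples = NULL) {
  ia <- resolve_snp(x, snp_a)
  ib <- resolve_snp(x, snp_b)
  ridx <- sample_rows(x, samples)
  ga <- x$geno[ridx, ia]
  gb <- x$geno[ridx, ib]
  ids <- x$samples$sample_id[ridx]
  ok <- !is.na(ga) & !is.na(gb)
  lab <- c("hom_ref", "het", "hom_alt")
  combo <- paste(lab[ga[ok] + 1L], lab[gb[ok] + 1L], sep = "/")
  split(ids[ok], combo)
}

# Greedy compact-letter display: classes in descending-median order; a class
# joins an existing letter group iff no member differs significantly from it.
assign_letters <- function(classes, pairwise, alpha) {
  ord <- order(-classes$median)
  sig <- function(a, b) {
    hit <- (pairwise$class_a == a & pairwise$class_b == b) |
      (pairwise$class_a == b & pairwise$class_b == a)
    any(hit) && !is.na(pairwise$adjusted_p[hit]) && pairwise$adjusted_p[hit] < alpha
  }
  groups_members <- list()
  letters_out <- setNames(rep("", nrow(classes)), classes$combo)
  for (i in ord) {
    cls <- classes$combo[i]
    placed <- FALSE
    for (gi in seq_along(groups_members)) {
      if (!any(vapply(groups_members[[gi]], sig, logical(1), b = cls))) {
        groups_members[[gi]] <- c(groups_members[[gi]], cls)
        letters_out[cls] <- paste0(letters_out[cls], letters[gi])
        placed <- TRUE
      }
    }
    if (!placed) {
      groups_members[[length(groups_members) + 1]] <- cls
      letters_out[cls] <- letters[length(groups_members)]
    }
  }
  unname(letters_out[classes$combo])
}

#' @export
print.combo_assoc <- function(x, ...) {
  cat("<combo_assoc> overall Mood's median test: ")
  cat(sprintf("X2 = %.3g, df = %s, p = %.3g\n",
              x$overall$statistic, x$overall$df, x$overall$p_value))
  print(x$classes)
  invisible(x)
}

#' @rdname allele_combination_assoc
#' @param ... Unused.
#' @method tidy combo_assoc
#' @export
tidy.combo_assoc <- function(x, ...) x$pairwise

#' @rdname allele_combination_assoc
#' @method glance combo_assoc
#' @export
glance.combo_assoc <- function(x, ...) x$overall

#' Two-locus combination frequencies by population
#'
#' Counts and frequencies of each two-locus genotype-class combination in a
#' wild and a cultivar panel, with a chi-square test of the frequency
#' difference between the populations.
#'
#' @inheritParams allele_combination_assoc
#' @param group_wild,group_cultivar Character vectors of sample ids.
#' @return List with `table` (tibble: `combo`, `population`, `n`,
#'   `frequency`) and `test` (one-row tibble: chi-square statistic, df, p).
#' @export
combination_frequency <- function(x, snp_a, snp_b, group_wild, group_cultivar) {
  if (!length(group_wild) || !length(group_cultivar)) {
    abort("both groups must be non-empty.")
  }
  cw <- combination_classes(x, snp_a, snp_b, group_wild)
  cc <- combination_classes(x, snp_a, snp_b, group_cultivar)
  combos <- sort(union(names(cw), names(cc)))
  nw <- vapply(combos, function(k) length(cw[[k]]) %||% 0L, integer(1))
  nc <- vapply(combos, function(k) length(cc[[k]]) %||% 0L, integer(1))
  tab <- rbind(wild = nw, cultivar = nc)
  tbl <- tibble(
    combo = rep(combos, 2),
    population = rep(c("wild", "cultivar"), each = length(combos)),
    n = c(nw, nc),
    frequency = c(nw / sum(nw), nc / sum(nc))
  )
  keep <- colSums(tab) > 0
  test <- if (sum(keep) >= 2 && all(rowSums(tab) > 0)) {
    ct <- suppressWarnings(chisq.test(tab[, keep, drop = FALSE], correct = FALSE))
    tibble(test = "chi_square", statistic = unname(ct$statistic),
           df = as.integer(ct$parameter), p_value = ct$p.value)
  } else {
    tibble(test = "chi_square", statistic = NA_real_, df = NA_integer_,
           p_value = NA_real_)
  }
  list(table = tbl, test = test)
}
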