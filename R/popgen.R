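#' Classical population-genetic statistics
#'
#' Diversity summaries, exact Hardy-Weinberg and linkage-disequilibrium tests
#' under a one-individual-per-colony resampling design, likelihood (G) tests
#' of pairwise colony differentiation with Fisher combination and Bonferroni
#' correction, and the Evanno delta-K summary of clustering likelihoods.
#'
#' @name popgen
NULL

#' Per-locus diversity summaries
#'
#' Observed heterozygosity is the fraction of typed diploids that are
#' heterozygous; expected heterozygosity is Nei's unbiased gene diversity
#' `(2n/(2n-1)) (1 - sum f^2)`. The overall row is the unweighted mean
#' across loci.
#'
#' @param table a [genotype_table]; haploids are excluded.
#' @return list with `per_locus` (data.frame locus, n_a, n_typed, h_o, h_e)
#'   and `overall` (unweighted means).
#' @export
locus_summaries <- function(table) {
  dip <- diploid_subset(table)
  if (nrow(dip) == 0) stop("no diploid individuals")
  loci <- locus_names(dip)
  rows <- lapply(loci, function(loc) {
    calls <- locus_calls(dip, loc)
    typed <- calls[, 1] != 0 & calls[, 2] != 0
    calls <- calls[typed, , drop = FALSE]
    n <- nrow(calls)
    if (n == 0) {
      return(data.frame(locus = loc, n_a = 0L, n_typed = 0L,
                        h_o = NA_real_, h_e = NA_real_))
    }
    alleles <- c(calls)
    f <- as.numeric(base::table(alleles)) / length(alleles)
    h_o <- mean(calls[, 1] != calls[, 2])
    h_e <- (2 * n / (2 * n - 1)) * (1 - sum(f^2))
    data.frame(locus = loc, n_a = length(f), n_typed = n,
               h_o = h_o, h_e = h_e)
  })
  per_locus <- do.call(rbind, rows)
  list(per_locus = per_locus,
       overall = list(h_o = mean(per_locus$h_o, na.rm = TRUE),
                      h_e = mean(per_locus$h_e, na.rm = TRUE)))
}

# --- exact HWE tests --------------------------------------------------------

# log conditional probability statistic of a genotype array given allele
# counts (terms constant under allele permutation are dropped)
hwe_logstat <- function(pairs) {
  g <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  ngg <- table(g)
  h <- sum(pairs[, 1] != pairs[, 2])
  h * log(2) - sum(lfactorial(ngg))
}

# exact biallelic HWE test by full enumeration of heterozygote counts
hwe_exact_biallelic <- function(pairs) {
  alleles <- c(pairs)
  ab <- sort(unique(alleles))
  n1 <- sum(alleles == ab[1])
  n <- nrow(pairs)
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  logp <- vapply(hs, function(h) {
    n11 <- (n1 - h) / 2
    n22 <- n - n11 - h
    h * log(2) - lfactorial(n11) - lfactorial(n22) - lfactorial(h)
  }, 1)
  p_h <- exp(logp - max(logp))
  p_h <- p_h / sum(p_h)
  h_obs <- sum(pairs[, 1] != pairs[, 2])
  sum(p_h[p_h <= p_h[match(h_obs, hs)] * (1 + 1e-12)])
}

# Monte-Carlo exact HWE test (multi-allelic); permutes the allele vector
hwe_exact_mc <- function(pairs, n_mc = 2000L) {
  obs <- hwe_logstat(pairs)
  alleles <- c(pairs)
  n <- nrow(pairs)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(alleles)
    pp <- cbind(perm[seq_len(n)], perm[n + seq_len(n)])
    if (hwe_logstat(pp) <= obs + 1e-12) hits <- hits + 1L
  }
  perm_pvalue(hits, n_mc)
}

#' Exact Hardy-Weinberg test at one locus
#'
#' Full enumeration for biallelic configurations, Monte-Carlo otherwise
#' (conditional probability test of Guo & Thompson type).
#'
#' @param pairs n x 2 integer matrix of allele calls (no zeros).
#' @param n_mc Monte-Carlo draws for multi-allelic configurations.
#' @return p-value, or NA for a monomorphic sample.
#' @export
hwe_exact <- function(pairs, n_mc = 2000L) {
  pairs <- pairs[pairs[, 1] != 0 & pairs[, 2] != 0, , drop = FALSE]
  k <- length(unique(c(pairs)))
  if (k < 2) return(NA_real_)
  if (k == 2) hwe_exact_biallelic(pairs) else hwe_exact_mc(pairs, n_mc)
}

# draw one diploid individual per colony (row indices)
resample_one_per_colony <- function(table) {
  idx <- which(table$ploidy == 2L)
  split_idx <- split(idx, table$colony[idx])
  vapply(split_idx, function(v) v[sample.int(length(v), 1)], 1L)
}

#' Resampled exact HWE tests
#'
#' Family structure makes nestmates non-independent, so each replicate draws
#' a single diploid individual per colony before testing every locus.
#'
#' @param table a [genotype_table] with >= 2 colonies.
#' @param n_replicates resampling replicates (default 20).
#' @param seed integer seed.
#' @param n_mc Monte-Carlo draws per multi-allelic test.
#' @param alpha significance level for the summary count.
#' @return list with `p` (replicates x loci matrix), `n_tests`,
#'   `n_significant`.
#' @export
hwe_exact_resampled <- function(table, n_replicates = 20L, seed = 1L,
                                n_mc = 2000L, alpha = 0.05) {
  if (length(unique(table$colony)) < 2) stop("need >= 2 colonies")
  loci <- locus_names(table)
  set.seed(seed)
  p <- matrix(NA_real_, n_replicates, length(loci),
              dimnames = list(NULL, loci))
  for (r in seq_len(n_replicates)) {
    rows <- resample_one_per_colony(table)
    sub <- table[rows, , drop = FALSE]
    for (j in seq_along(loci)) {
      p[r, j] <- hwe_exact(locus_calls(sub, loci[j]), n_mc = n_mc)
    }
  }
  list(p = p, n_tests = sum(!is.na(p)),
       n_significant = sum(p < alpha, na.rm = TRUE))
}

# --- linkage disequilibrium -------------------------------------------------

g_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / e[keep]))
}

# permutation genotypic contingency test for one locus pair
ld_pair_test <- function(g1, g2, n_perm = 1000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) return(NA_real_)
  obs <- g_stat(table(g1, g2))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (g_stat(table(g1, sample(g2))) >= obs - 1e-12) hits <- hits + 1L
  }
  perm_pvalue(hits, n_perm)
}

#' Resampled linkage-disequilibrium tests
#'
#' Permutation-based genotypic contingency test (G statistic) for each locus
#' pair, under the same one-individual-per-colony resampling design as
#' [hwe_exact_resampled].
#'
#' @param table a [genotype_table] with >= 2 colonies.
#' @param n_replicates resampling replicates.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param alpha significance level for the summary.
#' @return list with `p` (data.frame replicate, locus1, locus2, p),
#'   `n_tests`, `n_significant`, `expected_false_positives`.
#' @export
ld_test_resampled <- function(table, n_replicates = 20L, n_perm = 1000L,
                              seed = 1L, alpha = 0.05) {
  if (length(unique(table$colony)) < 2) stop("need >= 2 colonies")
  loci <- locus_names(table)
  prs <- utils::combn(loci, 2)
  set.seed(seed)
  out <- list()
  for (r in seq_len(n_replicates)) {
    rows <- resample_one_per_colony(table)
    sub <- table[rows, , drop = FALSE]
    gg <- lapply(loci, function(loc) {
      calls <- locus_calls(sub, loc)
      ifelse(calls[, 1] == 0, NA,
             paste(pmin(calls[, 1], calls[, 2]),
                   pmax(calls[, 1], calls[, 2])))
    })
    names(gg) <- loci
    for (k in seq_len(ncol(prs))) {
      p <- ld_pair_test(gg[[prs[1, k]]], gg[[prs[2, k]]], n_perm)
      out[[length(out) + 1]] <- data.frame(replicate = r,
                                           locus1 = prs[1, k],
                                           locus2 = prs[2, k], p = p)
    }
  }
  df <- do.call(rbind, out)
  n_tests <- sum(!is.na(df$p))
  list(p = df, n_tests = n_tests,
       n_significant = sum(df$p < alpha, na.rm = TRUE),
       expected_false_positives = alpha * n_tests)
}

# --- pairwise colony differentiation ---------------------------------------

#' Pairwise G-test differentiation between colonies
#'
#' Per locus, a Monte-Carlo exact G test on the colony-by-genotype
#' contingency table; per colony pair, Fisher's combined probability
#' `-2 sum(ln p) ~ chi-square(2k)`; the Bonferroni threshold is
#' `alpha / (number of pairs tested)`.
#'
#' @param table a [genotype_table] (diploids used).
#' @param alpha family-wise significance level.
#' @param n_perm Monte-Carlo permutations per locus test.
#' @param seed integer seed.
#' @return data.frame with colony1, colony2, n_loci, p_combined,
#'   significant; the Bonferroni threshold is attached as attribute
#'   `"threshold"`.
#' @export
gtest_pairwise_differentiation <- function(table, alpha = 0.05,
                                           n_perm = 10000L, seed = 1L) {
  dip <- diploid_subset(table)
  colonies <- unique(dip$colony)
  if (length(colonies) < 2) stop("need >= 2 colonies")
  loci <- locus_names(dip)
  set.seed(seed)
  prs <- utils::combn(colonies, 2)
  res <- lapply(seq_len(ncol(prs)), function(k) {
    sub <- dip[dip$colony %in% prs[, k], , drop = FALSE]
    pvals <- c()
    for (loc in loci) {
      calls <- locus_calls(sub, loc)
      typed <- calls[, 1] != 0
      if (sum(typed) < 2) next
      g <- paste(pmin(calls[typed, 1], calls[typed, 2]),
                 pmax(calls[typed, 1], calls[typed, 2]))
      cl <- sub$colony[typed]
      if (length(unique(g)) < 2 || length(unique(cl)) < 2) next
      obs <- g_stat(base::table(cl, g))
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (g_stat(base::table(cl, sample(g))) >= obs - 1e-12) hits <- hits + 1L
      }
      pvals <- c(pvals, perm_pvalue(hits, n_perm))
    }
    if (length(pvals) == 0) {
      return(data.frame(colony1 = prs[1, k], colony2 = prs[2, k],
                        n_loci = 0L, p_combined = NA_real_))
    }
    x2 <- -2 * sum(log(pvals))
    data.frame(colony1 = prs[1, k], colony2 = prs[2, k],
               n_loci = length(pvals),
               p_combined = pchisq(x2, df = 2 * length(pvals),
                                   lower.tail = FALSE))
  })
  df <- do.call(rbind, res)
  thr <- alpha / sum(!is.na(df$p_combined))
  df$significant <- !is.na(df$p_combined) & df$p_combined < thr
  attr(df, "threshold") <- thr
  df
}

# --- Evanno delta-K ---------------------------------------------------------

#' Evanno delta-K summary of clustering log-likelihoods
#'
#' `deltaK(K) = mean over runs |L(K+1) - 2 L(K) + L(K-1)| / sd over runs of
#' L(K)`; undefined at the endpoints and where the run-to-run SD is zero.
#'
#' @param lnp data.frame with columns `K`, `run`, `lnp` (>= 2 runs for each
#'   of >= 3 consecutive K values).
#' @return list with `table` (data.frame K, mean_lnp, sd_lnp, delta_k) and
#'   `best_k` (argmax of delta_k).
#' @export
evanno_delta_k <- function(lnp) {
  stopifnot(all(c("K", "run", "lnp") %in% names(lnp)))
  ks <- sort(unique(lnp$K))
  if (length(ks) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  runs <- sort(unique(lnp$run))
  if (length(runs) < 2) stop("need >= 2 runs per K")
  m <- matrix(NA_real_, length(runs), length(ks),
              dimnames = list(runs, ks))
  for (i in seq_len(nrow(lnp))) {
    m[as.character(lnp$run[i]), as.character(lnp$K[i])] <- lnp$lnp[i]
  }
  if (any(is.na(m))) stop("every run must cover every K")
  sd_k <- apply(m, 2, sd)
  delta <- rep(NA_real_, length(ks))
  for (j in 2:(length(ks) - 1)) {
    second <- abs(m[, j + 1] - 2 * m[, j] + m[, j - 1])
    delta[j] <- if (sd_k[j] > 0) mean(second) / sd_k[j] else NA_real_
  }
  tab <- data.frame(K = ks, mean_lnp = colMeans(m), sd_lnp = sd_k,
                    delta_k = delta)
  best <- if (all(is.na(delta))) NA_integer_ else ks[which.max(delta)]
  list(table = tab, best_k = best)
}
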