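#' Weir-Cockerham F-statistics
#'
#' Method-of-moments variance-components estimators f (F_IS), theta (F_ST)
#' and F (F_IT) of Weir & Cockerham (1984), with nests treated as demes.
#' Multi-locus estimates are ratios of summed components; standard errors
#' come from a delete-one-locus jackknife and 95% confidence intervals from
#' a seeded bootstrap over loci.
#'
#' @name fstats
NULL

# per-locus Weir-Cockerham variance components summed over alleles:
# returns c(a, b, c) or NULL when the locus is uninformative
wc_locus_components <- function(calls, deme) {
  typed <- calls[, 1] != 0 & calls[, 2] != 0
  calls <- calls[typed, , drop = FALSE]
  deme <- deme[typed]
  keep_demes <- names(which(base::table(deme) >= 1))
  r <- length(keep_demes)
  if (r < 2) return(NULL)
  alleles <- sort(unique(c(calls)))
  if (length(alleles) < 2) return(NULL)
  n_i <- vapply(keep_demes, function(d) sum(deme == d), 1)
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  n_c <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  if (n_c <= 0) return(NULL)
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- vapply(keep_demes, function(d) {
      cc <- calls[deme == d, , drop = FALSE]
      mean(c(cc) == al)
    }, 1)
    h_i <- vapply(keep_demes, function(d) {
      cc <- calls[deme == d, , drop = FALSE]
      mean((cc[, 1] == al) != (cc[, 2] == al))
    }, 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / n_c) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

wc_ratios <- function(comp) {
  a <- sum(comp[, "a"]); b <- sum(comp[, "b"]); cc <- sum(comp[, "c"])
  c(fst = a / (a + b + cc),
    fis = 1 - cc / (b + cc),
    fit = 1 - cc / (a + b + cc))
}

#' Multi-locus Weir-Cockerham F-statistics with jackknife and bootstrap
#'
#' @param table a [genotype_table]; haploids are excluded.
#' @param demes grouping column, default "colony" (nests as demes).
#' @param n_boot bootstrap draws over loci for the 95% CI.
#' @param seed integer seed for the bootstrap.
#' @return list of class `fstat_result` with `fis`, `fst`, `fit`, jackknife
#'   SEs, bootstrap CIs, and the per-locus component matrix.
#' @export
weir_cockerham_fstats <- function(table, demes = "colony", n_boot = 10000L,
                                  seed = 1L) {
  dip <- diploid_subset(table)
  deme <- dip[[demes]]
  if (length(unique(deme)) < 2) stop("F_ST undefined for a single deme")
  loci <- locus_names(dip)
  comp <- lapply(loci, function(loc) {
    wc_locus_components(locus_calls(dip, loc), deme)
  })
  keep <- !vapply(comp, is.null, TRUE)
  comp <- do.call(rbind, comp[keep])
  rownames(comp) <- loci[keep]
  if (is.null(comp) || nrow(comp) == 0) stop("no informative locus")
  est <- wc_ratios(comp)
  L <- nrow(comp)
  if (L >= 2) {
    jack <- t(vapply(seq_len(L), function(j) {
      wc_ratios(comp[-j, , drop = FALSE])
    }, c(fst = 1, fis = 1, fit = 1)))
    se <- sqrt((L - 1) / L * colSums(sweep(jack, 2, colMeans(jack))^2))
    set.seed(seed)
    boot <- t(vapply(seq_len(n_boot), function(b) {
      wc_ratios(comp[sample.int(L, L, replace = TRUE), , drop = FALSE])
    }, c(fst = 1, fis = 1, fit = 1)))
    ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  } else {
    se <- c(fst = NA_real_, fis = NA_real_, fit = NA_real_)
    ci <- matrix(NA_real_, 2, 3, dimnames = list(NULL, names(est)))
  }
  structure(list(fst = unname(est["fst"]), fis = unname(est["fis"]),
                 fit = unname(est["fit"]),
                 se_fst = unname(se["fst"]), se_fis = unname(se["fis"]),
                 ci_fst = unname(ci[, "fst"]), ci_fis = unname(ci[, "fis"]),
                 n_loci = L, components = comp),
            class = "fstat_result")
}

#' Pairwise F_ST (Weir-Cockerham theta) between colonies
#'
#' @param table a [genotype_table].
#' @return symmetric colony x colony matrix with a zero diagonal; pairs with
#'   no informative locus are NA.
#' @export
pairwise_fst <- function(table) {
  dip <- diploid_subset(table)
  colonies <- unique(dip$colony)
  if (length(colonies) < 2) stop("need >= 2 colonies")
  loci <- locus_names(dip)
  m <- matrix(0, length(colonies), length(colonies),
              dimnames = list(colonies, colonies))
  for (i in seq_len(length(colonies) - 1)) {
    for (j in (i + 1):length(colonies)) {
      sub <- dip[dip$colony %in% colonies[c(i, j)], , drop = FALSE]
      comp <- lapply(loci, function(loc) {
        wc_locus_components(locus_calls(sub, loc), sub$colony)
      })
      comp <- do.call(rbind, comp[!vapply(comp, is.null, TRUE)])
      v <- if (is.null(comp) || nrow(comp) == 0) NA_real_
           else unname(wc_ratios(comp)["fst"])
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}
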