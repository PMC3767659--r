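#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions squared inter-individual distances into hierarchical variance
#' components (among groups, among populations within groups, within
#' populations) following the Excoffier-Smouse-Quattro framework, with
#' permutation tests of each component. For sequence data the distance is
#' the pairwise substitution count (giving Phi statistics); for
#' microsatellites the allele-mismatch count summed over loci gives the
#' F_ST-like analysis.
#'
#' @name amova
NULL

# sum of squared deviations within each level of a factor, from a squared
# distance matrix
ssd_within <- function(d2, f) {
  sum(vapply(split(seq_along(f), f), function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }, 1))
}

amova_components <- function(d2, pop, group = NULL) {
  n <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  ssd_total <- sum(d2[upper.tri(d2)]) / n
  ssd_wp <- ssd_within(d2, pop)
  n_p <- vapply(split(seq_along(pop), pop), length, 1)
  if (is.null(group)) {
    df_ap <- P - 1; df_wp <- n - P
    sigma_c <- ssd_wp / df_wp
    n_prime <- (n - sum(n_p^2) / n) / (P - 1)
    ms_ap <- (ssd_total - ssd_wp) / df_ap
    sigma_b <- (ms_ap - sigma_c) / n_prime
    total <- sigma_b + sigma_c
    return(list(levels = 2,
                ssd = c(among_pops = ssd_total - ssd_wp, within = ssd_wp),
                df = c(among_pops = df_ap, within = df_wp),
                sigma = c(among_pops = sigma_b, within = sigma_c),
                percent = 100 * c(among_pops = sigma_b, within = sigma_c) /
                  total,
                phi = c(phi_st = sigma_b / total)))
  }
  # three-level design
  grp_of_pop <- vapply(pops, function(p) unique(group[pop == p])[1], group[1])
  G <- length(unique(group))
  ssd_wg <- ssd_within(d2, group)
  ssd_ag <- ssd_total - ssd_wg
  ssd_ap_wg <- ssd_wg - ssd_wp
  df_ag <- G - 1; df_ap <- P - G; df_wp <- n - P
  ms_ag <- ssd_ag / df_ag
  ms_ap <- ssd_ap_wg / df_ap
  sigma_c <- ssd_wp / df_wp
  n_g <- vapply(split(seq_along(group), group), length, 1)
  a_g <- vapply(unique(group), function(g) {
    sum(n_p[names(n_p) %in% pops[grp_of_pop == g]]^2) / sum(group == g)
  }, 1)
  n1 <- (n - sum(a_g)) / (P - G)
  n2 <- (sum(a_g) - sum(n_p^2) / n) / (G - 1)
  n3 <- (n - sum(n_g^2) / n) / (G - 1)
  sigma_b <- (ms_ap - sigma_c) / n1
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  total <- sigma_a + sigma_b + sigma_c
  list(levels = 3,
       ssd = c(among_groups = ssd_ag, among_pops = ssd_ap_wg,
               within = ssd_wp),
       df = c(among_groups = df_ag, among_pops = df_ap, within = df_wp),
       sigma = c(among_groups = sigma_a, among_pops = sigma_b,
                 within = sigma_c),
       percent = 100 * c(among_groups = sigma_a, among_pops = sigma_b,
                         within = sigma_c) / total,
       phi = c(phi_ct = sigma_a / total,
               phi_sc = sigma_b / (sigma_b + sigma_c),
               phi_st = (sigma_a + sigma_b) / total))
}

#' AMOVA from a distance matrix
#'
#' @param d distance matrix (class dist or square matrix) between
#'   individuals; squared internally unless `squared = TRUE`.
#' @param pop population label per individual.
#' @param group optional group label per individual (must be constant within
#'   population); when given a three-level analysis is returned.
#' @param n_perm permutations for the significance tests.
#' @param seed integer seed.
#' @param truncate report negative variance components as zero in the
#'   percentage table (components themselves are always reported as
#'   computed).
#' @return list of class `amova_result` with `ssd`, `df`, `sigma`,
#'   `percent`, `phi` and permutation `p` values per statistic.
#' @export
amova <- function(d, pop, group = NULL, n_perm = 1000L, seed = 1L,
                  squared = FALSE, truncate = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(pop) != n) stop("pop labels do not match distance matrix")
  if (length(unique(pop)) < 2) stop("need >= 2 populations")
  if (!is.null(group)) {
    chk <- tapply(group, pop, function(g) length(unique(g)))
    if (any(chk != 1)) stop("group must be constant within population")
    if (length(unique(group)) < 2) {
      warning("single group: falling back to two-level AMOVA")
      group <- NULL
    }
  }
  d2 <- if (squared) d else d^2
  obs <- amova_components(d2, pop, group)

  set.seed(seed)
  p <- c()
  # Phi_ST: permute individuals among populations (whole design)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    st <- amova_components(d2, pop[perm],
                           if (is.null(group)) NULL else group[perm])
    if (st$phi["phi_st"] >= obs$phi["phi_st"] - 1e-12) hits <- hits + 1L
  }
  p["phi_st"] <- perm_pvalue(hits, n_perm)
  if (!is.null(group)) {
    # Phi_SC: permute individuals among pops within groups
    hits <- 0L
    for (k in seq_len(n_perm)) {
      pop_perm <- pop
      for (g in unique(group)) {
        idx <- which(group == g)
        pop_perm[idx] <- pop[idx][sample.int(length(idx))]
      }
      st <- amova_components(d2, pop_perm, group)
      if (st$phi["phi_sc"] >= obs$phi["phi_sc"] - 1e-12) hits <- hits + 1L
    }
    p["phi_sc"] <- perm_pvalue(hits, n_perm)
    # Phi_CT: permute whole populations among groups
    pops <- unique(pop)
    grp_of_pop <- vapply(pops, function(q) unique(group[pop == q])[1],
                         group[1])
    hits <- 0L
    for (k in seq_len(n_perm)) {
      gp <- grp_of_pop[sample.int(length(pops))]
      names(gp) <- pops
      st <- amova_components(d2, pop, unname(gp[pop]))
      if (st$phi["phi_ct"] >= obs$phi["phi_ct"] - 1e-12) hits <- hits + 1L
    }
    p["phi_ct"] <- perm_pvalue(hits, n_perm)
  }
  pct <- obs$percent
  if (truncate) {
    s <- pmax(obs$sigma, 0)
    pct <- 100 * s / sum(s)
  }
  structure(list(ssd = obs$ssd, df = obs$df, sigma = obs$sigma,
                 percent = pct, phi = obs$phi, p = p,
                 n_perm = n_perm, truncated = truncate),
            class = "amova_result")
}

#' Distance matrix for microsatellite AMOVA
#'
#' Squared distance between two diploid individuals is the number of allele
#' mismatches summed over loci (0, 1 or 2 per locus, minimised over the two
#' possible pairings); loci missing in either individual are skipped.
#'
#' @param table a [genotype_table] (diploids used).
#' @return list with `d2` (squared distance matrix) and `ids`.
#' @export
microsat_distance <- function(table) {
  dip <- diploid_subset(table)
  loci <- locus_names(dip)
  n <- nrow(dip)
  d2 <- matrix(0, n, n, dimnames = list(dip$id, dip$id))
  calls <- lapply(loci, function(loc) locus_calls(dip, loc))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- 0
      for (k in seq_along(loci)) {
        a <- calls[[k]][i, ]; b <- calls[[k]][j, ]
        if (any(a == 0) || any(b == 0)) next
        m1 <- (a[1] != b[1]) + (a[2] != b[2])
        m2 <- (a[1] != b[2]) + (a[2] != b[1])
        tot <- tot + min(m1, m2)
      }
      d2[i, j] <- d2[j, i] <- tot
    }
  }
  list(d2 = d2, ids = dip$id)
}
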