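#' Queller-Goodnight relatedness with jackknife errors
#'
#' Symmetric regression relatedness for codominant loci. Reference allele
#' frequencies are estimated from one randomly chosen diploid individual per
#' colony (avoiding family pseudo-replication) and, for each focal colony,
#' exclude that colony's representative (bias correction). Colonies are
#' weighted equally: the estimator is the mean over colonies of the
#' within-colony ratio of summed numerators to summed denominators, and the
#' standard error is a delete-one-colony jackknife.
#'
#' @name relatedness
NULL

# per-locus QG numerator/denominator increments for a dyad
# x, y: length-2 allele vectors; p: named frequency vector for the locus
qg_terms <- function(x, y, p) {
  pa <- function(a) { v <- p[as.character(a)]; ifelse(is.na(v), 0, v) }
  share <- function(a, g) 0.5 * ((g[1] == a) + (g[2] == a))
  num_x <- 0.5 * (share(x[1], y) + share(x[2], y)) -
    0.5 * (pa(x[1]) + pa(x[2]))
  den_x <- 0.5 * (share(x[1], x) + share(x[2], x)) -
    0.5 * (pa(x[1]) + pa(x[2]))
  num_y <- 0.5 * (share(y[1], x) + share(y[2], x)) -
    0.5 * (pa(y[1]) + pa(y[2]))
  den_y <- 0.5 * (share(y[1], y) + share(y[2], y)) -
    0.5 * (pa(y[1]) + pa(y[2]))
  c(num = unname(num_x + num_y), den = unname(den_x + den_y))
}

# genotype matrix (2 x L) for row i of a genotype table; haploids duplicated
# only when allow_haploid
geno_matrix <- function(table, i, loci, allow_haploid = FALSE) {
  m <- vapply(loci, function(loc) {
    a <- locus_calls(table, loc)[i, ]
    if (table$ploidy[i] == 1L) {
      if (!allow_haploid) stop("haploid individual in diploid estimator")
      a <- c(a[1], a[1])
    }
    as.integer(a)
  }, integer(2))
  m[, , drop = FALSE]
}

# reference allele frequencies from one random diploid per colony;
# returns list(freqs_by_colony_excluded): for colony c, per-locus named
# frequency vectors computed without c's representative
reference_frequencies <- function(table, seed = 1L) {
  loci <- locus_names(table)
  colonies <- unique(table$colony)
  set.seed(seed)
  reps <- vapply(colonies, function(cl) {
    idx <- which(table$colony == cl & table$ploidy == 2L)
    if (length(idx) == 0) NA_integer_ else idx[sample.int(length(idx), 1)]
  }, 1L)
  reps <- reps[!is.na(reps)]
  # allele count tables per locus per representative colony
  counts <- lapply(loci, function(loc) {
    calls <- locus_calls(table, loc)[reps, , drop = FALSE]
    rownames(calls) <- names(reps)
    calls
  })
  names(counts) <- loci
  freqs_excluding <- function(excl) {
    out <- lapply(loci, function(loc) {
      calls <- counts[[loc]]
      keep <- setdiff(rownames(calls), excl)
      a <- c(calls[keep, , drop = FALSE])
      a <- a[a != 0]
      if (length(a) == 0) return(NULL)
      tab <- base::table(a)
      stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    })
    names(out) <- loci
    out
  }
  list(colonies = names(reps), freqs_excluding = freqs_excluding)
}

# dyads for one colony as a list of list(x = 2xL matrix, y = 2xL matrix)
colony_dyads <- function(sub, loci, class, pedigree = NULL) {
  widx <- which(sub$caste == "worker" & sub$ploidy == 2L)
  qidx <- which(sub$caste %in% c("queen", "dealate_queen"))
  fidx <- which(sub$caste == "alate_female" & sub$ploidy == 2L)
  queen_m <- if (length(qidx) >= 1) {
    geno_matrix(sub, qidx[1], loci)
  } else if (!is.null(pedigree)) pedigree$queen else NULL

  pair_up <- function(mats_a, mats_b = NULL) {
    out <- list()
    if (is.null(mats_b)) {
      if (length(mats_a) < 2) return(out)
      for (i in seq_len(length(mats_a) - 1)) {
        for (j in (i + 1):length(mats_a)) {
          out[[length(out) + 1]] <- list(x = mats_a[[i]], y = mats_a[[j]])
        }
      }
    } else {
      for (i in seq_along(mats_a)) for (j in seq_along(mats_b)) {
        out[[length(out) + 1]] <- list(x = mats_a[[i]], y = mats_b[[j]])
      }
    }
    out
  }

  switch(class,
    worker_worker = pair_up(lapply(widx, geno_matrix, table = sub,
                                   loci = loci)),
    queen_worker = {
      if (is.null(queen_m)) return(list())
      pair_up(list(queen_m), lapply(widx, geno_matrix, table = sub,
                                    loci = loci))
    },
    queen_alate = {
      if (is.null(queen_m) || length(fidx) == 0) return(list())
      pair_up(list(queen_m), lapply(fidx, geno_matrix, table = sub,
                                    loci = loci))
    },
    mate_mate = {
      if (is.null(pedigree) || is.null(pedigree$patrilines$fathers) ||
          nrow(pedigree$patrilines$fathers) < 2) return(list())
      f <- pedigree$patrilines$fathers
      mats <- lapply(seq_len(nrow(f)), function(i) {
        m <- rbind(f[i, ], f[i, ])
        colnames(m) <- colnames(f)
        m
      })
      pair_up(mats)
    },
    stop("unknown dyad class: ", class))
}

#' Estimate Queller-Goodnight relatedness for a dyad class
#'
#' @param table a [genotype_table] covering >= 2 colonies.
#' @param class one of `"worker_worker"`, `"queen_worker"`, `"queen_alate"`,
#'   `"mate_mate"`. The mate-mate class correlates inferred father haploid
#'   genotypes (single alleles counted as both gene copies) and requires
#'   `pedigrees`.
#' @param pedigrees optional named list (colony -> [colony_pedigree] result)
#'   supplying reconstructed queens and father haplotypes.
#' @param min_workers colonies with fewer genotyped workers are skipped
#'   (default 8, the usual field-survey inclusion threshold).
#' @param seed seed for the one-individual-per-colony reference sample.
#' @return list of class `relatedness_estimate`: `r`, `se` (jackknife over
#'   colonies), `n_colonies`, `per_colony` (named vector) and `status`.
#' @export
qg_relatedness <- function(table, class = "worker_worker", pedigrees = NULL,
                           min_workers = 8L, seed = 1L) {
  loci <- locus_names(table)
  ref <- reference_frequencies(table, seed = seed)
  colonies <- unique(table$colony)
  per_num <- per_den <- stats::setNames(numeric(0), character(0))
  for (cl in colonies) {
    sub <- table[table$colony == cl, , drop = FALSE]
    if (sum(sub$caste == "worker" & sub$ploidy == 2L) < min_workers) next
    dy <- colony_dyads(sub, loci, class, pedigree = pedigrees[[cl]])
    if (length(dy) == 0) next
    freqs <- ref$freqs_excluding(cl)
    num <- den <- 0
    for (d in dy) {
      for (j in seq_along(loci)) {
        x <- d$x[, j]; y <- d$y[, j]
        if (any(x == 0) || any(y == 0) || any(is.na(x)) || any(is.na(y))) next
        p <- freqs[[j]]
        if (is.null(p)) next
        t <- qg_terms(x, y, p)
        num <- num + t["num"]; den <- den + t["den"]
      }
    }
    if (den != 0) {
      per_num[cl] <- num; per_den[cl] <- den
    }
  }
  g <- length(per_num)
  if (g < 2) {
    return(structure(list(r = NA_real_, se = NA_real_, n_colonies = g,
                          per_colony = per_num / per_den,
                          status = "undefined: fewer than 2 colonies"),
                     class = "relatedness_estimate"))
  }
  r_c <- per_num / per_den
  r_hat <- mean(r_c)
  r_jack <- vapply(seq_len(g), function(j) mean(r_c[-j]), 1)
  se <- sqrt((g - 1) / g * sum((r_jack - mean(r_jack))^2))
  structure(list(r = r_hat, se = se, n_colonies = g, per_colony = r_c,
                 status = "ok"),
            class = "relatedness_estimate")
}

#' @export
print.relatedness_estimate <- function(x, ...) {
  cat(sprintf("Queller-Goodnight relatedness: r = %.3f +/- %.3f (jackknife SE, %d colonies)\n",
              x$r, x$se, x$n_colonies))
  invisible(x)
}
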