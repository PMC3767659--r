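#' Pedigree inference for monogynous, polyandrous colonies
#'
#' Queen reconstruction, matriline and patriline assignment, mating-frequency
#' estimation and male/female parentage classification, all from codominant
#' multilocus genotypes of colony members.
#'
#' @name sociogenetics
NULL

# --- genotype helpers -------------------------------------------------------

# queen genotype as a 2 x L integer matrix (colnames = loci); accepts a
# genotype_table row index or a ready-made matrix
as_queen_matrix <- function(queen, loci = NULL) {
  if (is.matrix(queen)) {
    if (nrow(queen) != 2) stop("queen genotype must be a 2 x L matrix")
    return(queen)
  }
  stop("queen must be a 2 x L matrix of allele sizes")
}

queen_from_table <- function(table, id) {
  i <- match(id, table$id)
  if (is.na(i)) stop("no individual with id ", id)
  loci <- locus_names(table)
  m <- vapply(loci, function(loc) locus_calls(table, loc)[i, ], integer(2))
  m
}

shares_queen_allele <- function(alleles, qpair) {
  any(alleles %in% qpair)
}

# per-locus paternal candidate allele set for one diploid offspring given the
# queen pair; NULL = untyped locus (no constraint); integer(0) = Mendelian
# violation (no queen allele present)
paternal_candidates <- function(alleles, qpair) {
  if (is.null(alleles)) return(NULL)
  in_q <- alleles %in% qpair
  if (!any(in_q)) return(integer(0))
  if (all(in_q)) return(sort(unique(alleles)))
  sort(unique(alleles[!in_q]))
}

# --- queen reconstruction ---------------------------------------------------

#' Reconstruct the queen genotype from worker genotypes
#'
#' Under strict monogyny every worker carries at least one maternal allele at
#' every typed locus. When the queen was genotyped her genotype is verified
#' against this constraint. Otherwise candidate queen allele pairs are
#' enumerated per locus from the alleles observed in workers, and the
#' combination across loci that minimises the implied number of fathers
#' (`M_p`) is selected; among co-optimal solutions the lexicographically
#' smallest per-locus allele pairs win.
#'
#' @param workers a [genotype_table] subset of >= 2 diploid workers from one
#'   colony.
#' @param observed_queen optional 2 x L queen genotype matrix (colnames =
#'   locus names) to verify instead of reconstructing.
#' @param freqs optional population allele frequencies used to rank
#'   co-optimal queens: a list per locus of named numeric vectors
#'   (names = allele sizes). Defaults to empirical worker-pool frequencies,
#'   which cannot break symmetric homozygote/homozygote ambiguities.
#' @param max_combos cap on the number of cross-locus candidate combinations
#'   scored exactly; beyond it the result carries status "not_solved".
#' @return list with `queen` (2 x L matrix), `m_p`, `ambiguous` (TRUE when
#'   several co-optimal queen genotypes exist), `candidates` (all co-optimal
#'   queen matrices) and `status` ("ok" or "not_solved").
#' @export
reconstruct_queen <- function(workers, observed_queen = NULL, freqs = NULL,
                              max_combos = 20000L) {
  workers <- diploid_subset(workers)
  if (nrow(workers) < 2) stop("need >= 2 diploid workers")
  loci <- locus_names(workers)

  if (!is.null(observed_queen)) {
    q <- as_queen_matrix(observed_queen)
    for (loc in loci) {
      for (i in seq_len(nrow(workers))) {
        a <- indiv_alleles(workers, i, loc)
        if (!is.null(a) && !shares_queen_allele(a, q[, loc])) {
          stop("monogyny violated at locus ", loc, ": worker ",
               workers$id[i], " shares no allele with the queen")
        }
      }
    }
    pat <- infer_patrilines(workers, q)
    return(list(queen = q, m_p = pat$m_p, ambiguous = FALSE,
                candidates = list(q), status = "ok"))
  }

  cand_by_locus <- lapply(loci, function(loc) {
    calls <- locus_calls(workers, loc)
    typed <- calls[, 1] != 0
    if (!any(typed)) {
      return(matrix(c(0L, 0L), nrow = 2)) # untyped locus: unknown queen pair
    }
    alleles <- sort(unique(c(calls[typed, ])))
    pairs <- if (length(alleles) == 1) {
      matrix(rep(alleles, 2), nrow = 2) # monomorphic: homozygous queen
    } else {
      cbind(utils::combn(alleles, 2),
            rbind(alleles, alleles)) # heterozygous + homozygous pairs
    }
    ok <- apply(pairs, 2, function(q) {
      all(apply(calls[typed, , drop = FALSE], 1, function(a) any(a %in% q)))
    })
    pairs <- pairs[, ok, drop = FALSE]
    if (ncol(pairs) == 0) {
      stop("monogyny violated at locus ", loc,
           ": no queen genotype is compatible with all workers")
    }
    # deterministic ordering: lexicographic on the sorted pair
    pairs <- apply(pairs, 2, sort)
    ord <- order(pairs[1, ], pairs[2, ])
    pairs[, ord, drop = FALSE]
  })
  names(cand_by_locus) <- loci

  n_combos <- prod(vapply(cand_by_locus, ncol, 1))
  if (n_combos > max_combos) {
    return(list(queen = NULL, m_p = NA_integer_, ambiguous = NA,
                candidates = list(), status = "not_solved"))
  }

  # allele frequencies for scoring: population-level when supplied,
  # else empirical from the worker pool
  emp_freq <- lapply(seq_along(loci), function(j) {
    if (!is.null(freqs) && !is.null(freqs[[j]]) &&
        !is.null(names(freqs[[j]]))) {
      return(freqs[[j]])
    }
    calls <- locus_calls(workers, loci[j])
    a <- c(calls); a <- a[a != 0]
    if (length(a) == 0) return(NULL)
    base::table(a) / length(a)
  })
  names(emp_freq) <- loci
  logf <- function(loc, allele) {
    f <- emp_freq[[loc]]
    v <- f[as.character(allele)]
    log(max(if (is.na(v)) 0 else as.numeric(v), 1e-12))
  }

  # pedigree log-likelihood of a candidate queen + its minimal patriline
  # partition: queen genotype at Hardy-Weinberg, one frequency draw per
  # father (not per worker), and a binomial maternal-transmission term for
  # heterozygous queen loci; used to rank co-optimal queens
  pedigree_score <- function(q, pat) {
    total <- 0
    for (j in seq_along(loci)) {
      loc <- loci[j]
      qp <- q[, j]
      if (all(qp == 0) || is.null(emp_freq[[loc]])) next
      het <- qp[1] != qp[2]
      total <- total + logf(loc, qp[1]) + logf(loc, qp[2]) +
        if (het) log(2) else 0
      for (fs in pat$father_sets) {
        s <- fs[[j]]
        if (is.null(s)) next
        total <- total + max(vapply(s, function(a) logf(loc, a), 1))
      }
      if (het) {
        # each typed worker draws its maternal allele with probability 1/2
        # under a heterozygous queen (probability 1 under a homozygote)
        calls <- locus_calls(workers, loc)
        n_typed <- sum(calls[, 1] != 0)
        total <- total + n_typed * log(0.5)
      }
    }
    total
  }

  idx_grid <- do.call(expand.grid,
                      lapply(cand_by_locus, function(p) seq_len(ncol(p))))
  best_mp <- Inf; best <- list(); best_scores <- numeric(0)
  for (r in seq_len(nrow(idx_grid))) {
    q <- vapply(seq_along(loci), function(j) {
      cand_by_locus[[j]][, idx_grid[r, j]]
    }, integer(2))
    colnames(q) <- loci
    pat <- infer_patrilines(workers, q, best_bound = best_mp + 1)
    mp <- pat$m_p
    if (is.na(mp) || mp > best_mp) next
    sc <- pedigree_score(q, pat)
    if (mp < best_mp) {
      best_mp <- mp; best <- list(q); best_scores <- sc
    } else {
      best <- c(best, list(q)); best_scores <- c(best_scores, sc)
    }
  }
  # rank co-optimal queens by likelihood score, then lexicographically
  keys <- vapply(best, function(q) paste(sprintf("%06d", c(q)),
                                         collapse = ""), "")
  ord <- order(-best_scores, keys)
  sel <- best[[ord[1]]]
  list(queen = sel, m_p = as.integer(best_mp),
       ambiguous = length(best) > 1, candidates = best[ord],
       status = "ok")
}

# --- matrilines -------------------------------------------------------------

#' Assign individuals to matrilines relative to a queen
#'
#' An individual belongs to a different matriline when it shares no allele
#' with the queen at one or more typed loci; loci with missing data are
#' skipped; individuals untyped everywhere are flagged uninformative.
#'
#' @param offspring a [genotype_table] subset of diploid offspring.
#' @param queen 2 x L queen genotype matrix.
#' @return data.frame with `id` and `matriline` in
#'   `{"same", "different", "uninformative"}`.
#' @export
assign_matrilines <- function(offspring, queen) {
  q <- as_queen_matrix(queen)
  loci <- intersect(locus_names(offspring), colnames(q))
  out <- vapply(seq_len(nrow(offspring)), function(i) {
    typed <- FALSE
    for (loc in loci) {
      a <- indiv_alleles(offspring, i, loc)
      if (is.null(a)) next
      typed <- TRUE
      if (!shares_queen_allele(a, q[, loc])) return("different")
    }
    if (typed) "same" else "uninformative"
  }, "")
  data.frame(id = offspring$id, matriline = out)
}

# --- patrilines -------------------------------------------------------------

#' Partition workers into patrilines and count fathers
#'
#' At each locus a worker's paternal allele is the allele not attributable to
#' the queen; when the worker carries only queen alleles the paternal allele
#' is ambiguous within the worker's own pair. The function finds the minimum
#' number of haploid father genotypes that jointly explain all workers
#' (exact depth-first search with admissible pruning), resolving ambiguity
#' inside the minimisation.
#'
#' @param workers a [genotype_table] subset of diploid workers.
#' @param queen 2 x L queen genotype matrix.
#' @param best_bound prune branches reaching this many fathers (internal).
#' @return list with `m_p` (minimum father count; NA when pruned by
#'   `best_bound`), `assignment` (father index per worker),
#'   `contributions` (workers per father), `fathers` (father haploid
#'   genotypes, one row per father; NA where every locus assignment is
#'   ambiguous or untyped) and `father_sets` (per-father per-locus candidate
#'   allele sets).
#' @export
infer_patrilines <- function(workers, queen, best_bound = Inf) {
  q <- as_queen_matrix(queen)
  workers <- diploid_subset(workers)
  loci <- colnames(q)
  n <- nrow(workers)
  if (n == 0) stop("no diploid workers")

  cand <- lapply(seq_len(n), function(i) {
    lapply(loci, function(loc) {
      a <- indiv_alleles(workers, i, loc)
      p <- paternal_candidates(a, q[, loc])
      if (!is.null(p) && length(p) == 0) {
        stop("worker ", workers$id[i], " is not Mendel-consistent with the ",
             "queen at locus ", loc)
      }
      p
    })
  })
  L <- length(loci)

  # workers with identical candidate profiles always fit in one patriline of
  # some optimal solution, so collapse them before searching
  sig <- vapply(cand, function(ci) {
    paste(vapply(ci, function(s) {
      if (is.null(s)) "*" else paste(s, collapse = ",")
    }, ""), collapse = "|")
  }, "")
  usig <- unique(sig)
  u_cand <- cand[match(usig, sig)]
  u_members <- lapply(usig, function(s) which(sig == s))
  m <- length(usig)

  # lower bound: at each locus, count distinct forced (singleton) paternal
  # alleles -- any valid solution needs at least that many fathers
  lb <- max(vapply(seq_len(L), function(j) {
    singles <- unlist(lapply(u_cand, function(ci) {
      if (!is.null(ci[[j]]) && length(ci[[j]]) == 1) ci[[j]] else NULL
    }))
    length(unique(singles))
  }, 1L), 1L)

  # order profiles: most constrained (fewest ambiguous loci) first
  ambig <- vapply(u_cand, function(ci) {
    sum(vapply(ci, function(s) is.null(s) || length(s) > 1, TRUE))
  }, 1L)
  ord <- order(ambig, seq_len(m))

  intersect_sets <- function(g, ci) {
    out <- vector("list", L)
    for (j in seq_len(L)) {
      a <- g[[j]]; b <- ci[[j]]
      if (is.null(a)) out[[j]] <- b
      else if (is.null(b)) out[[j]] <- a
      else {
        v <- intersect(a, b)
        if (length(v) == 0) return(NULL)
        out[[j]] <- v
      }
    }
    out
  }

  # iterative deepening: the first solution found at the smallest feasible
  # group count is the canonical (deterministic) partition
  best <- NULL
  k_max <- min(m, best_bound - 1)
  for (k_limit in lb:max(lb, k_max)) {
    if (k_limit > k_max) break
    solve_at <- function(pos, groups, members) {
      if (!is.null(best)) return()
      if (pos > m) { best <<- list(groups = groups, members = members); return() }
      i <- ord[pos]
      for (g in seq_along(groups)) {
        merged <- intersect_sets(groups[[g]], u_cand[[i]])
        if (!is.null(merged)) {
          g2 <- groups; g2[[g]] <- merged
          m2 <- members; m2[[g]] <- c(m2[[g]], i)
          solve_at(pos + 1, g2, m2)
          if (!is.null(best)) return()
        }
      }
      if (length(groups) < k_limit) {
        solve_at(pos + 1, c(groups, list(u_cand[[i]])), c(members, list(i)))
      }
    }
    solve_at(2, list(u_cand[[ord[1]]]), list(ord[1]))
    if (!is.null(best)) break
  }

  if (is.null(best)) {
    return(list(m_p = NA_integer_, assignment = NULL, contributions = NULL,
                fathers = NULL, father_sets = NULL))
  }
  # expand profiles back to worker indices; deterministic father order by
  # smallest original worker index
  members_full <- lapply(best$members, function(gr) {
    sort(unlist(u_members[gr]))
  })
  first_member <- vapply(members_full, min, 1L)
  ford <- order(first_member)
  groups <- best$groups[ford]; members <- members_full[ford]

  assignment <- integer(n)
  for (g in seq_along(members)) assignment[members[[g]]] <- g
  fvals <- vapply(groups, function(gr) {
    vapply(gr, function(s) {
      if (is.null(s)) NA_integer_
      else if (length(s) == 1) s
      else NA_integer_ # ambiguous within queen alleles
    }, integer(1))
  }, integer(L))
  fathers <- t(matrix(fvals, nrow = L)) # robust to L == 1 (vector return)
  dimnames(fathers) <- list(NULL, loci)
  list(m_p = length(groups), assignment = assignment,
       contributions = as.integer(table(factor(assignment,
                                               levels = seq_along(groups)))),
       fathers = fathers, father_sets = groups)
}

# --- mating-frequency estimators -------------------------------------------

#' Effective paternity (skew-corrected mating frequency)
#'
#' Sample-size-corrected effective number of patrilines
#' \deqn{M_{e,p} = \frac{(n-1)^2}{\sum_i p_i^2 (n+1)(n-2) + 3 - n}}
#' where `n` is the number of offspring scored and `p_i` the proportional
#' contribution of father `i`. Equals the absolute mating number when
#' contributions are even and `n` is large; may exceed the observed father
#' count for small `n` (bias correction).
#'
#' @param contributions per-father offspring counts (or proportions when `n`
#'   is supplied).
#' @param n total offspring; defaults to `sum(contributions)`.
#' @return scalar effective paternity.
#' @export
effective_paternity <- function(contributions, n = NULL) {
  if (length(contributions) == 0) stop("empty contribution vector")
  if (is.null(n)) n <- sum(contributions)
  if (n < 3) stop("effective paternity is undefined for n < 3")
  p <- contributions / sum(contributions)
  if (any(p < 0)) stop("contributions must be non-negative")
  (n - 1)^2 / (sum(p^2) * (n + 1) * (n - 2) + 3 - n)
}

#' Probability that two mates carry identical multilocus haplotypes
#'
#' The non-detection error of polyandry: the chance that two independent
#' haploid males share alleles at every locus,
#' \deqn{P = \prod_j \sum_i f_{ij}^2}
#' with `f_ij` the population frequency of allele `i` at locus `j`.
#'
#' @param freqs list of per-locus allele frequency vectors (each summing
#'   to 1), or a list of [locus_spec] objects.
#' @return probability.
#' @export
nondetect_two_males <- function(freqs) {
  fl <- lapply(freqs, function(f) {
    if (inherits(f, "locus_spec")) f$frequencies else f
  })
  for (f in fl) {
    if (abs(sum(f) - 1) > 1e-6) stop("frequencies must sum to 1 per locus")
  }
  prod(vapply(fl, function(f) sum(f^2), 1))
}

#' Probability that a worker's son shows only queen alleles
#'
#' A worker of patriline `i` is heterozygous queen/non-queen at her `l_i`
#' informative loci; her haploid son inherits the queen allele at each with
#' probability 1/2, so the chance he mimics a queen's son is
#' \deqn{P = \sum_i p_i (1/2)^{l_i}.}
#'
#' @param p per-patriline proportional contributions (normalised internally).
#' @param l per-patriline counts of informative loci (father allele absent
#'   from the queen genotype).
#' @return probability.
#' @export
nondetect_worker_son <- function(p, l) {
  if (length(p) != length(l)) stop("p and l differ in length")
  if (any(l < 0) || any(l != round(l))) stop("l must be non-negative integers")
  p <- p / sum(p)
  sum(p * 0.5^l)
}

# informative loci per patriline: father allele known and non-queen
informative_loci <- function(fathers, queen) {
  q <- as_queen_matrix(queen)
  loci <- colnames(q)
  vapply(seq_len(nrow(fathers)), function(i) {
    sum(vapply(loci, function(loc) {
      a <- fathers[i, loc]
      !is.na(a) && !(a %in% q[, loc])
    }, TRUE))
  }, 1L)
}

# --- parentage classification ----------------------------------------------

#' Classify males as queen's sons or workers' sons
#'
#' A haploid male carrying a non-queen allele at any typed locus is a
#' worker's son. As a group check, putative queen sons must not display more
#' than two alleles at a single locus (a queen has only two to give).
#'
#' @param males a [genotype_table] subset of haploid males.
#' @param queen 2 x L queen genotype matrix.
#' @return list with `classes` (data.frame id, class) and `group_ok`
#'   (per-locus logical: putative queen sons jointly show <= 2 alleles).
#' @export
classify_males <- function(males, queen) {
  q <- as_queen_matrix(queen)
  if (any(males$ploidy != 1L)) stop("males must be haploid")
  loci <- intersect(locus_names(males), colnames(q))
  cls <- vapply(seq_len(nrow(males)), function(i) {
    for (loc in loci) {
      if (all(q[, loc] == 0)) next # queen untyped: only the group check applies
      a <- indiv_alleles(males, i, loc)
      if (!is.null(a) && !a %in% q[, loc]) return("worker_son")
    }
    "queen_son"
  }, "")
  qs <- males[cls == "queen_son", , drop = FALSE]
  group_ok <- vapply(loci, function(loc) {
    a <- locus_calls(qs, loc)[, 1]
    length(unique(a[a != 0])) <= 2
  }, TRUE)
  list(classes = data.frame(id = males$id, class = cls),
       group_ok = group_ok)
}

#' Screen alate females for thelytokous (clonal) production
#'
#' A female bearing at least one non-queen allele was produced sexually; a
#' female identical to the queen at all typed loci is only
#' "thelytoky-compatible", since a sexually produced daughter can mimic a
#' clone when her father's alleles coincide with the queen's. The matching
#' non-detection probability (from the colony's patriline structure) is
#' attached when available.
#'
#' @param females a [genotype_table] subset of diploid alate females.
#' @param queen 2 x L queen genotype matrix.
#' @param patrilines optional result of [infer_patrilines] on the colony's
#'   workers, used to attach the non-detection probability.
#' @return data.frame with `id`, `class` in `{"sexual",
#'   "thelytoky_compatible"}` and `p_nondetect`.
#' @export
thelytoky_check <- function(females, queen, patrilines = NULL) {
  q <- as_queen_matrix(queen)
  loci <- intersect(locus_names(females), colnames(q))
  cls <- vapply(seq_len(nrow(females)), function(i) {
    for (loc in loci) {
      a <- indiv_alleles(females, i, loc)
      if (!is.null(a) && any(!a %in% q[, loc])) return("sexual")
    }
    "thelytoky_compatible"
  }, "")
  p_nd <- NA_real_
  if (!is.null(patrilines) && !is.null(patrilines$fathers)) {
    l <- informative_loci(patrilines$fathers, q)
    p_nd <- nondetect_worker_son(patrilines$contributions, l)
  }
  data.frame(id = females$id, class = cls,
             p_nondetect = ifelse(cls == "thelytoky_compatible", p_nd, 0))
}

# --- colony-level wrapper ---------------------------------------------------

#' Full pedigree analysis of one colony
#'
#' Reconstructs (or verifies) the queen, partitions workers into patrilines,
#' estimates absolute and effective mating frequency with both non-detection
#' probabilities, and classifies males and alate females.
#'
#' @param table a [genotype_table].
#' @param colony colony id to analyse.
#' @param panel_freqs optional list of population allele frequency vectors
#'   (per locus) for the two-males non-detection probability.
#' @param min_workers minimum genotyped workers required (default 8).
#' @return list of class `pedigree_result`.
#' @export
colony_pedigree <- function(table, colony, panel_freqs = NULL,
                            min_workers = 8L) {
  sub <- table[table$colony == colony, , drop = FALSE]
  workers <- sub[sub$caste == "worker" & sub$ploidy == 2L, , drop = FALSE]
  if (nrow(workers) < min_workers) {
    stop("colony ", colony, " has ", nrow(workers),
         " genotyped workers (< ", min_workers, ")")
  }
  qrow <- sub[sub$caste %in% c("queen", "dealate_queen"), , drop = FALSE]
  observed <- nrow(qrow) >= 1
  obs_q <- if (observed) queen_from_table(sub, qrow$id[1]) else NULL
  rec <- reconstruct_queen(workers, observed_queen = obs_q,
                           freqs = panel_freqs)
  queen <- rec$queen
  pat <- infer_patrilines(workers, queen)
  n <- nrow(workers)
  me_p <- if (n >= 3) effective_paternity(pat$contributions, n) else NA_real_
  l <- informative_loci(pat$fathers, queen)
  males <- sub[sub$caste == "male", , drop = FALSE]
  females <- sub[sub$caste == "alate_female", , drop = FALSE]
  structure(list(
    colony = colony,
    queen = queen,
    queen_observed = observed,
    queen_ambiguous = rec$ambiguous,
    patrilines = pat,
    m_p = pat$m_p,
    m_e_p = me_p,
    p_nondetect_two_males = if (is.null(panel_freqs)) NA_real_
                            else nondetect_two_males(panel_freqs),
    p_nondetect_worker_son = nondetect_worker_son(pat$contributions, l),
    male_classes = if (nrow(males) > 0) classify_males(males, queen)
                   else NULL,
    female_classes = if (nrow(females) > 0)
      thelytoky_check(females, queen, pat) else NULL
  ), class = "pedigree_result")
}
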