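# shared fixture builders and independent oracles

# compact genotype table builder: geno is a list of rows, each
# list(id, colony, caste, ploidy, alleles = vector of length 2*L)
build_table <- function(rows, loci) {
  df <- do.call(rbind, lapply(rows, function(r) {
    g <- as.list(r$alleles)
    names(g) <- paste0(rep(loci, each = 2), c(".1", ".2"))
    as.data.frame(c(list(id = r$id, colony = r$colony, caste = r$caste,
                         ploidy = r$ploidy), g))
  }))
  genotype_table(df)
}

# one-locus diploid worker table from a vector of "a/b" strings
worker_table <- function(genos, colony = "C1", locus = "L1") {
  rows <- lapply(seq_along(genos), function(i) {
    ab <- as.integer(strsplit(genos[i], "/")[[1]])
    list(id = paste0("w", i), colony = colony, caste = "worker",
         ploidy = 2L, alleles = ab)
  })
  build_table(rows, locus)
}

# bind several simulated colonies into one genotype table
sim_colony_set <- function(panel, n_colonies, n_workers, contributions_fun,
                           base_seed = 1L, ...) {
  set.seed(base_seed)
  seeds <- sample.int(2^30, n_colonies)
  tabs <- lapply(seq_len(n_colonies), function(i) {
    contr <- contributions_fun(i)
    simulate_colony(panel, colony_spec(n_workers, contr, ...),
                    seed = seeds[i],
                    colony_id = sprintf("C%03d", i))$genotypes
  })
  genotype_table(do.call(rbind, tabs))
}

# --- independent oracles ----------------------------------------------------

# all set partitions of 1..n (Bell-number enumeration; n <= 8)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (g in seq_along(p)) {
      q <- p
      q[[g]] <- c(q[[g]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# brute-force minimum father count: candidate sets per worker per locus
# (NULL = unconstrained), a partition is feasible iff every block has a
# non-empty per-locus intersection
brute_force_mp <- function(cand) {
  n <- length(cand)
  L <- length(cand[[1]])
  feasible <- function(block) {
    for (j in seq_len(L)) {
      sets <- Filter(Negate(is.null), lapply(cand[block], `[[`, j))
      if (length(sets) == 0) next
      if (length(Reduce(intersect, sets)) == 0) return(FALSE)
    }
    TRUE
  }
  best <- n
  for (p in all_partitions(n)) {
    if (length(p) >= best) next
    if (all(vapply(p, feasible, TRUE))) best <- length(p)
  }
  best
}

# paternal candidate sets for random instances, mirroring the definition in
# the package but computed directly from genotypes here
oracle_candidates <- function(workers_mat, queen) {
  # workers_mat: n x (2L) matrix; queen: 2 x L
  n <- nrow(workers_mat); L <- ncol(queen)
  lapply(seq_len(n), function(i) {
    lapply(seq_len(L), function(j) {
      a <- workers_mat[i, c(2 * j - 1, 2 * j)]
      in_q <- a %in% queen[, j]
      if (all(in_q)) sort(unique(a)) else sort(unique(a[!in_q]))
    })
  })
}

# minimal spanning tree total weight (Prim), independent of the package MSN
prim_mst_weight <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  while (sum(in_tree) < n) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    total <- total + min(sub)
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    in_tree[j] <- TRUE
  }
  total
}

# random DNA haplotype matrix over a few segregating sites
random_haps <- function(n_hap, n_sites, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_hap * n_sites, replace = TRUE),
              nrow = n_hap)
  rownames(m) <- paste0("H", seq_len(n_hap))
  m[!duplicated(apply(m, 1, paste, collapse = "")), , drop = FALSE]
}
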