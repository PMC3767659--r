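#' Synthetic locus panels, colonies, plots and mitochondrial transects
#'
#' The generator emulates the sociogenetic structure the downstream analyses
#' assume: strictly monogynous colonies headed by a single once-genotyped
#' queen mated with 1-5 haploid males contributing unequally to the brood;
#' microsatellite panels with 4-13 alleles per locus; nests mapped in a square
#' plot; and mitochondrial haplotypes diverging between two regional groups
#' along a linear transect.
#'
#' @name synthetic
NULL

#' Locus specification
#'
#' @param name locus name.
#' @param alleles integer allele sizes (bp); distinct.
#' @param frequencies probability vector, same length as `alleles`.
#' @return object of class `locus_spec`.
#' @export
locus_spec <- function(name, alleles, frequencies) {
  alleles <- as.integer(alleles)
  if (anyDuplicated(alleles)) stop("allele sizes must be distinct")
  if (length(alleles) != length(frequencies)) {
    stop("alleles and frequencies differ in length")
  }
  if (abs(sum(frequencies) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (any(frequencies < 0)) stop("frequencies must be non-negative")
  structure(list(name = name, alleles = alleles,
                 frequencies = as.numeric(frequencies)),
            class = "locus_spec")
}

#' Draw a random microsatellite locus panel
#'
#' Allele counts are uniform on `allele_count_range`; allele frequencies are
#' drawn from a symmetric Dirichlet with concentration `concentration`
#' (default 1, uninformative). Allele sizes are distinct even integers in a
#' microsatellite-like bp range; they are labels only.
#'
#' @param n_loci number of loci (>= 1).
#' @param allele_count_range integer pair, within [2, 30].
#' @param seed integer seed.
#' @param concentration Dirichlet concentration parameter.
#' @return list of [locus_spec] objects.
#' @export
make_locus_panel <- function(n_loci, allele_count_range = c(4, 13),
                             seed = 1L, concentration = 1) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  r <- as.integer(allele_count_range)
  if (length(r) != 2 || r[1] < 2 || r[2] > 30 || r[1] > r[2]) {
    stop("allele_count_range must lie within [2, 30] with lo <= hi")
  }
  set.seed(seed)
  lapply(seq_len(n_loci), function(j) {
    k <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
    start <- sample(seq(90L, 230L, by = 2L), 1)
    alleles <- start + 2L * (seq_len(k) - 1L)
    g <- rgamma(k, shape = concentration)
    locus_spec(sprintf("L%02d", j), alleles, g / sum(g))
  })
}

#' Colony specification
#'
#' `contributions` are integer offspring counts per father and must sum to
#' `n_workers + n_alate_females` (workers and alate gynes are both sexually
#' produced). Worker-derived males are only allowed in queenless colonies,
#' where orphaned workers lay haploid eggs by arrhenotoky.
#'
#' @param n_workers genotyped workers.
#' @param contributions per-father offspring counts; its length is the true
#'   mating number.
#' @param queenless flag; queenless colonies contribute no observed queen row.
#' @param n_queen_son_males,n_worker_son_males,n_alate_females counts.
#' @param n_thelytokous_females diploid females copied clonally from the
#'   queen genotype (0 in the default, sexual-reproduction-only world).
#' @return object of class `colony_spec`.
#' @export
colony_spec <- function(n_workers, contributions, queenless = FALSE,
                        n_queen_son_males = 0L, n_worker_son_males = 0L,
                        n_alate_females = 0L, n_thelytokous_females = 0L) {
  contributions <- as.integer(contributions)
  if (length(contributions) < 1 || any(contributions < 0)) {
    stop("contributions must be non-negative counts")
  }
  if (sum(contributions) != n_workers + n_alate_females) {
    stop("contributions must sum to n_workers + n_alate_females (got ",
         sum(contributions), " vs ", n_workers + n_alate_females, ")")
  }
  if (n_worker_son_males > 0 && !queenless) {
    stop("worker-son males are only generated in queenless colonies")
  }
  structure(list(n_workers = as.integer(n_workers),
                 n_fathers = length(contributions),
                 contributions = contributions,
                 queenless = isTRUE(queenless),
                 n_queen_son_males = as.integer(n_queen_son_males),
                 n_worker_son_males = as.integer(n_worker_son_males),
                 n_alate_females = as.integer(n_alate_females),
                 n_thelytokous_females = as.integer(n_thelytokous_females)),
            class = "colony_spec")
}

draw_allele <- function(ls, n = 1) sample(ls$alleles, n, replace = TRUE,
                                          prob = ls$frequencies)

sort2 <- function(a) if (a[1] <= a[2]) a else a[c(2, 1)]

#' Simulate one monogynous colony
#'
#' The queen is a random diploid draw from the panel frequencies; each father
#' is an independent haploid draw. Every worker and alate female receives one
#' uniformly chosen queen allele plus her father's allele at each locus;
#' queen-son males receive one queen allele; worker-son males receive one
#' allele of a uniformly chosen worker; thelytokous females copy the queen.
#'
#' @param panel list of [locus_spec].
#' @param spec [colony_spec].
#' @param seed integer seed.
#' @param colony_id colony label.
#' @param mask_rate per-genotype missing-data masking probability (default 0).
#' @return list of class `colony` with `$genotypes` (a [genotype_table]
#'   without the hidden truth) and `$truth` (queen genotype, father
#'   haplotypes, per-offspring father index).
#' @export
simulate_colony <- function(panel, spec, seed = 1L, colony_id = "C1",
                            mask_rate = 0) {
  stopifnot(inherits(spec, "colony_spec"), length(panel) >= 1)
  set.seed(seed)
  L <- length(panel)
  loci <- vapply(panel, `[[`, "", "name")

  queen <- vapply(panel, function(ls) sort2(draw_allele(ls, 2)), integer(2))
  fathers <- vapply(panel, function(ls) draw_allele(ls, spec$n_fathers),
                    integer(spec$n_fathers))
  fathers <- matrix(fathers, nrow = spec$n_fathers, ncol = L,
                    dimnames = list(NULL, loci))

  father_of <- rep(seq_len(spec$n_fathers), spec$contributions)
  n_off <- length(father_of)

  daughter <- function(f) {
    vapply(seq_len(L), function(j) {
      sort2(c(queen[sample(1:2, 1), j], fathers[f, j]))
    }, integer(2))
  }

  rows <- list()
  add_row <- function(id, caste, ploidy, g) {
    # g: 2 x L matrix (diploid) or length-L vector (haploid)
    if (ploidy == 1L) g <- rbind(g, 0L)
    r <- as.list(c(g))
    names(r) <- paste0(rep(loci, each = 2), c(".1", ".2"))
    rows[[length(rows) + 1L]] <<- c(list(id = id, colony = colony_id,
                                         caste = caste, ploidy = ploidy), r)
  }

  if (!spec$queenless) {
    add_row(paste0(colony_id, "_Q"), "queen", 2L, queen)
  }
  worker_g <- vector("list", spec$n_workers)
  for (i in seq_len(spec$n_workers)) {
    g <- daughter(father_of[i])
    worker_g[[i]] <- g
    add_row(sprintf("%s_W%02d", colony_id, i), "worker", 2L, g)
  }
  for (i in seq_len(spec$n_alate_females)) {
    g <- daughter(father_of[spec$n_workers + i])
    add_row(sprintf("%s_F%02d", colony_id, i), "alate_female", 2L, g)
  }
  for (i in seq_len(spec$n_thelytokous_females)) {
    add_row(sprintf("%s_T%02d", colony_id, i), "alate_female", 2L, queen)
  }
  for (i in seq_len(spec$n_queen_son_males)) {
    g <- vapply(seq_len(L), function(j) queen[sample(1:2, 1), j], integer(1))
    add_row(sprintf("%s_M%02d", colony_id, i), "male", 1L, g)
  }
  for (i in seq_len(spec$n_worker_son_males)) {
    w <- worker_g[[sample(spec$n_workers, 1)]]
    g <- vapply(seq_len(L), function(j) w[sample(1:2, 1), j], integer(1))
    add_row(sprintf("%s_WM%02d", colony_id, i), "male", 1L, g)
  }

  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (mask_rate > 0) {
    for (loc in loci) {
      mask <- runif(nrow(df)) < mask_rate
      df[mask, paste0(loc, ".1")] <- 0L
      df[mask, paste0(loc, ".2")] <- 0L
    }
  }
  dimnames(queen) <- list(NULL, loci)
  structure(list(genotypes = genotype_table(df),
                 truth = list(queen = queen, fathers = fathers,
                              father_of = father_of),
                 spec = spec, id = colony_id),
            class = "colony")
}

#' Plot specification for nest mapping
#' @param side_length plot side (m).
#' @param n_nests number of nests (>= 2).
#' @param placement one of "random" (complete spatial randomness), "grid",
#'   "clustered" (Thomas-style parent/offspring displacement).
#' @param seed integer seed.
#' @param cluster_parents,cluster_sd Thomas-process parameters.
#' @return object of class `plot_spec`.
#' @export
plot_spec <- function(side_length, n_nests, placement = "random", seed = 1L,
                      cluster_parents = 5L, cluster_sd = NULL) {
  if (n_nests < 2) stop("n_nests must be >= 2")
  placement <- match.arg(placement, c("random", "grid", "clustered"))
  structure(list(side_length = side_length, n_nests = as.integer(n_nests),
                 placement = placement, seed = as.integer(seed),
                 cluster_parents = as.integer(cluster_parents),
                 cluster_sd = cluster_sd %||% (side_length / 20)),
            class = "plot_spec")
}

#' Simulate a mapped population of colonies
#'
#' Coordinates follow the requested point process inside the square plot;
#' colony genotypes are independent draws across nests (no spatial
#' autocorrelation, i.e. no population viscosity).
#'
#' @param panel list of [locus_spec].
#' @param plot [plot_spec].
#' @param colony_template [colony_spec] applied to every nest.
#' @param mask_rate missing-data masking rate passed to [simulate_colony].
#' @return list with `$genotypes` (row-bound [genotype_table]), `$coords`
#'   (colony, x, y), `$truth` (per-colony truth records).
#' @export
simulate_plot <- function(panel, plot, colony_template, mask_rate = 0) {
  stopifnot(inherits(plot, "plot_spec"))
  set.seed(plot$seed)
  n <- plot$n_nests
  s <- plot$side_length
  coords <- switch(plot$placement,
    random = cbind(runif(n, 0, s), runif(n, 0, s)),
    grid = {
      k <- ceiling(sqrt(n))
      sp <- s / k
      g <- expand.grid(x = sp / 2 + sp * (0:(k - 1)),
                       y = sp / 2 + sp * (0:(k - 1)))
      as.matrix(g[seq_len(n), ])
    },
    clustered = {
      par_xy <- cbind(runif(plot$cluster_parents, 0, s),
                      runif(plot$cluster_parents, 0, s))
      idx <- sample(plot$cluster_parents, n, replace = TRUE)
      xy <- par_xy[idx, , drop = FALSE] +
        matrix(stats::rnorm(2 * n, 0, plot$cluster_sd), ncol = 2)
      xy[] <- pmin(pmax(xy, 0), s)
      xy
    })
  colony_seeds <- sample.int(.Machine$integer.max, n)
  cols <- lapply(seq_len(n), function(i) {
    simulate_colony(panel, colony_template, seed = colony_seeds[i],
                    colony_id = sprintf("N%03d", i), mask_rate = mask_rate)
  })
  geno <- do.call(rbind, lapply(cols, `[[`, "genotypes"))
  list(genotypes = genotype_table(geno),
       coords = data.frame(colony = sprintf("N%03d", seq_len(n)),
                           x = coords[, 1], y = coords[, 2]),
       truth = lapply(cols, `[[`, "truth"))
}

#' Transect specification for mitochondrial haplotype simulation
#' @param n_sites sampling sites along the transect.
#' @param site_spacing distance between consecutive sites (km).
#' @param n_groups regional groups (contiguous blocks of sites).
#' @param samples_per_site sequences sampled per site.
#' @param mutation_steps_within substitutions separating each haplotype from
#'   its group founder.
#' @param mutation_steps_between substitutions separating group founders.
#' @param seq_length alignment length in bp (default 622).
#' @return object of class `transect_spec`.
#' @export
transect_spec <- function(n_sites, site_spacing = 10, n_groups = 2,
                          samples_per_site = 2, mutation_steps_within = 1,
                          mutation_steps_between = 14, seq_length = 622L) {
  if (seq_length <= 0) stop("seq_length must be positive")
  if (mutation_steps_between < mutation_steps_within) {
    stop("between-group steps must be >= within-group steps")
  }
  structure(list(n_sites = as.integer(n_sites), site_spacing = site_spacing,
                 n_groups = as.integer(n_groups),
                 samples_per_site = as.integer(samples_per_site),
                 mutation_steps_within = as.integer(mutation_steps_within),
                 mutation_steps_between = as.integer(mutation_steps_between),
                 seq_length = as.integer(seq_length)),
            class = "transect_spec")
}

BASES <- c("A", "C", "G", "T")

#' Simulate mitochondrial haplotypes along a two-group transect
#'
#' One random ancestral sequence is mutated into per-group founder
#' haplotypes separated by `mutation_steps_between` substitutions at disjoint
#' sites; each within-group haplotype adds `mutation_steps_within` private
#' substitutions. Each sampling site draws sequences uniformly from its
#' group's haplotype pool, so genetic and geographic distance are positively
#' associated by construction.
#'
#' @param spec [transect_spec].
#' @param seed integer seed.
#' @return list with `$alignment` (a `hap_alignment`), `$site`, `$group`
#'   labels per sequence, `$positions` (site positions, km) and `$geo`
#'   (pairwise geographic distance matrix between sequences, km).
#' @export
simulate_transect_mtdna <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "transect_spec"))
  total_steps <- spec$mutation_steps_between * (spec$n_groups - 1) +
    spec$mutation_steps_within * spec$n_sites
  if (total_steps > spec$seq_length) {
    stop("requested mutation steps exceed sequence length")
  }
  set.seed(seed)
  L <- spec$seq_length
  ancestor <- sample(BASES, L, replace = TRUE)
  free_sites <- sample.int(L) # disjoint mutation sites, consumed in order
  take_sites <- function(k) {
    s <- free_sites[seq_len(k)]
    free_sites <<- free_sites[-seq_len(k)]
    s
  }
  mutate <- function(seq, sites) {
    for (s in sites) seq[s] <- sample(setdiff(BASES, seq[s]), 1)
    seq
  }
  founders <- list(ancestor)
  for (g in seq_len(spec$n_groups - 1)) {
    founders[[g + 1]] <- mutate(ancestor,
                                take_sites(spec$mutation_steps_between))
  }
  group_of_site <- sort(rep_len(seq_len(spec$n_groups), spec$n_sites))
  hap_by_site <- lapply(seq_len(spec$n_sites), function(i) {
    f <- founders[[group_of_site[i]]]
    if (spec$mutation_steps_within == 0) f
    else mutate(f, take_sites(spec$mutation_steps_within))
  })
  ids <- character(0); seqs <- list(); site <- integer(0)
  for (i in seq_len(spec$n_sites)) {
    for (k in seq_len(spec$samples_per_site)) {
      ids <- c(ids, sprintf("S%02d_%02d", i, k))
      # within-site sampling: site's own haplotype or a same-group one
      pool <- which(group_of_site == group_of_site[i])
      seqs[[length(seqs) + 1]] <- hap_by_site[[sample(pool, 1)]]
      site <- c(site, i)
    }
  }
  m <- do.call(rbind, seqs)
  rownames(m) <- ids
  positions <- (seq_len(spec$n_sites) - 1) * spec$site_spacing
  pos_ind <- positions[site]
  geo <- abs(outer(pos_ind, pos_ind, "-"))
  dimnames(geo) <- list(ids, ids)
  list(alignment = hap_alignment(m), site = site,
       group = group_of_site[site], positions = positions, geo = geo)
}
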