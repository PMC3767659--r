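test_that("locus panels respect the requested allele-count profile and are reproducible", {
  panel <- make_locus_panel(7, c(4, 13), seed = 1)
  expect_length(panel, 7)
  counts <- vapply(panel, function(l) length(l$alleles), 1L)
  expect_true(all(counts >= 4 & counts <= 13))
  for (l in panel) {
    expect_equal(sum(l$frequencies), 1, tolerance = 1e-9)
    expect_false(anyDuplicated(l$alleles) > 0)
  }
  expect_identical(panel, make_locus_panel(7, c(4, 13), seed = 1))
  expect_false(identical(panel, make_locus_panel(7, c(4, 13), seed = 2)))

  single <- make_locus_panel(1, c(2, 2), seed = 3)
  expect_length(single[[1]]$alleles, 2)

  expect_error(make_locus_panel(2, c(1, 5)), "allele_count_range")
  expect_error(make_locus_panel(2, c(5, 40)), "allele_count_range")
  expect_error(make_locus_panel(0, c(2, 5)), "n_loci")
})

test_that("colony specs enforce their bookkeeping invariants", {
  expect_error(colony_spec(10, c(5, 4)), "sum")
  expect_error(colony_spec(10, c(5, 5), n_worker_son_males = 2),
               "queenless")
  sp <- colony_spec(10, c(5, 5), queenless = TRUE, n_worker_son_males = 2)
  expect_equal(sp$n_fathers, 2L)
})

test_that("simulated colonies are Mendel-consistent with the hidden truth", {
  panel <- make_locus_panel(5, c(3, 8), seed = 2)
  loci <- vapply(panel, `[[`, "", "name")
  for (s in 1:8) {
    col <- simulate_colony(panel, colony_spec(12, c(6, 4, 2)), seed = s)
    w <- col$genotypes[col$genotypes$caste == "worker", ]
    for (loc in loci) {
      calls <- cbind(w[[paste0(loc, ".1")]], w[[paste0(loc, ".2")]])
      q <- col$truth$queen[, loc]
      expect_true(all(apply(calls, 1, function(a) any(a %in% q))))
    }
  }
})

test_that("single-father colonies share one paternal haplotype", {
  panel <- make_locus_panel(4, c(4, 6), seed = 3)
  col <- simulate_colony(panel, colony_spec(10, 10L), seed = 1)
  expect_equal(nrow(col$truth$fathers), 1)
  expect_true(all(col$truth$father_of == 1))
  w <- col$genotypes[col$genotypes$caste == "worker", ]
  pat <- infer_patrilines(w, col$truth$queen)
  expect_equal(pat$m_p, 1L)
})

test_that("haploid males carry one allele per locus; clones copy the queen", {
  panel <- make_locus_panel(3, c(3, 5), seed = 4)
  col <- simulate_colony(panel,
                         colony_spec(8, c(5, 3), n_queen_son_males = 4,
                                     n_thelytokous_females = 2),
                         seed = 2)
  g <- col$genotypes
  males <- g[g$caste == "male", ]
  expect_true(all(males$ploidy == 1L))
  loci <- locus_names(g)
  for (loc in loci) {
    expect_true(all(males[[paste0(loc, ".2")]] == 0))
    expect_true(all(males[[paste0(loc, ".1")]] %in% col$truth$queen[, loc]))
  }
  clones <- g[g$caste == "alate_female", ]
  for (loc in loci) {
    expect_true(all(sort(col$truth$queen[, loc]) ==
                      sort(c(clones[[paste0(loc, ".1")]][1],
                             clones[[paste0(loc, ".2")]][1]))))
  }
})

test_that("determinism: identical seeds give identical colonies", {
  panel <- make_locus_panel(3, c(3, 5), seed = 5)
  a <- simulate_colony(panel, colony_spec(6, c(4, 2)), seed = 11)
  b <- simulate_colony(panel, colony_spec(6, c(4, 2)), seed = 11)
  expect_identical(a, b)
})

test_that("queen allele frequencies converge to the panel frequencies", {
  panel <- make_locus_panel(2, c(4, 4), seed = 6)
  spec <- colony_spec(1, 1L)
  queens <- vapply(1:2500, function(s) {
    simulate_colony(panel, spec, seed = s)$truth$queen[, 1]
  }, integer(2))
  f_emp <- table(factor(c(queens), levels = panel[[1]]$alleles)) / 5000
  expect_lt(max(abs(as.numeric(f_emp) - panel[[1]]$frequencies)), 0.02)
})

test_that("nest placements follow the requested point process", {
  panel <- make_locus_panel(2, c(3, 4), seed = 7)
  tmpl <- colony_spec(3, 3L)
  pl <- plot_spec(40, 25, placement = "grid", seed = 1)
  sim <- simulate_plot(panel, pl, tmpl)
  xy <- as.matrix(sim$coords[, c("x", "y")])
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  expect_true(all(abs(apply(d, 1, min) - 8) < 1e-9)) # 40/5 lattice spacing
  expect_true(all(xy >= 0 & xy <= 40))

  pl2 <- plot_spec(34, 44, placement = "random", seed = 2)
  sim2 <- simulate_plot(panel, pl2, tmpl)
  sim3 <- simulate_plot(panel, pl2, tmpl)
  expect_identical(sim2$coords, sim3$coords)
  expect_equal(nrow(sim2$coords) / 34^2, 44 / 1156, tolerance = 1e-12)

  expect_error(plot_spec(10, 1), "n_nests")
})

test_that("transect haplotypes diverge by the requested substitution counts", {
  sp <- transect_spec(6, site_spacing = 10, samples_per_site = 2,
                      mutation_steps_within = 0,
                      mutation_steps_between = 14)
  tr <- simulate_transect_mtdna(sp, seed = 1)
  expect_equal(tr$alignment$length, 622L)
  col <- collapse_haplotypes(tr$alignment)
  # steps_within = 0: one haplotype per group
  expect_equal(nrow(col$haplotypes$seq), 2)
  pd <- pairwise_p_distance(col$haplotypes)
  expect_equal(pd$substitutions[1, 2], 14L)
  expect_equal(pd$p_percent[1, 2], 100 * 14 / 622, tolerance = 1e-9)

  sp2 <- transect_spec(6, mutation_steps_within = 1,
                       mutation_steps_between = 14)
  tr2 <- simulate_transect_mtdna(sp2, seed = 2)
  pd2 <- pairwise_p_distance(tr2$alignment)
  between <- tr2$group[row(pd2$substitutions)] !=
    tr2$group[col(pd2$substitutions)]
  expect_true(all(abs(pd2$substitutions[between] - 14) <= 2))

  expect_error(simulate_transect_mtdna(
    transect_spec(100, mutation_steps_within = 10,
                  mutation_steps_between = 14, seq_length = 50)),
    "exceed")
  expect_error(transect_spec(4, mutation_steps_within = 5,
                             mutation_steps_between = 2), "between-group")
})
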