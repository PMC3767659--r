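test_that("queen reconstruction finds the M_p-minimal genotype (exhaustive check)", {
  # workers B/A and C/A at one locus (A=100, B=102, C=104): queen B/C with a
  # single paternal allele A is the unique M_p = 1 solution
  w <- worker_table(c("102/100", "104/100"))
  rec <- reconstruct_queen(w)
  expect_equal(rec$m_p, 1L)
  expect_true(any(vapply(rec$candidates, function(q) {
    all(sort(q[, 1]) == c(102L, 104L))
  }, TRUE)))
  # exhaustive oracle over every queen pair from the observed alleles
  mats <- list()
  for (a in c(100L, 102L, 104L)) for (b in c(100L, 102L, 104L)) {
    if (b < a) next
    q <- matrix(c(a, b), 2, dimnames = list(NULL, "L1"))
    covered <- all(apply(cbind(w$L1.1, w$L1.2), 1,
                         function(x) any(x %in% q)))
    if (covered) mats[[length(mats) + 1]] <-
        infer_patrilines(w, q)$m_p
  }
  expect_equal(min(unlist(mats)), 1L)
})

test_that("an incompatible observed queen raises a monogyny violation", {
  w <- worker_table(c("100/102", "100/104"))
  q <- matrix(c(106L, 108L), 2, dimnames = list(NULL, "L1"))
  expect_error(reconstruct_queen(w, observed_queen = q),
               "monogyny violated at locus L1")
  # and reconstruction itself fails when no queen pair covers all workers
  w2 <- worker_table(c("100/102", "104/106", "108/110"))
  expect_error(reconstruct_queen(w2), "monogyny violated")
})

test_that("reconstructed queens match the simulation truth in >= 95% of colonies", {
  panel <- make_locus_panel(7, c(4, 13), seed = 1)
  # population-level frequencies (available in a field survey) break
  # symmetric homozygote/homozygote ambiguities
  pf <- lapply(panel, function(l) stats::setNames(l$frequencies, l$alleles))
  n <- 20; ok <- 0
  for (s in 1:n) {
    col <- simulate_colony(panel, colony_spec(12, c(6, 4, 2)), seed = 100 + s)
    w <- col$genotypes[col$genotypes$caste == "worker", ]
    rec <- reconstruct_queen(w, freqs = pf)
    if (identical(unname(apply(rec$queen, 2, sort)),
                  unname(apply(col$truth$queen, 2, sort)))) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

test_that("matriline assignment flags non-daughters and uninformative rows", {
  rows <- list(
    list(id = "w1", colony = "C", caste = "worker", ploidy = 2L,
         alleles = c(100L, 106L, 200L, 204L)),
    list(id = "w2", colony = "C", caste = "worker", ploidy = 2L,
         alleles = c(104L, 106L, 200L, 202L)), # shares nothing at L1
    list(id = "w3", colony = "C", caste = "worker", ploidy = 2L,
         alleles = c(0L, 0L, 0L, 0L)))
  tab <- build_table(rows, c("L1", "L2"))
  q <- matrix(c(100L, 102L, 200L, 202L), 2, dimnames = list(NULL, c("L1", "L2")))
  res <- assign_matrilines(tab, q)
  expect_equal(res$matriline, c("same", "different", "uninformative"))
})

test_that("patriline partitions: worked examples", {
  # two loci, unambiguous paternal haplotypes A.X, A.Y, B.X -> M_p = 3
  rows <- lapply(1:3, function(i) {
    pat <- list(c(110L, 210L), c(110L, 212L), c(112L, 210L))[[i]]
    list(id = paste0("w", i), colony = "C", caste = "worker", ploidy = 2L,
         alleles = c(100L, pat[1], 200L, pat[2]))
  })
  tab <- build_table(rows, c("L1", "L2"))
  q <- matrix(c(100L, 102L, 200L, 202L), 2,
              dimnames = list(NULL, c("L1", "L2")))
  pat <- infer_patrilines(tab, q)
  expect_equal(pat$m_p, 3L)
  expect_equal(sort(pat$contributions), c(1L, 1L, 1L))

  # ten workers sharing the same paternal alleles -> M_p = 1
  tab2 <- worker_table(rep("100/110", 10))
  q2 <- matrix(c(100L, 102L), 2, dimnames = list(NULL, "L1"))
  pat2 <- infer_patrilines(tab2, q2)
  expect_equal(pat2$m_p, 1L)
  expect_equal(pat2$contributions, 10L)
  expect_equal(unname(pat2$fathers[1, 1]), 110L)
})

test_that("patriline minimisation equals the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    n_w <- sample(2:6, 1); n_loc <- sample(1:3, 1)
    loci <- paste0("L", seq_len(n_loc))
    q <- matrix(sample(100:104, 2 * n_loc, replace = TRUE), 2,
                dimnames = list(NULL, loci))
    k <- sample(1:3, 1)
    fathers <- matrix(sample(100:104, k * n_loc, replace = TRUE), k)
    rows <- lapply(seq_len(n_w), function(i) {
      f <- sample(k, 1)
      al <- unlist(lapply(seq_len(n_loc), function(j) {
        sort(c(q[sample(1:2, 1), j], fathers[f, j]))
      }))
      list(id = paste0("w", i), colony = "C", caste = "worker", ploidy = 2L,
           alleles = al)
    })
    tab <- build_table(rows, loci)
    pat <- infer_patrilines(tab, q)
    wm <- as.matrix(tab[, -(1:4)])
    oracle <- brute_force_mp(oracle_candidates(wm, q))
    expect_equal(pat$m_p, oracle)
    # the returned partition must itself be feasible and Mendel-consistent
    expect_equal(sum(pat$contributions), n_w)
    expect_equal(length(unique(pat$assignment)), pat$m_p)
  }
})

test_that("effective paternity reproduces worked values and limits", {
  expect_equal(round(effective_paternity(rep(1, 1), n = 10), 2), 1.00)
  expect_equal(round(effective_paternity(c(11, 7)), 2), 2.00)
  expect_equal(round(effective_paternity(c(7, 5, 4, 4)), 2), 4.34)
  expect_error(effective_paternity(c(1, 1)), "n < 3")
  expect_error(effective_paternity(numeric(0)), "empty")
  # large-n limit with equal contributions tends to k
  for (k in c(2, 4)) {
    expect_equal(effective_paternity(rep(1 / k, k), n = 1e6), k,
                 tolerance = 1e-4)
  }
})

test_that("non-detection probabilities follow the product and mixture laws", {
  expect_equal(nondetect_two_males(list(c(0.5, 0.5))), 0.5)
  expect_equal(nondetect_two_males(rep(list(c(0.5, 0.5)), 3)), 0.125)
  # seven loci with sum f^2 = 0.01 each (100 equifrequent alleles)
  f7 <- rep(list(rep(0.01, 100)), 7)
  expect_equal(nondetect_two_males(f7), 1e-14)
  # monomorphic locus contributes a factor 1
  expect_equal(nondetect_two_males(list(c(0.5, 0.5), 1)), 0.5)
  expect_error(nondetect_two_males(list(c(0.5, 0.4))), "sum to 1")

  expect_equal(nondetect_worker_son(1, 1), 0.5)
  expect_equal(nondetect_worker_son(c(0.5, 0.5), c(2, 3)), 0.1875)
  expect_equal(nondetect_worker_son(c(0.3, 0.7), c(0, 0)), 1)
  expect_error(nondetect_worker_son(c(0.5, 0.5), 1), "length")
})

test_that("male parentage classification and the group criterion", {
  q <- matrix(c(100L, 102L, 200L, 202L, 0L, 0L), 2,
              dimnames = list(NULL, c("L1", "L2", "L3")))
  rows <- list(
    list(id = "m1", colony = "C", caste = "male", ploidy = 1L,
         alleles = c(100L, 0L, 202L, 0L, 300L, 0L)),
    list(id = "m2", colony = "C", caste = "male", ploidy = 1L,
         alleles = c(104L, 0L, 204L, 0L, 302L, 0L)), # two non-queen alleles
    list(id = "m3", colony = "C", caste = "male", ploidy = 1L,
         alleles = c(102L, 0L, 200L, 0L, 304L, 0L)))
  tab <- build_table(rows, c("L1", "L2", "L3"))
  res <- classify_males(tab, q)
  expect_equal(res$classes$class, c("queen_son", "worker_son", "queen_son"))
  # L3 is untyped in the queen: the two putative queen sons show 2 alleles
  # there (ok), but three would violate the group criterion
  expect_true(res$group_ok[["L3"]])
  rows[[2]]$alleles <- c(100L, 0L, 202L, 0L, 306L, 0L)
  res2 <- classify_males(build_table(rows, c("L1", "L2", "L3")), q)
  expect_equal(unique(res2$classes$class), "queen_son")
  expect_false(res2$group_ok[["L3"]])
})

test_that("thelytoky screening separates sexual from clone-compatible females", {
  panel <- make_locus_panel(5, c(4, 8), seed = 9)
  col <- simulate_colony(panel,
                         colony_spec(10, c(6L, 6L), n_alate_females = 2,
                                     n_thelytokous_females = 3),
                         seed = 4)
  g <- col$genotypes
  females <- g[g$caste == "alate_female", ]
  w <- g[g$caste == "worker", ]
  pat <- infer_patrilines(w, col$truth$queen)
  res <- thelytoky_check(females, col$truth$queen, patrilines = pat)
  clones <- grepl("_T", res$id)
  expect_true(all(res$class[clones] == "thelytoky_compatible"))
  expect_true(all(res$p_nondetect[clones] > 0))
  expect_true(all(res$p_nondetect[res$class == "sexual"] == 0))
})

test_that("colony_pedigree integrates reconstruction, counts and probabilities", {
  panel <- make_locus_panel(7, c(4, 13), seed = 1)
  freqs <- lapply(panel, `[[`, "frequencies")
  col <- simulate_colony(panel, colony_spec(12, c(6, 4, 2)), seed = 7,
                         colony_id = "K1")
  ped <- colony_pedigree(col$genotypes, "K1", panel_freqs = freqs)
  expect_s3_class(ped, "pedigree_result")
  expect_true(ped$queen_observed)
  expect_equal(ped$m_p, 3L)
  expect_equal(ped$p_nondetect_two_males, nondetect_two_males(freqs))
  expect_true(ped$p_nondetect_worker_son >= 0 &&
                ped$p_nondetect_worker_son <= 1)
  expect_gte(ped$m_e_p, 1)
  # queenless colony: queen reconstructed instead of observed
  col2 <- simulate_colony(panel, colony_spec(12, c(6, 4, 2), queenless = TRUE),
                          seed = 8, colony_id = "K2")
  ped2 <- colony_pedigree(col2$genotypes, "K2")
  expect_false(ped2$queen_observed)
  expect_equal(dim(ped2$queen), c(2L, 7L))
  expect_error(colony_pedigree(col$genotypes, "K1", min_workers = 20),
               "genotyped workers")
})
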