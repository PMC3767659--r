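test_that("diversity summaries match hand-computed values", {
  tab <- worker_table(c("100/100", "100/102"))
  ls <- locus_summaries(tab)
  expect_equal(ls$per_locus$h_o, 0.5)
  # n = 2, freqs 3/4, 1/4: (4/3) * (1 - 10/16) = 0.5
  expect_equal(ls$per_locus$h_e, 0.5)
  expect_equal(ls$per_locus$n_a, 2L)

  hom <- worker_table(c("100/100", "102/102", "100/100"))
  expect_equal(locus_summaries(hom)$per_locus$h_o, 0)

  # invariance under allele relabelling
  relab <- worker_table(c("300/300", "300/244"))
  expect_equal(locus_summaries(relab)$per_locus$h_e, 0.5)

  expect_error(locus_summaries(build_table(list(
    list(id = "m", colony = "C", caste = "male", ploidy = 1L,
         alleles = c(100L, 0L))), "L1")), "no diploid")
})

test_that("exact HWE test: enumeration and Monte-Carlo routes agree", {
  # all-heterozygote sample is grossly out of equilibrium
  pairs <- cbind(rep(100L, 50), rep(102L, 50))
  expect_lt(hwe_exact(pairs), 0.001)
  # equilibrium-looking biallelic sample
  pairs2 <- rbind(cbind(rep(100L, 9), rep(100L, 9)),
                  cbind(rep(100L, 12), rep(102L, 12)),
                  cbind(rep(102L, 4), rep(102L, 4)))
  p_exact <- hwe_exact(pairs2)
  expect_gt(p_exact, 0.2)
  set.seed(1)
  p_mc <- sociogen:::hwe_exact_mc(pairs2, n_mc = 20000L)
  expect_equal(p_mc, p_exact, tolerance = 0.02)
  # monomorphic: not applicable
  expect_true(is.na(hwe_exact(cbind(rep(100L, 5), rep(100L, 5)))))
})

test_that("resampled HWE design draws one individual per colony", {
  panel <- make_locus_panel(3, c(3, 6), seed = 5)
  tab <- sim_colony_set(panel, 10, 4, function(i) 4L, base_seed = 3)
  res <- hwe_exact_resampled(tab, n_replicates = 3, seed = 1, n_mc = 500)
  expect_equal(dim(res$p), c(3L, 3L))
  expect_true(res$n_significant <= res$n_tests)
  single <- tab[tab$colony == tab$colony[1], ]
  expect_error(hwe_exact_resampled(single), ">= 2 colonies")
})

test_that("linkage test flags a duplicated locus and skips monomorphic pairs", {
  set.seed(2)
  rows <- lapply(1:30, function(i) {
    g <- sort(sample(c(100L, 102L, 104L), 2, replace = TRUE))
    list(id = paste0("w", i), colony = paste0("C", i), caste = "worker",
         ploidy = 2L, alleles = c(g, g, 200L, 200L))
  })
  tab <- build_table(rows, c("L1", "L2", "L3"))
  res <- ld_test_resampled(tab, n_replicates = 2, n_perm = 500, seed = 1)
  dup <- res$p[res$p$locus1 == "L1" & res$p$locus2 == "L2", ]
  expect_true(all(dup$p < 0.05)) # perfect association
  mono <- res$p[res$p$locus2 == "L3" | res$p$locus1 == "L3", ]
  expect_true(all(is.na(mono$p))) # monomorphic: not applicable
})

test_that("pairwise G-test separates unrelated colonies but not a split colony", {
  panel <- make_locus_panel(7, c(4, 13), seed = 6)
  tab <- sim_colony_set(panel, 2, 10, function(i) c(5L, 5L), base_seed = 9)
  res <- gtest_pairwise_differentiation(tab, n_perm = 500, seed = 1)
  expect_true(res$significant[1])

  # one colony split in two pseudo-colonies: no differentiation
  one <- tab[tab$colony == "C001" & tab$caste == "worker", ]
  one$colony <- rep(c("A", "B"), length.out = nrow(one))
  res2 <- gtest_pairwise_differentiation(genotype_table(one),
                                         n_perm = 500, seed = 1)
  expect_false(res2$significant[1])
  expect_equal(attr(res2, "threshold"), 0.05)
})

test_that("Fisher combination of all-ones p-values is 1", {
  # via the chi-square tail: -2 * sum(log(1)) = 0 on 2k df
  expect_equal(pchisq(0, df = 6, lower.tail = FALSE), 1)
  # and the G statistic of an independent table is ~0
  expect_equal(sociogen:::g_stat(matrix(c(10, 10, 10, 10), 2)), 0,
               tolerance = 1e-12)
})

test_that("Evanno delta-K is flat for quadratic likelihoods and peaks at a kink", {
  ks <- 1:6
  quad <- function(K) -1000 + 50 * K - 4 * K^2
  lnp <- do.call(rbind, lapply(1:4, function(r) {
    data.frame(K = ks, run = r, lnp = quad(ks) + r) # constant run offsets
  }))
  res <- evanno_delta_k(lnp)
  dk <- res$table$delta_k[2:5]
  expect_equal(max(dk) - min(dk), 0, tolerance = 1e-9)

  kink <- function(K) ifelse(K <= 2, -2000 + 500 * K, -1000 + 10 * K)
  lnp2 <- do.call(rbind, lapply(1:4, function(r) {
    data.frame(K = ks, run = r, lnp = kink(ks) + r)
  }))
  res2 <- evanno_delta_k(lnp2)
  expect_equal(res2$best_k, 2)

  expect_error(evanno_delta_k(data.frame(K = c(1, 1, 2, 2),
                                         run = c(1, 2, 1, 2),
                                         lnp = 1:4)), ">= 3 consecutive")
  # zero run-to-run SD is flagged as undefined
  lnp3 <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(K = ks, run = r, lnp = quad(ks))
  }))
  expect_true(all(is.na(evanno_delta_k(lnp3)$table$delta_k)))
})
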