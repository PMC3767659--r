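test_that("haplotype collapsing merges identical sequences and labels by first occurrence", {
  m <- matrix(rep(c("A", "C", "G", "T"), 10), nrow = 10, byrow = TRUE)
  rownames(m) <- paste0("s", 1:10)
  col <- collapse_haplotypes(hap_alignment(m))
  expect_equal(nrow(col$haplotypes$seq), 1)
  expect_equal(unname(col$frequencies["H1"]), 10L)

  m2 <- rbind(A = c("A", "C", "G"), B = c("A", "C", "T"),
              C = c("A", "C", "G"))
  col2 <- collapse_haplotypes(hap_alignment(m2))
  expect_equal(col2$assignment, c("H1", "H2", "H1"))

  # ambiguous sequence joins the first compatible haplotype
  m3 <- rbind(a = c("A", "C", "G"), b = c("A", "N", "G"),
              c = c("T", "C", "G"))
  col3 <- collapse_haplotypes(hap_alignment(m3))
  expect_equal(col3$assignment, c("H1", "H1", "H2"))

  # site frequency table
  col4 <- collapse_haplotypes(hap_alignment(m2), site = c(1, 2, 2))
  expect_equal(unname(col4$site_frequencies["2", "H1"]), 1L)
})

test_that("p-distance is a metric on gap-free alignments with N handling", {
  haps <- random_haps(5, 40, seed = 11)
  pd <- pairwise_p_distance(hap_alignment(haps))
  s <- pd$substitutions
  expect_equal(s, t(s))
  expect_true(all(diag(s) == 0))
  for (i in 1:nrow(s)) for (j in 1:nrow(s)) for (k in 1:nrow(s)) {
    expect_lte(s[i, j], s[i, k] + s[k, j])
  }
  # N sites excluded pairwise
  m <- rbind(x = c("A", "N", "G", "T"), y = c("A", "C", "G", "A"))
  pd2 <- pairwise_p_distance(hap_alignment(m))
  expect_equal(pd2$substitutions[1, 2], 1L)
  expect_equal(pd2$p_percent[1, 2], 100 / 3)
})

test_that("median-joining network: worked examples", {
  # two haplotypes one step apart: a single edge, no medians
  m <- rbind(H1 = c("A", "A"), H2 = c("A", "T"))
  net <- median_joining_network(hap_alignment(m))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
  expect_true(all(net$nodes$observed))

  # three haplotypes pairwise distance 2 through a common intermediate:
  # one median vector becomes the star centre
  m2 <- rbind(H1 = c("T", "A", "A", "C"), H2 = c("A", "T", "A", "C"),
              H3 = c("A", "A", "T", "C"))
  net2 <- median_joining_network(hap_alignment(m2))
  medians <- net2$nodes$id[!net2$nodes$observed]
  expect_length(medians, 1)
  expect_equal(sort(net2$edges$weight), c(1, 1, 1))
  expect_equal(unname(net2$sequences[medians, ]), c("A", "A", "A", "C"))
})

test_that("network contains a spanning tree no longer than the observed MST", {
  for (seed in c(21, 22, 23)) {
    haps <- random_haps(6, 8, seed = seed)
    aln <- hap_alignment(haps)
    net <- median_joining_network(aln)
    # total spanning weight over the final node set, restricted to network
    # edges, must match the unrestricted MST of those nodes (network
    # contains an MST) ...
    dfull <- sociogen:::hamming(net$sequences)
    mst_all <- prim_mst_weight(dfull)
    # spanning weight using only network edges (Kruskal over edge list)
    parent <- seq_len(nrow(net$sequences))
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ord <- order(net$edges$weight)
    w_net <- 0
    ids <- rownames(net$sequences)
    for (e in ord) {
      i <- match(net$edges$from[e], ids); j <- match(net$edges$to[e], ids)
      if (find(i) != find(j)) { parent[find(i)] <- find(j)
        w_net <- w_net + net$edges$weight[e] }
    }
    expect_equal(w_net, mst_all)
    # ... and the network cannot be longer than the MST of the observed
    # haplotypes alone (medians only ever shorten the Steiner tree)
    d_obs <- sociogen:::hamming(haps)
    expect_lte(w_net, prim_mst_weight(d_obs))
  }
})

test_that("AMOVA reproduces the hand-computed fixture and its limits", {
  # pops {s1,s2} and {s3,s4}; deltas: within 1 each, cross 3,4,4,3.
  # By hand: SSD_total = 16/4 = 4, SSD_WP = 1, sigma_c = 0.5,
  # MS_AP = 3, n' = 2, sigma_b = 1.25, Phi_ST = 5/7.
  m <- rbind(s1 = strsplit("AAAAAAAA", "")[[1]],
             s2 = strsplit("CAAAAAAA", "")[[1]],
             s3 = strsplit("AATTTAAA", "")[[1]],
             s4 = strsplit("CATTTAAA", "")[[1]])
  d <- pairwise_p_distance(hap_alignment(m))$substitutions
  am <- amova(d, pop = c("p1", "p1", "p2", "p2"), n_perm = 999, seed = 1,
              squared = TRUE)
  expect_equal(unname(am$sigma), c(1.25, 0.5), tolerance = 1e-12)
  expect_equal(unname(am$phi["phi_st"]), 5 / 7, tolerance = 1e-12)
  expect_equal(sum(am$percent), 100, tolerance = 0.01)

  # fixed populations far apart: among-population share ~100%
  m2 <- rbind(a1 = rep("A", 20), a2 = rep("A", 20),
              b1 = c(rep("T", 14), rep("A", 6)),
              b2 = c(rep("T", 14), rep("A", 6)))
  d2 <- pairwise_p_distance(hap_alignment(m2))$substitutions
  am2 <- amova(d2, pop = c("p1", "p1", "p2", "p2"), n_perm = 99, seed = 1,
               squared = TRUE)
  expect_equal(unname(am2$percent["among_pops"]), 100, tolerance = 1e-9)

  # identical composition everywhere: within ~100%
  m3 <- rbind(a1 = rep("A", 10), a2 = c("T", rep("A", 9)),
              b1 = rep("A", 10), b2 = c("T", rep("A", 9)))
  d3 <- pairwise_p_distance(hap_alignment(m3))$substitutions
  am3 <- amova(d3, pop = c("p1", "p1", "p2", "p2"), n_perm = 99, seed = 1,
               squared = TRUE)
  expect_lt(unname(am3$percent["among_pops"]), 10)

  expect_error(amova(d, pop = rep("p1", 4)), ">= 2 populations")
})

test_that("three-level AMOVA partitions and permutation p-values behave", {
  sp <- transect_spec(8, samples_per_site = 3, mutation_steps_within = 1,
                      mutation_steps_between = 14)
  tr <- simulate_transect_mtdna(sp, seed = 5)
  d <- pairwise_p_distance(tr$alignment)$substitutions
  am <- amova(d, pop = as.character(tr$site), group = as.character(tr$group),
              n_perm = 499, seed = 2, squared = TRUE)
  expect_equal(sum(am$percent), 100, tolerance = 0.01)
  expect_length(am$sigma, 3)
  expect_gt(am$percent["among_groups"], 50) # divergence dominates
  expect_lt(am$p["phi_st"], 0.05)
  # truncation mode keeps percentages non-negative
  am_t <- amova(d, pop = as.character(tr$site),
                group = as.character(tr$group),
                n_perm = 99, seed = 2, squared = TRUE, truncate = TRUE)
  expect_true(all(am_t$percent >= 0))
})
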