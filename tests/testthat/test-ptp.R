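test_that("two-tip closed forms for the two-rate likelihood", {
  tr <- read_newick(text = "(A:0.1,B:0.1);")
  one <- ptp_loglik(tr, c(A = "s1", B = "s1"))
  expect_equal(one$lambda_W, 10, tolerance = 1e-12)
  expect_true(is.na(one$lambda_B))
  expect_equal(one$logL, 2 * (log(10) - 1), tolerance = 1e-12)

  two <- ptp_loglik(tr, c(A = "s1", B = "s2"))
  expect_equal(two$lambda_B, 10, tolerance = 1e-12)
  expect_true(is.na(two$lambda_W))
  expect_equal(two$logL, one$logL, tolerance = 1e-12)   # symmetric case
})

test_that("disconnected species assignments are rejected", {
  tr <- read_newick(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  expect_error(ptp_loglik(tr, c(A = "x", B = "y", C = "x", D = "y")),
               "connected")
  expect_error(ptp_delimit(ape::unroot(ape::rtree(5))), "rooted")
})

test_that("true partitions outscore lumping when rates differ strongly", {
  set.seed(55)
  wins <- 0L
  for (i in 1:20) {
    sim <- simulate_tree_dataset(small_sim(n_species = 2L, n_per = 4L,
                                           intra = 0.005, inter = 0.2,
                                           seed = 100L + i))
    ll_true <- ptp_loglik(sim$tree, sim$partition)$logL
    lump <- setNames(rep("one", length(sim$partition)),
                     names(sim$partition))
    if (ll_true > ptp_loglik(sim$tree, lump)$logL) wins <- wins + 1L
  }
  expect_identical(wins, 20L)
})

test_that("greedy search attains the exhaustive maximum on small trees", {
  set.seed(77)
  for (i in 1:50) {
    tr <- ape::rtree(10)
    # min_improve = 0 disables the low-signal collapse so the raw optima
    # are comparable
    ex <- suppressWarnings(ptp_delimit(tr, exhaustive_max = 14L,
                                       min_improve = 0))
    gr <- suppressWarnings(ptp_delimit(tr, exhaustive_max = 0L,
                                       min_improve = 0))
    expect_equal(gr$logL, ex$logL, tolerance = 1e-9)
    expect_equal(ex$logL, oracle_ptp_best(tr), tolerance = 1e-9)
    # the optimum dominates both extreme partitions
    ntip <- ape::Ntip(tr)
    lump <- setNames(rep("a", ntip), tr$tip.label)
    split <- setNames(paste0("s", seq_len(ntip)), tr$tip.label)
    expect_gte(ex$logL, ptp_loglik(tr, lump)$logL - 1e-9)
    expect_gte(ex$logL, ptp_loglik(tr, split)$logL - 1e-9)
  }
})

test_that("species counts are recovered on simulated genealogies", {
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_tree_dataset(small_sim(n_species = 4L, n_per = 4L,
                                           intra = 0.005, inter = 0.10,
                                           seed = seed))
    res <- suppressWarnings(ptp_delimit(sim$tree))
    if (res$partition$n_motus == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 16L)   # >= 80% of 20 seeds

  # rate recovery within a factor of 2 when both classes are populated
  sim <- simulate_tree_dataset(small_sim(n_species = 6L, n_per = 5L,
                                         intra = 0.005, inter = 0.10,
                                         seed = 31L))
  res <- suppressWarnings(ptp_delimit(sim$tree))
  truth <- ptp_loglik(sim$tree, sim$partition)
  if (res$partition$n_motus == 6L) {
    expect_lt(abs(log2(res$lambda_W / truth$lambda_W)), 1)
    expect_lt(abs(log2(res$lambda_B / truth$lambda_B)), 1)
  }
})

test_that("pipeline recovery from sequences through NJ to PTP", {
  hits <- 0L
  for (seed in 1:10) {
    sp <- lapply(1:6, function(i)
      species_spec(paste0("S", i), 4L, 0.005,
                   genus = sprintf("G%d", (i + 1L) %/% 2L), tribe = "T1"))
    sim <- simulate_tree_dataset(sim_config(sp, 0.10, seed = seed))
    tr <- root_tree(nj_tree(distance_matrix(sim$dataset)), "midpoint")
    res <- suppressWarnings(ptp_delimit(tr))
    if (res$partition$n_motus == 6L) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("a single-rate tree collapses to one species with a warning", {
  tr <- ape::stree(8, "balanced")
  tr$edge.length <- rep(0.05, nrow(tr$edge))
  expect_warning(res <- ptp_delimit(tr), "single species")
  expect_identical(res$partition$n_motus, 1L)
  expect_true(res$low_confidence)
  expect_equal(res$logL, res$logL_null, tolerance = 1e-12)
})
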