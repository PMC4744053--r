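test_that("simulation is deterministic for a fixed seed", {
  cfg <- small_sim(seed = 11L)
  a <- simulate_tree_dataset(cfg)
  b <- simulate_tree_dataset(cfg)
  expect_identical(a$dataset$seq, b$dataset$seq)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  c <- simulate_dataset(small_sim(seed = 12L))
  expect_false(identical(a$dataset$seq, c$dataset$seq))
})

test_that("infeasible divergence targets are rejected", {
  sp <- list(species_spec("A", 3, target_intra = 0.15),
             species_spec("B", 3, target_intra = 0.01))
  expect_error(sim_config(sp, target_inter_congeneric = 0.10),
               "infeasible")
  expect_error(species_spec("A", 0), "n_specimens")
  expect_error(small_sim(kappa = -1), "kappa")
})

test_that("generated datasets pass validation and match the config shape", {
  cfg <- small_sim(n_species = 4L, n_per = 4L, seed = 2L)
  sim <- simulate_tree_dataset(cfg)
  expect_s3_class(sim$dataset, "barcode_dataset")   # constructor validates
  expect_identical(nrow(sim$dataset$seq), 16L)
  expect_identical(length(unique(sim$partition)), 4L)
  expect_true(ape::is.rooted(sim$tree))
  expect_setequal(sim$tree$tip.label, rownames(sim$dataset$seq))

  one <- sim_config(list(species_spec("Solo", 5, 0.01)), seed = 4L)
  expect_identical(length(unique(simulate_tree_dataset(one)$partition)), 1L)
})

test_that("singleton-only designs have no within-species comparisons", {
  sp <- lapply(1:4, function(i)
    species_spec(paste0("S", i), 1L, 0, genus = "G1", tribe = "T1"))
  ds <- simulate_dataset(sim_config(sp, 0.10, seed = 9L))
  rs <- rank_summaries(distance_matrix(ds), ds)
  expect_identical(rs$n_comparisons[rs$stratum == "within_species"], 0L)
})

test_that("clean simulations carry no pseudogene signature; Numt injection is exact", {
  for (seed in 1:5)
    expect_identical(
      nrow(screen_pseudogenes(simulate_dataset(small_sim(seed = seed)))), 0L)

  cfg <- small_sim(n_species = 10L, n_per = 5L, seed = 6L,
                   numt_fraction = 0.1)
  ds <- simulate_dataset(cfg)
  flags <- screen_pseudogenes(ds)
  expect_identical(nrow(flags), 5L)                  # round(0.1 * 50)
  expect_setequal(flags$sample_id, attr(ds, "numt_ids"))
  expect_true(all(flags$reason == "internal stop"))
})

test_that("realized divergences calibrate to the configured targets", {
  # 2 species x 5 specimens, intra 0.005, inter 0.10, across 20 seeds
  within <- c(); between <- c()
  for (seed in 1:20) {
    cfg <- sim_config(list(
      species_spec("A", 5, 0.005, genus = "G1"),
      species_spec("B", 5, 0.005, genus = "G1")),
      target_inter_congeneric = 0.10, seed = seed)
    ds <- simulate_dataset(cfg)
    dm <- distance_matrix(ds)
    sp <- ds$meta$morphospecies
    same <- outer(sp, sp, "==") & upper.tri(dm$values)
    diff <- !outer(sp, sp, "==") & upper.tri(dm$values)
    within <- c(within, mean(dm$values[same]))
    between <- c(between, mean(dm$values[diff]))
  }
  expect_gt(mean(within), 0.002)
  expect_lt(mean(within), 0.009)
  expect_gt(mean(between), 0.07)
  expect_lt(mean(between), 0.13)

  # long sequences: relative error of the realized means within 10%
  w10 <- c(); b10 <- c()
  for (seed in 1:3) {
    cfg <- sim_config(list(
      species_spec("A", 6, 0.01, genus = "G1"),
      species_spec("B", 6, 0.01, genus = "G1")),
      target_inter_congeneric = 0.10, seq_length = 6580L, seed = seed)
    ds <- simulate_dataset(cfg)
    dm <- distance_matrix(ds)
    sp <- ds$meta$morphospecies
    same <- outer(sp, sp, "==") & upper.tri(dm$values)
    w10 <- c(w10, mean(dm$values[same]))
    b10 <- c(b10, mean(dm$values[!outer(sp, sp, "==") & upper.tri(dm$values)]))
  }
  expect_lt(abs(mean(w10) - 0.01) / 0.01, 0.10)
  expect_lt(abs(mean(b10) - 0.10) / 0.10, 0.10)
})

test_that("the study-shaped default config reproduces the library structure", {
  cfg <- default_study_config(seed = 5L)
  sim <- simulate_tree_dataset(cfg)
  ds <- sim$dataset
  expect_identical(nrow(ds$seq), 421L)
  expect_identical(length(unique(ds$meta$morphospecies)), 84L)
  expect_identical(length(unique(ds$meta$genus)), 36L)
  expect_identical(length(unique(ds$meta$tribe)), 3L)
  expect_identical(count_by_sampling(ds),
                   c(n_singleton_species = 38L, n_multi_species = 46L))
  expect_identical(nrow(screen_pseudogenes(ds)), 0L)
})
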