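test_that("closed-form distance values are reproduced", {
  # 100 comparable sites, 10 transitions, 5 transversions
  x <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1L]]
  y <- x
  # transitions at 10 'A' sites (A->G), transversions at 5 'C' sites (C->A)
  y[which(x == "A")[1:10]] <- "G"
  y[which(x == "C")[1:5]] <- "A"
  r <- pair_distance(paste(x, collapse = ""), paste(y, collapse = ""), "k2p")
  expect_equal(r$comparable_sites, 100L)
  expect_equal(r$distance, -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_equal(r$distance, 0.1702, tolerance = 5e-4)

  # p = 0.1 -> JC69 about 0.1073
  y2 <- x; y2[which(x == "A")[1:10]] <- "G"
  rj <- pair_distance(paste(x, collapse = ""), paste(y2, collapse = ""),
                      "jc69")
  expect_equal(rj$distance, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(rj$distance, 0.1073, tolerance = 5e-4)

  ident <- paste(x, collapse = "")
  for (m in c("p", "jc69", "k2p"))
    expect_identical(pair_distance(ident, ident, m)$distance, 0)
})

test_that("pair_distance agrees with a per-site counting oracle", {
  set.seed(101)
  acgt <- c("A", "C", "G", "T")
  for (i in 1:200) {
    xs <- sample(acgt, 300, TRUE)
    ys <- xs
    mut <- sample(300, 45)                     # ~15% divergence: unsaturated
    ys[mut] <- sample(acgt, 45, TRUE)
    miss <- sample(300, 20)                    # gaps/N/ambiguity sprinkled in
    ys[miss] <- sample(c("N", "-", "R", "Y"), 20, TRUE)
    xs[sample(300, 10)] <- "-"
    x <- paste(xs, collapse = "")
    y <- paste(ys, collapse = "")
    for (m in c("p", "jc69", "k2p")) {
      o <- oracle_pair_distance(x, y, m)
      got <- suppressWarnings(pair_distance(x, y, m, min_sites = 10L))
      expect_identical(got$comparable_sites, o$comparable_sites)
      if (is.finite(o$distance))
        expect_equal(got$distance, o$distance, tolerance = 1e-12)
    }
  }
})

test_that("distance_matrix matches pair_distance entrywise and ape's K80", {
  ds <- simulate_dataset(small_sim(n_species = 3L, n_per = 3L, seed = 8L))
  for (m in c("p", "jc69", "k2p")) {
    dm <- distance_matrix(ds, m)
    expect_identical(dm$values, t(dm$values))
    expect_true(all(diag(dm$values) == 0))
    for (i in 1:4) for (j in 5:9) {
      pd <- pair_distance(paste(ds$seq[i, ], collapse = ""),
                          paste(ds$seq[j, ], collapse = ""), m)
      expect_equal(dm$values[i, j], pd$distance, tolerance = 1e-12)
      expect_identical(dm$comparable_sites[i, j], pd$comparable_sites)
    }
  }
  bin <- ape::as.DNAbin(strsplit(apply(ds$seq, 1, paste, collapse = ""), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  got <- distance_matrix(ds, "k2p")$values
  expect_equal(unname(got), unname(ref), tolerance = 1e-9)
})

test_that("model corrections are ordered K2P >= JC69 >= p", {
  set.seed(7)
  for (i in 1:50) {
    ds <- simulate_dataset(small_sim(n_species = 2L, n_per = 2L,
                                     inter = runif(1, 0.05, 0.2), seed = i))
    p <- distance_matrix(ds, "p")$values
    jc <- distance_matrix(ds, "jc69")$values
    k2p <- distance_matrix(ds, "k2p")$values
    off <- upper.tri(p)
    expect_true(all(k2p[off] >= jc[off] - 1e-12))
    expect_true(all(jc[off] >= p[off] - 1e-12))
  }
})

test_that("saturation aborts by default and caps on request", {
  ids <- c("s1", "s2")
  seqs <- setNames(c(paste(rep("ACGT", 40), collapse = ""),
                     paste(rep("GTAC", 40), collapse = "")), ids)
  ds <- barcode_dataset(seqs, toy_meta(ids))
  expect_error(distance_matrix(ds, "jc69"), "saturated")
  capped <- distance_matrix(ds, "p")           # p never saturates
  expect_true(all(is.finite(capped$values)))
})

test_that("pairs with too few comparable sites are excluded with warning", {
  ids <- c("s1", "s2", "s3")
  base <- leucine_seq()
  masked <- paste0(strrep("N", 600), substr(base, 601, 658))
  seqs <- setNames(c(base, base, masked), ids)
  ds <- barcode_dataset(seqs, toy_meta(ids), max_missing_frac = 0.95)
  expect_warning(dm <- distance_matrix(ds, "p", min_sites = 100L),
                 "comparable sites")
  expect_true(is.na(dm$values[1, 3]) && is.na(dm$values[2, 3]))
  expect_false(is.na(dm$values[1, 2]))
})

test_that("rank summaries partition all pairs across the four strata", {
  cfg <- sim_config(list(
    species_spec("A", 3, 0.004, genus = "G1", tribe = "T1"),
    species_spec("B", 2, 0.004, genus = "G1", tribe = "T1"),
    species_spec("C", 2, 0.004, genus = "G2", tribe = "T1"),
    species_spec("D", 2, 0.004, genus = "G3", tribe = "T2")),
    target_inter_congeneric = 0.10, seed = 13L)
  ds <- simulate_dataset(cfg)
  dm <- distance_matrix(ds)
  rs <- rank_summaries(dm, ds)
  n <- nrow(ds$seq)
  expect_identical(sum(rs$n_comparisons), n * (n - 1L) %/% 2L)
  expect_identical(rs$n_comparisons,
                   c(3L + 1L + 1L + 1L,      # within species
                     3L * 2L,                # within genus, between species
                     5L * 2L,                # within tribe, between genera
                     7L * 2L))               # between tribes
  expect_true(all(rs$min <= rs$mean & rs$mean <= rs$max))
  # strata means reflect the configured hierarchy
  expect_true(rs$mean[1] < rs$mean[2])
  expect_true(rs$mean[2] < rs$mean[3])

  one <- simulate_dataset(sim_config(list(species_spec("A", 4, 0.005)),
                                     seed = 2L))
  rs1 <- rank_summaries(distance_matrix(one), one)
  expect_identical(rs1$n_comparisons, c(6L, 0L, 0L, 0L))
})

test_that("max intraspecific distances and low-divergence pairs", {
  ids <- sprintf("t%d", 1:4)
  seqs <- setNames(rep(leucine_seq(), 4L), ids)
  ds <- barcode_dataset(seqs, toy_meta(ids, species = c("A", "A", "B", "B")))
  mi <- max_intraspecific(distance_matrix(ds), ds)
  expect_identical(unname(mi), c(0, 0))   # identical sequences

  cfg <- sim_config(list(
    species_spec("near1", 3, 0.002, genus = "G1"),
    species_spec("near2", 3, 0.002, genus = "G1"),
    species_spec("far", 3, 0.002, genus = "G2")),
    target_inter_congeneric = 0.10, seed = 21L,
    ambiguous_pairs = list(list(a = "near1", b = "near2",
                                divergence = 0.03)))
  ds2 <- simulate_dataset(cfg)
  dm2 <- distance_matrix(ds2)
  pairs <- low_divergence_pairs(dm2, ds2, cutoff = 4.0)
  expect_identical(nrow(pairs), 1L)
  expect_setequal(c(pairs$species_a, pairs$species_b), c("near1", "near2"))
  expect_true(pairs$min > 1.5 && pairs$max < 4.5)
  expect_identical(nrow(low_divergence_pairs(dm2, ds2, cutoff = 0)), 0L)
})
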