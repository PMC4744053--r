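make_partition <- function(ids, motus, threshold = 0.036) {
  structure(list(assignment = setNames(as.integer(motus), ids),
                 threshold = threshold, method = "furthest_neighbor",
                 n_motus = length(unique(motus))),
            class = "motu_partition")
}

test_that("classification statuses follow the case logic", {
  ids <- sprintf("i%d", 1:7)
  species <- c("A", "A", "B", "B", "C", "D", "E")
  ds <- barcode_dataset(setNames(rep(leucine_seq(), 7L), ids),
                        toy_meta(ids, species = species))

  # identity partition: everything consistent
  ident <- classify(make_partition(ids, as.integer(factor(species))), ds)
  expect_true(all(ident$status %in% c("consistent", "singleton_consistent")))

  # A split into two pure MOTUs; B shares a MOTU with singleton C
  p <- make_partition(ids, c(1L, 2L, 3L, 3L, 3L, 4L, 5L))
  got <- classify(p, ds)
  expect_identical(got$status[got$morphospecies == "A"], "split")
  expect_identical(got$n_motus[got$morphospecies == "A"], 2L)
  expect_identical(got$status[got$morphospecies == "B"], "shared")
  expect_identical(got$partner_species[got$morphospecies == "B"], "C")
  expect_identical(got$status[got$morphospecies == "C"], "singleton_shared")
  expect_identical(got$status[got$morphospecies == "D"],
                   "singleton_consistent")

  # statuses always cover every morphospecies exactly once
  expect_identical(nrow(got), length(unique(species)))
  expect_identical(sum(table(got$status)), 5L)

  expect_error(classify(make_partition(ids[-1], 1:6), ds), "differ")
})

test_that("classify is all-consistent on identity partitions of random data", {
  for (seed in 4:6) {
    ds <- simulate_dataset(small_sim(n_species = 5L, n_per = 3L,
                                     seed = seed))
    p <- make_partition(rownames(ds$seq),
                        as.integer(factor(ds$meta$morphospecies)))
    expect_true(all(grepl("consistent", classify(p, ds)$status)))
  }
})

test_that("cryptic flags apply the divergence cutoff", {
  mi <- c(Stenagostus_like = 16.08, Mid = 4.9, Low = 0.3)
  fl <- flag_cryptic(mi, cutoff = 5.0)
  expect_identical(fl$morphospecies, "Stenagostus_like")
  expect_identical(fl$threshold_used, 5.0)
  expect_identical(nrow(flag_cryptic(c(a = 1, b = 2), 5.0)), 0L)
})

test_that("zone flags count the MOTUs dissolving between thresholds", {
  ids <- sprintf("z%d", 1:6)
  species <- c("A", "A", "B", "B", "C", "C")
  ds <- barcode_dataset(setNames(rep(leucine_seq(), 6L), ids),
                        toy_meta(ids, species = species))
  lo <- make_partition(ids, c(1L, 1L, 2L, 2L, 3L, 3L), 0.025)
  hi <- make_partition(ids, c(1L, 1L, 2L, 2L, 2L, 2L), 0.035)
  fl <- zone_diff(lo, hi, ds)
  expect_identical(sort(unique(fl$motu_low)), c(2L, 3L))
  expect_identical(lo$n_motus - hi$n_motus, 1L)
  expect_true(all(grepl("2.5% and 3.5%", fl$reason)))
  expect_identical(nrow(zone_diff(lo, lo, ds)), 0L)
})

test_that("a planted ambiguous-zone pair is flagged between 2.5% and 3.5%", {
  # long sequences keep the realized pair divergence tight around 3.0%
  cfg <- sim_config(list(
    species_spec("zoneA", 4, 0.002, genus = "G1"),
    species_spec("zoneB", 4, 0.002, genus = "G1"),
    species_spec("clear", 4, 0.002, genus = "G2")),
    target_inter_congeneric = 0.10, seed = 41L, seq_length = 6580L,
    ambiguous_pairs = list(list(a = "zoneA", b = "zoneB",
                                divergence = 0.030)))
  ds <- simulate_dataset(cfg)
  dm <- distance_matrix(ds)
  lo <- cluster_at(dm, 0.025)
  hi <- cluster_at(dm, 0.035)
  fl <- zone_diff(lo, hi, ds)
  expect_identical(lo$n_motus - hi$n_motus, 1L)
  expect_setequal(unique(unlist(strsplit(fl$species, ","))),
                  c("zoneA", "zoneB"))
  # and the sweep curve shows the same excess
  curve <- sweep_motus(dm, 2.5, 3.5, 1.0)
  expect_identical(curve$n_motus[1] - curve$n_motus[2],
                   lo$n_motus - hi$n_motus)
})

test_that("the pipeline on a clean dataset is fully consistent", {
  cfg <- small_sim(n_species = 6L, n_per = 4L, intra = 0.004,
                   inter = 0.10, seed = 19L)
  ds <- simulate_dataset(cfg)
  rep <- suppressWarnings(run_pipeline(ds))
  expect_s3_class(rep, "reconciliation_report")
  expect_identical(rep$partition$n_motus, 6L)
  expect_true(all(grepl("consistent", rep$classifications$status)))
  expect_identical(nrow(rep$cryptic_flags), 0L)
  expect_identical(nrow(rep$zone_flags), 0L)
  expect_identical(sum(table(rep$classifications$status)), 6L)
  # report writing produces the expected artifacts
  dir <- tempfile()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("rank_summaries.tsv", "classifications.tsv", "motu_assignment.tsv",
      "sweep.tsv", "nj_midpoint.nwk", "summary.txt")))))
})
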