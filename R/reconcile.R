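# Reconciling MOTU partitions against morphospecies labels: case
# classification (consistent / split / shared), cryptic-species flags,
# integrative-taxonomy-zone flags, and the end-to-end pipeline report.

#' Classify each morphospecies against a MOTU partition
#'
#' A morphospecies is `consistent` when its specimens occupy exactly one
#' MOTU containing no other species; `split` when they occupy two or more
#' MOTUs, each pure; and `shared` when any of its MOTUs also contains
#' another species. Sharing is the stronger conflict, so a species that is
#' both split and sharing is classified `shared`. Singleton species get
#' the statuses `singleton_consistent` / `singleton_shared` according to
#' whether their MOTU is private.
#'
#' @param partition A `motu_partition` covering the dataset.
#' @param ds The matching `barcode_dataset`.
#' @return Data frame with one row per morphospecies: `morphospecies`,
#'   `n_specimens`, `n_motus`, `status`, `partner_species`
#'   (comma-separated labels sharing a MOTU, empty otherwise).
#' @export
classify <- function(partition, ds) {
  stopifnot(inherits(partition, "motu_partition"),
            inherits(ds, "barcode_dataset"))
  ids <- rownames(ds$seq)
  if (!setequal(names(partition$assignment), ids))
    stop("partition and dataset sample ids differ", call. = FALSE)
  motu <- partition$assignment[ids]
  sp <- ds$meta$morphospecies

  motu_species <- tapply(sp, motu, unique)
  rows <- lapply(sort(unique(sp)), function(s) {
    mine <- unique(motu[sp == s])
    partners <- setdiff(unlist(motu_species[as.character(mine)]), s)
    n_spec <- sum(sp == s)
    shared <- length(partners) > 0L
    status <- if (n_spec == 1L) {
      if (shared) "singleton_shared" else "singleton_consistent"
    } else if (shared) {
      "shared"
    } else if (length(mine) > 1L) {
      "split"
    } else {
      "consistent"
    }
    data.frame(morphospecies = s, n_specimens = n_spec,
               n_motus = length(mine), status = status,
               partner_species = paste(sort(partners), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag cryptic-species candidates by maximum intraspecific divergence
#'
#' @param max_intra Named vector (percent) from [max_intraspecific()].
#' @param cutoff Percent; species exceeding it are flagged (default 5.0,
#'   the conventional cryptic-divergence bar).
#' @return Data frame `morphospecies`, `max_intra`, `threshold_used`,
#'   sorted by descending divergence.
#' @export
flag_cryptic <- function(max_intra, cutoff = 5.0) {
  hit <- max_intra[max_intra > cutoff]
  hit <- sort(hit, decreasing = TRUE)
  data.frame(morphospecies = names(hit), max_intra = unname(hit),
             threshold_used = rep(cutoff, length(hit)),
             stringsAsFactors = FALSE)
}

#' Flag MOTUs that dissolve between two thresholds
#'
#' Compares the partition at the lower threshold of the
#' integrative-taxonomy zone (conventionally 2.5%) with the one at the
#' upper threshold (3.5%): every MOTU of the low partition that is merged
#' with another at the high threshold is flagged, together with the
#' morphospecies involved. The number of excess MOTUs equals the
#' difference in MOTU counts.
#'
#' @param p_low,p_high `motu_partition`s of the same dataset at the lower
#'   and upper zone thresholds.
#' @param ds The matching `barcode_dataset`.
#' @return Data frame `motu_low`, `motu_high`, `species`, `reason`; zero
#'   rows when the partitions agree.
#' @export
zone_diff <- function(p_low, p_high, ds) {
  ids <- names(p_low$assignment)
  if (!setequal(ids, names(p_high$assignment)))
    stop("partitions cover different sample ids", call. = FALSE)
  lo <- p_low$assignment[ids]
  hi <- p_high$assignment[ids]
  sp <- ds$meta$morphospecies[match(ids, rownames(ds$seq))]

  # low-threshold MOTUs grouped by the high-threshold MOTU absorbing them
  lo_per_hi <- tapply(lo, hi, unique)
  merged_hi <- names(lo_per_hi)[vapply(lo_per_hi, length, 0L) > 1L]
  rows <- lapply(merged_hi, function(h) {
    members <- lo_per_hi[[h]]
    data.frame(
      motu_low = members,
      motu_high = as.integer(h),
      species = vapply(members, function(m)
        paste(sort(unique(sp[lo == m])), collapse = ","), ""),
      reason = sprintf("appears between %.1f%% and %.1f%% thresholds",
                       100 * p_low$threshold, 100 * p_high$threshold),
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(motu_low = integer(0), motu_high = integer(0),
                      species = character(0), reason = character(0)))
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' @param model Distance model (default `"k2p"`).
#' @param threshold MOTU threshold as a proportion (default 0.036, the
#'   conservative 3.6% recommendation for Denticollinae COI).
#' @param zone Lower/upper integrative-taxonomy zone thresholds in
#'   percent (default `c(2.5, 3.5)`).
#' @param sweep_grid `c(start, end, step)` in percent for the threshold
#'   sweep (default 0-8% by 0.1%).
#' @param cryptic_cutoff Percent for [flag_cryptic()] (default 5).
#' @param low_div_cutoff Percent for [low_divergence_pairs()] (default 4).
#' @param abgd An [abgd_config()].
#' @param run_ptp Whether to build the NJ tree and run PTP (default TRUE).
#' @param min_sites Minimum comparable sites per pair.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(model = "k2p", threshold = 0.036,
                            zone = c(2.5, 3.5),
                            sweep_grid = c(0, 8, 0.1),
                            cryptic_cutoff = 5.0, low_div_cutoff = 4.0,
                            abgd = abgd_config(), run_ptp = TRUE,
                            min_sites = 100L) {
  stopifnot(length(zone) == 2L, zone[1] < zone[2], threshold >= 0)
  structure(list(model = model, threshold = threshold, zone = zone,
                 sweep_grid = sweep_grid, cryptic_cutoff = cryptic_cutoff,
                 low_div_cutoff = low_div_cutoff, abgd = abgd,
                 run_ptp = run_ptp, min_sites = min_sites),
            class = "pipeline_config")
}

#' Run the full delimitation pipeline
#'
#' Distances, rank summaries, threshold sweep with plateau detection,
#' MOTU partitions at the working threshold and at both zone boundaries,
#' ABGD across the prior grid, a midpoint-rooted NJ tree with PTP
#' delimitation, and the reconciliation of the working partition against
#' morphospecies labels.
#'
#' @param ds A validated `barcode_dataset`.
#' @param config A [pipeline_config()].
#' @return Object of class `reconciliation_report`: a list with elements
#'   `rank_summaries`, `max_intra`, `low_divergence`, `sweep`, `plateaus`,
#'   `partition` (at the working threshold), `zone_partitions`,
#'   `zone_flags`, `abgd`, `abgd_table`, `tree`, `ptp`,
#'   `classifications`, `cryptic_flags`, `motu_counts` and `config`.
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "barcode_dataset"),
            inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  dm <- stage("distances",
              distance_matrix(ds, model = config$model,
                              min_sites = config$min_sites))
  summaries <- stage("rank_summaries", rank_summaries(dm, ds))
  mi <- stage("max_intraspecific", max_intraspecific(dm, ds))
  lowdiv <- stage("low_divergence_pairs",
                  low_divergence_pairs(dm, ds, config$low_div_cutoff))
  curve <- stage("sweep", sweep_motus(dm, config$sweep_grid[1],
                                      config$sweep_grid[2],
                                      config$sweep_grid[3]))
  plateaus <- stage("plateaus", find_plateaus(curve))
  part <- stage("cluster_at", cluster_at(dm, config$threshold))
  p_low <- stage("cluster_at_zone_low",
                 cluster_at(dm, config$zone[1] / 100))
  p_high <- stage("cluster_at_zone_high",
                  cluster_at(dm, config$zone[2] / 100))
  zflags <- stage("zone_diff", zone_diff(p_low, p_high, ds))
  abgd_res <- stage("abgd", abgd_partition(dm, config$abgd))

  tree <- NULL; ptp <- NULL
  if (config$run_ptp && length(dm$ids) >= 3L) {
    tree <- stage("nj_tree", root_tree(nj_tree(dm), "midpoint"))
    ptp <- stage("ptp", suppressWarnings(ptp_delimit(tree)))
  }

  classifications <- stage("classify", classify(part, ds))
  cflags <- stage("flag_cryptic", flag_cryptic(mi, config$cryptic_cutoff))

  motu_counts <- c(
    threshold = part$n_motus,
    zone_low = p_low$n_motus,
    zone_high = p_high$n_motus,
    abgd_median = as.integer(stats::median(abgd_table(abgd_res)$n_groups)),
    ptp = if (!is.null(ptp)) ptp$partition$n_motus else NA_integer_)

  structure(list(rank_summaries = summaries, max_intra = mi,
                 low_divergence = lowdiv, sweep = curve,
                 plateaus = plateaus, partition = part,
                 zone_partitions = list(low = p_low, high = p_high),
                 zone_flags = zflags, abgd = abgd_res,
                 abgd_table = abgd_table(abgd_res), tree = tree, ptp = ptp,
                 classifications = classifications, cryptic_flags = cflags,
                 motu_counts = motu_counts, config = config),
            class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  n_sp <- nrow(x$classifications)
  tab <- table(x$classifications$status)
  cat("reconciliation_report\n")
  cat(sprintf("  MOTUs at %.1f%% threshold: %d\n",
              100 * x$config$threshold, x$partition$n_motus))
  cat(sprintf("  MOTUs at zone %.1f%% / %.1f%%: %d / %d (excess %d)\n",
              x$config$zone[1], x$config$zone[2],
              x$motu_counts[["zone_low"]], x$motu_counts[["zone_high"]],
              x$motu_counts[["zone_low"]] - x$motu_counts[["zone_high"]]))
  if (!is.na(x$motu_counts[["ptp"]]))
    cat(sprintf("  PTP species: %d%s\n", x$motu_counts[["ptp"]],
                if (x$ptp$low_confidence) " [low confidence]" else ""))
  cat(sprintf("  morphospecies: %d (%s)\n", n_sp,
              paste(names(tab), as.integer(tab), sep = "=",
                    collapse = ", ")))
  cat(sprintf("  cryptic flags (> %.1f%%): %d\n",
              x$config$cryptic_cutoff, nrow(x$cryptic_flags)))
  invisible(x)
}

#' Write a reconciliation report to a directory
#'
#' Emits tab-separated tables (rank summaries, classifications, cryptic
#' and zone flags, low-divergence pairs, sweep curve, ABGD table, MOTU
#' assignments), the newick tree, and a plain-text summary.
#'
#' @param report A `reconciliation_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tsv(report$rank_summaries, "rank_summaries.tsv")
  tsv(data.frame(morphospecies = names(report$max_intra),
                 max_intra = unname(report$max_intra)), "max_intra.tsv")
  tsv(report$low_divergence, "low_divergence_pairs.tsv")
  tsv(as.data.frame(report$sweep), "sweep.tsv")
  tsv(report$plateaus, "plateaus.tsv")
  tsv(report$classifications, "classifications.tsv")
  tsv(report$cryptic_flags, "cryptic_flags.tsv")
  tsv(report$zone_flags, "zone_flags.tsv")
  tsv(report$abgd_table, "abgd_table.tsv")
  write_assignment(report$partition,
                   file.path(dir, "motu_assignment.tsv"),
                   file.path(dir, "motu_assignment.list"))
  if (!is.null(report$tree))
    write_newick(report$tree, file.path(dir, "nj_midpoint.nwk"))
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(report); sink(); close(con)
  invisible(dir)
}
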