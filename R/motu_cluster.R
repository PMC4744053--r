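# Furthest-neighbor (complete-linkage) threshold clustering into MOTUs,
# threshold sweeps and plateau detection.
#
# All partitions at all thresholds are cuts of one complete-linkage
# dendrogram, so increasing the threshold can only merge MOTUs (the
# partition at a lower threshold refines the one at a higher threshold)
# and the sweep curve is non-increasing by construction. The threshold is
# inclusive: clusters whose complete linkage equals the threshold exactly
# are merged, matching mothur's convention of reporting clusters "at"
# a distance.

complete_linkage <- function(dm) {
  vals <- dm$values
  off <- upper.tri(vals)
  if (anyNA(vals[off]))
    stop("distance matrix has undefined entries; clustering requires a ",
         "complete matrix", call. = FALSE)
  d <- stats::as.dist(vals)
  attr(d, "Labels") <- dm$ids
  stats::hclust(d, method = "complete")
}

relabel_first_appearance <- function(memb, ids) {
  motu <- match(memb, unique(memb))
  names(motu) <- ids
  motu
}

new_motu_partition <- function(assignment, threshold, method) {
  structure(list(assignment = assignment,
                 threshold = threshold,
                 method = method,
                 n_motus = length(unique(assignment))),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("motu_partition (", x$method, "): ", x$n_motus, " MOTUs over ",
      length(x$assignment), " sequences",
      if (!is.na(x$threshold))
        sprintf(" at threshold %.2f%%", 100 * x$threshold), "\n", sep = "")
  invisible(x)
}

#' Cluster sequences into MOTUs at a distance threshold
#'
#' Furthest-neighbor (complete-linkage) agglomeration: clusters are merged
#' while the maximum pairwise distance between them is at most the
#' threshold (inclusive). Consequently every within-MOTU pairwise distance
#' is at most the threshold. MOTU ids are assigned by order of first
#' member appearance in the input.
#'
#' @param dm A `barcode_dist` with no undefined entries.
#' @param threshold Distance threshold as a proportion (e.g. `0.036` for
#'   the conservative 3.6% recommendation for Denticollinae COI).
#' @return A `motu_partition` with `method = "furthest_neighbor"`.
#' @export
cluster_at <- function(dm, threshold) {
  stopifnot(inherits(dm, "barcode_dist"), threshold >= 0)
  if (length(dm$ids) == 1L)
    return(new_motu_partition(stats::setNames(1L, dm$ids), threshold,
                              "furthest_neighbor"))
  hc <- complete_linkage(dm)
  memb <- stats::cutree(hc, h = threshold)
  new_motu_partition(relabel_first_appearance(memb, dm$ids), threshold,
                     "furthest_neighbor")
}

#' MOTU counts across a grid of thresholds
#'
#' Evaluates [cluster_at()] on every grid point (one dendrogram, many
#' cuts). Grid units are percent to match how thresholds are quoted in
#' barcoding practice.
#'
#' @param dm A `barcode_dist`.
#' @param grid_start,grid_end,step Threshold grid in percent (defaults
#'   0-8% in 0.1% steps, bracketing the plateaus discussed for COI
#'   barcodes).
#' @return Object of class `sweep_curve`: data frame with `threshold_pct`
#'   and `n_motus` (non-increasing).
#' @export
sweep_motus <- function(dm, grid_start = 0, grid_end = 8, step = 0.1) {
  stopifnot(step > 0, grid_end >= grid_start)
  grid <- seq(grid_start, grid_end, by = step)
  n <- length(dm$ids)
  if (n == 1L) {
    counts <- rep(1L, length(grid))
  } else {
    hc <- complete_linkage(dm)
    h <- sort(hc$height)
    # merges with height <= t have happened at threshold t (inclusive)
    counts <- n - findInterval(grid / 100, h)
  }
  structure(data.frame(threshold_pct = grid, n_motus = as.integer(counts)),
            class = c("sweep_curve", "data.frame"))
}

#' Maximal constant-count plateaus of a sweep curve
#'
#' A plateau is a maximal run of consecutive grid points with the same
#' MOTU count; long plateaus mark threshold ranges where delimitation is
#' insensitive to the cut-off choice.
#'
#' @param curve A `sweep_curve`.
#' @param min_length Minimum run length (grid steps) to report.
#' @return Data frame `start`, `end` (percent), `count`, `length`
#'   (steps), ordered by `start`.
#' @export
find_plateaus <- function(curve, min_length = 2L) {
  stopifnot(nrow(curve) > 0L)
  r <- rle(curve$n_motus)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_length
  data.frame(start = curve$threshold_pct[starts[keep]],
             end = curve$threshold_pct[ends[keep]],
             count = r$values[keep],
             length = r$lengths[keep])
}

#' Write a MOTU assignment table
#'
#' Tab-separated `sample_id`, `motu_id` plus a mothur-like list line
#' (threshold, count, clusters with members comma-delimited).
#'
#' @param partition A `motu_partition`.
#' @param path Output path for the assignment table.
#' @param list_path Optional path for the mothur-like list line.
#' @return Invisibly, `partition`.
#' @export
write_assignment <- function(partition, path, list_path = NULL) {
  utils::write.table(
    data.frame(sample_id = names(partition$assignment),
               motu_id = partition$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(list_path)) {
    groups <- split(names(partition$assignment), partition$assignment)
    line <- paste(c(format(partition$threshold), partition$n_motus,
                    vapply(groups, paste, "", collapse = ",")),
                  collapse = "\t")
    writeLines(line, list_path)
  }
  invisible(partition)
}
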