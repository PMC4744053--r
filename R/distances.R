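# Pairwise genetic distances (p, JC69, K2P) and rank-stratified summaries.
#
# Distances are stored as proportions throughout; report-facing summaries
# are rendered as percentages. Sites where either sequence carries a gap,
# N or an IUPAC ambiguity code are excluded pair by pair (pairwise
# deletion), and ambiguity codes never count as transitions or
# transversions.

DIST_MODELS <- c("k2p", "jc69", "p")

# A,C,G,T -> 1..4; everything else (gap/N/ambiguity) is missing.
encode_acgt <- function(seq_mat) {
  code <- match(seq_mat, c("A", "C", "G", "T"))
  dim(code) <- dim(seq_mat)
  rownames(code) <- rownames(seq_mat)
  code
}

k2p_from_counts <- function(ts, tv, n) {
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d, sat = w1 <= 0 | w2 <= 0)
}

jc69_from_p <- function(p) {
  arg <- 1 - 4 * p / 3
  list(d = -0.75 * log(arg), sat = arg <= 0)
}

#' Pairwise distance between two aligned sequences
#'
#' Computes the raw mismatch proportion `p`, the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`, or the Kimura 2-parameter correction
#' `d = -(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q))`, where `P` and `Q` are the
#' transition (A<->G, C<->T) and transversion proportions over the sites
#' comparable in both sequences.
#'
#' @param x,y Aligned sequences: strings, or character vectors of single
#'   characters, of equal length.
#' @param model One of `"k2p"`, `"jc69"`, `"p"`.
#' @param min_sites Minimum number of comparable sites for a usable pair.
#' @return List with `distance` (proportion; `NA` if the pair has fewer
#'   than `min_sites` comparable sites) and `comparable_sites`.
#' @export
pair_distance <- function(x, y, model = c("k2p", "jc69", "p"),
                          min_sites = 100L) {
  model <- match.arg(model)
  if (is.character(x) && length(x) == 1L) x <- strsplit(toupper(x), "")[[1]]
  if (is.character(y) && length(y) == 1L) y <- strsplit(toupper(y), "")[[1]]
  if (length(x) != length(y))
    stop("sequences differ in length", call. = FALSE)
  cx <- match(x, c("A", "C", "G", "T"))
  cy <- match(y, c("A", "C", "G", "T"))
  use <- !is.na(cx) & !is.na(cy)
  n <- sum(use)
  if (n < min_sites) {
    warning("pair excluded: only ", n, " comparable sites (< ", min_sites,
            ")", call. = FALSE)
    return(list(distance = NA_real_, comparable_sites = n))
  }
  ts <- sum(use & abs(cx - cy) == 2L)            # A<->G (1,3), C<->T (2,4)
  mm <- sum(use & cx != cy)
  tv <- mm - ts
  d <- switch(model,
    p = mm / n,
    jc69 = {
      r <- jc69_from_p(mm / n)
      if (r$sat) stop("saturated pair: JC69 undefined", call. = FALSE)
      r$d
    },
    k2p = {
      r <- k2p_from_counts(ts, tv, n)
      if (r$sat) stop("saturated pair: K2P undefined", call. = FALSE)
      r$d
    })
  list(distance = d, comparable_sites = n)
}

#' Full pairwise distance matrix for a barcode dataset
#'
#' Vectorised over the whole alignment: per-base indicator matrices give
#' comparable-site, transition and transversion counts for all pairs via
#' matrix products, so the 421 x 421 case runs in well under a second.
#'
#' @param ds A `barcode_dataset`.
#' @param model One of `"k2p"`, `"jc69"`, `"p"`.
#' @param min_sites Pairs with fewer comparable sites are set `NA` with a
#'   warning.
#' @param on_saturation `"error"` (default) aborts when a correction's log
#'   argument is non-positive; `"cap"` replaces such distances with the
#'   largest finite distance in the matrix.
#' @return Object of class `barcode_dist`: list with `ids`, `values`
#'   (symmetric matrix of proportions, zero diagonal), `model` and
#'   `comparable_sites` (symmetric integer matrix).
#' @export
distance_matrix <- function(ds, model = c("k2p", "jc69", "p"),
                            min_sites = 100L,
                            on_saturation = c("error", "cap")) {
  stopifnot(inherits(ds, "barcode_dataset"))
  model <- match.arg(model)
  on_saturation <- match.arg(on_saturation)
  code <- encode_acgt(ds$seq)
  n <- nrow(code)

  ind <- lapply(1:4, function(b) {
    m <- (code == b)
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  V <- !is.na(code)
  storage.mode(V) <- "double"
  comparable <- tcrossprod(V)
  storage.mode(comparable) <- "integer"
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  ts <- tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]) +
        tcrossprod(ind[[2]], ind[[4]]) + tcrossprod(ind[[4]], ind[[2]])
  mm <- comparable - matches
  tv <- mm - ts

  # NaNs from saturated pairs are expected here; they are trapped below
  vals <- suppressWarnings(switch(model,
    p = mm / comparable,
    jc69 = jc69_from_p(mm / comparable)$d,
    k2p = k2p_from_counts(ts, tv, comparable)$d))
  diag(vals) <- 0

  off <- upper.tri(vals)
  sat <- off & !is.finite(vals)
  if (any(sat)) {
    if (on_saturation == "error")
      stop("saturated pair(s): ", model, " distance undefined for ",
           sum(sat), " pair(s); rerun with on_saturation = \"cap\"",
           call. = FALSE)
    cap <- max(vals[off & is.finite(vals)])
    vals[!is.finite(vals)] <- cap
  }

  low <- off & comparable < min_sites
  if (any(low)) {
    warning(sum(low), " pair(s) excluded: fewer than ", min_sites,
            " comparable sites", call. = FALSE)
    vals[low] <- NA_real_
    vals[t(low)] <- NA_real_
  }

  structure(list(ids = rownames(ds$seq), values = vals, model = model,
                 comparable_sites = comparable, min_sites = min_sites),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat("barcode_dist (", x$model, "): ", length(x$ids), " sequences, ",
      length(off), " pairs; range ",
      sprintf("%.2f%%-%.2f%%", 100 * min(off, na.rm = TRUE),
              100 * max(off, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

stratum_of_pairs <- function(ds) {
  sp <- ds$meta$morphospecies
  ge <- ds$meta$genus
  tr <- ds$meta$tribe
  same_sp <- outer(sp, sp, "==")
  same_ge <- outer(ge, ge, "==")
  same_tr <- outer(tr, tr, "==")
  strat <- ifelse(same_sp, "within_species",
           ifelse(same_ge, "within_genus_between_species",
           ifelse(same_tr, "within_tribe_between_genera", "between_tribes")))
  strat
}

RANK_STRATA <- c("within_species", "within_genus_between_species",
                 "within_tribe_between_genera", "between_tribes")

#' Distance summaries stratified by taxonomic rank
#'
#' Every unordered sequence pair contributes to exactly one of four
#' strata: within species; within genus, between species; within tribe,
#' between genera; between tribes. The standard error reported is the
#' sample standard deviation of the stratum's distances divided by the
#' square root of the comparison count (an analytic proxy, not a
#' bootstrap).
#'
#' @param dm A `barcode_dist`.
#' @param ds The `barcode_dataset` the matrix was computed from.
#' @return Data frame with one row per stratum: `stratum`,
#'   `n_comparisons`, and `mean`, `min`, `max`, `se` in percent.
#' @export
rank_summaries <- function(dm, ds) {
  stopifnot(identical(dm$ids, rownames(ds$seq)))
  strat <- stratum_of_pairs(ds)
  off <- upper.tri(dm$values)
  s <- factor(strat[off], levels = RANK_STRATA)
  d <- 100 * dm$values[off]
  agg <- function(f, ...) {
    v <- tapply(d, s, f, ...)
    as.numeric(v)
  }
  n <- as.integer(table(s))
  out <- data.frame(
    stratum = RANK_STRATA,
    n_comparisons = n,
    mean = agg(mean, na.rm = TRUE),
    min = agg(min, na.rm = TRUE),
    max = agg(max, na.rm = TRUE),
    se = agg(stats::sd, na.rm = TRUE) / sqrt(n),
    stringsAsFactors = FALSE)
  out$mean[n == 0L] <- NA_real_
  out$min[n == 0L] <- NA_real_
  out$max[n == 0L] <- NA_real_
  out$se[n == 0L] <- NA_real_
  out
}

#' Maximum intraspecific distance per multi-specimen morphospecies
#'
#' @param dm A `barcode_dist`.
#' @param ds Matching `barcode_dataset`.
#' @return Named numeric vector (percent), one entry per morphospecies
#'   with at least two specimens.
#' @export
max_intraspecific <- function(dm, ds) {
  stopifnot(identical(dm$ids, rownames(ds$seq)))
  sp <- ds$meta$morphospecies
  multi <- names(which(table(sp) >= 2L))
  out <- vapply(multi, function(s) {
    i <- which(sp == s)
    max(dm$values[i, i], na.rm = TRUE)
  }, 0)
  sort(100 * out, decreasing = TRUE)
}

#' Congeneric species pairs with low interspecific divergence
#'
#' @param dm A `barcode_dist`.
#' @param ds Matching `barcode_dataset`.
#' @param cutoff Percent; congeneric species pairs whose minimum
#'   interspecific distance is below this value are reported.
#' @return Data frame: `species_a`, `species_b`, `genus`, `min`, `max`
#'   (percent), `n_pairs`; sorted by `min`.
#' @export
low_divergence_pairs <- function(dm, ds, cutoff = 4.0) {
  stopifnot(identical(dm$ids, rownames(ds$seq)), cutoff >= 0)
  sp <- ds$meta$morphospecies
  ge <- ds$meta$genus
  sp_genus <- tapply(ge, sp, function(g) g[[1]])
  species <- names(sp_genus)
  rows <- list()
  for (g in unique(ge)) {
    in_g <- species[sp_genus == g]
    if (length(in_g) < 2L) next
    cmb <- utils::combn(sort(in_g), 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- which(sp == cmb[1L, k]); b <- which(sp == cmb[2L, k])
      dd <- dm$values[a, b, drop = FALSE]
      if (100 * min(dd, na.rm = TRUE) < cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          species_a = cmb[1L, k], species_b = cmb[2L, k], genus = g,
          min = 100 * min(dd, na.rm = TRUE),
          max = 100 * max(dd, na.rm = TRUE),
          n_pairs = length(dd), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(species_a = character(0), species_b = character(0),
                      genus = character(0), min = numeric(0),
                      max = numeric(0), n_pairs = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$min), , drop = FALSE]
}

#' Write a distance matrix as a square tab-separated table
#'
#' PHYLIP-style square format at full precision, plus an optional
#' long-format pair table.
#'
#' @param dm A `barcode_dist`.
#' @param path Output path for the square matrix.
#' @param long_path Optional path for a long-format `(id_a, id_b,
#'   distance, comparable_sites)` table.
#' @return Invisibly, `dm`.
#' @export
write_distance_matrix <- function(dm, path, long_path = NULL) {
  m <- dm$values
  dimnames(m) <- list(dm$ids, dm$ids)
  utils::write.table(format(m, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    utils::write.table(
      data.frame(id_a = dm$ids[idx[, 1]], id_b = dm$ids[idx[, 2]],
                 distance = m[idx],
                 comparable_sites = dm$comparable_sites[idx]),
      long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dm)
}
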