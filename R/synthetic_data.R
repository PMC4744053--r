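# Simulation of barcode libraries with controlled divergence structure.
#
# Sequences evolve along an ultrametric hierarchy (tribe > genus >
# species > specimens) under the continuous-time Kimura 2-parameter
# model, applied per site with the closed-form transition probabilities
# at each branch length. Branch lengths are chosen by inverting the
# expected-distance relation (the K2P estimator is consistent for the
# true branch-path length under this model), so realized mean pairwise
# K2P divergences converge to the configured targets as the sequence
# length grows. Within-species genealogies are star trees of equal
# branch lengths (expected pairwise divergence = target exactly), and
# the reading frame is kept free of stop codons so that pseudogene
# screening stays clean unless Numt corruption is requested explicitly.

#' Species specification for the simulator
#'
#' @param label Morphospecies label (also used to build sample ids).
#' @param n_specimens Number of specimens (tips) to simulate.
#' @param target_intra Expected pairwise K2P divergence within the species
#'   (proportion, `0 <= target_intra < 0.2`). With subclusters this is the
#'   divergence *between* subclusters (the species' maximum-scale
#'   intraspecific divergence).
#' @param genus,tribe Taxonomic labels.
#' @param n_subclusters Number of divergent lineages within the species
#'   (default 1, a plain star genealogy). Divergent morphospecies in real
#'   barcode libraries are typically a few tight haplotype clusters, not a
#'   uniform cloud; `n_subclusters = 2` emulates a cryptic split.
#' @param subcluster_intra Expected pairwise divergence within each
#'   subcluster (required < `target_intra` when `n_subclusters > 1`;
#'   default `target_intra / 5`).
#' @return List of class `species_spec`.
#' @export
species_spec <- function(label, n_specimens, target_intra = 0.008,
                         genus = "GenusA", tribe = "TribeA",
                         n_subclusters = 1L, subcluster_intra = NULL) {
  if (n_specimens < 1L) stop("n_specimens must be >= 1", call. = FALSE)
  if (target_intra < 0 || target_intra >= 0.2)
    stop("target_intra must be in [0, 0.2)", call. = FALSE)
  if (n_subclusters < 1L || n_subclusters > n_specimens)
    stop("n_subclusters must be in 1..n_specimens", call. = FALSE)
  if (is.null(subcluster_intra)) subcluster_intra <- target_intra / 5
  if (n_subclusters > 1L && subcluster_intra >= target_intra)
    stop("subcluster_intra must be below target_intra", call. = FALSE)
  structure(list(label = label, n_specimens = as.integer(n_specimens),
                 target_intra = target_intra, genus = genus, tribe = tribe,
                 n_subclusters = as.integer(n_subclusters),
                 subcluster_intra = subcluster_intra),
            class = "species_spec")
}

#' Simulator configuration
#'
#' @param species List of [species_spec()] objects.
#' @param target_inter_congeneric Expected pairwise K2P divergence between
#'   congeneric species (proportion); must exceed every species'
#'   `target_intra`.
#' @param kappa Transition/transversion rate ratio of the Kimura model.
#' @param seq_length Alignment length in bp (default 658, the Folmer COI
#'   fragment).
#' @param seed Integer seed; fixing it fixes the output byte-for-byte.
#' @param numt_fraction Fraction of sequences to corrupt with an in-frame
#'   TAA stop codon (exactly `round(numt_fraction * n)` sequences).
#' @param inter_genus,inter_tribe Expected divergence between genera
#'   within a tribe and between tribes.
#' @param ambiguous_pairs Optional list of `list(a, b, divergence)`
#'   entries placing a congeneric species pair at a stated divergence
#'   (e.g. inside the 2.5-3.5% integrative-taxonomy zone).
#' @param frame_offset Reading-frame offset used to keep simulated
#'   sequences stop-free (default 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(species, target_inter_congeneric = 0.117,
                       kappa = 4, seq_length = 658L, seed = 1L,
                       numt_fraction = 0, inter_genus = 0.198,
                       inter_tribe = 0.202, ambiguous_pairs = NULL,
                       frame_offset = 1L) {
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, TRUE, "species_spec")))
  max_intra <- max(vapply(species, function(s) s$target_intra, 0))
  if (target_inter_congeneric <= max_intra)
    stop("infeasible targets: target_inter_congeneric (",
         target_inter_congeneric, ") must exceed the largest target_intra (",
         max_intra, ")", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (seq_length < 3L) stop("seq_length too short", call. = FALSE)
  if (numt_fraction < 0 || numt_fraction > 1)
    stop("numt_fraction must be in [0, 1]", call. = FALSE)
  if (!(target_inter_congeneric < inter_genus && inter_genus < inter_tribe))
    stop("require target_inter_congeneric < inter_genus < inter_tribe",
         call. = FALSE)
  labels <- vapply(species, function(s) s$label, "")
  if (anyDuplicated(labels))
    stop("duplicate species labels", call. = FALSE)
  for (p in ambiguous_pairs) {
    a <- species[[match(p$a, labels)]]; b <- species[[match(p$b, labels)]]
    if (is.null(a) || is.null(b) || !identical(a$genus, b$genus))
      stop("ambiguous_pairs must name two congeneric species",
           call. = FALSE)
    if (p$divergence <= max(a$target_intra, b$target_intra) ||
        p$divergence >= target_inter_congeneric)
      stop("ambiguous pair divergence must lie between the species' ",
           "target_intra and target_inter_congeneric", call. = FALSE)
  }
  structure(list(species = species,
                 target_inter_congeneric = target_inter_congeneric,
                 kappa = kappa, seq_length = as.integer(seq_length),
                 seed = as.integer(seed), numt_fraction = numt_fraction,
                 inter_genus = inter_genus, inter_tribe = inter_tribe,
                 ambiguous_pairs = ambiguous_pairs,
                 frame_offset = as.integer(frame_offset)),
            class = "sim_config")
}

# --- K2P per-site evolution -------------------------------------------------

# int codes: A=1, C=2, G=3, T=4
K2P_TS_TARGET <- c(3L, 4L, 1L, 2L)    # A->G, C->T, G->A, T->C
K2P_TV_A <- c(2L, 1L, 2L, 1L)         # first transversion target
K2P_TV_B <- c(4L, 3L, 4L, 3L)         # second transversion target

evolve_k2p <- function(seq_int, d, kappa) {
  if (d <= 0) return(seq_int)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.5 - 0.5 * e1          # both transversion targets combined
  u <- stats::runif(length(seq_int))
  out <- seq_int
  is_ts <- u < p_ts
  is_tv <- !is_ts & u < p_ts + p_tv
  out[is_ts] <- K2P_TS_TARGET[seq_int[is_ts]]
  if (any(is_tv)) {
    pick <- stats::runif(sum(is_tv)) < 0.5
    out[is_tv] <- ifelse(pick, K2P_TV_A[seq_int[is_tv]],
                         K2P_TV_B[seq_int[is_tv]])
  }
  out
}

codon_starts <- function(seq_length, frame_offset) {
  seq.int(frame_offset + 1L, seq_length - 2L, by = 3L)
}

find_stop_codons <- function(seq_int, starts) {
  c1 <- seq_int[starts]; c2 <- seq_int[starts + 1L]; c3 <- seq_int[starts + 2L]
  # TAA = 4,1,1 ; TAG = 4,1,3 under the invertebrate mitochondrial code
  starts[c1 == 4L & c2 == 1L & (c3 == 1L | c3 == 3L)]
}

repair_stops <- function(child, parent, starts) {
  bad <- find_stop_codons(child, starts)
  for (s in bad) child[s:(s + 2L)] <- parent[s:(s + 2L)]
  child
}

random_stop_free_root <- function(seq_length, starts) {
  s <- sample.int(4L, seq_length, replace = TRUE)
  repeat {
    bad <- find_stop_codons(s, starts)
    if (!length(bad)) break
    for (b in bad) s[b:(b + 2L)] <- sample.int(4L, 3L, replace = TRUE)
  }
  s
}

# --- genealogy construction -------------------------------------------------

sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

# Recursive newick for an ultrametric hierarchy; single-child groups are
# collapsed so the resulting tree has no degree-2 internal nodes.
group_newick <- function(node, parent_depth) {
  if (!is.null(node$tip))
    return(sprintf("%s:%.10f", node$tip, parent_depth))
  if (length(node$children) == 1L)
    return(group_newick(node$children[[1L]], parent_depth))
  inner <- vapply(node$children, group_newick, "",
                  parent_depth = node$depth)
  sprintf("(%s):%.10f", paste(inner, collapse = ","),
          parent_depth - node$depth)
}

build_true_tree <- function(cfg) {
  d_sp <- function(s) s$target_intra / 2
  d_amb <- function(div) div / 2
  d_gen <- cfg$target_inter_congeneric / 2
  d_tri <- cfg$inter_genus / 2
  d_root <- cfg$inter_tribe / 2

  labels <- vapply(cfg$species, function(s) s$label, "")
  species_group <- function(s) {
    ids <- sprintf("%s_%02d", sanitize_id(s$label), seq_len(s$n_specimens))
    if (s$n_specimens == 1L) return(list(tip = ids, ids = ids, label = s$label))
    if (s$n_subclusters == 1L)
      return(list(depth = d_sp(s), ids = ids, label = s$label,
                  children = lapply(ids, function(id) list(tip = id))))
    grp <- rep_len(seq_len(s$n_subclusters), s$n_specimens)
    subs <- lapply(split(ids, grp), function(sub_ids) {
      if (length(sub_ids) == 1L) return(list(tip = sub_ids))
      list(depth = s$subcluster_intra / 2,
           children = lapply(sub_ids, function(id) list(tip = id)))
    })
    list(depth = d_sp(s), ids = ids, label = s$label, children = subs)
  }
  amb_of <- character(0)
  for (p in cfg$ambiguous_pairs) amb_of <- c(amb_of, p$a, p$b)

  tribes <- unique(vapply(cfg$species, function(s) s$tribe, ""))
  tribe_nodes <- lapply(tribes, function(tb) {
    sp_in_tribe <- Filter(function(s) s$tribe == tb, cfg$species)
    genera <- unique(vapply(sp_in_tribe, function(s) s$genus, ""))
    genus_nodes <- lapply(genera, function(g) {
      sp_in_g <- Filter(function(s) s$genus == g, sp_in_tribe)
      lab_in_g <- vapply(sp_in_g, function(s) s$label, "")
      kids <- list()
      used <- character(0)
      for (p in cfg$ambiguous_pairs) {
        if (!(p$a %in% lab_in_g)) next
        pa <- sp_in_g[[match(p$a, lab_in_g)]]
        pb <- sp_in_g[[match(p$b, lab_in_g)]]
        kids[[length(kids) + 1L]] <- list(
          depth = d_amb(p$divergence),
          children = list(species_group(pa), species_group(pb)))
        used <- c(used, p$a, p$b)
      }
      for (s in sp_in_g)
        if (!(s$label %in% used))
          kids[[length(kids) + 1L]] <- species_group(s)
      list(depth = d_gen, children = kids)
    })
    list(depth = d_tri, children = genus_nodes)
  })
  root <- list(depth = d_root, children = tribe_nodes)
  read_newick(text = paste0(group_newick_root(root), ";"))
}

group_newick_root <- function(root) {
  node <- root
  while (is.null(node$tip) && length(node$children) == 1L)
    node <- node$children[[1L]]
  if (!is.null(node$tip))
    stop("cannot build a tree for a single sequence", call. = FALSE)
  # keep the root binary (ape's rootedness criterion): fold extra children
  # in at the same depth via zero-length internal edges
  while (length(node$children) > 2L) {
    k <- length(node$children)
    node$children <- c(node$children[seq_len(k - 2L)],
                       list(list(depth = node$depth,
                                 children = node$children[(k - 1L):k])))
  }
  inner <- vapply(node$children, group_newick, "", parent_depth = node$depth)
  sprintf("(%s)", paste(inner, collapse = ","))
}

true_partition <- function(cfg) {
  out <- character(0)
  for (s in cfg$species) {
    ids <- sprintf("%s_%02d", sanitize_id(s$label), seq_len(s$n_specimens))
    out[ids] <- s$label
  }
  out
}

# --- main entry points ------------------------------------------------------

#' Simulate a barcode dataset with its true genealogy
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a `barcode_dataset`), `tree` (the true
#'   genealogy as a rooted `phylo` with the simulated tips), and
#'   `partition` (named character vector: true species per tip). Numt
#'   corruption, when requested, is recorded in
#'   `attr(dataset, "numt_ids")`.
#' @export
simulate_tree_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tr <- build_true_tree(cfg)
  ntip <- ape::Ntip(tr)
  starts <- codon_starts(cfg$seq_length, cfg$frame_offset)

  n_nodes <- ntip + tr$Nnode
  seqs <- matrix(0L, n_nodes, cfg$seq_length)
  root <- ntip + 1L
  seqs[root, ] <- random_stop_free_root(cfg$seq_length, starts)
  ord <- ape::reorder.phylo(tr, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    child <- evolve_k2p(seqs[p, ], ord$edge.length[i], cfg$kappa)
    seqs[ch, ] <- repair_stops(child, seqs[p, ], starts)
  }

  tip_seqs <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(tip_seqs) <- tr$tip.label

  numt_ids <- character(0)
  k <- round(cfg$numt_fraction * ntip)
  if (k > 0L) {
    numt_ids <- sort(sample(tr$tip.label, k))
    mid <- starts[max(2L, length(starts) %/% 2L)]
    for (id in numt_ids)
      tip_seqs[id, mid:(mid + 2L)] <- c(4L, 1L, 1L)   # TAA
  }

  chars <- matrix(c("A", "C", "G", "T")[tip_seqs], nrow = ntip,
                  dimnames = list(rownames(tip_seqs), NULL))
  part <- true_partition(cfg)[rownames(chars)]
  meta <- data.frame(
    sample_id = rownames(chars),
    morphospecies = unname(part),
    genus = vapply(cfg$species, function(s) s$genus,
                   "")[match(part, vapply(cfg$species,
                                          function(s) s$label, ""))],
    tribe = vapply(cfg$species, function(s) s$tribe,
                   "")[match(part, vapply(cfg$species,
                                          function(s) s$label, ""))],
    country = "simulated",
    province = "",
    source = "field",
    stringsAsFactors = FALSE)
  ds <- barcode_dataset(chars, meta, frame_offset = cfg$frame_offset)
  attr(ds, "numt_ids") <- numt_ids
  list(dataset = ds, tree = tr, partition = part)
}

#' Simulate a barcode dataset
#'
#' Convenience wrapper around [simulate_tree_dataset()] returning only the
#' dataset.
#'
#' @param cfg A [sim_config()].
#' @return A `barcode_dataset`.
#' @export
simulate_dataset <- function(cfg) {
  simulate_tree_dataset(cfg)$dataset
}

#' Study-shaped default configuration
#'
#' Emulates the structure of a Denticollinae (Elateridae) COI barcode
#' library: 3 tribes, 36 genera, 84 morphospecies and 421 specimens, of
#' which 38 morphospecies are singletons. Most species carry low
#' intraspecific divergence (< 2%), a band of species sits at 2.2-4.8%,
#' five deeply sampled species carry cryptic-scale divergence (> 5%), and
#' a configurable fraction of congeneric species pairs is planted inside
#' the 2.1-3.5% ambiguous zone. Congeneric interspecific divergence
#' targets 11.7%, between-genus 19.8% and between-tribe 20.2%.
#'
#' @param seed Integer seed.
#' @param ambiguous_fraction Fraction of multi-species genera given one
#'   species pair in the ambiguous zone (default 0.2, i.e. 4 of 22).
#' @return A [sim_config()].
#' @export
default_study_config <- function(seed = 1L, ambiguous_fraction = 0.2) {
  set.seed(seed %% 2147483647L)
  genus_sizes <- c(rep(1L, 14), rep(2L, 10), rep(3L, 6), rep(4L, 3),
                   rep(5L, 2), 10L)                     # 36 genera, 84 spp
  tribe_of_genus <- rep(c("Ctenicerini", "Denticollini", "Hypnoidini"),
                        c(18L, 12L, 6L))
  n_multi <- c(16L, 15L, 11L, 10L,
               rep(c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L,
                     13L, 14L), 3L), 5L, 6L, 8L)         # 46 sizes, sum 383
  sizes <- sample(c(n_multi, rep(1L, 38)))               # 84 spp, sum 421

  # intraspecific targets: 5 cryptic-scale and 13 intermediate species are
  # pairs of tight subclusters (divergent lineages), the rest plain stars
  intra <- numeric(84)
  subclusters <- rep(1L, 84)
  multi_idx <- which(sizes >= 2L)
  cryptic <- multi_idx[order(-sizes[multi_idx])][1:5]
  intra[cryptic] <- c(0.105, 0.11, 0.078, 0.052, 0.095)
  subclusters[cryptic] <- 2L
  mid <- setdiff(multi_idx, cryptic)[1:13]
  intra[mid] <- stats::runif(13, 0.022, 0.045)
  subclusters[mid] <- 2L
  rest <- setdiff(multi_idx, c(cryptic, mid))
  intra[rest] <- stats::runif(length(rest), 0.001, 0.018)

  species <- vector("list", 84)
  k <- 0L
  for (g in seq_along(genus_sizes)) {
    for (j in seq_len(genus_sizes[g])) {
      k <- k + 1L
      species[[k]] <- species_spec(
        label = sprintf("Genus%02d_sp%d", g, j),
        n_specimens = sizes[k],
        target_intra = intra[k],
        genus = sprintf("Genus%02d", g),
        tribe = tribe_of_genus[g],
        n_subclusters = if (sizes[k] >= 2L) subclusters[k] else 1L,
        subcluster_intra = if (subclusters[k] > 1L) 0.006 else NULL)
    }
  }

  # plant ambiguous-zone pairs in the largest multi-species genera
  multi_genera <- which(genus_sizes >= 2L)
  n_amb <- round(ambiguous_fraction * length(multi_genera))
  amb <- NULL
  if (n_amb > 0L) {
    chosen <- multi_genera[order(-genus_sizes[multi_genera])][seq_len(n_amb)]
    divs <- seq(0.021, 0.035, length.out = max(n_amb, 2L))[seq_len(n_amb)]
    all_labels <- vapply(species, function(s) s$label, "")
    amb <- lapply(seq_along(chosen), function(i) {
      g <- chosen[i]
      in_g <- which(vapply(species, function(s) s$genus, "") ==
                      sprintf("Genus%02d", g))
      # pair the two lowest-divergence species so cryptic species stay cryptic
      pick <- in_g[order(vapply(species[in_g],
                                function(s) s$target_intra, 0))][1:2]
      for (idx in pick)
        if (species[[idx]]$target_intra >= divs[i] * 0.6)
          species[[idx]]$target_intra <<- divs[i] * 0.3
      list(a = all_labels[pick[1L]], b = all_labels[pick[2L]],
           divergence = divs[i])
    })
  }

  sim_config(species = species, target_inter_congeneric = 0.117,
             kappa = 4, seq_length = 658L, seed = seed,
             ambiguous_pairs = amb)
}
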