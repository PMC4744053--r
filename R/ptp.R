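# Poisson Tree Processes species delimitation.
#
# A species partition assigns every tip to a species whose tips form a
# connected subtree; equivalently it is an antichain of "species-root"
# nodes covering all tips. Branches strictly inside a species subtree are
# within-species (W); every other branch — including the branch entering a
# species root — is between-species (B). Branch lengths in each class are
# modelled as exponential waiting times of two Poisson substitution
# processes with rates lambda_W and lambda_B; the MLE of each rate is the
# reciprocal of the class mean branch length and the maximised
# log-likelihood of a class with n branches summing to s is
# n*log(n/s) - n.

MIN_BRANCH <- 1e-10

tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

# per-node totals of the edges strictly below it (count, sum of lengths)
subtree_edge_stats <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  cnt <- numeric(n_nodes); sm <- numeric(n_nodes)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; c <- po$edge[i, 2L]; b <- po$edge.length[i]
    cnt[p] <- cnt[p] + cnt[c] + 1
    sm[p] <- sm[p] + sm[c] + b
  }
  list(count = cnt, sum = sm)
}

tips_below <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  tb <- vector("list", n_nodes)
  for (i in seq_len(ntip)) tb[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; c <- po$edge[i, 2L]
    tb[[p]] <- c(tb[[p]], tb[[c]])
  }
  tb
}

class_loglik <- function(n, s) {
  if (n == 0) return(0)
  n * log(n / s) - n
}

loglik_from_sums <- function(nW, sW, nB, sB) {
  class_loglik(nW, sW) + class_loglik(nB, sB)
}

#' Two-rate Poisson log-likelihood of a species partition on a tree
#'
#' @param tree Rooted `phylo` tree with positive branch lengths (lengths
#'   below `1e-10` are clamped).
#' @param partition Named character/integer vector mapping every tip label
#'   to a species; each species' tips must form a connected subtree.
#' @return List with `lambda_W`, `lambda_B` (MLE rates; `NA` when a class
#'   is empty), `logL`, `n_W`, `n_B`.
#' @export
ptp_loglik <- function(tree, partition) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree$edge.length <- pmax(tree$edge.length, MIN_BRANCH)
  if (is.null(names(partition)) ||
      !setequal(names(partition), tree$tip.label))
    stop("partition must be named by the tree's tip labels", call. = FALSE)
  ntip <- ape::Ntip(tree)
  sp <- as.character(partition[tree$tip.label])
  tb <- tips_below(tree)
  st <- subtree_edge_stats(tree)

  roots <- integer(0)
  for (s in unique(sp)) {
    tips <- which(sp == s)
    v <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    below <- tb[[v]]
    if (!setequal(below, tips))
      stop("species '", s, "' is not a connected subtree", call. = FALSE)
    roots <- c(roots, v)
  }
  nW <- sum(st$count[roots]); sW <- sum(st$sum[roots])
  nB <- nrow(tree$edge) - nW; sB <- sum(tree$edge.length) - sW
  list(lambda_W = if (nW > 0) nW / sW else NA_real_,
       lambda_B = if (nB > 0) nB / sB else NA_real_,
       logL = loglik_from_sums(nW, sW, nB, sB),
       n_W = nW, n_B = nB)
}

# Enumerate, per subtree, every antichain of species roots as (nW, sW)
# plus the root set itself. Used for the exact search on small trees.
enum_options <- function(v, kids, st) {
  own <- list(list(nW = st$count[v], sW = st$sum[v], roots = v))
  if (is.null(kids[[v]])) return(own)     # tip: only itself
  parts <- lapply(kids[[v]], enum_options, kids = kids, st = st)
  combos <- parts[[1L]]
  for (k in seq_along(parts)[-1L]) {
    nxt <- list()
    for (a in combos) for (b in parts[[k]])
      nxt[[length(nxt) + 1L]] <- list(nW = a$nW + b$nW, sW = a$sW + b$sW,
                                      roots = c(a$roots, b$roots))
    combos <- nxt
  }
  c(own, combos)
}

partition_from_roots <- function(tree, roots) {
  tb <- tips_below(tree)
  ntip <- ape::Ntip(tree)
  out <- character(ntip)
  roots <- sort(roots)
  for (k in seq_along(roots))
    out[tb[[roots[k]]]] <- paste0("sp", k)
  stats::setNames(out, tree$tip.label)
}

greedy_search <- function(tree, kids, st, start_roots, total_n, total_s) {
  score <- function(nW, sW) loglik_from_sums(nW, sW, total_n - nW,
                                             total_s - sW)
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  roots <- start_roots
  nW <- sum(st$count[roots]); sW <- sum(st$sum[roots])
  best <- score(nW, sW)
  repeat {
    improved <- FALSE
    best_move <- NULL; best_gain <- 0
    in_set <- logical(length(parent)); in_set[roots] <- TRUE
    # split moves: replace an internal root by its children
    for (v in roots) {
      ch <- kids[[v]]
      if (is.null(ch)) next
      dn <- nW - length(ch)
      ds <- sW - sum(st$sum[v]) + sum(st$sum[ch])
      g <- score(dn, ds) - best
      if (g > best_gain + 1e-12) {
        best_gain <- g; best_move <- list(type = "split", v = v)
      }
    }
    # merge moves: replace a full sibling set of roots by their parent
    cand_parents <- unique(parent[roots])
    cand_parents <- cand_parents[cand_parents != 0L]
    for (p in cand_parents) {
      ch <- kids[[p]]
      if (!all(in_set[ch])) next
      dn <- nW + length(ch)
      ds <- sW - sum(st$sum[ch]) + st$sum[p]
      g <- score(dn, ds) - best
      if (g > best_gain + 1e-12) {
        best_gain <- g; best_move <- list(type = "merge", p = p)
      }
    }
    if (is.null(best_move)) break
    if (best_move$type == "split") {
      v <- best_move$v; ch <- kids[[v]]
      roots <- c(setdiff(roots, v), ch)
      nW <- nW - length(ch)
      sW <- sW - st$sum[v] + sum(st$sum[ch])
    } else {
      p <- best_move$p; ch <- kids[[p]]
      roots <- c(setdiff(roots, ch), p)
      nW <- nW + length(ch)
      sW <- sW - sum(st$sum[ch]) + st$sum[p]
    }
    best <- best + best_gain
    improved <- TRUE
  }
  list(roots = sort(roots), logL = best)
}

# Block-coordinate ascent: re-optimize the antichain exhaustively inside
# any free subtree with at most `block_tips` tips, conditional on the
# classes outside it, sweeping until no block improves. Subsumes single
# split/merge moves and escapes their local optima.
block_ascent <- function(tree, kids, st, roots, total_n, total_s,
                         block_tips = 12L) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  parent <- integer(n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  tipcount <- numeric(n_nodes)
  tipcount[seq_len(ntip)] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge)))
    tipcount[po$edge[i, 1L]] <- tipcount[po$edge[i, 1L]] +
      tipcount[po$edge[i, 2L]]
  is_anc <- function(a, x) {        # is a an ancestor of (or equal to) x?
    while (x != 0L) {
      if (x == a) return(TRUE)
      x <- parent[x]
    }
    FALSE
  }
  blocks <- which(tipcount >= 2 & tipcount <= block_tips)
  opts_cache <- lapply(seq_len(n_nodes), function(i) NULL)

  nW <- sum(st$count[roots]); sW <- sum(st$sum[roots])
  logL <- loglik_from_sums(nW, sW, total_n - nW, total_s - sW)
  repeat {
    improved <- FALSE
    for (v in blocks) {
      # v must be free: no current root strictly above it
      if (any(vapply(roots, function(r) r != v && is_anc(r, v), TRUE)))
        next
      inside <- roots[vapply(roots, function(r) is_anc(v, r), TRUE)]
      if (!length(inside)) next
      if (is.null(opts_cache[[v]]))
        opts_cache[[v]] <- enum_options(v, kids, st)
      base_nW <- nW - sum(st$count[inside])
      base_sW <- sW - sum(st$sum[inside])
      ll <- vapply(opts_cache[[v]], function(o)
        loglik_from_sums(base_nW + o$nW, base_sW + o$sW,
                         total_n - base_nW - o$nW,
                         total_s - base_sW - o$sW), 0)
      k <- which.max(ll)
      if (ll[k] > logL + 1e-12) {
        o <- opts_cache[[v]][[k]]
        roots <- c(setdiff(roots, inside), o$roots)
        nW <- base_nW + o$nW
        sW <- base_sW + o$sW
        logL <- ll[k]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(roots = sort(roots), logL = logL)
}

# Coordinate ascent: for fixed rates the optimal antichain maximizes a sum
# of per-branch terms and is solved exactly by a postorder DP (a node is
# either a species root — every branch below scores as W — or delegates to
# its children, with the entering branches scored as B); rates are then
# re-estimated from the induced classes. Each step is an ascent of the
# profile likelihood.
em_search <- function(tree, kids, st, total_n, total_s, lamW, lamB,
                      max_iter = 100L) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  elen <- numeric(n_nodes)
  elen[tree$edge[, 2L]] <- tree$edge.length
  # process internal nodes children-first: order by tree depth, deepest first
  depth <- numeric(n_nodes)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge)))
    depth[pre$edge[i, 2L]] <- depth[pre$edge[i, 1L]] + 1
  internal <- (ntip + 1L):n_nodes
  node_order <- internal[order(depth[internal], decreasing = TRUE)]

  best <- list(roots = ntip + 1L, logL = -Inf)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    lw <- log(lamW); lb <- log(lamB)
    f <- numeric(n_nodes)
    as_root <- logical(n_nodes)
    as_root[seq_len(ntip)] <- TRUE
    for (v in node_order) {
      ch <- kids[[v]]
      if (is.null(ch)) next
      optA <- st$count[v] * lw - lamW * st$sum[v]
      optB <- sum(lb - lamB * elen[ch] + f[ch])
      as_root[v] <- optA >= optB
      f[v] <- max(optA, optB)
    }
    # backtrack the chosen antichain
    roots <- integer(0)
    stack <- ntip + 1L
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      if (as_root[v]) roots <- c(roots, v)
      else stack <- c(stack, kids[[v]])
    }
    nW <- sum(st$count[roots]); sW <- sum(st$sum[roots])
    logL <- loglik_from_sums(nW, sW, total_n - nW, total_s - sW)
    if (logL > best$logL) best <- list(roots = sort(roots), logL = logL)
    if (nW == 0 || total_n - nW == 0 || logL <= prev + 1e-10) break
    prev <- logL
    lamW <- nW / sW
    lamB <- (total_n - nW) / (total_s - sW)
  }
  best
}

#' PTP maximum-likelihood species delimitation
#'
#' Searches over species partitions (antichains of species-root nodes) for
#' the maximum two-rate Poisson likelihood: exhaustively for trees with at
#' most `exhaustive_max` tips, otherwise by greedy hill-climbing (node
#' split/merge moves) from both extreme partitions — one species, and all
#' singletons — keeping the better optimum. The one-class (single-rate)
#' null equals the all-one-species likelihood; when the best two-class
#' solution improves on it by less than `min_improve` log units there is
#' no delimitation signal and the one-species partition is returned with
#' `low_confidence = TRUE`.
#'
#' @param tree Rooted `phylo` tree with at least 2 tips.
#' @param exhaustive_max Tip count up to which the search is exhaustive
#'   (default 14).
#' @param min_improve Log-likelihood improvement over the single-rate null
#'   required to report more than one species (default 2).
#' @return List of class `ptp_result`: `partition` (a `motu_partition`
#'   with `method = "ptp"`), `lambda_W`, `lambda_B`, `logL`,
#'   `logL_null`, `low_confidence`, `method` (`"exhaustive"` or
#'   `"greedy"`).
#' @export
ptp_delimit <- function(tree, exhaustive_max = 14L, min_improve = 2) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("need at least 2 tips", call. = FALSE)
  tree$edge.length <- pmax(tree$edge.length, MIN_BRANCH)
  kids <- tree_children(tree)
  st <- subtree_edge_stats(tree)
  total_n <- nrow(tree$edge)
  total_s <- sum(tree$edge.length)
  root_node <- ntip + 1L

  if (ntip <= exhaustive_max) {
    opts <- enum_options(root_node, kids, st)
    ll <- vapply(opts, function(o)
      loglik_from_sums(o$nW, o$sW, total_n - o$nW, total_s - o$sW), 0)
    # tie-break: fewer species
    ord <- order(-ll, vapply(opts, function(o) length(o$roots), 0L))
    best <- opts[[ord[1L]]]
    roots <- sort(best$roots)
    logL <- ll[ord[1L]]
    search <- "exhaustive"
  } else {
    b <- sort(tree$edge.length)
    m <- length(b)
    mean_or <- function(x, fallback) if (length(x) && mean(x) > 0)
      mean(x) else fallback
    half <- mean_or(b[seq_len(m %/% 2)], min(b))
    rest <- mean_or(b[(m %/% 2 + 1):m], max(b))
    quarter <- mean_or(b[seq_len(max(1L, m %/% 4))], min(b))
    inits <- list(c(1 / half, 1 / rest),
                  c(4 / mean(b), 0.5 / mean(b)),
                  c(1 / quarter, 1 / mean(b)))
    cands <- lapply(inits, function(r)
      em_search(tree, kids, st, total_n, total_s, r[1], r[2]))
    cands <- c(cands, list(list(roots = root_node, logL = NA_real_),
                           list(roots = seq_len(ntip), logL = NA_real_)))
    # polish every candidate: move-based hill climbing, then exhaustive
    # block-coordinate ascent over small subtrees
    polished <- lapply(cands, function(cand) {
      g <- greedy_search(tree, kids, st, cand$roots, total_n, total_s)
      block_ascent(tree, kids, st, g$roots, total_n, total_s)
    })
    ll <- vapply(polished, function(p) p$logL, 0)
    win <- polished[[which.max(ll)]]
    roots <- win$roots
    logL <- win$logL
    search <- "greedy"
  }

  logL_null <- loglik_from_sums(st$count[root_node], st$sum[root_node],
                                total_n - st$count[root_node],
                                total_s - st$sum[root_node])
  low_confidence <- (logL - logL_null) < min_improve
  if (low_confidence) {
    roots <- root_node
    logL <- logL_null
    warning("no two-rate signal (improvement < ", min_improve,
            " log units); returning a single species", call. = FALSE)
  }

  assignment <- partition_from_roots(tree, roots)
  nW <- sum(st$count[roots]); sW <- sum(st$sum[roots])
  nB <- total_n - nW; sB <- total_s - sW
  motu <- new_motu_partition(
    stats::setNames(match(assignment, unique(assignment)),
                    names(assignment)),
    NA_real_, "ptp")
  structure(list(partition = motu,
                 lambda_W = if (nW > 0) nW / sW else NA_real_,
                 lambda_B = if (nB > 0) nB / sB else NA_real_,
                 logL = logL, logL_null = logL_null,
                 low_confidence = low_confidence,
                 species_roots = roots, method = search),
            class = "ptp_result")
}

#' @export
print.ptp_result <- function(x, ...) {
  cat(sprintf(
    "ptp_result (%s): %d species, logL = %.3f (null %.3f)%s\n",
    x$method, x$partition$n_motus, x$logL, x$logL_null,
    if (x$low_confidence) " [low confidence]" else ""))
  cat(sprintf("  lambda_W = %s, lambda_B = %s\n",
              format(x$lambda_W, digits = 4),
              format(x$lambda_B, digits = 4)))
  invisible(x)
}
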