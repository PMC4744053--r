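# Independent, deliberately naive reference implementations. They share no
# code with the package internals they check.

# per-site counting distance oracle (loops over sites)
oracle_pair_distance <- function(x, y, model) {
  xs <- strsplit(toupper(x), "")[[1L]]
  ys <- strsplit(toupper(y), "")[[1L]]
  acgt <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(xs)) {
    if (!(xs[i] %in% acgt) || !(ys[i] %in% acgt)) next
    n <- n + 1L
    if (xs[i] == ys[i]) next
    pur <- c("A", "G")
    if ((xs[i] %in% pur) == (ys[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n; p <- (ts + tv) / n
  d <- switch(model,
              p = p,
              jc69 = -3 / 4 * log(1 - 4 * p / 3),
              k2p = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
  list(distance = d, comparable_sites = n)
}

# textbook complete-linkage agglomeration: repeatedly merge the cluster
# pair with the smallest maximum pairwise distance while it is <= t
oracle_complete_linkage <- function(m, t) {
  clusters <- as.list(seq_len(nrow(m)))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      link <- max(m[clusters[[i]], clusters[[j]]])
      if (link < best) { best <- link; bi <- i; bj <- j }
    }
    if (best > t) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  memb <- integer(nrow(m))
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

# canonical form of a partition for comparison up to label permutation
canon_partition <- function(memb) {
  unname(split(seq_along(memb), memb)[
    order(vapply(split(seq_along(memb), memb), min, 0L))])
}

# exhaustive PTP oracle over all antichains, built directly on the edge
# table (no shared helpers with the package)
oracle_ptp_best <- function(tree) {
  tree$edge.length <- pmax(tree$edge.length, 1e-10)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  below <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(list(n = 0, s = 0))
    out <- list(n = 0, s = 0)
    for (c in ch) {
      b <- below(c)
      out$n <- out$n + b$n + 1
      out$s <- out$s + b$s + elen[[as.character(c)]]
    }
    out
  }
  options_of <- function(v) {
    b <- below(v)
    own <- list(c(n = b$n, s = b$s))
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(own)
    combos <- options_of(ch[1L])
    for (c in ch[-1L]) {
      nxt <- list()
      for (a in combos) for (d in options_of(c))
        nxt[[length(nxt) + 1L]] <- a + d
      combos <- nxt
    }
    c(own, combos)
  }
  tot <- below(ntip + 1L)
  cl <- function(n, s) if (n == 0) 0 else n * log(n / s) - n
  max(vapply(options_of(ntip + 1L), function(o)
    cl(o[["n"]], o[["s"]]) + cl(tot$n - o[["n"]], tot$s - o[["s"]]), 0))
}
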