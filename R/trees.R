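# Neighbor-joining tree construction, rooting and newick serialization.
#
# NJ itself is the standard Saitou-Nei agglomeration as implemented in
# ape; this module wraps it with the negative-branch-length adjustment
# (negative edges are clamped to zero with the deficit transferred to the
# adjacent edges so path lengths through the node are approximately
# preserved) and exposes rooting and newick round-trips.

fix_negative_edges <- function(tr) {
  adjust <- 0
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    b <- tr$edge.length[i]
    adjust <- adjust + abs(b)
    tr$edge.length[i] <- 0
    child <- tr$edge[i, 2L]
    down <- which(tr$edge[, 1L] == child)
    if (length(down))
      tr$edge.length[down] <- tr$edge.length[down] + b
  }
  # a transfer can itself go negative on very short edges; clamp the rest
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_length_adjustment") <- adjust
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param dm A complete `barcode_dist` over at least 3 sequences.
#' @return Unrooted `phylo` tree (ape) with non-negative branch lengths;
#'   the total length removed by the negative-branch adjustment is stored
#'   in `attr(tree, "negative_length_adjustment")`.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "barcode_dist"))
  if (length(dm$ids) < 3L)
    stop("neighbor-joining requires at least 3 sequences", call. = FALSE)
  vals <- dm$values
  if (anyNA(vals[upper.tri(vals)]))
    stop("distance matrix has undefined entries", call. = FALSE)
  dimnames(vals) <- list(dm$ids, dm$ids)
  fix_negative_edges(ape::nj(stats::as.dist(vals)))
}

#' Root a tree by midpoint or outgroup
#'
#' @param tree A `phylo` tree.
#' @param mode `"midpoint"` (root at the center of the longest tip-to-tip
#'   path) or `"outgroup"`.
#' @param outgroup_ids Tip labels of the outgroup (required for
#'   `mode = "outgroup"`).
#' @return Rooted `phylo` tree with a degree-2 root; total path lengths
#'   are preserved.
#' @export
root_tree <- function(tree, mode = c("midpoint", "outgroup"),
                      outgroup_ids = NULL) {
  mode <- match.arg(mode)
  if (mode == "midpoint") {
    phangorn::midpoint(tree)
  } else {
    if (is.null(outgroup_ids) || !all(outgroup_ids %in% tree$tip.label))
      stop("outgroup tips missing from tree", call. = FALSE)
    ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  }
}

#' Serialize / parse newick
#'
#' Round-trips preserve topology and branch lengths to 10 significant
#' digits; tip labels with spaces are quoted per the newick convention.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file path; when `NULL` the newick string is
#'   returned.
#' @return `write_newick`: the newick string (invisibly when writing to a
#'   file); `read_newick`: a `phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  lab <- tree$tip.label
  needs <- grepl("[^A-Za-z0-9_.|/-]", lab)
  if (any(needs)) {
    # placeholders dodge the serializer's label munging; the quoted
    # originals are substituted back into the newick text
    ph <- sprintf("xQUOTEDLABELx%04d", seq_along(lab))
    tree$tip.label[needs] <- ph[needs]
    txt <- ape::write.tree(tree, digits = 10)
    for (i in which(needs))
      txt <- sub(ph[i], sprintf("'%s'", lab[i]), txt, fixed = TRUE)
  } else {
    txt <- ape::write.tree(tree, digits = 10)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed newick", call. = FALSE)
  tr$tip.label <- sub("^'(.*)'$", "\\1", tr$tip.label)
  tr
}
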