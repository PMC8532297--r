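# Distance-based tree construction and newick utilities. UPGMA supplies
# the ultrametric tree the informativeness profiling consumes (a
# desk-scale stand-in for a dated Bayesian chronogram); NJ serves topology
# checks. Trees are ape "phylo" objects throughout.

.check_complete_dm <- function(dm) {
  if (any(is.na(dm))) {
    abort("distance matrix has undefined entries; impute or drop the affected pairs upstream")
  }
  invisible(dm)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node height is half the cluster
#' distance, so the output is rooted and ultrametric. Labels are sorted
#' lexicographically before clustering, making tie-breaks reproducible.
#'
#' @param dm symmetric labelled distance matrix (or `dist`).
#' @return rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  m <- as.matrix(dm)
  .check_complete_dm(m)
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  tr <- ape::as.phylo(hc)
  ape::reorder.phylo(tr, "postorder")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion (via
#' [ape::nj()]); negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param dm symmetric labelled distance matrix (or `dist`), >= 3 taxa.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  m <- as.matrix(dm)
  .check_complete_dm(m)
  if (nrow(m) < 3) abort("neighbour joining needs at least three taxa")
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warn(sprintf("clamping %d negative branch length(s) to zero",
                 sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Read a newick tree
#'
#' @param x path to a newick file, or the newick string itself.
#' @return a `phylo` tree.
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1 && !grepl("[();]", x) && file.exists(x)) {
    ape::read.tree(x)
  } else {
    ape::read.tree(text = x)
  }
  if (is.null(tr)) abort("cannot parse newick input")
  if (anyDuplicated(tr$tip.label)) {
    abort(sprintf("duplicate tip label(s): %s",
                  paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", ")))
  }
  tr
}

#' Write a tree as newick text
#'
#' @param tree a `phylo` tree.
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @return newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Maximum root-to-tip path length of a rooted tree
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return numeric depth.
#' @export
root_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Is a tree ultrametric (clock-like)?
#'
#' All root-to-tip path lengths equal within `tol`; by default the
#' tolerance scales with tree depth (`1e-6 * depth`).
#'
#' @param tree a rooted `phylo` tree.
#' @param tol absolute tolerance; default `1e-6 * root_depth(tree)`.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = NULL) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (is.null(tol)) tol <- 1e-6 * max(depths)
  diff(range(depths)) <= tol
}

#' Rescale a rooted tree so its root depth is 1
#'
#' Informativeness profiling works on a depth-normalized time axis.
#'
#' @param tree a rooted `phylo` tree.
#' @return the rescaled tree.
#' @export
normalize_depth <- function(tree) {
  tree$edge.length <- tree$edge.length / root_depth(tree)
  tree
}
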