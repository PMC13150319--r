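#' Read an ultrametric chronogram from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the two properties
#' the phylogenetic regression relies on: unique tip labels and
#' ultrametricity (all root-to-tip path lengths equal, within a relative
#' tolerance of the tree depth). Branch lengths are taken as given,
#' typically millions of years for a fossil-calibrated chronogram.
#'
#' @param path Path to a Newick file.
#' @param tol Relative ultrametricity tolerance (default 1e-6 of depth).
#' @return An [ape::phylo] object.
#' @export
read_chronogram <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  check_chronogram(tree, tol = tol)
  tree
}

#' Check that a tree is a usable chronogram
#'
#' @param tree An [ape::phylo] object.
#' @param tol Relative ultrametricity tolerance.
#' @return `tree`, invisibly; errors otherwise.
#' @export
check_chronogram <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label) > 0) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  depths <- tip_depths(tree)
  depth <- max(depths)
  dev <- max(abs(depths - depth))
  if (dev > tol * depth) {
    stop(sprintf(
      "tree is not ultrametric: max tip-depth deviation %.6g (depth %.6g)",
      dev, depth), call. = FALSE)
  }
  invisible(tree)
}

#' Root-to-tip path lengths
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return Named numeric vector, one depth per tip.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chronogram <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
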