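#' Parse and validate an ultrametric phylogeny from a Newick string
#'
#' Reads a single Newick tree and checks the invariants every downstream
#' phylogenetic metric relies on: at least two uniquely labelled tips,
#' branch lengths present and nonnegative on all non-root edges, and all
#' root-to-tip path lengths equal within a relative tolerance of the tree
#' height. Zero-length branches (soft polytomies, common in barcode trees)
#' are allowed.
#'
#' @param text a Newick string describing one rooted tree with branch
#'   lengths.
#' @param tol relative ultrametricity tolerance: the maximum allowed
#'   deviation of a tip depth from the tree height, as a fraction of the
#'   height. Default `1e-6`; real chronograms carry rounding noise.
#' @return an [ape::read.tree()] `"phylo"` object that has passed
#'   validation.
#' @seealso [read_ultrametric_tree()] for files,
#'   [validate_ultrametric_tree()] for the checks alone.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
#' @export
parse_newick <- function(text, tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("failed to parse Newick string", call. = FALSE)
  validate_ultrametric_tree(tr, tol = tol)
}

#' Read an ultrametric phylogeny from a Newick file
#'
#' @param path path to a file containing a single Newick tree.
#' @inheritParams parse_newick
#' @return a validated `"phylo"` object.
#' @export
read_ultrametric_tree <- function(path, tol = 1e-6) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop(sprintf("failed to parse Newick file '%s'", path), call. = FALSE)
  validate_ultrametric_tree(tr, tol = tol)
}

#' Validate the ultrametric-tree invariants
#'
#' @param tree a `"phylo"` object.
#' @inheritParams parse_newick
#' @return the tree, invisibly usable, after passing all checks; errors
#'   name the offending tip or branch otherwise.
#' @export
validate_ultrametric_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be a \"phylo\" object", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (ntip < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("tree must carry branch lengths on all edges", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  h <- max(depth)
  if (h <= 0)
    stop("tree height must be positive", call. = FALSE)
  dev <- abs(depth - h) / h
  if (any(dev > tol)) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' at depth %.8g vs height %.8g (relative deviation %.3g > tol %.3g)",
      tree$tip.label[worst], depth[worst], h, dev[worst], tol),
      call. = FALSE)
  }
  tree
}

#' Tree height (root-to-tip depth)
#'
#' @param tree a `"phylo"` object.
#' @return the maximum root-to-tip path length.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Pairwise phylogenetic distances between tips
#'
#' Tip-to-tip path-length (patristic / cophenetic) distances, the input to
#' MPD. Rows and columns are ordered as `tree$tip.label`.
#'
#' @param tree a validated `"phylo"` object.
#' @return a symmetric numeric matrix with zero diagonal and dimnames the
#'   tip labels.
#' @export
pairwise_distances <- function(tree) {
  validate_ultrametric_tree(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

# index of the parent edge for every node (0 for the root)
.parent_edge <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  pe <- integer(n_node)
  pe[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  pe
}

.match_tips <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip label(s): ",
         paste(tips[is.na(idx)], collapse = ", "), call. = FALSE)
  unique(idx)
}

#' Total branch length spanned by a set of tips (rooted Faith's PD)
#'
#' Sum of branch lengths in the minimal subtree connecting the given tips
#' *and the root* (the rooted-PD convention): every branch on the path from
#' each tip up to the root is counted once. Under this convention the PD of
#' a single tip is its root-path length, which keeps rarefaction to n = 1
#' individuals well defined.
#'
#' @param tree a `"phylo"` object.
#' @param tips character vector of tip labels (nonempty subset of
#'   `tree$tip.label`).
#' @return the spanned branch-length sum.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' total_branch_length(tr, c("A", "B", "C"))  # 5, all branches
#' total_branch_length(tr, "A")               # 2, root path
#' @export
total_branch_length <- function(tree, tips) {
  if (length(tips) < 1L)
    stop("`tips` must contain at least one tip", call. = FALSE)
  idx <- .match_tips(tree, tips)
  pe <- .parent_edge(tree)
  on_path <- logical(nrow(tree$edge))
  parent <- integer(length(pe))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  for (node in idx) {
    while (pe[node] != 0L && !on_path[pe[node]]) {
      on_path[pe[node]] <- TRUE
      node <- parent[node]
    }
  }
  sum(tree$edge.length[on_path])
}

# Per-edge abundance totals: for each edge, the summed count of individuals
# whose species descend from that edge. `counts` is a named vector; names
# must all be tip labels, tips absent from `counts` get 0.
branch_counts <- function(tree, counts) {
  if (is.null(names(counts)))
    stop("`counts` must be a named vector (names = tip labels)",
         call. = FALSE)
  .match_tips(tree, names(counts))
  ntip <- length(tree$tip.label)
  tot <- numeric(ntip + tree$Nnode)
  tot[match(names(counts), tree$tip.label)] <- as.numeric(counts)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    tot[po$edge[i, 1L]] <- tot[po$edge[i, 1L]] + tot[po$edge[i, 2L]]
  }
  data.frame(length = tree$edge.length,
             n_below = tot[tree$edge[, 2L]])
}
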