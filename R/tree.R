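#' Read a rooted phylogeny from Newick, assigning stable node identifiers
#'
#' Wraps [ape::read.tree()] and enforces the conventions used throughout the
#' package: the tree is rooted, every branch has a length, tip labels are
#' unique, and every internal node carries a stable identifier. Internal node
#' labels present in the Newick string are kept as identifiers; unlabeled
#' internal nodes receive deterministic identifiers (`"nd"` followed by the
#' node's postorder rank). These identifiers are the join key for the
#' shared-node analysis across communities, so they survive [prune_to_tips()]
#' and [reroot_at_node()].
#'
#' @param source path to a Newick file, or a Newick string (detected by the
#'   presence of `"("`).
#' @param fill_missing_lengths if `TRUE`, missing branch lengths are filled
#'   with 0; otherwise they are an error.
#' @return an object of class `"phylo"` with a complete `node.label` vector.
#' @seealso [write_newick()], [prune_to_tips()], [reroot_at_node()]
#' @export
read_newick <- function(source, fill_missing_lengths = FALSE) {
  stopifnot(is.character(source), length(source) == 1L)
  tr <- if (grepl("(", source, fixed = TRUE)) {
    ape::read.tree(text = source)
  } else {
    if (!file.exists(source)) stop("file not found: ", source)
    ape::read.tree(file = source)
  }
  if (is.null(tr)) stop("Newick parse error in: ", substr(source, 1L, 80L))
  as_phylopred_tree(tr, fill_missing_lengths = fill_missing_lengths)
}

#' Validate a phylo object and assign stable node identifiers
#'
#' Checks the invariants the package relies on (rooted, unique tip labels,
#' nonnegative branch lengths) and labels any unlabeled internal nodes with
#' deterministic postorder identifiers.
#'
#' @inheritParams read_newick
#' @param tree a `"phylo"` object.
#' @return the validated tree with a complete `node.label` vector.
#' @export
as_phylopred_tree <- function(tree, fill_missing_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (!fill_missing_lengths) stop("tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!fill_missing_lengths) stop("missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # structural rootedness: exactly one parentless node, every other node has
  # exactly one parent (a basal multifurcation still counts as a root)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  child_count <- tabulate(tree$edge[, 2L], nbins = n_node)
  roots <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(roots) != 1L || any(child_count[-roots] != 1L) ||
      child_count[roots] != 0L || nrow(tree$edge) != n_node - 1L)
    stop("tree is not a rooted, connected, acyclic phylogeny")
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  lab[is.na(lab)] <- ""
  blank <- !nzchar(lab)
  if (any(blank)) {
    # postorder rank of each internal node is stable under identical topology
    post <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
    rank <- match(seq_len(tree$Nnode) + n_tip, post)
    lab[blank] <- sprintf("nd%04d", rank[blank])
  }
  if (anyDuplicated(lab))
    stop("duplicate internal node identifiers: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  tree$node.label <- lab
  tree
}

#' Write a phylogeny to Newick, preserving node identifiers
#'
#' Node identifiers are written as internal node labels so that a
#' write/read round trip preserves them.
#'
#' @param tree a `"phylo"` object.
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Prune a phylogeny to a set of tips, preserving node identity
#'
#' Restricts the tree to `keep`, suppressing internal nodes left with a single
#' child (their branch lengths are summed, so every root-to-tip path length is
#' unchanged). Surviving branching nodes keep their identifiers from the input
#' tree, which makes pruned community trees comparable through shared node ids.
#'
#' @param tree a `"phylo"` object with node labels (see [read_newick()]).
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `"phylo"` object.
#' @export
prune_to_tips <- function(tree, keep) {
  tree <- as_phylopred_tree(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Reroot a phylogeny at an internal node
#'
#' Returns the tree rooted at the node carrying identifier `node_id`. All
#' pairwise tip path lengths are preserved; if the old root becomes
#' unifurcating it is suppressed. This is the rearrangement underlying
#' hidden-tip prediction: the generalized-least-squares estimate at the new
#' root is the Brownian-motion estimate of the trait at that point of the tree.
#'
#' @param tree a `"phylo"` object with node labels.
#' @param node_id identifier (internal node label) of the new root.
#' @return the rerooted `"phylo"` object.
#' @export
reroot_at_node <- function(tree, node_id) {
  tree <- as_phylopred_tree(tree)
  if (node_id %in% tree$tip.label)
    stop("'", node_id, "' is a tip; reroot requires an internal node")
  k <- match(node_id, tree$node.label)
  if (is.na(k)) stop("node id not found: ", node_id)
  node <- k + length(tree$tip.label)
  if (node == .root_node(tree)) return(tree)
  out <- ape::root(tree, node = node, resolve.root = FALSE)
  as_phylopred_tree(out)
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' `V[i, j]` is the root-to-MRCA path length shared by tips `i` and `j`
#' (the diagonal holds root-to-tip depths). Under Brownian motion with rate
#' `sigma2` the tip traits are jointly Gaussian with covariance `sigma2 * V`;
#' this matrix is the reference against which all fast pruning-based
#' computations in the package are defined.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) {
  tree <- as_phylopred_tree(tree)
  ape::vcv(tree)
}

## ---- internal helpers ------------------------------------------------------

# root node number (ape convention: Ntip + 1 after reordering, but derived
# defensively as the node that is never a child)
.root_node <- function(tree) setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]

# parent node number of a tip (by label)
.parent_of_tip <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("tip not found: ", tip)
  tree$edge[tree$edge[, 2L] == i, 1L]
}

# depth (root-to-node path length) of every node, numbered as in tree$edge
.node_depths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(n_node)
  pre <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(pre$edge)))
  for (e in ord) {
    depth[pre$edge[e, 2L]] <- depth[pre$edge[e, 1L]] + pre$edge.length[e]
  }
  depth
}

# error (or jitter) on zero-length terminal branches, which make V singular
.check_terminal_branches <- function(tree, jitter = FALSE) {
  term <- tree$edge[, 2L] <= length(tree$tip.label)
  if (any(tree$edge.length[term] <= 0)) {
    if (!jitter)
      stop("zero-length terminal branch(es) make the trait covariance ",
           "singular; use jitter = TRUE to add a small epsilon")
    eps <- 1e-8 * max(.node_depths(tree))
    tree$edge.length[term & tree$edge.length <= 0] <-
      tree$edge.length[term & tree$edge.length <= 0] + eps
  }
  tree
}
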