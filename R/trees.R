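# Rooted time-calibrated trees: reading, validation, pruning, and the
# covariance structures (shared path lengths, patristic distances) that every
# downstream model consumes. Trees are `ape::phylo` objects throughout.

#' Read and validate a rooted phylogeny from Newick text
#'
#' Parses a Newick string or file into an [ape::phylo] tree and validates it
#' for comparative analysis: branch lengths must be present on every edge and
#' tip labels must be unique. Polytomies are preserved. Internal node labels
#' are permitted and ignored.
#'
#' @param text A Newick string (e.g. `"((A:1,B:1):1,C:2);"`). Exactly one of
#'   `text` and `file` must be given.
#' @param file Path to a Newick file (`.nwk`/`.tre`).
#' @param normalise_labels If `TRUE`, underscores in tip labels are replaced
#'   by spaces (Newick files often use underscores where trait tables use
#'   spaces).
#'
#' @return A rooted `phylo` object in cladewise (preorder) edge order.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_depth(tr) # 2
#' @export
read_newick <- function(text = NULL, file = NULL, normalise_labels = FALSE) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file)
  if (is.null(tree)) stop("could not parse Newick input")
  if (normalise_labels) tree$tip.label <- gsub("_", " ", tree$tip.label, fixed = TRUE)
  validate_tree(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants the downstream models rely on: a single root, branch
#' lengths on all edges (positive except that zero-length edges are tolerated
#' only when `allow_zero` is `TRUE`), unique tip labels, and optionally
#' ultrametricity to a relative tolerance.
#'
#' @param tree A `phylo` object.
#' @param require_ultrametric If `TRUE`, reject trees whose tip depths differ
#'   by more than `tol` relative to tree depth. Ornstein-Uhlenbeck fitting
#'   requires an ultrametric tree; Brownian motion does not.
#' @param tol Relative ultrametricity tolerance.
#' @param allow_zero Accept zero-length branches.
#' @return The tree, reordered cladewise, invisibly validated.
#' @export
validate_tree <- function(tree, require_ultrametric = FALSE, tol = 1e-6,
                          allow_zero = FALSE) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- tree$edge[which(is.na(tree$edge.length))[1], 2]
    stop("missing branch length on the edge subtending node ", bad)
  }
  lim <- if (allow_zero) 0 else .Machine$double.xmin
  if (any(tree$edge.length < lim)) {
    bad <- tree$edge[which(tree$edge.length < lim)[1], 2]
    stop("non-positive branch length on the edge subtending node ", bad)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (require_ultrametric && !is_ultrametric(tree, tol)) {
    stop("tree is not ultrametric to relative tolerance ", tol)
  }
  ape::reorder.phylo(tree, "cladewise")
}

#' Test ultrametricity to a relative tolerance
#'
#' A tree is accepted as ultrametric when the maximum difference between
#' root-to-tip depths, relative to the tree depth, does not exceed `tol`.
#'
#' @inheritParams validate_tree
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  diff(range(d)) / max(d) <= tol
}

#' Root-to-tip depths and tree depth
#'
#' @param tree A `phylo` object.
#' @return `tip_depths()`: named numeric vector of root-to-tip path lengths in
#'   the tree's time units; `tree_depth()`: the maximum depth `T`.
#' @export
tip_depths <- function(tree) {
  n <- length(tree$tip.label)
  d <- ape::node.depth.edgelength(tree)[seq_len(n)] + .root_stem(tree)
  names(d) <- tree$tip.label
  d
}

#' @rdname tip_depths
#' @export
tree_depth <- function(tree) max(tip_depths(tree))

#' Prune a phylogeny to a set of tips
#'
#' Returns the induced tree on `keep`: unary internal nodes are suppressed
#' with branch lengths summed, so root-to-tip depths and patristic distances
#' among the retained tips are unchanged. When the retained tips' most recent
#' common ancestor lies below the original root, the basal path is kept as a
#' root stem (`root.edge`), which [tip_depths()] and [phylo_cov()] include —
#' pruning therefore commutes with taking submatrices of the phylogenetic
#' covariance.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least two).
#' @return The pruned `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' prune_tree(tr, c("A", "C")) # (A:2,C:2)
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop("tip labels not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2) stop("`keep` must contain at least two tips")
  old_depth <- max(tip_depths(tree)[keep])
  out <- ape::reorder.phylo(ape::keep.tip(tree, keep), "cladewise")
  stem <- old_depth - max(ape::node.depth.edgelength(out)[seq_along(keep)])
  if (stem > 1e-12) out$root.edge <- stem
  out
}

.root_stem <- function(tree) if (is.null(tree$root.edge)) 0 else tree$root.edge

#' Phylogenetic covariance matrix (shared path lengths)
#'
#' Entry `C[i, j]` is the path length from the root to the most recent common
#' ancestor of tips `i` and `j`; the diagonal holds the tip depths. Under
#' Brownian motion with rate `sigma2`, tip values have covariance
#' `sigma2 * C`. Rows/columns follow `tree$tip.label`.
#'
#' @param tree A `phylo` object.
#' @return A symmetric positive semidefinite matrix with tip-label dimnames
#'   and attribute `"depth"` holding the tree depth `T`.
#' @export
phylo_cov <- function(tree) {
  tree <- validate_tree(tree)
  C <- ape::vcv.phylo(tree) + .root_stem(tree)   # stem is shared by all tips
  C <- (C + t(C)) / 2
  attr(C, "depth") <- tree_depth(tree)
  C
}

#' Patristic distance matrix
#'
#' Path length between every pair of tips, i.e. the sum of branch lengths
#' along the connecting path. On an ultrametric tree of depth `T`,
#' `d[i, j] = 2 * (T - s[i, j])` with `s` the shared path length of
#' [phylo_cov()].
#'
#' @param tree A `phylo` object.
#' @return A symmetric matrix with zero diagonal and tip-label dimnames.
#' @export
patristic <- function(tree) {
  tree <- validate_tree(tree)
  as.matrix(stats::cophenetic(tree))[tree$tip.label, tree$tip.label]
}

# ---- internal tree plumbing -------------------------------------------------

# Parent edge index for every node (0 for the root), under cladewise order.
.parent_edge <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  pe <- integer(nn)
  pe[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  pe
}

# Per-tip lineages as flat segment vectors: for every (tip, edge-on-its-path)
# pair, the edge index and its start/end times measured from the root.
.tip_segments <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree) + .root_stem(tree)
  pe <- .parent_edge(tree)
  root <- n + 1L
  tip <- integer(0); edge <- integer(0)
  for (i in seq_len(n)) {
    node <- i
    while (node != root) {
      e <- pe[node]
      tip <- c(tip, i); edge <- c(edge, e)
      node <- tree$edge[e, 1]
    }
  }
  parent <- tree$edge[edge, 1]; child <- tree$edge[edge, 2]
  list(tip = tip, edge = edge, t0 = depth[parent], t1 = depth[child])
}

# Edge indices of the subtree rooted at the child end of `edge`, stopping at
# any edge in `stop_edges` (used when painting a new shift over a region not
# already overridden by a downstream shift).
.descendant_edges <- function(tree, edge, stop_edges = integer(0)) {
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- integer(0)
  stack <- edge
  while (length(stack) > 0) {
    e <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, e)
    below <- kids[[as.character(tree$edge[e, 2])]]
    if (!is.null(below)) {
      below <- below[!below %in% stop_edges]
      stack <- c(stack, below)
    }
  }
  sort(out)
}
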