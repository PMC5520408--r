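#' Rooted phylogeny with cached node indices
#'
#' Wraps an \pkg{ape} `phylo` object and precomputes the quantities the
#' distance machinery needs repeatedly: parent pointers, parent-edge lengths,
#' root-to-node depths, ancestor paths, and dense last-common-ancestor
#' tables.  Nodes are addressed by their `ape` ids (tips `1..n`, internals
#' `n+1..n+m`, root = `n+1`); an edge is addressed by the id of the node
#' below it, so the root has no edge.
#'
#' Node support labels, when present as numeric internal node labels, are
#' stored in `[0, 100]`; labels that all lie in `[0, 1]` are interpreted as
#' fractions and rescaled with a warning.  Supports are carried, never
#' interpreted, by the tree itself.
#'
#' The dense LCA tables are quadratic in the node count; trees in this
#' package's intended regime (hundreds to a few thousand tips) are fine.
#'
#' @param phy an `ape::phylo` object, rooted, with branch lengths (missing
#'   lengths default to 0 with a warning).
#' @return an object of class `pd_tree`.
#' @export
as_pd_tree <- function(phy) {
  if (inherits(phy, "pd_tree")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  if (any(duplicated(phy$tip.label)))
    stopf("duplicate leaf names: %s",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (any(!nzchar(phy$tip.label))) stopf("empty leaf names are not allowed")
  rooted_warning <- FALSE
  if (!ape::is.rooted(phy)) {
    # a basal multifurcation is accepted as a rooted multifurcating tree
    rooted_warning <- TRUE
    warnf("tree has a basal multifurcation; treating it as a rooted multifurcation")
  }
  if (is.null(phy$edge.length)) {
    warnf("tree has no branch lengths; defaulting to 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (any(phy$edge.length < 0)) stopf("negative branch lengths are not allowed")

  ntip <- length(phy$tip.label)
  N <- ntip + phy$Nnode
  root <- ntip + 1L

  parent <- integer(N); parent[] <- 0L
  edge_len <- numeric(N); edge_len[] <- NA_real_
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  edge_len[phy$edge[, 2]] <- phy$edge.length

  # support labels from internal node labels
  support <- rep(NA_real_, N)
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    num <- suppressWarnings(as.numeric(lab))
    support[root:N] <- num
    ok <- !is.na(num)
    if (any(ok) && all(num[ok] >= 0 & num[ok] <= 1)) {
      warnf("support labels look fractional; rescaling to [0, 100]")
      support <- support * 100
    }
    if (any(ok) && any(num[ok] < 0 | num[ok] > 100 * (1 + 1e-9)))
      stopf("support labels must lie in [0, 100]")
  }

  # preorder: parents before children
  pre <- root
  children <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = 1:N))
  stack <- root
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    pre <- c(pre, v)
    kids <- children[[v]]
    if (length(kids)) stack <- c(kids, stack)
  }
  depth <- numeric(N)
  for (v in pre) if (v != root) depth[v] <- depth[parent[v]] + edge_len[v]

  # ancestor path of each node (self .. root)
  anc_path <- vector("list", N)
  for (v in pre) anc_path[[v]] <- if (v == root) root else c(v, anc_path[[parent[v]]])

  # descendants (self included), then preorder subtree stamping gives the
  # LCA node/depth tables: deeper common ancestors overwrite shallower ones
  desc <- vector("list", N)
  for (v in rev(pre)) desc[[v]] <- c(v, unlist(desc[children[[v]]], use.names = FALSE))
  lca_node <- matrix(NA_integer_, N, N)
  for (v in pre) {
    d <- desc[[v]]
    lca_node[d, d] <- v
  }
  lca_depth <- matrix(depth[lca_node], N, N)

  structure(list(
    phy = phy, n_tip = ntip, n_node = N, root = root,
    parent = parent, edge_len = edge_len, depth = depth,
    support = support, children = children,
    anc_path = anc_path, lca_node = lca_node, lca_depth = lca_depth,
    tip_index = setNames(seq_len(ntip), phy$tip.label),
    edges = phy$edge[, 2],   # all valid edge refs (child ids)
    rooted_warning = rooted_warning
  ), class = "pd_tree")
}

#' Parse a newick string or file into a `pd_tree`
#'
#' Numeric internal node labels are kept as support values; branch lengths
#' default to 0 when absent.  Duplicate leaf names are an error; a basal
#' trifurcation is accepted as a rooted multifurcation with a warning.
#'
#' @param text newick string (used when `file` is NULL).
#' @param file path to a newick file.
#' @return a `pd_tree`.
#' @export
read_tree_newick <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(phy)) stopf("could not parse newick input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  as_pd_tree(phy)
}

#' Write a `pd_tree` back to newick
#'
#' Round-trips topology, branch lengths, leaf names, and support labels.
#'
#' @param tree a `pd_tree`.
#' @param file optional output path; when NULL the newick string is returned.
#' @export
write_tree_newick <- function(tree, file = NULL) {
  tree <- as_pd_tree(tree)
  s <- ape::write.tree(tree$phy)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Root a tree on an outgroup
#'
#' Explicit helper; never applied implicitly.
#'
#' @param tree a `pd_tree` or `phylo`.
#' @param outgroup leaf name(s).
#' @return a rooted `pd_tree`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  phy <- if (inherits(tree, "pd_tree")) tree$phy else tree
  as_pd_tree(ape::root(phy, outgroup = outgroup, resolve.root = TRUE))
}

node_id <- function(tree, x) {
  if (is.character(x)) {
    id <- tree$tip_index[x]
    if (any(is.na(id))) stopf("unknown leaf name: %s", paste(x[is.na(id)], collapse = ", "))
    unname(id)
  } else as.integer(x)
}

check_edge <- function(tree, e) {
  e <- as.integer(e)
  if (any(e < 1L | e > tree$n_node)) stopf("edge ref out of range")
  if (any(e == tree$root)) stopf("the root has no parent edge")
  e
}

#' Patristic distance between two nodes or leaves
#'
#' Sum of branch lengths on the unique path, in substitutions per site.
#'
#' @param tree a `pd_tree`.
#' @param a,b leaf names or node ids.
#' @return non-negative numeric distance.
#' @export
patristic_distance <- function(tree, a, b) {
  tree <- as_pd_tree(tree)
  i <- node_id(tree, a); j <- node_id(tree, b)
  tree$depth[i] + tree$depth[j] - 2 * tree$lca_depth[cbind(i, j)]
}

#' Are two edges phylogenetically independent?
#'
#' Two edges are independent when neither lies on the path from the root to
#' the other, i.e. neither substitution is ancestral to the other.  An edge
#' is never independent of itself.
#'
#' @param tree a `pd_tree`.
#' @param e1,e2 edge refs (child node ids); vectorized.
#' @return logical vector.
#' @export
is_independent <- function(tree, e1, e2) {
  tree <- as_pd_tree(tree)
  e1 <- check_edge(tree, e1); e2 <- check_edge(tree, e2)
  l <- tree$lca_node[cbind(e1, e2)]
  e1 != e2 & l != e1 & l != e2
}

#' Mid-edge distance between two independent edges
#'
#' The distance between the centers of the two edges: half of each edge
#' length plus the path lengths from the edges' parent nodes to the last
#' common ancestor of the two edges.  This is the inter-substitution
#' distance used throughout the homoplasy statistics.
#'
#' @param tree a `pd_tree`.
#' @param e1,e2 edge refs (child node ids); vectorized.
#' @return numeric distance(s) in substitutions per site.
#' @export
mid_edge_distance <- function(tree, e1, e2) {
  tree <- as_pd_tree(tree)
  e1 <- check_edge(tree, e1); e2 <- check_edge(tree, e2)
  if (!all(is_independent(tree, e1, e2)))
    stopf("mid_edge_distance requires phylogenetically independent edges")
  p1 <- tree$parent[e1]; p2 <- tree$parent[e2]
  dl <- tree$lca_depth[cbind(e1, e2)]
  tree$edge_len[e1] / 2 + tree$edge_len[e2] / 2 +
    (tree$depth[p1] - dl) + (tree$depth[p2] - dl)
}

#' @export
print.pd_tree <- function(x, ...) {
  cat(sprintf("pd_tree: %d leaves, %d nodes, total length %.4g subst/site\n",
              x$n_tip, x$n_node, sum(x$edge_len, na.rm = TRUE)))
  if (any(!is.na(x$support))) cat("  internal support labels present\n")
  invisible(x)
}

#' Random calibration tree
#'
#' A random rooted bifurcating tree (via `ape::rtree`) rescaled to a target
#' total branch length, the shape used by the simulation-calibration
#' experiments: many leaves, total depth of the order of a few substitutions
#' per site.
#'
#' @param n_leaves number of leaves.
#' @param total_length target sum of branch lengths (substitutions/site).
#' @param seed integer seed (private stream; the caller's RNG is untouched).
#' @return a `pd_tree`.
#' @export
random_calibration_tree <- function(n_leaves = 200L, total_length = 20,
                                    seed = 1L) {
  phy <- with_seed(seed, ape::rtree(n_leaves))
  phy$edge.length <- phy$edge.length * (total_length / sum(phy$edge.length))
  as_pd_tree(phy)
}
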