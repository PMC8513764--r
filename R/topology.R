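#' Canonical unrooted topologies
#'
#' A `topology` is a canonical, label-based representation of one unrooted
#' tree shape: the set of nontrivial splits (bipartitions of the leaf set
#' induced by internal edges) together with a deterministic key. Two trees
#' map to the same `topology` exactly when they display the same unrooted
#' shape, regardless of rooting, child order or branch lengths, which makes
#' "distinct tree topologies" well defined for multisets of sampled trees.
#'
#' Internally every split is stored both as a canonical string and as a
#' sorted integer block: leaf labels are sorted in the C locale and each
#' split is encoded by the block that does not contain the first label.
#'
#' @param x an object to convert: an [ape::phylo] tree, a Newick string, or
#'   an existing `topology`.
#' @param ... unused.
#' @return an object of class `topology` with fields `labels` (sorted leaf
#'   labels), `splits` (canonical split strings, sorted), `blocks` (integer
#'   index blocks parallel to `splits`) and `key`.
#' @examples
#' t1 <- as_topology(ape::read.tree(text = "((A,B),(C,D));"))
#' t2 <- as_topology(ape::read.tree(text = "((D,C),(B,A));"))
#' identical(t1$key, t2$key)  # TRUE: rotation and rooting are ignored
#' @export
as_topology <- function(x, ...) UseMethod("as_topology")

#' @export
as_topology.topology <- function(x, ...) x

#' @export
as_topology.phylo <- function(x, ...) {
  labs <- x$tip.label
  if (anyDuplicated(labs)) {
    stop_ti("duplicate leaf labels: %s",
            paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (length(labs) < 4) stop_ti("topologies need at least 4 leaves")
  phy <- ape::collapse.singles(x)
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  phy <- stats::reorder(phy, "postorder")
  labels <- sort_c(labs)
  n <- length(labels)
  idx <- match(phy$tip.label, labels)
  nnode <- phy$Nnode
  sets <- vector("list", n + nnode)
  for (i in seq_len(n)) sets[[i]] <- idx[i]
  e1 <- phy$edge[, 1L]
  e2 <- phy$edge[, 2L]
  for (k in seq_along(e1)) {
    sets[[e1[k]]] <- c(sets[[e1[k]]], sets[[e2[k]]])
  }
  blocks <- list()
  all_idx <- seq_len(n)
  for (k in which(e2 > n)) {
    blk <- sets[[e2[k]]]
    if (length(blk) >= 2 && length(blk) <= n - 2) {
      if (1L %in% blk) blk <- setdiff(all_idx, blk)
      blocks[[length(blocks) + 1L]] <- sort(blk)
    }
  }
  new_topology(labels, unique(blocks))
}

#' @export
as_topology.character <- function(x, ...) {
  as_topology(ape::read.tree(text = x))
}

# constructor from sorted labels and a list of integer blocks
# (each block excludes index 1); canonical ordering applied here
new_topology <- function(labels, blocks) {
  strings <- vapply(blocks, function(b) paste(labels[b], collapse = ","), "")
  o <- order(strings, method = "radix")
  blocks <- blocks[o]
  strings <- strings[o]
  structure(
    list(labels = labels,
         splits = strings,
         blocks = blocks,
         key = paste0(paste(labels, collapse = ","), "||",
                      paste(strings, collapse = ";"))),
    class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d leaves, %d nontrivial splits%s\n",
              length(x$labels), length(x$splits),
              if (is_binary_topology(x)) " (binary)" else ""))
  invisible(x)
}

#' Canonical key of a tree topology
#'
#' Returns the deterministic identifier of the unrooted topology of `tree`.
#' Keys are equal exactly when the unrooted shapes (on the same leaf set)
#' are equal; branch lengths, rooting and child order never affect the key.
#'
#' @param tree a `phylo` tree, Newick string or `topology`.
#' @return a character scalar.
#' @export
canonical_key <- function(tree) as_topology(tree)$key

#' Nontrivial splits of a topology
#'
#' The bipartitions of the leaf set induced by the internal edges of the
#' tree. Trivial splits (one leaf versus the rest) are excluded, so a binary
#' topology on n leaves has exactly n - 3 splits and a star tree has none.
#' Each split is rendered as the comma-joined block of leaf labels that does
#' not contain the lexicographically first label.
#'
#' @param t a `phylo` tree, Newick string or `topology`.
#' @return a character vector of canonical split strings (sorted).
#' @export
nontrivial_splits <- function(t) as_topology(t)$splits

is_binary_topology <- function(topo) {
  length(topo$splits) == length(topo$labels) - 3L
}

# laminar structure of the blocks of a topology (all blocks exclude leaf 1,
# so compatibility means the blocks form a laminar family).
# Returns parent[i] (0 = the vertex adjacent to leaf 1) and, for each leaf,
# the smallest block containing it (0 if none).
laminar_structure <- function(labels, blocks) {
  k <- length(blocks)
  n <- length(labels)
  sizes <- lengths(blocks)
  parent <- integer(k)
  for (i in seq_len(k)) {
    best <- 0L
    bestsize <- n + 1L
    for (j in seq_len(k)) {
      if (j != i && sizes[j] > sizes[i] && sizes[j] < bestsize &&
          all(blocks[[i]] %in% blocks[[j]])) {
        best <- j
        bestsize <- sizes[j]
      }
    }
    parent[i] <- best
  }
  tip_parent <- integer(n)
  for (t in seq_len(n)) {
    best <- 0L
    bestsize <- n + 1L
    for (j in seq_len(k)) {
      if (sizes[j] < bestsize && t %in% blocks[[j]]) {
        best <- j
        bestsize <- sizes[j]
      }
    }
    tip_parent[t] <- best
  }
  list(parent = parent, tip_parent = tip_parent, sizes = sizes)
}

# render a laminar block family as a Newick string rooted at the vertex
# adjacent to the first leaf; node_labels (parallel to blocks) optional
blocks_to_newick <- function(labels, blocks, node_labels = NULL) {
  lam <- laminar_structure(labels, blocks)
  render <- function(node) {
    ch_blocks <- which(lam$parent == node)
    ch_tips <- which(lam$tip_parent == node)
    if (node != 0L) ch_tips <- setdiff(ch_tips, integer(0))
    parts <- c(vapply(ch_blocks, render, ""), labels[ch_tips])
    parts <- sort_c(parts)
    lab <- if (!is.null(node_labels) && node != 0L) node_labels[node] else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(render(0L), ";")
}

#' Reconstruct a phylo tree from a topology
#'
#' Builds an [ape::phylo] object displaying exactly the splits of `x`. The
#' returned tree is unrooted (drawn from the vertex adjacent to the first
#' leaf label) and carries no branch lengths.
#'
#' @param x a `topology` (or a `consensus_tree`, whose split frequencies
#'   become node labels).
#' @param ... unused.
#' @return a `phylo` object.
#' @method as.phylo topology
#' @export
as.phylo.topology <- function(x, ...) {
  ape::read.tree(text = blocks_to_newick(x$labels, x$blocks))
}

# two blocks (both excluding leaf 1) are compatible iff nested or disjoint
blocks_compatible <- function(a, b) {
  inter <- sum(a %in% b)
  inter == 0L || inter == length(a) || inter == length(b)
}
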