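#' @name distances
#' @title Tree-to-tree distances and NNI neighborhoods
#' @description
#' Pairwise distances between unrooted topologies, with Robinson-Foulds
#' (RF) as the built-in metric. Throughout the package RF is the
#' *un-halved* symmetric difference of the two nontrivial split sets, so
#' that one nearest-neighbor interchange (NNI) between binary trees gives
#' an RF of exactly 2 and a 2-RF island coincides with a 1-NNI island.
#' A registry lets user metrics (including branch-length-aware ones) plug
#' into island finding without code changes.
NULL

.metric_registry <- new.env(parent = emptyenv())

#' Register a tree distance metric
#'
#' @param name metric identifier.
#' @param fn a function `(topology, topology) -> nonnegative number`.
#' @export
register_metric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .metric_registry)
  invisible(name)
}

#' @rdname register_metric
#' @export
list_metrics <- function() sort_c(ls(.metric_registry))

get_metric <- function(name) {
  if (!exists(name, envir = .metric_registry, inherits = FALSE)) {
    stop_ti("unknown metric '%s'; registered: %s", name,
            paste(list_metrics(), collapse = ", "))
  }
  get(name, envir = .metric_registry)
}

#' Robinson-Foulds distance
#'
#' The size of the symmetric difference of the nontrivial split sets of two
#' topologies on the same leaf set (un-halved: each split present in one
#' tree but not the other counts 1). For binary trees the value is even,
#' at most `2 * (n - 3)`, and equals 2 exactly when the trees are one NNI
#' apart.
#'
#' @param t1,t2 trees (`phylo`, Newick or `topology`) on the same leaf set.
#' @return a nonnegative integer.
#' @examples
#' rf_distance("((A,B),(C,D));", "((A,C),(B,D));")  # 2
#' @export
rf_distance <- function(t1, t2) {
  a <- as_topology(t1)
  b <- as_topology(t2)
  if (!identical(a$labels, b$labels)) stop_ti("leaf sets differ")
  length(a$splits) + length(b$splits) -
    2L * sum(a$splits %in% b$splits)
}

#' Pairwise distance matrix over unique topologies
#'
#' Computes the symmetric distance matrix over the *unique* topologies of a
#' multiset (multiplicity never duplicates rows). For the RF metric the
#' computation is vectorized through a split incidence matrix; other
#' registered metrics are evaluated pairwise.
#'
#' @param trees a [tree_multiset()].
#' @param metric a registered metric name (see [list_metrics()]).
#' @return an object of class `tree_dist`: list with `keys` (topology keys
#'   in multiset order), `matrix` (symmetric, zero diagonal) and `metric`.
#' @export
pairwise_matrix <- function(trees, metric = "rf") {
  fn <- get_metric(metric)
  k <- length(trees$keys)
  if (metric == "rf") {
    all_splits <- unique(unlist(lapply(trees$topologies, `[[`, "splits")))
    X <- matrix(0, nrow = k, ncol = length(all_splits))
    for (i in seq_len(k)) {
      X[i, match(trees$topologies[[i]]$splits, all_splits)] <- 1
    }
    shared <- tcrossprod(X)
    nsplits <- rowSums(X)
    m <- outer(nsplits, nsplits, `+`) - 2 * shared
    m[abs(m) < 1e-9] <- 0
  } else {
    m <- matrix(0, k, k)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          m[i, j] <- m[j, i] <- fn(trees$topologies[[i]], trees$topologies[[j]])
        }
      }
    }
  }
  structure(list(keys = trees$keys, matrix = m, metric = metric),
            class = "tree_dist")
}

#' @export
print.tree_dist <- function(x, ...) {
  cat(sprintf("<tree_dist> %d x %d, metric '%s'\n",
              length(x$keys), length(x$keys), x$metric))
  invisible(x)
}

# children components (blocks or tips, as integer index sets) of each
# vertex of the tree rooted at the vertex adjacent to leaf 1
vertex_components <- function(topo) {
  lam <- laminar_structure(topo$labels, topo$blocks)
  k <- length(topo$blocks)
  comp <- vector("list", k + 1L)  # index node+1; node 0 = top vertex
  for (node in 0:k) {
    ch_b <- which(lam$parent == node)
    ch_t <- which(lam$tip_parent == node)
    comp[[node + 1L]] <- c(lapply(ch_b, function(j) topo$blocks[[j]]),
                           as.list(ch_t))
  }
  list(lam = lam, comp = comp)
}

# the three local resolutions of internal edge e (index into blocks):
# a list of three blocks (original first), each the side excluding leaf 1
edge_resolutions <- function(topo, e, vc = vertex_components(topo)) {
  ch <- vc$comp[[e + 1L]]
  if (length(ch) != 2L) stop_ti("edge resolutions need a binary topology")
  p <- vc$lam$parent[e]
  pset <- if (p == 0L) seq_along(topo$labels)[-1L] else topo$blocks[[p]]
  C <- setdiff(pset, topo$blocks[[e]])
  list(sort(topo$blocks[[e]]),
       sort(c(ch[[1L]], C)),
       sort(c(ch[[2L]], C)))
}

#' NNI neighborhood of a binary topology
#'
#' All topologies reachable from `t` by exactly one nearest-neighbor
#' interchange: two alternatives per internal edge, `2 * (n - 3)` neighbors
#' in total, all distinct and all at RF distance 2 from `t`. NNI on
#' multifurcating trees is refused because the rearrangement is ambiguous
#' at a polytomy.
#'
#' @param t a binary tree (`phylo`, Newick or `topology`) with >= 4 leaves.
#' @return a named list of `topology` objects (names are canonical keys).
#' @export
nni_neighborhood <- function(t) {
  topo <- as_topology(t)
  if (length(topo$labels) < 4L) stop_ti("NNI needs at least 4 leaves")
  if (!is_binary_topology(topo)) {
    stop_ti("NNI neighborhood requires a binary topology; use RF-based islands for multifurcating trees")
  }
  vc <- vertex_components(topo)
  out <- list()
  for (e in seq_along(topo$blocks)) {
    res <- edge_resolutions(topo, e, vc)
    for (r in 2:3) {
      blocks <- topo$blocks
      blocks[[e]] <- res[[r]]
      nb <- new_topology(topo$labels, blocks)
      out[[nb$key]] <- nb
    }
  }
  out[names(out) != topo$key]
}

#' Exact NNI distance by breadth-first search
#'
#' Length of the shortest NNI path between two binary topologies, found by
#' breadth-first expansion of NNI neighborhoods. Exact rearrangement
#' distances are NP-hard in general, so this is a small-instance oracle: it
#' refuses trees above `max_leaves` and searches only up to `max_radius`.
#'
#' @param t1,t2 binary trees on the same leaf set.
#' @param max_radius maximum path length to search.
#' @param max_leaves guard on tree size (default 12).
#' @return the NNI distance, or `NA_integer_` if it exceeds `max_radius`.
#' @export
nni_distance_exact <- function(t1, t2, max_radius = 4L, max_leaves = 12L) {
  a <- as_topology(t1)
  b <- as_topology(t2)
  if (!identical(a$labels, b$labels)) stop_ti("leaf sets differ")
  if (length(a$labels) > max_leaves) {
    stop_ti("exact NNI search refused beyond %d leaves (NP-hard in general); use RF-based islands instead",
            max_leaves)
  }
  if (max_radius < 0) stop_ti("max_radius must be >= 0")
  if (identical(a$key, b$key)) return(0L)
  visited <- new.env(parent = emptyenv())
  assign(a$key, TRUE, envir = visited)
  frontier <- list(a)
  for (depth in seq_len(max_radius)) {
    nxt <- list()
    for (t in frontier) {
      for (nb in nni_neighborhood(t)) {
        if (identical(nb$key, b$key)) return(depth)
        if (!exists(nb$key, envir = visited, inherits = FALSE)) {
          assign(nb$key, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    if (!length(nxt)) break
    frontier <- nxt
  }
  NA_integer_
}

#' Export a distance matrix
#'
#' Writes either a square PHYLIP matrix (taxa named `T1..Tk`, with a
#' key-mapping table alongside impossible to fit in PHYLIP names) or a
#' three-column TSV edge list (`key1`, `key2`, `distance`) over unordered
#' pairs.
#'
#' @param dm a `tree_dist` from [pairwise_matrix()].
#' @param file output path.
#' @param format `"phylip"` or `"tsv"`.
#' @export
write_distance_matrix <- function(dm, file, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  k <- length(dm$keys)
  if (format == "phylip") {
    ids <- sprintf("T%d", seq_len(k))
    lines <- c(sprintf("%5d", k),
               vapply(seq_len(k), function(i) {
                 paste0(formatC(ids[i], width = -10),
                        paste(format(dm$matrix[i, ], trim = TRUE),
                              collapse = " "))
               }, ""))
    writeLines(lines, file)
  } else {
    pairs <- which(upper.tri(dm$matrix), arr.ind = TRUE)
    df <- data.frame(key1 = dm$keys[pairs[, 1L]],
                     key2 = dm$keys[pairs[, 2L]],
                     distance = dm$matrix[pairs],
                     stringsAsFactors = FALSE)
    write_tsv_plain(df, file)
  }
  invisible(file)
}
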