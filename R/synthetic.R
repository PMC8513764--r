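#' @name synthetic
#' @title Planted tree-island distributions
#' @description
#' Generates tree multisets with known island structure: well-separated
#' base topologies, each expanded into an island by combining the three
#' NNI resolutions of a set of pairwise non-adjacent internal edges. With
#' `i` perturbed edges an island holds up to `3^i` topologies, the same
#' combinatorial mechanism that produces large island bias in real
#' distributions, and every planted island is 1-NNI connected so the truth
#' partition equals the RF-threshold-2 partition. The generator's defaults
#' reproduce the structure of the motivating parsimony analysis: five
#' islands of sizes 18, 72, 90, 216 and 486 built from 4, 6, 6, 8 and 9
#' unstable edges on 76-leaf trees, all multiplicities 1.
NULL

#' Configuration for the planted-island generator
#'
#' @param n_leaves number of leaves (default 76, the size of the
#'   motivating morphological data set).
#' @param i integer vector: number of perturbed (NNI-ambiguous) internal
#'   edges per island; island k holds at most `3^i[k]` topologies.
#' @param occupancy fraction of each island's `3^i` combinations to keep,
#'   in `(0, 1]`; the kept combinations always form a 1-NNI-connected set.
#'   Defaults to the fractions that yield island sizes 18, 72, 90, 216,
#'   486 under the default `i`.
#' @param sizes alternative to `occupancy`: target island sizes directly
#'   (`sizes[k] <= 3^i[k]`).
#' @param mass_model `"unit"` (every topology once: set semantics, as for
#'   most parsimonious trees) or `"geometric"` (multiplicities
#'   `1 + rgeom`, emulating a posterior multiset).
#' @param mass_prob success probability of the geometric mass model.
#' @param min_separation required minimum RF distance between topologies
#'   of different islands; must exceed the detection threshold 2.
#' @param seed integer seed; the generated set is fully determined by
#'   (config, seed).
#' @return a `plant_config` list.
#' @export
plant_config <- function(n_leaves = 76,
                         i = c(4, 6, 6, 8, 9),
                         occupancy = NULL,
                         sizes = NULL,
                         mass_model = c("unit", "geometric"),
                         mass_prob = 0.5,
                         min_separation = 4,
                         seed = NULL) {
  mass_model <- match.arg(mass_model)
  if (any(i < 0) || any(i != floor(i))) stop_ti("i must be nonnegative integers")
  if (is.null(sizes)) {
    if (is.null(occupancy)) {
      occupancy <- if (identical(as.numeric(i), c(4, 6, 6, 8, 9))) {
        c(18, 72, 90, 216, 486) / 3^c(4, 6, 6, 8, 9)
      } else {
        rep(1, length(i))
      }
    }
    if (length(occupancy) == 1L) occupancy <- rep(occupancy, length(i))
    if (any(occupancy <= 0) || any(occupancy > 1)) {
      stop_ti("occupancy must be in (0, 1]")
    }
    sizes <- pmax(1L, as.integer(round(occupancy * 3^i)))
  }
  if (length(sizes) != length(i)) stop_ti("sizes and i must have equal length")
  if (any(sizes > 3^i)) stop_ti("island size cannot exceed 3^i")
  if (min_separation <= 2) stop_ti("min_separation must exceed the 1-NNI detection threshold 2")
  if (n_leaves < 2 * max(i) + 4) {
    stop_ti("n_leaves too small for %d pairwise non-adjacent internal edges",
            max(i))
  }
  structure(list(n_leaves = n_leaves, i = as.integer(i), sizes = sizes,
                 mass_model = mass_model, mass_prob = mass_prob,
                 min_separation = min_separation, seed = seed),
            class = "plant_config")
}

# pick `want` internal edges (block indices) at random that are pairwise
# non-adjacent AND not connected by a single edge, so each perturbed edge
# is an independent, spatially separated source of local instability
# (collapsing one never touches the region of another)
pick_nonadjacent_edges <- function(topo, want) {
  if (want == 0L) return(integer(0))
  lam <- laminar_structure(topo$labels, topo$blocks)
  k <- length(topo$blocks)
  p <- lam$parent
  p2 <- ifelse(p > 0L, p[pmax(p, 1L)], -1L)  # grandparent vertex (-1: none)
  cand <- sample.int(k)
  chosen <- integer(0)
  conflict <- function(a, b) {
    # share a vertex ...
    p[a] == b || p[b] == a || p[a] == p[b] ||
      # ... or their endpoint vertices are joined by one edge
      (p2[a] != -1L && (p2[a] == b || p2[a] == p[b])) ||
      (p2[b] != -1L && (p2[b] == a || p2[b] == p[a]))
  }
  for (e in cand) {
    if (all(!vapply(chosen, conflict, TRUE, a = e))) {
      chosen <- c(chosen, e)
      if (length(chosen) == want) return(chosen)
    }
  }
  NULL
}

#' Apply NNI resolutions at chosen edges
#'
#' Deterministically rewrites a binary topology by replacing the split at
#' each chosen internal edge with one of its three NNI-local resolutions
#' (0 keeps the original split; 1 and 2 are the two alternatives). Because
#' the edges are pairwise non-adjacent the moves commute: distinct
#' resolution vectors give distinct topologies, and vectors differing in
#' one coordinate are one NNI (RF 2) apart.
#'
#' @param base a binary `topology` (or tree convertible to one).
#' @param edges split strings of `base` (see [nontrivial_splits()])
#'   identifying pairwise non-adjacent internal edges.
#' @param resolution integer vector in `{0, 1, 2}`, one entry per edge.
#' @return a `topology`.
#' @export
perturb_edges <- function(base, edges, resolution) {
  topo <- as_topology(base)
  if (!is_binary_topology(topo)) stop_ti("base must be binary")
  eidx <- match(edges, topo$splits)
  if (anyNA(eidx)) stop_ti("edge not found among the base's nontrivial splits")
  if (length(resolution) != length(eidx) ||
      !all(resolution %in% 0:2)) {
    stop_ti("resolution must be one value in {0,1,2} per edge")
  }
  lam <- laminar_structure(topo$labels, topo$blocks)
  for (a in eidx) {
    for (b in eidx) {
      if (a < b && (lam$parent[a] == b || lam$parent[b] == a ||
                    lam$parent[a] == lam$parent[b])) {
        stop_ti("chosen edges must be pairwise non-adjacent")
      }
    }
  }
  vc <- vertex_components(topo)
  blocks <- topo$blocks
  for (j in seq_along(eidx)) {
    if (resolution[j] > 0L) {
      res <- edge_resolutions(topo, eidx[j], vc)
      blocks[[eidx[j]]] <- res[[resolution[j] + 1L]]
    }
  }
  new_topology(topo$labels, blocks)
}

# grow a connected subset of {0,1,2}^i of the requested size under
# single-coordinate moves, starting from the all-zero vector
grow_connected_vectors <- function(i, size) {
  if (i == 0L) return(matrix(0L, nrow = 1L, ncol = 0L))
  if (size == 3^i) {
    m <- as.matrix(expand.grid(rep(list(0:2), i), KEEP.OUT.ATTRS = FALSE))
    dimnames(m) <- NULL
    return(m)
  }
  seen <- new.env(parent = emptyenv())
  vecs <- matrix(0L, nrow = size, ncol = i)
  assign(paste(vecs[1L, ], collapse = ""), TRUE, envir = seen)
  count <- 1L
  guard <- 0L
  while (count < size) {
    guard <- guard + 1L
    if (guard > 1000L * size) stop_ti("connected growth failed (internal)")
    v <- vecs[sample.int(count, 1L), ]
    coord <- sample.int(i, 1L)
    v[coord] <- sample(setdiff(0:2, v[coord]), 1L)
    key <- paste(v, collapse = "")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      count <- count + 1L
      vecs[count, ] <- v
    }
  }
  vecs
}

random_unrooted_tree <- function(n) {
  ape::unroot(ape::rtree(n, rooted = TRUE,
                         tip.label = sprintf("t%03d", seq_len(n))))
}

#' Generate a tree multiset with planted islands
#'
#' Builds K well-separated base topologies by seeded random SPR walks from
#' a common random starting tree (walk length `2 + min_separation` moves,
#' lengthened on retry), accepting bases only when every pair is far
#' enough apart that members of different islands are guaranteed to be
#' more than `min_separation` RF units apart. Island k is then a
#' 1-NNI-connected set of `sizes[k]` combinations of NNI resolutions at
#' `i[k]` pairwise non-adjacent internal edges of base k, and
#' multiplicities are drawn from the mass model. Inter-island separation
#' is re-verified on the generated set.
#'
#' @param cfg a [plant_config()].
#' @return a list: `trees` (the [tree_multiset()]), `partition` (the true
#'   `island_partition` at RF threshold 2), `truth` (data frame: `key`,
#'   `island`, `i`, `multiplicity`).
#' @examples
#' out <- plant_islands(plant_config(n_leaves = 12, i = c(1, 2),
#'                                   sizes = c(3, 9), seed = 1))
#' island_summary(out$partition)
#' @export
plant_islands <- function(cfg) {
  stopifnot(inherits(cfg, "plant_config"))
  with_seed(cfg$seed, plant_islands_impl(cfg))
}

plant_islands_impl <- function(cfg) {
  K <- length(cfg$i)
  # required base separation guarantees member separation > min_separation:
  # members sit within 2*i RF of their base (triangle inequality)
  req <- outer(2 * cfg$i, 2 * cfg$i, `+`) + cfg$min_separation
  walk <- 2 + cfg$min_separation
  bases <- NULL
  for (try in seq_len(25L)) {
    start <- random_unrooted_tree(cfg$n_leaves)
    cand <- lapply(seq_len(K), function(k) {
      as_topology(phangorn::rSPR(start, moves = walk))
    })
    ok <- TRUE
    for (a in seq_len(K)) {
      for (b in seq_len(K)) {
        if (a < b && rf_distance(cand[[a]], cand[[b]]) < req[a, b]) ok <- FALSE
      }
    }
    if (ok && all(vapply(cand, is_binary_topology, TRUE))) {
      bases <- cand
      break
    }
    walk <- walk + 2
  }
  if (is.null(bases)) {
    stop_ti("could not generate %d bases with pairwise RF >= required separation; try more leaves", K)
  }
  topos <- list()
  island_of <- integer(0)
  for (k in seq_len(K)) {
    base <- bases[[k]]
    edges <- NULL
    for (try in seq_len(50L)) {
      edges <- pick_nonadjacent_edges(base, cfg$i[k])
      if (!is.null(edges)) break
    }
    if (is.null(edges) && cfg$i[k] > 0L) {
      stop_ti("could not find %d non-adjacent internal edges; try more leaves",
              cfg$i[k])
    }
    vc <- vertex_components(base)
    alts <- lapply(edges, function(e) edge_resolutions(base, e, vc))
    vecs <- grow_connected_vectors(cfg$i[k], cfg$sizes[k])
    for (r in seq_len(nrow(vecs))) {
      blocks <- base$blocks
      for (j in seq_along(edges)) {
        v <- vecs[r, j]
        if (v > 0L) blocks[[edges[j]]] <- alts[[j]][[v + 1L]]
      }
      topos[[length(topos) + 1L]] <- new_topology(base$labels, blocks)
      island_of <- c(island_of, k)
    }
  }
  keys <- vapply(topos, `[[`, "", "key")
  if (anyDuplicated(keys)) stop_ti("planted topologies collided across islands (internal)")
  mult <- switch(cfg$mass_model,
                 unit = rep(1L, length(topos)),
                 geometric = 1L + stats::rgeom(length(topos), cfg$mass_prob))
  ms <- structure(
    list(labels = topos[[1L]]$labels,
         topologies = topos,
         multiplicity = as.integer(mult),
         keys = keys,
         total_mass = as.integer(sum(mult))),
    class = "tree_multiset")
  verify_separation(ms, island_of, cfg$min_separation)
  part <- new_island_partition("rf", 2, split(seq_along(keys), island_of), ms)
  truth <- data.frame(key = keys,
                      island = unname(part$assignment[keys]),
                      i = cfg$i[island_of],
                      multiplicity = ms$multiplicity,
                      stringsAsFactors = FALSE)
  list(trees = ms, partition = part, truth = truth)
}

# check the minimum RF between members of different islands via the split
# incidence matrix (vectorized, so feasible on every generated set)
verify_separation <- function(ms, island_of, min_separation) {
  all_splits <- unique(unlist(lapply(ms$topologies, `[[`, "splits")))
  X <- matrix(0, nrow = length(ms$keys), ncol = length(all_splits))
  for (r in seq_along(ms$keys)) {
    X[r, match(ms$topologies[[r]]$splits, all_splits)] <- 1
  }
  shared <- tcrossprod(X)
  ns <- rowSums(X)
  rf <- outer(ns, ns, `+`) - 2 * shared
  inter <- outer(island_of, island_of, `!=`)
  if (any(inter) && min(rf[inter]) < min_separation) {
    stop_ti("generated set violates min_separation (internal)")
  }
  invisible(TRUE)
}

#' Write a planted set with its truth table
#'
#' Writes the generated trees (Newick or Nexus) and a TSV truth table
#' (`key`, `island`, `i`, `multiplicity`).
#'
#' @param planted result of [plant_islands()].
#' @param tree_file,truth_file output paths.
#' @param format tree format.
#' @export
write_planted <- function(planted, tree_file, truth_file,
                          format = c("newick", "nexus")) {
  write_trees(planted$trees, tree_file, format = match.arg(format))
  write_tsv_plain(planted$truth, truth_file)
  invisible(NULL)
}
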