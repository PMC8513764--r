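#' @name islands
#' @title Tree islands
#' @description
#' Given a multiset of topologies, a pairwise distance `d` and a threshold
#' `x`, build the graph with an edge between two topologies whenever
#' `d <= x`; the *islands* are its connected components. Islands partition
#' the multiset exhaustively and exclusively, and islands at a threshold
#' `x` nest inside islands at any larger threshold. Each island reports its
#' size (distinct topologies), mass (total multiplicity) and density
#' (size / mass).
NULL

# union-find with path compression, state held in an environment
uf_new <- function(k) {
  e <- new.env(parent = emptyenv())
  e$parent <- seq_len(k)
  e
}
uf_find <- function(e, i) {
  root <- i
  while (e$parent[root] != root) root <- e$parent[root]
  while (e$parent[i] != root) {
    nxt <- e$parent[i]
    e$parent[i] <- root
    i <- nxt
  }
  root
}
uf_union <- function(e, i, j) {
  ri <- uf_find(e, i)
  rj <- uf_find(e, j)
  if (ri != rj) e$parent[max(ri, rj)] <- min(ri, rj)
  invisible(NULL)
}
uf_roots <- function(e) {
  vapply(seq_along(e$parent), function(i) uf_find(e, i), 0L)
}

new_island_partition <- function(metric, x, member_idx_list, trees) {
  member_idx_list <- unname(member_idx_list)
  islands <- lapply(member_idx_list, function(idx) {
    keys <- trees$keys[idx]
    o <- order(keys, method = "radix")
    keys <- keys[o]
    mass <- sum(trees$multiplicity[idx])
    list(member_keys = keys,
         size = length(idx),
         mass = as.integer(mass),
         density = length(idx) / mass)
  })
  sizes <- vapply(islands, `[[`, 0L, "size")
  firstkey <- vapply(islands, function(isl) isl$member_keys[1L], "")
  o <- order(-sizes, firstkey, method = "radix")
  islands <- islands[o]
  assignment <- integer(length(trees$keys))
  names(assignment) <- trees$keys
  for (i in seq_along(islands)) {
    assignment[islands[[i]]$member_keys] <- i
  }
  structure(list(metric = metric, x = x, islands = islands,
                 assignment = assignment),
            class = "island_partition")
}

#' @export
print.island_partition <- function(x, ...) {
  cat(sprintf("<island_partition> metric '%s', threshold %g: %d islands\n",
              x$metric, x$x, length(x$islands)))
  s <- island_summary(x)
  print(utils::head(s, 10L), row.names = FALSE)
  if (nrow(s) > 10L) cat(sprintf("  ... %d more islands\n", nrow(s) - 10L))
  invisible(x)
}

#' Summarize an island partition
#'
#' @param partition an `island_partition`.
#' @return a data frame with one row per island: `island`, `size`, `mass`,
#'   `density`.
#' @export
island_summary <- function(partition) {
  data.frame(island = seq_along(partition$islands),
             size = vapply(partition$islands, `[[`, 0L, "size"),
             mass = vapply(partition$islands, `[[`, 0L, "mass"),
             density = vapply(partition$islands, `[[`, 0, "density"))
}

#' Find islands from a distance matrix
#'
#' Partitions the topologies of a multiset into islands at threshold `x`:
#' connected components (computed by union-find) of the graph with an edge
#' between topologies `T`, `T'` whenever `d(T, T') <= x`. Islands are
#' numbered by decreasing size, ties broken by the lexicographically
#' smallest member key, so labels are reproducible across runs.
#'
#' @param matrix a `tree_dist` from [pairwise_matrix()].
#' @param multiset the [tree_multiset()] the matrix was computed from (its
#'   multiplicities give island masses).
#' @param x nonnegative distance threshold.
#' @return an `island_partition`.
#' @export
find_islands <- function(matrix, multiset, x) {
  if (x < 0) stop_ti("threshold x must be nonnegative")
  if (!all(multiset$keys %in% matrix$keys)) {
    stop_ti("distance matrix does not cover the multiset")
  }
  idx <- match(multiset$keys, matrix$keys)
  m <- matrix$matrix[idx, idx, drop = FALSE]
  k <- length(multiset$keys)
  uf <- uf_new(k)
  for (i in seq_len(k)) {
    js <- which(m[i, ] <= x)
    js <- js[js > i]
    for (j in js) uf_union(uf, i, j)
  }
  comp <- split(seq_len(k), uf_roots(uf))
  new_island_partition(matrix$metric, x, comp, multiset)
}

#' Find 1-NNI islands without a distance matrix
#'
#' Direct neighborhood algorithm for binary topologies: generate the 1-NNI
#' neighborhood of each tree in the distribution, filter it to the trees
#' actually present, and merge overlapping neighborhoods until only the
#' islands remain. The result equals `find_islands(rf matrix, x = 2)` (one
#' NNI between binary trees is an RF of 2) but avoids materializing the
#' full matrix, which pays off when the distribution is much smaller than
#' its neighborhood space.
#'
#' @param trees a [tree_multiset()] whose topologies are all binary.
#' @return an `island_partition` (metric `"rf"`, threshold 2).
#' @export
find_1nni_islands <- function(trees) {
  if (!all(vapply(trees$topologies, is_binary_topology, TRUE))) {
    stop_ti("find_1nni_islands requires binary topologies; use find_islands with the rf metric instead")
  }
  k <- length(trees$keys)
  pos <- new.env(parent = emptyenv())
  for (i in seq_len(k)) assign(trees$keys[i], i, envir = pos)
  uf <- uf_new(k)
  for (i in seq_len(k)) {
    nb_keys <- names(nni_neighborhood(trees$topologies[[i]]))
    for (key in nb_keys) {
      if (!exists(key, envir = pos, inherits = FALSE)) next
      uf_union(uf, i, get(key, envir = pos))
    }
  }
  comp <- split(seq_len(k), uf_roots(uf))
  new_island_partition("rf", 2, comp, trees)
}

#' Island-size spectra across thresholds
#'
#' For each threshold, counts the islands of each size, giving the profile
#' of how island structure coarsens as the threshold grows: island counts
#' are non-increasing in `x` and islands at smaller thresholds nest inside
#' islands at larger ones.
#'
#' @param trees a [tree_multiset()].
#' @param metric registered metric name.
#' @param thresholds ascending numeric vector of thresholds.
#' @return a data frame of class `island_profile` with columns `threshold`,
#'   `island_size`, `n_islands`; `print()` shows the wide
#'   size-by-threshold layout with a total row.
#' @export
island_profile <- function(trees, metric = "rf", thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_ti("thresholds must be strictly ascending")
  }
  dm <- pairwise_matrix(trees, metric)
  rows <- list()
  for (x in thresholds) {
    part <- find_islands(dm, trees, x)
    sizes <- vapply(part$islands, `[[`, 0L, "size")
    tab <- table(sizes)
    rows[[length(rows) + 1L]] <-
      data.frame(threshold = x,
                 island_size = as.integer(names(tab)),
                 n_islands = as.integer(tab))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("island_profile", "data.frame")
  out
}

#' @export
print.island_profile <- function(x, ...) {
  df <- as.data.frame(x)
  sizes <- sort(unique(df$island_size))
  ths <- unique(df$threshold)
  wide <- matrix(0L, nrow = length(sizes), ncol = length(ths),
                 dimnames = list(sizes, sprintf("x=%g", ths)))
  for (i in seq_len(nrow(df))) {
    wide[as.character(df$island_size[i]),
         sprintf("x=%g", df$threshold[i])] <- df$n_islands[i]
  }
  wide <- rbind(wide, Total = colSums(wide))
  cat("<island_profile> islands per size (rows) and threshold (columns)\n")
  print(wide)
  invisible(x)
}

#' Average NNI-graph degree of an island
#'
#' The mean, over an island's members, of the number of fellow members
#' within distance `x` (self excluded). At the RF threshold 2 this is the
#' average vertex degree of the island's NNI graph: islands produced by
#' rearrangements around a few unstable nodes are densely connected and
#' have high average degree.
#'
#' @param island one element of `partition$islands`.
#' @param matrix the `tree_dist` the partition was computed from.
#' @param x the partition's threshold.
#' @return a nonnegative number (0 for a singleton island).
#' @export
average_degree <- function(island, matrix, x) {
  idx <- match(island$member_keys, matrix$keys)
  if (anyNA(idx)) stop_ti("island members missing from distance matrix")
  if (length(idx) == 1L) return(0)
  sub <- matrix$matrix[idx, idx, drop = FALSE]
  mean(rowSums(sub <= x) - 1)
}

#' @rdname average_degree
#' @param partition an `island_partition`.
#' @return for `average_degrees()`, one value per island.
#' @export
average_degrees <- function(partition, matrix) {
  vapply(partition$islands, average_degree, 0, matrix = matrix,
         x = partition$x)
}

#' Export island results
#'
#' `write_island_assignment()` writes one row per topology (`key`,
#' `island`, `multiplicity`); `write_island_summary()` writes one row per
#' island (`island`, `size`, `mass`, `density` and, when a distance matrix
#' is supplied, `average_degree`); `write_island_graph()` writes the
#' threshold graph as a TSV edge list or GraphML.
#'
#' @param partition an `island_partition`.
#' @param trees the underlying [tree_multiset()].
#' @param file output path.
#' @export
write_island_assignment <- function(partition, trees, file) {
  df <- data.frame(key = trees$keys,
                   island = unname(partition$assignment[trees$keys]),
                   multiplicity = trees$multiplicity,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, file)
  invisible(file)
}

#' @rdname write_island_assignment
#' @param matrix optional `tree_dist` for average degrees.
#' @export
write_island_summary <- function(partition, file, matrix = NULL) {
  df <- island_summary(partition)
  if (!is.null(matrix)) df$average_degree <- average_degrees(partition, matrix)
  write_tsv_plain(df, file)
  invisible(file)
}

#' @rdname write_island_assignment
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @export
write_island_graph <- function(partition, matrix, file,
                               format = c("tsv", "graphml")) {
  format <- match.arg(format)
  keys <- names(partition$assignment)
  idx <- match(keys, matrix$keys)
  m <- matrix$matrix[idx, idx, drop = FALSE]
  pairs <- which(upper.tri(m) & m <= partition$x, arr.ind = TRUE)
  if (format == "tsv") {
    df <- data.frame(key1 = keys[pairs[, 1L]], key2 = keys[pairs[, 2L]],
                     distance = m[pairs], stringsAsFactors = FALSE)
    write_tsv_plain(df, file)
  } else {
    esc <- function(s) {
      s <- gsub("&", "&amp;", s, fixed = TRUE)
      s <- gsub("<", "&lt;", s, fixed = TRUE)
      gsub(">", "&gt;", s, fixed = TRUE)
    }
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"d0\" for=\"edge\" attr.name=\"distance\" attr.type=\"double\"/>",
      "  <key id=\"d1\" for=\"node\" attr.name=\"island\" attr.type=\"int\"/>",
      "  <graph edgedefault=\"undirected\">",
      sprintf("    <node id=\"n%d\"><data key=\"d1\">%d</data></node>",
              seq_along(keys), unname(partition$assignment[keys])),
      sprintf("    <edge source=\"n%d\" target=\"n%d\"><data key=\"d0\">%g</data></edge>",
              pairs[, 1L], pairs[, 2L], m[pairs]),
      "  </graph>",
      "</graphml>")
    writeLines(lines, file)
  }
  invisible(file)
}
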