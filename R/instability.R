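#' @name instability
#' @title Areas of local instability and the island-size correlation analysis
#' @description
#' A consensus tree signals local instability through polytomies and
#' through branches whose occurrence frequency is below 100%. Each maximal
#' set of adjacent unstable nodes is one *area of local instability*; an
#' area spanning a single NNI-ambiguous edge admits up to 3 alternative
#' resolutions, so i independent areas can inflate an island by up to 3^i
#' trees. These tools delineate areas, tabulate their incidence across
#' per-island consensus trees, and run the Pearson correlation analysis
#' relating island size to instability and NNI-graph density.
NULL

dbl_factorial_resolutions <- function(deg) {
  # number of binary resolutions of an unrooted vertex of degree deg
  v <- seq(2 * deg - 5, 1, by = -2)
  prod(v[v > 0])
}

#' Areas of local instability in a consensus tree
#'
#' Marks every internal node of the consensus that is a polytomy or whose
#' subtending split has frequency below 1, and groups marked nodes that are
#' adjacent (share an edge) into areas. A fully resolved, fully supported
#' consensus has no areas. For each area the focal leaf cluster is the
#' smallest clade containing its nodes, and `alternatives` bounds the
#' number of local resolutions: 3 for a single NNI-ambiguous edge or
#' trifurcation, the product of per-node resolution counts otherwise.
#'
#' @param c a `consensus_tree`.
#' @return a data frame with one row per area: `area`, `kind` (`polytomy`
#'   or `support`), `n_nodes`, `alternatives`, `focal_cluster`
#'   (comma-joined leaf labels). The list of focal clusters (as label
#'   vectors) is attached as attribute `clusters`.
#' @export
instability_areas <- function(c) {
  ct <- c
  labels <- ct$labels
  n <- length(labels)
  k <- length(ct$blocks)
  lam <- laminar_structure(labels, ct$blocks)
  # vertex v = 0 (adjacent to first leaf) or block index 1..k
  n_children <- vapply(0:k, function(v) {
    sum(lam$parent == v) + sum(lam$tip_parent == v)
  }, 0L)
  degree <- n_children + c(0L, rep(1L, k))  # top vertex has no parent edge
  polytomy <- degree > 3L
  undersupported <- c(FALSE, ct$freq < 1)   # edge above each block vertex
  unstable <- polytomy | undersupported
  ids <- which(unstable) - 1L               # vertex ids
  if (!length(ids)) {
    out <- data.frame(area = integer(0), kind = character(0),
                      n_nodes = integer(0), alternatives = numeric(0),
                      focal_cluster = character(0), stringsAsFactors = FALSE)
    attr(out, "clusters") <- list()
    return(out)
  }
  # group adjacent unstable vertices (parent-child edges) by union-find
  uf <- uf_new(length(ids))
  posn <- match(0:k, ids)  # posn[v + 1]: position of vertex v in ids (NA if stable)
  for (pidx in seq_along(ids)) {
    v <- ids[pidx]
    if (v == 0L) next
    pv <- lam$parent[v]
    pp <- posn[pv + 1L]
    if (!is.na(pp)) uf_union(uf, pidx, pp)
  }
  comp <- split(seq_along(ids), uf_roots(uf))
  rows <- list()
  clusters <- list()
  for (ci in seq_along(comp)) {
    vs <- ids[comp[[ci]]]
    # smallest clade containing all area vertices: the shallowest vertex
    depth <- function(v) {
      d <- 0L
      while (v != 0L) {
        v <- lam$parent[v]
        d <- d + 1L
      }
      d
    }
    top_v <- vs[which.min(vapply(vs, depth, 0L))]
    cluster <- if (top_v == 0L) labels else labels[ct$blocks[[top_v]]]
    alt <- prod(vapply(vs, function(v) {
      if (polytomy[v + 1L]) {
        dbl_factorial_resolutions(degree[v + 1L])
      } else {
        3  # NNI ambiguity at one binary under-supported edge
      }
    }, 0))
    rows[[ci]] <- data.frame(
      area = ci,
      kind = if (any(polytomy[vs + 1L])) "polytomy" else "support",
      n_nodes = length(vs),
      alternatives = alt,
      focal_cluster = paste(cluster, collapse = ","),
      stringsAsFactors = FALSE)
    clusters[[ci]] <- cluster
  }
  # deterministic order: by focal cluster size then label string
  o <- order(lengths(clusters), vapply(rows, `[[`, "", "focal_cluster"),
             method = "radix")
  out <- do.call(rbind, rows[o])
  out$area <- seq_len(nrow(out))
  attr(out, "clusters") <- clusters[o]
  out
}

#' Incidence of instability areas across islands
#'
#' Matches areas of local instability across a list of per-island
#' consensus trees (from [partitioned_consensus()]) and tabulates their
#' presence, the analogue of a plus/minus incidence table with per-island
#' totals. Two areas from different islands are treated as the same area
#' when their focal leaf clusters overlap in at least a fraction `overlap`
#' of each (a declared heuristic; the delineation rule is adjacency
#' grouping, recorded in the result's metadata).
#'
#' @param partitioned a list of `consensus_tree` objects over the same
#'   leaf set, one per island.
#' @param overlap minimum mutual overlap fraction for cross-island area
#'   matching (default 0.5).
#' @param island_stats optional data frame with one row per island (e.g.
#'   columns `size`, `mass`, `average_degree`) carried through to the
#'   report.
#' @return an object of class `incidence_table`: `presence` (logical
#'   matrix, areas x islands), `clusters` (focal label sets per area),
#'   `totals` (per-island area counts), `island_stats`, `rule`.
#' @export
area_incidence <- function(partitioned, overlap = 0.5, island_stats = NULL) {
  n_isl <- length(partitioned)
  canon <- list()       # canonical focal clusters
  cols <- vector("list", n_isl)
  for (j in seq_len(n_isl)) {
    ar <- instability_areas(partitioned[[j]])
    cls <- attr(ar, "clusters")
    # candidate (area, canonical) pairs passing the mutual-overlap rule,
    # resolved greedily by Jaccard similarity; distinct areas of one
    # island never collapse onto the same canonical area
    cand <- list()
    for (a in seq_along(cls)) {
      for (i in seq_along(canon)) {
        inter <- length(intersect(cls[[a]], canon[[i]]))
        if (inter >= overlap * length(cls[[a]]) &&
            inter >= overlap * length(canon[[i]])) {
          cand[[length(cand) + 1L]] <-
            c(a, i, inter / length(union(cls[[a]], canon[[i]])))
        }
      }
    }
    matched <- rep(0L, length(cls))
    if (length(cand)) {
      cand <- cand[order(-vapply(cand, `[[`, 0, 3L))]
      used <- logical(length(canon))
      for (p in cand) {
        a <- p[1L]
        i <- p[2L]
        if (matched[a] == 0L && !used[i]) {
          matched[a] <- i
          used[i] <- TRUE
        }
      }
    }
    for (a in seq_along(cls)) {
      if (matched[a] == 0L) {
        canon[[length(canon) + 1L]] <- cls[[a]]
        matched[a] <- length(canon)
      }
    }
    cols[[j]] <- matched
  }
  presence <- matrix(FALSE, length(canon), n_isl)
  for (j in seq_len(n_isl)) presence[cols[[j]], j] <- TRUE
  if (nrow(presence)) {
    rownames(presence) <- as.character(utils::as.roman(seq_len(nrow(presence))))
  }
  colnames(presence) <- names(partitioned) %||%
    sprintf("island_%d", seq_len(n_isl))
  structure(
    list(presence = presence,
         clusters = canon,
         totals = stats::setNames(as.integer(colSums(presence)),
                                  colnames(presence)),
         island_stats = island_stats,
         rule = list(delineation = "adjacency-grouping",
                     matching = sprintf("focal-cluster overlap >= %g of each",
                                        overlap))),
    class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("<incidence_table> areas of local instability x islands\n")
  disp <- ifelse(x$presence, "+", "-")
  disp <- rbind(disp, Total = as.character(x$totals))
  if (!is.null(x$island_stats$average_degree)) {
    disp <- rbind(disp, `Avg degree` =
                    sprintf("%.2f", x$island_stats$average_degree))
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write an incidence table as TSV
#'
#' @param table an `incidence_table`.
#' @param file output path.
#' @export
write_incidence_table <- function(table, file) {
  disp <- ifelse(table$presence, "+", "-")
  df <- data.frame(area = rownames(table$presence), disp,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tot <- c("Total", as.character(table$totals))
  rows <- c(paste(colnames(df), collapse = "\t"),
            apply(df, 1L, paste, collapse = "\t"),
            paste(tot, collapse = "\t"))
  if (!is.null(table$island_stats$average_degree)) {
    rows <- c(rows, paste(c("Average_degree",
                            sprintf("%.2f", table$island_stats$average_degree)),
                          collapse = "\t"))
  }
  writeLines(rows, file)
  invisible(file)
}

#' Pearson product-moment correlation with two-sided test
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return a list with `r` (the correlation), `p` (two-sided p-value from
#'   the t transform on n - 2 degrees of freedom) and `n`.
#' @examples
#' pearson(c(18, 72, 90, 216, 486), c(4, 6, 6, 8, 9))
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_ti("x and y must have equal length")
  if (length(x) < 3L) stop_ti("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ti("undefined correlation: an input has zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Combinatorial bound on island size
#'
#' An island whose members differ only at `i` independent areas of local
#' instability, each admitting up to 3 NNI resolutions, contains at most
#' `3^i` topologies: linear growth in instability drives exponential
#' growth in island size, the mechanism behind large island bias.
#'
#' @param i nonnegative integer count of instability areas.
#' @return `3^i`.
#' @export
bounded_max_size <- function(i) {
  if (any(i < 0) || any(i != floor(i))) stop_ti("i must be a nonnegative integer")
  3^i
}

#' Island-size / instability correlation report
#'
#' Runs the four Pearson correlations that diagnose whether island-size
#' disparity is driven by local instability: island size vs instability
#' totals, size vs the combinatorial bound `3^totals`, totals vs average
#' NNI-graph degree, and size vs average degree. A pair whose correlation
#' is undefined (zero variance) is reported with `NA` and the error
#' message in `note`.
#'
#' @param table an `incidence_table` whose `island_stats` carry `size` and
#'   `average_degree` (at least 3 islands).
#' @return a data frame with columns `comparison`, `r`, `p`, `n`, `note`.
#' @export
instability_report <- function(table) {
  st <- table$island_stats
  if (is.null(st$size)) stop_ti("island_stats must include island sizes")
  if (length(table$totals) < 3L) stop_ti("need at least 3 islands")
  totals <- as.numeric(table$totals)
  pairs <- list(
    list("size_vs_instability", st$size, totals),
    list("size_vs_bounded_max_size", st$size, bounded_max_size(totals)),
    list("instability_vs_average_degree", totals, st$average_degree),
    list("size_vs_average_degree", st$size, st$average_degree))
  rows <- lapply(pairs, function(p) {
    if (is.null(p[[3]])) {
      return(data.frame(comparison = p[[1]], r = NA_real_, p = NA_real_,
                        n = NA_integer_, note = "statistic unavailable",
                        stringsAsFactors = FALSE))
    }
    res <- tryCatch(pearson(as.numeric(p[[2]]), as.numeric(p[[3]])),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(comparison = p[[1]], r = NA_real_, p = NA_real_,
                 n = NA_integer_, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(comparison = p[[1]], r = res$r, p = res$p, n = res$n,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
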