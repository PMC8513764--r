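#' @name consensus
#' @title Island-aware consensus summaries
#' @description
#' Strict and majority-rule consensus trees, plus the three summaries that
#' neutralize large island bias when islands have disparate sizes:
#' a consensus per island (partitioned-by-island), a single majority-rule
#' consensus in which every tree is down-weighted by the size of its
#' island so each island contributes equally (weighted-by-island-size),
#' and a consensus of equal-size random draws from every island
#' (rarefied-by-island-size). Split frequencies are carried as exact
#' rationals and rendered as percentages.
NULL

# weighted split occurrence counts over a multiset.
# weights: NULL (use multiplicities, denominator 1) or a tree_weights data
# frame (key, num, den). All arithmetic on a common integer denominator so
# the majority cutoff comparison is exact.
split_counts <- function(trees, weights = NULL) {
  k <- length(trees$keys)
  if (is.null(weights)) {
    wnum <- as.numeric(trees$multiplicity)
    D <- 1
  } else {
    idx <- match(trees$keys, weights$key)
    if (anyNA(idx)) stop_ti("weights do not cover every topology")
    den <- weights$den[idx]
    D <- Reduce(lcm2, unique(den))
    wnum <- weights$num[idx] * (D / den)
  }
  total <- sum(wnum)
  splits <- unlist(lapply(trees$topologies, `[[`, "splits"), use.names = FALSE)
  wrep <- rep(wnum, vapply(trees$topologies, function(t) length(t$splits), 0L))
  agg <- rowsum(wrep, splits)
  list(split = rownames(agg), count = as.numeric(agg), total = total,
       denom = D)
}

new_consensus_tree <- function(labels, blocks, freq_num, freq_den, method,
                               cutoff = NULL) {
  strings <- vapply(blocks, function(b) paste(labels[b], collapse = ","), "")
  o <- order(strings, method = "radix")
  structure(
    list(labels = labels,
         splits = strings[o],
         blocks = blocks[o],
         freq_num = freq_num[o],
         freq_den = freq_den[o],
         freq = if (length(o)) freq_num[o] / freq_den[o] else numeric(0),
         method = method,
         cutoff = cutoff),
    class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("<consensus_tree> %s, %d leaves, %d splits displayed\n",
              x$method, length(x$labels), length(x$splits)))
  if (length(x$freq)) {
    cat(sprintf("  split frequencies: min %.2f%%, max %.2f%%\n",
                100 * min(x$freq), 100 * max(x$freq)))
  }
  invisible(x)
}

#' @rdname as.phylo.topology
#' @method as.phylo consensus_tree
#' @export
as.phylo.consensus_tree <- function(x, ...) {
  labs <- sprintf("%.2f", 100 * x$freq)
  ape::read.tree(text = blocks_to_newick(x$labels, x$blocks, labs))
}

# the topology displayed by a consensus tree (frequencies dropped)
consensus_topology <- function(ct) new_topology(ct$labels, ct$blocks)

#' Strict consensus
#'
#' The tree displaying exactly the splits present in every topology of the
#' multiset; all displayed splits have frequency 1.
#'
#' @param trees a [tree_multiset()].
#' @return a `consensus_tree`.
#' @export
strict_consensus <- function(trees) {
  common <- Reduce(intersect, lapply(trees$topologies, `[[`, "splits"))
  blocks <- trees$topologies[[1L]]$blocks[
    match(common, trees$topologies[[1L]]$splits)]
  new_consensus_tree(trees$labels, blocks,
                     rep(1, length(blocks)), rep(1, length(blocks)),
                     "strict")
}

#' Majority-rule consensus
#'
#' The tree displaying exactly the splits whose (weighted) relative
#' frequency strictly exceeds `cutoff`. Without weights each unique
#' topology counts with its multiplicity; with weights (e.g. from
#' [island_weights()]) the frequency of a split is the weighted fraction of
#' trees containing it. Splits at frequency exactly the cutoff are
#' excluded, which guarantees the displayed splits are pairwise compatible
#' for any cutoff >= 0.5; candidates are nevertheless admitted greedily in
#' decreasing frequency with an explicit compatibility check so the same
#' code is safe for sub-majority cutoffs.
#'
#' @param trees a [tree_multiset()].
#' @param weights optional `tree_weights` data frame (`key`, `num`, `den`)
#'   covering every topology.
#' @param cutoff display threshold, in `[0.5, 1)`.
#' @return a `consensus_tree` whose displayed splits carry frequencies in
#'   `(cutoff, 1]`.
#' @export
majority_rule_consensus <- function(trees, weights = NULL, cutoff = 0.5) {
  if (cutoff < 0.5 || cutoff >= 1) stop_ti("cutoff must be in [0.5, 1)")
  sc <- split_counts(trees, weights)
  keep <- if (cutoff == 0.5) {
    2 * sc$count > sc$total
  } else {
    sc$count > cutoff * sc$total
  }
  cand <- order(-sc$count[keep])
  splits <- sc$split[keep][cand]
  counts <- sc$count[keep][cand]
  # map split strings back to blocks via any topology containing them
  block_of <- new.env(parent = emptyenv())
  for (t in trees$topologies) {
    for (i in seq_along(t$splits)) {
      if (!exists(t$splits[i], envir = block_of, inherits = FALSE)) {
        assign(t$splits[i], t$blocks[[i]], envir = block_of)
      }
    }
  }
  acc_blocks <- list()
  acc_counts <- numeric(0)
  for (i in seq_along(splits)) {
    b <- get(splits[i], envir = block_of)
    if (all(vapply(acc_blocks, blocks_compatible, TRUE, b = b))) {
      acc_blocks[[length(acc_blocks) + 1L]] <- b
      acc_counts <- c(acc_counts, counts[i])
    }
  }
  new_consensus_tree(trees$labels, acc_blocks, acc_counts,
                     rep(sc$total, length(acc_counts)),
                     "majority", cutoff)
}

#' Per-island consensus trees
#'
#' Computes an independent consensus for each island of a partition. When
#' islands reflect genuinely distinct resolutions, a consensus per island
#' stays well resolved where a global consensus would be dominated by the
#' largest island.
#'
#' @param partition an `island_partition` over `trees`.
#' @param trees the [tree_multiset()].
#' @param method `"majority"` or `"strict"`.
#' @param cutoff majority cutoff, passed to [majority_rule_consensus()].
#' @return a named list of `consensus_tree` objects, one per island, in
#'   island order.
#' @export
partitioned_consensus <- function(partition, trees,
                                  method = c("majority", "strict"),
                                  cutoff = 0.5) {
  method <- match.arg(method)
  out <- vector("list", length(partition$islands))
  for (i in seq_along(partition$islands)) {
    sub <- subset_multiset(trees, partition$islands[[i]]$member_keys)
    out[[i]] <- if (method == "strict") {
      strict_consensus(sub)
    } else {
      majority_rule_consensus(sub, cutoff = cutoff)
    }
  }
  names(out) <- sprintf("island_%d", seq_along(out))
  out
}

#' Island-size weights
#'
#' Assigns each unique topology the weight `m_t / n_i`, where `m_t` is its
#' multiplicity and `n_i` the size of its island. Under these weights every
#' island of a set (all multiplicities 1) has total weight exactly 1, so a
#' weighted majority-rule consensus gives all islands equal influence
#' regardless of size; in a multiset an island's total weight can exceed 1.
#'
#' @param partition an `island_partition` over `trees`.
#' @param trees the [tree_multiset()].
#' @return a data frame of class `tree_weights` with columns `key`, `num`,
#'   `den` (the weight as the exact fraction `num/den`) and `weight`.
#' @export
island_weights <- function(partition, trees) {
  sizes <- vapply(partition$islands, `[[`, 0L, "size")
  isl <- unname(partition$assignment[trees$keys])
  df <- data.frame(key = trees$keys,
                   num = trees$multiplicity,
                   den = sizes[isl],
                   stringsAsFactors = FALSE)
  df$weight <- df$num / df$den
  class(df) <- c("tree_weights", "data.frame")
  df
}

#' Rarefy islands to equal size
#'
#' Draws `n = floor(s * p)` distinct topologies from every island without
#' replacement, where `s` is the size of the smallest island and `p` in
#' `[1/s, 1]` the proportion of that island to keep, so that all islands
#' are equally represented. `p = 1` minimizes stochastic loss of
#' information from the larger islands. Sampled topologies retain their
#' multiplicities, so a consensus of the rarefied multiset weights repeated
#' topologies by their occurrence count.
#'
#' @param partition an `island_partition` over `trees`.
#' @param trees the [tree_multiset()].
#' @param p proportion of the smallest island to draw, in `[1/s, 1]`.
#' @param seed optional integer; the draw is reproducible under a fixed
#'   seed and leaves the session RNG state untouched.
#' @return a [tree_multiset()] with `n` topologies per island.
#' @export
rarefy_islands <- function(partition, trees, p = 1, seed = NULL) {
  s <- min(vapply(partition$islands, `[[`, 0L, "size"))
  if (p < 1 / s || p > 1) {
    stop_ti("p must be in [1/s, 1] = [%g, 1]; got %g", 1 / s, p)
  }
  n <- floor(s * p)
  with_seed(seed, {
    keys <- unlist(lapply(partition$islands, function(isl) {
      sort_c(sample(isl$member_keys, n, replace = FALSE))
    }), use.names = FALSE)
    subset_multiset(trees, keys)
  })
}

#' Rarefied-by-island-size consensus
#'
#' Repeats the rarefied draw `replicates` times; each replicate yields a
#' majority-rule consensus of its `n`-per-island sample, and the replicate
#' consensus topologies are then summarized by both strict and majority
#' rule. Replicate `r` draws from its own substream derived from `seed`, so
#' results are fully reproducible and each replicate is independently
#' re-creatable.
#'
#' @inheritParams rarefy_islands
#' @param replicates number of random draws (the headline analysis uses
#'   1000).
#' @param cutoff majority cutoff for the per-replicate consensus.
#' @return a list of class `rarefied_consensus`: `replicates` (a
#'   [tree_multiset()] of the replicate consensus topologies), `strict` and
#'   `majority` (their summaries), and `manifest` (seed, p, n per island,
#'   replicate count).
#' @export
rarefied_consensus <- function(partition, trees, p = 1, replicates = 1000,
                               seed = NULL, cutoff = 0.5) {
  if (replicates < 1) stop_ti("replicates must be >= 1")
  seed <- seed %||% sample.int(2^31 - 2, 1L)
  s <- min(vapply(partition$islands, `[[`, 0L, "size"))
  n <- floor(s * p)
  rep_topos <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sub_seed <- (seed + 104729 * r) %% 2147483647
    sub <- rarefy_islands(partition, trees, p, seed = sub_seed)
    rep_topos[[r]] <- consensus_topology(
      majority_rule_consensus(sub, cutoff = cutoff))
  }
  rep_ms <- tree_multiset(rep_topos)
  structure(
    list(replicates = rep_ms,
         strict = strict_consensus(rep_ms),
         majority = majority_rule_consensus(rep_ms, cutoff = cutoff),
         manifest = list(seed = seed, p = p, n_per_island = n,
                         replicates = replicates, cutoff = cutoff)),
    class = "rarefied_consensus")
}

#' @export
print.rarefied_consensus <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<rarefied_consensus> %d replicates, n = %d per island (p = %g, seed = %d)\n",
              m$replicates, m$n_per_island, m$p, m$seed))
  cat(sprintf("  %d distinct replicate consensus topologies\n",
              length(x$replicates$keys)))
  invisible(x)
}

#' Write a consensus tree
#'
#' Writes the consensus as Newick or as a Nexus TREES block. Internal node
#' labels carry the split occurrence percentages (two decimals), the usual
#' support-label convention, so the file round-trips through standard
#' parsers.
#'
#' @param ct a `consensus_tree`.
#' @param file output path or `""` for stdout.
#' @param format `"newick"` or `"nexus"`.
#' @export
write_consensus <- function(ct, file = "", format = c("newick", "nexus")) {
  format <- match.arg(format)
  labs <- sprintf("%.2f", 100 * ct$freq)
  nwk <- blocks_to_newick(ct$labels, ct$blocks, labs)
  out <- if (format == "newick") {
    nwk
  } else {
    c("#NEXUS", "", "BEGIN TREES;",
      paste0("\ttree consensus_", ct$method, " = ", nwk), "END;")
  }
  if (!identical(file, "")) writeLines(out, file) else cat(out, sep = "\n")
  invisible(out)
}
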