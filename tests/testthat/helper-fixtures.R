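# shared fixtures and independent oracles, built in code at test time

# k distinct random unrooted binary topologies on n leaves
rand_topos <- function(n, k, seed) {
  out <- list()
  with_seed_local(seed, {
    while (length(out) < k) {
      t <- as_topology(ape::unroot(ape::rtree(n, tip.label = paste0("L", seq_len(n)))))
      if (!t$key %in% names(out)) out[[t$key]] <- t
    }
  })
  unname(out)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# minimal multiset stub for island algorithms that only consume keys and
# multiplicities (e.g. when testing against hand-built distance matrices)
stub_multiset <- function(keys, mult = rep(1L, length(keys))) {
  structure(list(labels = NULL, topologies = NULL,
                 multiplicity = as.integer(mult), keys = keys,
                 total_mass = as.integer(sum(mult))),
            class = "tree_multiset")
}

stub_tree_dist <- function(m, keys) {
  structure(list(keys = keys, matrix = m, metric = "rf"),
            class = "tree_dist")
}

# breadth-first-search connected components: independent oracle for the
# union-find island algorithm
bfs_components <- function(m, x) {
  k <- nrow(m)
  comp <- integer(k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(m[v, ] <= x & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# island membership as a canonical set-of-sets (order-free comparison)
partition_sets <- function(partition) {
  sets <- lapply(partition$islands, `[[`, "member_keys")
  sets[order(vapply(sets, `[[`, "", 1L))]
}

# per-island instability/degree fixture mirroring the five-island
# incidence analysis (sizes, instability totals, average NNI degrees)
five_island_stats <- function() {
  list(sizes = c(18, 72, 90, 216, 486),
       totals = c(4, 6, 6, 8, 9),
       degrees = c(4.33, 6.33, 6.33, 7.67, 9.00))
}

make_multiset <- function(topos, mult = rep(1L, length(topos))) {
  tree_multiset(topos, counts = mult)
}
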