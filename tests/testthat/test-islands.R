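test_that("threshold extremes give one island or all singletons", {
  topos <- rand_topos(8, 6, seed = 1)
  ms <- make_multiset(topos)
  dm <- pairwise_matrix(ms)
  all_in_one <- find_islands(dm, ms, max(dm$matrix))
  expect_length(all_in_one$islands, 1L)
  expect_identical(all_in_one$islands[[1L]]$size, 6L)
  minpos <- min(dm$matrix[dm$matrix > 0])
  singles <- find_islands(dm, ms, minpos - 1)
  expect_length(singles$islands, 6L)
  expect_error(find_islands(dm, ms, -1), "nonnegative")
})

test_that("hand-built block matrix yields the breadth-first components", {
  keys <- paste0("k", 1:5)
  m <- matrix(10, 5, 5)
  m[1:3, 1:3] <- 2
  m[4:5, 4:5] <- 2
  diag(m) <- 0
  ms <- stub_multiset(keys)
  part <- find_islands(stub_tree_dist(m, keys), ms, 2)
  expect_length(part$islands, 2L)
  expect_identical(vapply(part$islands, `[[`, 0L, "size"), c(3L, 2L))
  expect_identical(unname(part$assignment), bfs_components(m, 2))
})

test_that("union-find islands equal BFS components on random matrices", {
  with_seed_local(99, {
    for (rep in 1:10) {
      k <- sample(10:50, 1)
      m <- matrix(0, k, k)
      m[upper.tri(m)] <- sample(c(2, 4, 10), k * (k - 1) / 2,
                                replace = TRUE, prob = c(0.05, 0.1, 0.85))
      m <- m + t(m)
      keys <- sprintf("k%03d", seq_len(k))
      ms <- stub_multiset(keys, mult = sample(1:3, k, replace = TRUE))
      for (x in c(2, 4)) {
        part <- find_islands(stub_tree_dist(m, keys), ms, x)
        oracle <- bfs_components(m, x)
        # same partition up to island relabeling: compare sets of member sets
        found_sets <- lapply(unname(split(keys, part$assignment[keys])), sort)
        oracle_sets <- lapply(unname(split(keys, oracle)), sort)
        expect_setequal(vapply(found_sets, paste, "", collapse = "|"),
                        vapply(oracle_sets, paste, "", collapse = "|"))
        # partition property: exhaustive, exclusive, masses and sizes add up
        expect_identical(sum(vapply(part$islands, `[[`, 0L, "size")), k)
        expect_identical(sum(vapply(part$islands, `[[`, 0L, "mass")),
                         ms$total_mass)
        expect_true(all(part$assignment >= 1))
        dens <- vapply(part$islands, `[[`, 0, "density")
        expect_true(all(dens > 0 & dens <= 1))
      }
    }
  })
})

test_that("islands nest as the threshold grows", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 2, 1),
                                        sizes = c(9, 6, 3), seed = 8))
  ms <- planted$trees
  dm <- pairwise_matrix(ms)
  parts <- lapply(c(2, 4, 8, 100), function(x) find_islands(dm, ms, x))
  for (i in 1:3) {
    fine <- parts[[i]]
    coarse <- parts[[i + 1L]]
    for (isl in fine$islands) {
      parents <- unique(coarse$assignment[isl$member_keys])
      expect_length(parents, 1L)  # each island sits inside exactly one
    }
    expect_true(length(coarse$islands) <= length(fine$islands))
  }
})

test_that("1-NNI islands equal RF islands at threshold 2", {
  # chain T1 - T2 - T3 with d(T1,T3) = 4: one island through included trees
  base <- rand_topos(10, 1, seed = 77)[[1L]]
  s <- nontrivial_splits(base)
  e2 <- NULL
  for (cand in seq_along(s)[-1L]) {
    ok <- tryCatch({
      perturb_edges(base, s[c(1L, cand)], c(1L, 1L))
      TRUE
    }, error = function(e) FALSE)
    if (ok) { e2 <- cand; break }
  }
  t1 <- base
  t2 <- perturb_edges(base, s[1L], 1L)
  t3 <- perturb_edges(base, s[c(1L, e2)], c(1L, 1L))
  expect_identical(rf_distance(t1, t2), 2L)
  expect_identical(rf_distance(t2, t3), 2L)
  expect_identical(rf_distance(t1, t3), 4L)
  chain <- make_multiset(list(t1, t2, t3))
  part <- find_1nni_islands(chain)
  expect_length(part$islands, 1L)

  # pairwise rf > 2: all singletons
  far <- make_multiset(rand_topos(10, 5, seed = 31))
  expect_true(all(pairwise_matrix(far)$matrix[upper.tri(diag(5))] > 2))
  expect_length(find_1nni_islands(far)$islands, 5L)

  # planted sets: identical to the matrix algorithm at x = 2
  for (seed in c(4, 5)) {
    planted <- plant_islands(plant_config(n_leaves = 14, i = c(1, 2, 2),
                                          sizes = c(3, 9, 5), seed = seed))
    direct <- find_1nni_islands(planted$trees)
    viamat <- find_islands(pairwise_matrix(planted$trees), planted$trees, 2)
    expect_identical(direct$assignment, viamat$assignment)
  }
  expect_error(find_1nni_islands(make_multiset(list("(A,B,C,D,E);"))),
               "binary")
})

test_that("island profiles tabulate size spectra and coarsen monotonically", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 1, 0),
                                        sizes = c(9, 3, 1), seed = 12))
  prof <- island_profile(planted$trees, "rf", c(2, 6, 1000))
  df <- as.data.frame(prof)
  # planted spectrum recovered at the detection threshold
  at2 <- df[df$threshold == 2, ]
  expect_identical(at2$island_size, c(1L, 3L, 9L))
  expect_identical(at2$n_islands, c(1L, 1L, 1L))
  # a threshold at least the diameter gives a single island
  atmax <- df[df$threshold == 1000, ]
  expect_identical(atmax$island_size, 13L)
  # island counts never increase with the threshold
  totals <- tapply(df$n_islands, df$threshold, sum)
  expect_true(all(diff(totals[order(as.numeric(names(totals)))]) <= 0))
  expect_error(island_profile(planted$trees, "rf", c(4, 2)), "ascending")
})

test_that("average degree counts within-threshold fellow members", {
  keys <- paste0("k", 1:3)
  # path T1 - T2 - T3: degrees 1, 2, 1 -> mean 4/3
  m <- matrix(c(0, 2, 4,
                2, 0, 2,
                4, 2, 0), 3, 3, byrow = TRUE)
  ms <- stub_multiset(keys)
  dmat <- stub_tree_dist(m, keys)
  part <- find_islands(dmat, ms, 2)
  expect_length(part$islands, 1L)
  expect_equal(average_degree(part$islands[[1L]], dmat, 2), 4 / 3)
  # singleton -> 0; clique of k -> k - 1
  single <- list(member_keys = "k1")
  expect_identical(average_degree(single, dmat, 2), 0)
  mc <- matrix(2, 4, 4); diag(mc) <- 0
  kc <- paste0("c", 1:4)
  pc <- find_islands(stub_tree_dist(mc, kc), stub_multiset(kc), 2)
  expect_equal(average_degree(pc$islands[[1L]], stub_tree_dist(mc, kc), 2), 3)
})

test_that("island outputs export as tsv and graphml", {
  planted <- plant_islands(plant_config(n_leaves = 12, i = c(1, 1),
                                        sizes = c(3, 3), seed = 6))
  dm <- pairwise_matrix(planted$trees)
  part <- find_islands(dm, planted$trees, 2)
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_island_assignment(part, planted$trees, fa)
  df <- read.delim(fa)
  expect_identical(nrow(df), 6L)
  expect_setequal(df$island, 1:2)
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_island_summary(part, fs, matrix = dm)
  sm <- read.delim(fs)
  expect_identical(names(sm),
                   c("island", "size", "mass", "density", "average_degree"))
  fg <- withr::local_tempfile(fileext = ".graphml")
  write_island_graph(part, dm, fg, "graphml")
  expect_true(any(grepl("<graphml", readLines(fg))))
})
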