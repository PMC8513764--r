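test_that("strict consensus displays exactly the shared splits", {
  topos <- rand_topos(8, 1, seed = 4)
  ms_same <- make_multiset(rep(topos, 3L))
  sc <- strict_consensus(ms_same)
  expect_setequal(sc$splits, topos[[1L]]$splits)
  expect_true(all(sc$freq == 1))

  # two 5-leaf trees sharing exactly one nontrivial split
  a <- "((A,B),(C,(D,E)));"  # splits: AB, DE
  b <- "((A,C),(B,(D,E)));"  # splits: AC, DE
  sc2 <- strict_consensus(tree_multiset(list(a, b)))
  expect_identical(sc2$splits, "D,E")

  # strict splits are a subset of every input's splits
  ms <- make_multiset(rand_topos(7, 5, seed = 19))
  sc3 <- strict_consensus(ms)
  for (t in ms$topologies) expect_true(all(sc3$splits %in% t$splits))
})

test_that("majority consensus displays splits above the cutoff with frequencies", {
  one <- tree_multiset("((A,B),(C,(D,E)));")
  mc1 <- majority_rule_consensus(one)
  expect_setequal(mc1$splits, nontrivial_splits("((A,B),(C,(D,E)));"))
  expect_true(all(mc1$freq == 1))

  # 3 equal-weight trees: a split in 2 shows at 2/3, a split in 1 is absent
  trees <- tree_multiset(list("((A,B),(C,(D,E)));",
                              "((A,B),(D,(C,E)));",
                              "((A,C),(B,(D,E)));"))
  mc <- majority_rule_consensus(trees)
  # the split {A,B}|{C,D,E} is canonically encoded by its A-free block
  expect_true("C,D,E" %in% mc$splits)
  expect_equal(mc$freq[mc$splits == "C,D,E"], 2 / 3)
  expect_false("C,E" %in% mc$splits)
  expect_true(all(mc$freq > 0.5))
  expect_error(majority_rule_consensus(trees, cutoff = 0.4), "cutoff")
  expect_error(majority_rule_consensus(trees, cutoff = 1), "cutoff")
})

test_that("majority and strict consensus agree with ape's consensus", {
  for (seed in c(2, 13)) {
    # odd tree count so no split sits exactly at the 0.5 boundary
    topos <- rand_topos(8, 7, seed = seed)
    ms <- make_multiset(topos)
    phys <- lapply(topos, as.phylo)
    class(phys) <- "multiPhylo"
    mc <- majority_rule_consensus(ms)
    expect_setequal(mc$splits,
                    nontrivial_splits(ape::consensus(phys, p = 0.5)))
    sc <- strict_consensus(ms)
    expect_setequal(sc$splits,
                    nontrivial_splits(ape::consensus(phys, p = 1)))
    # strict splits nest inside majority splits
    expect_true(all(sc$splits %in% mc$splits))
  }
})

test_that("multiplicities weight the unweighted consensus", {
  a <- "((A,B),(C,(D,E)));"
  b <- "((A,C),(B,(D,E)));"
  ms <- tree_multiset(list(a, b), counts = c(3L, 1L))
  mc <- majority_rule_consensus(ms)
  expect_true("C,D,E" %in% mc$splits)    # the {A,B} split: 3/4 of the mass
  expect_equal(mc$freq[mc$splits == "C,D,E"], 0.75)
})

test_that("uniform weights reproduce the unweighted consensus", {
  ms <- make_multiset(rand_topos(8, 6, seed = 23))
  w <- data.frame(key = ms$keys, num = rep(2L, 6L), den = rep(14L, 6L),
                  stringsAsFactors = FALSE)
  mc_u <- majority_rule_consensus(ms)
  mc_w <- majority_rule_consensus(ms, weights = w)
  expect_identical(mc_w$splits, mc_u$splits)
  expect_equal(mc_w$freq, mc_u$freq)
  w_bad <- w[-1L, ]
  expect_error(majority_rule_consensus(ms, weights = w_bad), "cover")
})

test_that("partitioned consensus is island-local", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 1),
                                        sizes = c(9, 3), seed = 10))
  ms <- planted$trees
  part <- planted$partition
  pc <- partitioned_consensus(part, ms)
  expect_length(pc, 2L)
  for (i in seq_along(pc)) {
    members <- part$islands[[i]]$member_keys
    sub <- lapply(ms$topologies[match(members, ms$keys)], `[[`, "splits")
    # locality: every displayed split occurs in >= 1 member
    expect_true(all(pc[[i]]$splits %in% unlist(sub)))
    # the island's stable splits (present in all members) show at 100%
    stable <- Reduce(intersect, sub)
    expect_true(all(stable %in% pc[[i]]$splits))
    expect_true(all(pc[[i]]$freq[pc[[i]]$splits %in% stable] == 1))
  }
  # a one-island partition reproduces the global consensus
  dm <- pairwise_matrix(ms)
  whole <- find_islands(dm, ms, max(dm$matrix))
  pc1 <- partitioned_consensus(whole, ms)
  expect_identical(pc1[[1L]]$splits, majority_rule_consensus(ms)$splits)
})

test_that("island weights are m_t over island size and sum to 1 per set island", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 1),
                                        sizes = c(9, 3), seed = 20))
  w <- island_weights(planted$partition, planted$trees)
  isl <- unname(planted$partition$assignment[w$key])
  sizes <- vapply(planted$partition$islands, `[[`, 0L, "size")
  expect_identical(w$den, sizes[isl])
  expect_identical(w$num, planted$trees$multiplicity)
  # all m_t = 1: each island's weights sum to exactly 1
  expect_equal(as.numeric(tapply(w$weight, isl, sum)), c(1, 1))
  # multiset: island weight sums exceed 1
  planted_m <- plant_islands(plant_config(n_leaves = 14, i = c(2, 1),
                                          sizes = c(9, 3),
                                          mass_model = "geometric",
                                          seed = 20))
  if (any(planted_m$trees$multiplicity > 1)) {
    wm <- island_weights(planted_m$partition, planted_m$trees)
    im <- unname(planted_m$partition$assignment[wm$key])
    sums <- tapply(wm$weight, im, sum)
    expect_true(all(sums >= 1))
    expect_true(any(sums > 1))
  }
})

test_that("weighted consensus frequencies average the per-island frequencies", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 1),
                                        sizes = c(9, 3), seed = 25))
  ms <- planted$trees
  part <- planted$partition
  w <- island_weights(part, ms)
  mc <- majority_rule_consensus(ms, weights = w)
  # independent oracle: for each displayed split, weighted frequency =
  # mean over islands of the split's within-island relative frequency
  for (s in mc$splits) {
    per_island <- vapply(part$islands, function(isl) {
      members <- ms$topologies[match(isl$member_keys, ms$keys)]
      mean(vapply(members, function(t) s %in% t$splits, TRUE))
    }, 0)
    expect_equal(mc$freq[mc$splits == s], mean(per_island))
  }
})

test_that("island size does not sway the weighted consensus", {
  # same island content semantics, different island sizes: island 2 grows
  # from 3 to 9 members that vary only at its unstable edges, so the
  # weighted consensus topology is unchanged
  base_cfg <- function(sz2, seed) plant_config(n_leaves = 14, i = c(2, 2),
                                               sizes = c(9, sz2), seed = seed)
  small <- plant_islands(base_cfg(3, 33))
  large <- plant_islands(base_cfg(9, 33))
  ct_small <- majority_rule_consensus(
    small$trees, weights = island_weights(small$partition, small$trees))
  ct_large <- majority_rule_consensus(
    large$trees, weights = island_weights(large$partition, large$trees))
  # both runs share the same bases (same seed), so the stable splits of
  # each island coincide; the weighted topologies must agree on them
  stable_small <- ct_small$splits[ct_small$freq == 1]
  stable_large <- ct_large$splits[ct_large$freq == 1]
  expect_identical(stable_small, stable_large)
})

test_that("rarefaction draws n = floor(s * p) distinct topologies per island", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 1),
                                        sizes = c(9, 3), seed = 40))
  ms <- planted$trees
  part <- planted$partition
  r1 <- rarefy_islands(part, ms, p = 1, seed = 1)
  expect_length(r1, 6L)  # 3 per island
  counts <- table(part$assignment[r1$keys])
  expect_true(all(counts == 3L))
  expect_false(anyDuplicated(r1$keys) > 0)  # without replacement
  # lower bound p = 1/s: one topology per island
  r2 <- rarefy_islands(part, ms, p = 1 / 3, seed = 1)
  expect_length(r2, 2L)
  expect_error(rarefy_islands(part, ms, p = 0.1), "p must be")
  expect_error(rarefy_islands(part, ms, p = 2), "p must be")
  # seeded draws are reproducible
  expect_identical(rarefy_islands(part, ms, p = 2 / 3, seed = 9)$keys,
                   rarefy_islands(part, ms, p = 2 / 3, seed = 9)$keys)
})

test_that("rarefied consensus replicates are seed-reproducible and accounted", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 2),
                                        sizes = c(9, 6), seed = 50))
  ms <- planted$trees
  part <- planted$partition
  rc1 <- rarefied_consensus(part, ms, p = 0.5, replicates = 25, seed = 7)
  rc2 <- rarefied_consensus(part, ms, p = 0.5, replicates = 25, seed = 7)
  expect_identical(rc1$replicates$keys, rc2$replicates$keys)
  expect_identical(rc1$majority$splits, rc2$majority$splits)
  expect_identical(rc1$manifest$n_per_island, 3)
  expect_identical(rc1$replicates$total_mass, 25L)  # one consensus per draw
  expect_error(rarefied_consensus(part, ms, replicates = 0), "replicates")
  # strict-of-replicates nests inside majority-of-replicates
  expect_true(all(rc1$strict$splits %in% rc1$majority$splits))
})

test_that("with equal island sizes the rarefied and weighted summaries agree", {
  planted <- plant_islands(plant_config(n_leaves = 14, i = c(2, 2),
                                        sizes = c(9, 9), seed = 60))
  ms <- planted$trees
  part <- planted$partition
  w <- island_weights(part, ms)
  weighted <- majority_rule_consensus(ms, weights = w)
  rc <- rarefied_consensus(part, ms, p = 1, replicates = 10, seed = 3)
  # p = 1 and equal sizes: every replicate uses the full multiset, and both
  # summaries reduce to equal island influence
  expect_identical(rc$majority$splits, weighted$splits)
  expect_identical(rc$strict$splits, weighted$splits)
})

test_that("displayed splits reconstruct into a valid tree with frequency labels", {
  ms <- make_multiset(rand_topos(8, 7, seed = 70))
  mc <- majority_rule_consensus(ms)
  phy <- as.phylo(mc)
  expect_s3_class(phy, "phylo")
  # reconstruction displays exactly the consensus splits (compatibility)
  expect_setequal(nontrivial_splits(phy), mc$splits)
  out <- write_consensus(mc, tempfile())
  expect_match(out, "^\\(")
  nex <- write_consensus(mc, tempfile(), format = "nexus")
  expect_true(any(grepl("BEGIN TREES", nex)))
})
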