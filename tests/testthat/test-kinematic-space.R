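test_that("aggregate_ratings averages binary votes", {
  votes <- array(0, c(2, 3, 4),
                 dimnames = list(c("s1", "s2"), c("a", "b", "c"), NULL))
  votes[1, 1, ] <- 1                    # unanimous involvement
  votes[1, 2, ] <- c(1, 0, 1, 0)        # split vote
  loads <- unclass(aggregate_ratings(votes))
  expect_equal(loads[1, "a"], 1.0)
  expect_equal(loads[1, "b"], 0.5)
  expect_equal(loads[1, "c"], 0.0)
  # 87 unanimous raters still give exactly 1
  v87 <- array(1, c(1, 2, 87), dimnames = list("s", c("a", "b"), NULL))
  expect_equal(unname(unclass(aggregate_ratings(v87))[1, ]), c(1, 1))
  # single rater: loadings equal that rater's binary vector
  v1 <- array(c(1, 0, 0, 1, 1, 0), c(2, 3, 1),
              dimnames = list(c("s1", "s2"), c("a", "b", "c"), NULL))
  expect_equal(unclass(aggregate_ratings(v1))[, ], v1[, , 1])
  # control columns dropped by id
  expect_equal(colnames(aggregate_ratings(votes, drop_objects = "b")),
               c("a", "c"))
  votes[1, 1, 1] <- 0.5
  expect_error(aggregate_ratings(votes), "binary")
})

test_that("median split keeps objects strictly above the median", {
  set.seed(1)
  cen66 <- sample(seq(1, 5, length.out = 66))   # 66 distinct values
  objs <- object_set(sprintf("o%02d", 1:66), cen66)
  high <- select_high_centrality(objs)
  expect_identical(nrow(high), 33L)
  expect_setequal(high$object_id, objs$object_id[order(-cen66)][1:33])
  # symmetric split
  o4 <- object_set(c("a", "b", "c", "d"), c(1, 1, 5, 5))
  expect_setequal(select_high_centrality(o4)$object_id, c("c", "d"))
  # all tied: empty subset with a warning
  o3 <- object_set(c("a", "b", "c"), c(3, 3, 3))
  expect_warning(res <- select_high_centrality(o3), "degenerate")
  expect_identical(nrow(res), 0L)
})

test_that("compute_rdm is 1 - Pearson r with hand-checked entries", {
  m <- cbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(1, 0, 0), d = c(0, 1, 1))
  rdm <- compute_rdm(m)
  expect_equal(attr(rdm, "mode"), "dissimilarity")
  expect_equal(diag(unclass(rdm)), rep(0, 4), ignore_attr = TRUE)
  expect_equal(rdm["a", "c"], 0)          # identical columns
  # hand computation: cor((1,0,0), (0,1,0)) = -0.5
  expect_equal(rdm["a", "b"], 1.5)
  # exactly anticorrelated columns give 2
  m2 <- cbind(u = c(1, 2, 3), v = c(3, 2, 1))
  expect_equal(compute_rdm(m2)["u", "v"], 2)
  expect_error(compute_rdm(cbind(x = c(1, 1, 1), y = c(0, 1, 2))),
               "flagged-object")
})

test_that("RSM and RDM are entrywise duals", {
  w <- tiny_world(seed = 5L)
  rdm <- compute_rdm(w$ratings$ratings)
  rsm <- sim_convert(rdm)
  expect_equal(attr(rsm, "mode"), "similarity")
  expect_equal(diag(unclass(rsm)), rep(1, ncol(rsm)), ignore_attr = TRUE)
  off <- !diag(nrow(rdm))
  expect_equal(unclass(rsm)[off], 1 - unclass(rdm)[off])
  expect_equal(unclass(sim_convert(rsm)), unclass(rdm), tolerance = 1e-12)
})

test_that("Ward dendrogram separates planted clusters before joining them", {
  # two tight clusters of 3 objects each, far apart in loading space
  set.seed(42)
  base1 <- runif(10)
  base2 <- rev(base1)
  loads <- cbind(a1 = base1 + rnorm(10, 0, 0.01),
                 a2 = base1 + rnorm(10, 0, 0.01),
                 a3 = base1 + rnorm(10, 0, 0.01),
                 b1 = base2 + rnorm(10, 0, 0.01),
                 b2 = base2 + rnorm(10, 0, 0.01),
                 b3 = base2 + rnorm(10, 0, 0.01))
  d <- build_dendrogram(compute_rdm(loads))
  hc <- d$hclust
  cluster_of <- function(id) substr(id, 1, 1)
  # brute-force check over the merge list: the first n - 2 merges must
  # join members of a single cluster
  members <- function(i) {
    if (i < 0) return(hc$labels[-i])
    c(members(hc$merge[i, 1]), members(hc$merge[i, 2]))
  }
  for (i in seq_len(nrow(hc$merge) - 1L)) {
    expect_length(unique(cluster_of(members(i))), 1L)
  }
  expect_length(unique(cluster_of(members(nrow(hc$merge)))), 2L)
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("dendrogram of 2 objects is a single merge; order-invariant", {
  m <- cbind(a = c(1, 0, 1), b = c(0, 1, 0))
  d <- build_dendrogram(compute_rdm(m))
  expect_identical(nrow(d$hclust$merge), 1L)
  w <- tiny_world(seed = 13L)
  loads <- unclass(w$ratings$ratings)
  d1 <- build_dendrogram(compute_rdm(loads))
  perm <- sample(ncol(loads))
  d2 <- build_dendrogram(compute_rdm(loads[, perm]))
  co1 <- as.matrix(stats::cophenetic(d1$hclust))
  co2 <- as.matrix(stats::cophenetic(d2$hclust))
  ids <- colnames(loads)
  expect_equal(co1[ids, ids], co2[ids, ids], tolerance = 1e-10)
})

test_that("entanglement matches its defining endpoints and symmetry", {
  ids <- sprintf("o%02d", 1:10)
  lad <- ladder_dendro(ids)
  rev_lad <- ladder_dendro(rev(ids))
  expect_equal(entanglement(lad, lad), 0)
  # reversed ladder hits the worst-case normalisation exactly
  expect_equal(entanglement(lad, rev_lad), 1)
  w <- tiny_world(seed = 3L)
  d1 <- dendro_of(unclass(w$ratings$ratings))
  d2 <- dendro_of(unclass(w$ratings$ratings)[sample(12), ])
  expect_equal(entanglement(d1, d2), entanglement(d2, d1))
  d3 <- dendro_of(unclass(w$ratings$ratings)[, 1:6])
  expect_error(entanglement(d1, d3), "mismatched")
})

test_that("entanglement stays in [0, 1] over random tree pairs", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:14, 1)
    m1 <- matrix(runif(8 * n), 8, n,
                 dimnames = list(NULL, sprintf("o%02d", 1:n)))
    m2 <- matrix(runif(8 * n), 8, n,
                 dimnames = list(NULL, sprintf("o%02d", 1:n)))
    e <- entanglement(dendro_of(m1), dendro_of(m2))
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("untangling never increases entanglement", {
  w <- tiny_world(seed = 17L)
  d1 <- dendro_of(unclass(w$ratings$ratings))
  d2 <- dendro_of(unclass(w$ratings$ratings) +
                    matrix(rnorm(12 * 12, 0, 0.05), 12, 12))
  raw <- entanglement(d1, d2)
  unt <- untangle_stepwise(d1, d2)
  expect_lte(unt$entanglement, raw + 1e-12)
  expect_equal(entanglement(unt$d1, unt$d2), unt$entanglement)
})

test_that("entanglement permutation test is calibrated at its endpoints", {
  w <- tiny_world(seed = 19L)
  d1 <- dendro_of(unclass(w$ratings$ratings))
  # identical trees: observed 0 is minimal, p = 1/(n_perm + 1)
  et <- entanglement_permutation_test(d1, d1, n_perm = 99L, seed = 1L)
  expect_equal(et$observed, 0)
  expect_equal(et$p_value, 1 / 100)
  # fixed seed reproduces the p-value exactly
  et2 <- entanglement_permutation_test(d1, d1, n_perm = 99L, seed = 1L)
  expect_identical(et$null, et2$null)
})

test_that("planted two-cluster ratings yield aligned trees (p < 0.01)", {
  cfg <- tiny_cfg(seed = 23L, n_objects = 16L)
  rat <- generate_ratings(cfg, structure = "two_cluster")
  # zero-noise: cluster the same loadings twice (independent builds)
  d1 <- dendro_of(unclass(rat$ratings))
  d2 <- dendro_of(unclass(rat$ratings))
  et <- entanglement_permutation_test(d1, d2, n_perm = 999L, seed = 7L)
  expect_lt(et$p_value, 0.01)
})

test_that("newick serialisation round-trips through ape", {
  skip_if_not_installed("ape")
  w <- tiny_world(seed = 29L)
  d <- dendro_of(unclass(w$ratings$ratings))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(d, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, d$object_ids)
  # Ward merge heights produce an ultrametric tree
  expect_true(ape::is.ultrametric(tree, tol = 1e-6))
})
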