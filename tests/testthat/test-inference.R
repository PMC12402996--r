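test_that("fisher_z matches the closed form and clips at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  expect_true(is.na(fisher_z(NA_real_)))
  m <- matrix(c(0.1, NA, -0.2, 0.9), 2, 2)
  expect_identical(dim(fisher_z(m)), dim(m))
})

test_that("masked smoothing is the identity at fwhm 0 and on constants", {
  mask <- make_brain_mask(c(10L, 10L, 10L))
  vol <- array(rnorm(1000), c(10, 10, 10))
  expect_identical(smooth_volume(vol, 0, 3, mask), vol)
  cvol <- array(0, c(10, 10, 10))
  cvol[mask] <- 7.5
  sm <- smooth_volume(cvol, 6, 3, mask)
  expect_equal(sm[mask], rep(7.5, sum(mask)), tolerance = 1e-10)
  expect_true(all(is.na(sm[!mask])))
  expect_error(smooth_volume(vol, -1, 3), "nonnegative")
})

test_that("smoothing a delta reproduces the Gaussian profile", {
  vol <- array(0, c(15, 15, 15))
  vol[8, 8, 8] <- 1
  fwhm <- 6; vox <- 3
  sm <- smooth_volume(vol, fwhm, vox)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  for (d in 1:3) {
    expect_equal(sm[8 + d, 8, 8] / sm[8, 8, 8], exp(-d^2 / (2 * sigma^2)),
                 tolerance = 1e-6)
  }
})

fake_scores <- function(z, mask) {
  structure(list(r = tanh(z), z = z, valid = !is.na(z), mask = mask,
                 grid_shape = dim(mask), voxel_size_mm = 3,
                 subject_ids = sprintf("sub%02d", seq_len(nrow(z))),
                 statistic = "test_z"),
            class = "score_maps")
}

test_that("group t test matches hand computation and flags degeneracies", {
  mask <- array(TRUE, c(3L, 1L, 1L))
  z <- rbind(c(0.2, 1, 5), c(0.4, -1, 5), c(0.6, 0, 5))
  gt <- group_ttest(fake_scores(z, mask))
  expect_equal(gt$t[1], 0.4 / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(gt$t[1], 3.464, tolerance = 1e-3)
  expect_equal(gt$t[2], 0)
  expect_true(is.na(gt$t[3]))  # zero variance across subjects
})

test_that("TFCE matches brute-force threshold integration", {
  dims <- c(5L, 5L, 5L)
  # independent R oracle: explicit component search per threshold step
  brute_tfce <- function(vol, H, E, n_steps) {
    mx <- max(vol, 0)
    if (mx <= 0) return(array(0, dim(vol)))
    dh <- mx / n_steps
    out <- array(0, dim(vol))
    for (h in seq(dh, mx, length.out = n_steps)) {
      supra <- which(vol >= h)
      seen <- rep(FALSE, length(supra))
      idx3 <- arrayInd(supra, dim(vol))
      for (start in seq_along(supra)) {
        if (seen[start]) next
        comp <- start
        frontier <- start
        while (length(frontier) > 0) {
          nxt <- integer(0)
          for (f in frontier) {
            d <- abs(idx3 - matrix(idx3[f, ], nrow(idx3), 3, byrow = TRUE))
            nb <- which(rowSums(d) == 1L & !seen & !(seq_along(supra) %in% comp))
            nb <- setdiff(nb, comp)
            comp <- c(comp, nb)
            nxt <- c(nxt, nb)
          }
          frontier <- unique(nxt)
        }
        seen[comp] <- TRUE
        out[supra[comp]] <- out[supra[comp]] +
          length(comp)^E * h^H * dh
      }
    }
    out
  }
  set.seed(5)
  vol <- array(pmax(rnorm(prod(dims), 0.5, 1), 0), dims)
  got <- tfce(vol, H = 2, E = 0.5, n_steps = 1000L)
  want <- brute_tfce(vol, 2, 0.5, 1000L)
  nz <- want > 0
  expect_lt(max(abs(got[nz] - want[nz]) / want[nz]), 0.01)
  # single isolated suprathreshold voxel: closed-form Riemann sum
  v1 <- array(0, dims)
  v1[3, 3, 3] <- 2
  got1 <- tfce(v1, H = 2, E = 0.5, n_steps = 100L)
  dh <- 2 / 100
  expect_equal(got1[3, 3, 3], sum(1^0.5 * (seq_len(100) * dh)^2 * dh),
               tolerance = 1e-10)
  # flat zero map stays zero; doubling t increases every nonzero value
  expect_true(all(tfce(array(0, dims)) == 0))
  got2 <- tfce(2 * vol, H = 2, E = 0.5, n_steps = 100L)
  base <- tfce(vol, H = 2, E = 0.5, n_steps = 100L)
  expect_true(all(got2[base > 0] > base[base > 0]))
  # negative tail mirrors the positive tail
  expect_equal(tfce(-vol, H = 2, E = 0.5, n_steps = 100L), -base)
})

test_that("identity sign-flip yields p = 1 everywhere; seeds reproduce", {
  mask <- make_brain_mask(c(8L, 8L, 8L))
  set.seed(9)
  z <- matrix(rnorm(5 * sum(mask), 0.1), 5)
  sc <- fake_scores(z, mask)
  sm <- permutation_correct(sc, flips = matrix(1, 1, 5))
  expect_true(all(sm$p_corrected == 1, na.rm = TRUE))
  s1 <- permutation_correct(sc, n_perm = 50L, seed = 4L)
  s2 <- permutation_correct(sc, n_perm = 50L, seed = 4L)
  expect_identical(s1$p_corrected, s2$p_corrected)
  expect_s3_class(s1, "stat_map")
  expect_identical(s1$method, "tfce_permutation")
})

test_that("planted signal survives TFCE permutation correction", {
  w <- tiny_world(seed = 73L, n_subjects = 8L, noise_sd = 0.8)
  sc <- univariate_rsa_score(w$cohort,
                             run_encoding_model(w$cohort, w$ratings$ratings))
  sm <- permutation_correct(smooth_score_maps(sc, 6), n_perm = 200L, seed = 2L)
  kin <- w$truth$region_masks$kinematic[w$cohort$mask]
  nulS <- w$truth$null_strict[w$cohort$mask]
  expect_gt(mean(sm$significant[kin], na.rm = TRUE), 0.5)
  expect_equal(sum(sm$significant[nulS], na.rm = TRUE), 0L,
               ignore_attr = TRUE)
})

test_that("FDR cluster correction finds planted clusters and only those", {
  w <- tiny_world(seed = 79L, n_subjects = 8L, noise_sd = 0.8)
  sc <- univariate_rsa_score(w$cohort,
                             run_encoding_model(w$cohort, w$ratings$ratings))
  sm <- fdr_cluster_correct(smooth_score_maps(sc, 6), height_p = 0.001,
                            q = 0.05, n_perm = 200L, seed = 3L)
  expect_s3_class(sm, "stat_map")
  expect_gt(nrow(sm$clusters), 0L)
  expect_true(any(sm$clusters$survives))
  kin <- w$truth$region_masks$kinematic[w$cohort$mask]
  expect_gt(mean(sm$significant[kin]), 0.5)
  # no-signal map: empty cluster table
  set.seed(11)
  mask <- w$cohort$mask
  z0 <- matrix(rnorm(8 * sum(mask), 0, 0.2), 8)
  sm0 <- fdr_cluster_correct(fake_scores(z0, mask), n_perm = 50L, seed = 1L)
  expect_identical(nrow(sm0$clusters), 0L)
})

test_that("cluster-extent Monte Carlo thresholds behave monotonically", {
  w <- tiny_world(seed = 83L, n_subjects = 8L, noise_sd = 0.8)
  sc <- univariate_rsa_score(w$cohort,
                             run_encoding_model(w$cohort, w$ratings$ratings))
  sm <- smooth_score_maps(sc, 6)
  mc_loose <- cluster_extent_mc(sm, height_p = 0.01, n_sim = 100L, seed = 5L)
  mc_strict <- cluster_extent_mc(sm, height_p = 0.001, n_sim = 100L, seed = 5L)
  expect_lte(mc_strict$extent_threshold, mc_loose$extent_threshold)
  expect_true(any(mc_strict$clusters$survives))
  # n_sim = 1: the threshold is that single null's max cluster size
  mc1 <- cluster_extent_mc(sm, height_p = 0.01, n_sim = 1L, seed = 7L)
  expect_identical(mc1$extent_threshold, max(mc1$null_sizes))
})
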