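# betas fixture: objects x voxels with recognisable values
toy_betas <- function(n_obj = 5L, n_vox = 7L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n_obj * n_vox), n_obj, n_vox,
         dimnames = list(sprintf("o%d", seq_len(n_obj)), NULL))
}

test_that("synergy maps equal pairwise-subtraction averages", {
  b <- toy_betas()
  loads <- matrix(c(0.9, 0.1, 0.1, 0.8, 0.2), 1, 5,
                  dimnames = list("s1", rownames(b)))
  map <- build_synergy_map(b, rating_matrix(loads), "s1", left_out = "o4")
  expect_setequal(attr(map, "high"), "o1")
  expect_setequal(attr(map, "low"), c("o2", "o3", "o5"))
  # pairwise-enumeration oracle: mean over all (high, low) pairs
  pairs <- expand.grid(h = "o1", l = c("o2", "o3", "o5"),
                       stringsAsFactors = FALSE)
  oracle <- Reduce(`+`, lapply(seq_len(nrow(pairs)), function(i) {
    b[pairs$h[i], ] - b[pairs$l[i], ]
  })) / nrow(pairs)
  expect_equal(as.numeric(map), oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("boundary loadings and empty sets follow the strict rules", {
  b <- toy_betas()
  # exactly 0.75 and 0.25 fall in neither set
  loads <- matrix(c(0.75, 0.25, 0.8, 0.1, 0.5), 1, 5,
                  dimnames = list("s1", rownames(b)))
  map <- build_synergy_map(b, rating_matrix(loads), "s1", left_out = "o5")
  expect_setequal(attr(map, "high"), "o3")
  expect_setequal(attr(map, "low"), "o4")
  # all low: absent map
  lo <- matrix(rep(0.1, 5), 1, dimnames = list("s1", rownames(b)))
  expect_null(build_synergy_map(b, rating_matrix(lo), "s1", "o1"))
  # held-out object never appears in either set
  hi <- matrix(c(0.9, 0.9, 0.1, 0.1, 0.5), 1, 5,
               dimnames = list("s1", rownames(b)))
  m2 <- build_synergy_map(b, rating_matrix(hi), "s1", left_out = "o1")
  expect_false("o1" %in% c(attr(m2, "high"), attr(m2, "low")))
})

test_that("predict_object is the stated weighted sum", {
  maps <- list(c(1, 2), c(10, 20), c(100, 200))
  # hand-summed combination on a 2-voxel grid
  expect_equal(predict_object(maps, c(0.8, 0.9, 0.0)),
               0.8 * c(1, 2) + 0.9 * c(10, 20))
  expect_equal(predict_object(maps[1], 1), c(1, 2))
  expect_equal(predict_object(maps, c(0, 0, 0)), c(0, 0))
  # absent synergies contribute zero
  expect_equal(predict_object(list(c(1, 2), NULL), c(0.5, 0.9)), c(0.5, 1))
  expect_error(predict_object(list(NULL, NULL), c(1, 1)), "empty-model")
})

test_that("the encoding model runs one fold per object", {
  w <- tiny_world(seed = 31L)
  preds <- run_encoding_model(w$cohort, w$ratings$ratings)
  expect_identical(preds$n_folds, length(w$cohort$object_ids))
  expect_identical(rownames(preds$predicted[[1]]), w$cohort$object_ids)
  expect_length(preds$invalid_folds, 0L)
})

test_that("no leakage: a fold never sees its own object's volumes", {
  w <- tiny_world(seed = 37L)
  preds <- run_encoding_model(w$cohort, w$ratings$ratings)
  for (t_obj in c("obj03", "obj09")) {
    tampered <- w$cohort
    for (j in seq_along(tampered$betas)) {
      tampered$betas[[j]][t_obj, ] <-
        rnorm(ncol(tampered$betas[[j]]), sd = 50)
    }
    preds2 <- run_encoding_model(tampered, w$ratings$ratings)
    for (j in seq_along(preds$predicted)) {
      expect_identical(preds$predicted[[j]][t_obj, ],
                       preds2$predicted[[j]][t_obj, ])
    }
  }
})

test_that("pairwise averaging equals mean(high) - mean(low) on random instances", {
  set.seed(61)
  for (i in 1:25) {
    n_obj <- sample(5:12, 1)
    b <- matrix(rnorm(n_obj * 6), n_obj, 6,
                dimnames = list(sprintf("o%d", 1:n_obj), NULL))
    k <- runif(n_obj)
    loads <- matrix(k, 1, n_obj, dimnames = list("s", rownames(b)))
    t_obj <- sample(rownames(b), 1)
    map <- build_synergy_map(b, rating_matrix(loads), "s", t_obj)
    hi <- setdiff(rownames(b)[k > 0.75], t_obj)
    lo <- setdiff(rownames(b)[k < 0.25], t_obj)
    if (length(hi) == 0L || length(lo) == 0L) {
      expect_null(map)
      next
    }
    oracle <- 0
    for (h in hi) for (l in lo) oracle <- oracle + (b[h, ] - b[l, ])
    oracle <- oracle / (length(hi) * length(lo))
    expect_equal(as.numeric(map), as.numeric(oracle), tolerance = 1e-10)
  }
})

test_that("univariate RSA scoring hits the correlation endpoints", {
  w <- tiny_world(seed = 41L, n_subjects = 2L)
  preds <- run_encoding_model(w$cohort, w$ratings$ratings)
  # predicted identical to observed: r = 1 everywhere valid
  preds_perfect <- preds
  preds_perfect$predicted <- w$cohort$betas
  sc <- univariate_rsa_score(w$cohort, preds_perfect)
  expect_true(all(abs(sc$r - 1) < 1e-12, na.rm = TRUE))
  # predicted = -observed: r = -1
  preds_anti <- preds
  preds_anti$predicted <- lapply(w$cohort$betas, function(b) -b)
  sc2 <- univariate_rsa_score(w$cohort, preds_anti)
  expect_true(all(abs(sc2$r + 1) < 1e-12, na.rm = TRUE))
  # Fisher z is finite even at |r| = 1
  expect_true(all(is.finite(sc$z[sc$valid])))
})

test_that("zero-variance voxels are flagged invalid, not zeroed", {
  w <- tiny_world(seed = 43L, n_subjects = 2L)
  cohort <- w$cohort
  cohort$betas[[1]][, 5] <- 3.14   # constant across objects at voxel 5
  preds <- run_encoding_model(cohort, w$ratings$ratings)
  sc <- univariate_rsa_score(cohort, preds)
  expect_true(is.na(sc$r[1, 5]))
  expect_false(sc$valid[1, 5])
  expect_false(anyNA(sc$r[2, ]))
})

test_that("noiseless planted cohort recovers the kinematic region (r > 0.9)", {
  cfg <- synth_config(seed = 47L, noise_sd = 0, n_subjects = 2L,
                      grid_shape = c(16L, 16L, 16L))
  rat <- generate_ratings(cfg)
  gen <- generate_cohort(cfg, rat$ratings,
                         generate_visual_features(cfg)$features)
  preds <- run_encoding_model(gen$cohort, rat$ratings)
  sc <- univariate_rsa_score(gen$cohort, preds)
  kin <- gen$truth$region_masks$kinematic[gen$cohort$mask]
  expect_gt(mean(sc$r[, kin], na.rm = TRUE), 0.9)
})

test_that("recovery degrades monotonically with noise", {
  cfg0 <- tiny_cfg(seed = 53L, n_subjects = 3L)
  rat <- generate_ratings(cfg0)
  feats <- generate_visual_features(cfg0)
  mean_r <- vapply(c(0, 1, 3), function(ns) {
    out <- numeric(3)
    for (rep in 1:3) {
      cfg <- tiny_cfg(seed = 53L + rep, n_subjects = 3L, noise_sd = ns)
      gen <- generate_cohort(cfg, rat$ratings, feats$features)
      sc <- univariate_rsa_score(gen$cohort,
                                 run_encoding_model(gen$cohort, rat$ratings))
      kin <- gen$truth$region_masks$kinematic[gen$cohort$mask]
      out[rep] <- mean(sc$r[, kin], na.rm = TRUE)
    }
    mean(out)
  }, 0)
  expect_true(all(diff(mean_r) < 0))
})

test_that("shuffling rating labels destroys in-region prediction", {
  # family-respecting derangement: no object keeps a label from its own
  # family, so no chance re-alignment survives the shuffle
  w <- tiny_world(seed = 59L, n_subjects = 6L)
  rat <- w$ratings
  fam <- rat$object_family
  ids <- colnames(unclass(rat$ratings))
  perm <- with(list(), {
    repeat {
      p <- sample(ids)
      if (all(fam[p] != fam[ids])) break
    }
    p
  })
  shuf <- unclass(rat$ratings)
  colnames(shuf) <- NULL
  shuf <- shuf[, match(ids, perm)]
  colnames(shuf) <- ids
  sc <- univariate_rsa_score(w$cohort,
                             run_encoding_model(w$cohort, rating_matrix(shuf)))
  sm <- smooth_score_maps(sc, 6)
  kin <- w$truth$region_masks$kinematic[w$cohort$mask]
  subj_mean <- rowMeans(sm$z[, kin], na.rm = TRUE)
  se <- sd(subj_mean) / sqrt(length(subj_mean))
  # one-sided: misaligned ratings must show no positive in-region
  # prediction; a small negative offset is the documented leave-one-out
  # correlation artefact (see the methods vignette), not prediction
  expect_lt(mean(subj_mean), 2 * se)
  expect_gt(mean(subj_mean), -0.1)
})
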