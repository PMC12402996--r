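# Group-level inference over per-subject score maps: smoothing, one-sample
# t, threshold-free cluster enhancement (TFCE) with sign-flip permutation
# correction, FDR cluster correction, and Monte-Carlo cluster-extent
# correction. The pipeline order mirrors standard practice:
# r -> Fisher z -> smooth -> group t -> TFCE -> permutation correction.

#' Smooth per-subject score maps within the brain mask
#'
#' Applies masked Gaussian smoothing (see [smooth_volume()]) to each
#' subject's z map. Voxels flagged invalid stay invalid.
#'
#' @param scores a `score_maps` object.
#' @param fwhm_mm smoothing kernel FWHM in mm (e.g. 6).
#' @return a new `score_maps` with smoothed `z` (and `r = tanh(z)`).
#' @export
smooth_score_maps <- function(scores, fwhm_mm) {
  stopifnot(inherits(scores, "score_maps"))
  if (fwhm_mm == 0) return(scores)
  out <- scores
  for (j in seq_len(nrow(scores$z))) {
    vol <- unmask(scores$z[j, ], scores$mask)
    sm <- smooth_volume(vol, fwhm_mm, scores$voxel_size_mm, mask = scores$mask)
    v <- sm[scores$mask]
    v[!scores$valid[j, ]] <- NA_real_
    out$z[j, ] <- v
  }
  out$r <- tanh(out$z)
  out
}

# One-sample t vs 0 per column with NA handling; voxels valid in fewer
# than min_frac of subjects, or with zero variance, become NA.
group_t_stats <- function(z, min_frac = 0.8) {
  valid <- !is.na(z)
  z0 <- z
  z0[!valid] <- 0
  n_v <- colSums(valid)
  mu <- colSums(z0) / pmax(n_v, 1L)
  ss <- colSums(z0^2)
  var_v <- (ss - n_v * mu^2) / pmax(n_v - 1L, 1L)
  t_v <- mu / sqrt(var_v / n_v)
  bad <- n_v < max(2L, ceiling(min_frac * nrow(z))) | var_v <= 0
  t_v[bad] <- NA_real_
  list(t = t_v, n = n_v, df = n_v - 1L)
}

#' Voxelwise one-sample t test over subjects
#'
#' Two-tailed one-sample t vs 0 at every in-mask voxel, over the subjects
#' with a valid value there. Voxels valid in fewer than `min_frac` of
#' subjects (or with zero variance across subjects) are dropped (NA).
#'
#' @param scores a `score_maps` object (use the `z` maps).
#' @param min_frac minimum fraction of subjects that must be valid.
#' @return list with in-mask vectors `t`, `p` (two-tailed), `df`, `n`.
#' @export
group_ttest <- function(scores, min_frac = 0.8) {
  stopifnot(inherits(scores, "score_maps"))
  st <- group_t_stats(scores$z, min_frac)
  p <- 2 * stats::pt(abs(st$t), df = st$df, lower.tail = FALSE)
  c(st, list(p = p))
}

#' Threshold-free cluster enhancement of a t map
#'
#' Per voxel, integrates `extent(h)^E * h^H dh` over thresholds `h` from 0
#' to the map maximum in `n_steps` equal steps, where `extent(h)` is the
#' size of the voxel's 6-connected suprathreshold component. The negative
#' tail is enhanced identically on the negated map and returned with a
#' negative sign, so the output is signed.
#'
#' @param t_vals in-mask t vector (NA allowed) or 3-D array.
#' @param mask logical 3-D array (required when `t_vals` is a vector).
#' @param H height exponent (default 2).
#' @param E extent exponent (default 0.5).
#' @param n_steps number of integration steps (default 100).
#' @return object shaped like the input: signed TFCE values, NA where the
#'   input was NA.
#' @export
tfce <- function(t_vals, mask = NULL, H = 2, E = 0.5, n_steps = 100L) {
  stopifnot(H > 0, E > 0, n_steps >= 1L)
  as_vol <- is.array(t_vals) && length(dim(t_vals)) == 3L
  if (as_vol) {
    vol <- t_vals
  } else {
    if (is.null(mask)) stop("mask required for vector input")
    vol <- unmask(t_vals, mask, fill = NA_real_)
  }
  dims <- as.integer(dim(vol))
  na_idx <- is.na(vol)
  v <- vol
  v[na_idx] <- 0
  pos <- tfce_cpp(v, dims, H, E, as.integer(n_steps))
  neg <- tfce_cpp(-v, dims, H, E, as.integer(n_steps))
  out <- as.numeric(pos) - as.numeric(neg)
  out[na_idx] <- NA_real_
  if (as_vol) array(out, dims) else array(out, dims)[mask]
}

sign_flip_t <- function(z, signs, min_frac = 0.8) {
  valid <- !is.na(z)
  z0 <- z
  z0[!valid] <- 0
  n_v <- colSums(valid)
  ss <- colSums(z0^2)
  mu <- as.numeric(signs %*% z0) / pmax(n_v, 1L)
  var_v <- (ss - n_v * mu^2) / pmax(n_v - 1L, 1L)
  t_v <- mu / sqrt(var_v / n_v)
  bad <- n_v < max(2L, ceiling(min_frac * nrow(z))) | var_v <= 0
  t_v[bad] <- NA_real_
  t_v
}

#' TFCE with sign-flip permutation familywise correction
#'
#' The observed group t map is TFCE-enhanced; a null distribution of the
#' maximum in-mask |TFCE| is built by randomly negating each subject's map
#' (sign-flip permutation, the valid exchangeability scheme for one-sample
#' designs), recomputing t and TFCE for each draw. Corrected p-values are
#' `(1 + #(null_max >= |tfce(v)|)) / (n_perm + 1)`, controlling the
#' familywise error over both tails.
#'
#' @param scores a `score_maps` object (z maps are tested).
#' @param n_perm number of sign-flip permutations (>= 1).
#' @param seed integer seed.
#' @param alpha familywise significance level (default 0.05).
#' @param H,E,n_steps TFCE parameters (defaults 2, 0.5, 100).
#' @param min_frac minimum valid-subject fraction per voxel.
#' @param flips optional n_perm x n_subjects matrix of +/-1 overriding the
#'   random draws (for deterministic checks).
#' @return object of class `stat_map`: in-mask `t`, `tfce`, `p_corrected`,
#'   `significant` vectors, the null maxima, and provenance fields.
#' @export
permutation_correct <- function(scores, n_perm = 10000L, seed = 1L,
                                alpha = 0.05, H = 2, E = 0.5,
                                n_steps = 100L, min_frac = 0.8,
                                flips = NULL) {
  stopifnot(inherits(scores, "score_maps"), n_perm >= 1L)
  z <- scores$z
  n_sub <- nrow(z)
  st <- group_t_stats(z, min_frac)
  obs_tfce <- tfce(st$t, scores$mask, H, E, n_steps)
  if (is.null(flips)) {
    flips <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n_sub,
                                           replace = TRUE),
                                    n_perm, n_sub))
  } else {
    flips <- matrix(flips, ncol = n_sub)
    n_perm <- nrow(flips)
  }
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    t_p <- sign_flip_t(z, flips[i, , drop = FALSE], min_frac)
    e_p <- tfce(t_p, scores$mask, H, E, n_steps)
    null_max[i] <- max(abs(e_p), na.rm = TRUE)
  }
  a <- abs(obs_tfce)
  p_corr <- rep(NA_real_, length(a))
  ok <- !is.na(a)
  p_corr[ok] <- (1 + vapply(a[ok], function(x) sum(null_max >= x), 0)) /
    (n_perm + 1)
  structure(list(t = st$t, tfce = obs_tfce, p_corrected = p_corr,
                 significant = !is.na(p_corr) & p_corr <= alpha,
                 null_max = null_max, mask = scores$mask,
                 grid_shape = scores$grid_shape,
                 method = "tfce_permutation", n_subjects = n_sub,
                 n_permutations = n_perm, seed = seed, alpha = alpha,
                 H = H, E = E, n_steps = n_steps),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map [%s]: %d subjects, %d permutations, %d significant voxel(s) at alpha = %g\n",
              x$method, x$n_subjects,
              if (is.null(x$n_permutations)) NA_integer_ else x$n_permutations,
              sum(x$significant, na.rm = TRUE), x$alpha))
  invisible(x)
}

# clusters of both signs at a two-tailed voxel height threshold
threshold_clusters <- function(t_vec, df, mask, height_p) {
  t_crit <- stats::qt(1 - height_p / 2, df = pmax(df, 1L))
  vol <- unmask(t_vec, mask, fill = 0)
  vol[is.na(vol)] <- 0
  dims <- as.integer(dim(mask))
  tabs <- list()
  for (sgn in c(1, -1)) {
    supra_in <- !is.na(t_vec) & (sgn * t_vec) > t_crit
    supra <- unmask(as.numeric(supra_in), mask, fill = 0) > 0
    lab <- label_clusters_cpp(supra, dims)
    if (length(lab$sizes) == 0L) next
    for (k in seq_along(lab$sizes)) {
      in_k <- which(lab$labels == k)
      peak <- in_k[which.max(sgn * vol[in_k])]
      tabs[[length(tabs) + 1L]] <- data.frame(
        sign = sgn, size = lab$sizes[k], peak_value = vol[peak],
        peak_x = arrayInd(peak, dims)[1], peak_y = arrayInd(peak, dims)[2],
        peak_z = arrayInd(peak, dims)[3])
    }
  }
  if (length(tabs) == 0L)
    return(data.frame(sign = numeric(0), size = numeric(0),
                      peak_value = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0)))
  do.call(rbind, tabs)
}

null_max_cluster_sizes <- function(z, mask, height_p, n_sim, seed,
                                   min_frac = 0.8) {
  n_sub <- nrow(z)
  flips <- with_seed(seed, matrix(sample(c(-1, 1), n_sim * n_sub,
                                         replace = TRUE), n_sim, n_sub))
  dims <- as.integer(dim(mask))
  vapply(seq_len(n_sim), function(i) {
    t_p <- sign_flip_t(z, flips[i, , drop = FALSE], min_frac)
    df_p <- colSums(!is.na(z)) - 1L
    t_crit <- stats::qt(1 - height_p / 2, df = df_p)
    supra_v <- !is.na(t_p) & abs(t_p) > t_crit
    vol <- unmask(as.numeric(supra_v), mask, fill = 0)
    lab <- label_clusters_cpp(vol > 0, dims)
    if (length(lab$sizes) == 0L) 0 else max(lab$sizes)
  }, 0)
}

#' FDR-corrected cluster inference
#'
#' Clusters are formed from the group t map at a two-tailed voxel height
#' threshold (`height_p`, default 0.001); each cluster's uncorrected
#' p-value comes from a sign-flip permutation null of the maximum cluster
#' extent at the same height threshold, and Benjamini-Hochberg is applied
#' across clusters at level `q`.
#'
#' @param scores a `score_maps` object.
#' @param height_p cluster-forming voxel p threshold (two-tailed).
#' @param q FDR level over clusters (default 0.05).
#' @param n_perm permutations for the extent null.
#' @param seed integer seed.
#' @param min_frac minimum valid-subject fraction per voxel.
#' @return object of class `stat_map` (method `fdr_cluster`) whose
#'   `clusters` data frame lists size, peak, uncorrected and FDR p-values,
#'   and survival at `q`; `significant` marks voxels in surviving clusters.
#' @export
fdr_cluster_correct <- function(scores, height_p = 0.001, q = 0.05,
                                n_perm = 1000L, seed = 1L, min_frac = 0.8) {
  stopifnot(inherits(scores, "score_maps"))
  st <- group_t_stats(scores$z, min_frac)
  tab <- threshold_clusters(st$t, st$df, scores$mask, height_p)
  sig_vox <- rep(FALSE, length(st$t))
  if (nrow(tab) > 0L) {
    null_sizes <- null_max_cluster_sizes(scores$z, scores$mask, height_p,
                                         n_perm, seed, min_frac)
    tab$p_unc <- vapply(tab$size, function(s) {
      (1 + sum(null_sizes >= s)) / (n_perm + 1)
    }, 0)
    tab$p_fdr <- stats::p.adjust(tab$p_unc, method = "BH")
    tab$survives <- tab$p_fdr <= q
    if (any(tab$survives)) {
      t_crit <- stats::qt(1 - height_p / 2, df = pmax(st$df, 1L))
      dims <- as.integer(dim(scores$mask))
      for (i in which(tab$survives)) {
        supra_in <- !is.na(st$t) & (tab$sign[i] * st$t) > t_crit
        supra <- unmask(as.numeric(supra_in), scores$mask, fill = 0) > 0
        lab <- label_clusters_cpp(supra, dims)
        pk <- (tab$peak_x[i]) + dims[1] * (tab$peak_y[i] - 1L) +
          dims[1] * dims[2] * (tab$peak_z[i] - 1L)
        k <- lab$labels[pk]
        sig_vox <- sig_vox | (lab$labels[scores$mask] == k & k > 0)
      }
    }
  } else {
    tab$p_unc <- numeric(0)
    tab$p_fdr <- numeric(0)
    tab$survives <- logical(0)
  }
  structure(list(t = st$t, clusters = tab, significant = sig_vox,
                 mask = scores$mask, grid_shape = scores$grid_shape,
                 method = "fdr_cluster", n_subjects = nrow(scores$z),
                 n_permutations = n_perm, seed = seed, alpha = q,
                 height_p = height_p),
            class = "stat_map")
}

#' Monte-Carlo cluster-extent correction
#'
#' The minimum surviving cluster extent is the 95th percentile of the
#' maximum cluster size under a sign-flip null at the given two-tailed
#' height threshold; observed clusters at least that large survive.
#'
#' @param scores a `score_maps` object.
#' @param height_p cluster-forming voxel p threshold (two-tailed).
#' @param n_sim number of null simulations.
#' @param seed integer seed.
#' @param min_frac minimum valid-subject fraction per voxel.
#' @return object of class `stat_map` (method `cluster_extent_mc`) with
#'   `extent_threshold`, the cluster table, and the null size vector.
#' @export
cluster_extent_mc <- function(scores, height_p = 0.001, n_sim = 1000L,
                              seed = 1L, min_frac = 0.8) {
  stopifnot(inherits(scores, "score_maps"), n_sim >= 1L)
  st <- group_t_stats(scores$z, min_frac)
  tab <- threshold_clusters(st$t, st$df, scores$mask, height_p)
  null_sizes <- null_max_cluster_sizes(scores$z, scores$mask, height_p,
                                       n_sim, seed, min_frac)
  thr <- as.numeric(stats::quantile(null_sizes, 0.95, type = 1))
  if (nrow(tab) > 0L) tab$survives <- tab$size >= pmax(thr, 1)
  else tab$survives <- logical(0)
  structure(list(t = st$t, clusters = tab, extent_threshold = thr,
                 null_sizes = null_sizes, mask = scores$mask,
                 grid_shape = scores$grid_shape,
                 method = "cluster_extent_mc", n_subjects = nrow(scores$z),
                 n_permutations = n_sim, seed = seed, alpha = 0.05,
                 height_p = height_p, significant = NULL),
            class = "stat_map")
}
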