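# Synthetic cohorts with planted generative structure: rater-level binary
# synergy ratings, visual feature matrices, and multi-subject beta-volume
# cohorts in which disjoint regions carry kinematic, visual, and
# centrality-driven signal. Every downstream stage is tested against the
# ground truth planted here.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the design being emulated: 54 kinematic synergies rated
#' by 87 raters over 33 high-centrality objects, 25 fMRI subjects on a
#' 24x24x24 grid of 3 mm voxels.
#'
#' @param n_synergies,n_objects,n_raters,n_subjects positive integers.
#' @param grid_shape length-3 positive integer grid dimensions.
#' @param voxel_size_mm voxel edge length in mm.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param noise_fwhm_mm spatial smoothness (FWHM) of the noise fields;
#'   preprocessed beta maps have spatially correlated noise, typically
#'   1.5-2 voxels FWHM. `0` gives white noise.
#' @param effect_scale multiplier on all planted signal.
#' @param region_fractions named fractions of in-mask voxels assigned to
#'   the planted `kinematic`, `visual`, and `centrality` regions; the
#'   remainder is pure-noise `null`. Must sum to at most 1.
#' @param seed integer master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_synergies = 54L, n_objects = 33L, n_raters = 87L,
                         n_subjects = 25L, grid_shape = c(24L, 24L, 24L),
                         voxel_size_mm = 3, noise_sd = 1, noise_fwhm_mm = 6,
                         effect_scale = 1,
                         region_fractions = c(kinematic = 0.08, visual = 0.08,
                                              centrality = 0.06),
                         seed = 1L) {
  counts <- c(n_synergies, n_objects, n_raters, n_subjects)
  if (any(counts < 1L)) stop("invalid-config: all counts must be >= 1")
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("invalid-config: grid_shape must be three integers >= 2")
  if (voxel_size_mm <= 0 || noise_sd < 0 || effect_scale < 0 ||
      noise_fwhm_mm < 0)
    stop("invalid-config: nonpositive scale parameter")
  if (sum(region_fractions) > 1 + 1e-12)
    stop("invalid-config: region fractions must sum to <= 1")
  structure(list(
    n_synergies = as.integer(n_synergies), n_objects = as.integer(n_objects),
    n_raters = as.integer(n_raters), n_subjects = as.integer(n_subjects),
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    noise_sd = noise_sd, noise_fwhm_mm = noise_fwhm_mm,
    effect_scale = effect_scale,
    region_fractions = region_fractions, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate per-rater binary synergy ratings and their group aggregate
#'
#' Each rater marks each (synergy, object) pair as involved or not; the
#' group loading is the mean of those binary votes, in `[0, 1]`.
#'
#' The generative model groups synergies and objects into latent action
#' families (pairs of objects sharing a manipulation pattern, e.g. the
#' twisting twins screwdriver and corkscrew): a synergy is very likely to
#' be marked involved for objects of its own family (vote probability
#' 0.9) and unlikely otherwise (0.1), with a configurable fraction of
#' ambiguous synergy-family relations whose probability is drawn
#' uniformly from (0.3, 0.7). Ambiguity lives at the (synergy, family)
#' level -- whether a movement component is involved is a property of the
#' shared manipulation pattern -- so family mates have identical expected
#' loadings and differ only by rater sampling noise. This mirrors the
#' strong synergy-to-synergy correlation of real kinematic ratings and
#' keeps the held-out object's family mate a faithful stand-in for it in
#' the encoding model's training set.
#'
#' Family-mate objects act as the forced high set for each synergy and a
#' sample of out-of-family objects as the forced low set: those cells'
#' rater votes are resampled (up to 1,000 attempts each) until the
#' aggregated loading is > 0.75 or < 0.25 respectively, so every synergy
#' retains non-empty high and low sets after any single object is held
#' out. `structure = "two_cluster"` is the two-family special case used
#' to plant a recoverable two-cluster similarity structure.
#'
#' @param cfg a [synth_config()].
#' @param structure `"families"` (default) or `"two_cluster"`.
#' @param n_families number of latent action families; the default
#'   splits the objects into pairs (a final triple when odd). Forced to 2
#'   by `structure = "two_cluster"`.
#' @param ambiguous_frac fraction of (synergy, family) relations given
#'   mid-range probabilities.
#' @param n_low number of forced low-loading objects per synergy.
#' @param seed integer; defaults to `cfg$seed`.
#' @return list with `votes` (synergies x objects x raters binary array),
#'   `ratings` (a [rating_matrix()] of group loadings), and the latent
#'   `object_family`/`synergy_family` assignments.
#' @export
generate_ratings <- function(cfg, structure = c("families", "two_cluster"),
                             n_families = cfg$n_objects %/% 2L,
                             ambiguous_frac = 0.2,
                             n_low = 4L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  structure <- match.arg(structure)
  if (cfg$n_raters < 1L) stop("invalid-config: n_raters must be >= 1")
  if (structure == "two_cluster") n_families <- 2L
  ns <- cfg$n_synergies; no <- cfg$n_objects; nr <- cfg$n_raters
  n_families <- max(1L, min(n_families, no %/% 2L))
  synergy_ids <- sprintf("syn%02d", seq_len(ns))
  object_ids <- sprintf("obj%02d", seq_len(no))
  syn_family <- rep(seq_len(n_families), length.out = ns)
  obj_family <- rep(seq_len(n_families), length.out = no)
  with_seed(seed, {
    # family-level probability table, broadcast to objects
    pf <- matrix(0.1, ns, n_families)
    ambiguous <- matrix(runif(ns * n_families) < ambiguous_frac,
                        ns, n_families)
    pf[ambiguous] <- runif(sum(ambiguous), 0.3, 0.7)
    pf[cbind(seq_len(ns), syn_family)] <- 0.9
    prob <- pf[, obj_family, drop = FALSE]
    # forced high = own family; forced low = sample of other families'
    # objects whose family relation is unambiguous
    forced_hi <- matrix(FALSE, ns, no)
    forced_lo <- matrix(FALSE, ns, no)
    for (s in seq_len(ns)) {
      fam <- which(obj_family == syn_family[s])
      out <- which(prob[s, ] < 0.25 & obj_family != syn_family[s])
      lo <- sample(out, min(max(2L, n_low), length(out)))
      forced_hi[s, fam] <- TRUE
      forced_lo[s, lo] <- TRUE
    }
    votes <- array(rbinom(ns * no * nr, 1L, rep(prob, nr)),
                   dim = c(ns, no, nr))
    for (s in seq_len(ns)) for (o in seq_len(no)) {
      if (!forced_hi[s, o] && !forced_lo[s, o]) next
      target_hi <- forced_hi[s, o]
      ok <- FALSE
      for (att in seq_len(1000L)) {
        m <- mean(votes[s, o, ])
        if ((target_hi && m > 0.75) || (!target_hi && m < 0.25)) {
          ok <- TRUE
          break
        }
        votes[s, o, ] <- rbinom(nr, 1L, prob[s, o])
      }
      if (!ok) stop("forced-separation constraint unsatisfied after 1,000 attempts")
    }
    dimnames(votes) <- list(synergy_ids, object_ids, NULL)
    list(votes = votes, ratings = aggregate_ratings(votes),
         object_family = stats::setNames(obj_family, object_ids),
         synergy_family = stats::setNames(syn_family, synergy_ids))
  })
}

#' Generate a visual feature matrix and its object similarity matrix
#'
#' Feature rows stand in for CNN layer activations per object. By default
#' the features are independent Gaussian draws, decorrelating the visual
#' similarity structure from any kinematic one; `mix > 0` blends in the
#' (standardised) kinematic loadings to induce a correlated visual RSM.
#'
#' @param cfg a [synth_config()].
#' @param n_features number of features per object.
#' @param mix in `[0, 1]`; 0 = fully decorrelated from `ratings`.
#' @param ratings optional [rating_matrix()] required when `mix > 0`.
#' @param seed integer; defaults to `cfg$seed + 1`.
#' @return list with `features` (objects x features matrix, rows named by
#'   object) and `rsm` (a similarity [sim_matrix()]).
#' @export
generate_visual_features <- function(cfg, n_features = 64L, mix = 0,
                                     ratings = NULL, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synth_config"), mix >= 0, mix <= 1)
  no <- cfg$n_objects
  object_ids <- sprintf("obj%02d", seq_len(no))
  with_seed(seed, {
    feats <- matrix(rnorm(no * n_features), no, n_features)
    if (mix > 0) {
      if (is.null(ratings)) stop("ratings required when mix > 0")
      k <- scale(t(unclass(ratings)))  # objects x synergies, standardised
      idx <- sample(ncol(k), n_features, replace = TRUE)
      feats <- sqrt(1 - mix^2) * feats + mix * k[, idx]
    }
    dimnames(feats) <- list(object_ids,
                            sprintf("feat%03d", seq_len(n_features)))
    list(features = feats, rsm = visual_model_rsm(feats))
  })
}

# Smooth K stacked white-noise volumes (grid x K matrix of full-grid
# voxel values) with a separable Gaussian, then rescale to unit marginal
# sd using the empirical global sd. Returns a matrix of the same shape.
smooth_noise_stack <- function(noise, grid_shape, sigma_vox) {
  k <- gaussian_kernel_1d(sigma_vox)
  if (length(k) == 1L) return(noise)
  d <- c(grid_shape, ncol(noise))
  v <- array(noise, d)
  conv4 <- function(v, axis) {
    perm <- switch(axis, c(1L, 2L, 3L, 4L), c(2L, 1L, 3L, 4L),
                   c(3L, 1L, 2L, 4L))
    vp <- aperm(v, perm)
    m <- matrix(vp, nrow = dim(vp)[1])
    n <- nrow(m)
    half <- (length(k) - 1L) %/% 2L
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    aperm(array(out, dim(vp)), order(perm))
  }
  for (ax in 1:3) v <- conv4(v, ax)
  m <- matrix(v, ncol = ncol(noise))
  m / sd(m)
}

# Chebyshev (box) dilation of a logical mask by `r` voxels.
dilate_mask <- function(mask, r) {
  v <- array(as.numeric(mask), dim(mask))
  k <- rep(1, 2L * r + 1L)
  for (ax in 1:3) v <- convolve_axis(v, k, ax)
  v > 1e-9
}

# Disjoint planted regions: each region claims the nearest unassigned
# in-mask voxels to a deterministic per-region centre.
assign_regions <- function(mask, region_fractions, grid_shape) {
  idx <- which(mask)
  coords <- arrayInd(idx, dim(mask))
  ctr <- (grid_shape + 1) / 2
  q <- grid_shape / 4
  centres <- list(kinematic = ctr + c(-q[1], 0, 0),
                  visual = ctr + c(q[1], 0, 0),
                  centrality = ctr + c(0, q[2], 0))
  taken <- rep(FALSE, length(idx))
  masks <- list()
  for (lab in names(region_fractions)) {
    n_take <- round(region_fractions[[lab]] * length(idx))
    cen <- centres[[lab]]
    if (is.null(cen)) cen <- ctr + c(0, -q[2], 0)
    d2 <- colSums((t(coords) - cen)^2)
    ord <- order(d2, seq_along(d2))
    pick <- ord[!taken[ord]][seq_len(n_take)]
    taken[pick] <- TRUE
    m <- array(FALSE, grid_shape)
    m[idx[pick]] <- TRUE
    masks[[lab]] <- m
  }
  null_mask <- array(FALSE, grid_shape)
  null_mask[idx[!taken]] <- TRUE
  masks$null <- null_mask
  masks
}

#' Generate a multi-subject beta-volume cohort with planted ground truth
#'
#' In the kinematic region, object `o`'s noiseless signal at voxel `v` is
#' `effect_scale * sum_i pattern_i(v) * loading(i, o)`; in the visual
#' region it is a linear function of the object's visual features; in the
#' centrality region the amplitude is proportional to the object's
#' (z-scored) centrality score. Independent Gaussian noise of sd
#' `noise_sd` is added per subject, with a per-subject signal-scale jitter
#' of +/-10%. Synergy spatial patterns are smoothed Gaussian random fields
#' mean-centred per voxel across synergies, then scaled so the planted
#' kinematic signal has unit average across-object sd at `effect_scale =
#' 1` (and the visual signal likewise), making `noise_sd` interpretable as
#' a noise-to-signal ratio.
#'
#' @param cfg a [synth_config()].
#' @param ratings a [rating_matrix()] with `cfg$n_objects` columns.
#' @param visual_features objects x features matrix (e.g. from
#'   [generate_visual_features()]).
#' @param seed integer; defaults to `cfg$seed + 2`.
#' @return list with `cohort` (a `beta_cohort`) and `truth` (a
#'   `ground_truth`: region masks, synergy patterns, visual weights,
#'   centrality/familiarity scores, and the noiseless signal matrix).
#' @export
generate_cohort <- function(cfg, ratings, visual_features,
                            seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "synth_config"))
  loads <- unclass(ratings)
  if (ncol(loads) != cfg$n_objects || nrow(loads) != cfg$n_synergies)
    stop("dimension-mismatch: ratings do not match cfg synergy/object counts")
  if (nrow(visual_features) != cfg$n_objects)
    stop("dimension-mismatch: visual_features rows must match cfg$n_objects")
  mask <- make_brain_mask(cfg$grid_shape)
  regions <- assign_regions(mask, cfg$region_fractions, cfg$grid_shape)
  mask_idx <- which(mask)
  pos <- function(m) match(which(m), mask_idx)
  kin_pos <- pos(regions$kinematic)
  vis_pos <- pos(regions$visual)
  cen_pos <- pos(regions$centrality)
  n_vox <- length(mask_idx)
  no <- cfg$n_objects; ns <- cfg$n_synergies
  object_ids <- colnames(loads)
  subject_ids <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  with_seed(seed, {
    # kinematic region: smoothed random-field pattern per synergy
    patterns <- matrix(0, length(kin_pos), ns)
    for (s in seq_len(ns)) {
      v <- array(0, cfg$grid_shape)
      v[regions$kinematic] <- rnorm(length(kin_pos))
      v <- smooth_volume(v, fwhm_mm = 2 * cfg$voxel_size_mm,
                         voxel_size_mm = cfg$voxel_size_mm,
                         mask = regions$kinematic)
      patterns[, s] <- v[regions$kinematic]
    }
    patterns <- patterns - rowMeans(patterns)  # centre across synergies
    kin_signal <- patterns %*% loads           # kin voxels x objects
    sd_k <- mean(apply(kin_signal, 1, sd))
    if (sd_k > 0) {
      patterns <- patterns / sd_k
      kin_signal <- kin_signal / sd_k
    }
    # visual region: linear in the supplied features
    vis_w <- matrix(rnorm(ncol(visual_features) * length(vis_pos)),
                    ncol(visual_features), length(vis_pos))
    vis_signal <- t(visual_features %*% vis_w)  # vis voxels x objects
    sd_v <- mean(apply(vis_signal, 1, sd))
    if (sd_v > 0) {
      vis_w <- vis_w / sd_v
      vis_signal <- vis_signal / sd_v
    }
    # centrality region: amplitude proportional to z-scored 1-5 ratings
    centrality_raw <- runif(no, 1, 5)
    centrality <- as.numeric(scale(centrality_raw))
    # familiarity is decorrelated from centrality by construction so the
    # planted centrality/familiarity dissociation is identifiable
    familiarity_raw <- runif(no, 1, 5)
    familiarity <- stats::residuals(stats::lm(familiarity_raw ~ centrality))
    familiarity <- as.numeric(scale(familiarity))
    gain <- runif(length(cen_pos), 0.5, 1.5)
    cen_signal <- outer(gain, centrality)       # cen voxels x objects
    signal <- matrix(0, no, n_vox)
    signal[, kin_pos] <- t(kin_signal)
    signal[, vis_pos] <- t(vis_signal)
    signal[, cen_pos] <- t(cen_signal)
    signal <- cfg$effect_scale * signal
    betas <- vector("list", cfg$n_subjects)
    names(betas) <- subject_ids
    sigma_vox <- cfg$noise_fwhm_mm / (2 * sqrt(2 * log(2))) / cfg$voxel_size_mm
    n_grid <- prod(cfg$grid_shape)
    for (j in seq_len(cfg$n_subjects)) {
      subj_scale <- 1 + runif(1, -0.1, 0.1)
      noise <- matrix(rnorm(n_grid * no), n_grid, no)
      if (sigma_vox > 0)
        noise <- smooth_noise_stack(noise, cfg$grid_shape, sigma_vox)
      b <- subj_scale * signal + cfg$noise_sd * t(noise[mask_idx, , drop = FALSE])
      dimnames(b) <- list(object_ids, NULL)
      betas[[j]] <- b
    }
    cohort <- structure(list(
      betas = betas, mask = mask, grid_shape = cfg$grid_shape,
      voxel_size_mm = cfg$voxel_size_mm,
      object_ids = object_ids, subject_ids = subject_ids
    ), class = "beta_cohort")
    names(centrality) <- names(familiarity) <- object_ids
    # strict null: null voxels beyond smoothing reach of any planted
    # signal (4-voxel box dilation covers a 6 mm FWHM kernel's support),
    # the evaluation mask for false-positive checks under smoothing
    signal_any <- regions$kinematic | regions$visual | regions$centrality
    null_strict <- regions$null & !dilate_mask(signal_any, 4L)
    truth <- structure(list(
      region_masks = regions, null_strict = null_strict,
      synergy_patterns = patterns,
      visual_weights = vis_w, centrality_scores = centrality,
      centrality_raw = setNames(centrality_raw, object_ids),
      familiarity_scores = familiarity,
      familiarity_raw = setNames(familiarity_raw, object_ids),
      centrality_gain = gain, signal = signal
    ), class = "ground_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' @export
print.beta_cohort <- function(x, ...) {
  cat(sprintf("beta_cohort: %d subjects x %d objects, grid %s, %d in-mask voxels\n",
              length(x$subject_ids), length(x$object_ids),
              paste(x$grid_shape, collapse = "x"), sum(x$mask)))
  invisible(x)
}
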