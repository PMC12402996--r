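# Rating-weighted leave-one-out encoding model. For each held-out object
# t: (step 1) per synergy, a whole-brain contrast map is built from the
# remaining objects rated high (> 0.75) vs low (< 0.25) on that synergy;
# (step 2) t's activity is predicted voxelwise as the sum of those synergy
# maps weighted by t's own loadings. Predictions are scored per voxel by
# the across-object correlation with the observed betas (univariate RSA).

high_low_sets <- function(loads_s, left_out, object_ids) {
  keep <- setdiff(object_ids, left_out)
  list(high = keep[loads_s[keep] > 0.75],
       low = keep[loads_s[keep] < 0.25])
}

#' Build one synergy's contrast map with the target object held out
#'
#' High objects are those (excluding the held-out object) whose group
#' loading on the synergy is strictly above 0.75; low objects strictly
#' below 0.25. The map is the average over all (high, low) pairs of the
#' pairwise volume differences -- algebraically, `mean(high volumes) -
#' mean(low volumes)`. If either set is empty the map is absent (`NULL`),
#' a modelled outcome rather than an error.
#'
#' @param betas objects x voxels matrix for one subject (rows named by
#'   object id).
#' @param ratings a [rating_matrix()].
#' @param synergy synergy id (row of `ratings`).
#' @param left_out id of the to-be-predicted object, excluded from both
#'   sets.
#' @return numeric voxel vector with attributes `high`/`low` (the object
#'   lists used), or `NULL` if the synergy map is absent.
#' @export
build_synergy_map <- function(betas, ratings, synergy, left_out) {
  stopifnot(left_out %in% rownames(betas))
  loads_s <- unclass(ratings)[synergy, ]
  hl <- high_low_sets(loads_s, left_out, rownames(betas))
  if (length(hl$high) == 0L || length(hl$low) == 0L) return(NULL)
  map <- colMeans(betas[hl$high, , drop = FALSE]) -
    colMeans(betas[hl$low, , drop = FALSE])
  attr(map, "high") <- hl$high
  attr(map, "low") <- hl$low
  map
}

#' Predict a held-out object's voxel activity from its synergy maps
#'
#' `y_v = sum_i s_vi * k_i(t)`: the synergy maps weighted by the held-out
#' object's loadings and summed, with absent maps contributing zero. The
#' weights are used exactly as given (no renormalisation) unless
#' `normalize_weights` is set, which rescales the present synergies'
#' weights to sum to one (sensitivity analysis only).
#'
#' @param maps list of voxel vectors (or `NULL` for absent), one per
#'   synergy, as from [build_synergy_map()].
#' @param k numeric loading vector for the held-out object, aligned with
#'   `maps`.
#' @param normalize_weights logical; default `FALSE`.
#' @return numeric voxel vector.
#' @export
predict_object <- function(maps, k, normalize_weights = FALSE) {
  stopifnot(length(maps) == length(k))
  present <- !vapply(maps, is.null, TRUE)
  if (!any(present)) stop("empty-model: all synergy maps are absent")
  w <- k
  if (normalize_weights && sum(k[present]) > 0)
    w <- k / sum(k[present])
  y <- numeric(length(maps[[which(present)[1]]]))
  for (i in which(present)) y <- y + w[i] * maps[[i]]
  as.numeric(y)
}

#' Run the full leave-one-out encoding model over a cohort
#'
#' For every subject and every object t, executes step 1 (synergy contrast
#' maps with t excluded) and step 2 (rating-weighted linear prediction of
#' t), i.e. one fold per object. The prediction for t never touches t's
#' observed volumes. Internally each fold reduces to a single weight
#' vector over training objects (the algebraic collapse of
#' mean(high) - mean(low) summed over synergies), shared across subjects.
#'
#' @param cohort a `beta_cohort`.
#' @param ratings a [rating_matrix()] covering the cohort's objects.
#' @param normalize_weights passed to the per-fold prediction.
#' @return object of class `prediction_result`: per-subject predicted
#'   objects x voxels matrices, per-fold skipped (absent) synergies, and
#'   any invalid folds (all synergies absent).
#' @export
run_encoding_model <- function(cohort, ratings, normalize_weights = FALSE) {
  stopifnot(inherits(cohort, "beta_cohort"))
  loads <- unclass(ratings)
  object_ids <- cohort$object_ids
  if (!all(object_ids %in% colnames(loads)))
    stop("dimension-mismatch: ratings missing cohort objects")
  if (length(object_ids) < 3L)
    stop("need at least 3 objects for held-out high/low contrasts")
  loads <- loads[, object_ids, drop = FALSE]
  n_obj <- length(object_ids)
  syn_ids <- rownames(loads)
  # fold weight matrix: W[t, o] such that prediction(t) = W[t, ] %*% betas
  W <- matrix(0, n_obj, n_obj, dimnames = list(object_ids, object_ids))
  skipped <- stats::setNames(vector("list", n_obj), object_ids)
  invalid <- character(0)
  for (t in object_ids) {
    k <- loads[, t]
    any_present <- FALSE
    skip_t <- character(0)
    w_row <- stats::setNames(numeric(n_obj), object_ids)
    present_sum <- 0
    contribs <- list()
    for (s in syn_ids) {
      hl <- high_low_sets(loads[s, ], t, object_ids)
      if (length(hl$high) == 0L || length(hl$low) == 0L) {
        skip_t <- c(skip_t, s)
        next
      }
      any_present <- TRUE
      present_sum <- present_sum + k[s]
      v <- stats::setNames(numeric(n_obj), object_ids)
      v[hl$high] <- 1 / length(hl$high)
      v[hl$low] <- -1 / length(hl$low)
      contribs[[s]] <- v
    }
    skipped[[t]] <- skip_t
    if (!any_present) {
      invalid <- c(invalid, t)
      next
    }
    for (s in names(contribs)) {
      w_s <- if (normalize_weights && present_sum > 0) k[s] / present_sum else k[s]
      w_row <- w_row + w_s * contribs[[s]]
    }
    W[t, ] <- w_row
  }
  predicted <- lapply(cohort$betas, function(b) {
    p <- W %*% b[object_ids, , drop = FALSE]
    rownames(p) <- object_ids
    p
  })
  structure(list(predicted = predicted, skipped_synergies = skipped,
                 invalid_folds = invalid, object_ids = object_ids,
                 subject_ids = cohort$subject_ids,
                 normalize_weights = normalize_weights,
                 n_folds = n_obj),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: %d subjects x %d folds; %d invalid fold(s)\n",
              length(x$predicted), x$n_folds, length(x$invalid_folds)))
  invisible(x)
}

# column-wise Pearson r between two matrices over rows
colwise_cor <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- rep(NA_real_, ncol(a))
  ok <- den > 0
  out[ok] <- pmin(1, pmax(-1, num[ok] / den[ok]))
  out
}

#' Fisher z transform with clipping
#'
#' `atanh` of r clamped to +/-(1 - 1e-7) so that perfect correlations map
#' to finite statistics; `NA` (invalid) values propagate.
#'
#' @param r numeric vector/array of correlations in `[-1, 1]`.
#' @return same shape, Fisher z values.
#' @export
fisher_z <- function(r) {
  atanh(pmax(pmin(r, 1 - 1e-7), -(1 - 1e-7)))
}

#' Score predictions voxelwise against observed betas (univariate RSA)
#'
#' At each in-mask voxel and for each subject, the Pearson correlation
#' across objects between observed and predicted activation. Voxels where
#' either vector has zero variance are flagged invalid (`NA`), not zeroed.
#'
#' @param cohort the `beta_cohort` that was modelled.
#' @param preds a `prediction_result` from [run_encoding_model()].
#' @return object of class `score_maps`: matrices `r` and `z`
#'   (subjects x in-mask voxels), a `valid` logical matrix, and grid
#'   metadata.
#' @export
univariate_rsa_score <- function(cohort, preds) {
  stopifnot(inherits(cohort, "beta_cohort"), inherits(preds, "prediction_result"))
  if (!setequal(cohort$object_ids, preds$object_ids))
    stop("dimension-mismatch: cohorts and predictions cover different objects")
  valid_objs <- setdiff(preds$object_ids, preds$invalid_folds)
  if (length(valid_objs) < 3L)
    stop("invalid-score: fewer than 3 valid folds")
  n_sub <- length(cohort$subject_ids)
  n_vox <- sum(cohort$mask)
  r <- matrix(NA_real_, n_sub, n_vox, dimnames = list(cohort$subject_ids, NULL))
  for (j in seq_len(n_sub)) {
    obs <- cohort$betas[[j]][valid_objs, , drop = FALSE]
    prd <- preds$predicted[[j]][valid_objs, , drop = FALSE]
    r[j, ] <- colwise_cor(obs, prd)
  }
  structure(list(r = r, z = fisher_z(r), valid = !is.na(r),
                 mask = cohort$mask, grid_shape = cohort$grid_shape,
                 voxel_size_mm = cohort$voxel_size_mm,
                 subject_ids = cohort$subject_ids,
                 statistic = "univariate_rsa_r"),
            class = "score_maps")
}

#' @export
print.score_maps <- function(x, ...) {
  cat(sprintf("score_maps (%s): %d subjects x %d in-mask voxels\n",
              x$statistic, nrow(x$r), ncol(x$r)))
  invisible(x)
}
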