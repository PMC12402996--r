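# Behavioural-amplitude correlation maps: voxelwise correlation, across
# objects, between response amplitude and a per-object behavioural score
# (centrality of manipulation, familiarity). Feeds group inference.

#' Voxelwise amplitude-score correlation maps
#'
#' For each subject and each in-mask voxel, the Pearson correlation across
#' objects between the beta amplitudes and the behavioural score. Scores
#' are z-scored before correlating (the r map is invariant to affine
#' rescaling of the scores in any case). Voxels with zero beta variance
#' are flagged invalid.
#'
#' @param cohort a `beta_cohort`.
#' @param scores named numeric vector, one value per cohort object.
#' @return a `score_maps` object (per-subject r and Fisher z).
#' @export
amplitude_correlation_map <- function(cohort, scores) {
  stopifnot(inherits(cohort, "beta_cohort"))
  ids <- cohort$object_ids
  if (!all(ids %in% names(scores)))
    stop("invalid-input: scores missing for some objects")
  s <- scores[ids]
  if (sd(s) == 0)
    stop("undefined-correlation: scores are constant across objects")
  s <- as.numeric(scale(s))
  n_sub <- length(cohort$subject_ids)
  n_vox <- sum(cohort$mask)
  s_mat <- matrix(s, length(ids), n_vox)
  r <- matrix(NA_real_, n_sub, n_vox,
              dimnames = list(cohort$subject_ids, NULL))
  for (j in seq_len(n_sub)) {
    r[j, ] <- colwise_cor(cohort$betas[[j]][ids, , drop = FALSE], s_mat)
  }
  structure(list(r = r, z = fisher_z(r), valid = !is.na(r),
                 mask = cohort$mask, grid_shape = cohort$grid_shape,
                 voxel_size_mm = cohort$voxel_size_mm,
                 subject_ids = cohort$subject_ids,
                 statistic = "amplitude_r"),
            class = "score_maps")
}
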