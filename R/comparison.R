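# Head-to-head model comparison within ROIs: per-subject ROI-mean r^2 per
# model, the Model Performance Contrast (M1 - M2)/(M1 + M2), planned
# per-ROI one-sample tests with Bonferroni adjustment and Cohen's d, and
# a permutation ANOVA for the ROI x Model interaction.

#' Visual-model similarity matrix from a feature matrix
#'
#' Pairwise Pearson correlation between object feature vectors (e.g. CNN
#' layer activations). A dissimilarity [sim_matrix()] passed instead of
#' features is converted to a similarity matrix (`1 - d`) and returned.
#'
#' @param features objects x features matrix, rows named by object id, or
#'   a `sim_matrix` to pass through.
#' @return a similarity [sim_matrix()].
#' @export
visual_model_rsm <- function(features) {
  if (inherits(features, "sim_matrix")) {
    if (attr(features, "mode") == "dissimilarity") return(sim_convert(features))
    return(features)
  }
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  r <- row_cor(features)
  dimnames(r) <- list(rownames(features), rownames(features))
  sim_matrix(r, mode = "similarity")
}

#' ROI-mean squared model performance per subject and model
#'
#' For each subject, model, and ROI: the mean of r^2 over the ROI's valid
#' in-mask voxels of that model's score map. ROIs with no valid voxel for
#' a subject yield `NA` with a warning.
#'
#' @param score_list named list of `score_maps`, one per model, sharing
#'   the grid.
#' @param rois named list of logical 3-D ROI masks within the brain mask.
#' @return data frame of class `model_scores` with columns `subject`,
#'   `model`, `roi`, `r2`.
#' @export
roi_scores <- function(score_list, rois) {
  stopifnot(length(names(score_list)) == length(score_list),
            length(names(rois)) == length(rois))
  out <- list()
  any_missing <- FALSE
  for (mod in names(score_list)) {
    sc <- score_list[[mod]]
    stopifnot(inherits(sc, "score_maps"))
    for (roi in names(rois)) {
      stopifnot(identical(dim(rois[[roi]]), dim(sc$mask)))
      in_roi <- rois[[roi]][sc$mask]
      if (!any(in_roi)) stop("ROI outside brain mask: ", roi)
      for (j in seq_len(nrow(sc$r))) {
        v <- sc$r[j, in_roi]
        v <- v[!is.na(v)]
        r2 <- if (length(v) == 0L) {
          any_missing <- TRUE
          NA_real_
        } else mean(v^2)
        out[[length(out) + 1L]] <- data.frame(
          subject = sc$subject_ids[j], model = mod, roi = roi, r2 = r2)
      }
    }
  }
  if (any_missing)
    warning("some subject/ROI cells had no valid voxels; entries are NA")
  structure(do.call(rbind, out), class = c("model_scores", "data.frame"))
}

#' Model Performance Contrast
#'
#' `(m1 - m2) / (m1 + m2)` for nonnegative performance scores; lies in
#' `[-1, 1]` and is antisymmetric in its arguments.
#'
#' @param m1,m2 nonnegative numeric vectors (e.g. ROI-mean r^2).
#' @return numeric vector of contrasts.
#' @export
performance_contrast <- function(m1, m2) {
  stopifnot(all(m1 >= 0, na.rm = TRUE), all(m2 >= 0, na.rm = TRUE))
  s <- m1 + m2
  if (any(s == 0, na.rm = TRUE))
    stop("undefined-contrast: both models scored 0")
  (m1 - m2) / s
}

scores_cube <- function(scores) {
  stopifnot(inherits(scores, "model_scores"))
  subjects <- unique(scores$subject)
  models <- unique(scores$model)
  rois <- unique(scores$roi)
  y <- array(NA_real_, c(length(subjects), length(rois), length(models)),
             dimnames = list(subjects, rois, models))
  y[cbind(match(scores$subject, subjects), match(scores$roi, rois),
          match(scores$model, models))] <- scores$r2
  if (anyNA(y)) {
    keep <- apply(y, 1, function(m) !anyNA(m))
    y <- y[keep, , , drop = FALSE]
    if (dim(y)[1] < 2L) stop("fewer than 2 complete subjects")
  }
  y
}

interaction_F <- function(y) {
  s <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  g <- mean(y)
  m_ab <- apply(y, c(2, 3), mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_s <- apply(y, 1, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  dev_ab <- sweep(sweep(m_ab, 1, m_a), 2, m_b) + g
  ss_ab <- s * sum(dev_ab^2)
  resid <- y
  for (i in seq_len(s)) for (j in seq_len(a)) for (k in seq_len(b)) {
    resid[i, j, k] <- y[i, j, k] - m_ab[j, k] - m_sa[i, j] - m_sb[i, k] +
      m_a[j] + m_b[k] + m_s[i] - g
  }
  ss_err <- sum(resid^2)
  df_ab <- (a - 1) * (b - 1)
  df_err <- (a - 1) * (b - 1) * (s - 1)
  f <- (ss_ab / df_ab) / (ss_err / df_err)
  list(F = f, df1 = df_ab, df2 = df_err)
}

#' Permutation ANOVA for the ROI x Model interaction
#'
#' Computes the repeated-measures interaction F (ROI x Model, subject as
#' block, one observation per cell) and a permutation p-value obtained by
#' shuffling the model labels within each subject (consistently across
#' ROIs, preserving subject and ROI marginals).
#'
#' @param scores a `model_scores` data frame from [roi_scores()];
#'   subjects with any missing cell are dropped listwise.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `F`, `df1`, `df2`, `p_value`, and the null `F` draws.
#' @export
permutation_anova <- function(scores, n_perm = 1000L, seed = 1L) {
  y <- scores_cube(scores)
  obs <- interaction_F(y)
  b <- dim(y)[3]
  null_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- y
      for (s in seq_len(dim(y)[1])) {
        yp[s, , ] <- y[s, , sample(b)]
      }
      interaction_F(yp)$F
    }, 0)
  })
  p <- (1 + sum(null_f >= obs$F)) / (n_perm + 1)
  c(obs, list(p_value = p, null = null_f, n_perm = n_perm))
}

#' Planned per-ROI contrast tests of two models
#'
#' For each ROI, computes the per-subject Model Performance Contrast of
#' `model1` vs `model2`, a two-tailed one-sample t test against zero with
#' Bonferroni adjustment over ROIs, and Cohen's d over subjects.
#'
#' @param scores a `model_scores` data frame.
#' @param model1,model2 model names present in `scores`.
#' @return data frame with per-ROI mean contrast, t, df, raw and
#'   Bonferroni-adjusted p, and Cohen's d.
#' @export
roi_contrast_tests <- function(scores, model1, model2) {
  y <- scores_cube(scores)
  stopifnot(model1 %in% dimnames(y)[[3]], model2 %in% dimnames(y)[[3]])
  rois <- dimnames(y)[[2]]
  res <- lapply(rois, function(roi) {
    con <- performance_contrast(y[, roi, model1], y[, roi, model2])
    tt <- stats::t.test(con, mu = 0)
    data.frame(roi = roi, mean_contrast = mean(con),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = mean(con) / sd(con))
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}
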