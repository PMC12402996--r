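# Readers/writers and the pipeline driver. Volumes go to single-file
# NIfTI with a JSON sidecar manifest; ratings, features and scores are
# comma-delimited text with header rows; configs are YAML; trees are
# Newick.

#' Write a rating or feature matrix as CSV
#'
#' Rows are synergies/features, columns are object ids; the first column
#' holds the row ids under the header `id`.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_ratings_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a rating matrix written by [write_ratings_csv()]
#' @param path CSV path.
#' @return a [rating_matrix()].
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  rating_matrix(m)
}

#' Read per-object scores from two-column CSV (`object_id`, `value`)
#' @param path CSV path.
#' @return named numeric vector.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write a beta cohort to a directory
#'
#' One NIfTI volume per (subject, object) plus `mask.nii` and a JSON
#' manifest recording the grid, ids and file names.
#'
#' @param cohort a `beta_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "beta_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(array(as.numeric(cohort$mask), dim(cohort$mask)),
              file.path(dir, "mask.nii"), cohort$voxel_size_mm)
  files <- list()
  for (sub in cohort$subject_ids) {
    for (obj in cohort$object_ids) {
      fn <- sprintf("beta_%s_%s.nii", sub, obj)
      vol <- unmask(cohort$betas[[sub]][obj, ], cohort$mask, fill = 0)
      write_nifti(vol, file.path(dir, fn), cohort$voxel_size_mm,
                  datatype = "float64")
      files[[length(files) + 1L]] <- list(subject = sub, object = obj,
                                          file = fn)
    }
  }
  manifest <- list(grid_shape = cohort$grid_shape,
                   voxel_size_mm = cohort$voxel_size_mm,
                   subject_ids = cohort$subject_ids,
                   object_ids = cohort$object_ids,
                   mask_file = "mask.nii", volumes = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a beta cohort directory written by [write_cohort()]
#'
#' Validates the shared grid and the subjects x objects inventory; a
#' missing (subject, object) volume raises an error naming the gap.
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a `beta_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  grid <- as.integer(mf$grid_shape)
  msk <- read_nifti(file.path(dir, mf$mask_file))
  if (!identical(as.integer(msk$dim), grid))
    stop("grid mismatch between manifest and mask volume")
  mask <- array(msk$data > 0.5, grid)
  subs <- mf$subject_ids
  objs <- mf$object_ids
  vols <- mf$volumes
  key <- paste(vols$subject, vols$object)
  want <- as.vector(outer(subs, objs, paste))
  missing <- setdiff(want, key)
  if (length(missing) > 0L)
    stop("cohort inventory gap: missing volume(s) for ", paste(missing, collapse = "; "))
  betas <- list()
  for (sub in subs) {
    b <- matrix(NA_real_, length(objs), sum(mask),
                dimnames = list(objs, NULL))
    for (obj in objs) {
      fn <- vols$file[vols$subject == sub & vols$object == obj][1]
      v <- read_nifti(file.path(dir, fn))
      if (!identical(as.integer(v$dim), grid))
        stop("grid mismatch in ", fn)
      b[obj, ] <- v$data[mask]
    }
    betas[[sub]] <- b
  }
  structure(list(betas = betas, mask = mask, grid_shape = grid,
                 voxel_size_mm = mf$voxel_size_mm,
                 object_ids = objs, subject_ids = subs),
            class = "beta_cohort")
}

#' Write per-subject score maps as NIfTI volumes
#' @param scores a `score_maps`.
#' @param dir output directory.
#' @param what `"r"` or `"z"`.
#' @export
write_score_maps <- function(scores, dir, what = c("r", "z")) {
  what <- match.arg(what)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_len(nrow(scores[[what]]))) {
    vol <- unmask(scores[[what]][j, ], scores$mask, fill = 0)
    vol[is.na(vol)] <- 0
    write_nifti(vol, file.path(dir, sprintf("%s_%s.nii", what,
                                            scores$subject_ids[j])),
                scores$voxel_size_mm)
  }
  invisible(dir)
}

#' Load a pipeline configuration from YAML
#'
#' Missing fields fall back to [synth_config()] defaults plus
#' `n_perm = 500`, `alpha = 0.05`, `fwhm_mm = 6`, all stage toggles on.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  base <- list(seed = 1L, n_synergies = 54L, n_objects = 33L,
               n_raters = 87L, n_subjects = 25L,
               grid_shape = c(24L, 24L, 24L), voxel_size_mm = 3,
               noise_sd = 1, noise_fwhm_mm = 6, effect_scale = 1,
               n_perm = 500L, alpha = 0.05, fwhm_mm = 6,
               radius = 3, min_voxels = 10L,
               stages = list(space = TRUE, encode = TRUE,
                             searchlight = TRUE, group = TRUE,
                             compare = TRUE, amplitude = TRUE))
  cfg <- utils::modifyList(base, user)
  for (k in c("seed", "n_synergies", "n_objects", "n_raters", "n_subjects",
              "grid_shape", "n_perm", "min_voxels"))
    cfg[[k]] <- as.integer(cfg[[k]])
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cohort, then executes the toggled stages -- kinematic
#' space (RDM, dendrogram, entanglement vs a re-clustered copy),
#' encoding model + univariate RSA + TFCE group correction, searchlight
#' RSA, ROI model comparison, and amplitude maps -- writing volumes,
#' tables, a Newick tree and a JSON provenance/summary report under
#' `out_dir`.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param out_dir output directory.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg <- synth_config(n_synergies = config$n_synergies,
                      n_objects = config$n_objects,
                      n_raters = config$n_raters,
                      n_subjects = config$n_subjects,
                      grid_shape = config$grid_shape,
                      voxel_size_mm = config$voxel_size_mm,
                      noise_sd = config$noise_sd,
                      noise_fwhm_mm = config$noise_fwhm_mm,
                      effect_scale = config$effect_scale,
                      seed = config$seed)
  summary <- list(seed = config$seed, stages_run = character(0),
                  stages_skipped = character(0))
  note("simulate", "generating ratings, features and cohort")
  rat <- stage_wrap("simulate", generate_ratings(cfg))
  feats <- stage_wrap("simulate", generate_visual_features(cfg))
  gen <- stage_wrap("simulate", generate_cohort(cfg, rat$ratings, feats$features))
  cohort <- gen$cohort
  truth <- gen$truth
  write_ratings_csv(rat$ratings, file.path(out_dir, "ratings.csv"))
  write_ratings_csv(t(feats$features), file.path(out_dir, "visual_features.csv"))
  summary$stages_run <- c(summary$stages_run, "simulate")
  kin_rsm <- sim_convert(compute_rdm(rat$ratings))

  if (isTRUE(config$stages$space)) {
    note("space", "RDM, dendrogram, entanglement permutation test")
    stage_wrap("space", {
      rdm <- compute_rdm(rat$ratings)
      dend <- build_dendrogram(rdm)
      write_newick(dend, file.path(out_dir, "kinematic_dendrogram.nwk"))
      dend2 <- build_dendrogram(compute_rdm(rat$ratings))
      ent <- entanglement_permutation_test(dend, dend2, n_perm = 999L,
                                           seed = config$seed)
      summary$entanglement <- ent$observed
      summary$entanglement_p <- ent$p_value
    })
    summary$stages_run <- c(summary$stages_run, "space")
  } else summary$stages_skipped <- c(summary$stages_skipped, "space")

  scores_kin <- NULL
  if (isTRUE(config$stages$encode)) {
    note("encode", sprintf("leave-one-out encoding model, %d folds",
                           cfg$n_objects))
    stage_wrap("encode", {
      preds <- run_encoding_model(cohort, rat$ratings)
      scores_kin <- smooth_score_maps(
        univariate_rsa_score(cohort, preds), config$fwhm_mm)
      summary$invalid_folds <- length(preds$invalid_folds)
    })
    summary$stages_run <- c(summary$stages_run, "encode")
  } else summary$stages_skipped <- c(summary$stages_skipped, "encode")

  if (isTRUE(config$stages$group) && !is.null(scores_kin)) {
    note("group", sprintf("TFCE sign-flip correction, %d permutations",
                          config$n_perm))
    stage_wrap("group", {
      sm <- permutation_correct(scores_kin, n_perm = config$n_perm,
                                seed = config$seed + 10L,
                                alpha = config$alpha)
      vol <- unmask(sm$tfce, sm$mask, fill = 0)
      vol[is.na(vol)] <- 0
      write_nifti(vol, file.path(out_dir, "encoding_tfce.nii"),
                  config$voxel_size_mm)
      kin_mask <- truth$region_masks$kinematic[cohort$mask]
      summary$n_significant <- sum(sm$significant, na.rm = TRUE)
      summary$kinematic_region_hit_rate <-
        mean(sm$significant[kin_mask], na.rm = TRUE)
    })
    summary$stages_run <- c(summary$stages_run, "group")
  } else if (!isTRUE(config$stages$group))
    summary$stages_skipped <- c(summary$stages_skipped, "group")

  scores_vis <- NULL
  if (isTRUE(config$stages$searchlight)) {
    note("searchlight", "kinematic and visual model searchlights")
    stage_wrap("searchlight", {
      spec <- searchlight_spec(radius = config$radius,
                               min_voxels = config$min_voxels)
      sl_kin <- searchlight_map(cohort, kin_rsm, spec)
      scores_vis <- searchlight_map(cohort, feats$rsm, spec)
      write_score_maps(sl_kin, file.path(out_dir, "searchlight_kinematic"))
      write_score_maps(scores_vis, file.path(out_dir, "searchlight_visual"))
      summary$searchlight_mean_r <- mean(sl_kin$r, na.rm = TRUE)
    })
    summary$stages_run <- c(summary$stages_run, "searchlight")
  } else summary$stages_skipped <- c(summary$stages_skipped, "searchlight")

  if (isTRUE(config$stages$compare) && !is.null(scores_kin) &&
      !is.null(scores_vis)) {
    note("compare", "ROI model comparison and permutation ANOVA")
    stage_wrap("compare", {
      rois <- list(kinematic = truth$region_masks$kinematic,
                   visual = truth$region_masks$visual)
      sc <- roi_scores(list(kinematic = scores_kin, visual = scores_vis),
                       rois)
      utils::write.csv(sc, file.path(out_dir, "roi_scores.csv"),
                       row.names = FALSE)
      con <- roi_contrast_tests(sc, "kinematic", "visual")
      utils::write.csv(con, file.path(out_dir, "roi_contrasts.csv"),
                       row.names = FALSE)
      an <- permutation_anova(sc, n_perm = min(1000L, config$n_perm),
                              seed = config$seed + 20L)
      summary$anova_F <- an$F
      summary$anova_p <- an$p_value
    })
    summary$stages_run <- c(summary$stages_run, "compare")
  } else if (!isTRUE(config$stages$compare))
    summary$stages_skipped <- c(summary$stages_skipped, "compare")

  if (isTRUE(config$stages$amplitude)) {
    note("amplitude", "centrality and familiarity amplitude maps")
    stage_wrap("amplitude", {
      amp_c <- amplitude_correlation_map(cohort, truth$centrality_scores)
      amp_f <- amplitude_correlation_map(cohort, truth$familiarity_scores)
      cen_mask <- truth$region_masks$centrality[cohort$mask]
      summary$centrality_region_mean_r <-
        mean(colMeans(amp_c$r)[cen_mask], na.rm = TRUE)
      summary$familiarity_region_mean_r <-
        mean(colMeans(amp_f$r)[cen_mask], na.rm = TRUE)
    })
    summary$stages_run <- c(summary$stages_run, "amplitude")
  } else summary$stages_skipped <- c(summary$stages_skipped, "amplitude")

  summary$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  summary$config_hash <- digest_config(config)
  summary$r_version <- as.character(getRversion())
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  # cheap stable hash (sum of char codes mixed); provenance only
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}
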