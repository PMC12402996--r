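# Searchlight RSA: at every in-mask sphere centre, correlate the local
# neural object-by-object similarity matrix with a model similarity
# matrix over the strictly lower triangle.

#' Searchlight parameters
#'
#' @param radius sphere radius in voxel units (>= 1; default 3).
#' @param min_voxels minimum in-mask voxels a sphere needs (>= 3,
#'   default 10); centres below this are invalid.
#' @param comparison `"spearman"` (default, standard RSA practice) or
#'   `"pearson"` for the RSM-to-model correlation.
#' @return object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius = 3, min_voxels = 10L,
                             comparison = c("spearman", "pearson")) {
  comparison <- match.arg(comparison)
  if (radius < 1) stop("invalid-config: radius must be >= 1 voxel")
  if (min_voxels < 3L) stop("invalid-config: min_voxels must be >= 3")
  structure(list(radius = radius, min_voxels = as.integer(min_voxels),
                 comparison = comparison),
            class = "searchlight_spec")
}

# Pearson correlation between the rows of a matrix (objects x voxels).
row_cor <- function(p) {
  pc <- p - rowMeans(p)
  ss <- rowSums(pc^2)
  cp <- tcrossprod(pc)
  den <- sqrt(outer(ss, ss))
  r <- matrix(NA_real_, nrow(p), nrow(p))
  ok <- den > 0
  r[ok] <- cp[ok] / den[ok]
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Neural similarity matrix of a local voxel pattern
#'
#' Pairwise Pearson correlation between the objects' voxel-pattern
#' vectors; zero-variance patterns yield flagged (`NA`) pairs.
#'
#' @param patterns objects x voxels matrix (>= 3 objects, >= 2 voxels).
#' @return a similarity [sim_matrix()].
#' @export
neural_rsm <- function(patterns) {
  stopifnot(is.matrix(patterns), nrow(patterns) >= 3L, ncol(patterns) >= 2L)
  r <- row_cor(patterns)
  dimnames(r) <- list(rownames(patterns), rownames(patterns))
  diag(r) <- 1
  r[is.na(r)] <- NA_real_
  out <- structure(r, mode = "similarity", class = c("sim_matrix", "matrix"))
  out
}

# in-mask neighbour table: for each in-mask centre, the in-mask voxel
# positions within `radius`; NA-padded columns.
sphere_neighbours <- function(mask, radius) {
  dims <- dim(mask)
  idx <- which(mask)
  pos_lookup <- array(NA_integer_, dims)
  pos_lookup[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  rr <- floor(radius)
  offs <- as.matrix(expand.grid(dx = -rr:rr, dy = -rr:rr, dz = -rr:rr))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  n <- length(idx)
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    cc <- coords + matrix(offs[k, ], n, 3, byrow = TRUE)
    okc <- cc[, 1] >= 1 & cc[, 1] <= dims[1] &
      cc[, 2] >= 1 & cc[, 2] <= dims[2] &
      cc[, 3] >= 1 & cc[, 3] <= dims[3]
    lin <- rep(NA_integer_, n)
    lin[okc] <- cc[okc, 1] + dims[1] * (cc[okc, 2] - 1L) +
      dims[1] * dims[2] * (cc[okc, 3] - 1L)
    nb[, k] <- pos_lookup[ifelse(is.na(lin), 1L, lin)]
    nb[is.na(lin), k] <- NA_integer_
  }
  nb
}

searchlight_subject <- function(betas, model_lt, nb, spec) {
  n_ctr <- nrow(nb)
  out <- rep(NA_real_, n_ctr)
  rank_model <- if (spec$comparison == "spearman") rank(model_lt) else model_lt
  lt_idx <- lower.tri(diag(nrow(betas)))
  for (i in seq_len(n_ctr)) {
    cols <- nb[i, ]
    cols <- cols[!is.na(cols)]
    if (length(cols) < spec$min_voxels) next
    r <- row_cor(betas[, cols, drop = FALSE])
    lt <- r[lt_idx]
    ok <- !is.na(lt)
    if (sum(ok) < 3L) next
    a <- if (spec$comparison == "spearman") rank(lt[ok]) else lt[ok]
    b <- if (spec$comparison == "spearman" && !all(ok)) rank(model_lt[ok]) else rank_model[ok]
    if (sd(a) == 0 || sd(b) == 0) next
    out[i] <- cor(a, b)
  }
  out
}

#' Whole-brain searchlight RSA against a model similarity matrix
#'
#' At each in-mask centre with at least `min_voxels` in-sphere voxels, the
#' local neural RSM is computed from the subject's object patterns and its
#' strictly-lower-triangle vector is correlated (Spearman by default) with
#' the model RSM's. Centres failing `min_voxels` are invalid (`NA`).
#'
#' @param cohort a `beta_cohort`.
#' @param model_rsm a similarity [sim_matrix()] over the cohort's objects
#'   (an RDM is converted automatically, reversing its sign convention via
#'   `1 - d`).
#' @param spec a [searchlight_spec()].
#' @return a `score_maps` object (per-subject searchlight r and Fisher z).
#' @export
searchlight_map <- function(cohort, model_rsm, spec = searchlight_spec()) {
  stopifnot(inherits(cohort, "beta_cohort"), inherits(spec, "searchlight_spec"))
  if (inherits(model_rsm, "sim_matrix") &&
      attr(model_rsm, "mode") == "dissimilarity")
    model_rsm <- sim_convert(model_rsm)
  m <- unclass(model_rsm)
  ids <- cohort$object_ids
  if (!is.null(colnames(m))) {
    if (!all(ids %in% colnames(m)))
      stop("dimension-mismatch: model RSM missing cohort objects")
    m <- m[ids, ids]
  } else if (nrow(m) != length(ids)) {
    stop("dimension-mismatch: model RSM size != number of objects")
  }
  model_lt <- m[lower.tri(m)]
  if (sd(model_lt) == 0)
    stop("undefined-comparison: model RSM off-diagonal is constant")
  nb <- sphere_neighbours(cohort$mask, spec$radius)
  n_sub <- length(cohort$subject_ids)
  r <- matrix(NA_real_, n_sub, nrow(nb),
              dimnames = list(cohort$subject_ids, NULL))
  for (j in seq_len(n_sub)) {
    b <- cohort$betas[[j]][ids, , drop = FALSE]
    r[j, ] <- searchlight_subject(b, model_lt, nb, spec)
  }
  structure(list(r = r, z = fisher_z(r), valid = !is.na(r),
                 mask = cohort$mask, grid_shape = cohort$grid_shape,
                 voxel_size_mm = cohort$voxel_size_mm,
                 subject_ids = cohort$subject_ids,
                 statistic = paste0("searchlight_", spec$comparison, "_r"),
                 spec = spec),
            class = "score_maps")
}
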