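# Kinematic state space: aggregate binary rater votes into group loadings,
# select high-centrality objects, compute 1-r representational
# (dis)similarity matrices, cluster with Ward's criterion, and compare
# trees via entanglement with a label-shuffling permutation null.

#' Construct a rating matrix of group kinematic loadings
#'
#' @param loadings synergies x objects numeric matrix with entries in
#'   `[0, 1]` and unique dimnames.
#' @return object of class `rating_matrix`.
#' @export
rating_matrix <- function(loadings) {
  stopifnot(is.matrix(loadings))
  if (anyNA(loadings) || any(loadings < 0 | loadings > 1))
    stop("invalid-input: loadings must be in [0, 1] with no missing values")
  if (is.null(rownames(loadings)))
    rownames(loadings) <- sprintf("syn%02d", seq_len(nrow(loadings)))
  if (is.null(colnames(loadings)))
    colnames(loadings) <- sprintf("obj%02d", seq_len(ncol(loadings)))
  if (anyDuplicated(rownames(loadings)) || anyDuplicated(colnames(loadings)))
    stop("invalid-input: synergy and object ids must be unique")
  structure(loadings, class = c("rating_matrix", class(loadings)))
}

#' Aggregate per-rater binary votes into group loadings
#'
#' The group loading for (synergy, object) is the mean of the raters'
#' binary involvement votes, i.e. the proportion of raters marking that
#' synergy as involved, in `[0, 1]`.
#'
#' @param votes synergies x objects x raters array with entries in `{0, 1}`.
#' @param drop_objects optional object ids (e.g. catch-trial or control
#'   columns) removed after aggregation.
#' @return a [rating_matrix()].
#' @export
aggregate_ratings <- function(votes, drop_objects = NULL) {
  stopifnot(is.array(votes), length(dim(votes)) == 3L)
  if (dim(votes)[3] < 1L) stop("invalid-input: need at least one rater")
  if (!all(votes %in% c(0, 1)))
    stop("invalid-input: votes must be binary")
  loads <- apply(votes, c(1, 2), mean)
  if (!is.null(drop_objects))
    loads <- loads[, !(colnames(loads) %in% drop_objects), drop = FALSE]
  rating_matrix(loads)
}

#' Construct an object set with behavioural scores
#'
#' @param object_ids character vector of unique ids.
#' @param centrality per-object centrality-of-manipulation rating (1-5).
#' @param familiarity optional per-object familiarity rating.
#' @return data frame of class `object_set` with an `is_high_centrality`
#'   flag filled in by [select_high_centrality()].
#' @export
object_set <- function(object_ids, centrality, familiarity = NA_real_) {
  stopifnot(!anyDuplicated(object_ids),
            length(centrality) == length(object_ids))
  structure(data.frame(object_id = object_ids, centrality = centrality,
                       familiarity = familiarity,
                       is_high_centrality = NA,
                       stringsAsFactors = FALSE),
            class = c("object_set", "data.frame"))
}

#' Median-split selection of high-centrality objects
#'
#' Returns the objects whose centrality rating lies strictly above the
#' median; objects tied at the median are excluded, so with an even number
#' of distinct values the split is exactly half (e.g. 33 of 66).
#'
#' @param objs an [object_set()] with centrality present for all objects.
#' @return the `object_set` subset, with `is_high_centrality` set; a
#'   warning is raised if the subset is empty (all values equal).
#' @export
select_high_centrality <- function(objs) {
  stopifnot(inherits(objs, "object_set"))
  if (anyNA(objs$centrality))
    stop("invalid-input: centrality missing for some objects")
  med <- stats::median(objs$centrality)
  high <- objs$centrality > med
  if (!any(high))
    warning("degenerate centrality split: no object strictly above the median")
  objs$is_high_centrality <- high
  out <- objs[high, , drop = FALSE]
  attr(out, "split_median") <- med
  attr(out, "n_selected") <- sum(high)
  out
}

#' Construct a similarity or dissimilarity matrix
#'
#' @param values symmetric objects x objects matrix.
#' @param mode `"similarity"` (RSM, unit diagonal) or `"dissimilarity"`
#'   (RDM, zero diagonal).
#' @return object of class `sim_matrix`.
#' @export
sim_matrix <- function(values, mode = c("similarity", "dissimilarity")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-8)
    stop("invalid-input: matrix is not symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- if (mode == "similarity") 1 else 0
  structure(values, mode = mode, class = c("sim_matrix", class(values)))
}

#' Correlation-distance RDM between object columns
#'
#' Entry (a, b) is `1 - r` where `r` is the Pearson correlation between
#' the columns for objects a and b; entries lie in `[0, 2]` and the
#' diagonal is 0.
#'
#' @param m features x objects matrix (e.g. a [rating_matrix()] or a
#'   voxel-pattern matrix) with >= 2 rows and >= 2 object columns.
#' @return a dissimilarity [sim_matrix()].
#' @export
compute_rdm <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), ncol(m) >= 2L, nrow(m) >= 2L)
  v <- apply(m, 2, sd)
  if (any(v == 0))
    stop("flagged-object: zero-variance column(s): ",
         paste(colnames(m)[v == 0], collapse = ", "))
  sim_matrix(1 - cor(m), mode = "dissimilarity")
}

#' Convert between RSM and RDM
#' @param sm a [sim_matrix()].
#' @return the dual `sim_matrix` (`1 - x` off-diagonal).
#' @export
sim_convert <- function(sm) {
  mode <- attr(sm, "mode")
  out <- 1 - unclass(sm)
  sim_matrix(out, mode = if (mode == "similarity") "dissimilarity" else "similarity")
}

#' Agglomerative clustering of an RDM under Ward's criterion
#'
#' Applies Ward linkage (`stats::hclust`, `"ward.D2"`) directly to the
#' correlation-distance matrix. Ward formally assumes squared Euclidean
#' input; following stated procedure, the 1-r distances are used as the
#' input metric as-is.
#'
#' @param rdm a dissimilarity [sim_matrix()].
#' @return object of class `kin_dendro`: the `hclust` fit, the object
#'   ids, and the displayed leaf order.
#' @export
build_dendrogram <- function(rdm) {
  stopifnot(inherits(rdm, "sim_matrix"))
  if (attr(rdm, "mode") != "dissimilarity")
    stop("invalid-input: build_dendrogram expects an RDM")
  d <- stats::as.dist(unclass(rdm))
  hc <- stats::hclust(d, method = "ward.D2")
  ids <- colnames(unclass(rdm))
  if (is.null(ids)) ids <- as.character(seq_len(ncol(rdm)))
  hc$labels <- ids
  structure(list(hclust = hc, object_ids = ids,
                 leaf_order = ids[hc$order]),
            class = "kin_dendro")
}

#' @export
print.kin_dendro <- function(x, ...) {
  cat(sprintf("kin_dendro: %d leaves (Ward on 1-r distances)\n",
              length(x$object_ids)))
  invisible(x)
}

leaf_ranks <- function(d, ref_ids) {
  r <- match(ref_ids, d$leaf_order)
  if (anyNA(r)) stop("invalid-input: mismatched leaf sets")
  r
}

#' Entanglement between two dendrograms' leaf orderings
#'
#' For the shared leaves, let `x` and `y` be each leaf's rank in the two
#' trees' displayed orders. Entanglement is
#' `sum(|x - y|^L) / sum(|x - rev(x)|^L)` with `L = norm_power`, the
#' denominator being the fully reversed worst case, so the value lies in
#' `[0, 1]`: 0 for perfectly aligned orders, 1 for exactly reversed ones.
#' The statistic is computed for the leaf orders as given; apply
#' [untangle_stepwise()] first to compare topologies under optimised
#' orderings.
#'
#' @param d1,d2 `kin_dendro` objects over the same object ids.
#' @param norm_power the exponent `L` (default 1.5, the common convention).
#' @return entanglement value in `[0, 1]`.
#' @export
entanglement <- function(d1, d2, norm_power = 1.5) {
  stopifnot(inherits(d1, "kin_dendro"), inherits(d2, "kin_dendro"))
  if (!setequal(d1$object_ids, d2$object_ids))
    stop("invalid-input: mismatched leaf sets")
  n <- length(d1$object_ids)
  if (n < 2L) return(0)
  x <- leaf_ranks(d1, d1$object_ids)
  y <- leaf_ranks(d2, d1$object_ids)
  worst <- sum(abs(seq_len(n) - rev(seq_len(n)))^norm_power)
  sum(abs(x - y)^norm_power) / worst
}

# All leaf orders reachable from `node` by flipping exactly one internal
# node; dendrograms are addressed positionally via a preorder counter.
flip_one <- function(dend, k) {
  counter <- 0L
  rec <- function(node) {
    if (is.leaf(node)) return(node)
    counter <<- counter + 1L
    if (counter == k) {
      node[] <- node[rev(seq_along(node))]
    }
    for (i in seq_along(node)) node[[i]] <- rec(node[[i]])
    node
  }
  rec(dend)
}

count_internal <- function(dend) {
  if (is.leaf(dend)) return(0L)
  1L + sum(vapply(seq_along(dend), function(i) count_internal(dend[[i]]), 0L))
}

dendro_with_order <- function(kd, dend) {
  kd$leaf_order <- labels(dend)
  kd$dend <- dend
  kd
}

#' Stepwise untangling of two dendrograms
#'
#' Greedy hill-climbing over single internal-node rotations of either
#' tree, accepting at each sweep the flip that most reduces the
#' entanglement, until no flip improves it (or `max_sweeps` is reached).
#' Deterministic: ties are broken by the first node in preorder.
#'
#' @param d1,d2 `kin_dendro` objects over the same object ids.
#' @param norm_power passed to [entanglement()].
#' @param max_sweeps maximum accepted flips.
#' @return list with reordered `d1`, `d2`, and the final `entanglement`.
#' @export
untangle_stepwise <- function(d1, d2, norm_power = 1.5, max_sweeps = 100L) {
  e1 <- stats::as.dendrogram(d1$hclust)
  e2 <- stats::as.dendrogram(d2$hclust)
  cur1 <- dendro_with_order(d1, e1)
  cur2 <- dendro_with_order(d2, e2)
  best <- entanglement(cur1, cur2, norm_power)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (tree in 1:2) {
      dend <- if (tree == 1) cur1$dend else cur2$dend
      for (k in seq_len(count_internal(dend))) {
        cand <- flip_one(dend, k)
        c1 <- if (tree == 1) dendro_with_order(cur1, cand) else cur1
        c2 <- if (tree == 2) dendro_with_order(cur2, cand) else cur2
        e <- entanglement(c1, c2, norm_power)
        if (e < best - 1e-12) {
          best <- e
          cur1 <- c1
          cur2 <- c2
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(d1 = cur1, d2 = cur2, entanglement = best)
}

#' Permutation test for dendrogram alignment
#'
#' The null distribution is built by shuffling the leaf labels of the
#' second tree (equivalently, permuting its leaf-rank vector) and
#' recomputing the entanglement; the p-value is left-tailed,
#' `(1 + #(null <= observed)) / (n_perm + 1)`, since small entanglement
#' means alignment.
#'
#' @param d1,d2 `kin_dendro` objects over the same object ids.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param norm_power passed to [entanglement()].
#' @return list with `observed`, `p_value`, and the `null` vector.
#' @export
entanglement_permutation_test <- function(d1, d2, n_perm = 10000L, seed = 1L,
                                          norm_power = 1.5) {
  stopifnot(n_perm >= 1L)
  obs <- entanglement(d1, d2, norm_power)
  n <- length(d1$object_ids)
  x <- leaf_ranks(d1, d1$object_ids)
  y <- leaf_ranks(d2, d1$object_ids)
  worst <- sum(abs(seq_len(n) - rev(seq_len(n)))^norm_power)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(abs(x - sample(y))^norm_power) / worst
    }, 0)
  })
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  list(observed = obs, p_value = p, null = null, n_perm = n_perm)
}

#' Serialise a dendrogram to Newick text
#'
#' Branch lengths are derived from Ward merge heights (each child branch
#' spans the gap between its own height, 0 for leaves, and its parent's
#' merge height).
#'
#' @param d a `kin_dendro`.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned instead.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(d, path = NULL) {
  hc <- d$hclust
  n <- length(hc$labels)
  node_str <- function(i, parent_h) {
    if (i < 0) {
      lab <- hc$labels[-i]
      sprintf("%s:%.12g", gsub("[,();: ]", "_", lab), parent_h)
    } else {
      h <- hc$height[i]
      kids <- paste(node_str(hc$merge[i, 1], h), node_str(hc$merge[i, 2], h),
                    sep = ",")
      sprintf("(%s):%.12g", kids, parent_h - h)
    }
  }
  top <- length(hc$height)
  s <- sprintf("(%s,%s);", node_str(hc$merge[top, 1], hc$height[top]),
               node_str(hc$merge[top, 2], hc$height[top]))
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
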