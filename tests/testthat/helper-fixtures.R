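# Small shared fixtures, built in code.

tiny_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_synergies = 12L, n_objects = 12L, n_raters = 20L,
         n_subjects = 4L, grid_shape = c(12L, 12L, 12L),
         noise_sd = 1, seed = seed),
    list(...))
  do.call(synth_config, args)
}

tiny_world <- function(seed = 1L, ...) {
  cfg <- tiny_cfg(seed = seed, ...)
  rat <- generate_ratings(cfg)
  feats <- generate_visual_features(cfg)
  gen <- generate_cohort(cfg, rat$ratings, feats$features)
  list(cfg = cfg, ratings = rat, feats = feats,
       cohort = gen$cohort, truth = gen$truth)
}

# a kin_dendro from an explicit loading matrix
dendro_of <- function(loads) {
  build_dendrogram(compute_rdm(loads))
}

# ladder (caterpillar) dendrogram over ids in the given left-to-right
# leaf order, built directly from an hclust skeleton
ladder_dendro <- function(ids) {
  n <- length(ids)
  merge <- matrix(0L, n - 1L, 2L)
  merge[1L, ] <- c(-1L, -2L)
  if (n > 2L) for (i in 2L:(n - 1L)) merge[i, ] <- c(i - 1L, -(i + 1L))
  hc <- structure(list(merge = merge, height = seq_len(n - 1L),
                       order = seq_len(n), labels = ids,
                       method = "ward.D2", call = NULL,
                       dist.method = "euclidean"),
                  class = "hclust")
  structure(list(hclust = hc, object_ids = ids, leaf_order = ids[hc$order]),
            class = "kin_dendro")
}
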