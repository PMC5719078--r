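# Shared fixtures. Small cohorts are regenerated per test; the full-scale
# run used by the acceptance tests is computed once and memoized.

small_config <- function(seed = 42, ...) {
  args <- utils::modifyList(list(
    n_tumor = 120, n_normal = 20, n_genes = 60,
    hypo_genes_per_subtype = c(20, 8, 8),
    hyper_genes_per_subtype = c(3, 0, 0),
    signature_size = 60, seed = seed), list(...))
  do.call(generator_config, args)
}

# generate -> filter/impute -> probe clusters -> states, for a config
run_states <- function(cfg, cut_height = 0.4, ...) {
  co <- generate_cohort(cfg)
  bv <- knn_impute(filter_missing(co$beta$values, 0.2), 15)
  beta <- beta_matrix(bv, co$beta$group[colnames(bv)])
  map <- cluster_probes(beta, co$manifest, cut_height)
  cb <- cluster_mean_beta(beta, map)
  states <- call_states(cb, beta$group, co$expression, cluster_genes(map),
                        seed = 1, ...)
  list(cohort = co, beta = beta, map = map, cluster_beta = cb,
       states = states)
}

# Full default-scale cohort run shared by the acceptance tests (memoized).
.acceptance_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (!is.null(.acceptance_cache$run)) return(.acceptance_cache$run)
  cfg <- generator_config(seed = 101)
  run <- run_states(cfg)
  truth <- run$cohort$truth$samples
  feats <- dm_feature_matrix(run$states)
  cons <- consensus_cluster(feats, k_max = 10, n_reps = 1000, seed = 101)
  probe_feats <- t(run$beta$values[
    unique(unlist(run$map[rownames(run$states$states)])),
    truth$sample_id, drop = FALSE])
  labels <- ifelse(truth$subtype == 1, "driver", "other")
  run <- c(run, list(truth = truth, consensus = cons,
                     probe_feats = probe_feats, labels = labels))
  .acceptance_cache$run <- run
  run
}
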