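#' Default pipeline thresholds
#'
#' Missingness filters (20% methylation / 10% expression), KNN k, probe
#' cluster cut height, abnormality and coupling thresholds, consensus and
#' classifier settings, and the overlap-resampling draw count.
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(max_missing_beta = 0.20, max_missing_expr = 0.10, knn_k = 15,
       cut_height = 0.4, dm_min = 0.10, coupling_r = -0.3,
       coupling_p = 0.05, k_max = 10, n_reps = 1000,
       subsample_frac = 0.8, n_folds = 10, conf_low = 0.40,
       conf_high = 0.60, n_draws = 10, driver_gene = "NSD1", seed = 1)
}

validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$cohort))
    stop("config missing required path: cohort")
  cfg <- utils::modifyList(pipeline_defaults(), config)
  stopifnot(cfg$max_missing_beta >= 0, cfg$max_missing_beta < 1,
            cfg$conf_low < cfg$conf_high, cfg$k_max >= 2)
  cfg
}

#' Run the full subtyping pipeline on a cohort directory
#'
#' Executes load -> missingness filter / KNN imputation -> probe
#' clustering -> mixture state calling -> consensus subtyping -> driver
#' lesion enrichment -> classifier cross-validation (and transfer
#' classification when a second cohort is given) -> signature-overlap and
#' T-cell scores, and writes a machine-readable run report.
#'
#' @param config Path to a YAML file or a named list. Required: `cohort`
#'   (directory holding a `cohort.yaml` descriptor plus `signature.txt`).
#'   Optional: `second_cohort` (directory for transfer classification),
#'   `out` (output directory), `seed`, and any threshold from
#'   [pipeline_defaults()].
#' @return Invisibly, a list with the fitted objects (`states`,
#'   `consensus`, `cv`, `transfer`, `scores`) and `report` (the run
#'   summary also written to `out/report.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))

  log_stage("load: %s", cfg$cohort)
  cohort <- load_cohort(file.path(cfg$cohort, "cohort.yaml"))
  signature <- readLines(file.path(cfg$cohort, "signature.txt"))

  log_stage("filter/impute")
  bv <- filter_missing(cohort$beta$values, cfg$max_missing_beta)
  bv <- knn_impute(bv, cfg$knn_k)
  keep_samples <- colnames(bv)
  beta <- beta_matrix(bv, cohort$beta$group[keep_samples],
                      cohort$beta$platform[rownames(bv)])
  expr <- filter_missing(cohort$expression, cfg$max_missing_expr)
  if (anyNA(expr)) expr <- knn_impute(expr, cfg$knn_k)

  log_stage("probe clustering (cut height %.2f)", cfg$cut_height)
  map <- cluster_probes(beta, cohort$manifest, cfg$cut_height)
  cb <- cluster_mean_beta(beta, map)

  log_stage("mixture state calling (%d clusters)", nrow(cb))
  states <- call_states(cb, beta$group, expr, cluster_genes(map),
                        dm_min = cfg$dm_min, r_max = cfg$coupling_r,
                        p_max = cfg$coupling_p, seed = cfg$seed)
  if (nrow(states$states) < 2)
    stop("fewer than 2 abnormal gene clusters called; nothing to subtype")

  log_stage("consensus subtyping (k_max %d, %d reps)", cfg$k_max,
            cfg$n_reps)
  feats <- dm_feature_matrix(states)
  cons <- consensus_cluster(feats, k_max = cfg$k_max, n_reps = cfg$n_reps,
                            subsample_frac = cfg$subsample_frac,
                            seed = cfg$seed)
  assign_k <- cons$assignments[[as.character(cons$chosen_k)]]
  hypo_counts <- count_hypo_per_patient(states)
  mean_hypo <- tapply(hypo_counts[names(assign_k)], assign_k, mean)
  driver_subtype <- as.integer(names(which.max(mean_hypo)))

  mut <- drop_silent_mutations(cohort$mutations)
  lesions <- lesion_table(mut, cohort$copynumber, cfg$driver_gene,
                          samples = names(assign_k))
  has_lesion <- lesions$lesion_score > 0
  enrich <- tryCatch(
    enrichment_test(assign_k, has_lesion[match(names(assign_k),
                                               lesions$sample_id)],
                    subtype = driver_subtype),
    error = function(e) list(statistic = NA_real_, p = NA_real_))

  log_stage("classifier CV (%d folds)", cfg$n_folds)
  probe_feats <- t(beta$values[unique(unlist(map[rownames(states$states)])),
                               names(assign_k), drop = FALSE])
  labels <- ifelse(assign_k == driver_subtype, "driver", "other")
  cv <- cross_validate(probe_feats, labels, positive = "driver",
                       n_folds = cfg$n_folds, seed = cfg$seed)

  transfer <- NULL
  if (!is.null(cfg$second_cohort)) {
    log_stage("transfer classification: %s", cfg$second_cohort)
    model <- train_nsc(probe_feats, labels, seed = cfg$seed)
    b2 <- load_cohort(file.path(cfg$second_cohort, "cohort.yaml"))
    bv2 <- knn_impute(filter_missing(b2$beta$values, cfg$max_missing_beta),
                      cfg$knn_k)
    tumors2 <- colnames(bv2)[b2$beta$group[colnames(bv2)] == "tumor"]
    shared <- intersect(names(beta$platform)[beta$platform == "both"],
                        rownames(bv2))
    transfer <- transfer_classify(model, t(bv2[shared, tumors2]),
                                  positive = "driver",
                                  conf_low = cfg$conf_low,
                                  conf_high = cfg$conf_high)
  }

  log_stage("scores")
  hypo_sets <- hypo_cpgs_per_patient(states, map)
  universe <- rownames(beta$values)
  idx <- vapply(hypo_sets, function(h) {
    if (length(h) == 0) NA_real_ else overlap_index(h, signature)
  }, numeric(1))
  rnd <- vapply(seq_along(hypo_sets), function(i) {
    h <- hypo_sets[[i]]
    if (length(h) == 0) return(NA_real_)
    random_overlap_index(h, universe, length(signature),
                         n_draws = cfg$n_draws, seed = cfg$seed + i)
  }, numeric(1))
  scores <- data.frame(sample_id = names(hypo_sets),
                       n_hypo_genes = hypo_counts[names(hypo_sets)],
                       n_hypo_cpgs = lengths(hypo_sets),
                       overlap_index = idx, random_overlap_index = rnd,
                       row.names = NULL, stringsAsFactors = FALSE)
  scores <- merge(scores, lesions, by = "sample_id", all.x = TRUE)
  assoc <- tryCatch(
    lesion_overlap_association(scores$lesion_score, scores$overlap_index),
    error = function(e) list(slope = NA_real_, p = NA_real_))
  tcell <- tryCatch(tcell_score(expr), error = function(e) NULL)

  report <- list(
    package_version = as.character(utils::packageVersion("methsub")),
    r_version = R.version.string,
    seed = cfg$seed,
    thresholds = cfg[setdiff(names(cfg), c("cohort", "second_cohort",
                                           "out"))],
    counts = list(
      probes = nrow(beta$values), samples = ncol(beta$values),
      tumors = sum(beta$group == "tumor"),
      clusters = nrow(cb), abnormal_clusters = nrow(states$states),
      skipped_clusters = length(states$skipped)),
    chosen_k = cons$chosen_k, pac = as.list(cons$pac),
    driver_subtype = driver_subtype,
    enrichment = list(statistic = enrich$statistic, p = enrich$p),
    cv_auc = cv$auc, cv_auc_ci = cv$auc_ci,
    mean_fold_auc = cv$mean_fold_auc,
    transfer_n_positive = if (!is.null(transfer))
      sum(transfer$call == "positive") else NA,
    lesion_overlap_slope = assoc$slope, lesion_overlap_p = assoc$p,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    write_states_tsv(states, file.path(cfg$out, "states.tsv"))
    utils::write.table(
      data.frame(sample_id = names(assign_k), subtype = assign_k),
      file.path(cfg$out, "subtypes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(scores, file.path(cfg$out, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(transfer))
      utils::write.table(transfer, file.path(cfg$out, "transfer.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_stage("done (%.1f s)", report$runtime_s)
  invisible(list(beta = beta, map = map, states = states, consensus = cons,
                 assignments = assign_k, driver_subtype = driver_subtype,
                 cv = cv, transfer = transfer, scores = scores,
                 tcell = tcell, report = report))
}

#' Generate synthetic cohorts from a generator config file
#'
#' Thin wrapper used by the `msub simulate` subcommand: reads a YAML
#' generator config, writes one cohort (or a transfer pair when
#' `second: true`) into `out`.
#'
#' @param config_path YAML file of [generator_config()] fields; the
#'   optional logical `second` and `shared_fraction` control the transfer
#'   pair.
#' @param out Output directory.
#' @return Invisibly, the generated cohort list (first cohort).
#' @export
simulate_command <- function(config_path, out) {
  raw <- yaml::read_yaml(config_path)
  second <- isTRUE(raw$second)
  shared <- if (is.null(raw$shared_fraction)) 1 else raw$shared_fraction
  raw$second <- NULL; raw$shared_fraction <- NULL
  cfg <- do.call(generator_config, raw)
  first <- generate_cohort(cfg, dir = if (second)
    file.path(out, "cohort1") else out)
  if (second) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + 1
    generate_second_cohort(cfg2, first, shared_fraction = shared,
                           dir = file.path(out, "cohort2"))
  }
  invisible(first)
}
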