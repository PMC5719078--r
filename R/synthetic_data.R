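#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a tumor methylation cohort with a planted
#' hypomethylated driver subtype: 400 tumors and 40 normals over 500 genes
#' (1-5 CpG probes each), three subtypes, beta values drawn from
#' Beta(mean * precision, (1 - mean) * precision) components, inverse
#' methylation-expression coupling at abnormal genes, driver mutations and
#' deletions enriched in subtype 1, a partial 450k/27k platform split, and
#' a CpG signature partially overlapping the planted hypomethylated CpGs.
#'
#' @param n_tumor,n_normal Sample counts (400 / 40).
#' @param n_genes Number of genes with methylation probes (500).
#' @param probes_per_gene Integer range of probes per gene (1-5).
#' @param n_subtypes Number of planted subtypes (3; subtype 1 carries the
#'   driver lesions).
#' @param subtype_props Subtype prevalences (0.2, 0.4, 0.4).
#' @param hypo_genes_per_subtype Planted hypomethylated gene counts per
#'   subtype (80, 30, 30).
#' @param hyper_genes_per_subtype Planted hypermethylated gene counts
#'   (10, 0, 0).
#' @param mu_normal Mean beta of the normal-like component at planted
#'   genes (0.7).
#' @param mu_hypo,mu_hyper Component means of planted hypo (0.2) and hyper
#'   (0.9) states.
#' @param precision Beta precision: alpha = mean * precision, beta =
#'   (1 - mean) * precision (30).
#' @param carry_prob Probability a subtype member carries a given planted
#'   (non-signature) gene (0.9).
#' @param sig_carry_base,sig_carry_slope Carriage probability of
#'   signature-pool genes in the driver subtype:
#'   `base + slope * lesion_score`, clamped to \[0.05, 0.95\] (0.2, 0.18)
#'   - ties signature hypomethylation to driver lesion load.
#' @param coupling Expression drop per unit beta increase at abnormal
#'   genes (4; 0 decouples expression entirely).
#' @param expr_noise_sd Gaussian noise SD on log2 expression (0.5).
#' @param driver_gene Driver gene symbol ("NSD1").
#' @param mut_rate_driver,mut_rate_other Per-patient driver mutation
#'   probability inside/outside subtype 1 (0.6 / 0.05).
#' @param del_probs_driver,del_probs_other Probabilities of GISTIC scores
#'   (-2, -1) for the driver gene inside/outside subtype 1.
#' @param silent_rate Fraction of extra silent mutation rows added (0.15).
#' @param signature_size Size of the CpG signature (200).
#' @param signature_overlap_frac Fraction of the signature drawn from the
#'   driver subtype's planted hypomethylated CpGs (0.5).
#' @param shared_platform_frac Fraction of probes flagged `both`
#'   (450k and 27k); the rest are `450k` (0.6).
#' @param missing_rate Fraction of beta cells set missing (0.005).
#' @param tcell_coupling Slope tying T-cell signature genes to
#'   standardized driver expression (0.5).
#' @param seed Mandatory integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_tumor = 400, n_normal = 40, n_genes = 500,
                             probes_per_gene = c(1, 5), n_subtypes = 3,
                             subtype_props = c(0.2, 0.4, 0.4),
                             hypo_genes_per_subtype = c(80, 30, 30),
                             hyper_genes_per_subtype = c(10, 0, 0),
                             mu_normal = 0.7, mu_hypo = 0.2,
                             mu_hyper = 0.9, precision = 30,
                             carry_prob = 0.9, sig_carry_base = 0.2,
                             sig_carry_slope = 0.18, coupling = 4,
                             expr_noise_sd = 0.5, driver_gene = "NSD1",
                             mut_rate_driver = 0.6, mut_rate_other = 0.05,
                             del_probs_driver = c(0.10, 0.45),
                             del_probs_other = c(0.01, 0.14),
                             silent_rate = 0.15, signature_size = 200,
                             signature_overlap_frac = 0.5,
                             shared_platform_frac = 0.6,
                             missing_rate = 0.005, tcell_coupling = 0.5,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(length(cfg$subtype_props) == cfg$n_subtypes,
            abs(sum(cfg$subtype_props) - 1) < 1e-8,
            length(cfg$hypo_genes_per_subtype) == cfg$n_subtypes,
            cfg$mu_hypo > 0, cfg$mu_hyper < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 0.1)
  if (sum(cfg$hypo_genes_per_subtype) + sum(cfg$hyper_genes_per_subtype) >
        cfg$n_genes)
    stop("infeasible config: more planted genes than genes")
  structure(cfg, class = "generator_config")
}

# Gene/probe scaffold shared between paired cohorts. Drawn from a fixed
# RNG stream so that cohorts generated with different seeds (but the same
# structural configuration) share dimensions, probes and baselines; only
# the data varies with the seed.
build_structure <- function(cfg) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(424243L)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  npp <- sample(cfg$probes_per_gene[1]:cfg$probes_per_gene[2],
                cfg$n_genes, replace = TRUE)
  probe_gene <- rep(genes, npp)
  probes <- sprintf("cg%08d", seq_along(probe_gene))
  platform <- ifelse(stats::runif(length(probes)) < cfg$shared_platform_frac,
                     "both", "450k")
  manifest <- data.frame(
    chrom = paste0("chr", sample(1:22, length(probes), replace = TRUE)),
    start = sample.int(2e8, length(probes)),
    probe_id = probes, gene = probe_gene, platform = platform,
    stringsAsFactors = FALSE)
  baseline <- stats::setNames(stats::runif(cfg$n_genes, 0.25, 0.75), genes)
  list(genes = genes, manifest = manifest, baseline = baseline)
}

# Assign planted hypo/hyper gene sets per subtype; driver subtype's hypo
# genes are split into a signature pool and a background pool.
plant_genes <- function(cfg, structure, forced_driver_hypo = NULL) {
  pool <- structure$genes
  planted <- list(hypo = vector("list", cfg$n_subtypes),
                  hyper = vector("list", cfg$n_subtypes))
  if (!is.null(forced_driver_hypo)) {
    planted$hypo[[1]] <- forced_driver_hypo
    pool <- setdiff(pool, forced_driver_hypo)
    extra <- cfg$hypo_genes_per_subtype[1] - length(forced_driver_hypo)
    if (extra > 0) {
      add <- sample(pool, extra)
      planted$hypo[[1]] <- c(planted$hypo[[1]], add)
      pool <- setdiff(pool, add)
    }
  } else {
    planted$hypo[[1]] <- sample(pool, cfg$hypo_genes_per_subtype[1])
    pool <- setdiff(pool, planted$hypo[[1]])
  }
  for (s in seq_len(cfg$n_subtypes)[-1]) {
    planted$hypo[[s]] <- sample(pool, cfg$hypo_genes_per_subtype[s])
    pool <- setdiff(pool, planted$hypo[[s]])
  }
  for (s in seq_len(cfg$n_subtypes)) {
    n <- cfg$hyper_genes_per_subtype[s]
    planted$hyper[[s]] <- if (n > 0) sample(pool, n) else character(0)
    pool <- setdiff(pool, planted$hyper[[s]])
  }
  planted
}

#' Generate a synthetic tumor/normal methylation cohort
#'
#' Emits a beta matrix (tumor + normal), an expression matrix with
#' negative methylation-expression coupling at planted genes, MAF-like
#' mutation and GISTIC copy-number tables with driver lesions enriched in
#' subtype 1, a probe manifest with the platform split, a CpG signature
#' overlapping the planted hypomethylated CpGs, and ground-truth tables.
#' Byte-identical outputs for identical seeds.
#'
#' @param config A `generator_config`.
#' @param dir Optional output directory; when given, all tables are
#'   written as TSV (plus `signature.txt` and `config.yaml`) and a
#'   [load_cohort()]-compatible `cohort.yaml` descriptor.
#' @return A list with `beta` (`beta_matrix`), `expression`, `mutations`,
#'   `copynumber`, `manifest`, `signature` (CpG ids), and `truth` (list:
#'   `samples` data.frame with subtype/lesions, `genes` data.frame with
#'   planted states and true DM, `signature_genes`).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  structure_ <- build_structure(config)
  planted <- plant_genes(config, structure_)
  build_cohort(config, structure_, planted, prefix = "T", dir = dir)
}

#' Generate a second cohort sharing (part of) the planted signature
#'
#' Reuses the first cohort's gene/probe scaffold and signature, and plants
#' the second cohort's driver subtype on a configurable fraction of the
#' first cohort's driver hypomethylated genes, emulating cross-cancer-type
#' transfer of a hypomethylation subtype. With `shared_fraction = 0` the
#' second cohort's driver genes are disjoint from the first's.
#'
#' @param config A `generator_config` for the second cohort (its seed
#'   should differ from the first's).
#' @param first The list returned by [generate_cohort()].
#' @param shared_fraction Fraction of the first cohort's driver
#'   hypomethylated genes reused (default 1).
#' @param dir Optional output directory.
#' @return Same shape as [generate_cohort()].
#' @export
generate_second_cohort <- function(config, first, shared_fraction = 1,
                                   dir = NULL) {
  stopifnot(inherits(config, "generator_config"),
            shared_fraction >= 0, shared_fraction <= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  structure_ <- first$structure
  g1 <- first$truth$genes
  driver_hypo_1 <- g1$gene[g1$direction == "hypo" & g1$subtype == 1]
  n_share <- round(shared_fraction * min(length(driver_hypo_1),
                                         config$hypo_genes_per_subtype[1]))
  forced <- if (n_share > 0) sample(driver_hypo_1, n_share) else character(0)
  avoid <- if (shared_fraction == 0) driver_hypo_1 else NULL
  planted <- plant_genes_second(config, structure_, forced, avoid)
  out <- build_cohort(config, structure_, planted, prefix = "U", dir = dir,
                      signature = first$signature)
  out
}

plant_genes_second <- function(cfg, structure_, forced, avoid) {
  pool <- setdiff(structure_$genes, c(forced, avoid))
  planted <- list(hypo = vector("list", cfg$n_subtypes),
                  hyper = vector("list", cfg$n_subtypes))
  extra <- cfg$hypo_genes_per_subtype[1] - length(forced)
  add <- if (extra > 0) sample(pool, extra) else character(0)
  planted$hypo[[1]] <- c(forced, add)
  pool <- setdiff(pool, add)
  for (s in seq_len(cfg$n_subtypes)[-1]) {
    planted$hypo[[s]] <- sample(pool, cfg$hypo_genes_per_subtype[s])
    pool <- setdiff(pool, planted$hypo[[s]])
  }
  for (s in seq_len(cfg$n_subtypes)) {
    n <- cfg$hyper_genes_per_subtype[s]
    planted$hyper[[s]] <- if (n > 0) sample(pool, n) else character(0)
    pool <- setdiff(pool, planted$hyper[[s]])
  }
  planted
}

# Core emission shared by both cohort generators. Assumes the RNG stream
# is already seeded.
build_cohort <- function(cfg, structure_, planted, prefix, dir = NULL,
                         signature = NULL) {
  genes <- structure_$genes
  manifest <- structure_$manifest
  baseline <- structure_$baseline

  tumor_ids <- sprintf("%s%03d", prefix, seq_len(cfg$n_tumor))
  normal_ids <- sprintf("%sN%02d", prefix, seq_len(cfg$n_normal))
  subtype <- sample(seq_len(cfg$n_subtypes), cfg$n_tumor, replace = TRUE,
                    prob = cfg$subtype_props)

  # driver lesions
  in_driver <- subtype == 1
  mut_p <- ifelse(in_driver, cfg$mut_rate_driver, cfg$mut_rate_other)
  n_mut <- stats::rbinom(cfg$n_tumor, 2, mut_p / 2)
  gistic <- integer(cfg$n_tumor)
  for (i in seq_len(cfg$n_tumor)) {
    pr <- if (in_driver[i]) cfg$del_probs_driver else cfg$del_probs_other
    gistic[i] <- sample(c(-2L, -1L, 0L), 1,
                        prob = c(pr[1], pr[2], 1 - sum(pr)))
  }
  lesion <- n_mut - gistic

  # signature pool: driver-subtype hypo genes whose CpGs seed the signature
  driver_hypo <- planted$hypo[[1]]
  probes_of <- split(manifest$probe_id, manifest$gene)[genes]
  if (is.null(signature)) {
    n_sig_cpg <- round(cfg$signature_overlap_frac * cfg$signature_size)
    sig_genes <- character(0)
    sig_cpgs <- character(0)
    for (g in sample(driver_hypo)) {
      if (length(sig_cpgs) >= n_sig_cpg) break
      sig_genes <- c(sig_genes, g)
      sig_cpgs <- c(sig_cpgs, probes_of[[g]])
    }
    sig_cpgs <- utils::head(sig_cpgs, n_sig_cpg)
    filler_pool <- setdiff(manifest$probe_id, sig_cpgs)
    filler <- sample(filler_pool,
                     min(cfg$signature_size - length(sig_cpgs),
                         length(filler_pool)))
    signature <- c(sig_cpgs, filler)
  } else {
    sig_genes <- intersect(driver_hypo,
                           unique(manifest$gene[manifest$probe_id %in%
                                                  signature]))
  }

  # per-gene, per-sample component means
  carry <- matrix(FALSE, cfg$n_genes, cfg$n_tumor,
                  dimnames = list(genes, tumor_ids))
  dir_gene <- matrix("normal", cfg$n_genes, cfg$n_subtypes,
                     dimnames = list(genes, NULL))
  for (s in seq_len(cfg$n_subtypes)) {
    for (g in planted$hypo[[s]]) dir_gene[g, s] <- "hypo"
    for (g in planted$hyper[[s]]) dir_gene[g, s] <- "hyper"
  }
  for (s in seq_len(cfg$n_subtypes)) {
    members <- which(subtype == s)
    for (g in c(planted$hypo[[s]], planted$hyper[[s]])) {
      p <- if (s == 1 && g %in% sig_genes) {
        pmin(pmax(cfg$sig_carry_base + cfg$sig_carry_slope * lesion[members],
                  0.05), 0.95)
      } else rep(cfg$carry_prob, length(members))
      carry[g, members] <- stats::runif(length(members)) < p
    }
  }

  # beta values
  n_probes <- nrow(manifest)
  all_ids <- c(tumor_ids, normal_ids)
  beta_vals <- matrix(NA_real_, n_probes, length(all_ids),
                      dimnames = list(manifest$probe_id, all_ids))
  prec <- cfg$precision
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    base_g <- if (any(dir_gene[g, ] != "normal")) cfg$mu_normal
              else baseline[g]
    mu_t <- rep(base_g, cfg$n_tumor)
    d <- dir_gene[g, subtype]
    hit <- carry[g, ]
    mu_t[hit & d == "hypo"] <- cfg$mu_hypo
    mu_t[hit & d == "hyper"] <- cfg$mu_hyper
    mu <- c(mu_t, rep(base_g, cfg$n_normal))
    for (p in probes_of[[g]]) {
      beta_vals[p, ] <- stats::rbeta(length(mu), mu * prec, (1 - mu) * prec)
    }
  }

  # expression: negative coupling at planted genes, noise elsewhere
  expr_genes <- c(genes, cfg$driver_gene, TCELL_GENES)
  expr <- matrix(NA_real_, length(expr_genes), cfg$n_tumor,
                 dimnames = list(expr_genes, tumor_ids))
  expr_base <- stats::setNames(stats::runif(length(expr_genes), 4, 10),
                               expr_genes)
  gene_mean_beta <- t(vapply(genes, function(g) {
    colMeans(beta_vals[probes_of[[g]], tumor_ids, drop = FALSE])
  }, numeric(cfg$n_tumor)))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    is_planted <- any(dir_gene[g, ] != "normal")
    mu0 <- if (is_planted) cfg$mu_normal else baseline[g]
    slope <- if (is_planted) cfg$coupling else 0
    expr[g, ] <- expr_base[g] - slope * (gene_mean_beta[gi, ] - mu0) +
      stats::rnorm(cfg$n_tumor, sd = cfg$expr_noise_sd)
  }
  driver_expr <- expr_base[cfg$driver_gene] - 0.8 * lesion +
    stats::rnorm(cfg$n_tumor, sd = cfg$expr_noise_sd)
  expr[cfg$driver_gene, ] <- driver_expr
  z <- as.numeric(scale(driver_expr))
  for (g in TCELL_GENES) {
    expr[g, ] <- expr_base[g] + cfg$tcell_coupling * z +
      stats::rnorm(cfg$n_tumor, sd = cfg$expr_noise_sd)
  }

  # mutation table: driver rows + background noise + silent rows
  mut_rows <- data.frame(sample_id = character(0), gene = character(0),
                         vc = character(0), stringsAsFactors = FALSE)
  for (i in which(n_mut > 0)) {
    mut_rows <- rbind(mut_rows, data.frame(
      sample_id = rep(tumor_ids[i], n_mut[i]), gene = cfg$driver_gene,
      vc = "Missense_Mutation", stringsAsFactors = FALSE))
  }
  bg <- which(stats::runif(cfg$n_tumor) < 0.3)
  if (length(bg) > 0) {
    mut_rows <- rbind(mut_rows, data.frame(
      sample_id = tumor_ids[bg], gene = sample(genes, length(bg),
                                               replace = TRUE),
      vc = "Nonsense_Mutation", stringsAsFactors = FALSE))
  }
  n_silent <- ceiling(cfg$silent_rate * max(nrow(mut_rows), 1))
  mut_rows <- rbind(mut_rows, data.frame(
    sample_id = sample(tumor_ids, n_silent, replace = TRUE),
    gene = sample(c(genes, cfg$driver_gene), n_silent, replace = TRUE),
    vc = "Silent", stringsAsFactors = FALSE))
  mutations <- data.frame(sample_id = mut_rows$sample_id,
                          gene = mut_rows$gene,
                          variant_classification = mut_rows$vc,
                          is_silent = mut_rows$vc == "Silent",
                          stringsAsFactors = FALSE)

  copynumber <- data.frame(sample_id = tumor_ids, gene = cfg$driver_gene,
                           gistic_score = gistic, stringsAsFactors = FALSE)

  # inject missingness
  if (cfg$missing_rate > 0) {
    n_cells <- length(beta_vals)
    miss <- sample.int(n_cells, round(cfg$missing_rate * n_cells))
    beta_vals[miss] <- NA_real_
    # no fully-missing rows
    empty <- which(rowSums(!is.na(beta_vals)) == 0)
    for (r in empty) beta_vals[r, 1] <- stats::rbeta(1, 0.5 * prec,
                                                     0.5 * prec)
  }

  group <- stats::setNames(c(rep("tumor", cfg$n_tumor),
                             rep("normal", cfg$n_normal)), all_ids)
  truth_genes <- do.call(rbind, lapply(seq_len(cfg$n_subtypes), function(s) {
    gs <- c(planted$hypo[[s]], planted$hyper[[s]])
    if (length(gs) == 0) return(NULL)
    d <- dir_gene[gs, s]
    data.frame(gene = gs, subtype = s, direction = d,
               true_dm = ifelse(d == "hypo", cfg$mu_hypo - cfg$mu_normal,
                                cfg$mu_hyper - cfg$mu_normal),
               is_signature_gene = gs %in% sig_genes,
               stringsAsFactors = FALSE)
  }))
  truth <- list(
    samples = data.frame(sample_id = tumor_ids, subtype = subtype,
                         n_mut = n_mut, gistic = gistic,
                         lesion_score = lesion, stringsAsFactors = FALSE),
    genes = truth_genes,
    signature_genes = sig_genes)

  out <- list(beta = beta_matrix(beta_vals, group,
                                 stats::setNames(manifest$platform,
                                                 manifest$probe_id)),
              expression = expr, mutations = mutations,
              copynumber = copynumber, manifest = manifest,
              signature = signature, truth = truth,
              structure = structure_, config = cfg)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a generated cohort to a directory of plain-text tables
#'
#' @param cohort A list from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(cohort$beta$values, p("beta.tsv"), "probe_id")
  write_matrix_tsv(cohort$expression, p("expression.tsv"), "gene_id")
  maf <- data.frame(Tumor_Sample_Barcode = cohort$mutations$sample_id,
                    Hugo_Symbol = cohort$mutations$gene,
                    Variant_Classification =
                      cohort$mutations$variant_classification)
  utils::write.table(maf, p("mutations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$copynumber, p("copynumber.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$signature, p("signature.txt"))
  groups <- data.frame(sample_id = names(cohort$beta$group),
                       group = unname(cohort$beta$group))
  utils::write.table(groups, p("groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth$samples, p("truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(cfg[setdiff(names(cfg), "probes_per_gene")],
                   p("config.yaml"))
  yaml::write_yaml(list(beta = p("beta.tsv"),
                        expression = p("expression.tsv"),
                        mutations = p("mutations.tsv"),
                        copynumber = p("copynumber.tsv"),
                        manifest = p("manifest.tsv"),
                        groups = p("groups.tsv")),
                   p("cohort.yaml"))
  invisible(dir)
}
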