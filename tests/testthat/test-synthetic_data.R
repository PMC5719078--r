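test_that("identical seeds reproduce cohorts byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 7, n_tumor = 40, n_normal = 8, n_genes = 20,
                      hypo_genes_per_subtype = c(6, 2, 2),
                      hyper_genes_per_subtype = c(1, 0, 0),
                      signature_size = 20)
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    if (f == "cohort.yaml") next   # embeds absolute paths
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seed: different betas, same shapes
  co1 <- generate_cohort(cfg)
  co3 <- generate_cohort(small_config(seed = 8, n_tumor = 40, n_normal = 8,
                                      n_genes = 20,
                                      hypo_genes_per_subtype = c(6, 2, 2),
                                      hyper_genes_per_subtype = c(1, 0, 0),
                                      signature_size = 20))
  expect_equal(dim(co1$beta$values), dim(co3$beta$values))
  expect_false(identical(co1$beta$values, co3$beta$values))
})

test_that("emitted betas are valid and component means match configuration", {
  cfg <- small_config(seed = 19, missing_rate = 0)
  co <- generate_cohort(cfg)
  v <- co$beta$values
  expect_true(all(v >= 0 & v <= 1))

  # carriers of a planted hypo gene average near mu_hypo, within 3 SE
  tg <- co$truth$genes
  g <- tg$gene[tg$subtype == 1 & tg$direction == "hypo" &
                 !tg$is_signature_gene][1]
  probes <- co$manifest$probe_id[co$manifest$gene == g]
  truth <- co$truth$samples
  sub1 <- truth$sample_id[truth$subtype == 1]
  carrier_beta <- colMeans(v[probes, sub1, drop = FALSE])
  carriers <- carrier_beta < 0.45   # bimodal split at midpoint
  mu <- cfg$mu_hypo
  se <- sqrt(mu * (1 - mu) / (cfg$precision + 1) /
               (sum(carriers) * length(probes)))
  expect_lt(abs(mean(v[probes, sub1[carriers]]) - mu), 3 * se)

  # normals sit at the normal-like component
  normals <- names(co$beta$group)[co$beta$group == "normal"]
  expect_lt(abs(mean(v[probes, normals]) - cfg$mu_normal), 0.05)

  # truth DM signs agree with threshold recomputation from config means
  expect_true(all(tg$true_dm[tg$direction == "hypo"] < -0.1))
  expect_true(all(tg$true_dm[tg$direction == "hyper"] > 0.1))
})

test_that("expression is inversely coupled at planted genes only", {
  co <- generate_cohort(small_config(seed = 23, missing_rate = 0))
  truth <- co$truth$samples
  tg <- co$truth$genes
  g <- tg$gene[tg$direction == "hypo"][1]
  probes <- co$manifest$probe_id[co$manifest$gene == g]
  mb <- colMeans(co$beta$values[probes, truth$sample_id, drop = FALSE])
  r <- stats::cor(mb, co$expression[g, truth$sample_id])
  expect_lt(r, -0.5)

  unplanted <- setdiff(unique(co$manifest$gene), tg$gene)[1]
  probes2 <- co$manifest$probe_id[co$manifest$gene == unplanted]
  mb2 <- colMeans(co$beta$values[probes2, truth$sample_id, drop = FALSE])
  r2 <- stats::cor(mb2, co$expression[unplanted, truth$sample_id])
  expect_gt(r2, -0.3)
})

test_that("driver lesions are enriched in the planted subtype", {
  co <- generate_cohort(small_config(seed = 29))
  truth <- co$truth$samples
  mut_rate <- tapply(truth$n_mut > 0, truth$subtype == 1, mean)
  expect_gt(mut_rate[["TRUE"]], mut_rate[["FALSE"]] + 0.2)
  del_rate <- tapply(truth$gistic < 0, truth$subtype == 1, mean)
  expect_gt(del_rate[["TRUE"]], del_rate[["FALSE"]])
  # mutation table carries silent rows for the filtering stage
  expect_gt(sum(co$mutations$is_silent), 0)
})

test_that("signature overlap fraction zero behaves like a random signature", {
  cfg0 <- small_config(seed = 31, signature_overlap_frac = 0,
                       missing_rate = 0)
  co <- generate_cohort(cfg0)
  truth <- co$truth$samples
  tg <- co$truth$genes
  hypo1 <- tg$gene[tg$subtype == 1 & tg$direction == "hypo"]
  planted_cpgs <- co$manifest$probe_id[co$manifest$gene %in% hypo1]
  obs <- overlap_index(planted_cpgs, co$signature)
  expected <- length(co$signature) / nrow(co$manifest)
  # binomial SE of the observed overlap proportion
  se <- sqrt(expected * (1 - expected) / length(planted_cpgs))
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("a second cohort shares planted driver genes as configured", {
  cfg <- small_config(seed = 37)
  first <- generate_cohort(cfg)
  cfg2 <- small_config(seed = 38)
  second <- generate_second_cohort(cfg2, first, shared_fraction = 1)
  g1 <- first$truth$genes
  g2 <- second$truth$genes
  h1 <- g1$gene[g1$subtype == 1 & g1$direction == "hypo"]
  h2 <- g2$gene[g2$subtype == 1 & g2$direction == "hypo"]
  expect_setequal(h1, h2)
  expect_identical(second$signature, first$signature)
  expect_identical(second$manifest, first$manifest)

  none <- generate_second_cohort(small_config(seed = 39), first,
                                 shared_fraction = 0)
  h0 <- none$truth$genes
  expect_length(intersect(h1, h0$gene[h0$subtype == 1 &
                                        h0$direction == "hypo"]), 0)

  # determinism
  second_b <- generate_second_cohort(cfg2, first, shared_fraction = 1)
  expect_identical(second$beta$values, second_b$beta$values)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_genes = 10,
                                hypo_genes_per_subtype = c(20, 5, 5),
                                seed = 1), "infeasible")
  expect_error(generator_config(), "seed")
})
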