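make_beta <- function(vals, genes) {
  probes <- rownames(vals)
  b <- beta_matrix(vals, rep("tumor", ncol(vals)))
  manifest <- data.frame(chrom = "chr1",
                         start = seq_along(probes) * 100L,
                         probe_id = probes, gene = genes,
                         platform = "both", stringsAsFactors = FALSE)
  list(beta = b, manifest = manifest)
}

test_that("perfectly correlated probes form one cluster", {
  s <- seq(0.1, 0.9, length.out = 8)
  vals <- rbind(cg1 = s, cg2 = s * 0.8 + 0.05, cg3 = s * 0.5 + 0.2)
  colnames(vals) <- paste0("t", 1:8)
  fx <- make_beta(vals, rep("GENE1", 3))
  map <- cluster_probes(fx$beta, fx$manifest, 0.4)
  expect_length(map, 1)
  expect_setequal(map[[1]], c("cg1", "cg2", "cg3"))
})

test_that("anti-correlated probe blocks split at the hand-computed height", {
  # two blocks, within-block r = 1, between-block r = -1:
  # complete-linkage merges blocks at d = 1 - (-1) = 2, far above 0.4
  s <- seq(0.1, 0.9, length.out = 10)
  vals <- rbind(cg1 = s, cg2 = s, cg3 = 1 - s, cg4 = 1 - s)
  colnames(vals) <- paste0("t", 1:10)
  fx <- make_beta(vals, rep("G", 4))
  map <- cluster_probes(fx$beta, fx$manifest, 0.4)
  expect_length(map, 2)
  expect_setequal(lapply(unname(map), sort),
                  list(c("cg1", "cg2"), c("cg3", "cg4")))
  # a cut above the merge height of 2 gives a single cluster
  map_all <- cluster_probes(fx$beta, fx$manifest, 2)
  expect_length(map_all, 1)
})

test_that("singleton gene yields one singleton cluster", {
  vals <- matrix(seq(0.2, 0.8, length.out = 6), 1,
                 dimnames = list("cg9", paste0("t", 1:6)))
  fx <- make_beta(vals, "LONELY")
  map <- cluster_probes(fx$beta, fx$manifest, 0.4)
  expect_length(map, 1)
  expect_equal(map[["LONELY--cluster--1"]], "cg9")
})

test_that("zero-variance probes land in their own cluster with a warning", {
  s <- seq(0.1, 0.9, length.out = 6)
  vals <- rbind(cg1 = s, cg2 = rep(0.5, 6))
  colnames(vals) <- paste0("t", 1:6)
  fx <- make_beta(vals, rep("G", 2))
  expect_warning(map <- cluster_probes(fx$beta, fx$manifest, 0.4),
                 "zero-variance")
  expect_length(map, 2)
})

test_that("cluster membership and means are invariant to probe order", {
  set.seed(21)
  vals <- matrix(stats::runif(40), 8, 5,
                 dimnames = list(paste0("cg", 1:8), paste0("t", 1:5)))
  genes <- rep(c("A", "B"), each = 4)
  fx <- make_beta(vals, genes)
  map1 <- cluster_probes(fx$beta, fx$manifest, 0.4)
  perm <- sample(8)
  fx2 <- make_beta(vals[perm, ], genes[perm])
  map2 <- cluster_probes(fx2$beta, fx2$manifest, 0.4)
  sets1 <- lapply(map1, sort)
  sets2 <- lapply(map2, sort)
  expect_setequal(unname(sets1), unname(sets2))
  # align clusters by their probe membership, not by arbitrary numbering
  key1 <- vapply(map1, function(p) paste(sort(p), collapse = "+"), "")
  key2 <- vapply(map2, function(p) paste(sort(p), collapse = "+"), "")
  cb1 <- cluster_mean_beta(fx$beta, map1)
  cb2 <- cluster_mean_beta(fx2$beta, map2)
  rownames(cb1) <- key1[rownames(cb1)]
  rownames(cb2) <- key2[rownames(cb2)]
  expect_equal(cb1[sort(key1), ], cb2[sort(key1), ])
})

test_that("cut height 0 gives singletons; cut >= 2 one cluster per gene", {
  set.seed(8)
  vals <- matrix(stats::runif(30), 6, 5,
                 dimnames = list(paste0("cg", 1:6), paste0("t", 1:5)))
  fx <- make_beta(vals, rep("G", 6))
  expect_length(cluster_probes(fx$beta, fx$manifest, 0), 6)
  expect_length(cluster_probes(fx$beta, fx$manifest, 2), 1)
})

test_that("cluster_mean_beta equals a brute-force mean oracle", {
  set.seed(4)
  vals <- matrix(stats::runif(20), 4, 5,
                 dimnames = list(paste0("cg", 1:4), paste0("t", 1:5)))
  fx <- make_beta(vals, rep("G", 4))
  map <- cluster_probes(fx$beta, fx$manifest, 2)   # one 4-probe cluster
  cb <- cluster_mean_beta(fx$beta, map)
  oracle <- apply(vals, 2, mean)
  expect_equal(unname(cb[1, ]), unname(oracle), tolerance = 1e-12)

  # pair mean and singleton identity
  vals2 <- rbind(a = c(0.2, 0.2), b = c(0.4, 0.4))
  colnames(vals2) <- c("t1", "t2")
  b2 <- beta_matrix(vals2, c("tumor", "tumor"))
  map2 <- structure(list("G--cluster--1" = c("a", "b")),
                    gene = c("G--cluster--1" = "G"),
                    class = "probe_cluster_map")
  expect_equal(unname(cluster_mean_beta(b2, map2)[1, ]), c(0.3, 0.3))
  map3 <- structure(list("G--cluster--1" = "a"),
                    gene = c("G--cluster--1" = "G"),
                    class = "probe_cluster_map")
  expect_equal(cluster_mean_beta(b2, map3)[1, ], vals2["a", ])
  map_bad <- structure(list("G--cluster--1" = c("a", "zz")),
                       gene = c("G--cluster--1" = "G"),
                       class = "probe_cluster_map")
  expect_error(cluster_mean_beta(b2, map_bad), "absent")
})
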