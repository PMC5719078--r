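test_that("SAM d equals the two-sample t statistic when s0 = 0", {
  set.seed(1)
  m <- matrix(stats::rnorm(20 * 12), 20, 12)
  g <- rep(c("a", "b"), each = 6)
  res <- sam_test(m, g, n_permutations = 50, s0 = 0)
  oracle <- apply(m, 1, function(r)
    stats::t.test(r[g == "a"], r[g == "b"], var.equal = TRUE)$statistic)
  expect_equal(res$d, unname(oracle), tolerance = 1e-10)
})

test_that("SAM d is antisymmetric under group swap", {
  set.seed(2)
  m <- matrix(stats::rnorm(15 * 10), 15, 10)
  g <- rep(c("g1", "g2"), each = 5)
  d1 <- sam_test(m, g, n_permutations = 50, seed = 3)$d
  swapped <- ifelse(g == "g1", "g2", "g1")
  d2 <- sam_test(m, swapped, n_permutations = 50, seed = 3)$d
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("SAM q-values are near 1 under the null and find planted shifts", {
  set.seed(4)
  m0 <- matrix(stats::rnorm(500 * 20), 500, 20)
  g <- rep(c("a", "b"), each = 10)
  null_res <- sam_test(m0, g, n_permutations = 100, seed = 5)
  expect_lt(mean(abs(null_res$d)), 0.5)
  expect_gte(mean(null_res$q > 0.5), 0.90)
  expect_true(all(null_res$q >= 0 & null_res$q <= 1))

  # planted 2-SD shift in 50 of 1000 features, n = 30 + 30
  set.seed(6)
  m1 <- matrix(stats::rnorm(1000 * 60), 1000, 60)
  g2 <- rep(c("a", "b"), each = 30)
  m1[1:50, g2 == "a"] <- m1[1:50, g2 == "a"] + 2
  res <- sam_test(m1, g2, n_permutations = 100, seed = 7)
  expect_gte(mean(res$q[1:50] < 0.1), 0.8)
  expect_lt(mean(res$q[51:1000] < 0.1), 0.1)
  expect_warning(sam_test(m0[1:20, ], g, n_permutations = 20), "unstable")
})

test_that("wilcoxon exact p matches full enumeration on small samples", {
  # oracle: enumerate all rank splits of {1..6} into two triples
  vals <- 1:6
  splits <- utils::combn(6, 3)
  obs_w <- sum(rank(vals)[4:6]) # ranks of y = {4,5,6}
  stat <- apply(splits, 2, function(ix) sum(rank(vals)[ix]))
  p_oracle <- mean(abs(stat - mean(stat)) >= abs(obs_w - mean(stat)))
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p, 1)
  x <- stats::rnorm(200)
  expect_lt(wilcoxon_rank_sum(x + 2, x)$p, 1e-6)
  expect_equal(wilcoxon_rank_sum(1:10, 1:10)$p, 1, tolerance = 0.01)
})

test_that("patient correlation matrix behaves on exact and null profiles", {
  set.seed(8)
  a <- matrix(stats::rnorm(621 * 3), 621,
              dimnames = list(paste0("cg", 1:621), paste0("h", 1:3)))
  ids <- rownames(a)
  r <- patient_correlation_matrix(a, a, ids)
  expect_equal(unname(diag(r)), rep(1, 3), tolerance = 1e-12)
  neg <- -(a - mean(a))
  rownames(neg) <- ids
  r2 <- patient_correlation_matrix(a, neg, ids)
  expect_lt(max(diag(r2)), -0.99)

  b <- matrix(stats::rnorm(621 * 100), 621,
              dimnames = list(ids, paste0("l", 1:100)))
  rn <- patient_correlation_matrix(a[, 1, drop = FALSE], b, ids)
  expect_lt(mean(abs(rn)), 0.1)

  flat <- matrix(0.5, 621, 1, dimnames = list(ids, "z"))
  expect_warning(rf <- patient_correlation_matrix(a, flat, ids),
                 "zero-variance")
  expect_true(all(is.na(rf)))
  expect_error(patient_correlation_matrix(a[1:2, ], b[1:2, ], ids[1:2]),
               ">= 3")
})

test_that("lesion score is the literal mutation-plus-inverse-gistic formula", {
  expect_equal(lesion_score(1, -1), 2L)
  expect_equal(lesion_score(0, 0), 0L)
  expect_equal(lesion_score(2, -2), 4L)
  expect_warning(s <- lesion_score(0, 1), "amplification")
  expect_equal(s, -1L)
  expect_error(lesion_score(0, 3))

  mut <- data.frame(sample_id = c("s1", "s1", "s2"), gene = "NSD1",
                    is_silent = FALSE)
  cn <- data.frame(sample_id = c("s1", "s3"), gene = "NSD1",
                   gistic_score = c(-2L, -1L))
  lt <- lesion_table(mut, cn, "NSD1", samples = c("s1", "s2", "s3"))
  expect_equal(lt$lesion_score, c(4L, 1L, 1L))
})

test_that("overlap index is exact set arithmetic, order-invariant", {
  expect_equal(overlap_index(c("a", "b", "c", "d"), c("b", "d", "z")), 0.5)
  expect_equal(overlap_index(c("d", "c", "b", "a"), c("z", "d", "b")), 0.5)
  expect_equal(overlap_index(c("a", "b"), c("x", "y")), 0)
  expect_equal(overlap_index(c("a", "b"), c("a", "b", "c")), 1)
  expect_warning(v <- overlap_index(character(0), "a"), "empty")
  expect_true(is.na(v))
})

test_that("random overlap index matches its hypergeometric expectation", {
  universe <- paste0("cg", 1:100)
  hypo <- universe[1:10]
  expect_equal(random_overlap_index(hypo, universe, 100, seed = 1), 1)
  expect_equal(random_overlap_index(hypo, universe, 0, seed = 1), 0)
  expect_error(random_overlap_index(hypo, universe, 101), "exceeds")

  means <- vapply(1:200, function(s)
    random_overlap_index(hypo, universe, 20, n_draws = 10, seed = s),
    numeric(1))
  # E = m/N = 0.2; SE of the grand mean from hypergeometric variance
  v1 <- 20 * (10 / 100) * (90 / 100) * (80 / 99) / 100
  se <- sqrt(v1 / (200 * 10))
  expect_lt(abs(mean(means) - 0.2), 3 * se)
})

test_that("lesion-overlap association recovers exact and null slopes", {
  score <- c(0, 1, 2, 3, 4, 0, 1, 2)
  # exact fit: summary.lm warns about a perfect fit, which is the point
  fit <- suppressWarnings(lesion_overlap_association(score, 0.1 * score))
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  expect_lt(fit$p, 1e-10)
  expect_error(lesion_overlap_association(rep(1, 5), stats::runif(5)),
               "constant")

  set.seed(9)
  rej <- vapply(1:500, function(s) {
    x <- sample(0:4, 50, replace = TRUE)
    y <- stats::runif(50)
    lesion_overlap_association(x, y)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("t-cell score averages available signature genes", {
  e <- matrix(5, length(TCELL_GENES), 3,
              dimnames = list(TCELL_GENES, c("s1", "s2", "s3")))
  expect_equal(unname(tcell_score(e)), rep(5, 3))
  e1 <- e["CD8A", , drop = FALSE]
  expect_message(sc <- tcell_score(e1), "absent")
  expect_equal(unname(sc), unname(e1[1, ]))
  expect_error(tcell_score(e1[0, , drop = FALSE]), "no signature genes")

  # the packaged gene list matches the exported constant
  shipped <- readLines(system.file("extdata", "tcell_signature_genes.txt",
                                   package = "methsub"))
  expect_equal(shipped, TCELL_GENES)
})

test_that("fraction_percent uses half-up integer rounding", {
  expect_equal(fraction_percent(24, 42), 57L)
  expect_equal(fraction_percent(21, 33), 64L)
  expect_equal(fraction_percent(0, 10), 0L)
  expect_equal(fraction_percent(1, 8), 13L)   # 12.5 rounds up
  expect_error(fraction_percent(1, 0), "positive")
  expect_error(fraction_percent(5, 4))
})
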