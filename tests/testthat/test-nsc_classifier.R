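sep_data <- function(n = 30, p = 20, gap = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  lab <- rep(c("A", "B"), length.out = n)
  x[lab == "A", 1] <- x[lab == "A", 1] + gap
  list(x = x, lab = lab)
}

test_that("only the informative feature survives shrinkage", {
  d <- sep_data(n = 40, gap = 4)
  m <- train_nsc(d$x, d$lab, seed = 2)
  expect_true("f1" %in% m$selected)
  expect_lte(length(m$selected), 3)
  acc <- mean(predict_nsc(m, d$x)$class == d$lab)
  expect_gt(acc, 0.95)
})

test_that("full shrinkage collapses posteriors to the priors", {
  d <- sep_data()
  st <- methsub:::nsc_stats(d$x, d$lab)
  m <- train_nsc(d$x, d$lab, delta = max(abs(st$d)) + 1)
  expect_length(m$selected, 0)
  post <- predict_nsc(m, d$x)$posterior
  expect_true(all(abs(post - 0.5) < 1e-12))
})

test_that("single-class labels are rejected", {
  d <- sep_data()
  expect_error(train_nsc(d$x, rep("A", nrow(d$x))), "2 classes")
})

test_that("NSC at delta 0 matches brute-force nearest-centroid classification", {
  # oracle: independent diagonal-covariance nearest-centroid implementation
  d <- sep_data(n = 20, p = 8, gap = 2, seed = 3)
  m <- train_nsc(d$x, d$lab, delta = 0)
  x <- d$x; lab <- d$lab
  cents <- rbind(colMeans(x[lab == "A", ]), colMeans(x[lab == "B", ]))
  ss <- colSums((x[lab == "A", ] - cents[rep(1, sum(lab == "A")), ])^2) +
        colSums((x[lab == "B", ] - cents[rep(2, sum(lab == "B")), ])^2)
  s <- sqrt(ss / (nrow(x) - 2))
  s0 <- stats::median(s)
  score <- sapply(1:2, function(k)
    apply(x, 1, function(r) sum(((r - cents[k, ]) / (s + s0))^2)))
  oracle_class <- c("A", "B")[apply(score, 1, which.min)]
  oracle_post <- t(apply(-score / 2, 1, function(z) {
    e <- exp(z - max(z)); e / sum(e)
  }))
  pred <- predict_nsc(m, x)
  expect_equal(pred$class, oracle_class)
  expect_equal(unname(pred$posterior), unname(oracle_post),
               tolerance = 1e-10)
})

test_that("feature survival is non-increasing in delta", {
  d <- sep_data(n = 40, p = 30, gap = 2, seed = 4)
  st <- methsub:::nsc_stats(d$x, d$lab)
  deltas <- seq(0, max(abs(st$d)), length.out = 12)
  counts <- vapply(deltas, function(dd)
    length(train_nsc(d$x, d$lab, delta = dd)$selected), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("AUC is rank-based and agrees with pROC", {
  set.seed(6)
  scores <- stats::rnorm(60)
  truth <- stats::runif(60) < stats::plogis(2 * scores)
  a1 <- auc_score(scores, truth)
  expect_equal(auc_score(exp(scores), truth), a1, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  a2 <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("cross-validation separates a separable subtype perfectly", {
  d <- sep_data(n = 60, p = 15, gap = 8, seed = 7)
  cv <- cross_validate(d$x, d$lab, positive = "A", n_folds = 10, seed = 8,
                       n_boot = 200)
  expect_equal(cv$auc, 1.0)
  expect_true(all(cv$fold_auc == 1))
  expect_true(all(table(cv$folds) > 0))
  # leave-one-out mechanics: per-sample probabilities all present
  loo <- cross_validate(d$x[1:20, ], d$lab[1:20], positive = "A",
                        n_folds = 20, seed = 8, n_boot = 50)
  expect_false(anyNA(loo$probabilities))
})

test_that("permuted labels give chance-level AUC", {
  d <- sep_data(n = 60, p = 15, gap = 4, seed = 9)
  set.seed(10)
  aucs <- vapply(1:20, function(s) {
    cross_validate(d$x, sample(d$lab), positive = "A", n_folds = 5,
                   seed = s, n_boot = 50)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("transfer calls respect the strict confidence boundaries", {
  # full-shrinkage model with chosen priors produces known posteriors
  mk_model <- function(p_pos) {
    structure(list(
      overall = c(f1 = 0), centroids = matrix(0, 1, 2,
        dimnames = list("f1", c("neg", "pos"))),
      sd = c(f1 = 1), d_shrunk = matrix(0, 1, 2,
        dimnames = list("f1", c("neg", "pos"))),
      delta = 1, priors = c(neg = 1 - p_pos, pos = p_pos),
      classes = c("neg", "pos"), selected = character(0)),
      class = "nsc_model")
  }
  feats <- matrix(0, 1, 1, dimnames = list("s1", "f1"))
  expect_equal(transfer_classify(mk_model(0.5), feats, "pos")$call,
               "abstain")
  expect_equal(transfer_classify(mk_model(0.61), feats, "pos")$call,
               "positive")
  expect_equal(transfer_classify(mk_model(0.60), feats, "pos")$call,
               "abstain")  # > 0.60 is strict
  expect_equal(transfer_classify(mk_model(0.39), feats, "pos")$call,
               "other")
})

test_that("transfer imputes absent features and needs feature overlap", {
  d <- sep_data(n = 40, p = 10, gap = 3, seed = 11)
  m <- train_nsc(d$x, d$lab, seed = 12)
  other <- d$x[1:5, 1:6]
  expect_warning(res <- transfer_classify(m, other, "A"), "imputed")
  expect_equal(nrow(res), 5)
  none <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("z1", "z2")))
  expect_error(transfer_classify(m, none, "A"), "overlapping")
})

test_that("minimal panels keep performance and pick the stronger feature", {
  set.seed(13)
  n <- 60
  x <- matrix(stats::rnorm(n * 50), n, 50,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:50)))
  lab <- rep(c("A", "B"), each = n / 2)
  for (j in 1:5) x[lab == "A", j] <- x[lab == "A", j] + 3
  pan <- minimal_panel(x, lab, 5, positive = "A", seed = 14)
  expect_lte(length(pan$panel), 5)
  expect_setequal(pan$panel, paste0("f", 1:5))
  expect_gte(pan$cv$auc, 0.95)
  expect_true(all(pan$stability >= 0.5))

  # n_features = all equals the unshrunk model
  full <- minimal_panel(x, lab, 50, positive = "A", seed = 14)
  expect_equal(full$model$centroids,
               train_nsc(x, lab, delta = 0)$centroids)

  # one feature: the larger effect wins
  x2 <- matrix(stats::rnorm(n * 2), n, 2,
               dimnames = list(paste0("s", 1:n), c("weak", "strong")))
  x2[lab == "A", "weak"] <- x2[lab == "A", "weak"] + 1
  x2[lab == "A", "strong"] <- x2[lab == "A", "strong"] + 4
  pan1 <- minimal_panel(x2, lab, 1, positive = "A", n_folds = 5, seed = 15)
  expect_equal(pan1$panel, "strong")
})
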