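#' Train a nearest-shrunken-centroid (PAM-style) classifier
#'
#' Standard NSC fit: per-feature class centroids are standardized against
#' the overall centroid using the pooled within-class standard deviation
#' s_i plus the offset s0 (median of the s_i), soft-thresholded by the
#' shrinkage Delta, and used for classification via discriminant scores
#' with class priors. Delta is chosen by inner cross-validation minimizing
#' misclassification error (largest Delta on ties, for parsimony), unless
#' `delta` fixes it.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Class labels, >= 2 classes with >= 2 samples each.
#' @param delta_grid Candidate shrinkage values; default 30 values spanning
#'   0 to the largest |standardized centroid difference|.
#' @param delta Optional fixed shrinkage (skips inner CV).
#' @param priors `"equal"` (default) or `"empirical"` class priors.
#' @param inner_folds Folds for the inner CV (default 5).
#' @param seed Seed for the inner CV folds.
#' @return A `nsc_model`: list with `overall`, `centroids` (shrunken,
#'   features x classes), `sd` (s_i + s0), `d_shrunk`, `delta`, `priors`,
#'   `classes`, `selected` (features with a nonzero shrunken difference).
#' @export
train_nsc <- function(features, labels, delta_grid = NULL, delta = NULL,
                      priors = c("equal", "empirical"), inner_folds = 5,
                      seed = 1) {
  priors <- match.arg(priors)
  labels <- as.character(labels)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples")

  if (is.null(delta)) {
    if (is.null(delta_grid)) {
      d0 <- nsc_stats(features, labels)$d
      delta_grid <- seq(0, max(abs(d0)), length.out = 30)
    }
    delta <- nsc_select_delta(features, labels, delta_grid, priors,
                              inner_folds, seed)
  }
  nsc_fit(features, labels, delta, priors)
}

# Raw NSC sufficient statistics (Tibshirani 2002).
nsc_stats <- function(features, labels) {
  x <- t(features)                       # features x samples
  classes <- sort(unique(labels))
  n <- ncol(x); K <- length(classes)
  nk <- table(labels)[classes]
  overall <- rowMeans(x)
  cents <- vapply(classes, function(k) rowMeans(x[, labels == k, drop = FALSE]),
                  numeric(nrow(x)))
  ss <- 0
  for (k in classes)
    ss <- ss + rowSums((x[, labels == k, drop = FALSE] - cents[, k])^2)
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(cents - overall, 1, s + s0, "/")
  d <- sweep(d, 2, mk, "/")
  list(overall = overall, centroids = cents, s = s, s0 = s0, mk = mk,
       d = d, classes = classes, nk = nk)
}

nsc_fit <- function(features, labels, delta, priors) {
  nsc_fit_from_stats(nsc_stats(features, labels), delta, priors)
}

# Soft-threshold precomputed statistics at one delta (cheap, so a delta
# grid can reuse one nsc_stats pass).
nsc_fit_from_stats <- function(st, delta, priors) {
  d_shr <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  cents <- st$overall + sweep(sweep(d_shr, 2, st$mk, "*"), 1,
                              st$s + st$s0, "*")
  pr <- if (priors == "equal") {
    rep(1 / length(st$classes), length(st$classes))
  } else as.numeric(st$nk) / sum(st$nk)
  names(pr) <- st$classes
  structure(list(overall = st$overall, centroids = cents,
                 sd = st$s + st$s0, d_shrunk = d_shr, delta = delta,
                 priors = pr, classes = st$classes,
                 selected = rownames(d_shr)[rowSums(d_shr != 0) > 0]),
            class = "nsc_model")
}

nsc_select_delta <- function(features, labels, delta_grid, priors,
                             inner_folds, seed) {
  folds <- stratified_folds(labels, min(inner_folds, min(table(labels))),
                            seed)
  errs <- numeric(length(delta_grid))
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2) next
    st <- nsc_stats(features[tr, , drop = FALSE], labels[tr])
    for (di in seq_along(delta_grid)) {
      m <- nsc_fit_from_stats(st, delta_grid[di], priors)
      pred <- predict_nsc(m, features[!tr, , drop = FALSE])
      errs[di] <- errs[di] + sum(pred$class != labels[!tr])
    }
  }
  # ties -> largest delta (fewest features)
  max(delta_grid[errs == min(errs)])
}

#' Posterior class probabilities from a shrunken-centroid model
#'
#' Discriminant score per class: squared standardized distance to the
#' shrunken centroid minus twice the log prior; posteriors via softmax of
#' -score/2.
#'
#' @param model An `nsc_model`.
#' @param features Numeric matrix, samples x features, using the training
#'   feature names.
#' @return List with `posterior` (samples x classes) and `class` (argmax).
#' @export
predict_nsc <- function(model, features) {
  stopifnot(inherits(model, "nsc_model"))
  # features with fully shrunken differences contribute equally to every
  # class score and cancel in the posterior; skip them
  sel <- rowSums(model$d_shrunk != 0) > 0
  if (!any(sel)) {
    post <- matrix(rep(model$priors, each = nrow(features)),
                   nrow(features), length(model$classes),
                   dimnames = list(rownames(features), model$classes))
    return(list(posterior = post,
                class = model$classes[max.col(post, ties.method = "first")]))
  }
  features <- features[, names(model$overall)[sel], drop = FALSE]
  cents <- model$centroids[sel, , drop = FALSE]
  sds <- model$sd[sel]
  scores <- vapply(model$classes, function(k) {
    z <- sweep(features, 2, cents[, k])
    z <- sweep(z, 2, sds, "/")
    rowSums(z^2) - 2 * log(model$priors[k])
  }, numeric(nrow(features)))
  if (nrow(features) == 1) scores <- matrix(scores, nrow = 1,
                                            dimnames = list(rownames(features),
                                                            model$classes))
  lp <- -scores / 2
  post <- exp(lp - apply(lp, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  list(posterior = post,
       class = model$classes[max.col(post, ties.method = "first")])
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("nsc_model: %d classes, delta = %.3f, %d/%d features selected\n",
              length(x$classes), x$delta, length(x$selected),
              length(x$overall)))
  invisible(x)
}

# Stratified fold ids (1..n_folds), shuffled deterministically per seed.
stratified_folds <- function(labels, n_folds, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  folds <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- sample(which(labels == k))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores for a binary truth vector;
#' equivalent to the trapezoid rule on the empirical ROC and invariant
#' under monotone transformation of the scores.
#'
#' @param scores Numeric vector.
#' @param truth Logical vector (TRUE = positive).
#' @return AUC in \[0,1\].
#' @export
auc_score <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated evaluation of the NSC subtype classifier
#'
#' Stratified `n_folds` cross-validation: per fold the model is trained on
#' the remaining samples (with inner Delta selection unless `delta` is
#' fixed) and held-out posteriors for the positive class are recorded.
#' Reports both the pooled-score AUC and the mean of per-fold AUCs, with a
#' bootstrap CI on the pooled AUC.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Class labels.
#' @param positive The positive class (default: rarest class).
#' @param n_folds Number of folds (default 10); `n_folds = n` gives
#'   leave-one-out.
#' @param seed Integer seed (folds and bootstrap).
#' @param delta Optional fixed shrinkage.
#' @param n_boot Bootstrap resamples for the AUC CI (default 2000).
#' @return A `cv_report`: list with `probabilities` (per-sample held-out
#'   posterior of the positive class), `folds`, `auc` (pooled), `auc_ci`,
#'   `fold_auc`, `mean_fold_auc`, `n_features_used` per fold, `positive`.
#' @export
cross_validate <- function(features, labels, positive = NULL, n_folds = 10,
                           seed = 1, delta = NULL, n_boot = 2000) {
  labels <- as.character(labels)
  stopifnot(n_folds >= 2, nrow(features) == length(labels))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.null(positive)) positive <- names(which.min(table(labels)))
  folds <- stratified_folds(labels, n_folds, seed)
  prob <- rep(NA_real_, length(labels))
  fold_auc <- rep(NA_real_, n_folds)
  nfeat <- rep(NA_integer_, n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2)
      stop("training fold lost a class; reduce n_folds")
    m <- train_nsc(features[tr, , drop = FALSE], labels[tr],
                   delta = delta, seed = seed + f)
    p <- predict_nsc(m, features[!tr, , drop = FALSE])$posterior
    prob[!tr] <- p[, positive]
    nfeat[f] <- length(m$selected)
    fold_auc[f] <- auc_score(p[, positive], labels[!tr] == positive)
  }
  pooled <- auc_score(prob, labels == positive)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(prob), replace = TRUE)
    auc_score(prob[idx], (labels == positive)[idx])
  }, numeric(1))
  structure(list(probabilities = stats::setNames(prob, rownames(features)),
                 folds = folds, auc = pooled,
                 auc_ci = stats::quantile(boot, c(0.025, 0.975),
                                          na.rm = TRUE, names = FALSE),
                 fold_auc = fold_auc,
                 mean_fold_auc = mean(fold_auc, na.rm = TRUE),
                 n_features_used = nfeat, positive = positive),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report: pooled AUC = %.3f (95%% CI %.3f-%.3f), mean fold AUC = %.3f\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$mean_fold_auc))
  invisible(x)
}

#' Classify another cohort with a confidence-abstention rule
#'
#' Applies a trained model to a second cohort, restricting to the shared
#' features (absent features, and missing cells within shared features,
#' are imputed with the overall centroid value, with a warning). A sample is called `positive` when its posterior for
#' the positive class strictly exceeds `conf_high`, `other` when strictly
#' below `conf_low`, and `abstain` otherwise.
#'
#' @param model An `nsc_model`.
#' @param features_other Numeric matrix, samples x features, of the other
#'   cohort.
#' @param positive The positive class name.
#' @param conf_low,conf_high Abstention band (defaults 0.40 / 0.60).
#' @return data.frame with `sample_id`, `p` (posterior of positive),
#'   `call` in \{positive, other, abstain\}.
#' @export
transfer_classify <- function(model, features_other, positive,
                              conf_low = 0.40, conf_high = 0.60) {
  stopifnot(inherits(model, "nsc_model"), positive %in% model$classes)
  shared <- intersect(names(model$overall), colnames(features_other))
  if (length(shared) == 0) stop("no overlapping features between cohorts")
  missing <- setdiff(names(model$overall), shared)
  x <- matrix(rep(model$overall, each = nrow(features_other)),
              nrow(features_other), length(model$overall),
              dimnames = list(rownames(features_other), names(model$overall)))
  x[, shared] <- features_other[, shared]
  if (length(missing) > 0)
    warning(sprintf("%d model features absent; imputed by overall centroid",
                    length(missing)))
  na_cells <- which(is.na(x))
  if (length(na_cells) > 0) {
    x[na_cells] <- model$overall[col(x)[na_cells]]
    warning(sprintf("%d missing cells imputed by overall centroid",
                    length(na_cells)))
  }
  p <- predict_nsc(model, x)$posterior[, positive]
  call <- ifelse(p > conf_high, "positive",
                 ifelse(p < conf_low, "other", "abstain"))
  data.frame(sample_id = rownames(features_other), p = p, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict the classifier to a minimal feature panel
#'
#' Raises the shrinkage Delta until at most `n_features` features survive
#' soft-thresholding, then reports cross-validated performance of the
#' restricted model and per-feature selection stability across folds.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Class labels.
#' @param n_features Maximum panel size (>= 1).
#' @param positive Positive class for the AUC (default: rarest).
#' @param n_folds,seed Passed to [cross_validate()].
#' @return List with `model` (restricted `nsc_model`), `cv` (`cv_report`),
#'   `panel` (selected feature ids), `stability` (named fraction of folds
#'   selecting each panel feature).
#' @export
minimal_panel <- function(features, labels, n_features, positive = NULL,
                          n_folds = 10, seed = 1) {
  stopifnot(n_features >= 1)
  labels <- as.character(labels)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.null(positive)) positive <- names(which.min(table(labels)))
  st <- nsc_stats(features, labels)
  dmax <- apply(abs(st$d), 1, max)
  ds <- sort(dmax, decreasing = TRUE)
  delta <- if (n_features >= length(ds)) 0 else ds[n_features + 1]
  model <- nsc_fit(features, labels, delta, "equal")
  cv <- cross_validate(features, labels, positive = positive,
                       n_folds = n_folds, seed = seed, delta = delta)
  folds <- stratified_folds(labels, n_folds, seed)
  sel <- sapply(seq_len(n_folds), function(f) {
    m <- nsc_fit(features[folds != f, , drop = FALSE], labels[folds != f],
                 delta, "equal")
    names(model$overall) %in% m$selected
  })
  stability <- stats::setNames(rowMeans(sel), names(model$overall))
  list(model = model, cv = cv, panel = model$selected,
       stability = stability[model$selected])
}
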