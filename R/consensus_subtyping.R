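#' Consensus k-means clustering of tumor samples
#'
#' For each k in 2..`k_max`, runs `n_reps` k-means clusterings on random
#' subsamples of the rows (samples) and records, for every sample pair, the
#' fraction of co-sampled runs in which the pair was co-clustered. Final
#' assignments per k come from average-linkage hierarchical clustering of
#' 1 - consensus. Deterministic given `seed`.
#'
#' @param features Numeric matrix, samples x features (e.g. from
#'   [dm_feature_matrix()]).
#' @param k_max Maximum number of clusters (default 10); needs at least
#'   3 * `k_max` samples.
#' @param n_reps Resampling rounds per k (default 1000).
#' @param subsample_frac Fraction of samples drawn per round (default 0.8).
#' @param seed Integer seed.
#' @param nstart k-means restarts per round (default 1; the resampling
#'   itself averages over initializations).
#' @return A `consensus_result`: list with `consensus` (list of
#'   samples x samples matrices, one per k), `assignments` (list of named
#'   integer vectors per k), `pac` (named numeric per k), `chosen_k`, and
#'   `k_values`.
#' @export
consensus_cluster <- function(features, k_max = 10, n_reps = 1000,
                              subsample_frac = 0.8, seed = 1,
                              nstart = 1) {
  stopifnot(is.matrix(features), all(is.finite(features)))
  if (k_max < 2) stop("k_max must be at least 2")
  n <- nrow(features)
  if (n < 3 * k_max)
    stop(sprintf("need >= %d samples for k_max = %d", 3 * k_max, k_max))
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m_sub <- max(2, round(subsample_frac * n))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  ks <- 2:k_max
  consensus <- vector("list", length(ks))
  names(consensus) <- as.character(ks)
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    co_clust <- matrix(0, n, n)
    co_samp <- matrix(0, n, n)
    for (rep in seq_len(n_reps)) {
      idx <- sort(sample.int(n, m_sub))
      lab <- kmeans_labels(features[idx, , drop = FALSE], k, nstart)
      Z <- matrix(0, length(idx), max(lab))
      Z[cbind(seq_along(lab), lab)] <- 1
      co_clust[idx, idx] <- co_clust[idx, idx] + tcrossprod(Z)
      co_samp[idx, idx] <- co_samp[idx, idx] + 1
    }
    off <- upper.tri(co_samp)
    if (any(co_samp[off] == 0))
      stop("some sample pairs never co-sampled; increase n_reps")
    M <- co_clust / co_samp
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    consensus[[ki]] <- M
  }

  assignments <- lapply(seq_along(ks), function(ki) {
    hc <- stats::hclust(stats::as.dist(1 - consensus[[ki]]),
                        method = "average")
    stats::setNames(stats::cutree(hc, k = ks[ki]), ids)
  })
  names(assignments) <- as.character(ks)
  pac <- vapply(consensus, pac_score, numeric(1))
  res <- structure(list(consensus = consensus, assignments = assignments,
                        pac = pac, k_values = ks),
                   class = "consensus_result")
  res$chosen_k <- suppressWarnings(select_k(res))
  res
}

# k-means labels with k-means++ seeding and a degenerate-data fallback
# (fewer distinct points than centers => a single trivial cluster).
kmeans_labels <- function(x, k, nstart) {
  if (nrow(unique(x)) <= k) return(rep(1L, nrow(x)))
  best <- NULL
  for (r in seq_len(nstart)) {
    km <- tryCatch(
      stats::kmeans(x, centers = x[kmeanspp_seeds(x, k), , drop = FALSE],
                    iter.max = 50),
      error = function(e) stats::kmeans(x, centers = k, iter.max = 50))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

# k-means++ seeding: centers drawn with probability proportional to the
# squared distance from the nearest chosen center.
kmeanspp_seeds <- function(x, k) {
  n <- nrow(x)
  seeds <- sample.int(n, 1)
  d2 <- rowSums((x - x[rep(seeds, n), , drop = FALSE])^2)
  while (length(seeds) < k) {
    if (all(d2 == 0)) {
      seeds <- c(seeds, sample.int(n, k - length(seeds)))
      break
    }
    s <- sample.int(n, 1, prob = d2)
    seeds <- c(seeds, s)
    d2 <- pmin(d2, rowSums((x - x[rep(s, n), , drop = FALSE])^2))
  }
  unique(seeds)[seq_len(k)]
}

# Proportion of ambiguous clustering: off-diagonal consensus entries
# strictly inside (lower, upper).
pac_score <- function(M, lower = 0.1, upper = 0.9) {
  v <- M[upper.tri(M)]
  mean(v > lower & v < upper)
}

#' Select the number of clusters by minimum PAC
#'
#' The proportion of ambiguous clustering (PAC) is the fraction of
#' off-diagonal consensus entries in (0.1, 0.9); the k minimizing PAC is
#' chosen (smallest k on ties). When no k achieves a reasonably crisp
#' consensus (every PAC above `ambiguous_min`) or the PAC profile is
#' nearly flat, there is no evidence of structure: k = 2 is returned with
#' a warning to inspect the consensus CDFs.
#'
#' @param result A `consensus_result`.
#' @param flat_tol PAC range below which the profile counts as flat
#'   (default 0.05).
#' @param ambiguous_min Minimum PAC above which every k counts as
#'   ambiguous (default 0.3).
#' @return The chosen k (integer).
#' @export
select_k <- function(result, flat_tol = 0.05, ambiguous_min = 0.3) {
  stopifnot(inherits(result, "consensus_result"))
  pac <- result$pac
  if (diff(range(pac)) < flat_tol || min(pac) > ambiguous_min) {
    warning("no clear cluster structure in the PAC profile - ",
            "returning k = 2, inspect consensus CDFs")
    return(result$k_values[1])
  }
  result$k_values[which.min(pac)]
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d samples, k in %d..%d, chosen k = %d\n",
              nrow(x$consensus[[1]]), min(x$k_values), max(x$k_values),
              x$chosen_k))
  print(round(x$pac, 3))
  invisible(x)
}

#' Chi-squared enrichment of a binary trait in a subtype
#'
#' Pearson's chi-squared test (without continuity correction) of a 2x2
#' table: trait presence versus membership in the focal subtype. A 2x2
#' count matrix may be passed directly as the first argument.
#'
#' @param subtype_labels Vector of subtype assignments, or a 2x2 count
#'   matrix.
#' @param binary_trait Logical vector per sample (ignored for matrix
#'   input).
#' @param subtype The focal subtype value defining "in-subtype".
#' @return List with `statistic`, `p`, `table`.
#' @export
enrichment_test <- function(subtype_labels, binary_trait = NULL,
                            subtype = NULL) {
  if (is.matrix(subtype_labels)) {
    tab <- subtype_labels
    stopifnot(all(dim(tab) == c(2, 2)))
  } else {
    if (length(unique(subtype_labels)) < 2)
      stop("need at least 2 subtypes")
    stopifnot(length(binary_trait) == length(subtype_labels))
    if (is.null(subtype)) stop("focal subtype must be given")
    tab <- table(factor(subtype_labels == subtype, levels = c(TRUE, FALSE)),
                 factor(binary_trait, levels = c(TRUE, FALSE)))
    tab <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Consensus CDF summary per k
#'
#' Empirical CDFs of the off-diagonal consensus entries, the display used
#' to judge cluster stability.
#'
#' @param result A `consensus_result`.
#' @param at Evaluation grid in \[0,1\].
#' @return data.frame with columns `k`, `index`, `cdf`.
#' @export
consensus_cdf <- function(result, at = seq(0, 1, by = 0.01)) {
  do.call(rbind, lapply(seq_along(result$k_values), function(ki) {
    v <- result$consensus[[ki]][upper.tri(result$consensus[[ki]])]
    data.frame(k = result$k_values[ki], index = at,
               cdf = stats::ecdf(v)(at))
  }))
}
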