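#' T-cell expression signature genes
#'
#' The 13 T-cell transcripts whose mean expression is used as a relative
#' T-cell infiltration score. Also shipped as a text file under
#' `inst/extdata/tcell_signature_genes.txt`.
#' @export
TCELL_GENES <- c("CD8A", "CCL2", "CCL3", "CCL4", "CXCL9", "CXCL10",
                 "ICOS", "GZMK", "IRF1", "HLA-DMA", "HLA-DMB",
                 "HLA-DOA", "HLA-DOB")

#' SAM-style moderated two-group test with permutation q-values
#'
#' Per feature, the statistic d_i = (mean1 - mean2) / (s_i + s0) where s_i
#' is the two-sample pooled standard error and s0 (default: median of the
#' s_i) the exchangeability offset. Null statistics come from label
#' permutations; the q-value of a feature uses the SAM median-false-positive
#' convention: the median across permutations of the number of null |d*|
#' at or above |d_i|, divided by the observed count at or above |d_i|,
#' clamped to \[0,1\] and made monotone in |d|.
#'
#' @param matrix Numeric matrix, features x samples.
#' @param group_labels Two-group vector over samples; group order follows
#'   `sort(unique(...))`, with d > 0 meaning higher in the first group.
#' @param n_permutations Number of label permutations (default 200; fewer
#'   than 50 warns about unstable q-values).
#' @param seed Integer seed for permutations.
#' @param s0 Optional fixed exchangeability constant.
#' @return data.frame with `feature`, `d`, `s`, `q`, `direction`; attribute
#'   `s0` records the offset used.
#' @export
sam_test <- function(matrix, group_labels, n_permutations = 200, seed = 1,
                     s0 = NULL) {
  stopifnot(is.matrix(matrix), ncol(matrix) == length(group_labels))
  groups <- sort(unique(as.character(group_labels)))
  if (length(groups) != 2) stop("exactly two groups required")
  g1 <- group_labels == groups[1]
  if (sum(g1) < 3 || sum(!g1) < 3) stop("each group needs n >= 3")
  if (n_permutations < 50) warning("n_permutations < 50: unstable q-values")

  stat <- sam_d(matrix, g1, s0)
  d <- stat$d

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- ncol(matrix)
  abs_d <- abs(d)
  # per permutation: count of null |d*| >= each observed threshold
  fp <- matrix(0L, length(d), n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    db <- sort(abs(sam_d(matrix, g1[perm], stat$s0)$d))
    fp[, b] <- length(db) - findInterval(abs_d, db, left.open = TRUE)
  }
  med_fp <- apply(fp, 1, stats::median)
  obs <- vapply(abs_d, function(t) sum(abs_d >= t), integer(1))
  q_raw <- pmin(med_fp / obs, 1)
  # monotone: a more extreme feature never gets a larger q
  ord <- order(abs_d, decreasing = TRUE)
  q <- q_raw
  q[ord] <- rev(cummin(rev(q_raw[ord])))
  feat <- rownames(matrix)
  if (is.null(feat)) feat <- as.character(seq_len(nrow(matrix)))
  out <- data.frame(feature = feat, d = d, s = stat$s, q = q,
                    direction = ifelse(d >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "s0") <- stat$s0
  out
}

sam_d <- function(m, g1, s0 = NULL) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(m[, g1, drop = FALSE])
  m2 <- rowMeans(m[, !g1, drop = FALSE])
  ss <- rowSums((m[, g1, drop = FALSE] - m1)^2) +
        rowSums((m[, !g1, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  if (is.null(s0)) s0 <- stats::median(s)
  list(d = (m1 - m2) / (s + s0), s = s, s0 = s0)
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p-value when both groups have at most 20 observations
#' and no ties are present; otherwise the normal approximation with tie
#' correction. All values tied across both groups gives p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (W, number of (x, y) pairs with x > y)
#'   and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- max(length(x), length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Cross-cohort patient-pairwise Pearson correlation matrix
#'
#' Correlation of every sample of cohort A with every sample of cohort B
#' across a shared feature set, with no clustering applied. Zero-variance
#' profiles yield missing correlations with a warning.
#'
#' @param betaA,betaB Numeric matrices, features x samples.
#' @param shared_feature_ids Feature ids (>= 3) present in both.
#' @return Numeric matrix, samples(A) x samples(B), of Pearson r.
#' @export
patient_correlation_matrix <- function(betaA, betaB, shared_feature_ids) {
  shared <- intersect(intersect(shared_feature_ids, rownames(betaA)),
                      rownames(betaB))
  if (length(shared) < 3) stop("need >= 3 shared features")
  a <- betaA[shared, , drop = FALSE]
  b <- betaB[shared, , drop = FALSE]
  flat <- c(colnames(a)[apply(a, 2, stats::sd) == 0],
            colnames(b)[apply(b, 2, stats::sd) == 0])
  if (length(flat) > 0)
    warning(sprintf("%d zero-variance profile(s); correlations set missing",
                    length(flat)))
  suppressWarnings(stats::cor(a, b))
}

#' Driver-gene lesion score
#'
#' The number of nonsilent driver-gene mutations plus the additive inverse
#' of the GISTIC copy-number score: an approximation of the number of
#' inactivated alleles (1 = one allele, 2 = both). The formula is applied
#' literally, so amplifications (gistic > 0) contribute negatively and
#' trigger a warning.
#'
#' @param n_mut Non-negative integer vector of nonsilent mutation counts.
#' @param gistic Integer vector of GISTIC scores in \{-2..2\}.
#' @return Integer vector `n_mut - gistic`.
#' @export
lesion_score <- function(n_mut, gistic) {
  stopifnot(all(n_mut >= 0), all(gistic %in% -2:2))
  if (any(gistic > 0))
    warning("amplifications (gistic > 0) reduce the lesion score; ",
            "the literal formula is applied")
  as.integer(n_mut - gistic)
}

#' Per-sample lesion records for one driver gene
#'
#' @param mutations Nonsilent mutation table (see
#'   [drop_silent_mutations()]).
#' @param copynumber GISTIC copy-number table.
#' @param gene Driver gene symbol.
#' @param samples Sample ids to score (default: union of both tables).
#' @return data.frame with `sample_id`, `n_mut`, `gistic`, `lesion_score`.
#' @export
lesion_table <- function(mutations, copynumber, gene, samples = NULL) {
  mut <- mutations[mutations$gene == gene, , drop = FALSE]
  cn <- copynumber[copynumber$gene == gene, , drop = FALSE]
  if (is.null(samples))
    samples <- sort(unique(c(mut$sample_id, cn$sample_id)))
  n_mut <- vapply(samples, function(s) sum(mut$sample_id == s), integer(1))
  gistic <- vapply(samples, function(s) {
    v <- cn$gistic_score[cn$sample_id == s]
    if (length(v) == 0) 0L else as.integer(v[1])
  }, integer(1))
  data.frame(sample_id = samples, n_mut = n_mut, gistic = gistic,
             lesion_score = lesion_score(n_mut, gistic),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signature overlap index of a hypomethylated CpG set
#'
#' The fraction of a patient's hypomethylated CpG probes that intersect a
#' fixed CpG signature: |hypo intersect signature| / |hypo|.
#'
#' @param hypo_cpgs Character vector of the patient's hypomethylated CpG
#'   probe ids (an empty set yields `NA` with a warning; the sample should
#'   be excluded).
#' @param signature Character vector of signature CpG ids.
#' @return Numeric index in \[0,1\], or `NA` for an empty hypo set.
#' @export
overlap_index <- function(hypo_cpgs, signature) {
  hypo_cpgs <- unique(hypo_cpgs)
  if (length(hypo_cpgs) == 0) {
    warning("empty hypomethylated CpG set: overlap index undefined")
    return(NA_real_)
  }
  length(intersect(hypo_cpgs, signature)) / length(hypo_cpgs)
}

#' Random-signature overlap index
#'
#' Mean of the overlap index against `n_draws` signatures of size `m`
#' sampled uniformly without replacement from the probe universe; the
#' resampling null for [overlap_index()], with analytic expectation
#' m / |universe|.
#'
#' @param hypo_cpgs Patient's hypomethylated CpG ids (subset of
#'   `universe`).
#' @param universe All candidate CpG ids.
#' @param m Signature size (<= |universe|).
#' @param n_draws Number of random signatures (default 10).
#' @param seed Integer seed.
#' @return Mean overlap index over the draws.
#' @export
random_overlap_index <- function(hypo_cpgs, universe, m, n_draws = 10,
                                 seed = 1) {
  universe <- unique(universe)
  if (m > length(universe)) stop("m exceeds the universe size")
  stopifnot(all(hypo_cpgs %in% universe))
  if (m == 0) return(0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mean(vapply(seq_len(n_draws), function(i) {
    overlap_index(hypo_cpgs, sample(universe, m))
  }, numeric(1)))
}

#' Linear association between lesion score and overlap index
#'
#' Ordinary least squares of the signature overlap index on the driver
#' lesion score; the slope and its two-sided p-value quantify whether more
#' heavily hit patients share more of the signature's hypomethylation.
#'
#' @param lesion_scores,overlap_indices Paired numeric vectors (>= 3
#'   complete pairs; the score must not be constant).
#' @return List with `slope`, `p`, `intercept`, `n`.
#' @export
lesion_overlap_association <- function(lesion_scores, overlap_indices) {
  ok <- is.finite(lesion_scores) & is.finite(overlap_indices)
  x <- lesion_scores[ok]; y <- overlap_indices[ok]
  if (length(x) < 3) stop("need >= 3 paired samples")
  if (stats::sd(x) == 0) stop("lesion score is constant")
  fit <- summary(stats::lm(y ~ x))
  list(slope = fit$coefficients["x", "Estimate"],
       p = fit$coefficients["x", "Pr(>|t|)"],
       intercept = fit$coefficients["(Intercept)", "Estimate"],
       n = length(x))
}

#' T-cell infiltration score from bulk expression
#'
#' Unweighted mean expression of the available T-cell signature genes per
#' sample; genes absent from the matrix are reported via a message.
#'
#' @param expression Numeric matrix, genes x samples.
#' @param genes Signature gene set (default [TCELL_GENES]).
#' @return Named numeric vector of per-sample scores.
#' @export
tcell_score <- function(expression, genes = TCELL_GENES) {
  present <- intersect(genes, rownames(expression))
  if (length(present) == 0) stop("no signature genes present in expression")
  absent <- setdiff(genes, present)
  if (length(absent) > 0)
    message(sprintf("tcell_score: %d signature gene(s) absent: %s",
                    length(absent), paste(absent, collapse = ", ")))
  colMeans(expression[present, , drop = FALSE])
}

#' Rounded percentage of a count fraction
#'
#' `round(100 * numerator / denominator)` with half-up rounding, the
#' convention used when reporting contingency percentages.
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @return Integer percent.
#' @export
fraction_percent <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator))
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator))
    stop("numerator must lie in [0, denominator]")
  as.integer(floor(100 * numerator / denominator + 0.5))
}
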