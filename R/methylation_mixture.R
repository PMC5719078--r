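#' Fit a beta mixture model to tumor beta values
#'
#' Fits mixtures of Beta(alpha, beta) components for K = 1..`k_max` by EM
#' (maximum-posterior responsibilities, exact weighted-MLE M-step via BFGS
#' warm-started at the current parameters, so the observed log-likelihood is
#' non-decreasing) and selects K by BIC with p = 3K - 1 free parameters.
#' Initialization is deterministic: the sorted values are split into K
#' quantile blocks and moment-matched; `n_restarts` additional seeded
#' jittered starts guard against local optima. Candidate fits in which two
#' component means lie within `merge_tol` of each other are treated as
#' over-parameterized and excluded from selection.
#'
#' @param values Numeric vector of beta values; at least 10 finite values
#'   are required. Values are clamped to \[1e-6, 1 - 1e-6\].
#' @param k_max Maximum number of components (default 3).
#' @param seed Integer seed controlling the jittered restarts.
#' @param max_iter,tol EM iteration cap (500) and log-likelihood tolerance.
#' @param n_restarts Seeded restarts per K >= 2 (default 3).
#' @param merge_tol Minimum separation of component means (default 0.05).
#' @return A `beta_mixture_fit`: list with `alpha`, `beta`, `pi`, `mu`,
#'   `K`, `loglik`, `bic`, `converged`, `loglik_trace`, and `posterior`
#'   (n x K responsibility matrix for the selected fit).
#' @export
fit_beta_mixture <- function(values, k_max = 3, seed = 1,
                             max_iter = 500, tol = 1e-6,
                             n_restarts = 3, merge_tol = 0.05) {
  x <- values[is.finite(values)]
  if (length(x) < 10) stop("insufficient samples: need >= 10 finite values")
  eps <- 1e-6
  x <- pmin(pmax(x, eps), 1 - eps)
  n <- length(x)

  fits <- list()
  for (K in seq_len(k_max)) {
    starts <- list(quantile_init(x, K))
    if (K >= 2 && n_restarts > 0) {
      for (r in seq_len(n_restarts)) {
        starts[[r + 1]] <- jitter_init(x, K, seed + r)
      }
    }
    # short-run each start, then polish the best to convergence
    best <- NULL
    for (s in starts) {
      f <- beta_mixture_em(x, s, min(10, max_iter), tol)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    if (!best$converged)
      best <- beta_mixture_em(x, best[c("alpha", "beta", "pi")],
                              max_iter, tol)
    best$K <- K
    best$bic <- -2 * best$loglik + (3 * K - 1) * log(n)
    fits[[K]] <- best
  }
  separated <- vapply(fits, function(f) {
    f$K == 1 || min(stats::dist(f$mu)) >= merge_tol
  }, logical(1))
  pick <- which(separated)[which.min(vapply(fits[separated], `[[`,
                                            numeric(1), "bic"))]
  fit <- fits[[pick]]
  fit$candidates <- data.frame(K = seq_len(k_max),
                               bic = vapply(fits, `[[`, numeric(1), "bic"),
                               separated = separated)
  class(fit) <- "beta_mixture_fit"
  fit
}

# Moment-matched (alpha, beta) from a mean and variance.
moments_to_shape <- function(m, v) {
  m <- min(max(m, 1e-3), 1 - 1e-3)
  phi <- m * (1 - m) / max(v, 1e-6) - 1
  phi <- min(max(phi, 2), 500)
  c(alpha = m * phi, beta = (1 - m) * phi)
}

quantile_init <- function(x, K) {
  xs <- sort(x)
  grp <- if (K == 1) rep(1L, length(xs))
         else cut(seq_along(xs), K, labels = FALSE)
  blocks <- split(xs, grp)
  shape <- t(vapply(blocks, function(b) {
    moments_to_shape(mean(b), stats::var(c(b, mean(b))))
  }, numeric(2)))
  list(alpha = shape[, 1], beta = shape[, 2], pi = rep(1 / K, K))
}

jitter_init <- function(x, K, seed) {
  init <- quantile_init(x, K)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  init$alpha <- init$alpha * exp(stats::rnorm(K, sd = 0.3))
  init$beta <- init$beta * exp(stats::rnorm(K, sd = 0.3))
  init
}

# One EM run. par: list(alpha, beta, pi). Returns fit with loglik trace.
beta_mixture_em <- function(x, par, max_iter, tol) {
  K <- length(par$pi)
  lx <- log(x); l1x <- log1p(-x)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  resp <- NULL
  n <- length(x)
  logd <- matrix(0, n, K)
  trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    # log pi_c + log Beta density, from precomputed log(x), log(1-x)
    cst <- log(par$pi) - lbeta(par$alpha, par$beta)
    for (c in seq_len(K))
      logd[, c] <- lx * (par$alpha[c] - 1) + l1x * (par$beta[c] - 1) + cst[c]
    mx <- logd[, 1]
    if (K > 1) for (c in 2:K) mx <- pmax(mx, logd[, c])
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    trace[it] <- ll
    resp <- exp(logd - lse)   # matrix minus vector recycles down columns
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # M-step
    w <- .colSums(resp, n, K)
    par$pi <- w / sum(w)
    T1 <- crossprod(resp, lx); T2 <- crossprod(resp, l1x)
    for (c in seq_len(K)) {
      if (w[c] < 1e-8) next   # starved component: keep parameters
      fit <- weighted_beta_mle_stats(w[c], T1[c], T2[c],
                                     par$alpha[c], par$beta[c])
      par$alpha[c] <- fit[1]; par$beta[c] <- fit[2]
    }
  }
  trace <- trace[seq_len(if (converged) it else max_iter)]
  mu <- par$alpha / (par$alpha + par$beta)
  list(alpha = par$alpha, beta = par$beta, pi = par$pi, mu = mu,
       loglik = trace[length(trace)], loglik_trace = trace,
       converged = converged, posterior = resp)
}

# Weighted beta MLE from sufficient statistics (W = sum of weights,
# T1 = sum w*log x, T2 = sum w*log(1-x)) on (log alpha, log beta):
# safeguarded Newton with step-halving, warm-started at the current
# parameters so the EM objective never decreases (generalized EM).
weighted_beta_mle_stats <- function(W, T1, T2, a0, b0) {
  lo <- log(1e-2); hi <- log(1e5)   # keeps the likelihood finite
  clamp <- function(z) if (z < lo) lo else if (z > hi) hi else z
  p1 <- clamp(log(a0)); p2 <- clamp(log(b0))
  f <- -((exp(p1) - 1) * T1 + (exp(p2) - 1) * T2 -
           W * lbeta(exp(p1), exp(p2)))
  for (it in 1:15) {
    a <- exp(p1); b <- exp(p2)
    dab <- digamma(a + b); tab <- trigamma(a + b)
    g1 <- (-T1 + W * (digamma(a) - dab)) * a
    g2 <- (-T2 + W * (digamma(b) - dab)) * b
    gmax <- max(abs(g1), abs(g2))
    if (gmax < 1e-7 * max(W, 1)) break
    haa <- g1 + a * a * W * (trigamma(a) - tab)
    hbb <- g2 + b * b * W * (trigamma(b) - tab)
    hab <- -a * b * W * tab
    det <- haa * hbb - hab * hab
    if (is.finite(det) && det > 0 && haa > 0) {
      s1 <- (hbb * g1 - hab * g2) / det
      s2 <- (haa * g2 - hab * g1) / det
    } else {                          # safeguarded gradient step
      s1 <- g1 / gmax; s2 <- g2 / gmax
    }
    accepted <- FALSE
    for (h in 0:12) {
      q1 <- clamp(p1 - s1 / 2^h); q2 <- clamp(p2 - s2 / 2^h)
      fn <- -((exp(q1) - 1) * T1 + (exp(q2) - 1) * T2 -
                W * lbeta(exp(q1), exp(q2)))
      if (is.finite(fn) && fn <= f) {
        p1 <- q1; p2 <- q2; f <- fn; accepted <- TRUE; break
      }
    }
    if (!accepted) break
  }
  c(exp(p1), exp(p2))
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat(sprintf("beta_mixture_fit: K = %d, BIC = %.1f%s\n", x$K, x$bic,
              if (x$converged) "" else " (EM not converged)"))
  print(round(data.frame(mu = x$mu, pi = x$pi,
                         alpha = x$alpha, beta = x$beta), 3))
  invisible(x)
}

#' Differential-methylation (DM) values of mixture components
#'
#' DM of a component is its mean beta minus the mean beta of the matched
#' normal tissue; negative values indicate a hypomethylated state, positive
#' a hypermethylated one.
#'
#' @param fit A `beta_mixture_fit`.
#' @param normal_values Non-empty numeric vector of normal-tissue beta
#'   values for the same gene cluster.
#' @return Numeric vector of per-component DM values in \[-1, 1\].
#' @export
compute_dm <- function(fit, normal_values) {
  nv <- normal_values[is.finite(normal_values)]
  if (length(nv) == 0) stop("normal values must be non-empty")
  fit$mu - mean(nv)
}

#' Test inverse coupling of methylation with expression
#'
#' Pearson correlation of a gene cluster's mean beta with the gene's
#' expression across tumor samples. The cluster passes when the correlation
#' is at most `r_max` (default -0.3) with two-sided p below `p_max`.
#'
#' @param cluster_beta_row,expression_row Paired numeric vectors over the
#'   same tumor samples (>= 10 pairs).
#' @param r_max,p_max Coupling thresholds.
#' @return List with `r`, `p`, `passes`.
#' @export
expression_coupling <- function(cluster_beta_row, expression_row,
                                r_max = -0.3, p_max = 0.05) {
  ok <- is.finite(cluster_beta_row) & is.finite(expression_row)
  if (sum(ok) < 10) stop("need >= 10 paired tumor samples")
  x <- cluster_beta_row[ok]; y <- expression_row[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: coupling undefined, treated as not passing")
    return(list(r = NA_real_, p = NA_real_, passes = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       passes = unname(ct$estimate) <= r_max && ct$p.value < p_max)
}

#' Call per-patient methylation states for all gene clusters
#'
#' For every gene cluster, fits a beta mixture to the tumor samples,
#' computes component DM values against the normal samples, and requires
#' (i) at least one component with |DM| >= `dm_min` and (ii) inverse
#' methylation-expression coupling for the cluster's gene, for the cluster
#' to be called abnormal. Each tumor sample of an abnormal cluster is
#' assigned to its maximum-posterior component; its state is `hypo` if the
#' component DM <= -`dm_min`, `hyper` if >= +`dm_min`, else `normal`.
#' Per-cluster fit failures are logged and skipped, never fatal.
#'
#' @param cluster_beta Numeric matrix, gene clusters x samples (tumor and
#'   normal), typically from [cluster_mean_beta()].
#' @param group Character vector (`"tumor"`/`"normal"`) per sample.
#' @param expression Numeric matrix, genes x tumor samples.
#' @param genes Named character vector mapping cluster id -> gene symbol
#'   (see [cluster_genes()]).
#' @param dm_min Minimum |DM| for an abnormal state (default 0.10).
#' @param r_max,p_max Coupling thresholds passed to
#'   [expression_coupling()].
#' @param k_max,seed Passed to [fit_beta_mixture()].
#' @return A `methylation_states` object: list with `states` (abnormal
#'   clusters x tumor samples, character), `dm` (same shape, DM of the
#'   assigned component), `calls` (per-cluster data.frame with
#'   `is_abnormal`, `direction`, `r`, `p`), and `skipped` (cluster ids whose
#'   fit failed).
#' @export
call_states <- function(cluster_beta, group, expression, genes,
                        dm_min = 0.10, r_max = -0.3, p_max = 0.05,
                        k_max = 3, seed = 1) {
  stopifnot(is.matrix(cluster_beta))
  group <- align_names(group, colnames(cluster_beta), "group")
  tumor <- names(group)[group == "tumor"]
  normal <- names(group)[group == "normal"]
  if (length(tumor) == 0 || length(normal) == 0)
    stop("need at least one tumor and one normal sample")
  tumor_e <- intersect(tumor, colnames(expression))

  clusters <- rownames(cluster_beta)
  calls <- data.frame(cluster_id = clusters, is_abnormal = FALSE,
                      direction = "", r = NA_real_, p = NA_real_,
                      K = NA_integer_, stringsAsFactors = FALSE)
  states <- list(); dm_rows <- list(); skipped <- character(0)
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    g <- genes[[cl]]
    tv <- cluster_beta[cl, tumor]
    nv <- cluster_beta[cl, normal]
    fit <- tryCatch(fit_beta_mixture(tv, k_max = k_max, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, cl); next }
    calls$K[i] <- fit$K
    dm <- compute_dm(fit, nv)
    abn <- abs(dm) >= dm_min
    if (!any(abn)) next
    if (is.null(g) || is.na(g) || !(g %in% rownames(expression))) next
    cp <- tryCatch(
      expression_coupling(cluster_beta[cl, tumor_e], expression[g, tumor_e],
                          r_max = r_max, p_max = p_max),
      error = function(e) list(r = NA_real_, p = NA_real_, passes = FALSE))
    calls$r[i] <- cp$r; calls$p[i] <- cp$p
    if (!isTRUE(cp$passes)) next
    calls$is_abnormal[i] <- TRUE
    dirs <- c(if (any(dm <= -dm_min)) "hypo", if (any(dm >= dm_min)) "hyper")
    calls$direction[i] <- paste(dirs, collapse = "+")
    comp <- max.col(fit$posterior, ties.method = "first")
    names(comp) <- tumor
    sdm <- dm[comp]
    st <- ifelse(sdm <= -dm_min, "hypo",
                 ifelse(sdm >= dm_min, "hyper", "normal"))
    states[[cl]] <- st
    dm_rows[[cl]] <- sdm
  }
  abn_ids <- names(states)
  state_mat <- if (length(abn_ids) > 0) {
    do.call(rbind, states)
  } else matrix(character(0), 0, length(tumor),
                dimnames = list(NULL, tumor))
  dm_mat <- if (length(abn_ids) > 0) {
    do.call(rbind, dm_rows)
  } else matrix(numeric(0), 0, length(tumor),
                dimnames = list(NULL, tumor))
  rownames(state_mat) <- abn_ids; colnames(state_mat) <- tumor
  rownames(dm_mat) <- abn_ids; colnames(dm_mat) <- tumor
  if (length(skipped) > 0)
    message(sprintf("call_states: skipped %d cluster(s) with failed fits",
                    length(skipped)))
  structure(list(states = state_mat, dm = dm_mat, calls = calls,
                 skipped = skipped, dm_min = dm_min),
            class = "methylation_states")
}

#' @export
print.methylation_states <- function(x, ...) {
  cat(sprintf(
    "methylation_states: %d abnormal clusters x %d tumors (%d skipped)\n",
    nrow(x$states), ncol(x$states), length(x$skipped)))
  invisible(x)
}

#' DM feature matrix for subtype clustering
#'
#' Samples x abnormal gene clusters; entries carry the assigned component's
#' DM value where the state is abnormal and 0 where it is normal (the
#' encoding used for consensus clustering). Set `encoding = "state"` for the
#' categorical \{-1, 0, +1\} alternative.
#'
#' @param states A `methylation_states` object.
#' @param encoding `"dm"` (default) or `"state"`.
#' @return Numeric matrix, samples x clusters.
#' @export
dm_feature_matrix <- function(states, encoding = c("dm", "state")) {
  encoding <- match.arg(encoding)
  abn <- states$states != "normal"
  f <- if (encoding == "dm") states$dm * abn
       else (states$states == "hyper") - (states$states == "hypo")
  t(f)
}

#' Count hypomethylated gene clusters per tumor sample
#'
#' @param states A `methylation_states` object (or a character state
#'   matrix, clusters x samples).
#' @return Named integer vector of per-sample counts of clusters in state
#'   `hypo`.
#' @export
count_hypo_per_patient <- function(states) {
  m <- if (inherits(states, "methylation_states")) states$states else states
  if (nrow(m) == 0)
    return(stats::setNames(integer(ncol(m)), colnames(m)))
  counts <- colSums(m == "hypo")
  stats::setNames(as.integer(counts), colnames(m))
}

#' Hypomethylated CpG probes per patient
#'
#' The per-patient hypomethylated CpG set: all probes belonging to gene
#' clusters called `hypo` for that patient.
#'
#' @param states A `methylation_states` object.
#' @param map The `probe_cluster_map` used to build the cluster matrix.
#' @return Named list: sample id -> character vector of probe ids.
#' @export
hypo_cpgs_per_patient <- function(states, map) {
  m <- states$states
  lapply(stats::setNames(colnames(m), colnames(m)), function(s) {
    cl <- rownames(m)[m[, s] == "hypo"]
    unique(unlist(map[cl], use.names = FALSE))
  })
}

#' Write methylation states as long-format TSV
#' @param states A `methylation_states` object.
#' @param path Output path.
#' @export
write_states_tsv <- function(states, path) {
  m <- states$states
  df <- data.frame(
    cluster_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    state = as.vector(m),
    dm = as.vector(states$dm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
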