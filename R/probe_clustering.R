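#' Collapse correlated CpG probes of each gene into clusters
#'
#' Within each gene, probes are clustered by complete-linkage hierarchical
#' clustering on the distance 1 - Pearson correlation across samples, and
#' the tree is cut at `cut_height`. Probes mapping to several genes are
#' duplicated into each gene's pool. Zero-variance probes (correlation
#' undefined) are placed in their own singleton cluster with a warning.
#'
#' @param beta A `beta_matrix` with no missing values (post-imputation).
#' @param manifest Probe manifest data.frame (`probe_id`, `gene`, ...);
#'   multi-gene probes use `;`-separated gene symbols.
#' @param cut_height Tree cut height on the 1 - r scale, in \[0, 2\].
#'   Default 0.4.
#' @return A `probe_cluster_map`: named list mapping cluster ids of the form
#'   `"GENE--cluster--k"` to character vectors of member probe ids, with a
#'   `gene` attribute giving each cluster's gene.
#' @export
cluster_probes <- function(beta, manifest, cut_height = 0.4) {
  stopifnot(inherits(beta, "beta_matrix"), cut_height >= 0)
  if (anyNA(beta$values)) stop("beta matrix must be complete; impute first")
  present <- manifest$probe_id %in% rownames(beta$values)
  unmapped <- setdiff(rownames(beta$values), manifest$probe_id)
  if (length(unmapped) > 0)
    warning(sprintf("%d probes not in manifest were dropped",
                    length(unmapped)))
  man <- manifest[present, , drop = FALSE]
  # duplicate multi-gene probes into each gene's pool
  genes <- strsplit(man$gene, ";", fixed = TRUE)
  long <- data.frame(
    probe_id = rep(man$probe_id, lengths(genes)),
    gene = unlist(genes), stringsAsFactors = FALSE)

  out <- list()
  gene_of <- character(0)
  for (g in unique(long$gene)) {
    probes <- unique(long$probe_id[long$gene == g])
    labs <- cluster_gene_probes(beta$values[probes, , drop = FALSE],
                                cut_height, g)
    for (k in sort(unique(labs))) {
      cid <- sprintf("%s--cluster--%d", g, k)
      out[[cid]] <- probes[labs == k]
      gene_of[cid] <- g
    }
  }
  structure(out, gene = gene_of, class = "probe_cluster_map")
}

# Complete-linkage clustering of one gene's probes; returns integer labels.
cluster_gene_probes <- function(vals, cut_height, gene) {
  n <- nrow(vals)
  if (n == 1) return(1L)
  sds <- apply(vals, 1, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sprintf(
      "gene %s: %d zero-variance probe(s) placed in singleton clusters",
      gene, sum(flat)))
  labs <- integer(n)
  ok <- which(!flat)
  if (length(ok) == 1) {
    labs[ok] <- 1L
  } else if (length(ok) > 1) {
    d <- stats::as.dist(1 - stats::cor(t(vals[ok, , drop = FALSE])))
    hc <- stats::hclust(d, method = "complete")
    labs[ok] <- stats::cutree(hc, h = cut_height)
  }
  labs[flat] <- max(labs) + seq_len(sum(flat))
  labs
}

#' @export
print.probe_cluster_map <- function(x, ...) {
  cat(sprintf("probe_cluster_map: %d clusters over %d genes, %d probes\n",
              length(x), length(unique(attr(x, "gene"))),
              length(unique(unlist(x)))))
  invisible(x)
}

#' Genes of a probe-cluster map
#' @param map A `probe_cluster_map`.
#' @return Named character vector: cluster id -> gene symbol.
#' @export
cluster_genes <- function(map) attr(map, "gene")

#' Mean beta value per probe cluster
#'
#' @param beta A `beta_matrix`.
#' @param map A `probe_cluster_map` from [cluster_probes()].
#' @return Numeric matrix, cluster ids x sample ids; each entry the
#'   unweighted mean of the member probes' beta values.
#' @export
cluster_mean_beta <- function(beta, map) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(map, "probe_cluster_map"))
  absent <- setdiff(unlist(map), rownames(beta$values))
  if (length(absent) > 0)
    stop("cluster members absent from beta matrix: ",
         paste(utils::head(absent, 3), collapse = ", "))
  out <- t(vapply(map, function(probes) {
    colMeans(beta$values[probes, , drop = FALSE])
  }, numeric(ncol(beta$values))))
  rownames(out) <- names(map)
  out
}

#' Serialize a probe-cluster map as two-column TSV
#' @param map A `probe_cluster_map`.
#' @param path Output path.
#' @export
write_cluster_map <- function(map, path) {
  df <- data.frame(cluster_id = rep(names(map), lengths(map)),
                   probe_id = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
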