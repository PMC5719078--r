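#' Construct a beta-value matrix with sample groups and platform flags
#'
#' Container for Illumina-style methylation beta values (probes x samples)
#' together with per-sample tumor/normal labels and per-probe platform
#' membership (450k-only, 27k-only, or shared).
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Entries
#'   must be in \[0,1\] or `NA`.
#' @param group Character vector, one of `"tumor"`/`"normal"` per sample.
#'   Named or positional.
#' @param platform Optional character vector per probe, values in
#'   `c("450k", "27k", "both")`. Defaults to `"both"`.
#' @return An object of class `beta_matrix`: a list with elements `values`,
#'   `group`, `platform`.
#' @export
beta_matrix <- function(values, group, platform = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs probe (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, , drop = FALSE]]))
  }
  group <- align_names(group, colnames(values), "group")
  if (!all(group %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'")
  if (is.null(platform)) platform <- rep("both", nrow(values))
  platform <- align_names(platform, rownames(values), "platform")
  if (!all(platform %in% c("450k", "27k", "both")))
    stop("platform flags must be '450k', '27k' or 'both'")
  structure(list(values = values, group = group, platform = platform),
            class = "beta_matrix")
}

align_names <- function(x, ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing) > 0)
      stop(sprintf("%s missing for: %s", what,
                   paste(utils::head(missing, 3), collapse = ", ")))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop(sprintf("%s length (%d) does not match ids (%d)",
                 what, length(x), length(ids)))
  } else {
    names(x) <- ids
  }
  x
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' Subset a beta matrix by probes and/or samples
#'
#' @param x A `beta_matrix`.
#' @param probes,samples Character vectors of ids to keep (default all).
#' @return A `beta_matrix` restricted to the requested probes/samples.
#' @export
subset_beta <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  if (is.null(probes)) probes <- rownames(x$values)
  if (is.null(samples)) samples <- colnames(x$values)
  beta_matrix(x$values[probes, samples, drop = FALSE],
              x$group[samples], x$platform[probes])
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature ids, remaining columns one sample each;
#' missing values encoded as `NA`.
#'
#' @param path Path to a TSV file with a header row.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(m[, 0, drop = FALSE], check.names = FALSE)
  df[[id_col]] <- rownames(m)
  df <- cbind(df[id_col], as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a MAF-like somatic mutation table
#'
#' Expects at least the columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`. Rows with classification `"Silent"` are flagged
#' via `is_silent`.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `sample_id`, `gene`,
#'   `variant_classification`, `is_silent`.
#' @export
read_mutation_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(need %in% names(df)))
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  data.frame(sample_id = df$Tumor_Sample_Barcode,
             gene = df$Hugo_Symbol,
             variant_classification = df$Variant_Classification,
             is_silent = df$Variant_Classification == "Silent",
             stringsAsFactors = FALSE)
}

#' Read a GISTIC-thresholded copy-number table
#'
#' Long-format TSV with columns `sample_id`, `gene`, `gistic_score`
#' (integers in -2..2, as in GISTIC `all_thresholded.by_genes` output after
#' melting).
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `sample_id`, `gene`, `gistic_score`.
#' @export
read_copynumber_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "gistic_score")
  if (!all(need %in% names(df)))
    stop("copy-number table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$gistic_score %in% -2:2))
    stop("gistic_score values must lie in {-2,...,2}")
  df[need]
}

#' Read a BED-like probe manifest
#'
#' Columns: chrom, 0-based start, probe_id, gene (possibly `;`-separated for
#' multi-gene probes), platform flag.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `chrom`, `start`, `probe_id`, `gene`,
#'   `platform`.
#' @export
read_manifest_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "probe_id", "gene", "platform")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (any(df$start < 0)) stop("manifest positions must be non-negative")
  df[need]
}

#' Load and align a full cohort from a path-set descriptor
#'
#' Reads the beta, expression, mutation, copy-number and manifest tables,
#' validates them, and restricts the beta (tumor samples) and expression
#' matrices to their shared samples. Mutation and copy-number rows for
#' samples absent from the aligned set are retained (lesion tables are often
#' wider than the molecular matrices) but flagged in the returned counts.
#'
#' @param config Either a path to a YAML file or a named list with elements
#'   `beta`, `expression`, `mutations`, `copynumber`, `manifest`, and the
#'   per-sample `groups` TSV (columns `sample_id`, `group`). An optional
#'   `batch_column` entry is reserved and currently rejected.
#' @return A list with elements `beta` (`beta_matrix`), `expression`
#'   (matrix), `mutations`, `copynumber`, `manifest` (data.frames), and
#'   `dropped` (named counts of samples excluded from the joint analyses).
#' @export
load_cohort <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$batch_column))
    stop("batch correction is not implemented")
  need <- c("beta", "expression", "mutations", "copynumber",
            "manifest", "groups")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0)
    stop("config missing paths: ", paste(missing, collapse = ", "))

  beta_vals <- read_matrix_tsv(config$beta)
  expr <- read_matrix_tsv(config$expression)
  mut <- read_mutation_tsv(config$mutations)
  cn <- read_copynumber_tsv(config$copynumber)
  manifest <- read_manifest_tsv(config$manifest)
  groups_df <- utils::read.delim(config$groups, sep = "\t",
                                 stringsAsFactors = FALSE)
  group <- stats::setNames(groups_df$group, groups_df$sample_id)

  beta <- beta_matrix(beta_vals, group[colnames(beta_vals)])
  tumor_ids <- names(beta$group)[beta$group == "tumor"]
  normal_ids <- names(beta$group)[beta$group == "normal"]
  shared <- intersect(tumor_ids, colnames(expr))
  if (length(shared) == 0)
    stop("no tumor samples shared between beta and expression matrices")
  dropped <- c(
    beta_only = length(setdiff(tumor_ids, shared)),
    expression_only = length(setdiff(colnames(expr), shared)))
  if (any(dropped > 0))
    warning(sprintf(
      "dropped from joint analyses: %d beta-only, %d expression-only samples",
      dropped["beta_only"], dropped["expression_only"]))

  beta <- subset_beta(beta, samples = c(shared, normal_ids))
  expr <- expr[, shared, drop = FALSE]
  list(beta = beta, expression = expr, mutations = mut, copynumber = cn,
       manifest = manifest, dropped = dropped)
}

#' Remove rows and columns with excessive missingness
#'
#' Rows whose missing fraction strictly exceeds `max_missing_fraction` are
#' removed first, then columns; the two passes repeat until no row or column
#' is above threshold (removing columns can raise a remaining row's missing
#' fraction), so the result is a fixed point and the operation idempotent.
#'
#' @param m Numeric matrix (features x samples).
#' @param max_missing_fraction Maximum tolerated missing fraction in \[0,1).
#' @return The filtered matrix.
#' @export
filter_missing <- function(m, max_missing_fraction) {
  stopifnot(is.matrix(m),
            max_missing_fraction >= 0, max_missing_fraction < 1)
  repeat {
    row_frac <- rowMeans(is.na(m))
    m <- m[row_frac <= max_missing_fraction, , drop = FALSE]
    if (nrow(m) == 0) stop("empty matrix: all rows exceeded missing threshold")
    col_frac <- colMeans(is.na(m))
    m <- m[, col_frac <= max_missing_fraction, drop = FALSE]
    if (ncol(m) == 0) stop("empty matrix: all columns exceeded missing threshold")
    if (all(rowMeans(is.na(m)) <= max_missing_fraction)) break
  }
  m
}

#' K-nearest-neighbor imputation of missing matrix entries
#'
#' For each missing cell, rows are ranked by Euclidean distance computed
#' over the columns both rows observe; the cell is filled with the mean of
#' the `k` nearest rows that are observed at that column. Observed entries
#' are left untouched. If none of the candidate neighbors observe the
#' column, the row mean (then the column mean) is used as fallback.
#'
#' @param m Numeric matrix with some `NA` entries; every row must retain at
#'   least one observed value.
#' @param k Number of neighbors (default 15). If `k` exceeds the number of
#'   other rows it is truncated with a warning.
#' @return The matrix with all `NA` entries imputed.
#' @export
knn_impute <- function(m, k = 15) {
  stopifnot(is.matrix(m), k >= 1)
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0))
    stop("rows with no observed values cannot be imputed")
  if (k > nrow(m) - 1) {
    warning(sprintf("k = %d exceeds available rows; using all %d neighbors",
                    k, nrow(m) - 1))
    k <- nrow(m) - 1
  }
  out <- m
  need <- which(rowSums(is.na(m)) > 0)
  col_means <- colMeans(m, na.rm = TRUE)
  for (i in need) {
    d <- knn_row_distances(m, i)
    ord <- order(d, na.last = NA)   # rows with no shared columns drop out
    for (j in which(is.na(m[i, ]))) {
      donors <- ord[!is.na(m[ord, j])]
      if (length(donors) == 0) {
        fill <- mean(m[i, ], na.rm = TRUE)
        out[i, j] <- if (is.finite(fill)) fill else col_means[j]
      } else {
        out[i, j] <- mean(m[donors[seq_len(min(k, length(donors)))], j])
      }
    }
  }
  out
}

# Euclidean distance from row i to every other row over co-observed columns.
knn_row_distances <- function(m, i) {
  diffs <- sweep(m, 2, m[i, ])
  d <- sqrt(rowSums(diffs^2, na.rm = TRUE))
  d[rowSums(!is.na(diffs)) == 0] <- NA   # no shared observed columns
  d[i] <- NA
  d
}

#' Drop silent mutations from a mutation table
#'
#' @param table Mutation `data.frame` as returned by [read_mutation_tsv()].
#' @return The table without rows flagged `is_silent`, with an attribute
#'   `nonsilent_counts`: per-sample counts of retained rows.
#' @export
drop_silent_mutations <- function(table) {
  stopifnot(is.data.frame(table), "is_silent" %in% names(table))
  out <- table[!table$is_silent, , drop = FALSE]
  rownames(out) <- NULL
  counts <- table(out$sample_id)
  attr(out, "nonsilent_counts") <- stats::setNames(as.integer(counts),
                                                   names(counts))
  out
}
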