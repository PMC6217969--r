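#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' vector of row-wise means of the column-sorted input. Ranks within each
#' column are preserved; the operation is idempotent.
#'
#' @param x Numeric genes x samples matrix, no missing values, >= 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' m <- cbind(s1 = c(1, 3), s2 = c(2, 4))
#' rownames(m) <- c("g1", "g2")
#' quantile_normalize(m)  # both columns become (1.5, 3.5)
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (anyNA(x)) stop("quantile normalization requires no missing values")
  if (ncol(x) < 2L) stop("need at least 2 samples")
  sorted <- apply(x, 2L, sort, method = "radix")
  target <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    out[order(x[, j], method = "radix"), j] <- target
  }
  out
}

#' Threshold-and-filter preprocessing
#'
#' Mirrors the classic microarray preprocessing step: values are clipped to
#' `[floor, ceiling]`, then genes whose clipped row fails either variation
#' test (max/min < `min_fold` or max - min < `min_delta`) are removed.
#' Optional row normalization (mean 0, sd 1) is for display only; downstream
#' differential statistics and enrichment consume unnormalized rows.
#'
#' @param x Numeric genes x samples matrix.
#' @param floor,ceiling Clipping bounds (defaults 20 and 20000).
#' @param min_fold Minimum max/min ratio to retain a gene (default 3).
#' @param min_delta Minimum max - min difference to retain a gene
#'   (default 100).
#' @param row_normalize Standardize surviving rows for display.
#' @return Filtered (and possibly row-normalized) matrix; attribute
#'   `n_removed` records the number of genes dropped.
#' @export
preprocess_filter <- function(x, floor = 20, ceiling = 20000, min_fold = 3,
                              min_delta = 100, row_normalize = FALSE) {
  check_expression_matrix(x)
  if (floor >= ceiling) stop("'floor' must be < 'ceiling'")
  if (min_fold < 1) stop("'min_fold' must be >= 1")
  if (min_delta < 0) stop("'min_delta' must be >= 0")
  x <- pmin(pmax(x, floor), ceiling)
  rmax <- apply(x, 1L, max)
  rmin <- apply(x, 1L, min)
  keep <- (rmax / rmin >= min_fold) & (rmax - rmin >= min_delta)
  if (!any(keep))
    stop("all genes removed by filtering; relax 'min_fold'/'min_delta'")
  out <- x[keep, , drop = FALSE]
  if (row_normalize) {
    mu <- rowMeans(out)
    s <- apply(out, 1L, sd)
    s[s == 0] <- 1
    out <- (out - mu) / s
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Collapse probes to genes
#'
#' When several probes map to one gene, the probe with the maximal mean
#' expression is kept (ties broken by the lexicographically smaller probe
#' id). Probes absent from the map are dropped with a logged count.
#'
#' @param x Numeric probes x samples matrix.
#' @param probe_to_gene Named character vector, `names` = probe ids,
#'   values = gene ids.
#' @return Genes x samples matrix; attribute `n_unmapped` records dropped
#'   probes.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  check_expression_matrix(x)
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene map")
  probes <- intersect(rownames(x), names(probe_to_gene))
  n_unmapped <- nrow(x) - length(probes)
  if (n_unmapped > 0L)
    message(n_unmapped, " unmapped probe(s) dropped")
  if (length(probes) == 0L) stop("no probe in the matrix is mapped")
  genes <- probe_to_gene[probes]
  means <- rowMeans(x[probes, , drop = FALSE])
  ord <- order(genes, -means, probes, method = "radix")
  pick <- probes[ord][!duplicated(genes[ord])]
  out <- x[pick, , drop = FALSE]
  rownames(out) <- unname(probe_to_gene[pick])
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Per-gene differential expression (Welch t)
#'
#' Welch two-sample t statistic and two-sided p-value per gene, plus a
#' linear-scale fold change (class 1 mean / class 2 mean, both means floored
#' at `mean_floor` to avoid division blow-ups). The selection mask applies
#' fold change > `fc_cutoff` in either direction AND p < `p_cutoff`, both
#' strict.
#'
#' @param x Numeric genes x samples matrix.
#' @param pheno Binary [phenotype]; each class needs >= 2 samples.
#' @param fc_cutoff Fold-change selection threshold (default 1.5, strict).
#' @param p_cutoff P-value selection threshold (default 0.05, strict).
#' @param mean_floor Floor applied to class means before the ratio
#'   (default 1).
#' @return `data.frame` with columns `gene_id`, `t_statistic`, `p_value`,
#'   `fold_change`, `direction` (sign of class1 - class2) and `selected`.
#' @export
differential_expression <- function(x, pheno, fc_cutoff = 1.5,
                                    p_cutoff = 0.05, mean_floor = 1) {
  check_expression_matrix(x)
  if (!inherits(pheno, "phenotype") || pheno$kind != "binary")
    stop("'pheno' must be a binary phenotype")
  if (length(pheno$values) != ncol(x))
    stop("phenotype length does not match sample count")
  ci <- class_indices(pheno)
  n1 <- length(ci$i1); n2 <- length(ci$i2)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  x1 <- x[, ci$i1, drop = FALSE]; x2 <- x[, ci$i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  # zero pooled SE with equal means is a flat gene (t = 0, p = 1); with
  # unequal means it is a degenerate perfect separation (p clamped below)
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                  ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / (ifelse(v1 > 0, (v1 / n1)^2 / (n1 - 1L), 0) +
                        ifelse(v2 > 0, (v2 / n2)^2 / (n2 - 1L), 0)),
               1)
  p <- 2 * pt(-abs(tstat), df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  fc <- pmax(m1, mean_floor) / pmax(m2, mean_floor)
  sel <- (pmax(fc, 1 / fc) > fc_cutoff) & (p < p_cutoff)
  data.frame(gene_id = rownames(x), t_statistic = tstat, p_value = p,
             fold_change = fc, direction = sign(m1 - m2), selected = sel,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exploratory PCA of samples
#'
#' Projects samples onto the principal components of the gene-centered
#' matrix (unscaled), reporting the first `n_components` score columns and
#' the variance fraction of every component.
#'
#' @param x Numeric genes x samples matrix, >= 3 samples.
#' @param n_components Number of score columns to report (default 3).
#' @return List with `scores` (samples x components) and
#'   `variance_fractions` (all components, non-increasing, sum <= 1).
#' @export
pca_explore <- function(x, n_components = 3L) {
  check_expression_matrix(x)
  if (ncol(x) < 3L) stop("PCA exploration needs at least 3 samples")
  fit <- prcomp(t(x), center = TRUE, scale. = FALSE)
  fractions <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       variance_fractions = fractions)
}
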