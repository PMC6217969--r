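#' GSEA engine parameters
#'
#' @param weight_exponent Exponent on |metric| in the running-sum hit
#'   weights; 1 is the classic "weighted" statistic, 0 the plain
#'   Kolmogorov-Smirnov statistic.
#' @param n_permutations Size of the permutation null (default 1000; fewer
#'   than 100 triggers a warning).
#' @param permutation_mode `"phenotype"` (relabel samples and fully re-rank),
#'   `"gene_set"` (random member sets of equal size on the observed ranking)
#'   or `"auto"`: phenotype for binary designs with >= 7 samples per class,
#'   gene_set otherwise and for continuous phenotypes.
#' @param min_set_size,max_set_size Size filter applied to each set's
#'   membership within the expression matrix (defaults 15 and 500).
#' @param sig_p,sig_fdr Significance regime for calling a set enriched
#'   (defaults 0.05 and 0.25); `high_sig_p` (default 0.01) defines the
#'   highly-significant call.
#' @param seed Optional integer seed for the permutation RNG.
#' @return List of class `gsea_params`.
#' @export
gsea_params <- function(weight_exponent = 1, n_permutations = 1000L,
                        permutation_mode = c("auto", "phenotype", "gene_set"),
                        min_set_size = 15L, max_set_size = 500L,
                        sig_p = 0.05, sig_fdr = 0.25, high_sig_p = 0.01,
                        seed = NULL) {
  permutation_mode <- match.arg(permutation_mode)
  stopifnot(weight_exponent >= 0, n_permutations >= 1,
            min_set_size >= 1, max_set_size >= min_set_size,
            sig_p > 0, sig_p < 1, sig_fdr > 0, sig_fdr <= 1,
            high_sig_p > 0, high_sig_p < 1)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 permutation_mode = permutation_mode,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 sig_p = sig_p, sig_fdr = sig_fdr, high_sig_p = high_sig_p,
                 seed = seed),
            class = "gsea_params")
}

# signal-to-noise metric for one class split, with the per-class sd floor
# sd >= max(sd, 0.2 |mean|, 0.2)
s2n_metric <- function(x, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  s1 <- sqrt(rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1L))
  s2 <- sqrt(rowSums((x[, i2, drop = FALSE] - m2)^2) / (n2 - 1L))
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s2 <- pmax(s2, 0.2 * abs(m2), 0.2)
  (m1 - m2) / (s1 + s2)
}

#' Rank genes by phenotype association
#'
#' Binary phenotypes use the signal-to-noise ratio
#' (mu1 - mu2) / (sd1 + sd2) with each class sd floored at
#' max(sd, 0.2 |mu|, 0.2); continuous phenotypes use the Pearson correlation
#' of each gene with the covariate. The list is sorted non-increasing with
#' deterministic ties broken by gene id.
#'
#' @param x Numeric genes x samples matrix.
#' @param pheno A [phenotype]; s2n requires >= 3 samples per class.
#' @param metric `"auto"` (s2n for binary, pearson for continuous), `"s2n"`
#'   or `"pearson"`.
#' @return `data.frame` of class `ranked_list` with columns `gene_id` and
#'   `metric`, rows in rank order.
#' @export
rank_genes <- function(x, pheno, metric = c("auto", "s2n", "pearson")) {
  check_expression_matrix(x)
  metric <- match.arg(metric)
  if (metric == "auto")
    metric <- if (pheno$kind == "binary") "s2n" else "pearson"
  if (length(pheno$values) != ncol(x))
    stop("phenotype length does not match sample count")
  if (metric == "s2n") {
    if (pheno$kind != "binary") stop("s2n requires a binary phenotype")
    ci <- class_indices(pheno)
    if (length(ci$i1) < 3L || length(ci$i2) < 3L)
      stop("s2n requires at least 3 samples per class")
    m <- s2n_metric(x, ci$i1, ci$i2)
  } else {
    if (pheno$kind != "continuous")
      stop("pearson requires a continuous phenotype")
    y <- pheno$values
    if (sd(y) == 0) stop("zero-variance covariate")
    m <- as.vector(suppressWarnings(cor(t(x), y)))
    m[is.na(m)] <- 0  # zero-variance genes carry no association
  }
  ord <- order(-m, rownames(x), method = "radix")
  out <- data.frame(gene_id = rownames(x)[ord], metric = m[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Running-sum enrichment score of one gene set
#'
#' Walks the ranked list: a hit increments the running sum by
#' |metric|^weight / sum over hits of |metric|^weight, a miss decrements by
#' 1/(N - s). The enrichment score is the signed deviation of maximal
#' absolute value (ties between equal positive and negative deviations
#' resolve to the positive score); with weight 0 this is the classic
#' Kolmogorov-Smirnov statistic.
#'
#' @param ranked A `ranked_list` from [rank_genes()].
#' @param members Character vector of gene-set members.
#' @param weight_exponent Hit-weight exponent (default 1).
#' @return List with `es`, `peak_rank` (the rank attaining the extreme; for
#'   negative scores the first rank of the trailing edge) and the full
#'   `running_sum` vector.
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  n <- nrow(ranked)
  hit <- ranked$gene_id %in% members
  s <- sum(hit)
  if (s == 0L) stop("no gene-set member present in the ranked list")
  if (s == n) stop("gene set spans the whole ranked list")
  w <- abs(ranked$metric)^weight_exponent
  pos <- which(hit)
  kern <- es_stat_cpp(pos, w[pos], n)
  inc <- rep.int(-1 / (n - s), n)
  tot <- sum(w[pos])
  inc[pos] <- if (tot > 0) w[pos] / tot else 1 / s
  list(es = kern[1L], peak_rank = as.integer(kern[2L]),
       running_sum = cumsum(inc))
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive score: the set members at ranks up to and including the
#' peak; for a negative score: the members at ranks at or beyond the peak.
#' Order follows the ranked list.
#'
#' @param ranked A `ranked_list`.
#' @param members Gene-set members.
#' @param es,peak_rank Score and peak as computed by [enrichment_score()].
#' @return Character vector of leading-edge gene ids (empty, with a warning,
#'   when `es == 0`).
#' @export
extract_leading_edge <- function(ranked, members, es, peak_rank) {
  if (es == 0) {
    warning("enrichment score is 0; empty leading edge")
    return(character(0))
  }
  pos <- which(ranked$gene_id %in% members)
  keep <- if (es > 0) pos[pos <= peak_rank] else pos[pos >= peak_rank]
  ranked$gene_id[keep]
}

# permuted-phenotype s2n metrics: G x P matrix for P random relabelings
perm_s2n_block <- function(x, n1, P) {
  n <- ncol(x)
  M1 <- matrix(0, n, P)
  for (j in seq_len(P)) M1[sample.int(n, n1), j] <- 1
  n2 <- n - n1
  s1 <- x %*% M1
  s2 <- rowSums(x) - s1
  q1 <- (x * x) %*% M1
  q2 <- rowSums(x * x) - q1
  m1 <- s1 / n1; m2 <- s2 / n2
  v1 <- (q1 - n1 * m1 * m1) / (n1 - 1L)
  v2 <- (q2 - n2 * m2 * m2) / (n2 - 1L)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  sd1 <- pmax(sqrt(v1), 0.2 * abs(m1), 0.2)
  sd2 <- pmax(sqrt(v2), 0.2 * abs(m2), 0.2)
  (m1 - m2) / (sd1 + sd2)
}

# permuted-covariate Pearson metrics
perm_pearson_block <- function(x, y, P) {
  Y <- vapply(seq_len(P), function(j) sample(y), numeric(length(y)))
  m <- cor(t(x), Y)
  m[is.na(m)] <- 0
  m
}

#' Run gene-set enrichment analysis
#'
#' Ranks genes by phenotype association and scores every gene set of the
#' collection with the weighted running-sum statistic, a permutation null,
#' normalized enrichment scores, nominal p-values (add-one corrected,
#' same-sign tail) and the permutation FDR q-value (pooled normalized null,
#' made monotone within each enrichment sign). Leading edges are extracted
#' from the observed ranking.
#'
#' @param x Numeric genes x samples matrix.
#' @param pheno A [phenotype].
#' @param collection A [gene_set_collection]; sets are filtered to those
#'   whose membership within `x` falls inside
#'   `[min_set_size, max_set_size]`.
#' @param params A [gsea_params()] list.
#' @return Object of class `gsea_run`: list with `results` (one row per
#'   retained set: `set_name`, `size`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   `peak_rank`, `direction`, `significant`, `highly_significant`,
#'   `leading_edge` list column; sorted by p, FDR, name), `ranked` (the
#'   observed `ranked_list`), `params` and `permutation_mode`.
#' @export
run_gsea <- function(x, pheno, collection, params = gsea_params()) {
  check_expression_matrix(x)
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(params, "gsea_params"))
  if (params$n_permutations < 100L)
    warning("fewer than 100 permutations; p-values and FDR are coarse")
  if (!is.null(params$seed)) set.seed(params$seed)

  universe <- rownames(x)
  members_in <- lapply(collection$sets, intersect, universe)
  size <- lengths(members_in)
  keep <- size >= params$min_set_size & size <= params$max_set_size
  if (!any(keep))
    stop("no gene set passes the size filter [",
         params$min_set_size, ", ", params$max_set_size, "]")
  members_in <- members_in[keep]
  set_names <- names(members_in)
  nsets <- length(set_names)
  sizes <- lengths(members_in)

  mode <- params$permutation_mode
  if (mode == "auto") {
    mode <- if (pheno$kind == "binary" &&
                min(table(pheno$values)) >= 7L) "phenotype" else "gene_set"
  }

  ranked <- rank_genes(x, pheno)
  n <- nrow(ranked)
  rankpos <- integer(n)
  ord_idx <- match(ranked$gene_id, universe)
  rankpos[ord_idx] <- seq_len(n)
  absw <- abs(ranked$metric)^params$weight_exponent
  set_idx <- lapply(members_in, match, universe)

  obs_es <- numeric(nsets)
  obs_peak <- integer(nsets)
  for (j in seq_len(nsets)) {
    p <- sort.int(rankpos[set_idx[[j]]])
    kern <- es_stat_cpp(p, absw[p], n)
    obs_es[j] <- kern[1L]
    obs_peak[j] <- as.integer(kern[2L])
  }

  P <- params$n_permutations
  null_es <- matrix(0, nsets, P)
  if (mode == "phenotype") {
    if (pheno$kind == "binary") {
      ci <- class_indices(pheno)
      n1 <- length(ci$i1)
    }
    block <- 200L
    done <- 0L
    while (done < P) {
      b <- min(block, P - done)
      M <- if (pheno$kind == "binary") perm_s2n_block(x, n1, b)
           else perm_pearson_block(x, pheno$values, b)
      for (k in seq_len(b)) {
        m <- M[, k]
        o <- order(-m, universe, method = "radix")
        rp <- integer(n); rp[o] <- seq_len(n)
        aw <- abs(m[o])^params$weight_exponent
        null_es[, done + k] <- es_many_cpp(rp, aw, set_idx)
      }
      done <- done + b
    }
  } else {
    for (j in seq_len(nsets)) {
      null_es[j, ] <- es_null_sets_cpp(absw, sizes[j], P)
    }
  }

  stats <- gsea_statistics(obs_es, null_es)

  leading <- vector("list", nsets)
  for (j in seq_len(nsets)) {
    leading[[j]] <- if (obs_es[j] == 0) character(0)
      else extract_leading_edge(ranked, members_in[[j]], obs_es[j],
                                obs_peak[j])
  }

  res <- data.frame(set_name = set_names, size = sizes, es = obs_es,
                    nes = stats$nes, p_nominal = stats$p,
                    fdr_q = stats$fdr, peak_rank = obs_peak,
                    direction = ifelse(obs_es >= 0, "pos", "neg"),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$significant <- res$p_nominal < params$sig_p &
    res$fdr_q < params$sig_fdr
  res$highly_significant <- res$p_nominal < params$high_sig_p &
    res$fdr_q < params$sig_fdr
  res$leading_edge <- I(unname(leading))
  res <- res[order(res$p_nominal, res$fdr_q, res$set_name), , drop = FALSE]
  rownames(res) <- NULL

  structure(list(results = res, ranked = ranked, params = params,
                 permutation_mode = mode),
            class = "gsea_run")
}

# nominal p (same-sign tail, add-one), NES (es over mean same-sign |null|)
# and the permutation FDR on the pooled normalized null
gsea_statistics <- function(obs_es, null_es) {
  nsets <- length(obs_es)
  P <- ncol(null_es)
  p <- numeric(nsets); nes <- numeric(nsets)
  null_nes <- matrix(0, nsets, P)
  for (j in seq_len(nsets)) {
    nul <- null_es[j, ]
    pos <- nul[nul > 0]; neg <- nul[nul < 0]
    mp <- if (length(pos)) mean(pos) else NA_real_
    mn <- if (length(neg)) mean(abs(neg)) else NA_real_
    e <- obs_es[j]
    if (e > 0) {
      p[j] <- (1 + sum(pos >= e)) / (1 + length(pos))
      nes[j] <- if (is.na(mp)) NA_real_ else e / mp
    } else if (e < 0) {
      p[j] <- (1 + sum(neg <= e)) / (1 + length(neg))
      nes[j] <- if (is.na(mn)) NA_real_ else e / mn
    } else {
      p[j] <- 1; nes[j] <- 0
    }
    row <- numeric(P)
    if (!is.na(mp)) row[nul > 0] <- nul[nul > 0] / mp
    if (!is.na(mn)) row[nul < 0] <- nul[nul < 0] / mn
    null_nes[j, ] <- row
  }
  all_null <- as.vector(null_nes)
  np <- all_null[all_null > 0]
  nn <- all_null[all_null < 0]
  op <- nes[!is.na(nes) & nes > 0]
  on_ <- nes[!is.na(nes) & nes < 0]
  fdr <- rep(NA_real_, nsets)
  for (j in seq_len(nsets)) {
    e <- nes[j]
    if (is.na(e)) next
    if (e > 0) {
      num <- if (length(np)) mean(np >= e) else 0
      den <- mean(op >= e)
      fdr[j] <- min(1, num / den)
    } else if (e < 0) {
      num <- if (length(nn)) mean(nn <= e) else 0
      den <- mean(on_ <= e)
      fdr[j] <- min(1, num / den)
    } else fdr[j] <- 1
  }
  # monotone non-increasing in |NES| within each sign (running maximum from
  # the most extreme score downward)
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & sign(nes) == sgn)
    if (length(idx) < 2L) next
    o <- idx[order(-abs(nes[idx]))]
    fdr[o] <- cummax(fdr[o])
  }
  list(p = p, nes = nes, fdr = fdr)
}

#' @export
print.gsea_run <- function(x, ...) {
  cat(sprintf("gsea_run: %d sets, %d permutations (%s mode), %d significant\n",
              nrow(x$results), x$params$n_permutations, x$permutation_mode,
              sum(x$results$significant)))
  invisible(x)
}

#' Leading-edge occurrence matrix
#'
#' Binary gene x pathway matrix over the union of leading edges of the
#' significantly enriched sets, with rows and columns ordered by
#' average-linkage hierarchical clustering on Jaccard distance (the
#' gene-by-pathway heatmap view of a leading-edge analysis).
#'
#' @param results A `gsea_run` or its `results` data.frame.
#' @param params [gsea_params()] supplying the significance regime.
#' @return List with `matrix` (reordered), `row_order` (gene ids) and
#'   `col_order` (set names); empty matrix with a warning when no set is
#'   significant.
#' @export
leading_edge_matrix <- function(results, params = gsea_params()) {
  if (inherits(results, "gsea_run")) results <- results$results
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no significantly enriched set; empty leading-edge matrix")
    m <- matrix(0L, 0L, 0L)
    return(list(matrix = m, row_order = character(0),
                col_order = character(0)))
  }
  genes <- sort(unique(unlist(sig$leading_edge)))
  m <- vapply(seq_len(nrow(sig)),
              function(j) as.integer(genes %in% sig$leading_edge[[j]]),
              integer(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, sig$set_name))
  row_ord <- if (nrow(m) > 2L)
    hclust(dist(m, method = "binary"), method = "average")$order
  else seq_len(nrow(m))
  col_ord <- if (ncol(m) > 2L)
    hclust(dist(t(m), method = "binary"), method = "average")$order
  else seq_len(ncol(m))
  m <- m[row_ord, col_ord, drop = FALSE]
  list(matrix = m, row_order = rownames(m), col_order = colnames(m))
}
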