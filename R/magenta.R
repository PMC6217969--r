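#' MAGENTA-style engine parameters
#'
#' @param upstream_kb,downstream_kb SNP-to-gene assignment window in kb
#'   (defaults 110 upstream, 40 downstream of the transcript, strand-aware).
#' @param cutoff_percentile Percentile of corrected gene scores defining the
#'   enrichment cutoff (default 75; 95 is the stricter alternative).
#' @param n_null Number of random gene sets drawn for the sampling null
#'   (default 10000).
#' @param sig_p,sig_fdr Significance regime for cross-enrichment calls
#'   (defaults 0.05 and 0.25).
#' @param min_scored Minimum scored members for a set to be testable
#'   (default 3).
#' @param seed Optional integer seed for the sampling RNG.
#' @return List of class `magenta_params`.
#' @export
magenta_params <- function(upstream_kb = 110, downstream_kb = 40,
                           cutoff_percentile = 75, n_null = 10000L,
                           sig_p = 0.05, sig_fdr = 0.25, min_scored = 3L,
                           seed = NULL) {
  stopifnot(upstream_kb >= 0, downstream_kb >= 0,
            cutoff_percentile > 0, cutoff_percentile < 100, n_null >= 1)
  structure(list(upstream_kb = upstream_kb, downstream_kb = downstream_kb,
                 cutoff_percentile = cutoff_percentile,
                 n_null = as.integer(n_null), sig_p = sig_p,
                 sig_fdr = sig_fdr, min_scored = as.integer(min_scored),
                 seed = seed),
            class = "magenta_params")
}

# strand-aware assignment windows, 0-based half-open
gene_windows <- function(genes, upstream_kb, downstream_kb) {
  up <- round(upstream_kb * 1000)
  down <- round(downstream_kb * 1000)
  win_start <- ifelse(genes$strand == "+", genes$start - up,
                      genes$start - down)
  win_end <- ifelse(genes$strand == "+", genes$end + down,
                    genes$end + up)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(win_start, 0L), end = win_end,
             stringsAsFactors = FALSE)
}

#' Assign SNPs to genes by window containment
#'
#' A gene's assignment region extends `upstream_kb` upstream and
#' `downstream_kb` downstream of its span, flipped on the minus strand.
#' A SNP inside several overlapping regions is assigned to every one of
#' them. Containment is evaluated on 0-based half-open intervals.
#'
#' @param snps GWAS `data.frame` from [read_gwas_table()] (columns `snp`,
#'   `chrom`, `pos0`, `p`).
#' @param genes Gene `data.frame` from [read_gene_bed()].
#' @param upstream_kb,downstream_kb Window widths in kb; must be >= 0.
#' @return Named list (one element per gene with >= 1 assigned SNP) of
#'   integer row indices into `snps`.
#' @export
assign_snps_to_genes <- function(snps, genes, upstream_kb = 110,
                                 downstream_kb = 40) {
  if (upstream_kb < 0 || downstream_kb < 0)
    stop("assignment windows must be >= 0")
  win <- gene_windows(genes, upstream_kb, downstream_kb)
  # 0-based half-open [start, end) -> 1-based closed [start+1, end]
  gr_gene <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(start = win$start + 1L, end = win$end))
  gr_snp <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(start = snps$pos0 + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene)
  gi <- S4Vectors::subjectHits(hits)
  si <- S4Vectors::queryHits(hits)
  # canonical order (sorted gene id) so downstream scoring and the sampling
  # null are invariant to input row order
  out <- split(si, factor(win$gene_id[gi], levels = sort(win$gene_id)))
  out <- out[lengths(out) > 0L]
  lapply(out, function(i) sort(unname(i)))
}

#' Best-SNP gene scores with confounder vector
#'
#' Each gene with at least one assigned SNP scores
#' `-log10(min p among assigned SNPs)`; genes without SNPs are absent. The
#' confounder vector holds the gene span in kb, the assigned-SNP count and
#' the SNP density per kb.
#'
#' @param assignment Mapping from [assign_snps_to_genes()].
#' @param snps The GWAS `data.frame` the assignment indexes into.
#' @param genes Gene `data.frame` (for spans).
#' @return `data.frame` of class `gene_score_table`: `gene_id`, `n_snps`,
#'   `best_p`, `raw_score`, `span_kb`, `density`, `corrected_score` (NA
#'   until [correct_gene_scores()]).
#' @export
score_genes <- function(assignment, snps, genes) {
  if (length(assignment) == 0L) stop("empty SNP-to-gene assignment")
  gid <- names(assignment)
  rows <- match(gid, genes$gene_id)
  if (anyNA(rows)) stop("assignment names missing from gene table")
  best_p <- vapply(assignment, function(i) min(snps$p[i]), numeric(1))
  n_snps <- lengths(assignment)
  span_kb <- (genes$end[rows] - genes$start[rows]) / 1000
  out <- data.frame(gene_id = gid, n_snps = as.integer(n_snps),
                    best_p = unname(best_p),
                    raw_score = -log10(unname(best_p)),
                    span_kb = span_kb, density = n_snps / span_kb,
                    corrected_score = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Regression correction of gene scores
#'
#' Regresses the raw score on the confounders (gene span in kb, SNP count,
#' SNP density per kb) by ordinary least squares with intercept and keeps
#' the residual as the corrected score. Collinear confounders are dropped
#' with a warning; residuals are orthogonal to every retained confounder.
#'
#' @param table A `gene_score_table` from [score_genes()] with >= 10 rows.
#' @return The table with `corrected_score` filled in.
#' @export
correct_gene_scores <- function(table) {
  stopifnot(inherits(table, "gene_score_table"))
  if (nrow(table) < 10L)
    stop("confounder correction needs at least 10 scored genes")
  conf <- c("span_kb", "n_snps", "density")
  # constant columns are intercept-collinear; drop them up front
  usable <- conf[vapply(conf, function(v) var(table[[v]]) > 0, logical(1))]
  if (length(usable) == 0L) {
    table$corrected_score <- table$raw_score - mean(table$raw_score)
    return(table)
  }
  fit <- lm(stats::reformulate(usable, response = "raw_score"),
            data = table)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    warning("dropping collinear confounder(s): ",
            paste(aliased, collapse = ", "))
    usable <- setdiff(usable, aliased)
    fit <- lm(stats::reformulate(usable, response = "raw_score"),
              data = table)
  }
  table$corrected_score <- unname(residuals(fit))
  table
}

#' Percentile-cutoff gene-set enrichment of GWAS scores
#'
#' Counts set members with corrected score strictly above the
#' `cutoff_percentile` of all corrected scores and compares the count with
#' a sampling null of equal-size random gene sets drawn without replacement
#' from the scored genes (add-one corrected). The exact hypergeometric tail
#' is reported alongside as a cross-check.
#'
#' @param table A corrected `gene_score_table`.
#' @param members Character vector of gene-set members.
#' @param cutoff_percentile Percentile cutoff (default 75).
#' @param n_null Number of null sets (default 10000).
#' @param min_scored Minimum scored members (default 3).
#' @return One-row `data.frame`: `n_scored`, `n_above`, `expected_above`,
#'   `p_enrich`, `p_hyper`, `cutoff_value`.
#' @export
magenta_set_enrichment <- function(table, members, cutoff_percentile = 75,
                                   n_null = 10000L, min_scored = 3L) {
  stopifnot(inherits(table, "gene_score_table"))
  if (anyNA(table$corrected_score))
    stop("run correct_gene_scores() first")
  scored <- table$gene_id
  idx <- which(scored %in% members)
  if (length(idx) < min_scored)
    stop("gene set has fewer than ", min_scored, " scored members")
  cutoff <- quantile(table$corrected_score, cutoff_percentile / 100,
                     names = FALSE)
  above <- table$corrected_score > cutoff
  n_scored <- length(idx)
  n_above <- sum(above[idx])
  counts <- count_null_sets_cpp(above, n_scored, as.integer(n_null))
  p_enrich <- (1 + sum(counts >= n_above)) / (n_null + 1)
  K <- sum(above)
  p_hyper <- stats::phyper(n_above - 1L, K, length(above) - K, n_scored,
                           lower.tail = FALSE)
  data.frame(n_scored = n_scored, n_above = n_above,
             expected_above = n_scored * (1 - cutoff_percentile / 100),
             p_enrich = p_enrich, p_hyper = p_hyper, cutoff_value = cutoff,
             stringsAsFactors = FALSE)
}

#' Run the GWAS gene-set enrichment arm
#'
#' Full chain: windowed SNP-to-gene assignment, best-SNP scoring,
#' confounder correction, per-set percentile-cutoff enrichment and
#' Benjamini-Hochberg FDR across sets. Results are sorted by enrichment p
#' ascending with ties broken by set name. Sets with fewer scored members
#' than `min_scored` are excluded with a message.
#'
#' @param snps GWAS `data.frame` ([read_gwas_table()]).
#' @param genes Gene `data.frame` ([read_gene_bed()]).
#' @param collection A [gene_set_collection].
#' @param params A [magenta_params()] list.
#' @return Object of class `magenta_run`: list with `results` (per set:
#'   `set_name`, `n_scored`, `n_above`, `expected_above`, `p_enrich`,
#'   `p_hyper`, `fdr_q`, `significant`), `scores` (the corrected
#'   `gene_score_table`), `cutoff_value`, `excluded` (untestable set names)
#'   and `params`.
#' @export
run_magenta <- function(snps, genes, collection,
                        params = magenta_params()) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(params, "magenta_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  assignment <- assign_snps_to_genes(snps, genes, params$upstream_kb,
                                     params$downstream_kb)
  if (length(assignment) == 0L)
    stop("no gene receives any SNP under the current windows")
  tab <- correct_gene_scores(score_genes(assignment, snps, genes))
  scored <- tab$gene_id
  n_in <- vapply(collection$sets, function(m) sum(scored %in% m),
                 integer(1))
  testable <- names(collection$sets)[n_in >= params$min_scored]
  excluded <- setdiff(names(collection$sets), testable)
  if (length(excluded))
    message(length(excluded), " set(s) excluded: fewer than ",
            params$min_scored, " scored members")
  if (length(testable) == 0L)
    stop("no testable gene set (all below min_scored)")
  rows <- lapply(testable, function(nm) {
    magenta_set_enrichment(tab, collection$sets[[nm]],
                           params$cutoff_percentile, params$n_null,
                           params$min_scored)
  })
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(set_name = testable, stringsAsFactors = FALSE),
               res)
  res$fdr_q <- p.adjust(res$p_enrich, method = "BH")
  res$significant <- res$p_enrich < params$sig_p &
    res$fdr_q < params$sig_fdr
  res <- res[order(res$p_enrich, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  cutoff <- res$cutoff_value[1L]
  res$cutoff_value <- NULL
  structure(list(results = res, scores = tab, cutoff_value = cutoff,
                 excluded = excluded, params = params),
            class = "magenta_run")
}

#' @export
print.magenta_run <- function(x, ...) {
  cat(sprintf(
    "magenta_run: %d sets tested (%d excluded), %d significant; %d scored genes\n",
    nrow(x$results), length(x$excluded), sum(x$results$significant),
    nrow(x$scores)))
  invisible(x)
}
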