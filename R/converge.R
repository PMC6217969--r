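#' Cross-interrogation parameters
#'
#' @param top_k_gsea Number of top expression-side pathways used as the
#'   custom superset evaluated in the GWAS arm (default 200, the GvsM
#'   configuration).
#' @param top_k_magenta Number of top GWAS-side pathways evaluated in the
#'   expression arm (default 30, the MvsG configuration).
#' @param sig_p,sig_fdr Cross-enrichment significance regime (defaults
#'   0.05 and 0.25).
#' @return List of class `convergence_params`.
#' @export
convergence_params <- function(top_k_gsea = 200L, top_k_magenta = 30L,
                               sig_p = 0.05, sig_fdr = 0.25) {
  stopifnot(top_k_gsea >= 1, top_k_magenta >= 1,
            sig_p > 0, sig_p < 1, sig_fdr > 0, sig_fdr <= 1)
  structure(list(top_k_gsea = as.integer(top_k_gsea),
                 top_k_magenta = as.integer(top_k_magenta),
                 sig_p = sig_p, sig_fdr = sig_fdr),
            class = "convergence_params")
}

#' Build a custom superset from one arm's top pathways
#'
#' Orders results canonically (p ascending, then FDR ascending, then set
#' name) and returns the top `top_k` pathways as a new collection with
#' their original memberships. Fewer than `top_k` available results are
#' all taken with a warning.
#'
#' @param results A `gsea_run`, `magenta_run` or their `results`
#'   data.frame.
#' @param collection The [gene_set_collection] the results were computed
#'   on (supplies memberships).
#' @param top_k Number of pathways to take.
#' @param direction For expression-side results: `"pos"`, `"neg"` or
#'   `"both"` to restrict by enrichment sign before ranking (default
#'   `"both"`).
#' @return A [gene_set_collection].
#' @export
build_custom_superset <- function(results, collection, top_k,
                                  direction = c("both", "pos", "neg")) {
  direction <- match.arg(direction)
  if (inherits(results, c("gsea_run", "magenta_run")))
    results <- results$results
  if (NROW(results) == 0L) stop("empty results; cannot build a superset")
  pcol <- if ("p_nominal" %in% names(results)) "p_nominal" else "p_enrich"
  if (direction != "both" && "direction" %in% names(results))
    results <- results[results$direction == direction, , drop = FALSE]
  if (NROW(results) == 0L)
    stop("no results left after direction filter")
  results <- results[order(results[[pcol]], results$fdr_q,
                           results$set_name), , drop = FALSE]
  if (nrow(results) < top_k) {
    warning("only ", nrow(results), " results available; taking all")
    top_k <- nrow(results)
  }
  nm <- results$set_name[seq_len(top_k)]
  gene_set_collection(collection$sets[nm], collection$desc[nm],
                      paste0("superset(", collection$source_label, ")"))
}

#' Cross-enrich a superset in the other analysis arm
#'
#' GvsM direction: the expression-side superset is evaluated by the GWAS
#' engine; MvsG direction: the GWAS-side superset is evaluated by the
#' expression engine. FDR is computed within the superset. Pathways with
#' p < `sig_p` and FDR < `sig_fdr` are flagged cross-enriched.
#'
#' @param superset A [gene_set_collection] from [build_custom_superset()].
#' @param direction `"gvm"` or `"mvg"`.
#' @param x,pheno Expression matrix and phenotype (MvsG direction).
#' @param snps,genes GWAS table and gene coordinates (GvsM direction).
#' @param gsea_par,magenta_par Engine parameter lists.
#' @return The engine run object (`magenta_run` or `gsea_run`) with an
#'   added `cross_enriched` character vector of pathway names.
#' @export
cross_enrich <- function(superset, direction = c("gvm", "mvg"),
                         x = NULL, pheno = NULL, snps = NULL, genes = NULL,
                         gsea_par = gsea_params(),
                         magenta_par = magenta_params()) {
  direction <- match.arg(direction)
  stopifnot(inherits(superset, "gene_set_collection"))
  if (length(superset) == 0L) stop("empty superset")
  if (direction == "gvm") {
    if (is.null(snps) || is.null(genes))
      stop("GvsM cross-enrichment needs 'snps' and 'genes'")
    run <- run_magenta(snps, genes, superset, magenta_par)
    hits <- run$results$set_name[run$results$significant]
  } else {
    if (is.null(x) || is.null(pheno))
      stop("MvsG cross-enrichment needs 'x' and 'pheno'")
    run <- run_gsea(x, pheno, superset, gsea_par)
    hits <- run$results$set_name[run$results$significant]
  }
  run$cross_enriched <- hits
  run
}

# GWAS-arm analogue of a leading edge: set members with corrected gene
# score strictly above the enrichment cutoff
magenta_leading_genes <- function(magenta_run, collection, set_names) {
  tab <- magenta_run$scores
  above <- tab$gene_id[tab$corrected_score > magenta_run$cutoff_value]
  sort(unique(unlist(lapply(set_names, function(nm)
    intersect(collection$sets[[nm]], above)))))
}

#' Intersect leading-edge genes across the two directions
#'
#' MvsG-side leading genes are the union of GSEA leading edges of the
#' cross-enriched pathways; GvsM-side leading genes are the union over
#' cross-enriched pathways of members with corrected gene score strictly
#' above the enrichment cutoff (the GWAS-arm analogue of a leading edge).
#' The overlap is the intersection of the two unions.
#'
#' @param gvm A `magenta_run` from [cross_enrich()] (direction "gvm").
#' @param mvg A `gsea_run` from [cross_enrich()] (direction "mvg").
#' @param superset_gvm The superset collection evaluated in `gvm`.
#' @return List with `gvm_genes`, `mvg_genes` and `overlap` (character
#'   vectors); all empty, with a warning, when either direction has no
#'   cross-enriched pathway.
#' @export
overlap_leading_edges <- function(gvm, mvg, superset_gvm) {
  if (length(gvm$cross_enriched) == 0L ||
      length(mvg$cross_enriched) == 0L) {
    warning("a direction has no cross-enriched pathway; empty overlap")
    return(list(gvm_genes = character(0), mvg_genes = character(0),
                overlap = character(0)))
  }
  gvm_genes <- magenta_leading_genes(gvm, superset_gvm, gvm$cross_enriched)
  mres <- mvg$results
  mvg_genes <- sort(unique(unlist(
    mres$leading_edge[mres$set_name %in% mvg$cross_enriched])))
  list(gvm_genes = gvm_genes, mvg_genes = mvg_genes,
       overlap = intersect(gvm_genes, mvg_genes))
}

#' Flag GWAS-SNP presence per gene
#'
#' TRUE when at least one input SNP lies inside the gene's assignment
#' window (the same strand-aware windows as the GWAS engine); NA for genes
#' absent from the coordinate table (serialized as "." in reports,
#' distinct from FALSE).
#'
#' @param gene_ids Genes to annotate.
#' @param snps GWAS `data.frame`.
#' @param genes Gene `data.frame`.
#' @param upstream_kb,downstream_kb Window widths in kb.
#' @return Named logical vector (NA = no coordinates).
#' @export
annotate_gwas_presence <- function(gene_ids, snps, genes,
                                   upstream_kb = 110, downstream_kb = 40) {
  out <- setNames(rep(NA, length(gene_ids)), gene_ids)
  known <- intersect(gene_ids, genes$gene_id)
  if (length(known)) {
    sub <- genes[genes$gene_id %in% known, , drop = FALSE]
    asg <- assign_snps_to_genes(snps, sub, upstream_kb, downstream_kb)
    out[known] <- known %in% names(asg)
  }
  out
}

#' Assemble the convergence report
#'
#' One row per gene appearing in either direction's leading genes, with the
#' differential-expression -log10(p), direction flags, the GWAS-SNP flag
#' and comma-joined cross-enriched pathway memberships per direction.
#'
#' @param edges Output of [overlap_leading_edges()].
#' @param gvm,mvg The two [cross_enrich()] runs.
#' @param superset_gvm Superset evaluated in the GvsM direction.
#' @param de Differential-expression table
#'   ([differential_expression()]).
#' @param snps,genes For the SNP flag.
#' @param upstream_kb,downstream_kb Annotation windows in kb.
#' @return Convergence-report `data.frame` in the order of
#'   [order_report()].
#' @export
convergence_report <- function(edges, gvm, mvg, superset_gvm, de, snps,
                               genes, upstream_kb = 110,
                               downstream_kb = 40) {
  all_genes <- sort(unique(c(edges$gvm_genes, edges$mvg_genes)))
  if (length(all_genes) == 0L) return(empty_report())
  dep <- setNames(de$p_value, de$gene_id)[all_genes]
  has_snp <- annotate_gwas_presence(all_genes, snps, genes, upstream_kb,
                                    downstream_kb)
  path_gvm <- vapply(all_genes, function(g) {
    nm <- gvm$cross_enriched[vapply(gvm$cross_enriched, function(s)
      g %in% intersect(superset_gvm$sets[[s]],
                       edges$gvm_genes), logical(1))]
    if (length(nm)) paste(nm, collapse = ",") else NA_character_
  }, character(1))
  mres <- mvg$results
  path_mvg <- vapply(all_genes, function(g) {
    nm <- mvg$cross_enriched[vapply(mvg$cross_enriched, function(s)
      g %in% mres$leading_edge[[match(s, mres$set_name)]], logical(1))]
    if (length(nm)) paste(nm, collapse = ",") else NA_character_
  }, character(1))
  rep <- data.frame(gene_id = all_genes,
                    has_gwas_snp = unname(has_snp),
                    de_minus_log10_p = -log10(unname(dep)),
                    in_gvm = all_genes %in% edges$gvm_genes,
                    in_mvg = all_genes %in% edges$mvg_genes,
                    pathways_gvm = unname(path_gvm),
                    pathways_mvg = unname(path_mvg),
                    stringsAsFactors = FALSE)
  order_report(rep)
}

#' Run the full convergence pipeline
#'
#' The complete bidirectional cross-interrogation: differential
#' expression, expression-side GSEA and GWAS-side enrichment on the full
#' collection, custom supersets from each arm's top *significantly*
#' enriched pathways (expression side restricted to positively enriched
#' pathways, mirroring enrichment in class 1), cross-enrichment in the
#' opposite arm, leading-edge overlap and the final report. When an arm
#' has no significant pathway its superset is empty and that direction
#' contributes no cross-enriched pathways, so fully null inputs produce an
#' empty report rather than an error.
#'
#' @param x Expression matrix.
#' @param pheno Binary [phenotype].
#' @param collection [gene_set_collection].
#' @param snps,genes GWAS table and gene coordinates.
#' @param params [convergence_params()].
#' @param gsea_par,magenta_par Engine parameters.
#' @return Object of class `convergence_run`: `report`, `overlap`,
#'   `gsea`, `magenta`, `gvm`, `mvg`, `superset_gvm`, `superset_mvg`,
#'   `de`, `params`.
#' @export
run_convergence <- function(x, pheno, collection, snps, genes,
                            params = convergence_params(),
                            gsea_par = gsea_params(),
                            magenta_par = magenta_params()) {
  stopifnot(inherits(params, "convergence_params"))
  de <- differential_expression(x, pheno)
  gsea_main <- run_gsea(x, pheno, collection, gsea_par)
  magenta_main <- run_magenta(snps, genes, collection, magenta_par)
  # supersets condition on significance: "top k significantly enriched".
  # The expression arm applies its full regime (p and FDR, positive
  # enrichment); the GWAS arm gates on nominal enrichment p, its method's
  # native significance label -- the FDR gate applies at the
  # cross-enrichment stage.
  gsig <- gsea_main$results[gsea_main$results$significant &
                              gsea_main$results$direction == "pos", ,
                            drop = FALSE]
  msig <- magenta_main$results[magenta_main$results$p_enrich <
                                 params$sig_p, , drop = FALSE]
  skipped_direction <- function() {
    list(cross_enriched = character(0), results = NULL, skipped = TRUE)
  }
  gvm_par <- magenta_par; gvm_par$sig_p <- params$sig_p
  gvm_par$sig_fdr <- params$sig_fdr
  mvg_par <- gsea_par; mvg_par$sig_p <- params$sig_p
  mvg_par$sig_fdr <- params$sig_fdr
  if (nrow(gsig)) {
    superset_gvm <- suppressWarnings(
      build_custom_superset(gsig, collection, params$top_k_gsea))
    gvm <- cross_enrich(superset_gvm, "gvm", snps = snps, genes = genes,
                        magenta_par = gvm_par)
  } else {
    warning("no significant positively enriched pathway; ",
            "GvsM direction skipped")
    superset_gvm <- NULL
    gvm <- skipped_direction()
  }
  if (nrow(msig)) {
    superset_mvg <- suppressWarnings(
      build_custom_superset(msig, collection, params$top_k_magenta))
    mvg <- cross_enrich(superset_mvg, "mvg", x = x, pheno = pheno,
                        gsea_par = mvg_par)
  } else {
    warning("no significant GWAS-enriched pathway; MvsG direction skipped")
    superset_mvg <- NULL
    mvg <- skipped_direction()
  }
  edges <- suppressWarnings(overlap_leading_edges(gvm, mvg, superset_gvm))
  report <- convergence_report(edges, gvm, mvg, superset_gvm, de, snps,
                               genes, magenta_par$upstream_kb,
                               magenta_par$downstream_kb)
  structure(list(report = report, overlap = edges$overlap,
                 gsea = gsea_main, magenta = magenta_main, gvm = gvm,
                 mvg = mvg, superset_gvm = superset_gvm,
                 superset_mvg = superset_mvg, de = de, params = params),
            class = "convergence_run")
}

#' @export
print.convergence_run <- function(x, ...) {
  cat(sprintf(
    paste0("convergence_run: %d GvsM and %d MvsG cross-enriched pathways; ",
           "%d overlap gene(s)\n"),
    length(x$gvm$cross_enriched), length(x$mvg$cross_enriched),
    length(x$overlap)))
  invisible(x)
}
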