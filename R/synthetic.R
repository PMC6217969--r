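#' Simulation configuration
#'
#' Declares a synthetic study mirroring the structure of a two-class
#' plaque-macrophage microarray comparison with a continuous lipid-content
#' covariate and GWAS summary statistics carrying planted signal: 12 vs 12
#' samples, coordinately up-regulated gene sets in class 1, one designated
#' planted module driving the continuous covariate, and low-p SNPs planted
#' inside the gene windows of selected pathways.
#'
#' Expression is generated on a log-like additive scale (Gaussian noise
#' around `baseline`); chip-level intensity physics is out of scope.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_samples_per_class Samples per class (default 12, the study
#'   scale).
#' @param n_sets Number of gene sets in the collection.
#' @param set_size_range Integer pair; set sizes drawn uniformly inside it.
#' @param n_planted_expression_sets Sets whose members are shifted in
#'   class 1.
#' @param n_planted_gwas_sets Sets whose genes receive planted signal SNPs.
#' @param n_convergent_sets Sets planted on BOTH sides (the testable
#'   analogue of cross-omics convergence); must not exceed either planted
#'   count.
#' @param expression_effect Standardized mean shift (in units of
#'   `noise_sd`) applied to planted genes in class 1.
#' @param noise_sd Per-gene Gaussian noise sd.
#' @param baseline Additive baseline expression level.
#' @param continuous_covariate_coupling Coupling in [0, 1] between the
#'   continuous covariate and the designated planted module's mean.
#' @param n_snps Number of null GWAS SNPs placed uniformly on the genome.
#' @param gwas_signal_fraction Probability that a planted-set gene receives
#'   a signal SNP.
#' @param gwas_signal_pvalue_scale Signal SNP p ~ Uniform(0, scale).
#' @param gene_length_kb Gene length range in kb (scalar or length-2);
#'   lengths are drawn uniformly inside it so gene span varies and the
#'   GWAS-arm confounder regression is non-degenerate.
#' @param intergene_gap_kb,n_chromosomes Genome layout; the default 400 kb
#'   gap keeps default 110/40 kb windows of adjacent genes disjoint.
#' @param seed Master seed; every generator derives its stream from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples_per_class = 12L,
                       n_sets = 200L, set_size_range = c(20L, 100L),
                       n_planted_expression_sets = 3L,
                       n_planted_gwas_sets = 2L, n_convergent_sets = 1L,
                       expression_effect = 1.0, noise_sd = 1.0,
                       baseline = 0, continuous_covariate_coupling = 0.8,
                       n_snps = 5000L, gwas_signal_fraction = 0.3,
                       gwas_signal_pvalue_scale = 1e-6,
                       gene_length_kb = c(5, 50), intergene_gap_kb = 400,
                       n_chromosomes = 20L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_class = as.integer(n_samples_per_class),
              n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              n_planted_expression_sets = as.integer(n_planted_expression_sets),
              n_planted_gwas_sets = as.integer(n_planted_gwas_sets),
              n_convergent_sets = as.integer(n_convergent_sets),
              expression_effect = expression_effect, noise_sd = noise_sd,
              baseline = baseline,
              continuous_covariate_coupling = continuous_covariate_coupling,
              n_snps = as.integer(n_snps),
              gwas_signal_fraction = gwas_signal_fraction,
              gwas_signal_pvalue_scale = gwas_signal_pvalue_scale,
              gene_length_kb = if (length(gene_length_kb) == 1L)
                rep(gene_length_kb, 2L) else gene_length_kb,
              intergene_gap_kb = intergene_gap_kb,
              n_chromosomes = as.integer(n_chromosomes),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_samples_per_class >= 2, n_sets > 0,
              length(set_size_range) == 2L, set_size_range[1] >= 2,
              set_size_range[2] >= set_size_range[1],
              set_size_range[2] <= n_genes,
              n_planted_expression_sets >= 0,
              n_planted_expression_sets <= n_sets,
              n_planted_gwas_sets >= 0, n_planted_gwas_sets <= n_sets,
              n_convergent_sets <= min(n_planted_expression_sets,
                                       max(n_planted_gwas_sets, 0)) ||
                n_convergent_sets == 0,
              noise_sd > 0,
              continuous_covariate_coupling >= 0,
              continuous_covariate_coupling <= 1,
              n_snps > 0, gwas_signal_fraction >= 0,
              gwas_signal_fraction <= 1, gwas_signal_pvalue_scale > 0,
              all(gene_length_kb > 0),
              gene_length_kb[2] >= gene_length_kb[1],
              intergene_gap_kb >= 0,
              n_chromosomes >= 1, seed >= 0)
  })
  structure(cfg, class = "sim_config")
}

gene_universe <- function(config) sprintf("G%05d", seq_len(config$n_genes))

#' Generate a gene-set collection with planted ground truth
#'
#' Draws `n_sets` sets with sizes uniform in `set_size_range` and members
#' sampled from the gene universe, then designates the planted
#' expression-side and GWAS-side sets (sharing `n_convergent_sets` names).
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `collection` (a [gene_set_collection]) and `truth`
#'   (partial ground truth: `planted_expression_sets`,
#'   `planted_gwas_sets`, `convergent_sets`, `covariate_module`).
#' @export
sim_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  universe <- gene_universe(config)
  sizes <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
                  config$n_sets, replace = TRUE)
  nm <- sprintf("SET_%04d", seq_len(config$n_sets))
  sets <- setNames(lapply(sizes, sample, x = universe), nm)
  n_expr <- config$n_planted_expression_sets
  n_gwas <- config$n_planted_gwas_sets
  n_conv <- config$n_convergent_sets
  n_planted <- n_expr + n_gwas - n_conv
  planted <- if (n_planted > 0) sample(nm, n_planted) else character(0)
  expr_sets <- planted[seq_len(n_expr)]
  conv_sets <- planted[seq_len(n_conv)]
  gwas_sets <- c(conv_sets,
                 planted[setdiff(seq_len(n_planted), seq_len(n_expr))])
  truth <- list(planted_expression_sets = expr_sets,
                planted_gwas_sets = gwas_sets,
                convergent_sets = intersect(expr_sets, gwas_sets),
                covariate_module = if (n_expr > 0) expr_sets[1L]
                                   else character(0))
  list(collection = gene_set_collection(
         sets, source_label = sprintf("synthetic(seed=%d)", config$seed)),
       truth = truth)
}

#' Generate the expression study
#'
#' Background expression is `baseline + Normal(0, noise_sd)`; genes of the
#' planted expression sets are additionally shifted by
#' `expression_effect * noise_sd` in class 1 only. The continuous covariate
#' couples to the standardized mean of the designated planted module:
#' `coupling * module_mean + (1 - coupling) * Normal(0, 1)`.
#'
#' @param config A [sim_config()].
#' @param collection,truth From [sim_collection()].
#' @return List with `matrix`, `pheno_binary` (class 1 "symptomatic"),
#'   `pheno_continuous` and `truth` updated with `planted_de_genes`.
#' @export
sim_expression <- function(config, collection, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  universe <- gene_universe(config)
  n <- 2L * config$n_samples_per_class
  x <- config$baseline +
    matrix(rnorm(config$n_genes * n, 0, config$noise_sd),
           config$n_genes, n,
           dimnames = list(universe, sprintf("S%02d", seq_len(n))))
  labels <- rep(c("symptomatic", "asymptomatic"),
                each = config$n_samples_per_class)
  planted <- sort(unique(unlist(
    collection$sets[truth$planted_expression_sets])))
  i1 <- which(labels == "symptomatic")
  if (length(planted))  # shift applied once per gene even if in two sets
    x[planted, i1] <- x[planted, i1] +
      config$expression_effect * config$noise_sd
  coup <- config$continuous_covariate_coupling
  module <- if (length(truth$covariate_module))
    collection$sets[[truth$covariate_module]] else character(0)
  z <- if (length(module)) {
    mm <- colMeans(x[module, , drop = FALSE])
    as.vector(scale(mm))
  } else rep(0, n)
  covariate <- coup * z + (1 - coup) * rnorm(n)
  truth$planted_de_genes <- planted
  list(matrix = x,
       pheno_binary = phenotype(labels,
                                class_names = c("symptomatic",
                                                "asymptomatic"),
                                name = "presentation"),
       pheno_continuous = phenotype(covariate, kind = "continuous",
                                    name = "lipid_pct"),
       truth = truth)
}

#' Generate the genome annotation
#'
#' Lays genes consecutively on `n_chromosomes` synthetic chromosomes with a
#' fixed gene length and inter-gene gap (default 400 kb, large enough that
#' default 110/40 kb assignment windows of neighbours stay disjoint).
#' Strands alternate deterministically with the seed.
#'
#' @param config A [sim_config()].
#' @return Gene `data.frame` (BED-like, 0-based half-open).
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  universe <- gene_universe(config)
  len <- round(runif(config$n_genes, config$gene_length_kb[1L],
                     config$gene_length_kb[2L]) * 1000)
  gap <- round(config$intergene_gap_kb * 1000)
  slot_pitch <- round(config$gene_length_kb[2L] * 1000) + gap
  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  chrom_i <- rep(seq_len(config$n_chromosomes), each = per_chrom,
                 length.out = config$n_genes)
  slot <- unlist(lapply(rle(chrom_i)$lengths, seq_len)) - 1L
  start <- gap + slot * slot_pitch
  data.frame(gene_id = universe,
             chrom = sprintf("chrS%02d", chrom_i),
             start = as.integer(start),
             end = as.integer(start + len),
             strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate GWAS summary statistics with planted signal
#'
#' Places `n_snps` null SNPs uniformly over the synthetic chromosomes with
#' p ~ Uniform(0, 1); then, for each gene of each planted GWAS set, with
#' probability `gwas_signal_fraction` appends one signal SNP inside the
#' gene body (hence inside its assignment window) with
#' p ~ Uniform(0, gwas_signal_pvalue_scale).
#'
#' @param config A [sim_config()].
#' @param annotation From [sim_annotation()].
#' @param collection,truth From [sim_collection()].
#' @return List with `snps` (GWAS `data.frame`, columns `snp`, `chrom`,
#'   `pos0`, `p`) and `truth` updated with `planted_gwas_genes` (genes
#'   actually given a signal SNP).
#' @export
sim_gwas <- function(config, annotation, collection, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  chroms <- unique(annotation$chrom)
  chrom_len <- vapply(chroms, function(cc) {
    max(annotation$end[annotation$chrom == cc]) +
      round(config$intergene_gap_kb * 1000)
  }, numeric(1))
  pick <- sample(length(chroms), config$n_snps, replace = TRUE,
                 prob = chrom_len / sum(chrom_len))
  pos0 <- floor(runif(config$n_snps) * chrom_len[pick])
  null_snps <- data.frame(snp = sprintf("snp%06d", seq_len(config$n_snps)),
                          chrom = chroms[pick], pos0 = as.integer(pos0),
                          p = runif(config$n_snps),
                          stringsAsFactors = FALSE)
  planted_genes <- sort(unique(unlist(
    collection$sets[truth$planted_gwas_sets])))
  hit <- planted_genes[runif(length(planted_genes)) <
                         config$gwas_signal_fraction]
  sig <- NULL
  if (length(hit)) {
    rows <- match(hit, annotation$gene_id)
    span <- annotation$end[rows] - annotation$start[rows]
    sig <- data.frame(snp = sprintf("sig%06d", seq_along(hit)),
                      chrom = annotation$chrom[rows],
                      pos0 = as.integer(annotation$start[rows] +
                                          floor(runif(length(hit)) * span)),
                      p = runif(length(hit)) *
                        config$gwas_signal_pvalue_scale,
                      stringsAsFactors = FALSE)
  }
  truth$planted_gwas_genes <- hit
  list(snps = rbind(null_snps, sig), truth = truth)
}

#' Generate a complete synthetic study
#'
#' Runs all generators in order and returns every artifact plus the
#' audit-consistent ground truth. With `dir` set, also writes the on-disk
#' study (GCT, binary and continuous CLS, GMT, BED6, GWAS TSV, truth JSON).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List of class `sim_study`: `config`, `collection`, `truth`,
#'   `matrix`, `pheno_binary`, `pheno_continuous`, `annotation`, `snps`,
#'   and (when written) `files`.
#' @export
sim_study <- function(config = sim_config(), dir = NULL) {
  coll <- sim_collection(config)
  expr <- sim_expression(config, coll$collection, coll$truth)
  ann <- sim_annotation(config)
  gwas <- sim_gwas(config, ann, coll$collection, expr$truth)
  out <- list(config = config, collection = coll$collection,
              truth = gwas$truth, matrix = expr$matrix,
              pheno_binary = expr$pheno_binary,
              pheno_continuous = expr$pheno_continuous,
              annotation = ann, snps = gwas$snps)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(gct = file.path(dir, "expression.gct"),
               cls = file.path(dir, "phenotype.cls"),
               cls_cont = file.path(dir, "lipid.cls"),
               gmt = file.path(dir, "sets.gmt"),
               bed = file.path(dir, "genes.bed"),
               gwas = file.path(dir, "gwas.tsv"),
               truth = file.path(dir, "truth.json"))
    write_gct(out$matrix, files[["gct"]])
    write_cls(out$pheno_binary, files[["cls"]])
    write_cls(out$pheno_continuous, files[["cls_cont"]])
    write_gmt(out$collection, files[["gmt"]])
    write_gene_bed(out$annotation, files[["bed"]])
    write_gwas_table(out$snps, files[["gwas"]])
    jsonlite::write_json(out$truth, files[["truth"]], auto_unbox = FALSE,
                         digits = NA)
    out$files <- files
  }
  class(out) <- "sim_study"
  out
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    paste0("sim_study: %d genes x %d samples, %d sets ",
           "(%d expr-planted, %d gwas-planted, %d convergent), %d SNPs\n"),
    nrow(x$matrix), ncol(x$matrix), length(x$collection),
    length(x$truth$planted_expression_sets),
    length(x$truth$planted_gwas_sets), length(x$truth$convergent_sets),
    nrow(x$snps)))
  invisible(x)
}
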