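small_cfg <- function(...) {
  args <- list(n_genes = 300L, n_sets = 20L, set_size_range = c(8L, 15L),
               n_snps = 1000L, seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("generators are deterministic under the seed", {
  a <- sim_study(small_cfg())
  b <- sim_study(small_cfg())
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$collection$sets, b$collection$sets)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$snps, b$snps)
  expect_identical(a$truth, b$truth)
  expect_equal(a$pheno_continuous$values, b$pheno_continuous$values,
               tolerance = 1e-12)
  c <- sim_study(small_cfg(seed = 12L))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("collection truth is audit-consistent set algebra", {
  cfg <- small_cfg(n_planted_expression_sets = 2L, n_planted_gwas_sets = 2L,
                   n_convergent_sets = 1L)
  out <- sim_collection(cfg)
  tr <- out$truth
  expect_length(tr$planted_expression_sets, 2L)
  expect_length(tr$planted_gwas_sets, 2L)
  expect_identical(tr$convergent_sets,
                   intersect(tr$planted_expression_sets,
                             tr$planted_gwas_sets))
  expect_length(tr$convergent_sets, 1L)
  # all members drawn from the declared universe
  universe <- sprintf("G%05d", seq_len(cfg$n_genes))
  expect_true(all(unlist(out$collection$sets) %in% universe))
  sz <- lengths(out$collection$sets)
  expect_true(all(sz >= 8 & sz <= 15))
})

test_that("planted expression effect matches its nominal size", {
  cfg <- sim_config(n_genes = 1500L, n_sets = 30L,
                    set_size_range = c(30L, 60L),
                    n_planted_expression_sets = 3L, expression_effect = 1,
                    noise_sd = 1, seed = 5L)
  coll <- sim_collection(cfg)
  ex <- sim_expression(cfg, coll$collection, coll$truth)
  planted <- ex$truth$planted_de_genes
  expect_gte(length(planted), 50L)
  ci <- which(ex$pheno_binary$values == "symptomatic")
  diffs <- rowMeans(ex$matrix[planted, ci]) -
    rowMeans(ex$matrix[planted, -ci])
  # mean class difference within 3 SE of effect * noise_sd
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1), 3 * se)
})

test_that("null expression study yields uniform DE p-values", {
  cfg <- sim_config(n_genes = 5000L, n_sets = 10L,
                    set_size_range = c(10L, 20L), expression_effect = 0,
                    seed = 21L)
  coll <- sim_collection(cfg)
  ex <- sim_expression(cfg, coll$collection, coll$truth)
  de <- differential_expression(ex$matrix, ex$pheno_binary)
  frac <- mean(de$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("degenerate coupling makes the covariate a pure module readout", {
  cfg <- small_cfg(continuous_covariate_coupling = 1)
  coll <- sim_collection(cfg)
  ex <- sim_expression(cfg, coll$collection, coll$truth)
  module <- coll$collection$sets[[coll$truth$covariate_module]]
  mm <- colMeans(ex$matrix[module, ])
  expect_equal(cor(ex$pheno_continuous$values, mm), 1, tolerance = 1e-12)
})

test_that("genome layout keeps default assignment windows disjoint", {
  cfg <- small_cfg()
  ann <- sim_annotation(cfg)
  expect_true(all(ann$end - ann$start >= 1000))
  win <- pathconverge:::gene_windows(ann, 110, 40)
  by_chrom <- split(win, win$chrom)
  overlaps <- vapply(by_chrom, function(w) {
    w <- w[order(w$start), ]
    if (nrow(w) < 2L) return(0L)
    sum(w$start[-1L] < w$end[-nrow(w)])
  }, integer(1))
  expect_true(all(overlaps == 0L))
})

test_that("null GWAS p-values are uniform; planted signal is audited", {
  cfg0 <- sim_config(n_genes = 500L, n_sets = 20L,
                     set_size_range = c(8L, 15L), n_snps = 10000L,
                     gwas_signal_fraction = 0, seed = 31L)
  c0 <- sim_collection(cfg0)
  ann0 <- sim_annotation(cfg0)
  g0 <- sim_gwas(cfg0, ann0, c0$collection, c0$truth)
  expect_equal(nrow(g0$snps), 10000L)
  expect_length(g0$truth$planted_gwas_genes, 0L)
  ks <- suppressWarnings(stats::ks.test(g0$snps$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  cfg1 <- sim_config(n_genes = 500L, n_sets = 20L,
                     set_size_range = c(8L, 15L), n_snps = 2000L,
                     gwas_signal_fraction = 1,
                     gwas_signal_pvalue_scale = 1e-6, seed = 32L)
  c1 <- sim_collection(cfg1)
  ann1 <- sim_annotation(cfg1)
  g1 <- sim_gwas(cfg1, ann1, c1$collection, c1$truth)
  planted_genes <- sort(unique(unlist(
    c1$collection$sets[c1$truth$planted_gwas_sets])))
  expect_identical(g1$truth$planted_gwas_genes, planted_genes)
  # every planted gene's window holds at least one p <= 1e-6 SNP
  asg <- assign_snps_to_genes(g1$snps, ann1)
  best <- vapply(planted_genes, function(g)
    min(g1$snps$p[asg[[g]]]), numeric(1))
  expect_true(all(best <= 1e-6))
})

test_that("written study files parse back to the generated objects", {
  dir <- tempfile("study")
  st <- sim_study(small_cfg(), dir = dir)
  back <- read_gct_cls(st$files[["gct"]], st$files[["cls"]])
  expect_equal(back$matrix, st$matrix, tolerance = 1e-12)
  expect_identical(back$phenotype$values, st$pheno_binary$values)
  expect_identical(read_gmt(st$files[["gmt"]])$sets, st$collection$sets)
  expect_identical(read_gene_bed(st$files[["bed"]]), st$annotation)
  snps <- read_gwas_table(st$files[["gwas"]])
  expect_equal(snps$pos0, st$snps$pos0)
  expect_equal(snps$p, st$snps$p, tolerance = 1e-12)
})
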