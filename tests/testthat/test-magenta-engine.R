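fake_scores <- function(corrected, gene_ids = sprintf("G%03d",
                                                      seq_along(corrected))) {
  out <- data.frame(gene_id = gene_ids,
                    n_snps = 1L, best_p = 0.5, raw_score = 0.3,
                    span_kb = 10, density = 0.1,
                    corrected_score = corrected,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

test_that("window assignment follows strand-aware interval arithmetic", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 1000000L,
                      end = 1010000L, strand = "+",
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp = c("in_up", "out_down", "at_start", "at_end"),
                     chrom = "chr1",
                     pos0 = c(895000L, 1060000L, 890000L, 1050000L),
                     p = 0.5, stringsAsFactors = FALSE)
  asg <- assign_snps_to_genes(snps, genes, 110, 40)
  # region [890000, 1050000): start included, end excluded
  expect_identical(snps$snp[asg$G1], c("in_up", "at_start"))
  genes$strand <- "-"
  snps2 <- data.frame(snp = c("down_ok", "up_no"), chrom = "chr1",
                      pos0 = c(1115000L, 895000L), p = 0.5,
                      stringsAsFactors = FALSE)
  asg2 <- assign_snps_to_genes(snps2, genes, 110, 40)
  # minus strand region [960000, 1120000)
  expect_identical(snps2$snp[asg2$G1], "down_ok")
  expect_error(assign_snps_to_genes(snps, genes, -1, 40), ">= 0")
})

test_that("a SNP inside two overlapping regions maps to both genes", {
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                      start = c(100000L, 150000L), end = c(120000L, 170000L),
                      strand = "+", stringsAsFactors = FALSE)
  snps <- data.frame(snp = "shared", chrom = "chr1", pos0 = 130000L,
                     p = 0.01, stringsAsFactors = FALSE)
  asg <- assign_snps_to_genes(snps, genes, 110, 40)
  expect_identical(sort(names(asg)), c("GA", "GB"))
})

test_that("widening the upstream window only grows assignments", {
  cfg <- sim_config(n_genes = 200L, n_sets = 10L,
                    set_size_range = c(5L, 10L), n_snps = 3000L,
                    seed = 13L)
  st <- sim_study(cfg)
  a1 <- assign_snps_to_genes(st$snps, st$annotation, 110, 40)
  a2 <- assign_snps_to_genes(st$snps, st$annotation, 220, 40)
  expect_true(all(names(a1) %in% names(a2)))
  for (g in names(a1)) expect_true(all(a1[[g]] %in% a2[[g]]))
})

test_that("best-SNP gene scores and monotonicity", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 0L,
                      end = 10000L, strand = "+", stringsAsFactors = FALSE)
  snps <- data.frame(snp = c("a", "b"), chrom = "chr1",
                     pos0 = c(1000L, 2000L), p = c(0.01, 0.5),
                     stringsAsFactors = FALSE)
  tab <- score_genes(assign_snps_to_genes(snps, genes, 10, 10), snps, genes)
  expect_equal(tab$raw_score, 2)
  expect_equal(tab$n_snps, 2L)
  expect_equal(tab$span_kb, 10)
  # single SNP with p = 1 scores exactly 0
  one <- snps[2, ]; one$p <- 1
  tab0 <- score_genes(assign_snps_to_genes(one, genes, 10, 10), one, genes)
  expect_equal(tab0$raw_score, 0)
  # adding a larger-p SNP never decreases the score
  set.seed(5)
  for (k in 1:10) {
    ps <- runif(4)
    base <- -log10(min(ps))
    expect_gte(-log10(min(c(ps, runif(1)))), base)
  }
})

test_that("confounder correction leaves orthogonal residuals", {
  set.seed(17)
  tab <- fake_scores(rnorm(50))
  tab$span_kb <- runif(50, 1, 60)
  tab$n_snps <- rpois(50, 4) + 1L
  tab$density <- tab$n_snps / tab$span_kb
  # perfect linear confounding -> all residuals 0
  tab$raw_score <- 2 + 3 * tab$span_kb
  out <- correct_gene_scores(tab)
  expect_equal(max(abs(out$corrected_score)), 0, tolerance = 1e-8)
  # generic scores: residuals orthogonal to each confounder
  tab$raw_score <- rexp(50)
  out <- correct_gene_scores(tab)
  for (v in c("span_kb", "n_snps", "density"))
    expect_lt(abs(cor(out$corrected_score, out[[v]])), 1e-8)
  # constant confounders -> centering only
  tab2 <- fake_scores(rnorm(12))
  tab2$raw_score <- rexp(12)
  out2 <- correct_gene_scores(tab2)
  expect_equal(out2$corrected_score, tab2$raw_score - mean(tab2$raw_score),
               tolerance = 1e-12)
  expect_error(correct_gene_scores(fake_scores(rnorm(5))), "at least 10")
})

test_that("percentile-cutoff enrichment agrees with the hypergeometric tail", {
  tab <- fake_scores(as.numeric(1:100))
  # 75th percentile of 1..100 is 75.25 -> exactly 25 genes strictly above
  members <- tab$gene_id[c(76:81, 10, 20)]  # 6 above, 2 below
  set.seed(29)
  res <- magenta_set_enrichment(tab, members, 75, n_null = 20000L)
  expect_equal(res$n_scored, 8L)
  expect_equal(res$n_above, 6L)
  expect_equal(res$expected_above, 2)
  p_exact <- phyper(5, 25, 75, 8, lower.tail = FALSE)
  expect_equal(res$p_hyper, p_exact, tolerance = 1e-12)
  expect_lt(abs(res$p_enrich - p_exact), 0.02)
  # no member above the cutoff -> p near 1
  low <- tab$gene_id[1:6]
  res0 <- magenta_set_enrichment(tab, low, 75, n_null = 2000L)
  expect_equal(res0$n_above, 0L)
  expect_gt(res0$p_enrich, 0.95)
  expect_error(magenta_set_enrichment(tab, tab$gene_id[1:2]),
               "fewer than 3")
})

test_that("null enrichment p-values are calibrated (discrete, conservative)", {
  set.seed(37)
  tab <- fake_scores(rnorm(300))
  ps <- vapply(1:150, function(k) {
    members <- sample(tab$gene_id, 12)
    magenta_set_enrichment(tab, members, 75, n_null = 400L)$p_enrich
  }, numeric(1))
  # the count statistic has ~13 support points, so p is discrete and
  # conservative: P(p <= t) <= t, checked with Monte-Carlo slack
  for (t in c(0.05, 0.1, 0.25))
    expect_lt(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / length(ps)))
  expect_gt(mean(ps), 0.4)
})

test_that("run_magenta recovers planted sets and is order-invariant", {
  cfg <- sim_config(n_genes = 600L, n_sets = 40L,
                    set_size_range = c(20L, 40L), n_snps = 2500L,
                    gwas_signal_fraction = 0.4, seed = 43L)
  st <- sim_study(cfg)
  par <- magenta_params(n_null = 3000L, seed = 44L)
  run <- suppressMessages(
    run_magenta(st$snps, st$annotation, st$collection, par))
  res <- run$results
  planted <- st$truth$planted_gwas_sets
  expect_true(all(match(planted, res$set_name) <= 4))
  expect_true(all(res$significant[match(planted, res$set_name)]))
  expect_true(all(diff(res$p_enrich) >= 0))
  # permuting SNP and gene input order leaves every output identical
  set.seed(45)
  snps_perm <- st$snps[sample(nrow(st$snps)), ]
  genes_perm <- st$annotation[sample(nrow(st$annotation)), ]
  run2 <- suppressMessages(
    run_magenta(snps_perm, genes_perm, st$collection, par))
  expect_equal(run2$results[names(run2$results) != "p_enrich"],
               res[names(res) != "p_enrich"], ignore_attr = TRUE)
  expect_equal(run2$results$p_enrich, res$p_enrich, tolerance = 1e-12)
  ord <- order(run$scores$gene_id)
  ord2 <- order(run2$scores$gene_id)
  expect_equal(run$scores[ord, ], run2$scores[ord2, ],
               ignore_attr = TRUE, tolerance = 1e-12)
})
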