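test_that("signal-to-noise metric applies the sd floor rule", {
  # class means 2 and 1, sds exactly 1 -> s2n = 0.5
  x <- rbind(gA = c(1, 2, 3, 0, 1, 2),
             gB = c(2, 2, 2, 1, 1, 1))
  colnames(x) <- paste0("s", 1:6)
  ph <- phenotype(rep(c("c1", "c2"), each = 3))
  rl <- rank_genes(x, ph)
  m <- setNames(rl$metric, rl$gene_id)
  expect_equal(unname(m["gA"]), 0.5, tolerance = 1e-12)
  # constant arms: floored sds 0.4 and 0.2 -> 1 / 0.6
  expect_equal(unname(m["gB"]), 1 / 0.6, tolerance = 1e-12)
  expect_identical(rl$gene_id, c("gB", "gA"))  # sorted non-increasing
})

test_that("pearson ranking puts a covariate-identical gene on top", {
  set.seed(2)
  x <- tiny_matrix(20, 8)
  y <- as.numeric(x[7, ])
  ph <- phenotype(y, kind = "continuous")
  rl <- rank_genes(x, ph)
  expect_identical(rl$gene_id[1], "g07")
  expect_equal(rl$metric[1], 1, tolerance = 1e-12)
  flat <- x; flat[3, ] <- 5  # zero-variance gene gets metric 0, no NA
  expect_false(anyNA(rank_genes(flat, ph)$metric))
  expect_error(rank_genes(x, phenotype(rep(1, 8), kind = "continuous")),
               "zero-variance covariate")
})

test_that("metric ties break deterministically by gene id", {
  x <- matrix(rep(c(2, 2, 2, 1, 1, 1), each = 4), 4, 6, byrow = FALSE,
              dimnames = list(c("d", "b", "a", "c"), paste0("s", 1:6)))
  ph <- phenotype(rep(c("c1", "c2"), each = 3))
  rl <- rank_genes(x, ph)
  expect_identical(rl$gene_id, c("a", "b", "c", "d"))
})

test_that("enrichment score matches hand-computed walks", {
  # metrics (4,3,2,1), set = {rank 2}, weight 1
  rl <- make_ranked(c(4, 3, 2, 1))
  es <- enrichment_score(rl, "g02", 1)
  expect_equal(es$es, 2 / 3, tolerance = 1e-12)
  expect_identical(es$peak_rank, 2L)
  expect_equal(es$running_sum, c(-1 / 3, 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  # top and bottom blocks at weight 0 reach +1 / -1
  rl5 <- make_ranked(c(5, 4, 3, 2, 1))
  expect_equal(enrichment_score(rl5, c("g01", "g02"), 0)$es, 1,
               tolerance = 1e-12)
  bottom <- enrichment_score(rl5, c("g04", "g05"), 0)
  expect_equal(bottom$es, -1, tolerance = 1e-12)
  expect_identical(bottom$peak_rank, 4L)
  # errors: empty intersection vs whole-list set are distinct
  expect_error(enrichment_score(rl5, "absent"), "no gene-set member")
  expect_error(enrichment_score(rl5, rl5$gene_id), "whole ranked list")
})

test_that("enrichment score is bounded and antisymmetric in the complement", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(8:30, 1)
    rl <- make_ranked(sort(rnorm(n), decreasing = TRUE))
    s <- sample(2:min(6, n - 2), 1)
    members <- sample(rl$gene_id, s)
    es1 <- enrichment_score(rl, members, 1)$es
    expect_lte(abs(es1), 1)
    # complement at weight 0 mirrors the set: the running sums are exact
    # negations, so |ES| matches always and the sign flips away from ties
    # (at an exact deviation tie both orientations resolve positive)
    full <- enrichment_score(rl, members, 0)
    e_comp <- enrichment_score(rl, setdiff(rl$gene_id, members), 0)$es
    expect_equal(abs(e_comp), abs(full$es), tolerance = 1e-12)
    tied <- abs(max(full$running_sum) + min(full$running_sum)) < 1e-9
    if (!tied) expect_equal(e_comp, -full$es, tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea on random fixtures", {
  skip_if_not_installed("fgsea")
  set.seed(19)
  for (k in 1:25) {
    n <- sample(15:60, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    rl <- make_ranked(stats)
    s <- sample(3:8, 1)
    idx <- sort(sample.int(n, s))
    mine <- enrichment_score(rl, rl$gene_id[idx], 1)$es
    ref <- fgsea::calcGseaStat(stats, idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("leading-edge extraction follows the peak on both sides", {
  rl <- make_ranked(c(4, 3, 2, 1))
  es <- enrichment_score(rl, "g02", 1)
  expect_identical(extract_leading_edge(rl, "g02", es$es, es$peak_rank),
                   "g02")
  # set entirely above the peak -> whole set, in rank order
  rl8 <- make_ranked(8:1)
  es8 <- enrichment_score(rl8, c("g02", "g01", "g03"), 1)
  expect_identical(
    extract_leading_edge(rl8, c("g02", "g01", "g03"), es8$es,
                         es8$peak_rank),
    c("g01", "g02", "g03"))
  # negative peak at rank N-1 -> members at ranks N-1 and N only
  rl6 <- make_ranked(6:1)
  esn <- enrichment_score(rl6, c("g05", "g06"), 0)
  expect_lt(esn$es, 0)
  expect_identical(esn$peak_rank, 5L)
  expect_identical(
    extract_leading_edge(rl6, c("g05", "g06"), esn$es, esn$peak_rank),
    c("g05", "g06"))
  expect_warning(le0 <- extract_leading_edge(rl6, "g01", 0, 0), "empty")
  expect_length(le0, 0L)
})

test_that("leading edge re-scored alone peaks at the same rank", {
  set.seed(23)
  for (k in 1:10) {
    rl <- make_ranked(sort(rnorm(40), decreasing = TRUE))
    members <- sample(rl$gene_id, 6)
    es <- enrichment_score(rl, members, 0)
    if (es$es <= 0) next
    le <- extract_leading_edge(rl, members, es$es, es$peak_rank)
    es_le <- enrichment_score(rl, le, 0)
    expect_identical(es_le$peak_rank, es$peak_rank)
  }
})

test_that("class-label swap negates metrics and scores", {
  set.seed(31)
  cfg <- sim_config(n_genes = 400L, n_sets = 15L,
                    set_size_range = c(10L, 20L), seed = 41L)
  st <- sim_study(cfg)
  ph <- st$pheno_binary
  ph_swap <- phenotype(ph$values, class_names = rev(ph$class_names))
  par <- gsea_params(n_permutations = 200L, min_set_size = 5L, seed = 51L)
  r1 <- run_gsea(st$matrix, ph, st$collection, par)
  r2 <- run_gsea(st$matrix, ph_swap, st$collection, par)
  m1 <- setNames(r1$ranked$metric, r1$ranked$gene_id)
  m2 <- setNames(r2$ranked$metric, r2$ranked$gene_id)
  expect_equal(m2[names(m1)], -m1, tolerance = 1e-12)
  e1 <- setNames(r1$results$es, r1$results$set_name)
  e2 <- setNames(r2$results$es, r2$results$set_name)
  expect_equal(e2[names(e1)], -e1, tolerance = 1e-12)
  # nominal p is approximately invariant (same-sign null pool flips)
  p1 <- setNames(r1$results$p_nominal, r1$results$set_name)
  p2 <- setNames(r2$results$p_nominal, r2$results$set_name)
  expect_gt(cor(p1, p2[names(p1)]), 0.8)
})

test_that("run_gsea recovers planted sets with coherent statistics", {
  cfg <- sim_config(n_genes = 800L, n_sets = 30L,
                    set_size_range = c(15L, 40L), seed = 61L)
  st <- sim_study(cfg)
  par <- gsea_params(n_permutations = 500L, seed = 62L)
  run <- run_gsea(st$matrix, st$pheno_binary, st$collection, par)
  res <- run$results
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$p_nominal > 0 & res$p_nominal <= 1))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1, na.rm = TRUE))
  # planted sets called significant under the p<0.05 / FDR<0.25 regime
  planted <- st$truth$planted_expression_sets
  expect_true(all(res$significant[match(planted, res$set_name)]))
  expect_true(all(res$highly_significant ==
                    (res$p_nominal < 0.01 & res$fdr_q < 0.25)))
  # leading edges are subsets of the set membership present in the matrix
  for (j in seq_len(nrow(res))) {
    expect_true(all(res$leading_edge[[j]] %in%
                      st$collection$sets[[res$set_name[j]]]))
  }
  expect_error(run_gsea(st$matrix, st$pheno_binary, st$collection,
                        gsea_params(min_set_size = 500L)),
               "size filter")
})

test_that("gene-set permutation mode drives the continuous-phenotype path", {
  cfg <- sim_config(n_genes = 500L, n_sets = 20L,
                    set_size_range = c(10L, 25L),
                    continuous_covariate_coupling = 0.9, seed = 71L)
  st <- sim_study(cfg)
  par <- gsea_params(n_permutations = 300L, min_set_size = 5L, seed = 72L)
  run <- run_gsea(st$matrix, st$pheno_continuous, st$collection, par)
  expect_identical(run$permutation_mode, "gene_set")
  # the covariate-coupled module is the top enriched set
  expect_identical(run$results$set_name[1], st$truth$covariate_module)
  expect_true(run$results$significant[1])
})

test_that("leading-edge matrix clusters genes and pathways", {
  res <- data.frame(set_name = c("P1", "P2", "P3", "P4"),
                    size = 3L, es = 0.8, nes = 2, p_nominal = 0.001,
                    fdr_q = 0.01, peak_rank = 5L, direction = "pos",
                    significant = c(TRUE, TRUE, TRUE, FALSE),
                    highly_significant = FALSE,
                    stringsAsFactors = FALSE)
  res$leading_edge <- I(list(c("A", "B"), c("B", "C"), c("X", "Y"),
                             c("Z")))
  lem <- leading_edge_matrix(res)
  expect_identical(dim(lem$matrix), c(5L, 3L))     # P4 not significant
  expect_equal(unname(lem$matrix["B", c("P1", "P2")]), c(1L, 1L))
  expect_false("Z" %in% rownames(lem$matrix))
  # disjoint leading edges come out block-diagonal: P3's genes contiguous
  xy <- match(c("X", "Y"), lem$row_order)
  expect_equal(abs(diff(xy)), 1L)
  res$significant <- FALSE
  expect_warning(empty <- leading_edge_matrix(res), "no significantly")
  expect_identical(dim(empty$matrix), c(0L, 0L))
})
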