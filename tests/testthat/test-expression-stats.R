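fpkm_mat <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  expression_matrix(m, "FPKM")
}

test_that("expressed-gene counting uses an inclusive threshold", {
  m <- fpkm_mat(matrix(c(0.1, 0.05), ncol = 1L))
  expect_equal(unname(count_expressed_genes(m, 0.1)), 1L)
  z <- fpkm_mat(matrix(0, nrow = 4L, ncol = 3L))
  expect_equal(unname(count_expressed_genes(z, 0.1)), c(0L, 0L, 0L))
  set.seed(5)
  r <- matrix(stats::rexp(200, 5), nrow = 20L)
  rm <- fpkm_mat(r)
  brute <- vapply(seq_len(ncol(r)), function(j) sum(r[, j] >= 0.1),
                  integer(1))
  expect_equal(unname(count_expressed_genes(rm, 0.1)), brute)
})

test_that("the exact binomial DE test matches its closed form and symmetries", {
  r <- de_test(10L, 10L, 1e6, 1e6)
  expect_equal(r$log2_fold_change, 0)
  expect_equal(r$p_value, 1.0)
  # kA=10, kB=0, equal libraries: 2 * P(X >= 10 | n=10, p=0.5) = 2/1024
  r <- de_test(10L, 0L, 1e6, 1e6)
  expect_equal(r$p_value, 2 / 1024, tolerance = 1e-12)
  # symmetry of p, antisymmetry of log2FC
  a <- de_test(30L, 12L, 2e6, 1e6)
  b <- de_test(12L, 30L, 1e6, 2e6)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$log2_fold_change, -b$log2_fold_change)
  # all-zero gene
  z <- de_test(0L, 0L, 1e6, 1e6)
  expect_equal(z$p_value, 1)
  expect_equal(z$log2_fold_change, 0)
  # replicate path: Welch t on log2 normalized counts
  w <- de_test(c(100L, 120L), c(10L, 12L), c(1e6, 1e6), c(1e6, 1e6))
  expect_identical(w$method, "welch_t")
  expect_gt(w$log2_fold_change, 3)
})

test_that("BH adjustment equals the closed form and the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:20) {
    p <- stats::runif(sample(1:400, 1L))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
    expect_true(all(adj >= 0 & adj <= 1))
    # monotone: preserves the ordering of p-values
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("tissue-specific selection applies the >2-fold, FDR and >=9-tissue rules", {
  mk <- function(lfc, fdr) data.frame(gene_id = c("gUp", "gEdge"),
                                      log2_fold_change = lfc, fdr = fdr,
                                      stringsAsFactors = FALSE)
  # gUp significant in 9 of 12 comparisons; gEdge at exactly FC=2 everywhere
  tabs <- lapply(1:12, function(i)
    mk(c(if (i <= 9) log2(3) else 0, 1.0), c(0.01, 0.01)))
  sel <- tissue_specific_genes(tabs)
  expect_identical(sel, "gUp")
  # 8 of 12 is not enough
  tabs8 <- lapply(1:12, function(i)
    mk(c(if (i <= 8) log2(3) else 0, 1.0), c(0.01, 0.01)))
  expect_length(tissue_specific_genes(tabs8), 0L)
  # strict fold change: log2FC == 1 (FC exactly 2) never selects
  expect_false("gEdge" %in% sel)
  # monotone in the tissue threshold
  s9 <- tissue_specific_genes(tabs, specificity_call_config(min_other_tissues = 9))
  s10 <- tissue_specific_genes(tabs, specificity_call_config(min_other_tissues = 10))
  expect_true(all(s10 %in% s9))
  expect_error(tissue_specific_genes(tabs[1:5]), "fewer comparison tables")
})

test_that("planted skin-specific genes are recovered under the no-replicate design", {
  cfg <- simulation_config(n_ref_genes = 600L, n_specific = 40L,
                           specific_fc = 8)
  ann <- simulate_reference(cfg, seed = 61L)
  sim <- simulate_expression(ann, cfg, seed = 61L, design = "tissues")
  focal <- sim$groups[["skin"]]
  others <- setdiff(names(sim$groups), "skin")
  tabs <- stats::setNames(lapply(others, function(o)
    de_table(sim$counts, focal, sim$groups[[o]])), others)
  sel <- tissue_specific_genes(tabs)
  planted <- sim$truth$gene_id[sim$truth$status == "DE"]
  expect_gte(mean(planted %in% sel), 0.95)
  expect_lte(length(setdiff(sel, planted)), 5L)
})

test_that("pairwise DEG union runs all pairs and recovers planted effects", {
  # recall property at a powered design: 6 replicates per color group
  # (the 2-replicate study default leaves a 2-df Welch test no room below
  # a BH-adjusted 0.05; see the methods vignette)
  cfg <- simulation_config(n_ref_genes = 400L, n_color_degs = 25L,
                           color_log2fc = 2, color_replicates = 6L)
  ann <- simulate_reference(cfg, seed = 71L)
  sim <- simulate_expression(ann, cfg, seed = 71L, design = "colors")
  res <- pairwise_deg_union(sim$counts, sim$groups)
  expect_length(res$tables, choose(4, 2))
  planted <- sim$truth$gene_id[sim$truth$status == "DE"]
  expect_gte(mean(planted %in% res$degs), 0.9)
  fdp <- length(setdiff(res$degs, planted)) / max(1L, length(res$degs))
  expect_lte(fdp, 0.15)
  # identical groups: union stays near the FDR null expectation
  cfg0 <- simulation_config(n_ref_genes = 400L, n_color_degs = 0L,
                            color_replicates = 6L)
  sim0 <- simulate_expression(ann, cfg0, seed = 72L, design = "colors")
  res0 <- pairwise_deg_union(sim0$counts, sim0$groups)
  expect_lte(length(res0$degs), 3 * 0.05 * 400)
  # the study design itself (2 replicates) still yields all 6 pair tables
  cfg2 <- simulation_config(n_ref_genes = 50L, n_color_degs = 5L)
  sim2 <- simulate_expression(ann, cfg2, seed = 73L, design = "colors")
  res2 <- pairwise_deg_union(sim2$counts, sim2$groups)
  expect_length(res2$tables, 6L)
  expect_true(all(vapply(res2$tables, nrow, integer(1)) ==
                    nrow(sim2$counts$values)))
})
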