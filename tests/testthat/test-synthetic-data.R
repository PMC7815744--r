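test_that("reference simulation is deterministic and produces disjoint single-isoform loci", {
  cfg <- simulation_config(n_ref_genes = 35L)
  a1 <- simulate_reference(cfg, seed = 1L)
  a2 <- simulate_reference(cfg, seed = 1L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotation(a1, f1, "gff3"); write_annotation(a2, f2, "gff3")
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(a1$index, simulate_reference(cfg, seed = 2L)$index))
  # one isoform per locus; no overlapping locus pairs at all
  expect_true(all(vapply(a1$loci, function(l) length(l$transcripts),
                         integer(1)) == 1L))
  spans <- t(vapply(a1$loci, locus_span, integer(2)))
  chroms <- vapply(a1$loci, `[[`, character(1), "chrom")
  for (ch in unique(chroms)) {
    s <- spans[chroms == ch, , drop = FALSE]
    s <- s[order(s[, 1L]), , drop = FALSE]
    if (nrow(s) > 1L) expect_true(all(s[-1L, 1L] > s[-nrow(s), 2L]))
  }
  mono <- simulate_reference(simulation_config(exons_per_gene = c(1L, 1L),
                                               n_ref_genes = 10L), seed = 3L)
  expect_true(all(vapply(mono$loci, function(l)
    nrow(l$transcripts[[1L]]$exons), integer(1)) == 1L))
})

test_that("packing more genes than the chromosome holds is an error", {
  cfg <- simulation_config(n_ref_genes = 50L, n_chromosomes = 1L,
                           chromosome_length = 10000L)
  expect_error(simulate_reference(cfg, seed = 1L), "infeasible packing")
})

test_that("query truth tables cover every query exactly once and replay deterministically", {
  cfg <- simulation_config(n_ref_genes = 30L)
  ann <- simulate_reference(cfg, seed = 7L)
  s1 <- simulate_queries(ann, cfg, seed = 7L)
  s2 <- simulate_queries(ann, cfg, seed = 7L)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$queries, `[[`, "exons"),
                   lapply(s2$queries, `[[`, "exons"))
  ids <- vapply(s1$queries, `[[`, character(1), "transcript_id")
  expect_identical(sort(ids), sort(s1$truth$transcript_id))
  expect_false(anyDuplicated(s1$truth$transcript_id) > 0L)
  expect_equal(nrow(s1$truth),
               cfg$n_known + cfg$n_novel_shift + cfg$n_novel_exoncount +
                 cfg$n_new_intergenic + cfg$n_new_antisense)
  # zero planted novelty -> everything classifies known
  cfg0 <- simulation_config(n_ref_genes = 15L, n_known = 8L,
                            n_novel_shift = 0L, n_novel_exoncount = 0L,
                            n_new_intergenic = 0L, n_new_antisense = 0L)
  s0 <- simulate_queries(ann, cfg0, seed = 8L)
  r0 <- classify_all(s0$queries, ann)
  expect_true(all(r0$records$category == "known_isoform"))
})

test_that("boundary-test mode plants shifts of exactly tolerance-1 and tolerance", {
  cfg <- simulation_config(n_ref_genes = 40L, n_known = 15L,
                           n_novel_shift = 15L, n_novel_exoncount = 0L,
                           n_new_intergenic = 0L, n_new_antisense = 0L,
                           boundary_test_mode = TRUE)
  ann <- simulate_reference(cfg, seed = 17L)
  sim <- simulate_queries(ann, cfg, seed = 17L)
  res <- classify_all(sim$queries, ann)
  truth <- sim$truth$planted_class[match(res$records$transcript_id,
                                         sim$truth$transcript_id)]
  # 5-nt shifts stay known, 6-nt shifts flip to novel
  expect_true(all(res$records$category[truth == "known"] == "known_isoform"))
  expect_true(all(res$records$max_deviation_nt[truth == "known"] == 5L))
  expect_true(all(res$records$category[truth == "novel_shift"] ==
                    "novel_isoform"))
})

test_that("antisense new genes stay out of the lincRNA class downstream", {
  cfg <- simulation_config(n_ref_genes = 20L, n_known = 0L,
                           n_novel_shift = 0L, n_novel_exoncount = 0L,
                           n_new_intergenic = 0L, n_new_antisense = 6L)
  ann <- simulate_reference(cfg, seed = 19L)
  sim <- simulate_queries(ann, cfg, seed = 19L)
  res <- classify_all(sim$queries, ann)
  expect_true(all(res$records$category == "novel_gene"))
  pos <- classify_lncrna_all(sim$queries, ann)
  expect_true(all(pos$positional_class == "antisense"))
})

test_that("expression simulation derives FPKM consistently and records truth", {
  cfg <- simulation_config(n_ref_genes = 50L, n_specific = 10L)
  ann <- simulate_reference(cfg, seed = 23L)
  sim <- simulate_expression(ann, cfg, seed = 23L)
  expect_equal(sort(unique(sim$truth$status)), c("DE", "null"))
  expect_equal(sum(sim$truth$status == "DE"), 10L)
  expect_equal(dim(sim$counts$values), dim(sim$fpkm$values))
  expect_equal(unname(sim$counts$library_sizes),
               unname(colSums(sim$counts$values)))
  # FPKM formula: count * 1e9 / (length * library size)
  lens <- vapply(ann$loci, function(l)
    transcript_exonic_length(l$transcripts[[1L]]), integer(1))
  g <- rownames(sim$counts$values)[5L]; s <- colnames(sim$counts$values)[3L]
  expect_equal(sim$fpkm$values[g, s],
               sim$counts$values[g, s] * 1e9 /
                 (lens[[g]] * sim$counts$library_sizes[[s]]))
  # equal counts and equal libraries give equal FPKM across samples
  cm <- matrix(5L, nrow = 2L, ncol = 3L,
               dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  fp <- sweep(cm * 1e9 / c(1000L, 2000L), 2L, rep(1e6, 3L), "/")
  expect_true(all(fp[, 1L] == fp[, 2L] & fp[, 2L] == fp[, 3L]))
})

test_that("ohnolog simulation plants the configured bias and validates n_pairs", {
  o <- simulate_ohnologs(simulation_config(n_ohnolog_pairs = 100L,
                                           ohnolog_bias = 2), seed = 29L)
  expect_equal(nrow(o$pairs), 100L)
  expect_equal(nrow(o$gene_matrix$values), 200L)
  expect_setequal(unique(o$isoform_map$gene_id),
                  c(o$pairs$l_gene, o$pairs$s_gene))
  # isoform FPKM sums back to the gene FPKM
  g <- o$pairs$l_gene[1L]
  iso <- o$isoform_map$isoform_id[o$isoform_map$gene_id == g]
  expect_equal(colSums(o$isoform_matrix$values[iso, , drop = FALSE]),
               o$gene_matrix$values[g, ])
  expect_error(simulate_ohnologs(simulation_config(n_ohnolog_pairs = 0L)),
               "n_ohnolog_pairs")
})
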