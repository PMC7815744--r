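ref_locus_2ex <- function(strand = "+") {
  gene_locus("gR", list(tx("gR.t1", c(1001, 1501), c(1200, 1800),
                           strand = strand)),
             biotype = "protein_coding")
}

test_that("exonic overlap fraction matches per-base intersection", {
  locus <- ref_locus_2ex()
  q_same <- tx("q", c(1001, 1501), c(1200, 1800))
  expect_equal(exonic_overlap_fraction(q_same, locus), 1.0)
  q_away <- tx("q", 5001, 5100)
  expect_equal(exonic_overlap_fraction(q_away, locus), 0.0)
  # 100 query bases, 30 inside the reference exons
  q_part <- tx("q", c(1171, 1301), c(1200, 1370))
  expect_equal(exonic_overlap_fraction(q_part, locus), 0.30)
  expect_equal(exonic_overlap_fraction(q_part, locus),
               oracle_overlap_fraction(q_part, locus))
  # random queries against the per-base oracle
  set.seed(7)
  for (i in 1:25) {
    s <- sample(900:1900, 1L); w <- sample(20:300, 1L)
    q <- tx("q", s, s + w)
    expect_equal(exonic_overlap_fraction(q, locus),
                 oracle_overlap_fraction(q, locus))
  }
  # different chromosome: 0 by contract
  expect_equal(exonic_overlap_fraction(tx("q", 1001, 1200, chrom = "chr9"),
                                       locus), 0)
})

test_that("reference-gene assignment applies the overlap and strand rules", {
  ann <- annotation(list(ref_locus_2ex()))
  cfg <- novelty_rule_config()
  # ~0.5 overlap, same strand -> assigned
  q <- tx("q", c(1101, 1301), c(1200, 1400))   # 100 of 200 bases in exons
  expect_identical(assign_reference_gene(q, ann, cfg), "gR")
  # same overlap, opposite strand -> new-gene candidate
  q_anti <- tx("q", c(1101, 1301), c(1200, 1400), strand = "-")
  expect_identical(assign_reference_gene(q_anti, ann, cfg), NA_character_)
  # below the 20% threshold -> none; at the threshold -> assigned
  q19 <- tx("q", c(1182, 1301), c(1200, 1381))  # 19 of 100 bases
  expect_identical(assign_reference_gene(q19, ann, cfg), NA_character_)
  q20 <- tx("q", c(1181, 1301), c(1200, 1380))  # 20 of 100 bases
  expect_identical(assign_reference_gene(q20, ann, cfg), "gR")
})

test_that("isoform classification obeys the boundary-tolerance rule at 5 vs 6 nt", {
  for (strand in c("+", "-")) {
    locus <- ref_locus_2ex(strand)
    ref <- locus$transcripts[[1L]]
    same <- tx("q", ref$exons$start, ref$exons$end, strand = strand)
    rec <- classify_isoform(same, locus)
    expect_identical(rec$category, "known_isoform")
    expect_identical(rec$matched_transcript, "gR.t1")
    expect_equal(rec$max_deviation_nt, 0L)
    # first-exon 3' end shifted by exactly 6 nt -> novel ("at least 6-nt")
    shifted6 <- if (strand == "+")
      tx("q", c(1001, 1501), c(1194, 1800), strand = strand)
    else tx("q", c(1001, 1507), c(1200, 1800), strand = strand)
    expect_identical(classify_isoform(shifted6, locus)$category,
                     "novel_isoform")
    expect_identical(oracle_classify(shifted6, locus), "novel_isoform")
    # 5 nt is within tolerance
    shifted5 <- if (strand == "+")
      tx("q", c(1001, 1501), c(1195, 1800), strand = strand)
    else tx("q", c(1001, 1506), c(1200, 1800), strand = strand)
    expect_identical(classify_isoform(shifted5, locus)$category,
                     "known_isoform")
    expect_identical(oracle_classify(shifted5, locus), "known_isoform")
    # different exon count -> novel regardless of coordinates
    extra <- tx("q", c(1001, 1501, 2001), c(1200, 1800, 2100),
                strand = strand)
    rec2 <- classify_isoform(extra, locus)
    expect_identical(rec2$category, "novel_isoform")
    expect_equal(rec2$exon_count_delta, 1L)
    # transcript termini are never tested: large 5' start shift stays known
    ends_shift <- if (strand == "+")
      tx("q", c(901, 1501), c(1200, 1900), strand = strand)
    else tx("q", c(901, 1501), c(1200, 1900), strand = strand)
    expect_identical(classify_isoform(ends_shift, locus)$category,
                     "known_isoform")
  }
})

test_that("classification agrees with the brute-force enumeration on random loci", {
  set.seed(101)
  n_checked <- 0L
  for (rep in 1:120) {
    locus <- random_locus("gR", n_tx = sample(1:5, 1L), max_exons = 6L)
    base <- locus$transcripts[[sample.int(length(locus$transcripts), 1L)]]
    ex <- shift_one_boundary(base$exons, sample(c(-1L, 1L), 1L) *
                               sample(1:12, 1L))
    if (is.null(ex)) next
    q <- transcript_model("q", base$chrom, base$strand, ex$start, ex$end)
    expect_identical(classify_isoform(q, locus)$category,
                     oracle_classify(q, locus))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 80L)
})

test_that("raising the tolerance never turns a known isoform novel", {
  set.seed(55)
  for (rep in 1:40) {
    locus <- random_locus("gR", n_tx = 2L, max_exons = 5L)
    base <- locus$transcripts[[1L]]
    ex <- shift_one_boundary(base$exons, sample(c(-1L, 1L), 1L) *
                               sample(1:10, 1L))
    if (is.null(ex)) next
    q <- transcript_model("q", base$chrom, base$strand, ex$start, ex$end)
    cats <- vapply(c(2L, 6L, 12L, 30L), function(tol)
      classify_isoform(q, locus,
                       novelty_rule_config(boundary_tolerance_nt = tol))$category,
      character(1))
    known_at <- cats == "known_isoform"
    # once known at some tolerance, known at every larger tolerance
    expect_true(all(known_at == cummax(known_at)))
  }
})

test_that("new-locus clustering is single-linkage over same-strand exonic overlap", {
  a <- tx("a", c(100, 300), c(200, 400))
  b <- tx("b", 350, 600)               # overlaps a's second exon
  c_ <- tx("c", 550, 700)              # overlaps b, not a
  d <- tx("d", 100, 400, strand = "-") # same interval, opposite strand
  loci <- cluster_new_loci(list(a, b, c_, d))
  expect_length(loci, 2L)
  sizes <- sort(vapply(loci, function(l) length(l$transcripts), integer(1)))
  expect_equal(sizes, c(1L, 3L))
  # order independence of ids and membership
  loci2 <- cluster_new_loci(list(d, c_, b, a))
  expect_identical(lapply(loci, function(l) sort(names(l$transcripts))),
                   lapply(loci2, function(l) sort(names(l$transcripts))))
  expect_identical(vapply(loci, `[[`, character(1), "gene_id"),
                   vapply(loci2, `[[`, character(1), "gene_id"))
  # intron-only overlap does not link
  e <- tx("e", c(100, 500), c(150, 550))
  f <- tx("f", 200, 300)  # inside e's intron
  expect_length(cluster_new_loci(list(e, f)), 2L)
})

test_that("redundancy collapse keeps the longest of each within-tolerance group", {
  a <- tx("a", c(100, 300), c(200, 400))
  a2 <- tx("a2", c(100, 297), c(200, 400))  # 3-nt internal shift: redundant
  b <- tx("b", 100, 400)                    # different exon count
  out <- collapse_redundant(list(a, a2, b))
  expect_setequal(vapply(out, `[[`, character(1), "transcript_id"),
                  c("a2", "b"))  # a2 has the longer exonic length
  out2 <- collapse_redundant(list(a, tx("acopy", c(100, 300), c(200, 400))))
  expect_length(out2, 1L)
  expect_identical(out2[[1L]]$transcript_id, "a")  # tie broken by id
  # symmetry of the relation on random pairs
  set.seed(77)
  for (i in 1:30) {
    locus <- random_locus("g", n_tx = 2L)
    t1 <- locus$transcripts[[1L]]; t2 <- locus$transcripts[[2L]]
    r12 <- length(collapse_redundant(list(t1, t2))) == 1L
    r21 <- length(collapse_redundant(list(t2, t1))) == 1L
    expect_identical(r12, r21)
  }
})

test_that("classify_all partitions queries and recovers planted labels", {
  cfg <- simulation_config(n_ref_genes = 40L, n_known = 10L,
                           n_novel_shift = 20L, n_novel_exoncount = 0L,
                           n_new_intergenic = 3L, n_new_antisense = 2L)
  ann <- simulate_reference(cfg, seed = 21L)
  sim <- simulate_queries(ann, cfg, seed = 21L)
  res <- classify_all(sim$queries, ann)
  expect_equal(nrow(res$records), length(sim$queries))
  expect_true(all(res$records$category %in%
                    c("known_isoform", "novel_isoform", "novel_gene")))
  truth <- sim$truth$planted_class[match(res$records$transcript_id,
                                         sim$truth$transcript_id)]
  expected <- c(known = "known_isoform", novel_shift = "novel_isoform",
                novel_exoncount = "novel_isoform",
                new_intergenic = "novel_gene", new_antisense = "novel_gene")
  expect_identical(res$records$category, unname(expected[truth]))
  # updated annotation: reference loci + new loci; novel isoforms attached
  expect_true(all(names(ann$loci) %in% names(res$annotation$loci)))
  n_new <- sum(!names(res$annotation$loci) %in% names(ann$loci))
  new_ids <- res$records$new_locus[res$records$category == "novel_gene"]
  expect_true(all(!is.na(new_ids)))
  expect_equal(n_new, length(unique(new_ids)))
  # queries that copy the reference are all known
  copies <- lapply(names(ann$loci)[1:5], function(g) {
    r <- ann$loci[[g]]$transcripts[[1L]]
    transcript_model(paste0("c_", g), r$chrom, r$strand,
                     r$exons$start, r$exons$end)
  })
  expect_true(all(classify_all(copies, ann)$records$category ==
                    "known_isoform"))
  # empty query list
  empty <- classify_all(list(), ann)
  expect_equal(nrow(empty$records), 0L)
  expect_identical(names(empty$annotation$loci), names(ann$loci))
})
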