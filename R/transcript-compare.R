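#' Novelty rule configuration
#'
#' Thresholds for the reference-guided classification rules: a query is a
#' novel isoform when any tested exon boundary deviates by at least
#' `boundary_tolerance_nt` from every same-exon-count reference isoform of
#' its gene, and a query belongs to a reference gene only when at least
#' `overlap_threshold` of its exonic bases overlap that gene's exons on the
#' same strand.
#'
#' @param boundary_tolerance_nt Minimum boundary difference (nt) that makes
#'   an isoform novel; deviations strictly below are tolerated. Default 6,
#'   i.e. shifts of up to 5 nt are treated as the same isoform.
#' @param overlap_threshold Minimum exonic-overlap fraction for assignment
#'   to a reference gene; queries below it (or overlapping only on the
#'   opposite strand) become new-gene candidates. Default 0.20.
#' @param overlap_denominator Whether the overlap fraction is relative to
#'   the query's exonic length (default) or the reference gene's.
#' @return A list of class `novelty_rule_config`.
#' @export
novelty_rule_config <- function(boundary_tolerance_nt = 6L,
                                overlap_threshold = 0.20,
                                overlap_denominator = c("query", "reference")) {
  boundary_tolerance_nt <- as.integer(boundary_tolerance_nt)
  stopifnot(boundary_tolerance_nt >= 1L,
            overlap_threshold > 0, overlap_threshold < 1)
  structure(list(boundary_tolerance_nt = boundary_tolerance_nt,
                 overlap_threshold = overlap_threshold,
                 overlap_denominator = match.arg(overlap_denominator)),
            class = "novelty_rule_config")
}

#' Fraction of a query's exonic bases overlapping a reference locus
#'
#' Strand is ignored here; strand agreement is tested separately by
#' [assign_reference_gene()]. Queries on a different chromosome return 0.
#'
#' @param query A [transcript_model()].
#' @param ref_locus A [gene_locus()].
#' @param denominator `"query"` (fraction of the query's exonic bases,
#'   default) or `"reference"` (fraction of the locus exon union).
#' @return Numeric in `[0, 1]`.
#' @export
exonic_overlap_fraction <- function(query, ref_locus,
                                    denominator = c("query", "reference")) {
  denominator <- match.arg(denominator)
  if (query$chrom != ref_locus$chrom) return(0)
  q <- IRanges::IRanges(query$exons$start, query$exons$end)
  r <- locus_exon_union(ref_locus)
  ov <- sum(IRanges::width(IRanges::intersect(q, r)))
  den <- if (denominator == "query") sum(IRanges::width(q))
         else sum(IRanges::width(r))
  ov / den
}

# overlapped exonic bases (numerator of the fraction), for tie-breaking
.exonic_overlap_bases <- function(query, ref_locus) {
  if (query$chrom != ref_locus$chrom) return(0L)
  q <- IRanges::IRanges(query$exons$start, query$exons$end)
  sum(IRanges::width(IRanges::intersect(q, locus_exon_union(ref_locus))))
}

#' Assign a query transcript to a reference gene
#'
#' Implements the new-gene side of the classification rules: a query with
#' no exonic overlap, with overlap below the threshold, or whose
#' above-threshold overlaps all lie on the opposite strand, is assigned to
#' no gene and becomes a new-gene candidate. Otherwise the same-strand gene
#' with the largest overlap fraction is returned (ties: larger overlapped
#' base count, then lexicographically smaller gene id).
#'
#' @param query A [transcript_model()].
#' @param ann An [annotation()] of reference loci.
#' @param config A [novelty_rule_config()].
#' @return A gene id, or `NA_character_` when the query is a new-gene
#'   candidate.
#' @export
assign_reference_gene <- function(query, ann, config = novelty_rule_config()) {
  sp <- transcript_span(query)
  cand <- overlapping_loci(ann, query$chrom, sp[1L], sp[2L])
  if (!length(cand)) return(NA_character_)
  keep <- character(0); frac <- numeric(0); bases <- integer(0)
  for (g in cand) {
    locus <- ann$loci[[g]]
    if (!same_strand(query$strand, locus$strand)) next
    f <- exonic_overlap_fraction(query, locus,
                                 denominator = config$overlap_denominator)
    if (f >= config$overlap_threshold) {
      keep <- c(keep, g)
      frac <- c(frac, f)
      bases <- c(bases, .exonic_overlap_bases(query, locus))
    }
  }
  if (!length(keep)) return(NA_character_)
  keep[order(-frac, -bases, keep)][1L]
}

# Boundary deviations between two same-exon-count chains, excluding the
# transcript termini. Exons are genomically sorted; the tested boundaries
# (all exon starts except the leftmost exon's, all exon ends except the
# rightmost exon's) are the same set on either strand, so the tolerance
# test is orientation-independent. Monoexonic chains degenerate to testing
# both termini.
.boundary_deviations <- function(q_exons, r_exons) {
  n <- nrow(q_exons)
  stopifnot(n == nrow(r_exons))
  if (n == 1L)
    return(abs(c(q_exons$start - r_exons$start, q_exons$end - r_exons$end)))
  abs(c(q_exons$start[-1L] - r_exons$start[-1L],
        q_exons$end[-n] - r_exons$end[-n]))
}

#' Classify a query against the isoforms of its assigned reference gene
#'
#' A query is a known isoform when some reference transcript of the gene
#' has the same exon count and every tested boundary (first-exon 3' end,
#' last-exon 5' start, both boundaries of middle exons; transcript termini
#' excluded) deviates by less than the boundary tolerance. Otherwise it is
#' a novel isoform: either the exon count differs from every reference
#' transcript, or some tested boundary is shifted by at least the
#' tolerance.
#'
#' @param query A [transcript_model()].
#' @param ref_gene The assigned [gene_locus()].
#' @param config A [novelty_rule_config()].
#' @return A one-row data.frame (a classification record) with columns
#'   `transcript_id`, `category`, `matched_gene`, `matched_transcript`,
#'   `exon_count_delta`, `max_deviation_nt`, `overlap_fraction`,
#'   `strand_relation`.
#' @export
classify_isoform <- function(query, ref_gene, config = novelty_rule_config()) {
  if (!length(ref_gene$transcripts))
    stop("reference gene has no transcripts")
  tol <- config$boundary_tolerance_nt
  nq <- nrow(query$exons)
  ref_n <- vapply(ref_gene$transcripts, function(t) nrow(t$exons), integer(1))
  same_n <- ref_gene$transcripts[ref_n == nq]

  best_tx <- NA_character_; best_sum <- Inf; best_max <- NA_integer_
  known <- FALSE
  if (length(same_n)) {
    devs <- lapply(same_n, function(r) .boundary_deviations(query$exons, r$exons))
    maxd <- vapply(devs, function(d) if (length(d)) max(d) else 0L, numeric(1))
    sumd <- vapply(devs, function(d) sum(d), numeric(1))
    ok <- maxd < tol
    if (any(ok)) {
      known <- TRUE
      ids <- names(same_n)[ok]
      o <- order(sumd[ok], ids)
      best_tx <- ids[o][1L]
      best_max <- as.integer(maxd[ok][o][1L])
    } else {
      # closest same-count reference, for evidence only
      o <- order(sumd, names(same_n))
      best_max <- as.integer(maxd[o][1L])
    }
  }
  delta <- if (length(ref_n)) nq - ref_n[which.min(abs(ref_n - nq))][[1L]] else NA_integer_
  classification_record(
    transcript_id = query$transcript_id,
    category = if (known) "known_isoform" else "novel_isoform",
    matched_gene = ref_gene$gene_id,
    matched_transcript = if (known) best_tx else NA_character_,
    exon_count_delta = as.integer(delta),
    max_deviation_nt = best_max,
    overlap_fraction = exonic_overlap_fraction(
      query, ref_gene, denominator = config$overlap_denominator),
    strand_relation = if (same_strand(query$strand, ref_gene$strand))
      "same" else "different")
}

classification_record <- function(transcript_id, category,
                                  matched_gene = NA_character_,
                                  matched_transcript = NA_character_,
                                  exon_count_delta = NA_integer_,
                                  max_deviation_nt = NA_integer_,
                                  overlap_fraction = NA_real_,
                                  strand_relation = NA_character_) {
  data.frame(transcript_id = transcript_id, category = category,
             matched_gene = matched_gene,
             matched_transcript = matched_transcript,
             exon_count_delta = exon_count_delta,
             max_deviation_nt = max_deviation_nt,
             overlap_fraction = overlap_fraction,
             strand_relation = strand_relation,
             stringsAsFactors = FALSE)
}

#' Group new-gene candidate transcripts into new loci
#'
#' Single-linkage clustering: two candidates share a locus when they are on
#' the same chromosome and strand and their exons overlap by at least one
#' base. Locus ids are assigned deterministically by chromosome, leftmost
#' coordinate and strand, so the result does not depend on input order.
#'
#' @param candidates List of [transcript_model()]s that
#'   [assign_reference_gene()] left unassigned.
#' @param prefix Prefix for generated gene ids.
#' @return List of [gene_locus()] objects.
#' @export
cluster_new_loci <- function(candidates, prefix = "NOVG") {
  if (!length(candidates)) return(list())
  key <- paste(vapply(candidates, `[[`, character(1), "chrom"),
               vapply(candidates, `[[`, character(1), "strand"), sep = "\r")
  clusters <- list()
  for (grp in split(seq_along(candidates), key)) {
    txs <- candidates[grp]
    ex_tx <- rep(seq_along(txs),
                 vapply(txs, function(t) nrow(t$exons), integer(1)))
    ir <- IRanges::IRanges(
      unlist(lapply(txs, function(t) t$exons$start)),
      unlist(lapply(txs, function(t) t$exons$end)))
    hits <- IRanges::findOverlaps(ir, ir)
    parent <- seq_along(txs)
    findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (h in seq_along(qh)) {
      a <- findr(ex_tx[qh[h]]); b <- findr(ex_tx[sh[h]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_along(txs), findr, integer(1))
    for (r in unique(roots)) clusters[[length(clusters) + 1L]] <- txs[roots == r]
  }
  left <- vapply(clusters, function(txs)
    min(vapply(txs, function(t) min(t$exons$start), integer(1))), integer(1))
  chrom <- vapply(clusters, function(txs) txs[[1L]]$chrom, character(1))
  strand <- vapply(clusters, function(txs) txs[[1L]]$strand, character(1))
  ord <- order(chrom, left, strand)
  clusters <- clusters[ord]
  lapply(seq_along(clusters), function(i)
    gene_locus(sprintf("%s%06d", prefix, i), clusters[[i]]))
}

# symmetric redundancy relation: same exon count and all tested boundary
# deviations strictly below the tolerance
.is_redundant_pair <- function(a, b, tol) {
  if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
  if (nrow(a$exons) != nrow(b$exons)) return(FALSE)
  d <- .boundary_deviations(a$exons, b$exons)
  !length(d) || max(d) < tol
}

#' Collapse redundant isoforms within one locus
#'
#' Two transcripts are redundant when they stand in the known-isoform
#' relation to each other (same exon count, all tested boundary deviations
#' below tolerance). The longest transcript by exonic length survives
#' (ties: lexicographically smaller id); the result contains no redundant
#' pair.
#'
#' @param transcripts List of [transcript_model()]s from one locus.
#' @param config A [novelty_rule_config()].
#' @return Filtered list of transcripts.
#' @export
collapse_redundant <- function(transcripts, config = novelty_rule_config()) {
  if (length(transcripts) <= 1L) return(transcripts)
  tol <- config$boundary_tolerance_nt
  len <- vapply(transcripts, transcript_exonic_length, integer(1))
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  ord <- order(-len, ids)
  kept <- list()
  for (i in ord) {
    t <- transcripts[[i]]
    red <- any(vapply(kept, function(k) .is_redundant_pair(t, k, tol),
                      logical(1)))
    if (!red) kept[[length(kept) + 1L]] <- t
  }
  # restore input order among survivors
  kept_ids <- vapply(kept, `[[`, character(1), "transcript_id")
  transcripts[ids %in% kept_ids]
}

#' Classify a set of query transcripts against a reference annotation
#'
#' Every query receives exactly one category: `known_isoform` (matches a
#' reference transcript within tolerance), `novel_isoform` (assigned to a
#' reference gene but structurally different) or `novel_gene` (unassigned;
#' grouped into new loci). The updated annotation contains the reference
#' loci augmented with the novel isoforms plus the new loci.
#'
#' @param queries List of [transcript_model()]s.
#' @param ann Reference [annotation()].
#' @param config A [novelty_rule_config()].
#' @param new_gene_prefix Prefix for new-gene ids.
#' @return List with `records` (data.frame of classification records, one
#'   row per query) and `annotation` (the updated [annotation()]).
#' @export
classify_all <- function(queries, ann, config = novelty_rule_config(),
                         new_gene_prefix = "NOVG") {
  records <- vector("list", length(queries))
  new_candidates <- list()
  loci <- ann$loci
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    g <- assign_reference_gene(q, ann, config)
    if (is.na(g)) {
      records[[i]] <- classification_record(
        transcript_id = q$transcript_id, category = "novel_gene",
        overlap_fraction = 0)
      new_candidates[[length(new_candidates) + 1L]] <- q
    } else {
      rec <- classify_isoform(q, ann$loci[[g]], config)
      records[[i]] <- rec
      if (rec$category == "novel_isoform") {
        q$gene_id <- g
        loci[[g]]$transcripts[[q$transcript_id]] <- q
      }
    }
  }
  new_loci <- cluster_new_loci(new_candidates, prefix = new_gene_prefix)
  records <- do.call(rbind, records)
  if (is.null(records)) records <- classification_record("", "")[0, ]
  # attach the new-gene locus id to each novel_gene record
  if (length(new_loci)) {
    tx2new <- unlist(lapply(new_loci, function(l)
      stats::setNames(rep(l$gene_id, length(l$transcripts)),
                      names(l$transcripts))))
    hit <- records$category == "novel_gene"
    records$matched_gene[hit] <- NA_character_
    records$new_locus <- rep(NA_character_, nrow(records))
    records$new_locus[hit] <- unname(tx2new[records$transcript_id[hit]])
  } else {
    records$new_locus <- rep(NA_character_, nrow(records))
  }
  list(records = records, annotation = annotation(c(loci, new_loci)))
}
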