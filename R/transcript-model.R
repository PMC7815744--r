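#' Construct a transcript model
#'
#' A transcript model is an ordered exon chain on one chromosome and strand.
#' Coordinates are 1-based inclusive throughout the package; an exon
#' `start..end` has length `end - start + 1`.
#'
#' @param transcript_id Transcript identifier (non-empty string).
#' @param chrom Chromosome identifier.
#' @param strand One of `"+"`, `"-"`, `"."`. `"."` is preserved but never
#'   matches `"+"` or `"-"` in strand-equality tests.
#' @param starts,ends Integer vectors of exon starts/ends (1-based, inclusive).
#'   Exons need not be pre-sorted; they are sorted by start. Overlapping or
#'   abutting exons (intron length < 1) are rejected.
#' @param gene_id Gene identifier; may be `""` before locus assignment.
#' @return An object of class `transcript_model`: a list with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand` and `exons`
#'   (a data.frame with columns `start`, `end`).
#' @export
#' @examples
#' t1 <- transcript_model("t1", "chr1", "+", c(1, 201), c(100, 300))
#' transcript_exonic_length(t1)  # 200
transcript_model <- function(transcript_id, chrom, strand, starts, ends,
                             gene_id = "") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id))
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) == 0L || length(starts) != length(ends))
    stop("transcript '", transcript_id, "': need >= 1 exon with matching starts/ends")
  if (any(is.na(starts)) || any(is.na(ends)))
    stop("transcript '", transcript_id, "': NA exon coordinate")
  if (any(ends < starts))
    stop("transcript '", transcript_id, "': exon end < start")
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1L) {
    gap <- starts[-1L] - ends[-length(ends)] - 1L
    if (any(gap < 1L))
      stop("transcript '", transcript_id,
           "': overlapping or abutting exons (intron length < 1)")
  }
  structure(list(transcript_id = transcript_id,
                 gene_id = gene_id,
                 chrom = as.character(chrom),
                 strand = strand,
                 exons = data.frame(start = starts, end = ends)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%d exon(s)] gene=%s\n",
              x$transcript_id, x$strand, x$chrom,
              min(x$exons$start), max(x$exons$end),
              nrow(x$exons),
              if (nzchar(x$gene_id)) x$gene_id else "<unassigned>"))
  invisible(x)
}

#' Total exonic length of a transcript (bp)
#' @param t A [transcript_model()].
#' @return Integer number of exonic bases.
#' @export
transcript_exonic_length <- function(t) {
  sum(t$exons$end - t$exons$start + 1L)
}

#' Genomic span of a transcript
#' @param t A [transcript_model()].
#' @return Integer vector `c(start, end)` of the transcript span.
#' @export
transcript_span <- function(t) {
  c(min(t$exons$start), max(t$exons$end))
}

#' Introns of a transcript
#'
#' Gaps between consecutive exons, in genomic order.
#' @param t A [transcript_model()].
#' @return data.frame with columns `start`, `end` (1-based inclusive intronic
#'   bases); zero rows for a monoexonic transcript.
#' @export
transcript_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = t$exons$end[-n] + 1L, end = t$exons$start[-1L] - 1L)
}

#' Construct a gene locus
#'
#' @param gene_id Gene identifier.
#' @param transcripts List of [transcript_model()]s, all on the same
#'   chromosome and strand. Their `gene_id` field is set to `gene_id`.
#' @param biotype One of `"protein_coding"`, `"lncRNA"`, `"mixed"`,
#'   `"unknown"`.
#' @return Object of class `gene_locus` with fields `gene_id`, `chrom`,
#'   `strand`, `transcripts` (named by transcript id), `biotype`.
#' @export
gene_locus <- function(gene_id, transcripts,
                       biotype = c("unknown", "protein_coding", "lncRNA", "mixed")) {
  biotype <- match.arg(biotype)
  stopifnot(length(transcripts) >= 1L)
  chroms <- vapply(transcripts, `[[`, character(1), "chrom")
  strands <- vapply(transcripts, `[[`, character(1), "strand")
  if (length(unique(chroms)) != 1L)
    stop("gene '", gene_id, "': transcripts span multiple chromosomes")
  if (length(unique(strands)) != 1L)
    stop("gene '", gene_id, "': transcripts on mixed strands")
  transcripts <- lapply(transcripts, function(t) { t$gene_id <- gene_id; t })
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "transcript_id")
  if (anyDuplicated(names(transcripts)))
    stop("gene '", gene_id, "': duplicated transcript ids")
  structure(list(gene_id = gene_id, chrom = chroms[[1L]],
                 strand = strands[[1L]], transcripts = transcripts,
                 biotype = biotype),
            class = "gene_locus")
}

#' Genomic span of a locus
#' @param locus A [gene_locus()].
#' @return Integer `c(start, end)` covering every exon of every transcript.
#' @export
locus_span <- function(locus) {
  s <- vapply(locus$transcripts, function(t) min(t$exons$start), integer(1))
  e <- vapply(locus$transcripts, function(t) max(t$exons$end), integer(1))
  c(min(s), max(e))
}

#' Union of exonic intervals of a locus
#' @param locus A [gene_locus()].
#' @return An [IRanges::IRanges] of the reduced (disjoint) exonic intervals.
#' @export
locus_exon_union <- function(locus) {
  st <- unlist(lapply(locus$transcripts, function(t) t$exons$start))
  en <- unlist(lapply(locus$transcripts, function(t) t$exons$end))
  IRanges::reduce(IRanges::IRanges(start = st, end = en))
}

#' Build an annotation from gene loci
#'
#' An annotation is a set of gene loci plus an interval index over the locus
#' spans used for overlap queries.
#'
#' @param loci List of [gene_locus()] objects; gene ids must be unique.
#' @return Object of class `annotation` with fields `loci` (named list) and
#'   `index` (a [GenomicRanges::GRanges] of locus spans, `gene_id` metadata).
#' @export
annotation <- function(loci = list()) {
  ids <- vapply(loci, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicated gene ids in annotation")
  names(loci) <- ids
  if (length(loci)) {
    spans <- t(vapply(loci, locus_span, integer(2)))
    idx <- GenomicRanges::GRanges(
      seqnames = vapply(loci, `[[`, character(1), "chrom"),
      ranges = IRanges::IRanges(start = spans[, 1L], end = spans[, 2L]),
      strand = sub("^\\.$", "*", vapply(loci, `[[`, character(1), "strand")))
    S4Vectors::mcols(idx)$gene_id <- ids
  } else {
    idx <- GenomicRanges::GRanges()
  }
  structure(list(loci = loci, index = idx), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  nt <- sum(vapply(x$loci, function(l) length(l$transcripts), integer(1)))
  cat(sprintf("<annotation> %d loci, %d transcripts on %d chromosome(s)\n",
              length(x$loci), nt,
              length(unique(vapply(x$loci, `[[`, character(1), "chrom")))))
  invisible(x)
}

#' Loci whose span overlaps a query interval
#'
#' @param ann An [annotation()].
#' @param chrom Chromosome.
#' @param start,end Query interval (1-based inclusive).
#' @return Character vector of gene ids whose locus span intersects the
#'   query, in annotation order. Strand is ignored here.
#' @export
overlapping_loci <- function(ann, chrom, start, end) {
  if (!length(ann$loci)) return(character(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, ann$index, ignore.strand = TRUE)
  S4Vectors::mcols(ann$index)$gene_id[S4Vectors::subjectHits(hits)]
}

#' All transcripts of an annotation as a flat list
#' @param ann An [annotation()].
#' @return Named list of [transcript_model()]s (names = transcript ids).
#' @export
annotation_transcripts <- function(ann) {
  out <- unlist(lapply(ann$loci, `[[`, "transcripts"), recursive = FALSE,
                use.names = FALSE)
  if (is.null(out)) out <- list()
  names(out) <- vapply(out, `[[`, character(1), "transcript_id")
  out
}

# strand equality under the package's convention: '.' never matches anything
same_strand <- function(a, b) {
  a %in% c("+", "-") && b %in% c("+", "-") && a == b
}

opposite_strand <- function(a, b) {
  a %in% c("+", "-") && b %in% c("+", "-") && a != b
}
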