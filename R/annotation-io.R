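#' Read a gene annotation from GFF3 or GTF
#'
#' Exon features are assembled into transcripts and grouped into gene loci.
#' In GTF, exons must carry `gene_id` and `transcript_id` attributes; in
#' GFF3, exons carry `Parent` pointing at a transcript-level feature whose
#' own `Parent` names the gene. On-disk coordinates (1-based inclusive) are
#' kept as-is: the package uses the same convention internally.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"gtf"`.
#' @return An [annotation()].
#' @export
read_annotation <- function(path, format = c("gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_annotation_lines(path)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "gtf")
  if (length(gr) == 0L) return(annotation(list()))
  mc <- S4Vectors::mcols(gr)
  is_exon <- !is.na(mc$type) & as.character(mc$type) == "exon"
  if (!any(is_exon)) return(annotation(list()))

  if (format == "gtf") {
    tx_id <- as.character(mc$transcript_id[is_exon])
    gene_of_tx <- tapply(as.character(mc$gene_id[is_exon]), tx_id,
                         function(g) unique(g)[1L])
    biotype_of_gene <- .attr_by_gene(mc, is_exon, "gene_biotype",
                                     as.character(mc$gene_id[is_exon]))
  } else {
    parent <- mc$Parent
    tx_id <- vapply(seq_along(gr)[is_exon], function(i) {
      p <- parent[[i]]
      if (length(p) == 0L) stop("GFF3 exon without Parent attribute")
      as.character(p[[1L]])
    }, character(1))
    # transcript-level features: ID present, referenced by an exon Parent
    has_id <- !is.na(mc$ID)
    feat_ids <- as.character(mc$ID)
    tx_rows <- which(has_id & feat_ids %in% unique(tx_id) & !is_exon)
    gene_of_tx <- vapply(tx_rows, function(i) {
      p <- parent[[i]]
      if (length(p) >= 1L) as.character(p[[1L]]) else feat_ids[i]
    }, character(1))
    names(gene_of_tx) <- feat_ids[tx_rows]
    missing_tx <- setdiff(unique(tx_id), names(gene_of_tx))
    if (length(missing_tx)) {
      # orphan exon parents: treat the parent as its own single-transcript gene
      gene_of_tx <- c(gene_of_tx, stats::setNames(missing_tx, missing_tx))
    }
    gene_rows <- which(has_id & as.character(mc$type) == "gene")
    biotype_of_gene <- NULL
    if (length(gene_rows) && "biotype" %in% colnames(mc)) {
      biotype_of_gene <- stats::setNames(as.character(mc$biotype[gene_rows]),
                                         feat_ids[gene_rows])
    }
  }

  ex <- gr[is_exon]
  exdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                     start = GenomicRanges::start(ex),
                     end = GenomicRanges::end(ex),
                     strand = sub("^\\*$", ".",
                                  as.character(GenomicRanges::strand(ex))),
                     tx = tx_id, stringsAsFactors = FALSE)
  transcripts <- lapply(split(exdf, exdf$tx), function(d) {
    if (length(unique(d$chrom)) != 1L)
      stop("transcript '", d$tx[1L], "' spans two chromosomes")
    if (length(unique(d$strand)) != 1L)
      stop("transcript '", d$tx[1L], "' has exons on mixed strands")
    transcript_model(d$tx[1L], d$chrom[1L], d$strand[1L], d$start, d$end,
                     gene_id = unname(gene_of_tx[[d$tx[1L]]]))
  })
  by_gene <- split(transcripts,
                   vapply(transcripts, `[[`, character(1), "gene_id"))
  loci <- lapply(names(by_gene), function(g) {
    bt <- "unknown"
    if (!is.null(biotype_of_gene) && g %in% names(biotype_of_gene)) {
      cand <- biotype_of_gene[[g]]
      if (!is.na(cand) &&
          cand %in% c("protein_coding", "lncRNA", "mixed", "unknown"))
        bt <- cand
    }
    gene_locus(g, by_gene[[g]], biotype = bt)
  })
  annotation(loci)
}

# field-count and coordinate sanity pass, reporting 1-based line numbers
.validate_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("parse error at line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop("parse error at line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("validation error at line ", i, ": feature end < start")
  }
  invisible(TRUE)
}

#' Write an annotation to GFF3 or GTF
#'
#' Output is deterministic: loci are ordered by chromosome, span start and
#' gene id; transcripts by id; exons by start. Reading the file back with
#' [read_annotation()] reproduces the loci, transcripts and exon
#' coordinates exactly.
#'
#' @param ann An [annotation()].
#' @param path Output path.
#' @param format `"gff3"` or `"gtf"`.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path, format = c("gff3", "gtf")) {
  format <- match.arg(format)
  loci <- ann$loci
  if (length(loci)) {
    spans <- t(vapply(loci, locus_span, integer(2)))
    ord <- order(vapply(loci, `[[`, character(1), "chrom"), spans[, 1L],
                 vapply(loci, `[[`, character(1), "gene_id"))
    loci <- loci[ord]
  }
  lines <- character(0)
  if (format == "gff3") lines <- "##gff-version 3"
  for (locus in loci) {
    sp <- locus_span(locus)
    txs <- locus$transcripts[order(names(locus$transcripts))]
    if (format == "gff3") {
      lines <- c(lines, sprintf(
        "%s\tisoforge\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
        locus$chrom, sp[1L], sp[2L], locus$strand, locus$gene_id,
        locus$biotype))
      for (t in txs) {
        tsp <- transcript_span(t)
        lines <- c(lines, sprintf(
          "%s\tisoforge\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
          t$chrom, tsp[1L], tsp[2L], t$strand, t$transcript_id, locus$gene_id))
        lines <- c(lines, sprintf(
          "%s\tisoforge\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          t$chrom, t$exons$start, t$exons$end, t$strand, t$transcript_id,
          seq_len(nrow(t$exons)), t$transcript_id))
      }
    } else {
      for (t in txs) {
        lines <- c(lines, sprintf(
          paste0("%s\tisoforge\texon\t%d\t%d\t.\t%s\t.\t",
                 "gene_id \"%s\"; transcript_id \"%s\"; gene_biotype \"%s\";"),
          t$chrom, t$exons$start, t$exons$end, t$strand,
          locus$gene_id, t$transcript_id, locus$biotype))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Construct an expression matrix
#'
#' @param values Numeric matrix, rows = genes or isoforms, columns = samples;
#'   all values must be non-negative, and integer when `unit = "count"`.
#' @param unit `"FPKM"` or `"count"`.
#' @param library_sizes Per-sample totals (required when `unit = "count"`);
#'   recycled names must match `colnames(values)` when named.
#' @return Object of class `expression_matrix`: list with `values`, `unit`,
#'   `library_sizes`.
#' @export
expression_matrix <- function(values, unit = c("FPKM", "count"),
                              library_sizes = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have row and column names")
  if (anyDuplicated(rownames(values))) stop("duplicate row id in matrix")
  if (any(is.na(values)) || any(values < 0))
    stop("expression values must be non-negative and non-missing")
  if (unit == "count") {
    if (any(values != round(values))) stop("counts must be integers")
    if (is.null(library_sizes))
      stop("library_sizes required for count matrices")
  }
  if (!is.null(library_sizes)) {
    if (!is.null(names(library_sizes))) {
      if (!all(colnames(values) %in% names(library_sizes)))
        stop("library_sizes names do not cover all samples")
      library_sizes <- library_sizes[colnames(values)]
    } else if (length(library_sizes) != ncol(values)) {
      stop("library_sizes length must equal number of samples")
    } else {
      names(library_sizes) <- colnames(values)
    }
    if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  }
  structure(list(values = values, unit = unit, library_sizes = library_sizes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d x %d [%s]%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (is.null(x$library_sizes)) "" else " +library sizes"))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The file must have a header row of sample names and row identifiers in
#' the first column.
#'
#' @param path Path to a TSV file.
#' @param unit `"FPKM"` or `"count"`.
#' @param library_sizes Optional per-sample totals: a numeric vector, or a
#'   path to a two-column TSV (`sample<TAB>total`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("FPKM", "count"),
                                   library_sizes = NULL) {
  unit <- match.arg(unit)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("matrix TSV needs a row-id column plus >= 1 sample")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row id in ", path)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (is.character(library_sizes) && length(library_sizes) == 1L) {
    ls <- utils::read.delim(library_sizes, header = FALSE,
                            stringsAsFactors = FALSE)
    library_sizes <- stats::setNames(as.numeric(ls[[2L]]), as.character(ls[[1L]]))
  }
  expression_matrix(m, unit = unit, library_sizes = library_sizes)
}

#' Read ohnolog gene pairs from a two-column TSV
#'
#' @param path Path to a headerless two-column TSV: L-subgenome gene id,
#'   S-subgenome gene id.
#' @param deduplicate Drop repeated pairs (a warning is emitted either way
#'   when duplicates are present).
#' @return data.frame with columns `l_gene`, `s_gene`, in file order.
#' @export
read_ohnolog_pairs <- function(path, deduplicate = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(l_gene = character(0), s_gene = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("parse error at line ", bad[1L], ": expected 2 fields, got ",
         length(parts[[bad[1L]]]))
  out <- data.frame(l_gene = vapply(parts, `[[`, character(1), 1L),
                    s_gene = vapply(parts, `[[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  dup <- duplicated(paste(out$l_gene, out$s_gene, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicated ohnolog pair(s) in ", path)
    if (deduplicate) out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.attr_by_gene <- function(mc, is_exon, attr, gene_ids) {
  if (!attr %in% colnames(mc)) return(NULL)
  v <- as.character(mc[[attr]][is_exon])
  tapply(v, gene_ids, function(x) unique(x[!is.na(x)])[1L])
}
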