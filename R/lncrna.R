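#' Combine coding-potential votes into lncRNA candidates
#'
#' Four predictors (CNCI, CPC, PLEK, Pfam) each call a transcript coding or
#' noncoding. Under the default `"all"` policy a transcript is a lncRNA
#' candidate only when every predictor calls it noncoding: a single coding
#' verdict filters it out. The `"majority"` policy (>= 3 noncoding of 4) is
#' provided as an alternative consensus.
#'
#' @param votes data.frame with column `transcript_id` plus one column per
#'   predictor (`cnci`, `cpc`, `plek`, `pfam`), values `"coding"` or
#'   `"noncoding"`.
#' @param policy `"all"` (intersection, default) or `"majority"`.
#' @param missing `"error"` (default): any missing/NA verdict is a
#'   validation error; `"coding"`: treat missing verdicts as coding
#'   (conservative).
#' @return Character vector of candidate transcript ids, in input order.
#' @export
combine_coding_votes <- function(votes, policy = c("all", "majority"),
                                 missing = c("error", "coding")) {
  policy <- match.arg(policy)
  missing <- match.arg(missing)
  predictors <- c("cnci", "cpc", "plek", "pfam")
  if (!nrow(votes)) return(character(0))
  cols <- tolower(colnames(votes))
  colnames(votes) <- cols
  if (!all(c("transcript_id", predictors) %in% cols))
    stop("vote table must have columns transcript_id, cnci, cpc, plek, pfam")
  if (anyDuplicated(votes$transcript_id))
    stop("duplicated transcript_id in vote table")
  v <- as.matrix(votes[, predictors])
  bad <- !(v %in% c("coding", "noncoding")) & !is.na(v)
  if (any(bad)) stop("verdicts must be 'coding' or 'noncoding'")
  if (any(is.na(v)) && missing == "error")
    stop("missing verdict for ",
         votes$transcript_id[which(rowSums(is.na(v)) > 0)[1L]])
  nc <- rowSums(v == "noncoding", na.rm = TRUE)
  keep <- if (policy == "all") nc == length(predictors) else nc >= 3L
  votes$transcript_id[keep]
}

#' Read a coding-potential vote table from TSV
#'
#' @param path TSV with header `transcript_id`, `cnci`, `cpc`, `plek`,
#'   `pfam`.
#' @return data.frame suitable for [combine_coding_votes()].
#' @export
read_coding_votes <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Classify a lncRNA candidate by position relative to coding genes
#'
#' Precedence-ordered decision against the protein-coding loci of the
#' annotation (span overlap, not exonic, defines "intergenic"):
#' 1. no span overlap with any coding locus: `lincRNA`;
#' 2. span overlap with a coding locus on the opposite strand:
#'    `antisense`;
#' 3. same strand, contained in one intron of a coding transcript with
#'    zero exonic overlap: `sense_intronic`;
#' 4. any other same-strand overlap: `sense_overlapping`.
#' The host gene is the class-determining coding gene with the most
#' overlapped bases.
#'
#' @param t A [transcript_model()] with strand `"+"` or `"-"`.
#' @param ann An [annotation()] whose protein-coding loci (biotype
#'   `"protein_coding"`) are the comparison set.
#' @return One-row data.frame: `transcript_id`, `positional_class`,
#'   `host_gene`, `exon_count`, `length_nt`.
#' @export
classify_lncrna_position <- function(t, ann) {
  if (!t$strand %in% c("+", "-"))
    stop("lncRNA candidate '", t$transcript_id, "' has undetermined strand")
  sp <- transcript_span(t)
  cand <- overlapping_loci(ann, t$chrom, sp[1L], sp[2L])
  coding <- Filter(function(g) ann$loci[[g]]$biotype == "protein_coding",
                   cand)
  record <- function(class, host) {
    data.frame(transcript_id = t$transcript_id, positional_class = class,
               host_gene = host, exon_count = nrow(t$exons),
               length_nt = transcript_exonic_length(t),
               stringsAsFactors = FALSE)
  }
  if (!length(coding)) return(record("lincRNA", NA_character_))

  span_overlap_bases <- function(g) {
    lsp <- locus_span(ann$loci[[g]])
    max(0L, min(sp[2L], lsp[2L]) - max(sp[1L], lsp[1L]) + 1L)
  }
  anti <- Filter(function(g) opposite_strand(t$strand, ann$loci[[g]]$strand),
                 coding)
  if (length(anti)) {
    ov <- vapply(anti, span_overlap_bases, integer(1))
    return(record("antisense", anti[order(-ov, anti)][1L]))
  }
  sense <- Filter(function(g) same_strand(t$strand, ann$loci[[g]]$strand),
                  coding)
  if (!length(sense))  # only '.'-strand coding loci overlap: treat as linc
    return(record("lincRNA", NA_character_))
  exonic_ov <- vapply(sense, function(g)
    .exonic_overlap_bases(t, ann$loci[[g]]), integer(1))
  in_one_intron <- vapply(sense, function(g) {
    any(vapply(ann$loci[[g]]$transcripts, function(rt) {
      intr <- transcript_introns(rt)
      any(intr$start <= sp[1L] & sp[2L] <= intr$end)
    }, logical(1)))
  }, logical(1))
  if (any(in_one_intron & exonic_ov == 0L)) {
    host <- sense[in_one_intron & exonic_ov == 0L]
    ov <- vapply(host, span_overlap_bases, integer(1))
    return(record("sense_intronic", host[order(-ov, host)][1L]))
  }
  ov <- vapply(sense, span_overlap_bases, integer(1))
  record("sense_overlapping", sense[order(-ov, sense)][1L])
}

#' Classify a set of lncRNA candidates
#'
#' @param candidates List of [transcript_model()]s.
#' @param ann An [annotation()] with protein-coding loci.
#' @return data.frame, one row per candidate (see
#'   [classify_lncrna_position()]).
#' @export
classify_lncrna_all <- function(candidates, ann) {
  if (!length(candidates))
    return(data.frame(transcript_id = character(0),
                      positional_class = character(0),
                      host_gene = character(0), exon_count = integer(0),
                      length_nt = integer(0)))
  do.call(rbind, lapply(candidates, classify_lncrna_position, ann = ann))
}

#' Summarize lncRNA records against an mRNA background
#'
#' @param lnc data.frame of lncRNA records from [classify_lncrna_all()].
#' @param mrna List of [transcript_model()]s (the mRNA comparison set).
#' @param decimals Decimal places for percentages (half-up rounding).
#' @return List with `class_table` (count and percentage per positional
#'   class), `n_lncrna`, `pct_monoexonic` (fraction of lncRNAs with one
#'   exon, as a percentage), `mean_mrna_exons`, `lengths` (mean/median
#'   exonic length for both sets) and `empty` flags.
#' @export
lncrna_summary <- function(lnc, mrna, decimals = 1L) {
  classes <- c("lincRNA", "antisense", "sense_intronic", "sense_overlapping")
  n <- nrow(lnc)
  counts <- stats::setNames(integer(length(classes)), classes)
  if (n) {
    tt <- table(factor(lnc$positional_class, levels = classes))
    counts[names(tt)] <- as.integer(tt)
  }
  class_table <- data.frame(
    class = classes, count = as.integer(counts),
    pct = if (n) vapply(counts, percentage, numeric(1), total = n,
                        decimals = decimals) else rep(0, length(classes)),
    stringsAsFactors = FALSE)
  mrna_exons <- vapply(mrna, function(t) nrow(t$exons), integer(1))
  mrna_len <- vapply(mrna, transcript_exonic_length, integer(1))
  list(
    class_table = class_table,
    n_lncrna = n,
    pct_monoexonic = if (n) percentage(sum(lnc$exon_count == 1L), n,
                                       decimals) else 0,
    mean_mrna_exons = if (length(mrna_exons)) round_half_up(mean(mrna_exons), 1L)
                      else 0,
    lengths = list(
      lncrna = c(mean = if (n) mean(lnc$length_nt) else 0,
                 median = if (n) stats::median(lnc$length_nt) else 0),
      mrna = c(mean = if (length(mrna_len)) mean(mrna_len) else 0,
               median = if (length(mrna_len)) stats::median(mrna_len) else 0)),
    empty = c(lncrna = n == 0L, mrna = length(mrna) == 0L))
}
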