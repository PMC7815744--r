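#' Half-up decimal rounding
#'
#' Rounds away from R's banker's rounding so printed values match the
#' conventional "round half up" (3.1151 -> 3.12 at 2 decimals).
#'
#' @param x Numeric vector.
#' @param decimals Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, decimals = 0L) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Mean and N50 of a set of lengths
#'
#' N50 is the largest length L such that elements of length >= L cover at
#' least half the summed length; computed by descending cumulative sum.
#' The mean is rounded half-up to the nearest integer, as conventionally
#' printed in sequencing summary tables.
#'
#' @param lengths Non-empty vector of positive integer lengths.
#' @return List with `mean` and `n50`.
#' @export
length_stats <- function(lengths) {
  if (!length(lengths)) stop("empty length vector")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  n50 <- s[which(cum >= sum(s) / 2)[1L]]
  list(mean = round_half_up(mean(lengths)), n50 = n50)
}

#' Percentage with half-up rounding
#'
#' @param count Non-negative count.
#' @param total Positive total.
#' @param decimals Decimal places (half-up).
#' @return `100 * count / total`, rounded.
#' @export
percentage <- function(count, total, decimals = 2L) {
  if (length(total) != 1L || total <= 0) stop("total must be positive")
  stopifnot(all(count >= 0))
  round_half_up(100 * count / total, decimals)
}

#' Summary report of a classification run
#'
#' @param records data.frame of classification records (from
#'   [classify_all()]).
#' @param ann The updated [annotation()] from the same run.
#' @param reference_gene_ids Character vector of the original reference
#'   gene ids, used to split loci into reference-overlapping vs new.
#' @param decimals Decimal places for percentages.
#' @return List with `category_table` (count + percentage per category),
#'   `n_isoforms`, `locus_counts` (reference-overlapping vs new loci among
#'   loci holding >= 1 classified isoform plus totals),
#'   `pct_multi_isoform` (share of loci with >= 2 isoforms) and
#'   `mean_isoforms_per_locus` (total isoforms / total loci, 2 decimals).
#' @export
classification_report <- function(records, ann, reference_gene_ids = NULL,
                                  decimals = 2L) {
  cats <- c("known_isoform", "novel_isoform", "novel_gene")
  counts <- stats::setNames(integer(length(cats)), cats)
  if (nrow(records)) {
    tt <- table(factor(records$category, levels = cats))
    counts[names(tt)] <- as.integer(tt)
  }
  total <- sum(counts)
  category_table <- data.frame(
    category = cats, count = as.integer(counts),
    pct = if (total) vapply(counts, percentage, numeric(1), total = total,
                            decimals = decimals) else rep(0, length(cats)),
    stringsAsFactors = FALSE)
  n_tx <- vapply(ann$loci, function(l) length(l$transcripts), integer(1))
  n_loci <- length(ann$loci)
  ref_overlapping <- if (!is.null(reference_gene_ids))
    sum(names(ann$loci) %in% reference_gene_ids) else NA_integer_
  list(
    category_table = category_table,
    n_isoforms = total,
    locus_counts = c(total = n_loci,
                     reference_overlapping = ref_overlapping,
                     new = if (is.na(ref_overlapping)) NA_integer_
                           else n_loci - ref_overlapping),
    pct_multi_isoform = if (n_loci) percentage(sum(n_tx >= 2L), n_loci,
                                               decimals) else 0,
    mean_isoforms_per_locus = if (n_loci)
      round_half_up(sum(n_tx) / n_loci, 2L) else 0)
}

#' Category percentage table from raw counts
#'
#' Convenience wrapper turning labeled counts into the printed
#' percentages of a category breakdown.
#'
#' @param counts Named non-negative integer vector.
#' @param total Optional explicit total (default `sum(counts)`); counts
#'   must not exceed it.
#' @param decimals Decimal places.
#' @return data.frame `category`, `count`, `pct`.
#' @export
category_percentages <- function(counts, total = sum(counts), decimals = 2L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  if (any(counts > total)) stop("count exceeds total")
  data.frame(category = names(counts), count = as.integer(counts),
             pct = vapply(counts, percentage, numeric(1), total = total,
                          decimals = decimals),
             stringsAsFactors = FALSE, row.names = NULL)
}
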