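#' Expression specificity of a gene
#'
#' The specificity of an expression vector (over tissues, or over the
#' isoforms of one gene) is `max(x_i^2) / sum(x_i^2)`: 1 when a single
#' tissue/isoform carries all expression, `1/n` when expression is
#' uniform. Invariant to positive scaling of `x`.
#'
#' @param x Non-negative numeric vector, not all zero.
#' @return Numeric in `[1/length(x), 1]`.
#' @export
specificity <- function(x) {
  stopifnot(all(x >= 0))
  s2 <- sum(x^2)
  if (s2 == 0) stop("specificity undefined for an all-zero vector")
  max(x^2) / s2
}

#' Shannon entropy of an expression vector
#'
#' Plug-in (maximum-likelihood) estimator on the normalized proportions
#' `p_i = x_i / sum(x)`, with `0 * log(0) = 0`. Natural log by default;
#' base-2 differs by the factor `log(2)` exactly.
#'
#' @param x Non-negative numeric vector, not all zero.
#' @param base `"e"` (natural log, default) or `"2"`.
#' @return Entropy in `[0, log(length(x))]` (in the chosen base).
#' @export
shannon_entropy <- function(x, base = c("e", "2")) {
  base <- match.arg(as.character(base), c("e", "2"))
  stopifnot(all(x >= 0))
  s <- sum(x)
  if (s == 0) stop("entropy undefined for an all-zero vector")
  p <- x / s
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (base == "2") h / log(2) else h
}

#' Paired t-test (closed form)
#'
#' Standard paired t on the differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from the t distribution
#' with `n - 1` degrees of freedom. A zero-variance difference vector is
#' flagged: p = 1 when the mean difference is also zero, p = 0 otherwise.
#'
#' @param a,b Numeric vectors of equal length >= 2 (already on the scale to
#'   be tested, e.g. log2 FPKM).
#' @return List with `t`, `p_value`, `df`, `mean_diff`,
#'   `zero_variance` flag.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) stop("paired t-test needs n >= 2")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p_value = if (m == 0) 1 else 0,
                df = n - 1L, mean_diff = m, zero_variance = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p_value = 2 * stats::pt(-abs(t), df = n - 1L),
       df = n - 1L, mean_diff = m, zero_variance = FALSE)
}

#' Compare ohnolog gene pairs across the L and S subgenomes
#'
#' For every resolvable pair the per-gene metrics are computed from the
#' tissue-level gene FPKM matrix and the isoform FPKM matrix: isoform
#' count, summed FPKM over tissues, tissue entropy and tissue specificity
#' of the gene's tissue vector, and per-tissue isoform entropy and
#' expression standard deviation over the gene's isoforms. Cohort-level
#' paired tests (L vs S) are then run on each metric; expression is tested
#' on `log2(FPKM + pseudo_count)`.
#'
#' @param pairs data.frame with columns `l_gene`, `s_gene` (see
#'   [read_ohnolog_pairs()]).
#' @param gene_matrix An [expression_matrix()] of gene FPKM (rows = genes,
#'   columns = tissues).
#' @param isoform_matrix Optional [expression_matrix()] of isoform FPKM.
#' @param isoform_map Optional data.frame `isoform_id`, `gene_id` mapping
#'   isoform rows to genes (required with `isoform_matrix`).
#' @param pseudo_count Added to FPKM before log2. Default 1.
#' @param entropy_base Passed to [shannon_entropy()].
#' @return List with `per_pair` (data.frame of per-pair metrics), `tests`
#'   (data.frame: metric, t, p_value, mean_diff, n), `per_tissue_tests`
#'   (isoform entropy and SD tested within each tissue) and `dropped`
#'   (counts of unresolvable pairs and of pairs excluded from
#'   entropy/specificity tests for zero expression).
#' @export
compare_ohnologs <- function(pairs, gene_matrix, isoform_matrix = NULL,
                             isoform_map = NULL, pseudo_count = 1,
                             entropy_base = "e") {
  stopifnot(inherits(gene_matrix, "expression_matrix"))
  if (!nrow(pairs)) stop("empty ohnolog pair list")
  gm <- gene_matrix$values
  ok <- pairs$l_gene %in% rownames(gm) & pairs$s_gene %in% rownames(gm)
  n_unresolved <- sum(!ok)
  if (n_unresolved)
    message(n_unresolved, " ohnolog pair(s) dropped: gene id not in matrix")
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) stop("no resolvable ohnolog pairs")

  iso_count <- NULL
  if (!is.null(isoform_matrix)) {
    stopifnot(!is.null(isoform_map),
              all(c("isoform_id", "gene_id") %in% colnames(isoform_map)))
    cnt <- table(isoform_map$gene_id)
    iso_count <- function(g) {
      v <- cnt[g]
      ifelse(is.na(v), 0L, as.integer(v))
    }
  }

  metric_row <- function(g) {
    x <- gm[g, ]
    tot <- sum(x)
    c(sum_fpkm = tot,
      tissue_entropy = if (tot > 0) shannon_entropy(x, entropy_base) else NA_real_,
      tissue_specificity = if (tot > 0) specificity(x) else NA_real_)
  }
  ml <- t(vapply(pairs$l_gene, metric_row, numeric(3)))
  ms <- t(vapply(pairs$s_gene, metric_row, numeric(3)))
  per_pair <- data.frame(
    l_gene = pairs$l_gene, s_gene = pairs$s_gene,
    l_sum_fpkm = ml[, "sum_fpkm"], s_sum_fpkm = ms[, "sum_fpkm"],
    l_tissue_entropy = ml[, "tissue_entropy"],
    s_tissue_entropy = ms[, "tissue_entropy"],
    l_tissue_specificity = ml[, "tissue_specificity"],
    s_tissue_specificity = ms[, "tissue_specificity"],
    stringsAsFactors = FALSE)
  if (!is.null(iso_count)) {
    per_pair$l_isoforms <- iso_count(pairs$l_gene)
    per_pair$s_isoforms <- iso_count(pairs$s_gene)
  }
  rownames(per_pair) <- NULL

  run_test <- function(a, b, metric) {
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 2L)
      return(data.frame(metric = metric, t = NA_real_, p_value = NA_real_,
                        mean_diff = NA_real_, n = sum(keep)))
    r <- paired_t_test(a[keep], b[keep])
    data.frame(metric = metric, t = r$t, p_value = r$p_value,
               mean_diff = r$mean_diff, n = sum(keep),
               stringsAsFactors = FALSE)
  }
  tests <- rbind(
    run_test(log2(per_pair$l_sum_fpkm + pseudo_count),
             log2(per_pair$s_sum_fpkm + pseudo_count), "log2_fpkm"),
    run_test(per_pair$l_tissue_entropy, per_pair$s_tissue_entropy,
             "tissue_entropy"),
    run_test(per_pair$l_tissue_specificity, per_pair$s_tissue_specificity,
             "tissue_specificity"))
  if (!is.null(iso_count))
    tests <- rbind(tests, run_test(per_pair$l_isoforms, per_pair$s_isoforms,
                                   "isoform_count"))
  n_zero <- sum(is.na(per_pair$l_tissue_entropy) |
                  is.na(per_pair$s_tissue_entropy))

  per_tissue_tests <- NULL
  if (!is.null(isoform_matrix)) {
    im <- isoform_matrix$values
    iso_of <- split(isoform_map$isoform_id, isoform_map$gene_id)
    gene_tissue_stat <- function(g, tissue, f) {
      iso <- iso_of[[g]]
      iso <- iso[iso %in% rownames(im)]
      if (length(iso) < 1L) return(NA_real_)
      f(im[iso, tissue])
    }
    rows <- list()
    for (tissue in colnames(im)) {
      ent <- function(v) if (sum(v) > 0 && length(v) > 1L)
        shannon_entropy(v, entropy_base) else NA_real_
      sdv <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
      le <- vapply(pairs$l_gene, gene_tissue_stat, numeric(1), tissue, ent)
      se <- vapply(pairs$s_gene, gene_tissue_stat, numeric(1), tissue, ent)
      ls <- vapply(pairs$l_gene, gene_tissue_stat, numeric(1), tissue, sdv)
      ss <- vapply(pairs$s_gene, gene_tissue_stat, numeric(1), tissue, sdv)
      r1 <- run_test(le, se, "isoform_entropy")
      r2 <- run_test(ls, ss, "expression_sd")
      r1$tissue <- tissue; r2$tissue <- tissue
      rows[[length(rows) + 1L]] <- rbind(r1, r2)
    }
    per_tissue_tests <- do.call(rbind, rows)
    rownames(per_tissue_tests) <- NULL
  }

  list(per_pair = per_pair, tests = tests,
       per_tissue_tests = per_tissue_tests,
       dropped = c(unresolved = n_unresolved, zero_expression = n_zero))
}
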