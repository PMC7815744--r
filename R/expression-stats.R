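#' Count expressed genes per sample
#'
#' A gene is expressed in a sample when its abundance is at or above the
#' threshold (the boundary is inclusive: FPKM >= 0.1 by default counts).
#'
#' @param mat An [expression_matrix()] with `unit = "FPKM"`.
#' @param threshold Expression threshold in FPKM.
#' @return Named integer vector, one count per sample.
#' @export
count_expressed_genes <- function(mat, threshold = 0.1) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$unit != "FPKM") stop("count_expressed_genes expects FPKM")
  colSums(mat$values >= threshold)
}

#' Two-group differential-expression test for one gene
#'
#' Without replicates (one count per group) an exact conditional binomial
#' test is used: given the total `kA + kB`, `kA` is binomial with success
#' probability `libA / (libA + libB)` under the null of equal relative
#' expression; the two-sided p-value doubles the smaller tail (capped at
#' 1). With replicates, a Welch t-test is run on
#' `log2(count/library_size + pseudo/mean(library_size))`.
#' The log2 fold change is
#' `log2((mean(kA/libA) + eps) / (mean(kB/libB) + eps))` with
#' `eps = pseudo_count / mean(lib)`.
#'
#' @param counts_a,counts_b Non-negative integer count vectors (length 1 =
#'   no replicates).
#' @param lib_a,lib_b Positive library sizes, same lengths as the counts.
#' @param pseudo_count Pseudo-count (count units) guarding zeros.
#' @return List with `log2_fold_change`, `p_value`, `method`.
#' @export
de_test <- function(counts_a, counts_b, lib_a, lib_b, pseudo_count = 1) {
  stopifnot(length(counts_a) == length(lib_a),
            length(counts_b) == length(lib_b),
            all(counts_a >= 0), all(counts_b >= 0),
            all(lib_a > 0), all(lib_b > 0))
  eps <- pseudo_count / mean(c(lib_a, lib_b))
  ra <- counts_a / lib_a; rb <- counts_b / lib_b
  lfc <- log2((mean(ra) + eps) / (mean(rb) + eps))
  if (sum(counts_a) + sum(counts_b) == 0)
    return(list(log2_fold_change = 0, p_value = 1, method = "all_zero"))
  if (length(counts_a) == 1L && length(counts_b) == 1L) {
    n <- counts_a + counts_b
    pr <- lib_a / (lib_a + lib_b)
    lower <- stats::pbinom(counts_a, n, pr)
    upper <- stats::pbinom(counts_a - 1L, n, pr, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    return(list(log2_fold_change = lfc, p_value = p, method = "binomial"))
  }
  la <- log2(ra + eps); lb <- log2(rb + eps)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    p <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    return(list(log2_fold_change = lfc, p_value = p, method = "welch_t"))
  }
  p <- stats::t.test(la, lb, var.equal = FALSE)$p.value
  list(log2_fold_change = lfc, p_value = p, method = "welch_t")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: with p-values sorted ascending, the adjusted value at
#' rank i is `min over j >= i of p_(j) * n / j`, capped at 1 and mapped
#' back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of FDR-adjusted values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p_values[o] * n / seq(n, 1)))
  adj[ro]
}

#' Run a full per-gene DE comparison between two sample groups
#'
#' @param mat An [expression_matrix()] with `unit = "count"` and library
#'   sizes.
#' @param samples_a,samples_b Column names of the two groups.
#' @param pseudo_count Passed to [de_test()].
#' @return data.frame `gene_id`, `log2_fold_change`, `p_value`, `fdr`
#'   (BH within this comparison).
#' @export
de_table <- function(mat, samples_a, samples_b, pseudo_count = 1) {
  stopifnot(inherits(mat, "expression_matrix"), mat$unit == "count")
  stopifnot(all(c(samples_a, samples_b) %in% colnames(mat$values)))
  la <- mat$library_sizes[samples_a]; lb <- mat$library_sizes[samples_b]
  res <- lapply(rownames(mat$values), function(g) {
    de_test(mat$values[g, samples_a], mat$values[g, samples_b], la, lb,
            pseudo_count = pseudo_count)
  })
  out <- data.frame(
    gene_id = rownames(mat$values),
    log2_fold_change = vapply(res, `[[`, numeric(1), "log2_fold_change"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out
}

#' Specificity-call configuration for tissue-specific gene selection
#'
#' @param fold_change_min Minimum linear fold change (strict: a gene at
#'   exactly this value is not called). Default 2.
#' @param fdr_max FDR cutoff (strict). Default 0.05.
#' @param min_other_tissues Minimum number of other-tissue comparisons in
#'   which the gene must be significantly up-regulated. Default 9 (of the
#'   12 non-focal tissues in a 13-tissue panel).
#' @param pseudo_count Pseudo-count in count units for fold changes.
#' @return List of class `specificity_call_config`.
#' @export
specificity_call_config <- function(fold_change_min = 2, fdr_max = 0.05,
                                    min_other_tissues = 9L,
                                    pseudo_count = 1) {
  stopifnot(fold_change_min > 1, fdr_max > 0, fdr_max < 1,
            min_other_tissues >= 1L)
  structure(list(fold_change_min = fold_change_min, fdr_max = fdr_max,
                 min_other_tissues = as.integer(min_other_tissues),
                 pseudo_count = pseudo_count),
            class = "specificity_call_config")
}

#' Select tissue-specific genes from per-comparison DE tables
#'
#' A gene is tissue-specific when it is up-regulated in the focal tissue
#' (linear fold change strictly above `fold_change_min` and FDR strictly
#' below `fdr_max`) against at least `min_other_tissues` of the other
#' tissues.
#'
#' @param de_tables Named list of DE data.frames (one per focal-vs-other
#'   comparison) with columns `gene_id`, `log2_fold_change`, `fdr`.
#' @param config A [specificity_call_config()].
#' @return Sorted character vector of selected gene ids.
#' @export
tissue_specific_genes <- function(de_tables, config = specificity_call_config()) {
  if (length(de_tables) < config$min_other_tissues)
    stop("fewer comparison tables (", length(de_tables),
         ") than min_other_tissues (", config$min_other_tissues, ")")
  lfc_min <- log2(config$fold_change_min)
  hits <- lapply(de_tables, function(d) {
    d$gene_id[d$log2_fold_change > lfc_min & d$fdr < config$fdr_max]
  })
  tally <- table(unlist(hits))
  sort(names(tally)[tally >= config$min_other_tissues])
}

#' Union of pairwise differentially expressed genes across groups
#'
#' Runs [de_test()] per gene for every pair of condition groups, adjusts
#' p-values by Benjamini-Hochberg within each pair, and returns the union
#' of genes significant (FDR strictly below `fdr_max`) in at least one
#' pair.
#'
#' @param mat An [expression_matrix()] of counts with library sizes.
#' @param groups Named list: group name -> character vector of sample
#'   columns (>= 2 groups, >= 1 replicate each).
#' @param fdr_max FDR cutoff.
#' @param pseudo_count Passed to [de_test()].
#' @return List with `degs` (sorted gene ids in the union) and `tables`
#'   (named list of per-pair DE data.frames, names `"A_vs_B"`).
#' @export
pairwise_deg_union <- function(mat, groups, fdr_max = 0.05,
                               pseudo_count = 1) {
  stopifnot(length(groups) >= 2L, !is.null(names(groups)))
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  tables <- lapply(pairs, function(p) {
    de_table(mat, groups[[p[1L]]], groups[[p[2L]]],
             pseudo_count = pseudo_count)
  })
  names(tables) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  degs <- sort(unique(unlist(lapply(tables, function(d)
    d$gene_id[d$fdr < fdr_max]))))
  list(degs = degs, tables = tables)
}
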