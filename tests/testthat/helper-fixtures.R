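`%||%` <- function(a, b) if (is.null(a)) b else a

# shorthand transcript builder
tx <- function(id, starts, ends, strand = "+", chrom = "chr1", gene = "") {
  transcript_model(id, chrom, strand, starts, ends, gene_id = gene)
}

# shift one tested boundary of an exon chain by `delta` nt (signed);
# returns NULL when no valid placement exists
shift_one_boundary <- function(exons, delta, which_boundary = NULL) {
  n <- nrow(exons)
  cand <- list()
  if (n == 1L) {
    cand <- list(c(1L, 1L), c(1L, 2L))
  } else {
    for (j in seq_len(n)) {
      if (j > 1L) cand[[length(cand) + 1L]] <- c(j, 1L)
      if (j < n) cand[[length(cand) + 1L]] <- c(j, 2L)
    }
  }
  if (is.null(which_boundary))
    which_boundary <- sample.int(length(cand), 1L)
  pick <- cand[[which_boundary]]
  e2 <- exons
  if (pick[2L] == 1L) e2$start[pick[1L]] <- e2$start[pick[1L]] + delta
  else e2$end[pick[1L]] <- e2$end[pick[1L]] + delta
  ok <- all(e2$end >= e2$start) &&
    (n == 1L || all(e2$start[-1L] - e2$end[-n] >= 2L))
  if (ok) e2 else NULL
}

# one random structural perturbation of an exon chain; NULL if infeasible
perturb_chain <- function(ex) {
  n <- nrow(ex)
  ops <- c("shift",
           if (n >= 2L) c("retain", "drop_first", "drop_last"),
           if (n >= 3L) "drop_internal",
           if (n >= 2L) "alt_first")
  op <- sample(ops, 1L)
  out <- switch(op,
    shift = shift_one_boundary(ex, sample(c(-1L, 1L), 1L) * sample(5:25, 1L)),
    retain = {
      j <- sample.int(n - 1L, 1L)
      d <- ex
      d$end[j] <- d$end[j + 1L]
      d[-(j + 1L), , drop = FALSE]
    },
    drop_internal = ex[-sample(2:(n - 1L), 1L), , drop = FALSE],
    drop_first = ex[-1L, , drop = FALSE],
    drop_last = ex[-n, , drop = FALSE],
    alt_first = {
      gap <- ex$start[2L] - ex$end[1L] - 1L
      if (gap < 30L) NULL
      else {
        d <- ex
        d$start[1L] <- ex$end[1L] + 5L
        d$end[1L] <- ex$end[1L] + 15L
        d
      }
    })
  if (is.null(out)) return(NULL)
  ok <- all(out$end >= out$start) &&
    (nrow(out) == 1L || all(out$start[-1L] - out$end[-nrow(out)] >= 2L))
  if (ok) out else NULL
}

random_master_chain <- function(max_exons = 5L) {
  n <- sample(2:max_exons, 1L)
  w <- sample(30:80, n, replace = TRUE)
  g <- sample(40:120, max(n - 1L, 1L), replace = TRUE)
  s <- integer(n); e <- integer(n)
  pos <- 1000L
  for (j in seq_len(n)) {
    s[j] <- pos; e[j] <- pos + w[j] - 1L
    pos <- e[j] + (if (j < n) g[j] else 0L) + 1L
  }
  data.frame(start = s, end = e)
}

# random multi-isoform locus built from perturbations of one master chain
random_locus <- function(id = "g1", n_tx = 3L, max_exons = 5L,
                         strand = sample(c("+", "-"), 1L)) {
  master <- random_master_chain(max_exons)
  txs <- list()
  for (i in seq_len(n_tx)) {
    ex <- master
    for (k in seq_len(sample(0:2, 1L))) {
      p <- perturb_chain(ex)
      if (!is.null(p)) ex <- p
    }
    txs[[i]] <- transcript_model(sprintf("%s.t%d", id, i), "chr1", strand,
                                 ex$start, ex$end)
  }
  gene_locus(id, txs)
}
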