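# Independent brute-force oracles, written directly from the published
# criteria and kept structurally separate from the package implementation.

# literal enumeration of the known/novel isoform criteria in transcription
# orientation: same exon count, and the first exon's 3' end, the last
# exon's 5' start, and both boundaries of every middle exon each deviate
# by < tol nt from some reference isoform
oracle_classify <- function(query, ref_locus, tol = 6L) {
  orient <- function(t) {
    ex <- t$exons
    if (t$strand == "-") ex[rev(seq_len(nrow(ex))), , drop = FALSE] else ex
  }
  # 5' ("start") and 3' ("stop") coordinate of each exon in transcription
  # orientation
  coord5 <- function(t, ex) if (t$strand == "-") ex$end else ex$start
  coord3 <- function(t, ex) if (t$strand == "-") ex$start else ex$end
  for (r in ref_locus$transcripts) {
    qe <- orient(query); re <- orient(r)
    n <- nrow(qe)
    if (n != nrow(re)) next
    q5 <- coord5(query, qe); q3 <- coord3(query, qe)
    r5 <- coord5(r, re); r3 <- coord3(r, re)
    devs <- c(abs(q3[1L] - r3[1L]),       # first-exon stop
              abs(q5[n] - r5[n]))         # last-exon start
    if (n > 2L) for (m in 2:(n - 1L))
      devs <- c(devs, abs(q5[m] - r5[m]), abs(q3[m] - r3[m]))
    if (n == 1L) devs <- c(abs(q3[1L] - r3[1L]), abs(q5[1L] - r5[1L]))
    if (all(devs < tol)) return("known_isoform")
  }
  "novel_isoform"
}

# per-base exonic overlap of a query against a locus, by integer sets
oracle_overlap_fraction <- function(query, locus) {
  if (query$chrom != locus$chrom) return(0)
  qb <- unlist(mapply(seq, query$exons$start, query$exons$end,
                      SIMPLIFY = FALSE))
  rb <- unique(unlist(lapply(locus$transcripts, function(t)
    mapply(seq, t$exons$start, t$exons$end, SIMPLIFY = FALSE))))
  length(intersect(qb, rb)) / length(qb)
}

# exhaustive pairwise enumeration of the seven event definitions; returns
# a sorted character vector of "type coords" keys
oracle_events <- function(locus) {
  txs <- locus$transcripts
  ids <- names(txs)
  strand <- locus$strand
  keys <- character(0)
  addk <- function(type, coords) {
    if (any(diff(coords) <= 0)) return()
    keys <<- c(keys, paste(type, paste(coords, collapse = ",")))
  }
  exon_key <- lapply(txs, function(t) paste(t$exons$start, t$exons$end))
  intr <- lapply(txs, transcript_introns)
  for (ai in seq_along(txs)) for (bi in seq_along(txs)) {
    if (ai == bi) next
    A <- txs[[ai]]; B <- txs[[bi]]
    ia <- intr[[ai]]; ib <- intr[[bi]]
    na <- nrow(A$exons)
    ## SE
    if (na >= 3L) for (j in 2:(na - 1L)) {
      d <- A$exons$end[j - 1L] + 1L; a2 <- A$exons$start[j + 1L] - 1L
      if (nrow(ib) && any(ib$start == d & ib$end == a2))
        addk("SE", c(d, A$exons$start[j], A$exons$end[j], a2))
    }
    ## RI
    if (nrow(ia)) for (j in seq_len(nrow(ia))) {
      aa <- A$exons$start[j]; bb <- A$exons$end[j + 1L]
      if (any(B$exons$start == aa & B$exons$end == bb))
        addk("RI", c(aa, ia$start[j], ia$end[j], bb))
    }
    ## intron pairs: A5/A3/AF/AL
    if (nrow(ia) && nrow(ib))
      for (j in seq_len(nrow(ia))) for (k in seq_len(nrow(ib))) {
        I <- ia[j, ]; J <- ib[k, ]
        if (I$start == J$start && I$end != J$end) {
          exA <- c(I$end + 1L, A$exons$end[j + 1L])
          exB <- c(J$end + 1L, B$exons$end[k + 1L])
          if (exA[1L] <= exB[2L] && exB[1L] <= exA[2L]) {
            addk(if (strand == "-") "A5" else "A3",
                 c(I$start, min(I$end, J$end), max(I$end, J$end)))
          } else if (j == nrow(ia) && k == nrow(ib)) {
            two <- if (exA[1L] < exB[1L]) c(exA, exB) else c(exB, exA)
            addk(if (strand == "-") "AF" else "AL", c(I$start, two))
          }
        } else if (I$end == J$end && I$start != J$start) {
          exA <- c(A$exons$start[j], I$start - 1L)
          exB <- c(B$exons$start[k], J$start - 1L)
          if (exA[1L] <= exB[2L] && exB[1L] <= exA[2L]) {
            addk(if (strand == "-") "A3" else "A5",
                 c(min(I$start, J$start), max(I$start, J$start), I$end))
          } else if (j == 1L && k == 1L) {
            two <- if (exA[1L] < exB[1L]) c(exA, exB) else c(exB, exA)
            addk(if (strand == "-") "AL" else "AF", c(two, I$end + 1L))
          }
        }
      }
    ## MX
    nb <- nrow(B$exons)
    if (na >= 3L && nb >= 3L)
      for (j in 2:(na - 1L)) for (k in 2:(nb - 1L)) {
        d1 <- A$exons$end[j - 1L] + 1L; a1 <- A$exons$start[j + 1L] - 1L
        d2 <- B$exons$end[k - 1L] + 1L; a2 <- B$exons$start[k + 1L] - 1L
        if (d1 != d2 || a1 != a2) next
        x1 <- c(A$exons$start[j], A$exons$end[j])
        x2 <- c(B$exons$start[k], B$exons$end[k])
        if (!(x1[2L] < x2[1L])) next
        k1 <- paste(x1[1L], x1[2L]); k2 <- paste(x2[1L], x2[2L])
        if (any(vapply(exon_key, function(s) all(c(k1, k2) %in% s),
                       logical(1)))) next
        addk("MX", c(d1, x1, x2, a1))
      }
  }
  sort(unique(keys))
}

event_keys <- function(events) {
  sort(vapply(events, function(ev)
    paste(ev$event_type, paste(ev$coords, collapse = ",")), character(1)))
}

# mirror a locus: reflect all coordinates and flip the strand
mirror_locus <- function(locus, C = 100000L) {
  txs <- lapply(locus$transcripts, function(t) {
    transcript_model(t$transcript_id, t$chrom,
                     if (t$strand == "+") "-" else if (t$strand == "-") "+"
                     else ".",
                     rev(C - t$exons$end), rev(C - t$exons$start))
  })
  gene_locus(locus$gene_id, txs, biotype = locus$biotype)
}
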