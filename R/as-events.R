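#' Intron chains of every transcript in a locus
#'
#' @param locus A [gene_locus()].
#' @return Named list (by transcript id) of data.frames with columns
#'   `start`, `end`: the introns in genomic order. Monoexonic transcripts
#'   yield zero-row frames.
#' @export
splice_chains <- function(locus) {
  lapply(locus$transcripts, transcript_introns)
}

.intron_key <- function(s, e) paste(s, e, sep = "-")

#' Detect local alternative-splicing events in a gene locus
#'
#' Pairwise comparison of the isoforms' intron chains yields candidate
#' local events of the seven classes -- skipped exon (SE), mutually
#' exclusive exons (MX), alternative 5'/3' splice site (A5/A3), retained
#' intron (RI), alternative first/last exon (AF/AL) -- deduplicated by
#' event type and defining coordinates, so one biological event seen in
#' many isoform pairs counts once.
#'
#' Definitions (all coordinates genomic, 1-based inclusive):
#' * SE: an internal exon flanked by introns `I1`, `I2` in one isoform vs
#'   a single intron spanning `I1.start..I2.end` in another.
#' * RI: an intron of one isoform lying inside an exon of another whose
#'   boundaries equal the intron-flanking exon boundaries.
#' * A5/A3: two introns sharing exactly one boundary, where the exons
#'   abutting the differing side overlap each other (two alternative
#'   boundaries of one shared exon); the differing side is the donor (A5)
#'   or acceptor (A3), resolved by strand.
#' * AF/AL: two introns sharing the boundary into a common exon whose
#'   differing sides abut non-overlapping transcription-first (last)
#'   exons in both isoforms. Pairs whose differing side abuts
#'   non-overlapping internal exons are skipped-exon configurations and
#'   yield no splice-site event.
#' * MX: two non-overlapping internal exons in different isoforms whose
#'   flanking introns share their outer boundaries, with no isoform
#'   containing both exons.
#'
#' Monoexonic isoforms participate only as the retaining partner of RI.
#'
#' @param locus A [gene_locus()].
#' @return List of `as_event` records: lists with fields `event_type`,
#'   `gene_id`, `chrom`, `strand`, `coords` (strictly increasing integer
#'   vector of defining coordinates), `inclusion`, `exclusion`
#'   (disjoint character vectors of transcript ids). Sorted by type then
#'   coordinates; empty for single-isoform loci.
#' @export
detect_events <- function(locus) {
  txs <- locus$transcripts
  if (length(txs) < 2L) return(list())
  strand <- locus$strand
  ids <- names(txs)
  introns <- lapply(txs, transcript_introns)
  intron_keys <- lapply(introns, function(d) .intron_key(d$start, d$end))
  exon_keys <- lapply(txs, function(t) .intron_key(t$exons$start, t$exons$end))

  # transcripts containing a given intron / exact exon
  with_intron <- function(s, e) ids[vapply(intron_keys, function(k)
    .intron_key(s, e) %in% k, logical(1))]
  with_exon <- function(s, e) ids[vapply(exon_keys, function(k)
    .intron_key(s, e) %in% k, logical(1))]
  # transcripts containing consecutive introns I1,I2 (i.e. the exon between
  # them with both flanks)
  with_flanked_exon <- function(i1s, i1e, i2s, i2e) {
    ids[vapply(seq_along(txs), function(i) {
      d <- introns[[i]]
      j <- which(d$start == i1s & d$end == i1e)
      length(j) == 1L && j < nrow(d) &&
        d$start[j + 1L] == i2s && d$end[j + 1L] == i2e
    }, logical(1))]
  }

  events <- new.env(parent = emptyenv())
  add_event <- function(type, coords, inclusion, exclusion) {
    if (any(diff(coords) <= 0)) return(invisible(NULL))  # degenerate (1-bp exon)
    key <- paste(type, paste(coords, collapse = ","))
    cur <- events[[key]]
    if (is.null(cur)) {
      events[[key]] <- list(event_type = type, gene_id = locus$gene_id,
                            chrom = locus$chrom, strand = strand,
                            coords = as.integer(coords),
                            inclusion = inclusion, exclusion = exclusion)
    } else {
      cur$inclusion <- union(cur$inclusion, inclusion)
      cur$exclusion <- union(cur$exclusion, exclusion)
      events[[key]] <- cur
    }
  }

  ## SE and the exon side of MX: internal exons with both flanking introns
  internal_exons <- list()  # list of (tx index, exon row, d, a)
  for (i in seq_along(txs)) {
    ex <- txs[[i]]$exons; n <- nrow(ex)
    if (n < 3L) next
    for (j in 2:(n - 1L)) {
      internal_exons[[length(internal_exons) + 1L]] <-
        list(tx = i, s = ex$start[j], e = ex$end[j],
             i1s = ex$end[j - 1L] + 1L, i2e = ex$start[j + 1L] - 1L)
    }
  }
  for (xe in internal_exons) {
    skip <- with_intron(xe$i1s, xe$i2e)
    if (length(skip)) {
      incl <- with_flanked_exon(xe$i1s, xe$s - 1L, xe$e + 1L, xe$i2e)
      add_event("SE", c(xe$i1s, xe$s, xe$e, xe$i2e), incl, skip)
    }
  }

  ## MX: pairs of internal exons sharing outer flanking-intron boundaries
  if (length(internal_exons) >= 2L) {
    for (a_i in seq_along(internal_exons)) {
      for (b_i in seq_along(internal_exons)) {
        x1 <- internal_exons[[a_i]]; x2 <- internal_exons[[b_i]]
        if (x1$tx == x2$tx) next
        if (!(x1$e < x2$s)) next                       # ordered, non-overlap
        if (x1$i1s != x2$i1s || x1$i2e != x2$i2e) next # shared outer bounds
        both <- ids[vapply(exon_keys, function(k)
          all(c(.intron_key(x1$s, x1$e), .intron_key(x2$s, x2$e)) %in% k),
          logical(1))]
        if (length(both)) next
        incl <- with_flanked_exon(x1$i1s, x1$s - 1L, x1$e + 1L, x1$i2e)
        excl <- with_flanked_exon(x2$i1s, x2$s - 1L, x2$e + 1L, x2$i2e)
        if (length(incl) && length(excl) && !length(intersect(incl, excl)))
          add_event("MX", c(x1$i1s, x1$s, x1$e, x2$s, x2$e, x1$i2e),
                    incl, excl)
      }
    }
  }

  ## RI: intron of one isoform retained in an exact-boundary exon of another
  for (i in seq_along(txs)) {
    ex <- txs[[i]]$exons; n <- nrow(ex)
    if (n < 2L) next
    for (j in seq_len(n - 1L)) {
      a <- ex$start[j]; d <- ex$end[j] + 1L
      r <- ex$start[j + 1L] - 1L; b <- ex$end[j + 1L]
      retain <- with_exon(a, b)
      if (!length(retain)) next
      # splicers: transcripts with intron (d, r) flanked by exons a.. and ..b
      spl <- ids[vapply(seq_along(txs), function(k) {
        dd <- introns[[k]]
        jj <- which(dd$start == d & dd$end == r)
        if (length(jj) != 1L) return(FALSE)
        txs[[k]]$exons$start[jj] == a && txs[[k]]$exons$end[jj + 1L] == b
      }, logical(1))]
      if (length(spl))
        add_event("RI", c(a, d, r, b), retain, spl)
    }
  }

  ## A5/A3/AF/AL: intron pairs sharing exactly one boundary
  # flatten distinct introns with position info per transcript
  all_introns <- list()
  for (i in seq_along(txs)) {
    d <- introns[[i]]
    if (!nrow(d)) next
    for (j in seq_len(nrow(d)))
      all_introns[[length(all_introns) + 1L]] <-
        list(tx = i, s = d$start[j], e = d$end[j], pos = j,
             n_introns = nrow(d))
  }
  if (length(all_introns) >= 2L) {
    for (a_i in seq_along(all_introns)) {
      for (b_i in seq_along(all_introns)) {
        I <- all_introns[[a_i]]; J <- all_introns[[b_i]]
        if (I$tx == J$tx) next
        share_left <- I$s == J$s; share_right <- I$e == J$e
        if (share_left == share_right) next  # need exactly one shared bound
        if (share_right) {
          if (!(I$s < J$s)) next  # canonical order: I has the longer intron
          # differing (left) side abuts the upstream exons
          ex_I <- c(txs[[I$tx]]$exons$start[I$pos], I$s - 1L)
          ex_J <- c(txs[[J$tx]]$exons$start[J$pos], J$s - 1L)
          if (ex_I[1L] <= ex_J[2L] && ex_J[1L] <= ex_I[2L]) {
            # alternative boundaries of one shared exon: splice-site shift
            type <- if (strand == "-") "A3" else "A5"
            add_event(type, c(I$s, J$s, I$e),
                      with_intron(J$s, J$e), with_intron(I$s, I$e))
          } else if (I$pos == 1L && J$pos == 1L) {
            # non-overlapping alternative terminal exons (ex_I is left of
            # ex_J here since I's intron starts first)
            type <- if (strand == "-") "AL" else "AF"
            add_event(type, c(ex_I, ex_J, I$e + 1L), ids[I$tx], ids[J$tx])
          }
          # otherwise: differing side abuts non-overlapping internal exons
          # (an SE/MX configuration); no splice-site event here
        } else {
          if (!(I$e > J$e)) next  # canonical order: I has the longer intron
          ex_I <- c(I$e + 1L, txs[[I$tx]]$exons$end[I$pos + 1L])
          ex_J <- c(J$e + 1L, txs[[J$tx]]$exons$end[J$pos + 1L])
          if (ex_I[1L] <= ex_J[2L] && ex_J[1L] <= ex_I[2L]) {
            type <- if (strand == "-") "A5" else "A3"
            add_event(type, c(I$s, J$e, I$e),
                      with_intron(J$s, J$e), with_intron(I$s, I$e))
          } else if (I$pos == I$n_introns && J$pos == J$n_introns) {
            type <- if (strand == "-") "AF" else "AL"
            add_event(type, c(I$s, ex_J, ex_I), ids[J$tx], ids[I$tx])
          }
        }
      }
    }
  }

  out <- lapply(ls(events, sorted = FALSE), function(k) events[[k]])
  # drop events whose inclusion/exclusion sets ended up empty or overlapping
  out <- Filter(function(ev) length(ev$inclusion) && length(ev$exclusion) &&
                  !length(intersect(ev$inclusion, ev$exclusion)), out)
  out <- lapply(out, function(ev) {
    ev$inclusion <- sort(ev$inclusion); ev$exclusion <- sort(ev$exclusion); ev
  })
  key <- vapply(out, function(ev)
    paste(ev$event_type, sprintf("%012d", ev$coords[1L]),
          paste(ev$coords, collapse = ","), sep = "|"), character(1))
  out[order(key)]
}

#' Detect AS events across every locus of an annotation
#'
#' @param ann An [annotation()].
#' @return Flat list of `as_event` records (see [detect_events()]).
#' @export
detect_events_all <- function(ann) {
  out <- lapply(ann$loci, detect_events)
  unlist(out, recursive = FALSE, use.names = FALSE)
}

#' Tabulate AS events
#'
#' @param events List of `as_event` records from [detect_events()].
#' @return List with `by_type` (named counts over all seven types, zeros
#'   included, plus `total`), `by_gene` (data.frame `gene_id`, `n_events`
#'   sorted descending, ties by gene id) and `top_gene` (the gene with the
#'   most events, or `NA` when empty).
#' @export
summarize_events <- function(events) {
  types <- c("SE", "MX", "A5", "A3", "RI", "AF", "AL")
  by_type <- stats::setNames(integer(length(types)), types)
  if (length(events)) {
    tt <- table(factor(vapply(events, `[[`, character(1), "event_type"),
                       levels = types))
    by_type[names(tt)] <- as.integer(tt)
  }
  if (length(events)) {
    genes <- vapply(events, `[[`, character(1), "gene_id")
    tg <- table(genes)
    by_gene <- data.frame(gene_id = names(tg), n_events = as.integer(tg),
                          stringsAsFactors = FALSE)
    by_gene <- by_gene[order(-by_gene$n_events, by_gene$gene_id), ]
    rownames(by_gene) <- NULL
  } else {
    by_gene <- data.frame(gene_id = character(0), n_events = integer(0))
  }
  list(by_type = c(by_type, total = sum(by_type)),
       by_gene = by_gene,
       top_gene = if (nrow(by_gene)) by_gene$gene_id[1L] else NA_character_)
}

#' Export AS events as a data.frame (TSV-ready)
#'
#' Coordinates are joined into a strand-explicit string,
#' `chrom:c1-c2-...:strand`.
#'
#' @param events List of `as_event` records.
#' @return data.frame with columns `event_type`, `gene_id`, `coords`,
#'   `inclusion`, `exclusion`.
#' @export
events_table <- function(events) {
  if (!length(events))
    return(data.frame(event_type = character(0), gene_id = character(0),
                      coords = character(0), inclusion = character(0),
                      exclusion = character(0)))
  data.frame(
    event_type = vapply(events, `[[`, character(1), "event_type"),
    gene_id = vapply(events, `[[`, character(1), "gene_id"),
    coords = vapply(events, function(ev)
      sprintf("%s:%s:%s", ev$chrom, paste(ev$coords, collapse = "-"),
              ev$strand), character(1)),
    inclusion = vapply(events, function(ev)
      paste(ev$inclusion, collapse = ","), character(1)),
    exclusion = vapply(events, function(ev)
      paste(ev$exclusion, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
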