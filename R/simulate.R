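#' Simulation configuration
#'
#' Defaults describe a compact version of a 13-tissue full-length
#' transcriptome study: single-isoform reference genes, query transcripts
#' with planted novelty classes, lncRNA placements per positional class,
#' negative-binomial count matrices with planted tissue-specific effects,
#' and ohnolog pairs with a configurable L-subgenome bias.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param n_ref_genes Reference genes (one isoform each).
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length,intergenic_gap Length ranges (bp).
#' @param chromosome_length Optional fixed chromosome length; an error is
#'   raised when the simulated genes do not fit.
#' @param n_known,n_novel_shift,n_novel_exoncount Planted query counts:
#'   within-tolerance copies, single-boundary shifts past the tolerance,
#'   exon-count changes.
#' @param n_new_intergenic,n_new_antisense Planted new-gene queries placed
#'   in intergenic gaps or antisense over reference genes.
#' @param boundary_tolerance_nt Tolerance the planted shifts are defined
#'   against (matches [novelty_rule_config()]).
#' @param boundary_test_mode When `TRUE`, planted known copies are shifted
#'   by exactly `tolerance - 1` and novel shifts by exactly `tolerance`,
#'   probing the inclusive rule; otherwise shifts stay at least 1 nt away
#'   from the boundary.
#' @param lncrna_per_class Planted lncRNA placements per positional class.
#' @param tissues Tissue names for the expression design (13 by default,
#'   with `"skin"` the focal tissue).
#' @param replicates Replicates per tissue (1 = no-replicate design, the
#'   exact binomial DE path).
#' @param n_specific Planted focal-tissue-specific genes.
#' @param specific_fc Linear fold change of the planted specific genes.
#' @param focal_tissue Focal tissue for the planted effects.
#' @param color_groups,color_replicates Color-skin design.
#' @param n_color_degs,color_log2fc Planted color DEGs and their effect.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param n_ohnolog_pairs,ohnolog_bias,ohnolog_noise_sdlog Ohnolog design:
#'   number of L/S pairs, multiplicative L bias in FPKM, log-normal noise.
#' @param ohnolog_extra_isoforms_l Extra isoforms planted on L genes.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    n_chromosomes = 2L, n_ref_genes = 30L,
    exons_per_gene = c(2L, 8L), exon_length = c(80L, 400L),
    intron_length = c(60L, 500L), intergenic_gap = c(600L, 2000L),
    chromosome_length = NULL,
    n_known = 10L, n_novel_shift = 10L, n_novel_exoncount = 10L,
    n_new_intergenic = 5L, n_new_antisense = 5L,
    boundary_tolerance_nt = 6L, boundary_test_mode = FALSE,
    lncrna_per_class = 3L,
    tissues = c("skin", "brain", "eye", "gill", "fin", "muscle", "heart",
                "liver", "spleen", "intestine", "kidney", "testis", "hood"),
    replicates = 1L,
    n_specific = 50L, specific_fc = 8, focal_tissue = "skin",
    color_groups = c("black", "cyan", "red", "white"),
    color_replicates = 2L, n_color_degs = 30L, color_log2fc = 2,
    baseline_meanlog = 4, baseline_sdlog = 1, nb_dispersion = 0.1,
    n_ohnolog_pairs = 500L, ohnolog_bias = 2, ohnolog_noise_sdlog = 0.25,
    ohnolog_extra_isoforms_l = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_ref_genes >= 1L, cfg$n_chromosomes >= 1L,
            length(exons_per_gene) == 2L, exons_per_gene[1L] >= 1L,
            exon_length[1L] >= 10L, intron_length[1L] >= 10L,
            boundary_tolerance_nt >= 2L,
            all(c(n_known, n_novel_shift, n_novel_exoncount,
                  n_new_intergenic, n_new_antisense, lncrna_per_class) >= 0L),
            focal_tissue %in% tissues)
  structure(cfg, class = "simulation_config")
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate a single-isoform reference annotation
#'
#' Gene loci are laid left to right along each chromosome with random
#' intergenic gaps; no two loci overlap. Each gene carries exactly one
#' transcript (mirroring a reference annotated with a single isoform per
#' gene) and biotype `protein_coding`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed; identical `config` + `seed` give
#'   byte-identical annotations.
#' @return An [annotation()].
#' @export
simulate_reference <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  per_chrom <- rep(config$n_ref_genes %/% config$n_chromosomes,
                   config$n_chromosomes)
  rem <- config$n_ref_genes %% config$n_chromosomes
  if (rem) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L
  loci <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    cursor <- .runif_int(1L, config$intergenic_gap)
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      n_ex <- .runif_int(1L, config$exons_per_gene)
      ex_len <- .runif_int(n_ex, config$exon_length)
      in_len <- if (n_ex > 1L) .runif_int(n_ex - 1L, config$intron_length)
                else integer(0)
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- cursor
      for (j in seq_len(n_ex)) {
        starts[j] <- pos
        ends[j] <- pos + ex_len[j] - 1L
        pos <- ends[j] + (if (j < n_ex) in_len[j] else 0L) + 1L
      }
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("G%05d", gi)
      tx <- transcript_model(paste0(gid, ".t1"), chrom, strand, starts, ends)
      loci[[gid]] <- gene_locus(gid, list(tx), biotype = "protein_coding")
      cursor <- ends[n_ex] + .runif_int(1L, config$intergenic_gap) + 1L
    }
    if (!is.null(config$chromosome_length) &&
        cursor > config$chromosome_length)
      stop("infeasible packing: ", per_chrom[ci], " genes exceed chromosome ",
           "length ", config$chromosome_length)
  }
  annotation(unname(loci))
}

# shift one tested (non-terminal, or terminal for monoexonic) boundary of
# an exon chain by `shift` nt, keeping the chain valid
.shift_boundary <- function(exons, shift) {
  n <- nrow(exons)
  # candidate boundaries: (row, side); termini excluded unless monoexonic
  cand <- list()
  if (n == 1L) {
    cand <- list(c(1L, 1L), c(1L, 2L))
  } else {
    for (j in seq_len(n)) {
      if (j > 1L) cand[[length(cand) + 1L]] <- c(j, 1L)  # start
      if (j < n) cand[[length(cand) + 1L]] <- c(j, 2L)   # end
    }
  }
  pick <- cand[[sample.int(length(cand), 1L)]]
  j <- pick[1L]; side <- pick[2L]
  dir <- sample(c(-1L, 1L), 1L)
  for (try_dir in c(dir, -dir)) {
    e2 <- exons
    if (side == 1L) e2$start[j] <- e2$start[j] + try_dir * shift
    else e2$end[j] <- e2$end[j] + try_dir * shift
    ok <- all(e2$end >= e2$start) &&
      (nrow(e2) == 1L || all(e2$start[-1L] - e2$end[-nrow(e2)] >= 2L))
    if (ok) return(e2)
  }
  stop("could not place boundary shift of ", shift, " nt")
}

#' Simulate query transcripts with planted novelty classes
#'
#' Known copies jitter tested boundaries by at most `tolerance - 2` nt
#' (`tolerance - 1` in boundary-test mode); novel shifts move a single
#' tested boundary by at least `tolerance + 1` nt (exactly `tolerance` in
#' boundary-test mode); exon-count variants drop or append an exon; new
#' genes are placed in intergenic gaps or antisense over reference genes.
#'
#' @param ann Reference [annotation()] from [simulate_reference()].
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List with `queries` (list of [transcript_model()]) and `truth`
#'   (data.frame `transcript_id`, `planted_class`, `source_gene`).
#' @export
simulate_queries <- function(ann, config = simulation_config(), seed = 1L) {
  set.seed(seed + 1L)
  genes <- names(ann$loci)
  tol <- config$boundary_tolerance_nt
  queries <- list(); truth <- list()
  qi <- 0L
  add <- function(tx, class, src) {
    qi <<- qi + 1L
    queries[[qi]] <<- tx
    truth[[qi]] <<- data.frame(transcript_id = tx$transcript_id,
                               planted_class = class, source_gene = src,
                               stringsAsFactors = FALSE)
  }
  pick_gene <- function(n) sample(genes, n, replace = n > length(genes))

  for (g in pick_gene(config$n_known)) {
    ref <- ann$loci[[g]]$transcripts[[1L]]
    shift <- if (config$boundary_test_mode) tol - 1L
             else sample.int(max(1L, tol - 2L), 1L) - 1L  # 0 .. tol-2
    ex <- if (shift > 0L) .shift_boundary(ref$exons, shift) else ref$exons
    add(transcript_model(sprintf("Q%04d", qi + 1L), ref$chrom, ref$strand,
                         ex$start, ex$end), "known", g)
  }
  for (g in pick_gene(config$n_novel_shift)) {
    ref <- ann$loci[[g]]$transcripts[[1L]]
    shift <- if (config$boundary_test_mode) tol
             else tol + sample.int(10L, 1L)  # tol+1 .. tol+10
    ex <- .shift_boundary(ref$exons, shift)
    add(transcript_model(sprintf("Q%04d", qi + 1L), ref$chrom, ref$strand,
                         ex$start, ex$end), "novel_shift", g)
  }
  for (g in pick_gene(config$n_novel_exoncount)) {
    ref <- ann$loci[[g]]$transcripts[[1L]]
    ex <- ref$exons
    if (nrow(ex) >= 2L) {
      ex <- ex[-nrow(ex), , drop = FALSE]
    } else {
      ex <- rbind(ex, data.frame(start = ex$end[nrow(ex)] + 61L,
                                 end = ex$end[nrow(ex)] + 160L))
    }
    add(transcript_model(sprintf("Q%04d", qi + 1L), ref$chrom, ref$strand,
                         ex$start, ex$end), "novel_exoncount", g)
  }
  # intergenic placements: the midpoint of the gap after a sampled gene
  if (config$n_new_intergenic > 0L) {
    for (g in pick_gene(config$n_new_intergenic)) {
      locus <- ann$loci[[g]]
      sp <- locus_span(locus)
      # place beyond the locus end, within the guaranteed minimum gap
      margin <- config$intergenic_gap[1L]
      s <- sp[2L] + margin %/% 3L
      e <- s + min(200L, margin %/% 3L) - 1L
      add(transcript_model(sprintf("Q%04d", qi + 1L), locus$chrom,
                           sample(c("+", "-"), 1L), s, e),
          "new_intergenic", NA_character_)
    }
  }
  for (g in pick_gene(config$n_new_antisense)) {
    ref <- ann$loci[[g]]$transcripts[[1L]]
    add(transcript_model(sprintf("Q%04d", qi + 1L), ref$chrom,
                         if (ref$strand == "+") "-" else "+",
                         ref$exons$start, ref$exons$end),
        "new_antisense", g)
  }
  list(queries = queries, truth = do.call(rbind, c(truth, list(
    data.frame(transcript_id = character(0), planted_class = character(0),
               source_gene = character(0))))))
}

#' Simulate lncRNA placements for each positional class
#'
#' Plants candidate transcripts whose positional class relative to the
#' protein-coding reference is known by construction: intergenic
#' (lincRNA), antisense over coding exons, inside one intron on the same
#' strand (sense intronic), and same-strand exon-overlapping
#' (sense overlapping).
#'
#' @param ann Reference [annotation()] (protein-coding, from
#'   [simulate_reference()]).
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List with `transcripts` and `truth` (data.frame
#'   `transcript_id`, `planted_class`, `host_gene`).
#' @export
simulate_lncrna_placements <- function(ann, config = simulation_config(),
                                       seed = 1L) {
  set.seed(seed + 2L)
  n <- config$lncrna_per_class
  genes <- names(ann$loci)
  multi <- genes[vapply(ann$loci, function(l)
    nrow(l$transcripts[[1L]]$exons) >= 2L, logical(1))]
  if (!length(multi))
    stop("need multiexonic reference genes for intronic placements")
  out <- list(); truth <- list(); li <- 0L
  add <- function(tx, class, host) {
    li <<- li + 1L
    out[[li]] <<- tx
    truth[[li]] <<- data.frame(transcript_id = tx$transcript_id,
                               planted_class = class, host_gene = host,
                               stringsAsFactors = FALSE)
  }
  margin <- config$intergenic_gap[1L]
  for (g in sample(genes, n, replace = n > length(genes))) {
    sp <- locus_span(ann$loci[[g]])
    s <- sp[2L] + margin %/% 3L
    add(transcript_model(sprintf("L%04d", li + 1L), ann$loci[[g]]$chrom,
                         sample(c("+", "-"), 1L), s, s + 150L),
        "lincRNA", NA_character_)
  }
  for (g in sample(genes, n, replace = n > length(genes))) {
    ref <- ann$loci[[g]]$transcripts[[1L]]
    e1 <- ref$exons[1L, ]
    add(transcript_model(sprintf("L%04d", li + 1L), ref$chrom,
                         if (ref$strand == "+") "-" else "+",
                         e1$start, e1$end),
        "antisense", g)
  }
  for (g in sample(multi, n, replace = n > length(multi))) {
    ref <- ann$loci[[g]]$transcripts[[1L]]
    intr <- transcript_introns(ref)
    j <- which.max(intr$end - intr$start)
    s <- intr$start[j] + 5L
    e <- min(intr$end[j] - 5L, s + 120L)
    add(transcript_model(sprintf("L%04d", li + 1L), ref$chrom, ref$strand,
                         s, e),
        "sense_intronic", g)
  }
  for (g in sample(multi, n, replace = n > length(multi))) {
    ref <- ann$loci[[g]]$transcripts[[1L]]
    e1 <- ref$exons[1L, ]
    # overlap the first exon and run into the first intron
    s <- e1$start + 5L
    e <- min(e1$end + 30L, transcript_span(ref)[2L])
    add(transcript_model(sprintf("L%04d", li + 1L), ref$chrom, ref$strand,
                         s, e),
        "sense_overlapping", g)
  }
  list(transcripts = out, truth = do.call(rbind, truth))
}

.fpkm_from_counts <- function(counts, lengths, library_sizes) {
  sweep(counts * 1e9 / lengths, 2L, library_sizes, "/")
}

#' Simulate an expression design with planted differential effects
#'
#' Per-gene baselines are log-normal; counts are negative-binomial around
#' the (possibly fold-changed) baseline. FPKM is derived as
#' `count * 1e9 / (length * library_size)` with library sizes equal to the
#' column sums.
#'
#' With `design = "tissues"`, planted tissue-specific genes get a linear
#' fold change of `specific_fc` in the focal tissue relative to every
#' other tissue. With `design = "colors"`, planted DEGs get a `2 ^
#' color_log2fc` fold change in one randomly chosen color group.
#'
#' @param ann [annotation()] supplying gene ids and transcript lengths.
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @param design `"tissues"` or `"colors"`.
#' @return List with `counts` and `fpkm` ([expression_matrix()]s), `truth`
#'   (data.frame `gene_id`, `status`, `effect_group`), `groups` (named
#'   list of sample columns per condition).
#' @export
simulate_expression <- function(ann, config = simulation_config(), seed = 1L,
                                design = c("tissues", "colors")) {
  design <- match.arg(design)
  set.seed(seed + 3L)
  genes <- names(ann$loci)
  lens <- vapply(ann$loci, function(l)
    transcript_exonic_length(l$transcripts[[1L]]), integer(1))
  if (design == "tissues") {
    conditions <- config$tissues
    reps <- config$replicates
    n_planted <- min(config$n_specific, length(genes))
    fc <- config$specific_fc
    focal <- config$focal_tissue
  } else {
    conditions <- config$color_groups
    reps <- config$color_replicates
    n_planted <- min(config$n_color_degs, length(genes))
    fc <- 2^config$color_log2fc
    focal <- NULL
  }
  samples <- as.vector(vapply(conditions, function(cd)
    sprintf("%s_%d", cd, seq_len(reps)), character(reps)))
  group_of <- rep(conditions, each = reps)
  groups <- split(samples, factor(group_of, levels = conditions))

  base <- stats::rlnorm(length(genes), config$baseline_meanlog,
                        config$baseline_sdlog)
  planted <- sample(genes, n_planted)
  effect_group <- stats::setNames(rep(NA_character_, length(genes)), genes)
  if (design == "tissues") {
    effect_group[planted] <- focal
  } else if (n_planted) {
    effect_group[planted] <- sample(conditions, n_planted, replace = TRUE)
  }
  mu <- matrix(base, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  for (g in planted)
    mu[g, group_of == effect_group[[g]]] <-
      mu[g, group_of == effect_group[[g]]] * fc
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  fpkm <- .fpkm_from_counts(counts, lens, lib)
  truth <- data.frame(gene_id = genes,
                      status = ifelse(genes %in% planted, "DE", "null"),
                      effect_group = unname(effect_group),
                      stringsAsFactors = FALSE)
  list(counts = expression_matrix(counts, "count", library_sizes = lib),
       fpkm = expression_matrix(fpkm, "FPKM"),
       truth = truth, groups = groups)
}

#' Simulate ohnolog pairs with a planted L-subgenome bias
#'
#' S-gene FPKM is log-normal per gene and tissue; the paired L gene is the
#' S value times `ohnolog_bias` times log-normal noise. L genes also carry
#' `ohnolog_extra_isoforms_l` extra isoforms; isoform FPKM splits the gene
#' FPKM by normalized gamma weights.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List with `pairs` (data.frame `l_gene`, `s_gene`),
#'   `gene_matrix` (FPKM [expression_matrix()], genes x tissues),
#'   `isoform_matrix`, `isoform_map` (data.frame `isoform_id`,
#'   `gene_id`) and `truth` (the bias used).
#' @export
simulate_ohnologs <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed + 4L)
  n <- config$n_ohnolog_pairs
  if (n < 1L) stop("n_ohnolog_pairs must be >= 1")
  tissues <- config$tissues
  lg <- sprintf("L%05d", seq_len(n)); sg <- sprintf("S%05d", seq_len(n))
  base <- stats::rlnorm(n, meanlog = 6, sdlog = 0.8)
  tfac <- matrix(stats::rlnorm(n * length(tissues), 0, 0.5), nrow = n)
  # independent, symmetric noise on both subgenomes so a bias of 1 is an
  # exact expression null for the paired log-ratio
  noise_l <- matrix(stats::rlnorm(n * length(tissues), 0,
                                  config$ohnolog_noise_sdlog), nrow = n)
  noise_s <- matrix(stats::rlnorm(n * length(tissues), 0,
                                  config$ohnolog_noise_sdlog), nrow = n)
  s_m <- base * tfac * noise_s
  l_m <- base * tfac * config$ohnolog_bias * noise_l
  gm <- rbind(l_m, s_m)
  dimnames(gm) <- list(c(lg, sg), tissues)

  n_iso_s <- stats::rpois(n, 1.5) + 1L
  n_iso_l <- n_iso_s + config$ohnolog_extra_isoforms_l
  gene_ids <- c(lg, sg)
  n_iso <- c(n_iso_l, n_iso_s)
  isoform_map <- data.frame(
    isoform_id = unlist(lapply(seq_along(gene_ids), function(i)
      sprintf("%s.i%d", gene_ids[i], seq_len(n_iso[i])))),
    gene_id = rep(gene_ids, n_iso), stringsAsFactors = FALSE)
  im <- matrix(0, nrow = nrow(isoform_map), ncol = length(tissues),
               dimnames = list(isoform_map$isoform_id, tissues))
  row0 <- 0L
  for (i in seq_along(gene_ids)) {
    k <- n_iso[i]
    w <- matrix(stats::rgamma(k * length(tissues), shape = 1), nrow = k)
    w <- sweep(w, 2L, colSums(w), "/")
    im[row0 + seq_len(k), ] <- sweep(w, 2L, gm[gene_ids[i], ], "*")
    row0 <- row0 + k
  }
  list(pairs = data.frame(l_gene = lg, s_gene = sg, stringsAsFactors = FALSE),
       gene_matrix = expression_matrix(gm, "FPKM"),
       isoform_matrix = expression_matrix(im, "FPKM"),
       isoform_map = isoform_map,
       truth = list(bias = config$ohnolog_bias,
                    extra_isoforms_l = config$ohnolog_extra_isoforms_l))
}
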