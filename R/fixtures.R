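# Deterministic toy genomes with planted ground truth.
#
# A fixture genome is a set of multi-exon genes on one chromosome.
# Panhandles are planted by writing a duplex sequence and its
# (loop-perturbed) base-paired partner into two intronic "conserved"
# islands of the same gene. The nucleotides adjacent to each planted
# region (and inside planted loops) are set to A on both strands so that
# the planted duplex cannot be extended by chance complementarity in the
# flanks; recovery is therefore exact unless an unrelated stronger
# complementarity overlaps the plant.

#' Specification of a synthetic fixture genome
#'
#' @param n_genes number of genes.
#' @param gene_length 2-vector, gene length range in nucleotides.
#' @param n_exons 2-vector, exons per gene.
#' @param exon_length 2-vector, exon length range.
#' @param n_plants number of planted panhandles.
#' @param plant_dg 2-vector, target free-energy range (kcal/mol) of
#'   plants.
#' @param plant_spread 2-vector, genomic inner-gap range between the two
#'   planted regions.
#' @param loop_prob probability that a plant carries one internal
#'   loop/bulge.
#' @param island_pad 2-vector, range of island padding around each
#'   planted region (nucleotides).
#' @param n_decoys shuffled decoy islands per gene.
#' @param gc background GC fraction.
#' @param minus_prob probability a gene is on the minus strand.
#' @param seed mandatory random seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 50L, gene_length = c(4000L, 9000L),
                         n_exons = c(2L, 4L), exon_length = c(80L, 150L),
                         n_plants = 120L, plant_dg = c(-40, -15),
                         plant_spread = c(100L, 6000L), loop_prob = 0.3,
                         island_pad = c(8L, 15L), n_decoys = 1L,
                         gc = 0.5, minus_prob = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory for fixture generation")
  stopifnot(gene_length[1] <= gene_length[2], plant_dg[1] <= plant_dg[2],
            plant_dg[2] <= -15, n_exons[1] >= 2)
  structure(as.list(environment()), class = "fixture_spec")
}

.sample_nt <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# grow one duplex for planting; returns top (5'->3'), bottom (3'->5',
# aligned), base pairs, loop description, and the summed energy
.grow_plant <- function(target, k, m, loop_prob, gc, max_tries = 50) {
  pair_pool <- list(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L),
                    c(3L, 4L), c(4L, 3L))  # AU UA CG GC GU UG
  w_pair <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2, 0.05, 0.05)
  SM <- .stack_matrix()
  for (try in seq_len(max_tries)) {
    top <- integer(0); bot <- integer(0)
    loop_at <- NULL; loop_ab <- NULL
    e <- 0; helix_len <- 0; last_wobbles <- integer(0)
    want_loop <- stats::runif(1) < loop_prob
    repeat {
      pick <- pair_pool[[sample.int(6, 1, prob = w_pair)]]
      wob <- pick[1] %in% c(3L, 4L) && pick[2] %in% c(3L, 4L)
      # at most one wobble per k-window
      if (wob && length(last_wobbles) > 0 &&
          length(top) + 1 - max(last_wobbles) < k) next
      if (helix_len > 0) {
        dt <- (top[length(top)] - 1) * 4 + pick[1]
        db <- (bot[length(bot)] - 1) * 4 + pick[2]
        e <- e + SM[dt, db]
      }
      top <- c(top, pick[1]); bot <- c(bot, pick[2])
      helix_len <- helix_len + 1
      if (wob) last_wobbles <- c(last_wobbles, length(top))
      if (want_loop && is.null(loop_at) && helix_len >= k &&
          e > target / 2) {
        # plant only internal loops with >= 1 nt on each strand: under
        # the bundled penalties a bulge can be undercut by widening it
        # into an internal loop at the cost of one weak pair, so bulge
        # plants would not always be the grammar optimum
        ab <- c(sample(1:m, 1), sample(1:m, 1))
        loop_at <- length(top); loop_ab <- ab
        e <- e + loop_penalty(ab[1], ab[2], m)
        helix_len <- 0
      }
      n <- length(top)
      span1 <- n + if (!is.null(loop_at)) loop_ab[1] else 0
      span2 <- n + if (!is.null(loop_at)) loop_ab[2] else 0
      done <- e <= target && helix_len >= k && span1 >= 10 && span2 >= 10 &&
        (is.null(loop_at) || loop_at >= k)
      if (done) break
      if (n > 60) break
    }
    if (e <= target && helix_len >= k && length(top) <= 60) {
      return(list(top = top, bot = bot, loop_at = loop_at,
                  loop_ab = loop_ab, energy = e))
    }
  }
  stop("could not grow a plant for target ", target)
}

# expand a grown plant into region sequences (sense strands) + local bp
.plant_regions <- function(pl) {
  n <- length(pl$top)
  if (is.null(pl$loop_at)) {
    s1 <- pl$top
    s2r <- pl$bot
    i <- seq_len(n); jr <- seq_len(n)
  } else {
    a <- pl$loop_ab[1]; b <- pl$loop_ab[2]
    s1 <- append(pl$top, rep(1L, a), after = pl$loop_at)
    s2r <- append(pl$bot, rep(1L, b), after = pl$loop_at)
    i <- c(seq_len(pl$loop_at), pl$loop_at + a + seq_len(n - pl$loop_at))
    jr <- c(seq_len(pl$loop_at), pl$loop_at + b + seq_len(n - pl$loop_at))
  }
  # sense sequence of region 2 is the reversed bottom strand
  j <- length(s2r) - jr + 1L
  list(seq1 = s1, seq2 = rev(s2r), bp = cbind(i = i, j = j))
}

.codes_to_dna <- function(codes) {
  paste(c("A", "C", "G", "T")[codes], collapse = "")
}

.revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)[[1]]))
}

#' Generate a toy genome with planted panhandles
#'
#' Builds random protein-coding genes (exon/intron structure) on one
#' chromosome, plants `n_plants` duplexes into pairs of intronic
#' conserved islands, adds shuffled decoy islands, and records the exact
#' ground truth (coordinates, base pairs, oracle free energy). Output is
#' byte-identical for a fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @return list with `genome` (DNAStringSet), `genes`, `exons`,
#'   `conserved` (GRanges), and `truth` (data.frame: gene, strand,
#'   genomic CCR intervals, oracle dG, structure string as in the
#'   catalog).
#' @export
make_toy_genome <- function(spec) {
  set.seed(spec$seed)
  k <- 5L; m <- 2L
  gap_between_genes <- 500L
  gene_lens <- sample(spec$gene_length[1]:spec$gene_length[2],
                      spec$n_genes, replace = TRUE)
  starts <- cumsum(c(1000L, head(gene_lens, -1) + gap_between_genes))
  chrom_len <- starts[spec$n_genes] + gene_lens[spec$n_genes] + 1000L
  chrom <- .sample_nt(chrom_len, spec$gc)

  genes <- GRanges("chrT", IRanges(starts, width = gene_lens),
                   strand = ifelse(stats::runif(spec$n_genes) < spec$minus_prob,
                                   "-", "+"))
  genes$gene_id <- sprintf("G%03d", seq_len(spec$n_genes))
  genes$biotype <- "protein_coding"

  exons <- GRanges(); introns_by_gene <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    ne <- sample(spec$n_exons[1]:spec$n_exons[2], 1)
    elen <- sample(spec$exon_length[1]:spec$exon_length[2], ne,
                   replace = TRUE)
    gs <- start(genes)[g]; ge <- end(genes)[g]
    # first exon at the gene start, last at the end, middle ones spread
    anchors <- round(seq(gs, ge - elen[ne] + 1, length.out = ne))
    es <- anchors; ee <- pmin(anchors + elen - 1, ge)
    exg <- GRanges("chrT", IRanges(es, ee), strand = strand(genes)[g])
    exg$gene_id <- genes$gene_id[g]
    exg$biotype <- "protein_coding"
    exons <- c(exons, exg)
    introns_by_gene[[g]] <- GRanges("chrT",
                                    IRanges(ee[-ne] + 1, es[-1] - 1),
                                    strand = strand(genes)[g])
  }

  used <- GRanges()   # islands already placed
  conserved <- GRanges()
  truth <- list()
  planted <- 0; attempts <- 0
  while (planted < spec$n_plants) {
    attempts <- attempts + 1
    if (attempts > spec$n_plants * 60)
      stop("could not place all plants; spec infeasible")
    g <- sample(spec$n_genes, 1)
    introns <- introns_by_gene[[g]]
    introns <- introns[width(introns) > 120]
    if (length(introns) < 1) next
    target <- stats::runif(1, spec$plant_dg[1] + 3.5, spec$plant_dg[2] - 0.5)
    pl <- tryCatch(.grow_plant(target, k, m, spec$loop_prob, spec$gc),
                   error = function(e) NULL)
    if (is.null(pl)) next
    reg <- .plant_regions(pl)
    n1 <- length(reg$seq1); n2 <- length(reg$seq2)
    pad <- spec$island_pad
    guard <- 7L  # A-run so flanks cannot extend or re-seed the duplex
    il1 <- n1 + 2 * (guard + sample(pad[1]:pad[2], 1))
    il2 <- n2 + 2 * (guard + sample(pad[1]:pad[2], 1))

    # choose two intron slots with the requested genomic spread
    slot <- .place_two_islands(introns, il1, il2, spec$plant_spread, used)
    if (is.null(slot)) next
    strand_g <- as.character(strand(genes))[g]
    islA <- slot$isl1; islB <- slot$isl2  # genomic left, right

    # island content is built in sense space (A-guards flanking the
    # plant, random padding outside) and reverse-complemented as a whole
    # for minus-strand genes
    place <- function(isl, seq_codes) {
      w <- width(isl)
      n <- length(seq_codes)
      off <- guard + 1L + sample(0:(w - n - 2L * guard), 1)
      s <- .sample_nt(w, spec$gc)
      s[(off - guard):(off - 1)] <- "A"
      s[(off + n):(off + n + guard - 1)] <- "A"
      s[off:(off + n - 1)] <- strsplit(.codes_to_dna(seq_codes), "")[[1]]
      sense_txt <- paste(s, collapse = "")
      plus_txt <- if (strand_g == "+") sense_txt else .revcomp_chr(sense_txt)
      if (strand_g == "+") {
        gstart <- start(isl) + off - 1L; gend <- gstart + n - 1L
      } else {
        gend <- end(isl) - off + 1L; gstart <- gend - n + 1L
      }
      list(plus = strsplit(plus_txt, "")[[1]], gstart = gstart, gend = gend)
    }
    lift_local <- function(p, t) {
      if (strand_g == "+") p$gstart + t - 1L else p$gend - t + 1L
    }
    # region 1 is transcription-upstream: left island on +, right on -
    isl_r1 <- if (strand_g == "+") islA else islB
    isl_r2 <- if (strand_g == "+") islB else islA
    p1 <- place(isl_r1, reg$seq1)
    p2 <- place(isl_r2, reg$seq2)
    chrom[start(isl_r1):end(isl_r1)] <- p1$plus
    chrom[start(isl_r2):end(isl_r2)] <- p2$plus

    # genomic base pairs
    bp_r1 <- lift_local(p1, reg$bp[, "i"])
    bp_r2 <- lift_local(p2, reg$bp[, "j"])
    left_bp <- pmin(bp_r1, bp_r2); right_bp <- pmax(bp_r1, bp_r2)
    ordp <- order(left_bp)
    oracle <- duplex_energy(reg$bp, .codes_to_rna(reg$seq1),
                            .codes_to_rna(reg$seq2), k = k, m = m)
    stopifnot(abs(oracle - pl$energy) < 1e-9)

    pL <- if (p1$gstart <= p2$gstart) p1 else p2
    pR <- if (p1$gstart <= p2$gstart) p2 else p1
    truth[[planted + 1]] <- data.frame(
      gene_id = genes$gene_id[g], strand = strand_g,
      start1 = pL$gstart, end1 = pL$gend,
      start2 = pR$gstart, end2 = pR$gend,
      dG = oracle, n_bp = nrow(reg$bp),
      structure = paste(left_bp[ordp], right_bp[ordp], sep = ":",
                        collapse = ","),
      stringsAsFactors = FALSE)
    used <- c(used, granges(islA), granges(islB))
    ciA <- granges(islA); ciA$gene_id <- genes$gene_id[g]
    ciB <- granges(islB); ciB$gene_id <- genes$gene_id[g]
    conserved <- c(conserved, ciA, ciB)
    planted <- planted + 1
  }

  # shuffled decoy islands
  for (g in seq_len(spec$n_genes)) {
    for (d in seq_len(spec$n_decoys)) {
      introns <- introns_by_gene[[g]]
      introns <- introns[width(introns) > 120]
      if (length(introns) == 0) next
      w <- sample(30:60, 1)
      slot <- .free_slot(introns[sample(length(introns), 1)], w, used)
      if (is.null(slot)) next
      chrom[start(slot):end(slot)] <- sample(chrom[start(slot):end(slot)])
      slot$gene_id <- genes$gene_id[g]
      conserved <- c(conserved, slot)
      used <- c(used, granges(slot))
    }
  }

  genome <- DNAStringSet(paste(chrom, collapse = ""))
  names(genome) <- "chrT"
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame()
  list(genome = genome, genes = genes, exons = exons,
       conserved = sort(conserved, ignore.strand = TRUE), truth = truth_df,
       spec = spec)
}

.encode_dna <- function(x) .encode(x)

.codes_to_rna <- function(codes) {
  paste(c("A", "C", "G", "U")[codes], collapse = "")
}

# find positions for two islands with an inner gap in `spread_range`
.place_two_islands <- function(introns, w1, w2, spread_range, used) {
  for (try in 1:20) {
    i1 <- sample(length(introns), 1)
    isl1 <- .free_slot(introns[i1], w1, used)
    if (is.null(isl1)) next
    lo <- spread_range[1]; hi <- spread_range[2]
    cand <- introns[end(introns) >= start(isl1)]
    for (i2 in sample(seq_along(cand))) {
      isl2 <- .free_slot(cand[i2], w2, c(used, granges(isl1)))
      if (is.null(isl2)) next
      gap <- start(isl2) - end(isl1) - 1L
      if (is.na(gap) || gap < lo || gap > hi) next
      return(list(isl1 = isl1, isl2 = isl2))
    }
  }
  NULL
}

# a random sub-interval of `intron` of width w not overlapping `used`
.free_slot <- function(intron, w, used) {
  if (width(intron) < w + 2) return(NULL)
  for (try in 1:15) {
    s <- start(intron) + sample(0:(width(intron) - w), 1)
    cand <- GRanges(seqnames(intron), IRanges(s, s + w - 1L),
                    strand = strand(intron))
    if (length(used) == 0 ||
        !any(overlapsAny(cand, used, ignore.strand = TRUE)))
      return(cand)
  }
  NULL
}

#' Write a fixture to standard-format files
#'
#' @param fix result of [make_toy_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (fasta, gtf, conserved bed,
#'   truth tsv).
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  writeXStringSet(fix$genome, fa)
  gtf <- file.path(dir, "genes.gtf")
  .write_gtf(fix$genes, fix$exons, gtf)
  bed <- file.path(dir, "conserved.bed")
  df <- data.frame(as.character(seqnames(fix$conserved)),
                   start(fix$conserved) - 1L, end(fix$conserved),
                   fix$conserved$gene_id, 0L,
                   as.character(strand(fix$conserved)))
  write.table(df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  truth <- file.path(dir, "truth.tsv")
  write.table(fix$truth, truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, gtf = gtf, conserved = bed, truth = truth))
}

.write_gtf <- function(genes, exons, path) {
  fmt <- function(gr, type) {
    sprintf(paste0("chrT\ttoy\t%s\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; gene_biotype \"%s\";"),
            type, start(gr), end(gr), as.character(strand(gr)),
            gr$gene_id, gr$biotype)
  }
  writeLines(c(fmt(genes, "gene"), fmt(exons, "exon")), path)
}
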