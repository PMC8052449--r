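# Toy feature tracks with known statistical structure, generated over a
# fixture genome / catalog. Each generator is deterministic under its
# seed.

#' Plant SNVs on PCCR base pairs
#'
#' `n_comp` randomly chosen base pairs receive qualifying SNVs on both
#' sides whose alternative alleles restore an admissible pair
#' (compensatory); `n_single` further pairs receive a one-sided SNV.
#' Plus-strand alleles are derived from the sense alleles via the
#' record's strand.
#'
#' @param bp_tab base-pair table from [pccr_basepair_table()].
#' @param n_single,n_comp counts of planted single/compensatory events.
#' @param af carrier fraction given to planted SNVs (default 0.05).
#' @param seed random seed.
#' @return SNV data.frame (`chrom`, `pos`, `ref`, `alt`, `af`) plus
#'   attribute `comp_rows` (indices of compensatory pairs in `bp_tab`).
#' @export
toy_snvs <- function(bp_tab, n_single = 20L, n_comp = 3L, af = 0.05,
                     seed = NULL) {
  .check_seed(seed)
  # a compensatory re-pairing for each sense pair type
  swap <- list(AT = c("G", "C"), TA = c("C", "G"), CG = c("T", "A"),
               GC = c("A", "T"), GT = c("A", "T"), TG = c("T", "A"))
  elig <- which(bp_tab$pair_type %in% names(swap))
  pick <- sample(elig, min(n_comp + n_single, length(elig)))
  comp_rows <- pick[seq_len(min(n_comp, length(pick)))]
  single_rows <- setdiff(pick, comp_rows)
  to_plus <- function(nt, strand) {
    if (strand == "-") unname(.DNA_COMP[nt]) else nt
  }
  rows <- list()
  for (r in comp_rows) {
    alts <- swap[[bp_tab$pair_type[r]]]
    rows[[length(rows) + 1]] <- data.frame(
      chrom = bp_tab$chrom[r],
      pos = c(bp_tab$gpos1[r], bp_tab$gpos2[r]),
      ref = to_plus(c(bp_tab$sense1[r], bp_tab$sense2[r]),
                    bp_tab$strand[r]),
      alt = to_plus(alts, bp_tab$strand[r]),
      af = af, stringsAsFactors = FALSE)
  }
  for (r in single_rows) {
    alt_sense <- setdiff(c("A", "C", "G", "T"),
                         c(bp_tab$sense1[r],
                           swap[[bp_tab$pair_type[r]]][1]))[1]
    rows[[length(rows) + 1]] <- data.frame(
      chrom = bp_tab$chrom[r], pos = bp_tab$gpos1[r],
      ref = to_plus(bp_tab$sense1[r], bp_tab$strand[r]),
      alt = to_plus(alt_sense, bp_tab$strand[r]),
      af = af, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), af = numeric(0))
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  attr(out, "comp_rows") <- comp_rows
  out
}

#' Generate eCLIP-like peaks around CCRs
#'
#' `mode = "independent"`: a peak lands near the left and near the right
#' CCR independently with probability `p`. `mode = "forked"`: with
#' probability `p` the record gets peaks near both CCRs (otherwise
#' none). `mode = "on_ccr"`: a peak overlapping one CCR with
#' probability `p`.
#'
#' @param catalog catalog data.frame.
#' @param mode peak geometry.
#' @param p placement probability per record (default 0.3).
#' @param rbp RBP name stored in the peaks (default "RBP1").
#' @param peak_width peak width (default 30).
#' @param max_offset maximal distance of the peak start from the CCR
#'   boundary (default 20).
#' @param seed random seed.
#' @return GRanges with an `rbp` column.
#' @export
toy_peaks <- function(catalog, mode = c("independent", "forked", "on_ccr"),
                      p = 0.3, rbp = "RBP1", peak_width = 30L,
                      max_offset = 20L, seed = NULL) {
  mode <- match.arg(mode)
  .check_seed(seed)
  mk <- function(chrom, anchor_end) {
    s <- anchor_end + sample(1:max_offset, 1)
    GRanges(chrom, IRanges(s, width = peak_width))
  }
  out <- GRanges()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    left <- runif(1) < p; right <- runif(1) < p
    if (mode == "forked") { left <- right <- runif(1) < p }
    if (mode == "on_ccr") {
      if (runif(1) < p)
        out <- c(out, GRanges(rec$chrom,
                              IRanges(rec$start1 + 1,
                                      width = min(peak_width,
                                                  rec$end1 - rec$start1))))
      next
    }
    if (left) out <- c(out, mk(rec$chrom, rec$end1))
    if (right) out <- c(out, mk(rec$chrom, rec$end2))
  }
  if (length(out)) mcols(out)$rbp <- rbp else mcols(out)$rbp <- character(0)
  out
}

#' Generate A-to-I editing sites over CIR adenosines
#'
#' Each sense-strand adenosine within a CCR is made an editing site with
#' probability `p_in`; adenosines in the remaining CIR parts with
#' probability `p_out`.
#'
#' @param catalog catalog data.frame.
#' @param cirs GRanges of CIRs.
#' @param genome DNAStringSet or FASTA path.
#' @param p_in,p_out editing probabilities (defaults 0.3, 0.05).
#' @param seed random seed.
#' @return GRanges of editing site positions.
#' @export
toy_editing <- function(catalog, cirs, genome, p_in = 0.3, p_out = 0.05,
                        seed = NULL) {
  .check_seed(seed)
  genome <- .get_genome(genome)
  ccr <- reduce(c(GRanges(catalog$chrom,
                          IRanges(catalog$start1, catalog$end1),
                          strand = catalog$strand),
                  GRanges(catalog$chrom,
                          IRanges(catalog$start2, catalog$end2),
                          strand = catalog$strand)))
  pos <- integer(0); chroms <- character(0)
  for (i in seq_along(cirs)) {
    chrom <- as.character(seqnames(cirs))[i]
    st <- as.character(strand(cirs))[i]
    s <- .fetch_seq(genome, chrom, start(cirs)[i], end(cirs)[i], st)
    codes <- .encode(s)
    is_a <- which(codes == 1L)
    gpos <- if (st == "-") end(cirs)[i] - is_a + 1L else
      start(cirs)[i] + is_a - 1L
    inside <- overlapsAny(GRanges(chrom, IRanges(gpos, width = 1)), ccr,
                          ignore.strand = TRUE)
    prob <- ifelse(inside, p_in, p_out)
    take <- runif(length(gpos)) < prob
    pos <- c(pos, gpos[take]); chroms <- c(chroms, rep(chrom, sum(take)))
  }
  sort(GRanges(chroms, IRanges(pos, width = 1)))
}

#' Generate a reactivity track depressed within CCRs
#'
#' Baseline reactivity is uniform on (0.4, 0.9) over all CIR positions;
#' paired CCR nucleotides are lowered by `depression` per energy-group
#' index (group I..IV lowers by 1..4 times `depression`).
#'
#' @param catalog catalog data.frame.
#' @param cirs GRanges of CIRs.
#' @param depression per-group depression step (default 0.08).
#' @param seed random seed.
#' @return GRanges with `score`, one position per covered nucleotide.
#' @export
toy_reactivity <- function(catalog, cirs, depression = 0.08, seed = NULL) {
  .check_seed(seed)
  cov <- reduce(granges(cirs), ignore.strand = TRUE)
  pos <- unlist(lapply(seq_along(cov), function(i)
    start(cov)[i]:end(cov)[i]))
  chroms <- rep(as.character(seqnames(cov)), width(cov))
  score <- runif(length(pos), 0.4, 0.9)
  for (i in seq_len(nrow(catalog))) {
    bp <- catalog_basepairs(catalog[i, ])
    gi <- match(catalog$energy_group[i], c("I", "II", "III", "IV"))
    hit <- chroms == catalog$chrom[i] &
      pos %in% c(bp[, "left"], bp[, "right"])
    score[hit] <- pmax(score[hit] - gi * depression, 0.01)
  }
  gr <- GRanges(chroms, IRanges(pos, width = 1))
  gr$score <- score
  gr
}

#' Generate split-read junction quantifications for exons
#'
#' Inclusion rates are drawn from a two-component model: exons in
#' `looped_ids` center at `psi_looped`, the rest at `psi_free`; read
#' counts are Poisson with mean `depth`.
#'
#' @param exon_ids character vector.
#' @param looped_ids subset of `exon_ids`.
#' @param psi_looped,psi_free inclusion-rate centers (defaults 0.55,
#'   0.85).
#' @param depth mean total junction reads per exon (default 60).
#' @param noise sd of the per-exon inclusion rate (default 0.08).
#' @param seed random seed.
#' @return data.frame: `exon_id`, `inc`, `exc`, `psi`.
#' @export
toy_junctions <- function(exon_ids, looped_ids = character(0),
                          psi_looped = 0.55, psi_free = 0.85,
                          depth = 60L, noise = 0.08, seed = NULL) {
  .check_seed(seed)
  center <- ifelse(exon_ids %in% looped_ids, psi_looped, psi_free)
  true_psi <- pmin(pmax(center + stats::rnorm(length(center), 0, noise),
                        0.02), 0.98)
  total <- rpois(length(exon_ids), depth) + 10L
  inc <- rbinom(length(exon_ids), total, true_psi)
  exc_reads <- total - inc
  exc <- as.integer(round(exc_reads / 2))
  data.frame(exon_id = exon_ids, inc = inc, exc = exc,
             psi = psi(inc, exc), stringsAsFactors = FALSE)
}

#' Generate all toy tracks for a fixture
#'
#' Convenience wrapper producing SNVs (with planted compensatory
#' pairs), forked peaks, editing sites, a reactivity track and junction
#' counts over a scanned fixture, optionally writing them to standard
#' text formats (VCF, BED, bedGraph, TSV).
#'
#' @param fix fixture from [make_toy_genome()].
#' @param catalog catalog from [pccr_scan()] over the fixture.
#' @param cirs CIR GRanges used in the scan.
#' @param seed random seed.
#' @param dir output directory, or NULL to skip writing.
#' @return list of the generated objects (and written paths).
#' @export
make_toy_tracks <- function(fix, catalog, cirs, seed, dir = NULL) {
  set.seed(seed)
  bp_tab <- pccr_basepair_table(catalog, fix$genome)
  snvs <- toy_snvs(bp_tab, seed = seed + 1L)
  peaks <- toy_peaks(catalog, mode = "forked", p = 0.4, seed = seed + 2L)
  editing <- toy_editing(catalog, cirs, fix$genome, seed = seed + 3L)
  react <- toy_reactivity(catalog, cirs, seed = seed + 4L)
  exon_ids <- sprintf("E%04d", seq_along(fix$exons))
  looped <- exon_ids[overlapsAny(
    fix$exons,
    GRanges(catalog$chrom, IRanges(catalog$end1 + 1, catalog$start2 - 1)),
    type = "within", ignore.strand = TRUE)]
  juncs <- toy_junctions(exon_ids, looped, seed = seed + 5L)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_snv_vcf(snvs, file.path(dir, "snvs.vcf"))
    .write_bed3 <- function(gr, path, extra = NULL) {
      df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
      if (!is.null(extra)) df <- cbind(df, extra)
      write.table(df, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    .write_bed3(peaks, file.path(dir, "peaks.bed"), peaks$rbp)
    .write_bed3(editing, file.path(dir, "editing.bed"))
    bg <- data.frame(as.character(seqnames(react)), start(react) - 1L,
                     end(react), react$score)
    write.table(bg, file.path(dir, "reactivity.bedGraph"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(juncs, file.path(dir, "junctions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- dir
  }
  list(snvs = snvs, peaks = peaks, editing = editing,
       reactivity = react, junctions = juncs, looped_exons = looped,
       dir = paths)
}
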