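# Shared toy objects built in code. Sequences are DNA; the package
# transcribes internally.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

RC <- function(x) as.character(reverseComplement(DNAString(x)))

# a sequence pair carrying one perfect Watson-Crick duplex between
# A-guarded flanks; returns sequences and the expected base pairs
guarded_pair <- function(core = "GCCGATGGCAGC", flank = 25, seed = 1) {
  set.seed(seed)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  guard <- strrep("A", 7)
  s1 <- paste0(pad(flank), guard, core, guard, pad(flank))
  s2 <- paste0(pad(flank), guard, RC(core), guard, pad(flank))
  off1 <- flank + 7
  off2 <- flank + 7
  n <- nchar(core)
  bp <- cbind(i = off1 + 1:n, j = off2 + n:1)
  list(seq1 = s1, seq2 = s2, bp = bp, core = core)
}

# minimal synthetic catalog rows (no genome needed) for the statistical
# modules; structure strings pair left/right positions antiparallel
toy_catalog <- function(n = 5, chrom = "chrT", gene = "G001",
                        strand = "+", start = 1000, spread = 400,
                        len = 12, dG = -22, gap_between = 2000) {
  rows <- lapply(seq_len(n), function(i) {
    s1 <- start + (i - 1) * gap_between
    e1 <- s1 + len - 1
    s2 <- e1 + spread + 1
    e2 <- s2 + len - 1
    bp_left <- s1:e1
    bp_right <- e2:s2
    data.frame(gene_id = gene, chrom = chrom, strand = strand,
               start1 = s1, end1 = e1, start2 = s2, end2 = e2,
               dG = dG, length1 = len, length2 = len, length_avg = len,
               spread = spread, n_bp = len, gc = 0.5,
               structure = paste(bp_left, bp_right, sep = ":",
                                 collapse = ","),
               energy_group = pccr::assign_energy_group(dG),
               rel_pos = 0.5, id = sprintf("PCCR%06d", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# small cached fixture shared by several test files
.toy_env <- new.env()
small_fixture <- function() {
  if (is.null(.toy_env$fix)) {
    .toy_env$fix <- make_toy_genome(
      fixture_spec(n_genes = 6, n_plants = 10, seed = 101))
    .toy_env$cirs <- build_cirs(.toy_env$fix$genes, .toy_env$fix$exons,
                                .toy_env$fix$conserved)
    .toy_env$catalog <- pccr_scan(.toy_env$fix$genes, .toy_env$cirs,
                                  .toy_env$fix$genome)
  }
  list(fix = .toy_env$fix, cirs = .toy_env$cirs,
       catalog = .toy_env$catalog)
}
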