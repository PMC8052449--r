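# Population-polymorphism statistics on PCCR base pairs, covariation
# E-value aggregation, and Stockholm export.

#' Read biallelic SNVs from a VCF text file
#'
#' Minimal parser for plain-text VCF: keeps single-nucleotide records,
#' splits multi-allelic rows, and extracts the carrier (allele) fraction
#' from the `AF` INFO key.
#'
#' @param path VCF file (uncompressed).
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
read_snv_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      af = numeric(0)))
  f <- strsplit(ln, "\t")
  rows <- lapply(f, function(x) {
    alts <- strsplit(x[5], ",")[[1]]
    af <- sub(".*AF=([0-9.eE+,-]+).*", "\\1", x[8])
    afs <- suppressWarnings(as.numeric(strsplit(af, ",")[[1]]))
    afs <- rep_len(afs, length(alts))
    data.frame(chrom = x[1], pos = as.integer(x[2]), ref = x[4],
               alt = alts, af = afs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[nchar(out$ref) == 1 & nchar(out$alt) == 1, , drop = FALSE]
}

#' Write SNVs as a minimal VCF
#' @param snvs data.frame as returned by [read_snv_vcf()].
#' @param path output file.
#' @export
write_snv_vcf <- function(snvs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
                  snvs$chrom, snvs$pos, snvs$ref, snvs$alt, snvs$af)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' SNP density in CCRs versus background, one-tailed Poisson test
#'
#' Regions of each set are merged before length computation; the test
#' asks whether the per-nucleotide SNP density in CCRs is lower than in
#' the background.
#'
#' @param snvs SNV data.frame (`chrom`, `pos`).
#' @param ccr_regions,background_regions GRanges.
#' @return list: `density_ccr`, `density_bg`, `p_value`.
#' @export
snp_density_test <- function(snvs, ccr_regions, background_regions) {
  ccr <- reduce(granges(ccr_regions), ignore.strand = TRUE)
  bg <- reduce(granges(background_regions), ignore.strand = TRUE)
  len_ccr <- sum(width(ccr)); len_bg <- sum(width(bg))
  if (len_ccr == 0 || len_bg == 0) stop("zero-length region set")
  pos <- GRanges(snvs$chrom, IRanges(snvs$pos, width = 1))
  n_ccr <- sum(overlapsAny(pos, ccr, ignore.strand = TRUE))
  n_bg <- sum(overlapsAny(pos, bg, ignore.strand = TRUE))
  d_ccr <- n_ccr / len_ccr; d_bg <- n_bg / len_bg
  p <- if (n_bg == 0) 1 else
    poisson.test(n_ccr, len_ccr, r = d_bg, alternative = "less")$p.value
  list(density_ccr = d_ccr, density_bg = d_bg, p_value = p)
}

# -- base-pair level machinery ------------------------------------------

.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Expand a catalog into its base-pair table
#'
#' One row per base pair of each PCCR, with the genomic positions of the
#' two sides and the sense-strand nucleotides (DNA alphabet).
#'
#' @param catalog catalog data.frame.
#' @param genome DNAStringSet or FASTA path.
#' @return data.frame: `id`, `gene_id`, `chrom`, `strand`, `gpos1`,
#'   `gpos2` (genomic left/right), `sense1`, `sense2`, `pair_type`.
#' @export
pccr_basepair_table <- function(catalog, genome) {
  genome <- .get_genome(genome)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    rec <- catalog[i, ]
    bp <- catalog_basepairs(rec)
    plus1 <- strsplit(as.character(subseq(genome[[rec$chrom]], 1)), "")[[1]]
    g1 <- bp[, "left"]; g2 <- bp[, "right"]
    n1 <- plus1[g1]; n2 <- plus1[g2]
    if (rec$strand == "-") { n1 <- .DNA_COMP[n1]; n2 <- .DNA_COMP[n2] }
    data.frame(id = rec$id, gene_id = rec$gene_id, chrom = rec$chrom,
               strand = rec$strand, gpos1 = g1, gpos2 = g2,
               sense1 = unname(n1), sense2 = unname(n2),
               pair_type = paste0(n1, n2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# energy of a duplex with fixed base-pair topology: stacks only where
# both flanking pairs remain admissible; loop penalties unchanged
.fixed_topology_energy <- function(bp, s1, s2, m = 2L) {
  n <- nrow(bp)
  i <- bp[, 1]; j <- bp[, 2]
  ok <- mapply(function(a, b) !is.na(a) && !is.na(b) && b %in% .PARTNERS[[a]],
               s1[i], s2[j])
  SM <- .stack_matrix()
  e <- 0
  consec <- which(diff(i) == 1 & diff(j) == -1)
  for (t in consec) {
    if (ok[t] && ok[t + 1]) {
      st <- SM[(s1[i[t]] - 1) * 4 + s1[i[t] + 1],
               (s2[j[t]] - 1) * 4 + s2[j[t] - 1]]
      if (!is.na(st)) e <- e + st
    }
  }
  brk <- which(diff(i) != 1 | diff(j) != -1)
  for (t in brk) {
    a <- i[t + 1] - i[t] - 1; b <- j[t] - j[t + 1] - 1
    e <- e + loop_penalty(a, b, m = m)
  }
  e
}

#' Free-energy impact of an SNV on a PCCR, with a positional null
#'
#' The duplex energy is re-evaluated on the fixed structure with the
#' observed substitution introduced (a broken pair loses its adjacent
#' stacking terms), giving the actual energy change. The null
#' distribution applies the same ref-to-alt substitution at every other
#' paired position of the same CCR that carries the reference allele.
#'
#' @param record one catalog row.
#' @param snv_pos genomic position of the SNV (1-based).
#' @param ref,alt plus-strand alleles (single characters).
#' @param genome DNAStringSet or FASTA path.
#' @return NULL when the SNV does not fall on a paired position;
#'   otherwise list: `ddg`, `null` (numeric vector, possibly empty,
#'   flagged by `n_null`).
#' @export
snp_ddg <- function(record, snv_pos, ref, alt, genome) {
  genome <- .get_genome(genome)
  bp <- catalog_basepairs(record)
  on1 <- match(snv_pos, bp[, "left"])
  on2 <- match(snv_pos, bp[, "right"])
  if (is.na(on1) && is.na(on2)) return(NULL)
  side <- if (!is.na(on1)) 1L else 2L

  # sense-space sequences and local base pairs (region 1 = upstream CCR)
  st <- record$strand
  if (st == "+") {
    seqA <- .fetch_seq(genome, record$chrom, record$start1, record$end1, st)
    seqB <- .fetch_seq(genome, record$chrom, record$start2, record$end2, st)
    li <- bp[, "left"] - record$start1 + 1L
    lj <- bp[, "right"] - record$start2 + 1L
    local_of <- function(gpos, s) if (s == 1L) gpos - record$start1 + 1L
                                  else gpos - record$start2 + 1L
  } else {
    seqA <- .fetch_seq(genome, record$chrom, record$start2, record$end2, st)
    seqB <- .fetch_seq(genome, record$chrom, record$start1, record$end1, st)
    li <- record$end2 - bp[, "right"] + 1L
    lj <- record$end1 - bp[, "left"] + 1L
    local_of <- function(gpos, s) if (s == 1L) record$end2 - gpos + 1L
                                  else record$end1 - gpos + 1L
    side <- 3L - side  # left/right swap to region1/region2
  }
  lb <- cbind(li, lj)[order(li), , drop = FALSE]
  s1 <- .encode(seqA); s2 <- .encode(seqB)
  # sense alleles
  ref_s <- if (st == "+") toupper(ref) else .DNA_COMP[toupper(ref)]
  alt_s <- if (st == "+") toupper(alt) else .DNA_COMP[toupper(alt)]
  ref_c <- match(rna_norm(ref_s), NTS)
  alt_c <- match(rna_norm(alt_s), NTS)
  e0 <- .fixed_topology_energy(lb, s1, s2)

  gside <- if (!is.na(on1)) "left" else "right"
  loc <- local_of(snv_pos, side)
  apply_mut <- function(pos, s) {
    t1 <- s1; t2 <- s2
    if (s == 1L) t1[pos] <- alt_c else t2[pos] <- alt_c
    .fixed_topology_energy(lb, t1, t2)
  }
  seq_side <- if (side == 1L) s1 else s2
  if (is.na(seq_side[loc]) || seq_side[loc] != ref_c)
    warning("reference allele does not match the genome at ", snv_pos)
  ddg <- apply_mut(loc, side) - e0

  cand <- if (side == 1L) lb[, 1] else lb[, 2]
  cand <- setdiff(cand[!is.na(seq_side[cand]) & seq_side[cand] == ref_c], loc)
  null <- vapply(cand, function(p) apply_mut(p, side) - e0, 0)
  list(ddg = unname(ddg), null = unname(null), n_null = length(null))
}

#' Count base pairs carrying SNVs and compensatory SNV pairs
#'
#' A base pair is "touched" when at least one qualifying SNV (carrier
#' fraction >= `min_af`) falls on either of its positions; it is
#' compensatory when both positions carry qualifying alternative alleles
#' whose sense-strand combination is again an admissible (Watson-Crick
#' or wobble) pair. Same-haplotype co-occurrence is not required.
#'
#' @param bp_tab base-pair table from [pccr_basepair_table()].
#' @param snvs SNV data.frame (`chrom`, `pos`, `ref`, `alt`, `af`).
#' @param min_af carrier-fraction cutoff (default 0.01).
#' @return list: `n_bp_with_snp`, `n_compensatory`, `density`
#'   (compensatory per touched pair).
#' @export
compensatory_counts <- function(bp_tab, snvs, min_af = 0.01) {
  snvs <- snvs[snvs$af >= min_af, , drop = FALSE]
  if (nrow(snvs) == 0 || nrow(bp_tab) == 0)
    return(list(n_bp_with_snp = 0L, n_compensatory = 0L, density = NA_real_))
  key <- function(chrom, pos) paste(chrom, pos)
  snv_by_pos <- split(snvs, key(snvs$chrom, snvs$pos))
  k1 <- key(bp_tab$chrom, bp_tab$gpos1)
  k2 <- key(bp_tab$chrom, bp_tab$gpos2)
  has1 <- k1 %in% names(snv_by_pos)
  has2 <- k2 %in% names(snv_by_pos)
  touched <- has1 | has2
  comp <- logical(nrow(bp_tab))
  idx <- which(has1 & has2)
  for (r in idx) {
    a1 <- snv_by_pos[[k1[r]]]$alt
    a2 <- snv_by_pos[[k2[r]]]$alt
    if (bp_tab$strand[r] == "-") {
      a1 <- .DNA_COMP[a1]; a2 <- .DNA_COMP[a2]
    }
    for (x in a1) for (y in a2) {
      if (admissible_pair(x, y)) comp[r] <- TRUE
    }
  }
  n_t <- sum(touched); n_c <- sum(comp)
  list(n_bp_with_snp = n_t, n_compensatory = n_c,
       density = if (n_t == 0) NA_real_ else n_c / n_t)
}

#' Re-wire base-pair partners within matched groups
#'
#' Base pairs are grouped by sense pair type, chromosome, and the number
#' of qualifying SNVs touching the pair; within each group the right
#' partners are permuted uniformly at random (so two pairs A1-T1 and
#' A2-T2 become A1-T2 / A2-T1 with probability one half). Singleton
#' groups are unchanged. The pair-type multiset per group is preserved.
#'
#' @param bp_tab base-pair table from [pccr_basepair_table()].
#' @param snvs SNV data.frame used only for the donor-count stratum.
#' @param min_af carrier-fraction cutoff used for the stratum.
#' @param seed random seed.
#' @return the re-wired base-pair table.
#' @export
rewire_basepairs <- function(bp_tab, snvs, min_af = 0.01, seed = NULL) {
  .check_seed(seed)
  q <- snvs[snvs$af >= min_af, , drop = FALSE]
  key <- function(chrom, pos) paste(chrom, pos)
  qk <- key(q$chrom, q$pos)
  n_snv <- (key(bp_tab$chrom, bp_tab$gpos1) %in% qk) +
    (key(bp_tab$chrom, bp_tab$gpos2) %in% qk)
  grp <- paste(bp_tab$pair_type, bp_tab$chrom, n_snv)
  out <- bp_tab
  for (g in unique(grp)) {
    w <- which(grp == g)
    if (length(w) < 2) next
    perm <- sample(w)
    out$gpos2[w] <- bp_tab$gpos2[perm]
    out$sense2[w] <- bp_tab$sense2[perm]
  }
  out$pair_type <- paste0(out$sense1, out$sense2)
  out
}

#' Null distribution of compensatory counts by re-wiring
#'
#' @inheritParams rewire_basepairs
#' @param n number of re-wirings (default 100).
#' @return list: `observed` ([compensatory_counts()] of the real table),
#'   `null_counts` (compensatory counts per re-wiring), `p_value`
#'   (one-tailed Poisson test of the observed count against the null
#'   mean).
#' @export
compensatory_null <- function(bp_tab, snvs, min_af = 0.01, n = 100L,
                              seed = NULL) {
  .check_seed(seed)
  obs <- compensatory_counts(bp_tab, snvs, min_af)
  nulls <- vapply(seq_len(n), function(r) {
    compensatory_counts(rewire_basepairs(bp_tab, snvs, min_af), snvs,
                        min_af)$n_compensatory
  }, 0L)
  lambda <- mean(nulls)
  p <- if (lambda == 0) as.numeric(obs$n_compensatory == 0) else
    stats::ppois(obs$n_compensatory - 1L, lambda, lower.tail = FALSE)
  list(observed = obs, null_counts = nulls, p_value = p)
}

#' Aggregate per-base-pair covariation E values per PCCR
#'
#' The PCCR E value is the product of the E values of base pairs flagged
#' as having significant covariation (an empty product is 1).
#' Benjamini-Hochberg adjustment is applied across the PCCRs whose E
#' value is below 1.
#'
#' @param per_pair data.frame: `pccr_id`, `evalue`, `significant`
#'   (logical).
#' @return data.frame: `pccr_id`, `evalue`, `evalue_adj` (NA where the
#'   raw E value is >= 1).
#' @export
aggregate_evalues <- function(per_pair) {
  if (any(per_pair$evalue < 0)) stop("negative E value")
  ids <- unique(per_pair$pccr_id)
  ev <- vapply(ids, function(id) {
    x <- per_pair[per_pair$pccr_id == id & per_pair$significant, "evalue"]
    prod(x)
  }, 0)
  out <- data.frame(pccr_id = ids, evalue = ev, evalue_adj = NA_real_,
                    stringsAsFactors = FALSE)
  sub <- out$evalue < 1
  out$evalue_adj[sub] <- p.adjust(out$evalue[sub], method = "BH")
  out
}

#' Export a duplex alignment pair in Stockholm format
#'
#' The two alignment blocks (one per CCR) are joined through a spacer of
#' ten adenines; the consensus secondary structure line (`#=GC SS_cons`)
#' marks the duplex base pairs with angle brackets. Rows containing
#' indels (gap characters) are dropped first; the surviving taxa must be
#' identical between the blocks.
#'
#' @param msa_block1,msa_block2 named character vectors (taxon ->
#'   aligned sequence), equal widths within a block.
#' @param structure 2-column matrix of base pairs: column 1 = position in
#'   block 1, column 2 = position in block 2 (both 1-based).
#' @param path output file, or NULL to return the text.
#' @param min_rows minimal number of surviving rows (default 15).
#' @return character vector of Stockholm lines (invisibly when writing).
#' @export
export_stockholm <- function(msa_block1, msa_block2, structure,
                             path = NULL, min_rows = 15L) {
  drop_gaps <- function(block) {
    block[!grepl("[-.]", block)]
  }
  b1 <- drop_gaps(msa_block1); b2 <- drop_gaps(msa_block2)
  common <- intersect(names(b1), names(b2))
  only1 <- setdiff(names(b1), common); only2 <- setdiff(names(b2), common)
  if (length(only1) || length(only2))
    stop("taxa mismatch after dropping indel rows: ",
         paste(c(only1, only2), collapse = ", "))
  b1 <- b1[common]; b2 <- b2[common]
  if (length(common) < min_rows)
    stop("only ", length(common), " rows survive; need >= ", min_rows)
  w1 <- unique(nchar(b1)); w2 <- unique(nchar(b2))
  if (length(w1) != 1 || length(w2) != 1)
    stop("ragged alignment block")
  spacer <- strrep("A", 10)
  merged <- paste0(b1, spacer, b2)
  ss <- rep(".", w1 + 10 + w2)
  structure <- .as_bp_matrix(structure)
  ss[structure[, 1]] <- "<"
  ss[w1 + 10 + structure[, 2]] <- ">"
  nm <- format(c(common, "#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0",
             paste(nm[seq_along(common)], merged),
             paste(nm[length(nm)], paste(ss, collapse = "")),
             "//")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a Stockholm file written by [export_stockholm()]
#'
#' @param path_or_lines file path or character vector of lines.
#' @return list: `seqs` (named character vector), `ss_cons`.
#' @export
read_stockholm <- function(path_or_lines) {
  ln <- if (length(path_or_lines) == 1 && file.exists(path_or_lines))
    readLines(path_or_lines) else path_or_lines
  ln <- ln[nzchar(ln) & ln != "//" & !startsWith(ln, "# STOCKHOLM")]
  ss <- ln[startsWith(ln, "#=GC SS_cons")]
  seqs_ln <- ln[!startsWith(ln, "#")]
  parts <- regmatches(seqs_ln, regexpr("\\S+", seqs_ln))
  vals <- sub("^\\S+\\s+", "", seqs_ln)
  list(seqs = setNames(vals, parts),
       ss_cons = sub("^#=GC SS_cons\\s+", "", ss))
}
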