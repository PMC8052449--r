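# Genome-wide orchestration: scan all CIR pairs of each gene, lift hits to
# genomic coordinates, and annotate the resulting catalog of PCCRs.
#
# Catalog layout (one data.frame row per PCCR): (start1, end1) is the
# genomically left CCR and (start2, end2) the right one, 1-based closed;
# transcription order follows the strand. `spread` is the inner gap
# between the two CCRs in nucleotides; `structure` encodes the base pairs
# as "leftpos:rightpos" genomic position pairs.

#' Enumerate distance-eligible CIR pairs of one gene
#'
#' All unordered pairs (a CIR with itself included) whose genomic inner
#' gap does not exceed `L`.
#'
#' @param cirs GRanges of the CIRs of one gene, any order.
#' @param L maximal distance between CIRs in nucleotides (default 10000).
#' @return data.frame with columns `idx1`, `idx2` (indices into the
#'   sorted CIRs, `idx1 <= idx2`); attribute `order` gives the sort
#'   permutation used.
#' @export
enumerate_cir_pairs <- function(cirs, L = 10000L) {
  o <- order(start(cirs), end(cirs))
  s <- start(cirs)[o]; e <- end(cirs)[o]
  n <- length(cirs)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      gap <- s[j] - e[i] - 1L
      if (gap <= L) out[[length(out) + 1]] <- c(i, j)
    }
  }
  df <- if (length(out)) as.data.frame(do.call(rbind, out)) else
    data.frame(V1 = integer(0), V2 = integer(0))
  names(df) <- c("idx1", "idx2")
  attr(df, "order") <- o
  df
}

.get_genome <- function(genome) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (!is.null(names(genome)))
    names(genome) <- sub("\\s.*", "", names(genome))
  genome
}

.fetch_seq <- function(genome, chrom, start, end, strand) {
  s <- subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- reverseComplement(s)
  as.character(s)
}

#' Scan the CIR pairs of one gene for complementary region pairs
#'
#' Sense-strand sequences of each distance-eligible CIR pair are passed
#' to [find_duplexes()]; non-intersecting hits are lifted back to genomic
#' coordinates. For self-pairs (a CIR against itself) duplexes whose two
#' regions overlap in genomic space are discarded, and mirrored
#' duplicates are collapsed.
#'
#' @param gene GRanges scalar with `gene_id`.
#' @param cirs GRanges of the gene's CIRs.
#' @param genome DNAStringSet (or FASTA path).
#' @param table k-mer energy table (NULL builds the default).
#' @param params [search_params()].
#' @param L distance limit between CIRs (default 10000).
#' @return catalog data.frame (possibly 0 rows).
#' @export
scan_gene <- function(gene, cirs, genome, table = NULL,
                      params = search_params(), L = 10000L) {
  genome <- .get_genome(genome)
  if (is.null(table)) table <- build_kmer_table(params$k, params$max_gu)
  pairs <- enumerate_cir_pairs(cirs, L)
  o <- attr(pairs, "order")
  cirs <- cirs[o]
  strand_g <- as.character(strand(gene))
  chrom <- as.character(seqnames(gene))
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    cL <- cirs[pairs$idx1[r]]  # genomically left
    cR <- cirs[pairs$idx2[r]]
    self <- pairs$idx1[r] == pairs$idx2[r]
    # transcription order: upstream CIR first
    if (strand_g == "-") { up <- cR; down <- cL } else { up <- cL; down <- cR }
    seq_up <- .fetch_seq(genome, chrom, start(up), end(up), strand_g)
    seq_down <- .fetch_seq(genome, chrom, start(down), end(down), strand_g)
    hits <- find_duplexes(seq_up, seq_down, table, params)
    hits <- select_nonintersecting(hits)
    for (h in hits) {
      lift <- .lift_hit(h, up, down, strand_g)
      if (is.null(lift)) next  # genomic overlap (self-complementarity)
      gc <- .paired_gc(h, seq_up, seq_down)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gene$gene_id, chrom = chrom, strand = strand_g,
        start1 = lift$start1, end1 = lift$end1,
        start2 = lift$start2, end2 = lift$end2,
        dG = h$dG, length1 = lift$len1, length2 = lift$len2,
        length_avg = (lift$len1 + lift$len2) / 2,
        spread = lift$start2 - lift$end1 - 1L,
        n_bp = nrow(h$bp), gc = gc,
        structure = lift$structure,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(.empty_catalog())
  cat_df <- do.call(rbind, rows)
  # collapse duplicates (mirrored self-pair hits, overlapping CIR parents)
  key <- with(cat_df, paste(gene_id, start1, end1, start2, end2, structure))
  cat_df <- cat_df[!duplicated(key), , drop = FALSE]
  cat_df$energy_group <- assign_energy_group(cat_df$dG)
  cat_df$rel_pos <- vapply(seq_len(nrow(cat_df)), function(i) {
    relative_position(
      GRanges(cat_df$chrom[i],
              IRanges(cat_df$start1[i], cat_df$end2[i])), gene)
  }, 0)
  rownames(cat_df) <- NULL
  cat_df
}

.empty_catalog <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             strand = character(0), start1 = integer(0), end1 = integer(0),
             start2 = integer(0), end2 = integer(0), dG = numeric(0),
             length1 = integer(0), length2 = integer(0),
             length_avg = numeric(0), spread = integer(0),
             n_bp = integer(0), gc = numeric(0), structure = character(0),
             energy_group = character(0), rel_pos = numeric(0),
             id = character(0), stringsAsFactors = FALSE)
}

# map hit coordinates (1-based within the up/down CIR sense sequences)
# to genomic intervals; returns NULL when the two genomic regions overlap
.lift_hit <- function(h, up, down, strand_g) {
  if (strand_g == "+") {
    g1 <- c(start(up) + h$start1 - 1L, start(up) + h$end1 - 1L)
    g2 <- c(start(down) + h$start2 - 1L, start(down) + h$end2 - 1L)
    bp1 <- start(up) + h$bp[, "i"] - 1L
    bp2 <- start(down) + h$bp[, "j"] - 1L
  } else {
    g1 <- c(end(up) - h$end1 + 1L, end(up) - h$start1 + 1L)
    g2 <- c(end(down) - h$end2 + 1L, end(down) - h$start2 + 1L)
    bp1 <- end(up) - h$bp[, "i"] + 1L
    bp2 <- end(down) - h$bp[, "j"] + 1L
  }
  # genomic left/right
  if (g1[1] <= g2[1]) {
    left <- g1; right <- g2; bpl <- bp1; bpr <- bp2
  } else {
    left <- g2; right <- g1; bpl <- bp2; bpr <- bp1
  }
  if (left[2] >= right[1]) return(NULL)
  ordp <- order(bpl)
  list(start1 = left[1], end1 = left[2], start2 = right[1], end2 = right[2],
       len1 = left[2] - left[1] + 1L, len2 = right[2] - right[1] + 1L,
       structure = paste(bpl[ordp], bpr[ordp], sep = ":", collapse = ","))
}

.paired_gc <- function(h, seq_up, seq_down) {
  n1 <- .encode(seq_up)[h$bp[, "i"]]
  n2 <- .encode(seq_down)[h$bp[, "j"]]
  mean(c(n1, n2) %in% c(2L, 3L))
}

#' Scan a whole genome of genes for PCCRs
#'
#' @param genes GRanges of genes with `gene_id`.
#' @param cirs GRanges of CIRs with `gene_id` (from [build_cirs()]).
#' @param genome DNAStringSet or FASTA path.
#' @inheritParams scan_gene
#' @return catalog data.frame with one row per PCCR and a unique `id`.
#' @export
pccr_scan <- function(genes, cirs, genome, table = NULL,
                      params = search_params(), L = 10000L) {
  genome <- .get_genome(genome)
  if (is.null(table)) table <- build_kmer_table(params$k, params$max_gu)
  parts <- lapply(seq_along(genes), function(g) {
    gene <- genes[g]
    cg <- cirs[cirs$gene_id == gene$gene_id]
    if (length(cg) == 0) return(.empty_catalog())
    tryCatch(
      scan_gene(gene, cg, genome, table, params, L),
      error = function(e) {
        warning("gene ", gene$gene_id, " failed: ", conditionMessage(e))
        .empty_catalog()
      })
  })
  parts <- parts[vapply(parts, nrow, 0L) > 0]
  if (length(parts) == 0) return(.empty_catalog())
  out <- do.call(rbind, parts)
  out$id <- sprintf("PCCR%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Relative position of an interval within its gene
#'
#' `p = (x - a) / ((b - a) - (y - x) + 1)` for a plus-strand gene
#' `[a, b]` and interval `[x, y]` (genomic coordinates); `1 - p` for
#' minus-strand genes, so that 0 is always the 5' end of the gene and
#' values near 1 the 3' end. Clamped to `[0, 1]`.
#'
#' @param interval,gene GRanges scalars; the interval must lie within
#'   the gene.
#' @return relative position in `[0, 1]`.
#' @export
relative_position <- function(interval, gene) {
  x <- start(interval); y <- end(interval)
  a <- start(gene); b <- end(gene)
  if (x < a || y > b) stop("interval outside gene")
  denom <- (b - a) - (y - x) + 1
  p <- if (denom <= 0) 0 else (x - a) / denom
  p <- min(max(p, 0), 1)
  if (as.character(strand(gene)) == "-") p <- 1 - p
  p
}

#' Conservation metrics of a CCR
#'
#' `s1`: mean per-nucleotide score within the CCR minus the mean within
#' the two `flank`-nucleotide regions adjacent to it (larger = locally
#' elevated conservation). `s2`: mean score over the CCR plus `flank`
#' nucleotides on each side (smaller = more isolated). `s3`: CCR length
#' relative to its parent CIR. Positions without score are treated as 0.
#'
#' @param ccr GRanges scalar.
#' @param cir GRanges scalar (parent of `ccr`).
#' @param score_track GRanges with a numeric `score` column
#'   (bedGraph-like), or an RleList of per-chromosome coverage.
#' @param flank flank size in nucleotides (default 300).
#' @return named numeric vector `c(s1, s2, s3)`.
#' @export
conservation_scores <- function(ccr, cir, score_track, flank = 300L) {
  chrom <- as.character(seqnames(ccr))
  need <- end(ccr) + flank
  if (inherits(score_track, "GRanges")) {
    cov <- coverage(score_track, weight = score_track$score)
  } else cov <- score_track
  rle <- if (chrom %in% names(cov)) cov[[chrom]] else S4Vectors::Rle(0, 0)
  win_mean <- function(s, e) {
    s <- max(s, 1L)
    if (e < s) return(0)
    v <- as.numeric(.rle_window(rle, s, e))
    mean(v)
  }
  in_ccr <- win_mean(start(ccr), end(ccr))
  fl <- c(.rle_window_vec(rle, start(ccr) - flank, start(ccr) - 1L),
          .rle_window_vec(rle, end(ccr) + 1L, end(ccr) + flank))
  s1 <- in_ccr - if (length(fl)) mean(fl) else 0
  s2 <- win_mean(start(ccr) - flank, end(ccr) + flank)
  s3 <- width(ccr) / width(cir)
  c(s1 = s1, s2 = s2, s3 = s3)
}

.rle_window_vec <- function(rle, s, e) {
  s <- max(s, 1L)
  if (e < s) return(numeric(0))
  .rle_window(rle, s, e)
}

.rle_window <- function(rle, s, e) {
  n <- length(rle)
  pad_right <- max(0L, e - n)
  e2 <- min(e, n)
  v <- if (e2 >= s && s <= n) as.numeric(S4Vectors::window(rle, s, e2))
       else numeric(0)
  c(v, rep(0, pad_right))
}

#' Assign the free-energy group of a PCCR
#'
#' Group I: -20 < dG <= -15; II: -25 < dG <= -20; III: -30 < dG <= -25;
#' IV: dG <= -30 (kcal/mol).
#'
#' @param dG numeric vector of free energies, all <= -15.
#' @return character vector of "I", "II", "III", "IV".
#' @export
assign_energy_group <- function(dG) {
  if (any(dG > -15)) stop("dG above the -15 kcal/mol catalog threshold")
  as.character(cut(dG, breaks = c(-Inf, -30, -25, -20, -15),
                   labels = c("IV", "III", "II", "I")))
}

#' Write a PCCR catalog as paired-block BED12 plus annotation TSV
#'
#' The BED12 line spans both CCRs with two blocks (one per CCR); the TSV
#' carries every catalog column and round-trips losslessly through
#' [read_catalog()].
#'
#' @param catalog catalog data.frame.
#' @param bed_path,tsv_path output files (either may be NULL to skip).
#' @export
write_catalog <- function(catalog, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    if (nrow(catalog) == 0) {
      writeLines(character(0), bed_path)
    } else {
      bad <- catalog$start2 <= catalog$end1
      if (any(bad)) {
        warning("skipping ", sum(bad), " malformed record(s) in BED output")
        catalog_bed <- catalog[!bad, , drop = FALSE]
      } else catalog_bed <- catalog
      df <- data.frame(
        chrom = catalog_bed$chrom,
        start = catalog_bed$start1 - 1L,
        end = catalog_bed$end2,
        name = paste0(catalog_bed$id, "|", catalog_bed$gene_id, "|",
                      sprintf("%.2f", catalog_bed$dG)),
        score = 0L,
        strand = catalog_bed$strand,
        thickStart = catalog_bed$start1 - 1L,
        thickEnd = catalog_bed$end2,
        rgb = "0,0,0",
        blockCount = 2L,
        blockSizes = paste(catalog_bed$length1, catalog_bed$length2,
                           sep = ","),
        blockStarts = paste(0L, catalog_bed$start2 - catalog_bed$start1,
                            sep = ","))
      write.table(df, bed_path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  if (!is.null(tsv_path)) {
    out <- catalog
    for (cc in c("dG", "length_avg", "gc", "rel_pos"))
      if (cc %in% names(out)) out[[cc]] <- sprintf("%.10g", out[[cc]])
    write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(catalog)
}

#' @rdname write_catalog
#' @param tsv_path annotation TSV written by [write_catalog()].
#' @return `read_catalog` returns the catalog data.frame.
#' @export
read_catalog <- function(tsv_path) {
  df <- read.table(tsv_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = list(structure = "character",
                                     energy_group = "character"))
  if (nrow(df) == 0) return(.empty_catalog())
  df
}

#' Base pairs of a catalog record
#'
#' @param record one catalog row.
#' @return 2-column integer matrix of genomic positions
#'   (left CCR, right CCR).
#' @export
catalog_basepairs <- function(record) {
  parts <- strsplit(strsplit(record$structure, ",")[[1]], ":")
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("left", "right")
  m
}
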