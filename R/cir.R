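# Construction of conserved intronic regions (CIRs): the search space for
# the duplex scan. Intervals are held as GRanges (1-based, closed);
# BED/GTF files are converted on read/write by rtracklayer.

#' Read gene and exon annotation from GTF/GFF
#'
#' @param path GTF/GFF file with `gene` and `exon` features carrying a
#'   `gene_id` attribute (and optionally `gene_biotype`/`gene_type`).
#' @return list with `genes` and `exons`, both GRanges with `gene_id`
#'   and `biotype` metadata columns.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  bt <- mcols(gr)$gene_biotype
  if (is.null(bt)) bt <- mcols(gr)$gene_type
  if (is.null(bt)) bt <- rep(NA_character_, length(gr))
  mcols(gr)$biotype <- bt
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  mcols(genes) <- mcols(genes)[, c("gene_id", "biotype")]
  mcols(exons) <- mcols(exons)[, c("gene_id", "biotype")]
  list(genes = genes, exons = exons)
}

#' Extract intronic regions of protein-coding genes
#'
#' For each protein-coding gene, the maximal segments of the gene body
#' that do not overlap any annotated exon (exons of all genes, on either
#' strand, are excluded), each then extended by `extend` nucleotides into
#' the flanking exonic segments so that duplexes may straddle splice
#' sites. The extension is clipped where the flanking exonic segment is
#' shorter than `extend`, and at gene boundaries.
#'
#' @param genes GRanges of gene bodies with `gene_id` and `biotype`.
#' @param exons GRanges of all exons (any gene, any biotype).
#' @param extend nucleotides of exonic extension (default 10).
#' @return GRanges of intronic regions with `gene_id`, sorted.
#' @export
extract_intronic_regions <- function(genes, exons, extend = 10L) {
  coding <- genes[is.na(genes$biotype) | genes$biotype == "protein_coding"]
  exon_union <- reduce(exons, ignore.strand = TRUE)
  out <- GRanges()
  for (g in seq_along(coding)) {
    gene <- coding[g]
    intronic <- setdiff(granges(gene), exon_union, ignore.strand = TRUE)
    intronic <- intronic[width(intronic) > 0]
    if (length(intronic) == 0) next
    # extend into flanking exonic segments, clipped to their width
    hitL <- findOverlaps(GRanges(seqnames(intronic),
                                 IRanges(start(intronic) - 1,
                                         width = 1)),
                         exon_union, ignore.strand = TRUE)
    hitR <- findOverlaps(GRanges(seqnames(intronic),
                                 IRanges(end(intronic) + 1, width = 1)),
                         exon_union, ignore.strand = TRUE)
    extL <- integer(length(intronic))
    extR <- integer(length(intronic))
    extL[queryHits(hitL)] <- pmin(extend, width(exon_union)[subjectHits(hitL)])
    extR[queryHits(hitR)] <- pmin(extend, width(exon_union)[subjectHits(hitR)])
    new_start <- pmax(start(intronic) - extL, start(gene))
    new_end <- pmin(end(intronic) + extR, end(gene))
    res <- GRanges(seqnames(intronic), IRanges(new_start, new_end),
                   strand = strand(gene))
    mcols(res)$gene_id <- gene$gene_id
    out <- c(out, res)
  }
  sort(out, ignore.strand = TRUE)
}

#' Subtract exclusion tracks from intronic regions
#'
#' Removes the portions of regions that overlap any interval of the
#' supplied exclusion tracks (repeats, small-RNA genes, conserved TFBS,
#' tandem repeats, ...); remaining fragments keep their gene attribution.
#'
#' @param regions GRanges with `gene_id` (from
#'   [extract_intronic_regions()]).
#' @param exclusion_tracks list of GRanges (may be empty).
#' @return GRanges of surviving fragments with `gene_id`.
#' @export
apply_exclusions <- function(regions, exclusion_tracks = list()) {
  if (length(exclusion_tracks) == 0) return(regions)
  excl <- reduce(do.call(c, lapply(exclusion_tracks, granges)),
                 ignore.strand = TRUE)
  if (length(excl) == 0) return(regions)
  frag <- subtract(regions, excl, ignore.strand = TRUE)
  n <- S4Vectors::elementNROWS(frag)
  out <- unlist(frag, use.names = FALSE)
  mcols(out)$gene_id <- rep(regions$gene_id, n)
  out[width(out) > 0]
}

#' Intersect intronic regions with conserved elements
#'
#' Produces CIRs: the pairwise intersections of the (exclusion-filtered)
#' intronic regions with a set of conserved-element intervals. Each CIR
#' records its gene and its parent intronic region; conserved intervals
#' are merged first so CIRs of one parent never overlap each other.
#'
#' @param regions GRanges with `gene_id`.
#' @param conserved GRanges of conserved elements (for example a
#'   phastCons elements track).
#' @return GRanges of CIRs with `gene_id`, `parent_start`, `parent_end`.
#' @export
intersect_conserved <- function(regions, conserved) {
  conserved <- reduce(granges(conserved), ignore.strand = TRUE)
  hits <- findOverlaps(regions, conserved, ignore.strand = TRUE)
  if (length(hits) == 0) {
    out <- GRanges()
    mcols(out)$gene_id <- character(0)
    return(out)
  }
  r <- regions[queryHits(hits)]
  cs <- conserved[subjectHits(hits)]
  out <- GRanges(seqnames(r),
                 IRanges(pmax(start(r), start(cs)),
                         pmin(end(r), end(cs))),
                 strand = strand(r))
  mcols(out)$gene_id <- r$gene_id
  mcols(out)$parent_start <- start(r)
  mcols(out)$parent_end <- end(r)
  sort(out, ignore.strand = TRUE)
}

#' Build conserved intronic regions from annotation and tracks
#'
#' Convenience wrapper: [extract_intronic_regions()], then
#' [apply_exclusions()], then [intersect_conserved()].
#'
#' @inheritParams extract_intronic_regions
#' @inheritParams apply_exclusions
#' @inheritParams intersect_conserved
#' @return GRanges of CIRs.
#' @export
build_cirs <- function(genes, exons, conserved, exclusion_tracks = list(),
                       extend = 10L) {
  regions <- extract_intronic_regions(genes, exons, extend = extend)
  regions <- apply_exclusions(regions, exclusion_tracks)
  intersect_conserved(regions, conserved)
}

#' Write CIRs as BED6
#'
#' Gene id goes into the BED name field.
#'
#' @param cirs GRanges from [intersect_conserved()].
#' @param path output file.
#' @export
write_cir_bed <- function(cirs, path) {
  df <- data.frame(chrom = as.character(seqnames(cirs)),
                   start = start(cirs) - 1L,
                   end = end(cirs),
                   name = cirs$gene_id,
                   score = 0L,
                   strand = as.character(strand(cirs)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
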