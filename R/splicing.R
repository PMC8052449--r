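# Splicing-side statistics: exon inclusion (PSI), splice-site activity
# classes, cryptic-site filtering, intron matching, structure-assay
# support, RNA-bridge / exon-loop-out candidate detection, and the
# benchmark agreement score.

#' Exon inclusion rate (PSI) from split-read counts
#'
#' `psi = inc / (inc + 2 exc)`; the value is unreliable and reported as
#' NA when the denominator is below `min_denominator`.
#'
#' @param inc,exc split-read counts supporting inclusion and exclusion
#'   (vectors).
#' @param min_denominator reliability cutoff on `inc + 2 exc`
#'   (default 10).
#' @return numeric vector in `[0, 1]`, NA where unreliable.
#' @examples
#' psi(8, 1)   # 0.8
#' psi(4, 2)   # NA: denominator 8 < 10
#' @export
psi <- function(inc, exc, min_denominator = 10) {
  if (any(inc < 0) || any(exc < 0)) stop("negative read counts")
  den <- inc + 2 * exc
  ifelse(den >= min_denominator, inc / den, NA_real_)
}

#' Classify splice sites as active or inactive by read support
#'
#' Among sites supported by at least `min_support` pooled split reads,
#' the top `frac` by support are "active" and the bottom `frac`
#' "inactive"; ranking ties are broken by position for determinism.
#'
#' @param sites data.frame with `position` and `support`.
#' @param frac quantile fraction (default 0.02).
#' @param min_support minimal pooled support (default 3).
#' @return the input with a `class` column ("active", "inactive",
#'   "none").
#' @export
classify_splice_sites <- function(sites, frac = 0.02, min_support = 3L) {
  sites$class <- "none"
  elig <- which(sites$support >= min_support)
  n_pick <- max(1L, floor(length(elig) * frac))
  if (length(elig) == 0) return(sites)
  o <- elig[order(-sites$support[elig], sites$position[elig])]
  sites$class[o[seq_len(min(n_pick, length(o)))]] <- "active"
  o2 <- elig[order(sites$support[elig], sites$position[elig])]
  inact <- setdiff(o2[seq_len(min(n_pick, length(o2)))],
                   o[seq_len(min(n_pick, length(o)))])
  sites$class[inact] <- "inactive"
  sites
}

#' Select cryptic splice sites
#'
#' Candidates above the side-specific strength threshold that are
#' neither expressed nor annotated.
#'
#' @param candidates data.frame with `position`, `side` ("donor" or
#'   "acceptor"), `score` (external splice-site strength score).
#' @param expressed,annotated integer vectors of positions to exclude.
#' @param donor_thr,acceptor_thr score thresholds (defaults 800, 950).
#' @return the cryptic subset of `candidates`.
#' @export
cryptic_sites <- function(candidates, expressed = integer(0),
                          annotated = integer(0), donor_thr = 800,
                          acceptor_thr = 950) {
  if (nrow(candidates) == 0) return(candidates)
  thr <- ifelse(candidates$side == "donor", donor_thr, acceptor_thr)
  keep <- candidates$score > thr &
    !(candidates$position %in% expressed) &
    !(candidates$position %in% annotated)
  candidates[keep, , drop = FALSE]
}

#' Length-matched intron samples with and without PCCRs
#'
#' Introns are labeled by PCCR containment (a PCCR entirely within the
#' intron), then sampled without replacement in log-length bins of width
#' `bin_width` so that the two samples have identical length profiles.
#' For each transcript-end feature set, a 2x2 table of "contains at
#' least one end" gives the odds ratio.
#'
#' @param introns GRanges.
#' @param catalog catalog data.frame.
#' @param features named list of GRanges (for example
#'   `list(three_prime = ..., five_prime = ...)`).
#' @param bin_width log10 bin width (default 0.1).
#' @param seed random seed.
#' @return list: `iwp`, `iwo` (sampled GRanges), `tables` (per feature:
#'   counts and [odds_ratio()] output).
#' @export
match_iwp_iwo <- function(introns, catalog, features = list(),
                          bin_width = 0.1, seed = NULL) {
  .check_seed(seed)
  spans <- GRanges(catalog$chrom,
                   IRanges(catalog$start1, catalog$end2))
  with_p <- overlapsAny(introns, spans, type = "equal") |
    vapply(seq_along(introns), function(i) {
      any(catalog$start1 >= start(introns)[i] &
            catalog$end2 <= end(introns)[i] &
            catalog$chrom == as.character(seqnames(introns))[i])
    }, TRUE)
  bins <- floor(log10(pmax(width(introns), 1)) / bin_width)
  idx_p <- which(with_p); idx_o <- which(!with_p)
  sel_p <- integer(0); sel_o <- integer(0)
  for (b in intersect(unique(bins[idx_p]), unique(bins[idx_o]))) {
    bp <- idx_p[bins[idx_p] == b]; bo <- idx_o[bins[idx_o] == b]
    nmin <- min(length(bp), length(bo))
    if (nmin == 0) next
    sel_p <- c(sel_p, sample(bp, nmin))
    sel_o <- c(sel_o, sample(bo, nmin))
  }
  iwp <- introns[sel_p]; iwo <- introns[sel_o]
  tables <- lapply(features, function(f) {
    if (length(f) == 0)
      return(list(or = NA_real_, flagged = "empty feature set"))
    has_p <- sum(overlapsAny(iwp, f, ignore.strand = TRUE))
    has_o <- sum(overlapsAny(iwo, f, ignore.strand = TRUE))
    o <- odds_ratio(has_p, length(iwp) - has_p,
                    has_o, length(iwo) - has_o)
    c(list(n_iwp = length(iwp), n_iwo = length(iwo),
           iwp_with = has_p, iwo_with = has_o,
           pct_iwp = 100 * has_p / max(length(iwp), 1),
           pct_iwo = 100 * has_o / max(length(iwo), 1)), o)
  })
  list(iwp = iwp, iwo = iwo, tables = tables)
}

#' Compare inclusion of looped-out exons with free exons
#'
#' Exons strictly between the two CCRs of a PCCR (per energy group) are
#' compared with exons not looped out by any PCCR using a two-sample
#' Kolmogorov-Smirnov test on their PSI values.
#'
#' @param exons GRanges with an `exon_id` column.
#' @param catalog catalog data.frame.
#' @param quants data.frame: `exon_id`, `psi` (NA allowed; dropped).
#' @return data.frame per energy group: sample sizes, KS statistic, p.
#' @export
loopout_psi_comparison <- function(exons, catalog, quants) {
  looped_by <- matrix(FALSE, length(exons), nrow(catalog))
  for (r in seq_len(nrow(catalog))) {
    looped_by[, r] <- as.character(seqnames(exons)) == catalog$chrom[r] &
      loops_out(catalog[r, ], start(exons), end(exons))
  }
  looped_any <- rowSums(looped_by) > 0
  psi_of <- quants$psi[match(exons$exon_id, quants$exon_id)]
  ctrl <- psi_of[!looped_any & !is.na(psi_of)]
  if (length(ctrl) < 2) stop("control group has fewer than 2 exons")
  groups <- c("I", "II", "III", "IV")
  rows <- lapply(groups, function(g) {
    in_g <- rowSums(looped_by[, catalog$energy_group == g,
                              drop = FALSE]) > 0
    x <- psi_of[in_g & !is.na(psi_of)]
    if (length(x) < 2)
      return(data.frame(group = g, n = length(x), n_ctrl = length(ctrl),
                        ks = NA_real_, p_value = NA_real_))
    kt <- suppressWarnings(ks.test(x, ctrl))
    data.frame(group = g, n = length(x), n_ctrl = length(ctrl),
               ks = unname(kt$statistic), p_value = kt$p.value)
  })
  do.call(rbind, rows)
}

#' Agreement with experimentally determined interacting region pairs
#'
#' Precision `P`: percent of PCCRs whose two CCRs each overlap (by at
#' least one nucleotide) the two sides of some experimental pair.
#' Recall `R`: percent of experimental pairs so matched. `pi`: percent
#' of PCCRs with a correctly predicted partner among PCCRs with at
#' least one CCR matching either side of an experimental pair.
#'
#' @param catalog catalog data.frame.
#' @param pairs data.frame of experimental interactions: `chrom`,
#'   `start1`, `end1`, `start2`, `end2` (1-based closed, left/right).
#' @return named numeric vector `c(P, R, pi)` in percent.
#' @export
structure_support <- function(catalog, pairs) {
  if (nrow(pairs) == 0) stop("empty experimental set")
  if (nrow(catalog) == 0) return(c(P = 0, R = 0, pi = NA_real_))
  ov <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
  full <- logical(nrow(catalog)); part <- logical(nrow(catalog))
  hit_exp <- logical(nrow(pairs))
  for (i in seq_len(nrow(catalog))) {
    same <- pairs$chrom == catalog$chrom[i]
    m1 <- same & ov(catalog$start1[i], catalog$end1[i],
                    pairs$start1, pairs$end1)
    m2 <- same & ov(catalog$start2[i], catalog$end2[i],
                    pairs$start2, pairs$end2)
    x1 <- same & ov(catalog$start1[i], catalog$end1[i],
                    pairs$start2, pairs$end2)
    x2 <- same & ov(catalog$start2[i], catalog$end2[i],
                    pairs$start1, pairs$end1)
    both <- (m1 & m2) | (x1 & x2)
    full[i] <- any(both)
    part[i] <- any(m1 | m2 | x1 | x2)
    hit_exp <- hit_exp | both
  }
  c(P = 100 * mean(full), R = 100 * mean(hit_exp),
    pi = if (sum(part) == 0) NA_real_ else 100 * sum(full) / sum(part))
}

#' Agreement score between two base-pair sets
#'
#' Fraction of the base pairs of `S1` present in `S2`.
#'
#' @param S1,S2 2-column matrices of base pairs (any consistent
#'   coordinate convention).
#' @return score in `[0, 1]`.
#' @export
benchmark_score <- function(S1, S2) {
  S1 <- .as_bp_matrix(S1)
  if (nrow(S1) == 0) stop("S1 is empty")
  S2 <- .as_bp_matrix(S2)
  k1 <- paste(S1[, 1], S1[, 2])
  k2 <- paste(S2[, 1], S2[, 2])
  sum(k1 %in% k2) / nrow(S1)
}

.near <- function(a_start, a_end, b_start, b_end, window) {
  # distance between nearest boundaries, 0 when overlapping
  gap <- pmax(b_start - a_end, a_start - b_end, 0)
  gap <= window
}

#' Detect candidate RNA bridges
#'
#' An RNA bridge approximates a distal RBP binding site to a regulated
#' exon: an eCLIP peak of the RBP lies within `window` nucleotides of
#' one CCR, an exon lies within `window` nucleotides of the mate CCR,
#' and the exon's inclusion responds significantly (q below `q_max`) to
#' knockdown of that RBP.
#'
#' @param catalog catalog data.frame.
#' @param peaks GRanges with `rbp`.
#' @param exons GRanges with `exon_id`.
#' @param kd_results data.frame: `exon_id`, `rbp`, `delta_psi`, `q`.
#' @param window distance cutoff in nucleotides (default 50).
#' @param q_max significance cutoff (default 0.01).
#' @return data.frame of candidates: `id`, `rbp`, `exon_id`,
#'   `delta_psi`, `q`.
#' @export
detect_rna_bridges <- function(catalog, peaks, exons, kd_results,
                               window = 50L, q_max = 0.01) {
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    pk <- peaks[as.character(seqnames(peaks)) == rec$chrom]
    ex <- exons[as.character(seqnames(exons)) == rec$chrom]
    if (length(pk) == 0 || length(ex) == 0) next
    near_pk1 <- .near(rec$start1, rec$end1, start(pk), end(pk), window)
    near_pk2 <- .near(rec$start2, rec$end2, start(pk), end(pk), window)
    near_ex1 <- .near(rec$start1, rec$end1, start(ex), end(ex), window)
    near_ex2 <- .near(rec$start2, rec$end2, start(ex), end(ex), window)
    combos <- rbind(
      expand.grid(p = which(near_pk1), e = which(near_ex2)),
      expand.grid(p = which(near_pk2), e = which(near_ex1)))
    if (nrow(combos) == 0) next
    for (r in seq_len(nrow(combos))) {
      rbp <- pk$rbp[combos$p[r]]
      eid <- ex$exon_id[combos$e[r]]
      kd <- kd_results[kd_results$exon_id == eid & kd_results$rbp == rbp, ]
      kd <- kd[!is.na(kd$q) & kd$q < q_max, ]
      if (nrow(kd) == 0) next
      out[[length(out) + 1]] <- data.frame(
        id = rec$id, rbp = rbp, exon_id = eid,
        delta_psi = kd$delta_psi[1], q = kd$q[1],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(id = character(0), rbp = character(0),
               exon_id = character(0), delta_psi = numeric(0),
               q = numeric(0))
  rownames(res) <- NULL
  res
}

#' Detect candidate exon loop-outs
#'
#' A PCCR surrounds an exon (the exon lies strictly between the two
#' CCRs), an eCLIP peak of some RBP overlaps one of the CCRs, and the
#' exon responds significantly to knockdown of that RBP.
#'
#' @inheritParams detect_rna_bridges
#' @return data.frame of candidates.
#' @export
detect_loopouts <- function(catalog, peaks, exons, kd_results,
                            q_max = 0.01) {
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    pk <- peaks[as.character(seqnames(peaks)) == rec$chrom]
    ex <- exons[as.character(seqnames(exons)) == rec$chrom]
    if (length(pk) == 0 || length(ex) == 0) next
    on_ccr <- (start(pk) <= rec$end1 & end(pk) >= rec$start1) |
      (start(pk) <= rec$end2 & end(pk) >= rec$start2)
    inside <- loops_out(rec, start(ex), end(ex))
    if (!any(on_ccr) || !any(inside)) next
    for (p in which(on_ccr)) for (e in which(inside)) {
      rbp <- pk$rbp[p]; eid <- ex$exon_id[e]
      kd <- kd_results[kd_results$exon_id == eid & kd_results$rbp == rbp, ]
      kd <- kd[!is.na(kd$q) & kd$q < q_max, ]
      if (nrow(kd) == 0) next
      out[[length(out) + 1]] <- data.frame(
        id = rec$id, rbp = rbp, exon_id = eid,
        delta_psi = kd$delta_psi[1], q = kd$q[1],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(id = character(0), rbp = character(0),
               exon_id = character(0), delta_psi = numeric(0),
               q = numeric(0))
  rownames(res) <- NULL
  res
}

#' Reactivity depression within CCRs and its energy trend
#'
#' For each CCR, the mean structure-probing reactivity of its paired
#' nucleotides minus the mean reactivity of equally many randomly chosen
#' covered nucleotides elsewhere in the same CIR; the trend is the
#' ordinary least-squares slope of this difference on the energy-group
#' index (I..IV = 1..4).
#'
#' @param catalog catalog data.frame.
#' @param cirs GRanges of CIRs with `gene_id`.
#' @param reactivity GRanges with `score` (per-nucleotide track;
#'   positions absent from the track are uncovered).
#' @param seed random seed for the control draw.
#' @return list: `per_ccr` data.frame (`id`, `group`, `delta`),
#'   `beta1`, `p_wilcoxon` (signed-rank test of delta against 0).
#' @export
reactivity_delta <- function(catalog, cirs, reactivity, seed = NULL) {
  .check_seed(seed)
  if (nrow(catalog) == 0 || length(reactivity) == 0)
    return(list(per_ccr = data.frame(), beta1 = NA_real_,
                p_wilcoxon = NA_real_))
  rpos <- start(reactivity)
  rval <- reactivity$score
  rchrom <- as.character(seqnames(reactivity))
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    bp <- catalog_basepairs(rec)
    for (sidecol in c("left", "right")) {
      ccr_pos <- bp[, sidecol]
      sel <- rchrom == rec$chrom & rpos %in% ccr_pos
      if (!any(sel)) next
      cir <- cirs[cirs$gene_id == rec$gene_id &
                  start(cirs) <= min(ccr_pos) & end(cirs) >= max(ccr_pos)]
      if (length(cir) == 0) next
      ctrl_sel <- rchrom == rec$chrom &
        rpos >= start(cir)[1] & rpos <= end(cir)[1] &
        !(rpos %in% ccr_pos)
      if (!any(ctrl_sel)) next
      n_in <- sum(sel)
      ctrl_vals <- rval[ctrl_sel]
      draw <- sample(ctrl_vals, min(n_in, length(ctrl_vals)),
                     replace = length(ctrl_vals) < n_in)
      rows[[length(rows) + 1]] <- data.frame(
        id = rec$id, group = rec$energy_group,
        delta = mean(rval[sel]) - mean(draw), stringsAsFactors = FALSE)
    }
  }
  per <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(per) == 0)
    return(list(per_ccr = per, beta1 = NA_real_, p_wilcoxon = NA_real_))
  gi <- match(per$group, c("I", "II", "III", "IV"))
  beta1 <- if (length(unique(gi)) > 1)
    unname(coef(lm(per$delta ~ gi))[2]) else NA_real_
  pw <- if (all(per$delta == 0)) 1 else
    suppressWarnings(wilcox.test(per$delta, mu = 0)$p.value)
  list(per_ccr = per, beta1 = beta1, p_wilcoxon = pw)
}

#' Odds ratio of RNA-editing at adenosines inside versus outside CCRs
#'
#' Counts sense-strand adenosines within CCRs and within the remaining
#' parts of the same CIRs, cross-classified by presence in the editing
#' site set.
#'
#' @param catalog catalog data.frame.
#' @param cirs GRanges of CIRs with `gene_id`.
#' @param editing_sites GRanges of editing site positions.
#' @param genome DNAStringSet or FASTA path.
#' @return [odds_ratio()] output plus the underlying counts.
#' @export
editing_site_or <- function(catalog, cirs, editing_sites, genome) {
  genome <- .get_genome(genome)
  ccr <- reduce(c(GRanges(catalog$chrom,
                          IRanges(catalog$start1, catalog$end1),
                          strand = catalog$strand),
                  GRanges(catalog$chrom,
                          IRanges(catalog$start2, catalog$end2),
                          strand = catalog$strand)))
  cir_in <- cirs[overlapsAny(cirs, ccr, ignore.strand = TRUE)]
  outside <- setdiff(granges(cir_in), granges(ccr), ignore.strand = FALSE)
  count_a <- function(gr) {
    tot_a <- 0L; edited_a <- 0L
    ed <- if (length(editing_sites)) start(editing_sites) else integer(0)
    edch <- if (length(editing_sites))
      as.character(seqnames(editing_sites)) else character(0)
    for (i in seq_along(gr)) {
      chrom <- as.character(seqnames(gr))[i]
      s <- .fetch_seq(genome, chrom, start(gr)[i], end(gr)[i],
                      as.character(strand(gr))[i])
      codes <- .encode(s)
      is_a <- which(codes == 1L)
      if (as.character(strand(gr))[i] == "-") {
        gpos <- end(gr)[i] - is_a + 1L
      } else gpos <- start(gr)[i] + is_a - 1L
      tot_a <- tot_a + length(is_a)
      edited_a <- edited_a + sum(gpos %in% ed[edch == chrom])
    }
    c(total = tot_a, edited = edited_a)
  }
  inc <- count_a(ccr); outc <- count_a(outside)
  if (inc["total"] + outc["total"] == 0) stop("no adenosines in regions")
  o <- odds_ratio(inc["edited"], inc["total"] - inc["edited"],
                  outc["edited"], outc["total"] - outc["edited"])
  c(list(a_in = unname(inc["total"]), a_in_edited = unname(inc["edited"]),
         a_out = unname(outc["total"]),
         a_out_edited = unname(outc["edited"])), o)
}
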