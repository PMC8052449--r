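# Resampling controls and association statistics: random-shift and
# random-gene pseudo-catalogs, interval-relation classification,
# enrichment against controls, re-wiring FDR, odds ratios.

#' Classify the relation between a PCCR span and a feature interval
#'
#' `inside`: the PCCR span lies entirely within the feature; `outside`:
#' the feature lies entirely within the PCCR span (for exon loop-out
#' semantics use [loops_out()], which additionally requires the feature
#' to fall strictly between the two CCRs); `crossing`: partial overlap;
#' `disjoint` otherwise.
#'
#' @param span_start,span_end PCCR span (start of left CCR to end of
#'   right CCR), 1-based closed.
#' @param f_start,f_end feature interval.
#' @return character vector.
#' @export
classify_overlap <- function(span_start, span_end, f_start, f_end) {
  n <- max(length(span_start), length(f_start))
  ss <- rep_len(span_start, n); se <- rep_len(span_end, n)
  fs <- rep_len(f_start, n); fe <- rep_len(f_end, n)
  out <- rep("disjoint", n)
  ov <- ss <= fe & fs <= se
  out[ov] <- "crossing"
  out[ov & ss >= fs & se <= fe] <- "inside"
  out[ov & fs >= ss & fe <= se] <- "outside"
  out
}

#' Does a PCCR loop out a feature?
#'
#' TRUE when the feature lies strictly between the two CCRs (within the
#' inner gap), the geometry that places an exon in the intervening loop.
#'
#' @param record catalog rows (data.frame with `end1`, `start2`).
#' @param f_start,f_end feature interval(s).
#' @export
loops_out <- function(record, f_start, f_end) {
  f_start > record$end1 & f_end < record$start2
}

.check_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' Random-shift control catalogs
#'
#' Each PCCR is shifted to a uniformly random offset within its gene,
#' preserving CCR lengths and spread. PCCRs longer than their gene stay
#' in place (flagged via a warning).
#'
#' @param catalog catalog data.frame.
#' @param genes GRanges with `gene_id` covering the catalog's genes.
#' @param n number of randomizations (default 40).
#' @param seed random seed.
#' @return list of `n` pseudo-catalog data.frames.
#' @export
random_shift_control <- function(catalog, genes, n = 40L, seed = NULL) {
  .check_seed(seed)
  gs <- setNames(start(genes), genes$gene_id)
  ge <- setNames(end(genes), genes$gene_id)
  span <- catalog$end2 - catalog$start1 + 1L
  room <- ge[catalog$gene_id] - gs[catalog$gene_id] + 1L - span
  if (any(room < 0)) {
    warning(sum(room < 0), " PCCR(s) longer than their gene kept in place")
  }
  lapply(seq_len(n), function(r) {
    off <- ifelse(room <= 0, 0L,
                  as.integer(floor(runif(nrow(catalog)) * (room + 1))))
    new_start <- ifelse(room < 0, catalog$start1,
                        gs[catalog$gene_id] + off)
    delta <- as.integer(new_start - catalog$start1)
    ps <- catalog
    ps$start1 <- catalog$start1 + delta; ps$end1 <- catalog$end1 + delta
    ps$start2 <- catalog$start2 + delta; ps$end2 <- catalog$end2 + delta
    ps
  })
}

#' Random-gene control catalogs
#'
#' For each PCCR, a pseudo-PCCR with the same spread and CCR lengths is
#' placed at the same relative position in a randomly chosen gene whose
#' length is within `tol` (fractional) of the host gene; if no such gene
#' exists the nearest-length gene is used (with a message).
#'
#' @inheritParams random_shift_control
#' @param tol fractional gene-length matching tolerance (default 0.1).
#' @return list of `n` pseudo-catalog data.frames (extra column
#'   `pseudo_gene`).
#' @export
random_gene_control <- function(catalog, genes, n = 40L, seed = NULL,
                                tol = 0.1) {
  .check_seed(seed)
  glen <- width(genes)
  gs <- start(genes)
  span <- catalog$end2 - catalog$start1 + 1L
  host_len <- glen[match(catalog$gene_id, genes$gene_id)]
  host_start <- gs[match(catalog$gene_id, genes$gene_id)]
  # relative position of the span start within the host gene
  relp <- (catalog$start1 - host_start) / pmax(host_len - span + 1L, 1L)
  fallback <- 0L
  pick_gene <- function(i) {
    ok <- which(abs(glen - host_len[i]) <= tol * host_len[i] &
                glen >= span[i])
    if (length(ok) == 0) {
      fallback <<- fallback + 1L
      ok <- which(glen >= span[i])
      if (length(ok) == 0) return(match(catalog$gene_id[i], genes$gene_id))
      return(ok[which.min(abs(glen[ok] - host_len[i]))])
    }
    ok[sample.int(length(ok), 1)]
  }
  out <- lapply(seq_len(n), function(r) {
    gi <- vapply(seq_len(nrow(catalog)), pick_gene, 0L)
    new_start <- gs[gi] +
      as.integer(round(relp * pmax(glen[gi] - span + 1L, 1L)))
    new_start <- pmin(pmax(new_start, gs[gi]), gs[gi] + glen[gi] - span)
    delta <- as.integer(new_start - catalog$start1)
    ps <- catalog
    ps$start1 <- catalog$start1 + delta; ps$end1 <- catalog$end1 + delta
    ps$start2 <- catalog$start2 + delta; ps$end2 <- catalog$end2 + delta
    ps$pseudo_gene <- genes$gene_id[gi]
    ps
  })
  if (fallback > 0)
    message(fallback, " placements used nearest-length fallback")
  out
}

.count_relation <- function(catalog, features, relation) {
  if (nrow(catalog) == 0 || length(features) == 0) return(0L)
  fs <- start(features); fe <- end(features)
  total <- 0L
  for (i in seq_len(nrow(catalog))) {
    if (relation == "loopout") {
      total <- total + sum(loops_out(catalog[i, ], fs, fe))
    } else {
      cl <- classify_overlap(catalog$start1[i], catalog$end2[i], fs, fe)
      total <- total + sum(cl == relation)
    }
  }
  total
}

#' Enrichment of PCCRs in a positional category against control catalogs
#'
#' Counts (PCCR, feature) pairs in the requested relation for the real
#' catalog and for each control catalog; enrichment is the observed count
#' over the mean control count, with a two-tailed one-sample Wilcoxon
#' signed-rank p value for the null that controls are centered at the
#' observed count (H0: enrichment = 1).
#'
#' @param catalog catalog data.frame.
#' @param features GRanges of features (introns, exons, ...).
#' @param control_catalogs list of pseudo-catalogs
#'   ([random_shift_control()] or [random_gene_control()]).
#' @param relation one of "inside", "outside", "crossing", "loopout".
#' @return list of class `enrichment_result`: `observed`,
#'   `control_counts`, `enrichment`, `p_value`.
#' @export
enrichment <- function(catalog, features, control_catalogs,
                       relation = c("inside", "outside", "crossing",
                                    "loopout")) {
  relation <- match.arg(relation)
  observed <- .count_relation(catalog, features, relation)
  ctrl <- vapply(control_catalogs, .count_relation, 0L,
                 features = features, relation = relation)
  mc <- mean(ctrl)
  enr <- if (mc == 0) NA_real_ else observed / mc
  if (mc == 0) warning("zero mean control count; enrichment undefined")
  p <- if (length(unique(c(ctrl, observed))) < 2) 1 else
    suppressWarnings(wilcox.test(ctrl, mu = observed)$p.value)
  structure(list(observed = observed, control_counts = ctrl,
                 enrichment = enr, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("observed %d vs mean control %.2f: enrichment = %.3f (p = %.3g)\n",
              x$observed, mean(x$control_counts), x$enrichment, x$p_value))
  invisible(x)
}

#' Odds ratio of a 2x2 contingency table with 95% CI
#'
#' `OR = (a d) / (b c)`; the confidence interval comes from the normal
#' approximation on the log odds ratio, and the p value from Fisher's
#' exact test. Tables with an off-diagonal zero get the Haldane 0.5
#' correction (flagged in the result).
#'
#' @param a,b,c,d non-negative counts: `a`,`b` = feature present/absent
#'   in group 1; `c`,`d` = present/absent in group 2.
#' @return list: `or`, `ci` (length 2), `p_value`, `corrected`.
#' @export
odds_ratio <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("negative counts")
  p <- fisher.test(matrix(cnt, 2, byrow = TRUE))$p.value
  corrected <- (b * c == 0) || (a * d == 0)
  if (corrected) cnt <- cnt + 0.5
  or <- (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
  se <- sqrt(sum(1 / cnt))
  ci <- exp(log(or) + c(-1.96, 1.96) * se)
  list(or = or, ci = ci, p_value = p, corrected = corrected)
}

#' Forked-peak odds ratios per RNA-binding protein
#'
#' For each RBP, PCCRs are cross-classified by the presence of an eCLIP
#' peak within `window` nucleotides of the left and of the right CCR;
#' the odds ratio measures how much more likely a peak is near one CCR
#' given a peak near the other (forked peaks flank both arms of a
#' duplex).
#'
#' @param catalog catalog data.frame.
#' @param peaks GRanges with an `rbp` metadata column (pre-filtered
#'   upstream).
#' @param window distance from a CCR still counted as "near"
#'   (default 50).
#' @return data.frame with one row per RBP: counts, `or`, `ci_lo`,
#'   `ci_hi`, `p_value`.
#' @export
forked_peak_or <- function(catalog, peaks, window = 50L) {
  if (nrow(catalog) == 0)
    return(data.frame(rbp = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), or = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      p_value = numeric(0)))
  rbps <- unique(peaks$rbp)
  rows <- list()
  left <- GRanges(catalog$chrom,
                  IRanges(catalog$start1 - window, catalog$end1 + window))
  right <- GRanges(catalog$chrom,
                   IRanges(pmax(catalog$start2 - window, 1),
                           catalog$end2 + window))
  for (r in rbps) {
    pk <- peaks[peaks$rbp == r]
    if (length(pk) == 0) next
    hasL <- overlapsAny(left, pk, ignore.strand = TRUE)
    hasR <- overlapsAny(right, pk, ignore.strand = TRUE)
    if (!any(hasL) && !any(hasR)) next
    a <- sum(hasL & hasR); b <- sum(hasL & !hasR)
    cc <- sum(!hasL & hasR); d <- sum(!hasL & !hasR)
    o <- odds_ratio(a, b, cc, d)
    rows[[length(rows) + 1]] <- data.frame(
      rbp = r, a = a, b = b, c = cc, d = d, or = o$or,
      ci_lo = o$ci[1], ci_hi = o$ci[2], p_value = o$p_value,
      corrected = o$corrected, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rbp = character(0))
  if (nrow(out) > 0) out$p_adj <- p.adjust(out$p_value, "BH")
  out
}

#' Enrichment of peak coverage on CCRs within their CIRs
#'
#' A CCR counts as bound when peaks cover at least half of its length;
#' the control shifts each CCR to a random position within its parent
#' CIR (CCRs longer than their CIR stay in place).
#'
#' @param ccrs GRanges of CCRs with `cir_start`, `cir_end` metadata
#'   columns (parent CIR bounds).
#' @param peaks GRanges.
#' @param n randomizations (default 40).
#' @param seed random seed.
#' @return an `enrichment_result`.
#' @export
ccr_peak_enrichment <- function(ccrs, peaks, n = 40L, seed = NULL) {
  .check_seed(seed)
  pk <- reduce(granges(peaks), ignore.strand = TRUE)
  count_bound <- function(gr) {
    if (length(gr) == 0 || length(pk) == 0) return(0L)
    ov <- findOverlaps(gr, pk, ignore.strand = TRUE)
    if (length(ov) == 0) return(0L)
    w <- width(pintersect(granges(gr)[queryHits(ov)], pk[subjectHits(ov)]))
    covered <- tapply(w, queryHits(ov), sum)
    idx <- as.integer(names(covered))
    sum(covered >= 0.5 * width(gr)[idx])
  }
  observed <- count_bound(ccrs)
  room <- (ccrs$cir_end - ccrs$cir_start + 1L) - width(ccrs)
  ctrl <- vapply(seq_len(n), function(r) {
    off <- ifelse(room <= 0, ccrs$cir_start,
                  ccrs$cir_start +
                    as.integer(floor(runif(length(ccrs)) * (room + 1))))
    sh <- GRanges(seqnames(ccrs), IRanges(off, width = width(ccrs)))
    count_bound(sh)
  }, 0L)
  mc <- mean(ctrl)
  structure(list(observed = observed, control_counts = ctrl,
                 enrichment = if (mc == 0) NA_real_ else observed / mc,
                 p_value = if (length(unique(c(ctrl, observed))) < 2) 1 else
                   suppressWarnings(wilcox.test(ctrl,
                                                mu = observed)$p.value)),
            class = "enrichment_result")
}

#' Re-wiring estimate of the false discovery rate
#'
#' The duplex pipeline is rerun on chimeric CIR pairs: each
#' distance-eligible cognate pair (c1, c2) is replaced by (c1, c2')
#' where c2' comes from a different gene and matches c2 in length
#' (fractional tolerance `len_tol`) and GC content (absolute tolerance
#' `gc_tol`). The FDR is the number of control predictions divided by
#' the number of real predictions; per-stratum FDRs by free-energy group
#' are included.
#'
#' @param cirs GRanges of CIRs with `gene_id`.
#' @param genome DNAStringSet or FASTA path.
#' @param table k-mer energy table (NULL builds the default).
#' @param params [search_params()].
#' @param L distance limit (default 10000).
#' @param n number of re-wired control sets (default 4).
#' @param seed random seed.
#' @param len_tol,gc_tol matching tolerances (defaults 0.1 and 0.05);
#'   relaxed stepwise (with a message) when the match pool is empty.
#' @return list of class `fdr_estimate`: `n_real`, `n_control` (mean
#'   over control sets), `fdr`, `by_group` data.frame.
#' @export
rewire_fdr <- function(cirs, genome, table = NULL,
                       params = search_params(), L = 10000L, n = 4L,
                       seed = NULL, len_tol = 0.1, gc_tol = 0.05) {
  .check_seed(seed)
  genome <- .get_genome(genome)
  if (is.null(table)) table <- build_kmer_table(params$k, params$max_gu)
  genes <- unique(cirs$gene_id)
  if (length(genes) < 2) stop("re-wiring needs CIRs from at least 2 genes")
  seqs <- vapply(seq_along(cirs), function(i) {
    .fetch_seq(genome, as.character(seqnames(cirs))[i], start(cirs)[i],
               end(cirs)[i], as.character(strand(cirs))[i])
  }, "")
  lens <- nchar(seqs)
  gcs <- vapply(seqs, function(s) {
    v <- .encode(s); mean(v %in% c(2L, 3L), na.rm = TRUE)
  }, 0, USE.NAMES = FALSE)

  # distance-eligible cognate pairs within genes
  pair_idx <- list()
  for (g in genes) {
    w <- which(cirs$gene_id == g)
    pp <- enumerate_cir_pairs(cirs[w], L)
    o <- attr(pp, "order")
    if (nrow(pp)) {
      pair_idx[[g]] <- cbind(w[o][pp$idx1], w[o][pp$idx2])
    }
  }
  pairs <- do.call(rbind, pair_idx)
  if (is.null(pairs) || nrow(pairs) == 0) stop("no distance-eligible CIR pairs")

  count_hits <- function(i1, i2) {
    res <- numeric(0)
    for (r in seq_along(i1)) {
      h <- select_nonintersecting(
        find_duplexes(seqs[i1[r]], seqs[i2[r]], table, params))
      res <- c(res, vapply(h, `[[`, 0, "dG"))
    }
    res
  }
  real_dg <- count_hits(pairs[, 1], pairs[, 2])

  match_partner <- function(i2) {
    lt <- len_tol; gt <- gc_tol
    repeat {
      pool <- which(cirs$gene_id != cirs$gene_id[i2] &
                    abs(lens - lens[i2]) <= lt * lens[i2] &
                    abs(gcs - gcs[i2]) <= gt)
      if (length(pool) > 0) return(pool[sample.int(length(pool), 1)])
      lt <- lt * 2; gt <- gt * 2
      if (lt > 1) {
        message("re-wiring match pool empty; using any other gene")
        pool <- which(cirs$gene_id != cirs$gene_id[i2])
        return(pool[sample.int(length(pool), 1)])
      }
    }
  }
  ctrl_counts <- vapply(seq_len(n), function(r) {
    alt <- vapply(pairs[, 2], match_partner, 0L)
    length(count_hits(pairs[, 1], alt))
  }, 0)

  n_real <- length(real_dg)
  n_ctrl <- mean(ctrl_counts)
  by_group <- NULL
  if (n_real > 0) {
    # local binning tolerant of permissive thresholds (extra top bin)
    bins <- cut(real_dg, breaks = c(-Inf, -30, -25, -20, -15, 0),
                labels = c("IV", "III", "II", "I", "above"))
    gr_real <- table(bins)
    by_group <- data.frame(group = names(gr_real),
                           n_real = as.integer(gr_real),
                           stringsAsFactors = FALSE)
  }
  structure(list(n_real = n_real, n_control = n_ctrl,
                 control_counts = ctrl_counts,
                 fdr = if (n_real == 0) NA_real_ else n_ctrl / n_real,
                 by_group = by_group),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("re-wiring FDR: %d real vs %.1f control predictions (FDR = %.3f)\n",
              x$n_real, x$n_control, x$fdr))
  invisible(x)
}
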