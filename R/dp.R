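# k-mer seeded local dynamic program for nearly perfect complementary
# region pairs between two sequences.
#
# Internal coordinate convention: seq1 is indexed 5'->3'; seq2 is reversed
# ("s2r") so that the bottom strand of the duplex reads left-to-right in
# 3'->5' orientation, aligned under seq1. A base pair is a cell (i, jr);
# jr is converted back to the natural seq2 position (L2 - jr + 1) in all
# reported structures.

#' Search parameters for the duplex scan
#'
#' @param k helix seed length in nucleotides (default 5).
#' @param m maximal internal loop/bulge size per strand (default 2).
#' @param max_gu maximal wobble pairs per k-mer window (default 2).
#' @param energy_threshold report duplexes with free energy at or below
#'   this value, kcal/mol (default -15).
#' @param min_len minimal span of each of the two paired regions,
#'   nucleotides (default 10).
#' @return a list of class `search_params`.
#' @export
search_params <- function(k = 5L, m = 2L, max_gu = 2L,
                          energy_threshold = -15, min_len = 10L) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (min_len < k) stop("min_len must be >= k")
  if (energy_threshold >= 0) stop("energy_threshold must be negative")
  structure(list(k = k, m = as.integer(m), max_gu = as.integer(max_gu),
                 energy_threshold = energy_threshold,
                 min_len = as.integer(min_len)),
            class = "search_params")
}

# fixed transition order for loops: by total size, then by size on strand 1
.loop_moves <- function(m) {
  g <- expand.grid(a = 0:m, b = 0:m)
  g <- g[g$a + g$b > 0, ]
  g <- g[order(g$a + g$b, g$a), ]
  g$pen <- mapply(loop_penalty, g$a, g$b, MoreArgs = list(m = m))
  g
}

# pad a lookup matrix with one NA row/column so NA indices can be routed
# to the sentinel
.pad_na <- function(M) {
  rbind(cbind(M, NA_real_), NA_real_)
}

.window_ids <- function(codes, k, nk) {
  L <- length(codes)
  out <- rep(nk + 1L, L)          # sentinel = inadmissible
  if (L >= k) {
    ids <- .kmer_ids(codes, k)
    ids[is.na(ids)] <- nk + 1L
    out[k:L] <- ids
  }
  out
}

.dinuc_ids <- function(codes) {
  L <- length(codes)
  out <- rep(17L, L)
  if (L >= 2) {
    d <- (codes[-L] - 1) * 4 + codes[-1]
    d[is.na(d)] <- 17L
    out[2:L] <- d
  }
  out
}

#' Find complementary region pairs between two sequences
#'
#' Local dynamic program over the grammar: seed a k-nucleotide helix from
#' the precomputed k-mer table, extend a helix by one stacking base pair,
#' or interrupt it with a short internal loop or bulge of up to `m`
#' nucleotides per strand followed by a new k-mer seed. For every end
#' cell the minimal free energy over all structures ending there is
#' computed; cells that pass the energy threshold and are not interior to
#' a strictly better continuation are reported, each with a deterministic
#' traceback.
#'
#' @param seq1,seq2 sense-strand sequences over A, C, G, T/U, N
#'   (N never pairs). `seq1` is the upstream region; base pairing is
#'   antiparallel, so positions in `seq2` decrease along the structure.
#' @param table a [build_kmer_table()] object, or NULL to build/cache one
#'   from `params`.
#' @param params a [search_params()] object.
#' @return an object of class `duplex_hits`: a list of hits sorted by
#'   free energy, each with elements `bp` (2-column matrix of 1-based
#'   positions, `i` increasing, `j` decreasing), `dG`, `start1`, `end1`,
#'   `start2`, `end2`, `length1`, `length2`. Attribute `D` carries the
#'   per-cell optimal energies (internal orientation) for oracle
#'   comparisons.
#' @examples
#' hits <- find_duplexes("GCGCGCGCGC", "GCGCGCGCGC")
#' hits[[1]]$dG  # about -26.5 kcal/mol for the full 10-bp duplex
#' @export
find_duplexes <- function(seq1, seq2, table = NULL,
                          params = search_params()) {
  k <- params$k; m <- params$m
  if (is.null(table)) table <- build_kmer_table(k, params$max_gu)
  if (table$k != k || table$max_gu != params$max_gu)
    stop("k-mer table does not match search parameters")
  s1 <- .encode(seq1)
  s2 <- .encode(seq2)
  L1 <- length(s1); L2 <- length(s2)
  empty <- structure(list(), class = "duplex_hits")
  if (L1 < k || L2 < k) return(empty)
  s2r <- rev(s2)

  nk <- 4^k
  Mpad <- .pad_na(table$energies)
  SMpad <- .pad_na(.stack_matrix())
  e1 <- .window_ids(s1, k, nk)      # window ending at i
  e2 <- .window_ids(s2r, k, nk)     # window ending at jr
  SE <- Mpad[e1, e2, drop = FALSE]  # seed energy per end cell
  d1 <- .dinuc_ids(s1)
  d2 <- .dinuc_ids(s2r)
  SS <- SMpad[d1, d2, drop = FALSE] # stack step ending at cell

  moves <- .loop_moves(m)
  D <- matrix(NA_real_, L1, L2)
  for (i in k:L1) {
    seedrow <- SE[i, ]
    if (all(is.na(seedrow))) { next }
    best <- seedrow
    if (i > k) {
      ext <- c(NA_real_, D[i - 1, -L2] + SS[i, -1])
      best <- pmin(best, ext, na.rm = TRUE)
    }
    for (t in seq_len(nrow(moves))) {
      pi <- i - k - moves$a[t]
      sh <- k + moves$b[t]
      if (pi < k || sh >= L2) next
      cand <- c(rep(NA_real_, sh), D[pi, 1:(L2 - sh)]) + moves$pen[t] + seedrow
      best <- pmin(best, cand, na.rm = TRUE)
    }
    best[is.na(seedrow)] <- NA_real_
    D[i, ] <- best
  }

  hits <- .extract_hits(D, SE, SS, moves, s1, s2r, k, params)
  attr(hits, "D") <- D
  hits
}

# cells passing the threshold that no strictly improving continuation
# consumes, then traceback + min_len filter
.extract_hits <- function(D, SE, SS, moves, s1, s2r, k, params) {
  L1 <- nrow(D); L2 <- ncol(D)
  thr <- params$energy_threshold
  pass <- !is.na(D) & D <= thr
  hits <- structure(list(), class = "duplex_hits")
  if (!any(pass)) return(hits)

  consumed <- matrix(FALSE, L1, L2)
  if (L1 > 1 && L2 > 1) {
    ext_gain <- SE[-1, -1]  # admissibility of the extended window
    stp <- SS[-1, -1]
    consumed[-L1, -L2] <- !is.na(ext_gain) & !is.na(stp) & stp < 0
  }
  for (t in seq_len(nrow(moves))) {
    di <- k + moves$a[t]; dj <- k + moves$b[t]
    if (di < L1 && dj < L2) {
      blk <- SE[(1 + di):L1, (1 + dj):L2, drop = FALSE] + moves$pen[t]
      imp <- !is.na(blk) & blk < 0
      consumed[1:(L1 - di), 1:(L2 - dj)] <-
        consumed[1:(L1 - di), 1:(L2 - dj)] | imp
    }
  }

  cells <- which(pass & !consumed, arr.ind = TRUE)
  if (nrow(cells) == 0) return(hits)
  ord <- order(D[cells], cells[, 1], cells[, 2])
  cells <- cells[ord, , drop = FALSE]
  out <- vector("list", nrow(cells))
  n_out <- 0
  for (r in seq_len(nrow(cells))) {
    bp_r <- .traceback(cells[r, 1], cells[r, 2], D, SE, SS, moves, k)
    span1 <- bp_r[nrow(bp_r), 1] - bp_r[1, 1] + 1
    span2 <- bp_r[nrow(bp_r), 2] - bp_r[1, 2] + 1
    if (min(span1, span2) < params$min_len) next
    jnat <- L2 - bp_r[, 2] + 1L
    hit <- list(
      bp = cbind(i = bp_r[, 1], j = jnat),
      dG = D[cells[r, 1], cells[r, 2]],
      start1 = bp_r[1, 1], end1 = bp_r[nrow(bp_r), 1],
      start2 = jnat[nrow(bp_r)], end2 = jnat[1],
      length1 = span1, length2 = span2
    )
    stopifnot(hit$dG <= thr, min(span1, span2) >= params$min_len)
    n_out <- n_out + 1
    out[[n_out]] <- hit
  }
  structure(out[seq_len(n_out)], class = "duplex_hits")
}

# deterministic traceback: stack move first, then loops in fixed order,
# then the terminal seed
.traceback <- function(i, j, D, SE, SS, moves, k, tol = 1e-9) {
  bp <- matrix(integer(0), ncol = 2)
  repeat {
    val <- D[i, j]
    stepped <- FALSE
    if (i > k && j > 1 && !is.na(D[i - 1, j - 1]) && !is.na(SS[i, j]) &&
        abs(D[i - 1, j - 1] + SS[i, j] - val) <= tol) {
      bp <- rbind(c(i, j), bp)
      i <- i - 1; j <- j - 1
      stepped <- TRUE
    } else {
      for (t in seq_len(nrow(moves))) {
        pi <- i - k - moves$a[t]; pj <- j - k - moves$b[t]
        if (pi < k || pj < 1 || is.na(D[pi, pj]) || is.na(SE[i, j])) next
        if (abs(D[pi, pj] + moves$pen[t] + SE[i, j] - val) <= tol) {
          bp <- rbind(cbind((i - k + 1):i, (j - k + 1):j), bp)
          i <- pi; j <- pj
          stepped <- TRUE
          break
        }
      }
      if (!stepped) {
        if (is.na(SE[i, j]) || abs(SE[i, j] - val) > tol)
          stop("traceback failed: inconsistent DP matrix")
        bp <- rbind(cbind((i - k + 1):i, (j - k + 1):j), bp)
        break
      }
    }
    if (!stepped) break
  }
  bp
}

#' @export
print.duplex_hits <- function(x, ...) {
  cat("duplex hits:", length(x), "\n")
  for (h in head(x, 10)) {
    cat(sprintf("  [%d-%d] x [%d-%d]  dG = %.2f kcal/mol, %d bp\n",
                h$start1, h$end1, h$start2, h$end2, h$dG, nrow(h$bp)))
  }
  invisible(x)
}

#' Exhaustive enumeration oracle for the duplex grammar
#'
#' Enumerates every structure allowed by the grammar (helices of at least
#' k base pairs, every k-window admissible with at most `max_gu` wobbles,
#' inter-helix gaps of up to `m` nucleotides per strand) on a small
#' sequence pair, scoring each by direct summation. Used to verify
#' [find_duplexes()]; refuses inputs with more than `max_cells` matrix
#' cells.
#'
#' @inheritParams find_duplexes
#' @param max_cells refuse inputs with `nchar(seq1) * nchar(seq2)` above
#'   this bound (default 400).
#' @return a `duplex_hits` list like [find_duplexes()], with attribute
#'   `D` holding the per-end-cell optima.
#' @export
brute_force_duplexes <- function(seq1, seq2, params = search_params(),
                                 max_cells = 400) {
  s1 <- .encode(seq1); s2 <- .encode(seq2)
  L1 <- length(s1); L2 <- length(s2)
  empty <- structure(list(), class = "duplex_hits")
  if (L1 < params$k || L2 < params$k) return(empty)
  if (L1 * L2 > max_cells)
    stop("input too large for brute force: ", L1 * L2, " cells > ", max_cells)
  k <- params$k; m <- params$m
  s2r <- rev(s2)

  AP <- matrix(FALSE, L1, L2)   # admissible pair (i, jr)
  WB <- matrix(FALSE, L1, L2)
  for (i in seq_len(L1)) for (j in seq_len(L2)) {
    a <- s1[i]; b <- s2r[j]
    if (!is.na(a) && !is.na(b) && b %in% .PARTNERS[[a]]) {
      AP[i, j] <- TRUE
      WB[i, j] <- (a == 3 && b == 4) || (a == 4 && b == 3)
    }
  }
  helix_ok <- function(i0, j0, len) {
    ii <- i0:(i0 + len - 1); jj <- j0:(j0 + len - 1)
    if (!all(AP[cbind(ii, jj)])) return(FALSE)
    w <- as.numeric(WB[cbind(ii, jj)])
    if (len >= k) {
      cs <- cumsum(w)
      win <- cs[k:len] - c(0, cs)[1:(len - k + 1)]
      if (any(win > params$max_gu)) return(FALSE)
    }
    TRUE
  }

  SM <- .stack_matrix()
  helix_energy <- function(i0, j0, len) {
    e <- 0
    for (t in seq_len(len - 1)) {
      dt <- (s1[i0 + t - 1] - 1) * 4 + s1[i0 + t]
      db <- (s2r[j0 + t - 1] - 1) * 4 + s2r[j0 + t]
      e <- e + SM[dt, db]
    }
    e
  }

  best <- matrix(NA_real_, L1, L2)
  best_bp <- vector("list", L1 * L2)
  moves <- .loop_moves(m)
  record <- function(i_end, j_end, energy, bp) {
    idx <- (j_end - 1) * L1 + i_end
    if (is.na(best[i_end, j_end]) || energy < best[i_end, j_end] - 1e-12) {
      best[i_end, j_end] <<- energy
      best_bp[[idx]] <<- bp
    }
  }
  # depth-first over structures: current structure ends a helix at
  # (i_end, j_end); every prefix is itself a complete structure
  extend <- function(i_end, j_end, energy, bp) {
    record(i_end, j_end, energy, bp)
    # grow current helix by one base pair
    if (i_end < L1 && j_end < L2 && AP[i_end + 1, j_end + 1]) {
      len1 <- nrow(bp)
      run <- 1
      while (run < len1 &&
             bp[len1 - run, 1] == bp[len1 - run + 1, 1] - 1 &&
             bp[len1 - run, 2] == bp[len1 - run + 1, 2] - 1) run <- run + 1
      i0 <- i_end - run + 1; j0 <- j_end - run + 1
      if (helix_ok(i0, j0, run + 1)) {
        dt <- (s1[i_end] - 1) * 4 + s1[i_end + 1]
        db <- (s2r[j_end] - 1) * 4 + s2r[j_end + 1]
        extend(i_end + 1, j_end + 1, energy + SM[dt, db],
               rbind(bp, c(i_end + 1, j_end + 1)))
      }
    }
    # or close it with a loop and seed a new k-helix
    for (t in seq_len(nrow(moves))) {
      i0 <- i_end + moves$a[t] + 1
      j0 <- j_end + moves$b[t] + 1
      if (i0 + k - 1 > L1 || j0 + k - 1 > L2) next
      if (!helix_ok(i0, j0, k)) next
      e2 <- energy + moves$pen[t] + helix_energy(i0, j0, k)
      extend(i0 + k - 1, j0 + k - 1, e2,
             rbind(bp, cbind(i0:(i0 + k - 1), j0:(j0 + k - 1))))
    }
  }
  for (i0 in seq_len(L1 - k + 1)) for (j0 in seq_len(L2 - k + 1)) {
    if (!helix_ok(i0, j0, k)) next
    extend(i0 + k - 1, j0 + k - 1, helix_energy(i0, j0, k),
           cbind(i0:(i0 + k - 1), j0:(j0 + k - 1)))
  }

  hits <- structure(list(), class = "duplex_hits")
  cells <- which(!is.na(best) & best <= params$energy_threshold,
                 arr.ind = TRUE)
  out <- list()
  if (nrow(cells) > 0) {
    ord <- order(best[cells], cells[, 1], cells[, 2])
    cells <- cells[ord, , drop = FALSE]
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]; j <- cells[r, 2]
      bp_r <- best_bp[[(j - 1) * L1 + i]]
      span1 <- bp_r[nrow(bp_r), 1] - bp_r[1, 1] + 1
      span2 <- bp_r[nrow(bp_r), 2] - bp_r[1, 2] + 1
      if (min(span1, span2) < params$min_len) next
      jnat <- L2 - bp_r[, 2] + 1L
      out[[length(out) + 1]] <- list(
        bp = cbind(i = bp_r[, 1], j = jnat),
        dG = best[i, j],
        start1 = bp_r[1, 1], end1 = bp_r[nrow(bp_r), 1],
        start2 = jnat[nrow(bp_r)], end2 = jnat[1],
        length1 = span1, length2 = span2)
    }
  }
  hits <- structure(out, class = "duplex_hits")
  attr(hits, "D") <- best
  hits
}

#' Select non-intersecting duplex hits
#'
#' Two hits intersect only if their region-1 intervals share nucleotides
#' AND their region-2 intervals share nucleotides; sharing one strand only
#' does not count. Hits are kept greedily by ascending free energy (most
#' stable first), ties broken by longer total span, then by leftmost
#' region-1 start.
#'
#' @param hits a `duplex_hits` list from one sequence pair.
#' @return the retained subset, in greedy order.
#' @export
select_nonintersecting <- function(hits) {
  if (length(hits) == 0) return(hits)
  dg <- vapply(hits, `[[`, 0, "dG")
  tot <- vapply(hits, function(h) h$length1 + h$length2, 0)
  st1 <- vapply(hits, `[[`, 0, "start1")
  ord <- order(dg, -tot, st1)
  kept <- list()
  for (r in ord) {
    h <- hits[[r]]
    clash <- any(vapply(kept, function(g) {
      o1 <- h$start1 <= g$end1 && g$start1 <= h$end1
      o2 <- h$start2 <= g$end2 && g$start2 <= h$end2
      o1 && o2
    }, TRUE))
    if (!clash) kept[[length(kept) + 1]] <- h
  }
  structure(kept, class = class(hits))
}

#' Pairing string of a duplex hit
#'
#' Dot-bracket-like annotation: one character per nucleotide of each
#' region span, `(`/`)` for paired positions, `.` for unpaired, the two
#' regions joined by `&`.
#'
#' @param hit one element of a `duplex_hits` list.
#' @return character scalar.
#' @export
pairing_string <- function(hit) {
  r1 <- rep(".", hit$length1)
  r2 <- rep(".", hit$length2)
  r1[hit$bp[, "i"] - hit$start1 + 1] <- "("
  r2[hit$bp[, "j"] - hit$start2 + 1] <- ")"
  paste0(paste(r1, collapse = ""), "&", paste(r2, collapse = ""))
}
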