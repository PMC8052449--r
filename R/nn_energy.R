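# Nearest-neighbor thermodynamic model: stacking energies, short
# internal-loop/bulge penalties, and the precomputed k-mer pair table that
# seeds the duplex search.

NTS <- c("A", "C", "G", "U")

# Admissible partners of each sense-strand nucleotide (Watson-Crick + G.U
# wobble), indexed by code 1..4 = A,C,G,U.
.PARTNERS <- list(4L, 3L, c(2L, 4L), c(1L, 3L))
.WC_PARTNER <- c(4L, 3L, 2L, 1L)

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and transcribes `T` to `U`. Characters outside `A`, `C`,
#' `G`, `U` (for example `N`) are preserved; they never pair.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @export
rna_norm <- function(x) {
  chartr("tT", "uU", toupper(x))
}

# Encode a normalized sequence as integer codes 1..4 (A,C,G,U); anything
# else becomes NA.
.encode <- function(x) {
  m <- match(strsplit(rna_norm(x), "")[[1]], NTS)
  m
}

.decode <- function(codes) paste(NTS[codes], collapse = "")

#' Is a base pair admissible?
#'
#' A pair of sense-strand nucleotides is admissible if it is Watson-Crick
#' (A-U, U-A, G-C, C-G) or a G-U wobble.
#'
#' @param left,right nucleotides (single characters), `left` on region 1,
#'   `right` on region 2, both read on the gene's sense strand. DNA input
#'   is transcribed.
#' @return logical vector.
#' @export
admissible_pair <- function(left, right) {
  l <- match(rna_norm(left), NTS)
  r <- match(rna_norm(right), NTS)
  ok <- !is.na(l) & !is.na(r)
  out <- logical(length(ok))
  out[ok] <- mapply(function(a, b) b %in% .PARTNERS[[a]], l[ok], r[ok])
  out
}

#' Is a base pair a G-U wobble?
#' @inheritParams admissible_pair
#' @return logical vector; `FALSE` for inadmissible pairs.
#' @export
is_wobble <- function(left, right) {
  l <- rna_norm(left); r <- rna_norm(right)
  admissible_pair(left, right) & ((l == "G" & r == "U") | (l == "U" & r == "G"))
}

.param_path <- function(file) {
  p <- system.file("extdata", file, package = "pccr")
  if (!nzchar(p)) stop("bundled parameter file not found: ", file)
  p
}

# 16x16 stacking matrix: rows = top-strand dinucleotide (5'->3'),
# columns = bottom-strand dinucleotide (3'->5', aligned under the top).
# Turner-2004 dG37 values; NA where the step is not admissible.
.stack_matrix <- function() {
  if (!is.null(.pccr_cache$stack)) return(.pccr_cache$stack)
  tab <- read.table(.param_path("turner2004_stacks.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  # row-major dinucleotide order (AA, AC, AG, AU, CA, ...) so that the
  # numeric id (n1-1)*4 + n2 matches the dimnames
  dn <- paste0(rep(NTS, each = 4), NTS)
  M <- matrix(NA_real_, 16, 16, dimnames = list(dn, dn))
  M[cbind(tab$top, tab$bottom)] <- tab$dg
  .pccr_cache$stack <- M
  M
}

.loop_matrix <- function() {
  if (!is.null(.pccr_cache$loop)) return(.pccr_cache$loop)
  tab <- read.table(.param_path("loop_penalties.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  mmax <- max(tab$n1, tab$n2)
  L <- matrix(NA_real_, mmax + 1, mmax + 1)
  L[cbind(tab$n1 + 1, tab$n2 + 1)] <- tab$penalty
  .pccr_cache$loop <- L
  L
}

#' Stacking free energy of a dinucleotide step
#'
#' Returns the published Turner-2004 nearest-neighbor dG37 (kcal/mol) for
#' the helix step formed by two consecutive base pairs. `pair1` and
#' `pair2` each give (left, right) nucleotides of a base pair, left on the
#' top (region 1, 5'->3') strand and right on the bottom (region 2) strand;
#' `pair2` stacks 3' of `pair1` on the top strand.
#'
#' @param pair1,pair2 character vectors of length 2: `c(left, right)`.
#' @return stacking dG37 in kcal/mol (<= 0 for all Watson-Crick steps;
#'   a few wobble-wobble steps are destabilizing).
#' @examples
#' stack_energy(c("G", "C"), c("C", "G"))  # 5'GC3'/3'CG5' = -3.42
#' stack_energy(c("A", "U"), c("A", "U"))  # 5'AA3'/3'UU5' = -0.93
#' @export
stack_energy <- function(pair1, pair2) {
  for (p in list(pair1, pair2)) {
    if (!admissible_pair(p[1], p[2]))
      stop("inadmissible base pair: ", rna_norm(p[1]), "-", rna_norm(p[2]))
  }
  top <- paste0(rna_norm(pair1[1]), rna_norm(pair2[1]))
  bottom <- paste0(rna_norm(pair1[2]), rna_norm(pair2[2]))
  unname(.stack_matrix()[top, bottom])
}

#' Penalty for a short internal loop or bulge
#'
#' Destabilizing free-energy penalty (kcal/mol) for an interruption of a
#' duplex with `n1` unpaired nucleotides on strand 1 and `n2` on strand 2.
#' The bundled table holds size-based initiation terms from the Turner-2004
#' parameter set (1- and 2-nt bulges; 1x1, 1x2, 2x2 internal loops, with
#' the asymmetry term folded into 1x2). The penalty is symmetric in
#' `(n1, n2)`; `(0, 0)` is not a loop and is an error.
#'
#' @param n1,n2 unpaired nucleotide counts, `0 <= n1, n2 <= m`.
#' @param m maximal loop size per strand (default 2).
#' @return penalty in kcal/mol (> 0).
#' @export
loop_penalty <- function(n1, n2, m = 2L) {
  if (n1 == 0 && n2 == 0) stop("(0,0) is not a loop")
  if (n1 < 0 || n2 < 0 || n1 > m || n2 > m)
    stop("loop size (", n1, ",", n2, ") outside 0..m = 0..", m)
  L <- .loop_matrix()
  if (n1 + 1 > nrow(L) || n2 + 1 > ncol(L) || is.na(L[n1 + 1, n2 + 1]))
    stop("no bundled penalty for loop (", n1, ",", n2, ")")
  L[n1 + 1, n2 + 1]
}

# integer ids (1-based) of all k-windows of an integer-coded sequence;
# window ending at position i gets index i - k + 1 in the result. NA if the
# window contains a non-ACGU character.
.kmer_ids <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  id <- rep(0, n - k + 1)
  for (t in seq_len(k)) {
    id <- id + (codes[t:(n - k + t)] - 1) * 4^(k - t)
  }
  id + 1
}

.id_to_kmer <- function(id, k) {
  id <- id - 1
  codes <- integer(k)
  for (t in k:1) {
    codes[t] <- id %% 4 + 1
    id <- id %/% 4
  }
  .decode(codes)
}

#' Precompute the k-mer pair hybridization energy table
#'
#' Enumerates all pairs of k-mers that form k consecutive admissible base
#' pairs with at most `max_gu` G-U wobbles, and stores the helix
#' hybridization energy of each pair: the sum of the k-1 nearest-neighbor
#' stacking terms. The first k-mer is read 5'->3' on region 1; the second
#' is the base-paired strand read 3'->5' (duplex orientation), aligned
#' position by position under the first. This table is the only
#' admissibility oracle the dynamic program consults.
#'
#' @param k helix seed length (2..6; default 5).
#' @param max_gu maximal number of wobble pairs per k-mer window
#'   (default 2).
#' @return an object of class `kmer_energy_table`: list with elements
#'   `k`, `max_gu` and `energies`, a `4^k x 4^k` matrix indexed by k-mer
#'   code with NA marking inadmissible pairs.
#' @examples
#' tab <- build_kmer_table(2, 0)
#' sum(!is.na(tab$energies))  # 16: one Watson-Crick partner per dimer
#' @export
build_kmer_table <- function(k = 5L, max_gu = 2L) {
  k <- as.integer(k); max_gu <- as.integer(max_gu)
  if (k < 2 || k > 6) stop("k must be in 2..6")
  if (max_gu < 0) stop("max_gu must be >= 0")
  key <- paste0("kt_", k, "_", max_gu)
  if (!is.null(.pccr_cache[[key]])) return(.pccr_cache[[key]])

  nk <- 4^k
  # all top k-mers as a code matrix (row = k-mer id)
  tops <- as.matrix(expand.grid(rev(replicate(k, 1:4, simplify = FALSE)))[, k:1])
  dimnames(tops) <- NULL
  SM <- .stack_matrix()

  M <- matrix(NA_real_, nk, nk)
  gu_possible <- tops == 3L | tops == 4L  # wobble only where top is G or U
  for (w in 0:min(max_gu, k)) {
    combos <- if (w == 0) list(integer(0)) else
      utils::combn(k, w, simplify = FALSE)
    for (pos in combos) {
      keep <- if (w == 0) rep(TRUE, nk) else
        rowSums(gu_possible[, pos, drop = FALSE]) == w
      if (!any(keep)) next
      t2 <- tops[keep, , drop = FALSE]
      bottoms <- matrix(.WC_PARTNER[t2], nrow(t2), k)
      if (w > 0) {
        # wobble partner: G pairs U (code 4), U pairs G (code 3)
        for (p in pos) bottoms[, p] <- ifelse(t2[, p] == 3L, 4L, 3L)
      }
      # energy = sum of k-1 stacks, via 16x16 dinucleotide lookup
      e <- rep(0, nrow(t2))
      bad <- rep(FALSE, nrow(t2))
      for (t in seq_len(k - 1)) {
        dt <- (t2[, t] - 1) * 4 + t2[, t + 1]
        db <- (bottoms[, t] - 1) * 4 + bottoms[, t + 1]
        s <- SM[cbind(dt, db)]
        bad <- bad | is.na(s)
        e <- e + ifelse(is.na(s), 0, s)
      }
      topid <- .kmer_code(t2)
      botid <- .kmer_code(bottoms)
      ok <- !bad
      M[cbind(topid[ok], botid[ok])] <- e[ok]
    }
  }
  out <- structure(list(k = k, max_gu = max_gu, energies = M),
                   class = "kmer_energy_table")
  .pccr_cache[[key]] <- out
  out
}

# k-mer id from a code matrix (rows = k-mers)
.kmer_code <- function(mat) {
  k <- ncol(mat)
  id <- rep(0, nrow(mat))
  for (t in seq_len(k)) id <- id + (mat[, t] - 1) * 4^(k - t)
  id + 1
}

#' @export
print.kmer_energy_table <- function(x, ...) {
  cat("k-mer energy table: k =", x$k, ", max_gu =", x$max_gu,
      ",", sum(!is.na(x$energies)), "admissible pairs\n")
  invisible(x)
}

#' @export
#' @method as.data.frame kmer_energy_table
as.data.frame.kmer_energy_table <- function(x, ...) {
  idx <- which(!is.na(x$energies), arr.ind = TRUE)
  data.frame(
    kmer1 = vapply(idx[, 1], .id_to_kmer, "", k = x$k),
    kmer2 = vapply(idx[, 2], .id_to_kmer, "", k = x$k),
    energy = x$energies[idx],
    stringsAsFactors = FALSE
  )
}

#' Write / read a k-mer table cache
#'
#' Serializes the admissible entries to a plain TSV with a header line
#' carrying `k` and `max_gu`, and reads it back bit-exactly.
#'
#' @param table a `kmer_energy_table`.
#' @param path file path.
#' @return `read_kmer_table` returns the reconstructed table.
#' @export
write_kmer_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d max_gu=%d", table$k, table$max_gu), con)
  df <- as.data.frame(table)
  df$energy <- sprintf("%.10g", df$energy)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("k=(\\d+) max_gu=(\\d+)", hdr))[[1]]
  if (length(m) != 3) stop("not a k-mer table cache: ", path)
  k <- as.integer(m[2]); max_gu <- as.integer(m[3])
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1,
                   colClasses = c("character", "character", "numeric"))
  M <- matrix(NA_real_, 4^k, 4^k)
  i1 <- .kmer_code(matrix(match(unlist(strsplit(df$kmer1, "")), NTS),
                          nrow(df), k, byrow = TRUE))
  i2 <- .kmer_code(matrix(match(unlist(strsplit(df$kmer2, "")), NTS),
                          nrow(df), k, byrow = TRUE))
  M[cbind(i1, i2)] <- df$energy
  structure(list(k = k, max_gu = max_gu, energies = M),
            class = "kmer_energy_table")
}

#' Free energy of a duplex structure by direct summation
#'
#' Independent oracle for the dynamic program: sums the nearest-neighbor
#' stacking terms over consecutive base pairs within helices and adds the
#' loop penalty for every inter-helix gap. The reported energy contains no
#' duplex-initiation or terminal-AU terms (pure-extension convention).
#'
#' @param bp integer matrix with columns `i`, `j`: ordered base pairs,
#'   `i` (position in `seq1`) strictly increasing, `j` (position in
#'   `seq2`) strictly decreasing (antiparallel duplex); 1-based.
#' @param seq1,seq2 sense-strand sequences (character scalars).
#' @param k minimal helix length for grammar validation (default 5).
#' @param m maximal loop size per strand (default 2).
#' @param max_gu maximal wobbles per k-window (default 2).
#' @param check validate the structure against the grammar (default TRUE).
#' @return free energy in kcal/mol.
#' @export
duplex_energy <- function(bp, seq1, seq2, k = 5L, m = 2L, max_gu = 2L,
                          check = TRUE) {
  bp <- .as_bp_matrix(bp)
  s1 <- .encode(seq1); s2 <- .encode(seq2)
  n <- nrow(bp)
  if (n == 0) stop("empty structure")
  i <- bp[, 1]; j <- bp[, 2]
  if (check) {
    if (any(diff(i) <= 0) || any(diff(j) >= 0))
      stop("base pairs must have i strictly increasing, j strictly decreasing")
    if (any(i < 1 | i > length(s1) | j < 1 | j > length(s2)))
      stop("base pair outside sequences")
    pl <- s1[i]; pr <- s2[j]
    if (any(is.na(pl) | is.na(pr)))
      stop("base pair on non-ACGU nucleotide")
    okp <- mapply(function(a, b) b %in% .PARTNERS[[a]], pl, pr)
    if (!all(okp)) stop("inadmissible base pair at position ", which(!okp)[1])
  }
  # split into helices: maximal runs of consecutive pairs (i+1, j-1)
  brk <- which(diff(i) != 1 | diff(j) != -1)
  starts <- c(1, brk + 1)
  ends <- c(brk, n)
  if (check) {
    if (any(ends - starts + 1 < k))
      stop("helix shorter than k = ", k)
    if (length(starts) > 1) {
      a <- i[starts[-1]] - i[ends[-length(ends)]] - 1
      b <- j[ends[-length(ends)]] - j[starts[-1]] - 1
      if (any(a > m | b > m | (a == 0 & b == 0)))
        stop("inter-helix gap violates loop bounds")
    }
    # per-window wobble constraint inside every helix
    wob <- is_wobble(NTS[s1[i]], NTS[s2[j]])
    for (h in seq_along(starts)) {
      w <- wob[starts[h]:ends[h]]
      if (length(w) >= k) {
        win <- stats::filter(as.numeric(w), rep(1, k), sides = 1)[k:length(w)]
        if (any(win > max_gu))
          stop("a k-window exceeds max_gu = ", max_gu, " wobble pairs")
      }
    }
  }
  SM <- .stack_matrix()
  e <- 0
  for (h in seq_along(starts)) {
    idx <- starts[h]:ends[h]
    if (length(idx) > 1) {
      t1 <- idx[-length(idx)]
      dt <- (s1[i[t1]] - 1) * 4 + s1[i[t1] + 1]
      db <- (s2[j[t1]] - 1) * 4 + s2[j[t1] - 1]
      st <- SM[cbind(dt, db)]
      if (check && any(is.na(st))) stop("inadmissible stacking step")
      e <- e + sum(st)
    }
  }
  if (length(starts) > 1) {
    for (h in seq_len(length(starts) - 1)) {
      a <- i[starts[h + 1]] - i[ends[h]] - 1
      b <- j[ends[h]] - j[starts[h + 1]] - 1
      e <- e + loop_penalty(a, b, m = m)
    }
  }
  e
}

.as_bp_matrix <- function(bp) {
  bp <- as.matrix(bp)
  if (ncol(bp) != 2) stop("base pairs must be a 2-column (i, j) matrix")
  storage.mode(bp) <- "integer"
  bp
}
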