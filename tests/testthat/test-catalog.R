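# Catalog orchestration and annotation

test_that("CIR pair enumeration respects the distance limit", {
  mk <- function(starts, w = 20) GRanges("chr1", IRanges(starts, width = w))
  far <- mk(c(1000, 16020))
  expect_equal(nrow(enumerate_cir_pairs(far, L = 10000)), 2)  # self-pairs only
  expect_equal(sum(enumerate_cir_pairs(far, L = 10000)$idx1 !=
                     enumerate_cir_pairs(far, L = 10000)$idx2), 0)
  adj <- mk(c(1000, 1020))
  pp <- enumerate_cir_pairs(adj, L = 10000)
  expect_true(any(pp$idx1 == 1 & pp$idx2 == 2))  # gap 0 pairs
  five <- mk(seq(1000, by = 500, length.out = 5))
  expect_equal(nrow(enumerate_cir_pairs(five, L = 10000)), 15)
})

test_that("relative position follows the corrected formula", {
  gene_p <- GRanges("chr1", IRanges(101, 1100), strand = "+")
  gene_m <- GRanges("chr1", IRanges(101, 1100), strand = "-")
  at5 <- GRanges("chr1", IRanges(101, 110))
  at3 <- GRanges("chr1", IRanges(1091, 1100))
  expect_equal(relative_position(at5, gene_p), 0)
  expect_equal(relative_position(at3, gene_p), 990 / 991)
  expect_equal(relative_position(at3, gene_m), 1 - 990 / 991)
  expect_equal(relative_position(at5, gene_m), 1)
  expect_error(relative_position(GRanges("chr1", IRanges(50, 60)), gene_p),
               "outside")
})

test_that("conservation metrics behave on constant and step tracks", {
  ccr <- GRanges("chrT", IRanges(1001, 1050))
  cir <- GRanges("chrT", IRanges(901, 1200))
  const <- GRanges("chrT", IRanges(1, 2000))
  const$score <- 0.7
  s <- conservation_scores(ccr, cir, const)
  expect_equal(unname(s["s1"]), 0)
  expect_equal(unname(s["s2"]), 0.7)
  expect_equal(unname(s["s3"]), 50 / 300)
  step <- GRanges("chrT", IRanges(1001, 1050))
  step$score <- 1
  s2 <- conservation_scores(ccr, cir, step)
  expect_equal(unname(s2["s1"]), 1)
  s3 <- conservation_scores(cir, cir, const)
  expect_equal(unname(s3["s3"]), 1)
})

test_that("energy groups follow the published bins", {
  expect_equal(assign_energy_group(c(-19.80, -25.70, -35.9)),
               c("I", "III", "IV"))
  # bin edges: each boundary belongs to the weaker-numbered side
  expect_equal(assign_energy_group(c(-15, -20, -25, -30)),
               c("I", "II", "III", "IV"))
  expect_equal(assign_energy_group(c(-19.99, -20.01)), c("I", "II"))
  expect_error(assign_energy_group(-14.9), "threshold")
})

test_that("a planted panhandle is recovered and a weak one is not", {
  # one gene, two conserved islands; plant core of known energy
  core <- "GGCGCCATGGCGCC"          # 14 WC pairs, strongly stable
  g <- GRanges("chrT", IRanges(1, 3000), strand = "+")
  g$gene_id <- "G1"; g$biotype <- "protein_coding"
  e <- GRanges("chrT", IRanges(c(1, 2901), c(100, 3000)), strand = "+")
  e$gene_id <- "G1"; e$biotype <- "protein_coding"
  set.seed(9)
  chrom <- sample(c("A", "C", "G", "T"), 3000, TRUE)
  put <- function(chrom, s, txt) {
    chrom[(s - 7):(s - 1)] <- "A"
    chrom[s:(s + nchar(txt) - 1)] <- strsplit(txt, "")[[1]]
    chrom[(s + nchar(txt)):(s + nchar(txt) + 6)] <- "A"
    chrom
  }
  chrom <- put(chrom, 501, core)
  chrom <- put(chrom, 1701, RC(core))
  genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
  names(genome) <- "chrT"
  cons <- GRanges("chrT", IRanges(c(480, 1680), c(540, 1740)))
  cirs <- build_cirs(g, e, cons)
  expect_length(cirs, 2)
  catalog <- scan_gene(g, cirs, genome)
  expect_equal(nrow(catalog), 1)
  expect_equal(catalog$start1, 501)
  expect_equal(catalog$end1, 514)
  expect_equal(catalog$start2, 1701)
  expect_equal(catalog$end2, 1714)
  oracle <- duplex_energy(cbind(1:14, 14:1), core, RC(core))
  expect_equal(catalog$dG, oracle, tolerance = 1e-9)
  expect_equal(catalog$spread, 1701 - 514 - 1)
  expect_equal(catalog$gc, 12 / 14)  # paired-nucleotide GC of the core

  # a weak plant (about -12.5 kcal/mol) is not reported at -15
  weak <- "GATTATAATC"
  expect_lt(duplex_energy(cbind(1:10, 10:1), weak, RC(weak)), -10)
  expect_gt(duplex_energy(cbind(1:10, 10:1), weak, RC(weak)), -15)
  chrom2 <- sample(c("A", "C", "G", "T"), 3000, TRUE)
  chrom2 <- put(chrom2, 501, weak)
  chrom2 <- put(chrom2, 1701, RC(weak))
  genome2 <- Biostrings::DNAStringSet(paste(chrom2, collapse = ""))
  names(genome2) <- "chrT"
  cirs2 <- build_cirs(g, e, cons)
  expect_equal(nrow(scan_gene(g, cirs2, genome2)), 0)
})

test_that("a plant spanning a splice site via the exonic extension is found", {
  core <- "GGCGCCATGGCGCC"
  g <- GRanges("chrT", IRanges(1, 3000), strand = "+")
  g$gene_id <- "G1"; g$biotype <- "protein_coding"
  # intron is [101, 2900]; place the left region so it ends 8 nt into
  # the downstream exon (positions 2893..2906 with exon at 2901)
  e <- GRanges("chrT", IRanges(c(1, 2901), c(100, 3000)), strand = "+")
  e$gene_id <- "G1"; e$biotype <- "protein_coding"
  set.seed(10)
  chrom <- sample(c("A", "C", "G", "T"), 3000, TRUE)
  put <- function(chrom, s, txt) {
    chrom[(s - 7):(s - 1)] <- "A"
    chrom[s:(s + nchar(txt) - 1)] <- strsplit(txt, "")[[1]]
    chrom[(s + nchar(txt)):(s + nchar(txt) + 6)] <- "A"
    chrom
  }
  chrom <- put(chrom, 501, core)
  chrom <- put(chrom, 2893, RC(core))
  genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
  names(genome) <- "chrT"
  cons <- GRanges("chrT", IRanges(c(480, 2870), c(540, 2910)))
  cirs <- build_cirs(g, e, cons)
  catalog <- scan_gene(g, cirs, genome)
  expect_equal(nrow(catalog), 1)
  expect_equal(catalog$start2, 2893)
  expect_equal(catalog$end2, 2906)  # 6 nt beyond the splice site
})

test_that("catalog round-trips through TSV and BED12 blocks are paired", {
  sf <- small_fixture()
  catalog <- sf$catalog
  expect_gt(nrow(catalog), 0)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_catalog(catalog, bed_path = bed, tsv_path = tsv)
  back <- read_catalog(tsv)
  expect_equal(back, catalog, tolerance = 1e-9)
  bed_lines <- strsplit(readLines(bed), "\t")
  expect_true(all(vapply(bed_lines, length, 0L) == 12))
  expect_true(all(vapply(bed_lines, `[[`, "", 10) == "2"))
  # empty catalog: header-only TSV, empty BED
  tsv0 <- tempfile(); bed0 <- tempfile()
  write_catalog(catalog[0, ], bed_path = bed0, tsv_path = tsv0)
  expect_equal(nrow(read_catalog(tsv0)), 0)
  expect_length(readLines(bed0), 0)
})

test_that("every cataloged PCCR obeys the search thresholds", {
  sf <- small_fixture()
  catalog <- sf$catalog
  expect_true(all(catalog$dG <= -15))
  expect_true(all(pmin(catalog$length1, catalog$length2) >= 10))
  expect_true(all(catalog$spread >= 0 & catalog$spread <= 10000))
  expect_true(all(catalog$rel_pos >= 0 & catalog$rel_pos <= 1))
  # deterministic: rescanning reproduces the catalog
  again <- pccr_scan(sf$fix$genes, sf$cirs, sf$fix$genome)
  expect_identical(catalog, again)
})
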