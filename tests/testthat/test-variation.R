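# Polymorphism statistics, E-value aggregation, Stockholm export

test_that("SNP density test compares merged region sets", {
  ccr <- GRanges("chrT", IRanges(c(1, 101), width = 100))      # 200 nt
  bg <- GRanges("chrT", IRanges(1001, width = 1000))
  snvs_eq <- data.frame(chrom = "chrT",
                        pos = c(seq(1, 200, by = 50),
                                seq(1001, 2000, by = 50)))
  res <- snp_density_test(snvs_eq, ccr, bg)
  expect_equal(res$density_ccr, 4 / 200)
  expect_equal(res$density_bg, 20 / 1000)
  expect_gt(res$p_value, 0.2)
  # strong depletion in CCR
  dep <- snp_density_test(data.frame(chrom = "chrT",
                                     pos = seq(1001, 2000, by = 10)),
                          ccr, bg)
  expect_lt(dep$p_value, 1e-3)
  expect_error(snp_density_test(snvs_eq, GRanges(), bg), "zero-length")
})

test_that("planted SNP depletion is detected reliably", {
  set.seed(11)
  hits <- 0
  for (rep in 1:20) {
    n_ccr <- rpois(1, 0.018 * 5e4)   # 10% depleted
    n_bg <- rpois(1, 0.020 * 5e4)
    ccr <- GRanges("chrT", IRanges(1, 5e4))
    bg <- GRanges("chrT", IRanges(1e5, width = 5e4))
    snvs <- data.frame(chrom = "chrT",
                       pos = c(sample(5e4, n_ccr),
                               1e5 - 1 + sample(5e4, n_bg)))
    p <- snp_density_test(snvs, ccr, bg)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 10)  # one-sided test has power under a 10% depletion
})

# a catalog record over an explicit genome for energy-based SNV tests
ddg_fixture <- function() {
  core <- "GGCGCCATGG"
  s2 <- RC(core)
  chrom <- paste0(strrep("A", 100), core, strrep("A", 300), s2,
                  strrep("A", 100))
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chrT"
  bp_left <- 101:110
  bp_right <- 420:411
  rec <- data.frame(gene_id = "G1", chrom = "chrT", strand = "+",
                    start1 = 101, end1 = 110, start2 = 411, end2 = 420,
                    dG = duplex_energy(cbind(1:10, 10:1), core, s2),
                    length1 = 10, length2 = 10, length_avg = 10,
                    spread = 300, n_bp = 10, gc = 0.7,
                    structure = paste(bp_left, sort(bp_right),
                                      sep = ":", collapse = ","),
                    energy_group = "IV", rel_pos = 0.5, id = "PCCR000001",
                    stringsAsFactors = FALSE)
  # structure must pair left ascending with right descending
  rec$structure <- paste(bp_left, bp_right, sep = ":", collapse = ",")
  list(rec = rec, genome = genome, core = core)
}

test_that("reference 'mutation' gives zero energy change", {
  fx <- ddg_fixture()
  res <- snp_ddg(fx$rec, 105, ref = "C", alt = "C", genome = fx$genome)
  expect_equal(res$ddg, 0)
  expect_true(all(res$null == 0))
})

test_that("disrupting a central G-C pair destabilizes the duplex", {
  fx <- ddg_fixture()
  # position 105 carries C (sense +); C->A breaks the pair
  res <- snp_ddg(fx$rec, 105, ref = "C", alt = "A", genome = fx$genome)
  expect_gt(res$ddg, 2)
  expect_equal(res$n_null, length(res$null))
  expect_gt(res$n_null, 0)
  # SNV outside paired positions is skipped
  expect_null(snp_ddg(fx$rec, 150, "A", "G", fx$genome))
  # no alternative position carrying the ref allele: empty null
  # (position 107 is the only A in the left CCR)
  res2 <- snp_ddg(fx$rec, 107, ref = "A", alt = "G", genome = fx$genome)
  expect_equal(res2$n_null, 0)
})

test_that("compensatory counting distinguishes restored pairs", {
  bp_tab <- data.frame(
    id = "P1", gene_id = "G1", chrom = "chrT", strand = "+",
    gpos1 = c(10, 20, 30), gpos2 = c(110, 120, 130),
    sense1 = c("A", "G", "C"), sense2 = c("T", "C", "G"),
    pair_type = c("AT", "GC", "CG"), stringsAsFactors = FALSE)
  # pair 1: compensatory A->G / T->C (G-C); pair 2: one-sided;
  # pair 3: both sides but incompatible alts (T-T)
  snvs <- data.frame(chrom = "chrT",
                     pos = c(10, 110, 20, 30, 130),
                     ref = c("A", "T", "G", "C", "G"),
                     alt = c("G", "C", "A", "T", "T"),
                     af = c(0.05, 0.05, 0.05, 0.05, 0.05))
  res <- compensatory_counts(bp_tab, snvs)
  expect_equal(res$n_bp_with_snp, 3)
  expect_equal(res$n_compensatory, 1)
  expect_equal(res$density, 1 / 3)
  # allele-frequency cutoff
  snvs$af <- 0.005
  res2 <- compensatory_counts(bp_tab, snvs)
  expect_equal(res2$n_bp_with_snp, 0)
  expect_equal(compensatory_counts(bp_tab, snvs[0, ])$n_compensatory, 0)
})

test_that("minus-strand alleles are complemented before pairing", {
  bp_tab <- data.frame(
    id = "P1", gene_id = "G1", chrom = "chrT", strand = "-",
    gpos1 = 10, gpos2 = 110,
    sense1 = "A", sense2 = "T", pair_type = "AT",
    stringsAsFactors = FALSE)
  # plus-strand alleles C (= sense G) and G (= sense C): compensatory
  snvs <- data.frame(chrom = "chrT", pos = c(10, 110),
                     ref = c("T", "A"), alt = c("C", "G"),
                     af = c(0.05, 0.05))
  expect_equal(compensatory_counts(bp_tab, snvs)$n_compensatory, 1)
})

test_that("re-wiring permutes within groups and preserves composition", {
  bp_tab <- data.frame(
    id = "P1", gene_id = "G1", chrom = "chrT", strand = "+",
    gpos1 = seq(10, 100, by = 10), gpos2 = seq(1010, 1100, by = 10),
    sense1 = "A", sense2 = "T", pair_type = "AT",
    stringsAsFactors = FALSE)
  snvs <- data.frame(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     af = numeric(0))
  rw <- rewire_basepairs(bp_tab, snvs, seed = 12)
  expect_setequal(rw$gpos2, bp_tab$gpos2)
  expect_equal(sort(rw$pair_type), sort(bp_tab$pair_type))
  # singleton group unchanged
  single <- bp_tab[1, ]
  expect_identical(rewire_basepairs(single, snvs, seed = 1), single)
  # two-pair group swaps about half the time
  two <- bp_tab[1:2, ]
  swapped <- vapply(1:400, function(s)
    rewire_basepairs(two, snvs, seed = s)$gpos2[1] == two$gpos2[2], TRUE)
  expect_gt(mean(swapped), 0.4)
  expect_lt(mean(swapped), 0.6)
})

test_that("planted compensatory signal beats the re-wired null", {
  # 12 compensatory pairs (left alt G, right alt C) among 60 pairs whose
  # both-sided SNVs cannot re-pair (left alt C, right alt A)
  n_comp <- 12; n_bad <- 60
  bp_tab <- data.frame(
    id = "P1", gene_id = "G1", chrom = "chrT", strand = "+",
    gpos1 = seq_len(n_comp + n_bad) * 10,
    gpos2 = 10000 + seq_len(n_comp + n_bad) * 10,
    sense1 = "A", sense2 = "T", pair_type = "AT",
    stringsAsFactors = FALSE)
  mk_snv <- function(pos, ref, alt) data.frame(chrom = "chrT", pos = pos,
                                               ref = ref, alt = alt,
                                               af = 0.05)
  idx_comp <- seq_len(n_comp)
  idx_bad <- n_comp + seq_len(n_bad)
  snvs <- rbind(mk_snv(bp_tab$gpos1[idx_comp], "A", "G"),
                mk_snv(bp_tab$gpos2[idx_comp], "T", "C"),
                mk_snv(bp_tab$gpos1[idx_bad], "A", "C"),
                mk_snv(bp_tab$gpos2[idx_bad], "T", "A"))
  res <- compensatory_null(bp_tab, snvs, n = 100, seed = 13)
  expect_equal(res$observed$n_compensatory, n_comp)
  expect_lt(mean(res$null_counts), n_comp / 2)
  expect_lt(res$p_value, 0.01)
})

test_that("E values aggregate multiplicatively with BH adjustment", {
  per <- data.frame(pccr_id = c("P1", "P1", "P1", "P2", "P3"),
                    evalue = c(0.1, 0.01, 0.9, 0.5, 2),
                    significant = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  agg <- aggregate_evalues(per)
  expect_equal(agg$evalue[agg$pccr_id == "P1"], 0.001)
  expect_equal(agg$evalue[agg$pccr_id == "P2"], 1)   # empty product
  expect_equal(agg$evalue[agg$pccr_id == "P3"], 2)
  expect_true(is.na(agg$evalue_adj[agg$pccr_id == "P3"]))
  # BH agrees with the reference implementation on the < 1 subset
  per10 <- data.frame(pccr_id = sprintf("Q%02d", 1:10),
                      evalue = c(0.001, rep(0.9, 9)),
                      significant = TRUE)
  agg10 <- aggregate_evalues(per10)
  expect_equal(agg10$evalue_adj, p.adjust(per10$evalue, "BH"))
  # order invariance
  shuf <- per[c(5, 3, 1, 4, 2), ]
  agg_s <- aggregate_evalues(shuf)
  expect_equal(agg_s$evalue[match(agg$pccr_id, agg_s$pccr_id)],
               agg$evalue)
  expect_error(aggregate_evalues(data.frame(pccr_id = "P", evalue = -1,
                                            significant = TRUE)),
               "negative")
})

test_that("Stockholm export merges blocks through a 10-A spacer", {
  taxa <- sprintf("sp%02d", 1:16)
  b1 <- setNames(rep(strrep("G", 12), 16), taxa)
  b2 <- setNames(rep(strrep("C", 9), 16), taxa)
  st <- cbind(1:5, 9:5)
  out <- export_stockholm(b1, b2, st)
  parsed <- read_stockholm(out)
  expect_equal(unique(nchar(parsed$seqs)), 12 + 10 + 9)
  expect_equal(sum(strsplit(parsed$ss_cons, "")[[1]] == "<"), 5)
  expect_equal(sum(strsplit(parsed$ss_cons, "")[[1]] == ">"), 5)
  # spacer columns unpaired
  expect_equal(substr(parsed$ss_cons, 13, 22), strrep(".", 10))
  # a row with an indel is dropped from both blocks
  b1g <- b1; b1g["sp01"] <- paste0(strrep("G", 11), "-")
  b2x <- b2[names(b2) != "sp01"]
  out2 <- export_stockholm(b1g, b2x, st, min_rows = 15)
  expect_length(read_stockholm(out2)$seqs, 15)
  # taxa mismatch is an error naming the offender
  b2bad <- b2; names(b2bad)[1] <- "spXX"
  expect_error(export_stockholm(b1, b2bad, st), "spXX")
  # file round trip
  f <- tempfile()
  export_stockholm(b1, b2, st, path = f)
  expect_equal(read_stockholm(f)$ss_cons, parsed$ss_cons)
})

test_that("VCF parsing splits multi-allelic records and keeps AF", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrT\t100\t.\tA\tG\t.\tPASS\tAF=0.05",
               "chrT\t200\t.\tC\tA,T\t.\tPASS\tAF=0.02,0.01",
               "chrT\t300\t.\tAT\tA\t.\tPASS\tAF=0.3"), f)
  snvs <- read_snv_vcf(f)
  expect_equal(nrow(snvs), 3)  # indel dropped, multi-allelic split
  expect_equal(snvs$af, c(0.05, 0.02, 0.01))
  f2 <- tempfile(fileext = ".vcf")
  write_snv_vcf(snvs, f2)
  expect_equal(`rownames<-`(read_snv_vcf(f2), NULL),
               `rownames<-`(snvs, NULL))
})
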