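# Splicing statistics and candidate detection

test_that("PSI follows the split-read formula with the denominator filter", {
  expect_equal(psi(8, 1), 0.8)
  expect_equal(psi(0, 5), 0)
  expect_true(is.na(psi(4, 2)))      # denominator 8 < 10
  expect_equal(psi(10, 0), 1)
  expect_error(psi(-1, 2), "negative")
  # monotone in inc, antitone in exc
  set.seed(14)
  for (r in 1:20) {
    inc <- sample(10:50, 1); exc <- sample(0:20, 1)
    expect_gte(psi(inc + 1, exc), psi(inc, exc))
    expect_lte(psi(inc, exc + 1, min_denominator = 1),
               psi(inc, exc, min_denominator = 1))
  }
})

test_that("splice-site activity classes pick the support tails", {
  sites <- data.frame(position = 1:100, support = 3:102)
  cl <- classify_splice_sites(sites)
  expect_equal(sites$position[cl$class == "active"], c(99, 100))
  expect_equal(sites$position[cl$class == "inactive"], c(1, 2))
  # below the support floor nothing is classified
  low <- data.frame(position = 1:10, support = rep(2, 10))
  expect_true(all(classify_splice_sites(low)$class == "none"))
  # deterministic tie-break by position: input order is irrelevant
  tie <- data.frame(position = 1:50, support = rep(7, 50))
  c1 <- classify_splice_sites(tie)
  shuf <- tie[sample(50), ]
  c2 <- classify_splice_sites(shuf)
  expect_identical(c2$class[order(shuf$position)],
                   c1$class[order(tie$position)])
})

test_that("cryptic sites pass thresholds and exclusion lists", {
  cand <- data.frame(position = c(10, 20, 30, 40),
                     side = c("donor", "acceptor", "donor", "acceptor"),
                     score = c(801, 951, 799, 960))
  out <- cryptic_sites(cand, expressed = integer(0), annotated = 40)
  expect_equal(out$position, c(10, 20))
  expect_equal(nrow(cryptic_sites(cand[0, ])), 0)
  out2 <- cryptic_sites(cand, expressed = 10)
  expect_false(10 %in% out2$position)
})

test_that("intron matching yields calibrated ORs under random labels", {
  set.seed(15)
  introns <- GRanges("chrT", IRanges(seq(1, by = 3000, length.out = 300),
                                     width = sample(500:2500, 300, TRUE)))
  # random catalog: PCCRs inside ~half of the introns, independent of ends
  host <- sample(300, 120)
  catalog <- do.call(rbind, lapply(seq_along(host), function(i) {
    s <- start(introns)[host[i]] + 20
    toy_catalog(n = 1, start = s, spread = 100, len = 12)
  }))
  catalog$id <- sprintf("PCCR%06d", seq_len(nrow(catalog)))
  ends <- GRanges("chrT", IRanges(sample(900000, 500), width = 1))
  m <- match_iwp_iwo(introns, catalog, features = list(e = ends),
                     seed = 16)
  expect_equal(length(m$iwp), length(m$iwo))
  expect_gt(length(m$iwp), 20)
  # length matching: same bin profile
  expect_equal(table(floor(log10(width(m$iwp)) / 0.1)),
               table(floor(log10(width(m$iwo)) / 0.1)))
  o <- m$tables$e
  expect_true(is.na(o$or) || (o$or > 0.4 && o$or < 2.5))
  # empty feature set flagged
  m0 <- match_iwp_iwo(introns, catalog, features = list(x = GRanges()),
                      seed = 16)
  expect_true(is.na(m0$tables$x$or))
})

test_that("looped-out exons show the planted inclusion shift", {
  catalog <- toy_catalog(n = 30, spread = 600, gap_between = 3000)
  # exons inside the loops of the first 20 records; free exons elsewhere
  ex_loop <- GRanges("chrT", IRanges(catalog$end1[1:20] + 100, width = 80))
  ex_free <- GRanges("chrT", IRanges(catalog$end2 + 500, width = 80))
  exons <- c(ex_loop, ex_free)
  exons$exon_id <- sprintf("E%03d", seq_along(exons))
  quants <- toy_junctions(exons$exon_id, looped_ids = exons$exon_id[1:20],
                          psi_looped = 0.55, psi_free = 0.85, seed = 17)
  res <- loopout_psi_comparison(exons, catalog, quants)
  g1 <- res[res$group == catalog$energy_group[1], ]
  expect_gt(g1$n, 10)
  expect_lt(g1$p_value, 0.05)
  # all exons looped: control group empty
  expect_error(loopout_psi_comparison(exons[1:20], catalog, quants),
               "control")
})

test_that("structure support metrics match their definitions", {
  catalog <- toy_catalog(n = 4)
  pairs_same <- catalog[, c("chrom", "start1", "end1", "start2", "end2")]
  s <- structure_support(catalog, pairs_same)
  expect_equal(unname(s["P"]), 100)
  expect_equal(unname(s["R"]), 100)
  expect_equal(unname(s["pi"]), 100)
  pairs_far <- data.frame(chrom = "chrT", start1 = 900000, end1 = 900050,
                          start2 = 901000, end2 = 901050)
  s0 <- structure_support(catalog, pairs_far)
  expect_equal(unname(s0["P"]), 0)
  expect_equal(unname(s0["R"]), 0)
  # one-sided overlap: P = 0 but the pi denominator is populated
  pairs_one <- data.frame(chrom = "chrT", start1 = catalog$start1,
                          end1 = catalog$end1, start2 = 900000 + 1:4,
                          end2 = 900020 + 1:4)
  s1 <- structure_support(catalog, pairs_one)
  expect_equal(unname(s1["P"]), 0)
  expect_equal(unname(s1["pi"]), 0)
  expect_error(structure_support(catalog, pairs_same[0, ]), "empty")
  # invariance to record order
  s_perm <- structure_support(catalog[4:1, ], pairs_same)
  expect_equal(s_perm, s)
})

test_that("benchmark score is the fraction of S1 found in S2", {
  S <- cbind(1:10, 101:110)
  expect_equal(benchmark_score(S, S), 1)
  expect_equal(benchmark_score(S, S + 1000), 0)
  expect_equal(benchmark_score(S, S[1:8, ]), 0.8)
  expect_error(benchmark_score(S[0, ], S), "empty")
})

test_that("RNA bridges require peak, exon, and significant response", {
  catalog <- toy_catalog(n = 1, start = 5000, spread = 800, len = 15)
  rec <- catalog[1, ]
  pk_ok <- GRanges("chrT", IRanges(rec$end1 + 30, width = 10))
  pk_ok$rbp <- "RBFOX2"
  pk_far <- GRanges("chrT", IRanges(rec$end1 + 51 + 10, width = 10))
  pk_far$rbp <- "RBFOX2"
  ex <- GRanges("chrT", IRanges(rec$end2 + 40, width = 60))
  ex$exon_id <- "E001"
  kd <- data.frame(exon_id = "E001", rbp = "RBFOX2",
                   delta_psi = -0.43, q = 0.001)
  out <- detect_rna_bridges(catalog, pk_ok, ex, kd)
  expect_equal(nrow(out), 1)
  expect_equal(out$delta_psi, -0.43)
  expect_equal(nrow(detect_rna_bridges(catalog, pk_far, ex, kd)), 0)
  kd_ns <- transform(kd, q = 0.5)
  expect_equal(nrow(detect_rna_bridges(catalog, pk_ok, ex, kd_ns)), 0)
  # significant exon but no peak near the mate CCR
  expect_equal(nrow(detect_rna_bridges(catalog, pk_ok[0], ex, kd)), 0)
})

test_that("exon loop-outs require a surrounded exon and an on-CCR peak", {
  catalog <- toy_catalog(n = 1, start = 5000, spread = 800, len = 15)
  rec <- catalog[1, ]
  pk_on <- GRanges("chrT", IRanges(rec$start1 + 2, width = 8))
  pk_on$rbp <- "QKI"
  pk_off <- GRanges("chrT", IRanges(rec$end1 + 200, width = 8))
  pk_off$rbp <- "QKI"
  ex_in <- GRanges("chrT", IRanges(rec$end1 + 300, width = 80))
  ex_in$exon_id <- "E001"
  ex_out <- GRanges("chrT", IRanges(rec$end2 + 300, width = 80))
  ex_out$exon_id <- "E002"
  kd <- data.frame(exon_id = c("E001", "E002"), rbp = "QKI",
                   delta_psi = -0.56, q = 0.002)
  out <- detect_loopouts(catalog, pk_on, c(ex_in, ex_out), kd)
  expect_equal(nrow(out), 1)
  expect_equal(out$exon_id, "E001")
  expect_equal(out$delta_psi, -0.56)
  expect_equal(nrow(detect_loopouts(catalog, pk_off, ex_in, kd)), 0)
  kd_ns <- transform(kd, q = 0.05)
  expect_equal(nrow(detect_loopouts(catalog, pk_on, ex_in, kd_ns)), 0)
})

test_that("reactivity depression tracks energy groups", {
  catalog <- rbind(toy_catalog(n = 6, dG = -17, start = 1000),
                   toy_catalog(n = 6, dG = -33, start = 40000))
  catalog$id <- sprintf("PCCR%06d", seq_len(nrow(catalog)))
  cirs <- GRanges("chrT", IRanges(c(catalog$start1 - 50,
                                    catalog$start2 - 50),
                                  c(catalog$end1 + 50,
                                    catalog$end2 + 50)))
  cirs$gene_id <- rep(catalog$gene_id, 2)
  # constant track: all deltas zero, slope zero
  flat <- GRanges("chrT", IRanges(unlist(mapply(seq, start(cirs),
                                                end(cirs))), width = 1))
  flat$score <- 0.5
  r0 <- reactivity_delta(catalog, cirs, flat, seed = 18)
  expect_true(all(r0$per_ccr$delta == 0))
  expect_equal(r0$beta1, 0)
  # depressed track: negative slope over groups
  dep <- toy_reactivity(catalog, cirs, depression = 0.1, seed = 19)
  r1 <- reactivity_delta(catalog, cirs, dep, seed = 20)
  expect_lt(r1$beta1, 0)
  expect_lt(r1$p_wilcoxon, 0.01)
  # absent track
  r2 <- reactivity_delta(catalog, cirs, GRanges(), seed = 21)
  expect_equal(nrow(r2$per_ccr), 0)
})

test_that("editing enrichment inside CCRs is detected", {
  sf <- small_fixture()
  catalog <- sf$catalog
  ed_in <- toy_editing(catalog, sf$cirs, sf$fix$genome, p_in = 0.6,
                       p_out = 0.0, seed = 22)
  res <- editing_site_or(catalog, sf$cirs, ed_in, sf$fix$genome)
  expect_gt(res$or, 5)
  # uniform editing: OR near 1
  ors <- vapply(1:10, function(s) {
    ed <- toy_editing(catalog, sf$cirs, sf$fix$genome, p_in = 0.25,
                      p_out = 0.25, seed = 200 + s)
    log(editing_site_or(catalog, sf$cirs, ed, sf$fix$genome)$or)
  }, 0)
  expect_lt(abs(mean(ors)), 0.25)
  # empty editing set: zero cells, flagged by the Haldane correction
  e0 <- editing_site_or(catalog, sf$cirs, GRanges(), sf$fix$genome)
  expect_true(e0$corrected)
})
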