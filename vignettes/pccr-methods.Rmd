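---
title: "Predicting long-range complementary region pairs in pre-mRNA: models and methods"
author: "pccr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting long-range complementary region pairs in pre-mRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccr)
library(GenomicRanges)
```

## The problem

Pre-mRNAs of eukaryotic genes can fold back on themselves over thousands
of nucleotides. Such long-range duplexes ("panhandles") between distant
intronic regions are implicated in exon skipping, suppression of cryptic
splice sites, circular RNA formation, and 3'-end processing. De novo
folding of full-length pre-mRNA is not feasible at these distances, so
this package takes the comparative route: restrict the search space to
evolutionarily conserved intronic fragments, then look for long, nearly
perfect complementary matches between every pair of fragments of a gene
that lie within a distance limit. The result is a catalog of *pairs of
conserved complementary regions* (PCCRs), each consisting of two arms
(CCRs) with a predicted hybridization free energy, plus a battery of
resampling statistics used to interrogate the catalog against splicing,
editing, protein-binding and polymorphism data.

## Thermodynamic model

Duplex stability is scored with the nearest-neighbor model: the free
energy of a helix is the sum of dinucleotide stacking terms, and every
interruption (internal loop or bulge of at most $m$ nucleotides per
strand, default $m = 2$) adds a fixed destabilizing penalty. The
stacking table bundled in `inst/extdata/turner2004_stacks.tsv` holds the
published Turner 2004 $\Delta G^\circ_{37}$ values at their full
two-decimal precision for all Watson–Crick and G·U wobble steps (36
admissible dinucleotide steps; e.g. 5'GC3'/3'CG5' $= -3.42$,
5'AA3'/3'UU5' $= -0.93$ kcal/mol).

Loop penalties are *size-based initiation terms* from the same parameter
set: 3.8 (1-nt bulge), 2.8 (2-nt bulge), 1.0 (1×1 internal loop), 1.6
(1×2, including the 0.6 asymmetry term), and 1.1 (2×2). The
sequence-dependent 1×1/2×1/2×2 tables of the full parameter set are
deliberately not used: the search targets near-perfect long duplexes
where stacking dominates, and a size-based penalty keeps the dynamic
program's state space minimal. Two consequences are worth knowing:

* a few wobble–wobble stacks are destabilizing (e.g. 5'GU3'/3'UG5'
  $= +1.29$), so extending a helix does not always lower the energy;
* a 1-nt bulge (3.8) costs more than a 1×2 internal loop (1.6), so a
  structure containing a bulge next to a weak pair can sometimes be
  undercut by widening the bulge — the search handles this correctly
  because it optimizes over the full grammar.

The reported $\Delta G$ is a *pure extension* energy: no duplex
initiation or terminal-AU terms are added. Absolute values are therefore
comparable within the catalog and to tools using the same convention,
but not to partition-function folders.

## The k-mer seeded dynamic program

`build_kmer_table(k, max_gu)` enumerates every pair of $k$-mers
(default $k = 5$) that forms $k$ consecutive admissible base pairs with
at most `max_gu` (default 2) wobbles and stores the sum of its $k-1$
stacks. This table is the *only* admissibility oracle of the search:
every $k$-window of every helix must be a table entry, which is how the
per-window wobble cap is enforced.

`find_duplexes()` runs a local dynamic program over the grammar

* seed a $k$-nt helix from the table,
* extend the current helix by one stacking base pair, or
* close the helix with a loop of $(a, b)$ unpaired nucleotides
  ($0 \le a, b \le m$, not both 0) and seed a new $k$-helix.

The cell $(i, j)$ holds the minimal energy over all structures whose
last helix ends at position $i$ of sequence 1 and $j$ of the reversed
sequence 2 (the duplex is antiparallel). Complexity is
$O(L_1 L_2 (m+1)^2)$. Hits are cells that pass the energy threshold
(default $-15$ kcal/mol) and have no strictly improving continuation;
each is resolved by a deterministic traceback with a fixed transition
order (stack first, then loops by total size, then by strand-1 size),
and must span at least `min_len` (default 10) nucleotides on both
strands. `N` never pairs: any window containing it is inadmissible.

Co-optimal structures are resolved to the first-found traceback under
that fixed order, so results are reproducible but a tie may differ from
another equally stable register. `brute_force_duplexes()` enumerates the
entire grammar on small inputs (≤ 400 matrix cells) with independent
energy summation; the test suite verifies cell-by-cell agreement of the
two on hundreds of random and near-complementary pairs.

Within one sequence pair, hits are filtered by
`select_nonintersecting()`: two hits conflict only when they share
nucleotides on *both* strands; conflicts are resolved greedily by
ascending $\Delta G$, then longer total span, then leftmost start. This
keeps nested and alternative duplexes that share only one arm.

## From annotation to the catalog

`build_cirs()` constructs the search space: per protein-coding gene, the
maximal segments free of any annotated exon (exons of all genes count),
each extended 10 nt into its flanking exonic segments (clipped at short
exons) so duplexes may straddle splice sites; exclusion tracks
(repeats, small RNAs, conserved TFBS, ...) are subtracted; the remainder
is intersected with a conserved-element track, producing CIRs.
Exclusions are applied after the exonic extension and before the
conserved intersection.

`pccr_scan()` applies the duplex search to all pairs of CIRs of a gene
(self-pairs included) with inner gap at most $L$ (default 10,000 nt),
using sense-strand sequences with the transcriptionally upstream CIR as
region 1, and lifts hits back to genomic coordinates. For self-pairs,
duplexes whose arms overlap in genomic space are discarded and mirrored
duplicates collapsed. Each record carries $\Delta G$, the two CCR
intervals, their spread $d$ (genomic inner gap between the arms, a
convention this package fixes since endpoint conventions differ between
tools), the energy group (I: $(-20,-15]$; II: $(-25,-20]$; III:
$(-30,-25]$; IV: $\le -30$ kcal/mol), the GC fraction of paired
nucleotides, and the base pairs themselves.

The relative position of an interval $[x, y]$ in its gene $[a, b]$ is
$p = (x-a) / ((b-a) - (y-x) + 1)$ on the plus strand and $1-p$ on the
minus strand, so $p = 0$ is always the 5' end. (The denominator is
written here with the gene length first; the opposite order, which
appears in some descriptions of this statistic, is negative for any
interval shorter than its gene and cannot be the intended quantity.)
Conservation metrics per CCR: $s_1$ = mean per-nucleotide conservation
inside the CCR minus the mean over 300-nt flanks, $s_2$ = mean over the
CCR ± 300 nt, $s_3$ = CCR length over parent CIR length.

In-memory intervals are 1-based closed `GRanges`/`IRanges` (the
Bioconductor convention); BED/GTF files are converted at the I/O
boundary by `rtracklayer` and the bundled writers.

## Null models and statistics

*Random shift*: each PCCR is displaced to a uniformly random offset
within its gene, preserving arm lengths and spread. *Random gene*: a
pseudo-PCCR is placed at the same relative position in a random gene of
matching length (±10%, nearest-length fallback). `enrichment()` counts
(PCCR, feature) pairs in a positional relation — `inside`, `outside`,
`crossing`, or `loopout` (the feature strictly between the arms, the
geometry of exon loop-out) — against $n = 40$ control catalogs, and
reports observed/mean-control with a two-tailed one-sample Wilcoxon
signed-rank p value. For calibration checks the package treats the range
of the $n$ control counts as the 95% prediction interval; under
exchangeability its exact coverage is $(n-1)/(n+1) = 95.1\%$ for
$n = 40$.

`rewire_fdr()` estimates the false discovery rate by rerunning the
duplex pipeline on chimeric pairs: each cognate CIR pair $(c_1, c_2)$ is
re-paired with a CIR from a *different* gene matched to $c_2$ in length
(±10%) and GC content (±5 percentage points; both relaxed stepwise if
the pool is empty). FDR = control predictions / real predictions. The
matching tolerances are package decisions — the underlying idea only
requires "controlling for composition and length". Two degenerate
anchors bound the estimator: duplicated genes give FDR ≈ 1, and
cross-incomplementary gene sets give FDR = 0; both are asserted in the
test suite.

Odds ratios for 2×2 tables use $(ad)/(bc)$ with a normal-approximation
CI on the log scale, Fisher's exact p, and Haldane's 0.5 correction for
zero cells (flagged). On this base sit: forked eCLIP peak ORs per RBP
(peak within 50 nt of each arm — the window is a package default, kept
configurable, mirroring the RNA-bridge distance rule), the ≥50%-coverage
rule for peak-on-CCR enrichment, the editing-site OR over sense-strand
adenosines inside vs outside CCRs, and the transcript-end ORs on
length-matched intron samples (log-scale bins of width 0.1).

Polymorphism statistics: SNP density in CCRs vs remaining CIR parts
(merged before length computation; one-tailed Poisson test);
$\Delta\Delta G$ of an SNV on the fixed structure (a broken pair loses
its adjacent stacks, no refolding — an interpretive choice documented
here) against the same substitution at alternative reference-carrying
positions of the same CCR; and compensatory-pair counting, where both
sides must carry qualifying alternative alleles (carrier fraction ≥ 1%)
whose combination is again admissible — same-haplotype co-occurrence is
*not* required, since phasing is out of scope. The re-wiring null
permutes right partners within groups of identical sense pair type,
chromosome and per-pair count of qualifying SNVs; individuals are not
modeled, so the "donor" stratum is that SNV count.

Covariation support: per-base-pair E values from external covariation
software are aggregated per PCCR as the product over pairs flagged
significant (empty product = 1), with Benjamini–Hochberg adjustment
across PCCRs with E < 1. `export_stockholm()` merges the two per-arm
alignment blocks through a 10-adenine spacer and writes the duplex as an
`SS_cons` line, dropping rows with indels and requiring ≥ 15 surviving
taxa.

Splicing: $\Psi = inc/(inc + 2\,exc)$, discarded when the denominator is
below 10; splice-site activity classes are the top/bottom 2% by pooled
split-read support among sites with ≥ 3 reads (ties broken by position);
cryptic sites are unannotated, unexpressed candidates above
side-specific strength-score thresholds (800 donor / 950 acceptor).
RNA-bridge candidates need an RBP peak within 50 nt of one arm, an exon
within 50 nt of the other arm (nearest boundaries, inclusive), and a
significant inclusion response (q < 0.01) to that RBP's knockdown;
exon-loop-out candidates need the exon strictly between the arms and a
peak on an arm. The knockdown ΔΨ/q values are inputs: the package does
not reimplement a specific differential-splicing pipeline and accepts
externally computed significance.

## The synthetic fixture

`make_toy_genome()` builds a deterministic toy chromosome of
protein-coding genes (both strands) and plants panhandles by writing a
grown duplex sequence and its base-paired partner into two intronic
conserved islands of one gene at a controlled genomic spread. Design
choices that matter for interpreting test results:

* Plants are grown pair-by-pair toward a target energy drawn from
  $[-40, -15]$ kcal/mol, with at most one wobble per $k$-window and an
  optional internal loop (both sides ≥ 1 nt; a planted 1-nt bulge would
  not always be the grammar optimum under the size-based penalties, see
  above, so bulges are exercised in dedicated search tests instead).
* Each planted region is flanked by 7-nt adenine guards on both
  strands, and loop nucleotides are adenines, so chance extension or
  re-seeding across the plant boundary is impossible; recovery is
  therefore exact unless an unrelated, strictly stronger or equally
  stable complementarity overlaps the plant, which the acceptance test
  verifies explicitly for every miss.
* Background sequence is i.i.d. with configurable GC; decoy islands
  containing shuffled sequence provide spurious-complementarity
  background for the FDR machinery.

Track generators (`toy_snvs()`, `toy_peaks()`, `toy_editing()`,
`toy_reactivity()`, `toy_junctions()`) plant known effect structure:
compensatory SNV pairs on chosen base pairs, forked/independent/on-arm
peak geometries, editing enrichment inside arms, reactivity depression
scaled with the energy group, and a two-component inclusion-rate model
for looped-out vs free exons.

What the fixtures do *not* emulate: realistic intron length and
composition heterogeneity, phylogenetically structured conservation
(islands are binary), alignment errors, haplotype structure, and
coverage biases of real assays. Green tests demonstrate algorithmic
correctness and statistical calibration under the stated generative
models, not performance on real genomes; the pipeline itself runs on
real GTF/FASTA/BED/VCF inputs unchanged.

## Problem sizes and numerical choices

The standard fixture used by the tests and the acceptance script has 50
genes (4–9 knt) and 120 planted panhandles with spreads up to 6 knt;
search-vs-enumeration agreement is checked on 200 pairs of length ≤ 15
(half near-complementary); calibration uses 100 replicates of 40
randomizations. Energies are exact sums of two-decimal table values;
equality checks in tracebacks use a $10^{-9}$ tolerance, and recovered
plant energies are required to match the construction oracle to
$10^{-6}$. Degenerate inputs: sequences shorter than $k$ return no hits;
empty feature sets give zero observed counts; zero cells in 2×2 tables
trigger the flagged Haldane correction; a zero mean control count leaves
enrichment undefined with a warning.

## Limitations

* The energy model has no initiation, terminal-AU, dangling-end or
  temperature terms; reported $\Delta G$ is comparable within the
  catalog, not across conventions.
* One optimum per end cell is reported (plus non-conflicting
  suboptima); no partition function or ensemble statistics.
* The re-wiring FDR inherits the assumption that different genes'
  pre-mRNAs do not interact; where that fails it overestimates the FDR.
* Donor-level (individual-level) polymorphism information is reduced to
  allele frequencies.
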