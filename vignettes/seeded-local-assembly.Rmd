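---
title: "Seeded local assembly: models, parameters and design choices"
author: "seedasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded local assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedasm)
```

## The method

Whole-genome assembly is wasteful when only one locus, gene family or
marker region is of interest. Seeded local assembly inverts the problem:
starting from a *seed* — a nucleotide or protein sequence expected to lie
inside the region — it alternates two steps over a fixed read store:

1. **Gather.** Align the current queries against the read store with a
   BLAST-like local aligner and rank the matching reads by bitscore.
2. **Assemble.** Select a subset of the ranked reads, optionally fragment
   long reads, assemble them de novo, keep only the contigs that still
   match the *original* seeds, optionally polish them with accurate short
   reads, and use the survivors as the next cycle's queries.

The carry-forward rule — contigs advance only if they match the original
seeds, while the *next search* uses the whole surviving contig as the query
— lets contigs grow outward from the seed without drifting into unrelated
sequence. Growth is not monotone: as more reads become available, reads can
be recruited away to competing non-target contigs, and a long contig can
split again in the next cycle. The package therefore treats the per-cycle
trajectory (longest, mean and count of matching and of all contigs) as a
first-class result, written to `report.tsv` and classified by
`trajectory_stats()`.

## Local search: seeding, extension, statistics

`align_local()` is a seed-and-extend aligner. Exact shared k-mers (k = 11
for nucleotide, k = 4 for translated search) define diagonal clusters; each
cluster is extended with banded affine-gap dynamic programming
(Smith–Waterman recurrences, gap of length L costing
`gap_open + L * gap_extend`) in a band covering the cluster's diagonals
plus `band_pad` (default 50) on each side. Raw scores convert to bitscores
and e-values with Karlin–Altschul statistics,
`S' = (lambda*S - ln K)/ln 2` and `E = m*n*2^(-S')`, using published gapped
parameters for the default schemes (+1/−2 with gap 5/2: lambda 1.28,
K 0.46; BLOSUM62 with gap 11/1: lambda 0.267, K 0.041). The database
length `n` is the total number of stored bases, with no edge-effect
correction — the thresholds that consume these e-values are user-tunable,
so absolute calibration against any particular external search tool is a
non-goal.

Two seeding policies exist. Nucleotide search extends **every** seeded
cluster (single-hit). We originally required two non-overlapping seeds per
cluster (a two-hit rule) for speed, but it measurably loses optimal
alignments: on short pairs at ~8% divergence an optimal local alignment
need not contain two disjoint clean 11-mers, and the test suite's
equivalence sweep against an independent full Smith–Waterman oracle caught
exactly such a miss. Translated search keeps the two-hit rule because
4-mer protein seeds are far noisier; its sensitivity is protected by the
BLOSUM62 raw-score cutoff instead. Protein queries are aligned against all
six reading frames of each subject (`six_frame_translate()`, standard
genetic code, partial codons dropped, stops as `*`), and hit coordinates
are mapped back to the forward nucleotide strand.

For read ranking, overlapping high-scoring pairs on one read collapse to
the best one: cycles rank *reads*, not alignments. Ties in bitscore break
deterministically by read id.

## Read selection and fragmentation

Five selection modes limit how many ranked reads reach the assembler:
`all`; `bitscore` (everything above a score floor); `increment` (top
`increment * cycle`, the mode that grew contigs most reliably in practice —
the increment should be scaled up with read depth); `population` (extend
the ranked prefix, one bitscore-tie group at a time, until every read from
the previous cycle is included; previously-selected reads that fall out of
the ranking are ignored with a warning rather than deadlocking the run);
and `manual` (an explicit per-cycle schedule whose exhaustion is a stopping
condition).

Long reads defeat short-read overlap assemblers directly, but their
*information* can be recovered by breaking them into non-overlapping
pieces. `fragment_single()` tiles a read at one length (e.g. 600 nt,
keeping the terminal remainder — discarding it would throw away unique
sequence exactly in the low-coverage regime fragmentation targets);
`fragment_double()` tiles the same read at two lengths (defaults 610 and
490), doubling apparent depth without adding information, which lets an
overlap assembler bridge stretches of 1–2x coverage. Fragmentation applies
after selection, so ranking reflects whole-read evidence; fragment ids
encode parent and offset for provenance.

## The greedy overlap-layout-consensus assembler

`greedy_assemble()` is a classical greedy OLC assembler with the tunables
such assemblers expose: `min_overlap` (default 40) and `min_identity`
(default 0.83; 0.93 is the usual stricter choice, and 0.97 is needed if
distinct alleles of a heterozygote must not merge), plus match/mismatch/gap
scores (+2/−4/5). Overlap candidates share an exact 12-mer in either
orientation; each candidate pair is aligned with banded ends-free dynamic
programming, so an accepted overlap touches an end of each sequence
(containment included). Merging is greedy by overlap score with
deterministic tie-breaks; the consensus is recomputed incrementally at each
merge by depth-weighted column votes (ties broken in the fixed order
A<C<G<T<N), never by global multiple alignment. Each read is oriented
canonically at first placement and a contig is reported in its first read's
orientation. Contigs track a layout (read, start, end, orientation) and a
per-column depth, and singletons are dropped unless `keep_singletons`.

Internally the merge loop is scheduled by *lazy revalidation*: overlaps
live in a max-heap, and an overlap whose endpoint has already been merged
away is re-aligned against the endpoints' current assemblies only when it
surfaces at the top. A final eager sweep re-detects overlaps among the
surviving contigs. This changes nothing about which overlaps are
acceptable and keeps the output deterministic, but avoids re-aligning the
growing contig against every remaining read after every merge, which
profiling showed dominated runtime roughly tenfold on dense multi-allele
simulations.

There is no scaffolding and no paired-end constraint in the built-in
assembler — classical overlap assemblers ignore pair relationships, and
mates can instead be pulled into the read set behind a configuration flag
(default off). External assemblers are supported as an adapter contract
only (`external_assembler()`): a command template plus an output parser;
when the executable is absent the error message points back to the
built-in assembler, and no test requires any external binary.

## Polishing

`polish()` replaces an external polishing chain (aligner + SAM + polisher)
with an internal pileup-majority procedure. Each iteration aligns the
polishing reads to the contig, stacks per-column votes over the symbols
{A, C, G, T, N, deletion} — the deletion symbol competes in the vote,
which is what fixes the indel errors that dominate noisy long-read
contigs — and applies weighted majorities (base qualities weight votes
when present). Insertions reported by more than half of the reads spanning
a junction are applied between columns. Columns with pileup depth below
`min_depth` (default 2) are never edited, so an unsupported contig region
passes through unchanged; zero iterations return the contig unchanged, and
a contig with no aligned reads is returned with a warning. Polished ids
gain a `.polN` suffix and polished contigs are written to a separate
per-cycle file.

On simulated data the expected pattern is a large jump in identity at the
first iteration (roughly 90% to better than 97% with accurate short reads
at moderate depth) and no further gain afterwards — later iterations can
wobble slightly downward as majority votes shift on low-depth columns. The
test suite asserts exactly this trend over 20 simulation seeds rather than
any particular percentage, which would be specific to a particular
polishing tool and read set.

## The simulators

`simulate_locus_reads()` and its parts generate every synthetic dataset
used in the tests.

**Locus model.** A random founder sequence (default 7 kb, uniform base
frequencies by default, with an AT-rich "dirigent-like" preset available)
carries a centered, relatively conserved core (default 1800 nt). Each of
`n_alleles` (default 9) derived alleles substitutes each site independently
at 0.005 (core) or 0.02 (flank); substitutions go to a uniformly chosen
different base and are logged as SNP truth. Per allele the SNP count is
Binomial(1800, 0.005) + Binomial(5200, 0.02), mean ≈ 113, which the test
suite checks within 3 standard errors.

**Read profiles.** `paired_short` draws 2x150 nt pairs on opposite strands
with a Normal(400, 50) insert (the insert distribution is our choice — a
common library geometry — as nothing in the method depends on it);
`long` draws single reads uniform in 7–14 kb; `length_file` draws single
reads from an empirical length pool, defaulting to Uniform(300, 900) as a
surrogate for medium-length pyrosequencing reads. Start positions and
strands are uniform; total bases approximate coverage x genome length;
read ids encode source, start and strand so every downstream result can be
checked against truth.

**Error model.** Four channels: per-base substitution, single-base
deletion, single-base insertion, and homopolymer run-length shifts of ±1.
Presets: `error_model_short()` = (0.005, 0.001, 0.001, 0.01) and
`error_model_long()` = (0.07, 0.01, 0.01, 0.80), Illumina-like and
nanopore-like respectively. The run-shift probability needs a unit, and the
choice matters enormously: maximal runs of length ≥ 2 occur at ~0.188 per
base in uniform random DNA, so applying 0.80 *per run* would add ~0.15
indels per base and drive identity to ~75–80%, and per run-base is worse
still. Only the *per-read* reading — each read suffers at most one
run-length shift, with probability 0.80 — is numerically compatible with
the ~90% alignment identity the long preset is meant to produce
(substitution 7% + indels 2% + one run shift ≈ 90.5% expected pident).
`runshift_unit` therefore defaults to `"read"`, with `"run"` and
`"run_base"` selectable for experimentation. The calibration is itself an
acceptance test: ≥ 1 Mb of simulated long reads must align to their source
at 90% ± 2 mean identity, and the short preset must realize less than 0.01
errors per base.

The generator does **not** emulate quality-score distributions (a constant
default is used), GC or positional bias, chimeric reads, or adapter
contamination. Passing tests on this synthetic data therefore demonstrate
the mechanics of gathering, assembly, carry-forward and polishing — not
robustness to every artifact of real sequencing.

## Stopping criteria and outputs

A run stops at whichever comes first: the cycle limit (default 21, long
enough in practice to exhaust target-matching growth); `minprogress`
(default 100 nt, 0 = off) — the absolute difference between consecutive
cycles' *longest matching* contig lengths falling below the threshold;
exhaustion of a manual selection schedule; no contigs; or no contigs
matching the seeds. Each cycle writes its matching contigs (and polished
contigs separately) as FASTA, and the run writes `report.tsv` plus a log of
every search, assembly and polish call with its parameters. Runs are fully
deterministic given the configuration seed; internal coordinates are
0-based half-open while all written coordinates are 1-based inclusive.

## Evaluation procedures

`contig_accuracy()` takes each contig's best local alignment to a
reference and reports identity (matches / alignment length) plus the
mismatch split between the terminal 100 contig bases at each end of the
alignment and the middle — terminal error enrichment is the expected
signature of low-coverage contig ends. `lengthening_bins()` bins
max-over-cycles / cycle-1 longest-contig ratios in steps of 0.4 from 1.00
up to an open 3.00+ bin. `call_loci()` estimates gene-family size from
reference hits: per reference, sorted hit intervals merge while each start
is at most the running end, a distinct hit is counted where a start
exceeds the previous end (book-ended hits start a new distinct hit), and a
locus break requires a gap above 10 kb; `contig_loci_ratio()` is the
contig count over the locus count. `primer_match_prob(x, m, n) = x^(m+n)`
gives the chance that two primers of lengths m and n both match an
assembly of per-base accuracy x — the arithmetic that motivates polishing
before primer design. `snp_anchor_scan()` mutually aligns contigs
(e-value 1e-08), bounds the scanned interval by the first and last
positions of nonself depth ≥ `min_depth` (a required argument — no default
is claimed), and reports positions where the contig base disagrees with
*every* aligned nonself base, paired at separations inside a product-size
window. A stricter reading — positions with no nonself coverage at all —
is available behind `strict = TRUE`, but only the disagree-with-all
reading yields PCR-discriminating SNPs, which is what anchor sites are
for. `classify_trajectory()` labels growth curves (monotone / stepwise /
peaked / alternating / flat / irregular) with simple documented rules on
the sign pattern of the per-cycle differences; the labels are heuristics
for browsing runs, not statistics.

## Numerical and scale choices

Scores are integer; all randomness flows from one seed; every tie in
ranking, selection, merging and consensus has a deterministic break.
Duplicate read ids are rejected outright rather than silently renamed. The
test suite sizes its simulations for a desk-scale run: the
Smith–Waterman equivalence sweep uses 1000 pairs of 60–500 nt; exact
reconstruction uses 100 error-free tilings of 1–10 kb sources; the
multi-allele chimerism and polishing-trend checks use 20 simulation seeds
at 5x and 15x coverage respectively; the error-model calibrations simulate
slightly over 1 Mb each. The whole suite runs in well under half an hour
on one CPU.

## Known limitations

The aligner does not reproduce any external tool's scores or e-values
exactly, performs no composition-based statistics and no low-complexity
masking. The assembler does not scaffold, split chimeric reads, or trim by
quality, and its banded overlap alignment assumes modest indel drift
within an overlap. Polishing is column-wise majority, not a partial-order
graph, so complex structural errors survive it. On multi-allele loci whose
conserved core exceeds the read length, chimeric flank joins and
multi-allele consensus contigs are the *expected* outcome — the package
reproduces and measures this failure mode rather than solving it; solving
it requires reads longer than the repeat or an identity threshold (0.97)
strict enough to keep alleles apart.
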