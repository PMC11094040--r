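---
title: "Classifying PIWI-bound piRNAs by their ping-pong partners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying PIWI-bound piRNAs by their ping-pong partners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the silkworm germline (and its BmN4 cell-culture model), transposons are
silenced by PIWI-interacting RNAs (piRNAs) bound to one of two PIWI
proteins, Siwi or BmAgo3.  The two populations amplify each other through
the ping-pong cycle: a piRNA-loaded PIWI cleaves a complementary transcript
between the nucleotides that pair with positions 10 and 11 of its guide,
and the 5' end of the cleavage fragment becomes the 5' end of a new piRNA
bound by the other (heterotypic) or the same (homotypic) PIWI.  Two
diagnostic signatures follow:

* **Geometry** — a ping-pong pair consists of two piRNAs on opposite
  strands whose 5' ends overlap by exactly 10 complementary nucleotides.
  For a plus-strand piRNA with 5' nucleotide at 1-based transposon
  position $p$, the partner's 5' nucleotide is at $p + 9$ on the minus
  strand (and symmetrically $p - 9$ for a minus-strand source).
* **Sequence bias** — Siwi-bound piRNAs tend to start with uridine (1U);
  BmAgo3-bound piRNAs tend to carry adenine at position 10 (10A).  Inside
  an exact pair these are two views of a single base pair: the partner of
  a 1U piRNA necessarily has 10A.

Given small-RNA libraries immunoprecipitated with each PIWI (Siwi-IP,
BmAgo3-IP), each reference piRNA can be assigned the PIWI it is
predominantly bound to, and so can its partner site.  Writing the partner's
PIWI before the arrow and the piRNA's own PIWI after it, every reference
piRNA falls into A→S, S→A or S→S (A→A configurations are excluded as
ambiguous, see below).  Comparing control and knockdown libraries then
shows which arms of the cycle a factor supports: the motivating experiment
is a helicase knockdown in which A→S piRNAs decrease while S→S piRNAs
increase, i.e. loss of the heterotypic cycle is partly compensated by
Siwi–Siwi homotypic ping-pong.

This package implements that full computational path — read preprocessing,
mapping, normalization, expression grouping, 1U/10A tables, and the
partner classification — together with a seeded synthetic-data generator
so that every stage can be validated end to end against known ground
truth.

## Read preprocessing

The library protocol ligates adapters carrying four randomized nucleotides
on each side of the insert, so a sequenced read is

```
5'-[NNNN][small RNA][NNNN][TGGAATTCTCGGGTGCCAAGG...]-3'
```

Preprocessing inverts this layout in the protocol's order:

1. **3'-adapter removal.**  The leftmost occurrence of the constant
   adapter core is located, allowing `floor(overlap × error_rate)`
   mismatches (default rate 0.1), either the full 21-nt core anywhere in
   the read or a ≥ 6-nt prefix flush with the read's 3' end.  The search
   is ungapped; this keeps an exact brute-force oracle feasible and
   matches the error model of the mapper.  The adapter-trimming error
   tolerance and minimum overlap are package choices — the upstream
   protocol names the trimming tool but not its parameters.  Reads
   without a detectable adapter are discarded as adapter dimers/junk
   rather than passed through untrimmed, because a genuine insert always
   carries the adapter by construction.
2. **Exact-duplicate collapsing.**  Completely identical sequences —
   UMIs still attached — are thinned to one record.  Because the 4+4
   randomized nucleotides are still present, distinct molecules with the
   same insert survive; only PCR copies collapse.  Counts after this step
   are molecule counts, and the operation is idempotent.
3. **UMI stripping and length gate.**  Four nucleotides are removed from
   each end and cores *longer than 12 nt* are kept — the gate is strict,
   so a 12-nt core is discarded and a 13-nt core is the shortest
   survivor.
4. For piRNA-level analyses, cores of 23–32 nt (inclusive) are extracted;
   everything ≥ 13 nt still counts toward the mapping denominator.

Quality strings are carried but never used: the emulated pipeline performs
no quality filtering.

## Mapping and normalization

The mapper is deliberately small and exact: end-to-end, ungapped, Hamming
distance ≤ 1, both strands, with only the best stratum reported (an exact
placement suppresses all one-mismatch placements).  The index stores every
panel substring of the query length keyed by sequence; an exact lookup is
a hash join, and a one-mismatch lookup joins the query's full
substitution neighborhood (3L variants of a length-L read).  On transposon
panels of tens of kilobases this is fast, and the design is verified in
the test suite against an exhaustive Hamming scan over all placements.

Two reporting policies serve different consumers:

* **TE-level counting** uses `best_single`: one placement per read,
  chosen by a deterministic tie-break (fewest mismatches, then te_id,
  then lowest start, then plus before minus), so repeated runs are
  byte-identical.
* **Reference-piRNA matching** uses `all_best` (multiple mapping): a read
  is a *5'-end match* to a reference piRNA when any best-stratum hit
  places the read's 5' nucleotide on the reference's
  (transposon, strand, position) anchor; read length is irrelevant.  A
  read matching $k$ reference anchors contributes $1/k$ to each, which
  conserves total counts.  The upstream method permits multi-mapping but
  does not state a weighting; fractional assignment is this package's
  choice.  By default the single-mismatch budget may fall on the 5'
  anchor nucleotide itself; `strict_five_prime_anchor` in
  `mapper_config()` disables that.

Normalization is reads-per-million with two denominators, each recorded
in the result's provenance: knockdown-experiment libraries are scaled by
reads mapped to the genome stand-in (the panel plus a decoy background
sequence — no genome-scale reference is used at desk scale), IP libraries
by the total read count over the reference piRNA set.

## Expression groups and bias tables

Per-key M and A statistics use a pseudocount of 1 RPM (conventional, and
configurable): $M = \log_2\frac{kd + c}{ctrl + c}$,
$A = \tfrac12(\log_2(kd+c) + \log_2(ctrl+c))$.  rRNA-transposon piRNAs
are removed, then keys with $\max(ctrl, kd) \ge$ `min_rpm` are ranked by
M (ties broken lexicographically) and cut into three contiguous
near-equal groups — increased, unchanged, decreased.  When the count is
not divisible by 3, the extras go to the outer groups (remainder 2) or to
the increased group (remainder 1); a 2474-item list therefore splits
825/824/825.  This rank-tertile rule is a reconstruction inferred from
those near-equal published group sizes, not a documented procedure; the
expression threshold behind the published set of plotted piRNAs is
likewise unstated, so `min_rpm` is exposed as a parameter.  Each group is
then cross-tabulated by the four 1U/10A classes (1U and 10A; 1U only;
10A only; neither), read off positions 1 and 10 of the mature sequence.

## Ping-pong classification

For each reference piRNA:

1. **Own PIWI.**  S if its Siwi-IP RPM strictly exceeds its BmAgo3-IP
   RPM, A in the opposite case, undetermined on ties or when neither IP
   library holds more than `low_count_threshold` (default 1) raw reads.
   The published rule defines only strict "more abundant", so ties are
   conservatively undetermined; the low-count rule is applied jointly
   across the two libraries (one library with ≥ 2 reads suffices),
   reading the "no more than 1 read in the IP libraries" exclusion as a
   property of the pair of libraries.
2. **Partner site.**  The coordinate above; all IP reads in the 23–32 nt
   window whose 5' ends fall on it are pooled across lengths — the
   partner need not itself be an annotated reference piRNA.  Restricting
   partner reads to the piRNA window is configurable.
3. **Class.**  partner→own, with exclusions in the precedence order
   rRNA transposon, then undetermined (own or partner), then the
   ambiguous A/A configuration.  The A/A exclusion operationalizes the
   published removal of BmAgo3-bound piRNAs "abundant in both the sense
   and antisense strands": a BmAgo3-bound piRNA whose complementary
   partner is also BmAgo3-bound is exactly such a both-strand BmAgo3
   configuration, and this reading also explains why no A→A class
   appears in the published scheme.  It is a reconstruction;
   `report_a_to_a = TRUE` reports the class instead.  The precedence
   order follows the listing order of the published exclusions and only
   affects the exclusion breakdown, never the three class sets.

The output is always a partition of the reference set, an invariant the
test suite asserts on every run.  Class-level expression change is then
the distribution of per-piRNA M values within each class; under the
simulated knockdown the A→S median falls below zero and the S→S median
rises above it.

## The synthetic generator

`sim_config()` defines the study conditions the package is validated
under; its defaults were fixed once, before any acceptance measurement,
and are not tuned:

* **Panel**: 20 transposons of 2 kb plus one rRNA-flagged transposon and
  a 4-kb decoy; sequences i.i.d. uniform ACGT.
* **Pairs**: 90 heterotypic pairs (each contributing one A→S and one
  S→A reference piRNA), 30 homotypic pairs (two S→S piRNAs each), and 6
  heterotypic pairs on the rRNA transposon (ground-truth exclusions);
  piRNA lengths uniform in 23–32 nt, pair windows non-overlapping so
  every planted 5' anchor is unique.  The heterotypic-dominant mix
  mirrors the canonical Siwi↔BmAgo3 cycle and keeps the knockdown's
  total library mass roughly conserved, so genome-mapped normalization
  stays comparable between conditions.
* **Biases**: each Siwi member's first base is forced to U with
  probability 0.9 (`bias_1U`), each BmAgo3 member's tenth base to A with
  probability 0.9 (`bias_10A`).  Within a pair both draws act on the
  same transposon base pair (they are complementary views of it), so in
  heterotypic pairs the effective forcing probability is
  $1-(1-0.9)^2$.
* **Counts**: per-piRNA base abundance log-normal (sdlog 0.75); control
  mean = abundance share × depth (2 × 10⁵ molecules per library);
  knockdown mean multiplied by class folds 0.3 (A→S), 0.7 (S→A), 2.5
  (S→S) — the folds reproduce the directions of the motivating
  experiment; their magnitudes are free generator parameters, since no
  magnitudes are published.  IP means weight abundance by ±8-fold
  enrichment toward the cognate PIWI.  Counts are negative-binomial
  (dispersion 0.05, sequencing counts being overdispersed; Poisson
  available).  5% of determinable piRNAs are planted at near-zero IP
  abundance; they and their pair partners are marked non-determinable in
  the truth table, because a starved piRNA removes the partner-site
  evidence for its mate as well.
* **Reads**: UMI + core + UMI + adapter, geometric PCR duplication
  (mean 3) *before* per-base substitution errors (rate 0.001), so
  duplicates can disagree at error sites and genuinely exercise the
  collapse-then-strip order; 10% decoy-derived off-size background.

What the generator does *not* emulate — ligation bias, realistic quality
scores, phased (trailing) piRNA production, genomic multi-mapping beyond
the panel — bounds what passing tests show: they validate the analysis
logic under the stated statistical structure, not performance on real
libraries.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally (BED convention) and
  1-based at the annotation surface; `five_prime_from_hit()` is the only
  conversion point.
* All sequences live in a single uppercase DNA alphabet (U → T on
  input).
* Ties are broken deterministically everywhere (mapper tie-break,
  lexicographic ordering of collapsed reads and ranked keys); the
  analysis path contains no randomness, and the generator's randomness
  flows from one seed, so identical inputs give byte-identical tables
  and identical seeds give byte-identical FASTQ.
* Empty inserts survive adapter trimming and are removed by the length
  gates; discards are tagged data, not errors.  An empty library
  (denominator 0) is an error.
* Fractional anchor counts make RPM ties between the IP libraries
  possible in principle; they resolve to undetermined.

## Problem sizes

The shipped validation runs the full pipeline twice (standard conditions
and the noiseless limit) at 2 × 10⁵ molecules per library — about 650,000
reads per library after duplication, or ~2.6 million reads per run across
the four libraries — plus property checks on small randomized panels.
These sizes were chosen as the smallest at which the count model's
asymptotics (binomial error of bias fractions, median class effects well
separated from normalization noise) are comfortably visible.

## Known limitations

* The construction of the published 3236-piRNA reference annotation is
  not reproduced; the annotation is an input (TSV of id, transposon,
  strand, 5' position, sequence).
* The published low-count and both-strand exclusions are reconstructed
  (jointly-applied threshold; A/A ambiguity) and exposed as switches;
  exact replication of the published 571/1036/1033 class counts would
  require the deposited libraries and the original annotation.
* No differential-expression statistics are computed (none are computed
  upstream either): the expression analysis is descriptive M/A ranking.
* The mapper is exact but not performance-engineered; it targets
  transposon panels, not genomes.
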