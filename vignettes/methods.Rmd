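---
title: "Models and methods behind srnaloci"
author: "srnaloci authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnaloci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

srnaloci annotates, from a genome and one or more collapsed small RNA
sequencing libraries, the three major classes of plant small RNA producing
loci — *MIRNA* hairpins, 21- and 24-nt *PHAS* loci, and heterochromatic
siRNA (hc-siRNA) loci — plus the archetypal *TAS3* genes among the 21-PHAS
calls. One uniform set of criteria is applied to every input, so results
are comparable across species and libraries. This vignette explains the
models, the tunable parameters, and the design decisions that were
genuinely open.

## Reads, placement and clusters

Libraries are collapsed: each unique sequence carries one count per
library. Reads are placed on the genome by exact matching on both strands
(`map_reads()`, built on Biostrings `PDict`/`matchPDict`). Exact matching
is a deliberate choice: small RNA reads are short, the annotation classes
tolerate losing reads with sequencing errors, and mismatch-tolerant
alignment would change what the placement count means — here the number of
genomic placements of a read, `n_hits`, *is* the repetitiveness signal
used downstream.

Two quantities are carried per placement:

* `n_hits`, the un-normalized total number of genomic placements of the
  read — this drives the repetitiveness filters;
* `weight = count / n_hits`, the hit-normalized abundance — this is what
  locus abundances sum, so a 10-copy repeat does not appear ten times as
  abundant as it is sequenced.

Placements are merged into clusters by single-linkage on start positions
(gap ≤ 200 bp, strand-agnostic), and clusters below 10 hit-normalized
counts are dropped. These are permissive pre-filters; every class applies
stricter rules on top. Reads with more than `max_hits = 50` placements are
flagged over-mapped but retained, so downstream stages decide their use.
Read length is windowed to 18–26 nt at collapse time, covering both the
21-nt and 24-nt classes with margin.

## MIRNA loci

Candidate precursors are proposed around the most abundant read placements
of a cluster (the putative matures, top 3 by default), with a grid of
flank lengths capped at 300 bp total — generous enough for typical
100–200 bp plant precursors and longer ones alike. Clusters made solely of
23–24-nt reads are skipped in strict mode; those are hc-siRNA territory.

Each window is folded by `fold_hairpin()`, a maximum-base-pair dynamic
program (Watson–Crick plus G:U wobble, minimum hairpin loop 3 nt) with a
deterministic traceback that prefers the outermost compatible pair. The
backend is pluggable — criteria evaluation consumes only the dot-bracket
string — but the default is self-contained and exactly testable against an
independent exhaustive dynamic program.

Maximum-pair folding has no stacking energies, so it happily places
isolated single pairs between an arm and its loop or flanks. Duplex
evaluation therefore

1. prunes helices shorter than 2 bp from the pair table,
2. anchors the star on the dominant contiguous block of mature partners
   (blocks split where the partner position jumps by more than 5 nt, the
   largest jump a legal duplex with ≤ 3-nt bulges can make),
3. evaluates up to two pair trims at each block end and keeps the
   interpretation closest to canonical duplex geometry, and
4. extrapolates the star interval through terminal fraying before adding
   the 2-nt 3′ overhang, mirroring how star coordinates are inferred from
   a mature and its duplex register in practice.

The criteria scorecard then requires: mature length 20–24 nt; at most 5
mismatched duplex positions with at most 3 nt in asymmetric bulges; 2-nt
3′ overhangs on both arms (±1 nt); precision ≥ 0.75, where precision is
the mature + star abundance (±1 nt positional variants included) over the
whole cluster's same-strand abundance; star expression; replication in ≥ 2
libraries when ≥ 2 are supplied; and ≤ 20 genomic placements for the
mature (repeat-derived candidates are rejected). Precision is computed
against the whole cluster rather than the candidate window alone — a
candidate must account for its locus, otherwise a small window inside a
phased cluster could cherry-pick two phased positions and masquerade as a
hairpin. In lenient mode a 21–22-nt mature with precision ≥ 0.75 and
replication may pass without star evidence. Overlapping accepted hairpins
merge keeping the best scorecard (most abundant mature arm, then highest
precision, fewest mismatches, shortest precursor), and loci sharing a
mature sequence are grouped into one family.

## PHAS loci

Phased siRNA production is tested per register window. A window spans
`c = 10` phase cycles (`D·c` bp, `D ∈ {21, 24}`) and slides at 1-bp
stride. Within a window, `N = 2·D·c` start positions are eligible (both
strands; minus-strand starts are shifted +2 nt so the two strands of a
phased duplex share one register), `m = 2·c` of them lie on the register
implied by the window start, `n` distinct positions are occupied and `k`
of those are on register. Occupancy counts *distinct positions*, not
abundance — that is what makes the hypergeometric model valid:

\[
p = \Pr[X \ge k], \qquad X \sim \mathrm{Hypergeometric}(N, m, n).
\]

`phasing_pvalue()` sums the tail term-by-term. The first term is built
from interleaved rational products (numerator and denominator factors
multiplied alternately, so no binomial coefficient is ever formed and
nothing overflows for `N ≤ 10^4`), and successive terms follow the
recurrence `t_{x+1} = t_x (m-x)(n-x) / ((x+1)(N-m-n+x+1))`. The suite
verifies ≥ 12 significant digits of agreement with an exact big-integer
enumeration and cross-checks against `phyper()`.

Abundance enters only through the phasing score of a window,

\[
\mathrm{score} = \ln\!\left[\left(1 + \frac{10P}{1+U}\right)^{k-2}\right]
\quad (k \ge 3;\ 0\ \text{otherwise}),
\]

with `P` the phased and `U` the unphased hit-normalized abundance.

A window is significant when `p ≤ 10^{-3}` (the cutoff the pipeline fixes
for this class) *and* the majority of its abundance lies on register
(`min_phased_frac = 0.5`). The second condition reflects what a phased
locus is — its reads are predominantly in register — and guards a known
artifact of stride-1 scanning: a window clipping the edge of a cluster
samples few positions, and across thousands of such windows a handful of
coincidentally spaced starts can reach the p cutoff. The guard only
removes calls, never creates them.

Significant windows sharing a register (±1 nt) within `2·D` bp merge into
loci; a locus reports the minimum p, the maximum phasing score, the
dominant register, and requires at least `min_cycles = 4` occupied phased
positions. Only reads of length exactly `D` with ≤ 10 placements enter the
scan. No multiple-testing correction is applied across windows — the
per-window count is reported so users can apply their own.

For `D = 24` an additional repetitiveness filter removes windows whose
contributing 24-nt reads have an abundance-weighted mean `n_hits` above 5,
or draw > 50% of abundance from reads with > 10 placements: such regions
produce abundant 24-nt hc-siRNAs that can mimic phasing locally.

## hc-siRNA loci

A cluster is called an hc-siRNA locus when 23–24-nt reads contribute
≥ 75% of its abundance, its abundance-weighted mean `n_hits`
(repetitiveness) is ≥ 2, it carries ≥ 10 hit-normalized counts over
≥ 50 bp, and it overlaps no accepted MIRNA or PHAS locus. Repetitiveness
is measured from read multi-mapping alone, so no RepeatMasker-style
annotation is needed. Class precedence MIRNA > PHAS > hc-siRNA is applied
once, at the end, by suppression — each surviving genomic interval carries
exactly one class.

## TAS3 genes

Among the 21-PHAS loci (extended by 200 bp flanks), regions carrying two
same-strand miR390 target sites qualify as TAS3. Sites are scored by
gap-free alignment of the small RNA against the site: mismatch 1, G:U
wobble 0.5, doubled at small RNA positions 2–13, with a cutoff of 6 —
conventional plant target-prediction settings. A mismatch (not a wobble)
at positions 9–11 marks a site non-cleavable; the canonical configuration
(cleavable 3′ site, 5′ site with a central mismatch) is reported as
attributes, not enforced, since monocot and eudicot variants differ. The
register is anchored at the 3′-site cleavage boundary (between small RNA
positions 10 and 11), in-register 21-mers toward the 5′ site are
enumerated, and each is matched against the tasiARF motif with ≤ 3
mismatches. The shipped mature miR390 and tasiARF motif live in an
editable data file (`inst/extdata/tas3_defaults.txt`) and can be
overridden per run.

## The synthetic data generator

`make_genome()` plants truth-tracked constructs in random background
sequence (GC 0.4 by default, single 500 kb chromosome in the shipped
study conditions):

* **MIRNA**: mature (21 nt) + 15-nt loop + reverse complement of
  mature[1..19] + a 2-nt tail chosen unable to pair either arm end — a
  hairpin whose duplex has clean 2-nt 3′ overhangs. Matures are resampled
  until they carry no appreciable self-structure (≤ 3 pairs when folded
  alone), as real matures do not fold onto themselves; without this, a
  GT-repeat-rich mature can out-pair its own planted duplex under
  max-pair folding.
* **MIRNA decoy**: the same construct passed through a
  dinucleotide-preserving randomization (first-order Markov chain fitted
  to the construct's own transitions). The decoy emits the same
  mature/star read pattern; only the structure criteria can reject it.
* **PHAS**: an interval of `D·(c+1)` bp with reads of length `D` at `c = 8`
  consecutive register positions on both strands (minus-strand starts at
  register − 2), per-position counts uniform in 5–50, plus ~10% off-phase
  abundance.
* **Repeat family**: one 300-bp unit copied 10 times, dispersed. Per-copy
  divergence defaults to 0: under exact-match placement any divergence
  inside a read window removes placements, and the planted repetitiveness
  would no longer reflect copy number.
* **TAS3**: a 21-PHAS construct bracketed by two miR390 target sites (5′
  site with a planted central mismatch, 3′ site perfect), phasing anchored
  at the 3′ cleavage position, and the tasiARF motif planted in register
  at phase index 2. The decoy lacks the 5′ site.

`make_reads()` splits counts 60/40 across two libraries by default so the
replication criterion is exercised. With `permute_phas = TRUE` the
PHAS/TAS3 read starts are redrawn uniformly within each locus as a
post-pass — counts and lengths untouched — which destroys register
structure and serves as the negative control.

What the generator does *not* emulate: sequencing errors (exact-match
placement would drop them by design), RNA degradation products,
transcriptome-level expression structure, miRNA families with imperfect
planted duplexes, and genome-scale repeat landscapes. Passing the planted
recovery tests therefore demonstrates that the statistics and criteria do
what they claim under their own model, not that real-data sensitivity
matches any published pipeline.

## Numerical and procedural choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at serialization (GFF3 1-based inclusive, BED 0-based
  half-open). The BED score column carries `−10·log10(p)` capped at 1000
  for PHAS loci.
* Collapsed FASTA headers are read permissively (`>name_count` with the
  count as the final underscore-delimited integer, or a bare `>count`)
  and written canonically (`>sN_count`).
* Reads-per-million values are computed per library from post-filter
  totals; raw counts are retained and used in all criteria.
* All tie-breaks are deterministic (fold traceback, candidate ordering,
  window merging, output sorting), so identical inputs give byte-identical
  outputs; the run log is the only file carrying timings.
* Problem sizes in the shipped tests: a 500 kb genome with the default
  plant specification for end-to-end recovery, 10^4 simulated windows for
  null calibration, 520-tuple oracle grids, and 200 random sequences
  (≤ 60 nt) for the folding oracle.

## Known limitations

Exact matching ignores sequencing errors and polymorphisms, so abundances
are floors. Max-pair folding is a screen, not thermodynamics; hairpins
whose acceptance hinges on subtle energetics may be mis-evaluated, which
is why every structural criterion carries tolerances and the backend is
pluggable. The hc-siRNA thresholds are conventional rather than canonical
— production-scale annotations of this class vary by orders of magnitude
with threshold choices. TAS3 detection targets the archetypal dual-site
configuration only; other TAS families and single-site variants are out
of scope.
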