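---
title: "Profiling and phasing analysis of locus-mapped small RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and phasing analysis of locus-mapped small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasir)
```

## Scope and model

`phasir` analyses deep-sequenced small RNA libraries against a *single*
annotated gene locus. The motivating biology is post-transcriptional
silencing of a plant gene — e.g. chalcone synthase in petunia — where the
silenced transcript is degraded into 21–24-nt siRNAs. Comparing the siRNA
populations of independently silenced samples (a transgenic cosuppressed
line vs a naturally silenced variety) asks whether the same degradation
machinery, the same hot spots and the same phased processing are at work.
Everything here operates on one coordinate frame: the reference locus,
with 1-based inclusive coordinates throughout all interfaces, as on a
GenBank record.

The analysis layers, bottom to top:

1. **Species.** Reads are 3′-adapter-trimmed and collapsed into unique
   *species* — a species is a distinct insert sequence; its count is the
   number of reads carrying exactly that sequence. Only inserts of
   15–45 nt are retained.
2. **Placements.** Each species is placed on the locus by exact matching
   on both strands. Perfect-match mapping is deliberate: with no
   mismatch tolerance, sequencing errors simply fall out as unmapped
   reads rather than distorting per-position counts.
3. **Profiles.** Size histograms, 5′-end position tracks, feature
   confinement, boundary distances, allele classes.
4. **Cross-sample statistics.** Abundance ranks, coverage of the
   abundance filter, top-N overlap, Spearman's rank correlation.
5. **Phasing.** 21 registers per strand, occupancy, region calling,
   phasing scores, conservation of region ends.

## Conventions that everything else depends on

**The 5′-end rule.** A single attribution convention is used everywhere:
an alignment is located by the reference coordinate of its 5′ end —
`start` for sense alignments and `end` (the rightmost matched base) for
antisense alignments. Position tracks, feature confinement, phase
assignment and occupancy all use this rule. Using one convention
throughout avoids a family of off-by-one disagreements between layers
(a midpoint rule, for instance, would decouple the phase arithmetic from
the track coordinates).

**Phase anchoring.** With a 21-nt unit, each strand has 21 possible
registers. Phase 1 is anchored at the *first* reference nucleotide for
the sense strand and at the *last* for the antisense strand:
sense `p = ((coord − 1) mod 21) + 1`, antisense
`p = ((L − coord) mod 21) + 1`. Antisense cycles are enumerated from
coordinate `L` downward, so the 5′ end of an antisense region is its
rightmost coordinate. Region tables therefore always report both
strand-relative ends (`five_prime_coord`, `three_prime_coord`) and
absolute ends (`left`, `right`). The unit length is a parameter (so
22-nt phasing can be explored), but 21 is the default because the unit
equals the dominant siRNA length.

**Boundary distances.** The distance from an intron–exon 2 boundary to
the nearest siRNA is measured from the first base of the downstream
feature to the *boundary-proximal* matched base of the nearest alignment
lying fully within that feature; 0 means flush. For antisense alignments
the boundary-proximal base is the alignment's 3′ end — which is exactly
how antisense siRNA ends are annotated next to an upstream boundary.
This is the simplest rule consistent with reporting, e.g., a sense
21-mer starting 13 nt into the exon as "13 nt distant". The rule is
stated in the report and is monotone: adding data can only shrink a
distance.

**Multimapping.** On an effectively single-copy locus multimapping is
negligible, but the policy is explicit rather than implicit. Under the
default `"all"` policy a species with `m` placements contributes its
full count at every placement in position tracks and size histograms
(every placement is shown), while read-total accounting weights each
placement `count/m` so that every read is counted exactly once and the
identity `mapped + unmapped = total` holds. `"fractional"` uses `count/m`
everywhere; `"unique"` drops multimapped species from attribution. The
one observable consequence of `"all"`: if a species does multimap, track
sums exceed the read totals by design.

## Read processing choices

The 3′ adapter is user-supplied (it is an artifact of library
preparation, not of the data). Trimming takes the *leftmost* exact
occurrence of the full adapter; if the full adapter is absent, an exact
adapter *prefix* of at least `min_overlap` bases (default 7) anchored at
the read's 3′ end is accepted, taking the longest such prefix. Reads with
no detectable adapter are discarded rather than passed through: for
short-cycle small RNA runs an adapterless read implies an insert longer
than the read, outside the 15–45-nt window anyway. There is no quality
filtering and no mismatch-tolerant trimming — downstream perfect-match
mapping already rejects erroneous reads. Pre-trimmed libraries (e.g.
processed public submissions) bypass trimming via `length_filter()` or
`pre_trimmed: true` in the pipeline config, which applies only the
length window.

The ">5 reads" abundance filter is strict (`count ≥ 6`), reading "more
than five" literally; the threshold is a parameter everywhere it
appears.

## Spearman correlation modes

The rank correlation between two samples is computed on species passing
the abundance filter in *both* samples. Two modes exist because the
choice is genuinely open: the default re-ranks within the common set
(equivalently, a Spearman correlation of the two count vectors), which
matches reporting the size of the common set as the `n` used for the
calculation; the alternative carries each sample's global ranks into the
common set and Pearson-correlates them. Both are exposed; they agree on
tie-free identical support, and the package's own validation does not
depend on the choice. P-values come from `stats::cor.test` (exact for
small tie-free `n`, t-approximation otherwise).

## Phasing score

The score follows the Howell et al. (2007) formulation: within a window
of `window_cycles = 9` consecutive cycle positions of one phase, with
`P` = reads at in-phase positions, `U` = reads at out-of-phase positions
inside the window footprint and `k` = occupied in-phase cycles,

```
score = (k − 2) · ln(1 + 10 · P / (1 + U)),   k ≥ 3 (else 0).
```

All constants (the factor 10, the `k − 2` exponent, the `k ≥ 3` gate,
the window length) are arguments. One choice required a decision: which
cycle a window's score is assigned to. `phasir` assigns each cycle the
*maximum* score over all full windows containing it. This makes the
score consistent with region calling — every cycle inside a clean
called region (≥ 3 units, no out-of-phase reads in reach) scores
positive — whereas a fixed window-start assignment would zero out the
trailing cycles of a region. On loci shorter than nine cycles the window
is clamped to the number of cycles.

Region calling itself is presence/absence: a cycle position is occupied
when at least one 21-nt read has its 5′ end exactly there (a `min_depth`
knob exists), and a region is a *maximal* run of ≥ 3 consecutive
occupied cycle positions. End conservation across samples uses exact
coordinate identity by default — regions in neighboring phases whose
ends differ by a single nucleotide are distinct phenomena, not matches —
with an explicit tolerance knob for exploration.

## The synthetic generator: what it emulates, and what not

`sirna_design()` encodes the structure of a silenced-tissue library:

* a size mixture dominated by 21-nt (0.62) then 22-nt (0.17) species
  over 18–25 nt;
* an antisense excess (`antisense_fraction = 0.7`, matching the roughly
  70 % antisense share seen in strongly silenced tissue);
* hot spots confined to exon 2, with log-normal hot-spot weights and
  log-normal per-species abundances — the simplest law that reproduces a
  few extra-abundant species dominating the ranking;
* phased unit trains with exact per-unit depth (defaults include a
  19-unit antisense train, so the longest-train arithmetic
  19 × 21 = 399 nt is exercised end to end);
* a thin uniform background over the whole locus (the "leaky" layer for
  negative controls), off-exon by construction;
* reads emitted as insert + adapter, truncated to a 52-nt read length
  (so even a 45-nt insert retains a 7-nt adapter overlap), in shuffled
  order, with sequencing error off by default.

Expected species abundances are rescaled so that the *expected read
mass* of each (length, strand) class matches the designed mixture;
within a class the heavy-tailed relative abundances are untouched. This
makes realized class proportions binomially tight around the design and
keeps strand/size recovery testable with closed-form tolerances.

Paired samples share the species universe, the trains and a shared
Gaussian log-abundance term (`shared_sdlog`), and differ by per-sample
Gaussian noise (`noise_sdlog`) before multinomial count realization; the
defaults (1.5 / 0.5) target a rank correlation around 0.85. The ground
truth records the *achieved* correlation of the realized counts — per
class and pooled — and validation always compares the pipeline's
estimate against the achieved value, never the target. A `realization =
"expected"` mode replaces sampling with rounded expectations, giving the
degenerate but useful check that zero noise yields a rank correlation of
exactly 1.

What the generator does **not** emulate: ligation and PCR biases,
realistic error/quality models, multi-locus backgrounds, or genomic
repeats. Tests passing on synthetic data therefore certify the
*computational* contract (conservation identities, exact planted-signal
recovery, statistical calibration of the coupling), not robustness to
platform artifacts in real libraries.

Problem sizes used by the test-suite simulations — libraries of five to
twenty thousand reads on a ~2-kb locus, 150–400 species, 20-seed
replication for the stochastic properties — are the package's chosen
working scale: large enough that class proportions and rank correlations
are statistically stable, small enough to iterate quickly.

## Numerical and degenerate-input behavior

* Empty inputs flow through: an empty library gives zero-count tables,
  no regions and an all-zero score track, not errors.
* Collapsing is order-invariant, with a deterministic output order
  (count descending, then lexicographic). Top-N membership ties are
  broken lexicographically so reports are reproducible; tie-breaking
  affects only membership listings, never the correlation itself.
* Coverage ratios are undefined (`NA`) when a class has no reads;
  correlations below three common species raise an explicit error,
  which the pipeline converts to an `NA` with a warning.
* Ambiguity codes in references are rejected at load time, naming the
  offending position: with perfect-match mapping, a wildcard would
  silently change counts.
* All randomness is scoped through `withr::with_seed`; identical
  (design, seed) pairs give byte-identical libraries, and identical
  configs give identical, hash-stamped report bundles.

## Running real deposited libraries

Public small RNA submissions are typically already adapter-trimmed. The
recipe: download the per-sample FASTA/FASTQ, set `pre_trimmed: true` for
those samples in the pipeline config, and supply the reference FASTA
(e.g. the GenBank record of the gene region) plus a feature TSV/GFF3 —
the exon/intron coordinates are user input, not hard-coded. Quantities
that depend on the full deposited libraries (absolute mapped-read
totals, the published rank correlations and region-end counts) can then
be recomputed with the same functions shown above; nothing in the
package's own validation requires that download.

## Known limitations

* Single-locus scope: no genome-scale PHAS discovery, no spliced-
  transcript coordinate projection, no miRNA-trigger prediction.
* Perfect-match mapping only — by design, not a missing feature.
* Raw counts throughout; rank-based comparisons are scale-free, and no
  library-size normalization is applied.
* The Spearman p-value uses the standard exact/approximate machinery of
  `stats::cor.test`; no multiple-testing control is applied across the
  handful of strand/length combinations reported.
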