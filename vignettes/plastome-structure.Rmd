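---
title: "Methods: structural analysis of plastid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of plastid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

This vignette documents the models behind `plastomics`, the parameters that
matter, the numerical conventions, and what the synthetic-data generators do
and do not emulate. It is the package's record of its own design choices.

## Coordinate and alphabet conventions

All internal coordinates are 0-based half-open; all file I/O (GFF3, the
minimal feature table, reported loci) is 1-based inclusive. Circular
features wrap the origin with `end < start` rather than through a duplicated
sequence, so the four region lengths of a partition always sum exactly to
the genome length. The alphabet is strict `{A,C,G,T,N}`: `U` maps to `T`
with a warning, and ambiguity codes other than `N` are rejected at read
time. Plastome assemblies are effectively unambiguous, and the strict
alphabet keeps GC and codon arithmetic exact. Reported percentages round
half away from zero (`round_half_up()`), the convention of published
characteristics tables; internal values are never rounded.

## Quadripartite detection

`detect_inverted_repeat()` finds the maximal pair of disjoint intervals
whose sequences are reverse complements of each other. Exact `k`-mer
matches (default `k = 21`) between the sequence and its reverse complement
are grouped by anti-diagonal — the quantity `i + j + k (mod n)` is invariant
along an inverted-repeat match, so each true IR concentrates its seeds on
one anti-diagonal. On each seeded anti-diagonal the longest exact run is
extended across isolated mismatches under two rules:

* the overall mismatch fraction stays at or below `max_mismatch_rate`
  (default 0.005 — plastome IR copies are near-identical; raise it to 0.01
  to absorb a couple of substitutions in a short IR);
* a mismatch gap is only bridged when the exact run beyond it has length at
  least `max(2·gap, 10)`. Unrelated sequence matches its mirror at ~25% per
  base, so without this rule extension would creep a few bases past the true
  junction on every genome; a 10-base exact run beyond the boundary has
  probability ~1e-6 per junction.

Ties on IR length break by fewest mismatches, then smallest start, making
the result deterministic; it is invariant (up to rotation) to where the
circular record happens to start. The shorter gap between the two copies is
the SSC, the longer the LSC, and "IRb" is the copy following the LSC in
canonical orientation. A genome with no inverted repeat of at least
`min_ir_len` (default 50 bp) raises a classed condition rather than a
guess — some taxa genuinely lack the quadripartite structure.

`canonicalize()` only rotates. A circular molecule's canonical form is
unique up to the flip of the SSC — that flip is exactly the flip-flop
isoform ambiguity, so fixing it would be arbitrary; both layouts are valid
canonical forms and the orientation module quantifies the mixture instead.

In `partition_stats()` every base receives exactly one class with priority
exon (protein > tRNA > rRNA) > intron > intergenic spacer; an intron is the
gap between consecutive exons of one feature. IR copies of a gene share a
name and are counted once; a gene counts as IR-duplicated when at least two
of its copies lie entirely inside the IR intervals. Pseudogenes (diagnosed
by `detect_internal_stops()`: in-frame TAA/TAG/TGA excluding the terminal
codon; a frame-broken CDS has no terminus, so all its complete codons count)
are excluded from gene counts and coding bases.

## Codon usage

RSCU(c) is the count of codon `c` divided by the mean count over its
synonymous family; the three stop codons form one family. Terminal stop
codons **are** counted — each CDS contributes exactly one, so the
stop-family total equals the number of CDS, which is what makes a published
codon panel's per-codon counts sum to its printed total. Families with zero
total get RSCU 0 and an undefined (NA) frequency, both flagged via the
`family_total` column. The genetic code is the plastid/bacterial code,
whose codon-to-amino-acid map coincides with the standard code.
`anticodon_recognition()` applies strict Watson–Crick complementation only —
no wobble — because the recognition flags mirror the convention of marking
exactly those codons that complement an encoded anticodon; ties for the
most common codon of a family all get flagged, since no tie policy is
canonical.

## Tandem repeats

Both scanners detect **perfect** repeats only. Minisatellites in the
source analyses were called by eye from dot plots, so their tolerated
impurity is undefined; perfect-only is the reproducible reading, and an
imperfection tolerance is deliberately left out rather than half-specified.
A maximal period-`u` array is a maximal run of positions with
`s[t] == s[t+u]`; it is reported under its smallest primitive unit
(non-primitive units are skipped because the same array surfaces at the
smaller period), and copies may be fractional through a partial final copy.
Microsatellites use per-unit-length minimum copy numbers
`10, 5, 4, 3, 3, 3` for units 1–6; minisatellites require unit ≥ 10 bp
(default cap 60) and ≥ 2.0 copies. Unit sizes 7–9 bp satisfy neither
definition and are ignored. Overlaps within a class resolve greedily by
longest array, then smallest start, so reported loci of one class never
overlap and runs contained in a longer reported run are suppressed (a
poly-A inside an AT array is not double-reported). Compound loci are not
merged. `dedup_ir()` keeps the IRb copy of each mirrored IR locus;
junction-spanning loci are kept and flagged.

## SSC-orientation isoforms

Classification is defined on the canonical (form-A) reference. A pair is
informative when both mates pass identity ≥ 90% and aligned fraction
≥ 0.60, map to a single locus, and lie wholly in the LSC and wholly in the
SSC respectively; any contact with an IR filters the pair as ambiguous,
because placements near the repeats are unreliable. The class is the strand
pair written LSC-mate first — the published convention does not define the
ordering, and only the {FR,RF} vs {FF,RR} split carries meaning; the
LSC-first rule just makes FR vs RF reproducible and classification
symmetric in mate file order. FR+RF support form A, FF+RR form B; the
form-B fraction gets an exact Clopper–Pearson interval, and the verdict is
`two_forms` only when both forms reach `min_support` (default 3) pairs,
guarding against isolated chimeric clones.

## NUPT detection

The query is the plastome with one IR removed (LSC+IRb+SSC): with both
copies present every IR insertion would be double-counted. The internal
aligner seeds exact 15-mers, clusters them per diagonal, and extends
without gaps under an X-drop of 20 at match +1 / mismatch −2; e-values are
Karlin–Altschul-style, `E = K·m·n·exp(−λS)` with λ = 1.33, K = 0.62 (the
ungapped constants for this scoring at uniform base composition). The
aligner is substitution-only by design — the synthetic insertions diverge by
substitutions only, where an indel-free aligner is exact — and externally
produced tabular hits (e.g. from a gapped aligner) are accepted in its
place with their e-values trusted. Filters are strict: alignment length
`> 100` bp and e-value `< 1e-5`. The per-base profile counts covering hits
on the IR-stripped genome; for display the IR values are halved and applied
to both copies, a presentation convention only — filtering and coverage
fractions never use the halved values. Per-chromosome cumulative bases
merge overlapping nuclear intervals before summing (the defensible measure
when hits can overlap), via `IRanges::reduce()`.

## IR boundary evolution

Each gene is scored against the IR intervals: all exon bases inside the IR
→ `complete_IR`; some → `partial_IR` (with the spanned junction recorded);
none → `SC`. Across taxa these states form an ordered ladder with unit step
costs — a direct SC → complete change costs 2, encoding the stepwise nature
of junction migration — and contractions cost the same as expansions, so
the algorithm stays direction-neutral. Events are placed by Sankoff small
parsimony with the root constrained to the declared reference architecture.
Among co-optimal reconstructions the reported one places changes as late
(tipward) as possible — the conservative reading, attributing changes to
the fewest deep branches — and the number of co-optima is always reported,
with full enumeration available (`enumerate = TRUE`) because "putative
events" deserve honest tie accounting. Gene presence/absence is a separate
binary character (`states = c("absent", "present")`), not folded into the
ladder.

## Marker diversity

Alleles are exact integer fragment lengths; a ±1 bp single-linkage binning
tolerance exists for capillary sizing noise but is off by default, since
published allele counts are exact. Counts are per marker per group
(missing data ignored; all-missing flagged), and group means recompute
exactly from the per-marker column. For nested accession groups the counts
are monotone non-increasing, which the tests exploit as an invariant.

## Assembly support

`bin_plastid_reads()` keeps a read when its best local alignment against
the circularly doubled reference (either strand; match +1, mismatch −2,
gap open 4 / extend 2, via `Biostrings::pairwiseAlignment`) reaches
`min_score_fraction` (default 0.5) of the read's self-score. Unrelated
100-mers score far below 50 against a kilobase-scale reference, so the
default separates cleanly even at 5% read error.

`elongate_contig()` is a majority-consensus elongator: per round and per
end, reads whose prefix overlaps the terminal window (overlap between
`min_overlap = 30` and `window = 100` bases, at most 2 anchor mismatches,
both orientations tried) vote base-wise on the overhang, which is appended
while ≥ `min_support = 5` reads cover a position at ≥ `min_agree = 0.8`
majority. These thresholds are this package's own — published
contig-elongation procedures state the goal, not the algorithm — and they
are deliberately conservative: a 50/50 disagreement is an `ambiguous` stop,
never a forced call. The single-copy/IR branch points of a plastome are
*expected* ambiguity stops (reads from the two IR copies carry conflicting
flanking context) and are tested as such rather than "fixed". Existing
contig bases are never rewritten; circularization is declared when the two
ends overlap by at least one window with ≤ 2 mismatches, and the overlap is
trimmed once.

## What the synthetic data emulate — and what they do not

The default simulated plastome is the real quadripartite architecture at
1/50 scale — LSC 1800 bp, IR 700 bp, SSC 250 bp — with protein genes in the
single-copy regions, tRNA genes in the LSC, rRNA genes duplicated inside
the IR, and IRa the exact reverse complement of IRb. Whole-pipeline tests
run in seconds at this scale with the same topology as a 170 kb genome.
Mate-pair inserts are sized to bridge the LSC and SSC across IRb
(`IR + 2·read + SSC/4` by default); nuclear chromosomes are uniform random
background of 6 kb with 150–600 bp plastid fragments spliced in at 2%
substitution divergence by default; genotype tables plant an exact number
of distinct alleles per marker in the outermost of the nested groups.

Two generator behaviours matter for interpreting the tests. First, every
generator is a pure function of its parameters and seed, with per-generator
streams fanned out from one seed by fixed offsets. Second, the generators
**guard the flanks of planted structures**: the bases just outside a
planted IR never complement their mirror partners, the bases outside a
tandem array never continue its period, and two guard bases flank each
nuclear splice so local alignment cannot profit from crossing them. Without
the guards, chance agreement (~25% per base) would extend detected elements
a few bases past the planted truth on a large fraction of genomes, and
"exact recovery" would be unattainable for any correct detector. The guards
make planted truth exactly maximal — they do not weaken the detectors.

What the simulations do not emulate: real base composition structure
(isochores, gene/IGS composition contrast), sequencing error profiles of
any particular platform (homopolymer errors in particular), indel
divergence in nuclear insertions (a substitution-only model by default),
biological repeat families, or annotation pathologies (trans-splicing is
representable in the data model but not generated). Passing tests therefore
demonstrate algorithmic correctness against the stated models, not
robustness to every artefact of real data.

## Problem sizes used by the test suite

The suite exercises: 100 seeded default-scale plastomes for IR detection
recovery, plus 20 smaller genomes (~1.75 kb) against an exhaustive
O(n²) anti-diagonal oracle; repeat scanning against a quadratic
brute-force tandem oracle on ~3.5 kb genomes; orientation mixtures of
2000 pairs across 20 seeds; planted-insertion recovery across several
seeds; parsimony against exhaustive internal-state enumeration on trees of
4–8 tips; and full-circle elongation on a 1.1 kb repeat-free circle at
20× error-free coverage. These sizes keep the default run to a couple of
minutes while leaving every algorithmic branch covered.

## Known limitations

* IR detection assumes a single dominant IR pair; genomes with multiple
  long inverted duplications report only the maximal pair.
* The mismatch-tolerant extension is greedy run-bridging, not optimal
  banded alignment; for the near-identical IRs of real plastomes the two
  coincide, but a deeply diverged IR pair could be under-extended.
* The internal NUPT aligner does not model indels; use external tabular
  hits for diverged insertions with gaps.
* `canonicalize()` does not resolve the flip-flop ambiguity (by design).
* Repeat scanning is linear-sequence based; a repeat spanning the circular
  origin is only seen after canonical rotation, which places junctions away
  from the origin.
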