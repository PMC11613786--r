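---
title: "Reconstructing complex genomic rearrangements: models and methods"
author: "cgrwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing complex genomic rearrangements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrwalk)
```

# The problem

A complex genomic rearrangement (CGR) is more than one structural variant
in *cis*: a derivative chromosome stitched together from duplicated,
deleted and inverted reference segments. Characterising one means
answering four questions: what is the **order and orientation** of the
segments on the derivative (including whether it closed into a ring);
what does each breakpoint **junction** look like at the nucleotide level
(microhomology, blunt join, templated or nontemplated insertion), which
constrains the formation mechanism; on which **parental homolog** did
the rearrangement arise; and how can the result be written down in an
unambiguous, machine-readable **nomenclature**. `cgrwalk` implements all
four steps over caller-level inputs (segment dosage tables, junction
calls as BEDPE or VCF breakends, trio SNV genotypes, binned read depth)
and ships the breakpoint tables of three chromosome 21 CGR cases as
worked examples: a chromoanasynthesis with six duplications, a ring
chromosome, and a 13-SV rearrangement with 26 breakpoints.

# Data model and conventions

**Coordinates.** Tables and nomenclature use 1-based inclusive
coordinates; internally everything is 0-based half-open, so a table row
`Start=s, End=e` has length `e - s + 1` and two rows abut when the
second starts at `e + 1`.

**Breakends and junction orientation.** A breakend is a position plus
the side of it that is retained in the derivative (`L` = sequence to
the left kept, junction attaches after the position; `R` = right side
kept). A junction is an unordered pair of breakends, canonicalised with
the lower coordinate first. The orientation class follows from the
retained sides and maps one-to-one onto BEDPE strand pairs:

| class | strands | meaning |
|-------|---------|-----------------------------------|
| HT | (+,+) | deletion-like / reference-orientation join |
| TH | (−,−) | tandem-duplication-like join |
| HH | (+,−) | head-to-head inversion junction |
| TT | (−,+) | tail-to-tail inversion junction |

Swapping the two breakends flips the reading of the junction (its
spanning sequence reverse-complements) but changes nothing physical;
the signature code therefore accepts junction-spanning sequences on
either strand.

**Derivative walks.** A derivative is an ordered, oriented list of
reference intervals (`derivative_walk()`), linear or circular. A join
between consecutive steps is a *reference adjacency* when the two steps
read on contiguously (forward: `end == start` of the next; inverted:
the mirror condition); every other join is a *novel adjacency* — a
junction — and their count is the template-switch lower bound under a
replicative model. Unresolved junction partners (`?` in the
nomenclature) become explicit gap steps whose joins are never reference
adjacencies.

Two walks describe the same molecule if they are equal after
*normalisation* (merging reference-contiguous same-orientation steps)
up to rotation and reflection for rings and reflection for linear walks
(`walk_equal()`). All round-trip guarantees in the package are stated
at this equivalence.

# Reconstruction as a breakpoint-graph traversal

`build_graph()` tiles the chromosome with the copy-number segments
(gaps auto-filled as diploid), attaches each junction breakend to a
segment boundary (tolerance 0 by default — the bundled tables are
exact; configurable for imprecise callers), and stores one novel edge
per junction. A derivative with copy number `cn` over a segment visits
it `cn - 1` times (the intact homolog carries the remaining copy), so a
deletion is skipped and a duplication visited twice.

`assemble_walk()` searches exhaustively for every walk that uses each
novel edge exactly once and matches the visit counts, and that is
anchored like a real chromosome: it starts at pter forward, or ends at
qter, or closes into a ring. Because a derivative whose p-terminus was
replaced does not begin at pter, the search launches from every
retained (segment, orientation) pair; ring walks are anchored at the
lowest-coordinate retained segment in both orientations, which is
exhaustive up to the rotations and reflections that canonical
deduplication absorbs. Tie-breaking is deterministic (novel edges
before reference continuation, lower partner coordinate first) and the
search is capped by a node budget and a solution cap.

Ambiguity is real: with several copies of similar segments, many
orderings can satisfy the same evidence (the duplication-only bundled
case admits 63 consistent walks, the 13-SV case 312). The original
analyses resolved this by manually following soft-clipped reads; the
package instead returns *all* solutions, flagged ambiguous, and the
tests assert that the published derivative is in the set. For the ring
case the solution is unique.

# Nomenclature

`parse_seq()`/`walk_to_seq()` interconvert walks with the ISCN-like
`NC_…:g.[…]` strings used in the bundled tables. The grammar covers
exactly the constructs those strings use: `::` and `;` concatenation,
`start_end` ranges, `inv`, `delins[...]`, `ins` (bare range or list),
`del`, uncertainty ranges `(lo_hi)`, `pter`/`qter`, and `?` for unknown
partners. Decisions worth stating explicitly:

* **Uncertain positions** resolve to the interval midpoint for walk
  construction; the range survives in the AST, and AST equivalence
  treats an uncertain position and its midpoint as equal.
* **Lenient repairs.** Two defect classes seen in printed strings are
  repaired (not fatal) in lenient mode, each recorded as a diagnostic:
  an `inv:` element separator (read as `inv;`) and a position exceeding
  the contig length by a surplus digit, normalised by single-digit
  deletion with preference for `start + 1` in insertion targets. The
  duplication-only case's printed string needs exactly these two
  repairs; the other two cases parse clean.
* **Ring inference.** A string whose first edit is anchored at `pter`
  and last at `qter` (at least two edits), with no replacement element
  still carrying telomeric sequence, describes a derivative that lost
  both telomeres — taken to close into a ring, the configuration in
  which terminal losses are rescued by ring formation. Emission writes
  rings in the same two-edit telomere-anchored form.
* **Emission** chooses backbone anchors (kept reference runs) by a
  weighted longest-increasing-subsequence over the walk's forward
  steps, maximising total kept length; everything between anchors
  becomes replacement elements. Canonical output never emits
  uncertainty parentheses. `parse(emit(w))` equals `w` at walk
  equivalence; this is property-tested on 200 random walks.

```{r nomenclature-example}
b <- cgr_case("RD_P26")
w <- b$metadata$nomenclature_walk
w
walk_to_seq(w, 45090682, accession = "NC_060945.1")
```

# Junction microarchitecture

Microhomology is the run of bases flanking a junction that is identical
in both reference copies, within which the true breakpoint cannot be
placed. With `flank_a`/`flank_b` the derivative sequences ending/
starting at the two breakpoints and `ref_beyond_a`/`ref_beyond_b` the
reference continuations (all in derivative orientation), the length is
`k_left + k_right`, the maximal suffix/prefix runs shared with the
other copy. A brute-force oracle that enumerates every breakpoint
placement validates this on 1000 random junctions in the test suite.

Insertion classification requires an observed junction-spanning
sequence whose ends anchor in the two flanks (≥ 10 nt each); the bases
between the anchors are the insertion. An insertion aligning locally at
≥ 90% identity over ≥ 10 nt inside a ±2 kb window around either
breakpoint (either strand) is TEMPLATED; otherwise NONTEMPLATED. These
defaults separate the bundled cases' 26–94 nt templated inserts from
their 4–9 nt nontemplated ones, the latter falling below the minimum
match length by construction. When both an insertion and flanking
homology could describe a junction, the insertion takes precedence and
microhomology is reported as 0 — the categories are mutually exclusive
per junction, so a junction is *blunt* iff both are zero. Inverted
templated inserts and homopolymer/short-tandem-repeat inserts are
flagged; flank-versus-flank identity over 50 nt above 80% is reported
as a separate "sequence similarity" category, not a mechanism.

Mechanism heuristics operate on a case's signature table plus its walk:
at least 3 copy-number gains with ≥ 50% microhomology-or-templated
junctions → CHROMOANASYNTHESIS (replicative template switching); a
circular walk with terminal losses → ALU_MEDIATED_RING (named for the
proposed repeat-mediated mechanism; the rule keys on topology because
repeat annotation is out of scope); ≤ 2 junctions, blunt or ≤ 2 nt
microhomology → SIMPLE_NHEJ_LIKE; otherwise UNCLASSIFIED.

# Parental-origin phasing

At an informative trio site one parent is homozygous alternate and the
other homozygous reference, so the origin of the allele(s) the child
carries is identifiable. Per segment, the *paternal fraction* is the
share of informative sites attributed to the father. Diploid segments
sit at 0.5; hemizygous (deleted) segments go to 0 or 1 and implicate
the *other* homolog as rearranged (the remaining allele belongs to the
unaffected parent); duplicated segments shift towards the carrier
haplotype's 2-of-3 dosage among read-backed phased SNV tallies.

Design choices: phased sites are filtered at QUAL strictly greater
than 40 in all three samples; the test is a Welch (unequal-variance)
two-sided two-sample *t* on per-segment fractions, affected versus
diploid control segments — per-segment rather than per-SNV because
segments are the unit whose dosage differs, and fractions within a
segment are exchangeable; alpha is 0.05 with no multiple-testing
correction (one test per case). Deleted segments enter the test as
`1 - paternal_fraction` so that "high" always means paternal origin.
Segments with no informative sites are excluded; fewer than two usable
segments per group yields INCONCLUSIVE with an explanation.

The package phases from genotype-level trio logic only. The simulator
therefore plants the duplication dosage effect in the informative-site
class frequencies (the carrier parent is over-represented at 2/3),
emulating what read-weighted phased-SNV counts show in real data;
read-level allelic depths are not consumed. This is a stated
limitation: with genotype-only real data, duplications carry no dosage
signal and phasing rests on deletions and on upstream haplotype-block
assignments.

# Copy number from binned depth

`normalize_depth()` divides per-bin mean depth by the profile median
(ratio 1 ⇔ CN 2) and `segment_cn()` merges consecutive bins with equal
`round(2 × ratio)` (half-up), absorbing runs shorter than 3 bins and
re-rounding each segment's mean. Defaults: 10 kb bins, no GC correction
(synthetic references are GC-neutral; real data would need it — a
documented limitation). Median normalisation presumes the diploid state
dominates the profiled region; a profile restricted to a mostly-gained
chromosome arm would need an external baseline.

# The synthetic-data generator

The generator is first-class, tested code: every pipeline input can be
produced with known truth. `make_reference()` draws a uniform-random
ACGT sequence (GC-neutral, no repeat structure unless repeat pairs are
planted). `simulate_derivative()` splices a reference along a truth
walk; requested microhomology `m` is realised by *mutating the
reference flanks before splicing*, so the shared bases genuinely occur
in both copies and the detector oracle stays honest; mismatches are
forced one base past the run on both sides, making the planted value
exact. When an exit breakend sits at a telomere the homology is planted
upstream of the entry instead. Junction contexts are checked for
conflicting writes; insertion junctions make no homology writes (their
microhomology is 0 by the exclusivity convention). Trio SNVs and
Poisson depth profiles (`reads ~ Pois(cov/2 · cn · bin/ℓ)`) are drawn
per the phasing and depth sections.

Three named scenarios mirror the bundled cases at 1/100 genomic scale
(toy contig ≈ 451 kb — chosen so the full round trip, including
exhaustive walk assembly, runs in seconds while every breakend keeps
≥ 200 nt of clear flank): `chromoanasynthesis_dup6` (9 junctions, six
with 1–79 nt microhomology, one 4 nt nontemplated insert, paternal
origin), `ring21` (4 junctions, one 20 nt templated insert, one blunt,
maternal-origin deletions) and `mixed_delsdups13` (15 junctions: ten
1–7 nt microhomologies, 4/9 nt nontemplated and 26/60 nt templated
inserts, paternal origin). The 13-SV case's genuinely unresolved
junction partner cannot be simulated as unknown *and* recovered
exactly, so the scenario's truth walk gives that element a concrete
extent and the unresolved partner is realised in the emitted breakend
VCF as an unpaired record, which the reader skips with a warning; the
genuinely-unknown path is exercised by the bundled case's own
nomenclature string. Per-junction categories are exclusive in the
simulator even where the original junction inventories overlap
(a junction listed with both microhomology and an insert is simulated
as the insert).

What passing the synthetic round trips does **not** show about real
data: no sequencing error, no repeats or segmental duplications (the
very elements implicated around acrocentric p-arm breakpoints), no
GC bias, no caller imprecision (graph tolerance is exercised at 0), and
genotype-level phasing only.

# Numerical and degenerate-input choices

* Boundary-matching tolerance 0 nt by default; configurable snapping
  with an error that names the nearest boundaries.
* Exhaustive search budget 10^6 states, 1000 solutions; deterministic
  move ordering; results sorted by canonical serialisation.
* Rounding: copy numbers round half-up; uncertain nomenclature
  positions use `floor((lo + hi)/2)`.
* Degenerate inputs: empty junction files warn and return empty sets;
  a walk with no consistent traversal returns a structured
  "inconsistent evidence" reason rather than an error; identical
  phasing groups give `t = 0, p = 1`; zero-variance groups are handled
  explicitly before the Welch test.
* `N` runs at a junction truncate microhomology comparison and set a
  flag.

# Known limitations

Multi-chromosome translocation walks are out of scope (all bundled
cases are intrachromosomal). Repeat-family annotation, read-level
evidence (soft-clip extraction, BAM parsing) and probabilistic walk
scoring are not implemented. Breakpoint counting follows an explicit
2-per-SV convention with shared-boundary deduplication; published
per-case totals counted under other conventions are not forced. The
counts here reproduce 26 breakpoints for the 13-SV case and 8 for the
ring case under that single convention.

# Problem sizes used in the checks

The bundled tests and the analysis scripts run the three 1/100-scale
scenarios once each (9 + 4 + 15 junctions), 1000 random junctions for
the microhomology oracle, 200 random walks for the nomenclature round
trip, 100 seeded trio replicates per phasing arm at 200 sites per
segment, and 100 depth replicates over the full-scale duplication
landscape at 10 kb bins.
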