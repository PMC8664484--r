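---
title: "Revising draft assemblies with optical maps and long-read contigs"
author: "gapsmith"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Revising draft assemblies with optical maps and long-read contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapsmith)
```

## The problem

Chromosome-scale assemblies of large, repeat-rich plant genomes (the
Triticeae are the archetype: > 4 Gb, ~85% repetitive) are built by layering
short-read contigs, hybrid scaffolding, and genetic-map anchoring. The
residue of that process is visible in the sequence itself as N-runs of two
kinds:

* **placeholder gaps** whose N count is a provenance code, not a span
  estimate — 10 Ns between assembler-joined contigs, 100 Ns from hybrid
  scaffolding, 1000 Ns between adjacent (super-)scaffolds; and
* **sized gaps** whose N count estimates the true span.

Two further classes of defect survive into such assemblies: scaffolds placed
on the wrong chromosome or in the wrong orientation, and spurious segmental
duplications created where assembly of a tandem-repeat block went wrong
(recognisable as a 10-N gap whose two flanks end and begin with the same
near-identical copy).

`gapsmith` implements the revision workflow that turns such a draft into an
improved release: optical-map validation of scaffold placement, correction
of the errors found, collapse of duplication artifacts, and replacement of
N-runs with long-read contig sequence, with coordinate lift-over maintained
through every edit so annotations survive. Around the sequence work it also
implements the bookkeeping layers used to describe such a release: gap
censuses and difference tables, parts-versus-totals validation of
annotation census tables, gene-model grading from BLAST evidence, and
small-RNA read classification.

## Ordered-map alignment

An optical map reduces a molecule to an ordered list of nick-site label
positions; alignment compares *fragment-length sequences*, not bases. The
aligner is a dynamic program over monotone label pairings. A transition from
matched pair $(i_0, j_0)$ to $(i, j)$ merges the intervening fragments on
each map (at most `max_merge` per side, default 3) and costs

$$\frac{(x - y)^2}{v\,(x + y) + 1}$$

for merged interval lengths $x$ (query) and $y$ (reference), with $v$ (the
sizing-variance scale, default 200 bp) reflecting that optical fragment
sizing error grows with fragment length. Every matched pair earns the bonus
$B$ (default 5); every interior label merged over costs `p_miss` (default
3). Alignment ends are free, so a scaffold can align into the middle of a
chromosome-scale map. Both query orientations are tried; ties prefer `+`.

**Significance.** The vendor software that historically performed this step
expresses cutoffs as P-values of a proprietary statistic (e.g.
$P < 10^{-10}$ for alignment); those thresholds are not reproducible
outside that software. Significance here is therefore re-grounded in a
permutation null: the reference's fragment order is shuffled
`n_permutations` times (default 100) and an alignment is significant only
if its score beats *every* permuted score — an exact test at
$\alpha = 1/(n\_permutations+1)$ — and at least `min_matched_labels`
(default 9) labels are matched. The label floor guards against short
segments whose handful of fragments can match anywhere.

In an ordered-map DP, "skipping an interior label" and "merging its two
flanking fragments" are the same move, so merged-over labels are reported
as merge events, and `missed_query`/`missed_ref` count only the unaligned
labels outside the aligned block.

**Chimera detection** uses a split-gain criterion: candidate breakpoints
cut the contig in two, each part is aligned on its own, and the contig is
called chimeric when the combined score beats the unsplit score by more
than `3 * B` and the parts align inconsistently (different reference,
different orientation, or a coordinate jump beyond 50 kb). An intact contig
never gains from splitting — it only forfeits one pair bonus — so the
criterion stays robust even where shared repeats let a glocal alignment
creep across the junction.

## Placement validation and correction

Validation works at the granularity the 1000-N convention defines: each
maximal segment between 1000-N joins (a scaffold) is digested in silico and
aligned to every optical map. The *consensus map* of a chromosome is the
map most of its assessed scaffolds align to — a scaffold-count vote with an
aligned-bp tiebreak, deliberately not bp-weighted so that one large
misplaced scaffold cannot outvote its host chromosome. Conflicts are:

* **misplaced** — the scaffold's best map is another chromosome's
  consensus; the proposed move inserts it right after the last scaffold of
  the target whose map position precedes it (scaffold ordinals, so
  unassessed scaffolds keep their physical position);
* **misoriented** — the scaffold aligns `-` to its consensus map. The
  map's forward orientation is treated as the canonical frame; this is what
  makes an inversion detectable even on a single-scaffold chromosome,
  where a neighbour-consistency rule would be blind;
* **out of order** — scaffolds off the longest increasing run of map
  positions are moved to their indicated ordinal.

Scaffolds with fewer labels than `min_matched_labels`, or with no
significant alignment, are left unassessed and untouched: absence of map
evidence is never treated as evidence of error. `applyEdits()` performs
the moves and flips, re-emits 1000-N joins at the new junctions, and
records the lift-over; moves and flips neither create nor destroy sequence
(base counts are conserved up to strand).

## Gap filling and duplication collapse

`placeContigs()` places contigs by k-mers that occur exactly once in the
assembly (default $k = 31$), chained per (sequence, diagonal) into ungapped
blocks, split at N-runs and where anchors are farther apart than 5 kb, then
extended outward while bases match. Splitting at N-runs matters: a
spanning contig must yield one block per gap flank — on the same diagonal
when the emitted N count happens to equal the true span — and never a
single block bridging the Ns.

`fillGaps()` closes a gap iff one contig anchors *both* flanks: at least
`min_anchor_bp` (500) aligned per flank at `min_identity` (0.99), within
`max_edge_distance` (100 bp) of the gap edge, same orientation, collinear
in contig coordinates. The contig subsequence between the anchor ends then
replaces the assembly interval between them. Placeholder gaps accept any
implied span ≥ 1 (their N count is arbitrary); sized gaps require the
implied span to be within `span_tolerance` (relative, 0.5) of the N count.
A gap is closed entirely or left intact — no partial shrinkage. Competing
contigs are ranked by total anchored bp, then mean identity, then contig
id; a full tie is an error demanding explicit resolution rather than an
arbitrary pick. Within a sequence, fills are applied right-to-left so
earlier coordinates stay valid while patching. These anchoring thresholds
are declared defaults: the original workflow did not state its own, and
every one is an exposed parameter.

`collapseDuplicationArtifacts()` handles the tandem-repeat artifact: for
each placeholder gap it seeks the longest suffix of the left 25-kb flank
window that matches the prefix of the right window at ≥ 0.99 identity over
≥ 1 kb, with both copies abutting the gap. When found, the gap and one copy
are removed — the sequence shortens by overlap + gap length — which is how
total assembly length can *decrease* while effective (N-free) length
increases, the signature seen in real revisions. Artifact gaps are
naturally immune to mis-filling: a genuine contig carries only one copy of
the duplicated block, so its two flank anchors fail the collinearity test.

## Lift-over

Every edit appends to a piecewise-affine monotone coordinate map.
Positions outside edited intervals map one-to-one (with strand for flips);
positions inside a replaced N-run map to the replacement start; positions
inside a removed duplicate copy map to the corresponding position in the
retained copy. The reverse direction uses only the bijective blocks, so
positions born inside replacement sequence return `NA` rather than a
fabricated pre-image.

## Gene-model grading

Grading consumes per-protein completeness plus best hits against a curated
protein database (UniMag), a Poaceae protein database (UniPoa), and a
hypothetical-TE-protein database (PTREP). A hit is significant when its
E-value is strictly below `evalue_max` and the database-appropriate
coverage is strictly above `coverage_min` (95%): subject coverage for the
protein databases, query coverage for the TE database. The decision tree
(HC1, HC2, REP, LC1, LC2 in order, REP before the complete-no-hit LC
fallback so the repeat tag wins) is documented on `gradeProtein()`. Three
reading choices deserve note:

* the source convention "E-value below 10e-10" is read as $10^{-10}$ by
  default; the literal reading ($10 \times 10^{-10} = 10^{-9}$) is one
  parameter away;
* the HC UniMag clause requires *both* subject and query coverage above
  threshold, per its wording, although general significance uses one
  coverage per database;
* evidence shapes the rules leave silent — e.g. a complete protein whose
  only UniMag hit is below coverage — are `unclassified`, never silently
  promoted or demoted. All $2 \times 3^3 = 54$ evidence shapes are pinned
  by an exhaustive truth-table test.

## Small RNAs

Reads are 18–34 nt (the library trim bounds). `sizeProfile()` returns both
the all-read and the distinct-sequence histograms, separating
abundance-driven peaks (a few highly expressed 21-nt miRNAs) from
diversity-driven ones (many distinct 24-nt hc-siRNAs). `classifyHcSirna()`
counts only 21–24-nt reads overlapping TE features, by superfamily.
`trfClassify()` labels tRNA-aligned reads 5-tRF (start at nucleotide 1),
3-tRF (end at the last nucleotide), otherwise i-tRF, with 5-tRF taking
declared precedence for full-length reads, and allocates the 5' position
into nine bins as `ceiling(9 * start / trna_length)` — the source
describes nine bins without a formula, so the uniform rule is a declared
default with configurable edges in spirit. `polycistronGroup()`
single-links same-sequence pre-miRNA loci separated by strictly fewer than
3000 intervening nucleotides ("separated by" read as intervening
nucleotides, not start-to-start).

## The synthetic world

Every stage is testable without external data because the `fixtures`
module generates a truth genome and everything derived from it, from one
explicit seed, byte-identically.

* `generateGenome()` emulates a Triticeae-like chromosome: a small library
  of repeat monomers (three LTR-retrotransposon-like of 5–8 kb, four
  MITE-like of 100–500 bp) copy-pasted with 1–5% per-copy divergence into
  random background to a target interspersed-repeat fraction (default
  0.844, the repeat content typical of these genomes), plus tandem-repeat
  blocks (10–200 bp monomers arrayed to 2–10 kb) at a Poisson rate per Mb
  (default 5). Each LTR-like monomer carries one nick-site motif at a
  fixed offset: mapping chemistries are chosen for adequate genome-wide
  label density, and real LTR families do carry recognition sites; per-copy
  divergence still destroys some sites, so density varies realistically.
  Without this, repeat-dense stretches are label deserts and scaffolds
  drop below the 9-label floor through no fault of the method.
* `fragmentAssembly()` hides true spans behind placeholder N-runs
  (10/100/1000 by a configurable mix) and sized N-runs, then plants
  requested errors: a scaffold moved between chromosomes, a scaffold
  reverse-complemented in place, or an exact flank duplication around a
  spurious 10-N gap (true span zero). Gaps avoid tandem blocks and each
  other by 3 kb so that a planted duplication is the only suffix/prefix
  identity at a gap. The spec-level interface does not fix a placeholder
  density, so the generator exposes `gap_rate` (default 20/Mb, sized gaps
  2/Mb) — about one gap per 45 kb, a plausible desk-scale density.
* `simulateContigs()` tiles the truth with exponential fragment lengths
  calibrated so the realized N50 approximates the target
  ($N50 \approx 1.678\,m$ for mean $m$), reverse-complements half, applies
  uniform substitutions, and can join unlinked fragments into chimeras.
* `simulateOpticalMap()` digests in silico (labels at motif starts on
  either strand, merged below the 1-kb resolution to cluster midpoints),
  optionally splits maps at fragile sites (opposite-strand nicks within a
  window; off by default — the workflow being modelled used chimera-revised
  consensus maps, and fragility is exercised explicitly in tests), then
  applies label dropout, spurious labels, and sizing noise of the given CV.

What a green end-to-end test establishes: with zero noise, the complete
pipeline (validate → correct → collapse → fill) returns the truth genome
byte-identically at the 2 × 1 Mb scale, with planted misplacement,
inversion, and duplication each recovered exactly. What it does not
establish: robustness to real PacBio error profiles (only uniform
substitutions are modelled), molecule-level map assembly (consensus maps
are simulated directly), structural heterozygosity, or scale beyond a few
Mb per chromosome.

## Numerical and coordinate conventions

* Coordinates are 1-based inclusive everywhere — internal containers are
  IRanges/GRanges, and AGP output is 1-based inclusive per the standard.
  Digest label positions are motif starts (1-based); the nick offset
  within the recognition site is unknowable from the workflow description
  and cancels in fragment arithmetic as long as the convention is
  consistent.
* Label-merge clusters are single-linkage with the cluster replaced by the
  midpoint of its extremes.
* A gap whose true span happens to be exactly 10/100/1000 bp is
  indistinguishable from a placeholder; classification is by length only.
* Percentage columns in census validation carry a 0.01 absolute tolerance
  (printed two-decimal rounding); count and bp columns are exact.
* Degenerate inputs fail loudly: maps with fewer than two labels, evidence
  rows missing a coverage field, liftover positions outside the sequence,
  overlapping edits (the conflicting pair is named), and ties between
  candidate fills are all errors, not silent choices.

## A worked example

```{r example, eval = FALSE}
tr <- generateGenome(seed = 1, n_chrom = 2, chrom_length = 1e6)
fa <- fragmentAssembly(tr, error_plan = list(list(kind = "misplacement"),
                                             list(kind = "inversion"),
                                             list(kind = "flank_duplication")))
maps <- simulateOpticalMap(tr)
vp <- validatePlacements(fa$assembly, maps, alignParams(seed = 7))
corrected <- applyEdits(fa$assembly, vp$edits)
co <- collapseDuplicationArtifacts(corrected$assembly)
ct <- simulateContigs(tr, n50_target = 5e4, coverage = 4)
fg <- fillGaps(co$assembly, placeContigs(co$assembly, ct$contigs),
               ct$contigs)
identical(as.character(assemblySeqs(fg$assembly)),
          as.character(truthGenome(tr)))
```

## Known limitations

* Contig placement is ungapped (substitutions only); true indel-bearing
  long reads would need a gapped extender or an external aligner, whose
  PAF is accepted via `readPAF()`.
* Placement validation needs map signal: scaffolds below the label floor
  are never corrected, and discrepancies smaller than the label spacing
  are invisible — the same resolution limit the underlying technology has.
* The duplication collapse assumes the artifact copies are near-identical
  and abut the gap, per the defect's signature; diverged or offset
  duplications are left alone.
* Multi-error interactions are resolved one edit at a time; pathological
  combinations (e.g. a misplaced scaffold that is itself chimeric) may
  need a second pass.
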