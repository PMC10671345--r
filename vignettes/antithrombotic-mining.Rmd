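---
title: "Mining antithrombotic gene families: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining antithrombotic gene families: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hirumine)
```

`hirumine` is a targeted homology-annotation pipeline for leech salivary
antithrombotic gene families. This vignette is the package's account of
the science behind each stage: the models and their assumptions, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## The registry

Twenty-one archetype families drive every stage, spanning four function
categories: 14 coagulation inhibitors (hirudin, granulin, antistasin,
lefaxin, therostasin, the five hirustasin-superfamily members, eglin,
bdellin, LDTI, HMEI), 3 platelet-aggregation inhibitors (saratin,
apyrase, lumbrokinase), 3 fibrinolysis enhancers (destabilase, GGT, LCI)
and hyaluronidase as a tissue-penetration enhancer. Each descriptor
records the expected mature-protein cysteine count (none for the
cysteine-free lefaxin and eglin), the internal tandem-repeat structure
where one exists (LDTI 2×6 cysteines, antistasin 2×10, granulin 5×12)
and the signal-peptide expectation.

The packaged archetype *sequences* are synthetic stand-ins: deterministic
constructs with the documented length class, cysteine scaffold and repeat
structure of each family (the five hirustasin-superfamily archetypes are
built as diverged variants of one ancestor so that subtype analysis is
meaningful). The published accessions are retained as metadata only. All
recovery results in the test suite are therefore statements about the
*method* under controlled conditions, not about any real genome.

## Alignment and the similarity index

Protein comparison uses Gotoh three-state affine-gap alignment
(Smith–Waterman locally, Needleman–Wunsch globally) with BLOSUM62 and the
EMBOSS `water`/`needle` default penalties — gap open 10.0, gap extend
0.5, a gap of length $L$ costing $10 + 0.5L$. The published workflow
names the tool but not its parameters, so the tool's defaults are the
only defensible choice. Similarity is summarized as

$$\mathrm{SI} = \frac{100 \times \#\{\text{aligned pairs with BLOSUM62 score} > 0\}}
                     {\text{alignment length} - \text{gap columns}}$$

with identities included among positive pairs and `X`/`*` never counted
as similar. Tie-breaks are deterministic: among co-optimal alignments the
*longest* is reported (score and length are optimized lexicographically
through the dynamic program); remaining ties resolve by the traceback
preference match > gap-in-subject > gap-in-query and by the smallest end
coordinates. End-cell rather than start-cell tie-breaking was chosen
because start positions only exist after traceback; the two differ only
on degenerate co-optimal ties.

One property of these penalties matters throughout the pipeline: gap
*extension* at 0.5 per column is almost free, so optimal local alignments
between unrelated sequences tend to be long chains of short positive
segments connected by cheap gaps, and their similarity index is high —
frequently above 50 — because gap columns are excluded from the
denominator. A similarity threshold alone therefore cannot separate
genuine family members from random look-alikes. Every place the pipeline
retains a result it pairs the index with an *absolute* evidence
requirement:

* family assignment (`assign_family`): a family is a candidate only when
  SI ≥ 50 **and** the raw local score is ≥ 60. Without the score gate, a
  five-residue perfect micro-alignment against an unrelated archetype
  reaches SI = 100 and outvotes the true family.
* locus discovery: extension alignments are split into compact segments
  at gap runs of ≥ 10 columns and each segment must reach score 60 on its
  own. A genuine locus is a compact per-exon protein match; gap-chained
  patchwork is not homology evidence.
* model retention: a merged model must overlap a same-strand confirming
  locus. Decoy genes arriving via the ab-initio set never acquire one.

## Six-frame scan

Seeds are exact 4-mer matches between a frame translation and an
archetype; two seeds on the same (archetype, diagonal) within 40 residues
trigger one extension per diagonal/position cluster. Extension is a full
Smith–Waterman of the archetype against a window of the frame translation
(the seeded archetype span ± 30 residues) rather than an X-drop heuristic
— at desk scale the exact alignment is affordable and directly certifies
the module's invariant that every reported locus is confirmed by the full
local aligner at or above the score threshold. Overlapping same-strand
loci merge, keeping the best-scoring archetype.

## Spliced mapping (est2genome style)

CDS-to-genome alignment is a local dynamic program with three column
classes: match/mismatch (+5/−4), affine short indels (open 8, extend 2),
and introns — genome-only gaps admitted solely between `GT..AG` termini,
at least 30 bp long, at a fixed penalty of 40, and flanked by aligned
exon columns. The intron length ceiling is effectively the mapped region
(regions are bounded by a 3 kb flank around each locus cluster, so a
20 kb ceiling never binds at desk scale). A mapping is accepted when at
least 60% of the CDS aligns; the model protein is the translation of the
spliced genomic CDS.

Two subtleties arose in practice and are part of the design:

* **Reading-frame inference.** When the mapped CDS is not an exact copy
  of the locus (a family relative, or a back-translated archetype), end
  trimming and net indels break the correspondence between query codons
  and the genomic CDS, so no single query-derived frame is valid. For
  such inexact mappings the frame of the spliced genomic CDS is inferred
  by homology: all three translations are classified against the
  registry and the best-scoring frame wins.
* **Pseudogene rescue.** Transcript evidence by construction contains
  only intact genes, so a pseudogene locus has no evidence CDS of its
  own. Candidate regions explained by neither an evidence model nor the
  ab-initio set are rescued by spliced mapping of a uniform-codon
  back-translation of the region's best archetype (seeded, hence
  deterministic), in the spirit of protein-to-genome aligners. A rescue
  model is kept only if its inferred protein classifies to the same
  family that seeded the locus.

## Merging, pseudogene flagging, catalogue

Two models are duplicates iff they share a strand and their genomic CDS
footprints overlap with Jaccard ≥ 0.5; within a duplicate group the
evidence tier wins, then the higher alignment score, then the smaller
start. The threshold is configurable; 0.5 is the natural midpoint and the
merge is idempotent under it.

A model is a pseudogene iff its spliced genomic CDS contains an internal
stop codon, or its (frame-adjusted) length is not a multiple of three, or
it lacks an initial ATG while covering at least 60% of its archetype.
The criteria are the package's own operationalization — the source
workflow reports pseudogene outcomes, not a rule — and every criterion
hit is recorded in the model attributes. A single 1-bp deletion is
detected through both routes: the length test when the mapping is exact,
and the frame-shifted garbage translation (which hits a stop within a few
dozen codons with high probability) when it is not.

The catalogue counts classified models per family and source. The
hirustasin/hirustasin-like pair is reported jointly: both members enter
column totals, but the pair counts as one family in nonzero-family
counts. The packaged transcription of the published per-family comparison
table keeps the printed column totals alongside the cells; one column's
cells sum to one less than its printed total, and
`check_printed_totals()` surfaces the discrepancy rather than
reconciling it.

## Protein validation

* **Cysteine scaffolds** are counted on the mature protein (after the
  predicted cleavage) and compared with the family expectation; a
  mismatch is reported as a deviation, never a rejection — real variants
  with a mutated cysteine still belong to their family. Whether published
  per-family counts include signal-peptide cysteines is not stated
  anywhere; the mature-protein convention is this package's choice.
* **Signal peptides** use a deterministic von-Heijne-style rule (a neural
  predictor is out of scope): initial M, a window of 8 residues within
  offsets 1–20 containing ≥ 6 hydrophobic residues (A,I,L,F,V,M,W,C),
  and a small residue (A/G/S) at an offset in [15, 35] after the core;
  the first such offset is the cleavage position. The call is marked
  approximate in all reports.
* **Tandem repeats** are found by aligning the protein against itself
  with the main diagonal masked (only offsets ≥ the minimum unit length
  are admissible). The off-diagonal self-alignment of a tandem array
  aligns the array against itself shifted by one period; detection
  requires similarity ≥ 40, an alignment at least as long as the minimum
  unit length (default 20) and covering ≥ 80% of one period. The array is
  then cut into consecutive period-length units, each reporting its
  cysteine count.

## Classification by trees

Distances are $1 - \mathrm{SI}/100$ on global alignments — reusing the
pipeline's own similarity metric rather than a substitution model.
Neighbor joining replaces the original maximum-likelihood analysis: it is
deterministic, dependency-free at desk scale, and exact on additive
matrices; topology-sensitive conclusions are restricted to clade
membership of near neighbours, where NJ and ML agree on low-divergence
panels. Construction is delegated to `ape::nj` (the field-standard
implementation), with negative branch-length estimates clamped to zero
and flagged. Determinism across reruns — the property the analyses need —
is guaranteed by fixed input ordering.

Subtype assignment roots the panel+query tree at the reference farthest
from the query (so that the query sits nested and its ancestors trace
progressively larger enclosing clades) and takes the label of the
smallest enclosing clade's references if they agree, with two fallbacks
to `"<superfamily>-like"`: conflicting labels in that clade, and nearest
references tied at equal distance with conflicting labels. Activity-clade
prediction for hirudins is a k-nearest-neighbour vote (k = 3, distance
radius 0.6, ties and out-of-radius queries → `unknown`); the published
tree figures show clade structure but no decision rule, so the k-NN rule
is this package's construct.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. Defaults: a 500 kb single-chromosome genome of uniform
background composition; 25 planted genes over 10 families with hirudin
×5, mirroring the multi-copy structure of the real catalogue; 10%
substitution divergence from the archetypes at non-cysteine positions
(scaffolds and repeats preserved by construction); synthetic signal
peptides satisfying the heuristic; two introns per gene (length 60–500,
`GT..AG` termini, exons ≥ 90 bp); genes placed ≥ 5 kb apart; 2
pseudogenes — the last lumbrokinase and destabilase copies, mirroring the
two pseudogenes of the real genome — degraded by a premature stop or a
1-bp deletion; 5 decoy genes of random full-alphabet protein sequence;
transcript evidence containing exactly the integral genes' spliced CDSs;
an ab-initio model set containing 60% of the planted genes at exact
coordinates plus all decoys (mirroring reported partial hirudin recovery
by automated predictors). Reverse translation draws codons uniformly;
codon-usage realism is out of scope. Identical seeds give byte-identical
output.

What passing recovery tests therefore shows: the scan, spliced mapper,
merger, pseudogene flagger and classifier are jointly correct and
precise under realistic gene structure, divergence and decoy load. What
it does not show: performance on real genomes with repeats, GC structure,
non-canonical splice sites, fragmented assemblies, deeper divergence than
30%, or archetypes whose true sequences differ in character from the
synthetic stand-ins.

## Numerical choices and problem sizes

Internal coordinates are 1-based inclusive (the IRanges/GFF3 convention
of the host ecosystem) so that serialized GFF3 equals in-memory
coordinates; positions in *protein feature reports* are 0-based offsets,
the common convention for sequence features. Alignment scores compare
with a 1e-9 tolerance inside the dynamic programs; similarity indices are
exact rational arithmetic. Degenerate inputs are defined, not errors: an
empty local alignment has score 0; translation of fewer than three bases
is the empty protein; a detector finding nothing returns an empty table.

The test suite validates the aligner against an independent plain-R
three-state dynamic program (itself checked against exhaustive
enumeration of all alignments on strings up to length 3), exhaustively
over all pairs of lengths ≤ 2 on a four-letter alphabet plus 600 seeded
random pairs up to length 6; neighbor joining against 50 random additive
matrices with 4–8 leaves; repeat detection over 20 seeds × three repeat
architectures; the full pipeline at the default 500 kb conditions (seed
1) and the merge-value property on a reduced 200 kb genome over 5 seeds.
These sizes are the package's choices for a thorough-but-quick default
run; all are plain parameters in the test code.

## Limitations

* The retention rules (score ≥ 60, compact segments, locus confirmation)
  are calibrated for desk-scale synthetic conditions; real genomes will
  need the exposed `mine_config()` thresholds revisited.
* The signal-peptide heuristic is a coarse stand-in for a trained
  predictor and is expected to miss atypical signal peptides and to
  mis-fire on hydrophobic N-termini.
* Similarity-index distances saturate for unrelated sequences (cheap gap
  extension); trees built from them are meaningful only within families.
* Disulfide connectivity, structural modelling and any laboratory
  quantity (specific activities in U/mg) are out of scope; only the
  titration formula $U = C_1 V_1 / (C_2 V_2)$ is implemented.
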