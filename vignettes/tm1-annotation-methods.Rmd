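---
title: "Annotating Tm1 foldback transposons: models, parameters and design choices"
author: "tm1annot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating Tm1 foldback transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tm1 is a family of class II (cut-and-paste) DNA transposons of root-knot
nematodes (*Meloidogyne*). Unlike most DNA transposons, whose terminal
inverted repeats (TIRs) are short and simple, Tm1 elements carry composite,
internally repetitive TIRs of the *Foldback* type. Each TIR is built from a
small motif grammar:

* **Motif A1 / A2** — asymmetric 7 bp motifs at the very ends of the
  element, *outside* the inverted repeat proper (consensus `CGGTTAA` /
  `CCTACCC` in *M. incognita*; A1 is `CGGATAA` in *M. hapla*). A1 marks the
  left end and A2 the right end of a canonically oriented element.
* **Motif B** — a 3 bp spacer (`GGA`) immediately internal to A1/A2.
* **Motif C** — a tandemly repeated ~14 bp unit (core consensus
  `CGATTCAGTATCGC`), 1–9 consecutive copies per TIR; copy number varies
  between elements and between the two ends of one element, which is why
  TIR lengths vary.
* **Motif D** — a purine-rich ~12 bp stretch (`GGGAAAAGGGGA` core) at the
  TIR's inner end, followed by one further C unit. MITE-like elements lack
  Motif D.

Because the transposase cuts a staggered target, elements are flanked by
8–10 bp (most commonly 9 bp) target site duplications (TSDs), and the
paralogous locus without the element carries a single copy of the target
(the *empty site*).

The package turns this description into a reproducible annotation
pipeline: seed a local-alignment search with a 38 bp composite-TIR query
(one C unit, Motif D, one C unit — `tm1_seed_query()`), pair
opposite-orientation hit clusters into candidate elements, delineate each
candidate's TIRs by aligning it against its own reverse complement,
annotate the motif grammar, call TSDs, classify the element, and summarise
the family.

## The two alignment engines

**Seeded local search** (`seeded_local_search()`) is a BLASTN-style
engine: exact word seeds (hash table), ungapped X-drop extension along the
diagonal, then affine-gapped X-drop extension for segments reaching a
trigger score; the final score of each hit is re-derived by bounded global
DP over the extended extents, so scores are exactly recomputable from the
reported alignment strings. Two presets reproduce the published search
settings verbatim:

| preset | word | match/mismatch | gap open/extend | use |
|---|---|---|---|---|
| `seed-search` | 7 | +1 / −3 | 4 / 2 | genome-wide TIR query, E ≤ 10 |
| `tir-delineation` | 11 | +1 / −2 | 5 / 2, X-drop 50 | element-vs-self TIR delineation |

E-values use ungapped Karlin–Altschul statistics: lambda is solved
numerically from the scoring scheme under a uniform background, K and the
entropy H come from the standard precomputed tables for these two
reward/penalty pairs, and the standard effective-length adjustment
`l = ln(K·m·n)/H` is applied to query and database lengths, as the BLASTN
implementations behind the published settings do. Note that a cutoff of
E ≤ 10 *expects* a handful of chance hits per 100 kb — chance hits are
eliminated downstream by pairing and terminal-motif validation, not by the
cutoff.

**Free-end-gap global alignment** (`global_align_free_end()`) is affine
Needleman–Wunsch with zero-cost terminal gaps. The `"element"` preset
(match 5, mismatch −4, gap 12/3) is used for element-vs-element identity;
the `"motif"` preset (gap 15/6.66) for Motif C repeat units. Traceback
tie-breaking is fixed (diagonal, then gap in the second sequence, then the
first), so identities are bit-reproducible. Low-complexity masking is a
DUST-style triplet score over 64 nt windows; it suppresses seeding only,
never extension, and sequences shorter than the window are scored as a
single clamped window (only sequences under 8 nt are exempt).

## From hits to elements

Hits are clustered per contig and strand by single linkage with a 200 bp
merge window — one composite TIR typically produces several seed hits, and
the tandem C block never spans more than ~150 bp, while distinct elements
are further apart. Every opposite-strand cluster pair with an outer span
of 100 bp – 10 kb is a potential element (published element lengths are
0.17–2.5 kb; the 10 kb ceiling leaves headroom for nested insertions).

Pair selection is the one place where the published procedure (manual
curation of "two or more hits in opposite orientation") needed a real
algorithm. Candidate pairs are scored by cluster strengths plus a bonus
for orientation-consistent terminal motifs probed just outward of each
cluster (A1+B left and B′+A2 right, or their reverse complements for
minus-strand elements; the 10 bp motif+B probe keeps chance matches
negligible), minus a span penalty (1 per 100 bp). The selected set is the
**maximum-weight non-crossing matching** over the ordered clusters of each
contig, computed exactly by interval dynamic programming. This matters for
neighbouring elements: the chimeric pairing of one element's right cluster
with the next element's left cluster, and the "wrap" pairing of their
outer clusters, both lose to the two correct pairings on total score.
Genuinely nested configurations are non-crossing and are kept, flagged
`nested`.

A candidate only becomes a reported element if it carries terminal-motif
evidence: both terminal motifs, or a resolved TIR self-hit plus at least
one motif, or the recombinant A2-at-both-ends configuration. This gate is
what keeps chance hit pairs and residual chimeras out of the final calls.
Distinct candidate hypotheses that converge on the same element bounds
(the strand-split cluster pairs of a single element) are deduplicated by
reciprocal overlap ≥ 0.95.

## TIR delineation and motif annotation

Each candidate window (span ± 200 bp) is searched against its own reverse
complement at the `tir-delineation` preset; the best inverted hit whose
two arms overlap the left and right seed clusters defines the TIR pair,
and its alignment identity is the reported TIR identity. If word size 11
finds nothing (short or diverged TIRs) the search retries at word 7.
Orientation is then resolved by the best-scoring consistent terminal-motif
interpretation — plus (A1 left, A2 right), minus (flip), or A2 at both
ends (reported, never flipped; the configuration expected from
inter-element recombination) — and the element is reverse-complemented if
needed so A1 is left. Element bounds are the outer edges of A1/A2; the
motif search scans ±5 bp around the delineated TIR edge and rescues
outward up to 160 bp, because the self-alignment extent under-calls the
longer TIR by whole C units whenever the two ends differ in copy number.

Motif C decomposition is a small dynamic programme: every position of a
terminal window is either part of a unit of length 8–17 bp (species
envelope) whose edit distance to the consensus is ≤ 3, or skipped at a
cost of 0.75 per residue; the optimum minimises total cost, prefers
covering more residues on ties, and is a partition — units plus skipped
residues reconstruct the sequence exactly. Phase is effectively anchored
by the consensus itself; the inner D-adjacent unit is annotated like any
other. Units must form a tandem chain: a gap of up to 16 bp between
consecutive units is allowed (Motif D sits inside the chain), anything
further inward is payload. The annotation window per end is
`min(180, (element length − 20)/2)` bp — wide enough for B + 9 C units +
D + C, but never reaching the opposite end. The self-alignment extent is
deliberately *not* used as the decomposition region: for MITE-like
elements the inverted-repeat payload chains into the self-hit and would
corrupt both the unit counts and the internal region.

Two printed versions of the Motif C consensus exist (a 15 bp
`CGATTCAGTATCCGC` and the 14 bp logo core `CGATTCAGTATCGC`); the package
uses the 14 bp core as the default and treats the other as a 1-edit
variant, which the edit-distance scoring absorbs.

## TSDs, empty sites, PCR

`detect_tsd()` searches the 15 bp flanks for the best direct repeat with
one copy ending at A1 and one beginning after A2, lengths 7–12, at most
one mismatch (supplementary tables of the family report imperfect TSDs in
lowercase, so perfection is not required), scored by length − mismatches
with ties broken toward 9 bp, then longer. Elements missing one terminal
motif are `n.a.` (not analyzed); missing both, `n.f.`. Empty-site
reconstruction removes the element plus one TSD copy; re-inserting with
duplication is its exact inverse. `in_silico_pcr()` reports every
convergent primer placement with ≤ 1 mismatch and an exact 3 bp 3′
anchor; product length is 5′-end to 5′-end inclusive, matching gel-size
reporting, so an occupied locus and its empty site differ by element
length + one TSD.

## Classification

Classes are assigned by fixed-order rules over internal-sequence features
(`classify_element()`):

1. reference coverage ≥ 0.8 with the MULE-domain region ≥ 0.5 covered →
   **Tm1-A** (putative autonomous);
2. reference coverage ≥ 0.2 with the MULE region uncovered → **Tm1-D**
   (deletion derivative);
3. a histone-hairpin hit → **Tm1-HH**;
4. an internal inverted repeat in a ≤ 600 bp interior → **Tm1-ML**
   (MITE-like);
5. otherwise **other**.

Autonomy is called by similarity to a user-supplied reference interior
(e.g. a transposase CDS with its MULE-domain region named in a side-car
table), not by de novo gene or protein-domain prediction — establishing
the spliced transposase originally required cDNA evidence and protein
databases, which are deliberately out of scope; coverage against a given
reference is deterministic and offline. Hairpin detection is structural
(stem ≥ 6 bp, loop 3–6 nt, ≤ 1 mismatched pair) *and*, by default,
sequence-gated by the 16 nt metazoan histone-hairpin consensus with ≤ 3
mismatches: random sequence is full of incidental stem-loops (the purely
structural scan finds one every few hundred bp), and without the sequence
gate rule 3 would swallow the MITE-like class. The thresholds in rules
1–4 are calibrated against the published class size envelopes (average
lengths 2593/1307/1182/431/788 bp) and are all configuration keys.

Nested insertions are found as ≥ 200 bp gaps in a free-end-gap alignment
to a same-class exemplar; each insertion is re-scanned for an internal
inverted repeat and its own TSD. Because the duplicated target makes the
gap placement ambiguous by one TSD width, the TSD is sought at both
placements (copies as suffixes of the pre-insertion flank and insertion
tail, or as prefixes of the insertion head and following sequence).

## Family summaries

Motif C instances are aligned by center-star multiple alignment (the
center minimises summed pairwise distance; duplicate instances are
collapsed before the distance computation, which selects the identical
center), with the published repeat-alignment gap costs (15 / 6.66).
Sequence logos report per-column information `2 − (H + e(n))` with the
small-sample correction `e(n) = 3/(2·ln2·n)` applied by default, floored
at 0; the consensus shows only positions with positive information.
Group identity is the mean over all unordered pairs of free-end-gap
global identity (the published group identities do not state their
averaging; mean pairwise is implemented and labelled as such). The
MITE-like element tree is Saitou–Nei neighbor joining (via ape) on
`1 − identity` distances from a center-star alignment of the elements,
with support from 100 column-resampling bootstrap replicates under a
mandatory seed.

## The synthetic genome generator

`plant_elements()` is first-class, tested code, not a fixture: it
assembles elements from the grammar

```
TSD · A1 · B · C^n · D · C · payload · rc(C·D) · rc(C^m) · rc(B) · A2 · TSD
```

(D and its flanking C omitted for Tm1-ML), with per-TIR C counts uniform
on 1–9, TSD lengths {8, 9, 10} weighted 2:6:2, random element orientation,
and class-specific payloads: the full synthetic 2.3 kb reference interior
(Tm1-A), a 500–700 bp 3′ fragment of it plus padding (Tm1-D), an 850–1000
bp payload with one histone hairpin at 70% of its length (Tm1-HH), a
60 bp arm + 30–200 bp spacer + reverse-complemented arm (Tm1-ML), or
plain random sequence (other). The default class mix is proportional to
the published family composition (A : D : HH : ML : other = 1 : 8 : 8 :
42 : 2 over 61 elements). The background is i.i.d. uniform ACGT with a
composition knob (uniform keeps false-positive analysis clean; an AT-rich
mode stress-tests the low-complexity masking). Divergence applies
per-site substitutions (and optional indels) to each element and to each
TSD copy independently, after which truth coordinates are recorded, so
ground truth is exact at any divergence. Identical seeds give
byte-identical genomes; the generator keeps its own RNG stream so caller
RNG state is untouched.

The reference interior is synthetic — generated from a fixed seed with a
designated MULE-domain region at 1150–1450 — because a real transposase
sequence cannot be redistributed with the package; classification
behaviour depends only on coverage geometry, not on the particular
residues.

What the generator does **not** emulate: real *Meloidogyne* base
composition and repeat landscape, phylogenetically structured families
(copies are independent draws, not a birth–death process), truncated or
recombinant elements, and sequencing/assembly artifacts. Passing the
recovery benchmarks therefore demonstrates correctness of the pipeline's
logic under the family's structural model, not performance on a real
draft assembly.

## Benchmarks and problem sizes

The test suite exercises recovery end to end at two scales, chosen to
keep the full suite comfortably within a desk-scale run: 50 elements in a
150 kb genome at zero divergence (all of precision, recall, boundary
error, TSD length accuracy and class accuracy must be perfect), and 200
elements in a 400 kb genome at 5% substitutions (recall and class
accuracy ≥ 0.9). The benchmark seeds are fixed (11 for the
zero-divergence block; 42 — the simulator's documented example seed —
for the divergence block). At 5% divergence the dominant loss is
structural, not algorithmic: a MITE-like TIR offers the 38 bp seed query
only a ~10–11 bp exact-match window per C unit, so a one-unit TIR whose
window is hit by substitutions simply produces no seed on that side, and
an element with seeds on one side only is undetectable under the
two-or-more-hits-in-opposite-orientation rule. With per-TIR unit counts
uniform on 1–9 this puts the expected detection ceiling only a few
percent above the 0.9 threshold, so measured recall at 5% divergence sits
close to that threshold by construction; the benchmark in the test suite
reports the realised values.

## Numerical and degenerate-input conventions

All coordinates are 1-based inclusive internally (the R/Bioconductor
convention), written directly to GFF3 and converted to 0-based half-open
for BED. Ambiguity codes other than N are degraded to N on ingest (draft
assemblies pass; a warning is logged). An empty genome or a genome with
no elements is a valid empty result, not an error. All randomness flows
from explicit seeds; reruns with an identical configuration are
byte-identical up to the header hash. Very large (> 2×10⁷ cell)
re-alignment requests inside the seeded search — which arise only from
the trivial self-match of a self-comparison — are scored gaplessly
instead of running the quadratic DP.
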