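# tm1annot

Discovery and annotation of **Tm1**, a family of class II
(*Foldback/Mutator*-like) DNA transposons of root-knot nematodes
(*Meloidogyne*). Tm1 elements are defined by composite terminal inverted
repeats (TIRs) built from a small motif grammar — asymmetric 7 bp terminal
motifs A1/A2 outside the inverted repeat, a 3 bp Motif B, 1–9 tandem
copies of a ~14 bp Motif C, and a purine-rich Motif D at the TIR's inner
end — and by 8–10 bp (most commonly 9 bp) target site duplications (TSDs).

The package is written for genome annotators and transposon biologists
who want a reproducible, scriptable version of the family's discovery
procedure:

1. **Seed search** — a BLASTN-style seeded local aligner (exact word
   seeds, ungapped + affine-gapped X-drop extension, Karlin–Altschul
   E-values with the standard effective-length adjustment) scans a genome
   with a 38 bp composite-TIR query (`tm1_seed_query()`), using the
   published search preset (word size 7, match/mismatch +1/−3, gap 4/2,
   E ≤ 10, DUST-style low-complexity filter).
2. **Element calling** — same-strand hits are clustered (single linkage,
   200 bp); opposite-orientation cluster pairs with spans of 0.1–10 kb
   become candidate elements via an exact maximum-weight non-crossing
   matching, with a pairing bonus for orientation-consistent terminal
   motifs probed outward of each cluster.
3. **TIR delineation and motif annotation** — each candidate is aligned
   against its own reverse complement (word size 11, +1/−2, gap 5/2,
   X-drop 50) to delineate the TIR pair and its identity; the A1/B/C/D
   grammar is annotated, with Motif C decomposed by a dynamic programme
   that optimally partitions each terminal region into consensus-scored
   units.
4. **TSDs, empty sites, PCR** — best flanking direct repeat (7–12 bp,
   ≤ 1 mismatch, ties toward 9 bp); empty-site reconstruction (element +
   one TSD copy excised) and in-silico PCR with a named primer table.
5. **Classification** — Tm1-A (autonomous; reference-interior coverage
   with the MULE-domain region present), Tm1-D (deletion derivative),
   Tm1-HH (histone-hairpin), Tm1-ML (MITE-like: internal inverted repeat,
   short interior, no Motif D), or other.
6. **Family summaries** — per-element tables with the `n.a.`/`n.f.`
   status vocabulary, class summary (counts and mean lengths), Motif C
   length histograms, sequence logos with small-sample correction, group
   identities, and a bootstrapped neighbor-joining tree of the MITE-like
   elements.

A first-class synthetic-genome generator (`plant_elements()`) builds
genomes with grammar-true planted elements, class-specific payloads,
drawn TSDs, optional nested insertions and tunable divergence, with exact
ground truth — so the whole pipeline is testable end to end without any
downloads (`evaluate_recovery()`).

## Worked example

```r
library(tm1annot)

# a 40 kb synthetic genome with 2 histone-hairpin and 3 MITE-like elements
p <- plant_elements(40000, 5, tm1_grammar(), seed = 42,
                    classes = c("Tm1-HH" = 2, "Tm1-ML" = 3))

res <- run_pipeline(tm1_config(p$genome, references = synthetic_reference(),
                               seed = 1))
res$log
#>         seed_hits seed_hits_precull          clusters        candidates
#>                51                98                14                 5
#>          elements        unresolved         tsd_found            tsd_nf
#>                 5                 0                 5                 0
#>            tsd_na
#>                 0

res$table[, c("start", "end", "orientation", "class", "tir_identity",
              "c_units_left", "c_units_right", "tsd_length")]
#>   start   end orientation  class tir_identity c_units_left c_units_right tsd_length
#> 1  7251  8322           - Tm1-HH          100            2             6          8
#> 2 11108 12240           - Tm1-HH          100            4             6          9
#> 3 18589 18899           + Tm1-ML          100            7             1          8
#> 4 39371 39815           + Tm1-ML          100            7             5         10
#> 5 41667 41995           + Tm1-ML          100            1             8          9

evaluate_recovery(p$truth, res$table)[c("precision", "recall",
                                        "boundary_mae", "class_accuracy")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $boundary_mae
#> [1] 0
#> $class_accuracy
#> [1] 1
```

Each row is one called element: its contig span (1-based inclusive),
orientation (normalised so Motif A1 is on the left), class, the identity
between its two TIRs over the self-alignment-defined region, the number
of Motif C units annotated in each TIR, and the called TSD length.

A thin command-line front end over the same functions ships in
`inst/scripts/tm1.R` (`simulate`, `discover`, `run`, `pcr`, `evaluate`).

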