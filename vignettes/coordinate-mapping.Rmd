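---
title: "Mapping genomic positions to protein isoforms and 3D structure residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genomic positions to protein isoforms and 3D structure residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structmapr)
```

## The problem

A residue seen in a crystal or cryo-EM structure lives in three coordinate
systems at once: the author residue numbering of a deposited chain
(possibly non-sequential, disambiguated by insertion codes), the 1-based
position in a protein sequence (which may be any splice isoform of the
gene, not necessarily the canonical database sequence), and the genomic
coordinates of the codon that encodes it (three bases that may straddle an
exon junction, on either strand). Connecting clinical variants to
structural context, or painting structure coverage onto a genome browser,
requires walking this chain in both directions without off-by-one errors.

`structmapr` implements that chain as four composable stages:

1. **codon arithmetic** — transcript-aware mapping between genomic offsets
   and protein positions, honouring strand, CDS phase and exon junctions;
2. **isoform selection** — matching the genomic translation against the
   isoform set of an accession, because the canonical database isoform
   frequently does *not* equal the genomic annotation;
3. **isoform → canonical projection** — a global alignment between the
   selected isoform and the canonical sequence, through which positions are
   projected (residue-level sequence/structure mappings are conventionally
   expressed against the canonical isoform only);
4. **sequence ↔ structure lookup** — a residue-level table in a simple TSV
   dialect (chain, author number, insertion code, observed flag) keyed by
   canonical position.

On top of the mapping chain sit *feature tracks*: provenance-tagged ranged
annotations on the canonical sequence (exon structure, variants with
predicted amino-acid consequences, per-chain structure coverage, sequence
mismatches), serialized as deterministic JSON, plus BED export of structure
coverage back onto the genome.

## Coordinate conventions

All internal genomic coordinates are 0-based half-open; conversion happens
only at file boundaries (GFF3 is 1-based inclusive, BED is 0-based
half-open, CLI point positions and variants are 1-based). Half-open
arithmetic makes codon and interval math closed under composition and
eliminates the classic ±1 errors. Protein and canonical positions are
1-based throughout, matching sequence-database convention.

`phase0` is the phase of the first CDS segment *in transcription order*
(the number of leading bases completing an upstream codon). Only that value
is trusted from the GFF3 phase column; downstream phases are recomputed
from cumulative CDS length and disagreement triggers a warning, because
annotation files are frequently internally inconsistent. Leader bases and
the trailing stop codon map to no protein position: the stop encodes no
residue and database protein sequences exclude it.

Codons containing ambiguous bases translate to `X` and the pipeline
proceeds; `validate_transcript()` separately reports `truncated`,
`internal_stop` and `non_atg_start` findings without raising, so dirty
annotations degrade visibly rather than fatally.

## Isoform selection and alignment

`select_isoform()` prefers exact sequence equality (ties: canonical first,
then smallest id). Non-exact matches are accepted at a global-alignment
identity of at least 0.95 — loose enough to tolerate engineered point
mutations in expression constructs, strict enough to reject paralogs. The
threshold is a configuration knob (`identity_threshold`), not a constant.

The aligner is a Needleman–Wunsch/Gotoh global alignment with identity
scoring: match +2, mismatch −1, gap open −10, gap extension −0.5 (a gap of
length *k* costs −10 − 0.5*k*). Isoforms of one accession are near-identical
segment rearrangements, so a substitution matrix would add parameters
without information; the heavy gap-open penalty keeps splice differences as
single clean gaps. Traceback ties are broken in the fixed order diagonal >
gap-in-canonical > gap-in-isoform, making block output bit-reproducible.
The result is a set of ungapped blocks (mismatches stay inside blocks);
projections through the blocks are partial, monotone bijections —
positions falling in a gap return "none" rather than a nearest guess.

## Pipeline composition semantics

`map_genome_to_structure()` never silently picks a transcript: a genomic
position is answered once per transcript, ordered by transcript id. Each
entry records how far it got; a stage with no answer truncates the entry
with a stated reason (`non-coding`, `no matching isoform`,
`not in canonical`, `no structure`) and never raises. Unobserved residues
(present in the construct, missing from the density) are *not* truncation:
they flow through flagged `observed = FALSE`, so coverage tracks can
distinguish "in construct" from "resolved". The reverse direction mirrors
this per transcript, reporting `not in isoform` when the canonical residue
is deleted in a transcript's isoform.

## The synthetic-fixture world

`make_fixed_fixtures()` is a hand-specified 400 bp world designed so every
edge case has a stable address:

* `T1` (+ strand, two coding exons, 19 residues): codon 11 spans the exon
  junction with its first base as the last base of exon 1.
* `T2` (− strand, single exon, 9 residues): exercises reverse-complement
  arithmetic.
* `T3`: skips a 12 bp in-frame mini-exon, so its translation equals the
  canonical sequence minus residues 5–8 (isoform `ACC1-2`).
* `T4`: retains a 6 bp cassette, inserting two residues after canonical
  position 11 (isoform `ACC1-3`) — the source of "not in canonical"
  truncations.
* `MAP1` (`1XYZ:A`): canonical 3–17 at author numbers 101–115, positions
  12–13 unobserved. `MAP2` (`2ABC:B`): canonical 5–14 including an
  insertion-code residue (auth 107, ins `A`) and an engineered `ALA` at
  canonical 10 for mismatch detection.

`make_random_fixtures(seed, n_genes)` generates clean genes (ATG start,
no internal stop, trailing stop) with 1–8 exons, random phases and both
strands, alternative deletion isoforms with probability 0.5 and residue
mappings with random unobserved runs and occasional insertion codes with
probability 0.7. Defaults emulate compact, well-formed annotation; they do
**not** emulate real-data pathologies — overlapping genes, non-ATG starts,
selenoproteins, frameshifts, chimeric chains — so a green test establishes
coordinate-arithmetic correctness, not robustness to every GENCODE corner
case.

Ground truth is computed by `per_base_ground_truth()`, a one-pass per-base
walk (membership vector, strand ordering, triplet grouping) that shares no
code with the interval-arithmetic mapper it checks.

## Numerical and determinism choices

* Alignment scores are doubles; tie comparisons use an epsilon of 1e-9,
  far below the 0.5 granularity of the scoring scheme.
* All serializers write binary-mode connections with `\n`, sort object
  keys, and avoid locale- or platform-dependent formatting; fixture
  regeneration and track JSON are asserted byte-identical across repeated
  runs (cross-platform identity is by construction — no platform state is
  consulted — but can only be asserted on one machine at a time).
* The random generator saves and restores the caller's RNG state; one seed
  drives all randomness.
* Degenerate inputs: empty mapping files yield empty lists; transcripts
  whose CDS is all leader/stop yield empty translations; features outside
  `[1, canonical length]` are rejected at serialization.

## Testing strategy and oracles

The acceptance suite (`tests/testthat/test-acceptance.R`) is property-based:
exhaustive genome↔protein round-trips on the fixed contig; agreement with
the per-base ground truth on 100 seeded random genes in both directions;
strand symmetry under mirror-imaging the genome; alignment-score agreement
with an independent memoized recursion on 200 random pairs (with a literal
all-paths enumeration additionally asserted for tiny pairs in the unit
tests, where it is tractable); stage-by-stage equality of the composed
pipeline with a brute-force table; byte-stability of all serialized
artifacts; and exact conservation counts. Runtime budgets are asserted
around the computation alone, with assertions performed in bulk afterwards.

## Known limitations

* Standard genetic code only; selenocysteine, mitochondrial codes, RNA
  editing and ribosomal frameshifting are out of scope.
* Residue mappings must be expressed against the canonical isoform;
  mappings naming unknown accessions are dropped with a warning at load.
* The exon-track rule assigning junction codons to the exon containing the
  codon's first base is a documented convention; upstream viewers do not
  specify one.
* The mismatch classifier's terminal-run heuristic labels any mismatch run
  touching the mapped range's edge as a putative expression tag; interior
  runs are substitutions. It does not consult chemical annotations.
* mmCIF/PDB coordinate parsing, live database access and all visualization
  are out of scope: the package is the data backbone, not the viewer.
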