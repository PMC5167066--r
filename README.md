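# structmapr

Bidirectional coordinate mapping between the genome, protein splice
isoforms, and 3D-structure residue numbering — plus provenance-tagged
annotation tracks on the canonical protein sequence and BED export of
structure coverage onto the genome.

## Who this is for

Structural bioinformaticians and variant analysts who need to answer, with
no off-by-one ambiguity:

* *Which structure residue corresponds to this genomic position?* — e.g.
  to place a clinical SNV on a deposited chain;
* *Which codon encodes this structure residue?* — the reverse walk, from a
  chain/author-number/insertion-code triple back to three genomic bases;
* *How do structures, exon boundaries and variants line up on the
  reference (canonical) protein sequence?* — the data model behind
  sequence-feature viewers and genome-browser structure tracks.

## The model

A genomic position maps to protein and structure space through four
composed stages, each a partial function that reports *why* when it has no
answer:

```
genomic offset
  --[codon arithmetic: strand, CDS phase, exon junctions]--> (transcript, protein_pos, codon_offset)
  --[isoform selection: translation vs isoform set]--------> isoform position
  --[global alignment projection]--------------------------> canonical position
  --[residue-level TSV mapping (SIFTS-style)]--------------> chain / auth_num / ins_code
```

Codon arithmetic enumerates CDS bases in transcription order (descending
genomic offsets on the minus strand); the first `phase0` bases are
out-of-frame leaders and the trailing stop codon encodes no residue, so
exactly `3 × protein_length` genomic bases of a transcript map. Isoform
selection is necessary because the canonical database isoform often does
not equal the genomic translation; projection to the canonical sequence
goes through a deterministic Needleman–Wunsch/Gotoh alignment (match +2,
mismatch −1, gap −10 − 0.5·k, fixed tie-break order), since residue-level
structure mappings are conventionally expressed against the canonical
isoform. All internal coordinates are 0-based half-open; GFF3/BED/CLI
conversions happen at the boundary.

## Worked example

Everything is testable offline: the package ships a deterministic
synthetic-fixture generator with known ground truth.

```r
library(structmapr)

b  <- make_fixed_fixtures()          # 400 bp contig, 4 transcripts, 2 accessions
ts <- all_transcripts(b$gene_models)

translate_transcript(ts$T1, b$genome)
#> [1] "MDEFHIKLNPQRSVWYACG"

# residue 11 of T1: its codon spans the exon-1/exon-2 junction
protein_to_codon(ts$T1, 11, b$genome)[c("base_positions", "codon", "amino_acid")]
#> $base_positions
#> [1] 130 200 201
#> $codon
#> [1] "CAA"
#> $amino_acid
#> [1] "Q"
```

The three base positions are non-contiguous — the codon's first base is
the last base of exon 1. Composing all four stages for genomic offset 106
(codon 3 of `T1`):

```r
r <- map_genome_to_structure("chrT", 106, b$gene_models, b$genome,
                             b$isoform_sets, b$maps)
e <- r$entries[[1]]
c(e$transcript_id, e$stage, e$canonical_pos,
  e$hits[[1]]$pdb_id, e$hits[[1]]$auth_num)
#> [1] "T1"  "complete"  "3"  "1XYZ"  "101"
```

The same query answers *per transcript* (never silently picking one): `T2`
truncates with reason `"non-coding"`, while the exon-skipped `T3` and the
cassette-retaining `T4` reach the same structure residue through their own
isoforms (`ACC1-2`, `ACC1-3`). Reverse direction:

```r
map_structure_to_genome("1XYZ", "A", 101, "", b$gene_models, b$genome,
                        b$isoform_sets, b$maps)$entries[[1]]$codon$base_positions
#> [1] 106 107 108
```

## Command line

```sh
DIR=$(mktemp -d)
structmapr fixtures --out "$DIR"                       # write the fixture bundle
structmapr map    --config "$DIR/config.txt" chrT:107  # genome -> structure (JSON)
structmapr rmap   --config "$DIR/config.txt" 1XYZ A 101
structmapr tracks --config "$DIR/config.txt" ACC1      # feature-track JSON
structmapr bed    --config "$DIR/config.txt" T1        # coverage as BED6
```

(`structmapr` is the launcher installed at
`system.file("bin/structmapr", package = "structmapr")`.) `map` on
`chrT:107` prints one JSON entry per transcript; the `T1` entry contains
`"canonical_pos":3` and the hit
`{"auth_num":101,"chain_id":"A",...,"pdb_id":"1XYZ"}`. `bed T1` prints two
records — coverage of residues 3–17 split at the intron:

```
chrT	106	131	1XYZ:A	0	+
chrT	112	131	2ABC:B	0	+
chrT	200	220	1XYZ:A	0	+
chrT	200	211	2ABC:B	0	+
```

Exit codes: 0 success (including "no mapping", with reasons in the JSON),
2 usage/input error, 1 internal error.

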