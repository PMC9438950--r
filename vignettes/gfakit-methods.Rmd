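---
title: "gfakit: model, metrics and editing semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gfakit: model, metrics and editing semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfakit)
```

## The assembly model

gfakit maps every input — FASTA, FASTQ, GFA1, GFA2, optionally gzipped —
onto one GFA2-like model:

* **Segment**: a contig; name, optional sequence (IUPAC codes plus `N`,
  case preserved), optional per-base qualities, length, tags.
* **Gap**: a junction of unknown sequence between two segment *ends*, with
  a sized distance (≥ 0; 0 means abutting contigs) or an unknown distance.
  A *terminal* gap has one open end and models leading/trailing Ns of a
  scaffold.
* **Overlap edge**: a GFA `L`/`E` record; kept, written back, and treated
  like a gap edge for graph connectivity.
* **Path**: one scaffold — an ordered, oriented walk whose elements
  strictly alternate segment/gap (abutting contigs are separated by a
  0-length gap so that one conservation law covers everything):
  scaffold length = Σ segment lengths + Σ gap lengths.

Ends are addressed as head (5′) or tail (3′); a `+` traversal enters at
the head and leaves at the tail. Internally each junction is a single
undirected edge between two ends — the two traversal directions of a
bidirected edge — which avoids double bookkeeping and matches GFA
semantics. Unknown gaps are rendered as 100 `N`s (the NCBI/AGP `U`-row
convention; configurable via `unknown_gap_size`) wherever a linear view is
needed: FASTA output, coordinates, statistics.

On FASTA/FASTQ input, every maximal run of ≥ 1 `N` splits a record into
segments separated by sized gaps whose distance is the run length; this is
the strict reading of "contig" as a contiguous stretch of called bases. A
minimum-run threshold could be added later, but the default is 1 and is
what the statistics assume. Leading/trailing runs become terminal gaps and
are re-emitted on output; `TRIM_NS` removes them. FASTQ qualities are
split at the same boundaries; the quality characters over an N-run carry
no information and are discarded, with `!` (lowest Phred) emitted over
gaps on output.

GFA1 has no gap lines, so GFA1 export is documented as lossy: gaps are
collapsed out of `P` member lists, their lengths stored in a reserved
`gl:Z:` tag (slots: leading terminal, internals, trailing terminal; `u`
for unknown), and the header is marked `ly:Z:1`. Reading that file
restores the gaps, so GFA1 → model → GFA2 is lossless where the standard
itself is not. Similarly, GFA2 `G` lines require two segment references;
terminal gaps are written with `*` in the open slot — a small documented
dialect extension needed to round-trip the terminal-gap model. Qualities
ride in a reserved `QL:Z:` segment tag.

## The graph and path synthesis

`build_graph()` produces an adjacency-list bidirected graph: one node per
segment, one edge per gap/overlap, attached to specific ends; terminal
gaps appear once. `walk_components()` runs a depth-first walk with
deterministic tie-breaks (start segments in ascending uid, neighbours in
insertion order) and linearizes any component in which every end carries
at most one connection and no cycle exists. Branching components are
flagged, never silently linearized: curation semantics are only defined on
linear scaffolds, so `paths_from_graph()` decomposes a branching component
into singleton scaffolds with a warning. GFA inputs that lack
path/ordered-group lines get their scaffolds synthesized this way (from
gap edges only; an overlap edge is evidence, not a declared scaffold
join).

## Statistics

`nx()` uses the dominant community convention: sort descending, take the
shortest length in the first prefix whose sum reaches **≥** x% of the
reference total. The convention matters only at exact halves, which is why
it is pinned by tests. `NG50` uses an expected genome size as the
reference and is reported as absent when x% of it exceeds the assembly.
`aun()` is Σ L²/Σ L, reported to 2 decimals. GC% is computed over
unambiguous A/C/G/T only; other IUPAC codes are tallied as `other`, and
lowercase bases count both in their base tally and as soft-masked. Unknown
gaps enter `total_gap_len` at the placeholder length and are also counted
separately (`n_unknown_gaps`), so either accounting convention can be
reconstructed. The report's invariant `total_scaffold_len =
total_contig_len + total_gap_len` is checked after every edit operation in
the test suite.

The statistics pass is single-scan: one pass over elements plus one sort
per length vector. The scaling check in the acceptance suite measures this
on assemblies of roughly 1, 2, 4 and 8 Mbp (5–40 scaffolds of ~200 kbp)
and asserts a log–log slope below 1.3; these sizes keep the check
informative while the whole suite stays quick, and on this implementation
the observed slope is ~1.0.

## The SAK edit script

The script is plain text, one instruction per line, `#` comments,
case-insensitive verbs; parsing is all-or-nothing and execution is
transactional (an error aborts the run and leaves the input untouched —
curation safety first). The paper-level operations are join, split,
reverse-complement and terminal-N trimming; the remaining verbs (`EXCISE`,
`REMOVE`, `ERASE`, `INVERT`, `RENAME`) close the edit algebra and are this
package's own, as is the operand grammar.

* `JOIN a± b± [gap|*] [name]` — `-` reverse-complements that scaffold
  first; terminal gaps at the junction are replaced by the new gap; the
  default gap is unknown, the default name is the first scaffold's.
* `SPLIT s1 s2` — removes the single gap between two adjacent segments;
  the scaffold splits into `name.1`/`name.2`. `JOIN` and `SPLIT` are
  mutual inverses up to gap and scaffold naming.
* `EXCISE s [gap]` — the segment leaves its scaffold and becomes a
  singleton; the default replacement gap spans the removed segment plus
  its flanking gaps, so scaffold length is conserved unless overridden.
  `REMOVE` is `EXCISE` plus deletion.
* `ERASE sc a-b` — deletes a 0-based half-open coordinate range; segments
  are truncated (an interior cut splits one segment around a 0-length
  gap), covered gaps vanish, and flanking pieces are rejoined by a
  0-length gap so alternation survives.
* `RVCP x` — reverse-complement (involution; case preserved, `N`→`N`);
  for scaffolds the element order and all orientations flip.
* `INVERT s` — flips one segment's orientation flag in place.

Every instruction appends a change-log entry (instruction, effect,
created/deleted elements); replaying the logged instructions on the
original assembly reproduces the edited one. Only `REMOVE` and `ERASE`
change total contig bases, and by exactly the deleted amount — the
conservation ledger asserted after every instruction of the randomized
acceptance scripts.

## Selection, sorting, homopolymers

Selection composes in a fixed order — include-names (kept in list order),
exclude-names, include-intervals, exclude-intervals — for deterministic
behaviour. Interval extraction names results `chrom:start-end` (0-based
half-open, printed as such to stay parseable) and flags intervals that
cover only gap sequence. Name sorting is natural (numeric substrings
compare numerically: `chr2` before `chr10`), all sorts are stable, and
sorting never changes any statistic except per-sequence row order.

Homopolymer compression collapses each maximal run to one base and keeps
the run lengths (a sidecar TSV, since no standard format exists). Run
detection is case-sensitive: case encodes soft-masking, and preserving it
makes decompression an exact inverse on any input — the property the test
suite enforces on random mixed-case sequences. Coordinates and statistics
computed on compressed sequence refer to compressed space.

## The synthetic generator

`generate_fixture()` emulates the shape of a scaffolded long-read
assembly, scaled down: log-normal contig lengths (default meanlog 8 ≈ 3
kbp — real assemblies are orders of magnitude larger, but contiguity
arithmetic is scale-free), Poisson gap counts (mean 2 per scaffold),
log-normal sized-gap lengths clamped to ≥ 1 bp so every gap is visible in
linear formats, optional unknown gaps, terminal gaps and qualities, and a
GC bias of 0.42 (a typical vertebrate value). It records its own
bookkeeping — counts, totals, N50/L50 by naive prefix scan, GC from the
sampled bases — independently of the stats module, so generator truth and
package output are two routes to the same numbers. What it does *not*
emulate: repeats, heterozygosity bubbles, overlap edges, sequencing error,
or realistic gap-size/contig-size correlation. Passing tests therefore
demonstrate the correctness of the arithmetic and the format handling,
not robustness to every artefact of real data.

## Numerical and degenerate-input choices

Lengths are kept as R integers in the model and widened to doubles in all
summary arithmetic (an 8 Gbp total overflows 32-bit integers). Empty
assemblies yield all-zero reports with absent N50/auN; empty FASTA records
produce a diagnostic and an empty scaffold; records that are all `N`
become pure-gap scaffolds (flagged on extraction). Zero-length gaps are
legal in the model (abutting joins) and simply produce no AGP row or BED
interval. Ties in sorting and DFS are broken by input order and ascending
uid everywhere, so all outputs are byte-reproducible.
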