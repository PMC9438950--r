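# gfakit

Summary statistics, format conversion and scriptable curation for genome
assemblies, built on a unified GFA2-like graph model.

## The problem

Genome assemblies circulate as FASTA/FASTQ (linear sequences, gaps rendered
as runs of `N`) and as GFA1/GFA2 graphs (segments, overlap edges and — in
GFA2 — explicit gap records and ordered groups). Assembly evaluation needs
one set of contiguity metrics across all of these, and assembly *curation*
— joining, splitting, reverse-complementing, trimming scaffolds — is most
naturally expressed on the graph, not on flat sequence. gfakit represents
every input in one in-memory model: **segments** (contigs), **gaps** (sized
or unknown, including terminal gaps for leading/trailing Ns), **overlap
edges** and **paths** (one oriented walk per scaffold). A bidirected graph
over segment ends, built with adjacency lists and walked by depth-first
search, supports both path reconstruction and the edit operations.

## The statistics

For scaffold and contig tiers the report includes the classic Nx/Lx family
and the area under the Nx curve:

- **N50** — the length of the shortest sequence in the minimal set of
  longest sequences whose summed length reaches ≥ 50% of the assembly
  total; **L50** is the size of that set. With an expected genome size *G*
  as the reference total these become **NG50/LG50**.
- **auN** = Σᵢ Lᵢ² / Σᵢ Lᵢ — the expected Nx over a uniformly random x,
  insensitive to the 50% threshold.
- Base composition (A/C/G/T/N/other), GC% over unambiguous bases,
  soft-masked (lowercase) count, and graph element counts including
  connected components.

Ties at exact halves follow the "≥ half, first qualifying prefix"
convention.

## A worked example

```r
library(gfakit)

fa <- tempfile(fileext = ".fa")
writeLines(c(">sc1", "ACGNNNTTG"), fa)
asm <- read_fasta(fa)         # 1 scaffold, 2 contigs, 1 sized gap (3 bp)

summarize_assembly(asm)
#> n_scaffolds: 1
#> n_contigs: 2
#> n_gaps: 1
#> ...
#> total_scaffold_len: 9
#> total_contig_len: 6
#> total_gap_len: 3
#> scaffold_n50: 9
#> contig_n50: 3
#> ...

write_gfa(asm)                # the same assembly as GFA2
#> H  VN:Z:2.0
#> S  sc1.1  3  ACG
#> S  sc1.2  3  TTG
#> G  gap1  sc1.1+  sc1.2+  3  *
#> O  sc1  sc1.1+ gap1 sc1.2+

agp_table(asm)                # AGP v2.1 tiling: W / N / W rows
#>   object object_beg object_end part_number component_type ...
#> 1 sc1    1          3          1           W
#> 2 sc1    4          6          2           N
#> 3 sc1    7          9          3           W

# curation: split the scaffold at its gap, then look at the new metrics
res <- sak_execute(asm, "SPLIT sc1.1 sc1.2")
res$log$effect
#> [1] "split sc1 between sc1.1 and sc1.2 (gap gap1 removed)"
summarize_assembly(res$assembly)$n_scaffolds
#> [1] 2
```

The edit script ("SAK", swiss army knife) is plain text, one instruction
per line (`JOIN`, `SPLIT`, `EXCISE`, `REMOVE`, `ERASE`, `RVCP`, `INVERT`,
`TRIM_NS`, `RENAME`), applied in order against the graph; the returned
change log doubles as a replayable record of the curation session.

A command-line wrapper is included:

```sh
Rscript inst/cli/gfakit.R assembly.fa.gz --out-format gfa2 --output out.gfa \
    --sak edits.sak --genome-size 1200000
```

Selection (`--include-list`, `--exclude-bed`, ...), sorting (`--sort
length --descending`), homopolymer compression and AGP/BED/sizes export
hang off the same pipeline; see `?run_pipeline`.

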