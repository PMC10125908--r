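# splicefx

Splicing-aberration calling from SpliceAI delta scores, for people who need
to know *what* a spliceogenic variant does — not just that it does
something.

SpliceAI reports, for every single-nucleotide variant (SNV), four delta
scores and four delta positions within a ±4999 bp window: acceptor gain
(AG), acceptor loss (AL), donor gain (DG) and donor loss (DL). The common
workflow collapses these to a single maximum score and a yes/no
spliceogenicity call. `splicefx` instead interprets the full score/position
quadruple against the exon/CDS structure of a reference transcript and
reports:

- the **aberration type** — pseudoexonization, partial intron retention,
  partial exon deletion, single- or multi-exon skipping, whole intron
  retention, or combinations of these;
- the **exact inserted/deleted size** in bp, always measured against the
  transcript's *native* splice sites (the annotated exon boundaries), never
  against a SpliceAI-predicted site position;
- the **reading-frame effect** (`delta mod 3`) and the altered amino-acid
  sequence in a bracketed notation (three wild-type residues, then the
  novel residues in `[...]`, `*` marking a new stop, `[]` for clean
  in-frame deletions);
- a **nonsense-mediated decay (NMD) flag** by the 50-nt rule (a premature
  stop more than 50 nt upstream of the last exon–exon junction of the
  *altered* transcript), or a truncated-protein flag when the PTC escapes.

## Calling rules in brief

With default thresholds (tunable everywhere): a delta score below 0.02 is
noise; gain-driven calls need a score ≥ 0.05; loss-driven calls need
≥ 0.2. Then, with all positions resolved to genomic coordinates:

| evidence | call | size |
|---|---|---|
| AG + DG in the same intron, acceptor 5′ of donor, 25–500 bp apart | pseudoexonization | donor − acceptor + 1 |
| lone DG in intron *i* | partial intron retention | distance from native donor |
| lone AG in intron *i* | partial intron retention | distance to native acceptor |
| AG or DG inside an exon | partial exon deletion | distance to the native boundary |
| AL + DL at both native sites of one exon | exon skipping | exon length |
| AL at exon *e₁*, DL at exon *e₂* > *e₁* | multi-exon skipping | summed exon lengths |
| DL + AL at both native sites of one intron | whole intron retention | intron length |

Three pairs are structurally indistinguishable from one score quadruple and
are never emitted together (exon skipping with multi-exon skipping, exon
skipping with whole intron retention, partial exon deletion with partial
intron retention); collisions resolve to the higher-scoring call. Other
combinations (e.g. exon skipping plus partial intron retention) are
reported jointly.

## Worked example

The package ships a deterministic synthetic-fixture generator (toy genomes
with real splice dinucleotides, ATG/stop-bounded CDS, and forged SpliceAI
annotations whose ground truth is known by construction):

```r
library(splicefx)
library(dplyr)

corpus <- build_corpus(seed = 7, n_per_type = 1)
res <- splice_annotate(corpus_records(corpus), corpus_transcripts(corpus),
                       corpus_genome(corpus))
res %>% select(gene, aberration_types, inserted_bp, deleted_bp,
               frame_effect, protein_notation, nmd_predicted)
```

```
  gene aberration_types                       inserted_bp deleted_bp frame_effect protein_notation                          nmd_predicted
1 G001 pseudoexonization                              182          0 frameshift   LSN[VGLLYESEGFL*]                          TRUE
2 G002 partial_intron_retention                       264          0 in_frame     PRD[LSRYRCRASTLHILEILAQDAHRTAHLLIRSFHTL*]  TRUE
3 G003 partial_exon_deletion                            0         99 in_frame     DGY[]DEN                                  FALSE
4 G004 exon_skipping                                    0        139 frameshift   IHY[QKAPLCPVLSPQGRGS*]                     TRUE
5 G005 multi_exon_skipping                              0        324 in_frame     RQR[]REP                                  FALSE
6 G006 whole_intron_retention                        1330          0 frameshift   AAN[V*]                                    TRUE
7 G007 exon_skipping;partial_intron_retention         182        155 in_frame     LGQ[RWKNGPTENA*]                           TRUE
8 G008 no_impact                                        0          0 none         .                                         FALSE
9 G009 no_impact                                        0          0 none         .                                         FALSE
```

Reading row 1: the forged AG/DG pair creates a 182-bp pseudoexon;
182 mod 3 ≠ 0, so the frame shifts after residues `LSN`, 11 novel residues
end at a premature stop, and that stop sits more than 50 nt upstream of the
last junction, so NMD is predicted. Row 3 is a 99-bp in-frame exonic
deletion with no missense residue: blank brackets between the flanking
wild-type residues `DGY` and `DEN`. Row 2 is an in-frame 264-bp intron
extension that nevertheless introduces a premature stop inside the retained
sequence. Row 7 shows a reported combination: the same SNV skips one exon
and extends another into its intron.

File-level equivalents: `run_annotate(vcf, genes, annotation, fasta, out)`
consumes a SpliceAI-annotated VCF, a tab-separated gene→RefSeq-transcript
table, a GTF/GFF3/refFlat annotation and a genome FASTA, and writes a TSV
(`"."` for missing, `";"` joining multiple types). `run_benchmark()` scores
predictions against an assay label table (sensitivity, specificity,
per-type accuracy). A thin CLI wrapper lives at `inst/cli/splicefx.R` with
subcommands `annotate`, `benchmark` and `fixtures`, and threshold flags
(`--gain-threshold`, `--loss-threshold`, `--noise-floor`,
`--pseudoexon-min/max`, `--nmd-distance`, `--dp-convention`).

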