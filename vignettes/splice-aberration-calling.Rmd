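---
title: "Calling splicing aberrations from SpliceAI delta scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling splicing aberrations from SpliceAI delta scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefx)
library(dplyr)
```

## The problem

SpliceAI scores a single-nucleotide variant (SNV) by how much it changes
the probability that any position within ±4999 bp is used as a splice
acceptor or donor. Its output per variant–gene pair is four delta scores
with four delta positions: acceptor gain (AG), acceptor loss (AL), donor
gain (DG), donor loss (DL). A maximum-score cutoff answers *whether* a
variant is spliceogenic; it does not say *what* the aberrant transcript
looks like, which is what a diagnostic lab needs to design a validation
assay or judge pathogenicity. `splicefx` closes that gap: it reads the full
quadruple, places each signal on a reference transcript, and emits a typed
aberration with an exact size, the frame consequence, and the altered
protein.

Only SNVs are processed. For an indel the delta positions are measured on
a shifted coordinate system and their interpretation is ambiguous, so
indel rows in the input VCF are counted and skipped.

## Geometry and conventions

All coordinates are 1-based inclusive genomic positions (the VCF/GTF
convention); any half-open source (refFlat) is converted at read time. The
native donor of an intron is the **last base of the upstream exon** and
the native acceptor the **first base of the downstream exon**, in
transcript orientation — the same labeling SpliceAI uses for splice
positions. Exon and intron indices always count in transcript orientation
(exon 1 contains the 5′ end of the mRNA), so minus-strand transcripts
index from the genomic right.

Delta positions are resolved as `variant_pos + dp` regardless of strand
(genome-forward). The SpliceAI documentation does not state the sign
convention unambiguously, so the alternative (strand-relative: `pos − dp`
on the minus strand) is selectable via `thresholds(dp_convention =
"strand_relative")`; the mapping is isolated in `resolve_dp()` so the
choice is a one-flag change.

## Thresholds

Published calibration on curated splicing-assay data motivates the
defaults, all exposed in `thresholds()` and as CLI flags:

| parameter | default | meaning |
|---|---|---|
| `noise_floor` | 0.02 | scores below this are inert everywhere |
| `loss_call_threshold` | 0.2 | minimum score for loss-driven calls (skipping, whole intron retention); the lower bound recommended by the SpliceAI authors |
| `gain_call_threshold` | 0.05 | minimum score for gain-driven calls (pseudoexon, partial retention/deletion); the value found to recover validated deep-intronic events |
| `pseudoexon_min_bp`, `pseudoexon_max_bp` | 25, 500 | accepted pseudoexon size range; brackets the 50–250 bp optimum for efficient exon inclusion |
| `nmd_distance` | 50 | PTC-to-last-junction distance for the NMD rule, nt |

All thresholds are **inclusive**: a score exactly at the threshold fires.
This boundary semantics is pinned by tests at threshold ± 0.01 and at
pseudoexon sizes 24/25/500/501.

## The decision logic

All four signals are first localized: genomic position, containing feature
(exon *i* / intron *i* / outside the transcript), and — for losses — whether
the position coincides exactly with a native splice site.

**Loss pairs.** A strong AL marks the acceptor of exon
*e₁* = intron(AL) + 1; a strong DL marks the donor of exon
*e₂* = intron(DL). One AL/DL pair therefore yields exactly one of:

- *e₁ = e₂*: skipping of that exon (deleted = exon length);
- *e₂ > e₁*: multi-exon skipping of *e₁..e₂* (deleted = summed lengths);
- *e₂ = e₁ − 1*: whole retention of the intron between them (inserted =
  intron length);
- *e₂ < e₁ − 1*: crossed losses — no call, an "unresolved" note.

This exhaustiveness is why the three excluded combinations (skipping with
multi-skipping, skipping with whole intron retention) cannot co-occur: a
single score quadruple has only one AL and one DL.

**Gain calls.** A qualifying AG and DG in the *same* intron with the
acceptor 5′ of the donor form a pseudoexon candidate; it is called iff its
inclusive size `donor − acceptor + 1` lies within 25–500 bp. A candidate
pair outside the range produces *no* gain call at all — the two gains are
interpreted as a failed pseudoexon, not re-read as two independent
retentions. Otherwise, a lone intronic gain is partial intron retention
(size = distance from the native donor for a DG, or to the native acceptor
for an AG), and an exonic gain is partial exon deletion (size = distance
to the exon's native boundary on the matching side). A gain exactly at a
native site sizes to zero and is suppressed. A matching native-site loss
strengthens a partial retention call and is recorded as supporting
evidence, but is not required — a cryptic site can be used alongside the
native one.

**Sizes are always measured to the annotated native site**, never to a
SpliceAI-predicted site position. The distinction matters in practice: a
predicted native-site position a few bases off the annotation shifts the
size by the same few bases. The engine's test suite pins this with a decoy
loss signal placed 6 bp from the native donor and verifies the deletion is
sized from the annotation.

**Collisions.** Partial exon deletion and partial intron retention can
both fire from one quadruple (AG in an exon, DG in an intron). They are
indistinguishable in a single transcript molecule, so the call whose
driving signal scores higher wins; at a tie the loss-driven call wins
(native-site evidence is anchored), and between two gain-driven calls the
retention wins. The losing call is recorded in the record's notes.

**Window limits.** Multi-exon skipping and whole intron retention are
only callable when both losses fall inside the ±4999 bp window. A lone
strong native-site loss whose partner site lies beyond the window is
reported as unresolved with a window-limited qualifier rather than being
silently dropped or promoted to a call; the annotated far boundary simply
cannot be confirmed from the scores. For the same reason, call-level
`window_limited` (computed from the annotated range bounds of the affected
feature) is false in ordinary calls.

## Transcript rebuild and protein consequence

Calls are applied to the exon segment list (pseudoexon inserts a segment;
skipping removes exons; whole intron retention merges across the intron;
partial retention/deletion moves one boundary), the mature mRNA is re-spliced
from the genome on the transcript strand, and the CDS is re-read from the
annotated start codon. The invariant `len(altered) − len(reference) =
Σ inserted − Σ deleted` is property-tested on every forged fixture.

Translation uses the standard genetic code; an `N`-containing codon gives
`X`; translation stops at (and consumes) the first stop codon. A premature
termination codon (PTC) is a stop whose position in the altered mRNA is
upstream of the native stop. The notation then reports up to three
wild-type residues before the first changed residue and the novel sequence
in brackets: through the new stop (`*` printed inside) for frameshifts and
premature stops, or to the point of re-synchronization (longest common
suffix) for in-frame events; a clean in-frame deletion serializes as
`XXX[]YYY`. Identical proteins give `"."`.

NMD is predicted by the canonical 50-nt rule evaluated on the **altered**
transcript's junction chain: flag iff the PTC lies more than
`nmd_distance` nt upstream of the last exon–exon junction; a PTC in the
last exon or within the boundary predicts a truncated protein instead.
When a call removes or splits the annotated start or stop codon, protein
prediction is suppressed with an explanatory note — there is no principled
reading frame to report in that case.

## Synthetic fixtures: what they do and do not show

`make_toy_gene()` builds a random contig containing one gene with correct
splice dinucleotides (GT/AG), an ATG at the CDS start, a stop codon at the
CDS end and no internal in-frame stop; minus-strand genes are exact mirror
images, which gives the strand-symmetry property its teeth.
`forge_case()` places delta scores/positions so that a chosen aberration
(or nothing) is the ground truth *by construction* — the truth is computed
from the generation parameters, never from the engine. The default corpus
covers all six types, a combination case (exon skipping plus a partial
retention in a different intron, so the rebuild is coherent), a
window-limited case and negatives, balanced across strands.

Forged scores are placed well clear of thresholds except in the dedicated
boundary cases, and are rounded to the two decimals a SpliceAI VCF prints,
so file round-trips are exact. What the fixtures deliberately do **not**
emulate: sequence-derived score structure (forged scores carry no motif
information), multi-gene loci, overlapping transcripts, indels, and the
correlated noise of real SpliceAI output. Perfect corpus recovery
therefore validates the *interpretation arithmetic*, not SpliceAI itself;
performance on real variants is bounded by the upstream scores.

Problem sizes used by the shipped checks: 30 cases per category (270
total) for the end-to-end corpus, 10,000 fuzzed signal sets for the
structural-exclusion property, and a 5×5 threshold grid for monotonicity —
sizes chosen to exercise every branch while keeping a full run in well
under a coffee break.

## Numerical and design notes

- Exact integer arithmetic throughout; there are no tolerances in the
  engine. Ties in collision resolution are broken deterministically (loss
  over gain, retention over deletion) and documented in the output notes.
- Detector-level threshold monotonicity (anything called at a stricter
  threshold is called at a laxer one) holds on the corpus and is asserted
  over the grid, but is not a theorem for adversarial inputs: lowering the
  gain threshold can complete a pseudoexon pair that then consumes a gain
  previously read as a partial retention. Variant-level spliceogenicity
  remains monotone.
- A combination whose retention is anchored to a skipped exon has no
  biological anchor; the rebuild keeps the skip and drops the extension.
- Genes absent from the gene→transcript table, transcripts absent from the
  annotation, and non-coding transcripts are reported with explicit
  statuses (`no_transcript`, missing-transcript warnings, protein
  prediction disabled), never silently dropped.

## Limitations

- SNVs only; no indel support, by design.
- One transcript per gene, supplied by the user's table; no automatic
  canonical-transcript selection.
- No modelling of EJC-independent or UTR-mediated NMD escape; the 50-nt
  rule is a deliberately simple, auditable proxy.
- No use of a masked/raw score distinction; scores are taken as given.
- The 50–250 bp "optimal" pseudoexon sub-range is not used as a
  confidence tier; the single 25–500 bp gate is applied.
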