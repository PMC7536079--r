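---
title: "Dissecting coding-region tandem-repeat architecture in a lectin gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting coding-region tandem-repeat architecture in a lectin gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrfam)
```

## The biological problem

Invertebrate C-type lectins are pattern-recognition receptors whose
carbohydrate-recognition domain (CRD) carries an EPN (mannose-type) or QPD
(galactose-type) tripeptide at Ca^2+^ site 2. In some crustacean lectin
families — the model for this package is the Rlec family of the oriental
river prawn — the second exon of every family member contains an in-frame
tandem-repeat region: an array of 30- or 33-nt units (10 or 11 codons)
repeated head-to-tail, with copy numbers varying from 1 to 9 among members.
Family members fall into types defined by a diagnostic six-amino-acid motif
in the block encoded by exon 5, and copy-number differences between members
of a type look like slipped-strand mispairing (replication slippage):
whole-unit excisions that conserve the flanking units. On top of this, the
family diversifies through alternative splicing in three modes: alternative
acceptor sites, combined alternative donor + acceptor sites, and exon
skipping.

`vntrfam` turns that descriptive analysis into a tested pipeline:

1. **seqio** — FASTA/GFF3 I/O, ORF finding, translation, polyadenylation
   signal and EPN/QPD scanning;
2. **repeat decomposition** — segmenting each CDS into an ordered unit
   array with 5′/3′ flanks;
3. **typing and phylogeny** — motif-based type assignment and a
   neighbour-joining tree with bootstrap support over repeat-masked
   proteins;
4. **arrangement catalogue** — unique unit-length patterns per copy
   number;
5. **slippage inference** — pairwise unit-excision events classified into
   five flank-conservation classes;
6. **splice classification** — transcript-versus-gene-model comparison
   with canonical GT/AG validation;
7. **a synthetic family generator** with complete ground truth, used by
   every test in the package.

## Coordinate and backbone conventions

Internally all coordinates are 0-based half-open; GFF3 I/O converts to and
from the standard's 1-based inclusive convention. Gene models are
plus-strand only.

The backbone gene has six coding exons of 160, 267, 159, 106, 108 and
58 nt separated by introns of 201, 910, 420, 563 and 532 nt. These printed
lengths are mutually consistent only if the non-repeat part of exon 2 is
24 nt: the 8-unit reference member has a 243-nt repeat region
(33 + 7×30) and a 267-nt exon 2, and the 9-unit member's 894-nt ORF is
591 nt (exons 1, 3–6) + 24 nt (exon-2 flanks) + 279 nt (repeat region).
The generator therefore places the repeat region between a 14-nt and a
10-nt flank inside exon 2, which also puts its start on a codon boundary
(CDS offset 174). Exon 2 scales with copy number (exons 1, 3 and 6 are
constant across members, as in the real family); the 5′UTR (47 nt) rides
inside exon 1 and the 3′UTR (467 nt, with an AATAAA signal 26 nt from the
3′ end) inside exon 6, so an emitted cDNA is an exact concatenation of
exon sequences.

```{r backbone}
cfg <- family_config(n_members = 1, motifs = "YRSKDD",
  fixed_patterns = list(c(33, 30, 30, 30, 30, 30, 33, 30, 33)),
  substitution_rate = 0, type_divergence = 0, seed = 1)
fam <- generate_family(cfg)
annotate_transcripts(fam$transcripts[, c("id", "seq")])[,
  c("id", "cdna_len", "utr5_len", "orf_len", "utr3_len", "protein_len")]
```

## Repeat decomposition

Decomposition is a three-step procedure.

**Period detection.** For each candidate period $p \in [24, 39]$, the
match indicator $m_i = [s_i = s_{i+p}]$ is averaged over the best window
of length $2p$, so a tandem region embedded in non-repetitive flanks still
scores 1.0. A score below 0.8 (default) means no usable self-similarity —
which is always the case for single-copy arrays, since one unit has
nothing to match against.

**Consensus and phase.** The per-column majority over period-length
windows of the detected region gives a raw consensus, but the region fixes
only the period, not the unit boundary phase. All $p$ rotations of the raw
consensus are therefore scored by a trial segmentation and the best phase
wins; ties (homogeneous arrays are genuinely phase-ambiguous) prefer a
frame-consistent region start (in-frame repeats begin on codon
boundaries), then the 5′-most region. The consensus is refined once by
column majority over the segmented full-length units and re-scanned,
because the first tiling may sit in a shifted phase. Mixed 30/33 arrays
can score similarly at both periods and the wrong one yields a chimeric
consensus, so the top three qualifying periods are each tried in full.

**Segmentation.** A dynamic program tiles a maximal contiguous region
into units whose identity to the consensus is at least 0.8, allowing unit
lengths equal to the consensus length ± one codon (intersected with the
configured set, default {30, 33}) — codon-granular indels only, which
enforces the family's observed frame preservation. The objective is
lexicographic: total matched bases, then total identity (this breaks phase
ties in favour of exact-length units over units padded with flank bases),
then fewer units, then the 5′-most region. A unit whose length differs
from the consensus pays a penalty of 2 matched-base equivalents: a codon
indel is rarer than two substitutions, and without the penalty a noisy
edge unit can "gain" a matched base by absorbing three flank bases through
a spurious codon deletion. Successful decompositions satisfy the
reconstruction identity `flank5 + units + flank3 == CDS`, byte-exact.

Members whose own signal is undetectable (copy number 1–2, or arrays with
no two adjacent similar units) are rescued at the family level:
`decompose_repeats()` retries them with consensus units borrowed from
successfully decomposed members, strongest signal first — the same logic a
geneticist uses when genotyping a short allele against the family's known
unit.

```{r decompose}
dec <- decompose_repeats(tibble::tibble(id = fam$members$id,
  seq = fam$members$cds))
dec[, c("id", "copy_number", "pattern", "region_len", "flank5_len")]
```

## Typing and phylogeny

The diagnostic motif is located by a configurable anchor — a conserved
upstream context k-mer (located exactly, then with one tolerated mismatch)
plus an offset — rather than a fixed residue coordinate, because
copy-number variation shifts absolute positions. One type per unique
motif; the type label is the motif itself, the field's naming convention.

Trees are built on repeat-masked proteins (repeat-encoded residues
removed, not substituted), so copy number does not dominate the distances:
with the backbone above, every masked protein is 204 aa regardless of copy
number. Distances are p-distances (columns with gaps or X excluded) — the
simplest defensible choice where the original analysis names only the
neighbour-joining method, and exposed as such. The NJ implementation is
the classic Saitou–Nei agglomeration with deterministic lowest-index
tie-breaks; negative branch lengths are clamped to zero with a warning.
Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and reports bipartition frequencies; the same seed
always gives the same supports.

If a detected repeat phase is off the codon frame (the tiling chooses the
phase, which is not pinned to codons), the pipeline rounds the region to
the nearest codon boundary when masking so the masked protein keeps its
length.

## Arrangement catalogue

A pattern is the ordered, 5′→3′ dash-joined unit-length string
(`"33-30-30-33"`); no reversal or rotation, because orientation is
biological. Identity is by unit length only, matching how such catalogues
are drawn; a `by_sequence` flag refines length-identical patterns whose
units have diverged below a configurable nucleotide identity (default
0.95). The catalogue partitions members (each appears in exactly one
pattern row) and is invariant under input order.

## Slippage inference

For each ordered within-type pair (longer, shorter), the inference finds
the order-preserving matching of all shorter units into the longer array
(deletions only in the longer) that maximizes matched units; among maxima
it prefers a single contiguous excised block, then the 5′-most block. Two
units match if they have equal length and ungapped identity ≥ 0.9.
Because two members may have been decomposed with different consensus
rotations (and thus rotated unit boundaries), the shorter member is also
re-segmented with the longer's consensus and the candidate that yields a
classified event wins.

Events are classified by a decision table over (conserved 5′/3′ flank
counts, excised unit lengths, array composition), evaluated
most-specific-first (5, 1, 2, 4, 3):

| class | conserved 5′ | conserved 3′ | excised units | extra condition |
|-------|--------------|--------------|---------------|-----------------|
| 5     | –            | –            | all 33 nt     | both arrays all-33 |
| 1     | ≥ 1          | ≥ 3          | all 30 nt     | |
| 2     | ≥ 2          | ≥ 1          | all 33 nt     | |
| 4     | ≥ 1          | ≥ 2          | all 30 nt     | class 1 failed |
| 3     | ≥ 1          | ≥ 1          | all 30 nt     | classes 1, 4 failed |

Flank thresholds are "at least" because the published examples are
exemplars, not exhaustive rules; they are exposed in the classifier's
arguments. Mixed excised lengths admit no class. The same event always
reports the contraction direction (longer → shorter); the data cannot
distinguish contraction from expansion.

## Splice classification

Transcripts are mapped onto gene models by exact matching — the data such
analyses come from are Sanger-sequenced clones, effectively mismatch-free
— with each exon contributing one contiguous substring, in order. The
mapper is a depth-first search preferring the longest contribution at the
5′-most exon offset, with two guards: an exon must anchor at least 8 nt
(unless its match consumes the remainder of the transcript), so short
coincidental matches cannot make a skipped exon look used; and a maximal
match may be backed off by up to 15 nt to resolve junction overlap.

Per-exon comparison against the canonical product yields the three modes:
a 5′ truncation is an alternative acceptor; a 3′ truncation of exon *i*
together with a 5′ truncation of exon *i*+1 is one combined
donor/acceptor event (a flag splits it in two); a fully absent exon is
skipping. Donor-side junctions can be genuinely ambiguous — when the
retained end of exon *i* equals the first bases of the acceptor side, the
offset pairs (d + k, a − k) all reproduce the transcript — and are
realigned to the pair whose shifted junctions carry GT/AG context, the
same criterion used to validate real splice sites
(`validate_splice_sites()` checks each intron for GT..AG;
`shifted_site_validation()` checks the alternative junctions). Intron
retention does not map and is reported as a mapping failure, since the
family shows no such mode.

```{r splice}
sv_cfg <- family_config(n_members = 0,
  n_splice_variants = c(alt_acceptor = 1, alt_donor_acceptor = 1,
    exon_skipping = 1), seed = 2)
sv_fam <- generate_family(sv_cfg)
classify_splicing(sv_fam$models, sv_fam$transcripts)[,
  c("transcript_id", "mode", "exon", "exon2", "donor_offset",
    "acceptor_offset")]
```

## What the generator emulates — and what it does not

`generate_family()` builds a founder gene (random stop-free codons, GT..AG
introns, protected start/stop, planted EPN tripeptide and motif anchor
context), derives one founder per type by mutation plus motif
substitution, and derives members by further mutation with per-member
repeat arrays. Defaults are the study conditions: 76 members, 15 motifs,
copy numbers uniform on 1–9 (the real distribution is not published),
within-type substitution rate 0.01 and type-founder divergence 0.05 —
members of a type are "highly conserved" while types form well-separated,
monophyletic clades (a 5× ratio achieves both). The 33-nt unit is the
30-nt unit with one codon inserted at a fixed position, so mixed arrays
stay alignable within a type. Unit mutations are realized at third codon
positions (at 3× the per-base rate, preserving the expected count), which
keeps units stop-free by construction. Mutations never touch the motif
anchor, start/stop codons, splice sites or the polyadenylation signal
unless the `hostile` flag lifts that protection — those signals are kept
separate from what is being tested.

Planted slippage pairs use fixed per-class recipes whose conserved flank
units carry small distinguishing marks (2–4 third-position substitutions,
sized so marked units fail the 0.9 unit-match threshold against each
other and against plain units, while still passing the 0.8 segmentation
threshold). Without marks, excisions from homogeneous arrays are
mathematically unidentifiable — any same-size block explains the data —
which mirrors the real situation: published exemplars are recognizable
precisely because their units differ.

What passing tests on synthetic families do **not** show: robustness to
alignment errors or indels outside the repeat region (members are
generated indel-free outside the array), sequencing error models beyond
uniform substitution, paralog assembly artefacts, or intron-length
variation (intron lengths are fixed at the backbone values though their
sequences mutate). Real data should be quality-controlled before the
mismatch-free splice mapper is applied.

## Numerical choices and degenerate inputs

* Identity thresholds: 0.8 per unit against the consensus (keeps divergent
  first/last units while rejecting flank sequence), 0.9 for unit-unit
  matching in slippage inference; both exposed as arguments.
* Consensus ties in a column go to the alphabetically first base; `N`
  never matches anything and codons containing `N` translate to `X`.
* Empty decompositions (no period and no rescuing consensus) return a
  zero-unit array with the whole CDS as 5′ flank, flagged for review, not
  an error.
* ORF finding returns the longest ATG-initiated stop-terminated frame
  (stop included in the span), 5′-most on ties; no ORF is a `NULL`
  result, not an exception.
* NJ requires a symmetric zero-diagonal matrix and at least 3 taxa;
  Q-matrix ties break to the lowest index pair.
* Bootstrap with `n_reps = 0` returns the bipartitions with zero support
  rather than omitting them.

## Problem sizes

The test suite runs the full pipeline on families of 6–19 members across
several seeds, a 76-member family for type counting, a 200-member family
at 2% substitution for copy-number recovery (the package recovers
≥ 95%), 50 additive matrices (4–7 taxa) against the generating-topology
oracle, and 100 small instances against an exhaustive tiling search.
These sizes were chosen to exercise every code path while keeping a full
check fast on a laptop; all of them are generated in code at test time.

## Known limitations

* Single-copy arrays are only decomposable relative to a family (or
  supplied) consensus; an isolated single-copy CDS yields a flagged empty
  result.
* The progressive alignment needed for real (indel-containing) protein
  sets is out of scope: trees require equal-length masked proteins, which
  the no-indel synthetic backbone guarantees. Align externally first for
  real data.
* Slippage classification reports pairwise events; reconstructing
  multi-step series or ancestral copy numbers is left to the user.
* Minus-strand gene models are rejected on ingest rather than
  reverse-complemented automatically.
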