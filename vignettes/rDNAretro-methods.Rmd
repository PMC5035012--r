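---
title: "Methods: junction analysis of rDNA-targeting R2 retrotransposons"
author: "rDNAretro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction analysis of rDNA-targeting R2 retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rDNAretro)
```

## The problem and the model

R2 non-LTR retrotransposons integrate by target-primed reverse
transcription at one fixed position inside 28S rRNA genes. The enzyme
nicks the bottom strand at an essentially invariant position, while the
top-strand cut varies by a few bases. Characterizing a family therefore
reduces to a small set of measurements against a single target
coordinate system:

* the **canonical insertion site**, stored here as the number of target
  bases preceding the insertion point, so an element inserted
  canonically sits between positions `canonicalSite` and
  `canonicalSite + 1`;
* the **junction offsets**: `offset5` is the number of target bases
  immediately upstream of the site absent at the element's 5′ junction
  (0 = canonical; 110 or 130 = that much 28S replaced by the element),
  `offset3` the downstream analogue;
* **family specificity**: `target_specific` families have essentially
  all copies adjacent to 28S, `non_specific` families none, and
  `partially_specific` covers the intermediate (e.g. a two-copy family
  with exactly one copy flanked by 28S);
* the **clade** (R2A–R2D), read from the CCHH/CCHC zinc-finger
  complement upstream of the RT domain: (2,1) CCHH/CCHC → R2A, (1,1) →
  R2B, (2,0) → R2C, (1,0) → R2D, anything else → `unknown` (reported,
  never an error);
* a possible **28S-derived 3′ UTR segment**: a degraded copy of the
  target sequence downstream of the site embedded inside the element's
  3′ UTR, recognizable because its identity to the 28S is clearly lower
  than that of true genomic flanks.

## What the simulator emulates — and what it does not

`buildTargetReference()` defines the synthetic 28S junction context from
the reverse complements of two 28S reverse PCR primers, concatenated
with the canonical site at their junction and padded with random flanks.
This is a documented *convention* for sequence context around the site,
not a claim about the biological 28S; all junction arithmetic depends
only on the coordinate, not the bases. Construction is resampled until
each 20-mer block occurs exactly once in the reference (on either
strand), so primer-site logic is unambiguous.

`simulateElementFamily()` builds a full element: 5′ UTR (optionally with
the HDV-like ribozyme core `CCTCCTCGTGG` at a recorded position; the
default position 37 reproduces a motif at nucleotides 37–47), one long
ORF (clade-specific zinc fingers in a fixed-length 120-aa block, then
filler drawn from an alphabet without C and H so no spurious fingers can
arise, with concrete in-frame binding sites for the nested degenerate
primers R2IIF2 and R2IF2 around the middle of the ORF), and a 3′ UTR
optionally carrying a copy of the target's downstream sequence mutated
to a requested identity. The fixed-length zinc-finger block makes ORF
products from different clades directly stackable as an alignment,
which the tree stage exploits.

`insertCopies()` assembles `spacer | unit | spacer | ... | unit | spacer`
with fixed-length uniform-random spacers (GC 0.5) and splices each
site-specific copy into one unit, deleting `offset5`/`offset3` target
bases. Decay is independent per-base substitution at the configured
rate; indels are optional at one tenth of that rate with geometric
lengths (mean 2). Truncation is 5′-only, matching the biology of
abortive target-primed reverse transcription. Non-specific copies are
placed uniformly inside spacers but kept at least ~100 bp away from the
spacer ends: a copy dropped a few bases from an rDNA unit would carry a
genuine 28S flank and its "non-specific" truth label would be wrong —
an inconsistency we observed before introducing the margin.

Deliberately **not** modeled: concerted evolution of the array, copy
number dynamics, segmental duplications, sequencing error, and
assembly-collapse artifacts. Passing tests therefore demonstrate
correctness of the measurement machinery on substitution-decayed copies
with known geometry, not robustness to every feature of real
assemblies (indel-rich decay in particular fragments seed chains and is
only lightly exercised).

## Copy discovery and junction calling

`findCopies()` seeds with exact k-mers (default k = 12), chains seeds on
nearby diagonals, and refines boundaries by ungapped X-drop extension
(match +1, mismatch −3, drop 12). Because a short terminal cluster of
mutations can stop the extension a few bases early, boundaries within
25 bp of a consensus end are *snapped* to the end when the skipped tail
still matches the consensus at ≥ 0.5 identity (random sequence matches
at ~0.25, element-derived sequence at ≥ ~0.8 for the divergences of
interest, so the rule is well separated on both sides). Overlapping
candidates are resolved best-hit-first by length × identity.

`callJunctions()` aligns the 60 bp (configurable) flanking each element
end to the target with the compiled Smith–Waterman. A flank qualifies
when its **window identity** — aligned matches divided by the full
window length, so unaligned positions count as mismatches — reaches 0.8
over a window of at least 30 bp. This denominator matters: the best
purely local alignment that 60 bp of random spacer achieves against a
440 bp target occasionally exceeds 0.8 *within-alignment* identity by
stitching short gapped matches, whereas its window identity stays near
0.4–0.55. True 28S flanks sit near 1.0. The element boundary is
projected from the aligned block only; slack between the aligned block
and the boundary (target-site alteration, or a boundary miscalled by a
base or two) is reported as `flank5_gap`/`flank3_gap`, not folded into
the offset.

Tolerances are asymmetric by default — `tol5 = 2`, `tol3 = 0` —
because bottom-strand cleavage at the site is strict while top-strand
cleavage varies. Offsets are reported on target coordinates regardless
of element strand. When only one flank qualifies, the missing side is
treated as displaced (the copy is still *adjacent*); when neither
qualifies the copy is `non_adjacent`. Offsets in this artifact are
measured to the stored canonical site; whether published "~110/130 bp"
figures were measured to the top- or bottom-strand cut is unknowable
from text alone, a ±2 bp ambiguity absorbed by `tol5`.

`classifyFamily()` needs a `specific_fraction` (default 0.9): families
at or above it are `target_specific`, zero adjacency is `non_specific`,
anything in between `partially_specific`.

### 28S-like 3′ UTRs and rDNA masking

`detectTargetLikeUTR()` aligns the 3′-terminal 300 bp of the consensus
to the target. A qualifying hit needs ≥ 30 aligned columns **and**
identity ≥ 0.7: without the identity floor, random UTR sequence
produces ~0.6-identity noise alignments against a 28S-sized target and
every family would be flagged. The segment is called internal when its
identity is below the measured flank identity minus a 0.02 margin; the
margin absorbs local-alignment noise (an exact embedded segment scores
~0.99 rather than 1.0 because the optimal local alignment extends a few
columns into surrounding random UTR). The degenerate case — an exact
28S copy at the very 3′ end — is therefore reported `FALSE`:
indistinguishable from true flank, by design.

A family carrying such a segment makes *every* intact 28S unit produce
a short spurious copy call. `maskTargetMatches()` removes calls whose
genomic sequence is explained by the target itself (local alignment
covering ≥ 80% of the call at identity at least the call's identity to
the element); the pipeline applies it after scanning. This is the
standard "mask the rDNA" practice, made explicit.

## Virtual PCR

`virtualPCR()` enumerates all inward-facing primer-pair placements with
product length in `(0, maxLen]`, on both template orientations, with
exact IUPAC matching by default (`maxMismatch` relaxes it; primer-site
decay is a plausible reason real families escape PCR). `maxLen`
defaults to 3000 bp — the product scale implied by a 2-minute extension
step, plus margin. Template ambiguity codes match a primer code only by
exact identity, so degenerate templates never silently inflate match
counts. Nested/duplicate products are all reported; deduplication is
the caller's concern.

## Consensus and identity

`majorityConsensus()` is per-column majority over A/C/G/T with a gap
rule (columns with gap frequency ≥ 0.5 by default are omitted), ties
broken A<C<G<T and flagged, and N never winning (all-N columns emit N).
With 10 copies at 5% divergence the per-column majority error rate is
far below 10⁻³, so the rebuilt consensus matches the ancestor at
≥ 99.5% of columns — verified over 50 seeds.

`pairwiseIdentity()` aligns globally with the shared scoring and offers
two denominators, `aligned_columns` (default; dual-gap columns
excluded) and `shorter_seq`, because published percent-identity figures
rarely state their convention; the choice is exposed rather than
guessed.

## Distance phylogeny

The tree stage is intentionally model-free: p-distance (pairwise or
complete deletion; `-`, `X`, `?`, `*`, `.` never compared) feeding a
bespoke Saitou–Nei neighbor joining with deterministic tie-breaking
(lexicographically smallest label pair; internal nodes keyed by their
smallest leaf) and negative branch lengths clamped to zero and counted.
`bootstrapSupport()` resamples columns and scores each internal edge of
the full-data tree by bipartition frequency. Maximum-likelihood
inference and substitution-model selection are out of scope; the claim
tested is clade *monophyly* on synthetic families (three descendants
per clade ancestor at 5% protein divergence — within-clade distances
~0.1, between-clade ~0.9 — recovered as connected subtrees in ≥ 95 of
100 simulations), not any particular published topology.

A note on clade typing under decay: a single decayed copy loses a
finger whenever one of its 4 coordinating residues mutates, so at 5%
per-residue divergence single-sequence recovery is only
0.95^(4·fingers) ≈ 54–81% — no scanner can do better without profile
scoring, which is out of scope. The pipeline instead types the
*consensus*: rebuilding from 10 copies at 5% DNA divergence restores
the complement essentially always, and that is the property the test
suite asserts.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in the R API and output
  files (IRanges/GRanges convention); the canonical site is a boundary
  count, so offset arithmetic is convention-free.
* Alignment scoring (match +1, mismatch −1, gap open −2, gap extend −1;
  a gap of length L costs `open + L·ext`) is shared across junction
  calling, UTR detection and identity computation, and is configurable
  per call.
* Zinc-finger spacing `C-x(2,4)-C-x(8,20)-H-x(3,5)-[H|C]` admits the
  classical Cys2His2 geometry; matching is leftmost-first with minimal
  extents and resume-after-match, making counts order-independent and
  exactly reproducible by exhaustive enumeration (the test oracle).
* Every stage of `runPipeline()` draws its seed from a named substream
  of the run seed, so stage-level reruns and whole-run reruns are
  byte-identical; the resolved config, all tables, FASTA/GFF3/Newick
  artifacts and an md5 MANIFEST are written to the output directory. A
  failed stage aborts with a stage-named error and leaves the MANIFEST
  marked incomplete.
* Problem sizes used by the test suite and the acceptance script —
  elements of 2.5–3.5 kb, arrays of 2–10 units, 100 specificity trials,
  50 consensus seeds, 100 monophyly simulations — were chosen as the
  smallest scales at which the binomial arguments above have comfortable
  margins.
* The command-line layer is deliberately thin
  (`inst/scripts/rdnaretro`): the package functions are the interface,
  and the config file is the contract.

## Known limitations

* The copy finder assumes substitution-dominated decay; heavy indel
  decay fragments seed chains and can split copies.
* Junction calling projects flanks onto the plus strand of the target;
  rDNA units inverted relative to the reference are out of scope.
* `stackCopies()` is an ungapped projection onto consensus coordinates,
  sufficient for the simulator's decay model but not a substitute for a
  real multiple aligner on indel-rich data.
* The specificity verdict depends on `specific_fraction` and flank
  thresholds; on real, fragmented assemblies the `partially_specific`
  class will absorb assembly artifacts as well as biology.
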