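# rDNAretro

Characterization of R2-family retrotransposons that target ribosomal DNA.

R2 elements are non-LTR retrotransposons that integrate by target-primed
reverse transcription at a single canonical site inside 28S rRNA genes.
Because the rDNA array is tandemly repeated and highly conserved, every
insertion junction can be read against one reference coordinate: the
number of 28S bases missing between the element end and the canonical
site is the *junction offset*. Most families insert with a 5′ offset of
0 (canonical); some replace ~110–130 bp of upstream 28S; a few families
have lost target specificity altogether and integrate anywhere. Clades
within the superclade (R2A–R2D) are defined by the zinc-finger
complement N-terminal to the reverse transcriptase (RT) domain:

| clade | zinc fingers |
|-------|--------------------------|
| R2A | CCHH + CCHH + CCHC (3) |
| R2B | CCHH + CCHC (2) |
| R2C | CCHH + CCHH (2) |
| R2D | CCHH (1) |

The package implements the full desk-top side of this characterization
workflow for genome assemblies, and ships a synthetic rDNA-array genome
simulator with an exact ground-truth table so every step is testable:

- **`syngenome`** — `buildTargetReference()`, `simulateElementFamily()`,
  `insertCopies()`: tandem 28S-like units with element insertions of
  configurable junction geometry (offsets, 5′ truncation, strand,
  substitution/indel decay, non-specific placement), written as
  FASTA + truth TSV + GFF3.
- **`motifscan`** — `detectZincFingers()` (pattern
  `C-x(2,4)-C-x(8,20)-H-x(3,5)-[H|C]`), `classifyClade()`,
  `scanProteins()`.
- **`ispcr`** — `degeneracy()`, `iupacMatch()`, `virtualPCR()` with the
  eight-primer panel (R2IF1/R2IIF1/R2IF2/R2IIF2 × four 28S reverse
  primers) built in.
- **`junctions`** — `findCopies()` (k-mer seed, ungapped X-drop
  extension, both strands), `callJunctions()` (flank Smith–Waterman
  against the target, offset computation, specificity classes
  `canonical` / `shifted_5prime` / `shifted_3prime` / `non_adjacent`),
  `classifyFamily()`, `detectTargetLikeUTR()` (degraded 28S-derived 3′
  UTR segments), `findMotif()` (e.g. the HDV-like ribozyme core
  `CCUCCUCGUGG`).
- **`consensus`** — `majorityConsensus()` (majority rule with a gap
  rule), `pairwiseIdentity()` (global alignment, selectable
  denominator).
- **`phylo`** — `pDistance()`, `njTree()` (Saitou–Nei neighbor joining),
  `bootstrapSupport()` (column bootstrap), `isCladeMonophyletic()`.
- **`runPipeline()`** — end-to-end orchestration with a YAML/list
  config, seeded sub-streams per stage, and a per-family report. A thin
  CLI lives in `inst/scripts/rdnaretro`.

Pairwise alignment (affine-gap local and global; match +1, mismatch −1,
gap open −2, gap extend −1) is implemented in C++ and verified against
full-DP oracles and `Biostrings::pairwiseAlignment`.

## Worked example

```r
library(rDNAretro)

tr <- buildTargetReference(flankLen = 200, seed = 1)
tr
#> TargetReference '28S_synthetic' (28S): 440 bp, canonical site after base 220

fam <- simulateElementFamily("R2A", seed = 7, target = tr,
                             utr3TargetSegment = list(length = 150,
                                                      identity = 0.85))
fam
#> ElementFamily 'R2A-sim' [R2A]: 3500 bp consensus, 899 aa ORF product
#>   ribozyme motif at 37-47 (5' UTR)
#>   28S-like 3' UTR segment: 150 bp at identity 0.85

detectZincFingers(proteinSeq(fam))
#>   kind start end
#> 1 CCHH     2  24
#> 2 CCHH    33  55
#> 3 CCHC    64  86
```

The demo pipeline simulates four families (canonical R2A; R2B shifted
110 bp upstream with a degraded 28S-like 3′ UTR; fully non-specific R2C;
canonical R2D with a 5′-truncated copy), rediscovers the copies, and
reports:

```r
runPipeline(demoConfig(42), "demo_out")
#>  family_id clade n_copies         verdict modal_offset5 utr_28S_like
#>      R2A-1   R2A        3 target_specific             0        FALSE
#>      R2B-1   R2B        2 target_specific           110         TRUE
#>      R2C-1   R2C        3    non_specific            NA        FALSE
#>      R2D-1   R2D        2 target_specific             0        FALSE
```

Every row matches the simulation truth: the clade call comes from the
zinc-finger scan of the ORF product, the verdict from junction
adjacency, `modal_offset5` is the most frequent 5′ junction offset
(110 = that much 28S replaced upstream), and `utr_28S_like` flags a 3′
UTR segment whose identity to the 28S (0.85) is clearly below that of
the true downstream flanks (~0.99).

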