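# gbcrispr

An R package for designing and simulating GoldenBraid-style Type IIS
assembly of CRISPR/Cas9 constructs at the desk, before any pipette moves.
It is written for plant synthetic biologists (and anyone using Golden Gate
/ GoldenBraid-like standards) who want to verify, in silico, that a set of
guide RNAs, promoters, scaffolds and destination vectors will assemble
into exactly one stable construct — and to run the routine arithmetic
around the wet-lab assays that validate those constructs.

## What it models

**Assembly chemistry.** DNA molecules are double-stranded sequences with
linear or circular topology; Type IIS enzymes are cut geometries
(recognition, spacer, 5'-overhang length; BsaI = `GGTCTC(N1)/4`,
BsmBI = `CGTCTC(N1)/4` by default). Digestion produces position-free
sticky fragments; ligation is a directed graph over 4-nt overhangs whose
simple cycles are the circular products. A Golden Gate reaction is its
cyclic endpoint: only products free of the assembly enzyme's recognition
on either strand are stable,

```
stable product  =  circular ligation cycle  with  no remaining GGTCTC/GAGACC
                   (resp. CGTCTC/GAGACG) on either strand
```

**The braid.** Level 0 parts (domesticated: no internal BsaI/BsmBI site)
are held in entry vectors and released by BsaI between 4-nt fusion sites
drawn from the plant common-syntax table (`GGAG..CGCT` transcriptional-
unit edges). Alpha destination vectors accept BsaI multipartite
assemblies and release their cargo with BsmBI; omega vectors the
converse, so binary assemblies alternate classes indefinitely.

**CRISPR design.** `scanTargets()` finds every `20-mer + NGG` on either
strand (5'-G filter, GC bounds, diagnostic restriction sites overlapping
the SpCas9 cut between protospacer nt 17 and 18); `domesticateTarget()`
emits the two annealing oligos with mode-specific fusion sites;
`assembleGuideCassette()` and `buildPolycistron()` build monocistronic
cassettes and polycistronic tRNA–gRNA structures (2-D multiplexing);
`binaryAssemble()` braids hosted units together.

**Assay arithmetic.** `predictBands()` (restriction validation of
clones), `correctedMutationRate(raw, wt) = raw × (1 − wt)` for
PCR/restriction-site-loss editing assays (one decimal, half-up), and
`normalizeReporter()` for dual-luciferase Fluc/Rluc ratios (reference
condition ≡ 1, induction range max/min).

Everything is testable offline: `makeVector()`, `makeGenome()` and
`demoMultiplex()` generate deterministic mock vectors and genomes with
planted targets and a truth table.

## Worked example

```r
library(gbcrispr)

## corrected editing rates from a PCR/restriction-site-loss assay:
## 17% resistant amplicons, but 29% of sequenced resistant clones wild type
correctedMutationRate(17, 0.29)
#> [1] 12.1
correctedMutationRate(14.5, 0.32)
#> [1] 9.9

## oligos for a monocistronic D-target (fusion sites ATTG / GCTT)
oligoSheet(domesticateTarget("GCATGCCGTAAACGACTAGT", "monocistronic_D"))
#>       name            sequence_5to3
#> 1 gRNA_1_F ATTGGCATGCCGTAAACGACTAGT
#> 2 gRNA_1_R AAGCACTAGTCGTTTACGGCATGC

## full 2-D multiplexing demonstration on fixtures: a 2-guide and a
## 3-guide polycistron, braided into one level 2 construct
demo <- demoMultiplex(seed = 1)
demo$n_guides   # protospacer slots in the level 2 construct
#> [1] 5
demo$n_genes    # distinct truth-table genes those guides cover
#> [1] 7
predictBands(partMolecule(demo$level2), "BsaI")
#> DigestPattern level2_fx / BsaI (3655 bp): 2518-1137
```

The first two numbers are the corrected mutation rates: the raw
restriction-resistant fraction scaled by the non-wild-type fraction of
sequenced clones. The demo counts say that the level 2 construct carries
all five designed guides, which between them target seven genes (one
guide covers a three-gene subfamily). The digest pattern is the
validation fingerprint a correct clone would show on a gel.

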