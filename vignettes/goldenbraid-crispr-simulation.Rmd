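---
title: "Simulating GoldenBraid CRISPR assembly: models, parameters and design choices"
author: "gbcrispr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GoldenBraid CRISPR assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbcrispr)
```

# The problem

Plant genome engineering with SpCas9 routinely requires several guide RNAs,
a Cas9 transcriptional unit and selection elements on a single T-DNA.
GoldenBraid-style modular cloning builds such constructs from standardized
parts with two Type IIS enzymes: BsaI assembles basic "level 0" parts
(promoter, coding sequence, terminator, CRISPR target) into transcriptional
units, and BsmBI combines hosted units pairwise into ever larger structures
through alternating *alpha* and *omega* destination vectors — the "braid",
a double loop with no upper level limit. `gbcrispr` is a desk-scale
designer and simulator for this workflow: it models the DNA chemistry
(digestion, sticky-end ligation, the cyclic Golden Gate endpoint), the part
grammar (fusion-site syntax, domestication, braid alternation), guide RNA
design (target scanning, oligo duplexes, one- and two-dimensional
multiplexing), and the downstream arithmetic used to validate clones and
quantify editing (band prediction, restriction-site-loss mutation rates,
dual-luciferase normalization).

# The sequence and reaction model

## Molecules, enzymes, cuts

A `DNAMolecule` is a double-stranded sequence given as its plus strand with
linear or circular topology; circular molecules compare equal under
rotation and reverse complement (`sameMolecule()`). An `EnzymeSpec` is a
cut geometry: recognition sequence, a spacer between the recognition 3'
end and the top-strand cut, and the length of the 5' overhang produced.
Defaults are BsaI = `GGTCTC(N1)` and BsmBI = `CGTCTC(N1)`, both leaving
4-nt 5' overhangs; these geometries are configuration entries
(`gb_config.yaml`), not code. Ordinary palindromic enzymes used for clone
validation (SpeI `A^CTAGT`, BamHI `G^GATCC`, EcoRI, HindIII) are expressed
in the same model with a negative spacer, placing the cut inside the
recognition site.

Coordinates are 0-based and half-open on the plus strand, cuts are
inter-nucleotide offsets, and circular arithmetic is modulo length.
`findSites()` reports both strands, including recognition sites spanning a
circular origin. Two cuts closer than the overhang length cannot both fire
cleanly; `digest()` refuses such molecules with an "ambiguous digest"
error naming the sites, rather than picking one cut silently.

## Fragments and ligation

A `Fragment` is position-free: top strand, left 5' protrusion, and the
right-hand cut stored as the plus-strand 4-mer spanning it (the physical
bottom-strand protrusion is its reverse complement). With this convention
two ends anneal exactly when one fragment's right overhang string equals
the next fragment's left overhang, so ligation is purely overhang-driven.
`ligate()` builds the directed compatibility graph over both orientations
of every fragment (a fragment may enter a reaction flipped), enumerates
simple cycles — each physical fragment used at most once — and reports
each circular product once, canonicalized by the lexicographically minimal
rotation of sequence or reverse complement. Output order is deterministic
(lexicographic on the canonical sequence). Caps (10 fragments per cycle,
50 products) guard against combinatorial blow-up and raise an explicit
error rather than truncating silently. Palindromic overhangs are permitted
but warn, since they allow self-ligation. Blunt-end joining is not
modelled: every reaction in this workflow is sticky-ended, and linear
products are reported only as maximal paths when circularity is not
required.

`goldenGate()` models the one-pot cyclic digestion–ligation *endpoint*:
every product still carrying a recognition site of the assembly enzyme
(including sites re-created across a ligation junction) would be re-cut in
the cyclic reaction, so only recognition-free circular products are
stable and returned. The destination backbone — the recognition-free
destination fragment — flags the product of interest. This endpoint model
deliberately ignores kinetics: ligation efficiency, partial digests and
methylation sensitivity are out of scope, which is why fixture tests
compare product *sets* against a brute-force ordering oracle rather than
yields.

Because multi-insert concatemers are chemically possible whenever overhang
multisets allow them, the simulator reports *all* stable cycles instead of
guessing which ones a gel would show; the caps above bound the
enumeration.

# The GoldenBraid grammar

Fusion sites are the 4-nt overhangs that give each part its position. The
part-syntax boundary table ships as editable YAML following the plant
common-syntax standard (`GGAG, TGAC, TCCC, TACT, CCAT, AATG, AGCC, TTCG,
GCTT, GGTA, CGCT`); the CRISPR-specific codes are package defaults since
no authoritative sequences are published for them: B3c left = `ATTG` (the
junction between a PolIII promoter and the target), B5c right = `GCTT`
(target–scaffold junction of the D path), B5d right = `GCAA` (the M path,
modelled as differing from D only in that right fusion site). All grammar
logic reads the table; nothing is hard-coded.

Level 0 parts are held in a pUPD-like entry vector (BsmBI sockets `CTCG` /
`CTCA`) with BsaI release arms around `fusion-left + insert +
fusion-right`; `makeLevel0()` enforces *domestication* — no internal BsaI
or BsmBI site on either strand (`checkDomestication()`) — because an
internal site would be cut in some later reaction of the hierarchy.

The braid itself is realized in the fixture vectors: alpha vectors expose
BsaI sockets `GGAG..CGCT` for multipartite assembly and release their
cargo with BsmBI between backbone-encoded flank overhangs (`CGGT / AGTG /
CGTA` for positions 1 and 2); omega vectors are the converse, their BsaI
release flanks reusing `GGAG` and `CGCT` as outer edges (with `ACGG` as
the middle) so that omega-released cargo re-enters alpha sockets. This
yields the two invariants the suite checks by property tests: the class of
a binary product always alternates with its inputs' class, and every
product is itself a valid binary input (the endless loop). A multipartite
TU assembly always lands in an alpha vector under this chemistry; a TU is
moved to an omega host through a binary step, which is how the fixture
demo hosts its Cas9 unit.

# Guide RNA design

`scanTargets()` enumerates every 20-mer followed by `NGG` on either
strand. Filters mirror design practice for PolIII-driven guides: a 5'-G
requirement (on by default; PolIII transcription initiates on G), optional
inclusive GC bounds (off by default — GC content is reported
descriptively, at `100 * (G+C)/20`), and optionally a *diagnostic*
restriction site. The blunt SpCas9 cut is placed between protospacer
nucleotides 17 and 18 (3 bp 5' of the PAM) — standard SpCas9 biology — and
a diagnostic site qualifies only when its recognition span strictly
contains that cut offset, the rationale being that indels at the cut must
disrupt the site for a restriction-loss assay to see them.

`domesticateTarget()` converts a protospacer into the two partially
complementary oligos whose annealed duplex carries the mode's fusion
sites: `ATTG..GCTT` (D), `ATTG..GCAA` (M), or the tRNA–scaffold sockets
`GTGT..GCGA` of the polycistronic path. Oligos are modelled as full-length
complements with 4-nt 5' protrusions; phosphorylation and annealing
thermodynamics are not modelled. A non-G first base is rejected or
substituted by G (flagged) per policy; substitution is the default, since
a mismatched first base is generally tolerated by the guide while PolIII
initiation is not.

Two-dimensional multiplexing follows the rice polycistronic tRNA–gRNA
strategy: level −1 plasmids hold a tRNA and the scaffold separated by
BsmBI sockets; inserting the target duplex yields a level 0 tRNA–gRNA
oligomer, and a BsaI multipartite assembly of the promoter plus all
oligomers produces the level 1 polycistron. The duplex chemistry is
slot-independent (the same two sockets in every level −1 plasmid); slot
identity lives in the level −1 backbone's release fusions, drawn from a
configurable boundary list (`ATTG, ACCT, CAGC, ...`), the final slot
always closing on the `CGCT` TU edge. Slot order is verified on the
product by protospacer positions downstream of the promoter.

# Assay arithmetic

* **Band prediction** (`predictBands()`): band lengths are distances
  between successive top-strand cuts; k sites give k bands on a circle and
  k + 1 on a line, and bands always sum to the molecule length — a
  conservation property the suite checks on random molecules. Uncut
  circular molecules are reported as such rather than as a single band,
  since an uncut plasmid runs as topological forms, not at its linear
  length.
* **Mutation rate** (`correctedMutationRate()`): the restriction-resistant
  amplicon fraction overestimates editing because some resistant clones
  sequence as wild type; the corrected rate is `raw * (1 − wt_fraction)`,
  reported in percent to one decimal, rounded half up (the convention that
  reproduces one-decimal hand calculation; a small epsilon guards the .5
  boundary against binary floating-point representation). Band-intensity
  densitometry is out of scope — the raw fraction is a user input.
* **Reporter normalization** (`normalizeReporter()`): per-sample Fluc/Rluc
  ratios, per-condition means normalized to the reference condition
  (exactly 1 by construction), sample SD (n − 1), and the induction range
  as max/min of non-reference normalized means. The computation is
  scale-invariant in Fluc, which the suite asserts. No hypothesis testing
  is performed; the source assays report mean ± SD only.

# Fixtures: what they emulate, and what they do not

Every pipeline stage is testable offline through `makeVector()`,
`makeGenome()` and friends: mock entry/alpha/omega/level −1 plasmids with
the exact enzyme geometry above and a few kb of scrubbed random backbone
(so digest patterns stay human-checkable), and linear mock genomes of gene
regions with planted `20-mer + NGG` targets recorded in a truth table.
Planting is deterministic under the master seed: random filler is
regenerated until no accidental recognition site or extra copy of a
planted 23-mer exists, so recall tests are exact. The demonstration
pipeline (`demoMultiplex()`) plants five distinct guides across seven gene
labels — two XT-style targets carrying SpeI/HindIII diagnostic sites at
the cut (with GC contents fixed by construction at 50% and 30%), and three
FucT-style targets of which one is shared by a three-gene subfamily — then
builds the 2 + 3 polycistrons, their level 2 binary combination, and adds
a Cas9 TU.

Two honest caveats. First, the genomes are uniform-random with planted
sites: no introns, repeats, paralogy or biased composition, so passing
recall tests says nothing about off-target behaviour on real genomes
(off-target scoring is explicitly delegated to external designers).
Second, the XT-style fixtures are *synthetic stand-ins*: their GC contents
and diagnostic-site placement reproduce the reported target properties,
but the sequences are not the biological targets. In the same spirit, the
diagnostic enzymes of the fixture XT targets were chosen (SpeI, HindIII)
so that no diagnostic site collides with an assembly enzyme: a BsmBI
diagnostic site inside a protospacer would be chemically incompatible with
the BsmBI-mediated polycistron cloning the same guide passes through, a
corner the simulator surfaces by construction.

# Numerical and degenerate-input choices

* Rotation-invariant equality uses the minimal-rotation canonical form of
  sequence and reverse complement; ties between identical rotations
  resolve to the first.
* A circular molecule with no site digests to an "uncut" marker, not an
  error; a linear molecule with no site is one blunt fragment.
* Sites whose cut window would run off a linear end are reported by
  `findSites()` but never cut.
* Errors are typed: validation errors (bad inputs, braid violations,
  domestication failures) and assembly failures (no stable product, with
  the unmatched overhangs listed) map to CLI exit codes 2 and 3.
* Problem sizes in the property suite — 200 random round-trip molecules,
  100 ligation-oracle cases of up to 6 fragments, a ~10 kb scan-oracle
  genome, braid chains of depth 4, 100 band-conservation molecules — were
  chosen so the brute-force oracles stay exhaustive while the whole suite
  runs in well under a minute.

# Worked example

```{r example}
## corrected mutation rates from a PCR/restriction assay
correctedMutationRate(17, 0.29)
correctedMutationRate(14.5, 0.32)

## design a guide against a mock genome and inspect its diagnostic assay
gen <- makeGenome(fixtureConfig(seed = 1, nGenes = 2),
                  planted = data.frame(gene = "gene1",
                                       protospacer = "GCATGCCGTAAACGACTAGT",
                                       diag = "SpeI"))
tt <- targetTable(scanTargets(gen$genome, enzymePanel = list("SpeI")))
tt[tt$diag_enzymes != "", ]

## oligos for the monocistronic D path
oligoSheet(domesticateTarget("GCATGCCGTAAACGACTAGT", "monocistronic_D"))
```

# Known limitations

The simulator is an endpoint model: it predicts *which* constructs a
reaction can yield, never how efficiently. Colony counts, assembly
success rates, editing efficiencies and reporter magnitudes are
experimental quantities outside its reach; what it reproduces of them is
the arithmetic applied to their readouts. GenBank I/O is a minimal
flat-file reader/writer sufficient for round-tripping the package's own
annotated outputs, not a general-purpose parser.
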