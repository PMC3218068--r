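---
title: "Detecting integrative and conjugative elements in actinobacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting integrative and conjugative elements in actinobacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The detection problem

Actinomycete integrative and conjugative elements (AICEs) are mobile
elements of high-G+C Gram-positive bacteria. Unlike the familiar ICEs of
Gram-negative bacteria and Firmicutes, which build a type IV secretion
system (T4SS) and transfer single-stranded DNA nicked at an origin of
transfer, AICEs transfer as double-stranded DNA through a single
FtsK/SpoIIIE-family translocase (Tra), and after excision they replicate
autonomously through a dedicated initiator. Their canonical gene complement
is therefore three modules:

* **integration/excision** — a tyrosine or serine site-specific recombinase
  (Int), usually with a recombination directionality factor (Xis);
* **replication** — a rolling-circle initiator of the RepSA or RepAM
  family, or a bifunctional primase-polymerase (Prim-Pol), the latter often
  operating as a small operon with an adjacent replication gene (here
  labelled RepPP);
* **transfer** — the FtsK/SpoIIIE-type translocase.

An integrated element sits between two short direct repeats, the
attachment sites *attL* and *attR*, which are duplications of the
integration target — almost always the 3' end of a tRNA gene.
Recombination between *attL* and *attR* regenerates the chromosomal *attB*
and circularizes the element around *attP*. T4SS-type ICEs also occur in
Actinobacteria; they are recognized by an integrase plus the conjugation
triplet of coupling protein (T4CP), VirB4-like ATPase and MOB_F-family
relaxase, with no replication requirement.

`aicescan` implements this reasoning as an auditable pipeline: a
position-specific profile search assigns module roles to annotated CDS; a
co-localization step assembles candidate regions; direct-repeat analysis
delimits elements at their att sites and reconstructs excision products in
silico; bootstrapped protein trees are cut into subfamilies; and summaries
tabulate hits and element distributions per host group. A synthetic-genome
generator with a machine-readable truth table makes every stage testable
without downloads.

## Profile model and scoring

Profiles are position-specific log-odds models built from a protein
multiple alignment. Columns with residue occupancy of at least 0.5 become
match states; emissions are `log2` ratios of pseudocounted column
probabilities to the alignment's background frequencies. Two numerical
choices matter:

* **Background smoothing.** The background is the alignment's overall
  residue frequency blended half-and-half with the uniform distribution.
  Without the floor, a residue absent from a small alignment receives a
  near-zero background and, through the ratio, an inflated log-odds at
  *every* state; in design simulations an H-free alignment scored any
  histidine in any target about +3 bits, which is clearly an artefact of
  estimating twenty frequencies from a few hundred residues.
* **Consensus from probabilities.** The consensus residue per state is the
  most *probable* residue, not the largest log-odds, for the same reason:
  in small alignments the log-odds argmax can be a residue never observed
  in the column.

Scoring is a semi-global affine-gap dynamic programme: all match states
must be consumed (deletions allowed), the protein contributes an arbitrary
substring, and unaligned flanks are free. Defaults are `gap_open = 4` and
`gap_extend = 1` bits. The kernel is exact; the test suite checks it
against exhaustive enumeration of all alignments on small instances.

### Threshold calibration

No published score cutoff exists for this kind of scan, so thresholds are
calibrated per profile from a shuffled null: the profile's consensus is
shuffled `n_shuffles = 100` times, each shuffle is scored embedded in
random flanking sequence (total decoy length 600, maximum over
`n_contexts = 25` embeddings per shuffle), and the threshold is the null
maximum plus a 2-bit margin. Embedding is essential: a bare 80-residue
decoy offers a single alignment offset, whereas a real protein offers
hundreds, so the maximum over a scanned proteome would otherwise routinely
exceed a bare-decoy null.

For the built-in roster the calibrated threshold is additionally floored
at 20% of the profile's maximal attainable score. An empirical null bounds
the background tail only up to its own sample size; across the millions of
alignment offsets in a genome collection the observed background maximum
creeps a few bits past any finite-sample null, while genuine family
members score at half the consensus score or more. The floor separates the
two regimes decisively: in the packaged test conditions the margin between
the threshold and the strongest of 5,000 background protein scores is
23-75 bits, with planted family members far above it.

The roster itself (tyrosine and serine integrases, FtsK/SpoIIIE, RepSA,
RepAM/DUF3631, Prim-Pol, T4CP, VirB4-like, MOB_F relaxase, and a Rep_2
family as the representative of the wider "other replication initiator"
class) is built from fixed synthetic reference alignments — 30 members at
10% per-site divergence from a family ancestor — so the package is fully
self-contained and deterministic. Real scans would substitute hit tables
from an external HMMER/Pfam run via `read_hits_tsv()`; everything
downstream is unchanged.

## Element calling

```{r}
library(aicescan)
sim <- simulate_genome(seed = 1)
res <- scan_replicon(sim$replicon)
tidy_regions <- res$regions
```

A chromosomal region is an element candidate when genes of all three core
modules co-occur within a **60-kb window**. The window is a maximum: known
elements run from roughly 10 kb upward, and the short excised form of a
multi-attL element can be 15 kb, so no minimum size is imposed. Regions
with exactly two of the three modules are reported as **remnants**
(decayed or mobilizable elements) and never enter element counts; a single
lone hit — e.g. the universal chromosomal FtsK — is ignored.

Because recombinases sit next to one of the two att sites, a candidate
whose integrase lies strictly **between** its replication and transfer
genes (by gene midpoint on the forward axis; strand carries no
information here) is excluded with reason `int-internal`.

Hits are assembled into regions by a small global assignment: for every
integrase all window-compatible (Tra, Rep) combinations are enumerated,
and hits are allocated to maximize the number of assembled integrases,
then minimize the total span, then the number of int-internal
arrangements, each hit serving one region. A sequential nearest-gene
pairing fails exactly where it matters most — in a tandem array the
downstream element's integrase is closer to its neighbour's transfer gene
than to its own — whereas the global objective recovers both elements and
leaves a nearby remnant's integrase unpaired rather than letting it steal
a transfer gene across tens of kilobases. Conflict components are tiny
(an integrase only competes with neighbours within the window), so the
exact search is cheap; a node cap falls back to a greedy for pathological
inputs.

T4SS-type regions require the integrase plus T4CP, VirB4-like and MOB_F
hits in one window; replication genes are recorded but not required. A
region satisfying both rules is reported once, as an AICE, with the T4SS
genes annotated. Plasmids are classified whole — an integrase plus
transfer plus replication gene anywhere marks the plasmid as the excised,
autonomously replicating form of an element; a conjugative plasmid
without an integrase is no call.

By default the replication module must be of the AICE-typical families
(RepSA, RepAM, Prim-Pol/RepPP); the fifteen additional initiator families
are admitted with `allow_rep_other = TRUE`, reflecting that elements
relying on, say, a Rep_2 initiator are a documented but exceptional
extension of the class.

Circular replicons are scanned over virtually doubled coordinates;
origin-spanning regions are reported with `start` in `[1, len]`, `end`
carried in doubled coordinates, and a `wraps_origin` flag (GFF3 output
follows the circular-genome convention of `end > seqlen`).

## Attachment sites and in-silico excision

Within the candidate span ±5 kb, same-orientation direct repeats are found
by exact 12-mer seeding on alignment diagonals and ungapped
mismatch-tolerant extension. Extension absorbs the adjacent exact match
run only when the run is worth the mismatches crossed (strictly more than
five matching bases per mismatch) and interval identity stays at or above
0.9. The gain rule exists because a bare identity threshold happily walks
from a 50-bp exact repeat into coincidental flanking matches — at 70% G+C
two aligned random bases match 29% of the time — and the reported repeat
would then overshoot the real attachment site. Defaults
(`min_len = 14`, `min_identity = 0.9`) are permissive enough for known att
sizes (a documented attL is 81 bp; the detector's floor allows much
shorter) and strict enough that random high-G+C sequence yields at most
sporadic minimum-length calls. The finder is checked against a quadratic
full-diagonal oracle.

Pairs whose copies bracket every core gene are att candidates, ranked:

1. **tRNA-anchored first** — one copy overlaps the 3'-terminal 25 bp of a
   tRNA gene lying within 2 kb of the integrase;
2. longer repeat first;
3. wider pair first.

Repeat length outranks width because a long high-identity repeat is far
stronger evidence of an att duplication than a minimum-length one; an
unanchored 60-bp spurious pair must not displace a genuine 40-bp
tRNA-anchored att, and conversely a 14-bp chance repeat that happens to be
wider must not set the boundaries of a serine-integrase element that has
no tRNA anchor at all. After ranking, only pairs sharing a copy with the
top-ranked pair are kept: an element's att sites are all copies of one
integration-target sequence (a multi-attL element shares its attR between
its two pairs), so an unrelated bracketing repeat is not an alternative
attachment site. Pairs spanning the integrase of a *different* candidate
region are dropped — in a tandem array they describe the composite form,
which `resolve_tandem()` reports separately, with the individual products
retained.

Boundaries use the top-ranked pair; all alternatives stay in the
`att_pairs` column. Naming is positional (attL upstream, attR downstream);
the tRNA-anchored copy may be either, since the element can integrate on
either side of its target.

Excision is string surgery with an exact conservation guarantee: per att
pair, the upstream repeat copy stays at the chromosomal attB locus (the
choice is symmetric; one copy has to stay and one has to travel) and the
element circularizes carrying the downstream copy as the junction-spanning
attP, so

```
circle_len = (attR_end - attL_start + 1) - repeat_len
```

and re-inserting the circle at the retained copy reproduces the input
character for character. The suite asserts both identities for every
product of every simulated genome, including two-circle multi-attL
elements and independent-plus-associative excision of tandem pairs.

## Subfamilies from bootstrapped trees

Protein trees (newick, branch lengths, bootstrap labels on internal
nodes) are cut into subfamilies: clades with at least 4 members, patristic
diameter at most the cutoff (1 for integrase and replication-initiator
trees, 2 for transfer proteins) and bootstrap support strictly above 80.
"Distance cutoff" is read as the clade's patristic diameter — the maximum
leaf-to-leaf path length — which is rooting-invariant and matches how a
reader would measure a clade's tightness on a scale bar. Only maximal
qualifying clades are reported (a qualifying clade nested in a larger
qualifying clade is absorbed); unrooted inputs are midpoint-rooted for
clade enumeration, and extraction is verified against brute-force
enumeration of all internal nodes. Subfamilies are named after a
user-supplied anchor member when present (e.g. the eponymous plasmid of a
known family), else the lexicographically first member.

Externally inferred maximum-likelihood trees are the intended input; for
desk-scale work the package provides a p-distance (pairwise gap-excluded)
neighbor-joining builder with column-resampling bootstrap, which recovers
additive topologies exactly and is reproducible per seed. Motif frequency
matrices over alignment windows support the rolling-circle initiator
hallmarks: a His-hydrophobic-His (HUH) metal-binding pattern in motif 2
and a majority-tyrosine catalytic column in motif 3.

## Summaries

`domain_hit_table()` counts passing hits per domain for complete versus
draft genomes with an element-total row; `element_distribution()`
summarizes per-genome element counts (median, standard deviation,
extremes, zeros included) by host suborder, environmental niche
(vocabulary: plant, soil, water, dairy, animal, insect, sediment, other)
or genome-size bin (1-Mbp default). Remnants and rejected candidates never
contribute to element counts.

## The synthetic-genome generator

`simulate_genome()` emulates the features of real actinobacterial
replicons that the pipeline's logic depends on:

* background sequence at a target G+C of 0.70 (±0.02 verified on the
  emitted genome; the intergenic composition is solved analytically to
  compensate the coding fraction);
* coding sequence realized through G+C-dependent amino-acid usage plus
  synonymous-codon weighting, calibrated so ORFs approach the genome
  target — the amino acid fixes most of a codon, so synonymous choice
  alone saturates near 62%;
* tRNA genes with one fixed canonical 3'-terminal 25-mer;
* planted elements inserted at tRNA 3' ends with the terminal repeat
  duplicated as attL/attR (default 50 bp), module ORFs sampled from the
  profile roster with random flanks, interspersed cargo (a third of it at
  G+C 0.5, emulating recently acquired low-G+C cargo), and variants:
  circularly permuted gene order, serine-integrase insertion into a
  random (non-tRNA) site, an extra internal attL giving two excision
  circles, tandem pairs sharing an att copy, and an
  integrase-between-rep-and-tra trap whose expected call is `REJECTED`;
* remnants (two of three modules) and decoys (lone FtsK, integrase-only
  prophage-like region, a bare duplicated 50-mer).

Two generator details exist purely to make the truth table exact. Planted
module proteins are re-sampled until they score clear of the profile
threshold, so a planted element is a *bona fide* family member rather
than a borderline draw. And the two bases flanking each repeat copy are
forced to differ between copies; otherwise roughly every third element
would, by coincidence of flanking sequence, contain a genuine maximal
repeat one or two bases longer than the planted one, and the truth table
would be wrong about its own genome. Placement is stratified: partial
items (remnants, gene-bearing decoys) sit pairwise at least 61 kb apart so
that windowed detection cannot chain them into spurious calls, with a
12-kb buffer around everything else; the detection rules themselves make
full elements immune to closer neighbours.

What the generator does **not** emulate: realistic codon usage and
genome-scale repeat families (insertion sequences, rRNA operons),
pseudogenization, draft-assembly fragmentation, or sequencing error.
Passing the planted-recovery suite therefore demonstrates the correctness
of the pipeline's logic under its stated assumptions, not the sensitivity
of any particular profile set on real data — on real genomes the
published Pfam profiles (via `read_hits_tsv()`) and genuine annotations
take over exactly at the module boundaries where the synthetic stand-ins
plug in.

## Problem sizes and determinism

The packaged validation runs at desk scale: 20 simulated 500-kb genomes
for end-to-end recovery (precision, recall and att-boundary exactness all
required to be 1.0), 100 sequences of up to 2 kb for the repeat-finder
oracle, 40 random trees of up to 32 leaves for the clade oracle, 50
additive matrices of up to 8 taxa for neighbor joining, and 500 background
proteins times the ten roster profiles for the zero-false-pass check.
Every stochastic step is seeded; identical inputs produce byte-identical
reports, and the same seed reproduces byte-identical simulated genomes.

## Known limitations

* The native profile model is deliberately simpler than a full profile
  HMM (no per-position gap probabilities, no E-values); it is a
  self-contained stand-in whose role in the architecture is to produce
  role-labelled hits, and externally computed hit tables can replace it.
* Gene order uses midpoints on the forward axis; the rare element
  interrupted by a large inversion would confuse the int-internal rule.
* The att search assumes direct, ungapped repeats; inverted or gapped
  attachment-site pairs are out of scope.
* Whether a region carrying both the FtsK/SpoIIIE and the full T4SS
  module set is one element or two is undecidable from co-localization
  alone; the package reports it once, as an AICE, with the T4SS genes
  annotated.
* Draft genomes are scanned per contig; elements split across contig
  breaks are reported as remnants at best.
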