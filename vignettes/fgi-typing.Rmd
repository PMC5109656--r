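---
title: "Detecting and typing flagellin glycosylation islands"
author: "fgiTyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and typing flagellin glycosylation islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgiTyper)
```

# The biological problem

Flagellin, the structural subunit of the bacterial flagellum, is
post-translationally glycosylated in many taxa. In thermophilic
Firmicutes of the genus *Geobacillus* the genetic machinery for this
modification sits in a discrete, horizontally acquired unit — the
flagellin glycosylation island (FGI) — integrated at a fixed position in
the flagellar biosynthetic locus, between the flagellin gene *flaA2* and
*flaG*. Islands differ sharply between strains: some encode
glycosyltransferases and complete sugar pathways (pseudaminic acid,
neuraminic acid, dTDP-rhamnose), others only motility-associated factor
(Maf) proteins, and half of the strains carry no island at all, just a
short intergap. `fgiTyper` turns the comparative analysis of this locus
into a reproducible pipeline: locate, excise, measure, annotate,
classify, and type.

# The procedure and its assumptions

## Locus anchoring

The flagellar locus is found by sequence, not by annotation strings: CDS
proteins are aligned against bundled anchor references and a CDS
qualifies as an anchor when it exceeds **50% identity over at least 70%
of the reference protein's length**. The inner anchors (FlaA2, FlaG)
delimit the island; the outer anchors (ComFA, RaiA) bound the whole locus
and restrict the search window when several flagellin paralogs
(FlaA1/FlaA3) qualify against the FlaA2 reference — among qualifying
candidates, the one nearest to FlaG on its 5' side wins. The island is
the intergenic span from the end of the *flaA2* CDS to the start of the
*flaG* CDS, anchors excluded, so anchor composition never inflates island
G+C. CDS membership requires full containment in the span. An empty
intergap is a legitimate record whose G+C and deviation are `NA`.

This assumes the locus is collinear on one contig with *flaA2* upstream
of *flaG*; draft genomes where the locus is split across contigs are
excluded with a warning rather than scaffolded.

## Compositional evidence

G+C content is (G+C)/(A+C+G+T), case-insensitive, with IUPAC ambiguity
codes excluded from numerator *and* denominator — on draft assemblies,
runs of N would otherwise bias the deviation. The horizontal-transfer
signal is the signed deviation (island minus genome, in percentage
points). The genome mean is cached on the `Genome` object and verified
against the contigs by the class validity method (tolerance 1e-9).

## Status and annotation

Island CDSs are annotated by their best qualifying hit against a
labelled reference set (same 50%/70% criterion, coverage measured over
the *reference* length; best hit by identity, ties broken by longer
aligned length, then lexicographic reference name). An island is
FGI-positive iff at least one CDS is a glycosyltransferase or a Maf
protein. A gene fragment that passes identity but covers less than 70%
of its reference is deliberately left `hypothetical` — the coverage rule
is applied strictly. The corner case this creates is documented under
*Limitations*.

## Ortholog families and presence/absence

Orthology between island proteins uses the stricter criterion
**identity > 70% over at least 70% of both protein lengths**, and
families are the connected components of the qualifying-pair graph
(single linkage): orthology was asserted per pair, and single linkage is
the minimal closure of that relation. Two refinements matter in
practice:

* **Fragment recruitment.** A truncated or transposon-split gene rarely
  reaches 70% mutual coverage against its full-length orthologs, so
  strict clustering would leave it as a private singleton "family" —
  scored present — while its true family shows an absence. That both
  miscounts the pan-gene set and distorts the similarity matrix. After
  strict clustering, each leftover singleton is therefore recruited into
  the family it matches at >70% identity over the aligned region with
  ≥70% coverage of *its own* length. Recruitment never merges two
  multi-member families and is switchable (`recruitFragments = FALSE`).
* **Scoring.** A cell of the presence/absence matrix is 1 iff the strain
  has at least one member that is neither *truncated* (shorter than half
  the family's median member length — the configurable
  `truncationFrac = 0.5`) nor *transposon-disrupted*. Disruption flags
  come from annotation context: an island CDS immediately adjacent to a
  transposase-annotated CDS is flagged, and the flag takes effect only
  for members shorter than the family median, so an intact gene that
  merely neighbours a mobile element keeps its 1. The provenance matrix
  records why each cell is 0 (`absent`, `truncated`, `disrupted`).

## Similarity, UPGMA and types

Profile similarity is Pearson's correlation of the binary profiles,
scaled to [-100, 100]. A pair involving a zero-variance profile (all
present or all absent) is defined as 100 when the profiles are identical
and 0 otherwise; this keeps degenerate cohorts well-defined without
inventing a correlation. Distances are d = 100 − similarity. Whether the
original desktop software rescaled negative correlations is not
documented; for well-separated types the 50% cutoff partition is
unaffected, which is the quantity this package claims.

UPGMA is implemented directly (size-weighted average-linkage updates)
because its determinism is part of the contract: ties in the minimum are
broken by the lowest (row, column) index pair, and the merged cluster
takes the position of its lower-indexed part. Merge heights are recorded
in full distance units on an `hclust`-compatible structure and halved on
the exported `phylo` tree, so leaf-to-leaf path lengths reproduce merge
distances and the tree is ultrametric by construction. Types are the
subtrees obtained by cutting at merge distance 100 − cutoff (default
cutoff 50% similarity), labelled I, II, … by decreasing size with ties
broken by the lexicographically first strain — labels are therefore
reproducible but match an external labelling only up to renaming.

## Flagellin paralogs and conservation

Flagellin CDSs are assigned to classes positionally: the anchor at the
island's 5' boundary is *flaA2*; a flagellin upstream of it (next to the
second *fliS* copy) is *flaA1*; an additional copy within or 3' of the
island is *flaA3*; anything unplaced falls back to its highest-identity
reference class. Within-class conservation uses a deterministic
center-star multiple alignment (center = maximal summed pairwise
identity; "once a gap, always a gap") — a full progressive aligner is
out of scope, and the downstream statistic only consumes an alignment,
which can equally be supplied externally as aligned FASTA. Per-column
conservation is the modal non-gap residue count over the number of
sequences (gaps count in the denominator; a gap-excluded variant is
available).

# Alignment engine

Pairwise alignment is global Needleman–Wunsch with affine gaps in the
Gotoh three-state formulation (C++): BLOSUM62, gap open 11, gap extend 1,
with a gap of length L costing open + L·extend. `X` and any unknown
residue score 0 against everything. These are the conventional BLAST
protein parameters, but implementations differ in their exact gap cost
bookkeeping, so the convention is fixed here and the test suite's
exhaustive enumeration oracle uses the same definition. Identity is
matches over alignment columns (BLAST-like; alternatives over the
shorter/longer sequence are available via `alignmentIdentity`), and
coverage of a sequence is the fraction of its residues aligned to a
residue of the partner — the operational reading of "identity over 70% of
the protein length". Traceback ties resolve diagonal > up > left, making
alignments bit-reproducible.

An alignment between two proteins is skipped only when a shared-5-mer
screen (fewer than two shared distinct 5-mers, or a length ratio that
makes mutual coverage unreachable) proves it cannot qualify; the screen
is switchable (`prefilter = FALSE`) and covered by an equivalence test.

# The synthetic cohort generator

The generator emulates the features of the real data that the pipeline
must detect, with known truth:

* a single-contig host backbone (default 250 kb, large enough that the
  implanted island does not drag the genome-wide mean) at 52% G+C — the
  typical *Geobacillus* value;
* the conserved flagellar locus (comFA … flgK/flgL/fliD … flaA2
  \[island\] flaG … fliS/fliT … raiA, with some genes on the minus
  strand) and one to three flagellin copies per strain, with conserved
  60-residue termini and a variable center (central substitution rates
  0.30/0.30/0.05 for flaA1/flaA2/flaA3);
* islands drawn from five type-specific gene complements over a pool of
  43 labelled families (neuraminic-acid, pseudaminic-acid, Pen/Pal,
  rhamnose and Fdt pathways, maf1–4, ten glycosyltransferases,
  methyl-/formyltransferases, hypotheticals), mutated at 5% amino-acid
  divergence; FGI-negative strains get 0–6 endonuclease/hypothetical
  filler genes;
* island composition controlled at reverse-translation time: per
  residue, the low- and high-G+C synonymous codons are mixed with a
  weight solved so the expected coding G+C equals the target (38% for
  FGI-positive islands; 46% for the mild depression of the negative
  intergaps); spacers are drawn at the same target. Targets outside the
  codon-achievable range raise a configuration error;
* per-gene truncation (to 25–45% of length) and transposon disruption
  (a transposase CDS splitting the gene in two) at 5% probability each,
  with the guarantee that at least one status-carrying
  (glycosyltransferase/Maf) gene per FGI-positive strain stays intact —
  otherwise the strain's truth label itself would be ill-defined.

All ancestral material (anchors, locus proteins, family pool, reference
database) derives from a fixed internal seed, independent of the cohort
seed, so any cohort is analysable with `defaultAnchorSet()` and
`defaultReferenceDb()`; the cohort seed drives only per-strain sampling,
and an identical configuration yields byte-identical GenBank output.

What the generator does **not** emulate: real codon-usage structure
(only a two-codon G+C mixture), indels within ortholog families
(substitutions only, so identity ≈ 1 − divergence is predictable),
assembly gaps and contig breaks, rearrangement of gene order within
islands, and homology between different families (ancestors are
independent random proteins, which makes family separation easier than in
real data). Passing the recovery tests therefore demonstrates the
pipeline's correctness under controlled conditions, not its performance
on real draft genomes.

# Numerical conventions and degenerate inputs

* Coordinates are 1-based closed (`GRanges`/`IRanges` convention)
  throughout, matching GenBank/GFF3 directly; the island of a record with
  `end == start − 1` is empty.
* The per-strain metrics table reports percentages to two decimals and
  sizes to one; the table loader enforces
  |deviation − (island − genome)| ≤ 0.02, the slack two-decimal rounding
  can introduce, and names the offending strain.
* UPGMA merge heights are monotone in exact arithmetic; the incremental
  averages can drift by ~1e-14 on tied merges, so drift up to 1e-8 is
  clamped to the previous height (anything larger is an error).
* Zero-length islands, cohorts with no FGI-positive strain (typing
  skipped, zero types), a single FGI-positive strain (degenerate type I),
  empty proteins (skipped on FASTA export with a warning), and CDSs whose
  translation contains an internal stop (kept with an empty protein and a
  warning) are all defined rather than fatal.
* GenBank parsing is a minimal flat-file reader (no R package parses the
  dialect offline): LOCUS/DEFINITION/FEATURES/ORIGIN, single-interval and
  `complement()` locations, multi-line qualifiers; `join()` locations
  collapse to their span with a warning. Files without a record
  terminator are rejected as truncated.

# Problem sizes used in validation

The test suite validates the aligner against exhaustive enumeration on
200 random pairs of length ≤ 8; UPGMA against a from-scratch
implementation on 100 random 3–7 leaf matrices plus 30 random ultrametric
matrices; and end-to-end recovery on 100 seeded cohort replicates of the
default study conditions (5 types × 3 strains + 5 FGI-negative, 250 kb
backbones), scoring FGI-status accuracy and adjusted Rand index of the
type partition against the generator truth, plus realized island G+C
against the configured target. `scripts/acceptance.R` re-runs the same
study at 10 replicates and writes the measured quantities as JSON.

# Limitations

* A strain whose *only* glycosyltransferase is transposon-disrupted is
  called FGI-negative: the disrupted fragments fail the strict 70%
  reference-coverage annotation rule. Real islands of this kind
  typically retain other pathway glycosyltransferases, and the generator
  always leaves one status gene intact, but the corner exists.
* The island G+C of loci split across contigs is not computed; the
  pipeline extracts within a single contig only.
* Desktop typing toolchains (Bionumerics-style similarity transforms,
  Phylip-style UPGMA) are not byte-reproduced; this package fixes its own
  deterministic conventions (similarity transform, tie-breaks, cut
  semantics) and claims agreement at the level of the cutoff partition,
  not branch-level identity.
* Real-data statistics that require the original genome assemblies or
  public protein databases — genus-wide pan-island gene counts, real
  flagellin identity percentages, glycosyltransferase inventories — are
  not reproducible offline; the package reproduces the bundled
  table-level aggregates and validates the statistics' definitions on
  synthetic data instead.
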