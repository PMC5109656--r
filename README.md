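# fgiTyper

Detection and typing of flagellin glycosylation islands (FGIs) in
bacterial genomes.

In *Geobacillus* and related Firmicutes, a horizontally acquired gene
cluster — the flagellin glycosylation island — integrates at a fixed spot
in the flagellar biosynthetic locus, between the flagellin gene *flaA2*
and *flaG*. Strains that carry it encode glycosyltransferases,
motility-associated factors (Maf) and sugar biosynthesis pathways
(pseudaminic acid, neuraminic acid, rhamnose) that decorate the flagellin
filament; strains that lack it have only a short intergap with
endonuclease or hypothetical genes. `fgiTyper` implements the full
comparative-genomic workflow around this locus for microbial genomicists:

1. **Locus anchoring and island extraction.** CDS proteins are screened
   against reference anchors (FlaA2, FlaG inner; ComFA, RaiA outer) with
   the annotation criterion *identity > 50% over ≥ 70% of the reference
   length*; the island is the intergenic span `[end(flaA2), start(flaG))`.
2. **Compositional evidence of horizontal transfer.** Island G+C% is
   compared with the genome mean; the signed deviation
   Δ = GC<sub>island</sub> − GC<sub>genome</sub> is the HGT signal
   (FGI<sup>+</sup> islands run ~10 points below their host).
3. **Status call.** An island is FGI<sup>+</sup> iff it encodes at least
   one glycosyltransferase or Maf protein.
4. **Ortholog families and typing.** Island proteins are clustered into
   ortholog families (global Needleman–Wunsch/Gotoh alignment, BLOSUM62,
   affine gaps 11/1; orthology at *identity > 70% over ≥ 70% of both
   lengths*, single linkage). Presence/absence profiles — truncated and
   transposon-disrupted genes scored 0 — give a Pearson similarity matrix
   (r × 100), a UPGMA dendrogram, and island types from a 50% similarity
   cutoff.
5. **Flagellin paralogs.** FlaA1/FlaA2/FlaA3 classes are identified
   positionally, and per-column conservation of a center-star multiple
   alignment shows the canonical pattern: conserved N-/C-termini, variable
   surface-exposed center.
6. **Synthetic cohorts with ground truth.** A seeded generator emulates
   all of the above — host backbone at 52% G+C, islands implanted at 38%,
   five type-specific gene complements, 5% protein divergence, occasional
   gene truncation and transposon disruption — so every stage is testable
   without downloading genomes.

The package ships the per-strain island metrics of a 36-strain survey of
*Geobacillus* genomes (`inst/extdata/island_metrics_table.csv`) and a
synthetic anchor/reference protein set (`inst/extdata/synthetic_*.faa`;
generated from a fixed seed, suitable for the simulator's cohorts — for
real genomes supply organism-appropriate references).

## Worked example

Simulate a small cohort (three island types, two strains each, two
FGI-negative strains) and run the pipeline:

```r
library(fgiTyper)

cfg <- fgiSimConfig(seed = 42, nStrainsPerType = c(I = 2L, IV = 2L, V = 2L),
                    nFgiMinus = 2L, hostLength = 60000L)
coh <- generateCohort(cfg)
res <- runPipeline(coh$genomes, refdb = coh$refdb)
res
#> FgiCohortResult
#> CohortSummary: 8 strains; 6 FGI+ / 2 FGI-; 3 island type(s)
#>   strains per type: I:2  II:2  III:2
#>  group n mean_island_gc_pct mean_abs_gc_deviation_pct min_size_kb max_size_kb
#>   FGI+ 6              38.06                     12.00         7.3        13.8
#>   FGI- 2              45.91                      6.06         0.9         1.8
#>  min_n_cds max_n_cds
#>          8        14
#>          0         1
```

All six implanted islands are detected as FGI<sup>+</sup>, their mean G+C
(38.06%) matches the configured 38% target, and the three generated gene
complements come back as three types (type labels are Roman numerals
assigned per cohort by decreasing size, so they match the generator's
labels up to renaming). Per-strain metrics follow the survey table
schema:

```r
head(res@table, 3)
#>  strain_id isolation_source fgi_type genome_gc_pct island_gc_pct gc_deviation_pct size_kb n_cds
#>      SIM01                         I         49.58         38.22           -11.37    13.7    13
#>      SIM02                         I         49.83         37.97           -11.86    13.7    13
#>      SIM03                        II         50.21         37.83           -12.38    11.6    12
```

Aggregating the packaged *Geobacillus* table reproduces the survey-wide
cohort statistics:

```r
tab <- loadIslandTable(system.file("extdata", "island_metrics_table.csv",
                                   package = "fgiTyper"))
summarizeIslands(tab)
#> CohortSummary: 36 strains; 18 FGI+ / 18 FGI-; 5 island type(s)
#>   strains per type: I:3  II:3  III:2  IV:8  V:2
#>  group  n mean_island_gc_pct mean_abs_gc_deviation_pct min_size_kb max_size_kb
#>   FGI+ 18              40.03                     10.32        13.4        30.4
#>   FGI- 18              44.73                      5.18         0.9         6.9
#>  min_n_cds max_n_cds
#>         11        23
#>          0         6
```

Half of the 36 strains carry an island; FGI<sup>+</sup> islands
(13.4–30.4 kb, up to 23 CDSs) sit on average 10.32 G+C percentage points
below their genomes, versus 5.18 for the small FGI<sup>-</sup> intergaps —
the compositional footprint of horizontal acquisition.

A command-line front end for shell use lives at
`inst/scripts/fgi-typer.R` (`run`, `simulate`, `summarize`,
`flagellins` subcommands).

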