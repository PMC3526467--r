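# cladecarve

Phylogeny-based subfamily delineation for large protein families, in the
style of the sequence-based subfamily classifications used for
carbohydrate-active enzyme families such as glycoside hydrolase family 5
(GH5).

## The problem

A family like GH5 holds thousands of catalytic modules and more than a
dozen enzyme activities, so knowing that a sequence belongs to the family
says little about what it does.  Partitioning the family tree into
**subfamilies** — monophyletic groups whose members are far more similar to
each other than to anything else in the family — restores predictive
power: most subfamilies carry a single EC activity, subfamilies without a
single characterized member become explicit targets for biochemistry, and
members that have lost the catalytic machinery stand out.

`cladecarve` implements the full workflow:

* **Inputs.** Catalytic-module sequences (FASTA), per-sequence metadata
  (TSV: organism, taxonomic group, characterization status, EC numbers,
  PDB codes, optional historical anchor tags A1–A10), and a phylogeny
  (Newick with branch lengths and supports) — or an alignment from which a
  neighbor-joining stand-in tree is built.
* **Method.** Fragment/quality filtering; greedy centroid clustering of
  the *uncharacterized* sequences at 75% global identity (characterized
  sequences are always kept in full), with identity defined as
  Needleman–Wunsch global alignment under BLOSUM62 (gap open 10, extend
  0.5, free terminal gaps), identity = identical pairs / alignment columns
  excluding terminal overhangs; midpoint rooting; anchoring of historical
  subfamilies (reproducing the GH5 fusions A3+A4 → `GH5_4`, A5+A6 →
  `GH5_5`, with numerals 3 and 6 reserved); and tree carving: a clade
  becomes a subfamily when it has support ≥ 0.7, at least 5 sequences from
  5 distinct organisms, is self-contained (every member's nearest neighbor
  lies inside) and is separated from the rest of the family by an identity
  gap.  New subfamilies are numbered in discovery order after the anchors.
* **Annotation.** Per subfamily: EC union and specificity class
  (monospecific / polyspecific / uncharacterized), taxonomic distribution,
  representative PDB structure, and a catalytic-residue integrity screen
  that flags subfamilies whose members all lack the essential residues
  (the two clan GH-A glutamates, for GH5).
* **Verification.** A sequence-evolution simulator with planted subfamily
  truth (`simulateFamily`) makes every stage testable at desk scale, and
  the recovered partition is scored against the planted one by adjusted
  Rand index (`evaluateRecovery`).

## Worked example

Simulate a family with three planted subfamilies (one with its catalytic
glutamates knocked out) plus three outliers, rebuild the tree, delineate,
and annotate:

```r
library(cladecarve)

fam <- simulateFamily(simulationConfig(nSubfamilies = 3, sizes = c(8, 10, 12),
                                       nOutliers = 3, knockoutSubfamilies = 3,
                                       seed = 42))
fam
#> SimulatedFamily: 33 sequences, 3 planted subfamilies, 3 outliers

tree <- midpointRoot(njTree(pDistanceMatrix(familyAlignment(fam))))
ids  <- identityMatrix(familyRecords(fam))
part <- assignNames(delineate(tree, familyMeta(fam), ids),
                    familyLabel = "SIM", reserved = integer())
part
#> SubfamilyPartition with 3 subfamilies over 33 leaves
#>   subfamilies: SIM_1 (12), SIM_2 (10), SIM_3 (8)
#>   unassigned: 3 leaves

integ <- catalyticIntegrity(familyAlignment(fam),
                            catalyticSpec(fam@config$catalyticColumns), part)
rep <- familyReport(part, familyMeta(fam), integ)
reportRows(rep)[, c("subfamily", "n_sequences", "tax_distribution",
                    "specificity", "noncatalytic")]
#>   subfamily n_sequences tax_distribution  specificity noncatalytic
#> 1     SIM_1          12          Archaea monospecific         TRUE
#> 2     SIM_2          10        Eukaryota polyspecific        FALSE
#> 3     SIM_3           8         Bacteria monospecific        FALSE

evaluateRecovery(truePartition(fam), part)$ari
#> [1] 1
```

The three planted subfamilies are recovered exactly (adjusted Rand index
1), the three outliers stay unassigned, and the knocked-out subfamily — and
only it — is flagged non-catalytic.  `runPipeline()` performs the same
stages from files plus a YAML config and writes `partition.tsv`,
`report.tsv`, `tree.nwk` and a manifest.

The package bundles a transcription of the published GH5 subfamily summary
table; replaying it through the report counters reproduces the headline
numbers of the original analysis:

```r
str(summaryCounts(loadTable1Fixture()))
#> List of 8
#>  $ n_subfamilies    : int 51
#>  $ n_characterized  : int 31
#>  $ n_uncharacterized: int 20
#>  $ n_monospecific   : int 20
#>  $ n_polyspecific   : int 11
#>  $ n_with_structure : int 13
#>  $ n_fungal_only    : int 8
#>  $ largest_subfamily: int 245
```

(Twenty of the 51 subfamilies have a single distinct EC token; three of
those carry only a partial `3.2.1.-` entry and are qualified as unresolved
in the report.)

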