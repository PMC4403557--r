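# vitasynth

Genome-annotation-based prediction of B-vitamin biosynthesis in gut
bacteria, and what it implies for the host.

Most gut microbes cannot be cultured, so whether an organism synthesises
a B-vitamin de novo — or competes with its host for it — is inferred from
its genome. `vitasynth` takes a binary genome × functional-role
annotation matrix (the spreadsheet form produced by curated subsystem
platforms) and, for each of the eight B-vitamins (biotin, cobalamin,
folate, niacin, pantothenate, pyridoxine, riboflavin, thiamin):

* calls each genome **producer / non-producer** with a declarative rule
  engine: each vitamin's rule is a set of lines over essential roles,
  e.g. biotin `BioW + BioFADB` or `BioC + BioFADB`, thiamin
  `(ThiH or ThiO) + ThiGSF + ThiCDE` or `Thi4 + ThiCDE`, with per-vitamin
  tolerances (pantothenate may miss one of `KPHMT`/`KPRED`/`ASPDC`, but
  `PBAL` absence always vetoes) and justified curation overrides; every
  call carries provenance;
* summarises **role and producer prevalence** by phylum/class/order/family
  or over the whole cohort;
* censuses the 2⁸ = 256 possible 8-bit **pathway patterns** across
  cohorts, partitions the pattern space between two cohorts, and detects
  **inversed (complementary) pattern pairs** — organisms whose synthesis
  capabilities mirror each other exactly, candidates for B-vitamin
  cross-feeding;
* scores predictions against **experimental growth evidence**
  (defined-medium requirement = non-producer-equivalent);
* estimates the percentage of the human **dietary reference intake**
  (DRI) the gut microbiota could maximally supply, via

  ```
  %DRI = conc [mmol/gDW] × (10¹⁴ cells × 4.89·10⁻¹³ gDW × 0.317 lysed)
         × molar mass [g/mol] × producer ratio / DRI [mg/day] × 100
  ```

  with unit conversion of heterogeneous literature measurements
  (molar, mass/volume, molecules/cell, mass/gDW, production rate) to a
  common mmol/gDW basis;
* generates **synthetic cohorts with planted ground truth** (taxonomic
  block structure, complete role sets for producers, verified
  rule-breaking deletions for non-producers, tolerated dropout noise,
  transporters in auxotrophs) so the whole pipeline is testable without
  any downloads.

A brute-force truth-table oracle ships in the package and is checked
exhaustively against the rule engine for every default rule.

## Worked example

```r
library(vitasynth)
rs <- read_rules()                       # packaged essential-role rules

spec <- cohort_spec(
  phyla = c("Actinobacteria", "Bacteroidetes", "Firmicutes",
            "Fusobacteria", "Proteobacteria"),
  n_genomes = 20, producer_prob = 0.5, noise = 0.1,
  transporter_prob = 0.5, seed = 42)
cohort <- generate_cohort(spec, rs)
cohort$matrix
#> role_matrix: 100 genomes x 75 functional roles
#> roles annotated per genome: 48-62

preds <- predict_cohort(cohort$matrix, rs)
producer_prevalence(preds, cohort$taxonomy, rank = "cohort")
#>   taxon      vitamin n_genomes n_producers fraction
#> 1   HGM       biotin       100          52     0.52
#> 2   HGM    cobalamin       100          55     0.55
#> ...                                      (8 rows; planted p = 0.5)

cen <- pattern_census(preds, cohort = "HGM")
cen
#> pattern_census (HGM): 85 distinct patterns over 100 genomes
head(inversed_pairs(cen), 3)
#>   pattern_a pattern_b count_a count_b genomes
#> 1  00000000  11111111       1       1       2
#> 2  00000100  11111011       1       1       2
#> 3  00000101  11111010       1       1       2
```

Each inversed pair is two observed patterns that are bitwise
complements (bit order: biotin, cobalamin, folate, niacin,
pantothenate, pyridoxine, riboflavin, thiamin; `1` = pathway present) —
the genomes on one side can synthesise exactly the vitamins the other
side cannot.

The supply table from the packaged constants:

```r
build_supply_table()[, c("vitamin", "percent_dri")]
#>        vitamin percent_dri
#> 1       biotin  4.54454712
#> 2    cobalamin 30.65239657
#> 3       folate 36.94469395
#> 4       niacin 26.44993950
#> 5 pantothenate  0.07972529
#> 6   pyridoxine 86.15908718
#> 7   riboflavin  2.84410877
#> 8      thiamin  2.26764016
```

Read: if all predicted producers lysed and their vitamin content were
absorbed, gut bacteria could cover ~86% of the pyridoxine DRI and about
a third of the cobalamin and folate DRIs, but almost none of the
pantothenate DRI. These are deliberate upper bounds.

A full run (predict → patterns → concordance → supply) over files on
disk is `run_pipeline(list(matrix = ..., taxonomy = ...,
evidence = ..., out_dir = ...))`, or from a shell via
`Rscript inst/scripts/vitasynth.R --config run.yaml`. See the vignette
(`vignettes/bvitamin-analysis.Rmd`) for the model details and design
choices.

## Data notes

The 16-strain evidence fixture under `inst/extdata/` is a labelled
**synthetic stand-in** (`synthetic_evidence16.tsv`,
`synthetic_predictions16.tsv`): it reproduces the dimensions and
agreement level typical of annotation-vs-growth-experiment comparisons
and exists to exercise the concordance machinery end to end. The
packaged supply constants (`supply_constants.yaml`) and measurement
table (`vitamin_measurements.tsv`) are literature-derived; two known
literature-vs-canonical discrepancies (biotin, niacin) are flagged by
the code rather than silently reconciled.
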