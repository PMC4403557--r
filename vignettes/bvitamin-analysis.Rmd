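---
title: "Predicting B-vitamin biosynthesis in gut microbial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting B-vitamin biosynthesis in gut microbial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitasynth)
```

## The problem

Most human gut bacteria have never been cultured, so whether a given
organism can synthesise a B-vitamin de novo — or must scavenge it from
the gut lumen, competing with its host — is usually inferred from its
genome. Curated subsystem annotations make that inference tractable: a
genome is represented as a binary vector over named functional roles
(enzymes and transporters), and a vitamin's biosynthesis pathway is
declared complete when a specific combination of essential roles is
present.

`vitasynth` implements that inference as a declarative rule engine plus
the downstream analyses it supports: taxon-level prevalence summaries,
a census of 8-bit "pathway patterns" across cohorts with detection of
complementary (inversed) pattern pairs — candidate cross-feeding
partners — concordance scoring against growth experiments, and a model
of how much of the human dietary reference intake (DRI) of each vitamin
the gut microbiota could maximally supply.

All tables and pattern strings use one fixed, alphabetical vitamin
order:

```{r}
bvitamins()
```

## The producer rules

Each vitamin's rule is one or more *lines*; a line is a conjunction of
terms, where a term is a single role/subset id or an OR-group such as
`(ThiH or ThiO)`. Compound mnemonics like `BioFADB` are conjunctive
subsets of atomic roles (`BioF`, `BioA`, `BioD`, `BioB`): the subset
counts as present only when every member is annotated. A genome is a
predicted producer when at least one line is satisfied.

```{r}
rs <- read_rules()
rs$rules$biotin
rs$rules$pantothenate
```

Two biological sufficiency decisions are encoded purely in which roles
appear in the lines, with no special logic: thiamin monophosphate
production suffices for thiamin producer status, and production of
either dihydrofolate or tetrahydrofolate suffices for folate. Roles
that are commonly missing from annotations without biological meaning
(`PyrP` in riboflavin, `FolQ` in folate) are simply absent from the
essential lists. The PABA branch roles `pabAa`/`pabAb` are likewise not
essential — only `pabAc` is — because their assignment from annotation
alone is unreliable.

Pantothenate is the one rule with an explicit *tolerance*: a genome
missing a single enzyme of the branched pathway (`KPHMT`, `KPRED` or
`ASPDC`) is still called a producer, but the absence of `PBAL` (or any
CoA-activation step) always vetoes. The tolerance is configuration,
not code, so other rule files can declare their own.

Where manual curation overrides a mechanical call (a genome missing one
role that every related genome carries), `predict_cohort()` accepts an
override table; every override must carry a justification and is
flagged in the per-call provenance, so no producer call is ever
unexplained: each is justified by exactly one of a satisfied line, a
tolerance rescue, or an override.

### Why a brute-force oracle ships in the package

Boolean rule semantics are easy to get subtly wrong (OR-groups inside
tolerances, mandatory vetoes). `brute_force_oracle()` therefore
enumerates *every* presence vector over a rule's atomic universe (all
universes here are at most 18 roles, refusing beyond 20) and derives
the verdict directly from the definition in an independent, vectorised
code path. The test suite checks the scalar engine against the oracle
exhaustively for all eight default rules.

## Subset expansions and open choices

The compound mnemonics are expanded by their letter structure
(`ThiGSF` = `ThiG`, `ThiS`, `ThiF`; `PdxBFAJH` = `PdxB`, `PdxF`,
`PdxA`, `PdxJ`, `PdxH`, the four-step erythrose branch plus the joining
and oxidase steps). Two ids are deliberately kept atomic rather than
expanded: `CbiKX` (the anaerobic cobaltochelatase, where the K/X
decomposition varies by lineage) and `CobAT` (the adenosyltransferase).
`CobS` is shared between the aerobic `CobNST` chelatase subset and the
final `CobUS` synthase subset. These choices live in the editable YAML
config, not in code; a user who prefers a different decomposition edits
the config and every downstream analysis follows.

Alternative biotin routes via `BioG`/`BioH` are intentionally *not*
part of the biotin rule (the essential-role table omits them); they
remain available to `role_prevalence()` for descriptive summaries, as
do the salvage transporters (`BioY`, `PANF`, `RibU`, `PnuC`, `PdxK`),
which never influence producer calls.

## Pathway patterns and complementarity

With eight vitamins there are $2^8 = 256$ possible producer/non-producer
patterns. `pattern_census()` tabulates the observed ones per cohort;
`compare_cohorts()` partitions the 256-pattern space into
cohort-specific, shared, and absent groups (the four group sizes always
sum to 256); and `inversed_pairs()` finds observed patterns whose
bitwise complement is also observed — organisms whose synthesis
capabilities mirror each other exactly, the strongest pattern-level
signal of potential B-vitamin cross-feeding. Because patterns have even
length, no pattern can be its own complement; the code asserts this
rather than handling it. Reports list both the pattern count and the
genome count per pair side, since either reading of "pairs" may be
wanted. Pattern strings, not integers, are the interchange form in all
outputs: they are human-diffable and make the bit order explicit.

## The synthetic cohort generator

Real per-genome annotation matrices are large, manually curated
objects. To make every pipeline stage testable without downloads, the
generator emulates the statistical structure such cohorts display:

* **taxonomic block structure** — genomes are drawn per phylum, with
  per-(phylum, vitamin) producer probabilities (the defaults in the
  examples use five phyla, matching the diversity of typical gut
  cohorts, with 50 genomes per phylum — large enough for binomial
  prevalence checks at three standard errors while keeping test runs
  in seconds);
* **complete essential-role sets for producers** — a producer genome
  receives the full atomic role set of one randomly chosen rule line,
  with one alternative picked per OR-group;
* **rule-breaking deletions for non-producers** — roles are removed
  (never merely-tolerable ones) until the rule verifiably fails;
* **tolerated dropout noise** — producers may lose tolerated roles up
  to the rule's `max_missing`, which changes the matrix but not the
  truth;
* **transporters in non-producers** — organisms that cannot make a
  vitamin optionally carry its uptake transporter, as observed for
  biotin, pantothenate and riboflavin auxotrophs.

Every emitted genome is re-evaluated through the rule engine rather
than trusted by construction — tolerances make naive deletion unsafe —
so the returned truth table is guaranteed consistent with the matrix.
A single integer seed drives one private RNG stream (the global
`.Random.seed` is saved and restored), making outputs byte-identical
across runs.

What the generator does *not* emulate: annotation error structure
beyond role dropout, genuine phylogenetic correlation between vitamins,
or partial pathway remnants. Passing tests on synthetic cohorts
therefore demonstrate the correctness of the machinery, not the
biological accuracy of the rules on real genomes; the latter is what
the concordance module measures against growth experiments.

## The supply model

The microbiota-to-host supply estimate asks: if the intracellular
vitamin content of lysed gut bacteria were fully absorbed, what
fraction of the human DRI would it cover? The chain is

$$\%\,\mathrm{DRI} \;=\; \frac{c \cdot (N \cdot m_{DW} \cdot f_{dead})
\cdot M \cdot r}{\mathrm{DRI}} \times 100$$

with $c$ the intracellular concentration (mmol/gDW), $N = 10^{14}$
cells in the colon, $m_{DW} = 4.89\times10^{-13}$ gDW per cell,
$f_{dead} = 0.317$ the lysed fraction (the measured dead-cell ratio in
feces, used for the colon where no measurement exists), $M$ the molar
mass (g/mol) of the measured chemical form, and $r$ the fraction of gut
genomes predicted to be producers. Note mmol × g/mol is numerically mg,
so the units close against a DRI in mg/day.

Literature measurements arrive in five unit kinds — molar, mass per
volume, molecules per cell, mass per gDW, and a production rate per
mgDW — and `to_mmol_per_gdw()` normalises each using the cell volume
($1.1\,\mu m^3$), dry mass, and anaerobic growth rate
($0.26\,h^{-1}$; at steady state, content = rate / growth rate).
Computation is at full precision; only display rounds to 2 significant
figures.

Two literature values are *known* to disagree with the canonical
concentration column shipped in the package: biotin (the 40 µM
measurement converts a hundredfold above the canonical
$9.0\times10^{-7}$ mmol/gDW) and niacin (about 15% above). The package
treats the canonical column as authoritative for %DRI and flags the
conversions as discrepant (warning plus a `discrepant` column) rather
than silently forcing either side. The cobalamin molar mass is the
base-form value (1329.35 g/mol); the cyanocobalamin form (1355.37)
changes the %DRI by under 2% and both round to the same printed value.

```{r}
tab <- build_supply_table()
tab[, c("vitamin", "conc_mmol_per_gdw", "dri_mg_per_day",
        "hgm_producer_ratio", "percent_dri")]
```

These estimates are deliberately *maximal* (every producer lyses, every
molecule is absorbed); the interesting quantity is their order of
magnitude: pyridoxine, folate and cobalamin could contribute large
fractions of the DRI, biotin a few percent, the rest little.

## Concordance scoring

Evidence semantics follow defined-medium growth logic: a vitamin
required in a defined medium is `nonproducer_equivalent`; growth
without it (or secretion) is `producer_equivalent`; ambiguous reports
are `unknown` and leave the denominator. Strain-versus-species
mismatches are handled only through an explicit organism-to-genome
mapping table — never fuzzy name matching — and unmapped records are
skipped with a warning, not errors, so partial evidence tables remain
usable. The packaged 16-strain evidence table is a **synthetic
stand-in** (see the file names): it mirrors the dimensions and the
~88% agreement scale reported for annotation-based predictions against
published growth data, and exists so the scoring path has a realistic
end-to-end fixture.

## Numerical and degenerate-input choices

* Role matrices must be strictly binary; the first offending cell is
  reported with its genome and role ids. Empty matrices (header only)
  are valid.
* Genomes present in the matrix but missing from the taxonomy keep
  their predictions but are excluded from taxon summaries with a
  warning.
* When several rule lines are satisfied, provenance records the first
  in config order (for cobalamin: aerobic before anaerobic, as the
  rule file lists them).
* Probabilities are validated into $[0,1]$; the generator refuses a
  non-producer request it cannot verifiably realise.
* `%DRI` requires a strictly positive DRI; a producer ratio of zero
  yields exactly 0%.

## Known limitations

The producer calls are binary — no fractional pathway completeness, by
design, since the underlying curation logic is itself binary. The
supply model propagates no uncertainty beyond its linear sensitivities
(every factor enters linearly, so relative errors add). Host absorption
and transport are out of scope. And the rules encode one curation
tradition; organisms using genuinely novel routes (as suspected for
PABA synthesis in some lactobacilli) will be mis-called until the
config is extended.
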