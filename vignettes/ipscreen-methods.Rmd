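---
title: "Methods: descriptor conventions, reactivity theory and banding rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor conventions, reactivity theory and banding rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipscreen)
```

## Scope and data model

`ipscreen` triages a 15-member library of imidazo[1,2-a]pyridine hybrids
(a dimedone-derived 3-hydroxy-5,5-dimethylcyclohex-2-enone attached at C3
of a 2-arylimidazo[1,2-a]pyridine, with a methyl option on the pyridine
ring and eight aryl substituents). Four kinds of externally produced
evidence are consumed **as data** and never recomputed: predicted logP
values, frontier-orbital energies, per-atom charges from population
analysis, and docking score/contact tables. What the package computes is
everything derivable from those inputs: structure-based descriptors and
rule-of-five verdicts, conceptual-DFT reactivity indices, condensed Fukui
functions, rankings, reference comparisons, and level/probability
bandings. Docking score functions, DFT electronic structure and
commercial ADMET/TOPKAT models are out of scope by design.

## Physicochemical descriptors

Structures enter as SMILES and are perceived through
ChemmineR/OpenBabel. Ring bonds are identified as non-bridge edges of the
bond graph (igraph), which is exact for any molecule: an edge is in a
cycle iff it is not a bridge.

* **Molecular weight** is the sum of IUPAC standard atomic weights
  (conventional values, three or more decimals) over the formula
  including implicit hydrogens. Weights are computed in full precision
  and rounded half-away-from-zero to 2 decimals only for reporting, so
  additivity over formulas holds exactly. Published values for these
  compounds differ from IUPAC-2021 sums by up to 0.01 g/mol (different
  weight-table vintages); the package's tolerance contract is
  0.05 g/mol.
* **Donors** are O-H and N-H hydrogens. **Acceptors** follow a
  pharmacophore-style convention calibrated against the published
  profile table: every N and O accepts, except the bridgehead aromatic
  nitrogen (three ring bonds; its lone pair is part of the aromatic
  system) and the nitro nitrogen; nitro oxygens each count. This is the
  only convention consistent with an acceptor count of 3 for the parent
  compound and 5 for the nitro analogues.
* **TPSA** is a fragment sum with the standard (Ertl) contributions for
  the polar fragments that occur in the scaffold grammar: hydroxyl
  20.23, terminal carbonyl O 17.07, two-ring-bond aromatic N 12.89,
  bridgehead aromatic N 4.41, aryl ether O 9.23, nitro group 45.82
  (Angstrom squared); carbon and halogens contribute zero. A polar
  fragment outside this table raises an error naming the atom — a silent
  zero would corrupt downstream verdicts. For chemistry beyond this
  grammar a general toolkit should be used instead.

### Lipinski verdict

The violation count uses the four classic criteria: MW < 500 g/mol,
logP <= 5, donors <= 5, acceptors <= 10; a compound passes with at most
one violation. Thresholds are applied exactly as printed — strict `<`
for MW, `<=` elsewhere — so boundary values do not violate. Although a
TPSA threshold of 40 A^2 is sometimes quoted alongside the rule, every
library compound has TPSA > 40 yet zero recorded violations in the
reference profile, so TPSA is reported as a descriptor and deliberately
excluded from the count. Note also that the reference table assigns a
680.79 g/mol standard drug zero violations; this package reports one
violation (still a pass) for such a profile and does not emulate the
discrepancy.

## Global reactivity (conceptual DFT)

With Koopmans' theorem and the Parr approximation, I = -E(HOMO) and
A = -E(LUMO). From these:

* gap dE = E(LUMO) - E(HOMO), with dE <= 0 rejected as degenerate;
* chemical hardness eta = dE/2 — the factor-of-two convention is pinned
  by the reference table, where eta equals half the printed gap in every
  row (the eta = I - A convention also circulates in the literature);
* chemical potential mu = (E(HOMO) + E(LUMO))/2, electronegativity
  chi = -mu;
* electrophilicity omega = mu^2 / (2 eta), so omega * 2 eta = mu^2 is an
  exact identity of the implementation (tested to 1e-9 on 1e5 random
  pairs);
* softness S = 1/(2 eta) is exposed as a convenience accessor; it is not
  part of the published table set.

Values are computed in full precision; reporting rounds
half-away-from-zero to 4 decimals, matching the source table's
presentation. Recomputing that table from its two energy columns
reproduces every derived cell to within one unit in the fourth decimal
(the residual is the table's own rounding). Rankings sort ascending with
lexicographic tie-breaks, so they are deterministic and invariant to row
order; the smallest gap marks the softest (most reactive) compound and
the largest omega the strongest electrophile.

## Local reactivity (condensed Fukui functions)

For charges q_k(N-1), q_k(N), q_k(N+1) at the three electron counts, the
charge-difference form is used:
f+ = q(N) - q(N+1), f- = q(N-1) - q(N), f0 = (q(N-1) - q(N+1))/2.
With this sign convention the *highest positive* values mark the
susceptible sites (f+ nucleophilic, f- electrophilic, f0 radical
attack), and each column sums to exactly one electron — enforced on
input with a 1e-3 e tolerance on the state totals, loose enough for real
population analyses and tight enough to catch wrong-state files.

Published Fukui tables can also be **imported verbatim**
(`import_fukui_table()`): no conservation check is applied, provenance
is marked `"imported"`, and absent index columns stay absent. The
shipped site table for the para-nitro compound is import-only because
its printed charge and index columns are mutually inconsistent (no sign
convention reproduces the printed f columns from the printed charges,
and the textual radical-attack site call differs from the table's
highlighted row); the package reproduces its published site calls by
aggregation, and does not attempt to resolve the inconsistency. Site
values are reported at 4-decimal half-up rounding (e.g. 1.485765 ->
1.4858).

## Docking summaries

All five score columns (MolDock, rerank, protein-ligand interaction,
steric, H-bond) are read as "more negative is better". "Better than
reference" means strictly more negative; equality is not better.
Residue identity for contact aggregation is (name, number), ignoring the
atom in parentheses. Column aliases and Unicode minus glyphs are
normalized at parse time. The per-ligand sum of contact energies is
reported alongside the docker's H-bond score column, never equated with
it — for one ligand in the shipped tables they agree to 1e-4, but the
docker's score is not defined as that sum. Contact energies below
-2.5 kJ/mol (the usual per-contact cap) trigger a validation warning,
not an error, on user data.

## ADMET and toxicity banding

Level semantics: BBB 0-4 = very high/high/medium/low/undefined;
absorption 0-3 = good/moderate/low/very low; hepatotoxicity and CYP2D6
are 0/1; PPB true/false = binding/nonbinding. Log-solubility bands are
[-6,-4) low, [-4,-2) good, [-2,0] optimal; toxicity probabilities band
as [0,0.30) nontoxic, [0.30,0.70) intermediate, [0.70,1] toxic. Band
endpoints are half-open and low-inclusive — the source states only the
ranges, so the boundary rule is a package decision, chosen once and
applied everywhere; all shipped values are interior to their bands
except two standard-drug solubilities below -6.0, which map to
`out_of_band` rather than being clamped. The AlogP98 flag is a neutral
"exceeds 5" threshold (5.0 itself is not flagged) with no
pharmacological interpretation attached, because the source's footnote
and prose disagree about its direction. The band label "intermediate"
corresponds to the source's (apparently typographical) "intervocal".

## Synthetic data generator

The generator exists so every stage is testable without commercial
engines. Its defaults are the study's own conditions: 15 compounds, 4/15
nitro-substituted, gaps uniform on 3.3-4.1 eV (the observed span) with
nitro members at the low end, docking columns Normal(-120, 10) truncated
negative (the scale of the real tables), contact energies in [-2.5, 0]
kJ/mol and lengths in [2.0, 3.6] A, solubilities in [-6, 0], TOPKAT
probabilities drawn 70/15/15 across the three bands. HOMO energies are
drawn uniform on [-6, -5] eV, bracketing the observed range.

Planted truths are **strict extrema by construction**, not statistical
tendencies: the softest compound gets the strictly smallest gap, the
per-target best ligand is forced below every column minimum, and the
Fukui hotspot's f+ share is boosted above 0.5 (all other shares are
nonnegative and sum to the remainder, so the hotspot is strictly
maximal). Recovery tests are therefore deterministic rather than
probabilistic. Charge sets are built from Dirichlet-style shares summing
to exactly one per transition, so conservation holds to machine
precision. Each generator reseeds from the config seed plus a fixed
per-module offset; identical configs give bit-identical outputs.

What the generator does **not** emulate: correlations between metrics,
pose geometry, the confidence-ellipse structure behind BBB levels, or
any real docking/QSAR numerical model. Passing recovery tests therefore
demonstrates correctness of the package's bookkeeping and ranking logic
under known ground truth — not predictive validity on real screening
data.

## Pipeline and reproducibility

`run_config()` validates all referenced paths for the enabled stages
before any computation; `run_pipeline()` executes stages in a fixed
order and returns a report whose sections are exactly the enabled
stages. Serialization uses stable key order and the stages' documented
rounding, so identical inputs give byte-identical `report.json`. The
`raw` option disables report rounding where full precision is needed.

Problem sizes used in the test suite: the 15-compound library for all
descriptor and table round-trips, 1,000 synthetic charge sets, 100
synthetic docking tables and 1e5 random energy pairs for the
property-style checks — sizes at which the planted-recovery counts are
exact and the whole suite runs in well under a minute.

## Known limitations

* The descriptor layer covers the scaffold grammar; general chemistry
  (aliphatic amines, thiols, charged species outside nitro) errors
  loudly instead of guessing.
* logP is never computed; profiles without a supplied logP cannot
  receive a Lipinski verdict.
* Imported Fukui tables are taken at face value; internal inconsistency
  is the importer's to flag, not repair.
* Single-heavy-atom SMILES are handled via an explicit-hydrogen
  round-trip through OpenBabel; multi-fragment SMILES are rejected.
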