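# ipscreen

In silico screening toolkit for a 15-member imidazo[1,2-a]pyridine
compound library.

Early triage of a synthesized compound series routinely combines four
kinds of computational evidence: drug-likeness descriptors, global and
local reactivity from electronic structure, docking scores against a
target panel, and ADMET/toxicity predictions. The numbers usually come
from disparate engines and end up in tables that are compared by hand.
`ipscreen` turns that comparison into a tested, reproducible pipeline
for a library of imidazo[1,2-a]pyridine–dimedone hybrids (compounds
`4a`–`4o`): it computes what is computable from structure, consumes the
engine outputs as data, and derives every ranking, verdict and summary
from them.

What the package computes:

* **Physicochemical profile & rule of five** — MW from IUPAC standard
  atomic weights, H-bond donors/acceptors and fragment-based TPSA from
  the SMILES (via ChemmineR/OpenBabel perception), Lipinski violation
  counts (MW < 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10; pass means ≤ 1
  violation). logP is imported, never computed.
* **Global reactivity (conceptual DFT)** — from frontier orbital
  energies, via Koopmans/Parr: gap ΔE = E_LUMO − E_HOMO, hardness
  η = ΔE/2, chemical potential μ = (E_HOMO + E_LUMO)/2,
  electronegativity χ = −μ, electrophilicity ω = μ²/(2η); softest
  compound and strongest electrophile calls.
* **Local reactivity (condensed Fukui functions)** — from per-atom
  charges at N−1, N, N+1 electrons: f⁺ = q(N) − q(N+1),
  f⁻ = q(N−1) − q(N), f⁰ = (q(N−1) − q(N+1))/2, with one-electron
  conservation enforced on input; top attack-site calls.
* **Docking summaries** — per-target ligand rankings
  (more negative = better), strict better-than-reference comparisons,
  per-residue hydrogen-bond contact reports, cross-target selectivity
  matrix.
* **ADMET/TOPKAT banding** — published level semantics (BBB,
  absorption, CYP2D6, PPB, hepatotoxicity), solubility bands, and
  toxicity-probability bands ([0, 0.30) nontoxic, [0.30, 0.70)
  intermediate, [0.70, 1] toxic).
* **Synthetic data** — a seeded generator with planted strict extrema
  for every stage, so the whole pipeline is testable offline.

## Worked example

```r
library(ipscreen)

# descriptors + rule of five from the shipped library
prof <- physchem_profile(ip_library())
head(prof[, c("id", "mw", "n_hba", "n_hbd", "tpsa", "logp",
              "n_lipinski_violations")], 3)
#>   id     mw n_hba n_hbd  tpsa logp n_lipinski_violations
#> 1 4a 332.40     3     1 54.60 3.56                     0
#> 2 4b 366.85     3     1 54.60 4.12                     0
#> 3 4c 348.40     4     2 74.83 3.18                     0

# global reactivity from the frontier-energy table
gr <- global_indices(read_frontier_energies(
  ip_extdata("frontier_energies.tsv")))
gr[gr$compound_id == "4a", c("gap", "hardness", "chemical_potential",
                             "electrophilicity")]
#>      gap hardness chemical_potential electrophilicity
#> 1 3.9728   1.9864            -3.4014           2.9122
softest_compound(gr)        # "4o"  (smallest gap, 3.3198 eV)
strongest_electrophile(gr)  # "4f"  (largest omega, 4.9965 eV)

# docking: rank, compare to the reference drug, summarize selectivity
scores <- rbind(read_dock_scores(ip_extdata("dock_fdps.csv")),
                read_dock_scores(ip_extdata("dock_pde3b.csv")))
selectivity_matrix(scores)
#> selectivity summary over 2 target(s) and 15 ligands
#>   FDPS: best 4k (MolDock -145.600), 15/15 beat minodronic acid
#>   PDE3B: best 4g (MolDock -130.663), 15/15 beat olprinone

# Fukui site calls from the shipped (imported) site table
ft <- import_fukui_table(ip_extdata("fukui_4o.tsv"))
top_sites(ft, "plus", 2)
#>   atom_label  value
#> 1        O25 1.4858
#> 2         C5 0.5879

# ADMET / toxicity banding
dl <- druglikeness_report(read_admet(ip_extdata("admet.csv")),
                          read_topkat(ip_extdata("topkat.csv")),
                          ids = sprintf("4%s", letters[1:15]))
dl
#> drug-likeness report for 15 compounds
#>   BBB levels 0-4: 0/8/3/0/4
#>   AlogP98 > 5: 2  CYP2D6 inhibitors: 4b, 4h, 4m
#>   compounds with any toxic endpoint: 2
```

Reading the output: every library member is Lipinski-clean; the
nitro-substituted compounds are the softest/most electrophilic (most
reactive) members; `4k` and `4g` are the top binders of the two primary
targets, both beating their reference drugs on MolDock score; the
strongest nucleophilic-attack site of the para-nitro compound sits on a
nitro oxygen (O25); and four compounds have an undefined BBB level while
three are flagged CYP2D6 inhibitors.

The synthetic route mirrors the same API end to end:

```r
dir <- tempfile()
simulate_screen(generator_config(seed = 1), dir)   # fixtures + manifest
cfg <- run_config(compounds = file.path(dir, "compounds.tsv"),
                  frontier_energies = file.path(dir, "frontier_energies.tsv"),
                  charges = file.path(dir, "charges.tsv"),
                  dock_scores = file.path(dir, "dock_scores.csv"),
                  admet = file.path(dir, "admet.csv"),
                  topkat = file.path(dir, "topkat.csv"))
run_pipeline(cfg)   # recovers exactly the manifest's planted truths
```

A thin command-line wrapper over the same functions ships at
`inst/scripts/screen.R`.

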