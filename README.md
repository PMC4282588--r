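# specflex

Specificity–flexibility profiling of protease subpockets.

Proteases recognize substrates in a row of binding subpockets
(S4…S1 in Schechter–Berger nomenclature; subpocket S*i* binds
substrate residue P*i*, counted N-terminally from the scissile bond).
For closely related proteases — the effector caspases 3 and 7 are the
motivating case — subtle differences in substrate readout track with
differences in binding-site *dynamics* rather than static structure.
`specflex` implements the complete analysis linking the two
observables:

* **Specificity** — per-subpocket *cleavage entropy* from tables of
  experimentally observed cleavage sites:
  S*i* = −Σₐ pₐ log₂₀ pₐ over the amino-acid frequencies at window
  position P*i*, ranging from 0 (fully specific) to 1 (fully
  promiscuous).
* **Flexibility** — per-residue Cα B-factors
  (B = 8π²/3 · ⟨Δr²⟩) from fitted MD trajectories (multi-model PDB),
  aggregated into subpocket averages normalized by the protein-wide
  mean and averaged over the two protomers of a dimer; plus
  hydrogen-bond occupancies under the geometric 3.0 Å / 135° criteria
  and pair-distance mean/CV statistics.
* **The link** — Spearman rank correlation between the two profiles,
  with an optional variant excluding named subpockets (classically
  the hydrophobic, hydrogen-bond-free S2 pocket).

A synthetic-data layer (`gen_substrates`, `gen_trajectory`,
`gen_hbond_series`, `gen_distance_series`) generates every input with
analytic ground truth — prescribed positional distributions, rigid
per-residue Gaussian fluctuations (so B = 8π²σ² exactly), exact
bonded-frame fractions — making the whole pipeline testable without
running simulations. Kabsch superposition with sequence-alignment
chain matching and iterative outlier rejection supports
cross-protease structure comparison, and per-residue values can be
written into the PDB B-factor column to render specificity or
flexibility landscapes in any molecular viewer.

## Worked example

A toy protease with a stringent S1 (Asp only), moderately specific
S2–S4, and a trajectory whose fluctuations are largest in S3:

```r
library(specflex)

subs <- gen_substrates(
  list(position_dist_spec("P1", c(D = 1)),
       position_dist_spec("P2", c(V = 0.7, I = 0.2, L = 0.1)),
       position_dist_spec("P3", c(E = 0.5, D = 0.3, Q = 0.2)),
       position_dist_spec("P4", c(D = 0.8, A = 0.1, S = 0.1))),
  n = 2000, seed = 42)
prof <- specificity_profile(subs, label = "toy caspase",
                            window = c("P4", "P3", "P2", "P1"))
prof
#> Cleavage-entropy profile: toy caspase
#>  position entropy    n
#>        P4  0.2135 2000
#>        P3  0.3475 2000
#>        P2  0.2717 2000
#>        P1  0.0000 2000

def <- subpocket_definition(
  list(S1 = data.frame(resno = 1:5),  S2 = data.frame(resno = 6:10),
       S3 = data.frame(resno = 11:15), S4 = data.frame(resno = 16:20)),
  protomers = list(A = "A", B = "B"))
tr <- gen_trajectory(
  fluctuation_spec(sigma = rep(c(0.25, 0.45, 0.8, 0.6), each = 5),
                   frames = 2000, seed = 43))
sf <- subpocket_flexibility(
  residue_bfactors(tr$trajectory, tr$topology), def)
sf
#> Normalized subpocket B-factors (1 = average flexibility)
#>  subpocket  value
#>         S1 0.1979
#>         S2 0.6449
#>         S3 2.0132
#>         S4 1.1439

correlate_profiles(prof, sf, exclude = "S2")
#> Spearman rho = 0.800 over 4 subpockets (S1, S2, S3, S4) [descriptive only]
#>   excluding S2: rho = 1.000 over 3 subpockets
```

Reading the output: P1 entropy 0 is the Asp-only point mass; the S1
pocket is also the most rigid (normalized B 0.20, far below the
protein average of 1), while S3 fluctuates twice the average. Ranking
specificity against flexibility over the four pockets gives ρ = 0.8;
S2 was constructed moderately rigid yet moderately specific out of
rank order, and dropping it yields a perfect rank agreement — the
signature pattern this analysis looks for. With four (or three)
points the coefficient is descriptive; no p-value is reported.

Real data enter the same way: a substrate TSV
(`parse_substrate_table`), a multi-model PDB trajectory
(`read_structure` + `fit_trajectory`), a subpocket YAML
(`read_subpocket_yaml`; the shipped
`caspase_subpockets_synthetic.yaml` is an editable template whose
residue lists must be replaced with a real binding-site definition).
A thin command-line wrapper with subcommands (`simulate`, `entropy`,
`flexibility`, `hbonds`, `distances`, `superpose`, `correlate`) lives
at `inst/scripts/specflex.R`.

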