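---
title: "Methods: cleavage entropy, subpocket flexibility, and their correlation"
author: "specflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleavage entropy, subpocket flexibility, and their correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specflex)
```

## The problem this package addresses

Proteases read out their substrates through a row of subpockets
(S4...S1 in Schechter–Berger nomenclature, binding substrate residues
P4...P1 on the non-prime side of the scissile bond). Two questions
recur when comparing closely related proteases such as the effector
caspases:

1. *How specific is each subpocket?* — a data-mining question, answered
   from tables of experimentally observed cleavage sites.
2. *How flexible is each subpocket?* — a structural-dynamics question,
   answered from molecular-dynamics (MD) trajectories of the protease.

`specflex` implements both measurements and the correlation between
them, so that the hypothesis "rigid subpockets read their substrate
stringently, flexible subpockets are promiscuous" (a conformational-
selection argument) can be tested on any protease for which both a
substrate table and a trajectory exist.

## Cleavage entropy

Substrate records are aligned at the scissile bond
(`align_at_scissile()`), so that column P1 holds the residue
immediately N-terminal of the cut. For a window position $i$ with
observed amino-acid frequencies $p_a(i)$, the cleavage entropy is the
normalized Shannon entropy

$$ S_i \;=\; -\sum_{a=1}^{20} p_a(i)\, \log_{20} p_a(i),
   \qquad 0\cdot\log 0 := 0 . $$

The base-20 logarithm makes the range exact: $S_i = 0$ for a point
mass (one residue type only — fully specific) and $S_i = 1$ for the
uniform distribution over the 20 canonical residues (fully
promiscuous). `cleavage_entropy()` is equivalent to Shannon entropy in
nats divided by $\ln 20$; the test suite holds it to that identity at
$10^{-12}$ on random frequency vectors.

Conventions, all of which were genuinely open choices:

* **Gaps and non-canonical codes** (X, B, ...) are excluded from the
  frequency denominator rather than added as extra letters; including
  them would dilute the 20-letter alphabet with bookkeeping symbols.
  Records carrying them are retained and flagged.
* **No pseudo-counts.** Zero-frequency residues contribute zero by the
  $0 \log 0$ convention, matching the statistic's definition. No
  small-sample bias correction is applied; instead the per-position
  observation count $n_i$ is always reported alongside $S_i$ so users
  can judge. Finite samples bias the entropy *downward*, which is why
  the profile of a uniformly generated position approaches 1 from
  below as $n$ grows.
* **Duplicates count.** Database rows are treated as cleavage events,
  so duplicated windows are independent observations. Deduplicate the
  input table first if you prefer per-substrate counting.
* **Inclusion threshold.** Profiles computed from 50 or fewer records
  warn (the customary inclusion rule for substrate databases) but are
  not refused.

Two table dialects are parsed: a long MEROPS-style export
(`id`, `sequence`, `p1_position`) and a pre-aligned 8-column window
(`P4`...`P4p`, `-` for gaps). Rows with an out-of-range scissile index
are skipped and reported, not silently dropped.

## Subpocket flexibility from trajectories

Trajectories are multi-model PDB files (`read_structure()`), the one
format every MD package can export; frames must agree in atom count,
alternate locations resolve to the highest occupancy (ties toward
altloc A).

**Fitting.** Before fluctuations are measured, rigid-body motion is
removed: every frame is least-squares superposed (Kabsch, SVD with
determinant correction, so no reflections) on the time-average of a
selection — conventionally all protein Cα atoms — and the average is
recomputed and the frames re-fitted until the procedure is
self-consistent (coordinate change below $10^{-10}$ Å, usually 2–4
passes). A fixed two-pass scheme was considered and rejected: it
leaves a residual of order $10^{-3}$ Å, so `fit_trajectory()` would
not be idempotent, while iterating to a fixed point is just as
deterministic and makes re-fitting an already-fitted trajectory a
no-op. The toy generator's output contains no net drift, so fitting
changes its B-factors only through the 6 rigid degrees of freedom it
absorbs — a relative deflation of about $2/N$ for $N$ fitted atoms,
below 1% for the system sizes used in the tests (300 residues).

**B-factors.** Per residue, the mean-square fluctuation of the Cα
about its time-mean position is converted by the crystallographic
relation

$$ B \;=\; \frac{8\pi^2}{3}\,\langle \Delta r^2 \rangle , $$

so users comparing raw RMSF values can convert exactly. For the
synthetic generator, which displaces each residue rigidly by isotropic
Gaussian noise with per-component standard deviation $\sigma$, the
relation is analytic: $\langle \Delta r^2 \rangle = 3\sigma^2$, hence
$B = 8\pi^2\sigma^2$. This is the ground truth the recovery tests use
(3% tolerance at 20 000 frames; the sampling error of a mean of
squares at that length is far smaller, the tolerance mostly absorbs
the finite-sample spread across residues).

**Subpocket aggregation.** A subpocket definition groups binding-site
residues per protomer of the dimer, with chain layout and an optional
residue-number offset between protomers. The subpocket value is

$$ F_s \;=\; \frac{1}{2}\sum_{\text{protomers } p}
   \frac{\overline{B}_{s,p}}{\overline{B}_{\text{protein}}} , $$

the mean Cα B-factor over the subpocket's residues, normalized by the
protein-wide average Cα B-factor, then averaged over the two
protomers. The normalization denominator is **pooled over both
protomers** (one constant per system) rather than computed per
protomer; either order is defensible, but a pooled constant keeps the
two protomer values on the same scale, so their difference is a
meaningful symmetry check. A value of 1 means average flexibility;
ligands, ions, caps and water never enter the protein average.

Mutant-vs-native comparisons use
`percent_change()` = $100\,(F^{mut}_s - F^{nat}_s)/F^{nat}_s$,
reported rounded to the nearest integer percent with the unrounded
value retained.

The subpocket residue lists for real caspases are an external
binding-site definition not shipped here; the packaged YAML
(`caspase_subpockets_synthetic.yaml`) is a synthetic stand-in matching
the toy generator's numbering and is meant as an editable template.

## Hydrogen bonds and distances

A donor–acceptor pair is bonded in a frame iff

* donor–acceptor heavy-atom distance $\le$ 3.0 Å, **and**
* donor–hydrogen–acceptor angle $\ge$ 135° (≤ 45° from linearity).

Both defaults are the classic trajectory-analysis criteria, and both
boundaries are **inclusive** — boundary behaviour must be pinned down
for counts to be bit-reproducible, and a geometry at exactly 3.00 Å /
135° counts as bonded. Donors are every N or O with a bonded hydrogen
(one donor entry per hydrogen; bonds are inferred geometrically,
nearest heavy atom within 1.2 Å); acceptors are every N or O. Explicit
hydrogens are required — structures without them are refused with
advice rather than silently producing zero bonds. Sulfur donors and
acceptors are not included in the default chemistry.

Per pair, occupancy = bonded frames / total frames, in $[0,1]$. Group
values for a (subpocket, ligand-position) cell are **sums** of pair
occupancies — two persistent bonds give 2.0 — protomer values are
averaged, and the report total is the sum over groups, an exact
conservation the tests assert.

Distance statistics pool the equivalent atom pair of each protomer
over all frames and report the mean (Å) and the standard deviation as
percent of the mean. The SD is the **population** σ (frame counts are
large; the convention must simply be fixed), and the percent form is
the coefficient of variation. A single observation reports 0% with a
warning rather than NaN.

## Correlating specificity with flexibility

`correlate_profiles()` pairs $S_i$ (entropy at substrate position
P$i$) with $F_{S_i}$ (flexibility of subpocket S$i$) by the
Schechter–Berger index correspondence and computes the Spearman rank
correlation (average ranks on ties, delegated to `stats::cor`). Two
deliberate restraints:

* With only four subpockets, a coefficient is descriptive, not
  inferential: results carry a `descriptive_only` flag and **no
  p-value** is attached.
* Zero rank variance (all subpockets equally flexible) makes the
  coefficient undefined; the result is `NA` and flagged, never 0.

The `exclude` argument computes an additional variant with named
subpockets dropped. The motivating use is the hydrophobic S2 pocket of
caspases, which binds without hydrogen bonds: it is rigid *and*
unspecific, so it opposes the rigidity–specificity trend, and removing
it raises the coefficient. The synthetic end-to-end test reproduces
exactly this pattern by construction (a discordant S2 gives
$\rho = 0.4$ over all four pockets and $\rho = 1.0$ without S2).

## What the synthetic generators do and do not emulate

The generators give every pipeline stage an input with analytic ground
truth:

| generator | emulates | ground truth |
|---|---|---|
| `gen_substrates()` | substrate-database extraction | per-position distributions, hence analytic entropy |
| `gen_trajectory()` | production-run fluctuations of a dimer | $B = 8\pi^2\sigma^2$ per residue |
| `gen_hbond_series()` | a bond toggling in/out of criteria | exact bonded-frame fraction `round(occ·frames)/frames` |
| `gen_distance_series()` | a pair-distance time series | prescribed mean and CV |

They are *not* physical: no force field, solvent, bonded dynamics or
conformational transitions; residues move as rigid units with
independent isotropic Gaussian noise, and frames are uncorrelated in
time. Consequently a passing recovery test validates the *measurement
machinery* — alignment bookkeeping, fluctuation estimators, occupancy
counting, normalization, correlation — but says nothing about whether
a 50-ns simulation of a real protease is converged or whether its
force field is adequate. Real-data questions (equilibration,
autocorrelation, sampling) remain the user's responsibility.

All generators take explicit seeds and restore the session RNG state;
there is no hidden global randomness, and identical (spec, seed) give
bit-identical output.

## Numerical choices and degenerate inputs

* Kabsch superposition refuses fewer than 3 pairs or collinear
  geometry (second singular value below $10^{-10}$); the determinant
  correction guarantees a proper rotation (det = +1, orthonormal to
  $10^{-8}$).
* Cross-structure superposition matches chains in order, aligns their
  sequences globally (BLOSUM62, gap open 10 / extend 0.5), pairs
  aligned Cα atoms, and refines with up to 5 outlier-rejection cycles
  at a 2.0 Å per-pair cutoff — common viewer defaults. Both the
  refined and the all-pair RMSD are reported, with the per-cycle log.
* PDB B-factor output is fixed-point `%6.2f` (columns 61–66); values
  outside the representable range clamp with a warning; residues
  without a value write 0.00.
* Entropy of an empty column is undefined (`NA` with a warning), which
  is distinct from an entropy of 0 — a point this package is strict
  about, since 0 means *maximally specific*.

## Problem sizes used by the test and acceptance suites

The suites run at desk scale by design: entropy recovery uses $10^4$
generated substrates, B-factor recovery 20 000 frames of a 3–20
residue dimer, occupancy recovery 400–1000 frames, correlation
pipelines 2 500 frames and 4 000 substrates. These sizes put sampling
error comfortably inside the stated tolerances (e.g. the relative
error of a 20 000-frame mean-square is ≈ $\sqrt{2/3n} < 1\%$) while
keeping the full suite under a few minutes.

## Known limitations

* Interface residue lists per subpocket must be supplied by the user
  for real proteins; results depend on that definition.
* B-factors are Cα-based; side-chain flexibility is invisible to the
  profile (the fluctuation analysis convention adopted here, since
  positional fluctuations are conventionally computed on Cα).
* The donor/acceptor chemistry is the default N/O rule; cysteine
  thiol donors and other exotica are not modelled.
* Four-point rank correlations are descriptive. Use them to compare
  systems and variants, not to test hypotheses.
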