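---
title: "Proteochemometric modeling of HDAC inhibitor selectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteochemometric modeling of HDAC inhibitor selectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Histone deacetylases fall into classes (I: HDAC1,2,3,8; IIa: 4,5,7,9;
IIb: 6,10; IV: 11), and inhibitors that silence all of them at once carry
the side effects of all of them at once. Screening for class- or
isoform-selective chemistry means asking, for one compound, a question
about five targets simultaneously. Proteochemometrics (PCM) answers it
with a single regression over compound–target *pairs*: the response is the
standardized pIC50 of a pair, and the features describe the ligand, the
protein, and optionally their interaction.

`hdacpcm` models the scaled response with ε-insensitive support vector
regression (SVR) under the Pearson VII universal ("Puk") kernel

$$K(x,y)=\Bigl[1+\bigl(2\,\lVert x-y\rVert\,
\sqrt{2^{1/\omega}-1}/\sigma\bigr)^2\Bigr]^{-\omega},$$

a distance kernel that interpolates between a Lorentzian ($\omega=1$) and
a Gaussian ($\omega\to\infty$) and therefore serves as a generic
replacement for linear, polynomial and RBF kernels. The fitted machine is
$\hat y(x)=\sum_i \alpha_i K(x_i,x)+b$ with $|\alpha_i|\le C$.

Assumptions worth stating: pIC50 values from different assays are treated
as commensurable once standardized; each (compound, target) pair carries
exactly one measurement; protein descriptors enter at the pair level by
repeating the target's descriptor row (standard PCM practice); and the
kernel treats all standardized feature dimensions as exchangeable — which
is why the width $\sigma$ must live on the scale of pairwise distances in
the assembled feature space (see *Operating points* below).

## Descriptor blocks

**Protein.** Three alternative blocks describe the panel (HDAC2, 8 of
class I; 4, 7 of IIa; 6 of IIb):

* **P0** — global sequence identity against the eleven classical HDACs:
  Needleman–Wunsch under BLOSUM62 with affine gaps (open 10, extend 0.5),
  identity = identical positions / full alignment length including gap
  columns. The denominator convention matters and is frozen; per-residue
  alternatives (shorter-sequence or aligned-columns denominators) inflate
  identities of length-mismatched pairs and were rejected.
* **P1** — structure-alignment similarity. The similarity definition of
  the external structure-comparison tool is not reproducible from its
  description, so P1 is *ingested, never computed*: the canonical 5×5
  matrix ships as a validated fixture (`hdac_p1()`), and any user matrix
  passing validation (non-negative, self-similarity 1 within 1e-9) is
  accepted.
* **P2** — backbone geometry: the mean and sample sd of 15
  internal-coordinate classes (bond lengths N–CA, CA–C, C–O, C–N′, CA–CB;
  angles N–CA–C, CA–C–N′, CA–C–O, C–N–CA, N–CA–CB, C–CA–CB; dihedrals φ,
  ψ, ω, χ1), 30 features, lengths in Å, angles in degrees. The original
  30-feature list behind this idea is not published in the main text, so
  this realization is the package's own, frozen in
  `geometry_feature_names()`. Dihedrals use the IUPAC sign convention in
  (−180°, 180°] and *circular* mean/sd — the trans-peptide ω sits exactly
  on the ±180° seam, where a linear mean of values like {179.9°, −179.9°}
  is nonsense (we measured ~9° before switching). Terminal residues
  lacking φ/ψ are skipped, not imputed; a class with no instances (χ1 in
  poly-alanine) yields NA features and a flag rather than silent zeros.

**Ligand.** Two blocks, computed from SMILES via OpenBabel parsing:

* **GD** (32) — a VSA-style scheme: each heavy atom (with its implicit
  hydrogens) gets an approximate van der Waals surface area (sphere at
  the Bondi radius minus neighbor caps at covalent-radius bond lengths — a
  topological approximation, no 3D conformer), an additive logP and molar
  refractivity contribution from a frozen 15-class atom-type table, and a
  Gasteiger partial charge. Atom areas are summed into 10 logP bins, 8 MR
  bins and 10 charge bins; whole-molecule logP, MR, total area and
  formal-charge sum complete the vector. The bin edges and contribution
  table are package constants; models built from them are reproducible,
  and externally computed 32-column tables can substitute via
  `read_descriptor_table()`.
* **DLI** (28) — topological drug-like indices on the heavy-atom graph:
  atom/bond/ring counts (smallest-ring statistics from per-edge shortest
  cycles), aromatic rings, ring systems, Murcko-style framework atoms and
  bonds with linker bonds and side-chain atoms, rotatable/rigid bonds,
  H-bond donors/acceptors, halogen and heteroatom counts, sp3-carbon
  percentage, explicit stereocentres, graph diameter/radius, terminal and
  branch atoms, and the degree distribution. Salts keep the largest
  covalent fragment; explicit hydrogens are never graph nodes; whether
  partial charges should be Gasteiger-like was an open choice and is
  documented as such.

**Assembly.** All descriptor columns are standardized (sample sd,
statistics fit on *training* pairs by default — the alternative, fitting
on all pairs, is available as `fit_on = "all"` for compatibility with
workflows that scale before splitting, at the price of mild leakage).
Cross-terms are the protein-major flattened outer product of the
*standardized* sections and are deliberately **not** re-standardized:
scaling is defined to happen prior to cross-term formation, and
re-scaling products of standardized columns would break the
interpretation of a cross-term as an interaction of standardized effects.
Constant columns are centered, flagged and kept, so the dimension
bookkeeping (e.g. 5+32+160 for P1-GD-C) is always exact. Three protein
blocks × two ligand blocks × {blocks, blocks+cross, cross-only} gives the
18-specification grid.

## Validation metrics

All three metrics share the PRESS form
$1-\sum(y-\hat y)^2/\sum(y-\bar y_{\mathrm{ref}})^2$: R² uses training
predictions and the training mean; Q²test uses test predictions and the
*training* mean; Q²cv pools out-of-fold predictions of a k-fold
partition, each residual referenced to its fold-training mean. The
reference-mean convention is the decisive detail (there is no universal
one) and is fixed and tested. Folds are random pair-level partitions;
grouping folds by compound would be stricter against
series-memorization, and the pair-level choice is recorded as matching
the validation design being emulated.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `omega` | 1 | — | kernel tail (1 = Lorentzian) |
| `sigma` | 1 (or `"median"`) | feature-space distance | kernel width |
| `sigma_scale` | 1 | — | multiplier on the median heuristic |
| `cost` | 1 | — | SVR box constraint C |
| `epsilon` | 0.001 | scaled response | insensitive-tube half-width |
| `fraction_train` | 0.65 | — | stratified split, floor(f·n) per target |
| `threshold` | 0 | scaled response | selectivity activity cutoff |
| `margin` | 0.1 | scaled response | required active/inactive separation |

`omega = sigma = 1` and `cost = 1, epsilon = 0.001` are the historical
defaults of the kernel's and solver's reference implementations and are
kept as package defaults. They are *not* a recommendation for
high-dimensional standardized features: with ~200 columns the typical
pairwise distance is ≈ √(2·200) ≈ 20, and a width of 1 makes the Gram
matrix essentially diagonal — every point is its own island and nothing
generalizes. `sigma = "median"` with a `sigma_scale` multiplier implements
the standard median-distance heuristic.

**Operating point of the synthetic study** (`synth_puk()`,
`synth_svr()`): σ = 12 × median distance, C = 1000, ε = 0.001. The
generator's ground truth is *linear* in the assembled features (main
effects plus bilinear cross-terms), and a very wide Pearson VII kernel is
locally quadratic in distance, so the expansion approximates a smooth
near-linear surface; the large C lets the bounded duals express it. These
were chosen from that reasoning at design time, before the recovery tests
were written, and frozen.

## The selectivity rule

A target is active when its predicted scaled affinity exceeds the
threshold (0 by default: predictions are centered, so "active" means
above-average affinity). All active → `pan`; none → `inactive`; exactly
one → `isoform_selective(target)` (called *before* class selectivity — a
single active class member is the more specific, more informative call);
all of one class and none of the other (IIa and IIb merge into II) →
`class_I_selective` / `class_II_selective`; anything else `mixed`. When
both active and inactive targets exist, the call additionally requires
`min(active) − max(inactive) > margin` (default 0.1), demoting borderline
profiles to `mixed`. On the shipped ten-inhibitor validation profiles the
rule reproduces the archetypes (Apicidin → class I, NCT-10a → class II,
LBH589 → pan) but not all ten labels — some published pan profiles
contain negative values, and no threshold rule can call them pan — so
label agreement is *reported*, never asserted.

## The synthetic generator: what it emulates and what it does not

`generate_dataset()` draws protein and ligand descriptors standard
normal and builds

$$\mathrm{pIC50}(t,c) = 6 + \beta_p^\top p_t + \beta_l^\top l_c +
p_t^\top W\, l_c + \varepsilon,\qquad \varepsilon\sim N(0, 0.1^2),$$

with per-target pair counts 43/39/106/9/57 — the real panel's unbalanced
215/197/531/46/286 shape at one-fifth scale, which exercises the
stratified splitter realistically (strata from 9 to 106 pairs). Two
structural choices make the simulation more than white noise:

* **class encoding** — protein dimension 1 is +1 for class I targets and
  −1 for class II (jitter sd 0.2), mimicking the empirical fact that
  similarity descriptors cluster HDACs by class;
* **a class-affinity channel** — the last ligand dimension has no main
  effect but is coupled to the class code through W (mild default
  W[1,32] = 0.6). Class-selective activity is therefore a genuine
  protein×ligand interaction: a cross-term model can *learn* it from
  ordinary compounds and *generalize* it to planted selectives
  (compounds with a strong ±5 signature on the channel and the rest of
  their descriptors shrunk to keep overall potency average). An additive
  "selectivity bonus" orthogonal to descriptors was rejected: no
  descriptor-based model could predict it except by memorizing training
  pairs, which the wide-kernel operating point deliberately does not do.

The default interaction is mild (≈5% of response variance; main effects
≈95%), matching the regime in which cross-terms do not improve external
predictivity; `interaction = "strong"` rescales W to interaction variance
comparable to the main effects (ΣW² = 3.5), the regime in which
blocks-plus-cross beats blocks-only — the machinery's positive control.
β defaults are dense (alternating ±0.32 across all 32 ligand dimensions,
a small decaying protein pattern): every feature dimension carries
signal, as after feature curation, so the isotropic kernel distance is
meaningful. Sparse β would mix signal and pure-noise dimensions in the
distance and is a harder, different regime — worth knowing about, not the
reference scenario.

What passing the synthetic benchmarks does **not** show about real data:
descriptors are Gaussian and uncorrelated (real descriptor blocks are
heavily collinear and heavy-tailed); the truth is exactly linear-bilinear
(real structure–activity landscapes have cliffs); noise is homoscedastic
(real IC50s mix assays and labs); and the panel has five targets with
fixed descriptor rows, so "generalization" is always across compounds,
never to unseen targets.

## Numerical choices and degenerate inputs

* Sample (n−1) sd everywhere, for responses and descriptor columns alike.
* Per-stratum train count = floor(fraction × n); of the published
  per-target splits this matches four of five rows exactly, and the fifth
  is inconsistent with any single rounding rule, so the totals are not
  reproduction targets.
* Constant descriptor columns: centered, flagged, kept (never dropped).
* Constant response inside one ε-tube: the SVR shortcut returns zero
  duals and bias = mean(y) — the solver's own degenerate case is
  intercepted before it errors.
* Gram matrices are symmetrized and the diagonal pinned to 1 against
  floating-point drift; squared distances are clamped at 0.
* `q_squared` refuses zero reference variance; response scaling refuses
  zero pIC50 variance; `stratified_split` refuses pre-assigned records
  and fractions outside (0,1); empty strata are skipped with a warning.
* PDB files quantize coordinates to 0.001 Å; ideal-geometry spreads are
  therefore bounded by format precision (~5×10⁻⁴ Å), not by 1e−6, and
  the in-memory path is used when exact invariance matters.
* Rejected activity rows (non-positive IC50, implausible SMILES, unknown
  target) are dropped and tallied, never fatal; duplicate pairs *are*
  fatal, because silently averaging them would change the response
  definition.

## Problem sizes

The test suite and acceptance script run the full synthetic scenario (254
pairs, up to 197 features) across ~45 SVR fits — 5 seeds of predictivity,
20 seeded replicates of planted-selectivity recovery and 10 seeds of the
cross-term-gain contrast — in well under a minute on one CPU; these sizes
were chosen so the whole evidence chain is cheap to re-run while keeping
every stratum, including the 9-pair one, non-trivially populated.

## Known limitations

* P1 cannot be computed, only ingested; users with structures must bring
  their own alignment similarities.
* The GD/DLI realizations are this package's own; they match the
  *described content* of the classical 32/28-dimensional blocks, not any
  proprietary implementation bit-for-bit. Models record which provider
  produced their features only insofar as blocks are passed explicitly.
* Chiral-centre counting uses explicit SMILES stereocentres only;
  unlabeled potential stereocentres are not perceived.
* Implicit-hydrogen counts assume neutral standard valences; exotic
  charged species get approximate surface areas.
* The SVR is deterministic given inputs, but kernlab's optimizer
  tolerance (0.001) bounds how exactly KKT conditions hold; diagnostics
  are exposed via `check_kkt()`.
* No hyperparameter search is performed anywhere: the package reports
  models at stated operating points rather than optimizing over them.
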