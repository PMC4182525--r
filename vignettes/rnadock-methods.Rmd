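---
title: "Scoring protein-RNA docking decoys: models, parameters and design choices"
author: "rnadock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-RNA docking decoys: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadock)
```

# The problem and the model

Rigid-body docking of a protein and an RNA molecule produces large ensembles
of candidate binding modes ("decoys"). Selecting the near-native candidates
requires a scoring function whose minimum coincides with the native binding
mode. `rnadock` implements a two-level scheme for this task:

1. a **coarse-grained stage**, where each residue or nucleotide is reduced
   to its backbone heavy atoms plus a single centroid pseudo-atom, scored by
   four cheap terms (interface contact count, steric bump penalty, an
   environment log-probability and a statistical pair potential); and
2. an **all-atom stage** with ten weighted terms: Lennard-Jones attraction
   and repulsion (`fa_atr`, `fa_rep`), Lazaridis-Karplus solvation
   (`fa_sol`), a statistical residue-nucleotide pair term (`fa_pair`), a
   rotamer slot (`fa_dun`, fixed at zero here), screened Coulomb
   electrostatics (`hack_elec`) and four 10-12 hydrogen-bond sub-terms
   split by backbone/side-chain and short/long range.

The all-atom total is the weighted sum `S = sum_k w_k S_k` with every
weight constrained to the box `[0, 1]`. The weights are learned by
maximizing the ROC-AUC of the score against near-native/decoy labels with a
(mu+lambda) evolution strategy, scoring decoys through a logistic model.
Because the logistic link is monotone, the AUC of the logistic output
equals the AUC of the linear score, so the optimizer works directly on the
negated weighted sum. Only inter-partner interactions are ever scored: in
rigid-body docking the intra-partner energy is pose-invariant and cancels
from any ranking.

# Decoy generation and labelling

Decoys are rigid perturbations of the native pose applied to the RNA
partner, the protein staying fixed. Three amplitude regimes are defined by
the expectation of the perturbation magnitudes, each drawn with unit
standard deviation:

| regime  | translation (Å) | each rotation (°) |
|---------|-----------------|-------------------|
| small   | 1               | 4                 |
| regular | 3               | 8                 |
| large   | 9               | 27                |

The magnitude interpretation is a deliberate design choice: the
*amplitude* of the translation follows Normal(mean, 1) clamped at zero and
is applied along a uniformly random direction; each Euler angle has
magnitude Normal(mean, 1) clamped at zero with a random sign. The
directional distribution and the clamping policy are not dictated by the
underlying protocol, so both are fixed here once and exposed in code. The
rotation pivot is the RNA partner's heavy-atom centroid (ZYX Euler
convention), which keeps the translational and rotational contributions to
the interface displacement approximately independent.

Each decoy is labelled by its interface RMSD against the native:
**near-native** below 5 Å, **decoy** above 8 Å, and **test** in the 5-8 Å
band. The test band is excluded from learning (the classes must be well
separated for the labels to be trustworthy) but is evaluated like any other
decoy at assessment time, where the split is near-native < 5 Å vs
non-native >= 5 Å. For each complex, an ensemble of 10,000 decoys is
generated and the smallest regime yielding at least 30 near-native and 30
decoy conformations is retained (`select_setting()`); balanced learning
sets then draw exactly 30 + 30 conformations per complex uniformly without
replacement. No rejection sampling is used: when no regime satisfies the
30/30 requirement the condition is reported as an error with the
per-regime counts rather than silently resampled.

# Interface RMSD

The interface is defined on the native complex only: every residue or
nucleotide with a heavy atom within 10 Å of the other partner (the
CAPRI-style convention; the cutoff is a parameter). The fit atoms are the
protein backbone N, CA, C, O of interface residues and the backbone P atom
of interface nucleotides — the P atom is the natural RNA anchor because it
is present in every (non-5'-terminal) nucleotide and insensitive to base
conformation. The decoy's fit atoms are superposed onto the native's by
least squares (Kabsch, via SVD) over the interface atoms of *both*
partners, and the RMSD over those atoms is returned. Fitting on both
partners is a design choice the Irmsd literature leaves open; it makes
Irmsd exactly zero for any globally moved copy of the native.

# Statistical terms

The environment term classifies every unit as interface/non-interface
(centroid within 6 Å of the other partner) times buried/exposed (at least
8 same-partner centroids within 10 Å; burial has no canonical operational
definition at the centroid level, so this one is exposed as two
parameters). The table entry is the negative log conditional frequency
with add-one pseudocounts over the 24 types, so types never observed in a
class still score finitely. The pair term uses the negative log odds of
observing a type pair in centroid contact versus the product of the
marginal type frequencies, with a small `eps = 1e-6` guard for empty
joints; over-represented (favourable) pairs get negative entries. Both
tables are counting statistics meant to be estimated once from a reference
set of native complexes and never optimized further; the low-resolution
term weights default to 1.

# All-atom term parameters

The atom-level parameters (Lennard-Jones radius and well depth,
Lazaridis-Karplus `dGfree`, `lambda`, volume, partial charge and
donor/acceptor flags) are bundled as a versioned text table
(`inst/extdata/atom_types.tsv`) over ~12 simplified element+context types;
RNA atoms map onto the same protein-derived types by element and polarity.
The values are plausible molecular-mechanics magnitudes, not a
reproduction of any upstream force field: the functional forms, the
weight-learning machinery and the assessment statistics are the
deliverable, and every numerical test in the package compares against
independent brute-force oracles evaluated with the *same* table.

Numerical choices, all exposed through `highres_config()`:

* LJ and solvation pair cutoff 6 Å; electrostatics cutoff 5.5 Å with
  distances clamped at 1.45 Å and the distance-dependent dielectric
  `eps(d) = d`; Coulomb constant 332.0637 kcal·Å/(mol·e²).
* The repulsive LJ branch is linearized below `0.6 r_min` so that deep
  clashes grow linearly instead of as `d^-12`; the energy is split by sign
  into `fa_atr` (<= 0) and `fa_rep` (> 0).
* Hydrogen bonds use the 10-12 form `eps_hb (5 (r0/d)^12 - 6 (r0/d)^10)`
  with `r0 = 2.9` Å and `eps_hb = 2` kcal/mol over donor-acceptor
  heavy-atom distances in [2.2, 3.6] Å, times the squared cosine of the
  deviation from donor-H...acceptor linearity. When no hydrogen is bonded
  to the donor the angular factor degrades to 1, so hydrogen-free
  structures (including the synthetic fixtures) remain scorable.
* `fa_dun` is identically zero: no side-chain repacking or rotamer search
  is performed in this rigid-body setting, but the weight slot is kept so
  weight vectors remain compatible with the full ten-term inventory.
  A solvent-accessible-surface term and an alignment-pattern term
  (relevant to antibodies, not protein-RNA) are deliberately out of scope.

# Weight optimization

`evolve()` implements a (mu+lambda) evolution strategy with mu = 10
parents and lambda = 80 offspring per generation. Offspring are produced
by binary-tournament selection, uniform crossover (probability 0.5,
otherwise cloning) and Gaussian mutation (sd 0.05), clipped to the box.
Survivors are the best mu of parents plus offspring, so the best-ever
fitness is non-decreasing. The budget of 100,000 is counted in *fitness
evaluations*; "iterations" is ambiguous between generations and
evaluations, and evaluations is both the stricter and the
hardware-independent reading. The specific genetic operators are our own
(the ROC-based genetic learner framework this follows is described only at
the level of mu, lambda and the budget); they are recorded in
`ga_config()` and logged per run. A logistic intercept is fitted post hoc
by likelihood maximization on the linear score — it cannot change the AUC
and only calibrates reported probabilities. Wider boxes ([-1, 1], [-1, 0])
are available through `ga_config(box_min=, box_max=)` but are not the
supported default, negative weights having no biophysical reading for
penalty terms.

Cross-validation is grouped leave-one-pdb-out: for each held-out complex,
the balanced 30+30 rows of *all other* complexes form the learning matrix
and the full decoy ensemble of the held-out complex is evaluated. The
held-out group can never leak into the fit: the training subset is
reconstructed from an explicit group filter, asserted at run time, and the
test suite additionally refits the reconstructed training matrix and
requires bit-identical weights.

# Assessment statistics

* **ROC-AUC** uses the tie-aware rank statistic (ties count one half),
  which equals the trapezoidal area under the tie-grouped ROC curve and is
  invariant under strictly monotone transforms of the score.
* **Top-k precision** counts near-natives among the k best-scoring decoys
  (stable input order breaks ties) and reports the chance level
  `k * n_near_native / N` beside it.
* The **enrichment score** is the overlap between the best 10% by energy
  and the best 10% by Irmsd, normalized by `fraction^2 * N`. This
  normalization is the unique choice satisfying both anchors of the
  definition: random scoring gives 1 in expectation and a perfect
  score-to-Irmsd ordering gives `1/fraction = 10`. Top-set sizes use
  `floor(fraction * N)`.

# The synthetic generators

`make_complex()` builds idealized helical complexes: a protein helix with
N/CA/C/O backbones and one or two side-chain dummy atoms per residue
(glycine has none, exercising the centroid fallback), and an RNA helix
with the phosphate group, the full sugar ring and a planar base per
nucleotide, placed so the minimum inter-partner heavy-atom distance equals
a requested gap. The geometry is parametric rather than real A-form
helical parameters: what the fixtures guarantee is standard nomenclature,
realistic atom densities and contact/H-bond-range distances — enough to
exercise every code path deterministically. They do not emulate real
structural statistics (base pairing, sequence-dependent geometry, ions,
waters, crystallographic artefacts), so green tests demonstrate
correctness of the *method*, not predictive performance on experimental
complexes. `make_decoy_ensemble()` mixes a low-amplitude regime with a
deliberately huge one (translation expectation 60 Å: the joint-interface
superposition absorbs part of any RNA-only displacement, so clearing the
8 Å label threshold reliably needs amplitudes well above it) to realize a
controllable near-native fraction while labels remain honestly computed
from the realized Irmsd. `make_feature_matrix()` plants ground-truth
weights: the class-mean difference of the term columns is minus the
planted weight vector with isotropic Gaussian noise, making the planted
vector the Bayes-optimal linear score — the recovery harness for the
optimizer.

# Degenerate inputs and tie-breaks

Glycine centroids fall back to CA; units with no heavy atoms are an error
naming the unit. Alternate PDB locations resolve to the highest-occupancy
conformer (ties: alphabetically first altLoc); only the first NMR model is
read; HETATM records, waters, ions and DNA residues are ignored or
rejected, and a file whose majority of residues is unrecognised is refused.
Modified nucleotides are skipped with a warning rather than guessed at.
All orderings that feed ranking statistics use R's stable `order()`.

# Problem sizes and runtime

The test suite runs entirely on synthetic data at reduced scale, chosen so
the whole suite completes in about a minute: decoy ensembles of a few
hundred poses for the pipeline (10,000 for the amplitude and
class-balance checks, which are cheap), learning matrices of 120-480 rows,
and GA budgets of 1,000-100,000 evaluations depending on what the test
asserts. These sizes are the package's own testing choices; the
defaults of every user-facing function remain at the headline protocol
values (10,000 decoys, 30+30 per complex, mu = 10, lambda = 80, budget
100,000).

# Known limitations

Ions, explicit solvent and polarized electrostatics are not modelled,
although RNA interfaces are frequently ion-mediated; RNA (and protein)
flexibility is not sampled — decoys are rigid perturbations; the atom
typing is deliberately coarse (~12 types) and not a faithful upstream
parameter reproduction; and the low-resolution statistical tables are only
as good as the reference set they are counted on.
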