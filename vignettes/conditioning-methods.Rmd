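---
title: "Pharmacophore-constrained diffusion sampling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore-constrained diffusion sampling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoregen)
```

## The conditioning model

`phoregen` steers a pretrained, unconditional 3D molecular diffusion model
toward poses that realize a set of 3D pharmacophores inside a protein
pocket. The generator itself is never retrained; all control happens
inside the reverse (denoising) process. A molecule is `M = {A, R, B}` —
element types, Cartesian positions in Ångström, and a categorical bond
matrix. At each reverse step the denoiser proposes Gaussian position means
and categorical type/bond distributions; the sampler then applies, in
order: the clash-guidance shift, the Gaussian draw, masked-position
anchoring, and atom-type clamping. Anchoring runs *last* so the
satisfaction geometry of the final pose cannot be disturbed by guidance.

### Position anchoring

A mask binds atom slot `k` to pharmacophore point `p̂_k` for the whole
trajectory (slot `k` of the generated molecule is point `k`'s atom; the
binding is never reassigned, which makes generation permutation-free).
After the Gaussian draw at step `t`, masked rows are mixed with their
points:

$$ r_k \leftarrow (1-\gamma_t)\,r_k + \gamma_t\,\hat p_k . $$

The anchoring weight is any monotone non-increasing schedule with a hard
window at the end of the reverse pass; the default is

$$ \gamma_t = \min\!\Big(1,\ \frac{(1-t/T)^2}{1-f}\Big),
   \qquad \gamma_t = 1 \text{ for } t \le \lceil fT \rceil,\ f = 0.1 . $$

Early steps (large `t`) nudge atoms gently toward the points; the final
10 % of steps pin them exactly. Because the hard window sets masked
positions to the points bit-exactly, an accepted pose satisfies its
distance constraints by construction, and the schedule constructor
enforces monotonicity and the hard window as invariants. Reference points
are used at their original coordinates by default; the
`noised_reference` mode (one of the three ablation variants, below)
forward-noises them at each step instead.

### Clash guidance

The pocket is represented as a differentiable proximity field — the
soft-minimum distance to the protein heavy atoms,

$$ S(r) = -\sigma \log \sum_j \exp(-\lVert r-a_j\rVert/\sigma), $$

which lower-bounds the true minimum distance and converges to it as
`σ → 0`. Atoms closer than the clash threshold `d_clash` are penalized by

$$ L(R) = \sum_i \max(0,\ d_\mathrm{clash} - S(r_i))^2 , $$

and the sampling mean is shifted by `−λ Σ_t ∇L(R^t)`, with the gradient
evaluated analytically at the current state `R^t` (evaluation at the
predicted mean is exposed as an option; evaluating at the state is the
standard choice in classifier guidance). Defaults: `σ = 1 Å`,
`d_clash = 2 Å`, `λ = 0.1`; all three are configuration parameters. Note
the sign convention: `∇L` points *toward* the protein (the loss grows as
an atom approaches the wall), and the applied shift `−λΣ_t∇L` pushes
clashing atoms away.

### Atom-type clamping and satisfaction

Fixed element types on masked slots are re-imposed after every step's
categorical draw; bond predictions pass through unchanged. A pose
satisfies its constraint specification when, for every point, some atom
of the matching feature family (typed on the generated molecule with the
same donor/acceptor definitions used for extraction) lies within
`τ = 1 Å`. Any atom may satisfy a point by default; a strict mode
restricts satisfaction to the bound slot. Each requested ligand is given
up to three full-trajectory attempts and rejected attempts are logged.

### Feature typing

Donor/acceptor features follow the default definitions of the standard
feature factory: donors are N/O (or S) carrying at least one hydrogen,
explicit or implicit; acceptors are hydrogen-free oxygens, hydroxyl
oxygens not adjacent to a carbonyl-type group, trivalent nitrogens
excluding amide-type environments and hydrogen-bearing aromatic
nitrogens, and divalent or aromatic sulfur. The definitions ship as a
versioned data file (`inst/extdata/feature_definitions.json`, including
the equivalent SMARTS) and are implemented as a rule-based typer on the
package's own bond-matrix graphs, so feature assignment is independent of
any external toolkit's version. Implicit hydrogens come from default
valences of neutral atoms; formal charges are not modelled, a documented
limitation that matters mainly for zwitterions.

## The toy system

Real conditioning targets a trained denoiser; shipping one is impossible
in a source package, and testing against one would be slow and
non-deterministic. The package therefore ships a **closed-form toy
denoiser**: for a known template `r₀*`, the forward process
`q(r_t|r_0) = N(√ᾱ_t r_0, (1-ᾱ_t)I)` admits an exact Gaussian posterior
for `r_{t-1}` given `(r_t, r_0*)`, which plays the role of the trained
network. The posterior mean is written in the centred form

$$ \mu = c_1 r_0 + c_2 r_t + (1 - c_1 - c_2)\,\bar r_0 $$

(`\bar r_0` the template centroid) so that the closed form is exactly
E(3)-equivariant — the plain DDPM posterior is not
translation-equivariant because the forward process scales positions,
and real molecular denoisers obtain the same property by working in
centred coordinates. For the origin-centred templates the generator
produces, the two forms coincide. Type and bond logits are one-hot
encodings of the template, so unconditional sampling recovers the
template to ~0.02 Å mean RMSD and conditioned runs have a well-defined
ground truth.

The fixture generator emulates a convex pocket: pseudo-atoms on a
spherical shell (default radius 8 Å, 150 atoms) with a 35° polar opening,
and a random tree-bonded heavy-atom template (C/N/O, single bonds,
1.4 Å) centred inside. Two leaves carry an O (hydroxyl: donor +
acceptor) and an N (amine: donor + acceptor), so pharmacophores are
always extractable; tree degree is capped at 2 for the first four atoms
so that a masked slot clamped to N or O keeps the hydrogen count its
feature family needs. Construction enforces that every template atom's
*smoothed* surface distance exceeds the clash threshold — the soft
minimum sits up to about `σ·log P` below the true wall distance, so the
template is kept inside a correspondingly smaller radius. What the toy
system does **not** emulate: real chemistry of the generated molecules
(valence beyond trees, rings, realistic geometry), learned chemical
priors, pocket shape diversity, or denoiser error. Passing tests
therefore certify the *conditioning machinery* — anchoring, guidance,
clamping, retry, equivariance, metrics — not generative quality on real
targets.

## Randomness and reproducibility

All randomness flows from one master seed through a counter-based
splitting scheme: every draw (initialization, per-step position noise,
reference-point noise, type sampling) uses a seed derived from
`(master, ligand, attempt, step, purpose)`, so attempts are independently
reproducible and the unconditional chain is a strict special case of the
conditioned one — an empty mask with `λ = 0` reproduces it bit-exactly
under a shared seed. The sampler also accepts a `noise_transform` hook;
rotating the noise stream together with all inputs makes the entire
sampler exactly equivariant, which the tests exploit (observed error
~1e-15 Å).

Initialization modes mirror the three ablation variants: random around
the pharmacophore points (default; spread 1 Å), pure random around the
pocket origin, and around-points with forward-noised reference points.
The mode changes trajectories, not necessarily final poses: the toy
posterior contracts strongly onto its template, so mode differences are
asserted on stored trajectories.

## Metrics

* **Shape-and-color similarity** — poses are compared in place, no
  realignment. Shape: Gaussian-overlap volume Tanimoto over heavy atoms
  (per-atom width 1.2 Å ≈ carbon van der Waals radius / √2). Color: the
  same overlap restricted to feature points, with cross-terms only
  between same-family pairs, families pooled. The score is the
  unweighted mean of the two (weights configurable). With no features on
  either side the score reduces to the shape term — otherwise two
  distant alkanes would score 0.5 on color vacuity.
* **Interaction similarity** — the fraction of the reference pose's
  protein hydrogen bonds that the generated pose reproduces, a bond
  being shared when it reaches the same protein residue with the same
  ligand role (donor/acceptor), matched with multiplicity and capped at
  1. Hydrogen bonds are detected geometrically: donor–acceptor heavy
  atoms within 3.5 Å, and on the ligand-donor side a D–H⋯A angle of at
  least 120°, using explicit hydrogens when present and otherwise one
  idealized hydrogen placed anti to the donor's heavy neighbours.
  Protein donors (nitrogens; Ser/Thr/Tyr hydroxyls) carry no hydrogens
  in heavy-atom structures, so only the distance criterion applies on
  that side. Both cutoffs are configuration parameters.
* **Synthetic accessibility** — fragment-frequency contributions over
  circular fragments (radius 0–2) plus size and macrocycle penalties and
  a symmetry bonus, mapped to [0, 1] with high = easy to synthesize. The
  frequency table is built at load time from a shipped synthetic corpus
  of ~50 common drug-like and fragment molecules
  (`sa_corpus_synthetic.sdf`); the historic million-compound tables are
  third-party data and are not shipped, so absolute values are
  calibrated to this corpus while orderings behave as expected
  (ethane 0.76, benzene 0.96, a heteroatom macrocycle 0.53). Stereo and
  spiro/bridge penalties are not implemented (no stereo perception on
  bond-matrix graphs).
* **QED** — weighted geometric mean of the published asymmetric-double-
  sigmoid desirabilities over MW, ALOGP, HBA, HBD, PSA, ROTB, AROM and
  ALERTS; the parameter table and weights ship as data. MW/logP/TPSA
  come from OpenBabel; HBA/HBD reuse the package's feature typer;
  rotatable bonds, aromatic rings (a kekulized-aware approximation:
  5–6-rings whose atoms are sp2 or lone-pair heteroatoms) and alerts are
  computed on the package's graphs. Given identical descriptor values
  the desirability evaluation agrees with the reference implementation
  to 1e-10; descriptor values themselves can differ from other toolkits
  (logP provenance, aromaticity perception).
* **Diversity** — 1 − mean pairwise Tanimoto of hashed circular
  fingerprints (radius 2, 2048 bits) computed on the package's graphs
  with ECFP-style environment-growth termination. Bits are not
  interchangeable with external toolkits'; both sides of every
  comparison use the same implementation.
* **Structural filters** — curated minimal NIH/PAINS/Brenk catalogs in
  pattern-graph form (allowed elements, hydrogen-count bounds, bond
  orders, optional non-ring constraints), matched by subgraph
  isomorphism (LAD with per-atom candidate domains). These are
  deliberately small, documented subsets of the published catalogs, not
  replacements.
* **Success rate** — per pocket, the fraction of molecules that are
  validity-flagged, pass the NIH catalog, and reach QED ≥ 0.19 and
  SA ≥ 0.33 (the thresholds used with the benchmark test set); pockets
  with no passer are counted separately. Pose-validity checking and
  docking are external tools behind adapter seams; the offline stub
  flags everything valid and labels the output `stubbed`, and only the
  docking-score normalization `score/√N` is computed in-package.

## Numerical choices and degenerate inputs

The soft-minimum field is evaluated with the max-shifted log-sum-exp for
stability; the clash gradient uses softmin weights and unit vectors with
a 1e-12 distance floor, and returns exact zero rows for non-clashing
atoms. Top-k selection is a stable descending sort (ties keep input
order); `k` beyond the candidate count returns all with a warning.
Fragment selection breaks ties toward the component containing the
smallest original atom index. Single-atom molecules bypass the main SDF
writer (the upstream reader rejects one-atom records) through an
equivalent fixed-width path, and V2000 coordinates are rounded to the
format's four decimals before writing so the fixed-width columns stay
parseable. An empty constraint specification is valid and means
unconditional sampling: satisfaction is vacuously true and around-points
initialization falls back to pure-random with a warning.

## Problem sizes

The shipped study conditions are a 12-atom template in an 8 Å pocket of
150 pseudo-atoms with a 50-step linear schedule (β from 1e-4 to 0.1,
Σ_t = β_t) — trajectories take ~0.1 s, so the test suite runs hundreds
of full generations: 50 conditioned runs for anchoring exactness, 100
paired seeds for the guidance sign test on a pocket tightened to 55 %
radius (the improvement per pair is small because the closed-form
posterior dominates the dynamics, but it is systematic), 20 runs for
equivariance, 200 for unconditional recovery, and 100 randomized cases
per brute-force oracle comparison.

## Known limitations

No formal charges, stereochemistry or tautomer handling; the aromatic
ring count is an approximation on kekulized graphs; SA calibration is
corpus-relative; protein-side hydrogen-bond geometry uses distance only;
the MolDiff adapter is a documented stub — plugging in a trained
denoiser is the intended extension point, not a shipped feature.
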