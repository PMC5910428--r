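---
title: "Residue-profile networks: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-profile networks: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fixed-backbone protein design asks: given only the backbone trace of a
protein (atoms N, CA, C, O), which amino acid should sit at each position?
profnet treats this as a per-position 20-way classification problem. Each
target residue is described by its local structural environment -- itself
plus its N nearest neighbor residues by CA-CA distance, the *structural
cluster* -- and a neural network maps the cluster to a probability profile
over the 20 amino-acid types. Profiles can then be thresholded into top-K
residue-type restraints and exported as Rosetta resfiles for use with
fixed-backbone design programs.

The approach rests on one assumption: the identity of a residue is largely
determined by the geometry of its surroundings, so similar local
environments in known structures should vote for similar residue types.
Because the network scores each position independently, correlations
between neighboring identities are deliberately left to the downstream
design program.

## Input features

Every target-neighbor residue pair is summarized by 31 numbers, in fixed
order:

* target backbone dihedrals phi, psi, omega as (cos, sin) pairs (6),
* target backbone SASA in square Angstrom (1),
* target three-state secondary structure, one-hot helix/sheet/loop (3),
* the same ten values for the neighbor (10),
* CA-CA distance in Angstrom (1),
* unit vector from target CA to neighbor CA (3),
* the neighbor's CA-to-N and CA-to-C unit vectors (3 + 3),
* the count of backbone-backbone hydrogen bonds between the two (1).

All directional quantities are expressed in the target's *canonical frame*:
the rigid transform that puts its CA at the origin, its N on the negative x
axis and its C in the z = 0 plane. The frame definition leaves a two-fold
ambiguity (which side of the x axis C falls on); we resolve it
deterministically by requiring the transformed C to have positive y.
Dihedrals are encoded as (cos, sin) because the angle itself is
discontinuous at +/-180 degrees; undefined angles (chain termini, chain
breaks with a peptide C-N distance above 2.0 A) are encoded as (0, 0), a
point off the unit circle that the network can recognize as a sentinel.
Terminal residues remain valid prediction targets with this encoding.

### Secondary structure

Three-state labels are computed internally from dihedrals and hydrogen
bonds: helix requires a run of at least three residues in the helical
dihedral basin (phi in (-100, -30), psi in (-80, -5)) or participating in
(i, i+4) backbone hydrogen bonds; sheet requires extended dihedrals plus at
least one backbone hydrogen bond to a residue more than two positions away
(or on another chain); everything else, including residues with undefined
dihedrals, is loop. This is a compact re-derivation, not a byte-compatible
reimplementation of Stride or DSSP assignments -- only the three coarse
states are needed as features, but users comparing against external tools
should expect boundary residues to differ occasionally.

### Hydrogen bonds

Backbone hydrogen bonds use the DSSP electrostatic model: E = 0.084 * 332 *
(1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN)) kcal/mol, with a bond when E <
-0.5. The amide hydrogen is reconstructed 1.0 A from N along the direction
opposite the bisector of the C(i-1)-N and CA-N bonds; prolines and
chain-start residues never donate. Pairs closer than 2 in sequence or
farther than 10 A by CA-CA are excluded.

### Backbone SASA

SASA is computed on the whole structure with all sidechain atoms removed
from both the measured and the occluding set -- the surface a design method
actually sees before identities are chosen -- with a Shrake-Rupley
procedure: probe 1.4 A, radii N 1.65, CA/C 1.76, O 1.40 A, 960 test points
per atom on a deterministic golden-angle lattice. Values are raw square
Angstrom (no normalization by residue-type reference areas, which would
require knowing the identity being predicted).

One numerical subtlety: with test points fixed in the laboratory frame,
rotating the input changes which points survive occlusion, so computed
areas would jitter by the point quantum (about 0.04 square Angstrom).
profnet instead orients each atom's point lattice in its residue's
canonical frame, which makes the sampling co-rotate with the structure and
the computed SASA exactly invariant under rigid motion -- a property the
test suite asserts at 1e-6 together with all other features. The price is
that mirror images, whose frames cannot be made to co-reflect with a proper
rotation, agree only to sampling resolution (a fraction of a percent).

## Architecture

Two subnetworks read each 31-feature pair vector with *shared parameters*
across all N neighbor slots, like a 1-D convolution over neighbors:

* the **residue-probability subnet** (default 64/64 ReLU, 20-way softmax)
  outputs a candidate distribution over residue types;
* the **weight subnet** (default 32/32 ReLU, 1 output) outputs that
  neighbor's scalar importance.

Each slot's probability vector is multiplied by its weight; the N weighted
20-vectors are concatenated in ascending-distance order and passed through
a fully-connected **head** (default 256/256 ReLU) ending in a 20-way
softmax. Hidden widths are configuration, not contract: they are stored in
the fitted object and validated at prediction time.

Two quantities the literature leaves open had to be fixed here. The weight
subnet's output activation is softplus by default, so weights are
nonnegative and interpretable as attention-like importances (a linear
output remains available via `train_config(weight_activation = "linear")`).
Initialization is seeded He-uniform, the standard choice for ReLU stacks.

### Input standardization

The 31 features mix unit-scale quantities (cos/sin, unit vectors) with
square-Angstrom SASA values in the tens. The features are therefore
z-scored -- mean and standard deviation estimated on the training rows,
stored in the fitted model, and re-applied at prediction -- before entering
the subnets. Without this, the fixed learning rate of 0.01 is numerically
fragile. Constant features keep scale 1 to avoid division by zero.

## Training

The loss is categorical cross entropy with per-sample class weights W_i =
N_max / N_i computed from the training labels, entering as multiplicative
loss factors (not resampling): the most abundant residue type has weight 1
and rarer types proportionally more. The optimizer is stochastic gradient
descent with Nesterov momentum; full-scale defaults are learning rate 0.01,
momentum 0.9, batch size 40000 and 1000 epochs. Gradients are derived in
closed form and applied with plain matrix algebra; parameter sharing means
one gradient accumulates across all neighbor slots. Training is
deterministic for a given seed (initialization and per-epoch shuffling are
both seeded), up to floating-point reduction order.

Desk-scale fits on the synthetic fixtures use batch 256 and at most 200
epochs; these sizes are stored in `train_config()` calls, not hidden
defaults, so full-scale settings remain one argument away.

## The synthetic data generator

`learnable_dataset()` builds clusters from idealized fragments with known
generating classes: alpha-helices (phi = -57, psi = -47), three-stranded
sheets assembled by translating an ideal extended strand along its carbonyl
direction (the middle strand is the one whose every interior residue forms
inter-strand hydrogen bonds -- in any single two-strand ladder only
alternate residues bond directly), and left-handed "loop" fragments with
dihedrals drawn from 40-80 degrees, a basin disjoint from both the helical
and extended regions. Labels are the generating class embedded in the
20-letter space (helix = Ala, sheet = Cys, loop = Asp), so the label is a
deterministic function of the target's dihedral/secondary-structure
features and Bayes-optimal accuracy is 1 by construction. Gaussian
coordinate noise of 0.05 A emulates the coordinate uncertainty of a
high-resolution crystal structure; at this level backbone dihedrals move by
up to roughly 20 degrees, which keeps the classes separated. Class
marginals are met by quota (rounding at fragment granularity), so requested
imbalances like 95:5 are realized to within about a percent.

What the generator does *not* emulate: sidechain packing, sequence-specific
geometry (every residue is built with identical ideal internal
coordinates), crystallographic artifacts, or the long-tailed environment
diversity of the PDB. Passing the learnability checks therefore
demonstrates that the architecture, gradients, weighting and data plumbing
are correct -- not that the model reaches literature-scale recovery rates,
which require training on a curated structure corpus that is out of scope
here.

A note on the class-weighting check: on a perfectly separable task even an
unweighted model eventually recovers the minority class, so the effect of
W_i weighting is probed early in training (2 epochs, batch 512, before the
unweighted model catches up), where the weighted run's minority recall
exceeds the unweighted run's for every tested seed.

## Numerical choices and degenerate inputs

* Torsions follow the IUPAC sign convention and are reported in
  (-180, 180]. The torsion of four points is invariant under reversing the
  point order (it looks the same from either end of the central bond) and
  flips sign under mirror reflection; the tests assert both identities.
  Collinear triples raise an error rather than returning an arbitrary
  angle.
* Argmax and top-K ties are broken alphabetically (A before C before D...),
  deterministically; uniform profiles therefore predict Ala.
* Per-class recall/precision with empty denominators are reported as NA
  (missing), never as 0, so class averages are not biased.
* The ideal-backbone builder uses standard peptide geometry (N-CA 1.458,
  CA-C 1.525, C-N 1.329 A; N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7
  degrees) and sequential natural-extension placement; rebuilding dihedrals
  from its output recovers the specification to better than 1e-6 degrees,
  which the tests use as a round-trip oracle.
* Dataset archives are a versioned single-file RDS container (manifest,
  feature array, labels, folds); loading validates the format version,
  dimensions against the manifest, the 0-19 label range and the fold
  partition. R stores doubles, so round trips are bit-exact.
* Structures with alternate locations keep altloc blank/'A' atoms, or the
  highest-occupancy location when only others exist; any residue with an
  atom below occupancy 1 is later excluded from clusters entirely, so the
  choice only affects which occluders exist for SASA.

## Problem sizes

The shipped tests and the results script run entirely on synthetic data:
100 random backbones for the geometry round trip, 50 random rigid motions
for feature invariance, 20 random sphere sets (up to 10 atoms) against a
Monte-Carlo surface oracle, and a 2000-cluster, N = 5 training run (1600
train / 400 held out, 200 epochs) for learnability, plus a 1000-cluster
95:5 imbalance probe over three seeds. These sizes were chosen to exercise
every code path at full fidelity while keeping a complete run on a single
CPU in the low minutes.

## Limitations

* Secondary structure and SASA are internal re-derivations; models trained
  on features from external assignment tools are not interchangeable with
  models trained here.
* The paper-scale experiment -- training on tens of thousands of curated
  PDB structures -- is out of scope; no pretrained weights ship with the
  package, and literature accuracy figures are not reproduced at desk
  scale.
* Only x-ray-style single-model PDB files are parsed (first MODEL of a
  multi-model file); mmCIF is not supported.
* Membrane-protein exclusion is delegated to a user-supplied identifier
  list in `filter_config(exclude_ids = ...)`.
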