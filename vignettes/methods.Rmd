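---
title: "Class-routed backbone angle regression: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-routed backbone angle regression: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A protein backbone conformation is fully described by per-residue torsion
angles: phi (C$_{i-1}$–N$_i$–CA$_i$–C$_i$) and psi
(N$_i$–CA$_i$–C$_i$–N$_{i+1}$), plus, in the CA-trace representation, the
planar angle theta (CA$_{i-1}$–CA$_i$–CA$_{i+1}$) and the torsion tau
(CA$_{i-1}$–CA$_i$–CA$_{i+1}$–CA$_{i+2}$). `ssbap` predicts all four from
sequence-derived per-residue features.

The central idea is *class routing*: secondary structure narrows angle
distributions dramatically (helical and strand residues concentrate in
tight Ramachandran basins; coil does not), so instead of one regressor per
angle trained on all residues, the package trains one regressor per
(3-state class, angle) pair — twelve in total — and routes each residue at
inference to the model of its *predicted* class. A generic model must
spread its capacity over all classes; a class-specific model specialises
on one conditional distribution. The cost is less training data per
model; whether the exchange is favourable is an empirical question, and
the package makes it directly testable: `train_bundle(by_class = FALSE)`
trains an equal-capacity pooled baseline per angle under the same
schedule, and both the test suite and the acceptance script run the
routed-versus-pooled comparison on synthetic data (see the limitations
section for what that comparison shows at desk scale).

Each regressor is a fully connected network with three hidden layers of
150 sigmoid units and one linear output emitting the angle in degrees
directly (no sine/cosine target encoding). Training is minibatch SGD with
momentum 0.9, initial learning rate 0.01, halved after three consecutive
epochs without improvement of the monitored loss, floored at 1e-15, with
Glorot-uniform initialisation. The loss is the periodic mean absolute
error, `AE = min(D, |360 - D|)` with `D = |predicted - actual|`, averaged
over residues whose target is defined; terminal residues, where an angle's
defining atom quadruple does not exist, are excluded everywhere (training,
validation, and every reported metric).

## Features and settings

Per residue the feature vector concatenates, in fixed order: a one-hot
encoding of the 8-state secondary-structure prediction (8, alphabet order
H, G, I, E, B, T, S, C), the PSSM profile (20), seven physicochemical
constants of the amino acid (7), optionally the HMM profile match
emissions (20) and predicted accessible surface area (1) — at most 56.
Features of the `W` residues centred on the target position are
concatenated (window sizes 5 or 9), giving up to `56 W` inputs; positions
beyond the chain ends contribute zero blocks. A four-character setting
name `AHIW` fixes the configuration: ASA on/off, HMM on/off, range or
Z-score normalization, window 5 or 9. The shipped per-slot defaults
(`default_settings()`) are: helix `YYR9` for all four angles; sheet `YYR9`
except psi `YYZ9`; coil `YYR5` for phi and theta, `YYR9` for psi and tau.

Normalization statistics (per-column min/max, or mean and *population*
standard deviation) are fitted on training residues only — by default on
the residues of the routed class, so each class model sees statistics of
its own training distribution (`normalization = "global"` fits on all
training residues instead). Range-normalized test values falling outside
the training range are not clipped. Columns constant in training map
to 0. The one-hot block is normalized like every other column; under
range normalization this is the identity on {0, 1}.

Three conventions are deliberate choices where the field has no single
standard, and are configurable:

* the one-hot position order is the declared alphabet above;
* window positions beyond the chain ends are zero blocks (zero is the
  neutral value of the dominant one-hot block after normalization);
* the 8-to-3-state collapse is the DSSP-style H,G,I to helix; E,B to
  sheet; T,S,C to coil (`map_ss8_to_ss3` accepts any mapping).

The physicochemical constants table (`pcp7_table()`) follows the standard
seven-parameter set used in sequence-based structure prediction (steric
parameter, polarizability, volume, hydrophobicity, isoelectric point,
helix and sheet propensity); tests depend only on its 20 x 7 shape and
determinism, not on individual entries.

## Numerical choices

* **Angles** live in the half-open interval (-180, 180]; `wrap_angle`
  chooses +180 over -180 so the wrap is a function. Theta is planar, not
  periodic: predictions are wrapped and then clamped to [0, 180].
* **Dihedral sign** follows IUPAC (positive clockwise viewed from the
  second to the third atom); an alpha-helical phi is about -60. A point
  triple is treated as degenerate when its cross-product norm falls below
  1e-10 square Angstrom.
* **Monitored loss.** Whether the schedule should watch the training or
  the validation loss is ambiguous in the underlying description; the
  default is the validation loss, `monitor = "train"` switches to the
  epoch's batch-averaged training loss. The training loss recorded in the
  history is the batch-averaged loss of the epoch's forward passes (the
  convention of the major deep-learning frameworks), not an extra
  full-dataset pass.
* **Batch size** defaults to 64. The periodic-MAE subgradient has
  constant magnitude (a sign), so the update size does not grow with the
  residual; with large batches (e.g. 256) there are so few updates per
  epoch that a model can sit at the constant-predictor plateau long
  enough for the patience-3 halving schedule to freeze it there. Smaller
  batches give more updates per epoch and reliably escape the plateau;
  16-64 work well at desk scale. The epoch budget (`max_epochs`, default
  300) and batch size are schedule parameters, not part of the method.
* **Best-weights snapshot.** The returned model carries the weights of
  the best monitored epoch, not the last one.
* **Determinism.** All randomness (initialisation, shuffling, the
  generator) flows from explicit integer seeds through R's RNG; a fixed
  seed reproduces training histories bit for bit on a fixed platform
  (fixed BLAS and thread count; floating-point summation order is not
  portable across those).
* **Serialization.** Bundles persist as JSON with doubles printed as
  `%.17g` strings, which round-trips IEEE doubles exactly; a reloaded
  bundle predicts bit-identically.

## Reconstruction

`build_backbone` rebuilds N/CA/C/CB coordinates from a sequence and
phi/psi by sequential internal-coordinate placement (the standard NeRF
scheme): each atom is placed from a bond length, bond angle and torsion
relative to the three previously placed atoms. The peptide junction is
fixed at C–N = 1.33 Angstrom with omega = 180 degrees; junction bond
angles use canonical peptide values; intra-residue geometry comes from a
residue template library. The bundled library is *synthetic* — idealized
templates built from canonical bond lengths and angles, identical across
amino acids except for glycine's missing CB — deliberately, so the
package ships no coordinates derived from deposited structures;
`residue_library_from_pdb()` ingests a user-supplied library from any PDB
file. Theta and tau are not used in construction; they are consequences
of phi/psi (and the fixed junction geometry), which also makes them
honest prediction targets for chains built by the generator. phi of the
first residue and psi of the last correspond to no torsion of the chain
and are ignored. Reconstruction quality is scored by least-squares
superposition RMSD over CA (or N/CA/C) atoms.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset` produces fully self-contained datasets: sequences,
true and corrupted 8-state secondary-structure strings, angle tables,
coordinates (built through `build_backbone`, so extracted angles equal
the sampled ones to numerical precision), and feature files in the same
formats the readers parse (PSI-BLAST-layout PSSM, HHsuite-layout HHM, ASA
TSV, PDB, FASTA).

It emulates the *statistical shape* of real inputs: secondary structure
arrives in segments with per-class mean lengths, and segment class
weights are derived from configurable stationary residue fractions
(default 38/23/39 helix/sheet/coil, the composition of an average
protein); helix and sheet phi/psi are tight Gaussians (sd 5 degrees,
about a 20-degree range) in the alpha and beta basins; coil is a broad
four-component mixture including a uniform background; the predicted
labels equal the true ones corrupted at a configurable rate (default
0.08, roughly the error of a good 8-state predictor). Profile features
are a planted signal: a low-order trigonometric polynomial of
(sin phi, cos phi, sin psi, cos psi) mapped through fixed random
coefficient matrices, plus Gaussian noise — non-linear but invertible, so
a sufficiently trained network can recover the angles, while noise and
label corruption keep the task non-trivial. With
`class_specific_link = TRUE` each class receives its own coefficient
matrices, the scenario in which class routing has a strict information
advantage.

What the generator does *not* emulate: evolutionary structure of real
profiles (conservation patterns, gap statistics), sequence-identity
redundancy, chain breaks and missing density, or any coupling between
amino-acid identity and secondary structure. Passing tests on synthetic
data therefore demonstrate that the pipeline's machinery — encoding,
routing, optimisation, reconstruction, evaluation — is correct and that
the architecture can extract an angle signal that is present in the
features; they say nothing about prediction accuracy on real proteins,
which depends on how much angle information real profiles carry.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely on generated data,
sized for a desk machine: a reusable 24-protein dataset for unit tests;
about 2,000 residues per class (noiseless, uncorrupted labels) for the
planted-signal recovery check, trained with batch 16 and the
training-loss monitor; five 60-protein seeds for the routing-benefit
comparison; and a 90-protein dataset for the end-to-end acceptance run.
Where training quality is asserted (validation periodic MAE below
5 degrees per model slot), the threshold reflects what the planted
generator conditions support, not a claim about real data.

## Known limitations

* Direct degree regression places a branch cut at the +/-180 wrap: a
  class whose angle distribution straddles the cut (strand tau values
  near +/-180) is intrinsically harder for a linear output than one in a
  single basin, even though the periodic loss scores it correctly. The
  method accepts this in exchange for simplicity; trigonometric target
  encodings avoid it at the cost of a different output head.
* Tau is the most data-hungry target. The generator plants each
  residue's own phi/psi in its features, so tau must be learned as a
  cross-residue composition of four torsions; residues at class-segment
  edges additionally depend on neighbours from another class's (broad)
  distribution. On synthetic data the tau models keep improving well
  past the point where the per-residue angles have converged: at about
  2,000 training residues per class the tau slots plateau around 8
  degrees (coil tau with a pure train/validation gap, strand tau also
  fit-limited by the wrap cut above), while doubling the class size
  brings coil tau near 1 degree. The per-residue angle slots are
  unaffected.
* One model per (class, angle) slot means twelve trainings; there is no
  weight sharing across angles or classes.
* The routing label is the *predicted* class, so routing errors compound
  prediction errors near class boundaries; evaluation can stratify by
  actual class to expose this.
* The specialization benefit itself does not reproduce at desk scale on
  this generator. The pooled baseline receives the residue's predicted
  class through the one-hot block of its own features, so class-divergent
  angle-feature maps yield positive transfer (the shared structure is
  learned once, on three times the data) rather than interference, and
  under the epoch-based halving schedule the pooled arm also takes about
  three times more gradient steps per epoch than each class model. In
  every configuration tried — equal epochs, update parity,
  convergence-matched budgets, capacity-limited networks, widely
  divergent class maps, noisy realistic maps — the pooled model matched
  or beat the routed bundle on held-out periodic MAE. Class routing's
  reported advantages on real proteins are of the order of a few
  percent, which is below seed-to-seed noise at these problem sizes;
  demonstrating them appears to require real-data scale and complexity.
* Backbone reconstruction uses idealized geometry (fixed omega, canonical
  junction angles), so even perfect torsions do not reproduce a deposited
  structure exactly.
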