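---
title: "Methods: simulated localization of focal ventricular ectopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated localization of focal ventricular ectopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`vtloc` implements, at desk scale and on fully synthetic geometry, a combined
physics-and-learning pipeline for localizing focal ventricular ectopic
sources (premature ventricular contractions, focal ventricular tachycardia)
in the left ventricle:

1. **Geometry** — a parametric truncated-ellipsoid LV shell with rule-based
   fibers, universal ventricular coordinates (UVC), AHA 17/68 segment
   models, and deterministic ECG/CIED electrode placements.
2. **Activation** — an anisotropic eikonal model: paced-beat activation
   times are shortest arrival times over the mesh edge graph under an
   elliptical conduction-velocity profile, expanded into transmembrane
   voltage by an action-potential template (a reaction-eikonal surrogate).
3. **Forward model** — an infinite homogeneous-medium lead field turns the
   transmembrane sources into electrode potentials (pseudo-ECG source
   integral), from which the 16 ECG and 16 EGM channels are derived.
4. **Encoding** — per beat, the QRS of each channel is windowed, resampled
   to 16 time points and stacked into a max-abs-normalized 16 x 16 matrix.
5. **Learning** — four small convolutional networks: a Segment classifier
   (17 or 68 AHA classes), a binary endo/epi classifier, a two-output
   (z, rho) regressor, and a 68-wedge phi classifier.
6. **Localization** — either the probability-weighted combination of
   segment centers of gravity (Cartesian scheme), or UVC predictions
   inverted to the nearest mesh node (UVC scheme); scored as Euclidean
   error in millimetres.
7. **Sensitivity** — noise-level and electrode-placement sweeps that
   re-render only the held-out test signals and re-evaluate frozen models.

This vignette documents the model assumptions, the tunable parameters, the
numerical choices, and what the synthetic testbed can and cannot show.

# The synthetic ventricle

The LV is the region between two half-ellipsoids of revolution truncated by
the base plane z = 0. Defaults: epicardial long axis 90 mm, epicardial
short-axis radius 35 mm, wall thickness 10 mm — physiological dimensions, so
millimetre errors are comparable to clinical scales. The mesh is a
structured grid (transmural layers x latitude rings x azimuthal sectors)
cut into tetrahedra by the Kuhn subdivision, which is conformal across the
whole grid including the azimuthal seam. The default target edge length is
2.5 mm (about 18,000 nodes): fine enough that segment models, eikonal
fronts and nearest-node UVC inversion behave smoothly, coarse enough that
the full study (3767 beats, six network trainings) runs on one CPU in
minutes. Resolution is a configuration knob; node count grows as the
inverse cube of the edge length.

Fibers follow a simplified rule: the helix angle rotates linearly across
the wall from +60 degrees (endocardium) to -60 degrees (epicardium), with
the fiber confined to the local wall tangent plane. This captures the
first-order transmural rotation that anisotropic conduction needs, without
the full rule-based construction used on image-derived anatomies.

**Coordinates.** UVC are computed from graph geodesics: z is the normalized
distance between the apex axis (z = 0) and the base plane (z = 1), rho
between endocardium (0) and epicardium (1), and phi is the azimuth about
the long axis with phi = 0 fixed at the configured septal direction (+x).
Anchoring z on the transmural apex axis (rather than the single epicardial
apex point) makes both surfaces reach z = 0, so the apex-cap segment
contains endocardial and epicardial surface patches. Any monotone,
surface-anchored construction would satisfy the same contracts; the
graph-distance form is exact on its anchors and cheap. The phi origin and
orientation are a package convention (documented, configurable through the
septal direction) — displays and wedge labels are self-consistent under any
fixed choice.

**Segments.** The 17-segment AHA model is expressed in UVC: basal
(z in [2/3, 1]) and mid (z in [1/3, 2/3)) rings carry six 60-degree
sectors, the apical ring (z in [z_cap, 1/3)) four 90-degree sectors, and
z < z_cap is the apex cap. The cap boundary z_cap defaults to 0.1 —
standard diagrams do not fix it; 0.1 keeps the cap area similar to the
other apical segments on the default geometry. The 68-segment variant
quarters every segment by halving its z and phi ranges (2 x 2); the cap is
split into four phi quadrants. Quartering axes are not fixed by the
standard either; halving both coordinate ranges is the symmetric choice and
preserves the nesting seg17 = ceiling(seg68 / 4).

# Electrophysiology and signals

Conduction velocities are 0.5455 m/s along and 0.1802 m/s transverse to the
fiber (anisotropy ratio about 3), entering through the edge metric
`L / v(d)`, `v(d)^2 = cv_long^2 (d.f)^2 + cv_trans^2 (1 - (d.f)^2)`.
A graph shortest-path solve was chosen over a PDE fast-marching scheme
because it is exactly testable against an independent Dijkstra oracle; the
price is a small systematic overestimate of continuum travel times (the
front must follow edges), which is part of the forward model that the
networks are trained on, and hence harmless for in-distribution learning.

The action potential is a template: resting -85 mV, linear 1-ms upstroke to
+25 mV, flat plateau to an APD of 300 ms (cycle length 400 ms is carried as
metadata; simulations are single beats). Only the QRS window — bounded by
the latest activation plus the upstroke — is consumed downstream, so the
repolarization shape is irrelevant by construction. On the default
geometry the latest activation over all pacing sites stays below ~290 ms,
inside the plateau.

Electrode potentials use the infinite homogeneous-medium kernel
`Z_e(x) = 1/(4 pi sigma_b |x - x_e|)` with sigma_b = 0.2 S/m and the
pseudo-ECG source integral
`phi_e(t) = sum_el sigma_i grad Vm . grad Z_e vol_el` (sigma_i = 0.1845
S/m, the along-fiber intracellular conductivity used isotropically). The
torso is deliberately absent: a heterogeneous FEM lead field would dominate
the runtime and cannot be validated at desk scale, while the homogeneous
kernel preserves the pipeline topology (precomputed per-electrode weights x
simulated sources) and admits closed-form oracles (dipole potentials,
1/r scaling, superposition). Consequently absolute signal amplitudes differ
from torso-model amplitudes; every learning input is max-abs normalized per
matrix, which removes the global scale (the relative scale between channels
is preserved). Two implementation notes:

* the source integral is assembled once per electrode into per-node
  weights, so a beat's full trace set is two cumulative sums over nodes
  sorted by activation time — algebraically identical to the explicit
  per-element integration (a test asserts equality to rounding);
* spatial uniformity of Vm maps to exactly zero potential because the
  discrete gradient of a constant vanishes element-wise.

ECG channels 1-12 are the standard leads (Wilson central terminal for
V1-V6); channels 13-16 are the literal electrode arithmetic LL-RA-LA,
LA-RA-LL, RA-LA-LL and (RA+LA+LL)/2. The literal reading of these
compound "leads" is a documented convention isolated in one function —
the alternative (augmented-lead constructions) would duplicate existing
channels. EGM channels are the far-field CAN-SVC, CAN-RVcoil, SVC-RVcoil,
near-field RVtip-RVring and LVtip_i-RVtip, plus CAN-LVtip_i and
SVC-LVtip_i: 16 in total.

**Noise.** White Gaussian noise is defined per channel: variance equals the
channel's mean-square power divided by `10^(SNR/10)`. Noise is added to raw
(pre-normalization) matrices, then the matrix is re-normalized. Training
augmentation replaces every training beat by k = 10 independently noised
copies at 25 dB; copies inherit their parent's labels and split, so
augmentation can never leak across the train/test boundary. Held-out beats
are also evaluated at 25 dB (the study's testing protocol); sweeps re-noise
the same held-out beats at 5-30 dB without retraining.

# Networks

All four tasks share one topology: conv 16 filters 3 x 3 -> ReLU -> maxpool
2 x 2 -> conv 32 filters 3 x 3 -> ReLU -> maxpool 2 x 2 -> fully connected
128 -> linear head (layer widths are package defaults, configurable; the
two-conv-two-pool-FC shape and all optimization hyperparameters are fixed:
batch 23, learning rate 0.001, 10 epochs for classification with softmax
cross-entropy, 15 epochs with mean-absolute-error loss for the (z, rho)
regression). The optimizer is plain stochastic gradient descent; weights
use He initialization from a seeded mt19937 stream and epoch shuffling uses
the same stream, so training is bit-reproducible per seed on a fixed
platform. phi is never regressed — its cyclic topology is handled by
classifying 68 equal wedges of 2 pi / 68 (0.09 rad) and returning the
midpoint of the argmax wedge.

Ten-fold cross-validation is available as a reporting option; folds group
augmented copies by parent beat so no beat appears on both sides of a fold.

# Localization

**Cartesian scheme.** The candidate set is the argmax segment plus its
mesh-adjacent segments; segment probabilities are renormalized over that
set and combined with the endo/epi probabilities and the per-segment
surface centers of gravity. The renormalization (not forced by the printed
combination rule, which leaves the restricted weights unnormalized) makes
the estimate a convex combination of the participating CoGs, hence always
inside their convex hull and the myocardial bounding region — the
geometrically sane reading.

**UVC scheme.** Predicted (z, rho) are clipped to [0, 1], phi comes from
the wedge classifier, and the triple is inverted by nearest-node search
under the scaled metric
`w_z dz^2 + w_rho drho^2 + (r_node wrap(dphi))^2` with
`w_z = (long axis)^2` and `w_rho = (wall)^2` — the natural unit
conversions of each coordinate to approximate millimetres. The phi
mismatch is charged its actual arc length at each candidate node's radius
`r_node` rather than a single global radius: near the apex phi is almost
degenerate (a large angular error is a tiny spatial error), and a global
weight would let a misclassified wedge drag apical estimates away from the
correct apex region. The inversion is exact on mesh nodes; on arbitrary
coordinates its error is bounded by the local edge length.

**Scores.** Localization error is the Euclidean distance in millimetres;
classifier accuracy is the percentage of beats assigned their true
segment; per-segment precision is true positives over predicted positives,
reported as missing (not zero) for segments never predicted.

# Problem sizes and determinism

The packaged study conditions are: default mesh (2.5 mm edges), 3767
simulated beats split 2767 train / 1000 test with stratified ~32/36/32
endo/mid/epi sampling, 10-fold augmentation at 25 dB, and the network
settings above. The full reference pipeline runs in roughly 6-10 minutes on
one CPU. The test suite exercises the same code paths on coarser meshes
(8 mm and 4 mm edges) and smaller beat counts so the whole suite stays
within a few minutes; the parameter-recovery checks use the default mesh
with reduced beat counts, which the bounds tolerate.

Every stochastic step (site sampling, splitting, noise, weight init,
shuffling) flows from one integer seed through isolated RNG scopes;
rerunning any driver with the same seed reproduces every reported number
exactly, and each report row carries the configuration hash and seed it
came from.

# What the synthetic testbed shows — and what it does not

The generator emulates: anisotropic wavefront spread from a focal source
through a fibered wall, near-field vs far-field sensing geometry, QRS
morphology variation with source position, measurement noise, and
electrode-placement perturbations. It does not emulate: torso
heterogeneity (lead fields are homogeneous-medium; the
`perturb_leadfield()` hook only scales weights per region and is labelled a
surrogate in reports), the right ventricle and atria, His-Purkinje
activation (total LV activation is therefore slower than a clinical QRS),
ionic-model dynamics beyond the template, scar or re-entry, and
image-derived patient anatomy. Passing tests therefore demonstrate the
internal correctness and learnability of the pipeline under its own forward
model — not clinical accuracy. Numbers obtained here are comparable in
spirit, not in detail, to what patient-specific torso models achieve; that
is the expected behaviour of a scaled-down, self-contained reimplementation.

Known limitations worth noting:

* azimuthal (phi) precision is the binding constraint of the UVC scheme on
  this testbed: the 68-wedge classifier plateaus around 0.3 rad (ECG) to
  0.5 rad (EGM) mean wrapped error under the fixed 10-epoch protocol, which
  translates to several millimetres of arc at mid-wall radii. Substituting
  the true phi drops the scheme error to roughly the mesh edge length, so
  the inversion itself is not the limit. Device electrograms are hit
  hardest — with a homogeneous-medium kernel, an axisymmetric LV and
  per-matrix amplitude normalization, sources at azimuths between the two
  near-field leads produce genuinely similar EGM matrices. The CIED lead
  layout is deliberately asymmetric (anteroseptal RV lead, posterolateral
  LV lead), which breaks the mirror degeneracy a symmetric layout would
  have; parameter recovery is therefore assessed on the ECG modality, and
  EGM-based coordinate localization lands above the segment-scheme errors
  rather than below them as it does on heterogeneous-torso models;
* the transmural coordinate rho is the hardest quantity to regress from
  normalized signals (depth changes signal shape far less than position
  does); its residual error contributes only ~wall/2 millimetres to the
  UVC scheme but dominates the regression MAE;
* the structured mesh crowds nodes near the apex pole; pacing-site
  sampling therefore weights nodes by lumped volume, and apex-adjacent
  tetrahedra are thin (their quality is irrelevant to the edge-graph
  solver but would matter to an FEM solver);
* with only ~16 basal/mid sectors of 60 degrees, segment classification
  near sector boundaries is intrinsically ambiguous under noise — the
  probability-weighted CoG combination absorbs most of that ambiguity.
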