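---
title: "Modelling pHLA-I complexes and scoring peptide foreignness with neoasurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pHLA-I complexes and scoring peptide foreignness with neoasurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoasurf)
```

## The problem

T cells recognize short peptides (7–14 residues) presented in the binding
groove of human leukocyte antigen class I (HLA-I) molecules. Tumour somatic
mutations create mutant peptides (neoantigens) whose usefulness for
immunotherapy depends on how *foreign* they look relative to their wild-type
(WT) counterpart. Sequence identity alone understates that difference: what a
T-cell receptor (TCR) actually contacts is the molecular *surface* of the
peptide–HLA (pHLA) complex, and small substitutions can reshape its exposed
geometry and chemistry substantially.

`neoasurf` implements, at desk scale and on fully synthetic fixtures, the
computational stack needed to study this question:

1. a **structure core**: a pHLA-I data model with PDB I/O, groove-domain
   trimming (HLA residues 1–180) and peptide padding to 16 tokens;
2. **structural metrics**: Kabsch superposition, TM-score, lDDT, pLDDT
   filtering, per-residue peptide–HLA interaction strength, AUROC/AUPRC;
3. **surface features**: solvent-calibrated molecular meshes, principal
   curvatures, shape index, distance-dependent curvature, chemical channels,
   geodesic radial patches rasterized onto polar grids;
4. **groove geometry**: the virtual plane through the C-alpha atoms of HLA
   residues 72/143/159, signed peptide-surface distances, and the strict
   > 4.0 Å *outer surface* (TCR-exposed) selection;
5. a miniature trainable **conformation model** with the exact loss
   composition `L = L_pep + L_pHLA`,
   `L_pep = L_FAPE + 0.3 L_dist + L_angle + L_viol`,
   `L_pHLA = 9.5 L_pHLA-FAPE + 0.5 L_pHLA-dist`;
6. a trainable **foreignness scorer** comparing WT and mutant through three
   blocks (outer-surface features, spatial structure, atom groups) fused into
   a sigmoid score trained with an L2 loss;
7. deterministic **synthetic-fixture generators** that define the study
   conditions for every test.

## Synthetic fixtures: what they emulate, and what they do not

Real pHLA-I structures are not redistributable inside a test suite, so every
numerical claim in this package is made against generated fixtures:

* `make_groove()` builds an idealized 180-residue groove: a backbone-only
  floor slab flanked by two wall ridges, with the three plane-anchor residues
  (author numbers 72, 143, 159; named Gln/Thr/Tyr as in the class I fold)
  placed at exact coordinates so the recovered groove plane is known a
  priori.
* `make_arch_peptide()` reproduces the conformational signature of bound
  peptides: terminal anchor residues low in the groove, central residues
  bulged upward (a parabolic C-alpha arc, default terminal height 1 Å and
  bulge height 6 Å above the groove floor, trans-like 3.8 Å spacing).
  Backbone N/C/O and C-beta are placed from the package's ideal-geometry
  table, so conformers are atom-for-atom comparable with model-realized
  structures.
* `make_pair_corpus()` generates labelled WT/Mut pairs with *controlled
  signal placement* (below).
* `perturb_structure()` applies seeded Gaussian displacements to selected
  peptide regions.

These fixtures capture the geometry the methods depend on — the arch, the
groove plane, exposure thresholds, substitution structure — but none of the
conformational diversity, side-chain packing, water structure or binding
chemistry of real complexes. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as designed under their
stated assumptions; they say nothing about predictive accuracy on
experimental data, which requires the curated corpora and full-scale training
that are out of scope here.

### Controlled signal placement in pair corpora

Each corpus draws random 9-mer WT peptides (glycine excluded, so every
residue carries a C-beta and undisplaced conformers share one surface mesh)
and 1–2 substitutions, then assigns labels as
`Bernoulli(sigmoid(effect_size * true_difference + noise))`. The named
`signal_block` decides what carries `true_difference`:

* **atom_group** — substitutions sit at terminal positions (1, 2, 8, 9) and
  are drawn from charge-neutral residues on both sides. Terminal residues lie
  below the 4.0 Å outer-surface cutoff and are not displaced, and neutral
  substitutions leave the (long-range) electrostatic channel untouched, so
  the surface and structure blocks are blind to the label *by construction*.
  The signal is the mean of a fixed arbitrary per-residue propensity over the
  two exchanged residues — a symmetric function of the unordered residue
  pair, which matches the WT/Mut symmetry of the broadcast comparison maps
  (the product and absolute-difference channels of the atom maps are
  invariant under swapping the two sequences, so only swap-symmetric signals
  are identifiable from them). The propensity values are deliberately not a
  physicochemical scale.
* **surface** — substitutions at central (outer-surface) positions; the
  signal is the Kyte–Doolittle hydropathy shift, visible in the hydropathy
  channel of exposed patches.
* **structure** — a smooth upward displacement of the mutant's central
  residues; the signal is the displacement magnitude, visible in the cross
  spatial distance matrix.

This placement is what makes block-ablation attribution meaningful: ablating
the signal-carrying block must collapse held-out AUROC toward 0.5 while
ablating an uninvolved block must not.

## Surface construction

The mesh backend is an atom-centred Gaussian density
`D(x) = sum_i exp(kappa (1 - |x - a_i|^2 / R_i^2))`, `kappa = 2`,
`R_i = vdW + probe (1.5 Å)`, extracted at isolevel 1 by marching tetrahedra
(each grid cube split into six tetrahedra; no case tables to transcribe, and
the output is manifold by construction). The isolevel calibration makes an
isolated atom mesh exactly a sphere of radius `R_i`, which the tests check
against the analytic area. Triangles are oriented outward against the
analytic density gradient. An isotropic remesher (longest-edge splits,
link-condition-guarded collapses, tangential smoothing, Newton projection
back to the isosurface) brings the median edge length within 25% of the
target resolution (default 1.0 Å).

Principal curvatures come from a least-squares fit of the shape operator to
the *normal field* over the 2-ring (tangential normal differences regressed
on tangential position differences). Unlike quadric height fits, this
estimator is exact on spheres and cylinders when normals are exact, which is
what makes 15%-accuracy curvature recovery attainable at 1.0 Å resolution.
Convexity is positive; the shape index is `(2/pi) atan((k1 + k2)/(k1 - k2))`
with `k1 >= k2` (umbilic points map to `sign(k1)`), so a convex
dome scores +1.

The distance-dependent curvature between a patch centre `i` and member `j`
is `theta(|r_j + n_j - r_i - n_i| - d_ij) |n_j - n_i| / d_ij`, with `theta`
read as the ±1 sign step encoding convex versus concave; parallel normals
give exactly zero.

Chemical channels are scaled to [-1, 1]: Kyte–Doolittle hydropathy of the
residue owning the nearest atom (÷ 4.5); a Coulomb potential with
distance-dependent dielectric `eps(r) = 4r` over bundled formal charges
(Arg/Lys +1, Asp/Glu −1, termini ±1) — an approximation with the correct sign
structure whose replacement by a full Poisson–Boltzmann solver is a single
function hook (`potential_fn`); and a ±1 hydrogen-bond donor/acceptor
proximity with linear falloff over 3.5 Å.

Patches are vertices within 6.0 Å edge-graph geodesic (Dijkstra) distance of
a centre; the in-patch angular coordinate is measured from the projected
direction of maximal curvature (seeded random tangent at umbilic centres),
and grids mean-pool features over 5 radial × 16 angular bins with an
occupancy mask channel.

## The groove plane and the outer surface

The TCR approaches pHLA-I "from the top", so only peptide surface
sufficiently above the groove can matter for recognition. The virtual plane
through the C-alpha atoms of HLA residues 72, 143 and 159 (oriented toward
the peptide centroid) provides the reference; vertices with signed distance
strictly greater than 4.0 Å form the outer surface, and a patch is retained
iff its centre passes. The sign convention means vertices below the groove
plane can never be "exposed", and the boundary value 4.0 Å itself is
excluded.

## The conformation engine

The miniature model is an attention-based network over the peptide sequence,
conditioned on a fixed HLA template (HLA coordinates are inputs, never
predicted):

* one-hot token embeddings plus learned positional embeddings, plus a
  context projection of radial-basis-encoded peptide–HLA distances;
* the **pHLA spatial distance matrix** — representative-atom (C-beta,
  C-alpha for glycine) distances over the concatenated peptide+HLA residues —
  enters three ways: as attention bias on the peptide–peptide block, as
  per-position HLA context, and as bin-resolution radial basis features of
  the two distogram heads. The matrix is *recycled*: each forward pass (and
  each training step) recomputes it from the current peptide estimate,
  treated as a constant input, so the interaction features sharpen as the
  prediction improves;
* `n_blocks` encoder blocks of single-head self-attention plus a two-layer
  feed-forward update;
* heads for backbone coordinate offsets (from a deterministic initial trace
  along the groove's principal axis), seven torsions as (sin, cos) pairs, a
  peptide–peptide and a peptide–HLA distogram (64 bins over [2, 22) Å, the
  last bin catching everything beyond), and a 50-bin pLDDT classification
  head whose expectation is the per-residue confidence.

The distance-feature-to-bin maps of both distogram heads are initialized at
a scaled identity: the radial basis is indexed by the same bins as the
targets, so "predict your own bin" is the natural prior, and plain gradient
descent then only needs to learn corrections. Without this, the
cross-entropy terms dominate the total loss long after the coordinates have
converged.

Training minimizes the exact composition above (plus a small auxiliary
cross-entropy on the pLDDT head against the binned lDDT of the current
prediction, following standard confidence-head practice; the reported
`L_total` contains only the six named terms). FAPE uses clamp 10 Å and scale
10 Å; the loss atoms are the backbone N/CA/C triples, whose frames come from
Gram–Schmidt orthogonalization. The violation loss enforces ideal bond
lengths, bond angles through their 1–3 distances, and a non-bonded clash
floor (vdW sum minus 1.5 Å) with one-sided tolerances; `make_extended_peptide()`
builds a chain that incurs exactly zero violation. The optimizer is plain
gradient descent with momentum behind one integer seed; every gradient in
the package is produced by the bundled reverse-mode autodiff tape and is
checked against central finite differences in the test suite.

Side chains beyond C-beta are realized for output along an idealized
extended topology (correct atom counts and coarse geometry, not
rotamer-accurate) and are excluded from the training losses, whose synthetic
ground truths are backbone+CB fixtures.

### Problem sizes

The overfitting probe — the standard check that a structure-learning
pipeline is differentiable and consistent end to end — trains a d = 16,
single-block model for 500 steps (learning rate 0.03) on one 9-mer bound in
the 180-residue toy groove and asks for a final total loss below 10% of the
initial and a C-alpha RMSD below 0.5 Å. Typical runs land near 0.1 Å.

## The foreignness engine

Three comparison blocks, each ending in a small dense map to a
`block_dim`-vector, are fused by a hidden layer and a sigmoid:

* **outer-surface block** — shared-weight 3×3 grid CNN over the polar patch
  grids of both peptides (circular in the angular axis), mean-pooled into a
  per-peptide descriptor, compared by the **qualinear difference**
  `w [x; y; (x*y) - 1; |x - y|]`. The quadratic term is read as elementwise
  product minus the scalar one; a config switch offers the
  elementwise-inverse reading for sensitivity analysis. The last two parts
  are swap-symmetric, the first two exchange places — asserted algebraically
  in the tests.
* **structure block** — the cross spatial distance matrix between mutant and
  WT residue centroids in the common HLA frame (Kabsch-aligned when the
  templates differ), through the same CNN machinery. Conformational change
  shows up as diagonal asymmetry of this matrix.
* **atom-group block** — both sequences are embedded over a shared residue
  table; the elementwise product and difference are broadcast into
  position × position maps with `B(x)[i, j] = x[i] + x[j]` and the channels
  `B(e_w * e_m)` and `|B(e_w - e_m)|` concatenated. This symmetric
  broadcast-sum is the reading of the broadcasting operation under
  which the difference channels vanish exactly when the sequences are
  identical and, for a single substitution, are supported exactly on the
  substituted row/column band. The atom-group convolution is per-cell
  (1x1): the comparison signal lives within cells, and a wider window would
  give the layer more input dimensions than a desk-scale corpus has examples,
  inviting memorization. The default embedding is the canonical
  one-hot token code: with it, separable functions of the exchanged residue
  identities are linearly exposed to the network after pooling, which is
  what lets small corpora train models that generalize rather than memorize.
  A fixed random dense table is available via config.

Training minimizes the mean squared error between the sigmoid score and the
binary labels (an L2 objective rather than cross-entropy) by full-batch
gradient descent with momentum and L2 weight decay; all block inputs are
precomputed once, and surface geometry is cached across structures sharing
coordinates. Because the flat-curvature L2–sigmoid objective leaves some
weight initializations in a dead basin (the run plateaus with training AUROC
near chance), `pepfore_fit()` applies a standard seeded restart heuristic:
if the training AUROC is below 0.9 at the end (with an early check a third
of the way in), the weights are reinitialized from a derived seed, at most
twice. The decision uses training data only and is deterministic under the
seed. Ablation (`ablate_block()`) replaces a block's output by zeros at
fusion — and skips its feature computation entirely.

The signal-recovery experiment trains on 400 of 500 generated pairs (the
rest held out) for 400 steps at learning rate 0.2, with an atom-group corpus
at a large logistic effect and no label noise; held-out AUROC and the two
block ablations are then evaluated on the untouched 100 pairs, replicated
over three weight seeds.

## Numerical choices and edge cases

* TM-score: the standard `d0(L)` is invalid for L <= 15, so it is floored at
  0.5 Å; the superposition search seeds Kabsch fits from every contiguous
  fragment (length >= 4) plus the global fit, iterates each on its
  well-fitting subset, and polishes with TM-weighted Kabsch refits. The test
  oracle is an independent Nelder–Mead maximization over rigid transforms.
* AUROC uses the Mann–Whitney half-credit convention for ties; AUPRC uses
  step-wise precision–recall integration with tie grouping.
* Interaction strength floors the minimum atom distance at 0.1 Å (capped
  value with a warning on clashed synthetic input).
* pLDDT aggregates as the unweighted mean over peptide residues; the
  self-distillation filter removes only structures strictly below the
  threshold (92), so the boundary is kept.
* Chain-role assignment in PDB files: the longest chain is the HLA heavy
  chain, the 7–16-residue chain nearest in space is the peptide; explicit
  chain-id overrides exist. Altloc conformers reduce to the
  highest-occupancy one (ties by letter); insertion codes are rejected.
* Electrostatics is a clamped Coulomb approximation, not Poisson–Boltzmann;
  the solver hook exists precisely because the default is approximate.
* The umbilic shape-index convention `sign(k1)` and the ±1 step reading of
  the DDC are recorded here because the formulas alone leave both open.

## Known limitations

* Everything is validated on synthetic fixtures; no claim transfers to
  experimental pHLA-I data without retraining and revalidation.
* The conformation model is a miniature: single-head attention, no MSA, no
  rotamer realism; its purpose is to exercise the loss composition, the
  pHLA distance matrix coupling and the training mechanics faithfully.
* The foreignness engine's blocks are deliberately small; their value here is
  the controlled attribution experiments, not absolute accuracy.
* Exact geodesics, full Poisson–Boltzmann electrostatics and HLA class II
  are out of scope.
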