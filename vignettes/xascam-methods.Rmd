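---
title: "Methods: explainable GNN prediction of carbon K-edge XAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable GNN prediction of carbon K-edge XAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and design decisions behind
`xascam` — what each stage assumes, which parameters matter, and what the
synthetic benchmark does and does not demonstrate.

## Spectrum representation

All spectra live on a uniform energy grid covering the carbon K-edge.  The
default grid spans $E_{min} = 270$ eV to $E_{max} = 300$ eV with
$N_{grid} = 100$ points.  Two conventions required a decision:

* **Grid placement.** "100 points between 270 and 300 eV" is ambiguous:
  inclusive endpoints would give a spacing of 30/99 eV, which contradicts
  the spacing definition $\Delta E = (E_{max}-E_{min})/N_{grid}$ used by the
  relative spectral error.  We use *bin centers*,
  $E_i = E_{min} + (i - \tfrac12)\Delta E$, so that $\Delta E = 0.3$ eV holds
  exactly.
* **Broadening width.** Stick spectra are broadened with Gaussians of width
  0.8 eV.  Whether such a width is $\sigma$ or the FWHM is convention-
  dependent; we interpret it as the **FWHM** ($\sigma =
  \mathrm{FWHM}/2.3548$), the more common reading in XAS practice, and keep
  it configurable (`broaden(..., width = )`).
* **Amplitude.** Each stick contributes its oscillator strength as the peak
  *height* (not area) of its Gaussian.  Only relative intensities matter to
  both the error metric and the attribution ranking, so this choice is one
  of convenience; it too is a parameter of `broaden()`.

Prediction quality is the relative spectral error,
$$\mathrm{RSE} = \sqrt{\tfrac{1}{N_{grid}}\textstyle\sum_i (y_i^{tar} -
y_i^{pred})^2} \,\Big/\, \textstyle\sum_i y_i^{tar} \Delta E,$$
the RMSE normalized by the target's total spectral energy.  It is zero iff
the spectra agree, invariant under joint rescaling, and undefined for an
all-zero target (an error, since such a molecule has no carbon edge).

**Peak detection** operates on the *reference* (quantum-chemistry) spectrum,
not the prediction, mirroring how a spectroscopist assigns experimental
peaks.  Local maxima are kept when their topographic prominence exceeds a
fraction (default 0.05) of the global maximum; plateau ties break toward
lower energy.  The FWHM is estimated by linear interpolation of the
half-height crossings, with the grid spacing as a floor so windows are never
degenerate.  A peak's window is the half-open energy interval
$[E_c - \mathrm{FWHM}/2,\ E_c + \mathrm{FWHM}/2)$; the same half-open rule
assigns transitions (sticks) to peaks, so no stick is double-counted by
adjacent peaks.

## Molecular graphs

Graphs are heavy-atom only: hydrogens fold into a per-atom count feature.
Nodes carry an 11-dimensional vector — one-hot element (C, N, O, F), one-hot
hybridization (sp, sp$^2$, sp$^3$, other), one-hot aromaticity, and the
hydrogen count.  Edges carry a one-hot bond order (single, double, triple,
aromatic; amide treated as single) plus the bond length in Å with a
presence flag (0/0 when no geometry is supplied), so models behave
identically with and without coordinates except through that flag.

Parsing and perception (aromaticity, hybridization, implicit hydrogens) are
delegated to Open Babel via `ChemmineOB`; atom order is the heavy-atom order
of the SMILES, which the toolkit preserves, making graph construction
deterministic.  Vocabulary orders are frozen so encodings are bit-stable
across sessions.

## GNN regressors

All three architectures share the head contract that makes CAM exact:

> message-passing layers → node activations $F$ → permutation-invariant
> readout → a *single affine* output layer (no hidden layers after pooling).

* **GCN** — degree-normalized propagation over the adjacency with self
  loops; edge features unused.
* **GraphNet** — full block updates: edges from (edge, endpoints, global),
  nodes from (node, aggregated incoming edges, global), global from
  (global, aggregated nodes, aggregated edges).  The global state gives
  every atom access to molecule-level context; its initial width is a
  config parameter (default 8).
* **GATv2** — per-edge attention logits $a^\top\mathrm{LeakyReLU}(W_l h_t +
  W_r h_s)$ (slope 0.2), softmax-normalized over each target's neighborhood
  including a self loop.  Intermediate layers concatenate heads (widths must
  divide by the head count); the final layer averages full-width heads.
  Heads default to 4 — unstated in the reference protocol, so chosen as the
  common default and kept configurable.

Open design points, decided as follows:

* **Readout:** sum (default).  Sum pooling makes CAM completeness an exact
  identity; mean pooling is available, with CAM scores divided by the atom
  count so completeness still holds.
* **Output activation:** none.  Raw affine outputs can go slightly negative;
  RSE and rank-based AUC tolerate this, and reporting paths offer a
  clamp-at-zero flag.  An output nonlinearity would break the CAM identity.
* **Nonlinearity / regularization:** leaky ReLU (slope 0.01), no dropout,
  seeded Glorot initialization.  AdamW uses decoupled weight decay 0.01.

Forward and reverse passes are written directly in matrix form over batched
graphs (block-diagonal layout).  The gradients of all three architectures
are verified in the test suite against central finite differences.

### Training protocol

The full-scale protocol: AdamW on the mean-squared intensity error (reported
as RMSE), learning rate $10^{-3}$ multiplied by 0.8 every 100 epochs,
batches of 100 graphs, an 80:20 train/validation split, validation every 50
epochs, 1000 epochs, hidden widths 128/256/512.  Model selection keeps the
checkpoint with the best validation RMSE, ties broken by validation RSE.
Validation molecules never contribute gradients.

The package's **desk-scale profile** (`small_profile()`,
`small_train_profile()`) uses hidden widths 32/64, 200 epochs and batches of
25 graphs.  The batch size is deliberately smaller than the full-scale 100:
with a few hundred training molecules, 100-graph batches would give the
optimizer only two or three steps per epoch, leaving it far from
convergence within 200 epochs; 25-graph batches restore a conventional
steps-per-epoch regime while keeping every other hyperparameter at its
full-scale value.  All vignette, example and test runs use a few hundred
synthetic molecules (300 for the end-to-end benchmark), sizes chosen so the
whole suite trains comfortably on one CPU core.

## CAM attribution

For output unit ("class") $c$ and atom $i$,
$\mathrm{CAM}(i, c) = \sum_k \omega^c_k F_k(i)$ with $\omega$ the output
layer's weights.  Properties relied on downstream:

* **Completeness** (sum readout, bias-free output):
  $\sum_i \mathrm{CAM}(i, c) = y^{pred}_c$ exactly — each atom's score *is*
  its additive share of the predicted intensity.
* **Equivariance:** relabeling atoms permutes score rows.
* Negative scores are **kept**: ROC-AUC depends only on rank order, and
  clamping would discard the model's evidence against an atom's
  involvement.  Per-molecule normalization is likewise omitted as
  AUC-irrelevant.

Per peak, scores are summed over the FWHM window's grid columns, giving one
score per atom per peak for comparison with the ground-truth labels.

## Ground-truth labels

A transition record holds an excitation energy, an oscillator strength
$f_s$, core→virtual orbital pairs with weights (normalized per transition),
and per-atom population vectors for each referenced orbital (each summing
to 1; deviations beyond $10^{-6}$ are renormalized with a warning).  For a
peak and channel (core or virtual),
$$w(a) = \sum_{s \in \text{peak}} f_s \sum_{\text{pairs}} w_{pair}\,
\mathrm{pop}_a(\mathrm{MO}),$$
max-normalized, then binarized: atom label 1 iff $w(a) \ge \theta\,
\max_a w(a)$, boundary inclusive.  The threshold is **relative**
($\theta = 0.1$ by default) because a scale-free cut is robust to molecule
size and to the arbitrary normalization of populations; the reference
procedure leaves its cut unstated, so $\theta$ is exposed as a parameter.
Max-normalization also makes labels invariant to a common rescaling of all
oscillator strengths.  The two channels are computed independently:
perturbing virtual populations can never change core labels.

Undefined cases are explicit: a peak whose labels are single-class (all 0 or
all 1) yields `NA` AUC, is excluded from averages, and is counted in the
report rather than imputed — imputing 0.5 would bias model comparisons on
small molecules where all-carbon peaks are common.

## Scoring and robustness

AUC uses the Mann–Whitney formulation with average ranks, i.e. ties earn
half credit — stated explicitly because per-atom score vectors are short and
ties frequent.  The implementation is checked in the tests against exhaustive
pairwise enumeration and against an independent library.

The RSE-decile profile sorts molecules by RSE, splits them into ten
equal-size groups (remainder spread one-per-bin over the first bins) and
averages AUC per group.  Δ-AUC is the percentage change of the mean AUC per
channel between paired reports, e.g. before/after methyl addition.

Perturbations: `add_methyl()` replaces one hydrogen on a uniformly chosen
eligible heavy atom (the site rule is unstated upstream; uniform is the
neutral choice), changing the heavy-atom count by exactly +1 and the
hydrogen count by +2 net.  `distort_coords()` adds i.i.d. zero-mean Gaussian
noise of standard deviation $\sigma$ Å per coordinate — "random distortion
with parameter $\sigma$" is read as Gaussian, the standard model of thermal
geometric noise; RMS per-atom displacement approaches $\sigma\sqrt{3}$.

## The synthetic benchmark

`generate_transitions()` plants a known explanation into every molecule:
each carbon emits 1–3 transitions at an energy determined by its chemical
environment (base 280 eV; +2.0 aromatic, +2.5 per O, +1.5 per N, +3.0 per F
neighbor, +1.0 non-aromatic sp$^2$, +0.5 sp; jitter SD 0.15 eV, intra-group
spread ≤ 0.25 eV), with oscillator strengths log-uniform in [0.01, 0.1].
Core populations put 0.92 on the excited carbon — well above the
$\theta = 0.1$ labeling contrast, so round-trip label recovery is exact on
collision-free peaks — and virtual populations spread equally over the
carbon plus a random subset of its neighbors.  Energy collisions between
different carbons are allowed (they are realistic) but flagged, so
exact-recovery tests can filter to clean peaks.

Each molecule's transition seed derives from the dataset seed and its
SMILES, so a structure's spectrum is deterministic *within a dataset*: the
spectrum is a function of the graph, which is what makes the task learnable
and lets a small GNN beat the constant mean-spectrum predictor on held-out
molecules.

What the generator does **not** emulate: real TDDFT energetics (placements
are chemically plausible trends, not physics), delocalized virtual orbitals
spanning more than a bonded neighborhood, state mixing across carbons, or
basis-set/functional effects.  Passing the synthetic benchmark therefore
demonstrates that the pipeline's bookkeeping, identities and learning
dynamics are correct — not that a given architecture will explain real
spectra equally well.

## Known limitations

* Geometry enters only through bond lengths; angular and through-space
  information is invisible to the models, so coordinate distortions that
  preserve bond lengths are undetectable by construction.
* The SMILES tokenizer behind `add_methyl()` covers the H/C/N/O/F organic
  subset and bracket atoms; exotic SMILES features (isotopes, multi-digit
  ring bonds beyond `%nn`) are untested territory.
* Training is plain R; it is sized for hundreds of molecules, not the
  tens of thousands a GPU stack would handle.  The full-scale configuration
  is preserved in `model_config()`/`train_config()` defaults for ports to
  accelerated backends.
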