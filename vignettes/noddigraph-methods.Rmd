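---
title: "Methods: invariant graph networks for protocol-agnostic microstructure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invariant graph networks for protocol-agnostic microstructure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffusion-weighted MRI probes tissue microstructure by measuring signal
attenuation along many diffusion-encoding directions and strengths. Each
measurement is characterised by a b-value $b_i$ (ms/µm²) and a unit
direction $g_i$, conveniently summarised as a q-space position
$q_i = \sqrt{b_i}\, g_i$, so a voxel's data is an *unordered point cloud*
$\{(q_i, S_i)\}_{i=1}^N$. Biophysical models such as NODDI map
microstructural parameters to signals; inverting them voxel-by-voxel with
nonlinear optimisation is accurate but slow. Learning-based estimators are
fast but typically assume a fixed acquisition protocol (fixed $N$, fixed
shells), and so must be retrained whenever the protocol changes.

`noddigraph` implements an estimator that is *protocol-agnostic by
construction*: a graph neural network over the q-space point cloud whose
inputs are restricted to quantities invariant under rotations, reflections
and permutations of the measurements. A single model trained once on
randomised simulated protocols can then be applied to unseen real-world
acquisition schemes.

## The NODDI forward model

The simulator composes three compartments with fixed diffusivities
$d_\parallel = 1.7$ µm²/ms (intrinsic neurite axial diffusivity) and
$d_{iso} = 3.0$ µm²/ms (free water). These are the standard NODDI
constants; they are configurable through `tissue_constants()` but held
fixed everywhere in this package.

* **Intra-neurite**: sticks (zero radial diffusivity) whose orientations
  $n$ follow a Watson distribution
  $W(n; \mu, \kappa) \propto \exp(\kappa (\mu^\top n)^2)$ with
  concentration $\kappa = 1/\tan(\mathrm{ODI}\cdot\pi/2)$:
  $A_{ic} = \int_{S^2} W(n)\, e^{-b\, d_\parallel (g^\top n)^2}\, dn$.
* **Extra-neurite**: an axially symmetric tensor (zeppelin) with
  tortuosity coupling $d_\perp = d_\parallel(1-\mathrm{NDI})$, dispersed
  by the same Watson distribution through its second moment
  $\langle n n^\top \rangle = \tau_1 \mu\mu^\top +
  \frac{1-\tau_1}{2}(I - \mu\mu^\top)$, where
  $\tau_1 = E[(\mu^\top n)^2]$.
* **Free water**: isotropic diffusion $e^{-b\, d_{iso}}$ weighted by FWF.

$\tau_1$ has the closed form
$1/(2\sqrt{\kappa}\,D(\sqrt{\kappa})) - 1/(2\kappa)$ with $D$ the Dawson
function (computed via `pracma::erfi`); below $\kappa < 10^{-6}$ a Taylor
branch $1/3 + 4\kappa/45$ avoids the $0/0$, and above $\kappa > 625$ an
asymptotic Dawson expansion avoids `erfi` overflow.

### Numerical evaluation of the Watson-stick integral

By rotational symmetry the integral reduces to two dimensions. We use
Gauss–Legendre quadrature with 32 nodes in $t = \cos\theta \in [0,1]$
crossed with a 32-point midpoint rule in $\phi \in [0,\pi]$ (both halved
ranges exploit the antipodal and azimuthal symmetries of the integrand).
The Watson weight is evaluated as $e^{\kappa(t^2-1)}$ so the normaliser
never overflows. This order was fixed once by validation against dense
quadrature (400×400 nodes): across $b \in [0.25, 5]$,
$\mathrm{ODI} \in [0.025, 0.975]$ and all angles the relative error is at
the $10^{-14}$ level, far inside the $10^{-4}$ tolerance we require.
Beyond $\kappa > 2\times 10^4$ (far outside the sampler range, whose ODI
floor of 0.025 maps to $\kappa \approx 25.5$) the density is numerically a
delta and the stick limit $e^{-b d_\parallel (g^\top\mu)^2}$ is returned.

### Noise

Rician noise models magnitude MR data:
$S \mapsto \sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with
$\epsilon_{1,2} \sim N(0, \sigma^2)$ and $\sigma = 1/\mathrm{SNR}$ defined
against the noise-free $b=0$ level. b0 measurements are themselves noised,
so the normaliser used downstream is noisy, as in real data.

## Graph construction

Signals are normalised by the mean of the $b=0$ measurements, b0 points
are dropped, and every remaining point $(q_i, E_i)$ is paired with its
antipode $(-q_i, E_i)$, making $M = 2(N - |\mathcal B_0|)$ nodes
(diffusion is antipodally symmetric, so this encodes a physical fact and
buys exact reflection invariance). Edges come from $k=8$ nearest
neighbours in q-space, symmetrised by union into an undirected neighbour
relation. Node features are $(E_i, b_i)$ only; edge features are
$(\lVert q_i - q_j\rVert,\ |\cos\angle(q_i, q_j)|,\ b_i - b_j)$. Raw
coordinates never enter the network, which is what makes the estimator
O(3)-invariant by construction rather than by augmentation.

Deterministic details chosen here (the formulation leaves them open):

* Nodes are canonically ordered by $(b, x, y, z)$ before k-NN, and
  distance ties break on the smaller node index. Graphs are therefore
  bit-reproducible, and permuting the input measurements yields the
  identical graph.
* The b-value difference keeps its sign; with union-symmetrised directed
  edges both signs occur.
* A node's own mirror may appear among its neighbours; it is not
  excluded.
* $k$ is capped at $M-1$ so tiny voxels (down to one DWI plus one b0)
  still produce valid graphs.
* The printed node-count expression is read as $M = 2(N - |\mathcal
  B_0|)$: b0 points are removed before mirroring.

## Network

Three message-passing layers. Layer 1 messages see the source node's
features and the edge features ($2+3=5$ inputs); later layers see only
the 16-dim source state, since edge geometry is already encoded. Messages
are mean-aggregated over neighbours, and node states updated from
$[x_i; \bar m_i]$. After the last layer, a scalar attention MLP scores
each node, softmax weights (computed with max-subtraction) give a convex
combination $z = \sum_i w_i x_i$ — a fixed-size, permutation-invariant
16-dim embedding — and a small readout maps $z$ to (NDI, ODI, FWF).

Widths: edge MLPs $d_{in}$–64–64–16, node MLPs $d+16$–64–64–16, attention
16–16–1, readout 16–32–3, SiLU on hidden layers, linear final layers.
This gives block parameter counts 5584/6416/6288/7312/6288/7312/289/643
— exactly 40,132 learnable scalars, which doubles as an audit that the
input-dimension reading above is the intended one (layer-1 messages use
the source state only; including $x_i$ as well would break the count).

The readout is unconstrained (no squashing): training uses a plain MSE
loss and estimates may slightly leave $[0,1]$; maps are clipped only at
export. The network core runs in single precision, the convention of the
deep-learning stacks this architecture comes from; graph geometry and the
optimiser state stay in double precision.

### Initialisation

Weights are drawn from $U(-a, a)$ with $a = 1.5\sqrt{3/d_{in}}$ and zero
biases. The gain matters: this is a deep stack (up to 20 linear layers on
the longest path), and SiLU contracts small activations by roughly a
factor 2. With a plain $1/\sqrt{d_{in}}$ fan-in scheme the embedding
collapses to a constant across inputs at initialisation (the
input-dependent part of the activation variance shrinks by orders of
magnitude per layer) and short optimisation runs stall at the
best-constant-predictor loss. The 1.5 gain approximately preserves
input-difference variance through the stack; noticeably larger gains make
the first optimisation steps unstable. The seed is recorded in the model
object.

## Training regime

The training distribution randomises the acquisition: shell count uniform
on $\{2,\dots,5\}$, per-shell b-values $\sim U(0.25, 5)$ ms/µm²,
per-shell direction counts uniform on $\{12,\dots,128\}$ with
hemisphere-uniform directions, one b0 per shell. Microstructure is drawn
from NDI, ODI, FWF $\sim U(0.025, 0.975)$ independently and $\mu$ uniform
on the sphere. The reference regime pairs 10,000 parameter sets with 10
protocols each (100,000 examples), trains 500 epochs with Adam (initial
learning rate $10^{-3}$, ×0.99 every fifth epoch, defaults
$\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$), batch size 10, global
gradient-norm clipping at 1, and groups of 10 successive batches that
share parameter sets under different protocols, with gradients
accumulated across each group before a step — the device that teaches the
network that microstructure, not protocol, determines the target.
Noise-free signals are cached per (parameters, protocol) pair; Rician
noise (SNR $\sim U(10, 40)$ per batch) and measurement dropout (with
probability 0.5 drop a fraction $\sim U(0, 0.5)$ of DWIs; b0s and at
least one DWI always survive) are applied freshly at every presentation,
so the model never sees the same data twice. Dropout is resampled every
presentation, which maximises augmentation diversity; it is applied
before mirroring and graph construction.

### Desk-scale runs

The shipped test-suite and reproduction script run a scaled-down version
of this regime: 160 parameter sets × 4 protocols, batch size 5 (4
batches per accumulation group), 20 epochs — roughly 13,000 voxel
presentations and 640 optimiser steps per model, with the graph network
and the point-set baseline trained under the identical schedule. At this
size the estimator clears the 0.0752 prior-variance floor on an unseen
two-shell protocol while both models train within minutes on one CPU;
the reference regime remains the documented default of
`training_config()`. Desk-scale accuracy sits between the untrained
floor and the converged optimum (estimates visibly shrink toward the
prior mean, the signature of an under-trained regressor): these runs
demonstrate the generalisation machinery, not final accuracy, which
requires the full schedule.

## Baselines

* **Nonlinear least squares**: box-constrained Levenberg–Marquardt
  (`minpack.lm`) on the normalised signals over (NDI, ODI, FWF) and
  spherical angles for $\mu$, initialised from a 2×2×2 grid of scalar
  starts crossed with a moment-based direction start (principal
  eigenvector of $\sum_i (1-E_i) g_i g_i^\top$), best residual kept,
  early exit once a near-zero residual is found. On noise-free data this
  fitter essentially inverts the forward model, which doubles as an
  end-to-end oracle for the simulator. When the fitted free-water
  fraction saturates (> 0.99) the NDI/ODI estimates carry no information
  and the fit is flagged non-identifiable.
* **Point-set network**: a PointNet-style baseline over the same mirrored
  point cloud with per-point features $(q_x, q_y, q_z, E, b)$ — i.e. raw
  coordinates included, so it is *not* rotation-invariant. Input and
  feature transform blocks (T-nets) start as identity maps; batch
  normalisation is omitted. Exact widths are recorded in
  `pointnet_layout()`; they were chosen to land at 3,529,688 parameters
  (~3.5M, two orders of magnitude above the graph network) while keeping
  the per-point encoder economical. ReLU activations with He-uniform
  initialisation.

## Evaluation experiments

* **Accuracy**: a 5×5×5 grid over (NDI, ODI, FWF) ∈ {0.1, …, 0.9} with
  100 noise realisations per point (12,500 voxels per protocol) on three
  fixed protocols — a 303-point Cartesian-grid DSI scheme (b ≤ 5), an
  HCP-style 3-shell scheme (b = 1, 2, 3; 90 directions each) and a
  UKBB-style 2-shell scheme (b = 1, 2; 50 directions each) — at SNR
  30/25/20 respectively. The fibre direction for each test voxel is drawn
  uniformly at random per realisation (the grid fixes only the scalars).
  Errors are reported per parameter and as their mean.
* **Rotation variance**: with noise removed (SNR = ∞), the underlying
  microstructure is rotated by random SO(3) rotations at each grid point
  and the standard deviation of each estimate over rotations is averaged
  over parameters and grid points. Note this is *not* zero even for a
  perfectly invariant estimator: rotating the microstructure under a
  fixed protocol is equivalent to sampling the same microstructure with a
  rotated protocol, so residual variation reflects finite direction
  sampling. Orientation-sensitive architectures add their own variance on
  top, which is the comparison of interest.
* **Embedding structure**: pooled embeddings of 10,000 random-prior
  voxels per protocol, centred PCA, cumulative explained variance. The
  evaluation protocols' direction sets are hemisphere-uniform under fixed
  seeds; real scanner point sets are typically optimised for coverage,
  a discrepancy we accept and note.

### The DSI grid

No radius of the integer lattice yields exactly 303 hemisphere points
(shells through $|n|^2 \le 26$ give 293, the $|n|^2 = 27$ shell adds 16),
so the grid takes lattice points in order of increasing $|n|^2$
(lexicographic within a shell) up to exactly 303, with
$b = 5 |n|^2 / 27$ so the maximum b-value is exactly 5. The cut is
deterministic; only the count and the maximum b-value are externally
constrained.

## What the simulations do and do not show

All training and evaluation data come from the package's own NODDI
simulator. Passing tests therefore demonstrate that the estimator inverts
*this* forward model across unseen protocols, noise levels and
measurement counts — the protocol-generalisation claim. They do not
demonstrate accuracy on real tissue, where the forward model is only an
approximation (real signals deviate from NODDI at high b-values), where
noise can be spatially correlated and non-Rician after preprocessing, and
where direction sets are optimised rather than uniform. Producing maps
from real volumes is supported (`predict_maps()`), but validating them
against histology or reference fits is out of scope here.

## Known limitations

* The NLLS fitter matches the *behaviour* of reference NODDI tooling
  (box-constrained least squares with multi-start), not any specific
  implementation; absolute MSE values of conventional fitting are
  implementation-sensitive.
* Orientation outputs are deliberately absent: the model predicts
  rotation-invariant scalars only, and the fitted $\mu$ from NLLS is
  reported only up to antipodal sign.
* Fixed diffusivities are an assumption of the forward model, not an
  estimate; if a dataset's true diffusivities differ, absolute estimates
  shift.
* Training determinism is exact on a fixed platform (one BLAS, one
  arithmetic order) but not across platforms.
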