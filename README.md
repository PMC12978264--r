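# noddigraph

Protocol-agnostic estimation of NODDI brain-microstructure parameters
from diffusion MRI, using a rotation- and permutation-invariant graph
neural network over q-space point clouds — plus the full simulation,
training, baseline and evaluation machinery around it.

## The problem

Diffusion MRI measures a voxel's signal attenuation under many diffusion
encodings; each measurement lives at a q-space position
$q_i = \sqrt{b_i}\,g_i$ (b-value in ms/µm², unit direction $g_i$).
Biophysical models such as NODDI map three interpretable scalars — the
neurite density index (NDI), orientation dispersion index (ODI) and
free-water fraction (FWF) — to these signals. Conventional voxelwise
nonlinear fitting is accurate but slow; learned estimators are fast but
almost always assume one fixed acquisition protocol and fail or need
retraining when the shell structure, direction count, or b-values change.

`noddigraph` treats a voxel's data as an unordered point cloud
$\{(q_i, S_i)\}$, builds an antipodally mirrored k-nearest-neighbour
graph in q-space, and restricts every feature the network sees to
O(3)- and permutation-invariant quantities: node features $(E_i, b_i)$
(b0-normalised signal and b-value) and edge features
$\big(\lVert q_i - q_j\rVert,\ |\cos\angle(q_i,q_j)|,\ b_i - b_j\big)$.
Three message-passing layers, attention pooling to a 16-dim embedding
$z$, and a small readout produce $(\widehat{NDI}, \widehat{ODI},
\widehat{FWF})$. The model has exactly 40,132 parameters and accepts any
number of measurements, so one model trained on randomised simulated
protocols transfers to unseen acquisition schemes — "train once, deploy
anywhere".

The package also provides:

* the NODDI forward simulator (Watson-dispersed sticks, tortuosity
  zeppelin, free water, Rician noise) with a spherical-quadrature core,
* randomised multi-shell protocol generation and fixed DSI/HCP/UKBB-style
  evaluation protocols, with FSL bval/bvec IO,
* the full training regime (grouped gradient accumulation across
  protocols, per-batch SNR, measurement dropout, Adam with stepped decay)
  implemented in compiled single-precision code with hand-written
  backpropagation,
* two baselines: a box-constrained Levenberg–Marquardt NODDI fitter and a
  ~3.5M-parameter PointNet-style point-set network (permutation- but not
  rotation-invariant),
* evaluation experiments (test-grid MSE tables, rotation-variance probe,
  embedding PCA) and NIfTI parameter-map production,
* a thin CLI (`inst/cli/noddigraph.R`) with `simulate`, `train`,
  `evaluate`, `rotvar`, `embed` and `predict` subcommands.

## Worked example

Train a small model on randomised protocols and apply it to a protocol
family it never saw:

```r
library(noddigraph)

cfg <- training_config(n_voxels = 160, protocols_per_voxel = 4,
                       epochs = 20, batch_size = 5, seed = 421)
ds    <- build_training_set(cfg)       # 640 (parameters, protocol) pairs
model <- train_gnn(gnn_init(421), ds, cfg)
round(tail(model$loss_trace, 3), 4)
#> [1] 0.0522 0.0528 0.0551

# evaluate on an unseen two-shell (UKBB-style) protocol at SNR 20
set.seed(1421)
ts  <- make_test_set(ukbb_protocol(),
                     test_grid_spec(realisations = 8, snr = 20))
rep <- mse_report(predict(model, test_set_voxels(ts)), ts$truth)
rep
#> MSE  total 0.058 | ndi 0.063  odi 0.078  fwf 0.034
prior_variance()   # the best-constant-predictor floor
#> [1] 0.07520833
```

Even this deliberately small run (about six minutes on one CPU; sizes
documented in the methods vignette) sits clearly below the 0.0752
constant-predictor floor on a protocol family absent from training, with
the free-water axis learned fastest — the expected signature of an
under-trained but correctly generalising estimator. Accuracy keeps
improving steadily with scale; the full reference regime
(`training_config()`'s defaults: 10,000 × 10 examples, 500 epochs) is a
long run. A single voxel goes through `gnn_forward()`:

```r
vox <- simulate_voxel(hcp_protocol(),
                      microstructure_params(0.5, 0.4, 0.2, c(1, 1, 1)),
                      snr = 25)
gnn_forward(model, vox)$theta
#>       ndi       odi       fwf
#> 0.6083444 0.4321209 0.3615800
```

and parameter maps come from `predict_maps(dwi, bval, bvec, model, mask)`
for a 4D NIfTI volume with its FSL gradient table.

Because the estimator is invariant by construction, rotating or
reflecting the gradient table, permuting the measurements, or flipping
the sign of any subset of directions leaves its output unchanged (exact
for permutations and sign flips, ~1e-6 for rotations in float32).

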