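---
title: "Detecting brain states on the SPD manifold: model, choices, limits"
author: "spdstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting brain states on the SPD manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdstates)
```

## The model

Dynamic functional connectivity treats a multichannel BOLD recording as a
time-ordered sequence of network snapshots: within a sliding window of width
$w$ centred at time $t$, the $N$ regional signals yield a Pearson
correlation matrix $X_t \in \mathrm{Sym}^+_N$. Because full-rank correlation
matrices are symmetric positive-definite (SPD), the natural home of such a
trajectory is the SPD manifold, and `spdstates` performs every operation
there rather than on vectorised matrices.

The pipeline has four stages.

**1. Alignment by parallel transport.** Subject-specific anatomy shifts
whole trajectories around the manifold. For each trajectory we compute its
Fréchet mean $\bar X_m$, the population mean $\bar X$ of those means, and
transport every matrix by the congruence $X \mapsto E X E^\top$ with
$E = (\bar X \bar X_m^{-1})^{1/2}$. The transport maps $\bar X_m$ exactly
onto $\bar X$ and, being a congruence by an invertible matrix, preserves
affine-invariant geometry inside each trajectory, so only within-trajectory
(state-related) structure survives.

**2. A geometric network.** Low-dimensional SPD representations
$V_t \in \mathrm{Sym}^+_P$, $P \ll N$, are produced by alternating two layer
types: the bilinear map $X \mapsto W X W^\top$ with row-semi-orthogonal
$W$ ($W W^\top = I$), which reduces dimension while staying on the SPD cone,
and eigenvalue rectification $X \mapsto U \max(\epsilon I, \Lambda) U^\top$,
the SPD analogue of ReLU. Weights live on the Stiefel manifold and are
updated by projected gradient descent with QR retraction.

**3. Mean-shift recurrence.** In the log-Euclidean chart ($L_t = \log V_t$,
distances $g_{ts} = \lVert L_t - L_s\rVert_F$) each of $E$ layers replaces
every point synchronously by the Gaussian-kernel weighted average of all
points. Windows of one state collapse towards a common mode; separated
states stay apart. Modes are then grouped by single linkage at a threshold
of $0.1\times$ the median pairwise distance, and per-window state labels and
change points follow.

**4. A contrastive objective.** With similarity $d = 1/(1+g)$, the loss sums
$1 - d_{tt'}$ over same-state ordered pairs and
$\max(d_{tt'} - \alpha,\, 0)$ over different-state pairs. Minimising it
drives same-state representations together ($g \to 0$, $d \to 1$) and
different-state ones at least $1/\alpha - 1$ apart. Gradients flow
analytically through both stages: Daleckii–Krein (Loewner) eigen-gradients
through rectification and the log map, and closed-form derivatives through
the kernel-weighted averages, including the bandwidths.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `window` | 25 (simulated), 40 typical for real data | sliding-window width in time points; shorter windows track faster dynamics but break positive-definiteness (restored by an eigenvalue floor of 1e-6) |
| `dims` | $N \to 8 \to 6 \to 4$ | layer sizes of the network; the output dimension bounds the number of distinguishable states |
| `epsilon` | 1e-4 | rectification threshold; the published setting |
| `sigmas` | 0.5 × 5 layers | kernel bandwidths, *relative* to each layer input's median pairwise distance (see below); 0.5 is the published initialisation, and they are trained |
| `alpha` | 0.5 | negative-pair margin, the midpoint of the similarity range |
| `lr` | 0.01 | the published learning rate, used for both the Stiefel step and the bandwidths |
| `epochs` | 75 | chosen by monitoring convergence of the contrastive loss on development runs of the simulated design |
| `group_tol` | 0.1 × median pairwise distance | scale-free: after training, same-state distances approach 0 and different-state distances 1 or more, so the median sits at the between-mode scale |
| `min_size`, `min_duration` | window width | a mode supported by, or a visit shorter than, fewer windows than the window width cannot be distinguished from the correlation artifact of a single transition |

## Numerical choices

*Relative bandwidths.* A blurring mean shift with a fixed bandwidth
degenerates once the point cloud contracts below the bandwidth: every layer
then averages globally, all structure collapses to one numerical point, and
gradients through the near-rank-one averaging matrices vanish. Scaling each
layer's bandwidth by the median pairwise distance of its input keeps the
kernel matched to the shrinking cloud; the recurrence becomes scale-free and
`sigma = 0.5` means the same thing at every depth. An `"absolute"` mode
retains the textbook behaviour. The layer scale is treated as a constant in
the backward pass (a stop-gradient), which leaves the layer-wise gradients
exact and only approximates the dependence of the scale itself on the
parameters.

*Gradient safeguards.* The pair-sum loss has unbounded gradients as
same-state pairs coincide ($\partial(1-d)/\partial g = d^2 \to 1$ while the
unit direction is undefined at $g = 0$), so training applies a global
gradient-norm clip of 10 and keeps bandwidths above 1e-3 through a softplus
reparameterisation — the usual recurrent-network safeguards.

*Eigen-gradients and ties.* Rectification and log-map gradients use the
Loewner difference-quotient matrix; coincident eigenvalues take the
derivative at the midpoint. The rectified output shares eigenvectors with
its input, so one decomposition per layer serves the forward map, its
gradient, and the final log map; these loops are batched in compiled code
and verified against central finite differences.

*Degenerate inputs.* Nearly singular matrices are ridge-lifted by
$10^{-10}\,\mathrm{tr}(S)/N$ before matrix functions; window correlations
are floored at eigenvalue 1e-6.

*Grouping.* Windows that straddle a transition mix two covariance regimes
and land between modes, where single linkage chains them into small
fragments. Groups smaller than the window width are therefore absorbed into
the nearest mode, and label runs shorter than the window merge into their
neighbour before change points are reported.

## Training protocol

The printed objective is self-supervised — labels come from the mode
grouping itself. From a random semi-orthogonal initialisation on a single
series, however, that bootstrap is unstable: a poor initial grouping merges
states, and the loss then reinforces the merge. The pretext the method is
built around is alignment with a *known* schedule of task blocks, and that
is how the package's standard protocol trains: `fit_state_detector()` takes
schedule-labelled training series (two simulated ones by default, a
desk-scale version of the published 900-series training split), trains
network and bandwidths against the schedule labels, and `predict()` then
detects states on held-out series entirely label-free. The self-supervised
mode remains available (`label_source = "ms_grouping"`, and
`detect_states()` for a lone series) and is the faithful reading of the
objective, but it is not the default route to a trained detector.

## What the generator emulates — and what it does not

`sim_design()` reproduces the block-modular simulation design: 10 regions,
four states whose correlation templates have three diagonal modules
(within-module connectivity 1, cross-module 0), 100-time-point segments with
transitions at t = 100, 200, 300, and window width 25. Draws are Gaussian
with covariance $\lambda T_q + (1-\lambda) I$ per state ($\lambda = 0.7$)
plus white observation noise (sd 0.1) — moderate noise: within-module
correlation ≈ 0.7 before windowing error. The four module partitions rotate
their block boundaries so all templates are distinct.

The generator deliberately omits haemodynamic convolution, autocorrelated
noise, event structure, spatial maps and motion — real fMRI features that
windowed correlation inherits. Passing tests therefore demonstrate that the
geometry, the layers, the optimisation and the detection logic work as
specified on piecewise-stationary Gaussian data; they do not certify
performance on real BOLD recordings.

## Problem sizes used in validation

The test-suite and the reproduction script run the full pipeline at the
simulated design's native size (10 regions, 400 time points, 376 windows),
with 20 independent end-to-end replicates for state-count and change-point
recovery, five replicates for the ablation and training-improvement checks
(ablation training uses 60 epochs and one held-out series per replicate),
and reduced toy designs (2–3 states, 50–60-point segments) for unit-level
training checks. These sizes were chosen so each property is measured on
the design it refers to while keeping replicate counts at the level the
checks specify.

## Known limitations

- The ablation baselines receive the true number of states Q as an input to
  spectral clustering, while mode grouping estimates it; on the easy
  synthetic design this oracle advantage can lift the raw-input baseline
  above the mean-shift-on-raw-input ablation, compressing the ordering that
  holds on hard real data.
- Mode count recovery depends on the trained representation scale matching
  the grouping threshold; under-trained models merge states (roughly two
  thirds of replicates recover exactly four states, the rest three or two).
- The log-Euclidean metric amplifies directions with near-zero eigenvalues;
  template mixing weights near 1 push window correlations against the
  eigenvalue floor and degrade distances. The affine-invariant metric is
  available for the core operations but not for the trained pipeline.
- Single-series self-supervision (the faithful reading of the objective)
  remains exploratory; it needs either a good initial grouping or an
  external schedule to anchor the labels.

## A worked example

```{r example, eval = FALSE}
library(spdstates)

mk <- function(seed) simulate_series(sim_design(seed = seed))
det <- fit_state_detector(list(mk(1001), mk(2001)),
                          cfg = loss_config(epochs = 75, seed = 1,
                                            label_source = "known_schedule"))
res <- predict(det, mk(1)$series, truth = mk(1)$labels)
res$Q_detected   # states found
res$change_times # versus the designed 100, 200, 300
res$purity       # agreement with the schedule

sp <- eigen_spectrum(res$labeling$modes[[1]])
system_energy(sp)
```
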