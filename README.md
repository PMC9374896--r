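# spdstates

Brain-state detection and spectral signatures of dynamic functional
connectivity on the manifold of symmetric positive-definite (SPD) matrices.

## The problem

Sliding-window functional connectivity turns a multichannel BOLD recording
(T time points × N regions) into a trajectory of N×N Pearson correlation
matrices — one SPD matrix per window. Cognitive state changes appear as
shifts of that trajectory on the SPD manifold, but vectorising the matrices
destroys their geometry. `spdstates` is for researchers who want to detect
those state changes, and characterise the detected states, while staying on
the manifold throughout:

- **Alignment** removes between-subject offsets by parallel transport: each
  matrix moves by the congruence `E X Eᵀ`, `E = (X̄ X̄ₘ⁻¹)^{1/2}`, from the
  subject Fréchet mean `X̄ₘ` to the population mean `X̄`.
- **Representation learning** compresses each matrix with a geometric
  network of bilinear layers `X ↦ W X Wᵀ` (semi-orthogonal `W`, trained on
  the Stiefel manifold) and eigenvalue rectification
  `X ↦ U max(εI, Λ) Uᵀ`, producing low-dimensional SPD representations.
- **Detection** runs a mean-shift recurrence in the log-Euclidean chart
  (`g = ‖log A − log B‖_F`): windows of one state collapse to a common mode,
  modes are grouped, and label changes give change points.
- **Training** minimises a contrastive loss on pair similarities
  `d = 1/(1+g)`: same-state pairs pay `1 − d`, different-state pairs pay
  `max(d − α, 0)`, with analytic gradients through every stage.
- **Spectral signatures** describe each state by the eigen-spectrum of its
  mean representation, its system energy `Σλᵢ² = ‖·‖_F²`, subsample
  stability, ±δ eigenmode perturbations, and reconstruction of the
  high-dimensional circuit via the pseudoinverse of the bilinear chain.

A block-modular synthetic generator (10 regions, four states of 100 time
points, transitions at t = 100/200/300, window 25) makes the whole pipeline
testable end to end.

## A worked example

```r
library(spdstates)

mk  <- function(seed) simulate_series(sim_design(seed = seed))
det <- fit_state_detector(list(mk(1001), mk(2001)),
                          cfg = loss_config(epochs = 75, seed = 1,
                                            label_source = "known_schedule"))
res <- predict(det, mk(1)$series, truth = mk(1)$labels)

res$Q_detected
#> [1] 4
res$change_times
#> [1] 100 195 303
res$purity
#> [1] 0.9441489
```

Four states are recovered; the detected transitions sit at window centres
100, 195 and 303 against designed boundaries at 100, 200 and 300 (within
half a window, the best achievable resolution); 94% of windows carry their
state's majority label. State signatures then follow from the modes:

```r
sp <- eigen_spectrum(res$labeling$modes[[1]])
round(sp$values, 3)
#> [1] 1.938 1.214 0.473 0.321
system_energy(sp)
#> [1] 5.55738
```

`run_pipeline()` wraps the same flow (simulate/load → window → align →
train → detect → evaluate → spectra) behind a YAML/JSON config and writes
label tables, change points, a purity report, spectra and a run manifest;
`exec/spdstates` exposes `simulate`, `run` and `spectrum` subcommands for
shell use.

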