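# beamattack

White-box adversarial attacks on deep seizure-detection models that read
**brain electrical activity mappings (BEAMs)** — the topographic images of
per-rhythm EEG power used in quantitative epilepsy work — together with the
full EEG ↔ BEAM transform pipeline those attacks pivot on.

Deep networks diagnosing epilepsy from EEG commonly consume either the raw
multichannel signal or BEAMs. BEAM-based classifiers are attractive
clinically (high spatial resolution, familiar to electroencephalographers),
but the EEG → BEAM conversion is not differentiable, so standard
gradient attacks on the raw signal do not apply directly. This package
implements the two-stage strategy that closes that gap, for robustness
testing of such systems:

1. **Dense attack (gradient perturbation of BEAMs).** A sample
   `E ∈ ℝ^{T×C×S}` (T = 5 one-second slices, C = 22 electrodes, S = 256
   samples at 256 Hz) is decomposed per slice and electrode by a level-8 db1
   wavelet packet transform; the leaves are band-filtered into the four
   rhythms delta/theta/alpha/beta, inverted, Fourier-transformed, and
   summarized as rhythm powers `P(t,b,c) = (1/S) Σᵢ |F(i)|`. Powers are
   interpolated (minimum-curvature / thin-plate spline) onto a 22 × 22 grid
   over the azimuthal-equidistant projection of the electrodes, giving the
   BEAM tensor `ℝ^{T×4×22×22}`. A gradient-sign perturbation
   `η_BEAM = ε·sign(∇_BEAM J(θ, BEAM, y))` (FGSM; I-FGSM/MI-FGSM/PGD are
   pluggable) is sampled back to the electrodes, imposed on the rhythm
   spectra component-wise in proportion to `Re²/(Re²+Im²)`, and the
   adversarial EEG is rebuilt by splicing the perturbed in-band wavelet
   leaves into the raw decomposition.
2. **Sparse attack (differential evolution).** Integer genomes
   `(t, c, v₁..v₄)` encode perturbations of single (slice, electrode) rows
   of the power array; a DE population evolves against the victim's
   confidence (fitness `1 − max_y P(y)`), stopping at the first label flip.
   A *perturbation overflow* rule redistributes any excess over ε to all
   electrodes with the sign pattern of the dense attack, clipped to ±ε.
3. **Dual-target (modified) variant.** An EEG-space gradient attack
   generates the carrier signal; the BEAM perturbation is spliced into it,
   producing samples aggressive to both BEAM-input and EEG-input victims at
   unchanged distortion.

Victim models (four heads × two input families: per-slice ConvNets with
maxpool / temporal-convolution / LSTM / mixed-LSTM aggregation) are
implemented in-package with full input-gradient support (no external deep
learning framework is required), plus training (Adam, cross-entropy),
evaluation metrics (success rate, RMSE distortion `DL_B`/`DL_E`, accuracy),
a Gaussian-noise baseline, a transferability harness, a synthetic
seizure/background EEG generator, a CHB-MIT-style EDF reader and
segmentation rules, and ggplot2 visual comparisons.

## Worked example

```r
library(beamattack)

montage <- build_montage()          # 22-electrode 10-20 set, r = 0.095 m
grid    <- build_grid(montage)      # 22 x 22 topographic grid

train <- generate_dataset(synthetic_config(n_per_class = 80, seed = 1))
test  <- generate_dataset(synthetic_config(n_per_class = 20, seed = 2))

victim <- train_victim(
  build_victim(architecture_spec("maxpool", "beam"), seed = 1),
  list(x = beams_of_samples(train$x, montage, grid), y = train$y),
  train_config(epochs = 8, seed = 1)
)
accuracy(predict_label(victim, beams_of_samples(test$x, montage, grid)),
         as.integer(test$y))
#> [1] 0.925

s <- array(test$x[22, , , ], dim(test$x)[2:4])   # one seizure trial
res <- attack_gpbeam(victim, s, y_true = 2L,
                     perturbation_config("fgsm", epsilon = 0.3),
                     montage, grid)
res
#> <adversarial_result> gpbeam SUCCESS  pred 2 -> 1  DL_B = 0.3  DL_E = 0.00613
```

`DL_B = 0.3` is the RMSE of the BEAM-space perturbation (every element of a
gradient-sign perturbation is ±ε), and `DL_E ≈ 0.006` says the adversarial
EEG deviates from the raw trial by about 0.006 z-units RMS — far
below what an eye (or the victim's owner) would notice — yet the victim now
calls the seizure trial background. `autoplot(res, electrode = "FCZ",
montage = montage)` overlays the two traces; `eval_report()` +
`glance()`/`tidy()` aggregate many attacks into the usual SR/Acc/DL tables,
`gaussian_baseline()` gives the matched random-noise control, and
`attack_gpbeam_de()`, `attack_modified()` and `transfer_eval()` cover the
sparse attack, the dual-target variant and cross-model transfer.
`run_experiment()` drives a whole seeded experiment from one config (also
available from the shell via `inst/cli/beamattack`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic world from the given seed, trains the BEAM-input
maxpool victim from scratch, runs the dense attack across the ε grid
{0.1, 0.3, 0.5}, the σ = 0.5 Gaussian-noise baseline and the sparse DE
attack, and prints the resulting metric tables; the JSON output records the
run.
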