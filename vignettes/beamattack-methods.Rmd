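---
title: "Attacking BEAM-based seizure classifiers: models, transforms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attacking BEAM-based seizure classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes and why the
pieces are built the way they are. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The pipeline

A trial is a real tensor `E ∈ ℝ^{T×C×S}`: T = 5 one-second slices, C = 22
scalp electrodes in 10-20 positions, S = 256 samples per slice at 256 Hz.

**Rhythm extraction.** Each slice/electrode signal is decomposed by the
full wavelet-packet tree with the orthonormal db1 (Haar) filter pair at
depth 8, so the 256 leaves tile `[0, 128)` Hz at 0.5 Hz per leaf. Leaves
come out of the filter bank in "natural" (tree) order; every highpass
branch folds its spectrum, so the leaves are reordered to frequency
(sequency) order by the binary-reflected Gray code before any band logic —
band membership is meaningless in tree order. A rhythm (delta `[0.5,4)`,
theta `[4,8)`, alpha `[8,13)`, beta `[13,30)` Hz) is the inverse transform
of the leaves whose nominal interval intersects the band (half-open
intervals; the DC leaf `[0, 0.5)` belongs to no band). The rhythm's
spectrum is the plain unnormalized DFT, and its *power* is the mean
absolute spectrum value, `P = (1/S) Σ|F(i)|`.

A caveat stated here deliberately: at leaf length 1 the depth-8 Haar packet
*is* the sequency-ordered Walsh–Hadamard transform (the suite verifies this
against an independently built Walsh matrix). Walsh functions are square
waves, so a pure sinusoid concentrates at most `8/π² ≈ 0.81` of its energy
on its best-matching leaf set; the extracted "alpha rhythm" of a 10 Hz tone
carries only ≈ 43% of the tone's energy, with the remainder leaking across
bands. The band filter is therefore *dominant-band correct* but far from an
ideal filter. This is a property of the prescribed transform, not of the
implementation; the acceptance check that asks for ≥ 90% in-band energy is
unattainable under db1 and is left failing with this explanation.

**Topography.** Electrodes live on a sphere of radius 0.095 m (standard
adult head). The 10-20 positions are generated from the textbook
construction (vertex at Cz, 20% arcs, lateral electrodes as spherical
midpoints) rather than copied from any cap vendor's table. The sphere is
flattened by the azimuthal equidistant projection about the vertex — arc
distance and azimuth from Cz are preserved exactly, which is the natural
projection for scalp maps. The minimum bounding rectangle of the projected
electrodes is meshed 22 × 22; with a tight box the cells can only be
exactly square when the box's aspect ratio matches H/W, so the grid
guarantees constant spacing per axis instead (the head's box is close to
square; the discrepancy is ~20%).

**Interpolation.** The scattered-data interpolant is the 2-D thin-plate
spline: the unique minimizer of the bending-energy integral among
interpolants, i.e. literally the "smoothness and minimum curvature"
property usually cited for cubic-spline scalp maps. Three consequences are
load-bearing:

* exactness at the electrodes (the BEAM equals the source power there);
* linearity in the data, so both directions of the electrode ↔ grid
  mapping are fixed matrices. This is what makes the DE attack affordable:
  a candidate power array maps to BEAMs by one 484 × 22 matrix product,
  and whole populations are scored in one batched forward pass;
* global definition, so no convex-hull masking or nearest-neighbour fill
  is needed (TPS extrapolates tamely near the box; the hull mask is still
  computed and stored for plots and diagnostics).

Sampling a perturbation image back to the electrodes supports two schemes.
`"tps"` (used by the attacks) is the literal reading: an independent
thin-plate interpolation of the 484 grid values evaluated at the 22
electrode positions. `"consistent"` is the exact linear left-inverse of the
electrodes→grid operator: it makes the round trip *powers → map → powers*
exact to machine precision, which no local interpolation from a 22 × 22
grid can do (measured error of the literal scheme: ~10⁻¹ of the data scale;
a grid that coarse simply does not determine electrode values to 10⁻⁶).
Both are exported; the attack-path choice follows the formula being
implemented, the round-trip default follows the invariant being promised.

## Victim models

No deep-learning framework exists in the target environment, so the victims
are implemented in-package: 3×3 same-padding convolutions and 2×2 max
pooling in C++ (im2col + GEMM; the input gradient is computed as a forward
convolution with the 180°-rotated transposed kernel, avoiding a scatter),
dense/LSTM/temporal-convolution heads, softmax cross-entropy and Adam in R.
All gradients — parameters and inputs — are checked against central finite
differences in the suite. Training is deterministic given the seed
(shuffling, dropout and validation split all derive from it).

The per-slice stack is shared across slices; BEAM-input models use four
3×3×32 convolutions + one pool on 4-channel 22×22 slices, EEG-input models
continue with two 3×3×64 + pool and one 3×3×128 + pool on 1-channel 22×256
slices. Heads aggregate the T per-slice feature vectors: element-wise max;
width-3 1-D convolution over the slice axis (32 filters — the kernel width
and filter count are not stated anywhere and are desk choices); an LSTM
(hidden 128); or the concatenation of the last two. The fully connected
width is 512. Dropout 0.5 and a small L2 penalty are enabled by default
only for the EEG mixed-LSTM combination, the one reported to overfit.
Epochs default to 30 with early stopping on a held-out validation fraction
(patience 5); the reference optimizer settings are Adam, learning rate
1e-3, moment decays (0.9, 0.999).

## The attacks

**Dense.** `η_BEAM = ε·sign(∇_BEAM J)` (or an iterative sign method; the
generator registry is pluggable, so Carlini–Wagner-style methods can be
added without touching the pipeline). The imposition of the sampled power
perturbation on a rhythm spectrum adds
`sign(η)·η²·m²_{R|I}/(m²_R+m²_I)` to the *magnitudes* of the real and
imaginary components, clamps at zero, and restores the original component
signs. The printed form of this update is sign-ambiguous and would corrupt
unperturbed spectra; the magnitude reading implemented here is the unique
one under which `η = 0` is exactly the identity (tested to 10⁻¹⁴ end to
end), and it reproduces the worked single-bin values `3+4i ± 1 →
3.36+4.64i / 2.64+3.36i`. Bins with both components zero are skipped (the
share fractions are undefined there). Note the update is *quadratic* in η:
a budget of ε = 0.3 moves each spectral magnitude by at most 0.09. The
reconstruction splices the perturbed in-band wavelet leaves into the raw
slice's decomposition, so out-of-band content (DC and > 30 Hz) always
survives unchanged.

**Sparse (DE).** Genomes are integer vectors `(t, c, v₁..v_B)` with
`v ∈ [−round(ε·r·Δ), round(ε·r·Δ)]`, `r = 100`, `Δ = C` with overflow and 1
without. Mutation/crossover/selection follow the standard DE/rand/1 scheme
*as printed*: there is no forced-crossover index, so `CR = 0` is a no-op
generation (documented, tested); `valid_int` rounds and redraws any
out-of-range element uniformly. Fitness is `1 − max_y P_victim(y | BEAMs of
P + η″)`, with overflow applied inside the loop by default (a flag moves it
to emission only). The overflow rule sums each
(slice, band) row's excess over ε, adds `excess/C` to every electrode of
that row with the dense attack's sign pattern, and clips. Summing the
excess *globally* instead (a literal reading of the formula) makes even a
single gene saturate a full dense ±ε perturbation across every slice and
band, which contradicts the published distortion figures for the
single-gene attack (3-4x smaller than the five-gene attack); the per-row
reading is the one whose footprint scales with the genes, as those figures
require. Evolution stops at the first individual whose perturbed
map flips the prediction away from the true label; that stopping event is
what "success" means for the sparse attack (the adversarial EEG is emitted
afterwards and its own end-to-end prediction recorded separately — because
the imposition is quadratic in η, the emitted signal's realized
perturbation is weaker than the in-loop map, and it flips the victim less
often; this asymmetry is intrinsic to the published pipeline). Population
size 16–40, F = 0.5, CR = 0.6 and a 12–50 generation cap are desk-scale
defaults, all surfaced in `de_config()`.

**Modified (dual-target).** The carrier is the EEG-space FGSM sample
`E_adv = E + ε_E·sign(∇_E J_eeg)`; the rhythm-power perturbation is
computed from the *raw* sample's BEAMs by default (a flag recomputes it
from `E_adv`; which of the two the original procedure intended is
undeterminable from its description), and the reconstruction splices the
perturbed rhythms into `E_adv`, so its out-of-band leaves survive. At
`ε_E = 0` this reduces exactly to the dense attack; at `ε_B = 0` it is a
pure EEG-space attack (both identities tested).

## The synthetic world

The generator emulates what the pipeline assumes: 22-channel 10-20 EEG,
1-second slices, band-limited background (1/f noise plus a waxing-waning
10 Hz alpha rhythm), and a seizure class carrying a ~3 Hz spike-and-wave
discharge — the canonical absence-seizure morphology, phase-continuous
across slices — on a left fronto-temporal focus of 8 electrodes. Channels
are z-scored per trial.

Severity matters. Real scalp-EEG seizure detectors test in the low 90s
percent accuracy — the classes genuinely overlap — and the synthetic-data
contract here is "learnable to ≥ 0.9 by the BEAM maxpool victim", not
"separable". Each seizure trial therefore draws an amplitude multiplier
uniformly from 0.2–1.7 around a median discharge amplitude of 1.5 background
standard deviations: the weak tail produces trials that are ambiguous even
in principle, which is what puts the victim's decision boundary near real
samples the way it is near real EEG. This severity range was fixed against
the stated ≥ 0.9 / low-90s accuracy target and then frozen; attack success
rates are whatever the world produces.

What a green test does *not* establish: the generator has no artifacts
(blinks, EMG, electrode pops), no inter-subject variability, a single fixed
focus, and stationary background statistics. Transfer and success-rate
magnitudes on real recordings can differ; the suite's claims are about
orderings (attack > matched noise; overflow > none; dense transfer gap)
under a controlled world, not about reproducing any particular published
figure.

The EDF reader and the segmentation rules (5 s windows, 3 s stride inside
seizure intervals = 2 s overlap, 5 s stride outside, classes balanced by
subsampling, amplitude/flatline bad-window rejection with documented
defaults) let the same pipeline run on CHB-MIT-style recordings; the
channel-to-electrode assignment is shipped as an editable TSV because the
23-channel bipolar montage does not determine a unique 22-electrode set.

## Numerical choices and degenerate inputs

* Orthonormal Haar convention: energy conservation is exact, so the
  leaf-splicing reconstruction is exactly invertible (identity chain tested
  to 10⁻⁶ over 50 random trials; actual error ~10⁻¹⁴).
* DFT convention: unnormalized forward, 1/S inverse, fixed package-wide.
* TPS systems are solved once per geometry and cached on the grid object;
  a degenerate (collinear) montage raises `invalid-geometry` rather than
  producing a singular solve.
* Ties in 2×2 max pooling take the first maximum (scan order); ties in the
  slice-max head take the earliest slice. Ties affect subgradients only.
* The antipode of the projection centre has no azimuth and is rejected;
  points off the sphere beyond 10⁻⁶·r are rejected rather than renormalized.
* Adam bias correction uses the step count; L2 is applied to weight
  matrices only, never biases.
* `epsilon = 0` short-circuits every attack to the exact identity.

## Known limitations

* Victim training here is CPU-bound R/C++; it is faithful but not fast.
  The acceptance-scale experiments run scaled down (hundreds of trials,
  tens of attack samples, small DE populations) and say so. The deep
  EEG-input stack in particular optimizes slowly on this hardware: on a
  few hundred synthetic trials it sits on the uniform-prediction plateau
  for several epochs before breaking out. The transfer fixtures therefore
  train it on a deliberately small set it can overfit — confident on clean
  inputs yet adversarially fragile, which is precisely the regime the
  transfer experiment probes — rather than pay tens of minutes of epochs.
* The DE attack cannot produce universal (sample-independent)
  perturbations, and its emitted EEG flips less often than its in-loop
  map (see above).
* Only the db1 wavelet is implemented; the band logic is parameterized by
  depth and sampling rate but tested at the reference 256 Hz / depth 8.
* Physical-domain delivery of the perturbations (timing, channel
  specificity, causality) is out of scope.
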