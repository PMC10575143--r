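---
title: "Seizure detection with VMD features and grey wolf channel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure detection with VMD features and grey wolf channel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Epileptic seizures appear in scalp EEG as organised rhythmic discharges —
classically 3 Hz spike-and-wave complexes, with a sharp biphasic transient
of roughly 20–70 ms riding on a slower wave — that replace the
desynchronised background of the interictal state. `vmdseiz` implements a
detection pipeline that turns multichannel recordings into a per-epoch
classification: preprocess, cut 2-s epochs, decompose each channel into
band-limited modes, summarise each mode by two complementary statistics,
select a small channel subset, and cross-validate an SVM.

### Variational mode decomposition

Each channel of each epoch is decomposed into `K` modes `p_z` with center
frequencies `ω_z` by minimising the summed bandwidths of the analytic,
demodulated modes subject to `Σ_z p_z = f`. The augmented Lagrangian is
solved by ADMM, entirely pointwise in the frequency domain:

* mode update — a Wiener filter centred on the current `ω_z`:
  `p̂_z ← (f̂ − Σ_{i≠z} p̂_i + λ̂/2) / (1 + α (ω − ω_z)²)`;
* frequency update — the spectral centroid of `|p̂_z|²` over `ω ≥ 0`;
* multiplier update — dual ascent `λ̂ ← λ̂ + τ (f̂ − Σ_z p̂_z)`.

Iteration stops when `Σ_z ‖p̂_z^{t+1} − p̂_z^t‖² / ‖p̂_z^t‖² < tol`.
Modes are returned sorted by ascending center frequency so feature
positions are stable.

**Assumptions.** The signal is real, finite and quasi-stationary over the
2-s epoch; its information content is a small number of compact spectral
lobes. Broadband noise *between* mode lobes is deliberately not modelled
— with `τ = 0` it simply remains in the residual.

### Features

**Differential entropy (DE).** For a Gaussian band-limited signal the
differential entropy is `½ ln(2πe σ²)`. Per 1-s non-overlapping Hamming
window, band power `σ̂²` is integrated from the periodogram over the five
canonical EEG bands (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–50 Hz), converted to DE, and averaged over bands then windows. DE is
offset-invariant (window means are removed) and exactly equivariant under
amplitude scaling: doubling the amplitude adds `ln 2`.

**Higuchi fractal dimension (HFD).** For each delay `k ≤ k_max` the
normalised curve length `L(k) = (1/k) Σ_w L_w(k)` of the `k`
delay-decimated subsequences is computed; the dimension is the negative
slope of `ln L(k)` on `ln k`. Smooth curves give 1, space-filling noise
gives 2, fractional Brownian motion with Hurst exponent `H` gives
`2 − H`.

DE is computed per mode (the feature set is "DE and HFD *of each
mode*"); a configuration switch `de_source = "raw"` computes DE from the
raw channel signal instead, for comparison.

### Channel selection

A binary grey wolf optimizer treats each channel subset as a wolf.
Continuous positions in `[0, 1]^d` move toward the three fittest wolves
(α, β, δ) under the canonical updates `I_i = X_i − A·|C·X_i − X|` with
`A = 2a·r − a`, `C = 2r` and `a` decaying linearly 2 → 0; the averaged
candidate `(I_1 + I_2 + I_3)/3` is mapped to bits through the steep
logistic `S(x) = 1/(1 + e^{−10(x − 0.5)})` compared against per-dimension
uniform draws. Fitness is stratified-CV accuracy of a KNN classifier on
the masked channels (z-scored on each training fold only), minus
`w · |mask|/d`. The best-ever mask is tracked elitistically, so the
fitness history is non-decreasing by construction.

### Classification and metrics

The soft-margin SVM dual — a box-constrained convex QP — is solved with
`quadprog`; no dedicated SVM backend exists in this dependency set, and
the dual is small (≤ 200 samples per training fold). Folds are stratified
by class; standardisation is fit on each training fold only. Reported:
pooled accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`
(positive class = ictal, label 1), and AUC as the mean over folds of the
rank-based (Mann–Whitney) statistic of the decision scores, with half
credit for ties. Ratios with an empty class are `NA`, never zero.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| band | 1–60 | Hz | most scalp-EEG information; spikes preserved by zero-phase filtering |
| notch_hz | 60 | Hz | North-American mains (CHB-MIT); set 50 for European data, `NULL` to skip |
| window_s | 2 | s | one epoch = one classified sample |
| K | 6 | modes | balance of resolution vs cost for 512-sample epochs |
| alpha | 2000 | – | standard literature value; larger → narrower modes |
| tau | 0 | – | no dual ascent: robust when epochs contain noise |
| tol / max_iter | 1e-6 / 500 | – | convergence is typically < 100 iterations |
| init | uniform | – | deterministic; `random` is seeded |
| k_max | 8 | samples | keeps ≥ 64 points in the fastest subsequence of 512 samples |
| pack_size / n_iter | 10 / 30 | – | desk-scale wrapper search (≤ 300 fitness evaluations) |
| knn_k / fitness_folds | 5 / 5 | – | common wrapper settings |
| cardinality_weight | 0.01 | – | gentle pressure toward small subsets |
| target_channels | 5 | channels | the pipeline's output contract |
| kernel / C / gamma | rbf / 1 / scale | – | standard nonlinear default; linear kernel available |
| n_folds | 10 | – | the evaluation protocol |

One `master_seed` derives all stage seeds by hashing
(`stage_seed(master, name)`), so a full run is reproducible from one
integer while stages consume independent streams.

## The synthetic world

`make_dataset()` emulates the experimental layout: 8 channels at 256 Hz,
100 interictal + 100 ictal 2-s epochs, 5 informative channels.

* **Interictal** (all channels): `0.35·σ` pink (1/f) noise under an
  organised rhythmic background — 2.2 Hz delta, dominant 10 Hz alpha,
  weak 19 Hz beta, random phases per epoch (`σ` = `noise_sd` = 20 µV).
* **Ictal** (informative channels): a 3 Hz spike-and-wave train
  (biphasic ~50 ms transient + half-sine slow wave, amplitude
  `0.3·ictal_effect·σ`), suppressed pink residual (`0.15·σ`) and
  broadband white noise (`0.45·σ`). Non-informative channels are
  identically distributed across classes.

**Calibration.** The binding contract is the planted contrast at the
*feature* level: on informative channels, mean per-mode DE is lower and
mean HFD higher in the ictal class (rank-sum p ≪ 0.01 on the default
world), and the contrast is absent on non-informative channels. A purely
stochastic interictal background (pink noise + alpha alone) cannot plant
this: VMD modes of pink noise are themselves band-limited noise, so
interictal HFD comes out high and the HFD direction inverts. The
rhythmic background is what makes interictal modes smooth; it is also
closer to resting EEG, which is rhythm-dominated rather than white.

`ictal_fraction` (default 1) is the probability that an informative
channel expresses the ictal pattern in a given ictal epoch. At the
default, a single informative channel can saturate classifier accuracy,
which makes the *identity* of a planted channel pair undecidable — any
superset ties. Recovery tests therefore use `ictal_fraction = 0.7`
(modelling spatial variability of seizure spread), where the planted
pair is strictly fitter than any single channel or impostor pair.

**What a green test does not establish.** The generator contains no
ocular or muscle artifacts, no electrode drift, no inter-subject
variability, and its rhythms are phase-random sinusoids rather than
neural-mass dynamics. Passing the planted-truth tests validates the
pipeline's mechanics — decomposition, feature directions, subset search,
leakage-free evaluation — not clinical performance. The headline numbers
reported on the CHB-MIT corpus require that external download and are
out of scope here.

## Numerical choices

* **Boundary handling.** Signals are mirror-extended by half their
  length on each side before the transform and cropped after inversion,
  suppressing edge ringing; updates operate on the one-sided spectrum
  with Hermitian symmetry enforced on inversion.
* **Penalty convention.** The Wiener denominator is
  `1 + α (ω − ω_z)²`, the convention of the reference VMD
  implementations, under which the default `α = 2000` has its usual
  literature meaning. (A variant with an extra factor 2 circulates in
  print; it silently doubles the effective penalty.)
* **Reconstruction check.** With `τ = 0`, `Σ_z p_z` reproduces
  band-passed *background* epochs within 5% relative L2 on the interior
  90% of samples. Ictal epochs deliberately contain broadband noise
  between mode lobes, which no `τ = 0` decomposition can absorb; they
  are not a reconstruction fixture.
* **DE estimators.** The per-epoch feature averages per-window log band
  powers (short-time definition). For oracle comparisons the package
  also exposes `de_bands()`, which averages band power across windows
  before one log — the consistent per-band estimator; the per-window
  variant carries a small-sample log bias (up to ~0.13 nat in the
  3-bin delta band) that is constant across epochs and therefore
  harmless as a feature.
* **Degenerate inputs.** Zero-power bands are skipped with a warning
  (all-silent is an error); constant series make the Higuchi curve
  length degenerate and raise an error; HFD estimates are clamped to
  `[1, 2]` with a warning beyond 0.05; the empty channel mask scores
  fitness 0 by convention; `B_z = 0` when `U_z = 0` (limit convention).
* **Tie-breaks.** Binary KNN with odd `k` cannot tie; `which.max` in
  the final mask coercion resolves exact fitness ties toward the
  lowest channel index, deterministically.
* **Exact-size coercion.** The optimizer's best mask is reduced to the
  target size by backward elimination (drop the channel whose removal
  costs least fitness) or grown by greedy addition — the output
  contract fixes the subset size, not the search mechanism.

## Limitations

* Per-channel, per-epoch VMD ignores cross-channel structure; montage
  re-referencing and artifact removal are out of scope.
* The wrapper fitness evaluates subsets on the same data later used for
  cross-validation, matching the original protocol; a fully nested
  evaluation would cost another fold level and is left to the user.
* `quadprog` solves the dense dual, practical to a few thousand samples
  per fold but not beyond.
* The Davies–Harte fBm generator clips (rare, tiny) negative embedding
  eigenvalues; the Hurst exponent is exact only within the tested ±0.1.
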