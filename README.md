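# vmdseiz

Seizure detection from multichannel scalp EEG: variational mode
decomposition (VMD) features, binary grey wolf channel selection, and SVM
classification with stratified cross-validation.

The package is aimed at biomedical-signal researchers who want a tested,
reproducible implementation of this detection pipeline — including a
calibrated synthetic EEG generator with planted informative channels, so
every stage can be validated without access to clinical recordings.

## The method

EEG recordings (EDF, e.g. CHB-MIT-style 23-channel, 256 Hz scalp data) are
band-pass filtered to 1–60 Hz with a power-line notch, and cut into
non-overlapping labelled 2-s epochs (interictal = 0, ictal = 1). Each
channel of each epoch is decomposed into K band-limited modes by VMD,
which minimises the summed bandwidths of the analytic, demodulated modes
subject to reconstruction; the saddle point of the augmented Lagrangian

L(p_z, ω_z, λ) = α Σ_z ‖∂_t[(δ(t) + j/πt) * p_z(t)] e^{−jω_z t}‖²
               + ‖f − Σ_z p_z‖² + ⟨λ, f − Σ_z p_z⟩

is found by ADMM in the frequency domain: Wiener-filter mode updates,
spectral-centroid updates of the center frequencies ω_z, and dual ascent
on the reconstruction constraint.

Two features are computed per mode:

* **Differential entropy (DE)** — treating band content as Gaussian,
  DE = ½ ln(2πe σ̂²) per canonical EEG band (δ, θ, α, β, γ) from 1-s
  Hamming-window band powers, averaged over bands and windows.
* **Higuchi fractal dimension (HFD)** — the negative slope of
  ln L(k) vs ln k, where L(k) is the mean normalised curve length of the
  k delay-decimated subsequences.

A binary grey wolf optimizer (BGWO) searches channel subsets: continuous
wolf positions are driven toward the three fittest wolves and mapped to
binary masks through the steep transfer S(x) = 1/(1 + e^{−10(x−0.5)})
against uniform draws; fitness is stratified-CV KNN accuracy on the masked
channels minus a small cardinality penalty. The selected channels (5 by
default) feed a soft-margin SVM evaluated by stratified 10-fold
cross-validation, reporting accuracy, sensitivity TP/(TP+FN), specificity
TN/(TN+FP), and rank-based AUC.

## Worked example

```r
library(vmdseiz)

spec <- synthetic_spec()                 # 8 channels, 5 informative,
                                         # 100 + 100 2-s epochs @ 256 Hz
res  <- run_pipeline(spec, pipeline_config(master_seed = 7))
#> [vmdseiz] simulate   200 epochs, 8 channels
#> [vmdseiz] features   200 x 96 matrix
#> [vmdseiz] select     channels {1,2,3,4,5}, fitness 0.994
#> [vmdseiz] classify   accuracy 1.000, sensitivity 1.000, specificity 1.000, AUC 1.000

res$selection$channels
#> [1] 1 2 3 4 5
res$report$accuracy
#> [1] 1
```

The generator plants the ictal signature (3 Hz spike-and-wave plus
broadband noise) on channels 1–5 only; the run above recovers exactly
those channels and classifies the held-out epochs perfectly. With
`synthetic_spec(informative_channels = integer(0))` the two classes are
identically distributed and accuracy drops to chance.

Lower-level entry points: `read_edf()` / `preprocess()` / `segment()`,
`vmd_decompose()` / `energy_entropy()`, `differential_entropy()` /
`higuchi_fd()` / `extract_features()`, `bgwo_select()` / `knn_fitness()`,
`train_svm()` / `cross_validate()` / `compute_metrics()`. A thin CLI with
subcommands `simulate | decompose | features | select | classify | run`
lives in `exec/vmdseiz`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline's main result from scratch: it simulates the
default synthetic world under the given seed, runs feature extraction,
BGWO channel selection and 10-fold SVM cross-validation, prints the pooled
metrics and selected channels, and writes the results JSON.

## Vignette

`vignettes/seizure-detection.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical choices and
known limitations.
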