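---
title: "Detecting internal produce defects from Vis/NIR and SWIR spectra"
author: "SpectraVote authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal produce defects from Vis/NIR and SWIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Internal defects of tubers and fruit (hollow heart, brown rot, black
heart) show no external symptoms, yet they alter how the tissue interacts
with light at specific wavelengths. A reflectance spectrometer covering
the visible/near-infrared (Vis/NIR, 350–1100 nm) and short-wavelength
infrared (SWIR, 1100–2500 nm) ranges therefore offers a non-destructive
route to sorting: measure the external reflectance spectrum, and decide
healthy/defective from it. Practical grading lines cannot afford
full-spectrum instruments, so the central methodological questions are
(i) which few wavelengths carry the defect signal, and (ii) how to
combine several imperfect classifiers into a reliable decision.

`SpectraVote` implements that complete workflow: spectral preprocessing,
wrapper-based *effective wavelength* selection driven by a cultural
algorithm (ANN-CA), two neural classifiers whose architectures are tuned
by metaheuristics (ANN-ICA using the imperialist competitive algorithm,
ANN-HS using harmony search), k-nearest neighbours and stepwise linear
discriminant analysis, a four-member majority-voting (MV) ensemble, and a
repeated stratified-split evaluation harness with pooled confusion
matrices, per-class metrics, ROC/AUC, and a paired t-test comparing
effective-wavelength against full-spectrum classification.

## Data model and preprocessing

Spectra live in a `SpectralSet`, an S4 class extending
`SummarizedExperiment`: wavelengths are rows, samples are columns, the
binary label (healthy = 0, defective = 1) sits in `colData`, and a
metadata tag records whether values are reflectance or absorbance.

Preprocessing applies, in a fixed order:

1. **Absorbance conversion** $A = \log_{10}(1/R)$ — linearises
   concentration-like effects and damps multiplicative illumination
   differences (a multiplicative reflectance factor becomes an additive
   absorbance constant).
2. **Detrending** — a per-sample least-squares polynomial in wavelength
   (default order 2) is subtracted, removing baseline offset, slope and
   curvature caused by light scattering. Order 2 is the package default
   because it exactly cancels the additive constant left by multiplicative
   scatter and the low-order drift the generator emulates; it is
   configurable.
3. **Median smoothing** — a per-sample sliding median (default window 5)
   with symmetric (edge-reflecting) padding. The median filter removes
   isolated spikes without smearing band edges; symmetric padding avoids
   the artificial step a zero-padded filter would create at the spectrum
   ends.

The spectrum is then split at 1100 nm into Vis/NIR ([350, 1100) nm) and
SWIR ([1100, 2500] nm); the boundary wavelength belongs to SWIR only, so
no column is duplicated.

## The synthetic study conditions

The reference potato dataset is not public, so the package ships a seeded
generator (`generatorConfig()`, `generateDataset()`) whose *defaults are
the study conditions* used by all end-to-end tests: 120 healthy and 120
defective samples on a 350–2500 nm grid at 1 nm (2151 points).

Each class-mean curve is a smooth mixture of 8 broad Gaussian peaks
(sd 120 nm, heights U(0.05, 0.15)) on a reflectance floor of 0.25; the
defective class additionally loses reflectance in six narrow Gaussian
*defect bands* (sd 10 nm) centred at 861, 883, 998 nm (Vis/NIR, depth
0.010) and 1539, 1858, 1896 nm (SWIR, depth 0.020 — twice the Vis/NIR
depth, so the SWIR region is the more separable one). Per-sample nuisance
terms are multiplicative scatter (sd 0.05), an order-2 polynomial
baseline (coefficient sd 0.005) and additive per-point noise (sd 0.015);
values are clipped to (10^-4, 1] so the log transform is always finite.
One master seed fans out to per-sample counter-indexed streams, so the
same configuration is bit-identical regardless of how many samples are
drawn.

Why these numbers: the band width matches the ±10 nm localisation the
selection stage is expected to achieve (a recovered wavelength within one
band width of the centre); the band depths and noise were chosen so that,
after preprocessing, a single band separates the classes by only 1–2
pooled standard deviations — every band is then genuinely needed, the
wrapper objective decreases strictly with each additional true band, and
the resulting ensemble accuracies (high 90s SWIR, low 80s Vis/NIR on
selected triples) sit in the regime the method targets rather than
saturating at 100%. The baseline-drift amplitude is kept small because a
larger drift survives order-2 detrending as smooth correlated noise, and
then an off-band *reference wavelength* (which lets a classifier cancel
that correlated noise) becomes as valuable as a true defect band — a real
chemometric phenomenon, but one that would make the planted centres no
longer the ground truth the recovery tests rely on.

What the generator does *not* emulate: detector-junction artifacts,
wavelength-dependent instrument noise, biological covariates (size,
cultivar, storage time), or multiple defect types with distinct spectral
signatures. Passing tests on this generator therefore demonstrate that
the pipeline recovers planted structure under realistic noise — not that
it would reach any particular accuracy on real produce.

`bayesOracleCCR()` supplies a matched-filter reference classifier derived
from the generating model itself; it is used to verify label symmetry
(50% CCR at zero band depth) and monotonicity of difficulty.

## Metaheuristics

`caOptimize`, `icaOptimize` and `hsOptimize` are generic minimizers over
mixed integer/real/categorical spaces (`searchSpace()`), operating on a
unit-hypercube genotype with reflection at the bounds; integer dimensions
decode by flooring, categorical ones by level index, mutation of
categorical dimensions is uniform resampling. All three are elitist, so
the best-so-far trace is non-increasing, and all respect a hard
objective-evaluation budget. Defaults follow the canonical literature
formulations: CA acceptance fraction 0.3; ICA with 8 imperialists per
population, assimilation coefficient 2.0, revolution rate 0.1, colony
mean weight 0.1; HS with memory 30, HMCR 0.9, PAR 0.3, bandwidth 0.1.
The CA population is initialised by Latin-hypercube sampling and its
variation step mixes Gaussian perturbation scaled by the normative range,
recombinative uniform draws inside the normative range (probability
0.25), and rare global resampling (probability 0.05) that keeps
exploration alive after the belief space has contracted.

## The network engine

The classifier networks are small fully-connected nets: 1–3 hidden
layers of 1–25 neurons, hidden activations from a 6-function catalog
(logistic, tanh, rectified linear, saturating linear, linear, softplus),
trained full-batch to minimise mean squared error against the 0/1 label
with a sigmoid (or, for the fixed selection net, linear) output. Four
trainers are available: plain gradient descent with step-halving (whose
training loss is monotone by construction), momentum, Adam, and a
quasi-Newton BFGS mode that delegates the step to `stats::optim` with
analytic backpropagation gradients. Features are z-scored with
training-set statistics only. When a validation split is supplied, BFGS
runs in chunks of 10 iterations with patience-based early stopping and
keeps the best-validation weights — essential for the linear-output
selection network, whose unbounded outputs otherwise overfit sharply.
Weight initialisation is seeded Glorot-uniform, so training is
deterministic given a seed.

The wavelength-selection network is fixed: hidden layers of 12 and 16
neurons, rectified-linear then log-sigmoid activations, linear output,
BFGS training (`fixedSelectionANN()`).

## Wavelength selection (ANN-CA)

`selectWavelengths()` searches for the k = 3 wavelengths of a region
whose columns minimise the test MSE of the fixed network under a
stratified 60/30/10 train/test/validation split. Design choices that
matter, all driven by the fact that a single-split test MSE is a *noisy*
estimate of candidate quality:

* candidate index triples are sorted before evaluation (the objective is
  permutation-symmetric; sorting gives the optimizer per-dimension
  structure to learn) and duplicates are repaired to the nearest unused
  index;
* the search runs as several independent CA restarts (default 3), each
  scoring candidates on one split whose seed is derived from the restart
  and the candidate, with results cached;
* the best candidates seen — plus *recombined* triples assembled from
  well-separated representative wavelengths found across the elite
  candidates — enter a sequential-halving race scored on a common split
  panel (identical splits for all finalists, so comparisons are paired),
  the panel widening as candidates are eliminated;
* the race winner is polished by coordinate descent over ±24-step
  neighbourhoods on a fresh common panel.

The reported fitness is the winner's mean test MSE over the recorded
split panel, and `reevaluateSelection()` reproduces it exactly from the
stored seeds. With no planted signal the selected wavelengths are
uniform over the region (checked by chi-square).

## Classifiers and the ensemble

* **KNN** — brute-force Euclidean, default k = 5 (odd, to limit ties);
  distance ties break to the lower training index, even class splits to
  the class with smaller summed distance. Its ROC score is the fraction
  of defective neighbours, which is intentionally coarse.
* **Stepwise LDA** — forward selection with backward removal on the
  Wilks'-lambda partial F (entry p < 0.05, removal p > 0.10), then a
  two-class linear discriminant on the pooled covariance with a ridge of
  1e-6 times the mean diagonal; the decision threshold is the class
  midpoint, with the midpoint itself assigned to the defective class. An
  empty selection falls back to the majority class.
* **ANN-ICA / ANN-HS** — `annMetaheuristicFit()` searches the full
  architecture space (layers x widths x activations x trainer x learning
  rule) by ICA or HS, scoring each candidate by test MSE; the best
  architecture is then retrained each evaluation iteration. Both methods
  search *exactly the same space*; only the optimizer differs.
* **Majority voting** — if at least three of the four members agree,
  that class wins; a 2–2 tie is resolved by the member with the highest
  validation CCR of the current iteration. The ensemble ROC score is the
  validation-CCR-weighted mean of member scores.

## Evaluation harness

`runRepeatedEvaluation()` repeats, for a configurable number of
iterations (200 in the reference design; the packaged end-to-end checks
use 50 to keep runtimes in minutes), a stratified 60/30/10 split; members
are fitted on the training split (hybrids early-stop on the validation
split), test predictions are pooled into 2x2 confusion matrices — with
240 samples and 200 iterations the pooled total is 200 x 72 = 14,400 —
and per-iteration CCRs, pooled ROC curves and AUCs are recorded.

`computeMetrics()` adopts the rows-predicted/columns-actual convention:
this is the only orientation under which the reference tables' recall,
precision and specificity values are arithmetically consistent with their
confusion matrices, and it is asserted in the acceptance tests. Recall of
a class is its correct count over the actual (column) total, precision
over the predicted (row) total, specificity is the other class's recall,
accuracy is the overall CCR, and zero denominators yield `NA` rather
than 0. Reports display one decimal; full precision is kept internally.

`pairedTTest()` compares matched CCR series (d = a − b, sample SD,
df = n − 1, two-tailed p); `pairedTTestSummary()` computes the same
worked example from a reported mean and SD.

## Numerical choices and degenerate inputs

* Reflectance must be strictly positive before the log transform; the
  generator guarantees this by clipping at 10^-4, and the converter
  rejects nonpositive values naming the offending sample.
* Detrending uses an orthonormal (QR) polynomial basis on wavelengths
  scaled to [−1, 1] for conditioning.
* A k equal to the full grid size degenerates to a single objective
  evaluation of the whole grid.
* The stepwise loop carries an anti-cycling cap and never removes the
  variable it just entered.
* Score 0.5 (ANN) and discriminant score 0 (LDA) classify as defective —
  a declared convention so ties are deterministic.

## Problem sizes used by the packaged checks

The heavy end-to-end checks run at deliberately reduced budgets chosen as
the package's reference configuration: wavelength recovery uses 20
selection seeds with 3 CA restarts of 16 x 5 populations (~96 objective
evaluations each) plus the race and polish; the ensemble evaluation uses
50 split iterations; optimizer benchmarks use 2000-evaluation budgets.
These sizes reproduce the qualitative results stably on a single CPU in
minutes.

## Known limitations

* The generator is a stand-in, not a fit to any measured potato spectra;
  no claim about real-world accuracy follows from it.
* The wrapper objective inherits the variance of 72-sample test splits;
  the race and polish mitigate but cannot remove the resulting
  winner's-curse bias.
* KNN's single-point ROC makes its AUC a coarse summary.
* The MV ensemble's score-averaging ROC is a declared construction; the
  hard-label voting rule itself has no intrinsic operating curve.
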