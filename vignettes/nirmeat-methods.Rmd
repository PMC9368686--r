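---
title: "Methods: NIR-HSI chemometrics for mutton adulteration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR-HSI chemometrics for mutton adulteration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Minced mutton adulterated with pork is hard to police once the pork has been
soaked in mutton flavour essence, because the essence defeats sensory
inspection. Near-infrared hyperspectral imaging (NIR-HSI) attacks the problem
optically: every image pixel carries a 288-band reflectance spectrum over
1000–2500 nm, and the protein (N–H, ~1020 and ~1520 nm), organic C–H
(~1250 nm) and water O–H (~2150 nm) absorption features differ subtly between
species. `nirmeat` implements the full evaluation pipeline for this setting:

1. reflectance calibration of raw cubes against white/black references,
2. band-math segmentation of the muscle-only region of interest (ROI),
3. block-mean spectral extraction (10 spectra per sample),
4. preprocessing by first derivative plus multiplicative scatter correction
   ("1D + MSC"),
5. three-class discrimination (mutton `M`, pork `P`, mixture `MP`) and
   adulteration-proportion regression with BP, ELM and SVM/SVR models,
6. hyperparameter/weight optimisation of those models by the sparrow search
   algorithm (SSA) with grouped cross-validated fitness.

Because no public dataset accompanies this design, the package ships a
first-class synthetic generator that emulates the experiment end to end; all
tests and the acceptance script run against it.

## The synthetic generator

**Endmembers.** Pure-class spectra are modelled in absorbance as a linear
class baseline plus four Gaussian dips at 1020/1250/1520/2150 nm, mapped to
reflectance as $R = 10^{-A}$. Mutton and pork share dip positions but differ
in amplitude and baseline, reproducing the "same trend, distinct reflectance
level" phenomenology of real minced-meat spectra. Dip widths (30/50/55/70 nm)
give features wide enough to survive a 15-band smoothing derivative. The
default amplitudes (mutton 0.10/0.16/0.14/0.22 vs pork 0.15/0.24/0.20/0.30
absorbance units, baselines 0.22 + 0.10u vs 0.30 + 0.14u over the normalised
wavelength u) were calibrated once so that the generated experiment lands in
the performance regime such studies report — near-separable classes and
quantification R² above 0.9 — and then frozen; they are configuration, not
fitted constants.

**Essence.** The flavour essence has no published spectral characterisation;
it is represented as a small constant absorbance offset on the pork endmember
(default 2% of the mean pork dip amplitude). This is a deliberate stand-in:
an additive absorbance constant is approximately multiplicative in
reflectance, so most of it is removed by MSC — the models must rely on the
species signature, not on a convenient essence marker.

**Mixing.** Mass fractions mix linearly in absorbance (a Beer–Lambert
surrogate): $A_{mix} = p\,A_{pork} + (1-p)\,A_{mutton}$. The physical
experiment mixes masses and implies no particular spectral mixing law;
linear absorbance mixing is the standard chemometric assumption and makes
proportion recovery well-posed (with noise off, 1-D least squares in absorbance recovers
p to 1e-10; this is a test).

**Scatter and noise.** Each pixel spectrum is corrupted as
$a + b\,x + \mathrm{drift} + \varepsilon$ with $a \sim N(0, 0.02)$,
$b \sim \mathrm{lognormal}(0, 0.08)$, a random quadratic drift of scale 0.01
and i.i.d. band noise $\varepsilon \sim N(0, 0.002)$ — exactly the artifact
family MSC and the derivative are designed to remove. Values are clipped into
(0, 1.5] with a warning.

**Design.** Defaults reproduce the emulated experimental design: 24 mutton + 24 pork
(8 per part: front leg, hind leg, back) + 144 mixtures (8 replicates × 6
proportions {5, 10, 15, 20, 30, 40}% × 3 parts) = 192 samples; 10 block-mean
spectra each = 1920 spectra; 100 pixels per sample by default (the emulated
design fixes no pixel count per ROI; 100 makes 10-pixel blocks).

**What the generator does not emulate.** No radiative transfer in meat, no
essence chemistry, no spatial texture within the muscle disc, no instrument
line-spread or wavelength miscalibration, and pixels are i.i.d. given the
sample. Passing tests therefore demonstrate that the pipeline is correct and
that the method chain behaves as designed under controlled artifacts — not
that real adulterated mutton reaches any particular accuracy.

## Imaging

Calibration is the elementwise $I = (I_R - I_B)/(I_W - I_B)$; any location
with $I_W = I_B$ is a hard error with its coordinates reported.

ROI segmentation follows the band-math recipe (background/shadow removal by
band subtraction, fat/bright-spot removal by band addition and binarisation)
with Otsu thresholds by default. The default subtraction pair is 1700 − 1520
nm: the 1520 nm protein dip versus its long-wavelength shoulder. Muscle has a
large difference there while the dark backdrop, specular spots and fat (all
spectrally flat) have nearly none; because the two bands are close, slow
baseline drift cancels almost exactly. A distant pair (e.g. 1250 − 2200 nm)
leaves the drift in the difference image and measurably degrades mask
accuracy on generated cubes. The addition pair defaults to 1250 + 1520 nm.
A contrast guard (default 0.15 reflectance-sum units) keeps Otsu from
splitting a clean unimodal ROI when no fat is present; all bands and
thresholds are recorded in the mask provenance.

Block means: ROI pixels are randomly permuted (seeded) and dealt into k
near-equal blocks (first `n mod k` blocks one pixel larger); the weighted
mean of the block means equals the ROI mean exactly, which is tested as a
conservation identity. The analysed window is the closed interval
1000–2445 nm (the noisy bands above 2445 nm are dropped).

## Preprocessing

The derivative estimator is a Savitzky–Golay smoothing-polynomial derivative
(window 15 bands, order 2) by default — robust to the injected band noise —
with a plain first difference available (`derivative_method = "diff"`; one
band shorter, midpoint wavelengths). The stage order "derivative, then MSC"
follows the method's name "1D + MSC"; the order is configurable and recorded
in the output metadata, since the method's name alone does not fix it.

MSC regresses each spectrum on a reference over bands, $x = a + b\,r$, and
returns $(x - a)/b$. The reference is the bandwise mean of the calibration
set only, frozen into a pipeline state object and reused verbatim for
prediction spectra — the prediction set never influences the transform.
Spectra with $|b|$ below 1e-10 (effectively constant) cannot be corrected and
are dropped with a warning and a recorded index. MSC is exactly idempotent on
an affine-distorted family and removes the generator's gain/offset to 1e-8;
both are tests.

## Models

All learners expose the same `fit(X, y)` / `predict(model, X)` contract so
the optimizer treats them uniformly.

* **BP** — a three-layer perceptron (logistic-sigmoid hidden layer, linear
  output, MSE on one-hot targets with argmax decoding) trained by full-batch
  gradient descent with momentum and an adaptive learning rate: the rate is
  multiplied by 1.05 after an improving epoch and by 0.7 otherwise; a step
  that would raise the loss by more than 4% is rejected and momentum reset.
  Unstated constants default to max_epochs 1000, lr 0.01, momentum 0.9 —
  conventional values for this training scheme, all exposed.
* **ELM** — random uniform input weights and hidden biases (never updated),
  sigmoid hidden layer, output weights solved in closed form as the
  minimum-norm least-squares solution via the Moore–Penrose pseudo-inverse.
  The solve is tested against an independent SVD oracle on 50 random
  problems.
* **SVM/SVR** — RBF-kernel C-classification / epsilon-regression through
  libsvm (`e1071`), penalty `c` and kernel radius `g`, one-vs-one multiclass,
  epsilon fixed at 0.01 g/g (not searched). Features are standardised inside
  each fit, on the training fold only.

Baseline tuning mirrors the study: exhaustive (c, g) grid search scored by
10-fold cross-validation, and hidden-layer sweeps 5–100 (step 5) for BP and
10–200 (step 10) for ELM with fixed folds and seeds, ties to the smaller
size.

## The sparrow search algorithm

Roles per iteration, after sorting the population best-first (population 20,
100 iterations, 7:3 discoverers:participants, 20% watchmen by default):

* discoverers: $X \leftarrow X\,e^{-i/(\alpha\,\mathrm{iter_{max}})}$ in a
  safe environment ($R_2 < ST$), else $X \leftarrow X + Q$;
* participants: ranks beyond n/2 scatter as
  $Q\,e^{(X_{worst}-X)/i^2}$; the rest move to
  $X_P + |X - X_P|\,A^+L$ with $A$ a ±1 row and $A^+ = A^T(AA^T)^{-1}$ —
  read with the canonical matrix dimensions, i.e. a signed scalar step along
  the all-ones row, which contracts followers towards the best discoverer
  (at d = 1 this reduces to $X_P + |X - X_P|$);
* watchmen (a fresh random 20% each iteration, any role): if worse than the
  global best, $X \leftarrow X_{best} + \beta\,|X - X_{best}|$ with β drawn
  per dimension; if already at the best fitness (tie tolerance 1e-12),
  $X \leftarrow X + K\,|X - X_{worst}|/((f_i - f_w) + \varepsilon)$.

Symbols the update equations leave open are drawn as: $R_2 \sim U[0,1]$ per
iteration, $ST = 0.8$, $\alpha \sim U(0,1]$ per discoverer,
$Q \sim N(0,1)$ per sparrow, $K \sim U[-1,1]$, $\varepsilon = 10^{-50}$.
Out-of-bounds coordinates are clipped (reflection available). As in the
algorithm's reference implementation, each sparrow keeps a personal best: a
proposed move is kept only when it strictly improves that sparrow's fitness,
and the global best is tracked with elitism (the reported best never
worsens). Without this bookkeeping the three update rules alone barely
refine a non-origin optimum; with it, the packaged configuration reaches a
2-D quadratic optimum to ~1e-6 (tested across seeds). Accepting ties rather
than strict improvements lets the population drift across fitness plateaus
(e.g. accuracy surfaces) toward bound corners, which is why ties are
rejected.

### Hybrids

* **SSA-SVM / SSA-SVR** search (c, g). Positions are parametrised as
  $(\log_{10} c, \log_{10} g)$ over (−5, 2) — the same (1e-5, 100) range on
  the natural scale — because on the raw scale the useful kernel radii
  occupy a sliver of the box and uniform exploration stalls on a flat
  worst-fitness plateau; log-scale RBF search is standard practice. Every
  candidate (c, g) a model actually sees lies inside (1e-5, 100).
* **SSA-ELM** searches the input weights and hidden biases in (−5, 5);
  output weights are always re-solved in closed form, never searched.
* **SSA-BP** searches the initial weights/thresholds in (−5, 5); each
  fitness evaluation trains briefly (100 epochs) from that initialisation,
  and the final model retrains fully at the best initialisation
  ("assigned to weights and thresholds" read as initialise-then-train).

Fitness is the sample-grouped 10-fold CV score (1 − accuracy, or RMSE) of
the model instantiated at the position; a failing fold poisons the position
with the worst possible fitness rather than aborting. Folds group block
spectra by parent sample so sibling spectra never straddle folds — the
obvious leakage channel in a 10-spectra-per-sample design. `optimize_model()`
can evaluate fitness on the per-sample mean spectra (`level = "sample"`)
instead of all block spectra; the package's own large-scale runs use this —
the hyperparameter surface is nearly identical while fitness evaluation cost
drops by two orders of magnitude — and the final model is always refit on
the full block-spectrum calibration set.

## Evaluation protocol

Samples (never spectra) are split 3:1 into calibration and prediction sets,
stratified by class (classification) or proportion × part (quantification),
yielding the canonical 144/48 and 108/36 sample counts; every block
spectrum inherits its sample's membership, and the no-leakage invariant is
asserted on every run. Calibration-set figures are 10-fold sample-grouped CV
results, reported from pooled out-of-fold predictions; prediction-set
figures come from the model refit on the whole calibration set. Metrics:
overall accuracy with a truth-by-prediction confusion matrix in class order
(M, P, MP), and RMSE (g/g) with $R^2 = 1 - SS_{res}/SS_{tot}$; zero-variance
truth yields an explicitly undefined R². Accuracy is counted per spectrum,
consistent with spectrum-level set sizes.

## Problem sizes used by the shipped checks

The test suite and acceptance script choose sizes that keep the full
statistical structure while running on one CPU: end-to-end parameter-recovery
runs use the full default design (192 samples × 100 pixels, 1920 block
spectra) with sample-level fitness and SSA budgets of 10 × 15 iterations
(classification; the baseline grid is stronger there) or 6 × 6
(quantification); paired SSA-vs-baseline comparisons pair the SVM family on
the full design and the ELM/BP families on a reduced quantification design
(36 samples, 2 parts × 3 proportions × 4 replicates, 30 pixels, 5 blocks)
across 10 seeds; SSA equation oracles, preprocessing
round-trips and metric oracles run at toy sizes with frozen draws. The SSA
defaults (20 × 100) remain the package defaults.

## Known limitations

* The generator's essence term is a placeholder, not an estimate; nothing
  here characterises real mutton flavour essence spectrally.
* Absorbance-linear mixing ignores multiple scattering between species
  particles; real mixtures deviate from it.
* BP training is full-batch with MSE; class probabilities are not
  calibrated, and no significance tests accompany model comparisons.
* SSA-BP/SSA-ELM search spaces grow with the band count (thousands of
  dimensions); with the default budgets the search selects good
  initialisations rather than exhaustively optimising weights.
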