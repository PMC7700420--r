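---
title: "Methods: fused NIR/MIR PLS-DA classification and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused NIR/MIR PLS-DA classification and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`specfuse` implements a complete chemometric pipeline for two-class tissue
discrimination from paired fibre-probe spectra: a mid-infrared (MIR,
attenuated total reflection) absorbance block over the fingerprint region
and a near-infrared (NIR) diffuse-reflectance block, measured at the same
tissue positions. The analysis has five stages — preprocessing, series-wide
normalisation, low-level fusion, PLS-DA modelling with VIP interpretation,
and cross-validated evaluation with ROC ranking — plus a synthetic cohort
generator that provides data with the statistical structure such studies
assume. This vignette records the modelling decisions, the parameters that
matter, and what the synthetic experiments do and do not demonstrate.

## The classification model

PLS-DA is realised as univariate PLS regression (PLS1, NIPALS) of the 0/1
class code on the spectral matrix. Both study questions are two-class
problems, and PLS1 is the common realisation of two-class PLS-DA; a PLS2
dummy-matrix formulation adds nothing here. The fit is fully deterministic:
the weight vector of each component is `X'y` normalised, so there is no
random initialisation to seed. `X` is column-centred but **not**
variance-scaled — per-spectrum scaling is the job of the preprocessing
chain (SNV) and per-block scaling of the min-max step, and channel
autoscaling on top of those would double-correct and inflate noise
channels.

The number of latent variables `A` is a fixed experiment parameter
(default 5), not auto-selected: the comparisons the package exists for
(instrument vs instrument, organ vs joint) only stay interpretable if every
cell uses the same model complexity. Inside cross-validation folds `A` is
clamped to the feasible maximum `min(n_train − 1, p)` so that tiny organ
subsets remain fittable.

Scores above the 0.5 threshold (the midpoint of the 0/1 coding) are called
tumour; a score exactly at the threshold is classified normal. The tie rule
is arbitrary but deterministic and conservative towards the negative class,
and it matters only on sets of measure zero for continuous spectra.

VIP follows Wold's definition with unit-norm weight columns; the identity
`sum(VIP^2) = p` is asserted in the test suite for every fitted model, which
pins down the normalisation variant among the several that circulate.

## Preprocessing

The chain vocabulary is `none`, `snv`, `1d`, `2d`, `1d+snv`, `2d+snv`, with
the derivative always preceding SNV. Decisions worth recording:

* **Savitzky–Golay windows.** Second-order polynomial throughout; 25
  channels for NIR. The MIR convention of an 8-point window cannot be
  centred (even width), so the package defaults to the nearest odd width,
  9 points, and exposes the window as a parameter. Filtering is delegated
  to `signal::sgolayfilt`, which fits the edge windows with the same
  polynomial and evaluates at the off-centre points — output length equals
  input length, and any polynomial of degree ≤ 2 is reproduced exactly at
  *every* channel, edges included. Both properties are asserted in the
  tests.
* **Derivative scaling.** Derivatives are returned per physical axis unit
  (divided by the channel step to the derivative's power), making MIR
  (8 cm⁻¹ steps) and NIR (1.66 nm steps) derivative magnitudes comparable
  before min-max scaling. A pure per-channel convention differs only by a
  block-constant factor, which the min-max step removes — the two
  conventions yield identical downstream models; the physical one is kept
  because intermediate spectra are then interpretable.
* **Series-wide min-max.** The final step rescales a whole block with one
  coefficient pair (global min and max over all entries) to [0, 1].
  Individual spectra need not span [0, 1]; what is guaranteed is equal
  intensity footing of the two instrument blocks at concatenation, which is
  the entire fusion-balance strategy — no block weighting is applied (an
  optional weight pair exists, defaulting to 1).
* **Replicate averaging** happens before everything else, and a background
  spectrum (e.g. a saline reference for contact-probe MIR) can optionally
  be subtracted first; no further reconstruction of experimental
  water-band subtraction is attempted.

## Fusion

Low-level fusion is horizontal concatenation of the two independently
preprocessed, min-max-scaled blocks, MIR columns first (fixed so VIP
indexing is reproducible), after pairing rows by position id and verifying
metadata consistency. The concatenation refuses blocks whose global range
is not [0, 1] — the balance contract is enforced structurally rather than
by convention. Slicing a fused matrix at the recorded boundary recovers
both parents exactly (tested).

## Cross-validation and leakage

The resampling unit is the measurement position (the replicate-averaged
row). Positions from one patient are correlated through the patient random
effect; patient-level grouping is deliberately **not** the default because
the evaluation target is the position-level protocol, but the metadata
carries patient ids so grouped schemes can be built on top.

Every fold-dependent quantity — the min-max coefficients, the PLS centring
means, the model — is refitted inside each training fold; held-out rows are
scaled with the *training* coefficients and may therefore fall slightly
outside [0, 1], so the fusion range check is relaxed during CV. Per-row
operations (SNV, derivatives) depend on one spectrum only and are
precomputed once; fold membership cannot leak through them. Two tests pin
this down: an exact identity (the LOO score of each position equals an
explicit refit on the data without it) and a null-band check (pure-noise
features plus an extreme-value artifact column that dominates the min-max
coefficients must yield chance-level LOO accuracy). A planted artifact can
never be informative *only* through normalisation leakage — any
label-dependent value in the rows is also visible to the classifier
directly — so the null band plus the refit identity is the sharpest
executable form of the anti-leakage requirement.

Monte Carlo CV holds out `round(0.1 · n)` positions per repetition, 100
repetitions, unstratified (a stratified option exists). Repetitions whose
training fold — or whose holdout, when it has at least two rows — contains
a single class are redrawn and counted; a single-position holdout cannot
contain both classes, and in that limit the scheme degenerates to
randomised leave-one-out subsampling, which is accepted. Pooled statistics
over all held-out predictions and per-repetition means are both reported,
since either convention is found in practice.

**LOO vs Monte Carlo optimism.** LOO trains on n−1 positions, Monte Carlo
on ~0.9 n, so LOO is expected to be the more optimistic scheme. In this
pipeline the effect is carried by the patient-level *scale* effect, which
survives derivative-only chains but is annihilated by SNV (it is exactly
the per-spectrum scale SNV removes). The optimism comparison is therefore
evaluated on derivative-preprocessed models; under SNV chains the two
schemes differ only through training-set size and the ordering is within
noise.

## ROC ranking

Curves are built by sweeping the threshold over every unique score (strict
`>` rule), giving a monotone staircase from (0, 0) to (1, 1); the tests
cross-check the point set against `pROC`. Models are ranked by the minimum
Euclidean distance of their curve to (0, 1); ties break by pooled accuracy,
then by model id. Curves can be built from calibration scores or from
pooled CV scores; the report ranking uses the LOO scores, the honest ones.

## The experiment grid

`run_experiment()` crosses {NIR, MIR, fused} with {colon, stomach, rectum,
joint} — 12 dataset cells — and searches the chain grid in each. The best
model per cell maximises **LOO accuracy** (cross-validated accuracy is the
comparison currency of such studies; calibration accuracy saturates), with
ties broken by calibration accuracy, then by the shorter chain, then by
model id — a total order independent of enumeration order (tested). For
the fused modality the default grid pairs the *same* chain on both blocks
(6 cells); the full 36-pair product grid is available via
`fused_grid = "product"`. Synergy is reported per sample set as fused
accuracy minus the best single-modality accuracy; the local-vs-global
comparison reports both readings of an ambiguous convention — organ model
vs the joint model's overall accuracy, and vs the joint model scored on
that organ's positions only.

## The synthetic cohort generator

The generator emulates the *structure* of a three-organ clinical cohort,
not any particular dataset. Defaults: 52 colon positions (27N/25T, 10
patients), 52 stomach (32N/20T, 12), 21 rectum (9N/12T, 6); 3 raw
replicates per position and modality; MIR axis 1800→900 cm⁻¹ at 8 cm⁻¹
(113 channels, stored ascending), NIR 900–1700 nm at 1.66 nm (482
channels).

Each spectrum is a sum of Gaussian bands (closed-form FWHM
parameterisation) at the positions characteristic of gastrointestinal
tissue — lipid carbonyl 1742 cm⁻¹, amides 1642/1550, glycogen complex
1125–1040, phosphates 1240/1083 in MIR; broad OH/CH overtone and
combination bands near 955, 1150, 1360 and 1500 nm in NIR — with
multiplicative organ factors (rectum lipid/phosphate-rich, colon
glycogen-rich) and class factors (amides up, lipids down, glycogen up in
colon but down in stomach tumours). All effect sizes are free generator
parameters chosen once to produce a realistic accuracy landscape
(cross-validated accuracies broadly between 55 and 95% across cells, with
preprocessing choice mattering); they are not estimates of real tissue.

The stochastic layers, per draw:

| component | default | role |
|---|---|---|
| patient effect | log-normal, sd 0.15 | one scale factor per patient, shared across positions — induces within-patient correlation |
| band jitter | log-normal, sd 0.10 per band | position-level compositional heterogeneity; the dominant within-class variance |
| baseline drift | linear, coefficient sd 0.5 | additive instrument baseline per replicate |
| scatter | log-normal, sd 0.30 | multiplicative contact-pressure factor per replicate |
| noise | Gaussian, sd 0.08 per channel | detector noise |

The band jitter deserves a note: without position-level compositional
variability, the only within-class variance is scale-like (removed by SNV)
or white (averaged away over hundreds of channels), and every model
saturates at 100% accuracy. Real tissue varies in composition from spot to
spot; the jitter models that, and it is drawn independently per modality
because the two instruments interrogate different effective tissue volumes
(micrometres for the ATR evanescent field, millimetres for NIR diffuse
reflectance). The patient effect remains a single scalar per patient.

Randomness is organised as one root seed with deterministic child streams
per (organ, patient/position, replicate, modality), so cohorts are
bit-identical across runs and enlarging one organ does not reshuffle
another's draws (both tested).

Two documented presets support the qualitative study findings:

* `preset_complementary()` — the tumour contrast is carried by MIR bands
  for colon and rectum positions and by NIR bands for stomach and rectum.
  Each instrument alone is only moderately informative (single-modality
  LOO accuracy designed into the 70–85% band); fusion is informative
  everywhere, so the synergy gain is structural. A same-positions
  information split was considered and rejected: its fusion gain is bounded
  by the √2 signal-combination factor (≈8 points at these accuracy levels)
  and is not robust across seeds, whereas organ-complementarity mirrors the
  organ-dependent VIP structure such studies report.
* `preset_organ_heterogeneous()` — organ-specific class contrasts pointing
  in conflicting directions (glycogen up in colon tumours, down in stomach
  tumours), so one joint linear classifier cannot serve all organs and
  per-organ models hold a structural advantage. Its control,
  `preset_organ_null()`, removes all organ structure; residual
  local-vs-global deltas then reflect only CV noise and the smaller
  training sets of per-organ models (a small *negative* bias, most visible
  for the 21-position rectum set).

## What the synthetic experiments show — and what they cannot

Passing tests demonstrate that the pipeline's machinery is correct (exact
preprocessing algebra, oracle-verified PLS, leak-free CV) and that it
*recovers planted structure*: fusion synergy when information is split
across modalities, local-model advantage when organ structure exists and
none when it does not, and LOO's optimism relative to Monte Carlo CV.
They cannot validate any claim about real tissue: the generator's Gaussian
bands, log-normal effects and white noise are idealisations — no water-band
interference, no detector nonlinearity, no penetration-depth physics, no
correlated biological covariates — and its effect sizes are design
choices. Conclusions about clinical data require clinical data.

## Problem sizes and numerical tolerances

The test suite runs the full default experiment (12 cells × 6 chains, LOO
plus 100-repetition Monte Carlo per cell, ≈ 11,000 model refits) and the
multi-seed property checks at 10 seeds each; the whole suite completes in a
few minutes on one CPU. Algebraic identities are asserted at 1e-8–1e-12;
the NIPALS-vs-oracle agreement at 1e-6; stochastic properties (null bands,
synergy and locality recoveries, optimism ordering) at the seed counts and
thresholds stated in the tests. SNV refuses constant spectra, min-max
refuses constant blocks, NIPALS refuses a deflated-to-zero covariance with
an instruction to reduce `ncomp` — degenerate inputs fail loudly rather
than silently.
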