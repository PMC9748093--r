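---
title: "Fetal state assessment with deep feature fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal state assessment with deep feature fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctgdffn)
```

## The problem

Intrapartum cardiotocography records the fetal heart rate (FHR, beats per
minute, sampled at 4 Hz) during labor. The clinical question is whether the
fetus is developing acidemia: the ground truth is the umbilical-artery blood
pH measured at delivery, with pH < 7.15 labelling a record *pathological*
and pH >= 7.15 *normal*. Visual interpretation of the traces is notoriously
observer-dependent; `ctgdffn` implements a complete computer-aided pipeline:
signal preprocessing, an engineered feature bank, a multiscale CNN-BiLSTM
backbone, and a two-stage *deep feature fusion network* (DFFN) classifier
evaluated by stratified cross-validation.

Because archived intrapartum databases cannot be redistributed with a
package, every component is exercised against a ground-truthed synthetic FHR
generator whose class contrasts emulate the clinically relevant phenotypes.

## Preprocessing

Analysis uses the trailing 20-minute window (4800 samples at 4 Hz), the
segment most strongly associated with the delivery outcome. Two rules flag a
sample invalid:

* **range rule** — the value lies outside 50--220 bpm;
* **jump rule** — the value differs by more than 25 bpm from the most recent
  *retained* sample. Using the last retained sample (rather than the raw
  predecessor) as reference stops an isolated spike from invalidating the
  rest of the trace. As a safeguard against the converse failure (a genuine
  sustained level shift being rejected forever) the reference re-anchors
  after 60 s of consecutive jump-rule rejections; true artifact runs are
  orders of magnitude shorter.

Invalid runs are replaced by linear interpolation between the flanking valid
samples; runs touching the record edges are filled with the nearest valid
value. Because interpolation happens between in-range endpoints, repaired
signals always lie in 50--220 bpm, and the repair is idempotent. Gaps longer
than 30 s are repaired but logged with a warning.

Record-level quality gates mirror common archive inclusion rules: at least
60 min of recording, at most 15% signal loss per 30-minute window, and an
available pH when labels are required (`record_passes_quality()`).

## The engineered feature bank

`fhr_features()` computes a named 16-dimensional vector per record
(`feature_layout()`):

* **morphological** (FIGO-style): baseline, acceleration count, deceleration
  count, variability;
* **time-domain / FHRV**: mean, sample SD, mean absolute deviation, median
  absolute deviation, LTV, STV, LTI, II;
* **entropy**: ApEn and SampEn, each at tolerance r = 0.15 and r = 0.2.

Definitions and conventions:

* `STV` is the mean absolute difference of consecutive 2.5-s block means
  (10 samples per block); `LTV` the mean per-minute range of the raw signal.
  Both are defined over the `M` whole minutes of the segment with a `24 M`
  denominator; a segment of exactly `M` minutes has only `24 M - 1`
  consecutive-block pairs, in which case the sum truncates at the available
  pairs (the denominator keeps its printed value).
* `LTI` has two selectable conventions because the defining expression's
  radical grouping is typographically ambiguous in the source literature:
  `literal` (default) averages `sqrt(sm(i) + sm(i+1))` — the literal
  reading — while `modulus` averages the classical
  `sqrt(sm(i)^2 + sm(i+1)^2)`.
* `II` is the ratio of the overall sample SD to the SD of the 2.5-s block
  means; it is undefined (an error) for constant signals.
* The **baseline** is an iteratively trimmed mean: samples further than
  10 bpm from the running mean are dropped and the mean recomputed, up to 20
  iterations. **Events** are maximal intervals whose (2.5-s smoothed)
  deviation from baseline is at least 15 bpm for at least 15 s, with
  sub-threshold gaps of up to 5 s bridged — without the smoothing and
  bridging, beat-to-beat variability fragments one clinical event into
  sub-gate pieces. **Variability** is the mean per-minute peak-to-peak range
  outside detected events; with no events and a constant baseline it
  coincides with LTV by construction.
* **ApEn/SampEn** use embedding dimension m = 4 and tolerances interpreted
  relative to the series SD (the convention in the FHR variability
  literature; absolute tolerances are selectable). The distance is Euclidean
  by default, following the source method's wording, with the classical
  Chebyshev metric selectable; ApEn includes self-matches, SampEn excludes
  them and returns an infinite sentinel (with a warning) when no
  (m+1)-dimensional template pair matches. Both are verified against
  brute-force O(N^2) reference implementations to 1e-10.
* **LZC** (available through the alternate feature layout) counts new
  patterns under the 1976 exhaustive-history parsing of the mean-threshold
  binarized series (ties map to symbol 1) and normalizes by `N / log2(N)`
  at N = 4800.

## The backbone and the fusion classifier

`backbone_spec()` encodes the layer table of the multiscale CNN-BiLSTM:
two parallel 1-D convolution branches (kernel sizes 32 and 64, 8 filters
each, stride 1, SAME padding) concatenated to 16 channels; three trunk
stages of convolution (kernel 32, 24 filters) + batch normalisation + ELU +
valid-padding average pooling (windows 4, 8, 16) + dropout 0.25; a
bidirectional LSTM over the resulting 9-step sequence; a parameter-free
residual add of the convolutional path and the BiLSTM output; flatten (216);
a 32-unit fully connected layer (ELU, dropout 0.5); and a 1-unit sigmoid
head. `backbone_shapes()` reports every realized layer shape from an actual
forward pass, and construction fails if any shape disagrees with the
specification.

Choices the layer table does not determine, fixed as package defaults:

* the BiLSTM row only fixes the concatenated output width (24), so 12 hidden
  units per direction is the unique width that makes the residual add
  shape-legal;
* branch convolutions carry batch-norm and ELU but no pooling/dropout — the
  only reading consistent with the declared branch output shapes;
* dropout sits on the convolutional path before the residual add, matching
  the row order of the table;
* Glorot-uniform initialisation, LSTM forget-gate bias 1, batch-norm
  epsilon 1e-5 with running-statistics momentum 0.1, ELU after the 32-unit
  layer, batch size 32 (all unstated upstream; recorded here once).

Training (`dffn_config()`): SGD with momentum 0.9, 130 epochs, initial
learning rate 0.01 divided by 10 after epochs 15 and 90, and class-weighted
binary cross-entropy, default weights 0.21 (normal) : 0.79 (pathological)
for the roughly 4:1 class imbalance of intrapartum archives. The loss clamps
probabilities to [1e-7, 1 - 1e-7].

`dffn()` trains in two stages. Stage 1 fits the backbone end-to-end on the
raw signals. Stage 2 freezes the backbone (a `finetune` switch is reserved
but not implemented), extracts the 32-dimensional deep representation
(evaluation-mode activations of the fully connected layer, pre-dropout),
z-scores the engineered features with training-set statistics (persisted in
the model object), concatenates deep and engineered parts into a
48-dimensional fused vector, and trains a dropout-regularised (0.25) sigmoid
head with the same optimiser settings. Prediction applies the stored scaler
and calls a record pathological when the fused probability is >= 0.5 (ties
to pathological; threshold configurable).

### Numerical implementation

The backbone, its backpropagation and the SGD loop are implemented in
C++/Armadillo directly against BLAS. Activations for a whole minibatch live
in one column-major matrix with zero "gap" rows between records; the gaps
double as the SAME-padding halo so each convolution tap is a single strided
GEMM, blocked over ~768-row chunks to stay cache-resident. Training runs in
single precision (the standard choice for neural networks); a parallel
double-precision instantiation of the same templated code backs the
finite-difference gradient check in the test suite, which verifies every
parameter group (convolutions, batch norm, LSTM gates, heads) to ~1e-8
relative error. The float path uses a fast exponential approximation inside
ELU (~3e-5 relative accuracy, well below fp32 training noise); the double
path keeps exact `expm1`. Given a seed, initialisation, shuffling and
dropout are fully deterministic, so fitted models are bit-reproducible.

## Evaluation

Sensitivity `SE = TP/(TP+FN)` (recall of pathological records), specificity
`SP = TN/(TN+FP)`, and the quality index `QI = sqrt(SE * SP)` — the
geometric mean is the headline metric under class imbalance. `cross_validate()`
assigns records to stratified folds (per-class round-robin after shuffling,
so per-fold class counts deviate from proportionality by at most one
record), trains a fresh DFFN per fold, and aggregates per-fold metrics as
mean and SD **across folds** rather than from a pooled confusion matrix —
pooling would make the printed QI irreproducible since
`sqrt(mean SE * mean SP) != mean QI`. `class_weight_sweep()` repeats the
cross-validation over a grid of class-weight pairs (default 0.22:0.78 down
to 0.16:0.84) and sorts by mean QI, breaking ties toward the higher-SP pair
(preserving normal-record detection). Precision–recall curves and average
precision are provided instead of ROC, which is less informative under
imbalance.

## The synthetic generator

`generate_fhr()` builds a record as baseline + band-limited variability +
events + noise, then injects artifacts:

* **baseline**: a per-record constant drawn around the class mean (jitter SD
  4--6 bpm across records, emulating between-fetus spread);
* **variability**: Gaussian noise FFT-band-limited to 0.03--0.5 Hz, scaled
  so the typical per-minute peak-to-peak range matches `variability_bpm`
  (the component SD is the target divided by 4, the expected range of the
  band-limited process over a minute). No cardiovascular model is claimed;
* **events**: Poisson-counted accelerations/decelerations as Tukey
  (plateau) pulses — peak magnitude N(20, 3) truncated at the 15 bpm gate,
  duration N(35, 8) s truncated at 20 s. The plateau shape makes the stated
  magnitude/duration meaningful under the FIGO gates: a fully tapered pulse
  of nominal duration d holds a 15 bpm excursion for well under d, which
  would make nominally detectable events undetectable;
* **artifacts**, mirroring the two invalid-sample classes the preprocessing
  removes: out-of-range spikes (values beyond 220 or below 50 bpm), dropout
  runs to 0 bpm, and step offsets of 45--60 bpm — deliberately far above the
  25 bpm jump rule so that an offset can never hide inside an ordinary
  variability excursion;
* a pH drawn consistently with the class label (normal: 7.16--7.42,
  pathological: 6.85--7.14) so the labelling rule can be exercised
  end-to-end.

`difficulty_schedule()` fixes three class-contrast levels. *Easy* (baseline
140 vs 125 bpm, variability 10 vs 3 bpm, accelerations 4 vs 0.5 and
decelerations 0.5 vs 4 per 20 min) emulates the textbook low-variability /
decelerating pathological phenotype and is almost perfectly separable.
*Hard* makes the class-conditional distributions nearly identical (140 vs
139.5 bpm, variability 10 vs 9.6, near-equal event rates, larger per-record
jitter), so any classifier can only reach chance-level QI. *Medium* lies
componentwise between. What passing tests on these data do **not** show is
performance on real cardiotocograms: the generator has no fetal physiology,
no uterine-contraction coupling, no gestational-age effects, and its class
contrasts are design choices, not epidemiology.

## Benchmarks computed by the test suite

The test suite runs two cross-validation benchmarks at the full study
condition — 200 records at the 4:1 class ratio, stratified 10-fold CV: the
easy schedule must reach mean QI >= 0.85 with 30-epoch stage-1 training per
fold, and the hard schedule must stay inside the chance band [0.4, 0.6]
(its arm trains for 15 stage-1 epochs: with no class signal to learn,
chance level does not depend on training length). The class-weight sweep uses the **hard** schedule: on separable
data every weight pair reaches SE = SP = 1 and the weight-trend rank
correlation is undefined; the sensitivity/specificity trade-off only exists
when the classes overlap, as they do on real data, and with near-identical
classes the weights act purely through the decision threshold. The sweep
runs at a reduced harness (100 records, 2 folds, 6 stage-1 epochs, two
repeated cross-validations with pooled held-out confusion matrices — the
pooled counts give a far less noisy SE/SP estimate per weight pair than
fold-averaged ratios). Auxiliary training properties (restart stability, seeded
determinism, weight-direction effects) run on stratified subsets of the
same cached data at small epoch counts. Problem sizes are stated here as
package choices so results are reproducible.

## Known limitations

* The backbone trains on CPU at desk scale; no GPU path is provided.
* Stage-2 backbone finetuning is not implemented (frozen backbone only).
* The PhysioNet reader covers the header + format-16 layout used by public
  intrapartum archives, not the full WFDB format zoo; files in other
  storage formats raise an explicit error.
* SampEn at m = 4 can diverge on short or very irregular series; the
  infinite sentinel is propagated as `NA` into feature tables, and the
  fusion stage imputes such entries with the training-set column mean.
* The uterine-contraction channel is deliberately out of scope, so
  contraction-relative deceleration typing (early/late/variable) is not
  available.
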