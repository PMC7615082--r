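---
title: "Hierarchical transformers and self-supervised pre-training for long EHR: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical transformers for long EHR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hierehr)
```

## The problem

Five-year risk prediction from linked primary- and secondary-care records
is a sequence-modelling problem with an awkward length distribution:
medians of one to two hundred records per patient, but a heavy right tail
in which a third of patients exceed the 256-record capacity of a standard
transformer encoder. Truncating to the newest 256 records throws away the
part of the history that is largest precisely for the sickest patients.
`hierehr` implements a two-level encoder whose receptive field covers up
to 1220 records at a 50-token attention footprint, together with the
cohort machinery, a self-supervised pre-training scheme, the evaluation
protocols, and a synthetic-cohort generator that makes all of it testable
without restricted data access.

## Cohort construction

A patient's timeline is a date-ordered multimodal sequence over nine
modalities: diagnoses, medications, procedures, tests, systolic and
diastolic blood pressure, BMI, smoking and drinking status. The three
continuous modalities are discretized into categorical tokens
(`bin_value()`): systolic 80–200 mmHg and diastolic 50–140 mmHg in 5-mmHg
steps, BMI 16–50 kg/m² in 1-unit steps; readings outside the plausible
range are dropped, and the upper boundary is kept in the last bin so that
a reading of exactly 200 mmHg is not silently lost. The arithmetic gives
24, 18, and 34 bins. (A well-known tabulation of the same scheme reports
17 diastolic categories — consistent with counting only *observed* bins in
a particular data set; the formula value 18 is what the package computes.)

Labelling: the incident date is the first occurrence of any
disease-defining code (`find_incident_date()`). Cases receive a baseline
date uniform over the days in `[incident - 5y, incident - 1y]`; event-free
patients receive one uniform over `[history start + 3y, data end - 5y]`.
Every patient needs at least 3 years of records before baseline, and an
incident inside the first year after baseline excludes the patient
(recording-lag blanking). A year is 365.25 days throughout, so windows are
leap-year stable. All records strictly before baseline form the learning
period; when it exceeds the model's maximum length the *latest* records
are kept, and `ehr_length` retains the pre-truncation count for the
subgroup analyses.

Encoding (`encode_history()`): tokens map to integer ids (reserved ids
PAD/UNK/MASK/CLS), per-event age is the floor of (event − birth)/365.25
clamped to 0–110, all records sharing one calendar date form one visit
(date is the only grouping key available in this kind of extract), the
segment id alternates 0/1 between visits, and the position id is the visit
index. Ties in event dates keep input order (stable sort) for determinism.

## The hierarchical encoder

Input embeddings are the sum of token, age, segment, and position lookups,
layer-normalized. A sliding window of size `W = 50`, stride `S = 30` cuts
the sequence into segments; when `(n - W)` is not a multiple of `S`, one
extra window anchored at `n - W` guarantees every record is covered
(`segment_windows()` — 40 windows at the full length 1220; the standard
count formula yields 40 rather than the occasionally quoted 39, and this
package mandates full coverage). A shared-weight post-LN transformer
encodes each window; the segment representation is the state at the
window's first position by default, with mean pooling over the window's
real tokens as a config alternative. A second transformer over
`[CLS; segments]`, with its own learned segment-position embeddings,
produces the pooled state `tanh(W p_CLS + b)` and the sigmoid risk head.
The flat baseline is the same embedding machinery with a single 8-layer
stack over CLS + the latest 256 records and first-timestep pooling.

Full-scale hyperparameters: hidden 150, 6 heads, intermediate 108, 4 + 4
layers, dropout 0.2, attention dropout 0.3, GELU activations (the sigmoid
approximation `x·sigma(1.702x)`, whose cost matters on CPU). A reduced
profile for CPU-scale experiments uses hidden 48, 4 heads, intermediate
64, 2 + 2 layers, maximum length 512, no dropout.

Numerical design worth knowing about:

* every forward pass caches what its hand-written backward pass needs;
  analytic gradients are verified against central finite differences in
  the test suite (tolerance 1e-3 relative on sampled coordinates);
* window grids are computed **per patient**, so a patient's output never
  depends on which batch it happens to share with longer patients
  (shorter patients are padded with fully masked dummy windows whose
  gradient contribution is exactly zero);
* attention probabilities are not cached; the backward pass recomputes
  them from Q/K, which is cheaper than streaming an `O(N·W·heads)` matrix
  through memory at these block sizes;
* all-padding windows yield a zero segment representation and a zero
  segment mask; masked keys get score −1e300 before the (max-shifted)
  softmax, and an all-masked block short-circuits to a zero context.

## Self-supervised pre-training

The scheme matches an online network (encoder → per-segment projector →
predictor) to an exponential-moving-average target network (encoder →
projector), with decay `tau = 0.996`, under the per-timestep loss
`2 − 2·cos(online prediction, target projection)` summed over augmented
timesteps and averaged over examples that have any. Augmentation is
one-sided and two-level: EHR-level — a random contiguous visit crop
(probability 0.5, uniform over the `V(V+1)/2` intervals) and random token
masking (probability 0.2 per token; ids replaced by `MASK`, the other
channels kept); segment-level — each masked-in segment joins the
augmented set with probability 0.5 and is zeroed (85%) or perturbed with
standard Gaussian noise (15%). Two interpretive choices, made once:

* the **crop is shared** by the online and target paths. The loss compares
  the two paths timestep by timestep, which requires aligned segment
  grids; token masking and segment augmentation stay online-only.
* the per-timestep augmentation probability is read **per timestep** (not
  per sequence); the alternative is a config knob.

The projector and predictor are one-hidden-layer MLPs (hidden 150 at full
scale) applied per segment timestep, with batch normalization on the
hidden layer and Xavier-scale initialization. Both choices are load-
bearing at small scale: without BN the objective collapses onto constant
representations (loss near zero, no usable features), and with tiny-scale
head init the normalized loss has `1/|u|`-scaled gradients that destroy
SGD. Pre-training uses SGD with momentum 0.9 under a cosine decay with
10% linear warm-up; zeroed segments block gradients exactly (the zeroing
is a hard replacement, not a multiplication).

## Optimization and evaluation protocols

Supervised training uses Adam under a three-stage schedule — linear
warm-up over the first 10% of steps, hold at the peak for 40%, cosine to
zero over the last 50% — with early stopping once the running-minimum
validation loss is more than 6 epochs old (ties do not reset the
counter), and best-weight restoration. A step-driven alternative,
`train_balanced_steps()`, draws half-positive/half-negative resampled
batches; this is what the benchmark experiments use, because a ~10%
prevalence outcome under plain epoch batching spends most of a desk-scale
budget learning the base rate.

AUROC is computed in the Mann–Whitney midrank form (ties count half);
AUPRC by step interpolation over distinct thresholds. Both are tested
against brute-force enumeration oracles. The protocol functions mirror
the usual analyses: `subgroup_eval()` splits at 256 learning-period
records and adds a positive-rate-matched view of the long subgroup (all
negatives kept, positives subsampled without replacement to the short
subgroup's rate, averaged over 5 draws); `fraction_curve()` retrains on
nested subsets (1%–100%) with and without a pre-trained encoder;
`modality_ablation()` re-encodes the cohort with diagnosis+medication
plus one further modality at a time. Subsampling for the fraction curve
is without replacement: resampling with replacement would distort
prevalence at the 1% end.

## The synthetic generator

`generate_cohort()` emulates the structure the model needs, not clinical
content: a gamma-renewal visit process (shape 2 — overdispersed gaps and
a long right tail of record counts), Poisson records per visit, a
configurable modality mix (defaults follow the relative frequencies seen
in primary-care extracts: medications and tests dominate), uniform values
inside the binning ranges, and a *plantable risk signal*: a small set of
dedicated tokens carried by a fraction of patients, placed either among
the recent records or strictly deeper than the newest 256 ("deep"), with
the outcome drawn from a logistic model on carriage. The outcome is
Bernoulli in the 1–5-year window rather than a hazard process because the
endpoint being modelled is a fixed-window binary label; the generator's
truth table carries the baselines it used, so experiments can encode
exactly the learning periods the signal placement refers to. What the
generator does **not** emulate: realistic code co-occurrence, visit-level
clinical structure, measurement trends, or informative observation — so a
passing benchmark shows the architecture can exploit deep signal, not
that it reaches any particular clinical performance.

## The two benchmark experiments

`longrange_benchmark()` (the qualitative analog of the long-EHR subgroup
result): 5,000 patients, all with learning periods above 300 records,
signal strictly deeper than the newest 256 records, ~10% prevalence;
3 seeds × (reduced hierarchical model vs matched flat baseline), 600
class-balanced steps of batch 8 at peak lr 1e-3 (10% warm-up, 60% hold,
30% cosine decay), mean segment pooling.
Problem sizes were chosen as the smallest at which the deep-signal
feature is reliably learned on one CPU: the optimization has a plateau of
roughly 300–500 balanced steps before the token-presence feature is
picked up, mean pooling provides the linear path that makes that
transition happen (first-position pooling memorizes instead at this
scale), and escape from the plateau is initialization-dependent, so a run
whose training loss still sits at the balanced-chance level at step 250
restarts from a jittered re-initialization (at most twice; the flat arm
runs without restarts because chance-level loss is its true optimum on
deep-signal data). The flat baseline — whose 256-record window cannot
contain the signal — stays at chance, and measured gaps sit around
0.15–0.25 against a cohort Bayes ceiling near 0.81 and the 0.10 margin.

`transfer_benchmark()` (the qualitative analog of the semi-supervised
result): BYOL pre-training on a 3,800-patient cohort with a strong recent
signal, then per seed a shared 1% label subset fine-tuned from the
pre-trained encoder vs from scratch. A candid limitation: at this scale
(hundreds of pre-training steps versus tens of millions of
patient-epochs at full scale) pre-trained representations measure no
better than random-init representations under a linear probe, both arms
remain near chance after fine-tuning on ~40 labels, and the AUPRC
difference is noise centred at zero. The protocol is implemented
faithfully and reported as computed; the weak inequality it targets holds
in expectation, not on every seed. Demonstrating a reproducible transfer
gain would need orders of magnitude more pre-training than a CPU-scale
run affords.

## Known limitations

* Visit definition is the calendar date; extracts with intra-day
  structure lose it.
* The flat baseline's CLS token borrows the age of its first kept record;
  other conventions exist.
* Dropout uses fresh R-side masks per step; runs are reproducible given
  the seed but not bit-portable across BLAS builds.
* The generator's modality mix and vocabulary sizes are scaled down from
  realistic magnitudes; chi-square-style distributional tests in the
  suite check the generator against its own parameters, not against real
  data.
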