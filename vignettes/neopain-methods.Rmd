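---
title: "Methods: neuro-symbolic assessment of neonatal pain at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuro-symbolic assessment of neonatal pain at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pain assessment in neonatal intensive care relies on observational scales
(NIPS, PIPP-R, COMFORT-B) scored intermittently by nurses, with substantial
inter-rater disagreement. `neopain` implements an automated, interpretable
pipeline over three signal modalities — cry audio (16 kHz mono), a
physiological stream (heart rate, SpO2, respiratory rate, optionally mean
arterial pressure at 100 Hz), and four facial action channels (30 fps, a
desk-scale stand-in for landmark-based video analysis) — plus context
metadata (gestational age, postnatal age, weight, ventilation status).

The architecture is a concept bottleneck: every prediction must pass through
twelve clinically meaningful concepts (C1–C4 facial: brow lowering, eye
squeeze, nasolabial furrow, mouth opening; C5–C8 vocal: cry intensity, F0
elevation, harmonic distortion, silence periods; C9–C12 physiological: HR
acceleration, O2 desaturation, respiratory irregularity, BP elevation).
Concepts feed a 12-node relational graph with learned adjacency, missing
modalities mask incident edges, two GraphSAGE layers propagate, and an
evidential Dirichlet head emits four class parameters
`alpha = ReLU(W h + b) + 1` with epistemic uncertainty `u = 4 / sum(alpha)`.
The system abstains and defers to a clinician when `u > 0.5`. An 18-rule
symbolic engine with three-tier conflict resolution turns concept
activations into templated explanations and recommendations.

## Concept detection

Each concept has a strict binary clinical rule (firing) and a graded
activation in [0, 1] used by the fusion graph. Firing follows the clinical
criteria exactly: for example C9 fires when mean clip heart rate exceeds the
2-minute pre-clip baseline by more than 15% or exceeds 180 bpm absolutely;
C10 reads the "4%" desaturation criterion as 4 percentage points (the
clinical convention for saturation); all comparisons are strict
inequalities. The graded activation is a logistic of the normalized margin,
`plogis((value - threshold) / (0.1 * threshold))`, so a value exactly at
threshold maps to 0.5. Facial concepts use the 90th-percentile channel value
over the clip as both activation and decision statistic.

Thresholds for the facial concepts are stratified by gestational age
(0.60 / 0.65 / 0.70 / 0.75 for <28, 28–32, 32–37, >=37 weeks; stratum
boundaries half-open), reflecting underdeveloped facial musculature in
extremely preterm infants; the cry F0 limit is 450 Hz preterm versus 500 Hz
at term. All thresholds ship as an editable YAML table.

Two vocal quantities have no canonical estimator and are defined here:

* **F0** is tracked by normalized autocorrelation on 25-ms frames
  (unbiased-corrected, parabolic peak refinement). Subharmonic lags of a
  harmonic source score as high as the true period, so the tracker takes
  the smallest lag within 10% of the global maximum — the standard octave-
  error guard.
* **Spectral irregularity** (part of C7) is the mean flux between
  standardized magnitude spectra of successive voiced frames, computed as
  `1 - cor(S_t, S_{t+1})`. This equals half the squared Euclidean flux
  between z-scored spectra. A plain sum-normalized flux saturates near 0.26
  even for pure noise, which would make the clinical 0.3 criterion
  unreachable; the standardized form spans [0, 1] with stationary harmonic
  sources near 0 and noise-dominated phonation near 1, so the published
  0.3 threshold separates dysphonated from modal cry.
* **HNR** is `r / (1 - r)` for the autocorrelation peak `r`, i.e. the
  harmonic-to-noise power ratio implied by the periodic-plus-noise model.

## Preprocessing

Physiological series are denoised with a Symlet-4 wavelet (level-5
periodized decomposition, soft universal threshold with the MAD noise
estimate), resampled to exactly 100 Hz, gaps shorter than 2 s linearly
interpolated, and gaps of 2 s or more marked missing rather than filled.
Audio becomes a log-power mel spectrogram (2048-point FFT, hop 1024, 128
bands, Hann window, no centre padding — frame counts are exactly
`1 + floor((n - 2048) / 1024)` — log floor 1e-10). Recordings are segmented
into 10-s clips with 50% overlap; a sub-10-s residue is dropped.

## Fusion graph and uncertainty

Concept node features are activation-scaled embeddings
`h_i = c_i * e_i + b_i`, which keep zero activations neutral. The adjacency
comes from a pairwise MLP on `[h_i; h_j; |h_i - h_j|]` with a row softmax
over `j != i` (self-edges excluded). When a modality is absent its four
concept nodes are masked: all incident edges are zeroed and surviving rows
renormalized, so the assessment is provably independent of whatever data
the dead sensor produced. Missing-ness also raises `u`: the trainer applies
modality dropout (default probability 0.15) so the evidential head learns
less evidence for masked input patterns — on the synthetic cohort mean `u`
rises from about 0.26 on complete inputs to about 0.36 with audio masked.

At desk scale the encoders (3-layer dilated TCNs for physio and
mel-spectrogram streams, a 2-layer temporal conv for the facial channels)
and the concept-node embeddings act as fixed random feature maps; the
supervised trainer fits the edge gates, GraphSAGE weights and evidential
head by minibatch SGD (cosine-annealed learning rate 0.3, 60 epochs, batch
32) on the weighted ordinal + evidential + sparsity objective. The
canonical concept path at inference is the rule-based detectors, keeping
the bottleneck fully interpretable. The evidential loss is the Brier-type
Dirichlet regression with an annealed KL-to-uniform regularizer on
misleading evidence (annealing horizon 10 epochs). The ordinal loss is the
squared difference of cumulative distributions, an earth-mover-style
penalty chosen because misclassifying moderate pain as no pain must cost
more than an adjacent confusion. One numerical note: the evidence ReLU is
kept exactly (`alpha = ReLU(e) + 1`) in the forward pass, but the backward
pass uses a leaky subgradient (slope 0.1 on the dead side) so that classes
whose evidence collapses to zero during early training can recover; all
gradients elsewhere are exact and verified against finite differences.

## Symbolic engine

Eighteen rules in four categories (6 high-confidence / tier 1, 5 moderate /
tier 2, 4 ambiguous and 3 no-pain / tier 3). Rule R1 is the canonical
high-pain exemplar — brow lowering, intense crying and an HR spike together,
with flat thresholds (0.7, 0.6, 0.5) when gestational age is unknown and
stratified ones otherwise. The remaining seventeen guards are package
configuration, authored to span the categories and overridable from YAML;
they are not clinical ground truth. Conflict resolution: any tier-1 rule
firing wins outright (highest weight picks the output); otherwise fired
tier-2 rules vote by weight with ties broken toward the higher severity;
otherwise `u` is elevated by 0.1 and the engine abstains past 0.5
("Clinician review required") or returns the no-pain baseline. Ventilated
infants get a dedicated protocol: C5–C8 suppressed, physiological
activations scaled 1.5x (clamped), a 6-rule subset replaces the standard
set, and `u` is elevated. When a trained fusion model is present the final
numeric pain level is the neural prediction; the symbolic engine supplies
tier, explanation and recommendation (and stands in fully when no model is
given) — consistent with the design premise that the symbolic layer adds
trust, not accuracy.

## Synthetic cohorts and what they show

No clinical recordings ship with the package; every experiment runs on a
generator whose constants were chosen once so that clean signals decisively
clear or miss the clinical thresholds. Signals: HR baseline ~ N(140, 10)
bpm with a pain-proportional step of +7% per level and AR(1) measurement
noise; SpO2 half-cosine desaturations of 2.6 points per level; respiratory
variability targeting CV = 0.05 + 0.09 per level over the trailing minute;
MAP offsets of 3.8 mmHg per level (recorded with probability 0.7); cries as
six-harmonic stacks (F0 = 380 + 45 per level Hz, +10 Hz at term) mixed with
turbulence noise whose share grows with level, in 1-s bursts with pauses of
0.10 + 0.08 per level seconds; facial channels as smoothed logistic means
with additive noise. Ground-truth concept labels are produced by running
the rule-based detectors on the clean (pre-measurement-noise) signals, so
at zero noise detector/label agreement is exact by construction and the
default-noise macro-F1 (about 0.97) measures pure noise robustness.

Per-infant heterogeneity is a single lognormal *reactivity* multiplier
`m = exp(0.25 * rho)`, `rho ~ N(0, 1)`, applied to every pain-driven
response. This makes pain level and reactivity confounded on any single
clip — a weak reactor in severe pain resembles a typical infant in moderate
pain — which is exactly the structure per-infant personalization must
recover from a handful of labeled clips, while leaving the population
problem learnable (held-out accuracy about 0.81 at the default mix). The
coupling 0.25 balances those two demands and was fixed with the generator.
Extremely preterm infants get an additive facial attenuation, giving the
GA-stratified thresholds real work.

What passing tests do **not** show: robustness to real sensor artifacts,
face-detection failure, inter-rater label noise beyond the federated
simulator's synthetic flips, cross-site covariate shift beyond GA skew, or
any clinical validity — the generator's cries are harmonic stacks, not
infants.

## Personalization protocol

Meta-training uses first-order MAML: the inner loop takes 10 gradient steps
at learning rate 0.005 on the per-infant adjacency offset `delta_A` and the
evidential head only (concept heads, encoders and graph weights are frozen
and bit-identical through adaptation); the outer loop updates the shared
initialization of those same parameters from query losses (12 outer passes
over 16 training infants). Support sets are stratified across observed pain
levels — the deployment analogue of labelling a spread of episodes rather
than whichever five come first. On 24 held-out infants the 5-shot uplift is
large and shot-monotone (20-shot >= 5-shot). The desk-scale inner loop
differs from a full-scale single-step recipe because one step of a small
model on five clips moves the head negligibly; 10 small steps on the
support is the package's adaptation recipe, applied identically at
meta-train and deployment time.

## Federated simulation

Eight sites with gestational-age skew (between-site spread 2.1 weeks),
severe-pain-event ratios spanning [0.15, 0.42], three sites stripped of
audio, and per-site label flips at `(1 - kappa) / 2` for kappa drawn in
[0.68, 0.84] (adjacent levels only). A pain event is a severe-pain episode
(level 3): with the default class mix the cohort-level severe rate (0.20)
lies inside the stated ratio range, so the partition can hit every site's
target exactly by deterministic count allocation without discarding any
episode — site sizes absorb the imbalance, and the targets are
right-skewed over the range so sizes stay comparable. Local updates are
DP-SGD: per-sample gradients clipped to L2 <= 1, Gaussian noise
`N(0, sigma^2 C^2)` on the sum, heavy-ball momentum 0.9 on the privatized
minibatch gradients (post-processing, so the privacy analysis is
untouched); the local learning rate decays on a cosine schedule across the
round budget. Aggregation is dataset-size-weighted FedAvg over 6 of 8
sites per round; training stops when best-validation improvement stays
under 0.5 points for 5 rounds, and the deployed model is the
best-validation checkpoint. The per-round noise scale follows the
closed-form Gaussian mechanism at the full budget
(`sigma = C sqrt(2 ln(1.25/delta)) / epsilon`, about 0.606 at epsilon = 8,
delta = 1e-5); the accountant then reports the honest cumulative epsilon
under Renyi composition of the Gaussian mechanism without subsampling
amplification — a deliberate upper bound, and the simulator flags when it
exceeds the budget (composing many rounds at the full-budget sigma does
exceed it; the flag is the point). Secure transport, SMPC and rollback
controls are out of scope and not simulated.

The non-private reference run (sigma = 0; 30 rounds of 4 local epochs,
batch 8, peak local rate 0.4) is compared against a centralized model
trained on the *pooled shard data* — the union of what the sites actually
saw, including their label flips and audio stripping. Pooling the clean
pre-partition labels instead would charge the federation for the sites'
rater noise, which no training scheme can recover; the matched pool
isolates the cost of federation itself, and the run lands within a few
accuracy points of it.

## Problem sizes and numerical choices

Experiments in the test suite and acceptance script use: a recovery cohort
of 200 infants x 4 episodes (default noise), a zero-noise exactness cohort
of 1,000 clips, a personalization cohort of 40 infants x 30 episodes (16
train / 24 evaluation), and a federated run over the recovery cohort's
training split. Training is 60 epochs at batch 32. Ties in the class
probabilities break toward the higher severity and are flagged. Degenerate
inputs are contracts, not surprises: an all-masked graph raises an
empty-graph error; fewer than 2 physiological samples raise an
insufficient-data error; an episode shorter than 10 s yields zero clips
and a warning.

## Known limitations

The facial stream is a 4-channel abstraction, not video. The 17 authored
rule guards beyond the canonical exemplar are configuration. The encoders
are untrained random feature maps at this scale, so reported accuracies
measure the concept-to-label mapping, not representation learning. The
privacy accountant is conservative by design. Ordinal and evidential loss
definitions follow the standard formulations but specific constants (KL
annealing horizon, tier-3 uncertainty increment 0.1, tier-2 unit vote
weights) are package choices.
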