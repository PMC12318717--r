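---
title: "Motor beta bursts in their large-scale network context: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor beta bursts in their large-scale network context: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstnet)
```

## The scientific problem

Resting-state MEG studies of Parkinson's disease report inconsistent
changes in motor-cortical beta activity: power and burst statistics
measured at a motor sensor or parcel mix together contributions from
several large-scale brain networks, only some of which are altered by
the disease. `burstnet` implements an analysis strategy that puts
single-region beta bursts back into their network context:

1. **Conventional burst analysis.** Motor-parcel time courses are
   band-pass filtered to the beta range (default 18–25 Hz), the Hilbert
   amplitude envelope is thresholded at a subject-specific percentile
   (default 75th), and supra-threshold runs strictly longer than one
   cycle of the band's low edge become bursts. Left and right motor
   tracks are OR-combined into one bilateral burst time course.
2. **TDE-HMM.** A time-delay-embedded hidden Markov model is fitted to
   all parcels jointly. Each hidden state is a zero-mean Gaussian over
   lag-embedded, PCA-reduced data, so a state captures a distinct
   auto- and cross-covariance signature — a transient oscillatory
   network. State dynamics are summarised by fractional occupancy (FO),
   mean lifetime, mean interval, and rate; posterior-weighted
   multitaper spectra describe each state's power and coherence.
3. **NABB segmentation.** Bursts are intersected sample-by-sample with
   the hard (Viterbi) state path, producing one network-associated
   beta-burst (NABB) track per state, plus an "other NABBs" aggregate
   over all non-sensorimotor states. Co-occurrence between bursts and
   states is tested against a circular-shift null.
4. **Group statistics.** Endpoints are contrasted between groups with
   confound-adjusted GLMs (two group indicators plus dataset, age, sex,
   education, handedness; contrast = PD − HC), with family-wise control
   by maximum-t-statistic permutation across states, cluster-based
   permutation across frequency bins for spectra, and symptom GLMs for
   the patient group.

## The state model and its assumptions

Writing $x_t \in \mathbb{R}^P$ for the parcel vector at sample $t$, the
embedded observation is
$y_t = (x_{t-L}, \dots, x_{t+L}) \in \mathbb{R}^{(2L+1)P}$ with $L = 7$
samples. Embedded columns are standardised (so no lag dominates) and
projected onto the leading $2P$ principal components of the pooled
correlation matrix. The HMM assumes

- one active state per sample, Markov transitions with a shared
  row-stochastic matrix $A$;
- zero-mean Gaussian emissions per state,
  $y_t \mid s_t = k \sim \mathcal{N}(0, \Sigma_k)$ in the reduced
  space — states differ only in covariance, i.e. in spectral content
  and cross-region coupling;
- subjects are independent sequences sharing all parameters.

Inference is full-batch EM maximising the exact likelihood; the
forward–backward recursion runs in compiled code. The model-selection
scalar reported as *free energy* is the negative log-likelihood, which
EM decreases monotonically — the test suite fails on any increase
beyond round-off. Stochastic mini-batching, used by some toolboxes for
very large cohorts, is a scalability device and is not implemented;
desk-scale cohorts fit in memory. Multiple seeded runs are fitted and
the lowest-free-energy run kept (ties broken by lowest seed).

Two inference conventions were genuinely open and are resolved as
follows. The hard state path used for occupancy tracks is the Viterbi
(maximum a-posteriori sequence) path. The per-sample argmax of the
forward–backward posterior is the simpler convention and agrees with
Viterbi on occupancy (FO), but its *event segmentation* is noisy: brief
posterior excursions fragment or bridge visits, and on synthetic
cohorts with planted dynamics this subject-level segmentation noise
roughly halves the group t-statistic of event-count endpoints (state
and NABB rates, intervals) at desk-scale recording lengths, while
leaving FO contrasts intact. Because Viterbi respects the learned
transition structure globally, its visit structure is markedly
cleaner; it is therefore the default for all track-based metrics, with
the argmax path retained alongside (`path_argmax`) and posterior-mass
FO always reported for comparison. Second, posteriors are padded at
each end by the $L$ trimmed samples using the subject's mean posterior
(the path by its first/last state), with padded samples flagged and
excluded from all metrics.

## Spectral estimation choices

- **Welch**: Hann window, 500 samples with 250 overlap (0.5 Hz
  resolution at 250 Hz); one-sided density normalised so integrated
  power equals signal variance (~1 after z-scoring, hence "relative
  power").
- **Multitaper**: 7 Slepian tapers on non-overlapping 2-s windows
  (time–bandwidth 4), 1–45 Hz at 0.5 Hz. DPSS tapers are computed from
  the standard symmetric tridiagonal eigenproblem. Per-sample weights
  (posterior probabilities, or burst on/off indicators) enter as
  window weights equal to the mean weight inside the window — an
  unbiased aggregation given that no sub-window weighting convention is
  canonical. With one-hot weights the estimator reduces exactly to a
  segment-wise multitaper over the windows belonging to one state, a
  property the test suite checks against an independent oracle at
  1e-6 relative tolerance.
- **Coherence networks**: band-averaged coherence thresholded at the
  97th percentile of the off-diagonal edge distribution; ties at the
  threshold are kept.
- Per-state **beta-power change** subtracts the unweighted mean across
  states at every frequency before band-averaging over the motor
  parcels (16–25.5 Hz), so changes sum to zero across states.

## Burst conventions

The burst threshold is computed per subject *and per parcel* before
bilateral combination. "Longer than one cycle" of the 18 Hz band edge
is read as a strict inequality on duration: a run qualifies with at
least `floor(fs/18) + 1 = 14` samples at 250 Hz (56 ms > 55.6 ms).
Masked (artefact) samples can never belong to a burst; a burst
truncated at a mask boundary is kept when its retained portion still
satisfies the duration rule, avoiding the loss of genuine events at
artefact edges. The inter-parcel overlap statistic is
intersection-over-union (intersection over each single parcel is also
attached), since the literature's reported overlap percentage does not
pin down a denominator.

## Preprocessing

Band-pass 1–45 Hz (zero-phase FIR, Hamming design, transition
bandwidth 2 Hz — > 50 dB stop-band per pass), integer-factor
downsampling to 250 Hz, then 10-s segments are tested for exaggerated
variance or kurtosis with the generalized extreme studentized deviate
(GESD) test at $\alpha = 0.05$ and an upper bound of 20% outlier
segments; variance- and kurtosis-flags are unioned (the conservative
reading of "variance or kurtosis"), each metric being the across-parcel
mean of a per-parcel segment statistic. A trailing partial segment is
never tested and stays retained. Standardisation runs *after* masking,
in the order filter → downsample → GESD → z-score; the order is
configurable because the original ordering convention is not
documented anywhere authoritative.

## The synthetic cohort generator

Real resting-state MEG of this kind cannot be redistributed, so the
package ships a generator that plants known structure:

- **Cohort**: 36 controls, 28 patients, 39 parcels at 250 Hz, 8-minute
  recordings, K = 8 states — the default `cohort_spec()`.
- **Dynamics**: geometric dwell times with mean lifetime 60 ms; with
  uniform entry weights each state has FO 1/K (12.5% at K = 8) and
  intervals of ~420 ms, matching the empirically reported ranges
  (FO ≈ 11–16%, lifetimes 50–90 ms, intervals 460–778 ms).
- **Group effect**: the patient transition matrix scales the entry
  probability *into* state 1 so that its stationary FO drops by 20%
  (`pd_fo_scale = 0.8`; the scale solves the stationary equations
  exactly). Entry-rate reduction lowers FO and rate and lengthens
  intervals while leaving lifetimes unchanged — the qualitative
  pattern reported for the sensorimotor network. Per-subject
  log-normal jitter (sd 0.2) on entry weights creates realistic
  between-subject FO variability.
- **Signatures**: state 1 is a bilateral "sensorimotor" state carrying
  16–25.5 Hz band-limited power on the two motor parcels; state 2 is a
  widespread broadband state covering all parcels (including motor),
  which sustains motor beta bursts outside sensorimotor activations so
  that the overall burst drive stays roughly constant while its
  network composition shifts; remaining states are narrowband
  non-motor networks. Oscillations are rendered as band-limited
  Gaussian noise (frequency-domain shaping with 1 Hz raised-cosine
  edges) rather than fixed-phase sinusoids, matching the stochastic
  character of resting oscillations; a configurable fraction (default
  0.7) of each state's oscillatory variance comes from a carrier
  shared across parcels, creating within-state coherence. Amplitude
  (default 2 background-noise SDs at weight 1) is a free parameter, as
  no empirical per-state SNR is available to fix it.
- **Covariates** are sampled independently of group by default
  (confounding can be switched on); symptom scores exist for patients
  only and can optionally be coupled to the planted sensorimotor FO.

What the generator does **not** emulate: volume conduction and
leakage, 1/f background spectra, non-stationary artefacts, spatially
graded parcel covariance, or asymmetric symptom expression. Passing
tests therefore demonstrate the correctness and sensitivity of the
pipeline under its own model assumptions, not performance on real
recordings.

## Problem sizes used by the test suite

The shipped tests exercise the full pipeline at sizes chosen for a
single desk CPU; these are the package's own test-design choices:

- HMM-correctness fixtures use 3 states with strongly separated
  spectral signatures (10/20/35 Hz, amplitude 2.5, 100 ms lifetimes) —
  a strong-separation regime that probes inference correctness rather
  than detection power at realistic SNR.
- End-to-end effect-recovery replicates use the full cohort size
  (36 + 28) with 7 parcels, 90-s recordings, and K = 4 planted and
  fitted states (uniform occupancies, ~180 ms intervals), an ensemble of
  two EM runs of up to 12 iterations each (degenerate runs excluded by
  free energy; metrics averaged after state matching),
  and 500-permutation GLMs, repeated over 20 seeds. Event-count endpoints (rates, intervals) are the most
  segmentation-sensitive quantities, and 90 s is the shortest
  recording at which their group contrasts are reliably recovered at
  this cohort size.
- The robustness harness plants 8 states in 32 subjects (40 s, 8
  parcels, a 30% occupancy reduction to keep sign-replication
  well-powered at a third of the cohort size) and refits at
  K ∈ {8, 10, 12} with 3 seeds each, checking that the
  sensorimotor-state contrast signs replicate across all nine fits.
- Calibration suites follow the classical sizes: 500 null cohorts ×
  1000 permutations for the max-t family-wise error, 200 × 200 for the
  cluster test, and 200 repetitions of the 40-shift overlap null.

`scripts/acceptance.R` reruns the full pipeline on one 64-subject
cohort at these desk-scale settings and emits its headline numbers as
JSON.

## Numerical choices and degenerate inputs

- EM convergence: relative free-energy change below 1e-6 or 15–50
  iterations; non-convergence returns a flagged fit rather than an
  error. Singular state covariances are ridge-regularised with an
  escalating jitter (recorded on the fit).
- Initialisation assigns random contiguous blocks of samples to states
  and fits covariances from them. Robustness against the occasional
  degenerate start (two networks merging) comes from independent
  repeated runs (`n_runs`, lowest free energy kept, and in the pipeline
  an ensemble average over comparable-evidence runs). A short-start
  mode that pre-scores several initialisations on half the subjects
  exists (`n_starts`) but is off by default: scoring partial fits by
  early free energy proved a poor predictor of converged quality and
  the half-data phase slows subsequent convergence.
- Degenerate GLM endpoints (zero residual variance with a non-zero
  contrast) report a capped t and a flag; subjects with undefined
  endpoints (e.g. lifetime of a never-visited state) are dropped
  listwise per endpoint with the count logged.
- Permutation p-values use the add-one convention
  $(1 + \#\{null \ge obs\})/(n_{perm} + 1)$, bounded away from zero.
- The circular-shift null draws offsets uniformly at least one second
  away from identity at both ends, so near-identity shifts cannot
  deflate the null.
- Cluster-forming threshold: per-bin two-sided $p < 0.05$ at the
  design's residual dof; the cluster statistic is the summed t (the
  mean t is reported descriptively alongside).
- Shuffling for group permutation tests is unrestricted; stratified
  variants can be added behind the same interface.

## Known limitations

- The Gaussian TDE-HMM shares one transition matrix across subjects;
  individual deviations in dwell structure are shrunk toward the
  pooled dynamics, which attenuates rate (event-count) contrasts more
  than occupancy contrasts on short recordings. A related compression
  is adaptive: subjects with more frequent visits have shorter gaps,
  which the ±L-sample embedding window bridges more often, so
  event-count group contrasts are systematically attenuated relative
  to occupancy contrasts. In consequence the joint
  recovery of *all* planted group effects (occupancy, rate, interval,
  NABB occupancy/rate, other-NABB occupancy, power coupling) depends
  on recording length: roughly 17 of 20 simulated cohorts at 90-s
  recordings, 19 of 20 at 120 s, with the occasional miss being a
  single marginal event-count endpoint on a weak cohort draw.
  Occupancy endpoints are reliable throughout.
- NABB segmentation uses per-sample intersection. A whole-burst
  dominant-state assignment is a plausible alternative reading of
  "segmenting bursts by network"; intersection preserves exact
  occupancy additivity, which the identities in the test suite rely
  on, and is therefore the default.
- The directed overlap test contrasts each subject's empirical overlap
  against that subject's mean shifted-null overlap with a paired
  one-sided t-test, Bonferroni-corrected across states. Pooling
  subject × permutation nulls into one distribution is a defensible
  alternative; the per-subject-mean construction keeps the test's
  units at the subject level.
- Free energy here is an exact negative log-likelihood, not a
  variational bound; comparisons are only meaningful between runs with
  equal K.
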