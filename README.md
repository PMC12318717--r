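# burstnet

Beta bursts in their large-scale network context, for resting-state
parcellated M/EEG.

## The problem

Motor-cortical beta activity is a leading candidate marker for
Parkinson's disease, but single-region analyses mix together signal
from several large-scale brain networks, and group differences can
cancel. `burstnet` implements a network-contextual analysis of
motor-cortical beta bursts for parcel-space resting-state recordings:

- **Conventional bursts** — 18–25 Hz Hilbert envelopes of the two
  motor parcels, thresholded at the subject's 75th percentile; runs
  longer than one 18 Hz cycle become bursts; left/right tracks are
  OR-combined. Dynamics are summarised as fractional occupancy (FO),
  mean lifetime, mean interval and rate, with the exact identity
  `FO = rate × mean lifetime`.
- **TDE-HMM networks** — a time-delay-embedded (±7 samples) hidden
  Markov model with zero-mean Gaussian states on PCA-reduced embedded
  data (2 × parcels components), fitted by EM with multi-run
  selection on the negative log-likelihood. States are transient
  oscillatory networks; posterior-weighted multitaper spectra (7
  Slepian tapers, 2-s windows, 1–45 Hz at 0.5 Hz) and 97th-percentile
  coherence networks describe them.
- **NABBs** — bursts are segmented by the co-occurring network state
  (per-sample intersection with the hard state path) into
  network-associated beta bursts; an "other NABBs" aggregate pools
  all non-sensorimotor states. Burst–state co-occurrence is tested
  against a circular-shift permutation null with directed t-tests and
  Bonferroni correction.
- **Group inference** — confound-adjusted GLMs (group indicators +
  dataset, age, sex, education, handedness; contrast PD − HC) with
  max-|t| permutation pooling across states, cluster-based
  permutation for spectra, symptom-score GLMs, and the per-frequency
  FO→spectrum projection.

Because resting-state patient MEG of this kind is not publicly
archivable, the package ships a synthetic cohort generator
(`cohort_spec()` / `generate_cohort()`) that plants Markov network
states with known oscillatory signatures, a configurable reduction of
sensorimotor-network occupancy in the patient group, covariates and
symptom scores — so the entire pipeline is testable end to end with
ground truth.

## Worked example

```r
library(burstnet)

spec <- cohort_spec(n_hc = 36, n_pd = 28, n_parcels = 7,
                    duration = 120, n_states = 4,
                    pd_fo_scale = 0.8,   # -20% sensorimotor FO in PD
                    seed = 1)
cohort <- generate_cohort(spec)
cfg <- pipeline_config(hmm_K = 4, hmm_runs = 2, hmm_max_iter = 12,
                       n_perm = 1000, n_perm_shift = 200,
                       preprocess = FALSE)
res <- run_pipeline(cohort, cfg, seed = 1)

sm <- res$hmm$sm_state        # state with maximal motor beta change
res$hmm$glms$fo$t[sm]         # -6.94   sensorimotor FO, PD - HC
res$hmm$glms$fo$p[sm]         #  0.001  (max-t permutation across states)
res$hmm$glms$rate$t[sm]       # -6.42   fewer visits per second in PD
res$hmm$glms$mean_interval$t[sm]  #  7.00   longer gaps between visits
res$nabb$glms$fo$t[sm]        # -6.48   sensorimotor NABBs rarer in PD
res$nabb$glms$rate$t[sm]      # -4.76
res$nabb$other_glm$t          #  6.42   other-network NABBs more frequent
res$hmm$fo_beta_cor$r         #  0.89   FO ~ motor beta power across subjects
mean(res$nabb$overlap$empirical[, sm])  # 53.1% of burst samples in SM state
```

The planted 20% occupancy reduction (recovered FO 26.1% in HC vs
22.9% in PD here) comes out as a significant FO and rate decrease
with lengthened intervals for the sensorimotor network and for
sensorimotor NABBs, an *increase* for the other-network NABBs, and a
positive subject-level correlation between sensorimotor FO and static
motor beta power — while the conventional, network-blind burst
metrics show no group difference at all
(`min(res$bursts$glms$p)` = 0.62): the dissociation the package
exists to expose. The static motor spectra show the matching
beta-band cluster with decreased power in the patient group (mean
cluster t = −3.82, peak 20.5 Hz, p = 0.001).

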