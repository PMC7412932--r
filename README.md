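# rsvpcar

Cross-subject ERP brain–computer interface analysis with correlation-ranked
donor selection.

## The problem

ERP spellers detect the symbol a user attends by finding the P300 — a
positive EEG deflection ~300–500 ms after a rare, attended stimulus — in
single-trial responses. In a rapid serial visual presentation (RSVP)
speller the 26 letters flash one at a time (200 ms on, 100 ms off), and
each letter selection spans several complete A–Z rounds. Classifiers
trained on one user transfer poorly to another because P300 latency,
amplitude and topography are individual, yet collecting labeled calibration
data from every new user is exactly what a practical BCI wants to avoid.

`rsvpcar` is for researchers studying that trade-off. Its core is the
**Correlation Analysis Rank (CAR)**: given a new user's averaged target ERP
`ŝ(n) = (1/M) Σᵢ xᵢ(n)` from a short calibration segment, every previously
recorded subject ("donor") is ranked by the Pearson correlation

    r = 1/(n−1) Σᵢ ((Xᵢ − X̄)/s_X) ((Yᵢ − Ȳ)/s_Y)

between the vectorized ERPs, and the top-N donors' labeled epochs form the
training set for a shrinkage-LDA target/nontarget classifier
(`w ∝ Σ̂⁻¹(μ₁ − μ₀)`, Ledoit–Wolf-regularized covariance). Performance is
measured as single-epoch AUC against a random-donor baseline with a paired
t-test, and at the speller level as symbol accuracy `P` and information
transfer rate

    ITR = [log₂N + P log₂P + (1 − P) log₂((1 − P)/(N − 1))] / T  bits/min.

The package also provides cohort-level ERP similarity statistics (angle
cosine with threshold matching, `cos θ = a·b/‖a‖‖b‖`), a standard ERP
preprocessing chain (zero-phase 0.1–30 Hz band-pass, decimation to 200 Hz,
[−200, 800) ms epochs with [−200, 0) ms baseline correction, channel
selection), and a seeded synthetic multi-subject cohort generator
(subject-specific Gaussian-bump P300 over 1/f noise, clustered
inter-subject structure) so every stage is testable without recordings.

## Worked example

```r
library(rsvpcar)

# A scaled-down session: 26 symbols, 8 blocks x 4 trials x 2 rounds.
paradigm <- paradigm_config(n_symbols = 26, rounds_per_trial = 2,
                            trials_per_block = 4, n_blocks = 8)
spec <- cohort_spec(n_subjects = 12, n_clusters = 2, seed = 42,
                    paradigm = paradigm, cluster_latencies = c(320, 440))
cohort <- generate_cohort(spec)
cohort
#> <erp_cohort> 12 subjects in 2 clusters (rsvp style), seed 42
#>   per subject: 1664 epochs x 6 channels x 200 samples @ 200 Hz

# How similar are the subjects' averaged target ERPs? (matches = number of
# other subjects with cosine > 0.5)
erps <- lapply(cohort$subjects, coherent_average)
match_counts(erps, threshold = 0.5)$counts
#> S01 S02 S03 S04 S05 S06 S07 S08 S09 S10 S11 S12
#>   0   5   0   3   0   4   0   5   0   4   0   5

# Cross-subject decoding: CAR-ranked donors vs random donors (N = 5), with
# 2 calibration blocks per test subject.
car  <- evaluate_model(cohort, "car",    N = 5, calibration_blocks = 2, seed = 7)
rand <- evaluate_model(cohort, "random", N = 5, calibration_blocks = 2,
                       reps = 5, seed = 7)
round(c(car = mean(subject_auc(car)), random = mean(subject_auc(rand))), 3)
#>    car random
#>  0.785  0.732
compare_models(car, rand)
#> <paired_comparison> car vs random over 12 test subjects
#>   mean AUC difference +0.0529, paired t = 7.210906, p = 1.728275e-05

# Speller-level information transfer rate at the full paradigm's timing
# (5 rounds x 26 symbols x 300 ms SOA = 0.65 min per selection).
compute_itr(26, 0.9, selection_time(paradigm_config()))
#> <itr_result> N = 26, P = 0.900, T = 0.65 min: 3.767 bits/selection, 5.795 bits/min
```

Reading the output: subjects in one cluster (the even ids, whose
cluster center drew a strong ~6 µV P300) match 3–5 of their 5 cluster
mates at cosine 0.5, while the other cluster's center drew a weak
~2.5 µV component whose 64-epoch averages stay noise-dominated and match
nobody — inter-subject ERP similarity is structured and SNR-dependent,
which is what donor ranking exploits. CAR's mean AUC of 0.785 beats random selection's 0.732 with a
paired p ≈ 2e−5: ranking donors by calibration-ERP correlation buys real
cross-subject accuracy at matched training-set size.

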