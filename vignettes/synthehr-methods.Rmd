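---
title: "Generating and auditing synthetic diabetes cohorts: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and auditing synthetic diabetes cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`synthehr` implements a complete generate-and-audit loop for longitudinal
diabetes cohorts: a ground-truth simulator, a dual adversarial autoencoder
(DAAE) over sequences of set-valued visits, a refinement pipeline for raw
generated records, and validation suites for statistical fidelity, privacy,
algorithmic sex bias, trajectory plausibility, and train-synthetic/test-real
(TSTR) predictive utility. This vignette explains the models and the design
decisions behind them, in the order a user meets them.

## 1. The data model

A patient record is a sex plus an ordered sequence of visits; each visit is
an age (years, one decimal) and a *set* of diagnosis codes. One code is the
diabetes anchor (every analysable record carries it), one is the chronic
kidney disease (CKD) endpoint. Codes are opaque strings — no terminology
validation or ontology mapping is attempted.

All column-wise metrics operate on the flattened one-row-per-patient table
(`flatten()`): sex (categorical), age at the first anchor visit
(continuous), and per comorbidity a presence flag (boolean) plus the age of
the first visit carrying the code (continuous, missing when the flag is
false), plus the visit count. This schema covers exactly the information the
sequence encoding carries, which is why it was chosen as the metric
substrate; a flags-only variant (`include_ages = FALSE`) is available for
users who consider first-diagnosis ages out of scope for tabular comparison.
The schema travels with the table as an attribute so metrics never guess
column types.

Missing sex is serialized as an explicit `null` in the JSON-lines format. It
is never treated as a third sex category by the sex-stratified audits; the
refinement pipeline removes such records before any refined-cohort metric
runs, and on raw cohorts the adherence metrics treat missing as valid only
where the real data also contains missing values.

## 2. The ground-truth simulator

`simulate_cohort()` is a first-class component, not a test fixture: every
audit in the package is validated by recovering parameters that the
simulator planted. The generative model per patient:

* sex ~ Bernoulli(`female_fraction`, default 0.5 — a neutral default chosen
  because the audits measure *departures* from the real composition, not the
  composition itself);
* age at diabetes diagnosis ~ Normal(60.56, 13.83) truncated below at 18
  years — the published demographic anchors of a large adult diabetes
  cohort;
* each comorbidity is assigned with probability
  `plogis(qlogis(base_prevalence) + log(female_multiplier)·I(female) +
  log(age_profile[band]))`, where the band (young < 45, mid 45–65, old > 65)
  is taken from the disease's drawn onset age. Drawing the onset age first
  and conditioning the assignment on its band is what produces the
  age-dependent sex difference in diagnosis rates — with the default catalog,
  women run higher rates in early adulthood and late life and men in middle
  age — while keeping the true per-sex prevalence available in closed form
  (band probabilities are Normal tail areas; see `ground_truth()`);
* the endpoint follows `logit P(CKD) = intercept + age_coef·dm_age +
  Σ risk_weight·flag` over diseases present *before* the diabetes age, and
  its onset is placed uniformly 0.5–15 years after the diabetes age, so it
  is always temporally consistent but the prediction-stage exclusion rules
  still have controllable hit rates on corrupted cohorts;
* visits group all onsets sharing the same rounded (1 decimal) age and are
  sorted ascending; the calendar year of diagnosis is uniform over
  2003–2022.

The default catalog (`default_diseases(80)`) spans prevalences geometrically
from 0.35 down to 5×10⁻⁴, cycling onset-age means over early/middle/late
adulthood, with mild sex multipliers and a shared sex-specific age profile.
Co-assignment is conditionally independent given sex and age: correlations
arise only through these shared factors, because the audits need a *known*
truth much more than they need realism. Pairwise dependence can be induced
(or destroyed) explicitly via the bias injector. Consequences for
interpretation: a passing identity or recovery test shows the audit
machinery is correct and calibrated; it does not certify behaviour on real
EHR data, whose code-dependency structure, coding artefacts, and visit
patterns are richer than anything this simulator emits.

`inject_bias()` plants failure modes with known magnitude: relabelling a
known fraction of male records as female (demographic shift), deleting
occurrences of codes below a prevalence threshold (mode collapse on sparse
patterns), reassigning one code's occurrences to random patients
(decorrelation), shifting all non-anchor onset ages for one sex (delayed
trajectories), and blanking sex or anchor fields (refinement fodder). An
all-zero configuration returns the input unchanged, which the tests assert
as an identity.

## 3. The generator

`daae()` trains a dual adversarial autoencoder on padded token sequences
(`encode_cohort()`): each visit is a multi-hot over diagnosis codes plus one
age-band token (`floor(age / age_band_width)`), the sex token is prepended
in the first visit, and an end-of-sequence token closes the record.
Sequences are truncated at `max_len` (dropping the oldest tail) and padded
under an explicit mask.

Architecture (the smallest faithful instantiation of "dual adversarial",
i.e., adversarial in both latent and data space):

* visit-set embedder: one `tanh` layer from the multi-hot to a dense vector;
* sequence encoder: a GRU consuming the embedded visits *in reverse order*
  (so the first visit, which carries the sex token, is adjacent to the final
  hidden state) followed by a linear map to the latent code;
* latent standardization: the raw code is standardized per batch (running
  statistics at inference). This pins the decoder's input scale to that of
  the standard-normal prior it will be sampled from; the latent critic then
  only has to correct the *shape* of the distribution, which is a far easier
  adversarial problem at small step counts;
* decoder: a GRU initialized from the latent code; its per-step input is the
  previous visit's embedding concatenated with a one-hot step position.
  Position-locked tokens (sex at step 1, end-of-sequence) would otherwise
  regress toward the strongly negative cross-step marginal for latent draws
  off the training manifold;
* critics: two-hidden-layer ReLU networks with sigmoid heads; non-saturating
  adversarial losses.

Each epoch runs, per minibatch: (a) a reconstruction step minimizing
per-token binary cross-entropy with a positive-class weight (`pos_weight`,
default 5 — visit vectors are sparse multi-hots, and without up-weighting,
all probabilities settle below the 0.5 activation threshold); (b) the latent
critic step (prior draws vs encoder outputs) followed by a gentle encoder
update toward the prior; (c) the data critic step (pooled real visit
embeddings vs pooled reconstructed ones) followed by a generator update.
Three further stabilizers matter at desk scale and are defaults: Gaussian
noise on the standardized latent code during reconstruction
(`latent_noise_sd = 0.6`, renormalized so the decoder-input variance stays
at 1 — this trains the decoder on the region the prior will actually sample);
small adversarial weights (0.02 each — the latent-generator update is the
main destabilizer of 50-epoch runs); and a global gradient-norm clip of 1 on
every optimizer step. Training runs a fixed number of epochs with no early
stopping, and is bit-reproducible given the seed, configuration and input
order on a fixed platform.

With `dp_enabled`, the reconstruction (generator/encoder) update switches to
per-sample gradients clipped at `dp_clip_norm` with Gaussian noise
`dp_noise_multiplier × dp_clip_norm` added to the sum. This reproduces the
mechanics of differentially-private optimization; **no formal (ε, δ)
accountant is implemented**, so no certified guarantee is claimed.

Sampling (`sample_cohort()`) draws latent codes from N(0, I) and decodes
greedily: tokens activate at probability ≥ 0.5, the sequence ends at the
end-of-sequence token or at `max_len`, age-band tokens map to band
midpoints (all raw labels are retained on the visit), and sex is the sex
token emitted with the highest probability anywhere in the record (missing
when none is emitted). The output is deliberately a *raw* cohort — it may
lack anchors, sexes or ages, contain empty visits, repeat chronic codes, or
carry several age labels in one visit — because repairing those is the
refinement pipeline's job.

Desk-scale defaults (50 epochs, 5-year bands, latent dimension 8, batch 64
in the tests) are sized for hundreds of training records and minute-scale
CPU runs; production-scale settings (500 epochs, 1-year bands, batch 256)
remain configurable. The validation suite trains on 200 simulated patients
for 50 epochs and samples 1000 records; at that size, training takes well
under a minute on one CPU core.

## 4. Refinement

`refine_cohort()` applies five rules in a fixed order: (1) drop records
lacking the anchor code or a sex; (2) drop visits that are empty or carry
only age information; (3) keep only the first visit occurrence of each
chronic code (by default every vocabulary code counts as chronic; a code
subset can be supplied); (4) where a visit carries several age labels, keep
the maximum; (5) impute a missing visit age as the arithmetic mean of the
adjacent visits' ages. Two boundary cases are not fixed by the rule set and
were decided as the minimal extension preserving monotonicity: a missing age
at the first (last) visit copies its single neighbour, and a record whose
every visit still lacks an age is dropped and counted. Missing-age
imputation runs after the empty-visit rule so age-only visits never donate
their age twice. The pipeline is idempotent, and the discard report's
fractions are exact ratios of the counted records (`fraction_total_discarded
= 1 − n_out/n_in` by construction).

`refine_for_prediction()` adds the two prediction-stage exclusions:
non-ascending visit ages, and an endpoint age before the anchor age.

## 5. Fidelity metrics

All scores are re-implemented from their definitions and cross-checked in
the test suite against independent brute-force oracles (exhaustive ECDF
scans, half-sum frequency distances, hand-built contingency tables,
path-enumeration DTW, pairwise match scans). Decisions that the definitions
leave open, and how they were fixed:

* **CrSS** — "1 minus the average absolute correlation difference" can go
  negative; the difference is divided by 2 (its maximum) so the score lives
  in [0, 1] like every other adherence-style score.
* **CtSS** — continuous columns are discretized into 10 equal-width bins
  with edges from the *real* data; Cramér's V of a degenerate (single-level)
  table is defined as 0, so two degenerate tables agree perfectly.
* **SWD** — flags enter as 0/1, categoricals as one-hot over real levels,
  missing continuous values are imputed to the real column median; features
  are min-max normalized by real bounds, zero-range features are dropped;
  1000 uniform random directions by default, with the exact 1-D
  Wasserstein-1 (integrated |ECDF difference|) along each.
* **CoC** — precedence is counted on *visit indices* with strict
  inequality: f(a→b) is the fraction of all patients in whom a's first
  occurrence is at a strictly earlier visit than b's; same-visit
  co-occurrence counts for neither direction, and the anchor code is
  excluded. The score is the Pearson correlation of the real and synthetic
  f-vectors over ordered pairs and is flagged undefined when either vector
  is constant.
* Missing values are a valid category/range member only where the real
  column itself contains missing values (adherence scores), and are removed
  per column before the KS statistic.

Every bounded metric is exactly 1 (SWD exactly 0) when the synthetic table
is a row-permuted copy of the real one, and all metrics are invariant to row
order; both properties are tested.

## 6. Privacy metrics

* **NRS** — a synthetic row "matches" a real row when all discrete values
  coincide (missing positions included) and every continuous value is within
  0.01 of the real column *range*; the tolerance is interpreted as relative
  to the range, the convention of reference implementations of this metric.
  The report includes the mean diagnosis count of matched rows, a diagnostic
  for the common case that matches are trivially short records.
* **DPS / DPeS** — a correct-attribution attack: for each target row, find
  synthetic rows agreeing on the keys (default: sex and age at diabetes,
  continuous keys within 1% of range) and predict the sensitive attribute by
  majority vote, falling back to the modal real category. The full variant
  uses the modal-category baseline; the estimate variant repeats the attack
  on random subsamples and uses the uniform-random-guess baseline. The score
  `1 − max(0, acc_attack − acc_base)/(1 − acc_base)` is clamped to [0, 1],
  and a single-category column scores 1 by definition. The sensitive
  attribute defaults to endpoint status and is configurable.
* **MIA** — a zero-knowledge attacker scoring each candidate by the negative
  distance to its closest synthetic record under a mixed-type distance
  (range-normalized absolute difference capped at 1 for continuous columns,
  both-missing = 0 and one-missing = 1, 0/1 mismatch for discrete columns,
  averaged over columns). Distance-to-closest-record is the canonical
  zero-knowledge attacker; the kernel is implemented in C++ because the
  calibration runs millions of row pairs. Because an attacker score can be
  arbitrarily oriented, results are reported with AUROC* = max(a, 1 − a) and
  Δ = |a − 0.5|; an AUROC below 0.5 signals an inverted ranking, not reduced
  leakage.

## 7. Bias, trajectory, and predictive-utility audits

**Sex bias.** The sex bias delta is the percentage-point difference in
female representation (synthetic − real). Per-disease tables report
prevalence by sex in both cohorts, the female−male gap, the per-sex KS
statistic on age at first diagnosis among the diagnosed, and the
sex-specific shift (synth − real in women) − (synth − real in men). Feature
amplification is the across-run Pearson correlation between that shift and
the run's sex bias delta. Sex-signal portability fits an L2-penalized
logistic model (ridge at unit inverse-strength, features standardized by
source-cohort statistics, missing ages imputed to the source median) on one
cohort and scores AUROC on the other, in both directions. Effect sizes use
Cohen's d (pooled SD) for continuous columns and Cohen's h (arcsine) for
proportions — the conventional standardized pair; the choice is a package
decision, not prescribed by the metric definitions. The prevalence-error
curve reports per-disease relative errors |p_s − p_r|/p_r and, at thresholds
{0, 0.013, 0.05}, the prevalence correlation and relative-error RMSE over
diseases at or above the threshold.

**Trajectories.** Diagnosis rates per person are computed by sex within
5-year age bins over [18, 100) with an open-ended top bin; the series of
interest is the female−male difference with a 95% Wald interval. Because
per-person rates can exceed 1, the Wald variance uses the Poisson
approximation `c_f/n_f² + c_m/n_m²` rather than a binomial one. Cohorts are
compared by *exact* dynamic-programming DTW (local cost |a−b|, symmetric
match/insert/delete steps, no window, un-normalized cumulative cost): the
series have at most 17 points, so the approximate-DTW shortcut common for
long series would buy nothing and exactness enables enumeration oracles in
the tests. DTW distances are therefore comparable across replicas within
this package, not numerically interchangeable with approximate
implementations. Bins without any event in either cohort are dropped
pairwise before the comparison.

**TSTR.** `build_task()` builds the endpoint-prediction task: features are
sex, age at diabetes, and per-comorbidity flags/first-diagnosis ages
restricted to the pre-anchor history — a comorbidity first diagnosed after
the anchor age contributes neither flag nor age, and a perturbation oracle
in the tests verifies that deleting all post-anchor visits changes no
feature. Missing ages use a −1 sentinel with the flag as companion, which
additive tree/bin models handle cleanly. Scenarios: real, synthetic, and
hybrid = plain concatenation (no reweighting or deduplication). Each
scenario runs repeated k-fold cross-validated fits, each evaluated on the
fixed real test set, plus one full-pool fit. The default classifier is a
cyclic-boosted additive model: features are binned (midpoint edges around at
most 8 quantile cut points — coarse bins keep per-bin Newton estimates
stable at moderate n), and boosting sweeps cyclically over features with
damped per-bin Newton updates on the logistic loss; global importance is the
mean absolute score contribution. Importance rankings break ties
lexicographically for determinism. The hyperbolic weighted Kendall tau uses
additive weights w(r) = 1/(1+r) on zero-based ranks, an exchanged pair
contributing w(i) + w(j), normalized by the total pair weight and
symmetrized by averaging over both reference rankings; with equal weights it
reduces to the unweighted Kendall tau (tested against `cor(method =
"kendall")`).

**Designs.** SSMR fixes one train/test split and varies the generator seed;
MSSR varies the split with one generator run each. Splits are patient-level
and stratified by endpoint status — stratification is a package decision
made to stabilize the cross-validated fits, not part of the design
definitions. Metrics aggregate as median (min–max) across runs.

## 8. Validation strategy and problem sizes

The test suite validates each metric against an independent brute-force
oracle on ≥100 randomized instances, checks the identity suite (all scores
perfect on a row-permuted copy), and recovers injected bias magnitudes:
a 3 pp female shift within the 99% binomial band at n = 20 000, rare-code
dropout through the prevalence-error RMSE ordering across thresholds, and a
10-year trajectory delay through the DTW ordering against an independent
draw. The Wald interval's 95% coverage is verified to fall in 93–97% over
500 equal-rate replicates. The TSTR harness is checked against the
Bayes-optimal AUROC of the generative model (computed by a 10⁶-draw Monte
Carlo from the known endpoint model) within ±0.03 at n = 20 000 with a
20-disease catalog, and hybrid augmentation with an independent simulator
draw is required to add nothing beyond cross-validation noise — the
data-saturation property; the 20-disease task was sized precisely so that
the real training pool already saturates the classifier. The generator smoke
test (200 patients, 50 epochs, 1000 samples) requires falling reconstruction
loss, ≥50% refinement survival, and bit-identical resampling under a fixed
seed. Cross-validation in the tests uses 2 repeats × 5 folds rather than the
full 10 × 10; the repeats/folds counts are compute knobs that do not change
any estimand.

## 9. Known limitations

* The simulator's conditional-independence structure understates real
  comorbidity dependence; audits validated here are calibrated, but their
  power against real-data pathologies may differ.
* The DAAE at desk scale (tens of optimizer steps per component) is a
  faithful miniature, not a statement about converged behaviour at
  production scale; in particular its fidelity scores on small cohorts are
  dominated by optimization, not model capacity.
* DP support reproduces clipping-plus-noise mechanics without a privacy
  accountant; treat `dp_enabled` as an experimentation switch, not a
  guarantee.
* The membership attack is the zero-knowledge distance attacker only; no
  shadow-model, record-linkage, or subpopulation-targeted attacks are
  implemented.
* DTW distances are exact for this package's short series and are not
  numerically interchangeable with approximate-DTW implementations.
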