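---
title: "Methods: temporal causal structure of ICU physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal causal structure of ICU physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures implemented in
`neurocausal`, the assumptions behind them, and the design decisions taken
where more than one reasonable choice existed. The package analyses
minute-resolution multivariate physiologic records of the kind produced by
invasive multimodality monitoring after severe brain injury (subarachnoid
hemorrhage in particular): systemic channels such as heart rate (HR), mean
arterial pressure (MAP) and end-tidal CO2, and brain channels such as
intracranial pressure (ICP), brain tissue oxygen (PbtO2) and regional
cerebral blood flow.

## Pipeline overview

```{r, eval = FALSE}
library(neurocausal)

specs <- variable_specs() # clinical ranges and plausibility bounds
record <- raw_observations |>
  minute_average(specs) |>
  remove_implausible(specs) |>
  derive_cpp() |>
  split_phases(bleed_minute = bleed) |>
  impute_flknn() |>
  bin_record(specs)

models <- infer_cohort(record, specs)
summary <- summarize_population(models, measured_channels(record))
```

## Preprocessing

**Minute averaging.** All devices are brought to a shared grid by averaging
each channel's observations over half-open minute bins `[m, m+1)`. Minutes
with no observation are missing. The operation is idempotent on data that is
already minute-resolved.

**Plausibility filtering.** Values outside hard physical bounds (e.g. a
negative oxygen saturation, ICP of 250 mmHg) are monitor artifact and set
missing. The shipped bounds are deliberately configuration, not code: they
are defaults a neuro-ICU analyst can override per site, and they are labelled
as shipped defaults because published consensus exists for normal ranges but
not for artifact bounds.

**Derived perfusion pressure.** Cerebral perfusion pressure is defined as
CPP = MAP − ICP minute by minute; CPP is missing wherever either parent is,
and its provenance records whether both parents were directly observed.
Patients without a parenchymal ICP monitor simply lack CPP (a warning, not
an error — in monitored cohorts only about half of patients receive one).

**Phases.** Analyses are run separately for two predefined post-bleed
phases: days 0–3 and days 4–7, implemented as half-open intervals
`[bleed, bleed+96h)` and `[bleed+96h, bleed+192h)`. The boundary minute
belongs to phase 2; the source conventions are not stated anywhere, so the
half-open choice is ours, applied consistently with the minute bins.
Splitting by phase reflects the clinical time course: most secondary
complications (delayed ischemia, delayed swelling) arise after day 3–4, so
relationships are allowed to differ between the phases rather than assuming
a stationary causal structure over a week.

**Data characteristics.** Per patient and channel the package reports the
observed-value SD as a percent of the mean, the percent of grid minutes
observed, and a KPSS level-stationarity test; a channel is called
nonstationary when the KPSS p-value is at or below 0.01, and the cohort-level
fraction divides by the number of patients that have the channel. The KPSS
statistic is computed in the package (Bartlett-kernel long-run variance, lag
truncation `ceiling(12 (n/100)^{1/4})`, p-values interpolated from the
published critical-value table and truncated to `[0.01, 0.10]`); it is
validated in the test suite against statistics computed independently with
Python's statsmodels on frozen series. Channels observed for under 30
minutes get no metrics — with fewer points the SD and KPSS statistics are
too unstable to report; the threshold is ours.

## FLk-NN imputation

Monitoring data go missing for two distinct reasons: a single device
malfunctions (missingness depends on the variable itself), or the patient is
disconnected for an intervention and every channel drops at once
(missingness depends on other variables). The imputer combines two
components, one suited to each mechanism:

* **Fourier (F):** per channel, missing entries are initialised at the
  observed mean and the series is iterated through FFT → keep the `m`
  largest-amplitude frequency components → inverse FFT → overwrite missing
  entries only, to convergence. The reconstruction exploits the channel's
  own slow and periodic structure and works even when every channel is
  missing simultaneously. `m` defaults to `ceiling(n/20)` components with
  tolerance `1e-6` and at most 100 iterations — all exposed in the API; the
  defaults keep the reconstruction smooth at minute resolution without
  flattening hour-scale excursions.
* **Lagged k-NN (Lk-NN):** for each ordered channel pair the `p = 3` lags
  (0–60 minutes) with the largest absolute Pearson cross-correlation over
  jointly observed minutes are retained; lags whose correlation is within
  two standard errors of zero are not retained at all, so uninformative
  pairs contribute no features and the component abstains rather than
  guessing. A missing entry's query vector stacks the other channels at
  their retained lags (standardized per channel within the patient-phase —
  no cross-patient leakage); candidates are minutes where the target is
  observed; the distance is Euclidean over features present in both query
  and candidate, each squared difference weighted by the absolute
  correlation that selected the feature, normalised by the shared weight
  mass. The estimate is the inverse-distance-weighted mean of the `k = 5`
  nearest candidates (exact matches dominate; ties break deterministically
  by earlier minute). Lag 0 is allowed here: contemporaneous information is
  legitimate for estimation, though never for causation.

Where both components produce an estimate the imputed value is their
unweighted mean (a configurable weight supports sensitivity analysis);
where only one exists it is used alone; where neither exists the entry
stays missing. Two hard rules are audited by the test suite: observed
values are never modified, and **no entry inside a missing run longer than
30 minutes is ever imputed** — consequently channels sampled about hourly
(microdialysis metabolites) are never imputed at all.

The `k = 5` neighbours, 1-hour lag horizon, `p = 3` lags and the 30-minute
cap are the method's established settings; the combination rule, spectral
order, convergence parameters and correlation weighting are our choices,
config-exposed and documented above.

## Discretization

Causes are clinical states, not raw values: each channel is binned into
LOW / NORMAL / HIGH against its clinically accepted normal range (ICP
normal below 20 mmHg, HR 60–80 bpm, CPP 60–90 mmHg, …). The normal range
is inclusive at both endpoints — printed ranges like "60–80" read naturally
as closed intervals — and one-sided ranges yield exactly two states. Brain
water content (TW%) has no accepted normal range; it is binned by
patient-phase tertiles and flagged as such in the output. Thresholds are
configuration: the point of the analysis is not to learn thresholds but to
relate excursions from the normal range to one another.

## Causal inference

For each patient and phase separately — ICU populations are too
heterogeneous for pooled models — the package evaluates every hypothesis
"(cause channel in state σ) → (effect channel)" at every analysis window.
The default grid is the twelve contiguous non-overlapping 5-minute windows
`[1,5], [6,10], …, [56,60]` minutes after the putative cause; window lower
bounds start at 1 because causes must strictly precede their effects.
Overlapping grids are available (`causal_windows(step = 1)`).

Effects are continuous and standardized to zero mean, unit variance over
the patient-phase. The *windowed effect value* at minute `t` is the mean of
the standardized effect over `[t+r, t+s]`, defined when at least 3 of the
5 window minutes are present.

**Prima facie screening.** A candidate cause must occur at least
`n_min = 10` times at minutes with a defined effect window, and shift the
windowed effect mean by more than 0.1 SD relative to its overall mean. This
loose screen keeps the set of seriously evaluated causes small — under
innovation-dominated null dynamics, unrelated channel pairs are screened
out the large majority of the time.

**Causal significance.** For a candidate `c` with prima facie set `X`, the
causal significance is

$$\varepsilon_{avg}(c, e, w) \;=\;
\frac{1}{|X \setminus \{c\}|} \sum_{x \in X \setminus \{c\}}
\Big[ \mathbb{E}(e_w \mid c \wedge x) - \mathbb{E}(e_w \mid \neg c \wedge x) \Big],$$

the average impact of the cause on the windowed effect value while holding
each other potential cause fixed. Conditioning states are evaluated at the
same minute as the candidate (the simplest faithful choice; the timing of
conditioning causes is not pinned down by the method's description).
Conditioning pairs with fewer than `n_joint = 10` joint occurrences on
either side are skipped; if nothing survives, the marginal contrast
`E(e_w|c) − E(e_w|¬c)` is used. States of the same channel are mutually
exclusive, so same-channel conditioning terms vanish automatically. A
constant effect channel cannot be standardized and is not evaluated —
causal inference for individuals requires variation.

**Significance.** Within a patient-phase, the ε population is scored
against an empirical normal null with robust location and scale (median,
MAD × 1.4826); two-sided p-values below 0.05 are significant, with no
multiplicity correction — each patient's model is its own small hypothesis
family, already thinned by the prima facie screen. When fewer than 20
values are available, or the MAD degenerates to zero, a per-hypothesis
permutation test replaces the empirical null: the candidate's state series
is circularly time-shifted (200 evenly spaced deterministic shifts),
ε recomputed against the fixed conditioning pool, and the two-sided rank
p-value taken. Significant results carry a direction: INCREASE if ε > 0,
DECREASE otherwise.

Imputed values participate in inference exactly like observed ones (the
data are imputed before inference); `observed_only = TRUE` restricts to
observed entries for sensitivity analysis. Microdialysis channels are
excluded by default — hourly sampling cannot meet 5-minute window support.

## Aggregation and recovery scoring

Population summaries count, per relationship (cause channel + state,
effect, window), the patients in which it is significant; the denominator
is always the number of patients with **both channels measured**,
regardless of significance. A window-collapsed view (significant in any
window) mirrors how relationship networks are usually displayed; the
per-window table is the primary data structure.

For synthetic cohorts with known planted edges, `score_recovery()` calls a
relationship at the per-window granularity when it is significant in at
least 30% of measuring patients. Recall asks for the exact planted (cause,
state, effect) to be called; precision is scored over directed channel
pairs, because a planted shift of one cause state necessarily displaces the
effect's conditional mean for the complementary states of the same channel
— detecting those is attribution to the true mechanism, not false
structure. Collapsing across all windows and states before thresholding
was measured to inflate false pairs structurally (a calibrated 5% error
rate gets ~36 chances per channel pair) and is deliberately not used for
calling. Timing attribution uses the called window with the most
significant patients: with persistent cause states the association smears
across neighbouring windows, so the check is that the best window
*intersects* the planted effect interval `[lag, lag + duration)`.

## Phenotyping

Patients are clustered on clinical features (age, severity scores, edema
indicators, outcome measures — the feature matrix is the analyst's choice,
as no canonical matrix exists) with k-means (25 seeded restarts), the
number of clusters chosen by the gap statistic against `B = 500` uniform
reference sets over the feature ranges, taking the smallest `k` with
`Gap(k) ≥ Gap(k+1) − s_{k+1}`. The implementation is `cluster::clusGap`
with `spaceH0 = "original"`. A companion permutation test asks, per
relationship, whether the patients exhibiting it sit closer together in
feature space than random subsets of the same size (at least 3 patients
required).

## The synthetic cohort generator

No patient-level data accompany the underlying study, so the package ships
a seeded generator that emulates the analysable structure of such cohorts:

* minute-grid channels following Gaussian AR(1) dynamics around clinical
  baselines, clipped to plausibility bounds, with optional linear drift for
  nonstationarity studies;
* planted lagged relationships: whenever the cause channel is in the cause
  state at minute `t`, the effect channel's mean shifts by a fixed amount
  over `[t+lag, t+lag+duration)` (default duration 5 minutes, so an effect
  lands inside one analysis window; overlapping triggers do not stack).
  Channels are generated in cause-before-effect order so cause states are
  read from final series;
* two missingness mechanisms: per-channel dropout blocks and all-channel
  disconnections, both with Poisson starts and geometric lengths (the
  simplest memoryless dropout model), with optional per-channel
  availability targets;
* per-patient device subsets (e.g. a brain-oxygen probe present in only a
  fraction of patients);
* deterministic seeding: patient seeds derive from the cohort seed by a
  fixed congruential scheme, so a stored configuration regenerates an
  identical cohort.

**Default dynamics.** The default ten-channel schema uses AR coefficients
between 0.70 and 0.90 (heterogeneous across channels) with marginal spreads
matching typical vitals. The coefficients are deliberately
innovation-dominated: the inference benchmarks presume a regime where
statistically independent channel pairs rarely pass the prima facie screen
at study-scale series lengths. Real monitoring data can be far more
persistent — up to nonstationary, which the data-characteristics module
measures and the discussion below flags as a limitation.

**Benchmark designs.** Three frozen configurations define the package's
study conditions. `config_null_cohort()` (ten independent channels, 4800
minutes, fully observed) is the null design for significance calibration.
`config_recovery_cohort()` plants eight edges of about one marginal SD at
lags 5–30 minutes in a cause/effect-disjoint arrangement across ten
channels and twenty patients, with roughly 20% mixed-mechanism missingness;
monitoring duration (4800 minutes ≈ 3.3 days) sits inside a phase, as
per-patient monitoring spans in such studies vary and are free choices
here. `config_coupled_cohort()` is the imputation benchmark: two smooth
near-continuous "driver" channels (arterial-line MAP, ventilator RR) whose
states drive six probe channels that owe about two thirds of their variance
to the drivers. The imputation levels are realised mainly through
probe-channel dropout, with a constant small driver deficit and brief
all-channel disconnections at every level. This design is deliberate: the
combined imputer's accuracy ordering is only a meaningful claim where both
of its components have information — smooth self-structure *and*
informative cross-channel structure — and where both missingness mechanisms
occur. In lopsided designs the benchmark measures composition artifacts
(whichever single component matches the design wins), not the value of
combining.

**What passing tests do and do not show.** The synthetic cohorts are
Gaussian, piecewise-mean-shifted, and memoryless in their dropout; real
physiology has regime changes, treatment feedback loops (vasopressors,
ventilation targets), measurement artifacts that survive plausibility
bounds, and missingness correlated with clinical state. Recovery and
calibration results on the generator therefore demonstrate that the
implementation is correct and self-consistent under its stated assumptions
— not that the method attains those operating characteristics on clinical
data.

## Numerical and degenerate-input choices

* Half-open minute bins and phase boundaries; boundary minute to phase 2.
* Neighbour and distance ties in Lk-NN break by earlier minute index;
  permutation shifts are evenly spaced — the pipeline is deterministic
  given seeds.
* Zero-distance neighbours dominate the k-NN estimate (their mean).
* Constant channels: SD% is 0, KPSS does not reject (statistic 0), they
  are never effects, and as causes they occupy a single state which the
  screen removes.
* MAD = 0 or small result sets route to the permutation null.
* Effects with all-missing windows, causes below support, and conditioning
  pairs below `n_joint` are skipped, never silently zero-filled.

## Known limitations

* Timing is resolved only to 5-minute windows within one hour; sub-minute
  and beyond-hour relationships are invisible, and persistent cause states
  smear associations across neighbouring windows.
* The empirical null is fitted to a screened population; its calibration
  is verified on the package's null design, but strongly autocorrelated or
  nonstationary channels (common in real recordings) inflate spurious
  low-frequency associations — profile data first with
  `data_characteristics()`.
* Latent confounders with consistent delays produce edges between their
  descendants; conditioning only spans measured prima facie causes.
* Single imputation: imputed values enter inference as if observed, with
  no uncertainty propagation.
* The gap statistic's uniform reference assumes feature ranges are
  meaningful; heavily skewed features should be transformed first.
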