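---
title: "Circadian rhythms, persistence and alter-specificity from call-detail records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian rhythms, persistence and alter-specificity from call-detail records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrhythms)
```

## The measurement problem

Call-detail records (CDRs) are operator-side metadata: one row per telephone
call with a timestamp, the caller (*ego*), the recipient (*alter*), the call
direction and the duration in seconds — no content. Because placing an
outgoing call is a voluntary, timestamped social act, a year of outgoing CDRs
is a passive, objective trace of when a person is socially active and with
whom. `cdrhythms` turns such a trace into three behavioural summaries:

1. **Circadian rhythm**: the 24-slot distribution of an ego's outgoing calls
   over the hours of the day.
2. **Persistence**: whether that distribution is a stable individual trait
   across successive observation periods, rather than noise.
3. **Alter-specificity**: whether particular alters are called at particular
   times of day, measured against a permutation null model, together with
   top-2 alter call fractions and duration profiles by social category
   (family, friends, associations, health professionals, others).

The package targets the cohort structure typical of small longitudinal
panels of older adults — a few dozen egos followed for about a year — but
nothing in the methods is age-specific.

## Preprocessing

Only outgoing calls are analysed (`select_outgoing()`): incoming calls are
timed by someone else's clock. With staggered enrollment,
`select_common_window()` picks the contiguous month-aligned window (12
months by default) covered by the largest number of egos, breaking ties
toward the earlier start. `filter_active_egos()` then keeps the egos with at
least one outgoing call in *every* calendar month of the window. "Active
throughout the observation period" is not self-defining; we operationalize
it as the calendar-month criterion and expose the granularity (`"month"` or
`"week"`) so stricter definitions can be tested. Both filters are idempotent
and report before/after cohort summaries (ego counts and per-ego call-count
quartiles).

Timestamps are interpreted in a single fixed local timezone with no DST
adjustment, and a call belongs to the hour in which it starts; calls
spanning an hour boundary are not split.

## Rhythm estimation

`hourly_pattern()` computes, per ego, the fraction `p(t)` of calls in each
of the 24 one-hour slots, `t = 0..23`. The population pattern
(`aggregate_pattern()`) is the *unweighted mean of per-ego patterns*, not a
pooled-call histogram: pooling would let heavy callers dominate and would
conflate aggregate and individual levels (an ecological fallacy); the
per-hour standard deviation across egos is reported alongside. For heatmap
display, `unity_normalize()` rescales each ego's pattern affinely onto
[0, 1]; a constant pattern has no shape and maps to zeros with a warning
(this avoids 0/0 while keeping the output in range).

## Persistence analysis

The window is split (`split_periods()`) into `n` successive equal-length
periods — three 4-month periods `T1, T2, T3` for a 12-month window. When the
day count does not divide evenly, the trailing periods absorb one extra day
each (365 days → 121/122/122).

For each ego `i` with pattern `p_i^T` in period `T`:

* self-distance: `D_self(i) = { d(p_i^T1, p_i^T2), d(p_i^T2, p_i^T3) }` —
  successive pairs only; the T1–T3 pair is deliberately excluded so that
  slow drift is measured through its consecutive steps;
* reference distance: `D_ref(i) = { d(p_i^T, p_j^T) : j ≠ i, T ∈ T1..T3 }`,
  i.e. `3(n−1)` values at population size `n`;
* the rhythm is **persistent** iff `⟨D_self⟩ / ⟨D_ref⟩ < 1`.

The dissimilarity `d` is the square root of the Jensen-Shannon divergence.
All entropies and divergences in the package use log base 2, so
`JSD ∈ [0, 1]` and `√JSD` is a bounded metric; the persistence ratio is
base-invariant, so this is purely a normalization convention.
Zero-probability hours are handled by the `0·log 0 = 0` convention, and no
pseudocounts are added — the JSD midpoint keeps every term finite. A
Euclidean (L2) alternative is provided for sensitivity analysis
(`persistence(ds, metric = "l2")`) and a two-sample Kolmogorov-Smirnov
comparison of the raw successive-period hour samples is reported per ego.
KS is applied to raw hour samples rather than the binned 24-vectors because
the test assumes samples, not histograms; hours are discrete, so ties are
unavoidable and the asymptotic p-value (conservative under ties) is used.

## Alter-specificity

Hours are coarse-grained into four 6-hour bins — night [0, 6), morning
[6, 12), afternoon [12, 18), evening [18, 24) — per ego and period.

* **Origin entropy** `H_orig(i, t)`: Shannon entropy (bits) of the
  distribution of ego `i`'s calls over alters within bin `t`. An empty bin
  is missing (`NA`), not zero: zero is a meaningful value (all calls to one
  alter).
* **Reference entropy** `⟨H_ref(i, t)⟩`: the null model permutes the
  (alter, duration) labels of the ego's calls within each consecutive
  14-day block while leaving every timestamp in place, so the hourly call
  histogram and the per-alter call totals per block are exactly conserved
  while alter–time associations are destroyed. `H_orig` of the shuffled
  data is averaged over `n_iter = 1000` iterations (configurable). The
  14-day block length follows the 2-week convention of this literature and
  is exposed as `block_days`.
* **Relative entropy** `H_rel = H_orig / ⟨H_ref⟩`: values near 0 indicate
  strong alter-specificity; values near 1 indicate none. `H_rel` can
  legitimately exceed 1 (a bin more diverse than the day-wide pool). When
  `⟨H_ref⟩` is below 1e-9 bits — a bin fed by a single alter or a single
  call — the ratio is numerically meaningless and would spuriously
  approach 1; the package reports `NA` for such cells instead of an
  unstable ratio.

`top2_fraction()` gives the share of a bin's calls going to the ego's two
most-called alters in that (period, bin), with lexicographic tie-breaks;
top-2 alters are chosen per (period, bin) rather than globally.
`entropy_top2_correlation()` computes, per ego, the Pearson correlation
between `H_rel` and the top-2 fraction over the up-to-12 complete
(period, bin) cells, requiring at least 3 complete pairs; egos with fewer,
or with zero variance in either series, are reported undetermined rather
than given an arbitrary value. `duration_profiles()` reports mean call
duration per hour and contact category, with unlisted alters grouped under
"others".

## The synthetic population

The study populations these methods were developed on are privacy-regulated
call records that cannot be redistributed, so the package ships a generator
(`generator_config()` / `generate_cdr()`) whose defaults emulate the cohort
structure of a 12-month older-adult panel, with full ground truth for
validation:

* 21 egos, 12 months, ~700 outgoing calls per ego-year with lognormal
  between-ego dispersion (sd 0.25 on the log scale; median ≈ 680, within
  the 590–710 range typical of such panels);
* per-ego circadian profiles: a wrapped-Gaussian mixture over the 24-hour
  circle with peaks at 10:00 and 18:00 (per-ego jitter ±0.5 h, spread
  1–2.5 h), a per-ego morning-vs-evening preference (morning weight
  uniform on 0.25–0.60 of the non-floor mass) and a 10% uniform floor. Any
  unimodal circular kernel would serve; the wrapped Gaussian is a modeling
  choice, not an empirical claim;
* one nocturnal ego peaking at 02:00 whose night calls all go to a single
  alter — reproducing the kind of atypical individual that shows up as a
  small 2 am bump in the population average;
* 15 alters per ego with Zipf base popularity; per-bin alter distributions
  drawn from a Dirichlet with per-bin total concentration (night 5,
  morning 50, afternoon 50, evening 5), and 70% of evening/night calls
  routed to the ego's top 2 alters (`top2_evening_share`) — the
  alter-time association the entropy analysis is designed to detect.
  Setting all concentrations to `Inf` and the share to `NA` produces the
  *calibration* configuration with no alter-time association, for which
  relative entropy should average 1;
* lognormal durations per category with a linear hour-of-day trend on the
  log scale: positive for family and friends (longer evening calls),
  negative for associations and health professionals;
* `drift = TRUE` redraws each ego's circadian mixture independently per
  4-month block — a persistence-breaking control;
* `silent_month_egos = k` gives the first `k` egos one empty calendar
  month, the device used to exercise the activity filter (for example a
  26-ego cohort with 5 silent-month egos filters to 21);
* hierarchical seeding: each ego draws from its own derived stream, so the
  same seed reproduces the dataset byte-for-byte and adding an ego never
  perturbs the others.

What the generator does **not** emulate: day-of-week and seasonal
structure (call days are uniform over the window), reciprocity and
conversations, alter churn, enrollment staggering, and the long-tailed
inter-event burstiness of real communication. Passing the package's
validation suite therefore shows that the estimators recover known
structure of this form; it does not certify behaviour on every pathology of
real CDRs.

## Numerical choices and degenerate inputs

* Probability inputs to `jsd()` must sum to 1 within 1e-9; the result is
  clamped into [0, 1] against floating-point fuzz.
* Empty bins/periods propagate as `NA` and are excluded with a report,
  never silently imputed.
* Ties in top-2 selection break lexicographically by alter id, making
  outputs order-independent.
* Per-ego call summaries use the default (type-7) sample quantiles.
* The common-window search ties toward the earliest start.

## Validation problem sizes

The test-suite checks run at deliberately modest sizes chosen to make the
statistical assertions sharp but cheap: metric axioms on 200 random
distribution triples; entropy against a brute-force oracle on 500 random
count tables; null-model conservation over 100 shuffles of a ~2,000-call
ego; calibration of mean relative entropy to [0.9, 1.1] over 30 seeds of a
5-ego association-free population at 200 null iterations; persistence
recovery and the drift contrast on the full 21-ego default population over
3 paired seeds; and the entropy/top-2 anticorrelation over 10 seeds. The
acceptance script (`scripts/acceptance.R`) re-runs the full pipeline at the
default study scale with 1,000 null iterations.

## Limitations

The persistence criterion is a descriptive ratio, not a significance test;
no uncertainty is attached to it. Relative entropy inherits small-sample
bias from plug-in entropies when bins contain few calls, and its missing
values are informative (sparse bins), so averages over cells should be
restricted to adequately filled cells, as the calibration check does.
Results depend on the single-timezone assumption; travelling egos would
need timezone-resolved timestamps.
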