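# cdrhythms

Circadian-rhythm and alter-specificity analysis of call-detail records
(CDRs), for researchers using telephone metadata as a passive behavioural
marker — e.g. monitoring daily social activity rhythms in older adults.

A CDR is one row per call: timestamp, caller (*ego*), recipient (*alter*),
direction, duration. From a year of outgoing CDRs the package answers three
questions per ego:

1. **Does the ego have a circadian calling rhythm?** The hourly pattern
   `p_i(t)`, `t = 0..23`, is the fraction of ego *i*'s outgoing calls in
   each one-hour slot; population patterns average egos with equal weight.
2. **Is the rhythm a stable trait?** The window is split into successive
   periods (T1, T2, T3). With the square-root Jensen-Shannon distance
   `d(p, q) = sqrt( H((p+q)/2) − [H(p)+H(q)]/2 )` (base-2 logs, so
   `d ∈ [0, 1]`), the ego's self-distance across successive periods is
   compared with its reference distance to all other egos in the same
   period: the rhythm is **persistent** iff `⟨D_self⟩ / ⟨D_ref⟩ < 1`.
   An L2 variant and per-ego Kolmogorov-Smirnov comparisons are included.
3. **Are specific alters called at specific times?** Within four 6-hour
   bins, the *origin entropy* `H_orig = −Σ_a f_a log2 f_a` of the alter
   distribution is compared with its mean under a permutation null that
   shuffles (alter, duration) labels within 2-week blocks while keeping
   every timestamp fixed. The *relative entropy*
   `H_rel = H_orig / ⟨H_ref⟩` tends to 0 under strong alter-specificity
   and to 1 under none; top-2 alter fractions and duration profiles by
   contact category (family, friends, associations, health professionals,
   others) complete the picture.

Because the study-type data are privacy-regulated, the package includes a
fully seeded synthetic CDR generator with ground truth (ego-specific
circadian mixtures, a nocturnal ego, evening/night concentration on the top
2 alters, category- and hour-dependent durations, drift and silent-month
controls) so the whole pipeline can be exercised and validated end to end.

## Worked example

```r
library(cdrhythms)

sim <- generate_cdr(generator_config(), seed = 101)   # 21 egos, 12 months
ds  <- preprocess_cdr(sim$dataset)                     # outgoing + active egos

res <- persistence(ds, metric = "sqrt_jsd")
res
#> Persistence analysis (sqrt_jsd metric, 21 egos)
#>   <D_self> = 0.196 (SD 0.033), <D_ref> = 0.337 (SD 0.129)
#>   persistent egos: 21 / 21
```

Every ego's average self-distance (~0.20) is well below its average
reference distance (~0.34), so each ego resembles its own past more than it
resembles anyone else — all 21 rhythms are persistent. Alter-specificity:

```r
prof <- entropy_profile(ds, n_iter = 1000, seed = 7)
corr <- entropy_top2_correlation(prof)
round(corr$population_r, 2)
#> [1] -0.79
```

The strong negative population correlation says that the 6-hour bins where
an ego's relative entropy is low are exactly the bins where its calls
concentrate on its two favourite alters (here by construction: the
generator routes 70% of evening/night calls to the top 2).

The end-to-end pipeline, driven by a YAML config or R code:

```r
report <- run_pipeline(pipeline_config(generator = generator_config(),
                                       seed = 1, out_dir = "run1"))
```

writes the preprocessing summary, per-ego and aggregate hourly patterns,
persistence tables for both metrics, the entropy/top-2 profile and the
duration profiles as CSV plus a JSON run report. The same stages are
available as subcommands of `inst/scripts/cdrhythms.R` (`simulate`,
`preprocess`, `rhythms`, `persistence`, `entropy`, `run-all`).

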