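# callrhythm

Rhythm, tempo and pulse–pant coupling analysis of primate long calls.

Flanged male orangutans produce loud, multi-pulse vocal displays ("long
calls") whose voiced exhales (**pulses**) form near-isochronous trains at
about 0.5 Hz, often interleaved with voiced inhales (**pants**). Whether and
how such non-song displays carry *double meter* — the division of the
primary beat into two equal parts, via 1:2 and 2:1 interval ratios — is a
question for bioacousticians and comparative musicologists working from
event-level annotation tables (file, call, kind, onset, duration). This
package implements that analysis chain as tested, reusable functions, plus a
ground-truthed synthetic corpus generator so every stage can be validated
without any field data.

## What it computes

Given onsets `o_k` of a series, the inter-onset intervals are
`t_k = o_{k+1} − o_k` and the rhythm ratios

```
r_k = t_k / (t_k + t_{k+1})
```

with `r_k = 0.50` marking isochrony (1:1), `1/3` the 1:2 and `2/3` the 2:1
category. Ratios are classified into on-integer windows around those values
and flanking off-integer windows (e.g. 1:1 on = [0.444, 0.555)), tallied per
recording file, and tested with a **zero-inflated Poisson mixed model**:

```
count_fb ~ ZIP( pi, exp(beta_b + log(width_b) + u_f) ),   u_f ~ N(0, sigma_u²)
```

fitted by direct marginal-likelihood maximization with adaptive
Gauss–Hermite quadrature, with full-vs-null likelihood-ratio tests and
planned off-minus-on contrasts. Four analysis levels are supported: all
pulses per call; all events of alternating pulse/pant sections; and the
pulses-only / pants-only series of those sections. Tempo differences between
the three section interval types are contrasted on a log-interval linear
mixed model, and pulse–pant coupling is quantified per section with lagged
cross-correlation (max lag 20) and order-1 Granger causality in both
directions (tally at p < 0.001).

## Worked example

```r
library(callrhythm)

corpus <- generate_corpus(synth_config(n_calls = 12, seed = 42))
ratios <- rhythm_ratios(corpus$events, "all_pulses")
counts <- count_bins(ratios)

fit <- fit_zip_mixed(counts)
fit
#> Zero-inflated Poisson mixed fit (agq, 15 nodes)
#>   logLik -123.1531 | n = 72 obs, 12 file(s) | converged: TRUE
#>   zero-inflation pi = 0.0000 | random-intercept SD = 0.3363
#>        Estimate     SE
#> off1:1   4.4246 0.1433
#> on1:1    4.8807 0.1237
#> off1:2   2.7074 0.3175
#> on1:2    2.4240 0.3673
#> off2:1   3.1427 0.2621
#> on2:1    2.4240 0.3673

lrt_full_vs_null(fit, fit_zip_mixed(counts, include_fixed = FALSE))
#> # A tibble: 1 × 3
#>    chi2    df  p_value
#>   <dbl> <int>    <dbl>
#> 1  180.     5 6.82e-37

posthoc_contrasts(fit)
#> # A tibble: 3 × 6
#>   contrast       estimate    se statistic    df  p_value
#> 1 off1:1 - on1:1   -0.456 0.127    -3.60     NA 0.000316
#> 2 off1:2 - on1:2    0.283 0.465     0.610    NA 0.542
#> 3 off2:1 - on2:1    0.719 0.429     1.68     NA 0.0937
```

The negative, significant `off1:1 - on1:1` contrast says ratios concentrate
*inside* the isochrony window beyond what the window widths predict — the
signature of a rhythmic category (the width enters as an exposure offset).
The 1:2 and 2:1 contrasts are not significant in this small 12-call corpus.
`double_meter_share(counts)` reports the share of on-integer double-meter
hits among all on-integer hits (here 16/201 ≈ 0.08, i.e. double meter about
8% of the time during periods of isochrony).

Pipeline runs (`run_analysis(run_config(...))`) write `intervals.csv`,
`ratios.csv`, `bin_counts.csv`, `table1.csv`, `table2.csv`, `coupling.csv`,
`tally.json` and `densities.csv` into an output directory, byte-identically
for identical configs. A thin CLI wrapper lives at `inst/cli/callrhythm.R`
(subcommands `synth`, `analyze`, `reproduce`). `reproduce_paper()` recomputes
the published headline values from a local copy of the deposited field
datasets, with column mappings in `inst/extdata/zenodo_mapping.yaml`.

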