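---
title: "Rhythm, tempo and pulse-pant coupling in long calls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm, tempo and pulse-pant coupling in long calls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callrhythm)
```

## The problem

Flanged male orangutans broadcast loud, minutes-long vocal displays ("long
calls") built from trains of voiced exhales ("pulses"), often interspersed
with voiced inhales ("pants"). Pulse trains are near-isochronous at roughly
0.5 Hz. Two mechanisms can divide that primary beat in two: tempo variation
between successive pulses, and pants inserted near the midpoint of a pulse
cycle, which doubles the event tempo of the pulse/pant sequence. callrhythm
implements the full analysis chain for such data, starting from event-level
annotation tables (file, call, kind, onset, duration in seconds) and ending
in category tests, tempo contrasts and coupling statistics.

## Data model and analysis levels

Events are validated into an `event_table`: rows sorted by
`(file_id, call_id, onset_s)`, onsets strictly increasing within a call
(tied onsets are rejected rather than broken arbitrarily, since time is
continuous), and calls with fewer than two pulses flagged but kept.

Four time series are derived per call:

* **all_pulses** — every pulse onset of the call, pants ignored;
* **pulse_pant_series** — all onsets inside *sections*, contiguous runs of
  at least three strictly alternating pulse/pant events;
* **pulses_within_series** / **pants_within_series** — only the pulses,
  respectively pants, of those sections.

The alternation rule needs a contiguity guard, otherwise a pant minutes away
from a pulse would join its "section". We use a configurable maximal
inter-onset gap (`max_gap_s`, default 5 s — two to three pulse cycles at the
typical tempo); the rule is: a maximal run of \(\ge 3\) events, alternating
in kind, with no gap above the threshold.

## Intervals, ratios and rhythmic categories

For each series the inter-onset intervals are
\(t_k = o_{k+1} - o_k\) and the rhythm ratios
\[
r_k = \frac{t_k}{t_k + t_{k+1}} \in (0, 1),
\]
never chained across call or section boundaries. \(r_k = 1/2\) marks
isochrony (1:1), \(1/3\) the 1:2 and \(2/3\) the 2:1 category. Each ratio is
classified into six bins: a narrow *on-integer* window per category and
flanking *off-integer* windows (`bin_scheme()`; 1:1 on = \([0.444, 0.555)\),
off = \([0.400,0.444) \cup [0.555,0.600)\), and analogously for 1:2 and 2:1
down to 0.286 and up to 0.714). The published boundaries say "between"
without fixing endpoint handling; we use half-open, lower-inclusive
intervals so the six bins tile \([0.286, 0.714)\) exactly — a measure-zero
decision that cannot affect continuous data but makes the partition
invariant testable. Ratios outside the covered range stay unclassified and
count only toward the per-file totals.

An excess of on-integer over off-integer counts is the evidence for a
rhythmic category. Within-call position of each ratio (`rel_pos`, onset of
the ratio's first interval scaled to the call span from first onset to last
event end) feeds a boundary-reflected Gaussian kernel density per category,
showing where along a call each category concentrates; the bandwidth
defaults to Silverman's rule on the matching positions.

## The zero-inflated Poisson mixed count model

Counts \(y_{fb}\) of ratios from file \(f\) in bin \(b\) are modelled as

\[
y_{fb} \sim \begin{cases}
0 & \text{with probability } \pi\\[2pt]
\mathrm{Poisson}\!\left(\exp(\beta_b + \log w_b + u_f)\right) & \text{otherwise}
\end{cases}
\qquad u_f \sim N(0, \sigma_u^2),
\]

with \(w_b\) the bin width as an exposure offset (wider bins catch more
ratios by chance alone; the log-offset is the canonical Poisson exposure
choice), an intercept-only logit zero-inflation component, and cell-means
coding over the six bins. Structural zeros are real here: a file can lack a
whole category outright, beyond Poisson sampling zeros.

`fit_zip_mixed()` maximizes the *marginal* likelihood directly. The scalar
random intercept makes the per-file integral one-dimensional, so adaptive
Gauss-Hermite quadrature is cheap and accurate: per file, damped Newton
iterations find the conditional mode of \(u_f\), the integrand is re-centred
and re-scaled there, and a 15-node rule (default; any number \(\ge 1\)) is
applied. The Laplace approximation is the 1-node limit and is offered as a
fast path for simulation loops. The test suite checks the quadrature
likelihood against brute-force trapezoid integration on small instances, and
the Laplace fit against an independent mixed-model implementation of the
same likelihood.

Numerical choices: BFGS on all parameters (6 cell means, the zero-inflation
logit, \(\log\sigma_u\)) with the conditional modes warm-started between
likelihood evaluations; starting values from a Poisson GLM; three jittered
restarts on non-convergence, never silent — the fit carries a `converged`
flag and optimizer diagnostics; \(\sigma_u\) estimates below \(10^{-4}\) are
flagged as boundary fits. The covariance of the estimates is the inverse of
a central-difference Hessian of the negative log-likelihood at the optimum.
With a single file the random intercept is unidentifiable and the model
falls back to a fixed-intercept fit with a warning.

Inference follows the full-versus-null pattern: the null model keeps the
random intercept and zero inflation but drops the bin effect, and
`lrt_full_vs_null()` compares twice the log-likelihood difference to
\(\chi^2\) with the parameter-count difference (5 here) as degrees of
freedom. Planned off-minus-on contrasts per category
(`posthoc_contrasts()`) use linear contrasts \(c'\hat\beta\) with
\(SE = \sqrt{c'Vc}\), Wald \(z\) tests, and no multiplicity adjustment —
three planned comparisons per model, reported as-is.

## The tempo model

Tempo differences between the three interval types of a section — `series`
(element to next element), `pants` (pant to pant) and `pulses` (pulse to
pulse) — are modelled on the log scale:
\(\log t_k = \mu_{\text{type}} + b_{\text{section}} + \varepsilon\), with a
Gaussian random intercept per section. Although a plain linear model would
also run, intervals from the same section share a local tempo, so the mixed
model is the honest specification; it is fitted by maximum likelihood (not
REML) so the full-vs-null likelihood-ratio test (2 df) is valid. Pairwise
contrasts use t statistics on residual degrees of freedom \(n - 3\);
Satterthwaite degrees of freedom are available as an option (lmerTest).
With midpoint pants the series interval is half the pulse interval, so the
expected series-minus-pulses contrast is \(\log(1/2) \approx -0.693\) — the
generator reproduces this exactly at zero jitter, which the tests assert.

## Synchrony and causality

Per section, the pulses-only and pants-only series are paired index-wise and
truncated to the shorter length. The default pairing uses interval durations
(the \(t_k\) sequences): onset times are monotone trends whose
cross-correlation is near 1 regardless of coupling, so intervals are the
scientifically meaningful choice; an `onset_times` mode exists for literal
replication of timing-based analyses.

`cross_correlate()` computes
\(r(h) = \sum_t (x_t - \bar x)(y_{t+h} - \bar y) / (n\, s_x s_y)\) with
full-series means and sample standard deviations — equal to `stats::ccf`
scaled by exactly \((n-1)/n\). Positive lag means x (pulses) leads y
(pants); the convention is stated in the output because ecosystems differ.
No detrending or prewhitening is applied.

`granger_order1()` tests, for direction \(x \to y\), the restricted OLS
\(y_t \sim 1 + y_{t-1}\) against \(y_t \sim 1 + y_{t-1} + x_{t-1}\) with an
F test on the added regressor. With \(n\) paired points there are \(n-1\)
usable rows and three unrestricted coefficients, so the test is
\(F(1, n-4)\) — the standard nested-OLS accounting, matching the classical
Granger-test implementations; series with fewer than five points leave no
residual degrees of freedom and are excluded with an explicit error. The
tally of significant directions uses \(p < 0.001\) per direction (a section
may count in both — bi-directional coupling is meaningful) over sections
with at least three observations, and always reports its own denominator.

## The synthetic corpus generator

`generate_corpus()` emulates the two double-meter mechanisms with full
ground truth. Pulse onsets follow a renewal process with lognormal
intervals (mean = current period, coefficient of variation `jitter_cv`;
lognormal rather than Gaussian jitter guarantees positive intervals and
keeps the jitter scale-free across tempi), the period multiplied by
`tempo_drift` each cycle. Each cycle independently receives a pant at
`onset + phase * interval`. The defaults are the study conditions the
pipeline targets: 47 calls, one per recording file, 10–45 pulses per call
(mean near 27), 2.0 s pulse period (0.5 Hz), jitter CV 0.2 (the within-series
interval spread of real calls is roughly a fifth of the mean), pant
insertion probability 0.5, midpoint phase 0.5 with SD 0.05, and an "edges"
position profile — a Beta(2,8)/Beta(8,2) mixture over normalized call
position — concentrating pants early and late in the call, reproducing the
observed bimodal pattern qualitatively (no quantitative profile is
published, so the mixture is a deliberate modelling choice).

What the generator does **not** emulate: the heavy right tail of real
interval distributions (observed SDs comparable to the means suggest a
mixture process; the lognormal is a simplification, not an inference),
inter-individual differences, drifting or switching tempo regimes, missed or
mis-labelled annotations, and any acoustic structure. Passing tests on
synthetic corpora therefore validate the *pipeline arithmetic and
inference machinery* under known ground truth — not distributional claims
about real long calls. One consequence visible in synthetic runs: because
pants are placed relative to their own pulse cycle with independent phase
noise, pulse and pant interval series share tempo without either leading,
so Granger detections are rare and best cross-correlation lags concentrate
at 0 only loosely — weaker synchrony than real, physiologically coupled
phonation shows.

`generate_coupled_sections()` complements this with directly constructed
coupling mechanisms (`none`, `x_leads`, `y_leads`, `shared_tempo`) for
calibration and power checks of the coupling statistics.

## Validation problem sizes

The simulation-based checks in the test suite use sizes chosen to make the
Monte-Carlo error small relative to the tested bands while keeping the suite
quick: Wald-interval coverage of the count model over 200 replicates at 40
files; likelihood-ratio type-I error over 500 null replicates at 12 files
(Laplace path inside loops, quadrature for final fits); Granger type-I error
over 1000 independent pairs of length 30; white-noise cross-correlation
bounds over 500 pairs of length 200. Deterministic identities (quadrature vs
brute-force integration, Granger vs normal-equations OLS, ccf vs its
estimator) are asserted at \(10^{-6}\) to \(10^{-12}\).

## Known limitations

* The deposited field datasets are external; the package recomputes and
  compares their headline values only in `reproduce_paper()` once the four
  files are present locally, with column mappings supplied through a YAML
  file because the deposit's headers are not fixed by the pipeline.
* The count model is exactly the six-bin, intercept-only-zero-inflation,
  single-random-intercept specification; there is no general formula
  interface.
* Published degrees of freedom for some full-vs-null tests are not
  derivable from the stated model structure; `lrt_full_vs_null()` always
  reports the parameter-count difference.
* The double-meter share has two defensible denominators (all on-integer
  hits, or all classified ratios); both are implemented
  (`double_meter_share(denominator=)`) and the on-integer base is the
  default.
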