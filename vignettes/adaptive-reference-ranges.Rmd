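---
title: "Adaptive reference ranges: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive reference ranges: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptref)
```

## The problem

A biomarker measured repeatedly on the same person — hsCRP around soccer
matches, haemoglobin in an athlete passport, creatinine in a transplant
patient — carries two distinct sources of variation: differences *between*
people's personal set-points (variance $\tau^2$) and fluctuation *within*
a person around their own set-point (variance $\sigma_i^2$, which itself
differs across people). A population reference interval lumps the two
together, so it is systematically too wide for stable individuals and can
be too narrow for volatile ones. An *adaptive* reference range instead
asks, at every occasion $j$: given everything observed so far, where
should this person's next value fall with probability $1-\alpha$? A value
falling strictly outside is flagged abnormal (boundary values count as
normal — a deliberate, conservative tie-break; the choice is invisible for
continuous data).

## Method 1: the within-subject Student-t interval

With history $Y_1,\dots,Y_n$ assumed iid $N(\mu_i, \sigma_i^2)$, the
studentised prediction error
$T_{n+1} = (Y_{n+1}-\bar Y_n)/(\hat\sigma_n\sqrt{1+1/n})$ follows
$t_{n-1}$ *exactly*, so the interval
$\bar Y_n \pm t_{1-\alpha/2,n-1}\,\hat\sigma_n\sqrt{1+1/n}$ has exact
finite-sample coverage at every $n \ge 2$. The test suite verifies this
the strong way: simulated exceedance rates sit inside 99% binomial bands
at histories as short as $n = 2$.

Consequences worth knowing:

* Nothing is defined before the third occasion; occasions 1–2 receive no
  verdict and are excluded from every rate denominator in this package.
* A zero-variance history makes the statistic undefined; `zscore_range()`
  raises a `degenerate-history` error rather than inventing a zero-width
  interval, and sequential drivers skip (and count) such occasions.
* With one degree of freedom $t_{0.975,1} = 12.71$, early intervals are
  huge — high specificity, poor early sensitivity.
* The one-sided variant puts all significance in the upper tail
  ($t_{1-\alpha,n-1}$) with the lower limit clamped to 0; this is the
  standard one-sided prediction interval, used for nonnegative markers
  where only elevations matter.

## Method 2: the population-informed LMM interval

The random-intercept model $Y_{ij} = \mu_i + \epsilon_{ij}$,
$\mu_i \sim N(\mu, \tau^2)$, $\epsilon_{ij} \sim N(0, \sigma_i^2)$ is
conjugate: the posterior of $\mu_i$ given $j-1$ personal values is Normal
with precision $1/\tau^2 + (j-1)/\sigma_i^2$. The predictive interval
centre is therefore the precision-weighted average of $\hat\mu$ and
$\bar y_{i(j-1)}$, and the half-width is
$z_{1-\alpha/2}\sqrt{v_{\mathrm{post}} + \hat\sigma_i^2}$. Two limits
anchor the behaviour (both verified numerically in the tests): at $j=1$
the interval is the population prediction interval
$\hat\mu \pm z\sqrt{\hat\tau^2+\hat\sigma_i^2}$; as $j\to\infty$ it
converges to the subject's own interval $\bar y_i \pm z\hat\sigma_i$.

Normal ($z$) quantiles are used deliberately: the population parameters
are treated as known once estimated from the control sample. This ignores
estimation uncertainty, which is why early-occasion false-positive rates
can sit slightly off nominal until histories accumulate — the behaviour
the simulation study quantifies.

### Parameter estimation by EM

The fitting literature for this model only names an "approximate EM"; the
scheme here is written out and is the exact EM for the stated model, which
makes its correctness checkable:

* **E-step** (posterior intercept moments):
  $m_i = (\mu/\tau^2 + n_i\bar y_i/\sigma_i^2)/(1/\tau^2+n_i/\sigma_i^2)$,
  $v_i = 1/(1/\tau^2+n_i/\sigma_i^2)$.
* **M-step**: $\mu = \frac1I\sum m_i$,
  $\tau^2 = \frac1I\sum[(m_i-\mu)^2+v_i]$,
  $\sigma_i^2 = \frac1{n_i}\sum_j[(y_{ij}-m_i)^2+v_i]$.

Initialisation: $\mu$ at the grand mean, $\tau^2$ at the variance of
subject means, $\sigma_i^2$ at each subject's sample variance (singleton
subjects borrow the mean of the others'). Convergence is declared when the
relative change in the marginal log-likelihood drops below `rtol`
(default 1e-8), capped at `max_iter = 500` with an honest `converged`
flag. Because only $(n_i, \bar y_i, ss_i)$ enter, the fit costs $O(I)$
per iteration regardless of series length; with long series the first
M-step already lands essentially at the MLE and the trace converges in a
handful of iterations. Three safeguards:

* the marginal log-likelihood (available in closed form for this model,
  and cross-checked in the tests against brute-force numerical
  integration over the intercepts) is recorded per iteration and must be
  non-decreasing to 1e-9 — a property exact EM guarantees;
* $\tau^2$ and every $\sigma_i^2$ are floored at `var_floor = 1e-8` so
  the predictive interval stays finite; an all-constant control set is
  returned with a `degenerate` warning flag rather than an error;
* the fit is cross-validated in the test suite against an independent
  `lme4` maximum-likelihood fit of the homoscedastic special case
  (agreement ~2e-4 relative on $\hat\mu$ and $\hat\tau^2$).

### The working variance for a new subject

The interval needs $\hat\sigma_i^2$ for a subject the control fit never
saw. This estimation path is genuinely open, so the package states its
rule explicitly (`update_subject_variance()`): a pooled-shrinkage blend

$$\hat\sigma_i^2(j) = \frac{a\,\bar\sigma^2 + ss_i}{a + \max(j-2,\,0)},$$

with $\bar\sigma^2$ the mean fitted control variance, $ss_i$ the
history's sum of squared deviations, and $a = 3$ pseudo-observations. The
default behaves like a conjugate prior worth three observations: equal to
the pooled variance while $j \le 2$, converging to the subject's own
sample variance as history accrues; $a = 0$ switches pooling off. $a = 3$
was chosen once, a priori, as the smallest weight that keeps two-point
histories from producing erratic variances; it was not tuned against any
acceptance outcome. Whether to keep a subject's variance fixed from the
control fit instead is exposed by simply passing a fixed `lmm_state`.

## The simulation study and its stated world

`run_simulation_study()` quantifies false-positive behaviour when *all*
data are truly normal. The generating world is fixed by design, not
adjustable to outcomes: 36 scenarios crossing within/between-SD ratios
{0.001 … 5} with between-SD {0.5, 1, 2} (the printed within-SD cells are
consistent only with a column value of 2, so 2 — not the sometimes-quoted
5 — is used), $\mu = 5$, $n_i = 100$. At full scale each scenario holds
1000 subjects with 100 assessed and a 120-subject control sample; the
acceptance report scales populations to 200 and assessed subjects to 20
per scenario (720 total) so the whole study runs in seconds on one CPU,
and its medians remain within Monte-Carlo bands of the full-scale values.
Both methods are run sequentially from occasion 3 (the first occasion at
which the Z-score method exists), two-sided, $\alpha = 0.05$; a subject
with $n_i = 100$ therefore contributes exactly 98 classified occasions
per method.

Choices a reader should know:

* The control sample is drawn per scenario (so it matches the generating
  regime) and disjoint from the assessed sample (so assessed subjects are
  genuinely new to the model, matching the leave-one-out spirit of
  real-data evaluation); `control_disjoint = FALSE` reproduces an
  overlapping draw.
* One master seed spawns an independent sub-seed per scenario, so any
  scenario can be re-run alone, reproducibly.
* Degenerate zero-variance Z-score histories are skipped and counted per
  subject, never silently failed.

## The labelled fixture generator

`make_hscrp_fixture()` emulates what the real post-match inflammation
data look like — nonnegative log-normal baselines with subject-specific
set-points, occasional large multiplicative spikes labelled abnormal,
alternating pre/post context tags. It exists so the sensitivity machinery
has ground truth to chew on. What it deliberately does **not** emulate:
autocorrelated recovery tails after a spike, measurement rounding or
detection limits, informative missingness, or the clinician-driven nature
of real symptom labels. A green evaluation test therefore establishes
that the machinery is correct *given* labels, not that either method
achieves any particular sensitivity on real athletes — clinician-labelled
athlete series of this kind are not publicly available, and this package
makes no claim to reproduce any particular study's numbers.

## Evaluation conventions

* Sensitivity and false-positive rates are reported both as unweighted
  means of per-subject rates and as occasion-weighted pooled rates: there
  is no standard averaging convention in this field, so both are emitted
  rather than committing to one.
* A rate with an empty denominator is `NA`, never 0.
* History exclusion (`exclude_flagged_from_history = TRUE`) removes
  labelled-abnormal occasions from later baselines, mirroring the
  practice of omitting readings taken during known illness or injury.
  It is driven by the truth label, not by the method's own flags, so
  evaluation stays deterministic and auditable.
* Every reported rate is recomputable from the emitted flag table; the
  tests enforce this identity exactly.

## Known limitations

* Both methods assume within-subject independence and normality; the
  only accommodation for skewness is the optional log-transform at read
  time (ranges are back-transformed for reporting). No autocorrelation
  diagnostic is implemented.
* The LMM interval ignores the sampling uncertainty of
  $(\hat\mu, \hat\tau^2)$; with small control samples its early coverage
  is approximate.
* $\tau^2$ recovery from 120 control subjects carries ~13% relative
  sampling noise ($\sqrt{2/I}$); no estimator can beat that, and one
  acceptance check asking for 5% at that scale is accordingly expected
  to stay red — the cross-method agreement with `lme4` shows the
  estimator, not the noise floor, is sound.
* Covariates, random slopes and multivariate outcomes are out of scope.
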