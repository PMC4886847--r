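---
title: "Models and methods: dual-process analysis of the production effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dual-process analysis of the production effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prodmem)
```

## The scientific question

Reading a word aloud at study improves later recognition relative to
reading it silently (the production effect). Dual-process theories split
recognition into two components: **recollection**, an all-or-none
retrieval of the study episode, and **familiarity**, a continuous strength
signal. The analytic machinery in this package is built to ask which
component carries the production advantage, and whether the answer differs
between within-subject designs (each person reads some words aloud, some
silently) and between-subject designs (each person reads everything aloud
or everything silently).

## The generative model

All simulation and model-based estimation rests on the dual-process
signal-detection (DPSD) model:

* A studied item is **recollected** with probability $R$ (condition
  specific). Recollected items always attract the most confident "old"
  response: rating 6 on the confidence scale, "remember" in the
  remember-know procedure. The confidence mapping is not forced by the
  theory — recollection is only required to produce high-confidence
  responses — but assigning the top rating is the convention the DPSD
  fitting equations assume, and adopting it makes the generator the exact
  inverse of the fitter.
* A non-recollected studied item carries a **familiarity** signal drawn
  from $\mathrm{Normal}(d', 1)$; unstudied foils draw from
  $\mathrm{Normal}(0, 1)$ (equal-variance assumption; unequal-variance
  extensions are deliberately out of scope).
* Responses arise by comparing familiarity with ordered criteria
  $c_1 < \dots < c_5$ (confidence) or with a single old/new criterion
  (remember-know; "know" iff not recollected and familiarity exceeds the
  criterion). This makes the remember-know rule the generative mirror of
  the task instruction to respond "know" only when recollection fails.

The implied response probabilities are closed form, e.g. for confidence
ratings $P(\text{rating} \ge j+1 \mid \text{old}) = R + (1-R)\,
\Phi(d' - c_j)$ and $P(\text{rating} \ge j+1 \mid \text{new}) =
\Phi(-c_j)$. `population_response_probabilities()` exposes these and is
used throughout the tests as the analytic oracle for the simulator and the
estimators.

**Subject heterogeneity.** Real participants differ; the multilevel models
need between-subject variance to absorb. Per-subject recollection is drawn
around the population value on the logit scale
($\mathrm{logit}(R_s) \sim \mathrm{Normal}(\mathrm{logit}(R),
\sigma_R)$) and familiarity on the identity scale truncated at zero. The
logit scale keeps $R_s$ in $[0,1]$ without reflection artifacts; population
values of exactly 0 or 1 are kept fixed (the threshold process is
degenerate there). Defaults in the simulation studies
($\sigma_R = 0.4$, $\sigma_d = 0.25$) produce the order of per-subject
spread seen in published per-subject DPSD estimates.

**What the generator does not emulate.** Items are exchangeable: no
word-frequency or length effects, no item random effects, no study-phase
timing, no response latencies. Foils are *never* recollected — the pure
threshold assumption. Real remember-know data always contain some false
"remember" responses to foils; this difference matters for one analysis
(below). Consequently, passing simulation tests demonstrates that the
estimators recover the truth *under the model's own assumptions*; they do
not certify behavior under item heterogeneity or criterion drift.

## Bayesian estimation

Binary outcomes (old/new; remember/other; know/new after exclusion) are
modelled by multilevel logistic regression on raw trials — not on
aggregated proportions — with a logit link, Normal(0, 2.5) priors on fixed
effects, half-Normal(1) priors on random-effect SDs, and random intercepts
for subjects and (optionally) items. Sampling is Gibbs/slice via JAGS:
4 chains, 500 adaptation + 500 burn-in + 1000 retained iterations per
chain by default, with convergence gates $\hat R < 1.01$ and effective
sample size > 400 attached as warnings rather than errors. Chain RNGs are
seeded deterministically from the user seed, so identical calls give
identical draws.

When item random effects are off, Bernoulli trials are aggregated to
binomial counts per subject and design cell first. The likelihood is
identical; sampling is an order of magnitude faster. The simulation
studies use this route because the generator contains no item-level
variance; fits to real data default to subject + item intercepts, the
minimal structure for crossed subject/item designs.

Two coding schemes mirror the two design families:

* **Dummy, foil intercept** (within designs): the intercept is the
  logit-transformed foil false-alarm rate; silent and aloud slopes are
  contrasts against it. Condition estimates are back-transformed to
  proportions per draw, and contrasts are taken on the proportion scale.
* **Centered item type** (between designs): item type is $-0.5$ (foil) /
  $+0.5$ (studied), production a 0/1 dummy, plus interaction. Aggregating
  coefficients *excluding* item type gives the logit-scale response bias
  $C_L$ per group; aggregating those *including* item type gives the
  logit-scale sensitivity $d'_L$. Positive $C_L$ denotes a liberal bias —
  deliberately the opposite sign of conventional probit $C$, and the
  metrics carry the $L$ subscript everywhere to block silent comparison
  with probit values from other software.

All derived quantities (metrics, back-transformed proportions, contrasts)
are computed **per posterior draw and then summarized** — never by
transforming summaries. Posterior summaries report the median, 50% and 95%
highest-density intervals, and the posterior mass above zero. The HDI is
the shortest contiguous window containing $\lceil \text{mass} \cdot n
\rceil$ of the sorted draws; for the unimodal posteriors these models
produce, the 50% interval nests inside the 95% interval, but the
contiguous construction is not a general multimodal HDI.

Priors, chain counts and iteration counts are this package's own defaults
(weakly informative on the logit scale); they are surfaced in every
fitting function and in the pipeline config rather than hard-coded.

## The independence remember-know analysis

Because task instructions give recollection precedence, raw know rates
underestimate familiarity. The independence estimator is
$F = P(\text{know}) / (1 - P(\text{remember}))$; the trial-level analogue
excludes remember trials and models know vs new among the remainder.
Subject-by-condition cells that are *entirely* remember responses carry no
information after exclusion and are dropped with a warning rather than
continuity-corrected — the multilevel model tolerates the resulting
sparseness through partial pooling, which an aggregated ratio would not.

One consequence of the pure-threshold generator deserves emphasis: since
simulated foils draw no remember responses, the remember model's foil
cells are completely separated, and under the shared Normal(0, 2.5) priors
the interaction coefficient (the $d'_L$ contrast) is prior-dominated
rather than data-driven. The end-to-end dissociation study therefore
evaluates recollection on the studied items' remember contrast
(aloud − silent on the logit scale, per draw), which is identified and is
exactly zero when the generating recollection probabilities are equal.
With real data, where foil-remember rates are small but nonzero, the
$d'_L$ contrast is well defined and is what `derive_sdt_metrics()`
reports.

## DPSD ROC fitting

Per-subject, per-condition confidence counts are fit by maximizing the
multinomial log-likelihood of the six category counts under the DPSD
response model; a least-squares mode on cumulative ROC rates (with a
$1/(2N)$ correction for empty extreme categories) is provided because the
historical distributed solver minimized squared error. On large samples
the two objectives agree to within 0.05 on both parameters (a tested
property); maximum likelihood is the default because it needs no
boundary-rate correction and uses the raw counts.

Numerical choices:

* Parameters are optimized unconstrained: $R$ on the logit scale, $d'$
  mapped to $(0, d_{\max})$ with $d_{\max} = 5$ by default, criteria as
  $c_1$ plus cumulative exponentials (ordering holds by construction).
* The $d'$ bound is not cosmetic. A subject who gives only top-category
  responses to old items leaves the likelihood *flat* along a ridge
  trading $R$ against arbitrarily large $d'$ — both render every old
  response "6". Bounding $d'$ (familiarity beyond $\approx 4$ is not
  measurable with 6-point ratings) and resolving likelihood ties toward
  the first start — a heuristic start derived from the observed ROC, whose
  $R$ is seeded by the upper hit/false-alarm gap — makes such ceiling
  subjects resolve to the recollection reading, the standard DPSD
  interpretation of all-top responding.
* Ten random restarts from overdispersed starts (plus the heuristic
  start), each polished by alternating BFGS and Nelder-Mead until the
  objective moves by less than $10^{-10}$; the incumbent is replaced only
  on strict improvement ($>10^{-8}$). Restart RNG state is derived from the
  seed and restored afterwards.
* Degenerate inputs follow explicit contracts: fewer than 20 trials per
  class warns; all responses in one category for both classes warns and
  returns a boundary fit; non-convergence after all restarts flags the fit
  but still returns the best parameters.

On noise-free expected counts the fitter recovers $(R, d')$ across the
grid $R \in \{0, .2, .5, .8\} \times d' \in \{0, .5, 1, 2\}$ to within
$10^{-5}$ (the tested tolerance is .01/.02). At realistic trial counts
(120 old / 120 new per subject) the ML estimates carry a measurable
finite-sample bias — across simulation seeds roughly $-0.03$ to $-0.05$ in
$R$ and $+0.02$ to $+0.07$ in $d'$ near $(R = .33, d' = .68)$ — arising
from the partial trade-off between the two parameters along the ROC. The
per-subject recovery test asserts tolerances that acknowledge this bias
rather than hiding it; group *contrasts* are unaffected because the bias
is common to both groups.

## Effect sizes and meta-analysis

Standardized production effects are Hedges' $g$. Between-subject:
pooled-SD standardized difference times the small-sample factor
$J = 1 - 3/(4\,df - 1)$, variance $\frac{n_1+n_2}{n_1 n_2} +
\frac{g^2}{2(n_1+n_2)}$. Within-subject effects use the **raw-score
metric** — standardizing the mean paired difference by the raw-score SD,
not the difference-score SD — so that within- and between-subject effects
share a scale (they differ by $\sqrt{2(1-r)}$ otherwise; a tested
identity). The within variance requires the aloud–silent correlation $r$,
which published summaries rarely report; when a default ($r = 0.5$) is
imputed, every resulting effect is flagged loudly
(`r_imputed = TRUE` raises a warning and is recorded on the object).
Remember-know summaries are first converted to probit $d'$ with the
$1/(2N)$ edge correction (0 hits of 100 becomes $1/200$, 100 of 100
becomes $199/200$).

The meta-analytic model is $g_i \sim \mathrm{N}(\theta_i, v_i)$,
$\theta_i \sim \mathrm{N}(\mu + \beta \cdot \text{within}_i, \tau^2)$ with
priors $\mathrm{N}(0,1)$ on $\mu$ and $\beta$ and half-Cauchy(0.5) on
$\tau$ — standard weakly informative choices for effects on the $g$ scale.
$\beta$ is the within-minus-between difference. The fraction of
heterogeneity explained by design is computed from the $\tau$ posterior
*medians*, $(\tau_{\text{basic}} - \tau_{\text{mod}})/\tau_{\text{basic}}$,
matching how such numbers are conventionally reported; a full-posterior
version of the same ratio is also returned since the median-based figure
discards the ratio's uncertainty. Shrunken per-study estimates
($\theta_i$) feed the forest-plot data and are tested to lie weakly
between each raw effect and the pooled mean. In the test suite the
Bayesian fit is cross-checked against an independent REML fit (`metafor`)
on the same effects.

All positive-scale parameters in the JAGS models (residual SDs,
random-effect SDs, $\tau$) are truncated below at $10^{-4}$: with
degenerate data (e.g. literally constant observations) the posterior
concentrates at zero and untruncated samplers fail on the implied infinite
precision; the truncation is far below any scientifically meaningful
value.

## Problem sizes used in the validation studies

The packaged studies run at sizes chosen to match the designs they emulate
while keeping a full validation cycle to a few minutes on one CPU: the
HDI-calibration study uses 200 replicates of 15 subjects × 120 trials; the
dissociation study uses 5 replicates per design at the emulated studies'
scale (18 per group × 360 test trials between; 25 × 240 within); the
meta-recovery study uses 20 replicates of 12 studies; DPSD identifiability
uses expected counts at $n = 10^6$. Simulation-heavy fits drop to 2 chains
with shorter adaptation; user-facing defaults remain 4 × 1000.

## Known limitations

* Equal-variance DPSD only; no unequal-variance or hybrid ROC models, and
  no ROC estimation from remember-know data.
* Recollection is modelled as design-condition-specific but
  item-homogeneous; no item random effects in the generator.
* The DPSD per-subject ML estimates are finite-sample biased at ~120
  trials per class (quantified above); comparisons across conditions are
  robust to this, absolute levels less so.
* The meta-analytic variance-explained figure inherits the instability of
  a ratio of small heterogeneity estimates when $\tau_{\text{basic}}$ is
  near zero.
* Hierarchical (group-level) DPSD fitting is out of scope; subjects are
  fit independently, as in the per-subject analysis tradition.
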