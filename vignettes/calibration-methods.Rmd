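---
title: "Calibrating functional assay scores into ACMG/AMP evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating functional assay scores into ACMG/AMP evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavecal)
```

## The problem

High-throughput functional assays score thousands of variants in a gene on
a continuous scale, but clinical variant classification consumes discrete
evidence: supporting, moderate, strong or very strong, in a pathogenic or
benign direction. The common practice of declaring a single
normal/abnormal score threshold and giving every variant beyond it the
same strength both over-rewards variants barely past the threshold and
under-rewards variants far past it. `mavecal` instead assigns
variant-level evidence from the *local* positive likelihood ratio of the
score, with all distributional quantities estimated from the assay's own
control samples.

## Model

Let $S_P$, $S_B$, $S_G$ and (optionally) $S_S$ be the assay scores of the
P/LP controls, B/LB controls, a population-reference sample (e.g. gnomAD
missense variants in the assayed region), and synonymous variants. Each
sample's score distribution is a two-component mixture sharing one pair of
skew-normal components,

$$p_i(s) = w_i \, \mathrm{SN}(s;\theta_a) + (1-w_i)\,\mathrm{SN}(s;\theta_n),
\qquad i \in \{P, B, G, S\},$$

where $\theta_a$ describes functionally abnormal and $\theta_n$
functionally normal variants, and only the abnormal weight $w_i$ differs
between samples. Skew normals are used because assay score distributions
are routinely asymmetric; the synonymous sample, when present, enters the
likelihood exactly like the others (it mostly pins down $\theta_n$ and the
measurement asymmetry).

Three quantities follow from a fit:

* local positive likelihood ratio
  $\mathrm{lr}^+(s) = p_P(s) / p_B(s)$;
* prior probability of pathogenicity, from reading the reference sample as
  a pathogenic/benign mixture:
  $P(Y{=}1) = (w_G - w_B)/(w_P - w_B)$, flagged invalid outside $(0,1)$ or
  when $w_P \le w_B$;
* evidence thresholds: with scaling constant $c$, a pathogenic level of
  $x$ points requires $\mathrm{lr}^+(s) \ge c^{x/8}$ and a benign level
  $\mathrm{lr}^+(s) \le c^{-x/8}$, and the threshold for a level is the
  most extreme score at which its floor is met (located by `uniroot` on
  the monotone log-$\mathrm{lr}^+$ curve, score tolerance $10^{-8}$).

## The scaling constant and the combining rules

`solve_c()` finds the smallest $c \ge 1$ such that, at the given prior,
every pathogenic evidence combination reaches posterior probability 0.99
and every likely-pathogenic combination reaches 0.90, where a combination
holding $n_{su}, n_{mo}, n_{st}, n_{vs}$ lines has
$\mathrm{LR}^+ = c^{n_{su}/8 + n_{mo}/4 + n_{st}/2 + n_{vs}}$. The
feasible set is a half-line, so bisection to relative precision $10^{-4}$
suffices.

One design decision matters here. Under the exponential point system the
classic "two strong lines $\Rightarrow$ pathogenic" combination (8 points)
is discordant with the rest of the rule set: satisfying it at the 0.99
posterior level forces $c \approx 891$ at prior 0.1, while the accepted
derivation of the constant yields $c \approx 350$ there (and
$c \approx 1124$ at prior 0.044) — driven by the 6-point
likely-pathogenic combinations, for which the closed form is
$c = (9 \cdot \tfrac{1-\pi}{\pi})^{4/3}$ at prior $\pi$. The default rule
set therefore excludes the two-strong combination, reproducing the
established constants; `default_acmg_rules(include_two_strong = TRUE)`
restores it, and any rule set can be supplied as a delimited file for
expert-panel variations. Benign combinations never constrain $c$; benign
floors are simply $c^{-x/8}$. The intermediate $\pm 3$-point level is
included by default since points are just log-$\mathrm{LR}^+$ units.

## Constrained EM

The EM algorithm works in the alternate parameterization
$X = \mu + \Delta T + \sqrt{\Gamma}\, U$ ($T$ standard normal truncated
below zero, $U$ standard normal; $\Delta = \omega\lambda/\sqrt{1+\lambda^2}$,
$\Gamma = \omega^2 - \Delta^2$). The E-step computes each observation's
abnormal responsibility with its own sample's weight, plus the conditional
truncated-normal moments $e_1 = E[T\mid x]$ and $e_2 = E[T^2 \mid x]$. The
M-step updates, pooling responsibilities $p_j$ across all samples,

$$\ddot\mu = \frac{\sum_j p_j (x_j - \bar\Delta e_{1j})}{\sum_j p_j},\quad
\ddot\Delta = \frac{\sum_j p_j (x_j - \ddot\mu) e_{1j}}{\sum_j p_j e_{2j}},\quad
\ddot\Gamma = \frac{\sum_j p_j\big[(x_j-\ddot\mu)^2 - 2\ddot\Delta (x_j-\ddot\mu) e_{1j} + \ddot\Delta^2 e_{2j}\big]}{\sum_j p_j},$$

and each sample's weight becomes its mean abnormal responsibility. Each
coordinate update was verified against a one-dimensional numerical
maximization oracle of the expected complete-data log-likelihood (see
`test-mixture-em.R`). All density work is done in log space with
log-sum-exp, since extreme skews underflow ordinary densities.

**Monotone density ratio.** The calibration requires
$\mathrm{SN}(s;\theta_a)/\mathrm{SN}(s;\theta_n)$ non-increasing over the
observed score range (lower scores = more abnormal); together with
$w_P > w_B$ this makes $\mathrm{lr}^+$ and the posterior monotone, so
stronger scores never earn weaker evidence. The constraint is checked on a
2048-point grid spanning the observed range padded by 5% on each side
(padding guards edge crossings), and is re-imposed by a 50-step binary
search along the segment from the last feasible value to the proposed
value *after each of the six component-parameter updates*
($\mu^{(a)}, \Delta^{(a)}, \Gamma^{(a)}, \mu^{(n)}, \Delta^{(n)},
\Gamma^{(n)}$). Per-coordinate projection is deliberate: the EM objective
is unimodal along each single-coordinate segment, so any partial move
preserves monotone ascent, whereas projecting the whole parameter vector
at once can reduce the objective and stall the fit. The projection acts on
the full alternate triple, so the skew (carried by $\Delta$) is
constrained too. As a safety net, an iteration that would still decrease
the observed-data log-likelihood by more than $10^{-9}$ is rejected and
the run stops at the previous parameters, so the per-iteration likelihood
trace is non-decreasing by construction.

**Initialization and restarts.** K-means ($K = 2$, 10 starts) on the
pooled observations; per-cluster Gaussian fits give locations and scales;
skews are drawn from $U(-0.25, 0.25)$; the lower-location component is
labeled abnormal, and that identity is fixed for the rest of the run.
Initial weights are each sample's fraction in the abnormal cluster,
clipped to $[0.02, 0.98]$ so no restart starts at a degenerate fixed
point. If the initial pair violates the ratio constraint, the component
locations are stepped apart (2% of the padded range per step) until it
holds. The procedure is restarted from `n_restarts` seeds (default 100;
the test suite uses 10) and the highest-likelihood fit is kept; restart
$r$ uses master seed $+\,r-1$, so runs are exactly reproducible.

**Convergence.** Relative log-likelihood change below $10^{-6}$ or 500
iterations, whichever first. These are conventional EM settings; the
likelihood surface is flat in the location/skew directions (see
Limitations), so much tighter tolerances mostly spend iterations drifting
along a ridge of nearly-equal likelihood.

## Bootstrap

`bootstrap_calibrate()` repeats the whole procedure (default 5000
iterations; a few hundred are adequate for exploration) on stratified
resamples: each labeled sample is resampled with replacement
independently, keeping the observation sets disjoint. Each iteration
re-estimates the prior, re-solves $c$ *for that prior*, and recomputes
thresholds. Iterations with invalid priors are excluded from aggregation
(and counted). Final thresholds take the conservative tail: the 5th
percentile of pathogenic thresholds and the 95th percentile of benign
thresholds; a level is reported only if at least 95% of the *valid*
iterations reach it — the valid-only denominator is an interpretation
choice, consistent with excluding invalid iterations everywhere else.
Out-of-bag assignment (`oob_assign()`) gives each variant the modal points
over iterations whose resample excluded it, with ties broken toward 0 (a
residual $+x$ vs $-x$ tie returns 0, the conservative choice).

## Synthetic data: what it does and does not emulate

`generator_config()`/`generate_dataset()` draw each sample from exactly
the assumed mixture, with a truth sidecar kept in a separate file so the
pipeline cannot consume labels accidentally. The reference study condition
(`make_fixture_suite()`, also used throughout the tests) is: components
$\theta_a = (-3, 1, 0.2)$ and $\theta_n = (0, 1, -0.2)$ — three scale
units of separation, mild opposite skews — weights
$w_P = 0.9, w_B = 0.05, w_G = 0.135, w_S = 0.02$ (implied prior exactly
0.1), 2000 variants per sample. The suite adds an overlapping-pathogenic
condition ($w_P = 0.45$: an assay blind to half the disease mechanism,
which should earn no benign evidence level because
$\mathrm{lr}^+ \to (1-w_P)/(1-w_B) \approx 0.58$ stays above the $-1$
floor), a tiny-B/LB condition (8 benign controls, the size of a real
lipid-phosphatase dataset) and a no-synonymous condition. The generator
draws from the true parametric family with independent observations; it
does not emulate replicate correlation, score normalization artifacts,
label errors, or ascertainment bias in the control sets — so passing
recovery tests demonstrates correctness of the estimator under the model,
not robustness to real-data misspecification.

## Fit diagnostics

`cdf_distance()` evaluates the empirical and fitted CDFs of one sample at
all unique observed scores and returns the normalized $p=2$ distance
$\|F-G\|_2 / (\|F\|_2 + \|G\|_2) \in [0, 1]$. The reference and synonymous
samples are the informative ones (the control samples are small and
selection-biased); medians below about 0.2 across bootstrap iterations
indicate an acceptable fit. `lr_dor()` summarizes a P/LP-vs-B/LB direction
contingency table by the global positive likelihood ratio and diagnostic
odds ratio, for the pathogenic-vs-rest and benign-vs-rest
dichotomizations.

## Numerical choices collected

* Density-ratio grid: 2048 points, 5% padding; violation tolerance
  $10^{-12}$ on log-ratio increments.
* Binary search: 50 bisection steps, last feasible point accepted.
* `solve_c`: bisection, relative precision $10^{-4}$.
* Threshold roots: `uniroot`, tolerance $10^{-8}$ score units.
* Skew-normal CDF: Owen's T by adaptive quadrature
  ($F(x) = \Phi(z) - 2T(z, \lambda)$), agreeing with quadrature of the
  density to $10^{-6}$.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; bootstrap iteration $k$ and restart $r$ derive
  seeds `seed + (k-1)(n_restarts+1) + r - 1`.
* Test-suite problem sizes: 20 generator replicates at 2000
  observations/sample with 10 restarts for recovery checks; 50 bootstrap
  iterations with 5 restarts for the fit-quality distribution. These are
  the package's desk-scale defaults for property checks; production runs
  use the full 100 restarts and 5000 iterations.

## Known limitations

* **Location/skew weak identifiability.** The skew normal's Fisher
  information is singular at $\lambda = 0$; with true skews of $\pm 0.2$
  the likelihood is nearly flat along a ridge trading location against
  skew. At 2000 observations per sample, maximum likelihood (verified with
  a direct numerical MLE, independent of the EM) can place a component's
  location 0.3–0.5 score units from the truth *with higher likelihood than
  the truth* while leaving the component's overall density — and therefore
  $\mathrm{lr}^+$, thresholds and evidence — essentially unchanged.
  Location parameters should not be over-interpreted at small skew;
  weights and the prior are well identified.
* Single abnormal mechanism: genes with mixed gain/loss-of-function would
  need a third component, out of scope here.
* The control samples are assumed unbiased draws of their class; curation
  or ascertainment bias propagates directly into $\mathrm{lr}^+$.
* Dataset-specific normalizations (e.g. multi-promoter medians) are left
  to upstream preprocessing; splice filtering expects a precomputed
  per-variant splice score (maximum over the four delta categories) and
  simply drops scores strictly above the cutoff (default 0.5).
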