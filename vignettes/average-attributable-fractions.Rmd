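---
title: "Partitioning disability among co-morbid chronic conditions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning disability among co-morbid chronic conditions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aafsurvey)
```

## The estimand

In a cross-sectional survey where respondents report several chronic
conditions at once, the attributable fraction of condition $i$ —
Levin's $AF_i = P_e(RR-1)/[1+P_e(RR-1)]$ — answers "what fraction of
disability involves condition $i$", not "what fraction is due to condition
$i$ alone". Summed over co-morbid conditions the gross AFs exceed one,
because cases with several conditions are counted once per condition.

The average attributable fraction (AAF) removes the double counting by
averaging over elimination orders. Write $K$ for the set of $k$ condition
groups and $AF(S)$ for the joint attributable fraction of eliminating the
subset $S \subseteq K$. The sequential AF of condition $i$ after $S$ is
$AF(S \cup \{i\}) - AF(S)$, and

$$AAF_i \;=\; \sum_{S \subseteq K \setminus \{i\}}
\frac{|S|!\,(k-|S|-1)!}{k!}\,\bigl[AF(S \cup \{i\}) - AF(S)\bigr],$$

the average sequential AF over all $k!$ elimination orders — the Shapley
value of the set function $AF$. Three consequences are load-bearing and are
asserted by the test suite rather than assumed: *efficiency*
($\sum_i AAF_i = AF(K)$, exactly in exact mode), the *dummy* axiom (a
condition with no effect on the outcome model has AAF $0$) and *symmetry*
(exchangeable conditions receive equal AAFs).

## Subset AFs by model-based standardization

$AF(S)$ is evaluated by g-computation from a single survey-weighted
logistic model of the binary disability outcome on all $k$ condition
indicators plus the adjustment covariates (sex, place of residence, marital
status, living situation, educational level; age class is added when age
groups are pooled). With fitted probabilities $\hat p_j$ at the observed
data and $\hat p_{S,j}$ after setting the indicators in $S$ to zero for
respondent $j$ with analysis weight $w_j$,

$$AF(S) \;=\; 1 - \frac{\sum_j w_j\,\hat p_{S,j}}{\sum_j w_j\,\hat p_j}.$$

Fitting one joint model and standardizing over the subset lattice — rather
than refitting per subset — keeps the lattice internally consistent, makes
the efficiency identity exact, and sidesteps the odds-ratio/relative-risk
distinction: counterfactual probabilities, not effect ratios, are averaged.
The denominator uses *predicted* weighted cases so that $AF(\varnothing)=0$
holds exactly under any model misfit; an observed-case denominator is
available via `denominator = "observed"`.

Subset values are memoized in a $2^k$ bitmask table. Exact enumeration is
capped at $k \le 12$ (4,096 evaluations); beyond that `aaf_montecarlo()`
averages sequential increments over sampled permutations and reports a
per-factor Monte Carlo standard error. `aaf_permutation_oracle()`
($k \le 8$) enumerates all $k!$ orders directly; it is deliberately an
independent code path used to validate `aaf_exact()` to $10^{-12}$.

## Weighting chain

The analysis weight is built in three stages, mirroring standard practice
for two-stage stratified disability surveys:

1. **Design weight** — inverse of the stratum sampling fraction (strata =
   four presumed-severity levels × geographic areas, with the most severely
   disabled sampled at the highest rate).
2. **Non-response adjustment** — a logistic response-propensity model fitted
   on respondents and non-respondents together; respondent weights are
   divided by the fitted propensity (floored at 0.02 by default to cap
   weight inflation, with the number of clipped records logged), and
   non-respondents are then dropped.
3. **Calibration** — multiplicative raking (iterative proportional fitting)
   to marginal population totals of area, age class and sex, iterated until
   the maximum relative margin error is below $10^{-8}$ (default; at most
   100 cycles, with a convergence error otherwise). Raking preserves the
   weighted interaction structure of the margin variables.

Variances for weighted prevalences use with-replacement Taylor
linearization within strata. Count-based interval formulas (the AF interval
below) receive weighted cells rescaled to the Kish effective sample size
$(\sum w)^2/\sum w^2$.

## Gross AFs, intervals and grouping

Gross AFs feed Levin's formula with the *crude* weighted relative risk:
Levin's formula presumes the population RR, and covariate adjustment is the
AAF stage's job (a covariate-standardized RR option exists). The
confidence interval is a delta-method interval on $\log(1-AF)$ from the
effective 2×2 cells, back-transformed — symmetric on the log-complement
scale and validated against a 10,000-resample bootstrap oracle rather than
claimed to match any particular published variant, since the variant used
in the source analyses of this design is not recoverable.

Conditions whose gross AF is at or below 15% (ties grouped) in **every**
age class are merged into a single "other diseases" indicator (the OR of
the member conditions per record) before the AAF stage, so the same factor
set is analyzed in every column; a per-class mode exists behind
`scope = "per_class"`. Expected prevented-case counts are $AAF \times$
(weighted disabled count), reported raw and rounded to the nearest 10,000
(configurable), matching the reporting granularity of national estimates.

## The synthetic-data generator

`population_spec()` defines the generating model; its defaults are the
study conditions the package validates itself under:

* **Conditions** — twelve ICD-10 groups at published adult household
  prevalences (sensorial 65.4% … cancer 1.9%). Co-morbidity comes from a
  shared standard-normal frailty $U$: condition $j$ is present when
  $\lambda_j U + \sqrt{1-\lambda_j^2}\,Z_j \le \Phi^{-1}(p_j)$, a Gaussian
  copula that keeps every marginal exact while pairwise association grows
  with $\lambda_i\lambda_j$ (default loading 0.5). A single-factor copula
  is the simplest structure reproducing the observed clustering of
  condition counts; richer dependence is out of scope.
* **Covariates** — age mixture over the three broad classes (37.7 / 42.8 /
  19.5%), sex, marital status, living alone, education, residence, with
  class-typical French-population shares.
* **Outcomes** — one logistic model per definition, log odds ratios chosen
  so the implied ordering of contributions is realistic (neurological and
  psychiatric conditions strongest for ADL and severe disability,
  musculoskeletal and sensorial for self-report). Intercepts are calibrated
  by root-finding so the marginal rates equal 12.0% (self-reported), 3.9%
  (ADL disability) and 1.4% (severe). The two ADL outcomes share one
  uniform draw with the severe probability truncated at the disability
  probability, so severe ⇒ disabled holds by construction.
* **ADL items** — disabled persons get one primary restricted item (score 4
  if severe, else 1–3) and each further item restricted with probability
  0.3; non-disabled persons score 0 everywhere. The filter-survey scoring
  behind presumed severity is not published, so the generator uses the
  convention: level 4 = any item 4, level 3 = any restriction, level 2 =
  self-report only, level 1 otherwise.
* **Design and non-response** — severity sampling fractions (0.10, 0.20,
  0.50, 0.90) over 11 areas (uniform area multipliers by default, since no
  published per-area fractions exist), Bernoulli-within-stratum sampling by
  default (simplest unbiased Horvitz–Thompson weights; fixed-size mode
  available), and a logistic response model calibrated to a 76.6% marginal
  response rate with lower response at higher severity and age.

`true_aaf_oracle()` computes ground-truth AAFs by large-sample
g-computation under the known generating model on the generated population
— the same Shapley combination applied to exact model probabilities rather
than estimates.

What the generator does **not** emulate: proxy-respondent measurement
error, item non-response, institutional (non-household) populations,
age-dependent condition prevalence, and model misspecification (outcomes
really are logistic in the indicators). Passing recovery tests therefore
demonstrates that the estimation chain is consistent and unbiased under its
own assumptions, not that those assumptions hold in any real survey.

## Numerical and design choices

* **Age classes** — half-open intervals $[18,40)$, $[40,65)$, $[65,\infty)$;
  `inclusive_forty = TRUE` moves exactly-40 into the youngest class, since
  both boundary conventions appear in common reporting.
* **Grouping rule** — "merge iff AF ≤ threshold in every age class" was
  chosen over per-class grouping so that one factor set (and hence one
  comparable decomposition) is used across all columns.
* **Report sums** — sum rows use unrounded values, formatted once at the
  end (the alternative, summing the printed one-decimal entries, is
  available as `sum_mode = "sum_of_rounded"`); published tables of this
  kind are consistent with unrounded summation.
* **Separation and convergence** — logistic fits error (naming the terms)
  on non-convergence, aliasing, or coefficients beyond ±15; raking errors
  on empty cells with positive margins and on non-convergence, listing the
  offending cells and final errors.
* **AAF confidence intervals** — none are produced: no established method
  exists for AAF interval estimation, and the package does not pretend
  otherwise. (A design-respecting bootstrap could be layered on by the
  user; it is deliberately not built in as if it were standard.)
* **Seeds** — one master seed per run; per-stage child seeds are derived
  deterministically, so identical configurations produce byte-identical
  written reports.
* **Problem sizes** — the validation suite uses populations of 2,000–50,000
  and 50 replicate surveys of 20,000 for rank-order recovery; these sizes
  give Monte Carlo error comfortably below the tested tolerances while
  keeping the suite quick to run.

## Known limitations

* Exact AAF mode is exponential in $k$; the cap of 12 factors matches the
  twelve condition groups, and Monte Carlo mode covers larger sets at the
  cost of sampling error.
* The crude RR feeding Levin's formula is confounded whenever covariates
  are; the gross-AF table is descriptive, and the adjusted AAF table is the
  substantive result.
* Taylor-linearized variances treat sampling as with-replacement within
  strata; replicate-weight variance systems are out of scope.
* `fleiss_ci()` requires all four effective cells positive; sparse
  condition × outcome cells in small age classes need the continuity
  option or a coarser analysis.
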