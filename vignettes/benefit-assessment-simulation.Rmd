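---
title: "Comparing additional-benefit assessment rules by simulating phase-III survival trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing additional-benefit assessment rules by simulating phase-III survival trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a positive phase-III trial with overall survival as the primary
endpoint, several bodies grade how much *additional benefit* the new
treatment offers — and they read different statistics off the same trial:

* **ASCO** (net health benefit, reduced here to its statistical core) scores
  continuously from the hazard-ratio point estimate,
  $\mathrm{NHB} = 100\,(1 - \widehat{HR})$, plus a 20-point *tail-of-curve*
  bonus judged at twice the control arm's median survival.
* **IQWiG** grades ordinally (minor < considerable < major) from the *upper*
  95% confidence limit $HR^{+}$ against thresholds 0.85 and 0.95 that were
  originally derived on the relative-risk scale.
* **Mod-IQWiG** applies the same rule after converting those thresholds to
  the hazard-ratio scale with VanderWeele's approximation
  $RR(HR) = \frac{1 - 0.5^{\sqrt{HR}}}{1 - 0.5^{1/\sqrt{HR}}}$, giving 0.79
  and 0.93.
* **ESMO** (magnitude of clinical benefit, grades 1–4) uses a dual rule on
  the *lower* confidence limit $HR^{-}$ and the absolute gain in median
  survival, with thresholds depending on the control-median band, plus a
  milestone rule: a survival-rate increase of at least 10 percentage points
  at the band's key milestone grants grade 4 on its own.

Because each rule keys on a different estimate, the interesting questions
are empirical: how often does each rule award its maximal category under a
given true effect, how strongly do the rules agree, and which ASCO score
ranges correspond to which ordinal categories? benefitsim answers these by
simulation: it generates large grids of realistically sized two-arm trials,
scores every significant one with all four rules, and summarizes agreement
with rank correlations and weighted-kappa-optimal cutoffs.

## Trial designs and the scenario grid

A *subscenario* fixes a design hazard ratio (grid 0.30–0.90 in steps of
0.02), a control median (6–30 months), a target power (80% or 90%), a
failure-time family with shape, and a deviation factor
$HR_\mathrm{var} = \text{trueHR}/\text{designHR}$.  Events are sized by
Schoenfeld's formula
$d = \lceil 4\,(z_{1-\alpha/2} + z_{\beta})^2 / \log(\text{designHR})^2\rceil$
for a two-sided 5% log-rank test with 1:1 allocation, and the total sample
size inflates the event count for the targeted 60% overall censoring,
$n = \lceil d / 0.4 \rceil$ rounded up to even (the rounding is this
package's choice; any convention changes $n$ by at most one patient pair).

Five scenarios cover the study conditions: `standard` (exponential,
trueHR = designHR; 310 subscenarios), `mispowered` (exponential,
$HR_\mathrm{var} \in \{0.8, 0.9, 1.1, 1.2\}$; 1,240), `weibull` (shapes 0.5
and 1.5; 620), `gompertz` (shapes −0.2 and 0.2; 620) and `delayed`
(piecewise exponential; 310).  We label trials *overpowered* when the true
effect is stronger than designed ($HR_\mathrm{var} < 1$): the realized power
then exceeds the design power.  The published wording ties "overpowered" to
$HR_\mathrm{var} > 1$, but the reported behaviour of all methods (higher
maximal-category rates, tighter intervals) matches the operational reading,
which we adopt; the grid stores $HR_\mathrm{var}$ so either convention can
be recovered.

## Failure times

Control-arm parameters come from fixing the control median: exponential
$\lambda = \log 2 / m$; Weibull with hazard $\lambda k t^{k-1}$,
$\lambda = \log 2 / m^{k}$; Gompertz with hazard $\lambda e^{bt}$,
$\lambda = b \log 2 / (e^{bm} - 1)$.  Treatment arms multiply the rate by
trueHR (proportional hazards).  A negative Gompertz shape implies a survival
plateau (a "cured" fraction $e^{\lambda\,\text{trueHR}/b}$ never fails);
such draws return `Inf` and end as administratively censored, which is why
some decreasing-hazard designs cannot reach the 60% censoring target and are
excluded from the grid.

The delayed scenario gives the treatment arm hazard $\lambda_C$ on
$[0, t_0]$ and $\lambda_T = \text{trueHR}\,\lambda_C$ afterwards, with onset
$t_0 = \text{med}_C/3$; draws invert the piecewise cumulative hazard, using
the standard piecewise-exponential law
$S_T(x) = \exp(-\lambda_C t_0 - \lambda_T (x - t_0))$ for $x > t_0$ — the
only monotone distribution with hazard $\lambda_C$ before the onset and
$\lambda_T$ after, continuous at the onset with
$F_T(t_0) = 1 - e^{-\lambda_C t_0}$.

## Censoring

Each patient enters uniformly over a 24-month accrual period and is
administratively censored at `accrual + followup − entry` with follow-up
$2\,\text{med}_C$; on top of that an independent exponential censoring time
applies.  Its rate is calibrated per design so that the *overall* censoring
probability — under the design effect, the 1:1 arm mixture, and uniform
entry — equals 60%, by Gauss–Legendre quadrature over entry and censoring
time (32 × 64 nodes, split at the onset for the delayed family) and a root
search to below 1e−6 relative tolerance.  A Monte-Carlo check at $10^6$
patients reproduces the target to ±0.002.  Designs whose administrative
censoring alone exceeds 60% are flagged excluded and never simulated; with
the entry-averaged convention used here that affects 76 decreasing-hazard
Gompertz subscenarios.  Calibration uses the design effect (not the true
effect) because sizing does: in mispowered scenarios the realized censoring
deviates slightly, which is part of what those scenarios emulate.

## Estimation and scoring

Each simulated trial is reduced to: a two-sided log-rank p-value; the Cox
hazard-ratio estimate with Wald 95% limits (Efron tie handling — ties are
measure-zero for continuous failure times, so the tie policy is
inconsequential); Kaplan–Meier medians per arm, where a curve that never
drops to 0.5 conservatively falls back to the arm's last observed event or
censoring time (flagged); and Kaplan–Meier survival at 24, 36 and 60 months
and at twice the estimated (and design) control median, carrying the last
value beyond follow-up with a flag.  For speed these estimators are computed
by lean internal routines built on `survival::coxph.fit` and
cumsum/cumprod algebra; the test suite pins them to `survival::survfit`,
`survival::survdiff` and `survival::coxph` on tied and untied data.

A trial enters scoring when the log-rank p-value is below 0.05 *and* the
hazard ratio points in the favorable direction; scoring a significantly
harmful trial for "benefit" is meaningless, and the directional gate can be
switched off (`directional = FALSE`).  Degenerate replicates (an arm without
events, a failed fit) are counted and excluded, never re-simulated.

Two scoring details deserve emphasis:

* **ESMO thresholds** are shipped as a config file
  (`inst/extdata/esmo-thresholds-os-advanced.csv`) reconstructed from the
  published ESMO-MCBS v1.1 form for overall survival in the non-curative
  setting, since only the rule *structure* is fixed by the running text.
  Under this table the simulated standard scenario reproduces the published
  grade-1/grade-4 proportions and per-grade ASCO medians closely; the split
  between grades 2 and 3 (which no headline result uses) is the one place
  where the reconstruction is visibly uncertain.
* **The ASCO tail-of-curve bonus** ("proportion alive improved by 50% or
  more, assuming >20% surviving in the control arm") is ambiguous: read
  *relatively* ($S_T \ge 1.5\,S_C$) the bonus fires for essentially every
  hazard ratio below 0.71 under exponential failure times and inflates the
  pooled score median by ~13 points; read *absolutely* (an increase of at
  least 50 percentage points) it is rare under proportional hazards.  Only
  the absolute reading reproduces the published score medians and cutoffs,
  so it is the default; `tail_rule = "relative"` selects the other reading.

## Agreement and cutoffs

Pooled over a scenario's subscenarios, the package reports category
proportions, ASCO medians (overall and per category), tie-aware Spearman
correlations (Kendall $\tau_b$ available for moderate pools), and the ASCO
cutoffs most concordant with each ordinal scale.  The primary cutoff method
maximizes weighted Cohen's kappa,
$\kappa = 1 - \sum w_{ij} x_{ij} / \sum w_{ij} m_{ij}$ with quadratic
Fleiss–Cohen disagreement weights, by exhaustive search over strictly
increasing integer cutoff vectors in 0–100 (ties resolved to the
lexicographically smallest vector — the published work specifies neither the
grid nor the tie-break, and integer cutoffs match the reported values).  Two
sensitivity methods are included: ROC cutoffs closest to the (0, 1) corner
for each pairwise category split (ties toward higher specificity), and
Svensson cutoffs at the score quantiles matching the ordinal marginals.

## Reproducibility and problem sizes

Each subscenario owns an L'Ecuyer-CMRG stream indexed by its grid position,
so results are bit-reproducible and invariant to grid subsetting, row order,
or worker partitioning.  The package's own checks and the acceptance script
run at 50–100 replicates per subscenario (tens of thousands of simulated
trials per scenario, a few minutes each on one core); the published study
used 10,000 replicates per subscenario.  At the scaled size, pooled category
proportions carry Monte-Carlo noise of roughly one percentage point, pooled
medians about one score point, and kappa-optimal cutoffs one to two points;
the tests assert published values at correspondingly scaled tolerances.

## What the generator does and does not emulate

The simulator covers the statistical core: realistic event sizing, four
failure-time families including one non-proportional-hazards mechanism, and
heavy mixed censoring.  It does not model toxicity or quality-of-life bonus
points (both frameworks' full versions include them), drop-out beyond
exponential censoring, non-uniform accrual, covariates, stratification,
interim analyses, or multi-trial approvals.  Agreement statistics computed
here therefore characterize the *statistical* behaviour of the rules; real
applications add non-statistical components that can shift absolute scores.

## Known limitations

* The ESMO threshold table is a reconstruction (see above); grades 2/3 are
  the least certain rows.
* Under decreasing-hazard Gompertz designs the ESMO grade distribution is
  highly sensitive to how plateau-shaped curves interact with the fallback
  median and the milestone rule; the package reproduces every published
  Gompertz headline quantity except the grade-1 proportion, which it
  underestimates (≈27% vs 34.75%) for reasons the available description does
  not pin down.
* Kendall's $\tau_b$ uses the quadratic-time base-R implementation and is
  off by default for large pools.
* The exclusion rule's integration convention (entry-averaged administrative
  censoring) yields 76 excluded Gompertz subscenarios; the published count
  is 56, and the published description leaves the convention open.
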