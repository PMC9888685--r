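---
title: "Tree-structured moderation models for censored survival disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-structured moderation models for censored survival disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prismsurv)
```

## The model

Health-disparity analyses often ask not whether a group difference exists,
but *where* it is concentrated and *what moderates it*. prismsurv models the
log survival time $T$ of a patient as a varying-coefficient regression on a
binary focus variable $x$ (here a race indicator, focus group coded 1):

$$ T = \beta_0(\mathbf z) + \beta_1(\mathbf z)\,x + e, $$

where the coefficient surfaces $\beta_j(\mathbf z)$ depend on
individual-level covariates $\mathbf z$ (age, stage, grade, treatment, ...).
Because the surfaces are unknown and potentially high-dimensional, they are
approximated by a tree: a recursive partition of the covariate space into
cells $A_1, \dots, A_L$ with constant coefficients per cell,

$$ T = \sum_l \bigl(\theta_{0l} + \theta_{1l}\,x\bigr)\,
       \mathbf 1(\mathbf z \in A_l) + e . $$

This is the PRISM model: within each discovered subgroup the focus effect
$\theta_{1l}$ is the predicted difference in mean log survival between the
groups, i.e. the log of their survival-time ratio.

The hierarchical extension (HPRISM) adds an area-level (census-tract)
contextual variable $w$ — a social determinant such as median household
income, constant within tract — interacting with the focus variable:

$$ T = \sum_l \bigl(\theta_{0l} + \theta_{1l}\,x + \theta_{2l}\,x\,w\bigr)\,
       \mathbf 1(\mathbf z \in A_l) + e . $$

The focus effect in cell $l$ at contextual value $w$ is then
$d_l(w) = \theta_{1l} + \theta_{2l} w$: moderation operates at two levels,
through the partition (individual-level) and through $w$ (contextual).

Key assumptions: the error distribution is unspecified but censoring must be
*random* — independent of $(x, \mathbf z, w)$ — for the Kaplan–Meier
weighting below to identify the regression; the focus variable is binary;
one contextual variable enters at a time (fit several HPRISM trees to
compare determinants).

## Estimation under right censoring

We observe $y = \min(T, C)$ and $\delta = \mathbf 1(T \le C)$ on the log
scale (times are recorded in days and log-transformed at load, with no
offset). Within each node the coefficients are estimated by weighted least
squares with Kaplan–Meier (Stute) jump weights computed from that node's own
observations: ordering the node's $y$ ascending (events before censorings at
ties),

$$ d_{(1)} = \frac{\delta_{(1)}}{n}, \qquad
   d_{(i)} = \frac{\delta_{(i)}}{n-i+1}
   \prod_{j<i}\Bigl(\frac{n-j}{n-j+1}\Bigr)^{\delta_{(j)}} . $$

Censored observations get weight zero; the weights are the jumps of the
node's Kaplan–Meier estimate of the event-time distribution, which makes the
weighted fit consistent under random censoring. `stute_weights()` and
`fit_node_model()` expose this machinery directly.

### Split search

A split of node $\tau$ into daughters $\tau_L, \tau_R$ is scored by the drop
in the sum of squared *imputed* residuals,

$$ \Delta RSS(s) = \sum_{i\in\tau}\hat r_i^2 -
   \Bigl(\sum_{i\in\tau_L}\hat r_i^2 + \sum_{i\in\tau_R}\hat r_i^2\Bigr), $$

where $\hat r_i = r_i$ for events and, for censored records,
$\hat r_i = \widehat E(e \mid e > r_i)$ — the mean of the uncensored
residuals strictly exceeding $r_i$. The parent term uses the parent's fitted
model; each daughter term refits its own model, with weights recomputed and
residuals re-imputed inside the daughter. (Whether the daughter terms should
re-use the parent's coefficients was genuinely open; refitting matches the
definition of the approximation as separate per-cell models and is the
default, while `daughter_residuals = "parent"` re-imputes under the parent's
coefficients for comparison. Re-partitioning the parent's *imputed*
residuals themselves would make $\Delta RSS \equiv 0$ and cannot be meant.)

A log-rank alternative (`criterion = "logrank"`) scores a candidate by
$|LR(\tau_L) - LR(\tau_R)|$, the absolute difference of the two daughters'
two-sample log-rank statistics comparing the focus groups; it is computed on
the original time scale (log-rank statistics are rank-invariant, so this is
immaterial). Because this criterion carries no goodness-of-fit scale of its
own, the complexity rule below is still applied to the selected split's
$\Delta RSS$.

### Exclusion criteria and stopping

Only candidates whose daughters each contain at least `min_node` records
(default 20) and at least `min_events_per_group` (default 1) uncensored
records of *each* focus group are admissible; in HPRISM mode the uncensored
records of each focus group must additionally span at least two distinct
tracts per daughter, otherwise the $x \cdot w$ interaction would not be
estimable after the split. A split is accepted only when its improvement is
at least `cp` (default 0.01) times the root's imputed-residual sum of
squares — the rpart-style complexity rule. Cost-complexity pruning and
cross-validated `cp` selection are intentionally out of scope; the knob is
exposed.

### Numerical choices

* Candidate thresholds are midpoints between consecutive distinct observed
  values within the node, so a returned cut always lies strictly between two
  observations and the `<` rule is unambiguous.
* Ties at equal $y$ order events before censorings (the usual Kaplan–Meier
  convention); tied events share the product formula applied sequentially.
* When no uncensored residual exceeds a censored $r_i$, the raw residual is
  kept — a conservative fallback for the right tail.
* Nominal covariates with at most 6 observed levels are scanned over all
  binary level partitions (each partition once, in lexicographic order of
  the left set); with more levels the levels are ordered by the mean log
  time of their uncensored members and scanned as ordinal.
* Exact criterion ties break toward the earlier covariate, then the smaller
  threshold / lexicographically smaller subset, making `prism()` fully
  deterministic given the data and configuration.
* If $w$ does not vary among an HPRISM node's positively weighted focus
  records, the interaction column is collinear and is dropped for that node
  ($\theta_2 = 0$); downstream disparity estimates inherit the zero.
* The recursion is depth-first, left daughter first, with node ids assigned
  in creation order; `max_depth` (default 30) is a safety bound, not a
  tuning device.
* The candidate scan — daughter refits and re-imputation for every midpoint
  — is the computational core and is implemented in compiled code, with the
  readable R functions (`stute_weights()`, `fit_node_model()`,
  `impute_residuals()`) kept as an independently tested reference path.

## Predictive evaluation

`prism_holdout()` repeats a censoring-stratified 80/20 split (both sets
preserve the censoring fraction to integer rounding), grows the tree on the
training set, and scores test-set predictions with Harrell's concordance
(`harrell_c()`); repeats default to 100. Predictions are log survival
times, so *higher* predictions accompany *longer* survival — the opposite
orientation from risk scores; comparisons with risk-score concordances must
flip. Pairs are usable when the shorter observed time is an event; pairs
tied on time are used only when exactly one member is an event, and
prediction ties count one half.

## Interpreting the tree

**Local variable importance.** `lvimp()` scores covariate $v$ for terminal
node $l$ by noising up: permute $v$'s column across the whole dataset,
rebuild the entire tree with the identical configuration, route node $l$'s
original members down the rebuilt tree, and compare their prediction error
with the original. "Prediction error" is the Stute-weighted mean squared
error of predicted versus observed log time, with the node members' own
Kaplan–Meier weights (the definition of the weighting was open; the node's
own weights keep the error on the same footing as the node's fit). Values
at or below zero mean the variable does not matter for that node. The
permutation is global (the tree is rebuilt globally), `n_perm` (default 10)
replicates average out Monte-Carlo noise with `n_perm = 1` reproducing the
single-pass procedure, and ranks are assigned within node, descending,
ties sharing the minimum rank (`rank_abs = TRUE` ranks by magnitude
instead).

**Andrews curves.** `andrews_curves()` embeds each node's rank-ordered
importance vector $c$ into
$f_c(t) = c_1/\sqrt2 + c_2\sin t + c_3\cos t + c_4\sin 2t + c_5\cos 2t +
\dots$ on $[-\pi, \pi]$ — the classical construction with increasing
frequencies (a series that repeated frequency one would collapse terms and
be degenerate). Nodes with similar importance profiles yield nearby curves.

## Tract-level disparity (SPADE)

Direct tract-level estimation is impossible when every patient in a tract
shares one $w$; the fitted tree lets a tract-level estimate be reverse
engineered. For tract $m$, every terminal node $l$ containing its records
contributes the node disparity at the tract's own contextual value,
$d_{lm} = \theta_{1l} + \theta_{2l} w_m$, weighted by
$\eta_{lm} = n_{lm} / n_m$, the share of the tract's records in that node
(the only normalization for which $\sum_l \eta_{lm} = 1$):

$$ \hat d_m = \sum_l \eta_{lm}\, d_{lm} . $$

Because terminal nodes pool patients across tracts, tracts with one or two
records still receive estimates — borrowing strength in the small-area
estimation sense — where a direct per-tract Kaplan–Meier contrast
(`direct_tract_disparity()`) is undefined. Signs follow focus = 1 minus
focus = 0 on the log scale; displays oriented the other way are a sign
flip. `composite_spade()` sums SPADEs across contextual variables (a crude
but useful aggregate), and `robust_z()` standardizes heavy-tailed tract
distributions by $(v - \mathrm{median})/(1.4826\,\mathrm{MAD})$, the
normal-consistent scaling. `moderation_profile()` draws the per-node lines
$d_l(w)$ and flags "nearly parallel" when the range of $\hat\theta_{2l}$
falls below `parallel_tol` (default $10^{-3}$ log-time units per
contextual unit).

## The synthetic cohort generator

`simulate_prism_data()` draws multilevel cohorts with known moderation so
every claim above is testable without access to a cancer registry. The
reference condition (`prism_truth()`): n = 2000 patients in M = 100 tracts,
tract sizes multinomial under a Dirichlet(1) profile so that near-empty
tracts occur (exercising SPADE's borrowing of strength); one standardized
contextual value $w \sim N(0,1)$ per tract — area determinants are
standardized before modelling, which keeps $\theta_1$ and $\theta_2$
separately identifiable, whereas an uncentred income-like scale makes $x$
and $x w$ nearly collinear; three uniform covariates of which only `z1`
acts, splitting the space at 0.5 into leaves with
$(\theta_0, \theta_1, \theta_2)$ equal to $(1, -0.6, 0.15)$ and
$(2, 0.3, -0.12)$ — opposite-signed focus effects of realistic log-scale
magnitude; Gaussian noise with sd 0.25; and 20% random censoring,
implemented as an exponential censoring time on the day scale whose rate is
solved numerically so the marginal censoring probability hits the target.
`simulate_prism_null()` sets $\theta_1 = \theta_2 = 0$ for no-signal
checks. Everything flows from one seed; identical seeds give identical
cohorts.

What the generator does *not* emulate: informative censoring, competing
risks, covariate-dependent censoring, measurement error in $w$, spatial
correlation between tracts, or registry artefacts (duplicate reports,
misclassification). Passing tests therefore demonstrate correctness of the
estimators under the model's own assumptions, not robustness to their
violation.

## Problem sizes used by the test suite

The suite exercises the reference condition directly: truth recovery uses
100 simulated cohorts of n = 2000 at 20% censoring; holdout comparisons use
20 stratified repeats; the importance study uses 50 cohorts of n = 400 in
25 tracts with 5 permutation replicates (a size at which the full-rebuild
permutation scheme stays comfortably interactive); oracle comparisons run
on instances up to n = 200. These sizes are the package's reference
designs, chosen to estimate the relevant proportions with adequate
precision.

## Descriptive cohort statistics

The `chisq_homogeneity()` / `fisher_exact()` / `binary_logit()` /
`multinomial_logit()` / `proportional_odds()` family reproduces the
standard descriptive comparison of focus groups across levels of one
variable from a 2×K count table. Conventions that matter for matching
published tables: the focus group is coded 1, so coefficients are log odds
for the focus group relative to the reference group; the multinomial fit is
by maximum likelihood (`nnet::multinom`) whose saturated-model estimates
equal the closed-form log odds ratios up to optimizer accuracy; the ordinal
model is the cumulative logit
$\mathrm{logit}\,P(Y \le k \mid x) = \zeta_k - \beta x$ (`MASS::polr`,
tight tolerance), the parameterization under which the reported thresholds
match the empirical reference-group logits; Fisher's test switches to a
fixed-margin Monte-Carlo p-value for K > 2, where exact network algorithms
are out of scope. Categories with a zero cell are flagged non-estimable
(the true log odds diverge) rather than silently capped. The packaged
endometrial-cancer cross-tabulations (`ec_cohort_tables()`) carry a flagged
inconsistency: the surgery table's focus-group row duplicates the
chemotherapy row in the source and should not be used for coefficient
reproduction.

## Known limitations

* One focus variable at a time (the binary-contrast case); the general
  multi-focus form is documented but not fitted.
* No surrogate splits: records with missing values are rejected at load.
* No pruning or cp cross-validation; `cp` is user-set.
* Node-level coefficient p-values are deliberately not reported: after
  tree search they would be optimistic, and a principled correction
  (bootstrap or selective inference) is future work.
* SPADE output is a tract-keyed table; rendering against real tract
  geometry is out of scope.
* The composite SPADE is a simple sum across determinants, an upper-bound
  style aggregate, not a joint model.

## A worked session

```{r example, eval = FALSE}
ds  <- simulate_prism_data(seed = 1)      # reference synthetic cohort
fit <- prism(ds, contextual = "w")        # HPRISM tree
fit
coef(fit)                                  # terminal-node models
ev  <- prism_holdout(ds, contextual = "w", repeats = 20, seed = 1)
lv  <- lvimp(fit, n_perm = 10, seed = 1)  # local importance + Andrews curves
plot(andrews_curves(lv))
sp  <- spade(fit)                          # tract-level disparity
head(sp$estimates)
```
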