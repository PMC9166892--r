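---
title: "The Faking Mixture model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Faking Mixture model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fakemix)
```

## The problem

Multidimensional forced-choice (MFC) questionnaires group items measuring
different traits into blocks of size $B$ and ask respondents to rank the
items within each block, so a response is one of $R = B!$ rank orders.
The format is used in selection settings because ranking makes it harder to
inflate all desirable traits at once — but blocks differ in how *fakable*
they are: when one rank order is clearly more desirable than the rest,
motivated respondents can and do pick it. Test constructors therefore need a
block-level estimate of fakability, together with the desirability profile
over rank orders, to decide which blocks to keep, modify or discard.

`fakemix` implements a mixture item response model for exactly this
question, plus the machinery around it: the Thurstonian honest-response
engine, a synthetic data generator, Bayesian estimation with diagnostics, a
multigroup variant for comparing questionnaire versions, and a
parameter-recovery harness.

## Model

Under high stakes, the response of person $j$ on block $k$ is modelled as a
two-component mixture. With probability
$\Phi(\theta_j + \alpha_k)$ the person *fakes* the block and selects rank
order $r$ with probability
$$P(X_k = r \mid F = 1) = \frac{\exp(\beta_{kr})}{\sum_u \exp(\beta_{ku})},$$
a softmax over block-level *rank-order parameters* $\beta_{kr}$
($\beta_{k1} \equiv 0$ for identification; the parameters are interpretable
only relative to each other, the probabilities absolutely). Otherwise the
person responds *honestly*, with probabilities fixed from a low-stakes
administration (the two-step procedure below).

Two points are worth emphasising:

* **Fakability is derived, not free.** The block fakability is
  $\alpha_k = \Phi^{-1}\big(\sum_r (P_{kr} - 1/R)^2\big)$: the
  standard-normal quantile of the spread of the faking rank-order
  probabilities around their mean $1/R$. A block where one rank order is
  clearly preferable has concentrated probabilities, a large sum of
  squares, and hence high fakability; a perfectly matched block has a
  uniform profile and fakability $-\infty$ (see *Numerical choices*).
  `block_fakability()` implements this. The sum of squared deviations is
  bounded by $(R-1)/R$, so $\alpha_k \le \Phi^{-1}(5/6) \approx 0.967$ for
  triplets.
* **The faking trait $\theta_j$** captures person-level propensity to fake
  through the probit term $\Phi(\theta_j + \alpha_k)$. It is assumed
  independent of the content traits and shared across blocks.

### Honest responding

The honest component is a Thurstonian item response model: item $i$ has a
latent utility $t_{ji} = \mu_i + \lambda_i \eta_{j} + \varepsilon_{ji}$
with $\varepsilon_{ji} \sim N(0, \psi_i^2)$ independent across items, and a
person ranks the items of a block by decreasing utility. The probability of
a given rank order is the probability that all successive differences of
the sorted utilities are positive — a $(B-1)$-dimensional positive-orthant
probability of a multivariate normal with mean $A\,m_{(r)}$ and covariance
$A\,\mathrm{diag}(\psi^2_{(r)})\,A^\top$, where $A$ is the banded
comparison matrix (`comparison_matrix()`). We write the covariance as the
full quadratic form; it is the only reading of the sorted error-variance
operator that yields a valid covariance matrix. Throughout, $\psi_i^2$ is
treated as the error *variance* (consistent with the standardized-utility
convention $\psi_i^2 = 1 - \lambda_i^2$).

Orthant integrals are evaluated with `mvtnorm`: exact univariate normal
for $B = 2$, the deterministic TVPACK routine for $B \in \{3, 4\}$ and the
deterministic Miwa algorithm for larger blocks, with an absolute accuracy
target of $10^{-6}$; if a deterministic routine fails, a quasi-Monte-Carlo
(Genz–Bretz) estimate is used and its error bound attached with a warning.
Per person-block, the $R$ probabilities are then rescaled to sum exactly to
one — numerical integration (or, in practice, external estimation error in
the item parameters) can leave the sum slightly off, and the mixture
requires a proper probability vector. Deviations beyond a threshold
(default $10^{-3}$) are reported with the offending cells.

### Two-step estimation

Estimating the Thurstonian item parameters from rank-order probabilities
directly is not tractable at realistic scale, so the package follows the
two-step design: honest-response probabilities are computed *once* from
low-stakes data (or from known parameters, as in simulations) and enter the
mixture likelihood as fixed constants. `faking_mixture()` therefore takes
the response matrix and the honest probability array as separate inputs.
The package deliberately does not estimate item parameters from honest MFC
data (a structural-equation task for dedicated software), and does not
attempt to correct content-trait estimates for faking.

## Priors and sampling

The hierarchical priors are
$\beta \sim N(0, SD(\beta))$, $\theta \sim N(M(\theta), SD(\theta))$,
$M(\theta) \sim N(1, 2)$, $Var(\theta) \sim \mathrm{InvGamma}(1.5, 1)$ and
$Var(\beta) \sim N(5, 10)$ truncated to $(0, 15)$. The second argument of
every normal is a standard deviation; the truncated normal is read as mean
5, SD 10 on the interval $(0, 15)$. All of this is configurable in
`fm_priors()`; supplying `fix_var_theta` / `fix_var_beta` replaces the
corresponding hyperprior with a fixed value. For empirical data the
recommended configuration is `fix_var_theta = 0.25` (a typical variance for
a response-bias trait), `fix_var_beta = 4` (admits both low and high
fakability) with the `"empirical"` sampler preset (6 chains of 5000, 2500
warmup); the `"simulation"` preset is 3 chains of 3500 with 750 warmup.

Sampling is an adaptive Metropolis-within-Gibbs scheme written in C++:

* the discrete faking indicator is marginalized analytically — the
  likelihood is the mixture probability itself — so no discrete parameters
  are sampled;
* each free $\beta_{kr}$ and each $\theta_j$ gets a Gaussian random-walk
  proposal whose scale adapts during warmup toward a 0.44 acceptance rate
  (batches of 50, diminishing adaptation);
* in addition, each block's free-beta vector gets a *joint*
  adaptive-Metropolis proposal (running empirical covariance, $2.38^2/d$
  scaling, global scale adapted toward 0.23 acceptance): the softmax ties a
  block's parameters together, and the joint move is what lets the chain
  traverse that correlated ridge — with single-site moves alone the
  rank-order parameters mix an order of magnitude more slowly;
* $M(\theta)$ and $Var(\theta)$ are drawn exactly from their conjugate
  conditionals (normal and inverse-gamma given $\theta$);
* $Var(\beta)$ uses a random-walk step on the log scale with Jacobian
  correction, with the truncated-normal prior evaluated on the natural
  scale.

Proposal updates exploit the model's structure: a $\beta_{kr}$ update
touches only block $k$'s likelihood column (softmax, derived $\alpha_k$ and
the probit terms are recomputed for that block alone), a $\theta_j$ update
only person $j$'s row. The sampler's joint log target is validated in the
test suite against an independent R implementation of likelihood plus
priors to $10^{-8}$.

Chains are initialized near the prior: free $\beta$ jittered around 0,
$M(\theta)$ jittered around its hyperprior mean, $\theta$ around the
initial $M(\theta)$, variances at their prior medians; each chain derives
its jitter from `seed + chain - 1`, so runs are exactly reproducible.

Derived quantities — $\alpha_k$ and the faking rank-order probabilities —
are recomputed *per posterior draw* from the $\beta$ draws, never from
summarized parameters; posterior medians and 95% central intervals are
reported. `fm_convergence()` computes split-chain $\hat{R}$ and effective
sample sizes (implemented directly from the standard split-chain formulas)
and flags parameters with $\hat{R} \ge 1.01$ or an ESS ratio $\le .001$.

### Multigroup fits

`faking_mixture_multigroup()` fits two groups jointly, sharing $\beta$ on
blocks that contain identical items in both questionnaire versions and
estimating separate $\beta$ blocks elsewhere; each group keeps its own
faking traits under a common $M(\theta)$/$Var(\theta)$ hierarchy. For every
non-shared block the fakability difference is computed per draw, giving a
95% posterior interval for the difference *inside* the model rather than by
comparing point estimates afterwards. The two groups are fitted in one
joint sampler run.

## The synthetic data generator

`simulate_fc_study()` emulates a two-administration faking study and is the
package's reference data-generating process:

* **Content traits**: multivariate normal, mean 0, unit variances,
  correlations set to meta-analytic Big Five values
  (`big_five_correlations()`).
* **Items**: intercepts $\mu \sim U(-1, 1)$, loading magnitudes
  $|\lambda| \sim U(.65, .95)$, error variances $\psi^2 = 1 - \lambda^2$
  (standardized utilities). Within each triplet one item is negatively
  keyed, so 2 of 3 pairwise comparisons are between differently keyed items
  — the closest realizable fraction to one half for $B = 3$. A block is
  redrawn when its loadings are (near-)linearly dependent; the
  operationalization — any duplicated within-block loading ratio, or
  loadings equal in magnitude, at tolerance $10^{-3}$ — is a documented
  heuristic, as the precise dependency rule is under-determined.
* **Honest responses**: independent normal errors added to mean utilities,
  items ranked by decreasing realized utility. Exact ties have probability
  zero under the continuous model; were they to occur at degenerate
  parameter values they would be broken by stable item order.
* **Faking overlay**: per condition of the crossed design — fakability
  low/high ($\beta_{kr} \sim U(-2,2)$ / $U(-4,4)$), faking trait mean
  $\in \{0, 1, 2\}$ and variance $\in \{0.2, 0.5, 1\}$, 18 conditions
  (`condition_grid()`) — faking indicators are Bernoulli with probability
  $\Phi(\theta_j + \alpha_k)$ and faked cells are redrawn from the block's
  softmax distribution. All $R$ entries of $\beta$ are drawn from the
  uniform: the identification constraint is an estimation device, and by
  shift invariance of the softmax the generated probabilities are
  unaffected.

The default scale is the study design: 500 persons, 20 triplet blocks, 5
traits. Under these defaults the design's own calibration reproduces: the
per-block maximum softmax probability averages about .44 (low fakability)
and .62 (high), and the condition-mean faking probability spans roughly .16
to .90 between the grid's extreme cells.

What the generator does *not* emulate: correlation between faking and
content traits (drawn independently by design), cross-block error
correlations, person-specific desirability perceptions, and item-parameter
estimation error in the honest probabilities (they are computed from the
true parameters). Passing recovery tests on these data therefore shows
correct self-consistent estimation, not robustness to honest-model
misspecification.

## The recovery harness

`run_recovery_study()` crosses conditions with replications; each
replication simulates, fits and scores. Metrics per parameter family
(faking traits, free rank-order parameters, the three hyperparameters, and
the derived fakabilities and rank-order probabilities): coverage of the 95%
intervals, correlation of true values with posterior medians, mean bias,
and the SD of bias computed across a family's parameters within a
replication (the replication is the unit of analysis; condition summaries
average over replications). True $\beta$ values are mapped to the
identified scale $\beta_{kr} - \beta_{k1}$ before comparison, and the
"true" $Var(\beta)$ is the empirical variance of those identified values —
the generator draws raw uniforms, while the estimated $Var(\beta)$ is the
prior scale of the free parameters.

`variance_explained()` decomposes a metric's variance over the three design
factors with all interactions (descriptive sums of squares; no F-tests,
which would be distorted by the heterogeneous cell variances that occur in
some conditions). Components sum to 100%.

Failed replications (e.g. sampler errors) are excluded and logged with
their seeds; reports regenerate bit-identically from the stored
configuration.

## Numerical choices

* **Fakability floor**: the sum-of-squares argument of $\Phi^{-1}$ is
  clamped below at $10^{-10}$ ($\alpha \approx -6.36$). The exactly uniform
  profile has measure zero in the posterior but occurs at initialization
  ($\beta = 0$); the clamp keeps the log target finite there.
* **Softmax** is computed with max-subtraction; probit and quantile
  functions use R's standard high-accuracy implementations.
* **Orthant accuracy**: deterministic algorithms at $10^{-6}$ absolute;
  QMC fallback with logged error bound.
* **Honest-probability rescaling**: division by the per-cell sum, with a
  warning beyond $10^{-3}$ pre-rescaling deviation.
* **Problem sizes in the test suite**: property suites run at tiny scale;
  the end-to-end checks use one replication at the full study scale
  (500 persons, 20 blocks, single chain with 1500 iterations) and a
  multi-condition run at 300 persons, 10 blocks, 8 replications. These are
  the package's chosen desk-scale settings; the full 1000-replication,
  18-condition study is hours-to-days of compute and is available through
  `run_recovery_study()` at its full defaults.

## Known limitations

* One faking trait, uncorrelated with content traits; differential
  desirability across content domains is captured only through the
  rank-order probabilities.
* Honest probabilities are treated as known constants; their estimation
  error (when they come from an external SEM fit) is not propagated.
* Rank-order desirability is fixed across persons — a person-specific
  desirability model would not be identified from these data.
* The random-walk sampler is robust but less efficient per iteration than
  gradient-based samplers; the structured updates and cheap likelihood make
  up for this at the questionnaire sizes the model targets (hundreds of
  persons, tens of blocks).
* When the $Var(\beta)$ posterior piles up at its truncation bound (high
  fakability with few blocks), the variance hyperparameters can stay
  marginally above the strict $\hat{R} < 1.01$ criterion even at long run
  lengths. This is a property of the weakly identified hierarchy, not of
  the sampler alone; the remedy — as in empirical applications of the
  model — is to fix $Var(\theta)$ and $Var(\beta)$ via `fm_priors()`.
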