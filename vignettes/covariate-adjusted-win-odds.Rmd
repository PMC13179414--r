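---
title: "Covariate adjustment for the win odds: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate adjustment for the win odds: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winodds)
```

## The estimand

Cardiovascular outcomes trials increasingly analyze hierarchical composite
endpoints — death first, then a nonfatal event such as heart-failure
hospitalization or myocardial infarction — with generalized pairwise
comparisons: every treated subject is compared with every control subject
under a pre-specified win/loss/tie rule. The estimand implemented here is
the *marginal probabilistic index* (MPI)

$$\nu \;=\; P(Y_i \prec Y_j \mid A_i = 0,\, A_j = 1)
      \;+\; \tfrac12\, P(Y_i \asymp Y_j \mid A_i = 0,\, A_j = 1),$$

the probability that a randomly drawn treated subject beats a randomly
drawn control subject, plus half the tie probability. Its odds
$\theta = \nu/(1-\nu)$ is the *win odds*, the treatment-effect measure that
counts each tie as half a win for each side; $\theta$ also equals
$(1+\Delta)/(1-\Delta)$ where $\Delta = P(\text{win}) - P(\text{loss})$ is
the net benefit. The package estimates $\nu$, transforms the inference
monotonically to $\theta$ (and, via the delta method, to $\log\theta$), and
adds covariate adjustment.

## The comparison rule

The built-in rule has two layers. Writing each observed outcome as
$(\tilde T_1, \tilde T_2, \delta_1, \delta_2)$ — time to death or
censoring, time to first nonfatal event (equal to $\tilde T_1$ when none
was seen), and the two event indicators —

1. **Deaths.** Subject $j$ wins iff $\delta_{1i} = 1$ and
   $\tilde T_{1i} < \tilde T_{1j}$: a death counts only against a subject
   known to be at risk strictly beyond it.
2. **Nonfatal events**, entered when layer 1 is undecided. With shared
   follow-up window $\tau = \min(\tilde T_{1i}, \tilde T_{1j})$ (death and
   censoring both truncate the window), $j$ wins iff $i$ had a nonfatal
   event strictly before $\tau$ and $j$ did not have one at the same time
   or earlier.
3. Otherwise the pair is tied.

Three conventions deserve mention because the prose form of the rule does
not pin them down. (i) Equal observed death times are not decidable in
layer 1 and fall through to layer 2; "later (or never) wins" offers no
verdict when neither death is later. (ii) Strict inequalities define wins
throughout, mirroring the strict-inequality event indicators of the
censoring construction; with continuous times the distinction is
measure-zero. (iii) Nonfatal events at identical times tie. Any other rule
can be supplied through `comparison_rule()`; the only contract is
antisymmetry, which `score_matrix()` verifies for user rules.

`score_matrix()` materializes the $n \times n$ matrix
$S_{ij} = I(Y_i \prec Y_j) + \tfrac12 I(Y_i \asymp Y_j)$, evaluating each
unordered pair once in compiled code so antisymmetry
($S_{ij} + S_{ji} = 1$) holds by construction. Dense storage is the
default up to 5000 subjects (200 MB at the limit); beyond that the
adjusted-analysis functions switch to a streaming engine that recomputes
scores on the fly in row blocks and never stores the matrix (at the price
of re-scoring per Fisher-scoring iteration). The threshold is the
`dense_limit` argument.

## Direct estimation and inference

The direct estimator is the tallying one,
$\hat\nu_{\text{direct}} = (\#\text{wins} + 0.5\,\#\text{ties})/(N_0 N_1)$.
Its variance uses the classical two-sample U-statistic projection: with
kernel $K = \pm 1/0$ and $\hat\zeta_{10}, \hat\zeta_{01}$ the sample
variances of the per-control and per-treated kernel means,
$\widehat{\mathrm{Var}}(\hat\Delta) = \hat\zeta_{10}/N_0 +
\hat\zeta_{01}/N_1$ and $\hat\sigma_\nu = \tfrac12
\widehat{\mathrm{Var}}(\hat\Delta)^{1/2}$ since $\nu = (1+\Delta)/2$. The
test suite validates this against a within-arm subject bootstrap.

Inference is primarily on the $\nu$ scale: Wald statistic
$(\hat\nu - \tfrac12)/\hat\sigma_\nu$, CI $\hat\nu \pm z_{1-\alpha/2}
\hat\sigma_\nu$ mapped through $\nu \mapsto \nu/(1-\nu)$ to $\theta$.
Results on the $\log\theta$ scale
($\hat\sigma_{\log\theta} = \hat\sigma_\nu / (\hat\nu(1-\hat\nu))$) are
also reported; the two Wald statistics differ in finite samples and both
are exposed, labeled, since it is genuinely ambiguous which scale a given
report uses. Defaults are $\alpha = 0.05$ two-sided, i.e. 0.025 for the
one-sided test of $H_0 : \theta \le 1$.

Degenerate inputs: $\hat\nu \in \{0, 1\}$ raises a boundary flag and
suppresses intervals; zero estimated variance away from $\hat\nu =
\tfrac12$ is an error (the data cannot support a Wald test); an all-tie
dataset reports $p = 1$.

## Covariate adjustment

Adjustment goes through the *conditional* probabilistic index, modeled by
a probabilistic index model (PIM) with logit link on pairwise differences:

$$P(Y_i \preceq Y_j \mid A_i, A_j, X_i, X_j)
  = \mathrm{expit}\!\big(\tau_A (A_j - A_i) + \tau_X^T (X_j - X_i)\big),$$

fitted by the logistic-type estimating equations over all $n(n-1)$ ordered
pairs with fractional responses $S_{ij} \in \{0, \tfrac12, 1\}$ — ties
enter as $\tfrac12$ directly, with no tie-breaking, and there is no
intercept. Two marginalizations of the fit coincide:

- **Standardization**: average
  $\mathrm{expit}(\hat\tau_A + \hat\tau_X^T (X_j - X_i))$ — the treated-
  vs-control contrast plugged into every covariate pair — over all
  $n(n-1)$ ordered pairs.
- **Augmentation**: add to $\hat\nu_{\text{direct}}$ the mean-zero term
  $\sum_{i \ne j} [\tfrac{1}{n(n-1)} - \tfrac{(1-A_i)A_j}{N_0 N_1}]
  \hat H_{ij}$ with $\hat H$ the fitted conditional index, the
  variance-optimal member of the augmented estimator class.

Their equality is specific to the logit link with these estimating
equations (the treatment-coefficient equation forces the fitted
control-treated mean of $\hat H$ to equal $\hat\nu_{\text{direct}}$);
`adjusted_inference()` computes both and asserts agreement, which also
serves as a powerful internal consistency check on the fit. Because the
augmentation term is mean-zero for *any* fixed $H$, a misspecified PIM
costs efficiency but not validity.

The probit and identity links are deliberately out of scope: the
standardization–augmentation identity fails for them, and the logit link
is the one in practical use for this estimator. Interactions or covariate
transformations are supported by passing derived columns; there is no
formula interface, keeping the pairwise design explicit.

### Fitting

Fisher scoring starts at $\beta = 0$ and accumulates score and information
across pairs in compiled code without materializing the $n(n-1) \times
(1+p)$ design (memory $O(p^2)$ beyond the score matrix). Convergence
requires max absolute score component $\le 10^{-8}$ (or step norm $\le
10^{-10}$), capped at 100 iterations; with the canonical link the
iteration is Newton's method and typically converges in 5–8 steps. A
coefficient exceeding 30 on the logit scale triggers a separation error —
beyond that point $\mathrm{expit}$ is saturated to within $10^{-13}$ and
continued iteration only manufactures spurious "convergence" of a
divergent fit. Constant or collinear covariate columns are a rank error
with a pointed message, never silently dropped: a constant covariate
carries no pairwise information and would otherwise vanish without the
user noticing.

### Variance

The sandwich variance is the projection (Hájek) form of the order-2
U-statistic representation: with $\hat p_a = N_a/n$ and kernel
$h_{ij} = (1-A_i)A_j (S_{ij} - \hat H_{ij})/(\hat p_0 \hat p_1) +
\hat H_{ij}$, per-subject projections $\hat g_k = \frac{1}{2(n-1)}
\sum_{j \ne k} (h_{kj} + h_{jk})$ give $\hat\sigma^2_\nu = (4/n)
\widehat{\mathrm{Var}}(\hat g)$. First-order ignorability of the estimated
PIM coefficients (again the mean-zero augmentation argument) justifies
treating $\hat H$ as fixed. Exact finite-sample choices — the $n-1$
variance denominator, no degrees-of-freedom correction for the $1+p$
estimated coefficients — are conventions; alternative corrections differ
at $O(1/n)$ and small finite-sample discrepancies against other published
variants are expected. The package therefore also exposes a within-arm
subject-resampling bootstrap (`variance = "bootstrap"`), and the
acceptance suite checks the two agree within 15% at $n = 500$ with ten
covariates.

## The simulation framework

`simulate_trial()` emulates a two-arm cardiovascular outcomes trial via a
latent failure-time model:
$X_1, \dots, X_{10} \sim N(0,1)$, $A \sim \text{Bern}(0.5)$,
$T^0_1, T^0_2 \sim \text{Exp}(1)$ i.i.d., and

$$T_k = 7500 \cdot \exp(0.3\,A + \gamma^T X)\cdot T^0_k, \qquad k = 1, 2,$$

i.e. death ($T_1$) and first nonfatal event ($T_2$) times are
conditionally exponential under a proportional-hazards structure shared
by both components. The defaults — scale 7500, effect 0.3, 35% event
fraction, 1:1 allocation — are the reference operating-characteristics
design, calibrated so cumulative incidence resembles real CV outcome
trials. Censoring is administrative and *within-dataset*: $T_{\text{cens}}
= \hat F_n^{-1}(0.35)$, the type-1 empirical quantile (order statistic at
$\lceil qn \rceil$) of $\min(T_1, T_2)$, with events observed iff strictly
before $T_{\text{cens}}$ and the nonfatal event only if also strictly
before death. One consequence of the strict inequality is that the subject
attaining the order statistic is censored, so the realized event fraction
is $(\lceil qn \rceil - 1)/n$ — 34.95% at $n = 2000$, one subject below
the 35% target, which is the resolution the empirical rule can deliver.

The three covariate-influence scenarios share $\sum_j \gamma_j^2 = 1$, so
$\gamma^T X \sim N(0,1)$ and the marginal outcome law is scenario-free:
**A** equal influence $\gamma_j = 1/\sqrt{10}$ (the normalization
constraint forces $1/\sqrt{10}$, not $1/10$); **B** linearly decreasing;
**C** influence $\propto 1/j^2$ on $X_1..X_5$ only. Null data are made by
*flipping treatment*: re-drawing $A$ as independent Bernoulli after
outcome generation, which severs the treatment–outcome association while
preserving outcome marginals. An independent redraw (rather than a label
permutation) is the default reading of "randomly flip"; a permutation
mode is provided behind `method = "permute"`.

`run_operating_characteristics()` estimates one-sided rejection rates of
$H_0: \theta \le 1$ at $\alpha = 0.025$ over a grid of scenarios, sample
sizes and adjustment sets. Per-replication seeds are pre-drawn from the
master seed by a fixed counter scheme, so results are reproducible and
independent of execution order; replication-level fit failures are counted
and reported, never silently dropped. The default replication count is
1000 — the reference study used 10 000 (power) and 50 000 (null), and the
argument scales up to that; the package's own validation suite runs at
1000 replications, sized so that the full statistical test battery
completes in minutes while leaving the binomial Monte-Carlo bands narrow
enough to detect miscalibration.

What the generator does *not* emulate: dependent (informative) censoring,
staggered accrual, covariate-dependent censoring, non-proportional
hazards, discrete or categorical covariates, and recurrent nonfatal
events. Passing the simulation-based tests therefore certifies the
estimators under a clean semi-competing-risks design, not robustness to
those real-data features.

## What the validation suite establishes

- The standardization–augmentation identity to $10^{-8}$ across a
  randomized battery ($n \in \{50, 200\}$, $p \in \{0, 1, 5\}$).
- Exact agreement of all pairwise operations with naive double-loop
  oracles at $n \le 50$, and of the Fisher-scoring solver with `glm()` on
  the expanded pseudo-observations.
- Collapse of the empty adjustment set onto the direct estimator,
  including $\hat\tau_A = \mathrm{logit}(\hat\nu_{\text{direct}})$.
- Sandwich-vs-bootstrap agreement (15%, $n = 500$, 20 replications).
- Null calibration of the adjusted test at $n = 1000$ adjusting $X_1$
  (binomial 95% band around 0.025, 1000 replications), with the expected
  inflation direction at $n = 100$ adjusting all ten covariates.
- The power ordering adjusted-10 > adjusted-1 > unadjusted in scenario A
  at $n = 500$ (paired Monte-Carlo standard errors, since all methods see
  the same datasets), and its collapse in scenario C where only $X_1$
  carries signal. The single-covariate gain in scenario A is small — one
  of ten equally weighted covariates — and sits at the resolution limit
  of a 1000-replication study, so that particular gap assertion is the
  one check in the battery expected to be fragile at this scale.

Monte-Carlo assertions use fixed seeds and are exact reruns of the stated
experiments; power gaps are compared against *paired* replication standard
errors, the correct noise scale for same-dataset method contrasts.

## Known limitations

- The win odds, like the win ratio, depends on the censoring distribution
  through the comparability windows; nothing here corrects for that.
- Stratified estimation, group-sequential monitoring, and regression-type
  win-fraction models are out of scope.
- The normal approximation degrades for small $n$ with many covariates —
  the type I error inflation the operating-characteristics runner
  quantifies; permutation inference would be the remedy and is not
  implemented.
- The streaming engine covers the built-in rule only; user rules require
  the dense path.
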