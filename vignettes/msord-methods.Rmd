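---
title: "Open-population capture-recapture with msord: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-population capture-recapture with msord: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msord)
```

`msord` implements the inference stack of a photo-identification
mark-recapture study sampled under Pollock's robust design: a multi-state
open robust design (MSORD) likelihood for seasonal abundance, apparent
survival and temporary emigration; a Jolly-Seber POPAN likelihood for the
super-population of marked animals; mark-rate estimation; and the scaling
chain that turns marked abundance into total abundance with delta-method
uncertainty. This vignette explains the models, the numerical choices, and
what the bundled simulators do and do not emulate.

## Sampling structure

Surveys are organised as $T$ *primary periods* (seasons), each containing
$J_t$ *secondary occasions* (complete single-day surveys). The population is
open between primaries (births, deaths, temporary emigration) and — unlike
the classical robust design — also open *within* primaries: animals may
enter the study area once and leave once during a season. Capture histories
are binary detection records per individual over all $\sum_t J_t$ occasions,
built from graded dorsal-fin photographs: only excellent/good-quality images
of highly distinctive (D1/D2) fins enter the histories, because those marks
are the "tags" whose permanence and identifiability the method assumes.

## The MSORD likelihood

Between primaries an animal occupies a latent state: present in the study
area ($P$, observable), temporary emigrant ($E$, unobservable), or dead.
Parameters:

* $S$ — apparent survival per inter-primary interval (true survival times
  site fidelity); shared between states $P$ and $E$.
* $\psi^{P\to E}, \psi^{E\to E}$ — Markov transition probabilities to the
  emigrant state, applied after survival. Transitions out of a state sum to
  one, so the return probabilities are complements:
  $\psi^{P\to P} = 1-\psi^{P\to E}$, $\psi^{E\to P} = 1-\psi^{E\to E}$.
  *Random* emigration ties $\psi^{P\to E}=\psi^{E\to E}$; *no* emigration
  fixes both at zero; *Markovian* leaves both free.
* Within a primary, an animal in state $P$ draws one availability window
  $[a, d]$: it enters at occasion $a$ with probability $\mathrm{pent}_a$
  ($\sum_a \mathrm{pent}_a = 1$), persists from occasion $j$ to $j+1$ with
  probability $\varphi_j$, and after leaving does not return that season.
  While available it is detected independently with per-occasion probability
  $p$ (capture and recapture probabilities equal — photo-identification is
  non-invasive, so no trap response is modelled).

The within-primary probability of a detection vector $\omega$ sums over all
windows compatible with the observed detections,

$$\Pr(\omega \mid P) \;=\; \sum_{a \le \min(\omega)}\;\sum_{d \ge \max(\omega)}
  \mathrm{pent}_a \Big(\prod_{j=a}^{d-1}\varphi_j\Big)(1-\varphi_d)^{[d<J]}
  \prod_{j=a}^{d} p_j^{\omega_j}(1-p_j)^{1-\omega_j},$$

and these probabilities form a distribution over all $2^J$ vectors (the test
suite checks this exhaustively for $J \le 4$). The probability of at least
one detection, $p^*$, is one minus the all-zero case.

The history likelihood is conditional on first encounter: the primary of
first detection contributes $\Pr(\omega)/p^*$ (the animal is known present
and detected there), and a forward recursion over $\{P, E, \text{dead}\}$
handles the remaining primaries — survival, then transition, then emission
($\Pr(\omega)$ in $P$; probability one for an all-zero season in $E$ or
dead). Conditioning on "at least one detection in the first primary" rather
than on the exact first occasion keeps all within-primary information from
the first season while remaining a proper conditional likelihood; its
agreement with a brute-force enumeration over every latent state sequence
and window combination is asserted to $10^{-10}$ in the tests, and
simulation-based recovery (below) is the arbiter of unbiasedness.

Derived quantities, all computed at the MLE with delta-method variances:

* marked abundance per primary, $\hat N_{m,t} = n_t / \hat p^*_t$ with $n_t$
  the distinct individuals detected in season $t$; its SE is reported both
  with and without the Horvitz-Thompson binomial component
  $n_t(1-p^*)/p^{*2}$ (which of the two a black-box implementation includes
  is not standardised, so both are available);
* transition complements with SEs equal to the source SEs;
* expected residence time $E(d-a+1)$ per primary under the fitted window
  distribution.

## POPAN super-population

For the total number of distinct animals using the area across the whole
study, detections are pooled within primaries (seen/not seen per season) and
the Schwarz–Arnason POPAN likelihood is maximised over entry proportions,
survival, detection, and the super-population size $N$ of marked animals.
The likelihood includes the binomial term for the $N - D$ animals never
detected; $N$ is parameterised as $D + e^{\eta}$ so the constraint
$N \ge D$ is structural. With $T = 2$, $S = 1$ and all entry mass on the
first occasion this maximum reduces to the Lincoln–Petersen estimator
$n_1 n_2 / m_2$, which the tests verify. Only the super-population estimate
is carried into downstream reporting; its survival and entry estimates are
less trustworthy than the MSORD's because the pooled model ignores
within-season movement.

## Mark rate and abundance scaling

Capture-recapture estimates cover only distinctively marked animals. Two
independent mark-rate estimators are pooled as ratios of totals:

* $\hat\theta_1$: among fully photographed groups larger than 20 animals,
  the proportion of high-quality images showing a distinct fin;
* $\hat\theta_2$: among fully photographed groups of at most 20 animals
  (where field counts of group size are reliable), distinct individuals over
  summed group sizes.

Each has binomial SE $\sqrt{\hat\theta(1-\hat\theta)/n}$ with $n$ the pooled
denominator; the combined rate is their unweighted mean (the two estimates
are methodologically independent and no weighting is prescribed). Scaling:

$$\hat N_{\text{total}} = \hat N_m / \hat\theta, \qquad
  SE = \sqrt{\hat N_{\text{total}}^2\Big(\tfrac{SE(\hat N_m)^2}{\hat N_m^2}
  + \tfrac{1-\hat\theta}{n\,\hat\theta}\Big)},$$

with log-normal 95% intervals $(\hat N/C,\; \hat N C)$,
$C = \exp(1.96\sqrt{\ln(1 + (SE/\hat N)^2)})$, geometrically symmetric about
the estimate. Two conventions in this chain were genuinely open and are
fixed as package design choices:

* **The $n$ in the binomial term** is the number of distinct individuals
  identified in the period being scaled (and the total identified count for
  the super-population row). This convention reproduces the published
  per-season SEs to one decimal in four of five checkable cells and the
  super-population SE exactly; the alternative (image counts from the
  mark-rate data) does not. It is an explicit argument, so callers can
  override it.
* **Rounding**: computation is on unrounded values throughout; the
  presentation layer rounds abundances to integers and SEs to one decimal,
  and recomputes the displayed CI from the rounded pair, because that is the
  convention printed tables follow and it makes them reproducible from their
  own entries.
* $z$ is fixed at 1.96, not the exact 97.5% quantile.

## Model structures, selection and diagnostics

Structures use the field's shorthand, e.g.
`S(.) p(.) pent(season.day) phi(season.day) psi(Markovian)`: `.` constant,
`season` one value per primary, `season.day`/`season.survey` one value per
secondary occasion. Entry vectors use a multinomial-logit link with the
first occasion as reference, so a primary with $J$ occasions has $J-1$ free
entry cells; under `season` variation those cells share one parameter per
primary. Transition parameters may additionally vary by interval
(`psi(Markovian.t)`), since per-interval emigration is often the quantity of
ecological interest — but with a single dataset of a few hundred animals the
interval-specific $\psi^{E\to E}$ frequently sit on the boundary, which is
precisely what the data-cloning screen below flags.

Ranking uses AICc with effective sample size equal to the number of capture
histories (MARK's internal convention is not public; ranking at this scale
is insensitive to the choice, which is nevertheless configurable). Models
within two criterion units of the best are averaged with renormalised Akaike
weights, the unconditional SE combining within-model variance and
between-model spread.

Goodness of fit follows the deviance route: a fully time-varying
Cormack-Jolly-Seber model per primary period gives
$\hat c = \text{deviance}/\text{df}$, and the global factor pools components
as $\sum\chi^2 / \sum df$ — a ratio of sums, not a mean of ratios. When
$\hat c > 1$ is applied, POPAN ranking switches to QAICc (one extra
parameter for $\hat c$) and SEs inflate by $\sqrt{\hat c}$; $\hat c$ is
capped below at 1 and values above 3 trigger a structural-inadequacy
warning. RELEASE-style contingency components test equal catchability
(TEST 2: capture at $i$ versus capture at $i+1$ among animals known alive
through the interval) and equal fate of new versus previously seen animals
(TEST 3); sub-tables with expected counts below 2 are dropped rather than
pooled further, since a 2x2 cannot be pooled without vanishing.

Identifiability is screened by data cloning: replicating the dataset $K$
times multiplies the likelihood information by $K$, so point estimates must
not move and the SE of every estimable parameter must shrink by
$1/\sqrt{K}$. Both the $1/\sqrt{K}$ line (the pass criterion, from Fisher
information arithmetic) and a $1/K$ reference are reported, because the
cloning literature's informal phrasing ("converge at a rate of $1/r$") is
ambiguous between the two; parameters off the scaling are flagged
non-estimable and `run_analysis()` drops such models from the ranking.

## Numerical choices

Probabilities are estimated on the logit scale, entry vectors on the
multinomial-logit scale, $N_{\text{super}}$ on a log scale offset by the
observed count. Optimisation is BFGS with finite-difference gradients,
relative objective tolerance $10^{-8}$, and jittered restarts (3 by default;
recovery harnesses use 1 for speed). SEs come from the finite-difference
Hessian inverted at the MLE and are propagated to the natural scale by
numerically differentiated delta method; a singular Hessian marks the whole
covariance as unavailable rather than silently reporting partial SEs.
Link-scale estimates beyond $\pm 8$ are flagged as boundary estimates.
Duplicate capture histories are collapsed to frequency weights before
optimisation (an exact transformation that also implements data cloning).
Every stochastic routine takes an explicit integer seed and is a pure
function of its inputs and that seed.

Degenerate inputs are handled explicitly: all-zero histories are rejected
(dropped with a warning at data construction); $p^* \approx 0$ marks the
abundance row as undefined; detection probabilities of exactly 0 or 1 route
the within-primary computation through a direct product rather than the
log-cumulative shortcut.

## What the simulators emulate — and what they do not

`simulate_msord()` mirrors the fitted process exactly: individuals seeded at
the first primary (initial state drawn from the transition chain's
stationary distribution by default, configurable), survival then transition
between primaries, one availability window per primary in state $P$,
independent detection within the window. `simulate_popan()` adds staggered
entry into the marked population, which the conditional MSORD likelihood
deliberately ignores. `simulate_sightings()` draws group sizes (negative
binomial around a mean of 30 by default, in the range of coastal dolphin
groups), with distinct counts and image tallies binomial in the true mark
rate.

The generators therefore share all the model's assumptions: homogeneous
detection and survival, permanent and correctly matched marks, single
within-season entry and exit, no group structure in detection. Passing
recovery tests demonstrates that the estimators are consistent and
well-calibrated *under those assumptions*; they say nothing about
heterogeneous real data — that is what the $\hat c$ and contingency
diagnostics are for on a real dataset.

Problem sizes used in the test suite were chosen to mirror the motivating
study while keeping a full run to minutes: 8 primaries x 6 secondaries,
200 simulated individuals per replicate, 100 replicates for the recovery
experiment (truth $S = 0.95$, $p = 0.30$, Markovian $\psi = (0.35, 0.60)$,
seasonal-decay entry), 25-fold cloning for the SE-scaling check.

## Worked sketch

```{r, eval = FALSE}
design <- study_design(6, n_primary = 8)
data <- read_inp("histories.inp", design)

fits <- lapply(msord_model_suite(), fit_msord, data = data)
rank <- rank_models(fits)
best <- attr(rank, "fits")[[1]]

theta <- combine_mark_rates(theta1(sightings), theta2(sightings))
ab <- derive_abundance(best)
abundance_table(data.frame(period = ab$period, n = ab$n,
                           N_m = ab$N_m, se_N_m = ab$se_N_m), theta)

popan <- fit_popan(pool_primaries(data), "p(season) S(.) pent(.)",
                   c_hat = attr(median_c_hat(data), "global_c_hat"))
total_abundance(popan$N_super, theta$theta)
```

## Known limitations

* Two geographic states only; no dead recoveries, no individual covariates,
  no multiple within-season entries.
* Exact numerical equivalence with MARK's MSORD implementation (its AICc
  values and parameter counts) is not guaranteed: MARK's internal effective
  sample size, design-matrix conventions and parameter-count corrections for
  boundary estimates are not public. Simulation-based calibration, not
  value-for-value agreement with another program, is this package's
  correctness standard.
* Calendar gaps between seasons are ignored: $S$ and $\psi$ are per
  seasonal interval, with no exponentiation by interval length.
* The $\hat c$ here is the deviance ratio, not a bootstrap or
  logistic-regression median-$\hat c$; with sparse m-arrays the deviance
  ratio is itself noisy.
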