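---
title: "Rapid guessing and plausible values: models, thresholds, and the simulation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid guessing and plausible values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgpv)
```

## The problem

Group comparisons in low-stakes assessments are usually made on
plausible values (PVs): random draws from each respondent's posterior
ability distribution under a latent-regression IRT model. A disengaged
respondent who rapid-guesses produces chance-level answers in a few
seconds; those responses violate the monotone item response function
the model assumes. The questions this package addresses are (a) how
much rapid guessing (RG) distorts PV-based estimates of a standardized
group difference, and (b) how well three correction strategies work:
conditioning on a person-level engagement summary, discarding flagged
responses at the response level, or both.

## The generating model

`simulateCondition()` draws, for each group $g$, person parameters
$(\phi_i, \theta_i, \tau_i)$ — engagement, ability, and speed — from a
multivariate normal with mean $(\mu_{\phi g}, \mu_{\theta g}, 0)$ and a
shared covariance $\Sigma$. For each person–item encounter a latent
class $e_{ij} \sim \mathrm{Bernoulli}(\mathrm{expit}(\phi_i))$ decides
between:

* solution behaviour ($e_{ij}=1$): $P(Y_{ij}=1) =
  \mathrm{expit}(\theta_i - \xi_j)$ and $\log t_{ij} \sim
  N(\beta_j - \tau_i,\ \sigma_E)$;
* rapid guessing ($e_{ij}=0$): $P(Y_{ij}=1) = z_j$ and $\log t_{ij}
  \sim N(\beta_D,\ \sigma_D)$, independent of $\theta_i$ and $\tau_i$.

The default item bank (`defaultItemBank()`) crosses difficulties
$\xi_j \in \{-1,-.5,0,.5,1\}$ logits with time intensities $\beta_j \in
\{2.9,\dots,3.7\}$ log-seconds (mean engaged response times of roughly
15–40 s), four items per parameter set, with $\sigma_E = 0.30$,
$z_j = 0.25$ (four-option multiple choice), $\beta_D = 1.25$
($\approx 3.5$ s) and $\sigma_D = 0.60$. The twelve canonical design
cells (`tableConditions()`) cross a 0.5 vs 1.0 SD ability gap, a 5% vs
15% overall RG rate, and a $-5/0/+5$ point between-group RG-rate
difference, with $N = 1000$ per group.

### The person covariance

The association structure of $(\phi, \theta, \tau)$ is the scientific
core of the generator: engaged respondents tend to be more able
($r_{\phi\theta} > 0$), so rapid guessing is concentrated among weaker
respondents and its damage partially cancels at the group level. The
entries we adopt are variances $1.70 / 1.00 / 0.05$ and associations
$\{.35, -.20, -.20\}$. Read as covariances those associations do not
form a valid (positive definite) matrix, and the implied
ability–speed correlation would be $-0.89$; read as correlations they
are automatically valid and moderate. `defaultSigma()` therefore uses
the correlation reading; `defaultSigma("covariance")` provides the
covariance reading, in which case the ability–speed entry is moved to
the nearest admissible value by a deterministic root find
(`repairSigma()`), and any user matrix can be supplied per condition.
The choice is consequential mainly for the speed margins: under the
correlation reading the empirical SE of pooled Cohen's $d$ in our runs
is 0.053–0.057, and condition-level antimode thresholds span roughly
5.6–11.7 s, both in line with reported values for this class of
designs.

### From RG rates to engagement means

A design cell specifies each group's response-level RG rate
$\mathrm{RGR}_g$. The group identity $1-\mathrm{RGR}_g =
E[\mathrm{expit}(\phi_i)]$ involves the whole $\phi$ distribution, not
just its mean: because expit is concave above one half, plugging the
rate into the mean alone (`rgrToMuPhi()`, the "location" conversion)
yields data whose realized RG rate is nearly double the nominal one
when $\mathrm{var}(\phi) = 1.70$ (5% nominal becomes 8.9% realized).
`makeCondition()` therefore defaults to the "response" conversion
(`muPhiForRate()`), which solves $E[\mathrm{expit}(\phi)] =
1-\mathrm{RGR}$ by numerical integration so that the simulated
responses exhibit the stated rate in expectation; the location
conversion remains available via `rgrConversion = "location"`. Setting
a rate to zero disables rapid guessing (the engagement mean is set to
the largest finite logit), which the parameter-recovery checks use.

What the generator deliberately does **not** emulate: item-position or
fatigue effects (RG probability is constant over items given
$\phi_i$), partial engagement (skimming), omitted responses, polytomous
items, and multidimensional ability. Tests passing under this
generator show that the estimators behave as intended when RG is a
two-class, response-time-separable process; they do not certify
performance on real data where engagement is graded and thresholds are
harder to place.

## Threshold methods

`fixedThresholds()` applies one common cutoff (default 5 s).
`visualThresholds()` automates the visual-inspection rule: the
response-time density (Gaussian kernel, Sheather–Jones plug-in
bandwidth, evaluated on a 0.01 s grid) is minimized over a 5–15 s
window, placing the threshold at the antimode between the RG and
solution-behaviour modes; ties break toward the smaller time, an empty
window falls back to its lower bound with a warning. In simulation,
items sharing a (difficulty, intensity) parameter set are pooled to one
threshold per condition, computed once from a calibration dataset and
reused across replications — mirroring a design in which one threshold
per item parameter set and condition is fixed for a whole study. For
observed data, thresholds are per item with optional pooling keys.

Flags follow a strict inequality ($t_{ij} < \rho_j$ is a rapid guess; a
time exactly at the threshold counts as engaged). Response time effort
is the person mean of available flags, dichotomized at 0.9 with 0.9
itself mapping to "disengaged". Missing times drop out of both the
numerator and denominator; a configurable minimum number of scorable
items (default 1) guards degenerate persons.

## The three-step PV procedure

1. **Rasch calibration** (`fitRaschMML()`): EM over a fixed quadrature
   grid; latent mean fixed at 0 for identification, latent variance
   estimated, difficulties free. Items lacking both a correct and an
   incorrect response are excluded with a warning.
2. **Latent regression** (`fitLatentRegression()`): difficulties fixed
   from step 1, normal prior $\theta_i \sim N(\psi_0 + \psi_X' X_i,
   \sigma^2)$ estimated by EM. The grouping indicator is always a
   covariate; person-level and combined models add dichotomized RTE.
   If RTE$^*$ happens to be constant in a replication the covariate is
   dropped for that replication with a note. Collinear covariates are
   rejected by name. For the response-level and combined models both
   steps run on the filtered matrix (flagged responses recoded missing
   via `applyEmmFilter()`), keeping each model self-contained; the
   baseline and person-level models use the raw matrix.
3. **PV drawing** (`drawPlausibleValues()`): for each person the
   discrete posterior over the grid is sampled, plus uniform jitter of
   half a node spacing to avoid lattice artifacts.

### Numerical choices

* *Quadrature*: 61 equally spaced nodes on $[-6, 6]$ logits, i.e. five
  prior SDs on either side for the unit-variance abilities simulated
  here, configurable via `nQuad`/`gridBounds`. The grid is chosen once
  and held fixed during EM, so each iteration maximizes the same
  discretized marginal likelihood and the log-likelihood trace is
  provably nondecreasing (asserted in the tests). Tiny-instance tests
  use finer grids ($301$ nodes on $[-8,8]$) when comparing against
  brute-force oracles.
* *Convergence*: relative log-likelihood change below $10^{-9}$ or
  maximum parameter change below $10^{-4}$, cap 500 iterations. The
  parameter-change rule is the operative one at scale; looser
  likelihood-based rules stop EM while difficulties are still drifting
  by several hundredths of a logit.
* *M-steps*: difficulties by per-item Newton iterations on the expected
  complete-data likelihood (concave in $\xi_j$); regression weights by
  weighted least squares on posterior means; both are exact maximizers,
  preserving EM monotonicity.
* *Standard errors*: optional (`computeSE = TRUE`), from the
  numerically differentiated observed information of the marginal
  likelihood.
* *Intervals for coverage*: Rubin's rules with normal quantiles on
  $\sqrt{T}$; with 10–25 PV sets and $N = 2000$ the Barnard–Rubin
  small-sample correction changes intervals negligibly, but it is
  available via `smallSample = TRUE`.

## Estimands, pooling, and the performance harness

Per PV set, Cohen's $d$ uses the pooled SD with $n_g - 1$ weights and
the large-sample variance $(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))$;
group means and SDs carry $s^2/n$ and $s^2/(2(n-1))$. Rubin's rules
pool the $M$ sets: point estimate = mean, total variance $T = W +
(1+1/M)B$. `performanceTable()` aggregates replications into bias,
empirical SE, MSE and coverage, each with its Monte Carlo standard
error; non-converged replications are excluded from the measures but
reported through the convergence rate. All seven models inside a
replication consume the identical generated dataset, and the PV seed is
shared across models, so models that differ only in inert options
coincide exactly.

Seeds follow a fixed hierarchy (study seed → condition → replication →
generation/PV streams), making any single replication reproducible in
isolation; the same dataset is obtained through
`simulateCondition(condition, seed)`.

## Problem sizes used by the tests

The bundled checks run the full design at reduced scale, chosen to keep
Monte Carlo error well below the effects of interest: threshold
diagnostics over 12 conditions × 500 replications (classification only),
and the performance study on the two most informative cells (conditions
1 and 12) at 200 replications × 10 PV sets, where the MCSE of the bias
of $d$ is $\approx 0.004$. The reference design (12 × 1000 × 25) is a
`studyConfig()` away but takes hours on one CPU; `runStudy()` writes
per-condition raw estimates and resumes from them.

## Known limitations

* The response-level and combined models inherit the effort-moderated
  assumption that flagged responses are ignorable once coded missing;
  when rapid guessing is informative beyond the included covariates the
  remaining bias is not corrected.
* Residual bias in our scaled runs: with a 5% RG rate the pooled-SD
  denominator of $d$ still shrinks by a few percent under the baseline
  model, inflating $d$ slightly even when the mean gap is nearly
  unbiased; correcting the SDs themselves would require modelling the
  contamination rather than filtering it.
* The antimode search assumes a visible bimodal structure inside the
  window; items answerable in a few seconds under full engagement defeat
  it (the fallback is the window's lower bound).
* One ability dimension, dichotomous items, two groups.
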