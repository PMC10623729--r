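---
title: "Modelling nonlinear longitudinal trajectories with trajmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nonlinear longitudinal trajectories with trajmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trajmix fits three nonlinear mixed-effects models for a Gaussian
longitudinal outcome $y_{ij}$ of subject $i$ at time $t_{ij}$,

$$y_{ij} = f(t_{ij}, \psi_i) + \epsilon_{ij}, \qquad
  \epsilon_{ij} \sim N(0, \sigma_\epsilon^2),$$

where $\psi_i$ is a vector of four interpretable person-specific
parameters built from fixed effects, optional covariates and Gaussian
random effects,
$\psi_{ki} = \alpha_k + X_{ki}^\top \beta_k \,(+\, \eta_{ki})$.
The motivating application is terminal cognitive decline on a
death-anchored timescale (time 0 at death, negative years before it),
but any outcome with a consistent timescale fits the framework.

## The three structural models

**Sigmoidal (four-parameter logistic).**
$f(t) = \psi_1 + (\psi_2-\psi_1)\,/\,(1 + (t/\psi_3)^{\psi_4})$ with
$\psi_1$ the *first level* (the plateau far from time 0), $\psi_2$ the
*last level* (the value at time 0, i.e. the intercept), $\psi_3$ the
*midpoint* (time at which half of the total change has occurred, in time
units) and $\psi_4$ the dimensionless, positive *Hill slope* governing
the steepness of the transition. Random effects are placed on the two
levels with a free correlation; the midpoint and Hill slope are kept
marginal, which helps convergence in practice. The ratio $t/\psi_3$ must
be non-negative, so the timescale must not mix signs; the fit refuses
mixed-sign data rather than silently taking absolute values, because
that would change the model without notice.

**Piecewise with abrupt change (broken stick).** Two linear phases
joined continuously at a subject-specific changepoint $\psi_4$:
slope $\psi_3$ before the changepoint and slope $\psi_2$ after it, with
$\psi_1$ the value at time 0. On a death-anchored timescale the segment
containing time 0 is the terminal one, so $\psi_2$ is the terminal
slope. In the user-facing vocabulary the early slope is `slope1`
($\psi_3$) and the late slope is `slope2` ($\psi_2$): names follow the
segments' temporal order, while the equations fix which symbol carries
which role. All four parameters carry random effects; their covariance
is diagonal except for a free covariance between the two slopes.

**Piecewise with smooth polynomial transition.** The kink is replaced by
a cubic $g$ on a window $[\psi_4, \psi_4+v]$ of fixed, user-chosen
length $v$ (default 2 time units; $v$ is a model constant, not an
estimated parameter — no estimation procedure for it is defined, and
treating it as data-driven would blur the changepoint's meaning). The
early line is $\lambda + \psi_3 t$ and the late line $\psi_1 + \psi_2
t$, with the derived intercept
$\lambda = \psi_1 + (\psi_2-\psi_3)(\psi_4 + v/2)$ forcing the two lines
to intersect at the middle of the window; $g$ matches the value and
slope of the adjoining line at each end of the window, so the curve is
$C^1$. Those four boundary conditions determine the cubic uniquely;
the package implements both the two-point Hermite closed form and the
explicit $4\times 4$ linear solve, which agree to machine precision and
cross-check each other in the test-suite. Setting $v = 0$ recovers the
abrupt model exactly — the specification constructor silently reduces
the family in that case so the two code paths are literally identical.
$\lambda$ is always derived, never free: freeing it would break both the
mid-window intersection property and the interpretability of $\psi_1$ as
the level at time 0.

## Estimation: two-phase SAEM

The marginal likelihood integrates the random effects out of a
nonlinear model, so EM's E-step is intractable. SAEM replaces it by
simulation: at iteration $k$,

1. **E-step (MCMC).** For each subject (and each of `n_chains`
   independent chains) the random effects are refreshed by
   Metropolis–Hastings: one independence proposal from the prior
   $N(0, B)$, then `mh_steps` sweeps of component-wise random-walk
   proposals whose scales adapt during the exploration phase towards an
   acceptance rate near 37%.
2. **SA-step.** The complete-data sufficient statistics (per-subject
   sampled parameters, their second moments, the residual sum of
   squares) are averaged with step size $\gamma_k$: $\gamma_k = 1$
   during the `K1` exploration iterations, $\gamma_k = 1/(k-K_1)$
   during the `K2` smoothing iterations, so that phase 2 averages the
   stochastic fluctuations away ($\sum\gamma_k = \infty$,
   $\sum\gamma_k^2 < \infty$).
3. **M-step.** Closed-form updates: generalised least squares of the
   smoothed person-specific parameters on the covariate designs for
   the fixed effects; empirical second moments, projected onto the
   family's free covariance structure, for $B$; the mean squared
   residual for $\sigma_\epsilon^2$. The sigmoidal midpoint and Hill
   slope carry no random effects and are instead updated by a nested,
   warm-started BFGS maximization of the complete-data likelihood, with
   the Hill slope log-parameterised (it must stay positive: the power
   $0^{\psi_4}$ is only stable for $\psi_4>0$) and soft quadratic
   penalties keeping the midpoint on the data's side of zero.

During phase 1 the variance components are *annealed*: each update is
floored at 0.95 times its previous value, so the residual variance and
$B$ cannot collapse before the random effects have explored their
conditional distributions. This matters most in near-degenerate
problems (tiny noise, tiny heterogeneity).

**Defaults and why.** `K1 = 300`, `K2 = 300`; the E-step does
`mh_steps = 2` random-walk sweeps over `ceiling(200/N)` chains (capped
at 10) for the sigmoidal family, and `mh_steps = 4` sweeps over
`ceiling(400/N)` chains for the piecewise families. The asymmetry is
deliberate: the sigmoidal model is *linear* in its two random effects,
so their conditional distribution is close to Gaussian and easy to
traverse, whereas the piecewise families carry a four-dimensional
random effect including a changepoint whose conditional distribution
mixes slowly; with a weaker E-step the sufficient statistics stay
autocorrelated across iterations and the smoothing phase leaves both
visible Monte-Carlo scatter in the estimates and downward bias in the
slope variance components. The long smoothing phase is
deliberate: the convergence diagnostic declares stabilization only when
every parameter's consecutive-iteration step stays below $10^{-3}$ of
its scale over the last 20 smoothing iterations, and the late-phase
step size of a variance component is of order
$\gamma_k \cdot B\sqrt{2/(N\,C)}$ — with a short smoothing phase that
quantity cannot fall below the tolerance at realistic sample sizes, and
the flag would be noise rather than a diagnostic. Scaling the chain
count inversely with $N$ equalises the Monte-Carlo noise of the
sufficient statistics across sample sizes. Coefficient steps are
measured relative to the magnitude of the structural parameter they
modify (floored at 0.01): a covariate effect whose true value is zero
can never satisfy a purely self-relative criterion.

**Uncertainty.** Standard errors come from the Fisher information of
the linearized model: expanding $f$ to first order around the
conditional means $\hat\eta_i$ gives a Gaussian marginal with mean
gradient $A_i$ and covariance $V_i = Z_i B Z_i^\top +
\sigma_\epsilon^2 I$; the fixed-effect block is $\sum_i A_i^\top
V_i^{-1} A_i$ and the variance block uses the standard Gaussian trace
formula. Wald tests use the normal reference with no small-sample
degrees-of-freedom correction. The marginal log-likelihood is reported
both by this linearization and by importance sampling (Gaussian
proposal at each subject's conditional mean and linearized conditional
covariance, 5000 draws by default, with a prior-proposal fallback for
degenerate subjects); AIC/BIC use the linearized value. Only the
linearization information estimator is implemented.

## Automatic starting values

Nonlinear mixed fits are sensitive to their starting point, so the
package derives informative initials from the data.

*Sigmoidal*: the pooled times are cut at their 5th and 95th
percentiles and the mean outcome in each tail window starts the first
and last level. The midpoint start is $\pm 300$ when the pooled trend
is nearly linear (an extremely distant midpoint makes the logistic
locally linear over the observation window) and $\pm 2$ otherwise,
signed to the timescale in use. Near-linearity is judged on time-bin
means: nearly linear when the quadratic term's $|t|$-statistic is below
2 *or* the quadratic's relative RSS improvement over the linear fit is
below 5% — the disjunction keeps genuinely linear data (whose expected
chance improvement from one extra parameter is of order one part in the
bin count) classified as linear. The Hill start is chosen between the
fixed candidates 0.5 and 1.05 by evaluating the population-mean
sigmoid's residual sum of squares at each with the other three starts
held fixed (the candidate pair is stated without a selection rule, so
the lower-RSS rule is this package's concrete choice).

*Piecewise*: the last-level start is the mean outcome beyond the 95th
time percentile. The pooled times are split into quintiles and a random
intercept-and-slope linear mixed model (REML, via lme4, with a pooled
least-squares fallback for singular sub-fits) is fitted per quintile;
the changepoint start is the lower bound of the quintile with the
largest absolute slope, ties resolved towards the earliest quintile.
Slope starts come from segment-wise linear mixed models before and
after that changepoint (early segment feeding `slope1`, late feeding
`slope2`).

*Variance components*: the residual variance starts at the variance of
the outcome residuals around the structural curve evaluated at the
starting values; each random-effect variance starts at 10% of that,
floored at $(0.3\,|\text{start}_k|)^2$. The floor exists because a
residual-variance-based start is only meaningful for parameters on the
outcome scale — a changepoint random effect lives in time units, and
starting its prior spread at a few hundredths of a year freezes the
sampler's exploration of it.

Users may override the four main starts element-wise (`NA` keeps the
automatic value); an all-zero override (the "naive" comparison arm of
the replication harness) is accepted, with the sigmoidal midpoint and
Hill slope clamped to small valid magnitudes since zero is outside
their domain.

## What the generators emulate — and what they do not

`generate_simulation_dataset()` mimics an annually-tested cohort
followed to death: per subject, a follow-up duration is drawn from a
Beta distribution scaled to the design's support and calibrated so the
realised first-to-last-visit span has mean ≈ 10 and SD ≈ 5 years
(window −24…0); visits are laid out backwards from a last visit within
a year of death with inter-visit gaps of one year plus uniform ±2-month
jitter; subjects with fewer than 4 observations are redrawn so the
requested count is exact. A uniform baseline-time draw with rejection
cannot match both follow-up moments simultaneously (a uniform on
$[3, b]$ with mean 10 forces SD ≈ 4.0), which is why the shape of the
follow-up distribution, not its range, is the calibrated quantity.
`generate_datacog()` uses the same machinery (window −20…0, follow-up
mean ≈ 7, SD ≈ 5, minimum span ~4 years) with an integer age-at-death
covariate centred near 90 that lowers both cognitive levels and
advances the midpoint of decline, so that each model family detects an
age effect; it emulates published summary descriptors of such a
dataset — the true generating process behind those descriptors is not
public, so only the descriptors are binding.

Neither generator models informative dropout or missingness tied to
the outcome, practice/retest effects, floor or ceiling effects of real
cognitive composites, measurement-error heteroscedasticity, or visit
schedules that depend on health. Passing parameter-recovery and MSE
checks on these data therefore demonstrates correctness of the
estimation machinery under the stated design, not robustness to the
full messiness of observational cohorts.

## The replication harness

`run_simulation_study()` generates data, computes initials (automatic
or naive-zero), fits, and evaluates the estimated marginal mean on a
yearly grid against the generating truth — the structural mean at zero
random effects and covariates at their generating means. It aggregates
the empirical MSE, $\mathrm{MSE}(t) = \frac1R\sum_r (Y(t)-\hat
Y_r(t))^2$, the percent bias of the replicate-averaged curve (masked
where $|Y(t)| < 10^{-6}$), the smoothing-phase convergence rate, and
runtimes (recorded, never asserted — they are hardware facts, not
statistical ones). The desk-scale default is one scenario (sigmoidal,
$N = 100$, no covariates, 20 replicates), which is what the test-suite
and the reproduction script run; the full three-sample-size by
three-covariate-count grid is exposed through
`full_performance_grid()` for batch use and is intentionally not part
of any automated check. The automatic-versus-naive-initials comparison
is asserted on the abrupt piecewise family, where the quintile
changepoint scan does substantive work; the sigmoidal fit, whose long
exploration phase makes it largely insensitive to its starting point,
reaches the same optimum from either arm, so a paired inequality there
would compare two realisations of the same number. Test-suite fits use shortened SAEM schedules
(e.g. `K1 = 150–200`, `K2 = 100–150`) chosen as the package's own
trade-off between statistical resolution and suite turnaround.

## Numerical choices and edge cases

* Engine-internal evaluations clamp the sigmoidal midpoint away from
  zero (at $10^{-3}$ of the time range, on the correct side) and the
  Hill slope to at least 0.02, so optimizer and sampler excursions are
  penalised smoothly instead of raising domain errors; the exported
  structural functions remain strict.
* $0^{\psi_4}$ is defined as 0 for $\psi_4 > 0$, making
  $f(0) = \psi_2$ exact; $\psi_4 \le 0$ is excluded at fit time.
* The projected covariance update keeps $B$ inside its structure:
  eigenvalue flooring for the full (sigmoidal) case, and shrinkage of
  the slope covariance to 99% of its Cauchy–Schwarz bound for the
  piecewise case.
* Quintile slope ties break to the earliest quintile; degenerate
  percentile windows fall back to per-subject first/last observations
  with a warning; fewer than three distinct times is treated as
  nearly linear by convention.
* Non-stabilization is reported (`converged_phase2 = FALSE` plus a
  warning), never thrown; a singular information matrix yields `NA`
  standard errors naming the affected parameters.

## Known limitations

Beyond the generator simplifications above: exactly two phases (no
multi-changepoint trajectories) and Gaussian outcomes only; the
hyperbolic-tangent style smooth transition is deliberately not offered
(the cubic construction avoids its artificial post-changepoint bump);
$v$ is never estimated; standard errors rely on the linearized
information (no stochastic Louis estimator); and Wald tests are
asymptotic — at small $N$ (the fit warns below 30 subjects) their
calibration degrades together with the linearization itself. The
linearized information is least trustworthy exactly where the model is
least curved: for the smooth piecewise family the cubic window blurs
the changepoint, and the replication tests show the empirical sampling
spread of the changepoint and terminal-slope estimates exceeding their
reported standard errors by a factor approaching two at $N = 200$ —
confidence intervals for those two parameters of the smooth family
should be read as optimistic.
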