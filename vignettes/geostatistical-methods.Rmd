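---
title: "Geostatistical prediction and sampling design with GeoKrige"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical prediction and sampling design with GeoKrige}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeoKrige)
```

GeoKrige models point-referenced solute concentrations in groundwater — the
motivating application is sodium (mg/L) measured at irregular monitoring
wells — and answers two questions: *what is the concentration at unsampled
locations, with what uncertainty?* and *which monitoring sites should be
added or removed to predict best at fixed cost?* This vignette explains the
statistical machinery, the choices behind the defaults, and what the
synthetic-data tests do and do not establish.

## The data model

Concentrations are strictly positive and right-skewed, so modelling starts
with a Box-Cox transformation $z = (y^\lambda - 1)/\lambda$ (natural log at
$\lambda = 0$), with $\lambda$ estimated by maximizing the i.i.d.-normal
profile likelihood over $[-2, 2]$ by golden-section search (tolerance
$10^{-4}$). On the transformed scale the field is Gaussian,

$$Y \sim N(F\beta,\; \Sigma), \qquad
  \Sigma = \sigma^2\left[(1-\tau^2) R_\alpha + \tau^2 I\right],$$

where $F$ is a polynomial basis in (latitude, longitude) — the constant for
ordinary kriging, $(1, \mathrm{lat}, \mathrm{lon})$ for universal kriging
with linear trend — and the covariance is parametrized by the **total sill**
$\sigma^2$, the **range** $\alpha$, and the **relative nugget**
$\tau^2 \in [0, 1)$, the nugget fraction of the sill. Four correlation
families are available: exponential, Gaussian, spherical, and the standard
cubic model $\rho(u) = 1 - 7u^2 + 8.75u^3 - 3.5u^5 + 0.75u^7$ for
$u = h/\alpha \le 1$. Distances are Euclidean in decimal degrees with
latitude as the first coordinate; at the scale of the study region
(roughly $3.5^\circ \times 2.5^\circ$) this is the convention under which
the fitted ranges are interpretable, and geodesic distances are out of
scope.

Relative versus absolute nugget deserves a warning: published parameter
tables do not always say which convention they use. `variogramModel()`
accepts both (`nugget.type = "relative"` or `"absolute"`), and analyses
that compare against external fits should state the convention explicitly.

## Variogram estimation

Four estimation routes are implemented behind one interface.

* **OLS / WLS** fit the parametric semivariogram
  $\gamma(h) = \sigma^2[\tau^2 + (1-\tau^2)(1 - \rho(h/\alpha))]$ to the
  classical Matheron estimator computed on residuals from an
  ordinary-least-squares trend fit (true GLS residuals would require the
  unknown covariance). Defaults: 13 equally spaced bins up to half the
  maximum pairwise distance; empty bins are dropped. WLS uses Cressie
  weights $N_k / \gamma(h_k)^2$.
* **ML / REML** minimize the Gaussian negative log-likelihood with $\beta$
  profiled out by generalized least squares and $\sigma^2$ profiled in
  closed form ($\hat\sigma^2 = Q/n$ for ML, $Q/(n-p)$ for REML, with $Q$
  the GLS residual quadratic form), reducing the search to
  $(\log\alpha, \mathrm{logit}\,\tau^2)$. The REML criterion includes all
  constants of the likelihood of an orthonormal error-contrast basis, so it
  equals that contrast likelihood exactly — a property the test suite
  checks against an explicit contrast construction. REML is the preferred
  default because it removes the downward bias that trend estimation
  induces in the sill.

All numeric fits use Nelder-Mead from five fixed starting points spanning
the (sill, range, nugget) box (fractions 0.1–0.75 of the maximum lag for
the range, 0.05–0.7 for the nugget), tolerance $10^{-8}$; among ties the
smallest range wins, making fits deterministic. A consequence of profiling
worth knowing: both the ML and REML criteria are exactly invariant to
adding any trend-space shift $Fc$ to the data, because profiling $\beta$
removes it; the two criteria differ by the REML adjustment
$\tfrac12\log|F^\top\Sigma^{-1}F|$ (plus constants).

## Universal kriging

Prediction at a target $x_0$ solves the bordered semivariogram system

$$\begin{pmatrix} \Gamma & F \\ F^\top & 0 \end{pmatrix}
  \begin{pmatrix} \lambda \\ \ell \end{pmatrix} =
  \begin{pmatrix} \gamma_0 \\ f_0 \end{pmatrix},$$

giving the predictor $\lambda^\top Y$ and the kriging variance
$\lambda^\top\gamma_0 + \ell^\top f_0$. One LU factorization of the
bordered matrix serves a whole batch of targets. The implementation is
verified, instance by instance, against an independent covariance-form GLS
computation ($\hat Y_0 = f_0^\top\hat\beta +
c_0^\top\Sigma^{-1}(Y - F\hat\beta)$ with its standard variance), which is
algebraically identical but numerically a different route. Variances in
$(-10^{-10}, 0)$ — which arise when a target coincides with a data site —
are clamped to zero (silently below roundoff scale $10^{-13}$, with a
warning above it); anything more negative is an error.

Leave-one-out cross-validation under a fixed covariance uses the closed
form $e_i = (HY)_i / H_{ii}$, $\sigma^2_i = 1/H_{ii}$ with
$H = \Sigma^{-1} - \Sigma^{-1}F(F^\top\Sigma^{-1}F)^{-1}F^\top\Sigma^{-1}$,
which equals deleting each site and re-solving — the suite checks this
against a literal per-fold rebuild. The variogram is estimated once on the
full data and held fixed across folds (the common cross-validation
convention for kriging); `refit = TRUE` re-estimates per fold. The
comparison statistic is RMSPE, by default computed after back-transforming
predictions to mg/L, since that is the scale on which monitoring decisions
are made; `backtransform = FALSE` gives the transformed-scale version.
Naive inverse-transformation of the kriging mean is not the conditional
mean on the raw scale — it is the conditional median under log-like
transforms — which is a known, accepted bias of this reporting convention.

## Bayesian universal kriging

The Bayesian layer treats all parameters as uncertain with the standard
noninformative/discrete prior combination: $\pi(\beta) \propto 1$,
$\pi(\sigma^2) \propto 1/\sigma^2$, and a discrete prior on
$(\tau^2, \alpha)$ (defaults: 51 equally spaced ranges in (0, half the
maximum pairwise distance], nugget fractions $0, 0.05, \dots, 0.95$,
uniform over the product grid). Then the posterior over the support is
available in closed form,

$$\pi(\tau^2, \alpha \mid Y) \;\propto\; \pi(\tau^2, \alpha)\,
  |F^\top R^{-1} F|^{-1/2}\, |R|^{-1/2}\, (S^2)^{-(n-p)/2},$$

with $S^2 = (Y - F\hat\beta)^\top R^{-1}(Y - F\hat\beta)/(n-p)$ the GLS
scale statistic. (Some published statements of this density carry the
exponent $+1/2$ on $|F^\top R^{-1}F|$; the integrated marginal likelihood
requires $-1/2$ — the covariance factor of $\hat\beta$ — and that is what
is implemented and what the brute-force oracle in the tests evaluates.)
Conditionally, $\sigma^2 \mid \tau^2, \alpha, Y \sim
\chi^{-2}(n-p,\, S^2)$ (scaled inverse chi-square) and
$\beta \mid \sigma^2, \tau^2, \alpha, Y$ is Gaussian at the GLS estimate.
Everything is computed in log space and normalized by log-sum-exp.

Prediction is by composition sampling: draw a support point
(multinomial), draw $\sigma^2$ from its conditional, then draw the target
value from the Gaussian whose mean is the universal kriging predictor and
whose variance is the universal kriging variance under the drawn
parameters. Two computational facts keep this cheap: the kriging *mean*
does not involve the sill, and the kriging *variance* is linear in it, so
the bordered system is solved once per support point rather than once per
draw. Equal-tailed empirical quantiles of the draws give credible
intervals (1 000 draws suffice for maps, 10 000 for interval reporting).

The same facts make the Bayesian leave-one-out RMSPE deterministic: the
posterior-predictive mean at a held-out site is the posterior-weight
average of per-support-point kriging predictions, so no Monte Carlo enters
the cross-validation. Weights are computed once from the full data and
held fixed across folds, mirroring the plug-in convention; `refit = TRUE`
recomputes them per fold at $n$ times the cost.

## Sampling design

The design objective is the **mean universal kriging variance** (MUKV):
the kriging variance averaged over a regular evaluation grid (default
spacing $0.1^\circ$ for maps, coarser for optimization; `stat = "sum"`
gives the unnormalized total for comparison with conventions that do not
divide by the node count). Since kriging variances do not involve the
observations, a design is scored from its site geometry alone.

Spatial simulated annealing searches over designs: **add mode** displaces
one of the new sites uniformly within a disc (radius initialized by the
mean within-cluster diameter of a $k$-means clustering with $k = 6$,
shrinking with the temperature; draws are clipped to the bounding box);
**delete mode** swaps one deleted site with one retained site, so deleted
sites always come from the existing network. Improvements are always
accepted; worsenings with probability $\exp(-\Delta/T)$ where $\Delta$ is
the change against the *current* design (the standard Metropolis form).
The initial temperature is calibrated from 100 warm-up proposals so that
the initial worsening-acceptance rate is about one half (median positive
$\Delta$ divided by $\log 2$); cooling multiplies $T$ by 0.9 every 50
proposals, and the search stops after 10 stages without improving the best
design or at the proposal budget. The best-so-far design and the full
trace are returned; the best-so-far trace is non-increasing by
construction and asserted in every test run. An exhaustive deletion
oracle (capped at $10^5$ subsets) provides ground truth on small
problems.

Two monotonicity facts anchor the design results and are verified
numerically rather than assumed: adding a site never increases the kriging
variance at any target, and deleting one never decreases it. When ordinary
and universal kriging are compared *each under its own REML-fitted
variogram* — the meaningful comparison, since the trend absorbs part of
the sill — the universal-kriging MUKV sits below the ordinary-kriging one
on trend-bearing fields in the typical replicate, though the margin is a
fraction of a percent and individual replicates can flip; the test suite
therefore checks the median over seeds. Under a single shared variogram
the inequality provably points the other way (universal kriging carries
more unbiasedness constraints), which is why `runDesign()` fits
per-predictor models by default.

## The synthetic study

`simulationSpec()` defaults encode the reference conditions the package is
exercised under: $n = 370$ sites uniform in the box lat 28–31.5°,
lon 69.5–72°; spherical covariance with total sill 0.7078, range 1.1709°,
relative nugget 0.43 on the transformed scale; linear trend with
coefficients $(12, -0.25, 0.01)$, chosen once so that the transformed
field sits near 5.2 (a median concentration of roughly 300 mg/L after
back-transformation with $\lambda = -0.028$) and concentrations increase
toward the south of the box; and Box-Cox exponent $-0.028$ linking the two
scales, so the raw values are positive and strongly right-skewed and the
transform-estimation stage is genuinely exercised. Fields are simulated
exactly via the Cholesky factor of the model covariance. Sites are
scattered uniformly by default; `layout = "clustered"` instead places two
sites per randomly chosen cell of a regular partition, mimicking paired
sampling of administrative units, and evaluation grids accept an optional
inclusion mask for non-rectangular regions.

One sampling fact worth knowing when interpreting single realizations: at
the study's range (≈1.17° in a 3.5° × 2.5° box) the field has few
effectively independent replicates, so the Box-Cox exponent estimated from
one realization scatters by roughly ±0.1 around the generating value even
with the trend profiled out — an uncertainty that marginal profile
likelihoods on real data share.

What passing tests on this generator establish: the estimation,
prediction, posterior and design machinery is internally correct (oracle
agreement to near machine precision) and statistically calibrated
(parameter recovery, coverage of closed-form moments) *under the model*.
What they do not establish: behavior under real-data features the
generator omits — preferential/clustered sampling (wells sit where people
live), measurement batches, non-stationarity of the trend or covariance,
coordinate error, and any departure from Gaussianity that a single global
Box-Cox cannot absorb.

## Numerical choices and limitations

* All covariance algebra is Cholesky-based; a singular matrix is an error
  naming the offending parameters, not a silent regularization. The
  simulator retries once with a $10^{-10}\sigma^2$ diagonal jitter before
  failing.
* Duplicate coordinates are an error by default (`jitterDuplicates = TRUE`
  displaces them by $10^{-6}$ degrees with a warning), because coincident
  sites make every kriging matrix exactly singular.
* Problem sizes in the shipped tests: oracle comparisons at $n \le 30$,
  parameter-recovery at the full $n = 370$ over 20 replicates, annealing
  correctness on 6-site toys against exhaustive enumeration, and one
  end-to-end run at study size with a coarsened ($0.35^\circ$) design
  grid and reduced annealing budget — sizes chosen so the whole suite
  exercises study-scale behavior while remaining quick to run routinely.
* Anisotropy, the Matérn family, local-neighborhood and block kriging,
  continuous (MCMC) covariance priors, model averaging across families,
  and space-time designs are out of scope.
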