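---
title: "Estimating abundance, trend, and cycles from aerial strip-transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating abundance, trend, and cycles from aerial strip-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stripgam)
```

`stripgam` estimates the size, spatial density, trend, and cyclic period of
a rare, patchily distributed bird population from aerial strip-transect
surveys. The motivating setting is tundra-nesting sea ducks surveyed from
fixed-wing aircraft: observers count single males and male-female pairs
within a 200 m strip on each side of the trackline, densities are low, most
transect segments hold zero birds, and the population swings several-fold
between years. The package provides two complementary estimators — a
design-based strip estimator and a model-based spatio-temporal density
surface — plus posterior machinery for population totals, detection
correction, growth rates, and wavelet cycle detection, all exercised
against a synthetic survey generator with recorded truth.

## The observation unit

Counts are *indicated pairs*: each observed single male and each observed
pair is one indicated pair (a lone male is taken to indicate an unseen
nesting female). Lone females are dropped, off-transect sightings are
dropped, and a size-1 group of unknown status is recoded as a single male;
groups larger than one are an error rather than a guess, since the
supported surveys never produced one (`apply_inclusion_rules()`,
`indicated_units()`). *Indicated breeding birds*, the estimand after
detection correction, is twice the indicated pairs.

## Design-based estimation

For strips of area $a_i$ with counts $n_i$ ($i = 1,\dots,k$, totals $n$
and $a$) in a stratum of area $A$:

$$\hat N = A \frac{\sum_i n_i}{\sum_i a_i}, \qquad
\widehat{\mathrm{var}}(\hat N) = \left(\frac{A}{a}\right)^2 \frac{a}{k-1}
\sum_i a_i \left(\frac{n_i}{a_i} - \frac{n}{a}\right)^2.$$

No finite-population correction is applied (birds move and detection is
imperfect, so strips are not repeatable plots), and no detection
correction: this estimator tracks the *observed* density. The 95% CI is
normal-theory, truncated below at zero; with no encounters both the
estimate and its variance are exactly zero — the structural weakness that
motivates the model-based route. The sampling unit is the transect, so
segments are re-aggregated per transect before estimation
(`annual_design_series()`). A classical ratio estimator is included only as
a comparator (`ratio_estimate()`); it degrades badly when birds concentrate
on short transects, making count and strip size negatively correlated.

## The density model

Transects are chopped into fixed-length segments (1 km for dense designs,
6 km for sparse ones; the boundary remainder keeps its true, smaller area),
observations are assigned to the nearest segment of their survey-year, and
segment counts $y$ are modelled as negative binomial (NB2,
$\mathrm{var} = \mu + \mu^2/\theta$) with log link and
$\log(\text{segment area})$ offset, so the linear predictor is log density
per km². The model menu is the standard density-surface family:

* `M0`: `s(X,Y)` — a static spatial surface;
* `M1`: `s(X,Y) + s(Year)` — separable space and time;
* `M2`: adds `ti(X,Y,Year)`, letting the spatial pattern drift through time;
* `M3`: `M1` plus a year random effect for abrupt non-smooth year shocks;
* `M4`: `s(X,Y)` plus a year random effect only;

optionally an observer random effect and a fixed survey factor when data
sets are combined. Random-effect terms are penalized indicator columns
(ridge); the survey factor is unpenalized treatment coding, so the baseline
level is the survey the detection study was run on.

### Basis and penalty choices

Smooths use tensor products of cubic B-splines with second-order difference
penalties. Coordinates and year are standardized to zero mean and unit SD
before basis construction, and the 2-D spatial smooth carries a single
smoothing parameter on the sum of its two margin penalties, making it
effectively isotropic in standardized space. The interaction tensor is a
functional-ANOVA term: each margin is centred (sum-to-zero over the data)
before the product is formed, which excludes the main effects it interacts
with; its spatial and year margins carry separate smoothing parameters.
Every smooth is constrained to sum to zero over the fitting data, absorbed
by an orthonormal reparameterization so the penalized system stays full
rank. Default basis dimensions are 6×6 (spatial), 15 (year), and
(4×4)×5 (interaction margins). The year default is sized so that a
25-year series with a ~6.5-year cycle (nearly four full oscillations,
~10–12 effective degrees of freedom) is not forced smooth; a k = 10 margin
caps the term at 9 edf and audibly flattens the cycle, which is why the
default is larger. A thin-plate basis would serve equally well — the
inferential content is the penalty structure and the ANOVA decomposition,
not the basis family — and the chosen family is recorded in the fit object.

### Fitting

The inner loop is penalized IRLS (Fisher scoring with step halving,
guaranteed ascent of the penalized log-likelihood, plus two trailing Newton
"polish" steps); the outer loop maximizes a Laplace-approximate restricted
marginal likelihood over the log smoothing parameters and log dispersion
with Nelder-Mead, restarted once from its own optimum because penalty
directions that shrink a term away are asymptotically flat. Tolerances:
1e-8 relative penalized-likelihood change (inner), 1e-6 (outer), 200/500
iteration caps. The coefficient posterior is
$\beta \sim N(\hat\beta, (X^\top W X + S_\lambda)^{-1})$, the usual
Bayesian covariance of a penalized fit. AIC uses the trace effective
degrees of freedom ($-2\ell + 2\,\mathrm{edf}$, "edf-AIC"); a
degeneracy-corrected df would shift all models by similar amounts and is
out of scope, so published AIC tables from other implementations are not
expected to reproduce digit-for-digit. Model checking uses randomized
quantile residuals plus observed/expected zero fractions and a Pearson
dispersion ratio (`quantile_residuals()`).

## Population totals and detection

The study area is gridded into ≤1 km² cells clipped to the boundary
(`make_grid()`); coefficient draws come either from the multivariate normal
posterior or, for sparse surveys where the quadratic approximation is poor
in the tails, from a Metropolis-Hastings sampler that alternates a
heavy-tailed independence proposal with random-walk steps, both scaled by
the posterior covariance (`sample_coef_mvn()`, `sample_coef_mh()`). For
draw $i$ and year $j$,

$$\hat Y_{ij} = \sum_k a_k \exp(x_{jk}^\top \beta_i), \qquad
\hat N_{ij} = 2 \hat Y_{ij} / d_i,$$

with $d_i \sim \mathrm{Beta}(\alpha, \beta)$ one detection draw per
posterior draw, constant across years within a draw. The Beta prior is
moment-matched to a distance-bin-averaged double-observer detection
estimate: per-bin SE approximated as CI range / (2·1.96), equal bin
weights (the design puts birds uniformly in distance), pooled variance the
*mean* of bin variances — the per-observation detection uncertainty, not
the variance of the mean, which is what makes the prior honestly wide. The
canonical configured prior is mean 0.307, SD 0.092, i.e. roughly
Beta(7.41, 16.73). Because expectations, not realizations, are summed,
totals are strictly positive, and the wide detection prior makes corrected
posteriors visibly right-skewed. Year random effects refuse prediction
into unsurveyed years (a ridge level has no information there); temporal
smooths interpolate them.

The geometric-mean growth rate between years $j$ and $j+t$ is
$T = (\log N_{j+t} - \log N_j)/t$ per draw. A constant-within-draw
detection correction cancels in $T$ exactly, so trends are identical for
index and corrected totals draw by draw — a useful internal consistency
check that the correction enters only as a scale.

## Wavelet cycle analysis

Annual series (posterior means, or each posterior draw) are centred,
scaled, zero-padded to a power of two, and transformed with a Morlet
wavelet (ω₀ = 6) over a geometric scale ladder (dj = 1/20, s₀ = 2 yr,
ladder reaching the series length — the standard convention). Significance
is a white-noise bootstrap: 200 simulated Gaussian series, p-value per
period the fraction of simulations whose time-averaged power meets the
observed. The dominant period is the argmax of time-averaged power (ties
to the smallest period); it is flagged when it falls at a ladder end or
beyond the widest cone of influence, where padding artifacts dominate —
a monotone trend with no cycle lands there. The bootstrap CI perturbs the
observed average spectrum by each null draw's relative deviation and takes
the argmax distribution; this is the package's own construction and is not
claimed to match any particular toolkit's internal interval. Series are
*not* detrended by default (a slow ~15-year component would be destroyed);
a loess detrend option exists. Boundary periods are reported, not excluded,
from the time average, mirroring the use of the full-series average on
short (~25-point) ecological series.

## The synthetic survey generator

`sim_preset()` / `simulate_survey()` emulate the two survey designs the
analysis is meant for:

* `triangle_like` — a 140 km² triangular area with its apex on the north
  coast (so the densest transects are the short northern ones), 1 km
  east-west transect spacing at 0.4 km strip width (40% coverage, inside
  the 25–50% regime of a dense monitoring plot), 25 consecutive years,
  1 km segments, base density 0.5 pairs/km².
* `acp_like` — a 2560 km² rectangle in two strata (8 / 16 km spacing,
  ~5% / 2.5% coverage), 16 surveyed years of 18 (two missing), 6 km
  segments, base density 0.04 pairs/km² — yearly truth swings roughly
  170–1250 pairs, the rare-species regime where design-based estimates
  routinely hit zero.
* `combined` — both at once over one shared intensity field, the sparse
  survey carrying a +0.46 log-scale crew effect, the triangle nested
  inside the larger region.

Log intensity is `log(base) + gradient·(y/height) + amp·sin(2π(t −
t₀)/P) + drift·(t − t̄)·(y − ȳ)`: a north-coast gradient (default 2.5), a
cycle of default period 6.5 years and amplitude 1.0 (so yearly truth swings
by ≈ e², matching observed several-fold fluctuation), and an optional
planar space-time tilt (default 0). Latent segment counts are NB2
(θ = 1.5); observed counts are binomial thinnings at detection 0.307.
Thinning a NB2 keeps the NB2 form (mean d·μ, same θ), so the fitted model
is correctly specified and the detection correction has a concrete latent
target — this latent-first construction is deliberate. Observed units are
scattered uniformly within their segment strip; configurable rates of lone
females and off-transect sightings exercise the inclusion rules. Truth is
the numeric integral of the intensity surface (midpoint quadrature,
0.25 km). Coordinates are offset to (300, 2000) km to mimic a projected
(Albers-like) range.

What the generator does *not* emulate: flushing and flocking behaviour,
availability-versus-perception components of detection, observer-specific
detection fields, real boundary geometry, or covariate-driven (e.g.
predator-mediated) dynamics. Passing tests therefore demonstrate that the
estimators recover the truth of a correctly specified, stationary-cycle
world — they do not validate the model against real survey idiosyncrasies.

## Numerical and design choices worth knowing

* Observation-to-segment assignment is nearest-segment (perpendicular
  distance, ties to the lexicographically smaller segment id, 1 km orphan
  gate); field protocols do not record an along-track index, so some
  assignment rule is unavoidable and this one is deterministic.
* Remainder segments are kept, not merged — their smaller area flows into
  the offset, which is exactly what the offset is for.
* The optimizer works in log(λ), log(θ) with a ±18 box; penalties are
  scaled to unit mean diagonal so λ = 1 is a comparable starting point
  across terms; the generalized penalty log-determinant uses the rank of
  the unweighted penalty sum, computed once, so the REML criterion stays
  continuous when individual λ's diverge.
* Degenerate inputs: all-zero counts are a fit error (the NB likelihood
  degenerates); a constant series is a wavelet error; zero-variance
  posterior draws are skipped (and counted) in the period posterior;
  sub-metre transects are skipped with a warning.
* Problem sizes in the tests (replicate counts, grid resolutions, draw
  counts) are chosen as the smallest that make the Monte-Carlo tolerances
  meaningful; they are stated alongside each test.

## Known limitations

The engine fits the model family it advertises and nothing more: no
Poisson or Tweedie responses (the counts at hand are firmly
overdispersed), no spatial correlation beyond the smooth, no
boundary-aware (soap-film) smoothing, no spatially varying detection (the
interface anticipates per-cell correction but the implementation applies
one scalar per draw). AIC values are comparable within this engine only.
The Metropolis-Hastings sampler targets the Laplace posterior at the
selected smoothing parameters; smoothing-parameter uncertainty is not
propagated.
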