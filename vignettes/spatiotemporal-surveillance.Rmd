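---
title: "Methods: harmonic trends, SIRs and spatiotemporal models for pest complaint surveillance"
author: "pestsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonic trends, SIRs and spatiotemporal models for pest complaint surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestsurv)
```

# The problem

Municipal non-emergency reporting systems (311 lines and housing
maintenance code complaints) are, for urban pests such as bed bugs, the
largest available proxy for infestation burden. Three questions recur in
analysing them: is the citywide complaint burden rising or falling once
strong summer-peaking seasonality is removed; how does each
neighbourhood's burden compare with what its population size alone would
predict; and how does neighbourhood-level risk evolve over years once
spatial neighbourhood structure and shared temporal shocks are accounted
for. `pestsurv` implements the full chain — seasonal trend regression,
indirect standardization, and Bayesian hierarchical spatiotemporal
modelling — together with a synthetic-data generator so that every stage
is testable without administrative data extracts, which are continuously
revised and cannot be redistributed.

# Harmonic trend model with linearly varying amplitude

Monthly complaint series $y_t$, $t = 0, \dots, T-1$, are modelled as

$$
y_t = \beta_0 + \beta_1 t
    + (\text{seasonal component with period } 12)
    + \varepsilon_t ,
$$

where the seasonal component has a *linearly time-varying amplitude*.
Writing $\omega = 2\pi/12$, the model is linearized in the standard way:

$$
y_t = \beta_0 + \beta_1 t + \beta_2 \sin \omega t + \beta_3 \cos \omega t
    + \beta_4\, t \sin \omega t + \beta_5\, t \cos \omega t
    + \varepsilon_t .
$$

The instantaneous seasonal amplitude is then the derived quantity

$$
A(t) = \sqrt{(\beta_2 + \beta_4 t)^2 + (\beta_3 + \beta_5 t)^2},
$$

returned by `amplitude_at()`. Because the amplitude is derived rather
than constrained, a growing amplitude (as for cockroach-type series)
needs no separate model. Fitting is ordinary least squares through a QR
decomposition (`fit_harmonic_trend()`); the secular trend is a two-sided
$t$-test on $\beta_1$ with $n - 6$ degrees of freedom, and a joint Wald
$F$-test on $(\beta_4, \beta_5)$ is reported alongside because "the
amplitude changes" is a two-parameter hypothesis. Conventions worth
knowing:

* the month index starts at 0 and is *uncentred*, so $\beta_0$ is the
  level at the first month (this affects the intercept's meaning only);
* when a series carries a denominator (total inquiries, or population),
  the response is standardized to a percentage, $100\, y_t / d_t$,
  before fitting — both count-scale and standardized entry points exist
  because either may be wanted;
* the seasonal period is fixed at 12 months (annual seasonality is a
  structural fact of these series, not something to select);
* for a zero-variance response $R^2$ is defined as 0;
* no autocorrelation-robust standard errors are computed: the intent is
  a plain linear-model trend test, and that is a documented limitation.

The concordance check between two per-area reporting streams
(owner-mandated reports vs resident-initiated complaints) is a simple
linear regression with intercept (`concordance_regression()`), returning
the slope with its 95% confidence interval and $R^2$; a slope near 1
indicates proportional agreement, and a slope below 1 with high $R^2$
indicates systematic partial reporting of one stream relative to the
other.

# Indirect standardization

For areas $i$ with populations $n_i$ and observed counts $y_i$, expected
counts are

$$
E_i = r\, n_i, \qquad r = \frac{\sum_i y_i}{\sum_i n_i},
$$

with the reference rate $r$ computed within a *standardization stratum*.
The default stratum is the calendar year, matching per-year SIR maps; a
pooled mode exists for sensitivity. The standardized incidence ratio is
$\mathrm{SIR}_i = y_i / E_i$. Two identities are guaranteed and tested:
$\sum_i E_i = \sum_i y_i$ exactly within each stratum, and the
population-weighted mean SIR is exactly 1. Zero-population areas are
rejected rather than silently dropped — administrative geographies
should never have zero population, so a zero signals an upstream join
error; a `drop_zero_population()` pre-filter exists for real-data
dialects where uninhabited areas (parks, airports) legitimately occur.
A crude per-100,000 rate export is provided separately because rate maps
and SIR maps answer different display questions.

# The hierarchical spatiotemporal Poisson model

For areas $i = 1,\dots,n$ and periods $t = 1,\dots,T$ (years, in the
usual application), counts are

$$
y_{it} \sim \mathrm{Poisson}(E_{it}\, e^{\eta_{it}}), \qquad
\eta_{it} = b_0 + u_i + v_i + \gamma_t + \phi_t + \delta_{it},
$$

with

* $u$: spatially structured effect, intrinsic CAR with structure matrix
  $Q_u = D - W$ (graph Laplacian of the contiguity graph), constrained
  to sum to zero within each connected component;
* $v$: spatially unstructured iid Gaussian effect ($u + v$ is the
  classic BYM convolution, deliberately *not* the rescaled
  reparameterization, so precision components map directly onto the
  conventional summary table);
* $\gamma$: temporally structured RW2 effect (second-difference penalty,
  rank $T-2$), constrained orthogonal to constant and linear vectors;
* $\phi$: temporally unstructured iid effect;
* $\delta$: space-time interaction with one of three structures —
  type I, fully unstructured ($Q_\delta = I$, rank $nT$); type II, RW2
  in time within each area ($Q_\gamma \otimes I_n$, rank $n(T-2)$);
  type III, ICAR in space within each period ($I_T \otimes Q_u$, rank
  $T(n - c)$ for $c$ graph components) — or omitted entirely.

Each precision $\tau$ carries a Gamma(shape, rate) hyperprior, default
Gamma(1, 5e-4), the conventional weakly informative disease-mapping
choice (prior mean 2000, i.e. fields near zero unless the data demand
otherwise); a sensitivity run with Gamma(0.5, 5e-4) is part of the test
suite. Intrinsic field densities use the *generalized rank* as the
exponent, $\pi(x \mid \tau) \propto \tau^{\mathrm{rank}(Q)/2}
\exp(-\tfrac{\tau}{2} x^\top Q x)$, so the conjugate precision update is
Gamma(shape $+$ rank$/2$, rate $+ x^\top Q x / 2$).

## Sampler

The posterior is explored by Metropolis-within-Gibbs (the model, not the
fitting engine, is the scientific content; at the scale of a few hundred
areas a from-scratch MCMC targets the exact posterior without
approximation):

* latent fields: adaptive single-site random-walk Metropolis; each
  field's step size is tuned every `adapt_window` sweeps during burn-in
  only, toward a 30–50% acceptance rate, and frozen afterwards so the
  chain is a valid time-homogeneous Markov chain when samples are kept;
* $b_0$: random-walk Metropolis under a flat prior;
* precisions: conjugate Gamma draws with generalized ranks;
* constraints: after every sweep the intrinsic fields are re-centred to
  their constraint spaces ("centering on the fly", the classic
  disease-mapping device): $u$ per graph component with its overall mean
  absorbed into $b_0$; the mean of $\gamma$ into $b_0$ and its linear
  null-space component projected out; type II $\delta$ row means
  absorbed into $v$ (an $\eta$-preserving move) and row-linear parts
  projected out; type III $\delta$ period means absorbed into $\phi_t$.
  Constraint residuals are recorded per retained draw and are at machine
  precision by construction.

All randomness flows through R's RNG, so a fixed seed reproduces a fit
bit-for-bit; additional chains use independently derived seeds, and with
two or more chains a split-chain potential-scale-reduction factor is
reported for $b_0$ and the precisions. The sampler aborts with a state
report if $|\eta|$ exceeds 50 (divergence) and refuses to start from a
non-finite posterior.

A `prior_only = TRUE` flag ignores the data entirely and samples the
prior by an exact Gibbs chain (constrained GMRF field draws alternating
with conjugate precision draws); its marginal law for each precision is
exactly the Gamma hyperprior, which the test suite uses as a calibration
check of the hyperprior plumbing.

## Model comparison and relative risk

Model fit is compared by DIC: $\bar D$ is the posterior mean deviance,
$p_D = \bar D - D(\bar\eta)$ with the deviance evaluated at the
*posterior mean of the linear predictor* (not of the parameters
separately — $p_D$ depends on this parameterization choice, so it is
fixed and documented), and $\mathrm{DIC} = \bar D + p_D$. Candidates are
ranked ascending; models within 1 DIC of the best are flagged as ties
and the smaller-$p_D$ model is preferred on a tie (a parsimony
convention). A failed fit is recorded and the comparison proceeds with
the survivors, carrying a nonzero status.

Two relative-risk surfaces are exported, because the field's
cartographic convention is genuinely ambiguous between them: the default
`"interaction"` mode is the posterior mean of $e^{\delta_{it}}$ (the
space-time anomaly net of main effects), and `"full"` mode is the
posterior mean of $e^{\eta_{it} - b_0}$ (total risk relative to the
study-region rate). Means are taken after exponentiation, so Jensen's
inequality makes them larger than the exponentiated posterior means —
also the conventional choice.

# The synthetic-data generator

The generator produces exactly the structures the pipeline assumes, so
recovery tests are well-posed:

* `make_lattice()` builds one or more disconnected rectangular grids
  with rook contiguity (edge-sharing). Rook is used for synthetic grids
  because its degree structure is hand-verifiable; the polygon reader
  (`adjacency_from_polygons()`) uses queen contiguity (a shared boundary
  vertex suffices) to mirror how administrative neighbourhood graphs
  are built in practice. Disconnected components emulate an island
  borough, which is why every ICAR computation in the package is
  per-component.
* `sample_gmrf()` draws intrinsic fields exactly, by
  eigen-decomposition of the structure matrix with null-space
  coordinates set to zero; this is $O(m^3)$ in the field dimension and
  entirely adequate below a few hundred areas, which is the intended
  scale.
* `simulate_panel()` composes $\eta$ from the drawn fields and samples
  $y_{it} \sim \mathrm{Poisson}(E_{it} e^{\eta_{it}})$ with
  $E_{it} = \text{base\_rate} \times \text{population}_i$, mirroring
  indirect standardization with a global rate. The full latent truth is
  returned.
* `simulate_monthly_series()` generates
  $y_t = \text{level} + \text{slope}\, t + (a_0 + a_1 t)
  \cos(\omega t - \text{phase}) + \varepsilon_t$ with Gaussian noise.
  The administrative sources never reveal a noise family for monthly
  aggregate series; Gaussian is this package's documented choice for the
  series generator, while the panel generator is Poisson as the
  spatiotemporal model requires. An amplitude line $a_0 + a_1 t$ that
  crosses zero inside the window flips the seasonal phase; this is
  legitimate behaviour but almost always a configuration mistake, so it
  must be opted into with `allow_amplitude_flip`.

## Default generator conditions

Defaults describe a six-year monthly window over a mid-sized city
partition: populations uniform on 15,000–120,000 (administrative
neighbourhood units are built to a ~15,000-person floor), a base rate of
2e-4 events per person-month (a few dozen complaints per area-month),
seasonal amplitude starting at 20 events per month and shrinking by 0.15
per month with a late-July peak, a secular trend of −0.5 events per
month, and Gaussian noise with standard deviation 3. Latent-field
precisions are calibrated to realistic log-relative-risk magnitudes:
$\tau_u = 10$ and $\tau_v = 20$ give spatial fields with standard
deviation ≈ 0.15–0.25, $\tau_\phi = 50$ gives ≈ 0.14, and
$\tau_\gamma = 10^4$ gives an RW2 field of ≈ 0.3 over 72 months. The
RW2 value looks large only because the marginal variance of a
second-order random walk at fixed precision grows roughly cubically
with the window length; users changing `T_months` drastically should
rescale it.

What the generator deliberately does **not** emulate: the free-text
descriptor vocabulary of 311 exports, reporting-behaviour covariates,
sociodemographic structure, or any dependence of reporting propensity on
the latent risk. Passing tests therefore demonstrate that the estimators
recover the *statistical* structure they target, not that administrative
complaint data are an unbiased measure of infestation.

# Numerical choices and degenerate inputs

* OLS uses QR, never explicit normal-equation inversion; rank
  deficiency is reported with the names of the collinear columns.
* Eigenvalues below `1e-10 * max(eigenvalue)` are treated as null-space
  directions in GMRF sampling.
* DIC requires at least 10 retained draws; a negative $p_D$ is reported
  with a warning rather than silenced.
* Isolated areas (degree zero) form their own graph component and have
  their structured spatial effect pinned to zero by the per-component
  constraint; this is logged.
* With fewer than 4 periods an RW2 penalty has no second differences;
  `rw2_structure()` refuses to build it, the model fit requires
  $T \ge 4$, and the log-posterior evaluator treats the structured
  temporal prior as vacuous (zero structure, generalized rank 0) on
  shorter toy panels.
* Dates are truncated to calendar months as printed (administrative
  exports carry local dates; no timezone arithmetic). Population
  estimates for uncovered years use the nearest available estimate year,
  logged, with no interpolation.
* Keyword extraction is case-insensitive substring matching with a
  configurable set (default "bed bug", "bedbug", "bed bugs"); the exact
  production vocabulary of 311 descriptors is not reproducible from the
  public record, so the filter logs the matched keyword and field per
  record to keep any chosen set auditable.

# Problem sizes

The test suite and the reproduction script run at desk scale, chosen so
the whole suite completes in well under a minute of sampling: recovery
and coverage checks use a 6×6 lattice over 24 periods with chains of a
few thousand sweeps; selection-consistency checks use a 4×4 lattice over
6 periods with ten seeded replicates; the GMRF covariance check uses
20,000 exact draws on a 3×3 grid; the prior-calibration check uses
50,000 Gibbs draws on a 2-area lattice. These sizes are the package's
own choices for a laptop-scale demonstration; all estimators scale to a
few hundred areas.

# Known limitations

* The trend test uses iid-error OLS inference; monthly residuals are
  mildly autocorrelated in real series.
* Queen contiguity from polygons is vertex-based and misses edge-interior
  contact between polygons that do not share vertices; topologically
  clean administrative boundary files share vertices, but simplified or
  re-digitized geometries may not.
* The sampler is single-site and will mix slowly on very large lattices
  or under extreme posterior correlation; the selection and coverage
  guarantees in the test suite are established at the scales stated
  above.
* Relative-risk maps inherit the ambiguity described earlier; both
  surfaces are always exported and neither is asserted as "the" risk
  map.
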