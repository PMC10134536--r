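---
title: "Co-data adaptive penalties: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-data adaptive penalties: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

High-dimensional regression (p ≫ n) needs regularisation, and ordinary
ridge or elastic-net penalties treat all variables as exchangeable.  In
genomics that assumption is often wrong: external p-values, correlations
between molecular layers, or pathway memberships — *co-data*, information
on the variables rather than the samples — frequently predict which
variables carry larger effects.  `codapen` exploits this by giving every
variable its own ridge penalty, learned from the co-data.

# Model

The response follows a GLM or Cox model with canonical link,
$E(Y_i) = g^{-1}(X_i\beta)$, and the coefficients carry independent
normal priors $\beta_k \sim N(0, v_k)$ with

$$ v_k \;=\; \tau^2_{global}\,\sum_{d=1}^D w_d\, Z_k^{(d)}\gamma^{(d)}, $$

so the prior variance — inversely proportional to the ridge penalty — is
a regression on the co-data.  Per source the co-data model is

* **linear**: $v = Z\gamma$ (include a constant column in $Z$ if an
  intercept is wanted);
* **additive (GAM)**: each co-data variable is expanded in a B-spline
  basis, $v = \sum_g \Phi_g\gamma_g$, with a quadratic difference
  penalty $\lambda_g\,\gamma_g^\top S_g\gamma_g$ on adjacent spline
  coefficients (p-splines);
* **shape-constrained additive (SCAM)**: the additive model with linear
  inequality constraints $M\gamma \le 0$ on the spline coefficients —
  positivity constrains the coefficients themselves, monotonicity their
  first differences, convexity/concavity their second differences, and
  shapes combine by stacking rows.

# Estimation

Everything rests on an initial constant-ridge fit.  Its penalty
$\tilde\lambda$ is chosen by 10-fold cross-validated deviance over a
21-point log-spaced grid spanning $10^{-2}p$ to $10^{4}p$ (per-fold Gram
matrices make the sweep an $O(n^3)$ operation per fold).  The fit
provides $\tilde\beta$, the IRLS weight diagonal $W$ (constant
$1/\hat\sigma^2$ for gaussian, $\hat p_i(1-\hat p_i)$ for binomial, the
diagonal of the Breslow partial-likelihood information for Cox) and the
weighted-scale ridge level $\tilde\Omega$.

Equating theoretical to empirical second moments of $\tilde\beta$ gives a
linear system of p equations in the co-data coefficients:

$$ (C\circ C)\,Z\,\gamma = \tilde\beta^{.2} - \tilde v, \qquad
   C = (X^\top WX+\tilde\Omega)^{-1}X^\top WX, $$

with $\tilde v$ the sampling variance of $\tilde\beta$.  $C$ is $p\times
p$ but factors as $U^\top K^{-1}U$ with $U = W^{1/2}X$ and $K = UU^\top +
\tilde\omega I_n$, so the transformed design $(C\circ C)Z$ and
$\tilde v = (\mathrm{diag}(C)-\mathrm{diag}(C^2))/\tilde\omega$ are
accumulated per block of rows (default 500) without ever holding $C$:
peak additional memory is O(block × p + pG + np).

The stages then run sequentially: (1) the global scale from the
degenerate one-group system ($Z = 1_p$); (2) per-source co-data
coefficients — a least-squares solve (minimum-norm under rank
deficiency), a penalised solve for the additive model, or a convex
quadratic program (`pracma::lsqlincon` on quadprog) for the
shape-constrained model; (3) non-negative least-squares source weights;
(4) assembly of $\hat v$ with truncation at zero and a final scalar
least-squares rescale against the moment system, reported as
$\tau^2_{global}$; (5) a final weighted-ridge refit.

**Smoothing penalties** are estimated per co-data variable by random
half/half splits of the samples: coefficients fitted on one half's moment
system are scored on the other half's, the split-averaged score is
minimised over $\log_{10}\lambda \in [-8, 8]$ by Brent's method, and the
splits are seeded (default 10 splits).  This is the only smoothing-
penalty route implemented; joint multi-penalty REML estimation is out of
scope.

## Penalty anchoring

The moment estimates determine the prior variances on an absolute scale,
which is what the recovery diagnostics report.  For the final fit,
however, the package anchors the *global penalty level* to the
cross-validated constant ridge: the floored variances are normalised to
mean one and scaled by $1/\tilde\lambda$.  Two reasons: the
cross-validated level is a more robust estimate of overall signal than
the moment-based scalar, and it makes the degenerate case exact — with
constant co-data the adaptive fit reproduces the co-data agnostic
cross-validated ridge coefficient-for-coefficient, so co-data can only
reallocate penalisation, never silently change the overall level.

## Numerical choices

* IRLS/Newton: relative $L_\infty$ change $< 10^{-8}$, 100-iteration
  cap, step halving so the penalised log-likelihood never decreases;
  binomial weights floored at $10^{-10}$.
* $p>n$ ridge systems are solved through the n × n dual (Woodbury) form;
  the unpenalised intercept is profiled out by weighted centring, and
  excluded from the moment equations.
* Prior-variance floor: $\hat v_k < 10^{-6}\cdot\mathrm{median}(\hat
  v_+)$ is raised to that floor, capping the penalty rather than letting
  it diverge; floored variables are counted in the fit report.
* Rank-deficient co-data designs give the minimum-norm solution with a
  warning.  With several spline-expanded co-data variables in one source
  the coefficient system is always rank-deficient (each basis sums to
  one), but the fitted variances are unique.
* Spline bases use the p-spline convention: equally spaced knots
  extended `degree` intervals beyond the observed range, cubic degree,
  J = 20 basis functions and a second-order difference penalty by
  default.  With equally spaced knots the null space of the second-order
  penalty maps exactly onto affine functions of the co-data, so heavy
  smoothing degenerates to the linear co-data model — the property that
  makes the additive model a strict generalisation.  Clamped (replicated
  boundary) knots would break this exactness near the boundaries, which
  is why they are not used.
* The shape-constrained QP re-derives its multipliers to check
  stationarity; constraint violations above $10^{-8}$ warn.
* The elastic-net prior variance for $0<\alpha<1$ is computed by
  adaptive quadrature of the (shifted, rescaled) gaussian-tail integrals
  of the density $\propto \exp(-\lambda(\alpha|\beta| +
  (1-\alpha)\beta^2/2))$; the transform $h^{-1}$ uses closed forms at
  $\alpha\in\{0,1\}$ ($1/v$ and $\sqrt{2/v}$) and monotone root finding
  otherwise.  Conventions: $h(\lambda)=1/\lambda$ at $\alpha=0$,
  $h(\lambda)=2/\lambda^2$ at $\alpha=1$.
* The sparse fit is cyclic coordinate descent with soft-thresholding and
  per-variable penalty factors (gaussian and binomial families),
  converged at max coefficient change $< 10^{-7}$, 5000-sweep cap.

## Open design points, resolved

* The global scale is estimated through the same one-group moment solve
  as the per-source coefficients (one code path), and a single final
  scalar rescale after truncation/blending re-satisfies the intercept
  moment equation; no iterative re-estimation loop is performed, matching
  the sequential scheme.
* Sources are estimated independently against the full right-hand side
  and blended once by NNLS; with several co-data variables inside one
  shape-constrained source the solve is joint (stacked basis,
  block-diagonal penalty, stacked constraints).
* The sparse refit re-estimates the intercept.

# The synthetic-data generator

`sim_design()` / `simulate_dataset()` emulate the benchmark designs: a
uniform co-data score per variable, true prior variances following a
constant, linear, convex or two-level monotone relation, coefficients
drawn from the implied normal prior, standard normal X, gaussian or
logistic-Bernoulli response, and a paired test set.  "Random" co-data is
the informative co-data permuted after the coefficients are drawn.  For
sparse designs a stated fraction of coefficients is set exactly to zero;
under informative co-data the non-zero probability increases with the
co-data score (the co-data inform both where effects are and how large
they are) with mean matching the stated sparsity.  The exact functional
forms are representative stand-ins chosen once — effect-size scales
(e.g. a 0.01–0.11 prior-variance range over the score) put the ridge fit
in a regime where co-data matter but do not trivialise the problem.

What the generator does *not* emulate: correlated designs (LD blocks,
co-expression), heavy-tailed or heteroscedastic noise, co-data measured
with error, and multiple dependent co-data sources.  Passing benchmarks
therefore demonstrate correctness of the estimator under its own
generative model and qualitative orderings (informative beats permuted
co-data; adaptive selection beats uniform selection at matched size),
not performance guarantees on real data.

Default benchmark sizes (n = 150, p = 1000, 20–25 replicates) are the
package's desk-scale choice: large enough that p ≫ n and the moment
system is informative, small enough that the full harness runs in
minutes.  All replicate seeds derive from (design seed, replicate index),
so results are reproducible in any execution order.

# Limitations

* The Cox family supports the adaptive-ridge path (Breslow ties,
  diagonal information as IRLS weights) but not the sparse transform.
* Moment estimation is a method-of-moments procedure: negative fitted
  variances are truncated, and with very weak signal the estimator
  degrades gracefully to the co-data agnostic ridge (the fallback is
  flagged in the report) rather than failing.
* Modality-specific scaling factors for multi-modal X, hierarchical
  group shrinkage, and posterior-based selection are out of scope.
* The interface is the R package itself (plus a thin YAML-driven
  command-line wrapper in `inst/cli/`); there is no GUI or service.
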