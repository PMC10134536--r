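# codapen — co-data adaptive penalties for high-dimensional regression

`codapen` fits generalised linear and Cox models to high-dimensional data
(p ≫ n) with **variable-specific ridge penalties adapted to co-data**:
complementary information on the *variables* rather than the samples, such
as external p-values, mRNA–copy-number correlations, or group memberships.
When such co-data predict effect sizes, adapting the penalties to them
improves both prediction and variable selection over a single global
penalty.  The package targets statisticians and computational biologists
working with omics-scale regression problems.

## The model

Responses follow a GLM (or Cox model) with canonical link g,

    Y_i | X_i, β  ~  π(Y_i | X_i, β),    E(Y_i) = g⁻¹(X_i β),

and each coefficient carries a normal prior whose variance is regressed on
the co-data matrices Z⁽ᵈ⁾ (p × G_d):

    β_k ~ N(0, v_k),    v_k = τ²_global Σ_d w_d Z_k⁽ᵈ⁾ γ⁽ᵈ⁾ .

Three co-data models are available per source: **linear** (v = Zγ),
**generalised additive** (each co-data variable expanded in a p-spline
basis Φ with a difference penalty λ γᵀSγ), and **shape-constrained
additive** (the spline coefficients additionally satisfy positivity,
monotonicity and/or convexity constraints M γ ≤ 0).

The co-data coefficients are estimated by **empirical Bayes moment
estimation**.  Equating theoretical to empirical second moments of an
initial constant-ridge estimate β̃ yields the linear system

    (C ∘ C) Z γ = β̃·² − ṽ,     C = (XᵀWX + Ω̃)⁻¹ XᵀWX,

with W the IRLS weight diagonal, Ω̃ the initial ridge level and ṽ the
sampling variance of β̃.  C is p × p but never materialised: it factors
through an n × n system and the transformed design is accumulated per
block of rows, so memory grows sub-quadratically in p.  The system is
solved as-is (linear), under a smoothing penalty whose level is chosen by
random sample splits with Brent's method (additive), or as a quadratic
program under shape constraints (shape-constrained additive).  Multiple
co-data sources are blended with non-negative least-squares weights.

For variable selection, each fitted prior variance v̂_k is mapped through
the prior **variance function** h of an elastic-net prior,
λ̂_k = h⁻¹(v̂_k), and the model is refitted with variable-specific
elastic-net penalties by cyclic coordinate descent, yielding exact zeros.

## Worked example

```r
library(codapen)
set.seed(7)
n <- 100; p <- 500
z <- runif(p)                          # co-data: one continuous score
beta0 <- rnorm(p, 0, sqrt(0.01 + 0.1 * z))
x <- matrix(rnorm(n * p), n, p)
y <- drop(x %*% beta0) + rnorm(n)

fit <- codapen(x, y, codata_source(cbind(1, z)), family = "gaussian",
               seed = 1)
fit
#> <codapen> co-data adaptive gaussian ridge fit
#>   n = 100 , p = 500 , 1 co-data source(s)
#>   tau2_global = 1 ; source weights: 1

round(fit$prior$sources[[1]]$gamma, 4)
#> [1] 0.0186 0.0676
```

The fitted co-data coefficients (0.019, 0.068) recover the sign and
rough scale of the true intercept/slope (0.01, 0.1) of the
prior-variance relation from a single draw at n = 100 — averaging over
replicates tightens this considerably (see the simulation harness);
`tau2_global = 1` indicates the assembled variances needed no further
rescaling (exact for a single untruncated source).
`fit$penalties` holds the per-variable ridge penalties (smaller for
variables with larger co-data score), `predict(fit, xnew)` predicts, and

```r
sparse <- sparsify_fit(fit, codapen_data(x, y), alpha = 0.5)
select_variables(sparse)$count
#> [1] 136
```

transforms the adaptive ridge penalties to elastic-net penalties and
selects 136 of the 500 variables.  `prior_variance_curve(fit)` returns the
fitted v̂(z) curve for plotting; `write_fit_report(fit, "report.json")`
serialises all stage estimates.

Spline-based co-data models are declared the same way:
`codata_source(z, "gam", n_basis = 20)` or
`codata_source(z, "scam", shapes = c("positive", "monotone_increasing"))`.

A thin command-line wrapper (`inst/cli/codapen.R`) drives the same
workflows from YAML configurations: `fit`, `simulate`, `predict`.

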