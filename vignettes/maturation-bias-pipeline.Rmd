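---
title: "Methods: phylogenetic regression and path analysis of sex-biased maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic regression and path analysis of sex-biased maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matbias)
```

## The scientific problem

Across bird species the sexes often mature at different ages. `matbias`
implements a comparative pipeline for asking *why*: whether the sex under
stronger sexual selection (more polygamous, larger) matures later, whether
the adult sex ratio (ASR) — the social environment a maturing individual
faces — shapes that bias, and which causal structure among these variables
the interspecific data support. Species are not independent data points:
close relatives resemble each other, so every regression in the pipeline
is phylogenetic.

## Derived variables

All sex-bias variables are built so that zero means "no sex difference"
and the male direction is positive:

* maturation bias = log10(male age at maturation / female age), ages in
  months;
* SSD = log10(male adult mass / female adult mass), masses in grams;
* polygamy bias = mean male polygamy score − mean female polygamy score,
  each score on a 0–4 frequency scale, so the range is [−4, 4];
* ASR = males / (males + females) among adults; several estimates for a
  species are averaged **on the proportion scale** and the mean is then
  arcsine-square-root transformed. The order matters: because
  asin(sqrt(p)) + asin(sqrt(1 − p)) = π/2, transforming first and
  averaging afterwards can coincide with the correct order for estimates
  symmetric about 0.5 and silently diverge otherwise.

Life-history confounds are the log10 sex-mean body mass, the log10 male /
female adult mortality ratio, and chick developmental mode as a
three-level factor (altricial / semi / precocial, reference altricial,
entering design matrices as two indicator columns). Missing inputs
propagate to missing derived values; each model is then fitted on the
complete cases of its own variable set, so different models legitimately
have different n. The maturation-bias census (`maturation_bias_census()`)
counts species with an exactly nonzero log-ratio — ages are reported at
month resolution, so no numerical tolerance is applied.

## PGLS with maximum-likelihood Pagel's λ

The regression model is y = Xβ + ε with Var(ε) = σ²V(λ), where V is the
Brownian covariance of the tree (shared root-to-MRCA path lengths;
diagonal = root-to-tip depths) and V(λ) multiplies the off-diagonals by
λ ∈ [0, 1]. λ is profiled by maximizing the Gaussian log-likelihood with
`optimise()` on [0, 1] (tolerance 1e-6), with both endpoints evaluated
explicitly because a bounded golden-section search can otherwise miss a
boundary maximum. λ values above 1 are not searched: they are rarely
interpretable and push V(λ) toward indefiniteness.

Numerically, each likelihood evaluation whitens the data with the Cholesky
factor of V(λ). For ultrametric trees — where all diagonal entries of V
are equal to the height h — V(λ) = λV + (1 − λ)hI shares the eigenvectors
of V, so one symmetric eigendecomposition serves every λ and each profile
evaluation reduces to a diagonal reweighting. This is an exact
reformulation, not an approximation (the two routes agree to 1e-8 in the
tests), and it is what makes the thousand-replicate simulation checks
cheap. The fast path engages when the relative spread of tip depths is
below 1e-10; anything else takes the general Cholesky route.

Estimation choices, fixed as package defaults:

* σ² is the ML estimate r′V⁻¹r / n; standard errors use σ̂² with
  denominator n (`se_denominator = "residual"` switches to the unbiased
  n − p convention, which rescales SEs by sqrt(n/(n − p)) — at the sample
  sizes involved, ~180 species, the difference is under 1%);
* two-tailed p-values come from the t distribution with n − p df;
* λ is re-estimated inside every fit: per tree in multi-tree runs and per
  regression in the d-separation claims.

On a star phylogeny all off-diagonals of V are zero, V(λ) does not depend
on λ, and the profile likelihood is flat; `profile_lambda_ml()` then
returns λ = 0 with `flat_lambda = TRUE` rather than an arbitrary interior
point.

Predictors (never the response) can be standardized by Gelman's rule —
centered and divided by two standard deviations, binary indicators
centered only — which puts continuous and binary effects on a comparable
scale. A zero-variance column is an error, not a silent no-op.
Collinearity is diagnosed with ordinary (non-phylogenetic) variance
inflation factors, VIF = 1/(1 − R²); PGLS offers no standard VIF, and the
ordinary one answers the relevant design question.

### Multi-tree uncertainty

`multi_tree_pgls()` refits the model on every tree in a sample of
candidate phylogenies and reports, per predictor, the mean slope and mean
two-tailed p with two spread measures: the standard error of the mean
across trees (the headline value) and the raw standard deviation. The SE
of the mean over a large tree sample is tiny by construction; the SD is
the honest measure of phylogenetic uncertainty, which is why both are
emitted. Mean p-values are averaged on the raw p scale.

### The four-step protocol

`run_protocol()` fits ten model families: three bivariate models of
maturation bias on each focal predictor, the three again with the
life-history confounds, two additive models (polygamy bias + ASR, SSD +
ASR), and the two additive models with confounds. Polygamy bias and SSD
never enter the same model — both index sexual selection and are expected
to be collinear, which would make their joint coefficients uninterpretable.

## Confirmatory path analysis by d-separation

Each causal hypothesis is a DAG over the four focal variables. Its basis
set contains one conditional-independence claim per non-adjacent vertex
pair, conditioned on the union of both vertices' parents. Each claim is
tested by a PGLS of one pair member (the response) on the other plus the
conditioning set; the claim p-value is the two-tailed p of the other pair
member's coefficient. The response is the topologically deeper pair member
(longest directed path from a root); when both sit at equal depth — as SSD
and polygamy bias do in the ASR-driven model — the tie is broken toward
the earlier vertex in the model's declared order. The p-value is not
invariant to that choice in finite samples, which is a known asymmetry of
directional d-separation and the motivation for the nondirectional variant
below.

Model fit is Fisher's C = −2 Σ ln p over the k claims, χ²-distributed with
2k df under the model; claim p-values are floored at 1e-300 so C stays
finite. Models are ranked by CICc = C + 2qn/(n − 1 − q) with q = edges +
vertices (each path coefficient plus one free variance per variable — the
convention that matches the small-sample criterion used in phylogenetic
path analysis; "edges + error variances" conventions exist and give
different q). ΔCICc and Akaike-style weights follow, with Δ > 2 and Δ > 10
conventionally read as acceptable and very strong support for the best
model. A saturated (fully connected) DAG has an empty basis set: C = 0 by
definition and its fit p is reported as 1.

Standardized path coefficients of the best model are PGLS fits of each
child on all its parents with every variable scaled to unit variance
(plain 1-SD scaling here, not Gelman's 2-SD rule, which is reserved for
the regression protocol — the path diagram convention is unit-variance
coefficients); 95% CIs use the normal multiplier 1.96.

### The nondirectional (contrast-based) variant

Because λ̂ in a PGLS depends on which variable is the response, the
directional claims above embed an arbitrary choice. The variant
implemented in `santos_path_fit()` removes it: for each variable, λ is
estimated from an intercept-only model; the tree is λ-rescaled (internal
branches × λ, tip branches extended to preserve depths) and normalized to
unit height; independent contrasts are computed on that variable-specific
tree; and all claim tests and coefficient fits become through-origin
ordinary regressions on the contrasts. The n entering CICc defaults to the
species count (the contrast count n − 1 is available via `n_method`),
keeping the criterion comparable with the directional method. A constant
variable makes λ unidentifiable and is rejected with a clear error, and
the variant requires an ultrametric tree (relative depth spread ≤ 1e-6)
because the unit-tree transform is only defined there.

## The synthetic-data generator

`simulate_path_model()` generates the conditions the analyses assume: a
unit-height pure-birth (Yule) tree, then each DAG vertex in topological
order as the coefficient-weighted sum of its parents plus a λ-structured
Brownian error drawn from N(0, σ²V(λ)). Defaults emulate the empirical
study design: 201 species; the ASR-driven DAG (`model2`); edge
coefficients ±0.5 in standardized units (the sign pattern of the
best-supported empirical model — ASR negative into SSD and polygamy bias,
both positive into maturation bias — with a magnitude chosen as a strong
but realistic interspecific effect; no magnitude is claimed from any
empirical fit); error λ = 0.9, a high phylogenetic signal typical of avian
life-history traits; error σ = 1; and the ASR masked for a random 10% of
species, which leaves ≈181 complete cases for four-variable models, the
sample-size structure of the motivating dataset. These defaults are the
study conditions of the validation suite and are not tuned per test.

`simulate_tree_set()` stands in for a posterior sample of phylogenies:
each tree is the base topology after a Poisson(jitter × n) number of
random NNI moves, re-equipped with ultrametric branch lengths (Grafen node
ages jittered on the logit scale of the child/parent age ratio, so ages
stay ordered) and normalized to unit height.

What the generator deliberately does **not** emulate: birth–death
extinction dynamics or calibrated node ages; polygamy as a discrete 0–4
score (traits are continuous; the score scale matters for data curation,
not for the linear model); phylogenetic structure in developmental mode
(sampled independently); correlated missingness (ASR gaps are missing
completely at random, whereas real ASR availability plausibly correlates
with how well-studied a species is). Passing recovery tests therefore show
the estimators work under the model's own assumptions — they cannot show
robustness to the ways real data violate them.

## Validation design and problem sizes

The test suite checks three layers, in increasing strength:

1. **Algebraic identities** (exact): GLS = OLS at identity covariance; the
   two-tip contrast closed form; covariance equivalence of the λ branch
   transform (≤ 1e-8); basis-set size = C(|V|, 2) − |E|; weights summing
   to 1; PGLS at λ = 1 equal to through-origin contrast regression.
2. **Independent oracles**: brute-force path-sum covariance; explicit
   (X′V⁻¹X)⁻¹X′V⁻¹y inversion; `nlme::gls` with `ape::corPagel` for β and
   λ̂; direct 1/(1 − R²) for VIF.
3. **Simulation recovery at study scale**: λ̂ median within 0.1 of truth at
   n = 200 (25 replicates per λ ∈ {0, 0.5, 1}); type-I error of the
   two-tailed PGLS test within [0.03, 0.07] over 1000 null replicates at
   n = 180; the generative DAG selected as lowest CICc, and its four
   coefficient signs recovered, across 100 replicates at n = 180. The
   replicate counts are chosen so Monte-Carlo error is small relative to
   each acceptance band while the whole suite stays fast enough to run
   routinely; the eigendecomposition fast path is what makes these sizes
   cheap.

## Known limitations

* λ is bounded at 1; data truly exceeding Brownian covariance will pile up
  at the boundary rather than estimate λ > 1.
* The d-separation claim p-values depend on the response choice within a
  claim; the tie-break is deterministic and documented, and the
  nondirectional variant is the principled alternative.
* Mean p across trees is a descriptive summary, not a combined test.
* CICc weights compare only the models supplied; they say nothing about
  structures outside the candidate set.
* Zero-length internal branches are tolerated but make sister species
  exchangeable; strict reading rejects the polytomies that would result
  from collapsing them, and no automatic collapsing is performed.
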