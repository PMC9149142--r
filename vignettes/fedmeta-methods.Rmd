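---
title: "Methods: federated negative-symptom meta-analysis"
author: "fedmeta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated negative-symptom meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`fedmeta` implements the summary-statistic federation pattern for
multi-site analyses of SANS negative-symptom ratings. The statistical
model has three layers.

**Within site.** Subjects are scored from their 25 item ratings: the
Total (a sum over the model's 20-item set), five factor scores
(equal-weight means of each factor's items, so factors of different sizes
share the 0–5 item scale), and two composites, MAP over
(Anhedonia, Asociality, Avolition) and EXP over (Blunted Affect, Alogia),
equal-weight by default. For each outcome the site computes Cohen's d,
female minus male, standardized by the pooled SD, with the conventional
large-sample sampling variance
$v = \tfrac{n_M+n_F}{n_M n_F} + \tfrac{d^2}{2(n_M+n_F)}$. The F − M
direction is a fixed convention: male-more-severe findings appear as
negative d. No Hedges small-sample correction is applied by default
(`correct = TRUE` enables it), because the released quantity is defined
as Cohen's d; the correction matters at the ~3% level at these site
sizes and is discussed under limitations.

**Between sites.** The aggregator assumes the normal–normal
random-effects model $d_i \sim N(\theta_i, v_i)$,
$\theta_i \sim N(\theta, \tau^2)$. The default estimator of $\tau^2$ is
DerSimonian–Laird — closed-form, hand-checkable, computed from
fixed-effect weights and truncated at zero — with REML available
(`estimator = "REML"`) to mirror the default of mainstream meta-analysis
software. Inference is plain Wald: $z = \hat\theta/SE$, two-sided normal
p, CI with critical value 1.959964; no Knapp–Hartung adjustment.
Heterogeneity is reported as Cochran's Q and
$I^2 = 100\max(0,(Q-(k-1))/Q)$.

**Federation contract.** "Decentralization" is simulated in-process: site
computations run against a vault that logs every table access (so
isolation is auditable, not just asserted), and the only thing a site may
emit is a message whose payload passes a structural privacy audit —
exactly the flat 8-row table of `(outcome, d, v, n_M, n_F)`, or the
pinned sufficient-statistic/gradient shapes in regression mode. Any extra
component, attribute, or atomic vector whose length matches the site's
record count aborts the protocol. The audit is schema-based rather than a
bare "length equals n" scan because a site with exactly eight records
would otherwise false-positive on its own legitimate payload. Group
counts below the `min_cell` threshold are hard errors; counts below 5
draw a disclosure warning. The default `min_cell = 1` is deliberate: the
published consortium itself contains a site with a single female subject,
and refusing such sites by default would silently change the analysis.

# Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `estimator` | `"DL"` | between-site variance estimator (`"DL"`/`"REML"`) |
| `level` | 0.95 | Wald confidence level |
| `policy` | `"error"` | missing-item handling: `error`, `drop`, `prorate` |
| `min_cell` | 1 | smallest tolerated gender cell in a released payload |
| `dp_epsilon` | off | Laplace privacy budget; noise scale = sensitivity/ε |
| `correct` | `FALSE` | Hedges small-sample correction of d |
| outlier `threshold` | 3 | flag when \|d_i − d̂\|/√(v_i+τ²) exceeds it |

The factor structure itself is configuration, not fact: the published
two- and five-factor solutions do not pin item memberships or composite
weights, so the package ships one pinned, documented convention
(subscales 1–7 → Blunted Affect, 9–12 → Alogia, 14–16 → Avolition,
18–19 → Anhedonia, 20–21 → Asociality; the five global ratings excluded
from factors and from the 20-item Total; equal weights throughout),
echoed into every results document and overridable via
`factor_model()` / `composite_weights()` or a config file. Factor scores
are weighted means rather than sums so that effect sizes are comparable
across factors with different item counts.

# The synthetic generator

The generator's defaults are the published seven-site consortium: exact
per-site gender counts (N summing to 187 — the companion text reports
185, a discrepancy the package follows Table-side and does not resolve),
and uniform age / duration-of-illness draws within the published ranges
(cosmetic covariates; the pipeline regresses on gender only by default).

Severity is generated latently. Each subject carries a shared severity
random effect $u \sim N(0, \sigma_{subject}^2)$ common to all factors —
SANS domains correlate strongly within a person, and this term is what
makes composite effects behave sensibly. Each factor's latent level is

$$L_f = \mu_f + \mathrm{shift}_f + u + \delta_f\, s_f\, \mathbf{1}[F],
\qquad s_f = \sqrt{\sigma_{subject}^2 + \sigma_{item}^2/m_f},$$

items are $L_f + N(0, \sigma_{item}^2)$, and site shifts are
$N(0, \tau^2)$ per site and factor. The $\delta_f s_f$ scaling calibrates
the population Cohen's d of factor $f$'s score to exactly $\delta_f$ when
clipping is off. Composites and the Total mix factors with different
noise contributions, so their implied population d deviates from the
component $\delta$ by roughly 1% at the defaults; `true_effects()`
returns the exact analytic values and is the truth reference in recovery
and coverage studies. Defaults $\sigma_{subject} = 1.0$ and
$\sigma_{item} = 0.5$ (item-scale units) were fixed once on realism
grounds — subject heterogeneity of about one rating point, rater scatter
of about half a point — and with $\mu_f = 1.0$ they land clipped SANS
Totals in the published per-site ranges.

Two modes matter. The default `clip = TRUE` rounds items to integers on
0–5, which is what real data look like but attenuates injected effects
(documented and tested); estimator studies therefore run `clip = FALSE`,
where the calibration is exact. Per-site seeds derive from the master
seed by a counter scheme, so adding a site never perturbs the existing
ones.

What passing tests do **not** show about real data: items within a factor
are exchangeable here (no item-specific difficulty), the latent structure
is one severity factor plus independent item noise (no cross-loading, no
ordinal threshold model), and missingness only occurs if injected.
Recovery of $\delta$ under this generator demonstrates estimator
correctness, not robustness to violations of the scoring model.

# Numerical choices

- **REML.** $\hat\tau^2_{REML}$ is found by safeguarded bisection on the
  restricted score: return 0 if the score at 0 is non-positive, else
  bracket by doubling and bisect to `tol = 1e-10` (cap `max_iter = 100`,
  exceeded → convergence error reporting the last iterate). Fisher
  scoring with the expected information was tried first and oscillated
  slowly on small, unbalanced instances where the realized curvature is
  far from its expectation; bisection is monotone and deterministic. The
  estimator is verified against a dense grid search of the restricted
  likelihood and against an independent implementation.
- **Degenerate inputs.** A site missing a gender errors as a degenerate
  design; pooled SD of 0 errors as zero-variance; a single subject in one
  group is allowed (df ≥ 1) but flagged. k = 1 consortia are legal:
  Q = 0, τ² = 0, pooled = the site effect.
- **Reporting precision.** Tables round half-away-from-zero to 2 dp,
  switching to 3 dp when |x| < 0.05, echoing how such results are
  conventionally printed; full precision is kept internally and in the
  JSON results document (which round-trips numerically).
- **Gradient federation.** Fixed step 1/L with L the trace of the pooled
  per-observation curvature, obtained in one preliminary round of
  per-site `diag(X'X)`; age, when used, is standardized with pooled
  moments from a moment round so the fit equals the centralized one
  exactly. Sufficient-statistics mode is the exact reference the gradient
  mode must converge to.

# Relation to the published table

Printed (d, SE) pairs from the published consortium table are inputs, in
two roles. First, the Wald arithmetic: cells consistent with their
2-dp-rounded inputs (Total bounds, EXP lower, Blunted Affect lower,
Avolition bounds, Anhedonia lower bound and z) are reproduced exactly by
the package's CI operation; the remaining cells were evidently computed
from unrounded internals (e.g. the Alogia lower bound printed at 3 dp)
and are demonstrably unreachable from the printed inputs — the package
documents this rather than targeting them. Second, since the underlying
subject-level data are not public, the published five-factor d values act
as simulation ground truth in the generator's "paper-like" configuration,
never as recomputable results.

# Problem sizes

The recovery and coverage studies use 2,000 replicate consortia at the
published profiles (clip off, τ = 0, expressiveness components at
−0.39); federated-vs-centralized equivalence sweeps 100 random consortia
of up to 10 sites; estimator oracles run 1,000 (DL) and 100 (REML, grid
step 1e-4) random instances; the regression equivalence sweeps 500 random
tables. These sizes put Monte-Carlo error well below the bands being
checked while keeping a full test run in a few minutes.

# Known limitations

- Cohen's d is released uncorrected, so per-site estimates carry the
  ~2–6% small-sample inflation at these df; pooling partially offsets it
  because larger |d| draws larger v and smaller weight. The recovery
  study's observed net bias is well under the 0.02 acceptance band.
- At τ = 0 the DL estimate is truncated at zero, which inflates the mean
  model SE ~9–10% above the empirical SD of the pooled effect at k = 7
  and produces mild over-coverage (~96–97% for nominal 95%). This is a
  known property of DL at the homogeneous boundary, not an implementation
  artifact.
- Covariate-adjusted standardized effects are out of scope: the variance
  formula used is the two-group form, and the pipeline regresses on
  gender only (the regression mode reserves an age slot for the federated
  algebra, not for adjusted d).
- No meta-regression, mega-analysis, or publication-bias diagnostics; no
  real networking or authentication — the contract that only audited
  messages cross the boundary is what is implemented and tested.
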