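---
title: "Modelling HIV-prevention service engagement from injection-network exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HIV-prevention service engagement from injection-network exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

People who inject drugs (PWID) engage with HIV prevention services — HIV
testing, medication for opioid use disorder (MOUD) and syringe services —
at rates shaped not only by their own circumstances but by the behaviour of
the people they inject with. When a cohort is recruited through coupon
referral and duplicate recruits are resolved biometrically, the resulting
data are *sociometric*: we observe the whole web of injecting partnerships,
direct and indirect, rather than each participant's self-reported contacts
in isolation. `netmmm` implements the analysis toolchain for such cohorts:

1. assembly of the deduplicated, reciprocal partnership network from coupon
   records;
2. construction of ego-level *network exposures* — indicators that at least
   one (or the proportion of) network peers in a given scope carry an
   attribute;
3. three model families relating exposures to individual service use:
   multilevel multiple-membership logistic models (MMMM), cross-classified
   dyad-level logistic models with effect modification, and egocentric
   logistic models with covariate screening;
4. a synthetic-cohort generator that emulates the recruitment process and
   provides a mechanistic outcome model with known coefficients, so every
   estimator in the package can be exercised end-to-end and checked by
   parameter recovery.

# Network assembly and exposure construction

Every returned coupon defines an (issuer, redeemer) injecting partnership.
Linkages are assumed reciprocal, so the graph is undirected; repeated and
reciprocal coupons between the same pair collapse to a single edge, and a
coupon redeemed by an already-enrolled participant adds a cross-network
edge without a new node. Unreturned coupons contribute nothing.

Distances count edges on this deduplicated graph: a direct injecting
partner is at path length 1, and peers at path length $\le 3$ form the
*socially proximal* ego-network. The direct-tie-excluded window (distance
2–3) isolates purely indirect exposure and is used as a sensitivity
analysis. Proximity never crosses connected components.

An exposure aggregates a binary alter attribute over a scope. The primary
parameterization is *any* ($\ge 1$ versus $0$ exposed peers); the
*proportion* parameterization (positives over peers with a non-missing
value) is the sensitivity variant. Peers missing the attribute are removed
from numerator and denominator rather than treated as unexposed; an ego
whose every in-scope peer is missing the attribute gets a missing exposure
and falls out of that model under the complete-case policy. This choice
avoids biasing the *any* indicator downward at the cost of a slightly
smaller analysis set, and each such ego is identifiable from the logged
drop counts.

# The multiple-membership model

Classical multilevel models require each observation to belong to exactly
one higher-level unit. In a sociometric network an ego belongs
simultaneously to every partner's sphere of influence, so the model makes
each ego a *fractional member* of all its direct partners' units:

$$
\mathrm{logit}\,P(y_i = 1) \;=\; x_i'\beta \;+\;
\sum_{j \in \mathrm{alters}(i)} w_{ij}\, u_j,
\qquad u_j \sim \mathcal N(0, \sigma_u^2),
$$

with weights inversely proportional to the ego's number of injecting
partners, $w_{ij} = 1/\mathrm{degree}(i)$, summing to one. Every
participant indexes a random effect $u_j$ because every participant can
appear as a partner in other egos' membership sets — this realizes the
doubled ego/alter representation of each undirected dyad without
duplicating any outcome row (duplicating rows would double-count each
observation's likelihood). Participants excluded from the outcome rows
(for the HIV-testing outcome, the few already aware of an HIV-positive
serostatus) still index a $u_j$ as partners of others.

Fixed effects comprise the network-exposure indicator(s), the a-priori
adjustment set — age, gender (modelled male versus non-male; the raw
three-level category is retained in the data), marital status, education,
and the log number of injecting partners — plus any individual covariate
retained by screening (univariable logistic fit, Wald $p < 0.10$).
Cluster-level covariates are refused with an explanatory error: they are
collinear with the individual-level adjustment set in this design.

## Estimation

The posterior is sampled with an adaptive Metropolis-within-Gibbs kernel
written in C++:

* $\beta$ moves jointly via adaptive Metropolis, warm-started at the
  fixed-effects-only IRLS estimate with its Wald covariance as the
  proposal shape (rescaled by $2.38^2/p$); the global scale is tuned
  toward 23.4% acceptance and the shape is re-estimated once from the
  second half of warmup.
* each attached $u_j$ moves by single-site random walk tuned toward 44%
  acceptance; unattached levels are drawn from their conditional, the
  prior.
* $\sigma_u$ moves on the log scale, and additionally a *joint rescaling
  move* proposes $(\sigma_u, u) \to (c\sigma_u, cu)$. This move travels
  along the funnel-shaped ridge that makes centered parameterizations of
  weakly-identified variance components mix poorly; the Gaussian density
  of $u$ and the transform Jacobian cancel exactly, leaving only the
  likelihood and the $\sigma_u$ prior in the acceptance ratio.

Priors are $\beta \sim \mathcal N(0, 5^2)$ and $\sigma_u \sim$
half-$\mathcal N(2)$ — weakly informative defaults in the tradition of
applied Bayesian regression software; they are configurable and documented
rather than claimed equivalent to any particular historical fit. Four
chains with 1000 warmup and 1000 retained draws are the default; chains
are overdispersed around the IRLS start. Reported adjusted odds ratios are
posterior medians of $e^\beta$ (invariant to the order of transformation
and summary) with 2.5/97.5 percentile intervals; split-chain $\widehat R$
and an autocorrelation-based effective sample size accompany every term,
and a fit with any $\widehat R > 1.05$ is returned flagged rather than
suppressed.

The kernel is validated three ways in the test suite: against a dense-grid
quadrature posterior on a 30-row, two-level membership design (agreement
within Monte-Carlo error); against `lme4::glmer` on the one-partner-per-ego
reduction, where the MMMM collapses to an ordinary two-level
random-intercept model; and against the package's own IRLS engine when
$\sigma_u$ is fixed at zero.

## What recovery experiments show — and their limits

With the generator's mechanistic mode (true exposure log-OR $\log 2$,
$\sigma_u = 0.7$, $n = 2000$), the posterior median of the exposure effect
lands close to truth and 95% credible intervals achieve nominal coverage
across replicates at $n = 500$. Two caveats are worth recording. First,
with a median of two partners per ego, each $u_j$ is informed by very few
observations, so $\sigma_u$ is weakly identified: its posterior is wide
and its median can sit well above or below the generating value on any
single dataset. Second, because the exposure coefficient is conditional on
the random effects, datasets where the $\sigma_u$ posterior sits high also
show a correspondingly inflated conditional log-OR (logistic
non-collapsibility); on top of ordinary sampling noise (SD $\approx 0.07$
at $n = 2000$) this makes single-dataset point recovery a noisier check
than interval coverage, which is the more meaningful calibration property.

# Cross-classified dyad models

Partnership characteristics are reported by the recruiting ego for its
dyads, and the question is whether they *modify* the association between an
ego's service use and the partner's service engagement. One row per unique
characterized dyad:

$$
\mathrm{logit}\,P(y_{ea} = 1) = x_a'\beta + b_f f_e + b_{int} f_e m_{ea}
 + v_e + r_a, \qquad
v_e \sim \mathcal N(0, \sigma_e^2),\; r_a \sim \mathcal N(0, \sigma_a^2),
$$

where $y_{ea}$ is the partner's engagement in the outcome service, $f_e$
indicates the ego used any of the three services in the prior six months,
and $m_{ea}$ is a dichotomized partnership flag: duration over one year,
injecting together more than 15 times in the prior 30 days, or
moderate-to-high trust (trust score $\ge 7$ on the 1–10 scale; 6 and below
is none/low). The two random-intercept classifications are crossed, not
nested — a participant may appear as ego in some rows and partner in
others. Alter-level adjustment covariates are outcome-specific (for
HIV testing: homelessness, HCV-testing history, injection frequency,
injecting at the high-risk venue, recent incarceration; for MOUD and
syringe services, analogous sets including alcohol use and, for syringe
services, depression).

Estimation reuses the same MCMC kernel with two plain random-intercept
terms. Stratum-specific odds ratios are $e^{b_f}$ and $e^{b_f + b_{int}}$,
summarized from the joint draws. Interaction evidence is reported as the
two-sided posterior tail probability $2\min\{P(b_{int}>0),
P(b_{int}<0)\}$ — a Bayesian analogue of, and deliberately not identical
to, a frequentist interaction p-value; it is floored at $2/$(number of
draws), the resolution of the sampler.

# Egocentric models and covariate screening

The egocentric family is ordinary logistic regression of an ego's service
use on its aggregated network exposure, fit by the package's own IRLS
(deviance tolerance $10^{-8}$, 100-iteration cap), with a-priori
adjustment paralleling the MMMM (log ego-network size in place of log
degree for proximal scopes). Candidate covariates are screened
univariably and retained at Wald $p<0.10$; screening is univariable for
determinism, and the a-priori set is always retained regardless.
Complete-case rows are used per model with drop counts logged.

Degenerate small-sample designs are handled explicitly rather than left to
numerical luck: columns that are constant or aliased in the analysis
subset are pruned with a message; a coefficient diverging past 15 on the
logit scale raises a separation error naming the column; and in the
multivariable egocentric fit, a quasi-separated *adjustment* covariate
(for instance the male indicator in a subset whose handful of non-male
participants share one outcome value) is dropped with a message, while
separation in the exposure of interest remains a hard error — an effect
estimate rescued by silently removing its support would be meaningless.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture: its defaults
*are* the study conditions the package is validated under.

* **Recruitment.** Ten seed participants; each enrollee is issued 0–6
  coupons (median 1, mean ≈ 1.4); 75% of coupons are returned; a returned
  coupon is redeemed by an already-enrolled participant with probability
  0.05 (a cross-network linkage, no re-enrolment and no second dyad
  report) and otherwise enrols a new participant, who receives a dyad
  report from the recruiting ego only. With these rates the branching
  process is slightly subcritical, so chains die out before a
  2512-participant target; real coupon studies handle this by handing out
  further coupons without an upper limit until the target is reached, and
  the generator does the same (`reseed = TRUE`): on extinction a random
  enrolled participant receives a fresh batch. With `reseed = FALSE`
  extinction is an error suggesting larger coupon counts. At full scale
  the realized statistics sit on the intended values: ~75% return, median
  degree 2 (IQR 1–3), ≈ 2600–2700 unique dyads, ≈ 94% of dyads carrying an
  ego report, median socially-proximal network of ≈ 10 peers.
* **Attributes.** Drawn at the cohort's marginal prevalences (37.3% HIV
  positive with ~1% serostatus awareness among positives, 65% HCV
  positive, 67% daily injection, 47% non-sterile equipment use, 30%
  homelessness, and so on), with realistic per-field missingness
  (including ~31% missing overdose history, which exercises the
  complete-case machinery). Attributes are independent by default — a
  deliberate simplification; a single latent-risk parameter
  (`latent_risk_sd`) optionally induces positive correlation across the
  risk attributes without hand-tuned copulas. Age is lognormal (median 26,
  IQR ≈ 22–34, floored at 18).
* **Dyad characteristics.** Relationship type, years known (lognormal,
  median 4), trust score (2–10, median 7), injecting frequency together
  (negative binomial, median ≈ 15/30 days) and support items are drawn at
  the observed partnership marginals. The published marginals are
  ego-level ("$\ge 1$ alter such that …"); the generator applies them
  per-dyad, an approximation that preserves per-dyad realism without
  enforcing exact ego-level aggregates. The distributions of the
  ego-reported partner HIV/HCV status fields are not published and were
  fixed once at plausible values (pos/neg/unknown = 0.10/0.30/0.60 and
  0.15/0.25/0.60).
* **Outcomes.** In `marginal` mode the three service outcomes are
  independent draws at their prevalences (14.2% HIV testing among those
  not known-positive, 32.9% MOUD, 13.5% syringe services). In
  `mechanistic` mode the HIV-testing outcome is drawn from the MMMM data
  model itself, $y_i \sim \mathrm{Bern}(\mathrm{logit}^{-1}(x_i'\beta +
  \sum_j w_{ij} u_j))$, with user-specified $\beta$ and $\sigma_u$, the
  ground truth written alongside the data. Exposure terms in the true
  coefficient map must reference non-outcome attributes, since an
  outcome-based exposure would be circular at generation time.

What the generator does **not** emulate: spatial/venue structure, temporal
dynamics of recruitment, attribute homophily along edges, and
degree-assortative recruitment. Passing recovery tests therefore
demonstrate that the estimators are correct under the assumed data model
at realistic size and sparsity — not that the substantive published
associations would replicate, which would require the restricted-access
cohort itself.

# Numerical choices and degenerate inputs

* Membership weights force exact unit row sums (the final weight absorbs
  rounding); normalization is asserted to $10^{-12}$.
* BFS distances are computed on the simplified graph; multiple coupons
  between a pair never inflate degree.
* The IRLS separation guard activates only after the fourth iteration so
  early transients are not mistaken for divergence.
* MCMC chain seeds derive deterministically from the configuration seed;
  the pipeline fans one global seed out to stage seeds via
  $(s \cdot 1000003 + k) \bmod (2^{31}-19)$, keeping every derived seed a
  valid 32-bit integer and each stage independently rerunnable.
* Egos with no injecting partners cannot be assigned membership sets;
  `build_mmmm_design` refuses them, and the pipeline excludes isolates up
  front with a logged count.
* Problem sizes in the automated checks — $n = 2000$ for the headline
  recovery, 20 replicates at $n = 500$ for coverage, 3000 dyads for the
  cross-classified recovery, 200 random graphs for the proximity oracle —
  were chosen so each property is tested at the scale the study design
  implies while the full suite stays comfortably reproducible on a single
  CPU.

# Known limitations

* $\sigma_u$ is weakly identified at median degree 2; its posterior should
  be read as a regularized nuisance, not a substantive estimate.
* The interaction evidence from the cross-classified model is a posterior
  tail probability, not a frequentist p-value; the two agree closely in
  large balanced designs but are not interchangeable.
* Screening at $p<0.10$ is univariable; covariates that matter only
  jointly will be missed, exactly as in the analysis plan it implements.
* The generator's missingness is completely at random; informative
  missingness would require a mechanism the source data do not describe.
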