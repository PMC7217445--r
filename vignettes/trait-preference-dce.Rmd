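---
title: "Eliciting livestock trait preferences with choice experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting livestock trait preferences with choice experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockchoice)
```

## The problem

In smallholder systems without performance or pedigree recording,
breeding objectives cannot be derived from production data. A discrete
choice experiment (DCE) elicits them instead: respondents repeatedly
pick one hypothetical animal from a small set of profiles that differ in
a few traits, and a random-utility model converts those picks into
part-worth utilities per trait. `flockchoice` implements that workflow
around its motivating study system — indigenous sheep in the northwest
Ethiopian highlands, 370 respondents, six binary ram attributes and
seven binary ewe attributes (`ram_attributes()`, `ewe_attributes()`) —
but every stage takes arbitrary two-level attribute sets.

## Design

Attributes are effect-coded (+1/-1), so a part-worth is a symmetric
deviation between the two levels and position constants are not
confounded with trait effects. Because a 64- or 128-profile full
factorial is far beyond what a respondent can process, the design is a
16-run regular fraction of resolution IV, taken from standard
minimum-aberration generator tables (`fractional_factorial()`); the
achieved resolution is verified both from the defining relation and by a
brute-force search for constant column products
(`check_orthogonality()`). Resolution IV means main effects are aliased
only with three-factor and higher interactions, the usual working
assumption for main-effects choice designs.

The 16 profiles are split into four blocks of four
(`assign_blocks()`): each block is one choice situation, shown with an
opt-out (`add_opt_out()`) so nobody is forced to choose. Two design
decisions here were genuinely open:

* **Blocking objective.** How the original study blocked its array is
  not recoverable, so blocking is a seeded randomized search that
  minimizes within-block level imbalance — subject to a hard constraint
  that the conditional-logit information matrix of attributes plus
  position constants (at beta = 0, one situation per block) is
  nonsingular. The constraint matters: with only four distinct
  situations, level-balanced assignments exist in which some part-worths
  are linear combinations of position effects and nothing identifies
  them. A tiny tie-break favors better-conditioned assignments among
  equally balanced ones.
* **Sample-size rule.** The rule of thumb `N > 500 c / (t a)` is
  implemented to return the bound itself when it is an integer
  (`min_sample_size(2, 1, 4)` is 250, the value the rule is normally
  quoted as giving), since the strict reading (251) contradicts how the
  rule is used in practice; the off-by-one ambiguity is documented here.

One terminological ambiguity is resolved as follows: each respondent
answers all four blocks, i.e. four choice situations of four designed
alternatives each, which is what makes 370 respondents yield 1,480
situations before opt-out filtering. The opt-out is modeled as a flagged
pseudo-alternative without attribute codes; since opt-out choices are
rare (fractions of a percent) and carry no trade-off information, the
analysis drops those situations entirely (`drop_opt_outs()`), matching
the bookkeeping that turns 1,480 situations into 1,473/1,474 retained
observations at the study's opt-out rates.

## The choice models

Utility of alternative $i$ for respondent $n$ in situation $t$:

$$U_{int} = \mathrm{asc}_i + x_{int}'\left[\sigma_n \beta + \gamma \eta_n
  + (1-\gamma)\sigma_n \eta_n\right] + \varepsilon_{int},$$

with standard Gumbel $\varepsilon$, taste deviations
$\eta_n \sim N(0, \mathrm{diag}(s^2))$ on a user-chosen subset of
attributes (diagonal covariance: only per-attribute SDs are
interpretable at these sample sizes), and scale
$\sigma_n = \exp(-\tau^2/2 + \tau e_{0n})$. Key conventions:

* **Scale normalization.** $\bar\sigma = -\tau^2/2$ makes
  $E[\sigma_n] = 1$, so $\beta$ keeps its conditional-logit
  interpretation and $\hat\tau$ is comparable across fits. Any other
  normalization rescales $\beta$; this one is stated prominently because
  the interpretation of a reported $\tau$ depends on it.
* **$\gamma$ is fixed, not estimated** (default 0, the standard
  restriction; the full mixing form is implemented so other fixed values
  work). Estimating $\gamma$ is notoriously unstable from a neutral
  start.
* **ASCs are position effects and are not scaled by $\sigma_n$.** The
  utility model applies heterogeneity to the attribute part; intercepts
  absorb presentation-order effects. The simulator and estimator share
  the convention, so simulation-based tests are unaffected by it, but a
  fit to data generated under scaled intercepts would attribute that
  variation to $\tau$.
* **Nonnegativity of $s$ and $\tau$** is handled by estimating them
  unconstrained — the likelihood is symmetric in their signs — and
  reporting absolute values, the standard device that avoids boundary
  kinks; estimates within 1e-3 of zero are flagged as boundary cases.

The simulated likelihood (`fit_gmnl()`) averages each respondent's
product of situation probabilities over $D$ draws common to all
respondents — Halton sequences by default (distinct prime bases, first
100 points discarded, normal quantile map; `make_draws()`), $D = 500$ by
default, a conventional figure at which simulation noise is well below
sampling noise for datasets of this size. Log-sum-exp and log-space
products are used throughout; the likelihood and its analytic gradient
are computed in a compiled kernel and maximized by BFGS from the
conditional-logit solution ($s = \tau = 0.1$), with standard errors from
the finite-difference Hessian of the simulated log-likelihood. Fits are
exactly reproducible given the same seed and draw scheme. The plain-R
simulated probability (`gmnl_probability()`) is kept as a readable
reference and is tested against the kernel, against closed-form logit in
the degenerate cases, and against quadrature for one random coefficient.

The baseline conditional logit (`fit_mnl()`) is its own implementation
(analytic gradient, Newton polish on the analytic information matrix to
a gradient max-norm below 1e-6); an independent stratified
conditional-logistic fit cross-checks it in the tests. The null model
for McFadden's $\rho^2$ is the ASC-only fit, not equal shares: with four
alternatives, published null log-likelihoods of about $-1864$ for 1,473
situations sit far above $-1473\ln 4 \approx -2042$, which only an
ASC-only null can produce.

## The IIA test

`hausman_mcfadden()` drops one alternative (and the situations that
chose it), refits, and forms
$(b_r - b_f)'(V_r - V_f)^{+}(b_r - b_f)$ on the attribute coefficients.
In finite samples $V_r - V_f$ routinely has negative eigenvalues; a
signed pseudo-inverse lets those directions cancel real discrepancies
and makes the test severely undersized (empirically, rejection near 0.01
at nominal 0.05 in this package's calibration setting). The statistic
therefore uses only the positive eigendirections, with degrees of
freedom equal to their count — after which the simulated size is close
to nominal (the acceptance suite checks 500 replicates) and power rises
under strong scale heterogeneity. When negative directions were
projected out the result carries a `non_psd` flag.

## The synthetic-respondent generator

`simulate_choices()` draws from exactly the estimation model above, so
the estimators are testable end to end: per respondent it draws
$\eta_n$ and $\sigma_n$, adds Gumbel noise per alternative, records the
argmax, and independently thins situations into opt-out choices with a
fixed probability (the opt-out is exogenous and utility-free, mirroring
its exclusion from analysis). `preset_truth()` fixes the generating
parameters at the published ram and ewe G-MNL estimates, including their
opt-out rates (0.47% and 0.4% per situation). What the generator does
*not* emulate: attribute non-attendance, lexicographic or fatigued
responding, socio-demographic taste shifters, correlated taste
deviations, and utility-bearing opt-outs. Passing recovery tests
therefore show the estimation machinery is correct and well calibrated
under the model's own assumptions — not that the model is right for any
particular field dataset.

Problem sizes used in the test suite were chosen as the smallest at
which the checks are sharp: recovery runs use 2,000 respondents and
$D = 500$ Halton draws (all parameters within 3 reported SEs of truth;
on data generated without heterogeneity, $\hat\tau$ and the deviation
SDs collapse to zero); size calibration of the IIA test uses 500
replicates of 120 respondents on a 5-attribute, 8-block design — the
4-block survey layouts leave the restricted fit exactly saturated and
so cannot calibrate the test; survey-sized illustrations use 370.

## Ranking indices and descriptives

`rank_index()` implements the weighted rank-preference index with
weights $(4, 3, 2, 1)$ over ranks 1-4, normalized across items; items
never elicited (dashes in a published table) are excluded from the
denominator rather than zero-filled. Because the bundled tables print
proportions to two decimals, recomputed indices can differ from printed
ones by up to about 0.015 — e.g. the manure-source objective recomputes
as 0.155 against a printed 0.16 — so that is the documented reproduction
tolerance. The ram column of the bundled selection-criteria table is
known not to recompute exactly from its printed proportions (its printed
horn index of 0.06 is roughly three times the 0.02 implied by the
proportions), so only the production-objective and ewe columns are used
as reproduction checks. `flock_shares()` turns the flock-composition
table into category shares and the 1:11 breeding ram-to-ewe ratio.

## Pipeline and reproducibility

`run_pipeline()` chains design, simulation, validation, both fits, the
IIA test and the reports from one declarative YAML/JSON config with
explicit seeds for every stochastic stage, writing a manifest with a
config hash and MD5 checksum per artifact; reruns of the same config are
byte-identical. Bundled configs (`inst/extdata/*.yaml`) encode the ram
and ewe study conditions.

## Known limitations

* Only two-level attributes and regular two-level fractions (catalog up
  to 8 attributes); no D-efficient or multi-level designs.
* Diagonal taste covariance; no willingness-to-pay transformation (the
  motivating study has no price attribute); no latent classes; $\gamma$
  fixed rather than estimated.
* The G-MNL Hessian is a finite-difference one; near-boundary SDs make
  Wald SEs for those parameters approximate.
* Published coefficient tables cannot be reproduced numerically without
  the study's raw choice data; what the package reproduces are the
  desk-checkable derived quantities (indices, $\rho^2$, odds ratios,
  sample size, design combinatorics) and, by simulation, the estimator's
  ability to recover known truths.
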