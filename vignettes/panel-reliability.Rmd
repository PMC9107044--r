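---
title: "Generalizability theory for crowdsourced rating panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizability theory for crowdsourced rating panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelgt)
```

## The measurement problem

A physician records spoken responses to three video vignettes depicting a
disclosure of medical error; a panel of raters — trained patient advocates
or untrained crowdsourced laypeople acting as analog patients — scores
each response on six 5-point items (overall quality, accountability,
honesty, sincerity, understanding, caring). The question a program
director cares about is not any single rating but the *score*: is the
mean over items, vignettes and raters a reliable measure of that
physician's communication skill, and how many raters and vignettes does
a reliable measure need?

Generalizability (G) theory answers this by decomposing score variance
into facets. Here the object of measurement is the physician \(p\); the
measurement facets are vignettes \(v\) and raters \(r\). Two designs
arise in practice and are both supported:

* **Crossed** \(p \times v \times r\): every rater scores every
  physician on every vignette (a small dedicated panel). Seven variance
  components: \(\sigma^2_p, \sigma^2_r, \sigma^2_v, \sigma^2_{pr},
  \sigma^2_{pv}, \sigma^2_{rv}, \sigma^2_{res}\).
* **Nested** \((r:p) \times v\): each rater's ratings attach to a single
  physician — the structure induced by crowdsourcing platforms where each
  worker takes one batch. Five components: \(\sigma^2_p, \sigma^2_v,
  \sigma^2_{r:p}, \sigma^2_{pv}, \sigma^2_{res}\). A rater's main effect
  is inseparable from their interaction with "their" physician, which is
  why nested panels need more raters for the same reliability.

The analysis unit throughout is the vignette-level score (the mean of the
six items), so the residual conflates the highest-order interaction with
measurement error; there is no item facet in the decomposition.

## Estimation (G-study)

Estimation is method-of-moments, matching the GENOVA family of tools
that practitioners in this field use, not likelihood-based (REML is an
explicit non-goal; method-of-moments is unbiased before truncation,
assumption-light, and exactly reproducible).

For the crossed design, `estimate_crossed()` computes the seven mean
squares of the three-way random-effects ANOVA without replication and
solves the expected-mean-squares system in closed form, e.g.
\(\hat\sigma^2_{res} = MS_{pvr}\), \(\hat\sigma^2_{pr} = (MS_{pr} -
MS_{res})/n_v\), \(\hat\sigma^2_p = (MS_p - MS_{pr} - MS_{pv} +
MS_{res})/(n_v n_r)\).

For the nested design, rater counts per physician are unequal in real
batch data, so `estimate_nested()` uses analogous ANOVA (Henderson
Method 1): the uncorrected sums of quadratics (T-terms) for the
groupings mean, \(p\), \(v\), \(r{:}p\), \(pv\) and observation are
formed, their expectations are expressed in the five components with
unbalance-aware coefficients
\(\operatorname{coef}(T_G, \sigma^2_c) = \sum_{g \in G} \sum_{\ell}
n_{g\ell}^2 / m_g\)
(counts of observations in group \(g\) at level \(\ell\) of effect
\(c\)), and the resulting \(5 \times 5\) linear system is solved. On
balanced data this reduces exactly to the balanced-nested
expected-mean-squares solution, which the test suite verifies, along
with agreement to an independent quadratic-form (trace-formula) solver
on unbalanced data.

Numerical conventions:

* Negative raw estimates are truncated to zero for reporting and for
  all D-study projection — variances are non-negative, and this is the
  standard G-theory reporting convention. Raw estimates are kept in
  `raw_components` because truncation biases simulation-based
  unbiasedness checks.
* Percentages are truncated components over their sum; a numerically
  zero total (constant data) reports all-zero percentages rather than
  normalizing noise.
* Batch data declared nested (raters spanning several physicians) are
  folded into distinct (rater, physician) pseudo-raters with a warning —
  the only reading under which \((r:p) \times v\) applies to batch
  designs. The rater-to-physician incidence of a batch panel is
  otherwise not representable in this model.

## Projection (D-study)

`g_coefficient()` and `dstudy_grid()` project reliability for
hypothetical panels of \(n'_r\) raters and \(n'_v\) vignettes. Relative
error variance (rank-ordering decisions):

\[
\sigma^2(\delta) =
\frac{\sigma^2_{pr} \text{ or } \sigma^2_{r:p}}{n'_r} +
\frac{\sigma^2_{pv}}{n'_v} + \frac{\sigma^2_{res}}{n'_r n'_v},
\qquad
E\rho^2 = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2(\delta)}.
\]

Absolute error \(\sigma^2(\Delta)\) adds the measurement-facet main
effects (crossed: \(\sigma^2_r/n'_r + \sigma^2_v/n'_v +
\sigma^2_{rv}/(n'_r n'_v)\); nested: \(\sigma^2_v/n'_v\)), giving the
dependability coefficient \(\Phi \le E\rho^2\). The "G coefficient"
reported throughout is the relative \(E\rho^2\): recomputing the
published coefficient grids for both panel designs from their printed
component tables matches under the relative formula and not under the
absolute one, so \(\Phi\) is exposed as a clearly labelled extra.
Projection keeps the G-study's structure — crossed panels project
crossed, nested project nested; cross-design projection is out of scope.

Printed component tables are rounded to three decimals, so coefficients
recomputed from them can differ from originally published values by
about \(\pm 0.01\); the acceptance checks therefore use a \(\pm 0.02\)
band rather than "correcting" either side.

## Rater quality control

Crowdsourced panels are screened before estimation, in a fixed order
chosen to match how such removals are conventionally reported; a rater
failing several rules is attributed to the earliest:

1. **Incomplete** (`filter_incomplete()`): the rater lacks a rating for
   some (assigned physician, required vignette, item).
2. **Low response range** (`filter_low_range()`): the rater's entire
   output uses fewer than 3 distinct values of the 5-point scale —
   "using 2 or fewer response options" is read as straight-lining, the
   inattention signature, rather than as item non-response (which rule 1
   already covers).
3. **Reliability outliers** (`filter_irr_outliers()`): within each task
   group (raters sharing a physician set — the whole panel for a crossed
   design, one batch for a nested one), the panel consistency statistic
   is computed with all raters and leave-one-out per rater; raters whose
   removal raises it by at least 0.1 are removed sequentially, worst
   first, re-evaluating after each removal. Sequential removal avoids
   the over-deletion that simultaneous flagging produces. The statistic
   is pluggable because platforms report different "inter-rater
   reliability" numbers: the default is a Cronbach-type coefficient
   treating raters as items over the group's (physician, vignette, item)
   vectors; mean pairwise inter-rater correlation is the alternative.
   Groups smaller than 3 cannot support leave-one-out evaluation and are
   retained with a warning.

## The synthetic-panel generator

No rating data are distributed with the package, so every stage is
validated against `simulate_panel()`, which draws independent zero-mean
normal random effects per the design's decomposition — the
variance-components model G-theory itself assumes — and sums them into
latent cell scores. Defaults describe the study layout this package was
built around: 20 physicians, 3 vignettes, 6 items; a crossed panel of
8 advocate-style raters (grand mean 3.55 with a −0.36 stringency shift)
or a nested panel of 42 layperson-style raters in batches of 4
physicians assigned round-robin, which yields realistic unequal nest
sizes; default components are the published estimates for each design
(`default_true_components()`).

Item-level structure deserves a note, because the component tables
constrain only vignette-level variance:

* **Item main effects** (`item_effect_sd`, default 0.7): the six items
  probe different constructs and differ systematically in mean. They are
  drawn once per panel and centered to sum to zero, so vignette scores —
  and every variance component — are exactly unaffected.
* **Item noise** (`item_sd`, default 1.0) is carved *out of* the
  configured residual: the cell-level residual effect gets variance
  \(\sigma^2_{res} - \sigma^2_{item}/n_{items}\), so vignette scores
  carry exactly the configured residual for any `item_sd`.

Both defaults were calibrated so that the generator's item-level data
behave like the study's: real multi-construct instruments show item
means spreading by roughly half a scale point and substantial
within-vignette item disagreement, and under these settings the
leave-one-out reliability screen behaves as reported in the motivating
study (a lone injected contrarian is flagged; genuine raters are not).
With weak item structure, per-batch reliability statistics over
4-physician batches are so noisy that the 0.1 leave-one-out threshold
flags genuine raters — worth knowing if you apply the screen to data
whose items barely differ.

* **Discretization**: round-to-nearest then clip to the 1–5 scale —
  the simplest Likert mechanism. It attenuates components (so estimates
  from discretized panels sit slightly below the generating values) but
  preserves physician ordering as panels grow.
* **Contamination**: incomplete raters lose one whole vignette;
  straight-liners answer one constant; anti-correlated raters mirror
  their task's *consensus* (not their own idiosyncratic draw) about the
  scale midpoint, with no idiosyncratic item noise — a deliberate
  contrarian, which is the pathology the reliability screen exists to
  catch. The canonical contaminated fixture recruits 59 raters (42
  genuine + 8 + 8 + 1) and is engineered so the three screens recover
  exactly the injected sets.
* `simulate_paired_panels()` conditions two panels on one draw of
  physician effects, for studying between-group agreement: with only the
  person effect shared, the expected between-group correlation of
  physician scores is \(\sigma^2_p / \sqrt{V_A V_B}\), where \(V\) are
  the panel-mean variances — the attenuation formula the tests verify.

What passing these tests does *not* show about real data: real raters
are not exchangeable normal deviates (halo effects, scale-use styles,
fatigue), ordinal 5-point responses are only approximated by
round-and-clip, and real batch assignment is rarely as tidy as
round-robin. The generator validates the estimators and screens, not the
normality of any particular panel.

## Group comparison

`stringency_anova()` consumes one mean score per physician × vignette ×
rater group (raters averaged within group, because the two groups have
different, non-paired panels) and fits the two-within-factor
repeated-measures ANOVA with physicians as subjects. Uncorrected F
statistics are the default — matching how such analyses are typically
reported — with Greenhouse–Geisser correction available
(`sphericity = "greenhouse_geisser"`); for the 2-level group factor
sphericity holds trivially. The effect size \(d\) is the absolute group
mean difference over the pooled SD of the two groups' physician-level
scores — the natural standardizer given equal physician counts; no
standard exists for which \(d\) such studies report, so the choice is
documented rather than assumed universal. `correlate_groups()` reports
the Pearson correlation of per-physician scores between groups.

## Problem sizes used in validation

The test suite works at deliberately moderate sizes chosen to make
Monte-Carlo checks sharp: estimator-oracle equivalence uses 200 random
2–3-level crossed designs plus balanced and unbalanced nested designs;
calibration uses 500 replicates of each design at the study's own layout
(8 × 20 × 3 crossed; 42 raters in 4-physician batches nested), comparing
mean raw estimates to the generating truth within 3 Monte-Carlo standard
errors; coefficient properties are swept over 1,000 random non-negative
component sets. These sizes keep the full suite to a few minutes while
leaving the Monte-Carlo bands far tighter than any decision the
estimates would inform.

## Known limitations

* Only the two facet structures above are supported; no item facet,
  no multivariate G-theory, no REML/Bayesian estimation.
* The nested estimator requires every (pseudo-)rater to cover every
  vignette; raters with partial vignette coverage should be removed by
  QC first.
* Henderson Method 1 can return negative raw estimates in small or
  noisy designs; truncation introduces the usual positive bias in
  truncated components.
* The leave-one-out reliability screen needs at least 3 raters per task
  group and its stability depends on how much shared signal a group's
  cells carry (see the generator notes above).
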