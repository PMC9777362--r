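---
title: "Dual-factor analysis of adolescent well-being surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-factor analysis of adolescent well-being surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualfactor)
library(dplyr)
```

## The two measures and the dual-factor frame

Mental well-being in school-aged populations is increasingly described as
two related but distinct continua: subjective well-being and mental
illness. The absence of symptoms does not by itself imply good mental
health, and high life satisfaction can coexist with frequent symptoms.
Crossing a "high/low" split on each axis gives four states:

| | low complaints | high complaints |
|---|---|---|
| **high life satisfaction** | Flourishing (complete mental health) | Struggling (incomplete mental illness) |
| **low life satisfaction** | Languishing (incomplete mental health) | Floundering (complete mental illness) |

`dualfactor` operationalises this frame for HBSC-style repeated
cross-sectional surveys with two instruments:

* **LS** — the Cantril ladder, an integer 0 ("worst possible life") to
  10 ("best possible life"). The conventional HBSC split between low and
  high is 6, which we adopt as the default `ls_cutoff`.
* **PHC** — psychological health complaints, the sum of four symptom
  items (feeling low, irritability, nervousness, sleep difficulties),
  each asked on a 5-level frequency scale from 1 ("about every day") to
  5 ("rarely/never"). Items are reversed and rescaled to 0–4
  (`rescaled = 5 - code`) and summed to 0–16, higher meaning more
  numerous and frequent complaints.

The PHC axis has no conventional split on the continuous 0–16 scale, so
the package calibrates one (next section); 8 is the default
`phc_cutoff`.

### Scoring rules and missing data

Scoring is complete-case by default: a PHC score is produced only when
all four items are answered (`min_items = 4`). A four-item sum is too
short to prorate defensibly, but a `min_items` switch is exposed for
sensitivity analyses; when relaxed, the available-item mean is scaled to
the 0–16 range. A missing item always blanks the gold-standard label,
and an out-of-range ladder value (anything but an integer 0–10) is
treated as missing, never corrected.

## Calibrating the PHC cutoff

The dichotomous criterion "at least 2 of the 4 symptoms more than once a
week" (i.e. at least two original codes ≤ 2) is a recommended screening
definition for multiple complaints and serves as the gold standard. The
continuous score is swept over thresholds 0..17 with the test-positive
convention `score >= threshold`, giving a ROC curve whose AUC is
computed by the trapezoidal rule; for unweighted data this equals the
Mann–Whitney concordance probability, which the test suite verifies to
1e-12 against a brute-force pairwise oracle.

The operating threshold maximises the Youden index
\(J = sensitivity + specificity - 1\); "maximising the ROC curve" admits
more than one reading, so the rule is pluggable (a closest-to-corner
rule is included) and the choice is recorded in every report. Ties —
including floating-point ties, which arise because \(J\) is a sum of two
rationals — resolve to the *lower* threshold, the more sensitive choice
for a screening instrument.

Two structural facts about this design are worth noting. First, a
gold-positive respondent has two items at rescaled level ≥ 3 and
therefore PHC ≥ 6, so sensitivity is exactly 1 at any threshold ≤ 6.
Second, because the gold standard is a deterministic function of the
same items as the score, the empirical AUC is high by construction;
this is a property of the sensitivity-analysis design, not evidence of
diagnostic validity.

Interval estimates: sensitivity and specificity get Wilson score
intervals (bounded and well-behaved near 0/1, unlike Wald); the AUC gets
a percentile bootstrap resampling respondents, or whole school classes
when a cluster vector is passed, so the within-class dependence is
respected. One bootstrap mechanism serves weighted, unweighted and
clustered data alike. The ROC is unweighted by default with a
`--weighted` / `weights =` option, since survey-weighted ROC analysis is
a defensible but not universal choice.

## Design-based estimation

Group means (and quadrant proportions, which are means of indicators)
are estimated with design weights and their variance by Taylor
linearisation of the ratio estimator \(\hat y = \sum w y / \sum w\):
per-PSU totals \(z_{hj} = \sum_{i \in hj} w_i (y_i - \hat y) / \sum w\)
are combined as
\(\widehat{Var} = \sum_h \frac{n_h}{n_h-1} \sum_j (z_{hj} - \bar z_h)^2\),
treating PSUs (school classes) as drawn with replacement within strata
and applying no finite-population correction — the standard default
when sampling fractions are unknown. In the degenerate design (one
stratum, one respondent per cluster, equal weights) the formula reduces
*exactly* to the simple-random-sampling \(s/\sqrt n\), including the
\(n/(n-1)\) convention, which the tests assert to 1e-12.

Strata left with a single PSU after subsetting are handled by centring
the lone PSU at the grand PSU mean (`lonely_psu = "adjust"`), switchable
to collapsing all lone strata into one pseudo-stratum or to failing.
Confidence intervals use the normal reference, estimate ± 1.96 SE,
matching the symmetric two-decimal intervals such surveys publish. With
tens of PSUs per cell this slightly undercovers (a t reference with
PSU-based degrees of freedom would widen intervals by ~2%); the
simulation in the acceptance suite measures empirical coverage of ~94%
at 64 PSUs per cell, inside the 93–97% band we require.

Waves are repeated cross-sections and treated as independent, so a
between-wave shift in a group mean has SE
\(\sqrt{SE_a^2 + SE_b^2}\).

## Trajectories and jumps

Each gender–age group's per-wave (PHC mean, LS mean) point is classified
with the *same* threshold rule used for individuals — the frame is
deliberately identical at both levels — and a "jump" is recorded
whenever the state of chronologically consecutive waves differs. Jumps
are declared from point estimates, with per-axis CIs reported alongside;
no formal test of region membership is attempted, because the regions
are conventions, not hypotheses. A group missing a wave yields a gap
across which no jump is inferred (supply `wave_order` when a single
group's table does not contain every wave).

Boundary conventions are explicit config fields: by default the cutoff
value itself counts as "high" on both axes, so a mean point exactly at
(6, 8) is Struggling; both flags are recorded in the pipeline manifest
because published analyses rarely state inclusivity.

## The synthetic survey generator

National HBSC microdata are access-restricted, so the package ships a
generator that emulates the *structure* of such data and makes every
downstream stage testable against known truth.

Each respondent carries a latent symptom severity
\(\theta = \mu_{cell} + b_{class} + e\), with \(b_{class} \sim N(0,
\sigma_b^2)\) a school-class random effect (classes shared by boys and
girls within a wave–age layer, nested in strata) and \(e \sim N(0,
\sigma_\theta^2)\). Items follow a logistic graded-response model,
\(P(S_i \ge k) = \mathrm{logit}^{-1}(a_i(\theta - t_{ik}))\) — the
standard psychometric choice for 5-level symptom items, and one with
closed-form category probabilities, so cell expectations are computable
by Gauss–Hermite quadrature (`expected_phc()`) and every simulation can
be checked against analytic truth rather than against itself. The
ladder is linear in severity, rounded and clipped:
\(LS = \mathrm{clip}(\mathrm{round}(\beta_{0,cell} - \beta_1 \theta +
\varepsilon), 0, 10)\), whose expectation also has a closed form
(`expected_ls()`).

Defaults, chosen once as survey-realistic values:

| parameter | default | rationale |
|---|---|---|
| `sigma_theta` | 1 | latent scale fixed for identifiability |
| `cluster_sd` | 0.2 | latent ICC ≈ 0.04, typical for health complaints among classes |
| `item_discriminations` | 1.0–1.3 | moderate, unequal loadings |
| `item_thresholds` | per item, spanning ≈ −1.1 to 1.9 | nervousness/irritability more common than feeling low |
| `ls_slope` | 0.5 | within-cell PHC–LS correlation ≈ −0.27 |
| `ls_noise_sd` | 1.6 | ladder SD ≈ 1.7 |
| `n_strata`, `clusters_per_stratum` | 20 × 15 | regions × classes; ~33 pupils per class at 5000 per cell |
| `weight_cv` | 0.3 | moderate post-stratification spread; lognormal, mean 1 per wave |

`default_config()` calibrates the per-cell latent means so that the
analytic expected PHC of every (wave, gender, age) cell equals the
published national estimate for Italian adolescents (e.g. girls aged
15: 7.5 → 8.6 → 9.1 across 2010/2014/2018), and likewise the expected
LS (6.9 → 6.7 → 6.9). One global linear ladder map cannot reproduce
those targets — the same group shows LS 6.9 at both PHC 7.5 and 9.1, so
life satisfaction is *not* a function of the severity mean across
cells — which is precisely the dissociation the dual-factor frame is
about. The generator therefore uses one global slope (the within-cell
coupling) with per-cell intercepts (the between-cell dissociation),
each solved by `uniroot` on a strictly monotone expectation.

What the generator does **not** emulate: the real sampling frame and
regional stratification, nonresponse mechanisms, unequal class sizes,
informative weights (weights are independent of outcomes, so weighted
estimators are unbiased by construction), item-level response styles,
and any somatic-complaint items. Passing tests therefore demonstrate
that the *pipeline* is correct under a known data-generating process,
not that the published estimates are reproduced from real data — those
microdata are access-restricted by policy.

## Numerical and reproducibility choices

* Gauss–Hermite quadrature with 60 nodes; calibration roots solved to
  1e-10 on bracketing intervals where the expectation is strictly
  monotone.
* Item sampling uses a single uniform per item compared against the
  cumulative category probabilities, coupling categories monotonically.
* `round()` follows R's round-half-even convention; ladder values are
  clipped after rounding.
* Every random routine takes an explicit seed and restores the session
  RNG state (`withr::with_seed`); `run_pipeline()` output is
  byte-identical under a fixed seed, and the manifest records every
  convention flag (cutoffs, inclusivity, selection rule, variance
  options), so the classification of any (LS, PHC) pair is fully
  determined by manifest plus data.
* Degenerate inputs fail loudly and specifically: one-class ROC input,
  fewer than two clusters, invalid configuration fields (named in the
  error), malformed CSV rows (named with their line number).

## Problem sizes in the test and acceptance suites

Unit tests run on 100–4000 respondents per cell. The simulation-heavy
checks use: 300 replicate surveys of 6 cells × 240 respondents in
64 classes for CI coverage; 20 replicate surveys at 5000 respondents
per cell (90,000 records each) for the end-to-end trajectory scenario,
where generated cell means are required to match their calibration
targets within ±0.2 and the older-girls Flourishing→Struggling jumps
must appear in at least 95% of runs. The full suite completes in well
under a minute on one CPU.

## Known limitations

* The Taylor variance assumes with-replacement PSU sampling; with high
  sampling fractions it is conservative in expectation but the normal
  reference is slightly anticonservative at small PSU counts.
* Quadrant proportions near 0 or 1 get symmetric normal CIs (truncated
  to [0, 1]); a logit-scale interval would be preferable in tiny cells.
* The cutoff calibration inherits the circularity of its design: gold
  standard and score derive from the same items, so AUC and the
  sensitivity/specificity of the chosen cutoff describe internal
  consistency of the dichotomisation, not external validity.
* Classification of group means places the *mean* in the frame; it is
  not the modal individual state, and compositional statements should
  use `quadrant_distribution()` instead.
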