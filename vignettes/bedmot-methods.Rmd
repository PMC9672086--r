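---
title: "Methods: sentiment polarity, ordinal motivation inference, and the synthetic cohort"
author: "bedmot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentiment polarity, ordinal motivation inference, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedmot)
```

## What the package models

bedmot implements the quantitative arm of a mixed-methods design for
studying patient motivation in guided internet-based treatment of binge
eating disorder (BED). Patients entering such a program answer two
free-text questions — what they want from therapy, and why they chose an
online format — and clinicians label each answer with one of the four
extrinsic motivation types of self-determination theory (SDT), which form
an ordered scale from controlled to autonomous:

> external regulation < introjection < identification < integration

The package treats those labels as given input (the qualitative coding
itself is out of scope) and asks three statistical questions:

1. Does the *sentiment polarity* of an answer rise with the autonomy of the
   coded motivation type?
2. Does motivation type predict *adherence* (sessions completed) or
   *treatment outcome* (pre/post change on BED-Q, EDE-Q, MDI and a VAS
   health rating)?
3. Do these relationships differ between adults and young adults?

Because the patient data such analyses are built on cannot be shared, the
package also ships a seeded synthetic cohort generator that reproduces the
*statistical structure* of this setting, so every stage of the pipeline is
testable end to end without any external data.

## Sentiment scoring

Scoring is hybrid lexicon-and-rule based, in the style of Danish polarity
tools such as Sentida and of VADER-like systems generally. Three steps:

1. **Tokenize.** Sentences split on terminal `.`/`!`/`?` runs; tokens are
   maximal runs of Unicode letters, lowercased (so `æøå` survive);
   hyphenated words split; digits carry no valence. A sentence is
   *interrogative* iff its terminal punctuation contains `?`; terminal `!`
   marks are counted per sentence.
2. **Adjust.** Each token is looked up in a lexicon of valences on the
   \[−5, 5\] scale and adjusted by three rules, applied in the order
   modifier → negation → exclamation:
   * a *modifier* multiplies the next valence-bearing token in the same
     sentence by its factor (e.g. ×1.5 for an intensifier);
   * a *negator* flips the sign of valence-bearing tokens within the
     following `negation_window` tokens of the same sentence — but **not**
     in interrogative sentences, where negation is usually rhetorical
     rather than evaluative; stacked negators each flip, so double
     negation cancels;
   * each sentence-terminal `!` (at most three) multiplies all adjusted
     valences in the sentence by `exclamation_factor`.
   All three rule parameters are configuration keys of [lexicon()] with
   defaults `negation_window = 3`, `exclamation_factor = 1.5`, modifier
   scope = next valence token. Published descriptions of such scorers do
   not pin these constants down; the defaults are conventional values for
   rule-based sentiment engines and the ordering of the (multiplicative,
   hence order-insensitive in magnitude) rules is fixed for
   reproducibility.
3. **Pool.** The adjusted valences of the scored tokens are pooled once
   over the whole answer (document level). Besides `sum` and `mean`
   pooling the package provides a **partitioned signed geometric mean**,
   the default, designed for valence sets containing zeros and negatives
   where an ordinary geometric mean is undefined: with \(P\) the positive
   values, \(N\) the negative values, \(n\) the total count, and
   \(g^+, g^-\) the geometric means of \(P\) and \(|N|\) (zero for empty
   parts),
   \[
     \mathrm{gpool}(x) \;=\; \frac{|P|\,g^+ - |N|\,g^-}{n}.
   \]
   This operator reduces to the ordinary geometric mean on all-positive
   input, is antisymmetric under sign flip, shrinks towards zero as the
   neutral fraction grows, and is less sum-/mean-style sensitive to single
   extreme tokens. It is one member of the family of generalized geometric
   averages; the choice is surfaced in all output metadata as
   `pooling = "partitioned_signed_gmean"` rather than hidden. Documents
   with no lexicon hits score exactly 0 under every operator.

## The ordinal inference chain

Motivation types are an *ordered* predictor, so the package tests ordered
alternatives rather than generic group differences. For each variable,
question, and age stratum:

* **Jonckheere–Terpstra trend test.** The raw statistic is the sum of
  pairwise Mann–Whitney counts over group pairs in the hypothesised
  ascending order (ties count 0.5). It is standardised with the
  tie-corrected null variance; the reported `z` is signed so that
  ascending trends are positive, and p-values are two-sided with the sign
  carried separately (the reported statistic supports both ascending and
  descending readings). A permutation option relabels observations across
  groups keeping group sizes fixed — exactly (full enumeration) when the
  number of distinct arrangements is at most 10^5, otherwise by seeded
  Monte-Carlo. No installed package provides this test, so it is
  implemented here, with the statistic and the permutation loop in C++.
* **Brown–Forsythe homoscedasticity test**: one-way ANOVA F on absolute
  deviations from group medians. When the trend test rejects *and* the
  groups are homoscedastic (p > α), the ordering statement extends from
  mean ranks to group medians; the verdict records this as
  `medians_extend`.
* **Kendall τ\_B effect size** between the variable and the integer SDT
  level code 0..3 (codes, not labels, enter the statistic). τ\_B is the
  tie-appropriate choice for 3–4-level ordinal data. Its 95% CI is a
  seeded percentile bootstrap over subject pairs (default B = 2000) —
  robust to the heavy ties, with a normal-approximation CI available by
  flag. If either margin is constant the result is explicitly degenerate,
  never a number.
* **Dual effect-size rule.** An association is *practically* significant
  only if (a) \(|\hat\tau| > \mathrm{RMPE}\) with RMPE = 0.2, and (b) the
  CI is not "inversely significant": its bounds may not simultaneously
  reach −RMPE and +RMPE. Stars grade \(|\hat\tau|\) against 0.2 / 0.5 /
  0.8; p-value asterisks (0.05 / 0.01 / 0.001) are reported in a separate
  column to avoid conflating the two ladders.
* **Composite verdict**: a cell is `overall` significant only when the
  trend test rejects *and* the dual effect-size rule passes — stochastic
  dominance and practical effect size must both hold.

For pre/post outcomes the package fits a two-occasion mixed (split-plot)
ANOVA with time within subjects and motivation type between, reporting the
time×group interaction. With two occasions this is algebraically the
between-group ANOVA on change scores; the classical decomposition gives
numerator df k−1 and denominator df n−k. Reported denominator degrees of
freedom in comparable published tables sometimes imply a different
repeated-measures structure that cannot be reconstructed from a cohort of
this shape; this package always reports the classical split-plot df.
Shapiro–Wilk normality checks (with detrended QQ deviations) are computed
and reported alongside every variable but never gate the ANOVA: the
mixed ANOVA is run regardless, on the usual robustness grounds, with the
normality evidence left to the reader.

Incomplete pre/post pairs are excluded pairwise and the exclusion count is
logged in the bundle metadata. No multiple-testing correction is applied
across the variable × question × stratum grid; the grid size is visible in
the bundle so readers can apply their own.

## The synthetic cohort generator

`generate_cohort()` draws, per patient: age (19 of 148 young adults,
i.e. under 25), sex (17/148 male), BMI, two motivation labels (therapy
aims over levels 0/50/50/48 — external regulation absent, reflecting the
screening practice this setting is known for; why-online over
31/21/81/15), a latent polarity per question that is linear in the level
index, two statements realising that latent polarity, truncated-normal
pre-treatment scores inside the eligible region (BED-Q in the
mild–moderate band 10–21, MDI ≤ 40), post scores with a treatment effect
but — by default — *zero* motivation-type effect, and adherence.

The young-adult age cut is 25. The underlying studies motivate the
adult/young-adult split by brain maturation, which standardly puts the
boundary at the mid-twenties, but never print their cut; 25 is therefore a
documented, configurable guess (`age < 25` = young adult).

Two generator constants were calibrated once by large-n simulation
(n = 24,000–40,000) and then frozen:

* `polarity_link = 0.615` makes the *population* Kendall τ\_B between
  gmean-scored therapy-aims polarity and motivation level ≈ 0.310 — the
  association strength the pipeline is designed to detect;
* `young_adherence_link = -0.56` makes the population young-adult τ\_B
  between why-online polarity and completion category ≈ −0.31, the
  adherence link confined to young adults.

Statements are built from a synthetic lexicon of ≥ 200 pseudo-Danish
letter-only words with valences on an even grid spanning \[−5, 5\]:
valence tokens are drawn around the latent polarity (token SD 1.5, 12
content slots per statement), fillers at rate 0.3, and negations at rate
0.1 — a negated slot emits a negator, a token drawn around the *negated*
latent, and two fillers that exhaust the negation window, so the realised
contribution still tracks the latent. Sentences end in full stops, so the
interrogative rule never suppresses planted negations. Completion
categories follow proportions 54/56/37 (Low/High/Full); a quarter of Low
completers lose their post scores, exercising the pairwise-deletion path.
Outcome dispersions (e.g. MDI mean 23, SD 8 within 2–40) are chosen for
testability — published descriptives rarely include dispersion — and the
ground-truth file says so.

What the generator does *not* emulate: natural-language fluency (texts
are pseudo-word strings with controllable polarity, not Danish prose),
item-level questionnaire responses (sum scores are drawn directly),
therapist interaction, and any dependence structure between outcomes
beyond the planted links. Passing tests therefore demonstrate that the
*pipeline recovers planted statistical structure*, not that the sentiment
lexicon or rules would reach any particular accuracy on real clinical
text.

## Numerical and design choices

* **Seeding.** Every stochastic step (bootstrap, permutation, generation)
  takes an explicit seed; the pipeline derives per-cell seeds
  deterministically from the master seed, so bundles are byte-identical
  across reruns and the caller's RNG stream is never touched.
* **Degenerate inputs.** Constant samples: JT returns z = 0, p = 1;
  Brown–Forsythe returns F = 0, p = 1; τ\_B returns an explicit degenerate
  record; the mixed ANOVA returns F = 0, p = 1 when change scores are
  constant (this case is detected before the linear-model fit, which would
  otherwise manufacture an F from ~1e−30 rounding residue). Pipeline cells
  that cannot be computed (an empty stratum×level cell, a group below the
  minimum size) are reported as degenerate with a reason and the run
  continues.
* **Completion coding.** Ten sessions *without* follow-up counts as High,
  not Full — "full" is defined by the follow-up clause — and the rule is
  configurable. In correlations, completion enters as the ordered code
  Low = 0 < High = 1 < Full = 2.
* **Differentials** are post − pre (negative = improvement on symptom
  scales). Both baseline ("T1") and differential correlations with
  polarity are emitted, since published table conventions differ;
  neither is privileged.
* **Exclusion screening** is `BED-Q ≥ 22 or MDI > 40`, i.e. the severe
  BED band's lower edge; the generator only emits eligible patients.

## Validation problem sizes

The test suite validates the chain at these sizes, chosen to give
Monte-Carlo error well inside each acceptance band: τ\_B against a
brute-force O(n²) pair classifier on 500 instances with n ≤ 50 (exact
equality); JT permutation p against full enumeration on instances with
≤ 10^5 arrangements (exact equality); Brown–Forsythe and mixed-ANOVA
type-I error at 2000 null replicates (band 0.05 ± 3·SE); JT
normal-vs-permutation agreement within 0.02 at 20,000 relabellings per
dataset; CI coverage of the planted τ\_B = 0.31 over 200 cohorts of
n = 148 with B = 1000 bootstrap resamples; and the zeroed-link null grid
over 40 cohorts with B = 100.

## Known limitations

* The family-wise behaviour of the composite rule degrades in small
  strata. In a stratum of ~19 patients the trend test still rejects at
  its nominal 5% per cell, and at that sample size any τ̂ large enough to
  reject the trend test also exceeds the RMPE of 0.2 while the CI guard
  (half-width ≈ 0.33) cannot fire — so the dual rule provides essentially
  no additional family-wise protection there. Across a full default grid
  (9 variables × 2 questions × 3 strata), null cohorts produce at least
  one spuriously `overall`-significant young-adult cell in roughly half
  of the runs. This is the correct per-cell calibration of the underlying
  tests, not a coding artefact; conclusions drawn from small strata
  should rest on the CI width, not the star.
* The lexicon shipped by the generator is synthetic; no claims are made
  about agreement with any published Danish sentiment lexicon.
* The bootstrap CI for τ\_B is percentile-based; with n ≤ 20 and heavy
  ties it can be noticeably asymmetric, which is visible in the young
  stratum's wide intervals.
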