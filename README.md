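# bedmot

Motivation and sentiment analysis for online binge-eating-disorder (BED)
treatment cohorts.

Patients entering guided internet-based BED treatment answer two free-text
questions — what they want from therapy, and why they chose an online
format — and each answer is labelled with one of the four extrinsic
motivation types of self-determination theory, an ordered scale running
from controlled to autonomous:

    external regulation < introjection < identification < integration

`bedmot` provides the quantitative machinery for studying such cohorts:

* **Sentiment polarity scoring** of the free-text answers with a hybrid
  lexicon-and-rule engine (word valences in [−5, 5]; modifier,
  non-interrogative negation, and exclamation rules), pooled per answer by
  sum, arithmetic mean, or a *partitioned signed geometric mean* defined
  for mixed-sign data: with `P` the positive adjusted valences, `N` the
  negative ones, `n` the total count, and `g+`, `g−` the geometric means
  of `P` and `|N|`,

      gpool(x) = (|P|·g+ − |N|·g−) / n

* **Instrument scoring**: BED-Q sum score and severity bands, MDI
  depression bands, eligibility screening (severe BED or MDI > 40),
  completion-rate categories (Low < High < Full), descriptive tables.
* **An ordered-alternatives inference chain** per variable × question ×
  age stratum: signed Jonckheere–Terpstra trend test (tie-corrected
  normal approximation, or exact/Monte-Carlo permutation), Brown–Forsythe
  homoscedasticity test, Kendall τ_B with seeded bootstrap CIs, and a dual
  significance rule — a cell is *overall* significant only when the trend
  test rejects (p ≤ 0.05) **and** |τ̂| exceeds the recommended minimal
  practical effect size (0.2) with a CI that is not inversely significant.
* **Mixed pre/post ANOVA** (time × motivation-type interaction) for the
  treatment outcomes, plus Shapiro–Wilk normality checks.
* **A seeded synthetic cohort generator** reproducing the statistical
  structure of such a study (n = 148, 19 young adults, motivation-type
  distributions, a calibrated polarity–motivation link with population
  τ_B ≈ 0.31, a young-adult-only negative polarity–adherence link with
  τ_B ≈ −0.31, and a null motivation-type effect on outcomes), so the
  whole pipeline is testable without any patient data.

See `vignettes/bedmot-methods.Rmd` for the full methodological account.

## Worked example

```r
library(bedmot)

lx <- lexicon(valences  = c(glad = 3, håb = 2, trist = -3),
              modifiers = c(meget = 1.5), negators = "ikke")
score_document("Jeg er meget glad og har håb!", lx, method = "gmean")
#> Polarity 4.5000 (partitioned_signed_gmean pooling; 2 of 7 tokens scored)
score_document("ikke glad", lx, method = "gmean")
#> Polarity -3.0000 (partitioned_signed_gmean pooling; 1 of 2 tokens scored)
```

"meget glad" is 3 × 1.5, the sentence-terminal `!` amplifies both scored
tokens by 1.5, and the geometric pooling of (6.75, 3) gives 4.5; in the
second text the non-interrogative negation flips `glad` to −3.

```r
coh <- generate_cohort(generator_config(seed = 11))
res <- run_analysis(coh$records, coh$lexicon, analysis_config(seed = 11, B = 500))
res
#> bedmot results bundle: n = 148
#>   trend grid: 54 cells; 4 overall significant
#>   correlation grid: 30 cells
#>   anova grid: 8 cells
#>   warnings: 11 (see meta$warnings)

subset(res$trend_grid, variable == "polarity" & question == "therapy_aims" &
       age_group == "all")
#>  variable     question age_group T_JT   p_TJT  F_BF p_FBF tau_b ci_low ci_high stars overall
#>  polarity therapy_aims       all 4.57 4.8e-06 0.325 0.723 0.291  0.173   0.404     1    TRUE
```

Read: across all 148 synthetic patients, scored polarity of the
therapy-aims answers rises with motivation type (ascending trend,
z = 4.57, two-sided p = 4.8e-06), the motivation groups are homoscedastic
(Brown–Forsythe p = 0.72, so the ordering extends to medians), and the
effect size τ_B = 0.29 with 95% CI (0.17, 0.40) clears the 0.2
practical-significance threshold — the cell is overall significant, as it
should be for a cohort generated with the calibrated polarity link.
`write_bundle(res, "out/")` serializes the grids as CSV/JSON plus a run
log.

A thin command-line front end wrapping these functions is installed at
`inst/cli/bedmot.R` (`simulate`, `score`, `analyze` subcommands).

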