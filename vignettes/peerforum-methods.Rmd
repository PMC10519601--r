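---
title: "Methods: posting patterns and affect in peer online mental-health forums"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posting patterns and affect in peer online mental-health forums}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerforum)
```

## The scientific problem

Discussion platforms such as Reddit host communities (subreddits) for
mental-health (MH) topics alongside general-interest ones, and the same
account can post in both. For people living with bipolar disorder (BD) —
where extreme mood states are the defining feature — this makes such
platforms a rare observational window on three questions: who engages with
peer MH support forums at all, how the emotions expressed in MH-community
posts differ from the same person's posts elsewhere, and whether the mood a
user displays *outside* MH communities predicts whether they engage with MH
communities at all.

`peerforum` implements that full analysis chain as a tested pipeline:

1. **Cohort mining** — users are identified by self-reported diagnosis
   statements ("I was diagnosed with bipolar disorder"), with exclusion
   phrases ("not officially diagnosed", "self-diagnosed") and a
   psychotic-disorder comorbidity rule voiding candidates. A reported major
   depressive disorder does *not* exclude: a large fraction of people with a
   BD diagnosis first received a depression diagnosis, so excluding them
   would bias the cohort.
2. **Context classification** — each post is labelled `MH` or `nonMH` by
   looking its subreddit up in a topic taxonomy with an `is_mh` flag.
3. **Affect scoring** — each post gets five dictionary category scores:
   positive emotion, anxiety, anger, sadness, and first-person singular
   pronouns, each as the percentage of the post's tokens matching the
   category.
4. **Aggregation** — post scores are averaged per user and context. A
   single post's score is read as in-the-moment *emotion*; a user's average
   over many posts as *mood*.
5. **Analyses** — the posting partition, the paired within-user comparison,
   and the between-user logistic regression, described below.

## The three analyses

**Posting partition.** Users are classed as posting *only in MH*, *only in
non-MH*, or *both* (on unfiltered post counts), with activity strata:
"active contributors" post at least 4 times in each context; single-context
users are stratified at 8 or more posts. The partition is computed before
any word-count filtering because it describes posting behaviour, not
language.

**Within-user comparison.** For users with at least 4 qualifying posts in
each context, each category's per-user MH mean is compared with the non-MH
mean by a dependent t-test, Bonferroni-corrected for the 5 categories
(`p_bonf = min(1, 5p)`). Two paired effect sizes are reported:
`d_z = mean(diff)/sd(diff)` (the default) and
`d_av = mean(diff)/sqrt((sd_MH^2 + sd_nonMH^2)/2)`. Both are emitted because
the two variants differ when the within-user differences are strongly
correlated, and published paired analyses are frequently ambiguous about
which was used; `d_av` is the one recomputable from summary statistics
alone.

**Between-user regression.** A logistic model predicts `posted_in_MH`
(1 if the user has any MH post) from the five mood scores measured *only on
non-MH posts* — so that both outcome groups are measured in the same
communicative context — controlling for age, gender (0 = feminine,
1 = masculine), active days (days between first and last post) and activity
(posts per active day). The outcome-0 group requires no MH posts and at
least 8 qualifying non-MH posts; users with missing age or gender are
listwise-deleted. The controls-only and full models are compared by a
likelihood-ratio test, and fit is summarised by AIC (`2k - 2ll`), BIC
(`k ln n - 2ll`) and three pseudo-R² statistics: the likelihood-ratio index
`1 - ll/ll_null` (reported under its common "Hosmer and Lemeshow" label),
Cox–Snell `1 - exp(2(ll_null - ll)/n)`, and Nagelkerke (Cox–Snell rescaled
to a unit maximum). A robustness refit down-samples the majority gender
within each outcome group to the minority count
(`gender_balanced_rerun()`).

## Numerical choices

* The logistic fit is maximum likelihood via iteratively reweighted least
  squares with step-halving (the likelihood is kept monotone), convergence
  when the log-likelihood changes by less than `1e-8`, and a hard failure
  after 100 iterations. Rank-deficient designs error naming the collinear
  columns, and (quasi-)perfect separation errors explicitly rather than
  returning meaningless estimates — at small sample sizes with nine
  predictors this genuinely occurs, and silent output would be worse than
  an error. Standard errors come from the inverse observed information;
  Wald intervals use `beta ± 1.96 se`; coefficient p-values use the normal
  approximation to `z`, the standard convention for this model class.
* `active_days = max(1, ceiling((last - first)/86400))` in UTC seconds: the
  ceiling counts any partial day; the floor keeps posts-per-day defined for
  single-post users while preserving ordering.
* A subreddit absent from the taxonomy counts as non-MH: the MH list is the
  positive filter, and the analyses consume only the two-way split.
* Posts under 25 tokens are excluded from all score means (dictionary
  percentage estimates are unreliable for very short texts); the threshold,
  and the 4- and 8-post eligibility rules, are `run_config()` parameters.
* The tokeniser lower-cases, splits on whitespace, strips edge punctuation,
  keeps internal apostrophes, counts numerals, and drops pure-punctuation
  fragments. Dictionary entries are literal words or prefix stems with a
  trailing `*`; a token may hit several categories but counts once per
  category, and the score denominator is all tokens. These conventions are
  the package's documented contract — dictionary tools differ at the
  margins (hyphens, numerals), so the exact rules are stated rather than
  inherited silently.

## The synthetic study conditions

Real corpora of this kind are access-restricted, so the package ships a
generator (`synth_config()` / `synth_generate()`) whose defaults *are* the
study conditions every test runs under:

* Each token of a post is independently a category signature word with a
  per-(context, group) emission probability, else a neutral filler. The
  expected category score of a cell is therefore exactly `100 × rate`, and
  every downstream mean is checkable against a binomial oracle.
* Default emission rates are the canonical real-world post means divided by
  100: MH context (3.48, 0.67, 0.75, 0.81, 8.82 percent for posemo,
  anxiety, anger, sadness, first-person singular) versus non-MH context
  (3.64, 0.37, 0.78, 0.45, 6.39) — so MH-context posts carry more anxiety,
  sadness and self-focus and slightly less positive emotion. Users who
  never post in MH communities get slightly lower anxiety, sadness and
  positive emotion in their non-MH posts (0.30, 0.38, 3.45 percent; 6.30
  for pronouns), planting the between-user mood signal with the observed
  sign pattern.
* 76% of users are MH posters (the observed share of users with any MH
  post) and 52% have feminine gender; ages are normal with mean 32, SD 9,
  truncated at 13. Both groups share the same expected total activity
  (2 × `posts_per_user_per_context` posts): group membership shifts *where*
  users post, not how much. An earlier draft of the generator gave MH
  posters twice the total output, which made the activity control a
  quasi-separating predictor — a degenerate emulation, since observed
  activity effects in this population are near-null.
* Every user carries one diagnosis-statement post, deliberately shorter
  than 25 words: it drives cohort mining and the posting partition but
  never enters a score mean, keeping planted rates exactly recoverable.
  Contamination (`plant_contamination()`) appends exclusion-phrase or
  psychotic-statement posts per user with configured probabilities, and the
  planted truth records whom, so cohort decisions are checkable exactly.
* Post lengths are `26 + Poisson(mean - 26)` so everything passes the
  25-word filter by default; `allow_short_posts` enables shorter posts for
  filter tests. Timestamps are uniform over three years.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linguistically realistic text (tokens come
from a small controlled vocabulary, so negation, sarcasm and context
effects are absent); correlation between categories within a post beyond
the multinomial draw; per-user heterogeneity in emission rates (all users
of a group share one rate, so between-user score variance is purely
binomial); bursty, episodic posting over time; throwaway accounts; and any
association of gender or age with posting group (the generator plants
none, so the regression's gender effect is null under the defaults — the
design-level simulations are the ones that plant and recover nonzero
gender coefficients).

## Verification strategy and problem sizes

The test suite checks each stage against an independent route: the scorer
against a naive nested-loop matcher (exact equality on 1,000 random
texts), the logistic fit against the closed-form 2×2 log odds ratio
(`|error| < 1e-6`) and against `stats::glm` on random designs (coefficients
and standard errors to `1e-6`), the paired test against `stats::t.test`,
and the generator against binomial standard-error bounds. Planted-effect
recovery uses 20 design-level samples of n = 5,000 with known coefficients;
calibration runs 1,000 replicates of score-level and design-level null
generators and expects 5% rejection within three Monte-Carlo standard
errors. Calibration simulates at the score/design level rather than
re-generating full text corpora, because the text path is itself validated
against the same binomial oracle; this keeps a thousand replicates
affordable. End-to-end runs use 200-user corpora (roughly 5,000 posts),
large enough for all three analyses to be estimable and the planted signs
to be significant, and reruns under a fixed seed are verified byte-identical.

## A worked example

```{r example, eval = FALSE}
out <- tempfile("peerforum-demo")
res <- run_pipeline(run_config(out, seed = 1))
res$rq1$proportions          # posting partition
res$rq2                      # paired comparison table
res$rq3$full_fit             # logistic regression
res$rq3$lrt                  # model comparison
relative_probability(res$rq3$full_fit)  # gender contrast in probability
```

## Known limitations

* Cohort mining is regex-based; the shipped inclusion/exclusion pattern set
  is a documented default, not the exhaustive battery a production study
  would curate. A user-supplied pattern file is the source of truth.
* The bundled lexicon is a small open vocabulary for reproducible tests;
  real analyses should load the full proprietary dictionary via
  `read_dic()` (the scorer is entry-format compatible).
* Diagnosis veracity is not verifiable from text, and the binary gender
  coding follows the upstream attribute-inference convention; both are
  inherited limitations of the study design, not modelling choices.
* No mixed-effects or longitudinal structure: the regression is
  cross-sectional, and repeated posts enter only through per-user means.
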