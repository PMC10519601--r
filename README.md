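# peerforum

Posting patterns and dictionary-measured affect of social-media users with
a self-reported bipolar-disorder (BD) diagnosis.

Discussion platforms such as Reddit host peer support communities for
mental-health (MH) topics next to general-interest ones, and the same
account can post in both. `peerforum` is for researchers in computational
mental health and psycholinguistics who want a reproducible pipeline for
three questions about such users:

1. **Who engages with MH forums?** The share of cohort users posting only
   in MH communities, only elsewhere, or in both.
2. **Do the same users express different emotions in MH posts?** Paired
   within-user comparisons of affect scores between contexts.
3. **Does mood outside MH forums predict engaging with them?** A
   cross-sectional logistic regression of a binary posting outcome on mood
   measured from non-MH posts only.

## What it computes

Posts are scored LIWC-style: for category *c* with dictionary entries
*D_c* (literal words or `stem*` prefixes), a text with tokens *t_1..t_w*
gets

    score_c = 100 * |{ j : t_j matches D_c }| / w

for the five categories *posemo, anxiety, anger, sadness, i* (first-person
singular pronouns); posts with *w* < 25 are excluded from all means. A
single post's score is read as in-the-moment emotion; a user's mean over
many posts as mood.

The cohort is mined from self-reported diagnosis statements
("I was diagnosed with bipolar disorder") with exclusion phrases
("not officially diagnosed", "self-diagnosed") and a psychotic-disorder
comorbidity rule; a major-depressive-disorder statement does not exclude.

The analyses: a posting partition with activity strata; dependent t-tests
with Bonferroni correction (m = 5) and paired Cohen's d (both `d_z` and
`d_av` variants); and maximum-likelihood logistic regression
(`posted_in_MH ~ age + gender + active_days + activity + posemo + anxiety +
anger + sadness + i`) fitted by iteratively reweighted least squares with
Wald inference, odds ratios, AIC/BIC, a likelihood-ratio test against the
controls-only model, three pseudo-R² statistics, and a gender-balanced
robustness refit.

Because real corpora of this kind are access-restricted, a synthetic
generator with planted emission rates, diagnosis statements and
contamination makes every stage testable end to end; see the methods
vignette (`vignettes/peerforum-methods.Rmd`) for the study conditions it
emulates and its limits.

## Worked example

```r
library(peerforum)
res <- run_pipeline(run_config(tempfile(), seed = 1))
```

The run generates a 200-user synthetic corpus (~5,000 posts), mines the
cohort, classifies and scores posts, and runs the three analyses. The
partition:

```
      both    only_mh only_nonmh
     0.675      0.000      0.325
```

67.5% of users posted in both contexts and none only in MH communities
(every synthetic MH poster also posts elsewhere). The paired comparison
(`res$rq2`) recovers the planted within-user pattern:

```
  variable mean_mh mean_nonmh      t   p_bonf     d_z interpretation
    posemo   3.496      3.523 -0.357 1.00e+00 -0.0308     Very small
   anxiety   0.656      0.362  9.684 1.94e-16  0.8334          Large
     anger   0.779      0.811 -0.837 1.00e+00 -0.0720     Very small
   sadness   0.807      0.456 10.264 6.80e-18  0.8833          Large
         i   8.858      6.347 23.710 4.33e-49  2.0407           Huge
```

MH-context posts show more anxiety, sadness and self-focus at large
effect sizes, and a near-null positive-emotion and anger contrast — the
planted directions. The regression (`res$rq3$full_fit`) finds the planted
between-user mood signal: anxiety (β = 2.40, p = 0.015) and sadness
(β = 2.12, p = 0.020) predict posting in MH communities, and the
likelihood-ratio test prefers the full model (χ² = 18.53 on 5 df,
p = 0.002). Scoring a single text:

```r
score_text("I am worried about tomorrow", default_lexicon())
#>   wc posemo anxiety anger sadness  i
#>    5      0      20     0       0 20
```

A report bundle (partition, tables, coefficients, model fit, manifest with
file hashes) is written to the output directory;
`scripts/peerforum.R` exposes the same run from the shell, including on a
real JSONL corpus with a user-supplied taxonomy, `.dic` dictionary and
attribute table.

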