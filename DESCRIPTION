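Package: peerforum
Title: Posting Patterns and Affect in Peer Online Mental-Health Forums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for studying posting patterns and
    dictionary-measured affect of social-media users with a self-reported
    bipolar-disorder diagnosis. Provides streaming readers for JSONL post
    corpora, regex-based cohort mining from self-reported diagnosis
    statements with exclusion and comorbidity rules, a configurable
    subreddit topic taxonomy (mental-health versus other communities),
    a LIWC-style category-percentage text scorer with the 25-word
    reliability filter, user-level aggregation with context-stratified
    mean scores, and the three core analyses: the posting partition,
    within-user paired comparisons of emotion scores (dependent t-tests,
    Bonferroni correction, Cohen's d), and a cross-sectional logistic
    regression (iteratively reweighted least squares, Wald inference,
    odds ratios, information criteria, likelihood-ratio test, pseudo-R2)
    with a gender-balanced robustness refit. A synthetic corpus generator
    with planted effects makes every stage testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
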