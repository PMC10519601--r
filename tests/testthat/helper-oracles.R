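# Independent oracles and tiny fixtures shared across the suite.

# Brute-force dictionary matcher: nested loops over tokens x entries,
# deliberately naive and independent of the scorer's vectorised path.
brute_force_score <- function(text, lexicon) {
  toks <- tokenize(text)
  wc <- length(toks)
  out <- list(wc = wc)
  for (cat in c("posemo", "anxiety", "anger", "sadness", "i")) {
    cnt <- 0L
    for (tok in toks) {
      hit <- FALSE
      for (e in lexicon$entries[[cat]]) {
        if (endsWith(e, "*")) {
          stem <- substr(e, 1L, nchar(e) - 1L)
          if (substr(tok, 1L, nchar(stem)) == stem) hit <- TRUE
        } else if (tok == e) {
          hit <- TRUE
        }
        if (hit) break
      }
      if (hit) cnt <- cnt + 1L
    }
    out[[cat]] <- if (wc > 0L) 100 * cnt / wc else 0
  }
  out
}

# Vocabulary for random scoring texts: dictionary literals, inflected
# wildcard-stem words, neutral fillers, numerals and punctuation noise.
random_text <- function(n_tokens, rng_vocab = c(
  "love", "sweet", "nice", "happier", "joyful", "worried", "worrying",
  "fearful", "anxious", "panicking", "hate", "hateful", "killing",
  "annoyed", "angry", "crying", "grief", "grieving", "sad", "sadness",
  "depressed", "i", "me", "mine", "i'm", "myself", "the", "and", "went",
  "store", "42", "weather", "don't", "table", "river!")) {
  paste(sample(rng_vocab, n_tokens, replace = TRUE), collapse = " ")
}

# Closed-form logistic slope for a 2x2 design: log odds ratio.
logodds_2x2 <- function(a, b, c, d) log((a * d) / (b * c))

# Expand a 2x2 table (exposed events a / non-events b; unexposed events c /
# non-events d) into unit records.
design_2x2 <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(design = data.frame(x = x), outcome = y)
}

# Design-level regression sample with planted coefficients: realistic
# control-variable distributions plus five mood scores on the percentage
# scale. truth is the named coefficient vector (including intercept).
simulate_rq3_design <- function(n, truth = c(
  intercept = 0.5, age = 0, gender = -0.8, active_days = 0,
  activity = 0, posemo = 0, anxiety = 0.6, anger = 0, sadness = 0, i = 0)) {
  X <- data.frame(
    age = rnorm(n, 32, 9),
    gender = rbinom(n, 1, 0.5),
    active_days = runif(n, 10, 1500),
    activity = rlnorm(n, log(0.05), 0.7),
    posemo = rnorm(n, 3.6, 0.9),
    anxiety = rnorm(n, 0.4, 0.25),
    anger = rnorm(n, 0.8, 0.4),
    sadness = rnorm(n, 0.45, 0.25),
    i = rnorm(n, 6.4, 2)
  )
  eta <- truth[["intercept"]] + as.matrix(X) %*% truth[names(X)]
  y <- rbinom(n, 1, plogis(drop(eta)))
  list(design = X, outcome = y, truth = truth)
}

# Score-level null generator for t-test calibration: per-user context means
# of post-level percentage scores when both contexts share one emission
# rate (the no-effect world the paired test should not reject in).
simulate_null_paired <- function(n_users, posts_per_context = 8L,
                                 tokens = 80L, rate = 0.06) {
  user_mean <- function() {
    mean(100 * rbinom(posts_per_context, tokens, rate) / tokens)
  }
  list(mh = replicate(n_users, user_mean()),
       nonmh = replicate(n_users, user_mean()))
}

# Hand-written scored-post rows for aggregation tests (no text involved).
scored_row <- function(id, author, context, created_utc, wc,
                       posemo = 0, anxiety = 0, anger = 0, sadness = 0, i = 0) {
  tibble::tibble(id = id, author = author, subreddit = "x",
                 context = context, created_utc = created_utc, body = "",
                 wc = wc, posemo = posemo, anxiety = anxiety, anger = anger,
                 sadness = sadness, i = i)
}

mini_lexicon <- function() {
  affect_lexicon(list(
    posemo = c("sweet", "lov*"), anxiety = c("worri*", "fearful"),
    anger = c("hate", "kill", "annoy*"), sadness = c("crying", "grief", "sad"),
    i = c("i", "me", "mine")
  ), version = "mini")
}
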