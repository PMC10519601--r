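#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions a synthetic corpus emulates: a population of
#' forum users with a latent posting status (whether they post in
#' mental-health communities), gender and age attributes, self-reported
#' diagnosis statements, and per-token emission rates for the five affect
#' categories that differ by posting context (MH vs non-MH subreddit) and by
#' user group. Because each token is independently a category word with its
#' emission probability, the expected category percentage score of a cell is
#' exactly `100 * rate`, which makes every downstream estimate testable
#' against a binomial oracle.
#'
#' Default emission rates plant the canonical effect pattern for this
#' population: within users, MH-context posts carry less positive emotion,
#' more anxiety and sadness, and many more first-person singular pronouns
#' than non-MH posts; between users, those who never post in MH communities
#' show slightly lower anxiety, sadness and positive emotion in their non-MH
#' posts than MH posters do.
#'
#' @param n_users Number of users.
#' @param seed Integer seed; the same config and seed give a bit-identical
#'   corpus.
#' @param p_mh_poster Probability a user is an MH poster (posts in both
#'   contexts); others post only in non-MH communities.
#' @param p_feminine Probability `gender = 0`.
#' @param age_mean,age_sd Age distribution (years), truncated at 13.
#' @param posts_per_user_per_context Mean of the per-context post-count
#'   distribution (`1 + Poisson(mean - 1)`, so every context a user is
#'   active in has at least one post).
#' @param tokens_per_post Mean post length in tokens. Lengths are drawn as
#'   `26 + Poisson(mean - 26)` so every post passes the 25-word filter,
#'   unless `allow_short_posts` is set (then `1 + Poisson(mean - 1)`).
#' @param emission_rates Nested list `context -> group -> category -> rate`
#'   with contexts `MH`, `nonMH`, groups `mh_poster`, `non_mh_poster`, and
#'   the five categories `posemo`, `anxiety`, `anger`, `sadness`, `i`.
#'   Each cell's rates must sum to at most 1.
#' @param p_excluded_phrase Per-user probability of carrying an
#'   exclusion-phrase post (applied by [plant_contamination()]).
#' @param p_psychotic_comorbid Per-user probability of carrying a
#'   psychotic-disorder self-diagnosis post (applied by
#'   [plant_contamination()]).
#' @param p_missing_age,p_missing_gender Per-user probability that the
#'   attribute table leaves the field empty.
#' @param allow_short_posts Allow posts under 26 tokens (for filter tests).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_users = 200L,
                         seed = 1L,
                         p_mh_poster = 0.76,
                         p_feminine = 0.52,
                         age_mean = 32,
                         age_sd = 9,
                         posts_per_user_per_context = 12,
                         tokens_per_post = 80,
                         emission_rates = default_emission_rates(),
                         p_excluded_phrase = 0,
                         p_psychotic_comorbid = 0,
                         p_missing_age = 0,
                         p_missing_gender = 0,
                         allow_short_posts = FALSE) {
  cfg <- list(n_users = as.integer(n_users), seed = as.integer(seed),
              p_mh_poster = p_mh_poster, p_feminine = p_feminine,
              age_mean = age_mean, age_sd = age_sd,
              posts_per_user_per_context = posts_per_user_per_context,
              tokens_per_post = tokens_per_post,
              emission_rates = emission_rates,
              p_excluded_phrase = p_excluded_phrase,
              p_psychotic_comorbid = p_psychotic_comorbid,
              p_missing_age = p_missing_age,
              p_missing_gender = p_missing_gender,
              allow_short_posts = isTRUE(allow_short_posts))
  probs <- c(p_mh_poster, p_feminine, p_excluded_phrase, p_psychotic_comorbid,
             p_missing_age, p_missing_gender)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_users < 1L) stop("n_users must be at least 1")
  if (!cfg$allow_short_posts && tokens_per_post < 26) {
    stop("tokens_per_post must be at least 26 unless allow_short_posts = TRUE")
  }
  for (ctx in c("MH", "nonMH")) {
    for (grp in c("mh_poster", "non_mh_poster")) {
      r <- unlist(emission_rates[[ctx]][[grp]][.categories])
      if (length(r) != 5L || any(is.na(r))) {
        stop("emission_rates[['", ctx, "']][['", grp,
             "']] must give all five categories")
      }
      if (any(r < 0 | r > 1)) stop("emission rates must lie in [0, 1]")
      if (sum(r) > 1) {
        stop("emission probabilities for (", ctx, ", ", grp, ") sum to ",
             round(sum(r), 4), " > 1")
      }
    }
  }
  class(cfg) <- "synth_config"
  cfg
}

.categories <- c("posemo", "anxiety", "anger", "sadness", "i")

#' Default planted emission rates
#'
#' Per-token category emission probabilities by posting context and user
#' group. MH-context rates are the canonical real-world post means for this
#' population divided by 100 (posemo 3.48, anxiety 0.67, anger 0.75,
#' sadness 0.81, first-person singular 8.82, as percentages); non-MH rates
#' likewise (3.64, 0.37, 0.78, 0.45, 6.39). Users who never post in MH
#' communities get slightly lower positive emotion, anxiety and sadness in
#' their non-MH posts, planting the between-user mood signal.
#'
#' @return Nested list `context -> group -> category -> rate`.
#' @export
default_emission_rates <- function() {
  mh_ctx <- list(posemo = 0.0348, anxiety = 0.0067, anger = 0.0075,
                 sadness = 0.0081, i = 0.0882)
  nonmh_poster <- list(posemo = 0.0364, anxiety = 0.0037, anger = 0.0078,
                       sadness = 0.0045, i = 0.0639)
  nonmh_nonposter <- list(posemo = 0.0345, anxiety = 0.0030, anger = 0.0078,
                          sadness = 0.0038, i = 0.0630)
  list(MH = list(mh_poster = mh_ctx, non_mh_poster = mh_ctx),
       nonMH = list(mh_poster = nonmh_poster, non_mh_poster = nonmh_nonposter))
}

.category_words <- c(posemo = "sweet", anxiety = "worried", anger = "annoyed",
                     sadness = "grief", i = "i")
.filler_words <- c("the", "and", "went", "to", "store", "today", "some",
                   "bread", "weather", "was", "outside", "garden", "needs",
                   "water", "table", "chair", "window", "river")
.mh_subreddits <- c("bipolar", "bipolarreddit", "bipolar2", "depression",
                    "anxiety", "mentalhealth")
.nonmh_subreddits <- c("askreddit", "gaming", "movies", "cooking", "music",
                       "gardening", "personalfinance", "science")

.diagnosis_templates <- c(
  "I was diagnosed with bipolar disorder last year and it explained a lot.",
  "My psychiatrist diagnosed me with bipolar disorder after a long assessment.",
  "I was diagnosed with bipolar type 2 a while back."
)
.exclusion_templates <- c(
  "To be honest I am not officially diagnosed, I just relate to the symptoms.",
  "I am basically self-diagnosed at this point, never saw a professional."
)
.psychotic_templates <- c(
  "A few years later I was also diagnosed with schizophrenia.",
  "I was diagnosed with schizoaffective disorder as well."
)

.synth_post_text <- function(len, rates) {
  p <- unlist(rates[.categories])
  draw <- sample.int(6L, len, replace = TRUE, prob = c(p, 1 - sum(p)))
  words <- character(len)
  is_cat <- draw <= 5L
  words[is_cat] <- .category_words[draw[is_cat]]
  n_fill <- sum(!is_cat)
  if (n_fill > 0L) {
    words[!is_cat] <- .filler_words[sample.int(length(.filler_words), n_fill,
                                               replace = TRUE)]
  }
  paste(words, collapse = " ")
}

#' Generate a synthetic corpus with planted structure
#'
#' Produces a post corpus, an attribute table and a planted-truth record
#' from a [synth_config()]. Every user carries at least one self-reported
#' bipolar-diagnosis statement post (kept under 25 words, so it counts for
#' posting patterns but never enters the score means); MH posters receive
#' posts in MH-flagged subreddits plus non-MH posts, other users post only
#' in non-MH subreddits; post tokens are i.i.d. draws in which each token is
#' a category word with its planted emission probability and otherwise a
#' neutral filler word.
#'
#' All randomness flows through one RNG stream seeded from `config$seed`, so
#' the same config yields a bit-identical corpus. Contamination
#' (exclusion phrases, psychotic-disorder statements) is applied separately
#' by [plant_contamination()].
#'
#' @param config A `synth_config`.
#' @return A list with `posts` (tibble), `attributes` (tibble) and `truth`
#'   (list: `users` tibble with per-user group/gender/age/planted flags,
#'   `emission_rates`, `expected_scores` tibble with the implied expected
#'   percentage score per cell).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_users
  authors <- sprintf("user%05d", seq_len(n))
  ppc <- config$posts_per_user_per_context
  tpp <- config$tokens_per_post
  t0 <- 1451606400 # 2016-01-01T00:00:00Z
  span <- 3 * 365 * 86400

  post_author <- list(); post_sub <- list(); post_time <- list()
  post_body <- list()
  group <- character(n); gender <- integer(n); age <- numeric(n)
  for (u in seq_len(n)) {
    group[u] <- if (stats::runif(1) < config$p_mh_poster) "mh_poster" else "non_mh_poster"
    gender[u] <- if (stats::runif(1) < config$p_feminine) 0L else 1L
    age[u] <- round(max(13, stats::rnorm(1, config$age_mean, config$age_sd)), 1)

    # both groups share the same expected total activity (2 * ppc posts);
    # group membership shifts where users post, not how much
    if (group[u] == "mh_poster") {
      n_mh <- 1L + stats::rpois(1, max(0, ppc - 1))
      n_nonmh <- 1L + stats::rpois(1, max(0, ppc - 1))
    } else {
      n_mh <- 0L
      n_nonmh <- 2L + stats::rpois(1, 2 * max(0, ppc - 1))
    }

    subs <- character(0); bodies <- character(0)
    # the diagnosis statement post (always in a non-MH community)
    subs <- c(subs, .nonmh_subreddits[sample.int(length(.nonmh_subreddits), 1)])
    bodies <- c(bodies, .diagnosis_templates[sample.int(length(.diagnosis_templates), 1)])
    if (n_mh > 0L) {
      rates <- config$emission_rates[["MH"]][[group[u]]]
      for (k in seq_len(n_mh)) {
        len <- if (config$allow_short_posts) 1L + stats::rpois(1, max(0, tpp - 1)) else 26L + stats::rpois(1, tpp - 26)
        subs <- c(subs, .mh_subreddits[sample.int(length(.mh_subreddits), 1)])
        bodies <- c(bodies, .synth_post_text(len, rates))
      }
    }
    rates <- config$emission_rates[["nonMH"]][[group[u]]]
    for (k in seq_len(n_nonmh)) {
      len <- if (config$allow_short_posts) 1L + stats::rpois(1, max(0, tpp - 1)) else 26L + stats::rpois(1, tpp - 26)
      subs <- c(subs, .nonmh_subreddits[sample.int(length(.nonmh_subreddits), 1)])
      bodies <- c(bodies, .synth_post_text(len, rates))
    }
    times <- t0 + floor(stats::runif(length(subs)) * span)
    post_author[[u]] <- rep(authors[u], length(subs))
    post_sub[[u]] <- subs
    post_time[[u]] <- times
    post_body[[u]] <- bodies
  }
  posts <- tibble::tibble(
    id = sprintf("p%07d", seq_along(unlist(post_author))),
    author = unlist(post_author),
    subreddit = unlist(post_sub),
    created_utc = unlist(post_time),
    body = unlist(post_body)
  )
  miss_age <- stats::runif(n) < config$p_missing_age
  miss_gender <- stats::runif(n) < config$p_missing_gender
  attributes <- tibble::tibble(
    author = authors,
    age = ifelse(miss_age, NA_real_, age),
    gender = ifelse(miss_gender, NA_integer_, gender)
  )
  expected <- do.call(rbind, lapply(c("MH", "nonMH"), function(ctx) {
    do.call(rbind, lapply(c("mh_poster", "non_mh_poster"), function(grp) {
      data.frame(context = ctx, group = grp, category = .categories,
                 expected_score = 100 * unlist(config$emission_rates[[ctx]][[grp]][.categories]),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  truth <- list(
    users = tibble::tibble(author = authors, group = group, gender = gender,
                           age = age, posted_in_MH = as.integer(group == "mh_poster"),
                           excluded_phrase = FALSE, psychotic = FALSE),
    emission_rates = config$emission_rates,
    expected_scores = tibble::as_tibble(expected)
  )
  list(posts = posts, attributes = attributes, truth = truth, config = config)
}

#' Plant cohort contamination into a synthetic corpus
#'
#' With probability `p_excluded_phrase` (resp. `p_psychotic_comorbid`) per
#' user, appends one extra post containing an exclusion phrase (resp. a
#' psychotic-disorder self-diagnosis statement). The planted truth records
#' which users were contaminated, so cohort mining can be checked against it
#' exactly.
#'
#' @param sim Result of [synth_generate()].
#' @param p_excluded_phrase,p_psychotic_comorbid Override the probabilities
#'   in `sim$config`.
#' @param seed RNG seed for the contamination draws; defaults to
#'   `sim$config$seed + 1` so that contamination is reproducible and
#'   independent of the generation stream.
#' @return `sim` with contaminated posts appended and truth flags updated.
#' @export
plant_contamination <- function(sim,
                                p_excluded_phrase = sim$config$p_excluded_phrase,
                                p_psychotic_comorbid = sim$config$p_psychotic_comorbid,
                                seed = sim$config$seed + 1L) {
  stopifnot(is.list(sim), !is.null(sim$posts), !is.null(sim$truth))
  if (p_excluded_phrase == 0 && p_psychotic_comorbid == 0) return(sim)
  set.seed(seed)
  users <- sim$truth$users
  n <- nrow(users)
  excl <- stats::runif(n) < p_excluded_phrase
  psych <- stats::runif(n) < p_psychotic_comorbid
  extra_author <- character(0); extra_body <- character(0)
  for (u in seq_len(n)) {
    if (excl[u]) {
      extra_author <- c(extra_author, users$author[u])
      extra_body <- c(extra_body, .exclusion_templates[sample.int(length(.exclusion_templates), 1)])
    }
    if (psych[u]) {
      extra_author <- c(extra_author, users$author[u])
      extra_body <- c(extra_body, .psychotic_templates[sample.int(length(.psychotic_templates), 1)])
    }
  }
  if (length(extra_author) > 0L) {
    extra <- tibble::tibble(
      id = sprintf("x%07d", seq_along(extra_author)),
      author = extra_author,
      subreddit = .nonmh_subreddits[sample.int(length(.nonmh_subreddits),
                                               length(extra_author), replace = TRUE)],
      created_utc = 1451606400 + floor(stats::runif(length(extra_author)) * 3 * 365 * 86400),
      body = extra_body
    )
    sim$posts <- tibble::as_tibble(rbind(sim$posts, extra))
  }
  sim$truth$users$excluded_phrase <- excl
  sim$truth$users$psychotic <- psych
  sim
}
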