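day <- 86400

test_that("active days and activity follow the stated formulas", {
  # 20 posts spanning 10 UTC days
  posts <- do.call(rbind, lapply(1:20, function(k) {
    scored_row(paste0("p", k), "u1", "nonMH",
               1451606400 + (k - 1) * (10 * day) / 19, wc = 30)
  }))
  rec <- build_user_records("u1", posts)
  expect_equal(rec$active_days, 10)
  expect_equal(rec$activity, 2.0)
  expect_equal(rec$posted_in_MH, 0L)

  # single-post user: active_days floors at 1
  rec1 <- build_user_records("u2", scored_row("q1", "u2", "MH", 1451606400, 30))
  expect_equal(rec1$active_days, 1)
  expect_equal(rec1$activity, 1)
  expect_equal(rec1$posted_in_MH, 1L)
})

test_that("context means use only filtered posts and NA when none qualify", {
  posts <- rbind(
    scored_row("a", "u1", "MH", 1451606400, wc = 30, anxiety = 2),
    scored_row("b", "u1", "MH", 1451606400 + day, wc = 10, anxiety = 50),
    scored_row("c", "u1", "nonMH", 1451606400 + 2 * day, wc = 40, anxiety = 1),
    scored_row("d", "u1", "nonMH", 1451606400 + 3 * day, wc = 26, anxiety = 3)
  )
  rec <- build_user_records("u1", posts)
  expect_equal(rec$mean_mh_anxiety, 2)   # the 10-word post is excluded
  expect_equal(rec$mean_nonmh_anxiety, 2)
  expect_equal(rec$n_mh_all, 2L)
  expect_equal(rec$n_mh_posts, 1L)

  only_short <- scored_row("e", "u2", "MH", 1451606400, wc = 5, anxiety = 9)
  rec2 <- build_user_records("u2", only_short)
  expect_true(is.na(rec2$mean_mh_anxiety))
  expect_equal(rec2$posted_in_MH, 1L) # unfiltered count drives the outcome
})

test_that("a cohort author with zero posts is an error", {
  posts <- scored_row("a", "u1", "MH", 1451606400, 30)
  expect_error(build_user_records(c("u1", "ghost"), posts), "ghost")
})

test_that("planted per-user means sit within 3 binomial SEs", {
  cfg <- synth_config(n_users = 1, seed = 55, p_mh_poster = 0,
                      posts_per_user_per_context = 15, tokens_per_post = 100)
  sim <- synth_generate(cfg)
  tax <- load_taxonomy(example_taxonomy_path())
  sim$posts$context <- classify_context(sim$posts$subreddit, tax)
  scored <- score_posts(sim$posts, default_lexicon())
  rec <- build_user_records(sim$truth$users$author, scored, sim$attributes)
  rate <- sim$config$emission_rates$nonMH$non_mh_poster$anxiety
  tokens <- sum(scored$wc[scored$wc >= 25])
  se <- 100 * sqrt(rate * (1 - rate) / tokens)
  expect_lt(abs(rec$mean_nonmh_anxiety - 100 * rate), 3 * se)
})

test_that("posting partition classifies and stratifies users", {
  mk <- function(author, n_mh, n_nonmh) {
    rows <- list()
    for (k in seq_len(n_mh)) rows[[length(rows) + 1]] <-
      scored_row(paste0(author, "m", k), author, "MH", 1451606400 + k * day, 30)
    for (k in seq_len(n_nonmh)) rows[[length(rows) + 1]] <-
      scored_row(paste0(author, "n", k), author, "nonMH", 1451606400 + k * day, 30)
    do.call(rbind, rows)
  }
  posts <- rbind(mk("both", 4, 4), mk("onlym", 9, 0), mk("onlyn", 0, 2))
  rec <- build_user_records(c("both", "onlym", "onlyn"), posts)
  p <- partition_rq1(rec)
  expect_equal(unname(p$proportions), rep(1 / 3, 3))
  expect_equal(sum(p$proportions), 1)
  expect_equal(unname(p$strata["active_both"]), 1L)   # 4 + 4 qualifies
  expect_equal(unname(p$strata["only_mh_min"]), 1L)   # 9 >= 8
  expect_equal(unname(p$strata["only_nonmh_min"]), 0L)
  expect_equal(unname(p$low_activity["only_nonmh"]), 1L)

  # all-both corpus: single-context proportions are zero
  rec2 <- build_user_records(c("b1", "b2"), rbind(mk("b1", 1, 1), mk("b2", 2, 2)))
  p2 <- partition_rq1(rec2)
  expect_equal(unname(p2$proportions["only_mh"]), 0)
  # reordering users leaves the partition unchanged
  p3 <- partition_rq1(rec2[2:1, ])
  expect_equal(p2$proportions, p3$proportions)
})

test_that("eligibility rules apply their boundaries exactly", {
  rec <- tibble::tibble(
    author = c("a", "b", "c", "d", "e", "f"),
    age = c(30, 30, NA, 30, 30, 41), gender = c(0L, 1L, 1L, NA, 0L, 1L),
    active_days = 10, activity = 1,
    n_mh_all = c(5L, 3L, 0L, 5L, 1L, 0L), n_nonmh_all = c(9L, 9L, 9L, 9L, 9L, 9L),
    n_mh_posts = c(4L, 3L, 0L, 4L, 1L, 0L), n_nonmh_posts = c(4L, 9L, 8L, 4L, 8L, 9L),
    posted_in_MH = c(1L, 1L, 0L, 1L, 1L, 0L)
  )
  for (cat in c("posemo", "anxiety", "anger", "sadness", "i")) {
    rec[[paste0("mean_mh_", cat)]] <- 1
    rec[[paste0("mean_nonmh_", cat)]] <- 1
  }
  expect_equal(select_rq2(rec)$author, c("a", "d")) # 4-and-4 is eligible; 3 is not
  s3 <- select_rq3(rec)
  # a: outcome 1; f: 0 MH posts + >= 8 qualifying non-MH -> outcome 0;
  # c would be outcome 0 but has missing age; d is eligible but missing
  # gender; e has 1 MH post and too few filtered MH posts -> neither rule
  expect_equal(sort(s3$author), c("a", "f"))
  expect_equal(s3$outcome[s3$author == "f"], 0L)
  expect_error(select_rq3(rec[1, ]), "single outcome class")

  rec$age[3] <- 28
  s3 <- select_rq3(rec)
  expect_equal(sort(s3$author), c("a", "c", "f"))
  expect_equal(s3$outcome[s3$author == "c"], 0L)
  # outcome-group consistency
  expect_true(all(s3$n_mh_all[s3$outcome == 0] == 0))
  expect_true(all(s3$n_mh_posts[s3$outcome == 1] >= 4))
})
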