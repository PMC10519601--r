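#' Build user-level records
#'
#' Aggregates classified, scored posts into one record per cohort author:
#' context-stratified mean scores over the posts passing the word-count
#' filter, unfiltered per-context post counts, the activity control
#' variables, attributes and the binary outcome `posted_in_MH`.
#'
#' Per-context means are unweighted means over that user's qualifying posts
#' (each post counts equally, regardless of length), reflecting the
#' post-level operationalisation of emotion whose average over time stands
#' for mood. `active_days` is `max(1, ceiling((last - first)/86400))` in UTC
#' seconds, and `activity` is total (unfiltered) posts per active day; the
#' floor of one day keeps the ratio defined for single-post users.
#'
#' @param cohort_authors Character vector of included authors (e.g.
#'   `build_cohort(...)$authors`).
#' @param posts Scored, classified post tibble: the columns of
#'   [score_posts()] output plus a `context` column (`"MH"`/`"nonMH"`, from
#'   [classify_context()]).
#' @param attributes Attribute tibble ([read_attributes()]); authors absent
#'   from it get missing age and gender.
#' @param min_wc Word-count filter applied to the score means (default 25).
#' @return A tibble, one row per cohort author: `author`, `age`, `gender`,
#'   `active_days`, `activity`, `n_mh_all`, `n_nonmh_all`, `n_mh_posts`,
#'   `n_nonmh_posts`, `posted_in_MH`, and per-context mean scores
#'   `mean_mh_<cat>` / `mean_nonmh_<cat>` (NA where the context has no
#'   qualifying posts).
#' @export
build_user_records <- function(cohort_authors, posts, attributes = NULL,
                               min_wc = 25L) {
  need <- c("id", "author", "context", "created_utc", "wc", .categories)
  miss <- setdiff(need, names(posts))
  if (length(miss) > 0L) stop("posts missing column(s): ",
                              paste(miss, collapse = ", "))
  if (!all(posts$context %in% c("MH", "nonMH"))) {
    stop("context must be 'MH' or 'nonMH'")
  }
  cohort_authors <- unique(cohort_authors)
  absent <- setdiff(cohort_authors, posts$author)
  if (length(absent) > 0L) {
    stop("cohort author(s) with zero posts: ", paste(absent, collapse = ", "))
  }
  posts <- posts[posts$author %in% cohort_authors, , drop = FALSE]
  idx <- split(seq_len(nrow(posts)), posts$author)

  rows <- lapply(cohort_authors, function(a) {
    p <- posts[idx[[a]], , drop = FALSE]
    is_mh <- p$context == "MH"
    qual <- p$wc >= min_wc
    span <- max(p$created_utc) - min(p$created_utc)
    active_days <- max(1, ceiling(span / 86400))
    rec <- list(author = a,
                active_days = active_days,
                activity = nrow(p) / active_days,
                n_mh_all = sum(is_mh),
                n_nonmh_all = sum(!is_mh),
                n_mh_posts = sum(is_mh & qual),
                n_nonmh_posts = sum(!is_mh & qual),
                posted_in_MH = as.integer(any(is_mh)))
    for (cat in .categories) {
      v_mh <- p[[cat]][is_mh & qual]
      v_non <- p[[cat]][!is_mh & qual]
      rec[[paste0("mean_mh_", cat)]] <- if (length(v_mh) > 0L) mean(v_mh) else NA_real_
      rec[[paste0("mean_nonmh_", cat)]] <- if (length(v_non) > 0L) mean(v_non) else NA_real_
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  if (!is.null(attributes)) {
    m <- match(out$author, attributes$author)
    out$age <- attributes$age[m]
    out$gender <- attributes$gender[m]
  } else {
    out$age <- NA_real_
    out$gender <- NA_integer_
  }
  out[, c("author", "age", "gender", "active_days", "activity",
          "n_mh_all", "n_nonmh_all", "n_mh_posts", "n_nonmh_posts",
          "posted_in_MH",
          paste0("mean_mh_", .categories), paste0("mean_nonmh_", .categories))]
}

#' Partition users by posting context
#'
#' The first analysis: the share of users who posted only in MH
#' subreddits, only in non-MH subreddits, or in both, on unfiltered post
#' counts. Also reports the activity strata: "active contributors" posting
#' in both contexts with at least `active_min` posts in each; only-MH and
#' only-non-MH users with at least `only_min` posts; and, per class, the
#' users with fewer than `only_min` total posts.
#'
#' @param records User-record tibble from [build_user_records()].
#' @param active_min Post threshold per context for active contributors
#'   (default 4).
#' @param only_min Post threshold for single-context users (default 8).
#' @return A list: `n_users`, `proportions` (named: both / only_mh /
#'   only_nonmh, summing to 1), `counts`, `strata` (active_both,
#'   only_mh_min8, only_nonmh_min8), `low_activity` (users with fewer than
#'   `only_min` total posts, by class), and `table` (tidy tibble of all of
#'   the above as shares of all users).
#' @export
partition_rq1 <- function(records, active_min = 4L, only_min = 8L) {
  if (nrow(records) == 0L) stop("no user records")
  both <- records$n_mh_all >= 1L & records$n_nonmh_all >= 1L
  only_mh <- records$n_mh_all >= 1L & records$n_nonmh_all == 0L
  only_nonmh <- records$n_mh_all == 0L & records$n_nonmh_all >= 1L
  n <- nrow(records)
  counts <- c(both = sum(both), only_mh = sum(only_mh),
              only_nonmh = sum(only_nonmh))
  total <- records$n_mh_all + records$n_nonmh_all
  strata <- c(
    active_both = sum(both & records$n_mh_all >= active_min &
                        records$n_nonmh_all >= active_min),
    only_mh_min = sum(only_mh & records$n_mh_all >= only_min),
    only_nonmh_min = sum(only_nonmh & records$n_nonmh_all >= only_min)
  )
  low <- c(both = sum(both & total < only_min),
           only_mh = sum(only_mh & total < only_min),
           only_nonmh = sum(only_nonmh & total < only_min))
  tab <- tibble::tibble(
    stratum = c("both", "only_mh", "only_nonmh", "active_both",
                "only_mh_min", "only_nonmh_min",
                "both_low", "only_mh_low", "only_nonmh_low"),
    n = as.integer(c(counts, strata, low)),
    share = c(counts, strata, low) / n
  )
  list(n_users = n, proportions = counts / n, counts = counts,
       strata = strata, low_activity = low, table = tab)
}

#' Select users for the within-user comparison
#'
#' Keeps users with at least `min_posts` qualifying (word-count-filtered)
#' posts in each of the two contexts, the eligibility rule for the paired
#' emotion comparison.
#'
#' @param records User-record tibble.
#' @param min_posts Minimum filtered posts per context (default 4).
#' @return The eligible rows of `records`.
#' @export
select_rq2 <- function(records, min_posts = 4L) {
  records[records$n_mh_posts >= min_posts & records$n_nonmh_posts >= min_posts, ,
          drop = FALSE]
}

#' Select the between-user regression sample
#'
#' Outcome 1: users eligible for the within-user comparison (at least
#' `rq2_min` qualifying posts in each context). Outcome 0: users with no MH
#' posts at all and at least `rq3_min` qualifying non-MH posts. Users with
#' missing age or gender are dropped (listwise deletion of the control
#' variables).
#'
#' @param records User-record tibble.
#' @param rq2_min Per-context threshold for the outcome-1 group (default 4).
#' @param rq3_min Non-MH threshold for the outcome-0 group (default 8).
#' @return The sampled rows with an `outcome` column (= `posted_in_MH`).
#' @export
select_rq3 <- function(records, rq2_min = 4L, rq3_min = 8L) {
  pos <- records$n_mh_posts >= rq2_min & records$n_nonmh_posts >= rq2_min
  neg <- records$n_mh_all == 0L & records$n_nonmh_posts >= rq3_min
  out <- records[pos | neg, , drop = FALSE]
  out <- out[!is.na(out$age) & !is.na(out$gender), , drop = FALSE]
  out$outcome <- out$posted_in_MH
  if (length(unique(out$outcome)) < 2L) {
    stop("regression sample contains a single outcome class")
  }
  out
}
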