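test_that("paired comparison reproduces hand-computed cases", {
  # identical vectors: no effect
  r <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p_bonf, 1)
  expect_equal(r$d, 0)

  # differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, d_z = 2
  r <- paired_comparison(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$d_z, 2)
  expect_equal(r$df, 2L)

  expect_error(paired_comparison(c(1, 2), c(0, 1, 2)), "equal length")
  expect_error(paired_comparison(1, 0), "at least 2")
  expect_error(paired_comparison(c(2, 3, 4), c(1, 2, 3)), "degenerate")
})

test_that("paired comparison agrees with the t.test oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    mh <- rnorm(n, 1, 0.5); nonmh <- rnorm(n, 0.8, 0.4)
    r <- paired_comparison(mh, nonmh)
    tt <- t.test(mh, nonmh, paired = TRUE)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    expect_equal(r$p_bonf, min(1, 5 * tt$p.value), tolerance = 1e-12)
    expect_true(r$p_bonf >= r$p && r$p_bonf <= 1)
    expect_equal(sign(r$d), sign(r$mean_mh - r$mean_nonmh))
  }
})

test_that("effect sizes carry the conventional magnitude labels", {
  expect_equal(interpret_effect_size(c(-0.20, 0.97, -0.07, 1.11, 1.63)),
               c("Small", "Large", "Very small", "Large", "Very large"))
})

test_that("logistic slope on a 2x2 design equals the closed-form log odds ratio", {
  d <- design_2x2(10, 10, 5, 20)
  fit <- fit_logistic(d$design, d$outcome)
  expect_equal(fit$beta[["x"]], log(4), tolerance = 1e-7)
  expect_equal(fit$beta[["intercept"]], log(5 / 20), tolerance = 1e-7)

  set.seed(8)
  for (rep in 1:25) {
    cell <- sample(3:30, 4, replace = TRUE)
    d <- design_2x2(cell[1], cell[2], cell[3], cell[4])
    fit <- fit_logistic(d$design, d$outcome)
    expect_lt(abs(fit$beta[["x"]] - logodds_2x2(cell[1], cell[2], cell[3], cell[4])),
              1e-6)
  }
})

test_that("intercept-only fit on a balanced outcome gives logit(0.5) = 0", {
  fit <- fit_logistic(NULL, rep(c(0, 1), 25))
  expect_equal(fit$beta[["intercept"]], 0, tolerance = 1e-8)
  expect_equal(fit$fit$ll, fit$fit$ll_null)
})

test_that("IRLS estimates, SEs and fit statistics match the glm oracle", {
  set.seed(99)
  n <- 300
  X <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n, 0, 10))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X$a - 0.6 * X$b + 0.1 * X$c))
  fit <- fit_logistic(X, y)
  g <- glm(y ~ a + b + c, data = cbind(X, y = y), family = binomial())
  expect_equal(unname(fit$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(g)))), tolerance = 1e-6)
  expect_equal(fit$fit$ll, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(fit$fit$aic, AIC(g), tolerance = 1e-6)
  expect_equal(fit$fit$bic, BIC(g), tolerance = 1e-6)
  # score equation at the optimum: X'(y - p) = 0
  Xm <- cbind(1, as.matrix(X))
  mu <- plogis(drop(Xm %*% fit$beta))
  expect_lt(max(abs(t(Xm) %*% (y - mu))), 1e-6)
  # Wald CI structure
  co <- fit$coefficients
  expect_true(all(co$ci_lo < co$beta & co$beta < co$ci_hi))
  expect_equal(co$or, exp(co$beta))
})

test_that("degenerate designs raise explicit errors", {
  set.seed(4)
  X <- data.frame(a = rnorm(50))
  X$twice_a <- 2 * X$a
  y <- rbinom(50, 1, 0.5)
  expect_error(fit_logistic(X, y), "collinear.*twice_a")

  # perfectly separated predictor
  xs <- c(rnorm(25, -3), rnorm(25, 3))
  ys <- as.integer(xs > 0)
  expect_error(fit_logistic(data.frame(x = xs), ys), "separation")

  expect_error(fit_logistic(data.frame(x = rnorm(10)), rep(1, 10)), "classes")
  expect_error(fit_logistic(data.frame(x = c(NA, rnorm(9))), rep(c(0, 1), 5)),
               "missing")
})

test_that("information criteria and pseudo-R2 follow their formulas", {
  ic <- information_criteria(-5227, 5, 10309)
  expect_equal(ic$aic, 10464)
  expect_equal(round(ic$bic), 10500)

  r2 <- pseudo_r2(-10, -5, 20)
  expect_equal(r2$hosmer_lemeshow, 0.5)
  expect_equal(r2$cox_snell, 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(r2$nagelkerke, (1 - exp(-0.5)) / (1 - exp(-1)), tolerance = 1e-12)

  r0 <- pseudo_r2(-10, -10, 20)
  expect_equal(unlist(r0), c(hosmer_lemeshow = 0, cox_snell = 0, nagelkerke = 0))
  expect_error(pseudo_r2(0, 0, 10), "degenerate")
  expect_error(pseudo_r2(-5, -10, 10), "ll_null")
})

test_that("likelihood-ratio test matches the chi-squared reference", {
  fake <- function(ll, k, n = 100) list(fit = list(ll = ll, k = k, n = n))
  r <- likelihood_ratio(fake(-50, 5), fake(-50, 10))
  expect_equal(r$x2, 0)
  expect_equal(r$p, 1)

  r <- likelihood_ratio(fake(-5227, 5), fake(-5192, 10))
  expect_equal(r$x2, 70)
  expect_equal(r$df, 5L)
  expect_lt(r$p, 0.001)
  expect_equal(r$p, pchisq(70, 5, lower.tail = FALSE))

  expect_error(likelihood_ratio(fake(-50, 5), fake(-60, 10)), "non-nested")
  expect_error(likelihood_ratio(fake(-50, 5), fake(-49, 5)), "at least one")
})

test_that("relative probability reproduces the sigmoid hand-calculation", {
  fake <- structure(list(beta = c(intercept = 0, gender = -0.79),
                         x_means = numeric(0), x_range = NULL),
                    class = "logistic_fit")
  expect_equal(relative_probability(fake),
               (plogis(0) - plogis(-0.79)) / plogis(-0.79) * 100,
               tolerance = 1e-12)
  expect_equal(round(relative_probability(fake), 1), 60.2)

  fake0 <- structure(list(beta = c(intercept = 0.3, gender = 0),
                          x_means = numeric(0), x_range = NULL),
                     class = "logistic_fit")
  expect_equal(relative_probability(fake0), 0)
})

test_that("planted regression coefficients are recovered within 3 SEs", {
  set.seed(314)
  sim <- simulate_rq3_design(2000)
  fit <- fit_logistic(sim$design, sim$outcome)
  est <- fit$coefficients
  for (j in seq_len(nrow(est))) {
    expect_lt(abs(est$beta[j] - sim$truth[[est$name[j]]]), 3 * est$se[j])
  }
})

test_that("gender-balanced down-sampling balances each outcome group", {
  set.seed(6)
  n <- 400
  rec <- tibble::tibble(
    author = sprintf("u%03d", 1:n),
    age = rnorm(n, 32, 8),
    gender = c(rep(0L, 60), rep(1L, 40), rep(0L, 170), rep(1L, 130)),
    active_days = runif(n, 10, 900), activity = rlnorm(n, log(0.05), 0.5),
    n_mh_all = c(rep(0L, 100), rep(5L, 300)),
    n_nonmh_all = 10L, n_mh_posts = c(rep(0L, 100), rep(5L, 300)),
    n_nonmh_posts = 9L,
    posted_in_MH = c(rep(0L, 100), rep(1L, 300))
  )
  for (cat in c("posemo", "anxiety", "anger", "sadness", "i")) {
    rec[[paste0("mean_mh_", cat)]] <- rnorm(n, 1, 0.2)
    rec[[paste0("mean_nonmh_", cat)]] <- rnorm(n, 1, 0.2)
  }
  s <- select_rq3(rec)
  bal <- gender_balanced_rerun(s, seed = 11)
  # group 0: 60 feminine / 40 masculine -> 80 kept
  g0 <- bal$sample[bal$sample$outcome == 0, ]
  expect_equal(nrow(g0), 80L)
  expect_equal(sum(g0$gender == 0), sum(g0$gender == 1))
  g1 <- bal$sample[bal$sample$outcome == 1, ]
  expect_equal(sum(g1$gender == 0), sum(g1$gender == 1))

  # already-balanced groups are left untouched
  rec2 <- rec[c(1:40, 61:100, 101:230, 271:400), ]
  s2 <- select_rq3(rec2)
  bal2 <- gender_balanced_rerun(s2, seed = 2)
  expect_equal(nrow(bal2$sample), nrow(s2))

  # single-gender group is an error
  rec3 <- rec
  rec3$gender[rec3$posted_in_MH == 0] <- 1L
  expect_error(gender_balanced_rerun(select_rq3(rec3)), "single gender")
})
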