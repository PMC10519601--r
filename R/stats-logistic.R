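#' Maximum-likelihood logistic regression via IRLS
#'
#' Fits a binomial logit model by iteratively reweighted least squares,
#' with explicit failure modes: iteration stops when the log-likelihood
#' changes by less than `tol` (default 1e-8), errors after `max_iter`
#' iterations without convergence, errors on a rank-deficient design
#' (naming the collinear columns) and on (quasi-)perfect separation
#' (diverging coefficients). Standard errors come from the inverse observed
#' information at the optimum; Wald confidence intervals use the 1.96
#' normal quantile; odds ratios are `exp` of the coefficients and their CI.
#'
#' The null (intercept-only) log-likelihood on the same sample is computed
#' alongside, feeding the information criteria, pseudo-R-squared measures
#' and likelihood-ratio comparisons.
#'
#' @param design Data frame (or matrix) of numeric predictors, one row per
#'   observation, without an intercept column; `NULL` fits the
#'   intercept-only model.
#' @param outcome 0/1 numeric vector, both classes present, no missing
#'   values.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum IRLS iterations.
#' @return A `logistic_fit` object: list with `coefficients` (tibble: name,
#'   beta, se, z, p, ci_lo, ci_hi, or, or_lo, or_hi), `fit` (list: ll,
#'   ll_null, k, n, aic, bic, df_resid, pseudo_r2, iterations), `beta`
#'   (named vector), `x_means`, `x_range`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rbinom(200, 1, plogis(0.3 + 0.8 * x))
#' fit_logistic(data.frame(x = x), y)
fit_logistic <- function(design, outcome, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be 0/1 with no missing values")
  n <- length(y)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (is.null(design)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    Xp <- as.matrix(design)
    if (nrow(Xp) != n) stop("design and outcome lengths differ")
    if (anyNA(Xp)) stop("missing predictor values (listwise-delete before fitting)")
    if (!is.numeric(Xp)) stop("predictors must be numeric")
    X <- cbind(intercept = 1, Xp)
  }
  k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  loglik <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    sum(stats::dbinom(y, 1, mu, log = TRUE))
  }
  beta <- numeric(k)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    ll_new <- loglik(beta_new)
    # step-halving keeps the likelihood monotone on difficult samples
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll - 1e-10) && halvings < 30L) {
      beta_new <- (beta_new + beta) / 2
      ll_new <- loglik(beta_new)
      halvings <- halvings + 1L
    }
    if (!is.finite(ll_new) || max(abs(beta_new)) > 1e3) {
      stop("perfect separation detected: coefficients diverge")
    }
    delta <- abs(ll_new - ll)
    beta <- beta_new
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("IRLS did not converge in ", max_iter, " iterations")
  mu <- stats::plogis(drop(X %*% beta))
  if (all(abs(y - mu) < 1e-8)) {
    stop("perfect separation detected: fitted probabilities are degenerate")
  }
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  z_stat <- beta / se
  p <- 2 * stats::pnorm(-abs(z_stat))
  ci_lo <- beta - 1.96 * se
  ci_hi <- beta + 1.96 * se

  pbar <- mean(y)
  ll_null <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  ic <- information_criteria(ll, k, n)
  coefs <- tibble::tibble(
    name = colnames(X), beta = unname(beta), se = unname(se),
    z = unname(z_stat), p = unname(p),
    ci_lo = unname(ci_lo), ci_hi = unname(ci_hi),
    or = exp(unname(beta)), or_lo = exp(unname(ci_lo)), or_hi = exp(unname(ci_hi))
  )
  names(beta) <- colnames(X)
  xm <- colMeans(X)[-1]
  xr <- if (k > 1L) apply(X[, -1, drop = FALSE], 2, range) else NULL
  structure(list(
    coefficients = coefs,
    fit = list(ll = ll, ll_null = ll_null, k = k, n = n,
               aic = ic$aic, bic = ic$bic, df_resid = n - k,
               pseudo_r2 = pseudo_r2(ll_null, ll, n),
               iterations = iter),
    beta = beta, x_means = xm, x_range = xr
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$fit$n, "\n")
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("LL = %.2f  AIC = %.1f  BIC = %.1f  df_resid = %d\n",
              x$fit$ll, x$fit$aic, x$fit$bic, x$fit$df_resid))
  r2 <- x$fit$pseudo_r2
  cat(sprintf("pseudo-R2: Hosmer-Lemeshow %.3f, Cox-Snell %.3f, Nagelkerke %.3f\n",
              r2$hosmer_lemeshow, r2$cox_snell, r2$nagelkerke))
  invisible(x)
}

#' Akaike and Bayesian information criteria
#'
#' `aic = 2k - 2ll`, `bic = k ln(n) - 2ll`.
#'
#' @param ll Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size (used by BIC only).
#' @return List with `aic` and `bic`.
#' @export
information_criteria <- function(ll, k, n) {
  stopifnot(k >= 0, n >= 1)
  list(aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll)
}

#' Likelihood-based pseudo-R-squared measures
#'
#' Three conventional goodness-of-fit summaries computed from the fitted
#' and null log-likelihoods: the likelihood-ratio index `1 - ll/ll_null`
#' (reported here under the Hosmer-Lemeshow label, following common
#' regression-text usage), Cox-Snell `1 - exp(2 (ll_null - ll)/n)` and
#' Nagelkerke (Cox-Snell rescaled to a maximum of 1).
#'
#' @param ll_null Intercept-only log-likelihood (must be negative).
#' @param ll Full-model log-likelihood, `ll >= ll_null`.
#' @param n Sample size.
#' @return List with `hosmer_lemeshow`, `cox_snell`, `nagelkerke`.
#' @export
pseudo_r2 <- function(ll_null, ll, n) {
  if (ll_null == 0) stop("degenerate null model: ll_null = 0")
  if (ll < ll_null - 1e-8) stop("ll must be >= ll_null")
  cs <- 1 - exp(2 * (ll_null - ll) / n)
  list(hosmer_lemeshow = 1 - ll / ll_null,
       cox_snell = cs,
       nagelkerke = cs / (1 - exp(2 * ll_null / n)))
}

#' Likelihood-ratio test of nested logistic models
#'
#' `x2 = 2 (ll_full - ll_nested)` on `k_full - k_nested` degrees of
#' freedom, with the chi-squared upper-tail p-value. Errors when the full
#' model's likelihood falls below the nested one beyond tolerance (the fits
#' are then not nested, or not converged).
#'
#' @param nested,full `logistic_fit` objects (or lists with `fit$ll`,
#'   `fit$k`) fitted on the same sample.
#' @return List with `x2`, `df`, `p`.
#' @export
likelihood_ratio <- function(nested, full) {
  lln <- nested$fit$ll; llf <- full$fit$ll
  if (nested$fit$n != full$fit$n) stop("models fitted on different sample sizes")
  x2 <- 2 * (llf - lln)
  if (x2 < -1e-6) stop("full model log-likelihood below nested model: non-nested or non-converged fits")
  x2 <- max(0, x2)
  df <- full$fit$k - nested$fit$k
  if (df < 1L) stop("full model must add at least one parameter")
  list(x2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Relative change in predicted probability across a binary predictor
#'
#' Evaluates the fitted probability at a covariate profile with the binary
#' predictor set to 0 and to 1, and reports the percent change
#' `(p(var = 0) - p(var = 1)) / p(var = 1) * 100`. With the default profile
#' (sample means of all other predictors) and `var = "gender"`, this is the
#' "how much more likely is a feminine-gender user to post in MH
#' subreddits" summary.
#'
#' @param fit A `logistic_fit`.
#' @param var Name of the binary predictor (default `"gender"`).
#' @param profile Named numeric vector of values for the other predictors;
#'   defaults to their sample means. A profile outside the observed
#'   predictor ranges triggers a warning.
#' @return Percent change (numeric scalar).
#' @export
relative_probability <- function(fit, var = "gender", profile = NULL) {
  beta <- fit$beta
  if (!var %in% names(beta)) stop("predictor '", var, "' not in the fit")
  others <- setdiff(names(beta), c("intercept", var))
  if (is.null(profile)) {
    profile <- fit$x_means[others]
  } else {
    miss <- setdiff(others, names(profile))
    if (length(miss) > 0L) stop("profile missing predictor(s): ",
                                paste(miss, collapse = ", "))
    profile <- profile[others]
    if (!is.null(fit$x_range) && length(others) > 0L) {
      rng <- fit$x_range[, others, drop = FALSE]
      outside <- profile < rng[1, ] | profile > rng[2, ]
      if (any(outside)) {
        warning("profile outside observed range for: ",
                paste(others[outside], collapse = ", "))
      }
    }
  }
  base <- beta[["intercept"]] +
    if (length(others) > 0L) sum(beta[others] * profile) else 0
  p0 <- stats::plogis(base)
  p1 <- stats::plogis(base + beta[[var]])
  (p0 - p1) / p1 * 100
}

#' Fit the between-user mood regression
#'
#' Fits the controls-only and full logistic models on a regression sample
#' (see [select_rq3()]) and compares them with a likelihood-ratio test. The
#' outcome is `posted_in_MH`; the controls are age, gender, active days and
#' activity; the five added mood predictors are the users' mean category
#' scores measured from their *non-MH* posts only, so that both outcome
#' groups are measured in a comparable context.
#'
#' @param sample Output of [select_rq3()].
#' @return List with `controls_fit`, `full_fit` (both `logistic_fit`) and
#'   `lrt` (from [likelihood_ratio()]).
#' @export
rq3_regression <- function(sample) {
  controls <- data.frame(age = sample$age, gender = sample$gender,
                         active_days = sample$active_days,
                         activity = sample$activity)
  mood <- sample[, paste0("mean_nonmh_", .categories)]
  names(mood) <- .categories
  full <- cbind(controls, as.data.frame(mood))
  controls_fit <- fit_logistic(controls, sample$outcome)
  full_fit <- fit_logistic(full, sample$outcome)
  list(controls_fit = controls_fit, full_fit = full_fit,
       lrt = likelihood_ratio(controls_fit, full_fit))
}

#' Refit on gender-balanced outcome groups
#'
#' Robustness check for the between-user regression: within each outcome
#' group, the majority gender is randomly down-sampled to the minority
#' count, and the model is refitted on the union. Seed-controlled so the
#' subsample is reproducible.
#'
#' @param sample Output of [select_rq3()] (needs `outcome` and `gender`).
#' @param seed Integer seed for the down-sampling.
#' @return List with `sample` (the balanced rows), `fit` (the refitted
#'   `logistic_fit` of the full model) and `n` (balanced sample size).
#' @export
gender_balanced_rerun <- function(sample, seed = 1L) {
  set.seed(seed)
  keep <- integer(0)
  for (g in sort(unique(sample$outcome))) {
    rows <- which(sample$outcome == g)
    tab <- table(factor(sample$gender[rows], levels = c(0, 1)))
    if (any(tab == 0L)) {
      stop("outcome group ", g, " contains a single gender; cannot balance")
    }
    m <- min(tab)
    for (sex in c(0L, 1L)) {
      srows <- rows[sample$gender[rows] == sex]
      keep <- c(keep, if (length(srows) > m) base::sample(srows, m) else srows)
    }
  }
  balanced <- sample[sort(keep), , drop = FALSE]
  res <- rq3_regression(balanced)
  list(sample = balanced, fit = res$full_fit, lrt = res$lrt, n = nrow(balanced))
}
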