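#' Dependent t-test with Cohen's d for one paired variable
#'
#' Compares a user-level score between the two posting contexts with a
#' dependent (paired) t-test. Differences are taken as MH minus non-MH, so a
#' positive statistic means higher scores in MH-context posts. The raw
#' two-sided p-value is Bonferroni-adjusted for `m` comparisons
#' (`p_bonf = min(1, m * p)`), `m = 5` by default for the five category
#' scores.
#'
#' Two paired effect-size variants are reported: `d_z = mean(diff)/sd(diff)`
#' (the default `d`) and `d_av = mean(diff)/sqrt((sd_mh^2 + sd_nonmh^2)/2)`,
#' which standardises by the average of the two context SDs and is the
#' variant comparable with summary-statistics recomputation.
#'
#' @param mh,nonmh Equal-length numeric vectors of per-user means in the MH
#'   and non-MH context.
#' @param variable Label carried into the result.
#' @param m Number of comparisons for the Bonferroni correction.
#' @return A one-row tibble: `variable`, `n`, `mean_mh`, `sd_mh`,
#'   `mean_nonmh`, `sd_nonmh`, `t`, `df`, `p`, `p_bonf`, `d` (= `d_z`),
#'   `d_z`, `d_av`, `interpretation`.
#' @export
#' @examples
#' paired_comparison(c(2, 4, 6), c(1, 2, 3))
paired_comparison <- function(mh, nonmh, variable = "score", m = 5L) {
  if (length(mh) != length(nonmh)) stop("paired vectors must have equal length")
  if (anyNA(mh) || anyNA(nonmh)) stop("paired vectors must not contain NA")
  n <- length(mh)
  if (n < 2L) stop("paired comparison needs at least 2 pairs")
  diff <- mh - nonmh
  sd_d <- stats::sd(diff)
  md <- mean(diff)
  if (sd_d == 0) {
    if (md != 0) stop("degenerate paired comparison: constant nonzero difference")
    t_stat <- 0; p <- 1; d_z <- 0
  } else {
    t_stat <- md / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    d_z <- md / sd_d
  }
  sd_av <- sqrt((stats::sd(mh)^2 + stats::sd(nonmh)^2) / 2)
  d_av <- if (sd_av > 0) md / sd_av else 0
  tibble::tibble(
    variable = variable, n = n,
    mean_mh = mean(mh), sd_mh = stats::sd(mh),
    mean_nonmh = mean(nonmh), sd_nonmh = stats::sd(nonmh),
    t = t_stat, df = n - 1L, p = p, p_bonf = min(1, m * p),
    d = d_z, d_z = d_z, d_av = d_av,
    interpretation = interpret_effect_size(d_z)
  )
}

#' Qualitative effect-size label
#'
#' Standard magnitude bands for Cohen's d: very small (< 0.2), small
#' (< 0.5), medium (< 0.8), large (< 1.2), very large (< 2), huge.
#'
#' @param d Numeric vector of effect sizes (sign is ignored).
#' @return Character vector of labels.
#' @export
interpret_effect_size <- function(d) {
  a <- abs(d)
  cut(a, breaks = c(-Inf, 0.2, 0.5, 0.8, 1.2, 2, Inf),
      labels = c("Very small", "Small", "Medium", "Large", "Very large", "Huge"),
      right = FALSE) |> as.character()
}

#' Within-user context comparison for all five categories
#'
#' Runs [paired_comparison()] for each category score over the eligible
#' users (see [select_rq2()]), Bonferroni-corrected for the five
#' comparisons.
#'
#' @param records User records restricted to the eligible set; the
#'   `mean_mh_*` / `mean_nonmh_*` columns must be complete.
#' @param m Number of comparisons for Bonferroni (default 5).
#' @return A tibble with one row per category.
#' @export
rq2_table <- function(records, m = 5L) {
  rows <- lapply(.categories, function(cat) {
    paired_comparison(records[[paste0("mean_mh_", cat)]],
                      records[[paste0("mean_nonmh_", cat)]],
                      variable = cat, m = m)
  })
  do.call(rbind, rows)
}
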