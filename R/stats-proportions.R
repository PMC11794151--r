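## Prevalence, penetrance and contingency-table statistics. Confidence
## intervals for proportions come from prop.test (Wilson score with
## continuity correction), the procedure population-biobank reports of
## this kind cite for their prevalence/penetrance CIs.

proportion_estimate <- function(k, n, label) {
  if (length(k) != 1L || length(n) != 1L) stop("scalar counts expected")
  if (n <= 0) stop("denominator must be positive")
  if (k < 0 || k > n) stop("need 0 <= numerator <= denominator")
  pt <- stats::prop.test(k, n)
  gmmp_estimate(estimate = k / n,
                ci_low = pt$conf.int[1], ci_high = pt$conf.int[2],
                p_value = pt$p.value,
                n_numerator = as.integer(k), n_denominator = as.integer(n),
                label = label)
}

#' Carrier prevalence with confidence interval
#'
#' Proportion of the cohort carrying a qualifying variant, with a Wilson
#' score interval with continuity correction. Also report it as a
#' percentage via [percent_1dp()] and as a ratio via [ratio_one_in_n()].
#'
#' @param n_het Number of heterozygotes.
#' @param n_total Cohort size.
#' @param label Optional label.
#' @return A [gmmp_estimate()].
#' @export
#' @examples
#' prev <- prevalence(283, 170503)
#' ratio_one_in_n(283, 170503)  # 602
prevalence <- function(n_het, n_total, label = "prevalence") {
  proportion_estimate(n_het, n_total, label)
}

#' Penetrance with confidence interval
#'
#' Fraction of heterozygotes ever recorded with the outcome; same
#' interval machinery as [prevalence()].
#'
#' @param n_affected Heterozygotes with the outcome.
#' @param n_het Number of heterozygotes.
#' @param label Optional label.
#' @return A [gmmp_estimate()].
#' @export
#' @examples
#' percent_1dp(penetrance(55, 1049)$estimate)  # 5.2
penetrance <- function(n_affected, n_het, label = "penetrance") {
  proportion_estimate(n_affected, n_het, label)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger
#' than the observed table's, with fixed margins. A table with an
#' all-zero margin carries no information and returns p = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: `a` and `b` are the first row
#'   (e.g. deceased heterozygotes / alive heterozygotes), `c` and `d` the
#'   second (deceased controls / alive controls).
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)  # 1
#' fisher_exact_2x2(43, 240, 18848, 151299)
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
    return(1)
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with a Woolf log-normal confidence interval;
#' zero cells get the Haldane-Anscombe 0.5 correction (applied to every
#' cell). Companion sanity check for [adjusted_or_logistic()].
#'
#' @param a,b,c,d Cell counts: exposed-case, exposed-noncase,
#'   unexposed-case, unexposed-noncase.
#' @return A [gmmp_estimate()]; p-value from [fisher_exact_2x2()].
#' @export
#' @examples
#' crude_or_2x2(7, 276, 1018, 169129)  # about 4.21
crude_or_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  gmmp_estimate(estimate = or,
                ci_low = exp(log(or) - z * se),
                ci_high = exp(log(or) + z * se),
                p_value = fisher_exact_2x2(a, b, c, d),
                n_numerator = as.integer(a + b),
                n_denominator = as.integer(a + b + c + d),
                label = "crude OR")
}

#' Demographic comparison table (Table-1 style)
#'
#' Compares heterozygotes to controls (or any two groups) on categorical
#' risk factors via [fisher_exact_2x2()] and on continuous ones via the
#' Welch two-sample t-test, formatted as `n (%)` and `mean (sd)` at
#' printed precision.
#'
#' @param cohort A cohort data frame ([build_analysis_cohort()]).
#' @param group_col Column defining the two groups.
#' @param groups Length-2 character vector naming the groups to compare
#'   (first is reported first).
#' @param categorical,continuous Variable names. Categoricals must be
#'   logical (or coercible); continuous numeric.
#' @return Data frame with one row per variable: formatted summaries per
#'   group and the p-value.
#' @export
compare_demographics <- function(cohort,
                                 group_col = "carrier_status",
                                 groups = c("HETEROZYGOTE", "CONTROL"),
                                 categorical = c("male", "smoking_ever",
                                                 "deceased"),
                                 continuous = c("age_current", "bmi")) {
  stopifnot(length(groups) == 2)
  g1 <- cohort[cohort[[group_col]] == groups[1], , drop = FALSE]
  g2 <- cohort[cohort[[group_col]] == groups[2], , drop = FALSE]
  if (!nrow(g1) || !nrow(g2)) stop("need two non-empty groups")
  rows <- list()
  for (v in categorical) {
    x1 <- as.logical(g1[[v]]); x2 <- as.logical(g2[[v]])
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    a <- sum(x1); b <- length(x1) - a
    c_ <- sum(x2); d <- length(x2) - c_
    fmt <- function(k, n) {
      if (n == 0) return(NA_character_)
      sprintf("%d (%s)", k, formatC(round_half_up(100 * k / n),
                                    format = "fg"))
    }
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      group1 = fmt(a, a + b), group2 = fmt(c_, c_ + d),
      p_value = if ((a + b) && (c_ + d)) fisher_exact_2x2(a, b, c_, d)
                else NA_real_,
      stringsAsFactors = FALSE)
  }
  for (v in continuous) {
    x1 <- g1[[v]][!is.na(g1[[v]])]; x2 <- g2[[v]][!is.na(g2[[v]])]
    fmt <- function(x) {
      if (!length(x)) return(NA_character_)
      sprintf("%s (%s)", formatC(round_half_up(mean(x), 1), format = "fg"),
              formatC(signif(stats::sd(x), 2), format = "fg"))
    }
    p <- if (length(x1) > 1 && length(x2) > 1 &&
             (stats::sd(x1) > 0 || stats::sd(x2) > 0))
      stats::t.test(x1, x2)$p.value else NA_real_
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            group1 = fmt(x1), group2 = fmt(x2),
                            p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "group1"] <- groups[1]
  names(out)[names(out) == "group2"] <- groups[2]
  out
}
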