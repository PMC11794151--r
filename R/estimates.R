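#' Point estimate with confidence interval
#'
#' Lightweight container used throughout the package for prevalence,
#' penetrance, odds-ratio, hazard-ratio and cumulative-risk estimates.
#' Raw (unrounded) values are stored; rendering to printed precision is a
#' separate pass (see [render_estimate()]).
#'
#' @param estimate Point estimate.
#' @param ci_low,ci_high 95\% confidence bounds (may be `NA`).
#' @param p_value Two-sided p-value or `NA`.
#' @param n_numerator,n_denominator The counts behind the estimate
#'   (e.g. carriers / cohort size), for audit.
#' @param label Human-readable label.
#'
#' @return An object of class `gmmp_estimate`.
#' @export
gmmp_estimate <- function(estimate, ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, n_numerator = NA_integer_,
                          n_denominator = NA_integer_, label = "") {
  if (all(is.finite(c(estimate, ci_low, ci_high)))) {
    if (ci_low > estimate + 1e-12 || ci_high < estimate - 1e-12)
      stop("confidence bounds do not bracket the estimate")
  }
  if (is.finite(n_numerator) && is.finite(n_denominator) &&
      n_numerator > n_denominator)
    stop("n_numerator exceeds n_denominator")
  structure(
    list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
         p_value = p_value, n_numerator = n_numerator,
         n_denominator = n_denominator, label = label),
    class = "gmmp_estimate"
  )
}

#' @export
print.gmmp_estimate <- function(x, ...) {
  cat(if (nzchar(x$label)) paste0(x$label, ": ") else "",
      signif(x$estimate, 4),
      sprintf(" (95%% CI %s-%s)", signif(x$ci_low, 4), signif(x$ci_high, 4)),
      if (is.finite(x$p_value)) sprintf(", p = %.3g", x$p_value) else "",
      "\n", sep = "")
  if (is.finite(x$n_numerator))
    cat("  n = ", x$n_numerator, "/", x$n_denominator, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.gmmp_estimate <- function(x, ...) {
  data.frame(label = x$label, estimate = x$estimate, ci_low = x$ci_low,
             ci_high = x$ci_high, p_value = x$p_value,
             n_numerator = x$n_numerator, n_denominator = x$n_denominator,
             stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' all printed percentages and 1-in-N ratios, as opposed to the IEEE
#' round-half-even of [round()].
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
#' @examples
#' round_half_up(2.5)      # 3, where round(2.5) is 2
#' round_half_up(36.73, 0) # 37
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Express a carrier count as a "1 in N" ratio
#'
#' @param numerator Number of carriers (or affected); must be positive.
#' @param denominator Total count; at least `numerator`.
#' @return Integer N such that the frequency is about 1 in N
#'   (`denominator / numerator` rounded half-up).
#' @export
#' @examples
#' ratio_one_in_n(283, 170503) # 602
#' ratio_one_in_n(5, 196)      # 39
ratio_one_in_n <- function(numerator, denominator) {
  if (length(numerator) != 1L || length(denominator) != 1L)
    stop("scalar counts expected")
  if (is.na(numerator) || is.na(denominator))
    stop("counts must not be missing")
  if (numerator == 0)
    stop("no carriers: 1-in-N ratio undefined for a zero numerator")
  if (numerator < 0 || denominator < numerator)
    stop("need 0 < numerator <= denominator")
  as.integer(round_half_up(denominator / numerator))
}

#' Format a proportion as a percentage at printed precision
#'
#' One decimal place, half-up.
#'
#' @param p Proportion in \[0, 1\].
#' @return Numeric percentage (e.g. `5.2`).
#' @export
#' @examples
#' percent_1dp(55 / 1049) # 5.2
percent_1dp <- function(p) round_half_up(100 * p, 1)

#' Render an estimate at printed precision
#'
#' Percentages to one decimal, ratios as `1:N`, confidence intervals as
#' `(a-b)`. No arithmetic besides rounding happens here.
#'
#' @param x A [gmmp_estimate()].
#' @param style `"ratio_percent"` renders `1:N [p%]` (penetrance style),
#'   `"percent_ci"` renders `p% (a-b)`, `"value_ci"` renders `v (a-b)`.
#' @return A single string.
#' @export
#' @examples
#' render_estimate(penetrance(5, 196), style = "ratio_percent") # "1:39 [2.6%]"
render_estimate <- function(x, style = c("percent_ci", "ratio_percent",
                                         "value_ci")) {
  style <- match.arg(style)
  fmt_num <- function(v) trimws(formatC(v, format = "fg", digits = 2))
  switch(style,
    ratio_percent = if (isTRUE(x$n_numerator == 0)) "0 [0%]" else
      sprintf("1:%d [%s%%]",
              ratio_one_in_n(x$n_numerator, x$n_denominator),
              formatC(percent_1dp(x$estimate), format = "fg")),
    percent_ci = sprintf("%s%% (%s-%s)",
                         formatC(percent_1dp(x$estimate), format = "fg"),
                         fmt_num(100 * x$ci_low), fmt_num(100 * x$ci_high)),
    value_ci = sprintf("%s (%s-%s)", fmt_num(x$estimate),
                       fmt_num(x$ci_low), fmt_num(x$ci_high))
  )
}
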