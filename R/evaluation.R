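# ---- Diagnostic-accuracy statistics ---------------------------------------

#' Wilson score 95\% confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric vector \code{c(lower, upper)} on the proportion scale,
#'   always inside \code{[0, 1]} and containing \code{x/n}.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

clopper_pearson_ci <- function(x, n, conf_level = 0.95) {
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Diagnostic performance of binary predictions
#'
#' Confusion counts and the standard diagnostic-accuracy statistics:
#' sensitivity \eqn{100\,tp/(tp+fn)}, specificity \eqn{100\,tn/(tn+fp)},
#' positive predictive value \eqn{100\,tp/(tp+fp)} and negative predictive
#' value \eqn{100\,tn/(tn+fn)}, each with a 95\% confidence interval
#' (Wilson score by default).  A statistic with an empty denominator (e.g.
#' PPV when nothing is predicted positive) is reported as \code{NA} rather
#' than silently zero.
#'
#' @param predictions Logical vector of test calls.
#' @param labels Logical vector of reference-standard labels; both classes
#'   must be present.
#' @param ci_method \code{"wilson"} (default) or \code{"clopper-pearson"}.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class \code{dse_performance}: list with counts
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn} and, for each of
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv}, a
#'   vector \code{c(estimate, lower, upper)} in percent.
#' @examples
#' performance(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
performance <- function(predictions, labels,
                        ci_method = c("wilson", "clopper-pearson"),
                        conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(predictions) == length(labels), length(labels) > 0)
  predictions <- as.logical(predictions)
  labels <- as.logical(labels)
  if (anyNA(predictions) || anyNA(labels)) stop("NA in predictions or labels")
  if (length(unique(labels)) < 2) {
    stop("both outcome classes must be present in the labels")
  }
  tp <- sum(predictions & labels)
  fp <- sum(predictions & !labels)
  tn <- sum(!predictions & !labels)
  fn <- sum(!predictions & labels)
  ci_fun <- if (ci_method == "wilson") wilson_ci else clopper_pearson_ci
  stat <- function(x, n) {
    if (n == 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    ci <- ci_fun(x, n, conf_level)
    c(estimate = 100 * x / n, lower = 100 * ci[[1]], upper = 100 * ci[[2]])
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = stat(tp, tp + fn),
         specificity = stat(tn, tn + fp),
         ppv = stat(tp, tp + fp),
         npv = stat(tn, tn + fn),
         ci_method = ci_method, conf_level = conf_level),
    class = "dse_performance"
  )
}

#' @export
print.dse_performance <- function(x, ...) {
  cat(sprintf("<dse_performance> tp=%d fp=%d tn=%d fn=%d (%s CI)\n",
              x$tp, x$fp, x$tn, x$fn, x$ci_method))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %5.1f (%.1f; %.1f)\n", m, v[1], v[2], v[3]))
  }
  invisible(x)
}

# One flat report row from predictions + labels.
performance_row <- function(predictions, labels, ci_method = "wilson") {
  pf <- performance(predictions, labels, ci_method = ci_method)
  data.frame(
    tp = pf$tp, fp = pf$fp, tn = pf$tn, fn = pf$fn,
    sens = pf$sensitivity[[1]], sens_lo = pf$sensitivity[[2]], sens_hi = pf$sensitivity[[3]],
    spec = pf$specificity[[1]], spec_lo = pf$specificity[[2]], spec_hi = pf$specificity[[3]],
    ppv = pf$ppv[[1]], ppv_lo = pf$ppv[[2]], ppv_hi = pf$ppv[[3]],
    npv = pf$npv[[1]], npv_lo = pf$npv[[2]], npv_hi = pf$npv[[3]],
    stringsAsFactors = FALSE
  )
}

#' Compare two estimates by 95\% CI overlap
#'
#' The study's significance rule: a difference between two statistics is
#' declared significant at the 0.05 level exactly when their 95\%
#' confidence intervals do not overlap.  Intervals sharing only an endpoint
#' count as overlapping (not significant).
#'
#' @param a,b Numeric vectors \code{c(lower, upper)}.
#' @return \code{TRUE} if significant (disjoint intervals), \code{FALSE}
#'   otherwise.
#' @examples
#' compare_by_ci_overlap(c(65.6, 85.2), c(82.8, 96.1))  # FALSE (overlap)
#' @export
compare_by_ci_overlap <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  max(a[1], b[1]) > min(a[2], b[2])
}

#' Mean percentage difference between paired observer measurements
#'
#' Observer-agreement statistic: the mean over pairs of the absolute
#' difference divided by the pair mean,
#' \eqn{|v_1 - v_2| / ((v_1 + v_2)/2)}.  Pairs whose mean is zero are
#' excluded with a warning (the ratio is undefined there).
#'
#' @param v1,v2 Numeric vectors of paired measurements by the two observers
#'   (or the two readings of one observer).
#' @return Non-negative scalar; 0 means perfect agreement.
#' @examples
#' mean_percentage_difference(c(11, 10), c(9, 10))  # 0.1
#' @export
mean_percentage_difference <- function(v1, v2) {
  stopifnot(length(v1) == length(v2), length(v1) > 0)
  m <- (v1 + v2) / 2
  bad <- m == 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with zero mean excluded")
    v1 <- v1[!bad]; v2 <- v2[!bad]; m <- m[!bad]
  }
  if (length(m) == 0) stop("no usable pairs")
  mean(abs(v1 - v2) / abs(m))
}

#' Percentage as printed in a results table
#'
#' \code{100 * numerator / denominator} rounded to one decimal, rounding
#' halves away from zero (the convention of printed clinical tables, unlike
#' R's banker's rounding).
#'
#' @param numerator,denominator Counts; \code{denominator > 0}.
#' @return Percentage rounded to one decimal place.
#' @examples
#' printed_percentage(76, 151)  # 50.3
#' @export
printed_percentage <- function(numerator, denominator) {
  stopifnot(all(denominator > 0))
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Format a study report as a readable table
#'
#' Renders the performance rows of \code{\link{run_study}} with each
#' statistic shown as \code{estimate (lower; upper)} in percent.
#'
#' @param report The \code{report} data frame of a \code{dse_study}.
#' @return Data frame of formatted strings, one row per group x method.
#' @export
format_report <- function(report) {
  f <- function(e, lo, hi) {
    ifelse(is.na(e), "-", sprintf("%.1f (%.1f; %.1f)", e, lo, hi))
  }
  data.frame(
    group = report$group,
    method = report$method,
    sensitivity = f(report$sens, report$sens_lo, report$sens_hi),
    specificity = f(report$spec, report$spec_lo, report$spec_hi),
    ppv = f(report$ppv, report$ppv_lo, report$ppv_hi),
    npv = f(report$npv, report$npv_lo, report$npv_hi),
    stringsAsFactors = FALSE
  )
}
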