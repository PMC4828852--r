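# ---- Step 2: threshold-anchored rescaling with zero imputation ------------

#' Standard logistic function
#'
#' \eqn{\varphi(y) = e^y / (1 + e^y)}, evaluated overflow-safely.
#'
#' @param y Numeric vector.
#' @return Values in \code{(0, 1)}.
#' @examples
#' logistic_phi(0)  # 0.5
#' @export
logistic_phi <- function(y) stats::plogis(y)

#' Rescaled logistic regression response r(x)
#'
#' Replaces a raw covariate value by its distance from the covariate's
#' optimal classification threshold, normalized to \code{[0, 1]}: with
#' \eqn{p = \varphi(\beta_0 + \beta_1 x)} and threshold \eqn{T},
#' \deqn{r(x) = (p - T) / (1 - T) \quad if p > T,}
#' \deqn{r(x) = (T - p) / T \quad if p \le T,}
#' and \eqn{r = 0} when \eqn{x} is missing.  Both branches are nonnegative,
#' vanish exactly at \eqn{p = T} (so the map is continuous across the
#' branch boundary) and approach 1 as the fitted probability approaches
#' 0 or 1; a missing value is therefore indistinguishable from an
#' exactly-threshold observation, which is what permits the complete-case-free
#' second fitting stage.
#'
#' Since \eqn{T \in (0,1)} is a threshold on the probability scale, the
#' branch condition compares \eqn{\varphi(\beta_0+\beta_1 x)} to \eqn{T};
#' \code{strict_fidelity = TRUE} instead compares the linear predictor
#' \eqn{\beta_0+\beta_1 x} itself to \eqn{T}.
#'
#' @param x Raw covariate value(s); \code{NA} for missing.
#' @param beta0,beta1 Univariable logistic coefficients of the covariate.
#' @param threshold Classification threshold \eqn{T} strictly in
#'   \code{(0, 1)}.
#' @param strict_fidelity Apply the branch condition to the linear
#'   predictor instead of the fitted probability (default \code{FALSE}).
#' @return Rescaled value(s) in \code{[0, 1]}.
#' @examples
#' rescale_value(0, beta0 = 0, beta1 = 1, threshold = 0.25)  # 1/3
#' rescale_value(NA, beta0 = 0, beta1 = 1, threshold = 0.25) # 0
#' @export
rescale_value <- function(x, beta0, beta1, threshold,
                          strict_fidelity = FALSE) {
  if (any(!is.finite(threshold)) || any(threshold <= 0) || any(threshold >= 1)) {
    stop("threshold must lie strictly in (0, 1)")
  }
  lp <- beta0 + beta1 * x
  p <- stats::plogis(lp)
  above <- if (strict_fidelity) lp > threshold else p > threshold
  r <- ifelse(above,
              (p - threshold) / (1 - threshold),
              (threshold - p) / threshold)
  r[is.na(x)] <- 0
  r
}

#' Rescale a screened feature for a vector of raw values
#'
#' Convenience wrapper applying \code{\link{rescale_value}} with the
#' coefficients and threshold stored in one \code{dse_screen} row.
#'
#' @param x Raw covariate values.
#' @param feature One-row subset of a \code{\link{screen_all}} result.
#' @param ... Passed to \code{\link{rescale_value}}.
#' @return Rescaled values in \code{[0, 1]}.
#' @export
rescale_feature <- function(x, feature, ...) {
  stopifnot(nrow(feature) == 1)
  rescale_value(x, feature$beta0, feature$beta1, feature$threshold, ...)
}

#' Build the complete rescaled feature matrix
#'
#' Applies the rescaling transformation to every patient x screened-feature
#' cell of a cohort, mapping missing measurements to zero, so the resulting
#' matrix has no missing entries and every entry lies in \code{[0, 1]}.
#'
#' @param cohort A \code{dse_cohort}.
#' @param screened A \code{\link{screen_all}} result (or compatible data
#'   frame with \code{feature_id}, \code{beta0}, \code{beta1},
#'   \code{threshold}).
#' @param strict_fidelity See \code{\link{rescale_value}}.
#' @return Numeric matrix, patients x features, rownames = patient ids,
#'   colnames = feature ids.
#' @export
build_matrix <- function(cohort, screened, strict_fidelity = FALSE) {
  if (nrow(screened) == 0) stop("no screened features to rescale")
  X <- cohort_covariates(cohort)
  missing_feat <- setdiff(screened$feature_id, colnames(X))
  if (length(missing_feat) > 0) {
    stop("cohort lacks screened covariate(s): ",
         paste(missing_feat, collapse = ", "))
  }
  out <- matrix(0, nrow(X), nrow(screened),
                dimnames = list(rownames(X), screened$feature_id))
  for (k in seq_len(nrow(screened))) {
    out[, k] <- rescale_value(
      X[, screened$feature_id[k]],
      screened$beta0[k], screened$beta1[k], screened$threshold[k],
      strict_fidelity = strict_fidelity
    )
  }
  out
}
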