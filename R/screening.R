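# ---- Step 1: univariable logistic screening -------------------------------

#' Univariable logistic fit of one covariate against a binary endpoint
#'
#' Fits \code{y ~ x} by maximum likelihood on complete cases and reports the
#' intercept, slope and two-sided Wald p-value for the slope.  Fits with
#' (quasi-)complete separation, where the MLE diverges, are flagged
#' degenerate rather than returned with unstable coefficients.
#'
#' @param x Numeric covariate values, \code{NA} allowed.
#' @param y Binary endpoint labels (logical or 0/1), same length as
#'   \code{x}.
#' @param min_per_class Minimum number of complete-case patients required in
#'   each outcome class (default 2).
#' @return Object of class \code{dse_unifit}: list with \code{beta0},
#'   \code{beta1}, \code{se1}, \code{p_value}, \code{n} (complete cases),
#'   \code{degenerate} flag and \code{reason} (\code{NA} when usable).
#' @export
fit_univariable <- function(x, y, min_per_class = 2) {
  stopifnot(length(x) == length(y))
  y <- as.integer(as.logical(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  out <- structure(
    list(beta0 = NA_real_, beta1 = NA_real_, se1 = NA_real_,
         p_value = NA_real_, n = length(x), degenerate = TRUE,
         reason = NA_character_),
    class = "dse_unifit"
  )
  if (length(x) == 0) { out$reason <- "all values missing"; return(out) }
  if (min(sum(y == 1), sum(y == 0)) < min_per_class) {
    out$reason <- "fewer than min_per_class patients in an outcome class"
    return(out)
  }
  if (stats::sd(x) == 0) { out$reason <- "constant covariate"; return(out) }

  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial())
  )
  cf <- fit$coefficients
  if (!fit$converged || any(!is.finite(cf)) || max(abs(cf[2] * stats::sd(x)), abs(cf[1])) > 20) {
    out$reason <- "quasi-complete separation (diverging MLE)"
    return(out)
  }
  # Wald covariance from the final IRLS weights
  W <- fit$weights
  X <- cbind(1, x)
  XtWX <- crossprod(X * W, X)
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) {
    out$reason <- "singular information matrix"
    return(out)
  }
  se1 <- sqrt(cov[2, 2])
  z <- cf[2] / se1
  out$beta0 <- unname(cf[1])
  out$beta1 <- unname(cf[2])
  out$se1 <- se1
  out$p_value <- unname(2 * stats::pnorm(-abs(z)))
  out$degenerate <- FALSE
  out
}

#' Optimal classification threshold for a univariable logistic fit
#'
#' Computes the cutpoint on the fitted-probability scale that maximizes
#' Youden's J (sensitivity + specificity - 1), scanning the midpoints
#' between consecutive distinct fitted probabilities; a patient is called
#' positive when the fitted probability is at or above the cutpoint.  When
#' an interval of cutpoints attains the maximum, its midpoint is returned
#' (the lowest such interval if several tie).
#'
#' @param fit A non-degenerate \code{\link{fit_univariable}} result.
#' @param x,y The covariate and labels the fit was obtained from
#'   (missing \code{x} entries are dropped).
#' @param criterion \code{"youden"} (default) or \code{"accuracy"}
#'   (maximizes the raw proportion correctly classified).
#' @return Threshold strictly inside \code{(0, 1)}.
#' @export
optimal_threshold <- function(fit, x, y, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  if (inherits(fit, "dse_unifit") && isTRUE(fit$degenerate)) {
    stop("cannot compute a threshold from a degenerate fit")
  }
  y <- as.integer(as.logical(y))
  ok <- !is.na(x) & !is.na(y)
  p <- stats::plogis(fit$beta0 + fit$beta1 * x[ok])
  y <- y[ok]
  u <- sort(unique(p))
  if (length(u) < 2) stop("constant fitted probabilities; threshold undefined")
  cand <- (u[-length(u)] + u[-1]) / 2
  # integer-arithmetic scoring keeps mathematically tied cutpoints exactly
  # tied, so the lowest maximizing interval is returned deterministically:
  # Youden's J orders as tp*N + tn*P, accuracy as tp + tn
  P <- sum(y == 1)
  N <- sum(y == 0)
  score <- vapply(cand, function(t) {
    tp <- sum(p >= t & y == 1)
    tn <- sum(p < t & y == 0)
    if (criterion == "youden") tp * N + tn * P else tp + tn
  }, numeric(1))
  cand[which.max(score)]
}

#' Screen all candidate covariates for one endpoint
#'
#' Step 1 of model construction.  Because quantitative parameter amplitudes
#' depend on segment location, each (parameter, segment, phase) combination
#' is screened separately: a simple logistic regression is fitted per
#' covariate against the endpoint on complete cases, covariates significant
#' at \code{alpha} (two-sided Wald test, no multiplicity correction) are
#' retained, and for each retained covariate the optimal classification
#' threshold and the corresponding raw-scale cutoff are computed.  The
#' visual covariate (stress-minus-rest WMSI) always enters as a candidate.
#'
#' @param cohort A \code{dse_cohort}.
#' @param endpoint \code{"any"} (at least one stenotic vessel), \code{"LAD"},
#'   \code{"LCX"} or \code{"RCA"}.
#' @param alpha Significance level for retention (default 0.05).
#' @param criterion Threshold criterion, see \code{\link{optimal_threshold}}.
#' @return Object of class \code{dse_screen}: data frame with one row per
#'   retained covariate (\code{feature_id}, \code{parameter}, \code{segment},
#'   \code{phase}, \code{beta0}, \code{beta1}, \code{p_value},
#'   \code{threshold}, \code{cutoff_raw}, \code{n}), with attributes
#'   \code{endpoint}, \code{alpha}, \code{n_candidates} and \code{excluded}
#'   (features excluded as degenerate, with reasons).
#' @export
screen_all <- function(cohort, endpoint = c("any", "LAD", "LCX", "RCA"),
                       alpha = 0.05, criterion = "youden") {
  endpoint <- match.arg(endpoint)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1)
  X <- cohort_covariates(cohort)
  y <- endpoint_labels(cohort, endpoint)

  rows <- vector("list", ncol(X))
  excl <- list()
  for (j in seq_len(ncol(X))) {
    fid <- colnames(X)[j]
    f <- fit_univariable(X[, j], y)
    if (f$degenerate) {
      excl[[length(excl) + 1]] <- data.frame(
        feature_id = fid, reason = f$reason, stringsAsFactors = FALSE
      )
      next
    }
    if (f$p_value >= alpha) next
    thr <- optimal_threshold(f, X[, j], y, criterion = criterion)
    parts <- if (fid == "delta_wmsi") c("delta_wmsi", NA, NA)
             else strsplit(fid, "|", fixed = TRUE)[[1]]
    rows[[j]] <- data.frame(
      feature_id = fid,
      parameter = parts[1], segment = parts[2], phase = parts[3],
      beta0 = f$beta0, beta1 = f$beta1, p_value = f$p_value,
      threshold = thr,
      cutoff_raw = (stats::qlogis(thr) - f$beta0) / f$beta1,
      n = f$n,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(
      feature_id = character(), parameter = character(), segment = character(),
      phase = character(), beta0 = numeric(), beta1 = numeric(),
      p_value = numeric(), threshold = numeric(), cutoff_raw = numeric(),
      n = integer(), stringsAsFactors = FALSE
    )
  }
  structure(out,
            endpoint = endpoint, alpha = alpha, n_candidates = ncol(X),
            excluded = if (length(excl)) do.call(rbind, excl) else NULL,
            class = c("dse_screen", "data.frame"))
}

#' @export
print.dse_screen <- function(x, ...) {
  cat(sprintf(
    "<dse_screen> endpoint '%s': %d of %d candidate covariates retained at alpha = %g\n",
    attr(x, "endpoint"), nrow(x), attr(x, "n_candidates"), attr(x, "alpha")
  ))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
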