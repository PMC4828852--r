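# ---- Step 3: stepwise logistic combination --------------------------------

#' Stepwise logistic regression on the rescaled feature matrix
#'
#' Combines the screened, rescaled covariates into one endpoint classifier
#' by stepwise logistic regression.  The default criterion is bidirectional
#' AIC selection starting from the intercept-only model; classical
#' p-value-driven forward selection (enter at 0.05, remove at 0.10) is
#' available via \code{criterion = "pvalue"}.  Coefficients of the final
#' covariate set are the refitted maximum-likelihood estimates; if the final
#' fit is separated (diverging coefficients) a ridge-penalized refit with a
#' small fixed penalty replaces it, with a warning.
#'
#' @param matrix Complete rescaled feature matrix from
#'   \code{\link{build_matrix}} (entries in \code{[0, 1]}, no \code{NA}).
#' @param y Binary endpoint labels, one per matrix row.
#' @param screened The \code{\link{screen_all}} result the matrix was built
#'   from; stored in the model so new patients can be rescaled identically.
#' @param endpoint Endpoint label carried in the model.
#' @param criterion \code{"aic"} (default) or \code{"pvalue"}.
#' @param decision_threshold Probability cutpoint used by
#'   \code{\link{classify}} (default 0.5).
#' @param strict_fidelity Branch-condition flag stored for prediction-time
#'   rescaling, see \code{\link{rescale_value}}.
#' @return Object of class \code{dse_model}: endpoint, screened feature
#'   table, selected feature ids, named coefficient vector (intercept
#'   first), decision threshold and selection criterion.
#' @export
stepwise_fit <- function(matrix, y, screened, endpoint = "any",
                         criterion = c("aic", "pvalue"),
                         decision_threshold = 0.5,
                         strict_fidelity = FALSE) {
  criterion <- match.arg(criterion)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  stopifnot(is.numeric(decision_threshold), decision_threshold >= 0,
            decision_threshold <= 1)

  k <- if (is.null(dim(matrix))) 0L else ncol(matrix)
  if (k == 0 || nrow(screened) == 0) {
    coefs <- c("(Intercept)" = stats::qlogis(mean(y)))
    return(new_dse_model(endpoint, screened, character(0), coefs,
                         decision_threshold, criterion, strict_fidelity))
  }
  stopifnot(nrow(matrix) == length(y), !anyNA(matrix))

  ids <- colnames(matrix)
  safe <- paste0("f", seq_len(k))
  df <- as.data.frame(matrix)
  names(df) <- safe
  df$.y <- y

  if (criterion == "aic") {
    sel_idx <- aic_stepwise(matrix, y)
    sel_safe <- safe[sel_idx]
  } else {
    sel_safe <- pvalue_stepwise(df, safe, enter = 0.05, remove = 0.10)
  }
  fit <- suppressWarnings(stats::glm(
    stats::reformulate(c("1", sel_safe), response = ".y"),
    family = stats::binomial(), data = df
  ))

  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || max(abs(cf)) > 15) {
    warning("separation in the final stepwise model; using a ridge-penalized refit")
    cf <- ridge_refit(df, sel_safe)
  }
  sel_ids <- ids[match(sel_safe, safe)]
  names(cf) <- c("(Intercept)", sel_ids)[seq_along(cf)]
  new_dse_model(endpoint, screened, sel_ids, cf,
                decision_threshold, criterion, strict_fidelity)
}

# Bidirectional stepwise selection by AIC (deviance + 2 * n_par) from the
# intercept-only model.  At every round the single addition or deletion
# yielding the lowest AIC is applied; selection stops when no move improves
# on the current AIC.  The IRLS search itself runs in compiled code; returns
# the column indices of the selected features.
aic_stepwise <- function(X, y, max_steps = 1000L) {
  .aic_stepwise_cpp(X, as.numeric(y), max_steps)
}

# Forward selection with backward pruning on Wald p-values.
pvalue_stepwise <- function(df, candidates, enter = 0.05, remove = 0.10) {
  sel <- character(0)
  repeat {
    pool <- setdiff(candidates, sel)
    best <- NULL; best_p <- enter
    for (v in pool) {
      fit <- suppressWarnings(stats::glm(
        stats::reformulate(c("1", sel, v), response = ".y"),
        family = stats::binomial(), data = df
      ))
      p <- tryCatch(summary(fit)$coefficients[v, 4], error = function(e) NA)
      if (!is.na(p) && p < best_p) { best <- v; best_p <- p }
    }
    if (is.null(best)) break
    sel <- c(sel, best)
    # backward pass
    repeat {
      fit <- suppressWarnings(stats::glm(
        stats::reformulate(c("1", sel), response = ".y"),
        family = stats::binomial(), data = df
      ))
      pv <- summary(fit)$coefficients[sel, 4, drop = TRUE]
      worst <- which.max(pv)
      if (length(pv) == 0 || pv[worst] <= remove) break
      sel <- sel[-worst]
    }
  }
  sel
}

# Ridge refit at a small fixed penalty; returns intercept + selected coefs.
ridge_refit <- function(df, sel_safe, lambda = 1e-2) {
  if (length(sel_safe) == 0) {
    return(c("(Intercept)" = stats::qlogis(mean(df$.y))))
  }
  X <- as.matrix(df[sel_safe])
  if (length(sel_safe) == 1) X <- cbind(X, 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(X, df$.y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  cf <- as.numeric(stats::coef(fit))[seq_len(length(sel_safe) + 1)]
  names(cf) <- c("(Intercept)", sel_safe)
  cf
}

new_dse_model <- function(endpoint, screened, selected, coefficients,
                          decision_threshold, criterion, strict_fidelity) {
  structure(
    list(endpoint = endpoint,
         screened = as.data.frame(screened),
         selected = selected,
         coefficients = coefficients,
         decision_threshold = decision_threshold,
         criterion = criterion,
         strict_fidelity = strict_fidelity),
    class = "dse_model"
  )
}

#' @export
print.dse_model <- function(x, ...) {
  cat(sprintf(
    "<dse_model> endpoint '%s': %d of %d screened features selected (%s)\n",
    x$endpoint, length(x$selected), nrow(x$screened), x$criterion
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted probability of the endpoint for each patient
#'
#' Rescales the patients' raw covariates with the screened features stored
#' in the model (missing values mapped to 0, so prediction never fails on
#' incomplete data) and evaluates
#' \eqn{\varphi(\beta_0 + \sum_k w_k \tilde{x}_k)} over the
#' stepwise-selected features.
#'
#' @param model A \code{\link{stepwise_fit}} result.
#' @param cohort A \code{dse_cohort} of patients to score.
#' @return Named numeric vector of probabilities in \code{(0, 1)}, one per
#'   patient.
#' @export
predict_proba <- function(model, cohort) {
  stopifnot(inherits(model, "dse_model"))
  n <- nrow(cohort$patients)
  lp <- rep(model$coefficients[["(Intercept)"]], n)
  if (length(model$selected) > 0) {
    sub <- model$screened[match(model$selected, model$screened$feature_id), ]
    R <- build_matrix(cohort, sub, strict_fidelity = model$strict_fidelity)
    lp <- lp + as.vector(R %*% model$coefficients[model$selected])
  }
  stats::setNames(stats::plogis(lp), cohort$patients$patient_id)
}

#' Classify patients with a fitted endpoint model
#'
#' Positive when the predicted probability is greater than or equal to the
#' model's decision threshold (ties are called positive).
#'
#' @inheritParams predict_proba
#' @param decision_threshold Optional override of the stored threshold.
#' @return Named logical vector, one call per patient.
#' @export
classify <- function(model, cohort, decision_threshold = NULL) {
  thr <- if (is.null(decision_threshold)) model$decision_threshold
         else decision_threshold
  predict_proba(model, cohort) >= thr
}

#' Fit one endpoint model from a raw cohort
#'
#' Runs screening, rescaling and stepwise combination for a single endpoint
#' on one cohort: the three construction steps end to end.
#'
#' @param cohort Training \code{dse_cohort}.
#' @param endpoint \code{"any"}, \code{"LAD"}, \code{"LCX"} or \code{"RCA"}.
#' @param alpha Screening significance level.
#' @param threshold_criterion Passed to \code{\link{optimal_threshold}}.
#' @param stepwise_criterion Passed to \code{\link{stepwise_fit}}.
#' @param decision_threshold Classification cutpoint stored in the model.
#' @param strict_fidelity See \code{\link{rescale_value}}.
#' @return A \code{dse_model}.
#' @export
fit_endpoint_model <- function(cohort, endpoint = "any", alpha = 0.05,
                               threshold_criterion = "youden",
                               stepwise_criterion = "aic",
                               decision_threshold = 0.5,
                               strict_fidelity = FALSE) {
  scr <- screen_all(cohort, endpoint, alpha = alpha,
                    criterion = threshold_criterion)
  y <- endpoint_labels(cohort, endpoint)
  if (nrow(scr) == 0) {
    return(stepwise_fit(matrix(numeric(0), nrow(cohort$patients), 0), y,
                        screened = scr, endpoint = endpoint,
                        criterion = stepwise_criterion,
                        decision_threshold = decision_threshold,
                        strict_fidelity = strict_fidelity))
  }
  R <- build_matrix(cohort, scr, strict_fidelity = strict_fidelity)
  stepwise_fit(R, y, screened = scr, endpoint = endpoint,
               criterion = stepwise_criterion,
               decision_threshold = decision_threshold,
               strict_fidelity = strict_fidelity)
}

#' Run the full model-construction and validation study
#'
#' Builds the four endpoint models (at least one stenosis per patient, LAD,
#' LCX, RCA) on the training cohort only, then evaluates each model and the
#' visual wall-motion criterion on both the training and the held-out
#' cohort, producing a diagnostic-performance report (sensitivity,
#' specificity, PPV, NPV with 95\% CIs per group x method).  Per-vessel
#' models are evaluated against that vessel's stenosis label over all
#' patients of the cohort; the visual criterion is evaluated against the
#' any-stenosis label.
#'
#' @param train,validation Two \code{dse_cohort}s with identical schema.
#' @param alpha,threshold_criterion,stepwise_criterion,decision_threshold,strict_fidelity
#'   Model-construction settings, see \code{\link{fit_endpoint_model}}.
#' @param ci_method Confidence-interval method for
#'   \code{\link{performance}}.
#' @return Object of class \code{dse_study}: list with \code{models} (one
#'   \code{dse_model} per endpoint), \code{report} (data frame of
#'   performance rows) and \code{settings}.
#' @export
run_study <- function(train, validation, alpha = 0.05,
                      threshold_criterion = "youden",
                      stepwise_criterion = "aic",
                      decision_threshold = 0.5,
                      strict_fidelity = FALSE,
                      ci_method = "wilson") {
  check_schema_match(train, validation)
  endpoints <- c("any", .dse_vessels)
  models <- lapply(endpoints, function(ep) {
    fit_endpoint_model(train, ep, alpha = alpha,
                       threshold_criterion = threshold_criterion,
                       stepwise_criterion = stepwise_criterion,
                       decision_threshold = decision_threshold,
                       strict_fidelity = strict_fidelity)
  })
  names(models) <- endpoints

  cohorts <- list(test = train, validation = validation)
  rows <- list()
  for (g in names(cohorts)) {
    coh <- cohorts[[g]]
    rows[[length(rows) + 1]] <- cbind(
      data.frame(group = g, method = "visual", stringsAsFactors = FALSE),
      performance_row(coh$patients$visual_positive,
                      endpoint_labels(coh, "any"), ci_method)
    )
    for (ep in endpoints) {
      rows[[length(rows) + 1]] <- cbind(
        data.frame(group = g,
                   method = if (ep == "any") "model_patient"
                            else paste0("model_", ep),
                   stringsAsFactors = FALSE),
        performance_row(classify(models[[ep]], coh),
                        endpoint_labels(coh, ep), ci_method)
      )
    }
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(models = models, report = report,
                 settings = list(alpha = alpha,
                                 threshold_criterion = threshold_criterion,
                                 stepwise_criterion = stepwise_criterion,
                                 decision_threshold = decision_threshold,
                                 strict_fidelity = strict_fidelity,
                                 ci_method = ci_method)),
            class = "dse_study")
}

check_schema_match <- function(a, b) {
  for (coh in list(a, b)) {
    if (!inherits(coh, "dse_cohort")) stop("inputs must be dse_cohort objects")
  }
  ka <- unique(paste(a$segments$segment, a$segments$parameter, a$segments$phase))
  kb <- unique(paste(b$segments$segment, b$segments$parameter, b$segments$phase))
  if (!setequal(ka, kb)) {
    stop("train and validation cohorts carry different segment/parameter schemas")
  }
  if (length(intersect(a$patients$patient_id, b$patients$patient_id)) > 0) {
    warning("train and validation cohorts share patient ids; ",
            "validation performance will not be independent")
  }
  invisible(TRUE)
}

#' @export
print.dse_study <- function(x, ...) {
  cat("<dse_study>\n")
  for (ep in names(x$models)) {
    cat(sprintf("  %s: %d features selected\n", ep,
                length(x$models[[ep]]$selected)))
  }
  cat("\n")
  print(format_report(x$report))
  invisible(x)
}

#' Youden's J of a set of binary predictions
#'
#' Sensitivity plus specificity minus one; 0 for chance-level and 1 for
#' perfect discrimination.
#'
#' @param predictions,labels Logical vectors of equal length.
#' @return Youden's J in \code{[-1, 1]}.
#' @export
youden_j <- function(predictions, labels) {
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  sens <- mean(predictions[labels])
  spec <- mean(!predictions[!labels])
  sens + spec - 1
}
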