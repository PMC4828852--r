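# ---- CSV / JSON round-trips and fixtures ----------------------------------

#' Write a cohort to two CSV files
#'
#' Long-format segment table (\code{patient_id, group, segment, parameter,
#' phase, value}; an empty cell encodes a missing measurement) and patient
#' table (\code{patient_id, group, wmsi_rest, wmsi_stress, visual_positive,
#' LAD, LCX, RCA}).  UTF-8, header row, dot decimal separator.
#'
#' @param cohort A \code{dse_cohort}.
#' @param segment_csv,patient_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, segment_csv, patient_csv) {
  utils::write.csv(cohort$segments, segment_csv, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  p <- cohort$patients
  p$any_stenosis <- NULL  # derived on read
  utils::write.csv(p, patient_csv, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(c(segment_csv, patient_csv))
}

#' Read a cohort from two CSV files
#'
#' Inverse of \code{\link{write_cohort}}, with schema validation: unknown
#' segment or parameter names, duplicated (patient, segment, parameter,
#' phase) rows, non-binary vessel labels and non-numeric values are
#' rejected with informative errors.  Empty value cells become missing
#' measurements (never zero); \code{any_stenosis} is re-derived as the OR
#' of the vessel flags.
#'
#' @param segment_csv,patient_csv Input paths.
#' @return A \code{dse_cohort}.
#' @export
read_cohort <- function(segment_csv, patient_csv) {
  s <- utils::read.csv(segment_csv, stringsAsFactors = FALSE,
                       colClasses = c(value = "character"))
  p <- utils::read.csv(patient_csv, stringsAsFactors = FALSE)

  need_s <- c("patient_id", "group", "segment", "parameter", "phase", "value")
  if (!all(need_s %in% names(s))) {
    stop("segment CSV must have columns: ", paste(need_s, collapse = ", "))
  }
  bad_seg <- setdiff(unique(s$segment), dse_segments())
  if (length(bad_seg) > 0) {
    rows <- which(s$segment %in% bad_seg)[1]
    stop("unknown segment name(s) ", paste(bad_seg, collapse = ", "),
         " (first at row ", rows, ")")
  }
  bad_par <- setdiff(unique(s$parameter), .dse_parameter_table$parameter)
  if (length(bad_par) > 0) {
    stop("unknown parameter name(s): ", paste(bad_par, collapse = ", "))
  }
  if (!all(s$phase %in% .dse_phases)) stop("phase must be 'rest' or 'stress'")
  key <- paste(s$patient_id, s$segment, s$parameter, s$phase)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, segment, parameter, phase) row at line ",
         which(duplicated(key))[1] + 1)
  }
  raw <- trimws(s$value)
  val <- suppressWarnings(as.numeric(raw))
  if (any(!is.na(raw) & raw != "" & is.na(val))) {
    stop("non-numeric measurement value(s) in segment CSV")
  }
  val[raw == "" | is.na(raw)] <- NA_real_
  s$value <- val

  need_p <- c("patient_id", "group", "wmsi_rest", "wmsi_stress",
              "visual_positive", "LAD", "LCX", "RCA")
  if (!all(need_p %in% names(p))) {
    stop("patient CSV must have columns: ", paste(need_p, collapse = ", "))
  }
  for (v in c("LAD", "LCX", "RCA", "visual_positive")) {
    col <- p[[v]]
    if (is.numeric(col) && !all(col %in% c(0, 1))) {
      stop("label column ", v, " must be binary (0/1 or TRUE/FALSE)")
    }
    p[[v]] <- as.logical(col)
    if (anyNA(p[[v]])) stop("label column ", v, " must be binary")
  }
  if (!all(s$patient_id %in% p$patient_id)) {
    stop("segment CSV references patient(s) absent from patient CSV")
  }
  p$any_stenosis <- p$LAD | p$LCX | p$RCA
  new_cohort(p[c(need_p, "any_stenosis")], s[need_s])
}

#' Save / load a fitted endpoint model as JSON
#'
#' Models round-trip through a versioned JSON schema at full numeric
#' precision, so a reloaded model reproduces the original's predictions
#' bit-identically.
#'
#' @param model A \code{dse_model}.
#' @param path Output (or input) JSON path.
#' @return \code{write_model}: the path, invisibly.  \code{read_model}: the
#'   \code{dse_model}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "dse_model"))
  obj <- list(
    schema = "dsemodel/1",
    endpoint = model$endpoint,
    criterion = model$criterion,
    decision_threshold = model$decision_threshold,
    strict_fidelity = model$strict_fidelity,
    selected = model$selected,
    coefficients = as.list(model$coefficients),
    screened = model$screened
  )
  # 17 significant digits guarantee bit-identical double round trips
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "dsemodel/1") {
    stop("unrecognized model schema in ", path)
  }
  screened <- as.data.frame(obj$screened, stringsAsFactors = FALSE)
  new_dse_model(
    endpoint = obj$endpoint,
    screened = screened,
    selected = as.character(unlist(obj$selected)),
    coefficients = unlist(obj$coefficients),
    decision_threshold = obj$decision_threshold,
    criterion = obj$criterion,
    strict_fidelity = isTRUE(obj$strict_fidelity)
  )
}

#' Write a study performance report to CSV
#'
#' @param study A \code{dse_study} (or its \code{report} data frame).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(study, path) {
  report <- if (inherits(study, "dse_study")) study$report else study
  utils::write.csv(report, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Small deterministic cohorts for worked examples and tests
#'
#' Hand-constructed cohorts of at most 10 patients exercising edge cases:
#' \describe{
#'   \item{\code{"complete"}}{8 patients, no missing values, a real
#'     stenosis effect.}
#'   \item{\code{"null"}}{10 patients whose labels are independent of all
#'     covariates.}
#'   \item{\code{"separable"}}{8 patients with one covariate perfectly
#'     separating the labels.}
#'   \item{\code{"missing-heavy"}}{10 patients with half of all segment
#'     cells missing.}
#' }
#'
#' @param name Fixture name.
#' @return A \code{dse_cohort}.
#' @export
fixture_cohort <- function(name = c("complete", "null", "separable",
                                    "missing-heavy")) {
  name <- match.arg(name)
  base_cfg <- function(n, eff, miss_s = 0, seed) {
    cohort_config(n_patients = n, prevalence_any = 0.5, effect_size = eff,
                  missing_rate_rest = 0, missing_rate_stress = miss_s,
                  group = "test", seed = seed)
  }
  switch(name,
    "complete" = simulate_cohort(base_cfg(8, 2.0, 0, 421)),
    "null" = simulate_cohort(base_cfg(10, 0, 0, 422)),
    "separable" = {
      coh <- simulate_cohort(base_cfg(8, 0, 0, 423))
      # force perfect separation on one covariate
      pick <- coh$segments$segment == "apical septal" &
        coh$segments$parameter == "systolic_strain" &
        coh$segments$phase == "stress"
      lab <- coh$patients$any_stenosis[
        match(coh$segments$patient_id[pick], coh$patients$patient_id)]
      coh$segments$value[pick] <- ifelse(lab, -5, -25)
      coh
    },
    "missing-heavy" = simulate_cohort(base_cfg(10, 1.0, 0.5, 424))
  )
}

#' Read study settings from a YAML configuration file
#'
#' Validates and returns a study configuration: two cohort sections
#' (\code{train}, \code{validation}) accepted by \code{\link{cohort_config}}
#' plus pipeline settings (\code{alpha}, \code{stepwise_criterion},
#' \code{ci_method}, \code{decision_threshold}, \code{strict_fidelity},
#' \code{seed}).  Cohort seeds default to offsets of the global seed.
#'
#' @param path YAML file path.
#' @return Named list with elements \code{train}, \code{validation}
#'   (\code{dse_config}s) and \code{settings}.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configuration")
  }
  raw <- yaml::read_yaml(path)
  build_study_config(raw)
}

build_study_config <- function(raw = list()) {
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  mk <- function(section, preset, default_seed) {
    args <- if (is.null(raw[[section]])) list() else raw[[section]]
    if (!is.null(args$vessel_probs)) args$vessel_probs <- unlist(args$vessel_probs)
    if (is.null(args$seed)) args$seed <- default_seed
    args$preset <- preset
    do.call(cohort_config, args)
  }
  settings <- list(
    alpha = if (is.null(raw$alpha)) 0.05 else raw$alpha,
    threshold_criterion = if (is.null(raw$threshold_criterion)) "youden"
                          else raw$threshold_criterion,
    stepwise_criterion = if (is.null(raw$stepwise_criterion)) "aic"
                         else raw$stepwise_criterion,
    decision_threshold = if (is.null(raw$decision_threshold)) 0.5
                         else raw$decision_threshold,
    strict_fidelity = isTRUE(raw$strict_fidelity),
    ci_method = if (is.null(raw$ci_method)) "wilson" else raw$ci_method,
    seed = seed
  )
  list(
    train = mk("train", "test", seed),
    validation = mk("validation", "validation", seed + 1000L),
    settings = settings
  )
}
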