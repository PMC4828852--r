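# ---- Synthetic DSE cohort generator ---------------------------------------

#' Configuration for a synthetic DSE cohort
#'
#' Bundles and validates every knob of the cohort simulator.  The two presets
#' reproduce the shapes of the study cohorts: the model-construction ("test")
#' cohort of 151 patients with 50.3\% prevalence of significant coronary
#' stenosis and segment missingness of 2.1\% at rest / 5.0\% at stress, and
#' the independent validation cohort of 105 patients with 65.7\% prevalence
#' and missingness 2.5\% / 5.2\%.
#'
#' @param n_patients Number of patients (positive integer).
#' @param prevalence_any Probability that a patient has at least one
#'   stenotic vessel, in \code{[0, 1]}.
#' @param vessel_probs Named vector of per-vessel stenosis probabilities
#'   (\code{LAD}, \code{LCX}, \code{RCA}) conditional on the patient being
#'   diseased; draws are renormalized so that at least one vessel is
#'   involved, allowing multivessel disease.
#' @param effect_size Standardized mean shift (in stress-phase SD units)
#'   applied to stress-phase parameters of segments in a stenotic vessel's
#'   territory, in the ischemic direction for each parameter family.
#' @param missing_rate_rest,missing_rate_stress Per-cell probability that a
#'   segment measurement is uninterpretable (missing), by phase.
#' @param noise_sd_by_param Optional named vector of multipliers applied to
#'   each parameter's measurement SD (default 1 for all).
#' @param wmsi_delta_mean_diseased,wmsi_delta_sd_diseased Mean/SD of the
#'   stress-minus-rest WMSI increment in diseased patients.
#' @param wmsi_delta_mean_healthy,wmsi_delta_sd_healthy Same for patients
#'   without significant stenosis.
#' @param group Cohort label, \code{"test"} or \code{"validation"}.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param preset \code{"test"} or \code{"validation"} to load the study-shaped
#'   defaults for that cohort; explicit arguments override preset values.
#' @return Object of class \code{dse_config} (a validated list).
#' @examples
#' cfg <- cohort_config(preset = "test", seed = 7)
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = NULL, prevalence_any = NULL,
                          vessel_probs = c(LAD = 0.55, LCX = 0.40, RCA = 0.50),
                          effect_size = 0.8,
                          missing_rate_rest = NULL, missing_rate_stress = NULL,
                          noise_sd_by_param = NULL,
                          wmsi_delta_mean_diseased = 0.25,
                          wmsi_delta_sd_diseased = 0.15,
                          wmsi_delta_mean_healthy = 0.03,
                          wmsi_delta_sd_healthy = 0.08,
                          group = NULL, seed = 1L,
                          preset = c("test", "validation")) {
  preset <- match.arg(preset)
  pre <- if (preset == "test") {
    list(n_patients = 151L, prevalence_any = 0.503,
         missing_rate_rest = 0.021, missing_rate_stress = 0.050,
         group = "test")
  } else {
    list(n_patients = 105L, prevalence_any = 0.657,
         missing_rate_rest = 0.025, missing_rate_stress = 0.052,
         group = "validation")
  }
  cfg <- list(
    n_patients = if (is.null(n_patients)) pre$n_patients else n_patients,
    prevalence_any = if (is.null(prevalence_any)) pre$prevalence_any else prevalence_any,
    vessel_probs = vessel_probs,
    effect_size = effect_size,
    missing_rate_rest = if (is.null(missing_rate_rest)) pre$missing_rate_rest else missing_rate_rest,
    missing_rate_stress = if (is.null(missing_rate_stress)) pre$missing_rate_stress else missing_rate_stress,
    noise_sd_by_param = noise_sd_by_param,
    wmsi_delta_mean_diseased = wmsi_delta_mean_diseased,
    wmsi_delta_sd_diseased = wmsi_delta_sd_diseased,
    wmsi_delta_mean_healthy = wmsi_delta_mean_healthy,
    wmsi_delta_sd_healthy = wmsi_delta_sd_healthy,
    group = if (is.null(group)) pre$group else group,
    seed = seed
  )
  validate_cohort_config(cfg)
  class(cfg) <- "dse_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  stopifnot(
    "n_patients must be a positive integer" =
      num1(cfg$n_patients) && cfg$n_patients >= 1 &&
      cfg$n_patients == round(cfg$n_patients)
  )
  for (f in c("prevalence_any", "missing_rate_rest", "missing_rate_stress")) {
    v <- cfg[[f]]
    if (!num1(v) || v < 0 || v > 1) {
      stop(f, " must be a single value in [0, 1]")
    }
  }
  if (!num1(cfg$effect_size)) stop("effect_size must be a single finite number")
  vp <- cfg$vessel_probs
  if (!is.numeric(vp) || !all(.dse_vessels %in% names(vp)) ||
      any(!is.finite(vp)) || any(vp < 0 | vp > 1)) {
    stop("vessel_probs must be a named numeric vector with finite LAD, LCX, RCA entries in [0, 1]")
  }
  if (sum(vp[.dse_vessels]) <= 0 && cfg$prevalence_any > 0) {
    stop("vessel_probs must have at least one positive entry when prevalence_any > 0")
  }
  if (!is.null(cfg$noise_sd_by_param)) {
    nm <- names(cfg$noise_sd_by_param)
    bad <- setdiff(nm, .dse_parameter_table$parameter)
    if (length(bad) > 0) stop("unknown parameter(s) in noise_sd_by_param: ",
                              paste(bad, collapse = ", "))
    if (any(!is.finite(cfg$noise_sd_by_param)) || any(cfg$noise_sd_by_param < 0)) {
      stop("noise_sd_by_param entries must be finite and non-negative")
    }
  }
  for (f in grep("^wmsi_delta", names(cfg), value = TRUE)) {
    if (!num1(cfg[[f]])) stop(f, " must be a single finite number")
  }
  if (!num1(cfg$seed)) stop("seed must be a single finite number")
  invisible(cfg)
}

#' Simulate a synthetic DSE cohort
#'
#' Generates a seeded cohort of patients with per-vessel angiographic
#' stenosis labels, rest/stress wall motion score index (WMSI), a visual
#' positivity call, and the full long table of segment-level quantitative
#' speckle-tracking measurements (12 segments x 13 parameters x 2 phases per
#' patient, see \code{\link{dse_parameters}}).  For each stenotic vessel,
#' stress-phase values of segments in that vessel's territory are shifted by
#' \code{effect_size} measurement SDs in the ischemic direction (strain
#' magnitude blunted, time-to-peak prolonged, S' reduced, post-systolic and
#' positive systolic strain augmented).  Measurements are set missing
#' completely at random at the phase-specific rate.  Visual positivity is
#' defined as a stress-minus-rest WMSI increment of at least 0.13.
#'
#' @param config A \code{\link{cohort_config}} object.
#' @param territory_map Optional override of the segment-to-vessel map
#'   passed to \code{\link{territory_of}}.
#' @return Object of class \code{dse_cohort}: a list with data frames
#'   \code{patients} (one row per patient: \code{patient_id}, \code{group},
#'   \code{wmsi_rest}, \code{wmsi_stress}, \code{visual_positive},
#'   \code{LAD}, \code{LCX}, \code{RCA}, \code{any_stenosis}) and
#'   \code{segments} (long format: \code{patient_id}, \code{group},
#'   \code{segment}, \code{parameter}, \code{phase}, \code{value}, with
#'   \code{NA} for uninterpretable measurements).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 20, seed = 1))
#' head(coh$patients)
#' @export
simulate_cohort <- function(config, territory_map = NULL) {
  validate_cohort_config(config)
  n <- as.integer(config$n_patients)
  par_tab <- .dse_parameter_table
  segs <- dse_segments()

  with_seed(config$seed, {
    ids <- sprintf("%s_%04d", substr(config$group, 1, 1), seq_len(n))

    # vessel labels: diseased patients get independent per-vessel draws,
    # rejected until at least one vessel is involved
    diseased <- stats::runif(n) < config$prevalence_any
    vess <- matrix(FALSE, n, 3, dimnames = list(NULL, .dse_vessels))
    idx <- which(diseased)
    while (length(idx) > 0) {
      draw <- matrix(
        stats::runif(length(idx) * 3) <
          rep(config$vessel_probs[.dse_vessels], each = length(idx)),
        ncol = 3
      )
      vess[idx, ] <- draw
      idx <- idx[rowSums(draw) == 0]
    }

    wmsi_rest <- pmin(4, pmax(1, stats::rnorm(n, 1.02, 0.04)))
    delta <- ifelse(
      diseased,
      stats::rnorm(n, config$wmsi_delta_mean_diseased, config$wmsi_delta_sd_diseased),
      stats::rnorm(n, config$wmsi_delta_mean_healthy, config$wmsi_delta_sd_healthy)
    )
    wmsi_stress <- pmin(4, pmax(1, wmsi_rest + delta))

    patients <- data.frame(
      patient_id = ids,
      group = config$group,
      wmsi_rest = wmsi_rest,
      wmsi_stress = wmsi_stress,
      visual_positive = (wmsi_stress - wmsi_rest) >= 0.13,
      LAD = vess[, "LAD"], LCX = vess[, "LCX"], RCA = vess[, "RCA"],
      any_stenosis = diseased,
      stringsAsFactors = FALSE
    )

    # long segment table: patients x segments x parameters x phases
    grid <- expand.grid(
      patient_id = ids, segment = segs,
      parameter = par_tab$parameter, phase = .dse_phases,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    pi <- match(grid$parameter, par_tab$parameter)
    at_stress <- grid$phase == "stress"
    mu <- ifelse(at_stress, par_tab$stress_mean[pi], par_tab$rest_mean[pi])
    sd0 <- ifelse(at_stress, par_tab$stress_sd[pi], par_tab$rest_sd[pi])
    if (!is.null(config$noise_sd_by_param)) {
      mult <- config$noise_sd_by_param[grid$parameter]
      sd0 <- sd0 * ifelse(is.na(mult), 1, mult)
    }
    value <- mu + sd0 * stats::rnorm(nrow(grid))

    # ischemic shift on stress-phase cells in stenotic territories
    vessel_of_seg <- territory_of(grid$segment, map = territory_map)
    prow <- match(grid$patient_id, ids)
    seg_stenotic <- vess[cbind(prow, match(vessel_of_seg, .dse_vessels))]
    shift <- at_stress & seg_stenotic
    stress_sd <- par_tab$stress_sd[pi]
    value[shift] <- value[shift] +
      (config$effect_size * par_tab$direction[pi] * stress_sd)[shift]

    miss_rate <- ifelse(at_stress, config$missing_rate_stress, config$missing_rate_rest)
    value[stats::runif(nrow(grid)) < miss_rate] <- NA_real_

    segments <- data.frame(
      patient_id = grid$patient_id,
      group = config$group,
      segment = grid$segment,
      parameter = grid$parameter,
      phase = grid$phase,
      value = value,
      stringsAsFactors = FALSE
    )

    new_cohort(patients, segments)
  })
}

new_cohort <- function(patients, segments) {
  structure(list(patients = patients, segments = segments),
            class = "dse_cohort")
}

#' @export
print.dse_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf(
    "<dse_cohort> %d patients (%s), %.1f%% with >=1 stenotic vessel\n",
    nrow(p), paste(unique(p$group), collapse = "/"),
    100 * mean(p$any_stenosis)
  ))
  cat(sprintf("  segment measurements: %d (%.1f%% missing)\n",
              nrow(x$segments), 100 * mean(is.na(x$segments$value))))
  invisible(x)
}

# Wide covariate matrix: one row per patient, one column per
# (parameter, segment, phase) plus the visual delta-WMSI covariate.
# Column names are canonical feature ids.
cohort_covariates <- function(cohort) {
  p <- cohort$patients
  s <- cohort$segments
  fid <- feature_id(s$parameter, s$segment, s$phase)
  cols <- unique(fid)
  m <- matrix(NA_real_, nrow(p), length(cols) + 1,
              dimnames = list(p$patient_id, c(cols, "delta_wmsi")))
  m[cbind(match(s$patient_id, p$patient_id), match(fid, cols))] <- s$value
  m[, "delta_wmsi"] <- delta_wmsi(p$wmsi_rest, p$wmsi_stress)
  m
}

# Binary endpoint labels for a cohort.
endpoint_labels <- function(cohort, endpoint = c("any", "LAD", "LCX", "RCA")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "any") cohort$patients$any_stenosis
  else cohort$patients[[endpoint]]
}
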