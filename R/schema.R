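#' @keywords internal
#' @useDynLib dsemodel, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# ---- Segment / parameter schema -------------------------------------------
#
# 12 analyzable segments from the two apical views (6 per view): the
# 4-chamber view contributes the septal and lateral walls, the 2-chamber
# view the anterior and inferior walls, each at basal / mid / apical level.

.dse_walls <- c("septal", "lateral", "anterior", "inferior")
.dse_levels <- c("basal", "mid", "apical")

#' Names of the 12 apical-view myocardial segments
#'
#' @return Character vector of the 12 segment names
#'   (\code{"basal septal"}, \code{"mid septal"}, ..., \code{"apical inferior"}).
#' @export
dse_segments <- function() {
  as.vector(outer(.dse_levels, .dse_walls, paste))
}

# Quantitative speckle-tracking parameter families, their units and the
# generator's per-phase population means/SDs.  `direction` is the sign of the
# additive shift applied to stress-phase values in ischemic territories:
# longitudinal strain and strain rate are negative (shortening) and move
# toward 0, peak times prolong, S' blunts, post-systolic shortening and
# positive systolic (stretching) strain increase, radial thickening and
# displacement fall.
.dse_parameter_table <- data.frame(
  parameter = c(
    "s_velocity", "e_velocity", "a_velocity",
    "time_to_s", "time_to_max_strain",
    "systolic_strain", "post_systolic_strain", "maximal_strain",
    "radial_systolic_strain", "systolic_strain_rate", "a_strain_rate",
    "radial_displacement", "positive_systolic_strain"
  ),
  unit = c(
    "cm/s", "cm/s", "cm/s",
    "ms", "ms",
    "%", "%", "%",
    "%", "1/s", "1/s",
    "mm", "%"
  ),
  rest_mean = c(5.5, -6.5, -5.0, 160, 380, -18, -19, -19.5, 35, -1.1, 1.5, 6, 0.2),
  rest_sd = c(1.2, 1.8, 1.5, 30, 50, 4, 4.5, 4.5, 10, 0.3, 0.5, 2, 0.3),
  stress_mean = c(8.5, -7.5, -6.0, 110, 300, -20, -21, -21.5, 45, -1.8, 2.0, 8, 0.3),
  stress_sd = c(2.0, 2.2, 2.0, 25, 45, 5, 5.5, 5.5, 12, 0.5, 0.7, 2.5, 0.4),
  direction = c(-1, +1, +1, +1, +1, +1, -1, +1, -1, +1, -1, -1, +1),
  stringsAsFactors = FALSE
)

#' Quantitative DSE parameter schema
#'
#' The 13 speckle-tracking parameter families carried per segment and phase:
#' longitudinal velocities (S', E', A'), time-to-peak measures, longitudinal
#' systolic / post-systolic / maximal strain, radial systolic strain,
#' systolic and late-diastolic strain rate, radial systolic displacement and
#' positive systolic strain, with their units and the population moments used
#' by \code{\link{simulate_cohort}}.
#'
#' @return Data frame with columns \code{parameter}, \code{unit},
#'   \code{rest_mean}, \code{rest_sd}, \code{stress_mean}, \code{stress_sd},
#'   \code{direction}.
#' @export
dse_parameters <- function() .dse_parameter_table

.dse_phases <- c("rest", "stress")
.dse_vessels <- c("LAD", "LCX", "RCA")

# Conventional ASE-style assignment of the 12 apical-view segments to
# coronary territories.
.dse_territory_map <- c(
  "basal anterior" = "LAD", "mid anterior" = "LAD", "apical anterior" = "LAD",
  "mid septal" = "LAD", "apical septal" = "LAD",
  "basal lateral" = "LCX", "mid lateral" = "LCX", "apical lateral" = "LCX",
  "basal septal" = "RCA", "basal inferior" = "RCA", "mid inferior" = "RCA",
  "apical inferior" = "RCA"
)

#' Coronary territory of a myocardial segment
#'
#' Maps each of the 12 apical-view segments to the coronary artery
#' (LAD, LCX or RCA) conventionally supplying it.  The default map follows
#' the standard ASE territory chart: anterior wall and mid/apical septum to
#' the left anterior descending artery, lateral wall to the circumflex,
#' inferior wall and basal septum to the right coronary artery.
#'
#' @param segment Character vector of segment names (see
#'   \code{\link{dse_segments}}).
#' @param map Named character vector overriding the default
#'   segment-to-vessel assignment.
#' @return Character vector of vessel identifiers (\code{"LAD"},
#'   \code{"LCX"}, \code{"RCA"}).
#' @examples
#' territory_of("apical septal")
#' territory_of(c("basal inferior", "mid lateral"))
#' @export
territory_of <- function(segment, map = NULL) {
  if (is.null(map)) map <- .dse_territory_map
  unknown <- setdiff(segment, names(map))
  if (length(unknown) > 0) {
    stop("unknown segment name(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[segment])
}

# Canonical covariate identifier: parameter|segment|phase, or "delta_wmsi"
# for the patient-level visual covariate.
feature_id <- function(parameter, segment, phase) {
  ifelse(parameter == "delta_wmsi", "delta_wmsi",
    paste(parameter, segment, phase, sep = "|")
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
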