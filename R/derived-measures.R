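# ---- Derived echo quantities ----------------------------------------------

#' Post-systolic index (PSI)
#'
#' PSI is the peak post-systolic strain minus the peak systolic strain, a
#' marker of delayed segmental contraction seen in ischemia.  Missing inputs
#' propagate to a missing result.
#'
#' @param systolic_strain Peak systolic strain (\%), possibly \code{NA}.
#' @param post_systolic_strain Peak post-systolic strain (\%), possibly
#'   \code{NA}.
#' @return \code{post_systolic_strain - systolic_strain} (\%).
#' @examples
#' psi(-18, -22)  # -4
#' @export
psi <- function(systolic_strain, post_systolic_strain) {
  post_systolic_strain - systolic_strain
}

#' Maximal strain
#'
#' The maximal strain of a segment coincides with the systolic or the
#' post-systolic strain, whichever is larger.  Because longitudinal strain is
#' negative (shortening), "larger" is taken as larger absolute magnitude;
#' ties return the systolic value.  If one input is missing the other is
#' returned; if both are missing the result is missing.
#'
#' @param systolic_strain,post_systolic_strain Strain values (\%), vectors
#'   of equal length, \code{NA} allowed.
#' @param by Comparison rule: \code{"magnitude"} (default, absolute value)
#'   or \code{"signed"} (plain numeric comparison).
#' @return Elementwise maximal strain (\%).
#' @examples
#' maximal_strain(-18, -22)  # -22
#' maximal_strain(0.3, 0.1)  # 0.3
#' @export
maximal_strain <- function(systolic_strain, post_systolic_strain,
                           by = c("magnitude", "signed")) {
  by <- match.arg(by)
  s <- systolic_strain
  p <- post_systolic_strain
  key_s <- if (by == "magnitude") abs(s) else s
  key_p <- if (by == "magnitude") abs(p) else p
  out <- ifelse(is.na(s), p,
         ifelse(is.na(p), s,
         ifelse(key_p > key_s, p, s)))  # ties -> systolic
  out
}

#' Wall motion score index (WMSI)
#'
#' The sum of all interpretable segment scores divided by the number of
#' interpretable segments.  Scores grade segmental wall motion
#' semiquantitatively: 1 normal, 2 hypokinetic, 3 akinetic, 4 dyskinetic;
#' uninterpretable segments (coded \code{NA}) are excluded from both the
#' numerator and the denominator.
#'
#' @param scores Numeric vector of segment scores in \code{{1, 2, 3, 4}},
#'   with \code{NA} for uninterpretable segments.
#' @return The WMSI, a value in \code{[1, 4]}.
#' @examples
#' wmsi(c(rep(1, 15), 3))  # 1.125
#' @export
wmsi <- function(scores) {
  ok <- !is.na(scores)
  if (!any(ok)) stop("WMSI undefined: no interpretable segments")
  s <- scores[ok]
  if (any(s != round(s) | s < 1 | s > 4)) {
    stop("interpretable segment scores must be integers in 1..4")
  }
  mean(s)
}

#' Stress-minus-rest change in WMSI
#'
#' The visual covariate entering every endpoint model: the wall motion score
#' index at peak stress minus at rest.  Negative values are permitted
#' (biphasic responses); no clipping is applied.
#'
#' @param wmsi_rest,wmsi_stress WMSI values in \code{[1, 4]}.
#' @return \code{wmsi_stress - wmsi_rest}.
#' @examples
#' delta_wmsi(1.02, 1.21)  # 0.19
#' @export
delta_wmsi <- function(wmsi_rest, wmsi_stress) {
  if (any(wmsi_rest < 1 | wmsi_rest > 4, na.rm = TRUE) ||
      any(wmsi_stress < 1 | wmsi_stress > 4, na.rm = TRUE)) {
    stop("WMSI values must lie in [1, 4]")
  }
  wmsi_stress - wmsi_rest
}
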