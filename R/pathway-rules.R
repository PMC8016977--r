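#' Classification rules for pathway assignment
#'
#' The thresholds and target sets that drive isotope-based pathway
#' classification. For species in families where both C3 and C4 occur,
#' tissue \eqn{\delta^{13}}C below -19 permil indicates C3 and above -19
#' indicates C4 (the two distributions, roughly -37 to -20 and -16 to -12
#' permil, do not overlap there). For genera with confirmed C3-CAM
#' potential a three-way rule is used instead: values above `cam_upper`
#' (-20) are tentatively CAM, values between `cam_lower` (-24) and
#' `cam_upper` are potentially C3+CAM, and values below `cam_lower` are
#' C3. All CAM and C3+CAM calls from isotopes alone are tentative, because
#' \eqn{\delta^{13}}C cannot separate CAM from C4 nor weakly expressed CAM
#' from C3.
#'
#' @param c3_c4_threshold C3/C4 decision boundary (permil, VPDB).
#' @param cam_upper,cam_lower Bounds of the potential-C3+CAM band (permil);
#'   must satisfy `cam_lower < cam_upper < 0`.
#' @param c4_target_families Families screened by isotope analysis because
#'   they are known to contain C4 lineages.
#' @param cam_potential_genera Genera with previously confirmed C3-CAM
#'   potential, classified with the CAM rule.
#' @return A list of class `"classification_rules"`.
#' @examples
#' rules <- classification_rules()
#' classify_c3_c4(c(-27, -13), rules)
#' @export
classification_rules <- function(c3_c4_threshold = -19,
                                 cam_upper = -20,
                                 cam_lower = -24,
                                 c4_target_families = NULL,
                                 cam_potential_genera = NULL) {
  if (!(cam_lower < cam_upper && cam_upper < 0)) {
    abort("need cam_lower < cam_upper < 0 (permil, VPDB)")
  }
  if (!is_number(c3_c4_threshold) || c3_c4_threshold >= 0) {
    abort("`c3_c4_threshold` must be a negative number")
  }
  structure(
    list(
      c3_c4_threshold = c3_c4_threshold,
      cam_upper = cam_upper,
      cam_lower = cam_lower,
      c4_target_families = c4_target_families %||%
        c("Aizoaceae", "Asteraceae", "Boraginaceae", "Caryophyllaceae",
          "Chenopodiaceae", "Euphorbiaceae", "Poaceae", "Portulacaceae",
          "Zygophyllaceae"),
      cam_potential_genera = cam_potential_genera %||%
        c("Calandrinia", "Carpobrotus", "Gunniopsis", "Portulaca",
          "Sarcozona", "Sesuvium", "Tetragonia", "Trianthema")
    ),
    class = "classification_rules"
  )
}

#' Classify tissue \eqn{\delta^{13}}C as C3 or C4
#'
#' Values strictly below the threshold (default -19 permil) are C3, values
#' strictly above are C4. A value exactly on the threshold is undefined
#' under strict inequalities and is returned as `"ambiguous"` for manual
#' review rather than forced to a side.
#'
#' @param delta13c Numeric vector of calibrated \eqn{\delta^{13}}C (permil,
#'   VPDB).
#' @param rules A [classification_rules()].
#' @return Character vector in `{"C3", "C4", "ambiguous"}`.
#' @examples
#' classify_c3_c4(c(-27, -13, -19))
#' @export
classify_c3_c4 <- function(delta13c, rules = classification_rules()) {
  check_delta(delta13c)
  dplyr::case_when(
    delta13c < rules$c3_c4_threshold ~ "C3",
    delta13c > rules$c3_c4_threshold ~ "C4",
    TRUE ~ "ambiguous"
  )
}

#' Classify \eqn{\delta^{13}}C for genera with CAM potential
#'
#' Three-way rule for genera with confirmed C3-CAM potential: above -20
#' permil tentatively CAM, from -24 to -20 permil potentially C3+CAM,
#' below -24 permil C3. The rule partitions the real line: the band
#' boundaries belong to the C3+CAM interval, i.e. the intervals are
#' \eqn{(-\infty, -24)}, \eqn{[-24, -20]}, \eqn{(-20, \infty)}.
#'
#' @inheritParams classify_c3_c4
#' @return Character vector in `{"C3", "C3+CAM", "CAM"}`. CAM and C3+CAM
#'   calls should always be treated as tentative.
#' @examples
#' classify_cam_potential(c(-18, -22, -26))
#' @export
classify_cam_potential <- function(delta13c, rules = classification_rules()) {
  check_delta(delta13c)
  dplyr::case_when(
    delta13c > rules$cam_upper ~ "CAM",
    delta13c >= rules$cam_lower ~ "C3+CAM",
    TRUE ~ "C3"
  )
}

check_delta <- function(delta13c) {
  if (!is.numeric(delta13c) || any(!is.finite(delta13c))) {
    abort("delta13c must be finite numeric (permil, VPDB)")
  }
  invisible(delta13c)
}
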