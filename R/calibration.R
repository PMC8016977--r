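#' Delta notation from isotope abundance ratios
#'
#' Expresses a \eqn{^{13}}C/\eqn{^{12}}C abundance ratio as a per-mil
#' deviation from the reference gas ratio:
#' \deqn{\delta^{13}C = (R_{sa}/R_{ref} - 1) \times 1000}
#'
#' @param r_sa Abundance ratio \eqn{^{13}}C/\eqn{^{12}}C of the sample(s).
#' @param r_ref Abundance ratio of the reference gas (recycled).
#' @return \eqn{\delta^{13}}C in permil. Reported relative to VPDB when the
#'   reference is on the VPDB scale.
#' @examples
#' delta_from_ratios(0.987, 1) # -13 permil
#' @export
delta_from_ratios <- function(r_sa, r_ref) {
  if (!is.numeric(r_sa) || !is.numeric(r_ref)) {
    abort("ratios must be numeric")
  }
  if (any(!is.finite(r_sa)) || any(!is.finite(r_ref)) ||
      any(r_sa <= 0) || any(r_ref <= 0)) {
    abort("abundance ratios must be finite and strictly positive")
  }
  (r_sa / r_ref - 1) * 1000
}

#' Fit a multipoint normalization to the VPDB scale
#'
#' Ordinary least squares of the verified ("true") standard values on the
#' measured values, the normalization used for runs with several reference
#' standards: measured \eqn{\delta} on the x-axis, accepted
#' \eqn{\delta_{VPDB}} on the y-axis, and unknowns corrected as
#' \eqn{\delta^T = a\,\delta^M + b}.
#'
#' @param standards Data frame with columns `measured` and `verified`
#'   (permil), one row per standard measurement; repeated measurements of
#'   the same standard enter as separate rows.
#' @return A `"calibration"` object (kind `"multipoint"`) with slope `a`,
#'   intercept `b`. Use [apply_calibration()] or `predict()` to correct
#'   measurements, and [tidy()]/[glance()] to inspect the fit.
#' @examples
#' std <- tibble::tibble(measured = c(-28, -24, -16, -12) + 0.4,
#'                       verified = c(-28, -24, -16, -12))
#' fit_multipoint(std)
#' @export
fit_multipoint <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("measured", "verified") %in% names(standards)))
  if (nrow(standards) < 2L) abort("need at least 2 standard measurements")
  if (dplyr::n_distinct(standards$measured) < 2L) {
    abort("degenerate standards: all measured values are equal")
  }
  fit <- lm(verified ~ measured, data = standards)
  new_calibration(
    kind = "multipoint",
    a = unname(coef(fit)[2]),
    b = unname(coef(fit)[1]),
    standards = tibble::as_tibble(standards),
    sigma = suppressWarnings(summary(fit)$sigma)
  )
}

#' Fit a two-point normalization to the VPDB scale
#'
#' Affine correction anchored at two standards of known value measured in
#' the same run, used when a run carries only a pair of anchors:
#' \deqn{\delta_{sa,c} = \delta_{std1} + (\delta_{sa,m} - \delta_{std1,m})
#'   \frac{\delta_{std2} - \delta_{std1}}{\delta_{std2,m} - \delta_{std1,m}}}
#' This is the standard dimensionally consistent form of the two-point
#' correction; it maps each measured anchor exactly onto its known value
#' and interpolates linearly between them.
#'
#' @param anchors Data frame with exactly two rows and columns `measured`
#'   and `verified` (permil); an optional `name` column is carried along.
#' @return A `"calibration"` object (kind `"two_point"`).
#' @examples
#' anchors <- tibble::tibble(name = c("Glycine", "USGS 41"),
#'                           measured = c(-31.0, -37.4),
#'                           verified = c(-31.20, -37.63))
#' apply_calibration(fit_two_point(anchors), -29.1)
#' @export
fit_two_point <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("measured", "verified") %in% names(anchors)))
  if (nrow(anchors) != 2L) abort("two-point calibration needs exactly 2 anchors")
  if (anchors$measured[1] == anchors$measured[2]) {
    abort("coincident measured anchor values")
  }
  a <- (anchors$verified[2] - anchors$verified[1]) /
    (anchors$measured[2] - anchors$measured[1])
  b <- anchors$verified[1] - a * anchors$measured[1]
  new_calibration(
    kind = "two_point",
    a = a, b = b,
    standards = tibble::as_tibble(anchors),
    sigma = NA_real_
  )
}

new_calibration <- function(kind, a, b, standards, sigma,
                            uncertainty = NA_real_,
                            n_standard_repeats = NA_integer_) {
  structure(
    list(kind = kind, a = a, b = b, standards = standards, sigma = sigma,
         uncertainty = uncertainty, n_standard_repeats = n_standard_repeats),
    class = "calibration"
  )
}

#' Correct measured values with a fitted calibration
#'
#' @param model A `"calibration"` from [fit_multipoint()] or
#'   [fit_two_point()].
#' @param delta_measured Measured \eqn{\delta^{13}}C values (permil).
#' @return Corrected \eqn{\delta^{13}}C on the VPDB scale (permil). The
#'   correction is affine with positive slope for any well-posed standard
#'   set, so it preserves the ordering of measurements.
#' @examples
#' m <- fit_two_point(tibble::tibble(measured = c(-29, -9),
#'                                   verified = c(-30, -10)))
#' apply_calibration(m, -19) # -20
#' @export
apply_calibration <- function(model, delta_measured) {
  stopifnot(inherits(model, "calibration"))
  if (!is.numeric(delta_measured) || any(!is.finite(delta_measured))) {
    abort("`delta_measured` must be finite numeric")
  }
  model$a * delta_measured + model$b
}

#' @export
predict.calibration <- function(object, newdata, ...) {
  apply_calibration(object, newdata)
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration:", x$kind, "> delta_vpdb =",
      format(x$a, digits = 6), "* measured +",
      format(x$b, digits = 6), "\n")
  if (!is.na(x$uncertainty)) {
    cat("  run uncertainty (max |corrected std - verified|):",
        format(x$uncertainty, digits = 3), "permil, n =",
        x$n_standard_repeats, "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$a, x$b))
}

#' @exportS3Method generics::glance
glance.calibration <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_standards = nrow(x$standards),
    sigma = x$sigma,
    uncertainty = x$uncertainty,
    n_standard_repeats = x$n_standard_repeats
  )
}

#' Remove linear instrument drift from an IRMS run
#'
#' Instrument response commonly drifts over a long autorun. The drift slope
#' is estimated by regressing the raw readings of the repeated reference
#' standards on sequence position with a separate intercept per standard
#' (so standards of different isotopic composition pool into one slope
#' estimate), and the fitted trend is subtracted from every reading in the
#' run. On a noise-free run with injected linear drift this recovers the
#' slope exactly; if no standard was measured at two distinct positions the
#' run is returned unchanged with a warning.
#'
#' @param run An IRMS run tibble with columns `sequence_no`, `sample_type`,
#'   `standard_name`, `raw_delta` (as produced by [simulate_irms_run()] or
#'   [read_irms_run()]).
#' @return The run with `raw_delta` drift-corrected; the estimated slope is
#'   attached as attribute `drift_slope` (permil per sequence step).
#' @examples
#' cfg <- sim_config(seed = 2, noise_sd = 0, drift_per_position = 0.01)
#' specs <- tibble::tibble(sample_id = sprintf("S%02d", 1:30),
#'                         true_delta = runif(30, -30, -12))
#' run <- simulate_irms_run(specs, "CSIRO", cfg)
#' attr(drift_correct(run), "drift_slope")
#' @export
drift_correct <- function(run) {
  stopifnot(is.data.frame(run),
            all(c("sequence_no", "sample_type", "standard_name",
                  "raw_delta") %in% names(run)))
  std <- run[run$sample_type == "standard", ]
  repeated <- std |>
    dplyr::count(.data$standard_name) |>
    dplyr::filter(.data$n >= 2L)
  std <- std[std$standard_name %in% repeated$standard_name, ]
  if (nrow(std) < 2L ||
      dplyr::n_distinct(std$sequence_no) < 2L) {
    warn("no standard measured at two distinct positions; returning run unchanged")
    attr(run, "drift_slope") <- 0
    return(run)
  }
  fit <- if (dplyr::n_distinct(std$standard_name) > 1L) {
    lm(raw_delta ~ sequence_no + factor(standard_name), data = std)
  } else {
    lm(raw_delta ~ sequence_no, data = std)
  }
  slope <- unname(coef(fit)["sequence_no"])
  out <- dplyr::mutate(run,
                       raw_delta = .data$raw_delta - slope * .data$sequence_no)
  attr(out, "drift_slope") <- slope
  attr(out, "truth") <- attr(run, "truth")
  out
}

#' Run-level quality control statistics
#'
#' Repeat-standard accuracy and replicate-sample agreement for a calibrated
#' run: the maximum and SD of the absolute deviation of corrected standard
#' readings from their verified values (the "uncertainty" a facility quotes
#' from repeat standard analysis), and the mean and SD of the absolute
#' difference between replicate pairs of unknowns.
#'
#' @param run A calibrated run tibble containing at least `sample_type`,
#'   `sample_id`, `standard_name` and `delta_vpdb`.
#' @param standards Verified values to compare against, defaulting to
#'   [irms_standards()].
#' @return One-row tibble: `max_abs_standard_deviation`,
#'   `sd_standard_deviation`, `n_standard_repeats`,
#'   `replicate_mean_abs_diff`, `replicate_sd_abs_diff`,
#'   `n_replicate_pairs`. Replicate fields are `NA` (not zero) when the run
#'   holds no replicates.
#' @export
run_qc <- function(run, standards = irms_standards()) {
  stopifnot(is.data.frame(run),
            all(c("sample_type", "sample_id", "standard_name",
                  "delta_vpdb") %in% names(run)))
  std <- run |>
    dplyr::filter(.data$sample_type == "standard") |>
    dplyr::left_join(dplyr::select(standards, "name", "verified_delta"),
                     by = c(standard_name = "name"))
  dev <- abs(std$delta_vpdb - std$verified_delta)
  reps <- run |>
    dplyr::filter(.data$sample_type == "replicate") |>
    dplyr::select("sample_id", rep_delta = "delta_vpdb")
  pairs <- run |>
    dplyr::filter(.data$sample_type == "unknown") |>
    dplyr::select("sample_id", "delta_vpdb") |>
    dplyr::inner_join(reps, by = "sample_id")
  diffs <- abs(pairs$delta_vpdb - pairs$rep_delta)
  tibble::tibble(
    max_abs_standard_deviation = if (length(dev)) max(dev) else NA_real_,
    sd_standard_deviation = if (length(dev) > 1L) sd(dev) else NA_real_,
    n_standard_repeats = length(dev),
    replicate_mean_abs_diff = if (length(diffs)) mean(diffs) else NA_real_,
    replicate_sd_abs_diff = if (length(diffs) > 1L) sd(diffs) else NA_real_,
    n_replicate_pairs = length(diffs)
  )
}

#' Calibrate a full IRMS run to the VPDB scale
#'
#' The complete per-run reduction: (optionally) remove linear instrument
#' drift using the repeated standards, fit the normalization (multipoint
#' OLS over all standard measurements, or a two-point correction anchored
#' at the pair of standards spanning the widest verified range unless
#' `anchors` names another pair), apply it to every reading, and compute
#' run QC.
#'
#' @param run An IRMS run tibble (see [simulate_irms_run()]).
#' @param method `"multipoint"` or `"two_point"`.
#' @param drift Apply drift correction first? Default `TRUE`.
#' @param anchors Optional character vector of two standard names to anchor
#'   a two-point fit.
#' @param standards Standard definitions; defaults to [irms_standards()]
#'   filtered to the run's facility.
#' @return A list of class `"calibrated_run"`: `samples` (one row per
#'   unknown: `sample_id`, `facility`, `delta_vpdb`, `replicate_deltas`
#'   list-column), `run` (every reading with its corrected value), `model`
#'   (the `"calibration"`), and `qc` (one-row [run_qc()] tibble).
#'   `tidy()` returns `samples`; `glance()` returns the QC row.
#' @examples
#' cfg <- sim_config(seed = 5)
#' specs <- tibble::tibble(sample_id = sprintf("S%02d", 1:40),
#'                         true_delta = runif(40, -30, -12))
#' cal <- calibrate_run(simulate_irms_run(specs, "CSIRO", cfg))
#' glance(cal)
#' @export
calibrate_run <- function(run, method = c("multipoint", "two_point"),
                          drift = TRUE, anchors = NULL, standards = NULL) {
  method <- match.arg(method)
  facility <- unique(run$facility)
  standards <- standards %||%
    (if (length(facility) == 1L && facility %in% c("CSIRO", "MASS")) {
      irms_standards(facility)
    } else {
      irms_standards()
    })
  if (drift) run <- drift_correct(run)
  meas <- run |>
    dplyr::filter(.data$sample_type == "standard") |>
    dplyr::left_join(dplyr::select(standards, "name", "verified_delta"),
                     by = c(standard_name = "name")) |>
    dplyr::select(name = "standard_name", measured = "raw_delta",
                  verified = "verified_delta")
  if (any(is.na(meas$verified))) {
    abort(paste0("unknown standard(s) in run: ",
                 paste(unique(meas$name[is.na(meas$verified)]),
                       collapse = ", ")))
  }
  model <- if (method == "multipoint") {
    fit_multipoint(meas)
  } else {
    fit_two_point(pick_anchors(meas, anchors))
  }
  corrected <- dplyr::mutate(run,
                             delta_vpdb = apply_calibration(model, .data$raw_delta))
  qc <- run_qc(corrected, standards)
  model$uncertainty <- qc$max_abs_standard_deviation
  model$n_standard_repeats <- qc$n_standard_repeats
  reps <- corrected |>
    dplyr::filter(.data$sample_type == "replicate") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(replicate_deltas = list(.data$delta_vpdb),
                     .groups = "drop")
  samples <- corrected |>
    dplyr::filter(.data$sample_type == "unknown") |>
    dplyr::select("sample_id", "facility", "delta_vpdb") |>
    dplyr::left_join(reps, by = "sample_id") |>
    dplyr::mutate(replicate_deltas = purrr::map(
      .data$replicate_deltas, function(v) v %||% numeric(0)
    )) |>
    dplyr::arrange(.data$sample_id)
  structure(
    list(samples = samples, run = corrected, model = model, qc = qc),
    class = "calibrated_run"
  )
}

# Two-point anchors: mean measured value per standard; default pair spans
# the widest verified range (alphabetical tie-break).
pick_anchors <- function(meas, anchors = NULL) {
  per_std <- meas |>
    dplyr::group_by(.data$name, .data$verified) |>
    dplyr::summarise(measured = mean(.data$measured), .groups = "drop") |>
    dplyr::arrange(.data$verified, .data$name)
  if (!is.null(anchors)) {
    if (length(anchors) != 2L || !all(anchors %in% per_std$name)) {
      abort("`anchors` must name two standards present in the run")
    }
    per_std <- per_std[match(anchors, per_std$name), ]
  } else {
    per_std <- per_std[c(1L, nrow(per_std)), ]
  }
  dplyr::select(per_std, "name", "measured", "verified")
}

#' @export
print.calibrated_run <- function(x, ...) {
  cat("<calibrated_run>", nrow(x$samples), "unknowns,",
      x$qc$n_standard_repeats, "standard readings,",
      x$qc$n_replicate_pairs, "replicate pairs\n")
  print(x$model)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibrated_run <- function(x, ...) x$samples

#' @exportS3Method generics::glance
glance.calibrated_run <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(kind = x$model$kind), x$qc)
}
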