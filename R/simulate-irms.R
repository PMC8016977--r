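#' Simulate an IRMS run sheet
#'
#' Builds an ordered isotope-ratio mass-spectrometry sequence the way the
#' analytical facilities run plant tissue: a full block of the facility's
#' reference standards at the start and end of the run, one interleaved
#' standard after every 10 unknowns (cycling through the facility set), and
#' a replicate section in which a fraction of unknowns (default 10%) is
#' re-measured before the closing standard block. Raw readings are the true
#' value plus a linear instrument drift in sequence position plus Gaussian
#' analytical noise:
#' \deqn{\delta_{raw} = \delta_{true} + d \cdot (position - 1) + \epsilon,
#'   \quad \epsilon \sim N(0, \sigma^2)}
#'
#' @param specimens Tibble of unknowns with columns `sample_id` and
#'   `true_delta` (permil, VPDB).
#' @param facility `"CSIRO"` or `"MASS"`; selects the standard set from
#'   [irms_standards()].
#' @param config A [sim_config()]; uses `noise_sd`, `drift_per_position`,
#'   `replicate_fraction` and `seed`.
#' @return A tibble of class `"irms_run"`: `sequence_no`, `sample_type`
#'   (`"standard"`, `"unknown"`, `"replicate"`), `sample_id`,
#'   `standard_name`, `raw_delta`, `facility`. The hidden truth (including
#'   the injected drift slope) is attached as attributes `truth` and
#'   `drift_per_position` for testing.
#' @examples
#' cfg <- sim_config(seed = 9, noise_sd = 0.05)
#' specs <- tibble::tibble(sample_id = sprintf("S%02d", 1:25),
#'                         true_delta = runif(25, -30, -12))
#' run <- simulate_irms_run(specs, "MASS", cfg)
#' table(run$sample_type)
#' @export
simulate_irms_run <- function(specimens, facility = c("CSIRO", "MASS"),
                              config = sim_config()) {
  facility <- match.arg(facility)
  stopifnot(is.data.frame(specimens),
            all(c("sample_id", "true_delta") %in% names(specimens)))
  standards <- irms_standards(facility)
  with_seed(derive_seed(config$seed, paste0("irms_", facility)), {
    n <- nrow(specimens)
    std_block <- tibble::tibble(
      sample_type = "standard",
      sample_id = standards$name,
      standard_name = standards$name,
      true_delta = standards$verified_delta
    )
    unknown_rows <- tibble::tibble(
      sample_type = "unknown",
      sample_id = specimens$sample_id,
      standard_name = NA_character_,
      true_delta = specimens$true_delta
    )
    # interleave: after every 10 unknowns, one standard (cycling)
    chunks <- split(seq_len(n), ceiling(seq_len(n) / 10))
    cycle <- 0L
    body <- purrr::map(chunks, function(idx) {
      cycle <<- cycle + 1L
      std_i <- ((cycle - 1L) %% nrow(standards)) + 1L
      dplyr::bind_rows(unknown_rows[idx, ], std_block[std_i, ])
    })
    n_rep <- as.integer(round(n * config$replicate_fraction))
    rep_rows <- if (n_rep > 0L) {
      picks <- sort(sample.int(n, n_rep))
      dplyr::mutate(unknown_rows[picks, ], sample_type = "replicate")
    } else {
      NULL
    }
    run <- dplyr::bind_rows(c(list(std_block), unname(body),
                              list(rep_rows), list(std_block))) |>
      dplyr::mutate(
        sequence_no = dplyr::row_number(),
        raw_delta = .data$true_delta +
          config$drift_per_position * (.data$sequence_no - 1) +
          rnorm(dplyr::n(), 0, config$noise_sd),
        facility = facility
      )
    truth <- dplyr::select(run, "sequence_no", "sample_type", "sample_id",
                           "true_delta")
    out <- dplyr::select(run, "sequence_no", "sample_type", "sample_id",
                         "standard_name", "raw_delta", "facility")
    structure(out, class = c("irms_run", class(out)),
              truth = truth, drift_per_position = config$drift_per_position)
  })
}
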