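#' Write the two-table pathway dataset
#'
#' Serializes the assignment table and its source list in the published
#' two-table shape, plus a machine-readable column-descriptor file. Files
#' are UTF-8 CSV with deterministic (alphabetical) row order; list-columns
#' (`sources`, `replicate_deltas`) are serialized as `"; "`-joined strings
#' and survive a write/read round trip losslessly.
#'
#' @param assignments Output of [assign_pathways()].
#' @param sources Tibble describing the literature sources, with at least
#'   `source_id`; a `n_species_assigned` column is (re)computed from the
#'   assignments.
#' @param dir Output directory (created if needed).
#' @return Invisibly, named character vector of the files written
#'   (`pathway_table`, `sources_table`, `column_descriptors`).
#' @seealso [read_pathway_table()]
#' @export
write_pathway_tables <- function(assignments, sources, dir) {
  stopifnot(is.data.frame(assignments), is.data.frame(sources),
            "source_id" %in% names(sources))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- flatten_assignments(assignments)
  used <- tibble::tibble(
    source_id = as.character(unlist(assignments$sources %||% list()))
  ) |> dplyr::count(.data$source_id, name = "n_species_assigned")
  src <- sources |>
    dplyr::distinct(.data$source_id, .keep_all = TRUE) |>
    dplyr::select(-dplyr::any_of("n_species_assigned")) |>
    dplyr::left_join(used, by = "source_id") |>
    dplyr::mutate(n_species_assigned =
                    dplyr::coalesce(.data$n_species_assigned, 0L)) |>
    dplyr::arrange(.data$source_id)
  paths <- c(
    pathway_table = file.path(dir, "pathway_table.csv"),
    sources_table = file.path(dir, "sources_table.csv"),
    column_descriptors = file.path(dir, "column_descriptors.csv")
  )
  readr::write_csv(tbl, paths["pathway_table"], na = "")
  readr::write_csv(src, paths["sources_table"], na = "")
  readr::write_csv(column_descriptors(tbl), paths["column_descriptors"],
                   na = "")
  invisible(paths)
}

flatten_assignments <- function(assignments) {
  tbl <- tibble::as_tibble(assignments)
  if (is.list(tbl$sources)) {
    tbl$sources <- purrr::map_chr(tbl$sources,
                                  function(v) paste(v, collapse = "; "))
  }
  if ("replicate_deltas" %in% names(tbl) && is.list(tbl$replicate_deltas)) {
    tbl$replicate_deltas <- purrr::map_chr(
      tbl$replicate_deltas,
      function(v) paste(format_delta(v), collapse = "; ")
    )
  }
  dplyr::arrange(tbl, .data$species)
}

# permil values printed with 2 decimals, matching reference-table precision
format_delta <- function(x) {
  if (length(x) == 0L) return(character(0))
  sprintf("%.2f", x)
}

column_descriptors <- function(tbl) {
  known <- c(
    species = "Binomial scientific name (herbarium determination collapsed to species rank)",
    family = "Plant family of the species",
    genus = "Genus of the species",
    pathway = "Photosynthetic pathway: C3, C4, CAM, C3-CAM, C3-C4, C4-CAM, or C3+CAM (tentative isotope call); empty when unassigned",
    method = "Assignment route: literature, lineage_inferred, or isotope",
    sources = "Semicolon-separated citation keys supporting the assignment",
    delta13C = "Calibrated bulk-tissue delta13C (permil, VPDB) of the tested specimen, when measured",
    facility = "Analytical facility of the isotope measurement (CSIRO or MASS)",
    replicate_deltas = "Semicolon-separated replicate delta13C values (permil, VPDB)",
    plot_id = "Identifier of the plot the tested specimen came from",
    tentative = "TRUE when the assignment needs confirmation (CAM/C3+CAM isotope calls, evidence ties)",
    discrepancy_note = "Conflicting sources, replicate specimens, or standing cautions",
    unassigned_reason = "Why no pathway could be assigned, when applicable"
  )
  tibble::tibble(
    column = names(tbl),
    description = dplyr::coalesce(known[names(tbl)], "(auxiliary column)")
  )
}

#' Read a pathway table written by [write_pathway_tables()]
#'
#' @param path Path to `pathway_table.csv`.
#' @return The assignment tibble with `sources` and `replicate_deltas`
#'   restored as list-columns.
#' @export
read_pathway_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           species = "c",
                           sources = "c",
                           .default = readr::col_guess()
                         ))
  if ("sources" %in% names(tbl)) {
    tbl$sources <- purrr::map(tbl$sources, split_list_chr)
  }
  if ("replicate_deltas" %in% names(tbl)) {
    tbl$replicate_deltas <- purrr::map(
      as.character(tbl$replicate_deltas),
      function(s) as.numeric(split_list_chr(s))
    )
  }
  tbl
}

split_list_chr <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  stringr::str_split_1(s, ";\\s*")
}

#' Read and write IRMS run sheets and survey points
#'
#' Plain-CSV persistence for the run-sheet schema (`sequence_no`,
#' `sample_type`, `sample_id`, `standard_name`, `raw_delta`, `facility`)
#' and the point-intercept schema (`plot_id`, `transect`, `point_m`,
#' `substrate`, `species`).
#'
#' @param run,survey Tibbles in the schemas above.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name run_io
NULL

#' @rdname run_io
#' @export
write_irms_run <- function(run, path) {
  readr::write_csv(tibble::as_tibble(run), path, na = "")
  invisible(path)
}

#' @rdname run_io
#' @export
read_irms_run <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sequence_no = "i", sample_type = "c", sample_id = "c",
                    standard_name = "c", raw_delta = "d", facility = "c"
                  ))
}

#' @rdname run_io
#' @export
write_survey_points <- function(survey, path) {
  readr::write_csv(survey, path, na = "")
  invisible(path)
}

#' @rdname run_io
#' @export
read_survey_points <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    plot_id = "c", transect = "i", point_m = "i",
                    substrate = "c", species = "c"
                  ))
}
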