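#' Per-species cover from point-intercept records
#'
#' Species cover is the percentage of survey points at which the species
#' was intercepted: `100 * hits / n_points_observed`. A point intercepting
#' a species several times (layered canopy) counts once, so a
#' single-species plot cannot exceed 100%. A complete plot has 1010
#' points; partial surveys are normalized by the points actually observed,
#' with a completeness warning.
#'
#' @param survey Long point-intercept tibble: `plot_id`, `transect`,
#'   `point_m`, `species` (`NA` on points with no vascular hit), as
#'   produced by [simulate_plot_survey()] or [read_survey_points()].
#' @return Tibble with one row per (plot, species): `plot_id`, `species`,
#'   `n_hits`, `cover_pct`, `n_points_observed`.
#' @examples
#' cfg <- sim_config(n_species = 15, n_plots = 1, seed = 8)
#' pool <- simulate_species_pool(cfg)
#' species_cover(simulate_plot_survey(pool, cfg))
#' @export
species_cover <- function(survey) {
  stopifnot(is.data.frame(survey),
            all(c("plot_id", "transect", "point_m", "species") %in%
                  names(survey)))
  if (nrow(survey) == 0L) abort("survey has no points")
  pts <- survey |>
    dplyr::distinct(.data$plot_id, .data$transect, .data$point_m) |>
    dplyr::count(.data$plot_id, name = "n_points_observed")
  partial <- pts$plot_id[pts$n_points_observed < 1010L]
  if (length(partial)) {
    warn(paste0("partial survey (<1010 points) at: ",
                paste(partial, collapse = ", "),
                "; cover normalized by observed points"))
  }
  survey |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::distinct(.data$plot_id, .data$species, .data$transect,
                    .data$point_m) |>
    dplyr::count(.data$plot_id, .data$species, name = "n_hits") |>
    dplyr::left_join(pts, by = "plot_id") |>
    dplyr::mutate(cover_pct = 100 * .data$n_hits / .data$n_points_observed) |>
    dplyr::arrange(.data$plot_id, .data$species)
}

#' Aggregate species cover to pathway cover
#'
#' Joins each surveyed species to its pathway assignment and sums member
#' covers per pathway and plot. Species without an assignment are never
#' dropped: they are reported under the `"unassigned"` category, so
#' pathway covers plus unassigned cover always add up exactly to total
#' species cover.
#'
#' @param cover Output of [species_cover()].
#' @param assignments A tibble with `species` and `pathway` (e.g. from
#'   [assign_pathways()]); `NA` pathways count as unassigned.
#' @return Tibble `plot_id`, `pathway` (a label or `"unassigned"`),
#'   `cover_pct`, `n_species`.
#' @export
pathway_cover <- function(cover, assignments) {
  stopifnot(is.data.frame(cover),
            all(c("plot_id", "species", "cover_pct") %in% names(cover)),
            is.data.frame(assignments),
            all(c("species", "pathway") %in% names(assignments)))
  cover |>
    dplyr::left_join(
      dplyr::distinct(assignments, .data$species, .data$pathway),
      by = "species"
    ) |>
    dplyr::mutate(pathway = dplyr::coalesce(.data$pathway, "unassigned")) |>
    dplyr::group_by(.data$plot_id, .data$pathway) |>
    dplyr::summarise(cover_pct = sum(.data$cover_pct),
                     n_species = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$plot_id, .data$pathway)
}

#' Relative C4 cover per plot
#'
#' The share of the C3+C4 vegetation cover contributed by C4 species:
#' `100 * C4 / (C3 + C4)`. Facultative classes (C3-CAM, C3-C4, C4-CAM,
#' CAM) contribute to neither pole by default; `pole_map` can reassign
#' them. Plots with no C3 and no C4 cover return `NA` rather than an
#' error.
#'
#' @param pw_cover Output of [pathway_cover()].
#' @param pole_map Named character vector mapping pathway labels to
#'   `"C3"` or `"C4"`; labels not mapped are ignored in the ratio.
#' @return Tibble `plot_id`, `c3_cover`, `c4_cover`, `relative_c4`.
#' @examples
#' pc <- tibble::tibble(plot_id = "P1", pathway = c("C3", "C4"),
#'                      cover_pct = c(30, 30), n_species = c(3, 2))
#' relative_c4_cover(pc) # 50%
#' @export
relative_c4_cover <- function(pw_cover,
                              pole_map = c(C3 = "C3", C4 = "C4")) {
  stopifnot(is.data.frame(pw_cover),
            all(c("plot_id", "pathway", "cover_pct") %in% names(pw_cover)))
  if (!all(pole_map %in% c("C3", "C4"))) {
    abort("`pole_map` values must be \"C3\" or \"C4\"")
  }
  pw_cover |>
    dplyr::mutate(pole = unname(pole_map[.data$pathway])) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      c3_cover = sum(.data$cover_pct[.data$pole %in% "C3"]),
      c4_cover = sum(.data$cover_pct[.data$pole %in% "C4"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      relative_c4 = dplyr::if_else(
        .data$c3_cover + .data$c4_cover > 0,
        100 * .data$c4_cover / (.data$c3_cover + .data$c4_cover),
        NA_real_
      )
    )
}

#' One-row-per-plot cover summary
#'
#' Convenience wrapper running [species_cover()], [pathway_cover()] and
#' [relative_c4_cover()] and spreading pathway covers wide.
#'
#' @inheritParams species_cover
#' @inheritParams pathway_cover
#' @inheritParams relative_c4_cover
#' @return Tibble with one row per plot: `plot_id`, one `cover_*` column
#'   per pathway present (plus `cover_unassigned`), `relative_c4`,
#'   `n_species`, `n_points_observed`.
#' @export
plot_cover_summary <- function(survey, assignments,
                               pole_map = c(C3 = "C3", C4 = "C4")) {
  cov <- species_cover(survey)
  pw <- pathway_cover(cov, assignments)
  rel <- relative_c4_cover(pw, pole_map)
  wide <- pw |>
    dplyr::select("plot_id", "pathway", "cover_pct") |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "cover_pct",
                       names_prefix = "cover_", values_fill = 0)
  n_sp <- cov |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(n_species = dplyr::n(),
                     n_points_observed = .data$n_points_observed[1],
                     .groups = "drop")
  wide |>
    dplyr::left_join(rel, by = "plot_id") |>
    dplyr::left_join(n_sp, by = "plot_id") |>
    dplyr::arrange(.data$plot_id)
}
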