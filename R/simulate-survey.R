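#' Simulate point-intercept plot surveys
#'
#' Emulates the field protocol: each 1-ha plot carries ten 100 m transects
#' laid out in a grid, read every metre with inclusive endpoints, giving
#' 10 × 101 = 1010 point records per plot. At each point the observer
#' records a substrate and zero or more vascular species hits; layered
#' canopies mean a point may intercept several species, each counted once.
#' A species can only be hit at plots where its voucher records place it,
#' with a per-species per-plot occupancy (per-point hit probability) drawn
#' from a Beta distribution with mean `config$mean_occupancy`, or supplied
#' directly via `occupancy`.
#'
#' @param pool A [simulate_species_pool()] result (species membership per
#'   plot is taken from its registry).
#' @param config The [sim_config()] used for the pool.
#' @param occupancy Optional tibble with columns `plot_id`, `species`,
#'   `occupancy` overriding the drawn per-point hit probabilities; species
#'   and plots absent from it fall back to drawn values.
#' @return A long tibble, one row per (point × species hit), with empty
#'   points carried as `species = NA`: columns `plot_id`, `transect`
#'   (1-10), `point_m` (0-100), `substrate`, `species`. Exactly 1010
#'   distinct (transect, point_m) positions per plot.
#' @examples
#' cfg <- sim_config(n_species = 20, n_plots = 1, seed = 3)
#' survey <- simulate_plot_survey(simulate_species_pool(cfg), cfg)
#' dplyr::n_distinct(survey$transect, survey$point_m)
#' @export
simulate_plot_survey <- function(pool, config, occupancy = NULL) {
  stopifnot(inherits(pool, "species_pool"), inherits(config, "sim_config"))
  if (nrow(pool$registry) == 0L) abort("registry is empty")
  with_seed(derive_seed(config$seed, "plot_survey"), {
    # species set per plot: binomials whose voucher records sit at the plot
    membership <- pool$registry |>
      dplyr::semi_join(pool$truth, by = c(raw_name = "species")) |>
      dplyr::distinct(.data$plot_id, species = .data$raw_name)

    grid <- tidyr::expand_grid(transect = 1:10, point_m = 0:100)
    substrates <- c("bare", "litter", "rock", "cryptogam")

    surveys <- purrr::map(pool$plots$plot_id, function(pid) {
      pts <- grid |>
        dplyr::mutate(
          plot_id = pid,
          substrate = sample(substrates, dplyr::n(), replace = TRUE,
                             prob = c(0.45, 0.35, 0.1, 0.1))
        )
      spp <- membership$species[membership$plot_id == pid]
      if (length(spp) == 0L) {
        return(dplyr::mutate(pts, species = NA_character_))
      }
      occ <- draw_occupancy(spp, pid, config, occupancy)
      hits <- purrr::map2(spp, occ, function(sp, p) {
        idx <- which(runif(nrow(grid)) < p)
        if (length(idx) == 0L) return(NULL)
        dplyr::mutate(pts[idx, ], species = sp)
      }) |> purrr::compact()
      hit_tbl <- dplyr::bind_rows(hits)
      empty <- pts |>
        dplyr::anti_join(hit_tbl, by = c("transect", "point_m")) |>
        dplyr::mutate(species = NA_character_)
      dplyr::bind_rows(hit_tbl, empty)
    })

    dplyr::bind_rows(surveys) |>
      dplyr::arrange(.data$plot_id, .data$transect, .data$point_m,
                     .data$species) |>
      dplyr::select("plot_id", "transect", "point_m", "substrate", "species")
  })
}

# Beta-distributed sparse occupancies with configurable mean; shape1 fixed
# at 1.2 so most species are rare and a few are locally dominant.
draw_occupancy <- function(species, plot_id, config, override) {
  shape1 <- 1.2
  shape2 <- shape1 * (1 - config$mean_occupancy) / config$mean_occupancy
  occ <- stats::rbeta(length(species), shape1, shape2)
  if (!is.null(override)) {
    key <- match(paste(plot_id, species),
                 paste(override$plot_id, override$species))
    occ[!is.na(key)] <- override$occupancy[key[!is.na(key)]]
  }
  occ
}
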