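#' Simulate a literature trait table and genus pathway table
#'
#' Emulates the published knowledge a compiler would cross-reference:
#' species-level pathway entries from synthetic trait databases and
#' regional floras covering a configurable fraction of the pool (entries
#' report the species' true pathway), a small rate of discordant entries
#' (a second source disagreeing at weaker evidence), and a genus-level
#' table marking genera as exclusively one pathway when every pool member
#' shares it and the genus is not a known mixed-pathway genus.
#'
#' @param pool A [simulate_species_pool()] result.
#' @param coverage Fraction of species with at least one literature entry.
#' @param discrepancy_rate Fraction of covered species that also receive a
#'   conflicting entry from a weaker-evidence source.
#' @param config The [sim_config()] (for the seed).
#' @return List with `entries` (tibble `source_id`, `species`, `pathway`,
#'   `evidence`) and `genus_table` (tibble `genus`, `pathway`,
#'   `exclusive`).
#' @examples
#' cfg <- sim_config(n_species = 40, seed = 11)
#' lit <- simulate_literature(simulate_species_pool(cfg), config = cfg)
#' head(lit$entries)
#' @export
simulate_literature <- function(pool, coverage = 0.72,
                                discrepancy_rate = 0.003,
                                config = pool$config) {
  stopifnot(inherits(pool, "species_pool"))
  assert_fraction(coverage, "coverage")
  assert_fraction(discrepancy_rate, "discrepancy_rate")
  with_seed(derive_seed(config$seed, "literature"), {
    truth <- pool$truth
    n_cov <- as.integer(round(nrow(truth) * coverage))
    covered <- truth[sort(sample.int(nrow(truth), n_cov)), ]
    sources <- c(trait_db_global = "database",
                 trait_db_regional = "database",
                 flora_compilation = "database",
                 gas_exchange_survey = "direct",
                 leaf_anatomy_study = "direct")
    src <- sample(names(sources), n_cov, replace = TRUE,
                  prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
    entries <- tibble::tibble(
      source_id = src,
      species = covered$species,
      pathway = covered$pathway,
      evidence = unname(sources[src])
    )
    n_disc <- as.integer(round(n_cov * discrepancy_rate))
    if (n_disc > 0L) {
      pick <- sample.int(n_cov, n_disc)
      wrong <- vapply(covered$pathway[pick], function(pw) {
        sample(setdiff(c("C3", "C4"), pw), 1L)
      }, "")
      entries <- dplyr::bind_rows(entries, tibble::tibble(
        source_id = "legacy_checklist",
        species = covered$species[pick],
        pathway = wrong,
        evidence = "inference"
      ))
    }
    genus_table <- truth |>
      dplyr::group_by(.data$genus) |>
      dplyr::summarise(
        pathway = .data$pathway[1],
        exclusive = dplyr::n_distinct(.data$pathway) == 1L &
          !.data$genus[1] %in% known_mixed_genera(),
        .groups = "drop"
      ) |>
      dplyr::mutate(pathway = dplyr::if_else(.data$exclusive, .data$pathway,
                                             NA_character_)) |>
      dplyr::arrange(.data$genus)
    list(entries = dplyr::arrange(entries, .data$species, .data$source_id),
         genus_table = genus_table)
  })
}

# Genera documented to contain more than one photosynthetic pathway;
# lineage inference is never allowed for these.
known_mixed_genera <- function() {
  c("Alternanthera", "Aristida", "Cleome", "Cyperus", "Eragrostis",
    "Euphorbia", "Heliotropium", "Neurachne", "Panicum", "Polycarpaea",
    "Tecticornia", "Tetragonia", "Tribulus")
}
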