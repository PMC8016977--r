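#' Simulate a species pool and voucher registry
#'
#' Generates a pool of `n_species` binomials with family composition and
#' pathway truth drawn from the configured priors, then emulates the raw
#' voucher record stream a plot network produces: every species yields at
#' least one barcoded voucher record at a plot, and configurable fractions
#' of extra records are exact duplicates, infraspecific variants
#' (`var.`/`subsp.`), genus-only determinations (`sp.`) and hybrids
#' (`×`). Families with no known C4 or CAM lineages always receive C3
#' truth; only families in [c4_capable_families()] can draw C4/CAM labels.
#'
#' The hidden truth table (species, pathway, true mean \eqn{\delta^{13}}C)
#' is retained so downstream stages can be tested against it; it is never
#' consulted by the analysis functions themselves.
#'
#' @param config A [sim_config()].
#' @return A list of class `"species_pool"` with elements `registry`
#'   (voucher records: `voucher_barcode`, `genetic_barcode`, `raw_name`,
#'   `family`, `genus`, `epithet`, `plot_id`, `survey_date`, `latitude`,
#'   `longitude`), `truth` (`species`, `family`, `genus`, `pathway`,
#'   `true_delta`), `plots` (`plot_id`, `latitude`, `longitude`) and
#'   `config`.
#' @examples
#' pool <- simulate_species_pool(sim_config(n_species = 30, seed = 42))
#' dplyr::count(pool$truth, pathway)
#' @export
simulate_species_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "species_pool"), {
    n <- config$n_species
    fams <- sample(names(config$family_mix), n, replace = TRUE,
                   prob = config$family_mix)
    genera_by_family <- family_genera()
    genus <- vapply(fams, function(f) sample(genera_by_family[[f]], 1L), "")
    epithet <- make_epithets(n)
    species <- paste(genus, epithet)
    # regenerate any accidental duplicate binomials (same genus + epithet)
    while (anyDuplicated(species)) {
      dup <- duplicated(species)
      epithet[dup] <- make_epithets(sum(dup), offset = n)
      species <- paste(genus, epithet)
    }
    pathway <- vapply(seq_len(n), function(i) {
      prior <- config$pathway_priors[[fams[i]]]
      if (is.null(prior) || !fams[i] %in% c4_capable_families()) {
        return("C3")
      }
      sample(names(prior), 1L, prob = prior)
    }, "")
    true_delta <- numeric(n)
    for (pw in unique(pathway)) {
      idx <- which(pathway == pw)
      true_delta[idx] <- draw_true_delta(length(idx), pw)
    }
    truth <- tibble::tibble(
      species = species, family = fams, genus = genus,
      pathway = pathway, true_delta = true_delta
    ) |> dplyr::arrange(.data$species)

    plots <- make_plots(config$n_plots)

    base <- tibble::tibble(
      raw_name = species, family = fams, genus = genus, epithet = epithet,
      plot_id = sample(plots$plot_id, n, replace = TRUE)
    )
    extras <- list(
      duplicate_records(base, config$duplicate_fraction, plots),
      infraspecific_records(base, config$infraspecific_fraction, plots),
      genus_only_records(base, config$genus_only_fraction, plots),
      hybrid_records(base, config$hybrid_fraction, plots)
    )
    registry <- dplyr::bind_rows(base, extras)
    m <- nrow(registry)
    registry <- registry |>
      dplyr::left_join(plots, by = "plot_id") |>
      dplyr::mutate(
        voucher_barcode = sprintf("V%06d", seq_len(m)),
        genetic_barcode = sprintf("G%06d", seq_len(m)),
        survey_date = as.Date("2011-01-01") +
          sample.int(2556L, m, replace = TRUE) - 1L
      ) |>
      dplyr::select("voucher_barcode", "genetic_barcode", "raw_name",
                    "family", "genus", "epithet", "plot_id", "survey_date",
                    "latitude", "longitude")

    structure(
      list(registry = registry, truth = truth, plots = plots,
           config = config),
      class = "species_pool"
    )
  })
}

#' @export
print.species_pool <- function(x, ...) {
  cat("<species_pool>", x$config$n_species, "species,",
      nrow(x$registry), "voucher records,", nrow(x$plots), "plots\n")
  invisible(x)
}

# Latin-flavoured specific epithets; binomial uniqueness is enforced by the
# caller (duplicate binomials are redrawn).
make_epithets <- function(n) {
  stems <- c("aur", "bas", "cal", "dent", "erem", "fil", "glab", "hirt",
             "lept", "mont", "nan", "obtus", "pall", "ram", "setos", "tenu",
             "vill", "virg", "xanth", "zon")
  ends <- c("ifolia", "icarpa", "ophylla", "ensis", "oides", "ata", "osa",
            "ella", "ifera", "ula", "ina", "escens")
  grid <- as.vector(outer(stems, ends, paste0))
  if (n <= length(grid)) {
    sample(grid, n)
  } else {
    sprintf("species%04d", sample.int(99999L, n))
  }
}

# Plot identifiers: <STATE 2-3 letters><IBRA bioregion 3 letters><4-digit
# sequence within bioregion>, e.g. "NTFIN0002", plus plot coordinates.
make_plots <- function(n_plots) {
  states <- c("SA", "NT", "WA", "QLD", "NSW", "VIC")
  bioregions <- c("FLB", "STP", "FIN", "GAS", "MDD", "CHC", "BBS", "MUL")
  st <- sample(states, n_plots, replace = TRUE)
  br <- sample(bioregions, n_plots, replace = TRUE)
  key <- paste0(st, br)
  seq_no <- stats::ave(seq_len(n_plots), key, FUN = seq_along)
  tibble::tibble(
    plot_id = sprintf("%s%s%04d", st, br, seq_no),
    latitude = runif(n_plots, -38, -12),
    longitude = runif(n_plots, 115, 150)
  )
}

n_extra <- function(base, fraction) as.integer(round(nrow(base) * fraction))

duplicate_records <- function(base, fraction, plots) {
  k <- n_extra(base, fraction)
  if (k == 0L) return(NULL)
  base[sample.int(nrow(base), k, replace = TRUE), ] |>
    dplyr::mutate(plot_id = sample(plots$plot_id, k, replace = TRUE))
}

infraspecific_records <- function(base, fraction, plots) {
  k <- n_extra(base, fraction)
  if (k == 0L) return(NULL)
  src <- base[sample.int(nrow(base), k, replace = TRUE), ]
  marker <- sample(c("var.", "subsp."), k, replace = TRUE)
  src |>
    dplyr::mutate(
      raw_name = paste(.data$raw_name, marker, make_epithets(k)),
      plot_id = sample(plots$plot_id, k, replace = TRUE)
    )
}

genus_only_records <- function(base, fraction, plots) {
  k <- n_extra(base, fraction)
  if (k == 0L) return(NULL)
  src <- base[sample.int(nrow(base), k, replace = TRUE), ]
  src |>
    dplyr::mutate(
      raw_name = paste(.data$genus, "sp."),
      epithet = NA_character_,
      plot_id = sample(plots$plot_id, k, replace = TRUE)
    )
}

hybrid_records <- function(base, fraction, plots) {
  k <- n_extra(base, fraction)
  if (k == 0L) return(NULL)
  src <- base[sample.int(nrow(base), k, replace = TRUE), ]
  src |>
    dplyr::mutate(
      epithet = make_epithets(k),
      raw_name = paste(.data$genus, "×", .data$epithet),
      plot_id = sample(plots$plot_id, k, replace = TRUE)
    )
}
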