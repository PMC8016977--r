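#' Reference standards used for \eqn{\delta^{13}}C normalization
#'
#' Certified and in-house calibrated standards used by the two analytical
#' facilities (the CSIRO Waite stable isotope facility and the MASS facility,
#' University of Adelaide) to drift-correct and normalize plant
#' \eqn{\delta^{13}}C measurements onto the VPDB scale. USGS-40 is an
#' internationally certified standard and is run at both facilities; all
#' others are in-house standards calibrated against certified materials.
#'
#' @param facility Optional facility filter, `"CSIRO"` or `"MASS"`. Standards
#'   flagged `"both"` are returned for either facility.
#'
#' @return A tibble with columns `name`, `verified_delta` (permil, VPDB) and
#'   `facility`.
#' @examples
#' irms_standards("MASS")
#' @export
irms_standards <- function(facility = NULL) {
  tbl <- tibble::tribble(
    ~name,                              ~verified_delta, ~facility,
    "USGS-40",                          -26.39,          "both",
    "High Organic Sediment Standard OAS", -28.85,        "CSIRO",
    "Wheat Flour Standard OAS",         -26.43,          "CSIRO",
    "Sorghum Flour Standard OAS",       -13.78,          "CSIRO",
    "Glycine",                          -31.20,          "MASS",
    "Glutamic Acid",                    -16.72,          "MASS",
    "Triphenylamine",                   -29.20,          "MASS",
    "USGS 41",                          -37.63,          "MASS"
  )
  if (!is.null(facility)) {
    facility <- match.arg(facility, c("CSIRO", "MASS"))
    tbl <- dplyr::filter(tbl, .data$facility %in% c(!!facility, "both"))
  }
  tbl
}

#' Pathway-conditional \eqn{\delta^{13}}C distributions
#'
#' Default distributions of bulk-tissue \eqn{\delta^{13}}C by photosynthetic
#' pathway, used by the synthetic-data generator. C3 tissue spans roughly
#' -37 to -20 permil (mean about -27), C4 tissue -16 to -12 permil (mean
#' about -13), and facultative C3-CAM tissue is highly variable across
#' roughly -27 to -13 permil depending on how much carbon is fixed in the
#' dark, so it is modelled as uniform over that range. Distributions for the
#' rarer pure-CAM, C3-C4 intermediate and C4-CAM classes are plausible
#' field values consistent with the classification thresholds.
#'
#' @return A tibble with one row per pathway label: `pathway`, `dist`
#'   (`"normal"`, truncated, or `"uniform"`), `mean_delta`, `sd_delta`,
#'   `range_low`, `range_high` (all permil, VPDB).
#' @examples
#' pathway_distributions()
#' @export
pathway_distributions <- function() {
  tibble::tribble(
    ~pathway, ~dist,     ~mean_delta, ~sd_delta, ~range_low, ~range_high,
    "C3",     "normal",  -27,         2.5,       -37,        -20,
    "C4",     "normal",  -13,         1.0,       -16,        -12,
    "CAM",    "normal",  -15,         1.5,       -19,        -11,
    "C3-CAM", "uniform", -20,         NA,        -27,        -13,
    "C3-C4",  "normal",  -25,         2.0,       -30,        -20,
    "C4-CAM", "normal",  -13.5,       1.0,       -16,        -11
  )
}

#' @rdname pathway_distributions
#' @format NULL
#' @export
pathway_labels <- function() {
  c("C3", "C4", "CAM", "C3-CAM", "C3-C4", "C4-CAM")
}

# Draw n true delta13C values for one pathway from the distribution table.
draw_true_delta <- function(n, pathway, dists = pathway_distributions()) {
  row <- dists[dists$pathway == pathway, ]
  if (nrow(row) != 1L) abort(paste0("unknown pathway label: ", pathway))
  if (row$dist == "uniform") {
    runif(n, row$range_low, row$range_high)
  } else {
    rnorm_trunc(n, row$mean_delta, row$sd_delta, row$range_low, row$range_high)
  }
}

# Families in which C4 (or CAM) lineages are known, hence eligible for
# non-C3 truth in simulation and targeted for isotope screening in analysis.
c4_capable_families <- function() {
  c("Aizoaceae", "Amaranthaceae", "Asteraceae", "Boraginaceae",
    "Caryophyllaceae", "Chenopodiaceae", "Cyperaceae", "Euphorbiaceae",
    "Poaceae", "Portulacaceae", "Zygophyllaceae")
}

# Genera available to the name generator, keyed by family.
family_genera <- function() {
  list(
    Poaceae         = c("Triodia", "Eragrostis", "Aristida", "Panicum",
                        "Themeda", "Austrostipa", "Enneapogon", "Neurachne"),
    Cyperaceae      = c("Cyperus", "Fimbristylis", "Schoenus"),
    Chenopodiaceae  = c("Atriplex", "Maireana", "Sclerolaena", "Tecticornia"),
    Aizoaceae       = c("Tetragonia", "Carpobrotus", "Gunniopsis"),
    Euphorbiaceae   = c("Euphorbia", "Beyeria"),
    Zygophyllaceae  = c("Tribulus", "Zygophyllum"),
    Portulacaceae   = c("Portulaca", "Calandrinia"),
    Asteraceae      = c("Olearia", "Senecio", "Rhodanthe"),
    Boraginaceae    = c("Heliotropium", "Halgania"),
    Caryophyllaceae = c("Polycarpaea", "Spergularia"),
    Amaranthaceae   = c("Ptilotus", "Alternanthera"),
    Fabaceae        = c("Acacia", "Senna", "Indigofera", "Swainsona"),
    Myrtaceae       = c("Eucalyptus", "Corymbia", "Melaleuca"),
    Malvaceae       = c("Sida", "Abutilon"),
    Proteaceae      = c("Hakea", "Grevillea"),
    Solanaceae      = c("Solanum")
  )
}

#' Published sources used to compile pathway assignments
#'
#' The bundled reference list of trait databases and peer-reviewed studies
#' a pathway compilation draws on, with the number of species each source
#' assigns. Several sources can support one species, so the column sum
#' exceeds the number of unique species.
#'
#' @return A tibble with columns `source_id` and `n_species_assigned`.
#' @examples
#' nrow(literature_sources())
#' @export
literature_sources <- function() {
  path <- system.file("extdata", "literature_sources.csv",
                      package = "photopath", mustWork = TRUE)
  readr::read_csv(path, col_types = "ci")
}
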