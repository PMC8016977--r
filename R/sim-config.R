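#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator:
#' species-pool composition, survey geometry, and IRMS run structure. The
#' defaults describe the study conditions the downstream analysis assumes:
#' 1-ha plots read at 1010 point-intercept positions, about 10% of isotope
#' unknowns re-run as replicates, and pathway-conditional
#' \eqn{\delta^{13}}C truth drawn from [pathway_distributions()].
#'
#' @param n_species Number of distinct species in the pool.
#' @param n_plots Number of 1-ha survey plots.
#' @param family_mix Named numeric vector of family proportions (must sum to
#'   1 within `1e-6`). Names must be plant families known to
#'   [family_genera()].
#' @param pathway_priors Named list: family -> named probability vector over
#'   the labels in [pathway_labels()]. Families absent from the list, and
#'   all families without known C4/CAM lineages, are forced to C3.
#' @param noise_sd Analytical noise SD added to raw IRMS readings (permil).
#' @param drift_per_position Linear instrument drift per sequence position
#'   (permil per step).
#' @param replicate_fraction Fraction of isotope unknowns re-measured as
#'   replicates within a run.
#' @param genus_only_fraction,hybrid_fraction,infraspecific_fraction,duplicate_fraction
#'   Fractions (of `n_species`) of extra voucher records that are genus-only
#'   determinations, hybrids, infraspecific variants of pool species, and
#'   exact duplicate binomials, emulating the raw herbarium record stream.
#' @param mean_occupancy Mean per-point hit probability of a species present
#'   at a plot (occupancies are drawn from a Beta distribution with this
#'   mean; sparse arid-zone cover).
#' @param seed Master seed; every generated artifact derives its own child
#'   stream from it, so outputs are bit-reproducible.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_species = 50, n_plots = 2, seed = 1)
#' @export
sim_config <- function(n_species = 200,
                       n_plots = 5,
                       family_mix = NULL,
                       pathway_priors = NULL,
                       noise_sd = 0.1,
                       drift_per_position = 0.005,
                       replicate_fraction = 0.10,
                       genus_only_fraction = 0.05,
                       hybrid_fraction = 0.02,
                       infraspecific_fraction = 0.08,
                       duplicate_fraction = 0.15,
                       mean_occupancy = 0.06,
                       seed = 1L) {
  if (!is_number(n_species) || n_species < 1) abort("`n_species` must be >= 1")
  if (!is_number(n_plots) || n_plots < 1) abort("`n_plots` must be >= 1")
  family_mix <- family_mix %||% default_family_mix()
  if (is.null(names(family_mix)) || any(!nzchar(names(family_mix)))) {
    abort("`family_mix` must be a named numeric vector")
  }
  if (any(family_mix < 0) || abs(sum(family_mix) - 1) > 1e-6) {
    abort("`family_mix` proportions must be non-negative and sum to 1")
  }
  unknown <- setdiff(names(family_mix), names(family_genera()))
  if (length(unknown)) {
    abort(paste0("families without a genus pool: ",
                 paste(unknown, collapse = ", ")))
  }
  pathway_priors <- pathway_priors %||% default_pathway_priors()
  for (fam in names(pathway_priors)) {
    p <- pathway_priors[[fam]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      abort(paste0("pathway priors for ", fam,
                   " must be non-negative and sum to 1"))
    }
    if (!all(names(p) %in% pathway_labels())) {
      abort(paste0("unknown pathway label in priors for ", fam))
    }
    if (!fam %in% c4_capable_families() &&
        sum(p[setdiff(names(p), "C3")]) > 1e-9) {
      abort(paste0(fam, " has no known C4/CAM lineages; its prior must be ",
                   "entirely C3"))
    }
  }
  assert_fraction(replicate_fraction, "replicate_fraction")
  assert_fraction(genus_only_fraction, "genus_only_fraction")
  assert_fraction(hybrid_fraction, "hybrid_fraction")
  assert_fraction(infraspecific_fraction, "infraspecific_fraction")
  assert_fraction(duplicate_fraction, "duplicate_fraction")
  if (!is_number(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (!is_number(drift_per_position)) abort("`drift_per_position` must be a number")
  if (!is_number(mean_occupancy) || mean_occupancy <= 0 || mean_occupancy >= 1) {
    abort("`mean_occupancy` must be in (0, 1)")
  }
  structure(
    list(
      n_species = as.integer(n_species),
      n_plots = as.integer(n_plots),
      family_mix = family_mix,
      pathway_priors = pathway_priors,
      noise_sd = noise_sd,
      drift_per_position = drift_per_position,
      replicate_fraction = replicate_fraction,
      genus_only_fraction = genus_only_fraction,
      hybrid_fraction = hybrid_fraction,
      infraspecific_fraction = infraspecific_fraction,
      duplicate_fraction = duplicate_fraction,
      mean_occupancy = mean_occupancy,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

default_family_mix <- function() {
  c(Poaceae = 0.25, Fabaceae = 0.15, Myrtaceae = 0.10,
    Chenopodiaceae = 0.10, Asteraceae = 0.08, Cyperaceae = 0.06,
    Malvaceae = 0.06, Proteaceae = 0.05, Aizoaceae = 0.04,
    Euphorbiaceae = 0.03, Zygophyllaceae = 0.02, Portulacaceae = 0.02,
    Boraginaceae = 0.02, Caryophyllaceae = 0.01, Amaranthaceae = 0.01)
}

# Field-plausible priors: warm-season grasses and chenopods carry most of
# the C4 signal; succulent families carry the CAM potential.
default_pathway_priors <- function() {
  list(
    Poaceae         = c(C3 = 0.52, C4 = 0.45, "C3-C4" = 0.03),
    Cyperaceae      = c(C3 = 0.60, C4 = 0.40),
    Chenopodiaceae  = c(C3 = 0.70, C4 = 0.30),
    Aizoaceae       = c(C3 = 0.40, C4 = 0.20, CAM = 0.15, "C3-CAM" = 0.25),
    Euphorbiaceae   = c(C3 = 0.80, C4 = 0.20),
    Zygophyllaceae  = c(C3 = 0.70, C4 = 0.30),
    Portulacaceae   = c(C4 = 0.60, "C4-CAM" = 0.20, "C3-CAM" = 0.20),
    Asteraceae      = c(C3 = 0.95, C4 = 0.05),
    Boraginaceae    = c(C3 = 0.85, C4 = 0.15),
    Caryophyllaceae = c(C3 = 0.85, C4 = 0.15),
    Amaranthaceae   = c(C3 = 0.75, C4 = 0.25)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  species:", x$n_species, " plots:", x$n_plots,
      " seed:", x$seed, "\n")
  cat("  noise_sd:", x$noise_sd, "permil  drift:", x$drift_per_position,
      "permil/step  replicates:", x$replicate_fraction, "\n")
  invisible(x)
}
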