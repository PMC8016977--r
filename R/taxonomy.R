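#' Parse herbarium determination strings
#'
#' Decomposes raw scientific-name strings as herbaria write them into
#' genus, specific epithet, rank and markers, so that the record-filtering
#' rules (exclude genus/family-level and hybrid determinations, collapse
#' infraspecific taxa to the binomial) can be applied mechanically.
#' Authority strings (`"(Benth.) Maiden"` and similar trailing author
#' abbreviations) are stripped before parsing. Hybrid markers (`×` or a
#' free-standing `x`), placeholders (`sp.`, `spp.`, `aff.`, `cf.`) and
#' infraspecific markers (`var.`, `subsp.`/`ssp.`, `f.`) are recognised.
#' Unparseable strings degrade to `rank = "genus_only"` with a warning,
#' never an error.
#'
#' @param raw Character vector of determination strings.
#' @return A tibble, one row per input: `raw`, `genus`, `epithet`, `rank`
#'   (`"species"`, `"genus_only"`, `"family_only"`, `"infraspecific"`),
#'   `infraspecific_marker` (`"var."`, `"subsp."`, `"f."` or `NA`),
#'   `is_hybrid`, `binomial` (`NA` unless resolvable to *Genus epithet*).
#' @examples
#' parse_taxon_name(c("Acacia aneura var. major", "Eragrostis sp.",
#'                    "Eucalyptus × phylacis"))
#' @export
parse_taxon_name <- function(raw) {
  stopifnot(is.character(raw))
  purrr::map(raw, parse_one_name) |> dplyr::bind_rows()
}

parse_one_name <- function(raw) {
  out <- tibble::tibble(
    raw = raw, genus = NA_character_, epithet = NA_character_,
    rank = "genus_only", infraspecific_marker = NA_character_,
    is_hybrid = FALSE, binomial = NA_character_
  )
  s <- stringr::str_squish(raw %||% "")
  if (!nzchar(s)) {
    warn("empty name string")
    return(out)
  }
  # strip parenthesised and trailing authority fragments
  s <- stringr::str_squish(stringr::str_remove_all(s, "\\([^)]*\\)"))
  # case data-entry noise (all-caps or all-lower): sentence-case first
  if (!stringr::str_detect(s, "[a-z]") || stringr::str_detect(s, "^[a-z]")) {
    s <- stringr::str_to_sentence(s)
  }
  tokens <- stringr::str_split_1(s, " ")
  hybrid <- tokens %in% c("×", "x", "X")
  out$is_hybrid <- any(hybrid) || any(stringr::str_detect(tokens, "^×"))
  tokens <- stringr::str_remove(tokens[!hybrid], "^×")
  if (length(tokens) == 0L || !stringr::str_detect(tokens[1], "^[A-Z]")) {
    warn(paste0("cannot parse name: '", raw, "'"))
    return(out)
  }
  out$genus <- tokens[1]
  if (stringr::str_detect(tokens[1], "aceae$") && length(tokens) == 1L) {
    out$rank <- "family_only"
    out$genus <- NA_character_
    return(out)
  }
  placeholders <- c("sp.", "spp.", "sp", "aff.", "cf.")
  if (length(tokens) < 2L || tokens[2] %in% placeholders) {
    out$rank <- "genus_only"
    return(out)
  }
  if (!stringr::str_detect(tokens[2], "^[a-z][a-z-]+$")) {
    warn(paste0("cannot parse epithet in: '", raw, "'"))
    return(out)
  }
  out$epithet <- tokens[2]
  out$rank <- "species"
  out$binomial <- paste(out$genus, out$epithet)
  rest <- tokens[-(1:2)]
  markers <- c("var." = "var.", "subsp." = "subsp.", "ssp." = "subsp.",
               "f." = "f.", "forma" = "f.")
  hit <- which(rest %in% names(markers))
  if (length(hit)) {
    out$rank <- "infraspecific"
    out$infraspecific_marker <- unname(markers[rest[hit[1]]])
  }
  out
}

#' Filter voucher records to the unique-species list
#'
#' Applies the record-elimination rules that turn a raw multi-state voucher
#' stream into the species list that receives pathway assignments: records
#' determined only to family or genus level are excluded, hybrids are
#' excluded, infraspecific taxa (varieties, subspecies, forms) are
#' collapsed to their binomial on the assumption that they share the
#' species' pathway, and duplicate binomials are deduplicated after
#' case/whitespace normalization. Output order is alphabetical, so the
#' result is deterministic. Synonyms are never merged automatically — the
#' herbarium name is the point of truth; any `synonym` column on the input
#' is carried through as an annotation.
#'
#' @param records A data frame with a `raw_name` column (a bare character
#'   vector is also accepted); optional `family` and `plot_id` columns are
#'   carried onto the species list (first occurrence wins).
#' @return An object of class `"species_filter"`: a list with `species`
#'   (tibble: `species`, `genus`, and `family` if supplied), `report`
#'   (one-row tibble of reconciling counts) and `exclusions` (tibble:
#'   `raw_name`, `reason`). `tidy()` returns the species tibble, `glance()`
#'   the report. The counts reconcile exactly:
#'   `n_input_records = n_unique_species + n_excluded_genus_or_family +
#'   n_excluded_hybrid + n_duplicates_removed`.
#' @examples
#' res <- filter_species_records(c("Acacia aneura", "Acacia aneura var. major",
#'                                 "Acacia sp.", "Triodia basedowii"))
#' glance(res)
#' @export
filter_species_records <- function(records) {
  if (is.character(records)) {
    records <- tibble::tibble(raw_name = records)
  }
  stopifnot(is.data.frame(records), "raw_name" %in% names(records))
  if (nrow(records) == 0L) {
    return(new_species_filter(
      species = tibble::tibble(species = character(), genus = character()),
      report = filter_report_row(0L, 0L, 0L, 0L, 0L, 0L),
      exclusions = tibble::tibble(raw_name = character(),
                                  reason = character())
    ))
  }
  parsed <- parse_taxon_name(stringr::str_squish(records$raw_name))
  parsed$family <- if ("family" %in% names(records)) {
    records$family
  } else {
    NA_character_
  }
  excl_rank <- !parsed$is_hybrid &
    parsed$rank %in% c("genus_only", "family_only")
  excl_hybrid <- parsed$is_hybrid
  keep <- parsed[!excl_rank & !excl_hybrid, ]
  n_collapsed <- sum(keep$rank == "infraspecific")
  # normalize case before deduplication: genus capitalised, epithet lower
  keep$binomial <- paste(
    stringr::str_to_title(keep$genus), stringr::str_to_lower(keep$epithet)
  )
  dup <- duplicated(keep$binomial)
  species <- keep[!dup, ] |>
    dplyr::transmute(
      species = .data$binomial,
      genus = stringr::str_to_title(.data$genus),
      family = .data$family
    ) |>
    dplyr::arrange(.data$species)
  if (all(is.na(species$family))) species$family <- NULL
  exclusions <- dplyr::bind_rows(
    tibble::tibble(raw_name = parsed$raw[excl_rank],
                   reason = "genus_or_family_only"),
    tibble::tibble(raw_name = parsed$raw[excl_hybrid], reason = "hybrid"),
    tibble::tibble(raw_name = keep$raw[dup], reason = "duplicate_binomial")
  )
  new_species_filter(
    species = species,
    report = filter_report_row(
      n_input = nrow(records),
      n_genus_family = sum(excl_rank),
      n_hybrid = sum(excl_hybrid),
      n_collapsed = n_collapsed,
      n_dupes = sum(dup),
      n_unique = nrow(species)
    ),
    exclusions = exclusions
  )
}

filter_report_row <- function(n_input, n_genus_family, n_hybrid,
                              n_collapsed, n_dupes, n_unique) {
  tibble::tibble(
    n_input_records = as.integer(n_input),
    n_excluded_genus_or_family = as.integer(n_genus_family),
    n_excluded_hybrid = as.integer(n_hybrid),
    n_collapsed_infraspecific = as.integer(n_collapsed),
    n_duplicates_removed = as.integer(n_dupes),
    n_unique_species = as.integer(n_unique)
  )
}

new_species_filter <- function(species, report, exclusions) {
  structure(list(species = species, report = report,
                 exclusions = exclusions),
            class = "species_filter")
}

#' @export
print.species_filter <- function(x, ...) {
  r <- x$report
  cat("<species_filter>", r$n_input_records, "records ->",
      r$n_unique_species, "unique species\n")
  cat("  excluded:", r$n_excluded_genus_or_family, "genus/family-only,",
      r$n_excluded_hybrid, "hybrid;", r$n_collapsed_infraspecific,
      "collapsed to binomial;", r$n_duplicates_removed, "duplicates\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.species_filter <- function(x, ...) x$species

#' @exportS3Method generics::glance
glance.species_filter <- function(x, ...) x$report
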