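#' Evidence ranking for literature sources
#'
#' Ordered evidence classes, strongest first, used to resolve discordant
#' literature assignments: a direct physiological or isotopic measurement
#' beats a regional flora or trait-database compilation, which beats
#' lineage-level inference. The ranking is configurable because "best
#' direct evidence" is ultimately a judgement call.
#'
#' @return Character vector of evidence classes, strongest first.
#' @export
evidence_ranking <- function() c("direct", "database", "inference")

#' Assign a pathway to one species from literature entries
#'
#' Cross-references a species against literature entries. If all entries
#' agree, the assignment carries every supporting source; if they
#' disagree, the discordant entries are returned as a conflict set for
#' [resolve_conflict()].
#'
#' @param species A single binomial.
#' @param entries Literature table: `source_id`, `species`, `pathway`,
#'   `evidence` (a class in `ranking`).
#' @param ranking Evidence classes, strongest first.
#' @return A one-row assignment tibble (`species`, `pathway`, `method`,
#'   `sources` list-column, `tentative`, `discrepancy_note`), or the
#'   conflicting entries with class `"pathway_conflict"`, or `NULL` when
#'   the species has no entry (it then falls through to the isotope
#'   route).
#' @examples
#' lit <- tibble::tibble(source_id = c("sage2016", "watson1992"),
#'                       species = "Eragrostis eriopoda",
#'                       pathway = "C4", evidence = "database")
#' assign_from_literature("Eragrostis eriopoda", lit)
#' @export
assign_from_literature <- function(species, entries,
                                   ranking = evidence_ranking()) {
  check_literature(entries, ranking)
  hits <- entries[entries$species == species, ]
  if (nrow(hits) == 0L) return(NULL)
  if (dplyr::n_distinct(hits$pathway) == 1L) {
    return(tibble::tibble(
      species = species,
      pathway = hits$pathway[1],
      method = "literature",
      sources = list(sort(unique(hits$source_id))),
      tentative = FALSE,
      discrepancy_note = NA_character_
    ))
  }
  structure(hits, class = c("pathway_conflict", class(hits)))
}

#' Resolve discordant literature assignments
#'
#' The entry whose evidence class ranks highest wins; the losing sources
#' are recorded in a discrepancy note. When the strongest evidence class
#' still contains more than one pathway, the tie is broken
#' deterministically by `source_id` order and the assignment is flagged
#' tentative.
#'
#' @param conflicts Conflict set from [assign_from_literature()] (or any
#'   tibble of discordant entries for one species).
#' @inheritParams assign_from_literature
#' @return A one-row assignment tibble.
#' @examples
#' cf <- tibble::tibble(source_id = c("trait_db", "gas_exchange_study"),
#'                      species = "Panicum decompositum",
#'                      pathway = c("C3", "C4"),
#'                      evidence = c("database", "direct"))
#' resolve_conflict(cf)
#' @export
resolve_conflict <- function(conflicts, ranking = evidence_ranking()) {
  stopifnot(is.data.frame(conflicts), nrow(conflicts) >= 2L)
  check_literature(conflicts, ranking)
  if (dplyr::n_distinct(conflicts$species) != 1L) {
    abort("conflict set must concern a single species")
  }
  rank_no <- match(conflicts$evidence, ranking)
  best <- conflicts[rank_no == min(rank_no), ]
  best <- best[order(best$source_id), ]
  tie <- dplyr::n_distinct(best$pathway) > 1L
  chosen <- best$pathway[1]
  supporting <- conflicts$source_id[conflicts$pathway == chosen]
  losing <- conflicts[conflicts$pathway != chosen, ]
  tibble::tibble(
    species = conflicts$species[1],
    pathway = chosen,
    method = "literature",
    sources = list(sort(unique(supporting))),
    tentative = tie,
    discrepancy_note = paste0(
      "conflicting assignment(s): ",
      paste(sprintf("%s (%s, %s)", losing$pathway, losing$source_id,
                    losing$evidence), collapse = "; "),
      if (tie) "; tie broken by source_id order" else ""
    )
  )
}

check_literature <- function(entries, ranking) {
  stopifnot(is.data.frame(entries),
            all(c("source_id", "species", "pathway", "evidence") %in%
                  names(entries)))
  bad <- setdiff(unique(entries$evidence), ranking)
  if (length(bad)) {
    abort(paste0("unknown evidence class(es): ", paste(bad, collapse = ", ")))
  }
  bad_pw <- setdiff(unique(entries$pathway), pathway_labels())
  if (length(bad_pw)) {
    abort(paste0("unknown pathway label(s): ", paste(bad_pw, collapse = ", ")))
  }
  invisible(entries)
}

#' Infer a pathway from an exclusively C3/C4/CAM genus
#'
#' Species without species-level literature can inherit the pathway of
#' their genus when every known member of the genus shares it (e.g.
#' *Acacia* and *Eucalyptus* are presumptive C3). Genera flagged
#' non-exclusive (mixed-pathway genera such as *Eragrostis*, *Panicum* or
#' *Tecticornia*) are never inferable.
#'
#' @param species A binomial; the genus is its first word.
#' @param genus_table Tibble `genus`, `pathway`, `exclusive` (logical).
#' @return A one-row assignment tibble with `method = "lineage_inferred"`,
#'   or `NULL` when the genus is absent or not exclusive.
#' @examples
#' gt <- tibble::tibble(genus = c("Acacia", "Eragrostis"),
#'                      pathway = c("C3", "C4"),
#'                      exclusive = c(TRUE, FALSE))
#' infer_from_genus("Acacia victoriae", gt)
#' infer_from_genus("Eragrostis eriopoda", gt) # NULL
#' @export
infer_from_genus <- function(species, genus_table) {
  stopifnot(is.data.frame(genus_table),
            all(c("genus", "pathway", "exclusive") %in% names(genus_table)))
  genus <- stringr::str_split_1(species, " ")[1]
  row <- genus_table[genus_table$genus == genus & genus_table$exclusive, ]
  if (nrow(row) == 0L) return(NULL)
  tibble::tibble(
    species = species,
    pathway = row$pathway[1],
    method = "lineage_inferred",
    sources = list(character(0)),
    tentative = FALSE,
    discrepancy_note = NA_character_
  )
}

#' Assign photosynthetic pathways to a species list
#'
#' The full assignment cascade, in strict precedence order: (1)
#' species-level literature (conflicts resolved by evidence rank); (2)
#' lineage inference from exclusively C3/C4/CAM genera; (3)
#' \eqn{\delta^{13}}C classification — the CAM rule for genera with known
#' CAM potential, otherwise the -19 permil C3/C4 rule, and only for
#' species in the C4-target families or CAM-potential genera (other
#' families are presumed C3-only and are not isotope-classified). Species
#' with no literature, no exclusive genus and no usable tissue
#' \eqn{\delta^{13}}C remain unassigned with a reason.
#'
#' @param species Tibble with columns `species` and (ideally) `family`;
#'   `genus` is derived from the binomial when absent. A bare character
#'   vector of binomials is accepted.
#' @param literature Optional literature table (`source_id`, `species`,
#'   `pathway`, `evidence`).
#' @param genus_table Optional genus table (`genus`, `pathway`,
#'   `exclusive`).
#' @param deltas Optional calibrated tissue values: `species`, `delta13C`
#'   (or `delta_vpdb`), plus optional `facility`, `plot_id`,
#'   `replicate_deltas`. When a species has several rows the first is used
#'   (rows are expected in specimen-priority order) and the rest are noted.
#' @param rules A [classification_rules()].
#' @param ranking Evidence classes, strongest first.
#' @return A tibble with one row per input species: `species`, `family`,
#'   `genus`, `pathway` (`NA` when unassigned), `method` (`"literature"`,
#'   `"lineage_inferred"`, `"isotope"` or `NA`), `sources` (list-column),
#'   `delta13C`, `facility`, `tentative`, `discrepancy_note`,
#'   `unassigned_reason`.
#' @examples
#' sp <- tibble::tibble(species = c("Acacia aneura", "Triodia basedowii"),
#'                      family = c("Fabaceae", "Poaceae"))
#' gt <- tibble::tibble(genus = "Acacia", pathway = "C3", exclusive = TRUE)
#' dl <- tibble::tibble(species = "Triodia basedowii", delta13C = -13.2)
#' assign_pathways(sp, genus_table = gt, deltas = dl)
#' @export
assign_pathways <- function(species, literature = NULL, genus_table = NULL,
                            deltas = NULL, rules = classification_rules(),
                            ranking = evidence_ranking()) {
  if (is.character(species)) species <- tibble::tibble(species = species)
  stopifnot(is.data.frame(species), "species" %in% names(species))
  out <- tibble::as_tibble(species)
  if (!"genus" %in% names(out)) {
    out$genus <- stringr::str_extract(out$species, "^\\S+")
  }
  if (!"family" %in% names(out)) out$family <- NA_character_
  if (!is.null(literature)) check_literature(literature, ranking)
  deltas <- normalize_deltas(deltas)

  rows <- purrr::pmap(
    list(out$species, out$family, out$genus),
    function(sp, fam, gen) {
      assign_one(sp, fam, gen, literature, genus_table, deltas, rules,
                 ranking)
    }
  )
  res <- dplyr::bind_rows(rows)
  out |>
    dplyr::select("species", "family", "genus") |>
    dplyr::left_join(res, by = "species") |>
    dplyr::arrange(.data$species)
}

assign_one <- function(sp, fam, gen, literature, genus_table, deltas,
                       rules, ranking) {
  base <- tibble::tibble(
    species = sp, pathway = NA_character_, method = NA_character_,
    sources = list(character(0)), delta13C = NA_real_,
    facility = NA_character_, tentative = FALSE,
    discrepancy_note = NA_character_, unassigned_reason = NA_character_
  )
  drow <- if (!is.null(deltas)) deltas[deltas$species == sp, ] else NULL
  note_delta <- function(row) {
    # literature/lineage assignments keep the measured delta as context
    if (!is.null(drow) && nrow(drow) > 0L) {
      row$delta13C <- drow$delta13C[1]
      row$facility <- drow$facility[1]
    }
    row
  }
  if (!is.null(literature)) {
    lit <- assign_from_literature(sp, literature, ranking)
    if (inherits(lit, "pathway_conflict")) {
      lit <- resolve_conflict(lit, ranking)
    }
    if (!is.null(lit)) {
      row <- dplyr::bind_cols(
        lit[, c("species", "pathway", "method", "sources", "tentative",
                "discrepancy_note")],
        base[, c("delta13C", "facility", "unassigned_reason")]
      )
      return(note_delta(cam_potential_note(row, gen, rules)))
    }
  }
  if (!is.null(genus_table)) {
    lin <- infer_from_genus(sp, genus_table)
    if (!is.null(lin)) {
      row <- dplyr::bind_cols(
        lin[, c("species", "pathway", "method", "sources", "tentative",
                "discrepancy_note")],
        base[, c("delta13C", "facility", "unassigned_reason")]
      )
      return(note_delta(row))
    }
  }
  cam_genus <- gen %in% rules$cam_potential_genera
  target <- (!is.na(fam) && fam %in% rules$c4_target_families) || cam_genus
  if (!target) {
    base$unassigned_reason <- "outside isotope target families"
    return(base)
  }
  if (is.null(drow) || nrow(drow) == 0L) {
    base$unassigned_reason <- "no tissue delta13C available"
    return(base)
  }
  d <- drow$delta13C[1]
  base$delta13C <- d
  base$facility <- drow$facility[1]
  if (nrow(drow) > 1L) {
    base$discrepancy_note <- paste0(
      "additional specimen delta13C held as replicates: ",
      paste(sprintf("%.2f", drow$delta13C[-1]), collapse = ", ")
    )
  }
  label <- if (cam_genus) classify_cam_potential(d, rules) else
    classify_c3_c4(d, rules)
  if (label == "ambiguous") {
    base$unassigned_reason <-
      "delta13C exactly on the C3/C4 boundary; flagged for review"
    return(base)
  }
  base$pathway <- label
  base$method <- "isotope"
  base$tentative <- label %in% c("CAM", "C3+CAM")
  base
}

# standing caution for documented-C4 genera with CAM potential
cam_potential_note <- function(row, gen, rules) {
  if (!is.na(row$pathway) && row$pathway == "C4" &&
      gen %in% rules$cam_potential_genera) {
    note <- "genus has documented CAM potential; C4-CAM cannot be excluded"
    row$discrepancy_note <- if (is.na(row$discrepancy_note)) note else
      paste(row$discrepancy_note, note, sep = "; ")
  }
  row
}

normalize_deltas <- function(deltas) {
  if (is.null(deltas)) return(NULL)
  stopifnot(is.data.frame(deltas), "species" %in% names(deltas))
  if (!"delta13C" %in% names(deltas)) {
    if ("delta_vpdb" %in% names(deltas)) {
      deltas$delta13C <- deltas$delta_vpdb
    } else {
      abort("`deltas` needs a `delta13C` (or `delta_vpdb`) column")
    }
  }
  if (!"facility" %in% names(deltas)) deltas$facility <- NA_character_
  deltas
}

#' Summarize a pathway assignment table
#'
#' Counts per pathway, the family composition of the C4 flora with
#' percentage shares (truncated, not rounded, to one decimal place), and
#' the genera that contain more than one pathway — always computed from
#' the assignments themselves.
#'
#' @param assignments Output of [assign_pathways()] (or any tibble with
#'   `species`, `family`, `genus`, `pathway`).
#' @return A list of class `"pathway_summary"`: `pathway_counts` (tibble
#'   `pathway`, `n`), `c4_family_shares` (tibble `family`, `n`,
#'   `share_pct`), `mixed_genera` (sorted character vector), `n_assigned`,
#'   `n_unassigned`.
#' @examples
#' tbl <- tibble::tibble(
#'   species = c("A a", "B b", "C c"), family = "Poaceae",
#'   genus = c("A", "B", "C"), pathway = c("C4", "C4", "C3")
#' )
#' summarize_pathways(tbl)
#' @export
summarize_pathways <- function(assignments) {
  stopifnot(is.data.frame(assignments),
            all(c("species", "family", "genus", "pathway") %in%
                  names(assignments)))
  assigned <- assignments[!is.na(assignments$pathway), ]
  counts <- assigned |>
    dplyr::count(.data$pathway) |>
    dplyr::arrange(.data$pathway)
  c4 <- assigned[assigned$pathway == "C4", ]
  shares <- c4 |>
    dplyr::count(.data$family) |>
    dplyr::mutate(share_pct = truncate1(100 * .data$n / nrow(c4))) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$family)
  mixed <- assigned |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$pathway),
                     .groups = "drop") |>
    dplyr::filter(.data$k >= 2L)
  structure(
    list(
      pathway_counts = counts,
      c4_family_shares = shares,
      mixed_genera = sort(mixed$genus),
      n_assigned = nrow(assigned),
      n_unassigned = nrow(assignments) - nrow(assigned)
    ),
    class = "pathway_summary"
  )
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat("<pathway_summary>", x$n_assigned, "assigned,", x$n_unassigned,
      "unassigned\n")
  print(x$pathway_counts, n = Inf)
  if (nrow(x$c4_family_shares)) {
    cat("C4 flora by family (share %, truncated to 1 dp):\n")
    print(x$c4_family_shares, n = 5)
  }
  if (length(x$mixed_genera)) {
    cat("mixed-pathway genera:", paste(x$mixed_genera, collapse = ", "),
        "\n")
  }
  invisible(x)
}
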