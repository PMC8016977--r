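test_that("C3/C4 threshold rule, including the exact boundary", {
  expect_equal(classify_c3_c4(-27), "C3")
  expect_equal(classify_c3_c4(-13), "C4")
  expect_equal(classify_c3_c4(-19), "ambiguous")
  expect_error(classify_c3_c4(NaN), "finite")
})

test_that("CAM rule partitions the line with closed C3+CAM band", {
  expect_equal(classify_cam_potential(-18), "CAM")
  expect_equal(classify_cam_potential(-22), "C3+CAM")
  expect_equal(classify_cam_potential(-26), "C3")
  expect_equal(classify_cam_potential(-20.5), "C3+CAM")
  expect_equal(classify_cam_potential(c(-24, -20)), c("C3+CAM", "C3+CAM"))
})

test_that("every finite delta receives exactly one label under each rule", {
  grid <- seq(-45, -5, by = 0.001)
  lab1 <- classify_c3_c4(grid)
  lab2 <- classify_cam_potential(grid)
  expect_false(any(is.na(lab1)))
  expect_false(any(is.na(lab2)))
  # the boundary review label occurs only exactly on the threshold
  expect_setequal(unique(lab1), c("C3", "C4", "ambiguous"))
  expect_equal(grid[lab1 == "ambiguous"], -19)
  expect_setequal(unique(lab2), c("C3", "C3+CAM", "CAM"))
})

test_that("literature assignment aggregates sources and surfaces conflicts", {
  lit <- tibble::tibble(
    source_id = c("trait_db", "flora", "gas_exchange"),
    species = c("Panicum decompositum", "Panicum decompositum",
                "Panicum decompositum"),
    pathway = c("C4", "C4", "C4"),
    evidence = c("database", "database", "direct")
  )
  a <- assign_from_literature("Panicum decompositum", lit)
  expect_equal(a$pathway, "C4")
  expect_equal(a$sources[[1]], c("flora", "gas_exchange", "trait_db"))
  expect_false(a$tentative)
  expect_null(assign_from_literature("Acacia aneura", lit))

  conf <- tibble::tibble(
    source_id = c("trait_db", "gas_exchange"),
    species = "Heliotropium tenuifolium",
    pathway = c("C3", "C4"),
    evidence = c("database", "direct")
  )
  cset <- assign_from_literature("Heliotropium tenuifolium", conf)
  expect_s3_class(cset, "pathway_conflict")
  resolved <- resolve_conflict(cset)
  expect_equal(resolved$pathway, "C4")
  expect_false(resolved$tentative)
  expect_match(resolved$discrepancy_note, "C3 \\(trait_db")
})

test_that("evidence ties break deterministically by source_id and are tentative", {
  tie <- tibble::tibble(
    source_id = c("zeta_study", "alpha_study"),
    species = "Euphorbia tannensis",
    pathway = c("C4", "C3"),
    evidence = c("direct", "direct")
  )
  r <- resolve_conflict(tie)
  expect_equal(r$pathway, "C3") # alpha_study sorts first
  expect_true(r$tentative)

  db_tie <- tibble::tibble(
    source_id = c("b_flora", "a_flora"),
    species = "Calandrinia balonensis",
    pathway = c("C3", "C3-CAM"),
    evidence = c("database", "database")
  )
  r2 <- resolve_conflict(db_tie)
  expect_equal(r2$pathway, "C3-CAM")
  expect_true(r2$tentative)
})

test_that("genus inference only works for exclusive genera", {
  gt <- tibble::tibble(genus = c("Acacia", "Eragrostis"),
                       pathway = c("C3", "C4"),
                       exclusive = c(TRUE, FALSE))
  a <- infer_from_genus("Acacia victoriae", gt)
  expect_equal(a$pathway, "C3")
  expect_equal(a$method, "lineage_inferred")
  expect_null(infer_from_genus("Eragrostis eriopoda", gt))
  expect_null(infer_from_genus("Triodia basedowii", gt))
})

test_that("assignment cascade honours precedence and targeting", {
  species <- tibble::tibble(
    species = c("Panicum decompositum", "Triodia basedowii",
                "Acacia aneura", "Solanum ellipticum",
                "Calandrinia balonensis"),
    family = c("Poaceae", "Poaceae", "Fabaceae", "Solanaceae",
               "Portulacaceae")
  )
  lit <- tibble::tibble(source_id = "trait_db",
                        species = "Panicum decompositum",
                        pathway = "C4", evidence = "database")
  gt <- tibble::tibble(genus = "Acacia", pathway = "C3", exclusive = TRUE)
  deltas <- tibble::tibble(
    species = c("Panicum decompositum", "Triodia basedowii",
                "Calandrinia balonensis"),
    delta13C = c(-27, -13.5, -18),
    facility = "CSIRO"
  )
  res <- assign_pathways(species, lit, gt, deltas)
  by_sp <- setNames(split(res, res$species), sort(species$species))

  # literature beats a contradicting tissue delta; delta kept as context
  pan <- by_sp[["Panicum decompositum"]]
  expect_equal(pan$pathway, "C4")
  expect_equal(pan$method, "literature")
  expect_equal(pan$delta13C, -27)
  # Poaceae, no literature: isotope C4 via the -19 rule
  tri <- by_sp[["Triodia basedowii"]]
  expect_equal(tri$pathway, "C4")
  expect_equal(tri$method, "isotope")
  # exclusive genus inference
  aca <- by_sp[["Acacia aneura"]]
  expect_equal(aca$pathway, "C3")
  expect_equal(aca$method, "lineage_inferred")
  # non-target family, no literature, no exclusive genus: unassigned
  sol <- by_sp[["Solanum ellipticum"]]
  expect_true(is.na(sol$pathway))
  expect_match(sol$unassigned_reason, "target")
  # CAM-potential genus goes through the CAM rule, tentatively
  cal <- by_sp[["Calandrinia balonensis"]]
  expect_equal(cal$pathway, "CAM")
  expect_true(cal$tentative)
})

test_that("species without tissue delta stay unassigned; boundary deltas are flagged", {
  species <- tibble::tibble(species = c("Aristida contorta",
                                        "Enneapogon avenaceus"),
                            family = "Poaceae")
  deltas <- tibble::tibble(species = "Enneapogon avenaceus",
                           delta13C = -19)
  res <- assign_pathways(species, deltas = deltas)
  expect_true(all(is.na(res$pathway)))
  expect_match(res$unassigned_reason[res$species == "Aristida contorta"],
               "no tissue")
  expect_match(res$unassigned_reason[res$species == "Enneapogon avenaceus"],
               "boundary")
})

test_that("perturbing deltas never changes literature assignments", {
  cfg <- small_config(seed = 23)
  pool <- simulate_species_pool(cfg)
  lit <- simulate_literature(pool, coverage = 0.8, config = cfg)
  species <- pool$truth[, c("species", "family", "genus")]
  deltas <- tibble::tibble(species = pool$truth$species,
                           delta13C = pool$truth$true_delta)
  res1 <- assign_pathways(species, lit$entries, lit$genus_table, deltas)
  deltas2 <- dplyr::mutate(deltas, delta13C = delta13C + 5)
  res2 <- assign_pathways(species, lit$entries, lit$genus_table, deltas2)
  lit_rows <- res1$method %in% "literature"
  expect_true(any(lit_rows))
  expect_equal(res1$pathway[lit_rows], res2$pathway[lit_rows])
})

test_that("isotope classification recovers true C3/C4 labels at realistic noise", {
  withr::with_seed(29, {
    n <- 1000
    truth <- sample(c("C3", "C4"), n, replace = TRUE)
    true_d <- vapply(truth, function(pw) {
      photopath:::draw_true_delta(1, pw)
    }, 0)
    for (noise in c(0.3, 0)) {
      measured <- true_d + rnorm(n, 0, noise)
      called <- classify_c3_c4(measured)
      recovery <- mean(called == truth)
      expect_gte(recovery, if (noise == 0) 1 else 0.99)
    }
  })
})

test_that("summaries count, truncate shares, and list mixed genera", {
  fam <- c(rep("Poaceae", 2), "Cyperaceae")
  toy <- tibble::tibble(
    species = c("Aristida contorta", "Panicum decompositum",
                "Cyperus bulbosus", "Acacia aneura", "Eragrostis dielsii",
                "Eragrostis falcata"),
    family = c(fam, "Fabaceae", "Poaceae", "Poaceae"),
    genus = c("Aristida", "Panicum", "Cyperus", "Acacia", "Eragrostis",
              "Eragrostis"),
    pathway = c("C4", "C4", "C4", "C3", "C3", "C4")
  )
  s <- summarize_pathways(toy)
  expect_equal(sum(s$pathway_counts$n), s$n_assigned)
  expect_equal(s$n_unassigned, 0)
  # 3 of 4 C4 species are Poaceae: 75.0; 1 of 4 Cyperaceae: 25.0
  poa <- s$c4_family_shares$share_pct[s$c4_family_shares$family == "Poaceae"]
  expect_equal(poa, 75.0)
  expect_equal(s$mixed_genera, "Eragrostis")

  # truncation, not rounding: 2/3 -> 66.6
  toy2 <- tibble::tibble(
    species = c("A a", "B b", "C c"),
    family = c("Poaceae", "Poaceae", "Cyperaceae"),
    genus = c("A", "B", "C"), pathway = "C4"
  )
  s2 <- summarize_pathways(toy2)
  expect_equal(s2$c4_family_shares$share_pct,
               c(66.6, 33.3))
  # truncated share never exceeds the exact ratio
  expect_true(all(s2$c4_family_shares$share_pct <=
                    100 * s2$c4_family_shares$n / 3))
})
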