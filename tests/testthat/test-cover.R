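toy_survey <- function(hits_at, n_points = 10, plot_id = "SAFLB0001") {
  # one transect of n_points positions; species hit at given positions
  pts <- tibble::tibble(plot_id = plot_id, transect = 1L,
                        point_m = seq_len(n_points) - 1L,
                        substrate = "bare")
  hit_rows <- dplyr::bind_rows(purrr::imap(hits_at, function(pos, sp) {
    dplyr::mutate(pts[pts$point_m %in% pos, ], species = sp)
  }))
  empty <- dplyr::anti_join(pts, hit_rows, by = c("transect", "point_m")) |>
    dplyr::mutate(species = NA_character_)
  dplyr::bind_rows(hit_rows, empty)
}

test_that("species cover is hits over observed points", {
  sv <- toy_survey(list(A = 0:4, B = integer(0)), n_points = 10)
  suppressWarnings(cov <- species_cover(sv))
  expect_equal(cov$cover_pct[cov$species == "A"], 50)
  expect_false("B" %in% cov$species) # never-hit species has no hit rows
  # full-cover species
  sv2 <- toy_survey(list(A = 0:9), n_points = 10)
  suppressWarnings(cov2 <- species_cover(sv2))
  expect_equal(cov2$cover_pct, 100)
  expect_error(species_cover(sv2[0, ]), "no points")
})

test_that("complete simulated plots normalize by 1010 without warning", {
  cfg <- small_config(seed = 41)
  pool <- simulate_species_pool(cfg)
  survey <- simulate_plot_survey(pool, cfg)
  expect_no_warning(cov <- species_cover(survey))
  expect_true(all(cov$n_points_observed == 1010L))
  # 101-of-1010 example
  expect_equal(100 * 101 / 1010, 10)
})

test_that("pathway cover is additive and never drops unassigned species", {
  cov <- tibble::tibble(
    plot_id = "P1",
    species = c("A a", "B b", "C c"),
    n_hits = c(101, 51, 30),
    cover_pct = c(10, 5, 3),
    n_points_observed = 1010
  )
  asn <- tibble::tibble(species = c("A a", "B b"), pathway = "C4")
  pw <- pathway_cover(cov, asn)
  expect_equal(pw$cover_pct[pw$pathway == "C4"], 15)
  expect_equal(pw$cover_pct[pw$pathway == "unassigned"], 3)
  expect_equal(sum(pw$cover_pct), sum(cov$cover_pct))

  # all species unassigned
  pw2 <- pathway_cover(cov, tibble::tibble(species = character(),
                                           pathway = character()))
  expect_equal(pw2$pathway, "unassigned")
  expect_equal(pw2$cover_pct, 18)
})

test_that("relative C4 cover handles both poles, zero and scaling", {
  pc <- tibble::tibble(plot_id = c("P1", "P1", "P2", "P3", "P3"),
                       pathway = c("C3", "C4", "C3", "CAM", "unassigned"),
                       cover_pct = c(30, 30, 20, 10, 5),
                       n_species = 1L)
  rel <- relative_c4_cover(pc)
  expect_equal(rel$relative_c4[rel$plot_id == "P1"], 50)
  expect_equal(rel$relative_c4[rel$plot_id == "P2"], 0)
  expect_true(is.na(rel$relative_c4[rel$plot_id == "P3"]))
  # scaling all covers by a common factor leaves the ratio unchanged
  rel_scaled <- relative_c4_cover(dplyr::mutate(pc, cover_pct = cover_pct / 3))
  expect_equal(rel_scaled$relative_c4, rel$relative_c4)
})

test_that("conservation holds on full synthetic plots", {
  cfg <- small_config(seed = 43)
  pool <- simulate_species_pool(cfg)
  survey <- simulate_plot_survey(pool, cfg)
  asn <- pool$truth[, c("species", "pathway")]
  cov <- species_cover(survey)
  pw <- pathway_cover(cov, asn)
  total_by_plot <- dplyr::summarise(dplyr::group_by(cov, plot_id),
                                    total = sum(cover_pct))
  pw_by_plot <- dplyr::summarise(dplyr::group_by(pw, plot_id),
                                 total = sum(cover_pct))
  expect_equal(dplyr::arrange(pw_by_plot, plot_id)$total,
               dplyr::arrange(total_by_plot, plot_id)$total)
})

test_that("estimated relative C4 cover converges to the occupancy-implied value", {
  # one plot, two species with known occupancies: C4 0.10, C3 0.05;
  # expected relative C4 = 100 * p4 / (p3 + p4) (hit probabilities are
  # per-point, cover estimates are binomial proportions over 1010 points)
  cfg <- sim_config(n_species = 2, n_plots = 1, duplicate_fraction = 0,
                    infraspecific_fraction = 0, genus_only_fraction = 0,
                    hybrid_fraction = 0,
                    family_mix = c(Poaceae = 1),
                    pathway_priors = list(Poaceae = c(C3 = 0.5, C4 = 0.5)),
                    seed = 47)
  pool <- simulate_species_pool(cfg)
  # force one species per pathway for a clean oracle
  pool$truth$pathway <- c("C4", "C3")
  occ <- tibble::tibble(plot_id = pool$registry$plot_id[1],
                        species = pool$truth$species,
                        occupancy = c(0.10, 0.05))
  # ensure both species occupy the single plot
  pool$registry$plot_id <- pool$plots$plot_id[1]
  occ$plot_id <- pool$plots$plot_id[1]
  survey <- simulate_plot_survey(pool, cfg, occupancy = occ)
  pw <- pathway_cover(species_cover(survey),
                      pool$truth[, c("species", "pathway")])
  rel <- relative_c4_cover(pw)
  expected <- 100 * 0.10 / 0.15
  # binomial jitter on both covers: allow a generous Monte-Carlo margin
  expect_lt(abs(rel$relative_c4 - expected), 10)
})

test_that("plot_cover_summary produces one reconciled row per plot", {
  cfg <- small_config(seed = 53)
  pool <- simulate_species_pool(cfg)
  survey <- simulate_plot_survey(pool, cfg)
  asn <- pool$truth[, c("species", "pathway")]
  pcs <- plot_cover_summary(survey, asn)
  expect_equal(nrow(pcs), cfg$n_plots)
  expect_true(all(c("relative_c4", "n_species",
                    "n_points_observed") %in% names(pcs)))
  expect_true(all(pcs$n_points_observed == 1010L))
})
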