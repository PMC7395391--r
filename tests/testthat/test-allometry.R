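test_that("group allometric equations match direct evaluation", {
  # frozen from high-precision evaluation of the group equations
  expect_equal(stem_biomass_kg("riparian_tree", 10), 26.74052,
               tolerance = 1e-6)
  expect_equal(stem_biomass_kg("woody_shrub", 10), 24.67701,
               tolerance = 1e-6)
  expect_equal(stem_biomass_kg("semi_woody", 10), 1.74)
  # vectorised across mixed groups
  expect_equal(
    stem_biomass_kg(c("riparian_tree", "semi_woody"), c(10, 10)),
    c(26.74052, 1.74), tolerance = 1e-6)
})

test_that("dead stems are reduced by the density factor; factor 1 is identity", {
  co8 <- allometry_coefficients(dead_density_factor = 0.8)
  co1 <- allometry_coefficients(dead_density_factor = 1)
  live <- stem_biomass_kg("riparian_tree", 15, TRUE, co8)
  expect_equal(stem_biomass_kg("riparian_tree", 15, FALSE, co8), 0.8 * live)
  expect_equal(stem_biomass_kg("riparian_tree", 15, FALSE, co1), live)
})

test_that("stem biomass is strictly increasing in DBH for every group", {
  dbh <- seq(2.5, 60, by = 0.5)
  for (g in c("riparian_tree", "woody_shrub", "semi_woody")) {
    b <- stem_biomass_kg(rep(g, length(dbh)), dbh)
    expect_true(all(diff(b) > 0), label = paste(g, "monotone"))
  }
})

test_that("invalid stems are rejected", {
  expect_error(stem_biomass_kg("riparian_tree", 2.0), "2.5")
  expect_error(stem_biomass_kg("riparian_tree", -1), "2.5")
  expect_error(stem_biomass_kg("oak", 10), "species_group")
  expect_error(allometry_coefficients(carbon_fraction = 0), "carbon_fraction")
  expect_error(allometry_coefficients(dead_density_factor = 1.2),
               "dead_density_factor")
})

test_that("plot carbon expands a 2-m plot correctly and is additive", {
  one <- data.frame(species_group = "riparian_tree", dbh_cm = 10,
                    alive = TRUE)
  # 26.74 kg x 0.5 C x (10000 / 4 pi m2) / 1000
  expect_equal(plot_abg_carbon_mg_ha(one), 10.63971, tolerance = 1e-5)
  expect_equal(plot_abg_carbon_mg_ha(one[0, ]), 0)

  two <- rbind(one, data.frame(species_group = "woody_shrub", dbh_cm = 7,
                               alive = TRUE))
  expect_equal(plot_abg_carbon_mg_ha(two),
               plot_abg_carbon_mg_ha(two[1, , drop = FALSE]) +
                 plot_abg_carbon_mg_ha(two[2, , drop = FALSE]))
  # degree-1 homogeneity in per-stem biomass via the carbon fraction
  half <- allometry_coefficients(carbon_fraction = 0.25)
  expect_equal(plot_abg_carbon_mg_ha(two, coeffs = half),
               plot_abg_carbon_mg_ha(two) / 2)
  expect_error(plot_abg_carbon_mg_ha(one, plot_radius_m = 0), "positive")
})

test_that("root carbon reproduces the published belowground column", {
  # spot values from the published accumulation table (ABG, age) -> BLG
  expect_equal(root_carbon_mg_ha(134.65, 5), 24.38, tolerance = 0.02 / 24.38)
  expect_equal(root_carbon_mg_ha(152.78, 20), 31.52, tolerance = 0.02 / 31.52)
  expect_equal(root_carbon_mg_ha(171.52, 5), 30.2, tolerance = 0.02 / 30.2)
  expect_equal(root_carbon_mg_ha(195.49, 50), 43.17, tolerance = 0.02 / 43.17)
  # zero conventions and rejection
  expect_equal(root_carbon_mg_ha(0, 30), 0)
  expect_equal(root_carbon_mg_ha(100, 0), 0)
  expect_error(root_carbon_mg_ha(-5, 10), "non-negative")
})

test_that("root carbon is monotone and sublinear in aboveground density", {
  abg <- seq(10, 300, by = 10)
  blg <- root_carbon_mg_ha(abg, 20)
  expect_true(all(diff(blg) > 0))
  expect_true(all(diff(root_carbon_mg_ha(100, 1:50)) > 0))
  # exponent < 1: the root:shoot ratio declines as the stand grows
  expect_true(all(diff(blg / abg) < 0))
})

test_that("every published belowground cell rebuilds from its ABG and age", {
  ref <- reference_projection_inputs()$abg
  ref <- ref[ref$age > 0, ]
  blg_expected <- c(
    24.38, 28.95, 30.55, 31.52, 32.27, 32.89, 33.42, 33.89, 34.31, 34.69,
    30.2, 39.68, 43.27, 45.07, 46.26, 47.18, 47.96, 48.63, 49.24, 49.78,
    27.37, 34.98, 37.73, 39.15, 40.14, 40.92, 41.59, 42.18, 42.70, 43.17)
  expect_equal(root_carbon_mg_ha(ref$abg_c, ref$age), blg_expected,
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("stem reader validates schema and vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(small_stems(), path, row.names = FALSE)
  df <- read_stems(path)
  expect_equal(nrow(df), 3)

  bad <- small_stems()
  bad$landform[1] <- "terrace"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_stems(path), "landform")

  bad <- small_stems()
  bad$dbh_cm[1] <- 1.0
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_stems(path), "threshold")

  bad <- small_stems()
  bad$decay_class[1] <- 3L  # live stem with a decay class
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_stems(path), "decay_class")
})

test_that("plot carbon table joins stems to sites with zero for empty plots", {
  tab <- plot_carbon_table(small_stems(), small_sites())
  expect_equal(nrow(tab), 6)
  a_ch <- tab[tab$site_id == "A" & tab$landform == "channel", ]
  expect_gt(a_ch$abg_c_mg_ha, 0)
  expect_gt(a_ch$blg_c_mg_ha, 0)
  # unrestored site B has no stems and age 0: all zero
  expect_equal(tab$abg_c_mg_ha[tab$site_id == "B"], rep(0, 3))
  expect_equal(tab$blg_c_mg_ha[tab$site_id == "B"], rep(0, 3))
})
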