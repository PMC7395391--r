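test_that("stem decomposition hits the target carbon within 0.5%", {
  co <- allometry_coefficients()
  set.seed(14)
  for (target in c(5, 40, 150, 280)) {
    st <- decompose_to_stems(target)
    expect_true(all(st$dbh_cm >= 2.5))
    got <- plot_abg_carbon_mg_ha(st)
    expect_equal(got, target, tolerance = 5e-3)
  }
  # target 0: empty stem list
  expect_equal(nrow(decompose_to_stems(0)), 0)
  # a target equal to one DBH-10 tree's contribution inverts back to one
  # stem of DBH ~10
  one_tree <- plot_abg_carbon_mg_ha(
    data.frame(species_group = "riparian_tree", dbh_cm = 10, alive = TRUE))
  set.seed(3)
  st1 <- decompose_to_stems(one_tree,
                            species_mix = c(riparian_tree = 1))
  if (nrow(st1) == 1L) expect_equal(st1$dbh_cm, 10, tolerance = 1e-6)
  expect_equal(plot_abg_carbon_mg_ha(st1), one_tree, tolerance = 5e-3)
  # sub-minimum target: one minimum stem, with a warning
  expect_warning(tiny <- decompose_to_stems(0.05), "minimum")
  expect_equal(tiny$dbh_cm, 2.5)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 21)
  d1 <- suppressWarnings(generate_synthetic_dataset(cfg))
  d2 <- suppressWarnings(generate_synthetic_dataset(cfg))
  expect_identical(d1$stems, d2$stems)
  expect_identical(d1$horizons, d2$horizons)
  expect_identical(d1$sites, d2$sites)
  d3 <- suppressWarnings(
    generate_synthetic_dataset(synthetic_config(seed = 22)))
  expect_false(identical(d1$stems, d3$stems))
})

test_that("generated tables satisfy every loader invariant", {
  cfg <- synthetic_config(seed = 9, n_sites = 12, n_unrestored = 4)
  ds <- suppressWarnings(generate_synthetic_dataset(cfg))
  # stems survive the stem reader round trip
  sp <- tempfile(fileext = ".csv")
  write.csv(ds$stems, sp, row.names = FALSE)
  expect_silent(read_stems(sp))
  # horizons build stocks for every site x landform without error
  tab <- soil_stock_table(ds$horizons)
  expect_equal(nrow(tab), nrow(ds$sites))
  expect_true(all(tab$c_stock_kg_m2 >= 0))
  # statuses respect the design: unrestored sites at age 0, failures and
  # unrestored plots carry no stems
  merged <- merge(ds$sites, ds$stems, by = c("site_id", "landform"))
  expect_true(all(merged$status == "restored_success"))
  expect_true(all(ds$sites$age_years[ds$sites$status == "unrestored"] == 0))
  # truth record round-trips through JSON serialization
  js <- jsonlite::toJSON(ds$truth, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$config$seed, 9)
  expect_equal(back$plot_truth$abg_target_mg_ha,
               ds$truth$plot_truth$abg_target_mg_ha)
})

test_that("noise-free generation round-trips through the estimators", {
  cfg <- synthetic_config(seed = 33, abg_noise_sd_log = 0, soil_noise_sd = 0,
                          n_sites = 16, n_unrestored = 5)
  ds <- suppressWarnings(generate_synthetic_dataset(cfg))
  pc <- plot_carbon_table(ds$stems, ds$sites)
  # recomputed stand carbon matches the growth curve within the stem
  # discretization tolerance (plots flagged as sub-minimum excluded)
  for (lf in c("channel", "floodplain", "upper_bank")) {
    g <- cfg$true_growth[[lf]]
    sub <- pc[pc$landform == lf & pc$status == "restored_success", ]
    expected <- eval_vb(g[["a"]], g[["b"]], sub$age_years)
    keep <- expected > 0.5  # above one minimum stem
    expect_equal(sub$abg_c_mg_ha[keep], expected[keep], tolerance = 5e-3,
                 label = paste(lf, "stand carbon"))
  }
  # soil stocks recover the generating trend exactly
  stocks <- merge(select_for_age_regression(ds$sites),
                  soil_stock_table(ds$horizons),
                  by = c("site_id", "landform"))
  fp <- stocks[stocks$landform == "floodplain", ]
  tr <- suppressWarnings(fit_soil_trend(fp$age_years, fp$c_stock_kg_m2))
  expect_equal(tr$slope, 0.087, tolerance = 1e-9)
  expect_equal(tr$intercept, 5.2447, tolerance = 1e-9)
  expect_equal(tr$r2, 1, tolerance = 1e-9)
})

test_that("wider stand noise widens the bootstrap interval", {
  widths <- vapply(c(0.05, 0.2, 0.45), function(sd_log) {
    cfg <- synthetic_config(seed = 71, abg_noise_sd_log = sd_log)
    ds <- suppressWarnings(generate_synthetic_dataset(cfg))
    pc <- select_for_age_regression(plot_carbon_table(ds$stems, ds$sites))
    fp <- pc[pc$landform == "floodplain", ]
    fit <- fit_vb(fp$age_years, fp$abg_c_mg_ha)
    iv <- vb_point_interval(fit, 20, n_draws = 150, seed = 71)
    iv$high - iv$low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("failure probabilities shape per-landform status frequencies", {
  cfg <- synthetic_config(seed = 55, n_sites = 400, n_unrestored = 0)
  ds <- suppressWarnings(generate_synthetic_dataset(cfg))
  fail_rate <- with(ds$sites,
                    tapply(status == "restored_failure", landform, mean))
  expect_equal(fail_rate[["channel"]], 0.3812, tolerance = 0.12)
  expect_equal(fail_rate[["floodplain"]], 0.2393, tolerance = 0.15)
  expect_equal(fail_rate[["upper_bank"]], 0.7322, tolerance = 0.08)
})

test_that("config validation catches bad parameters", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, abg_noise_sd_log = -1))
  expect_error(synthetic_config(seed = 1,
                                failure_prob_by_landform = c(channel = 2)))
})
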