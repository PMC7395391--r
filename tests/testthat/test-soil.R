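test_that("horizon mass converts thickness and bulk density", {
  expect_equal(horizon_mass_kg_m2(0, 20, 1.0), 200)
  expect_equal(horizon_mass_kg_m2(20, 50, 1.5), 450)
  expect_error(horizon_mass_kg_m2(10, 10, 1.0), "top_cm < bottom_cm")
  expect_error(horizon_mass_kg_m2(0, 20, 0), "positive")
})

test_that("reference mass is the median 50-cm mass over profiles", {
  mk <- function(id, bd) data.frame(
    site_id = id, landform = "floodplain", top_cm = 0, bottom_cm = 50,
    bulk_density_g_cm3 = bd, c_pct = 1, n_pct = 0.1)
  two <- rbind(mk("a", 1.2), mk("b", 1.4))    # masses 600, 700
  expect_equal(reference_mass(two), 650)
  expect_equal(reference_mass(mk("a", 1.2)), 600)
  three <- rbind(mk("a", 1.0), mk("b", 1.3), mk("c", 1.8))  # 500,650,900
  expect_equal(reference_mass(three), 650)
  expect_error(reference_mass(two[0, ]), "no profiles")
  # per-landform pooling returns one median per landform
  four <- rbind(two, transform(mk("c", 1.0), landform = "upper_bank"))
  by_lf <- reference_mass(four, pooling = "by_landform")
  expect_equal(by_lf[["floodplain"]], 650)
  expect_equal(by_lf[["upper_bank"]], 500)
})

test_that("equivalent-soil-mass stock pro-rates the final horizon by mass", {
  prof <- two_horizon_profile()
  st <- profile_stock_esm(prof, ref_mass = 500)
  expect_equal(st$c_stock_kg_m2, 7.0)          # 4 + (300/450) x 4.5
  expect_equal(st$basis, "esm_50cm")
  # full-mass reference: plain sum of horizon element masses
  full <- profile_stock_esm(prof, ref_mass = 650)
  expect_equal(full$c_stock_kg_m2, 8.5)
  expect_equal(full$n_stock_kg_m2, 0.85)
  # uniform concentration: stock depends only on the reference mass
  uni <- transform(prof, c_pct = 1.5)
  expect_equal(profile_stock_esm(uni, 500)$c_stock_kg_m2, 500 * 1.5 / 100)
  # insufficient mass names the deficit
  expect_error(profile_stock_esm(prof, 1000), "short")
})

test_that("equivalent-soil-mass stock is monotone in reference mass", {
  set.seed(101)
  for (rep in 1:5) {
    prof <- random_profile()
    total <- sum(horizon_mass_kg_m2(prof$top_cm, prof$bottom_cm,
                                    prof$bulk_density_g_cm3))
    masses <- seq(total * 0.1, total, length.out = 12)
    stocks <- vapply(masses,
                     function(m) profile_stock_esm(prof, m)$c_stock_kg_m2,
                     numeric(1))
    expect_true(all(diff(stocks) >= -1e-12))
  }
})

test_that("stocks and weighted properties are invariant to horizon subdivision", {
  set.seed(77)
  for (rep in 1:8) {
    prof <- random_profile()
    fine <- discretize_profile(prof, step = 1)
    ref <- 0.8 * sum(horizon_mass_kg_m2(prof$top_cm, prof$bottom_cm,
                                        prof$bulk_density_g_cm3))
    expect_equal(profile_stock_esm(fine, ref)$c_stock_kg_m2,
                 profile_stock_esm(prof, ref)$c_stock_kg_m2,
                 tolerance = 1e-9)
    # independent fine-walk oracle
    expect_equal(profile_stock_esm(prof, ref)$c_stock_kg_m2,
                 esm_oracle(prof, ref), tolerance = 1e-9)
    pw_coarse <- mass_weighted_properties(prof)
    pw_fine <- mass_weighted_properties(fine)
    for (cn in c("bulk_density", "c_pct", "n_pct", "cn_ratio")) {
      expect_equal(pw_fine[[cn]], pw_coarse[[cn]], tolerance = 1e-9)
    }
  }
})

test_that("channel stocks use the proxy bulk density over 10 cm", {
  st <- channel_stock_topsoil(1.0, 0.1, proxy_bd = 1.2)
  expect_equal(st$c_stock_kg_m2, 1.2)
  expect_equal(st$basis, "volumetric_10cm")
  expect_equal(channel_stock_topsoil(0, 0, proxy_bd = 1.2)$c_stock_kg_m2, 0)
  # linear in the proxy density
  expect_equal(channel_stock_topsoil(1.0, 0.1, proxy_bd = 2.4)$c_stock_kg_m2,
               2.4)
  expect_error(channel_stock_topsoil(1.0, 0.1), "bulk density")
})

test_that("mass-weighted properties average with horizon-mass weights", {
  prof <- two_horizon_profile()
  pw <- mass_weighted_properties(prof)
  expect_equal(pw$c_pct, (4 + 4.5) / 650 * 100, tolerance = 1e-9)  # 1.308
  # single horizon: identity
  one <- data.frame(top_cm = 0, bottom_cm = 50, bulk_density_g_cm3 = 1.3,
                    c_pct = 1.7, n_pct = 0.15, labile_c_frac = 0.02,
                    fa_ha_ratio = 1.1)
  pw1 <- mass_weighted_properties(one)
  expect_equal(pw1$c_pct, 1.7)
  expect_equal(pw1$cn_ratio, 1.7 / 0.15)
  expect_equal(pw1$labile_c_frac, 0.02)
  # a property constant across horizons stays constant
  const <- transform(prof, n_pct = 0.12)
  expect_equal(mass_weighted_properties(const)$n_pct, 0.12)
  # weighted value bounded by contributing horizon values
  expect_gte(pw$c_pct, min(prof$c_pct))
  expect_lte(pw$c_pct, max(prof$c_pct))
  # zero nitrogen flags an undefined C:N
  zn <- transform(prof, n_pct = 0)
  expect_warning(pwz <- mass_weighted_properties(zn), "C:N")
  expect_true(is.na(pwz$cn_ratio))
})

test_that("profiles must be contiguous from the surface", {
  gap <- data.frame(top_cm = c(0, 30), bottom_cm = c(20, 50),
                    bulk_density_g_cm3 = 1.2, c_pct = 1, n_pct = 0.1)
  expect_error(profile_stock_esm(gap, 300), "contiguous")
  deep_start <- data.frame(top_cm = 10, bottom_cm = 60,
                           bulk_density_g_cm3 = 1.2, c_pct = 1, n_pct = 0.1)
  expect_error(profile_stock_esm(deep_start, 300), "start at 0")
})

test_that("soil stock table handles both bases and the missing-companion error", {
  horizons <- rbind(
    data.frame(site_id = "A", landform = "floodplain",
               top_cm = c(0, 20), bottom_cm = c(20, 50),
               bulk_density_g_cm3 = c(1.0, 1.5),
               c_pct = c(2, 1), n_pct = c(0.2, 0.1)),
    data.frame(site_id = "A", landform = "upper_bank",
               top_cm = c(0, 50), bottom_cm = c(50, 100),
               bulk_density_g_cm3 = c(1.3, 1.5),
               c_pct = c(1.5, 0.6), n_pct = c(0.12, 0.05)),
    data.frame(site_id = "A", landform = "channel",
               top_cm = 0, bottom_cm = 10, bulk_density_g_cm3 = 99,
               c_pct = 1.0, n_pct = 0.1))
  tab <- soil_stock_table(horizons)
  ch <- tab[tab$landform == "channel", ]
  # proxy comes from the floodplain top horizon (BD 1.0), not the
  # unusable channel value
  expect_equal(ch$c_stock_kg_m2, 10 * 1.0 * 10 * 1.0 / 100)
  expect_equal(ch$basis, "volumetric_10cm")
  expect_setequal(tab$basis[tab$landform != "channel"], "esm_50cm")
  # reference mass is the pooled median of the two deep profiles
  expect_equal(unique(tab$reference_mass_kg_m2[tab$landform != "channel"]),
               stats::median(c(650, 650)))

  orphan <- horizons[horizons$landform != "floodplain", ]
  expect_error(soil_stock_table(orphan), "companion floodplain")
})
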