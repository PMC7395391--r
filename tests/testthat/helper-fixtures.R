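# Shared fixtures and independent oracles, built in code.

# Two-horizon reference profile used across the soil tests.
two_horizon_profile <- function() {
  data.frame(
    top_cm = c(0, 20), bottom_cm = c(20, 50),
    bulk_density_g_cm3 = c(1.0, 1.5),
    c_pct = c(2, 1), n_pct = c(0.2, 0.1)
  )
}

# Random multi-horizon profile (depth breaks, BD and chemistry drawn
# fresh; always reaches 100 cm).
random_profile <- function() {
  n <- sample(2:5, 1)
  breaks <- sort(c(0, sample(5:95, n - 1), 100))
  data.frame(
    top_cm = breaks[-length(breaks)],
    bottom_cm = breaks[-1],
    bulk_density_g_cm3 = runif(n, 0.8, 1.8),
    c_pct = runif(n, 0.2, 4),
    n_pct = runif(n, 0.02, 0.4)
  )
}

# Slice a profile into thin (default 1-cm) layers with identical BD and
# chemistry; stocks and weighted properties must be unchanged.
discretize_profile <- function(profile, step = 1) {
  rows <- lapply(seq_len(nrow(profile)), function(i) {
    tops <- seq(profile$top_cm[i], profile$bottom_cm[i] - step, by = step)
    data.frame(
      top_cm = tops, bottom_cm = tops + step,
      bulk_density_g_cm3 = profile$bulk_density_g_cm3[i],
      c_pct = profile$c_pct[i], n_pct = profile$n_pct[i]
    )
  })
  do.call(rbind, rows)
}

# Independent equivalent-soil-mass oracle: walk 1-mm slices from the
# surface, accumulating mass and carbon, pro-rating the final slice.
esm_oracle <- function(profile, ref_mass, step = 0.1) {
  fine <- discretize_profile(profile, step = step)
  mass <- (fine$bottom_cm - fine$top_cm) * fine$bulk_density_g_cm3 * 10
  c_kg <- mass * fine$c_pct / 100
  acc_m <- 0; acc_c <- 0
  for (i in seq_along(mass)) {
    if (acc_m + mass[i] >= ref_mass) {
      frac <- (ref_mass - acc_m) / mass[i]
      return(acc_c + frac * c_kg[i])
    }
    acc_m <- acc_m + mass[i]
    acc_c <- acc_c + c_kg[i]
  }
  stop("oracle: profile too shallow")
}

# Closed-form two-parameter least squares via centred normal equations.
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

# Published modeled accumulation tables: per-landform aboveground series
# plus the soil slopes (Mg C/ha/yr) that rebuild the full table.
reference_projection_inputs <- function() {
  list(
    abg = reference_abg_series(),
    soil_slope = c(channel = 0, floodplain = 0.867, upper_bank = 1.12)
  )
}

# Expected full accumulation tables, frozen from the published tables:
# total carbon by landform and age (Mg C/ha).
reference_totals <- function() {
  data.frame(
    landform = rep(c("channel", "floodplain", "upper_bank"), each = 11),
    age = rep(seq(0, 50, 5), 3),
    total_c = c(
      0, 159.03, 179.61, 183.10, 184.30, 185.07, 185.70, 186.23, 186.70,
      187.12, 187.50,
      0, 206.07, 263.21, 282.09, 291.00, 297.22, 302.66, 307.81, 312.83,
      317.77, 322.66,
      0, 186.38, 232.62, 248.07, 256.62, 263.54, 269.99, 276.28, 282.47,
      288.59, 294.66)
  )
}

# Small site metadata + stems fixture for the table builders.
small_sites <- function() {
  data.frame(
    site_id = rep(c("A", "B"), each = 3),
    landform = rep(c("channel", "floodplain", "upper_bank"), 2),
    age_years = rep(c(20, 0), each = 3),
    status = rep(c("restored_success", "unrestored"), each = 3)
  )
}

small_stems <- function() {
  data.frame(
    site_id = c("A", "A", "A"),
    landform = c("channel", "channel", "floodplain"),
    species_group = c("riparian_tree", "woody_shrub", "semi_woody"),
    dbh_cm = c(10, 8, 5),
    alive = c(TRUE, TRUE, TRUE),
    decay_class = NA_integer_
  )
}
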