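# Synthetic chronosequence generator: stem inventories, soil horizon
# records and site metadata with the statistical structure the analysis
# assumes, so every pipeline stage is testable without archived field data.

#' Configuration for the synthetic chronosequence
#'
#' Defaults emulate the study design the analysis targets: 32 restored
#' stream reaches aged 1-45 years plus 10 unrestored (age-0) reaches, three
#' landforms per site, per-landform failure probabilities equal to the
#' complements of the observed area-weighted success rates, saturating
#' stand growth with multiplicative lognormal noise, and soil stocks
#' following a linear age trend with additive Gaussian noise.
#'
#' @param n_sites Number of restored (attempted) sites.
#' @param age_range Integer age range for restored sites, years.
#' @param n_unrestored Number of unrestored age-0 sites.
#' @param failure_prob_by_landform Named probabilities that an attempted
#'   revegetation fails on each landform.
#' @param true_growth Named list of `c(a, b)` growth-curve parameters per
#'   landform (Mg C/ha and 1/yr).
#' @param abg_noise_sd_log Log-scale sd of multiplicative stand-carbon
#'   noise.
#' @param soil_trend Named list of `c(intercept, slope)` per landform, in
#'   kg C/m2 and kg C/m2/yr.
#' @param soil_noise_sd Additive sd of soil stock noise, kg C/m2.
#' @param horizon_template Data frame `top_cm, bottom_cm,
#'   bulk_density_g_cm3, source` defining every deep profile's layering.
#' @param plot_radius_m Radius of the simulated vegetation plot, m.
#' @param species_mix Named sampling weights over species groups for stem
#'   draws.
#' @param dbh_meanlog,dbh_sdlog Lognormal parameters for drawn DBH, cm.
#' @param seed Integer seed; mandatory, all generation is deterministic
#'   given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 32,
                             age_range = c(1, 45),
                             n_unrestored = 10,
                             failure_prob_by_landform = c(
                               channel = 0.3812,
                               floodplain = 0.2393,
                               upper_bank = 0.7322),
                             true_growth = list(
                               channel = c(a = 152.8, b = 0.14),
                               floodplain = c(a = 229.5, b = 0.12),
                               upper_bank = c(a = 195.5, b = 0.09)),
                             abg_noise_sd_log = 0.25,
                             soil_trend = list(
                               channel = c(intercept = 1.2159,
                                           slope = -0.008),
                               floodplain = c(intercept = 5.2447,
                                              slope = 0.087),
                               upper_bank = c(intercept = 8.8594,
                                              slope = 0.112)),
                             soil_noise_sd = 2.4,
                             horizon_template = data.frame(
                               top_cm = c(0, 20, 50),
                               bottom_cm = c(20, 50, 100),
                               bulk_density_g_cm3 = c(1.2, 1.4, 1.5),
                               source = c("pit", "pit", "auger"),
                               stringsAsFactors = FALSE),
                             plot_radius_m = 2,
                             species_mix = c(riparian_tree = 0.7,
                                             woody_shrub = 0.2,
                                             semi_woody = 0.1),
                             dbh_meanlog = log(10),
                             dbh_sdlog = 0.6,
                             seed = NULL) {
  if (is.null(seed)) stop("synthetic_config requires an integer seed",
                          call. = FALSE)
  stopifnot(
    n_sites >= 1, n_unrestored >= 0,
    length(age_range) == 2L, age_range[1] >= 1,
    age_range[1] <= age_range[2],
    all(failure_prob_by_landform >= 0), all(failure_prob_by_landform <= 1),
    setequal(names(failure_prob_by_landform), landforms),
    setequal(names(true_growth), landforms),
    setequal(names(soil_trend), landforms),
    abg_noise_sd_log >= 0, soil_noise_sd >= 0,
    plot_radius_m > 0,
    all(names(species_mix) %in% species_groups), sum(species_mix) > 0
  )
  structure(list(
    n_sites = as.integer(n_sites), age_range = as.integer(age_range),
    n_unrestored = as.integer(n_unrestored),
    failure_prob_by_landform = failure_prob_by_landform,
    true_growth = true_growth, abg_noise_sd_log = abg_noise_sd_log,
    soil_trend = soil_trend, soil_noise_sd = soil_noise_sd,
    horizon_template = horizon_template, plot_radius_m = plot_radius_m,
    species_mix = species_mix, dbh_meanlog = dbh_meanlog,
    dbh_sdlog = dbh_sdlog, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Invert a group's allometric equation: dry biomass (kg) -> DBH (cm).
invert_allometry <- function(species_group, biomass_kg,
                             coeffs = allometry_coefficients()) {
  switch(species_group,
    riparian_tree = exp((log(biomass_kg) - coeffs$tree_intercept) /
                          coeffs$tree_slope),
    woody_shrub = exp((log(biomass_kg) - coeffs$shrub_intercept) /
                        coeffs$shrub_slope),
    semi_woody = biomass_kg / coeffs$semiwoody_slope,
    stop("unknown species_group", call. = FALSE)
  )
}

#' Decompose a target stand carbon density into a stem list
#'
#' Draws stems (group from `species_mix`, DBH lognormal, clamped to the
#' 2.5-cm measurement threshold) until the plot-scaled carbon of the
#' accumulated stems reaches the target within one stem's contribution;
#' the final stem is sized by inverting the group's allometric equation so
#' the plot total matches the target within 0.5%. A target smaller than
#' one minimum-DBH stem's contribution is emitted as a single minimum stem
#' with a warning. Uses the current RNG state; call inside a seeded
#' context for reproducibility.
#'
#' @param target_abg_mg_ha Target aboveground carbon density, Mg C/ha
#'   (>= 0).
#' @param plot_radius_m Plot radius, m.
#' @param species_mix Named sampling weights over species groups.
#' @param dbh_meanlog,dbh_sdlog Lognormal DBH parameters.
#' @param coeffs An [allometry_coefficients()] object.
#' @return Data frame with columns `species_group, dbh_cm, alive,
#'   decay_class` (possibly zero rows).
#' @export
decompose_to_stems <- function(target_abg_mg_ha, plot_radius_m = 2,
                               species_mix = c(riparian_tree = 0.7,
                                               woody_shrub = 0.2,
                                               semi_woody = 0.1),
                               dbh_meanlog = log(10), dbh_sdlog = 0.6,
                               coeffs = allometry_coefficients()) {
  stopifnot(target_abg_mg_ha >= 0)
  empty <- data.frame(species_group = character(0), dbh_cm = numeric(0),
                      alive = logical(0), decay_class = integer(0),
                      stringsAsFactors = FALSE)
  if (target_abg_mg_ha == 0) return(empty)
  # Mg C/ha per kg of stem dry biomass on this plot
  scale <- coeffs$carbon_fraction * (10000 / (pi * plot_radius_m^2)) / 1000
  min_contrib <- stem_biomass_kg("riparian_tree", DBH_MIN,
                                 coeffs = coeffs) * scale
  if (target_abg_mg_ha < min_contrib) {
    warning(sprintf(
      "target %.3f Mg C/ha is below one minimum-DBH stem (%.3f); emitting a single minimum stem",
      target_abg_mg_ha, min_contrib), call. = FALSE)
    return(data.frame(species_group = "riparian_tree", dbh_cm = DBH_MIN,
                      alive = TRUE, decay_class = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  groups <- character(0); dbhs <- numeric(0)
  total <- 0
  repeat {
    remaining <- target_abg_mg_ha - total
    g <- sample(names(species_mix), 1L, prob = species_mix)
    d <- max(DBH_MIN, stats::rlnorm(1, dbh_meanlog, dbh_sdlog))
    contrib <- stem_biomass_kg(g, d, coeffs = coeffs) * scale
    if (contrib >= remaining) {
      # size the final stem exactly to the remainder
      need_kg <- remaining / scale
      d_final <- invert_allometry(g, need_kg, coeffs)
      if (d_final >= DBH_MIN) {
        groups <- c(groups, g); dbhs <- c(dbhs, d_final)
      } else if (length(groups)) {
        # remainder too small for a legal stem of this group: absorb it
        # into the largest stem already drawn
        i <- which.max(stem_biomass_kg(groups, dbhs, coeffs = coeffs))
        new_kg <- stem_biomass_kg(groups[i], dbhs[i], coeffs = coeffs) +
          need_kg
        dbhs[i] <- invert_allometry(groups[i], new_kg, coeffs)
      } else {
        # first and only stem: a riparian tree of this mass is always
        # above the measurement threshold (the sub-minimum case was
        # handled before the loop)
        groups <- "riparian_tree"
        dbhs <- invert_allometry("riparian_tree", need_kg, coeffs)
      }
      break
    }
    groups <- c(groups, g); dbhs <- c(dbhs, d)
    total <- total + contrib
  }
  data.frame(species_group = groups, dbh_cm = dbhs, alive = TRUE,
             decay_class = NA_integer_, stringsAsFactors = FALSE)
}

#' Generate a synthetic chronosequence dataset
#'
#' Draws site ages uniformly over the configured range (plus the age-0
#' unrestored sites), assigns per-landform success/failure by the
#' configured failure probabilities, realises successful stands as stem
#' lists whose plot-scaled carbon follows the landform's growth curve
#' under multiplicative lognormal noise, and realises soil stocks from the
#' landform's linear age trend plus Gaussian noise as uniform-C% profiles
#' over the horizon template. Failed and unrestored plots get empty stem
#' lists and age-0 soil. Deterministic under the configured seed; the
#' caller's RNG state is untouched.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset`: `stems`, `horizons`,
#'   `sites` data frames (the exact schemas the loaders consume) and
#'   `truth`, a record of every generating parameter plus per-plot noise
#'   realisations.
#' @export
generate_synthetic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(config) {
  coeffs <- allometry_coefficients()
  tmpl <- config$horizon_template
  n_total <- config$n_sites + config$n_unrestored
  site_ids <- sprintf("S%02d", seq_len(n_total))
  ages <- c(sample(seq(config$age_range[1], config$age_range[2]),
                   config$n_sites, replace = TRUE),
            rep(0L, config$n_unrestored))
  restored <- c(rep(TRUE, config$n_sites), rep(FALSE, config$n_unrestored))

  sites <- expand.grid(site_id = site_ids, landform = landforms,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sites <- sites[order(sites$site_id, sites$landform), , drop = FALSE]
  sites$age_years <- ages[match(sites$site_id, site_ids)]
  site_restored <- restored[match(sites$site_id, site_ids)]
  failed <- site_restored &
    stats::runif(nrow(sites)) < config$failure_prob_by_landform[sites$landform]
  sites$status <- ifelse(!site_restored, "unrestored",
                         ifelse(failed, "restored_failure",
                                "restored_success"))
  rownames(sites) <- NULL

  # -- stems ----------------------------------------------------------
  abg_target <- numeric(nrow(sites))
  grow <- sites$status == "restored_success"
  for (i in which(grow)) {
    g <- config$true_growth[[sites$landform[i]]]
    mu <- eval_vb(g[["a"]], g[["b"]], sites$age_years[i])
    abg_target[i] <- mu * exp(stats::rnorm(1, 0, config$abg_noise_sd_log))
  }
  stem_list <- vector("list", nrow(sites))
  tiny <- character(0)
  for (i in seq_len(nrow(sites))) {
    if (abg_target[i] <= 0) next
    st <- withCallingHandlers(
      decompose_to_stems(abg_target[i], config$plot_radius_m,
                         config$species_mix, config$dbh_meanlog,
                         config$dbh_sdlog, coeffs),
      warning = function(w) {
        tiny <<- c(tiny, paste(sites$site_id[i], sites$landform[i]))
        invokeRestart("muffleWarning")
      })
    if (nrow(st)) {
      st$site_id <- sites$site_id[i]
      st$landform <- sites$landform[i]
      stem_list[[i]] <- st[, c("site_id", "landform", "species_group",
                               "dbh_cm", "alive", "decay_class")]
    }
  }
  if (length(tiny)) {
    warning("stand target below one minimum stem at: ",
            paste(tiny, collapse = ", "), call. = FALSE)
  }
  stems <- do.call(rbind, stem_list)
  if (is.null(stems)) {
    stems <- data.frame(site_id = character(0), landform = character(0),
                        species_group = character(0), dbh_cm = numeric(0),
                        alive = logical(0), decay_class = integer(0),
                        stringsAsFactors = FALSE)
  }
  rownames(stems) <- NULL

  # -- soil -----------------------------------------------------------
  deep_mass_50 <- sum(pmax(0, pmin(tmpl$bottom_cm, 50) - tmpl$top_cm) *
                        tmpl$bulk_density_g_cm3 * 10)
  soil_rows <- vector("list", nrow(sites))
  soil_target <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    lf <- sites$landform[i]
    tr <- config$soil_trend[[lf]]
    # failures erode back to baseline: soil follows age 0
    age_soil <- if (sites$status[i] == "restored_success")
      sites$age_years[i] else 0
    target <- tr[["intercept"]] + tr[["slope"]] * age_soil +
      stats::rnorm(1, 0, config$soil_noise_sd)
    target <- max(target, 0.1)  # stocks cannot be negative
    soil_target[i] <- target
    if (lf == "channel") {
      bd <- tmpl$bulk_density_g_cm3[1]  # proxy: floodplain top horizon
      c_pct <- target / (10 * bd * 10) * 100
      soil_rows[[i]] <- data.frame(
        site_id = sites$site_id[i], landform = lf, top_cm = 0,
        bottom_cm = 10, bulk_density_g_cm3 = bd, c_pct = c_pct,
        n_pct = c_pct / 12, labile_c_frac = 0.025, fa_ha_ratio = 1.2,
        source = "pit", stringsAsFactors = FALSE)
    } else {
      c_pct <- target / deep_mass_50 * 100
      soil_rows[[i]] <- data.frame(
        site_id = sites$site_id[i], landform = lf, top_cm = tmpl$top_cm,
        bottom_cm = tmpl$bottom_cm,
        bulk_density_g_cm3 = tmpl$bulk_density_g_cm3,
        c_pct = ifelse(tmpl$source == "auger", 0.5 * c_pct, c_pct),
        n_pct = ifelse(tmpl$source == "auger", 0.5 * c_pct, c_pct) / 12,
        labile_c_frac = if (lf == "floodplain") 0.026 else 0.021,
        fa_ha_ratio = if (lf == "floodplain") 1.25 else 0.95,
        source = tmpl$source, stringsAsFactors = FALSE)
    }
  }
  horizons <- do.call(rbind, soil_rows)
  rownames(horizons) <- NULL

  truth <- list(
    config = unclass(config),
    plot_truth = cbind(sites,
                       abg_target_mg_ha = abg_target,
                       soil_target_kg_m2 = soil_target)
  )
  structure(list(stems = stems, horizons = horizons, sites = sites,
                 truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic chronosequence: %d site x landform plots, %d stems, %d horizons (seed %d)\n",
    nrow(x$sites), nrow(x$stems), nrow(x$horizons),
    x$truth$config$seed))
  invisible(x)
}
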