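# End-to-end orchestration: stems + horizons + sites -> carbon tables,
# fits, projections, county scale-up and valuation, with a reproducible
# manifest.

#' Group summaries of soil properties
#'
#' Mean and standard error of every numeric column, per landform and
#' restoration group. Failed restorations are pooled with unrestored sites
#' (sites with no established vegetation are considered to have continued
#' to erode), so the groups are `restored` (= successful) vs
#' `unrestored`.
#'
#' @param site_table Data frame with `landform`, `status`, and numeric
#'   property/stock columns (e.g. the output of [soil_stock_table()]
#'   merged with site metadata).
#' @return Data frame with one row per landform x group: `n`, then
#'   `<column>_mean` and `<column>_se` for every numeric column. A group
#'   with a single record gets `NA` standard errors; empty groups get
#'   `n = 0` rows of `NA`.
#' @export
summarize_groups <- function(site_table) {
  stopifnot(is.data.frame(site_table),
            all(c("landform", "status") %in% names(site_table)))
  grp <- ifelse(site_table$status == "restored_success",
                "restored", "unrestored")
  num_cols <- names(site_table)[vapply(site_table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("age_years"))
  keys <- expand.grid(landform = sort(unique(site_table$landform)),
                      group = c("restored", "unrestored"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- site_table[site_table$landform == keys$landform[i] &
                        grp == keys$group[i], num_cols, drop = FALSE]
    out <- data.frame(landform = keys$landform[i], group = keys$group[i],
                      n = nrow(sub), stringsAsFactors = FALSE)
    for (cn in num_cols) {
      x <- sub[[cn]][is.finite(sub[[cn]])]
      out[[paste0(cn, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      out[[paste0(cn, "_se")]] <- if (length(x) > 1L) {
        stats::sd(x) / sqrt(length(x))
      } else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Run the full carbon-accounting pipeline
#'
#' Sequences every stage: load (or synthesise) stems, horizons and site
#' metadata; compute per-plot tree/shrub carbon and per-site soil stocks;
#' fit the growth curve and soil trend per landform on the age-regression
#' subset (failures excluded, unrestored at age 0); build age projections;
#' scale 20-year densities to the county with success-rate discounting,
#' CO2e conversion and valuation; and write the report bundle to
#' `out_dir`:
#'
#' * `plot_carbon.csv`, `soil_stocks.csv` - stage outputs per plot/site
#' * `growth_fits.csv`, `soil_trends.csv` - fitted models per landform
#' * `projections.csv` - per-landform, per-age accumulation table
#' * `scaleup.csv`, `valuation.csv` - county totals, CO2e, value
#' * `group_summaries.csv` - mean +/- SE by landform x restoration group
#' * `manifest.json` - config echo, seed, versions, file checksums
#'
#' The bundle is byte-identical across reruns with the same inputs, seed
#' and package version.
#'
#' @param out_dir Output directory (created if needed).
#' @param synthetic A [synthetic_config()], or `NULL` when reading real
#'   input files.
#' @param stems_path,horizons_path,sites_path CSV inputs (ignored when
#'   `synthetic` is given; all three required otherwise).
#' @param areas Restorable-area table (data frame or CSV path) with
#'   columns `landform, buffer_lo_m, buffer_hi_m, restorable_area_ha` and
#'   `successful_area_ha, attempted_area_ha` (or `success_fraction`).
#' @param target_age Age, years, at which densities enter the scale-up
#'   (default 20).
#' @param projection_ages Age grid of the projection table.
#' @param n_draws Bootstrap/posterior draws for the interval at
#'   `target_age`.
#' @param seed Integer seed governing every stochastic step; mandatory.
#' @param uncertainty_method `"bootstrap"` or `"posterior"`, see
#'   [vb_point_interval()].
#' @param sig_level Significance threshold for projecting a soil trend.
#' @param price_usd_per_mg_co2e Carbon price, USD per Mg CO2e.
#' @param stream_km Restorable stream length, km.
#' @param plot_radius_m Vegetation plot radius, m.
#' @return Invisibly, a list with every table plus the manifest.
#' @export
run_pipeline <- function(out_dir,
                         synthetic = NULL,
                         stems_path = NULL, horizons_path = NULL,
                         sites_path = NULL,
                         areas = default_areas(),
                         target_age = 20,
                         projection_ages = seq(0, 50, by = 5),
                         n_draws = 500,
                         seed,
                         uncertainty_method = c("bootstrap", "posterior"),
                         sig_level = 0.05,
                         price_usd_per_mg_co2e = 17.45,
                         stream_km = 1215,
                         plot_radius_m = 2) {
  uncertainty_method <- match.arg(uncertainty_method)
  if (missing(seed)) stop("run_pipeline requires an integer seed",
                          call. = FALSE)
  real <- !is.null(stems_path) || !is.null(horizons_path) ||
    !is.null(sites_path)
  if (is.null(synthetic) == !real) {
    stop("supply exactly one of: a synthetic config, or the three input paths",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(areas)) areas <- utils::read.csv(areas)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- load ------------------------------------------------------------
  if (!is.null(synthetic)) {
    ds <- stage("simulate", generate_synthetic_dataset(synthetic))
    stems <- ds$stems; horizons <- ds$horizons; sites <- ds$sites
  } else {
    stems <- stage("load", read_stems(stems_path))
    horizons <- stage("load", read_horizons(horizons_path))
    sites <- stage("load", utils::read.csv(sites_path,
                                           stringsAsFactors = FALSE))
  }

  # -- biomass and soil stages ----------------------------------------
  plot_c <- stage("biomass",
                  plot_carbon_table(stems, sites, plot_radius_m))
  soil <- stage("stocks", soil_stock_table(horizons))
  soil <- merge(sites, soil, by = c("site_id", "landform"), sort = TRUE)
  message(sprintf("biomass: %d plots; stocks: %d profiles",
                  nrow(plot_c), nrow(soil)))

  # -- model fits ------------------------------------------------------
  reg_plots <- select_for_age_regression(plot_c)
  reg_soil <- select_for_age_regression(soil)
  message(sprintf(
    "age regressions: %d of %d biomass plots retained (failures excluded)",
    nrow(reg_plots), nrow(plot_c)))
  fits <- list(); trends <- list(); intervals <- list()
  for (lf in landforms) {
    pb <- reg_plots[reg_plots$landform == lf, ]
    if (nrow(pb) == 0L || all(pb$abg_c_mg_ha <= 0)) {
      # no established stand on this landform: biomass stays zero, the
      # soil stages still run
      message(sprintf("fit: no stand carbon on %s; growth curve skipped",
                      lf))
      fits[[lf]] <- structure(
        list(a = NA_real_, b = NA_real_, residual_sd = NA_real_,
             n = nrow(pb), converged = FALSE, landform = lf),
        class = "growth_fit")
      intervals[[lf]] <- list(point = 0, low = 0, high = 0)
    } else {
      fits[[lf]] <- stage("fit", fit_vb(pb$age_years, pb$abg_c_mg_ha, lf))
      intervals[[lf]] <- stage("fit", vb_point_interval(
        fits[[lf]], target_age = target_age, n_draws = n_draws,
        seed = seed + match(lf, landforms), method = uncertainty_method))
    }
    ss <- reg_soil[reg_soil$landform == lf, ]
    trends[[lf]] <- stage("fit",
                          fit_soil_trend(ss$age_years, ss$c_stock_kg_m2, lf))
  }
  growth_tbl <- do.call(rbind, lapply(fits, function(f) {
    data.frame(landform = f$landform, a = f$a, b = f$b,
               residual_sd = f$residual_sd, n = f$n,
               converged = f$converged)
  }))
  trend_tbl <- do.call(rbind, lapply(trends, function(t) {
    data.frame(landform = t$landform, a = t$intercept, b = t$slope,
               p = t$p_value, df = t$df, r2 = t$r2,
               slope_ci_lo = t$slope_ci_95[1],
               slope_ci_hi = t$slope_ci_95[2])
  }))

  # -- projections -----------------------------------------------------
  proj <- do.call(rbind, lapply(landforms, function(lf) {
    src <- if (fits[[lf]]$converged) fits[[lf]] else
      data.frame(age = projection_ages, abg_c = 0)
    stage("project", build_projection(
      src,
      soil_slope_mg_ha_yr = soil_slope_for_projection(trends[[lf]],
                                                      sig_level),
      ages = projection_ages, landform = lf))
  }))

  # -- scale-up --------------------------------------------------------
  densities <- do.call(rbind, lapply(landforms, function(lf) {
    slope <- soil_slope_for_projection(trends[[lf]], sig_level)
    iv <- intervals[[lf]]
    soil_add <- slope * target_age
    # bound endpoints: growth-curve interval endpoints, with belowground
    # recomputed from each, plus the soil-slope CI endpoints (only when
    # the trend is projected at all)
    soil_lo <- if (slope > 0) trends[[lf]]$slope_ci_95[1] * 10 * target_age
    else 0
    soil_hi <- if (slope > 0) trends[[lf]]$slope_ci_95[2] * 10 * target_age
    else 0
    data.frame(
      landform = lf,
      c_density_mg_ha = iv$point +
        root_carbon_mg_ha(iv$point, target_age) + soil_add,
      low_density_mg_ha = iv$low +
        root_carbon_mg_ha(iv$low, target_age) + max(soil_lo, 0),
      high_density_mg_ha = iv$high +
        root_carbon_mg_ha(iv$high, target_age) + soil_hi
    )
  }))
  scale_tbl <- stage("scaleup", scaleup_table(areas, densities))
  valuation <- stage("scaleup",
                     county_summary(scale_tbl, price_usd_per_mg_co2e,
                                    stream_km))

  # -- group summaries -------------------------------------------------
  drop <- c("reference_mass_kg_m2")
  groups <- stage("report",
                  summarize_groups(soil[, setdiff(names(soil), drop)]))

  # -- write bundle ----------------------------------------------------
  tables <- list(plot_carbon = plot_c, soil_stocks = soil,
                 growth_fits = growth_tbl, soil_trends = trend_tbl,
                 projections = proj, scaleup = scale_tbl,
                 valuation = valuation, group_summaries = groups)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg <- list(
    synthetic = if (!is.null(synthetic)) unclass(synthetic) else NULL,
    inputs = if (real) list(stems = stems_path, horizons = horizons_path,
                            sites = sites_path) else NULL,
    target_age = target_age, projection_ages = projection_ages,
    n_draws = n_draws, seed = seed,
    uncertainty_method = uncertainty_method, sig_level = sig_level,
    price_usd_per_mg_co2e = price_usd_per_mg_co2e, stream_km = stream_km,
    plot_radius_m = plot_radius_m
  )
  manifest <- list(
    package = "ripcarbon",
    version = as.character(utils::packageVersion("ripcarbon")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = cfg,
    files = as.list(tools::md5sum(paths))
  )
  names(manifest$files) <- basename(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(c(tables, list(manifest = manifest, fits = fits,
                           trends = trends, intervals = intervals)))
}

#' Bundled restorable-area table
#'
#' The per-landform restorable (grassland) areas within the 0-3, 3-12 and
#' 12-24 m stream buffers of the published county analysis, with attempted
#' and successful revegetation areas scaled so their ratios equal the
#' published area-weighted success rates (only the ratios are published,
#' so `attempted_area_ha` is normalised to 100).
#'
#' @return Data frame with one row per landform.
#' @export
default_areas <- function() {
  utils::read.csv(system.file("extdata", "restorable_areas.csv",
                              package = "ripcarbon"),
                  stringsAsFactors = FALSE)
}

#' Bundled reference aboveground carbon series
#'
#' The per-landform modeled aboveground tree/shrub carbon series (ages 0-50
#' by 5 years, Mg C/ha) from the published accumulation tables, usable as
#' an explicit `abg_source` in [build_projection()].
#'
#' @return Data frame with columns `landform, age, abg_c`.
#' @export
reference_abg_series <- function() {
  utils::read.csv(system.file("extdata", "reference_abg_series.csv",
                              package = "ripcarbon"),
                  stringsAsFactors = FALSE)
}
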