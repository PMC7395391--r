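# Allometric conversion of stem inventories to per-hectare tree/shrub carbon.

#' Allometric and root-regression coefficients
#'
#' Bundles the coefficients used throughout the biomass calculations: the
#' log-log allometric equations for riparian trees and woody shrubs, the
#' proportional equation for semi-woody shrubs (blackberry, wild rose), the
#' root biomass density (RBD) regression that predicts belowground stocks
#' from aboveground density and stand age, the carbon fraction of dry
#' biomass, and the wood-density reduction applied to standing dead stems.
#'
#' The tree equation is `exp(tree_intercept + tree_slope * log(DBH))` and the
#' shrub equation `exp(shrub_intercept + shrub_slope * log(DBH))`, both in kg
#' dry weight with DBH in cm. Semi-woody biomass is `semiwoody_slope * DBH`.
#' The RBD regression is
#' `exp(rbd_intercept + rbd_abg_coef * log(ABG) + rbd_age_coef * log(age))`.
#'
#' @param tree_intercept,tree_slope Riparian tree equation coefficients.
#' @param shrub_intercept,shrub_slope Woody shrub equation coefficients.
#' @param semiwoody_slope Semi-woody biomass per cm DBH (kg/cm).
#' @param rbd_intercept,rbd_abg_coef,rbd_age_coef Root biomass density
#'   regression coefficients.
#' @param carbon_fraction Fraction of dry biomass that is carbon, in (0, 1].
#' @param dead_density_factor Multiplier in (0, 1] applied to the biomass of
#'   standing dead stems (decay-class density reduction). No single published
#'   value is hard-coded; supply the factor appropriate to the decay class
#'   observed.
#' @return An object of class `allometry_coefficients` (a named list).
#' @examples
#' co <- allometry_coefficients()
#' stem_biomass_kg("riparian_tree", 10, coeffs = co)
#' @export
allometry_coefficients <- function(tree_intercept = -2.2094,
                                   tree_slope = 2.3867,
                                   shrub_intercept = -0.7152,
                                   shrub_slope = 1.7029,
                                   semiwoody_slope = 0.174,
                                   rbd_intercept = -1.3267,
                                   rbd_abg_coef = 0.8877,
                                   rbd_age_coef = 0.1045,
                                   carbon_fraction = 0.5,
                                   dead_density_factor = 0.8) {
  co <- list(
    tree_intercept = tree_intercept, tree_slope = tree_slope,
    shrub_intercept = shrub_intercept, shrub_slope = shrub_slope,
    semiwoody_slope = semiwoody_slope,
    rbd_intercept = rbd_intercept, rbd_abg_coef = rbd_abg_coef,
    rbd_age_coef = rbd_age_coef,
    carbon_fraction = carbon_fraction,
    dead_density_factor = dead_density_factor
  )
  vals <- unlist(co)
  if (!all(is.finite(vals))) {
    stop("all allometry coefficients must be finite", call. = FALSE)
  }
  if (carbon_fraction <= 0 || carbon_fraction > 1) {
    stop("carbon_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (dead_density_factor <= 0 || dead_density_factor > 1) {
    stop("dead_density_factor must lie in (0, 1]", call. = FALSE)
  }
  structure(co, class = "allometry_coefficients")
}

#' @export
print.allometry_coefficients <- function(x, ...) {
  cat("Allometry coefficients\n")
  cat(sprintf("  riparian tree : exp(%g + %g ln DBH)\n",
              x$tree_intercept, x$tree_slope))
  cat(sprintf("  woody shrub   : exp(%g + %g ln DBH)\n",
              x$shrub_intercept, x$shrub_slope))
  cat(sprintf("  semi-woody    : %g * DBH\n", x$semiwoody_slope))
  cat(sprintf("  RBD           : exp(%g + %g ln ABG + %g ln age)\n",
              x$rbd_intercept, x$rbd_abg_coef, x$rbd_age_coef))
  cat(sprintf("  carbon fraction %g; dead density factor %g\n",
              x$carbon_fraction, x$dead_density_factor))
  invisible(x)
}

#' Species groups recognised by the allometry
#' @keywords internal
species_groups <- c("riparian_tree", "woody_shrub", "semi_woody")

#' Riparian landforms
#' @keywords internal
landforms <- c("channel", "floodplain", "upper_bank")

# Minimum measured stem diameter, cm.
DBH_MIN <- 2.5

#' Dry biomass of a single stem
#'
#' Applies the group-specific allometric equation to diameter at breast
#' height. Standing dead stems are reduced by the configured density factor.
#' All arguments are vectorised and recycled to a common length.
#'
#' @param species_group One of `"riparian_tree"`, `"woody_shrub"`,
#'   `"semi_woody"`.
#' @param dbh_cm Diameter at breast height (1.4 m), cm; must be >= 2.5, the
#'   field measurement threshold.
#' @param alive Logical; dead stems have biomass multiplied by
#'   `coeffs$dead_density_factor`.
#' @param coeffs An [allometry_coefficients()] object.
#' @return Dry biomass in kg per stem.
#' @examples
#' stem_biomass_kg("semi_woody", 10)  # 1.74 kg
#' @export
stem_biomass_kg <- function(species_group, dbh_cm, alive = TRUE,
                            coeffs = allometry_coefficients()) {
  n <- max(length(species_group), length(dbh_cm), length(alive))
  if (n == 0L) return(numeric(0))
  species_group <- rep_len(as.character(species_group), n)
  dbh_cm <- rep_len(as.numeric(dbh_cm), n)
  alive <- rep_len(as.logical(alive), n)
  bad_group <- !species_group %in% species_groups
  if (any(bad_group)) {
    stop("unknown species_group: ",
         paste(unique(species_group[bad_group]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(dbh_cm)) || any(dbh_cm < DBH_MIN)) {
    stop(sprintf("dbh_cm must be finite and >= %.1f cm (measurement threshold)",
                 DBH_MIN), call. = FALSE)
  }
  kg <- numeric(n)
  tr <- species_group == "riparian_tree"
  sh <- species_group == "woody_shrub"
  sw <- species_group == "semi_woody"
  kg[tr] <- exp(coeffs$tree_intercept + coeffs$tree_slope * log(dbh_cm[tr]))
  kg[sh] <- exp(coeffs$shrub_intercept + coeffs$shrub_slope * log(dbh_cm[sh]))
  kg[sw] <- coeffs$semiwoody_slope * dbh_cm[sw]
  kg[!alive] <- kg[!alive] * coeffs$dead_density_factor
  kg
}

#' Aboveground carbon density of a radial plot
#'
#' Sums stem dry biomass, applies the carbon fraction, and expands the
#' circular plot to a hectare: `10000 / (pi * r^2)` with `r` the plot radius
#' (795.77 plots per hectare for the default 2-m radius).
#'
#' @param stems A data frame with columns `species_group`, `dbh_cm` and
#'   (optionally) `alive`; zero rows give zero carbon.
#' @param plot_radius_m Plot radius in metres (> 0); default 2.
#' @param coeffs An [allometry_coefficients()] object.
#' @return Aboveground carbon in Mg C per ha.
#' @examples
#' one_tree <- data.frame(species_group = "riparian_tree", dbh_cm = 10,
#'                        alive = TRUE)
#' plot_abg_carbon_mg_ha(one_tree)  # 10.64 Mg C/ha
#' @export
plot_abg_carbon_mg_ha <- function(stems, plot_radius_m = 2,
                                  coeffs = allometry_coefficients()) {
  stopifnot(is.data.frame(stems))
  if (!is.numeric(plot_radius_m) || length(plot_radius_m) != 1L ||
      !is.finite(plot_radius_m) || plot_radius_m <= 0) {
    stop("plot_radius_m must be a single positive number", call. = FALSE)
  }
  if (nrow(stems) == 0L) return(0)
  alive <- if ("alive" %in% names(stems)) stems$alive else TRUE
  kg <- stem_biomass_kg(stems$species_group, stems$dbh_cm, alive, coeffs)
  kg_c <- sum(kg) * coeffs$carbon_fraction
  # kg/plot -> Mg/ha: expand by plots-per-ha, divide by 1000 kg/Mg
  kg_c * (10000 / (pi * plot_radius_m^2)) / 1000
}

#' Belowground (root) carbon density from aboveground density and age
#'
#' Evaluates the root biomass density regression on a carbon basis:
#' `exp(rbd_intercept + rbd_abg_coef * log(abg_c) + rbd_age_coef * log(age))`.
#' Zero aboveground carbon or age zero return zero (no established stand
#' implies no modelled root stock). Vectorised over both arguments.
#'
#' @param abg_c Aboveground carbon density, Mg C/ha (>= 0).
#' @param age_years Stand age in years (>= 0).
#' @param coeffs An [allometry_coefficients()] object.
#' @return Belowground carbon in Mg C per ha.
#' @examples
#' root_carbon_mg_ha(152.78, 20)  # 31.52 Mg C/ha
#' @export
root_carbon_mg_ha <- function(abg_c, age_years,
                              coeffs = allometry_coefficients()) {
  n <- max(length(abg_c), length(age_years))
  if (n == 0L) return(numeric(0))
  abg_c <- rep_len(as.numeric(abg_c), n)
  age_years <- rep_len(as.numeric(age_years), n)
  if (any(!is.finite(abg_c)) || any(abg_c < 0)) {
    stop("abg_c must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(age_years)) || any(age_years < 0)) {
    stop("age_years must be finite and non-negative", call. = FALSE)
  }
  out <- numeric(n)
  pos <- abg_c > 0 & age_years > 0
  out[pos] <- exp(coeffs$rbd_intercept +
                    coeffs$rbd_abg_coef * log(abg_c[pos]) +
                    coeffs$rbd_age_coef * log(age_years[pos]))
  out
}

#' Read a stem inventory table
#'
#' Expects a CSV with header `site_id, landform, species_group, dbh_cm,
#' alive, decay_class` (decay_class may be empty for live stems). Validates
#' the landform and species-group vocabularies, the 2.5-cm DBH threshold,
#' and that decay class is recorded only for dead stems.
#'
#' @param path Path to the CSV file.
#' @return A data frame of stems.
#' @export
read_stems <- function(path) {
  req <- c("site_id", "landform", "species_group", "dbh_cm", "alive")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("stem table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"decay_class" %in% names(df)) df$decay_class <- NA_integer_
  df$alive <- as.logical(df$alive)
  validate_stems(df)
  df
}

#' @keywords internal
validate_stems <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  bad_lf <- !df$landform %in% landforms
  if (any(bad_lf)) {
    stop("unknown landform in stem table: ",
         paste(unique(df$landform[bad_lf]), collapse = ", "), call. = FALSE)
  }
  if (!all(df$species_group %in% species_groups)) {
    stop("unknown species_group in stem table", call. = FALSE)
  }
  if (any(!is.finite(df$dbh_cm)) || any(df$dbh_cm < DBH_MIN)) {
    stop("stem table contains DBH below the 2.5 cm measurement threshold",
         call. = FALSE)
  }
  if (any(df$alive & !is.na(df$decay_class))) {
    stop("decay_class recorded for a live stem", call. = FALSE)
  }
  invisible(df)
}

#' Per-plot carbon table from stems and site metadata
#'
#' Joins the stem inventory against site metadata, computes aboveground
#' carbon per plot, and predicts belowground carbon from the plot's
#' aboveground density and site age. Sites x landforms with no stems (failed
#' or unrestored plots) appear with zero carbon.
#'
#' @param stems Stem data frame (see [read_stems()]).
#' @param sites Site metadata with columns `site_id`, `landform`,
#'   `age_years`, `status` (`restored_success`, `restored_failure`,
#'   `unrestored`).
#' @param plot_radius_m Radius of the field plot, m.
#' @param coeffs An [allometry_coefficients()] object.
#' @return Data frame with columns `site_id, landform, age_years, status,
#'   abg_c_mg_ha, blg_c_mg_ha`.
#' @export
plot_carbon_table <- function(stems, sites, plot_radius_m = 2,
                              coeffs = allometry_coefficients()) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "landform", "age_years", "status") %in%
                  names(sites)))
  validate_stems(stems)
  out <- sites[, c("site_id", "landform", "age_years", "status")]
  key <- paste(stems$site_id, stems$landform)
  out$abg_c_mg_ha <- vapply(seq_len(nrow(out)), function(i) {
    sub <- stems[key == paste(out$site_id[i], out$landform[i]), , drop = FALSE]
    plot_abg_carbon_mg_ha(sub, plot_radius_m, coeffs)
  }, numeric(1))
  out$blg_c_mg_ha <- root_carbon_mg_ha(out$abg_c_mg_ha,
                                       out$age_years, coeffs)
  out[order(out$site_id, out$landform), , drop = FALSE]
}
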