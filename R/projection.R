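# Age-indexed carbon accumulation tables per riparian landform.

#' Build a per-landform carbon projection table
#'
#' For each requested age, takes aboveground tree/shrub carbon from either
#' a fitted growth curve or an explicit age-indexed series, predicts
#' belowground carbon with the root biomass density regression (zero at age
#' 0), accumulates soil carbon linearly at the trend slope, and totals the
#' three pools. A non-significant soil trend enters as slope 0 (see
#' [soil_slope_for_projection()]).
#'
#' @param abg_source Either a `growth_fit` (see [fit_vb()]) or a data frame
#'   with columns `age` and `abg_c` supplying the aboveground series
#'   explicitly.
#' @param soil_slope_mg_ha_yr Soil carbon accumulation slope, Mg C/ha/yr
#'   (note: 1 kg/m2/yr = 10 Mg/ha/yr). A negative slope is accepted with a
#'   warning.
#' @param ages Ascending ages starting at 0 (default 0-50 by 5 years).
#' @param landform Optional label carried into the table.
#' @param coeffs An [allometry_coefficients()] object.
#' @return Data frame with columns `landform, age, abg_c, blg_c,
#'   delta_soil_c, total_c`, all carbon densities in Mg C/ha.
#' @examples
#' series <- data.frame(age = c(0, 20, 50), abg_c = c(0, 152.78, 152.81))
#' build_projection(series, soil_slope_mg_ha_yr = 0,
#'                  ages = c(0, 20, 50), landform = "channel")
#' @export
build_projection <- function(abg_source, soil_slope_mg_ha_yr = 0,
                             ages = seq(0, 50, by = 5),
                             landform = NA_character_,
                             coeffs = allometry_coefficients()) {
  stopifnot(length(ages) >= 1L, ages[1] == 0, !is.unsorted(ages, strictly = TRUE))
  if (soil_slope_mg_ha_yr < 0) {
    warning("negative soil slope: projected soil carbon declines with age",
            call. = FALSE)
  }
  if (inherits(abg_source, "growth_fit")) {
    if (!abg_source$converged) {
      stop("growth fit did not converge; cannot project", call. = FALSE)
    }
    abg <- eval_vb(abg_source$a, abg_source$b, ages)
  } else if (is.data.frame(abg_source)) {
    stopifnot(all(c("age", "abg_c") %in% names(abg_source)))
    idx <- match(ages, abg_source$age)
    if (anyNA(idx)) {
      stop("no aboveground value supplied for age(s) ",
           paste(ages[is.na(idx)], collapse = ", "),
           " (no interpolation is performed)", call. = FALSE)
    }
    abg <- abg_source$abg_c[idx]
  } else {
    stop("abg_source must be a growth_fit or a data frame with age, abg_c",
         call. = FALSE)
  }
  blg <- root_carbon_mg_ha(abg, ages, coeffs)
  delta_soil <- soil_slope_mg_ha_yr * ages
  data.frame(
    landform = landform,
    age = ages,
    abg_c = abg,
    blg_c = blg,
    delta_soil_c = delta_soil,
    total_c = abg + blg + delta_soil,
    stringsAsFactors = FALSE
  )
}

#' Soil slope entering a projection
#'
#' Converts a fitted [fit_soil_trend()] to the Mg C/ha/yr slope used in
#' projections, zeroing it when the trend is not significant at the given
#' threshold (a non-significant accumulation is not projected).
#'
#' @param trend A `soil_trend` object.
#' @param sig_level Significance threshold for the slope (default 0.05).
#' @return Slope in Mg C/ha/yr (kg/m2/yr x 10), or 0 when non-significant.
#' @export
soil_slope_for_projection <- function(trend, sig_level = 0.05) {
  stopifnot(inherits(trend, "soil_trend"))
  if (trend$p_value >= sig_level) return(0)
  trend$slope * 10
}

#' Total carbon density at a tabulated age
#'
#' Looks up `total_c` at an age present in the projection; ages between
#' table rows are an error, never interpolated.
#'
#' @param projection A table from [build_projection()].
#' @param age Age to look up, years.
#' @return Total carbon density, Mg C/ha.
#' @export
density_at_age <- function(projection, age) {
  stopifnot(is.data.frame(projection),
            all(c("age", "total_c") %in% names(projection)))
  i <- match(age, projection$age)
  if (is.na(i)) {
    stop(sprintf("age %g is not tabulated in this projection (ages: %s)",
                 age, paste(projection$age, collapse = ", ")),
         call. = FALSE)
  }
  projection$total_c[i]
}
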