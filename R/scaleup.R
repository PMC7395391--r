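# County-level scale-up: restorable area x carbon density x success rate,
# CO2-equivalent conversion and valuation.

# Mass ratio of CO2 to elemental carbon.
CO2_PER_C <- 44 / 12

#' Area-weighted revegetation success fraction
#'
#' The proportion, by area, of attempted revegetation projects on a
#' landform that resulted in successful woody establishment; used to
#' discount restorable area in the scale-up.
#'
#' @param successful_area_ha Area of successful projects, ha.
#' @param attempted_area_ha Area of attempted projects, ha (> 0).
#' @return Fraction in \[0, 1\]. Vectorised.
#' @examples
#' success_fraction(61.88, 100)  # 0.6188
#' @export
success_fraction <- function(successful_area_ha, attempted_area_ha) {
  if (any(attempted_area_ha <= 0)) {
    stop("attempted_area_ha must be positive", call. = FALSE)
  }
  if (any(successful_area_ha < 0) ||
      any(successful_area_ha > attempted_area_ha)) {
    stop("need 0 <= successful_area_ha <= attempted_area_ha", call. = FALSE)
  }
  successful_area_ha / attempted_area_ha
}

#' Landform carbon total
#'
#' Restorable area x 20-year carbon density x success fraction, in Mg C.
#' Vectorised over rows.
#'
#' @param restorable_area_ha Restorable (grassland) area within the
#'   landform's stream buffer, ha.
#' @param c_density_mg_ha Projected carbon density at the target age,
#'   Mg C/ha.
#' @param success_fraction Area-weighted success fraction in \[0, 1\].
#' @return Total carbon, Mg C.
#' @examples
#' landform_total(207.2, 184.30, 0.6188)  # 23,630 Mg C
#' @export
landform_total <- function(restorable_area_ha, c_density_mg_ha,
                           success_fraction) {
  stopifnot(all(restorable_area_ha >= 0), all(c_density_mg_ha >= 0),
            all(success_fraction >= 0), all(success_fraction <= 1))
  restorable_area_ha * c_density_mg_ha * success_fraction
}

#' Build the per-landform scale-up table
#'
#' Combines a restorable-area table with per-landform carbon densities
#' (central, and optionally low/high interval endpoints) into the
#' county-level bookkeeping table: one row per landform with the recomputed
#' totals.
#'
#' @param areas Data frame with columns `landform, buffer_lo_m, buffer_hi_m,
#'   restorable_area_ha` and either `success_fraction` or the pair
#'   `successful_area_ha, attempted_area_ha`.
#' @param densities Data frame with columns `landform, c_density_mg_ha` and
#'   optional `low_density_mg_ha, high_density_mg_ha`.
#' @return Data frame with one row per landform: areas, densities, success
#'   fraction, and `total_mg_c`, `low_mg_c`, `high_mg_c`.
#' @export
scaleup_table <- function(areas, densities) {
  stopifnot(is.data.frame(areas), is.data.frame(densities),
            all(c("landform", "restorable_area_ha") %in% names(areas)),
            all(c("landform", "c_density_mg_ha") %in% names(densities)))
  if (!"success_fraction" %in% names(areas)) {
    areas$success_fraction <- success_fraction(areas$successful_area_ha,
                                               areas$attempted_area_ha)
  }
  idx <- match(areas$landform, densities$landform)
  if (anyNA(idx)) {
    stop("no density supplied for landform(s): ",
         paste(areas$landform[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- areas
  out$c_density_mg_ha <- densities$c_density_mg_ha[idx]
  out$total_mg_c <- landform_total(out$restorable_area_ha,
                                   out$c_density_mg_ha,
                                   out$success_fraction)
  lo <- densities$low_density_mg_ha %||% densities$c_density_mg_ha
  hi <- densities$high_density_mg_ha %||% densities$c_density_mg_ha
  out$low_mg_c <- landform_total(out$restorable_area_ha, lo[idx],
                                 out$success_fraction)
  out$high_mg_c <- landform_total(out$restorable_area_ha, hi[idx],
                                  out$success_fraction)
  out
}

#' County totals, CO2 equivalents, value, and per-km figures
#'
#' Sums the landform totals, converts elemental carbon to CO2 equivalents
#' by the molar mass ratio 44/12, prices the CO2e, and expresses both
#' quantities per km of restorable stream network. Low/high columns are
#' propagated through the identical arithmetic.
#'
#' @param rows Scale-up table from [scaleup_table()] (one row per
#'   landform).
#' @param price_usd_per_mg_co2e Carbon price, USD per Mg CO2e.
#' @param stream_km Restorable stream network length, km (> 0).
#' @return One-row data frame: `county_c_mg, county_co2e_mg, value_usd,
#'   per_km_co2e, per_km_usd` plus `low_*` / `high_*` bounds for the C and
#'   CO2e totals.
#' @examples
#' rows <- data.frame(landform = "channel", restorable_area_ha = 207.2,
#'                    c_density_mg_ha = 184.30, success_fraction = 0.6188)
#' rows$total_mg_c <- with(rows, restorable_area_ha * c_density_mg_ha *
#'                         success_fraction)
#' rows$low_mg_c <- rows$high_mg_c <- rows$total_mg_c
#' county_summary(rows, price_usd_per_mg_co2e = 17.45, stream_km = 1215)
#' @export
county_summary <- function(rows, price_usd_per_mg_co2e, stream_km) {
  stopifnot(is.data.frame(rows), "total_mg_c" %in% names(rows),
            price_usd_per_mg_co2e >= 0)
  if (stream_km <= 0) stop("stream_km must be positive", call. = FALSE)
  c_mg <- sum(rows$total_mg_c)
  lo_mg <- sum(rows$low_mg_c %||% rows$total_mg_c)
  hi_mg <- sum(rows$high_mg_c %||% rows$total_mg_c)
  co2e <- c_mg * CO2_PER_C
  data.frame(
    county_c_mg = c_mg,
    low_c_mg = lo_mg,
    high_c_mg = hi_mg,
    county_co2e_mg = co2e,
    low_co2e_mg = lo_mg * CO2_PER_C,
    high_co2e_mg = hi_mg * CO2_PER_C,
    price_usd_per_mg_co2e = price_usd_per_mg_co2e,
    value_usd = co2e * price_usd_per_mg_co2e,
    stream_km = stream_km,
    per_km_co2e = co2e / stream_km,
    per_km_usd = co2e * price_usd_per_mg_co2e / stream_km
  )
}
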