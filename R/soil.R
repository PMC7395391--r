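# Equivalent-soil-mass stocks and mass-weighted soil property profiles.

#' Areal mass of a soil horizon
#'
#' Converts horizon thickness and bulk density to mass per unit area:
#' `(bottom_cm - top_cm) * bulk_density * 10` kg/m2 (1 cm of soil at
#' 1 g/cm3 weighs 10 kg/m2). Vectorised.
#'
#' @param top_cm,bottom_cm Horizon depth interval, cm; `top_cm < bottom_cm`.
#' @param bulk_density_g_cm3 Oven-dry bulk density, g/cm3 (> 0).
#' @return Horizon mass in kg per m2.
#' @examples
#' horizon_mass_kg_m2(0, 20, 1.0)   # 200 kg/m2
#' horizon_mass_kg_m2(20, 50, 1.5)  # 450 kg/m2
#' @export
horizon_mass_kg_m2 <- function(top_cm, bottom_cm, bulk_density_g_cm3) {
  n <- max(length(top_cm), length(bottom_cm), length(bulk_density_g_cm3))
  if (n == 0L) return(numeric(0))
  top_cm <- rep_len(as.numeric(top_cm), n)
  bottom_cm <- rep_len(as.numeric(bottom_cm), n)
  bd <- rep_len(as.numeric(bulk_density_g_cm3), n)
  if (any(!is.finite(top_cm)) || any(!is.finite(bottom_cm)) ||
      any(top_cm < 0) || any(bottom_cm <= top_cm)) {
    stop("horizons need 0 <= top_cm < bottom_cm", call. = FALSE)
  }
  if (any(!is.finite(bd)) || any(bd <= 0)) {
    stop("bulk_density_g_cm3 must be positive", call. = FALSE)
  }
  (bottom_cm - top_cm) * bd * 10
}

#' @keywords internal
validate_profile <- function(profile, min_depth = NULL) {
  req <- c("top_cm", "bottom_cm", "bulk_density_g_cm3", "c_pct", "n_pct")
  stopifnot(is.data.frame(profile))
  missing <- setdiff(req, names(profile))
  if (length(missing)) {
    stop("profile missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profile) == 0L) stop("empty soil profile", call. = FALSE)
  profile <- profile[order(profile$top_cm), , drop = FALSE]
  if (profile$top_cm[1] != 0) {
    stop("profile must start at 0 cm", call. = FALSE)
  }
  horizon_mass_kg_m2(profile$top_cm, profile$bottom_cm,
                     profile$bulk_density_g_cm3)  # triggers interval checks
  if (nrow(profile) > 1L &&
      any(abs(profile$top_cm[-1] -
              profile$bottom_cm[-nrow(profile)]) > 1e-9)) {
    stop("profile horizons must be contiguous", call. = FALSE)
  }
  if (any(profile$c_pct < 0) || any(profile$n_pct < 0)) {
    stop("c_pct and n_pct must be non-negative", call. = FALSE)
  }
  if (!is.null(min_depth) && max(profile$bottom_cm) < min_depth) {
    stop(sprintf("profile reaches %.1f cm but %.0f cm is required",
                 max(profile$bottom_cm), min_depth), call. = FALSE)
  }
  profile
}

# Mass of one profile over 0..depth_cm, pro-rating the horizon that crosses
# the boundary by depth.
profile_mass_to_depth <- function(profile, depth_cm = 50) {
  thick <- pmax(0, pmin(profile$bottom_cm, depth_cm) - profile$top_cm)
  sum(thick * profile$bulk_density_g_cm3 * 10)
}

#' Reference soil mass for equivalent-soil-mass stocks
#'
#' The median, over a set of soil profiles, of cumulative soil mass in the
#' top 50 cm. Stocks are then expressed over this fixed mass rather than a
#' fixed depth, so that bulk-density change does not masquerade as a carbon
#' change. By default the floodplain and upper-bank profiles of a dataset
#' are pooled into one reference; set `pooling = "by_landform"` to
#' standardise each landform on its own median.
#'
#' @param horizons Horizon table covering one or more profiles, with columns
#'   `site_id, landform, top_cm, bottom_cm, bulk_density_g_cm3, c_pct,
#'   n_pct`.
#' @param depth_cm Depth defining the reference layer, cm (default 50).
#' @param pooling `"pooled"` (one reference mass) or `"by_landform"`.
#' @return A single reference mass in kg/m2, or a named vector per landform
#'   when `pooling = "by_landform"`.
#' @export
reference_mass <- function(horizons, depth_cm = 50, pooling = c("pooled", "by_landform")) {
  pooling <- match.arg(pooling)
  stopifnot(is.data.frame(horizons))
  if (nrow(horizons) == 0L) stop("no profiles supplied", call. = FALSE)
  one <- function(df) {
    masses <- vapply(split(df, paste(df$site_id, df$landform)), function(p) {
      p <- validate_profile(p, min_depth = depth_cm)
      profile_mass_to_depth(p, depth_cm)
    }, numeric(1))
    stats::median(masses)
  }
  if (pooling == "pooled") return(one(horizons))
  vapply(split(horizons, horizons$landform), one, numeric(1))
}

#' Equivalent-soil-mass carbon and nitrogen stock of a profile
#'
#' Accumulates carbon (and nitrogen) horizon by horizon, from the surface
#' down, until the cumulative soil mass reaches `ref_mass`; the final
#' partial horizon is pro-rated by mass fraction, treating the element as
#' uniformly distributed over the horizon's mass. Auger horizons below the
#' pit are included so deep profiles can be equalised to the reference
#' mass.
#'
#' @param profile Horizon table for one site x landform (columns as in
#'   [reference_mass()]), contiguous from 0 cm.
#' @param ref_mass Reference soil mass, kg/m2 (see [reference_mass()]).
#' @return A one-row data frame: `c_stock_kg_m2, n_stock_kg_m2,
#'   reference_mass_kg_m2, basis` (`"esm_50cm"`).
#' @examples
#' prof <- data.frame(top_cm = c(0, 20), bottom_cm = c(20, 50),
#'                    bulk_density_g_cm3 = c(1.0, 1.5),
#'                    c_pct = c(2, 1), n_pct = c(0.2, 0.1))
#' profile_stock_esm(prof, ref_mass = 500)  # 7 kg C/m2
#' @export
profile_stock_esm <- function(profile, ref_mass) {
  profile <- validate_profile(profile)
  stopifnot(is.numeric(ref_mass), length(ref_mass) == 1L, ref_mass > 0)
  mass <- horizon_mass_kg_m2(profile$top_cm, profile$bottom_cm,
                             profile$bulk_density_g_cm3)
  total <- sum(mass)
  if (total < ref_mass - 1e-9) {
    stop(sprintf(
      "profile mass %.1f kg/m2 is %.1f kg/m2 short of the reference mass %.1f",
      total, ref_mass - total, ref_mass), call. = FALSE)
  }
  cum_prev <- cumsum(c(0, mass[-length(mass)]))
  take <- pmin(pmax(ref_mass - cum_prev, 0), mass)  # kg of each horizon used
  data.frame(
    c_stock_kg_m2 = sum(take * profile$c_pct / 100),
    n_stock_kg_m2 = sum(take * profile$n_pct / 100),
    reference_mass_kg_m2 = ref_mass,
    basis = "esm_50cm",
    stringsAsFactors = FALSE
  )
}

#' Volumetric topsoil stock for the active channel
#'
#' Channel soils are sampled only over 0-10 cm (deeper layers are stream
#' sediment and saturated), and intact cores cannot be extracted, so the
#' bulk density of the top horizon of the same site's floodplain pit is
#' used as a proxy. The stock is volumetric over the fixed 10-cm depth:
#' `10 cm x proxy_bd x 10 x pct/100` kg/m2.
#'
#' @param c_pct,n_pct Carbon and nitrogen percentages of the 0-10 cm sample.
#' @param proxy_bd Bulk density proxy, g/cm3, from the companion floodplain
#'   profile's top horizon.
#' @param depth_cm Sampled depth, cm (default 10).
#' @return A one-row data frame as in [profile_stock_esm()] with basis
#'   `"volumetric_10cm"`.
#' @examples
#' channel_stock_topsoil(1.0, 0.1, proxy_bd = 1.2)  # 1.2 kg C/m2
#' @export
channel_stock_topsoil <- function(c_pct, n_pct, proxy_bd, depth_cm = 10) {
  if (missing(proxy_bd) || length(proxy_bd) != 1L || is.na(proxy_bd)) {
    stop("channel stocks need the companion floodplain top-horizon bulk density",
         call. = FALSE)
  }
  stopifnot(proxy_bd > 0, depth_cm > 0, c_pct >= 0, n_pct >= 0)
  mass <- depth_cm * proxy_bd * 10
  data.frame(
    c_stock_kg_m2 = mass * c_pct / 100,
    n_stock_kg_m2 = mass * n_pct / 100,
    reference_mass_kg_m2 = mass,
    basis = "volumetric_10cm",
    stringsAsFactors = FALSE
  )
}

#' Mass-weighted soil properties to 50 cm
#'
#' Averages bulk density, C%, N%, labile carbon fraction and the fulvic
#' acid : humic acid ratio over 0-50 cm with horizon-mass weights (the
#' horizon crossing 50 cm is pro-rated by depth). The C:N ratio is the
#' ratio of the weighted percentages, not the weighted ratio. Optional
#' properties absent from the profile are returned as `NA`.
#'
#' @param profile Horizon table for one profile; optional columns
#'   `labile_c_frac`, `fa_ha_ratio`.
#' @param depth_cm Averaging depth, cm (default 50).
#' @return A one-row data frame: `bulk_density, c_pct, n_pct, cn_ratio,
#'   labile_c_frac, fa_ha_ratio`.
#' @export
mass_weighted_properties <- function(profile, depth_cm = 50) {
  profile <- validate_profile(profile, min_depth = depth_cm)
  thick <- pmax(0, pmin(profile$bottom_cm, depth_cm) - profile$top_cm)
  w <- thick * profile$bulk_density_g_cm3 * 10
  keep <- w > 0
  profile <- profile[keep, , drop = FALSE]
  w <- w[keep]
  wmean <- function(x) {
    if (is.null(x)) return(NA_real_)
    if (anyNA(x)) return(NA_real_)
    sum(w * x) / sum(w)
  }
  # bulk density weighted by depth (thickness), not by mass of itself
  bd <- sum(thick[keep] * profile$bulk_density_g_cm3) / sum(thick[keep])
  c_w <- wmean(profile$c_pct)
  n_w <- wmean(profile$n_pct)
  cn <- if (is.na(n_w) || n_w == 0) {
    warning("weighted N% is zero; C:N undefined", call. = FALSE)
    NA_real_
  } else c_w / n_w
  data.frame(
    bulk_density = bd,
    c_pct = c_w,
    n_pct = n_w,
    cn_ratio = cn,
    labile_c_frac = wmean(profile$labile_c_frac),
    fa_ha_ratio = wmean(profile$fa_ha_ratio),
    stringsAsFactors = FALSE
  )
}

#' Read a soil horizon table
#'
#' Expects a CSV with header `site_id, landform, top_cm, bottom_cm,
#' bulk_density_g_cm3, c_pct, n_pct` and optional `labile_c_frac,
#' fa_ha_ratio, source` (`pit` or `auger`) and `moisture_frac` columns.
#' When a gravimetric moisture fraction is present the concentration
#' columns are corrected to an oven-dry basis.
#'
#' @param path Path to the CSV file.
#' @return A data frame of horizons.
#' @export
read_horizons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "landform", "top_cm", "bottom_cm",
           "bulk_density_g_cm3", "c_pct", "n_pct")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("horizon table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$landform %in% landforms)) {
    stop("unknown landform in horizon table", call. = FALSE)
  }
  if ("moisture_frac" %in% names(df) && any(df$moisture_frac > 0, na.rm = TRUE)) {
    m <- ifelse(is.na(df$moisture_frac), 0, df$moisture_frac)
    df$c_pct <- df$c_pct * (1 + m)
    df$n_pct <- df$n_pct * (1 + m)
    df$moisture_frac <- NULL
  }
  df
}

#' Per-site soil stock and property table
#'
#' Computes, for every site x landform profile, the equivalent-soil-mass C
#' and N stocks (floodplain and upper bank) or the volumetric 10-cm stock
#' with proxy bulk density (channel), together with mass-weighted
#' properties for the deep profiles. A channel record whose site lacks a
#' floodplain profile is an error, since its bulk-density proxy is taken
#' from the companion floodplain pit.
#'
#' @param horizons Horizon table (see [read_horizons()]).
#' @param ref_mass Reference mass in kg/m2; computed from the pooled
#'   floodplain + upper-bank profiles when `NULL`.
#' @param pooling Passed to [reference_mass()] when `ref_mass` is `NULL`.
#' @return Data frame keyed by `site_id, landform` with stock and property
#'   columns.
#' @export
soil_stock_table <- function(horizons, ref_mass = NULL,
                             pooling = c("pooled", "by_landform")) {
  pooling <- match.arg(pooling)
  stopifnot(is.data.frame(horizons), nrow(horizons) > 0L)
  deep <- horizons[horizons$landform != "channel", , drop = FALSE]
  if (is.null(ref_mass) && nrow(deep) > 0L) {
    ref_mass <- reference_mass(deep, pooling = pooling)
  }
  keys <- unique(horizons[, c("site_id", "landform")])
  keys <- keys[order(keys$site_id, keys$landform), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sid <- keys$site_id[i]; lf <- keys$landform[i]
    prof <- horizons[horizons$site_id == sid & horizons$landform == lf, ,
                     drop = FALSE]
    if (lf == "channel") {
      fp <- horizons[horizons$site_id == sid &
                       horizons$landform == "floodplain", , drop = FALSE]
      if (nrow(fp) == 0L) {
        stop(sprintf(
          "site %s: channel stock needs the companion floodplain profile for its bulk-density proxy",
          sid), call. = FALSE)
      }
      fp <- fp[order(fp$top_cm), , drop = FALSE]
      top <- prof[order(prof$top_cm), , drop = FALSE][1, ]
      st <- channel_stock_topsoil(top$c_pct, top$n_pct,
                                  proxy_bd = fp$bulk_density_g_cm3[1],
                                  depth_cm = max(prof$bottom_cm))
      props <- data.frame(bulk_density = fp$bulk_density_g_cm3[1],
                          c_pct = top$c_pct, n_pct = top$n_pct,
                          cn_ratio = if (top$n_pct > 0)
                            top$c_pct / top$n_pct else NA_real_,
                          labile_c_frac = top$labile_c_frac %||% NA_real_,
                          fa_ha_ratio = top$fa_ha_ratio %||% NA_real_)
    } else {
      rm_i <- if (length(ref_mass) > 1L) ref_mass[[lf]] else ref_mass
      st <- profile_stock_esm(prof, rm_i)
      props <- mass_weighted_properties(prof)
    }
    cbind(data.frame(site_id = sid, landform = lf,
                     stringsAsFactors = FALSE), st, props)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
}
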