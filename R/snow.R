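#' Areal water volume from weighed snow cores
#'
#' Each core's areal water volume (AWV, L/m^2, numerically equal to mm of
#' water equivalent) is its snow weight (kg, taking 1 kg = 1 L of water)
#' divided by the corer cross-section pi * r^2. Replicate cores are averaged
#' within a site first; the survey mean and standard error are then taken
#' over sites, so the SE reflects between-site variability.
#'
#' @param cores data frame with columns `site`, `replicate`, `weight_kg`,
#'   `corer_radius_m`.
#' @return list with `site_awv` (data frame site, awv), `mean`, `se` (L/m^2),
#'   and `n_sites`.
#' @export
areal_water_volume <- function(cores) {
  stopifnot(nrow(cores) >= 1)
  if (any(cores$corer_radius_m <= 0)) stop("corer radius must be > 0")
  if (any(cores$weight_kg < 0)) stop("core weight must be >= 0")
  awv <- cores$weight_kg / (pi * cores$corer_radius_m^2)
  site_awv <- aggregate(list(awv = awv), list(site = cores$site), mean)
  n <- nrow(site_awv)
  list(site_awv = site_awv,
       mean = mean(site_awv$awv),
       se = if (n > 1) stats::sd(site_awv$awv) / sqrt(n) else NA_real_,
       n_sites = n)
}

#' Runoff fraction from a conservative snowpack tracer
#'
#' If a tracer (sulfate by default) is fully conserved in the snowpack while
#' part of the melt sublimates, the meltwater leaving as overland flow is
#' enriched by the inverse of the volume fraction that ran off. The runoff
#' volume fraction is therefore the ratio of the mean tracer concentration
#' in the snowpack to that in the snowmelt streams; the remainder
#' sublimated. The ratio is scale-invariant in the two concentrations.
#'
#' @param c_snowpack mean tracer concentration in the snowpack (mg/L).
#' @param c_snowmelt mean tracer concentration in snowmelt streams (mg/L).
#' @return list with `runoff_fraction` and `sublimated_fraction` (sum to 1).
#' @export
tracer_runoff_fraction <- function(c_snowpack, c_snowmelt) {
  if (c_snowpack < 0 || c_snowmelt <= 0)
    stop("tracer concentrations must be positive")
  if (c_snowmelt < c_snowpack)
    stop("snowmelt tracer concentration below snowpack concentration: ",
         "tracer-enrichment (conservation) assumption violated")
  f <- c_snowpack / c_snowmelt
  list(runoff_fraction = f, sublimated_fraction = 1 - f)
}

#' Snowmelt water volumes entering the lake
#'
#' Snow on the lake surface melts directly into the lake with no sublimation
#' correction: volume = AWV x lake area. Landscape snowmelt reaches the lake
#' only as the overland-flow fraction of the landscape snowpack:
#' volume = AWV x landscape area x runoff fraction. SEs scale linearly with
#' the AWV SE.
#'
#' @param awv result of [areal_water_volume()], or a list with `mean`, `se`.
#' @param lake_area_km2,landscape_area_km2 areas in km^2.
#' @param runoff_fraction overland-flow fraction from
#'   [tracer_runoff_fraction()] (or a configured override).
#' @return data frame with rows `snow_on_lake` and `snow_from_land`:
#'   `volume_km3`, `se_km3`.
#' @export
snow_input_volumes <- function(awv, lake_area_km2, landscape_area_km2,
                               runoff_fraction) {
  if (is.null(lake_area_km2) || is.null(landscape_area_km2) ||
      is.na(lake_area_km2) || is.na(landscape_area_km2))
    stop("lake and landscape areas must be configured")
  stopifnot(lake_area_km2 > 0, landscape_area_km2 > 0,
            runoff_fraction >= 0, runoff_fraction <= 1)
  # AWV in L/m^2 = mm; km^3 = AWV * area_km2 * 1e-6
  se <- if (is.na(awv$se)) 0 else awv$se
  data.frame(
    compartment = c("snow_on_lake", "snow_from_land"),
    volume_km3 = c(awv$mean * lake_area_km2 * 1e-6,
                   awv$mean * landscape_area_km2 * runoff_fraction * 1e-6),
    se_km3 = c(se * lake_area_km2 * 1e-6,
               se * landscape_area_km2 * runoff_fraction * 1e-6))
}

#' Chemical loads delivered by snowmelt
#'
#' On-lake loads use snowpack chemistry (the snow melts straight into the
#' lake); landscape loads use snowmelt-stream chemistry (elution and
#' sublimation have already concentrated the runoff). Load = concentration x
#' volume x 1000 t per (mg/L km^3), with SEs combined linearly:
#' se = c * se_V * 1000 + se_c * V * 1000.
#'
#' @param volumes output of [snow_input_volumes()].
#' @param snowpack_chem,snowmelt_chem data frames `species`, `value` (mg/L),
#'   optional `se`.
#' @param species species to compute; default all species present in the
#'   relevant chemistry table.
#' @return data frame `compartment`, `species`, `load_t`, `se_t`.
#' @export
snow_loads <- function(volumes, snowpack_chem, snowmelt_chem, species = NULL) {
  one <- function(compartment, chem) {
    v <- volumes[volumes$compartment == compartment, ]
    sp <- species %||% chem$species
    miss <- setdiff(sp, chem$species)
    if (length(miss))
      stop("no ", compartment, " chemistry for species: ",
           paste(miss, collapse = ", "))
    i <- match(sp, chem$species)
    conc <- chem$value[i]
    conc_se <- if ("se" %in% names(chem)) ifelse(is.na(chem$se[i]), 0, chem$se[i]) else 0
    data.frame(compartment = compartment, species = sp,
               load_t = convert_load(conc, v$volume_km3),
               se_t = conc * v$se_km3 * 1000 + conc_se * v$volume_km3 * 1000)
  }
  rbind(one("snow_on_lake", snowpack_chem),
        one("snow_from_land", snowmelt_chem))
}
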