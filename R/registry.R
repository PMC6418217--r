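#' Chemical species registry
#'
#' The pipeline tracks a fixed vocabulary of analytes. Each species has a
#' phase (dissolved, particulate or bulk), canonical reporting units
#' (everything is stored internally in mg/L; values read in ug/L are
#' rescaled on ingest), and an optional method detection limit in the same
#' canonical units. Two composites are defined on top of the registry:
#' DIN = NH4 + NO3NO2 and TC = DIC + DOC + PC.
#'
#' @param name species identifier, e.g. `"NH4"`.
#' @param phase one of `"dissolved"`, `"particulate"`, `"bulk"`.
#' @param canonical_units `"mg/L"` or `"ug/L"` — the units the species is
#'   conventionally reported in; storage is always mg/L.
#' @param detection_limit method detection limit in mg/L, or `NA`.
#' @return one-row data frame.
#' @export
chem_species <- function(name, phase = c("dissolved", "particulate", "bulk"),
                         canonical_units = "mg/L", detection_limit = NA_real_) {
  phase <- match.arg(phase)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.na(detection_limit) && detection_limit <= 0)
    stop("detection_limit must be > 0 when present (species ", name, ")")
  data.frame(name = name, phase = phase, canonical_units = canonical_units,
             detection_limit = detection_limit, stringsAsFactors = FALSE)
}

#' Default species registry
#'
#' Dissolved: NH4, NO3NO2, SO4, dSiO2, DIC, DOC, TDP; particulate: PN, PC,
#' TSS; bulk: TP, TN, TFe, CHLA. Detection limits default to the two the
#' workflow depends on — TFe (0.007 mg/L, i.e. 7 ug/L) and TDP
#' (0.0018 mg/L) — and can be extended via [chem_species()] rows or the
#' YAML config.
#'
#' @return data frame with one row per species.
#' @export
default_species_registry <- function() {
  rbind(
    chem_species("NH4",    "dissolved",   "ug/L"),
    chem_species("NO3NO2", "dissolved",   "ug/L"),
    chem_species("SO4",    "dissolved",   "mg/L"),
    chem_species("dSiO2",  "dissolved",   "mg/L"),
    chem_species("DIC",    "dissolved",   "mg/L"),
    chem_species("DOC",    "dissolved",   "mg/L"),
    chem_species("TDP",    "dissolved",   "ug/L", detection_limit = 0.0018),
    chem_species("PN",     "particulate", "ug/L"),
    chem_species("PC",     "particulate", "mg/L"),
    chem_species("TSS",    "particulate", "mg/L"),
    chem_species("TP",     "bulk",        "ug/L"),
    chem_species("TN",     "bulk",        "ug/L"),
    chem_species("TFe",    "bulk",        "ug/L", detection_limit = 0.007),
    chem_species("CHLA",   "bulk",        "ug/L")
  )
}

#' Sampling compartments along the land-to-ocean continuum
#' @return character vector of valid `compartment` labels.
#' @export
loac_compartments <- function() {
  c("snowpack", "snowmelt", "glacial_terminus", "glacial_delta",
    "lake_shoreline", "lake_column", "outflow", "fjord")
}

#' Physical constants and default watershed geometry
#'
#' Watershed geometry defaults describe the study system: a 7516 km^2 High
#' Arctic watershed, 40.9% glacierized, containing a 544 km^2 lake, leaving
#' ~3898 km^2 of ice-free landscape. The snow corer has a 4.3 cm diameter
#' (radius 0.0215 m); sediment core tubes are 8.6 cm inner diameter, so a
#' 1-cm slice is 58.09 cm^3. Atomic masses are used for mass-to-molar ratio
#' conversion; the Poole-Atkins constant (1.7) converts Secchi depth to a
#' light extinction coefficient.
#'
#' @return named list of constants.
#' @export
loac_constants <- function() {
  watershed_km2 <- 7516
  glacier_frac <- 0.409
  lake_km2 <- 544
  list(
    watershed_area_km2  = watershed_km2,
    glacierized_fraction = glacier_frac,
    lake_area_km2       = lake_km2,
    landscape_area_km2  = watershed_km2 * (1 - glacier_frac) - lake_km2,
    snow_corer_radius_m = 0.0215,
    sediment_tube_diameter_cm = 8.6,
    secchi_constant     = 1.7,
    din_tp_thresholds   = c(1.5, 3.4),
    atomic_mass         = c(C = 12.011, N = 14.007, P = 30.974),
    seconds_per_day     = 86400
  )
}

#' Read a pipeline configuration file
#'
#' A single YAML file can override the species registry (detection limits),
#' physical constants, and the master seed. Absent keys fall back to
#' [default_species_registry()] and [loac_constants()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return list with elements `registry`, `constants`, `seed`.
#' @export
read_loac_config <- function(path = NULL) {
  registry <- default_species_registry()
  constants <- loac_constants()
  seed <- 1L
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$seed)) seed <- as.integer(cfg$seed)
    for (nm in names(cfg$constants %||% list()))
      constants[[nm]] <- cfg$constants[[nm]]
    for (sp in cfg$species %||% list()) {
      row <- chem_species(sp$name,
                          sp$phase %||% "dissolved",
                          sp$canonical_units %||% "mg/L",
                          as.numeric(sp$detection_limit %||% NA))
      hit <- registry$name == row$name
      if (any(hit)) registry[hit, ] <- row else registry <- rbind(registry, row)
    }
  }
  list(registry = registry, constants = constants, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
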