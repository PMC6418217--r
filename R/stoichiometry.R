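#' Depth-weighted mean of a water-column profile
#'
#' Trapezoidal integral of the profile over depth divided by the depth
#' range, i.e. a geometrically depth-weighted mean (no hypsographic volume
#' weighting). A single-depth profile returns its value with a
#' `single_depth` flag.
#'
#' @param depths_m increasing depths (m).
#' @param values analyte values at those depths.
#' @param method `"trapezoid"` (depth-weighted) or `"arithmetic"` (plain
#'   mean of the sampled depths).
#' @return list `mean`, `single_depth`.
#' @export
depth_integrated_mean <- function(depths_m, values,
                                  method = c("trapezoid", "arithmetic")) {
  method <- match.arg(method)
  stopifnot(length(depths_m) == length(values))
  if (length(depths_m) < 2)
    return(list(mean = values[1], single_depth = TRUE))
  if (any(diff(depths_m) <= 0)) stop("depths must be strictly increasing")
  m <- if (method == "arithmetic") mean(values) else {
    h <- diff(depths_m)
    sum(h * (values[-1] + values[-length(values)]) / 2) / diff(range(depths_m))
  }
  list(mean = m, single_depth = FALSE)
}

#' Light extinction coefficient from Secchi depth
#'
#' k = constant / Secchi depth, with the Poole-Atkins constant 1.7 by
#' default (so k x Secchi depth = 1.7 exactly).
#'
#' @param z_sd_m Secchi depth (m), > 0.
#' @param constant Poole-Atkins constant.
#' @param digits optional rounding of the reported coefficient.
#' @return k in 1/m.
#' @export
extinction_from_secchi <- function(z_sd_m, constant = 1.7, digits = NULL) {
  if (any(z_sd_m <= 0)) stop("Secchi depth must be > 0")
  k <- constant / z_sd_m
  if (!is.null(digits)) k <- round(k, digits)
  k
}

#' Nutrient limitation class from the DIN:TP mass ratio
#'
#' Below the lower threshold phytoplankton are N-limited, above the upper
#' threshold P-limited, and N-and-P co-limited in between (boundaries
#' inclusive). Default mass-ratio thresholds 1.5 and 3.4.
#'
#' @param din_tp_mass_ratio DIN:TP mass ratio(s), >= 0.
#' @param thresholds length-2 numeric `(lower, upper)`.
#' @return character vector: `"N_limited"`, `"co_limited"`, `"P_limited"`.
#' @export
nutrient_limitation <- function(din_tp_mass_ratio, thresholds = c(1.5, 3.4)) {
  if (any(din_tp_mass_ratio < 0)) stop("ratio must be >= 0")
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
  ifelse(din_tp_mass_ratio < thresholds[1], "N_limited",
         ifelse(din_tp_mass_ratio > thresholds[2], "P_limited", "co_limited"))
}

#' Convert a mass ratio of two elements to a molar ratio
#'
#' molar = mass ratio x (atomic mass of denominator / atomic mass of
#' numerator), with C = 12.011, N = 14.007, P = 30.974.
#'
#' @param ratio_mass mass ratio(s).
#' @param element_pair e.g. `"N:P"` or `c("N", "P")` (numerator first).
#' @return molar ratio.
#' @export
mass_to_molar_ratio <- function(ratio_mass, element_pair) {
  masses <- loac_constants()$atomic_mass
  el <- if (length(element_pair) == 1) strsplit(element_pair, ":")[[1]] else element_pair
  if (length(el) != 2 || !all(el %in% names(masses)))
    stop("unknown element pair; use two of ", paste(names(masses), collapse = ", "))
  ratio_mass * masses[[el[2]]] / masses[[el[1]]]
}

# Freshwater carbonate equilibrium constants at in-situ temperature.
# K1, K2: Harned & Davis (1943) / Harned & Scholes (1941) infinite-dilution
# fits; KH (mol/L/atm): Weiss (1974) CO2 solubility at salinity 0.
carbonate_constants <- function(temp_c) {
  TK <- temp_c + 273.15
  k1 <- 10^(-3404.71 / TK + 14.8435 - 0.032786 * TK)
  k2 <- 10^(-2902.39 / TK + 6.4980 - 0.02379 * TK)
  kh <- exp(-58.0931 + 90.5069 * (100 / TK) + 22.2940 * log(TK / 100))
  list(k1 = k1, k2 = k2, kh = kh)
}

#' CO2 percent saturation from DIC, pH and temperature
#'
#' Speciates DIC into CO2*/HCO3-/CO3-- with freshwater equilibrium
#' constants at the in-situ temperature and compares the dissolved CO2
#' concentration with the Henry's-law equilibrium at the atmospheric
#' partial pressure: 100 x [CO2] / (KH x pCO2).
#'
#' @param dic_mgc_l DIC in mg C/L, > 0.
#' @param ph pH in `[4, 10]`.
#' @param temp_c water temperature (deg C).
#' @param atm_co2_ppm atmospheric CO2 mixing ratio (ppm = uatm).
#' @return percent saturation (100 = equilibrium).
#' @export
co2_saturation <- function(dic_mgc_l, ph, temp_c, atm_co2_ppm = 400) {
  if (any(ph < 4 | ph > 10)) stop("pH outside [4, 10]")
  if (any(dic_mgc_l <= 0)) stop("DIC must be > 0")
  k <- carbonate_constants(temp_c)
  h <- 10^(-ph)
  dic_mol <- dic_mgc_l / 12.011 / 1000             # mol C/L
  alpha0 <- 1 / (1 + k$k1 / h + k$k1 * k$k2 / h^2) # CO2* fraction of DIC
  co2 <- dic_mol * alpha0
  100 * co2 / (k$kh * atm_co2_ppm * 1e-6)
}

#' Stoichiometric summary along the land-to-ocean continuum
#'
#' Per-compartment means and standard errors of concentrations and of the
#' nutrient ratios DIN:TP (mass), TN:TP and TC:TP (molar), ordered from the
#' glacier termini to the outflow. DIN and TC composites are assembled per
#' sample from their constituents when absent ([add_composite_species()]);
#' when both a bulk TN column and DIN + PN are available per sample, their
#' consistency (within 20%) is flagged in `tn_consistent`. The lake water
#' column is split into surface (< 50 m) and bottom (>= 200 m) strata.
#' Empty compartments are omitted with a warning.
#'
#' @param table a [sample_table()].
#' @param surface_max_m,bottom_min_m depth cuts for the lake strata.
#' @return list with `concentrations` and `ratios` data frames (columns
#'   `compartment`, `variable`, `mean`, `se`, `n`) and `tn_consistent`.
#' @export
loac_summary <- function(table, surface_max_m = 50, bottom_min_m = 200) {
  table <- add_composite_species(table)
  df <- as.data.frame(table)
  strat <- df$compartment
  lake <- strat == "lake_column"
  strat[lake & !is.na(df$depth_m) & df$depth_m < surface_max_m] <- "lake_surface"
  strat[lake & !is.na(df$depth_m) & df$depth_m >= bottom_min_m] <- "lake_bottom"
  df$stratum <- strat
  order_levels <- c("glacial_terminus", "glacial_delta", "lake_shoreline",
                    "lake_surface", "lake_bottom", "outflow", "fjord")
  df <- df[df$stratum %in% order_levels, ]
  empty <- setdiff(order_levels, unique(df$stratum))
  if (length(empty))
    warning("no samples in compartment(s): ", paste(empty, collapse = ", "))

  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  summarize <- function(d, valcol) {
    ag <- aggregate(d[[valcol]],
                    list(compartment = d$stratum, variable = d$variable),
                    function(x) c(mean = mean(x), se = se(x), n = length(x)))
    out <- data.frame(ag[1:2], ag$x)
    out$compartment <- factor(out$compartment, levels = order_levels)
    out[order(out$compartment, out$variable), ]
  }

  conc <- df[, c("stratum", "species", "value")]
  names(conc)[2] <- "variable"
  conc_sum <- summarize(conc, "value")

  # per-sample ratios, then compartment means
  wide_key <- paste(df$stratum, df$site, df$date, df$depth_m, sep = "\r")
  keys <- unique(wide_key)
  get <- function(sp) {
    v <- rep(NA_real_, length(keys))
    i <- df$species == sp
    v[match(wide_key[i], keys)] <- df$value[i]
    v
  }
  din <- get("DIN"); tp <- get("TP"); tn <- get("TN"); tc <- get("TC"); pn <- get("PN")
  stratum_of <- df$stratum[match(keys, wide_key)]
  ratios <- rbind(
    data.frame(stratum = stratum_of, variable = "DIN:TP (mass)",
               value = din / tp),  # both stored mg/L, so unit-free
    data.frame(stratum = stratum_of, variable = "TN:TP (molar)",
               value = mass_to_molar_ratio(tn / tp, "N:P")),
    data.frame(stratum = stratum_of, variable = "TC:TP (molar)",
               value = mass_to_molar_ratio(tc / tp, "C:P")))
  ratios$value[!is.finite(ratios$value)] <- NA
  ratios <- ratios[!is.na(ratios$value), ]
  ratio_sum <- if (nrow(ratios)) summarize(ratios, "value") else NULL

  tn_alt <- din + pn
  comparable <- !is.na(tn) & !is.na(tn_alt)
  tn_consistent <- if (any(comparable))
    all(abs(tn[comparable] - tn_alt[comparable]) <=
          0.2 * pmax(tn[comparable], 1e-12)) else NA
  list(concentrations = conc_sum, ratios = ratio_sum,
       tn_consistent = tn_consistent)
}
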