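#' Synthetic-watershed scenario configuration
#'
#' Defines a seeded ground-truth scenario mirroring the study design: seven
#' glacial rivers feeding a large Arctic lake over a mid-June to end-August
#' melt season, two of them sampled weekly (11 calibration samplings across
#' the two study years), snow surveys on the lake (20 sites) and landscape
#' (13 sites) with a conservative sulfate tracer, sediment O2 microprofiles
#' with known consumption zones, and a plankton community structured along
#' a DIN:TP gradient. Dissolved constituents dilute with discharge
#' (c = c0 (q/q0)^-b) and particulates amplify (c = c0 (q/q0)^+d), with
#' multiplicative log-normal noise.
#'
#' @param seed master seed; per-component substreams are derived from it so
#'   components can be regenerated independently.
#' @param n_rivers number of glacial inflow rivers.
#' @param years calendar years simulated.
#' @param peak_q peak discharges (m^3/s), recycled to `n_rivers`; defaults
#'   give a few rivers dominating the total inflow.
#' @param peak_doy,width_days hydrograph peak date (mm-dd) and Gaussian
#'   pulse width.
#' @param event_sdlog log-SD of daily melt-event noise on discharge.
#' @param chem data frame `species`, `kind`, `c0`, `exponent`, `sdlog`
#'   describing concentration-discharge behaviour (mg/L at q = q0).
#' @param awv_mean,awv_site_sd landscape/lake snowpack areal water volume
#'   (L/m^2) and its between-site SD.
#' @param tracer_snowpack conservative tracer concentration in snowpack
#'   (mg/L).
#' @param runoff_fraction true overland-flow fraction of landscape melt.
#' @param o2 list: `zones_mm` breakpoints, `rates` (nmol/cm^3/s), `phi`,
#'   `d0` (cm^2/s), `c_top` (umol/L), `noise_sd` (umol/L).
#' @param community list: `n_samples`, `ratio_range` (DIN:TP mass),
#'   `taxa_per_group`, `abundance` (mean cells/mL scale).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(
    seed = 1L, n_rivers = 7, years = c(2015, 2016),
    peak_q = c(100, 60, 45, 30, 25, 20, 10),
    peak_doy = "07-20", width_days = 15, event_sdlog = 0.3,
    chem = data.frame(
      species  = c("SO4", "DOC", "NO3NO2", "TP"),
      kind     = c("dissolved", "dissolved", "dissolved", "particulate"),
      c0       = c(12, 0.5, 0.02, 0.4),
      exponent = c(0.2, 0.1, 0.3, 0.8),
      sdlog    = c(0.10, 0.15, 0.20, 0.45)),
    awv_mean = 145, awv_site_sd = 30,
    tracer_snowpack = 1.82, runoff_fraction = 0.122,
    o2 = list(zones_mm = c(0, 7.5, 15), rates = c(2.5e-3, 5e-4),
              phi = 0.9, d0 = 1.2e-5, c_top = 300, noise_sd = 2),
    community = list(n_samples = 30, ratio_range = c(2, 60),
                     taxa_per_group = 3, abundance = 500)) {
  structure(list(seed = as.integer(seed), n_rivers = n_rivers, years = years,
                 peak_q = rep_len(peak_q, n_rivers), peak_doy = peak_doy,
                 width_days = width_days, event_sdlog = event_sdlog,
                 chem = chem, awv_mean = awv_mean, awv_site_sd = awv_site_sd,
                 tracer_snowpack = tracer_snowpack,
                 runoff_fraction = runoff_fraction, o2 = o2,
                 community = community),
            class = "scenario_config")
}

# independent substreams from the master seed (kept below 2^31)
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000 * 10007 + k * 7919) %% 2147483647)
}

#' Generate a seasonal melt hydrograph
#'
#' Smooth Gaussian seasonal pulse between 15 June and 31 August with
#' multiplicative log-normal daily event noise (mean-corrected so the
#' expected discharge equals the smooth pulse); zero outside the window.
#'
#' @param year calendar year.
#' @param peak_q peak discharge of the smooth pulse (m^3/s).
#' @param peak_doy pulse peak date, `"mm-dd"`.
#' @param width_days Gaussian width (days).
#' @param event_sdlog log-SD of daily event noise (0 = deterministic).
#' @param seed RNG seed.
#' @return data frame `date`, `q` covering 15 June - 31 August.
#' @export
gen_melt_hydrograph <- function(year, peak_q, peak_doy = "07-20",
                                width_days = 15, event_sdlog = 0.3,
                                seed = 1L) {
  dates <- seq(as.Date(sprintf("%d-06-15", year)),
               as.Date(sprintf("%d-08-31", year)), by = "day")
  t <- as.numeric(dates - as.Date(sprintf("%d-%s", year, peak_doy)))
  q <- peak_q * exp(-t^2 / (2 * width_days^2))
  if (event_sdlog > 0) {
    set.seed(seed)
    q <- q * exp(stats::rnorm(length(q), -event_sdlog^2 / 2, event_sdlog))
  }
  data.frame(date = dates, q = q)
}

#' Generate concentration series and a calibration set for one species
#'
#' Daily concentrations follow a power law in discharge relative to the
#' mean melt-season discharge q0 — diluting for dissolved species
#' (exponent applied negatively) and amplifying for particulates — with
#' multiplicative log-normal noise. The realized true annual load is the
#' direct sum of daily concentration x discharge.
#'
#' @param q_series data frame `date`, `q`.
#' @param species species name.
#' @param kind `"dissolved"` or `"particulate"`.
#' @param c0 concentration (mg/L) at q = q0.
#' @param exponent power-law magnitude b (dissolved) or d (particulate),
#'   >= 0.
#' @param sdlog multiplicative noise log-SD.
#' @param n_calib number of calibration samplings (evenly spaced over
#'   flowing days).
#' @param seed RNG seed.
#' @return list: `daily` (date, q, c), `calib` (date, q, c subset),
#'   `true_load_t` (metric tons).
#' @export
gen_chemistry <- function(q_series, species, kind = "dissolved", c0 = 1,
                          exponent = 0.2, sdlog = 0.1, n_calib = 11,
                          seed = 1L) {
  stopifnot(exponent >= 0, kind %in% c("dissolved", "particulate"))
  pos <- q_series$q > 0
  q0 <- mean(q_series$q[pos])
  sgn <- if (kind == "dissolved") -1 else 1
  conc <- rep(NA_real_, nrow(q_series))
  conc[pos] <- c0 * (q_series$q[pos] / q0)^(sgn * exponent)
  if (sdlog > 0) {
    set.seed(seed)
    conc[pos] <- conc[pos] *
      exp(stats::rnorm(sum(pos), -sdlog^2 / 2, sdlog))
  }
  daily <- data.frame(date = q_series$date, q = q_series$q, c = conc)
  ipos <- which(pos)
  idx <- ipos[unique(round(seq(1, length(ipos), length.out = min(n_calib, length(ipos)))))]
  true_load_t <- sum(daily$c[pos] * daily$q[pos]) * 86400 / 1e6
  list(daily = daily, species = species,
       calib = daily[idx, c("date", "q", "c")], true_load_t = true_load_t)
}

#' Generate a snow survey with known areal water volume and tracer truth
#'
#' Site AWVs are drawn around the target mean; three replicate cores per
#' site convert AWV back to core weights through the corer geometry. The
#' snowmelt tracer concentration is the snowpack concentration divided by
#' the true runoff fraction, so the tracer partition inverts exactly in the
#' noise-free case.
#'
#' @param config a [scenario_config()].
#' @param n_lake_sites,n_land_sites numbers of survey sites.
#' @param seed RNG seed (defaults to a substream of the master seed).
#' @return list: `cores_lake`, `cores_land` (site, replicate, weight_kg,
#'   corer_radius_m), `snowpack_chem`, `snowmelt_chem` (species, value),
#'   `truth` (awv_mean, runoff_fraction, tracer concentrations).
#' @export
gen_snow_survey <- function(config, n_lake_sites = 20, n_land_sites = 13,
                            seed = sub_seed(config$seed, 2)) {
  set.seed(seed)
  r <- loac_constants()$snow_corer_radius_m
  mk <- function(n, prefix) {
    awv_site <- stats::rnorm(n, config$awv_mean, config$awv_site_sd)
    awv_site <- pmax(awv_site, 1)
    cores <- expand.grid(site = paste0(prefix, seq_len(n)),
                         replicate = 1:3, stringsAsFactors = FALSE)
    cores$corer_radius_m <- r
    cores$weight_kg <- awv_site[match(cores$site, paste0(prefix, seq_len(n)))] *
      pi * r^2
    cores
  }
  tracer_melt <- config$tracer_snowpack / config$runoff_fraction
  list(cores_lake = mk(n_lake_sites, "L"), cores_land = mk(n_land_sites, "S"),
       snowpack_chem = data.frame(species = c("SO4", "DOC", "NO3NO2"),
                                  value = c(config$tracer_snowpack, 0.3, 0.04)),
       snowmelt_chem = data.frame(species = c("SO4", "DOC", "NO3NO2"),
                                  value = c(tracer_melt, 4.8, 0.12)),
       truth = list(awv_mean = config$awv_mean,
                    runoff_fraction = config$runoff_fraction,
                    tracer_snowpack = config$tracer_snowpack,
                    tracer_snowmelt = tracer_melt))
}

#' Generate a sediment O2 microprofile from known consumption zones
#'
#' Forward-solves the steady-state diffusion-reaction equation for the
#' configured zone rates on a 0.1-mm grid (plus 1 cm of bottom water above
#' the interface at the boundary concentration) and adds Gaussian
#' measurement noise. The generating truth is returned alongside.
#'
#' @param config a [scenario_config()] (its `o2` element is used).
#' @param seed RNG seed.
#' @return list: `profile` (ready for [fit_consumption_zones()]: `z_mm`,
#'   `c`, `phi`, `d0`) and `truth` (zones, rates, integrated rate).
#' @export
gen_o2_profile <- function(config, seed = sub_seed(config$seed, 3)) {
  o2 <- config$o2
  zmax <- max(o2$zones_mm)
  z_sed <- seq(0, zmax, by = 0.1)
  phi_ds <- o2$phi * sediment_diffusivity(o2$d0, o2$phi)
  closed <- identical(o2$bc, "bottom_closed")
  c_sed <- solve_steady_profile(
    z_sed, o2$rates, o2$zones_mm, phi_ds,
    if (closed) list(c_bottom = 0, flux_bottom = 0)
    else list(c_top = o2$c_top, c_bottom = 0))
  z_above <- seq(-10, -0.1, by = 0.1)
  c_all <- c(rep(c_sed[1], length(z_above)), c_sed)
  if (o2$noise_sd > 0) {
    set.seed(seed)
    c_all <- c_all + stats::rnorm(length(c_all), 0, o2$noise_sd)
  }
  list(profile = list(z_mm = c(z_above, z_sed), c = c_all,
                      phi = o2$phi, d0 = o2$d0, temperature_C = 3.76),
       truth = list(zones_mm = o2$zones_mm, rates = o2$rates,
                    integrated_rate = sum(o2$rates * diff(o2$zones_mm) / 10),
                    c_top = c_sed[1], bc = o2$bc %||% "dirichlet"))
}

#' Generate a plankton community along a DIN:TP gradient
#'
#' Group abundances follow monotone logistic responses to the DIN:TP mass
#' ratio — mixotroph-like groups (chrysophytes, cryptophytes,
#' dinoflagellates) decline as the ratio rises while diatoms, chlorophytes
#' and cyanobacteria increase — with Poisson sampling noise per taxon.
#' Environmental covariates include the gradient itself plus unrelated
#' noise variables.
#'
#' @param config a [scenario_config()] (its `community` element is used).
#' @param noise `TRUE` for Poisson counts, `FALSE` for noiseless expected
#'   abundances.
#' @param seed RNG seed.
#' @return list: `community` (samples x taxa matrix), `env` (data frame of
#'   covariates incl. `DIN_TP`), `groups` (taxon -> group map), `season`
#'   (sample season labels), `truth`.
#' @export
gen_community <- function(config, noise = TRUE,
                          seed = sub_seed(config$seed, 4)) {
  cm <- config$community
  set.seed(seed)
  ratio <- seq(cm$ratio_range[1], cm$ratio_range[2],
               length.out = cm$n_samples)
  groups <- c(chrysophyte = -1, cryptophyte = -1, dinoflagellate = -1,
              diatom = 1, chlorophyte = 1, cyanobacteria = 1)
  mid <- mean(cm$ratio_range); scale <- diff(cm$ratio_range) / 8
  taxa <- unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(cm$taxa_per_group))))
  group_of <- rep(names(groups), each = cm$taxa_per_group)
  mult <- stats::runif(length(taxa), 0.5, 1.5)
  mu <- sapply(seq_along(taxa), function(j) {
    resp <- stats::plogis(groups[[group_of[j]]] * (ratio - mid) / scale)
    cm$abundance * mult[j] * resp
  })
  colnames(mu) <- taxa
  community <- if (noise) {
    cnt <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
                  dimnames = dimnames(mu))
    cnt
  } else mu
  season <- ifelse(ratio > mid, "under_ice", "open_water")
  env <- data.frame(DIN_TP = ratio,
                    TP = stats::rlnorm(cm$n_samples, log(0.01), 0.3),
                    temperature = stats::rnorm(cm$n_samples, 3.5, 0.5),
                    SO4 = stats::rlnorm(cm$n_samples, log(8), 0.2),
                    CO2_sat = stats::rnorm(cm$n_samples, 95, 10))
  list(community = community, env = env,
       groups = stats::setNames(group_of, taxa), season = season,
       truth = list(gradient = ratio, direction = groups))
}

#' Simulate a complete synthetic field season
#'
#' Runs every generator with substreams of the master seed: hydrographs and
#' chemistry for each river and year (rivers 1-2 sampled with the weekly
#' design, the rest synoptically), the snow survey, one sediment
#' microprofile, the plankton community, and an outflow approximated by the
#' summed inflows. The `truth` element records all generating parameters
#' and realized true loads.
#'
#' @param config a [scenario_config()].
#' @return list of class `synthetic_watershed` with elements `config`,
#'   `hydrographs` (river x year), `chemistry`, `snow`, `sediment`,
#'   `community`, `truth`.
#' @export
simulate_watershed <- function(config = scenario_config()) {
  rivers <- paste0("river", seq_len(config$n_rivers))
  hydro <- list(); chem <- list(); truth_loads <- list()
  k <- 10L
  for (y in config$years) {
    for (i in seq_len(config$n_rivers)) {
      k <- k + 1L
      qs <- gen_melt_hydrograph(y, config$peak_q[i], config$peak_doy,
                                config$width_days, config$event_sdlog,
                                seed = sub_seed(config$seed, k))
      hydro[[paste(rivers[i], y, sep = ".")]] <- qs
      n_cal <- if (i <= 2) (if (y == min(config$years)) 5 else 6) else
        (if (y == min(config$years)) 1 else 2)
      for (j in seq_len(nrow(config$chem))) {
        k <- k + 1L
        cc <- config$chem[j, ]
        g <- gen_chemistry(qs, cc$species, cc$kind, cc$c0, cc$exponent,
                           cc$sdlog, n_calib = n_cal,
                           seed = sub_seed(config$seed, k))
        chem[[paste(rivers[i], y, cc$species, sep = ".")]] <- g
        truth_loads[[paste(rivers[i], y, cc$species, sep = ".")]] <-
          g$true_load_t
      }
    }
  }
  snow <- gen_snow_survey(config)
  sed <- gen_o2_profile(config)
  comm <- gen_community(config)
  structure(list(config = config, hydrographs = hydro, chemistry = chem,
                 snow = snow, sediment = sed, community = comm,
                 truth = list(loads_t = truth_loads, snow = snow$truth,
                              sediment = sed$truth, community = comm$truth)),
            class = "synthetic_watershed")
}

#' Write a synthetic scenario to a directory of CSV files
#'
#' Produces the pipeline's file interface: `discharge.csv`,
#' `calibration.csv`, `snowcores.csv`, `snow_chemistry.csv`,
#' `sediment_profiles.csv`, `community.csv`, `env.csv` and `truth.json`
#' (the master seed is recorded in every file header line).
#'
#' @param sim a [simulate_watershed()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# seed %d", sim$config$seed)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
    path
  }
  dis <- do.call(rbind, lapply(names(sim$hydrographs), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(river = parts[1], date = sim$hydrographs[[nm]]$date,
               q_m3s = sim$hydrographs[[nm]]$q)
  }))
  wr(dis, "discharge.csv")
  cal <- do.call(rbind, lapply(names(sim$chemistry), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cbind(data.frame(river = parts[1], species = parts[3]),
          sim$chemistry[[nm]]$calib)
  }))
  wr(cal, "calibration.csv")
  wr(rbind(sim$snow$cores_lake, sim$snow$cores_land), "snowcores.csv")
  wr(rbind(cbind(compartment = "snowpack", sim$snow$snowpack_chem),
           cbind(compartment = "snowmelt", sim$snow$snowmelt_chem)),
     "snow_chemistry.csv")
  wr(data.frame(core = "core1", depth_mm = sim$sediment$profile$z_mm,
                o2_umolL = sim$sediment$profile$c), "sediment_profiles.csv")
  comm <- as.data.frame(as.table(sim$community$community))
  names(comm) <- c("sample", "taxon", "density_cells_mL")
  comm$group <- sim$community$groups[as.character(comm$taxon)]
  wr(comm[, c("sample", "taxon", "group", "density_cells_mL")],
     "community.csv")
  env <- cbind(sample = rownames(sim$community$env) %||%
                 seq_len(nrow(sim$community$env)), sim$community$env)
  wr(env, "env.csv")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' One rating-curve recovery experiment on synthetic truth
#'
#' Generates a melt hydrograph and a diluting dissolved constituent with
#' known realized annual load, samples `n_calib` calibration points, fits
#' and selects a rating curve, and integrates the annual load with a
#' residual-bootstrap SE.
#'
#' @param seed replicate seed.
#' @param n_calib calibration samplings.
#' @param sdlog concentration noise log-SD.
#' @param n_boot bootstrap replicates (0 skips the SE).
#' @param peak_q,exponent,c0 hydrograph and chemistry truth parameters.
#' @return list `true_tons`, `est_tons`, `se_tons`, `Bp`, `r2`, `form`.
#' @export
simulate_load_recovery <- function(seed, n_calib = 11, sdlog = 0.3,
                                   n_boot = 300, peak_q = 50,
                                   exponent = 0.2, c0 = 5) {
  qs <- gen_melt_hydrograph(2015, peak_q, event_sdlog = 0.3,
                            seed = sub_seed(seed, 1))
  g <- gen_chemistry(qs, "X", "dissolved", c0, exponent, sdlog,
                     n_calib = n_calib, seed = sub_seed(seed, 2))
  fit <- select_rating_model(g$calib)
  al <- annual_load(fit, qs, n_boot = n_boot, seed = sub_seed(seed, 3),
                    reselect = TRUE)
  list(true_tons = g$true_load_t, est_tons = al$tons, se_tons = al$se,
       Bp = fit$Bp, r2 = fit$r2, form = fit$form)
}

#' One conservative-tracer budget closure experiment
#'
#' A species with the same concentration in every hydrological compartment
#' (so the flow-weighted outflow concentration equals that of the inputs)
#' is pushed through the full pipeline: rating curves per inflow river and
#' for the outflow (whose discharge is the summed inflows plus snowmelt),
#' snow loads from the survey, and the input-output budget. The ground
#' truth is zero storage change, so a well-calibrated pipeline classifies
#' the budget neutral with |delta storage| within ~2 combined SEs.
#'
#' @param seed replicate seed.
#' @param n_rivers inflow rivers.
#' @param conc tracer concentration (mg/L) common to all compartments.
#' @param sdlog measurement noise on sampled concentrations.
#' @param n_calib calibration samplings per river.
#' @param n_boot bootstrap replicates for load SEs.
#' @return one-row budget data frame (see [assemble_budget()]) with an
#'   extra column `closure_z` = |delta storage| / (se_in + se_out).
#' @export
simulate_conservative_budget <- function(seed, n_rivers = 3, conc = 10,
                                         sdlog = 0.05, n_calib = 11,
                                         n_boot = 200) {
  peaks <- c(80, 40, 20, 15, 10)[seq_len(n_rivers)]
  qs_list <- lapply(seq_len(n_rivers), function(i)
    gen_melt_hydrograph(2015, peaks[i], event_sdlog = 0.3,
                        seed = sub_seed(seed, 20 + i)))
  river_loads <- lapply(seq_len(n_rivers), function(i) {
    g <- gen_chemistry(qs_list[[i]], "cons", "dissolved", conc, 0, sdlog,
                       n_calib = n_calib, seed = sub_seed(seed, 40 + i))
    fit <- select_rating_model(g$calib)
    annual_load(fit, qs_list[[i]], n_boot = n_boot,
                seed = sub_seed(seed, 60 + i))
  })
  glacial_t <- sum(vapply(river_loads, function(x) x$tons, numeric(1)))
  glacial_se <- sum(vapply(river_loads, function(x) x$se, numeric(1)))

  cfg <- scenario_config(seed = sub_seed(seed, 80),
                         tracer_snowpack = conc, runoff_fraction = 0.122)
  snow <- gen_snow_survey(cfg)
  awv <- areal_water_volume(rbind(snow$cores_lake, snow$cores_land))
  cons <- loac_constants()
  vols <- snow_input_volumes(awv, cons$lake_area_km2, cons$landscape_area_km2,
                             cfg$runoff_fraction)
  chem_df <- data.frame(species = "cons", value = conc)
  sl <- snow_loads(vols, chem_df, chem_df)

  out_q <- qs_list[[1]]
  for (i in seq_len(n_rivers)[-1]) out_q$q <- out_q$q + qs_list[[i]]$q
  snow_q_km3 <- sum(vols$volume_km3)
  melt_days <- sum(out_q$q > 0)
  out_q$q <- out_q$q + snow_q_km3 * 1e9 / (melt_days * 86400)
  g_out <- gen_chemistry(out_q, "cons", "dissolved", conc, 0, sdlog,
                         n_calib = n_calib, seed = sub_seed(seed, 81))
  fit_out <- select_rating_model(g_out$calib)
  out_load <- annual_load(fit_out, out_q, n_boot = n_boot,
                          seed = sub_seed(seed, 82))

  components <- rbind(
    data.frame(species = "cons", year = 2015, compartment = sl$compartment,
               load = sl$load_t, se = sl$se_t),
    data.frame(species = "cons", year = 2015, compartment = "glacial_rivers",
               load = glacial_t, se = glacial_se))
  outflow <- data.frame(species = "cons", year = 2015,
                        load = out_load$tons, se = out_load$se)
  b <- assemble_budget(components, outflow)
  b$closure_z <- abs(b$delta_storage) / (b$se_in + b$se_out)
  b
}

#' One sediment inverse-model recovery experiment
#'
#' Forward-simulates an O2 microprofile from known consumption zones (with
#' optional Gaussian noise), then inverts it with
#' [fit_consumption_zones()] starting from `max_zones` equal zones with
#' boundaries matched to the truth grid span.
#'
#' @param seed replicate seed.
#' @param noise_sd measurement noise (umol/L); 0 for the noiseless check.
#' @param rates,zones_mm generating truth.
#' @param max_zones starting zone count for the fit.
#' @param bc boundary-condition mode passed to [fit_consumption_zones()].
#' @return list `truth_rates`, `fitted` (`zone_model`), `matched_rates`
#'   (fitted rate evaluated at each truth zone midpoint), `rate_se`.
#' @export
simulate_o2_recovery <- function(seed, noise_sd = 2,
                                 rates = c(5.57e-3, 1.115e-3),
                                 zones_mm = c(0, 7.5, 15), max_zones = 4,
                                 bc = "bottom_closed") {
  cfg <- scenario_config(seed = seed,
                         o2 = list(zones_mm = zones_mm, rates = rates,
                                   phi = 0.9, d0 = 1.2e-5, c_top = 300,
                                   noise_sd = noise_sd, bc = bc))
  g <- gen_o2_profile(cfg, seed = sub_seed(seed, 5))
  fit <- fit_consumption_zones(g$profile, max_zones = max_zones, bc = bc)
  mids <- (zones_mm[-1] + zones_mm[-length(zones_mm)]) / 2
  zi <- zone_index(mids / 10, fit$boundaries_mm / 10)
  list(truth_rates = rates, fitted = fit,
       matched_rates = fit$rates[zi], rate_se = fit$rate_se[zi])
}
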