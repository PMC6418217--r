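#' Porosity of a sediment core section
#'
#' Porosity is the void fraction of the slice, assuming all voids were
#' water-filled before freeze-drying: the mass of water lost (wet - dry, g,
#' at 1 g/cm^3) divided by the section volume. With the default 8.6 cm
#' inner-diameter core tube, a 1-cm slice is pi * 4.3^2 = 58.09 cm^3.
#'
#' @param wet_g,dry_g section weights before and after freeze-drying.
#' @param slice_volume_cm3 section volume; default 1-cm slice of the 8.6 cm
#'   tube.
#' @return porosity in `[0, 1]` (values outside are clipped with a warning).
#' @export
porosity <- function(wet_g, dry_g,
                     slice_volume_cm3 = pi * (8.6 / 2)^2 * 1) {
  if (any(dry_g > wet_g)) stop("dry weight exceeds wet weight")
  phi <- (wet_g - dry_g) / 1.0 / slice_volume_cm3
  if (any(phi > 1)) {
    warning("porosity > 1 clipped to 1")
    phi <- pmin(phi, 1)
  }
  phi
}

#' Sediment diffusion coefficient from porosity
#'
#' Tortuosity correction Ds = D0 / (1 + 3 * (1 - phi)): the free-solution
#' diffusivity is recovered at phi = 1 and reduced up to four-fold at
#' phi = 0.
#'
#' @param d0 free-solution diffusivity (cm^2/s), > 0.
#' @param phi porosity in `[0, 1]`.
#' @return Ds in cm^2/s.
#' @export
sediment_diffusivity <- function(d0, phi) {
  if (any(phi < 0 | phi > 1)) stop("phi outside [0, 1]")
  if (any(d0 <= 0)) stop("d0 must be > 0")
  d0 / (1 + 3 * (1 - phi))
}

#' Free-solution O2 diffusivity at temperature
#'
#' Linear interpolation in a small freshwater literature-style table
#' (cm^2/s against deg C). Intended as a convenience default; site work
#' should supply its own temperature-specific value.
#'
#' @param temp_c temperature in deg C.
#' @return D0 in cm^2/s.
#' @export
o2_diffusivity_d0 <- function(temp_c) {
  tab_t <- c(0, 5, 10, 15, 20, 25)
  tab_d <- c(1.10, 1.26, 1.43, 1.62, 1.82, 2.04) * 1e-5
  stats::approx(tab_t, tab_d, xout = temp_c, rule = 2)$y
}

zone_index <- function(z_cm, boundaries_cm) {
  n_zones <- length(boundaries_cm) - 1L
  pmin(pmax(findInterval(z_cm, boundaries_cm, rightmost.closed = TRUE), 1L),
       n_zones)
}

# overlap lengths of segment [a, b] with each zone
zone_overlap <- function(a, b, boundaries) {
  lo <- pmax(a, boundaries[-length(boundaries)])
  hi <- pmin(b, boundaries[-1])
  pmax(hi - lo, 0)
}

# series (harmonic) effective diffusivity of a segment spanning zones
segment_harmonic_d <- function(a, b, boundaries, d_zone) {
  w <- zone_overlap(a, b, boundaries)
  (b - a) / sum(w / d_zone)
}

# length-weighted mean rate over a segment
segment_mean_r <- function(a, b, boundaries, r_zone) {
  w <- zone_overlap(a, b, boundaries)
  sum(w * r_zone) / (b - a)
}

#' Steady-state diffusion-reaction O2 profile
#'
#' Solves d/dz(phiDs dC/dz) = R(z) by second-order finite differences on
#' the supplied depth grid, with R piecewise constant over consumption
#' zones (positive R = consumption). Boundary conditions are either
#' concentrations at both ends (`bc = list(c_top, c_bottom)`) or a closed
#' bottom (`bc = list(c_bottom, flux_bottom)`, typically both zero where O2
#' is exhausted within the profile).
#'
#' @param z_mm strictly increasing depth grid in mm below the interface.
#' @param rates volumetric net consumption per zone (nmol/cm^3/s).
#' @param boundaries_mm zone breakpoints (mm), length `length(rates) + 1`,
#'   spanning the grid.
#' @param phi_ds effective diffusivity phi * Ds per zone (cm^2/s), scalar or
#'   per-zone vector.
#' @param bc boundary-condition list (see above).
#' @return O2 concentrations (umol/L) at `z_mm`; negative fitted values
#'   trigger a warning.
#' @export
solve_steady_profile <- function(z_mm, rates, boundaries_mm, phi_ds, bc,
                                 check_negative = TRUE) {
  n <- length(z_mm)
  stopifnot(n >= 3, all(diff(z_mm) > 0),
            length(boundaries_mm) == length(rates) + 1L)
  z <- z_mm / 10; b <- boundaries_mm / 10
  n_zones <- length(rates)
  phi_ds <- rep_len(phi_ds, n_zones)
  h <- diff(z)
  # harmonic-mean diffusivity per interval and control-volume-averaged
  # rates: second-order accurate even when zone boundaries fall between
  # grid nodes
  Dmid <- vapply(seq_len(n - 1), function(i)
    segment_harmonic_d(z[i], z[i + 1], b, phi_ds), numeric(1))
  Rnode <- numeric(n)
  for (i in 2:(n - 1))
    Rnode[i] <- segment_mean_r(z[i] - h[i - 1] / 2, z[i] + h[i] / 2, b, rates)
  A <- matrix(0, n, n); r <- numeric(n)
  for (i in 2:(n - 1)) {
    hm <- h[i - 1]; hp <- h[i]
    Dm <- Dmid[i - 1]; Dp <- Dmid[i]
    denom <- (hm + hp) / 2
    A[i, i - 1] <- Dm / (hm * denom)
    A[i, i]     <- -(Dm / hm + Dp / hp) / denom
    A[i, i + 1] <- Dp / (hp * denom)
    r[i] <- Rnode[i]
  }
  if (!is.null(bc$c_top) && !is.null(bc$c_bottom)) {
    A[1, 1] <- 1; r[1] <- bc$c_top
    A[n, n] <- 1; r[n] <- bc$c_bottom
  } else if (!is.null(bc$c_bottom) && !is.null(bc$flux_bottom)) {
    # both conditions at the bottom; the top node keeps no equation of its
    # own (row 1 carries the one-sided second-order bottom-gradient row)
    a <- z[n - 1] - z[n - 2]; bb <- z[n] - z[n - 1]
    A[1, n - 2] <- bb / (a * (a + bb))
    A[1, n - 1] <- -(a + bb) / (a * bb)
    A[1, n]     <- (a + 2 * bb) / (bb * (a + bb))
    r[1] <- -bc$flux_bottom / phi_ds[n_zones]   # J = -phiDs dC/dz
    A[n, n] <- 1; r[n] <- bc$c_bottom
  } else {
    stop("ill-posed boundary conditions: give (c_top, c_bottom) or (c_bottom, flux_bottom)")
  }
  C <- solve(A, r)
  if (check_negative && any(C < -1e-8 * max(abs(C), 1)))
    warning("steady-state profile has negative concentrations")
  C
}

#' Fit piecewise-constant O2 consumption zones to a microprofile
#'
#' Inverse model for a steady-state O2 microprofile: the forward solution is
#' linear in the zone rates, so for fixed zone boundaries the rates are
#' estimated by linear least squares against the measured concentrations
#' below the sediment-water interface. Starting from `max_zones`
#' equal-thickness zones, adjacent zones are merged stepwise (always the
#' merge with the smallest SSE increase, a nested rate-equality constraint)
#' while an F test finds the richer model not significantly better at
#' `alpha`; the minimal adequate model is returned.
#'
#' @param profile list with `z_mm` (depths, mm; points above the interface
#'   are negative and ignored by the fit), `c` (O2, umol/L), `phi`
#'   (porosity: scalar, or function of depth in mm), `d0` (cm^2/s).
#' @param max_zones initial number of equal-thickness zones.
#' @param alpha significance level of the zone-reduction F test.
#' @param bc `"dirichlet"` (measured top and bottom concentrations) or
#'   `"bottom_closed"` (zero concentration and zero flux at the bottom).
#' @return object of class `zone_model`: `boundaries_mm`, `rates`
#'   (nmol/cm^3/s, positive = consumption), `rate_se`, `fitted_c`, `sse`,
#'   `n_zones`, `f_steps`, `integrated_rate` and `swi_flux` (nmol/cm^2/s),
#'   plus the data it was fitted to.
#' @export
fit_consumption_zones <- function(profile, max_zones = 4, alpha = 0.05,
                                  bc = c("dirichlet", "bottom_closed")) {
  bc <- match.arg(bc)
  keep <- profile$z_mm >= 0
  z <- profile$z_mm[keep]; y <- profile$c[keep]
  o <- order(z); z <- z[o]; y <- y[o]
  if (length(z) < 10) stop("need >= 10 measurement points below the interface")
  phi_fun <- if (is.function(profile$phi)) profile$phi else
    function(zz) rep_len(profile$phi, length(zz))
  bclist <- if (bc == "dirichlet")
    list(c_top = y[1], c_bottom = y[length(y)])
  else list(c_bottom = 0, flux_bottom = 0)

  # The forward solution is linear in the zone rates and (for measured-
  # concentration boundaries) in the two boundary concentrations, so the
  # whole inverse problem is one linear least squares. The Dirichlet
  # boundary concentrations are estimated alongside the rates — via the two
  # homogeneous (zero-rate) solutions as extra basis columns — rather than
  # pinned to single noisy readings.
  fit_k <- function(boundaries) {
    k <- length(boundaries) - 1L
    mid <- (boundaries[-1] + boundaries[-(k + 1)]) / 2
    phi_ds <- phi_fun(mid) * sediment_diffusivity(profile$d0, phi_fun(mid))
    hom <- if (bc == "dirichlet") list(c_top = 0, c_bottom = 0)
           else list(c_bottom = 0, flux_bottom = 0)
    B <- vapply(seq_len(k), function(j) {
      e <- rep(0, k); e[j] <- 1
      solve_steady_profile(z, e, boundaries, phi_ds, hom,
                           check_negative = FALSE)
    }, numeric(length(z)))
    if (bc == "dirichlet") {
      u_top <- solve_steady_profile(z, rep(0, k), boundaries, phi_ds,
                                    list(c_top = 1, c_bottom = 0))
      u_bot <- solve_steady_profile(z, rep(0, k), boundaries, phi_ds,
                                    list(c_top = 0, c_bottom = 1))
      M <- cbind(u_top, u_bot, B)
    } else M <- B
    ls <- stats::lm(y ~ 0 + M)
    cf <- unname(stats::coef(ls))
    # noiseless oracles fit perfectly; summary.lm warns about that
    se_all <- suppressWarnings(unname(sqrt(diag(stats::vcov(ls)))))
    off <- if (bc == "dirichlet") 2L else 0L
    list(boundaries = boundaries, phi_ds = phi_ds,
         rates = cf[(off + 1):(off + k)],
         rate_se = se_all[(off + 1):(off + k)],
         bclist = if (bc == "dirichlet")
           list(c_top = cf[1], c_bottom = cf[2]) else bclist,
         fitted = unname(stats::fitted(ls)),
         sse = sum(stats::residuals(ls)^2), k = k)
  }

  cur <- fit_k(seq(min(z), max(z), length.out = max_zones + 1))
  f_steps <- list()
  scale_tol <- 1e-10 * sum(y^2) / length(y)
  while (cur$k > 1) {
    cands <- lapply(seq_len(cur$k - 1), function(j)
      fit_k(cur$boundaries[-(j + 1)]))
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "sse"))]]
    df2 <- length(z) - cur$k
    dsse <- best$sse - cur$sse
    if (cur$sse <= scale_tol) {
      p <- if (dsse <= scale_tol) 1 else 0
    } else {
      Fstat <- dsse / (cur$sse / df2)
      p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
    }
    f_steps[[length(f_steps) + 1]] <-
      data.frame(from = cur$k, to = best$k, delta_sse = dsse, p = p)
    if (p > alpha) cur <- best else break
  }
  # rate magnitude implied by the profile itself, for a numerical-zero guard
  rate_scale <- max(cur$phi_ds) * max(abs(y)) / (diff(range(z)) / 10)^2
  if (any(cur$rates < -1e-8 * rate_scale))
    warning("negative rate fitted: net production in at least one zone")
  thick_cm <- diff(cur$boundaries) / 10
  out <- structure(list(
    boundaries_mm = cur$boundaries, rates = cur$rates, rate_se = cur$rate_se,
    phi_ds = cur$phi_ds, fitted_c = cur$fitted, sse = cur$sse,
    n_zones = cur$k,
    f_steps = if (length(f_steps)) do.call(rbind, f_steps) else NULL,
    integrated_rate = sum(cur$rates * thick_cm),
    bc = bc, bclist = cur$bclist, z_mm = z, c = y),
    class = "zone_model")
  out$swi_flux <- swi_flux(out)
  out
}

#' @export
print.zone_model <- function(x, ...) {
  cat("O2 consumption zone model:", x$n_zones, "zone(s)\n")
  for (i in seq_len(x$n_zones))
    cat(sprintf("  %5.1f-%5.1f mm: R = %.3e +/- %.1e nmol/cm^3/s\n",
                x$boundaries_mm[i], x$boundaries_mm[i + 1],
                x$rates[i], x$rate_se[i]))
  cat(sprintf("  depth-integrated: %.3e nmol/cm^2/s; SWI flux %.3e; SSE %.3g\n",
              x$integrated_rate, x$swi_flux, x$sse))
  invisible(x)
}

#' Depth-integrated consumption of a fitted zone model
#'
#' Sum of zone rate x zone thickness. At steady state with no bottom leak
#' this equals the downward diffusive O2 flux across the sediment-water
#' interface.
#'
#' @param zone_model a fitted `zone_model`.
#' @return nmol/cm^2/s.
#' @export
depth_integrated_rate <- function(zone_model) {
  sum(zone_model$rates * diff(zone_model$boundaries_mm) / 10)
}

#' Diffusive O2 flux at the sediment-water interface
#'
#' -phiDs dC/dz at z = 0, from a 10x-refined forward solve of the fitted
#' model (second-order one-sided gradient). Positive = downward into the
#' sediment.
#'
#' @param zone_model a fitted `zone_model`.
#' @param refine grid-refinement factor.
#' @return nmol/cm^2/s.
#' @export
swi_flux <- function(zone_model, refine = 10) {
  zf <- seq(min(zone_model$z_mm), max(zone_model$z_mm),
            length.out = refine * length(zone_model$z_mm))
  Cf <- solve_steady_profile(zf, zone_model$rates, zone_model$boundaries_mm,
                             zone_model$phi_ds, zone_model$bclist,
                             check_negative = FALSE)
  h <- (zf[2] - zf[1]) / 10
  dcdz <- (-3 * Cf[1] + 4 * Cf[2] - Cf[3]) / (2 * h)
  -zone_model$phi_ds[1] * dcdz
}

#' O2 penetration depth of a fitted zone model
#'
#' First depth at which the modelled concentration falls below `threshold`,
#' from a refined forward solve; the maximum profile depth when O2 never
#' drops that low.
#'
#' @param zone_model a fitted `zone_model`.
#' @param threshold umol/L.
#' @return depth in mm.
#' @export
o2_penetration_depth <- function(zone_model, threshold = 1) {
  zf <- seq(min(zone_model$z_mm), max(zone_model$z_mm),
            length.out = 10 * length(zone_model$z_mm))
  Cf <- solve_steady_profile(zf, zone_model$rates, zone_model$boundaries_mm,
                             zone_model$phi_ds, zone_model$bclist,
                             check_negative = FALSE)
  i <- which(Cf < threshold)
  if (length(i)) zf[min(i)] else max(zf)
}
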