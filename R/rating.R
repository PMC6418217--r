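#' Center log discharge for rating-curve regression
#'
#' Log-linear load models use a centered log discharge lnQhat = ln(q) - c.
#' The centering constant c is chosen so that the linear and quadratic terms
#' are decorrelated over the calibration points: sum(lnQhat_i^3) = 0
#' (equivalently sum(lnQhat * lnQhat^2) = 0). sum((x - c)^3) is strictly
#' decreasing in c, so the cubic has a unique real root; when the root solve
#' fails numerically we fall back to the plain mean of ln q.
#'
#' @param q discharges (m^3/s), all > 0.
#' @param method `"orthogonal"` (cubic-root solve, the load-regression
#'   convention) or `"mean"` (plain mean of ln q).
#' @return list with `lnq_centered` and `center`.
#' @export
center_log_discharge <- function(q, method = c("orthogonal", "mean")) {
  method <- match.arg(method)
  if (any(q <= 0)) stop("all calibration discharges must be > 0")
  x <- log(q)
  center <- mean(x)
  if (method == "orthogonal") {
    n <- length(x)
    # sum((x - c)^3) = S3 - 3 c S2 + 3 c^2 S1 - n c^3, ascending coefficients
    r <- tryCatch(polyroot(c(sum(x^3), -3 * sum(x^2), 3 * sum(x), -n)),
                  error = function(e) complex(0))
    real <- Re(r[abs(Im(r)) < 1e-8 * max(1, abs(Re(r)))])
    if (length(real)) center <- real[which.min(abs(real - mean(x)))]
  }
  list(lnq_centered = x - center, center = center)
}

#' Fit a log-linear rating curve for constituent load
#'
#' Ordinary least squares of ln(load) on centered ln(discharge), where the
#' observed load is concentration x discharge (mg/L x m^3/s = g/s). Form 1
#' is linear in lnQhat; form 2 adds a quadratic term. Retransformation bias
#' on the exponentiated predictions is corrected by Duan's smearing factor,
#' the mean of exp(residuals).
#'
#' @param calib data frame with columns `q` (m^3/s) and `c` (mg/L), both
#'   strictly positive; optional `date`.
#' @param form 1 (linear) or 2 (quadratic).
#' @param centering passed to [center_log_discharge()].
#' @return object of class `rating_curve_fit`: coefficients `a0`, `a1`
#'   (and `a2`), `center`, residual variance `s2`, `smearing`, `r2`, load
#'   bias `Bp` (%), and the calibration data.
#' @export
fit_rating_curve <- function(calib, form = 1, centering = "orthogonal") {
  stopifnot(form %in% c(1, 2))
  if (any(calib$q <= 0) || any(calib$c <= 0))
    stop("calibration discharge and concentration must be > 0 (log-transformable)")
  n <- nrow(calib)
  p <- form + 1L        # number of regression coefficients
  if (n < p + 1L)
    stop("need at least ", p + 1L, " calibration points for form ", form)
  cen <- center_log_discharge(calib$q, centering)
  x <- cen$lnq_centered
  if (stats::var(x) < 1e-12) stop("singular design: no variance in ln discharge")
  y <- log(calib$c * calib$q)   # ln load, load in g/s
  X <- if (form == 1) cbind(1, x) else cbind(1, x, x^2)
  ls <- stats::lm.fit(X, y)
  res <- ls$residuals
  fitted <- ls$fitted.values
  s2 <- sum(res^2) / (n - p)
  sst <- sum((y - mean(y))^2)
  fit <- structure(list(
    form = form, center = cen$center,
    coef = stats::setNames(ls$coefficients, c("a0", "a1", "a2")[seq_len(p)]),
    s2 = s2, smearing = mean(exp(res)),
    r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
    n = n, residuals = res, fitted_log = fitted, calib = calib),
    class = "rating_curve_fit")
  fit$Bp <- load_bias_percentage(fit)
  fit
}

#' @export
print.rating_curve_fit <- function(x, ...) {
  cat("Rating curve (form ", x$form, "), n = ", x$n, "\n", sep = "")
  cat("  coefficients:", paste(names(x$coef), signif(x$coef, 4),
                               sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  center = %.4f  smearing = %.4f  r2 = %.4f  Bp = %.2f%%\n",
              x$center, x$smearing, x$r2, x$Bp))
  invisible(x)
}

#' Predict smearing-corrected instantaneous load
#'
#' @param fit a `rating_curve_fit`.
#' @param q discharges (m^3/s); zeros yield zero load.
#' @return loads in g/s.
#' @export
predict_load <- function(fit, q) {
  out <- numeric(length(q))
  pos <- q > 0
  if (any(pos)) {
    x <- log(q[pos]) - fit$center
    eta <- fit$coef[["a0"]] + fit$coef[["a1"]] * x
    if (fit$form == 2) eta <- eta + fit$coef[["a2"]] * x^2
    out[pos] <- fit$smearing * exp(eta)
  }
  out
}

#' Load bias percentage of a rating-curve fit
#'
#' Bp = 100 x (sum of model-estimated loads - sum of observed loads) /
#' sum of observed loads over the calibration points, with estimates
#' including the smearing correction. Model selection minimizes |Bp|.
#'
#' @param fit a `rating_curve_fit`.
#' @param calib calibration set; defaults to the one the fit was made on.
#' @return bias in percent.
#' @export
load_bias_percentage <- function(fit, calib = fit$calib) {
  obs <- calib$c * calib$q
  est <- predict_load(fit, calib$q)
  100 * (sum(est) - sum(obs)) / sum(obs)
}

#' Select between rating-curve forms by load bias
#'
#' Fits form 1 and, when the calibration set has at least 5 points, form 2;
#' keeps the fit with the smaller |Bp|. A near-tie (|difference| < `tie_bp`
#' percentage points) is broken by the higher r2, then by the simpler form.
#'
#' @param calib calibration data frame (`q`, `c`).
#' @param tie_bp tie tolerance on |Bp| in percentage points.
#' @param centering passed to [fit_rating_curve()].
#' @return the selected `rating_curve_fit`.
#' @export
select_rating_model <- function(calib, tie_bp = 0.1, centering = "orthogonal") {
  f1 <- fit_rating_curve(calib, 1, centering)
  if (nrow(calib) < 5) {
    warning("fewer than 5 calibration points: form 1 only")
    return(f1)
  }
  f2 <- fit_rating_curve(calib, 2, centering)
  d <- abs(f1$Bp) - abs(f2$Bp)
  if (abs(d) < tie_bp) {
    if (!is.na(f2$r2) && !is.na(f1$r2) && f2$r2 > f1$r2) f2 else f1
  } else if (d > 0) f2 else f1
}

#' Integrate a rating curve to an annual load with bootstrap SE
#'
#' Daily loads are the smearing-corrected back-transformed predictions at
#' each day's mean discharge, times 86 400 s/day; the annual total is their
#' sum in metric tons (1 g/s for one day = 0.0864 t). Uncertainty comes
#' from a residual bootstrap: resample the calibration residuals with
#' replacement, rebuild ln-load responses, refit the same-form model,
#' re-integrate, and take the SD over replicates.
#'
#' Resampled residuals are inflated by sqrt(n / (n - p)) so their variance
#' matches the residual variance estimate, and when `reselect = TRUE` the
#' form-1/form-2 choice is repeated inside every replicate so that
#' model-selection uncertainty enters the SE. With `prediction = TRUE`
#' (default) each replicate also draws day-level log-normal scatter around
#' the curve, so the SE describes the realized annual load rather than only
#' the curve's expected load.
#'
#' @param fit a `rating_curve_fit`.
#' @param q_series data frame with `date` and `q` (m^3/s) covering the flow
#'   season; days with q = 0 contribute zero load.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param reselect rerun [select_rating_model()] on each bootstrap sample.
#' @param prediction include day-level scatter around the curve in the SE.
#' @param river,species,year optional labels carried into the result.
#' @return data frame (class `annual_load`): `river`, `species`, `year`,
#'   `tons`, `se`, `n_calibration`.
#' @export
annual_load <- function(fit, q_series, n_boot = 500, seed = 1L,
                        reselect = FALSE, prediction = TRUE,
                        river = NA_character_, species = NA_character_,
                        year = NA_integer_) {
  if (is.null(q_series) || nrow(q_series) == 0) stop("empty discharge series")
  if (any(q_series$q < 0)) stop("negative discharge")
  integrate_tons <- function(f)
    sum(predict_load(f, q_series$q)) * 86400 / 1e6
  tons <- integrate_tons(fit)
  se <- 0
  if (n_boot > 0 && stats::sd(fit$residuals) > 0) {
    calib <- fit$calib
    n <- fit$n
    p <- fit$form + 1L
    res_scaled <- fit$residuals * sqrt(n / (n - p))
    x <- log(calib$q) - fit$center
    X <- if (fit$form == 1) cbind(1, x) else cbind(1, x, x^2)
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      yb <- fit$fitted_log + sample(res_scaled, n, replace = TRUE)
      if (reselect) {
        cb <- calib
        cb$c <- exp(yb) / cb$q
        fb <- suppressWarnings(select_rating_model(cb))
      } else {
        ls <- stats::lm.fit(X, yb)
        fb <- fit
        fb$coef <- stats::setNames(ls$coefficients, names(fit$coef))
        fb$smearing <- mean(exp(ls$residuals))
        fb$residuals <- ls$residuals
      }
      daily <- predict_load(fb, q_series$q)
      if (prediction) {
        pb <- fb$form + 1L
        sb <- sqrt(sum(fb$residuals^2) / (fb$n - pb)) * sqrt(fb$n / (fb$n - pb))
        daily <- daily * exp(stats::rnorm(length(daily), -sb^2 / 2, sb))
      }
      sum(daily) * 86400 / 1e6
    }, numeric(1))
    se <- stats::sd(boots)
  }
  structure(data.frame(river = river, species = species, year = year,
                       tons = tons, se = se, n_calibration = fit$n),
            class = c("annual_load", "data.frame"))
}

#' Transfer a modelled runoff series to an ungauged catchment by area
#'
#' Specific runoff (per unit area) is assumed equal, so discharge scales by
#' the ratio of catchment areas and dates are preserved.
#'
#' @param source_series data frame `date`, `q`.
#' @param source_area_km2,target_area_km2 catchment areas, > 0.
#' @return a discharge series for the target catchment.
#' @export
scale_runoff_by_area <- function(source_series, source_area_km2, target_area_km2) {
  if (source_area_km2 <= 0 || target_area_km2 <= 0)
    stop("catchment areas must be > 0")
  out <- source_series
  out$q <- out$q * (target_area_km2 / source_area_km2)
  out
}
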