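# Shared fixtures built in code.

# minimal sample table with one censored TFe and one uncensored row
make_censored_table <- function() {
  sample_table(data.frame(
    compartment = "lake_column", site = "deep", date = "2015-08-10",
    depth_m = c(250, 250, 100),
    species = c("TFe", "TFe", "TDP"),
    value = c(0.007, 0.495, 0.0018),
    censored = c(TRUE, FALSE, TRUE)))
}

# calibration set following an exact power law load = a * q^b (so that
# concentration c = a * q^(b-1)), optionally with lognormal noise
power_law_calib <- function(q, a = 2, b = 1, sdlog = 0, seed = 1) {
  load <- a * q^b
  if (sdlog > 0) {
    set.seed(seed)
    load <- load * exp(rnorm(length(q), 0, sdlog))
  }
  data.frame(q = q, c = load / q)
}

# brute-force root-finder oracle for the ln-discharge centering condition
center_oracle <- function(lnq) {
  f <- function(cc) sum((lnq - cc)^3)
  uniroot(f, interval = mean(lnq) + c(-50, 50), tol = 1e-12)$root
}

# independent carbonate-system oracle: solve for [CO2] numerically so that
# total carbon matches DIC at the given pH
co2_oracle <- function(dic_mgc_l, ph, temp_c, atm_co2_ppm = 400) {
  TK <- temp_c + 273.15
  k1 <- 10^(-3404.71 / TK + 14.8435 - 0.032786 * TK)
  k2 <- 10^(-2902.39 / TK + 6.4980 - 0.02379 * TK)
  kh <- exp(-58.0931 + 90.5069 * (100 / TK) + 22.2940 * log(TK / 100))
  dic <- dic_mgc_l / 12.011 / 1000
  h <- 10^(-ph)
  f <- function(x) x * (1 + k1 / h + k1 * k2 / h^2) - dic
  co2 <- uniroot(f, c(0, dic), tol = 1e-18)$root
  100 * co2 / (kh * atm_co2_ppm * 1e-6)
}

# 3-significant-figure half-unit, for checking printed-table arithmetic
half_unit_3sf <- function(x) 0.5 * 10^(floor(log10(abs(x))) - 2)
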