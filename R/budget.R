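#' Published annual budget components for the Lake Hazen watershed
#'
#' Annual hydrological inputs (snow on the lake, snowmelt from the
#' landscape, glacial rivers) and the outflow export for 2015 and 2016, as
#' published for the Lake Hazen system: water volumes in km^3 and dissolved
#' constituent loads in metric tons per year with standard errors. Shipped
#' as an example/reference dataset; `total_inputs` rows carry the published
#' totals so budget arithmetic can be checked against them.
#'
#' @return data frame `species`, `year`, `compartment`, `load`, `se`, `units`.
#' @export
hazen_budget_components <- function() {
  utils::read.csv(system.file("extdata", "hazen_budget_components.csv",
                              package = "glacierLOAC"),
                  stringsAsFactors = FALSE)
}

input_compartments <- c("snow_on_lake", "snow_from_land", "glacial_rivers")

#' Sum the three hydrological input loads
#'
#' Totals the snow-on-lake, snow-from-land and glacial-river loads for one
#' species and year. SEs are combined by linear addition by default (the
#' convention the published totals follow); quadrature is available.
#' Components without an SE contribute zero uncertainty.
#'
#' @param components data frame `compartment`, `species`, `year`, `load`,
#'   `se` holding exactly the three input compartments.
#' @param se_method `"linear"` or `"quadrature"`.
#' @return list `load`, `se`.
#' @export
sum_inputs <- function(components, se_method = c("linear", "quadrature")) {
  se_method <- match.arg(se_method)
  if (length(unique(components$species)) != 1L ||
      length(unique(components$year)) != 1L)
    stop("components mix species or years")
  if (!setequal(components$compartment, input_compartments) ||
      nrow(components) != 3L)
    stop("expected exactly the three input compartments: ",
         paste(input_compartments, collapse = ", "))
  se <- ifelse(is.na(components$se), 0, components$se)
  list(load = sum(components$load),
       se = if (se_method == "linear") sum(se) else sqrt(sum(se^2)))
}

#' Annual storage change
#'
#' Delta storage = total outputs - total inputs. Negative means the lake
#' retained the constituent that year (net sink); positive means it exported
#' more than it received (net source, e.g. from internal processing).
#'
#' @param total_in,total_out annual loads (same units).
#' @return storage change, out - in.
#' @export
delta_storage <- function(total_in, total_out) total_out - total_in

#' Classify a budget as sink, source or neutral
#'
#' The budget is significant when the k-SE intervals around total inputs and
#' total outputs are disjoint; the sign of the storage change then decides
#' sink (out < in) versus source (out > in). Overlapping intervals are
#' neutral. Symmetric under exchanging inputs and outputs (with the sign of
#' the storage change flipping).
#'
#' @param total_in,se_in,total_out,se_out annual load totals and SEs.
#' @param k interval half-width in SEs (default 1).
#' @return `"sink"`, `"source"` or `"neutral"` (vectorized).
#' @export
classify_budget <- function(total_in, se_in, total_out, se_out, k = 1) {
  stopifnot(k > 0)
  if (any(c(se_in, se_out) < 0, na.rm = TRUE)) stop("negative SE")
  disjoint <- (total_out + k * se_out < total_in - k * se_in) |
              (total_out - k * se_out > total_in + k * se_in)
  ifelse(!disjoint, "neutral", ifelse(total_out > total_in, "source", "sink"))
}

#' Percent difference between outputs and inputs
#'
#' Computed as 100 x (out - in) / in. Note this plain formula does not
#' reproduce the published table's "% diff." column, whose construction is
#' undocumented; it is reported as this package's own definition.
#'
#' @param total_in,total_out annual totals.
#' @return percent difference.
#' @export
percent_difference <- function(total_in, total_out) {
  100 * (total_out - total_in) / total_in
}

#' Glacial share of total inputs
#'
#' @param components the three input-compartment rows for one species/year.
#' @return percent of the total input load delivered by glacial rivers, or
#'   `NA` (with a warning) when the total is zero.
#' @export
glacial_share <- function(components) {
  if (!all(input_compartments %in% components$compartment))
    stop("all three input compartments required")
  tot <- sum(components$load[components$compartment %in% input_compartments])
  gl <- components$load[components$compartment == "glacial_rivers"]
  if (tot == 0) {
    warning("zero total input load; glacial share undefined")
    return(NA_real_)
  }
  100 * gl / tot
}

#' Range of glacial shares across species and years
#'
#' @param budgets data frame with a `glacial_share` column (e.g. from
#'   [assemble_budget()]); rows with `NA` share are ignored.
#' @param species optional species filter (default: all rows, which is how
#'   the dissolved-species range is taken after upstream filtering).
#' @return named numeric `c(min, max)` in percent.
#' @export
share_range <- function(budgets, species = NULL) {
  if (!is.null(species)) budgets <- budgets[budgets$species %in% species, ]
  s <- budgets$glacial_share
  s <- s[!is.na(s)]
  if (!length(s)) stop("no budgets with a defined glacial share")
  c(min = min(s), max = max(s))
}

#' Approximate outflow discharge as the sum of inputs
#'
#' With an ungauged outflow, annual discharge is approximated by summing the
#' modelled glacial inflow volumes and the two snowmelt volumes, assuming
#' negligible evaporation (recorded in the result's attributes).
#'
#' @param glacial_km3,snow_on_lake_km3,snow_from_land_km3 annual volumes.
#' @return outflow volume in km^3/yr with attribute
#'   `assumes = "no evaporation"`.
#' @export
outflow_discharge <- function(glacial_km3, snow_on_lake_km3, snow_from_land_km3) {
  structure(glacial_km3 + snow_on_lake_km3 + snow_from_land_km3,
            assumes = "no evaporation")
}

#' Assemble annual input-output budgets
#'
#' For every species x year present in both the input components and the
#' outflow loads, totals the inputs, takes the storage change
#' (out - in), classifies the budget by k-SE interval disjointness, and
#' computes the percent difference and the glacial share of inputs.
#'
#' @param components long data frame `species`, `year`, `compartment`
#'   (the three input compartments), `load`, `se`.
#' @param outflow data frame `species`, `year`, `load`, `se` for the
#'   outflow river (a `compartment` column, if present, is ignored).
#' @param k classification interval half-width in SEs.
#' @param se_method SE combination for input totals.
#' @return data frame, one row per species x year: `total_in`, `se_in`,
#'   `total_out`, `se_out`, `delta_storage`, `classification`,
#'   `percent_difference`, `glacial_share`.
#' @export
assemble_budget <- function(components, outflow, k = 1, se_method = "linear") {
  components <- components[components$compartment %in% input_compartments, ]
  keys <- unique(components[, c("species", "year")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sp <- keys$species[i]; yr <- keys$year[i]
    comp <- components[components$species == sp & components$year == yr, ]
    if (nrow(comp) != 3L) return(NULL)
    out <- outflow[outflow$species == sp & outflow$year == yr, ]
    if (nrow(out) != 1L) return(NULL)
    tot <- sum_inputs(comp, se_method)
    se_out <- ifelse(is.na(out$se), 0, out$se)
    data.frame(
      species = sp, year = yr,
      total_in = tot$load, se_in = tot$se,
      total_out = out$load, se_out = se_out,
      delta_storage = delta_storage(tot$load, out$load),
      classification = classify_budget(tot$load, tot$se, out$load, se_out, k),
      percent_difference = percent_difference(tot$load, out$load),
      glacial_share = glacial_share(comp))
  })
  do.call(rbind, rows)
}
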