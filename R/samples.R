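#' Water-sample tables
#'
#' A sample table is a long data frame of analyte observations, one row per
#' sample x species, with columns `compartment`, `site`, `date`, `depth_m`,
#' `species`, `value` (mg/L), `censored` (logical: value is a detection
#' bound, not a measurement) and `substituted` (logical: censored value has
#' been replaced by DL/2). The species registry travels with the table as an
#' attribute so detection limits are always resolvable.
#'
#' @param samples data frame with the columns above (`substituted` optional).
#' @param registry species registry; see [default_species_registry()].
#' @return the validated table, class `sample_table`.
#' @export
sample_table <- function(samples, registry = default_species_registry()) {
  need <- c("compartment", "site", "date", "species", "value", "censored")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (!"depth_m" %in% names(samples)) samples$depth_m <- NA_real_
  if (!"substituted" %in% names(samples)) samples$substituted <- FALSE
  bad <- setdiff(unique(samples$species), registry$name)
  if (length(bad)) stop("species not in registry: ", paste(bad, collapse = ", "))
  bad_comp <- setdiff(unique(samples$compartment), loac_compartments())
  if (length(bad_comp)) stop("unknown compartment: ", paste(bad_comp, collapse = ", "))
  if (any(!is.na(samples$depth_m) & samples$depth_m < 0))
    stop("depth_m must be >= 0 (positive down from the surface)")
  samples$date <- as.Date(samples$date)  # ISO-8601
  if (anyNA(samples$date)) stop("dates must parse as ISO-8601")
  samples$censored <- as.logical(samples$censored)
  samples$substituted <- as.logical(samples$substituted)
  structure(samples[, c("compartment", "site", "date", "depth_m", "species",
                        "value", "censored", "substituted")],
            registry = registry,
            class = c("sample_table", "data.frame"))
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", nrow(x), " observations, ",
      length(unique(x$species)), " species, ",
      length(unique(x$compartment)), " compartments\n", sep = "")
  NextMethod()
}

registry_of <- function(table) {
  attr(table, "registry") %||% default_species_registry()
}

#' Read a samples CSV
#'
#' Expected columns: `compartment,site,date,depth_m,species,value,units,censored`.
#' Values with `units = "ug/L"` are rescaled to mg/L. The reader is lenient
#' about censoring: a `value` written as `"<0.007"` is parsed as a censored
#' observation at that bound even when the `censored` column is absent.
#'
#' @param path CSV file.
#' @param registry species registry.
#' @return a [sample_table()].
#' @export
read_samples <- function(path, registry = default_species_registry()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  val <- raw$value
  lt <- grepl("^\\s*<", val)
  val <- as.numeric(sub("^\\s*<\\s*", "", val))
  censored <- if ("censored" %in% names(raw))
    tolower(raw$censored) %in% c("true", "t", "1", "yes") | lt else lt
  units <- if ("units" %in% names(raw)) raw$units else "mg/L"
  scale <- ifelse(grepl("ug|µg", units), 1e-3, 1)
  substituted <- if ("substituted" %in% names(raw))
    tolower(raw$substituted) %in% c("true", "t", "1", "yes") else FALSE
  sample_table(data.frame(
    compartment = raw$compartment, site = raw$site, date = raw$date,
    depth_m = if ("depth_m" %in% names(raw)) as.numeric(raw$depth_m) else NA_real_,
    species = raw$species, value = val * scale,
    censored = censored, substituted = substituted,
    stringsAsFactors = FALSE), registry)
}

#' Write a samples CSV
#'
#' Values are serialized at full double precision (`%.17g`) with an explicit
#' `censored` flag column, so write-then-read round-trips bit-identically.
#'
#' @param table a [sample_table()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  out <- as.data.frame(table)
  out$units <- "mg/L"
  out$value <- sprintf("%.17g", out$value)
  out$date <- format(out$date, "%Y-%m-%d")
  out <- out[, c("compartment", "site", "date", "depth_m", "species",
                 "value", "units", "censored", "substituted")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Substitute half the detection limit for censored values
#'
#' Observations below the method detection limit are quantified as half the
#' detection limit and flagged `substituted`. Uncensored rows are untouched,
#' and the operation is idempotent (re-applying never halves again).
#'
#' @param table a [sample_table()].
#' @return the table with censored values replaced by DL/2.
#' @export
apply_detection_limits <- function(table) {
  registry <- registry_of(table)
  idx <- which(table$censored)
  if (length(idx)) {
    dl <- registry$detection_limit[match(table$species[idx], registry$name)]
    no_dl <- unique(table$species[idx][is.na(dl)])
    if (length(no_dl))
      stop("censored values with no registered detection limit for: ",
           paste(no_dl, collapse = ", "))
    table$value[idx] <- dl / 2
    table$substituted[idx] <- TRUE
  }
  table
}

#' Concentration x volume to a mass load
#'
#' 1 km^3 of water at 1 mg/L carries exactly 1000 metric tons.
#'
#' @param concentration mg/L (vectorized).
#' @param volume km^3 (vectorized).
#' @return load in metric tons.
#' @export
convert_load <- function(concentration, volume) {
  if (any(concentration < 0, na.rm = TRUE) || any(volume < 0, na.rm = TRUE))
    stop("concentration and volume must be non-negative")
  concentration * volume * 1000
}

#' Add composite species rows (DIN, TC) to a sample table
#'
#' DIN = NH4 + NO3NO2; TC = DIC + DOC + PC. A composite row is added for a
#' sample only when all of its constituents were measured there.
#'
#' @param table a [sample_table()].
#' @return the table with `DIN` and `TC` rows appended where computable.
#' @export
add_composite_species <- function(table) {
  registry <- registry_of(table)
  for (comp in list(list(name = "DIN", parts = c("NH4", "NO3NO2"), phase = "dissolved"),
                    list(name = "TC", parts = c("DIC", "DOC", "PC"), phase = "bulk"))) {
    sub <- table[table$species %in% comp$parts, , drop = FALSE]
    if (!nrow(sub)) next
    key <- paste(sub$compartment, sub$site, sub$date, sub$depth_m, sep = "\r")
    done <- tapply(seq_len(nrow(sub)), key, function(i) {
      if (length(unique(sub$species[i])) == length(comp$parts)) i[1] else NA_integer_
    })
    sums <- tapply(sub$value, key, sum)
    keep <- !is.na(done)
    if (!any(keep)) next
    first <- sub[done[keep], c("compartment", "site", "date", "depth_m")]
    newrows <- data.frame(first, species = comp$name, value = as.numeric(sums[keep]),
                          censored = FALSE, substituted = FALSE)
    if (!comp$name %in% registry$name)
      registry <- rbind(registry, chem_species(comp$name, comp$phase))
    table <- sample_table(rbind(as.data.frame(table), newrows), registry)
  }
  table
}
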