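inputs_for <- function(tab, sp, yr) {
  tab[tab$species == sp & tab$year == yr &
        tab$compartment %in% c("snow_on_lake", "snow_from_land",
                               "glacial_rivers"), ]
}

test_that("input sums reproduce the published totals", {
  tab <- hazen_budget_components()
  nh4 <- sum_inputs(inputs_for(tab, "NH4", 2015))
  expect_equal(signif(nh4$load, 3), 25.2)
  expect_equal(signif(nh4$se, 3), 16.5)   # 0.115 + 0.454 + 15.9, linear
  water <- sum_inputs(inputs_for(tab, "water", 2015))
  expect_equal(signif(water$load, 3), 1.07)
  zeros <- data.frame(species = "x", year = 1,
                      compartment = c("snow_on_lake", "snow_from_land",
                                      "glacial_rivers"),
                      load = 0, se = 0)
  expect_equal(sum_inputs(zeros), list(load = 0, se = 0))
})

test_that("every published species-year is internally consistent", {
  tab <- hazen_budget_components()
  keys <- unique(tab[tab$compartment == "total_inputs", c("species", "year")])
  for (i in seq_len(nrow(keys))) {
    comp <- inputs_for(tab, keys$species[i], keys$year[i])
    tot <- tab[tab$species == keys$species[i] & tab$year == keys$year[i] &
                 tab$compartment == "total_inputs", ]
    s <- sum_inputs(comp)
    tol_load <- sum(half_unit_3sf(comp$load)) + half_unit_3sf(tot$load)
    expect_lte(abs(s$load - tot$load), tol_load)
    if (!is.na(tot$se)) {
      se_known <- comp$se[!is.na(comp$se)]
      tol_se <- sum(half_unit_3sf(se_known)) + half_unit_3sf(tot$se)
      expect_lte(abs(s$se - tot$se), tol_se)
    }
  }
})

test_that("storage change is outputs minus inputs", {
  expect_equal(round(delta_storage(25.2, 3.79), 1), -21.4)
  expect_equal(delta_storage(6550, 9700), 3150)
  expect_equal(delta_storage(7, 7), 0)
})

test_that("sum_inputs rejects malformed component sets", {
  tab <- hazen_budget_components()
  mixed <- rbind(inputs_for(tab, "NH4", 2015)[1:2, ],
                 inputs_for(tab, "NH4", 2016)[3, ])
  expect_error(sum_inputs(mixed), "mix")
  two <- inputs_for(tab, "NH4", 2015)[1:2, ]
  expect_error(sum_inputs(two), "three input compartments")
})

test_that("interval-disjointness classification matches the published budgets", {
  tab <- hazen_budget_components()
  cls <- function(sp, yr) {
    tin <- tab[tab$species == sp & tab$year == yr &
                 tab$compartment == "total_inputs", ]
    out <- tab[tab$species == sp & tab$year == yr &
                 tab$compartment == "outflow", ]
    classify_budget(tin$load, tin$se, out$load, out$se, k = 1)
  }
  # hand interval arithmetic on the printed cells
  expect_equal(cls("NH4", 2015), "sink")      # [8.7,41.7] vs [2.41,5.17]
  expect_equal(cls("NH4", 2016), "sink")
  expect_equal(cls("NO3NO2", 2015), "sink")
  expect_equal(cls("NO3NO2", 2016), "sink")
  expect_equal(cls("DIC", 2015), "source")    # [6055,7045] vs [7230,12170]
  expect_equal(cls("DOC", 2015), "sink")
  expect_equal(cls("dSiO2", 2015), "neutral") # intervals overlap
  expect_equal(cls("dSiO2", 2016), "neutral")
  # cells where the 1-SE rule and the published stars disagree; the rule's
  # arithmetic is asserted (known discrepancies of the published criterion)
  expect_equal(cls("DIC", 2016), "neutral")   # [1988,2252] vs [2145,3615] overlap
  expect_equal(cls("SO4", 2016), "sink")      # [3941,5139] vs [2362,3218] disjoint
  expect_equal(cls("SO4", 2015), "sink")
  expect_equal(cls("DOC", 2016), "sink")
})

test_that("classification is symmetric under input-output exchange", {
  set.seed(2)
  for (i in 1:50) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    sa <- runif(1, 0, 30); sb <- runif(1, 0, 30)
    fwd <- classify_budget(a, sa, b, sb)
    rev <- classify_budget(b, sb, a, sa)
    expect_equal(fwd == "neutral", rev == "neutral")
    if (fwd == "sink") expect_equal(rev, "source")
    if (fwd == "source") expect_equal(rev, "sink")
  }
  expect_error(classify_budget(1, -1, 2, 1), "negative")
})

test_that("glacial shares span the published 62-98% range", {
  tab <- hazen_budget_components()
  expect_equal(signif(glacial_share(inputs_for(tab, "DOC", 2015)), 3), 98.1)
  expect_equal(signif(glacial_share(inputs_for(tab, "NO3NO2", 2016)), 3), 62.5)
  budgets <- assemble_budget(tab[tab$species != "water", ],
                             tab[tab$compartment == "outflow" &
                                   tab$species != "water", ])
  rng <- share_range(budgets)
  expect_equal(signif(unname(rng), 3), c(62.5, 98.1))
  one <- budgets[1, ]
  expect_equal(unname(share_range(one)["min"]), unname(share_range(one)["max"]))
  # species filter excludes requested species
  expect_gt(share_range(budgets, species = "DOC")["min"], 85)
})

test_that("glacial share handles degenerate inputs", {
  comp <- data.frame(species = "x", year = 1,
                     compartment = c("snow_on_lake", "snow_from_land",
                                     "glacial_rivers"),
                     load = c(0, 0, 5), se = 0)
  expect_equal(glacial_share(comp), 100)
  comp$load <- 0
  expect_warning(expect_true(is.na(glacial_share(comp))), "undefined")
})

test_that("outflow discharge is the sum of the modelled inflows", {
  expect_equal(round(as.numeric(outflow_discharge(0.948, 0.069, 0.055)), 2), 1.07)
  expect_equal(round(as.numeric(outflow_discharge(0.281, 0.060, 0.059)), 3), 0.400)
  expect_equal(as.numeric(outflow_discharge(0, 0, 0)), 0)
  expect_equal(attr(outflow_discharge(1, 0, 0), "assumes"), "no evaporation")
})

test_that("assembled budgets carry consistent derived columns", {
  tab <- hazen_budget_components()
  budgets <- assemble_budget(tab, tab[tab$compartment == "outflow", ])
  expect_equal(budgets$delta_storage,
               budgets$total_out - budgets$total_in)
  sinks <- budgets$classification == "sink"
  expect_true(all(budgets$delta_storage[sinks] < 0))
  sources <- budgets$classification == "source"
  expect_true(all(budgets$delta_storage[sources] > 0))
  expect_equal(budgets$percent_difference,
               100 * budgets$delta_storage / budgets$total_in)
  # TDP lacks river and outflow loads and must be dropped, not guessed
  expect_false("TDP" %in% budgets$species)
})

test_that("a conservative tracer with identical concentrations closes to zero", {
  conc <- 8.5
  vols <- c(snow_on_lake = 0.07, snow_from_land = 0.06, glacial_rivers = 0.9)
  comp <- data.frame(species = "cons", year = 2015,
                     compartment = names(vols),
                     load = convert_load(conc, vols), se = 1)
  outflow <- data.frame(species = "cons", year = 2015,
                        load = convert_load(conc, sum(vols)), se = 1)
  b <- assemble_budget(comp, outflow)
  expect_equal(b$delta_storage, 0, tolerance = 1e-10)
  expect_equal(b$classification, "neutral")
})
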