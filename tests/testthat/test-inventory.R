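test_that("province-to-region mapping is closed-world", {
  expect_equal(region_of_province("Henan"), "CC")
  expect_equal(region_of_province("Xinjiang"), "NC")
  expect_equal(region_of_province(c("Anhui", "Gansu")), c("SC", "NC"))
  expect_error(region_of_province("Hunan"), "unmapped_province")
  # the three province lists are disjoint
  provs <- unlist(wheat_regions())
  expect_equal(anyDuplicated(provs), 0L)
})

test_that("city straw totals use the documented unit chain", {
  expect_equal(total_straw_yield(4000, 100), 40)       # 1e4 t
  expect_equal(total_straw_yield(5000, 0), 0)
  expect_equal(total_straw_yield(1, 10), 0.001)
  expect_true(is.na(total_straw_yield(NA_real_, 10)))
})

test_that("disposal partition conserves mass", {
  p <- partition_disposal(40, disposal_shares(0.5, 0.3, 0.2))
  expect_equal(unname(p), c(20, 12, 8))
  expect_equal(unname(partition_disposal(40, disposal_shares(1, 0, 0))),
               c(40, 0, 0))
  expect_equal(unname(partition_disposal(0, global_shares())), c(0, 0, 0))
  expect_error(disposal_shares(0.5, 0.3, 0.1), "invalid_shares")
  expect_error(disposal_shares(-0.1, 0.6, 0.5), "invalid_shares")
  # property: components always sum to total
  sh <- generate_disposal_shares(13, 50)
  totals <- exp(stats::runif(50, 0, 10))
  for (i in seq_len(50)) {
    s <- disposal_shares(sh$p_recycle[i], sh$p_burn[i], sh$p_remove[i])
    expect_equal(sum(partition_disposal(totals[i], s)), totals[i],
                 tolerance = 1e-9)
  }
})

test_that("nutrient supply applies regional fractions to recycled+burned mass", {
  ns <- nutrient_supply(60, 40, "NC")
  expect_equal(unname(ns), c(0.49, 0.032, 1.801))
  expect_equal(unname(nutrient_supply(500, 500, "CC"))[1], 5.2)
  expect_equal(unname(nutrient_supply(0, 0, "SC")), c(0, 0, 0))
  expect_error(nutrient_supply(1, 1, "ZZ"), "invalid_region")
  # the alternative published coefficient set scales P and K up tenfold
  alt <- nutrient_supply(60, 40, "NC", nutrient_coefficients("eq3text"))
  expect_equal(unname(alt), c(0.49, 0.32, 18.01))
})

test_that("burning emissions follow the emission factors with exact ratios", {
  e <- burning_emissions(1000)
  expect_equal(e[["NOx"]], 3.3)
  expect_equal(unname(burning_emissions(0)), rep(0, 6))
  for (mass in c(1, 123.4, 1e6)) {
    e <- burning_emissions(mass)
    expect_equal(e[["CH4"]] / e[["CO2"]], 3.4 / 1460, tolerance = 1e-14)
    expect_equal(e[["NOx"]] / e[["SO2"]], 3.3 / 0.85, tolerance = 1e-14)
  }
})

test_that("run_inventory matches the hand-composed single-city chain", {
  models <- list(CC = structure(list(region = "CC", a = 3000, b = 1.1e-4),
                                class = "straw_yield_model"))
  city <- data.frame(city_id = "x", province = "Shandong", year = 2013,
                     area_1000ha = 80, grain_yield_kg_ha = 6000)
  inv <- run_inventory(city, global_shares(), models)
  # hand-composed chain
  py <- 3000 * exp(1.1e-4 * 6000)
  total <- py * 80 * 1e-4
  parts <- total * c(0.55, 0.20, 0.25)
  expect_equal(inv$straw_yield_kg_ha, py)
  expect_equal(inv$straw_total_1e4t, total)
  expect_equal(inv$recycled_1e4t, parts[1])
  expect_equal(inv$burned_1e4t, parts[2])
  expect_equal(inv$removed_1e4t, parts[3])
  returned_t <- (parts[1] + parts[2]) * 1e4
  expect_equal(inv$n_supply_t, returned_t * 0.0052)
  expect_equal(inv$k_supply_t, returned_t * 0.01809)
  expect_equal(inv$CO2_t, parts[2] * 1e4 * 1.46)
  expect_equal(inv$NH3_t, parts[2] * 1e4 * 0.37 / 1000)
})

test_that("run_inventory enforces keys, models and missing/zero semantics", {
  models <- fitted_models()
  cities <- mixed_city_table()
  inv <- run_inventory(cities, global_shares(), models)

  # missing row stays missing everywhere
  mrow <- inv[inv$status == "missing", ]
  expect_equal(nrow(mrow), 1)
  expect_true(all(is.na(mrow[, c("straw_total_1e4t", "recycled_1e4t",
                                 "n_supply_t", "CO2_t")])))
  # zero row stays zero everywhere
  zrow <- inv[inv$status == "zero", ]
  expect_true(all(zrow[, c("straw_total_1e4t", "burned_1e4t", "k_supply_t",
                           "CH4_t")] == 0))
  # mass conservation on every non-missing row
  keep <- inv[inv$status != "missing", ]
  expect_equal(keep$recycled_1e4t + keep$burned_1e4t + keep$removed_1e4t,
               keep$straw_total_1e4t, tolerance = 1e-9)

  dup <- rbind(cities, cities[1, ])
  expect_error(run_inventory(dup, global_shares(), models),
               "duplicate_city_year")
  expect_error(run_inventory(cities, global_shares(), models["NC"]),
               "missing_model")
  bad <- cities
  bad$province[1] <- "Hunan"
  expect_error(run_inventory(bad, global_shares(), models),
               "unmapped_province")
})

test_that("inventory scales linearly with area and aggregates consistently", {
  models <- fitted_models()
  cfg <- synthetic_config(seed = 6, n_cities_per_region = 5)
  cities <- generate_city_table(cfg)
  inv1 <- run_inventory(cities, global_shares(), models)
  scaled <- cities
  scaled$area_1000ha <- scaled$area_1000ha * 3
  inv3 <- run_inventory(scaled, global_shares(), models)
  qty <- c("straw_total_1e4t", "recycled_1e4t", "burned_1e4t",
           "removed_1e4t", "n_supply_t", "p_supply_t", "k_supply_t",
           "PM2_5_t", "SO2_t", "NOx_t", "NH3_t", "CH4_t", "CO2_t")
  for (q in qty) expect_equal(inv3[[q]], 3 * inv1[[q]])

  # national total == sum over regions == sum over cities
  nat <- aggregate_inventory(inv1, "national")
  reg <- aggregate_inventory(inv1, "region")
  keep <- inv1[inv1$status != "missing", ]
  for (q in qty) {
    expect_equal(nat[[q]], sum(reg[[q]]))
    expect_equal(nat[[q]], sum(keep[[q]]))
  }

  # all-missing input yields missing aggregates
  allmiss <- cities
  allmiss$area_1000ha <- NA_real_
  allmiss$grain_yield_kg_ha <- NA_real_
  allmiss$status <- NULL
  invm <- run_inventory(allmiss, global_shares(), models)
  expect_true(all(is.na(invm$straw_total_1e4t)))
  expect_true(is.na(aggregate_inventory(invm, "national")$straw_total_1e4t))
})

test_that("disposal-share precedence is city over region over global", {
  models <- fitted_models()
  cities <- data.frame(
    city_id = c("special", "plain_cc", "plain_nc"),
    province = c("Henan", "Shandong", "Gansu"),
    year = 2011,
    area_1000ha = c(10, 10, 10),
    grain_yield_kg_ha = c(5000, 5000, 5000)
  )
  shares <- data.frame(
    scope = c(NA, NA, "all"),
    city_id = c("special", NA, NA),
    region = c(NA, "CC", NA),
    p_recycle = c(1, 0.5, 0.2),
    p_burn = c(0, 0.3, 0.4),
    p_remove = c(0, 0.2, 0.4)
  )
  inv <- run_inventory(cities, shares, models)
  get <- function(id) inv[inv$city_id == id, ]
  expect_equal(get("special")$burned_1e4t, 0)          # city-specific
  expect_equal(get("special")$recycled_1e4t,
               get("special")$straw_total_1e4t)
  expect_equal(get("plain_cc")$burned_1e4t,
               0.3 * get("plain_cc")$straw_total_1e4t) # region-level
  expect_equal(get("plain_nc")$burned_1e4t,
               0.4 * get("plain_nc")$straw_total_1e4t) # global fallback
})
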