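test_that("coefficient draws honour CV, seed and truncation", {
  cfg <- mc_config(n_draws = 100, seed = 3)
  # CV = 0: every draw equals the point estimate
  d0 <- draw_coefficients(nutrient_coefficients(cv = 0),
                          emission_factors(cv = 0), cfg)
  expect_true(all(apply(d0$nc, 2, stats::sd) == 0))
  expect_equal(unname(d0$ef[1, ]), emission_factors()$ef_g_per_kg)
  # reproducibility
  expect_identical(draw_coefficients(cfg = cfg), draw_coefficients(cfg = cfg))
  # realised CV close to nominal at large n
  dn <- draw_coefficients(nutrient_coefficients(cv = 0.1),
                          emission_factors(cv = 0.1),
                          mc_config(n_draws = 10000, seed = 8))
  realised <- apply(dn$ef, 2, stats::sd) / apply(dn$ef, 2, mean)
  expect_true(all(realised > 0.095 & realised < 0.105))
  # clamp truncation never yields negatives even at extreme CV
  wild <- draw_coefficients(nutrient_coefficients(cv = 5),
                            emission_factors(cv = 5),
                            mc_config(100, 1, truncation = "clamp"))
  expect_true(all(wild$nc >= 0) && all(wild$ef >= 0))
  resam <- draw_coefficients(nutrient_coefficients(cv = 5),
                             emission_factors(cv = 5),
                             mc_config(100, 1, truncation = "resample"))
  expect_true(all(resam$nc >= 0) && all(resam$ef >= 0))
})

test_that("zero CV collapses the Monte-Carlo onto the deterministic inventory", {
  models <- fitted_models()
  cities <- generate_city_table(synthetic_config(seed = 14,
                                                 n_cities_per_region = 4))
  coeffs <- nutrient_coefficients(cv = 0)
  efs <- emission_factors(cv = 0)
  det <- aggregate_inventory(
    run_inventory(cities, global_shares(), models, coeffs, efs), "national")
  u <- propagate_uncertainty(cities, global_shares(), models, coeffs, efs,
                             mc_config(50, 2))
  for (i in seq_len(nrow(u))) {
    q <- u$quantity[i]
    expect_equal(u$mean[i], det[[q]], tolerance = 1e-12)
    expect_equal(u$p5[i], det[[q]], tolerance = 1e-12)
    expect_equal(u$p95[i], det[[q]], tolerance = 1e-12)
    expect_equal(u$sd[i], 0)
  }
})

test_that("Monte-Carlo summaries match the linear closed form", {
  # the emission step is linear in the EF, so for burned mass m (tons):
  # q = m * EF/1000, mean(q) = m*mu/1000, sd(q) = m*mu*cv/1000
  models <- list(CC = structure(list(region = "CC", a = 3000, b = 1.1e-4),
                                class = "straw_yield_model"))
  city <- data.frame(city_id = "x", province = "Henan", year = 2012,
                     area_1000ha = 50, grain_yield_kg_ha = 6000)
  n <- 1000
  u <- propagate_uncertainty(city, global_shares(), models,
                             nutrient_coefficients(cv = 0.1),
                             emission_factors(cv = 0.1),
                             mc_config(n, 31))
  inv <- run_inventory(city, global_shares(), models)
  m_burn <- inv$burned_1e4t * 1e4
  for (p in c("CO2_t", "SO2_t")) {
    mu_q <- m_burn * emission_factors()$ef_g_per_kg[
      paste0(gsub("\\.", "_", emission_factors()$pollutant), "_t") == p] / 1000
    sd_q <- 0.1 * mu_q
    row <- u[u$quantity == p, ]
    expect_lt(abs(row$mean - mu_q), 3 * sd_q / sqrt(n))
    expect_lt(abs(row$sd - sd_q), 3 * sd_q / sqrt(2 * n))
    expect_true(row$p5 <= row$p95)
  }
})

test_that("summaries are reproducible and widen with CV", {
  models <- fitted_models()
  cities <- generate_city_table(synthetic_config(seed = 17,
                                                 n_cities_per_region = 3))
  cfg <- mc_config(500, 9)
  u1 <- propagate_uncertainty(cities, global_shares(), models, cfg = cfg)
  u2 <- propagate_uncertainty(cities, global_shares(), models, cfg = cfg)
  expect_identical(u1, u2)
  expect_true(all(u1$p5 <= u1$p95))
  expect_true(all(u1$sd >= 0))
  # doubling the CV (same seed) does not shrink the 5-95 band
  wide <- propagate_uncertainty(cities, global_shares(), models,
                                nutrient_coefficients(cv = 0.2),
                                emission_factors(cv = 0.2), cfg = cfg)
  expect_true(all(wide$p95 - wide$p5 >= (u1$p95 - u1$p5) * 0.99))
  # regional totals sum to the national total in the mean
  ureg <- propagate_uncertainty(cities, global_shares(), models, cfg = cfg,
                                by = "region")
  for (q in unique(u1$quantity)) {
    expect_equal(sum(ureg$mean[ureg$quantity == q]),
                 u1$mean[u1$quantity == q], tolerance = 1e-9)
  }
})

test_that("QQ normality diagnostic separates normal from heavy-tailed samples", {
  norm_s <- local({
    set.seed(42)
    stats::rnorm(1000)
  })
  res <- normality_check(norm_s)
  expect_gt(res$correlation, 0.99)
  expect_true(res$pass)
  cauchy_s <- local({
    set.seed(42)
    stats::rcauchy(1000)
  })
  res_c <- normality_check(cauchy_s)
  expect_lt(res_c$correlation, res$correlation)
  expect_false(res_c$pass)
  expect_error(normality_check(rep(1, 100)), "degenerate_samples")
  expect_error(normality_check(stats::rnorm(5)), "too_few_samples")
})
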