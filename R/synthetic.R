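# Seed hygiene: every generator scopes its RNG use so that library code never
# perturbs the caller's random stream, and identical seeds give identical tables.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the synthetic field-experiment and city-activity
#' generators in one validated object. The defaults describe the study
#' conditions the pipeline is designed for: grain yields spanning roughly
#' 1000--9000 kg per hectare, an exponential straw--grain relationship with
#' region-specific parameters, multiplicative log-normal noise, and
#' city-year activity tables for 2011--2015 that include both zero-acreage
#' municipal districts and missing records.
#'
#' @param seed Integer seed; the same seed always yields byte-identical
#'   tables.
#' @param n_obs_per_region Number of field observations generated per region.
#' @param grain_range Length-2 numeric, min and max grain yield (kg/ha).
#' @param true_params Named list mapping region code to \code{c(a =, b =)}
#'   of the generating exponential \code{straw = a * exp(b * grain)};
#'   \code{a} in kg/ha, \code{b} in ha/kg.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise on straw yield (0 disables noise).
#' @param n_cities_per_region Cities generated per region.
#' @param years Integer vector of calendar years.
#' @param area_range Length-2 numeric, min and max planting acreage in
#'   units of 1000 ha.
#' @param na_fraction Fraction of city-year rows emitted as missing
#'   (\code{NA} activity data).
#' @param zero_fraction Fraction of city-year rows emitted as zero-acreage
#'   (wheat-free municipal districts).
#' @param grain_sampler \code{"uniform"} (default) or \code{"truncnorm"}
#'   (normal centred on the middle of \code{grain_range} with SD a quarter of
#'   its width, truncated to the range by resampling).
#' @return A validated list of class \code{synthetic_config}.
#' @examples
#' cfg <- synthetic_config(seed = 1, n_obs_per_region = 50)
#' @export
synthetic_config <- function(seed = 1L,
                             n_obs_per_region = 500L,
                             grain_range = c(1000, 9000),
                             true_params = list(
                               NC = c(a = 2600, b = 1.2e-4),
                               CC = c(a = 3000, b = 1.1e-4),
                               SC = c(a = 2800, b = 1.15e-4)
                             ),
                             noise_cv = 0.1,
                             n_cities_per_region = 10L,
                             years = 2011:2015,
                             area_range = c(5, 300),
                             na_fraction = 0.05,
                             zero_fraction = 0.05,
                             grain_sampler = c("uniform", "truncnorm")) {
  grain_sampler <- match.arg(grain_sampler)
  cfg <- list(
    seed = as.integer(seed),
    n_obs_per_region = as.integer(n_obs_per_region),
    grain_range = as.numeric(grain_range),
    true_params = true_params,
    noise_cv = as.numeric(noise_cv),
    n_cities_per_region = as.integer(n_cities_per_region),
    years = as.integer(years),
    area_range = as.numeric(area_range),
    na_fraction = as.numeric(na_fraction),
    zero_fraction = as.numeric(zero_fraction),
    grain_sampler = grain_sampler
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_obs_per_region < 1L) {
    stop("invalid_config: n_obs_per_region must be >= 1", call. = FALSE)
  }
  if (length(cfg$grain_range) != 2L || cfg$grain_range[1] <= 0 ||
      diff(cfg$grain_range) < 0) {
    stop("invalid_config: grain_range must be (min, max) with min > 0",
         call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("invalid_config: noise_cv must be >= 0", call. = FALSE)
  if (!all(region_codes() %in% names(cfg$true_params))) {
    stop("invalid_config: true_params must name every region", call. = FALSE)
  }
  for (r in region_codes()) {
    p <- cfg$true_params[[r]]
    if (!all(c("a", "b") %in% names(p)) || p[["a"]] <= 0) {
      stop("invalid_config: true_params[[", r, "]] needs a > 0 and b",
           call. = FALSE)
    }
  }
  if (cfg$na_fraction < 0 || cfg$zero_fraction < 0 ||
      cfg$na_fraction + cfg$zero_fraction >= 1) {
    stop("invalid_config: need na_fraction + zero_fraction < 1, both >= 0",
         call. = FALSE)
  }
  if (length(cfg$area_range) != 2L || cfg$area_range[1] <= 0 ||
      diff(cfg$area_range) < 0) {
    stop("invalid_config: area_range must be (min, max) with min > 0",
         call. = FALSE)
  }
  if (length(cfg$years) < 1L) stop("invalid_config: years empty", call. = FALSE)
  invisible(cfg)
}

sample_grain <- function(cfg, n) {
  lo <- cfg$grain_range[1]
  hi <- cfg$grain_range[2]
  if (cfg$grain_sampler == "uniform") {
    return(stats::runif(n, lo, hi))
  }
  mu <- (lo + hi) / 2
  sd <- (hi - lo) / 4
  out <- stats::rnorm(n, mu, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mu, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Generate synthetic field-experiment observations for one region
#'
#' Draws grain yields over the configured range and generates straw yields
#' from the regional exponential model \code{straw = a * exp(b * grain)}
#' with multiplicative log-normal noise of the configured coefficient of
#' variation (mean-one noise, so the conditional mean follows the model).
#' The harvest index is computed as \code{grain / (grain + straw)}.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @param region Region code (\code{"NC"}, \code{"CC"} or \code{"SC"}).
#' @return A \code{data.frame} with columns \code{region},
#'   \code{grain_yield_kg_ha}, \code{straw_yield_kg_ha},
#'   \code{harvest_index}.
#' @examples
#' obs <- generate_observations(synthetic_config(seed = 7), "CC")
#' @export
generate_observations <- function(cfg, region) {
  validate_synthetic_config(cfg)
  assert_region(region)
  p <- cfg$true_params[[region]]
  # region index decorrelates the per-region streams under one config seed
  seed <- cfg$seed + match(region, region_codes())
  with_seed(seed, {
    grain <- sample_grain(cfg, cfg$n_obs_per_region)
    straw_mean <- p[["a"]] * exp(p[["b"]] * grain)
    straw <- straw_mean * lognormal_noise(cfg$n_obs_per_region, cfg$noise_cv)
    data.frame(
      region = region,
      grain_yield_kg_ha = grain,
      straw_yield_kg_ha = straw,
      harvest_index = grain / (grain + straw),
      stringsAsFactors = FALSE
    )
  })
}

# mean-one multiplicative log-normal noise with coefficient of variation cv;
# positivity is automatic, so no truncation is needed
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic city-level activity table
#'
#' Emulates a statistical-yearbook extract: one row per city and year with
#' planting acreage (1000 ha) and grain yield per hectare (kg/ha). A
#' configurable fraction of city-years is emitted as missing (all activity
#' fields \code{NA}, status \code{"missing"}) and another fraction as
#' zero-acreage municipal districts (status \code{"zero"}). Provinces are
#' drawn from the three regional province lists.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return A \code{data.frame} with columns \code{city_id}, \code{province},
#'   \code{region}, \code{year}, \code{area_1000ha},
#'   \code{grain_yield_kg_ha}, \code{status}.
#' @examples
#' cities <- generate_city_table(synthetic_config(seed = 3))
#' @export
generate_city_table <- function(cfg) {
  validate_synthetic_config(cfg)
  regions <- wheat_regions()
  with_seed(cfg$seed + 101L, {
    rows <- list()
    for (r in region_codes()) {
      provs <- sample(regions[[r]], cfg$n_cities_per_region, replace = TRUE)
      for (ci in seq_len(cfg$n_cities_per_region)) {
        city_id <- sprintf("%s_city_%02d", r, ci)
        area <- stats::runif(1, cfg$area_range[1], cfg$area_range[2])
        for (yr in cfg$years) {
          grain <- stats::runif(1, cfg$grain_range[1], cfg$grain_range[2])
          # mild year-to-year area drift around the city's base acreage
          a_yr <- area * stats::runif(1, 0.9, 1.1)
          rows[[length(rows) + 1L]] <- data.frame(
            city_id = city_id, province = provs[ci], region = r,
            year = yr, area_1000ha = a_yr, grain_yield_kg_ha = grain,
            status = "ok", stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    n <- nrow(out)
    n_na <- round(cfg$na_fraction * n)
    n_zero <- round(cfg$zero_fraction * n)
    flagged <- sample.int(n, n_na + n_zero)
    if (n_na > 0L) {
      idx <- flagged[seq_len(n_na)]
      out$area_1000ha[idx] <- NA_real_
      out$grain_yield_kg_ha[idx] <- NA_real_
      out$status[idx] <- "missing"
    }
    if (n_zero > 0L) {
      idx <- flagged[n_na + seq_len(n_zero)]
      out$area_1000ha[idx] <- 0
      out$grain_yield_kg_ha[idx] <- 0
      out$status[idx] <- "zero"
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic disposal-share records
#'
#' Samples recycle/burn/remove share triples from a Dirichlet distribution
#' (constructed from independent gamma draws normalised to the simplex), so
#' every record sums to one exactly and every share lies in [0, 1].
#'
#' @param seed Integer seed.
#' @param n Number of records.
#' @param concentration Positive length-3 Dirichlet concentration
#'   (recycle, burn, remove).
#' @return A \code{data.frame} with columns \code{p_recycle}, \code{p_burn},
#'   \code{p_remove}.
#' @examples
#' generate_disposal_shares(1, 5, c(6, 2, 2))
#' @export
generate_disposal_shares <- function(seed, n, concentration = c(1, 1, 1)) {
  if (!is.numeric(concentration) || length(concentration) != 3L ||
      any(concentration <= 0)) {
    stop("invalid_concentration: need 3 positive entries", call. = FALSE)
  }
  stopifnot(n >= 1L)
  with_seed(seed, {
    g <- matrix(stats::rgamma(3L * n, shape = rep(concentration, each = n)),
                nrow = n)
    s <- g / rowSums(g)
    data.frame(p_recycle = s[, 1], p_burn = s[, 2], p_remove = s[, 3])
  })
}
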