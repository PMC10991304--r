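#' Monte-Carlo configuration
#'
#' @param n_draws Number of Monte-Carlo replicates (default 1000).
#' @param seed Integer seed.
#' @param truncation Handling of negative normal draws for physical
#'   (non-negative) coefficients: \code{"resample"} (default; redraw until
#'   non-negative) or \code{"clamp"} (set to 0).
#' @return A validated list of class \code{mc_config}.
#' @examples
#' mc_config(n_draws = 500, seed = 42)
#' @export
mc_config <- function(n_draws = 1000L, seed = 1L,
                      truncation = c("resample", "clamp")) {
  truncation <- match.arg(truncation)
  cfg <- list(n_draws = as.integer(n_draws), seed = as.integer(seed),
              truncation = truncation)
  if (cfg$n_draws < 2L) {
    stop("invalid_mc_config: n_draws must be >= 2", call. = FALSE)
  }
  class(cfg) <- "mc_config"
  cfg
}

rnorm_nonneg <- function(n, mean, sd, truncation) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  if (truncation == "clamp") {
    x[x < 0] <- 0
  } else {
    bad <- which(x < 0)
    while (length(bad) > 0L) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- which(x < 0)
    }
  }
  x
}

#' Draw perturbed coefficient sets
#'
#' Each nutrient fraction and emission factor is drawn independently from
#' \code{Normal(mean, mean * CV)}, with negative draws handled per the
#' truncation rule. Draws are reproducible under the config seed.
#'
#' @param coeffs A \code{\link{nutrient_coefficients}} table.
#' @param efs An \code{\link{emission_factors}} table.
#' @param cfg An \code{\link{mc_config}}.
#' @return A list with \code{nc} (array n_draws x coefficient rows) and
#'   \code{ef} (array n_draws x pollutants); column order matches the input
#'   tables.
#' @examples
#' d <- draw_coefficients(nutrient_coefficients(), emission_factors(),
#'                        mc_config(n_draws = 10, seed = 1))
#' @export
draw_coefficients <- function(coeffs = nutrient_coefficients(),
                              efs = emission_factors(),
                              cfg = mc_config()) {
  stopifnot(inherits(cfg, "mc_config"))
  with_seed(cfg$seed, {
    nc <- vapply(seq_len(nrow(coeffs)), function(i) {
      rnorm_nonneg(cfg$n_draws, coeffs$fraction[i],
                   coeffs$fraction[i] * coeffs$cv[i], cfg$truncation)
    }, numeric(cfg$n_draws))
    colnames(nc) <- paste(coeffs$region, coeffs$nutrient, sep = "_")
    ef <- vapply(seq_len(nrow(efs)), function(i) {
      rnorm_nonneg(cfg$n_draws, efs$ef_g_per_kg[i],
                   efs$ef_g_per_kg[i] * efs$cv[i], cfg$truncation)
    }, numeric(cfg$n_draws))
    colnames(ef) <- efs$pollutant
    list(nc = nc, ef = ef)
  })
}

summarize_draws <- function(x, quantity) {
  data.frame(
    quantity = quantity,
    mean = mean(x),
    sd = stats::sd(x),
    p5 = unname(stats::quantile(x, 0.05, type = 7)),
    p95 = unname(stats::quantile(x, 0.95, type = 7)),
    stringsAsFactors = FALSE
  )
}

#' Propagate coefficient uncertainty through the inventory
#'
#' Holds the activity data (areas, yields, disposal shares) fixed at their
#' deterministic values and re-applies the nutrient and emission steps once
#' per Monte-Carlo draw of the coefficients, summarising every output
#' quantity by mean, SD, and 5th/95th percentiles (linear interpolation
#' between order statistics, i.e. \code{\link[stats]{quantile}} type 7).
#'
#' Because those steps are linear in the coefficients, only the regional
#' straw masses are needed per draw, which keeps 1000 replicates cheap.
#'
#' @param cities,shares,models,coeffs,efs As in \code{\link{run_inventory}}.
#' @param cfg An \code{\link{mc_config}}.
#' @param by \code{"national"} (default) or \code{"region"}: scope of the
#'   summarised totals.
#' @return A \code{data.frame} with columns \code{scope}, \code{quantity},
#'   \code{mean}, \code{sd}, \code{p5}, \code{p95}. Nutrient quantities in
#'   tons, emissions in tons.
#' @examples
#' # propagate_uncertainty(cities, shares, models, cfg = mc_config(seed = 9))
#' @export
propagate_uncertainty <- function(cities, shares, models,
                                  coeffs = nutrient_coefficients(),
                                  efs = emission_factors(),
                                  cfg = mc_config(),
                                  by = c("national", "region")) {
  by <- match.arg(by)
  inv <- run_inventory(cities, shares, models, coeffs, efs)
  keep <- inv[inv$status != "missing", , drop = FALSE]
  # fixed activity-side masses, tons, by region
  returned_t <- tapply((keep$recycled_1e4t + keep$burned_1e4t) * T_PER_1E4T,
                       factor(keep$region, levels = region_codes()), sum,
                       default = 0)
  burned_t <- tapply(keep$burned_1e4t * T_PER_1E4T,
                     factor(keep$region, levels = region_codes()), sum,
                     default = 0)
  returned_t[is.na(returned_t)] <- 0
  burned_t[is.na(burned_t)] <- 0

  draws <- draw_coefficients(coeffs, efs, cfg)
  scopes <- if (by == "national") "national" else region_codes()
  out <- list()
  for (sc in scopes) {
    w_ret <- returned_t
    w_burn <- burned_t
    if (sc != "national") {
      w_ret[region_codes() != sc] <- 0
      w_burn[region_codes() != sc] <- 0
    }
    for (nutr in c("n", "p", "k")) {
      cols <- paste(region_codes(), nutr, sep = "_")
      vals <- as.numeric(draws$nc[, cols] %*% w_ret)
      out[[length(out) + 1L]] <- cbind(scope = sc,
                                       summarize_draws(vals,
                                                       paste0(nutr,
                                                              "_supply_t")))
    }
    burn_total <- sum(w_burn)
    for (j in seq_len(ncol(draws$ef))) {
      vals <- draws$ef[, j] / 1000 * burn_total
      out[[length(out) + 1L]] <- cbind(
        scope = sc,
        summarize_draws(vals, paste0(gsub("\\.", "_",
                                          colnames(draws$ef)[j]), "_t")))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' QQ normality diagnostic
#'
#' Correlation between the sorted sample and the theoretical normal
#' quantiles at \code{ppoints(n)} positions -- the numeric analogue of
#' eyeballing a QQ-plot for straightness. Values near 1 indicate
#' approximate normality; heavy tails pull the correlation down.
#'
#' @param samples Numeric vector, at least 10 non-missing values with
#'   positive variance.
#' @param threshold Pass threshold on the correlation (default 0.99).
#' @return A list with \code{correlation}, \code{pass}, \code{n}.
#' @examples
#' normality_check(rnorm(100))
#' @export
normality_check <- function(samples, threshold = 0.99) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L) {
    stop("too_few_samples: need >= 10 finite samples", call. = FALSE)
  }
  if (stats::sd(samples) == 0) {
    stop("degenerate_samples: zero variance", call. = FALSE)
  }
  r <- stats::cor(sort(samples), stats::qnorm(stats::ppoints(length(samples))))
  list(correlation = r, pass = r >= threshold, n = length(samples))
}
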