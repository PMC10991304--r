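# Unit conventions, centralized:
#   activity area        : 1000 ha
#   per-hectare yields   : kg/ha
#   city straw amounts   : 1e4 tons   (kg/ha * 1000 ha = 1 t, then / 1e4)
#   nutrient supplies    : tons
#   pollutant emissions  : tons       (g/kg == kg/t, so tons = t * ef / 1000)
KG_PER_HA_X_1000HA_TO_1E4T <- 1e-4
T_PER_1E4T <- 1e4

#' City total straw yield
#'
#' Scales straw yield per hectare to the city total:
#' \code{kg/ha * (1000 ha) = tons}, reported in units of 1e4 tons.
#' Vectorised; \code{NA} inputs propagate.
#'
#' @param straw_yield_per_ha Straw yield, kg/ha.
#' @param area_1000ha Planting acreage, 1000 ha.
#' @return Total straw yield in 1e4 tons.
#' @examples
#' total_straw_yield(4000, 100) # 40 (1e4 t)
#' @export
total_straw_yield <- function(straw_yield_per_ha, area_1000ha) {
  stopifnot(all(straw_yield_per_ha >= 0, na.rm = TRUE),
            all(area_1000ha >= 0, na.rm = TRUE))
  straw_yield_per_ha * area_1000ha * KG_PER_HA_X_1000HA_TO_1E4T
}

#' Partition a straw total across field-management modes
#'
#' @param total Total straw, any mass unit (commonly 1e4 t).
#' @param shares A \code{\link{disposal_shares}} triple.
#' @return Named numeric \code{c(recycled =, burned =, removed =)} in the
#'   unit of \code{total}; components sum to \code{total}.
#' @examples
#' partition_disposal(40, disposal_shares(0.5, 0.3, 0.2))
#' @export
partition_disposal <- function(total, shares) {
  stopifnot(length(total) == 1L, is.na(total) || total >= 0)
  validate_shares(shares)
  out <- total * unclass(shares)
  names(out) <- c("recycled", "burned", "removed")
  out
}

nc_lookup <- function(coeffs, region, nutrient) {
  v <- coeffs$fraction[coeffs$region == region & coeffs$nutrient == nutrient]
  if (length(v) != 1L) {
    stop("unknown_region: no ", nutrient, " coefficient for region ", region,
         call. = FALSE)
  }
  v
}

#' Nutrient supply from recycled and burned straw
#'
#' Straw removed from the field contributes nothing; recycled and burned
#' straw return N, P and K in proportion to the regional straw nutrient
#' concentrations.
#'
#' @param recycled,burned Straw masses in tons.
#' @param region Region code.
#' @param coeffs A \code{\link{nutrient_coefficients}} table.
#' @return Named numeric \code{c(n =, p =, k =)} in tons.
#' @examples
#' nutrient_supply(60, 40, "NC", nutrient_coefficients())
#' @export
nutrient_supply <- function(recycled, burned, region,
                            coeffs = nutrient_coefficients()) {
  assert_region(region)
  stopifnot(recycled >= 0, burned >= 0)
  mass <- recycled + burned
  c(n = mass * nc_lookup(coeffs, region, "n"),
    p = mass * nc_lookup(coeffs, region, "p"),
    k = mass * nc_lookup(coeffs, region, "k"))
}

#' Gaseous-pollutant emissions from open straw burning
#'
#' \code{emission_k (t) = burned (t) * EF_k (g/kg) / 1000}, since
#' g/kg is numerically kg per ton.
#'
#' @param burned Burned straw mass in tons (scalar or vector).
#' @param efs An \code{\link{emission_factors}} table.
#' @return If \code{burned} is scalar, a named numeric of emissions (tons)
#'   per pollutant; otherwise a matrix with one row per element of
#'   \code{burned}.
#' @examples
#' burning_emissions(1000)
#' @export
burning_emissions <- function(burned, efs = emission_factors()) {
  stopifnot(all(burned >= 0, na.rm = TRUE))
  out <- outer(burned, efs$ef_g_per_kg / 1000)
  colnames(out) <- efs$pollutant
  if (length(burned) == 1L) out[1, ] else out
}

resolve_shares <- function(cities, shares) {
  if (inherits(shares, "disposal_shares")) {
    return(matrix(rep(unclass(shares), each = nrow(cities)), ncol = 3L,
                  dimnames = list(NULL, c("recycle", "burn", "remove"))))
  }
  stopifnot(is.data.frame(shares),
            all(c("p_recycle", "p_burn", "p_remove") %in% names(shares)))
  out <- matrix(NA_real_, nrow = nrow(cities), ncol = 3L,
                dimnames = list(NULL, c("recycle", "burn", "remove")))
  # precedence: city-specific > region-specific > global (scope == "all")
  pick <- function(keycol, keyval) {
    if (!keycol %in% names(shares)) return(NULL)
    hit <- which(shares[[keycol]] == keyval)
    if (length(hit) == 0L) return(NULL)
    as.numeric(shares[hit[1L], c("p_recycle", "p_burn", "p_remove")])
  }
  global <- if ("scope" %in% names(shares)) {
    hit <- which(shares$scope == "all")
    if (length(hit) > 0L)
      as.numeric(shares[hit[1L], c("p_recycle", "p_burn", "p_remove")])
    else NULL
  } else if (!any(c("city_id", "region") %in% names(shares))) {
    as.numeric(shares[1L, c("p_recycle", "p_burn", "p_remove")])
  } else NULL
  for (i in seq_len(nrow(cities))) {
    s <- pick("city_id", cities$city_id[i])
    if (is.null(s)) s <- pick("region", cities$region[i])
    if (is.null(s)) s <- global
    if (is.null(s)) {
      stop("missing_shares: no disposal shares resolvable for city ",
           cities$city_id[i], call. = FALSE)
    }
    validate_shares(s)
    out[i, ] <- s
  }
  out
}

#' Run the full city-level straw inventory
#'
#' Composes the four-step accounting chain for every city-year record:
#' straw yield per hectare from the regional exponential model, city total
#' straw, disposal partition, and nutrient supply plus burning emissions.
#' Missing records stay missing throughout (every output \code{NA});
#' zero-acreage records stay zero.
#'
#' @param cities City activity \code{data.frame} with columns
#'   \code{city_id}, \code{province}, \code{year}, \code{area_1000ha},
#'   \code{grain_yield_kg_ha}, optionally \code{region} and \code{status}
#'   (derived when absent). Duplicate (city_id, year) keys are rejected.
#' @param shares Either a single \code{\link{disposal_shares}} (global) or a
#'   \code{data.frame} with columns \code{p_recycle}, \code{p_burn},
#'   \code{p_remove} and optionally \code{city_id}, \code{region} and/or
#'   \code{scope == "all"}; precedence city > region > global.
#' @param models Named list of \code{straw_yield_model}s, one per region
#'   present among the ok-status cities.
#' @param coeffs A \code{\link{nutrient_coefficients}} table.
#' @param efs An \code{\link{emission_factors}} table.
#' @return A \code{data.frame} of class \code{inventory_result}, one row per
#'   city-year, with straw totals (1e4 t), disposal amounts (1e4 t),
#'   nutrient supplies (t) and six pollutant emission columns (t).
#' @examples
#' cfg <- synthetic_config(seed = 2, n_obs_per_region = 100,
#'                         n_cities_per_region = 3)
#' models <- lapply(setNames(nm = region_codes()), function(r)
#'   fit_straw_model(generate_observations(cfg, r), r))
#' inv <- run_inventory(generate_city_table(cfg),
#'                      disposal_shares(0.55, 0.2, 0.25), models)
#' @export
run_inventory <- function(cities, shares, models,
                          coeffs = nutrient_coefficients(),
                          efs = emission_factors()) {
  stopifnot(is.data.frame(cities),
            all(c("city_id", "province", "year", "area_1000ha",
                  "grain_yield_kg_ha") %in% names(cities)))
  if (anyDuplicated(cities[, c("city_id", "year")])) {
    dup <- cities[duplicated(cities[, c("city_id", "year")]),
                  c("city_id", "year")]
    stop("duplicate_city_year: duplicated keys: ",
         paste(paste(dup$city_id, dup$year, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  if (!"region" %in% names(cities)) {
    cities$region <- region_of_province(cities$province)
  }
  if (!"status" %in% names(cities)) {
    cities$status <- ifelse(
      is.na(cities$area_1000ha) | is.na(cities$grain_yield_kg_ha), "missing",
      ifelse(cities$area_1000ha == 0, "zero", "ok")
    )
  }
  ok <- cities$status == "ok"
  need <- unique(cities$region[ok])
  have <- names(models)[vapply(models, inherits, TRUE, "straw_yield_model")]
  if (!all(need %in% have)) {
    miss <- setdiff(need, have)
    bad <- cities$city_id[ok & cities$region %in% miss]
    stop("missing_model: no fitted model for region(s) ",
         paste(miss, collapse = ", "), "; affected cities: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  share_mat <- resolve_shares(cities, shares)

  n <- nrow(cities)
  straw_per_ha <- rep(NA_real_, n)
  for (r in unique(cities$region)) {
    idx <- which(cities$region == r & cities$status == "ok")
    if (length(idx) > 0L) {
      straw_per_ha[idx] <- predict_straw_yield(models[[r]],
                                               cities$grain_yield_kg_ha[idx])
    }
  }
  straw_per_ha[cities$status == "zero"] <- 0

  total_1e4t <- ifelse(cities$status == "missing", NA_real_,
                       total_straw_yield(ifelse(is.na(straw_per_ha), 0,
                                                straw_per_ha),
                                         ifelse(is.na(cities$area_1000ha), 0,
                                                cities$area_1000ha)))
  total_1e4t[cities$status == "missing"] <- NA_real_

  recycled <- total_1e4t * share_mat[, "recycle"]
  burned <- total_1e4t * share_mat[, "burn"]
  removed <- total_1e4t * share_mat[, "remove"]

  # nutrient fractions per region, vectorised over rows
  frac <- function(nutr) {
    vapply(cities$region, function(r) nc_lookup(coeffs, r, nutr), numeric(1))
  }
  returned_t <- (recycled + burned) * T_PER_1E4T
  n_t <- returned_t * frac("n")
  p_t <- returned_t * frac("p")
  k_t <- returned_t * frac("k")

  burned_t <- burned * T_PER_1E4T
  emis <- outer(burned_t, efs$ef_g_per_kg / 1000)
  colnames(emis) <- paste0(gsub("\\.", "_", efs$pollutant), "_t")

  out <- data.frame(
    city_id = cities$city_id,
    province = cities$province,
    region = cities$region,
    year = cities$year,
    status = cities$status,
    area_1000ha = cities$area_1000ha,
    grain_yield_kg_ha = cities$grain_yield_kg_ha,
    straw_yield_kg_ha = straw_per_ha,
    straw_total_1e4t = total_1e4t,
    recycled_1e4t = recycled,
    burned_1e4t = burned,
    removed_1e4t = removed,
    n_supply_t = n_t,
    p_supply_t = p_t,
    k_supply_t = k_t,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(emis))
  out <- out[order(out$province, out$city_id, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("inventory_result", "data.frame")
  out
}

#' Aggregate an inventory over cities
#'
#' Sums every mass quantity over non-missing records, nationally or by
#' region. Missing records are excluded; an all-missing input yields
#' \code{NA} totals.
#'
#' @param inv An \code{inventory_result} from \code{\link{run_inventory}}.
#' @param by \code{"national"} or \code{"region"}.
#' @return A \code{data.frame} of totals (same units as the inventory
#'   columns).
#' @examples
#' # aggregate_inventory(inv, "region")
#' @export
aggregate_inventory <- function(inv, by = c("national", "region")) {
  by <- match.arg(by)
  qty <- setdiff(names(inv), c("city_id", "province", "region", "year",
                               "status", "area_1000ha", "grain_yield_kg_ha",
                               "straw_yield_kg_ha"))
  keep <- inv[inv$status != "missing", , drop = FALSE]
  sum_block <- function(d) {
    if (nrow(d) == 0L) {
      as.data.frame(as.list(stats::setNames(rep(NA_real_, length(qty)), qty)))
    } else {
      as.data.frame(lapply(d[qty], sum))
    }
  }
  if (by == "national") {
    out <- sum_block(keep)
    cbind(data.frame(scope = "national", stringsAsFactors = FALSE), out)
  } else {
    blocks <- lapply(split(keep, factor(keep$region, levels = region_codes())),
                     sum_block)
    out <- do.call(rbind, blocks)
    cbind(data.frame(scope = region_codes(), stringsAsFactors = FALSE), out)
  }
}
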