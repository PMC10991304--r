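# CSV dialect used everywhere: comma separator, header row, UTF-8, "NA" as
# the missing token, "." decimal point.

read_strict_csv <- function(path) {
  if (!file.exists(path)) {
    stop("io_error: input file not found: ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  encoding = "UTF-8")
}

parse_numeric_col <- function(raw, col, path) {
  if (is.numeric(raw)) return(raw)
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(out))
  if (length(bad) > 0L) {
    stop("parse_error: non-numeric value in column '", col, "' of ", path,
         " at data row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a city activity table
#'
#' Parses a statistical-yearbook-style CSV of city-year activity records.
#' The literal token \code{NA} in the acreage or yield columns marks a city
#' without available data (status \code{"missing"}); a numeric 0 acreage
#' marks a wheat-free municipal district (status \code{"zero"}). Negative
#' acreage or yield is rejected with the offending row named. Provinces are
#' validated against the regional province lists.
#'
#' @param path CSV path with columns \code{city_id}, \code{province},
#'   \code{year}, \code{area_1000ha}, \code{grain_yield_kg_ha}.
#' @return A \code{data.frame} with those columns plus derived
#'   \code{region} and \code{status}.
#' @export
read_city_table <- function(path) {
  d <- read_strict_csv(path)
  need <- c("city_id", "province", "year", "area_1000ha",
            "grain_yield_kg_ha")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("parse_error: ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d$area_1000ha <- parse_numeric_col(d$area_1000ha, "area_1000ha", path)
  d$grain_yield_kg_ha <- parse_numeric_col(d$grain_yield_kg_ha,
                                           "grain_yield_kg_ha", path)
  d$year <- parse_numeric_col(d$year, "year", path)
  neg <- which(!is.na(d$area_1000ha) & d$area_1000ha < 0 |
                 !is.na(d$grain_yield_kg_ha) & d$grain_yield_kg_ha < 0)
  if (length(neg) > 0L) {
    stop("parse_error: negative acreage or yield in ", path,
         " at data row(s) ", paste(neg, collapse = ", "), call. = FALSE)
  }
  d$region <- region_of_province(d$province)
  d$status <- ifelse(is.na(d$area_1000ha) | is.na(d$grain_yield_kg_ha),
                     "missing",
                     ifelse(d$area_1000ha == 0, "zero", "ok"))
  d
}

#' Read a field-observation table
#'
#' @param path CSV with columns \code{region}, \code{grain_yield_kg_ha} and
#'   at least one of \code{straw_yield_kg_ha}, \code{harvest_index}.
#' @return Normalized observation \code{data.frame} (both straw yield and
#'   harvest index populated).
#' @export
read_observations <- function(path) {
  d <- read_strict_csv(path)
  bad <- setdiff(unique(d$region), region_codes())
  if (length(bad) > 0L) {
    stop("parse_error: unknown region code(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  normalize_observations(d)
}

#' Read a disposal-shares table
#'
#' @param path CSV with columns \code{p_recycle}, \code{p_burn},
#'   \code{p_remove}, optionally \code{scope}/\code{region}/\code{city_id}.
#' @return A \code{data.frame}; every row validated to sum to 1.
#' @export
read_shares_table <- function(path) {
  d <- read_strict_csv(path)
  need <- c("p_recycle", "p_burn", "p_remove")
  if (!all(need %in% names(d))) {
    stop("parse_error: ", path, " lacks share columns", call. = FALSE)
  }
  for (i in seq_len(nrow(d))) validate_shares(as.numeric(d[i, need]))
  d
}

write_csv_na <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = FALSE)
}

#' Write the five-sheet inventory output
#'
#' Writes the inventory as five CSV files mirroring the canonical
#' five-sheet workbook layout: \code{models_building.csv} (fitted regional
#' model parameters), \code{wheat_planting_situation.csv} (acreage, yields,
#' total straw), \code{straw_field_management.csv} (recycled / burned /
#' removed amounts), \code{nutrient_supplies.csv} (N, P, K in tons) and
#' \code{gaseous_pollutants.csv} (six pollutants in tons). Rows are ordered
#' by (province, city, year); missing records are written with the
#' \code{NA} token, wheat-free districts as numeric zeros. Column names
#' embed units.
#'
#' @param inv An \code{inventory_result}.
#' @param models Named list of fitted \code{straw_yield_model}s.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the five file paths.
#' @export
write_sheets <- function(inv, models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inv <- inv[order(inv$province, inv$city_id, inv$year), , drop = FALSE]
  key <- c("province", "city_id", "year")

  paths <- c(
    models_building = file.path(dir, "models_building.csv"),
    planting = file.path(dir, "wheat_planting_situation.csv"),
    management = file.path(dir, "straw_field_management.csv"),
    nutrients = file.path(dir, "nutrient_supplies.csv"),
    pollutants = file.path(dir, "gaseous_pollutants.csv")
  )
  mb <- do.call(rbind, lapply(models, function(m) data.frame(
    region = m$region, a_kg_ha = m$a, b_ha_kg = m$b, n_obs = m$n_obs,
    r_squared = m$r_squared, residual_sd_kg_ha = m$residual_sd,
    stringsAsFactors = FALSE
  )))
  if (is.null(mb)) {
    mb <- data.frame(region = character(), a_kg_ha = numeric(),
                     b_ha_kg = numeric(), n_obs = integer(),
                     r_squared = numeric(), residual_sd_kg_ha = numeric())
  }
  write_csv_na(mb, paths[["models_building"]])
  write_csv_na(inv[, c(key, "area_1000ha", "grain_yield_kg_ha",
                       "straw_yield_kg_ha", "straw_total_1e4t")],
               paths[["planting"]])
  write_csv_na(inv[, c(key, "recycled_1e4t", "burned_1e4t", "removed_1e4t")],
               paths[["management"]])
  write_csv_na(inv[, c(key, "n_supply_t", "p_supply_t", "k_supply_t")],
               paths[["nutrients"]])
  write_csv_na(inv[, c(key, "PM2_5_t", "SO2_t", "NOx_t", "NH3_t", "CH4_t",
                       "CO2_t")],
               paths[["pollutants"]])
  invisible(paths)
}

#' Write a city activity table
#'
#' Inverse of \code{\link{read_city_table}} for the columns it consumes.
#'
#' @param cities City \code{data.frame}.
#' @param path Output CSV path.
#' @export
write_city_table <- function(cities, path) {
  cols <- intersect(c("city_id", "province", "region", "year", "area_1000ha",
                      "grain_yield_kg_ha", "status"), names(cities))
  write_csv_na(cities[, cols], path)
  invisible(path)
}
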