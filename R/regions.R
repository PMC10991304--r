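#' Wheat planting zone definitions
#'
#' The three ecological wheat planting zones used throughout the package:
#' northern China (\code{NC}), central China (\code{CC}) and southern China
#' (\code{SC}), each defined by a closed list of provinces. Provinces outside
#' the three lists (e.g. Tianjin, Inner Mongolia) have no defined zone and are
#' refused by \code{\link{region_of_province}} rather than silently assigned.
#'
#' @return Named list of character vectors of province names, one per region
#'   code.
#' @examples
#' wheat_regions()$CC
#' @export
wheat_regions <- function() {
  list(
    NC = c("Shanxi", "Shaanxi", "Ningxia", "Gansu", "Qinghai", "Xinjiang"),
    CC = c("Beijing", "Hebei", "Henan", "Shandong"),
    SC = c("Anhui", "Jiangsu", "Zhejiang", "Hubei", "Chongqing", "Sichuan",
           "Guizhou", "Yunnan")
  )
}

#' Region codes
#'
#' @return Character vector \code{c("NC", "CC", "SC")}.
#' @export
region_codes <- function() c("NC", "CC", "SC")

#' Map a province to its wheat planting zone
#'
#' Deterministic closed-world mapping from province name to region code.
#' Vectorised over \code{province}.
#'
#' @param province Character vector of province names.
#' @return Character vector of region codes (\code{"NC"}, \code{"CC"} or
#'   \code{"SC"}).
#' @examples
#' region_of_province(c("Henan", "Xinjiang"))
#' @export
region_of_province <- function(province) {
  stopifnot(is.character(province), length(province) >= 1L)
  regions <- wheat_regions()
  lookup <- rep(names(regions), lengths(regions))
  names(lookup) <- unlist(regions, use.names = FALSE)
  out <- lookup[province]
  if (anyNA(out)) {
    bad <- unique(province[is.na(out)])
    stop("unmapped_province: province(s) not in any wheat planting zone: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

assert_region <- function(region) {
  if (!(is.character(region) && length(region) == 1L &&
        region %in% region_codes())) {
    stop("invalid_region: region must be one of ",
         paste(region_codes(), collapse = ", "), call. = FALSE)
  }
  invisible(region)
}
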