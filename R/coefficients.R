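#' Regional straw nutrient concentration coefficients
#'
#' Mass fractions of nitrogen (N), phosphorus (P) and potassium (K) in wheat
#' straw dry matter, by wheat planting zone, together with coefficients of
#' variation used by the Monte-Carlo uncertainty module.
#'
#' Two named coefficient sets are shipped. The default, \code{"table1"}, has
#' straw K around 1.8\% — physically plausible for cereal straw. The
#' alternative, \code{"eq3text"}, is a published variant in which P and K are
#' an order of magnitude larger (K around 18\%); it is retained as a
#' selectable set because some headline numbers in the source literature
#' appear to be computed with it, but it is not the default.
#'
#' The coefficients of variation are not part of either published set; the
#' default of 0.1 is an illustrative value for uncertainty propagation and
#' should be overridden when study-specific CVs are available.
#'
#' @param set Name of the coefficient set: \code{"table1"} (default) or
#'   \code{"eq3text"}.
#' @param cv Coefficient of variation applied to every fraction (recycled by
#'   nutrient), or a named numeric of length 3 (\code{n}, \code{p}, \code{k}).
#' @return A \code{data.frame} of class \code{nutrient_coefficients} with
#'   columns \code{region}, \code{nutrient}, \code{fraction}, \code{cv}.
#' @examples
#' nutrient_coefficients()
#' nutrient_coefficients("eq3text")
#' @export
nutrient_coefficients <- function(set = c("table1", "eq3text"), cv = 0.1) {
  set <- match.arg(set)
  frac <- switch(set,
    table1 = c(NC_n = 0.0049, NC_p = 0.00032, NC_k = 0.01801,
               CC_n = 0.0052, CC_p = 0.00037, CC_k = 0.01809,
               SC_n = 0.0051, SC_p = 0.00032, SC_k = 0.01801),
    eq3text = c(NC_n = 0.0049, NC_p = 0.0032, NC_k = 0.1801,
                CC_n = 0.0052, CC_p = 0.0037, CC_k = 0.1809,
                SC_n = 0.0051, SC_p = 0.0032, SC_k = 0.1801)
  )
  if (length(cv) == 1L) cv <- c(n = cv, p = cv, k = cv)
  stopifnot(all(c("n", "p", "k") %in% names(cv)), all(cv >= 0))
  out <- data.frame(
    region = rep(region_codes(), each = 3L),
    nutrient = rep(c("n", "p", "k"), times = 3L),
    fraction = unname(frac),
    cv = unname(cv[rep(c("n", "p", "k"), times = 3L)]),
    stringsAsFactors = FALSE
  )
  attr(out, "set") <- set
  class(out) <- c("nutrient_coefficients", "data.frame")
  out
}

#' Emission factors for open straw burning
#'
#' Grams of pollutant emitted per kilogram of straw burned, for the six
#' gaseous pollutants tracked by the inventory, with coefficients of
#' variation for Monte-Carlo propagation (default 0.1, illustrative).
#'
#' @param cv Coefficient of variation, scalar or named by pollutant.
#' @return A \code{data.frame} of class \code{emission_factors} with columns
#'   \code{pollutant}, \code{ef_g_per_kg}, \code{cv}.
#' @examples
#' emission_factors()
#' @export
emission_factors <- function(cv = 0.1) {
  pollutants <- c("PM2.5", "SO2", "NOx", "NH3", "CH4", "CO2")
  ef <- c(7.6, 0.85, 3.3, 0.37, 3.4, 1460)
  if (length(cv) == 1L) {
    cv <- stats::setNames(rep(cv, 6L), pollutants)
  }
  stopifnot(all(pollutants %in% names(cv)), all(cv >= 0))
  out <- data.frame(
    pollutant = pollutants,
    ef_g_per_kg = ef,
    cv = unname(cv[pollutants]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("emission_factors", "data.frame")
  out
}

#' Disposal-share triple
#'
#' Fractions of the city straw total that are recycled to the field, burned
#' in the open, and removed for other uses. The three shares must be in
#' [0, 1] and sum to 1.
#'
#' @param recycle,burn,remove Numeric fractions.
#' @return Named numeric vector of class \code{disposal_shares}.
#' @examples
#' disposal_shares(0.5, 0.3, 0.2)
#' @export
disposal_shares <- function(recycle, burn, remove) {
  s <- c(recycle = recycle, burn = burn, remove = remove)
  validate_shares(s)
  class(s) <- "disposal_shares"
  s
}

validate_shares <- function(s) {
  if (!is.numeric(s) || length(s) != 3L || anyNA(s)) {
    stop("invalid_shares: need three finite numeric shares", call. = FALSE)
  }
  if (any(s < 0) || any(s > 1)) {
    stop("invalid_shares: each share must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(s) - 1) > 1e-9) {
    stop("invalid_shares: shares must sum to 1 (got ", format(sum(s)), ")",
         call. = FALSE)
  }
  invisible(s)
}
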