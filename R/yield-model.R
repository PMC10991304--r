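#' Normalize field observations
#'
#' Each observation must carry grain yield plus at least one of straw yield
#' and harvest index (HI, grain over grain-plus-straw). This fills whichever
#' of the two is absent, using \code{straw = grain * (1 - HI) / HI} and
#' \code{HI = grain / (grain + straw)}, and rejects records in which both are
#' present but mutually inconsistent beyond tolerance (no silent averaging).
#' The operation is idempotent.
#'
#' @param obs A \code{data.frame} with columns \code{region},
#'   \code{grain_yield_kg_ha} and at least one of \code{straw_yield_kg_ha},
#'   \code{harvest_index} (either may be \code{NA} row-wise).
#' @param tol Consistency tolerance on HI when both fields are present.
#' @return The same \code{data.frame} with both \code{straw_yield_kg_ha} and
#'   \code{harvest_index} populated.
#' @examples
#' normalize_observations(data.frame(
#'   region = "CC", grain_yield_kg_ha = 4000,
#'   straw_yield_kg_ha = NA, harvest_index = 0.4
#' ))
#' @export
normalize_observations <- function(obs, tol = 1e-6) {
  stopifnot(is.data.frame(obs), "grain_yield_kg_ha" %in% names(obs))
  if (!"straw_yield_kg_ha" %in% names(obs)) obs$straw_yield_kg_ha <- NA_real_
  if (!"harvest_index" %in% names(obs)) obs$harvest_index <- NA_real_
  grain <- obs$grain_yield_kg_ha
  straw <- obs$straw_yield_kg_ha
  hi <- obs$harvest_index
  if (any(!is.finite(grain) | grain <= 0)) {
    stop("invalid_observation: grain_yield_kg_ha must be finite and > 0",
         call. = FALSE)
  }
  neither <- is.na(straw) & is.na(hi)
  if (any(neither)) {
    stop("invalid_observation: rows ", paste(which(neither), collapse = ", "),
         " carry neither straw yield nor harvest index", call. = FALSE)
  }
  hi_bad <- !is.na(hi) & (hi <= 0 | hi >= 1)
  if (any(hi_bad)) {
    stop("invalid_observation: harvest index outside (0,1) in rows ",
         paste(which(hi_bad), collapse = ", "), call. = FALSE)
  }
  straw_bad <- !is.na(straw) & straw <= 0
  if (any(straw_bad)) {
    stop("invalid_observation: straw yield <= 0 in rows ",
         paste(which(straw_bad), collapse = ", "), call. = FALSE)
  }
  both <- !is.na(straw) & !is.na(hi)
  if (any(both)) {
    implied <- grain[both] / (grain[both] + straw[both])
    off <- abs(implied - hi[both]) > tol
    if (any(off)) {
      stop("inconsistent_observation: straw yield and harvest index disagree ",
           "in rows ", paste(which(both)[off], collapse = ", "), call. = FALSE)
    }
  }
  fill_straw <- is.na(straw)
  straw[fill_straw] <- grain[fill_straw] * (1 - hi[fill_straw]) / hi[fill_straw]
  hi <- grain / (grain + straw)
  obs$straw_yield_kg_ha <- straw
  obs$harvest_index <- hi
  obs
}

#' Fit the regional exponential straw-yield model
#'
#' Fits \code{straw = a * exp(b * grain)} to one region's observations by
#' least squares in straw space (so high-yield observations are not
#' down-weighted, matching how the raw data are inspected), using
#' Levenberg-Marquardt nonlinear least squares initialised from the ordinary
#' linear regression of \code{log(straw)} on \code{grain}.
#'
#' @param obs A \code{data.frame} of observations (see
#'   \code{\link{normalize_observations}}); rows of other regions are
#'   ignored.
#' @param region Region code to fit.
#' @return An object of class \code{straw_yield_model}: a list with
#'   \code{region}, \code{a} (kg/ha), \code{b} (ha/kg), \code{n_obs},
#'   \code{r_squared} (in straw space), \code{residual_sd} (kg/ha).
#' @examples
#' obs <- generate_observations(synthetic_config(seed = 1, noise_cv = 0), "NC")
#' fit_straw_model(obs, "NC")
#' @export
fit_straw_model <- function(obs, region) {
  assert_region(region)
  obs <- normalize_observations(obs)
  obs <- obs[obs$region == region, , drop = FALSE]
  ok <- is.finite(obs$grain_yield_kg_ha) & is.finite(obs$straw_yield_kg_ha) &
    obs$grain_yield_kg_ha > 0 & obs$straw_yield_kg_ha > 0
  obs <- obs[ok, , drop = FALSE]
  if (nrow(obs) < 3L) {
    stop("too_few_observations: need >= 3 usable observations for region ",
         region, call. = FALSE)
  }
  grain <- obs$grain_yield_kg_ha
  straw <- obs$straw_yield_kg_ha
  init <- stats::lm(log(straw) ~ grain)
  start <- list(a = exp(unname(stats::coef(init)[1])),
                b = unname(stats::coef(init)[2]))
  # if the initialization already fits to machine precision (e.g. exactly
  # model-generated or constant data), the NLS gradient is singular; accept it
  start_pred <- start$a * exp(start$b * grain)
  if (sum((straw - start_pred)^2) <= 1e-18 * sum(straw^2)) {
    est <- c(a = start$a, b = start$b)
    pred <- start_pred
    ss_res <- sum((straw - pred)^2)
    ss_tot <- sum((straw - mean(straw))^2)
    out <- list(
      region = region, a = est[["a"]], b = est[["b"]], n_obs = nrow(obs),
      r_squared = 1,
      residual_sd = sqrt(ss_res / max(1L, nrow(obs) - 2L))
    )
    class(out) <- "straw_yield_model"
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      straw ~ a * exp(b * grain),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) {
      stop("fit_not_converged: exponential fit failed for region ", region,
           " (", conditionMessage(e), "); log-linear initialization was a=",
           format(start$a), ", b=", format(start$b), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  pred <- est[["a"]] * exp(est[["b"]] * grain)
  ss_res <- sum((straw - pred)^2)
  ss_tot <- sum((straw - mean(straw))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  out <- list(
    region = region,
    a = est[["a"]],
    b = est[["b"]],
    n_obs = nrow(obs),
    r_squared = max(0, min(1, r2)),
    residual_sd = sqrt(ss_res / max(1L, nrow(obs) - 2L))
  )
  class(out) <- "straw_yield_model"
  out
}

#' @export
print.straw_yield_model <- function(x, ...) {
  cat("Exponential straw-yield model [", x$region, "]\n", sep = "")
  cat(sprintf("  straw = %.4g * exp(%.4g * grain)  (kg/ha)\n", x$a, x$b))
  cat(sprintf("  n = %d, R^2 = %.4f, residual SD = %.1f kg/ha\n",
              x$n_obs, x$r_squared, x$residual_sd))
  invisible(x)
}

as_straw_model <- function(model) {
  if (inherits(model, "straw_yield_model")) return(model)
  if (is.list(model) && all(c("a", "b") %in% names(model))) {
    model$region <- model$region %||% NA_character_
    class(model) <- "straw_yield_model"
    return(model)
  }
  stop("invalid_model: expected a straw_yield_model or list(a =, b =)",
       call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Predict straw yield per hectare
#'
#' @param model A \code{straw_yield_model} (or \code{list(a =, b =)}).
#' @param grain_yield Grain yield(s), kg/ha, non-negative.
#' @return Predicted straw yield(s), kg/ha; strictly positive.
#' @examples
#' m <- list(a = 2000, b = 1e-4)
#' predict_straw_yield(m, 5000)
#' @export
predict_straw_yield <- function(model, grain_yield) {
  model <- as_straw_model(model)
  stopifnot(is.numeric(grain_yield), all(grain_yield >= 0, na.rm = TRUE))
  model$a * exp(model$b * grain_yield)
}

#' Harvest-index curve implied by a fitted model
#'
#' \code{HI(grain) = grain / (grain + straw(grain))}; always in (0, 1).
#' With \code{b > 0} the curve eventually declines as grain yield rises,
#' because predicted straw grows faster than linearly.
#'
#' @inheritParams predict_straw_yield
#' @return Harvest index value(s) in (0, 1).
#' @examples
#' harvest_index_curve(list(a = 2000, b = 1e-4), 5000)
#' @export
harvest_index_curve <- function(model, grain_yield) {
  stopifnot(all(grain_yield > 0, na.rm = TRUE))
  grain_yield / (grain_yield + predict_straw_yield(model, grain_yield))
}

#' Compare the exponential model against constant straw-to-grain ratios
#'
#' Constant-ratio schemes predict \code{straw = ratio * grain}. For every
#' grid point and scheme this returns the model prediction, the scheme
#' prediction, their signed difference (scheme minus model) and ratio, plus
#' a per-scheme summary of the mean relative deviation and its sign -- a
#' positive sign flags schemes that systematically overestimate straw yield
#' relative to the exponential model, a negative sign systematic
#' underestimation.
#'
#' @param model A \code{straw_yield_model}.
#' @param constant_ratios Named numeric vector of straw-to-grain ratios
#'   (may be empty).
#' @param grain_grid Numeric vector of grain yields (kg/ha).
#' @return A list with \code{table} (per point and scheme) and
#'   \code{summary} (per scheme: \code{mean_rel_dev}, \code{direction}).
#' @examples
#' m <- list(a = 2000, b = 1e-4)
#' compare_ratio_schemes(m, c(liu = 1.1), seq(1000, 9000, by = 2000))
#' @export
compare_ratio_schemes <- function(model, constant_ratios, grain_grid) {
  model <- as_straw_model(model)
  stopifnot(length(grain_grid) >= 1L, all(grain_grid > 0))
  if (length(constant_ratios) == 0L) {
    empty <- data.frame(scheme = character(), grain_yield_kg_ha = numeric(),
                        model_straw = numeric(), scheme_straw = numeric(),
                        difference = numeric(), ratio = numeric())
    return(list(table = empty,
                summary = data.frame(scheme = character(),
                                     mean_rel_dev = numeric(),
                                     direction = character())))
  }
  if (any(constant_ratios <= 0)) {
    stop("invalid_ratio: constant ratios must be > 0", call. = FALSE)
  }
  if (is.null(names(constant_ratios))) {
    names(constant_ratios) <- paste0("scheme", seq_along(constant_ratios))
  }
  model_straw <- predict_straw_yield(model, grain_grid)
  tab <- do.call(rbind, lapply(names(constant_ratios), function(s) {
    scheme_straw <- constant_ratios[[s]] * grain_grid
    data.frame(
      scheme = s,
      grain_yield_kg_ha = grain_grid,
      model_straw = model_straw,
      scheme_straw = scheme_straw,
      difference = scheme_straw - model_straw,
      ratio = scheme_straw / model_straw,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(split(tab, tab$scheme), function(d) {
    mrd <- mean((d$scheme_straw - d$model_straw) / d$model_straw)
    data.frame(
      scheme = d$scheme[1],
      mean_rel_dev = mrd,
      direction = if (mrd > 0) "overestimates" else if (mrd < 0)
        "underestimates" else "matches",
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}
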