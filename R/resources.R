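#' Yield versus nitrogen-uptake response model
#'
#' Grain yield responds to crop N uptake as a square-root curve,
#' `yield = intercept + slope * sqrt(N)`, with published coefficients for
#' rice (-1573, 643) and maize (-3710, 995) (yield in kg ha^-1 at commercial
#' moisture, N in kg N ha^-1). The curve is calibrated on well-managed crops
#' and is used here to invert potential yields into the N uptake required to
#' support them; uptake is a biological requirement, not a fertiliser-rate
#' recommendation.
#'
#' @param extra Optional data frame of additional crops with columns `crop`,
#'   `intercept`, `slope`; rows override defaults on `crop`.
#' @return Tibble with columns `crop`, `intercept`, `slope`.
#' @export
n_uptake_model <- function(extra = NULL) {
  mod <- tibble::tibble(
    crop = c("rice", "maize"),
    intercept = c(-1573, -3710),
    slope = c(643, 995)
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    need <- c("crop", "intercept", "slope")
    if (!all(need %in% names(extra))) {
      stop("`extra` must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    mod <- dplyr::bind_rows(
      dplyr::filter(mod, !.data$crop %in% extra$crop), extra[need])
  }
  if (any(mod$slope <= 0)) stop("slopes must be positive", call. = FALSE)
  mod
}

n_model_coef <- function(crop, model) {
  idx <- match(crop, model$crop)
  if (anyNA(idx)) {
    stop("crop(s) not in N-uptake model: ",
         paste(unique(crop[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  list(intercept = model$intercept[idx], slope = model$slope[idx])
}

#' Convert between grain yield and crop N uptake
#'
#' `yield_from_n()` evaluates the square-root response; `n_from_yield()` is
#' its exact algebraic inverse, `N = ((yield - intercept) / slope)^2`. Below
#' the curve root (the N uptake at which predicted yield crosses zero) the
#' response is negative; `yield_from_n()` censors such values at zero and
#' attaches a `"censored"` attribute flagging them.
#'
#' @param n_uptake Crop N uptake, kg N ha^-1 (>= 0).
#' @param crop Character crop id(s) present in `model`.
#' @param model N model from [n_uptake_model()].
#' @return `yield_from_n()`: grain yield in kg ha^-1 at commercial moisture;
#'   `n_from_yield()`: N uptake in kg N ha^-1.
#' @examples
#' yield_from_n(276, "rice")        # about 9109 kg ha^-1
#' n_from_yield(9100, "rice")       # about 275.5 kg N ha^-1
#' @export
yield_from_n <- function(n_uptake, crop, model = n_uptake_model()) {
  if (any(n_uptake < 0, na.rm = TRUE)) {
    stop("N uptake must be non-negative", call. = FALSE)
  }
  cf <- n_model_coef(crop, model)
  y <- cf$intercept + cf$slope * sqrt(n_uptake)
  censored <- y < 0
  y[censored] <- 0
  attr(y, "censored") <- censored
  y
}

#' @rdname yield_from_n
#' @param yield_kg_ha Grain yield, kg ha^-1 at commercial moisture (>= 0).
#' @export
n_from_yield <- function(yield_kg_ha, crop, model = n_uptake_model()) {
  if (any(yield_kg_ha < 0, na.rm = TRUE)) {
    stop("yield must be non-negative", call. = FALSE)
  }
  cf <- n_model_coef(crop, model)
  ((yield_kg_ha - cf$intercept) / cf$slope)^2
}

#' Annual N uptake required by a cropping system
#'
#' Inverts the yield-N response for each component crop of a system at its
#' potential yield and sums over the annual sequence.
#'
#' @param crop_yields Data frame with columns `crop` and `yield_t_ha`
#'   (grain at commercial moisture).
#' @param model N model from [n_uptake_model()].
#' @return Total kg N ha^-1 yr^-1 (unrounded; printed tables round to
#'   integer).
#' @examples
#' system_n_requirement(data.frame(
#'   crop = c("rice", "maize", "maize"), yield_t_ha = c(7.4, 9.4, 16.2)))
#' @export
system_n_requirement <- function(crop_yields, model = n_uptake_model()) {
  crop_yields <- tibble::as_tibble(crop_yields)
  if (nrow(crop_yields) == 0) return(0)
  if (!all(c("crop", "yield_t_ha") %in% names(crop_yields))) {
    stop("`crop_yields` needs columns `crop` and `yield_t_ha`",
         call. = FALSE)
  }
  sum(n_from_yield(1000 * crop_yields$yield_t_ha, crop_yields$crop, model))
}

#' Annual water capture summary
#'
#' Sums seasonal crop evapotranspiration over the annual sequence and
#' expresses it relative to annual rainfall. The percentage can exceed 100
#' for irrigated systems whose ET is met partly from groundwater.
#'
#' @param et_mm Numeric vector of per-crop seasonal ET totals, mm.
#' @param annual_rainfall_mm Annual rainfall, mm (> 0).
#' @return One-row tibble: `annual_et_mm`, `pct_of_rainfall`.
#' @examples
#' water_summary(c(406, 678, 440), 1767)
#' @export
water_summary <- function(et_mm, annual_rainfall_mm) {
  if (annual_rainfall_mm <= 0) stop("rainfall must be positive",
                                    call. = FALSE)
  if (any(et_mm < 0)) stop("ET must be non-negative", call. = FALSE)
  et <- sum(et_mm)
  tibble::tibble(annual_et_mm = et,
                 pct_of_rainfall = 100 * et / annual_rainfall_mm)
}

#' Annual PAR-interception summary
#'
#' @param par_intercepted_mj_m2 Intercepted PAR summed over the annual
#'   sequence, MJ m^-2 yr^-1.
#' @param annual_par_mj_m2 Annual incident PAR, MJ m^-2 yr^-1 (> 0).
#' @return Percent of annual PAR intercepted.
#' @examples
#' par_summary(3844, 6252)  # about 61%
#' @export
par_summary <- function(par_intercepted_mj_m2, annual_par_mj_m2) {
  if (any(annual_par_mj_m2 <= 0)) stop("annual PAR must be positive",
                                       call. = FALSE)
  if (any(par_intercepted_mj_m2 < 0)) {
    stop("intercepted PAR must be non-negative", call. = FALSE)
  }
  100 * par_intercepted_mj_m2 / annual_par_mj_m2
}

#' Resource requirements of cropping systems
#'
#' Builds a per-system table of annual PAR interception, evapotranspiration
#' and N uptake from component-crop records and location climate scalars.
#'
#' @param components Tibble with one row per (location, system, crop):
#'   `location`, `system`, `crop`, `yield_t_ha`, `et_mm`, `par_mj_m2`.
#' @param climate Tibble with one row per location: `location`,
#'   `annual_par_mj_m2`, `annual_rainfall_mm`.
#' @param model N model from [n_uptake_model()].
#' @return One row per (location, system): intercepted PAR and its percent
#'   of annual PAR, annual ET and its percent of rainfall, annual N uptake
#'   (all unrounded; reporting rounds to integers).
#' @export
resource_table <- function(components, climate, model = n_uptake_model()) {
  components <- tibble::as_tibble(components)
  need <- c("location", "system", "crop", "yield_t_ha", "et_mm", "par_mj_m2")
  miss <- setdiff(need, names(components))
  if (length(miss)) {
    stop("`components` missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- components |>
    dplyr::group_by(.data$location, .data$system) |>
    dplyr::summarise(
      par_intercepted_mj_m2 = sum(.data$par_mj_m2),
      annual_et_mm = sum(.data$et_mm),
      annual_n_kg_ha = system_n_requirement(
        dplyr::pick("crop", "yield_t_ha"), model),
      .groups = "drop"
    ) |>
    dplyr::left_join(tibble::as_tibble(climate), by = "location")
  if (any(is.na(out$annual_par_mj_m2) | is.na(out$annual_rainfall_mm))) {
    stop("climate scalars missing for some location", call. = FALSE)
  }
  out |>
    dplyr::mutate(
      pct_par_intercepted = par_summary(.data$par_intercepted_mj_m2,
                                        .data$annual_par_mj_m2),
      pct_of_rainfall = 100 * .data$annual_et_mm / .data$annual_rainfall_mm
    ) |>
    dplyr::relocate("location", "system", "annual_par_mj_m2",
                    "par_intercepted_mj_m2", "pct_par_intercepted",
                    "annual_rainfall_mm", "annual_et_mm", "pct_of_rainfall",
                    "annual_n_kg_ha")
}
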