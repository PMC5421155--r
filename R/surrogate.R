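#' Default surrogate parameters for the Bangladesh rice-maize case study
#'
#' The package does not re-implement process-based crop models. Instead, a
#' stochastic surrogate generates potential-yield surfaces with the structure
#' that crop-model output for irrigated rice and maize in a sub-tropical
#' monsoon climate exhibits:
#'
#' * a smooth unimodal response of potential yield to sowing/transplanting
#'   date, modelled as a circular Gaussian peaking near 1 October (DOY 274)
#'   for maize and 15 November (DOY 319) for rice;
#' * longer-duration maturity classes with higher peak yields;
#' * multiplicative log-normal year-to-year variability with a target
#'   inter-annual CV of a few percent near the optimum;
#' * for rice only, a cold-injury window of transplanting dates (crops that
#'   would flower in the coldest weeks) with depressed mean yield and
#'   inflated CV.
#'
#' One parameter row describes one (location, crop, maturity class). Peak
#' yields are anchored per location so the date-response maxima fall in the
#' observed ranges (maize 15-18 t ha^-1, rice 13-14.5 t ha^-1). Seasonal
#' evapotranspiration and intercepted PAR are generated as affine functions
#' of yield with per-crop baselines; they are plumbing for the resource
#' accounting, not a water balance.
#'
#' @param location Optional character vector to subset locations.
#' @return A tibble with one row per (location, crop, variety): columns
#'   `location`, `crop`, `variety`, `peak_yield_t_ha`, `optimal_doy`,
#'   `season_width_d`, `duration_d`, `interannual_cv`, `injury_start_doy`,
#'   `injury_end_doy`, `injury_penalty`, `injury_cv_inflation`, `et_base_mm`,
#'   `et_per_t_mm`, `par_base_mj_m2`, `par_per_t_mj_m2`.
#' @export
surrogate_params <- function(location = NULL) {
  locs <- c("Bogra", "Dhaka", "Rajshahi", "Rangpur")
  maize_peak <- c(Bogra = 16.5, Dhaka = 15.2, Rajshahi = 17.5, Rangpur = 18.0)
  rice_peak <- c(Bogra = 13.5, Dhaka = 13.8, Rajshahi = 13.0, Rangpur = 14.2)

  maize <- tidyr::expand_grid(
    location = locs,
    tibble::tibble(
      variety = c("early", "medium", "medium-late", "late"),
      peak_ratio = c(0.80, 0.88, 0.94, 1.00),
      duration_d = c(85L, 100L, 115L, 128L)
    )
  ) |>
    dplyr::mutate(
      crop = "maize",
      peak_yield_t_ha = unname(maize_peak[.data$location]) * .data$peak_ratio,
      optimal_doy = 274L,
      season_width_d = 110,
      interannual_cv = 0.05,
      injury_start_doy = NA_integer_,
      injury_end_doy = NA_integer_,
      injury_penalty = 0,
      injury_cv_inflation = 1,
      et_base_mm = 30, et_per_t_mm = 40,
      par_base_mj_m2 = 350, par_per_t_mj_m2 = 93
    )

  rice <- tidyr::expand_grid(
    location = locs,
    tibble::tibble(
      variety = c("extra-short", "short", "intermediate", "late"),
      peak_ratio = c(0.72, 0.80, 0.91, 1.00),
      duration_d = c(70L, 83L, 112L, 130L)
    )
  ) |>
    dplyr::mutate(
      crop = "rice",
      peak_yield_t_ha = unname(rice_peak[.data$location]) * .data$peak_ratio,
      optimal_doy = 319L,
      season_width_d = 100,
      interannual_cv = 0.06,
      injury_start_doy = 283L,
      injury_end_doy = 311L,
      injury_penalty = 0.35,
      injury_cv_inflation = 2.5,
      et_base_mm = 240, et_per_t_mm = 35,
      par_base_mj_m2 = 230, par_per_t_mj_m2 = 67
    )

  out <- dplyr::bind_rows(maize, rice) |>
    dplyr::select(-"peak_ratio") |>
    dplyr::relocate("location", "crop", "variety")
  if (!is.null(location)) {
    loc <- location
    out <- dplyr::filter(out, .data$location %in% loc)
  }
  validate_surrogate_params(out)
  out
}

validate_surrogate_params <- function(params) {
  need <- c("location", "crop", "variety", "peak_yield_t_ha", "optimal_doy",
            "season_width_d", "duration_d", "interannual_cv")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop("surrogate params missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(
    all(params$peak_yield_t_ha > 0),
    all(params$duration_d > 0),
    all(params$interannual_cv >= 0),
    all(params$injury_penalty >= 0 & params$injury_penalty <= 1, na.rm = TRUE)
  )
  check_doy(params$optimal_doy, "optimal_doy")
  # longer-duration classes never yield less at their optimum
  chk <- params |>
    dplyr::group_by(.data$location, .data$crop) |>
    dplyr::arrange(.data$duration_d, .by_group = TRUE) |>
    dplyr::summarise(
      ok = !is.unsorted(.data$peak_yield_t_ha), .groups = "drop"
    )
  if (!all(chk$ok)) {
    stop("peak yield must be non-decreasing in maturity-class duration",
         call. = FALSE)
  }
  invisible(params)
}

circular_distance <- function(a, b) {
  d <- abs(as.numeric(a) - as.numeric(b)) %% 365
  pmin(d, 365 - d)
}

in_injury_window <- function(doy, start, end) {
  if (is.na(start) || is.na(end)) return(rep(FALSE, length(doy)))
  # window may wrap the year boundary
  if (start <= end) doy >= start & doy <= end else doy >= start | doy <= end
}

#' Deterministic seasonal yield response of the surrogate
#'
#' The noise-free expected potential yield for one (crop, maturity class) as
#' a function of sowing/transplanting DOY: a circular Gaussian around the
#' optimal date, multiplied by `(1 - injury_penalty)` inside the cold-injury
#' window.
#'
#' @param doy Sowing/transplanting day(s) of year.
#' @param params_row One-row data frame (a row of [surrogate_params()]).
#' @return Numeric vector of expected yields, t ha^-1.
#' @export
seasonal_yield_curve <- function(doy, params_row) {
  check_doy(doy, "doy")
  p <- as.list(params_row)
  d <- circular_distance(doy, p$optimal_doy)
  y <- p$peak_yield_t_ha * exp(-d^2 / (2 * p$season_width_d^2))
  inj <- in_injury_window(doy, p$injury_start_doy, p$injury_end_doy)
  y[inj] <- y[inj] * (1 - p$injury_penalty)
  y
}

#' Simulate a potential-yield surface
#'
#' Generates per-(variety, sowing date, year) potential yields, cycle end
#' dates, seasonal evapotranspiration and intercepted PAR for one location,
#' emulating multi-year crop-model runs over a grid of sowing/transplanting
#' dates. Year-to-year variability is multiplicative log-normal with unit
#' mean, parameterised by the target inter-annual CV (inflated inside the
#' rice cold-injury window). Identical seeds give bit-identical surfaces.
#'
#' @param params Tibble of surrogate parameters (rows of
#'   [surrogate_params()]), all for one location.
#' @param sowing_dates Integer DOY grid; default 24 dates at 15-day intervals
#'   chosen so both crops' optimal dates (DOY 274 and 319) lie on the grid.
#' @param years Number of simulation years (default 14).
#' @param seed Integer random seed (required: surfaces must be reproducible).
#' @return A `yield_surface` tibble with columns `location`, `crop`,
#'   `variety`, `sowing_doy`, `year`, `yp_t_ha`, `cycle_end_doy`,
#'   `duration_d`, `et_mm`, `par_mj_m2`.
#' @examples
#' surf <- simulate_yield_surface(
#'   surrogate_params("Bogra"), years = 5, seed = 42)
#' summarize_surface(surf)
#' @export
simulate_yield_surface <- function(params,
                                   sowing_dates = seq(4L, 349L, by = 15L),
                                   years = 14,
                                   seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (length(sowing_dates) < 1) stop("need at least one sowing date",
                                     call. = FALSE)
  check_doy(sowing_dates, "sowing_dates")
  if (anyDuplicated(sowing_dates)) {
    stop("duplicate sowing dates", call. = FALSE)
  }
  if (years < 1) stop("`years` must be >= 1", call. = FALSE)
  validate_surrogate_params(params)
  if (length(unique(params$location)) != 1) {
    stop("simulate one location at a time", call. = FALSE)
  }

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }

  grid <- params |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::expand_grid(sowing_doy = as.integer(sort(sowing_dates)),
                       year = seq_len(years)) |>
    dplyr::arrange(.data$.row, .data$sowing_doy, .data$year)

  d <- circular_distance(grid$sowing_doy, grid$optimal_doy)
  inj <- !is.na(grid$injury_start_doy) & !is.na(grid$injury_end_doy) &
    ifelse(grid$injury_start_doy <= grid$injury_end_doy,
           grid$sowing_doy >= grid$injury_start_doy &
             grid$sowing_doy <= grid$injury_end_doy,
           grid$sowing_doy >= grid$injury_start_doy |
             grid$sowing_doy <= grid$injury_end_doy)
  mu <- grid$peak_yield_t_ha * exp(-d^2 / (2 * grid$season_width_d^2)) *
    ifelse(inj, 1 - grid$injury_penalty, 1)
  cv <- grid$interannual_cv * ifelse(inj, grid$injury_cv_inflation, 1)

  noise <- withr_seed({
    sdlog <- sqrt(log1p(cv^2))
    exp(stats::rnorm(nrow(grid), mean = -sdlog^2 / 2, sd = sdlog))
  })
  noise[cv == 0] <- 1

  out <- grid |>
    dplyr::mutate(
      yp_t_ha = mu * noise,
      cycle_end_doy = cycle_end(.data$sowing_doy, .data$duration_d),
      et_mm = .data$et_base_mm + .data$et_per_t_mm * .data$yp_t_ha,
      par_mj_m2 = .data$par_base_mj_m2 + .data$par_per_t_mj_m2 * .data$yp_t_ha
    ) |>
    dplyr::select("location", "crop", "variety", "sowing_doy", "year",
                  "yp_t_ha", "cycle_end_doy", duration_d = "duration_d",
                  "et_mm", "par_mj_m2")
  as_yield_surface(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_yield_surface <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("location", "crop", "variety", "sowing_doy", "year", "yp_t_ha",
            "cycle_end_doy", "duration_d", "et_mm", "par_mj_m2")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("yield surface missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$yp_t_ha)) || any(x$yp_t_ha < 0)) {
    stop("yields must be finite and non-negative", call. = FALSE)
  }
  key <- paste(x$location, x$crop, x$variety, x$sowing_doy, x$year)
  if (anyDuplicated(key)) {
    stop("duplicate (location, crop, variety, sowing date, year) rows",
         call. = FALSE)
  }
  class(x) <- c("yield_surface", class(x))
  x
}

#' Summarise a yield surface over years
#'
#' Collapses a multi-year surface to the per-(variety, date) mean potential
#' yield and its inter-annual coefficient of variation
#' (CV% = 100 x sample SD / mean, n-1 denominator) -- the quantities on which
#' sequence stability filtering operates.
#'
#' @param surface A `yield_surface` tibble (>= 2 years for a defined CV).
#' @return Tibble with columns `location`, `crop`, `variety`, `sowing_doy`,
#'   `duration_d`, `mean_yp_t_ha`, `cv_pct`, `n_years`.
#' @export
summarize_surface <- function(surface) {
  surface <- as_yield_surface(surface)
  out <- surface |>
    dplyr::group_by(.data$location, .data$crop, .data$variety,
                    .data$sowing_doy, .data$duration_d) |>
    dplyr::summarise(
      mean_yp_t_ha = mean(.data$yp_t_ha),
      cv_pct = 100 * stats::sd(.data$yp_t_ha) / mean(.data$yp_t_ha),
      n_years = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_years < 2)) {
    warning("CV undefined for single-year surfaces (reported as NA)",
            call. = FALSE)
  }
  out
}

#' Read and write yield-surface CSV files
#'
#' The on-disk format is a plain CSV with one row per
#' (location, crop, variety, sowing date, year):
#' `location,crop,variety,sowing_doy,year,yp_t_ha,cycle_end_doy,duration_d,et_mm,par_mj_m2`.
#' Externally simulated crop-model output in this format is interchangeable
#' with surrogate output everywhere downstream.
#'
#' @param path File path.
#' @return `read_yield_surface()`: a validated `yield_surface` tibble.
#' @export
read_yield_surface <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(x) == 0) stop("empty yield-surface file: ", path, call. = FALSE)
  if (!is.numeric(x$yp_t_ha %||% NA)) {
    stop("non-numeric yields in ", path, call. = FALSE)
  }
  as_yield_surface(x)
}

#' @rdname read_yield_surface
#' @param surface A `yield_surface` tibble.
#' @export
write_yield_surface <- function(surface, path) {
  surface <- as_yield_surface(surface)
  readr::write_csv(surface, path)
  invisible(path)
}
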