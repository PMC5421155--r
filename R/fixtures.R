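#' Packaged Bangladesh rice-maize case-study tables
#'
#' The package ships the published case-study tables for four Bangladeshi
#' locations (Bogra, Dhaka, Rajshahi, Rangpur) as plain-CSV fixtures:
#'
#' * `bangladesh_systems()` -- current cropping systems with actual and
#'   potential yields (t ha^-1 yr^-1, system totals), percent area shares
#'   and inter-annual CV of potential yield;
#' * `bangladesh_cs_star()` -- the selected alternative system per location:
#'   component crops, maturity classes, cycle dates (both as day-month
#'   strings and DOY on the 365-day calendar) and per-crop potential yields
#'   on both unit bases;
#' * `bangladesh_gap_inputs()` -- location-level CSYa/CSYp/CSYp* on the mass
#'   and energy bases, as printed (the two bases are kept as printed even
#'   where they disagree on which location holds which CSYp*; see the
#'   methods vignette);
#' * `bangladesh_climate()` -- annual incident PAR (MJ m^-2 yr^-1) and
#'   rainfall (mm yr^-1) per location;
#' * `bangladesh_resources()` -- published annual PAR-interception, ET and
#'   N-uptake table per (location, system).
#'
#' @return A tibble (see each description).
#' @name bangladesh
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "cropgap")
  if (p == "") stop("fixture not found: ", file, call. = FALSE)
  p
}

read_fixture <- function(file) {
  readr::read_csv(fixture_path(file), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname bangladesh
#' @export
bangladesh_systems <- function() read_fixture("bangladesh_systems.csv")

#' @rdname bangladesh
#' @export
bangladesh_cs_star <- function() read_fixture("bangladesh_cs_star.csv")

#' @rdname bangladesh
#' @export
bangladesh_gap_inputs <- function() read_fixture("bangladesh_gap_inputs.csv")

#' @rdname bangladesh
#' @export
bangladesh_climate <- function() read_fixture("bangladesh_climate.csv")

#' @rdname bangladesh
#' @export
bangladesh_resources <- function() read_fixture("bangladesh_resources.csv")

#' Anchor yield surface built from the published alternative systems
#'
#' Expands the per-crop cycles of [bangladesh_cs_star()] into a small
#' `yield_surface` (constant across years: the published values are
#' multi-year means) so the published systems can be fed through the same
#' option-building, enumeration and selection machinery as simulated
#' surfaces.
#'
#' @param location Location name.
#' @param years Number of (identical) year replicates.
#' @return A `yield_surface` tibble.
#' @export
anchor_surface <- function(location, years = 3) {
  cs <- bangladesh_cs_star()
  loc <- location
  cs <- dplyr::filter(cs, .data$location == loc)
  if (nrow(cs) == 0) stop("unknown location: ", location, call. = FALSE)
  par_def <- surrogate_params(location) |>
    dplyr::distinct(.data$crop, .data$et_base_mm, .data$et_per_t_mm,
                    .data$par_base_mj_m2, .data$par_per_t_mj_m2)
  cs |>
    dplyr::left_join(par_def, by = "crop") |>
    tidyr::expand_grid(year = seq_len(years)) |>
    dplyr::mutate(
      sowing_doy = .data$start_doy,
      duration_d = gap_days(.data$start_doy, .data$end_doy),
      cycle_end_doy = .data$end_doy,
      yp_t_ha = .data$yp_t_ha,
      et_mm = .data$et_base_mm + .data$et_per_t_mm * .data$yp_t_ha,
      par_mj_m2 = .data$par_base_mj_m2 +
        .data$par_per_t_mj_m2 * .data$yp_t_ha
    ) |>
    dplyr::select("location", "crop", "variety", "sowing_doy", "year",
                  "yp_t_ha", "cycle_end_doy", "duration_d", "et_mm",
                  "par_mj_m2") |>
    as_yield_surface()
}
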