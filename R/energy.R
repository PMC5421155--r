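#' Crop energy-content registry
#'
#' Energy per unit land and time (GJ ha^-1 yr^-1) is the common currency that
#' makes systems with different species and cropping intensities comparable.
#' The registry stores, per crop, the commercial-standard grain moisture
#' fraction and the energy content of grain at that moisture, in kJ per 100 g
#' as conventionally tabulated. The conversion factor to GJ per tonne is the
#' kJ/100 g value divided by 100 (1440 kJ/100 g = 14.40 GJ t^-1); no
#' dry-matter or protein adjustment is applied because the energy content is
#' already defined at commercial moisture.
#'
#' Defaults cover the two case-study crops: rice (14% moisture, 1440 kJ/100 g)
#' and maize (15.5% moisture, 1480 kJ/100 g).
#'
#' @param extra Optional data frame of additional crops with columns `crop`,
#'   `moisture_frac`, `energy_kj_per_100g`; rows override defaults on `crop`.
#' @return A tibble with columns `crop`, `moisture_frac`,
#'   `energy_kj_per_100g`, `gj_per_t`.
#' @examples
#' crop_registry()
#' crop_registry(extra = data.frame(
#'   crop = "wheat", moisture_frac = 0.135, energy_kj_per_100g = 1420))
#' @export
crop_registry <- function(extra = NULL) {
  reg <- tibble::tibble(
    crop = c("rice", "maize"),
    moisture_frac = c(0.14, 0.155),
    energy_kj_per_100g = c(1440, 1480)
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    need <- c("crop", "moisture_frac", "energy_kj_per_100g")
    if (!all(need %in% names(extra))) {
      stop("`extra` must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    reg <- dplyr::bind_rows(
      dplyr::filter(reg, !.data$crop %in% extra$crop),
      extra[need]
    )
  }
  if (any(reg$moisture_frac < 0 | reg$moisture_frac >= 0.5)) {
    stop("moisture_frac must lie in [0, 0.5)", call. = FALSE)
  }
  if (any(reg$energy_kj_per_100g <= 0)) {
    stop("energy_kj_per_100g must be positive", call. = FALSE)
  }
  reg$gj_per_t <- reg$energy_kj_per_100g / 100
  reg
}

energy_factor <- function(crop, registry = crop_registry()) {
  idx <- match(crop, registry$crop)
  if (anyNA(idx)) {
    stop("crop(s) not in energy registry: ",
         paste(unique(crop[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  registry$gj_per_t[idx]
}

#' Convert grain yield to energy yield and back
#'
#' `grain_to_energy()` maps grain mass at commercial moisture (t ha^-1) to
#' energy yield (GJ ha^-1) as the exact linear product of mass and the crop's
#' energy content; `energy_to_grain()` is its exact inverse. Both are
#' vectorised and recycle `crop` against the yield vector.
#'
#' @param yield_t_ha Grain yield, t ha^-1 at commercial moisture (>= 0).
#' @param crop Character crop id(s) present in `registry`.
#' @param registry Energy registry from [crop_registry()].
#' @return Numeric vector: GJ ha^-1 (`grain_to_energy`) or t ha^-1
#'   (`energy_to_grain`).
#' @examples
#' grain_to_energy(16.2, "maize")  # 239.76 GJ ha^-1, reported as 240
#' grain_to_energy(7.4, "rice")    # 106.56 GJ ha^-1
#' energy_to_grain(240, "maize")   # 16.216 t ha^-1
#' @export
grain_to_energy <- function(yield_t_ha, crop, registry = crop_registry()) {
  if (any(yield_t_ha < 0, na.rm = TRUE)) {
    stop("grain yield must be non-negative", call. = FALSE)
  }
  yield_t_ha * energy_factor(crop, registry)
}

#' @rdname grain_to_energy
#' @param energy_gj_ha Energy yield, GJ ha^-1 (>= 0).
#' @export
energy_to_grain <- function(energy_gj_ha, crop, registry = crop_registry()) {
  if (any(energy_gj_ha < 0, na.rm = TRUE)) {
    stop("energy yield must be non-negative", call. = FALSE)
  }
  energy_gj_ha / energy_factor(crop, registry)
}

#' Add an energy-yield column to a per-crop table
#'
#' Tabular convenience around [grain_to_energy()]: takes any data frame with a
#' crop id column and a yield column and appends the corresponding energy
#' yield.
#'
#' @param data Data frame with at least the columns named by `crop` and
#'   `yield`.
#' @param yield,crop Column names (strings) holding grain yield (t ha^-1) and
#'   crop id.
#' @param out Name of the new energy column.
#' @param registry Energy registry from [crop_registry()].
#' @return `data` as a tibble with the extra column `out` (GJ ha^-1).
#' @export
add_energy_yield <- function(data, yield = "yp_t_ha", crop = "crop",
                             out = "yp_gj_ha", registry = crop_registry()) {
  data <- tibble::as_tibble(data)
  if (!all(c(yield, crop) %in% names(data))) {
    stop("`data` must contain columns `", yield, "` and `", crop, "`",
         call. = FALSE)
  }
  data[[out]] <- grain_to_energy(data[[yield]], data[[crop]], registry)
  data
}
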