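#' Actual and potential yields of current cropping systems
#'
#' Sums component-crop yields of each existing system into system-level
#' annual actual (CSYa) and potential (CSYp) yields on the mass basis, and on
#' the energy basis whenever per-crop rows are available (tonnes of
#' different crops are summed as printed in survey tables, with the caveat
#' that rice and maize tonnes are not energy-equivalent; energy sums are the
#' unit-coherent alternative).
#'
#' @param systems Tibble with one row per (location, system, crop):
#'   columns `location`, `system`, `crop`, `ya_t_ha`, `yp_t_ha` and
#'   optionally `area_pct`, `n_crops`, `cv_pct`. Rows carrying system totals
#'   (crop = `"total"`) are passed through unsummed.
#' @param registry Energy registry from [crop_registry()].
#' @return Tibble with one row per system: `location`, `system`, `n_crops`,
#'   `csya_t_ha`, `csyp_t_ha`, `csya_gj_ha`, `csyp_gj_ha` (energy columns NA
#'   for rows given only as cross-crop totals), plus `area_pct`/`cv_pct`
#'   when supplied.
#' @export
system_yields <- function(systems, registry = crop_registry()) {
  systems <- tibble::as_tibble(systems)
  need <- c("location", "system", "crop", "ya_t_ha", "yp_t_ha")
  miss <- setdiff(need, names(systems))
  if (length(miss)) {
    stop("`systems` missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(systems) == 0) stop("empty systems table", call. = FALSE)
  is_total <- systems$crop == "total"
  per_crop <- systems[!is_total, ]
  if (nrow(per_crop) > 0) {
    # will error on unknown crops before any aggregation
    energy_factor(per_crop$crop, registry)
  }

  keep_first <- function(x) x[1]
  out <- systems |>
    dplyr::group_by(.data$location, .data$system) |>
    dplyr::summarise(
      n_crops = if ("n_crops" %in% names(systems)) {
        keep_first(.data$n_crops)
      } else {
        sum(.data$crop != "total")
      },
      csya_t_ha = sum(.data$ya_t_ha),
      csyp_t_ha = sum(.data$yp_t_ha),
      csya_gj_ha = if (any(.data$crop == "total")) NA_real_ else {
        sum(grain_to_energy(.data$ya_t_ha, .data$crop, registry))
      },
      csyp_gj_ha = if (any(.data$crop == "total")) NA_real_ else {
        sum(grain_to_energy(.data$yp_t_ha, .data$crop, registry))
      },
      dplyr::across(dplyr::any_of(c("area_pct", "cv_pct")), keep_first),
      .groups = "drop"
    )
  bad <- !is.na(out$csya_t_ha) & out$csya_t_ha > out$csyp_t_ha
  if (any(bad)) {
    warning("actual yield exceeds potential yield for: ",
            paste(out$system[bad], collapse = "; "), call. = FALSE)
  }
  out
}

#' Decompose the cropping-system yield gap
#'
#' Splits the total gap between the best alternative system's potential
#' (CSYp*) and a current system's actual yield (CSYa) into a management
#' component (CSYgM = CSYp - CSYa: what better management of the current
#' crops could recover) and an arrangement component
#' (CSYgA = CSYp* - CSYp: what a different spatial/temporal crop arrangement
#' could add). The identity CSYg = CSYgM + CSYgA is exact by construction.
#' Negative components are reported as-is (a current system can out-arrange
#' the selected alternative) with a warning, never clamped.
#'
#' @param data Data frame with columns holding CSYp*, CSYp and CSYa on a
#'   common unit basis (any number of id columns is carried through).
#' @param csyp_star,csyp,csya Column names (strings).
#' @param suffix Appended to the three output columns `csyg`, `csygm`,
#'   `csyga` (e.g. `"_t_ha"`).
#' @return `data` with the gap columns appended.
#' @examples
#' decompose_gap(data.frame(csyp_star = 33.0, csyp = 18.2, csya = 5.0))
#' @export
decompose_gap <- function(data, csyp_star = "csyp_star", csyp = "csyp",
                          csya = "csya", suffix = "") {
  data <- tibble::as_tibble(data)
  cols <- c(csyp_star, csyp, csya)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("`data` missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ps <- data[[csyp_star]]; p <- data[[csyp]]; a <- data[[csya]]
  if (any(is.na(ps) | is.na(p) | is.na(a))) {
    stop("missing values in gap inputs", call. = FALSE)
  }
  if (any(a > p) || any(p > ps)) {
    warning("expected CSYa <= CSYp <= CSYp*; negative gap components ",
            "reported as-is", call. = FALSE)
  }
  data[[paste0("csygm", suffix)]] <- p - a
  data[[paste0("csyga", suffix)]] <- ps - p
  data[[paste0("csyg", suffix)]] <- (p - a) + (ps - p)
  data
}

#' Area-weighted location summary of current systems
#'
#' Aggregates per-system yields to a single location estimate by weighting
#' each current system by its share of regional crop area, and re-derives
#' the gap decomposition from the weighted aggregates (equivalent to
#' weighting per-system gaps, since every operation is linear). Also reports
#' the area-weighted cropping intensity (crops per year).
#'
#' @param systems Per-system tibble from [system_yields()] (or equivalent)
#'   with columns `location`, `system`, `n_crops`, `area_pct`, `csya_t_ha`,
#'   `csyp_t_ha` and optionally energy-basis columns.
#' @param csyp_star Tibble with columns `location`, `csyp_star_t_ha` and
#'   optionally `csyp_star_gj_ha`: one CS* per location.
#' @return One row per location: weighted `csya`, `csyp`, `intensity`, the
#'   gap decomposition on the mass basis (and energy basis when available).
#' @export
area_weighted_summary <- function(systems, csyp_star) {
  systems <- tibble::as_tibble(systems)
  if (!"area_pct" %in% names(systems)) {
    stop("`systems` must carry `area_pct` shares", call. = FALSE)
  }
  wsum <- function(x, w) if (all(is.na(x))) NA_real_ else sum(x * w)
  out <- systems |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(
      share_total = sum(.data$area_pct),
      w = list(.data$area_pct / sum(.data$area_pct)),
      csya_t_ha = wsum(.data$csya_t_ha, w[[1]]),
      csyp_t_ha = wsum(.data$csyp_t_ha, w[[1]]),
      csya_gj_ha = if ("csya_gj_ha" %in% names(systems)) {
        wsum(.data$csya_gj_ha, w[[1]])
      } else NA_real_,
      csyp_gj_ha = if ("csyp_gj_ha" %in% names(systems)) {
        wsum(.data$csyp_gj_ha, w[[1]])
      } else NA_real_,
      intensity = wsum(.data$n_crops, w[[1]]),
      .groups = "drop"
    ) |>
    dplyr::select(-"w")
  if (any(out$share_total <= 0)) {
    stop("area shares sum to zero for some location", call. = FALSE)
  }
  if (any(abs(out$share_total - 100) > 1e-4)) {
    warning("area shares do not sum to 100%; shares were renormalised",
            call. = FALSE)
  }
  out <- dplyr::left_join(out, tibble::as_tibble(csyp_star), by = "location")
  if (!"csyp_star_t_ha" %in% names(out)) {
    stop("`csyp_star` must carry `location` and `csyp_star_t_ha`",
         call. = FALSE)
  }
  out <- decompose_gap(out, "csyp_star_t_ha", "csyp_t_ha", "csya_t_ha",
                       suffix = "_t_ha")
  if ("csyp_star_gj_ha" %in% names(out) && !all(is.na(out$csya_gj_ha))) {
    out <- decompose_gap(out, "csyp_star_gj_ha", "csyp_gj_ha", "csya_gj_ha",
                         suffix = "_gj_ha")
  }
  dplyr::select(out, -"share_total")
}

#' Yield-gap components versus cropping intensity
#'
#' Emits the per-system table of management and arrangement gap components
#' against cropping intensity, with Spearman rank correlations between
#' intensity and each component. The expected pattern in intensification
#' gradients: the management component grows and the arrangement component
#' shrinks as current systems already grow more crops per year.
#'
#' @param system_gaps Per-system tibble with columns `system`, `n_crops`,
#'   and gap components `csygm`/`csyga` (any shared suffix, e.g. `_t_ha`).
#' @param suffix Suffix of the gap columns to use.
#' @return List with `table` (system, n_crops, csygm, csyga) and
#'   `correlations` (one-row tibble of Spearman rho; NA with a warning when
#'   intensity does not vary).
#' @export
gap_vs_intensity <- function(system_gaps, suffix = "_t_ha") {
  gm <- paste0("csygm", suffix); ga <- paste0("csyga", suffix)
  need <- c("system", "n_crops", gm, ga)
  miss <- setdiff(need, names(system_gaps))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(system_gaps) < 2) {
    stop("need at least two systems", call. = FALSE)
  }
  tab <- tibble::as_tibble(system_gaps)[need]
  if (length(unique(tab$n_crops)) == 1) {
    warning("cropping intensity does not vary; correlations undefined",
            call. = FALSE)
    cors <- tibble::tibble(rho_intensity_csygm = NA_real_,
                           rho_intensity_csyga = NA_real_)
  } else {
    cors <- tibble::tibble(
      rho_intensity_csygm = stats::cor(tab$n_crops, tab[[gm]],
                                       method = "spearman"),
      rho_intensity_csyga = stats::cor(tab$n_crops, tab[[ga]],
                                       method = "spearman")
    )
  }
  list(table = tab, correlations = cors)
}
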