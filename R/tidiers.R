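#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CS* selection
#'
#' `tidy()` returns one row per component crop cycle of the selected
#' sequence (crop, maturity class, calendar placement, mean yield on both
#' unit bases); `glance()` returns a one-row summary of the selection
#' (CSYp* on both bases, stability, and filter bookkeeping).
#'
#' @param x A `cs_star` object from [select_best()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cs_star
#' @export
tidy.cs_star <- function(x, ...) {
  cyc <- x$cycles
  if (is.null(cyc)) {
    stop("selection carries no cycle detail (options were not supplied ",
         "to select_best())", call. = FALSE)
  }
  tibble::tibble(
    crop = cyc$crop,
    variety = cyc$variety,
    start_doy = cyc$start_doy,
    end_doy = cyc$end_doy,
    duration_d = cyc$duration_d,
    yp_t_ha = vapply(cyc$yields, mean, numeric(1)),
    yp_gj_ha = grain_to_energy(vapply(cyc$yields, mean, numeric(1)),
                               cyc$crop)
  )
}

#' @rdname tidy.cs_star
#' @method glance cs_star
#' @export
glance.cs_star <- function(x, ...) {
  b <- x$best
  tibble::tibble(
    crops = b$crops,
    n_crops = b$n_crops,
    csyp_star_gj_ha = b$csyp_gj_ha,
    csyp_star_t_ha = b$csyp_t_ha,
    cv_pct = b$cv_pct,
    n_candidates = nrow(x$candidates),
    n_cv_discarded = x$n_cv_discarded,
    n_surviving = x$n_surviving,
    max_cv_pct = x$max_cv_pct
  )
}
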