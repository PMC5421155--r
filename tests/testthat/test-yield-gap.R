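test_that("system yields sum component crops on both unit bases", {
  per_crop <- tibble::tibble(
    location = "Bogra", system = "aman rice - boro rice",
    crop = c("rice", "rice"), ya_t_ha = c(2.2, 3.9), yp_t_ha = c(9.1, 12.4))
  out <- system_yields(per_crop)
  expect_equal(out$csya_t_ha, 6.1)
  expect_equal(out$csya_gj_ha, 6.1 * 14.4)
  expect_equal(out$n_crops, 2)

  expect_error(system_yields(per_crop[0, ]), "empty")
  expect_error(system_yields(dplyr::mutate(per_crop, crop = "quinoa")),
               "not in energy registry")

  # no management gap when actual equals potential
  eq <- dplyr::mutate(per_crop, ya_t_ha = yp_t_ha)
  out_eq <- system_yields(eq)
  expect_equal(out_eq$csya_t_ha, out_eq$csyp_t_ha)

  expect_warning(
    system_yields(dplyr::mutate(per_crop, ya_t_ha = c(12, 15))),
    "exceeds potential")
})

test_that("gap decomposition is exact and additive", {
  out <- decompose_gap(
    data.frame(csyp_star = 33.0, csyp = 18.2, csya = 5.0))
  expect_equal(out$csygm, 13.2)
  expect_equal(out$csyga, 14.8)
  expect_equal(out$csyg, 28.0)

  gj <- decompose_gap(data.frame(csyp_star = 486, csyp = 259, csya = 82))
  expect_equal(gj$csygm, 177)
  expect_equal(gj$csyga, 227)
  expect_equal(gj$csyg, 404)

  z <- decompose_gap(data.frame(csyp_star = 7, csyp = 7, csya = 7))
  expect_equal(unlist(z[c("csygm", "csyga", "csyg")]), c(0, 0, 0),
               ignore_attr = TRUE)

  # additivity holds exactly for arbitrary inputs
  set.seed(1)
  r <- tibble::tibble(csyp_star = runif(50, 20, 40),
                      csyp = runif(50, 10, 30), csya = runif(50, 0, 15))
  suppressWarnings(rd <- decompose_gap(r))
  expect_true(all(rd$csygm + rd$csyga - rd$csyg == 0))

  expect_warning(decompose_gap(data.frame(csyp_star = 10, csyp = 12,
                                          csya = 5)),
                 "reported as-is")
  expect_error(decompose_gap(data.frame(csyp_star = 10)), "missing columns")
})

test_that("area weighting reproduces the published location summaries", {
  systems <- system_yields(bangladesh_systems())
  stars <- dplyr::distinct(bangladesh_cs_star(), .data$location,
                           .data$csyp_star_t_ha)
  out <- area_weighted_summary(systems, stars) |>
    dplyr::arrange(.data$location)
  expect_equal(cropgap:::round_half_up(out$csyp_t_ha, 1),
               c(18.2, 17.0, 19.0, 18.5))
  expect_equal(out$intensity, c(1.75, 1.60, 2.00, 1.70))
  # weighted aggregates stay within the range of the component systems
  rng <- systems |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(lo = min(.data$csyp_t_ha), hi = max(.data$csyp_t_ha))
  expect_true(all(out$csyp_t_ha >= rng$lo & out$csyp_t_ha <= rng$hi))
})

test_that("a single system with full area share is its own summary", {
  one <- tibble::tibble(location = "X", system = "s", n_crops = 2,
                        area_pct = 100, csya_t_ha = 6, csyp_t_ha = 20)
  out <- area_weighted_summary(
    one, tibble::tibble(location = "X", csyp_star_t_ha = 30))
  expect_equal(out$csya_t_ha, 6)
  expect_equal(out$csyp_t_ha, 20)
  expect_equal(out$csygm_t_ha, 14)
  expect_equal(out$csyga_t_ha, 10)
})

test_that("gap components correlate with cropping intensity as expected", {
  systems <- system_yields(bangladesh_systems())
  stars <- dplyr::distinct(bangladesh_cs_star(), .data$location,
                           .data$csyp_star_t_ha)
  gaps <- dplyr::left_join(systems, stars, by = "location") |>
    decompose_gap("csyp_star_t_ha", "csyp_t_ha", "csya_t_ha",
                  suffix = "_t_ha")
  gi <- gap_vs_intensity(gaps)
  expect_lt(gi$correlations$rho_intensity_csyga, 0)
  expect_gt(gi$correlations$rho_intensity_csygm, 0)

  # two-system toy against hand ranks: higher intensity, smaller csyga
  toy <- tibble::tibble(system = c("s1", "s2"), n_crops = c(1, 3),
                        csygm_t_ha = c(2, 9), csyga_t_ha = c(20, 3))
  gi2 <- gap_vs_intensity(toy)
  expect_equal(gi2$correlations$rho_intensity_csygm, 1)
  expect_equal(gi2$correlations$rho_intensity_csyga, -1)

  same <- dplyr::mutate(toy, n_crops = 2)
  expect_warning(gap_vs_intensity(same), "undefined")
  expect_error(gap_vs_intensity(toy[1, ]), "at least two")
})
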