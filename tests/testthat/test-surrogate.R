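test_that("surfaces are bit-identical under the same seed", {
  p <- surrogate_params("Bogra")
  a <- simulate_yield_surface(p, years = 5, seed = 11)
  b <- simulate_yield_surface(p, years = 5, seed = 11)
  c <- simulate_yield_surface(p, years = 5, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$yp_t_ha, c$yp_t_ha))
})

test_that("zero inter-annual CV gives identical years and zero CV", {
  p <- dplyr::mutate(surrogate_params("Bogra"), interannual_cv = 0,
                     injury_cv_inflation = 1)
  s <- simulate_yield_surface(p, years = 4, seed = 3)
  smry <- summarize_surface(s)
  expect_true(all(abs(smry$cv_pct) < 1e-12))
  wide <- tidyr::pivot_wider(s, id_cols = c("crop", "variety", "sowing_doy"),
                             names_from = "year", values_from = "yp_t_ha")
  expect_equal(wide$`1`, wide$`2`)
  expect_equal(wide$`1`, wide$`4`)
})

test_that("empirical means recover the deterministic seasonal curve", {
  p <- surrogate_params("Rangpur")
  s <- simulate_yield_surface(p, years = 14, seed = 5)
  smry <- summarize_surface(s)
  curve <- purrr::pmap_dbl(
    list(smry$crop, smry$variety, smry$sowing_doy),
    function(cr, v, d) {
      row <- dplyr::filter(p, .data$crop == cr, .data$variety == v)
      seasonal_yield_curve(d, row)
    })
  se <- smry$mean_yp_t_ha * (smry$cv_pct / 100) / sqrt(smry$n_years)
  z <- abs(smry$mean_yp_t_ha - curve) / pmax(se, 1e-12)
  # nominal 3-SE coverage is 99.7%; demand at least 95% of cells inside
  expect_gte(mean(z <= 3), 0.95)
})

test_that("cold-injury window depresses rice yield and inflates its CV", {
  p <- surrogate_params("Bogra")
  rice <- dplyr::filter(p, .data$crop == "rice", .data$variety == "late")
  s <- simulate_yield_surface(rice, sowing_dates = c(304L, 319L),
                              years = 14, seed = 9)
  smry <- summarize_surface(s)
  win <- smry[smry$sowing_doy == 304, ]   # inside [283, 311]
  opt <- smry[smry$sowing_doy == 319, ]
  expect_lt(win$mean_yp_t_ha, opt$mean_yp_t_ha)
  expect_gt(win$cv_pct, opt$cv_pct)
  # the deterministic drop is the configured penalty
  det <- seasonal_yield_curve(c(304L, 319L), rice)
  gauss <- rice$peak_yield_t_ha *
    exp(-cropgap:::circular_distance(304, 319)^2 /
          (2 * rice$season_width_d^2))
  expect_equal(det[1], gauss * (1 - rice$injury_penalty))
})

curve_by_row <- function(params, doys) {
  vapply(seq_len(nrow(params)),
         function(i) max(seasonal_yield_curve(doys, params[i, ])),
         numeric(1))
}

test_that("longer maturity classes yield at least as much at the optimum", {
  for (loc in c("Bogra", "Dhaka", "Rajshahi", "Rangpur")) {
    p <- dplyr::arrange(surrogate_params(loc), .data$crop, .data$duration_d)
    p$y_opt <- vapply(seq_len(nrow(p)), function(i) {
      seasonal_yield_curve(p$optimal_doy[i], p[i, ])
    }, numeric(1))
    for (cr in c("maize", "rice")) {
      expect_false(is.unsorted(p$y_opt[p$crop == cr]))
    }
  }
})

test_that("noise-free maxima sit in the observed per-crop ranges", {
  for (loc in c("Bogra", "Dhaka", "Rajshahi", "Rangpur")) {
    p <- surrogate_params(loc)
    p$max_y <- curve_by_row(p, 1:365)
    maize <- max(p$max_y[p$crop == "maize"])
    rice <- max(p$max_y[p$crop == "rice"])
    expect_gte(maize, 15); expect_lte(maize, 18)
    expect_gte(rice, 13); expect_lte(rice, 14.5)
  }
})

test_that("surface summaries compute mean and sample-SD CV", {
  s <- tibble::tibble(
    location = "X", crop = "rice", variety = "v", sowing_doy = 100,
    year = 1:3, yp_t_ha = c(5, 5, 5), cycle_end_doy = 183, duration_d = 83,
    et_mm = 400, par_mj_m2 = 900)
  out <- summarize_surface(s)
  expect_equal(out$mean_yp_t_ha, 5)
  expect_equal(out$cv_pct, 0)

  s2 <- dplyr::mutate(s[1:2, ], year = 1:2, yp_t_ha = c(9, 11))
  out2 <- summarize_surface(s2)
  expect_equal(out2$mean_yp_t_ha, 10)
  expect_equal(out2$cv_pct, 100 * sqrt(2) / 10, tolerance = 1e-12)

  expect_warning(summarize_surface(s[1, ]), "single-year")
})

test_that("surface CSV round-trips and rejects malformed input", {
  s <- anchor_surface("Bogra")
  path <- withr::local_tempfile(fileext = ".csv")
  write_yield_surface(s, path)
  back <- read_yield_surface(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(s))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("location,crop", empty)
  expect_error(read_yield_surface(empty), "empty|missing")

  one <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(s[1, ], one)
  expect_s3_class(read_yield_surface(one), "yield_surface")

  dup <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rbind(s[1, ], s[1, ]), dup)
  expect_error(read_yield_surface(dup), "duplicate")
})

test_that("simulation rejects invalid grids and missing seeds", {
  p <- surrogate_params("Bogra")
  expect_error(simulate_yield_surface(p, years = 5), "seed")
  expect_error(simulate_yield_surface(p, sowing_dates = c(0, 10), seed = 1),
               "1..365")
  expect_error(simulate_yield_surface(p, years = 0, seed = 1), ">= 1")
})
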