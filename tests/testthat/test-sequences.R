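test_that("the published triple-crop cycles pack feasibly at Bogra", {
  # kharif-II maize 166->248, rabi maize 274->37, aus rice 62->145
  opts <- toy_options(starts = c(166, 274, 62),
                      durations = c(82, 128, 83),
                      crops = c("maize", "maize", "rice"))
  seqs <- enumerate_sequences(opts, min_turnaround = 21, max_crops = 3)
  triple <- seqs[seqs$n_crops == 3, ]
  expect_equal(nrow(triple), 1)
  expect_equal(triple$crops, "rice-maize-maize")  # ordered by start DOY
  # gaps 21 (145->166), 26 (248->274), 25 (37->62) partition the year
  expect_equal(sum(c(82, 128, 83)) + sum(c(21, 26, 25)), 365)
})

test_that("overlapping cycles are excluded", {
  opts <- toy_options(starts = c(1, 100), durations = c(120, 101))
  seqs <- enumerate_sequences(opts, min_turnaround = 21, max_crops = 2)
  expect_true(all(seqs$n_crops == 1))
  expect_equal(attr(seqs, "counts")$overlap_discarded, 1)
})

test_that("enumeration matches the day-occupancy brute-force oracle", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    opts <- toy_options(starts = sample(365, n),
                        durations = sample(60:160, n, replace = TRUE))
    for (mt in c(7, 21)) {
      got <- enumerate_sequences(opts, min_turnaround = mt, max_crops = 3)
      want <- oracle_enumerate(opts, min_turnaround = mt, max_crops = 3)
      got_sets <- lapply(got$option_ids, sort)
      expect_setequal(
        vapply(got_sets, paste, character(1), collapse = ","),
        vapply(want, paste, character(1), collapse = ","))
      # discard bookkeeping sums to the candidate count
      cnt <- attr(got, "counts")
      expect_equal(cnt$candidates,
                   cnt$feasible + cnt$overlap_discarded +
                     cnt$turnaround_discarded)
    }
  }
})

test_that("sequence scores match the published sums and a hand oracle", {
  # Bogra CS* component means
  opts <- toy_options(
    starts = c(166, 274, 62), durations = c(82, 128, 83),
    crops = c("maize", "maize", "rice"),
    yields = list(rep(9.4, 3), rep(16.2, 3), rep(7.4, 3)))
  sc <- score_sequence(opts)
  expect_equal(sc$csyp_t_ha, 33.0)
  expect_equal(sc$csyp_gj_ha, 9.4 * 14.8 + 16.2 * 14.8 + 7.4 * 14.4)
  expect_equal(sc$cv_pct, 0)

  # constant 10 t rice single cycle
  one <- toy_options(starts = 1, durations = 100, crops = "rice",
                     yields = list(rep(10, 3)))
  sc1 <- score_sequence(one)
  expect_equal(sc1$csyp_gj_ha, 144)
  expect_equal(sc1$cv_pct, 0)

  # anticorrelated components cancel at the system level
  two <- toy_options(
    starts = c(1, 180), durations = c(100, 100), crops = c("rice", "rice"),
    yields = list(c(100, 120) / 14.4, c(50, 30) / 14.4), m = 2)
  sc2 <- score_sequence(two)
  expect_equal(sc2$per_year_gj[[1]], c(150, 150))
  expect_equal(sc2$cv_pct, 0)

  # random case against the independent loop-based oracle
  set.seed(7)
  rnd <- toy_options(
    starts = c(10, 150, 280), durations = c(80, 80, 60),
    crops = c("rice", "maize", "rice"),
    yields = lapply(1:3, function(i) runif(5, 2, 12)), m = 5)
  got <- score_sequence(rnd)
  want <- oracle_score(rnd, list(rice = 14.4, maize = 14.8))
  expect_equal(got$per_year_gj[[1]], want$per_year)
  expect_equal(got$cv_pct, want$cv_pct)
  expect_error(score_sequence(rnd[0, ]), "empty")
})

test_that("selection filters on CV then maximises energy yield", {
  seqs <- tibble::tibble(
    n_crops = c(2, 2, 3),
    crops = c("a", "b", "c"), varieties = c("x", "y", "z"),
    start_doys = c("1", "2", "3"),
    csyp_gj_ha = c(480, 504, 520), csyp_t_ha = c(33, 34, 35),
    cv_pct = c(5, 4.5, 12),
    option_ids = list(1, 2, 3), per_year_gj = list(0, 0, 0))
  sel <- select_best(seqs, max_cv_pct = 10)
  expect_equal(sel$best$csyp_gj_ha, 504)
  expect_equal(sel$n_cv_discarded, 1)

  single <- select_best(seqs[2, ], max_cv_pct = 10)
  expect_equal(single$best$csyp_gj_ha, 504)

  expect_error(select_best(dplyr::mutate(seqs, cv_pct = 50)),
               "no feasible stable system")

  # deterministic tie-breaking: equal energy, lower CV wins
  tied <- dplyr::mutate(seqs[1:2, ], csyp_gj_ha = 500)
  expect_equal(select_best(tied)$best$cv_pct, 4.5)
})

test_that("feasibility is re-checkable post hoc on surrogate output", {
  surf <- simulate_yield_surface(surrogate_params("Dhaka"), years = 6,
                                 seed = 2)
  opts <- surface_to_options(surf)
  seqs <- enumerate_sequences(opts, min_turnaround = 21, max_crops = 3)
  for (ids in seqs$option_ids[seq_len(min(200, nrow(seqs)))]) {
    rows <- opts[match(ids, opts$option_id), ]
    rows <- rows[order(rows$start_doy), ]
    gaps <- gap_days(rows$end_doy,
                     rows$start_doy[c(seq_len(nrow(rows))[-1], 1)])
    expect_true(all(gaps >= 21))
    expect_equal(sum(rows$duration_d) + sum(gaps), 365)
  }
  best <- select_best(seqs, opts)
  surviving <- seqs[!is.na(seqs$cv_pct) & seqs$cv_pct <= 10, ]
  expect_true(all(best$best$csyp_gj_ha >= surviving$csyp_gj_ha))
})

test_that("constraint relaxation never shrinks the feasible set", {
  set.seed(99)
  opts <- toy_options(starts = sample(365, 6),
                      durations = sample(60:140, 6, replace = TRUE))
  key <- function(s) vapply(s$option_ids, paste, character(1),
                            collapse = ",")
  tight <- enumerate_sequences(opts, min_turnaround = 21, max_crops = 3)
  loose <- enumerate_sequences(opts, min_turnaround = 7, max_crops = 3)
  expect_true(all(key(tight) %in% key(loose)))

  # raising the CV threshold keeps every previously surviving sequence
  surf <- simulate_yield_surface(surrogate_params("Bogra")[c(4, 8), ],
                                 years = 6, seed = 4)
  seqs <- enumerate_sequences(surface_to_options(surf))
  s10 <- seqs[seqs$cv_pct <= 10, ]
  s15 <- seqs[seqs$cv_pct <= 15, ]
  expect_true(all(key(s10) %in% key(s15)))
})

test_that("single-crop sequences respect the wrap-around turnaround", {
  opts <- toy_options(starts = c(1, 50), durations = c(350, 100))
  seqs <- enumerate_sequences(opts, min_turnaround = 21, max_crops = 1)
  expect_equal(nrow(seqs), 1)  # the 350-day cycle leaves only 15 free days
  expect_equal(seqs$option_ids[[1]], 2)
})

test_that("mismatched year labels across options are rejected", {
  opts <- toy_options(starts = c(1, 200), durations = c(100, 100))
  opts$yields[[1]] <- rep(5, 4)  # four years vs three
  expect_error(enumerate_sequences(opts), "year labels")
})
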