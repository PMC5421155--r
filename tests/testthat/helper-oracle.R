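# Independent brute-force oracle for sequence feasibility and scoring.
#
# Deliberately avoids the package's modular-gap arithmetic: each cycle is
# expanded to the set of calendar days it occupies, and feasibility is read
# off a day-occupancy scan of the 365-day circle. Requires min_turnaround
# >= 1 (a zero-length free run is indistinguishable from no boundary).

occupied_days <- function(start, duration) {
  ((start - 1 + seq_len(duration) - 1) %% 365) + 1
}

oracle_feasible <- function(starts, durations, min_turnaround) {
  stopifnot(min_turnaround >= 1)
  occ <- rep(0L, 365)
  for (i in seq_along(starts)) {
    days <- occupied_days(starts[i], durations[i])
    if (any(occ[days] != 0L)) return(FALSE)  # overlap
    occ[days] <- i
  }
  # walk the circle: lengths of maximal free runs between occupied runs
  r <- rle(occ)
  if (r$values[1] == 0L && r$values[length(r$values)] == 0L &&
      length(r$values) > 1) {
    # merge the wrap-around free run
    r$lengths[1] <- r$lengths[1] + r$lengths[length(r$lengths)]
    r$lengths <- r$lengths[-length(r$lengths)]
    r$values <- r$values[-length(r$values)]
  }
  free <- r$lengths[r$values == 0L]
  length(free) == length(starts) && all(free >= min_turnaround)
}

oracle_enumerate <- function(options, min_turnaround, max_crops) {
  n <- nrow(options)
  sets <- list()
  for (k in seq_len(min(max_crops, n))) {
    for (idx in asplit(utils::combn(n, k), 2)) {
      if (oracle_feasible(options$start_doy[idx], options$duration_d[idx],
                          min_turnaround)) {
        sets <- c(sets, list(sort(options$option_id[idx])))
      }
    }
  }
  sets
}

oracle_score <- function(cycles, gj_per_t) {
  m <- length(cycles$yields[[1]])
  per_year <- numeric(m)
  for (y in seq_len(m)) {
    for (i in seq_len(nrow(cycles))) {
      per_year[y] <- per_year[y] +
        cycles$yields[[i]][y] * gj_per_t[[cycles$crop[i]]]
    }
  }
  list(per_year = per_year, mean_gj = mean(per_year),
       cv_pct = 100 * stats::sd(per_year) / mean(per_year))
}

# small hand-built options table for enumeration tests
toy_options <- function(starts, durations, crops = NULL, yields = NULL,
                        m = 3) {
  n <- length(starts)
  tibble::tibble(
    option_id = seq_len(n),
    location = "Toy",
    crop = crops %||% rep("rice", n),
    variety = paste0("v", seq_len(n)),
    start_doy = starts,
    duration_d = durations,
    end_doy = ((starts + durations - 1) %% 365) + 1,
    yields = yields %||% lapply(seq_len(n), function(i) rep(5 + i, m)),
    et = lapply(seq_len(n), function(i) rep(400, m)),
    par = lapply(seq_len(n), function(i) rep(900, m)),
    mean_yp_t_ha = vapply(yields %||% lapply(seq_len(n),
                                             function(i) rep(5 + i, m)),
                          mean, numeric(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
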