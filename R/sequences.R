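#' Build candidate crop-cycle options from a yield surface
#'
#' Each (crop, maturity class, sowing date) cell of a multi-year surface
#' becomes one candidate cycle option carrying its annual potential-yield
#' series. Options from the same surface share year labels and can be packed
#' into annual sequences by [enumerate_sequences()].
#'
#' @param surface A `yield_surface` tibble (one location).
#' @param min_mean_yield Drop options whose mean yield falls below this
#'   threshold (t ha^-1); default 0 keeps everything.
#' @return Tibble with one row per option: `option_id`, `location`, `crop`,
#'   `variety`, `start_doy`, `duration_d`, `end_doy`, list-columns `yields`,
#'   `et`, `par` (one value per year), and `mean_yp_t_ha`.
#' @export
surface_to_options <- function(surface, min_mean_yield = 0) {
  surface <- as_yield_surface(surface)
  if (length(unique(surface$location)) != 1) {
    stop("build options for one location at a time", call. = FALSE)
  }
  years <- sort(unique(surface$year))
  opts <- surface |>
    dplyr::arrange(.data$crop, .data$variety, .data$sowing_doy, .data$year) |>
    dplyr::group_by(.data$location, .data$crop, .data$variety,
                    start_doy = .data$sowing_doy, .data$duration_d,
                    end_doy = .data$cycle_end_doy) |>
    dplyr::summarise(
      yields = list(.data$yp_t_ha),
      et = list(.data$et_mm),
      par = list(.data$par_mj_m2),
      n_years = dplyr::n(),
      .groups = "drop"
    )
  if (any(opts$n_years != length(years))) {
    stop("options must share the same year labels", call. = FALSE)
  }
  opts |>
    dplyr::mutate(
      option_id = dplyr::row_number(),
      mean_yp_t_ha = purrr::map_dbl(.data$yields, mean)
    ) |>
    dplyr::filter(.data$mean_yp_t_ha >= min_mean_yield) |>
    dplyr::relocate("option_id")
}

#' Score one crop sequence
#'
#' Annual system yield is the sum over component cycles of that year's
#' energy yield; the sequence score is its mean over years (GJ ha^-1 yr^-1),
#' the mass-basis mean (sum of mean grain yields, t ha^-1 yr^-1), and the
#' inter-annual CV% of the annual energy series. Anticorrelated component
#' crops can therefore stabilise a sequence beyond any single crop.
#'
#' @param cycles Tibble of the member cycle options (rows of
#'   [surface_to_options()]), each with `crop` and list-column `yields`.
#' @param registry Energy registry from [crop_registry()].
#' @return One-row tibble: `csyp_gj_ha`, `csyp_t_ha`, `cv_pct`, and
#'   list-column `per_year_gj`.
#' @examples
#' opts <- tibble::tibble(
#'   crop = "rice", variety = "x", start_doy = 1, duration_d = 100,
#'   yields = list(c(10, 10, 10)))
#' score_sequence(opts)  # 144 GJ, CV 0
#' @export
score_sequence <- function(cycles, registry = crop_registry()) {
  if (nrow(cycles) == 0) stop("empty sequence", call. = FALSE)
  m <- lengths(cycles$yields)
  if (length(unique(m)) != 1) {
    stop("member cycles carry different numbers of years", call. = FALSE)
  }
  fac <- energy_factor(cycles$crop, registry)
  E <- do.call(rbind, cycles$yields) * fac
  per_year <- colSums(E)
  mean_gj <- mean(per_year)
  cv <- if (length(per_year) >= 2) {
    100 * stats::sd(per_year) / mean_gj
  } else {
    NA_real_
  }
  tibble::tibble(
    csyp_gj_ha = mean_gj,
    csyp_t_ha = sum(vapply(cycles$yields, mean, numeric(1))),
    cv_pct = cv,
    per_year_gj = list(unname(per_year))
  )
}

# Pairwise circular-calendar relations between cycle options. Two cycles
# [s_i, e_i) and [s_j, e_j) are disjoint iff their durations plus both
# directed gaps sum to exactly 365 (overlapping arcs make the modular "gaps"
# overshoot to 730); they are sequence-compatible iff additionally both
# directed gaps meet the turnaround minimum. Because gaps only ever get
# subdivided (never shortened) when more cycles are added, every subset of a
# feasible sequence is pairwise compatible, so feasible sequences are exactly
# the cliques of the compatibility graph.
pairwise_relations <- function(start, duration, min_turnaround) {
  n <- length(start)
  end <- cycle_end(start, duration)
  gf <- outer(end, start, function(e, s) (s - e) %% 365)   # gf[i,j]: i -> j
  total <- outer(duration, duration, `+`) + gf + t(gf)
  disjoint <- total == 365
  diag(disjoint) <- FALSE
  compat <- disjoint & gf >= min_turnaround & t(gf) >= min_turnaround
  list(disjoint = disjoint, compat = compat, gap_fwd = gf)
}

count_cliques <- function(adj, kmax) {
  n <- nrow(adj)
  a <- adj * 1
  counts <- c(n, sum(adj) / 2, if (kmax >= 3) sum((a %*% a) * a) / 6)
  counts[seq_len(min(kmax, 3))]
}

list_cliques <- function(adj, kmax, keep1 = rep(TRUE, nrow(adj))) {
  n <- nrow(adj)
  out <- lapply(which(keep1), function(i) i)
  if (kmax >= 2) {
    e <- which(adj & upper.tri(adj), arr.ind = TRUE)
    out <- c(out, lapply(seq_len(nrow(e)), function(r) as.integer(e[r, ])))
    if (kmax >= 3 && nrow(e) > 0) {
      tri <- lapply(seq_len(nrow(e)), function(r) {
        i <- e[r, 1]; j <- e[r, 2]
        ks <- which(adj[i, ] & adj[j, ])
        ks <- ks[ks > j]
        if (length(ks)) lapply(ks, function(k) c(i, j, k))
      })
      out <- c(out, unlist(tri[!vapply(tri, is.null, logical(1))],
                           recursive = FALSE))
    }
  }
  out
}

#' Enumerate all feasible annual crop sequences
#'
#' Considers every subset of 1 to `max_crops` cycle options and keeps those
#' that pack onto the circular 365-day calendar: cycles pairwise
#' non-overlapping, and every inter-cycle gap (including the wrap-around
#' from the last maturity back to the first sowing) at least
#' `min_turnaround` days. The turnaround threshold is inclusive: a gap of
#' exactly 21 days passes the default rule. Each feasible sequence is scored
#' with [score_sequence()]. Discard counts at each stage (overlap, turnaround)
#' are attached as the `"counts"` attribute for audit logging.
#'
#' @param options Options tibble from [surface_to_options()].
#' @param min_turnaround Minimum fallow days between consecutive cycles
#'   (default 21 = three weeks).
#' @param max_crops Maximum cycles per year (default 3).
#' @param registry Energy registry from [crop_registry()].
#' @return Tibble of feasible sequences ordered by decreasing energy yield:
#'   `n_crops`, `crops`, `varieties`, `start_doys` (hyphenated, in start
#'   order), `csyp_gj_ha`, `csyp_t_ha`, `cv_pct`, list-columns `option_ids`
#'   and `per_year_gj`.
#' @export
enumerate_sequences <- function(options, min_turnaround = 21, max_crops = 3,
                                registry = crop_registry()) {
  if (nrow(options) == 0) stop("no cycle options supplied", call. = FALSE)
  if (min_turnaround < 0) stop("min_turnaround must be >= 0", call. = FALSE)
  if (max_crops < 1) stop("max_crops must be >= 1", call. = FALSE)
  if (max_crops > 3) {
    stop("sequences with more than 3 crops per year are not supported",
         call. = FALSE)
  }
  if (length(unique(lengths(options$yields))) != 1) {
    stop("options must share the same year labels", call. = FALSE)
  }

  rel <- pairwise_relations(options$start_doy, options$duration_d,
                            min_turnaround)
  # a one-crop sequence still faces the wrap-around gap back to its own
  # next-year sowing
  keep1 <- (365 - options$duration_d) >= min_turnaround
  sets <- list_cliques(rel$compat, max_crops, keep1)
  if (length(sets) == 0) {
    stop("no feasible sequences under the given constraints", call. = FALSE)
  }

  n <- nrow(options)
  n_candidates <- sum(vapply(seq_len(max_crops), choose, numeric(1), n = n))
  n_disjoint <- sum(count_cliques(rel$disjoint, max_crops))
  counts <- list(
    candidates = n_candidates,
    overlap_discarded = n_candidates - n_disjoint,
    turnaround_discarded = n_disjoint - length(sets),
    feasible = length(sets)
  )

  fac <- energy_factor(options$crop, registry)
  Y <- do.call(rbind, options$yields)
  E <- Y * fac
  ymean <- rowMeans(Y)
  m <- ncol(Y)

  len <- lengths(sets)
  seq_id <- rep(seq_along(sets), len)
  memb <- unlist(sets)
  ord <- order(seq_id, options$start_doy[memb])
  seq_id <- seq_id[ord]
  memb <- memb[ord]

  per_year <- rowsum(E[memb, , drop = FALSE], seq_id, reorder = TRUE)
  rownames(per_year) <- NULL
  mu <- rowMeans(per_year)
  cv <- if (m >= 2) {
    100 * sqrt(pmax(rowSums(per_year^2) - m * mu^2, 0) / (m - 1)) / mu
  } else {
    rep(NA_real_, length(mu))
  }
  collapse_by <- function(x) {
    unname(vapply(split(x, seq_id), paste, character(1), collapse = "-"))
  }
  out <- tibble::tibble(
    n_crops = len,
    crops = collapse_by(options$crop[memb]),
    varieties = collapse_by(options$variety[memb]),
    start_doys = collapse_by(options$start_doy[memb]),
    csyp_gj_ha = mu,
    csyp_t_ha = as.vector(rowsum(ymean[memb], seq_id)),
    cv_pct = cv,
    option_ids = unname(split(options$option_id[memb], seq_id)),
    per_year_gj = lapply(asplit(per_year, 1), unname)
  ) |>
    dplyr::arrange(dplyr::desc(.data$csyp_gj_ha))
  attr(out, "counts") <- counts
  attr(out, "min_turnaround") <- min_turnaround
  out
}

#' Select the best stable sequence (CS*)
#'
#' Applies the stability filter (inter-annual CV of annual energy yield at
#' most `max_cv_pct`) and returns the surviving sequence with the highest
#' mean energy yield. Ties are broken deterministically: highest energy
#' yield, then lowest CV, then fewest crops, then lexicographic
#' crop/variety/start order.
#'
#' @param sequences Scored sequences from [enumerate_sequences()].
#' @param options The options tibble the sequences index into (kept so the
#'   selection can be unpacked into component cycles).
#' @param max_cv_pct Stability threshold, percent (default 10).
#' @return A `cs_star` object: list with elements `best` (one-row sequence
#'   tibble), `cycles` (component-cycle tibble), `candidates`, and filter
#'   bookkeeping. Supports [tidy()], [glance()], `print()`.
#' @export
select_best <- function(sequences, options = NULL, max_cv_pct = 10) {
  if (nrow(sequences) == 0) stop("no sequences to select from", call. = FALSE)
  keep <- !is.na(sequences$cv_pct) & sequences$cv_pct <= max_cv_pct
  surviving <- sequences[keep, ]
  if (nrow(surviving) == 0) {
    stop("no feasible stable system: all sequences exceed CV ",
         max_cv_pct, "%", call. = FALSE)
  }
  best <- surviving |>
    dplyr::arrange(dplyr::desc(.data$csyp_gj_ha), .data$cv_pct,
                   .data$n_crops, .data$crops, .data$varieties,
                   .data$start_doys) |>
    dplyr::slice(1)
  cycles <- if (!is.null(options)) {
    options[match(best$option_ids[[1]], options$option_id), ]
  }
  structure(
    list(
      best = best,
      cycles = cycles,
      candidates = sequences,
      max_cv_pct = max_cv_pct,
      n_cv_discarded = sum(!keep),
      n_surviving = nrow(surviving)
    ),
    class = "cs_star"
  )
}

#' @export
print.cs_star <- function(x, ...) {
  b <- x$best
  cat("CS* selection\n")
  cat(sprintf("  sequence : %s (%s), sown DOY %s\n",
              b$crops, b$varieties, b$start_doys))
  cat(sprintf("  CSYp*    : %.1f GJ ha-1 yr-1 (%.1f t ha-1 yr-1), CV %.1f%%\n",
              b$csyp_gj_ha, b$csyp_t_ha, b$cv_pct))
  cat(sprintf("  filter   : %d of %d feasible sequences within CV <= %g%%\n",
              x$n_surviving, nrow(x$candidates), x$max_cv_pct))
  invisible(x)
}
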