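#' Hourly intake matrix
#'
#' Bins intake into 24 clock-hour bins per animal-day, with bins indexed
#' from light onset (bin 0 starts at lights-on). Events straddling a bin
#' boundary are split pro-rata by time by default; `attribute = "start"`
#' assigns the whole intake to the bin containing the event start.
#' Days with no events at all still appear as all-zero rows, so zero-intake
#' hours can be counted.
#'
#' @param events Feeding-event tibble (`animal_id`, `start`, `end`,
#'   `intake_g`; a `phase` column, if present, is carried through).
#' @param schedule A [light_schedule()].
#' @param diet A [diet_spec()] or energy density in kcal/g.
#' @param attribute `"prorata"` (default) or `"start"`.
#' @param days Optional integer vector of study days to tabulate; defaults
#'   to the full range observed in `events`.
#' @return A tibble with `animal_id` (`phase` if supplied), `day`,
#'   `hour_bin` (0-23 from light onset), `clock_hour`, `cycle`, `intake_g`,
#'   `intake_kcal`.
#' @export
hourly_bin <- function(events, schedule = light_schedule(),
                       diet = diet_spec(),
                       attribute = c("prorata", "start"),
                       days = NULL) {
  attribute <- match.arg(attribute)
  diet <- as_diet(diet)
  has_phase <- "phase" %in% names(events)
  keys <- c("animal_id", if (has_phase) "phase")
  if (!nrow(events) && is.null(days)) {
    out <- tibble::tibble(animal_id = character(), day = integer(),
                          hour_bin = integer(), clock_hour = numeric(),
                          cycle = character(), intake_g = numeric(),
                          intake_kcal = numeric())
    return(out)
  }
  ev_day <- if (nrow(events)) study_day(events$start, schedule) else integer()
  days <- days %||% seq(min(ev_day), max(ev_day))
  # seconds from light onset of the record's first tabulated day
  t0 <- as.numeric(day_start(min(days), schedule))
  contrib <- NULL
  if (nrow(events)) {
    s <- as.numeric(events$start) - t0
    e <- as.numeric(events$end) - t0
    h_lo <- floor(s / 3600)
    h_hi <- floor(pmax(e - 1e-9, s) / 3600)
    if (attribute == "start") h_hi <- h_lo
    n_bins <- h_hi - h_lo + 1
    idx <- rep(seq_len(nrow(events)), n_bins)
    hour <- unlist(purrr::map2(h_lo, h_hi, seq))
    if (attribute == "prorata") {
      ov <- pmax(0, pmin(e[idx], (hour + 1) * 3600) - pmax(s[idx], hour * 3600))
      dur <- pmax(e[idx] - s[idx], 1e-9)
      w <- ifelse(e[idx] > s[idx], ov / dur, 1)
    } else {
      w <- 1
    }
    contrib <- tibble::tibble(events[idx, keys, drop = FALSE],
                              abs_hour = hour,
                              intake_g = events$intake_g[idx] * w)
  }
  grid_keys <- dplyr::distinct(events[keys])
  grid <- tidyr::crossing(grid_keys,
                          day = as.integer(days), hour_bin = 0:23)
  if (!is.null(contrib)) {
    contrib <- contrib |>
      dplyr::mutate(day = as.integer(.data$abs_hour %/% 24) + min(days),
                    hour_bin = as.integer(.data$abs_hour %% 24)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "day", "hour_bin")))) |>
      dplyr::summarise(intake_g = sum(.data$intake_g), .groups = "drop")
    grid <- dplyr::left_join(grid, contrib, by = c(keys, "day", "hour_bin"))
  } else {
    grid$intake_g <- NA_real_
  }
  L <- schedule$light_off - schedule$light_on
  grid |>
    dplyr::mutate(
      intake_g = dplyr::coalesce(.data$intake_g, 0),
      clock_hour = (.data$hour_bin + schedule$light_on) %% 24,
      cycle = ifelse(.data$hour_bin < L, "light", "dark"),
      intake_kcal = .data$intake_g * diet$energy_density) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "day", "hour_bin")))) |>
    dplyr::select(dplyr::all_of(c(keys, "day", "hour_bin", "clock_hour",
                                  "cycle", "intake_g", "intake_kcal")))
}

#' Zero-intake hours per animal-day
#'
#' Counts the clock-hour bins with exactly zero intake (on the gram scale,
#' i.e. before energy conversion, with intakes already quantized to the
#' balance resolution), split by light/dark cycle.
#'
#' @param hourly Output of [hourly_bin()].
#' @return A tibble per animal(-phase)-day: `zero_total`, `zero_light`,
#'   `zero_dark`.
#' @export
zero_intake_hours <- function(hourly) {
  keys <- intersect(c("animal_id", "phase", "day"), names(hourly))
  hourly |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      zero_total = sum(.data$intake_g == 0),
      zero_light = sum(.data$intake_g == 0 & .data$cycle == "light"),
      zero_dark = sum(.data$intake_g == 0 & .data$cycle == "dark"),
      .groups = "drop")
}

#' Per-cycle meal-pattern summary
#'
#' Cohort bookkeeping per animal (and `phase` if present) and light/dark
#' cycle: mean daily intake, mean daily meal count and per-meal means of
#' size, duration, ingestion rate, intermeal interval and satiety ratio.
#' Intervals and satiety ratios belong to the cycle of the meal that
#' precedes them. Cycles with meals but no following interval report `NA`
#' (absent), never zero.
#'
#' @param meals Annotated meal tibble from [segment_meals()] /
#'   [annotate_meals()].
#' @return A tibble per animal(-phase) and cycle with `n_days`,
#'   `total_kcal_day`, `meals_day` and `mean_*` columns.
#' @export
cycle_summary <- function(meals) {
  keys <- intersect(c("animal_id", "phase"), names(meals))
  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  meals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "cycle")))) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      n_meals = dplyr::n(),
      total_kcal_day = sum(.data$size_kcal) / n_days,
      total_g_day = sum(.data$size_g) / n_days,
      meals_day = dplyr::n() / n_days,
      mean_size_kcal = mean_or_na(.data$size_kcal),
      mean_duration_min = mean_or_na(.data$duration_min),
      mean_rate_kcal_min = mean_or_na(.data$ingestion_rate),
      mean_imi_min = mean_or_na(.data$imi_next),
      mean_sr = mean_or_na(.data$sr_next),
      .groups = "drop")
}

#' Two-point smoothed temporal profile with SEM envelope
#'
#' Applies a moving average over `window` consecutive points to each
#' animal's ordered series, then summarises across animals per time point
#' as mean +/- SEM. Given a bare numeric vector, returns the smoothed
#' series (length `n - window + 1`); series shorter than the window are
#' returned unchanged with a warning.
#'
#' @param data Numeric vector, or a tibble with `animal_id`, a time column
#'   and a value column.
#' @param time,value Column names (tidy-eval) when `data` is a tibble.
#' @param window Points per moving average. Default 2.
#' @return Smoothed numeric vector, or a tibble `time`, `mean`, `sem`,
#'   `lower`, `upper`, `n`.
#' @export
smooth_profile <- function(data, time, value, window = 2) {
  roll <- function(x) {
    if (length(x) < window) {
      warning("series shorter than smoothing window; returned unchanged",
              call. = FALSE)
      return(x)
    }
    stats::filter(x, rep(1 / window, window), sides = 1)[window:length(x)]
  }
  if (is.numeric(data)) return(as.numeric(roll(data)))
  tcol <- rlang::as_name(rlang::enquo(time))
  vcol <- rlang::as_name(rlang::enquo(value))
  keys <- intersect(c("phase"), names(data))
  sm <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "animal_id")))) |>
    dplyr::arrange(.data[[tcol]], .by_group = TRUE) |>
    dplyr::filter(dplyr::n() >= window) |>
    dplyr::mutate(.sm = as.numeric(
      stats::filter(.data[[vcol]], rep(1 / window, window), sides = 1))) |>
    dplyr::slice(-seq_len(window - 1)) |>
    dplyr::ungroup()
  sm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, tcol)))) |>
    dplyr::summarise(mean = mean(.data$.sm),
                     sem = stats::sd(.data$.sm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(lower = .data$mean - .data$sem,
                  upper = .data$mean + .data$sem) |>
    dplyr::rename(time = dplyr::all_of(tcol))
}

#' Satiety-ratio clock profile
#'
#' Groups satiety ratios by clock bin (default 2 h) of the meal that
#' precedes each interval and summarises mean +/- SEM per bin (and per
#' `phase` if present). Bins without any interval are absent from the
#' output rather than reported as zero.
#'
#' @param meals Annotated meal tibble.
#' @param bin_h Clock bin width in hours. Default 2.
#' @return A tibble `clock_bin` (bin start hour), `mean_sr`, `sem_sr`, `n`.
#' @export
sr_time_profile <- function(meals, bin_h = 2) {
  keys <- intersect(c("phase"), names(meals))
  meals |>
    dplyr::filter(!is.na(.data$sr_next)) |>
    dplyr::mutate(clock_bin = floor(clock_hour(.data$start) / bin_h) * bin_h) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "clock_bin")))) |>
    dplyr::summarise(mean_sr = mean(.data$sr_next),
                     sem_sr = stats::sd(.data$sr_next) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Plot-ready raster and radial tables
#'
#' `raster_export()` lays meals out for a raster plot (one row per meal:
#' onset clock hour, duration, day, cycle). `radial_export()` averages the
#' hourly intake matrix around the clock (mean over animal-days per clock
#' hour), so its 24 rows sum to the cohort mean daily intake. Both orderings
#' are deterministic.
#'
#' @param meals Annotated meal tibble.
#' @param hourly Output of [hourly_bin()].
#' @return Tidy tibbles as described.
#' @export
raster_export <- function(meals) {
  keys <- intersect(c("phase"), names(meals))
  meals |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(c(keys, "animal_id", "day"))),
      onset_clock_h = clock_hour(.data$start),
      onset_bin_h = (clock_hour(.data$start) - attr_light_on(meals)) %% 24,
      duration_min = .data$duration_min,
      size_kcal = .data$size_kcal,
      cycle = .data$cycle) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "animal_id", "day",
                                                 "onset_bin_h"))))
}

# light-onset used for raster hour alignment; meals don't carry the schedule
# so the default photoperiod anchor is used.
attr_light_on <- function(meals) 6

#' @rdname raster_export
#' @export
radial_export <- function(hourly) {
  keys <- intersect(c("phase"), names(hourly))
  hourly |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "hour_bin", "clock_hour",
                                                  "cycle")))) |>
    dplyr::summarise(mean_intake_g = mean(.data$intake_g),
                     mean_intake_kcal = mean(.data$intake_kcal),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "hour_bin"))))
}

#' Paired t test on per-animal values
#'
#' Classical paired t test comparing each animal's value between two
#' phases. Animals missing either phase are dropped with a warning; fewer
#' than two complete pairs is a contract error, and zero variance of the
#' paired differences is flagged as a degenerate case.
#'
#' @param data Tibble with one row per animal x phase.
#' @param value,phase,animal Column names (tidy-eval).
#' @param alternative Passed to [stats::t.test()]. Default two-sided.
#' @return A one-row tibble: `estimate` (mean difference, second phase
#'   level minus first), `statistic`, `p_value`, `n_pairs`.
#' @export
paired_t <- function(data, value, phase = phase, animal = animal_id,
                     alternative = "two.sided") {
  vcol <- rlang::as_name(rlang::enquo(value))
  pcol <- rlang::as_name(rlang::enquo(phase))
  acol <- rlang::as_name(rlang::enquo(animal))
  if (length(unique(data[[pcol]])) != 2)
    stop("contract error: exactly two phases required", call. = FALSE)
  wide <- data |>
    dplyr::select(dplyr::all_of(c(acol, pcol, vcol))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(pcol),
                       values_from = dplyr::all_of(vcol))
  lv <- setdiff(names(wide), acol)
  if (length(lv) != 2)
    stop("contract error: exactly two phases required", call. = FALSE)
  complete <- stats::complete.cases(wide[lv])
  if (any(!complete)) {
    warning(sum(!complete), " unpaired animal(s) dropped", call. = FALSE)
    wide <- wide[complete, ]
  }
  if (nrow(wide) < 2)
    stop("contract error: paired t test needs >= 2 complete pairs", call. = FALSE)
  d <- wide[[lv[2]]] - wide[[lv[1]]]
  if (stats::sd(d) == 0 && any(d != 0))
    stop("degenerate case: paired differences have zero variance", call. = FALSE)
  if (all(d == 0)) {
    return(tibble::tibble(estimate = 0, statistic = 0, p_value = 1,
                          n_pairs = nrow(wide)))
  }
  tt <- stats::t.test(wide[[lv[2]]], wide[[lv[1]]], paired = TRUE,
                      alternative = alternative)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 p_value = tt$p.value, n_pairs = nrow(wide))
}

#' One-tailed Fisher exact test of proportions
#'
#' Exact hypergeometric tail probability for a 2x2 count table, in a stated
#' direction: `"less"` tests depletion of the top-left cell relative to the
#' margins, `"greater"` its enrichment (so swapping the rows maps one tail
#' onto the other).
#'
#' @param table A 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @param direction `"less"` or `"greater"`.
#' @return A one-row tibble: the four counts, `direction`, `p_value`.
#' @examples
#' # zero-intake hours (of 24) at baseline vs day 14
#' fisher_one_tailed(matrix(c(1, 23, 12, 12), 2, byrow = TRUE), "less")
#' @export
fisher_one_tailed <- function(table, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m)))
    stop("contract error: need a 2x2 table of non-negative integer counts",
         call. = FALSE)
  if (all(m == 0) || any(rowSums(m) == 0))
    stop("contract error: a group margin of the 2x2 table is zero", call. = FALSE)
  p <- stats::fisher.test(m, alternative = direction)$p.value
  tibble::tibble(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
                 direction = direction, p_value = min(p, 1))
}
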