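#' Intake within a time window
#'
#' Sums event intake over a half-open window, with events straddling a
#' window edge contributing pro-rata by time (consistent with hourly
#' binning). Zero-duration events count if their start lies in the window.
#'
#' @param events Feeding-event tibble.
#' @param from,to POSIXct window bounds.
#' @return Total intake in g.
#' @export
window_intake <- function(events, from, to) {
  if (!nrow(events)) return(0)
  s <- as.numeric(events$start); e <- as.numeric(events$end)
  dur <- e - s
  ov <- pmax(0, pmin(e, as.numeric(to)) - pmax(s, as.numeric(from)))
  w <- ifelse(dur > 0, ov / dur,
              as.numeric(s >= as.numeric(from) & s < as.numeric(to)))
  sum(events$intake_g * w)
}

check_window_covered <- function(events, days, schedule = light_schedule()) {
  if (!nrow(events))
    stop("contract error: no events in record; response window not covered",
         call. = FALSE)
  rng <- range(study_day(events$start, schedule))
  if (any(days < rng[1] | days > rng[2]))
    stop("contract error: requested day(s) outside the recorded range",
         call. = FALSE)
}

# Apply window_intake per animal(-phase) over a window grid. `grid` carries
# columns `from` and `to` (POSIXct) plus any label columns; the result is
# the key columns x grid with an `intake_g` column (0 for empty windows).
window_grid <- function(events, keys, grid) {
  key_df <- dplyr::distinct(events[keys])
  purrr::map_dfr(seq_len(nrow(key_df)), function(i) {
    sub <- dplyr::semi_join(events, key_df[i, , drop = FALSE], by = keys)
    out <- grid
    out$intake_g <- purrr::map2_dbl(grid$from, grid$to,
                                    ~window_intake(sub, .x, .y))
    dplyr::bind_cols(key_df[rep(i, nrow(grid)), , drop = FALSE], out)
  })
}

#' Feeding response to dark-cycle onset
#'
#' Hourly and cumulative intake over the first `hours` hours of the dark
#' cycle (from lights-off), per animal-day. Nocturnal feeders respond to
#' the lights-out cue with a burst of feeding; in cachexia this response
#' initiates normally but is not sustained past the first dark hour.
#'
#' @param events Feeding-event tibble (a `phase` column is carried through).
#' @param schedule A [light_schedule()].
#' @param days Study days to evaluate; default all days in the record.
#' @param hours Window length in dark hours. Default 4.
#' @return A tibble per animal(-phase) x day x dark hour (1-based):
#'   `intake_g` for that hour and `cum_g` cumulative intake.
#' @export
dark_onset_response <- function(events, schedule = light_schedule(),
                                days = NULL, hours = 4) {
  keys <- intersect(c("animal_id", "phase"), names(events))
  if (!nrow(events))
    stop("contract error: no events in record", call. = FALSE)
  days <- days %||% sort(unique(study_day(events$start, schedule)))
  check_window_covered(events, days, schedule)
  L <- schedule$light_off - schedule$light_on
  grid <- tidyr::crossing(day = as.integer(days), hour = seq_len(hours)) |>
    dplyr::mutate(from = day_start(.data$day, schedule) +
                    (L + .data$hour - 1) * 3600,
                  to = day_start(.data$day, schedule) + (L + .data$hour) * 3600)
  window_grid(events, keys, grid) |>
    dplyr::select(-dplyr::all_of(c("from", "to"))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "day")))) |>
    dplyr::arrange(.data$hour, .by_group = TRUE) |>
    dplyr::mutate(cum_g = cumsum(.data$intake_g)) |>
    dplyr::ungroup()
}

#' Refeeding response after an overnight fast
#'
#' Intake in the first 1 h and 4 h after food is returned at light onset,
#' following a dark-cycle (12-h) fast. The fast window (the preceding dark
#' cycle) is verified to be empty of events first; any event found there is
#' a validation error. Both windows are reported as first-class outputs.
#'
#' @param events Feeding-event tibble covering the refeed day (and the fast
#'   night before it).
#' @param schedule A [light_schedule()].
#' @param day The refeed study day (food returned at its light onset).
#' @param windows Window lengths in hours. Default `c(1, 4)`.
#' @return A tibble per animal(-phase) x window: `window_h`, `intake_g`.
#' @export
refeed_response <- function(events, schedule = light_schedule(), day,
                            windows = c(1, 4)) {
  keys <- intersect(c("animal_id", "phase"), names(events))
  check_window_covered(events, day, schedule)
  t_return <- day_start(day, schedule)
  dark_h <- 24 - (schedule$light_off - schedule$light_on)
  fast_from <- t_return - dark_h * 3600
  in_fast <- events$start < t_return & events$end > fast_from
  if (any(in_fast))
    stop("validation error: ", sum(in_fast),
         " event(s) found inside the starvation window ",
         ts_fmt(fast_from), " - ", ts_fmt(t_return), call. = FALSE)
  grid <- tibble::tibble(window_h = windows, from = t_return,
                         to = t_return + windows * 3600)
  window_grid(events, keys, grid) |>
    dplyr::select(-dplyr::all_of(c("from", "to")))
}

#' Ghrelin- (or vehicle-) evoked feeding response
#'
#' Intake over the response window following an i.p. injection at a fixed
#' clock time in the light cycle. The vehicle arm is summarised
#' identically, as the null comparison.
#'
#' @param events Feeding-event tibble for the injection day(s).
#' @param schedule A [light_schedule()].
#' @param day Injection study day(s); default all days in the record.
#' @param injection_time Clock hour of injection. Default 8 (08:00).
#' @param window_h Response window in hours. Default 2.
#' @return A tibble per animal(-phase) x day: `intake_g` over the window.
#' @export
ghrelin_response <- function(events, schedule = light_schedule(), day = NULL,
                             injection_time = 8, window_h = 2) {
  if (is.null(injection_time) || !is.finite(injection_time))
    stop("contract error: injection time is required", call. = FALSE)
  keys <- intersect(c("animal_id", "phase"), names(events))
  if (!nrow(events))
    stop("contract error: no events in record", call. = FALSE)
  day <- day %||% sort(unique(study_day(events$start, schedule)))
  check_window_covered(events, day, schedule)
  offset_h <- (injection_time - schedule$light_on) %% 24
  grid <- tibble::tibble(day = as.integer(day)) |>
    dplyr::mutate(from = day_start(.data$day, schedule) + offset_h * 3600,
                  to = .data$from + window_h * 3600)
  window_grid(events, keys, grid) |>
    dplyr::select(-dplyr::all_of(c("from", "to")))
}

#' Within-animal contrast of an evoked response
#'
#' Percent change of the cohort means between two phases plus the paired
#' t-test over animals. Animals observed in only one phase are dropped with
#' a warning (via [paired_t()]). Identical phases give 0% and p = 1.
#'
#' @param data Tibble with one row per animal x phase and a value column.
#' @param value Value column (tidy-eval), e.g. `intake_g`.
#' @param phase,animal Phase and animal columns.
#' @return One-row tibble: per-phase means, `pct_change` (raw),
#'   `pct_change_rounded` (whole percent), `p_value`, `n_pairs`.
#' @export
evoked_contrast <- function(data, value = intake_g, phase = phase,
                            animal = animal_id) {
  vcol <- rlang::as_name(rlang::enquo(value))
  pcol <- rlang::as_name(rlang::enquo(phase))
  acol <- rlang::as_name(rlang::enquo(animal))
  lv <- sort(unique(data[[pcol]]))
  if (length(lv) != 2)
    stop("contract error: exactly two phases required", call. = FALSE)
  complete <- names(which(table(unique(data[c(acol, pcol)])[[acol]]) == 2))
  dropped <- setdiff(unique(data[[acol]]), complete)
  if (length(dropped))
    warning(length(dropped), " unpaired animal(s) dropped", call. = FALSE)
  data <- data[data[[acol]] %in% complete, ]
  means <- tapply(data[[vcol]], data[[pcol]], mean)
  tt <- rlang::inject(paired_t(data, !!rlang::sym(vcol), !!rlang::sym(pcol),
                               !!rlang::sym(acol)))
  tibble::tibble(
    phase_a = lv[1], mean_a = unname(means[lv[1]]),
    phase_b = lv[2], mean_b = unname(means[lv[2]]),
    pct_change = percent_change(unname(means[lv[1]]), unname(means[lv[2]])),
    pct_change_rounded = percent_change(unname(means[lv[1]]),
                                        unname(means[lv[2]]), round_to = 0),
    p_value = tt$p_value, n_pairs = tt$n_pairs)
}
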