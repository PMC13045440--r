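#' Merge feeding events into candidate meal clusters
#'
#' Consecutive hopper interactions of one animal belong to the same cluster
#' when the non-eating gap between them (next start minus previous end) is
#' shorter than `min_imi` minutes; a gap of exactly `min_imi` or more starts
#' a new cluster. Cluster intake is the sum of its event intakes and the
#' cluster span runs from the first start to the last end.
#'
#' @param events Tibble with `animal_id`, `start`, `end`, `intake_g`, sorted
#'   by start within animal and non-overlapping (as returned by
#'   [read_events()] or [generate_feeding_events()]). Extra columns are
#'   preserved from the first event of each cluster.
#' @param min_imi Minimum intermeal interval in minutes. Default 5.
#' @return A tibble of clusters: `animal_id`, `meal_id`, `start`, `end`,
#'   `size_g`, `duration_min`, `n_events`.
#' @examples
#' ev <- tibble::tibble(
#'   animal_id = "M01",
#'   start = ms_time(0) + c(0, 240, 900),
#'   end = ms_time(0) + c(120, 360, 960),
#'   intake_g = c(0.05, 0.04, 0.05))
#' merge_events_to_meals(ev)
#' @export
merge_events_to_meals <- function(events, min_imi = 5) {
  req <- c("animal_id", "start", "end", "intake_g")
  stopifnot(all(req %in% names(events)))
  if (!nrow(events)) {
    return(tibble::tibble(animal_id = character(), meal_id = integer(),
                          start = ms_origin()[0], end = ms_origin()[0],
                          size_g = numeric(), duration_min = numeric(),
                          n_events = integer()))
  }
  check_sorted(events)
  events |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      gap_min = (as.numeric(.data$start) -
                   as.numeric(dplyr::lag(.data$end))) / 60,
      meal_id = cumsum(is.na(.data$gap_min) | .data$gap_min >= min_imi)) |>
    dplyr::group_by(.data$animal_id, .data$meal_id) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      size_g = sum(.data$intake_g),
      duration_min = (as.numeric(max(.data$end)) -
                        as.numeric(min(.data$start))) / 60,
      n_events = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$animal_id, .data$start)
}

check_sorted <- function(events) {
  by_animal <- split(seq_len(nrow(events)), events$animal_id)
  for (i in by_animal) {
    s <- as.numeric(events$start[i]); e <- as.numeric(events$end[i])
    if (is.unsorted(s))
      stop("contract error: events must be sorted by start time within animal",
           call. = FALSE)
    if (length(i) > 1 && any(e[-length(i)] > s[-1] + 1e-9))
      stop("contract error: events overlap within animal", call. = FALSE)
  }
  invisible(TRUE)
}

#' Filter clusters to meals by minimum intake
#'
#' Clusters with intake at or below `min_size` grams (sub-threshold
#' "nibbles") are discarded. The comparison is strict (`>`), and removal
#' happens after merging but before interval annotation, so a discarded
#' nibble never terminates an intermeal interval: the interval of the
#' preceding meal spans across it.
#'
#' @param clusters Output of [merge_events_to_meals()].
#' @param min_size Minimum meal intake in g (strict). Default 0.03.
#' @return The clusters with `size_g > min_size`.
#' @export
filter_meals <- function(clusters, min_size = 0.03) {
  dplyr::filter(clusters, .data$size_g > min_size)
}

#' Annotate meals with meal-level parameters
#'
#' Adds the five canonical meal-pattern parameters: meal size in kcal
#' (grams times diet energy density), meal duration (min), ingestion rate
#' (kcal/min, size over duration, with a 1-s duration floor so instantaneous
#' events stay finite), the intermeal interval to the next meal
#' (`imi_next`, min, end-of-meal to start-of-next) and the satiety ratio
#' (`sr_next`, min per 0.1 kcal: the following interval divided by this
#' meal's energy). The last meal of each animal's record has no following
#' interval, so `imi_next`/`sr_next` are `NA`. Each meal is assigned to the
#' light or dark cycle containing its start; the following interval inherits
#' the cycle of the meal that precedes it.
#'
#' @param meals Output of [filter_meals()] (or any meal tibble with
#'   `animal_id`, `start`, `end`, `size_g`, `duration_min`).
#' @param diet A [diet_spec()] or energy density in kcal/g.
#' @param schedule A [light_schedule()].
#' @param duration_floor_s Duration floor in seconds for the ingestion-rate
#'   denominator. Default 1.
#' @details Intervals are only meaningful within one continuous recording:
#'   when the supplied meals skip one or more whole study days (the animal
#'   was out of the cage, or a non-adjacent subset of days is being
#'   analysed), the interval chain is terminated at the gap and the last
#'   meal before it gets `NA` for `imi_next`/`sr_next`.
#' @return A meal tibble with added `day`, `cycle`, `size_kcal`,
#'   `ingestion_rate`, `imi_next`, `sr_next`.
#' @export
annotate_meals <- function(meals, diet = diet_spec(),
                           schedule = light_schedule(),
                           duration_floor_s = 1) {
  diet <- as_diet(diet)
  meals |>
    dplyr::mutate(
      day = study_day(.data$start, schedule),
      cycle = cycle_of(.data$start, schedule),
      size_kcal = .data$size_g * diet$energy_density,
      ingestion_rate = .data$size_kcal /
        pmax(.data$duration_min, duration_floor_s / 60)) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      .block = cumsum(c(0, pmax(diff(.data$day) - 1, 0)))) |>
    dplyr::group_by(.data$animal_id, .data$.block) |>
    dplyr::mutate(
      imi_next = (as.numeric(dplyr::lead(.data$start)) -
                    as.numeric(.data$end)) / 60,
      sr_next = .data$imi_next / (.data$size_kcal / 0.1)) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(".block"))
}

#' Segment feeding events into annotated meals
#'
#' Convenience wrapper chaining [merge_events_to_meals()], [filter_meals()]
#' and [annotate_meals()]. The default order (merge first, then size-filter,
#' then compute intervals across removed clusters) treats sub-threshold
#' nibbles as non-meals that neither count nor interrupt intervals;
#' `filter_first = TRUE` instead drops sub-threshold raw events before
#' merging, for sensitivity analyses of the threshold-ordering choice.
#'
#' @inheritParams merge_events_to_meals
#' @inheritParams filter_meals
#' @inheritParams annotate_meals
#' @param filter_first Apply the size filter to raw events before merging.
#'   Default `FALSE`.
#' @return An annotated meal tibble (see [annotate_meals()]).
#' @examples
#' cfg <- clams_config(seed = 1, n_animals = 1)
#' meals <- segment_meals(generate_feeding_events(cfg, days = 1))
#' dplyr::count(meals, cycle)
#' @export
segment_meals <- function(events, min_imi = 5, min_size = 0.03,
                          diet = diet_spec(), schedule = light_schedule(),
                          filter_first = FALSE) {
  if (filter_first) events <- dplyr::filter(events, .data$intake_g > min_size)
  events |>
    merge_events_to_meals(min_imi = min_imi) |>
    filter_meals(min_size = min_size) |>
    annotate_meals(diet = diet, schedule = schedule)
}

#' Timestamp helper for examples and tests
#'
#' Builds a POSIXct time `sec` seconds after light onset of study day `day`
#' on the package's fixed clock anchor.
#'
#' @param sec Seconds after light onset.
#' @param day Study day. Default 1.
#' @param schedule A [light_schedule()].
#' @return POSIXct vector.
#' @export
ms_time <- function(sec, day = 1, schedule = light_schedule()) {
  day_start(day, schedule) + sec
}
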