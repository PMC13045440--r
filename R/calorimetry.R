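#' Respiratory exchange ratio
#'
#' RER = VCO2 / VO2, dimensionless. Approaches 0.7 under pure fat oxidation
#' and 1.0 under pure carbohydrate oxidation.
#'
#' @param vo2 Oxygen consumption, L/h (> 0).
#' @param vco2 Carbon dioxide production, L/h.
#' @return Numeric vector of ratios.
#' @examples
#' rer(1.0, 0.7)
#' @export
rer <- function(vo2, vco2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0))
    stop("contract error: vo2 must be positive", call. = FALSE)
  vco2 / vo2
}

#' Lusk caloric value
#'
#' Heat equivalent of oxygen as a function of RER, the linear interpolation
#' of Lusk's table used by metabolic-cage software:
#' CV = 3.815 + 1.232 x RER, in kcal per litre of O2. RER values outside
#' the physiological table range \[0.7, 1.0\] are clamped to it with a
#' warning (protein oxidation is ignored, as is conventional for
#' respiratory calorimetry in ad libitum-fed rodents).
#'
#' @param rer Respiratory exchange ratio.
#' @return Caloric value in kcal/L O2.
#' @examples
#' lusk_caloric_value(c(0.707, 1.0))
#' @export
lusk_caloric_value <- function(rer) {
  if (any(rer < 0.7 | rer > 1.0, na.rm = TRUE)) {
    warning("RER outside [0.7, 1.0] clamped to the Lusk table range",
            call. = FALSE)
    rer <- pmin(pmax(rer, 0.7), 1.0)
  }
  3.815 + 1.232 * rer
}

#' Heat production (energy expenditure)
#'
#' Heat (kcal/h) = CV(RER) x VO2, the standard indirect-calorimetry
#' energy-expenditure equation.
#'
#' @inheritParams rer
#' @return Heat production in kcal/h.
#' @examples
#' heat(0.06, 0.06 * 0.85)
#' @export
heat <- function(vo2, vco2) {
  lusk_caloric_value(rer(vo2, vco2)) * vo2
}

#' Add energy columns to calorimetry samples
#'
#' Convenience verb appending `rer`, `cv_kcal_l` and `heat_kcal_h` to a
#' gas-exchange tibble.
#'
#' @param samples Tibble with `vo2_l_h` and `vco2_l_h`.
#' @return The tibble with the three derived columns.
#' @export
add_energy <- function(samples) {
  r <- rer(samples$vo2_l_h, samples$vco2_l_h)
  cv <- suppressWarnings(lusk_caloric_value(r))
  dplyr::mutate(samples, rer = r, cv_kcal_l = cv,
                heat_kcal_h = cv * .data$vo2_l_h)
}

#' Ambulatory event counts from beam breaks
#'
#' Quantifies locomotion by the two-consecutive-beams rule: the X-axis
#' break stream is split into maximal runs separated by more than
#' `quiescence_gap_s` seconds of quiescence, and a run counts as one
#' ambulatory event when it contains breaks of at least two distinct
#' adjacent beam positions. Repeated breaks of a single beam (grooming,
#' scratching in place) are stationary and never counted.
#'
#' @param activity Beam-break tibble (`animal_id`, `time`, `axis`,
#'   `beam_index`; a `phase` column is carried through).
#' @param schedule A [light_schedule()].
#' @param quiescence_gap_s Gap (s) that delimits runs. Default 1.
#' @return A tibble per animal(-phase) x day x cycle with `ambulatory`
#'   counts (days/cycles with no X-axis breaks simply do not appear).
#' @export
ambulatory_count <- function(activity, schedule = light_schedule(),
                             quiescence_gap_s = 1) {
  keys <- intersect(c("animal_id", "phase"), names(activity))
  x <- activity[activity$axis == "X", , drop = FALSE]
  if (!nrow(x)) {
    return(tibble::tibble(animal_id = character(), day = integer(),
                          cycle = character(), ambulatory = integer()))
  }
  x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(c(keys, "time"))))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(run = cumsum(
      c(TRUE, diff(as.numeric(.data$time)) > quiescence_gap_s))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "run")))) |>
    dplyr::summarise(
      t0 = .data$time[1],
      ambulatory = is_ambulatory_run(.data$beam_index), .groups = "drop") |>
    dplyr::mutate(day = study_day(.data$t0, schedule),
                  cycle = cycle_of(.data$t0, schedule)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "day", "cycle")))) |>
    dplyr::summarise(ambulatory = sum(.data$ambulatory), .groups = "drop")
}

# A run is ambulatory iff it covers two adjacent beam positions.
is_ambulatory_run <- function(beams) {
  u <- sort(unique(beams))
  length(u) >= 2 && any(diff(u) == 1L)
}

#' Per-cycle energy and activity summary
#'
#' Aggregates calorimetry (and optionally ambulatory activity) per animal
#' (-phase) and light/dark cycle: mean VO2, mean RER, mean heat production
#' and mean daily ambulatory count.
#'
#' @param samples Gas-exchange tibble.
#' @param activity Optional beam-break tibble.
#' @param schedule A [light_schedule()].
#' @return An `EnergySummary`-style tibble.
#' @export
cycle_energy_summary <- function(samples, activity = NULL,
                                 schedule = light_schedule()) {
  keys <- intersect(c("animal_id", "phase"), names(samples))
  en <- add_energy(samples) |>
    dplyr::mutate(cycle = cycle_of(.data$time, schedule)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "cycle")))) |>
    dplyr::summarise(mean_vo2_l_h = mean(.data$vo2_l_h),
                     mean_rer = mean(.data$rer),
                     mean_heat_kcal_h = mean(.data$heat_kcal_h),
                     n_scans = dplyr::n(), .groups = "drop")
  if (!is.null(activity)) {
    amb <- ambulatory_count(activity, schedule) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "cycle")))) |>
      dplyr::summarise(ambulatory_day = mean(.data$ambulatory), .groups = "drop")
    en <- dplyr::left_join(en, amb, by = c(keys, "cycle"))
  }
  en
}

#' Percent change
#'
#' `100 * (b - a) / a`: the signed percent change from a reference value
#' `a` to a comparison value `b`. Undefined when the reference is zero
#' (returns `NA` with a warning).
#'
#' @param a Reference value(s).
#' @param b Comparison value(s).
#' @param round_to Optional number of digits (whole percent = 0); `NULL`
#'   (default) leaves the value unrounded.
#' @return Percent change.
#' @examples
#' percent_change(0.81, 0.39)   # refeeding response, baseline -> day 14
#' @export
percent_change <- function(a, b, round_to = NULL) {
  out <- ifelse(a == 0, NA_real_, 100 * (b - a) / a)
  if (any(a == 0)) warning("percent change undefined for zero reference",
                           call. = FALSE)
  if (!is.null(round_to)) out <- round(out, round_to)
  out
}
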