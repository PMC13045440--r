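#' Generate synthetic indirect-calorimetry scans
#'
#' Produces gas-exchange samples (VO2, VCO2 in L/h) on a regular scan grid
#' for each animal. Cycle-mean VO2 and the implied respiratory exchange
#' ratio (VCO2/VO2) follow the per-state setpoints: higher VO2 and RER in
#' the dark (nocturnal activity and carbohydrate oxidation), and in the
#' cachectic `kpc_d14` state VO2 lowered by ~8% in the light and ~21-23% in
#' the dark with a shift of RER towards lipid oxidation. Multiplicative
#' noise is applied per scan; values are rounded to 4 decimals so that
#' serialization round-trips exactly.
#'
#' @inheritParams generate_feeding_events
#' @return A tibble with columns `animal_id`, `time`, `vo2_l_h`, `vco2_l_h`.
#' @export
generate_calorimetry <- function(config, days = 3, start_day = 1) {
  stopifnot(inherits(config, "ms_config"))
  if (!is.numeric(days) || days < 1)
    stop("configuration error: `days` must be >= 1", call. = FALSE)
  mp <- config$metabolic
  step <- mp$scan_interval_min * 60
  ids <- animal_ids(config)
  purrr::map_dfr(seq_along(ids), function(a) {
    withr::with_seed(sub_seed(config$seed, a, stream = 2L, block = start_day), {
      t0 <- day_start(start_day, config$schedule)
      times <- t0 + seq(0, days * 86400 - step, by = step)
      cyc <- cycle_of(times, config$schedule)
      vo2 <- ifelse(cyc == "light", mp$vo2_light, mp$vo2_dark) *
        (1 + stats::rnorm(length(times), 0, mp$vo2_cv))
      vo2 <- pmax(vo2, 0.005)
      rer <- ifelse(cyc == "light", mp$rer_light, mp$rer_dark) +
        stats::rnorm(length(times), 0, mp$rer_sd)
      rer <- pmin(pmax(rer, 0.70), 1.045)
      tibble::tibble(animal_id = ids[a], time = times,
                     vo2_l_h = round(vo2, 4),
                     vco2_l_h = round(rer * vo2, 4))
    })
  })
}

#' Generate synthetic beam-break activity streams
#'
#' Emits infrared photocell break events along the X (horizontal) and Z
#' (rearing) axes. Locomotion appears as short runs of breaks over
#' consecutive, distinct X beams (ambulatory by the two-adjacent-beams
#' rule); grooming/stationary behaviour as repeated breaks of a single
#' beam; both are generated so the downstream ambulatory filter is
#' genuinely exercised. Dark-cycle run rates are 3.8-fold the light-cycle
#' rate at baseline, and reduced by 67% (dark) / 48% (light) in `kpc_d14`.
#'
#' @inheritParams generate_feeding_events
#' @return A tibble with columns `animal_id`, `time`, `axis` ("X"/"Z") and
#'   `beam_index`, sorted by animal and time.
#' @export
generate_activity <- function(config, days = 3, start_day = 1) {
  stopifnot(inherits(config, "ms_config"))
  if (!is.numeric(days) || days < 1)
    stop("configuration error: `days` must be >= 1", call. = FALSE)
  ap <- config$activity
  ids <- animal_ids(config)
  L <- config$schedule$light_off - config$schedule$light_on
  purrr::map_dfr(seq_along(ids), function(a) {
    withr::with_seed(sub_seed(config$seed, a, stream = 3L, block = start_day), {
      out <- purrr::map_dfr(seq_len(days), function(d) {
        day <- start_day + d - 1L
        t0 <- as.numeric(day_start(day, config$schedule))
        runs <- rbind(
          gen_runs(t0, 0, L, ap$amb_runs_h_light, ap, ambulatory = TRUE),
          gen_runs(t0, L, 24, ap$amb_runs_h_dark, ap, ambulatory = TRUE),
          gen_runs(t0, 0, L, ap$stationary_rate_h, ap, ambulatory = FALSE),
          gen_runs(t0, L, 24, ap$stationary_rate_h, ap, ambulatory = FALSE))
        z_n <- stats::rpois(1, ap$z_rate_h * 24)
        z <- if (z_n > 0)
          data.frame(time = t0 + stats::runif(z_n, 0, 86400 - 1),
                     axis = "Z",
                     beam_index = sample.int(ap$n_beams, z_n, replace = TRUE) - 1L)
          else NULL
        rbind(runs, z)
      })
      if (is.null(out) || !nrow(out)) {
        return(tibble::tibble(animal_id = character(), time = ms_origin()[0],
                              axis = character(), beam_index = integer()))
      }
      out <- out[order(out$time), ]
      tibble::tibble(animal_id = ids[a],
                     time = ms_origin() + round(out$time - as.numeric(ms_origin()), 1),
                     axis = out$axis, beam_index = as.integer(out$beam_index))
    })
  })
}

# Beam-break runs within one cycle window (hours from_h..to_h of the day).
# Ambulatory runs sweep >= 2 consecutive distinct beams; stationary runs
# repeat one beam. Run starts are separated by > 5 s so runs cannot merge
# under the default 1-s quiescence gap.
gen_runs <- function(t0, from_h, to_h, rate_h, ap, ambulatory) {
  n <- stats::rpois(1, rate_h * (to_h - from_h))
  if (n == 0) return(NULL)
  starts <- sort(stats::runif(n, from_h * 3600, to_h * 3600 - 30))
  starts <- starts[c(TRUE, diff(starts) > 12)]
  n <- length(starts)
  if (ambulatory) {
    lens <- 2L + stats::rpois(n, 2)
    b0 <- sample.int(ap$n_beams - 1L, n, replace = TRUE) - 1L
    dirn <- sample(c(-1L, 1L), n, replace = TRUE)
    pos <- sequence(lens) - 1L
    idx <- rep(seq_len(n), lens)
    beams <- pmin(pmax(b0[idx] + dirn[idx] * pos, 0L), ap$n_beams - 1L)
  } else {
    lens <- sample(2:5, n, replace = TRUE)
    b <- sample.int(ap$n_beams, n, replace = TRUE) - 1L
    pos <- sequence(lens) - 1L
    idx <- rep(seq_len(n), lens)
    beams <- b[idx]
  }
  data.frame(time = t0 + starts[idx] + pos * ap$intra_break_gap_s,
             axis = "X", beam_index = beams)
}

#' Generate a complete paired study
#'
#' Builds the full within-animal study: every animal is observed for
#' `days_per_phase` spontaneous days plus one fast-refeed pair and one
#' ghrelin and one vehicle day, first in the healthy `baseline` state and
#' then again in the cachectic `kpc_d14` state, with synchronous
#' calorimetry and activity streams. Day layout per phase: days 1-3
#' spontaneous (day 3 doubles as the dark-onset evaluation day), day 4 fast
#' night, day 5 refeed, day 6 ghrelin, day 7 vehicle; the kpc_d14 phase
#' occupies days 8-14, so study day 14 is the final cachectic observation.
#'
#' @param config A [clams_config()]; its `state` is ignored (both phases are
#'   generated from per-state defaults, with any `feeding`/`metabolic`/
#'   `activity` overrides applied to both).
#' @param days_per_phase Spontaneous days per phase. Default 3.
#' @return An object of class `ms_study`: a list with `manifest` (see
#'   [write_manifest()]), `events`, `calorimetry` and `activity` tibbles.
#' @examples
#' study <- generate_study(clams_config(seed = 7, n_animals = 2))
#' study$manifest$phases
#' @export
generate_study <- function(config, days_per_phase = 3) {
  stopifnot(inherits(config, "ms_config"))
  phase_len <- days_per_phase + 4L
  phases <- c("baseline", "kpc_d14")
  all_ev <- list(); all_cal <- list(); all_act <- list(); rows <- list()
  for (p in seq_along(phases)) {
    ph <- phases[p]
    cfg <- clams_config(seed = config$seed, n_animals = config$n_animals,
                        state = ph, schedule = config$schedule,
                        diet = config$diet,
                        scale_resolution = config$scale_resolution)
    d0 <- (p - 1L) * phase_len + 1L
    spont_days <- seq(d0, d0 + days_per_phase - 1L)
    all_ev[[length(all_ev) + 1]] <-
      generate_feeding_events(cfg, days = days_per_phase, start_day = d0)
    all_ev[[length(all_ev) + 1]] <-
      generate_feeding_events(cfg, days = 2, protocol = protocol_spec("starve_refeed"),
                              start_day = d0 + days_per_phase)
    all_ev[[length(all_ev) + 1]] <-
      generate_feeding_events(cfg, days = 1, protocol = protocol_spec("ghrelin"),
                              start_day = d0 + days_per_phase + 2L)
    all_ev[[length(all_ev) + 1]] <-
      generate_feeding_events(cfg, days = 1, protocol = protocol_spec("vehicle"),
                              start_day = d0 + days_per_phase + 3L)
    all_cal[[p]] <- generate_calorimetry(cfg, days = phase_len, start_day = d0)
    all_act[[p]] <- generate_activity(cfg, days = phase_len, start_day = d0)
    rows[[p]] <- tibble::tibble(
      day = seq(d0, d0 + phase_len - 1L),
      phase = ph,
      protocol = c(rep("spontaneous", days_per_phase - 1L), "dark_onset",
                   "starve_refeed", "starve_refeed", "ghrelin", "vehicle"),
      role = c(rep("spontaneous", days_per_phase - 1L), "dark_onset",
               "fast_night", "refeed", "ghrelin", "vehicle"))
  }
  manifest <- list(
    animals = animal_ids(config),
    light_on = config$schedule$light_on,
    light_off = config$schedule$light_off,
    diet_energy_density = config$diet$energy_density,
    seed = config$seed,
    phases = dplyr::bind_rows(rows),
    injection_time = 8
  )
  structure(list(manifest = manifest,
                 events = dplyr::bind_rows(all_ev) |>
                   dplyr::arrange(.data$animal_id, .data$start),
                 calorimetry = dplyr::bind_rows(all_cal),
                 activity = dplyr::bind_rows(all_act)),
            class = "ms_study")
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf("<ms_study: %d animals, %d phases, %d feeding events>\n",
              length(x$manifest$animals),
              length(unique(x$manifest$phases$phase)), nrow(x$events)))
  invisible(x)
}

#' Slice a study by phase and day role
#'
#' Convenience accessor returning the feeding events of one phase, optionally
#' restricted to days with a given protocol role (e.g. `"spontaneous"`,
#' `"refeed"`, `"ghrelin"`), with `phase` and `day` columns attached.
#'
#' @param study An `ms_study`.
#' @param phase `"baseline"` or `"kpc_d14"`.
#' @param role Optional day role filter; `"spontaneous"` also includes the
#'   dark-onset evaluation day (which is spontaneous feeding).
#' @return A tibble of events with `phase` and `day` columns.
#' @export
study_slice <- function(study, phase, role = NULL) {
  stopifnot(inherits(study, "ms_study"))
  ph <- study$manifest$phases
  days <- ph$day[ph$phase == phase]
  if (!is.null(role)) {
    want <- if (identical(role, "spontaneous")) c("spontaneous", "dark_onset") else role
    days <- ph$day[ph$phase == phase & ph$role %in% want]
  }
  sched <- light_schedule(study$manifest$light_on, study$manifest$light_off)
  ev <- study$events
  ev$day <- study_day(ev$start, sched)
  ev <- ev[ev$day %in% days, ]
  ev$phase <- phase
  ev
}
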