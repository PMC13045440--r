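#' Diet specification
#'
#' Metabolisable energy density of the chow. Hopper balances report intake in
#' grams; all meal-level energetics convert with this single factor.
#'
#' @param energy_density Energy density in kcal per g of diet. Default 3.0,
#'   a typical value for standard rodent chow.
#' @return An object of class `ms_diet`.
#' @export
diet_spec <- function(energy_density = 3.0) {
  if (!is.numeric(energy_density) || length(energy_density) != 1 ||
      !is.finite(energy_density) || energy_density <= 0) {
    stop("`energy_density` must be a single positive number (kcal/g)",
         call. = FALSE)
  }
  structure(list(energy_density = energy_density), class = "ms_diet")
}

as_diet <- function(x) {
  if (inherits(x, "ms_diet")) return(x)
  diet_spec(x)
}

#' Evoked-feeding protocol specification
#'
#' Describes how a protocol day deviates from spontaneous feeding:
#' `"spontaneous"` and `"dark_onset"` leave feeding untouched (the dark-onset
#' response is an analysis window, not an intervention); `"starve_refeed"`
#' removes food over the full dark cycle and restores it at light onset;
#' `"ghrelin"` and `"vehicle"` are an injection at a fixed clock time in the
#' light cycle, with (`ghrelin`) or without (`vehicle`) an orexigenic effect.
#'
#' @param kind One of `"spontaneous"`, `"dark_onset"`, `"starve_refeed"`,
#'   `"ghrelin"`, `"vehicle"`.
#' @param injection_time Clock hour of the i.p. injection for the
#'   ghrelin/vehicle paradigms. Default 8 (08:00), i.e. two hours after light
#'   onset.
#' @param response_window_h Length in hours of the post-stimulus analysis
#'   window. Defaults: 2 (ghrelin/vehicle), 4 (dark onset), 4 (refeed).
#' @return An object of class `ms_protocol`.
#' @export
protocol_spec <- function(kind = c("spontaneous", "dark_onset",
                                   "starve_refeed", "ghrelin", "vehicle"),
                          injection_time = 8,
                          response_window_h = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(injection_time) || injection_time < 0 || injection_time >= 24)
    stop("`injection_time` must be a clock hour in [0, 24)", call. = FALSE)
  window <- response_window_h %||%
    switch(kind, ghrelin = 2, vehicle = 2, 4)
  if (!is.numeric(window) || window <= 0)
    stop("`response_window_h` must be positive", call. = FALSE)
  structure(list(kind = kind, injection_time = injection_time,
                 response_window_h = window),
            class = "ms_protocol")
}

# ---------------------------------------------------------------------------
# Default stochastic parameters, per physiological state.
#
# The feeding process is an inhomogeneous renewal process: after each meal a
# gap of at least `imi_min` minutes is drawn (shifted gamma), with per-cycle
# mean gap and meal size/duration distributions. Per-cycle gap means are
# solved from the cycle length, the mean meal duration and the target meal
# count; meal-size means from the target cycle intake divided by the count.
# The kpc_d14 state adds sampled multi-hour zero-intake blocks and reduced
# free-time meal frequency. See the methods vignette for the calibration.
# ---------------------------------------------------------------------------
feeding_defaults <- function(state = c("baseline", "kpc_d14")) {
  state <- match.arg(state)
  common <- list(
    imi_min = 5.1,          # min gap between meals (min); keeps sampled gaps
                            # above the 5-min segmentation threshold
    imi_shape = 3,          # gamma shape of the gap above imi_min
    dur_shape = 8,          # gamma shape of meal duration
    size_shape = 6,         # gamma shape of meal size
    dur_floor_min = 0.2,
    split_prob = 0.3,       # probability a meal is logged as two bouts
    pause_range_min = c(0.5, 3),  # within-meal pause (strictly < 5 min)
    post_block_delay_min = 3,
    nibble_rate_h = 0.3,    # sub-threshold events (<= 0.03 g) per hour
    refeed_boost_h = 1,     # duration of the post-fast hyperphagic hour
    animal_cv_imi = 0.12,   # between-animal lognormal SD of gap means
    animal_cv_size = 0.08   # between-animal lognormal SD of meal size
  )
  state_pars <- switch(
    state,
    baseline = list(
      light = list(imi_mean = 68, d0_mean = 25, dur_mean = 1.90,
                   size_kcal_mean = 0.385),
      dark  = list(imi_mean = 28.2, d0_mean = 15, dur_mean = 1.94,
                   size_kcal_mean = 0.3305),
      refeed_imi_mean = 8,
      ghrelin_imi_mean = 27,
      zero_blocks = NULL
    ),
    kpc_d14 = list(
      light = list(imi_mean = 80, d0_mean = 45, dur_mean = 2.00,
                   size_kcal_mean = 0.412),
      dark  = list(imi_mean = 36, d0_mean = 15, dur_mean = 2.22,
                   size_kcal_mean = 0.3645),
      refeed_imi_mean = 27,
      ghrelin_imi_mean = 47,
      zero_blocks = list(
        n_range = c(2L, 4L),       # blocks per day
        len_range = c(2L, 8L),     # consecutive hours per block
        total_range = c(10L, 12L), # daily total zero-block hours
        p_light = 0.6,             # placement bias towards the light cycle
        light_bins = 3:11,         # light hours (from light onset) eligible
        dark_bins = 13:23          # dark onset hour (bin 12) never blocked
      )
    )
  )
  c(state_pars, common)
}

metabolic_defaults <- function(state = c("baseline", "kpc_d14")) {
  state <- match.arg(state)
  base <- list(vo2_light = 0.085, vo2_dark = 0.105,  # L O2/h
               rer_light = 0.80, rer_dark = 0.93,
               vo2_cv = 0.04, rer_sd = 0.015,
               scan_interval_min = 10)
  if (state == "kpc_d14") {
    base$vo2_light <- base$vo2_light * 0.92   # -8% light-cycle VO2
    base$vo2_dark <- base$vo2_dark * 0.785    # -21.5% dark-cycle VO2
    base$rer_light <- 0.74                    # shift to lipid oxidation
    base$rer_dark <- 0.82
  }
  base
}

activity_defaults <- function(state = c("baseline", "kpc_d14")) {
  state <- match.arg(state)
  base <- list(amb_runs_h_light = 8, amb_runs_h_dark = 33.5,  # 3.8-fold effective ratio
               stationary_rate_h = 10, z_rate_h = 5,
               n_beams = 16, intra_break_gap_s = 0.3)
  if (state == "kpc_d14") {
    base$amb_runs_h_light <- base$amb_runs_h_light * 0.505  # -48%
    base$amb_runs_h_dark <- base$amb_runs_h_dark * 0.305   # -67%
    base$stationary_rate_h <- 6
  }
  base
}

check_positive <- function(x, what) {
  bad <- vapply(x, function(v) is.numeric(v) && any(v < 0), logical(1))
  if (any(bad))
    stop("configuration error: negative parameter(s) in ", what, ": ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
}

#' Generator configuration for a virtual CLAMS cohort
#'
#' Bundles the seed, cohort size, physiological state and all stochastic
#' parameters of the synthetic data generator. The defaults emulate either
#' healthy adult male C57BL/6 mice (`"baseline"`) or the same animals 14 days
#' after i.p. KPC pancreatic-tumour implantation (`"kpc_d14"`): diurnal meal
#' frequency and cycle intakes, multi-hour zero-intake blocks in the
#' cachectic state, light/dark VO2 and RER setpoints, and ambulatory beam
#' break rates.
#'
#' One master `seed` determines every stream; per-animal, per-stream,
#' per-day-block sub-seeds are derived with a fixed splitting rule so that
#' regenerating any single stream reproduces it exactly.
#'
#' @param seed Integer master seed.
#' @param n_animals Number of virtual animals (>= 1). Default 7.
#' @param state `"baseline"` or `"kpc_d14"`.
#' @param schedule A [light_schedule()].
#' @param diet A [diet_spec()] or a bare energy density in kcal/g.
#' @param scale_resolution Balance quantum in g; intakes are quantized to
#'   this resolution. Default 0.01 g.
#' @param feeding,metabolic,activity Optional overrides of the per-state
#'   parameter lists (see `feeding_defaults()` in the package source and the
#'   methods vignette).
#' @return An object of class `ms_config`.
#' @examples
#' cfg <- clams_config(seed = 1, n_animals = 2)
#' ev <- generate_feeding_events(cfg, days = 1)
#' head(ev)
#' @export
clams_config <- function(seed,
                         n_animals = 7,
                         state = c("baseline", "kpc_d14"),
                         schedule = light_schedule(),
                         diet = diet_spec(),
                         scale_resolution = 0.01,
                         feeding = NULL,
                         metabolic = NULL,
                         activity = NULL) {
  state <- match.arg(state)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("configuration error: a single integer `seed` is required", call. = FALSE)
  if (!is.numeric(n_animals) || n_animals < 1)
    stop("configuration error: `n_animals` must be >= 1", call. = FALSE)
  if (!inherits(schedule, "ms_schedule"))
    stop("configuration error: `schedule` must be a light_schedule()", call. = FALSE)
  if (!is.numeric(scale_resolution) || scale_resolution <= 0)
    stop("configuration error: `scale_resolution` must be positive", call. = FALSE)
  feeding <- utils::modifyList(feeding_defaults(state), feeding %||% list())
  metabolic <- utils::modifyList(metabolic_defaults(state), metabolic %||% list())
  activity <- utils::modifyList(activity_defaults(state), activity %||% list())
  for (cyc in c("light", "dark")) check_positive(feeding[[cyc]], paste0("feeding$", cyc))
  check_positive(metabolic, "metabolic")
  check_positive(activity, "activity")
  if (metabolic$scan_interval_min <= 0)
    stop("configuration error: scan interval must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), n_animals = as.integer(n_animals),
                 state = state, schedule = schedule, diet = as_diet(diet),
                 scale_resolution = scale_resolution,
                 feeding = feeding, metabolic = metabolic, activity = activity),
            class = "ms_config")
}

#' @export
print.ms_config <- function(x, ...) {
  cat(sprintf("<clams_config: %d animals, state '%s', seed %d>\n",
              x$n_animals, x$state, x$seed))
  invisible(x)
}

animal_ids <- function(config) sprintf("M%02d", seq_len(config$n_animals))
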