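#' Light/dark schedule
#'
#' Describes the housing photoperiod as clock hours of lights-on and
#' lights-off. All analyses in the package are clock-relative: a "study day"
#' starts at light onset (default 06:00) so that one light cycle and the
#' following dark cycle belong to the same day.
#'
#' @param light_on Clock hour (0-24) at which lights turn on. Default 6.
#' @param light_off Clock hour at which lights turn off. Default 18.
#' @return An object of class `ms_schedule`.
#' @examples
#' sched <- light_schedule()
#' cycle_of(as.POSIXct("2024-01-01 19:00:00", tz = "UTC"), sched)
#' @export
light_schedule <- function(light_on = 6, light_off = 18) {
  stopifnot(is.numeric(light_on), is.numeric(light_off),
            light_on >= 0, light_on < 24, light_off > light_on, light_off <= 24)
  structure(list(light_on = light_on, light_off = light_off),
            class = "ms_schedule")
}

#' @export
print.ms_schedule <- function(x, ...) {
  cat(sprintf("<light schedule: on %02d:00, off %02d:00 (%g h light : %g h dark)>\n",
              x$light_on, x$light_off,
              x$light_off - x$light_on, 24 - (x$light_off - x$light_on)))
  invisible(x)
}

# Fixed local-clock anchor for generated timestamps. The generator and all
# analyses use UTC as a stand-in for cage-local clock time; no time-zone
# arithmetic is ever applied.
ms_origin <- function() as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

#' Clock hour of day
#'
#' Fractional hour-of-day (0-24) of a timestamp, on the local cage clock.
#'
#' @param time POSIXct vector.
#' @return Numeric vector in [0, 24).
#' @export
clock_hour <- function(time) {
  lubridate::hour(time) + lubridate::minute(time) / 60 +
    lubridate::second(time) / 3600
}

#' Light or dark cycle containing a timestamp
#'
#' @param time POSIXct vector.
#' @param schedule A [light_schedule()].
#' @return Character vector, `"light"` or `"dark"`.
#' @export
cycle_of <- function(time, schedule = light_schedule()) {
  h <- clock_hour(time)
  ifelse(h >= schedule$light_on & h < schedule$light_off, "light", "dark")
}

#' Study day index of a timestamp
#'
#' Days are indexed from 1 and begin at light onset, so the dark cycle
#' following a given light cycle belongs to the same study day.
#'
#' @inheritParams cycle_of
#' @return Integer vector of day indices.
#' @export
study_day <- function(time, schedule = light_schedule()) {
  secs <- as.numeric(time) - as.numeric(ms_origin()) - schedule$light_on * 3600
  as.integer(floor(secs / 86400)) + 1L
}

# POSIXct moment at which study day `day` begins (light onset).
day_start <- function(day, schedule = light_schedule()) {
  ms_origin() + ((day - 1) * 24 + schedule$light_on) * 3600
}

# Deterministic sub-seed derivation: one master seed, split per animal,
# stream and day block. Kept below 2^31 - 1 so it is a valid R integer seed.
sub_seed <- function(master, animal_idx, stream, block = 0L) {
  stopifnot(is.numeric(master), length(master) == 1)
  as.integer((abs(master) %% 2^20) * 1009 + animal_idx * 5323 +
               stream * 7919 + block * 101) %% .Machine$integer.max
}

# Overlap (in hours) of interval [a1, a2] with interval [b1, b2], all POSIXct
# or numeric seconds.
overlap_hours <- function(a1, a2, b1, b2) {
  pmax(0, as.numeric(pmin(a2, b2)) - as.numeric(pmax(a1, b1))) / 3600
}
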