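#' Generate synthetic feeding-event logs
#'
#' Simulates per-animal hopper-interaction logs (start, end, grams consumed)
#' from a seeded inhomogeneous renewal process. After each meal a non-eating
#' gap of at least ~5 min is drawn from a shifted gamma distribution whose
#' mean depends on the light/dark cycle and physiological state; meal
#' durations and sizes are gamma-distributed with per-cycle means. Meals may
#' be logged as two bouts separated by a pause strictly shorter than 5 min
#' (so downstream segmentation is unaffected), and sub-threshold "nibble"
#' events (<= 0.03 g) are sprinkled into the gaps at least 5.5 min away from
#' any meal. In the `kpc_d14` state, 2-8 h zero-intake blocks are sampled
#' each day and contain no events at all. Intakes are quantized to the
#' balance resolution (default 0.01 g) and timestamps to 1 s.
#'
#' @param config A [clams_config()].
#' @param days Number of consecutive study days to simulate (>= 1; for the
#'   `starve_refeed` protocol, >= 2: the penultimate day's dark cycle is the
#'   fast and the final day opens with the refeed).
#' @param protocol A [protocol_spec()]. Default spontaneous feeding.
#' @param start_day Index of the first simulated study day (days start at
#'   light onset). Default 1.
#' @return A tibble with columns `animal_id`, `start`, `end` (POSIXct, 1-s
#'   resolution) and `intake_g`, sorted by animal and start time;
#'   non-overlapping within animal.
#' @examples
#' cfg <- clams_config(seed = 42, n_animals = 2)
#' ev <- generate_feeding_events(cfg, days = 1)
#' nrow(ev)
#' @export
generate_feeding_events <- function(config, days = 3,
                                    protocol = protocol_spec("spontaneous"),
                                    start_day = 1) {
  stopifnot(inherits(config, "ms_config"))
  if (!inherits(protocol, "ms_protocol"))
    stop("configuration error: `protocol` must be a protocol_spec()", call. = FALSE)
  if (!is.numeric(days) || days < 1)
    stop("configuration error: `days` must be >= 1", call. = FALSE)
  if (protocol$kind == "starve_refeed" && days < 2)
    stop("configuration error: starve_refeed needs >= 2 days (fast night + refeed day)",
         call. = FALSE)
  ids <- animal_ids(config)
  res <- purrr::map_dfr(seq_along(ids), function(a) {
    # stable per-animal trait (appetite phenotype), identical across days,
    # protocols and disease states so the paired design is coherent
    cfg_a <- withr::with_seed(sub_seed(config$seed, a, stream = 4L, block = 0L), {
      fp <- config$feeding
      tr_imi <- exp(stats::rnorm(1, 0, fp$animal_cv_imi))
      tr_size <- exp(stats::rnorm(1, 0, fp$animal_cv_size))
      for (cyc in c("light", "dark")) {
        fp[[cyc]]$imi_mean <- fp[[cyc]]$imi_mean * tr_imi
        fp[[cyc]]$size_kcal_mean <- fp[[cyc]]$size_kcal_mean * tr_size
      }
      fp$refeed_imi_mean <- fp$refeed_imi_mean * tr_imi
      fp$ghrelin_imi_mean <- fp$ghrelin_imi_mean * tr_imi
      cfg <- config
      cfg$feeding <- fp
      cfg
    })
    purrr::map_dfr(seq_len(days), function(d) {
      day <- start_day + d - 1L
      role <- day_role(protocol, d, days)
      ev <- withr::with_seed(
        sub_seed(config$seed, a, stream = 1L, block = day),
        gen_animal_day(cfg_a, day, role, protocol)
      )
      if (nrow(ev)) ev$animal_id <- ids[a]
      ev
    })
  })
  if (!nrow(res)) {
    return(tibble::tibble(animal_id = character(), start = ms_origin()[0],
                          end = ms_origin()[0], intake_g = numeric()))
  }
  dplyr::arrange(res[c("animal_id", "start", "end", "intake_g")],
                 .data$animal_id, .data$start)
}

# Role of the d-th day of a protocol call.
day_role <- function(protocol, d, days) {
  switch(protocol$kind,
         starve_refeed = if (d == days - 1) "fast_night"
                         else if (d == days) "refeed" else "spontaneous",
         ghrelin = "ghrelin",
         vehicle = "vehicle",
         "spontaneous")
}

# --- one animal-day -------------------------------------------------------

gen_animal_day <- function(config, day, role, protocol) {
  fp <- config$feeding
  sched <- config$schedule
  L <- sched$light_off - sched$light_on     # light-cycle length, h
  density <- config$diet$energy_density
  resol <- config$scale_resolution

  forbidden <- NULL
  boosts <- list()
  if (role == "fast_night") forbidden <- rbind(forbidden, c(L, 24))
  if (role == "refeed")
    boosts <- c(boosts, list(list(from = 0, to = fp$refeed_boost_h,
                                  imi_mean = fp$refeed_imi_mean, d0_mean = 2)))
  if (role %in% c("ghrelin", "vehicle")) {
    inj <- protocol$injection_time - sched$light_on
    if (inj < 0) inj <- inj + 24
    if (role == "ghrelin")
      boosts <- c(boosts, list(list(from = inj, to = inj + protocol$response_window_h,
                                    imi_mean = fp$ghrelin_imi_mean, d0_mean = 2)))
  }
  if (!is.null(fp$zero_blocks)) {
    zb <- sample_zero_blocks(fp$zero_blocks, L, skip_light = role == "refeed")
    forbidden <- rbind(forbidden, zb)
  }
  if (role == "fast_night" && !is.null(forbidden)) {
    # food is physically absent over the dark cycle; merge overlapping spans
    forbidden <- merge_spans(forbidden)
  }

  segs <- build_segments(L, forbidden, boosts, fp)
  meals <- purrr::map_dfr(segs, gen_segment, fp = fp, density = density,
                          resol = resol)
  bouts <- if (nrow(meals)) expand_bouts(meals, fp, resol) else meals
  nib <- gen_nibbles(segs, bouts, fp, resol)
  ev <- rbind(bouts[c("start_s", "end_s", "intake_g")],
              nib[c("start_s", "end_s", "intake_g")])
  if (!nrow(ev)) {
    return(tibble::tibble(start = ms_origin()[0], end = ms_origin()[0],
                          intake_g = numeric()))
  }
  ev <- ev[order(ev$start_s), ]
  t0 <- day_start(day, sched)
  tibble::tibble(start = t0 + ev$start_s, end = t0 + ev$end_s,
                 intake_g = ev$intake_g)
}

merge_spans <- function(m) {
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, ])
  }
  out
}

# Sample the day's zero-intake blocks: 2-4 blocks of 2-8 whole hours,
# totalling 10-12 h, aligned to clock hours, biased towards the light cycle,
# never covering the first dark hour. Returns a matrix of (from, to) hours.
sample_zero_blocks <- function(zb, L, skip_light = FALSE) {
  for (try in 1:200) {
    nb <- sample(seq(zb$n_range[1], zb$n_range[2]), 1)
    lens <- sample(seq(zb$len_range[1], zb$len_range[2]), nb, replace = TRUE)
    if (sum(lens) >= zb$total_range[1] && sum(lens) <= zb$total_range[2]) break
  }
  occupied <- rep(FALSE, 24)
  out <- NULL
  for (len in sort(lens, decreasing = TRUE)) {
    placed <- FALSE
    for (try in 1:100) {
      light <- stats::runif(1) < zb$p_light && !skip_light
      bins <- if (light) zb$light_bins else zb$dark_bins
      starts <- bins[bins + len - 1 <= max(bins)]
      if (!length(starts)) next
      s <- sample(rep(starts, 2), 1)   # rep() guards length-1 sample()
      if (any(occupied[(s + 1):(s + len)])) next
      occupied[(s + 1):(s + len)] <- TRUE
      out <- rbind(out, c(s, s + len))
      placed <- TRUE
      break
    }
  }
  out
}

# Cut the 24-h day (hours from light onset; light = [0, L)) into free
# segments, each carrying its renewal parameters.
build_segments <- function(L, forbidden, boosts, fp) {
  cuts <- c(0, L, 24)
  if (!is.null(forbidden)) cuts <- c(cuts, as.vector(forbidden))
  for (b in boosts) cuts <- c(cuts, b$from, b$to)
  cuts <- sort(unique(pmin(pmax(cuts, 0), 24)))
  segs <- list()
  for (i in seq_len(length(cuts) - 1)) {
    from <- cuts[i]; to <- cuts[i + 1]
    if (to - from < 1e-9) next
    mid <- (from + to) / 2
    if (!is.null(forbidden) &&
        any(mid > forbidden[, 1] & mid < forbidden[, 2])) next
    cyc <- if (mid < L) "light" else "dark"
    pars <- fp[[cyc]]
    boosted <- FALSE
    for (b in boosts) {
      if (mid > b$from && mid < b$to) {
        pars$imi_mean <- b$imi_mean
        pars$d0_mean <- b$d0_mean
        boosted <- TRUE
      }
    }
    after_block <- !is.null(forbidden) &&
      any(abs(forbidden[, 2] - from) < 1e-9)
    d0 <- if (boosted) pars$d0_mean
          else if (after_block) fp$post_block_delay_min
          else pars$d0_mean
    segs[[length(segs) + 1]] <- list(from = from, to = to, cycle = cyc,
                                     imi_mean = pars$imi_mean,
                                     dur_mean = pars$dur_mean,
                                     size_kcal_mean = pars$size_kcal_mean,
                                     d0_mean = d0)
  }
  segs
}

# Renewal process within one free segment; returns whole meals (not yet
# split into bouts), times in seconds from day start.
gen_segment <- function(seg, fp, density, resol) {
  from_s <- seg$from * 3600
  to_s <- seg$to * 3600
  size_g_mean <- seg$size_kcal_mean / density
  t <- from_s + stats::rexp(1, 1 / (seg$d0_mean * 60))
  starts <- ends <- sizes <- numeric()
  while (t < to_s) {
    dur_min <- max(fp$dur_floor_min,
                   stats::rgamma(1, shape = fp$dur_shape,
                                 rate = fp$dur_shape / seg$dur_mean))
    dur_s <- round(dur_min * 60)
    if (t + dur_s > to_s) dur_s <- floor(to_s - t)
    if (dur_s < 12) break
    g <- stats::rgamma(1, shape = fp$size_shape,
                       rate = fp$size_shape / size_g_mean)
    g <- max(round(g / resol) * resol, 4 * resol)  # quantized, strictly > 0.03
    starts <- c(starts, round(t)); ends <- c(ends, round(t) + dur_s)
    sizes <- c(sizes, g)
    gap_min <- fp$imi_min + stats::rgamma(1, shape = fp$imi_shape,
                                          rate = fp$imi_shape /
                                            (seg$imi_mean - fp$imi_min))
    t <- round(t) + dur_s + gap_min * 60
  }
  tibble::tibble(start_s = starts, end_s = ends, intake_g = sizes)
}

# Split a fraction of meals into two bouts separated by a < 5 min pause.
# The meal's span and total intake are preserved exactly, so segmentation
# reconstructs the same meal.
expand_bouts <- function(meals, fp, resol) {
  out <- vector("list", nrow(meals))
  for (i in seq_len(nrow(meals))) {
    m <- meals[i, ]
    dur_min <- (m$end_s - m$start_s) / 60
    split <- stats::runif(1) < fp$split_prob && dur_min >= 1.2
    if (split) {
      a <- dur_min * stats::runif(1, 0.3, 0.5)
      p <- stats::runif(1, fp$pause_range_min[1], fp$pause_range_min[2])
      p <- min(p, dur_min - a - 0.25, 4.5)
      if (p >= 0.4) {
        b1_end <- m$start_s + round(a * 60)
        b2_start <- b1_end + round(p * 60)
        g1 <- round(m$intake_g * (a / dur_min) / resol) * resol
        g1 <- min(max(g1, resol), m$intake_g - resol)
        out[[i]] <- tibble::tibble(
          start_s = c(m$start_s, b2_start),
          end_s = c(b1_end, m$end_s),
          intake_g = c(g1, round((m$intake_g - g1) / resol) * resol))
        next
      }
    }
    out[[i]] <- m
  }
  dplyr::bind_rows(out)
}

# Sub-threshold nibble events placed in free time, >= 5.5 min from any meal
# bout and from each other, so they always form their own (filtered)
# clusters and never alter segmentation.
gen_nibbles <- function(segs, bouts, fp, resol) {
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          intake_g = numeric())
  if (!length(segs) || fp$nibble_rate_h <= 0) return(empty)
  lens <- vapply(segs, function(s) s$to - s$from, numeric(1))
  n <- stats::rpois(1, fp$nibble_rate_h * sum(lens))
  if (n == 0) return(empty)
  guard <- 330  # s
  spans <- if (nrow(bouts)) cbind(bouts$start_s - guard, bouts$end_s + guard)
           else matrix(numeric(), ncol = 2)
  placed <- NULL
  for (k in seq_len(3 * n)) {
    if (!is.null(placed) && nrow(placed) >= n) break
    seg <- segs[[sample.int(length(segs), 1, prob = lens)]]
    dur <- round(stats::runif(1, 10, 30))
    s <- round(stats::runif(1, seg$from * 3600, seg$to * 3600 - dur - 1))
    lo <- s - guard; hi <- s + dur + guard
    clash <- (nrow(spans) && any(spans[, 1] < hi & spans[, 2] > lo)) ||
      (!is.null(placed) && any(placed[, 1] - guard < hi & placed[, 2] + guard > lo))
    if (clash) next
    placed <- rbind(placed, c(s, s + dur))
  }
  if (is.null(placed)) return(empty)
  tibble::tibble(start_s = placed[, 1], end_s = placed[, 2],
                 intake_g = sample(c(1, 2, 3), nrow(placed), replace = TRUE) * resol)
}
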