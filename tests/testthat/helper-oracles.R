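# Independent reference implementations (deliberately naive loops) used as
# oracles against the package's vectorized code, plus small fixture builders.

# Event tibble for one animal from offsets in minutes.
make_events <- function(start_min, end_min, intake_g, animal = "M01", day = 1) {
  t0 <- ms_time(0, day = day)
  tibble::tibble(animal_id = animal,
                 start = t0 + start_min * 60,
                 end = t0 + end_min * 60,
                 intake_g = intake_g)
}

# Brute-force segmentation for a single animal: enumerate every gap
# comparison explicitly, then apply the strict size filter.
brute_segment <- function(events, min_imi = 5, min_size = 0.03) {
  stopifnot(length(unique(events$animal_id)) <= 1)
  if (!nrow(events)) return(data.frame(start = numeric(), end = numeric(),
                                       size_g = numeric(), n_events = integer()))
  clusters <- list()
  cur <- list(start = events$start[1], end = events$end[1],
              size = events$intake_g[1], n = 1L)
  for (i in seq_len(nrow(events))[-1]) {
    gap_min <- (as.numeric(events$start[i]) - as.numeric(cur$end)) / 60
    if (gap_min < min_imi) {
      cur$end <- events$end[i]
      cur$size <- cur$size + events$intake_g[i]
      cur$n <- cur$n + 1L
    } else {
      clusters[[length(clusters) + 1]] <- cur
      cur <- list(start = events$start[i], end = events$end[i],
                  size = events$intake_g[i], n = 1L)
    }
  }
  clusters[[length(clusters) + 1]] <- cur
  out <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(start = as.numeric(cl$start), end = as.numeric(cl$end),
               size_g = cl$size, n_events = cl$n)))
  out[out$size_g > min_size, , drop = FALSE]
}

# Random, sorted, non-overlapping event list for one animal.
random_events <- function(n, animal = "M01") {
  gaps_min <- stats::rexp(n, 1 / 6)           # straddles the 5-min threshold
  durs_min <- stats::runif(n, 0.1, 3)
  starts <- cumsum(c(stats::runif(1, 0, 10), gaps_min[-1] + durs_min[-n]))
  make_events(starts, starts + durs_min,
              round(stats::runif(n, 0, 0.2), 2), animal = animal)
}

# Exact one-tailed Fisher p by full enumeration of all 2x2 tables with the
# observed margins, using only choose().
enum_fisher <- function(m, direction = "less") {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- r1 + r2
  a_obs <- m[1, 1]
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  if (direction == "less") sum(probs[a_range <= a_obs])
  else sum(probs[a_range >= a_obs])
}

# Brute-force ambulatory counter: explicit run splitting and adjacency scan.
brute_ambulatory <- function(times, beams, gap_s = 1) {
  if (!length(times)) return(0L)
  count <- 0L
  run <- beams[1]
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] > gap_s) {
      count <- count + run_is_amb(run)
      run <- beams[i]
    } else {
      run <- c(run, beams[i])
    }
  }
  count + run_is_amb(run)
}

run_is_amb <- function(run) {
  u <- unique(run)
  for (a in u) for (b in u) if (abs(a - b) == 1) return(1L)
  0L
}
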