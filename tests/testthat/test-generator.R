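test_that("identical seeds yield identical outputs across all generators", {
  cfg <- clams_config(seed = 7, n_animals = 2)
  expect_identical(generate_feeding_events(cfg, days = 2),
                   generate_feeding_events(cfg, days = 2))
  expect_identical(generate_calorimetry(cfg, days = 1),
                   generate_calorimetry(cfg, days = 1))
  expect_identical(generate_activity(cfg, days = 1),
                   generate_activity(cfg, days = 1))
  s1 <- generate_study(clams_config(seed = 9, n_animals = 2), days_per_phase = 1)
  s2 <- generate_study(clams_config(seed = 9, n_animals = 2), days_per_phase = 1)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$manifest, s2$manifest)
  # different seed, different data
  expect_false(identical(
    generate_feeding_events(clams_config(seed = 8, n_animals = 2), days = 2),
    generate_feeding_events(cfg, days = 2)))
})

test_that("event logs satisfy their structural postconditions", {
  cfg <- clams_config(seed = 31, n_animals = 3)
  ev <- generate_feeding_events(cfg, days = 2)
  by_animal <- split(ev, ev$animal_id)
  for (sub in by_animal) {
    expect_false(is.unsorted(as.numeric(sub$start)))
    if (nrow(sub) > 1)
      expect_true(all(utils::head(sub$end, -1) <= sub$start[-1]))
  }
  expect_true(all(ev$end >= ev$start))
  # intakes quantized to the balance resolution (0.01 g)
  expect_equal(round(ev$intake_g * 100), ev$intake_g * 100, tolerance = 1e-9)
  # timestamps at 1-s resolution
  expect_equal(as.numeric(ev$start), round(as.numeric(ev$start)))
})

test_that("invalid configurations are rejected", {
  expect_error(clams_config(seed = 1, state = "tumour"), "arg")
  expect_error(clams_config(seed = 1, n_animals = 0), "n_animals")
  expect_error(clams_config(), "seed")
  expect_error(clams_config(seed = 1, feeding = list(
    dark = list(imi_mean = -5, d0_mean = 1, dur_mean = 1, size_kcal_mean = 1))),
    "negative")
  expect_error(clams_config(seed = 1, metabolic = list(scan_interval_min = 0)),
               "scan interval")
  cfg <- clams_config(seed = 1, n_animals = 1)
  expect_error(generate_feeding_events(cfg, days = 0), "days")
  expect_error(generate_feeding_events(cfg, days = 1, protocol = "ghrelin"),
               "protocol_spec")
})

test_that("baseline cohort reproduces healthy cycle intakes", {
  cfg <- clams_config(seed = 101, n_animals = 7)
  meals <- segment_meals(generate_feeding_events(cfg, days = 3))
  cs <- cycle_summary(meals)
  light <- mean(cs$total_kcal_day[cs$cycle == "light"])
  dark <- mean(cs$total_kcal_day[cs$cycle == "dark"])
  expect_lt(abs(light - 4.12) / 4.12, 0.10)
  expect_lt(abs(dark - 7.9) / 7.9, 0.10)
})

test_that("cachectic cohort reproduces the reduced 24-h intake", {
  cfg <- clams_config(seed = 102, n_animals = 7, state = "kpc_d14")
  meals <- segment_meals(generate_feeding_events(cfg, days = 3))
  cs <- cycle_summary(meals)
  total <- sum(tapply(cs$total_kcal_day, cs$cycle, mean))
  expect_lt(abs(total - 6.07) / 6.07, 0.15)
})

test_that("zero-intake blocks contain no events and fasts are respected", {
  cfg <- clams_config(seed = 103, n_animals = 4, state = "kpc_d14")
  ev <- generate_feeding_events(cfg, days = 2)
  hz <- hourly_bin(ev)
  z <- zero_intake_hours(hz)
  # multi-hour zero blocks exist in every animal-day
  expect_true(all(z$zero_total >= 2))

  # starve_refeed: dark cycle of the fast night is empty, feeding resumes
  cfgb <- clams_config(seed = 104, n_animals = 3)
  ev <- generate_feeding_events(cfgb, days = 2,
                                protocol = protocol_spec("starve_refeed"))
  fast_from <- ms_time(12 * 3600, day = 1)
  fast_to <- ms_time(0, day = 2)
  expect_equal(sum(ev$start >= fast_from & ev$start < fast_to), 0)
  after <- ev[ev$start >= fast_to & ev$start < fast_to + 3600, ]
  expect_true(all(table(after$animal_id) >= 1))
})

test_that("nibbles and bout splitting never alter the segmented meal count", {
  for (s in 105:107) {
    ev <- generate_feeding_events(clams_config(seed = s, n_animals = 2), days = 2)
    meals <- segment_meals(ev)
    cl <- merge_events_to_meals(ev)
    # standalone nibble clusters: removing those events entirely leaves the
    # meal sequence untouched (they never bridge or terminate meals)
    nib <- cl[cl$size_g <= 0.03, ]
    keep <- rep(TRUE, nrow(ev))
    for (i in seq_len(nrow(nib)))
      keep[ev$animal_id == nib$animal_id[i] & ev$start >= nib$start[i] &
             ev$end <= nib$end[i]] <- FALSE
    meals_no_nib <- segment_meals(ev[keep, ])
    expect_equal(nrow(meals_no_nib), nrow(meals))
    expect_equal(meals_no_nib$size_g, meals$size_g)
    # un-splitting bouts (one synthetic event per meal) reproduces the meals
    unsplit <- meals[c("animal_id", "start", "end")]
    unsplit$intake_g <- meals$size_g
    meals_unsplit <- segment_meals(unsplit)
    expect_equal(nrow(meals_unsplit), nrow(meals))
    expect_equal(meals_unsplit$size_g, meals$size_g)
  }
})

test_that("energy is an exact linear conversion of grams", {
  cfg <- clams_config(seed = 108, n_animals = 2, diet = diet_spec(3.4))
  ev <- generate_feeding_events(cfg, days = 1)
  meals <- segment_meals(ev, diet = cfg$diet)
  expect_identical(meals$size_kcal, meals$size_g * 3.4)
  # daily grams = sum of event intakes (conservation through binning)
  hb <- hourly_bin(ev, diet = cfg$diet)
  expect_equal(sum(hb$intake_g), sum(ev$intake_g), tolerance = 1e-9)
})

test_that("calorimetry traces follow the diurnal and disease structure", {
  cfgb <- clams_config(seed = 109, n_animals = 4)
  cfgk <- clams_config(seed = 109, n_animals = 4, state = "kpc_d14")
  cb <- generate_calorimetry(cfgb, days = 2)
  ck <- generate_calorimetry(cfgk, days = 2)
  expect_true(all(cb$vo2_l_h > 0) && all(cb$vco2_l_h > 0))
  # regular scan grid per animal
  one <- cb[cb$animal_id == "M01", ]
  expect_equal(unique(diff(as.numeric(one$time))), 600)
  # generated RER within physiological bounds
  expect_true(all(rer(cb$vo2_l_h, cb$vco2_l_h) > 0.69))
  expect_true(all(rer(cb$vo2_l_h, cb$vco2_l_h) < 1.06))
  # dark-cycle VO2 exceeds light-cycle VO2 at baseline
  cyc <- cycle_of(cb$time)
  expect_gt(mean(cb$vo2_l_h[cyc == "dark"]), mean(cb$vo2_l_h[cyc == "light"]))
  # cachexia lowers dark VO2 by ~21-23%
  cyck <- cycle_of(ck$time)
  drop <- percent_change(mean(cb$vo2_l_h[cyc == "dark"]),
                         mean(ck$vo2_l_h[cyck == "dark"]))
  expect_true(drop > -26 && drop < -18)
})

test_that("activity streams exercise the ambulatory filter", {
  cfg <- clams_config(seed = 110, n_animals = 3)
  act <- generate_activity(cfg, days = 2)
  x <- act[act$axis == "X", ]
  runs <- split(x$beam_index,
                cumsum(c(TRUE, diff(as.numeric(x$time)) > 1)))
  amb <- vapply(runs, function(b) length(unique(b)) >= 2, logical(1))
  expect_true(any(amb))            # ambulatory runs present
  expect_true(any(!amb))           # stationary repeats present
  expect_true(any(act$axis == "Z"))

  # zero rate -> empty stream -> downstream count 0
  silent <- clams_config(seed = 111, n_animals = 1, activity = list(
    amb_runs_h_light = 0, amb_runs_h_dark = 0, stationary_rate_h = 0,
    z_rate_h = 0))
  act0 <- generate_activity(silent, days = 1)
  expect_equal(nrow(act0), 0)
  expect_equal(nrow(ambulatory_count(act0)), 0)
})

test_that("dark-cycle activity is ~3.8-fold light and collapses in cachexia", {
  ab <- ambulatory_count(generate_activity(
    clams_config(seed = 112, n_animals = 7), days = 3))
  ak <- ambulatory_count(generate_activity(
    clams_config(seed = 112, n_animals = 7, state = "kpc_d14"), days = 3))
  rb <- tapply(ab$ambulatory, ab$cycle, mean)
  rk <- tapply(ak$ambulatory, ak$cycle, mean)
  expect_lt(abs(rb[["dark"]] / rb[["light"]] - 3.8) / 3.8, 0.15)
  expect_lt(abs(percent_change(rb[["dark"]], rk[["dark"]]) - (-67)), 7)
  expect_lt(abs(percent_change(rb[["light"]], rk[["light"]]) - (-48)), 9)
})

test_that("a study pairs every animal across phases with a coherent manifest", {
  study <- generate_study(clams_config(seed = 113, n_animals = 7),
                          days_per_phase = 1)
  man <- study$manifest
  expect_length(man$animals, 7)
  expect_setequal(unique(man$phases$phase), c("baseline", "kpc_d14"))
  # every animal appears in both phases
  ev <- study$events
  ev$phase <- man$phases$phase[match(study_day(ev$start), man$phases$day)]
  tab <- table(ev$animal_id, ev$phase)
  expect_true(all(tab > 0))
  # fast nights are empty in both phases
  for (ph in c("baseline", "kpc_d14")) {
    fast_day <- man$phases$day[man$phases$phase == ph &
                                 man$phases$role == "fast_night"]
    from <- ms_time(12 * 3600, day = fast_day)
    to <- ms_time(0, day = fast_day + 1)
    expect_equal(sum(ev$start >= from & ev$start < to), 0)
  }
})
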