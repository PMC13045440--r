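test_that("hourly binning attributes intake to clock bins", {
  # wholly inside hour 3 (bins count from light onset)
  ev <- make_events(3 * 60 + 10, 3 * 60 + 12, 0.10)
  hb <- hourly_bin(ev)
  expect_equal(nrow(hb), 24)
  expect_equal(hb$intake_g[hb$hour_bin == 3], 0.10)
  expect_equal(sum(hb$intake_g), 0.10)

  # straddling 06:59-07:01 splits pro-rata: 0.02 g to each bin
  ev <- make_events(59, 61, 0.04)
  hb <- hourly_bin(ev)
  expect_equal(hb$intake_g[hb$hour_bin %in% 0:1], c(0.02, 0.02))

  # start-attribution alternative
  hb <- hourly_bin(ev, attribute = "start")
  expect_equal(hb$intake_g[hb$hour_bin == 0], 0.04)
  expect_equal(hb$intake_g[hb$hour_bin == 1], 0)

  # a recorded day without events is an all-zero row block
  ev <- make_events(10, 12, 0.10, day = 1)
  hb <- hourly_bin(ev, days = 1:2)
  expect_equal(sum(hb$intake_g[hb$day == 2]), 0)
  expect_equal(nrow(hb), 48)

  # empty input, no error
  expect_equal(nrow(hourly_bin(make_events(numeric(), numeric(), numeric()))), 0)
})

test_that("zero-intake hours count exactly-zero bins by cycle", {
  # all-zero day
  ev <- make_events(10, 12, 0.1, day = 1)
  z <- zero_intake_hours(hourly_bin(ev, days = 1:2))
  expect_equal(z$zero_total[z$day == 2], 24)
  expect_equal(z$zero_light[z$day == 2], 12)
  expect_equal(z$zero_dark[z$day == 2], 12)

  # intake in every hour
  ev <- make_events(seq(0, 23) * 60 + 5, seq(0, 23) * 60 + 7, rep(0.05, 24))
  z <- zero_intake_hours(hourly_bin(ev))
  expect_equal(z$zero_total, 0)

  # 12 zero bins, 7 in light and 5 in dark
  feed_hours <- c(7:11, 17:23)  # bins with intake: 5 light + 7 dark
  ev <- make_events(feed_hours * 60 + 5, feed_hours * 60 + 7,
                    rep(0.05, length(feed_hours)))
  z <- zero_intake_hours(hourly_bin(ev))
  expect_equal(c(z$zero_total, z$zero_light, z$zero_dark), c(12, 7, 5))
})

test_that("cycle summaries report absent means as NA and are deterministic", {
  # single meal: no following interval -> NA, not 0
  meals <- segment_meals(make_events(0, 2, 0.10))
  cs <- cycle_summary(meals)
  expect_true(is.na(cs$mean_imi_min))
  expect_true(is.na(cs$mean_sr))
  expect_equal(cs$meals_day, 1)
  # duplicate input gives identical summary
  withr::with_seed(406, {
    ev <- random_events(60)
    m <- segment_meals(ev)
    expect_identical(cycle_summary(m), cycle_summary(m))
  })
})

test_that("conservation: hourly bins equal meals plus filtered nibbles", {
  withr::with_seed(407, {
    ev <- dplyr::bind_rows(random_events(60, "M01"), random_events(40, "M02"))
    hb <- hourly_bin(ev)
    cl <- merge_events_to_meals(ev)
    meals <- filter_meals(cl)
    nib <- cl[cl$size_g <= 0.03, ]
    expect_equal(sum(hb$intake_g), sum(meals$size_g) + sum(nib$size_g),
                 tolerance = 1e-9)
  })
})

test_that("paired t test matches the closed-form computation", {
  # identical pairs -> t = 0, p = 1
  d <- tibble::tibble(animal_id = rep(c("a", "b", "c"), 2),
                      phase = rep(c("p1", "p2"), each = 3),
                      y = c(1, 2, 3, 1, 2, 3))
  res <- paired_t(d, y)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # constant non-zero differences -> degenerate-case error
  d$y <- c(1, 1, 1, 2, 2, 2)
  expect_error(paired_t(d, y), "degenerate")

  # textbook pairs vs the direct formula
  x1 <- c(4.2, 5.1, 6.3, 5.8, 4.9)
  x2 <- c(5.0, 5.9, 6.1, 6.6, 5.5)
  d <- tibble::tibble(animal_id = rep(letters[1:5], 2),
                      phase = rep(c("p1", "p2"), each = 5), y = c(x1, x2))
  res <- paired_t(d, y)
  diffs <- x2 - x1
  t_manual <- mean(diffs) / (sd(diffs) / sqrt(5))
  expect_equal(res$statistic, t_manual)
  expect_equal(res$estimate, mean(diffs))
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), 4))

  # contract errors
  expect_error(paired_t(d[c(1, 6), ], y), "2 complete pairs")
  d$phase <- "p1"
  expect_error(paired_t(d, y), "two phases")
})

test_that("one-tailed Fisher test equals full hypergeometric enumeration", {
  # zero group margin is a contract error; an uninformative zero column
  # (no zero-intake hours in either phase) gives p = 1
  expect_error(fisher_one_tailed(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
  expect_error(fisher_one_tailed(matrix(0, 2, 2)), "margin")
  expect_equal(fisher_one_tailed(matrix(c(0, 24, 0, 24), 2, byrow = TRUE),
                                 "less")$p_value, 1)

  # zero-feeding-hours table: 1/24 at baseline vs 12/24 at day 14
  tab <- matrix(c(1, 23, 12, 12), 2, byrow = TRUE)
  p <- fisher_one_tailed(tab, "less")$p_value
  expect_lt(p, 0.0004)
  expect_equal(p, enum_fisher(tab, "less"), tolerance = 1e-12)
  # swapping rows maps onto the other tail
  swapped <- tab[2:1, ]
  expect_equal(fisher_one_tailed(swapped, "greater")$p_value,
               enum_fisher(swapped, "greater"), tolerance = 1e-12)

  # random small tables against the enumeration oracle
  withr::with_seed(408, {
    for (case in 1:60) {
      m <- matrix(rpois(4, 5), 2)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      dirn <- sample(c("less", "greater"), 1)
      expect_equal(fisher_one_tailed(m, dirn)$p_value, enum_fisher(m, dirn),
                   tolerance = 1e-10)
    }
  })
})

test_that("two-point smoothing behaves on vectors and cohorts", {
  expect_equal(smooth_profile(c(0, 2)), 1)
  expect_equal(smooth_profile(rep(3, 5)), rep(3, 4))   # constant unchanged
  expect_warning(out <- smooth_profile(5), "window")
  expect_equal(out, 5)

  d <- tidyr::crossing(animal_id = c("a", "b"), t = 1:4)
  d$v <- ifelse(d$animal_id == "a", d$t, d$t + 2)  # means 1.5..3.5 / 3.5..5.5
  prof <- smooth_profile(d, t, v)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$mean, c(2.5, 3.5, 4.5))
  expect_equal(prof$sem, rep(1, 3))
  expect_equal(prof$upper - prof$lower, rep(2, 3))
})

test_that("satiety-ratio clock profile groups by preceding-meal bin", {
  # meals at 06:10, 06:40, 09:20, 12:40; the last interval is absent so
  # only bins 6-8 (two intervals) and 8-10 (one) appear; empty bins absent
  ev <- make_events(c(10, 40, 200, 400), c(12, 42, 202, 402),
                    rep(0.1, 4))
  meals <- segment_meals(ev)
  prof <- sr_time_profile(meals)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$clock_bin, c(6, 8))
  expect_equal(prof$n, c(2L, 1L))
  # all intervals in one bin -> single-bin profile
  prof1 <- sr_time_profile(meals[meals$day == 1 & clock_hour(meals$start) < 7, ])
  expect_equal(nrow(prof1), 1)
})

test_that("raster and radial export tables are deterministic and conserving", {
  withr::with_seed(409, {
    ev <- random_events(40)
    meals <- segment_meals(ev)
    r1 <- raster_export(meals)
    expect_equal(nrow(r1), nrow(meals))      # one raster row per meal
    expect_identical(r1, raster_export(meals))

    hb <- hourly_bin(ev)
    rad <- radial_export(hb)
    expect_equal(nrow(rad), 24)
    # radial row sums equal the mean daily intake
    expect_equal(sum(rad$mean_intake_g),
                 sum(hb$intake_g) / dplyr::n_distinct(hb$day),
                 tolerance = 1e-9)
  })
})
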