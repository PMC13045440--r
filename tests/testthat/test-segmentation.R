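test_that("events merge into clusters by the 5-min gap rule", {
  # single event
  one <- make_events(0, 2, 0.10)
  cl <- merge_events_to_meals(one)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size_g, 0.10)
  expect_equal(cl$duration_min, 2)

  # hand-merged: gap 2 min joins, gap 9 min splits
  ev <- make_events(c(0, 4, 15), c(2, 6, 16), c(0.05, 0.04, 0.05))
  cl <- merge_events_to_meals(ev)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$size_g, c(0.09, 0.05))
  expect_equal(cl$duration_min, c(6, 1))
  expect_equal(cl$n_events, c(2L, 1L))

  # boundary: a gap of exactly 5 min starts a new meal
  ev <- make_events(c(0, 7), c(2, 8), c(0.05, 0.05))  # gap exactly 5
  expect_equal(nrow(merge_events_to_meals(ev)), 2)
  ev <- make_events(c(0, 6.99), c(2, 8), c(0.05, 0.05))  # gap 4.99
  expect_equal(nrow(merge_events_to_meals(ev)), 1)

  # empty input
  expect_equal(nrow(merge_events_to_meals(make_events(numeric(), numeric(),
                                                      numeric()))), 0)
})

test_that("unsorted or overlapping input is a contract error", {
  ev <- make_events(c(10, 0), c(12, 2), c(0.1, 0.1))
  expect_error(merge_events_to_meals(ev), "sorted")
  ev <- make_events(c(0, 1), c(2, 3), c(0.1, 0.1))
  expect_error(merge_events_to_meals(ev), "overlap")
})

test_that("size filter is strict and nibbles do not terminate intervals", {
  cl <- merge_events_to_meals(make_events(0, 1, 0.030))
  expect_equal(nrow(filter_meals(cl)), 0)        # exactly 0.03 removed
  cl <- merge_events_to_meals(make_events(0, 1, 0.031))
  expect_equal(nrow(filter_meals(cl)), 1)        # strictly above kept

  # nibble between meals: IMI of meal 1 spans across it
  ev <- make_events(c(0, 20, 60), c(2, 21, 61), c(0.10, 0.02, 0.10))
  meals <- segment_meals(ev)
  expect_equal(nrow(meals), 2)
  expect_equal(meals$imi_next[1], 58)
})

test_that("annotation computes the five meal parameters", {
  # SR worked example: 0.26 kcal then 26-min interval -> 10 min/0.1 kcal
  ev <- make_events(c(0, 28), c(2, 30), c(0.26 / 3, 0.26 / 3))
  meals <- segment_meals(ev)
  expect_equal(meals$size_kcal[1], 0.26)
  expect_equal(meals$imi_next[1], 26)
  expect_equal(meals$sr_next[1], 10.0)
  expect_true(is.na(meals$imi_next[2]))          # last meal: absent, not 0
  expect_true(is.na(meals$sr_next[2]))

  # ingestion rate: 0.30 kcal over 2 min
  ev <- make_events(0, 2, 0.10)
  expect_equal(segment_meals(ev)$ingestion_rate, 0.15)

  # zero-duration cluster: 1-s duration floor keeps the rate finite
  ev <- make_events(0, 0, 0.10)
  expect_equal(segment_meals(ev)$ingestion_rate, 0.30 / (1 / 60))

  # cycle by start time: meal starting 17:59, ending 18:05 is light
  ev <- make_events(11 * 60 + 59, 12 * 60 + 5, 0.10)  # minutes from 06:00
  expect_equal(segment_meals(ev)$cycle, "light")
  ev <- make_events(12 * 60, 12 * 60 + 5, 0.10)
  expect_equal(segment_meals(ev)$cycle, "dark")
})

test_that("segmentation equals the brute-force oracle on random event lists", {
  withr::with_seed(401, {
    for (case in 1:300) {
      n <- sample(1:50, 1)
      ev <- random_events(n)
      got <- segment_meals(ev)
      want <- brute_segment(ev)
      expect_equal(nrow(got), nrow(want))
      expect_equal(as.numeric(got$start), want$start)
      expect_equal(as.numeric(got$end), want$end)
      expect_equal(got$size_g, want$size_g, tolerance = 1e-12)
      expect_equal(got$n_events, want$n_events)
    }
  })
})

test_that("segmenting already-merged meals returns them unchanged", {
  withr::with_seed(402, {
    ev <- random_events(40)
    meals <- segment_meals(ev)
    again <- segment_meals(meals[c("animal_id", "start", "end")] |>
                             dplyr::mutate(intake_g = meals$size_g))
    expect_equal(nrow(again), nrow(meals))
    expect_equal(again$size_g, meals$size_g)
    expect_equal(again$start, meals$start)
  })
})

test_that("thresholds act monotonically on meal count", {
  withr::with_seed(403, {
    for (case in 1:20) {
      ev <- random_events(40)
      cl5 <- merge_events_to_meals(ev, min_imi = 5)
      # raising min_size never increases meal count
      sizes <- c(0, 0.03, 0.05, 0.1)
      counts <- vapply(sizes, function(s) nrow(filter_meals(cl5, s)), numeric(1))
      expect_true(all(diff(counts) <= 0))
      # lowering min_imi never decreases meal count
      imis <- c(10, 5, 2, 0.5)
      counts <- vapply(imis, function(i)
        nrow(merge_events_to_meals(ev, min_imi = i)), numeric(1))
      expect_true(all(diff(counts) >= 0))
    }
  })
})

test_that("mass is conserved through merge and filter, exactly", {
  withr::with_seed(404, {
    ev <- random_events(50)
    cl <- merge_events_to_meals(ev)
    meals <- filter_meals(cl)
    nibbles <- cl[cl$size_g <= 0.03, ]
    expect_identical(sum(meals$size_g) + sum(nibbles$size_g), sum(ev$intake_g))
  })
})

test_that("SR identity holds for every annotated meal", {
  withr::with_seed(405, {
    ev <- dplyr::bind_rows(random_events(50, "M01"), random_events(30, "M02"))
    meals <- segment_meals(ev)
    ok <- !is.na(meals$imi_next)
    expect_equal(meals$sr_next[ok] * meals$size_kcal[ok] / 0.1,
                 meals$imi_next[ok], tolerance = 1e-9)
  })
})

test_that("interval chains terminate at recording gaps", {
  ev <- dplyr::bind_rows(make_events(0, 2, 0.1, day = 1),
                         make_events(0, 2, 0.1, day = 5))
  meals <- segment_meals(ev)
  expect_true(all(is.na(meals$imi_next)))  # 4-day hole: no interval across it
})

test_that("filter-first ordering is available and differs as documented", {
  # nibble adjacent to a meal: default merges it in; filter-first drops it
  ev <- make_events(c(0, 3), c(2, 3.5), c(0.10, 0.02))
  expect_equal(segment_meals(ev)$size_g, 0.12)
  expect_equal(segment_meals(ev, filter_first = TRUE)$size_g, 0.10)
})
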