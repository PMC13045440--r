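#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the generator seed and cohort,
#' segmentation thresholds, diet and light schedule. Can be written to /
#' read from YAML for scripted use.
#'
#' @param seed Master seed (required).
#' @param n_animals Cohort size. Default 7.
#' @param days_per_phase Spontaneous days per phase. Default 3.
#' @param min_imi Meal-separation threshold, min. Default 5.
#' @param min_size Minimum meal intake, g (strict). Default 0.03.
#' @param diet_energy_density kcal/g. Default 3.0.
#' @param light_on,light_off Photoperiod clock hours. Defaults 6 and 18.
#' @return A `ms_pipeline_config` list.
#' @export
pipeline_config <- function(seed, n_animals = 7, days_per_phase = 3,
                            min_imi = 5, min_size = 0.03,
                            diet_energy_density = 3.0,
                            light_on = 6, light_off = 18) {
  if (min_imi <= 0 || min_size < 0)
    stop("configuration error: thresholds must be positive", call. = FALSE)
  structure(list(seed = seed, n_animals = n_animals,
                 days_per_phase = days_per_phase,
                 min_imi = min_imi, min_size = min_size,
                 diet_energy_density = diet_energy_density,
                 light_on = light_on, light_off = light_off),
            class = "ms_pipeline_config")
}

#' Run the full simulate - segment - summarise pipeline
#'
#' Generates a paired study, writes the raw data streams, segments meals,
#' and produces every summary table: per-cycle meal-pattern summaries,
#' hourly intake and zero-intake hours, mixed-model results, paired and
#' exact tests, raster/radial plot tables, the energy/activity summary and
#' the three evoked-response contrasts. A run manifest (seed, package
#' version, parameter hash, per-stage row counts) makes the bundle
#' self-describing; the whole bundle is deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages. Default `FALSE`.
#' @return Invisibly, a list with the output `paths`, the stage `counts`
#'   and the in-memory `tables`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "ms_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- file(log_path, open = "wt")
  on.exit(close(logf))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logf)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sched <- light_schedule(config$light_on, config$light_off)
  diet <- diet_spec(config$diet_energy_density)
  counts <- list()

  say("stage simulate: seed %d, %d animals", config$seed, config$n_animals)
  study <- stage("simulate", {
    cfg <- clams_config(seed = config$seed, n_animals = config$n_animals,
                        schedule = sched, diet = diet)
    generate_study(cfg, days_per_phase = config$days_per_phase)
  })
  counts$events_in <- nrow(study$events)
  say("  %d feeding events, %d calorimetry scans, %d beam breaks",
      nrow(study$events), nrow(study$calorimetry), nrow(study$activity))

  paths <- list(events = file.path(out_dir, "events.csv"),
                calorimetry = file.path(out_dir, "calorimetry.csv"),
                activity = file.path(out_dir, "activity.csv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  stage("write_raw", {
    write_events(study$events, paths$events)
    write_calorimetry(study$calorimetry, paths$calorimetry)
    write_activity(study$activity, paths$activity)
    write_manifest(study$manifest, paths$manifest)
  })

  phase_of_day <- study$manifest$phases
  add_phase <- function(df, time_col) {
    df$day <- study_day(df[[time_col]], sched)
    dplyr::left_join(df, phase_of_day[c("day", "phase", "role")], by = "day")
  }

  say("stage segment: min_imi %.3g min, min_size %.3g g",
      config$min_imi, config$min_size)
  seg <- stage("segment", {
    clusters <- merge_events_to_meals(study$events, min_imi = config$min_imi)
    m <- clusters |>
      filter_meals(min_size = config$min_size) |>
      annotate_meals(diet = diet, schedule = sched)
    list(n_clusters = nrow(clusters),
         meals = dplyr::left_join(m, phase_of_day[c("day", "phase", "role")],
                                  by = "day"))
  })
  counts$clusters <- seg$n_clusters
  meals <- seg$meals
  counts$meals <- nrow(meals)
  say("  %d events -> %d clusters -> %d meals", counts$events_in,
      counts$clusters, counts$meals)

  say("stage summarise")
  spont_meals <- meals[meals$role %in% c("spontaneous", "dark_onset"), ]
  spont_ev <- dplyr::bind_rows(study_slice(study, "baseline", "spontaneous"),
                               study_slice(study, "kpc_d14", "spontaneous"))
  tables <- stage("summarise", {
    hourly <- hourly_bin(spont_ev, schedule = sched, diet = diet,
                         days = sort(unique(spont_ev$day)))
    zeros <- zero_intake_hours(hourly)
    summary_cycle <- cycle_summary(spont_meals)
    lmm_results <- if (nrow(spont_meals) &&
                       length(unique(spont_meals$phase)) == 2)
      lmm_by_cycle(spont_meals) else tibble::tibble()
    tests <- build_tests(spont_meals, zeros)
    list(hourly = hourly, zeros = zeros, summary_cycle = summary_cycle,
         lmm_results = lmm_results, tests = tests,
         raster = if (nrow(spont_meals)) raster_export(spont_meals)
                  else tibble::tibble(),
         radial = radial_export(hourly))
  })

  say("stage energy")
  tables$energy <- stage("energy", {
    cal <- add_phase(study$calorimetry, "time")
    act <- add_phase(study$activity, "time")
    spont_days <- phase_of_day$day[phase_of_day$role %in%
                                     c("spontaneous", "dark_onset")]
    cycle_energy_summary(cal[cal$day %in% spont_days, ],
                         act[act$day %in% spont_days, ], schedule = sched)
  })

  say("stage evoked")
  tables$evoked <- stage("evoked", evoked_table(study, sched))

  out_files <- c(meals = "meals.csv", summary_cycle = "summary_cycle.csv",
                 hourly = "hourly.csv", zeros = "zero_hours.csv",
                 lmm_results = "lmm_results.csv", tests = "tests.csv",
                 raster = "raster.csv", radial = "radial.csv",
                 energy = "energy_summary.csv", evoked = "evoked_results.csv")
  tables$meals <- meals
  for (nm in names(out_files)) {
    p <- file.path(out_dir, out_files[[nm]])
    readr::write_csv(tables[[nm]], p)
    paths[[nm]] <- p
  }

  run_manifest <- list(
    package = "mealscan",
    version = as.character(utils::packageVersion("mealscan")),
    seed = config$seed,
    parameter_hash = rlang::hash(unclass(config)),
    counts = counts,
    outputs = unname(vapply(paths, basename, character(1))))
  paths$run_manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(run_manifest, paths$run_manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d output files in %s", length(paths), out_dir)
  invisible(list(paths = paths, counts = counts, tables = tables))
}

# Paired tests on per-animal cycle totals and meal counts, plus the
# one-tailed exact test on zero-intake hours (cohort-mean 2x2 table).
build_tests <- function(spont_meals, zeros) {
  out <- list()
  if (nrow(spont_meals) && length(unique(spont_meals$phase)) == 2) {
    cs <- cycle_summary(spont_meals)
    for (cyc in unique(cs$cycle)) {
      sub <- cs[cs$cycle == cyc, ]
      if (length(unique(sub$phase)) == 2 && nrow(sub) >= 4) {
        for (v in c("total_kcal_day", "meals_day")) {
          tt <- tryCatch(rlang::inject(paired_t(sub, !!rlang::sym(v))),
                         error = function(e) NULL, warning = function(w) NULL)
          if (!is.null(tt))
            out[[length(out) + 1]] <- dplyr::mutate(tt, test = "paired_t",
                                                    variable = v, cycle = cyc,
                                                    .before = 1)
        }
      }
    }
  }
  if (nrow(zeros) && "phase" %in% names(zeros) &&
      length(unique(zeros$phase)) == 2) {
    ph <- sort(unique(zeros$phase))
    z <- tapply(zeros$zero_total, zeros$phase, function(x) round(mean(x)))
    tab <- matrix(c(z[[ph[1]]], 24 - z[[ph[1]]], z[[ph[2]]], 24 - z[[ph[2]]]),
                  2, byrow = TRUE)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ft <- fisher_one_tailed(tab, "less")
      out[[length(out) + 1]] <- tibble::tibble(
        test = "fisher_one_tailed", variable = "zero_hours", cycle = "24h",
        estimate = NA_real_, statistic = NA_real_, p_value = ft$p_value,
        n_pairs = NA_integer_)
    }
  }
  if (!length(out)) return(tibble::tibble())
  dplyr::bind_rows(out)
}

# The three evoked-response contrasts from a paired study.
evoked_table <- function(study, sched) {
  man <- study$manifest
  res <- list()
  for (paradigm in c("dark_onset", "refeed", "ghrelin", "vehicle")) {
    vals <- purrr::map_dfr(c("baseline", "kpc_d14"), function(ph) {
      role_days <- man$phases$day[man$phases$phase == ph &
                                    man$phases$role == paradigm]
      if (!length(role_days)) return(tibble::tibble())
      ev <- study_slice(study, ph,
                        if (paradigm == "dark_onset") NULL else paradigm)
      per <- switch(paradigm,
        dark_onset = dark_onset_response(ev, sched, days = role_days) |>
          dplyr::group_by(.data$animal_id, .data$phase) |>
          dplyr::summarise(intake_g = sum(.data$intake_g), .groups = "drop"),
        refeed = {
          night_ev <- study_slice(study, ph)
          night_ev <- night_ev[night_ev$day %in% c(role_days - 1, role_days), ]
          refeed_response(night_ev, sched, day = role_days, windows = 1) |>
            dplyr::select(dplyr::all_of(c("animal_id", "phase", "intake_g")))
        },
        ghrelin = ,
        vehicle = ghrelin_response(ev, sched, day = role_days,
                                   injection_time = man$injection_time) |>
          dplyr::select(dplyr::all_of(c("animal_id", "phase", "intake_g"))))
      per
    })
    if (nrow(vals) && length(unique(vals$phase)) == 2) {
      res[[paradigm]] <- dplyr::mutate(evoked_contrast(vals),
                                       paradigm = paradigm, .before = 1)
    }
  }
  dplyr::bind_rows(res)
}
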