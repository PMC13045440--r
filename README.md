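# mealscan

Meal-microstructure and indirect-calorimetry analysis for continuous
metabolic-cage (CLAMS-style) recordings, with a seeded synthetic cohort
generator emulating healthy and cachectic (KPC pancreatic-cancer day-14)
mice.

## The problem

Daily food intake is the sum of discrete meals, and diseases that suppress
feeding do so by perturbing specific meal dimensions — meal number, size,
duration, ingestion rate, or the intervals between meals. Cancer cachexia
halves intake in the KPC mouse model, and resolving *which* dimension
carries the deficit requires meal-level analysis of continuous
feeding-event logs rather than aggregate 24-h weights. This package is for
researchers doing ingestive-behaviour and energy-balance phenotyping in
metabolic cages.

## What it computes

A *meal* is a cluster of hopper interactions separated from its neighbours
by non-eating intervals of at least 5 min, with total intake strictly
above 0.03 g. Each meal *m* with energy *E(m)* (kcal), duration *d(m)*
(min) and following intermeal interval *IMI(m)* (min) yields

- ingestion rate = *E(m)* / *d(m)* (kcal/min),
- satiety ratio SR = *IMI(m)* / (*E(m)*/0.1) (min per 0.1 kcal),

summarised per light/dark cycle and compared across disease phases with
linear mixed models (`value ~ phase + (1 | animal)`, REML; estimated
marginal means ± SEM), paired t tests, and a one-tailed Fisher exact test
for the count of zero-intake hours. Indirect calorimetry uses
RER = VCO2/VO2 and heat = (3.815 + 1.232 RER) x VO2 (Lusk's oxygen
caloric value); ambulation counts runs of two or more adjacent beam
breaks. Evoked feeding responses (dark onset, 12-h fast-refeed, ghrelin
injection) are windowed intake analyses with within-animal contrasts.

## Worked example

```r
library(mealscan)
library(dplyr)

cfg <- clams_config(seed = 1, n_animals = 7)       # healthy virtual cohort
events <- generate_feeding_events(cfg, days = 3)   # 1039 hopper events
meals <- segment_meals(events)                     # 704 meals

cycle_summary(meals) |>
  group_by(cycle) |>
  summarise(kcal_day = mean(total_kcal_day), meals_day = mean(meals_day),
            imi_min = mean(mean_imi_min, na.rm = TRUE))
#>   cycle kcal_day meals_day imi_min
#> 1  dark     7.60      23.2    29.8
#> 2 light     3.83      10.3    66.7
```

Healthy virtual mice eat ~7.6 kcal in the dark and ~3.8 kcal in the light
per day, in ~23 and ~10 meals with ~30 and ~67 min mean intermeal
intervals — the nocturnal feeding pattern the generator is calibrated to.
The cachectic state shows the voluntary multi-hour fasts:

```r
evk <- generate_feeding_events(
  clams_config(seed = 1, n_animals = 7, state = "kpc_d14"), days = 3)
zero_intake_hours(hourly_bin(evk))$zero_total |> mean()
#> 12.4        # hours per day without any intake (vs ~1 at baseline)
```

and a blunted refeeding response after an overnight fast, contrasted
within animals:

```r
refeed <- function(state) refeed_response(
  generate_feeding_events(clams_config(seed = 1, n_animals = 7, state = state),
                          days = 2, protocol = protocol_spec("starve_refeed")),
  day = 2, windows = 1)

evoked_contrast(bind_rows(
  refeed("baseline") |> mutate(phase = "baseline"),
  refeed("kpc_d14") |> mutate(phase = "kpc_d14")))
#>    phase_a mean_a phase_b mean_b pct_change_rounded p_value n_pairs
#> 1 baseline  0.789 kpc_d14  0.346                -56 0.00109       7
```

First-hour refeed intake falls from ~0.79 g to ~0.35 g (−56%, paired
p ≈ 0.001 in this cohort). `run_pipeline(pipeline_config(seed = 1), "out/")`
runs the whole chain — simulate, write the CSV/YAML bundle, segment,
summarise, energy, evoked — deterministically for a given seed. A thin
command-line wrapper is included at `inst/scripts/mealscan.R`.

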