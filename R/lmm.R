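#' Linear mixed model for meal-level parameters
#'
#' Fits `value ~ phase + (1 | animal)` by REML: a fixed phase effect with an
#' animal random intercept, accounting for repeated measures, individual
#' variability and unequal numbers of meals per observation period.
#' Estimated marginal means (EMMs) per phase and the phase contrast with its
#' Wald p-value are extracted with \pkg{emmeans}. When the random-intercept
#' variance is estimated as zero (singular fit) the model degenerates to an
#' ordinary fixed-effects fit, which is used as a fallback with a warning;
#' in that case the EMMs equal the pooled phase means.
#'
#' @param data Tibble with one row per observation (e.g. per meal).
#' @param value,phase,animal Column names (tidy-eval) of the response, the
#'   phase label (exactly two levels present) and the animal id.
#' @return An object of class `meal_lmm` with [generics::tidy()] (EMMs per
#'   phase) and [generics::glance()] (contrast, p, sizes) methods.
#' @examples
#' d <- tidyr::crossing(animal_id = c("a", "b", "c"),
#'                      phase = c("baseline", "kpc_d14"), rep = 1:5)
#' d$imi <- 26 + 16 * (d$phase == "kpc_d14")
#' fit <- fit_lmm(d, imi)
#' tidy(fit)
#' @export
fit_lmm <- function(data, value, phase = phase, animal = animal_id) {
  vcol <- rlang::as_name(rlang::enquo(value))
  pcol <- rlang::as_name(rlang::enquo(phase))
  acol <- rlang::as_name(rlang::enquo(animal))
  d <- data[stats::complete.cases(data[c(vcol, pcol, acol)]), c(vcol, pcol, acol)]
  names(d) <- c(".value", ".phase", ".animal")
  d$.phase <- factor(d$.phase)
  if (nlevels(droplevels(d$.phase)) != 2)
    stop("contract error: both phases must be present", call. = FALSE)
  if (length(unique(d$.animal)) < 2)
    stop("contract error: >= 2 animals required", call. = FALSE)
  singular <- FALSE
  model <- tryCatch({
    fit <- suppressMessages(lme4::lmer(.value ~ .phase + (1 | .animal), data = d,
                                       REML = TRUE))
    if (lme4::isSingular(fit, tol = 1e-5)) singular <- TRUE
    fit
  }, error = function(e) {
    singular <<- TRUE
    NULL
  })
  if (singular) {
    if (is.null(model))
      warning("mixed model could not be fitted; falling back to pooled fixed-effects fit",
              call. = FALSE)
    else
      warning("singular random-intercept variance; falling back to pooled fixed-effects fit",
              call. = FALSE)
    model <- stats::lm(.value ~ .phase, data = d)
  }
  emm <- emmeans::emmeans(model, ".phase")
  emm_df <- as.data.frame(emm)
  ctr <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  structure(list(
    model = model,
    response = vcol,
    singular = singular,
    emm = tibble::tibble(phase = as.character(emm_df$.phase),
                         emmean = emm_df$emmean, se = emm_df$SE,
                         df = emm_df$df),
    contrast = tibble::tibble(contrast = ctr$contrast,
                              estimate = ctr$estimate, se = ctr$SE,
                              statistic = ctr$t.ratio, p_value = ctr$p.value),
    n_animals = length(unique(d$.animal)),
    n_obs = nrow(d)),
    class = "meal_lmm")
}

#' @export
print.meal_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s ~ phase + (1 | animal)%s\n", x$response,
              if (x$singular) "  [singular; pooled fixed-effects fallback]" else ""))
  cat(sprintf("  %d observations from %d animals\n", x$n_obs, x$n_animals))
  print(as.data.frame(x$emm), row.names = FALSE)
  cat(sprintf("  contrast %s: %.4g +/- %.3g (p = %.3g)\n",
              x$contrast$contrast[1], x$contrast$estimate[1],
              x$contrast$se[1], x$contrast$p_value[1]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_lmm
#' @param x A `meal_lmm` object.
#' @param ... Unused.
#' @export
tidy.meal_lmm <- function(x, ...) x$emm

#' @rdname fit_lmm
#' @export
glance.meal_lmm <- function(x, ...) {
  tibble::tibble(response = x$response,
                 estimate = x$contrast$estimate[1],
                 se = x$contrast$se[1],
                 statistic = x$contrast$statistic[1],
                 p_value = x$contrast$p_value[1],
                 n_animals = x$n_animals, n_obs = x$n_obs,
                 singular = x$singular)
}

#' Per-cycle mixed-model table for the meal parameters
#'
#' Fits [fit_lmm()] separately within the light and the dark cycle for each
#' requested meal parameter and binds the tidied results: EMM +/- SEM per
#' phase with the phase-contrast p-value.
#'
#' @param meals Annotated meal tibble with a `phase` column.
#' @param params Character vector of meal columns to model.
#' @return A tibble with one row per parameter x cycle x phase.
#' @export
lmm_by_cycle <- function(meals, params = c("imi_next", "sr_next", "size_kcal",
                                           "duration_min", "ingestion_rate")) {
  stopifnot("phase" %in% names(meals))
  tidyr::crossing(param = params, cyc = c("light", "dark")) |>
    purrr::pmap_dfr(function(param, cyc) {
      sub <- meals[meals$cycle == cyc & !is.na(meals[[param]]), ]
      fit <- tryCatch(
        suppressWarnings(rlang::inject(fit_lmm(sub, !!rlang::sym(param)))),
        error = function(e) NULL)  # cycle infeasible (e.g. one phase absent)
      if (is.null(fit)) return(tibble::tibble())
      dplyr::mutate(tidy(fit), parameter = param, cycle = cyc,
                    p_value = fit$contrast$p_value[1],
                    n_obs = fit$n_obs, .before = 1)
    })
}
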