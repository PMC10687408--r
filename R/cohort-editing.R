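# Cohort construction: the data-editing cascade, breeding status,
# herd-year aggregation and the insemination-moment datasets.
#
# Filters are applied in a fixed order, each percentile threshold computed
# on the data remaining at that step (linear-interpolation quantiles,
# strict exceedance).  Every step's drop count is logged so the cascade is
# auditable.

INSEMINATION_MOMENTS <- c(50L, 75L, 100L, 125L)
# closest-earlier-day fallback bound per moment (90th percentile of the
# closest available day to each moment)
MOMENT_FALLBACK_BOUND <- c(`50` = 48L, `75` = 74L, `100` = 98L, `125` = 122L)
GESTATION_DAYS <- 282L

#' Calving season from calving date
#'
#' Months 3--5 Spring, 6--8 Summer, 9--11 Autumn, 12--2 Winter.
#'
#' @param date A `Date` vector.
#' @return Character vector of seasons.
#' @export
calving_season <- function(date) {
  m <- as.integer(format(date, "%m"))
  dplyr::case_when(
    m %in% 3:5 ~ "Spring",
    m %in% 6:8 ~ "Summer",
    m %in% 9:11 ~ "Autumn",
    TRUE ~ "Winter"
  )
}

new_exclusion_log <- function(step, n_excluded) {
  tibble::tibble(step = step, n_excluded = as.integer(n_excluded))
}

#' Lactation-level filters
#'
#' Drops, in order: (1) lactations with missing parity; (2) lactations with
#' age in days at calving outside the (1%, 99%) percentiles computed
#' *within parity* on the remaining data; (3) lactations with lactation
#' length above the 99% percentile of the remaining data.  Thresholds use
#' linear-interpolation quantiles and strict exceedance.
#'
#' @param lactations Tibble with at least `parity`, `age_days`,
#'   `lactation_length`.
#' @return List with `kept` (filtered tibble) and `exclusion_log`
#'   (tibble of `step`, `n_excluded`).
#' @export
lactation_level_filters <- function(lactations) {
  log <- list()
  x <- lactations

  n0 <- nrow(x)
  x <- dplyr::filter(x, !is.na(.data$parity))
  log[[1]] <- new_exclusion_log("missing_parity", n0 - nrow(x))

  n0 <- nrow(x)
  if (n0 > 0) {
    x <- x |>
      dplyr::group_by(.data$parity) |>
      dplyr::filter({
        lo <- q_lin(.data$age_days, 0.01)
        hi <- q_lin(.data$age_days, 0.99)
        !(.data$age_days < lo | .data$age_days > hi)
      }) |>
      dplyr::ungroup()
  }
  log[[2]] <- new_exclusion_log("extreme_age_within_parity", n0 - nrow(x))

  n0 <- nrow(x)
  if (n0 > 0) {
    hi <- q_lin(x$lactation_length, 0.99)
    x <- dplyr::filter(x, !(.data$lactation_length > hi))
  }
  log[[3]] <- new_exclusion_log("extreme_lactation_length", n0 - nrow(x))

  list(kept = x, exclusion_log = dplyr::bind_rows(log))
}

#' Post-fit record filters
#'
#' Applied to fitted-curve records joined to their lactations, in order:
#' (1) drop all records of lactations ending before DIM 305 (no DIM-305
#' curve exists for them); (2) drop records with negative decay; (3) drop
#' records with fit RMSE above the 95% percentile; (4) drop records with
#' magnitude, time to peak yield or decay outside the (1%, 99%)
#' percentiles; (5) drop all records of lactations left without a curve at
#' DIM 305 or its substitute DIM 304.  Percentiles are recomputed on the
#' data remaining at each step.
#'
#' @param fitted_curves Tibble with `lactation_key`, `as_of_dim`,
#'   `magnitude`, `time_to_peak`, `offset`, `decay`, `fit_rmse`.
#' @param lactations Tibble with `lactation_key`, `lactation_length`.
#' @return List with `kept` and `exclusion_log`.
#' @export
post_fit_filters <- function(fitted_curves, lactations) {
  log <- list()
  x <- dplyr::left_join(
    fitted_curves,
    dplyr::select(lactations, "lactation_key", "lactation_length"),
    by = "lactation_key")

  n0 <- nrow(x)
  x <- dplyr::filter(x, !is.na(.data$lactation_length),
                     .data$lactation_length >= 305)
  log[[1]] <- new_exclusion_log("lactation_shorter_than_305", n0 - nrow(x))

  n0 <- nrow(x)
  x <- dplyr::filter(x, .data$decay >= 0)
  log[[2]] <- new_exclusion_log("negative_decay", n0 - nrow(x))

  n0 <- nrow(x)
  if (n0 > 0) {
    hi <- q_lin(x$fit_rmse, 0.95)
    x <- dplyr::filter(x, !(.data$fit_rmse > hi))
  }
  log[[3]] <- new_exclusion_log("fit_rmse_above_p95", n0 - nrow(x))

  n0 <- nrow(x)
  if (n0 > 0) {
    qs <- lapply(x[c("magnitude", "time_to_peak", "decay")],
                 function(v) c(q_lin(v, 0.01), q_lin(v, 0.99)))
    ok <- !(x$magnitude < qs$magnitude[1] | x$magnitude > qs$magnitude[2] |
            x$time_to_peak < qs$time_to_peak[1] | x$time_to_peak > qs$time_to_peak[2] |
            x$decay < qs$decay[1] | x$decay > qs$decay[2])
    x <- x[ok, , drop = FALSE]
  }
  log[[4]] <- new_exclusion_log("extreme_lcc_percentiles", n0 - nrow(x))

  n0 <- nrow(x)
  with_target <- x |>
    dplyr::filter(.data$as_of_dim %in% c(304L, 305L)) |>
    dplyr::distinct(.data$lactation_key)
  x <- dplyr::semi_join(x, with_target, by = "lactation_key")
  log[[5]] <- new_exclusion_log("no_dim_305_or_304_curve", n0 - nrow(x))

  list(kept = dplyr::select(x, -"lactation_length"),
       exclusion_log = dplyr::bind_rows(log))
}

#' Breeding status of daily records
#'
#' The calculated conception date of a lactation is the subsequent calving
#' date minus 282 days of gestation.  A record is `Never` if the lactation
#' has no subsequent calving, `Bred` if the calculated conception date is
#' strictly earlier than the record date, and `Open` otherwise (a record
#' exactly on the conception date is still Open).
#'
#' @param records Tibble with `lactation_key` and `date` (Date).
#' @param lactations Tibble with `lactation_key`, `calving_date` and
#'   `next_calving_date` (`NA` if none).
#' @return `records` with a `breeding_status` column.
#' @export
assign_breeding_status <- function(records, lactations) {
  x <- dplyr::left_join(
    records,
    dplyr::select(lactations, "lactation_key", "next_calving_date"),
    by = "lactation_key")
  conception <- x$next_calving_date - GESTATION_DAYS
  x$breeding_status <- dplyr::case_when(
    is.na(x$next_calving_date) ~ "Never",
    conception < x$date ~ "Bred",
    TRUE ~ "Open"
  )
  dplyr::select(x, -"next_calving_date")
}

#' Herd-year aggregation of completed lactations
#'
#' Aggregates the final lactation curve characteristics of completed
#' lactations to the calendar year in which each lactation ended.  Herd
#' LCC (HLCC) are means per herd, year and parity group; herd M305 (HM305)
#' is a mean per herd and year only.
#'
#' @param completed Tibble with one row per completed lactation:
#'   `herd_id`, `lactation_key`, `parity_group`, `end_year`, `magnitude`,
#'   `time_to_peak`, `offset`, `decay`, `m305`.
#' @return List with `hlcc` (herd, year, parity group means of the LCC and
#'   a lactation count) and `hm305` (herd, year mean M305).
#' @export
herd_year_aggregate <- function(completed) {
  hlcc <- completed |>
    dplyr::group_by(.data$herd_id, .data$end_year, .data$parity_group) |>
    dplyr::summarise(
      herd_magnitude = mean(.data$magnitude),
      herd_time_to_peak = mean(.data$time_to_peak),
      herd_offset = mean(.data$offset),
      herd_decay = mean(.data$decay),
      n_lactations = dplyr::n(),
      .groups = "drop")
  hm305 <- completed |>
    dplyr::group_by(.data$herd_id, .data$end_year) |>
    dplyr::summarise(herd_m305 = mean(.data$m305),
                     n_lactations = dplyr::n(), .groups = "drop")
  list(hlcc = hlcc, hm305 = hm305)
}

#' Build the feature/target table for one insemination moment
#'
#' For every lactation still Open at the moment, selects the fitted curve
#' at exactly the moment DIM or, failing that, the closest earlier day not
#' below the moment's fallback bound (48, 74, 98 or 122 for moments 50,
#' 75, 100, 125).  Joins the daily yield at the chosen day, the cow's age
#' in months at that day (age in days / 30.4375, one decimal), calving
#' season, parity group, and the herd's previous-calendar-year HLCC
#' (matching parity group) and HM305.  The targets are the decay at DIM
#' 305 (DIM 304 substituting when 305 is absent) and, as a methodological
#' control, the M305 implied by the same final curve.  Rows lacking
#' previous-year herd summaries are dropped (and counted).
#'
#' @param moment One of 50, 75, 100, 125.
#' @param fitted_curves Post-filter fitted records with `breeding_status`
#'   and `date` columns (see [assign_breeding_status()]).
#' @param daily_records Daily yields from [daily_from_visits()].
#' @param lactations Lactation table with `lactation_key`, `herd_id`,
#'   `age_days`, `calving_date`, `parity_group`.
#' @param herd_summaries List from [herd_year_aggregate()].
#' @return Tibble with one row per eligible lactation, plus attributes
#'   `n_no_herd_summary` and `n_no_target`.
#' @export
build_insemination_dataset <- function(moment, fitted_curves, daily_records,
                                       lactations, herd_summaries) {
  if (!moment %in% INSEMINATION_MOMENTS) {
    stop("`moment` must be one of 50, 75, 100, 125", call. = FALSE)
  }
  bound <- MOMENT_FALLBACK_BOUND[[as.character(moment)]]

  # curve at the moment: exact day, else closest earlier day >= bound;
  # only records Open at their own date qualify
  at_moment <- fitted_curves |>
    dplyr::filter(.data$as_of_dim <= moment, .data$as_of_dim >= bound,
                  .data$breeding_status == "Open") |>
    dplyr::group_by(.data$lactation_key) |>
    dplyr::slice_max(.data$as_of_dim, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()

  # target curve: DIM 305, else DIM 304
  target <- fitted_curves |>
    dplyr::filter(.data$as_of_dim %in% c(304L, 305L)) |>
    dplyr::group_by(.data$lactation_key) |>
    dplyr::slice_max(.data$as_of_dim, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(m305 = mb_m305(.data$magnitude, .data$time_to_peak,
                                 .data$offset, .data$decay)) |>
    dplyr::select("lactation_key", target_dim = "as_of_dim",
                  decay_305 = "decay", "m305")

  n_before <- nrow(at_moment)
  rows <- at_moment |>
    dplyr::inner_join(target, by = "lactation_key")
  n_no_target <- n_before - nrow(rows)

  rows <- rows |>
    dplyr::left_join(
      dplyr::select(daily_records, "lactation_key", "dim", "daily_yield_kg"),
      by = c("lactation_key", "as_of_dim" = "dim")) |>
    dplyr::left_join(
      dplyr::select(lactations, "lactation_key", "herd_id", "age_days",
                    "calving_date", "parity_group"),
      by = "lactation_key") |>
    dplyr::mutate(
      age_months = round((.data$age_days + .data$as_of_dim) / 30.4375, 1),
      calving_season = calving_season(.data$calving_date),
      summary_year = as.integer(format(.data$date, "%Y")) - 1L
    )

  n_before <- nrow(rows)
  rows <- rows |>
    dplyr::inner_join(
      herd_summaries$hlcc,
      by = c("herd_id", "summary_year" = "end_year", "parity_group")) |>
    dplyr::inner_join(
      dplyr::select(herd_summaries$hm305, "herd_id", "end_year", "herd_m305"),
      by = c("herd_id", "summary_year" = "end_year"))
  n_no_summary <- n_before - nrow(rows)

  out <- rows |>
    dplyr::mutate(moment = as.integer(moment)) |>
    dplyr::select("moment", "lactation_key", "herd_id",
                  chosen_dim = "as_of_dim", "date", "breeding_status",
                  "magnitude", "time_to_peak", "offset", "decay",
                  "daily_yield_kg", "age_months", "calving_season",
                  "parity_group", "summary_year", "herd_magnitude",
                  "herd_time_to_peak", "herd_offset", "herd_decay",
                  "herd_m305", "target_dim", "decay_305", "m305")
  attr(out, "n_no_herd_summary") <- n_no_summary
  attr(out, "n_no_target") <- n_no_target
  out
}
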