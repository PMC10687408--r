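# Conversion of robot-visit milk records into one 24-h yield per cow-day.
#
# Automatic milking systems record a yield per robot visit; the analysis
# needs one "daily" yield per cow per day.  Following the ICAR-style
# procedure, a 24-h yield is computed at every visit from a rolling window
# of up to the 12 previous milkings as a rate estimate
# (window kg / window hours * 24), and the 24-h yield of the *last* visit
# on a calendar day is taken as that day's daily milk yield.

#' 24-hour milk yield at a visit
#'
#' Rate-based 24-h yield from a window of consecutive milkings ending at
#' the visit of interest.  The first visit in the window serves as the time
#' anchor: its own yield accrued *before* the window, so the rate is the
#' sum of the remaining yields divided by the time span from the anchor to
#' the last visit, scaled to 24 h.  With fewer than 12 prior milkings the
#' window uses all available visits (at least 2).
#'
#' @param window A data frame of consecutive milkings of one lactation,
#'   ordered in time, with columns `visit_datetime` (POSIXct) and
#'   `yield_kg`.  The last row is the visit whose 24-h yield is computed.
#' @return The 24-h yield in kg, with attribute `n_visits_used` giving the
#'   number of milkings whose yields entered the sum.
#' @export
twenty_four_hour_yield <- function(window) {
  stopifnot(is.data.frame(window),
            all(c("visit_datetime", "yield_kg") %in% names(window)))
  n <- nrow(window)
  if (n < 2) stop("at least 2 visits (anchor + current) are required", call. = FALSE)
  span_h <- as.numeric(difftime(window$visit_datetime[n],
                                window$visit_datetime[1], units = "hours"))
  if (span_h <= 0) stop("window time-span must be > 0", call. = FALSE)
  out <- sum(window$yield_kg[-1]) * 24 / span_h
  attr(out, "n_visits_used") <- n - 1L
  out
}

#' Daily yields from robot-visit records
#'
#' Converts a visit-level table (possibly covering many lactations) into
#' one daily record per lactation per calendar day with at least one
#' visit.  The daily value is the 24-h yield at that day's last visit,
#' computed from a rolling window of up to the 12 previous milkings (see
#' [twenty_four_hour_yield()]).  Days whose last visit has no predecessor
#' (the very first visit of a lactation) are skipped with a warning.  No
#' imputation is done for days without visits.
#'
#' Days in milk are whole days since the calving date: the calving day is
#' DIM 0 (dropped), the first full day DIM 1.
#'
#' @param visits Tibble with columns `lactation_key`, `cow_id`, `herd_id`,
#'   `parity`, `calving_date` (Date), `visit_datetime` (POSIXct) and
#'   `yield_kg`.  Visits within a lactation must have distinct timestamps.
#' @param max_window Maximum number of previous milkings in the rolling
#'   window (default 12).
#' @return Tibble of daily records: `lactation_key`, `cow_id`, `herd_id`,
#'   `parity`, `date`, `dim`, `daily_yield_kg`, `n_visits_used`.
#' @export
daily_from_visits <- function(visits, max_window = 12L) {
  req <- c("lactation_key", "cow_id", "herd_id", "parity", "calving_date",
           "visit_datetime", "yield_kg")
  missing_cols <- setdiff(req, names(visits))
  if (length(missing_cols)) {
    stop("`visits` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(visits$yield_kg < 0)) stop("`yield_kg` must be >= 0", call. = FALSE)

  visits <- dplyr::arrange(visits, .data$lactation_key, .data$visit_datetime)

  bad <- as.Date(visits$visit_datetime, tz = "UTC") < visits$calving_date
  if (any(bad)) {
    stop("visits before calving date at rows: ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  }

  out <- visits |>
    dplyr::group_by(.data$lactation_key) |>
    dplyr::mutate(
      .i = dplyr::row_number(),
      .anchor = pmax(1L, .data$.i - as.integer(max_window)),
      .cum = cumsum(.data$yield_kg),
      .sum = .data$.cum - .data$.cum[.data$.anchor],
      .span_h = as.numeric(difftime(.data$visit_datetime,
                                    .data$visit_datetime[.data$.anchor],
                                    units = "hours")),
      y24 = ifelse(.data$.i == 1L, NA_real_, .data$.sum * 24 / .data$.span_h),
      n_visits_used = .data$.i - .data$.anchor
    ) |>
    dplyr::ungroup()

  if (any(out$.span_h[out$.i > 1L] <= 0)) {
    stop("visits within a lactation must be strictly ordered in time ",
         "(duplicate or non-increasing timestamps found)", call. = FALSE)
  }

  out <- out |>
    dplyr::mutate(date = as.Date(.data$visit_datetime, tz = "UTC"),
                  dim = as.integer(.data$date - .data$calving_date))

  # last visit per lactation-day
  daily <- out |>
    dplyr::group_by(.data$lactation_key, .data$date) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup()

  n_skipped <- sum(is.na(daily$y24))
  if (n_skipped > 0) {
    warning(sprintf("%d day(s) skipped: single visit with no predecessor", n_skipped),
            call. = FALSE)
  }

  daily |>
    dplyr::filter(!is.na(.data$y24), .data$dim >= 1L) |>
    dplyr::select("lactation_key", "cow_id", "herd_id", "parity", "date",
                  "dim", daily_yield_kg = "y24", "n_visits_used")
}

#' Read / write visit-level and daily tables
#'
#' Thin CSV readers and writers for the pipeline's delimited interchange
#' schema: `herd_id, cow_id, parity, birth_date, calving_date,
#' visit_datetime, yield_kg` for visits.  Dates are ISO `yyyy-mm-dd`,
#' timestamps ISO in UTC.  A `lactation_key` (`cow_id "_" parity`) is added
#' on read if absent.
#'
#' @param path File path.
#' @return `read_visits()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
read_visits <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  x$birth_date <- as.Date(x$birth_date)
  x$calving_date <- as.Date(x$calving_date)
  x$visit_datetime <- as.POSIXct(x$visit_datetime, tz = "UTC")
  if (!"lactation_key" %in% names(x)) {
    x$lactation_key <- paste(x$cow_id, x$parity, sep = "_")
  }
  x
}

#' @rdname read_visits
#' @param visits Visit-level tibble.
#' @export
write_visits <- function(visits, path) {
  v <- visits
  v$visit_datetime <- format(v$visit_datetime, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(v, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_visits
#' @param daily Daily-record tibble from [daily_from_visits()].
#' @export
write_daily_records <- function(daily, path) {
  utils::write.csv(daily, path, row.names = FALSE)
  invisible(path)
}
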