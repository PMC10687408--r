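make_lactations <- function(n, parity = 1L, age = NULL, len = NULL,
                            herd = "h01") {
  tibble::tibble(
    lactation_key = sprintf("c%03d_%d", seq_len(n), parity),
    cow_id = sprintf("c%03d", seq_len(n)), herd_id = herd,
    parity = parity,
    parity_group = ifelse(parity == 1L, "primiparous", "multiparous"),
    age_days = if (is.null(age)) rep(800, n) else age,
    lactation_length = if (is.null(len)) rep(340, n) else len,
    calving_date = as.Date("2020-02-01"),
    next_calving_date = as.Date(NA)
  )
}

test_that("lactation filters drop missing parity, extreme age and length", {
  x <- make_lactations(100, age = seq(701, 800))
  x$parity[5] <- NA
  res <- lactation_level_filters(x)
  log <- res$exclusion_log
  expect_identical(log$n_excluded[log$step == "missing_parity"], 1L)

  # uniform ages: exactly the rows a brute-force percentile filter drops
  remaining <- x$age_days[-5]
  lo <- quantile(remaining, 0.01, type = 7)
  hi <- quantile(remaining, 0.99, type = 7)
  brute <- sum(remaining < lo | remaining > hi)
  expect_identical(log$n_excluded[log$step == "extreme_age_within_parity"],
                   as.integer(brute))

  # step counts account exactly for input minus output
  expect_identical(nrow(x) - nrow(res$kept), sum(log$n_excluded))
})

test_that("degenerate percentiles drop nothing", {
  x <- make_lactations(50)  # all-identical ages and lengths
  res <- lactation_level_filters(x)
  expect_identical(nrow(res$kept), 50L)
  expect_true(all(res$exclusion_log$n_excluded == 0L))
})

test_that("age percentiles are computed within parity", {
  young <- make_lactations(60, parity = 1L, age = seq(700, 759))
  old <- make_lactations(60, parity = 3L, age = seq(1400, 1459))
  res <- lactation_level_filters(dplyr::bind_rows(young, old))
  # a pooled filter would drop whole age groups; within parity only each
  # group's two tail lactations go
  expect_identical(
    res$exclusion_log$n_excluded[res$exclusion_log$step ==
                                   "extreme_age_within_parity"], 4L)
})

make_fitted <- function(keys, dims, decay = 1.5e-3, rmse = 1.2,
                        magnitude = 40, ttp = 25, offset = -0.5) {
  tidyr::crossing(lactation_key = keys, as_of_dim = as.integer(dims)) |>
    dplyr::mutate(magnitude = magnitude, time_to_peak = ttp, offset = offset,
                  decay = decay, fit_rmse = rmse, n_points = as_of_dim)
}

test_that("post-fit filters apply the cascade in order", {
  lact <- make_lactations(4)
  lact$lactation_length[1] <- 200  # ends before DIM 305
  fitted <- make_fitted(lact$lactation_key, c(50, 304, 305))
  fitted$decay[fitted$lactation_key == "c002_1" &
                 fitted$as_of_dim == 50] <- -1e-4
  res <- post_fit_filters(fitted, lact)
  log <- res$exclusion_log
  expect_identical(log$n_excluded[log$step == "lactation_shorter_than_305"], 3L)
  expect_identical(log$n_excluded[log$step == "negative_decay"], 1L)
  expect_false("c001_1" %in% res$kept$lactation_key)
  expect_false(any(res$kept$decay < 0))
  expect_identical(nrow(fitted) - nrow(res$kept), sum(log$n_excluded))
})

test_that("post-fit percentile filters equal a brute-force reapplication", {
  withr::local_seed(23)
  n <- 400
  lact <- make_lactations(n)
  fitted <- tibble::tibble(
    lactation_key = rep(lact$lactation_key, each = 2),
    as_of_dim = rep(c(75L, 305L), n),
    magnitude = rnorm(2 * n, 40, 6),
    time_to_peak = rnorm(2 * n, 25, 3),
    offset = rnorm(2 * n, -0.5, 0.1),
    decay = rnorm(2 * n, 1.6e-3, 0.9e-3),  # some negative by construction
    fit_rmse = rexp(2 * n, 1), n_points = 1L)

  res <- post_fit_filters(fitted, lact)

  # independent brute-force reapplication of the stated thresholds
  x <- fitted[fitted$decay >= 0, ]
  x <- x[x$fit_rmse <= quantile(x$fit_rmse, 0.95, type = 7), ]
  ok <- rep(TRUE, nrow(x))
  for (col in c("magnitude", "time_to_peak", "decay")) {
    lo <- quantile(x[[col]], 0.01, type = 7)
    hi <- quantile(x[[col]], 0.99, type = 7)
    ok <- ok & x[[col]] >= lo & x[[col]] <= hi
  }
  x <- x[ok, ]
  keys305 <- unique(x$lactation_key[x$as_of_dim %in% c(304L, 305L)])
  x <- x[x$lactation_key %in% keys305, ]

  expect_identical(nrow(res$kept), nrow(x))
  expect_setequal(paste(res$kept$lactation_key, res$kept$as_of_dim),
                  paste(x$lactation_key, x$as_of_dim))
})

test_that("breeding status follows the 282-day back-calculation", {
  lact <- make_lactations(2)
  lact$next_calving_date[1] <- lact$calving_date[1] + 382  # conception DIM 100
  records <- tidyr::crossing(lactation_key = lact$lactation_key,
                             dim = c(50L, 100L, 101L, 150L)) |>
    dplyr::mutate(date = as.Date("2020-02-01") + dim)
  out <- assign_breeding_status(records, lact)

  bred1 <- out[out$lactation_key == "c001_1", ]
  expect_identical(bred1$breeding_status[bred1$dim <= 100],
                   rep("Open", 2))  # record on the conception date is Open
  expect_identical(bred1$breeding_status[bred1$dim > 100], rep("Bred", 2))

  never <- out[out$lactation_key == "c002_1", ]
  expect_true(all(never$breeding_status == "Never"))
})

test_that("herd-year aggregation equals independent group means", {
  completed <- tibble::tibble(
    herd_id = c("h01", "h01", "h01", "h02"),
    lactation_key = sprintf("c%03d_1", 1:4),
    parity_group = c("primiparous", "primiparous", "multiparous", "primiparous"),
    end_year = 2020L,
    magnitude = c(38, 42, 50, 39), time_to_peak = c(28, 27, 21, 29),
    offset = c(-0.5, -0.5, -0.5, -0.5), decay = c(1e-3, 3e-3, 2e-3, 1.5e-3),
    m305 = c(8800, 9200, 10500, 8700))
  hs <- herd_year_aggregate(completed)

  expect_equal(hs$hlcc$herd_decay[hs$hlcc$herd_id == "h01" &
                                    hs$hlcc$parity_group == "primiparous"],
               2e-3)
  # HM305 pools parity groups within the herd-year
  expect_equal(hs$hm305$herd_m305[hs$hm305$herd_id == "h01"],
               mean(c(8800, 9200, 10500)))
  expect_equal(hs$hm305$herd_m305[hs$hm305$herd_id == "h02"], 8700)

  # brute-force group-by on a random cohort
  withr::local_seed(61)
  big <- tibble::tibble(
    herd_id = sample(sprintf("h%02d", 1:3), 200, TRUE),
    lactation_key = sprintf("c%03d_1", 1:200),
    parity_group = sample(c("primiparous", "multiparous"), 200, TRUE),
    end_year = sample(2019:2020, 200, TRUE),
    magnitude = rnorm(200, 45), time_to_peak = rnorm(200, 24),
    offset = rnorm(200, -0.5, 0.1), decay = rnorm(200, 2e-3, 5e-4),
    m305 = rnorm(200, 9500, 800))
  hs2 <- herd_year_aggregate(big)
  brute <- aggregate(decay ~ herd_id + end_year + parity_group, big, mean)
  merged <- merge(hs2$hlcc, brute)
  expect_equal(merged$herd_decay, merged$decay)
  brute305 <- aggregate(m305 ~ herd_id + end_year, big, mean)
  merged305 <- merge(hs2$hm305, brute305)
  expect_equal(merged305$herd_m305, merged305$m305)
})

test_that("insemination datasets pick the exact day or a bounded fallback", {
  lact <- make_lactations(3)
  lact$next_calving_date <- lact$calving_date + 500  # conception DIM 218
  # c001 has every day; c002 misses DIM 75 but has 74; c003 has nothing
  # in the window [74, 75]
  fitted <- dplyr::bind_rows(
    make_fitted("c001_1", c(74, 75, 304, 305)),
    make_fitted("c002_1", c(73, 74, 304, 305)),
    make_fitted("c003_1", c(50, 73, 304, 305)))
  fitted$date <- as.Date("2020-02-01") + fitted$as_of_dim
  fitted <- assign_breeding_status(fitted, lact)
  daily <- fitted |>
    dplyr::transmute(lactation_key, dim = as_of_dim, daily_yield_kg = 30)
  completed <- tibble::tibble(
    herd_id = "h01", lactation_key = "c099_1", parity_group = "primiparous",
    end_year = 2019L, magnitude = 40, time_to_peak = 25, offset = -0.5,
    decay = 1.5e-3, m305 = 9000)
  hs <- herd_year_aggregate(completed)

  ds <- build_insemination_dataset(75, fitted, daily, lact, hs)
  expect_identical(ds$chosen_dim[ds$lactation_key == "c001_1"], 75L)
  expect_identical(ds$chosen_dim[ds$lactation_key == "c002_1"], 74L)
  expect_false("c003_1" %in% ds$lactation_key)
  expect_true(all(ds$target_dim == 305L))
  expect_equal(unique(ds$herd_m305), 9000)
  # herd summaries must come from the year before the record date
  expect_true(all(as.integer(format(ds$date, "%Y")) - 1L == 2019L))

  expect_error(build_insemination_dataset(60, fitted, daily, lact, hs),
               "must be one of")
})

test_that("rows from Bred lactations are excluded at the moment", {
  lact <- make_lactations(1)
  lact$next_calving_date <- lact$calving_date + 332  # conception DIM 50
  fitted <- make_fitted("c001_1", c(74, 75, 304, 305))
  fitted$date <- as.Date("2020-02-01") + fitted$as_of_dim
  fitted <- assign_breeding_status(fitted, lact)
  daily <- fitted |>
    dplyr::transmute(lactation_key, dim = as_of_dim, daily_yield_kg = 30)
  completed <- tibble::tibble(
    herd_id = "h01", lactation_key = "c099_1", parity_group = "primiparous",
    end_year = 2019L, magnitude = 40, time_to_peak = 25, offset = -0.5,
    decay = 1.5e-3, m305 = 9000)
  ds <- build_insemination_dataset(75, fitted, daily, lact,
                                   herd_year_aggregate(completed))
  expect_identical(nrow(ds), 0L)
})
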