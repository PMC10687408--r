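toy_dataset <- function(n, seed = 1, beta = NULL, noise_sd = 1) {
  withr::with_seed(seed, {
    x <- tibble::tibble(
      magnitude = rnorm(n, 45, 6),
      decay = rnorm(n, 2e-3, 8e-4),
      daily_yield_kg = rnorm(n, 35, 5),
      age_months = rnorm(n, 40, 12),
      calving_season = sample(c("Winter", "Spring", "Summer", "Autumn"), n,
                              replace = TRUE),
      parity_group = sample(c("primiparous", "multiparous"), n, replace = TRUE)
    )
    if (is.null(beta)) beta <- c(magnitude = 0, decay = 0, daily_yield_kg = 0)
    x$decay_305 <- as.numeric(as.matrix(x[names(beta)]) %*% beta) +
      rnorm(n, 0, noise_sd)
    x
  })
}

test_that("train/test split is deterministic and correctly sized", {
  d <- toy_dataset(10)
  sp <- split_train_test(d, 0.8, seed = 3)
  expect_identical(nrow(sp$train), 8L)
  expect_identical(nrow(sp$test), 2L)
  sp2 <- split_train_test(d, 0.8, seed = 3)
  expect_identical(sp$train, sp2$train)
  # no overlap, full coverage
  expect_identical(nrow(dplyr::bind_rows(sp$train, sp$test)), 10L)
  expect_identical(nrow(dplyr::intersect(sp$train, sp$test)), 0L)
  expect_error(split_train_test(d[0, ]), "non-empty")
})

test_that("standardization centres train and reuses the train scaler", {
  d <- toy_dataset(200, seed = 5)
  sp <- split_train_test(d, 0.8, seed = 1)
  st <- standardize(sp$train, sp$test)
  for (col in c("magnitude", "decay", "daily_yield_kg", "age_months")) {
    expect_lt(abs(mean(st$train[[col]])), 1e-10)
    expect_equal(sd(st$train[[col]]), 1, tolerance = 1e-10)
  }
  # test columns transformed with the train means/sds, not their own
  sc <- st$scaler
  j <- match("magnitude", sc$column)
  expect_equal(st$test$magnitude,
               (sp$test$magnitude - sc$mean[j]) / sc$sd[j])

  # constant columns are dropped with a warning
  d$herd_offset <- -0.5
  expect_warning(standardize(d), "constant")
})

test_that("standardized coefficients equal raw coefficients times sd", {
  d <- toy_dataset(500, seed = 8,
                   beta = c(magnitude = 1e-5, decay = 0.3,
                            daily_yield_kg = -2e-5), noise_sd = 5e-4)
  raw <- lm(decay_305 ~ magnitude + decay + daily_yield_kg, data = d)
  st <- standardize(d, cols = c("magnitude", "decay", "daily_yield_kg"))
  std <- lm(decay_305 ~ magnitude + decay + daily_yield_kg, data = st$train)
  for (col in c("magnitude", "decay", "daily_yield_kg")) {
    j <- match(col, st$scaler$column)
    expect_equal(unname(coef(std)[col]),
                 unname(coef(raw)[col]) * st$scaler$sd[j], tolerance = 1e-8)
  }
})

test_that("OLS recovers simulated coefficients within sampling error", {
  withr::local_seed(100)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    d <- toy_dataset(200, seed = 1000 + r,
                     beta = c(magnitude = 2e-5, decay = 0.25,
                              daily_yield_kg = -1.5e-5), noise_sd = 8e-4)
    st <- standardize(d, cols = c("magnitude", "decay", "daily_yield_kg"))
    fit <- fit_linear_model(st$train, "decay_305",
                            predictors = c("magnitude", "decay",
                                           "daily_yield_kg"))
    cf <- summary(fit$model)$coefficients
    j <- match("decay", st$scaler$column)
    true_std <- 0.25 * st$scaler$sd[j]
    hits <- hits +
      as.integer(abs(cf["decay", "Estimate"] - true_std) <=
                   3 * cf["decay", "Std. Error"])
  }
  # ~99.7% coverage expected at 3 SEs; allow generous sampling slack
  expect_gte(hits, 180L)
})

test_that("a pure-noise target gives near-zero held-out R2", {
  d <- toy_dataset(5000, seed = 77, noise_sd = 1)
  ev <- evaluate_moment(
    dplyr::mutate(d, m305 = 0), target = "decay_305", seed = 9)
  expect_lt(abs(ev$metrics$r2), 0.05)
})

test_that("duplicated predictors raise a rank-deficiency error", {
  d <- toy_dataset(100, seed = 2)
  d$decay_copy <- d$decay
  st <- standardize(d, cols = c("magnitude", "decay"))
  expect_error(
    fit_linear_model(st$train, "decay_305",
                     predictors = c("magnitude", "decay", "decay_copy")),
    "decay_copy")
})

test_that("metrics match hand-computed values", {
  m <- compute_metrics(predicted = c(2, 2, 2, 2), observed = c(1, 2, 3, 4))
  expect_equal(m$rmse, sqrt(6 / 4))
  expect_equal(m$mae, 1)
  expect_equal(m$mape, (1 / 1 + 0 + 1 / 3 + 2 / 4) / 4)

  perfect <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mape, 0)

  # predicting the mean gives R2 exactly 0
  obs <- c(1, 2, 3, 4)
  at_mean <- compute_metrics(rep(mean(obs), 4), obs)
  expect_equal(at_mean$r2, 0)

  # zero observations are excluded from the MAPE with a count
  z <- compute_metrics(c(1, 1), c(0, 2))
  expect_identical(z$n_mape_excluded, 1L)
  expect_equal(z$mape, 0.5)

  expect_error(compute_metrics(1:3, 1:2), "equal-length")
})

test_that("cross-validation folds are balanced, seeded and leakage-free", {
  d <- toy_dataset(53, seed = 10, beta = c(magnitude = 1e-5, decay = 0.2,
                                           daily_yield_kg = 0),
                   noise_sd = 1e-3)
  cv <- cross_validate(d, "decay_305", k = 10, seed = 2,
                       predictors = c("magnitude", "decay"))
  sizes <- table(cv$predictions$fold)
  expect_lte(diff(range(sizes)), 1)
  cv2 <- cross_validate(d, "decay_305", k = 10, seed = 2,
                        predictors = c("magnitude", "decay"))
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(cross_validate(d, "decay_305", k = 1), "k")
})

test_that("leave-one-out cross-validation matches a brute-force loop", {
  d <- toy_dataset(20, seed = 11, beta = c(magnitude = 1e-5, decay = 0.2,
                                           daily_yield_kg = 0),
                   noise_sd = 1e-3)
  d <- d[c("magnitude", "decay", "decay_305")]  # continuous terms only
  preds_cols <- c("magnitude", "decay")
  cv <- cross_validate(d, "decay_305", k = 20, seed = 4,
                       predictors = preds_cols)

  brute <- vapply(seq_len(20), function(i) {
    tr <- d[-i, ]
    mu <- vapply(tr[preds_cols], mean, numeric(1))
    sdev <- vapply(tr[preds_cols], sd, numeric(1))
    tr_s <- tr; te_s <- d[i, ]
    for (j in seq_along(preds_cols)) {
      tr_s[[preds_cols[j]]] <- (tr[[preds_cols[j]]] - mu[j]) / sdev[j]
      te_s[[preds_cols[j]]] <- (d[i, ][[preds_cols[j]]] - mu[j]) / sdev[j]
    }
    m <- lm(decay_305 ~ magnitude + decay, data = tr_s)
    unname(predict(m, newdata = te_s))
  }, numeric(1))

  got <- cv$predictions$predicted[order(cv$predictions$row)]
  expect_equal(got, brute, tolerance = 1e-10)
})

test_that("coefficient ranking is by |estimate| with deterministic ties", {
  d <- toy_dataset(400, seed = 13,
                   beta = c(magnitude = 0, decay = 0.5, daily_yield_kg = 0),
                   noise_sd = 1e-4)
  st <- standardize(d, cols = c("magnitude", "decay", "daily_yield_kg"))
  fit <- fit_linear_model(st$train, "decay_305",
                          predictors = c("magnitude", "decay",
                                         "daily_yield_kg"))
  rk <- coefficient_ranking(fit)
  expect_identical(rk$term[1], "decay")
  expect_identical(rk$rank, seq_len(nrow(rk)))

  # invariant to predictor column order
  fit2 <- fit_linear_model(st$train, "decay_305",
                           predictors = c("daily_yield_kg", "decay",
                                          "magnitude"))
  expect_identical(coefficient_ranking(fit2)$term, rk$term)

  # an all-zero fit ranks alphabetically
  d0 <- d; d0$decay_305 <- 0
  st0 <- standardize(d0, cols = c("magnitude", "decay", "daily_yield_kg"))
  fit0 <- fit_linear_model(st0$train, "decay_305",
                           predictors = c("magnitude", "decay",
                                          "daily_yield_kg"))
  rk0 <- coefficient_ranking(fit0)
  expect_identical(rk0$term, sort(rk0$term))
})
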