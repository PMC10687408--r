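# Linear prediction models for decay-305 (and the M305 control) at each
# insemination moment, with a leakage-safe split / standardize / fit /
# evaluate workflow and the usual regression metrics.

#' Continuous predictor columns used by the prediction models
#' @export
persist_continuous_predictors <- function() {
  c("magnitude", "time_to_peak", "offset", "decay", "daily_yield_kg",
    "age_months", "herd_magnitude", "herd_time_to_peak", "herd_offset",
    "herd_decay", "herd_m305")
}

#' Random train/test split
#'
#' Splits rows (cow-parity records) at random into training and test
#' sets.  Deterministic for a given seed; sizes are within one row of the
#' requested fractions.
#'
#' @param data A data frame.
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(data, fraction = 0.8, seed = 1L) {
  n <- nrow(data)
  if (n == 0) stop("`data` must be non-empty", call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  idx <- with_preserved_seed(seed, sample.int(n, size = round(n * fraction)))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Standardize continuous predictors with a train-fitted scaler
#'
#' Centres and scales the continuous predictor columns using the training
#' set's means and SDs; the test set (if given) is transformed with the
#' *training* scaler, never its own.  Columns that are constant in the
#' training set cannot be standardized and are dropped from both tables
#' with a warning.
#'
#' @param train,test Data frames (test may be `NULL`).
#' @param cols Columns to standardize; defaults to the model's continuous
#'   predictors present in `train`.
#' @return List with `train`, `test`, `scaler` (tibble of column, mean,
#'   sd) and `dropped` (character).
#' @export
standardize <- function(train, test = NULL,
                        cols = intersect(persist_continuous_predictors(),
                                         names(train))) {
  mu <- vapply(train[cols], mean, numeric(1))
  sdev <- vapply(train[cols], stats::sd, numeric(1))
  constant <- sdev < 1e-10 | !is.finite(sdev)
  if (any(constant)) {
    warning("dropping constant column(s): ",
            paste(cols[constant], collapse = ", "), call. = FALSE)
    drop_cols <- cols[constant]
    train <- train[, setdiff(names(train), drop_cols), drop = FALSE]
    if (!is.null(test)) test <- test[, setdiff(names(test), drop_cols), drop = FALSE]
    cols <- cols[!constant]
    mu <- mu[!constant]; sdev <- sdev[!constant]
  }
  for (j in seq_along(cols)) {
    train[[cols[j]]] <- (train[[cols[j]]] - mu[j]) / sdev[j]
    if (!is.null(test)) test[[cols[j]]] <- (test[[cols[j]]] - mu[j]) / sdev[j]
  }
  list(train = train, test = test,
       scaler = tibble::tibble(column = cols, mean = unname(mu), sd = unname(sdev)),
       dropped = if (exists("drop_cols")) drop_cols else character(0))
}

# categorical predictors with their reference levels
season_factor <- function(x) factor(x, levels = c("Winter", "Spring", "Summer", "Autumn"))
parity_factor <- function(x) factor(x, levels = c("primiparous", "multiparous"))

#' Fit the insemination-moment linear model
#'
#' Ordinary least squares for the target (`decay_305` or `m305`) on the
#' standardized continuous predictors plus calving season (reference
#' Winter) and parity group (reference primiparous).  The intercept is
#' the overall mean term.  A rank-deficient design (e.g. a duplicated
#' predictor) is an error naming the aliased terms.
#'
#' @param train Standardized training tibble (see [standardize()]).
#' @param target `"decay_305"` or `"m305"`.
#' @param predictors Optional character vector of continuous predictor
#'   columns; defaults to those of [persist_continuous_predictors()]
#'   present in `train`.
#' @return List of class `"persist_model"`: `model` (an `lm`), `target`,
#'   `predictors`.
#' @export
fit_linear_model <- function(train, target = c("decay_305", "m305"),
                             predictors = NULL) {
  target <- match.arg(target)
  if (is.null(predictors)) {
    predictors <- intersect(persist_continuous_predictors(), names(train))
  }
  dat <- train
  cat_terms <- character(0)
  if ("calving_season" %in% names(dat)) {
    dat$calving_season <- season_factor(dat$calving_season)
    cat_terms <- c(cat_terms, "calving_season")
  }
  if ("parity_group" %in% names(dat)) {
    dat$parity_group <- parity_factor(dat$parity_group)
    cat_terms <- c(cat_terms, "parity_group")
  }
  rhs <- paste(c(predictors, cat_terms), collapse = " + ")
  fml <- stats::as.formula(paste(target, "~", rhs))
  m <- stats::lm(fml, data = dat)
  aliased <- is.na(stats::coef(m))
  if (any(aliased)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(which(aliased)), collapse = ", "), call. = FALSE)
  }
  structure(list(model = m, target = target,
                 predictors = c(predictors, cat_terms)),
            class = "persist_model")
}

#' @export
predict.persist_model <- function(object, newdata, ...) {
  nd <- newdata
  if ("calving_season" %in% names(nd)) nd$calving_season <- season_factor(nd$calving_season)
  if ("parity_group" %in% names(nd)) nd$parity_group <- parity_factor(nd$parity_group)
  unname(stats::predict(object$model, newdata = nd))
}

#' Regression evaluation metrics
#'
#' R-squared (`1 - SSres/SStot`), root mean squared error, mean absolute
#' error and mean absolute percentage error of predictions against
#' observations.  Rows with observed value 0 cannot enter the MAPE and
#' are excluded from it with a count (`n_mape_excluded`); decay targets
#' are strictly positive after filtering so this is normally zero.
#'
#' @param predicted,observed Equal-length non-empty numeric vectors.
#' @return Tibble with `r2`, `rmse`, `mae`, `mape`, `n`, `n_mape_excluded`.
#' @export
compute_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) == 0) {
    stop("`predicted` and `observed` must be equal-length, non-empty",
         call. = FALSE)
  }
  err <- predicted - observed
  ss_res <- sum(err^2)
  ss_tot <- sum((observed - mean(observed))^2)
  nonzero <- observed != 0
  tibble::tibble(
    r2 = 1 - ss_res / ss_tot,
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    mape = mean(abs(err[nonzero] / observed[nonzero])),
    n = length(observed),
    n_mape_excluded = sum(!nonzero)
  )
}

#' k-fold cross-validation of the linear model
#'
#' Splits the (unstandardized) training data into `k` disjoint folds of
#' sizes differing by at most one, then for each fold standardizes and
#' fits on the other folds and predicts the held-out fold.  Used for
#' validation reporting only -- plain OLS has no hyperparameters to tune.
#'
#' @param data Unstandardized training tibble.
#' @param target `"decay_305"` or `"m305"`.
#' @param k Number of folds (>= 2, <= rows); `k = n` gives leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @inheritParams fit_linear_model
#' @return List with `folds` (per-fold metrics where defined),
#'   `predictions` (row, fold, observed, predicted for every row) and
#'   `pooled` (metrics on the pooled out-of-fold predictions).
#' @export
cross_validate <- function(data, target = c("decay_305", "m305"), k = 10L,
                           seed = 1L, predictors = NULL) {
  target <- match.arg(target)
  n <- nrow(data)
  if (k < 2 || k > n) stop("need 2 <= k <= nrow(data)", call. = FALSE)
  fold <- with_preserved_seed(seed, sample(rep(seq_len(k), length.out = n)))
  preds <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    st <- suppressWarnings(standardize(data[!hold, , drop = FALSE],
                                       data[hold, , drop = FALSE]))
    fit <- fit_linear_model(st$train, target, predictors = predictors)
    preds[hold] <- predict(fit, st$test)
  }
  predictions <- tibble::tibble(row = seq_len(n), fold = fold,
                                observed = data[[target]], predicted = preds)
  folds <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::reframe(compute_metrics(.data$predicted, .data$observed))
  list(folds = folds, predictions = predictions,
       pooled = compute_metrics(preds, data[[target]]))
}

#' Coefficient ranking by standardized effect size
#'
#' Orders the fitted coefficients (intercept excluded) by the absolute
#' value of the standardized estimate, largest first; exact ties break
#' alphabetically by term name, so the order is deterministic and
#' invariant to predictor column order.
#'
#' @param fit A `"persist_model"` from [fit_linear_model()].
#' @return Tibble with `term`, `estimate`, `std_error`, `rank`.
#' @export
coefficient_ranking <- function(fit) {
  stopifnot(inherits(fit, "persist_model"))
  cf <- summary(fit$model)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  out <- tibble::tibble(term = rownames(cf),
                        estimate = unname(cf[, "Estimate"]),
                        std_error = unname(cf[, "Std. Error"]))
  out <- out[order(-abs(out$estimate), out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
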