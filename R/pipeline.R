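# End-to-end study pipeline: synthetic population -> daily yields ->
# editing cascade -> curve fits at decision and target days -> herd-year
# covariates -> insemination-moment datasets -> prediction models.

#' Fit curves for a cohort at the days the analysis consumes
#'
#' For every lactation, fits the curve "as of" each requested day that has
#' a daily record: every day within each moment's fallback window (so the
#' closest day that *survives* the editing cascade can be chosen) for every
#' moment, plus the target days DIM 305 and 304.  Fits
#' within a lactation are warm-started in DIM order.  Lactations too short
#' to ever have a DIM-305 curve are not fitted (the editing cascade would
#' drop all their records).
#'
#' @param daily Daily records (see [daily_from_visits()]).
#' @param lactations Lactation table with `parity_group`,
#'   `lactation_length`, `calving_date`.
#' @param moments Insemination moments to serve (default all four).
#' @param priors Named list of [lcc_prior()]s per parity group.
#' @param seed Seed forwarded to [fit_curve()] restarts.
#' @return Tibble of fitted records with `lactation_key`, `as_of_dim`,
#'   the LCC columns, `fit_rmse`, `n_points`, `converged`, `date`.
#' @export
fit_cohort_curves <- function(daily, lactations,
                              moments = INSEMINATION_MOMENTS,
                              priors = default_lcc_priors(), seed = 0L) {
  eligible <- lactations[lactations$lactation_length >= 305, , drop = FALSE]
  daily <- daily[daily$lactation_key %in% eligible$lactation_key, , drop = FALSE]
  daily_split <- split(daily, daily$lactation_key)
  grp <- stats::setNames(eligible$parity_group, eligible$lactation_key)
  calv <- stats::setNames(eligible$calving_date, eligible$lactation_key)

  bounds <- MOMENT_FALLBACK_BOUND[as.character(moments)]
  out <- vector("list", length(daily_split))
  for (i in seq_along(daily_split)) {
    d <- daily_split[[i]]
    key <- d$lactation_key[1]
    dims <- sort(unique(d$dim))
    want <- integer(0)
    for (j in seq_along(moments)) {
      want <- c(want, dims[dims >= bounds[j] & dims <= moments[j]])
    }
    # both target days are fitted so DIM 304 can substitute when the DIM
    # 305 record is later removed by the editing cascade
    want <- sort(unique(c(want, dims[dims %in% c(304L, 305L)])))
    if (!length(want)) next
    fits <- incremental_fit_series(d, priors[[grp[[key]]]], dims = want,
                                   seed = seed)
    fits$lactation_key <- key
    fits$date <- as.Date(calv[[key]]) + fits$as_of_dim
    out[[i]] <- fits
  }
  bind_rows_safe(out)
}

#' Fit and evaluate one insemination-moment model
#'
#' 80/20 train-test split, train-fitted standardization, OLS fit,
#' held-out metrics, optional k-fold cross-validation on the training
#' set, and the coefficient ranking.
#'
#' @param dataset One moment's table from [build_insemination_dataset()].
#' @param target `"decay_305"` or `"m305"`.
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Split (and fold) seed.
#' @param cv_folds If >= 2, also run k-fold cross-validation.
#' @return List with `metrics` (held-out test metrics), `model`,
#'   `ranking`, `cv` (or `NULL`), `n_train`, `n_test`.
#' @export
evaluate_moment <- function(dataset, target = c("decay_305", "m305"),
                            train_fraction = 0.8, seed = 1L, cv_folds = 0L) {
  target <- match.arg(target)
  sp <- split_train_test(dataset, fraction = train_fraction, seed = seed)
  st <- suppressWarnings(standardize(sp$train, sp$test))
  fit <- fit_linear_model(st$train, target)
  pred <- predict(fit, st$test)
  metrics <- compute_metrics(pred, st$test[[target]])
  cv <- if (cv_folds >= 2) {
    cross_validate(sp$train, target, k = cv_folds, seed = seed)
  }
  list(metrics = metrics, model = fit, ranking = coefficient_ranking(fit),
       cv = cv, n_train = nrow(sp$train), n_test = nrow(sp$test))
}

#' Run the full persistency study on a synthetic population
#'
#' Generates a population, reconstructs daily yields from robot visits,
#' applies the lactation-level and post-fit editing cascades, assigns
#' breeding status, aggregates herd-year covariates, builds the
#' insemination-moment datasets and fits/evaluates the prediction models
#' for each moment and target.
#'
#' @param config A [simulation_config()].
#' @param moments Insemination moments (subset of 50, 75, 100, 125).
#' @param targets Model targets to evaluate.
#' @param split_seed Seed for the train/test splits.
#' @param cv_folds If >= 2, cross-validate each training set.
#' @return List with `metrics` (tibble: moment, target, r2, rmse, mae,
#'   mape, n, n_train, n_test), `datasets`, `evaluations`, `exclusion_log`,
#'   `herd_summaries` and `ground_truth`.
#' @export
run_persistency_study <- function(config = simulation_config(),
                                  moments = INSEMINATION_MOMENTS,
                                  targets = c("decay_305", "m305"),
                                  split_seed = 1L, cv_folds = 0L) {
  sim <- simulate_population(config)
  daily <- suppressWarnings(daily_from_visits(sim$visits))
  lact <- sim$lactations

  lf <- lactation_level_filters(lact)
  lact_kept <- lf$kept
  daily <- daily[daily$lactation_key %in% lact_kept$lactation_key, , drop = FALSE]

  fitted <- fit_cohort_curves(daily, lact_kept, moments = moments)
  pf <- post_fit_filters(fitted, lact_kept)
  kept <- assign_breeding_status(pf$kept, lact_kept)

  # herd-year covariates from the final (DIM 305/304) curve of each
  # completed lactation, keyed by the calendar year the lactation ended
  completed <- kept |>
    dplyr::filter(.data$as_of_dim %in% c(304L, 305L)) |>
    dplyr::group_by(.data$lactation_key) |>
    dplyr::slice_max(.data$as_of_dim, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::inner_join(
      dplyr::select(lact_kept, "lactation_key", "herd_id", "parity_group",
                    "calving_date", "lactation_length"),
      by = "lactation_key") |>
    dplyr::mutate(
      end_year = as.integer(format(.data$calving_date +
                                     .data$lactation_length, "%Y")),
      m305 = mb_m305(.data$magnitude, .data$time_to_peak, .data$offset,
                     .data$decay))
  herd_summaries <- herd_year_aggregate(completed)

  datasets <- lapply(moments, function(m) {
    build_insemination_dataset(m, kept, daily, lact_kept, herd_summaries)
  })
  names(datasets) <- as.character(moments)

  evaluations <- list()
  metric_rows <- list()
  for (m in as.character(moments)) {
    for (tg in targets) {
      ev <- evaluate_moment(datasets[[m]], target = tg,
                            seed = split_seed + as.integer(m),
                            cv_folds = cv_folds)
      evaluations[[paste(tg, m, sep = "_")]] <- ev
      metric_rows[[paste(tg, m, sep = "_")]] <- dplyr::bind_cols(
        tibble::tibble(moment = as.integer(m), target = tg),
        ev$metrics,
        tibble::tibble(n_train = ev$n_train, n_test = ev$n_test))
    }
  }

  list(
    metrics = dplyr::bind_rows(metric_rows),
    datasets = datasets,
    evaluations = evaluations,
    exclusion_log = dplyr::bind_rows(
      dplyr::mutate(lf$exclusion_log, stage = "lactation_level"),
      dplyr::mutate(pf$exclusion_log, stage = "post_fit")),
    herd_summaries = herd_summaries,
    ground_truth = sim$ground_truth
  )
}
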