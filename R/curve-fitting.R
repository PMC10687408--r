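# Prior-regularised MilkBot curve fitting.
#
# Lactation curve characteristics are estimated "as of" a day in milk T by
# fitting the MilkBot model to all daily yields with dim <= T.  With few
# records the data barely identify four parameters, so the fit is shrunk
# toward parity-group population priors: the estimate is the MAP solution
# of a penalized nonlinear least-squares problem
#
#   min_theta  sum_i (y_i - Y(t_i; theta))^2 + sum_p ((theta_p - mu_p)/sigma_p)^2
#
# i.e. Gaussian priors with homoscedastic Gaussian noise whose variance
# scaling is absorbed into the prior sds.  The penalty is constant while
# the data term grows with n, so prior influence fades automatically as a
# lactation accumulates records.

# Optimizer box constraints, in (a, b, c, d) order.  Negative decay is
# allowed during fitting (such records are filtered downstream).
FIT_LOWER <- c(a = 5,   b = 1,  c = -20, d = -0.005)
FIT_UPPER <- c(a = 120, b = 80, c = 20,  d = 0.02)

#' Population prior for lactation curve characteristics
#'
#' @param parity_group `"primiparous"` or `"multiparous"`.
#' @param mean,sd Named numeric vectors with elements `magnitude`, `ramp`
#'   (time to peak yield), `offset`, `decay`; all sds must be > 0.
#' @return An object of class `"lcc_prior"`.
#' @seealso [default_lcc_priors()]
#' @export
lcc_prior <- function(parity_group, mean, sd) {
  parity_group <- match.arg(parity_group, c("primiparous", "multiparous"))
  nm <- c("magnitude", "ramp", "offset", "decay")
  stopifnot(all(nm %in% names(mean)), all(nm %in% names(sd)))
  mean <- mean[nm]; sd <- sd[nm]
  assert_finite(c(mean, sd), "prior mean/sd")
  if (any(sd <= 0)) stop("all prior sds must be > 0", call. = FALSE)
  structure(list(parity_group = parity_group, mean = mean, sd = sd),
            class = "lcc_prior")
}

#' Default parity-group priors
#'
#' Population means and SDs of the lactation curve characteristics for
#' primiparous and multiparous Holstein cows on robot-milking herds, used
#' as the default Gaussian priors for curve fitting (and as the default
#' population parameters of the synthetic generator).  Note the
#' primiparous offset SD is tiny (2.5e-5 days): the offset is effectively
#' constant at -0.50 days in first lactations.
#'
#' @return Named list of two [lcc_prior()] objects (`primiparous`,
#'   `multiparous`).
#' @export
default_lcc_priors <- function() {
  list(
    primiparous = lcc_prior(
      "primiparous",
      mean = c(magnitude = 38.2, ramp = 28.2, offset = -0.50, decay = 1.4e-3),
      sd   = c(magnitude = 6.0,  ramp = 2.4,  offset = 2.5e-5, decay = 0.9e-3)
    ),
    multiparous = lcc_prior(
      "multiparous",
      mean = c(magnitude = 51.2, ramp = 21.0, offset = -0.53, decay = 1.9e-3),
      sd   = c(magnitude = 7.5,  ramp = 3.8,  offset = 0.36,  decay = 1.0e-3)
    )
  )
}

#' A deliberately weak prior, for recovery studies
#'
#' Same means as the default prior of the group but sds inflated 100-fold,
#' so the data term dominates whenever more than a handful of records are
#' available.
#' @inheritParams lcc_prior
#' @export
weak_lcc_prior <- function(parity_group = "primiparous") {
  p <- default_lcc_priors()[[match.arg(parity_group,
                                       c("primiparous", "multiparous"))]]
  lcc_prior(p$parity_group, p$mean, p$sd * 100)
}

# Penalized residual vector and analytic Jacobian for nls.lm.
# theta in (a, b, c, d) order; if freeze_c, theta is (a, b, d) and c fixed.
mb_residual_fn <- function(t, y, mu, sigma, freeze_c, c_fixed) {
  function(theta) {
    if (freeze_c) {
      a <- theta[1]; b <- theta[2]; cc <- c_fixed; d <- theta[3]
      pen <- (c(a, b, d) - mu[c(1, 2, 4)]) / sigma[c(1, 2, 4)]
    } else {
      a <- theta[1]; b <- theta[2]; cc <- theta[3]; d <- theta[4]
      pen <- (theta - mu) / sigma
    }
    c(y - mb_yield_raw(t, a, b, cc, d), pen)
  }
}

mb_jacobian_fn <- function(t, y, mu, sigma, freeze_c, c_fixed) {
  n <- length(t)
  function(theta) {
    if (freeze_c) {
      a <- theta[1]; b <- theta[2]; cc <- c_fixed; d <- theta[3]
    } else {
      a <- theta[1]; b <- theta[2]; cc <- theta[3]; d <- theta[4]
    }
    eu <- exp((cc - t) / b)         # ramp exponential
    E <- exp(-d * t)
    g <- 1 - eu / 2
    dy_da <- g * E
    dy_db <- a * E * eu * (cc - t) / (2 * b^2)
    dy_dc <- -a * E * eu / (2 * b)
    dy_dd <- -t * a * g * E
    if (freeze_c) {
      jac_data <- -cbind(dy_da, dy_db, dy_dd)
      jac_pen <- diag(1 / sigma[c(1, 2, 4)])
    } else {
      jac_data <- -cbind(dy_da, dy_db, dy_dc, dy_dd)
      jac_pen <- diag(1 / sigma)
    }
    rbind(jac_data, jac_pen)
  }
}

#' Fit the MilkBot curve to daily records under a Gaussian prior
#'
#' MAP estimate of the lactation curve characteristics from the daily
#' yields of one lactation, shrunk toward the parity-group prior.  Solved
#' by bounded Levenberg--Marquardt ([minpack.lm::nls.lm()]) on the
#' penalized residual vector, with the prior means (and, on
#' non-convergence, up to `max_restarts` seeded random perturbations of
#' them) as starting points.  The returned solution never has a worse
#' penalized objective than the prior means themselves; if no optimizer
#' run converges the prior means are returned flagged `converged = FALSE`
#' so downstream stages can exclude the record.
#'
#' @param daily Data frame with columns `dim` and `daily_yield_kg`; at
#'   least one row.  All rows are used (callers restrict to `dim <= T`).
#' @param prior An [lcc_prior()].
#' @param start Optional named numeric `(magnitude, ramp, offset, decay)`
#'   warm start (e.g. the previous day's solution).
#' @param freeze_c If `TRUE` the offset is held at its prior mean and only
#'   the other three parameters are optimized.
#' @param seed Integer seed for the restart perturbations (deterministic).
#' @param max_restarts Random restarts attempted after a failed fit.
#' @return A list of class `"fitted_curve"`: `lcc` (an [lcc()] with
#'   `fit_rmse` filled in), `fit_rmse` (kg, over the data points only),
#'   `n_points`, `converged`, `objective`.
#' @export
fit_curve <- function(daily, prior, start = NULL, freeze_c = FALSE,
                      seed = 0L, max_restarts = 3L) {
  stopifnot(inherits(prior, "lcc_prior"))
  if (!all(c("dim", "daily_yield_kg") %in% names(daily))) {
    stop("`daily` needs columns `dim` and `daily_yield_kg`", call. = FALSE)
  }
  if (nrow(daily) < 1) stop("at least one daily record is required", call. = FALSE)
  t <- as.numeric(daily$dim)
  y <- as.numeric(daily$daily_yield_kg)
  mu <- unname(prior$mean)
  sigma <- unname(prior$sd)

  fn <- mb_residual_fn(t, y, mu, sigma, freeze_c, mu[3])
  jac <- mb_jacobian_fn(t, y, mu, sigma, freeze_c, mu[3])
  idx <- if (freeze_c) c(1L, 2L, 4L) else 1:4
  lower <- unname(FIT_LOWER)[idx]
  upper <- unname(FIT_UPPER)[idx]

  starts <- list()
  if (!is.null(start)) {
    s <- unname(start[c("magnitude", "ramp", "offset", "decay")])
    starts[[length(starts) + 1L]] <- pmin(pmax(s[idx], lower), upper)
  }
  starts[[length(starts) + 1L]] <- pmin(pmax(mu[idx], lower), upper)
  perturbed <- with_preserved_seed(seed, {
    lapply(seq_len(max_restarts), function(i) {
      s <- mu[idx] + stats::rnorm(length(idx)) * pmin(sigma[idx], abs(mu[idx]) + 1)
      pmin(pmax(s, lower), upper)
    })
  })

  obj_of <- function(theta) sum(fn(theta)^2)
  best <- list(theta = pmin(pmax(mu[idx], lower), upper), converged = FALSE)
  best$objective <- obj_of(best$theta)

  try_start <- function(s) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = fn,
                         jac = jac,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    list(theta = res$par, objective = obj_of(res$par),
         converged = res$info %in% 1:3)
  }

  runs_left <- c(starts, perturbed)
  for (k in seq_along(runs_left)) {
    r <- try_start(runs_left[[k]])
    if (!is.null(r) && r$objective <= best$objective) {
      best <- list(theta = r$theta, objective = r$objective,
                   converged = r$converged || best$converged)
    } else if (!is.null(r) && r$converged && best$converged == FALSE &&
               r$objective <= best$objective * (1 + 1e-9)) {
      best$converged <- TRUE
    }
    # stop early once a converged run has been found from the primary starts
    if (best$converged && k >= length(starts)) break
  }

  theta <- best$theta
  full <- if (freeze_c) c(theta[1], theta[2], mu[3], theta[3]) else theta
  resid_data <- y - mb_yield_raw(t, full[1], full[2], full[3], full[4])
  rmse <- sqrt(mean(resid_data^2))
  structure(
    list(
      lcc = lcc(full[1], full[2], full[3], full[4], fit_rmse = rmse),
      fit_rmse = rmse, n_points = length(t),
      converged = isTRUE(best$converged), objective = best$objective
    ),
    class = "fitted_curve"
  )
}

#' Incremental curve estimates over a lactation
#'
#' Fits the curve "as of" every requested day in milk, each fit using all
#' daily records up to and including that day and warm-started from the
#' previous day's solution.  This reproduces estimation at decision time:
#' the curve known at DIM 50 uses only the first 50 days of data.
#'
#' @param daily Daily records of one lactation (`dim`, `daily_yield_kg`),
#'   sorted by `dim`.
#' @param prior An [lcc_prior()].
#' @param dims Days at which to fit; defaults to every available `dim`.
#' @inheritParams fit_curve
#' @return Tibble with one row per fitted day: `as_of_dim`, `magnitude`,
#'   `time_to_peak`, `offset`, `decay`, `fit_rmse`, `n_points`,
#'   `converged`.
#' @export
incremental_fit_series <- function(daily, prior, dims = NULL,
                                   freeze_c = FALSE, seed = 0L) {
  daily <- dplyr::arrange(daily, .data$dim)
  if (is.null(dims)) dims <- unique(daily$dim)
  dims <- sort(dims)
  start <- NULL
  rows <- vector("list", length(dims))
  for (i in seq_along(dims)) {
    sub <- daily[daily$dim <= dims[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    fit <- fit_curve(sub, prior, start = start, freeze_c = freeze_c, seed = seed)
    start <- c(magnitude = fit$lcc$magnitude, ramp = fit$lcc$ramp,
               offset = fit$lcc$offset, decay = fit$lcc$decay)
    rows[[i]] <- tibble::tibble(
      as_of_dim = dims[i],
      magnitude = fit$lcc$magnitude, time_to_peak = fit$lcc$ramp,
      offset = fit$lcc$offset, decay = fit$lcc$decay,
      fit_rmse = fit$fit_rmse, n_points = fit$n_points,
      converged = fit$converged
    )
  }
  bind_rows_safe(rows)
}

#' @rdname incremental_fit_series
#' @param fitted Tibble from [incremental_fit_series()].
#' @param path CSV destination.
#' @export
write_fitted_curves <- function(fitted, path) {
  utils::write.csv(fitted, path, row.names = FALSE)
  invisible(path)
}
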