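# Synthetic multi-herd robot-milking data with known ground truth.
#
# The generator emulates the structure the pipeline consumes: several
# herds, cows with parity-dependent lactation curve characteristics
# (population scale = the package's default priors), 2-4 robot visits per
# day with visit yields equal to the integral of the true curve between
# visits plus multiplicative and additive noise, calvings spread across
# seasons and years, and conception dates (VWP + 21-day cycles with a
# fixed per-cycle conception probability, 282-day gestation) defining the
# Open / Bred / Never breeding-status mix and subsequent calving dates.
#
# Its central design device is `signal_fraction`: the lactation-average
# decay over [0, 305] (the quantity the DIM-305 fit estimates) is
# constructed as
#
#   decay305 = mu + sd * (sqrt(sf) * z + sqrt(1 - sf) * eps)
#
# where z is a unit-variance index of attributes measurable at the
# insemination moment (parity group, the herd decay effect, the cow's
# magnitude deviation and her early-lactation decay deviation, with
# fixed weights) and eps is independent noise.  The cow's decay then
# evolves at conception from d_early to the d_late that realises this
# decay305, so exactly `signal_fraction` of the decay-305 variance is
# explainable from measured predictors.  signal_fraction = 1
# makes persistency fully predictable at the decision moment; low values
# reproduce the predictability ceiling the prediction models run into.
# Routing part of the signal through magnitude and herd mirrors field
# observations that milk-yield level and herd management, not only the
# early decline itself, carry most of the predictable persistency signal.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-population
#' generator.  Defaults define the package's reference study conditions:
#' 16 herds of 90 cow places followed over 4 calendar years, population
#' curve parameters at the default parity-group priors, 2-4 visits/day,
#' 0.9 kg additive + 3% multiplicative visit noise, herd-level voluntary
#' waiting periods of 50--100 days with 35% conception risk per 21-day
#' cycle (282-day
#' gestation, 60-day dry period, 28% cull-and-replace), and
#' `signal_fraction = 0.35`.
#'
#' @param ... Named overrides of any default field.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_herds = 16L,
    cows_per_herd = 90L,
    years = 4L,
    start_year = 2018L,
    parity_init_probs = c(0.30, 0.24, 0.19, 0.15, 0.12),
    lcc_pop = default_lcc_priors(),
    herd_sd = c(magnitude = 3.5, ramp = 1.2, offset = 0, decay = 0.35e-3),
    visits_per_day = 2:4,
    visits_per_day_probs = c(0.3, 0.5, 0.2),
    visit_noise_sd = 0.9,
    visit_noise_cv = 0.03,
    daily_wobble_sd = 0.04,
    daily_wobble_rho = 0.8,
    vwp_days = c(50L, 100L),
    cycle_days = 21L,
    p_conception = 0.35,
    max_cycles = 10L,
    cull_prob = 0.28,
    dry_days = 60L,
    gestation_days = 282L,
    open_length_range = c(330, 430),
    heifer_age_days = 770,
    heifer_age_sd = 60,
    parity_interval_days = 385,
    signal_fraction = 0.40,
    conception_decay_shift = 0,
    decay305_mean = 2.2e-3,
    decay305_sd = 0.85e-3,
    signal_weights = c(parity = 0.55, herd = 0.55, magnitude = 0.65,
                       decay_early = 0.45),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots

  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$n_herds >= 1, "n_herds must be >= 1")
  chk(cfg$cows_per_herd >= 1, "cows_per_herd must be >= 1")
  chk(cfg$years >= 1, "years must be >= 1")
  chk(all(cfg$visits_per_day >= 1), "visits_per_day must be >= 1")
  chk(length(cfg$visits_per_day) == length(cfg$visits_per_day_probs) &&
        all(cfg$visits_per_day_probs >= 0) && sum(cfg$visits_per_day_probs) > 0,
      "visits_per_day_probs must be nonnegative and match visits_per_day")
  chk(cfg$visit_noise_sd >= 0, "visit_noise_sd must be >= 0")
  chk(cfg$visit_noise_cv >= 0, "visit_noise_cv must be >= 0")
  chk(cfg$daily_wobble_sd >= 0, "daily_wobble_sd must be >= 0")
  chk(cfg$daily_wobble_rho >= 0 && cfg$daily_wobble_rho < 1,
      "daily_wobble_rho must be in [0, 1)")
  chk(all(cfg$herd_sd >= 0), "herd_sd must be >= 0")
  chk(cfg$signal_fraction >= 0 && cfg$signal_fraction <= 1,
      "signal_fraction must be in [0, 1]")
  chk(cfg$p_conception > 0 && cfg$p_conception <= 1,
      "p_conception must be in (0, 1]")
  chk(length(cfg$vwp_days) %in% 1:2 && all(cfg$vwp_days > 0),
      "vwp_days must be a positive scalar or range")
  chk(cfg$cull_prob >= 0 && cfg$cull_prob <= 1, "cull_prob must be in [0, 1]")
  chk(all(cfg$parity_init_probs >= 0) && sum(cfg$parity_init_probs) > 0,
      "parity_init_probs must be nonnegative")
  chk(all(cfg$decay305_sd > 0), "decay305_sd must be > 0")
  chk(all(c("parity", "herd", "magnitude", "decay_early") %in%
            names(cfg$signal_weights)) && sum(cfg$signal_weights^2) > 0,
      "signal_weights must name parity/herd/magnitude/decay_early, not all zero")
  if (length(problems)) {
    stop("infeasible simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Piecewise cumulative milk: decay d_e up to the changepoint t_c (days in
# milk), d_l after, with the curve kept continuous at t_c.  All arguments
# vectors of equal length (t_c = Inf means no changepoint).
pw_cumulative <- function(t, a, b, c, d_e, d_l, t_c) {
  pre <- mb_cumulative(pmin(t, t_c), a, b, c, d_e)
  post_needed <- t > t_c
  if (!any(post_needed)) return(pre)
  a2 <- a * exp((d_l - d_e) * t_c)  # continuity at the changepoint
  post <- mb_cumulative(t, a2, b, c, d_l) - mb_cumulative(t_c, a2, b, c, d_l)
  ifelse(post_needed, pre + post, pre)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a multi-herd robot-milking population
#'
#' Draws herd effects, cow-level lactation curve characteristics per
#' parity group, conception outcomes and visit-level milk records
#' according to the configuration.  The ground truth (true curve
#' parameters per lactation, true lactation-average decay over `[0, 305]`
#' and true M305) is returned separately from the visible tables and is
#' never consumed by pipeline stages.
#'
#' Identical configuration (including seed) yields identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `visits` (robot-visit table in the schema
#'   [daily_from_visits()] consumes), `lactations` (one row per
#'   cow-parity lactation) and `ground_truth`.
#' @export
simulate_population <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  start_date <- as.Date(sprintf("%d-01-01", cfg$start_year))
  end_date <- start_date + cfg$years * 365L

  pop <- cfg$lcc_pop
  herd_eff <- matrix(stats::rnorm(cfg$n_herds * 4), ncol = 4) %*%
    diag(unname(cfg$herd_sd[c("magnitude", "ramp", "offset", "decay")]))
  colnames(herd_eff) <- c("magnitude", "ramp", "offset", "decay")

  # each herd manages its own voluntary waiting period
  vwp_lo <- min(cfg$vwp_days); vwp_hi <- max(cfg$vwp_days)
  herd_vwp <- round(stats::runif(cfg$n_herds, vwp_lo, vwp_hi))

  # cow-level sd: herd variance carved out of the total population sd,
  # with a floor so every parameter keeps some cow-level spread
  cow_sd <- lapply(pop, function(p) {
    tot <- p$sd
    hs <- cfg$herd_sd[names(tot)]
    pmax(sqrt(pmax(tot^2 - hs^2, 0)), 0.15 * tot)
  })

  # ---- pass 1: lactation histories per cow place -------------------------
  rows <- list()
  cow_counter <- 0L
  for (h in seq_len(cfg$n_herds)) {
    for (slot in seq_len(cfg$cows_per_herd)) {
      cow_counter <- cow_counter + 1L
      cow_id <- sprintf("c%06d", cow_counter)
      parity <- sample(seq_along(cfg$parity_init_probs), 1L,
                       prob = cfg$parity_init_probs)
      calving <- start_date +
        floor(stats::runif(1, 0, min(546, cfg$years * 365 - 1)))
      birth <- calving - round(cfg$heifer_age_days +
                                 (parity - 1L) * cfg$parity_interval_days +
                                 stats::rnorm(1, 0, cfg$heifer_age_sd))
      while (calving <= end_date) {
        g <- stats::rgeom(1, cfg$p_conception) + 1L
        if (g <= cfg$max_cycles) {
          t_c <- herd_vwp[h] + (g - 1L) * cfg$cycle_days + sample(0:6, 1L)
          next_calving <- calving + t_c + cfg$gestation_days
          len <- t_c + cfg$gestation_days - cfg$dry_days
        } else {
          t_c <- NA_integer_
          next_calving <- as.Date(NA)
          len <- round(stats::runif(1, cfg$open_length_range[1],
                                    cfg$open_length_range[2]))
        }
        rows[[length(rows) + 1L]] <- list(
          herd_id = sprintf("h%02d", h), cow_id = cow_id, parity = parity,
          birth_date = birth, calving_date = calving,
          next_calving_date = next_calving, lactation_length = as.numeric(len),
          conception_dim = t_c)

        culled <- is.na(t_c) || stats::runif(1) < cfg$cull_prob
        slot_next <- if (!is.na(t_c)) next_calving else calving + len + cfg$dry_days
        if (culled) {
          cow_counter <- cow_counter + 1L
          cow_id <- sprintf("c%06d", cow_counter)
          parity <- 1L
          birth <- slot_next - round(cfg$heifer_age_days +
                                       stats::rnorm(1, 0, cfg$heifer_age_sd))
        } else {
          parity <- parity + 1L
        }
        calving <- slot_next
      }
    }
  }

  lact <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  lact$lactation_key <- paste(lact$cow_id, lact$parity, sep = "_")
  lact$parity_group <- ifelse(lact$parity == 1L, "primiparous", "multiparous")
  lact$age_days <- as.numeric(lact$calving_date - lact$birth_date)
  lact$herd_idx <- as.integer(sub("h", "", lact$herd_id))
  n <- nrow(lact)

  # ---- pass 2: true curves ----------------------------------------------
  grp <- lact$parity_group
  param <- function(nm) {
    mu <- ifelse(grp == "primiparous", pop$primiparous$mean[[nm]],
                 pop$multiparous$mean[[nm]])
    cs <- ifelse(grp == "primiparous", cow_sd$primiparous[[nm]],
                 cow_sd$multiparous[[nm]])
    mu + herd_eff[lact$herd_idx, nm] + stats::rnorm(n) * cs
  }
  a <- clamp(param("magnitude"), 10, 100)
  b <- clamp(param("ramp"), 5, 60)
  cc <- clamp(param("offset"), -5, 5)
  d_e <- clamp(param("decay"), 1e-4, 6e-3)

  # predictable persistency index z and target decay-305 (see header)
  sf <- cfg$signal_fraction
  prim <- grp == "primiparous"
  mu_ah <- ifelse(prim, pop$primiparous$mean[["magnitude"]],
                  pop$multiparous$mean[["magnitude"]]) +
    herd_eff[lact$herd_idx, "magnitude"]
  mu_dh <- ifelse(prim, pop$primiparous$mean[["decay"]],
                  pop$multiparous$mean[["decay"]]) +
    herd_eff[lact$herd_idx, "decay"]
  sd_a_cow <- ifelse(prim, cow_sd$primiparous[["magnitude"]],
                     cow_sd$multiparous[["magnitude"]])
  sd_d_cow <- ifelse(prim, cow_sd$primiparous[["decay"]],
                     cow_sd$multiparous[["decay"]])
  h_std <- if (cfg$herd_sd[["decay"]] > 0) {
    herd_eff[lact$herd_idx, "decay"] / cfg$herd_sd[["decay"]]
  } else rep(0, n)
  g_std <- if (length(unique(prim)) > 1) {
    (as.numeric(!prim) - mean(!prim)) / stats::sd(!prim)
  } else rep(0, n)
  wts <- cfg$signal_weights / sqrt(sum(cfg$signal_weights^2))
  z <- wts[["parity"]] * g_std +
    wts[["herd"]] * h_std +
    wts[["magnitude"]] * (a - mu_ah) / sd_a_cow +
    wts[["decay_early"]] * (d_e - mu_dh) / sd_d_cow
  # noise truncated at +-2.5 sd: decline rates live in a bounded
  # biological range, and unbounded noise tails would otherwise dominate
  # the percentile-trimmed extremes of the cohort
  eps <- clamp(stats::rnorm(n), -2.5, 2.5)
  d_bar_target <- cfg$decay305_mean +
    cfg$decay305_sd * (sqrt(sf) * z + sqrt(1 - sf) * eps)

  t_c <- ifelse(is.na(lact$conception_dim), Inf, lact$conception_dim)
  has_cp <- is.finite(t_c) & t_c < 305
  w <- ifelse(has_cp, t_c / 305, 1)
  # decay after conception chosen to realise the target decay-305; cows
  # without a changepoint before DIM 305 keep d_early throughout
  d_l <- ifelse(has_cp,
                (d_bar_target - w * d_e) / (1 - w) +
                  cfg$conception_decay_shift,
                d_e)
  d_l <- ifelse(has_cp, clamp(d_l, -4e-3, 1.6e-2), d_e)
  d_bar <- w * d_e + (1 - w) * d_l   # realised average decay over [0, 305]

  ground_truth <- tibble::tibble(
    lactation_key = lact$lactation_key, herd_id = lact$herd_id,
    magnitude = a, ramp = b, offset = cc,
    decay_early = d_e, decay_late = d_l,
    conception_dim = lact$conception_dim,
    decay_305 = d_bar,
    m305 = pw_cumulative(rep(305, n), a, b, cc, d_e, d_l, t_c)
  )

  # ---- pass 3: visit records (vectorized across lactations) -------------
  vpd <- sample(cfg$visits_per_day, n, replace = TRUE,
                prob = cfg$visits_per_day_probs)
  gap_mean_h <- 24 / vpd
  n_vis <- as.integer(ceiling(lact$lactation_length * vpd * 1.08))
  idx <- rep.int(seq_len(n), n_vis)
  gaps <- stats::runif(length(idx), 0.75, 1.25) * gap_mean_h[idx]
  cs <- cumsum(gaps)
  ends <- cumsum(n_vis)
  offsets <- c(0, cs[ends[-n]])
  times_h <- cs - offsets[idx]

  keep <- times_h <= lact$lactation_length[idx] * 24
  idx <- idx[keep]; times_h <- times_h[keep]

  t_days <- times_h / 24
  cum <- pw_cumulative(t_days, a[idx], b[idx], cc[idx],
                       d_e[idx], d_l[idx], t_c[idx])
  first <- c(TRUE, idx[-1] != idx[-length(idx)])
  prev <- c(0, cum[-length(cum)])
  prev[first] <- 0
  y <- cum - prev

  # autocorrelated day-level wobble shared by all visits of a day: feed,
  # weather and health push daily yield off the smooth curve in slowly
  # varying multiplicative episodes
  if (cfg$daily_wobble_sd > 0) {
    rho <- cfg$daily_wobble_rho
    sd_innov <- cfg$daily_wobble_sd * sqrt(1 - rho^2)
    nd <- as.integer(ceiling(lact$lactation_length)) + 2L
    wob <- unlist(lapply(seq_len(n), function(i) {
      as.numeric(stats::filter(stats::rnorm(nd[i], 0, sd_innov), rho,
                               method = "recursive"))
    }), use.names = FALSE)
    day_pos <- c(0L, cumsum(nd))[idx] + pmin(as.integer(floor(t_days)) + 1L,
                                             nd[idx])
    y <- y * exp(wob[day_pos])
  }

  y <- pmax(0, y * (1 + cfg$visit_noise_cv * stats::rnorm(length(y))) +
              cfg$visit_noise_sd * stats::rnorm(length(y)))

  visits <- tibble::tibble(
    herd_id = lact$herd_id[idx],
    cow_id = lact$cow_id[idx],
    parity = lact$parity[idx],
    birth_date = lact$birth_date[idx],
    calving_date = lact$calving_date[idx],
    visit_datetime = as.POSIXct(lact$calving_date[idx], tz = "UTC") +
      round(times_h * 3600),
    yield_kg = round(y, 3),
    lactation_key = lact$lactation_key[idx]
  )

  list(
    visits = visits,
    lactations = dplyr::select(lact, "lactation_key", "cow_id", "herd_id",
                               "parity", "parity_group", "birth_date",
                               "calving_date", "next_calving_date",
                               "lactation_length", "age_days"),
    ground_truth = ground_truth
  )
}

#' Simulate daily records directly from a known curve
#'
#' Convenience generator for parameter-recovery studies: daily yields at
#' the given days in milk equal to the curve plus i.i.d. Gaussian noise
#' (no visit-level structure).
#'
#' @param curve An [lcc()] ground-truth curve.
#' @param dims Integer days in milk (default 1--305).
#' @param noise_sd Daily noise SD in kg (0 gives noise-free records).
#' @param seed Integer seed.
#' @return Tibble with `dim` and `daily_yield_kg`.
#' @export
simulate_daily_records <- function(curve, dims = 1:305, noise_sd = 1.5,
                                   seed = 1L) {
  y <- milk_yield(curve, dims)
  if (noise_sd > 0) {
    y <- y + with_preserved_seed(seed, stats::rnorm(length(dims), 0, noise_sd))
  }
  tibble::tibble(dim = as.integer(dims), daily_yield_kg = y)
}

#' Write a named fixture bundle
#'
#' Generates a population at one of three named scales and writes it as
#' plain-text files: `visits.csv`, `lactations.csv`, `ground_truth.csv`
#' and `config.json` (the full configuration including the seed, so the
#' bundle can be regenerated identically).
#'
#' Scales: `tiny` = 2 herds x 20 cow places x 1 year; `small` = 5 x 100 x
#' 2; `paper_like` = 9 x 230 x 4 (a scaled-down echo of a multi-year,
#' multi-herd study population).
#'
#' @param scale `"tiny"`, `"small"` or `"paper_like"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths.
#' @export
make_fixture <- function(scale = c("tiny", "small", "paper_like"), seed = 1L,
                         dir = tempfile("fixture")) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    tiny = list(n_herds = 2L, cows_per_herd = 20L, years = 1L),
    small = list(n_herds = 5L, cows_per_herd = 100L, years = 2L),
    paper_like = list(n_herds = 9L, cows_per_herd = 230L, years = 4L))
  cfg <- do.call(simulation_config, c(dims, list(seed = as.integer(seed))))
  sim <- simulate_population(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    visits = file.path(dir, "visits.csv"),
    lactations = file.path(dir, "lactations.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    config = file.path(dir, "config.json"))
  write_visits(sim$visits, paths$visits)
  utils::write.csv(sim$lactations, paths$lactations, row.names = FALSE)
  utils::write.csv(sim$ground_truth, paths$ground_truth, row.names = FALSE)
  cfg_json <- unclass(cfg)
  cfg_json$lcc_pop <- lapply(cfg_json$lcc_pop, function(p) {
    list(parity_group = p$parity_group, mean = as.list(p$mean),
         sd = as.list(p$sd))
  })
  jsonlite::write_json(c(list(scale = scale), cfg_json), paths$config,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
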