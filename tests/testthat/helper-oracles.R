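# Independent brute-force oracles used across tests.  These deliberately
# re-derive quantities with the plainest possible arithmetic so they stay
# independent of the package's implementation paths.

# MilkBot curve written out directly (raw, no floor)
oracle_milkbot <- function(t, a, b, c, d) {
  a * (1 - exp((c - t) / b) / 2) * exp(-d * t)
}

# 24-h yield as a plain rate computation on a window of visits:
# total kg after the anchor / total hours since the anchor, scaled to 24 h
oracle_rate_24h <- function(times_h, yields) {
  sum(yields[-1]) / (times_h[length(times_h)] - times_h[1]) * 24
}

# quadrature reference for the 305-day production
oracle_m305 <- function(a, b, c, d) {
  stats::integrate(function(t) pmax(0, oracle_milkbot(t, a, b, c, d)),
                   lower = 0, upper = 305, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

# Table-2-scale 5%-95% parameter ranges used for random curve draws
lcc_ranges <- function(parity_group = c("primiparous", "multiparous")) {
  parity_group <- match.arg(parity_group)
  if (parity_group == "primiparous") {
    list(a = c(28.2, 47.9), b = c(24.1, 31.9), c = c(-0.50, -0.50),
         d = c(0.2e-3, 3.0e-3))
  } else {
    list(a = c(38.6, 63.4), b = c(13.3, 26.4), c = c(-0.78, 0.01),
         d = c(0.3e-3, 3.7e-3))
  }
}

draw_lcc <- function(parity_group = "primiparous") {
  r <- lcc_ranges(parity_group)
  lcc(magnitude = runif(1, r$a[1], r$a[2]),
      ramp = runif(1, r$b[1], r$b[2]),
      offset = runif(1, r$c[1], r$c[2]),
      decay = runif(1, r$d[1], r$d[2]))
}

# visit table for a single synthetic lactation with an arbitrary schedule
make_visit_table <- function(times_h, yields, calving = as.Date("2020-03-01"),
                             key = "cow1_1") {
  tibble::tibble(
    lactation_key = key, cow_id = sub("_.*", "", key), herd_id = "h01",
    parity = 1L, birth_date = calving - 770, calving_date = calving,
    visit_datetime = as.POSIXct(calving, tz = "UTC") + times_h * 3600,
    yield_kg = yields
  )
}
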