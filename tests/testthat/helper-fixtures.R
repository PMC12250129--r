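# Shared fixture builders; all inputs are generated in code.

fix_time0 <- function() as.POSIXct("2026-01-05 09:00:00", tz = "UTC")

# Minimal single-animal worksheet with one standard.
make_worksheet <- function(organ = "tumor", mass_g = 0.1, cpm = 5000,
                           std_cpm = 10000, f_std = 0.01,
                           t_sample_h = 1, t_std_h = 1,
                           injected_MBq = 37) {
  t0 <- fix_time0()
  count_worksheet(
    "A1", t0, injected_MBq,
    data.frame(organ = organ, mass_g = mass_g, cpm = cpm,
               count_time = t0 + t_sample_h * 3600),
    data.frame(f_std = f_std, cpm = std_cpm,
               count_time = t0 + t_std_h * 3600))
}

# Analytic residence time of a preset organ curve: the human-scaled curve
# is piecewise exponential (log-linear anchors times physical decay);
# integrate each segment in closed form plus the extrapolated tail.
# Independent of fit_time_activity / cumulated_activity.
analytic_preset_tau <- function(preset, organ, phantom, animal_kg, nuc) {
  a <- preset[[organ]]
  per_kg <- phantom$masses[[organ]] / phantom$total_body_kg
  lam <- nuc$lambda_h
  f <- function(t) preset_pia_g(preset, organ, t) / 100 * animal_kg *
    per_kg * exp(-lam * t)
  # numeric quadrature over a long horizon plus analytic exponential tail
  horizon <- 2000
  head <- stats::integrate(Vectorize(f), 0, horizon,
                           rel.tol = 1e-10, subdivisions = 2000L)$value
  # beyond the last anchor the curve is a single exponential: rate =
  # biological end slope + physical lambda
  k <- nrow(a)
  bio_rate <- -(log(a$pia_g[k]) - log(a$pia_g[k - 1])) /
    (a$time_h[k] - a$time_h[k - 1])
  tail <- f(horizon) / (bio_rate + lam)
  head + tail
}
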