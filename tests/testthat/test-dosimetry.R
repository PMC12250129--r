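test_that("organ-mass scaling follows the relative-mass formula", {
  lu <- lu177()
  bt <- summarize_biodist(data.frame(
    animal_id = "a", organ = "liver", time_h = 4, pia = NA, pia_g = 10))
  phantom <- list(masses = c(liver = 1800), total_body_kg = 70)
  out <- extrapolate_to_human(bt, phantom, animal_total_body_kg = 0.025,
                              nuc = lu)
  # 10 %IA/g x 0.025 kg x (1800 g / 70 kg) = 6.4286 %IA before decay
  expect_equal(out$curves$liver$pia_organ / decay_factor(4, lu),
               10 * 0.025 * 1800 / 70, tolerance = 1e-9)
  expect_equal(round(out$curves$liver$pia_organ / decay_factor(4, lu), 4),
               6.4286)
})

test_that("an identity phantom preserves the animal curve", {
  lu <- lu177()
  animal_kg <- 0.025
  bt <- summarize_biodist(data.frame(
    animal_id = "a", organ = "kidney", time_h = c(1, 4, 24), pia = NA,
    pia_g = c(40, 20, 5)))
  # choose organ mass so animal_kg * organ_g / TB_kg = 1
  phantom <- list(masses = c(kidney = 70 / animal_kg), total_body_kg = 70)
  out <- extrapolate_to_human(bt, phantom, animal_kg, lu)
  expect_equal(out$curves$kidney$pia_organ,
               c(40, 20, 5) * decay_factor(c(1, 4, 24), lu))
  # organs missing from the phantom are reported and excluded
  bt2 <- summarize_biodist(data.frame(
    animal_id = "a", organ = c("kidney", "tail"), time_h = 1, pia = NA,
    pia_g = c(40, 1)))
  expect_message(out2 <- extrapolate_to_human(bt2, phantom, animal_kg, lu),
                 "tail")
  expect_equal(out2$unmatched, "tail")
})

test_that("biokinetic fits recover exponential truths under the rate bound", {
  lu <- lu177()
  t_ <- c(1, 4, 24, 48)
  y <- 60 * exp(-0.1 * t_) + 40 * exp(-0.01 * t_)   # %IA
  fit <- fit_time_activity(t_, y, lu, model = "bi")
  expect_equal(fit$rates, c(0.1, 0.01), tolerance = 1e-4)
  expect_equal(fit$coefficients, c(60, 40), tolerance = 1e-4)
  # two points on a pure physical-decay curve: boundary solution
  y2 <- 80 * decay_factor(c(2, 30), lu)
  fit2 <- fit_time_activity(c(2, 30), y2, lu, model = "mono")
  expect_equal(fit2$rates, lu$lambda_h, tolerance = 1e-8)
  expect_equal(fit2$coefficients, 80, tolerance = 1e-6)
  # all-zero curve
  fit0 <- fit_time_activity(t_, rep(0, 4), lu)
  expect_equal(cumulated_activity(fit0), 0)
  # fitted disappearance is never slower than physical decay
  expect_true(all(fit$rates >= lu$lambda_h))
})

test_that("model auto-selection prefers mono when a biexponential is unsupported", {
  lu <- lu177()
  t4 <- c(1, 4, 24, 48)
  fit <- fit_time_activity(t4, 50 * exp(-0.02 * t4), lu, model = "auto")
  expect_identical(fit$model, "mono")  # AICc undefined for k = 4, n = 4
  t8 <- c(0.5, 1, 2, 4, 8, 24, 48, 96)
  y8 <- 60 * exp(-0.15 * t8) + 40 * exp(-0.012 * t8)
  fit8 <- fit_time_activity(t8, y8, lu, model = "auto")
  expect_identical(fit8$model, "bi")
})

test_that("cumulated activity matches closed forms and numeric quadrature", {
  lu <- lu177()
  # single term at the physical rate integrates to T1/2 / ln 2
  t_ <- c(1, 4, 24, 48)
  fit <- fit_time_activity(t_, 100 * exp(-lu$lambda_h * t_), lu, "mono")
  expect_equal(cumulated_activity(fit), lu$half_life_h / log(2),
               tolerance = 1e-6)
  expect_equal(cumulated_activity(fit), 233.03, tolerance = 1e-4)
  # hand sum of term ratios (coefficients are %IA)
  fit2 <- structure(list(coefficients = c(60, 40), rates = c(0.1, 0.01),
                         model = "bi", converged = TRUE,
                         lambda_phys = lu$lambda_h,
                         samples = data.frame(time_h = t_, pia_organ = NA)),
                    class = "exp_fit")
  expect_equal(cumulated_activity(fit2), 46.0)
  # residence time equals numeric quadrature of the fitted curve to 0.1%
  quad <- stats::integrate(function(t) (60 * exp(-0.1 * t) +
                                          40 * exp(-0.01 * t)) / 100,
                           0, Inf)$value
  expect_lt(abs(cumulated_activity(fit2) - quad) / quad, 1e-3)
})

test_that("trapezoid fallback integrates samples with a physical-decay tail", {
  lu <- lu177()
  t_ <- c(1, 4, 24, 48)
  y <- 50 * exp(-lu$lambda_h * t_)
  fit <- structure(list(coefficients = NA_real_, rates = NA_real_,
                        model = "mono", converged = FALSE,
                        lambda_phys = lu$lambda_h,
                        samples = data.frame(time_h = t_, pia_organ = y)),
                   class = "exp_fit")
  tau <- cumulated_activity(fit)
  truth <- 0.5 / lu$lambda_h   # analytic integral of the true curve
  expect_equal(tau, truth, tolerance = 0.02)  # trapezoid discretisation
})

test_that("remainder of body closes the disintegration balance", {
  taus <- c(liver = 60, kidney = 40)
  out <- remainder_of_body(taus, 150)
  expect_equal(unname(out["remainder"]), 50)
  expect_equal(unname(remainder_of_body(c(a = 33.03), 233.03)["remainder"]),
               200.0)
  expect_warning(out2 <- remainder_of_body(c(a = 10), 9.9), "clamped")
  expect_equal(unname(out2["remainder"]), 0)
})

test_that("the MIRD dose sum is a linear matrix product", {
  S <- structure(matrix(c(1, 0.2, 0.1, 2), 2, 2,
                        dimnames = list(target = c("liver", "kidney"),
                                        source = c("liver", "kidney"))),
                 class = c("smatrix", "matrix"))
  d <- organ_doses(c(liver = 3, kidney = 4), S)
  expect_equal(as.numeric(d), c(3 + 0.4, 0.6 + 8))
  # identity-like S
  S1 <- structure(diag(c(1, 1)), class = c("smatrix", "matrix"))
  dimnames(S1) <- list(target = c("liver", "kidney"),
                       source = c("liver", "kidney"))
  d1 <- organ_doses(c(liver = 2), S1)
  expect_equal(as.numeric(d1), c(2, 0))
  # linearity in tau (property over random inputs)
  set.seed(12)
  for (i in 1:10) {
    tau <- stats::runif(2, 0, 100); names(tau) <- c("liver", "kidney")
    expect_equal(as.numeric(organ_doses(2 * tau, S)),
                 2 * as.numeric(organ_doses(tau, S)))
  }
  expect_warning(organ_doses(c(liver = 1, brain = 1), S), "excluded")
})

test_that("S-matrix construction and CSV reading agree on the self-dose model", {
  lu <- lu177()
  m <- c(kidney = 299, liver = 1910)
  S <- build_smatrix(m, lu)
  expect_equal(S["kidney", "kidney"], 0.5767 * 0.1335 / 0.299)
  expect_equal(S["kidney", "liver"], 0)
  toy <- read_smatrix(system.file("extdata", "smatrix_toy.csv",
                                  package = "radlig"))
  expect_true(all(diag(unclass(toy)) > 0))
  expect_equal(toy["kidney", "liver"], 0.0004)
  # photon cross-dose via absorbed fractions
  af <- matrix(0, 2, 2); af[1, 2] <- 0.1
  S2 <- build_smatrix(m, lu, photon_af = af)
  e_ph <- (208 * 0.11 + 113 * 0.06) / 1000
  expect_equal(S2["kidney", "liver"], 0.5767 * e_ph * 0.1 / 0.299)
})

test_that("effective dose honours the weighted-sum contract", {
  tw <- read_tissue_weights()
  expect_equal(sum(tw$weights) + tw$remainder, 1)
  # uniform organ dose: effective dose equals it exactly
  organs <- c(names(tw$weights), "pancreas", "brain")
  uniform <- stats::setNames(rep(0.42, length(organs)), organs)
  expect_equal(effective_dose(uniform, tw), 0.42)
  # single fully-weighted tissue
  tw1 <- list(weights = c(liver = 1), remainder = 0)
  expect_equal(effective_dose(c(liver = 3, kidney = 99), tw1), 3)
  expect_error(effective_dose(c(liver = 1),
                              list(weights = c(liver = 0.5),
                                   remainder = 0.1)), "sum to 1")
  # linear in the dose vector
  set.seed(5)
  d <- stats::setNames(stats::runif(length(organs)), organs)
  expect_equal(effective_dose(3 * d, tw), 3 * effective_dose(d, tw))
  # never exceeds the maximum organ dose
  expect_lte(effective_dose(d, tw), max(d))
})

test_that("effective dose matches a spreadsheet-style hand sum on a dose table", {
  tw <- read_tissue_weights()
  doses <- c(testes = 2.16e-2, red_marrow = 1.47e-2, colon = 2.01e-2,
             lung = 1.47e-3, stomach = 1.98e-2, bladder = 8.32e-3,
             breast = 7.86e-3, liver = 5.81e-4, oesophagus = 8.01e-4,
             thyroid = 8.08e-3, skin = 1.54e-3, bone_surface = 4.98e-3,
             kidney = 2.19e-4, spleen = 6.92e-5, muscle = 6.33e-5,
             brain = 3.54e-5, pancreas = 8.27e-4)
  # independent brute-force weighted sum
  w <- tw$weights
  rem_organs <- setdiff(names(doses), names(w))
  hand <- sum(w[names(w)] * doses[names(w)]) +
    tw$remainder * mean(doses[rem_organs])
  expect_equal(effective_dose(doses, tw), hand, tolerance = 1e-12)
})

test_that("end-to-end residence times match the analytic preset integral", {
  lu <- lu177()
  preset <- biodist_preset_lncap()
  phantom <- read_phantom()
  animal_kg <- 0.025
  sheets <- simulate_worksheet(preset, sim_config(seed = 42), lu)
  bt <- summarize_biodist(lapply(sheets, percent_ia_per_gram, nuc = lu))
  total_tau <- 0
  for (org in c("kidney", "liver", "spleen", "lung", "muscle")) {
    cu <- extrapolate_to_human(bt[bt$organ == org, ], phantom, animal_kg,
                               lu)$curves[[org]]
    tau <- cumulated_activity(fit_time_activity(cu$time_h, cu$pia_organ, lu))
    truth <- analytic_preset_tau(preset, org, phantom, animal_kg, lu)
    expect_lt(abs(tau - truth) / truth, 0.01)
    total_tau <- total_tau + tau
  }
  # every disintegration happens somewhere at most once
  expect_lte(total_tau, lu$half_life_h / log(2))
})
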