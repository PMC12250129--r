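# Synthetic-data generators. Forward models here are written directly from
# the model equations (decay evaluated inline from the nuclide constants)
# and never call the analysis pipeline, so generator -> pipeline round
# trips are genuine tests.

#' Default simulation configuration
#'
#' @param seed RNG seed (default 42); every stochastic output is a
#'   function of (preset, seed) only.
#' @param noise `"none"`, `"poisson"`, or `list(type = "gaussian",
#'   cv = <fraction>)`.
#' @param n_animals Animals per biodistribution timepoint (default 3).
#' @param timepoints Sacrifice times, hours post-injection.
#' @param injected_activity_MBq Administered activity per animal (MBq).
#' @param calibration_cpm_per_MBq Gamma-counter calibration.
#' @param f_std Fraction of the injected activity in each counting
#'   standard.
#' @return A list, usable as `cfg` by the `simulate_*` generators.
#' @export
sim_config <- function(seed = 42, noise = "none", n_animals = 3,
                       timepoints = c(1, 4, 24, 48),
                       injected_activity_MBq = 37,
                       calibration_cpm_per_MBq = 1e4, f_std = 0.01) {
  list(seed = seed, noise = noise, n_animals = n_animals,
       timepoints = timepoints,
       injected_activity_MBq = injected_activity_MBq,
       calibration_cpm_per_MBq = calibration_cpm_per_MBq, f_std = f_std)
}

apply_count_noise <- function(counts, noise) {
  if (identical(noise, "none")) return(counts)
  if (identical(noise, "poisson"))
    return(stats::rpois(length(counts), counts))
  if (is.list(noise) && identical(noise$type, "gaussian"))
    return(pmax(0, stats::rnorm(length(counts), counts,
                                noise$cv * counts)))
  stop("unknown noise spec", call. = FALSE)
}

#' Biodistribution preset calibrated to the LNCaP tumor model
#'
#' Decay-corrected %IA/g anchors per organ, interpolated log-linearly in
#' time (and extrapolated log-linearly beyond the anchors). Tumor and
#' kidney anchors are the published means; the 1 h tumor value and all
#' blood/muscle values are back-derived from the published
#' tumor-to-normal ratios (tumor/kidney 0.3 at 1 h, tumor/blood 69.5 at
#' 1 h and 434.4 at 24 h, tumor/muscle 60.2 at 1 h and 857.4 at 24 h,
#' tumor/kidney 26.3 at 48 h), and the 48 h tumor value extends the
#' 4-to-24 h log-linear slope. Liver, spleen and lung are nominal
#' low-uptake fixture curves (mono-exponential decline), not published
#' values.
#'
#' @return A named list of anchor data frames (`time_h`, `pia_g`), class
#'   `"biodist_preset"`.
#' @export
biodist_preset_lncap <- function() {
  tumor_48 <- 12.88 * exp(log(12.88 / 23.31) / 20 * 24)  # extend 4->24 slope
  anchors <- list(
    tumor  = data.frame(time_h = c(1, 4, 24, 48),
                        pia_g = c(43.83 * 0.3, 23.31, 12.88, tumor_48)),
    kidney = data.frame(time_h = c(1, 48),
                        pia_g = c(43.83, tumor_48 / 26.3)),
    blood  = data.frame(time_h = c(1, 24),
                        pia_g = c(43.83 * 0.3 / 69.5, 12.88 / 434.4)),
    muscle = data.frame(time_h = c(1, 24),
                        pia_g = c(43.83 * 0.3 / 60.2, 12.88 / 857.4)),
    # nominal low-uptake fixture organs, ~0.05/h biological decline
    liver  = data.frame(time_h = c(1, 48), pia_g = 1.0 * exp(-0.05 * c(0, 47))),
    spleen = data.frame(time_h = c(1, 48), pia_g = 0.8 * exp(-0.05 * c(0, 47))),
    lung   = data.frame(time_h = c(1, 48), pia_g = 0.9 * exp(-0.05 * c(0, 47))))
  structure(anchors, class = "biodist_preset")
}

#' Evaluate a biodistribution preset
#'
#' Log-linear interpolation between anchors; beyond the first/last anchor
#' the nearest segment's log-slope is extended.
#'
#' @param preset A `"biodist_preset"`.
#' @param organ Organ name.
#' @param time_h Times (hours) at which to evaluate.
#' @return %IA/g values (decay-corrected convention).
#' @export
preset_pia_g <- function(preset, organ, time_h) {
  a <- preset[[organ]]
  if (is.null(a)) stop("organ '", organ, "' not in preset", call. = FALSE)
  lt <- a$time_h; lv <- log(a$pia_g)
  vapply(time_h, function(tt) {
    if (length(lt) == 1L) return(exp(lv[1]))
    if (tt <= lt[1]) {
      sl <- (lv[2] - lv[1]) / (lt[2] - lt[1])
      return(exp(lv[1] + sl * (tt - lt[1])))
    }
    k <- length(lt)
    if (tt >= lt[k]) {
      sl <- (lv[k] - lv[k - 1]) / (lt[k] - lt[k - 1])
      return(exp(lv[k] + sl * (tt - lt[k])))
    }
    exp(stats::approx(lt, lv, xout = tt)$y)
  }, 0)
}

#' Fixture mouse organ/sample masses (g)
#'
#' Declared fixture values for a ~25 g mouse (tumor 0.3 g, kidneys 0.4 g,
#' blood pool 1.4 g, ...), not study data.
#' @return Named numeric vector of masses, g.
#' @export
mouse_organ_masses <- function() {
  c(tumor = 0.3, kidney = 0.4, blood = 1.4, muscle = 9.0,
    liver = 1.3, spleen = 0.1, lung = 0.15)
}

#' Simulate gamma-counter worksheets from a biodistribution preset
#'
#' Forward model: for an animal sacrificed at `t` hours, each organ's
#' counts are `pia_g(t)/100 * mass * A0 * calibration * 2^(-t / T1/2)`
#' (the preset is decay-corrected, so physical decay is re-applied), plus
#' optional counting noise. One standard (an aliquot of `f_std` of the
#' injected activity) is generated per counting session at the same
#' count time.
#'
#' @param preset A `"biodist_preset"`.
#' @param cfg A [sim_config()] list.
#' @param nuc A `"nuclide"` supplying the physical half-life.
#' @param organ_masses_g Named masses of the dissected samples, g.
#' @param injection_time Injection timestamp.
#' @return A list of `"count_worksheet"` objects (one per animal).
#' @export
simulate_worksheet <- function(preset, cfg = sim_config(), nuc = lu177(),
                               organ_masses_g = mouse_organ_masses(),
                               injection_time = as.POSIXct(
                                 "2026-01-05 09:00:00", tz = "UTC")) {
  set.seed(cfg$seed)
  hl <- nuc$half_life_h
  organs <- intersect(names(preset), names(organ_masses_g))
  out <- list()
  for (tt in cfg$timepoints) {
    df_phys <- 2^(-tt / hl)
    count_time <- injection_time + tt * 3600
    for (a in seq_len(cfg$n_animals)) {
      cpm <- vapply(organs, function(org)
        preset_pia_g(preset, org, tt) / 100 * organ_masses_g[[org]] *
          cfg$injected_activity_MBq * cfg$calibration_cpm_per_MBq * df_phys,
        0)
      cpm <- apply_count_noise(cpm, cfg$noise)
      std_cpm <- cfg$f_std * cfg$injected_activity_MBq *
        cfg$calibration_cpm_per_MBq * df_phys
      std_cpm <- apply_count_noise(std_cpm, cfg$noise)
      out[[length(out) + 1L]] <- count_worksheet(
        sprintf("M%02.0fh_%d", tt, a), injection_time,
        cfg$injected_activity_MBq,
        data.frame(organ = organs, mass_g = unname(organ_masses_g[organs]),
                   cpm = unname(cpm), count_time = count_time),
        data.frame(f_std = cfg$f_std, cpm = std_cpm,
                   count_time = count_time))
    }
  }
  out
}

#' Simulate saturation and competition binding assays
#'
#' One-site forward models: saturation specific binding
#' `Bmax * c / (Kd + c)` with nonspecific binding a fixed fraction of
#' total; competition `Bottom + (Top - Bottom) / (1 + c / IC50)`.
#' Default truth is the LNCaP preset (Kd 4.358 nM, IC50 17.709 nM) with
#' the assay's 0.75 nM radioligand concentration.
#'
#' @param truth List with `Kd`, `Bmax`, `IC50`, `Top`, `Bottom` (CPM) and
#'   `radioligand_nM`.
#' @param cfg A [sim_config()] list (`noise` and `seed` are used).
#' @param sat_conc_nM Saturation concentrations (default 8 log-spaced
#'   points, 0.5-100 nM).
#' @param comp_conc_nM Competitor concentrations (default 10 log-spaced
#'   points, 0.01-10000 nM).
#' @param nonspecific_fraction Nonspecific binding as a fraction of total
#'   binding at each concentration.
#' @return List with `saturation` (data frame `concentration_nM`,
#'   `total_cpm`, `nonspecific_cpm`), `competition` (data frame
#'   `competitor_nM`, `bound_cpm`), `radioligand_nM` and `truth`.
#' @export
simulate_binding <- function(truth = list(Kd = 4.358, Bmax = 5000,
                                          IC50 = 17.709, Top = 4000,
                                          Bottom = 400,
                                          radioligand_nM = 0.75),
                             cfg = sim_config(),
                             sat_conc_nM = 10^seq(log10(0.5), log10(100),
                                                  length.out = 8),
                             comp_conc_nM = 10^seq(-2, 4, length.out = 10),
                             nonspecific_fraction = 0.1) {
  set.seed(cfg$seed)
  spec <- truth$Bmax * sat_conc_nM / (truth$Kd + sat_conc_nM)
  total <- spec / (1 - nonspecific_fraction)
  nonspec <- nonspecific_fraction * total
  bound <- truth$Bottom +
    (truth$Top - truth$Bottom) / (1 + comp_conc_nM / truth$IC50)
  total <- apply_count_noise(total, cfg$noise)
  nonspec <- apply_count_noise(nonspec, cfg$noise)
  bound <- apply_count_noise(bound, cfg$noise)
  list(saturation = data.frame(concentration_nM = sat_conc_nM,
                               total_cpm = total,
                               nonspecific_cpm = nonspec),
       competition = data.frame(competitor_nM = comp_conc_nM,
                                bound_cpm = bound),
       radioligand_nM = truth$radioligand_nM, truth = truth)
}

#' Survival preset for the three-arm efficacy study
#'
#' Group sizes and median survivals of the three study arms (saline
#' control n = 6, median 26 d; 37 MBq n = 8, median 34 d; 111 MBq n = 9,
#' median 40 d), with Weibull event-time laws of shape `k` (default 6,
#' chosen for realistic spread; medians are shape-robust) and scale
#' `median / log(2)^(1/k)`.
#'
#' @param k Weibull shape.
#' @return Data frame `group`, `n`, `median_days`, `shape`.
#' @export
survival_preset_threearm <- function(k = 6) {
  data.frame(group = c("control", "lu177_37MBq", "lu177_111MBq"),
             n = c(6L, 8L, 9L), median_days = c(26, 34, 40), shape = k)
}

#' Simulate subject records for a survival experiment
#'
#' Weibull event times rounded up to whole days; optional administrative
#' censoring at `censor_day` (subjects alive then are censored).
#'
#' @param preset A preset data frame as from [survival_preset_threearm()].
#' @param cfg A [sim_config()] list (only `seed` is used).
#' @param censor_day Optional administrative censoring day.
#' @return Data frame `id`, `group`, `time_days`, `event`.
#' @export
simulate_survival <- function(preset = survival_preset_threearm(),
                              cfg = sim_config(), censor_day = NULL) {
  set.seed(cfg$seed)
  rows <- lapply(seq_len(nrow(preset)), function(i) {
    g <- preset[i, ]
    scale <- g$median_days / log(2)^(1 / g$shape)
    t_ <- ceiling(stats::rweibull(g$n, shape = g$shape, scale = scale))
    ev <- rep(1L, g$n)
    if (!is.null(censor_day)) {
      cens <- t_ > censor_day
      t_[cens] <- censor_day
      ev[cens] <- 0L
    }
    data.frame(id = sprintf("%s_%02d", g$group, seq_len(g$n)),
               group = g$group, time_days = t_, event = ev)
  })
  do.call(rbind, rows)
}

#' Simulate an iTLC/HPLC count profile with a known product fraction
#'
#' Two Gaussian peaks on a position grid: the product at the origin end
#' and free radiometal at the solvent front, with total counts split
#' according to `purity`. The returned object carries the generating
#' windows as attributes (`product_window`, `free_window`).
#'
#' @param purity Product percent of total counts.
#' @param cfg A [sim_config()] list (`noise`, `seed`).
#' @param total_counts Total profile counts.
#' @param kind Profile kind tag.
#' @return A `"count_profile"` (positions 0-100) with window attributes.
#' @export
simulate_chromatogram <- function(purity = 98.5, cfg = sim_config(),
                                  total_counts = 1e5,
                                  kind = c("iTLC", "radio-HPLC")) {
  kind <- match.arg(kind)
  if (purity < 0 || purity > 100) stop("purity must be in [0, 100]",
                                       call. = FALSE)
  set.seed(cfg$seed)
  pos <- seq(0, 100, by = 1)
  shape1 <- stats::dnorm(pos, 20, 5); shape1 <- shape1 / sum(shape1)
  shape2 <- stats::dnorm(pos, 80, 5); shape2 <- shape2 / sum(shape2)
  counts <- total_counts * (purity / 100 * shape1 +
                            (1 - purity / 100) * shape2)
  counts <- apply_count_noise(counts, cfg$noise)
  p <- count_profile(pos, counts, kind)
  attr(p, "product_window") <- c(0, 50)
  attr(p, "free_window") <- c(50, 101)
  p
}

#' Serum-stability fixture records
#'
#' Free-radiometal percentages by temperature and time, anchored at the
#' published stability results (1.2% free at 4 C after 2 h, about 1.1% at
#' 25 C, none detected at 37 C, under 5% and 4% at 4 and 25 C after
#' 72 h); intermediate cells are fixture values.
#'
#' @param cfg A [sim_config()] list (`noise` applies gaussian CV only).
#' @return Data frame `temperature_C`, `time_h`, `free_pct`.
#' @export
simulate_serum_stability <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  rec <- rbind(
    data.frame(temperature_C = 4, time_h = c(2, 24, 48, 72),
               free_pct = c(1.2, 0.6, 0.0, 4.8)),
    data.frame(temperature_C = 25, time_h = c(2, 24, 48, 72),
               free_pct = c(1.1, 0.5, 0.0, 3.7)),
    data.frame(temperature_C = 37, time_h = c(2, 24, 48, 72),
               free_pct = c(0.0, 0.0, 0.0, 0.0)))
  if (is.list(cfg$noise) && identical(cfg$noise$type, "gaussian"))
    rec$free_pct <- pmin(100, pmax(0, stats::rnorm(
      nrow(rec), rec$free_pct, cfg$noise$cv * pmax(rec$free_pct, 0.1))))
  rec
}
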