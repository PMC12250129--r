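#' Read a phantom organ-mass table
#'
#' CSV with columns `organ`, `mass_g`, plus one `TOTAL_BODY` row whose
#' `mass_g` field carries the total-body mass in kg. The shipped
#' `phantom_adult_male.csv` is an editable 70-kg adult male reference
#' table (external standard constants, see its header comment).
#'
#' @param path CSV path; default is the packaged adult-male table.
#' @return A list with `masses` (named numeric, g) and `total_body_kg`.
#' @export
read_phantom <- function(path = system.file("extdata",
                                            "phantom_adult_male.csv",
                                            package = "radlig")) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("organ", "mass_g") %in% names(df)))
    stop("phantom CSV needs columns organ, mass_g", call. = FALSE)
  tb <- df$organ == "TOTAL_BODY"
  if (sum(tb) != 1L)
    stop("phantom CSV must contain exactly one TOTAL_BODY row", call. = FALSE)
  masses <- stats::setNames(df$mass_g[!tb], tolower(trimws(df$organ[!tb])))
  if (any(masses <= 0)) stop("organ masses must be > 0", call. = FALSE)
  total_kg <- df$mass_g[tb]
  if (sum(masses) > total_kg * 1000)
    stop("organ masses exceed total-body mass", call. = FALSE)
  list(masses = masses, total_body_kg = total_kg)
}

#' Extrapolate mouse %IA/g to human whole-organ %IA time-activity curves
#'
#' Relative organ-mass scaling: for each organ and timepoint,
#' `(%IA/organ)_human = (%IA/g)_animal x (kg TB)_animal x
#' (g_organ / kg TB)_human`. Because the %IA/g table is decay-referenced
#' to injection (biology only), the scaled value is then multiplied by the
#' physical decay factor at the timepoint so the human curve represents
#' physical activity, ready for disintegration integrals.
#'
#' @param bt A `"biodist_table"`.
#' @param phantom A phantom list from [read_phantom()].
#' @param animal_total_body_kg Animal total-body mass, kg (default 0.025,
#'   a typical adult mouse).
#' @param nuc A `"nuclide"` (default [lu177()]).
#' @param organ_map Optional named character vector mapping biodistribution
#'   organ labels to phantom organ labels (e.g. `c(blood =
#'   "heart_contents")`).
#' @return A list with `curves` (named list of data frames `time_h`,
#'   `pia_organ`, percent of injected activity in the whole organ, decay
#'   included) and `unmatched` (organ labels absent from the phantom,
#'   excluded with a message).
#' @export
extrapolate_to_human <- function(bt, phantom,
                                 animal_total_body_kg = 0.025,
                                 nuc = lu177(), organ_map = NULL) {
  if (animal_total_body_kg <= 0)
    stop("animal total-body mass must be > 0", call. = FALSE)
  organs <- unique(bt$organ)
  curves <- list(); unmatched <- character()
  for (org in organs) {
    target <- if (!is.null(organ_map) && org %in% names(organ_map))
      tolower(organ_map[[org]]) else org
    if (!target %in% names(phantom$masses)) {
      unmatched <- c(unmatched, org)
      next
    }
    m_h <- phantom$masses[[target]]            # g
    per_kg <- m_h / phantom$total_body_kg      # g organ per kg TB, human
    d <- bt[bt$organ == org, , drop = FALSE]
    d <- d[order(d$time_h), , drop = FALSE]
    pia_organ <- d$mean_pia_g * animal_total_body_kg * per_kg *
      decay_factor(d$time_h, nuc)
    curves[[org]] <- data.frame(time_h = d$time_h, pia_organ = pia_organ)
  }
  if (length(unmatched))
    message("organs absent from phantom, excluded: ",
            paste(unmatched, collapse = ", "))
  list(curves = curves, unmatched = unmatched)
}

#' Fit an exponential biokinetic model to a whole-organ time-activity curve
#'
#' Fits `A(t) = sum_i c_i exp(-r_i t)` (one or two terms) by bounded least
#' squares with every rate constrained to at least the physical decay
#' constant (physical decay is a lower bound on total disappearance) and a
#' deterministic multi-start grid over rate decades. In `"auto"` mode the
#' model order is chosen by corrected AIC (ties go to the
#' mono-exponential); a bi-exponential needs at least 4 samples and, with
#' exactly 4, AICc is undefined (+Inf), so auto selection falls back to
#' mono.
#'
#' @param time_h Sample times, hours, strictly increasing, >= 0.
#' @param pia_organ Whole-organ activity, %IA, physical decay included.
#' @param nuc A `"nuclide"`.
#' @param model `"auto"`, `"mono"` or `"bi"`.
#' @return A list of class `"exp_fit"`: `coefficients` (%IA), `rates`
#'   (1/h), `model`, `sse`, `aicc`, and the input samples (used by the
#'   trapezoid fallback).
#' @export
fit_time_activity <- function(time_h, pia_organ, nuc = lu177(),
                              model = c("auto", "mono", "bi")) {
  model <- match.arg(model)
  t_ <- as.numeric(time_h); y <- as.numeric(pia_organ)
  if (length(t_) != length(y)) stop("inputs must align", call. = FALSE)
  if (any(t_ < 0) || any(diff(t_) <= 0))
    stop("times must be >= 0 and strictly increasing", call. = FALSE)
  if (any(y < 0)) stop("activities must be >= 0", call. = FALSE)
  lam <- nuc$lambda_h
  samples <- data.frame(time_h = t_, pia_organ = y)
  mk <- function(coefs, rates, mdl, sse, aicc, converged = TRUE)
    structure(list(coefficients = coefs, rates = rates, model = mdl,
                   sse = sse, aicc = aicc, converged = converged,
                   lambda_phys = lam, samples = samples),
              class = "exp_fit")
  if (all(y == 0))
    return(mk(0, lam, "mono", 0, -Inf))
  aicc_of <- function(sse, n, k) {
    if (n - k - 1 <= 0) return(Inf)
    n * log(max(sse, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  rate_grid <- lam * c(1, 3, 10, 30, 100)
  fit_mono <- function() {
    if (length(t_) < 2L) return(NULL)
    starts <- lapply(rate_grid, function(r) c(c1 = max(y), r1 = r))
    f <- multistart_nls(B ~ c1 * exp(-r1 * t_),
                        data.frame(t_ = t_, B = y), starts,
                        lower = c(c1 = 0, r1 = lam),
                        upper = c(c1 = Inf, r1 = Inf))
    if (is.null(f)) return(NULL)
    co <- stats::coef(f); sse <- sum(stats::resid(f)^2)
    mk(unname(co["c1"]), unname(co["r1"]), "mono", sse,
       aicc_of(sse, length(t_), 2))
  }
  fit_bi <- function() {
    if (length(t_) < 4L) return(NULL)
    starts <- list()
    for (rf in c(10, 30, 100)) for (sp in c(0.3, 0.5, 0.7))
      starts[[length(starts) + 1L]] <-
        c(c1 = sp * max(y), r1 = lam * rf, c2 = (1 - sp) * max(y), r2 = lam)
    f <- multistart_nls(B ~ c1 * exp(-r1 * t_) + c2 * exp(-r2 * t_),
                        data.frame(t_ = t_, B = y), starts,
                        lower = c(c1 = 0, r1 = lam, c2 = 0, r2 = lam),
                        upper = c(c1 = Inf, r1 = Inf, c2 = Inf, r2 = Inf))
    if (is.null(f)) return(NULL)
    co <- stats::coef(f); sse <- sum(stats::resid(f)^2)
    ord <- order(c(co["r1"], co["r2"]), decreasing = TRUE)
    mk(unname(c(co["c1"], co["c2"])[ord]),
       unname(c(co["r1"], co["r2"])[ord]), "bi", sse,
       aicc_of(sse, length(t_), 4))
  }
  res <- switch(model,
    mono = fit_mono(),
    bi = fit_bi(),
    auto = {
      m <- fit_mono(); b <- fit_bi()
      if (is.null(m) && is.null(b)) NULL
      else if (is.null(b) || (!is.null(m) && m$aicc <= b$aicc)) m else b
    })
  if (is.null(res)) {
    # non-convergence fallback: flag it; downstream integrates the samples
    res <- mk(NA_real_, NA_real_, if (model == "bi") "bi" else "mono",
              NA_real_, Inf, converged = FALSE)
  }
  res
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %s-exponential%s\n", x$model,
              if (!x$converged) " (NOT converged; trapezoid fallback)" else ""))
  if (x$converged)
    for (i in seq_along(x$coefficients))
      cat(sprintf("  %.6g %%IA * exp(-%.6g /h * t)\n",
                  x$coefficients[i], x$rates[i]))
  invisible(x)
}

#' Cumulated activity (residence time) from a biokinetic fit
#'
#' Integrates the fitted curve from zero to infinity:
#' `tau = sum_i (c_i / 100) / r_i` hours per unit injected activity
#' (coefficients are %IA, hence the /100). For a fit flagged as
#' non-converged, falls back to trapezoid integration over the samples
#' plus an analytic physical-decay tail from the last sample.
#'
#' @param fit An `"exp_fit"`.
#' @return Residence time tau, hours (MBq h per MBq injected).
#' @export
cumulated_activity <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  if (fit$converged) {
    if (all(fit$coefficients == 0)) return(0)
    return(sum((fit$coefficients / 100) / fit$rates))
  }
  s <- fit$samples
  frac <- s$pia_organ / 100
  head_int <- if (nrow(s) > 1)
    sum(diff(s$time_h) * (utils::head(frac, -1) + utils::tail(frac, -1)) / 2)
  else 0
  first <- frac[1] * s$time_h[1]          # rectangle back to t = 0
  tail_int <- utils::tail(frac, 1) / fit$lambda_phys
  first + head_int + tail_int
}

#' Remainder-of-body residence time
#'
#' The remainder region absorbs the disintegrations not assigned to an
#' explicit source organ: `tau_remainder = tau_wholebody - sum(organ tau)`,
#' floored at zero (with a warning if the organ sum exceeds the whole-body
#' value, which indicates inconsistent inputs).
#'
#' @param organ_taus Named numeric vector of organ residence times, hours.
#' @param whole_body_tau Whole-body residence time, hours.
#' @return Named numeric vector: the organ taus plus a
#'   `"remainder"` entry.
#' @export
remainder_of_body <- function(organ_taus, whole_body_tau) {
  if (any(organ_taus < 0) || whole_body_tau < 0)
    stop("residence times must be >= 0", call. = FALSE)
  rem <- whole_body_tau - sum(organ_taus)
  if (rem < 0) {
    warning("organ residence times exceed whole-body value by ",
            signif(-rem, 4), " h; remainder clamped to 0")
    rem <- 0
  }
  c(organ_taus, remainder = rem)
}

#' Read / build an S-matrix of dose factors
#'
#' An S-matrix gives the absorbed dose rate in a target region per unit
#' activity in a source region, in mGy/(MBq h). `read_smatrix` reads a
#' long-format CSV `target,source,S_mGy_per_MBq_h`; `build_smatrix`
#' constructs a simplified matrix from organ masses: the self-dose term is
#' `S_self = 0.5767 * E_beta(MeV) / m(kg)` (3.6e9 decays per MBq h times
#' the mean beta energy, locally absorbed), and photon cross-dose is added
#' via user-supplied absorbed-fraction factors. This is a transparent toy
#' model, not a phantom Monte-Carlo table.
#'
#' @param path CSV path.
#' @return A square numeric matrix, rows = targets, cols = sources, class
#'   `"smatrix"`.
#' @export
read_smatrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("target", "source", "S_mGy_per_MBq_h")
  if (!all(need %in% names(df)))
    stop("S-matrix CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tg <- tolower(trimws(df$target)); sr <- tolower(trimws(df$source))
  organs <- sort(unique(c(tg, sr)))
  S <- matrix(0, length(organs), length(organs),
              dimnames = list(target = organs, source = organs))
  S[cbind(match(tg, organs), match(sr, organs))] <- df$S_mGy_per_MBq_h
  if (any(S < 0)) stop("S-values must be >= 0", call. = FALSE)
  if (any(diag(S) <= 0))
    stop("self-dose S-values must be > 0 for every organ", call. = FALSE)
  structure(S, class = c("smatrix", "matrix"))
}

#' @rdname read_smatrix
#' @param masses_g Named numeric vector of organ masses, g.
#' @param nuc A `"nuclide"` providing the mean beta energy and photon
#'   lines.
#' @param photon_af Optional square matrix of photon absorbed fractions
#'   (target x source, values in `[0, 1]`; energy absorbed in target per
#'   photon energy emitted in source). When `NULL`, photon energy is
#'   ignored (electrons only).
#' @export
build_smatrix <- function(masses_g, nuc = lu177(), photon_af = NULL) {
  if (is.null(names(masses_g)) || any(masses_g <= 0))
    stop("'masses_g' must be a named vector of positive masses",
         call. = FALSE)
  organs <- tolower(names(masses_g))
  n <- length(organs)
  m_kg <- masses_g / 1000
  S <- matrix(0, n, n, dimnames = list(target = organs, source = organs))
  diag(S) <- 0.5767 * nuc$beta_mean_MeV / m_kg
  if (!is.null(photon_af)) {
    if (!all(dim(photon_af) == n))
      stop("'photon_af' must be a ", n, "x", n, " matrix", call. = FALSE)
    if (any(photon_af < 0 | photon_af > 1))
      stop("absorbed fractions must lie in [0, 1]", call. = FALSE)
    e_photon <- sum(nuc$photons$energy_keV / 1000 * nuc$photons$yield)  # MeV
    S <- S + 0.5767 * e_photon * sweep(photon_af, 1, m_kg, "/")
  }
  structure(S, class = c("smatrix", "matrix"))
}

#' Organ absorbed doses from residence times and an S-matrix
#'
#' The MIRD sum: `D(target) = sum_source tau_source * S(target <- source)`
#' in mGy per MBq administered. Source regions missing from the S-matrix
#' are excluded with a warning.
#'
#' @param taus Named numeric vector of residence times, hours.
#' @param S An `"smatrix"`.
#' @return A named numeric vector of absorbed doses (mGy/MBq) over the
#'   S-matrix target organs, class `"dose_report"`.
#' @export
organ_doses <- function(taus, S) {
  stopifnot(inherits(S, "smatrix"))
  if (any(taus < 0)) stop("residence times must be >= 0", call. = FALSE)
  names(taus) <- tolower(names(taus))
  missing <- setdiff(names(taus), colnames(S))
  if (length(missing)) {
    warning("source regions absent from S-matrix, excluded: ",
            paste(missing, collapse = ", "))
    taus <- taus[setdiff(names(taus), missing)]
  }
  if (!length(taus)) stop("no usable source regions", call. = FALSE)
  tau_vec <- stats::setNames(rep(0, ncol(S)), colnames(S))
  tau_vec[names(taus)] <- taus
  d <- drop(unclass(S) %*% tau_vec)
  structure(d[rownames(S)], class = "dose_report")
}

#' Read a tissue-weighting-factor table
#'
#' CSV `tissue,wT` with a `REMAINDER` row; weights (including the
#' remainder) must sum to 1. The shipped `tissue_weights_icrp60.csv` is
#' the ICRP Publication 60 set (external standard constants).
#'
#' @param path CSV path; default the packaged ICRP-60 table.
#' @return A list with `weights` (named numeric) and `remainder`
#'   (numeric).
#' @export
read_tissue_weights <- function(path = system.file(
    "extdata", "tissue_weights_icrp60.csv", package = "radlig")) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("tissue", "wT") %in% names(df)))
    stop("weights CSV needs columns tissue, wT", call. = FALSE)
  rem <- df$tissue == "REMAINDER"
  if (sum(rem) != 1L)
    stop("weights CSV must contain exactly one REMAINDER row", call. = FALSE)
  w <- stats::setNames(df$wT[!rem], tolower(trimws(df$tissue[!rem])))
  list(weights = w, remainder = df$wT[rem])
}

#' Effective dose from organ equivalent doses
#'
#' `E = sum_T wT * H_T` with radiation weighting 1 for beta/gamma (H
#' numerically equals the absorbed dose, so mGy/MBq in equals mSv/MBq
#' out). The remainder tissue receives the mass-weighted mean equivalent
#' dose of the organs not explicitly weighted (simple mean when masses
#' are not supplied). A weighted tissue absent from the dose report takes
#' the remainder dose, with a warning.
#'
#' @param doses Named numeric vector of organ equivalent doses (mSv/MBq),
#'   e.g. a `"dose_report"`.
#' @param tw A tissue-weight list from [read_tissue_weights()].
#' @param masses_g Optional named organ masses for the mass-weighted
#'   remainder mean.
#' @return Effective dose, mSv/MBq (never above the maximum organ dose).
#' @export
effective_dose <- function(doses, tw, masses_g = NULL) {
  w <- tw$weights
  if (abs(sum(w) + tw$remainder - 1) > 1e-6)
    stop("tissue weights (including remainder) must sum to 1", call. = FALSE)
  if (any(w < 0) || tw$remainder < 0)
    stop("weights must be >= 0", call. = FALSE)
  doses <- stats::setNames(as.numeric(doses), tolower(names(doses)))
  unweighted <- setdiff(names(doses), names(w))
  rem_dose <- if (length(unweighted)) {
    if (!is.null(masses_g)) {
      mm <- masses_g[unweighted]
      if (any(is.na(mm))) {
        warning("masses missing for some remainder organs; using simple mean")
        mean(doses[unweighted])
      } else stats::weighted.mean(doses[unweighted], mm)
    } else mean(doses[unweighted])
  } else if (length(doses)) mean(doses) else 0
  e <- tw$remainder * rem_dose
  for (tissue in names(w)) {
    h <- if (tissue %in% names(doses)) doses[[tissue]] else {
      warning("weighted tissue '", tissue,
              "' absent from dose report; assigned the remainder dose")
      rem_dose
    }
    e <- e + w[[tissue]] * h
  }
  unname(e)
}
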