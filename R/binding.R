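#' Cellular uptake per million cells
#'
#' Converts gamma-counter readings of the surface-bound (acid-strippable)
#' and internalized fractions into percent initial activity per 10^6 cells.
#' The standard is a count of the full applied activity, or a known
#' fraction `f_std` of it, measured in the same counting session so that
#' physical decay cancels.
#'
#' @param surface_cpm,internalized_cpm Counts for the two fractions (CPM).
#' @param standard_cpm Counts of the standard (CPM, must be > 0).
#' @param f_std Fraction of the applied activity represented by the
#'   standard, in `(0, 1]`.
#' @param cells Number of cells in the well (> 0).
#' @return Named numeric vector `c(surface, internalized)` in
#'   %IA / 10^6 cells.
#' @examples
#' uptake_per_million_cells(4790, 0, 100000, cells = 1e5)  # surface 47.9
#' @export
uptake_per_million_cells <- function(surface_cpm, internalized_cpm,
                                     standard_cpm, f_std = 1, cells) {
  if (any(c(surface_cpm, internalized_cpm) < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (standard_cpm <= 0)
    stop("standard counts must be > 0", call. = FALSE)
  if (f_std <= 0 || f_std > 1) stop("'f_std' must be in (0, 1]", call. = FALSE)
  if (cells <= 0) stop("'cells' must be > 0", call. = FALSE)
  applied <- standard_cpm / f_std
  scale <- 1e6 / cells
  c(surface = 100 * surface_cpm / applied * scale,
    internalized = 100 * internalized_cpm / applied * scale)
}

# Deterministic multi-start bounded Levenberg-Marquardt least squares.
# starts: list of named start vectors (tried in order); lower/upper named.
# Returns the converged fit with smallest deviance; ties broken by the
# smallest value of tie_par (when given), then by start order.
multistart_nls <- function(formula, data, starts, lower, upper,
                           tie_par = NULL) {
  best <- NULL; best_sse <- Inf; best_tie <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = as.list(st),
        lower = lower[names(st)], upper = upper[names(st)],
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    tie <- if (is.null(tie_par)) Inf else unname(stats::coef(fit)[tie_par])
    if (sse < best_sse * (1 - 1e-10) ||
        (abs(sse - best_sse) <= 1e-10 * max(best_sse, 1) && tie < best_tie)) {
      best <- fit; best_sse <- sse; best_tie <- tie
    }
  }
  best
}

#' Fit a one-site saturation binding model
#'
#' Specific binding is computed pointwise as total minus nonspecific
#' (negative values floored at zero with a warning) and fitted with the
#' hyperbolic one-site model `B(c) = Bmax * c / (Kd + c)` by bounded
#' least squares with a deterministic log-spaced multi-start grid over
#' plausible Kd decades; ties are broken towards the smallest Kd.
#'
#' @param concentration_nM Radioligand concentrations, nM, strictly
#'   increasing, length >= 4.
#' @param total_cpm,nonspecific_cpm Total and nonspecific bound counts.
#' @return A list of class `"binding_params"` with `Kd` (nM), `Bmax`
#'   (CPM), standard errors `se`, residual `sse` and the underlying `fit`.
#' @export
fit_saturation <- function(concentration_nM, total_cpm, nonspecific_cpm) {
  c_ <- as.numeric(concentration_nM)
  if (length(c_) < 4L) stop("need >= 4 concentration points", call. = FALSE)
  if (any(c_ <= 0) || any(diff(c_) <= 0))
    stop("concentrations must be positive and strictly increasing",
         call. = FALSE)
  if (length(total_cpm) != length(c_) || length(nonspecific_cpm) != length(c_))
    stop("count vectors must align with concentrations", call. = FALSE)
  spec <- total_cpm - nonspecific_cpm
  if (any(spec < 0)) {
    warning("negative specific binding floored at 0 at ",
            sum(spec < 0), " point(s)")
    spec <- pmax(spec, 0)
  }
  dat <- data.frame(c_ = c_, B = spec)
  kd_grid <- 10^seq(log10(min(c_) / 10), log10(max(c_) * 10), length.out = 5)
  bmax_grid <- max(spec) * c(0.5, 0.8, 1, 1.5, 3)
  starts <- list()
  for (k in kd_grid) for (b in bmax_grid)
    starts[[length(starts) + 1L]] <- c(Bmax = b, Kd = k)
  fit <- multistart_nls(B ~ Bmax * c_ / (Kd + c_), dat, starts,
                        lower = c(Bmax = 0, Kd = 1e-12),
                        upper = c(Bmax = Inf, Kd = Inf), tie_par = "Kd")
  if (is.null(fit))
    stop("saturation fit failed to converge from any start; inspect data",
         call. = FALSE)
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  structure(list(Kd = unname(co["Kd"]), Bmax = unname(co["Bmax"]),
                 se = c(Kd = unname(se["Kd"]), Bmax = unname(se["Bmax"])),
                 sse = sum(stats::resid(fit)^2), fit = fit),
            class = "binding_params")
}

#' Fit a one-site competition (displacement) model
#'
#' Fits `B(c) = Bottom + (Top - Bottom) / (1 + c / IC50)` on the log
#' concentration axis (IC50 is parameterised as 10^logIC50), Top and
#' Bottom free, by bounded least squares with a deterministic multi-start
#' grid spanning the competitor concentration decades.
#'
#' @param competitor_nM Competitor concentrations, nM, positive,
#'   length >= 5, spanning the binding transition.
#' @param bound_cpm Bound counts at each concentration.
#' @return A `"binding_params"` list with `IC50` (nM), `Top`, `Bottom`,
#'   `se`, `sse` and `fit`.
#' @export
fit_competition <- function(competitor_nM, bound_cpm) {
  c_ <- as.numeric(competitor_nM)
  if (length(c_) < 5L) stop("need >= 5 competitor points", call. = FALSE)
  if (any(c_ <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(bound_cpm) != length(c_))
    stop("'bound_cpm' must align with concentrations", call. = FALSE)
  if (diff(range(bound_cpm)) <= 1e-9 * max(abs(bound_cpm), 1))
    stop("binding curve is flat (Top = Bottom): IC50 is unidentifiable",
         call. = FALSE)
  dat <- data.frame(c_ = c_, B = as.numeric(bound_cpm))
  l_grid <- seq(log10(min(c_)), log10(max(c_)), length.out = 5)
  starts <- lapply(l_grid, function(l)
    c(Top = max(bound_cpm), Bottom = min(bound_cpm), lIC50 = l))
  fit <- multistart_nls(
    B ~ Bottom + (Top - Bottom) / (1 + c_ / 10^lIC50), dat, starts,
    lower = c(Top = 0, Bottom = 0, lIC50 = log10(min(c_)) - 3),
    upper = c(Top = Inf, Bottom = Inf, lIC50 = log10(max(c_)) + 3),
    tie_par = "lIC50")
  if (is.null(fit))
    stop("competition fit failed to converge from any start", call. = FALSE)
  co <- stats::coef(fit)
  ic50 <- 10^unname(co["lIC50"])
  if (ic50 < min(c_) || ic50 > max(c_))
    stop("fitted IC50 (", signif(ic50, 4),
         " nM) lies outside the data range: transition not bracketed",
         call. = FALSE)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(IC50 = ic50, Top = unname(co["Top"]),
                 Bottom = unname(co["Bottom"]),
                 se = c(logIC50 = unname(se["lIC50"]),
                        Top = unname(se["Top"]),
                        Bottom = unname(se["Bottom"])),
                 sse = sum(stats::resid(fit)^2), fit = fit),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat("<binding_params>\n")
  for (nm in intersect(c("Kd", "Bmax", "IC50", "Ki", "Top", "Bottom"),
                       names(x)))
    cat(sprintf("  %-6s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + [radioligand] / Kd)`: corrects a competition IC50 for
#' the occupancy of the receptor by the radioligand present in the assay.
#'
#' @param IC50 Half-maximal inhibitory concentration, nM (> 0).
#' @param radioligand_nM Radioligand concentration used in the assay, nM
#'   (>= 0).
#' @param Kd Radioligand dissociation constant, nM (> 0).
#' @return Inhibition constant Ki, nM. Always `<= IC50`.
#' @examples
#' cheng_prusoff(17.709, 0.75, 4.358)
#' @export
cheng_prusoff <- function(IC50, radioligand_nM, Kd) {
  if (any(Kd <= 0)) stop("'Kd' must be > 0", call. = FALSE)
  if (any(IC50 <= 0)) stop("'IC50' must be > 0", call. = FALSE)
  if (any(radioligand_nM < 0))
    stop("'radioligand_nM' must be >= 0", call. = FALSE)
  IC50 / (1 + radioligand_nM / Kd)
}
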