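#' Radionuclide physical constants
#'
#' Constructs a nuclide object holding the physical half-life and emission
#' constants needed for decay correction and dosimetry. Time is handled in
#' hours throughout the package; the constructor accepts the half-life in
#' days or hours with an explicit unit tag.
#'
#' @param name Nuclide label, e.g. `"Lu-177"`.
#' @param half_life Physical half-life, in the unit given by `half_life_unit`.
#' @param half_life_unit Either `"hours"` or `"days"`.
#' @param beta_mean_MeV Mean beta (electron) energy emitted per decay, MeV.
#' @param photon_keV Photon emission energies, keV.
#' @param photon_yield Photon yields (fraction of decays), same length as
#'   `photon_keV`, each in `[0, 1]`.
#'
#' @return An object of class `"nuclide"`: a list with elements `name`,
#'   `half_life_h`, `lambda_h` (physical decay constant, 1/h),
#'   `beta_mean_MeV` and a `photons` data frame.
#' @examples
#' lu <- nuclide("Lu-177", 6.73, "days", beta_mean_MeV = 0.1335,
#'               photon_keV = c(208, 113), photon_yield = c(0.11, 0.06))
#' decay_factor(24, lu)
#' @export
nuclide <- function(name, half_life, half_life_unit = c("hours", "days"),
                    beta_mean_MeV = 0, photon_keV = numeric(),
                    photon_yield = numeric()) {
  half_life_unit <- match.arg(half_life_unit)
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0)
    stop("'half_life' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(beta_mean_MeV) || beta_mean_MeV < 0)
    stop("'beta_mean_MeV' must be >= 0", call. = FALSE)
  if (length(photon_keV) != length(photon_yield))
    stop("'photon_keV' and 'photon_yield' must have the same length",
         call. = FALSE)
  if (any(photon_yield < 0 | photon_yield > 1))
    stop("photon yields must lie in [0, 1]", call. = FALSE)
  hl_h <- if (half_life_unit == "days") half_life * 24 else half_life
  structure(list(
    name = as.character(name),
    half_life_h = hl_h,
    lambda_h = log(2) / hl_h,
    beta_mean_MeV = beta_mean_MeV,
    photons = data.frame(energy_keV = as.numeric(photon_keV),
                         yield = as.numeric(photon_yield))
  ), class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %.4g h (%.4g d), mean E_beta = %.4g MeV\n",
              x$name, x$half_life_h, x$half_life_h / 24, x$beta_mean_MeV))
  if (nrow(x$photons))
    cat(sprintf("  photons: %s\n",
                paste(sprintf("%.0f keV @ %.1f%%", x$photons$energy_keV,
                              100 * x$photons$yield), collapse = ", ")))
  invisible(x)
}

#' Default Lutetium-177 constants
#'
#' Lu-177 as shipped in the package nuclide table: physical half-life
#' 6.73 days, mean beta energy 0.1335 MeV (external standard constant; the
#' 490 keV figure often quoted for Lu-177 is the spectrum endpoint region,
#' not the mean), and the two main low-energy gamma lines (208 keV at 11%,
#' 113 keV at 6%) used for gamma-counter and SPECT work.
#'
#' @return A `"nuclide"` object.
#' @export
lu177 <- function() {
  tab <- read_nuclide_table(system.file("extdata", "nuclides.csv",
                                        package = "radlig"))
  tab[["Lu-177"]]
}

#' Read a nuclide constants table
#'
#' Delimited text with columns `name`, `half_life_days`, `beta_mean_MeV`,
#' `photon_keV_yield` (semicolon-separated `energy:yield` pairs, may be
#' empty).
#'
#' @param path Path to the CSV file.
#' @return A named list of `"nuclide"` objects.
#' @export
read_nuclide_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "half_life_days", "beta_mean_MeV", "photon_keV_yield")
  if (!all(need %in% names(df)))
    stop("nuclide table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    spec <- trimws(df$photon_keV_yield[i])
    if (is.na(spec) || spec == "") {
      e <- numeric(); y <- numeric()
    } else {
      pairs <- strsplit(strsplit(spec, ";")[[1]], ":")
      e <- vapply(pairs, function(p) as.numeric(p[1]), 0)
      y <- vapply(pairs, function(p) as.numeric(p[2]), 0)
    }
    nuclide(df$name[i], df$half_life_days[i], "days",
            beta_mean_MeV = df$beta_mean_MeV[i],
            photon_keV = e, photon_yield = y)
  })
  names(out) <- df$name
  out
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `elapsed_h` hours,
#' `2^(-elapsed_h / T1/2)`. Negative elapsed times are allowed and give
#' factors above 1 (back-correction).
#'
#' @param elapsed_h Elapsed time in hours (vectorised; may be negative).
#' @param nuc A `"nuclide"` object.
#' @return Numeric decay factor(s), strictly positive.
#' @export
decay_factor <- function(elapsed_h, nuc) {
  stopifnot(inherits(nuc, "nuclide"))
  if (any(!is.finite(elapsed_h)))
    stop("'elapsed_h' must be finite", call. = FALSE)
  2^(-elapsed_h / nuc$half_life_h)
}

#' Elapsed hours between two timestamps
#'
#' @param t,t0 Timestamps (`POSIXct` or anything `difftime` accepts).
#' @return Numeric hours (`t - t0`).
#' @export
elapsed_hours <- function(t, t0) {
  as.numeric(difftime(t, t0, units = "hours"))
}

#' Decay-correct an activity measurement to a reference time
#'
#' Divides a measured activity by the decay factor for the interval from
#' the reference time to the measurement time, i.e. the inverse of forward
#' decay: an activity measured after the reference time is corrected
#' upwards.
#'
#' @param value_MBq Measured activity, MBq (must be >= 0).
#' @param measured_at,reference_time Timestamps.
#' @param nuc A `"nuclide"` object.
#' @return Activity in MBq referred to `reference_time`.
#' @examples
#' lu <- lu177()
#' t0 <- as.POSIXct("2026-01-05 09:00", tz = "UTC")
#' decay_correct(37, t0 + 24 * 3600, t0, lu)  # ~41.0 MBq at reference
#' @export
decay_correct <- function(value_MBq, measured_at, reference_time, nuc) {
  if (any(value_MBq < 0)) stop("activity must be >= 0", call. = FALSE)
  dt <- elapsed_hours(measured_at, reference_time)
  value_MBq / decay_factor(dt, nuc)
}

#' Molar (specific) activity
#'
#' Activity per amount of substance, reported in GBq per micromole.
#'
#' @param activity_GBq Activity, GBq.
#' @param amount_nmol Amount of precursor, nmol (must be > 0).
#' @return Molar activity, GBq/umol.
#' @examples
#' molar_activity(1, 50)  # 20 GBq/umol
#' @export
molar_activity <- function(activity_GBq, amount_nmol) {
  if (any(amount_nmol <= 0)) stop("'amount_nmol' must be > 0", call. = FALSE)
  activity_GBq / (amount_nmol * 1e-3)
}
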