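#' Chromatographic count profile
#'
#' A one-dimensional activity profile from an iTLC strip scan (positions in
#' mm) or a radio-HPLC trace (retention time in minutes), used to quantify
#' radiochemical purity by peak-window integration.
#'
#' @param positions Strictly increasing numeric positions.
#' @param counts Non-negative counts, same length.
#' @param kind `"iTLC"` or `"radio-HPLC"`.
#' @return An object of class `"count_profile"`.
#' @export
count_profile <- function(positions, counts, kind = c("iTLC", "radio-HPLC")) {
  kind <- match.arg(kind)
  positions <- as.numeric(positions); counts <- as.numeric(counts)
  if (length(positions) != length(counts))
    stop("'positions' and 'counts' must have the same length", call. = FALSE)
  if (any(diff(positions) <= 0))
    stop("'positions' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and >= 0", call. = FALSE)
  structure(list(positions = positions, counts = counts, kind = kind),
            class = "count_profile")
}

#' Read a count profile CSV (columns position, counts)
#' @param path CSV path.
#' @param kind Profile kind tag.
#' @return A `"count_profile"`.
#' @export
read_count_profile <- function(path, kind = c("iTLC", "radio-HPLC")) {
  df <- utils::read.csv(path)
  if (!all(c("position", "counts") %in% names(df)))
    stop("profile CSV needs columns 'position' and 'counts'", call. = FALSE)
  count_profile(df$position, df$counts, kind)
}

#' Fraction of counts inside a position window
#'
#' Percent of total counts falling in the half-open window `[lo, hi)`.
#' Half-open intervals are used everywhere so that a partition of the
#' position axis tiles without double counting.
#'
#' @param profile A `"count_profile"`.
#' @param window Numeric length-2 vector `c(lo, hi)`, `lo < hi`.
#' @return Percent in `[0, 100]`.
#' @export
window_fraction <- function(profile, window) {
  stopifnot(inherits(profile, "count_profile"))
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("'window' must be c(lo, hi) with lo < hi", call. = FALSE)
  total <- sum(profile$counts)
  if (total <= 0)
    stop("profile has zero total counts; cannot compute fractions",
         call. = FALSE)
  if (window[2] <= min(profile$positions) || window[1] > max(profile$positions))
    stop("window does not overlap the profile position range", call. = FALSE)
  inside <- profile$positions >= window[1] & profile$positions < window[2]
  100 * sum(profile$counts[inside]) / total
}

#' Radiochemical purity from a product-peak window
#'
#' Percent of total profile counts inside the product peak window. For the
#' default iTLC convention with an EDTA mobile phase, the labeled product
#' stays at the origin and free radiometal (as its EDTA complex) migrates
#' to the solvent front, so the product window covers the origin half of
#' the strip.
#'
#' @inheritParams window_fraction
#' @param product_window Half-open window `c(lo, hi)` containing the
#'   product peak.
#' @return Percent purity, with attributes `kind` (profile kind) and
#'   `acceptable` (logical; labeling acceptance threshold of 90%).
#' @export
radiochemical_purity <- function(profile, product_window) {
  p <- window_fraction(profile, product_window)
  structure(p, kind = profile$kind, acceptable = p >= 90)
}

#' Serum-stability summary table
#'
#' Pivots free-radiometal stability records into a temperature-by-time
#' table of free activity percentages. Missing combinations are left `NA`
#' (absent), never imputed.
#'
#' @param records Data frame with columns `temperature_C`, `time_h`,
#'   `free_pct` (each `free_pct` in `[0, 100]`); `(temperature, time)` keys
#'   must be unique.
#' @return A data frame with one row per temperature and one column per
#'   time (named `t<h>h`), plus a leading `temperature_C` column.
#' @export
stability_summary <- function(records) {
  need <- c("temperature_C", "time_h", "free_pct")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    return(data.frame(temperature_C = numeric(0)))
  if (any(records$free_pct < 0 | records$free_pct > 100))
    stop("'free_pct' must lie in [0, 100]", call. = FALSE)
  key <- paste(records$temperature_C, records$time_h)
  if (anyDuplicated(key))
    stop("duplicate (temperature, time) keys in stability records",
         call. = FALSE)
  temps <- sort(unique(records$temperature_C))
  times <- sort(unique(records$time_h))
  out <- data.frame(temperature_C = temps)
  for (tt in times) {
    col <- rep(NA_real_, length(temps))
    sel <- records$time_h == tt
    col[match(records$temperature_C[sel], temps)] <- records$free_pct[sel]
    out[[sprintf("t%gh", tt)]] <- col
  }
  out
}
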