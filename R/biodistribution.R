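#' Gamma-counter worksheet for one animal
#'
#' Holds the raw per-organ counts, sample masses and counting timestamps
#' for a single animal, together with the calibration standards (aliquots
#' of a known fraction of the injected activity counted in the same
#' sessions).
#'
#' @param animal_id Animal label.
#' @param injection_time Injection timestamp (`POSIXct`).
#' @param injected_activity_MBq Administered activity, MBq.
#' @param records Data frame with columns `organ`, `mass_g` (> 0),
#'   `cpm` (>= 0), `count_time` (`POSIXct`).
#' @param standards Data frame with columns `f_std` (fraction of injected
#'   activity in `(0, 1]`), `cpm`, `count_time`; at least one row.
#' @return An object of class `"count_worksheet"`.
#' @export
count_worksheet <- function(animal_id, injection_time, injected_activity_MBq,
                            records, standards) {
  if (!all(c("organ", "mass_g", "cpm", "count_time") %in% names(records)))
    stop("records need columns organ, mass_g, cpm, count_time", call. = FALSE)
  if (!all(c("f_std", "cpm", "count_time") %in% names(standards)))
    stop("standards need columns f_std, cpm, count_time", call. = FALSE)
  if (nrow(standards) < 1L)
    stop("at least one standard is required", call. = FALSE)
  if (any(records$mass_g <= 0)) stop("masses must be > 0", call. = FALSE)
  if (any(records$cpm < 0) || any(standards$cpm < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (any(standards$f_std <= 0 | standards$f_std > 1))
    stop("'f_std' must be in (0, 1]", call. = FALSE)
  structure(list(animal_id = as.character(animal_id),
                 injection_time = injection_time,
                 injected_activity_MBq = injected_activity_MBq,
                 records = records, standards = standards),
            class = "count_worksheet")
}

#' Write / read worksheet CSVs
#'
#' The worksheet file mixes three row kinds, discriminated by the first
#' field: header rows (`animal_id`, `injection_time`,
#' `injected_activity_MBq`), standard rows (`STANDARD,f_std,cpm,count_time`)
#' and organ record rows (`organ,mass_g,cpm,count_time`). Timestamps are
#' `%Y-%m-%d %H:%M:%S` UTC.
#'
#' @param ws A `"count_worksheet"`.
#' @param path File path.
#' @return `read_worksheet_csv` returns a `"count_worksheet"`;
#'   `write_worksheet_csv` returns `path` invisibly.
#' @export
write_worksheet_csv <- function(ws, path) {
  stopifnot(inherits(ws, "count_worksheet"))
  fmt_t <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  lines <- c(
    paste0("animal_id,", ws$animal_id),
    paste0("injection_time,", fmt_t(ws$injection_time)),
    paste0("injected_activity_MBq,",
           format(ws$injected_activity_MBq, digits = 15)),
    sprintf("STANDARD,%s,%s,%s", format(ws$standards$f_std, digits = 15),
            format(ws$standards$cpm, digits = 15),
            fmt_t(ws$standards$count_time)),
    sprintf("%s,%s,%s,%s", ws$records$organ,
            format(ws$records$mass_g, digits = 15),
            format(ws$records$cpm, digits = 15),
            fmt_t(ws$records$count_time)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_worksheet_csv
#' @export
read_worksheet_csv <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  hdr <- list(); recs <- list(); stds <- list()
  parse_t <- function(s) as.POSIXct(s, format = "%Y-%m-%d %H:%M:%S",
                                    tz = "UTC")
  for (p in parts) {
    key <- p[[1]]
    if (key %in% c("animal_id", "injection_time", "injected_activity_MBq")) {
      hdr[[key]] <- p[[2]]
    } else if (key == "STANDARD") {
      stds[[length(stds) + 1L]] <- data.frame(
        f_std = as.numeric(p[2]), cpm = as.numeric(p[3]),
        count_time = parse_t(p[4]))
    } else {
      recs[[length(recs) + 1L]] <- data.frame(
        organ = key, mass_g = as.numeric(p[2]), cpm = as.numeric(p[3]),
        count_time = parse_t(p[4]))
    }
  }
  count_worksheet(hdr$animal_id, parse_t(hdr$injection_time),
                  as.numeric(hdr$injected_activity_MBq),
                  do.call(rbind, recs), do.call(rbind, stds))
}

#' Percent injected activity per gram for one worksheet
#'
#' Converts raw organ counts to %IA/g. Each organ record is matched to the
#' standard counted nearest in time (error if the gap exceeds 24 h); both
#' sample and standard counts are decay-referenced to the injection time
#' before taking the ratio, so the result reflects biological distribution
#' only. When sample and standard share a counting session the decay
#' factors cancel exactly.
#'
#' @param ws A `"count_worksheet"`.
#' @param nuc A `"nuclide"` (default [lu177()]).
#' @param max_standard_gap_h Maximum tolerated gap between an organ count
#'   and its matched standard (default 24 h).
#' @return Data frame with columns `animal_id`, `organ` (lower-cased),
#'   `time_h` (hours post-injection at counting), `pia` (%IA for the
#'   sample) and `pia_g` (%IA per gram).
#' @export
percent_ia_per_gram <- function(ws, nuc = lu177(), max_standard_gap_h = 24) {
  stopifnot(inherits(ws, "count_worksheet"))
  rec <- ws$records
  t_rec <- elapsed_hours(rec$count_time, ws$injection_time)
  t_std <- elapsed_hours(ws$standards$count_time, ws$injection_time)
  if (any(t_rec < -1e-6) || any(t_std < -1e-6))
    stop("counting before injection time: check timestamps", call. = FALSE)
  std_corr <- ws$standards$cpm / decay_factor(t_std, nuc) / ws$standards$f_std
  pia <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    j <- which.min(abs(t_std - t_rec[i]))
    if (abs(t_std[j] - t_rec[i]) > max_standard_gap_h)
      stop("no standard within ", max_standard_gap_h,
           " h of organ count for '", rec$organ[i], "'", call. = FALSE)
    samp_corr <- rec$cpm[i] / decay_factor(t_rec[i], nuc)
    pia[i] <- 100 * samp_corr / std_corr[j]
  }
  data.frame(animal_id = ws$animal_id,
             organ = tolower(trimws(rec$organ)),
             time_h = t_rec, pia = pia, pia_g = pia / rec$mass_g)
}

#' Summarize per-animal %IA/g into a biodistribution table
#'
#' Groups per-animal results by organ and timepoint and reports the
#' arithmetic mean, sample standard deviation (n - 1 denominator; `NA`
#' when n = 1) and group size. Timepoints are grouped on the nominal
#' post-injection hour (rounded to `digits`).
#'
#' @param per_animal A data frame as returned by [percent_ia_per_gram()]
#'   (rows from several animals may be concatenated), or a list of such
#'   data frames.
#' @param digits Rounding applied to `time_h` for grouping (default 3).
#' @return A data frame of class `"biodist_table"` with columns `organ`,
#'   `time_h`, `mean_pia_g`, `sd`, `n`.
#' @export
summarize_biodist <- function(per_animal, digits = 3) {
  if (is.list(per_animal) && !is.data.frame(per_animal))
    per_animal <- do.call(rbind, per_animal)
  if (nrow(per_animal) == 0L) stop("no records to summarize", call. = FALSE)
  grp <- interaction(per_animal$organ, round(per_animal$time_h, digits),
                     drop = TRUE)
  agg <- lapply(split(per_animal, grp), function(d) data.frame(
    organ = d$organ[1], time_h = round(d$time_h[1], digits),
    mean_pia_g = mean(d$pia_g),
    sd = if (nrow(d) > 1) stats::sd(d$pia_g) else NA_real_,
    n = nrow(d)))
  out <- do.call(rbind, agg)
  out <- out[order(out$organ, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("biodist_table", "data.frame")
  out
}

#' Tumor-to-normal tissue ratios
#'
#' Ratio of tumor mean %IA/g to each other organ's mean %IA/g, per
#' timepoint. Cells where the organ mean is zero (or the organ is missing
#' at that timepoint) are marked absent with a warning rather than
#' reported as infinite.
#'
#' @param bt A `"biodist_table"` from [summarize_biodist()].
#' @param tumor_label Organ label of the tumor (matched case-insensitively,
#'   default `"tumor"`).
#' @return Data frame with columns `organ`, `time_h`, `ratio`
#'   (tumor / organ).
#' @export
tn_ratios <- function(bt, tumor_label = "tumor") {
  tumor_label <- tolower(tumor_label)
  tum <- bt[bt$organ == tumor_label, , drop = FALSE]
  if (nrow(tum) == 0L)
    stop("no '", tumor_label, "' rows in the biodistribution table",
         call. = FALSE)
  oth <- bt[bt$organ != tumor_label, , drop = FALSE]
  tmean <- stats::setNames(tum$mean_pia_g, sprintf("%.6f", tum$time_h))
  ratio <- rep(NA_real_, nrow(oth))
  for (i in seq_len(nrow(oth))) {
    key <- sprintf("%.6f", oth$time_h[i])
    if (!key %in% names(tmean)) next  # tumor absent at this timepoint
    if (oth$mean_pia_g[i] <= 0) {
      warning("organ mean is 0 for ", oth$organ[i], " at ", key,
              " h; ratio marked absent")
      next
    }
    ratio[i] <- tmean[[key]] / oth$mean_pia_g[i]
  }
  data.frame(organ = oth$organ, time_h = oth$time_h, ratio = ratio)
}
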