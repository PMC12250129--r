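#' Humane-endpoint event day from a body-weight series
#'
#' Returns the first observation day on which body weight has dropped by
#' at least `threshold` (default 20%) relative to the baseline-day weight;
#' the boundary is inclusive ("20% or more"). Animals reaching the
#' endpoint are treated as events (deaths) in the survival analysis, not
#' censored.
#'
#' @param day Observation days (numeric).
#' @param weight_g Body weights, g, same length.
#' @param baseline_day Day whose weight is the reference (must be present
#'   in `day` with weight > 0).
#' @param threshold Fractional weight-loss threshold (default 0.20).
#' @return The first qualifying day, or `NA` if the threshold is never
#'   reached (or the series is empty).
#' @export
humane_endpoint_events <- function(day, weight_g, baseline_day = min(day),
                                   threshold = 0.20) {
  if (length(day) == 0L) return(NA_real_)
  if (length(day) != length(weight_g))
    stop("'day' and 'weight_g' must align", call. = FALSE)
  if (any(weight_g < 0)) stop("weights must be >= 0", call. = FALSE)
  i0 <- match(baseline_day, day)
  if (is.na(i0) || weight_g[i0] <= 0)
    stop("baseline day not found or baseline weight is 0", call. = FALSE)
  ord <- order(day)
  hit <- weight_g[ord] <= (1 - threshold) * weight_g[i0] + 1e-12
  if (!any(hit)) return(NA_real_)
  day[ord][which(hit)[1]]
}

#' Kaplan-Meier product-limit curve
#'
#' Computes the product-limit survivor estimate. Censored subjects leave
#' the risk set without producing a step; a death and a censoring tied at
#' the same time are resolved death-first (the censored subject is still
#' at risk at that death time), the standard convention.
#'
#' @param time Event/censoring times (> 0).
#' @param event Event indicator: 1/TRUE = death (or humane endpoint),
#'   0/FALSE = censored.
#' @return An object of class `"km_curve"`: a data frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `surv`), with
#'   `S(0) = 1` implicit before the first row.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) stop("need >= 1 record", call. = FALSE)
  if (any(time <= 0)) stop("times must be > 0", call. = FALSE)
  event <- as.integer(as.logical(event))
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  s <- 1
  rows <- lapply(ut, function(tt) {
    n_risk <- sum(time >= tt)                 # death-first tie rule
    d <- sum(time == tt & event == 1)
    s <<- s * (1 - d / n_risk)
    data.frame(time = tt, n_risk = n_risk, n_event = d, surv = s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival time
#'
#' The smallest survival time for which the survivor function is less
#' than or equal to 0.5. Returns `NA` ("not reached") when the curve
#' never drops to 0.5.
#'
#' @param km A `"km_curve"`.
#' @return Median survival time, or `NA_real_` if not reached.
#' @export
median_survival <- function(km) {
  stopifnot(inherits(km, "km_curve"))
  hit <- which(km$surv <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  km$time[hit[1]]
}

#' Two-group log-rank test
#'
#' Mantel-Cox log-rank: at each pooled distinct event time, the observed
#' deaths in group A are compared with the hypergeometric expectation
#' given the risk sets; `chi^2 = (O_A - E_A)^2 / V` with V the sum of
#' hypergeometric variances (tie-corrected), referred to chi-square with
#' 1 degree of freedom.
#'
#' @param time_a,event_a Times and event indicators for group A.
#' @param time_b,event_b Times and event indicators for group B.
#' @return List with `chisq`, `p`, `df = 1`, `observed` and `expected`
#'   (length-2, groups A and B).
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    stop("both groups must be non-empty", call. = FALSE)
  time <- c(time_a, time_b)
  event <- as.integer(as.logical(c(event_a, event_b)))
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))
  ut <- sort(unique(time[event == 1]))
  if (!length(ut))
    stop("no events in the pooled sample; log-rank undefined", call. = FALSE)
  o_a <- 0; e_a <- 0; v <- 0
  for (tt in ut) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 1L)
    d <- sum(time == tt & event == 1)
    d_a <- sum(time == tt & event == 1 & grp == 1L)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(list(chisq = 0, p = 1, df = 1L,
                          observed = c(o_a, sum(event) - o_a),
                          expected = c(e_a, sum(event) - e_a)))
  chisq <- (o_a - e_a)^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L, observed = c(o_a, sum(event) - o_a),
       expected = c(e_a, sum(event) - e_a))
}

#' Lifespan increase relative to control
#'
#' `100 * (median_treated - median_control) / median_control`, percent.
#' Propagates `NA` when either median is not reached.
#'
#' @param median_treated,median_control Median survival times, days.
#' @return Percent lifespan increase (may be negative), or `NA`.
#' @examples
#' lifespan_increase(34, 26)  # 30.77
#' @export
lifespan_increase <- function(median_treated, median_control) {
  if (is.na(median_treated) || is.na(median_control)) return(NA_real_)
  if (median_control <= 0)
    stop("control median must be > 0", call. = FALSE)
  100 * (median_treated - median_control) / median_control
}

#' Efficacy summary across treatment arms
#'
#' Per-group Kaplan-Meier median survival, pairwise log-rank tests
#' against the control arm, and lifespan increase.
#'
#' @param subjects Data frame with columns `id`, `group`, `time_days`,
#'   `event` (0/1).
#' @param control Label of the control group.
#' @return List with `medians` (data frame `group`, `n`, `median_days`),
#'   `tests` (data frame `group`, `chisq`, `p`), and `lifespan_increase`
#'   (data frame `group`, `percent`).
#' @export
efficacy_summary <- function(subjects, control) {
  need <- c("group", "time_days", "event")
  if (!all(need %in% names(subjects)))
    stop("subjects need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!control %in% subjects$group)
    stop("control group '", control, "' not found", call. = FALSE)
  groups <- unique(subjects$group)
  med <- vapply(groups, function(g) {
    d <- subjects[subjects$group == g, ]
    median_survival(km_curve(d$time_days, d$event))
  }, 0)
  n <- vapply(groups, function(g) sum(subjects$group == g), 0L)
  ctrl <- subjects[subjects$group == control, ]
  treated <- setdiff(groups, control)
  tests <- do.call(rbind, lapply(treated, function(g) {
    d <- subjects[subjects$group == g, ]
    lr <- logrank(d$time_days, d$event, ctrl$time_days, ctrl$event)
    data.frame(group = g, chisq = lr$chisq, p = lr$p)
  }))
  li <- data.frame(group = treated,
                   percent = vapply(treated, function(g)
                     lifespan_increase(med[[g]], med[[control]]), 0))
  list(medians = data.frame(group = groups, n = n, median_days = unname(med)),
       tests = tests, lifespan_increase = li)
}
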